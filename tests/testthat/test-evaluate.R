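test_that("cascade units decompose as specified", {
  s <- simplify_bel(parse_bel_statement(
    "p(HGNC:TIMP2) decreases cat(p(HGNC:MMP2))"))
  expect_setequal(extract_units(s, "term"), c("HGNC:TIMP2", "HGNC:MMP2"))
  expect_identical(extract_units(s, "function"), "act{HGNC:MMP2}")
  expect_identical(extract_units(s, "function_secondary"), "act")
  expect_identical(extract_units(s, "relationship"),
                   "{HGNC:TIMP2} decreases {HGNC:MMP2}")
  expect_identical(extract_units(s, "statement"),
                   "p(HGNC:TIMP2) decreases act(p(HGNC:MMP2))")
  expect_error(extract_units(s, "nope"), "unknown cascade level")

  # modification carriers are function-level units
  s2 <- simplify_bel(parse_bel_statement(
    "cat(p(MGI:Crk)) increases p(MGI:Bcar1, pmod(P))"))
  expect_setequal(extract_units(s2, "function"),
                  c("act{MGI:Crk}", "pmod{MGI:Bcar1}"))

  # a nested statement adds its inner relationship as an extra unit
  nested <- simplify_bel(parse_bel_statement(
    "p(HGNC:HGF) decreases (p(HGNC:FAS) increases bp(GOBP:\"cell death\"))"))
  expect_length(extract_units(nested, "relationship"), 2L)
})

test_that("equal annotation sets score 1.0 at every level", {
  corpus <- gen_corpus(synth_config(n_sentences = 25, seed = 5))
  report <- score_bel(corpus, corpus)
  expect_equal(report$precision, rep(1, 6))
  expect_equal(report$recall, rep(1, 6))
  expect_equal(report$f, rep(1, 6))
})

test_that("track-equivalent predictions earn full statement credit", {
  gold <- list(s1 = "cat(p(MGI:Crk)) directlyIncreases p(MGI:Bcar1,pmod(P))")
  pred <- list(s1 = "act(p(MGI:Crk)) -> p(MGI:Bcar1,pmod(P,S,41))")
  report <- score_bel(gold, pred)
  expect_equal(report_row(report, "statement")$f, 1)
})

test_that("a flipped relationship loses statement and relationship credit but keeps terms", {
  gold <- list(s1 = "cat(p(MGI:Crk)) directlyIncreases p(MGI:Bcar1,pmod(P))")
  pred <- list(s1 = "act(p(MGI:Crk)) -| p(MGI:Bcar1,pmod(P))")
  report <- score_bel(gold, pred)
  expect_equal(report_row(report, "term")$f, 1)
  expect_equal(report_row(report, "function")$f, 1)
  expect_equal(report_row(report, "relationship")$f, 0)
  expect_equal(report_row(report, "statement")$f, 0)
})

test_that("sentences present in only one set contribute fp or fn", {
  gold <- list(s1 = "p(HGNC:A1CF) increases p(HGNC:AAAS)")
  pred <- list(s2 = "p(HGNC:A1CF) increases p(HGNC:AAAS)")
  report <- score_bel(gold, pred)
  st <- report_row(report, "statement")
  expect_equal(c(st$tp, st$fp, st$fn), c(0, 1, 1))
  # empty prediction: precision convention 1.0, recall 0
  report2 <- score_bel(gold, stats::setNames(list(), character()))
  st2 <- report_row(report2, "statement")
  expect_equal(c(st2$precision, st2$recall, st2$f), c(1, 0, 0))
})

test_that("duplicate predictions neither help nor hurt", {
  gold <- list(s1 = "p(HGNC:A1CF) increases p(HGNC:AAAS)")
  pred <- list(s1 = c("p(HGNC:A1CF) increases p(HGNC:AAAS)",
                      "p(HGNC:A1CF) -> p(HGNC:AAAS)"))
  report <- score_bel(gold, pred)
  expect_equal(report_row(report, "statement")$f, 1)
})

test_that("swapping gold and prediction swaps precision and recall, F unchanged", {
  corpus <- gen_corpus(synth_config(n_sentences = 40, seed = 8))
  pert <- perturb(corpus, perturb_spec(flip_relationship = 0.2,
                                       drop_statement = 0.1, seed = 2))
  ab <- score_iaa(corpus, pert$predicted)
  ba <- score_iaa(pert$predicted, corpus)
  expect_equal(ab$precision, ba$recall)
  expect_equal(ab$recall, ba$precision)
  expect_equal(ab$f, ba$f)
})

test_that("micro counts conserve and statement credit is monotone", {
  corpus <- gen_corpus(synth_config(n_sentences = 50, seed = 13))
  pert <- perturb(corpus, perturb_spec(flip_relationship = 0.15,
                                       swap_entity = 0.1,
                                       add_statement = 0.1, seed = 4))
  report <- score_bel(corpus, pert$predicted)
  gold_sets <- as_annotation_set(corpus)
  pred_sets <- as_annotation_set(pert$predicted)
  count_units <- function(sets, level) {
    sum(vapply(sets, function(stmts) {
      length(unique(unlist(lapply(stmts, function(s) {
        extract_units(simplify_bel(s), level)
      }))))
    }, 0L))
  }
  for (lv in report$level) {
    row <- report_row(report, lv)
    expect_equal(row$tp + row$fn, count_units(gold_sets, lv), label = lv)
    expect_equal(row$tp + row$fp, count_units(pred_sets, lv), label = lv)
  }
  expect_lte(report_row(report, "statement")$tp,
             report_row(report, "relationship")$tp)
})

test_that("the scorer agrees with the brute-force matcher on small sets", {
  specs <- list(
    perturb_spec(seed = 1),
    perturb_spec(flip_relationship = 0.3, seed = 2),
    perturb_spec(swap_entity = 0.3, drop_function = 0.2, seed = 3),
    perturb_spec(drop_statement = 0.3, add_statement = 0.4, seed = 4)
  )
  for (sp in specs) {
    corpus <- gen_corpus(synth_config(n_sentences = 6,
                                      two_statement_share = 1, seed = 21))
    pert <- perturb(corpus, sp)
    report <- score_bel(corpus, pert$predicted)
    for (lv in report$level) {
      row <- report_row(report, lv)
      expect_equal(unname(oracle_counts(corpus, pert$predicted, lv)),
                   c(row$tp, row$fp, row$fn),
                   label = paste(lv, sp$rates["flip_relationship"]))
    }
  }
})
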