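make_record <- function(bel_id = "B1",
                        statement = "p(HGNC:IL6) increases p(HGNC:CRP)",
                        sentence = sprintf(
                          "Sufficiently long supporting evidence text for record %s.",
                          bel_id),
                        sentence_id = paste0("S", bel_id),
                        pmid = "123456") {
  data.frame(bel_id = bel_id, statement = statement,
             sentence_id = sentence_id, sentence = sentence, pmid = pmid,
             stringsAsFactors = FALSE)
}

test_that("evidence-length bounds are inclusive at 36 and 425 characters", {
  recs <- rbind(
    make_record("B1", sentence = strrep("a", 35)),
    make_record("B2", sentence = strrep("a", 36)),
    make_record("B3", sentence = strrep("a", 425)),
    make_record("B4", sentence = strrep("a", 426))
  )
  res <- filter_corpus(recs)
  expect_setequal(res$kept$bel_id, c("B2", "B3"))
  expect_true(all(grepl("evidence-length", res$rejected$rules)))
})

test_that("statement-level filter rules fire individually", {
  recs <- rbind(
    make_record("B1", "composite(p(MGI:Il13),p(MGI:Ifng)) increases bp(GOBP:inflammation)"),
    make_record("B2", "p(HGNC:A1BG) increases complex(p(HGNC:AKT1), p(HGNC:AKT2), p(HGNC:AKT3), p(HGNC:GSK3B))"),
    make_record("B3", "p(RGD:Fas) increases p(HGNC:CRP)"),
    make_record("B4", "p(HGNC:IL6) increases p(HGNC:CRP)", pmid = "n/a"),
    make_record("B5", "g(HGNC:ERBB2) increases r(HGNC:ERBB2)")
  )
  res <- filter_corpus(recs)
  rules <- setNames(res$rejected$rules, res$rejected$bel_id)
  expect_match(rules[["B1"]], "forbidden-function")
  expect_match(rules[["B2"]], "entity-count")
  expect_match(rules[["B3"]], "namespace")
  expect_match(rules[["B4"]], "pmid")
  expect_setequal(res$kept$bel_id, "B5")
})

test_that("evidence shared by five nanopubs rejects the whole group", {
  shared <- strrep("Shared supporting evidence text. ", 3)
  five <- do.call(rbind, lapply(1:5, function(i) {
    make_record(paste0("B", i),
                sprintf("p(HGNC:GENE%d) increases p(HGNC:CRP)", i),
                sentence = shared, sentence_id = "S1")
  }))
  res <- filter_corpus(five)
  expect_identical(nrow(res$kept), 0L)
  expect_true(all(grepl("evidence-cap", res$rejected$rules)))
  res4 <- filter_corpus(five[1:4, ])
  expect_identical(nrow(res4$kept), 4L)
})

test_that("exact duplicates are removed before rule checks", {
  recs <- rbind(make_record("B1"), make_record("B2"))
  recs$sentence <- recs$sentence[1]
  recs$sentence_id <- "S1"
  res <- filter_corpus(recs)
  expect_identical(res$kept$bel_id, "B1")
  expect_identical(res$rejected$rules, "duplicate")
})

test_that("the variants profile additionally rejects sub/trunc/fus", {
  recs <- rbind(
    make_record("B1", "p(HGNC:PIK3CA, sub(E, 545, K)) increases p(HGNC:AKT1)"),
    make_record("B2", "p(HGNC:AKT1, pmod(P)) increases p(HGNC:GSK3B)")
  )
  expect_identical(nrow(filter_corpus(recs)$kept), 2L)
  res <- filter_corpus(recs, filter_config(exclude_variants = TRUE))
  expect_identical(res$kept$bel_id, "B2")
  expect_match(res$rejected$rules, "variant")
})

test_that("filtering is idempotent and order-independent", {
  corpus <- gen_corpus(synth_config(n_sentences = 60, seed = 31))
  corpus$sentence[1:5] <- strrep("x", 10)      # too short
  corpus$statement[6] <- "composite(p(MGI:Il13),p(MGI:Ifng)) increases bp(GOBP:inflammation)"
  res <- filter_corpus(corpus)
  again <- filter_corpus(res$kept)
  expect_identical(again$kept, res$kept)
  expect_identical(nrow(again$rejected), 0L)
  perm <- rev(seq_len(nrow(corpus)))
  res_perm <- filter_corpus(corpus[perm, ])
  expect_setequal(res_perm$kept$bel_id, res$kept$bel_id)
})

test_that("entity counting excludes translocation locations", {
  expect_identical(
    count_entities("p(HGNC:TIMP2) decreases cat(p(HGNC:MMP2))"), 2L)
  expect_identical(
    count_entities("complex(p(MGI:Fos), p(MGI:Jun)) -> bp(GOBP:apoptosis)"), 3L)
  expect_identical(
    count_entities(
      "a(CHEBI:\"brefeldin A\") increases tloc(p(MGI:Stk16), GOCC:cytoplasm, GOCC:nucleus)"),
    2L)
})

test_that("corpus statistics reproduce the generator quotas exactly", {
  cfg <- synth_config(n_sentences = 80, seed = 77)
  corpus <- gen_corpus(cfg)
  st <- corpus_stats(corpus)
  n_stmt <- nrow(corpus)
  n_complex <- st$functions$count[st$functions$type == "complex"]
  total_occ <- 2L * n_stmt + n_complex
  expect_identical(sum(st$terms$count), total_occ)
  tq <- beltools:::apportion(total_occ, cfg$term_shares)
  expect_identical(setNames(st$terms$count, st$terms$type)[names(tq)], tq)
  fq <- beltools:::apportion(round(cfg$function_rate * n_stmt),
                             cfg$function_shares)
  expect_identical(setNames(st$functions$count, st$functions$type)[names(fq)],
                   fq)
  rq <- beltools:::apportion(n_stmt, c(increases = cfg$increases_share,
                                       decreases = 1 - cfg$increases_share))
  expect_identical(setNames(st$relationships$count,
                            st$relationships$type)[names(rq)], rq)
  expect_identical(st$overview$n_unique_sentences, cfg$n_sentences)
})

test_that("published training-corpus counts yield the published shares", {
  counts <- published_corpus_counts()
  expect_equal(unname(shares_from_counts(counts$terms[, "train"])["P"]), 87)
  expect_equal(unname(shares_from_counts(counts$functions[, "train"])["act"]), 69)
  expect_equal(
    unname(shares_from_counts(counts$relationships[, "train"])["increases"]),
    73)
  # the re-annotated test split retains activities for only ~46% of functions
  expect_equal(unname(shares_from_counts(counts$functions[, "test"])["act"]), 46)
})

test_that("classification label arithmetic matches the published table", {
  counts <- published_corpus_counts()$classification
  n <- sum(counts[, "fully_supportive"])
  n_fully <- counts["true", "fully_supportive"]
  n_partial <- counts["true", "partially_supportive"]
  records <- data.frame(
    fully_supportive = rep(c(TRUE, FALSE, FALSE),
                           c(n_fully, n_partial - n_fully, n - n_partial)),
    partially_supportive = rep(c(TRUE, TRUE, FALSE),
                               c(n_fully, n_partial - n_fully, n - n_partial)))
  st <- classification_stats(records)
  expect_equal(st$table$true_pct[st$table$tier == "fully_supportive"], 37)
  expect_equal(st$table$true_pct[st$table$tier == "partially_supportive"], 52)
  expect_equal(st$n_changed_tier, 226)
})

test_that("classification stats handle degenerate inputs", {
  allt <- data.frame(fully_supportive = rep(TRUE, 5),
                     partially_supportive = rep(TRUE, 5))
  expect_equal(classification_stats(allt)$n_changed_tier, 0)
  empty <- data.frame(fully_supportive = logical(),
                      partially_supportive = logical())
  st <- classification_stats(empty)
  expect_equal(st$table$true, c(0L, 0L))
  expect_equal(st$n_changed_tier, 0L)
})
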