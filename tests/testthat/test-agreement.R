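test_that("kappa matches hand-computed values on the 18/2/2/18 table", {
  a <- rep(c(TRUE, FALSE), each = 20)
  b <- c(rep(TRUE, 18), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 18))
  k <- cohen_kappa(a, b)
  expect_equal(k$po, 0.90)
  expect_equal(k$pe, 0.50)
  expect_equal(k$kappa, 0.80)
  expect_equal(k$n, 40L)
})

test_that("kappa degenerate and boundary cases", {
  x <- c(TRUE, FALSE, TRUE, TRUE)
  expect_equal(cohen_kappa(x, x)$kappa, 1)
  # one constant annotator with a balanced partner: po == pe, kappa 0
  a <- rep(c(TRUE, FALSE), 10)
  b <- rep(TRUE, 20)
  k <- cohen_kappa(a, b)
  expect_equal(k$po, k$pe)
  expect_equal(k$kappa, 0)
  # both constant on the same class: pe == 1, po == 1, kappa reported as 1
  expect_equal(cohen_kappa(rep(TRUE, 5), rep(TRUE, 5))$kappa, 1)
  expect_error(cohen_kappa(logical(), logical()), "empty")
  expect_error(cohen_kappa(c(TRUE), c(TRUE, FALSE)), "length")
})

test_that("kappa is invariant under annotator swap and class relabeling", {
  pair <- gen_annotator_pair(200, target_kappa = 0.5, prevalence = 0.3,
                             seed = 12)
  expect_equal(cohen_kappa(pair$b, pair$a)$kappa,
               cohen_kappa(pair$a, pair$b)$kappa)
  expect_equal(cohen_kappa(!pair$a, !pair$b)$kappa,
               cohen_kappa(pair$a, pair$b)$kappa)
})

test_that("kappa agrees with the independent caret implementation", {
  skip_if_not_installed("caret")
  pair <- gen_annotator_pair(300, target_kappa = 0.6, prevalence = 0.4,
                             seed = 9, method = "iid")
  ours <- cohen_kappa(pair$a, pair$b)$kappa
  cm <- caret::confusionMatrix(factor(pair$a, c(FALSE, TRUE)),
                               factor(pair$b, c(FALSE, TRUE)))
  expect_equal(ours, unname(cm$overall["Kappa"]))
})

test_that("pairwise label agreement aligns items and excludes missing ones", {
  mk <- function(ids, fully) {
    data.frame(bel_id = ids, statement = "p(HGNC:IL6) increases p(HGNC:CRP)",
               pmid = "1", excerpt = "IL6 induces CRP.",
               fully_supportive = fully, partially_supportive = TRUE,
               stringsAsFactors = FALSE)
  }
  ann <- list(a1 = mk(c("i1", "i2", "i3"), c(TRUE, FALSE, TRUE)),
              a2 = mk(c("i1", "i2", "i3"), c(TRUE, FALSE, TRUE)),
              a3 = mk(c("i3", "i2", "i1"), c(TRUE, FALSE, TRUE)))
  res <- pairwise_label_iaa(ann, tier = "fully")
  expect_equal(nrow(res), 3L)
  expect_true(all(res$kappa == 1))

  # an item present for only one annotator is excluded, with a warning
  ann$a2 <- mk(c("i1", "i2", "i3", "i4"), c(TRUE, FALSE, TRUE, TRUE))
  expect_warning(res <- pairwise_label_iaa(ann[1:2], tier = "fully"),
                 "excluded")
  expect_equal(res$n, 3L)
  expect_equal(res$n_excluded, 1L)

  disjoint <- list(a1 = mk("i1", TRUE), a2 = mk("i2", TRUE))
  expect_error(pairwise_label_iaa(disjoint), "share no items")
})

test_that("pairwise statement agreement delegates to the cascade scorer", {
  corpus <- gen_corpus(synth_config(n_sentences = 15, seed = 3))
  sets <- list(c1 = as_annotation_set(corpus),
               c2 = as_annotation_set(corpus),
               c3 = as_annotation_set(
                 perturb(corpus, perturb_spec(flip_relationship = 0.2,
                                              seed = 6))$predicted))
  res <- pairwise_statement_iaa(sets)
  ident <- res[res$annotator_a == "c1" & res$annotator_b == "c2", ]
  expect_true(all(ident$f == 1))
  flip <- res[res$annotator_a == "c1" & res$annotator_b == "c3", ]
  expect_true(all(flip$f[flip$level == "term"] == 1))
  expect_lt(flip$f[flip$level == "statement"], 1)
})

test_that("simulated annotator pairs recover the target kappa", {
  # exact-quota construction at n=40 reproduces 0.80 analytically
  pair <- gen_annotator_pair(40, target_kappa = 0.8, prevalence = 0.5,
                             seed = 7)
  expect_equal(cohen_kappa(pair$a, pair$b)$kappa, 0.80)
  # i.i.d. sampling recovers the target within Monte-Carlo error
  pair <- gen_annotator_pair(2000, target_kappa = 0.7, prevalence = 0.5,
                             seed = 42, method = "iid")
  expect_lt(abs(cohen_kappa(pair$a, pair$b)$kappa - 0.7), 0.05)
  # target 0: independent labels, kappa near zero at large n
  pair <- gen_annotator_pair(4000, target_kappa = 0, prevalence = 0.5,
                             seed = 5, method = "iid")
  expect_lt(abs(cohen_kappa(pair$a, pair$b)$kappa), 0.05)
})
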