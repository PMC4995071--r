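docs_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(pmid = r[[1]], date = r[[2]],
               sentence_index = as.integer(r[[3]]), sentence = r[[4]],
               stringsAsFactors = FALSE)
  }))
}

test_that("a tri-occurrence sentence is retrieved and re-verifies its match", {
  docs <- docs_df(list("1", "2015-01-01", 0, "AAA upregulates BBB."))
  hits <- find_excerpts("p(HGNC:AAA) increases p(HGNC:BBB)", docs)
  expect_equal(nrow(hits), 1L)
  expect_match(hits$excerpt, "AAA")
  expect_match(hits$excerpt, "BBB")
  expect_match(tolower(hits$excerpt), "upregulat")
})

test_that("sentences missing an entity or the right polarity trigger do not match", {
  docs <- docs_df(
    list("1", "2015-01-01", 0, "AAA upregulates something else."),
    list("2", "2015-01-01", 0, "AAA binds BBB."),
    list("3", "2015-01-01", 0, "AAA inhibits BBB."))
  hits <- find_excerpts("p(HGNC:AAA) increases p(HGNC:BBB)", docs)
  expect_equal(nrow(hits), 0L)
  # the decreases polarity matches the inhibition sentence
  hits <- find_excerpts("p(HGNC:AAA) decreases p(HGNC:BBB)", docs)
  expect_equal(hits$pmid, "3")
})

test_that("matching is word-bounded and case-insensitive", {
  docs <- docs_df(
    list("1", "2015-01-01", 0, "aaa UPREGULATES bbb."),
    list("2", "2015-01-01", 0, "XAAAX upregulates BBB."))
  hits <- find_excerpts("p(HGNC:AAA) increases p(HGNC:BBB)", docs)
  expect_equal(hits$pmid, "1")
})

test_that("twelve qualifying windows cap at ten, newest dates first", {
  rows <- lapply(1:12, function(i) {
    list(sprintf("pm%02d", i), sprintf("2015-%02d-01", i), 0,
         "AAA upregulates BBB.")
  })
  docs <- do.call(docs_df, rows)
  hits <- find_excerpts("p(HGNC:AAA) increases p(HGNC:BBB)", docs)
  expect_equal(nrow(hits), 10L)
  expect_equal(hits$date, sort(docs$date, decreasing = TRUE)[1:10])
  # missing dates sort last; ties break by pmid then window start
  docs$date[docs$pmid == "pm12"] <- ""
  hits <- find_excerpts("p(HGNC:AAA) increases p(HGNC:BBB)", docs)
  expect_false("pm12" %in% hits$pmid[1:9])
})

test_that("a match split across adjacent sentences yields the two-sentence window", {
  docs <- docs_df(
    list("1", "2016-05-01", 0, "AAA was present in the lysate."),
    list("1", "2016-05-01", 1, "It strongly induces BBB."),
    list("1", "2016-05-01", 2, "Unrelated closing remark."))
  hits <- find_excerpts("p(HGNC:AAA) increases p(HGNC:BBB)", docs)
  expect_equal(nrow(hits), 1L)
  expect_equal(c(hits$start, hits$end), c(0L, 1L))
  # but a qualifying single sentence suppresses the enclosing window
  docs2 <- docs_df(
    list("1", "2016-05-01", 0, "AAA induces BBB."),
    list("1", "2016-05-01", 1, "AAA was also detected."))
  hits2 <- find_excerpts("p(HGNC:AAA) increases p(HGNC:BBB)", docs2)
  expect_equal(nrow(hits2), 1L)
  expect_equal(c(hits2$start, hits2$end), c(0L, 0L))
})

test_that("synonyms extend matching; shrinking the trigger lexicon never adds excerpts", {
  docs <- docs_df(list("1", "2015-01-01", 0,
                       "Interleukin-6 upregulates CRP levels."))
  stmt <- "p(HGNC:IL6) increases p(HGNC:CRP)"
  expect_equal(nrow(find_excerpts(stmt, docs)), 0L)
  syn <- list("HGNC:IL6" = "Interleukin-6")
  expect_equal(nrow(find_excerpts(stmt, docs, synonyms = syn)), 1L)

  full <- default_trigger_lexicon()
  small <- list(increases = "induc", decreases = full$decreases)
  hits_full <- find_excerpts(stmt, docs, synonyms = syn, triggers = full)
  hits_small <- find_excerpts(stmt, docs, synonyms = syn, triggers = small)
  expect_lte(nrow(hits_small), nrow(hits_full))
})

test_that("retrieval requires entities on both sides and triggers for the polarity", {
  docs <- docs_df(list("1", "2015-01-01", 0, "AAA upregulates BBB."))
  expect_error(
    find_excerpts("bp(GOBP:apoptosis) increases bp(GOBP:inflammation)",
                  docs, triggers = list(increases = character(),
                                        decreases = "inhibit")),
    "no stems")
})

test_that("retrieval output is deterministic", {
  corpus <- gen_corpus(synth_config(n_sentences = 30, seed = 19))
  docs <- data.frame(pmid = corpus$pmid[!duplicated(corpus$sentence_id)],
                     date = "2016-01-01", sentence_index = 0L,
                     sentence = corpus$sentence[!duplicated(corpus$sentence_id)],
                     stringsAsFactors = FALSE)
  h1 <- find_excerpts(corpus$statement[1], docs)
  h2 <- find_excerpts(corpus$statement[1], docs)
  expect_identical(h1, h2)
  expect_gte(nrow(h1), 1L)   # generated evidence embeds its own entities
  expect_lte(nrow(h1), 10L)
})

test_that("label templates populate the classification skeleton and dedupe", {
  docs <- docs_df(list("1", "2015-01-01", 0, "AAA upregulates BBB."))
  hits <- find_excerpts("p(HGNC:AAA) increases p(HGNC:BBB)", docs)
  rec <- label_template("p(HGNC:AAA) -> p(HGNC:BBB)", rbind(hits, hits),
                        bel_id = "B9")
  expect_equal(nrow(rec), 1L)
  expect_identical(rec$statement, "p(HGNC:AAA) increases p(HGNC:BBB)")
  expect_true(is.na(rec$fully_supportive))
  long <- hits
  long$excerpt <- "One. Two here. Three here."
  long$end <- long$start + 2L
  expect_error(label_template("p(HGNC:AAA) -> p(HGNC:BBB)", long),
               "two sentences")
})
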