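# Shared fixtures and an independent brute-force matching oracle.

# a tiny hand-written corpus data.frame
tiny_corpus <- function() {
  data.frame(
    bel_id = c("B1", "B2", "B3"),
    statement = c(
      "p(HGNC:TIMP2) decreases cat(p(HGNC:MMP2))",
      "cat(p(MGI:Crk)) directlyIncreases p(MGI:Bcar1, pmod(P))",
      "a(CHEBI:water) -> bp(GOBP:\"wound healing\")"
    ),
    sentence_id = c("S1", "S2", "S2"),
    sentence = c(
      "TIMP2 strongly inhibits the catalytic activity of MMP2 in vitro.",
      "Crk induces phosphorylation of Bcar1, and water promotes wound healing.",
      "Crk induces phosphorylation of Bcar1, and water promotes wound healing."
    ),
    pmid = c("1000001", "1000002", "1000002"),
    stringsAsFactors = FALSE
  )
}

# maximum bipartite matching by augmenting paths over an equality matrix --
# an implementation of unit matching independent of the set-based scorer
max_equality_matching <- function(gold_units, pred_units) {
  ng <- length(gold_units)
  np <- length(pred_units)
  if (ng == 0 || np == 0) return(0L)
  match_of_pred <- rep(0L, np)
  try_assign <- function(g, seen) {
    for (p in seq_len(np)) {
      if (!seen[p] && gold_units[g] == pred_units[p]) {
        seen[p] <- TRUE
        if (match_of_pred[p] == 0L ||
            Recall(match_of_pred[p], seen)) {
          match_of_pred[p] <<- g
          return(TRUE)
        }
      }
    }
    FALSE
  }
  matched <- 0L
  for (g in seq_len(ng)) {
    if (try_assign(g, rep(FALSE, np))) matched <- matched + 1L
  }
  matched
}

# brute-force cascade counter over annotation sets; enumerates unit pairs
# per sentence instead of using set operations
oracle_counts <- function(gold, pred, level,
                          config = beltools::simplify_config()) {
  gold <- beltools::as_annotation_set(gold)
  pred <- beltools::as_annotation_set(pred)
  units_of <- function(stmts) {
    u <- character()
    for (s in stmts) {
      u <- c(u, beltools::extract_units(
        beltools::simplify_bel(s, config), level))
    }
    unique(u)
  }
  tp <- fp <- fn <- 0L
  for (sid in union(names(gold), names(pred))) {
    gu <- units_of(if (sid %in% names(gold)) gold[[sid]] else list())
    pu <- units_of(if (sid %in% names(pred)) pred[[sid]] else list())
    m <- max_equality_matching(gu, pu)
    tp <- tp + m
    fp <- fp + length(pu) - m
    fn <- fn + length(gu) - m
  }
  c(tp = tp, fp = fp, fn = fn)
}

report_row <- function(report, level) {
  report[report$level == level, , drop = FALSE]
}
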