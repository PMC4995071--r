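# Corpus selection filters and corpus statistics.
#
# The base-corpus selection pipeline keeps nanopubs whose evidence text is
# informative for text-mining training: a PubMed citation is present, the
# evidence text is 36-425 characters long (one or two sentences), at most 4
# nanopubs share one evidence text (more usually indicates a table/figure
# reference), the statement uses only the causal relationship types and the
# whitelisted namespaces, carries at most 4 named entities, and avoids
# composite()/rxn(). Identical (statement, sentence, pmid) duplicates are
# removed first.

#' Configuration of the corpus-selection filter
#'
#' Defaults reproduce the base-corpus selection profile; the sample/test
#' profile additionally excludes protein variants (`exclude_variants`).
#'
#' @param require_pmid Require a non-empty, numeric PubMed ID.
#' @param max_nanopubs_per_evidence Reject all nanopubs of an evidence text
#'   shared by more than this many nanopubs ("fewer than five" = at most 4).
#' @param evidence_len_min,evidence_len_max Inclusive character bounds on
#'   the whitespace-trimmed evidence text (Unicode code points).
#' @param allowed_relationships Permitted top-level relationship types.
#' @param allowed_namespaces Namespace whitelist for subject/object
#'   entities (case-insensitive); translocation location arguments are
#'   exempt.
#' @param max_entities Maximum named-entity occurrences per statement
#'   (locations excluded, see [count_entities()]).
#' @param forbidden_functions Function codes that disqualify a statement.
#' @param exclude_variants Also reject statements with sub/trunc/fus
#'   modifications.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(require_pmid = TRUE,
                          max_nanopubs_per_evidence = 4L,
                          evidence_len_min = 36L, evidence_len_max = 425L,
                          allowed_relationships = .bel_relationships,
                          allowed_namespaces = c("HGNC", "MGI", "EGID",
                                                 "MESHD", "CHEBI", "GOBP"),
                          max_entities = 4L,
                          forbidden_functions = c("composite", "rxn"),
                          exclude_variants = FALSE) {
  stopifnot(evidence_len_min <= evidence_len_max,
            max_nanopubs_per_evidence >= 0, max_entities >= 0)
  structure(
    list(require_pmid = require_pmid,
         max_nanopubs_per_evidence = as.integer(max_nanopubs_per_evidence),
         evidence_len_min = as.integer(evidence_len_min),
         evidence_len_max = as.integer(evidence_len_max),
         allowed_relationships = allowed_relationships,
         allowed_namespaces = toupper(allowed_namespaces),
         max_entities = as.integer(max_entities),
         forbidden_functions = forbidden_functions,
         exclude_variants = exclude_variants),
    class = "filter_config"
  )
}

collect_fns <- function(x) {
  if (is_bel_statement(x)) return(c(collect_fns(x$subject), collect_fns(x$object)))
  if (!is_bel_term(x)) return(character())
  c(x$fn,
    unlist(lapply(x$args, collect_fns)),
    unlist(lapply(x$reactants %||% list(), collect_fns)),
    unlist(lapply(x$products %||% list(), collect_fns)))
}

collect_mod_kinds <- function(x) {
  if (is_bel_statement(x)) {
    return(c(collect_mod_kinds(x$subject), collect_mod_kinds(x$object)))
  }
  if (!is_bel_term(x)) return(character())
  c(vapply(x$mods, function(m) m$kind, ""),
    unlist(lapply(x$args, collect_mod_kinds)),
    unlist(lapply(x$reactants %||% list(), collect_mod_kinds)),
    unlist(lapply(x$products %||% list(), collect_mod_kinds)))
}

# namespaces of subject/object term entities (tloc locations exempt; fusion
# partners counted, they are named entities of the statement)
collect_term_namespaces <- function(x) {
  if (is_bel_statement(x)) {
    return(c(collect_term_namespaces(x$subject),
             collect_term_namespaces(x$object)))
  }
  if (!is_bel_term(x)) return(character())
  out <- character()
  if (!is.null(x$entity)) out <- c(out, x$entity$ns)
  for (m in x$mods) if (m$kind == "fus" && !is.null(m$partner)) {
    out <- c(out, m$partner$ns)
  }
  c(out,
    unlist(lapply(x$args, collect_term_namespaces)),
    unlist(lapply(x$reactants %||% list(), collect_term_namespaces)),
    unlist(lapply(x$products %||% list(), collect_term_namespaces)))
}

#' Count the named entities of a statement
#'
#' Counts namespace-entity occurrences in the subject and object terms
#' (including complex/composite members and fusion partners) but not
#' translocation location arguments, which name compartments rather than
#' statement entities.
#'
#' @param statement A [bel_statement()] or a BEL string.
#' @return Integer count of entity occurrences.
#' @export
#' @examples
#' count_entities("complex(p(MGI:Fos), p(MGI:Jun)) -> bp(GOBP:apoptosis)")
count_entities <- function(statement) {
  if (is.character(statement)) statement <- parse_bel_statement(statement)
  length(collect_term_namespaces(statement))
}

# rule checks for a single parsed record; returns character vector of
# violated rule names
record_violations <- function(stmt, sentence, pmid, config) {
  rules <- character()
  if (config$require_pmid && !grepl("^[0-9]+$", trimws(pmid))) {
    rules <- c(rules, "pmid")
  }
  len <- nchar(trimws(sentence), type = "chars")
  if (len < config$evidence_len_min || len > config$evidence_len_max) {
    rules <- c(rules, "evidence-length")
  }
  if (!stmt$rel %in% config$allowed_relationships ||
      (is_bel_statement(stmt$object) &&
       !stmt$object$rel %in% config$allowed_relationships)) {
    rules <- c(rules, "relationship")
  }
  ns <- toupper(collect_term_namespaces(stmt))
  if (length(ns) && !all(ns %in% config$allowed_namespaces)) {
    rules <- c(rules, "namespace")
  }
  if (count_entities(stmt) > config$max_entities) {
    rules <- c(rules, "entity-count")
  }
  if (any(collect_fns(stmt) %in% config$forbidden_functions)) {
    rules <- c(rules, "forbidden-function")
  }
  if (config$exclude_variants &&
      any(collect_mod_kinds(stmt) %in% c("sub", "trunc", "fus"))) {
    rules <- c(rules, "variant")
  }
  rules
}

#' Filter a nanopub corpus
#'
#' Applies the corpus-selection rules of `config` to a record data.frame.
#' Exact duplicates (identical statement + sentence + pmid) are removed
#' first; each rejected record is returned with every rule it violated.
#' The operation is idempotent and the kept set does not depend on record
#' order.
#'
#' @param records A corpus record data.frame (see [read_corpus_tab()]).
#' @param config A [filter_config()].
#' @return A list with components `kept` (record data.frame) and
#'   `rejected` (records plus a `rules` column, violated rule names
#'   separated by `";"`).
#' @export
filter_corpus <- function(records, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  dup <- duplicated(paste(records$statement, records$sentence, records$pmid,
                          sep = "\r"))
  rejected <- records[dup, , drop = FALSE]
  rejected$rules <- if (nrow(rejected)) "duplicate" else character()
  records <- records[!dup, , drop = FALSE]

  parsed <- lapply(records$statement, parse_bel_statement)
  rules <- mapply(record_violations, parsed, records$sentence, records$pmid,
                  MoreArgs = list(config = config), SIMPLIFY = FALSE)

  # per-evidence cap: counted over the deduplicated records, grouped by the
  # trimmed evidence text
  key <- trimws(records$sentence)
  per_evidence <- table(key)
  over <- key %in% names(per_evidence)[per_evidence > config$max_nanopubs_per_evidence]
  rules <- mapply(function(r, o) if (o) c(r, "evidence-cap") else r,
                  rules, over, SIMPLIFY = FALSE)

  bad <- lengths(rules) > 0
  rej2 <- records[bad, , drop = FALSE]
  rej2$rules <- vapply(rules[bad], paste, "", collapse = ";")
  kept <- records[!bad, , drop = FALSE]
  rownames(kept) <- NULL
  rejected <- rbind(rejected, rej2)
  rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

# --- corpus statistics ------------------------------------------------------

# entity occurrences tallied by their enclosing abundance/process function
collect_term_types <- function(x) {
  if (is_bel_statement(x)) {
    return(c(collect_term_types(x$subject), collect_term_types(x$object)))
  }
  if (!is_bel_term(x)) return(character())
  out <- character()
  if (!is.null(x$entity)) {
    out <- switch(x$fn,
      p = "P", a = "A", bp = "bp", path = "path",
      g = "G", r = "R", m = "M", complex = "NCH",
      "other")
  }
  c(out,
    unlist(lapply(x$args, collect_term_types)),
    unlist(lapply(x$reactants %||% list(), collect_term_types)),
    unlist(lapply(x$products %||% list(), collect_term_types)))
}

tally <- function(values, categories) {
  stats::setNames(vapply(categories, function(k) sum(values == k), 0L),
                  categories)
}

share_pct <- function(counts) {
  total <- sum(counts)
  if (total == 0) return(stats::setNames(rep(NA_real_, length(counts)),
                                         names(counts)))
  round_half_up(100 * counts / total)
}

#' Corpus statistics: term, function and relationship distributions
#'
#' Tallies a nanopub corpus the way the published corpus summaries do:
#' unique sentence and statement counts; term types per entity occurrence
#' by enclosing function (P = proteins, A = chemical abundances, bp =
#' biological processes, path = pathologies; entities under g()/r()/m() and
#' named complexes are tallied separately and excluded from the four-way
#' share); function types (act = all activity functions, pmod, complex,
#' tloc including sec/surf, deg, sub, trunc); and relationship types with
#' the directly* forms folded into their plain forms. Percentage shares are
#' rounded half-up to whole percent.
#'
#' @param records A corpus record data.frame.
#' @return A list of class `corpus_stats` with components `overview`,
#'   `terms`, `functions`, `relationships` (data.frames with `count` and,
#'   where applicable, `share_pct`).
#' @export
corpus_stats <- function(records) {
  parsed <- lapply(records$statement, parse_bel_statement)

  term_types <- unlist(lapply(parsed, collect_term_types)) %||% character()
  term_main <- tally(term_types, c("P", "A", "bp", "path"))
  term_extra <- tally(term_types, c("G", "R", "M", "NCH"))
  term_extra <- term_extra[term_extra > 0]

  fns <- unlist(lapply(parsed, collect_fns)) %||% character()
  mods <- unlist(lapply(parsed, collect_mod_kinds)) %||% character()
  fn_counts <- c(
    act = sum(fns %in% .bel_activity_fns),
    pmod = sum(mods == "pmod"),
    complex = sum(fns == "complex"),
    tloc = sum(fns %in% c("tloc", "sec", "surf")),
    deg = sum(fns == "deg"),
    sub = sum(mods == "sub"),
    trunc = sum(mods == "trunc")
  )

  rels_raw <- unlist(lapply(parsed, function(s) {
    r <- s$rel
    if (is_bel_statement(s$object)) r <- c(r, s$object$rel)
    r
  })) %||% character()
  rel_folded <- ifelse(grepl("ncreases$", rels_raw), "increases", "decreases")
  rel_counts <- tally(rel_folded, c("increases", "decreases"))

  structure(list(
    overview = new_df(
      n_unique_sentences = length(unique(records$sentence_id)),
      n_statements = nrow(records)
    ),
    terms = new_df(
      type = c(names(term_main), names(term_extra)),
      count = as.integer(c(term_main, term_extra)),
      share_pct = c(share_pct(term_main), rep(NA_real_, length(term_extra)))
    ),
    functions = new_df(
      type = names(fn_counts),
      count = as.integer(fn_counts),
      share_pct = share_pct(fn_counts)
    ),
    relationships = new_df(
      type = names(rel_counts),
      count = as.integer(rel_counts),
      share_pct = share_pct(rel_counts)
    )
  ), class = "corpus_stats")
}

#' Percentage shares from printed category counts
#'
#' Computes the rounded percentage shares [corpus_stats()] reports, but
#' from externally supplied category counts (e.g. the published corpus
#' summary tables) instead of records.
#'
#' @param counts A named numeric vector of category counts.
#' @return A named numeric vector of whole-percent shares (half-up).
#' @export
#' @examples
#' shares_from_counts(c(P = 19918, A = 1927, bp = 877, path = 244))
shares_from_counts <- function(counts) {
  share_pct(counts)
}

#' Label statistics of a sentence-classification corpus
#'
#' Tallies the fully/partially-supportive labels: true/false counts per
#' tier, percentage shares, and the number of excerpts that change from
#' false to true when the partially-supportive criterion replaces the
#' fully-supportive one.
#'
#' @param records A classification data.frame (see [read_classification()]).
#' @return A list with `table` (per-tier counts and shares) and
#'   `n_changed_tier` (false-to-true changes between tiers).
#' @export
classification_stats <- function(records) {
  n <- nrow(records)
  tier_row <- function(label, x) {
    new_df(tier = label, true = sum(x), false = sum(!x), total = n,
           true_pct = if (n) round_half_up(100 * sum(x) / n) else NA_real_)
  }
  tab <- rbind(
    tier_row("fully_supportive", records$fully_supportive %||% logical()),
    tier_row("partially_supportive", records$partially_supportive %||% logical())
  )
  list(
    table = tab,
    n_changed_tier = sum(records$partially_supportive & !records$fully_supportive)
  )
}

#' Published BioCreative V BEL track corpus summary counts
#'
#' The category counts published for the BEL_Extraction corpora (training,
#' sample, test) and the BEL_Sentence_Classification corpus, shipped as
#' reference data: overview (unique sentences / statements), term-,
#' function- and relationship-type distributions, and the classification
#' label table. These are inputs for share computations and consistency
#' checks; the package does not need the (optional, external) corpus
#' downloads to work with them.
#'
#' @return A list with components `overview`, `terms`, `functions`,
#'   `relationships` (matrices with columns train/sample/test) and
#'   `classification` (fully/partially true-false counts).
#' @export
#' @examples
#' shares_from_counts(published_corpus_counts()$terms[, "train"])
published_corpus_counts <- function() {
  cols <- c("train", "sample", "test")
  list(
    overview = matrix(
      c(6353, 11066, 183, 354, 105, 202), nrow = 2,
      dimnames = list(c("unique_sentences", "statements"), cols)),
    base_corpus = c(unique_sentences = 18224, statements = 29484),
    terms = matrix(
      c(19918, 1927, 877, 244,
        497, 79, 79, 54,
        346, 37, 31, 15), nrow = 4,
      dimnames = list(c("P", "A", "bp", "path"), cols)),
    functions = matrix(
      c(6332, 1411, 750, 406, 205, 23, 6,
        0, 24, 26, 11, 18, 0, 0,
        36, 9, 15, 13, 6, 0, 0), nrow = 7,
      dimnames = list(c("act", "pmod", "complex", "tloc", "deg", "sub", "trunc"),
                      cols)),
    relationships = matrix(
      c(8112, 2956, 221, 84, 155, 53), nrow = 2,
      dimnames = list(c("increases", "decreases"), cols)),
    classification = matrix(
      c(578, 976, 804, 750), nrow = 2,
      dimnames = list(c("true", "false"),
                      c("fully_supportive", "partially_supportive")))
  )
}
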