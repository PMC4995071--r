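# Cascade scorer: predicted vs gold BEL statements per sentence, with
# precision/recall/F at term, function, relationship and full-statement
# levels (plus argument-free "secondary" variants of the function and
# relationship levels). Units are matched as sets within each sentence and
# tp/fp/fn are micro-averaged over sentences.

.eval_levels <- c("term", "function", "function_secondary",
                  "relationship", "relationship_secondary", "statement")

# all rendered entities in a subtree (locations and fusion partners
# included; after full simplification those are gone anyway)
collect_entities <- function(x) {
  if (is_bel_statement(x)) {
    return(c(collect_entities(x$subject), collect_entities(x$object)))
  }
  if (!is_bel_term(x)) return(character())
  out <- character()
  if (!is.null(x$entity)) out <- c(out, render_entity(x$entity))
  for (m in x$mods) {
    if (m$kind == "fus" && !is.null(m$partner)) {
      out <- c(out, render_entity(m$partner))
    }
  }
  out <- c(out, vapply(x$locations, render_entity, ""))
  for (a in x$args) out <- c(out, collect_entities(a))
  for (a in x$reactants %||% list()) out <- c(out, collect_entities(a))
  for (a in x$products %||% list()) out <- c(out, collect_entities(a))
  out
}

entity_set_key <- function(entities) {
  paste(sort(unique(entities)), collapse = "+")
}

# function-level units: (function code, contained entity set) for every
# non-abundance function occurrence, with modification carriers (pmod, sub,
# trunc, fus) contributing their kind as the function code
collect_function_units <- function(x, with_args = TRUE) {
  if (is_bel_statement(x)) {
    return(c(collect_function_units(x$subject, with_args),
             collect_function_units(x$object, with_args)))
  }
  if (!is_bel_term(x)) return(character())
  out <- character()
  fn_class <- NULL
  if (x$fn %in% .bel_activity_fns) fn_class <- "act"
  if (x$fn %in% c("tloc", "sec", "surf", "deg", "complex", "composite", "rxn")) {
    fn_class <- x$fn
  }
  if (!is.null(fn_class)) {
    out <- c(out, if (with_args) {
      paste0(fn_class, "{", entity_set_key(collect_entities(x)), "}")
    } else {
      fn_class
    })
  }
  for (m in x$mods) {
    out <- c(out, if (with_args) {
      paste0(m$kind, "{", entity_set_key(render_entity(x$entity)), "}")
    } else {
      m$kind
    })
  }
  for (a in x$args) out <- c(out, collect_function_units(a, with_args))
  for (a in x$reactants %||% list()) out <- c(out, collect_function_units(a, with_args))
  for (a in x$products %||% list()) out <- c(out, collect_function_units(a, with_args))
  out
}

# relationship-level units: (subject entity set, relationship, object entity
# set); a nested object statement contributes its own inner relationship
# unit in addition to the outer one
collect_relationship_units <- function(s, secondary = FALSE) {
  subj_key <- entity_set_key(collect_entities(s$subject))
  obj_key <- entity_set_key(collect_entities(s$object))
  unit <- if (secondary) {
    paste0(s$rel, "(", paste(sort(c(subj_key, obj_key)), collapse = " ~ "), ")")
  } else {
    paste0("{", subj_key, "} ", s$rel, " {", obj_key, "}")
  }
  if (is_bel_statement(s$object)) {
    c(unit, collect_relationship_units(s$object, secondary))
  } else {
    unit
  }
}

#' Extract cascade-level evaluation units from a statement
#'
#' Decomposes a (simplified) BEL statement into the unit set compared at a
#' given cascade level:
#' \describe{
#'   \item{term}{the rendered namespace entities occurring anywhere in the
#'     statement}
#'   \item{function}{pairs of function code and contained entity set, for
#'     non-abundance functions (act, tloc, deg, complex, ...) and
#'     modification carriers (pmod, sub, trunc, fus)}
#'   \item{function_secondary}{the bare function codes}
#'   \item{relationship}{the (subject entity set, relationship, object
#'     entity set) triple; a nested statement contributes its inner
#'     relationship as an additional unit}
#'   \item{relationship_secondary}{the relationship plus the unordered pair
#'     of side entity sets}
#'   \item{statement}{the whole canonical rendering}
#' }
#'
#' @param statement A [bel_statement()] (apply [simplify_bel()] first for
#'   track-equivalent comparison).
#' @param level One of `"term"`, `"function"`, `"function_secondary"`,
#'   `"relationship"`, `"relationship_secondary"`, `"statement"`.
#' @return A character vector of unique unit keys.
#' @export
#' @examples
#' s <- simplify_bel(parse_bel_statement(
#'   "p(HGNC:TIMP2) decreases cat(p(HGNC:MMP2))"))
#' extract_units(s, "term")
#' extract_units(s, "function")
extract_units <- function(statement, level) {
  if (is.character(statement)) statement <- parse_bel_statement(statement)
  stopifnot(is_bel_statement(statement))
  if (!level %in% .eval_levels) {
    stop("unknown cascade level: ", level, call. = FALSE)
  }
  units <- switch(level,
    term = collect_entities(statement),
    "function" = collect_function_units(statement, with_args = TRUE),
    function_secondary = collect_function_units(statement, with_args = FALSE),
    relationship = collect_relationship_units(statement, secondary = FALSE),
    relationship_secondary = collect_relationship_units(statement, secondary = TRUE),
    statement = render_bel(statement)
  )
  unique(units)
}

#' Build an annotation set
#'
#' An annotation set maps sentence IDs to the set of BEL statements
#' annotated (or predicted) for that sentence. Statements are parsed and
#' stored as ASTs; duplicates within a sentence collapse once simplified.
#'
#' @param x A data.frame with columns `sentence_id` and `statement`
#'   (character BEL), or a named list mapping sentence IDs to character
#'   vectors of statements. Corpus record data.frames from
#'   [read_corpus_tab()] work directly.
#' @return An object of class `annotation_set`: a named list of lists of
#'   [bel_statement()]s.
#' @export
as_annotation_set <- function(x) {
  if (inherits(x, "annotation_set")) return(x)
  if (is.data.frame(x)) {
    stopifnot(all(c("sentence_id", "statement") %in% names(x)))
    x <- split(as.character(x$statement), as.character(x$sentence_id))
  }
  stopifnot(is.list(x), !is.null(names(x)))
  out <- lapply(x, function(stmts) {
    lapply(stmts, function(s) if (is.character(s)) parse_bel_statement(s) else s)
  })
  structure(out, class = "annotation_set")
}

prf <- function(tp, fp, fn) {
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f = f)
}

#' Score predicted against gold BEL statements (cascade model)
#'
#' For every sentence, the gold and predicted statements are simplified
#' under `config`, decomposed into unit sets at each cascade level, and
#' matched as sets; tp/fp/fn are summed over all sentences
#' (micro-averaging) and converted to precision, recall and F. Sentences
#' present in only one of the two sets contribute false negatives or false
#' positives; a duplicated prediction neither helps nor hurts.
#'
#' @param gold,predicted Annotation sets (see [as_annotation_set()]).
#' @param config A [simplify_config()]; the default applies the full track
#'   equivalence rules.
#' @return A data.frame of class `eval_report` with one row per level and
#'   columns `level`, `tp`, `fp`, `fn`, `precision`, `recall`, `f`.
#' @export
#' @examples
#' gold <- list(s1 = "cat(p(MGI:Crk)) directlyIncreases p(MGI:Bcar1, pmod(P))")
#' pred <- list(s1 = "act(p(MGI:Crk)) -> p(MGI:Bcar1, pmod(P, S, 41))")
#' score_bel(gold, pred)
score_bel <- function(gold, predicted, config = simplify_config()) {
  gold <- as_annotation_set(gold)
  predicted <- as_annotation_set(predicted)
  gold_simple <- lapply(gold, lapply, simplify_bel, config = config)
  pred_simple <- lapply(predicted, lapply, simplify_bel, config = config)
  sentences <- union(names(gold_simple), names(pred_simple))
  counts <- matrix(0L, nrow = length(.eval_levels), ncol = 3,
                   dimnames = list(.eval_levels, c("tp", "fp", "fn")))
  units_of <- function(stmts, level) {
    unique(unlist(lapply(stmts, extract_units, level = level))) %||% character()
  }
  for (sid in sentences) {
    g <- gold_simple[[sid]] %||% list()
    p <- pred_simple[[sid]] %||% list()
    for (level in .eval_levels) {
      gu <- units_of(g, level)
      pu <- units_of(p, level)
      counts[level, "tp"] <- counts[level, "tp"] + length(intersect(gu, pu))
      counts[level, "fp"] <- counts[level, "fp"] + length(setdiff(pu, gu))
      counts[level, "fn"] <- counts[level, "fn"] + length(setdiff(gu, pu))
    }
  }
  report <- new_df(
    level = .eval_levels,
    tp = counts[, "tp"], fp = counts[, "fp"], fn = counts[, "fn"]
  )
  m <- t(mapply(prf, report$tp, report$fp, report$fn))
  report$precision <- m[, "precision"]
  report$recall <- m[, "recall"]
  report$f <- m[, "f"]
  rownames(report) <- NULL
  class(report) <- c("eval_report", class(report))
  report
}

#' Score two annotators against each other (cascade IAA)
#'
#' Inter-annotator agreement for statement corpora: the first annotator's
#' statements are taken as the gold standard and the second annotator's as
#' the prediction, then scored with [score_bel()]. Swapping the annotators
#' swaps precision and recall and leaves F unchanged.
#'
#' @param annotator_a,annotator_b Annotation sets (see
#'   [as_annotation_set()]); `annotator_a` plays the gold role.
#' @param config A [simplify_config()].
#' @return An `eval_report` data.frame as for [score_bel()].
#' @export
score_iaa <- function(annotator_a, annotator_b, config = simplify_config()) {
  score_bel(annotator_a, annotator_b, config)
}
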