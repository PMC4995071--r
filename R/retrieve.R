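# Tri-occurrence candidate-evidence retrieval: find windows of one or two
# consecutive sentences in a local sentence collection that contain (i) a
# synonym of a subject-side entity, (ii) a synonym of an object-side
# entity, and (iii) a trigger word of the statement's polarity, sorted by
# publication date (newest first) and capped at 10 excerpts per statement.
#
# Matching is token-level and case-insensitive: exact on entity synonyms,
# stem-prefix on triggers. Either side may precede the other in the text.

#' Default relationship trigger lexicon
#'
#' Trigger-word stems per relationship polarity, matched case-insensitively
#' as token prefixes (so "upregulat" hits "upregulates" and
#' "upregulation"). The shipped contents are an editable artifact default,
#' not a fixed vocabulary; extend or replace via [read_trigger_lexicon()].
#'
#' @return A list with character-vector components `increases` and
#'   `decreases`.
#' @export
default_trigger_lexicon <- function() {
  list(
    increases = c("increas", "induc", "enhanc", "upregulat", "up-regulat",
                  "stimulat", "activat", "promot", "elevat", "augment",
                  "trigger"),
    decreases = c("decreas", "inhibit", "suppress", "reduc", "downregulat",
                  "down-regulat", "repress", "attenuat", "block", "abolish",
                  "impair")
  )
}

#' Read a trigger lexicon file
#'
#' Two tab-separated columns: polarity (`increases` or `decreases`) and
#' trigger stem, one per line.
#'
#' @param path File path.
#' @return A trigger lexicon list as from [default_trigger_lexicon()].
#' @export
read_trigger_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    stop(sprintf("trigger lexicon %s: line %d does not have 2 columns",
                 path, bad[1]), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  pol <- m[, 1]
  if (!all(pol %in% c("increases", "decreases"))) {
    stop("trigger polarities must be 'increases' or 'decreases'", call. = FALSE)
  }
  list(increases = m[pol == "increases", 2],
       decreases = m[pol == "decreases", 2])
}

#' Read a sentence-collection file
#'
#' The document collection searched by [find_excerpts()]: tab-separated
#' columns pmid, publication date (ISO 8601, may be empty), sentence index
#' (0-based, contiguous per document) and sentence text.
#'
#' @param path File path.
#' @return A data.frame with columns `pmid`, `date`, `sentence_index`,
#'   `sentence`.
#' @export
read_sentence_docs <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(new_df(pmid = character(), date = character(),
                  sentence_index = integer(), sentence = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4)
  if (length(bad)) {
    stop(sprintf("sentence collection %s: line %d does not have 4 columns",
                 path, bad[1]), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  if (tolower(m[1, 1]) == "pmid") m <- m[-1, , drop = FALSE]
  df <- new_df(pmid = m[, 1], date = m[, 2],
               sentence_index = as.integer(m[, 3]), sentence = m[, 4])
  for (pm in unique(df$pmid)) {
    idx <- sort(df$sentence_index[df$pmid == pm])
    if (!identical(idx, seq(0L, length(idx) - 1L))) {
      stop(sprintf("document %s: sentence indices are not contiguous from 0", pm),
           call. = FALSE)
    }
  }
  df
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1", x)

# does the text contain any of the surface forms (exact, case-insensitive,
# word-bounded)?
match_synonym <- function(text, surfaces) {
  any(vapply(surfaces, function(s) {
    grepl(paste0("(^|[^A-Za-z0-9])", escape_regex(s), "($|[^A-Za-z0-9])"),
          text, ignore.case = TRUE)
  }, TRUE))
}

match_trigger <- function(text, stems) {
  any(vapply(stems, function(s) {
    grepl(paste0("(^|[^A-Za-z0-9])", escape_regex(s)), text,
          ignore.case = TRUE)
  }, TRUE))
}

surfaces_for <- function(entities, synonyms) {
  out <- lapply(entities, function(key) {
    name <- sub("^[^:]+:", "", key)
    name <- gsub("^\"|\"$", "", name)
    c(name, synonyms[[key]])
  })
  lapply(out, unique)
}

#' Retrieve candidate evidence excerpts for a BEL statement
#'
#' Scans a local sentence collection for windows of one or two consecutive
#' sentences that contain a synonym of at least one subject-side entity, a
#' synonym of at least one object-side entity, and a trigger word matching
#' the statement's (simplified) polarity. Two-sentence windows are only
#' proposed when neither of their sentences qualifies alone, so returned
#' excerpts never duplicate one another. Results are sorted by publication
#' date, newest first (missing dates last; ties broken by pmid, then window
#' start) and capped at `limit` excerpts.
#'
#' @param statement A [bel_statement()] or BEL string with at least one
#'   entity on each side.
#' @param docs A sentence collection data.frame (see
#'   [read_sentence_docs()]).
#' @param synonyms Optional named list mapping `"NS:name"` keys to extra
#'   surface forms; every entity always matches its own name.
#' @param triggers A trigger lexicon (see [default_trigger_lexicon()]).
#' @param limit Maximum number of excerpts (default 10).
#' @return A data.frame with columns `pmid`, `date`, `start`, `end`
#'   (sentence indices) and `excerpt`.
#' @export
find_excerpts <- function(statement, docs, synonyms = NULL,
                          triggers = default_trigger_lexicon(), limit = 10L) {
  if (is.character(statement)) statement <- parse_bel_statement(statement)
  stopifnot(is_bel_statement(statement))
  simple <- simplify_bel(statement)
  polarity <- if (grepl("ncreases$", simple$rel)) "increases" else "decreases"
  stems <- triggers[[polarity]]
  if (!length(stems)) {
    stop(sprintf("trigger lexicon has no stems for polarity '%s'", polarity),
         call. = FALSE)
  }
  subj_entities <- unique(collect_entities(statement$subject))
  obj_entities <- unique(collect_entities(statement$object))
  if (!length(subj_entities) || !length(obj_entities)) {
    stop("statement must carry at least one entity on each side", call. = FALSE)
  }
  subj_surfaces <- unlist(surfaces_for(subj_entities, synonyms))
  obj_surfaces <- unlist(surfaces_for(obj_entities, synonyms))

  qualifies <- function(text) {
    match_synonym(text, subj_surfaces) && match_synonym(text, obj_surfaces) &&
      match_trigger(text, stems)
  }

  hits <- list()
  for (pm in unique(docs$pmid)) {
    d <- docs[docs$pmid == pm, , drop = FALSE]
    d <- d[order(d$sentence_index), , drop = FALSE]
    single_ok <- vapply(d$sentence, qualifies, TRUE, USE.NAMES = FALSE)
    for (i in seq_len(nrow(d))) {
      if (single_ok[i]) {
        hits[[length(hits) + 1L]] <- new_df(
          pmid = pm, date = d$date[1], start = d$sentence_index[i],
          end = d$sentence_index[i], excerpt = d$sentence[i])
      }
    }
    if (nrow(d) > 1) {
      for (i in seq_len(nrow(d) - 1L)) {
        if (single_ok[i] || single_ok[i + 1L]) next
        window <- paste(d$sentence[i], d$sentence[i + 1L])
        if (qualifies(window)) {
          hits[[length(hits) + 1L]] <- new_df(
            pmid = pm, date = d$date[1], start = d$sentence_index[i],
            end = d$sentence_index[i + 1L], excerpt = window)
        }
      }
    }
  }
  if (!length(hits)) {
    return(new_df(pmid = character(), date = character(), start = integer(),
                  end = integer(), excerpt = character()))
  }
  out <- do.call(rbind, hits)
  date_key <- suppressWarnings(as.Date(out$date))
  ord <- order(is.na(date_key), -as.numeric(date_key), out$pmid, out$start,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  out <- utils::head(out, limit)
  rownames(out) <- NULL
  out
}

#' Build an unlabeled classification record from a retrieved excerpt
#'
#' Emits a sentence-classification record skeleton (labels unset, `NA`) for
#' manual annotation, pairing the statement with one excerpt from
#' [find_excerpts()]. Excerpts longer than two sentences are rejected.
#'
#' @param statement A [bel_statement()] or BEL string.
#' @param excerpt One row of a [find_excerpts()] result (or a data.frame of
#'   rows; duplicates by statement + excerpt text are removed).
#' @param bel_id Identifier to assign to the record(s).
#' @return A classification record data.frame with `NA` labels.
#' @export
label_template <- function(statement, excerpt, bel_id = "B1") {
  if (is.character(statement)) statement <- parse_bel_statement(statement)
  stopifnot(is.data.frame(excerpt), nrow(excerpt) >= 1)
  over <- which(excerpt$end - excerpt$start + 1L > 2L |
                  vapply(excerpt$excerpt, count_excerpt_sentences, 0L,
                         USE.NAMES = FALSE) > 2L)
  if (length(over)) {
    stop("excerpts are limited to two sentences", call. = FALSE)
  }
  stmt_text <- render_bel(statement)
  out <- new_df(
    bel_id = rep(bel_id, nrow(excerpt)),
    statement = rep(stmt_text, nrow(excerpt)),
    pmid = excerpt$pmid,
    excerpt = excerpt$excerpt,
    fully_supportive = rep(NA, nrow(excerpt)),
    partially_supportive = rep(NA, nrow(excerpt))
  )
  out <- out[!duplicated(paste(out$statement, out$excerpt, sep = "\r")), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
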