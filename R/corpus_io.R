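# Readers and writers for the corpus file formats.
#
# A nanopub corpus is distributed either as a single 5-column tab-separated
# ".tab" file (bel_id, statement, sentence_id, sentence, pmid) or as a
# ".BEL" + ".sentence" pair: the .BEL file carries bel_id, statement and the
# sentence_id reference, the .sentence file carries sentence_id, pmid and
# the supporting evidence text. The sentence-classification corpus is a
# 6-column tab-separated file (bel_id, statement, pmid, excerpt,
# fully_supportive, partially_supportive).
#
# Reads and writes round-trip byte-identically up to newline convention:
# embedded tabs/newlines in evidence text are escaped as \t/\n, a header row
# is always written and auto-detected on read.

.tab_header <- c("bel_id", "statement", "sentence_id", "sentence", "pmid")
.bel_header <- c("bel_id", "statement", "sentence_id")
.sentence_header <- c("sentence_id", "pmid", "sentence")
.classification_header <- c("bel_id", "statement", "pmid", "excerpt",
                            "fully_supportive", "partially_supportive")

escape_field <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

unescape_field <- function(x) {
  # single pass so that "\\t" stays a literal backslash-t
  vapply(x, function(s) {
    if (!grepl("\\", s, fixed = TRUE)) return(s)
    out <- character()
    parts <- strsplit(s, "", fixed = FALSE)[[1]]
    i <- 1L
    while (i <= length(parts)) {
      ch <- parts[i]
      if (ch == "\\" && i < length(parts)) {
        nxt <- parts[i + 1L]
        out <- c(out, switch(nxt, t = "\t", n = "\n", "\\" = "\\", nxt))
        i <- i + 2L
      } else {
        out <- c(out, ch)
        i <- i + 1L
      }
    }
    paste(out, collapse = "")
  }, "", USE.NAMES = FALSE)
}

read_tsv_lines <- function(path, n_cols, header, what) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    cols <- replicate(n_cols, character(), simplify = FALSE)
    names(cols) <- header
    return(do.call(new_df, cols))
  }
  # field count from the raw line (strsplit drops trailing empty fields)
  n_fields <- nchar(lines) - nchar(gsub("\t", "", lines, fixed = TRUE)) + 1L
  bad <- which(n_fields != n_cols)
  if (length(bad)) {
    stop(sprintf("%s %s: line %d has %d tab-separated columns, expected %d",
                 what, path, bad[1], n_fields[bad[1]], n_cols),
         call. = FALSE)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  parts <- lapply(parts, function(p) c(p, rep("", n_cols - length(p))))
  m <- do.call(rbind, parts)
  # header row detected by its first cell naming the ID column
  if (tolower(m[1, 1]) == tolower(header[1])) m <- m[-1, , drop = FALSE]
  cols <- lapply(seq_len(n_cols), function(j) unescape_field(m[, j]))
  names(cols) <- header
  do.call(new_df, cols)
}

write_tsv_lines <- function(df, path, header) {
  body <- apply(as.matrix(df[, header, drop = FALSE]), 1,
                function(row) paste(escape_field(row), collapse = "\t"))
  writeLines(c(paste(header, collapse = "\t"), body), path, useBytes = TRUE)
}

check_parse <- function(statements, bel_ids, lenient, what) {
  parsed <- lapply(statements, function(s) {
    tryCatch(parse_bel_statement(s), error = function(e) e)
  })
  failed <- vapply(parsed, inherits, TRUE, what = "error")
  if (any(failed)) {
    msgs <- sprintf("%s: %s", bel_ids[failed],
                    vapply(parsed[failed], conditionMessage, ""))
    if (lenient) {
      warning(sprintf("%s: dropped %d unparseable statement(s): %s",
                      what, sum(failed), paste(msgs, collapse = "; ")),
              call. = FALSE)
    } else {
      stop(sprintf("%s: %d statement(s) failed to parse: %s",
                   what, sum(failed), paste(msgs, collapse = "; ")),
           call. = FALSE)
    }
  }
  !failed
}

check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicate %s: %s", what,
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  }
}

check_sentence_ids <- function(sentence_id, sentence) {
  per_id <- tapply(sentence, sentence_id, function(x) length(unique(x)))
  bad <- names(per_id)[per_id > 1]
  if (length(bad)) {
    stop(sprintf("sentence_id %s maps to more than one distinct evidence text",
                 bad[1]), call. = FALSE)
  }
}

#' Read and write nanopub corpus .tab files
#'
#' `read_corpus_tab()` reads the 5-column tab-separated corpus format
#' (bel_id, statement, sentence_id, sentence, pmid), parses every BEL
#' statement, and enforces ID invariants: bel_id unique per nanopub, each
#' sentence_id tied to a single evidence text. `write_corpus_tab()` writes
#' records back; `write(read(f))` is byte-identical to `f` up to newline
#' convention and header spelling.
#'
#' @param path File path.
#' @param lenient If `TRUE`, records whose statement does not parse are
#'   dropped with a warning instead of rejecting the file.
#' @return A data.frame of corpus records with character columns `bel_id`,
#'   `statement`, `sentence_id`, `sentence`, `pmid`.
#' @export
read_corpus_tab <- function(path, lenient = FALSE) {
  df <- read_tsv_lines(path, 5L, .tab_header, "corpus file")
  keep <- check_parse(df$statement, df$bel_id, lenient, basename(path))
  df <- df[keep, , drop = FALSE]
  check_unique(df$bel_id, "bel_id")
  check_sentence_ids(df$sentence_id, df$sentence)
  rownames(df) <- NULL
  df
}

#' @rdname read_corpus_tab
#' @param records A corpus record data.frame (as returned by
#'   `read_corpus_tab()` or [gen_corpus()]).
#' @export
write_corpus_tab <- function(records, path) {
  stopifnot(all(.tab_header %in% names(records)))
  check_unique(records$bel_id, "bel_id")
  write_tsv_lines(records, path, .tab_header)
  invisible(path)
}

#' Read and write the .BEL / .sentence file pair
#'
#' The `.BEL` file carries the statement side of a corpus (bel_id,
#' statement, sentence_id reference), the `.sentence` file the evidence
#' side (sentence_id, pmid, evidence text). [join_corpus()] combines a
#' consistent pair into the same records `read_corpus_tab()` yields;
#' [split_corpus()] is its inverse.
#'
#' @param path File path.
#' @return Data.frames with the respective columns.
#' @export
read_bel_file <- function(path) {
  df <- read_tsv_lines(path, 3L, .bel_header, ".BEL file")
  check_parse(df$statement, df$bel_id, lenient = FALSE, basename(path))
  check_unique(df$bel_id, "bel_id")
  df
}

#' @rdname read_bel_file
#' @export
read_sentence_file <- function(path) {
  df <- read_tsv_lines(path, 3L, .sentence_header, ".sentence file")
  check_unique(df$sentence_id, "sentence_id")
  df
}

#' @rdname read_bel_file
#' @param bel,sentences Data.frames from `read_bel_file()` and
#'   `read_sentence_file()`.
#' @export
join_corpus <- function(bel, sentences) {
  dangling <- setdiff(bel$sentence_id, sentences$sentence_id)
  if (length(dangling)) {
    stop(sprintf(".BEL file references sentence_id(s) absent from .sentence file: %s",
                 paste(utils::head(dangling, 5), collapse = ", ")),
         call. = FALSE)
  }
  idx <- match(bel$sentence_id, sentences$sentence_id)
  new_df(
    bel_id = bel$bel_id,
    statement = bel$statement,
    sentence_id = bel$sentence_id,
    sentence = sentences$sentence[idx],
    pmid = sentences$pmid[idx]
  )
}

#' @rdname read_bel_file
#' @param records A corpus record data.frame.
#' @return `split_corpus()` returns `list(bel = , sentences = )`.
#' @export
split_corpus <- function(records) {
  sent <- records[!duplicated(records$sentence_id),
                  c("sentence_id", "pmid", "sentence")]
  rownames(sent) <- NULL
  list(
    bel = records[, .bel_header],
    sentences = sent
  )
}

#' @rdname read_bel_file
#' @export
write_bel_file <- function(bel, path) {
  write_tsv_lines(bel, path, .bel_header)
  invisible(path)
}

#' @rdname read_bel_file
#' @export
write_sentence_file <- function(sentences, path) {
  write_tsv_lines(sentences, path, .sentence_header)
  invisible(path)
}

# naive sentence splitter: terminal punctuation + space + capital/digit.
# A documented heuristic used only for the excerpt-length advisory check.
count_excerpt_sentences <- function(text) {
  if (!nzchar(trimws(text))) return(0L)
  breaks <- gregexpr("[.?!]\\s+(?=[A-Z0-9])", text, perl = TRUE)[[1]]
  if (breaks[1] == -1) 1L else length(breaks) + 1L
}

#' Read and write the sentence-classification corpus
#'
#' The classification format pairs a BEL statement with a text excerpt of
#' at most two sentences and two binary labels: `fully_supportive` (the
#' whole statement can be extracted or directly inferred from the excerpt)
#' and `partially_supportive` (extractable with background knowledge or
#' context). The label implication fully => partially is enforced: a row
#' labeled fully-supportive but not partially-supportive is rejected.
#' Excerpts that look longer than two sentences trigger a warning
#' (`excerpt_limit = "error"` upgrades it).
#'
#' @param path File path.
#' @param excerpt_limit `"warn"` (default) or `"error"`: what to do when an
#'   excerpt exceeds the two-sentence limit per the heuristic splitter.
#' @return A data.frame with columns `bel_id`, `statement`, `pmid`,
#'   `excerpt`, `fully_supportive`, `partially_supportive` (the labels as
#'   logicals).
#' @export
read_classification <- function(path, excerpt_limit = c("warn", "error")) {
  excerpt_limit <- match.arg(excerpt_limit)
  df <- read_tsv_lines(path, 6L, .classification_header, "classification file")
  check_parse(df$statement, df$bel_id, lenient = FALSE, basename(path))
  parse_label <- function(x, col) {
    out <- tolower(trimws(x)) %in% c("true", "t", "1", "yes")
    okfalse <- tolower(trimws(x)) %in% c("false", "f", "0", "no")
    bad <- which(!(out | okfalse))
    if (length(bad)) {
      stop(sprintf("classification file %s: row %d has unreadable %s label '%s'",
                   basename(path), bad[1], col, x[bad[1]]), call. = FALSE)
    }
    out
  }
  df$fully_supportive <- parse_label(df$fully_supportive, "fully_supportive")
  df$partially_supportive <- parse_label(df$partially_supportive,
                                         "partially_supportive")
  bad <- which(df$fully_supportive & !df$partially_supportive)
  if (length(bad)) {
    stop(sprintf(
      "row %d (%s): fully_supportive implies partially_supportive, but partially is false",
      bad[1], df$bel_id[bad[1]]), call. = FALSE)
  }
  n_sent <- vapply(df$excerpt, count_excerpt_sentences, 0L, USE.NAMES = FALSE)
  over <- which(n_sent > 2)
  if (length(over)) {
    msg <- sprintf("%d excerpt(s) appear longer than two sentences (first: row %d, %s)",
                   length(over), over[1], df$bel_id[over[1]])
    if (excerpt_limit == "error") stop(msg, call. = FALSE) else
      warning(msg, call. = FALSE)
  }
  df
}

#' @rdname read_classification
#' @param records A classification record data.frame.
#' @export
write_classification <- function(records, path) {
  out <- records[, .classification_header]
  out$fully_supportive <- ifelse(is.na(out$fully_supportive), "",
                                 tolower(as.character(out$fully_supportive)))
  out$partially_supportive <- ifelse(is.na(out$partially_supportive), "",
                                     tolower(as.character(out$partially_supportive)))
  write_tsv_lines(out, path, .classification_header)
  invisible(path)
}
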