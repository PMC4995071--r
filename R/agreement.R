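# Inter-annotator agreement. Label corpora are compared with observed
# agreement po and Cohen's kappa = (po - pe) / (1 - pe), where pe is the
# agreement expected by chance from the two annotators' label marginals.
# Statement corpora are compared with the cascade F model (one annotator as
# gold, the other as prediction).

#' Cohen's kappa for two binary annotators
#'
#' Computes the observed agreement `po` (matching fraction), the chance
#' agreement `pe` (sum over classes of the product of the two annotators'
#' marginals), and `kappa = (po - pe) / (1 - pe)`. When `pe == 1` (both
#' annotators constant on the same class) kappa is reported as 1 if
#' `po == 1` and is an error otherwise.
#'
#' @param labels_a,labels_b Logical (or 0/1) vectors of equal length >= 1,
#'   aligned by item.
#' @return An object of class `agreement_result`: a list with `n`, `po`,
#'   `pe`, `kappa`.
#' @export
#' @examples
#' a <- rep(c(TRUE, FALSE), each = 20)
#' b <- c(rep(TRUE, 18), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 18))
#' cohen_kappa(a, b)   # po 0.90, pe 0.50, kappa 0.80
cohen_kappa <- function(labels_a, labels_b) {
  a <- as.logical(labels_a)
  b <- as.logical(labels_b)
  if (length(a) != length(b)) {
    stop("label sequences differ in length", call. = FALSE)
  }
  if (length(a) == 0) stop("empty label sequences", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("labels contain missing values", call. = FALSE)
  n <- length(a)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  kappa <- if (pe < 1) {
    (po - pe) / (1 - pe)
  } else if (po == 1) {
    1
  } else {
    stop("chance agreement is 1 but observed agreement is not; kappa undefined",
         call. = FALSE)
  }
  structure(list(n = n, po = po, pe = pe, kappa = kappa),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Agreement on %d items: po = %.1f%%, pe = %.1f%%, kappa = %.2f\n",
              x$n, 100 * x$po, 100 * x$pe, x$kappa))
  invisible(x)
}

#' Pairwise label agreement across annotators
#'
#' Computes observed agreement and Cohen's kappa for every unordered pair
#' of annotators on one label tier of a sentence-classification corpus.
#' Items are aligned by ID; items present for only one annotator of a pair
#' are excluded (with a warning) rather than counted as disagreement.
#'
#' @param annotations A named list of classification data.frames (one per
#'   annotator, see [read_classification()]). Items are identified by
#'   `id_cols`.
#' @param tier `"fully"` or `"partially"`: which label column to compare.
#' @param id_cols Columns identifying an item; defaults to the
#'   statement/excerpt pair via `bel_id`.
#' @return A data.frame with one row per annotator pair: `annotator_a`,
#'   `annotator_b`, `n`, `n_excluded`, `po`, `pe`, `kappa`.
#' @export
pairwise_label_iaa <- function(annotations, tier = c("fully", "partially"),
                               id_cols = "bel_id") {
  tier <- match.arg(tier)
  col <- paste0(tier, "_supportive")
  stopifnot(is.list(annotations), length(annotations) >= 2,
            !is.null(names(annotations)))
  ids <- lapply(annotations, function(df) {
    do.call(paste, c(df[id_cols], sep = "\r"))
  })
  pairs <- utils::combn(names(annotations), 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    ia <- ids[[pr[1]]]; ib <- ids[[pr[2]]]
    common <- intersect(ia, ib)
    n_excluded <- (length(ia) - length(common)) + (length(ib) - length(common))
    if (!length(common)) {
      stop(sprintf("annotators %s and %s share no items", pr[1], pr[2]),
           call. = FALSE)
    }
    if (n_excluded > 0) {
      warning(sprintf("annotators %s and %s: %d item(s) present for only one annotator were excluded",
                      pr[1], pr[2], n_excluded), call. = FALSE)
    }
    la <- annotations[[pr[1]]][[col]][match(common, ia)]
    lb <- annotations[[pr[2]]][[col]][match(common, ib)]
    k <- cohen_kappa(la, lb)
    new_df(annotator_a = pr[1], annotator_b = pr[2], n = k$n,
           n_excluded = n_excluded, po = k$po, pe = k$pe, kappa = k$kappa)
  })
  do.call(rbind, out)
}

#' Pairwise statement agreement across annotators (cascade F)
#'
#' For every unordered annotator pair, the first annotator's statements are
#' taken as gold and the second's as prediction, and the full cascade
#' report is computed with [score_iaa()].
#'
#' @param annotation_sets A named list of annotation sets (see
#'   [as_annotation_set()]), one per annotator.
#' @param config A [simplify_config()].
#' @return A data.frame with one row per pair and level: `annotator_a`,
#'   `annotator_b` plus the [score_bel()] report columns.
#' @export
pairwise_statement_iaa <- function(annotation_sets,
                                   config = simplify_config()) {
  stopifnot(is.list(annotation_sets), length(annotation_sets) >= 2,
            !is.null(names(annotation_sets)))
  pairs <- utils::combn(names(annotation_sets), 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    rpt <- score_iaa(annotation_sets[[pr[1]]], annotation_sets[[pr[2]]], config)
    cbind(new_df(annotator_a = rep(pr[1], nrow(rpt)),
                 annotator_b = rep(pr[2], nrow(rpt))),
          as.data.frame(rpt))
  })
  do.call(rbind, out)
}
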