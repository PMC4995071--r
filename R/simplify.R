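# Canonicalization of BEL statements under the BioCreative V BEL-track
# equivalence rules, so that gold and predicted statements that the track
# treats as equal compare equal:
#   (i)   directlyIncreases -> increases, directlyDecreases -> decreases;
#   (ii)  every specific activity function -> act();
#   (iii) pmod() keeps only its type code (pmod(P, T, 202) -> pmod(P));
#   (iv)  translocation location arguments are dropped; sec()/surf()
#         rewrite to the generic tloc();
#   (v)   optionally, gene-namespace entities are folded into ortholog
#         equivalence classes.
# complex()/composite() members are sorted by canonical rendering so that
# member order never distinguishes equivalent curations.

#' Configuration for BEL statement simplification
#'
#' Each flag enables one of the track's equivalence rules (all on by
#' default, matching the official evaluation); ortholog folding is off by
#' default because it needs an explicit equivalence map.
#'
#' @param apply_ortholog Fold gene-namespace entities (HGNC, MGI, EGID, RGD)
#'   into equivalence classes via `map`.
#' @param map An ortholog map from [read_ortholog_map()] (a named character
#'   vector keyed `"NS:name"`, values are class labels), required when
#'   `apply_ortholog = TRUE`. Entities absent from the map stay as they are
#'   (singleton classes).
#' @param collapse_direct Treat `directlyIncreases`/`directlyDecreases` as
#'   `increases`/`decreases`.
#' @param collapse_activity Map all specific activity functions (cat, kin,
#'   tscript, ...) to `act()`.
#' @param strip_pmod_args Keep only the type code of `pmod()`.
#' @param strip_tloc_args Drop translocation location arguments and rewrite
#'   `sec()`/`surf()` to the generic `tloc()`.
#' @return An object of class `simplify_config`.
#' @export
simplify_config <- function(apply_ortholog = FALSE, map = NULL,
                            collapse_direct = TRUE, collapse_activity = TRUE,
                            strip_pmod_args = TRUE, strip_tloc_args = TRUE) {
  if (apply_ortholog && is.null(map)) {
    stop("apply_ortholog = TRUE requires an ortholog map", call. = FALSE)
  }
  structure(
    list(apply_ortholog = apply_ortholog, map = map,
         collapse_direct = collapse_direct,
         collapse_activity = collapse_activity,
         strip_pmod_args = strip_pmod_args,
         strip_tloc_args = strip_tloc_args),
    class = "simplify_config"
  )
}

#' Read an ortholog equivalence map
#'
#' Reads a tab-separated file with three columns -- namespace, name,
#' equivalence-class label -- into the lookup used by [simplify_bel()].
#' Orthologous genes listed under the same class label (e.g. HGNC:MAPK3 and
#' MGI:Mapk3) simplify to the same term.
#'
#' @param path Path to a 3-column tab-separated file (no header).
#' @return A named character vector keyed `"NS:name"` with class labels as
#'   values.
#' @export
read_ortholog_map <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(stats::setNames(character(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad)) {
    stop(sprintf("ortholog map %s: line %d does not have 3 tab-separated columns",
                 path, bad[1]), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  stats::setNames(m[, 3], paste0(m[, 1], ":", m[, 2]))
}

# equivalence-class entities carry the reserved ORTH namespace
map_entity <- function(e, config) {
  if (!config$apply_ortholog || !toupper(e$ns) %in% .bel_gene_namespaces) {
    return(e)
  }
  key <- paste0(e$ns, ":", e$name)
  if (!key %in% names(config$map)) return(e)
  bel_entity("ORTH", unname(config$map[[key]]))
}

simplify_term <- function(t, config) {
  fn <- t$fn
  if (config$collapse_activity && fn %in% .bel_activity_fns) fn <- "act"
  if (config$strip_tloc_args && fn %in% c("sec", "surf")) fn <- "tloc"
  entity <- if (!is.null(t$entity)) map_entity(t$entity, config)
  args <- lapply(t$args, simplify_term, config = config)
  mods <- lapply(t$mods, function(m) {
    if (config$strip_pmod_args && m$kind == "pmod") {
      bel_mod("pmod", type = m$type)
    } else if (m$kind == "fus") {
      bel_mod("fus", partner = map_entity(m$partner, config),
              breakpoints = m$breakpoints)
    } else {
      m
    }
  })
  locations <- if (config$strip_tloc_args) list() else
    lapply(t$locations, map_entity, config = config)
  reactants <- if (!is.null(t$reactants))
    lapply(t$reactants, simplify_term, config = config)
  products <- if (!is.null(t$products))
    lapply(t$products, simplify_term, config = config)
  if (fn %in% c("complex", "composite") && length(args) > 1) {
    args <- args[order(vapply(args, render_bel, ""))]
  }
  if (fn == "rxn") {
    if (length(reactants) > 1) reactants <- reactants[order(vapply(reactants, render_bel, ""))]
    if (length(products) > 1) products <- products[order(vapply(products, render_bel, ""))]
  }
  bel_term(fn, entity = entity, args = args, mods = mods,
           locations = locations, reactants = reactants, products = products)
}

#' Simplify a BEL statement under the track equivalence rules
#'
#' Applies the rules selected in `config` (see [simplify_config()]) and
#' returns a new statement; the operation is idempotent and never changes
#' the number of terms or the subject/object structure.
#'
#' @param x A [bel_statement()] or [bel_term()].
#' @param config A [simplify_config()].
#' @return A node of the same class as `x`.
#' @export
#' @examples
#' s <- parse_bel_statement(
#'   "cat(p(MGI:Crk)) directlyIncreases p(MGI:Bcar1, pmod(P, T, 202))")
#' render_bel(simplify_bel(s))
simplify_bel <- function(x, config = simplify_config()) {
  stopifnot(inherits(config, "simplify_config"))
  if (is_bel_term(x)) return(simplify_term(x, config))
  if (!is_bel_statement(x)) stop("not a BEL term or statement", call. = FALSE)
  rel <- x$rel
  if (config$collapse_direct) {
    rel <- sub("^directly(I)", "i", sub("^directly(D)", "d", rel))
  }
  object <- if (is_bel_statement(x$object)) {
    simplify_bel(x$object, config)
  } else {
    simplify_term(x$object, config)
  }
  bel_statement(simplify_term(x$subject, config), rel, object)
}

#' Test two BEL statements for track equivalence
#'
#' Two statements are equivalent when their simplified canonical renderings
#' are equal. This is the comparison the cascade scorer uses at statement
#' level.
#'
#' @param a,b [bel_statement()]s (or strings, parsed on the fly).
#' @param config A [simplify_config()].
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' statements_equivalent(
#'   "cat(p(MGI:Crk)) directlyIncreases p(MGI:Bcar1, pmod(P))",
#'   "act(p(MGI:Crk)) -> p(MGI:Bcar1, pmod(P, S, 41))")
statements_equivalent <- function(a, b, config = simplify_config()) {
  if (is.character(a)) a <- parse_bel_statement(a)
  if (is.character(b)) b <- parse_bel_statement(b)
  identical(render_bel(simplify_bel(a, config)),
            render_bel(simplify_bel(b, config)))
}
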