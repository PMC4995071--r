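# Canonical text rendering of BEL abstract syntax. Deterministic: short-form
# function codes by default (long on request), ", " between arguments,
# double-quote quoting exactly when the name contains a character outside
# [A-Za-z0-9_], relationships always in long form. parse(render(x)) == x
# for every valid AST.

quote_bel_name <- function(name) {
  if (grepl("^[A-Za-z0-9_]+$", name)) {
    name
  } else {
    paste0('"', gsub('(["\\\\])', "\\\\\\1", name), '"')
  }
}

render_entity <- function(x) paste0(x$ns, ":", quote_bel_name(x$name))

render_mod <- function(x, style) {
  fn <- if (style == "long") .bel_mod_long_form[[x$kind]] else x$kind
  args <- switch(x$kind,
    pmod = c(x$type, x$residue, if (!is.null(x$position)) as.character(x$position)),
    sub = c(x$ref, as.character(x$position), x$alt),
    trunc = as.character(x$position),
    fus = c(if (!is.null(x$partner)) render_entity(x$partner),
            if (!is.null(x$breakpoints)) as.character(x$breakpoints))
  )
  paste0(fn, "(", paste(args, collapse = ", "), ")")
}

render_term <- function(x, style) {
  fn <- if (style == "long") .bel_long_form[[x$fn]] else x$fn
  args <- character()
  if (x$fn == "rxn") {
    args <- c(
      paste0("reactants(",
             paste(vapply(x$reactants, render_term, "", style = style),
                   collapse = ", "), ")"),
      paste0("products(",
             paste(vapply(x$products, render_term, "", style = style),
                   collapse = ", "), ")")
    )
  } else {
    if (!is.null(x$entity)) args <- c(args, render_entity(x$entity))
    if (length(x$args)) {
      args <- c(args, vapply(x$args, render_term, "", style = style))
    }
    if (length(x$mods)) {
      args <- c(args, vapply(x$mods, render_mod, "", style = style))
    }
    if (length(x$locations)) {
      args <- c(args, vapply(x$locations, render_entity, ""))
    }
  }
  paste0(fn, "(", paste(args, collapse = ", "), ")")
}

#' Render a BEL node as canonical text
#'
#' Produces a deterministic canonical string for an entity, term or
#' statement: short-form function codes (or long forms with
#' `style = "long"`), a single space after each comma, double-quote quoting
#' exactly when a name requires it, and relationships in long form. The
#' canonical string re-parses to an identical AST, and is used as the
#' identity of a statement throughout the evaluation machinery.
#'
#' @param x A [bel_entity()], [bel_term()] or [bel_statement()].
#' @param style `"short"` (default) or `"long"` function spellings.
#' @return A single character string.
#' @export
#' @examples
#' render_bel(parse_bel_statement("a(CHEBI:water) -> p(HGNC:IL6)"))
#' render_bel(parse_bel_term("p(HGNC:IL6)"), style = "long")
render_bel <- function(x, style = c("short", "long")) {
  style <- match.arg(style)
  if (is_bel_entity(x)) return(render_entity(x))
  if (is_bel_term(x)) return(render_term(x, style))
  if (is_bel_statement(x)) {
    obj <- if (is_bel_statement(x$object)) {
      paste0("(", render_bel(x$object, style), ")")
    } else {
      render_term(x$object, style)
    }
    return(paste(render_term(x$subject, style), x$rel, obj))
  }
  stop("not a BEL AST node", call. = FALSE)
}
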