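# Structural and namespace-compatibility validation of BEL ASTs. Violations
# are data (a data.frame), not errors, so that batch validation of corpora
# can report everything at once.

violation <- function(rule, node, message) {
  new_df(rule = rule, node = node, message = message)
}

no_violations <- function() {
  new_df(rule = character(), node = character(), message = character())
}

validate_entity <- function(e, fn, where) {
  v <- no_violations()
  if (!nzchar(e$name)) {
    v <- rbind(v, violation("entity-name", where, "entity name is empty"))
  }
  allowed <- .bel_ns_restrictions[[toupper(e$ns)]]
  if (!is.null(allowed) && !is.null(fn) && !fn %in% allowed) {
    v <- rbind(v, violation(
      "namespace-compatibility", where,
      sprintf("namespace %s may only appear under %s(), not %s()",
              e$ns, paste(allowed, collapse = "()/"), fn)))
  }
  # microRNA names are valid under g()/m()/r() but not p(); detected by the
  # conventional MIR/Mir symbol prefix (a documented heuristic)
  if (!is.null(fn) && fn == "p" && toupper(e$ns) %in% .bel_gene_namespaces &&
      grepl("^[Mm][Ii][Rr][0-9]", e$name)) {
    v <- rbind(v, violation(
      "microrna-under-p", where,
      sprintf("microRNA name %s:%s is not valid under p()", e$ns, e$name)))
  }
  v
}

validate_mod <- function(m, where) {
  v <- no_violations()
  need <- function(cond, msg) {
    if (!cond) v <<- rbind(v, violation("modification-arity", where, msg))
  }
  switch(m$kind,
    pmod = {
      need(!is.null(m$type), "pmod requires a modification type code")
      need(is.null(m$position) || !is.null(m$residue),
           "pmod position requires a residue")
    },
    sub = need(!is.null(m$ref) && !is.null(m$position) && !is.null(m$alt),
               "sub requires reference, position and alternate"),
    trunc = need(!is.null(m$position), "trunc requires a position"),
    fus = {
      need(!is.null(m$partner), "fus requires a partner entity")
      if (!is.null(m$partner)) {
        v <- rbind(v, validate_entity(m$partner, NULL, where))
      }
    }
  )
  if (!is.null(m$position)) {
    if (any(m$position < 1)) {
      v <- rbind(v, violation("modification-arity", where,
                              "positions must be >= 1"))
    }
  }
  v
}

validate_term <- function(t, where = render_bel(t)) {
  v <- no_violations()
  add <- function(rule, msg) v <<- rbind(v, violation(rule, where, msg))
  fn <- t$fn
  n_args <- length(t$args)
  abundance_member <- function(x) is_bel_term(x) && x$fn %in% .bel_abundance_fns

  if (fn %in% c(.bel_abundance_fns, .bel_process_fns)) {
    if (is.null(t$entity)) add("arity", sprintf("%s() requires one entity", fn))
    if (n_args > 0) add("arity", sprintf("%s() takes no inner terms", fn))
    if (length(t$mods) > 0 && fn != "p") {
      add("mods-only-on-p",
          sprintf("modifications are only valid on p(), not %s()", fn))
    }
  } else if (fn == "complex") {
    if (!is.null(t$entity) && n_args > 0) {
      add("arity", "complex() carries either a named entity or member terms, not both")
    }
    if (is.null(t$entity)) {
      if (n_args < 2) add("arity", "complex() requires at least two member terms")
      if (n_args > 0 && !all(vapply(t$args, abundance_member, TRUE))) {
        add("arity", "complex() members must be abundance terms")
      }
    }
  } else if (fn == "composite") {
    if (!is.null(t$entity)) add("arity", "composite() does not carry a named entity")
    if (n_args < 2) add("arity", "composite() requires at least two member terms")
    if (n_args > 0 && !all(vapply(t$args, abundance_member, TRUE))) {
      add("arity", "composite() members must be abundance terms")
    }
  } else if (fn %in% .bel_activity_fns) {
    ok_inner <- n_args == 1 && is_bel_term(t$args[[1]]) &&
      (t$args[[1]]$fn %in% c(.bel_abundance_fns, "complex"))
    if (!ok_inner) {
      add("arity",
          sprintf("%s() requires exactly one inner abundance or complex term", fn))
    }
  } else if (fn %in% c("deg", "sec", "surf", "tloc")) {
    ok_inner <- n_args == 1 && is_bel_term(t$args[[1]]) &&
      (t$args[[1]]$fn %in% c(.bel_abundance_fns, "complex"))
    if (!ok_inner) {
      add("arity", sprintf("%s() requires exactly one inner abundance term", fn))
    }
    if (fn != "tloc" && length(t$locations) > 0) {
      add("arity", sprintf("%s() takes no location arguments", fn))
    }
    if (fn == "tloc" && !length(t$locations) %in% c(0, 2)) {
      add("arity", "tloc() takes either zero or two location arguments")
    }
  } else if (fn == "rxn") {
    if (length(t$reactants %||% list()) < 1 || length(t$products %||% list()) < 1) {
      add("arity", "rxn() requires non-empty reactants() and products()")
    }
  } else {
    add("unknown-function", sprintf("unknown function code '%s'", fn))
  }

  if (!is.null(t$entity)) v <- rbind(v, validate_entity(t$entity, fn, where))
  for (m in t$mods) v <- rbind(v, validate_mod(m, where))
  for (loc in t$locations) v <- rbind(v, validate_entity(loc, NULL, where))
  for (inner in t$args) v <- rbind(v, validate_term(inner, where = render_bel(inner)))
  for (inner in t$reactants %||% list()) v <- rbind(v, validate_term(inner))
  for (inner in t$products %||% list()) v <- rbind(v, validate_term(inner))
  v
}

#' Validate a BEL term or statement
#'
#' Checks the structural invariants of BEL 1.0 (function arity, modification
#' arguments, nesting depth) and the namespace--function compatibility rules
#' used in the corpora: CHEBI entities only under `a()`, MESHD only under
#' `path()`, GOBP only under `bp()`, gene namespaces (HGNC, MGI, EGID, RGD)
#' only under `g()`/`r()`/`m()`/`p()`, and microRNA gene symbols not under
#' `p()`. Statement nesting is limited to one level (a statement may appear
#' as object of a statement, but not deeper).
#'
#' @param x A [bel_term()] or [bel_statement()], typically from
#'   [parse_bel_term()]/[parse_bel_statement()].
#' @return A data.frame with columns `rule`, `node` and `message`, one row
#'   per violation; zero rows when the node is valid.
#' @export
#' @examples
#' nrow(bel_validate(parse_bel_statement("a(CHEBI:water) -> p(HGNC:IL6)")))
#' bel_validate(parse_bel_term("p(CHEBI:water)"))
bel_validate <- function(x) {
  if (is_bel_term(x)) return(validate_term(x))
  if (!is_bel_statement(x)) stop("not a BEL term or statement", call. = FALSE)
  v <- no_violations()
  if (statement_depth(x) > 1) {
    v <- rbind(v, violation("nesting-depth", render_bel(x),
                            "statements may be nested at most one level deep"))
  }
  v <- rbind(v, validate_term(x$subject))
  obj <- x$object
  if (is_bel_statement(obj)) {
    v <- rbind(v, validate_term(obj$subject))
    if (is_bel_statement(obj$object)) {
      # deeper nesting already reported above; still validate the terms inside
      v <- rbind(v, bel_validate(obj$object))
    } else {
      v <- rbind(v, validate_term(obj$object))
    }
  } else {
    v <- rbind(v, validate_term(obj))
  }
  v
}

#' @rdname bel_validate
#' @return `bel_is_valid()` returns `TRUE` when there are no violations.
#' @export
bel_is_valid <- function(x) nrow(bel_validate(x)) == 0
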