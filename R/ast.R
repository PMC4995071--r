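# Abstract syntax for BEL 1.0: namespaced entities, protein modifications,
# terms and statements, as plain S3 lists so that parser output and
# programmatically built nodes are identical().

#' Construct a namespaced entity
#'
#' An entity is a name grounded in a controlled vocabulary (namespace), e.g.
#' `HGNC:IL6` or `CHEBI:"leukotriene D4"`. Namespaces are an open set; the
#' compatibility restrictions for the well-known ones (CHEBI under `a()`,
#' MESHD under `path()`, GOBP under `bp()`, gene namespaces under
#' `g()/r()/m()/p()`) are checked by [bel_validate()].
#'
#' @param ns Namespace code, e.g. `"HGNC"`.
#' @param name Entity name or identifier; must be non-empty.
#' @return An object of class `bel_entity`.
#' @export
#' @examples
#' bel_entity("HGNC", "IL6")
bel_entity <- function(ns, name) {
  stopifnot(is.character(ns), length(ns) == 1, nzchar(ns),
            is.character(name), length(name) == 1)
  structure(list(ns = ns, name = name), class = "bel_entity")
}

#' Construct a protein modification
#'
#' Builds the four modification kinds that may decorate a `p()` term:
#' `pmod` (post-translational modification, e.g. `pmod(P)` for
#' phosphorylation), `sub` (amino-acid substitution), `trunc` (truncation)
#' and `fus` (fusion protein).
#'
#' @param kind One of `"pmod"`, `"sub"`, `"trunc"`, `"fus"`.
#' @param type Single-letter modification type code for `pmod` (P, A, H, ...).
#' @param residue Optional one-letter amino-acid code (`pmod`).
#' @param position Optional integer sequence position (`pmod`, required for
#'   `trunc` and `sub`).
#' @param ref,alt One-letter reference/alternate amino acids (`sub`).
#' @param partner A [bel_entity()], the 3' fusion partner (`fus`).
#' @param breakpoints Optional integer pair of fusion breakpoints (`fus`).
#' @return An object of class `bel_mod`.
#' @export
#' @examples
#' bel_mod("pmod", type = "P", residue = "T", position = 202)
bel_mod <- function(kind, type = NULL, residue = NULL, position = NULL,
                    ref = NULL, alt = NULL, partner = NULL,
                    breakpoints = NULL) {
  kind <- match.arg(kind, c("pmod", "sub", "trunc", "fus"))
  if (!is.null(position)) position <- as.integer(position)
  if (!is.null(breakpoints)) breakpoints <- as.integer(breakpoints)
  structure(
    list(kind = kind, type = type, residue = residue, position = position,
         ref = ref, alt = alt, partner = partner, breakpoints = breakpoints),
    class = "bel_mod"
  )
}

#' Construct a BEL term
#'
#' Low-level constructor used by the parser; also usable to build terms
#' programmatically. `fn` is always stored as the short-form code, so a
#' parsed long-form expression and the equivalent short-form one yield
#' `identical()` ASTs.
#'
#' @param fn Short-form function code (see [bel_vocabulary()]).
#' @param entity Optional [bel_entity()] for abundance/process functions and
#'   named complexes.
#' @param args List of inner [bel_term()]s (complex/composite members, the
#'   single argument of activity and transformation functions).
#' @param mods List of [bel_mod()] modifications (on `p()` terms).
#' @param locations List of up to two [bel_entity()]s: the from/to
#'   compartments of `tloc()`.
#' @param reactants,products Lists of [bel_term()]s, for `rxn()`.
#' @return An object of class `bel_term`.
#' @export
#' @examples
#' bel_term("p", entity = bel_entity("HGNC", "IL6"))
bel_term <- function(fn, entity = NULL, args = list(), mods = list(),
                     locations = list(), reactants = NULL, products = NULL) {
  stopifnot(is.character(fn), length(fn) == 1)
  structure(
    list(fn = fn, entity = entity, args = args, mods = mods,
         locations = locations, reactants = reactants, products = products),
    class = "bel_term"
  )
}

#' Construct a BEL statement
#'
#' A statement is a subject term, a causal relationship and an object, where
#' the object may itself be a statement (one level of nesting).
#'
#' @param subject A [bel_term()].
#' @param rel Relationship: long form (`"increases"`, `"decreases"`,
#'   `"directlyIncreases"`, `"directlyDecreases"`) or the symbolic short form
#'   (`->`, `-|`, `=>`, `=|`).
#' @param object A [bel_term()] or nested `bel_statement`.
#' @return An object of class `bel_statement`.
#' @export
#' @examples
#' bel_statement(
#'   bel_term("p", entity = bel_entity("HGNC", "TIMP2")),
#'   "decreases",
#'   bel_term("cat", args = list(bel_term("p", entity = bel_entity("HGNC", "MMP2"))))
#' )
bel_statement <- function(subject, rel, object) {
  if (rel %in% names(.bel_rel_short)) rel <- .bel_rel_short[[rel]]
  if (!rel %in% .bel_relationships) {
    stop("unknown relationship type: ", rel, call. = FALSE)
  }
  structure(list(subject = subject, rel = rel, object = object),
            class = "bel_statement")
}

#' @export
print.bel_entity <- function(x, ...) {
  cat("<bel_entity> ", render_bel(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.bel_term <- function(x, ...) {
  cat("<bel_term> ", render_bel(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.bel_statement <- function(x, ...) {
  cat("<bel_statement> ", render_bel(x), "\n", sep = "")
  invisible(x)
}

is_bel_term <- function(x) inherits(x, "bel_term")
is_bel_statement <- function(x) inherits(x, "bel_statement")
is_bel_entity <- function(x) inherits(x, "bel_entity")

# depth of statement nesting: 0 for term object, 1 for statement object, ...
statement_depth <- function(x) {
  if (!is_bel_statement(x)) return(-1L)
  if (is_bel_statement(x$object)) 1L + statement_depth(x$object) else 0L
}
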