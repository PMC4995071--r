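# Recursive-descent parser for BEL 1.0 term and statement expressions.
#
# The tokenizer normalizes Unicode curly quotes and non-breaking spaces
# (corpus files in the wild contain them), accepts both ' and " as quote
# characters, and treats whitespace between tokens as insignificant.
# Function and namespace codes are matched case-sensitively; namespaces are
# an open set.

bel_parse_error <- function(msg, pos = NA_integer_) {
  stop(errorCondition(
    if (is.na(pos)) msg else sprintf("%s (at position %d)", msg, pos),
    pos = pos,
    class = c("bel_parse_error", "error")
  ))
}

.token_regex <- paste0(
  "\\s+",                                  # whitespace (skipped)
  "|[A-Za-z0-9_]+",                        # bare identifier / number
  "|\"(?:[^\"\\\\]|\\\\.)*\"",             # double-quoted name
  "|'(?:[^'\\\\]|\\\\.)*'",                # single-quoted name
  "|->|=>|-\\||=\\|",                      # relationship symbols
  "|[(),:]",
  "|."                                     # anything else -> lexical error
)

normalize_bel_text <- function(text) {
  text <- gsub("[“”]", "\"", text)
  text <- gsub("[‘’]", "'", text)
  gsub(" ", " ", text)
}

tokenize_bel <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- normalize_bel_text(text)
  m <- gregexpr(.token_regex, text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(list(type = character(), value = character(), pos = integer()))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  vals <- substring(text, starts, starts + lens - 1)
  keep <- !grepl("^\\s", vals)
  vals <- vals[keep]; starts <- starts[keep]; lens <- lens[keep]
  n <- length(vals)
  types <- character(n)
  out_vals <- vals
  for (i in seq_len(n)) {
    v <- vals[i]
    c1 <- substr(v, 1, 1)
    if (grepl("^[A-Za-z0-9_]", c1)) {
      types[i] <- "IDENT"
    } else if (c1 == "\"" || c1 == "'") {
      if (lens[i] < 2 || substr(v, lens[i], lens[i]) != c1) {
        bel_parse_error("unterminated quoted name", starts[i])
      }
      inner <- substr(v, 2, lens[i] - 1)
      out_vals[i] <- gsub("\\\\(.)", "\\1", inner)
      types[i] <- "STRING"
    } else if (v %in% names(.bel_rel_short)) {
      types[i] <- "REL"
      out_vals[i] <- .bel_rel_short[[v]]
    } else if (v %in% c("(", ")", ",", ":")) {
      types[i] <- "PUNCT"
    } else {
      bel_parse_error(sprintf(
        "unexpected character '%s'; names containing special characters must be quoted",
        v), starts[i])
    }
  }
  list(type = types, value = out_vals, pos = starts)
}

# --- parser state -----------------------------------------------------------

new_pstate <- function(toks) {
  env <- new.env(parent = emptyenv())
  env$type <- toks$type
  env$value <- toks$value
  env$pos <- toks$pos
  env$i <- 1L
  env$n <- length(toks$type)
  env
}

pk_type <- function(st, ahead = 0L) {
  j <- st$i + ahead
  if (j > st$n) "EOF" else st$type[j]
}
pk_value <- function(st, ahead = 0L) {
  j <- st$i + ahead
  if (j > st$n) "" else st$value[j]
}
pk_pos <- function(st) {
  if (st$i > st$n) {
    if (st$n > 0) st$pos[st$n] + 1L else 1L
  } else {
    st$pos[st$i]
  }
}
p_advance <- function(st) {
  v <- pk_value(st)
  st$i <- st$i + 1L
  v
}
p_expect <- function(st, value, what = NULL) {
  if (pk_type(st) == "EOF" || pk_value(st) != value) {
    bel_parse_error(sprintf("expected '%s'%s but found '%s'",
                            value,
                            if (is.null(what)) "" else paste0(" ", what),
                            if (pk_type(st) == "EOF") "end of input" else pk_value(st)),
                    pk_pos(st))
  }
  p_advance(st)
}

resolve_fn <- function(code, pos) {
  if (code %in% names(.bel_long_form)) return(code)
  hit <- names(.bel_long_form)[match(code, .bel_long_form)]
  if (!is.na(hit)) return(hit)
  if (code %in% names(.bel_long_aliases)) return(.bel_long_aliases[[code]])
  bel_parse_error(sprintf("unknown function code '%s'", code), pos)
}

resolve_mod <- function(code) {
  if (code %in% names(.bel_mod_long_form)) return(code)
  hit <- names(.bel_mod_long_form)[match(code, .bel_mod_long_form)]
  if (!is.na(hit)) return(hit)
  NA_character_
}

is_all_digits <- function(x) grepl("^[0-9]+$", x)

# --- grammar productions ----------------------------------------------------

p_entity <- function(st) {
  pos <- pk_pos(st)
  if (pk_type(st) != "IDENT") {
    bel_parse_error("expected a namespace code", pos)
  }
  ns <- p_advance(st)
  p_expect(st, ":", "after namespace code")
  if (!pk_type(st) %in% c("IDENT", "STRING")) {
    bel_parse_error("expected an entity name after ':'", pk_pos(st))
  }
  name <- p_advance(st)
  if (!nzchar(name)) bel_parse_error("entity name is empty", pos)
  bel_entity(ns, name)
}

# lookahead: does an entity (IDENT ':') start here?
at_entity <- function(st) {
  pk_type(st) == "IDENT" && pk_type(st, 1L) == "PUNCT" && pk_value(st, 1L) == ":"
}

p_single_letter <- function(st, what) {
  pos <- pk_pos(st)
  if (pk_type(st) != "IDENT") bel_parse_error(paste0("expected ", what), pos)
  v <- p_advance(st)
  if (nchar(v) != 1 || is_all_digits(v)) {
    bel_parse_error(sprintf("expected a single-letter %s, found '%s'", what, v), pos)
  }
  v
}

p_number <- function(st, what) {
  pos <- pk_pos(st)
  if (pk_type(st) != "IDENT" || !is_all_digits(pk_value(st))) {
    bel_parse_error(paste0("expected ", what), pos)
  }
  as.integer(p_advance(st))
}

p_mod <- function(st) {
  pos <- pk_pos(st)
  kind <- resolve_mod(pk_value(st))
  if (is.na(kind)) {
    bel_parse_error(sprintf("expected a modification function, found '%s'",
                            pk_value(st)), pos)
  }
  p_advance(st)
  p_expect(st, "(")
  out <- switch(kind,
    pmod = {
      type <- p_single_letter(st, "modification type code")
      residue <- NULL; position <- NULL
      if (pk_value(st) == ",") {
        p_advance(st)
        if (is_all_digits(pk_value(st))) {
          bel_parse_error("pmod position requires a residue code before it",
                          pk_pos(st))
        }
        residue <- p_single_letter(st, "amino-acid code")
        if (pk_value(st) == ",") {
          p_advance(st)
          position <- p_number(st, "a sequence position")
        }
      }
      bel_mod("pmod", type = type, residue = residue, position = position)
    },
    sub = {
      ref <- p_single_letter(st, "reference amino-acid code")
      p_expect(st, ",")
      position <- p_number(st, "a sequence position")
      p_expect(st, ",")
      alt <- p_single_letter(st, "alternate amino-acid code")
      bel_mod("sub", ref = ref, alt = alt, position = position)
    },
    trunc = {
      position <- p_number(st, "a truncation position")
      bel_mod("trunc", position = position)
    },
    fus = {
      partner <- p_entity(st)
      breakpoints <- NULL
      if (pk_value(st) == ",") {
        p_advance(st)
        b1 <- p_number(st, "a fusion breakpoint")
        p_expect(st, ",")
        b2 <- p_number(st, "a fusion breakpoint")
        breakpoints <- c(b1, b2)
      }
      bel_mod("fus", partner = partner, breakpoints = breakpoints)
    }
  )
  p_expect(st, ")")
  out
}

p_term <- function(st) {
  pos <- pk_pos(st)
  if (pk_type(st) != "IDENT") {
    bel_parse_error(sprintf("expected a function code, found '%s'",
                            if (pk_type(st) == "EOF") "end of input" else pk_value(st)),
                    pos)
  }
  fn <- resolve_fn(p_advance(st), pos)
  p_expect(st, "(", sprintf("after function '%s'", fn))

  term <- if (fn %in% c(.bel_abundance_fns, .bel_process_fns)) {
    entity <- p_entity(st)
    mods <- list()
    while (pk_value(st) == ",") {
      p_advance(st)
      mods <- c(mods, list(p_mod(st)))
    }
    bel_term(fn, entity = entity, mods = mods)
  } else if (fn == "complex") {
    if (at_entity(st)) {
      bel_term("complex", entity = p_entity(st))
    } else {
      members <- list(p_term(st))
      while (pk_value(st) == ",") {
        p_advance(st)
        members <- c(members, list(p_term(st)))
      }
      bel_term("complex", args = members)
    }
  } else if (fn == "composite") {
    members <- list(p_term(st))
    while (pk_value(st) == ",") {
      p_advance(st)
      members <- c(members, list(p_term(st)))
    }
    bel_term("composite", args = members)
  } else if (fn %in% c(.bel_activity_fns, "deg", "sec", "surf")) {
    bel_term(fn, args = list(p_term(st)))
  } else if (fn == "tloc") {
    inner <- p_term(st)
    locations <- list()
    while (pk_value(st) == ",") {
      p_advance(st)
      if (length(locations) >= 2) {
        bel_parse_error("tloc() takes at most two location arguments", pk_pos(st))
      }
      locations <- c(locations, list(p_entity(st)))
    }
    bel_term("tloc", args = list(inner), locations = locations)
  } else if (fn == "rxn") {
    if (pk_value(st) != "reactants") {
      bel_parse_error("expected 'reactants(...)' inside rxn()", pk_pos(st))
    }
    p_advance(st)
    p_expect(st, "(")
    reactants <- list(p_term(st))
    while (pk_value(st) == ",") { p_advance(st); reactants <- c(reactants, list(p_term(st))) }
    p_expect(st, ")")
    p_expect(st, ",")
    if (pk_value(st) != "products") {
      bel_parse_error("expected 'products(...)' inside rxn()", pk_pos(st))
    }
    p_advance(st)
    p_expect(st, "(")
    products <- list(p_term(st))
    while (pk_value(st) == ",") { p_advance(st); products <- c(products, list(p_term(st))) }
    p_expect(st, ")")
    bel_term("rxn", reactants = reactants, products = products)
  } else {
    bel_parse_error(sprintf("function '%s' cannot be parsed as a term", fn), pos)
  }
  p_expect(st, ")", sprintf("to close '%s('", fn))
  term
}

p_relationship <- function(st) {
  pos <- pk_pos(st)
  if (pk_type(st) == "REL") return(p_advance(st))
  if (pk_type(st) == "IDENT" && pk_value(st) %in% .bel_relationships) {
    return(p_advance(st))
  }
  bel_parse_error(sprintf("expected a relationship type, found '%s'",
                          if (pk_type(st) == "EOF") "end of input" else pk_value(st)),
                  pos)
}

p_statement <- function(st) {
  subject <- p_term(st)
  rel <- p_relationship(st)
  object <- if (pk_value(st) == "(" && pk_type(st) == "PUNCT") {
    p_advance(st)
    inner <- p_statement(st)
    p_expect(st, ")", "to close the nested statement")
    inner
  } else {
    p_term(st)
  }
  bel_statement(subject, rel, object)
}

p_eof <- function(st) {
  if (pk_type(st) != "EOF") {
    bel_parse_error(sprintf("unexpected trailing input '%s'", pk_value(st)),
                    pk_pos(st))
  }
}

# --- public entry points ----------------------------------------------------

#' Parse a BEL term expression
#'
#' Parses a single BEL 1.0 term, e.g. `p(HGNC:IL6)` or
#' `complex(p(MGI:Fos), p(MGI:Jun))`. Short- and long-form function names
#' parse to identical abstract syntax; both `'` and `"` are accepted as quote
#' characters. Syntax errors carry the character position at which parsing
#' failed.
#'
#' @param text A single BEL term string.
#' @return A [bel_term()] object.
#' @seealso [parse_bel_statement()], [render_bel()], [bel_validate()]
#' @export
#' @examples
#' parse_bel_term("p(HGNC:AKT1, pmod(P))")
#' identical(parse_bel_term("proteinAbundance(HGNC:IL6)"),
#'           parse_bel_term("p(HGNC:IL6)"))
parse_bel_term <- function(text) {
  st <- new_pstate(tokenize_bel(text))
  term <- p_term(st)
  p_eof(st)
  term
}

#' Parse a BEL statement
#'
#' Parses a subject--relationship--object BEL 1.0 statement. The symbolic
#' relationship forms `->`, `=>`, `-|`, `=|` are normalized to their long
#' forms `increases`, `directlyIncreases`, `decreases`,
#' `directlyDecreases`. A parenthesized statement is accepted as object
#' (nested statement); [bel_validate()] enforces the nesting-depth limit.
#'
#' @param text A single BEL statement string.
#' @return A [bel_statement()] object.
#' @export
#' @examples
#' parse_bel_statement("p(HGNC:TIMP2) directlyDecreases cat(p(HGNC:MMP2))")
#' parse_bel_statement("a(CHEBI:water) -> p(HGNC:IL6)")$rel
parse_bel_statement <- function(text) {
  st <- new_pstate(tokenize_bel(text))
  stmt <- p_statement(st)
  p_eof(st)
  stmt
}

#' Parse a BEL expression, auto-detecting term versus statement
#'
#' Convenience wrapper: an input containing a top-level relationship parses
#' as a statement, anything else as a term.
#'
#' @param text A single BEL expression string.
#' @return A [bel_term()] or [bel_statement()].
#' @export
parse_bel <- function(text) {
  toks <- tokenize_bel(text)
  depth <- 0L
  has_rel <- FALSE
  for (j in seq_along(toks$type)) {
    v <- toks$value[j]
    if (toks$type[j] == "PUNCT") {
      if (v == "(") depth <- depth + 1L
      if (v == ")") depth <- depth - 1L
    } else if (depth == 0L &&
               (toks$type[j] == "REL" ||
                (toks$type[j] == "IDENT" && v %in% .bel_relationships))) {
      has_rel <- TRUE
      break
    }
  }
  if (has_rel) parse_bel_statement(text) else parse_bel_term(text)
}
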