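test_that("every canonical example parses, validates and round-trips", {
  for (s in bel_examples()) {
    x <- parse_bel(s)
    expect_identical(parse_bel(render_bel(x)), x, label = s)
    expect_identical(bel_validate(x)$message, character(), label = s)
  }
})

test_that("short and long function forms parse to identical ASTs", {
  for (s in bel_examples()) {
    x <- parse_bel(s)
    expect_identical(parse_bel(render_bel(x, style = "long")), x, label = s)
  }
  # the alternate capitalization of the microRNA long form is accepted too
  expect_identical(parse_bel_term("microRNAAbundance(MGI:Mir21)"),
                   parse_bel_term("m(MGI:Mir21)"))
})

test_that("symbolic relationship forms normalize to long forms", {
  expect_identical(parse_bel_statement("a(CHEBI:water) -> p(HGNC:IL6)")$rel,
                   "increases")
  expect_identical(parse_bel_statement("a(CHEBI:water) => p(HGNC:IL6)")$rel,
                   "directlyIncreases")
  expect_identical(parse_bel_statement("a(CHEBI:water) -| p(HGNC:IL6)")$rel,
                   "decreases")
  expect_identical(parse_bel_statement("a(CHEBI:water) =| p(HGNC:IL6)")$rel,
                   "directlyDecreases")
  expect_identical(
    render_bel(parse_bel_statement("a(CHEBI:water) -> p(HGNC:IL6)")),
    "a(CHEBI:water) increases p(HGNC:IL6)")
})

test_that("single, double and curly quotes are interchangeable on input", {
  base <- parse_bel_term('a(CHEBI:"brefeldin A")')
  expect_identical(parse_bel_term("a(CHEBI:'brefeldin A')"), base)
  expect_identical(parse_bel_term("a(CHEBI:“brefeldin A”)"), base)
  expect_identical(parse_bel_term("a(CHEBI:‘brefeldin A’)"), base)
  # canonical rendering always uses double quotes
  expect_identical(render_bel(base), 'a(CHEBI:"brefeldin A")')
})

test_that("quoting is involutive and applied exactly when required", {
  names <- c("IL6", "AP-1 Complex", "synaptic transmission, cholinergic",
             "a(b)", "5'-phosphate", 'say "hi"', "back\\slash")
  for (nm in names) {
    t <- bel_term("a", entity = bel_entity("CHEBI", nm))
    expect_identical(parse_bel_term(render_bel(t))$entity$name, nm, label = nm)
  }
  expect_identical(render_bel(bel_entity("HGNC", "IL6")), "HGNC:IL6")
  expect_match(render_bel(bel_entity("NCH", "AP-1 Complex")), "^NCH:\"")
})

test_that("whitespace between tokens is insignificant", {
  expect_identical(
    parse_bel_statement("p( HGNC : TIMP2 )  decreases  cat( p( HGNC:MMP2 ) )"),
    parse_bel_statement("p(HGNC:TIMP2) decreases cat(p(HGNC:MMP2))"))
  expect_identical(parse_bel_term("path(MESHD: Atherosclerosis)"),
                   parse_bel_term("path(MESHD:Atherosclerosis)"))
})

test_that("syntax errors carry a character position", {
  err <- tryCatch(parse_bel_term("p(HGNC:IL6"), error = identity)
  expect_s3_class(err, "bel_parse_error")
  expect_false(is.na(err$pos))

  err <- tryCatch(parse_bel_term("p(HGNC:AP-1 Complex)"), error = identity)
  expect_s3_class(err, "bel_parse_error")
  expect_match(conditionMessage(err), "quoted")
  expect_equal(err$pos, 10)

  expect_error(parse_bel_term("xyz(HGNC:IL6)"), "unknown function")
  expect_error(parse_bel_term('a(CHEBI:"unterminated)'), "unterminated")
  expect_error(parse_bel_statement("p(HGNC:A) p(HGNC:B)"), "relationship")
  expect_error(parse_bel_statement("p(HGNC:A)"), "relationship")
  expect_error(
    parse_bel_statement("p(HGNC:A) increases p(HGNC:B) increases p(HGNC:C)"),
    "trailing")
})

test_that("modification arguments are checked at parse time", {
  m <- parse_bel_term("p(HGNC:HIF1A, pmod(H, N, 803))")$mods[[1]]
  expect_identical(m[c("kind", "type", "residue", "position")],
                   list(kind = "pmod", type = "H", residue = "N",
                        position = 803L))
  # residue without position is allowed; position without residue is not
  expect_silent(parse_bel_term("p(MGI:Rela, pmod(A, K))"))
  expect_error(parse_bel_term("p(HGNC:AKT1, pmod(P, 303))"),
               "requires a residue")
  expect_error(parse_bel_term("p(HGNC:PIK3CA, sub(E, 545))"), "expected")
  s <- parse_bel_term("p(HGNC:BCR, fus(HGNC:JAK2, 1875, 2626))")$mods[[1]]
  expect_identical(s$breakpoints, c(1875L, 2626L))
})

test_that("nested statements parse as objects and render in parentheses", {
  s <- parse_bel_statement(
    "p(HGNC:HGF) decreases (p(HGNC:FAS) increases bp(GOBP:\"cell death\"))")
  expect_s3_class(s$object, "bel_statement")
  expect_identical(parse_bel_statement(render_bel(s)), s)
})
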