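#' Canonical BEL 1.0 example expressions
#'
#' A reference set of example terms and statements covering every function
#' and relationship of the BEL 1.0 subset used in the BioCreative V BEL
#' track corpora: one or more examples per abundance, modification,
#' transformation, activity and process function, plus one statement per
#' relationship type. Useful as a grammar-coverage fixture: every entry
#' parses, validates cleanly and round-trips through [render_bel()].
#'
#' @return A character vector of BEL expressions.
#' @export
#' @examples
#' all(vapply(bel_examples(), function(s) bel_is_valid(parse_bel(s)), TRUE))
bel_examples <- function() {
  c(
    # abundance functions
    "a(CHEBI:water)",
    "p(HGNC:IL6)",
    "complex(NCH:\"AP-1 Complex\")",
    "complex(p(MGI:Fos), p(MGI:Jun))",
    "composite(p(MGI:Il13),p(MGI:Ifng))",
    "g(HGNC:ERBB2)",
    "m(MGI:Mir21)",
    "r(HGNC:IL6)",
    # modification functions
    "p(HGNC:AKT1, pmod(P))",
    "p(MGI:Rela, pmod(A, K))",
    "p(HGNC:HIF1A, pmod(H, N, 803))",
    "p(HGNC:PIK3CA, sub(E, 545, K))",
    "p(HGNC:ABCA1, trunc(1851))",
    "p(HGNC:BCR, fus(HGNC:JAK2, 1875, 2626))",
    "p(HGNC:BCR, fus(HGNC:JAK2))",
    # transformation functions
    "deg(r(HGNC:MYC))",
    "sec(p(MGI:Il6))",
    "surf(p(RGD:Fas))",
    "tloc(p(HGNC:NFE2L2), MESHCL:Cytoplasm, MESHCL:\"Cell Nucleus\")",
    "rxn(reactants(a(CHEBI:\"leukotriene D4\")), products(a(CHEBI:\"leukotriene E4\")))",
    # activity functions
    "act(p(RGD:Sod1))",
    "cat(p(RGD:Sod1))",
    "chap(p(HGNC:CANX))",
    "gtp(p(PFH:\"RAS Family\"))",
    "kin(p(HGNC:CHEK1))",
    "pep(p(RGD:Ace))",
    "phos(p(HGNC:DUSP1))",
    "ribo(p(HGNC:PARP1))",
    "tscript(p(MGI:Trp53))",
    "tport(complex(NCH:\"ENaC Complex\"))",
    # process functions
    "bp(GO:\"cellular senescence\")",
    "path(MESHD:Atherosclerosis)",
    # relationship types
    "cat(p(MGI:Crk)) increases p(MGI:Bcar1,pmod(P))",
    "cat(p(MGI:Crk)) directlyIncreases p(MGI:Bcar1,pmod(P))",
    "p(HGNC:TIMP2) decreases cat(p(HGNC:MMP2))",
    "p(HGNC:TIMP2) directlyDecreases cat(p(HGNC:MMP2))"
  )
}
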