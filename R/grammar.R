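# Static grammar tables for BEL 1.0 as used in the BioCreative V BEL track
# corpora: function codes (short and long form), relationship types, and the
# namespace/function compatibility restrictions.

# short form -> long form, grouped by function class
.bel_long_form <- c(
  # abundance functions
  a        = "abundance",
  p        = "proteinAbundance",
  complex  = "complexAbundance",
  composite = "compositeAbundance",
  g        = "geneAbundance",
  m        = "microRNAabundance",
  r        = "rnaAbundance",
  # transformation functions
  deg      = "degradation",
  sec      = "cellSecretion",
  surf     = "cellSurfaceExpression",
  tloc     = "translocation",
  rxn      = "reaction",
  # activity functions
  act      = "molecularActivity",
  cat      = "catalyticActivity",
  chap     = "chaperoneActivity",
  gtp      = "gtpBoundActivity",
  kin      = "kinaseActivity",
  pep      = "peptidaseActivity",
  phos     = "phosphataseActivity",
  ribo     = "ribosylationActivity",
  tscript  = "transcriptionalActivity",
  tport    = "transportActivity",
  # process functions
  bp       = "biologicalProcess",
  path     = "pathology"
)

# modification functions live inside p() terms, not as terms of their own
.bel_mod_long_form <- c(
  pmod  = "proteinModification",
  sub   = "substitution",
  trunc = "truncation",
  fus   = "fusion"
)

# alternative long-form spellings accepted on input (capitalization dialects)
.bel_long_aliases <- c(
  microRNAAbundance = "m"
)

.bel_abundance_fns  <- c("a", "p", "g", "r", "m")
.bel_activity_fns   <- c("act", "cat", "chap", "gtp", "kin", "pep", "phos",
                         "ribo", "tscript", "tport")
.bel_transform_fns  <- c("deg", "sec", "surf", "tloc")
.bel_process_fns    <- c("bp", "path")

.bel_relationships <- c(
  "increases", "decreases", "directlyIncreases", "directlyDecreases"
)
.bel_rel_short <- c(
  "->" = "increases",
  "=>" = "directlyIncreases",
  "-|" = "decreases",
  "=|" = "directlyDecreases"
)

# namespace -> permitted enclosing functions; namespaces not listed form an
# open set and carry no restriction. Lookup is by upper-cased code so that
# CHEBI and ChEBI spellings resolve to the same restriction.
.bel_ns_restrictions <- list(
  CHEBI = "a",
  MESHD = "path",
  GOBP  = "bp",
  HGNC  = c("g", "r", "m", "p"),
  MGI   = c("g", "r", "m", "p"),
  RGD   = c("g", "r", "m", "p"),
  EGID  = c("g", "r", "m", "p")
)
.bel_gene_namespaces <- c("HGNC", "MGI", "RGD", "EGID")

#' BEL function and relationship vocabulary
#'
#' Returns the function codes of BEL 1.0 as used in the BioCreative V BEL
#' track corpora, mapping short form to long form, together with the
#' relationship vocabulary.
#'
#' @return A list with components `functions` (named character vector, short
#'   form to long form), `modifications` (ditto, for the modification
#'   functions usable inside `p()`), `relationships` (long forms) and
#'   `relationship_short` (named vector mapping symbols to long forms).
#' @export
#' @examples
#' bel_vocabulary()$relationships
bel_vocabulary <- function() {
  list(
    functions = .bel_long_form,
    modifications = .bel_mod_long_form,
    relationships = .bel_relationships,
    relationship_short = .bel_rel_short
  )
}
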