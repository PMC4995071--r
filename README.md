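# beltools

Tools for corpora of **BEL nanopubs** — statements in the Biological
Expression Language 1.0 paired with their PubMed citation and supporting
evidence text, as used in the BioCreative V BEL track.

BEL encodes causal biological findings as subject–relationship–object
triples over namespaced entities:

```
p(HGNC:TIMP2) decreases cat(p(HGNC:MMP2))
```

("the human TIMP2 protein decreases the catalytic activity of MMP2").
Building and evaluating systems that extract such statements from text
requires exact machinery around the language, and that machinery is what
this package provides:

* **Parse, validate, render** — a full parser for the BEL 1.0 subset used
  in the corpora (short and long function forms, quoted names, symbolic
  relationship forms, nested statements), a validator for arity and
  namespace–function compatibility rules, and a deterministic canonical
  renderer with `parse(render(x)) == x`.
* **Canonicalize** — the track's equivalence rules (`directly*` folding,
  activity collapse to `act()`, `pmod`/`tloc` argument stripping,
  optional ortholog folding, canonical complex member order), so
  statements the evaluation treats as equal compare equal.
* **Score** — the cascade precision/recall/F model: per-sentence set
  matching at term, function, relationship and full-statement levels
  (plus argument-free secondary variants), micro-averaged, with partial
  credit for partially correct statements.
* **Corpus I/O and filtering** — byte-exact readers/writers for the
  `.tab`, `.BEL`/`.sentence` and sentence-classification formats; the
  corpus-selection filter pipeline (evidence length 36–425 characters,
  per-evidence nanopub cap, namespace whitelist, entity cap, forbidden
  functions) with per-record rejection reasons; corpus statistics tables.
* **Agreement** — observed agreement and Cohen's kappa for label corpora,
  cascade-F inter-annotator agreement for statement corpora.
* **Retrieval** — trigger-word tri-occurrence search for candidate
  evidence excerpts (1–2 sentence windows, both entities plus a polarity
  trigger, newest publications first, capped at 10).
* **Synthetic corpora** — a generator with exact quota marginals shaped
  after the published training corpus, controlled prediction
  perturbations with manifest-exact expected scores, and annotator pairs
  at an analytic target kappa — the test bed for all of the above.

## Worked example

```r
library(beltools)

# parse and canonicalize under the track equivalence rules
s <- parse_bel_statement(
  "cat(p(MGI:Crk)) directlyIncreases p(MGI:Bcar1, pmod(P, T, 202))")
render_bel(simplify_bel(s))
#> [1] "act(p(MGI:Crk)) increases p(MGI:Bcar1, pmod(P))"

# cascade scoring: sentence s1 is predicted track-equivalently,
# sentence s2 with the wrong relationship direction
gold <- list(s1 = "cat(p(MGI:Crk)) directlyIncreases p(MGI:Bcar1, pmod(P))",
             s2 = "p(HGNC:TIMP2) decreases cat(p(HGNC:MMP2))")
pred <- list(s1 = "act(p(MGI:Crk)) -> p(MGI:Bcar1, pmod(P, S, 41))",
             s2 = "p(HGNC:TIMP2) increases act(p(HGNC:MMP2))")
score_bel(gold, pred)
#>                    level tp fp fn precision recall   f
#> 1                   term  4  0  0       1.0    1.0 1.0
#> 2               function  3  0  0       1.0    1.0 1.0
#> 3     function_secondary  3  0  0       1.0    1.0 1.0
#> 4           relationship  1  1  1       0.5    0.5 0.5
#> 5 relationship_secondary  1  1  1       0.5    0.5 0.5
#> 6              statement  1  1  1       0.5    0.5 0.5
```

All four entities and every function are recovered (term and function F
= 1.0), but the flipped direction on `s2` costs half of the relationship
and statement credit — exactly the partial-credit behaviour the cascade
model is for.

```r
# the published training-corpus term counts yield the published shares
shares_from_counts(published_corpus_counts()$terms[, "train"])
#>    P    A   bp path
#>   87    8    4    1

# annotator pairs at an analytic target kappa (quota-exact)
pair <- gen_annotator_pair(40, target_kappa = 0.8, prevalence = 0.5, seed = 7)
cohen_kappa(pair$a, pair$b)
#> Agreement on 40 items: po = 90.0%, pe = 50.0%, kappa = 0.80
```

A command-line interface wrapping these functions is installed under
`exec/beltools` (subcommands `parse`, `validate`, `simplify`, `evaluate`,
`convert`, `filter`, `stats`, `iaa`, `retrieve`, `synth`); see
`?bel_cli`.

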