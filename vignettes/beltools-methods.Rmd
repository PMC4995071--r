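---
title: "Parsing, canonicalizing and scoring BEL nanopub corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsing, canonicalizing and scoring BEL nanopub corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beltools)
```

## The problem this package addresses

Biological Expression Language (BEL) encodes causal biological findings as
subject--relationship--object triples over entities grounded in controlled
vocabularies ("namespaces"): `p(HGNC:TIMP2) decreases cat(p(HGNC:MMP2))`
says that the human TIMP2 protein decreases the catalytic activity of MMP2.
A *nanopub* pairs such a statement with its citation (a PubMed ID) and the
text excerpt supporting it. Corpora of nanopubs — most prominently the
BioCreative V BEL track corpora — are used to train and evaluate systems
that extract BEL statements from the literature.

Working with these corpora requires a stack of small, exacting pieces:
a parser and validator for the BEL 1.0 subset used in the corpora; a
canonicalizer implementing the track's equivalence rules, so that
statements the evaluation treats as equal actually compare equal; a
cascade scorer that grants partial credit at term, function and
relationship levels; readers and writers for the tab-separated corpus
formats; the corpus-selection filter pipeline and its statistics;
inter-annotator agreement measures; and a simple trigger-word
tri-occurrence retrieval method for proposing candidate evidence
sentences. `beltools` implements all of these, plus a synthetic corpus
generator that serves as the controlled test bed for everything else.

## The grammar and its validation

The parser is a hand-written recursive-descent parser over a tokenizer
that normalizes Unicode curly quotes and non-breaking spaces (corpus files
in the wild contain both), accepts `'` and `"` interchangeably as quote
characters, and ignores whitespace between tokens. Short and long function
spellings (`p()` vs `proteinAbundance()`) parse to identical abstract
syntax; the symbolic relationship forms `->`, `=>`, `-|`, `=|` normalize
to their long forms. Rendering is deterministic — short codes, `", "`
separators, double-quote quoting exactly when a name contains a character
outside `[A-Za-z0-9_]` — and `parse(render(x))` is the identity on valid
ASTs, a property tested over more than 10^4 generated statements.

Validation is separate from parsing and returns violations as data rather
than errors, so corpus batches can be screened in one pass. Checked
invariants include function arity (e.g. `composite()` needs two or more
abundance members, activity functions wrap exactly one abundance or
complex), modification arguments (`pmod` position requires a residue,
`sub` needs reference/position/alternate), and namespace--function
compatibility: CHEBI entities only under `a()`, MESHD only under
`path()`, GOBP only under `bp()`, gene namespaces only under
`g()/r()/m()/p()`. MicroRNA symbols are flagged under `p()` using the
conventional `MIR`/`Mir` + digit symbol prefix — a documented heuristic,
since the package deliberately does not resolve names against namespace
dictionaries.

Two decisions were genuinely open. Statement nesting depth is nowhere
formally bounded; because the annotation guidance discourages nested
statements and only ever shows one level, objects may be statements but
deeper nesting is a validation error rather than a guess at semantics.
Second, `composite()` is allowed only at term top level; nothing in the
corpora motivates it inside other functions.

## Canonicalization (track equivalence rules)

The BioCreative V BEL track evaluation simplifies statements before
comparison, and `simplify_bel()` reproduces those rules: `directly*`
relationship variants fold into `increases`/`decreases`; all specific
activity functions (`cat`, `kin`, `tscript`, ...) collapse to `act()`;
`pmod()` keeps only its type code; translocation location arguments are
dropped. Each rule is individually switchable in `simplify_config()`.
Three choices go beyond the letter of the rules and are package decisions:

* `sec()`/`surf()` rewrite to the generic `tloc()` under the
  location-stripping rule, on the reading that the track treated
  translocations generically; this is configurable off.
* Ortholog equivalence is materialized as a three-column tab-separated
  map (namespace, name, class label); mapped gene-namespace entities are
  replaced by their class label under a reserved `ORTH` namespace, and
  unmapped entities remain distinct singletons.
* `complex()`/`composite()` members are sorted by canonical rendering
  (after entity mapping), so member order never distinguishes equivalent
  curations; whether the official scorer sorted members is not documented,
  but without sorting, equal curations could fail to compare equal.

Simplification is idempotent and never changes entity counts or
subject/object structure — both property-tested.

## Cascade scoring

`score_bel()` compares predicted against gold statements per sentence at
six levels. Units are matched *as sets* within each sentence, and tp/fp/fn
are summed over sentences (micro-averaging, the standard BioCreative
practice; whether the official scorer micro- or macro-averaged is recorded
as an assumption, not a fact):

* **term** — rendered namespace entities anywhere in the statement;
* **function** — (function code, contained entity set) pairs for
  non-abundance functions and modification carriers;
* **function-secondary** — bare function codes;
* **relationship** — (subject entity set, relationship, object entity
  set); a nested object statement contributes its inner relationship as an
  additional unit;
* **relationship-secondary** — the relationship with the unordered pair of
  side entity sets;
* **statement** — the full canonical rendering.

The two *secondary* levels appear in published agreement tables without a
definition; they are defined here as the argument-free variants above and
flagged as such. Precision is 1 when nothing is predicted, recall 1 when
there is no gold, and F is 0 when both are 0 — conventions that make empty
sentences behave sensibly. Because units are sets, duplicated predictions
neither help nor hurt. The scorer is checked against an independent
brute-force matcher (maximum bipartite matching over unit equality) on
small sets, and against manifest-derived expected counts on perturbed
synthetic corpora (below).

## Corpus formats and the filter pipeline

The 5-column `.tab` format (bel_id, statement, sentence_id, sentence,
pmid) round-trips byte-identically; embedded tabs/newlines in evidence
text are escaped as `\t`/`\n` (the format description is silent on this),
a header row is always written and auto-detected on read. The published
format notes give the `.BEL` file only two columns (bel_id, statement),
which would leave the join to `.sentence` files undefined; since the
formats must join losslessly and dangling-reference checking is expected
behaviour, the `.BEL` writer here carries the `sentence_id` reference as a
third column, which is documented as this package's convention. The
sentence-classification format enforces the label implication *fully
supportive ⇒ partially supportive* and warns on excerpts that exceed the
two-sentence limit per a naive splitter (terminal punctuation + space +
capital), documented as a heuristic.

The selection filter reproduces the base-corpus pipeline: deduplication of
identical (statement, sentence, pmid) records first, then per-record
rules — PubMed ID present; evidence length 36--425 characters (bounds read
as inclusive; measured on the whitespace-trimmed text in Unicode code
points); at most 4 nanopubs per shared evidence text ("fewer than five");
only the four causal relationship types; only HGNC/MGI/EGID/MESHD/
CHEBI/GOBP entities in subject/object terms; at most 4 named entities;
no `composite()`/`rxn()`. Translocation location arguments (GOCC/MESHCL)
are exempt from both the namespace whitelist and the entity cap, because
published sample statements retain them while the filter criteria name
only subject or object term namespaces. Rejected records carry every rule
they violate; the filter is idempotent and order-independent (tested on
1000 records).

`corpus_stats()` tallies term types per entity occurrence by enclosing
function (P/A/bp/path; entities under `g()/r()/m()` and named complexes
are tallied separately and excluded from the four-way share), function
types (`act` = all activity functions; `tloc` includes `sec`/`surf`),
and relationships with `directly*` folded in. Shares are rounded half-up
to whole percent — with the published training-corpus counts this yields
the published 87% protein / 69% activity / 73% increases shares, which the
test suite and acceptance script recompute.

## Inter-annotator agreement

For label corpora, `cohen_kappa()` implements kappa = (po − pe)/(1 − pe)
with pe the product-of-marginals chance agreement; the degenerate case
pe = 1 reports kappa 1 when po = 1 and errors otherwise. Binary labels
only: the fully- and partially-supportive tiers are analysed as two
separate binary comparisons. Items present for only one annotator of a
pair are excluded with a warning, not counted as disagreement — the
published protocol does not address missingness. For statement corpora,
`score_iaa()` treats the first annotator as gold and the second as
prediction, exactly as the track's agreement protocol did; swapping
annotators swaps precision and recall and leaves F unchanged. The
published pairwise agreement values themselves cannot be reproduced
because the underlying annotation pairs are unpublished; the package
instead verifies the machinery by parameter recovery (below). The
published protocol description also disagrees with itself about whether
30 or 40 items were used in the label-agreement round; the package takes
no position and works with any n.

## Tri-occurrence retrieval

`find_excerpts()` reproduces the simple semantic tri-occurrence method:
an excerpt qualifies if it contains a synonym of a subject-side entity, a
synonym of an object-side entity, and a trigger word of the statement's
simplified polarity. The original used an NER-backed search engine, which
is out of scope; matching here is token-level and case-insensitive —
exact (word-bounded) for entity synonyms, stem-prefix for triggers — and
the trigger lexicon ships as editable data. Windows are one or two
consecutive sentences within a document; a two-sentence window is proposed
only when neither sentence qualifies alone, so results never duplicate.
Whether the original required the trigger to sit between the entities is
unstated; anywhere-in-window is implemented, and both entity orders are
accepted. Results sort by publication date, newest first (ISO dates;
missing dates last; ties by pmid then window start) and cap at 10 per
statement. Retrieval is fully deterministic.

## The synthetic corpus generator

The generator is first-class, tested code, and its defaults are the study
conditions: marginals shaped after the published training corpus — 1.74
statements per sentence (74% of sentences carry two), term shares
87/8/4/1 (P/A/bp/path), 0.83 function occurrences per statement split
69/15.5/8.2/4.5/2.3/0.4/0.1 percent over act/pmod/complex/tloc/deg/sub/
trunc, 73% increases — with evidence text that embeds the entity surface
forms and a polarity trigger inside the 36--425 character bounds, so
generated corpora pass the default filter and can feed the retrieval
module. Category counts are met *exactly* by largest-remainder quota
apportionment plus seeded shuffling, not i.i.d. draws, so marginal
assertions in tests are exact rather than flaky. Entity names use
reserved synthetic vocabularies (`HGNC:GENE0001`, `MGI:Gene0001`,
`CHEBI:chem0001`, quoted `GOBP:"process 0001"`) that cannot collide with
real symbols. Everything is a deterministic function of the seed.

What the generator does *not* emulate: linguistically realistic sentences,
co-references, real gene symbols and their ambiguity, nested statements,
or curator-style biological interpretation. Passing tests therefore
demonstrate the correctness of the machinery under controlled conditions,
not extraction performance on real literature.

`perturb()` turns a gold corpus into a controlled prediction set:
relationship flips, entity swaps, function drops, pmod-argument edits
(harmless under full simplification), statement drops and spurious
additions, each applied to a disjoint, exactly quota-sized subset of
eligible records. The returned manifest makes expected statement-level
tp/fp/fn an arithmetic consequence (`perturb_expected_counts()`), exact
when statements are unique per sentence — the calibration tests use one
statement per sentence for this reason. `gen_annotator_pair()` draws
paired binary labels from the 2×2 distribution with common marginal p and
cells p² + κpq / pq(1−κ) / pq(1−κ) / q² + κpq, whose analytic kappa is the
target; the quota method reproduces, e.g., kappa 0.80 exactly from the
18/2/2/18 table at n = 40, and the i.i.d. method recovers the target
within Monte-Carlo error.

## Numerical and scale choices

Printed ratios round half-up (base R rounds half-to-even): shares to whole
percent, CLI report ratios to two decimals. Problem sizes in the test
suite are chosen to keep the default run fast while still exercising the
properties at scale: the parser round-trip property runs on ~10,000
generated statements, filter stability on ~1,000 records, kappa recovery
at n = 2,000, and the scorer-vs-oracle comparison on small sets where
brute-force matching is tractable. The acceptance script
(`scripts/acceptance.R`) recomputes the published-share arithmetic and the
calibration quantities on 200-statement corpora in a few seconds.

## Known limitations

* No namespace dictionary resolution: `HGNC:IL6` is accepted whether or
  not the symbol exists; the microRNA check is a symbol-prefix heuristic.
* BEL v2.0 syntax (variants, `regulates`, location modifiers) is out of
  scope by design.
* The secondary cascade levels are this package's definitions of
  under-specified published level names.
* The statement-level expected-count calculus for perturbed corpora
  assumes no unit collisions within a sentence; with multiple statements
  per sentence it is an approximation (and the tests use the exact
  configuration).
* Retrieval is a deliberately simple stand-alone reconstruction of the
  tri-occurrence idea; it does not include NER, ranking models, or live
  literature access.
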