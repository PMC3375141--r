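---
title: "From recursive text-mining events to gene association networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From recursive text-mining events to gene association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioeventnet)
```

## The problem

Event extraction systems turn sentences from biomedical abstracts into
typed, recursively nested predicates over gene and protein mentions: a
sentence such as *"IL-2 acts by enhancing binding activity of NF-κB to
p55"* becomes

```
Positive-Regulation(C:IL-2, T:Binding(T:NF-kB, T:p55))
```

where `T:` marks the Theme (the affected participant) and `C:` the
Cause.  These structures are faithful to the text but awkward for a
biologist who simply wants to know which genes regulate, bind or
co-regulate which others, across millions of abstracts.  `bioeventnet`
implements the post-processing layer between raw event extraction
output and such a gene-centric view: canonicalization and family
generalization of gene symbols, confidence scoring of events from
classifier margins, structural refinement of nested regulation chains,
typed pairwise abstraction, and hypothesis-level indirect associations.

## The event model

Nine event types are supported.  Five "physical" types (gene
expression, transcription, localization, protein catabolism,
phosphorylation) take exactly one Theme, a gene mention.  Binding takes
one or more gene Themes and never a Cause.  The three regulation-class
types (positive, negative, unspecified regulation) take exactly one
Theme and at most one Cause, either of which may recursively be another
event.  `read_standoff()` enforces these constraints;
`validate_event_constraints()` reports violations as data for corpus
screening.  Offsets are 0-based and end-exclusive — the standoff
convention; the annotation files themselves do not say, so the choice
is stated here once and tested everywhere (every mention and trigger
surface must equal its text slice).

## Canonicalization and generalization

Named-entity recognizers often include context around the core symbol
("human Esr-1 subunit").  `canonicalize()` strips affix-lexicon tokens
iteratively from both ends of the whitespace-tokenized surface, then
drops non-alphanumeric characters and lowercases: `"human Esr-1
subunit"` → `"esr1"`.  Three design points deserve justification:

* **Token-based stripping.**  Affixes are matched as whole whitespace
  tokens, not substrings: substring stripping would mutilate symbols
  that merely contain an affix ("genea" losing "gene").  Hyphenated
  affixes are therefore not stripped; they disappear anyway in the
  non-alphanumeric cleanup when they are attached to the core token.
* **Greek letters are dropped, not transliterated** (`"NF-κB"` →
  `"nfb"`).  The cleanup rule is "discard non-alphanumerics"; a
  transliteration table (κ → k) would be an additional modelling
  decision with its own ambiguities, so it is left configurable rather
  than default.
* **Never empty.**  If stripping consumes every token, the result falls
  back to the alphanumeric core of the original surface; surfaces with
  no alphanumeric characters at all are flagged uncanonicalizable and
  excluded from generalization.  This keeps the operation total and
  idempotent, which the tests check by property.

The default affix lexicon seeds species adjectives and structural words
("human", "murine", "protein", "gene", "subunit", "promoter", ...); it
is a configuration input (`affix_lexicon()`, YAML-loadable), since no
authoritative list exists.

Family schemes (`family_scheme()`) map canonical symbols many-to-one
onto family identifiers, in the manner of homology resources.  When a
symbol is claimed by several families, the scheme resolves the tie at
construction time in favour of the family with the most member symbols
(ties by lexicographic id): a deterministic stand-in for a
likelihood-based disambiguator, which is an input to this package, not
part of it.  `generalization_key()` returns the family id, falling back
to the canonical symbol as its own singleton key when unmapped — so
generalized events always partition the occurrence set.

## Confidence scores

Event extraction uses two separate linear SVM classifiers — one for
triggers, one for arguments — whose margins are not mutually
comparable.  `fit_normalization()` z-normalizes all margins corpus-wide,
separately per kind.  The **population** standard deviation
(divide-by-n) is used: the corpus is the entire population of scores
being ranked, and the choice makes small-fixture tests exactly
reproducible.  An occurrence's score is the **minimum** of its
normalized components (a fuzzy AND — every decision involved must be
confident); a generalized event's score is the **mean** over its scored
occurrences.  Events missing any component are unscored and rank last;
refined structures inherit the score of their original occurrence,
since scores belong to extractions, not rewrites.

Scores are mapped to five categories, `very_low` … `very_high`.  Two
readings of "20%" are defensible: 20% of the confidence *range*
(equal-width bins) or 20% of the *events* (quantile bins).  Both are
implemented (`confidence_bins(mode = "range")` is the default,
`"quantile"` behind the flag); the range reading is primary because it
keeps category boundaries interpretable as fixed score thresholds,
independent of the score distribution.  A degenerate single-valued
score set yields the single category `average` — there is no range to
split.  The top bin is closed so the maximum score is `very_high`.

## Refinement of nested regulation chains

Extraction follows sentence wording, so *"Ang II induces a rapid
increase in MAPK activity"* yields
`Pos(C:AngII, T:Pos(T:MAPK))` — a regulation whose Theme is another
regulation with no Cause.  The rewrite system splices out such
Cause-less single-argument regulatory events and composes polarities:

| outer \\ nested | Pos | Reg | Neg |
|---|---|---|---|
| **Pos** | Pos | Pos | Neg |
| **Reg** | Pos | Reg | Neg |
| **Neg** | Neg | Neg | Pos |

Four of the nine compositions change the outer event's type.  Each such
change is an inference beyond the literal sentence, so only **one
polarity change per structure** is allowed; any later type-changing
application forces unspecified regulation.  Rewriting proceeds
outermost-first with re-scan from the root.  The order matters only
through its interaction with the change budget, and no ordering is
canonical; outermost-first is frozen here (and mirrored by the
brute-force oracle in the tests) because it consumes the budget on the
inference closest to the asserted root statement.  The budget is
per-structure, not per-chain: a structure with chains under both Cause
and Theme still licenses only one polarity flip in total, keeping the
total inference bounded per textual statement.  Nested regulations that
carry a Cause are never removed — they name a regulator, which the
pairwise stage needs.  Originals are preserved on the `refined_event`
(with trigger provenance of removed events); refinement is an
aggregation layer, not a replacement.

## Pairwise abstraction

`extract_pairs()` turns one refined structure into typed gene-pair
seeds.  Every unordered pair of distinct genes is classified at its
lowest common ancestor (LCA) event:

1. both direct Themes of one binding event → `binding` (undirected);
2. otherwise the Cause-side gene regulates the Theme-side gene
   (`regulation`, directed);
3. a gene reached through a Theme role inside the **Cause** argument is
   only an **indirect** regulator (`indirect_regulation`) — the direct
   regulator is someone else in that subtree;
4. a gene that acts as a Cause inside the **Theme** argument makes the
   Cause–Cause candidate unclassifiable as a regulation: the pair is
   discarded as a direct association and kept as a
   `coregulation_capture` seed toward the inner event's Theme.

Genuinely open corners were resolved as follows.  A Cause-of-Cause gene
(reached through Cause roles only) stays a plain regulator.  Pairs
whose two genes sit in the same argument subtree are classified at
their own, deeper LCA — the outer event says nothing about their mutual
relation.  Binding Themes nested under a regulation pair both with each
other (binding) and with the regulation's Cause (regulation): both
statements are licensed by the structure.  Self-pairs (same key under
the active scheme) are never emitted.  Mixed-class duplicates — the
same ordered keys supported as both regulation and indirect regulation,
say — are kept as separate rows, because the classes answer different
questions.

`aggregate_pairs()` merges seeds across documents on (keys, class,
direction) under a chosen generalization scheme, pools evidence,
averages scores, and assigns confidence categories from the
corpus-wide range of aggregate scores.  `threshold_sweep()` screens a
confidence cut-off over the score range in steps of 0.05 by default,
trading recall for precision.

## Indirect associations

`derive_indirect()` joins the aggregated pair table through shared
partners: co-regulation (A→Z ← B), common regulator (A ← Z → B), and
common binding partner (A–Z–B).  Direction semantics: regulation *and*
indirect-regulation edges feed both regulatory joins (both assert
regulation, one of them indirectly); `coregulation_capture` seeds feed
only the co-regulation join, which is exactly the claim they preserve.
A partner supported by several edge classes is counted once.  No
confidence floor is applied to the supporting edges by default — none
is canonical — but `min_score` filtering upstream provides one when
wanted.  Every association record carries a fixed `hypothetical` flag:
these are literature-derived hypotheses (true co-regulation would
additionally require, e.g., coexpression evidence), and downstream
users should see that caveat in the data itself, not only in prose.
`rank_associations()` orders by number of shared partners, then best
supporting edge score, then keys — fully deterministic.

## The synthetic corpus generator

`generate_corpus()` produces standoff corpora with planted ground
truth.  It emulates the statistical shape of large-scale event data:

* structures drawn from a mixture over the nine prevalent coarse
  patterns, with default weights 58.6, 15.0, 8.4, 8.0, 4.7, 3.8, 0.2,
  0.2, 0.2 percent (renormalized) — the observed occurrence shares of
  those patterns;
* a frequency-skewed gene pool (roughly Zipfian) in which the frequent
  symbols are family-mapped and the long tail is not, so
  family-coverage statistics behave qualitatively like real corpora
  (few distinct symbols, many occurrences covered);
* surface decorations (affixes, case and hyphen variants) that the
  canonicalizer must undo;
* optional Cause-less regulation chains spliced above regulation roots
  (`chain_prob`, default 0.25) as raw material for the refinement
  rewrite;
* Gaussian raw margins per trigger and argument.

Sentence text is a deterministic token template — offset correctness,
not linguistic realism, is the goal.  Ground truth (canonical symbols,
refined structures, pairs, associations) is computed by an
intentionally naive, separate implementation of the pairwise walk
(`naive_pair_walk()`), never by the main extractor.  What passing tests
on generated corpora show is therefore that the pipeline's stages
compose correctly and agree with an independent reading of the
classification rules; what they cannot show is robustness to real
extraction noise — misrecognized entities, wrong event types,
negation and speculation — which the generator deliberately does not
model.

## Numerical and determinism choices

All exports are written with fixed numeric formatting so identical
inputs give byte-identical files.  Sorting everywhere uses explicit,
total tie-breaks (counts desc, scores desc, then lexicographic keys).
A fixed generator seed reproduces corpora byte-for-byte.  Degenerate
inputs are handled explicitly: all-identical margins are a
degenerate-corpus error (no unit-variance transform exists); an empty
corpus yields empty tables, not errors; uncanonicalizable mentions are
excluded from pairing rather than silently keyed.

The test suite exercises the checks at these problem sizes, chosen to
make the properties sharp while keeping the suite quick: exhaustive
pair-extraction equivalence on all valid structures of depth ≤ 3 with
≤ 4 genes (~47 000 structures); refinement properties on 10 000 random
trees; full pipeline closure against planted ground truth on a
1 000-document corpus, run twice to confirm byte-identical exports.

## Limitations

The package consumes event-extraction output; it does not extract
events, recognize entities, or disambiguate synonyms — family mapping
tables are inputs.  Confidence margins are treated as ordinal only; no
probability calibration is attempted.  Shared-task extensions (sites,
coreference, non-causal relations) are out of scope.  Indirect
associations are hypotheses by construction and are flagged as such.
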