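---
title: "Multi-criteria ontology recommendation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-criteria ontology recommendation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontorec)
```

## The problem

A researcher who needs to annotate biomedical text — a corpus of free
prose, or a list of keywords — faces hundreds of candidate ontologies.
Which single ontology, or which small set of ontologies, best covers the
terms in *their* data? `ontorec` answers this by running a dictionary-based
concept recognizer over the input and scoring every candidate ontology on
four criteria, each in $[0,1]$:

* **coverage** — how much of the input's annotatable content the ontology
  captures;
* **acceptance** — how trusted the ontology is by the community, proxied by
  repository presence and recent page visits;
* **detail** — how richly the matched classes are described (definitions,
  synonyms, other properties);
* **specialization** — how tailored the ontology is to the input's domain,
  rewarding deep matches and penalizing sheer size.

The criteria are combined linearly,

$$\mathrm{score}(o,t) = w_c\,\mathrm{coverage}(o,t) + w_a\,\mathrm{acceptance}(o)
 + w_d\,\mathrm{detail}(o,t) + w_s\,\mathrm{specialization}(o,t),$$

with $w_c + w_a + w_d + w_s = 1$. The defaults (0.55, 0.15, 0.15, 0.15)
encode that coverage is the dominant requirement; all weights are
user-tunable through `recommender_config()`. Scores are computed in
$[0,1]$ and displayed in $[0,100]$ with one decimal (halves round up —
`round_half_up()` exists because base R's banker's rounding would print
0.125 as 0.12).

## The annotator

Ontologies are dictionaries of surface forms: every class contributes its
preferred name (PREF) and each of its synonyms (SYN). Matching is exact on
normalized token sequences: a token is a maximal run of letters or digits
(hyphens separate), case-folded; no stemming or lemmatization is applied.
All matches are returned — nested spans, overlapping spans, and multiple
classes on the same span — because the specialization criterion consumes
the full annotation set. Two bookkeeping rules keep the output canonical:
when one class matches the same span via both its preferred name and a
synonym only the PREF annotation is emitted, and the result is sorted by
(start, end, ontology, class, type) so identical inputs always produce
identical annotation tables.

For keyword input (comma-delimited), partial annotations are discarded:
an annotation survives only if its span covers all the words of exactly
one keyword. Keywords with internal commas are unsupported by
construction.

### Annotation scoring and overlap resolution

Each annotation $a$ scores

$$\mathrm{annotationScore}(a) = (\mathrm{typeScore}(a) + \mathrm{multiWordScore}(a))
  \times \mathrm{annotatedWords}(a),$$

with typeScore 10 for PREF and 5 for SYN, and a multi-word bonus of 3 when
the annotation covers more than one word. A two-word preferred-name match
is thus worth $(10+3)\times 2 = 26$ — deliberately more than matching the
two words separately ($10 + 10$ loses to $26$ only through overlap
resolution, which is the point: the multi-word match suppresses both
one-word matches it overlaps).

When an ontology produces several annotations for intersecting fragments,
only the best contributes to coverage: annotations are swept in order of
descending score and kept when they do not intersect any kept span.
Ties break deterministically — PREF before SYN, longer span, smaller
start, class id, ontology acronym. This greedy per-fragment rule is the
documented behavior (it is not a claim of globally optimal weighted
interval scheduling); it reproduces every worked example and guarantees
that each discarded annotation overlaps a kept annotation of at least its
own score.

### Coverage

$$\mathrm{coverage}(o,t) = \frac{\sum_{a \in \mathrm{selected}(A_o)} \mathrm{annotationScore}(a)}
  {\text{max coverage points}},$$

where the normalizer is obtained by pooling *all* candidates' annotations,
resolving overlaps on the pooled list, and summing — the best any
combination of candidates could achieve, so every candidate lands in
$[0,1]$ and at least one ontology set can reach 1. Term frequency is
respected: a term matched at three occurrences contributes three times.
Candidates with no annotations at all are dropped before scoring rather
than carried with zeros.

## Acceptance

$$\mathrm{acceptance}(o) = w_{presence} \sum_i w_{p_i}\,\mathrm{presence}_i(o)
 + w_{visits} \sum_i w_{v_i}\,\frac{\mathrm{visits}_i(o)}{\max_{o'} \mathrm{visits}_i(o')}.$$

Presence flags are 0/1 per repository; visit counts are normalized per
repository against the maximum over the current candidate pool (a
repository with no visits anywhere contributes 0 rather than dividing by
zero). The per-repository weights and the presence/visits split (default
0.5/0.5) live in the metadata table and configuration respectively. The
metadata file format carries one number of visits per repository; whether
that number is a recency-windowed or cumulative count is the data
provider's choice — the score is agnostic.

## Detail

Each selected annotation earns

$$\mathrm{detailScore}(a) = \tfrac13\left(\min\!\big(\tfrac{|D|}{k_d},1\big)
 + \min\!\big(\tfrac{|S|}{k_s},1\big) + \min\!\big(\tfrac{|P|}{k_p},1\big)\right),$$

with $|D|, |S|, |P|$ the matched class's definition, synonym and
other-property counts and saturation constants $k_d = 1$, $k_s = 4$,
$k_p = 10$: one definition, four synonyms and ten properties are "fully
detailed". The ontology's detail is the **mean over selected annotations**.
The denominator is a genuine design choice — averaging over all
annotations instead would let a cloud of shallow duplicate matches dilute
the score of the classes actually used for coverage, so the selected set
is the right population.

For OBO input, "other properties" are approximated as all stanza
tag–value lines other than id, name, def, synonym, is_a and is_obsolete.
This is a pragmatic stand-in for a property count no flat format defines
precisely; the dictionary dialect carries the count explicitly for data
sources that know better.

## Specialization

$$\mathrm{specialization}(o,t) = \mathrm{norm}\!\left(
  \frac{\sum_{a \in A_o} \big(\mathrm{annotationScore}(a) + 2\,\mathrm{depth}(a)\big)}
       {\log_{10}|o|}\right),$$

over **all** annotations $A_o$, not the selected subset: an ontology that
matches a fragment with several classes is more specialized for that
fragment than one that matches it once. Depth is 1-based (root = 1) and is
computed as the shortest parent-path to any root — with multiple parents
the most conservative granularity claim, and order-independent. $|o|$ is
the *declared* size, which may exceed the number of classes loaded when
the dictionary at hand is a partial extract of a large ontology; sizes
below 2 are rejected ($\log_{10}$ would vanish). `norm` divides by the
largest raw value in the candidate pool, so exactly one candidate scores
1 barring ties. Normalizing by the pool maximum (rather than, say, a fixed
constant) makes the score a *relative* statement about the current run,
which is also true of coverage and the visits factor — acceptance apart,
scores are not comparable across runs with different candidate pools.

## Ontology sets

When no single ontology covers the input, sets of 2 up to `max_set_size`
(default 3) candidates are enumerated. A set's coverage pools the members'
annotations and re-runs overlap resolution, so it never falls below the
best member's coverage. Each selected annotation is attributed to the
member that supplied it (the selection tie-break settles joint claims, so
nothing is double-counted), giving per-member *coverage contributions*
that sum to 1. The other three criteria are the members' single-ontology
scores averaged with these contributions — a member matters in proportion
to what it actually adds to the set's coverage.

Two pruning rules discard sets before full evaluation:

1. two members cover exactly the same selected fragments with the same
   annotation scores, or
2. the pooled selection scores no more points than some proper subset.

Rule 1 is a fast path subsumed by rule 2: because the fragment identity
includes the score, dropping one of two "twins" provably leaves the pooled
points unchanged. (Identity on spans alone would occasionally discard a
set that genuinely gains — two members covering the same spans with
PREF/SYN roles swapped across fragments — so the score is part of the
identity.) Pruned sets are sound by construction: every pruned set's
pooled points equal those of some proper subset, a property the test
suite verifies by brute force on small pools.

## The legacy scorer

`score_v1()` implements the predecessor formula,
$\sum_a (\mathrm{annotationScore}(a) + 2\,\mathrm{hierarchyLevel}(a)) / \log_{10}|o|$
with type scores 10/8, no multi-word bonus, and no overlap resolution. It
exists for comparison: because every annotation contributes, an ontology
with many duplicate classes over few terms can outrank one that covers
many terms once — the failure mode the four-criterion method was designed
to fix, and the package's tests reproduce the divergence on a constructed
pool. Hierarchy-level conventions differ between the two scorers: the
current method always counts the root as level 1, while `score_v1()`
defaults to root = 0 (`depth_base_v1 = 0`) with the 1-based convention
available as a flag, since both conventions exist in the wild.

## The synthetic repository generator

`generate_synthetic_repository()` emulates the study conditions the
package is meant for: several ontologies sharing a controlled fraction of
a common vocabulary (`shared_fraction`), a mix of single- and multi-word
terms (`multiword_fraction`), synonym lists that occasionally alias other
vocabulary terms (so SYN/PREF competition occurs), parent chains bounded
by `depth_max`, repository metadata with random presence flags and visit
counts, and documents interleaving vocabulary terms with filler words.
Defaults — 5 ontologies, 120 terms of vocabulary, 30 classes each, 30%
multi-word terms, 50% shared core, depth up to 8, 60-slot documents —
give pools where single-ontology coverage is partial and 2–3-ontology
sets genuinely help, which is the regime the method targets. Everything
is driven by one seed and regenerates byte-identically.

What it does **not** emulate: real label morphology (inflection,
abbreviations, punctuation-heavy chemical names), skewed pageview
distributions, obsolete-term churn, and cross-ontology class reuse.
Passing tests on synthetic pools therefore demonstrate the algorithmic
contracts — not that the default weights are optimal for any particular
real corpus.

## Numerical choices and degenerate inputs

* Weight sums are validated to $10^{-9}$; contribution sums likewise.
* Set-pruning point comparisons use an absolute $10^{-12}$ slack; scores
  are small integers divided by logarithms, so this is far below one
  point.
* An input that no candidate annotates yields an empty ranking with an
  explanatory status, not an error; a lone candidate self-normalizes to
  coverage 1.
* Ontologies must contain at least one class; parent links must resolve
  within the ontology and be acyclic (a witness cycle is reported);
  duplicate synonyms collapse case-insensitively.
* Display rounding is half-up to one decimal; internal computation keeps
  full precision, and reports serialize unrounded criterion scores so
  relevance recombines exactly.

## Problem sizes in the test suite

The property tests run the brute-force annotator oracle on documents of
up to ~20 tokens against pools of 4–5 ontologies (a dozen seeds), verify
selection invariants on random instances of up to 12 annotations, and
check pruning soundness exhaustively on pools of up to 5 ontologies —
sizes at which exhaustive enumeration is exact yet the whole suite runs
in well under a minute.

## Limitations

* Matching is exact after normalization: no lemmatization, fuzzy matching
  or abbreviation expansion, so morphological variants go unmatched.
* The OBO property count is a flat-file approximation, not an OWL-aware
  property census.
* Set search is enumerative over sizes 2–3 by default; it is not a
  set-cover optimizer, and larger sets grow combinatorially.
* Acceptance depends entirely on the metadata table supplied; ontologies
  missing from it score 0 by definition, and runs without metadata score
  acceptance 0 for every candidate.
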