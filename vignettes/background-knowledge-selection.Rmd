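---
title: "Selecting background knowledge for ontology matching by mapping gain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting background knowledge for ontology matching by mapping gain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontobk)
```

## The matching model

`ontobk` treats an ontology purely as a *lexicon*: a set of class IRIs,
each carrying weighted normalized names. Everything else — axioms,
hierarchy, properties, individuals — is deliberately ignored, because
the selection methodology the package implements only requires a
matcher that is precise and linear-time, and full-name lexical matching
is both, as well as being the standard first step of essentially every
ontology matching pipeline.

Names are normalized (NFKC, lower case, punctuation to spaces,
whitespace collapsed) and weighted by provenance: primary label 1.00,
exact synonym 0.95, related/broad/narrow synonyms 0.85. These weights
are a declared convention, not an empirical fit; what matters is their
ordering (labels are the most trustworthy source of a class's name),
and they are configurable through `load_ontology(weights = )`. Two
classes match directly when they share a normalized name, with
similarity equal to the largest product of the two name weights, so a
label–label match scores 1.0 and synonym-backed matches score less.
Matching is a hash join on the name index — never an all-pairs scan —
which keeps it linear in the total number of name entries.

Indirect matching maps both input ontologies to a background lexicon
and emits a mapping (s, t) whenever both classes hit the same
background class. Because the matcher derives only equivalences,
transitivity across the bridge is sound. The two bridge similarities
are combined by minimum — the conservative choice, keeping mediated
similarities in (0, 1] and never above either leg; a product combiner
is available (`combine = "product"`) for users who prefer multiplied
evidence. When several background classes bridge the same pair, the
best resulting similarity is kept: one good bridge suffices for an
equivalence claim.

## Ranking metrics

For a mediated alignment $A$ and the direct baseline $B$ over the same
ontology pair:

* **Mapping gain** $MG(A,B) = |\{m \in A : m \notin B\}| / |B|$ —
  novel mappings per baseline mapping. Asymmetric on purpose: it
  measures what the background source adds on top of direct matching.
* **1-to-1 mapping gain** $MG'$ counts a mapping only when both its
  classes are unmapped in $B$. When the true alignment is (near)
  1-to-1 — the usual case in anatomy and large-biomedical matching
  tasks — a mapping that re-maps an already-mapped class cannot be
  correct, and counting it would overestimate the source. $MG' \le MG$
  always. The exact printed form of this variant is not recoverable
  from our source material; the implementation follows its stated
  semantics (both endpoints previously unmapped, normalized by $|B|$),
  and the general variant is always available.
* **Similarity score** $a \cdot \min(J(S,X), J(T,X)) + b \cdot
  \max(J(S,X), J(T,X))$ with defaults $a = 1 \ge b = 0.9$, where $J$ is
  the Jaccard index with the intersection estimated by the lexical
  matcher. Weighting the *weaker* overlap more enforces that a useful
  source must resemble both inputs; the exact combination is likewise a
  declared reading of the stated intent, with the descending-weights
  alternative selectable in code.
* **Effectiveness** $|A| / ((|C_S|+|C_T|)/2)$ — mediated alignment size
  over mean input size. Unlike the gain it does not discount what
  direct matching already finds, which is exactly why it mis-ranks
  sources whose knowledge is redundant with the inputs.

## The two-stage selection algorithm

Choosing the smallest source subset maximizing mapped classes is
set-cover, so the package uses the greedy two-stage heuristic: rank all
candidates by individual gain against $B$, discarding those strictly
below the threshold $k$; then sweep the ranking with an accumulating
alignment $B'$, re-evaluating each survivor against the current $B'$
and keeping it only if its residual gain is still $\ge k$. The strict
"below $k$ removes" test is applied verbatim at both stages with a
single threshold, and a gain of exactly $k$ survives. Ties in gain are
broken toward larger mediated alignments, then lexicographic source id,
making results reproducible across platforms. Stage-1 mediated
alignments are cached and reused in stage 2, since only the gains need
recomputation.

Defaults: $k = 0.02$. Two percent is a robust general-purpose threshold
for a high-precision matcher; 0.003 is the aggressive end of the useful
range, below which noisy sources start to cost more F-measure than
their marginal novel mappings earn. Candidates are prefiltered at
similarity score $\ge 10^{-4}$ (0.01%) and sources identical to either
input ontology are excluded outright. `optimal_source_subset()`
provides the exponential exhaustive search as a diagnostic yardstick
for the greedy path.

## Evaluation

Alignments are evaluated OAEI-style on (source, target) keys only:
precision, recall and F-measure against a reference alignment, after
optional greedy 1-to-1 extraction (`ranked_select_1to1()`, similarity
descending, ties by IRI order — a declared convention). Reference cells
with relation "?" are ignored on read.

Under constant matcher precision the relation between $MG'$ and
F-measure is monotonic and, over F ranges up to about 30 percentage
points, very nearly linear — this is what makes the gain a usable
selection criterion without a reference alignment. The package tests
this claim on gradient problems (below): with precision exactly
constant the per-task linear fit of F on $MG'$ attains $R^2 > 0.999$;
with a fixed positive noise rate precision is only approximately
constant across sources and the fit degrades slightly (measured
$R^2 \approx 0.988$ at noise 0.05) while the correlation stays above
0.99 — the same qualitative deviation that heterogeneous-precision
sources cause on real whole-ontology tasks.

## What the synthetic generator emulates

`generate_problem()` builds a pair of ontologies over `n_shared`
concepts (each concept = one class in S, one in T, one reference
mapping; the reference is strictly 1-to-1). A `direct_fraction` of the
concepts have identical labels in S and T — the part direct matching
can recover; the rest have disjoint names. Each synthetic background
source holds, for a controlled subset of those remaining concepts, one
class carrying both the S-name and the T-name as exact synonyms, so it
bridges exactly that subset. `noise_rate` gives each bridge class a
probability of also carrying the T-name of an unrelated (non-direct)
concept, producing a bookkept false mediated mapping — the synthetic
analogue of lexical ambiguity. Labels are seeded pseudo-words (1–3
tokens from a shared token pool, so distinct names share tokens and the
hash join is genuinely exercised); no natural-language word lists are
used, keeping generation deterministic: a fixed seed reproduces
byte-identical OBO output.

The bookkeeping makes expectations exact rather than statistical: with
zero noise, source $i$'s measured $MG'$ equals `round(g_i · |B|) / |B|`
by construction, every mediated mapping is correct, and recall
arithmetic reduces to counting (`recall gain = novel-correct / |ref|`).
`generate_usefulness_gradient()` uses this to build source sets with
prescribed gains for the correlation experiments, and
`disjoint_bridges` assigns non-overlapping bridge sets — the regime in
which the greedy selection is provably optimal and is checked against
exhaustive search.

What the generator does *not* emulate: the scale and lexical richness
of real anatomies and thesauri (hundreds of thousands of classes,
systematic naming conventions, partial-string overlaps), reference
incompleteness, and non-1-to-1 reference cardinality (the divergence
between the two gain variants is exercised with hand-built many-to-many
alignments in the test suite instead). Passing tests therefore demonstrate correctness of the
metrics, matchers and selection logic under controlled conditions — not
performance claims about any particular real corpus.

## Numerical and design choices

* Degenerate inputs are errors, not silent NAs: gain with an empty
  baseline, correlation with zero variance or fewer than 3 points,
  evaluation against an empty reference, matching an ontology to
  itself.
* Duplicate (class, name) entries keep the maximum weight; duplicate
  (source, target) mappings keep the maximum similarity.
* Obsolete/deprecated classes are dropped at parse time so their
  deprecated synonymy cannot seed the name index; OBO prefixed ids are
  canonicalized to OBO-library PURLs so a concept serialized in OWL and
  in OBO compares equal.
* All internal values are fractions; command-line reports print
  percentages.
* Problem sizes in the test and acceptance workloads (lexicons up to 50
  classes against brute-force oracles, 40–200 shared concepts for
  selection and correlation experiments, 25–50 random instances per
  property) were chosen as the smallest sizes at which every integer
  expectation in the construction bookkeeping is non-trivially
  exercised.

## Known limitations

Purely lexical: no structural, string-distance or semantic matcher, so
concept pairs sharing no name through any source are unreachable by
design. No OWL reasoning or imports-closure resolution; RDF/XML and OBO
flat files only. Property and individual matching are out of scope, as
is deriving non-equivalence (subsumption) mappings across bridges. The
mapping-gain threshold trades recall against noise and cannot be
validated a priori without a reference; 0.02 is a safe default for
high-precision matchers, and settings with less precise matchers should
raise it.
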