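---
title: "Evidence-based confidence scores for integrated protein interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-based confidence scores for integrated protein interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippie)
```

## The problem

Human protein–protein interactions (PPIs) are measured by assays with very
different reliabilities — a crystal structure pins down a direct contact,
a yeast two-hybrid call reports a binary interaction in a heterologous
system, an affinity-capture/mass-spectrometry experiment reports
co-membership in a complex — and the measurements are scattered across
curated databases and primary publications that overlap only partially.
Systematic analyses need a single non-redundant network in which every
interaction carries a continuous confidence value, so that a user can slide
a threshold between "everything we know" and "only well-supported pairs".

This package builds that network: it merges source datasets into canonical,
unordered protein pairs with a unioned evidence ledger, scores each pair
from its evidence, selects the score's free parameters by an internal
reproducibility criterion, and provides the standard downstream operations
(stratified-recall evaluation against an external screen, and
confidence-thresholded subnetwork extraction).

## The scoring model

Each interaction's evidence is reduced to three quantities:

* $n_s$ — the number of distinct studies (PubMed IDs) reporting the
  interaction, regardless of how many experiments each study ran;
* $n_o$ — the number of non-human model organisms in which orthologs of
  the pair were observed to interact (nine species are accepted by
  default, from *Bos taurus* to *Sus scrofa*; the list is extensible);
* $n_t$ — the *technique mass*: the sum of curated reliability scores of
  the distinct techniques that verified the interaction (even if several
  were used within one study). A technique reused across studies counts
  once — the study count already rewards the repetition.

Each quantity enters through a saturating transform

$$s(n) = 1 - e^{-a n},$$

which satisfies $s(0) = 0$ and $s(\infty) = 1$ with steepness $a$: the
first unit of evidence moves the subscore most, further corroboration has
diminishing returns, and no finite amount of evidence yields certainty.
The closed form is one design choice of this package — any transform that
meets the boundary conditions would do, and the implementation keeps it as
a single internal function so alternatives (e.g. $n/(n+a)$) can be swapped
— but this choice reproduces the published score landscape: under the
published parameters a single-study interaction supported by one
average-reliability technique (score 5) evaluates to $S \approx 0.7295$,
immediately below the canonical high-confidence boundary of 0.73, and any
second study clears it.

The total score is the weighted sum

$$S = w_s\, s(n_s, a_s) + w_o\, s(n_o, a_o) + w_t\, s(n_t, a_t),
\qquad w_s + w_o + w_t = 1,$$

so $S \in [0, 1)$, $S = 0$ exactly for evidence-free bundles, and $S$ is
monotone in every evidence component. Two rules are enforced upstream of
the formula: genetic interactions are excluded during integration, and
ortholog evidence only ever *boosts* an interaction that already has human
experimental support — organism annotations attach to existing pairs, and
ortholog-only pairs are discarded.

```{r}
params <- scoring_params()   # published optimum
params
score_interaction(evidence_counts_values(1, 0, 5), params)
score_interaction(evidence_counts_values(2, 0, 5), params)
```

## Technique reliability scores

The packaged table maps 125 detection-method names (and their PSI-MI codes
where the vocabulary has one) to curated scores in $[0, 10]$: structure
determination and biophysics at the top (x-ray crystallography 10, NMR
10), complementation- and affinity-based assays around 5, and methods that
only suggest association (colocalization, cosedimentation) at the bottom;
"no experiment assigned" scores 0. Lookups resolve by PSI-MI code first
and by normalized name second (case-folded, hyphens/slashes collapsed), so
"Two-hybrid" and "two hybrid" are one method. An unknown technique scores
0 and warns — an unrecognized assay must never inflate confidence.

## Parameter selection

The six free parameters are chosen by exhaustive grid search: steepness
constants on $[0, 3]$ and weights on $[0, 1]$, both at step 0.1, weights
constrained to the simplex — 31³ steepness combinations × 66 weight
triples = 1,966,206 candidates. Combinations inducing fewer than 20
distinct score values on the reference (configurable) are excluded as
degenerate; setting $w_t = 0$ is the canonical way this happens, because
the technique scores provide most of the score's granularity.

Candidates are ranked by a leave-one-study-out reproducibility objective
computed on a reference dataset with explicit study–interaction
associations. For each eligible held-out study $j$ (at least 10
interactions and more than two multi-study PPIs): remove the study's
evidence from the reference (a PPI keeps its other studies and techniques;
a PPI left with no evidence drops out), rescore the reduced dataset, let
$Q_3$ be its upper quartile (nearest rank), and measure

$$\mathrm{dev}_j = \frac{n^{\mathrm{high}}_j + 0.5}
                        {0.25\,|O_j| + 0.5},$$

where $O_j$ is the set of PPIs shared between study $j$ and the reduced
dataset and $n^{\mathrm{high}}_j$ counts those scoring $\ge Q_3$. The 0.5
pseudocounts keep $\log \mathrm{dev}$ finite when nothing lands in the top
quartile; $Q_3$ makes the null fraction exactly $1/4$. The objective is
the overlap-weighted geometric mean

$$f = \exp\!\left(\frac{\sum_j v_j \log \mathrm{dev}_j}{\sum_j v_j}\right),
\qquad v_j \propto |O_j|,$$

invariant under rescaling of the $v_j$ and under study permutation; any
strictly increasing outer function would give the same argmax — the
exponential is chosen so that $f$ sits on the natural "1 = chance" scale.
The winner maximizes $f$; among $f$-maximizers the largest nearest-rank
interquartile range of the full-reference score distribution wins (a wider
spread separates confidence classes better); residual ties go to the
lexicographically smallest tuple, which makes the search fully
deterministic. Whether $Q_3$ should be recomputed per holdout or fixed
once on the full reference is a genuinely open choice; this implementation
recomputes it per holdout, consistent with rescoring the reduced dataset.

`fit_scoring_params()` exposes the search as a classic fitting function
returning an object with `coef()`, `print()`, `summary()` and
`predict()`. The full grid is large; a coarser grid is the practical
default and tests run at reduced resolution (steepness step 1.0, weight
step 0.2).

## Evaluation protocol

An external screen detects a network PPI only if at least one endpoint was
a bait, so recall is computed on the *detectable* subset. The scored
network is stratified at a threshold (ties land in the high stratum:
membership is `score >= threshold`), per-stratum recall is the overlap
with the screen's detected pairs divided by the detectable count, and a
one-sided Fisher's exact test asks whether the high-confidence stratum is
recalled better. The 2×2 table pairs each stratum's overlap count with its
detectable count — `[[k_high, n_high], [k_low, n_low]]`; this is the
convention that reproduces the published worked examples
(`fisher_one_sided(75, 2239, 45, 5760)` = 6.40e-15,
`fisher_one_sided(41, 322, 32, 806)` = 1.75e-6), which a
conventional successes-vs-failures table does not.

```{r}
fisher_one_sided(75, 2239, 45, 5760)
fisher_one_sided(41, 322, 32, 806)
```

## Numerical choices

* **Quantiles** use the nearest-rank convention (the
  $\lceil 0.75 n \rceil$-th order statistic), deterministic across
  platforms and always an observed score; the interquartile tie-breaker
  uses the same convention for both quartiles.
* **Flat-file scores** are written at 2 decimals (round-half-even), the
  granularity of the 0.73 threshold; comparisons are always on full
  precision in memory.
* **Tie handling** in the search compares $f$ and iqr with an absolute
  tolerance of 1e-9 before falling through to the lexicographic rule.
* **Degenerate inputs**: empty record lists merge to an empty network;
  upper quartiles require at least 4 scores; an all-degenerate grid is an
  error rather than an arbitrary winner.
* Self-interactions are kept and flow through scoring unchanged; the
  evidence ledger is pure set union, the conservative reading when a
  database copy and a primary-paper copy of the same PPI coexist.

## The synthetic generator, and what passing tests do not show

`generate_sources()` emulates the *evidence structure* of an integrated
collection — study multiplicity, technique composition, ortholog support,
gene-mapping ambiguity, contamination with genetic records and unmappable
identifiers — with a ground-truth ledger computed by independent
bookkeeping, so integration and scoring are checked end to end
(conservation of evidence). Defaults (80 proteins, 220 interactions, 14
studies, multiplicities 1–4 with 60% singletons, 3 source datasets, 10%
gene ambiguity, 5% genetic records, 3% unmappable endpoints, 3%
per-species ortholog rate) reflect a realistic collection at test scale;
techniques are drawn per pair and shared by its studies, as replicate
studies typically reuse the assay. It does **not** simulate interactome
topology (degree distributions, clustering), database-specific curation
styles, or identifier noise beyond plain unmappability — passing tests
therefore certify the machinery, not corpus-scale published figures
(total network size, per-source counts, the 109 eligible studies,
$\max(f) = 1.023$), which depend on database snapshots that are not
shipped.

The parameter-recovery test uses a fixture with *planted strong study
reproducibility*: multi-study PPIs a minority (70% singletons, the rest
3–4 studies deep, so one removal leaves them multi-study) and a
homogeneous mid-tier technique pool, so the reproducibility signal lives
in the studies; the reduced-resolution search then puts the dominant
weight on the study count in ≥ 90% of seeds. The converse regime is worth
knowing: if *most* pairs are multi-study, the reduced-set upper quartile
sits among untouched multi-study pairs and held-out overlap pairs are
systematically *depleted* above $Q_3$ — reproducibility is no longer
informative and the search rightly drifts elsewhere. Problem sizes
throughout the tests (tens of proteins, a few hundred interactions,
1,344-combination grids, 10–20 fixture seeds) are the package's chosen
test scale; the algorithms are size-independent.

## Known limitations

* Orthology calls are input data; the package performs no orthology
  inference and accepts only the configured species list.
* The PSI-MI TAB reader targets version 2.5 (15 columns); later versions'
  extra columns are ignored, and XML-based PSI-MI is out of scope.
* A technique absent from the score table contributes 0 — deliberately
  conservative; extend the table rather than relying on parent-term
  guesses.
* The interaction-type filter drops untyped interactions when active,
  since sources disagree on annotation completeness; this is loud in the
  documentation because it surprises users with sparsely annotated inputs.
* Layer-1 subnetworks include only query-incident edges, not edges among
  the newly added partners; iterate `neighborhood_expand()` if closure is
  wanted.
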