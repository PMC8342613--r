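---
title: "Calibrating similarity thresholds for higher-taxon barcode assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating similarity thresholds for higher-taxon barcode assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxathresh)
```

## The model

`taxathresh` treats higher-taxon identification as a nearest-neighbour
classification problem on aligned COI barcodes. The only distance used is
the uncorrected p-distance with pairwise deletion: for a pair of aligned
sequences, every column where either sequence carries a gap or any
character outside `{A,C,G,T}` is discarded, and `p` is the fraction of the
remaining (overlap) sites that differ. Ambiguity codes, including `N`, are
treated as missing rather than partially matched; this keeps `p` exact and
mirrors the conservative reading of "pairwise deletion". Two consequences
are worth keeping in mind:

* p-distances on pairwise-deleted sites need not satisfy the triangle
  inequality, and the package never assumes they do;
* a pair with no overlapping sites has an *undefined* distance. Undefined
  distances are carried as `NA`, excluded from silhouette means, treated as
  "far" (no edge) in clustering, and make a candidate ineligible as a hit —
  they are never silently zeroed.

Similarity, the quantity practitioners see from identification engines, is
`s = 100 (1 − p)` percent computed over the same overlap sites.

### Library dilution

Reference coverage is degraded in a controlled way by single-linkage
clustering at a divergence cutoff `t`: clusters are the connected
components of the graph with an edge wherever `d < t`, so any two clusters
are separated by at least `t` ("at least 5% divergence"); a pair at exactly
`t` falls in different clusters. Within each cluster the member with the
highest silhouette score `s(i) = (b − a) / max(a, b)` — `a` the mean
distance to its own cluster, `b` the smallest mean distance to another
cluster, singletons scoring 0 — becomes the representative. Dilution is
*sequential*: the 10% level clusters the 5% level's representative library,
not the original (an `independent` flag inverts this for sensitivity
analysis). Ties in silhouette go to the longer sequence, then the smaller
id; all id comparisons in the package use C-locale (radix) order so results
do not depend on the session locale.

### Modified leave-one-out identification

Each sequence is queried against the library it came from with three
exclusion rules: candidates within the exclusion divergence of the query
(strictly, a hit must satisfy `d > exclusion_div`), candidates lacking a
family label, and candidates whose overlap with the query is below half the
query's own non-gap length. The exclusion divergence is bound to the
dilution level — 2% for the BIN-level library, 5% for DIV5, 10% for DIV10 —
so a query can never simply rediscover its own BIN or cluster. The top hit
is the eligible candidate with maximal similarity (smallest id on ties) and
its order/family labels are scored against the truth. Queries with no
eligible candidate are reported as unassignable and excluded from
calibration denominators rather than counted as errors.

### Threshold calibration

A query is *assigned* at threshold `t` iff its top-hit similarity strictly
exceeds `t`. The strict inequality matters at boundaries: a false positive
sitting exactly at the chosen threshold is excluded by it. Candidate
thresholds are the observed similarity values themselves (plus a sentinel
below the minimum so the ROC reaches (1, 1)), which keeps reported
thresholds interpretable as observed scores. From the confusion counts at
each candidate the package derives TPR, FPR, precision, accuracy and
assigned fraction; the AUC is the trapezoid over the (FPR, TPR) staircase
and equals the concordance probability with ties counted one half (the
tests verify this against both a brute-force pair count and pROC).

Two families of thresholds are reported:

* **Youden's J** — the candidate maximising TPR − FPR, ties resolved to the
  largest (most conservative) threshold. Undefined when the results contain
  only one outcome class; such groups are flagged rather than guessed.
* **Precision-based (P100/P99/P95)** — the smallest candidate `t` such that
  precision is at least 100%/99%/95% at `t` *and at every higher candidate*
  (candidates assigning nothing are vacuously acceptable). The guarantee
  form makes the threshold well-defined even when precision is
  non-monotone; when the criterion holds everywhere the threshold falls
  back to the minimum observed similarity. A corollary worth noting: a
  lone false positive scoring above every correct match forces the
  precision threshold up to its own score, because no lower threshold can
  guarantee the error budget.

Per-order calibration subsets queries by their *true* order, so each
lineage's thresholds are estimated from its own error structure.

### Divergence structure

`taxon_divergences()` reports, per taxon, the maximum within-taxon and
minimum between-taxon p-distance (monotypic taxa have no within value and
are excluded from barcode-gap flags but counted). The barcode gap uses the
strict rule `max_intra < min_inter`. The divergence–richness relationship
is fitted with three least-squares models — linear, logarithmic and the
asymptotic form `y = A + (y0 − A) e^{−kx}` (the standard self-starting
asymptotic-regression parameterisation; the half-asymptote point is
`x = ln(2(A − y0)/A)/k`) — compared by AIC in the Gaussian profile form
`n·ln(RSS/n) + 2p` with `p` = 2, 2, 3 mean-function parameters. This form
differs from `stats::AIC` by a model-independent constant plus the error
variance parameter, so model ranking is unaffected; it is stated explicitly
because AIC conventions differ. Outlier flagging uses the boxplot rule with
type-7 (linear-interpolation) quartiles, again stated because quartile
conventions differ.

## The synthetic generator

`generate_library()` evolves sequences down an order → family → BIN
hierarchy from a single random root. Substitutions are independent per-site
uniform replacements: an event picks a column uniformly and writes a
uniformly random base (possibly the same one). After `m` events on a path
of an `L`-column alignment the expected p-distance between the endpoints is
exactly `0.75 (1 − (1 − 1/L)^m)`, which saturates below 0.75 — the same
qualitative saturation that compresses deep COI divergences in real data.
Branch event counts are obtained by inverting this curve, so divergence
parameters are *expectations with sampling noise of order*
`sqrt(p(1−p)/L)`, not guarantees; tests and acceptance checks therefore use
tolerance bands, never exact equality. The truth table records the event
count of every generation branch, which lets tests compare realised
distances with their exact expectations.

Default configuration (used by `run_study()` and the acceptance script, and
chosen once as a realistic desk-scale analogue of a densely sampled
continental mite library):

| parameter | default | rationale |
|---|---|---|
| orders × families | 4 × 10 | four focal orders; tens of families with coverage |
| BINs per family | 1–14 (mean 7.5) | ≈ 300 BINs; includes singleton families (~7%), the main source of forced family-level misassignments in real libraries |
| sequences per BIN | 4 | ≈ 1200 records before BIN-representative selection |
| alignment width | 658 | full-length barcode region; amplicon trim 196–658 → 463 bp |
| intra-BIN divergence | ≤ 2% | species-proxy cohesion |
| inter-BIN (within family) | 4–20% | lets intrafamily maxima approach saturation values and makes the 5%/10% dilution levels non-trivial |
| interfamily floor | 12% | family ancestors separated beyond the strictest exclusion radius |
| interorder floor | 18% | smallest divergence between orders |
| ambiguity rate | 0.2%/site | below the 1% compliance cut |
| decoys | 0 | see below |

What the generator deliberately does **not** emulate: codon structure,
indels (gaps arise only from truncation), rate heterogeneity across sites
or lineages, and the heavy-tailed taxon abundances of real libraries. Its
inter-order distances also sit higher above the floor than real saturated
COI distances do, because every branch adds its expected load. Passing
tests on synthetic libraries therefore demonstrate that the *machinery* —
distances, dilution, exclusion rules, confusion accounting, threshold
guarantees — is correct under known truth, not that any particular
threshold value transfers to a real reference library; thresholds must be
recalibrated per library with the same functions.

Decoy records (distant outgroup lineages, for emulating cross-phylum
captures) are available via `n_decoys`/`inject_decoys()` but default to
off: in the generator's clean hierarchy a decoy beyond the inter-order
floor is never the nearest neighbour of a query whose own lineage is
present, so decoys only matter for removed-lineage scenarios, which the
test suite exercises explicitly.

## Numerical and design choices

* **Edge rule** `d < t` for clustering (between-cluster divergence ≥ t) and
  **strict** `s > t` for assignment; both boundary conventions are
  load-bearing and tested.
* **Tie-breaks** are total and deterministic everywhere (silhouette →
  length → id; similarity → id; Youden → largest t), so reruns are
  digest-identical.
* **Undefined quantities are flagged, not imputed**: zero-overlap
  distances, single-class AUCs, single-cluster silhouettes, monotypic
  `max_intra`.
* **Problem sizes**: the shipped study runs on ~1200 sequences / ~300 BINs
  (about a quarter of the scale of a continental mite library), which keeps
  a full six-dataset study to well under a minute while leaving every
  statistic estimable; the generator scales to larger configurations if
  needed.
* **Overlap denominator**: the query's non-gap length. A reference longer
  than the query can always achieve full overlap; a truncated reference is
  penalised.

## A complete run

```{r study, eval = FALSE}
m <- run_study(config = synthetic_config(seed = 1),
               out_dir = "study_out")
m               # per-dataset success and exclusion summary
m$datasets$BIN$report |>
  dplyr::filter(scope == "all", rank == "family")
```

The manifest lists every emitted file with its MD5 digest; two runs with
the same config and seed produce identical digests, which the test suite
asserts. Known limitations beyond those of the generator: calibration
assumes the reference library's labels are correct (no error-screening
step), BOLD's proprietary similarity ranking is approximated by
`100 (1 − p)` on pairwise-deleted sites, and no uncertainty is attached to
the thresholds themselves — resampling the library is the natural
extension.
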