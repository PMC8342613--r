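# taxathresh

Calibrating DNA-barcode similarity thresholds for assigning species proxies
(BINs — Barcode Index Numbers) to higher taxonomic ranks.

## The problem

Large barcoding and metabarcoding surveys of hyperdiverse groups such as
mites (Acari) recover thousands of COI BINs that no taxonomist has seen.
A nearest-neighbour search against a reference library can still place such
a BIN in an **order** or **family**, but only if the similarity of its best
match is trusted — and the similarity value at which an assignment stops
being trustworthy depends on the lineage, on how completely the library
covers it, and on how much of the barcode was sequenced. `taxathresh`
implements the full calibration workflow that turns an aligned reference
library into defensible, rank- and lineage-specific similarity thresholds:

1. **Library construction** — barcode-compliance filtering (≥ 500 bp, < 1%
   ambiguous bases), one representative per BIN, and optional trimming to a
   shorter amplicon (463 bp by default) to mimic metabarcoding reads.
2. **Dilution series** — uncorrected p-distances with pairwise deletion,
   single-linkage clustering at 5% and then 10% divergence, and
   silhouette-optimal representatives per cluster, yielding progressively
   sparser libraries (BIN → DIV5 → DIV10) that emulate declining taxon
   coverage.
3. **Modified leave-one-out identification** — every sequence is queried
   against the library with its self-match *and every neighbour within an
   exclusion divergence* (2% / 5% / 10%, bound to the dataset level)
   removed, so a query cannot trivially match its own BIN or cluster; hits
   also need a family label and ≥ 50% site overlap.
4. **Threshold calibration** — each query's top-hit similarity
   `s = 100 (1 − p)` and correctness feed ROC curves
   (TPR = TP/(TP+FN), FPR = FP/(FP+TN), trapezoidal AUC), Youden's
   J = TPR − FPR threshold, and precision-based thresholds P100 / P99 / P95
   (the smallest similarity above which at most 0% / 1% / 5% of accepted
   assignments are wrong), globally and per order. Assignment is strict:
   a query is accepted iff its similarity exceeds the threshold.
5. **Divergence structure** — per-taxon maximum-intra / minimum-inter
   p-distances, barcode-gap tables, and linear / logarithmic / asymptotic
   (`y = A + (y0 − A) e^{−kx}`) regression of family divergence on BIN
   richness with AIC model selection.

A seeded synthetic-library generator (`generate_library()`) evolves
sequences down an order → family → BIN hierarchy by per-site uniform
replacement (so deep divergences saturate, as real COI p-distances do) and
makes every stage testable without any downloads.

## Worked example

```r
library(taxathresh)

cfg <- synthetic_config(n_orders = 2, families_per_order = 5,
                        bins_per_family = c(1, 6), seqs_per_bin = 2,
                        seed = 2026)
lib <- generate_library(cfg)$library
bin_lib <- select_bin_representatives(filter_compliant(lib))
res <- loo_identify(bin_lib, loo_config(exclusion_div = 0.02))
summarize_success(res)
#>   group n_queries n_assigned n_unassignable order_success_pct family_success_pct
#> 1 all          31         31              0               100               96.8

calibrate(res, rank = "family", scope = "all")[,
  c("criterion", "threshold", "auc", "TP", "FP", "precision", "assigned_fraction")]
#>   criterion threshold auc TP FP precision assigned_fraction
#> 1    youden        77   1 30  0         1             0.968
#> 2      P100        77   1 30  0         1             0.968
#> 3       P99        77   1 30  0         1             0.968
#> 4       P95        77   1 30  0         1             0.968
```

Reading the output: of 31 BIN representatives, the one misassigned query is
the sole member of a singleton family — its nearest *eligible* neighbour is
necessarily another family, at 77% similarity. Because that false positive
sits below every correct match, the calibrated thresholds at 77% exclude it
while keeping 96.8% of queries assigned, and the ROC separates the classes
perfectly (AUC = 1). On sparser or noisier libraries the P100 threshold
rises above Youden's and the assigned fraction drops — the trade-off the
calibration quantifies.

`run_study()` chains the whole design (six datasets: full-length and
trimmed × BIN/DIV5/DIV10), writes every table plus a digest manifest to an
output directory, and is reproducible to identical digests under a fixed
seed. `autoplot()` methods draw ROC curves, barcode-gap scatters and
divergence-richness fits; `tidy()`/`glance()` give broom-style summaries.

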