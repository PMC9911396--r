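# retrokit

Retroelement expression, enrichment and divergence analysis for regulatory
genomics — built around the biology of the human endogenous retrovirus
HERVH and its long terminal repeat LTR7, whose transcriptional activity
marks naïve-like pluripotent states.

The package is aimed at computational biologists who need the
retroelement-centric half of a perturbation study (knockdown versus
control) as tested, reusable components:

* **TSS pipeline** — demultiplex barcoded 5'-capture (nanoCAGE-style)
  reads (Hamming ≤ 2), trim the 11-nt non-genomic prefix, cluster 5' ends
  into TSS peaks, keep peaks with ≥ 30 supporting reads, annotate them
  (TSS / 3'UTR / exonic / intronic / intergenic), extract 300-bp promoter
  windows (−250/+50 around the TSS) and test known-motif enrichment
  (PWM scan + Fisher exact + Benjamini–Hochberg; significant at
  p < 0.01 and q < 0.01).
* **Repeat expression** — per-locus counts by any-overlap, CPM
  normalization, per-locus log2 fold change
  `log2((CPM_kd + c)/(CPM_ctrl + c))`, and the two-sample
  Kolmogorov–Smirnov statistic `D = sup_t |F_group(t) − F_ref(t)|`
  comparing each retrotransposon subfamily (LINE, SINE, LTR, ERV1,
  LTR7/HERVH, MERs, other ERV1) to a background; plus Pearson correlation
  of fold changes across perturbations and between HERVH units and their
  overlapping lncRNAs (CPM > 1 filter).
* **Peak enrichment** — A-ratio (fraction of peak bases in a feature
  class), B-ratio (fraction of genome covered by the class), enrichment
  score `log2(A/B)`, a length- and chromosome-preserving permutation null,
  and peak-to-HERVH association within 10-kb flanks.
* **LTR dating** — detection of full-length LTR7–HERVH-int–LTR7 units,
  global pairwise LTR alignment, transition/transversion proportions P and
  Q, the Kimura two-parameter distance
  `K = ½ ln[1/(1 − 2P − Q)] + ¼ ln[1/(1 − 2Q)]`, divergence time
  `T = K/(2r)` at `r = 1.28e−8` substitutions/site/year, and
  Mann–Whitney comparison of top-200 versus bottom-200 units by expression
  or fold change.
* **Synthetic data** — seeded generators that plant every effect the
  stages are meant to detect: per-subfamily log2 fold-change shifts on
  negative-binomial counts, peak sets with a controlled placement density
  over a repeat class, LTR pairs diverged under the exact K2P chain to a
  known distance, and barcoded reads piling up at planted TSS positions.

## Worked example

Simulate a knockdown that doubles HERVH expression (planted
`δ(LTR7) = δ(HERVH-int) = 1`) on a census of 5,300 repeat loci, then ask
which subfamilies shifted:

```r
library(retrokit)
loci <- make_locus_table()
ct   <- simulate_counts(loci, delta = c(LTR7 = 1, `HERVH-int` = 1), seed = 42)
lfc  <- log2_fold_change(ct)
subfamily_ks_scan(lfc, loci, reference = "background")
#>        group  reference      D         p   n1   n2
#> 1       LINE background 0.0748  1.60e-05 1500 3500
#> 2       SINE background 0.0798  4.55e-07 2000 3000
#> 3        LTR background 0.1557  1.54e-22 1500 3500
#> 4       ERV1 background 0.1557  1.54e-22 1500 3500
#> 5 LTR7/HERVH background 0.7918 5.23e-154  300 4700
#> 6       MERs background 0.0890  1.44e-04  700 4300
#> 7 other-ERV1 background 0.0680  3.12e-02  500 4500
```

The planted LTR7/HERVH shift dominates (D ≈ 0.79); the small D values of
untouched subfamilies reflect the mild library-composition shift CPM
introduces when one subfamily doubles. Dating a synthetic LTR pair
generated at pairwise divergence 0.05:

```r
pair <- simulate_ltr_pair(ltr_length = 1000, k_true = 0.05, seed = 1)
pq   <- count_pq(align_pair(pair$ltr5, pair$ltr3))
K    <- k2p_distance(pq$P, pq$Q)
divergence_time(K)   # T = K / (2r), r = 1.28e-8 per site per year
#> P = 0.0290  Q = 0.0210  K = 0.0519  T = 2026348 years
```

`run_demo(pipeline_config())` chains every stage on one seeded synthetic
dataset and returns a self-check table (planted-parameter recovery for TSS
depths, KS power, enrichment, correlations, unit detection and dating);
it errors if any check fails, and identical seeds give byte-identical
reports.

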