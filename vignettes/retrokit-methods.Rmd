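---
title: "retrokit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{retrokit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrokit)
```

retrokit analyses the regulatory biology of endogenous retroviruses —
principally the primate-specific HERVH family and its long terminal repeat
LTR7 — in pluripotent cells. It chains five stages: 5'-capture
(nanoCAGE-style) read processing into transcription start site (TSS) peaks;
fold-change statistics of repeat subfamilies after a knockdown; ChIP-peak
enrichment over repeat classes; HERVH–lncRNA overlap and correlation; and
insertion dating of full-length LTR elements. Every stage is validated by
recovering parameters planted by the package's own synthetic-data
generators. This vignette records the statistical models, the defaults that
matter, and the design decisions that were genuinely open.

## Coordinates and interval arithmetic

All coordinates are 0-based half-open (`[start, end)`), the BED native
convention; GTF input is converted on read (`start - 1`) and back on write.
A single convention removes the usual off-by-one bug class: abutting
intervals never overlap, widths are `end - start`, and a TSS is a single
base position. Interval overlap and merging are delegated to IRanges behind
the package's `overlap_intervals()` / `merge_intervals()` surface; unit
tests compare the engine against an all-pairs brute-force scan. Strand `"."`
participates only in unstranded overlap, because repeat annotations often
lack strand.

## TSS peaks and promoters

Reads are demultiplexed by a 6-nt barcode prefix with a budget of 2
mismatches; a read is assigned only when exactly one barcode qualifies, so
ties go to the unassigned bin rather than bleeding between samples. The
first 11 nucleotides (barcode plus spacer) are non-genomic and trimmed.
Five-prime positions are clustered per chromosome and strand by a greedy
rule: sorted positions join a cluster while they lie within `merge_window`
(default 20 bp) of the cluster's right edge. The load-bearing filter is the
read-support threshold: peaks need at least 30 unique supporting reads.
The original peak caller in this line of work (HOMER) adds an FDR filter
whose effect cannot be reconstructed from published settings; only the
stated support rule is implemented, and the clustering window is explicit
and configurable for the same reason.

Peak categories follow a fixed priority: within 1 kb of an annotated
transcript 5' end the peak is a TSS peak (distance signed, positive
downstream in the transcript's orientation); otherwise 3'UTR, then exonic,
then intronic by point membership of the peak's representative position;
otherwise intergenic. Using a single representative point (mode for TSS
peaks, midpoint for ChIP peaks) keeps category fractions summing to one.

Promoter windows cover 250 bp upstream to 50 bp downstream of the TSS.
Since only "upstream/downstream" is stated by convention, the exact
half-open coordinates are a package decision: `[t - 250, t + 50)` on the
plus strand and the mirror image `[t - 49, t + 251)` on the minus strand,
both 300 bp, both containing the TSS base, with minus-strand sequences
reverse-complemented. A strand-flip symmetry test (reverse-complement the
genome, flip all strands, expect identical promoter sequences) pins this
convention down.

Known-motif enrichment scans position weight matrices over both
orientations; a sequence is a hit when some window reaches 80% of the
motif's maximum achievable log-odds score (configurable). Hits are tested
by Fisher's exact test (two-sided) with Benjamini–Hochberg correction
across motifs; significance requires p < 0.01 and q < 0.01. De novo motif
discovery is out of scope; motifs are supplied in JASPAR-style text.

"Stage-specific" peaks are defined by presence/absence: a peak is specific
to a stage when it passes the support filter there and overlaps no filtered
peak of any other stage on the same strand. The literature definition is
ambiguous (presence/absence versus fold change); this reading is the
simplest consistent one and the threshold is configurable.

## Repeat expression and KS statistics

Fragments are counted per repeat locus by the any-overlap rule (1 bp
suffices; a fragment spanning k loci increments all k), mirroring default
interval-coverage quantification; a unique-assignment mode exists for
comparison. Counts are normalized to CPM (counts per million per sample),
and the per-locus log2 fold change is
`log2((mean CPM_kd + c) / (mean CPM_ctrl + c))` with pseudocount `c = 0.5`.
The fold-change estimator is deliberately the plain CPM ratio — the
upstream work normalizes to CPM and states no shrinkage — and the
pseudocount, which keeps zero-count loci finite and cancels when both
conditions are zero, is configurable.

Subfamily shifts are measured with the two-sample Kolmogorov–Smirnov
statistic: D is the supremum of the ECDF difference between a group's fold
changes and a reference. Group definitions follow the standard repeat
hierarchy: classes LINE/SINE/LTR, family ERV1, the LTR7/HERVH pair (LTR7
plus HERVH-int subfamilies), MER subfamilies within ERV1, and the remaining
"other ERV1". One deliberate deviation: the "total background" reference
here excludes the tested group. The figure legends this framework follows
compare each subtype to a total that includes it, but overlapping samples
make the KS test conservative and uncalibrated; with disjoint samples the
null p-values are uniform, which is what the package's calibration tests
require. For minority subfamilies the numerical difference is negligible.

The p-value uses exact enumeration of the Smirnov distribution (tie-aware,
via `stats::psmirnov`) when `n1 + n2 <= 20` and the asymptotic Kolmogorov
series at effective size `n1 n2/(n1 + n2)` otherwise — the same rule and
series every mainstream implementation uses. A numerical note: at the seam
(n1 = n2 = 10) the limiting series differs from the exact tail by up to
about 0.028 (at D = 0.3); this is a property of the limiting approximation
itself — published small-sample corrections do worse at effective size 5 —
and the package's test suite measures it explicitly rather than hiding it.

Cross-perturbation agreement (e.g. two different knockdowns) is the Pearson
correlation of per-locus log2 fold changes over a locus subset, with the
usual t-based two-sided p.

## HERVH–lncRNA analysis

lncRNA genes are paired with full-length HERVH units when the gene interval
overlaps an LTR7 or HERVH-int locus by at least 1 bp. Overlap is
strand-agnostic by default because LTR7 drives both sense and antisense
transcripts; a strand-matched mode exists. Expression filtering retains
lncRNAs whose mean control CPM is strictly greater than 1 ("higher than
one" is read as strict). A unit's fold change pools raw counts over its
LTR7 and internal segments before the CPM ratio, so the unit is measured as
one transcriptional element. The reported correlation is Pearson's R over
(unit, lncRNA) fold-change pairs; a mode correlating absolute expression
instead of fold change is available, fold change being the default reading.

## Peak enrichment

Enrichment of a peak set over a feature class is `log2(A/B)` with A the
fraction of peak base pairs inside the merged feature ("size of peaks that
overlap", hence base-pair-weighted; a count-weighted mode exists) and B the
fraction of the genome the merged feature covers. Significance comes from a
permutation null — the upstream work asserts significance without stating a
test, so this is an explicit substitute, not a reconstruction: each
permutation re-places every peak uniformly on its original chromosome with
length preserved, and the empirical p uses the add-one estimator
`(1 + #{perm >= obs})/(n_perm + 1)`, which cannot return 0. Permutations
use a prefix-sum coverage lookup (equal to the interval engine, asserted in
tests) so a 999-permutation run costs well under a second on toy genomes.
No gap/blacklist masking is applied on synthetic genomes; real-genome use
would add a mask hook. Peak-to-HERVH association is a mutually exclusive
priority: overlapping LTR7 beats overlapping the internal region, which
beats lying within 10 kb of either LTR7, else unassociated.

## Paired-LTR dating

Full-length units are maximal LTR7 / HERVH-int / LTR7 runs on one
chromosome and strand with inter-segment gaps of at most `gap_tolerance`
(default 100 bp — no adjacency rule is published, so the tolerance is
explicit and logged); adjacent internal fragments merge; solo LTRs are
never dated. The two LTRs are globally aligned (match +1, mismatch −1, gap
open −5, extend −1 per gapped position; the dynamic programming engine is
Biostrings' `pairwiseAlignment`, checked against an exhaustive-search
oracle on short sequences). Over ungapped non-N columns, P and Q are the
transition and transversion proportions and the Kimura two-parameter
distance is

K = 1/2 ln[1/(1 − 2P − Q)] + 1/4 ln[1/(1 − 2Q)].

Saturated pairs (domain violations) are flagged and excluded, never
clamped, which avoids piling excluded elements at an artificial maximum
age. Divergence time uses T = K/(2r) with r = 1.28e−8 substitutions per
site per year: the two LTRs are identical at insertion and then diverge
along two independent lineages, so per-lineage divergence is K/2. Only r is
published for this analysis, so the 2r convention is flagged prominently
and a K/r mode exists for sensitivity analysis. Expression-stratified
comparisons (top versus bottom 200 by expression or fold change) default to
a two-sided Mann–Whitney U test — the published test is unstated, so the
test name is always recorded in the output and KS and Welch-t alternatives
are selectable. With completely tied data the tie-corrected normal
approximation is undefined and the comparison reports p = 1.

## Synthetic data: what is planted and what is not

The generators are pure functions of their arguments and a seed.

* **K2P evolution** uses the exact finite-time transition probabilities of
  the K2P chain (transition rate α, each transversion target β; expected
  substitutions per site `(α + 2β)t`), so there is no discretization error
  at any branch length. LTR pairs mutate one ancestor along two independent
  branches of length t each, with `2(α + 2β)t` equal to the requested
  pairwise divergence — matching post-insertion LTR biology. Default
  κ = α/β = 2. Indels are not simulated.
* **Counts** are negative-binomial (dispersion 0.1 unless stated) around
  log-normal per-locus baselines, with knockdown means `baseline · 2^δ`.
  No count model is published for the repeat quantification; NB with
  log-normal baselines is the standard RNA-seq noise model and suffices for
  KS/correlation recovery. The default locus census keeps LTR7/HERVH a
  ~6% minority (300 of 5300 loci) so that CPM library-composition bias
  under a planted δ stays below ~0.1 log2 units; the real annotation is
  even more skewed (LTR7/HERVH is ~1% of quantified loci).
* **Peaks** draw start positions from a piecewise-constant density:
  `enrichment_factor` on bases of the target class, 1 elsewhere, with fixed
  length and no out-of-bounds placement. Factor 1 is the calibration null.
* **Reads** are barcode (optional per-base substitution errors) + fixed
  spacer to 11 nt + genomic sequence starting exactly at a planted TSS on
  the annotated strand. Barcodes within Hamming distance 4 of each other
  are rejected at generation time because they would break 2-mismatch
  demultiplexing. Read ids carry the generating truth, which stands in for
  alignment (alignment is out of scope).

What the generators do **not** emulate: mappability and multi-mapping
ambiguity of young repeats, PCR duplicates, indel evolution, GC or
length biases, and genome-scale annotation complexity. Passing recovery
tests therefore demonstrates correctness of the statistics and plumbing
under the assumed noise models, not robustness to real-data artefacts —
in particular, multi-mapping is the dominant unmodelled difficulty for
LTR7/HERVH quantification on real genomes.

## Problem sizes and numerical choices in the test suite

The suite validates, among others: D against a brute-force ECDF scan on 500
random small instances; null calibration of subfamily p-values over 200
simulated datasets and power at planted δ(HERVH) = 1 over 50; K2P recovery
at pairwise divergences 0.02/0.05/0.10 with 100 pairs of 1-kb LTRs each
(mean within 10% of truth); permutation-p uniformity over 200 null peak
sets (199 permutations each) and detection of a planted factor-5 enrichment
at 999 permutations; exact TSS recovery at boundary depths 29/30/31; and
Pearson recovery of planted ρ = −0.6 (500 loci) and ρ = 0.5 (56 pairs)
within their 95% sampling intervals. These sizes were chosen so each
property has clear statistical resolution while the whole suite stays
desk-scale; the headline figures of the original genome-scale analyses
(e.g. D = 0.79 for LTR7/HERVH, 940 dated units, 280/56 lncRNAs) depend on
full human-genome data and are not reproduced numerically.

Tie-breaking and degenerate-input rules worth knowing: cluster mode ties
resolve to the leftmost position; demultiplexing ties go unassigned;
`A = 0` in the enrichment score returns −Inf with a flag rather than an
error; empty annotation makes all peaks intergenic with a warning; zero
usable alignment columns, zero-total samples and constant correlation
vectors are errors, not silent NAs.

## Limitations

The package is a desk-scale re-implementation of a published analysis
style, validated on synthetic data only. Real-data use would additionally
need: read alignment, multi-mapping-aware repeat quantification, peak
calling, blacklist masking in the permutation null, and a multiple-sequence
aligner if more than two LTRs per element are compared. The KS framework
compares distributions of per-locus fold changes and is deliberately free
of a parametric differential-expression model; it answers "did this
subfamily shift as a population", not "which locus changed".
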