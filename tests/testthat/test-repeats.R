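make_loci_iv <- function() {
  gintervals("c", c(100, 200), c(200, 300), "+",
             locus_id = c("l1", "l2"), class = "LTR", family = "ERV1",
             subfamily = c("LTR7", "HERVH-int"))
}

test_that("fragment counting uses the any-overlap rule with multi-assignment", {
  loci <- make_loci_iv()
  frags <- list(s1 = gintervals("c", c(120, 190, 300), c(130, 210, 310)))
  ct <- quantify_repeats(frags, loci)
  # fragment [190,210) spans both loci and increments both;
  # [300,310) abuts l2 (half-open) and counts nowhere
  expect_equal(unname(ct$counts[, 1]), c(2, 1))
  # unique-assignment mode: the spanning fragment goes to l2 (10 bp vs 10 bp
  # tie -> first by locus order), i.e. exactly one of the two
  ct2 <- quantify_repeats(frags, loci, unique_assignment = TRUE)
  expect_equal(sum(ct2$counts), 2)
  # permutation invariance in fragment order
  frags_rev <- list(s1 = frags$s1[3:1, ])
  expect_equal(quantify_repeats(frags_rev, loci)$counts, ct$counts)
})

test_that("CPM normalization scales each sample to one million", {
  loci <- data.frame(locus_id = c("a", "b"), class = "LTR", family = "ERV1",
                     subfamily = "LTR7")
  samples <- data.frame(sample_id = c("s1", "s2"), condition = "control",
                        replicate = 1:2)
  ct <- count_table(matrix(c(10, 90, 20, 180), 2), loci, samples)
  ct <- cpm_normalize(ct)
  expect_equal(unname(ct$cpm[, 1]), c(1e5, 9e5))
  # proportional samples give identical CPM columns
  expect_equal(ct$cpm[, 1], ct$cpm[, 2], ignore_attr = TRUE)
  expect_equal(unname(colSums(ct$cpm)), c(1e6, 1e6))
  ct0 <- count_table(matrix(c(1, 1, 0, 0), 2), loci, samples)
  expect_error(cpm_normalize(ct0), "zero total")
})

test_that("log2 fold change follows the pseudocount formula", {
  loci <- data.frame(locus_id = c("a", "b", "z"), class = "LTR",
                     family = "ERV1", subfamily = "LTR7")
  samples <- data.frame(sample_id = c("c1", "k1"),
                        condition = c("control", "knockdown"),
                        replicate = c(1, 1))
  # craft counts so that CPM(a): ctrl 10, kd 40; CPM(z): 0 both
  counts <- matrix(c(1, 99, 0, 4, 96, 0), 3)
  ct <- count_table(counts, loci, samples)
  ct$cpm <- matrix(c(10, 990, 0, 40, 960, 0), 3,
                   dimnames = dimnames(ct$counts))
  lfc <- log2_fold_change(ct, pseudocount = 0.5)
  expect_equal(unname(lfc["a"]), log2(40.5 / 10.5))
  expect_equal(round(unname(lfc["a"]), 4), 1.9475)
  expect_equal(unname(lfc["z"]), 0)  # both zero: pseudocount cancels
  # equal means give 0
  ct2 <- count_table(matrix(c(5, 5, 5, 5, 5, 5), 3), loci, samples)
  expect_equal(unname(log2_fold_change(ct2)), rep(0, 3))
})

test_that("KS statistic matches the brute-force ECDF oracle", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$D, 1)
  expect_equal(ks_two_sample(c(1, 3), c(2, 4))$D, 0.5)
  set.seed(8)
  for (i in 1:200) {
    x <- sample(1:10, sample(1:8, 1), replace = TRUE)
    y <- sample(1:10, sample(1:8, 1), replace = TRUE)
    expect_equal(ks_two_sample(x, y)$D, brute_ks_D(x, y))
  }
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("subfamily scan groups partition ERV1 and forbid self-comparison", {
  loci <- make_locus_table()
  g <- repeat_groups(loci)
  expect_equal(g$ERV1, g$`LTR7/HERVH` | g$MERs | g$`other-ERV1`)
  expect_false(any(g$`LTR7/HERVH` & g$MERs))
  lfc <- stats::setNames(rnorm(nrow(loci)), loci$locus_id)
  expect_error(subfamily_ks_scan(lfc, loci, groups = "MERs",
                                 reference = "MERs"), "self-comparison")
  res <- subfamily_ks_scan(lfc, loci, groups = c("LINE", "LTR7/HERVH"))
  expect_equal(res$n1 + res$n2, rep(nrow(loci), 2))
})

test_that("planted HERVH shift dominates the subfamily KS scan", {
  loci <- make_locus_table()
  ct <- simulate_counts(loci, delta = c(LTR7 = 1, `HERVH-int` = 1), seed = 21)
  res <- subfamily_ks_scan(log2_fold_change(ct), loci)
  d <- stats::setNames(res$D, res$group)
  expect_gt(d[["LTR7/HERVH"]], d[["SINE"]])
  expect_gt(d[["LTR7/HERVH"]], d[["LINE"]])
  expect_lt(res$p[res$group == "LTR7/HERVH"], 1e-6)
})

test_that("cross-knockdown correlation handles exact and degenerate cases", {
  a <- stats::setNames(rnorm(50), paste0("l", 1:50))
  expect_equal(cross_kd_correlation(a, -a)$R, -1)
  expect_equal(cross_kd_correlation(a, a * 2)$R, 1)
  expect_error(cross_kd_correlation(a[1:2], a[1:2]), "at least 3")
  b <- stats::setNames(rep(1, 50), names(a))
  expect_error(cross_kd_correlation(a, b), "constant")
  # subset restriction
  r <- cross_kd_correlation(a, -a, subset = paste0("l", 1:10))
  expect_equal(r$n, 10)
})

test_that("lncRNA-HERVH overlap pairs per unit with half-open boundaries", {
  reps <- gintervals("c", c(1000, 1450, 5000), c(1450, 5000, 5450), "+",
                     locus_id = c("u1_ltr5", "u1_int", "u2_ltr5"),
                     class = "LTR", family = "ERV1",
                     subfamily = c("LTR7", "HERVH-int", "LTR7"),
                     unit_id = c("u1", "u1", "u2"))
  genes <- data.frame(chrom = "c", start = c(900, 990, 1400),
                      end = c(1100, 1000, 5100), strand = "+",
                      feature_kind = "gene", gene_id = c("g1", "g2", "g3"),
                      transcript_id = NA, biotype = "lncRNA")
  pairs <- lncrna_hervh_overlap(genes, reps)
  # g1 overlaps u1; g2 abuts (end 1000 = start 1000) -> no pair;
  # g3 spans u1 and u2 -> two pairs
  expect_equal(nrow(pairs), 3)
  expect_setequal(pairs$unit_id[pairs$gene_id == "g3"], c("u1", "u2"))
  expect_false("g2" %in% pairs$gene_id)
  # non-lncRNA genes are ignored
  genes$biotype <- "protein_coding"
  expect_equal(nrow(lncrna_hervh_overlap(genes, reps)), 0)
})

test_that("expression filter is strictly greater than the CPM threshold", {
  loci <- data.frame(locus_id = c("a", "b", "c"), class = "gene",
                     family = "gene", subfamily = "lncRNA")
  samples <- data.frame(sample_id = c("c1", "k1"),
                        condition = c("control", "knockdown"),
                        replicate = 1)
  ct <- count_table(matrix(c(1, 0, 5, 3, 3, 3), 3), loci, samples)
  ct <- cpm_normalize(ct)
  # force CPM values directly for a crisp boundary test
  ct$cpm[, 1] <- c(1.0, 1.01, 0.5)
  expect_equal(expressed_lncrna_filter(ct, threshold = 1), "b")
})

test_that("unit pooling and pair correlation recover exact relationships", {
  hl <- simulate_hervh_lnc_dataset(n_units = 20, rho = 0.5, seed = 31)
  pooled <- pool_unit_counts(hl$counts)
  expect_equal(nrow(pooled$counts), 20)
  expect_equal(sum(pooled$counts), sum(hl$counts$counts))
  ulfc <- log2_fold_change(pooled)
  # lncRNA fold changes copied from their units give R = 1
  fake <- stats::setNames(ulfc[hl$pairs$unit_id], hl$pairs$gene_id)
  r <- hervh_lncrna_correlation(hl$pairs, ulfc, fake)
  expect_equal(r$R, 1)
  expect_equal(r$n, 20)
  expect_error(hervh_lncrna_correlation(hl$pairs[1:2, ], ulfc, fake),
               "at least 3")
})
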