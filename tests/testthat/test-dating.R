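unit_repeats <- function(gap = 0) {
  s2 <- 450 + gap
  s3 <- s2 + 4000 + gap
  gintervals("c", c(0, s2, s3), c(450, s2 + 4000, s3 + 450), "+",
             locus_id = c("a", "b", "d"), class = "LTR", family = "ERV1",
             subfamily = c("LTR7", "HERVH-int", "LTR7"))
}

test_that("full-length unit detection applies the gap rule", {
  u <- find_full_length_units(unit_repeats())
  expect_equal(nrow(u), 1)
  expect_equal(u$ltr5_end, 450)
  expect_equal(u$ltr3_start, 4450)
  # within tolerance
  expect_equal(nrow(find_full_length_units(unit_repeats(gap = 100))), 1)
  # a 5 kb gap breaks the unit at default tolerance
  big <- unit_repeats()
  big$start[3] <- big$start[3] + 5000
  big$end[3] <- big$end[3] + 5000
  expect_equal(nrow(find_full_length_units(big)), 0)
  # solo LTRs never form units
  solo <- unit_repeats()[1, ]
  expect_equal(nrow(find_full_length_units(solo)), 0)
  # adjacent internal fragments merge into one internal interval
  frag <- unit_repeats()
  frag <- rbind(frag[1, ],
                within(frag[2, ], end <- 2000),
                within(frag[2, ], { start <- 2050; locus_id <- "b2" }),
                frag[3, ])
  u2 <- find_full_length_units(frag)
  expect_equal(nrow(u2), 1)
  expect_equal(c(u2$int_start, u2$int_end), c(450, 4450))
})

test_that("pairwise alignment matches hand and exhaustive-search results", {
  id <- align_pair("ACGTACGT", "ACGTACGT")
  expect_equal(id$a, id$b)
  expect_equal(id$score, 8)
  mm <- align_pair("ACGT", "AGGT")
  expect_equal(nchar(mm$a), 4)         # no gaps, one mismatch column
  expect_equal(sum(strsplit(mm$a, "")[[1]] != strsplit(mm$b, "")[[1]]), 1)
  expect_equal(mm$score, 3 - 1)
  gp <- align_pair("ACGT", "ACG")
  expect_equal(sum(strsplit(gp$b, "")[[1]] == "-"), 1)
  expect_equal(gp$score, 3 - 6)        # 3 matches, one length-1 gap (5 + 1)
  expect_error(align_pair("", "ACG"), "non-empty")
  # exhaustive oracle on short random sequences
  set.seed(19)
  for (i in 1:25) {
    a <- random_dna_str(sample(2:6, 1))
    b <- random_dna_str(sample(2:6, 1))
    expect_equal(align_pair(a, b)$score, brute_align_score(a, b))
  }
})

test_that("P/Q counting excludes gap and N columns from the denominator", {
  expect_equal(count_pq(list(a = "ACGT", b = "ACGT")),
               list(P = 0, Q = 0, aligned_columns = 4))
  pq <- count_pq(list(a = "AAAA", b = "GAAA"))
  expect_equal(pq$P, 0.25)   # one A<->G transition over 4 columns
  expect_equal(pq$Q, 0)
  pq2 <- count_pq(list(a = "A-CG", b = "AACG"))
  expect_equal(pq2$aligned_columns, 3)
  pq3 <- count_pq(list(a = "ANCG", b = "AACG"))
  expect_equal(pq3$aligned_columns, 3)
  # transversion: A<->C
  expect_equal(count_pq(list(a = "AAAA", b = "CAAA"))$Q, 0.25)
  expect_error(count_pq(list(a = "--", b = "AA")), "usable")
})

test_that("K2P distance matches the closed form and its domain guards", {
  expect_equal(k2p_distance(0, 0), 0)
  expect_equal(k2p_distance(0.1, 0.05),
               0.5 * log(1 / 0.75) + 0.25 * log(1 / 0.9))
  expect_equal(k2p_distance(0.1, 0.05), 0.170181, tolerance = 1e-6)
  expect_error(k2p_distance(0.5, 0.2), "saturated", class = "k2p_saturation")
  expect_error(k2p_distance(-0.1, 0), "non-negative")
  # monotone in P (Q fixed) and Q (P fixed); K >= P + Q on a domain grid
  for (P in seq(0, 0.3, 0.05)) for (Q in seq(0, 0.2, 0.05)) {
    if (1 - 2 * P - Q <= 0.05) next
    K <- k2p_distance(P, Q)
    expect_gte(K, P + Q - 1e-12)
    expect_gt(k2p_distance(P + 0.01, Q), K)
    expect_gt(k2p_distance(P, Q + 0.01), K)
  }
})

test_that("divergence time follows T = K/(2r) with a K/r mode", {
  expect_equal(divergence_time(0), 0)
  expect_equal(divergence_time(0.0256, 1.28e-8), 1e6)
  expect_equal(divergence_time(0.1, 1.28e-8 / 2),
               2 * divergence_time(0.1, 1.28e-8))
  expect_equal(divergence_time(0.0256, 1.28e-8, mode = "one_lineage"), 2e6)
  expect_error(divergence_time(Inf), "finite")
  expect_error(divergence_time(0.1, 0), "rate")
})

test_that("unit dating on a toy genome recovers the planted divergence", {
  toy <- make_toy_genome(seed = 23, n_hervh_units = 6, k_true = 0.05,
                         n_lnc = 0, n_coding = 0)
  units <- find_full_length_units(toy$repeats)
  expect_equal(nrow(units), 6)
  rep1 <- date_ltr_units(units, toy$genome)
  expect_true(all(rep1$flag == "ok"))
  expect_lt(abs(mean(rep1$K) - 0.05), 0.02)
  expect_equal(rep1$T_years, rep1$K / (2 * 1.28e-8))
  # byte-identical report on re-run
  rep2 <- date_ltr_units(units, toy$genome)
  expect_identical(rep1, rep2)
})

test_that("group comparison returns the exact Mann-Whitney p on tiny fixtures", {
  r <- compare_divergence_groups(c(1, 2, 3, 4, 5, 6), c(10, 9, 8, 3, 2, 1),
                                 top_n = 3)
  # top group (ranking 10,9,8) has times 1,2,3 vs bottom 4,5,6: U = 0,
  # exact two-sided p = 2 * 1/C(6,3) * ... = 0.1
  expect_equal(r$p, 0.1)
  expect_equal(r$statistic, 0)
  expect_equal(r$median_top, 2)
  expect_equal(r$median_bottom, 5)
  expect_equal(r$test, "mann_whitney")
  # identical groups: p = 1
  same <- compare_divergence_groups(rep(7, 20), 1:20, top_n = 5)
  expect_equal(same$p, 1)
  expect_error(compare_divergence_groups(1:5, 1:5, top_n = 3),
               "at least 6")
  # alternative tests are recorded
  expect_equal(compare_divergence_groups(1:6, 6:1, top_n = 3,
                                         test = "ks")$test, "ks")
})
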