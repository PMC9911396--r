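test_that("demultiplexing assigns unique matches within budget, ties go unassigned", {
  bc <- c(s1 = "AAAAAA", s2 = "TTTTTT")
  reads <- c(exact = "AAAAAAGGGG",       # distance 0 from s1
             two_mm = "AACCAAGGGG",      # distance 2 from s1
             three_mm = "AACCCAGGGG",    # distance 3 from both
             tie = "AAATTTGGGG")         # distance 3 from both -> unassigned
  d <- demultiplex(reads, bc, max_mismatch = 2)
  expect_setequal(names(d$assigned$s1), c("exact", "two_mm"))
  expect_length(d$assigned$s2, 0)
  expect_setequal(names(d$unassigned), c("three_mm", "tie"))
  # a read within the budget of BOTH barcodes is unassigned
  bc2 <- c(a = "AAAAAA", b = "AAAATT")
  r <- c(mid = "AAAAATGGGG")  # distance 1 from both
  expect_equal(hamming_distance(substr(r, 1, 6), bc2[["a"]]), 1)
  expect_equal(hamming_distance(substr(r, 1, 6), bc2[["b"]]), 1)
  d2 <- demultiplex(r, bc2, max_mismatch = 2)
  expect_length(d2$unassigned, 1)
  expect_error(demultiplex(reads, c(x = "AAAAAA", y = "AAAAAA")), "duplicate")
})

test_that("trim_reads removes exactly n bases and drops short reads", {
  r <- c(a = strrep("A", 150), b = strrep("C", 11), c = strrep("G", 12))
  out <- trim_reads(r, n = 11)
  expect_equal(nchar(out[["a"]]), 139)
  expect_false("b" %in% names(out))
  expect_equal(nchar(out[["c"]]), 1)
  expect_equal(attr(out, "n_dropped"), 1)
  empty <- trim_reads(character(0))
  expect_length(empty, 0)
})

test_that("TSS clustering follows the greedy merge rule by hand", {
  pos <- data.frame(chrom = "c", pos = c(rep(100, 5), rep(105, 3)),
                    strand = "+")
  pk <- call_tss_clusters(pos, merge_window = 20)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$read_support, 8)
  expect_equal(pk$mode_position, 100)
  expect_equal(c(pk$start, pk$end), c(100, 106))
  # beyond the window: two peaks
  pk2 <- call_tss_clusters(data.frame(chrom = "c", pos = c(100, 150),
                                      strand = "+"), merge_window = 20)
  expect_equal(nrow(pk2), 2)
  # chained positions each within window merge into one cluster
  pk3 <- call_tss_clusters(data.frame(chrom = "c", pos = c(100, 115, 130),
                                      strand = "+"), merge_window = 20)
  expect_equal(nrow(pk3), 1)
  # opposite strands never merge
  pk4 <- call_tss_clusters(data.frame(chrom = "c", pos = c(100, 100),
                                      strand = c("+", "-")))
  expect_equal(nrow(pk4), 2)
  # mode tie broken to the left
  pk5 <- call_tss_clusters(data.frame(chrom = "c", pos = c(100, 100, 105, 105),
                                      strand = "+"))
  expect_equal(pk5$mode_position, 100)
})

test_that("peak support filter applies the >= 30 boundary exactly", {
  pk <- data.frame(chrom = "c", start = c(0, 100, 200),
                   end = c(10, 110, 210), strand = "+",
                   mode_position = c(5, 105, 205),
                   read_support = c(29, 30, 31))
  kept <- filter_peaks(pk, min_reads = 30)
  expect_equal(kept$read_support, c(30, 31))
  expect_equal(attr(kept, "n_removed"), 1)
  expect_equal(nrow(filter_peaks(pk, min_reads = 100)), 0)
  expect_equal(nrow(filter_peaks(pk, min_reads = 1)), 3)
})

test_that("peak annotation applies the <1 kb TSS rule then category priority", {
  ann <- data.frame(
    chrom = "c", start = c(10000, 10000, 10000, 14700, 12000),
    end = c(15000, 15000, 10500, 15000, 12500), strand = "+",
    feature_kind = c("gene", "transcript", "exon", "exon",
                     "three_prime_utr"),
    gene_id = "g", transcript_id = c(NA, "t", "t", "t", "t"),
    biotype = "protein_coding")
  mk <- function(p) data.frame(chrom = "c", start = p, end = p + 10,
                               strand = "+", mode_position = p,
                               read_support = 50)
  expect_equal(annotate_peaks(mk(10500), ann)$category, "TSS")  # 500 bp away
  expect_equal(annotate_peaks(mk(10500), ann)$distance_to_tss, 500)
  expect_equal(annotate_peaks(mk(13000), ann)$category, "intronic")
  expect_equal(annotate_peaks(mk(12100), ann)$category, "three_prime_utr")
  expect_equal(annotate_peaks(mk(14800), ann)$category, "exonic")
  # upstream within 1 kb, negative distance
  a <- annotate_peaks(mk(9500), ann)
  expect_equal(a$category, "TSS")
  expect_equal(a$distance_to_tss, -500)
  # a chromosome with no genes is intergenic
  far <- data.frame(chrom = "other", start = 5, end = 15, strand = "+",
                    mode_position = 5, read_support = 50)
  expect_equal(annotate_peaks(far, ann)$category, "intergenic")
})

test_that("promoter windows follow the 250/50 convention on both strands", {
  set.seed(9)
  genome <- c(z = random_dna_str(3000))
  plus <- data.frame(chrom = "z", strand = "+", mode_position = 1000)
  pw <- extract_promoters(plus, genome)
  expect_equal(c(pw$start, pw$end), c(750, 1050))
  expect_equal(nchar(pw$sequence), 300)
  expect_false(pw$clipped)
  minus <- data.frame(chrom = "z", strand = "-", mode_position = 1000)
  mw <- extract_promoters(minus, genome)
  expect_equal(c(mw$start, mw$end), c(951, 1251))
  expect_equal(mw$sequence, reverse_complement(
    extract_sequence(genome, gintervals("z", 951, 1251, "+"))))
  # TSS base is inside both windows
  expect_true(pw$start <= 1000 && 1000 < pw$end)
  expect_true(mw$start <= 1000 && 1000 < mw$end)
  # clipping near the chromosome edge
  edge <- extract_promoters(data.frame(chrom = "z", strand = "+",
                                       mode_position = 100), genome)
  expect_true(edge$clipped)
  expect_equal(edge$start, 0)
})

test_that("promoter extraction is strand-flip symmetric", {
  set.seed(10)
  genome <- c(z = random_dna_str(2000))
  L <- 2000
  flipped <- c(z = reverse_complement(genome[["z"]]))
  for (t in c(500, 777, 1300)) {
    for (st in c("+", "-")) {
      orig <- extract_promoters(
        data.frame(chrom = "z", strand = st, mode_position = t), genome)
      mirr <- extract_promoters(
        data.frame(chrom = "z", strand = if (st == "+") "-" else "+",
                   mode_position = L - 1 - t), flipped)
      expect_equal(mirr$sequence, orig$sequence)
    }
  }
})

test_that("stage-specific peaks are those with no cross-stage overlap", {
  a <- data.frame(chrom = "c", start = c(0, 1000), end = c(100, 1100),
                  strand = "+", mode_position = c(50, 1050),
                  read_support = c(40, 40))
  b <- data.frame(chrom = "c", start = 1050, end = 1150, strand = "+",
                  mode_position = 1100, read_support = 40)
  sp <- stage_specific_peaks(list(A = a, B = b))
  expect_equal(sp$A$start, 0)           # peak 2 overlaps a B peak
  expect_equal(nrow(sp$B), 0)
  # identical stages share everything: nothing specific
  sp2 <- stage_specific_peaks(list(A = a, B = a))
  expect_equal(nrow(sp2$A), 0)
  expect_error(stage_specific_peaks(list(A = a)), "two stages")
})

test_that("motif enrichment reproduces the exact hypergeometric example", {
  consensus <- "TGACGTCA"
  m <- matrix(0.01 / 3, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in 1:8) m[substr(consensus, j, j), j] <- 0.99
  p1 <- pwm("motif1", m)
  set.seed(3)
  fg <- vapply(1:10, function(i)
    paste0(random_dna_str(20), consensus, random_dna_str(20)), character(1))
  bg <- vapply(1:10, function(i) random_dna_str(48), character(1))
  res <- motif_enrichment(fg, bg, list(p1))
  expect_equal(res$fg_hits, 10)
  expect_equal(res$bg_hits, 0)
  # two-sided Fisher p for [[10,0],[0,10]] = 2 / C(20,10); the one-sided
  # tail is 1 / C(20,10) = 5.41e-6
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(res$significant)
  # fg = bg (mixed hits and misses): odds ratio 1, p = 1
  mixed <- c(fg[1:6], bg[1:4])
  res2 <- motif_enrichment(mixed, mixed, list(p1))
  expect_equal(res2$p, 1)
  expect_equal(res2$odds_ratio, 1, tolerance = 1e-6)
  expect_false(res2$significant)
})

test_that("degenerate single-base PWM hits every sequence containing the base", {
  m <- matrix(c(1e-9, 1e-9, 1 - 3e-9, 1e-9), 4, 1,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  pg <- pwm("justG", m)
  res <- motif_enrichment(c("AAAGAAA", "GGGG"), c("AAAA", "TTTT"), list(pg))
  expect_equal(res$fg_hits, 2)
  # reverse-strand scanning: C is a hit for the G motif
  expect_equal(res$bg_hits, 0)
  res2 <- motif_enrichment(c("AACAA"), c("TTTT"), list(pg))
  expect_equal(res2$fg_hits, 1)
})

test_that("Fisher p agrees with hypergeometric enumeration on small tables", {
  set.seed(4)
  for (i in 1:20) {
    n_fg <- sample(3:15, 1); n_bg <- sample(3:15, 1)
    k_fg <- sample(0:n_fg, 1); k_bg <- sample(0:n_bg, 1)
    tab <- matrix(c(k_fg, n_fg - k_fg, k_bg, n_bg - k_bg), 2)
    got <- stats::fisher.test(tab)$p.value
    # enumerate all tables with fixed margins; two-sided p = sum of
    # probabilities <= that of the observed table
    K <- k_fg + k_bg
    xs <- max(0, K - n_bg):min(K, n_fg)
    probs <- stats::dhyper(xs, n_fg, n_bg, K)
    want <- sum(probs[probs <= stats::dhyper(k_fg, n_fg, n_bg, K) *
                        (1 + 1e-7)])
    expect_equal(got, want, tolerance = 1e-7)
  }
})

test_that("BH q-values are monotone in rank order and at least p", {
  consensus <- c("TGACGTCA", "AAAATTTT", "GCGCGCGC")
  pwms <- lapply(seq_along(consensus), function(k) {
    m <- matrix(0.01 / 3, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in 1:8) m[substr(consensus[k], j, j), j] <- 0.99
    pwm(paste0("m", k), m)
  })
  set.seed(6)
  fg <- c(vapply(1:8, function(i)
    paste0(random_dna_str(5), consensus[1], random_dna_str(5)),
    character(1)), random_dna_str(18))
  bg <- vapply(1:9, function(i) random_dna_str(18), character(1))
  res <- motif_enrichment(fg, bg, pwms)
  expect_true(all(res$q >= res$p - 1e-12))
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-12))
})

test_that("JASPAR-style motif files parse into valid PWMs", {
  tf <- withr::local_tempfile()
  writeLines(c(">MA0001.1 TEST",
               "A [ 10  0  5 ]",
               "C [  0 10  5 ]",
               "G [  0  0  5 ]",
               "T [  0  0  5 ]"), tf)
  ps <- read_jaspar_pwms(tf)
  expect_length(ps, 1)
  expect_equal(colSums(ps[[1]]$matrix), rep(1, 3), ignore_attr = TRUE)
  expect_equal(ps[[1]]$name, "MA0001.1 TEST")
})
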