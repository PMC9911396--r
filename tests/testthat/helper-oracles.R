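# Independent brute-force oracles used to validate the fast implementations.

# all-pairs interval overlap scan
brute_overlap <- function(query, subject) {
  out <- list()
  for (i in seq_len(nrow(query))) for (j in seq_len(nrow(subject))) {
    if (query$chrom[i] != subject$chrom[j]) next
    ov <- min(query$end[i], subject$end[j]) -
      max(query$start[i], subject$start[j])
    if (ov >= 1)
      out[[length(out) + 1L]] <- data.frame(query = i, subject = j,
                                            overlap_bp = ov)
  }
  if (!length(out))
    return(data.frame(query = integer(0), subject = integer(0),
                      overlap_bp = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$query, res$subject), ]
}

# KS statistic by scanning every candidate threshold
brute_ks_D <- function(x, y) {
  max(vapply(c(x, y), function(t)
    abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# per-base membership scan for the base-pair overlap ratio
brute_A_ratio <- function(peaks, features, chrom_sizes) {
  in_feat <- 0; total <- 0
  for (i in seq_len(nrow(peaks))) {
    for (b in seq(peaks$start[i], peaks$end[i] - 1)) {
      total <- total + 1
      hit <- any(features$chrom == peaks$chrom[i] &
                   features$start <= b & b < features$end)
      if (hit) in_feat <- in_feat + 1
    }
  }
  in_feat / total
}

# exhaustive global alignment score with affine gaps: a length-L gap costs
# -(gap_open) - L * (-gap_extend); explores every alignment path
brute_align_score <- function(a, b, match = 1, mismatch = -1,
                              gap_open = -5, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "diag"))
    }
    if (i <= length(av)) {  # gap in b
      pen <- if (state == "gap_b") gap_extend else gap_open + gap_extend
      best <- max(best, pen + rec(i + 1, j, "gap_b"))
    }
    if (j <= length(bv)) {  # gap in a
      pen <- if (state == "gap_a") gap_extend else gap_open + gap_extend
      best <- max(best, pen + rec(i, j + 1, "gap_a"))
    }
    best
  }
  rec(1, 1, "diag")
}

random_intervals <- function(n, chroms = c("c1", "c2"), max_pos = 1000,
                             max_len = 60) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  gintervals(sample(chroms, n, replace = TRUE), start, start + len,
             sample(c("+", "-", "."), n, replace = TRUE))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
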