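#' Detect full-length LTR7-HERVH-int-LTR7 units
#'
#' Scans each chromosome and strand for maximal runs LTR7, one or more
#' HERVH-int fragments (merged into a single internal interval), LTR7, with
#' consecutive segments separated by at most `gap_tolerance` bp. Solo LTRs
#' are never reported.
#'
#' @param repeats Repeat interval table with `subfamily` (values `LTR7` /
#'   `HERVH-int` are used) and `strand`.
#' @param gap_tolerance Maximum gap between consecutive segments, default
#'   100 bp.
#' @return Unit table: `unit_id`, `chrom`, `strand`, segment coordinates
#'   (`ltr5_*`, `int_*`, `ltr3_*`).
#' @export
find_full_length_units <- function(repeats, gap_tolerance = 100) {
  validate_intervals(repeats)
  rel <- repeats[repeats$subfamily %in% c("LTR7", "HERVH-int"), ,
                 drop = FALSE]
  cols <- c("unit_id", "chrom", "strand", "ltr5_start", "ltr5_end",
            "int_start", "int_end", "ltr3_start", "ltr3_end")
  empty <- stats::setNames(
    data.frame(character(0), character(0), character(0), numeric(0),
               numeric(0), numeric(0), numeric(0), numeric(0), numeric(0),
               stringsAsFactors = FALSE), cols)
  if (!nrow(rel)) return(empty)
  units <- list()
  for (key in unique(paste(rel$chrom, rel$strand))) {
    sub <- rel[paste(rel$chrom, rel$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    i <- 1
    while (i <= nrow(sub)) {
      if (sub$subfamily[i] != "LTR7") { i <- i + 1; next }
      # candidate 5' LTR; collect adjacent internal fragments
      j <- i + 1
      int_start <- NA; int_end <- NA; prev_end <- sub$end[i]
      while (j <= nrow(sub) && sub$subfamily[j] == "HERVH-int" &&
             sub$start[j] - prev_end <= gap_tolerance) {
        if (is.na(int_start)) int_start <- sub$start[j]
        int_end <- sub$end[j]
        prev_end <- sub$end[j]
        j <- j + 1
      }
      if (!is.na(int_start) && j <= nrow(sub) &&
          sub$subfamily[j] == "LTR7" &&
          sub$start[j] - prev_end <= gap_tolerance) {
        units[[length(units) + 1L]] <- data.frame(
          unit_id = sprintf("flu_%s_%d", sub$chrom[1], sub$start[i]),
          chrom = sub$chrom[1], strand = sub$strand[1],
          ltr5_start = sub$start[i], ltr5_end = sub$end[i],
          int_start = int_start, int_end = int_end,
          ltr3_start = sub$start[j], ltr3_end = sub$end[j],
          stringsAsFactors = FALSE)
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
  }
  if (!length(units)) return(empty)
  out <- do.call(rbind, units)
  rownames(out) <- NULL
  out
}

#' Global pairwise alignment of two LTR sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1, and affine
#' gaps costing `gap_open` plus `gap_extend` per gapped position (defaults
#' -5 and -1, i.e. a length-1 gap costs 6). Backed by the dynamic
#' programming engine of `Biostrings::pairwiseAlignment`.
#'
#' @param a,b Non-empty sequences over `{A,C,G,T,N}`.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return List: gapped strings `a` and `b` (equal length) and the
#'   alignment `score`.
#' @export
align_pair <- function(a, b, match = 1, mismatch = -1, gap_open = -5,
                       gap_extend = -1) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = -gap_open, gapExtension = -gap_extend)
  list(a = as.character(Biostrings::alignedPattern(al)),
       b = as.character(Biostrings::alignedSubject(al)),
       score = Biostrings::score(al))
}

.PURINES <- c("A", "G")

#' Count transition and transversion proportions in an alignment
#'
#' Over alignment columns where both symbols are in `{A,C,G,T}` (gap and N
#' columns excluded from numerator and denominator): `P` is the proportion
#' of transition differences (A<->G, C<->T), `Q` the proportion of
#' transversion differences.
#'
#' @param alignment List with gapped strings `a` and `b` (as from
#'   [align_pair()]).
#' @return List: `P`, `Q`, `aligned_columns`.
#' @export
count_pq <- function(alignment) {
  a <- strsplit(alignment$a, "")[[1]]
  b <- strsplit(alignment$b, "")[[1]]
  if (length(a) != length(b)) stop("aligned strings differ in length")
  use <- a %in% .BASES & b %in% .BASES
  n <- sum(use)
  if (n == 0) stop("no usable (ungapped, non-N) alignment columns")
  a <- a[use]; b <- b[use]
  diff <- a != b
  ts <- diff & ((a %in% .PURINES) == (b %in% .PURINES))
  list(P = sum(ts) / n, Q = sum(diff & !ts) / n, aligned_columns = n)
}

#' Kimura two-parameter distance
#'
#' `K = 1/2 ln[1 / (1 - 2P - Q)] + 1/4 ln[1 / (1 - 2Q)]`, defined for
#' `2P + Q < 1` and `2Q < 1`. Outside that domain the pair is saturated and
#' the distance undefined; an error of class `k2p_saturation` is thrown so
#' callers can flag and exclude the pair.
#'
#' @param P,Q Transition and transversion proportions.
#' @return Distance `K` in substitutions per site.
#' @export
k2p_distance <- function(P, Q) {
  if (P < 0 || Q < 0) stop("P and Q must be non-negative")
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
    stop(structure(class = c("k2p_saturation", "error", "condition"),
                   list(message = sprintf(
                     "saturated pair (P = %.3f, Q = %.3f): K2P undefined",
                     P, Q), call = sys.call(-1))))
  0.5 * log(1 / (1 - 2 * P - Q)) + 0.25 * log(1 / (1 - 2 * Q))
}

#' Divergence time from a paired-LTR distance
#'
#' Default convention `T = K / (2 r)`: the two LTRs of one insertion
#' accumulate divergence along two independent lineages, so the per-lineage
#' divergence is `K / 2`. A single-lineage mode `T = K / r` is available
#' for sensitivity analysis.
#'
#' @param K K2P distance (substitutions/site), finite and >= 0.
#' @param rate Substitution rate per site per year, default 1.28e-8.
#' @param mode `"two_lineage"` (default, `K/(2r)`) or `"one_lineage"`
#'   (`K/r`).
#' @return Time in years.
#' @export
divergence_time <- function(K, rate = 1.28e-8,
                            mode = c("two_lineage", "one_lineage")) {
  mode <- match.arg(mode)
  if (any(!is.finite(K)) || any(K < 0)) stop("K must be finite and >= 0")
  if (rate <= 0) stop("rate must be > 0")
  if (mode == "two_lineage") K / (2 * rate) else K / rate
}

#' Date all full-length units of a genome
#'
#' For each unit: extract the two LTR sequences (strand-adjusted), align
#' them, count P and Q, apply the K2P correction and convert to years.
#' Saturated pairs are flagged (`flag = "saturated"`, `K` and `T_years`
#' `NA`) and should be excluded from downstream statistics.
#'
#' @param units Unit table (see [find_full_length_units()]).
#' @param genome Named chromosome sequences.
#' @param rate Substitution rate per site per year.
#' @param mode Time convention, see [divergence_time()].
#' @return Data frame: `unit_id`, `chrom`, `strand`, `aligned_columns`,
#'   `P`, `Q`, `K`, `T_years`, `flag`.
#' @export
date_ltr_units <- function(units, genome, rate = 1.28e-8,
                           mode = "two_lineage") {
  rows <- list()
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    ltr5 <- extract_sequence(
      genome, gintervals(u$chrom, u$ltr5_start, u$ltr5_end, u$strand))
    ltr3 <- extract_sequence(
      genome, gintervals(u$chrom, u$ltr3_start, u$ltr3_end, u$strand))
    al <- align_pair(ltr5, ltr3)
    pq <- count_pq(al)
    K <- tryCatch(k2p_distance(pq$P, pq$Q), k2p_saturation = function(e) NA)
    rows[[i]] <- data.frame(
      unit_id = u$unit_id, chrom = u$chrom, strand = u$strand,
      aligned_columns = pq$aligned_columns, P = pq$P, Q = pq$Q, K = K,
      T_years = if (is.na(K)) NA_real_
      else divergence_time(K, rate, mode),
      flag = if (is.na(K)) "saturated" else "ok", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare divergence times of top- versus bottom-ranked units
#'
#' Splits units into the `top_n` highest and `top_n` lowest by a ranking
#' value (expression level or fold change) and compares their divergence
#' times with a two-sided Mann-Whitney U test (exact for small samples
#' without ties, normal approximation with tie correction otherwise; KS and
#' Welch t alternatives are selectable and the test used is recorded).
#'
#' @param times Numeric divergence times (finite values only are used).
#' @param ranking Numeric ranking values aligned with `times`.
#' @param top_n Group size, default 200.
#' @param test `"mann_whitney"` (default), `"ks"` or `"t"`.
#' @return List: `statistic`, `p`, `median_top`, `median_bottom`, `test`,
#'   `top_n`.
#' @export
compare_divergence_groups <- function(times, ranking, top_n = 200,
                                      test = c("mann_whitney", "ks", "t")) {
  test <- match.arg(test)
  stopifnot(length(times) == length(ranking))
  ok <- is.finite(times) & is.finite(ranking)
  times <- times[ok]; ranking <- ranking[ok]
  if (length(times) < 2 * top_n)
    stop("need at least ", 2 * top_n, " dated units, got ", length(times))
  ord <- order(ranking, decreasing = TRUE)
  top <- times[ord[seq_len(top_n)]]
  bottom <- times[rev(ord)[seq_len(top_n)]]
  res <- switch(test,
    mann_whitney = {
      # ties force the normal approximation; the tie-corrected variant is
      # what wilcox.test falls back to, so its warning carries no signal
      h <- suppressWarnings(
        stats::wilcox.test(top, bottom, alternative = "two.sided"))
      # completely tied data leaves the normal approximation undefined;
      # there is then no evidence against the null
      list(statistic = unname(h$statistic),
           p = if (is.na(h$p.value)) 1 else h$p.value)
    },
    ks = {
      h <- ks_two_sample(top, bottom)
      list(statistic = h$D, p = h$p)
    },
    t = {
      h <- stats::t.test(top, bottom)
      list(statistic = unname(h$statistic), p = h$p.value)
    })
  c(res, list(median_top = stats::median(top),
              median_bottom = stats::median(bottom),
              test = test, top_n = top_n))
}
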