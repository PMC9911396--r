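#' Fraction of peak bases overlapping a feature class (A-ratio)
#'
#' Base-pair-weighted: the total number of peak bases intersecting the
#' merged feature, divided by the total peak bases. A peak-count-weighted
#' alternative (`mode = "count"`: fraction of peaks with any overlap) is
#' provided for comparison.
#'
#' @param peaks Interval table of peaks (non-empty).
#' @param features Interval table of the feature class; merged internally.
#' @param mode `"bp"` (default) or `"count"`.
#' @return A ratio in [0, 1].
#' @export
feature_overlap_ratio <- function(peaks, features, mode = c("bp", "count")) {
  mode <- match.arg(mode)
  validate_intervals(peaks)
  if (nrow(peaks) == 0) stop("empty peak set")
  feat <- merge_intervals(features)
  ov <- overlap_intervals(peaks, feat)
  if (mode == "count") return(length(unique(ov$query)) / nrow(peaks))
  sum(ov$overlap_bp) / sum(interval_width(peaks))
}

#' Fraction of the genome covered by a feature class (B-ratio)
#'
#' @param features Interval table; overlapping records are merged before
#'   measuring.
#' @param chrom_sizes Named vector of chromosome lengths in bp.
#' @return Covered fraction in (0, 1].
#' @export
genome_background_ratio <- function(features, chrom_sizes) {
  validate_intervals(features)
  if (nrow(features) == 0) stop("empty feature set: background undefined")
  unknown <- setdiff(unique(features$chrom), names(chrom_sizes))
  if (length(unknown)) stop("feature on unknown chromosome: ", unknown[1])
  over <- features$end > chrom_sizes[features$chrom]
  if (any(over))
    stop("feature extends beyond chromosome ",
         features$chrom[which(over)[1]])
  covered_bp(features) / sum(chrom_sizes)
}

#' Log2 enrichment score of peak overlap versus genomic background
#'
#' `score = log2(A / B)`. `A = 0` yields `-Inf` with the `a_zero` flag;
#' `B = 0` is an error (the background ratio must be positive).
#'
#' @param A_ratio,B_ratio Ratios from [feature_overlap_ratio()] and
#'   [genome_background_ratio()].
#' @return List with `score` and logical `a_zero`.
#' @export
enrichment_score <- function(A_ratio, B_ratio) {
  if (B_ratio <= 0) stop("B_ratio must be > 0")
  if (A_ratio < 0 || A_ratio > 1 || B_ratio > 1)
    stop("ratios must lie in [0, 1]")
  list(score = log2(A_ratio / B_ratio), a_zero = A_ratio == 0)
}

#' Permutation null for the peak enrichment score
#'
#' Each permutation re-places every peak uniformly at random on its original
#' chromosome, preserving peak lengths, and the enrichment score is
#' recomputed. The empirical p uses the add-one estimator
#' `(1 + #[perm >= observed]) / (n_perm + 1)`, which never returns 0.
#'
#' @param peaks Peak interval table.
#' @param chrom_sizes Named chromosome lengths.
#' @param features Feature interval table.
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return List: `observed` score, `perm_p`, `n_perm`, `perm_scores`.
#' @export
permutation_null <- function(peaks, chrom_sizes, features, n_perm = 999,
                             seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  validate_intervals(peaks)
  widths <- interval_width(peaks)
  lim <- chrom_sizes[peaks$chrom] - widths
  if (any(lim < 0)) stop("peak longer than its chromosome")
  feat <- merge_intervals(features)
  B <- genome_background_ratio(feat, chrom_sizes)
  total_bp <- sum(widths)
  # prefix-sum coverage per chromosome: overlap bp of [s, e) with the merged
  # feature is C(e) - C(s), each an O(log n) lookup
  cov_fns <- lapply(split(feat, feat$chrom), function(d) {
    f_s <- d$start; f_e <- d$end
    cum0 <- c(0, cumsum(f_e - f_s))
    function(x) {
      i <- findInterval(x, f_s)
      ip <- pmax(i, 1)
      ifelse(i == 0, 0, cum0[ip] + pmin(x, f_e[ip]) - f_s[ip])
    }
  })
  overlap_bp <- function(chrs, starts, ends) {
    tot <- 0
    for (chr in unique(chrs)) {
      f <- cov_fns[[chr]]
      if (is.null(f)) next
      sel <- chrs == chr
      tot <- tot + sum(f(ends[sel]) - f(starts[sel]))
    }
    tot
  }
  observed <- log2((overlap_bp(peaks$chrom, peaks$start, peaks$end) /
                      total_bp) / B)
  perm_scores <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    starts <- floor(stats::runif(nrow(peaks)) * (lim + 1))
    log2((overlap_bp(peaks$chrom, starts, starts + widths) / total_bp) / B)
  }, numeric(1)))
  perm_p <- (1 + sum(perm_scores >= observed)) / (n_perm + 1)
  list(observed = observed, perm_p = perm_p, n_perm = n_perm,
       perm_scores = perm_scores)
}

#' Full enrichment report for one peak set versus one feature class
#'
#' Convenience wrapper computing A-ratio, B-ratio, log2 score and the
#' permutation p in one call.
#'
#' @inheritParams permutation_null
#' @return One-row data frame: `A_ratio`, `B_ratio`, `score`, `perm_p`,
#'   `n_perm`.
#' @export
peak_feature_enrichment <- function(peaks, features, chrom_sizes,
                                    n_perm = 999, seed = 1) {
  A <- feature_overlap_ratio(peaks, features)
  B <- genome_background_ratio(merge_intervals(features), chrom_sizes)
  sc <- enrichment_score(A, B)
  pn <- permutation_null(peaks, chrom_sizes, features, n_perm, seed)
  data.frame(A_ratio = A, B_ratio = B, score = sc$score,
             perm_p = pn$perm_p, n_perm = n_perm)
}

#' Genomic category composition of a peak set
#'
#' Assigns each peak a single category from its midpoint (TSS/promoter,
#' three_prime_utr, exonic, intronic, intergenic; see [annotate_peaks()]),
#' so the per-category fractions sum to one.
#'
#' @param peaks Peak interval table.
#' @param annotation Gene annotation table.
#' @param tss_distance_bp TSS distance rule, default 1000.
#' @return List: `peaks` (annotated) and `fractions` (named, sums to 1).
#' @export
assign_peak_categories <- function(peaks, annotation,
                                   tss_distance_bp = 1000) {
  ann <- annotate_peaks(peaks, annotation, tss_distance_bp = tss_distance_bp,
                        at = "midpoint")
  tab <- table(factor(ann$category,
                      levels = c("TSS", "three_prime_utr", "exonic",
                                 "intronic", "intergenic")))
  frac <- stats::setNames(as.numeric(tab) / nrow(ann), names(tab))
  list(peaks = ann, fractions = frac)
}

#' Associate peaks with full-length HERVH units within a flank
#'
#' Mutually exclusive priority assignment: a peak overlapping an LTR7
#' segment is `on_LTR7`; else overlapping the internal segment,
#' `on_internal`; else within `flank` bp of either LTR7, `flank_10kb`; else
#' `unassociated`. Distance is the bp gap to the nearest LTR7 edge (0 for
#' overlaps).
#'
#' @param peaks Peak interval table (a `name` column is used as peak id).
#' @param units Unit table from [make_toy_genome()] /
#'   [find_full_length_units()]: columns `unit_id`, `chrom`, `ltr5_start`,
#'   `ltr5_end`, `int_start`, `int_end`, `ltr3_start`, `ltr3_end`.
#' @param flank Flank width in bp, default 10000.
#' @return Data frame: `peak`, `association`, `unit_id`, `distance`.
#' @export
associate_peaks_hervh <- function(peaks, units, flank = 10000) {
  validate_intervals(peaks)
  ids <- if ("name" %in% names(peaks)) peaks$name
  else paste0("peak_", seq_len(nrow(peaks)))
  gap <- function(ps, pe, fs, fe) {
    # bp gap between [ps,pe) and [fs,fe); 0 if overlapping
    pmax(0, pmax(fs - pe, ps - fe))
  }
  out <- data.frame(peak = ids, association = "unassociated",
                    unit_id = NA_character_, distance = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peaks))) {
    ps <- peaks$start[i]; pe <- peaks$end[i]; chrom <- peaks$chrom[i]
    u <- units[units$chrom == chrom, , drop = FALSE]
    if (!nrow(u)) next
    d_ltr <- pmin(gap(ps, pe, u$ltr5_start, u$ltr5_end),
                  gap(ps, pe, u$ltr3_start, u$ltr3_end))
    d_int <- gap(ps, pe, u$int_start, u$int_end)
    j <- which.min(d_ltr)
    if (d_ltr[j] == 0) {
      out$association[i] <- "on_LTR7"
    } else if (any(d_int == 0)) {
      j <- which(d_int == 0)[1]
    } else if (d_ltr[j] <= flank) {
      out$association[i] <- "flank_10kb"
    } else next
    if (out$association[i] == "unassociated")
      out$association[i] <- "on_internal"
    out$unit_id[i] <- u$unit_id[j]
    out$distance[i] <- d_ltr[j]
  }
  out
}
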