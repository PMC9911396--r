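#' Construct a count table
#'
#' The central expression container: a loci x samples matrix of raw counts
#' plus locus metadata (repeat class/family/subfamily) and sample metadata
#' (condition, replicate). Modelled on the matrix-plus-annotation layout of
#' standard RNA-seq containers.
#'
#' @param counts Integer matrix, loci in rows, samples in columns.
#' @param loci Data frame with at least `locus_id`; typically also `class`,
#'   `family`, `subfamily`.
#' @param samples Data frame with `sample_id`, `condition`
#'   (`"control"`/`"knockdown"`) and `replicate`.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, loci, samples) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == nrow(loci), ncol(counts) == nrow(samples),
            "locus_id" %in% names(loci), "sample_id" %in% names(samples),
            "condition" %in% names(samples))
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  rownames(counts) <- loci$locus_id
  colnames(counts) <- samples$sample_id
  structure(list(counts = counts, loci = as.data.frame(loci),
                 samples = as.data.frame(samples), cpm = NULL),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "loci x", ncol(x$counts), "samples\n")
  cat("conditions:", paste(table(x$samples$condition), collapse = " / "),
      "\n")
  invisible(x)
}

#' Quantify fragments over repeat loci
#'
#' Counts, per sample, the fragments overlapping each locus by at least 1 bp
#' (any-overlap rule); a fragment spanning k loci increments all k. With
#' `unique_assignment = TRUE` a fragment counts only toward the locus with
#' the largest overlap (first by position on tie).
#'
#' @param fragments Named list (one element per sample) of interval tables.
#' @param loci Interval table of repeat loci with `locus_id` (and class /
#'   family / subfamily metadata carried through).
#' @param samples Optional sample data frame; defaults to all-control.
#' @param unique_assignment Single-assignment mode, default `FALSE`.
#' @return A `count_table` of raw counts.
#' @export
quantify_repeats <- function(fragments, loci, samples = NULL,
                             unique_assignment = FALSE) {
  validate_intervals(loci)
  counts <- matrix(0L, nrow(loci), length(fragments))
  for (s in seq_along(fragments)) {
    ov <- overlap_intervals(fragments[[s]], loci)
    if (unique_assignment && nrow(ov)) {
      ov <- ov[order(ov$query, -ov$overlap_bp, ov$subject), ]
      ov <- ov[!duplicated(ov$query), ]
    }
    if (nrow(ov)) {
      tab <- table(factor(ov$subject, levels = seq_len(nrow(loci))))
      counts[, s] <- as.integer(tab)
    }
  }
  nm <- names(fragments)
  if (is.null(nm)) nm <- paste0("sample_", seq_along(fragments))
  if (is.null(samples))
    samples <- data.frame(sample_id = nm, condition = "control",
                          replicate = seq_along(fragments))
  meta <- loci[, intersect(c("locus_id", "class", "family", "subfamily"),
                           names(loci)), drop = FALSE]
  count_table(counts, meta, samples)
}

#' Fill counts-per-million normalization
#'
#' `cpm[i, s] = raw[i, s] / total[s] * 1e6`; each sample's CPM column sums
#' to one million.
#'
#' @param ct A `count_table`.
#' @return The table with its `cpm` matrix filled.
#' @export
cpm_normalize <- function(ct) {
  stopifnot(inherits(ct, "count_table"))
  totals <- colSums(ct$counts)
  zero <- which(totals == 0)
  if (length(zero))
    stop("sample '", colnames(ct$counts)[zero[1]], "' has zero total count")
  ct$cpm <- sweep(ct$counts, 2, totals, "/") * 1e6
  ct
}

#' Per-locus log2 fold change from mean CPM
#'
#' `log2((mean knockdown CPM + c) / (mean control CPM + c))` with
#' pseudocount `c`; the pseudocount keeps the ratio finite for loci with
#' zero counts and cancels exactly when both means are zero.
#'
#' @param ct A `count_table` with control and knockdown samples.
#' @param pseudocount Pseudocount `c`, default 0.5 CPM.
#' @return Named numeric vector of log2 fold changes, one per locus.
#' @export
log2_fold_change <- function(ct, pseudocount = 0.5) {
  stopifnot(inherits(ct, "count_table"))
  if (is.null(ct$cpm)) ct <- cpm_normalize(ct)
  ctrl <- ct$samples$condition == "control"
  kd <- ct$samples$condition == "knockdown"
  if (!any(ctrl) || !any(kd))
    stop("need at least one control and one knockdown sample")
  m_ctrl <- rowMeans(ct$cpm[, ctrl, drop = FALSE])
  m_kd <- rowMeans(ct$cpm[, kd, drop = FALSE])
  stats::setNames(log2((m_kd + pseudocount) / (m_ctrl + pseudocount)),
                  ct$loci$locus_id)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic `D` is the supremum over thresholds of the absolute
#' difference of the two empirical CDFs. The two-sided p-value uses exact
#' enumeration (via the Smirnov distribution, tie-aware) when
#' `n1 + n2 <= 20`, and otherwise the asymptotic Kolmogorov series at
#' effective sample size `n1 n2 / (n1 + n2)`.
#'
#' @param x,y Numeric vectors (at least one observation each).
#' @return List with `D`, `p`, `n1`, `n2`, `method`.
#' @export
ks_two_sample <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  z <- sort(unique(c(x, y)))
  Fx <- findInterval(z, sort(x)) / n1
  Fy <- findInterval(z, sort(y)) / n2
  D <- max(abs(Fx - Fy))
  if (n1 + n2 <= 20) {
    p <- stats::psmirnov(D, sizes = c(n1, n2), z = c(x, y),
                         two.sided = TRUE, lower.tail = FALSE)
    method <- "exact"
  } else {
    p <- ks_asymptotic_p(D, n1, n2)
    method <- "asymptotic"
  }
  list(D = D, p = min(max(p, 0), 1), n1 = n1, n2 = n2, method = method)
}

#' Asymptotic two-sided Kolmogorov-Smirnov p-value
#'
#' Kolmogorov limiting series `2 sum_k (-1)^(k-1) exp(-2 k^2 t^2)` with
#' `t = sqrt(n1 n2 / (n1 + n2)) D`.
#'
#' @param D Observed statistic.
#' @param n1,n2 Sample sizes.
#' @return p-value in [0, 1].
#' @export
ks_asymptotic_p <- function(D, n1, n2) {
  ne <- n1 * n2 / (n1 + n2)
  t <- sqrt(ne) * D
  if (t < 1e-8) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, 0), 1)
}

#' Standard retrotransposon group definitions
#'
#' Builds the locus groupings used throughout the fold-change comparisons:
#' repeat classes (LINE, SINE, LTR), the ERV1 family, the LTR7/HERVH
#' subfamily pair, MER subfamilies within ERV1, and the remaining ("other")
#' ERV1 members.
#'
#' @param loci Locus metadata with `class`, `family`, `subfamily`.
#' @return Named list of logical vectors over the loci.
#' @export
repeat_groups <- function(loci) {
  hervh <- loci$subfamily %in% c("LTR7", "HERVH-int")
  erv1 <- loci$family == "ERV1"
  mers <- erv1 & grepl("^MER", loci$subfamily)
  list(
    LINE = loci$class == "LINE",
    SINE = loci$class == "SINE",
    LTR = loci$class == "LTR",
    ERV1 = erv1,
    `LTR7/HERVH` = hervh,
    MERs = mers,
    `other-ERV1` = erv1 & !hervh & !mers)
}

#' KS scan of fold-change distributions per retrotransposon group
#'
#' Compares each group's log2 fold-change distribution against a reference:
#' either `"background"` (all loci outside the group) or `"MERs"` (the MER
#' subfamilies of ERV1). Loci belonging to both a group and its reference
#' are excluded from the group side so the two samples are disjoint;
#' comparing a group against itself is an error.
#'
#' @param log2fc Named numeric vector of per-locus log2 fold changes.
#' @param loci Locus metadata aligned with `log2fc`.
#' @param groups Character vector of group names (see [repeat_groups()]);
#'   default all.
#' @param reference `"background"` or `"MERs"`.
#' @return Data frame: `group`, `reference`, `D`, `p`, `n1`, `n2`.
#' @export
subfamily_ks_scan <- function(log2fc, loci,
                              groups = c("LINE", "SINE", "LTR", "ERV1",
                                         "LTR7/HERVH", "MERs", "other-ERV1"),
                              reference = c("background", "MERs")) {
  reference <- match.arg(reference)
  stopifnot(length(log2fc) == nrow(loci))
  defs <- repeat_groups(loci)
  rows <- list()
  for (g in groups) {
    if (!g %in% names(defs)) stop("unknown group: ", g)
    sel <- defs[[g]]
    ref_sel <- if (reference == "background") !sel else defs$MERs
    if (reference == "MERs") {
      if (identical(which(sel), which(ref_sel)))
        stop("group '", g, "' is identical to its reference; ",
             "self-comparison is not defined")
      sel <- sel & !ref_sel
    }
    if (!any(sel) || !any(ref_sel)) {
      warning("group '", g, "' or its reference is empty; skipped")
      next
    }
    ks <- ks_two_sample(log2fc[sel], log2fc[ref_sel])
    rows[[g]] <- data.frame(group = g, reference = reference, D = ks$D,
                            p = ks$p, n1 = ks$n1, n2 = ks$n2,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation of fold changes across two perturbations
#'
#' @param log2fc_a,log2fc_b Named log2 fold-change vectors from two
#'   experiments sharing locus ids.
#' @param subset Optional character vector of locus ids to restrict to
#'   (e.g. the ERV1 loci).
#' @return List with `R`, `p` (two-sided, t-distribution), `n`.
#' @export
cross_kd_correlation <- function(log2fc_a, log2fc_b, subset = NULL) {
  shared <- intersect(names(log2fc_a), names(log2fc_b))
  if (!is.null(subset)) shared <- intersect(shared, subset)
  if (length(shared) < 3) stop("need at least 3 shared loci")
  a <- log2fc_a[shared]; b <- log2fc_b[shared]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant fold-change vector; correlation undefined")
  ct <- stats::cor.test(a, b, method = "pearson")
  list(R = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Find lncRNAs overlapping LTR7/HERVH loci
#'
#' Reports one pair per (lncRNA gene, HERVH unit) with >= 1 bp overlap
#' between the gene interval and any LTR7 or HERVH-int locus of the unit.
#' Overlap is strand-agnostic by default since HERVH can drive sense or
#' antisense transcripts.
#'
#' @param genes Annotation table (as from [read_gtf()]); rows with
#'   `feature_kind == "gene"` and `biotype == "lncRNA"` are used.
#' @param repeats Repeat interval table with `subfamily` and (optionally)
#'   `unit_id`; loci lacking a unit id are treated as their own unit.
#' @param strand_matched Require identical strand, default `FALSE`.
#' @return Data frame of pairs: `gene_id`, `unit_id`.
#' @export
lncrna_hervh_overlap <- function(genes, repeats, strand_matched = FALSE) {
  lnc <- genes[genes$feature_kind == "gene" & genes$biotype == "lncRNA", ,
               drop = FALSE]
  hervh <- repeats[repeats$subfamily %in% c("LTR7", "HERVH-int"), ,
                   drop = FALSE]
  if (!nrow(lnc) || !nrow(hervh))
    return(data.frame(gene_id = character(0), unit_id = character(0)))
  unit <- if ("unit_id" %in% names(hervh)) hervh$unit_id else NA
  unit <- ifelse(is.na(unit), hervh$locus_id, unit)
  ov <- overlap_intervals(lnc, hervh, strand_matched = strand_matched)
  if (!nrow(ov))
    return(data.frame(gene_id = character(0), unit_id = character(0)))
  pairs <- unique(data.frame(gene_id = lnc$gene_id[ov$query],
                             unit_id = unit[ov$subject],
                             stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  pairs
}

#' Filter lncRNAs by expression level
#'
#' Retains genes whose mean CPM over control replicates is strictly greater
#' than the threshold.
#'
#' @param ct A `count_table` whose rows are lncRNA genes.
#' @param threshold CPM cutoff, default 1 (strictly greater than).
#' @return Character vector of retained locus ids.
#' @export
expressed_lncrna_filter <- function(ct, threshold = 1) {
  stopifnot(inherits(ct, "count_table"))
  if (is.null(ct$cpm)) ct <- cpm_normalize(ct)
  ctrl <- ct$samples$condition == "control"
  m <- rowMeans(ct$cpm[, ctrl, drop = FALSE])
  ct$loci$locus_id[m > threshold]
}

#' Pool segment counts into per-unit counts
#'
#' Sums counts of all loci belonging to the same full-length unit (LTR7 +
#' HERVH-int segments), yielding a unit-level count table whose fold change
#' reflects the whole element.
#'
#' @param ct A `count_table` whose loci carry a `unit_id` column.
#' @return A `count_table` with one row per unit.
#' @export
pool_unit_counts <- function(ct) {
  stopifnot(inherits(ct, "count_table"), "unit_id" %in% names(ct$loci))
  keep <- !is.na(ct$loci$unit_id)
  u <- ct$loci$unit_id[keep]
  pooled <- rowsum(ct$counts[keep, , drop = FALSE], group = u)
  loci <- data.frame(locus_id = rownames(pooled), stringsAsFactors = FALSE)
  count_table(pooled, loci, ct$samples)
}

#' Correlate HERVH-unit and overlapping-lncRNA fold changes
#'
#' Pearson correlation between the log2 fold change of each HERVH unit
#' (counts pooled over its segments) and that of its overlapping lncRNA,
#' over a supplied pair list.
#'
#' @param pairs Data frame with `gene_id`, `unit_id` (see
#'   [lncrna_hervh_overlap()]).
#' @param unit_log2fc Named vector of per-unit log2 fold changes.
#' @param lnc_log2fc Named vector of per-lncRNA log2 fold changes.
#' @return List with `R`, `p`, `n` and the per-pair data frame `table`.
#' @export
hervh_lncrna_correlation <- function(pairs, unit_log2fc, lnc_log2fc) {
  keep <- pairs$unit_id %in% names(unit_log2fc) &
    pairs$gene_id %in% names(lnc_log2fc)
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) < 3) stop("need at least 3 pairs with fold changes")
  x <- unit_log2fc[pairs$unit_id]
  y <- lnc_log2fc[pairs$gene_id]
  ct <- stats::cor.test(x, y, method = "pearson")
  list(R = unname(ct$estimate), p = ct$p.value, n = nrow(pairs),
       table = data.frame(gene_id = pairs$gene_id, unit_id = pairs$unit_id,
                          unit_log2fc = unname(x), lnc_log2fc = unname(y)))
}
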