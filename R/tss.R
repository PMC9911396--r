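#' Hamming distance between equal-length strings
#'
#' @param a,b Strings of equal length.
#' @return Number of mismatching positions.
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("strings must have equal length")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Demultiplex barcoded reads
#'
#' A read is assigned to a barcode when that barcode is the only one within
#' `max_mismatch` Hamming distance of the read prefix. If no barcode
#' qualifies, or more than one does (including exact ties), the read goes to
#' the unassigned bin — the conservative rule that avoids sample
#' bleed-through.
#'
#' @param reads Named character vector of read sequences.
#' @param barcodes Named character vector of equal-length barcodes.
#' @param max_mismatch Mismatch budget, default 2.
#' @return List with `assigned` (list of read vectors, one per barcode name)
#'   and `unassigned`.
#' @export
demultiplex <- function(reads, barcodes, max_mismatch = 2) {
  if (anyDuplicated(barcodes)) stop("duplicate barcode sequences")
  blen <- unique(nchar(barcodes))
  if (length(blen) != 1) stop("barcodes must all have equal length")
  if (any(nchar(reads) <= blen)) stop("reads must be longer than barcodes")
  if (is.null(names(barcodes))) names(barcodes) <- barcodes
  prefixes <- substr(reads, 1, blen)
  # distance matrix reads x barcodes via per-position comparison
  pm <- do.call(cbind, lapply(seq_len(blen), function(i)
    substr(prefixes, i, i)))
  dist <- sapply(seq_along(barcodes), function(j) {
    bc <- strsplit(barcodes[[j]], "")[[1]]
    rowSums(pm != matrix(bc, nrow(pm), blen, byrow = TRUE))
  })
  dist <- matrix(dist, nrow = length(reads))
  qualifies <- dist <= max_mismatch
  n_qual <- rowSums(qualifies)
  assigned_to <- ifelse(n_qual == 1, max.col(qualifies, ties.method = "first"),
                        NA_integer_)
  out <- lapply(seq_along(barcodes), function(j)
    reads[which(assigned_to == j)])
  names(out) <- names(barcodes)
  list(assigned = out, unassigned = reads[is.na(assigned_to)])
}

#' Trim the non-genomic prefix from reads
#'
#' Removes the first `n` bases (barcode plus spacer) of each read. Reads not
#' longer than `n` are dropped; the number dropped is attached as the
#' `n_dropped` attribute.
#'
#' @param reads Named character vector.
#' @param n Bases to remove, default 11.
#' @return Trimmed reads, order preserved, with attribute `n_dropped`.
#' @export
trim_reads <- function(reads, n = 11) {
  keep <- nchar(reads) > n
  out <- substring(reads[keep], n + 1)
  names(out) <- names(reads)[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Cluster 5' read positions into TSS peaks
#'
#' Greedy strand-separated clustering: within each chromosome and strand,
#' positions are sorted and a cluster is extended while the next position
#' lies within `merge_window` bp of the cluster's current rightmost
#' position. The peak spans the cluster, `read_support` counts its reads,
#' and `mode_position` is the most frequent 5' end (leftmost on ties).
#'
#' @param positions Data frame with `chrom`, `pos` (0-based 5' end, one row
#'   per read) and `strand`.
#' @param merge_window Clustering window in bp, default 20.
#' @return Peak table: `chrom`, `start`, `end`, `strand`, `mode_position`,
#'   `read_support`.
#' @export
call_tss_clusters <- function(positions, merge_window = 20) {
  stopifnot(all(c("chrom", "pos", "strand") %in% names(positions)))
  if (!nrow(positions))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      mode_position = numeric(0), read_support = integer(0)))
  key <- paste(positions$chrom, positions$strand)
  rows <- list()
  for (k in unique(key)) {
    sub <- positions[key == k, ]
    p <- sort(sub$pos)
    breaks <- c(0, which(diff(p) > merge_window), length(p))
    for (b in seq_len(length(breaks) - 1)) {
      cl <- p[(breaks[b] + 1):breaks[b + 1]]
      tab <- table(cl)
      mode <- as.numeric(names(tab)[which.max(tab)])  # leftmost max
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = sub$chrom[1], start = min(cl), end = max(cl) + 1,
        strand = sub$strand[1], mode_position = mode,
        read_support = length(cl), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Filter TSS peaks by read support
#'
#' Retains peaks supported by at least `min_reads` unique reads (default
#' 30), the high-confidence rule applied before annotation.
#'
#' @param peaks Peak table with `read_support`.
#' @param min_reads Support threshold, default 30.
#' @return Filtered peaks, order preserved, with attribute `n_removed`.
#' @export
filter_peaks <- function(peaks, min_reads = 30) {
  keep <- peaks$read_support >= min_reads
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

# Strand-aware 5' end of transcript records (0-based base position).
.transcript_tss <- function(tx) {
  ifelse(tx$strand == "-", tx$end - 1, tx$start)
}

#' Annotate peaks by genomic category
#'
#' Each peak's `mode_position` (or midpoint, see `at`) is compared to the
#' annotation: within 1 kb of an annotated transcript 5' end it is a `TSS`
#' peak (distance signed, positive = downstream of that TSS in the
#' transcript's orientation); otherwise the first matching category in the
#' priority order `three_prime_utr` > `exonic` > `intronic`; with no overlap
#' at all, `intergenic`.
#'
#' @param peaks Peak table with `chrom`, `strand` and `mode_position` (or
#'   `start`/`end` when `at = "midpoint"`).
#' @param annotation Annotation table (see [read_gtf()]); transcript records
#'   define TSS positions, exon and three_prime_utr records define the
#'   remaining categories.
#' @param tss_distance_bp Distance cutoff for the TSS category, default 1000.
#' @param at `"mode"` (default) or `"midpoint"` - which single point
#'   represents the peak.
#' @return `peaks` with `category` and `distance_to_tss` columns.
#' @export
annotate_peaks <- function(peaks, annotation, tss_distance_bp = 1000,
                           at = c("mode", "midpoint")) {
  at <- match.arg(at)
  pos <- if (at == "mode") peaks$mode_position
  else floor((peaks$start + peaks$end) / 2)
  tx <- annotation[annotation$feature_kind == "transcript", , drop = FALSE]
  if (!nrow(tx)) warning("annotation has no transcript records; ",
                         "all peaks will be intergenic")
  utr <- annotation[annotation$feature_kind == "three_prime_utr", ,
                    drop = FALSE]
  exon <- annotation[annotation$feature_kind == "exon", , drop = FALSE]
  category <- character(nrow(peaks))
  distance <- rep(NA_real_, nrow(peaks))
  tss_pos <- .transcript_tss(tx)
  pt_in <- function(tab, chrom, p) {
    nrow(tab) > 0 && any(tab$chrom == chrom & tab$start <= p & p < tab$end)
  }
  for (i in seq_len(nrow(peaks))) {
    p <- pos[i]; chrom <- peaks$chrom[i]
    on_chr <- which(tx$chrom == chrom)
    if (length(on_chr)) {
      d_abs <- abs(tss_pos[on_chr] - p)
      j <- on_chr[which.min(d_abs)]
      distance[i] <- if (tx$strand[j] == "-") tss_pos[j] - p else p - tss_pos[j]
    }
    if (!is.na(distance[i]) && abs(distance[i]) < tss_distance_bp) {
      category[i] <- "TSS"
    } else if (pt_in(utr, chrom, p)) {
      category[i] <- "three_prime_utr"
    } else if (pt_in(exon, chrom, p)) {
      category[i] <- "exonic"
    } else if (pt_in(tx, chrom, p)) {
      category[i] <- "intronic"
    } else {
      category[i] <- "intergenic"
    }
  }
  peaks$category <- category
  peaks$distance_to_tss <- distance
  peaks
}

#' Extract proximal promoter windows around TSS peaks
#'
#' The window covers 250 bp upstream through 50 bp downstream of the TSS in
#' the transcript's reading direction: plus strand `[t-250, t+50)`, minus
#' strand the mirrored `[t-49, t+251)` with the sequence
#' reverse-complemented. Both are exactly 300 bp and contain the TSS base.
#' Windows truncated by a chromosome edge are clipped and flagged
#' (`clipped = TRUE`) so callers can exclude them from motif statistics.
#'
#' @param peaks Peak table with `chrom`, `strand`, `mode_position`.
#' @param genome Named character vector of chromosome sequences.
#' @param upstream,downstream Window extents in bp (defaults 250 and 50).
#' @return Data frame: interval columns, `tss_position`, `sequence`,
#'   `clipped`.
#' @export
extract_promoters <- function(peaks, genome, upstream = 250,
                              downstream = 50) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    t <- peaks$mode_position[i]
    chrom <- peaks$chrom[i]
    strand <- peaks$strand[i]
    L <- nchar(genome[[chrom]])
    if (strand == "-") {
      start <- t - downstream + 1; end <- t + upstream + 1
    } else {
      start <- t - upstream; end <- t + downstream
    }
    clipped <- start < 0 || end > L
    s2 <- max(start, 0); e2 <- min(end, L)
    iv <- gintervals(chrom, s2, e2, strand)
    rows[[i]] <- data.frame(
      chrom = chrom, start = s2, end = e2, strand = strand,
      tss_position = t, sequence = extract_sequence(genome, iv),
      clipped = clipped, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select stage-specific TSS peaks
#'
#' A peak is specific to its stage when it passes the read-support filter
#' there and overlaps (same strand, >= 1 bp) no filtered peak of any other
#' stage. Presence/absence is one possible reading of stage specificity; the
#' support threshold is configurable.
#'
#' @param peak_sets Named list of peak tables, one per stage (unfiltered;
#'   the support filter is applied here).
#' @param min_reads Support threshold applied per stage, default 30.
#' @return Named list of stage-specific peak tables.
#' @export
stage_specific_peaks <- function(peak_sets, min_reads = 30) {
  if (length(peak_sets) < 2) stop("need at least two stages")
  filtered <- lapply(peak_sets, filter_peaks, min_reads = min_reads)
  out <- list()
  for (s in names(filtered)) {
    mine <- filtered[[s]]
    others <- do.call(rbind, c(filtered[setdiff(names(filtered), s)],
                               make.row.names = FALSE))
    if (!nrow(mine)) { out[[s]] <- mine; next }
    if (is.null(others) || !nrow(others)) { out[[s]] <- mine; next }
    ov <- overlap_intervals(mine, others, strand_matched = TRUE)
    keep <- setdiff(seq_len(nrow(mine)), unique(ov$query))
    res <- mine[keep, , drop = FALSE]
    rownames(res) <- NULL
    out[[s]] <- res
  }
  out
}

## ---- position weight matrices --------------------------------------------

.BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param name Motif name.
#' @param matrix 4 x L matrix of base probabilities, rows A, C, G, T;
#'   columns must each sum to 1 (tolerance 1e-9). Count matrices can be
#'   passed through [normalize_pwm()] first.
#' @param background Background base probabilities, default uniform.
#' @return An object of class `pwm`.
#' @export
pwm <- function(name, matrix, background = rep(0.25, 4)) {
  matrix <- as.matrix(matrix)
  stopifnot(nrow(matrix) == 4, length(background) == 4)
  rownames(matrix) <- .BASES
  if (any(abs(colSums(matrix) - 1) > 1e-9))
    stop("PWM columns must each sum to 1")
  if (abs(sum(background) - 1) > 1e-9)
    stop("background must sum to 1")
  structure(list(name = name, matrix = matrix,
                 background = stats::setNames(background, .BASES)),
            class = "pwm")
}

#' Convert a count matrix to a probability PWM
#'
#' @param counts 4 x L non-negative matrix (rows A, C, G, T).
#' @param pseudocount Added to every cell before normalization.
#' @return 4 x L column-stochastic matrix.
#' @export
normalize_pwm <- function(counts, pseudocount = 0.5) {
  counts <- as.matrix(counts) + pseudocount
  sweep(counts, 2, colSums(counts), "/")
}

#' Read motifs from a JASPAR-style text file
#'
#' Expects blocks of the form `>ID NAME` followed by four lines
#' `A [ n n ... ]` (rows A, C, G, T). Counts are converted to probabilities
#' with a pseudocount.
#'
#' @param path Path to the motif file.
#' @param pseudocount Passed to [normalize_pwm()].
#' @return List of `pwm` objects.
#' @export
read_jaspar_pwms <- function(path, pseudocount = 0.5) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- which(startsWith(lines, ">"))
  if (!length(heads)) stop("no motif headers ('>') found in ", path)
  out <- list()
  for (h in heads) {
    nm <- trimws(sub("^>\\s*", "", lines[h]))
    if (h + 4 > length(lines)) stop("truncated motif block: ", nm)
    rows <- lapply(lines[(h + 1):(h + 4)], function(l) {
      s <- sub("^\\s*[ACGT]", "", l)
      as.numeric(regmatches(s, gregexpr("[0-9.]+", s))[[1]])
    })
    if (length(unique(lengths(rows))) != 1)
      stop("ragged motif matrix for ", nm)
    counts <- do.call(rbind, rows)
    out[[length(out) + 1L]] <- pwm(nm, normalize_pwm(counts, pseudocount))
  }
  out
}

pwm_log_odds <- function(p) log2(p$matrix / p$background)

# Best log-odds score of a PWM over all windows of a sequence, both
# orientations. Windows containing N are skipped.
pwm_best_score <- function(p, seq) {
  lo <- pwm_log_odds(p)
  L <- ncol(lo)
  best <- -Inf
  for (s in c(seq, reverse_complement(seq))) {
    idx <- match(strsplit(s, "")[[1]], .BASES)  # N -> NA
    n <- length(idx)
    if (n < L) next
    for (start in seq_len(n - L + 1)) {
      win <- idx[start:(start + L - 1)]
      if (anyNA(win)) next
      sc <- sum(lo[cbind(win, seq_len(L))])
      if (sc > best) best <- sc
    }
  }
  best
}

#' Test known-motif enrichment in foreground vs background promoters
#'
#' A sequence "has" a motif when some window (either orientation) scores at
#' least `threshold_frac` of the PWM's maximum achievable log-odds score.
#' Hit counts form a 2x2 table tested by Fisher's exact test (two-sided);
#' p-values are Benjamini-Hochberg corrected across motifs, and a motif is
#' called significant when both `p < p_threshold` and `q < q_threshold`.
#'
#' @param foreground,background Character vectors of promoter sequences, or
#'   promoter tables from [extract_promoters()] (clipped windows excluded).
#' @param pwms List of `pwm` objects.
#' @param threshold_frac Fraction of the maximum log-odds score required for
#'   a hit, default 0.8.
#' @param p_threshold,q_threshold Significance cutoffs, both default 0.01.
#' @return Data frame: `pwm`, `fg_hits`, `fg_total`, `bg_hits`, `bg_total`,
#'   `odds_ratio`, `p`, `q`, `significant`.
#' @export
motif_enrichment <- function(foreground, background, pwms,
                             threshold_frac = 0.8, p_threshold = 0.01,
                             q_threshold = 0.01) {
  as_seqs <- function(x) {
    if (is.data.frame(x)) x$sequence[!x$clipped] else x
  }
  fg <- as_seqs(foreground); bg <- as_seqs(background)
  if (!length(fg) || !length(bg))
    stop("foreground and background must be non-empty")
  rows <- list()
  for (p in pwms) {
    if (ncol(p$matrix) > min(nchar(c(fg, bg)))) {
      warning("PWM '", p$name, "' longer than the sequences; skipped")
      next
    }
    thr <- threshold_frac * sum(apply(pwm_log_odds(p), 2, max))
    fg_hits <- sum(vapply(fg, function(s) pwm_best_score(p, s) >= thr,
                          logical(1)))
    bg_hits <- sum(vapply(bg, function(s) pwm_best_score(p, s) >= thr,
                          logical(1)))
    tab <- matrix(c(fg_hits, length(fg) - fg_hits,
                    bg_hits, length(bg) - bg_hits), 2)
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    rows[[length(rows) + 1L]] <- data.frame(
      pwm = p$name, fg_hits = fg_hits, fg_total = length(fg),
      bg_hits = bg_hits, bg_total = length(bg),
      odds_ratio = unname(ft$estimate), p = ft$p.value,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no usable PWMs")
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < p_threshold & out$q < q_threshold
  rownames(out) <- NULL
  out
}
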