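## Synthetic-data generators. Every generator is a pure function of its
## arguments plus an explicit seed: the same call yields byte-identical
## output and leaves the caller's RNG state untouched.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single number")
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Deterministic per-module substream of a top-level seed.
sub_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483587)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Kimura two-parameter per-site substitution probabilities
#'
#' Exact transition probabilities of the K2P continuous-time chain after time
#' `t`, with instantaneous transition rate `alpha` and rate `beta` toward
#' each of the two transversion targets. The expected number of
#' substitutions per site is `(alpha + 2 beta) t`.
#'
#' @param alpha Transition rate (A<->G, C<->T).
#' @param beta Rate toward each transversion target.
#' @param t Branch length (time units; only the products `alpha t`, `beta t`
#'   matter).
#' @return Named vector: probability the site is unchanged (`same`), changed
#'   by a transition (`transition`), or changed to one given transversion
#'   target (`transversion_each`).
#' @export
k2p_site_probs <- function(alpha, beta, t) {
  if (alpha < 0 || beta < 0 || t < 0)
    stop("alpha, beta and t must be non-negative")
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv_each <- 0.25 - 0.25 * e1
  c(same = 1 - p_ts - 2 * p_tv_each, transition = p_ts,
    transversion_each = p_tv_each)
}

.TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
.TV_TARGETS <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))

#' Evolve a sequence along one branch under the K2P model
#'
#' Each site evolves independently; per-site outcome probabilities are the
#' exact finite-time transition probabilities of the K2P chain (see
#' [k2p_site_probs()]), so no discretization error accrues for any `t`.
#'
#' @param ancestor Sequence string over `{A,C,G,T}`.
#' @param alpha,beta K2P rates (transition; each transversion target).
#' @param t Branch length.
#' @param seed Optional RNG seed for a self-contained draw.
#' @return The derived sequence string.
#' @export
evolve_pair_k2p <- function(ancestor, alpha, beta, t, seed = NULL) {
  if (grepl("[^ACGT]", ancestor)) stop("ancestor must be over {A,C,G,T}")
  with_seed(seed, {
    p <- k2p_site_probs(alpha, beta, t)
    sites <- strsplit(ancestor, "")[[1]]
    u <- stats::runif(length(sites))
    out <- sites
    ts <- u >= p["same"] & u < p["same"] + p["transition"]
    out[ts] <- .TS_PARTNER[sites[ts]]
    tv1 <- u >= p["same"] + p["transition"] &
      u < p["same"] + p["transition"] + p["transversion_each"]
    tv2 <- u >= p["same"] + p["transition"] + p["transversion_each"]
    for (b in c("A", "C", "G", "T")) {
      out[tv1 & sites == b] <- .TV_TARGETS[[b]][1]
      out[tv2 & sites == b] <- .TV_TARGETS[[b]][2]
    }
    paste(out, collapse = "")
  })
}

#' Generate a pair of LTR sequences diverged from one ancestor
#'
#' Mirrors post-insertion LTR evolution: both flanking LTRs start as copies
#' of the ancestral element and accumulate substitutions independently along
#' two branches of length `t` each, so their expected pairwise divergence is
#' `2 (alpha + 2 beta) t = k_true`.
#'
#' @param ltr_length Ancestor length in bp.
#' @param k_true Target expected pairwise divergence (substitutions/site).
#' @param alpha,beta Relative K2P rates (default transition/transversion
#'   rate ratio 2 per branch, i.e. kappa = 2).
#' @param seed Optional RNG seed.
#' @return List with `ancestor`, `ltr5`, `ltr3` sequence strings.
#' @export
simulate_ltr_pair <- function(ltr_length = 450, k_true = 0.05, alpha = 1,
                              beta = 0.5, seed = NULL) {
  if (k_true < 0) stop("k_true must be >= 0")
  with_seed(seed, {
    anc <- random_dna(ltr_length)
    t_branch <- (k_true / 2) / (alpha + 2 * beta)
    list(ancestor = anc,
         ltr5 = evolve_pair_k2p(anc, alpha, beta, t_branch),
         ltr3 = evolve_pair_k2p(anc, alpha, beta, t_branch))
  })
}

.DEFAULT_CENSUS <- data.frame(
  subfamily = c("LTR7", "HERVH-int", "MER41", "MER57", "HERVE",
                "HERVIP10", "L1PA4", "AluY"),
  family = c("ERV1", "ERV1", "ERV1", "ERV1", "ERV1", "ERV1", "L1", "Alu"),
  class = c("LTR", "LTR", "LTR", "LTR", "LTR", "LTR", "LINE", "SINE"),
  n = c(150, 150, 400, 300, 250, 250, 1500, 2000),
  stringsAsFactors = FALSE)

#' Build a synthetic repeat-locus census
#'
#' A locus table for expression simulations, without genome coordinates.
#' The default census keeps LTR7/HERVH a small minority (about 6 percent of
#' loci), echoing the real repeat annotation where LTR7/HERVH is roughly one
#' percent of quantified loci, so that library-composition effects on CPM
#' stay small.
#'
#' @param census Data frame with columns `subfamily`, `family`, `class`,
#'   `n` (locus count per subfamily).
#' @return Locus table with `locus_id`, `class`, `family`, `subfamily`.
#' @export
make_locus_table <- function(census = .DEFAULT_CENSUS) {
  stopifnot(all(c("subfamily", "family", "class", "n") %in% names(census)))
  rows <- census[rep(seq_len(nrow(census)), census$n), ]
  data.frame(
    locus_id = paste0(rows$subfamily, "_", unlist(lapply(census$n, seq_len))),
    class = rows$class, family = rows$family, subfamily = rows$subfamily,
    stringsAsFactors = FALSE)
}

#' Simulate a control/knockdown count table with planted fold changes
#'
#' Counts are negative-binomial around locus-specific baseline means drawn
#' log-normally across loci; knockdown means are `baseline * 2^delta` where
#' `delta` is the planted per-subfamily (or per-locus) log2 fold change.
#'
#' @param loci Locus table (see [make_locus_table()]); needs `locus_id` and
#'   `subfamily` columns.
#' @param delta Named numeric: planted log2 fold change per subfamily;
#'   subfamilies not named get 0.
#' @param locus_delta Optional numeric vector (one per locus) overriding
#'   `delta`; used to plant per-locus effects such as correlated shifts.
#' @param n_replicates Replicates per condition.
#' @param dispersion Negative-binomial dispersion phi (variance
#'   `mu + phi mu^2`); must be > 0.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   mean counts across loci.
#' @param seed Optional RNG seed.
#' @return A `count_table` object (see [count_table()]).
#' @export
simulate_counts <- function(loci, delta = NULL, locus_delta = NULL,
                            n_replicates = 3, dispersion = 0.1,
                            baseline_meanlog = log(100), baseline_sdlog = 1,
                            seed = NULL) {
  if (dispersion <= 0) stop("dispersion must be > 0")
  n <- nrow(loci)
  if (is.null(locus_delta)) {
    locus_delta <- rep(0, n)
    if (!is.null(delta)) {
      hit <- loci$subfamily %in% names(delta)
      locus_delta[hit] <- delta[loci$subfamily[hit]]
    }
  }
  stopifnot(length(locus_delta) == n)
  with_seed(seed, {
    mu0 <- stats::rlnorm(n, baseline_meanlog, baseline_sdlog)
    mu_kd <- mu0 * 2^locus_delta
    size <- 1 / dispersion
    counts <- cbind(
      matrix(stats::rnbinom(n * n_replicates, mu = mu0, size = size), n),
      matrix(stats::rnbinom(n * n_replicates, mu = mu_kd, size = size), n))
    colnames(counts) <- c(paste0("ctrl_", seq_len(n_replicates)),
                          paste0("kd_", seq_len(n_replicates)))
    rownames(counts) <- loci$locus_id
    samples <- data.frame(
      sample_id = colnames(counts),
      condition = rep(c("control", "knockdown"), each = n_replicates),
      replicate = rep(seq_len(n_replicates), 2), stringsAsFactors = FALSE)
    count_table(counts, loci, samples)
  })
}

#' Simulate two knockdown experiments with correlated planted effects
#'
#' Per-locus log2 fold changes for the two perturbations are drawn from a
#' bivariate normal with correlation `rho`, then counts are simulated
#' independently for each experiment. Used to validate recovery of
#' cross-knockdown fold-change correlation.
#'
#' @param n_loci Number of loci (labelled as ERV1 subfamily members).
#' @param rho Planted correlation between the two per-locus effects.
#' @param delta_sd Standard deviation of each effect across loci.
#' @param delta_mean Mean effect (applies to both experiments).
#' @param seed Optional RNG seed.
#' @inheritParams simulate_counts
#' @return List with count tables `a` and `b` and the true effect matrix
#'   `delta` (n_loci x 2).
#' @export
simulate_cross_kd <- function(n_loci = 500, rho = -0.6, delta_sd = 1.5,
                              delta_mean = 0, n_replicates = 3,
                              dispersion = 0.05, seed = NULL) {
  if (abs(rho) > 1) stop("rho must be in [-1, 1]")
  with_seed(seed, {
    z1 <- stats::rnorm(n_loci)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_loci)
    delta <- cbind(a = delta_mean + delta_sd * z1,
                   b = delta_mean + delta_sd * z2)
    loci <- data.frame(locus_id = paste0("erv1_", seq_len(n_loci)),
                       class = "LTR", family = "ERV1", subfamily = "HERVE",
                       stringsAsFactors = FALSE)
    a <- simulate_counts(loci, locus_delta = delta[, "a"],
                         n_replicates = n_replicates, dispersion = dispersion,
                         baseline_meanlog = log(300))
    b <- simulate_counts(loci, locus_delta = delta[, "b"],
                         n_replicates = n_replicates, dispersion = dispersion,
                         baseline_meanlog = log(300))
    list(a = a, b = b, delta = delta)
  })
}

## ---- toy genome -----------------------------------------------------------

.SOLO_LEN <- c(MER41 = 600, MER57 = 400, HERVE = 500, HERVIP10 = 500,
               L1PA4 = 1000, AluY = 300, LTR7 = 450)

#' Generate a toy genome with planted HERVH units, repeats and genes
#'
#' Lays out, per chromosome, full-length retroelement units (LTR7 /
#' HERVH-int / LTR7 on one strand, the two LTRs independently diverged from
#' one ancestor to a known expected distance `k_true`), solo repeats of
#' background subfamilies, solo LTR7 elements, protein-coding genes, and
#' lncRNA genes of which a configurable fraction overlaps a HERVH unit.
#'
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param n_hervh_units Number of full-length LTR7-HERVH-int-LTR7 units.
#' @param ltr_length,internal_length Segment lengths in bp.
#' @param k_true Expected pairwise divergence of the two LTRs of a unit.
#' @param alpha,beta K2P rates used by the mutation process.
#' @param n_solo Named vector: solo repeat count per subfamily.
#' @param n_lnc Number of lncRNA genes.
#' @param lnc_overlap_frac Fraction of lncRNAs laid over a HERVH unit.
#' @param n_coding Number of protein-coding genes (transcript + exons +
#'   three_prime_utr records, for peak annotation).
#' @param seed RNG seed; the same seed reproduces the genome byte-for-byte.
#' @return List: `genome` (named sequences), `repeats` (interval table with
#'   `locus_id`, `class`, `family`, `subfamily`, `unit_id`), `genes`
#'   (GTF-style annotation table), `units` (unit truth table with segment
#'   coordinates and `k_true`).
#' @export
make_toy_genome <- function(chrom_lengths = c(chrA = 220000, chrB = 220000),
                            n_hervh_units = 8, ltr_length = 450,
                            internal_length = 4000, k_true = 0.05,
                            alpha = 1, beta = 0.5,
                            n_solo = c(MER41 = 12, MER57 = 8, HERVE = 8,
                                       HERVIP10 = 8, L1PA4 = 10, AluY = 16,
                                       LTR7 = 6),
                            n_lnc = 10, lnc_overlap_frac = 0.5,
                            n_coding = 6, seed = 1) {
  with_seed(seed, {
    chroms <- lapply(chrom_lengths, random_dna)
    cursor <- stats::setNames(rep(1000, length(chrom_lengths)),
                              names(chrom_lengths))
    place <- function(len) {
      # round-robin-ish allocator with random gaps; errors when full
      ok <- names(cursor)[cursor + len + 1000 <= chrom_lengths]
      if (!length(ok))
        stop("infeasible packing: features exceed chromosome lengths")
      chr <- if (length(ok) == 1) ok else sample(ok, 1)
      gap <- sample(200:800, 1)
      start <- cursor[[chr]] + gap
      cursor[[chr]] <<- start + len
      list(chrom = chr, start = start)
    }
    put_seq <- function(chr, start, s) {
      substr(chroms[[chr]], start + 1, start + nchar(s)) <<- s
    }

    reps <- list(); units <- list(); genes <- list()
    t_branch <- (k_true / 2) / (alpha + 2 * beta)
    for (i in seq_len(n_hervh_units)) {
      unit_len <- 2 * ltr_length + internal_length
      at <- place(unit_len)
      strand <- sample(c("+", "-"), 1)
      anc <- random_dna(ltr_length)
      ltr5 <- evolve_pair_k2p(anc, alpha, beta, t_branch)
      ltr3 <- evolve_pair_k2p(anc, alpha, beta, t_branch)
      int_seq <- random_dna(internal_length)
      s0 <- at$start
      put_seq(at$chrom, s0, ltr5)
      put_seq(at$chrom, s0 + ltr_length, int_seq)
      put_seq(at$chrom, s0 + ltr_length + internal_length, ltr3)
      uid <- sprintf("unit_%02d", i)
      seg <- data.frame(
        chrom = at$chrom,
        start = c(s0, s0 + ltr_length, s0 + ltr_length + internal_length),
        end = c(s0 + ltr_length, s0 + ltr_length + internal_length,
                s0 + unit_len),
        strand = strand,
        locus_id = paste0(uid, c("_ltr5", "_int", "_ltr3")),
        class = "LTR", family = "ERV1",
        subfamily = c("LTR7", "HERVH-int", "LTR7"),
        unit_id = uid, stringsAsFactors = FALSE)
      reps[[length(reps) + 1L]] <- seg
      units[[length(units) + 1L]] <- data.frame(
        unit_id = uid, chrom = at$chrom, strand = strand,
        ltr5_start = seg$start[1], ltr5_end = seg$end[1],
        int_start = seg$start[2], int_end = seg$end[2],
        ltr3_start = seg$start[3], ltr3_end = seg$end[3],
        k_true = k_true, stringsAsFactors = FALSE)
    }
    for (sf in names(n_solo)) {
      info <- .DEFAULT_CENSUS[.DEFAULT_CENSUS$subfamily == sf, ]
      len <- .SOLO_LEN[[sf]]
      for (i in seq_len(n_solo[[sf]])) {
        at <- place(len)
        put_seq(at$chrom, at$start, random_dna(len))
        reps[[length(reps) + 1L]] <- data.frame(
          chrom = at$chrom, start = at$start, end = at$start + len,
          strand = sample(c("+", "-"), 1),
          locus_id = sprintf("%s_solo_%03d", sf, i),
          class = info$class, family = info$family, subfamily = sf,
          unit_id = NA_character_, stringsAsFactors = FALSE)
      }
    }

    unit_df <- if (length(units)) do.call(rbind, units) else NULL
    mk_gene <- function(chrom, start, end, strand, gid, biotype,
                        with_utr = FALSE) {
      tid <- paste0(gid, ".t1")
      ex1 <- c(start, start + 200)
      ex2 <- c(end - 300, end)
      rows <- data.frame(
        chrom = chrom, start = c(start, start, ex1[1], ex2[1]),
        end = c(end, end, ex1[2], ex2[2]), strand = strand,
        feature_kind = c("gene", "transcript", "exon", "exon"),
        gene_id = gid, transcript_id = c(NA, tid, tid, tid),
        biotype = biotype, stringsAsFactors = FALSE)
      if (with_utr) {
        utr <- if (strand == "+") c(end - 150, end) else c(start, start + 150)
        rows <- rbind(rows, data.frame(
          chrom = chrom, start = utr[1], end = utr[2], strand = strand,
          feature_kind = "three_prime_utr", gene_id = gid,
          transcript_id = tid, biotype = biotype, stringsAsFactors = FALSE))
      }
      rows
    }
    n_overlap <- round(n_lnc * lnc_overlap_frac)
    for (i in seq_len(n_lnc)) {
      gid <- sprintf("LNC%03d", i)
      if (i <= n_overlap && !is.null(unit_df)) {
        u <- unit_df[1 + (i - 1) %% nrow(unit_df), ]
        start <- u$ltr5_start - sample(100:400, 1)
        end <- u$int_end + sample(100:400, 1)
        genes[[length(genes) + 1L]] <-
          mk_gene(u$chrom, start, end, u$strand, gid, "lncRNA")
      } else {
        at <- place(1500)
        genes[[length(genes) + 1L]] <-
          mk_gene(at$chrom, at$start, at$start + 1500,
                  sample(c("+", "-"), 1), gid, "lncRNA")
      }
    }
    for (i in seq_len(n_coding)) {
      at <- place(3000)
      genes[[length(genes) + 1L]] <-
        mk_gene(at$chrom, at$start, at$start + 3000, sample(c("+", "-"), 1),
                sprintf("GENE%03d", i), "protein_coding", with_utr = TRUE)
    }

    repeats <- do.call(rbind, reps)
    rownames(repeats) <- NULL
    gene_df <- if (length(genes)) do.call(rbind, genes) else
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 strand = character(0), feature_kind = character(0),
                 gene_id = character(0), transcript_id = character(0),
                 biotype = character(0), stringsAsFactors = FALSE)
    rownames(gene_df) <- NULL
    validate_intervals(repeats)
    validate_intervals(gene_df)
    list(genome = vapply(chroms, identity, character(1)),
         repeats = repeats, genes = gene_df, units = unit_df)
  })
}

#' Write a toy genome bundle to FASTA / BED / GTF files
#'
#' @param toy Output of [make_toy_genome()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths.
#' @export
write_toy_genome <- function(toy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             repeats = file.path(dir, "repeats.bed"),
             genes = file.path(dir, "genes.gtf"),
             sizes = file.path(dir, "chrom.sizes"))
  write_fasta(toy$genome, paths[["genome"]])
  bed <- toy$repeats
  bed$name <- paste(bed$locus_id, bed$class, bed$family, bed$subfamily,
                    sep = "|")
  bed$score <- 0
  write_bed(bed, paths[["repeats"]])
  write_gtf(toy$genes, paths[["genes"]])
  writeLines(sprintf("%s\t%d", names(toy$genome), nchar(toy$genome)),
             paths[["sizes"]])
  paths
}

#' Simulate a ChIP peak set with controlled enrichment over a feature class
#'
#' Peak start positions are drawn from a piecewise-constant density:
#' `enrichment_factor` on bases inside the (merged) target feature, 1
#' elsewhere. Peak length is fixed and peaks never extend beyond chromosome
#' ends.
#'
#' @param target Interval table of the feature class to enrich on.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param n_peaks Number of peaks.
#' @param peak_length Peak width in bp.
#' @param enrichment_factor Placement density ratio inside/outside the
#'   target; 1 means uniform (null) placement. Must be >= 0.
#' @param seed Optional RNG seed.
#' @return Interval table of peaks (strand `"."`, `name` = peak id).
#' @export
simulate_peaks <- function(target, chrom_sizes, n_peaks = 2000,
                           peak_length = 200, enrichment_factor = 1,
                           seed = NULL) {
  if (enrichment_factor < 0) stop("enrichment_factor must be >= 0")
  if (any(peak_length > chrom_sizes))
    stop("peak_length exceeds a chromosome length")
  if (n_peaks == 0)
    return(gintervals(character(0), numeric(0), numeric(0),
                      name = character(0), score = numeric(0)))
  tgt <- merge_intervals(target)
  with_seed(seed, {
    # per chromosome: candidate starts [0, L - peak_length], partitioned into
    # in-target and background bases
    per_chrom <- lapply(names(chrom_sizes), function(chr) {
      lim <- chrom_sizes[[chr]] - peak_length
      ti <- tgt[tgt$chrom == chr & tgt$start <= lim, , drop = FALSE]
      if (nrow(ti)) ti$end <- pmin(ti$end, lim + 1)
      bp_in <- if (nrow(ti)) sum(ti$end - ti$start) else 0
      list(chr = chr, ti = ti, bp_in = bp_in, bp_out = (lim + 1) - bp_in)
    })
    w <- vapply(per_chrom, function(p)
      enrichment_factor * p$bp_in + p$bp_out, numeric(1))
    chrom_idx <- sample.int(length(per_chrom), n_peaks, replace = TRUE,
                            prob = w)
    starts <- numeric(n_peaks); chrs <- character(n_peaks)
    for (k in seq_len(n_peaks)) {
      p <- per_chrom[[chrom_idx[k]]]
      chrs[k] <- p$chr
      p_in <- enrichment_factor * p$bp_in /
        (enrichment_factor * p$bp_in + p$bp_out)
      if (stats::runif(1) < p_in) {
        widths <- p$ti$end - p$ti$start
        i <- sample.int(nrow(p$ti), 1, prob = widths)
        starts[k] <- p$ti$start[i] + sample.int(widths[i], 1) - 1
      } else {
        # rejection-sample the complement (background dominates, fast)
        repeat {
          cand <- sample.int(chrom_sizes[[p$chr]] - peak_length + 1, 1) - 1
          inside <- nrow(p$ti) > 0 &&
            any(cand >= p$ti$start & cand < p$ti$end)
          if (!inside) break
        }
        starts[k] <- cand
      }
    }
    gintervals(chrs, starts, starts + peak_length, ".",
               name = sprintf("peak_%05d", seq_len(n_peaks)), score = 0)
  })
}

#' Simulate barcoded 5'-capture (nanoCAGE-style) reads
#'
#' Each read is a 6-nt sample barcode (with optional per-base substitution
#' errors), filler up to 11 non-genomic nucleotides, then genomic sequence
#' whose first base sits exactly at a planted TSS position on the annotated
#' strand.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param tss Data frame with columns `chrom`, `pos` (0-based TSS base),
#'   `strand`, `sample` (barcode name), `depth` (reads to emit).
#' @param barcodes Named character vector of 6-mers; any two barcodes closer
#'   than Hamming distance 5 are rejected (would break 2-mismatch
#'   demultiplexing).
#' @param genomic_length Genomic bases per read.
#' @param barcode_error_rate Per-base substitution probability in the
#'   barcode part.
#' @param seed Optional RNG seed.
#' @return Named character vector of reads. Read ids encode the generating
#'   truth as `chrom:pos:strand:sample:rNNN`, which downstream steps may use
#'   in place of alignment (see [cage_truth_positions()]).
#' @export
simulate_cage_reads <- function(genome, tss, barcodes, genomic_length = 25,
                                barcode_error_rate = 0, seed = NULL) {
  stopifnot(all(c("chrom", "pos", "strand", "sample", "depth") %in%
                  names(tss)))
  if (any(nchar(barcodes) != 6)) stop("barcodes must be 6-mers")
  if (length(barcodes) > 1) {
    for (i in seq_along(barcodes)) for (j in seq_len(i - 1)) {
      if (hamming_distance(barcodes[[i]], barcodes[[j]]) <= 4)
        stop("barcodes '", barcodes[[i]], "' and '", barcodes[[j]],
             "' are within Hamming distance 4")
    }
  }
  filler <- "TATAG"  # fixed 5-nt spacer: barcode(6) + spacer(5) = 11 nt
  with_seed(seed, {
    reads <- character(0)
    for (r in seq_len(nrow(tss))) {
      row <- tss[r, ]
      if (!row$chrom %in% names(genome)) stop("unknown chrom: ", row$chrom)
      L <- nchar(genome[[row$chrom]])
      if (row$strand == "+") {
        iv <- gintervals(row$chrom, row$pos,
                         min(row$pos + genomic_length, L), "+")
      } else {
        iv <- gintervals(row$chrom, max(row$pos - genomic_length + 1, 0),
                         row$pos + 1, "-")
      }
      gseq <- extract_sequence(genome, iv)
      bc <- barcodes[[row$sample]]
      for (d in seq_len(row$depth)) {
        b <- bc
        if (barcode_error_rate > 0) {
          hit <- which(stats::runif(6) < barcode_error_rate)
          if (length(hit)) {
            cs <- strsplit(b, "")[[1]]
            for (h in hit) cs[h] <- sample(setdiff(c("A", "C", "G", "T"),
                                                   cs[h]), 1)
            b <- paste(cs, collapse = "")
          }
        }
        id <- sprintf("%s:%d:%s:%s:r%03d", row$chrom, row$pos, row$strand,
                      row$sample, d)
        reads[id] <- paste0(b, filler, gseq)
      }
    }
    reads
  })
}
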