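#' Recover 5' positions from synthetic read ids
#'
#' The synthetic read generator encodes each read's true genomic origin in
#' its id (`chrom:pos:strand:sample:rNNN`). This parser stands in for the
#' alignment step, which is outside the scope of the package.
#'
#' @param read_names Character vector of synthetic read ids.
#' @return Data frame with `chrom`, `pos`, `strand` (one row per read).
#' @export
cage_truth_positions <- function(read_names) {
  parts <- strsplit(read_names, ":", fixed = TRUE)
  bad <- lengths(parts) != 5
  if (any(bad)) stop("not a synthetic read id: ", read_names[which(bad)[1]])
  data.frame(chrom = vapply(parts, `[`, "", 1),
             pos = as.numeric(vapply(parts, `[`, "", 2)),
             strand = vapply(parts, `[`, "", 3),
             stringsAsFactors = FALSE)
}

.CONFIG_DEFAULTS <- list(
  min_peak_reads = 30,        # peak support filter (stated threshold)
  tss_distance_bp = 1000,     # TSS category rule (stated threshold)
  promoter_upstream = 250,    # promoter window (stated threshold)
  promoter_downstream = 50,   # promoter window (stated threshold)
  barcode_max_mismatch = 2,   # demultiplexing budget (stated threshold)
  trim_length = 11,           # non-genomic prefix (stated threshold)
  cpm_expression_threshold = 1,   # lncRNA detection cutoff (stated)
  hervh_flank_bp = 10000,     # peak-unit association flank (stated)
  top_n = 200,                # divergence group size (stated)
  motif_p_threshold = 0.01,   # motif significance (stated)
  motif_q_threshold = 0.01,   # motif significance (stated)
  evolution_rate = 1.28e-8,   # substitutions/site/year (stated)
  pseudocount = 0.5,
  merge_window = 20,
  gap_tolerance = 100,
  n_perm = 199,
  seed = 7)

.CONFIG_POSITIVE <- setdiff(names(.CONFIG_DEFAULTS), "seed")

#' Build and validate a pipeline configuration
#'
#' Starts from the package defaults (the thresholds the analyses were
#' designed around) and applies overrides. Unknown keys are rejected and
#' all range violations are reported together.
#'
#' @param ... Named overrides of default fields, or a single named list.
#' @return Named list of resolved configuration values, class
#'   `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  cfg <- .CONFIG_DEFAULTS
  problems <- character(0)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    problems <- c(problems, paste0("unknown key: ", unknown))
  for (k in intersect(names(over), names(cfg))) {
    v <- over[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      problems <- c(problems, paste0(k, ": must be a single number"))
    } else if (k %in% .CONFIG_POSITIVE && v <= 0) {
      problems <- c(problems, paste0(k, ": must be > 0 (got ", v, ")"))
    } else {
      cfg[[k]] <- v
    }
  }
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}

.check <- function(reports, name, value, pass) {
  reports[[length(reports) + 1L]] <- data.frame(
    check = name, value = as.numeric(value), pass = isTRUE(pass),
    stringsAsFactors = FALSE)
  reports
}

#' Run the end-to-end synthetic demonstration
#'
#' Generates one seeded synthetic dataset and pushes it through every
#' analysis stage: 5'-read processing to TSS peaks, repeat fold-change KS
#' scan, peak enrichment with permutation null, HERVH-lncRNA overlap and
#' correlation, cross-knockdown correlation, and paired-LTR dating with the
#' young-versus-old group comparison. Each stage's planted parameter must be
#' recovered; the returned report lists every self-check.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the report and stage
#'   tables are written as TSV (deterministic bytes for a fixed seed).
#' @param error_on_failure Stop (rather than return) when a self-check
#'   fails; default `TRUE`.
#' @return List: `checks` (data frame), `tables` (per-stage results),
#'   `config`.
#' @export
run_demo <- function(config = pipeline_config(), out_dir = NULL,
                     error_on_failure = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  checks <- list()
  tables <- list()

  ## stage 1: toy genome
  toy <- make_toy_genome(seed = sub_seed(seed, "genome"))
  checks <- .check(checks, "genome_units_planted", nrow(toy$units),
                   nrow(toy$units) == 8)

  ## stage 2: nanoCAGE-style TSS recovery (boundary depths included)
  barcodes <- c(s1 = "ACGTAC", s2 = "TGCAGG")
  tss_truth <- data.frame(
    chrom = "chrA",
    pos = c(5000, 9000, 13000, 17000, 21000),
    strand = c("+", "+", "-", "+", "-"),
    sample = "s1",
    depth = c(45, 31, 30, 29, 12))
  reads <- simulate_cage_reads(toy$genome, tss_truth, barcodes,
                               seed = sub_seed(seed, "cage"))
  dmx <- demultiplex(reads, barcodes,
                     max_mismatch = config$barcode_max_mismatch)
  trimmed <- trim_reads(dmx$assigned$s1, n = config$trim_length)
  pos <- cage_truth_positions(names(trimmed))
  peaks <- call_tss_clusters(pos, merge_window = config$merge_window)
  kept <- filter_peaks(peaks, min_reads = config$min_peak_reads)
  expected <- tss_truth$pos[tss_truth$depth >= config$min_peak_reads]
  checks <- .check(checks, "tss_recovered_at_depth_30", nrow(kept),
                   setequal(kept$mode_position, expected))
  prom <- extract_promoters(kept, toy$genome,
                            upstream = config$promoter_upstream,
                            downstream = config$promoter_downstream)
  checks <- .check(checks, "promoter_width_300",
                   unique(prom$end - prom$start),
                   all(prom$end - prom$start ==
                         config$promoter_upstream +
                         config$promoter_downstream))
  tables$tss_peaks <- kept

  ## stage 3: repeat fold-change KS scan with planted HERVH shift
  loci <- make_locus_table()
  ct <- simulate_counts(loci, delta = c(LTR7 = 1, `HERVH-int` = 1),
                        seed = sub_seed(seed, "counts"))
  lfc <- log2_fold_change(ct, pseudocount = config$pseudocount)
  ks <- subfamily_ks_scan(lfc, loci, reference = "background")
  tables$ks_scan <- ks
  d_hervh <- ks$D[ks$group == "LTR7/HERVH"]
  p_hervh <- ks$p[ks$group == "LTR7/HERVH"]
  d_bgsub <- ks$D[ks$group %in% c("LINE", "SINE", "MERs")]
  checks <- .check(checks, "ks_hervh_p_below_1e6", p_hervh, p_hervh < 1e-6)
  checks <- .check(checks, "ks_hervh_d_dominates", d_hervh,
                   all(d_hervh > d_bgsub))

  ## stage 4: peak enrichment over LTR repeats, planted factor 5
  sizes <- stats::setNames(nchar(toy$genome), names(toy$genome))
  ltr <- toy$repeats[toy$repeats$class == "LTR", ]
  pk <- simulate_peaks(ltr, sizes, n_peaks = 400, peak_length = 200,
                       enrichment_factor = 5,
                       seed = sub_seed(seed, "peaks"))
  enr <- peak_feature_enrichment(pk, ltr, sizes, n_perm = config$n_perm,
                                 seed = sub_seed(seed, "perm"))
  tables$enrichment <- enr
  checks <- .check(checks, "enrichment_score_positive", enr$score,
                   enr$score > 0)
  checks <- .check(checks, "enrichment_perm_p_significant", enr$perm_p,
                   enr$perm_p <= 0.01)

  ## stage 5: HERVH-lncRNA overlap and fold-change correlation
  pairs <- lncrna_hervh_overlap(toy$genes, toy$repeats)
  checks <- .check(checks, "lncrna_pairs_found", nrow(pairs),
                   nrow(pairs) >= 1)
  hl <- simulate_hervh_lnc_dataset(n_units = 56, rho = 0.5,
                                   seed = sub_seed(seed, "lnc"))
  ulfc <- log2_fold_change(pool_unit_counts(hl$counts),
                           pseudocount = config$pseudocount)
  llfc <- log2_fold_change(hl$lnc_counts, pseudocount = config$pseudocount)
  hc <- hervh_lncrna_correlation(hl$pairs, ulfc, llfc)
  tables$hervh_lnc <- hc[c("R", "p", "n")]
  checks <- .check(checks, "hervh_lnc_correlation_recovered", hc$R,
                   abs(hc$R - 0.5) < 0.25)

  ## stage 6: cross-knockdown fold-change correlation, planted rho = -0.6
  xk <- simulate_cross_kd(n_loci = 500, rho = -0.6,
                          seed = sub_seed(seed, "crosskd"))
  cc <- cross_kd_correlation(log2_fold_change(xk$a),
                             log2_fold_change(xk$b))
  tables$cross_kd <- cc
  checks <- .check(checks, "cross_kd_correlation_recovered", cc$R,
                   abs(cc$R - (-0.6)) < 0.1)

  ## stage 7: paired-LTR dating, planted divergence recovery
  units <- find_full_length_units(toy$repeats,
                                  gap_tolerance = config$gap_tolerance)
  checks <- .check(checks, "full_length_units_detected", nrow(units),
                   nrow(units) == nrow(toy$units))
  dated <- date_ltr_units(units, toy$genome, rate = config$evolution_rate)
  tables$dating <- dated
  k_mean <- mean(dated$K[dated$flag == "ok"])
  checks <- .check(checks, "k2p_mean_recovered", k_mean,
                   abs(k_mean - toy$units$k_true[1]) <
                     0.5 * toy$units$k_true[1])

  ## stage 8: young-vs-old divergence group comparison (planted)
  grp <- simulate_age_expression_cohort(n_per_group = 50,
                                        seed = sub_seed(seed, "cohort"))
  cmp <- compare_divergence_groups(grp$T_years, grp$expression, top_n = 50)
  tables$divergence_groups <- cmp
  checks <- .check(checks, "young_units_more_expressed", cmp$p,
                   cmp$p < 1e-6 && cmp$median_top < cmp$median_bottom)

  report <- do.call(rbind, checks)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report, file.path(out_dir, "self_checks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tables$ks_scan, file.path(out_dir, "ks_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tables$dating, file.path(out_dir, "ltr_dating.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tables$tss_peaks, file.path(out_dir, "tss_peaks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (error_on_failure && !all(report$pass))
    stop("self-check failed: ",
         paste(report$check[!report$pass], collapse = ", "))
  list(checks = report, tables = tables, config = config)
}

#' Simulate a HERVH-unit / overlapping-lncRNA expression dataset
#'
#' Unit-level planted log2 fold changes are drawn normally; each overlapping
#' lncRNA's planted effect correlates with its unit's at level `rho`. Counts
#' for the unit segments (two LTR7 plus one internal locus per unit) and the
#' lncRNAs are then simulated independently.
#'
#' @param n_units Number of full-length units, each overlapped by one
#'   lncRNA.
#' @param rho Planted unit-lncRNA effect correlation.
#' @param delta_mean,delta_sd Distribution of unit effects.
#' @param seed Optional RNG seed.
#' @return List: `counts` (segment-level `count_table` with `unit_id`),
#'   `lnc_counts` (lncRNA `count_table`), `pairs`, `delta` matrix.
#' @export
simulate_hervh_lnc_dataset <- function(n_units = 56, rho = 0.5,
                                       delta_mean = 1, delta_sd = 0.8,
                                       seed = NULL) {
  with_seed(seed, {
    z1 <- stats::rnorm(n_units)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_units)
    unit_delta <- delta_mean + delta_sd * z1
    lnc_delta <- delta_mean + delta_sd * z2
    uid <- sprintf("unit_%03d", seq_len(n_units))
    seg <- data.frame(
      locus_id = paste0(rep(uid, each = 3), c("_ltr5", "_int", "_ltr3")),
      class = "LTR", family = "ERV1",
      subfamily = rep(c("LTR7", "HERVH-int", "LTR7"), n_units),
      unit_id = rep(uid, each = 3), stringsAsFactors = FALSE)
    counts <- simulate_counts(seg, locus_delta = rep(unit_delta, each = 3),
                              baseline_meanlog = log(200), dispersion = 0.05)
    lnc <- data.frame(locus_id = sprintf("LNC%03d", seq_len(n_units)),
                      class = "gene", family = "gene",
                      subfamily = "lncRNA", stringsAsFactors = FALSE)
    lnc_counts <- simulate_counts(lnc, locus_delta = lnc_delta,
                                  baseline_meanlog = log(200),
                                  dispersion = 0.05)
    list(counts = counts, lnc_counts = lnc_counts,
         pairs = data.frame(gene_id = lnc$locus_id, unit_id = uid,
                            stringsAsFactors = FALSE),
         delta = cbind(unit = unit_delta, lnc = lnc_delta))
  })
}

#' Simulate a cohort of dated units with expression tied to age
#'
#' Half the units are young (low planted divergence) and highly expressed,
#' half old and lowly expressed. Each unit's divergence time is estimated
#' from a freshly generated LTR pair, so the group comparison exercises the
#' full dating stack.
#'
#' @param n_per_group Units per age group.
#' @param k_young,k_old Planted pairwise divergences.
#' @param ltr_length LTR length in bp.
#' @param rate Substitution rate per site per year.
#' @param seed Optional RNG seed.
#' @return Data frame: `unit`, `age_group`, `expression`, `K`, `T_years`.
#' @export
simulate_age_expression_cohort <- function(n_per_group = 200,
                                           k_young = 0.02, k_old = 0.10,
                                           ltr_length = 450,
                                           rate = 1.28e-8, seed = NULL) {
  with_seed(seed, {
    k_true <- rep(c(k_young, k_old), each = n_per_group)
    expr <- c(stats::rlnorm(n_per_group, log(200), 0.5),
              stats::rlnorm(n_per_group, log(5), 0.5))
    K <- vapply(k_true, function(k) {
      pair <- simulate_ltr_pair(ltr_length, k)
      pq <- count_pq(align_pair(pair$ltr5, pair$ltr3))
      tryCatch(k2p_distance(pq$P, pq$Q), k2p_saturation = function(e) NA)
    }, numeric(1))
    data.frame(unit = seq_along(K),
               age_group = rep(c("young", "old"), each = n_per_group),
               expression = expr, K = K,
               T_years = ifelse(is.na(K), NA, divergence_time(K, rate)))
  })
}
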