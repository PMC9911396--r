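#' Construct a validated genomic interval table
#'
#' Intervals are the universal coordinate unit of the package: peaks, repeat
#' loci, gene models and promoter windows are all rows of an interval table.
#' Coordinates are uniformly 0-based half-open (`start` inclusive, `end`
#' exclusive), the BED native convention; GTF input is converted on read.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start Integer vector, 0-based inclusive start positions.
#' @param end Integer vector, 0-based exclusive end positions; must satisfy
#'   `start < end`.
#' @param strand Strand per interval, one of `"+"`, `"-"`, `"."`. Recycled.
#' @param ... Further equal-length columns (e.g. `name`, `score`) carried
#'   through unchanged.
#'
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`
#'   plus any extra columns.
#' @export
#' @examples
#' gintervals("chr1", 10, 20, "+")
gintervals <- function(chrom, start, end, strand = ".", ...) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n)
  start <- rep_len(start, n)
  end <- rep_len(end, n)
  strand <- rep_len(as.character(strand), n)
  df <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  validate_intervals(df)
  df
}

#' Validate an interval table
#'
#' Checks the coordinate invariants: non-empty chromosome names, integral
#' coordinates with `0 <= start < end`, and strand in `{+, -, .}`.
#'
#' @param x A data.frame with `chrom`, `start`, `end` (and optionally
#'   `strand`) columns.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x))
  req <- c("chrom", "start", "end")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("interval table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
    stop("empty or missing chromosome name")
  if (any(!is.finite(x$start)) || any(!is.finite(x$end)) ||
      any(x$start != floor(x$start)) || any(x$end != floor(x$end)))
    stop("interval coordinates must be finite integers")
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) at row ", bad[1],
         ": [", x$start[bad[1]], ", ", x$end[bad[1]], ")")
  if ("strand" %in% names(x) && any(!x$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(x)
}

interval_width <- function(x) x$end - x$start

## Per-chromosome IRanges views of an interval table. Positions are shifted
## to 1-based closed for IRanges; widths are preserved.
.as_iranges_by_chrom <- function(x) {
  sp <- split(seq_len(nrow(x)), x$chrom)
  lapply(sp, function(idx) {
    list(idx = idx,
         ir = IRanges::IRanges(start = x$start[idx] + 1, end = x$end[idx]))
  })
}

#' Find overlapping interval pairs between two tables
#'
#' Reports every (query, subject) pair sharing at least 1 bp on the same
#' chromosome, exactly once, together with the overlap width. Half-open
#' coordinates mean abutting intervals (`end == start`) do not overlap.
#'
#' @param query,subject Interval tables (see [gintervals()]).
#' @param strand_matched If `TRUE`, only pairs with identical `+`/`-` strands
#'   are reported; intervals with strand `"."` never match in this mode.
#'   Default `FALSE` (strand ignored), since repeat annotations may lack
#'   strand.
#' @return A `data.frame` with columns `query` and `subject` (row indices into
#'   the inputs) and `overlap_bp`.
#' @export
overlap_intervals <- function(query, subject, strand_matched = FALSE) {
  validate_intervals(query)
  validate_intervals(subject)
  empty <- data.frame(query = integer(0), subject = integer(0),
                      overlap_bp = numeric(0))
  if (nrow(query) == 0 || nrow(subject) == 0) return(empty)
  qs <- .as_iranges_by_chrom(query)
  ss <- .as_iranges_by_chrom(subject)
  out <- list()
  for (chr in intersect(names(qs), names(ss))) {
    q <- qs[[chr]]; s <- ss[[chr]]
    hits <- IRanges::findOverlaps(q$ir, s$ir, minoverlap = 1L)
    if (length(hits) == 0) next
    qi <- q$idx[S4Vectors::queryHits(hits)]
    si <- s$idx[S4Vectors::subjectHits(hits)]
    ov <- pmin(query$end[qi], subject$end[si]) -
      pmax(query$start[qi], subject$start[si])
    keep <- rep(TRUE, length(qi))
    if (strand_matched) {
      keep <- query$strand[qi] == subject$strand[si] &
        query$strand[qi] %in% c("+", "-")
    }
    out[[chr]] <- data.frame(query = qi[keep], subject = si[keep],
                             overlap_bp = ov[keep])
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$query, res$subject), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Collapse overlapping or bookended intervals
#'
#' Merges, per chromosome, all intervals that overlap by at least 1 bp.
#' Strand is ignored and the merged intervals carry strand `"."`. Used to
#' de-duplicate feature annotations before base-pair ratio computations.
#'
#' @param x Interval table.
#' @return Interval table of disjoint merged intervals, sorted by chromosome
#'   and start.
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0) return(gintervals(character(0), numeric(0), numeric(0)))
  parts <- lapply(split(x, x$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1, d$end))
    data.frame(chrom = d$chrom[1], start = IRanges::start(ir) - 1,
               end = IRanges::end(ir), strand = ".",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, parts)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Total base pairs covered by an interval set after merging
#'
#' @param x Interval table.
#' @return Number of distinct genomic bases covered.
#' @export
covered_bp <- function(x) {
  m <- merge_intervals(x)
  sum(interval_width(m))
}
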