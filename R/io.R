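#' Read a multi-record FASTA file
#'
#' Sequences are uppercased and restricted to the alphabet `{A,C,G,T,N}`;
#' record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, one uppercase sequence per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- withCallingHandlers(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    warning = function(w) stop("malformed FASTA in ", path, ": ",
                               conditionMessage(w)))
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA record with empty header in ", path)
  empty <- which(!nzchar(seqs))
  if (length(empty))
    stop("FASTA record '", ids[empty[1]], "' has an empty sequence")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("FASTA record '", ids[which(bad)[1]],
         "' contains characters outside {A,C,G,T,N}")
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(unname(as.character(seqs)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  invisible(path)
}

#' Read a BED3-BED6 file
#'
#' Coordinates are kept in BED's native 0-based half-open convention. A
#' missing strand column yields strand `"."`; a missing name or score column
#' yields `NA`.
#'
#' @param path Path to a tab-separated BED file.
#' @return Interval table with `name` and `score` columns.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines))
    return(gintervals(character(0), numeric(0), numeric(0),
                      name = character(0), score = numeric(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED line ", which(nf < 3)[1], " has fewer than 3 fields")
  get <- function(i, default) vapply(fields, function(f)
    if (length(f) >= i) f[i] else default, character(1))
  start <- suppressWarnings(as.numeric(get(2, NA_character_)))
  end <- suppressWarnings(as.numeric(get(3, NA_character_)))
  if (any(is.na(start)) || any(is.na(end)) ||
      any(start != floor(start)) || any(end != floor(end)))
    stop("non-integer coordinate in BED file at line ",
         which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))[1])
  bad <- which(start >= end)
  if (length(bad))
    stop("BED line ", bad[1], ": start >= end (", start[bad[1]], " >= ",
         end[bad[1]], ")")
  strand <- get(6, ".")
  strand[!strand %in% c("+", "-")] <- "."
  score <- suppressWarnings(as.numeric(get(5, NA_character_)))
  gintervals(get(1, NA_character_), start, end, strand,
             name = get(4, NA_character_), score = score)
}

#' Write an interval table as BED6
#'
#' Round-trips coordinates and strands bit-exactly with [read_bed()].
#'
#' @param x Interval table; optional `name` and `score` columns are used for
#'   BED columns 4-5 (defaults `"."` and 0).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  name <- if ("name" %in% names(x)) ifelse(is.na(x$name), ".", x$name) else "."
  score <- if ("score" %in% names(x)) ifelse(is.na(x$score), 0, x$score) else 0
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, as.integer(x$start),
                   as.integer(x$end), name, format(score, trim = TRUE),
                   x$strand)
  writeLines(lines, path)
  invisible(path)
}

.BIOTYPES <- c("protein_coding", "lncRNA")

#' Read a GTF gene annotation
#'
#' GTF's 1-based closed coordinates are converted to the package's 0-based
#' half-open convention (`start - 1`, `end`). Only `gene`, `transcript`,
#' `exon` and `three_prime_utr` features are retained. The `gene_id`
#' attribute is required; `transcript_id` and a biotype attribute
#' (`gene_type`, `gene_biotype`, `transcript_type` or `biotype`) are parsed
#' when present. Biotypes other than `protein_coding` and `lncRNA` collapse
#' to `"other"`.
#'
#' @param path Path to a GTF file.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `feature_kind`, `gene_id`, `transcript_id`, `biotype`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  keep_kinds <- c("gene", "transcript", "exon", "three_prime_utr")
  recs <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) stop("GTF line ", i, " has fewer than 9 fields")
    kind <- f[3]
    if (!kind %in% keep_kinds) next
    start1 <- suppressWarnings(as.numeric(f[4]))
    end1 <- suppressWarnings(as.numeric(f[5]))
    if (is.na(start1) || is.na(end1))
      stop("GTF line ", i, ": non-numeric coordinates")
    attrs <- f[9]
    gid <- .gtf_attr(attrs, "gene_id")
    if (is.na(gid)) stop("GTF line ", i, ": missing gene_id attribute")
    tid <- .gtf_attr(attrs, "transcript_id")
    bt <- NA_character_
    for (key in c("gene_type", "gene_biotype", "transcript_type", "biotype")) {
      bt <- .gtf_attr(attrs, key)
      if (!is.na(bt)) break
    }
    if (is.na(bt) || !bt %in% .BIOTYPES) bt <- "other"
    recs[[length(recs) + 1L]] <- data.frame(
      chrom = f[1], start = start1 - 1, end = end1,
      strand = if (f[7] %in% c("+", "-")) f[7] else ".",
      feature_kind = kind, gene_id = gid, transcript_id = tid, biotype = bt,
      stringsAsFactors = FALSE)
  }
  if (!length(recs))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      feature_kind = character(0), gene_id = character(0),
                      transcript_id = character(0), biotype = character(0)))
  out <- do.call(rbind, recs)
  validate_intervals(out)
  out
}

.gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, ' "([^"]*)"'), attrs))[[1]]
  if (length(m) == 2) m[2] else NA_character_
}

#' Write a gene annotation table as GTF
#'
#' Converts back from 0-based half-open to GTF's 1-based closed coordinates.
#'
#' @param x Annotation table as returned by [read_gtf()].
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(x, path, source = "retrokit") {
  validate_intervals(x)
  attrs <- sprintf('gene_id "%s";', x$gene_id)
  has_tid <- !is.na(x$transcript_id)
  attrs[has_tid] <- paste0(attrs[has_tid],
                           sprintf(' transcript_id "%s";',
                                   x$transcript_id[has_tid]))
  attrs <- paste0(attrs, sprintf(' gene_type "%s";', x$biotype))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s", x$chrom, source,
                   x$feature_kind, as.integer(x$start) + 1L,
                   as.integer(x$end), x$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Read a 4-line FASTQ file (sequences and ids only)
#'
#' Quality strings are parsed for format validation but not retained.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(toupper(as.character(set)), sub("\\s.*$", "", names(set)))
}

#' Write reads as FASTQ with uniform placeholder qualities
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  writeLines(as.vector(rbind(paste0("@", ids), unname(reads), "+", qual)),
             path)
  invisible(path)
}

#' Read a two-column chromosome sizes table
#'
#' @param path Tab-separated file: chromosome name, length in bp.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "size"),
                         colClasses = c("character", "numeric"))
  if (any(d$size <= 0 | d$size != floor(d$size)))
    stop("chromosome sizes must be positive integers")
  stats::setNames(d$size, d$chrom)
}

#' Reverse-complement DNA sequences
#'
#' @param x Character vector over `{A,C,G,T,N}`.
#' @return Reverse complements, vectorized.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract a genomic subsequence, strand-aware
#'
#' Returns the genome substring covered by `interval`; for strand `"-"` the
#' reverse complement is returned. `N` bases are preserved.
#'
#' @param genome Named character vector of chromosome sequences (as from
#'   [read_fasta()]).
#' @param interval A one-row interval table.
#' @return A single sequence string.
#' @export
extract_sequence <- function(genome, interval) {
  validate_intervals(interval)
  stopifnot(nrow(interval) == 1)
  chrom <- interval$chrom
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  L <- nchar(genome[[chrom]])
  if (interval$start < 0 || interval$end > L)
    stop("interval [", interval$start, ", ", interval$end,
         ") out of bounds for ", chrom, " (length ", L, ")")
  s <- substr(genome[[chrom]], interval$start + 1, interval$end)
  if (identical(interval$strand, "-")) s <- reverse_complement(s)
  s
}
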