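#' Genomic interval tables
#'
#' All coordinates in this package are 0-based, half-open (BED convention):
#' an interval covers bases `start, ..., end - 1`. Browser-style spans
#' (1-based, inclusive) must be converted on input, e.g. with
#' [browser_to_bed()]. An interval table is a plain `data.frame` with at
#' least columns `chrom`, `start`, `end`, optionally `strand` and `name`,
#' kept sorted by `(chrom, start, end)`.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end integer vectors; `0 <= start < end` required.
#' @param strand optional; values in `+`, `-`, `*` (unstranded).
#' @param name optional identifier per interval.
#' @param ... further equal-length columns carried along.
#' @param sort sort by `(chrom, start, end)`? Default `TRUE`.
#' @return a `data.frame` of intervals.
#' @examples
#' gintervals("chr1", c(0, 500), c(100, 900))
#' @export
gintervals <- function(chrom, start, end, strand = NULL, name = NULL, ...,
                       sort = TRUE) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (!is.null(strand)) df$strand <- as.character(strand)
  if (!is.null(name))   df$name <- as.character(name)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  validate_intervals(df)
  if (sort && nrow(df) > 1L)
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname gintervals
#' @param x an interval `data.frame` to check.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$chrom) | !nzchar(x$chrom)))
    stop("chrom must be non-empty")
  if (any(x$start < 0L) || any(x$start >= x$end))
    stop("intervals must satisfy 0 <= start < end")
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  invisible(x)
}

#' Convert 1-based inclusive browser coordinates to 0-based half-open
#'
#' @param chrom,first,last chromosome and 1-based inclusive span
#'   (e.g. the printed form `chr15:60733512-60954051`).
#' @return an interval table.
#' @export
browser_to_bed <- function(chrom, first, last) {
  gintervals(chrom, as.integer(first) - 1L, as.integer(last))
}

#' Overlap, in base pairs, of two intervals
#'
#' Vectorized over rows. Abutting half-open intervals overlap by 0;
#' intervals on different chromosomes overlap by 0.
#'
#' @param a,b interval tables (recycled to a common length).
#' @return non-negative integer vector of shared base pairs.
#' @examples
#' overlap_bp(gintervals("c", 0, 100), gintervals("c", 50, 150))  # 50
#' @export
overlap_bp <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n)
  ib <- rep_len(seq_len(nrow(b)), n)
  ov <- pmin(a$end[ia], b$end[ib]) - pmax(a$start[ia], b$start[ib])
  ov[a$chrom[ia] != b$chrom[ib]] <- 0L
  pmax(0L, as.integer(ov))
}

#' Reciprocal-overlap test
#'
#' TRUE iff the shared span covers at least `fraction` of *both*
#' intervals (the convention used to compare loop calls between sexes).
#'
#' @inheritParams overlap_bp
#' @param fraction required fraction of each interval, in (0, 1].
#' @return logical vector.
#' @export
reciprocal_overlap <- function(a, b, fraction = 0.8) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n)
  ib <- rep_len(seq_len(nrow(b)), n)
  ov <- overlap_bp(a, b)
  ov >= fraction * (a$end[ia] - a$start[ia]) &
    ov >= fraction * (b$end[ib] - b$start[ib])
}

# Internal: IRanges overlap hits between two interval tables.
# Returns data.frame(query, subject) of row indices with >= minoverlap bp.
interval_hits <- function(query, subject, minoverlap = 1L) {
  if (nrow(query) == 0L || nrow(subject) == 0L)
    return(data.frame(query = integer(), subject = integer()))
  out_q <- integer(0); out_s <- integer(0)
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    qr <- IRanges::IRanges(query$start[qi] + 1L, query$end[qi])
    sr <- IRanges::IRanges(subject$start[si] + 1L, subject$end[si])
    h <- IRanges::findOverlaps(qr, sr, minoverlap = minoverlap)
    out_q <- c(out_q, qi[S4Vectors::queryHits(h)])
    out_s <- c(out_s, si[S4Vectors::subjectHits(h)])
  }
  data.frame(query = out_q, subject = out_s)
}

# Internal: does each query interval overlap any subject interval (>= 1 bp)?
overlaps_any <- function(query, subject, minoverlap = 1L) {
  res <- logical(nrow(query))
  h <- interval_hits(query, subject, minoverlap)
  res[unique(h$query)] <- TRUE
  res
}

# Internal: number of subject intervals overlapped by each query.
count_overlaps <- function(query, subject, minoverlap = 1L) {
  h <- interval_hits(query, subject, minoverlap)
  out <- integer(nrow(query))
  if (nrow(h)) {
    tb <- table(h$query)
    out[as.integer(names(tb))] <- as.integer(tb)
  }
  out
}

#' Distance to the nearest target interval
#'
#' Distance is 0 for overlapping intervals, otherwise the gap in bp
#' between closest edges. Ties are broken by the leftmost target start.
#' Queries with no same-chromosome target get `distance = Inf` and
#' `target = NA` (a sentinel, never an error).
#'
#' @param query interval table of query regions.
#' @param targets interval table of candidate features.
#' @return `data.frame(distance, target)`: gap in bp and the row index of
#'   the chosen target in `targets`.
#' @export
nearest_distance <- function(query, targets) {
  n <- nrow(query)
  dist <- rep(Inf, n)
  tgt <- rep(NA_integer_, n)
  if (nrow(targets) == 0L || n == 0L)
    return(data.frame(distance = dist, target = tgt))
  for (ch in intersect(unique(query$chrom), unique(targets$chrom))) {
    qi <- which(query$chrom == ch)
    ti <- which(targets$chrom == ch)
    ts <- targets$start[ti]; te <- targets$end[ti]
    ord <- order(ts, ti)            # leftmost-start preference on ties
    ts <- ts[ord]; te <- te[ord]; ti <- ti[ord]
    for (q in qi) {
      gap <- pmax(ts - query$end[q], query$start[q] - te)
      gap <- pmax(gap, 0L)
      k <- which.min(gap)           # first minimum = leftmost start
      dist[q] <- gap[k]
      tgt[q] <- ti[k]
    }
  }
  data.frame(distance = dist, target = tgt)
}

#' Read / write BED files
#'
#' Minimal BED3/BED6 support (tab-separated, 0-based half-open), enough
#' for peak, TAD, TSS and enhancer tracks.
#'
#' @param path file path.
#' @return `read_bed`: an interval table (with `name`, `score`, `strand`
#'   when present in the file).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score",
                 "strand")[seq_len(ncol(df))]
  validate_intervals(df)
  df
}

#' @rdname read_bed
#' @param x interval table to write.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  all6 <- c("chrom", "start", "end", "name", "score", "strand")
  # BED columns are positional: keep the longest fully-present prefix
  miss <- which(!all6 %in% names(x))
  keep <- if (length(miss)) all6[seq_len(miss[1L] - 1L)] else all6
  utils::write.table(x[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write FASTA genomes
#'
#' A genome is represented as a named character vector of uppercase
#' sequences, one element per chromosome.
#'
#' @param path file path.
#' @return `read_fasta`: named character vector.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname read_fasta
#' @param genome named character vector of sequences.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write reads as FASTQ
#'
#' @param reads character vector of read sequences.
#' @param path file path.
#' @param ids optional read identifiers.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read%07d", seq_along(reads))
  qual <- vapply(nchar(reads), function(n) strrep("I", n), "")
  writeLines(paste0("@", ids, "\n", reads, "\n+\n", qual), path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  ln[seq(2L, length(ln), by = 4L)]
}
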