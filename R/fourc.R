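#' Restriction fragment map of a genome
#'
#' Scans every chromosome for exact occurrences of the DpnII recognition
#' sequence GATC (overlapping occurrences included) and derives the
#' restriction fragments between consecutive cut starts, plus the
#' chromosome termini. A chromosome with no cut site becomes a single
#' whole-chromosome fragment, flagged in `no_cut`.
#'
#' @param genome named character vector of chromosome sequences.
#' @return object of class `"fragment_map"`: list with `cut_sites`
#'   (named list of 0-based match starts) and `fragments` (interval
#'   table with `id` and `no_cut` columns).
#' @export
build_fragment_map <- function(genome) {
  stopifnot(length(genome) > 0, !is.null(names(genome)))
  cuts <- list()
  frags <- NULL
  for (ch in names(genome)) {
    s <- genome[[ch]]
    m <- gregexpr("GATC", s, fixed = TRUE)[[1]]
    pos <- if (m[1] == -1L) integer(0) else as.integer(m) - 1L
    cuts[[ch]] <- pos
    bounds <- unique(c(0L, pos, nchar(s)))
    bounds <- sort(bounds[bounds <= nchar(s)])
    fr <- data.frame(chrom = ch, start = bounds[-length(bounds)],
                     end = bounds[-1L], stringsAsFactors = FALSE)
    fr$no_cut <- length(pos) == 0L
    frags <- rbind(frags, fr)
  }
  frags$id <- sprintf("%s_f%06d", frags$chrom,
                      stats::ave(seq_len(nrow(frags)), frags$chrom,
                                 FUN = seq_along))
  rownames(frags) <- NULL
  structure(list(cut_sites = cuts, fragments = frags),
            class = "fragment_map")
}

#' @export
print.fragment_map <- function(x, ...) {
  cat("fragment_map:", sum(lengths(x$cut_sites)), "cut sites,",
      nrow(x$fragments), "fragments on", length(x$cut_sites),
      "chromosomes\n")
  invisible(x)
}

#' Reduced genome of cut-site flanks
#'
#' Two entries per cut site: the `flank` bp upstream of the GATC match
#' start and the `flank` bp downstream of the 4-bp recognition sequence,
#' truncated at chromosome boundaries. Each entry records the restriction
#' fragment it lies in (upstream flank: the fragment ending at the cut;
#' downstream flank: the fragment starting at the cut), so mapped reads
#' can be accumulated per fragment.
#'
#' @param genome named character vector of chromosome sequences.
#' @param fragment_map a [build_fragment_map()] result (rebuilt if
#'   `NULL`).
#' @param flank flank length in bp (default 105).
#' @return object of class `"reduced_genome"`: list with `entries`
#'   (data.frame: `chrom`, `start`, `end`, `side`, `cut_index`,
#'   `fragment`, `sequence`) and `flank`.
#' @export
build_reduced_genome <- function(genome, fragment_map = NULL, flank = 105L) {
  if (is.null(fragment_map)) fragment_map <- build_fragment_map(genome)
  fr <- fragment_map$fragments
  entries <- NULL
  for (ch in names(fragment_map$cut_sites)) {
    pos <- fragment_map$cut_sites[[ch]]
    if (!length(pos)) next
    len <- nchar(genome[[ch]])
    frc <- fr[fr$chrom == ch, ]
    up_frag <- frc$id[match(pos, frc$end)]
    dn_frag <- frc$id[match(pos, frc$start)]
    e <- data.frame(chrom = ch,
                    start = c(pmax(0L, pos - flank), pmin(pos + 4L, len)),
                    end = c(pos, pmin(pos + 4L + flank, len)),
                    side = rep(c("upstream", "downstream"), each = length(pos)),
                    cut_index = rep(seq_along(pos), 2L),
                    fragment = c(up_frag, dn_frag),
                    stringsAsFactors = FALSE)
    e <- e[e$end > e$start, , drop = FALSE]
    e$sequence <- substring(genome[[ch]], e$start + 1L, e$end)
    entries <- rbind(entries, e)
  }
  entries <- entries[order(entries$chrom, entries$start, entries$side), ]
  rownames(entries) <- NULL
  structure(list(entries = entries, flank = as.integer(flank)),
            class = "reduced_genome")
}

#' @export
print.reduced_genome <- function(x, ...) {
  cat("reduced_genome:", nrow(x$entries), "flank entries (flank",
      x$flank, "bp)\n")
  invisible(x)
}

# Internal: per-length unique-lookup dictionaries over flank entries.
# For a trimmed read of length L, a forward hit is an entry whose first
# L bases equal the read; a reverse hit is an entry whose last L bases
# equal the reverse complement of the read (a capture read entering the
# fragment from its right cut). A key is usable only if it identifies
# exactly one entry across both orientations.
index_reduced_genome <- function(reduced, lengths) {
  ent <- reduced$entries
  idx <- list()
  for (L in lengths) {
    ok <- nchar(ent$sequence) >= L
    fwd <- substring(ent$sequence[ok], 1L, L)
    rev_ <- revcomp_vec(substring(ent$sequence[ok],
                                  nchar(ent$sequence[ok]) - L + 1L))
    keys <- c(fwd, rev_)
    entry <- rep(which(ok), 2L)
    dup <- keys[duplicated(keys)]
    keep <- !(keys %in% dup)
    idx[[as.character(L)]] <- list(keys = keys[keep], entry = entry[keep])
  }
  idx
}

#' Iteratively map trimmed 4C reads to the reduced genome
#'
#' Exact unique lookup: a read maps when its sequence (or reverse
#' complement) matches exactly one flank entry at the current length.
#' Non-unique or unmapped reads are trimmed from the 3' end by the step
#' (10 nt for reads of 100 nt or longer, 2 nt for shorter reads) and
#' retried, down to a minimum length of 20 nt. This rescues reads that
#' span a second ligation junction.
#'
#' @param reads character vector of primer-stripped reads (typically
#'   105 nt).
#' @param reduced a [build_reduced_genome()] result.
#' @param min_len stop trimming below this read length (default 20).
#' @param step trim step in nt; default 10 for reads >= 100 nt, else 2.
#' @param index optional precomputed [index_reduced_genome] dictionaries
#'   (reused across replicates for speed).
#' @return list with `entry` (per-read matched entry row or `NA`),
#'   `fragment_counts` (named counts per fragment id), `stats`
#'   (per-iteration data.frame: `length`, `mapped`), `n_mapped`.
#' @export
iterative_map <- function(reads, reduced, min_len = 20L, step = NULL,
                          index = NULL) {
  L0 <- max(nchar(reads))
  if (is.null(step)) step <- if (L0 >= 100L) 10L else 2L
  lens <- seq(L0, min_len, by = -step)
  if (is.null(index)) index <- index_reduced_genome(reduced, lens)
  entry <- rep(NA_integer_, length(reads))
  active <- seq_along(reads)
  stats_ <- NULL
  nc <- nchar(reads)
  for (L in lens) {
    if (!length(active)) break
    dict <- index[[as.character(L)]]
    qry <- reads[active]
    trim <- nc[active] > L
    qry[trim] <- substring(qry[trim], 1L, L)
    hit <- match(qry, dict$keys)
    mapped <- !is.na(hit)
    entry[active[mapped]] <- dict$entry[hit[mapped]]
    stats_ <- rbind(stats_, data.frame(length = L, mapped = sum(mapped)))
    active <- active[!mapped]
  }
  frag <- reduced$entries$fragment[entry]
  fragment_counts <- table(factor(frag,
                                  levels = unique(reduced$entries$fragment)))
  list(entry = entry,
       fragment_counts = as.integer(fragment_counts),
       fragment_ids = names(fragment_counts),
       stats = stats_, n_mapped = sum(!is.na(entry)))
}

#' Demultiplex pooled 4C reads by reading primer and trim
#'
#' A read is assigned to a viewpoint iff its first 20 nt exactly match
#' that viewpoint's reading primer; the primer is then removed. Reads of
#' 150 nt are first trimmed by 25 nt from the 3' end so that all
#' libraries yield 105-nt captures.
#'
#' @param reads character vector of raw reads (barcode-split upstream).
#' @param viewpoints list of viewpoint specs, each with `name` and
#'   `reading_primer` (20 nt).
#' @return list with one trimmed read vector per viewpoint name, plus
#'   `unassigned` (count).
#' @export
demultiplex_and_trim <- function(reads, viewpoints) {
  if (!is.null(viewpoints$name)) viewpoints <- list(viewpoints)
  primers <- vapply(viewpoints, `[[`, "", "reading_primer")
  nms <- vapply(viewpoints, `[[`, "", "name")
  if (anyDuplicated(primers)) stop("viewpoints share a reading primer")
  if (any(nchar(primers) != 20L)) stop("reading primers must be 20 nt")
  long <- nchar(reads) >= 150L
  reads[long] <- substring(reads[long], 1L, nchar(reads[long]) - 25L)
  lead <- substring(reads, 1L, 20L)
  out <- list()
  assigned <- logical(length(reads))
  for (k in seq_along(viewpoints)) {
    sel <- lead == primers[k]
    out[[nms[k]]] <- substring(reads[sel], 21L)
    assigned <- assigned | sel
  }
  out$unassigned <- sum(!assigned)
  out
}

#' Per-fragment 4C signal profile
#'
#' @param fragment_counts integer counts named by fragment id, or an
#'   [iterative_map()] result.
#' @param fragment_map a [build_fragment_map()] result.
#' @return object of class `"fourc_profile"`: the fragment table with
#'   `raw` and `rpm` (reads per million mapped for this viewpoint)
#'   columns.
#' @export
fourc_profile <- function(fragment_counts, fragment_map) {
  fr <- fragment_map$fragments
  if (is.list(fragment_counts) && !is.null(fragment_counts$fragment_counts)) {
    cnt <- fragment_counts$fragment_counts
    names(cnt) <- fragment_counts$fragment_ids
    fragment_counts <- cnt
  }
  fr$raw <- 0
  m <- match(names(fragment_counts), fr$id)
  fr$raw[m[!is.na(m)]] <- as.numeric(fragment_counts)[!is.na(m)]
  total <- sum(fr$raw)
  if (total <= 0) stop("profile has zero mapped reads")
  fr$rpm <- fr$raw * 1e6 / total
  structure(fr, class = c("fourc_profile", "data.frame"))
}

#' Median-smooth a 4C profile
#'
#' Sliding window of `window` restriction fragments (genomic order,
#' per chromosome), replacing each fragment's RPM by the window median;
#' windows shrink symmetrically at chromosome ends.
#'
#' @param profile a [fourc_profile()].
#' @param window odd window size in fragments (default 11).
#' @param column which signal column to smooth (default `"rpm"`).
#' @return the profile with a `smoothed` column added.
#' @export
smooth_profile <- function(profile, window = 11L, column = "rpm") {
  if (window %% 2L == 0L) stop("window must be odd")
  x <- profile[[column]]
  sm <- numeric(length(x))
  h0 <- window %/% 2L
  for (ch in unique(profile$chrom)) {
    i <- which(profile$chrom == ch)
    xi <- x[i]
    n <- length(i)
    sm[i] <- vapply(seq_len(n), function(k) {
      h <- min(h0, k - 1L, n - k)   # window always has odd size 2h + 1
      w <- xi[(k - h):(k + h)]
      sort(w, partial = h + 1L)[h + 1L]
    }, 0)
  }
  profile$smoothed <- sm
  profile
}

#' RPM-normalize, merge replicates, and mask the viewpoint
#'
#' Each replicate profile is already RPM-normalized per viewpoint; the
#' merged signal per fragment is the median across replicates of the
#' smoothed RPM. The viewpoint fragment plus `exclusion_frags` flanking
#' fragments on each side are masked (`NA`) before output.
#'
#' @param profiles list of smoothed [fourc_profile()]s (replicates of
#'   one viewpoint and sex).
#' @param viewpoint viewpoint spec (with `fragment`, `exclusion_frags`).
#' @return a merged profile with columns `merged` and `masked`.
#' @export
normalize_and_merge <- function(profiles, viewpoint) {
  keep <- vapply(profiles, function(p) sum(p$raw) > 0, TRUE)
  if (!all(keep)) warning("dropping replicate(s) with zero mapped reads")
  profiles <- profiles[keep]
  if (!length(profiles)) stop("no usable replicates")
  base <- profiles[[1L]]
  col <- if ("smoothed" %in% names(base)) "smoothed" else "rpm"
  mat <- vapply(profiles, function(p) p[[col]], numeric(nrow(base)))
  base$merged <- apply(as.matrix(mat), 1L, stats::median)
  vp_row <- match(viewpoint$fragment, base$id)
  excl <- viewpoint$exclusion_frags
  same <- which(base$chrom == base$chrom[vp_row])
  maskrows <- same[abs(same - vp_row) <= excl]
  base$masked <- FALSE
  base$masked[maskrows] <- TRUE
  base$merged[base$masked] <- NA_real_
  base
}

#' Call 4C interactions against a distance-decay expectation
#'
#' A monotone decay expectation is fitted per side of the viewpoint by
#' least squares of `log(signal + eps)` on `log(distance)`; per-fragment
#' z-scores are residuals divided by a robust scale (1.4826 x MAD), with
#' one-sided p-values and genome-wide BH FDR. Fragments with `z >
#' z_threshold` and `FDR < fdr_threshold` are merged into regions
#' (closing gaps of up to `gap` fragments); region-level significance is
#' additionally evaluated over the region padded by `pad` bp (Stouffer
#' combination of member fragments).
#'
#' @param profile a merged (or single smoothed) profile.
#' @param viewpoint viewpoint spec.
#' @param fdr_threshold,z_threshold call thresholds (defaults 0.05, 3).
#' @param eps pseudo-signal before log (default 0.5).
#' @param min_side minimum usable fragments per side (default 30).
#' @param gap merge gap in fragments (default 2).
#' @param pad region padding for region-level significance (default
#'   2500 bp).
#' @return list with `calls` (region table: `chrom`, `start`, `end`,
#'   `z_score`, `fdr`, `n_fragments`, `region_z`, `region_p`) and
#'   `fragments` (per-fragment `z`, `p`, `fdr`).
#' @export
call_interactions <- function(profile, viewpoint, fdr_threshold = 0.05,
                              z_threshold = 3, eps = 0.5, min_side = 30L,
                              gap = 2L, pad = 2500L) {
  col <- if ("merged" %in% names(profile)) "merged" else
    if ("smoothed" %in% names(profile)) "smoothed" else "rpm"
  fr <- profile[profile$chrom == viewpoint$chrom, , drop = FALSE]
  vp_row <- match(viewpoint$fragment, fr$id)
  mid <- (fr$start + fr$end) / 2
  d <- mid - mid[vp_row]
  usable <- !is.na(fr[[col]]) & abs(d) > 0
  fr$z <- NA_real_
  for (side in c(-1, 1)) {
    i <- which(usable & sign(d) == side)
    if (length(i) < min_side) next
    x <- log(abs(d[i])); y <- log(fr[[col]][i] + eps)
    fit <- stats::lm.fit(cbind(1, x), y)
    res <- fit$residuals
    scale <- stats::mad(res)
    if (scale <= 0) scale <- stats::sd(res)
    # a profile lying exactly on the decay curve has no excess anywhere
    fr$z[i] <- if (scale < 1e-9) 0 else res / scale
  }
  fr$p <- stats::pnorm(fr$z, lower.tail = FALSE)
  tested <- which(!is.na(fr$p))
  fr$fdr <- NA_real_
  fr$fdr[tested] <- bh_fdr(fr$p[tested])
  sig <- which(!is.na(fr$z) & fr$z > z_threshold & fr$fdr < fdr_threshold)
  calls <- NULL
  if (length(sig)) {
    grp <- cumsum(c(1L, diff(sig) > gap + 1L))
    for (g in unique(grp)) {
      rows <- sig[grp == g]
      reg_start <- fr$start[rows[1L]]; reg_end <- fr$end[rows[length(rows)]]
      inpad <- which(!is.na(fr$z) & fr$end > reg_start - pad &
                       fr$start < reg_end + pad)
      region_z <- sum(fr$z[inpad]) / sqrt(length(inpad))
      calls <- rbind(calls,
                     data.frame(chrom = viewpoint$chrom, start = reg_start,
                                end = reg_end,
                                z_score = max(fr$z[rows]),
                                fdr = min(fr$fdr[rows]),
                                n_fragments = length(rows),
                                region_z = region_z,
                                region_p = stats::pnorm(region_z,
                                                        lower.tail = FALSE)))
    }
  }
  if (is.null(calls))
    calls <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), z_score = numeric(0),
                        fdr = numeric(0), n_fragments = integer(0),
                        region_z = numeric(0), region_p = numeric(0))
  list(calls = calls, fragments = fr)
}

#' Sex-differential test of 4C interactions over candidate regions
#'
#' Per region, raw per-replicate counts are summed over the region's
#' fragments, rescaled to a common sequencing depth, and compared
#' between sexes with the overdispersed exact NB count test; BH FDR is
#' applied across regions.
#'
#' @param profiles_m,profiles_f lists of replicate profiles (with `raw`
#'   counts) per sex.
#' @param regions interval table of regions to test.
#' @param dispersion optional NB dispersion (estimated across regions if
#'   `NULL`).
#' @param fdr_threshold differential call threshold (default 0.1).
#' @return the `regions` table with `counts_m`, `counts_f`, `log2_mf`,
#'   `p_value`, `fdr`, `called` columns.
#' @export
compare_sexes <- function(profiles_m, profiles_f, regions,
                          dispersion = NULL, fdr_threshold = 0.1) {
  if (length(profiles_m) < 1L || length(profiles_f) < 1L)
    stop("need at least one replicate per sex")
  region_counts <- function(profiles) {
    vapply(profiles, function(p) {
      hits <- interval_hits(regions, p)
      out <- numeric(nrow(regions))
      if (nrow(hits)) {
        agg <- rowsum(p$raw[hits$subject], hits$query)
        out[as.integer(rownames(agg))] <- agg[, 1L]
      }
      out
    }, numeric(nrow(regions)))
  }
  cm <- as.matrix(region_counts(profiles_m))
  cf <- as.matrix(region_counts(profiles_f))
  tot_m <- vapply(profiles_m, function(p) sum(p$raw), 0)
  tot_f <- vapply(profiles_f, function(p) sum(p$raw), 0)
  depth <- mean(c(tot_m, tot_f))
  cm <- round(sweep(cm, 2L, depth / tot_m, "*"))
  cf <- round(sweep(cf, 2L, depth / tot_f, "*"))
  res <- nb_count_test(cm, cf, dispersion = dispersion)
  out <- regions
  out$counts_m <- res$sum_a
  out$counts_f <- res$sum_b
  out$log2_mf <- res$log2_ratio
  out$p_value <- res$p_value
  out$fdr <- bh_fdr(res$p_value)
  out$called <- out$fdr < fdr_threshold
  attr(out, "fallback_exact") <-
    length(profiles_m) < 2L || length(profiles_f) < 2L
  out
}
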