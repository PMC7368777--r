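#' Call peaks from pooled read coverage
#'
#' A deliberately simple enrichment caller, contract-compatible with
#' imported peak lists (e.g. MACS2 narrowPeak read via [read_bed()]):
#' the genome is tiled in sliding windows, read midpoints are counted,
#' and windows whose count exceeds the uniform background expectation at
#' a Poisson tail p below `p_threshold` are merged into peaks. The
#' summit is the maximum-coverage position at 10-bp resolution.
#'
#' @param samples a read sample (list with `reads`, `total_mapped`) or a
#'   list of them (pooled).
#' @param p_threshold Poisson enrichment p-value cutoff (default 1e-5).
#' @param window,step window size and slide in bp.
#' @param background_rate optional background reads per bp; default:
#'   per-chromosome uniform rate of the pooled sample.
#' @return interval table of peaks with a `summit` column.
#' @export
call_peaks <- function(samples, p_threshold = 1e-5, window = 200L,
                       step = 100L, background_rate = NULL) {
  if (!is.null(samples$reads)) samples <- list(samples)
  reads <- do.call(rbind, lapply(samples, function(s) s$reads))
  if (is.null(reads) || nrow(reads) == 0L)
    return(gintervals(character(0), integer(0), integer(0),
                      summit = integer(0)))
  peaks <- NULL
  for (ch in unique(reads$chrom)) {
    r <- reads[reads$chrom == ch, ]
    mid <- (r$start + r$end) %/% 2L
    len <- max(r$end)
    nb <- ceiling(len / step)
    bins <- tabulate(mid %/% step + 1L, nb)
    wcnt <- bins[-nb] + bins[-1L]
    lambda <- if (is.null(background_rate))
      nrow(r) * window / len else background_rate * window
    pp <- stats::ppois(wcnt - 1L, lambda, lower.tail = FALSE)
    sig <- which(pp < p_threshold)
    if (!length(sig)) next
    grp <- cumsum(c(1L, diff(sig) > 1L))
    for (g in unique(grp)) {
      w <- sig[grp == g]
      ps <- (w[1L] - 1L) * step
      pe <- min((w[length(w)] + 1L) * step, len)
      inpk <- mid[mid >= ps & mid < pe]
      h <- tabulate((inpk - ps) %/% 10L + 1L, ceiling((pe - ps) / 10L))
      peaks <- rbind(peaks, data.frame(chrom = ch, start = ps, end = pe,
                                       summit = ps + (which.max(h) - 1L) * 10L + 5L))
    }
  }
  if (is.null(peaks))
    return(gintervals(character(0), integer(0), integer(0),
                      summit = integer(0)))
  peaks <- peaks[order(peaks$chrom, peaks$start), ]
  rownames(peaks) <- NULL
  peaks
}

#' Remove PCR-artifact and blacklisted peaks
#'
#' A peak is spurious when the reads covering it consist exclusively of
#' five or more identical-coordinate reads with no other overlapping
#' read. Peaks intersecting the optional blacklist are also removed.
#'
#' @param peaks interval table of peaks.
#' @param samples read sample or list of samples (pooled).
#' @param blacklist optional interval table.
#' @param min_identical identical-read threshold (default 5).
#' @return the retained peaks.
#' @export
filter_artifact_peaks <- function(peaks, samples, blacklist = NULL,
                                  min_identical = 5L) {
  if (!is.null(samples$reads)) samples <- list(samples)
  reads <- do.call(rbind, lapply(samples, function(s) s$reads))
  drop <- logical(nrow(peaks))
  hits <- interval_hits(peaks, reads)
  for (i in unique(hits$query)) {
    rr <- reads[hits$subject[hits$query == i], c("start", "end")]
    key <- paste(rr$start, rr$end)
    tb <- table(key)
    drop[i] <- length(tb) == 1L && tb[1L] >= min_identical
  }
  if (!is.null(blacklist) && nrow(blacklist))
    drop <- drop | overlaps_any(peaks, blacklist)
  peaks[!drop, , drop = FALSE]
}

#' RIPM normalization and FRiP quality metric
#'
#' Reads-in-peaks-per-million: browser-style signal is the read count
#' divided by the total number of reads overlapping any union peak, per
#' million; FRiP is reads-in-peaks over total mapped. Normalization is
#' performed separately per factor (pass that factor's union peak list).
#'
#' @param sample a read sample.
#' @param union_peaks union peak list for the sample's factor.
#' @return list with `frip`, `divisor` (reads-in-peaks / 1e6),
#'   `reads_in_peaks`, `total_mapped`.
#' @export
compute_ripm <- function(sample, union_peaks) {
  inpk <- sum(overlaps_any(sample$reads, union_peaks))
  if (inpk == 0L) stop("degenerate sample: no reads in peaks")
  list(frip = inpk / sample$total_mapped, divisor = inpk / 1e6,
       reads_in_peaks = inpk, total_mapped = sample$total_mapped)
}

#' @rdname compute_ripm
#' @param peaks peaks at which to report RIPM-normalized signal.
#' @return `ripm_peak_signal`: per-peak read counts divided by the RIPM
#'   divisor.
#' @export
ripm_peak_signal <- function(sample, peaks, union_peaks = peaks) {
  qc <- compute_ripm(sample, union_peaks)
  count_overlaps(peaks, sample$reads) / qc$divisor
}

# Internal: pool replicate samples of one sex into one merged sample.
merge_samples <- function(samples) {
  reads <- do.call(rbind, lapply(samples, function(s) s$reads))
  reads <- reads[order(reads$chrom, reads$start), ]
  rownames(reads) <- NULL
  list(factor = samples[[1L]]$factor, sex = samples[[1L]]$sex,
       replicate_id = "merged", reads = reads, total_mapped = nrow(reads))
}

#' Sliding-window differential binding test
#'
#' The genome is tiled in `window_size` windows sliding by half a
#' window; per-window replicate counts (read midpoints, rescaled to a
#' common depth) are compared between sexes with the exact
#' negative-binomial test ([nb_count_test()], pooled moment-matched
#' dispersion), and genome-wide BH FDR is attached. Overlapping
#' candidate windows (FDR below `merge_fdr`) of the same direction are
#' merged into sites; each site carries its best window's p/FDR and the
#' recounted reads over the merged span.
#'
#' @param male_reps,female_reps lists of read samples (>= 2 per group
#'   for a replicate-aware test; with 1 vs 1 the same exact test runs at
#'   dispersion 0 and the result is flagged `fallback_exact`).
#' @param window_size window in bp (default 200).
#' @param merge_fdr window FDR below which a window seeds/joins a site
#'   (reporting threshold; final stringency filters are applied by
#'   [filter_standard()]).
#' @param min_total minimum summed count for a window to be tested.
#' @param dispersion optional fixed NB dispersion.
#' @return data.frame of sites: `chrom`, `start`, `end`, `log2_mf`,
#'   `counts_m`, `counts_f`, `p_value`, `fdr`, `n_windows`, `direction`,
#'   `tier = "unfiltered"`.
#' @export
diff_windows <- function(male_reps, female_reps, window_size = 200L,
                         merge_fdr = 0.25, min_total = 5L,
                         dispersion = NULL) {
  step <- window_size %/% 2L
  reps <- c(male_reps, female_reps)
  nm <- length(male_reps); nf <- length(female_reps)
  chroms <- sort(unique(unlist(lapply(reps, function(s) unique(s$reads$chrom)))))
  meta <- NULL; cnt <- NULL
  for (ch in chroms) {
    len <- max(vapply(reps, function(s) {
      r <- s$reads
      if (any(r$chrom == ch)) max(r$end[r$chrom == ch]) else 0L
    }, 0L))
    nb <- ceiling(len / step)
    if (nb < 2L) next
    bins <- vapply(reps, function(s) {
      r <- s$reads[s$reads$chrom == ch, ]
      tabulate(((r$start + r$end) %/% 2L) %/% step + 1L, nb)
    }, integer(nb))
    cnt <- rbind(cnt, bins[-nb, , drop = FALSE] + bins[-1L, , drop = FALSE])
    w <- seq_len(nb - 1L)
    meta <- rbind(meta, data.frame(chrom = ch, start = (w - 1L) * step,
                                   end = pmin((w + 1L) * step, len)))
  }
  # rescale to common depth so the NB test sees comparable libraries
  totals <- vapply(reps, function(s) s$total_mapped, 0)
  cnt <- round(sweep(cnt, 2L, mean(totals) / totals, "*"))
  tot <- rowSums(cnt)
  tested <- which(tot >= min_total)
  res <- nb_count_test(cnt[tested, seq_len(nm), drop = FALSE],
                       cnt[tested, nm + seq_len(nf), drop = FALSE],
                       dispersion = dispersion)
  q <- bh_fdr(res$p_value)
  sites <- NULL
  cand <- which(q < merge_fdr)
  if (length(cand)) {
    rows <- tested[cand]                      # window row indices
    dirn <- sign(res$log2_ratio[cand])
    ord <- order(rows)
    rows <- rows[ord]; cand <- cand[ord]; dirn <- dirn[ord]
    newgrp <- c(TRUE, diff(rows) > 1L | dirn[-1L] != dirn[-length(dirn)] |
                  meta$chrom[rows[-1L]] != meta$chrom[rows[-length(rows)]])
    grp <- cumsum(newgrp)
    for (g in unique(grp)) {
      k <- which(grp == g)
      w <- rows[k]
      best <- k[which.min(res$p_value[cand[k]])]
      site <- data.frame(chrom = meta$chrom[w[1L]],
                         start = meta$start[w[1L]],
                         end = meta$end[w[length(w)]])
      cm <- cf <- 0
      for (j in seq_along(reps)) {
        r <- reps[[j]]$reads
        r <- r[r$chrom == site$chrom, ]
        mids <- (r$start + r$end) %/% 2L
        n <- sum(mids >= site$start & mids < site$end) *
          mean(totals) / totals[j]
        if (j <= nm) cm <- cm + n else cf <- cf + n
      }
      sites <- rbind(sites, data.frame(
        site, log2_mf = log2((cm / nm + 0.5) / (cf / nf + 0.5)),
        counts_m = round(cm), counts_f = round(cf),
        p_value = res$p_value[cand[best]], fdr = q[cand[best]],
        n_windows = length(w),
        direction = if (dirn[best] >= 0) "male-biased" else "female-biased",
        tier = "unfiltered", stringsAsFactors = FALSE))
    }
    sites <- sites[order(sites$chrom, sites$start), ]
    rownames(sites) <- NULL
  }
  if (is.null(sites))
    sites <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), log2_mf = numeric(0),
                        counts_m = numeric(0), counts_f = numeric(0),
                        p_value = numeric(0), fdr = numeric(0),
                        n_windows = integer(0), direction = character(0),
                        tier = character(0), stringsAsFactors = FALSE)
  attr(sites, "dispersion") <- attr(res, "dispersion")
  attr(sites, "fallback_exact") <- nm < 2L || nf < 2L
  sites
}

#' Standard-stringency filter for sex-differential sites
#'
#' Retains sites that overlap the union peak list by at least 1 bp,
#' contain at least `min_reads` sequence reads (summed over all
#' replicates), show more than `fold`-fold sex difference, and have FDR
#' below `fdr`.
#'
#' @param sites [diff_windows()] output.
#' @param union_peaks union peak list for the factor.
#' @param min_reads,fold,fdr the three numeric gates (defaults 10, 2,
#'   0.05).
#' @return the retained sites with `tier = "standard"`.
#' @export
filter_standard <- function(sites, union_peaks, min_reads = 10L,
                            fold = 2, fdr = 0.05) {
  if (nrow(sites) == 0L) return(sites)
  keep <- overlaps_any(sites, union_peaks) &
    (sites$counts_m + sites$counts_f) >= min_reads &
    abs(sites$log2_mf) > log2(fold) &
    sites$fdr < fdr
  out <- sites[keep, , drop = FALSE]
  if (nrow(out)) {
    out$tier <- "standard"
    out$direction <- ifelse(out$log2_mf >= 0, "male-biased", "female-biased")
  }
  rownames(out) <- NULL
  out
}

#' FRiP-match two merged samples by down-sampling
#'
#' The merged sample with the higher reads-in-peaks count is
#' down-sampled by the ratio of the two reads-in-peaks counts so that
#' both sexes carry the same normalized number of reads in peaks.
#' Sampling is seeded and stratified (in-peak and out-of-peak reads
#' subsampled separately in exact proportion), so the matched in-peak
#' counts agree to within one read of rounding.
#'
#' @param sample_m,sample_f merged (pooled-replicate) read samples.
#' @param union_peaks union peak list for the factor.
#' @param seed RNG seed for the subsampling.
#' @return list with `male`, `female` (matched samples), `factor_m`,
#'   `factor_f` (applied down-sampling factors; one of them is 1).
#' @export
frip_downsample <- function(sample_m, sample_f, union_peaks, seed = 1L) {
  in_m <- overlaps_any(sample_m$reads, union_peaks)
  in_f <- overlaps_any(sample_f$reads, union_peaks)
  n_m <- sum(in_m); n_f <- sum(in_f)
  if (n_m == 0L || n_f == 0L) stop("a merged sample has no reads in peaks")
  factor_m <- factor_f <- 1
  if (n_m > n_f) {
    factor_m <- n_f / n_m
    sample_m <- subsample_stratified(sample_m, in_m, factor_m, seed)
  } else if (n_f > n_m) {
    factor_f <- n_m / n_f
    sample_f <- subsample_stratified(sample_f, in_f, factor_f, seed)
  }
  list(male = sample_m, female = sample_f,
       factor_m = factor_m, factor_f = factor_f)
}

# Internal: keep round(f * n) reads within each stratum (in/out of peaks).
subsample_stratified <- function(sample, in_peak, f, seed) {
  set.seed(seed)
  keep <- logical(nrow(sample$reads))
  for (stratum in c(TRUE, FALSE)) {
    i <- which(in_peak == stratum)
    keep[sample(i, round(f * length(i)))] <- TRUE
  }
  sample$reads <- sample$reads[keep, , drop = FALSE]
  rownames(sample$reads) <- NULL
  sample$total_mapped <- nrow(sample$reads)
  sample
}

#' MA rescaling and lenient-stringency differential sites
#'
#' Per peak, M = log2((m + 0.5) / (f + 0.5)) and A = 0.5 log2((m + 0.5)
#' (f + 0.5)) from the FRiP-matched merged samples. A linear fit of M on
#' A over common peaks (occupied in both sexes), after trimming the
#' extreme M tails, is subtracted to rescale M; p-values come from a
#' normal approximation on the rescaled log-ratio. Peaks passing the
#' fold / adjusted-p / read-count gates that do not overlap a
#' standard-tier site are the lenient tier.
#'
#' @param matched_m,matched_f FRiP-matched merged samples (from
#'   [frip_downsample()]).
#' @param peaks union peak list to evaluate.
#' @param standard_sites standard-tier sites to exclude (may be `NULL`).
#' @param fold,padj_threshold,min_reads gates (defaults 2, 0.01, 15;
#'   `min_reads` applies to the upregulated sex's count).
#' @param occupancy_min minimum count in both sexes for a peak to be a
#'   common (rescaling) peak.
#' @param min_common minimum number of common peaks for a usable fit.
#' @param trim total fraction of extreme M values trimmed before the fit.
#' @return list with `ma` (per-peak `a_value`, `m_value`, `m_rescaled`,
#'   `counts_m`, `counts_f`, `p_value`, `padj`, `common`), `sites`
#'   (lenient-tier site table), `fit` (intercept/slope).
#' @export
manorm_lenient <- function(matched_m, matched_f, peaks,
                           standard_sites = NULL, fold = 2,
                           padj_threshold = 0.01, min_reads = 15L,
                           occupancy_min = 10L, min_common = 10L,
                           trim = 0.05) {
  m <- count_overlaps(peaks, matched_m$reads)
  f <- count_overlaps(peaks, matched_f$reads)
  M <- log2((m + 0.5) / (f + 0.5))
  A <- 0.5 * log2((m + 0.5) * (f + 0.5))
  common <- m >= occupancy_min & f >= occupancy_min
  if (sum(common) < min_common)
    stop("insufficient common peaks for MA rescaling")
  ci <- which(common)
  ntrim <- floor(trim / 2 * length(ci))
  if (ntrim > 0) {
    ord <- ci[order(M[ci])]
    ci <- sort(ord[(ntrim + 1L):(length(ord) - ntrim)])
  }
  fit <- stats::lm(M[ci] ~ A[ci])
  co <- unname(stats::coef(fit))
  m_rescaled <- M - (co[1L] + co[2L] * A)
  sd_log2 <- sqrt(1 / (m + 0.5) + 1 / (f + 0.5)) / log(2)
  p <- 2 * stats::pnorm(-abs(m_rescaled) / sd_log2)
  padj <- bh_fdr(p)
  ma <- data.frame(peaks[, c("chrom", "start", "end")],
                   a_value = A, m_value = M, m_rescaled = m_rescaled,
                   counts_m = m, counts_f = f, p_value = p, padj = padj,
                   common = common)
  up_count <- ifelse(m_rescaled >= 0, m, f)
  sel <- abs(m_rescaled) > log2(fold) & padj < padj_threshold &
    up_count > min_reads
  if (!is.null(standard_sites) && nrow(standard_sites))
    sel <- sel & !overlaps_any(ma, standard_sites)
  sites <- ma[sel, , drop = FALSE]
  if (nrow(sites)) {
    sites$log2_mf <- sites$m_rescaled
    sites$fdr <- sites$padj
    sites$direction <- ifelse(sites$m_rescaled >= 0, "male-biased",
                              "female-biased")
    sites$tier <- "lenient"
  }
  rownames(sites) <- NULL
  list(ma = ma, sites = sites, fit = co)
}

#' Sex-independent peak set
#'
#' Ranks peaks by how close their male/female RIPM-normalized signal
#' ratio is to 1 (ascending absolute log ratio, ties broken by stronger
#' total signal) and returns the first `n`.
#'
#' @param peaks interval table of peaks.
#' @param signal_m,signal_f per-peak RIPM-normalized merged signal.
#' @param n peaks to return (default 1000; if fewer exist all are
#'   returned, flagged in the `"truncated"` attribute).
#' @return the selected peaks with `ratio_mf` column, ranked.
#' @export
sex_independent_set <- function(peaks, signal_m, signal_f, n = 1000L) {
  eps <- 1e-9
  ratio <- (signal_m + eps) / (signal_f + eps)
  ord <- order(abs(log(ratio)), -(signal_m + signal_f))
  sel <- ord[seq_len(min(n, nrow(peaks)))]
  out <- peaks[sel, , drop = FALSE]
  out$ratio_mf <- ratio[sel]
  rownames(out) <- NULL
  attr(out, "truncated") <- n > nrow(peaks)
  out
}

#' Strict / lenient stringency bands for sex-biased marks
#'
#' For MA-style differential peaks of a histone mark or DHS: significant
#' peaks (adjusted p below `padj_threshold`, upregulated count above
#' `min_reads`) are banded by fold-change: above `strict_fold` is
#' strict, between `lenient_fold` and `strict_fold` is lenient,
#' otherwise none.
#'
#' @param ma per-peak MA table (from [manorm_lenient()]`$ma`).
#' @param padj_threshold,min_reads significance gates (defaults 0.05,
#'   15).
#' @param strict_fold,lenient_fold band boundaries (defaults 2.5, 1.5).
#' @return the table with a `band` column in `strict`, `lenient`,
#'   `none`.
#' @export
stringency_bands <- function(ma, padj_threshold = 0.05, min_reads = 15L,
                             strict_fold = 2.5, lenient_fold = 1.5) {
  fold <- 2^abs(ma$m_rescaled)
  up_count <- ifelse(ma$m_rescaled >= 0, ma$counts_m, ma$counts_f)
  sig <- ma$padj < padj_threshold & up_count > min_reads
  ma$band <- ifelse(!sig, "none",
                    ifelse(fold > strict_fold, "strict",
                           ifelse(fold > lenient_fold, "lenient", "none")))
  ma
}
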