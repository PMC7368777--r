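#' Build loop-anchor candidates from CAC peaks
#'
#' Each CAC peak is scanned for the CTCF motif; the best-scoring motif
#' (ties: leftmost, `+` strand first) assigns the anchor orientation.
#' Peaks without a motif scoring above the presence threshold are not
#' anchor candidates.
#'
#' @param cac_peaks peak table; a `strength` column (combined
#'   normalized CTCF + cohesin signal) is carried through (default 1).
#' @param genome named character vector of sequences.
#' @param pwm CTCF PWM (default [ctcf_pwm()]).
#' @param threshold motif presence cutoff, strict (default 10).
#' @return anchor table: the peak columns plus `orientation`,
#'   `motif_start`, `motif_score`, `strength`.
#' @export
build_anchors <- function(cac_peaks, genome, pwm = ctcf_pwm(),
                          threshold = 10) {
  if (is.null(cac_peaks$strength)) cac_peaks$strength <- 1
  out <- NULL
  for (i in seq_len(nrow(cac_peaks))) {
    p <- cac_peaks[i, ]
    s <- substring(genome[[p$chrom]], p$start + 1L, p$end)
    hits <- scan_pwm(s, pwm, threshold, chrom = p$chrom)
    if (nrow(hits) == 0L) next
    hits <- hits[order(-hits$score, hits$start, hits$strand), ]
    best <- hits[1L, ]
    p$orientation <- best$strand
    p$motif_start <- p$start + best$start
    p$motif_score <- best$score
    out <- rbind(out, p)
  }
  if (is.null(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), orientation = character(0),
                      motif_start = integer(0), motif_score = numeric(0),
                      strength = numeric(0)))
  rownames(out) <- NULL
  out
}

# Internal: TRUE if intervals (s1,e1) and (s2,e2) partially cross
# (overlap without nesting; shared endpoints count as nesting).
loops_cross <- function(s1, e1, s2, e2) {
  ov <- pmin(e1, e2) - pmax(s1, s2)
  nested <- (s1 <= s2 & e2 <= e1) | (s2 <= s1 & e1 <= e2)
  ov > 0 & !nested
}

#' Predict intra-TAD loops from convergent anchors
#'
#' Candidate loops are all anchor pairs within one TAD with the
#' upstream anchor on `+` and the downstream anchor on `-` (convergent
#' CTCF motifs). Each candidate is scored by the geometric mean of its
#' anchor strengths times a span penalty `exp(-span / lambda)`. The top
#' `initial_count` candidates are then accepted greedily in score
#' order, allowing nested loops but rejecting partial crossings within
#' a TAD. Anchors may be shared by several accepted loops.
#'
#' @param anchors [build_anchors()] output.
#' @param tads TAD table; an anchor belongs to a TAD when fully inside
#'   it.
#' @param initial_count candidate pool size (default 20000;
#'   effectively unlimited on toy genomes).
#' @param lambda span-penalty scale in bp (default 200 kb, the scale of
#'   the ~151 kb median loop).
#' @return loop table: `chrom`, `start`, `end` (anchor5 start to
#'   anchor3 end), `start5`, `end5`, `start3`, `end3`, `score`, `span`,
#'   `tad`, sorted by score.
#' @export
predict_loops <- function(anchors, tads, initial_count = 20000L,
                          lambda = 200000) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), start5 = integer(0),
                      end5 = integer(0), start3 = integer(0),
                      end3 = integer(0), score = numeric(0),
                      span = numeric(0), tad = character(0))
  if (nrow(anchors) == 0L) return(empty)
  if (is.null(tads$name)) tads$name <- sprintf("tad%d", seq_len(nrow(tads)))
  cands <- NULL
  for (t in seq_len(nrow(tads))) {
    a <- anchors[anchors$chrom == tads$chrom[t] &
                   anchors$start >= tads$start[t] &
                   anchors$end <= tads$end[t], , drop = FALSE]
    if (nrow(a) < 2L) next
    a <- a[order(a$start), ]
    up <- which(a$orientation == "+")
    dn <- which(a$orientation == "-")
    for (i in up) for (j in dn) {
      if (a$start[i] >= a$start[j]) next
      span <- a$end[j] - a$start[i]
      cands <- rbind(cands, data.frame(
        chrom = tads$chrom[t], start = a$start[i], end = a$end[j],
        start5 = a$start[i], end5 = a$end[i],
        start3 = a$start[j], end3 = a$end[j],
        score = sqrt(a$strength[i] * a$strength[j]) * exp(-span / lambda),
        span = span, tad = tads$name[t], stringsAsFactors = FALSE))
    }
  }
  if (is.null(cands)) return(empty)
  cands <- cands[order(-cands$score, cands$span, cands$start), ]
  cands <- cands[seq_len(min(nrow(cands), initial_count)), , drop = FALSE]
  acc <- integer(0)
  for (i in seq_len(nrow(cands))) {
    same <- acc[cands$tad[acc] == cands$tad[i]]
    if (!length(same) ||
        !any(loops_cross(cands$start[i], cands$end[i],
                         cands$start[same], cands$end[same])))
      acc <- c(acc, i)
  }
  out <- cands[acc, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare two loop sets by reciprocal overlap
#'
#' A loop in one set is shared when some loop in the other set overlaps
#' it reciprocally by at least `fraction` of both spans; sharing is
#' reported in both directions.
#'
#' @param loops_a,loops_b loop tables (anchor-to-anchor spans).
#' @param fraction reciprocal-overlap fraction (default 0.8).
#' @return list with logical `shared_a`, `shared_b` and percentages
#'   `pct_a_shared`, `pct_b_shared`.
#' @export
compare_loop_sets <- function(loops_a, loops_b, fraction = 0.8) {
  shared_flags <- function(x, y) {
    out <- logical(nrow(x))
    h <- interval_hits(x, y)
    if (nrow(h)) {
      ok <- reciprocal_overlap(x[h$query, , drop = FALSE],
                               y[h$subject, , drop = FALSE], fraction)
      out[unique(h$query[ok])] <- TRUE
    }
    out
  }
  sa <- shared_flags(loops_a, loops_b)
  sb <- shared_flags(loops_b, loops_a)
  list(shared_a = sa, shared_b = sb,
       pct_a_shared = 100 * mean(sa), pct_b_shared = 100 * mean(sb))
}

#' Overlap of loop anchors with sex-differential sites
#'
#' Flags each differential site that coincides (>= 1 bp) with a loop
#' anchor.
#'
#' @param anchors anchor table (anchor intervals `start`..`end`, or a
#'   loop table whose `start5/end5`, `start3/end3` columns are
#'   expanded).
#' @param diff_sites differential site table.
#' @return `diff_sites` with `overlaps_anchor` flag; total in the
#'   `"n_overlapping"` attribute.
#' @export
anchors_vs_diff_sites <- function(anchors, diff_sites) {
  if (!is.null(anchors$start5))
    anchors <- data.frame(
      chrom = rep(anchors$chrom, 2L),
      start = c(anchors$start5, anchors$start3),
      end = c(anchors$end5, anchors$end3))
  diff_sites$overlaps_anchor <- overlaps_any(diff_sites, anchors)
  attr(diff_sites, "n_overlapping") <- sum(diff_sites$overlaps_anchor)
  diff_sites
}
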