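# Independent brute-force oracles used to verify the optimized
# implementations. These deliberately share no code with the package
# internals.

# Linear-scan nearest target with leftmost-start tie-break.
brute_nearest <- function(q_chrom, q_start, q_end, targets) {
  best_d <- Inf
  best_i <- NA_integer_
  for (i in seq_len(nrow(targets))) {
    if (targets$chrom[i] != q_chrom) next
    gap <- max(targets$start[i] - q_end, q_start - targets$end[i], 0)
    better <- gap < best_d ||
      (gap == best_d && !is.na(best_i) &&
         targets$start[i] < targets$start[best_i])
    if (is.na(best_i) || better) {
      best_d <- gap
      best_i <- i
    }
  }
  list(distance = best_d, target = best_i)
}

# Per-window PWM scoring on both strands, one window at a time.
brute_scan <- function(sequence, pwm, threshold) {
  w <- pwm$width
  n <- nchar(sequence) - w + 1L
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- NULL
  if (n < 1L) return(out)
  for (i in seq_len(n)) {
    win <- strsplit(substring(sequence, i, i + w - 1L), "")[[1]]
    for (strand in c("+", "-")) {
      bases <- if (strand == "+") win else rev(unname(comp[win]))
      if (any(!bases %in% c("A", "C", "G", "T"))) next
      sc <- sum(pwm$log_odds[cbind(match(bases, c("A", "C", "G", "T")),
                                   seq_len(w))])
      if (sc > threshold)
        out <- rbind(out, data.frame(start = i - 1L, strand = strand,
                                     score = sc))
    }
  }
  out
}

# Hand-rolled BH step-up.
brute_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  running <- 1
  for (k in n:1) {
    running <- min(running, n * p[ord[k]] / k)
    q[ord[k]] <- running
  }
  q
}

# Windowed median with symmetric shrink at the ends.
brute_median_smooth <- function(x, k) {
  h <- k %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    hh <- min(h, i - 1L, n - i)
    stats::median(x[(i - hh):(i + hh)])
  }, 0)
}

# Independent greedy loop selection: all convergent pairs per TAD,
# scored and accepted in score order unless partially crossing an
# accepted loop (O(n^2) scans, no shared code).
oracle_loops <- function(anchors, tads, lambda = 200000) {
  cands <- NULL
  for (t in seq_len(nrow(tads))) {
    inside <- anchors[anchors$chrom == tads$chrom[t] &
                        anchors$start >= tads$start[t] &
                        anchors$end <= tads$end[t], ]
    if (nrow(inside) < 2L) next
    for (i in seq_len(nrow(inside))) for (j in seq_len(nrow(inside))) {
      if (inside$orientation[i] != "+" || inside$orientation[j] != "-") next
      if (inside$start[i] >= inside$start[j]) next
      span <- inside$end[j] - inside$start[i]
      cands <- rbind(cands, data.frame(
        tad = t, start = inside$start[i], end = inside$end[j],
        score = sqrt(inside$strength[i] * inside$strength[j]) *
          exp(-span / lambda), span = span))
    }
  }
  if (is.null(cands)) return(cands)
  cands <- cands[order(-cands$score, cands$span, cands$start), ]
  acc <- NULL
  for (i in seq_len(nrow(cands))) {
    ok <- TRUE
    if (!is.null(acc)) for (j in seq_len(nrow(acc))) {
      if (acc$tad[j] != cands$tad[i]) next
      s1 <- cands$start[i]; e1 <- cands$end[i]
      s2 <- acc$start[j]; e2 <- acc$end[j]
      overlap <- min(e1, e2) > max(s1, s2)
      nested <- (s1 <= s2 && e2 <= e1) || (s2 <= s1 && e1 <= e2)
      if (overlap && !nested) { ok <- FALSE; break }
    }
    if (ok) acc <- rbind(acc, cands[i, ])
  }
  acc
}

# All-pairs reciprocal-overlap sharing flags.
brute_shared <- function(a, b, fraction) {
  vapply(seq_len(nrow(a)), function(i) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= fraction * (a$end[i] - a$start[i]) &&
          ov >= fraction * (b$end[j] - b$start[j])) return(TRUE)
    }
    FALSE
  }, TRUE)
}

# Shared tiny truth used by several test files (built once per run).
tiny_truth <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- make_genome(sim_config(n_chroms = 1L, chrom_length = 200000L,
                                     n_tads = 2L, n_motifs = 12L,
                                     n_genes = 18L, n_cnc = 6L, n_lone = 6L,
                                     chip_background = 8000L, seed = 11L))
    val
  }
})
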