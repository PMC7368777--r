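#' Position weight matrices and motif scanning
#'
#' A PWM here is a log2 likelihood-ratio matrix (4 rows, A/C/G/T) versus
#' a background base composition, the scoring used by FIMO-style motif
#' scanners. A window's score is the sum of per-position log2 ratios;
#' motif presence is conventionally a score above a fixed cutoff
#' (`> 10` for the CTCF core motif throughout this package).
#'
#' @param probs 4 x W matrix of per-position base probabilities, rows
#'   named A, C, G, T, columns the motif positions.
#' @param background length-4 base frequencies (sum to 1). Default
#'   uniform.
#' @param pseudo small probability added before log to keep log-odds
#'   finite.
#' @return an object of class `"pwm"`: list with `log_odds` (4 x W),
#'   `width`, `background`.
#' @export
make_pwm <- function(probs, background = rep(0.25, 4), pseudo = 1e-4) {
  stopifnot(is.matrix(probs), nrow(probs) == 4L)
  if (is.null(rownames(probs))) rownames(probs) <- c("A", "C", "G", "T")
  probs <- probs[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(background <= 0) || abs(sum(background) - 1) > 1e-9)
    stop("background frequencies must be > 0 and sum to 1")
  probs <- sweep(probs + pseudo, 2, colSums(probs + pseudo), "/")
  lo <- log2(probs / background)
  if (any(!is.finite(lo))) stop("non-finite log-odds")
  structure(list(log_odds = lo, width = ncol(lo), background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM: width", x$width, "\nconsensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (highest log-odds base per position)
#' @param pwm a `"pwm"` object.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$log_odds)[apply(pwm$log_odds, 2, which.max)],
        collapse = "")
}

#' CTCF core-motif PWM used by the synthetic genome
#'
#' A 19-bp CTCF-like motif built from the canonical core consensus with
#' per-position probability `p` on the consensus base. The consensus
#' contains a CpG, so planted sites carry the CpG flag tested downstream.
#'
#' @param p probability of the consensus base at each position (default
#'   0.85, an information-rich motif whose planted instances score well
#'   above the `> 10` presence cutoff).
#' @return a `"pwm"` object.
#' @export
ctcf_pwm <- function(p = 0.85) {
  cons <- strsplit("TGGCCACCAGGGGGCGCTA", "")[[1]]
  probs <- matrix((1 - p) / 3, 4, length(cons),
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  probs[cbind(match(cons, rownames(probs)), seq_along(cons))] <- p
  make_pwm(probs)
}

# Internal: reverse complement of a character sequence (ACGTN).
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                ""))
}

# Internal: score every window of `seq_chars` (integer-coded 1..4, NA for N)
# against log-odds matrix; returns numeric vector of window scores
# (-Inf where the window contains an N).
score_windows <- function(code, lo) {
  w <- ncol(lo)
  n <- length(code) - w + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  bad <- logical(n)
  for (j in seq_len(w)) {
    cj <- code[j:(j + n - 1L)]
    na <- is.na(cj)
    bad <- bad | na
    cj[na] <- 1L
    sc <- sc + lo[cbind(cj, j)]
  }
  sc[bad] <- -Inf
  sc
}

#' Scan a sequence with a PWM on both strands
#'
#' Every window with score strictly above `threshold` is reported, on
#' either strand (the minus strand is scored on the reverse complement).
#' Windows containing `N` are disqualified. Hits are returned in
#' coordinate order; the same window may be reported on both strands.
#'
#' @param sequence a nucleotide string over A/C/G/T/N, or a named genome
#'   vector (scanned per chromosome).
#' @param pwm a `"pwm"` object.
#' @param threshold minimum score, strict inequality (default 10).
#' @param chrom chromosome label used when `sequence` is a bare string.
#' @return interval table of hits with columns `chrom`, `start`, `end`,
#'   `strand`, `score`, `contains_cpg`.
#' @export
scan_pwm <- function(sequence, pwm, threshold = 10, chrom = "seq") {
  stopifnot(inherits(pwm, "pwm"))
  if (length(sequence) > 1L || !is.null(names(sequence))) {
    if (is.null(names(sequence))) names(sequence) <- paste0("chr", seq_along(sequence))
    out <- do.call(rbind, lapply(names(sequence), function(ch)
      scan_pwm(unname(sequence[ch]), pwm, threshold, chrom = ch)))
    return(out)
  }
  w <- pwm$width
  empty <- gintervals(character(0), integer(0), integer(0),
                      strand = character(0), score = numeric(0),
                      contains_cpg = logical(0))
  if (nchar(sequence) < w) return(empty)
  chars <- strsplit(toupper(sequence), "")[[1]]
  code <- match(chars, c("A", "C", "G", "T"))   # N -> NA
  fwd <- score_windows(code, pwm$log_odds)
  # minus strand: score the reverse complement of each window; equivalent
  # to scanning with the reverse-complemented matrix
  lo_rc <- pwm$log_odds[4:1, rev(seq_len(w)), drop = FALSE]
  rownames(lo_rc) <- c("A", "C", "G", "T")
  rev_ <- score_windows(code, lo_rc)
  hits <- list()
  for (str in c("+", "-")) {
    sc <- if (str == "+") fwd else rev_
    k <- which(sc > threshold)
    if (length(k)) {
      sub <- substring(sequence, k, k + w - 1L)
      hits[[str]] <- data.frame(chrom = chrom, start = k - 1L,
                                end = k - 1L + w, strand = str,
                                score = sc[k],
                                contains_cpg = grepl("CG", sub, fixed = TRUE),
                                stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
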