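#' Shared statistical helpers
#'
#' Thin, contract-checked wrappers around the standard tests used
#' throughout the analyses: Benjamini-Hochberg FDR for every
#' multiple-testing family (applied genome-wide), a two-sample
#' Kolmogorov-Smirnov test for comparing distributions (e.g. distance
#' CDFs), and a two-tailed Mann-Whitney test for comparing values.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return `bh_fdr`: q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' @rdname bh_fdr
#' @param x,y numeric samples, each of size >= 2.
#' @return `ks_test` / `mann_whitney`: list with `statistic`, `p_value`.
#' @export
ks_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples must have size >= 2")
  res <- suppressWarnings(stats::ks.test(x, y))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' @rdname bh_fdr
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples must have size >= 2")
  # exact for small tie-free samples, normal approximation otherwise
  res <- suppressWarnings(stats::wilcox.test(x, y))
  p <- unname(res$p.value)
  if (is.nan(p)) p <- 1   # fully tied samples carry no evidence
  list(statistic = unname(res$statistic), p_value = p)
}

#' Exact negative-binomial test for two groups of replicate counts
#'
#' The windowed differential-binding test: per feature (window, peak or
#' region), replicate counts are modelled as NB with common dispersion
#' `phi` (variance = mu + phi * mu^2). Group sums are then NB with size
#' `n_g / phi`, and equality of means is tested exactly by enumerating
#' the conditional distribution of the split of the observed total
#' between groups, summing the probability of outcomes as or less likely
#' than the observed one (Robinson-Smyth style double tail).
#'
#' @param counts_a,counts_b matrices, features x replicates, for the two
#'   groups (vectors are treated as single features).
#' @param dispersion NB dispersion; if `NULL`, a pooled moment estimate
#'   across features is used (see [estimate_dispersion()]).
#' @param max_enum totals above this are tested with a Wald
#'   approximation on the log ratio instead of exact enumeration.
#' @return data.frame with `sum_a`, `sum_b`, `log2_ratio` (a vs b,
#'   pseudocount 0.5), `p_value`, and the `dispersion` used (attribute).
#' @export
nb_count_test <- function(counts_a, counts_b, dispersion = NULL,
                          max_enum = 10000L) {
  if (is.null(dim(counts_a))) counts_a <- matrix(counts_a, nrow = 1L)
  if (is.null(dim(counts_b))) counts_b <- matrix(counts_b, nrow = 1L)
  stopifnot(nrow(counts_a) == nrow(counts_b))
  n_a <- ncol(counts_a); n_b <- ncol(counts_b)
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(cbind(counts_a, counts_b),
                                      groups = rep(c("a", "b"), c(n_a, n_b)))
  phi <- max(dispersion, 1e-8)
  sa <- rowSums(counts_a); sb <- rowSums(counts_b)
  tt <- sa + sb
  p <- rep(1, length(tt))
  frac_a <- n_a / (n_a + n_b)
  enum <- which(tt > 0 & tt <= max_enum)
  if (length(enum)) {
    te <- tt[enum]
    idx <- rep.int(seq_along(te), te + 1L)
    x <- sequence(te + 1L) - 1L
    mu_a <- te * frac_a
    mu_b <- te - mu_a
    size_a <- n_a / phi; size_b <- n_b / phi
    ll <- stats::dnbinom(x, size = size_a, mu = mu_a[idx], log = TRUE) +
      stats::dnbinom(te[idx] - x, size = size_b, mu = mu_b[idx], log = TRUE)
    obs <- stats::dnbinom(sa[enum], size = size_a, mu = mu_a, log = TRUE) +
      stats::dnbinom(sb[enum], size = size_b, mu = mu_b, log = TRUE)
    pr <- exp(ll)
    num <- rowsum(pr * (ll <= obs[idx] + 1e-12), idx, reorder = TRUE)
    den <- rowsum(pr, idx, reorder = TRUE)
    p[enum] <- pmin(1, num / den)
  }
  big <- which(tt > max_enum)
  if (length(big)) {
    # Wald on log ratio of group means; delta-method variance of log-sum
    la <- log((sa[big] + 0.5) / n_a); lb <- log((sb[big] + 0.5) / n_b)
    va <- 1 / (sa[big] + 0.5) + phi / n_a
    vb <- 1 / (sb[big] + 0.5) + phi / n_b
    z <- (la - lb) / sqrt(va + vb)
    p[big] <- 2 * stats::pnorm(-abs(z))
  }
  out <- data.frame(sum_a = sa, sum_b = sb,
                    log2_ratio = log2((sa / n_a + 0.5) / (sb / n_b + 0.5)),
                    p_value = p)
  attr(out, "dispersion") <- phi
  out
}

#' Pooled moment estimate of NB dispersion
#'
#' Per feature and group, the method-of-moments dispersion
#' `(s^2 - xbar) / xbar^2` is computed from replicate counts; estimates
#' from features with group mean >= `min_mean` are averaged (negatives
#' floored at zero after pooling).
#'
#' @param counts features x replicates count matrix.
#' @param groups group label per column.
#' @param min_mean minimum group mean for a feature to contribute.
#' @return scalar dispersion >= 0.
#' @export
estimate_dispersion <- function(counts, groups, min_mean = 5) {
  ests <- numeric(0)
  for (g in unique(groups)) {
    m <- counts[, groups == g, drop = FALSE]
    if (ncol(m) < 2L) next
    mu <- rowMeans(m)
    v <- apply(m, 1L, stats::var)
    ok <- mu >= min_mean
    if (any(ok)) ests <- c(ests, (v[ok] - mu[ok]) / mu[ok]^2)
  }
  if (!length(ests)) return(0)
  max(0, mean(ests))
}
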