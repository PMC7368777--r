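make_sample <- function(chrom, starts, len = 50L, factor = "CTCF",
                        sex = "M") {
  reads <- data.frame(chrom = rep_len(chrom, length(starts)),
                      start = as.integer(starts),
                      end = as.integer(starts + len))
  reads <- reads[order(reads$chrom, reads$start), ]
  list(factor = factor, sex = sex, replicate_id = "r1", reads = reads,
       total_mapped = nrow(reads))
}

test_that("peak calling finds planted enrichment and little else", {
  set.seed(61)
  # uniform background only: no peaks expected at p < 1e-5
  bg <- make_sample("chr1", sample(0:199950, 4000, TRUE))
  expect_lte(nrow(call_peaks(bg)), 1L)
  # one 50-fold enriched kilobase
  enr <- make_sample("chr1", c(sample(0:199950, 2000, TRUE),
                               sample(100000:100999, 500, TRUE)))
  pk <- call_peaks(enr)
  expect_equal(nrow(pk), 1L)
  expect_true(pk$start <= 100000 && pk$end >= 101000)
  expect_true(pk$summit >= 100000 && pk$summit < 101000)
  # empty input
  expect_equal(nrow(call_peaks(make_sample("chr1", integer(0)))), 0L)
})

test_that("artifact filter implements the identical-read rule exactly", {
  pk <- gintervals("chr1", c(1000, 5000, 9000), c(1400, 5400, 9400))
  reads <- rbind(
    data.frame(chrom = "chr1", start = rep(1100L, 7), end = rep(1150L, 7)),
    data.frame(chrom = "chr1", start = c(rep(5100L, 7), 5120L),
               end = c(rep(5150L, 7), 5170L)),
    data.frame(chrom = "chr1", start = rep(9100L, 4), end = rep(9150L, 4)))
  s <- list(reads = reads, total_mapped = nrow(reads))
  kept <- filter_artifact_peaks(pk, s)
  # 7 identical only -> removed; +1 offset read -> kept; 4 identical -> kept
  expect_equal(kept$start, c(5000L, 9000L))
  # blacklist removal
  kept2 <- filter_artifact_peaks(pk, s, blacklist = gintervals("chr1", 9000, 9400))
  expect_equal(kept2$start, 5000L)
})

test_that("RIPM normalization is scale-invariant and FRiP is correct", {
  set.seed(62)
  peaks <- gintervals("chr1", 10000, 12000)
  inpk <- sample(10000:11950, 400, TRUE)
  outpk <- sample(20000:199000, 1600, TRUE)
  s <- make_sample("chr1", c(inpk, outpk))
  qc <- compute_ripm(s, peaks)
  expect_equal(qc$frip, 0.2)
  expect_equal(qc$divisor, sum(sexbias3d:::overlaps_any(s$reads, peaks)) / 1e6)
  # doubling depth with same in-peak proportion leaves RIPM signal fixed
  s2 <- make_sample("chr1", c(inpk, inpk, outpk, outpk))
  expect_equal(ripm_peak_signal(s2, peaks), ripm_peak_signal(s, peaks))
  # background-only sample has low FRiP
  bg <- make_sample("chr1", sample(0:199000, 5000, TRUE))
  expect_lte(compute_ripm(bg, peaks)$frip, 0.05)
  expect_error(compute_ripm(make_sample("chr2", 1:10 * 100), peaks),
               "degenerate")
})

test_that("windowed differential test finds planted effects, not nulls", {
  tr <- tiny_truth()
  reps <- simulate_chip_replicates(tr, "CTCF", 3L, 3L, seed = 63L)
  sites <- diff_windows(reps[1:3], reps[4:6])
  peaks <- call_peaks(reps)
  std <- filter_standard(sites, peaks)
  planted <- tr$peaks[tr$peaks$factor %in% c("both", "ctcf_only") &
                        tr$peaks$sex_bias != "none", ]
  unplanted <- tr$peaks[tr$peaks$factor %in% c("both", "ctcf_only") &
                          tr$peaks$sex_bias == "none", ]
  expect_gte(sum(sexbias3d:::overlaps_any(planted, std)),
             ceiling(0.8 * nrow(planted)))
  expect_lte(sum(sexbias3d:::overlaps_any(unplanted, std)), 1L)
  # directions match the planted sex
  hits <- sexbias3d:::interval_hits(planted, std)
  dir_ok <- ifelse(planted$sex_bias[hits$query] == "M", "male-biased",
                   "female-biased") == std$direction[hits$subject]
  expect_true(all(dir_ok))
})

test_that("standard-stringency filter applies all four gates strictly", {
  peaks <- gintervals("chr1", 1000, 2000)
  site <- function(start, counts_m, counts_f, log2_mf, fdr)
    data.frame(chrom = "chr1", start = start, end = start + 200L,
               log2_mf = log2_mf, counts_m = counts_m, counts_f = counts_f,
               p_value = fdr / 2, fdr = fdr, n_windows = 1L,
               direction = ifelse(log2_mf >= 0, "male-biased", "female-biased"),
               tier = "unfiltered")
  pass <- site(1100, 60, 10, log2(6), 0.001)
  expect_equal(nrow(filter_standard(pass, peaks)), 1L)
  expect_equal(filter_standard(pass, peaks)$tier, "standard")
  # single-violation boundary fixtures
  fails <- rbind(
    site(1100, 6, 3, log2(6), 0.001),        # 9 reads (< 10)
    site(1100, 55, 45, log2(55 / 45), 0.001),# 1.2-fold (<= 2)
    site(1100, 60, 10, 1, 0.001),            # exactly 2-fold (not > 2)
    site(1100, 60, 10, log2(6), 0.08),       # FDR 0.08 (>= 0.05)
    site(1100, 60, 10, log2(6), 0.05),       # FDR exactly 0.05
    site(5000, 60, 10, log2(6), 0.001))      # no union-peak overlap
  for (i in seq_len(nrow(fails)))
    expect_equal(nrow(filter_standard(fails[i, ], peaks)), 0L)
  justpass <- rbind(
    site(1100, 7, 3, log2(6), 0.001),        # exactly 10 reads
    site(1100, 60, 10, log2(2.05), 0.001),   # just over 2-fold
    site(1100, 60, 10, log2(6), 0.049),      # just under FDR 0.05
    site(801, 60, 10, log2(6), 0.001))       # 1 bp overlap with the peak
  expect_equal(nrow(filter_standard(justpass, peaks)), 4L)
})

test_that("FRiP down-sampling equalizes reads in peaks exactly", {
  set.seed(64)
  peaks <- gintervals("chr1", 10000, 15000)
  sm <- make_sample("chr1", c(sample(10000:14950, 5000, TRUE),
                              sample(30000:190000, 7000, TRUE)), sex = "M")
  sf <- make_sample("chr1", c(sample(10000:14950, 3730, TRUE),
                              sample(30000:190000, 6000, TRUE)), sex = "F")
  ds <- frip_downsample(sm, sf, peaks, seed = 1)
  expect_equal(ds$factor_m, 3730 / 5000)
  expect_equal(ds$factor_f, 1)
  in_m <- sum(sexbias3d:::overlaps_any(ds$male$reads, peaks))
  in_f <- sum(sexbias3d:::overlaps_any(ds$female$reads, peaks))
  expect_lte(abs(in_m - in_f) / max(in_m, in_f), 0.001)
  # equal samples are untouched
  ds2 <- frip_downsample(sm, sm, peaks, seed = 1)
  expect_equal(ds2$factor_m, 1)
  expect_equal(nrow(ds2$male$reads), nrow(sm$reads))
})

test_that("MA rescaling recenters depth imbalance and flags planted bias", {
  set.seed(65)
  n <- 120
  starts <- seq(5000, by = 3000, length.out = n)
  peaks <- gintervals("chr1", starts, starts + 600)
  base <- rpois(n, 80)
  mk_reads <- function(counts) {
    i <- rep.int(seq_len(n), counts)
    make_sample("chr1", starts[i] + sample(0:550, length(i), TRUE))
  }
  # symmetric samples: fit ~ 0, no lenient sites
  sm <- mk_reads(base); sf <- mk_reads(base)
  r <- manorm_lenient(sm, sf, peaks)
  expect_lt(abs(r$fit[1]), 0.3)
  expect_equal(nrow(r$sites), 0L)
  # pure 2x depth imbalance: M recentred near zero, few false positives
  sm2 <- mk_reads(rpois(n, 2 * base))
  r2 <- manorm_lenient(sm2, sf, peaks)
  expect_lt(abs(median(r2$ma$m_rescaled[r2$ma$common])), 0.1)
  expect_lte(nrow(r2$sites), ceiling(0.05 * n))
  # a planted 3-fold peak missing from the standard tier comes out lenient
  b3 <- base; b3[5] <- 3 * base[5]
  r3 <- manorm_lenient(mk_reads(b3), sf, peaks)
  expect_true(starts[5] %in% r3$sites$start)
  # degenerate input: too few common peaks
  tiny <- gintervals("chr1", 5000, 5600)
  expect_error(manorm_lenient(sm, sf, tiny), "common peaks")
})

test_that("sex-independent set ranks by ratio closeness with signal ties", {
  peaks <- gintervals("chr1", c(0, 1000, 2000), c(500, 1500, 2500))
  sel <- sex_independent_set(peaks, signal_m = c(1.0, 1.1, 0.5),
                             signal_f = c(1.0, 1.0, 1.0), n = 2)
  expect_equal(sel$start, c(0L, 1000L))
  # ratio exactly 1 ranks first even among strong peaks
  sel2 <- sex_independent_set(peaks, c(10, 5, 8), c(10, 2, 9), n = 1)
  expect_equal(sel2$start, 0L)
  # |log ratio| symmetry: swapping labels selects the same peaks
  set.seed(66)
  m <- runif(50, 0.5, 2); f <- runif(50, 0.5, 2)
  big <- gintervals("chr1", 1:50 * 1000, 1:50 * 1000 + 500)
  s1 <- sex_independent_set(big, m, f, n = 10)
  s2 <- sex_independent_set(big, f, m, n = 10)
  expect_equal(sort(s1$start), sort(s2$start))
  # n larger than available: all returned, flagged
  s3 <- sex_independent_set(peaks, c(1, 1, 1), c(1, 1, 1), n = 10)
  expect_equal(nrow(s3), 3L)
  expect_true(attr(s3, "truncated"))
})

test_that("stringency bands follow the strict/lenient fold boundaries", {
  ma <- data.frame(chrom = "chr1", start = 1:4 * 100, end = 1:4 * 100 + 50,
                   m_rescaled = log2(c(3.0, 2.0, 3.0, 1.2)),
                   counts_m = c(40, 40, 40, 40), counts_f = c(5, 5, 5, 5),
                   padj = c(0.01, 0.01, 0.2, 0.01))
  b <- stringency_bands(ma)
  expect_equal(b$band, c("strict", "lenient", "none", "none"))
})
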