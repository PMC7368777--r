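test_that("genome generation is reproducible and validates its config", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 100000L, n_tads = 2L,
                    n_motifs = 8L, n_genes = 9L, seed = 5L)
  t1 <- make_genome(cfg)
  t2 <- make_genome(cfg)
  expect_identical(t1$genome, t2$genome)
  expect_identical(t1$peaks, t2$peaks)
  expect_identical(t1$interactions, t2$interactions)
  expect_error(make_genome(sim_config(chrom_length = 10000L, n_tads = 3L)),
               "too small")
  expect_error(sim_config(junction_fraction = 1.5))
})

test_that("planted motifs are recovered by PWM scanning at threshold 10", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 500000L, n_tads = 5L,
                    n_motifs = 50L, n_genes = 9L, seed = 21L)
  tr <- make_genome(cfg)
  expect_gte(nrow(tr$motifs), 50L)
  hits <- scan_pwm(tr$genome, tr$pwm, 10)
  key <- paste(hits$chrom, hits$start, hits$strand)
  found <- paste(tr$motifs$chrom, tr$motifs$start, tr$motifs$strand) %in% key
  expect_gte(sum(found), nrow(tr$motifs) - 2L)
  # chance hits are rare: well under one per 10 kb scanned
  expect_lt(nrow(hits) - sum(found), 2 * nchar(tr$genome[[1]]) / 10000)
})

test_that("planted loops are convergent anchor pairs within one TAD", {
  tr <- tiny_truth()
  for (i in seq_len(nrow(tr$loops))) {
    lp <- tr$loops[i, ]
    tad <- tr$tads[tr$tads$name == lp$tad, ]
    expect_true(lp$start >= tad$start && lp$end <= tad$end)
    m5 <- tr$motifs[tr$motifs$chrom == lp$chrom & tr$motifs$start == lp$start, ]
    m3 <- tr$motifs[tr$motifs$chrom == lp$chrom & tr$motifs$end == lp$end, ]
    expect_equal(m5$strand, "+")
    expect_equal(m3$strand, "-")
  }
})

test_that("ChIP counts follow the planted negative-binomial model", {
  # dispersion -> 0 approaches Poisson (variance ~ mean)
  cfg <- sim_config(n_chroms = 1L, chrom_length = 100000L, n_tads = 2L,
                    n_motifs = 6L, n_genes = 9L, nb_dispersion = 1e-6,
                    sex_biased_frac = 0, chip_background = 1000L, seed = 31L)
  tr <- make_genome(cfg)
  reps <- simulate_chip_replicates(tr, "CTCF", 10L, 0L, seed = 1)
  pk <- tr$peaks[tr$peaks$factor %in% c("both", "ctcf_only"), ]
  counts <- vapply(reps[1:10], function(s)
    sexbias3d:::count_overlaps(pk, s$reads), numeric(nrow(pk)))
  vmr <- apply(counts, 1, var) / rowMeans(counts)
  expect_lt(median(vmr), 1.6)
  # planted 4-fold male bias recovered in the count ratio
  cfg2 <- sim_config(n_chroms = 1L, chrom_length = 100000L, n_tads = 2L,
                     n_motifs = 6L, n_genes = 9L, sex_effect_fold = 4,
                     sex_biased_frac = 0.5, chip_background = 1000L,
                     seed = 32L)
  tr2 <- make_genome(cfg2)
  pk2 <- tr2$peaks[tr2$peaks$factor %in% c("both", "ctcf_only"), ]
  male_pk <- pk2[pk2$sex_bias == "M", ]
  ratios <- replicate(15, {
    reps <- simulate_chip_replicates(tr2, "CTCF", 4L, 4L,
                                     seed = sample.int(1e6, 1))
    cm <- rowSums(vapply(reps[1:4], function(s)
      sexbias3d:::count_overlaps(male_pk, s$reads), numeric(nrow(male_pk))))
    cf <- rowSums(vapply(reps[5:8], function(s)
      sexbias3d:::count_overlaps(male_pk, s$reads), numeric(nrow(male_pk))))
    mean(cm / pmax(cf, 1))
  })
  expect_gte(mean(ratios), 3)
  expect_lte(mean(ratios), 5)
  # null configuration: no planted differential sites
  cfg3 <- sim_config(n_chroms = 1L, chrom_length = 100000L, n_tads = 2L,
                     n_motifs = 6L, n_genes = 9L, sex_biased_frac = 0,
                     seed = 33L)
  expect_true(all(make_genome(cfg3)$peaks$fold == 1))
})

test_that("4C reads respect decay, junction and determinism contracts", {
  tr <- tiny_truth()
  s1 <- simulate_4c_reads(tr, sex = "M", n_reads = 5000L, seed = 41L)
  s2 <- simulate_4c_reads(tr, sex = "M", n_reads = 5000L, seed = 41L)
  expect_identical(s1$reads, s2$reads)
  expect_equal(mean(s1$truth$junction), tr$config$junction_fraction,
               tolerance = 0.1)
  # a steep decay keeps nearly all captures near the viewpoint
  cfg <- tr$config
  cfg$decay_exponent <- 3
  cfg$fourc_decay_sd <- 0
  tr_steep <- tr
  tr_steep$config <- cfg
  ss <- simulate_4c_reads(tr_steep, sex = "M", n_reads = 20000L, seed = 42L)
  fr <- tr$fragments[match(ss$truth$fragment, tr$fragments$id), ]
  vp <- tr$fragments[match(tr$viewpoint$fragment, tr$fragments$id), ]
  d <- abs((fr$start + fr$end) / 2 - (vp$start + vp$end) / 2)
  expect_gte(mean(d <= 100000), 0.95)
  # junction-free reads all map full length without iterative trimming
  cfg0 <- tr$config
  cfg0$junction_fraction <- 0
  tr0 <- tr
  tr0$config <- cfg0
  s0 <- simulate_4c_reads(tr0, sex = "M", n_reads = 3000L, seed = 43L)
  rg <- build_reduced_genome(tr$genome)
  trimmed <- demultiplex_and_trim(s0$reads, tr$viewpoint)[[tr$viewpoint$name]]
  mp <- iterative_map(trimmed, rg)
  expect_gte(mp$stats$mapped[1] / length(trimmed), 0.99)
})

test_that("planted 4C enrichment appears at the expected magnitude", {
  tr <- tiny_truth()
  cfg <- tr$config
  cfg$fourc_fold_sd <- 0
  cfg$fourc_decay_sd <- 0
  trf <- tr
  trf$config <- cfg
  ss <- simulate_4c_reads(trf, sex = "M", n_reads = 200000L, seed = 44L)
  fr <- tr$fragments[tr$fragments$chrom == "chr1", ]
  vp_row <- match(tr$viewpoint$fragment, fr$id)
  mid <- (fr$start + fr$end) / 2
  d <- pmax(abs(mid - mid[vp_row]), 1000)
  prob <- d^(-tr$config$decay_exponent)
  prob[abs(seq_len(nrow(fr)) - vp_row) <= tr$viewpoint$exclusion_frags] <- 0
  both <- tr$interactions[tr$interactions$sex == "both", ][1, ]
  inblock <- fr$start >= both$start & fr$end <= both$end
  cnt <- table(factor(ss$truth$fragment, levels = fr$id))
  # observed / decay-expected ratio inside the block is ~ the planted fold
  ratio <- (sum(cnt[inblock]) / sum(cnt)) /
    (sum(prob[inblock]) / sum(prob))
  expect_gte(ratio, both$fold / 2)
  expect_lte(ratio, both$fold * 2)
})

test_that("expression simulation recovers planted suppression folds", {
  tr <- tiny_truth()
  ex <- simulate_expression(tr, 4L, 4L, sigma = 0.05, seed = 51L)
  rel <- relative_to_wt(ex)
  dep <- rowMeans(rel$ratios[, rel$condition == "depleted"])
  distal <- tr$expression$group == "distal"
  expect_gte(median(dep[distal]), 0.08)
  expect_lte(median(dep[distal]), 0.125)
  # null effect: group medians ~ 1
  trn <- tr
  trn$expression$suppression <- 1
  exn <- simulate_expression(trn, 4L, 4L, sigma = 0.05, seed = 52L)
  reln <- relative_to_wt(exn)
  depn <- rowMeans(reln$ratios[, reln$condition == "depleted"])
  expect_equal(median(depn), 1, tolerance = 0.1)
  # degenerate gene with zero WT mean stays finite downstream
  trz <- tr
  trz$expression$wt_mean[1] <- 0
  exz <- simulate_expression(trz, 4L, 4L, seed = 53L)
  relz <- relative_to_wt(exz)
  expect_true(all(is.finite(relz$ratios[1, ])))
})
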