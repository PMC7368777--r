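test_that("fragment map records every GATC occurrence", {
  fm <- build_fragment_map(c(chr1 = "AAGATCAA"))
  expect_equal(fm$cut_sites$chr1, 2L)
  expect_equal(fm$fragments$start, c(0L, 2L))
  expect_equal(fm$fragments$end, c(2L, 8L))
  fm2 <- build_fragment_map(c(chr1 = "GATCGATC"))
  expect_equal(fm2$cut_sites$chr1, c(0L, 4L))
  # no cut site: one whole-chromosome fragment, flagged
  fm3 <- build_fragment_map(c(chr1 = "AAAAAAAA"))
  expect_equal(nrow(fm3$fragments), 1L)
  expect_true(fm3$fragments$no_cut)
  # random 100 kb sequence against a direct per-position scan
  set.seed(91)
  s <- paste(sample(c("A", "C", "G", "T"), 100000, TRUE), collapse = "")
  fm4 <- build_fragment_map(c(chrX = s))
  direct <- which(vapply(1:(100000 - 3),
                         function(i) substring(s, i, i + 3) == "GATC",
                         TRUE)) - 1L
  expect_equal(fm4$cut_sites$chrX, direct)
  expect_true(all(diff(fm4$fragments$start) > 0))
  expect_equal(fm4$fragments$end[-nrow(fm4$fragments)],
               fm4$fragments$start[-1L])  # fragments tile the chromosome
})

test_that("reduced genome flanks follow the 105-bp construction rule", {
  set.seed(92)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  s <- paste0(substring(s, 1, 150), "GATC", substring(s, 155))
  # remove other chance GATCs so the arithmetic is exact
  while (length(gregexpr("GATC", s, fixed = TRUE)[[1]]) > 1 ||
         gregexpr("GATC", s, fixed = TRUE)[[1]][1] != 151) {
    pos <- setdiff(as.integer(gregexpr("GATC", s, fixed = TRUE)[[1]]), 151L)
    for (p in pos) substring(s, p, p) <- "C"
  }
  rg <- build_reduced_genome(c(chr1 = s))
  expect_equal(nrow(rg$entries), 2L)
  up <- rg$entries[rg$entries$side == "upstream", ]
  dn <- rg$entries[rg$entries$side == "downstream", ]
  expect_equal(c(up$start, up$end), c(45L, 150L))
  expect_equal(c(dn$start, dn$end), c(154L, 259L))
  expect_equal(up$sequence, substring(s, 46, 150))
  # boundary truncation near the chromosome start
  s2 <- paste0(paste(rep("A", 50), collapse = ""), "GATC",
               paste(rep("C", 200), collapse = ""))
  rg2 <- build_reduced_genome(c(chr1 = s2))
  up2 <- rg2$entries[rg2$entries$side == "upstream", ]
  expect_equal(c(up2$start, up2$end), c(0L, 50L))
  expect_equal(nchar(up2$sequence), 50L)
})

test_that("entry count is twice the cut-site count on a toy genome", {
  tr <- tiny_truth()
  fm <- build_fragment_map(tr$genome)
  rg <- build_reduced_genome(tr$genome, fm)
  expect_equal(nrow(rg$entries), 2L * sum(lengths(fm$cut_sites)))
})

test_that("demultiplexing is exact-match and trims to 105 nt", {
  vp1 <- list(name = "vpA", reading_primer = strrep("AC", 10))
  vp2 <- list(name = "vpB", reading_primer = strrep("GT", 10))
  capture <- paste(rep("T", 105), collapse = "")
  reads <- c(paste0(vp1$reading_primer, capture),
             paste0(vp2$reading_primer, capture),
             paste0("G", substring(vp1$reading_primer, 2), capture),
             paste0(vp1$reading_primer, capture, strrep("A", 25)))  # 150 nt
  out <- demultiplex_and_trim(reads, list(vp1, vp2))
  expect_equal(length(out$vpA), 2L)
  expect_equal(length(out$vpB), 1L)
  expect_equal(out$unassigned, 1L)
  expect_true(all(nchar(out$vpA) == 105L))
  expect_true(all(nchar(out$vpB) == 105L))
  # identical primers are a configuration error
  expect_error(demultiplex_and_trim(reads, list(vp1, vp1)), "share")
})

test_that("iterative mapping rescues junction reads to the first capture", {
  tr <- tiny_truth()
  rg <- build_reduced_genome(tr$genome)
  ent <- rg$entries[nchar(rg$entries$sequence) == 105, ]
  # junction-free read maps at iteration 0
  mp0 <- iterative_map(ent$sequence[1], rg)
  expect_equal(rg$entries$fragment[mp0$entry], ent$fragment[1])
  expect_equal(mp0$stats$mapped[1], 1L)
  # constructed junction read: 52 nt of flank A + 53 nt of flank B
  jread <- paste0(substring(ent$sequence[10], 1, 52),
                  substring(ent$sequence[400], 1, 53))
  mpj <- iterative_map(jread, rg)
  expect_equal(rg$entries$fragment[mpj$entry], ent$fragment[10])
  it <- which(mpj$stats$mapped == 1L)
  expect_lte(it, 7L)                       # <= 6 trims of 10 nt
  expect_lte(mpj$stats$length[it], 52L)
  # a read matching two entries is never counted
  dupseq <- strrep("ACGT", 30)
  g <- c(chr1 = paste0("GATC", dupseq, "GATCAAATTTGGGCCC",
                       strrep("T", 120), "GATC", dupseq, "GATC"))
  rgd <- build_reduced_genome(g)
  dup_entries <- rgd$entries[rgd$entries$sequence == substring(dupseq, 1, 105), ]
  mp <- iterative_map(substring(dupseq, 1, 105), rgd, min_len = 100L)
  expect_true(is.na(mp$entry))
})

test_that("every flank's own sequence maps back to its origin entry", {
  tr <- tiny_truth()
  rg <- build_reduced_genome(tr$genome)
  full <- which(nchar(rg$entries$sequence) == 105)
  mp <- iterative_map(rg$entries$sequence[full], rg)
  mapped <- !is.na(mp$entry)
  # unique sequences must come back to themselves
  uniq <- !(duplicated(rg$entries$sequence[full]) |
              duplicated(rg$entries$sequence[full], fromLast = TRUE))
  expect_true(all(mapped[uniq]))
  expect_equal(mp$entry[uniq], full[uniq])
})

test_that("median smoothing equals the brute-force windowed median", {
  fm <- build_fragment_map(tiny_truth()$genome)
  prof <- fourc_profile(stats::setNames(rep(1L, nrow(fm$fragments)),
                                        fm$fragments$id), fm)
  # constant profile stays constant
  sm <- smooth_profile(prof)
  expect_true(all(abs(sm$smoothed - sm$rpm[1]) < 1e-9))
  # a single spike is erased by the median
  cnt <- rep(0L, nrow(fm$fragments)); cnt[100] <- 100L
  names(cnt) <- fm$fragments$id
  sp <- smooth_profile(fourc_profile(cnt, fm))
  expect_true(all(sp$smoothed[setdiff(1:200, 100)] == 0))
  expect_equal(sp$smoothed[100], 0)
  # random profile equals the brute-force median everywhere
  set.seed(93)
  cnt <- rpois(nrow(fm$fragments), 5)
  names(cnt) <- fm$fragments$id
  pr <- fourc_profile(cnt, fm)
  got <- smooth_profile(pr, 11L)
  for (ch in unique(pr$chrom)) {
    i <- which(pr$chrom == ch)
    expect_equal(got$smoothed[i], brute_median_smooth(pr$rpm[i], 11L))
  }
  expect_error(smooth_profile(pr, 10L), "odd")
})

test_that("replicate merging is an RPM median with viewpoint masking", {
  tr <- tiny_truth()
  fm <- build_fragment_map(tr$genome)
  n <- nrow(fm$fragments)
  mk <- function(counts) {
    names(counts) <- fm$fragments$id
    smooth_profile(fourc_profile(counts, fm))
  }
  set.seed(94)
  base <- rpois(n, 20)
  p1 <- mk(base); p2 <- mk(base + rpois(n, 2)); p3 <- mk(base * 9L)
  vp <- tr$viewpoint
  merged <- normalize_and_merge(list(p1, p2, p3), vp)
  i <- which(!merged$masked)[50]
  expect_equal(merged$merged[i],
               median(c(p1$smoothed[i], p2$smoothed[i], p3$smoothed[i])))
  # single replicate: merged equals that replicate
  m1 <- normalize_and_merge(list(p1), vp)
  expect_equal(m1$merged[!m1$masked], p1$smoothed[!m1$masked])
  # RPM invariance: doubling one replicate's counts changes nothing
  p1x2 <- mk(base * 2L)
  merged2 <- normalize_and_merge(list(p1x2, p2, p3), vp)
  expect_equal(merged2$merged, merged$merged)
  # viewpoint fragment and neighbours masked
  vp_row <- match(vp$fragment, merged$id)
  expect_true(all(merged$masked[(vp_row - vp$exclusion_frags):
                                  (vp_row + vp$exclusion_frags)]))
  expect_true(all(is.na(merged$merged[merged$masked])))
})

test_that("profiles exactly on the decay curve produce no calls", {
  tr <- tiny_truth()
  fm <- build_fragment_map(tr$genome)
  fr <- fm$fragments
  vp <- tr$viewpoint
  vp_row <- match(vp$fragment, fr$id)
  mid <- (fr$start + fr$end) / 2
  d <- pmax(abs(mid - mid[vp_row]), 1)
  prof <- fr
  prof$raw <- 1
  prof$rpm <- prof$smoothed <- pmax(6e5 * d^(-1) - 0.5, 0)
  res <- call_interactions(prof, vp)   # log(signal + 0.5) is exactly linear
  expect_equal(nrow(res$calls), 0L)
  expect_lt(max(abs(res$fragments$z), na.rm = TRUE), 1e-6)
})
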