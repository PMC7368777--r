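#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate
#' the study design at desk scale: a two-chromosome toy genome with
#' DpnII (GATC) sites planted at geometric spacing, CTCF consensus
#' motifs inside TADs, negative-binomial ChIP replicate counts with
#' 4-fold planted sex effects (4 male / 4 female CTCF, 3 / 3 cohesin),
#' power-law 4C contacts with 5-fold planted focal interactions and 30%
#' multi-junction reads, and lognormal expression with 10-fold (distal)
#' versus 1.4-fold (proximal) planted cohesin-depletion suppression.
#'
#' @param n_chroms,chrom_length genome shape (bp per chromosome).
#' @param gatc_spacing_mean mean spacing (bp) of planted GATC sites;
#'   chance occurrences in the random background add further sites.
#' @param n_tads TADs per chromosome.
#' @param n_motifs total planted CTCF consensus motifs (split over TADs).
#' @param motif_prob consensus-base probability of the planted motif PWM.
#' @param chip_peak_mean expected ChIP reads per peak per replicate.
#' @param chip_background background reads per replicate (uniform).
#' @param nb_dispersion NB dispersion of per-peak replicate counts
#'   (variance = mu + phi mu^2).
#' @param sex_effect_fold planted fold-change at sex-biased peaks.
#' @param sex_biased_frac fraction of planted peaks given a sex effect.
#' @param peak_width planted peak width (bp).
#' @param n_cnc,n_lone planted cohesin-only and CTCF-only (motif-free)
#'   peaks.
#' @param decay_exponent 4C power-law contact decay exponent.
#' @param n_4c_reads reads per 4C replicate.
#' @param junction_fraction fraction of 4C reads carrying a second
#'   ligation junction (unmappable full length).
#' @param fourc_fold_sd lognormal sd of per-replicate variability of
#'   planted interaction folds (biological replicate noise).
#' @param fourc_decay_sd lognormal sd of per-replicate variability of
#'   the decay exponent.
#' @param interaction_fold planted focal 4C enrichment fold.
#' @param interaction_span_frags fragments per planted interaction block.
#' @param read_length 4C read length (20 nt reading primer + capture).
#' @param flank reduced-genome flank length (bp).
#' @param n_genes genes on the expression panel (split equally into
#'   proximal / distal / other).
#' @param expr_sigma lognormal sd of replicate FPKM noise.
#' @param suppression_distal,suppression_proximal planted expression
#'   suppression folds under cohesin depletion.
#' @param seed RNG seed for all generators.
#' @return object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_chroms = 2L, chrom_length = 600000L,
                       gatc_spacing_mean = 250, n_tads = 3L,
                       n_motifs = 36L, motif_prob = 0.85,
                       chip_peak_mean = 100, chip_background = 20000L,
                       nb_dispersion = 0.1, sex_effect_fold = 4,
                       sex_biased_frac = 0.25, peak_width = 400L,
                       n_cnc = 12L, n_lone = 12L,
                       decay_exponent = 1, n_4c_reads = 200000L,
                       junction_fraction = 0.3, fourc_fold_sd = 0.15,
                       fourc_decay_sd = 0.02, interaction_fold = 5,
                       interaction_span_frags = 15L, read_length = 125L,
                       flank = 105L, n_genes = 90L, expr_sigma = 0.2,
                       suppression_distal = 10, suppression_proximal = 1.4,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chroms >= 1L, cfg$chrom_length >= 1L,
            cfg$n_tads >= 1L, cfg$nb_dispersion >= 0,
            cfg$decay_exponent > 0,
            cfg$junction_fraction >= 0, cfg$junction_fraction <= 1,
            cfg$motif_prob > 0.25, cfg$motif_prob < 1,
            cfg$seed == as.integer(cfg$seed))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_chroms, "x", x$chrom_length, "bp;",
      x$n_motifs, "motifs;", x$n_genes, "genes; seed", x$seed, "\n")
  invisible(x)
}

# Internal: random DNA of length n as a single string.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a toy genome with planted truth
#'
#' Generates the synthetic genome and all planted structures: GATC cut
#' sites (geometric spacing on top of chance occurrences), TADs, oriented
#' CTCF consensus motifs (first half of each TAD's motifs on `+`, second
#' half on `-`, giving nested convergent pairs as planted loops), CAC /
#' CNC / Lone-CTCF peaks with sex effects, 4C viewpoint and planted focal
#' interactions, and an expression panel of proximally versus distally
#' regulated male-biased genes laid out so the 20-kb distance rule
#' reproduces the planted groups exactly.
#'
#' @param config a [sim_config()].
#' @return object of class `"sim_truth"`: list with `genome`, `tads`,
#'   `motifs`, `peaks`, `loops`, `sex_tss`, `fragments`, `viewpoint`,
#'   `interactions`, `expression`, `male_dhs`, `male_k27ac`, `config`.
#' @export
make_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (cfg$chrom_length < cfg$n_tads * 20000L)
    stop("chrom_length too small to host the requested TADs")
  set.seed(cfg$seed)
  pwm <- ctcf_pwm(cfg$motif_prob)
  cons <- pwm_consensus(pwm)
  wm <- nchar(cons)

  genome <- character(cfg$n_chroms)
  names(genome) <- paste0("chr", seq_len(cfg$n_chroms))
  tads <- motifs <- NULL
  motifs_per_tad <- ceiling(cfg$n_motifs / (cfg$n_chroms * cfg$n_tads))

  for (ci in seq_len(cfg$n_chroms)) {
    ch <- names(genome)[ci]
    chars <- sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE)
    # plant GATC sites at geometric spacing
    n_gap <- ceiling(2 * cfg$chrom_length / cfg$gatc_spacing_mean) + 10L
    pos <- cumsum(stats::rgeom(n_gap, 1 / cfg$gatc_spacing_mean) + 30L)
    pos <- pos[pos + 4L < cfg$chrom_length]
    for (p in pos) chars[(p + 1L):(p + 4L)] <- c("G", "A", "T", "C")
    # TADs: equal blocks separated by 2 kb gaps
    block <- cfg$chrom_length %/% cfg$n_tads
    t_start <- (seq_len(cfg$n_tads) - 1L) * block + 1000L
    t_end <- seq_len(cfg$n_tads) * block - 1000L
    tads <- rbind(tads, data.frame(chrom = ch, start = t_start, end = t_end,
                                   name = sprintf("%s_tad%d", ch,
                                                  seq_len(cfg$n_tads))))
    # motifs: evenly spread inside each TAD, +...+ then -...-
    for (ti in seq_len(cfg$n_tads)) {
      m <- motifs_per_tad
      at <- round(seq(t_start[ti] + 5000L, t_end[ti] - 5000L,
                      length.out = m)) +
        sample(-1000:1000, m, replace = TRUE)
      at <- sort(pmax(t_start[ti] + 100L, pmin(at, t_end[ti] - 100L)))
      strand <- rep(c("+", "-"), c(ceiling(m / 2), floor(m / 2)))
      for (k in seq_len(m)) {
        ins <- if (strand[k] == "+") cons else revcomp(cons)
        chars[(at[k] + 1L):(at[k] + wm)] <- strsplit(ins, "")[[1]]
      }
      motifs <- rbind(motifs,
                      data.frame(chrom = ch, start = at, end = at + wm,
                                 strand = strand,
                                 tad = sprintf("%s_tad%d", ch, ti)))
    }
    genome[ci] <- paste(chars, collapse = "")
  }

  # planted peaks: CAC at every motif; motif-free CNC and Lone-CTCF peaks
  half <- cfg$peak_width %/% 2L
  mid <- (motifs$start + motifs$end) %/% 2L
  peaks <- data.frame(chrom = motifs$chrom, start = mid - half,
                      end = mid + half, factor = "both",
                      motif = seq_len(nrow(motifs)),
                      stringsAsFactors = FALSE)
  free_peaks <- function(n, label) {
    out <- NULL
    guard <- 0L
    while (is.null(out) || nrow(out) < n) {
      guard <- guard + 1L
      if (guard > 50L * n) stop("cannot place motif-free peaks")
      ti <- sample(nrow(tads), 1L)
      at <- sample((tads$start[ti] + half):(tads$end[ti] - half), 1L)
      cand <- data.frame(chrom = tads$chrom[ti], start = at - half,
                         end = at + half, factor = label, motif = NA_integer_,
                         stringsAsFactors = FALSE)
      near <- rbind(peaks[, 1:3], if (!is.null(out)) out[, 1:3])
      if (!any(cand$chrom == near$chrom &
               cand$start < near$end + 500L &
               cand$end > near$start - 500L))
        out <- rbind(out, cand)
    }
    out
  }
  peaks <- rbind(peaks, free_peaks(cfg$n_cnc, "cohesin_only"),
                 free_peaks(cfg$n_lone, "ctcf_only"))
  peaks$strength <- stats::rlnorm(nrow(peaks), 0, 0.4)
  nb <- round(cfg$sex_biased_frac * nrow(peaks))
  biased <- sample(nrow(peaks), nb)
  peaks$sex_bias <- "none"
  peaks$sex_bias[biased] <- rep_len(c("M", "F"), nb)
  peaks$fold <- ifelse(peaks$sex_bias == "none", 1, cfg$sex_effect_fold)
  peaks <- peaks[order(peaks$chrom, peaks$start), ]
  rownames(peaks) <- NULL

  # planted loops: pair i-th "+" motif with i-th-from-last "-" per TAD
  loops <- NULL
  for (td in unique(motifs$tad)) {
    mm <- motifs[motifs$tad == td, ]
    pl <- which(mm$strand == "+"); mn <- which(mm$strand == "-")
    k <- min(length(pl), length(mn))
    if (k == 0L) next
    for (i in seq_len(k)) {
      a <- mm[pl[i], ]; b <- mm[mn[length(mn) - i + 1L], ]
      if (a$start >= b$start) next
      loops <- rbind(loops, data.frame(chrom = a$chrom, start = a$start,
                                       end = b$end, tad = td))
    }
  }

  # sex-biased TSS inside TADs (for proximity annotation of sites)
  sex_tss <- NULL
  for (ti in seq_len(nrow(tads))) {
    at <- round((tads$start[ti] + tads$end[ti]) / 2) + 3000L
    sex_tss <- rbind(sex_tss,
                     data.frame(chrom = tads$chrom[ti], start = at,
                                end = at + 1L,
                                name = sprintf("sbgene%d", ti),
                                mf_ratio = sample(c(5, 0.2), 1L)))
  }

  # 4C layer: fragments, viewpoint near the middle of chr1, planted
  # interaction blocks (3 in both sexes, 1 female-only)
  fragments <- build_fragment_map(genome)$fragments
  fr1 <- fragments[fragments$chrom == "chr1", ]
  vp_idx <- which.min(abs((fr1$start + fr1$end) / 2 - cfg$chrom_length / 2))
  primer <- random_dna(20L)
  viewpoint <- list(name = "vp1", chrom = "chr1",
                    fragment = fr1$id[vp_idx],
                    reading_primer = primer, barcode = "ACGT",
                    exclusion_frags = 2L)
  span <- cfg$interaction_span_frags
  # planted blocks at fixed fractions of the chromosome from the viewpoint
  # (20 kb, 40 kb, 60 kb and -25 kb on the default 600-kb chromosome)
  dist_bp <- round(cfg$chrom_length * c(1 / 30, 1 / 15, 1 / 10, -1 / 24))
  mid1 <- (fr1$start + fr1$end) / 2
  sexes <- c("both", "both", "both", "F")
  interactions <- NULL
  for (k in seq_along(dist_bp)) {
    i0 <- which.min(abs(mid1 - (mid1[vp_idx] + dist_bp[k])))
    i1 <- i0 + span - 1L
    if (i0 <= vp_idx + viewpoint$exclusion_frags &&
        i1 >= vp_idx - viewpoint$exclusion_frags)
      stop("interaction block collides with the viewpoint")
    if (i0 < 1L || i1 > nrow(fr1)) stop("interaction block outside chr1")
    interactions <- rbind(interactions,
                          data.frame(chrom = "chr1",
                                     start = fr1$start[i0], end = fr1$end[i1],
                                     frag_first = fr1$id[i0],
                                     frag_last = fr1$id[i1],
                                     fold = cfg$interaction_fold,
                                     sex = sexes[k]))
  }

  # expression panel: genes on a coordinate-only chromosome "chrG",
  # spaced 45 kb so the 20-kb rule separates planted groups exactly
  ng <- 3L * (cfg$n_genes %/% 3L)
  grp <- rep(c("proximal", "distal", "other"), each = ng / 3L)
  grp <- sample(grp)  # shuffle along the chromosome
  tss <- 10000L + (seq_len(ng) - 1L) * 45000L
  wt_mean <- stats::rlnorm(ng, log(10), 0.5)
  mf_ratio <- ifelse(grp == "other", rep_len(c(1, 5), ng), 5)
  low_expr <- grp == "other" & mf_ratio == 5
  wt_mean[low_expr] <- 0.5   # fails the FPKM > 1 gate
  supp <- ifelse(grp == "distal", cfg$suppression_distal,
                 ifelse(grp == "proximal", cfg$suppression_proximal, 1))
  expression <- data.frame(gene = sprintf("gene%03d", seq_len(ng)),
                           chrom = "chrG", tss = tss,
                           length = sample(1000:5000, ng, replace = TRUE),
                           wt_mean = wt_mean, mf_ratio = mf_ratio,
                           group = grp, suppression = supp,
                           stringsAsFactors = FALSE)
  dhs_at <- ifelse(grp == "distal", tss + 22500L, tss - 5000L)
  k27_at <- ifelse(grp == "distal", tss + 23500L, tss - 8000L)
  # "other" male-biased genes get one near, one far feature (mixed)
  k27_at[grp == "other"] <- tss[grp == "other"] + 23500L
  male_dhs <- gintervals("chrG", dhs_at, dhs_at + 500L)
  male_k27ac <- gintervals("chrG", k27_at, k27_at + 1000L)

  structure(list(genome = genome, tads = gintervals(tads$chrom, tads$start,
                                                    tads$end, name = tads$name),
                 motifs = motifs, pwm = pwm, peaks = peaks, loops = loops,
                 sex_tss = sex_tss, fragments = fragments,
                 viewpoint = viewpoint, interactions = interactions,
                 expression = expression, male_dhs = male_dhs,
                 male_k27ac = male_k27ac, config = cfg, seed = cfg$seed),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", length(x$genome), "chromosomes,",
      nrow(x$motifs), "planted motifs,", nrow(x$peaks), "peaks,",
      nrow(x$loops), "loops,", nrow(x$interactions), "4C interactions,",
      nrow(x$expression), "genes\n")
  invisible(x)
}

#' Simulate ChIP-seq replicates with planted sex effects
#'
#' Per-peak per-replicate read counts are negative binomial with mean
#' `chip_peak_mean * strength * sex_multiplier` (the multiplier equals
#' the planted fold in the favored sex, 1 otherwise) and the configured
#' dispersion; reads are 50-bp intervals placed uniformly inside the
#' peak, on top of `chip_background` uniform background reads.
#'
#' @param truth a [make_genome()] result.
#' @param factor `"CTCF"` (uses CTCF-only and CAC peaks) or `"cohesin"`.
#' @param n_male,n_female replicates per sex (study design: 4/4 CTCF,
#'   3/3 cohesin).
#' @param seed RNG seed (defaults to the truth seed + 1).
#' @return list of read samples; each is a list with `factor`, `sex`,
#'   `replicate_id`, `reads` (interval table), `total_mapped`.
#' @export
simulate_chip_replicates <- function(truth, factor = c("CTCF", "cohesin"),
                                     n_male = 4L, n_female = 4L,
                                     seed = truth$seed + 1L) {
  factor <- match.arg(factor)
  cfg <- truth$config
  set.seed(seed)
  want <- if (factor == "CTCF") c("both", "ctcf_only") else
    c("both", "cohesin_only")
  pk <- truth$peaks[truth$peaks$factor %in% want, , drop = FALSE]
  chrom_len <- nchar(truth$genome)
  rd_len <- 50L
  out <- list()
  for (sex in c("M", "F")) {
    nrep <- if (sex == "M") n_male else n_female
    for (r in seq_len(nrep)) {
      mult <- ifelse(pk$sex_bias == sex, pk$fold, 1)
      mu <- cfg$chip_peak_mean * pk$strength * mult
      cnt <- stats::rnbinom(nrow(pk), mu = mu,
                            size = 1 / max(cfg$nb_dispersion, 1e-8))
      starts <- integer(0); chroms <- character(0)
      if (sum(cnt) > 0) {
        i <- rep.int(seq_len(nrow(pk)), cnt)
        starts <- pk$start[i] +
          floor(stats::runif(length(i)) * (pk$end[i] - pk$start[i] - rd_len))
        chroms <- pk$chrom[i]
      }
      bg_chr <- sample(names(truth$genome), cfg$chip_background,
                       replace = TRUE, prob = chrom_len / sum(chrom_len))
      bg_start <- floor(stats::runif(cfg$chip_background) *
                          (chrom_len[bg_chr] - rd_len))
      reads <- data.frame(chrom = c(chroms, bg_chr),
                          start = as.integer(c(starts, bg_start)),
                          stringsAsFactors = FALSE)
      reads$end <- reads$start + rd_len
      reads <- reads[order(reads$chrom, reads$start), ]
      rownames(reads) <- NULL
      out[[length(out) + 1L]] <-
        list(factor = factor, sex = sex,
             replicate_id = sprintf("%s_%s%d", factor, sex, r),
             reads = reads, total_mapped = nrow(reads))
    }
  }
  out
}

#' Simulate one 4C-seq read set
#'
#' Capture probability for each restriction fragment on the viewpoint
#' chromosome decays as `distance^-decay_exponent` from the viewpoint,
#' multiplied by the planted enrichment fold inside interaction blocks
#' active for the given sex. Each read is the 20-nt reading primer plus
#' the flank sequence adjacent to one of the captured fragment's
#' bounding cut sites; a `junction_fraction` of reads concatenate two
#' captured flanks (breakpoint uniform in 35-95 nt), so the full-length
#' read cannot map and must be rescued by iterative trimming.
#'
#' @param truth a [make_genome()] result.
#' @param viewpoint viewpoint spec (default `truth$viewpoint`).
#' @param sex `"M"` or `"F"` (selects the active planted interactions).
#' @param n_reads reads to draw (default `config$n_4c_reads`).
#' @param seed RNG seed.
#' @return list with `reads` (character vector), `truth` (per-read
#'   data.frame: `fragment`, `junction`, `breakpoint`), `sex`,
#'   `viewpoint`.
#' @export
simulate_4c_reads <- function(truth, viewpoint = truth$viewpoint,
                              sex = "M", n_reads = truth$config$n_4c_reads,
                              seed = truth$seed + 2L) {
  cfg <- truth$config
  set.seed(seed)
  fr <- truth$fragments[truth$fragments$chrom == viewpoint$chrom, ]
  vp_row <- which(fr$id == viewpoint$fragment)
  mid <- (fr$start + fr$end) / 2
  vp_mid <- mid[vp_row]
  d <- pmax(abs(mid - vp_mid), 1000)
  decay <- cfg$decay_exponent * exp(stats::rnorm(1L, 0, cfg$fourc_decay_sd))
  prob <- d^(-decay)
  mask <- abs(seq_len(nrow(fr)) - vp_row) <= viewpoint$exclusion_frags
  prob[mask] <- 0
  act <- truth$interactions[truth$interactions$sex %in% c("both", sex), ,
                            drop = FALSE]
  for (k in seq_len(nrow(act))) {
    sel <- fr$start >= act$start[k] & fr$end <= act$end[k]
    fold_r <- act$fold[k] * exp(stats::rnorm(1L, 0, cfg$fourc_fold_sd))
    prob[sel] <- prob[sel] * fold_r
  }
  prob <- prob / sum(prob)
  cache <- fragment_capture_cache(truth$genome, fr, cfg$flank)
  pick <- sample.int(nrow(fr), n_reads, replace = TRUE, prob = prob)
  flank <- draw_capture(cache, pick)
  is_junc <- stats::runif(n_reads) < cfg$junction_fraction
  bp <- integer(n_reads)
  if (any(is_junc)) {
    j <- which(is_junc)
    second <- sample.int(nrow(fr), length(j), replace = TRUE, prob = prob)
    bp[j] <- sample(35:95, length(j), replace = TRUE)
    f2 <- draw_capture(cache, second)
    flank[j] <- paste0(substring(flank[j], 1L, bp[j]),
                       substring(f2, 1L, cfg$flank - bp[j]))
  }
  reads <- paste0(viewpoint$reading_primer, flank)
  list(reads = reads,
       truth = data.frame(fragment = fr$id[pick], junction = is_junc,
                          breakpoint = bp),
       sex = sex, viewpoint = viewpoint)
}

# Internal: per-fragment capture sequences, computed once per call.
# A capture enters the fragment from one of its bounding cuts: from the
# left cut it is the sequence just downstream of the 4-bp GATC; from
# the right cut, the reverse strand of the sequence just upstream of
# it. Either way it equals a reduced-genome flank entry (truncated only
# at chromosome ends); terminal fragments have a single bounding cut.
fragment_capture_cache <- function(genome, fr, flank) {
  len <- nchar(genome[[fr$chrom[1L]]])
  s <- genome[[fr$chrom[1L]]]
  left_seq <- substring(s, pmin(fr$start + 4L, len) + 1L,
                        pmin(fr$start + 4L + flank, len))
  right_seq <- revcomp_vec(substring(s, pmax(0L, fr$end - flank) + 1L,
                                     fr$end))
  list(left = left_seq, right = right_seq,
       can_left = fr$start > 0L, can_right = fr$end < len)
}

# Internal: draw one capture per picked fragment (random entry side).
draw_capture <- function(cache, rows) {
  left <- stats::runif(length(rows)) < 0.5
  left[!cache$can_left[rows]] <- FALSE
  left[!cache$can_right[rows]] <- TRUE
  ifelse(left, cache$left[rows], cache$right[rows])
}

# Internal: vectorized reverse complement.
revcomp_vec <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a replicated two-sex 4C experiment
#'
#' @inheritParams simulate_4c_reads
#' @param n_male,n_female replicates per sex (study design: 3 / 3).
#' @return list of [simulate_4c_reads()] results with `$replicate_id`.
#' @export
simulate_4c_experiment <- function(truth, viewpoint = truth$viewpoint,
                                   n_male = 3L, n_female = 3L,
                                   n_reads = truth$config$n_4c_reads,
                                   seed = truth$seed + 2L) {
  out <- list()
  k <- 0L
  for (sex in c("M", "F")) {
    nrep <- if (sex == "M") n_male else n_female
    for (r in seq_len(nrep)) {
      k <- k + 1L
      rep_ <- simulate_4c_reads(truth, viewpoint, sex, n_reads,
                                seed = seed + k)
      rep_$replicate_id <- sprintf("%s%d", sex, r)
      out[[k]] <- rep_
    }
  }
  out
}

#' Simulate an expression matrix with planted depletion effects
#'
#' Replicate FPKM values are lognormal around the planted wild-type mean;
#' depleted replicates are scaled down by the planted suppression fold
#' (strong for distally regulated genes, weak for proximal, none
#' otherwise).
#'
#' @param truth a [make_genome()] result.
#' @param n_wt,n_depleted replicates per condition (study design: 4 / 4).
#' @param sigma lognormal noise sd (default from config).
#' @param seed RNG seed.
#' @return list with `values` (genes x replicates FPKM matrix),
#'   `condition` (per column: `"WT"` / `"depleted"`), `genes` (the truth
#'   gene table).
#' @export
simulate_expression <- function(truth, n_wt = 4L, n_depleted = 4L,
                                sigma = truth$config$expr_sigma,
                                seed = truth$seed + 3L) {
  set.seed(seed)
  g <- truth$expression
  ng <- nrow(g)
  cond <- rep(c("WT", "depleted"), c(n_wt, n_depleted))
  mu <- cbind(matrix(g$wt_mean, ng, n_wt),
              matrix(g$wt_mean / g$suppression, ng, n_depleted))
  vals <- mu * matrix(exp(stats::rnorm(ng * (n_wt + n_depleted), 0, sigma)),
                      ng)
  dimnames(vals) <- list(g$gene, paste0(cond, c(seq_len(n_wt),
                                                seq_len(n_depleted))))
  list(values = vals, condition = cond, genes = g)
}
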