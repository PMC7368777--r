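# sexbias3d

Tools for analyzing how 3D genome organization — CTCF/cohesin binding,
TADs and intra-TAD loops, and enhancer–promoter contacts — shapes
sex-biased gene expression in mouse liver.

Many sex-biased genes are controlled by distal enhancers, and whether
those enhancers can reach their promoters depends on loops anchored by
sites bound by CTCF and cohesin together (CAC sites). This package
implements the full computational chain for that question:

* **Differential ChIP-seq binding.** A sliding-window (200 bp, half-window
  step) exact negative-binomial test on replicate counts with
  moment-matched pooled dispersion and genome-wide BH FDR. Standard-tier
  sites must overlap a union peak, contain ≥ 10 reads, show > 2-fold sex
  difference and FDR < 0.05. A lenient tier comes from FRiP-matched
  pooled samples via MA rescaling (M = log2((m+0.5)/(f+0.5)) recentred
  by a common-peak linear fit; 2-fold, p-adj < 0.01, > 15 reads).
  Normalization is RIPM — reads in union-list peaks per million.
* **Site classification.** Sex-differential cohesin sites are CAC if they
  overlap CTCF peaks in ≥ 3 of 4 sex-matched replicates, CNC at 0–1,
  excluded at exactly 2; CTCF sites are CAC at 2–3 of 3 cohesin
  replicates, Lone-CTCF at 0–1. Proximity to sex-biased genes is
  annotated with precedence Proximal (< 20 kb) > IntraTAD > TAD > Outside.
* **Intra-TAD loop prediction.** Anchors are CAC peaks with a CTCF motif
  scoring > 10 (FIMO-style log2-odds); loops are convergent anchor pairs
  within a TAD, scored by `sqrt(s5*s3) * exp(-span/λ)` and accepted
  greedily with nesting allowed and crossings rejected. Loop sets are
  compared at 80% reciprocal overlap.
* **4C-seq pipeline.** Reduced genome of 105-bp flanks around every GATC
  site; exact 20-nt reading-primer demultiplexing; iterative 3′ trimming
  (10-nt steps to 20 nt) to rescue multi-junction reads; per-fragment
  RPM, 11-fragment median smoothing, median merge across replicates,
  viewpoint masking; interaction calls against a per-side log–log
  distance-decay fit at Z > 3 and FDR < 0.05, and sex-differential
  region tests at FDR < 0.1.
* **Cohesin-depletion response.** RPKM normalization, per-gene expression
  relative to the wild-type mean (+ 1e-6 pseudocount), grouping of
  strongly male-biased genes (FPKM > 1, M/F > 3) into enhancer-proximal
  (< 20 kb to male-biased DHS *and* H3K27ac) versus distal (> 20 kb to
  both), and a Mann–Whitney comparison of group medians.

A synthetic-data generator (`sim_config()`, `make_genome()`,
`simulate_chip_replicates()`, `simulate_4c_reads()`,
`simulate_expression()`) emulates the study design — 4/4 male/female
CTCF and 3/3 cohesin ChIP replicates, 3/3 4C replicates at 200,000
reads with 30% junction reads, 4/4 wild-type/cohesin-depleted
expression replicates — with known planted truth, so every stage has a
closed-loop test.

## Worked example

```r
library(sexbias3d)

truth <- make_genome(sim_config(seed = 42))
truth
#> sim_truth: 2 chromosomes, 36 planted motifs, 60 peaks, 18 loops,
#>   4 4C interactions, 90 genes

## sex-differential CTCF binding, standard stringency
reps <- simulate_chip_replicates(truth, "CTCF", n_male = 4, n_female = 4)
union_peaks <- call_peaks(reps)
standard <- filter_standard(diff_windows(reps[1:4], reps[5:8]), union_peaks)
nrow(standard)
#> [1] 13
head(standard[, c("chrom", "start", "end", "log2_mf", "fdr", "direction")], 3)
#>   chrom  start    end   log2_mf          fdr     direction
#> 1  chr1  45000  45600  1.777517 6.857198e-16   male-biased
#> 2  chr1  80000  80700 -1.821872 2.295079e-19 female-biased
#> 3  chr1 155900 156600  1.455485 1.683015e-12   male-biased

## classify the differential CTCF sites by cohesin replicate support
coh_reps <- simulate_chip_replicates(truth, "cohesin", 3, 3)
classified <- classify_ctcf_site(standard, lapply(coh_reps[1:3], call_peaks))
table(classified$site_class)
#>      CAC LoneCTCF
#>       10        3

## intra-TAD loops from convergent CTCF motifs at CAC peaks
cac <- truth$peaks[truth$peaks$factor == "both", ]
loops <- predict_loops(build_anchors(cac, truth$genome, truth$pwm),
                       truth$tads)
nrow(loops)
#> [1] 30

## cohesin depletion: distally vs proximally regulated genes
rel <- relative_to_wt(simulate_expression(truth, n_wt = 4, n_depleted = 4))
ctx <- group_genes(truth$expression, truth$expression$wt_mean,
                   truth$male_dhs, truth$male_k27ac)
cmp <- compare_depletion_effect(rel, ctx)
unlist(cmp[c("median_proximal", "median_distal", "p_value")])
#> median_proximal   median_distal         p_value
#>    7.245959e-01    1.000752e-01    1.691123e-17
```

The 13 standard-tier sites recover the planted 4-fold sex effects; 10
of them sit on cohesin-supported (CAC) sites. The depletion medians —
~0.72 for enhancer-proximal genes versus ~0.10 for distal ones —
recover the planted 1.4-fold and 10-fold suppressions and show the
distal group's much stronger dependence on cohesin (Mann–Whitney
p ≈ 2e-17).

## Vignette

`vignettes/sexbias3d-methods.Rmd` documents the models and their
assumptions, every tunable threshold with its default and rationale,
what the synthetic generator does and does not emulate, numerical
choices and degenerate-input behaviour, and known limitations.
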