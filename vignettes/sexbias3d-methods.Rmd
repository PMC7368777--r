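---
title: "Methods: sex-differential CTCF/cohesin binding, intra-TAD loops and 4C-seq interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-differential CTCF/cohesin binding, intra-TAD loops and 4C-seq interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexbias3d)
```

# The scientific problem

In mouse liver, hundreds of genes are expressed sex-differentially, and
many of their regulatory enhancers lie tens of kilobases to megabases
from their target promoters. Whether a distal enhancer can act on a
promoter depends on 3D genome organization: topologically associating
domains (TADs) and shorter, nested intra-TAD loops anchored by sites
bound by both CTCF and cohesin (CAC sites). This package implements a
complete analysis chain for asking how sex differences in CTCF/cohesin
binding and in chromatin contacts relate to sex-biased gene expression:

1. detection of sex-differential CTCF and cohesin (Rad21) ChIP-seq
   binding sites at two stringencies (`diff_windows()`,
   `filter_standard()`, `manorm_lenient()`);
2. classification of differential sites into CAC, CNC
   (cohesin-non-CTCF) and Lone-CTCF classes by replicate-overlap
   counting, with proximity annotation relative to sex-biased genes,
   enhancers, TADs and loops (`classify_cohesin_site()`,
   `classify_ctcf_site()`, `proximity_category()`);
3. prediction of intra-TAD loops from convergently oriented CTCF motifs
   at CAC anchors (`build_anchors()`, `predict_loops()`);
4. a 4C-seq pipeline from demultiplexing through reduced-genome
   iterative mapping, median smoothing, RPM normalization, replicate
   merging and distance-decay interaction calling
   (`build_reduced_genome()`, `iterative_map()`, `call_interactions()`,
   `compare_sexes()`);
5. quantification of how cohesin depletion affects genes with distal
   versus proximal sex-biased enhancers (`relative_to_wt()`,
   `group_genes()`, `compare_depletion_effect()`).

Because the original sequencing datasets are large external resources,
the package ships a first-class synthetic-data generator
(`sim_config()`, `make_genome()`, `simulate_*()`) that emulates the
study design with known planted truth, so every stage has a closed-loop
test.

# Coordinate and interval conventions

All coordinates are 0-based half-open (BED convention). Printed
browser-style spans are 1-based inclusive and converted on input with
`browser_to_bed()`. "Overlap" anywhere in the package means an
intersection of at least 1 bp of half-open intervals; abutting
intervals do not overlap. Nearest-feature queries measure the gap
between closest edges (0 for overlap) and break ties by the leftmost
target start, a deterministic choice made because any convention is
defensible and reproducibility matters more than the choice itself.
Queries with no same-chromosome target return an `Inf` sentinel rather
than an error, so annotation of sparse toy genomes never aborts.

# Motif scanning

CTCF motif presence is scored FIMO-style: a position weight matrix of
log2 likelihood ratios against a background base composition, summed
over the window, both strands scanned, and presence defined as score
strictly greater than 10. Windows containing `N` are disqualified
(conservative and deterministic). The packaged CTCF PWM
(`ctcf_pwm()`) is built from the canonical 19-bp core consensus with a
configurable consensus-base probability (default 0.85); at that
information content, chance hits above the cutoff occur at roughly
1e-5 per window, which mirrors the behaviour of genome-wide FIMO scans
at a comparable threshold.

# Differential ChIP-seq binding

## Windowed negative-binomial test

The genome is tiled in 200-bp windows sliding by half a window. Read
midpoints are counted per window and replicate, rescaled to a common
depth, and the two sexes are compared with an exact negative-binomial
test on group sums: with per-replicate counts NB(mu, phi)
(variance = mu + phi mu^2) and a common dispersion, each group sum is
NB with size n_g / phi, and the two-sided p-value sums the
probabilities of all splits of the observed total that are no more
likely than the observed one. The pooled dispersion is estimated by
the method of moments across windows (per-window, per-group
`(s^2 - xbar) / xbar^2`, averaged over windows with group mean of at
least 5 and floored at zero). The exact-sum construction keeps the
test conservative at small counts — important because genome-wide BH
correction then operates on thousands of discrete p-values. With a
single replicate per group the same machinery degenerates gracefully
to an exact Poisson-style test and the output is flagged.

Windows with BH FDR below a reporting threshold (default 0.25) and a
shared direction are merged into candidate sites carrying their best
window's p/FDR and recounted reads; `filter_standard()` then applies
the four standard-stringency gates: at least 1 bp of union-peak
overlap, at least 10 reads summed over all replicates, strictly more
than 2-fold sex difference, and FDR below 0.05. The 10-read rule is
applied to the sum over all replicates of both groups (the plausible
reading of a total-count filter; a per-group variant would only be
stricter and is easy to recreate by filtering on the count columns).

## Peak calling and normalization

The bundled peak caller is deliberately simple — sliding-window Poisson
enrichment at p < 1e-5 over a uniform background, merged into peaks
with a maximum-coverage summit — because externally called peaks (e.g.
MACS2 narrowPeak) can be imported through `read_bed()` and used
identically everywhere a peak list is accepted. Spurious peaks covered
exclusively by five or more identical-coordinate reads with no other
overlapping read are removed, as are peaks intersecting an optional
blacklist. Signal is normalized as reads-in-peaks-per-million (RIPM):
the read count divided by the number of reads overlapping any
union-list peak, per million, computed separately per factor; FRiP
(reads-in-peaks over total mapped) is the accompanying quality metric.

## Lenient tier via MA rescaling

For the lenient stringency tier, replicates are pooled per sex and the
pooled sample with the higher reads-in-peaks count is down-sampled by
the ratio of the two counts. Down-sampling is seeded and stratified
(in-peak and out-of-peak reads separately, in exact proportion), so the
matched in-peak counts agree to within a single read of rounding — the
post-condition is recounted in the tests rather than assumed. Per-peak
M/A statistics use a 0.5 pseudocount; M is rescaled by subtracting a
least-squares line fitted on common peaks (occupied in both sexes)
after trimming 5% extreme M values, which guards the fit on small toy
peak sets. P-values come from a normal approximation on the rescaled
log2 ratio with delta-method standard errors; the gates are 2-fold,
adjusted p < 0.01, and more than 15 reads in the upregulated sex.
Peaks already on the standard list are excluded, making the tiers
disjoint by construction. For histone-mark/DHS tracks,
`stringency_bands()` bands significant peaks into strict (fold > 2.5)
and lenient (1.5 < fold <= 2.5); a fold of exactly 2.5 falls between
the two published band definitions and is assigned to neither.

# Site classification and proximity

Replicate-overlap classification is a pure rule table: a
sex-differential cohesin site is CAC when it overlaps CTCF peaks in at
least 3 of 4 sex-matched CTCF replicates, CNC at 0-1, excluded at
exactly 2; a sex-differential CTCF site is CAC at 2-3 of 3 cohesin
replicates and Lone-CTCF at 0-1. The replicate sets used are those of
the sex with higher binding at the site (taken from the site's
direction). Any other replicate count is an explicit error unless
rescaled thresholds are passed, because silently adapting the rule
would change the science. Proximity categories are mutually exclusive
with precedence Proximal (< 20 kb site-edge to sex-biased TSS) >
IntraTAD (shares an intra-TAD loop with a sex-biased gene) > TAD >
Outside.

# Intra-TAD loop prediction

Anchors are CAC peaks whose best motif (highest score, ties leftmost)
passes the score-10 cutoff; the motif strand orients the anchor.
Candidate loops are convergent anchor pairs (`+` upstream, `-`
downstream) within one TAD. The published loop-calling method's full
scoring is not reproduced here; the package uses a transparent
reconstruction, `score = sqrt(strength5 * strength3) * exp(-span /
lambda)` with lambda = 200 kb, which prefers tightly bound anchors and
spans on the scale of observed median loop sizes (~150 kb). Candidates
are accepted greedily in score order; nesting (including shared
anchors) is allowed to arbitrary depth, partial crossings within a TAD
are rejected. An exhaustive independent re-implementation verifies the
selection on all toy TADs with up to 12 anchors. Loop sets from two
conditions are compared by 80% reciprocal overlap of anchor-to-anchor
spans.

# 4C-seq pipeline

The reduced genome comprises, for every GATC occurrence, the 105 bp
upstream of the match start and the 105 bp downstream of the 4-bp
recognition sequence (truncated at chromosome ends). Reads are
demultiplexed by exact match of their first 20 nt to a viewpoint's
reading primer (exact because no mismatch tolerance is defined for the
primer match and determinism is preferable on error-free synthetic
reads); 150-nt libraries are first trimmed by 25 nt so every library
yields a 105-nt capture. Mapping is exact unique lookup against the
flank entries in either orientation; reads that fail or map ambiguously
are trimmed from the 3' end in fixed steps (10 nt for long reads, 2 nt
for short ones — the fixed-step reading of a "~10% per round" schedule)
down to 20 nt. This rescues reads spanning a second ligation junction;
the mapping contract is an internal interface, so an external aligner
can be substituted for real, error-containing data.

Per-fragment counts are RPM-normalized per viewpoint, median-smoothed
over 11 fragments (windows shrink symmetrically at chromosome ends —
note that `stats::runmed`'s "median" end rule is Tukey's median-of-3
and differs near the ends, which is why the windowed median is computed
directly), merged across replicates by the per-fragment median, and
the viewpoint fragment plus two flanking fragments are masked. Order
of smoothing and scaling is immaterial for per-sample scaling (medians
commute with positive rescaling), so smoothing RPM values matches a
smooth-then-normalize pipeline.

Interaction calling fits a monotone distance-decay expectation per side
of the viewpoint by least squares of log(signal + 0.5) on
log(distance); a log-log line is the simplest monotone surrogate for
the published fit and is exact for the generator's power-law decay.
Fragment z-scores are residuals over a robust scale (1.4826 x MAD,
falling back to the SD and then to a flat zero when residuals are
degenerate); calls require z > 3 and BH FDR < 0.05, merged into
regions whose significance is additionally summarized over the region
± 2.5 kb (Stouffer combination). Sex-differential interactions are
tested per candidate region with the same exact NB machinery on
depth-rescaled per-replicate region counts, BH-corrected across
regions at FDR 0.1.

# Cohesin depletion and distal regulation

Expression is RPKM/FPKM-normalized (`count * 1e9 / (length * total)`),
and each replicate is divided by the gene's wild-type mean plus a 1e-6
pseudocount, so wild-type ratios average to ~1 and all-zero genes stay
finite. Eligible strongly male-biased genes (FPKM > 1 and M/F > 3,
strict) are grouped by TSS distance to the nearest male-biased DHS and
male-biased H3K27ac region: proximal when both are under 20 kb, distal
when both exceed it, neither otherwise (strict inequalities; exactly
20 kb is neither — a measure-zero boundary). Distances run from the
TSS point to the feature edge. The depleted-condition summary per gene
is the mean of per-replicate ratios (matching a mean-relative-expression
± SD presentation, rather than a ratio of means); group medians are
compared with a two-tailed Mann-Whitney test.

# The synthetic-data generator

`make_genome()` plants, on a configurable toy genome (default two
600-kb chromosomes):

* GATC sites at geometric spacing (default mean 250 bp) on top of
  chance occurrences in the uniform-random background — the fragment
  map always reflects the realized sequence;
* three TADs per chromosome with oriented CTCF consensus motifs, the
  first half of each TAD's motifs on `+` and the rest on `-`, so the
  planted loop truth is a set of nested convergent pairs;
* CAC (CTCF + cohesin), CNC (cohesin-only) and Lone-CTCF (CTCF-only)
  peaks, a quarter of them given a 4-fold sex effect, matching the
  4 male / 4 female CTCF and 3 / 3 cohesin replicate design;
* a 4C viewpoint near the middle of chromosome 1 with planted focal
  interaction blocks (15 fragments, 5-fold, at 20/40/60 kb and a
  female-only block at -25 kb) on a power-law contact background
  (exponent 1), 30% multi-junction reads, and 200,000 reads per
  replicate with 3 replicates per sex;
* an expression panel of 90 genes (30 proximal / 30 distal / 30
  other) on a coordinate-only chromosome laid out at 45-kb spacing so
  the 20-kb rule reproduces the planted groups exactly, with planted
  10-fold (distal) and 1.4-fold (proximal) depletion suppression and
  lognormal replicate noise (sigma 0.2).

Two generator choices deserve comment. Per-replicate lognormal jitter
of planted interaction folds (sd 0.15) and of the decay exponent (sd
0.02) gives 4C replicates the biological variability real libraries
show; without it, replicate counts are effectively multinomial and a
correctly calibrated count test resolves the few-percent compositional
shifts that one sex's extra interaction block induces everywhere else
on the chromosome — statistically real but biologically meaningless
differences. Second, simulated captures equal reduced-genome flank
sequences exactly (entering a fragment from either bounding cut), so
the mapping layer can be exact; sequencing errors, PCR duplicates and
cross-digestion chemistry are deliberately not modelled.

What passing tests on these data do show: the filter cascades, rule
tables, normalizations and callers implement their contracts; planted
effects of the stated sizes are recovered at the stated thresholds;
null configurations stay null at the nominal error rates. What they do
not show: robustness to alignment artifacts, GC/mappability bias,
copy-number variation, or mismatched real-world library chemistry —
on real data the import paths (peak BED, external aligner) exist
precisely so those stages can be replaced by battle-tested tools.

# Numerical choices and degenerate inputs

* Pseudocounts: 0.5 in M/A and log-ratio computations (MA convention);
  0.5 pseudo-signal in the 4C decay fit; 1e-6 in relative expression.
* BH correction is applied genome-wide (per tested family), not per
  chromosome — the family boundary is stated nowhere upstream, and the
  genome-wide family is the conservative, conventional choice.
* Ties: nearest features by leftmost start; best motif by highest
  score then leftmost; sex-independent peak ranking by |log ratio|
  then stronger total signal.
* Degenerate inputs error early and explicitly: zero reads in peaks,
  even smoothing windows, fewer than 10 common peaks for MA rescaling,
  replicate-set counts that do not match the rule tables.
* Problem sizes in the tests (two 600-kb chromosomes, 2,000 windows x
  200 null replications, 50 seeds for the 4C and expression
  Monte-Carlos, 10 seeds in the acceptance script) were chosen so a
  full run completes on a single CPU in minutes while keeping
  Monte-Carlo standard errors well inside the asserted margins.

# Known limitations

* The loop score is a documented reconstruction, not the published
  tool's exact scoring; absolute loop counts on real data will differ
  even though the convergence/nesting structure is faithful.
* The MA-rescaling p-value uses a normal approximation; the reference
  implementation's exact p-value model may diverge in the extreme
  tails.
* The 4C interaction caller is a surrogate for the published
  Bioconductor caller's variance model; thresholds (z > 3, FDR < 0.05)
  are matched, internals are not.
* The exact NB test assumes a common dispersion per family; strongly
  feature-specific dispersion would call for shrinkage estimators of
  the kind differential-expression packages use.
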