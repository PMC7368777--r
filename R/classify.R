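#' Classify sex-differential cohesin sites by CTCF replicate support
#'
#' A sex-differential cohesin site is CAC if it overlaps (>= 1 bp) a
#' CTCF peak in at least 3 of the 4 CTCF biological replicates of the
#' sex showing higher cohesin binding, CNC if it overlaps 0 or 1
#' replicates, and excluded from downstream analyses if it overlaps
#' exactly 2.
#'
#' @param sites diff-site table (one or more rows).
#' @param replicate_peaks list of replicate peak interval tables,
#'   already sex-matched to the sites' direction.
#' @param n_replicates expected number of replicate sets (default 4);
#'   a different count must be stated explicitly, otherwise an error.
#' @param cac_min,cnc_max rule thresholds (hits >= `cac_min` is CAC,
#'   hits <= `cnc_max` is CNC, anything between is excluded).
#' @return sites with `replicate_hits` and `site_class` columns.
#' @export
classify_cohesin_site <- function(sites, replicate_peaks,
                                  n_replicates = 4L, cac_min = 3L,
                                  cnc_max = 1L) {
  if (length(replicate_peaks) != n_replicates)
    stop("expected ", n_replicates, " replicate peak sets, got ",
         length(replicate_peaks),
         "; pass n_replicates and rescaled thresholds explicitly")
  hits <- replicate_hit_count(sites, replicate_peaks)
  sites$replicate_hits <- hits
  sites$site_class <- ifelse(hits >= cac_min, "CAC",
                             ifelse(hits <= cnc_max, "CNC", "excluded"))
  sites
}

#' Classify sex-differential CTCF sites by cohesin replicate support
#'
#' CAC if the site overlaps a cohesin peak in 2 or 3 of the 3 cohesin
#' replicates (sex-matched), Lone-CTCF if it overlaps 0 or 1. There is
#' no excluded class for CTCF sites.
#'
#' @inheritParams classify_cohesin_site
#' @param n_replicates expected replicate sets (default 3).
#' @param cac_min hits at or above this are CAC (default 2).
#' @return sites with `replicate_hits` and `site_class` columns.
#' @export
classify_ctcf_site <- function(sites, replicate_peaks, n_replicates = 3L,
                               cac_min = 2L) {
  if (length(replicate_peaks) != n_replicates)
    stop("expected ", n_replicates, " replicate peak sets, got ",
         length(replicate_peaks),
         "; pass n_replicates and rescaled thresholds explicitly")
  hits <- replicate_hit_count(sites, replicate_peaks)
  sites$replicate_hits <- hits
  sites$site_class <- ifelse(hits >= cac_min, "CAC", "LoneCTCF")
  sites
}

# Internal: number of replicate peak sets each site overlaps (>= 1 bp).
replicate_hit_count <- function(sites, replicate_peaks) {
  hits <- integer(nrow(sites))
  for (rp in replicate_peaks) hits <- hits + overlaps_any(sites, rp)
  hits
}

#' Overlap between sex-differential CTCF and cohesin site sets
#'
#' Sites common to both factors (>= 1 bp overlap) are the joint
#' CAC(dCoh/dCTCF) set. One CTCF site may match several cohesin sites
#' and vice versa, so counts are reported from both directions.
#'
#' @param ctcf_sites,cohesin_sites standard-tier site tables.
#' @return list with `pairs` (row-index pairs), `n_ctcf`, `n_cohesin`
#'   (sites of each factor in the joint set), and per-input logical
#'   flags `ctcf_joint`, `cohesin_joint`.
#' @export
cross_factor_overlap <- function(ctcf_sites, cohesin_sites) {
  h <- interval_hits(ctcf_sites, cohesin_sites)
  list(pairs = data.frame(ctcf = h$query, cohesin = h$subject),
       n_ctcf = length(unique(h$query)),
       n_cohesin = length(unique(h$subject)),
       ctcf_joint = seq_len(nrow(ctcf_sites)) %in% h$query,
       cohesin_joint = seq_len(nrow(cohesin_sites)) %in% h$subject)
}

#' Proximity of sites to sex-biased genes
#'
#' Mutually exclusive categories with precedence Proximal > IntraTAD >
#' TAD > Outside: Proximal when the site edge is within `prox_bp` of a
#' sex-biased TSS; IntraTAD when the site lies in the same intra-TAD
#' loop as a sex-biased gene; TAD when it shares a TAD with one;
#' Outside otherwise (including sites in TADs without sex-biased
#' genes).
#'
#' @param sites site table.
#' @param sex_biased_tss interval table of sex-biased gene TSS (points).
#' @param loops loop span table (`chrom`, `start`, `end`).
#' @param tads TAD table.
#' @param prox_bp proximal distance cutoff (default 20000).
#' @return sites with `proximity` and `nearest_tss_bp` columns.
#' @export
proximity_category <- function(sites, sex_biased_tss, loops, tads,
                               prox_bp = 20000L) {
  nd <- nearest_distance(sites, sex_biased_tss)
  prox <- nd$distance < prox_bp
  containing_sb <- function(spans) {
    if (is.null(spans) || nrow(spans) == 0L) return(spans[0, ])
    spans[overlaps_any(spans, sex_biased_tss), , drop = FALSE]
  }
  in_loop <- overlaps_any(sites, containing_sb(loops))
  in_tad <- overlaps_any(sites, containing_sb(tads))
  sites$nearest_tss_bp <- nd$distance
  sites$proximity <- ifelse(prox, "Proximal",
                            ifelse(in_loop, "IntraTAD",
                                   ifelse(in_tad, "TAD", "Outside")))
  sites
}

#' Annotate sites with enhancer context
#'
#' Adds the distance to the nearest enhancer DHS and nearest TSS, and a
#' flag for overlap with the merged sex-biased enhancer list (sex-biased
#' DHS plus sex-biased H3K27ac regions, supplied as input).
#'
#' @param sites site table.
#' @param enhancer_dhs enhancer DHS interval table (DHS pre-classified
#'   as enhancer-type upstream; not recomputed here).
#' @param tss TSS interval table.
#' @param sex_biased_regions merged sex-biased DHS/H3K27ac intervals.
#' @return sites with `nearest_enhancer_bp`, `nearest_tss_bp`,
#'   `overlaps_sex_biased_enhancer` columns.
#' @export
annotate_enhancer_context <- function(sites, enhancer_dhs, tss,
                                      sex_biased_regions) {
  sites$nearest_enhancer_bp <- nearest_distance(sites, enhancer_dhs)$distance
  sites$nearest_tss_bp <- nearest_distance(sites, tss)$distance
  sites$overlaps_sex_biased_enhancer <-
    overlaps_any(sites, sex_biased_regions)
  sites
}
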