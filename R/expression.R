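#' RPKM/FPKM normalization
#'
#' FPKM = count x 1e9 / (gene length x total mapped reads).
#'
#' @param raw_counts genes x replicates count matrix.
#' @param gene_lengths gene lengths in bp (> 0).
#' @param totals total mapped reads per replicate (> 0).
#' @param condition per-replicate condition labels (`"WT"` /
#'   `"depleted"`), carried through.
#' @return list with `values` (FPKM matrix) and `condition`.
#' @export
rpkm_normalize <- function(raw_counts, gene_lengths, totals,
                           condition = NULL) {
  raw_counts <- as.matrix(raw_counts)
  if (any(gene_lengths <= 0)) stop("gene lengths must be > 0")
  if (any(totals <= 0)) stop("totals must be > 0")
  vals <- sweep(raw_counts / gene_lengths, 2L, totals, "/") * 1e9
  list(values = vals, condition = condition)
}

#' Expression relative to the wild-type mean
#'
#' Each replicate's value is divided by the gene's wild-type mean plus
#' a small pseudocount (1e-6, guarding against division by zero), so
#' the wild-type group averages to ~1 per gene.
#'
#' @param expr list with `values` (FPKM matrix) and `condition`
#'   (per-column `"WT"` / `"depleted"`), e.g. from
#'   [simulate_expression()] or [rpkm_normalize()].
#' @param pseudocount added to the WT mean before division.
#' @return list with `ratios` (matrix), `condition`, and `summary`
#'   (per-gene per-condition mean and sd of ratios).
#' @export
relative_to_wt <- function(expr, pseudocount = 1e-6) {
  vals <- expr$values
  cond <- expr$condition
  stopifnot(!is.null(cond), any(cond == "WT"))
  wt_mean <- rowMeans(vals[, cond == "WT", drop = FALSE])
  ratios <- vals / (wt_mean + pseudocount)
  summ <- do.call(rbind, lapply(unique(cond), function(cc) {
    m <- ratios[, cond == cc, drop = FALSE]
    data.frame(gene = rownames(vals), condition = cc,
               mean = rowMeans(m), sd = apply(m, 1L, stats::sd),
               row.names = NULL)
  }))
  list(ratios = ratios, condition = cond, summary = summ)
}

#' Group male-biased genes by enhancer proximity
#'
#' Eligible genes (wild-type FPKM above `min_fpkm` and male/female
#' expression ratio above `min_mf`) are grouped by the distance from
#' their TSS to the nearest male-biased DHS and male-biased H3K27ac
#' region: proximal when both distances are below `prox_bp`, distal
#' when both exceed it, neither otherwise. In relaxed mode a gene is
#' proximal when either feature is near.
#'
#' @param genes gene table with `gene`, `chrom`, `tss`, `mf_ratio`.
#' @param wt_fpkm per-gene wild-type mean FPKM (for the eligibility
#'   gate).
#' @param male_dhs,male_k27ac male-biased feature interval tables.
#' @param prox_bp distance cutoff (default 20000; strict inequalities,
#'   a TSS at exactly the cutoff is neither).
#' @param min_fpkm,min_mf eligibility gates (defaults 1 and 3, strict).
#' @param relaxed proximal = near either feature (default `FALSE`).
#' @return data.frame: `gene`, `dist_dhs`, `dist_k27ac`, `eligible`,
#'   `group` (`proximal` / `distal` / `neither`; `NA` for ineligible
#'   genes).
#' @export
group_genes <- function(genes, wt_fpkm, male_dhs, male_k27ac,
                        prox_bp = 20000L, min_fpkm = 1, min_mf = 3,
                        relaxed = FALSE) {
  tss_iv <- gintervals(genes$chrom, genes$tss, genes$tss + 1L, sort = FALSE)
  d_dhs <- nearest_distance(tss_iv, male_dhs)$distance
  d_k27 <- nearest_distance(tss_iv, male_k27ac)$distance
  eligible <- wt_fpkm > min_fpkm & genes$mf_ratio > min_mf
  near_d <- d_dhs < prox_bp; near_k <- d_k27 < prox_bp
  far_d <- d_dhs > prox_bp; far_k <- d_k27 > prox_bp
  group <- if (relaxed)
    ifelse(near_d | near_k, "proximal",
           ifelse(far_d & far_k, "distal", "neither"))
  else
    ifelse(near_d & near_k, "proximal",
           ifelse(far_d & far_k, "distal", "neither"))
  group[!eligible] <- NA_character_
  data.frame(gene = genes$gene, dist_dhs = d_dhs, dist_k27ac = d_k27,
             eligible = eligible, group = group, stringsAsFactors = FALSE)
}

#' Cohesin-depletion sensitivity of proximal versus distal genes
#'
#' Per gene, the mean depleted-condition relative expression; group
#' medians for proximally and distally regulated genes, compared with a
#' two-tailed Mann-Whitney test.
#'
#' @param rel a [relative_to_wt()] result.
#' @param contexts a [group_genes()] result (row order matching the
#'   expression matrix).
#' @return list with `median_proximal`, `median_distal`, `p_value`,
#'   `per_gene` (gene, group, mean depleted relative expression).
#' @export
compare_depletion_effect <- function(rel, contexts) {
  dep <- rel$ratios[, rel$condition == "depleted", drop = FALSE]
  per_gene <- data.frame(gene = contexts$gene, group = contexts$group,
                         rel_expr = rowMeans(dep), stringsAsFactors = FALSE)
  prox <- per_gene$rel_expr[per_gene$group %in% "proximal"]
  dist <- per_gene$rel_expr[per_gene$group %in% "distal"]
  if (!length(prox) || !length(dist)) {
    warning("empty proximal or distal group; no test performed")
    return(list(median_proximal = stats::median(prox),
                median_distal = stats::median(dist), p_value = NA_real_,
                per_gene = per_gene))
  }
  mw <- mann_whitney(prox, dist)
  list(median_proximal = stats::median(prox),
       median_distal = stats::median(dist),
       p_value = mw$p_value, per_gene = per_gene)
}
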