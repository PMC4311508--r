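# Normalization, RPKM, and negative-binomial differential expression.
#
# The NB machinery is implemented here rather than wrapped from an
# existing DE package: median-of-ratios size factors, method-of-moments
# dispersion with a fitted a0 + a1/mean trend (per-gene value =
# max(gene, trend), conservative), and an exact-style test on group count
# sums under the NB model.

#' Median-of-ratios size factors
#'
#' s_j = median over genes (nonzero in all samples) of
#' k_gj / (prod_j k_gj)^(1/m): each sample's median ratio to the
#' geometric-mean pseudo-reference. Identical columns give factors of 1.
#'
#' @param counts genes x samples matrix (or a `counts_matrix`).
#' @param pseudo_reference if `TRUE`, fall back to computing the geometric
#'   mean over nonzero samples only when no gene is nonzero everywhere.
#' @return named numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  m <- if (inherits(counts, "counts_matrix")) counts$counts else counts
  all_nonzero <- rowSums(m == 0) == 0L
  if (!any(all_nonzero)) {
    if (!pseudo_reference)
      stopf("size_factors: no gene with nonzero counts in all samples; rerun with pseudo_reference = TRUE")
    log_geo <- apply(m, 1L, function(r) mean(log(r[r > 0])))
    use <- is.finite(log_geo)
    ratios <- log(m[use, , drop = FALSE]) - log_geo[use]
    sf <- apply(ratios, 2L, function(col) exp(stats::median(col[is.finite(col)])))
  } else {
    lm_ <- log(m[all_nonzero, , drop = FALSE])
    log_geo <- rowMeans(lm_)
    sf <- apply(lm_ - log_geo, 2L, function(col) exp(stats::median(col)))
  }
  if (any(!is.finite(sf) | sf <= 0))
    stopf("size_factors: non-finite or non-positive factor estimated")
  sf
}

#' Reads per kilobase per million mapped reads
#'
#' RPKM_gj = counts_gj / (length_g/1e3) / (lib_j/1e6), with lib_j the
#' sample's total mapped reads.
#'
#' @param counts a `counts_matrix`, or genes x samples matrix (then
#'   `lengths` is required).
#' @param lengths named per-gene mature lengths in bp.
#' @return genes x samples RPKM matrix.
#' @export
rpkm <- function(counts, lengths = NULL) {
  if (inherits(counts, "counts_matrix")) {
    lengths <- lengths %||% counts$lengths
    counts <- counts$counts
  }
  stopifnot(!is.null(lengths))
  len <- lengths[rownames(counts)]
  if (any(is.na(len)))
    stopf("rpkm: missing gene length for %d gene(s)", sum(is.na(len)))
  if (any(len <= 0)) stopf("rpkm: zero or negative gene length")
  lib <- colSums(counts)
  sweep(counts / (len / 1e3), 2L, lib / 1e6, `/`)
}

#' Per-gene coefficient of variation within one sample group
#'
#' sd/mean (sample sd) over the samples of `group`; genes with zero mean
#' get `NA` and are flagged via the `undefined` attribute.
#'
#' @param expr genes x samples expression matrix (e.g. RPKM).
#' @param groups named group label per sample.
#' @param group the group to evaluate (default `"NN"`).
#' @return named per-gene CV vector.
#' @export
coefficient_of_variation <- function(expr, groups, group = "NN") {
  cols <- names(groups)[groups == group]
  cols <- intersect(cols, colnames(expr))
  if (length(cols) < 2L)
    stopf("coefficient_of_variation: need >= 2 samples in group '%s'", group)
  sub <- expr[, cols, drop = FALSE]
  mu <- rowMeans(sub)
  s <- apply(sub, 1L, stats::sd)
  cv <- ifelse(mu > 0, s / mu, NA_real_)
  names(cv) <- rownames(expr)
  attr(cv, "undefined") <- rownames(expr)[mu == 0]
  cv
}

# method-of-moments dispersions, smoothed by an a0 + a1/mean trend,
# per-gene value = max(gene estimate, trend)
estimate_dispersions <- function(norm_counts, groups_vec, sf) {
  base_mean <- rowMeans(norm_counts)
  # pooled within-group variance of normalized counts
  lv <- lapply(unique(groups_vec), function(g) {
    sub <- norm_counts[, groups_vec == g, drop = FALSE]
    if (ncol(sub) < 2L) return(NULL)
    list(ss = apply(sub, 1L, stats::var) * (ncol(sub) - 1L),
         df = ncol(sub) - 1L)
  })
  lv <- Filter(Negate(is.null), lv)
  ss <- Reduce(`+`, lapply(lv, `[[`, "ss"))
  df <- sum(vapply(lv, `[[`, 1L, "df"))
  pooled_var <- ss / df
  xim <- mean(1 / sf)     # shot-noise correction for normalized counts
  raw <- (pooled_var - xim * base_mean) / base_mean^2
  raw[!is.finite(raw)] <- 0
  raw <- pmax(raw, 1e-8)

  # parametric trend a0 + a1/mean on genes with usable estimates
  use <- base_mean > 0 & raw > 1e-8
  if (sum(use) >= 10L) {
    fit <- stats::lm(raw[use] ~ I(1 / base_mean[use]))
    a0 <- max(coef(fit)[1L], 1e-8)
    a1 <- max(coef(fit)[2L], 0)
  } else {
    a0 <- stats::median(raw[use]) %||% 0.01
    if (!is.finite(a0)) a0 <- 0.01
    a1 <- 0
  }
  trend <- a0 + a1 / pmax(base_mean, 1e-8)
  list(raw = raw, trend = trend, disp = pmax(raw, trend),
       base_mean = base_mean, a0 = a0, a1 = a1)
}

# exact-style NB p-value comparing group count sums: with the gene's
# pooled mean and dispersion, enumerate splits (a, kS - a) of the total
# and sum the probabilities of outcomes no more likely than the observed
nb_exact_pvalue <- function(kA, kB, muA, muB, sizeA, sizeB) {
  kS <- kA + kB
  if (kS == 0L) return(1)
  a <- 0:kS
  pa <- stats::dnbinom(a, mu = muA, size = sizeA)
  pb <- stats::dnbinom(kS - a, mu = muB, size = sizeB)
  p_all <- pa * pb
  tot <- sum(p_all)
  if (tot <= 0) return(1)
  p_obs <- p_all[kA + 1L]
  min(1, sum(p_all[p_all <= p_obs]) / tot)
}

#' Negative-binomial differential expression test
#'
#' Two-sided exact-style test of equal means between two sample groups
#' under a negative-binomial read-count model. Per gene: dispersion is
#' estimated by method of moments on normalized counts and smoothed by a
#' fitted mean-dispersion trend (per-gene value = max(gene, trend));
#' the group count sums are then modeled as NB with matched first two
#' moments under the null of a common mean, and the p-value is the total
#' probability of splits no more likely than the one observed. log2 fold
#' change uses normalized group means with a 0.5 pseudocount.
#'
#' @param counts a `counts_matrix` (or genes x samples matrix with
#'   `groups` supplied).
#' @param groupA,groupB the two group labels to compare; fold change is
#'   reported as groupB over groupA.
#' @param groups named group label per sample (taken from the
#'   `counts_matrix` when omitted).
#' @param sf precomputed size factors (optional).
#' @param pseudocount added to each normalized group mean before the
#'   log2 ratio (default 0.5).
#' @return data.frame of class `de_result`: `gene_id`, `base_mean`,
#'   `mean_A`, `mean_B`, `log2fc`, `p_value`, `fdr`, `is_de`
#'   (FDR <= 0.1 and |log2FC| >= 1).
#' @export
nb_test <- function(counts, groupA, groupB, groups = NULL, sf = NULL,
                    pseudocount = 0.5) {
  if (inherits(counts, "counts_matrix")) {
    groups <- groups %||% counts$groups
    counts <- counts$counts
  }
  stopifnot(!is.null(groups))
  colsA <- names(groups)[groups == groupA]
  colsB <- names(groups)[groups == groupB]
  colsA <- intersect(colsA, colnames(counts))
  colsB <- intersect(colsB, colnames(counts))
  if (length(colsA) < 2L || length(colsB) < 2L)
    stopf("nb_test: need >= 2 samples per group (%s: %d, %s: %d)",
          groupA, length(colsA), groupB, length(colsB))
  sub <- counts[, c(colsA, colsB), drop = FALSE]
  if (any(colSums(sub) == 0))
    stopf("nb_test: sample with all-zero library in the comparison")
  sf <- sf %||% size_factors(sub, pseudo_reference = TRUE)
  sf <- sf[colnames(sub)]
  norm <- sweep(sub, 2L, sf, `/`)
  gvec <- c(rep("A", length(colsA)), rep("B", length(colsB)))

  disp <- estimate_dispersions(norm, gvec, sf)

  sfA <- sf[seq_along(colsA)]
  sfB <- sf[length(colsA) + seq_along(colsB)]
  kA <- rowSums(sub[, seq_along(colsA), drop = FALSE])
  kB <- rowSums(sub[, length(colsA) + seq_along(colsB), drop = FALSE])
  meanA <- rowMeans(norm[, seq_along(colsA), drop = FALSE])
  meanB <- rowMeans(norm[, length(colsA) + seq_along(colsB), drop = FALSE])

  # pooled per-normalized-count mean under the null
  q0 <- (kA + kB) / sum(sf)
  n_genes <- nrow(sub)
  p <- numeric(n_genes)
  sumA <- sum(sfA); sumB <- sum(sfB)
  sumA2 <- sum(sfA^2); sumB2 <- sum(sfB^2)
  for (g in seq_len(n_genes)) {
    muA <- q0[g] * sumA
    muB <- q0[g] * sumB
    varA <- muA + disp$disp[g] * q0[g]^2 * sumA2
    varB <- muB + disp$disp[g] * q0[g]^2 * sumB2
    sizeA <- if (varA > muA) muA^2 / (varA - muA) else 1e8
    sizeB <- if (varB > muB) muB^2 / (varB - muB) else 1e8
    p[g] <- nb_exact_pvalue(kA[g], kB[g], muA, muB, sizeA, sizeB)
  }

  log2fc <- log2((meanB + pseudocount) / (meanA + pseudocount))
  res <- data.frame(gene_id = rownames(sub),
                    base_mean = disp$base_mean,
                    mean_A = meanA, mean_B = meanB,
                    log2fc = log2fc, p_value = p,
                    fdr = bh_fdr(p), stringsAsFactors = FALSE)
  res <- call_degs(res)
  attr(res, "comparison") <- c(groupA, groupB)
  attr(res, "dispersion") <- disp
  class(res) <- c("de_result", class(res))
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR values via [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values.
#' @return vector of monotone BH-adjusted values.
#' @export
bh_fdr <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes
#'
#' `is_de` is TRUE when FDR <= 0.1 and |log2FC| >= 1, both boundaries
#' inclusive.
#'
#' @param results data.frame with `fdr` and `log2fc` columns.
#' @param max_fdr,min_abs_log2fc the significance criteria.
#' @return `results` with an `is_de` column.
#' @export
call_degs <- function(results, max_fdr = 0.1, min_abs_log2fc = 1) {
  results$is_de <- results$fdr <= max_fdr &
    abs(results$log2fc) >= min_abs_log2fc
  results
}

#' Per-category DE summary across comparisons
#'
#' Counts and integer percentages of differentially expressed transcripts
#' per catalog category, one row block per comparison.
#'
#' @param results_list named list of `de_result` data.frames, one per
#'   comparison (e.g. `list("NN vs PP" = ...)`).
#' @param catalog an `lnc_catalog` giving each gene's category.
#' @return data.frame with `comparison`, `category`, `n_expressed`,
#'   `n_de`, `pct_de` (rounded to integer).
#' @export
summarize_degs <- function(results_list, catalog) {
  cat_of <- stats::setNames(catalog$transcripts$category,
                            catalog$transcripts$transcript_id)
  out <- list()
  for (cmp in names(results_list)) {
    res <- results_list[[cmp]]
    cats <- cat_of[res$gene_id]
    for (cl in c(CATEGORY_LEVELS, "novel_total")) {
      sel <- if (cl == "novel_total") cats %in% NOVEL_CATEGORIES
             else cats == cl
      sel[is.na(sel)] <- FALSE
      n_ex <- sum(sel)
      n_de <- sum(res$is_de[sel])
      out[[length(out) + 1L]] <- data.frame(
        comparison = cmp, category = cl, n_expressed = n_ex, n_de = n_de,
        pct_de = de_percentage(n_de, n_ex), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Integer DE percentage
#'
#' `round(100 * n_de / n_expressed)`; 0 when nothing is expressed.
#'
#' @param n_de,n_expressed counts.
#' @return integer percentage.
#' @export
de_percentage <- function(n_de, n_expressed) {
  if (n_expressed == 0) return(0L)
  as.integer(round(100 * n_de / n_expressed))
}

#' Cytokine-stimulation response calls
#'
#' Among genes with FDR <= `max_fdr`, fold change > 2 is called enhanced
#' and fold change < 0.5 repressed (fold change on the linear scale,
#' treated over control).
#'
#' @param results data.frame with `fdr` and either `fc` (linear fold
#'   change) or `log2fc`.
#' @param max_fdr significance cutoff (default 0.1).
#' @return list with `enhanced` and `repressed` gene id vectors.
#' @export
cytokine_calls <- function(results, max_fdr = 0.1) {
  fc <- if ("fc" %in% names(results)) results$fc else 2^results$log2fc
  sig <- results$fdr <= max_fdr
  list(enhanced = results$gene_id[sig & fc > 2],
       repressed = results$gene_id[sig & fc < 0.5])
}

#' Write a DE result table to TSV
#' @param results a `de_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_de_results <- function(results, path) {
  write_tsv(as.data.frame(results), path)
  invisible(path)
}
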