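# Tissue-specificity index and expressed-proportion summaries over the
# 17-tissue panel.

#' Tissue-specificity index
#'
#' T_s = RPKM_s / sum_t RPKM_t per gene: each tissue's share of the
#' gene's total expression. Rows sum to 1 for genes with nonzero total;
#' zero-total genes are flagged undefined (`NA` rows, ids in the
#' `undefined` attribute).
#'
#' @param panel genes x tissues RPKM matrix (17 tissues after skin
#'   averaging; see [average_skin_replicates()]).
#' @return genes x tissues matrix of T_s values.
#' @export
specificity_index <- function(panel) {
  if (any(panel < 0)) stopf("specificity_index: negative RPKM value")
  totals <- rowSums(panel)
  out <- panel / totals
  out[totals == 0, ] <- NA_real_
  attr(out, "undefined") <- rownames(panel)[totals == 0]
  out
}

#' Proportion of each category's genes expressed per tissue
#'
#' Fraction of genes in each catalog category with RPKM at or above
#' `threshold` (inclusive) in each tissue.
#'
#' @param panel genes x tissues RPKM matrix.
#' @param categories named category label per gene (e.g. from the
#'   catalog via a truth map).
#' @param threshold minimum RPKM to count a gene as expressed
#'   (default 0.1).
#' @return category x tissue matrix of proportions.
#' @export
expressed_proportions <- function(panel, categories, threshold = 0.1) {
  categories <- categories[rownames(panel)]
  cats <- sort(unique(categories[!is.na(categories)]))
  out <- matrix(NA_real_, length(cats), ncol(panel),
                dimnames = list(cats, colnames(panel)))
  for (cl in cats) {
    sub <- panel[which(categories == cl), , drop = FALSE]
    out[cl, ] <- colMeans(sub >= threshold)
  }
  out
}

#' High skin-specificity gene subset
#'
#' Genes with T_skin strictly greater than `t_min`.
#'
#' @param ts genes x tissues T_s matrix from [specificity_index()].
#' @param t_min strict lower bound on skin specificity (default 0.4).
#' @param tissue tissue column to threshold (default `"skin"`).
#' @return character vector of gene ids.
#' @export
high_specificity_subset <- function(ts, t_min = 0.4, tissue = "skin") {
  if (!tissue %in% colnames(ts))
    stopf("high_specificity_subset: no '%s' column in T_s matrix", tissue)
  v <- ts[, tissue]
  rownames(ts)[!is.na(v) & v > t_min]
}
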