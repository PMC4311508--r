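# Guilt-by-association function inference: ontology ancestor propagation,
# squared Spearman co-expression, sampling-based cutoff calibration with
# F-beta optimization, annotation transfer, and enrichment of inferred
# functions among DE lncRNAs.

#' Propagate ontology annotations to all ancestral terms
#'
#' Closes each gene's term set under ancestry in the DAG. Idempotent:
#' propagating an already-propagated set changes nothing.
#'
#' @param edges data.frame of DAG edges (`child`, `parent`).
#' @param annotations data.frame (`gene_id`, `term`) of direct
#'   annotations.
#' @return data.frame (`gene_id`, `term`) closed under ancestry.
#' @export
propagate_ancestors <- function(edges, annotations) {
  terms <- unique(c(edges$child, edges$parent, annotations$term))
  topological_order(terms, edges)  # errors (naming an edge) on cycles
  parent_of <- split(edges$parent, edges$child)
  ancestors_of <- function(t) {
    seen <- character(0)
    frontier <- t
    while (length(frontier)) {
      nxt <- unique(unlist(parent_of[frontier], use.names = FALSE))
      nxt <- setdiff(nxt, seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  anc_cache <- lapply(stats::setNames(terms, terms), ancestors_of)
  out <- lapply(split(annotations$term, annotations$gene_id), function(ts) {
    unique(c(ts, unlist(anc_cache[ts], use.names = FALSE)))
  })
  res <- data.frame(
    gene_id = rep(names(out), lengths(out)),
    term = unlist(out, use.names = FALSE), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Squared Spearman correlation of lncRNAs against coding genes
#'
#' Spearman correlation (average-rank ties) of each lncRNA expression
#' profile against every coding gene profile, squared. For each lncRNA
#' the maximum value and the set of genes attaining it (within a relative
#' tolerance of 1e-12) are retained. Constant profiles have undefined
#' correlation and are flagged.
#'
#' @param lnc_expr lncRNAs x samples expression matrix.
#' @param mrna_expr coding genes x samples matrix (same sample order).
#' @return list with `r2` (lncRNA x gene matrix), `max_r2` (named
#'   vector), `argmax` (named list of gene id vectors), `undefined`
#'   (flagged constant profiles).
#' @export
correlation_matrix <- function(lnc_expr, mrna_expr) {
  stopifnot(ncol(lnc_expr) == ncol(mrna_expr))
  rho <- suppressWarnings(
    stats::cor(t(lnc_expr), t(mrna_expr), method = "spearman"))
  r2 <- rho^2
  undefined <- c(rownames(lnc_expr)[apply(lnc_expr, 1L, stats::sd) == 0],
                 rownames(mrna_expr)[apply(mrna_expr, 1L, stats::sd) == 0])
  max_r2 <- apply(r2, 1L, function(row) {
    if (all(is.na(row))) NA_real_ else max(row, na.rm = TRUE)
  })
  argmax <- lapply(seq_len(nrow(r2)), function(i) {
    row <- r2[i, ]
    m <- max_r2[i]
    if (is.na(m)) return(character(0))
    colnames(r2)[!is.na(row) & row >= m * (1 - 1e-12)]
  })
  names(argmax) <- rownames(lnc_expr)
  list(r2 = r2, max_r2 = max_r2, argmax = argmax, undefined = undefined)
}

#' The F-beta measure
#'
#' F_beta = (1 + beta^2) * rho * gamma / (rho * beta^2 + gamma), with rho
#' precision and gamma recall; beta > 1 emphasizes recall.
#'
#' @param precision,recall values in [0, 1].
#' @param beta weight (default 5).
#' @return F_beta (0 when precision and recall are both 0).
#' @export
f_beta <- function(precision, recall, beta = 5) {
  denom <- precision * beta^2 + recall
  ifelse(denom > 0, (1 + beta^2) * precision * recall / denom, 0)
}

# ROC AUC of scores against binary labels (rank/Mann-Whitney form)
roc_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Calibrate the co-expression cutoff by function-pair sampling
#'
#' The sampling scheme: at each iteration two expressed annotated genes
#' are drawn at random (with replacement across iterations). If they
#' share an annotated function (>= 1 propagated non-root term), one of
#' them is picked and the score is its maximum squared correlation with
#' any other gene of a shared function (a positive example). Otherwise
#' one gene is picked and scored by its maximum squared correlation with
#' m randomly selected genes, m drawn from the empirical distribution of
#' genes-per-function (a negative example). Precision, recall and F_beta
#' are evaluated on a cutoff grid; the returned cutoff maximizes F_beta.
#' The ROC AUC of the score as a same-function classifier is also
#' reported. Fully seeded and reproducible.
#'
#' @param expr genes x samples expression matrix of the annotated coding
#'   genes.
#' @param annotations propagated annotations (`gene_id`, `term`).
#' @param n_samplings number of sampling iterations (study scale:
#'   100000).
#' @param beta F-measure weight (default 5, emphasizing recall).
#' @param seed integer seed.
#' @param root_term term to ignore when deciding "same function"
#'   (uninformative root), or `NULL`.
#' @param grid cutoff grid on the squared-correlation scale.
#' @return a `calibration_curve`: list with `curve` (data.frame `cutoff`,
#'   `precision`, `recall`, `f_beta`), `best_cutoff`, `auc`, `beta`,
#'   `n_samplings`, `scores`, `labels`.
#' @export
calibrate_cutoff <- function(expr, annotations, n_samplings = 100000,
                             beta = 5, seed = 1L, root_term = NULL,
                             grid = seq(0, 1, by = 0.01)) {
  genes <- intersect(rownames(expr), unique(annotations$gene_id))
  if (length(genes) < 4L)
    stopf("calibrate_cutoff: need >= 4 annotated genes with expression")
  ann <- annotations[annotations$gene_id %in% genes, , drop = FALSE]
  if (!is.null(root_term))
    ann <- ann[ann$term != root_term, , drop = FALSE]
  term_genes <- split(ann$gene_id, ann$term)
  term_genes <- term_genes[lengths(term_genes) >= 2L]
  if (length(term_genes) < 2L)
    stopf("calibrate_cutoff: need >= 2 annotated functions with >= 2 genes")
  gene_terms <- split(ann$term, ann$gene_id)
  fn_sizes <- lengths(term_genes)          # genes-per-function distribution

  rho <- suppressWarnings(stats::cor(t(expr[genes, , drop = FALSE]),
                                     method = "spearman"))
  r2 <- rho^2
  diag(r2) <- NA_real_

  with_seed(seed, {
    g1 <- sample(genes, n_samplings, replace = TRUE)
    g2 <- sample(genes, n_samplings, replace = TRUE)
    scores <- numeric(n_samplings)
    labels <- logical(n_samplings)
    for (i in seq_len(n_samplings)) {
      shared <- intersect(gene_terms[[g1[i]]], gene_terms[[g2[i]]])
      pick <- if (stats::runif(1) < 0.5) g1[i] else g2[i]
      if (length(shared) && g1[i] != g2[i]) {
        partners <- setdiff(
          unique(unlist(term_genes[intersect(gene_terms[[pick]], shared)],
                        use.names = FALSE)), pick)
        # widen to all genes sharing any function with the picked gene
        if (!length(partners))
          partners <- setdiff(
            unique(unlist(term_genes[gene_terms[[pick]]],
                          use.names = FALSE)), pick)
        scores[i] <- max(r2[pick, partners], na.rm = TRUE)
        labels[i] <- TRUE
      } else {
        m <- unname(sample(fn_sizes, 1L))
        others <- sample(setdiff(genes, pick), min(m, length(genes) - 1L))
        scores[i] <- max(r2[pick, others], na.rm = TRUE)
        labels[i] <- FALSE
      }
    }
    if (!any(labels))
      stopf("calibrate_cutoff: no positive (same-function) samples drawn; increase n_samplings")
    auc <- roc_auc(scores, labels)
    curve <- do.call(rbind, lapply(grid, function(ct) {
      called <- scores >= ct
      tp <- sum(called & labels)
      prec <- if (sum(called)) tp / sum(called) else 0
      rec <- if (sum(labels)) tp / sum(labels) else 0
      data.frame(cutoff = ct, precision = prec, recall = rec,
                 f_beta = f_beta(prec, rec, beta))
    }))
    best <- curve$cutoff[which.max(curve$f_beta)]
    structure(list(curve = curve, best_cutoff = best, auc = auc,
                   beta = beta, n_samplings = n_samplings,
                   scores = scores, labels = labels),
              class = "calibration_curve")
  })
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("calibration_curve: ", x$n_samplings, " samplings, AUC = ",
      round(x$auc, 3), ", best cutoff (F_beta=", x$beta, ") = ",
      x$best_cutoff, "\n", sep = "")
  invisible(x)
}

#' Transfer functions to lncRNAs from their most correlated coding genes
#'
#' For every lncRNA whose maximum squared Spearman correlation with a
#' coding gene reaches the cutoff, the propagated terms of every gene
#' attaining that maximum (ties within relative tolerance 1e-12) are
#' transferred. Each transfer records the source gene(s), the squared
#' correlation, and whether any source gene is a cis partner (same
#' chromosome, within 1 Mb).
#'
#' @param corr result of [correlation_matrix()].
#' @param annotations propagated annotations (`gene_id`, `term`).
#' @param cutoff squared-correlation cutoff (default 0.5; pass
#'   `calibration$best_cutoff` to use the calibrated one).
#' @param positions optional data.frame (`gene_id`, `chrom`, `start`) for
#'   cis-pair flagging.
#' @param cis_window cis distance in bp (default 1e6).
#' @return data.frame (`lnc_id`, `term`, `source_genes`, `r2`, `is_cis`).
#' @export
transfer_functions <- function(corr, annotations, cutoff = 0.5,
                               positions = NULL, cis_window = 1e6) {
  gene_terms <- split(annotations$term, annotations$gene_id)
  out <- list()
  for (lnc in names(corr$max_r2)) {
    m <- corr$max_r2[[lnc]]
    if (is.na(m) || m < cutoff) next
    sources <- corr$argmax[[lnc]]
    sources <- sources[sources %in% names(gene_terms)]
    if (!length(sources)) next
    terms <- unique(unlist(gene_terms[sources], use.names = FALSE))
    is_cis <- FALSE
    if (!is.null(positions)) {
      lp <- positions[positions$gene_id == lnc, , drop = FALSE]
      sp <- positions[positions$gene_id %in% sources, , drop = FALSE]
      if (nrow(lp) && nrow(sp))
        is_cis <- any(sp$chrom == lp$chrom[1L] &
                        abs(sp$start - lp$start[1L]) <= cis_window)
    }
    out[[length(out) + 1L]] <- data.frame(
      lnc_id = lnc, term = terms,
      source_genes = paste(sources, collapse = ","),
      r2 = m, is_cis = is_cis, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(lnc_id = character(), term = character(),
               source_genes = character(), r2 = numeric(),
               is_cis = logical(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) drawing `n` from a population of `N` with `K` successes.
#' k = 0 returns 1.
#'
#' @param k observed successes in the draw.
#' @param N population size.
#' @param K successes in the population.
#' @param n draw size.
#' @return upper-tail probability.
#' @export
hyper_upper_tail <- function(k, N, K, n) {
  if (n > N) stopf("hyper_upper_tail: draws exceed population")
  if (k <= 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Enrichment of inferred functions among DE lncRNAs
#'
#' Universe N = lncRNAs with >= 1 inferred function; n = those that are
#' differentially expressed. Per term: K = lncRNAs carrying the term,
#' k = DE lncRNAs carrying it, hypergeometric P(X >= k), fold change
#' FC = k / (K n / N) (observed over expected), and BH FDR. The display
#' subset keeps FDR <= 0.1 and terms annotated to at most
#' `max_display_genes` lncRNAs; the full table is always returned.
#'
#' @param inferred data.frame from [transfer_functions()].
#' @param de_lnc_set character vector of DE lncRNA ids.
#' @param max_fdr display FDR cutoff (default 0.1).
#' @param max_display_genes display size cutoff (default 100).
#' @return list with `table` (all terms) and `display` (filtered),
#'   both data.frames (`term`, `K`, `k`, `p_value`, `fc`, `fdr`).
#' @export
inferred_function_enrichment <- function(inferred, de_lnc_set,
                                         max_fdr = 0.1,
                                         max_display_genes = 100) {
  universe <- unique(inferred$lnc_id)
  N <- length(universe)
  if (N == 0L) stopf("inferred_function_enrichment: empty universe")
  de_in <- intersect(de_lnc_set, universe)
  n <- length(de_in)
  rows <- lapply(split(inferred$lnc_id, inferred$term), function(ids) {
    ids <- unique(ids)
    K <- length(ids)
    k <- length(intersect(ids, de_in))
    data.frame(K = K, k = k,
               p_value = hyper_upper_tail(k, N, K, n),
               fc = enrichment_fc(k, K, n, N))
  })
  tab <- do.call(rbind, rows)
  tab <- data.frame(term = names(rows), tab, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  tab$fdr <- bh_fdr(tab$p_value)
  tab <- tab[order(tab$p_value), , drop = FALSE]
  display <- tab[tab$fdr <= max_fdr & tab$K <= max_display_genes, ,
                 drop = FALSE]
  list(table = tab, display = display, N = N, n = n)
}

#' Observed-to-expected enrichment ratio
#'
#' FC = k / (K n / N): observed DE members of a set over the count
#' expected if DE status were independent of membership.
#'
#' @param k observed overlap.
#' @param K set size.
#' @param n DE total in the universe.
#' @param N universe size.
#' @return the ratio (0 when the expectation is 0).
#' @export
enrichment_fc <- function(k, K, n, N) {
  expected <- K * n / N
  ifelse(expected > 0, k / expected, 0)
}
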