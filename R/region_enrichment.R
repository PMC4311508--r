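# Regional census and enrichment: lncRNA counts in regions of interest
# (EDC/MHC-style), susceptibility-locus catalogs, genome-wide density,
# and cytokine-signature enrichment among DE lncRNAs.

#' Define a genomic region of interest
#'
#' @param name region name.
#' @param chrom chromosome.
#' @param start,end region bounds (1-based inclusive).
#' @param flank symmetric flank in bp added to both sides (0 default;
#'   susceptibility loci use 500 kb, MHC-scale loci 3 Mb).
#' @return a one-row `region_spec` data.frame with the flank applied
#'   (`start`/`end` are the flanked bounds; originals kept).
#' @export
region_spec <- function(name, chrom, start, end, flank = 0) {
  if (start >= end) stopf("region_spec: start must be < end")
  if (flank < 0) stopf("region_spec: flank must be >= 0")
  data.frame(name = name, chrom = chrom,
             start = max(1, start - flank), end = end + flank,
             core_start = start, core_end = end, flank = flank,
             stringsAsFactors = FALSE)
}

#' Census of catalog transcripts inside a region
#'
#' A transcript is in-region when its span overlaps the (flanked) region
#' by at least 1 bp.
#'
#' @param catalog an `lnc_catalog`.
#' @param region a [region_spec()] row.
#' @return list with `counts` (per category), `ids` (in-region
#'   transcript ids).
#' @export
region_census <- function(catalog, region) {
  tx <- catalog$transcripts
  if (!region$chrom %in% tx$chrom) {
    warnf("region_census: chromosome '%s' absent from catalog", region$chrom)
    hit <- rep(FALSE, nrow(tx))
  } else {
    hit <- tx$chrom == region$chrom & tx$start <= region$end &
      tx$end >= region$start
  }
  counts <- table(factor(tx$category[hit], levels = CATEGORY_LEVELS))
  list(counts = counts, ids = tx$transcript_id[hit])
}

#' Novel-lncRNA enrichment in a region
#'
#' One-sided hypergeometric test: population = all expressed lncRNAs
#' genome-wide (annotated + novel), successes = novel lncRNAs, draws =
#' lncRNAs in the region, observed = novel lncRNAs in the region. The
#' equivalent 2x2 Fisher construction is co-reported.
#'
#' @param k_novel_in,n_in in-region novel count and total lncRNA count.
#' @param K_novel,N genome-wide novel count and total lncRNA count.
#' @return data.frame with `N`, `K`, `n`, `k`, `p_hyper`, `p_fisher`,
#'   `fc` (observed/expected).
#' @export
region_novelty_enrichment <- function(k_novel_in, n_in, K_novel, N) {
  if (n_in > N) stopf("region_novelty_enrichment: draws exceed population")
  p_h <- hyper_upper_tail(k_novel_in, N, K_novel, n_in)
  tab <- matrix(c(k_novel_in, n_in - k_novel_in,
                  K_novel - k_novel_in,
                  (N - K_novel) - (n_in - k_novel_in)), 2L, 2L)
  p_f <- stats::fisher.test(tab, alternative = "greater")$p.value
  data.frame(N = N, K = K_novel, n = n_in, k = k_novel_in,
             p_hyper = p_h, p_fisher = p_f,
             fc = enrichment_fc(k_novel_in, K_novel, n_in, N))
}

#' Per-locus catalog of expressed lncRNAs
#'
#' For each (flanked) locus: expressed lncRNAs overlapping it, the novel
#' subset, and the differentially expressed subset; genome-wide totals
#' for ratio reporting.
#'
#' @param catalog an `lnc_catalog` of expressed transcripts.
#' @param de_results a `de_result` (NN vs PP) covering the catalog, or a
#'   character vector of DE ids.
#' @param loci data.frame of [region_spec()] rows.
#' @return list with `per_locus` data.frame (`name`, `n_lncRNA`,
#'   `n_novel`, `n_de`), `totals`, and `ids` (per-locus id lists).
#' @export
susceptibility_catalog <- function(catalog, de_results, loci) {
  de_ids <- if (is.character(de_results)) de_results else
    de_results$gene_id[de_results$is_de]
  tx <- catalog$transcripts
  lnc <- tx[tx$category %in% LNCRNA_CATEGORIES, , drop = FALSE]
  rows <- list(); ids <- list()
  for (i in seq_len(nrow(loci))) {
    r <- loci[i, , drop = FALSE]
    hit <- lnc$chrom == r$chrom & lnc$start <= r$end & lnc$end >= r$start
    in_ids <- lnc$transcript_id[hit]
    rows[[i]] <- data.frame(
      name = r$name, n_lncRNA = length(in_ids),
      n_novel = sum(lnc$category[hit] %in% NOVEL_CATEGORIES),
      n_de = length(intersect(in_ids, de_ids)),
      stringsAsFactors = FALSE)
    ids[[r$name]] <- in_ids
  }
  per_locus <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), n_lncRNA = integer(),
               n_novel = integer(), n_de = integer(),
               stringsAsFactors = FALSE)
  list(per_locus = per_locus,
       totals = c(lncRNA = nrow(lnc),
                  novel = sum(lnc$category %in% NOVEL_CATEGORIES),
                  de = length(intersect(lnc$transcript_id, de_ids))),
       ids = ids)
}

#' Genome-wide lncRNA density per bin
#'
#' Counts of expressed lncRNAs per non-overlapping bin (assignment by
#' span start) and the genome-wide mean per Mb.
#'
#' @param catalog an `lnc_catalog` of expressed transcripts (already
#'   restricted to lncRNA categories by the caller, or restricted here
#'   via `lncRNA_only`).
#' @param chrom_lengths named chromosome lengths in bp.
#' @param bin bin width in bp (default 1 Mb).
#' @param lncRNA_only restrict to lncRNA categories (default TRUE).
#' @return list with `bins` (data.frame `chrom`, `start`, `end`,
#'   `count`) and `mean_per_mb`.
#' @export
density_track <- function(catalog, chrom_lengths, bin = 1e6,
                          lncRNA_only = TRUE) {
  tx <- catalog$transcripts
  if (lncRNA_only) tx <- tx[tx$category %in% LNCRNA_CATEGORIES, ,
                            drop = FALSE]
  bins <- list()
  for (ch in names(chrom_lengths)) {
    starts <- seq(1, chrom_lengths[[ch]], by = bin)
    ends <- pmin(starts + bin - 1, chrom_lengths[[ch]])
    cnt <- integer(length(starts))
    sel <- tx$chrom == ch
    if (any(sel)) {
      idx <- findInterval(tx$start[sel], starts)
      tb <- table(idx)
      cnt[as.integer(names(tb))] <- as.integer(tb)
    }
    bins[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                             count = cnt, stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, bins)
  rownames(bins) <- NULL
  total_mb <- sum(as.numeric(unlist(chrom_lengths))) / 1e6
  list(bins = bins, mean_per_mb = nrow(tx) / total_mb)
}

#' Cytokine-signature enrichment among DE lncRNAs
#'
#' Hypergeometric test of the overlap between psoriasis-regulated lncRNAs
#' (up or down) and cytokine-responsive lncRNAs (enhanced or repressed)
#' within the expressed-lncRNA universe, with Bonferroni correction over
#' the treatment conditions tested and the observed/expected ratio.
#'
#' @param de_set DE lncRNA ids (e.g. upregulated in lesional skin).
#' @param cytokine_set cytokine-responsive ids (e.g. enhanced).
#' @param universe expressed lncRNA ids.
#' @param n_conditions number of treatment conditions tested (Bonferroni
#'   factor; default 1).
#' @return data.frame with `N`, `K`, `n`, `k`, `p_value`, `p_adjusted`,
#'   `fc`.
#' @export
cytokine_enrichment <- function(de_set, cytokine_set, universe,
                                n_conditions = 1L) {
  de_set <- intersect(de_set, universe)
  cytokine_set <- intersect(cytokine_set, universe)
  N <- length(universe)
  K <- length(cytokine_set)
  n <- length(de_set)
  k <- length(intersect(de_set, cytokine_set))
  p <- hyper_upper_tail(k, N, K, n)
  data.frame(N = N, K = K, n = n, k = k, p_value = p,
             p_adjusted = min(1, p * n_conditions),
             fc = enrichment_fc(k, K, n, N))
}
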