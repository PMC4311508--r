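# Enhancer/promoter proximity across nine cell-line segmentations:
# nearest-element distances from gene starts, the ectodermal relative
# distance D_ecto/D_average, elncRNA/plncRNA classification, and
# neighbor-gene correlation.

# extract intervals of one element type from a segmentation track
seg_elements <- function(track, element = c("enhancer", "promoter"),
                         state_map = c(enhancer = "Strong_Enhancer",
                                       promoter = "Active_Promoter")) {
  element <- match.arg(element)
  track[track$state == state_map[[element]], , drop = FALSE]
}

#' Distance from a gene start to the nearest element
#'
#' Minimum distance in bp from a point (the gene's start position) to the
#' nearest interval of the track on the same chromosome; 0 when the point
#' falls inside an element; `NA` sentinel when the chromosome carries no
#' element.
#'
#' @param chrom,pos the gene-start coordinate.
#' @param elements data.frame of element intervals (`chrom`, `start`,
#'   `end`; 1-based inclusive).
#' @return distance in bp (or `NA`).
#' @export
nearest_element_distance <- function(chrom, pos, elements) {
  e <- elements[elements$chrom == chrom, , drop = FALSE]
  if (nrow(e) == 0L) return(NA_real_)
  inside <- pos >= e$start & pos <= e$end
  if (any(inside)) return(0)
  as.numeric(min(pmin(abs(pos - e$start), abs(pos - e$end))))
}

# strand-aware 5' start (TSS) for a table of genes/transcripts;
# mode "leftmost" uses the lower coordinate regardless of strand
gene_start_positions <- function(tx, mode = c("tss", "leftmost")) {
  mode <- match.arg(mode)
  if (mode == "leftmost") return(tx$start)
  ifelse(tx$strand == "-", tx$end, tx$start)
}

#' Relative distance to regulatory elements in an ectodermal cell line
#'
#' For one gene and one element type: D per cell line (distance from the
#' gene start to the closest element), D_ecto for the chosen ectodermal
#' line, D_average = mean of the closest distances over the other cell
#' lines, and relative = D_ecto / D_average (undefined, `NA`, when
#' D_average is 0 or any distance is missing).
#'
#' @param chrom,pos gene-start coordinate.
#' @param tracks named list of segmentation tracks (one per cell line).
#' @param ecto_cell name of the ectodermal cell line.
#' @param element `"enhancer"` or `"promoter"`.
#' @return list with `D` (named per-line distances), `D_ecto`,
#'   `D_average`, `relative`.
#' @export
relative_distance <- function(chrom, pos, tracks, ecto_cell,
                              element = c("enhancer", "promoter")) {
  element <- match.arg(element)
  stopifnot(ecto_cell %in% names(tracks))
  D <- vapply(tracks, function(tr)
    nearest_element_distance(chrom, pos, seg_elements(tr, element)), 1)
  d_ecto <- D[[ecto_cell]]
  others <- D[setdiff(names(tracks), ecto_cell)]
  d_avg <- mean(others)
  rel <- if (is.na(d_ecto) || is.na(d_avg) || d_avg == 0) NA_real_
         else d_ecto / d_avg
  list(D = D, D_ecto = d_ecto, D_average = d_avg, relative = rel)
}

#' Relative distances for a whole catalog
#'
#' Computes [relative_distance()] for every transcript, separately per
#' element type and per ectodermal cell line.
#'
#' @param catalog an `lnc_catalog` (or any data.frame-bearing list with
#'   `transcripts`).
#' @param seg a `segmentation_bundle` (or named list of tracks with an
#'   `ecto_lines` attribute supplied via `ecto_lines`).
#' @param ecto_lines ectodermal cell line names (default from `seg`).
#' @param start_mode `"tss"` (strand-aware 5' end, default) or
#'   `"leftmost"`.
#' @return data.frame with `transcript_id`, `category`, `element`,
#'   `ecto_cell`, `D_ecto`, `D_average`, `relative`.
#' @export
catalog_relative_distances <- function(catalog, seg, ecto_lines = NULL,
                                       start_mode = "tss") {
  tracks <- if (inherits(seg, "segmentation_bundle")) seg$tracks else seg
  ecto_lines <- ecto_lines %||%
    (if (inherits(seg, "segmentation_bundle")) seg$ecto_lines else
       stop("ecto_lines required"))
  tx <- catalog$transcripts
  pos <- gene_start_positions(tx, start_mode)
  # pre-split elements per line/type for speed
  elem <- list()
  for (cl in names(tracks))
    for (el in c("enhancer", "promoter"))
      elem[[paste(cl, el)]] <- seg_elements(tracks[[cl]], el)
  out <- list()
  for (el in c("enhancer", "promoter")) {
    D <- sapply(names(tracks), function(cl) {
      e <- elem[[paste(cl, el)]]
      vapply(seq_len(nrow(tx)), function(i)
        nearest_element_distance(tx$chrom[i], pos[i], e), 1)
    })
    for (ec in ecto_lines) {
      others <- setdiff(names(tracks), ec)
      d_avg <- rowMeans(D[, others, drop = FALSE])
      rel <- ifelse(is.na(D[, ec]) | is.na(d_avg) | d_avg == 0,
                    NA_real_, D[, ec] / d_avg)
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = tx$transcript_id, category = tx$category,
        element = el, ecto_cell = ec, D_ecto = D[, ec],
        D_average = d_avg, relative = rel, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' IQR-trimmed quartile outlier bounds
#'
#' Values outside [Q1 - 1.5 IQR, Q3 + 1.5 IQR] (linear-interpolation
#' quantiles) are outliers.
#'
#' @param x numeric vector.
#' @return logical vector, TRUE for retained values.
#' @keywords internal
iqr_keep <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE,
                       type = 7)
  iqr <- q[2L] - q[1L]
  !is.na(x) & x >= q[1L] - 1.5 * iqr & x <= q[2L] + 1.5 * iqr
}

#' Summarize relative distances per category with IQR outlier trimming
#'
#' Per category (and element/ectodermal line when present): the mean and
#' standard error of the relative distance after excluding values outside
#' 1.5 times the inter-quartile range.
#'
#' @param records data.frame from [catalog_relative_distances()] (needs
#'   `relative` plus any of `category`, `element`, `ecto_cell`).
#' @return data.frame of group means, standard errors and counts
#'   (`n_used`, `n_outliers`, `n_undefined`).
#' @export
summarize_relative_distance <- function(records) {
  by_cols <- intersect(c("category", "element", "ecto_cell"),
                       names(records))
  key <- if (length(by_cols))
    interaction(records[by_cols], drop = TRUE, sep = " | ")
  else factor(rep("all", nrow(records)))
  out <- lapply(levels(key), function(k) {
    v <- records$relative[key == k]
    undef <- sum(is.na(v))
    v <- v[!is.na(v)]
    keep <- iqr_keep(v)
    used <- v[keep]
    data.frame(group = k,
               mean = if (length(used)) mean(used) else NA_real_,
               se = if (length(used) > 1L)
                 stats::sd(used) / sqrt(length(used)) else NA_real_,
               n_used = length(used), n_outliers = sum(!keep),
               n_undefined = undef, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify a lncRNA as enhancer- or promoter-associated
#'
#' elncRNA: within `window` bp of an enhancer but not of a promoter;
#' plncRNA: the converse; `neither` otherwise (including when both
#' element types are within the window).
#'
#' @param enhancer_distance,promoter_distance distances from the lncRNA
#'   start to the nearest element (bp; `NA` treated as beyond the window).
#' @param window proximity window in bp (default 5000, exclusive:
#'   "close" means distance < window).
#' @return `"elncRNA"`, `"plncRNA"`, or `"neither"`.
#' @export
classify_elnc_plnc <- function(enhancer_distance, promoter_distance,
                               window = 5000) {
  enh_close <- !is.na(enhancer_distance) & enhancer_distance < window
  prom_close <- !is.na(promoter_distance) & promoter_distance < window
  ifelse(enh_close & !prom_close, "elncRNA",
  ifelse(prom_close & !enh_close, "plncRNA", "neither"))
}

#' elncRNA/plncRNA calls for a lncRNA set against one reference cell line
#'
#' @param catalog an `lnc_catalog`; only lncRNA categories are called.
#' @param track the reference cell line's segmentation track (default
#'   usage: NHEK).
#' @param window proximity window in bp (default 5000).
#' @param start_mode `"tss"` or `"leftmost"`.
#' @return data.frame `transcript_id`, `category`, `enhancer_distance`,
#'   `promoter_distance`, `call`.
#' @export
call_elnc_plnc <- function(catalog, track, window = 5000,
                           start_mode = "tss") {
  tx <- catalog$transcripts
  tx <- tx[tx$category %in% LNCRNA_CATEGORIES, , drop = FALSE]
  pos <- gene_start_positions(tx, start_mode)
  enh <- seg_elements(track, "enhancer")
  prom <- seg_elements(track, "promoter")
  d_enh <- vapply(seq_len(nrow(tx)), function(i)
    nearest_element_distance(tx$chrom[i], pos[i], enh), 1)
  d_prom <- vapply(seq_len(nrow(tx)), function(i)
    nearest_element_distance(tx$chrom[i], pos[i], prom), 1)
  data.frame(transcript_id = tx$transcript_id, category = tx$category,
             enhancer_distance = d_enh, promoter_distance = d_prom,
             call = classify_elnc_plnc(d_enh, d_prom, window),
             stringsAsFactors = FALSE)
}

#' Correlate lncRNA values with their nearest coding neighbors
#'
#' For each lncRNA, finds the nearest protein-coding gene by
#' start-position distance (optionally within `max_distance`), pairs the
#' supplied per-gene values (e.g. T_skin or log2FC), and reports the
#' Spearman correlation with exact average-rank tie handling.
#'
#' @param lnc_tx data.frame of lncRNA transcripts (`transcript_id`,
#'   `chrom`, `start`, `end`, `strand`).
#' @param coding_tx data.frame of protein-coding transcripts (same
#'   columns).
#' @param values named numeric vector covering both sets (by id).
#' @param max_distance maximum neighbor distance in bp (default `Inf`;
#'   use `1e6` for the cis-restricted variant).
#' @param start_mode `"tss"` or `"leftmost"`.
#' @return list with `rho`, `p_value`, `n_pairs`, `pairs` (data.frame).
#' @export
neighbor_correlation <- function(lnc_tx, coding_tx, values,
                                 max_distance = Inf, start_mode = "tss") {
  lpos <- gene_start_positions(lnc_tx, start_mode)
  cpos <- gene_start_positions(coding_tx, start_mode)
  pairs <- list()
  for (i in seq_len(nrow(lnc_tx))) {
    same <- which(coding_tx$chrom == lnc_tx$chrom[i])
    if (!length(same)) next
    d <- abs(cpos[same] - lpos[i])
    j <- same[which.min(d)]
    if (min(d) > max_distance) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      lnc_id = lnc_tx$transcript_id[i],
      neighbor_id = coding_tx$transcript_id[j],
      distance = min(d), stringsAsFactors = FALSE)
  }
  if (length(pairs) < 3L)
    stopf("neighbor_correlation: fewer than 3 lncRNA/neighbor pairs")
  pairs <- do.call(rbind, pairs)
  x <- values[pairs$lnc_id]
  y <- values[pairs$neighbor_id]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L)
    stopf("neighbor_correlation: fewer than 3 pairs with values")
  ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_pairs = sum(ok), pairs = pairs)
}
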