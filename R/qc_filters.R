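# Stepwise artifact-filter cascade: recurrence, exon distance,
# mappability, length, read support - applied in the fixed order of the
# attrition report, each removal attributable to exactly one stage.

NOVEL_CATEGORIES <- c("novel_intronic", "novel_intergenic",
                      "novel_interleaving", "novel_encompassing")

LNCRNA_CATEGORIES <- c("annotated_ncRNA", NOVEL_CATEGORIES)

subset_catalog <- function(catalog, keep_ids) {
  removed <- setdiff(catalog$transcripts$transcript_id, keep_ids)
  out <- structure(list(
    transcripts = catalog$transcripts[
      catalog$transcripts$transcript_id %in% keep_ids, , drop = FALSE],
    exons = catalog$exons[catalog$exons$transcript_id %in% keep_ids, ,
                          drop = FALSE],
    presence = catalog$presence[
      names(catalog$presence) %in% keep_ids]),
    class = "lnc_catalog")
  attr(out, "removed") <- removed
  out
}

#' Recurrence filter
#'
#' Keeps transcripts assembled in at least `ceiling(min_fraction *
#' n_samples)` samples. With the study-scale cohort of 216 samples and the
#' default 5% fraction the threshold is 11 (5% of 216 = 10.8, rounded up).
#'
#' @param catalog an `lnc_catalog`.
#' @param n_samples total number of samples in the cohort.
#' @param min_fraction minimum fraction of samples with coverage.
#' @return filtered catalog; removed ids in `attr(, "removed")`.
#' @export
recurrence_filter <- function(catalog, n_samples, min_fraction = 0.05) {
  if (!is_count(n_samples) || n_samples <= 0)
    stopf("recurrence_filter: n_samples must be a positive integer")
  threshold <- ceiling(min_fraction * n_samples)
  keep <- catalog$transcripts$transcript_id[
    catalog$transcripts$n_samples >= threshold]
  out <- subset_catalog(catalog, keep)
  attr(out, "threshold") <- threshold
  out
}

#' Distance from a transcript to the nearest exon of another gene
#'
#' Minimum gap in bp between any exon of the transcript and any annotated
#' exon (optionally excluding one gene's own exons), per chromosome.
#' Overlapping exons give 0; a gap of g bases between an exon ending at x
#' and one starting at x+g gives g. Returns `Inf` when the chromosome
#' carries no other annotated exon.
#'
#' @param exons the transcript's exon table (`chrom`, `start`, `end`).
#' @param ref a [reference_annotation()].
#' @param exclude_gene gene id whose exons are ignored (for annotated
#'   genes' own distance), or `NULL`.
#' @return distance in bp (0 for overlap, `Inf` sentinel when empty).
#' @export
nearest_exon_distance <- function(exons, ref, exclude_gene = NULL) {
  ref_ex <- ref$exon_gr
  if (!is.null(exclude_gene))
    ref_ex <- ref_ex[S4Vectors::mcols(ref_ex)$gene_id != exclude_gene]
  ref_ex <- ref_ex[as.character(GenomicRanges::seqnames(ref_ex)) ==
                     exons$chrom[1L]]
  if (length(ref_ex) == 0L) return(Inf)
  q <- GenomicRanges::GRanges(exons$chrom,
                              IRanges::IRanges(exons$start, exons$end))
  ov <- GenomicRanges::countOverlaps(q, ref_ex, ignore.strand = TRUE)
  if (any(ov > 0L)) return(0)
  d <- GenomicRanges::distanceToNearest(q, ref_ex, ignore.strand = TRUE)
  min(S4Vectors::mcols(d)$distance) + 1
}

# vectorized transcript-level distances for a whole catalog
catalog_exon_distances <- function(catalog, ref) {
  tx_ids <- catalog$transcripts$transcript_id
  ex <- catalog$exons
  q <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end))
  ov <- GenomicRanges::countOverlaps(q, ref$exon_gr, ignore.strand = TRUE)
  dtn <- GenomicRanges::distanceToNearest(q, ref$exon_gr,
                                          ignore.strand = TRUE)
  d_exon <- rep(Inf, length(q))
  d_exon[S4Vectors::queryHits(dtn)] <- S4Vectors::mcols(dtn)$distance + 1
  d_exon[ov > 0L] <- 0
  agg <- tapply(d_exon, ex$transcript_id, min)
  out <- rep(Inf, length(tx_ids))
  names(out) <- tx_ids
  out[names(agg)] <- as.numeric(agg)
  out
}

#' Per-gene distance to the exon of another annotated gene
#'
#' @param ref a [reference_annotation()].
#' @return named numeric vector of distances d_i per gene.
#' @export
gene_exon_distances <- function(ref) {
  vapply(ref$genes$gene_id, function(g) {
    nearest_exon_distance(ref$exons[ref$exons$gene_id == g, , drop = FALSE],
                          ref, exclude_gene = g)
  }, 1)
}

#' Derive the premature-fragment distance threshold
#'
#' The median of the annotated-lncRNA distances d_i, reported alongside
#' the fixed 2000 bp default used by the cascade.
#'
#' @param ref a [reference_annotation()].
#' @return list with `median_lncRNA_distance` and `default` (2000).
#' @export
derive_distance_threshold <- function(ref) {
  lnc <- ref$genes$gene_id[biotype_category(ref$genes$biotype) ==
                             "annotated_ncRNA"]
  if (length(lnc) == 0L)
    stopf("derive_distance_threshold: no annotated lncRNAs in reference; use the 2000 bp default")
  d <- vapply(lnc, function(g) {
    nearest_exon_distance(ref$exons[ref$exons$gene_id == g, , drop = FALSE],
                          ref, exclude_gene = g)
  }, 1)
  list(median_lncRNA_distance = stats::median(d), default = 2000)
}

#' Exon-distance filter
#'
#' Removes novel transcripts lying within `threshold` bp of the nearest
#' annotated exon (premature-mRNA fragment artifacts). The boundary is
#' retained: distance exactly equal to the threshold passes. Annotated
#' categories pass unchanged.
#'
#' @param catalog an `lnc_catalog`.
#' @param ref a [reference_annotation()].
#' @param threshold minimum distance in bp (default 2000).
#' @return filtered catalog; removed ids in `attr(, "removed")`;
#'   per-transcript distances in `attr(, "distances")`.
#' @export
distance_filter <- function(catalog, ref, threshold = 2000) {
  if (threshold < 0) stopf("distance_filter: threshold must be >= 0")
  d <- catalog_exon_distances(catalog, ref)
  tx <- catalog$transcripts
  novel <- tx$category %in% NOVEL_CATEGORIES
  drop <- novel & d[tx$transcript_id] < threshold
  out <- subset_catalog(catalog, tx$transcript_id[!drop])
  attr(out, "distances") <- d
  out
}

# length-weighted mean track score over a set of ranges; bases not
# covered by the track count as score 0 (with a warning upstream)
track_mean_score <- function(chrom, start, end, track) {
  total <- sum(end - start + 1)
  tr <- track[track$chrom %in% chrom, , drop = FALSE]
  if (nrow(tr) == 0L) return(list(score = 0, gap = total))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  s <- GenomicRanges::GRanges(tr$chrom, IRanges::IRanges(tr$start, tr$end),
                              score = tr$score)
  hits <- GenomicRanges::findOverlaps(q, s)
  if (length(hits) == 0L) return(list(score = 0, gap = total))
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    q[S4Vectors::queryHits(hits)], s[S4Vectors::subjectHits(hits)]))
  sc <- S4Vectors::mcols(s)$score[S4Vectors::subjectHits(hits)]
  covered <- sum(w)
  list(score = sum(w * sc) / total, gap = total - covered)
}

#' Mappability filter
#'
#' Per-transcript score = length-weighted mean track value over the
#' transcript's genomic span (or exons only, with `region = "exons"`).
#' Transcripts with either the uniqueness or the alignability score below
#' `min_score` are removed. By default the filter applies to all
#' categories; `apply_to = "novel"` restricts it to novel transcripts.
#' Track gaps over a transcript score 0 for the gapped bases and log a
#' warning.
#'
#' @param catalog an `lnc_catalog`.
#' @param uniqueness,alignability tracks as data.frames (`chrom`, `start`,
#'   `end`, `score`; 1-based inclusive, see [read_track()]).
#' @param min_score minimum acceptable score in both tracks (inclusive).
#' @param apply_to `"all"` or `"novel"`.
#' @param region `"span"` (default) or `"exons"`.
#' @return filtered catalog; removed ids in `attr(, "removed")`; scores in
#'   `attr(, "scores")`.
#' @export
mappability_filter <- function(catalog, uniqueness, alignability,
                               min_score = 0.9, apply_to = c("all", "novel"),
                               region = c("span", "exons")) {
  apply_to <- match.arg(apply_to)
  region <- match.arg(region)
  tx <- catalog$transcripts
  n <- nrow(tx)
  u_score <- a_score <- numeric(n)
  gap_seen <- FALSE
  for (i in seq_len(n)) {
    if (region == "span") {
      chrom <- tx$chrom[i]; start <- tx$start[i]; end <- tx$end[i]
    } else {
      e <- catalog$exons[catalog$exons$transcript_id == tx$transcript_id[i], ]
      chrom <- e$chrom; start <- e$start; end <- e$end
    }
    u <- track_mean_score(chrom, start, end, uniqueness)
    a <- track_mean_score(chrom, start, end, alignability)
    u_score[i] <- u$score; a_score[i] <- a$score
    if (u$gap > 0 || a$gap > 0) gap_seen <- TRUE
  }
  if (gap_seen)
    warnf("mappability_filter: track gap(s) over transcript(s); gapped bases scored 0")
  eligible <- if (apply_to == "novel") tx$category %in% NOVEL_CATEGORIES
              else rep(TRUE, n)
  drop <- eligible & (u_score < min_score | a_score < min_score)
  out <- subset_catalog(catalog, tx$transcript_id[!drop])
  attr(out, "scores") <- data.frame(transcript_id = tx$transcript_id,
                                    uniqueness = u_score,
                                    alignability = a_score,
                                    stringsAsFactors = FALSE)
  out
}

#' Mature-length filter
#'
#' Removes transcripts with mature length (sum of exon lengths, not
#' genomic span) below `min_len`.
#'
#' @param catalog an `lnc_catalog`.
#' @param min_len minimum mature length in bp (inclusive; default 200).
#' @return filtered catalog; removed ids in `attr(, "removed")`.
#' @export
length_filter <- function(catalog, min_len = 200) {
  keep <- catalog$transcripts$transcript_id[
    catalog$transcripts$mature_length >= min_len]
  subset_catalog(catalog, keep)
}

#' Read-support filter
#'
#' Keeps transcripts averaging at least one read per sample: total count
#' across all samples >= number of samples. Transcripts missing from the
#' counts matrix are treated as zero-count with a warning.
#'
#' @param catalog an `lnc_catalog`.
#' @param counts a `counts_matrix` (or plain genes x samples matrix).
#' @return filtered catalog; removed ids in `attr(, "removed")`.
#' @export
read_support_filter <- function(catalog, counts) {
  m <- if (inherits(counts, "counts_matrix")) counts$counts else counts
  n_samples <- ncol(m)
  tx_ids <- catalog$transcripts$transcript_id
  totals <- rep(0, length(tx_ids))
  found <- tx_ids %in% rownames(m)
  if (any(!found))
    warnf("read_support_filter: %d transcript(s) missing from counts, treated as zero",
          sum(!found))
  totals[found] <- rowSums(m[tx_ids[found], , drop = FALSE])
  keep <- tx_ids[totals >= n_samples]
  out <- subset_catalog(catalog, keep)
  attr(out, "totals") <- stats::setNames(totals, tx_ids)
  out
}

#' Run the full filter cascade
#'
#' Applies the five filters in fixed order - recurrence, exon distance,
#' mappability, length, read support - and builds the per-stage,
#' per-category attrition report. The expressed lncRNA set after the
#' cascade is the annotated_ncRNA plus all surviving novel transcripts.
#'
#' @param catalog an `lnc_catalog` (the raw merged catalog).
#' @param ref a [reference_annotation()].
#' @param uniqueness,alignability mappability tracks (data.frames).
#' @param counts a `counts_matrix` covering the catalog.
#' @param n_samples cohort size (defaults to `ncol(counts)`).
#' @param min_fraction recurrence fraction (default 0.05).
#' @param distance_bp exon-distance threshold (default 2000).
#' @param min_mappability mappability threshold (default 0.9).
#' @param min_len mature-length threshold (default 200).
#' @param mappability_applies `"all"` (attrition-report semantics, the
#'   default) or `"novel"`.
#' @return list with `catalog` (survivors), `report` (a `filter_report`
#'   data.frame: stage x category counts), `removals` (data.frame
#'   `transcript_id`, `stage`), `expressed_lncRNAs` (ids).
#' @export
run_cascade <- function(catalog, ref, uniqueness, alignability, counts,
                        n_samples = NULL, min_fraction = 0.05,
                        distance_bp = 2000, min_mappability = 0.9,
                        min_len = 200,
                        mappability_applies = c("all", "novel")) {
  mappability_applies <- match.arg(mappability_applies)
  m <- if (inherits(counts, "counts_matrix")) counts$counts else counts
  n_samples <- n_samples %||% ncol(m)

  count_row <- function(cat) {
    tb <- table(factor(cat$transcripts$category, levels = CATEGORY_LEVELS))
    as.integer(tb)
  }
  stages <- c("Raw",
              sprintf(">=%d%% (%d) samples", round(min_fraction * 100),
                      ceiling(min_fraction * n_samples)),
              sprintf("Distance (>=%g kb)", distance_bp / 1000),
              "Mappability",
              sprintf("Length (>=%d bp)", min_len),
              sprintf(">=%d mapped reads", n_samples))
  rows <- list(count_row(catalog))
  removals <- list()
  note_removed <- function(cat, stage) {
    rem <- attr(cat, "removed")
    if (length(rem))
      removals[[length(removals) + 1L]] <<- data.frame(
        transcript_id = rem, stage = stage, stringsAsFactors = FALSE)
  }

  cat1 <- recurrence_filter(catalog, n_samples, min_fraction)
  note_removed(cat1, stages[2L]); rows[[2L]] <- count_row(cat1)
  cat2 <- distance_filter(cat1, ref, distance_bp)
  note_removed(cat2, stages[3L]); rows[[3L]] <- count_row(cat2)
  cat3 <- mappability_filter(cat2, uniqueness, alignability,
                             min_mappability,
                             apply_to = mappability_applies)
  note_removed(cat3, stages[4L]); rows[[4L]] <- count_row(cat3)
  cat4 <- length_filter(cat3, min_len)
  note_removed(cat4, stages[5L]); rows[[5L]] <- count_row(cat4)
  cat5 <- read_support_filter(cat4, m)
  note_removed(cat5, stages[6L]); rows[[6L]] <- count_row(cat5)

  report <- data.frame(stage = stages, do.call(rbind, rows),
                       stringsAsFactors = FALSE)
  names(report)[-1L] <- CATEGORY_LEVELS
  report$total <- rowSums(report[, CATEGORY_LEVELS])
  class(report) <- c("filter_report", class(report))

  removals <- if (length(removals)) do.call(rbind, removals) else
    data.frame(transcript_id = character(), stage = character(),
               stringsAsFactors = FALSE)

  expressed_lnc <- cat5$transcripts$transcript_id[
    cat5$transcripts$category %in% LNCRNA_CATEGORIES]

  list(catalog = cat5, report = report, removals = removals,
       expressed_lncRNAs = expressed_lnc)
}

#' Write a filter attrition report to TSV
#' @param report a `filter_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  write_tsv(as.data.frame(report), path)
  invisible(path)
}
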