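# The stepwise filter cascade and its attrition accounting.

test_that("recurrence threshold uses the ceiling and inclusive boundary", {
  ex <- data.frame(chrom = "chr1", start = 100L, end = 400L, strand = "+",
                   transcript_id = "t1", stringsAsFactors = FALSE)
  m <- models_from_exons(ex)
  # 5% of 216 = 10.8 -> threshold 11
  m$transcripts$n_samples <- 10L
  cat10 <- structure(list(transcripts = m$transcripts, exons = m$exons,
                          presence = m$presence), class = "lnc_catalog")
  out <- recurrence_filter(cat10, 216L)
  expect_identical(attr(out, "threshold"), 11)
  expect_identical(nrow(out$transcripts), 0L)
  m$transcripts$n_samples <- 11L
  cat11 <- structure(list(transcripts = m$transcripts, exons = m$exons,
                          presence = m$presence), class = "lnc_catalog")
  expect_identical(nrow(recurrence_filter(cat11, 216L)$transcripts), 1L)
  expect_error(recurrence_filter(cat11, 0L), "positive")
})

test_that("transcripts at 4% presence are removed, at 6% kept", {
  fx <- default_fixture()
  cat_ <- fx$catalog
  n <- fx$config$n_samples
  # rewrite presence counts to 4% and 6% on two disjoint novel subsets
  nov_ids <- cat_$transcripts$transcript_id[
    startsWith(cat_$transcripts$category, "novel")]
  lo <- nov_ids[seq_len(5L)]
  hi <- nov_ids[6:10]
  cat_$transcripts$n_samples[
    cat_$transcripts$transcript_id %in% lo] <- floor(0.04 * n)
  cat_$transcripts$n_samples[
    cat_$transcripts$transcript_id %in% hi] <- ceiling(0.06 * n)
  out <- recurrence_filter(cat_, n)
  expect_false(any(lo %in% out$transcripts$transcript_id))
  expect_true(all(hi %in% out$transcripts$transcript_id))
})

test_that("nearest exon distance: overlap 0, gap exact, brute-force match", {
  ref <- toy_reference()
  # overlap with an annotated exon -> 0
  expect_identical(
    nearest_exon_distance(data.frame(chrom = "chr1", start = 1100L,
                                     end = 1300L), ref), 0)
  # exon ending at x, nearest annotated exon at x+500 -> 500
  expect_identical(
    nearest_exon_distance(data.frame(chrom = "chr1", start = 300L,
                                     end = 501L), ref), 500)
  # no other exon on the chromosome -> Inf sentinel
  expect_identical(
    nearest_exon_distance(data.frame(chrom = "chr9", start = 10L,
                                     end = 20L), ref), Inf)
  # random transcripts vs an exhaustive all-pairs scan
  set.seed(7)
  for (i in 1:100) {
    s <- sample(500:27000, 1L); e <- s + sample(50:400, 1L)
    got <- nearest_exon_distance(data.frame(chrom = "chr1", start = s,
                                            end = e), ref)
    want <- min(vapply(seq_len(nrow(ref$exons)), function(j)
      brute_gap(s, e, ref$exons$start[j], ref$exons$end[j]), 1))
    expect_identical(got, want)
  }
})

test_that("derived distance threshold is the annotated-lncRNA median", {
  # three single-exon lncRNAs at gaps 1000 / 2000 / 3000 from a coding exon
  genes <- data.frame(
    gene_id = c("C1", "L1", "L2", "L3"),
    biotype = c("protein_coding", "lincRNA", "lincRNA", "lincRNA"),
    chrom = "chr1", strand = "+",
    start = c(1000L, 3000L, 14100L, 26200L),
    end = c(2000L, 3100L, 14200L, 26300L), stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = genes$gene_id,
    transcript_id = paste0(genes$gene_id, ".t1"),
    chrom = "chr1", strand = "+", start = genes$start, end = genes$end,
    stringsAsFactors = FALSE)
  ref <- reference_annotation(genes, exons)
  # L1 gap to C1: 3000-2000 = 1000; L2 to L1: 14100-3100 = 11000? use
  # explicit check through gene_exon_distances instead of mental math
  d <- gene_exon_distances(ref)
  lnc_d <- d[c("L1", "L2", "L3")]
  thr <- derive_distance_threshold(ref)
  expect_identical(thr$median_lncRNA_distance, median(lnc_d))
  expect_identical(thr$default, 2000)
  # single annotated lncRNA -> its own distance
  ref1 <- reference_annotation(genes[1:2, ], exons[1:2, ])
  expect_identical(derive_distance_threshold(ref1)$median_lncRNA_distance,
                   unname(gene_exon_distances(ref1)["L1"]))
  # no annotated lncRNAs -> instructive error
  ref0 <- reference_annotation(genes[1, , drop = FALSE],
                               exons[1, , drop = FALSE])
  expect_error(derive_distance_threshold(ref0), "default")
})

test_that("distance filter removes close novels, keeps the 2 kb boundary", {
  ref <- toy_reference()
  mk_cat <- function(start, end, category) {
    ex <- data.frame(chrom = "chr1", start = start, end = end,
                     strand = "+", transcript_id = "t1",
                     stringsAsFactors = FALSE)
    m <- models_from_exons(ex)
    m$transcripts$category <- category
    m$transcripts$n_samples <- 100L
    structure(list(transcripts = m$transcripts, exons = m$exons,
                   presence = m$presence), class = "lnc_catalog")
  }
  # novel at 1999 bp from GENE_A's last exon (ends 5200) -> removed
  out <- distance_filter(mk_cat(7199L, 7400L, "novel_intergenic"), ref)
  expect_identical(nrow(out$transcripts), 0L)
  # at exactly 2000 bp -> kept (">= 2 kb" row semantics)
  out <- distance_filter(mk_cat(7200L, 7400L, "novel_intergenic"), ref)
  expect_identical(nrow(out$transcripts), 1L)
  # annotated lncRNA 100 bp from a coding exon -> untouched
  out <- distance_filter(mk_cat(5300L, 5400L, "annotated_ncRNA"), ref)
  expect_identical(nrow(out$transcripts), 1L)
  expect_error(distance_filter(mk_cat(1L, 2L, "novel_intergenic"), ref,
                               threshold = -5), ">= 0")
})

test_that("distance filter removes every planted premature fragment", {
  fx <- default_fixture()
  out <- distance_filter(fx$catalog, fx$reference)
  prem <- fx$truth_map$transcript_id[
    fx$truth_map$label == "artifact_premature"]
  expect_gt(length(prem), 0L)
  expect_true(all(prem %in% attr(out, "removed")))
  # and keeps every planted true novel
  nov <- fx$truth_map$transcript_id[
    startsWith(fx$truth_map$label, "novel")]
  expect_false(any(nov %in% attr(out, "removed")))
})

test_that("mappability scoring and filtering behave at the boundaries", {
  track1 <- data.frame(chrom = "chr1", start = 1L, end = 100000L,
                       score = 1)
  track05 <- data.frame(chrom = "chr1", start = 1L, end = 100000L,
                        score = 0.5)
  ex <- data.frame(chrom = "chr1", start = 5000L, end = 6000L,
                   strand = "+", transcript_id = "t1",
                   stringsAsFactors = FALSE)
  m <- models_from_exons(ex)
  m$transcripts$category <- "novel_intergenic"
  cat_ <- structure(list(transcripts = m$transcripts, exons = m$exons,
                         presence = m$presence), class = "lnc_catalog")
  out <- mappability_filter(cat_, track1, track1)
  expect_identical(nrow(out$transcripts), 1L)
  expect_equal(attr(out, "scores")$uniqueness, 1)
  # uniform 0.5 -> removed
  out <- mappability_filter(cat_, track05, track1)
  expect_identical(nrow(out$transcripts), 0L)
  # either track below threshold removes
  out <- mappability_filter(cat_, track1, track05)
  expect_identical(nrow(out$transcripts), 0L)
  # track gap scores 0 with a warning
  gappy <- data.frame(chrom = "chr1", start = 1L, end = 5499L, score = 1)
  expect_warning(out <- mappability_filter(cat_, gappy, track1),
                 "gap")
  expect_lt(attr(out, "scores")$uniqueness, 0.9)
  # novel-only mode leaves annotated transcripts alone
  m$transcripts$category <- "protein_coding"
  catp <- structure(list(transcripts = m$transcripts, exons = m$exons,
                         presence = m$presence), class = "lnc_catalog")
  out <- mappability_filter(catp, track05, track1, apply_to = "novel")
  expect_identical(nrow(out$transcripts), 1L)
  out <- mappability_filter(catp, track05, track1, apply_to = "all")
  expect_identical(nrow(out$transcripts), 0L)
})

test_that("mappability filter removes planted low-map artifacts only", {
  fx <- default_fixture()
  out <- mappability_filter(fx$catalog, fx$mappability$uniqueness,
                            fx$mappability$alignability)
  lowmap <- fx$truth_map$transcript_id[
    fx$truth_map$label == "artifact_lowmap"]
  expect_true(all(lowmap %in% attr(out, "removed")))
  nov <- fx$truth_map$transcript_id[
    startsWith(fx$truth_map$label, "novel")]
  expect_false(any(nov %in% attr(out, "removed")))
})

test_that("length filter uses mature length, not genomic span", {
  mk <- function(starts, ends) {
    ex <- data.frame(chrom = "chr1", start = starts, end = ends,
                     strand = "+", transcript_id = "t1",
                     stringsAsFactors = FALSE)
    m <- models_from_exons(ex)
    m$transcripts$category <- "novel_intergenic"
    structure(list(transcripts = m$transcripts, exons = m$exons,
                   presence = m$presence), class = "lnc_catalog")
  }
  expect_identical(nrow(length_filter(mk(1000L, 1198L))$transcripts), 0L)
  expect_identical(nrow(length_filter(mk(1000L, 1199L))$transcripts), 1L)
  # span 5000 but mature length 150 -> removed
  wide <- mk(c(1000L, 5900L), c(1074L, 5974L))
  expect_identical(wide$transcripts$mature_length, 150L)
  expect_identical(nrow(length_filter(wide)$transcripts), 0L)
})

test_that("read support keeps >= one read per sample on average", {
  ex <- data.frame(chrom = "chr1", start = 100L, end = 400L, strand = "+",
                   transcript_id = "t1", stringsAsFactors = FALSE)
  m <- models_from_exons(ex)
  m$transcripts$category <- "novel_intergenic"
  cat_ <- structure(list(transcripts = m$transcripts, exons = m$exons,
                         presence = m$presence), class = "lnc_catalog")
  counts <- matrix(1L, 1L, 216L,
                   dimnames = list("t1", sprintf("s%03d", 1:216)))
  counts[1L, 1L] <- 0L  # total 215 -> removed
  expect_identical(nrow(read_support_filter(cat_, counts)$transcripts), 0L)
  counts[1L, 1L] <- 1L  # total 216 -> kept
  expect_identical(nrow(read_support_filter(cat_, counts)$transcripts), 1L)
  # missing transcript treated as zero with a warning
  counts2 <- matrix(5L, 1L, 216L, dimnames = list("other", NULL))
  expect_warning(out <- read_support_filter(cat_, counts2), "missing")
  expect_identical(nrow(out$transcripts), 0L)
})

test_that("cascade attrition is monotone, attributable, and idempotent", {
  fx <- default_fixture()
  casc <- run_cascade(fx$catalog, fx$reference,
                      fx$mappability$uniqueness,
                      fx$mappability$alignability, fx$counts)
  rep <- casc$report
  for (cl in setdiff(names(rep), "stage"))
    expect_false(is.unsorted(rev(rep[[cl]])))
  # every removal attributed to exactly one stage
  expect_false(anyDuplicated(casc$removals$transcript_id) > 0)
  expect_setequal(
    c(casc$catalog$transcripts$transcript_id,
      casc$removals$transcript_id),
    fx$catalog$transcripts$transcript_id)
  # idempotent: re-running on survivors removes nothing
  casc2 <- run_cascade(casc$catalog, fx$reference,
                       fx$mappability$uniqueness,
                       fx$mappability$alignability, fx$counts)
  expect_identical(nrow(casc2$removals), 0L)
  expect_identical(casc2$catalog$transcripts, casc$catalog$transcripts)
  # survivors of the read-support stage equal an independent
  # recomputation from the counts matrix
  totals <- rowSums(fx$counts$counts)
  survivors_by_counts <- names(totals)[totals >= ncol(fx$counts$counts)]
  expect_true(all(casc$catalog$transcripts$transcript_id %in%
                    survivors_by_counts))
  # report serializes with the documented column order
  d <- withr::local_tempfile(fileext = ".tsv")
  write_filter_report(rep, d)
  back <- read.delim(d)
  expect_identical(names(back),
                   c("stage", lncskin:::CATEGORY_LEVELS, "total"))
})

test_that("cascade recovers exactly the planted expressed set", {
  fx <- default_fixture()
  casc <- run_cascade(fx$catalog, fx$reference,
                      fx$mappability$uniqueness,
                      fx$mappability$alignability, fx$counts)
  lab <- fx$truth_map$label[match(casc$removals$transcript_id,
                                  fx$truth_map$transcript_id)]
  # all removals are artifacts; all artifacts are removed
  expect_true(all(startsWith(lab, "artifact")))
  artifacts <- fx$truth_map$transcript_id[
    startsWith(fx$truth_map$label, "artifact")]
  expect_setequal(casc$removals$transcript_id, artifacts)
  # final novel count = planted true novels present at >= threshold
  n_novel_final <- sum(startsWith(casc$catalog$transcripts$category,
                                  "novel"))
  expect_identical(n_novel_final,
                   sum(startsWith(fx$truth_map$label, "novel")))
})
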