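# Consensus merging, splice-site strand inference, and category
# classification against the reference.

test_that("identical transcripts across samples merge with union presence", {
  ex <- data.frame(chrom = "chr1", start = c(100L, 500L),
                   end = c(200L, 700L), strand = "+",
                   transcript_id = "t1", stringsAsFactors = FALSE)
  bundle <- list(per_sample = list(s1 = ex, s2 = ex))
  m <- merge_assemblies(bundle)
  expect_identical(nrow(m$transcripts), 1L)
  expect_setequal(m$presence[[1L]], c("s1", "s2"))
  expect_identical(m$transcripts$n_samples, 2L)
})

test_that("same intron chain with different terminal ends merges; span covers both", {
  a <- data.frame(chrom = "chr1", start = c(100L, 500L),
                  end = c(200L, 700L), strand = "+",
                  transcript_id = "tA", stringsAsFactors = FALSE)
  b <- data.frame(chrom = "chr1", start = c(80L, 500L),
                  end = c(200L, 760L), strand = "+",
                  transcript_id = "tB", stringsAsFactors = FALSE)
  m <- merge_assemblies(list(per_sample = list(s1 = a, s2 = b)))
  expect_identical(nrow(m$transcripts), 1L)
  expect_identical(m$transcripts$start, 80L)
  expect_identical(m$transcripts$end, 760L)
  # different intron chain does NOT merge
  c_ <- data.frame(chrom = "chr1", start = c(100L, 520L),
                   end = c(200L, 700L), strand = "+",
                   transcript_id = "tC", stringsAsFactors = FALSE)
  m2 <- merge_assemblies(list(per_sample = list(s1 = a, s3 = c_)))
  expect_identical(nrow(m2$transcripts), 2L)
})

test_that("mono-exon transcripts merge by >= 1 bp overlap, chained", {
  mk <- function(id, s, e) data.frame(chrom = "chr1", start = s, end = e,
                                      strand = "+", transcript_id = id,
                                      stringsAsFactors = FALSE)
  m <- merge_assemblies(list(per_sample = list(
    s1 = mk("a", 100L, 200L), s2 = mk("b", 200L, 300L),
    s3 = mk("c", 301L, 400L))))
  # a-b overlap at base 200; c is adjacent (no shared base) -> separate
  expect_identical(nrow(m$transcripts), 2L)
  expect_identical(sort(m$transcripts$n_samples), c(1L, 2L))
})

test_that("merging is invariant to sample input order", {
  fx <- small_fixture()
  ps <- fx$bundle$per_sample
  m1 <- merge_assemblies(list(per_sample = ps))
  m2 <- merge_assemblies(list(per_sample = rev(ps)))
  expect_identical(m1$transcripts, m2$transcripts)
  expect_identical(m1$exons, m2$exons)
  expect_identical(m1$presence, m2$presence)
})

test_that("fixture consensus count equals planted distinct transcripts", {
  fx <- default_fixture()
  expect_identical(nrow(fx$models$transcripts), nrow(fx$bundle$truth))
})

test_that("GTF records with end < start raise a parse error", {
  bad <- data.frame(chrom = "chr1", start = 200L, end = 100L,
                    strand = "+", transcript_id = "t1",
                    stringsAsFactors = FALSE)
  expect_error(merge_assemblies(list(per_sample = list(s1 = bad))),
               "end < start")
})

test_that("strand inference reads canonical splice motifs", {
  genome <- Biostrings::DNAStringSet(c(
    chrT = paste0(strrep("A", 100),          # exon1 1..100
                  "GT", strrep("A", 96), "AG",  # intron + : 101..200
                  strrep("A", 100))))        # exon2 201..300
  ex <- data.frame(chrom = "chrT", start = c(1L, 201L),
                   end = c(100L, 300L))
  expect_identical(infer_strand(ex, genome), "+")
  genome_m <- Biostrings::DNAStringSet(c(
    chrT = paste0(strrep("A", 100), "CT", strrep("A", 96), "AC",
                  strrep("A", 100))))
  expect_identical(infer_strand(ex, genome_m), "-")
  # non-canonical both ways -> unknown
  genome_x <- Biostrings::DNAStringSet(c(chrT = strrep("A", 300)))
  expect_identical(infer_strand(ex, genome_x), "unknown")
  # mono-exon: always unknown
  expect_identical(infer_strand(ex[1L, ], genome), "unknown")
  # exon beyond chromosome end
  bad <- data.frame(chrom = "chrT", start = c(1L, 290L),
                    end = c(100L, 400L))
  expect_error(infer_strand(bad, genome), "beyond chromosome")
})

test_that("classification follows the documented rules on a toy reference", {
  ref <- toy_reference()
  tx <- function(starts, ends, strand = "+")
    data.frame(chrom = "chr1", start = starts, end = ends,
               strand = strand, stringsAsFactors = FALSE)
  # exon-identical to the reference lincRNA -> annotated_ncRNA
  expect_identical(
    classify_transcript(tx(c(20001L, 24001L), c(20400L, 24400L), "-"),
                        ref)$category, "annotated_ncRNA")
  # entirely inside one intron of the coding gene -> novel_intronic
  expect_identical(
    classify_transcript(tx(1500L, 1900L), ref)$category, "novel_intronic")
  # one exon in an intron, one beyond all gene spans -> interleaving
  expect_identical(
    classify_transcript(tx(c(3500L, 8000L), c(3700L, 8200L)),
                        ref)$category, "novel_interleaving")
  # outside all spans -> intergenic
  expect_identical(
    classify_transcript(tx(10000L, 10500L), ref)$category,
    "novel_intergenic")
  # two exons flanking GENE_B entirely -> encompassing
  expect_identical(
    classify_transcript(tx(c(18000L, 26000L), c(18400L, 26400L)),
                        ref)$category, "novel_encompassing")
  # opposite-strand exonic overlap -> antisense
  expect_identical(
    classify_transcript(tx(1100L, 1300L, "-"), ref)$category, "antisense")
  # unknown strand on an exon overlap: location only, flagged,
  # never antisense
  res <- classify_transcript(tx(1100L, 1300L, "."), ref)
  expect_identical(res$category, "protein_coding")
  expect_true(res$flagged)
})

test_that("classifier agrees with a brute-force oracle on random transcripts", {
  ref <- toy_reference()
  set.seed(99)
  n_checked <- 0L
  for (i in 1:200) {
    n_ex <- sample(1:3, 1L)
    starts <- sort(sample(seq(500L, 27000L, by = 50L), n_ex))
    widths <- sample(50:400, n_ex, replace = TRUE)
    ends <- starts + widths
    if (n_ex > 1L && any(ends[-n_ex] + 10L >= starts[-1L])) next
    strand <- sample(c("+", "-", "."), 1L)
    exdf <- data.frame(chrom = "chr1", start = starts, end = ends,
                       strand = strand, stringsAsFactors = FALSE)
    got <- classify_transcript(exdf, ref)$category
    want <- brute_classify(exdf, ref)
    expect_identical(got, want,
                     info = sprintf("tx %d: %s [%s]", i,
                                    paste(starts, ends, collapse = " "),
                                    strand))
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 100L)
})

test_that("catalog category counts match ground truth and partition", {
  fx <- default_fixture()
  tx <- fx$catalog$transcripts
  lab <- fx$truth_map$label[match(tx$transcript_id,
                                  fx$truth_map$transcript_id)]
  # artifacts are novel-class by construction; exclude them from the
  # label agreement check (their labels name the artifact mechanism)
  real <- !startsWith(lab, "artifact")
  expect_identical(tx$category[real], lab[real])
  # classification partitions the catalog
  expect_identical(sum(table(tx$category)), nrow(tx))
  # strand of planted novels recovered from splice sites
  nov <- fx$truth_map[startsWith(fx$truth_map$label, "novel"), ]
  truth_strand <- fx$bundle$truth$strand[
    match(nov$planted_id, fx$bundle$truth$planted_id)]
  got_strand <- tx$strand[match(nov$transcript_id, tx$transcript_id)]
  expect_identical(got_strand, truth_strand)
})

test_that("empty bundle yields an empty catalog and duplicate ids error", {
  m <- merge_assemblies(list(per_sample = list()))
  ref <- toy_reference()
  cat0 <- build_catalog(m, ref)
  expect_identical(nrow(cat0$transcripts), 0L)
  dup <- models_from_exons(data.frame(
    chrom = "chr1", start = c(100L, 300L), end = c(200L, 400L),
    strand = "+", transcript_id = c("t1", "t1"),
    stringsAsFactors = FALSE))
  dup$transcripts <- rbind(dup$transcripts, dup$transcripts)
  expect_error(build_catalog(dup, ref), "duplicate")
})

test_that("catalog GTF round-trips through an independent parser", {
  fx <- small_fixture()
  d <- withr::local_tempdir()
  write_catalog(fx$catalog, d)
  back <- read_gtf_exons(file.path(d, "catalog.gtf"))
  orig <- fx$catalog$exons
  orig <- orig[order(orig$chrom, orig$start, orig$transcript_id), ]
  back <- back[order(back$chrom, back$start, back$transcript_id), ]
  expect_identical(nrow(back), nrow(orig))
  expect_equal(back$start, orig$start)
  expect_equal(back$end, orig$end)
  expect_identical(back$transcript_id, orig$transcript_id)
  # categories preserved in attributes
  cat_of <- stats::setNames(fx$catalog$transcripts$category,
                            fx$catalog$transcripts$transcript_id)
  expect_identical(unname(cat_of[back$transcript_id]), back$category)
})
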