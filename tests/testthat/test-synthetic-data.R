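# Synthetic-data generators: determinism, planted structure, and
# recoverability of ground truth from sidecars.

test_that("fixture config validates counts, proportions and dispersion", {
  expect_s3_class(fixture_config(), "fixture_config")
  expect_error(fixture_config(de_fraction = 1.5), "proportion")
  expect_error(fixture_config(nb_dispersion = 0), "dispersion")
  expect_error(fixture_config(n_coding_genes = -1), "non-negative")
  expect_error(fixture_config(de_log2fc_range = c(3, 1)), "increasing")
  expect_error(fixture_config(novel_presence_fraction = 0.001,
                              n_samples_NN = 2L, n_samples_PN = 2L,
                              n_samples_PP = 2L), "below 1 sample")
})

test_that("same seed gives byte-identical reference GTF and FASTA", {
  cfg <- small_config()
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  d <- withr::local_tempdir()
  write_reference_gtf(r1$annotation, file.path(d, "a.gtf"))
  write_reference_gtf(r2$annotation, file.path(d, "b.gtf"))
  expect_identical(readLines(file.path(d, "a.gtf")),
                   readLines(file.path(d, "b.gtf")))
  write_genome_fasta(r1$genome, file.path(d, "a.fa"))
  write_genome_fasta(r2$genome, file.path(d, "b.fa"))
  expect_identical(tools::md5sum(file.path(d, "a.fa"))[[1]],
                   tools::md5sum(file.path(d, "b.fa"))[[1]])
})

test_that("reference honors configured gene counts (independent re-parse)", {
  cfg <- fixture_config(seed = 3L, n_coding_genes = 50L,
                        n_antisense = 0L, n_samples_NN = 2L,
                        n_samples_PN = 2L, n_samples_PP = 2L)
  ref <- generate_reference(cfg)
  d <- withr::local_tempdir()
  write_reference_gtf(ref$annotation, file.path(d, "ref.gtf"))
  # independent parser: rtracklayer, not the package's own tables
  reparsed <- read_gtf_exons(file.path(d, "ref.gtf"))
  coding_genes <- unique(reparsed$gene_id[reparsed$gene_biotype ==
                                            "protein_coding"])
  expect_length(coding_genes, 50L)
  # no antisense requested: no opposite-strand overlapping gene pairs
  g <- ref$annotation$genes
  for (i in seq_len(nrow(g))) {
    same_chr <- g[g$chrom == g$chrom[i] & g$gene_id != g$gene_id[i], ]
    ov <- same_chr$start <= g$end[i] & same_chr$end >= g$start[i]
    expect_false(any(ov & same_chr$strand != g$strand[i]))
  }
})

test_that("reference placement errors name the sizing constraint", {
  cfg <- fixture_config(seed = 1L, chrom_length_bp = 150000L)
  expect_error(generate_reference(cfg), "too short")
})

test_that("multi-exon reference genes have >= 2 exons and GT..AG introns", {
  fx <- small_fixture()
  ex <- fx$reference$exons
  per_tx <- split(ex, ex$transcript_id)
  multi <- Filter(function(e) nrow(e) >= 2L, per_tx)
  expect_gt(length(multi), 0L)
  for (e in multi[1:5]) {
    e <- e[order(e$start), ]
    strand <- e$strand[1L]
    seq <- fx$genome[[e$chrom[1L]]]
    for (k in seq_len(nrow(e) - 1L)) {
      istart <- e$end[k] + 1L; iend <- e$start[k + 1L] - 1L
      donor <- as.character(Biostrings::subseq(seq, istart, istart + 1L))
      accept <- as.character(Biostrings::subseq(seq, iend - 1L, iend))
      if (strand == "+") expect_identical(c(donor, accept), c("GT", "AG"))
      else expect_identical(c(donor, accept), c("CT", "AC"))
    }
  }
})

test_that("assembly truth is a partition with planted presence counts", {
  fx <- default_fixture()
  truth <- fx$bundle$truth
  # every transcript carries exactly one ground-truth label
  expect_false(anyDuplicated(truth$planted_id) > 0)
  all_ids <- unique(unlist(lapply(fx$bundle$per_sample,
                                  function(df) df$transcript_id)))
  expect_setequal(all_ids, truth$planted_id)
  # planted presence: 0.6 * 216 = 129.6 -> 130 samples
  cfg <- fx$config
  k <- round(cfg$novel_presence_fraction * cfg$n_samples)
  planted <- truth[grepl("^(NOV|ART)", truth$planted_id), ]
  expect_true(all(planted$presence_n == k))
  # sidecar presence matches actual per-sample occurrence
  occur <- table(unlist(lapply(fx$bundle$per_sample,
                               function(df) unique(df$transcript_id))))
  expect_true(all(occur[planted$planted_id] == planted$presence_n))
  # premature artifacts carry their planted exon distance
  prem <- truth[truth$label == "artifact_premature", ]
  expect_true(all(prem$detail >= 200 & prem$detail <= 1500))
})

test_that("planted novel presence fraction of 50% lands on exactly half", {
  cfg <- fixture_config(seed = 2L, novel_presence_fraction = 0.5)
  ref <- generate_reference(cfg)
  bundle <- generate_sample_assemblies(cfg, ref$annotation, ref$genome)
  planted <- bundle$truth[grepl("^NOV", bundle$truth$planted_id), ]
  expect_true(all(planted$presence_n == 108L))  # 50% of 216
})

test_that("simulated counts recover planted fold changes and sizes", {
  # Monte-Carlo: PP/NN mean ratio of a planted log2FC = 2 gene is close
  # to 4 at n = 90 vs 99, across replicate fixtures
  ratios <- vapply(1:10, function(s) {
    cfg <- fixture_config(seed = s, de_fraction = 1,
                          de_log2fc_range = c(2, 2))
    genes <- data.frame(gene_id = sprintf("g%02d", 1:20), length = 1000L)
    cm <- simulate_counts(cfg, genes)
    g <- cm$truth_de$gene_id[cm$truth_de$log2fc > 0][1L]
    if (is.na(g)) return(NA_real_)
    norm <- sweep(cm$counts, 2, cm$size_factors_true, "/")
    mean(norm[g, cm$groups == "PP"]) / mean(norm[g, cm$groups == "NN"])
  }, 1)
  ratios <- ratios[!is.na(ratios)]
  expect_gt(length(ratios), 5L)
  expect_true(all(abs(log2(ratios) - 2) < 0.35))

  # de_fraction = 0: empty ground-truth DE table
  cfg0 <- fixture_config(seed = 1L, de_fraction = 0)
  cm0 <- simulate_counts(cfg0, data.frame(gene_id = "g1", length = 500L))
  expect_identical(nrow(cm0$truth_de), 0L)

  # dispersion -> 0 limit: variance/mean ratio ~ 1 at equal library sizes
  cfg <- fixture_config(seed = 4L, de_fraction = 0)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:50), length = 1000L)
  cm <- simulate_counts(cfg, genes, dispersion = 1e-15)
  norm <- sweep(cm$counts, 2, cm$size_factors_true, "/")
  vmr <- apply(norm, 1, var) / rowMeans(norm)
  expect_lt(abs(median(vmr) - 1), 0.25)

  expect_error(simulate_counts(cfg, genes, dispersion = -1), "dispersion")
})

test_that("library-size multipliers always span at least 2-fold", {
  for (s in 1:5) {
    cm <- simulate_counts(fixture_config(seed = s),
                          data.frame(gene_id = "g1", length = 500L))
    sf <- cm$size_factors_true
    expect_gte(max(sf) / min(sf), 2)
  }
})

test_that("tissue panel plants skin-specific genes and averages PN reps", {
  cfg <- fixture_config(seed = 6L)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:40),
                      skin_specific = rep(c(TRUE, FALSE), each = 20L))
  panel <- simulate_tissue_panel(cfg, genes)
  expect_identical(dim(panel$rpkm), c(40L, 19L))
  spec <- panel$rpkm[genes$skin_specific, ]
  other_cols <- setdiff(colnames(panel$rpkm), c("PN1", "PN2", "PN3"))
  expect_true(all(spec[, other_cols] == 0))
  expect_true(all(spec[, c("PN1", "PN2", "PN3")] > 0))
  # averaging yields genes x 17 with a skin column
  avg <- average_skin_replicates(panel)
  expect_identical(dim(avg), c(40L, 17L))
  expect_true("skin" %in% colnames(avg))
  expect_equal(avg[, "skin"],
               rowMeans(panel$rpkm[, c("PN1", "PN2", "PN3")]))
  # round trip through TSV
  p <- withr::local_tempfile(fileext = ".tsv")
  write_tissue_panel(panel, p)
  expect_equal(read_tissue_panel(p), panel$rpkm, tolerance = 1e-12)
})

test_that("segmentations emit nine non-empty tracks with exact counts", {
  fx <- small_fixture()
  seg <- fx$segmentations
  expect_length(seg$tracks, 9L)
  d <- withr::local_tempdir()
  write_segmentations(seg, d)
  beds <- list.files(d, pattern = "\\.bed$", full.names = TRUE)
  expect_length(beds, 9L)
  for (b in beds) {
    # independent BED parse (rtracklayer) must reproduce sidecar counts
    df <- read_segmentation_bed(b)
    expect_gt(nrow(df), 0L)
    cl <- sub("\\.bed$", "", basename(b))
    side <- seg$sidecar[seg$sidecar$cell_line == cl, ]
    expect_identical(sum(df$state == "Strong_Enhancer"), side$n_enhancer)
    expect_identical(sum(df$state == "Active_Promoter"), side$n_promoter)
  }
  # element counts differ across cell lines
  expect_gt(length(unique(seg$sidecar$n_enhancer)), 1L)
  # ectodermal lines have extra planted enhancers near novel starts
  non_ecto_max <- max(seg$sidecar$n_enhancer[
    !seg$sidecar$cell_line %in% seg$ecto_lines])
  base_ecto <- 80L + 15L * match(seg$ecto_lines, lncskin:::CELL_LINES)
  n_novel <- sum(startsWith(fx$bundle$truth$label, "novel"))
  for (i in seq_along(seg$ecto_lines)) {
    ecto_n <- seg$sidecar$n_enhancer[seg$sidecar$cell_line ==
                                       seg$ecto_lines[i]]
    expect_identical(ecto_n, base_ecto[i] + n_novel)
  }
})

test_that("mappability tracks score 1 genome-wide except planted regions", {
  fx <- small_fixture()
  mp <- fx$mappability
  low <- fx$catalog$transcripts[
    fx$catalog$transcripts$transcript_id %in%
      fx$truth_map$transcript_id[fx$truth_map$label == "artifact_lowmap"], ]
  expect_gt(nrow(low), 0L)
  for (i in seq_len(nrow(low))) {
    s <- lncskin:::track_mean_score(low$chrom[i], low$start[i], low$end[i],
                                    mp$uniqueness)
    expect_equal(s$score, 0.5)
  }
  ok <- fx$catalog$transcripts[
    fx$catalog$transcripts$category == "protein_coding", ][1, ]
  s <- lncskin:::track_mean_score(ok$chrom, ok$start, ok$end,
                                  mp$uniqueness)
  expect_equal(s$score, 1)
  # bedGraph round trip through rtracklayer
  p <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(mp$uniqueness, p)
  back <- read_track(p)
  expect_equal(back$start, mp$uniqueness$start)
  expect_equal(back$score, mp$uniqueness$score)
})

test_that("ontology DAG is acyclic with coherent module expression", {
  fx <- small_fixture()
  onto <- fx$ontology
  expect_no_error(lncskin:::topological_order(onto$terms, onto$edges))
  # only coding genes annotated
  cats <- fx$genes$category[match(unique(onto$annotations$gene_id),
                                  fx$genes$gene_id)]
  expect_true(all(cats == "protein_coding"))
  # propagation includes all ancestors of an annotated leaf
  ann <- propagate_ancestors(onto$edges, onto$annotations)
  g <- onto$modules$gene_id[1L]
  t <- onto$modules$module_term[1L]
  anc <- t
  repeat {
    more <- unique(onto$edges$parent[onto$edges$child %in% anc])
    new <- setdiff(more, anc)
    if (!length(new)) break
    anc <- c(anc, new)
  }
  expect_true(all(anc %in% ann$term[ann$gene_id == g]))

  # within-module correlation exceeds between-module, across seeds
  deltas <- vapply(1:5, function(s) {
    cfg <- fixture_config(seed = s, de_fraction = 0)
    genes <- data.frame(gene_id = sprintf("g%02d", 1:30), length = 1000L,
                        module = rep(1:5, each = 6L))
    cm <- simulate_counts(cfg, genes)
    norm <- sweep(cm$counts, 2, cm$size_factors_true, "/")
    rho <- cor(t(log2(norm + 1)), method = "spearman")
    same <- outer(genes$module, genes$module, "==")
    diag(same) <- NA
    mean(rho[same & !is.na(same)]) - mean(rho[!same & !is.na(same)])
  }, 1)
  expect_true(all(deltas > 0.2))
})
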