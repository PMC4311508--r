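# Shared fixtures, cached per test run (the default cohort-scale bundle
# takes ~20 s to build; everything downstream reuses it).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# full-size default fixture (216 samples, study-shaped)
default_fixture <- function() cached("default", build_fixture(fixture_config(seed = 1L)))

# small fast fixture for pipeline/file-level tests (28 samples)
small_config <- function(seed = 5L) {
  fixture_config(seed = seed, n_samples_NN = 12L, n_samples_PN = 4L,
                 n_samples_PP = 12L, n_coding_genes = 40L,
                 n_annotated_lncRNAs = 16L, n_pseudogenes = 6L,
                 n_antisense = 6L, n_novel_per_subtype = 3L,
                 n_artifacts_premature = 4L, n_artifacts_lowmap = 3L,
                 n_artifacts_short = 3L)
}
small_fixture <- function() cached("small", build_fixture(small_config()))

# hand-built toy reference: two genes on chr1 with known structure
#   GENE_A (+, protein_coding): exons [1001,1200], [3001,3200], [5001,5200]
#   GENE_B (-, lincRNA):        exons [20001,20400], [24001,24400]
toy_reference <- function() {
  genes <- data.frame(
    gene_id = c("GENE_A", "GENE_B"),
    biotype = c("protein_coding", "lincRNA"),
    chrom = "chr1", strand = c("+", "-"),
    start = c(1001L, 20001L), end = c(5200L, 24400L),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c(rep("GENE_A", 3L), rep("GENE_B", 2L)),
    transcript_id = c(rep("GENE_A.t1", 3L), rep("GENE_B.t1", 2L)),
    chrom = "chr1",
    strand = c(rep("+", 3L), rep("-", 2L)),
    start = c(1001L, 3001L, 5001L, 20001L, 24001L),
    end = c(1200L, 3200L, 5200L, 20400L, 24400L),
    stringsAsFactors = FALSE)
  reference_annotation(genes, exons)
}

# helper to build a transcript_models object from an exon table
models_from_exons <- function(exons, presence = NULL) {
  ids <- unique(exons$transcript_id)
  tx <- do.call(rbind, lapply(ids, function(id) {
    e <- exons[exons$transcript_id == id, , drop = FALSE]
    data.frame(transcript_id = id, chrom = e$chrom[1L],
               strand = e$strand[1L], start = min(e$start),
               end = max(e$end), n_exons = nrow(e),
               mature_length = sum(e$end - e$start + 1L),
               n_samples = 1L, stringsAsFactors = FALSE)
  }))
  presence <- presence %||% stats::setNames(
    lapply(ids, function(i) "s1"), ids)
  structure(list(transcripts = tx, exons = exons, presence = presence),
            class = "transcript_models")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force transcript classifier: tests every exon against every
# reference exon / intron / intergenic base range, independent of the
# GenomicRanges implementation path
brute_classify <- function(exons, ref) {
  strand <- exons$strand[1L]
  overlaps <- function(s1, e1, s2, e2) s1 <= e2 && e1 >= s2
  # exonic overlap with reference exons
  hit_bt <- character(0); hit_same <- character(0); hit_anti <- character(0)
  for (i in seq_len(nrow(exons))) {
    for (j in seq_len(nrow(ref$exons))) {
      if (exons$chrom[i] != ref$exons$chrom[j]) next
      if (!overlaps(exons$start[i], exons$end[i],
                    ref$exons$start[j], ref$exons$end[j])) next
      g <- ref$exons$gene_id[j]
      bt <- ref$genes$biotype[ref$genes$gene_id == g]
      cat_bt <- lncskin:::biotype_category(bt)
      if (!(strand %in% c("+", "-"))) hit_bt <- c(hit_bt, cat_bt)
      else if (strand == ref$exons$strand[j]) hit_same <- c(hit_same, cat_bt)
      else hit_anti <- c(hit_anti, cat_bt)
    }
  }
  rank <- c(protein_coding = 1, pseudogene = 2, annotated_ncRNA = 3,
            antisense = 4)
  if (length(hit_same)) return(hit_same[which.min(rank[hit_same])])
  if (length(hit_bt)) return(hit_bt[which.min(rank[hit_bt])])
  if (length(hit_anti)) return("antisense")
  # encompassing: a whole gene span inside an intron gap
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) >= 2L) {
    for (k in seq_len(nrow(exons) - 1L)) {
      gs <- exons$end[k] + 1L; ge <- exons$start[k + 1L] - 1L
      for (j in seq_len(nrow(ref$genes))) {
        if (ref$genes$chrom[j] != exons$chrom[1L]) next
        if (ref$genes$start[j] >= gs && ref$genes$end[j] <= ge)
          return("novel_encompassing")
      }
    }
  }
  # per-base location classes over each exon
  base_class <- function(chrom, pos) {
    in_span <- FALSE; in_exon <- FALSE
    for (j in seq_len(nrow(ref$genes))) {
      if (ref$genes$chrom[j] != chrom) next
      if (pos >= ref$genes$start[j] && pos <= ref$genes$end[j])
        in_span <- TRUE
    }
    for (j in seq_len(nrow(ref$exons))) {
      if (ref$exons$chrom[j] != chrom) next
      if (pos >= ref$exons$start[j] && pos <= ref$exons$end[j])
        in_exon <- TRUE
    }
    if (!in_span) "intergenic" else if (in_exon) "exonic" else "intronic"
  }
  any_intronic <- FALSE; any_intergenic <- FALSE
  all_intronic <- TRUE; all_intergenic <- TRUE
  for (i in seq_len(nrow(exons))) {
    cls <- vapply(exons$start[i]:exons$end[i],
                  function(p) base_class(exons$chrom[i], p), "")
    if (any(cls == "intronic")) any_intronic <- TRUE
    if (any(cls == "intergenic")) any_intergenic <- TRUE
    if (!all(cls == "intronic")) all_intronic <- FALSE
    if (!all(cls == "intergenic")) all_intergenic <- FALSE
  }
  if (all_intronic) return("novel_intronic")
  if (any_intronic && any_intergenic) return("novel_interleaving")
  if (all_intergenic) return("novel_intergenic")
  "novel_intronic"
}

# brute-force gap distance between two interval sets (bp; 0 on overlap)
brute_gap <- function(s1, e1, s2, e2) {
  if (s1 <= e2 && e1 >= s2) return(0)
  max(s2 - e1, s1 - e2)
}

# brute-force hypergeometric upper tail by explicit summation
brute_hyper_upper <- function(k, N, K, n) {
  if (k <= 0) return(1)
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
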