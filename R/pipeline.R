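# End-to-end orchestration: run every analysis stage in order against a
# serialized input bundle, with a checksum manifest and stage-level
# resume.

#' Pipeline configuration
#'
#' Collects input paths and every tunable threshold, validating ranges
#' up front so a bad configuration fails before any stage runs.
#'
#' @param input_dir directory holding the serialized inputs (layout of
#'   [write_fixture()]: `reference.gtf`, `genome.fa`, `assemblies/`,
#'   `counts/`, `tissue_panel.tsv`, `segmentations/`,
#'   `uniqueness.bedgraph`, `alignability.bedgraph`, `ontology/`,
#'   optional `loci.tsv`).
#' @param out_dir output directory.
#' @param seed integer seed for the sampling-based calibration.
#' @param min_fraction,distance_bp,min_mappability,min_len filter
#'   thresholds.
#' @param de_max_fdr,de_min_abs_log2fc DE significance criteria.
#' @param expressed_threshold RPKM threshold for expressed-in-tissue.
#' @param elnc_window elncRNA/plncRNA proximity window (bp).
#' @param r2_cutoff squared-correlation transfer cutoff.
#' @param beta F-measure weight for calibration.
#' @param n_samplings calibration sampling iterations.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir, seed = 1L,
                            min_fraction = 0.05, distance_bp = 2000,
                            min_mappability = 0.9, min_len = 200,
                            de_max_fdr = 0.1, de_min_abs_log2fc = 1,
                            expressed_threshold = 0.1,
                            elnc_window = 5000, r2_cutoff = 0.5,
                            beta = 5, n_samplings = 10000) {
  if (!dir.exists(input_dir))
    stopf("pipeline_config: input_dir '%s' does not exist", input_dir)
  required <- c("reference.gtf", "genome.fa", "assemblies",
                "counts", "tissue_panel.tsv", "segmentations",
                "uniqueness.bedgraph", "alignability.bedgraph", "ontology")
  missing <- required[!file.exists(file.path(input_dir, required))]
  if (length(missing))
    stopf("pipeline_config: missing input(s): %s",
          paste(missing, collapse = ", "))
  if (min_fraction < 0 || min_fraction > 1)
    stopf("pipeline_config: min_fraction must be in [0,1]")
  if (distance_bp < 0 || min_len < 0 || elnc_window <= 0)
    stopf("pipeline_config: thresholds must be non-negative")
  if (min_mappability < 0 || min_mappability > 1)
    stopf("pipeline_config: min_mappability must be in [0,1]")
  if (r2_cutoff < 0 || r2_cutoff > 1)
    stopf("pipeline_config: r2_cutoff must be in [0,1]")
  if (de_max_fdr <= 0 || de_max_fdr > 1)
    stopf("pipeline_config: de_max_fdr must be in (0,1]")
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 seed = as.integer(seed), min_fraction = min_fraction,
                 distance_bp = distance_bp,
                 min_mappability = min_mappability, min_len = min_len,
                 de_max_fdr = de_max_fdr,
                 de_min_abs_log2fc = de_min_abs_log2fc,
                 expressed_threshold = expressed_threshold,
                 elnc_window = elnc_window, r2_cutoff = r2_cutoff,
                 beta = beta, n_samplings = n_samplings),
            class = "pipeline_config")
}

PIPELINE_STAGES <- c("catalog", "filters", "de", "tissue", "proximity",
                     "inference", "regions")

manifest_path <- function(out_dir) file.path(out_dir, "manifest.tsv")

read_manifest <- function(out_dir) {
  p <- manifest_path(out_dir)
  if (!file.exists(p))
    return(data.frame(stage = character(), file = character(),
                      md5 = character(), stringsAsFactors = FALSE))
  read_tsv(p)
}

stage_valid <- function(manifest, stage, out_dir) {
  rows <- manifest[manifest$stage == stage, , drop = FALSE]
  if (nrow(rows) == 0L) return(FALSE)
  paths <- file.path(out_dir, rows$file)
  if (!all(file.exists(paths))) return(FALSE)
  all(unname(tools::md5sum(paths)) == rows$md5)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order - catalog, filters, differential
#' expression, tissue specificity, regulatory proximity, function
#' inference, region enrichment - reading inputs and intermediate
#' results only through their serialized on-disk forms. Every stage's
#' outputs are checksummed into `manifest.tsv`; with `resume = TRUE`,
#' stages whose outputs match the manifest are skipped and the first
#' stage with a missing or tampered output (and everything downstream)
#' is recomputed. Thresholds in use are logged to `pipeline.log`.
#'
#' @param config a [pipeline_config()].
#' @param resume reuse validated stage outputs (default FALSE).
#' @return list with `manifest` (data.frame), `stages_run` (character),
#'   and `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "pipeline.log")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  cat(sprintf("lncskin pipeline\nseed\t%d\n", config$seed),
      file = log_path)
  for (k in c("min_fraction", "distance_bp", "min_mappability", "min_len",
              "de_max_fdr", "de_min_abs_log2fc", "expressed_threshold",
              "elnc_window", "r2_cutoff", "beta", "n_samplings"))
    logf("%s\t%s", k, format(config[[k]]))

  old_manifest <- if (resume) read_manifest(out) else
    read_manifest(out)[0, ]
  # first invalid stage: everything from there on is recomputed
  first_bad <- length(PIPELINE_STAGES) + 1L
  for (i in seq_along(PIPELINE_STAGES)) {
    if (!stage_valid(old_manifest, PIPELINE_STAGES[i], out)) {
      first_bad <- i
      break
    }
  }
  stages_run <- character(0)
  manifest_rows <- old_manifest[
    old_manifest$stage %in% PIPELINE_STAGES[seq_len(first_bad - 1L)], ,
    drop = FALSE]
  record <- function(stage, files) {
    paths <- file.path(out, files)
    manifest_rows <<- rbind(manifest_rows, data.frame(
      stage = stage, file = files, md5 = unname(tools::md5sum(paths)),
      stringsAsFactors = FALSE))
    stages_run <<- c(stages_run, stage)
    logf("stage %s: %d file(s)", stage, length(files))
  }
  run_stage <- function(i) i >= first_bad
  ind <- config$input_dir

  # --- stage 1: catalog -------------------------------------------------
  if (run_stage(1L)) {
    ref_ex <- read_gtf_exons(file.path(ind, "reference.gtf"))
    genes <- unique(ref_ex[, c("gene_id", "gene_biotype", "chrom",
                               "strand")])
    spans <- do.call(rbind, lapply(split(ref_ex, ref_ex$gene_id),
      function(e) data.frame(gene_id = e$gene_id[1L],
                             start = min(e$start), end = max(e$end))))
    genes <- merge(genes, spans, by = "gene_id")
    names(genes)[names(genes) == "gene_biotype"] <- "biotype"
    ref <- reference_annotation(genes, ref_ex)
    genome <- Biostrings::readDNAStringSet(file.path(ind, "genome.fa"))
    names(genome) <- sub("\\s.*$", "", names(genome))
    gtfs <- list.files(file.path(ind, "assemblies"), pattern = "\\.gtf$",
                       full.names = TRUE)
    per_sample <- lapply(gtfs, function(p) {
      df <- read_gtf_exons(p)
      df[, c("chrom", "start", "end", "strand", "transcript_id")]
    })
    names(per_sample) <- sub("\\.gtf$", "", basename(gtfs))
    models <- merge_assemblies(list(per_sample = per_sample))
    catalog <- build_catalog(models, ref, genome)
    dir.create(file.path(out, "catalog"), showWarnings = FALSE)
    write_catalog(catalog, file.path(out, "catalog"))
    presence_df <- data.frame(
      transcript_id = rep(names(catalog$presence),
                          lengths(catalog$presence)),
      sample_id = unlist(catalog$presence, use.names = FALSE))
    write_tsv(presence_df, file.path(out, "catalog", "presence.tsv"))
    record("catalog", file.path("catalog",
                                c("catalog.tsv", "catalog.gtf",
                                  "presence.tsv")))
  }

  # serialized-interface readers for downstream stages
  load_catalog <- function(dir = file.path(out, "catalog")) {
    tx <- read_tsv(file.path(dir, "catalog.tsv"))
    ex <- read_gtf_exons(file.path(dir, "catalog.gtf"))
    pres <- read_tsv(file.path(dir, "presence.tsv"))
    structure(list(
      transcripts = tx,
      exons = data.frame(transcript_id = ex$transcript_id,
                         chrom = ex$chrom, strand = ex$strand,
                         start = ex$start, end = ex$end,
                         stringsAsFactors = FALSE),
      presence = split(pres$sample_id, pres$transcript_id)),
      class = "lnc_catalog")
  }
  load_ref <- function() {
    ref_ex <- read_gtf_exons(file.path(ind, "reference.gtf"))
    genes <- unique(ref_ex[, c("gene_id", "gene_biotype", "chrom",
                               "strand")])
    spans <- do.call(rbind, lapply(split(ref_ex, ref_ex$gene_id),
      function(e) data.frame(gene_id = e$gene_id[1L],
                             start = min(e$start), end = max(e$end))))
    genes <- merge(genes, spans, by = "gene_id")
    names(genes)[names(genes) == "gene_biotype"] <- "biotype"
    reference_annotation(genes, ref_ex)
  }

  # --- stage 2: filters -------------------------------------------------
  if (run_stage(2L)) {
    catalog <- load_catalog()
    ref <- load_ref()
    uniq <- read_track(file.path(ind, "uniqueness.bedgraph"))
    align <- read_track(file.path(ind, "alignability.bedgraph"))
    cm <- read_counts(file.path(ind, "counts"))
    casc <- run_cascade(catalog, ref, uniq, align, cm,
                        min_fraction = config$min_fraction,
                        distance_bp = config$distance_bp,
                        min_mappability = config$min_mappability,
                        min_len = config$min_len)
    dir.create(file.path(out, "filters"), showWarnings = FALSE)
    write_filter_report(casc$report,
                        file.path(out, "filters", "filter_report.tsv"))
    write_tsv(casc$removals, file.path(out, "filters", "removals.tsv"))
    write_catalog(casc$catalog, file.path(out, "filters", "expressed"))
    pres <- casc$catalog$presence
    write_tsv(data.frame(transcript_id = rep(names(pres), lengths(pres)),
                         sample_id = unlist(pres, use.names = FALSE)),
              file.path(out, "filters", "expressed", "presence.tsv"))
    writeLines(casc$expressed_lncRNAs,
               file.path(out, "filters", "expressed_lncRNAs.txt"))
    record("filters", file.path("filters",
      c("filter_report.tsv", "removals.tsv", "expressed/catalog.tsv",
        "expressed/catalog.gtf", "expressed/presence.tsv",
        "expressed_lncRNAs.txt")))
  }
  load_expressed <- function() load_catalog(file.path(out, "filters",
                                                      "expressed"))

  # --- stage 3: differential expression --------------------------------
  if (run_stage(3L)) {
    cm <- read_counts(file.path(ind, "counts"))
    expressed <- load_expressed()
    keep <- intersect(rownames(cm$counts),
                      expressed$transcripts$transcript_id)
    cm$counts <- cm$counts[keep, , drop = FALSE]
    cm$lengths <- cm$lengths[keep]
    dir.create(file.path(out, "de"), showWarnings = FALSE)
    comparisons <- list(c("NN", "PP"), c("PN", "PP"), c("NN", "PN"))
    results <- list()
    for (cmp in comparisons) {
      res <- nb_test(cm, cmp[1L], cmp[2L])
      res <- call_degs(res, config$de_max_fdr, config$de_min_abs_log2fc)
      nm <- paste(cmp, collapse = "_vs_")
      results[[paste(cmp, collapse = " vs ")]] <- res
      write_de_results(res, file.path(out, "de",
                                      paste0("de_", nm, ".tsv")))
    }
    write_tsv(summarize_degs(results, expressed),
              file.path(out, "de", "de_summary.tsv"))
    record("de", file.path("de", c("de_NN_vs_PP.tsv", "de_PN_vs_PP.tsv",
                                   "de_NN_vs_PN.tsv", "de_summary.tsv")))
  }

  # --- stage 4: tissue specificity -------------------------------------
  if (run_stage(4L)) {
    panel_raw <- read_tissue_panel(file.path(ind, "tissue_panel.tsv"))
    panel <- average_skin_replicates(panel_raw)
    expressed <- load_expressed()
    keep <- intersect(rownames(panel), expressed$transcripts$transcript_id)
    panel <- panel[keep, , drop = FALSE]
    ts <- specificity_index(panel)
    cat_of <- stats::setNames(expressed$transcripts$category,
                              expressed$transcripts$transcript_id)
    props <- expressed_proportions(panel, cat_of,
                                   config$expressed_threshold)
    dir.create(file.path(out, "tissue"), showWarnings = FALSE)
    write_tsv(data.frame(gene_id = rownames(ts), ts, check.names = FALSE),
              file.path(out, "tissue", "specificity.tsv"))
    write_tsv(data.frame(category = rownames(props), props,
                         check.names = FALSE),
              file.path(out, "tissue", "expressed_proportions.tsv"))
    writeLines(high_specificity_subset(ts),
               file.path(out, "tissue", "high_specificity.txt"))
    record("tissue", file.path("tissue",
      c("specificity.tsv", "expressed_proportions.tsv",
        "high_specificity.txt")))
  }

  # --- stage 5: regulatory proximity -----------------------------------
  if (run_stage(5L)) {
    beds <- list.files(file.path(ind, "segmentations"),
                       pattern = "\\.bed$", full.names = TRUE)
    tracks <- lapply(beds, read_segmentation_bed)
    names(tracks) <- sub("\\.bed$", "", basename(beds))
    ecto <- intersect(c("NHEK", "HMEC"), names(tracks))
    expressed <- load_expressed()
    rel <- catalog_relative_distances(expressed, tracks,
                                      ecto_lines = ecto)
    summ <- summarize_relative_distance(rel)
    ref_line <- if ("NHEK" %in% names(tracks)) "NHEK" else names(tracks)[1L]
    calls <- call_elnc_plnc(expressed, tracks[[ref_line]],
                            window = config$elnc_window)
    dir.create(file.path(out, "proximity"), showWarnings = FALSE)
    write_tsv(rel, file.path(out, "proximity", "relative_distances.tsv"))
    write_tsv(summ, file.path(out, "proximity", "relative_summary.tsv"))
    write_tsv(calls, file.path(out, "proximity", "elnc_plnc.tsv"))
    record("proximity", file.path("proximity",
      c("relative_distances.tsv", "relative_summary.tsv",
        "elnc_plnc.tsv")))
  }

  # --- stage 6: function inference -------------------------------------
  if (run_stage(6L)) {
    cm <- read_counts(file.path(ind, "counts"))
    expressed <- load_expressed()
    edges <- read_tsv(file.path(ind, "ontology", "ontology_edges.tsv"))
    direct <- read_tsv(file.path(ind, "ontology", "gene_to_term.tsv"))
    ann <- propagate_ancestors(edges, direct)
    sf <- size_factors(cm$counts, pseudo_reference = TRUE)
    norm <- sweep(cm$counts, 2L, sf, `/`)
    use <- names(cm$groups)[cm$groups %in% c("NN", "PP")]
    expr <- log2(norm[, use, drop = FALSE] + 1)
    tx <- expressed$transcripts
    lnc_ids <- intersect(tx$transcript_id[tx$category %in%
                                            LNCRNA_CATEGORIES],
                         rownames(expr))
    coding_ids <- intersect(unique(ann$gene_id), rownames(expr))
    calib <- calibrate_cutoff(expr[coding_ids, , drop = FALSE], ann,
                              n_samplings = config$n_samplings,
                              beta = config$beta, seed = config$seed)
    corr <- correlation_matrix(expr[lnc_ids, , drop = FALSE],
                               expr[coding_ids, , drop = FALSE])
    positions <- data.frame(gene_id = tx$transcript_id, chrom = tx$chrom,
                            start = tx$start, stringsAsFactors = FALSE)
    inferred <- transfer_functions(corr, ann, cutoff = config$r2_cutoff,
                                   positions = positions)
    de_nn_pp <- read_tsv(file.path(out, "de", "de_NN_vs_PP.tsv"))
    de_lnc <- intersect(de_nn_pp$gene_id[de_nn_pp$is_de], lnc_ids)
    enr <- if (nrow(inferred))
      inferred_function_enrichment(inferred, de_lnc) else
      list(table = data.frame(), display = data.frame())
    dir.create(file.path(out, "inference"), showWarnings = FALSE)
    write_tsv(calib$curve, file.path(out, "inference", "calibration.tsv"))
    writeLines(c(sprintf("auc\t%.6f", calib$auc),
                 sprintf("best_cutoff\t%g", calib$best_cutoff)),
               file.path(out, "inference", "calibration_summary.tsv"))
    write_tsv(inferred, file.path(out, "inference", "inferred.tsv"))
    write_tsv(enr$table, file.path(out, "inference", "enrichment.tsv"))
    write_tsv(enr$display,
              file.path(out, "inference", "enrichment_display.tsv"))
    record("inference", file.path("inference",
      c("calibration.tsv", "calibration_summary.tsv", "inferred.tsv",
        "enrichment.tsv", "enrichment_display.tsv")))
  }

  # --- stage 7: region enrichment --------------------------------------
  if (run_stage(7L)) {
    expressed <- load_expressed()
    genome <- Biostrings::readDNAStringSet(file.path(ind, "genome.fa"))
    names(genome) <- sub("\\s.*$", "", names(genome))
    chrom_lengths <- stats::setNames(as.list(Biostrings::width(genome)),
                                     names(genome))
    dens <- density_track(expressed, chrom_lengths)
    loci_path <- file.path(ind, "loci.tsv")
    loci <- if (file.exists(loci_path)) {
      lt <- read_tsv(loci_path)
      do.call(rbind, lapply(seq_len(nrow(lt)), function(i)
        region_spec(lt$name[i], lt$chrom[i], lt$start[i], lt$end[i],
                    lt$flank[i] %||% 0)))
    } else {
      # default regions of interest: the densest lncRNA bin per chromosome
      do.call(rbind, lapply(names(chrom_lengths), function(ch) {
        b <- dens$bins[dens$bins$chrom == ch, , drop = FALSE]
        top <- b[which.max(b$count), , drop = FALSE]
        region_spec(paste0(ch, "_dense"), ch, top$start, top$end)
      }))
    }
    de_nn_pp <- read_tsv(file.path(out, "de", "de_NN_vs_PP.tsv"))
    sus <- susceptibility_catalog(expressed, de_nn_pp, loci)
    # novelty enrichment in the first locus
    tx <- expressed$transcripts
    lnc <- tx[tx$category %in% LNCRNA_CATEGORIES, , drop = FALSE]
    enr_rows <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
      ids <- sus$ids[[loci$name[i]]]
      k <- sum(lnc$category[lnc$transcript_id %in% ids] %in%
                 NOVEL_CATEGORIES)
      cbind(name = loci$name[i],
            region_novelty_enrichment(k, length(ids),
                                      sum(lnc$category %in%
                                            NOVEL_CATEGORIES),
                                      nrow(lnc)))
    }))
    dir.create(file.path(out, "regions"), showWarnings = FALSE)
    write_tsv(dens$bins, file.path(out, "regions", "density.tsv"))
    writeLines(sprintf("mean_lncRNA_per_mb\t%.6f", dens$mean_per_mb),
               file.path(out, "regions", "density_summary.tsv"))
    write_tsv(sus$per_locus, file.path(out, "regions", "loci.tsv"))
    write_tsv(enr_rows, file.path(out, "regions", "novelty_enrichment.tsv"))
    record("regions", file.path("regions",
      c("density.tsv", "density_summary.tsv", "loci.tsv",
        "novelty_enrichment.tsv")))
  }

  write_tsv(manifest_rows, manifest_path(out))
  invisible(list(manifest = manifest_rows, stages_run = stages_run,
                 out_dir = out))
}

#' Write consolidated report tables
#'
#' Re-emits the three headline tables from a completed pipeline run into
#' one reports directory: the filter attrition table (monotonicity
#' asserted before writing), the per-category DE summary (percentages
#' recomputed from counts), and the inferred-function enrichment display
#' table.
#'
#' @param out_dir a completed pipeline output directory.
#' @param reports_dir destination (default `<out_dir>/reports`).
#' @return paths of the written files, invisibly.
#' @export
write_reports <- function(out_dir, reports_dir = file.path(out_dir,
                                                           "reports")) {
  dir.create(reports_dir, showWarnings = FALSE, recursive = TRUE)
  rep1 <- read_tsv(file.path(out_dir, "filters", "filter_report.tsv"))
  for (cl in setdiff(names(rep1), "stage"))
    if (is.unsorted(rev(rep1[[cl]])))
      stopf("write_reports: non-monotone attrition in category '%s'", cl)
  p1 <- file.path(reports_dir, "table_filters.tsv")
  write_tsv(rep1, p1)

  rep2 <- read_tsv(file.path(out_dir, "de", "de_summary.tsv"))
  rep2$pct_de <- mapply(de_percentage, rep2$n_de, rep2$n_expressed)
  p2 <- file.path(reports_dir, "table_de_summary.tsv")
  write_tsv(rep2, p2)

  rep3 <- read_tsv(file.path(out_dir, "inference",
                             "enrichment_display.tsv"))
  p3 <- file.path(reports_dir, "table_enrichment.tsv")
  write_tsv(rep3, p3)
  invisible(c(p1, p2, p3))
}
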