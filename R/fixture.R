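# One-call fixture builder wiring all generators together, plus a bundle
# writer for the on-disk layout the pipeline consumes.

#' Build the complete synthetic fixture bundle
#'
#' Runs every generator in sequence and wires their outputs together:
#' reference + genome, per-sample assemblies with ground truth, merged and
#' classified catalog, ontology with co-expression modules, counts (module
#' structure applied to coding genes and to lncRNAs planted to co-express
#' with them), tissue panel (all recovered novel transcripts planted
#' skin-specific, plus a seeded fraction of annotated genes),
#' segmentations and mappability tracks. Identical configs give identical
#' bundles.
#'
#' @param config a [fixture_config()].
#' @return a `fixture_bundle` list with elements `config`, `reference`,
#'   `genome`, `bundle` (assemblies + truth), `models`, `catalog`,
#'   `truth_map`, `ontology`, `genes` (the per-transcript table used for
#'   simulation), `counts`, `panel`, `segmentations`, `mappability`,
#'   `lnc_modules` (planted lncRNA-to-module assignments).
#' @export
build_fixture <- function(config = fixture_config()) {
  ref <- generate_reference(config)
  bundle <- generate_sample_assemblies(config, ref$annotation, ref$genome)
  models <- merge_assemblies(bundle)
  catalog <- build_catalog(models, ref$annotation, ref$genome)
  truth_map <- map_to_truth(catalog, bundle)

  tx <- catalog$transcripts
  genes <- data.frame(gene_id = tx$transcript_id,
                      length = tx$mature_length,
                      category = tx$category,
                      stringsAsFactors = FALSE)

  onto <- simulate_ontology(config, genes)
  genes$module <- onto$modules$module[match(genes$gene_id,
                                            onto$modules$gene_id)]

  # plant lncRNA co-expression: each expressed lncRNA joins a module so
  # guilt-by-association transfer has signal to find
  lnc_idx <- which(genes$category %in%
                     c("annotated_ncRNA", "novel_intronic",
                       "novel_intergenic", "novel_interleaving",
                       "novel_encompassing"))
  lnc_modules <- NULL
  if (length(lnc_idx) && nrow(onto$modules)) {
    mods <- sort(unique(onto$modules$module))
    assign <- with_seed(sub_seed(config$seed, 83L),
                        sample(mods, length(lnc_idx), replace = TRUE))
    genes$module[lnc_idx] <- assign
    lnc_modules <- data.frame(
      gene_id = genes$gene_id[lnc_idx], module = assign,
      module_term = onto$modules$module_term[match(assign,
                                                   onto$modules$module)],
      stringsAsFactors = FALSE)
  }

  counts <- simulate_counts(config, genes)

  genes$skin_specific <- genes$category %in%
    c("novel_intronic", "novel_intergenic", "novel_interleaving",
      "novel_encompassing")
  ann_idx <- which(!genes$skin_specific)
  n_extra <- floor(config$skin_specific_fraction * length(ann_idx))
  if (n_extra > 0) {
    extra <- with_seed(sub_seed(config$seed, 89L),
                       sample(ann_idx, n_extra))
    genes$skin_specific[extra] <- TRUE
  }
  panel <- simulate_tissue_panel(config, genes)

  seg <- simulate_segmentations(config)
  mapp <- simulate_mappability(config)

  structure(list(config = config, reference = ref$annotation,
                 genome = ref$genome, bundle = bundle, models = models,
                 catalog = catalog, truth_map = truth_map,
                 ontology = onto, genes = genes, counts = counts,
                 panel = panel, segmentations = seg, mappability = mapp,
                 lnc_modules = lnc_modules),
            class = "fixture_bundle")
}

#' Write a fixture bundle to an on-disk directory tree
#'
#' Serializes every component in the plain-text formats the pipeline
#' reads: reference GTF, genome FASTA, per-sample assembly GTFs with the
#' ground-truth sidecar, counts/groups/length TSVs, tissue panel TSV,
#' segmentation BEDs, mappability bedGraphs, and ontology TSVs.
#'
#' @param fx a `fixture_bundle` from [build_fixture()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reference_gtf(fx$reference, file.path(dir, "reference.gtf"))
  write_genome_fasta(fx$genome, file.path(dir, "genome.fa"))
  write_assembly_bundle(fx$bundle, file.path(dir, "assemblies"))
  write_counts(fx$counts, file.path(dir, "counts"))
  write_tissue_panel(fx$panel, file.path(dir, "tissue_panel.tsv"))
  write_segmentations(fx$segmentations, file.path(dir, "segmentations"))
  write_bedgraph(fx$mappability$uniqueness,
                 file.path(dir, "uniqueness.bedgraph"))
  write_bedgraph(fx$mappability$alignability,
                 file.path(dir, "alignability.bedgraph"))
  write_ontology(fx$ontology, file.path(dir, "ontology"))
  invisible(dir)
}
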