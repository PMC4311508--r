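#' Configuration for the synthetic skin-cohort fixture
#'
#' Builds and validates the configuration object consumed by every
#' `simulate_*()` / `generate_*()` function. The defaults emulate the
#' structure of a large psoriasis skin RNA-seq cohort: 216 samples
#' (90 normal controls NN, 27 uninvolved psoriatic PN, 99 lesional
#' psoriatic PP), a reference annotation with protein-coding, lincRNA,
#' pseudogene and antisense biotypes, planted novel transcripts of the
#' four subtypes (intronic, intergenic, interleaving, encompassing), and
#' planted artifact transcripts (premature-mRNA fragments, low-mappability
#' regions, short transcripts) that the QC cascade must remove.
#'
#' The fixture genome is deliberately small (2 chromosomes of a few Mb)
#' so the full pipeline runs in minutes on one CPU.
#'
#' @param seed integer master seed; identical configs (including seed)
#'   yield byte-identical fixture bundles.
#' @param n_chromosomes,chrom_length_bp genome shape.
#' @param n_coding_genes,n_annotated_lncRNAs,n_pseudogenes,n_antisense
#'   reference gene counts per biotype.
#' @param n_novel_per_subtype planted true novel transcripts per subtype
#'   (intronic/intergenic/interleaving/encompassing).
#' @param n_artifacts_premature,n_artifacts_lowmap,n_artifacts_short
#'   planted artifact transcripts per artifact class.
#' @param n_samples_NN,n_samples_PN,n_samples_PP cohort group sizes.
#' @param novel_presence_fraction fraction of samples in which each planted
#'   novel/artifact transcript is assembled (exercises the recurrence filter).
#' @param de_fraction fraction of genes with a planted NN-vs-PP fold change.
#' @param de_log2fc_range absolute log2 fold-change range for planted DE genes.
#' @param nb_dispersion negative-binomial dispersion of simulated counts.
#' @param n_tissues number of tissues in the expression panel (16 other
#'   tissues + skin).
#' @param skin_specific_fraction fraction of genes expressed only in skin.
#' @param n_ontology_terms,terms_per_gene ontology fixture shape.
#' @param module_sd standard deviation of the per-module latent log factor
#'   that induces within-function expression correlation.
#' @return a validated list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L,
                           n_chromosomes = 2L,
                           chrom_length_bp = 3000000L,
                           n_coding_genes = 60L,
                           n_annotated_lncRNAs = 30L,
                           n_pseudogenes = 12L,
                           n_antisense = 10L,
                           n_novel_per_subtype = 5L,
                           n_artifacts_premature = 8L,
                           n_artifacts_lowmap = 6L,
                           n_artifacts_short = 6L,
                           n_samples_NN = 90L,
                           n_samples_PN = 27L,
                           n_samples_PP = 99L,
                           novel_presence_fraction = 0.6,
                           de_fraction = 0.1,
                           de_log2fc_range = c(1, 3),
                           nb_dispersion = 0.1,
                           n_tissues = 17L,
                           skin_specific_fraction = 0.15,
                           n_ontology_terms = 40L,
                           terms_per_gene = 3L,
                           module_sd = 1.0) {
  cfg <- list(
    seed = seed, n_chromosomes = n_chromosomes,
    chrom_length_bp = chrom_length_bp,
    n_coding_genes = n_coding_genes,
    n_annotated_lncRNAs = n_annotated_lncRNAs,
    n_pseudogenes = n_pseudogenes, n_antisense = n_antisense,
    n_novel_per_subtype = n_novel_per_subtype,
    n_artifacts_premature = n_artifacts_premature,
    n_artifacts_lowmap = n_artifacts_lowmap,
    n_artifacts_short = n_artifacts_short,
    n_samples_NN = n_samples_NN, n_samples_PN = n_samples_PN,
    n_samples_PP = n_samples_PP,
    novel_presence_fraction = novel_presence_fraction,
    de_fraction = de_fraction, de_log2fc_range = de_log2fc_range,
    nb_dispersion = nb_dispersion, n_tissues = n_tissues,
    skin_specific_fraction = skin_specific_fraction,
    n_ontology_terms = n_ontology_terms, terms_per_gene = terms_per_gene,
    module_sd = module_sd
  )
  count_fields <- c("seed", "n_chromosomes", "chrom_length_bp",
                    "n_coding_genes", "n_annotated_lncRNAs", "n_pseudogenes",
                    "n_antisense", "n_novel_per_subtype",
                    "n_artifacts_premature", "n_artifacts_lowmap",
                    "n_artifacts_short", "n_samples_NN", "n_samples_PN",
                    "n_samples_PP", "n_tissues", "n_ontology_terms",
                    "terms_per_gene")
  for (f in count_fields) {
    if (!is_count(cfg[[f]]))
      stopf("fixture_config: '%s' must be a non-negative integer", f)
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  if (cfg$n_chromosomes < 1L) stopf("fixture_config: need >= 1 chromosome")
  for (f in c("novel_presence_fraction", "de_fraction",
              "skin_specific_fraction")) {
    if (!is_proportion(cfg[[f]]))
      stopf("fixture_config: '%s' must be a proportion in [0,1]", f)
  }
  if (cfg$nb_dispersion <= 0)
    stopf("fixture_config: nb_dispersion must be > 0")
  if (length(cfg$de_log2fc_range) != 2L || any(cfg$de_log2fc_range < 0) ||
      cfg$de_log2fc_range[1] > cfg$de_log2fc_range[2])
    stopf("fixture_config: de_log2fc_range must be an increasing pair >= 0")
  if (cfg$n_tissues < 2L)
    stopf("fixture_config: n_tissues must be >= 2")
  n_samples <- cfg$n_samples_NN + cfg$n_samples_PN + cfg$n_samples_PP
  if (n_samples < 2L) stopf("fixture_config: need >= 2 samples")
  if (cfg$novel_presence_fraction * n_samples < 1)
    stopf("fixture_config: novel_presence_fraction of %d samples is below 1 sample",
          n_samples)
  cfg$n_samples <- n_samples
  class(cfg) <- "fixture_config"
  cfg
}

#' @export
print.fixture_config <- function(x, ...) {
  cat("fixture_config (seed ", x$seed, ")\n", sep = "")
  cat("  genome: ", x$n_chromosomes, " x ", x$chrom_length_bp, " bp\n", sep = "")
  cat("  reference genes: ", x$n_coding_genes, " coding, ",
      x$n_annotated_lncRNAs, " lncRNA, ", x$n_pseudogenes, " pseudogene, ",
      x$n_antisense, " antisense\n", sep = "")
  cat("  planted novel: ", x$n_novel_per_subtype, " per subtype; artifacts: ",
      x$n_artifacts_premature, " premature, ", x$n_artifacts_lowmap,
      " low-mappability, ", x$n_artifacts_short, " short\n", sep = "")
  cat("  cohort: ", x$n_samples_NN, " NN / ", x$n_samples_PN, " PN / ",
      x$n_samples_PP, " PP\n", sep = "")
  invisible(x)
}
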