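# Multi-tissue RPKM panel: 16 non-skin tissues plus three uninvolved-skin
# (PN) replicates whose average forms the skin column.

OTHER_TISSUES <- c("adipose", "adrenal", "brain", "breast", "colon",
                   "heart", "kidney", "liver", "lung", "lymph_node",
                   "ovary", "prostate", "muscle", "testis", "thyroid",
                   "white_blood_cells")

#' Simulate the multi-tissue expression panel
#'
#' RPKM values for every gene across 16 non-skin tissues and three PN skin
#' replicates. A seeded fraction of genes (or an explicit id set) is
#' planted skin-specific: expressed only in the skin replicates. The skin
#' column of the final 17-tissue panel is the average of the three PN
#' replicates (see [average_skin_replicates()]).
#'
#' @param config a [fixture_config()]; `n_tissues` must be 17 (16 other
#'   tissues + skin).
#' @param genes data.frame with `gene_id`; optionally `skin_specific`
#'   (logical) to plant an explicit set, otherwise
#'   `config$skin_specific_fraction` of genes is drawn.
#' @return a `tissue_panel` object: list with `rpkm` (genes x 19 matrix:
#'   16 tissues + PN1..PN3), `skin_specific` (gene ids).
#' @export
simulate_tissue_panel <- function(config, genes) {
  stopifnot(inherits(config, "fixture_config"), "gene_id" %in% names(genes))
  if (config$n_tissues != length(OTHER_TISSUES) + 1L)
    stopf("simulate_tissue_panel: n_tissues must be %d (16 other tissues + skin)",
          length(OTHER_TISSUES) + 1L)
  n_genes <- nrow(genes)
  with_seed(sub_seed(config$seed, 53L), {
    if ("skin_specific" %in% names(genes)) {
      spec <- which(genes$skin_specific)
    } else {
      n_spec <- floor(config$skin_specific_fraction * n_genes)
      spec <- if (n_spec > 0) sort(sample(n_genes, n_spec)) else integer(0)
    }
    base <- stats::rlnorm(n_genes, meanlog = log(10), sdlog = 1)
    cols <- c(OTHER_TISSUES, "PN1", "PN2", "PN3")
    rpkm <- matrix(0, n_genes, length(cols),
                   dimnames = list(genes$gene_id, cols))
    for (j in seq_along(cols)) {
      rpkm[, j] <- base * stats::rlnorm(n_genes, 0, 0.3)
    }
    if (length(spec))
      rpkm[spec, OTHER_TISSUES] <- 0
    structure(list(rpkm = rpkm, skin_specific = genes$gene_id[spec]),
              class = "tissue_panel")
  })
}

#' Average the PN skin replicates into a single skin column
#'
#' Collapses the three PN replicate columns into one `skin` column by
#' averaging, yielding the final genes x 17-tissue RPKM matrix.
#'
#' @param panel a `tissue_panel` or a genes x 19 matrix with PN1..PN3
#'   columns.
#' @return genes x 17 RPKM matrix (16 tissues + `skin`).
#' @export
average_skin_replicates <- function(panel) {
  m <- if (inherits(panel, "tissue_panel")) panel$rpkm else panel
  pn_cols <- grep("^PN", colnames(m))
  if (length(pn_cols) == 0L)
    stopf("average_skin_replicates: no PN replicate columns found")
  skin <- rowMeans(m[, pn_cols, drop = FALSE])
  out <- cbind(m[, -pn_cols, drop = FALSE], skin = skin)
  out
}

#' Write a tissue panel to TSV
#' @param panel a `tissue_panel`.
#' @param path output TSV path (genes x columns, `gene_id` first).
#' @return `path`, invisibly.
#' @export
write_tissue_panel <- function(panel, path) {
  m <- if (inherits(panel, "tissue_panel")) panel$rpkm else panel
  write_tsv(data.frame(gene_id = rownames(m), m, check.names = FALSE), path)
  invisible(path)
}

#' Read a tissue panel from TSV
#' @param path TSV written by [write_tissue_panel()].
#' @return genes x columns RPKM matrix.
#' @export
read_tissue_panel <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}
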