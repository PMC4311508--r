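# Negative-binomial read-count simulation with planted fold changes,
# planted library-size multipliers, and optional co-expression modules.

#' Simulate a read-count matrix for the fixture cohort
#'
#' Draws per-gene, per-sample counts from a negative binomial with
#' gene-specific means, library-size multipliers spanning at least 2-fold,
#' and planted NN-vs-PP log2 fold changes for a `de_fraction` of genes.
#' PN sample means equal NN means, emulating the near-identity of
#' uninvolved and normal skin transcriptomes. Genes sharing a
#' co-expression `module` receive a common per-sample latent factor
#' (log-normal, sd `config$module_sd`), inducing within-module expression
#' correlation for the function-inference calibration.
#'
#' @param config a [fixture_config()].
#' @param genes data.frame with `gene_id`, `length` (mature bp), and
#'   optionally `module` (integer or NA) and `de_eligible` (logical; genes
#'   from which the planted DE set is drawn, default all).
#' @param dispersion negative-binomial dispersion; defaults to
#'   `config$nb_dispersion`. `dispersion` below `1e-12` uses the Poisson
#'   limit.
#' @return a `counts_matrix` object: list with `counts` (genes x samples
#'   integer matrix), `samples`, `groups`, `lengths`, `size_factors_true`,
#'   `truth_de` (data.frame `gene_id`, `log2fc`), `modules`.
#' @export
simulate_counts <- function(config, genes, dispersion = NULL) {
  stopifnot(inherits(config, "fixture_config"),
            all(c("gene_id", "length") %in% names(genes)))
  dispersion <- dispersion %||% config$nb_dispersion
  if (dispersion <= 0)
    stopf("simulate_counts: dispersion must be > 0")
  n_genes <- nrow(genes)
  samples <- c(sprintf("NN%03d", seq_len(config$n_samples_NN)),
               sprintf("PN%03d", seq_len(config$n_samples_PN)),
               sprintf("PP%03d", seq_len(config$n_samples_PP)))
  groups <- stats::setNames(
    c(rep("NN", config$n_samples_NN), rep("PN", config$n_samples_PN),
      rep("PP", config$n_samples_PP)), samples)
  n_samples <- length(samples)

  with_seed(sub_seed(config$seed, 41L), {
    base_mean <- stats::rlnorm(n_genes, meanlog = log(80), sdlog = 1)

    # planted DE set
    eligible <- if ("de_eligible" %in% names(genes))
      which(genes$de_eligible) else seq_len(n_genes)
    n_de <- floor(config$de_fraction * length(eligible))
    de_idx <- if (n_de > 0) sort(sample(eligible, n_de)) else integer(0)
    lfc <- numeric(n_genes)
    if (n_de > 0) {
      mag <- stats::runif(n_de, config$de_log2fc_range[1],
                          config$de_log2fc_range[2])
      lfc[de_idx] <- mag * sample(c(-1, 1), n_de, replace = TRUE)
    }

    # library-size multipliers rescaled to [0.6, 1.3] so the spread is
    # always >= 2-fold
    raw <- stats::runif(n_samples)
    if (n_samples >= 2L) {
      raw <- (raw - min(raw)) / (max(raw) - min(raw))
      size_factors <- 0.6 + raw * 0.7
    } else size_factors <- 1
    names(size_factors) <- samples

    # mean matrix
    mu <- outer(base_mean, size_factors)
    is_pp <- groups == "PP"
    if (any(lfc != 0))
      mu[, is_pp] <- mu[, is_pp] * 2^lfc

    modules <- if ("module" %in% names(genes)) genes$module else
      rep(NA_integer_, n_genes)
    if (any(!is.na(modules))) {
      for (m in unique(modules[!is.na(modules)])) {
        f <- exp(stats::rnorm(n_samples, 0, config$module_sd))
        rows <- which(modules == m)
        mu[rows, ] <- sweep(mu[rows, , drop = FALSE], 2, f, `*`)
      }
    }

    counts <- if (dispersion < 1e-12) {
      matrix(stats::rpois(length(mu), lambda = mu), nrow = n_genes)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             nrow = n_genes)
    }
    dimnames(counts) <- list(genes$gene_id, samples)

    truth_de <- data.frame(gene_id = genes$gene_id[de_idx],
                           log2fc = lfc[de_idx],
                           stringsAsFactors = FALSE)
    structure(list(counts = counts, samples = samples, groups = groups,
                   lengths = stats::setNames(genes$length, genes$gene_id),
                   size_factors_true = size_factors,
                   truth_de = truth_de, modules = modules),
              class = "counts_matrix")
  })
}

#' @export
print.counts_matrix <- function(x, ...) {
  cat("counts_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples (", paste(sprintf("%s=%d", names(table(x$groups)),
                                  as.integer(table(x$groups))),
                          collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Write a counts matrix bundle to TSV files
#' @param cm a `counts_matrix`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_counts <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  write_tsv(df, file.path(dir, "counts.tsv"))
  write_tsv(data.frame(sample_id = cm$samples,
                       group = unname(cm$groups[cm$samples])),
            file.path(dir, "groups.tsv"))
  write_tsv(data.frame(gene_id = names(cm$lengths),
                       length = unname(cm$lengths)),
            file.path(dir, "gene_lengths.tsv"))
  write_tsv(cm$truth_de, file.path(dir, "truth_de.tsv"))
  invisible(dir)
}

#' Read a counts matrix bundle from TSV files
#' @param dir directory written by [write_counts()].
#' @return a `counts_matrix` (without simulation ground truth unless
#'   `truth_de.tsv` is present).
#' @export
read_counts <- function(dir) {
  df <- read_tsv(file.path(dir, "counts.tsv"))
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene_id
  storage.mode(counts) <- "integer"
  grp <- read_tsv(file.path(dir, "groups.tsv"))
  len <- read_tsv(file.path(dir, "gene_lengths.tsv"))
  truth_path <- file.path(dir, "truth_de.tsv")
  truth <- if (file.exists(truth_path)) read_tsv(truth_path) else NULL
  structure(list(counts = counts, samples = grp$sample_id,
                 groups = stats::setNames(grp$group, grp$sample_id),
                 lengths = stats::setNames(len$length, len$gene_id),
                 size_factors_true = NULL, truth_de = truth,
                 modules = NULL),
            class = "counts_matrix")
}
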