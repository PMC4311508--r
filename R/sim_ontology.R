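# Ontology fixture: a rooted DAG plus direct gene-to-term annotations for
# coding genes only (lncRNAs are left unannotated, as in real catalogs
# where almost no lncRNA carries a functional annotation).

#' Simulate an ontology DAG and gene annotations
#'
#' Generates a rooted, possibly multi-parent, acyclic term graph and
#' assigns direct annotations to protein-coding genes only. Each coding
#' gene gets one "module" term - a leaf-level functional group - plus
#' `terms_per_gene - 1` random additional terms. The module index is the
#' hook [simulate_counts()] uses to give genes of the same function
#' correlated expression, so functional coherence holds in the fixture.
#'
#' Acyclicity holds by construction (parents always precede children);
#' it is still verified with a topological sort and an internal
#' consistency error is raised if that ever fails.
#'
#' @param config a [fixture_config()].
#' @param genes data.frame with `gene_id` and `category` (catalog labels;
#'   only `protein_coding` rows receive annotations).
#' @return an `ontology_fixture`: list with `terms`, `root`, `edges`
#'   (data.frame `child`, `parent`), `annotations` (data.frame `gene_id`,
#'   `term`; direct annotations only), `modules` (data.frame `gene_id`,
#'   `module`, `module_term`).
#' @export
simulate_ontology <- function(config, genes) {
  stopifnot(inherits(config, "fixture_config"),
            all(c("gene_id", "category") %in% names(genes)))
  n_terms <- config$n_ontology_terms
  if (n_terms < 4L) stopf("simulate_ontology: need >= 4 terms")
  coding <- genes$gene_id[genes$category == "protein_coding"]
  with_seed(sub_seed(config$seed, 71L), {
    terms <- sprintf("T%04d", seq_len(n_terms))
    root <- terms[1L]
    edges <- do.call(rbind, lapply(2:n_terms, function(i) {
      n_par <- if (i <= 3L) 1L else sample(1:2, 1L)
      parents <- sample(seq_len(i - 1L), min(n_par, i - 1L))
      data.frame(child = terms[i], parent = terms[parents],
                 stringsAsFactors = FALSE)
    }))
    rownames(edges) <- NULL

    # internal consistency: topological order must exist
    order_ok <- tryCatch({
      topological_order(terms, edges); TRUE
    }, error = function(e) FALSE)
    if (!order_ok)
      stopf("simulate_ontology: internal consistency error - generated term graph contains a cycle")

    # module terms: the deepest (last) half of the term list
    module_terms <- terms[(n_terms %/% 2L + 1L):n_terms]
    ann <- NULL; mod <- NULL
    if (length(coding)) {
      module_idx <- rep(seq_along(module_terms),
                        length.out = length(coding))
      mod <- data.frame(gene_id = coding, module = module_idx,
                        module_term = module_terms[module_idx],
                        stringsAsFactors = FALSE)
      extra <- max(0L, config$terms_per_gene - 1L)
      ann <- do.call(rbind, lapply(seq_along(coding), function(g) {
        tset <- mod$module_term[g]
        if (extra > 0L)
          tset <- unique(c(tset, sample(terms[-1L], extra)))
        data.frame(gene_id = coding[g], term = tset,
                   stringsAsFactors = FALSE)
      }))
      rownames(ann) <- NULL
    } else {
      ann <- data.frame(gene_id = character(), term = character(),
                        stringsAsFactors = FALSE)
      mod <- data.frame(gene_id = character(), module = integer(),
                        module_term = character(), stringsAsFactors = FALSE)
    }
    structure(list(terms = terms, root = root, edges = edges,
                   annotations = ann, modules = mod),
              class = "ontology_fixture")
  })
}

# Kahn topological sort; errors (naming an offending edge) on cycles.
topological_order <- function(terms, edges) {
  indeg <- stats::setNames(rep(0L, length(terms)), terms)
  tab <- table(edges$child)
  indeg[names(tab)] <- as.integer(tab)
  out_edges <- split(edges$child, edges$parent)
  queue <- names(indeg)[indeg == 0L]
  order <- character(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (w in out_edges[[v]] %||% character(0)) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) < length(terms)) {
    rem <- setdiff(terms, order)
    bad <- edges[edges$child %in% rem & edges$parent %in% rem, , drop = FALSE]
    stopf("cycle detected in ontology involving edge %s -> %s",
          bad$child[1L], bad$parent[1L])
  }
  order
}

#' Write an ontology fixture to TSV files
#' @param onto an `ontology_fixture`.
#' @param dir output directory (`ontology_edges.tsv`, `gene_to_term.tsv`).
#' @return `dir`, invisibly.
#' @export
write_ontology <- function(onto, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(onto$edges, file.path(dir, "ontology_edges.tsv"))
  write_tsv(onto$annotations, file.path(dir, "gene_to_term.tsv"))
  invisible(dir)
}
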