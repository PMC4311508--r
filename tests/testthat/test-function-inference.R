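# Ancestor propagation, co-expression transfer, F-beta calibration, and
# enrichment of inferred functions.

test_that("ancestor propagation closes chains and is idempotent", {
  edges <- data.frame(child = c("c", "b"), parent = c("b", "a"))
  ann <- data.frame(gene_id = "g1", term = "c")
  out <- propagate_ancestors(edges, ann)
  expect_setequal(out$term[out$gene_id == "g1"], c("a", "b", "c"))
  # annotated at the root: unchanged
  ann_root <- data.frame(gene_id = "g2", term = "a")
  out2 <- propagate_ancestors(edges, ann_root)
  expect_identical(out2$term, "a")
  # idempotent
  out3 <- propagate_ancestors(edges, out)
  expect_setequal(out3$term[out3$gene_id == "g1"],
                  out$term[out$gene_id == "g1"])
  # cycle detection names an offending edge
  cyc <- data.frame(child = c("a", "b"), parent = c("b", "a"))
  expect_error(propagate_ancestors(cyc, ann), "cycle")
})

test_that("propagation equals a transitive-closure oracle on random DAGs", {
  for (s in 1:5) {
    set.seed(s)
    n <- 12L
    terms <- sprintf("t%02d", 1:n)
    edges <- do.call(rbind, lapply(2:n, function(i) {
      k <- sample(1:min(2, i - 1), 1L)
      data.frame(child = terms[i],
                 parent = terms[sample(seq_len(i - 1), k)])
    }))
    ann <- data.frame(gene_id = "g",
                      term = sample(terms, 3L))
    got <- sort(propagate_ancestors(edges, ann)$term)
    # oracle: boolean reachability matrix powers
    adj <- matrix(FALSE, n, n, dimnames = list(terms, terms))
    adj[cbind(edges$child, edges$parent)] <- TRUE
    reach <- adj
    for (i in 1:n) reach <- reach | (reach %*% adj > 0)
    want <- unique(c(ann$term,
                     unlist(lapply(ann$term, function(t)
                       terms[reach[t, ]]))))
    expect_identical(got, sort(want))
  }
})

test_that("squared Spearman correlation: monotone 1, anti-monotone 1, oracle", {
  x <- matrix(c(1, 2, 3, 4, 5), 1, dimnames = list("l1", NULL))
  up <- matrix(c(2, 4, 6, 8, 10), 1, dimnames = list("g_up", NULL))
  down <- matrix(c(10, 8, 6, 4, 2), 1, dimnames = list("g_dn", NULL))
  cm <- correlation_matrix(x, rbind(up, down))
  expect_equal(unname(cm$r2["l1", ]), c(1, 1))
  expect_setequal(cm$argmax$l1, c("g_up", "g_dn"))
  # small vectors vs a brute-force midrank computation
  brute_spearman <- function(a, b) {
    ra <- rank(a); rb <- rank(b)
    sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  }
  set.seed(8)
  for (i in 1:20) {
    a <- sample(1:5, 8, replace = TRUE)  # ties on purpose
    b <- sample(1:5, 8, replace = TRUE)
    got <- correlation_matrix(matrix(a, 1, dimnames = list("a", NULL)),
                              matrix(b, 1, dimnames = list("b", NULL)))
    expect_equal(unname(got$r2[1, 1]), brute_spearman(a, b)^2,
                 tolerance = 1e-12)
  }
  # constant profile flagged undefined
  const <- matrix(5, 1, 5, dimnames = list("flat", NULL))
  cm2 <- correlation_matrix(const, up)
  expect_true("flat" %in% cm2$undefined)
})

test_that("F-beta matches the stated formula and its identities", {
  # rho = 1, gamma = 0.5, beta = 5 -> 26 * 0.5 / 25.5
  expect_equal(f_beta(1, 0.5, 5), 26 * 0.5 / 25.5)
  expect_equal(f_beta(1, 0.5, 5), 0.5098, tolerance = 1e-4)
  # wherever precision = recall, F = that value
  for (v in c(0.1, 0.5, 0.9)) expect_equal(f_beta(v, v, 5), v)
  expect_equal(f_beta(0, 0, 5), 0)
})

test_that("calibration is seed-reproducible with AUC above chance", {
  fx <- default_fixture()
  cm <- fx$counts
  sf <- size_factors(cm$counts, pseudo_reference = TRUE)
  norm <- sweep(cm$counts, 2, sf, "/")
  use <- names(cm$groups)[cm$groups %in% c("NN", "PP")]
  expr <- log2(norm[, use] + 1)
  ann <- propagate_ancestors(fx$ontology$edges, fx$ontology$annotations)
  coding <- intersect(unique(ann$gene_id), rownames(expr))
  c1 <- calibrate_cutoff(expr[coding, ], ann, n_samplings = 2000,
                         beta = 5, seed = 17L,
                         root_term = fx$ontology$root)
  c2 <- calibrate_cutoff(expr[coding, ], ann, n_samplings = 2000,
                         beta = 5, seed = 17L,
                         root_term = fx$ontology$root)
  expect_identical(c1$curve, c2$curve)
  expect_identical(c1$best_cutoff, c2$best_cutoff)
  expect_identical(c1$auc, c2$auc)
  expect_gt(c1$auc, 0.6)
  # precision/recall land in [0,1]; F bounded accordingly
  expect_true(all(c1$curve$precision >= 0 & c1$curve$precision <= 1))
  expect_true(all(c1$curve$recall >= 0 & c1$curve$recall <= 1))
  expect_true(all(c1$curve$f_beta >= 0 & c1$curve$f_beta <= 1))
})

test_that("transfer respects the cutoff boundary and tie union", {
  corr <- list(
    max_r2 = c(l_low = 0.49, l_hit = 0.8),
    argmax = list(l_low = "gA", l_hit = c("gA", "gB")),
    undefined = character(0))
  ann <- data.frame(gene_id = c("gA", "gA", "gB"),
                    term = c("t1", "t2", "t3"))
  out <- transfer_functions(corr, ann, cutoff = 0.5)
  expect_false("l_low" %in% out$lnc_id)           # 0.49 < 0.5: no transfer
  expect_setequal(out$term[out$lnc_id == "l_hit"], c("t1", "t2", "t3"))
  expect_identical(unique(out$source_genes[out$lnc_id == "l_hit"]),
                   "gA,gB")
  # cis flag when a source lies within 1 Mb on the same chromosome
  pos <- data.frame(gene_id = c("l_hit", "gA", "gB"),
                    chrom = c("chr1", "chr1", "chr2"),
                    start = c(1e6, 1.5e6, 1e6))
  out2 <- transfer_functions(corr, ann, cutoff = 0.5, positions = pos)
  expect_true(all(out2$is_cis[out2$lnc_id == "l_hit"]))
})

test_that("planted co-expressed lncRNAs recover their module terms", {
  fx <- default_fixture()
  cm <- fx$counts
  sf <- size_factors(cm$counts, pseudo_reference = TRUE)
  norm <- sweep(cm$counts, 2, sf, "/")
  use <- names(cm$groups)[cm$groups %in% c("NN", "PP")]
  expr <- log2(norm[, use] + 1)
  ann <- propagate_ancestors(fx$ontology$edges, fx$ontology$annotations)
  coding <- intersect(unique(ann$gene_id), rownames(expr))
  lnc <- intersect(fx$lnc_modules$gene_id, rownames(expr))
  corr <- correlation_matrix(expr[lnc, ], expr[coding, ])
  inf <- transfer_functions(corr, ann, cutoff = 0.5)
  lm <- fx$lnc_modules[fx$lnc_modules$gene_id %in% lnc, ]
  hit <- vapply(seq_len(nrow(lm)), function(i)
    lm$module_term[i] %in% inf$term[inf$lnc_id == lm$gene_id[i]], TRUE)
  expect_gte(mean(hit), 0.8)
  # transferred term sets stay closed under ancestry
  parent_of <- split(fx$ontology$edges$parent, fx$ontology$edges$child)
  for (l in unique(inf$lnc_id)[1:5]) {
    terms <- inf$term[inf$lnc_id == l]
    parents <- unlist(parent_of[terms], use.names = FALSE)
    expect_true(all(parents %in% terms))
  }
})

test_that("enrichment reproduces observed/expected ratios from counts", {
  # N = 959 lncRNAs with inferred functions, n = 490 differentially
  # expressed: a 42-gene term with 41 DE members has FC 1.91, a 69-gene
  # term with 60 DE members 1.70
  expect_equal(round(enrichment_fc(41, 42, 490, 959), 2), 1.91)
  expect_equal(round(enrichment_fc(60, 69, 490, 959), 2), 1.70)
  expect_equal(round(enrichment_fc(72, 87, 490, 959), 2), 1.62)
  expect_equal(round(enrichment_fc(22, 23, 490, 959), 2), 1.87)
  expect_equal(enrichment_fc(0, 10, 490, 959), 0)
})

test_that("hypergeometric tail equals explicit summation for small N", {
  set.seed(12)
  for (i in 1:50) {
    N <- sample(20:200, 1L)
    K <- sample(1:N, 1L)
    n <- sample(1:N, 1L)
    k <- sample(0:min(K, n), 1L)
    expect_equal(hyper_upper_tail(k, N, K, n),
                 brute_hyper_upper(k, N, K, n), tolerance = 1e-12)
  }
  expect_equal(hyper_upper_tail(0, 100, 10, 5), 1)
  expect_error(hyper_upper_tail(1, 10, 5, 20), "exceed")
})

test_that("inferred-function enrichment builds the display subset", {
  inferred <- data.frame(
    lnc_id = c(sprintf("l%02d", 1:10), sprintf("l%02d", 1:4)),
    term = c(rep("tA", 10), rep("tB", 4)),
    source_genes = "g", r2 = 0.9, is_cis = FALSE,
    stringsAsFactors = FALSE)
  de <- sprintf("l%02d", 1:4)
  enr <- inferred_function_enrichment(inferred, de)
  expect_identical(enr$N, 10L)
  expect_identical(enr$n, 4L)
  tb <- enr$table
  expect_equal(tb$fc[tb$term == "tB"],
               enrichment_fc(4, 4, 4, 10))
  expect_equal(tb$p_value[tb$term == "tB"],
               brute_hyper_upper(4, 10, 4, 4))
  # display filter keeps FDR <= 0.1 and K <= 100
  expect_true(all(enr$display$fdr <= 0.1 & enr$display$K <= 100))
  expect_error(inferred_function_enrichment(inferred[0, ], de), "universe")
})
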