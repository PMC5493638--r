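toy_corr_table <- function(r, p, genes = paste0("g", seq_along(r)),
                           anchor = "ANCH") {
  structure(data.frame(gene_id = genes, r = r, p = p, n = 10,
                       stringsAsFactors = FALSE),
            class = c("anchor_correlation_table", "data.frame"),
            anchor_gene = anchor)
}

test_that("anchor correlation reproduces the direct Pearson formula", {
  x <- expression_matrix(rbind(c(1, 2, 3, 4),
                               c(2, 1, 4, 3),
                               c(4, 3, 2, 1),
                               c(5, 5, 5, 5)),
                         gene_ids = c("ANCH", "g1", "g2", "flat"),
                         sample_ids = paste0("s", 1:4))
  tab <- anchor_correlation(x, "ANCH")
  expect_equal(tab$r[tab$gene_id == "ANCH"], 1)
  expect_equal(tab$r[tab$gene_id == "g1"],
               oracle_pearson(c(1, 2, 3, 4), c(2, 1, 4, 3)))
  expect_equal(tab$r[tab$gene_id == "g2"], -1)
  expect_true(is.na(tab$r[tab$gene_id == "flat"]))
  # p cross-checked against stats::cor.test
  expect_equal(tab$p[tab$gene_id == "g1"],
               stats::cor.test(c(1, 2, 3, 4), c(2, 1, 4, 3))$p.value)
  expect_error(anchor_correlation(x, "nope"), "not in")
  x2 <- x; x2["ANCH", ] <- 3
  expect_error(anchor_correlation(expression_matrix(x2), "ANCH"),
               "zero variance")
})

test_that("anchor correlation is invariant to positive per-gene affine
           maps", {
  set.seed(5)
  x <- expression_matrix(matrix(rnorm(60), nrow = 6),
                         gene_ids = c("ANCH", paste0("g", 1:5)),
                         sample_ids = paste0("s", 1:10))
  tab <- anchor_correlation(x, "ANCH")
  a <- runif(6, 0.5, 2); b <- rnorm(6)
  tab2 <- anchor_correlation(expression_matrix(x * a + b), "ANCH")
  expect_equal(tab2$r, tab$r, tolerance = 1e-9)
})

test_that("threshold selection applies r and p cutoffs as stated", {
  tab <- toy_corr_table(r = c(0.9, 0.41, 0.39, -0.8),
                        p = rep(1e-5, 4))
  sel <- select_synexpression_set(tab)
  expect_setequal(sel$members, c("g1", "g2"))
  sel_abs <- select_synexpression_set(tab, use_absolute_r = TRUE)
  expect_setequal(sel_abs$members, c("g1", "g2", "g4"))
  expect_error(select_synexpression_set(tab, r_min = 1.1), "empty")
  # top-n mode ranks by |r|
  sel_top <- select_synexpression_set(tab, mode = "top_n", n_top = 2)
  expect_setequal(sel_top$members, c("g1", "g4"))
})

test_that("threshold selection is monotone in r_min and excludes the
           anchor", {
  set.seed(9)
  tab <- toy_corr_table(r = c(1, round(runif(20, -1, 1), 2)),
                        p = c(0, runif(20, 0, 0.01)),
                        genes = c("ANCH", paste0("g", 1:20)))
  prev <- NULL
  for (rmin in c(0.6, 0.4, 0.2, 0)) {
    sel <- try(select_synexpression_set(tab, r_min = rmin), silent = TRUE)
    members <- if (inherits(sel, "try-error")) character(0) else sel$members
    expect_false("ANCH" %in% members)
    if (!is.null(prev)) expect_true(all(prev %in% members))
    prev <- members
  }
})

test_that("clustering matches a brute-force average-linkage oracle on
           small inputs", {
  set.seed(13)
  for (i in 1:40) {
    n <- sample(3:6, 1)
    x <- expression_matrix(matrix(rnorm(8 * n), nrow = 8),
                           gene_ids = paste0("g", 1:8),
                           sample_ids = paste0("s", 1:n))
    got <- cluster_samples(x, paste0("g", 1:8),
                           n_clusters = min(2, n))
    # oracle distance computed from scratch: z-score by hand, 1 - Pearson
    z <- t(apply(x, 1, function(v) (v - mean(v)) / stats::sd(v)))
    D <- matrix(0, n, n)
    for (a in 1:n) for (b in 1:n)
      D[a, b] <- 1 - oracle_pearson(z[, a], z[, b])
    oracle <- oracle_average_linkage(D)
    expect_equal(sort(got$hclust$height), sort(oracle$heights),
                 tolerance = 1e-9)
    expect_identical(partition_from_labels(got$cluster),
                     canonical_partition(oracle$partition2))
  }
})

test_that("duplicate-sample groups are recovered perfectly and boundary
           cuts behave", {
  base <- matrix(rnorm(10 * 2), nrow = 10)
  x <- expression_matrix(cbind(base[, 1], base[, 1], base[, 2], base[, 2]),
                         gene_ids = paste0("g", 1:10),
                         sample_ids = c("a1", "a2", "b1", "b2"))
  cl <- cluster_samples(x, paste0("g", 1:10))
  expect_identical(partition_from_labels(cl$cluster),
                   list(c(1L, 2L), c(3L, 4L)))
  # n_clusters = n_samples: every sample its own cluster
  cl4 <- cluster_samples(x, paste0("g", 1:10), n_clusters = 4)
  expect_equal(length(unique(cl4$cluster)), 4)
  expect_error(cluster_samples(x, "g1"), "fewer than 2")
})

test_that("the lower-expression cluster is labeled reduced", {
  set.seed(3)
  g <- paste0("g", 1:20)
  x <- matrix(rnorm(20 * 10), nrow = 20,
              dimnames = list(g, paste0("s", 1:10)))
  x[, 6:10] <- x[, 6:10] - 2          # second group reduced on all genes
  x <- expression_matrix(rbind(ANCH = rnorm(10), x))
  corr <- toy_corr_table(r = rep(0.8, 20), p = rep(1e-5, 20), genes = g)
  cl <- cluster_samples(x, g, distance = "euclidean")
  cl <- label_clusters(cl, x, g, corr)
  expect_setequal(names(cl$subset)[cl$subset == "reduced"],
                  paste0("s", 6:10))
  # flipping every gene's values and every r leaves labels unchanged
  xf <- expression_matrix(-x)
  corr_f <- toy_corr_table(r = rep(-0.8, 20), p = rep(1e-5, 20), genes = g)
  clf <- label_clusters(cluster_samples(xf, g, distance = "euclidean"),
                        xf, g, corr_f)
  expect_equal(clf$subset, cl$subset)
})

test_that("exported heatmap matrix is row-standardized in leaf order and
           round-trips", {
  cfg <- cohort_sim_config(suppression_delta = 2, synexpr_block_size = 30,
                           n_background_genes = 20, seed = 41)
  qc <- list(sim = simulate_biopsy_cohort(cfg))
  corr <- anchor_correlation(qc$sim$expr, "ADIPOQ")
  syn <- select_synexpression_set(corr)
  cl <- cluster_samples(qc$sim$expr, syn)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_heatmap_matrix(qc$sim$expr, syn, cl, path, corr = corr)
  z <- read_expression_matrix(path)
  expect_lt(max(abs(rowMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 1, stats::sd) - 1)), 1e-9)
  expect_identical(colnames(z), cl$hclust$labels[cl$hclust$order])
  side <- utils::read.delim(paste0(path, ".clusters.tsv"))
  expect_identical(side$sample_id, colnames(z))
})

test_that("the pipeline recovers a strongly suppressed subset end to end", {
  skip_if_not_installed("mclust")
  # euclidean distance on z-scored genes: the planted module signal is a
  # level shift, which correlation distance discards by construction (see
  # the methods vignette); delta = 3 is the regime where the module
  # dominates the latent factor
  res <- vapply(1:50, function(i) {
    cfg <- cohort_sim_config(suppression_delta = 3, n_background_genes = 100,
                             seed = 8000 + i)
    sim <- simulate_biopsy_cohort(cfg)
    corr <- anchor_correlation(sim$expr, "ADIPOQ")
    syn <- select_synexpression_set(corr)
    cl <- label_clusters(cluster_samples(sim$expr, syn,
                                         distance = "euclidean"),
                         sim$expr, syn, corr)
    cases <- sim$meta$sample_id[sim$meta$group == "case"]
    truth_low <- sim$truth$sample_labels[cases] == "case_low"
    c(ari = mclust::adjustedRandIndex(cl$subset[cases], truth_low),
      cov = mean(cl$subset[cases][truth_low] == "reduced"))
  }, numeric(2))
  expect_gte(mean(res["ari", ] >= 0.8), 0.9)
  expect_gte(mean(res["cov", ] >= 0.9), 0.9)
})
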