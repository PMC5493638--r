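ref_fixture <- function() {
  # 2 genes, k = (+1, -1), control means (1, 1), SDs (1, 2)
  x <- expression_matrix(rbind(c(0, 1, 2, 3), c(-1, 1, 3, 2)),
                         gene_ids = c("up1", "dn1"),
                         sample_ids = c("c1", "c2", "c3", "s1"))
  meta <- sample_metadata(colnames(x), c("control", "control", "control",
                                         "case"))
  sig <- gene_signature("up1", "dn1")
  list(x = x, meta = meta, sig = sig)
}

test_that("control reference holds per-gene control mean and SD", {
  f <- ref_fixture()
  ref <- fit_control_reference(f$x, f$meta, f$sig)
  expect_equal(ref$genes$mean, c(1, 1))
  expect_equal(ref$genes$sd, c(1, 2))
  expect_equal(ref$n_controls, 3)
})

test_that("zero-SD and absent genes are excluded with reasons", {
  x <- expression_matrix(rbind(c(2, 2, 2, 5), c(1, 2, 3, 4)),
                         gene_ids = c("flat", "ok"),
                         sample_ids = c("c1", "c2", "c3", "s1"))
  meta <- sample_metadata(colnames(x),
                          c("control", "control", "control", "case"))
  sig <- gene_signature(c("flat", "ok"), "ghost")
  ref <- fit_control_reference(x, meta, sig)
  expect_equal(ref$genes$gene_id, "ok")
  expect_setequal(ref$excluded$gene_id, c("flat", "ghost"))
  expect_true(any(grepl("zero control SD", ref$excluded$reason)))
  # all genes excluded -> error
  sig2 <- gene_signature("flat", "ghost")
  expect_error(fit_control_reference(x, meta, sig2), "impossible")
})

test_that("fewer than 2 controls is a validation error", {
  f <- ref_fixture()
  meta1 <- sample_metadata(colnames(f$x), c("control", "case", "case", "case"))
  expect_error(fit_control_reference(f$x, meta1, f$sig), "at least 2")
})

test_that("the signed z-sum evaluates the score formula exactly", {
  f <- ref_fixture()
  ref <- fit_control_reference(f$x, f$meta, f$sig)
  # case sample: up1 = 3, dn1 = 2 -> (3-1)/1 * 1 + (2-1)/2 * (-1) = 1.5
  sc <- compute_pathway_scores(f$x, ref, f$sig)
  expect_equal(sc$score[sc$sample_id == "s1"], 1.5)
  expect_equal(unique(sc$n_genes), 2)
  # a sample exactly at the control means scores 0
  x0 <- f$x
  x0[, "s1"] <- c(1, 1)
  expect_equal(compute_pathway_scores(x0, fit_control_reference(
    x0, f$meta, f$sig), f$sig)$score[4], 0)
})

test_that("control scores average exactly zero on their own reference", {
  qc <- quick_cohort(seed = 31)
  ref <- fit_control_reference(qc$sim$expr, qc$sim$meta, qc$cfg$signature)
  sc <- compute_pathway_scores(qc$sim$expr, ref)
  ctl <- qc$sim$meta$sample_id[qc$sim$meta$group == "control"]
  expect_lt(abs(mean(sc$score[match(ctl, sc$sample_id)])), 1e-9)
})

test_that("scores are invariant under per-gene positive affine transforms", {
  qc <- quick_cohort(seed = 32)
  ref <- fit_control_reference(qc$sim$expr, qc$sim$meta, qc$cfg$signature)
  sc <- compute_pathway_scores(qc$sim$expr, ref)
  set.seed(1)
  a <- runif(nrow(qc$sim$expr), 0.5, 3)
  b <- rnorm(nrow(qc$sim$expr), 0, 5)
  expr2 <- expression_matrix(qc$sim$expr * a + b)
  sc2 <- compute_pathway_scores(
    expr2, fit_control_reference(expr2, qc$sim$meta, qc$cfg$signature))
  expect_equal(sc2$score, sc$score, tolerance = 1e-9)
})

test_that("negating every k negates every score and mirrors the call", {
  qc <- quick_cohort(seed = 33)
  sig <- qc$cfg$signature
  flipped <- gene_signature(sig$down, sig$up)
  ref <- fit_control_reference(qc$sim$expr, qc$sim$meta, sig)
  ref_f <- fit_control_reference(qc$sim$expr, qc$sim$meta, flipped)
  sc <- compute_pathway_scores(qc$sim$expr, ref, sig)
  sc_f <- compute_pathway_scores(qc$sim$expr, ref_f, flipped)
  expect_equal(sc_f$score[match(sc$sample_id, sc_f$sample_id)], -sc$score)
  # classification of negated scores flags exactly the samples at or above
  # the mirrored (upper-CI) threshold of the original scores
  cls_f <- classify_samples(sc_f, qc$sim$meta)
  ctl <- sc$score[qc$sim$meta$group[match(sc$sample_id,
                                          qc$sim$meta$sample_id)] == "control"]
  upper <- mean(ctl) + stats::qt(0.975, length(ctl) - 1) *
    stats::sd(ctl) / sqrt(length(ctl))
  expect_equal(attr(cls_f, "threshold"), -upper)
  is_case <- qc$sim$meta$group[match(sc_f$sample_id,
                                     qc$sim$meta$sample_id)] == "case"
  orig <- sc$score[match(sc_f$sample_id, sc$sample_id)]
  expect_equal(cls_f$class[is_case] == "low", (orig >= upper)[is_case])
})

test_that("the control-CI threshold matches the published t quantile", {
  sc <- structure(data.frame(sample_id = c("c1", "c2", "c3", "s1", "s2"),
                             score = c(-1, 0, 1, -3, -2), n_genes = 2),
                  class = c("pathway_score_table", "data.frame"))
  meta <- sample_metadata(sc$sample_id,
                          c("control", "control", "control", "case", "case"))
  cls <- classify_samples(sc, meta, method = "ci_of_mean")
  # 0 - 4.3027 * 1/sqrt(3) from the t table with 2 df
  expect_equal(attr(cls, "threshold"), -4.302653 / sqrt(3),
               tolerance = 1e-6)
  expect_equal(cls$class, c("control", "control", "control", "low", "normal"))
  # a case score exactly at the threshold is low (the rule is "<=")
  sc$score[4] <- attr(cls, "threshold")
  cls2 <- classify_samples(sc, meta)
  expect_equal(cls2$class[4], "low")
  # spread-based alternative
  cls3 <- classify_samples(sc, meta, method = "mean_minus_z_sd")
  expect_equal(attr(cls3, "threshold"), -stats::qnorm(0.975))
})

test_that("cases above the control maximum are all normal; absent cases
           warn", {
  sc <- structure(data.frame(sample_id = paste0("x", 1:5),
                             score = c(-1, 0, 1, 5, 9), n_genes = 2),
                  class = c("pathway_score_table", "data.frame"))
  meta <- sample_metadata(sc$sample_id,
                          c("control", "control", "control", "case", "case"))
  cls <- classify_samples(sc, meta)
  expect_equal(cls$class[4:5], c("normal", "normal"))
  meta_all_ctl <- sample_metadata(sc$sample_id, rep("control", 5))
  expect_warning(classify_samples(sc, meta_all_ctl), "no case")
})

test_that("lowering a case score can only move it from normal to low", {
  sc <- structure(data.frame(sample_id = paste0("x", 1:4),
                             score = c(-1, 1, 0.5, -2.6), n_genes = 2),
                  class = c("pathway_score_table", "data.frame"))
  meta <- sample_metadata(sc$sample_id, c("control", "control", "case", "case"))
  base <- classify_samples(sc, meta)$class
  for (drop in c(0.1, 1, 5)) {
    sc2 <- sc
    sc2$score[3] <- sc2$score[3] - drop
    moved <- classify_samples(sc2, meta)$class
    expect_true(moved[3] == base[3] || (base[3] == "normal" && moved[3] == "low"))
    expect_equal(moved[4], base[4])
  }
})

test_that("null case-score spread matches the sqrt(m) prediction", {
  # independent genes, no suppression: SD of case scores across replicates
  # within 15% of sqrt(m)
  sds <- vapply(1:200, function(i) {
    qc <- quick_cohort(seed = 7000 + i, suppression_delta = 0,
                       n_case_normal = 5, n_case_low = 0)
    ref <- fit_control_reference(qc$sim$expr, qc$sim$meta, qc$cfg$signature)
    sc <- compute_pathway_scores(qc$sim$expr, ref)
    sc$score[qc$sim$meta$group[match(sc$sample_id,
                                     qc$sim$meta$sample_id)] == "case"]
  }, numeric(5))
  expect_lt(abs(stats::sd(as.vector(sds)) - sqrt(29)) / sqrt(29), 0.15)
})

test_that("score-covariate correlation matches the direct Pearson formula", {
  sc <- structure(data.frame(sample_id = paste0("x", 1:4),
                             score = c(1, 2, 3, 4), n_genes = 2),
                  class = c("pathway_score_table", "data.frame"))
  cov <- c(x1 = 2, x2 = 1, x3 = 4, x4 = 3)
  out <- correlate_scores_with_covariate(sc, cov)
  expect_equal(out$r, oracle_pearson(1:4, c(2, 1, 4, 3)))
  expect_equal(out$r, 0.6)
  # independent route: stats::cor.test
  ct <- stats::cor.test(1:4, c(2, 1, 4, 3))
  expect_equal(out$p, ct$p.value)
  # identity and antisymmetry
  expect_equal(correlate_scores_with_covariate(
    sc, stats::setNames(sc$score, sc$sample_id))$r, 1)
  expect_equal(correlate_scores_with_covariate(
    sc, stats::setNames(-sc$score, sc$sample_id))$r, -1)
  # degenerate inputs
  expect_error(correlate_scores_with_covariate(sc, cov[1:2]), "at least 3")
  expect_error(correlate_scores_with_covariate(
    sc, stats::setNames(rep(1, 4), sc$sample_id)), "zero variance")
})
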