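# Small fixture builders shared across test files.

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A 3-gene x 2-sample matrix with known values.
tiny_expr <- function() {
  expression_matrix(matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE),
                    gene_ids = c("G1", "G2", "G3"),
                    sample_ids = c("S1", "S2"))
}

# A cohort sized like the motivating study, with small gene overhead so
# simulation-heavy tests stay fast.
quick_cohort <- function(seed, suppression_delta = 1, ...) {
  cfg <- cohort_sim_config(suppression_delta = suppression_delta,
                           synexpr_block_size = 0,
                           n_background_genes = 20, seed = seed, ...)
  list(cfg = cfg, sim = simulate_biopsy_cohort(cfg))
}

# Score + classify a simulated cohort, returning per-subset call rates.
classify_cohort <- function(sim, sig, method = "mean_minus_z_sd") {
  ref <- fit_control_reference(sim$expr, sim$meta, sig)
  sc <- compute_pathway_scores(sim$expr, ref, sig)
  classify_samples(sc, sim$meta, method = method)
}
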