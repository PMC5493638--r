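#' Assemble a pipeline configuration
#'
#' One flat list drives the whole analysis; every stage parameter has the
#' package default and can be overridden here or loaded from a YAML file via
#' [read_pipeline_config()]. A single seed governs both simulation stages
#' (split deterministically per stage).
#'
#' Two input modes: by default a perturbation dataset and a biopsy cohort
#' are simulated (`perturbation` / `cohort` override lists are forwarded to
#' the generator configs); alternatively set `expr_path`, `meta_path` and
#' `signature_path` to run on files on disk.
#'
#' @param seed integer seed (mandatory).
#' @param out_dir output directory for all artifacts.
#' @param expr_path,meta_path,signature_path optional file-input mode.
#' @param perturbation,cohort named lists of generator overrides.
#' @param k_top,metric signature-derivation parameters.
#' @param classify_method,conf_level classification parameters.
#' @param anchor_gene,synexpr_mode,r_min,p_max,n_top,use_absolute_r
#'   synexpression-selection parameters.
#' @param n_clusters,distance,linkage clustering parameters.
#' @param p_method,ci_level association parameters.
#' @param covariate optional metadata column to correlate scores with.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed, out_dir = tempfile("adipostrat_run_"),
                            expr_path = NULL, meta_path = NULL,
                            signature_path = NULL,
                            perturbation = list(), cohort = list(),
                            k_top = 20, metric = "difference",
                            classify_method = "ci_of_mean", conf_level = 0.95,
                            anchor_gene = "ADIPOQ",
                            synexpr_mode = "threshold", r_min = 0.4,
                            p_max = 0.005, n_top = 500,
                            use_absolute_r = FALSE,
                            n_clusters = 2, distance = "pearson",
                            linkage = "average",
                            p_method = "chisq", ci_level = 0.95,
                            covariate = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  file_mode <- !is.null(expr_path)
  if (file_mode && (is.null(meta_path) || is.null(signature_path)))
    stop("file-input mode needs expr_path, meta_path and signature_path",
         call. = FALSE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, raw)
}

stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

#' Run the full stratification pipeline
#'
#' Stages, in dependency order: simulate (or load) inputs; derive the signed
#' signature from the perturbation dataset and intersect it with the cohort
#' platform; fit the control reference and compute pathway scores; classify
#' cases low/normal; build the anchor synexpression set, cluster samples on
#' it and label the reduced subset; tabulate subset x status and compute the
#' enrichment odds ratio, CI and p; correlate scores with a covariate when
#' one is configured. All intermediate TSV/GMT artifacts plus a
#' machine-readable JSON report are written under `config$out_dir`. Output
#' is deterministic given the config (seed included).
#'
#' @param config a [pipeline_config()].
#' @return the report, a `pipeline_report` list (also written as
#'   `report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) file.path(config$out_dir, name)

  if (config$file_mode) {
    expr <- read_expression_matrix(config$expr_path)
    meta <- read_sample_metadata(config$meta_path,
                                 case_labels = c("case", "ssc"))
    signature <- read_signature_gmt(config$signature_path)
    sig_raw_sizes <- c(up = length(signature$up), down = length(signature$down))
    truth <- NULL
  } else {
    pert_cfg <- do.call(perturbation_sim_config,
                        c(config$perturbation,
                          list(seed = stage_seed(config$seed, 0))))
    pert <- simulate_perturbation_dataset(pert_cfg)
    diff_tab <- differential_response(pert$expr, pert$meta)
    sig_raw <- select_top_k(diff_tab, k_top = config$k_top,
                            metric = config$metric)
    sig_raw_sizes <- c(up = length(sig_raw$up), down = length(sig_raw$down))
    cohort_cfg <- do.call(cohort_sim_config,
                          c(config$cohort,
                            list(signature = sig_raw,
                                 seed = stage_seed(config$seed, 1))))
    cohort <- simulate_biopsy_cohort(cohort_cfg)
    expr <- cohort$expr; meta <- cohort$meta; truth <- cohort$truth
    signature <- intersect_platform(sig_raw, rownames(expr))
    write_expression_matrix(expr, art("expression.tsv"))
    write_sample_metadata(meta, art("metadata.tsv"))
    utils::write.table(
      data.frame(sample_id = names(truth$sample_labels),
                 subset = unname(truth$sample_labels)),
      art("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_signature_gmt(signature, art("signature.gmt"))

  ref <- fit_control_reference(expr, meta, signature)
  scores <- compute_pathway_scores(expr, ref, signature)
  scores <- classify_samples(scores, meta, method = config$classify_method,
                             conf_level = config$conf_level)
  utils::write.table(scores, art("scores.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  corr <- anchor_correlation(expr, config$anchor_gene)
  synexpr <- select_synexpression_set(corr, mode = config$synexpr_mode,
                                      r_min = config$r_min,
                                      p_max = config$p_max,
                                      n_top = config$n_top,
                                      use_absolute_r = config$use_absolute_r)
  write_gene_set_gmt(synexpr, art("synexpression.gmt"))
  export_ranked_gene_list(corr, art("ranked_genes.txt"))

  assign <- cluster_samples(expr, synexpr, n_clusters = config$n_clusters,
                            distance = config$distance,
                            linkage = config$linkage)
  assign <- label_clusters(assign, expr, synexpr, corr)
  export_heatmap_matrix(expr, synexpr, assign, art("heatmap_matrix.tsv"),
                        corr = corr,
                        labels_path = art("clusters.tsv"))

  tab <- contingency_from_labels(assign$subset, meta)
  assoc <- associate(tab, level = config$ci_level,
                     p_method = config$p_method)

  covariate_cor <- NULL
  if (!is.null(config$covariate) && config$covariate %in% names(meta)) {
    covariate_cor <- correlate_scores_with_covariate(
      scores, stats::setNames(meta[[config$covariate]], meta$sample_id))
  }

  subset_counts <- table(factor(unname(assign$subset),
                                levels = c("reduced", "normal-like")),
                         meta$group[match(names(assign$subset),
                                          meta$sample_id)])
  report <- structure(list(
    package_version = as.character(utils::packageVersion("adipostrat")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("out_dir"))],
    signature_sizes = list(derived = as.list(sig_raw_sizes),
                           after_platform = list(up = length(signature$up),
                                                 down = length(signature$down))),
    genes_scored = nrow(ref$genes),
    genes_excluded = nrow(ref$excluded),
    synexpression_set_size = length(synexpr$members),
    classification = as.list(table(scores$class)),
    score_threshold = attr(scores, "threshold"),
    subset_counts = list(
      case_reduced = unname(subset_counts["reduced", "case"]),
      case_normal_like = unname(subset_counts["normal-like", "case"]),
      control_reduced = unname(subset_counts["reduced", "control"]),
      control_normal_like = unname(subset_counts["normal-like", "control"])),
    association = assoc[c("odds_ratio", "ci_low", "ci_high", "ci_level",
                          "ci_method", "p_value", "p_method")],
    covariate_correlation = covariate_cor),
    class = "pipeline_report")
  jsonlite::write_json(unclass(report), art("report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE, pretty = TRUE)
  report
}

#' Export a rank-ordered gene list for external GO tools
#'
#' One gene identifier per line, ordered by decreasing anchor correlation
#' (ties broken lexicographically); the format expected by ranked-list GO
#' enrichment tools. Genes with undefined r are dropped.
#'
#' @param corr an [anchor_correlation()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_ranked_gene_list <- function(corr, path) {
  tab <- corr[is.finite(corr$r), , drop = FALSE]
  if (!nrow(tab)) stop("empty correlation table", call. = FALSE)
  ord <- order(-tab$r, tab$gene_id)
  writeLines(tab$gene_id[ord], path)
  invisible(path)
}
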