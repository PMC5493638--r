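#' Configuration for a simulated two-arm perturbation experiment
#'
#' Emulates a hormone-treated versus vehicle cell experiment with planted
#' responder genes: a fraction of genes is shifted up, a fraction down, in
#' the treated arm only. Per-gene baselines are drawn from Normal(8, 1.5) on
#' the log2 scale (the typical centre of array intensity distributions) and
#' noise is i.i.d. Normal with SD `gene_sd`.
#'
#' @param n_genes total number of genes.
#' @param n_per_arm samples per arm (>= 2).
#' @param n_up,n_down planted responder counts per direction.
#' @param effect_size mean log2 shift of a responder, in units of `gene_sd`.
#' @param gene_sd per-gene noise SD (log2 units).
#' @param baseline_mean,baseline_sd distribution of per-gene baseline means.
#' @param seed integer seed; mandatory so every dataset is reproducible.
#' @return a `perturbation_sim_config` list.
#' @export
perturbation_sim_config <- function(n_genes = 500, n_per_arm = 10,
                                    n_up = 20, n_down = 20,
                                    effect_size = 2, gene_sd = 1,
                                    baseline_mean = 8, baseline_sd = 1.5,
                                    seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  cfg <- list(n_genes = as.integer(n_genes), n_per_arm = as.integer(n_per_arm),
              n_up = as.integer(n_up), n_down = as.integer(n_down),
              effect_size = effect_size, gene_sd = gene_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              seed = as.integer(seed))
  if (cfg$n_up + cfg$n_down > cfg$n_genes)
    stop("n_up + n_down must not exceed n_genes", call. = FALSE)
  if (cfg$effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (cfg$n_per_arm < 2) stop("n_per_arm must be >= 2", call. = FALSE)
  if (cfg$gene_sd <= 0) stop("gene_sd must be > 0", call. = FALSE)
  structure(cfg, class = "perturbation_sim_config")
}

#' Simulate a two-arm perturbation dataset with planted responders
#'
#' The first `n_up` genes respond `+effect_size * gene_sd` and the next
#' `n_down` genes `-effect_size * gene_sd` in the treated arm; all other
#' genes are null. Identical config (including seed) gives bitwise-identical
#' output.
#'
#' @param config a [perturbation_sim_config()].
#' @return list with `expr` (genes x samples matrix), `meta` (sample
#'   metadata; treated arm carries group `case`, label `treated`), and
#'   `truth` (planted responder lists and arm labels).
#' @export
simulate_perturbation_dataset <- function(config) {
  stopifnot(inherits(config, "perturbation_sim_config"))
  set.seed(config$seed)
  g <- config$n_genes
  n <- config$n_per_arm
  gene_ids <- sprintf("GENE%04d", seq_len(g))
  up <- gene_ids[seq_len(config$n_up)]
  down <- gene_ids[config$n_up + seq_len(config$n_down)]
  sample_ids <- c(sprintf("TRT%02d", seq_len(n)), sprintf("VEH%02d", seq_len(n)))
  mu <- stats::rnorm(g, config$baseline_mean, config$baseline_sd)
  x <- matrix(stats::rnorm(g * 2L * n, sd = config$gene_sd), nrow = g) + mu
  shift <- numeric(g)
  shift[seq_len(config$n_up)] <- config$effect_size * config$gene_sd
  shift[config$n_up + seq_len(config$n_down)] <- -config$effect_size * config$gene_sd
  x[, seq_len(n)] <- x[, seq_len(n)] + shift
  expr <- expression_matrix(x, gene_ids, sample_ids)
  meta <- sample_metadata(sample_ids,
                          group = rep(c("case", "control"), each = n),
                          group_label = rep(c("treated", "vehicle"), each = n))
  truth <- structure(list(
    sample_labels = stats::setNames(rep(c("treated", "control"), each = n),
                                    sample_ids),
    up_genes = up, down_genes = down, synexpression_genes = character(0)),
    class = "cohort_truth")
  list(expr = expr, meta = meta, truth = truth)
}

#' Configuration for a simulated biopsy cohort
#'
#' Emulates a skin-biopsy cohort with three latent subsets: controls, a
#' normal-like case subgroup, and a pathway-suppressed case subgroup whose
#' signature genes are shifted *against* their signs k (up genes down, down
#' genes up) by `suppression_delta` control-SD units. The anchor gene and a
#' block of `synexpr_block_size` co-expression genes share a per-sample
#' latent factor (loading `factor_loading`), and — because a suppressed
#' pathway also lowers the anchor transcript and its co-regulated module —
#' are themselves shifted down in the suppressed subgroup: the anchor by
#' `suppression_delta` SD units, each module gene by `suppression_delta`
#' times its own response amplitude, drawn once per gene from Exp(1) (mean
#' 1) to emulate the fold-change heterogeneity of real co-regulated
#' modules. `suppression_delta = 0` is a clean global null.
#'
#' Defaults mirror the cohort shape of the motivating study: 22 controls,
#' 41 normal-like and 29 pathway-low cases, a 29-gene signature (16 up, 13
#' down), unit noise SD and unit suppression.
#'
#' @param n_control,n_case_normal,n_case_low subset sample counts.
#' @param signature a [gene_signature()]; its genes are planted in the matrix.
#' @param n_background_genes unstructured null genes added to the universe.
#' @param suppression_delta per-gene shift of the suppressed subgroup, in
#'   units of the per-gene SD.
#' @param synexpr_block_size number of co-expression genes tied to the anchor.
#' @param anchor_gene_id identifier of the anchor transcript.
#' @param factor_loading loading of the shared latent factor on the anchor
#'   and block genes; Pearson r between a block gene and the anchor under the
#'   null is about `loading^2 / (loading^2 + noise_sd^2)`.
#' @param noise_sd per-gene noise SD (log2 units).
#' @param baseline_mean,baseline_sd distribution of per-gene baseline means.
#' @param seed integer seed; mandatory.
#' @return a `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_control = 22, n_case_normal = 41,
                              n_case_low = 29,
                              signature = default_signature(),
                              n_background_genes = 400,
                              suppression_delta = 1,
                              synexpr_block_size = 50,
                              anchor_gene_id = "ADIPOQ",
                              factor_loading = 1, noise_sd = 1,
                              baseline_mean = 8, baseline_sd = 1.5,
                              seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(inherits(signature, "gene_signature"))
  cfg <- list(n_control = as.integer(n_control),
              n_case_normal = as.integer(n_case_normal),
              n_case_low = as.integer(n_case_low),
              signature = signature,
              n_background_genes = as.integer(n_background_genes),
              suppression_delta = suppression_delta,
              synexpr_block_size = as.integer(synexpr_block_size),
              anchor_gene_id = as.character(anchor_gene_id),
              factor_loading = factor_loading, noise_sd = noise_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              seed = as.integer(seed))
  if (any(c(cfg$n_control, cfg$n_case_normal, cfg$n_case_low,
            cfg$n_background_genes, cfg$synexpr_block_size) < 0))
    stop("counts must be >= 0", call. = FALSE)
  if (cfg$n_control < 2)
    stop("n_control must be >= 2 (control standardization needs it)",
         call. = FALSE)
  if (cfg$anchor_gene_id %in% c(signature$up, signature$down))
    stop("anchor gene must not be part of the signature", call. = FALSE)
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  structure(cfg, class = "cohort_sim_config")
}

#' Default 29-gene signature used by the cohort simulator
#'
#' Sixteen induced and thirteen suppressed placeholder genes — the signature
#' size retained after platform intersection in the motivating study.
#' @return a [gene_signature()].
#' @export
default_signature <- function() {
  gene_signature(sprintf("SIGUP%02d", 1:16), sprintf("SIGDN%02d", 1:13))
}

#' Simulate a biopsy cohort with planted pathway suppression
#'
#' Gene universe: signature genes, the anchor gene, `synexpr_block_size`
#' co-expression genes (`SYN...`), and `n_background_genes` null genes
#' (`BG...`). See [cohort_sim_config()] for the generative model.
#'
#' @param config a [cohort_sim_config()].
#' @return list with `expr`, `meta` (groups control/case; case subtype in
#'   `group_label`), and `truth` (per-sample subset label among
#'   control/case_normal/case_low, plus the planted synexpression genes).
#' @export
simulate_biopsy_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  sig <- config$signature
  syn <- if (config$synexpr_block_size > 0)
    sprintf("SYN%04d", seq_len(config$synexpr_block_size)) else character(0)
  bg <- if (config$n_background_genes > 0)
    sprintf("BG%04d", seq_len(config$n_background_genes)) else character(0)
  gene_ids <- c(sig$up, sig$down, config$anchor_gene_id, syn, bg)
  if (anyDuplicated(gene_ids))
    stop("gene universe has duplicated identifiers", call. = FALSE)
  n_s <- c(config$n_control, config$n_case_normal, config$n_case_low)
  sample_ids <- c(sprintf("CTRL%02d", seq_len(n_s[1L])),
                  sprintf("SSCN%02d", seq_len(n_s[2L])),
                  sprintf("SSCL%02d", seq_len(n_s[3L])))
  subset <- rep(c("control", "case_normal", "case_low"), times = n_s)
  g <- length(gene_ids); s <- length(sample_ids)
  mu <- stats::rnorm(g, config$baseline_mean, config$baseline_sd)
  x <- matrix(stats::rnorm(g * s, sd = config$noise_sd), nrow = g,
              dimnames = list(gene_ids, sample_ids)) + mu
  # shared latent factor on anchor + co-expression block
  f <- stats::rnorm(s)
  factor_genes <- c(config$anchor_gene_id, syn)
  x[factor_genes, ] <- x[factor_genes, , drop = FALSE] +
    config$factor_loading * rep(f, each = length(factor_genes))
  # per-gene response amplitude of the co-regulated module (anchor fixed at
  # 1); exponential spread emulates the fold-change heterogeneity of real
  # co-regulated genes
  amp <- c(1, stats::rexp(length(syn)))
  # pathway suppression in the case_low subgroup: signature genes move
  # against k; the anchor and its co-expression module move down, each
  # module gene by its own amplitude
  low <- subset == "case_low"
  if (any(low) && config$suppression_delta != 0) {
    d <- config$suppression_delta * config$noise_sd
    x[sig$up, low] <- x[sig$up, low, drop = FALSE] - d
    x[sig$down, low] <- x[sig$down, low, drop = FALSE] + d
    x[factor_genes, low] <- x[factor_genes, low, drop = FALSE] - d * amp
  }
  expr <- expression_matrix(x)
  meta <- sample_metadata(sample_ids,
                          group = ifelse(subset == "control", "control", "case"),
                          group_label = ifelse(subset == "control", "control", "SSc"))
  truth <- structure(list(
    sample_labels = stats::setNames(subset, sample_ids),
    up_genes = sig$up, down_genes = sig$down,
    synexpression_genes = syn,
    synexpression_amplitudes = stats::setNames(amp, factor_genes)),
    class = "cohort_truth")
  list(expr = expr, meta = meta, truth = truth)
}
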