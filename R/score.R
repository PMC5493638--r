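#' Fit the control reference for pathway scoring
#'
#' For every signature gene, the mean and SD (n-1 denominator) of its
#' expression over the healthy-control samples. These per-gene control
#' statistics standardize every biopsy before the signed sum. Signature
#' genes absent from the matrix or with zero control SD are excluded (with
#' the reason recorded); at least one gene must survive.
#'
#' @param expr genes x samples matrix.
#' @param meta sample metadata; rows with group `control` define the
#'   reference (at least 2 required).
#' @param sig a [gene_signature()].
#' @return object of class `control_reference`: data.frame `genes`
#'   (`gene_id`, `k`, `mean`, `sd`), `n_controls`, data.frame `excluded`
#'   (`gene_id`, `reason`).
#' @export
fit_control_reference <- function(expr, meta, sig) {
  expr <- validate_expression_matrix(expr)
  controls <- intersect(colnames(expr),
                        meta$sample_id[meta$group == "control"])
  if (length(controls) < 2)
    stop("need at least 2 control samples to fit the reference (found ",
         length(controls), ")", call. = FALSE)
  k <- signature_k(sig)
  genes <- names(k)
  present <- genes %in% rownames(expr)
  excluded <- data.frame(gene_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (any(!present))
    excluded <- rbind(excluded,
                      data.frame(gene_id = genes[!present],
                                 reason = "absent from expression matrix",
                                 stringsAsFactors = FALSE))
  genes <- genes[present]
  ctr <- expr[genes, controls, drop = FALSE]
  m <- rowMeans(ctr)
  s <- apply(ctr, 1L, stats::sd)
  zero <- s == 0
  if (any(zero))
    excluded <- rbind(excluded,
                      data.frame(gene_id = genes[zero],
                                 reason = "zero control SD",
                                 stringsAsFactors = FALSE))
  keep <- genes[!zero]
  if (!length(keep))
    stop("all signature genes were excluded (absent or zero control SD); ",
         "scoring is impossible", call. = FALSE)
  structure(list(
    genes = data.frame(gene_id = keep, k = unname(k[keep]),
                       mean = unname(m[keep]), sd = unname(s[keep]),
                       stringsAsFactors = FALSE, row.names = NULL),
    n_controls = length(controls),
    excluded = excluded), class = "control_reference")
}

#' Compute signed z-sum pathway scores
#'
#' For each sample s the score is `sum_i k_i * (x_is - mean_i) / sd_i` over
#' the retained reference genes, where `mean_i`/`sd_i` are the control
#' statistics and `k_i` is +1 for induced and -1 for suppressed genes. A
#' sample at the control means scores exactly 0; controls scored against a
#' reference fit on themselves average exactly 0.
#'
#' @param expr genes x samples matrix (must contain every retained gene).
#' @param ref a [fit_control_reference()] result.
#' @param sig the [gene_signature()] the reference was fit for (used only to
#'   sanity-check the gene/sign pairing).
#' @return data.frame of class `pathway_score_table` with columns
#'   `sample_id`, `score`, `n_genes`; attributes `genes_used`, `excluded`.
#' @export
compute_pathway_scores <- function(expr, ref, sig = NULL) {
  expr <- validate_expression_matrix(expr)
  stopifnot(inherits(ref, "control_reference"))
  g <- ref$genes
  missing <- setdiff(g$gene_id, rownames(expr))
  if (length(missing))
    stop("retained reference gene(s) missing from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!is.null(sig)) {
    k <- signature_k(sig)
    if (!all(g$gene_id %in% names(k)) ||
        !all(k[g$gene_id] == g$k))
      stop("signature does not match the fitted reference", call. = FALSE)
  }
  z <- (expr[g$gene_id, , drop = FALSE] - g$mean) / g$sd
  scores <- as.vector(crossprod(z, g$k))
  structure(data.frame(sample_id = colnames(expr), score = scores,
                       n_genes = nrow(g),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("pathway_score_table", "data.frame"),
            genes_used = g$gene_id, excluded = ref$excluded)
}

#' Classify case samples as pathway-low versus normal
#'
#' The threshold is derived from the control samples' scores:
#' \describe{
#'   \item{`ci_of_mean`}{lower bound of the two-sided 95\% confidence
#'     interval of the control *mean* score,
#'     `mean - t(0.975, n-1) * sd / sqrt(n)`. A tight bound on the control
#'     centre: it flags cases falling below where the control mean could
#'     plausibly sit, and is permissive about the case-score spread.}
#'   \item{`mean_minus_z_sd`}{`mean - 1.96 * sd`, a population-spread bound:
#'     cases below the lower ~2.5\% tail of the control score distribution
#'     are flagged. This is the rule whose null behavior is calibrated
#'     (about 2-5\% of null cases flagged).}
#' }
#' Case samples with score less than or equal to the threshold are labeled
#' `low`, the rest `normal`; control samples are labeled `control` and never
#' receive a low/normal call.
#'
#' @param scores a [compute_pathway_scores()] table.
#' @param meta sample metadata distinguishing control from case samples.
#' @param method threshold rule, see above.
#' @param conf_level confidence level of the `ci_of_mean` rule.
#' @return the score table with columns `class` and `threshold` added;
#'   attributes `threshold`, `method`.
#' @export
classify_samples <- function(scores, meta,
                             method = c("ci_of_mean", "mean_minus_z_sd"),
                             conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(inherits(scores, "pathway_score_table"))
  idx <- match(scores$sample_id, meta$sample_id)
  if (anyNA(idx))
    stop("scored sample(s) without metadata: ",
         paste(scores$sample_id[is.na(idx)], collapse = ", "), call. = FALSE)
  group <- meta$group[idx]
  ctr <- scores$score[group == "control"]
  if (length(ctr) < 2)
    stop("need at least 2 control scores to set a threshold", call. = FALSE)
  m <- mean(ctr); s <- stats::sd(ctr); n <- length(ctr)
  threshold <- switch(method,
    ci_of_mean = m - stats::qt(1 - (1 - conf_level) / 2, n - 1) * s / sqrt(n),
    mean_minus_z_sd = m - stats::qnorm(1 - (1 - conf_level) / 2) * s)
  cls <- ifelse(group == "control", "control",
                ifelse(scores$score <= threshold, "low", "normal"))
  if (!any(group == "case"))
    warning("no case samples to classify; returning controls only",
            call. = FALSE)
  out <- scores
  out$class <- cls
  out$threshold <- threshold
  attr(out, "threshold") <- threshold
  attr(out, "method") <- method
  class(out) <- class(scores)
  out
}

#' Pearson correlation of pathway scores with a per-sample covariate
#'
#' Pairs scores with a covariate (e.g. an image-derived pAMPK fraction) on
#' sample id, then computes Pearson r with a two-sided p from the t
#' transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)`.
#'
#' @param scores a [compute_pathway_scores()] table.
#' @param covariate named numeric vector (names = sample ids), or a
#'   data.frame with `sample_id` plus one value column.
#' @return list with `r`, `p`, `n`.
#' @export
correlate_scores_with_covariate <- function(scores, covariate) {
  stopifnot(inherits(scores, "pathway_score_table"))
  if (is.data.frame(covariate)) {
    value_col <- setdiff(names(covariate), "sample_id")[1L]
    covariate <- stats::setNames(covariate[[value_col]], covariate$sample_id)
  }
  ids <- intersect(scores$sample_id, names(covariate))
  x <- scores$score[match(ids, scores$sample_id)]
  y <- as.numeric(covariate[ids])
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    stop("need at least 3 paired non-missing observations (found ", n, ")",
         call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in scores or covariate; correlation undefined",
         call. = FALSE)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * stats::pt(-abs(t_stat), n - 2)
  }
  list(r = r, p = p, n = n)
}
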