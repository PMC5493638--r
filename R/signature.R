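#' Per-gene differential response between two arms
#'
#' Computes, for every gene, the treated-minus-control mean difference in
#' log2 units, with a Welch (unequal-variance) t statistic and two-sided p
#' as auxiliary columns. Genes with zero variance in both arms get an
#' undefined t (NA) and are excluded from downstream ranking.
#'
#' @param expr genes x samples matrix.
#' @param arms sample metadata; samples with group `case` form the treated
#'   arm, group `control` the reference arm. Arms must partition the samples
#'   of `expr` with at least 2 samples each.
#' @return data.frame of class `differential_table` with columns `gene_id`,
#'   `diff`, `t`, `p`.
#' @export
differential_response <- function(expr, arms) {
  expr <- validate_expression_matrix(expr)
  arms <- match_metadata(expr, arms)
  treated <- expr[, arms$group == "case", drop = FALSE]
  control <- expr[, arms$group == "control", drop = FALSE]
  n1 <- ncol(treated); n2 <- ncol(control)
  if (n1 < 2 || n2 < 2)
    stop("each arm needs at least 2 samples (treated: ", n1,
         ", control: ", n2, ")", call. = FALSE)
  m1 <- rowMeans(treated); m2 <- rowMeans(control)
  v1 <- rowSums((treated - m1)^2) / (n1 - 1)
  v2 <- rowSums((control - m2)^2) / (n2 - 1)
  d <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  t_stat <- ifelse(se2 > 0, d / sqrt(se2), NA_real_)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               NA_real_)
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(data.frame(gene_id = rownames(expr), diff = d, t = t_stat, p = p,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("differential_table", "data.frame"))
}

#' Select the top-k up- and down-regulated genes as a signed signature
#'
#' Ranks by mean log2 difference by default ("top k up-regulated" read as an
#' effect-size ranking); `metric = "t"` ranks by the Welch t statistic
#' instead. Ties are broken by smaller p, then lexicographic gene id. Genes
#' with undefined t are excluded from ranking. Only strictly positive
#' (negative) differences qualify for the up (down) list; if fewer than
#' `k_top` qualify, all are taken with a warning.
#'
#' @param table a `differential_table`.
#' @param k_top genes to take per direction.
#' @param metric ranking quantity, `"difference"` (default) or `"t"`.
#' @return a [gene_signature()], genes ordered strongest first.
#' @export
select_top_k <- function(table, k_top = 20, metric = c("difference", "t")) {
  metric <- match.arg(metric)
  if (!nrow(table)) stop("empty differential table", call. = FALSE)
  tab <- table[is.finite(table$t), , drop = FALSE]
  score <- if (metric == "difference") tab$diff else tab$t
  pick <- function(sign_dir) {
    qual <- if (sign_dir > 0) which(score > 0) else which(score < 0)
    if (length(qual) < k_top)
      warning("only ", length(qual), " gene(s) qualify for the ",
              if (sign_dir > 0) "up" else "down", " list (asked for ",
              k_top, ")", call. = FALSE)
    ord <- qual[order(-sign_dir * score[qual], tab$p[qual], tab$gene_id[qual])]
    tab$gene_id[utils::head(ord, k_top)]
  }
  gene_signature(pick(+1), pick(-1))
}

#' Restrict a signature to the genes of a measurement platform
#'
#' Emulates mapping a perturbation-derived signature onto the array platform
#' of the cohort: genes absent from the platform are dropped, order is
#' preserved, and the retained sizes are reported.
#'
#' @param sig a [gene_signature()].
#' @param platform_genes a [gene_set()] (or character vector) of genes
#'   measurable on the platform.
#' @return the restricted [gene_signature()].
#' @export
intersect_platform <- function(sig, platform_genes) {
  members <- if (inherits(platform_genes, "gene_set"))
    platform_genes$members else as.character(platform_genes)
  up <- sig$up[sig$up %in% members]
  down <- sig$down[sig$down %in% members]
  if (!length(up) && !length(down))
    stop("no signature gene is present on the platform; ",
         "pathway scoring is impossible", call. = FALSE)
  message("platform intersection retained ", length(up), " up and ",
          length(down), " down signature gene(s)")
  gene_signature(up, down)
}
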