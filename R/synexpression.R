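#' Correlate every gene with an anchor gene
#'
#' Pearson r of each gene's expression with the anchor transcript across all
#' samples, with a two-sided p from the t transform. Genes with zero
#' variance get `r = NA` and are excluded from downstream selection. The
#' anchor gene itself has r = 1 by construction.
#'
#' @param expr genes x samples matrix with at least 3 samples.
#' @param anchor_gene identifier of the anchor transcript (e.g. `ADIPOQ`).
#' @return data.frame of class `anchor_correlation_table` with columns
#'   `gene_id`, `r`, `p`, `n`; attribute `anchor_gene`.
#' @export
anchor_correlation <- function(expr, anchor_gene) {
  expr <- validate_expression_matrix(expr)
  if (!anchor_gene %in% rownames(expr))
    stop("anchor gene '", anchor_gene, "' not in expression matrix",
         call. = FALSE)
  n <- ncol(expr)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  a <- expr[anchor_gene, ]
  if (stats::sd(a) == 0)
    stop("anchor gene '", anchor_gene, "' has zero variance", call. = FALSE)
  centred <- expr - rowMeans(expr)
  ss <- rowSums(centred^2)
  ac <- a - mean(a)
  r <- as.vector(centred %*% ac) / sqrt(ss * sum(ac^2))
  r[ss == 0] <- NA_real_
  r <- pmax(-1, pmin(1, r))
  t_stat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t_stat), n - 2)
  p[is.finite(r) & abs(r) == 1] <- 0
  structure(data.frame(gene_id = rownames(expr), r = r, p = p, n = n,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("anchor_correlation_table", "data.frame"),
            anchor_gene = anchor_gene)
}

#' Select the anchor-gene synexpression set
#'
#' Threshold mode keeps genes with `r > r_min` (or `|r| > r_min` when
#' `use_absolute_r`) and `p < p_max` — the convention behind an
#' "r > 0.4, p < 0.005" co-regulated set. `top_n` mode keeps the `n_top`
#' genes of largest `|r|` — the "top 500 most differentially correlated"
#' reading. The anchor gene itself is always excluded.
#'
#' @param table an [anchor_correlation()] result.
#' @param mode `"threshold"` or `"top_n"`.
#' @param r_min,p_max threshold-mode cutoffs.
#' @param n_top top-n-mode size.
#' @param use_absolute_r select on `|r|` rather than signed r in threshold
#'   mode.
#' @return a [gene_set()] named `SYNEXPR`.
#' @export
select_synexpression_set <- function(table, mode = c("threshold", "top_n"),
                                     r_min = 0.4, p_max = 0.005,
                                     n_top = 500, use_absolute_r = FALSE) {
  mode <- match.arg(mode)
  if (!nrow(table)) stop("empty correlation table", call. = FALSE)
  anchor <- attr(table, "anchor_gene")
  tab <- table[is.finite(table$r) & table$gene_id != anchor, , drop = FALSE]
  if (mode == "threshold") {
    rr <- if (use_absolute_r) abs(tab$r) else tab$r
    keep <- tab$gene_id[rr > r_min & tab$p < p_max]
    desc <- sprintf("genes with %sr > %g and p < %g vs anchor %s",
                    if (use_absolute_r) "|" else "", r_min, p_max,
                    anchor %||% "?")
  } else {
    ord <- order(-abs(tab$r), tab$gene_id)
    keep <- tab$gene_id[utils::head(ord, n_top)]
    desc <- sprintf("top %d genes by |r| vs anchor %s", n_top, anchor %||% "?")
  }
  if (!length(keep))
    stop("synexpression selection is empty; relax r_min/p_max or use top_n",
         call. = FALSE)
  gene_set("SYNEXPR", keep, desc)
}

#' Hierarchically cluster samples on a gene set
#'
#' Restricts the matrix to the set, z-scores each gene across samples
#' (zero-variance genes are dropped with a warning), computes sample-sample
#' distances (1 - Pearson correlation by default) and agglomerates with
#' average linkage, cutting the tree into `n_clusters`.
#'
#' @param expr genes x samples matrix.
#' @param genes a [gene_set()] (or character vector) to cluster on; at least
#'   2 usable genes required.
#' @param n_clusters clusters to cut (2 reproduces a reduced/normal-like
#'   split).
#' @param distance `"pearson"` (1 - r) or `"euclidean"`.
#' @param linkage any `stats::hclust` method; `"average"` by default.
#' @return object of class `cluster_assignment`: named integer `cluster`,
#'   the `hclust` tree, `genes_used`, and `params`.
#' @export
cluster_samples <- function(expr, genes, n_clusters = 2,
                            distance = c("pearson", "euclidean"),
                            linkage = "average") {
  distance <- match.arg(distance)
  expr <- validate_expression_matrix(expr)
  members <- if (inherits(genes, "gene_set")) genes$members
             else as.character(genes)
  sub <- expr[intersect(rownames(expr), members), , drop = FALSE]
  if (nrow(sub) < 2)
    stop("fewer than 2 of the requested genes are present; cannot cluster",
         call. = FALSE)
  if (n_clusters > ncol(sub) || n_clusters < 1)
    stop("n_clusters must be between 1 and the number of samples",
         call. = FALSE)
  z <- zscore_rows(sub)
  if (nrow(z) < 2)
    stop("fewer than 2 genes with nonzero variance; cannot cluster",
         call. = FALSE)
  d <- if (distance == "pearson") stats::as.dist(1 - stats::cor(z))
       else stats::dist(t(z))
  hc <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(hc, k = n_clusters)
  structure(list(cluster = cl, hclust = hc, genes_used = rownames(z),
                 labels = NULL,
                 params = list(distance = distance, linkage = linkage,
                               n_clusters = n_clusters)),
            class = "cluster_assignment")
}

#' @keywords internal
zscore_rows <- function(x) {
  m <- rowMeans(x)
  s <- apply(x, 1L, stats::sd)
  drop <- s == 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " zero-variance gene(s) before z-scoring",
            call. = FALSE)
    x <- x[!drop, , drop = FALSE]; m <- m[!drop]; s <- s[!drop]
  }
  (x - m) / s
}

#' Label a two-cluster assignment as reduced versus normal-like
#'
#' For each cluster, the mean over its samples of the correlation-sign-
#' weighted gene z-scores (`sign(r_g) * z_gs`); the cluster with the lower
#' mean shows reduced levels of the (anchor-aligned) synexpression set and
#' is labeled `reduced`, the other `normal-like`. Flipping the sign of every
#' gene's values together with every r leaves the labels unchanged.
#'
#' @param assign a 2-cluster [cluster_samples()] result.
#' @param expr genes x samples matrix.
#' @param genes the gene set that was clustered on.
#' @param corr the [anchor_correlation()] table supplying sign(r) weights.
#' @return `assign` with `labels` (cluster index -> label) and `subset`
#'   (sample -> label) filled in.
#' @export
label_clusters <- function(assign, expr, genes, corr) {
  stopifnot(inherits(assign, "cluster_assignment"))
  if (length(unique(assign$cluster)) != 2)
    stop("labeling is defined for exactly 2 clusters", call. = FALSE)
  expr <- validate_expression_matrix(expr)
  members <- if (inherits(genes, "gene_set")) genes$members
             else as.character(genes)
  sub <- expr[intersect(rownames(expr), members), names(assign$cluster),
              drop = FALSE]
  z <- zscore_rows(sub)
  w <- sign(corr$r[match(rownames(z), corr$gene_id)])
  w[!is.finite(w)] <- 0
  sample_score <- as.vector(crossprod(z, w)) / nrow(z)
  cl_means <- tapply(sample_score, assign$cluster, mean)
  if (abs(diff(range(cl_means))) < 1e-12)
    stop("cluster means are tied; manual labeling required", call. = FALSE)
  reduced <- names(cl_means)[which.min(cl_means)]
  labels <- stats::setNames(
    ifelse(names(cl_means) == reduced, "reduced", "normal-like"),
    names(cl_means))
  assign$labels <- labels
  assign$subset <- stats::setNames(
    unname(labels[as.character(assign$cluster)]), names(assign$cluster))
  assign
}

#' Export the heatmap matrix behind a clustering
#'
#' Writes the gene-wise z-scored matrix with samples in dendrogram leaf
#' order and genes ordered by decreasing anchor correlation (when `corr` is
#' supplied), plus a sidecar TSV of cluster indices and subset labels. Every
#' exported row has mean 0 and SD 1; the file round-trips through
#' [read_expression_matrix()].
#'
#' @param expr genes x samples matrix.
#' @param genes the clustered gene set.
#' @param assign a [cluster_samples()] (optionally [label_clusters()]ed)
#'   result.
#' @param path output TSV path for the matrix.
#' @param corr optional [anchor_correlation()] table for gene ordering.
#' @param labels_path sidecar path; defaults to `<path>.clusters.tsv`.
#' @return invisible list with `matrix_path` and `labels_path`.
#' @export
export_heatmap_matrix <- function(expr, genes, assign, path, corr = NULL,
                                  labels_path = paste0(path, ".clusters.tsv")) {
  stopifnot(inherits(assign, "cluster_assignment"))
  expr <- validate_expression_matrix(expr)
  members <- if (inherits(genes, "gene_set")) genes$members
             else as.character(genes)
  sub <- expr[intersect(rownames(expr), members), , drop = FALSE]
  z <- zscore_rows(sub)
  leaf_order <- assign$hclust$labels[assign$hclust$order]
  z <- z[, leaf_order, drop = FALSE]
  if (!is.null(corr)) {
    r <- corr$r[match(rownames(z), corr$gene_id)]
    z <- z[order(-r, rownames(z)), , drop = FALSE]
  }
  write_expression_matrix(z, path)
  side <- data.frame(sample_id = leaf_order,
                     cluster = unname(assign$cluster[leaf_order]),
                     subset = if (is.null(assign$subset)) NA_character_
                              else unname(assign$subset[leaf_order]),
                     stringsAsFactors = FALSE)
  utils::write.table(side, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(matrix_path = path, labels_path = labels_path))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
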