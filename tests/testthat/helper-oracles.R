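# Independent oracles used to cross-check package computations. These are
# deliberately naive (enumeration / direct formulas), never shared code
# paths with the implementation.

# Two-sided Fisher exact p by full enumeration over all tables with the
# observed margins, with each table's probability computed from factorials.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  lp_table <- function(x) {
    # P(table) = r1! r2! c1! c2! / (n! x! (r1-x)! (c1-x)! (d cell)!)
    lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) + lgamma(n - c1 + 1) -
      lgamma(n + 1) - lgamma(x + 1) - lgamma(r1 - x + 1) -
      lgamma(c1 - x + 1) - lgamma(r2 - c1 + x + 1)
  }
  support <- max(0, c1 - r2):min(r1, c1)
  lp <- vapply(support, lp_table, numeric(1))
  lp_obs <- lp_table(a)
  min(1, sum(exp(lp[lp <= lp_obs + 1e-7])))
}

# Brute-force average-linkage agglomeration from a distance matrix:
# repeatedly merge the pair of clusters with the smallest mean pairwise
# distance between their original members. Returns the merge heights and a
# 2-group partition.
oracle_average_linkage <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partition_at_2 <- NULL
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    heights <- c(heights, best[1])
    if (length(clusters) == 2)
      partition_at_2 <- clusters
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  list(heights = heights, partition2 = partition_at_2)
}

# Sort-and-slice top-k selection oracle (ranking by difference, ties by p
# then gene id).
oracle_top_k <- function(tab, k_top) {
  tab <- tab[is.finite(tab$t), , drop = FALSE]
  pos <- tab[tab$diff > 0, , drop = FALSE]
  neg <- tab[tab$diff < 0, , drop = FALSE]
  up <- pos$gene_id[order(-pos$diff, pos$p, pos$gene_id)]
  down <- neg$gene_id[order(neg$diff, neg$p, neg$gene_id)]
  list(up = head(up, k_top), down = head(down, k_top))
}

# Canonical form of a partition (list of index vectors) for comparison up
# to cluster label permutation.
canonical_partition <- function(groups) {
  groups <- lapply(unname(groups), function(g) sort(as.integer(g)))
  groups[order(vapply(groups, `[`, integer(1), 1))]
}

partition_from_labels <- function(labels) {
  canonical_partition(split(seq_along(labels), labels))
}

# Direct Pearson r from the defining formula.
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
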