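#' Per-cluster marker gene scores from a count matrix
#'
#' Derives a non-negative marker score per gene and cluster for use as a
#' propagation seed. Counts are library-size normalized to the median total
#' and log1p-transformed; each gene is then compared in-cluster versus rest
#' with a two-sided Wilcoxon rank-sum test (normal approximation with tie
#' and continuity correction), p-values are Benjamini-Hochberg adjusted
#' across genes within the cluster, and the score is
#' `-log10(p_adj)` when the in-cluster mean exceeds the rest mean and 0
#' otherwise, capped at 300.
#'
#' @param counts Cells x genes matrix of raw counts (dense or sparse), with
#'   gene column names and cell row names.
#' @param labels Cluster label per cell (character or factor, length =
#'   number of cells). Clusters with fewer than 3 cells are excluded with a
#'   warning; at least 2 usable clusters are required.
#' @param gene_universe Optional character vector: restrict seeds to these
#'   genes (e.g. the network's gene nodes).
#' @return Named list of node seeds, one tibble `(node, score)` per
#'   cluster, each carrying its cluster as `context`.
#' @export
compute_marker_scores <- function(counts, labels, gene_universe = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(labels))
  labels <- as.character(labels)
  sizes <- table(labels)
  small <- names(sizes)[sizes < 3]
  if (length(small) > 0) {
    warn(sprintf("excluding cluster(s) with < 3 cells: %s",
                 paste(small, collapse = ", ")))
    keep <- !labels %in% small
    counts <- counts[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) {
    abort("need at least 2 clusters with >= 3 cells each",
          class = "osteoatlas_value_error")
  }

  x <- lognorm_counts(counts)
  n <- nrow(x)
  # rank each gene across all cells once; reused by every cluster contrast
  ranks <- apply(x, 2, rank)
  tie_term <- apply(x, 2, function(col) {
    tt <- table(col)
    sum(tt^3 - tt)
  })

  out <- lapply(clusters, function(cl) {
    in_cl <- labels == cl
    n1 <- sum(in_cl)
    n2 <- n - n1
    r1 <- colSums(ranks[in_cl, , drop = FALSE])
    u <- r1 - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    zed <- rep(0, ncol(x))
    ok <- sigma2 > 0
    # continuity-corrected normal approximation (as wilcox.test uses)
    zed[ok] <- (u[ok] - mu - sign(u[ok] - mu) * 0.5) / sqrt(sigma2[ok])
    p <- 2 * stats::pnorm(-abs(zed))
    p <- pmin(p, 1)
    p_adj <- p.adjust(p, method = "BH")
    up <- colMeans(x[in_cl, , drop = FALSE]) > colMeans(x[!in_cl, , drop = FALSE])
    score <- ifelse(up, pmin(-log10(p_adj), 300), 0)
    seed <- tibble::tibble(node = colnames(x), score = score)
    if (!is.null(gene_universe)) {
      seed <- seed[seed$node %in% gene_universe, , drop = FALSE]
    }
    new_node_seed(seed, context = cl)
  })
  setNames(out, clusters)
}

# library-size normalization to the median total count, then log1p
lognorm_counts <- function(counts) {
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    abort("cells with zero total count are not allowed",
          class = "osteoatlas_value_error")
  }
  log1p(counts * (median(totals) / totals))
}
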