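# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately naive (exhaustive loops, dense algebra) and never
# call the code paths they check.

# random typed tripartite network built directly from an edge tibble
random_network <- function(n_tf = 3, n_region = 8, n_gene = 12,
                           n_extra = 15, seed = 1) {
  withr::with_seed(seed, {
    tfs <- sprintf("TF%d", seq_len(n_tf))
    regions <- sprintf("chr1:%d-%d", seq_len(n_region) * 1000,
                       seq_len(n_region) * 1000 + 500)
    genes <- sprintf("g%d", seq_len(n_gene))
    edges <- dplyr::bind_rows(
      tibble::tibble(source = sample(tfs, n_region, replace = TRUE),
                     target = regions, layer = "tf-region"),
      tibble::tibble(source = sample(regions, n_gene, replace = TRUE),
                     target = genes, layer = "region-gene"),
      tibble::tibble(source = sample(tfs, n_extra, replace = TRUE),
                     target = sample(genes, n_extra, replace = TRUE),
                     layer = "tf-gene"))
    edges <- dplyr::distinct(edges, source, target, layer)
    edges$importance <- runif(nrow(edges), 0.1, 1)
    regulatory_network(edges)
  })
}

# exhaustive BFS connected components on the subset-induced undirected graph
bfs_components <- function(edges, subset) {
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    a <- edges$source[i]; b <- edges$target[i]
    if (a %in% subset && b %in% subset) {
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  remaining <- subset
  comps <- list()
  while (length(remaining) > 0) {
    queue <- remaining[1]
    seen <- character()
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% seen) next
      seen <- c(seen, v)
      queue <- c(queue, setdiff(adj[[v]], seen))
    }
    comps <- c(comps, list(sort(seen)))
    remaining <- setdiff(remaining, seen)
  }
  ord <- order(-lengths(comps), vapply(comps, `[`, "", 1))
  comps[ord]
}

# exhaustive pairwise-distance KNN
brute_knn <- function(query, ref, k) {
  lapply(seq_len(nrow(query)), function(i) {
    d <- sqrt(colSums((t(ref) - query[i, ])^2))
    ord <- order(d, seq_len(nrow(ref)))[seq_len(k)]
    list(idx = ord, dist = d[ord])
  })
}

# dense linear-system solve of the restart equation (I - (1-r)T) q = r s
dense_rwr <- function(tm, s, r = 0.15) {
  s <- s / sum(s)
  as.numeric(solve(diag(nrow(tm)) - (1 - r) * tm, r * s))
}

# study-condition fixture: simulated inputs written to disk once per run
sim_fixture_dir <- function(seed = 1) {
  dir <- file.path(tempdir(), sprintf("osteoatlas_fix_seed%d", seed))
  if (!file.exists(file.path(dir, "network_edges.tsv"))) {
    run_simulate(dir, seed = seed)
  }
  dir
}

# fraction of planted nodes ranked above the background median rank
planted_rank_fraction <- function(combined, planted) {
  rk <- rank(-combined$score)
  names(rk) <- combined$node
  bg <- setdiff(combined$node, planted)
  mean(rk[planted] < median(rk[bg]))
}
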