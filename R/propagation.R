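#' Propagation configuration
#'
#' Collects the tunable constants of the network-propagation engine. The
#' permutation count defaults to 1000 and the enrichment threshold to a
#' z-score of 2, the working conventions of the method; the restart
#' probability defaults to the PageRank-standard 0.15.
#'
#' @param restart_prob Restart probability r in (0, 1].
#' @param tol L1 convergence tolerance of the power iteration.
#' @param max_iter Maximum power iterations before erroring.
#' @param n_perm Number of seed permutations for the null.
#' @param rng_seed Integer seed governing the permutations.
#' @param z_thresh z-score threshold for subnetwork extraction.
#' @return A list of class `propagation_config`.
#' @export
propagation_config <- function(restart_prob = 0.15, tol = 1e-8,
                               max_iter = 1000, n_perm = 1000,
                               rng_seed = 1L, z_thresh = 2) {
  stopifnot(restart_prob > 0, restart_prob <= 1, tol > 0, max_iter >= 1,
            n_perm >= 1)
  structure(list(restart_prob = restart_prob, tol = tol,
                 max_iter = max_iter, n_perm = as.integer(n_perm),
                 rng_seed = as.integer(rng_seed), z_thresh = z_thresh),
            class = "propagation_config")
}

#' Build the column-stochastic transition matrix of a network
#'
#' Edges are symmetrized (propagation is undirected) and weighted by
#' importance; column j holds `w_ij / deg_j` where `deg_j` is node j's
#' weighted degree. Nodes with no incident weight (isolated, or all-zero
#' importances) become dangling and get a uniform column over all nodes.
#'
#' @param net A [regulatory_network()].
#' @return A dense column-stochastic matrix with node ids as dimnames.
#' @export
build_transition <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  ids <- net$nodes$id
  n <- length(ids)
  if (n == 0) abort("network is empty", class = "osteoatlas_value_error")
  w <- Matrix::sparseMatrix(
    i = match(net$edges$source, ids),
    j = match(net$edges$target, ids),
    x = net$edges$importance, dims = c(n, n))
  w <- w + Matrix::t(w)
  tm <- as.matrix(w)
  deg <- colSums(tm)
  dangling <- deg == 0
  if (any(dangling)) {
    warn(sprintf("%d node(s) have no incident edge weight; treated as dangling",
                 sum(dangling)))
  }
  ok <- which(!dangling)
  tm[, ok] <- sweep(tm[, ok, drop = FALSE], 2, deg[ok], "/")
  tm[, dangling] <- 1 / n
  dimnames(tm) <- list(ids, ids)
  tm
}

seed_vector <- function(seed, ids) {
  if (is.data.frame(seed)) {
    unknown <- setdiff(seed$node, ids)
    if (length(unknown) > 0) {
      abort(sprintf("seed refers to unknown node(s): %s",
                    paste(head(unknown, 5), collapse = ", ")),
            class = "osteoatlas_integrity_error")
    }
    s <- setNames(numeric(length(ids)), ids)
    s[seed$node] <- seed$score
  } else {
    s <- setNames(numeric(length(ids)), ids)
    s[intersect(names(seed), ids)] <- seed[intersect(names(seed), ids)]
  }
  if (any(!is.finite(s)) || any(s < 0)) {
    abort("seed scores must be finite and >= 0",
          class = "osteoatlas_value_error")
  }
  if (sum(s) <= 0) {
    abort("seed must have at least one positive entry",
          class = "osteoatlas_value_error")
  }
  s / sum(s)
}

# power iteration on one or many seed columns; S columns must each sum to 1
propagate_matrix <- function(tm, s_mat, cfg) {
  r <- cfg$restart_prob
  q <- s_mat
  for (iter in seq_len(cfg$max_iter)) {
    q_new <- r * s_mat + (1 - r) * (tm %*% q)
    delta <- max(colSums(abs(q_new - q)))
    q <- q_new
    if (delta < cfg$tol) return(q)
  }
  abort(sprintf("propagation did not converge in %d iterations (residual %.3g)",
                cfg$max_iter, delta),
        class = "osteoatlas_convergence_error")
}

#' Propagate a seed over the network by random walk with restart
#'
#' Finds the fixed point of \eqn{q = r s + (1 - r) T q} by power iteration,
#' where `s` is the seed normalized to sum 1 over all nodes (nodes absent
#' from the seed get 0) and `T` is the column-stochastic transition matrix.
#' The result conserves seed mass: \eqn{\sum_i q_i = 1}.
#'
#' @param tm Transition matrix from [build_transition()].
#' @param seed Node seed: data frame `(node, score)` or named numeric.
#' @param config A [propagation_config()].
#' @return Named numeric vector `q` over all network nodes.
#' @export
propagate <- function(tm, seed, config = propagation_config()) {
  s <- seed_vector(seed, rownames(tm))
  q <- propagate_matrix(tm, matrix(s, ncol = 1), config)
  setNames(as.numeric(q), rownames(tm))
}

#' Propagation with a permutation null
#'
#' Propagates the observed seed, then repeats the propagation with
#' `n_perm` uniform shuffles of the seed values across all network nodes
#' (zeros included) to obtain a per-node permutation mean and standard
#' deviation, a z-score `z = (q - mu) / sd` (defined as 0 where `sd = 0`)
#' and an empirical p-value `(1 + #\{q_perm >= q\}) / (1 + n_perm)`.
#' Fully reproducible given `config$rng_seed`.
#'
#' @inheritParams propagate
#' @param context Context label stored on the result.
#' @return A `propagation_result`: tibble `node`, `seed`, `q`, `mu_perm`,
#'   `sd_perm`, `z`, `p_emp`.
#' @export
permutation_zscores <- function(tm, seed, config = propagation_config(),
                                context = "trait") {
  ids <- rownames(tm)
  n <- length(ids)
  s <- seed_vector(seed, ids)
  q <- as.numeric(propagate_matrix(tm, matrix(s, ncol = 1), config))

  n_perm <- config$n_perm
  perm_seeds <- withr::with_seed(
    config$rng_seed,
    vapply(seq_len(n_perm), function(i) s[sample.int(n)], numeric(n)))
  # batch the permutations through one shared power iteration
  qp <- propagate_matrix(tm, perm_seeds, config)
  mu <- rowMeans(qp)
  sdev <- sqrt(rowSums((qp - mu)^2) / max(1, n_perm - 1))
  # tolerance when counting ties: identical permuted seeds must compare as
  # equal despite the different rounding of batched vs single matrix products
  eps <- abs(q) * 1e-12 + 1e-300
  z <- ifelse(sdev > eps, (q - mu) / sdev, 0)
  p_emp <- (1 + rowSums(qp >= q - eps)) / (1 + n_perm)

  out <- tibble::tibble(node = ids, seed = unname(s), q = q,
                        mu_perm = unname(mu), sd_perm = unname(sdev),
                        z = unname(z), p_emp = unname(p_emp))
  structure(out, context = context, config = config,
            class = c("propagation_result", class(out)))
}

#' @export
print.propagation_result <- function(x, ...) {
  cat(sprintf("<propagation_result> context '%s', %d nodes, %d permutations\n",
              attr(x, "context"), nrow(x), attr(x, "config")$n_perm))
  NextMethod()
}

#' Combine trait and cluster propagation results by per-node minimum
#'
#' The per-node minimum of the two z-scores: a node scores highly only if
#' it is enriched for both the trait signal and the cluster's marker
#' signal, making the combination cluster-specific.
#'
#' @param trait,cluster `propagation_result` objects on the same node set.
#' @return Tibble `node`, `score` (= min of the two z-scores), with a
#'   combined context attribute.
#' @export
combine_min <- function(trait, cluster) {
  if (!identical(trait$node, cluster$node)) {
    if (!setequal(trait$node, cluster$node)) {
      abort("trait and cluster results are on different node universes",
            class = "osteoatlas_integrity_error")
    }
    cluster <- cluster[match(trait$node, cluster$node), ]
  }
  out <- tibble::tibble(node = trait$node,
                        score = pmin(trait$z, cluster$z))
  attr(out, "context") <- paste(attr(trait, "context"),
                                attr(cluster, "context"), sep = "|")
  out
}

#' Extract enriched subnetworks from combined scores
#'
#' Thresholds the combined per-node scores and returns the connected
#' components of the induced (undirected) subgraph, ranked by decreasing
#' mean component score.
#'
#' @param net A [regulatory_network()].
#' @param combined Tibble `(node, score)`, e.g. from [combine_min()].
#' @param z_thresh Score threshold; nodes with `score > z_thresh` are kept.
#' @return Tibble `component` (rank), `node`, `score`, `mean_score`;
#'   zero rows if nothing passes the threshold.
#' @export
extract_subnetworks <- function(net, combined, z_thresh = 2) {
  unknown <- setdiff(combined$node, net$nodes$id)
  if (length(unknown) > 0) {
    abort(sprintf("combined scores refer to unknown node(s): %s",
                  paste(head(unknown, 5), collapse = ", ")),
          class = "osteoatlas_integrity_error")
  }
  keep <- combined$node[combined$score > z_thresh]
  if (length(keep) == 0) {
    return(tibble::tibble(component = integer(), node = character(),
                          score = numeric(), mean_score = numeric()))
  }
  comps <- network_components(net, keep)
  sc <- setNames(combined$score, combined$node)
  out <- purrr::imap_dfr(comps, function(members, i) {
    tibble::tibble(component = i, node = members,
                   score = unname(sc[members]),
                   mean_score = mean(sc[members]))
  })
  # rank components by mean score, keeping the size-based order as tiebreak
  ranks <- out |>
    dplyr::distinct(.data$component, .data$mean_score) |>
    dplyr::arrange(dplyr::desc(.data$mean_score), .data$component)
  out$component <- match(out$component, ranks$component)
  dplyr::arrange(out, .data$component, dplyr::desc(.data$score))
}
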