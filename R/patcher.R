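#' Construct a cell-by-gene count matrix with metadata
#'
#' @param counts Cells x genes matrix of raw counts (non-negative
#'   integers); rownames = cell ids, colnames = gene ids.
#' @param labels Optional per-cell cluster labels (named by cell id or in
#'   row order).
#' @param modality `"reference"` (high-dimensional droplet data) or
#'   `"iss"` (targeted panel).
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, labels = NULL,
                        modality = c("reference", "iss")) {
  modality <- match.arg(modality)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("cell%d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    abort("counts must have gene ids as column names",
          class = "osteoatlas_format_error")
  }
  if (anyDuplicated(colnames(counts))) {
    abort("gene ids must be unique", class = "osteoatlas_integrity_error")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers",
          class = "osteoatlas_value_error")
  }
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    abort(sprintf("%d cell(s) have zero total count; remove them first",
                  sum(zero)),
          class = "osteoatlas_value_error")
  }
  if (!is.null(labels)) {
    if (!is.null(names(labels))) {
      labels <- labels[rownames(counts)]
    }
    stopifnot(length(labels) == nrow(counts))
    labels <- setNames(as.character(labels), rownames(counts))
  }
  structure(list(counts = counts, labels = labels, modality = modality),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %s: %d cells x %d genes%s\n", x$modality,
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$labels)) "" else
                sprintf(", %d labelled clusters", length(unique(x$labels)))))
  invisible(x)
}

#' Shared gene panel between reference and ISS data
#'
#' @param ref,iss [cell_matrix()] objects.
#' @return Sorted character vector: the intersection of the gene sets.
#' @export
shared_panel <- function(ref, iss) {
  panel <- sort(intersect(colnames(ref$counts), colnames(iss$counts)))
  if (length(panel) == 0) {
    abort("reference and ISS data share no genes",
          class = "osteoatlas_value_error")
  }
  inform(sprintf("shared panel: %d genes", length(panel)))
  panel
}

#' Normalize a count matrix to the shared panel space
#'
#' Subsets to the panel, scales each cell so its panel total equals the
#' median panel total across cells of this modality, log1p-transforms, and
#' z-scores each gene within the modality (genes with zero variance are
#' set to 0 so they contribute nothing to distances). Cells whose panel
#' total is zero are dropped with a warning.
#'
#' @param m A [cell_matrix()].
#' @param panel Ordered gene list from [shared_panel()].
#' @return Dense cells x panel matrix of z-scored log expression.
#' @export
normalize_panel <- function(m, panel) {
  stopifnot(inherits(m, "cell_matrix"))
  missing_genes <- setdiff(panel, colnames(m$counts))
  if (length(missing_genes) > 0) {
    abort(sprintf("panel gene(s) absent from %s data: %s", m$modality,
                  paste(head(missing_genes, 5), collapse = ", ")),
          class = "osteoatlas_value_error")
  }
  x <- m$counts[, panel, drop = FALSE]
  totals <- rowSums(x)
  if (any(totals == 0)) {
    warn(sprintf("dropping %d cell(s) with zero panel total", sum(totals == 0)))
    x <- x[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  x <- log1p(x * (median(totals) / totals))
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  x <- sweep(x, 2, mu, "-")
  ok <- sdev > 0
  x[, ok] <- sweep(x[, ok, drop = FALSE], 2, sdev[ok], "/")
  x[, !ok] <- 0
  x
}

#' Exact k-nearest-neighbour matching in shared panel space
#'
#' For each ISS cell, finds the `k` nearest reference cells by Euclidean
#' distance in the z-scored log panel space. Ties in distance are broken
#' by reference cell order.
#'
#' @param iss_norm,ref_norm Matrices from [normalize_panel()] on the same
#'   panel (identical gene order).
#' @param k Number of neighbours (default 15).
#' @return A `neighbor_map`: tibble `cell`, `rank`, `neighbor`, `distance`
#'   with `k` rows per ISS cell, distances non-decreasing within a cell.
#' @export
knn_match <- function(iss_norm, ref_norm, k = 15) {
  stopifnot(ncol(iss_norm) == ncol(ref_norm),
            identical(colnames(iss_norm), colnames(ref_norm)), k >= 1)
  if (k > nrow(ref_norm)) {
    abort(sprintf("k = %d exceeds the %d reference cells", k, nrow(ref_norm)),
          class = "osteoatlas_value_error")
  }
  # squared Euclidean distances via the Gram expansion
  d2 <- outer(rowSums(iss_norm^2), rowSums(ref_norm^2), "+") -
    2 * tcrossprod(iss_norm, ref_norm)
  d2[d2 < 0] <- 0
  n_ref <- nrow(ref_norm)
  res <- lapply(seq_len(nrow(iss_norm)), function(i) {
    ord <- order(d2[i, ], seq_len(n_ref))[seq_len(k)]
    tibble::tibble(cell = rownames(iss_norm)[i], rank = seq_len(k),
                   neighbor = rownames(ref_norm)[ord],
                   distance = unname(sqrt(d2[i, ord])))
  })
  out <- dplyr::bind_rows(res)
  structure(out, k = k, class = c("neighbor_map", class(out)))
}

#' Impute unmeasured genes as mean raw counts of the neighbours
#'
#' @param nmap A `neighbor_map` from [knn_match()].
#' @param ref Reference [cell_matrix()].
#' @param target_genes Genes to impute (subset of the reference genes;
#'   typically the genes absent from the ISS panel).
#' @return ISS cells x `target_genes` matrix of mean neighbour raw counts
#'   (non-negative rationals, not re-normalized).
#' @export
impute_counts <- function(nmap, ref, target_genes) {
  stopifnot(inherits(nmap, "neighbor_map"))
  missing_genes <- setdiff(target_genes, colnames(ref$counts))
  if (length(missing_genes) > 0) {
    abort(sprintf("target gene(s) absent from reference: %s",
                  paste(head(missing_genes, 5), collapse = ", ")),
          class = "osteoatlas_value_error")
  }
  cells <- unique(nmap$cell)
  k <- attr(nmap, "k")
  # averaging matrix: one row per ISS cell, 1/k on its neighbours
  a <- Matrix::sparseMatrix(
    i = match(nmap$cell, cells),
    j = match(nmap$neighbor, rownames(ref$counts)),
    x = 1 / k,
    dims = c(length(cells), nrow(ref$counts)))
  imp <- as.matrix(a %*% ref$counts[, target_genes, drop = FALSE])
  dimnames(imp) <- list(cells, target_genes)
  imp
}

#' Transfer cell labels by majority vote among the neighbours
#'
#' The winning label is the most frequent among the `k` neighbours'
#' labels; confidence is the winning fraction. Ties are broken by the
#' smaller summed neighbour distance, then lexicographically.
#'
#' @param nmap A `neighbor_map` from [knn_match()].
#' @param ref_labels Named character vector: label per reference cell.
#'   Every neighbour must be labelled.
#' @return Tibble `cell`, `label`, `confidence`, `mean_distance`.
#' @export
transfer_labels <- function(nmap, ref_labels) {
  stopifnot(inherits(nmap, "neighbor_map"))
  unlabelled <- setdiff(unique(nmap$neighbor), names(ref_labels))
  if (length(unlabelled) > 0) {
    abort(sprintf("neighbour(s) without a reference label: %s",
                  paste(head(unlabelled, 5), collapse = ", ")),
          class = "osteoatlas_integrity_error")
  }
  nmap |>
    dplyr::mutate(nb_label = unname(ref_labels[.data$neighbor])) |>
    dplyr::group_by(.data$cell) |>
    dplyr::group_modify(function(df, key) {
      votes <- df |>
        dplyr::group_by(.data$nb_label) |>
        dplyr::summarise(n = dplyr::n(), dist_sum = sum(.data$distance),
                         .groups = "drop") |>
        dplyr::arrange(dplyr::desc(.data$n), .data$dist_sum, .data$nb_label)
      tibble::tibble(label = votes$nb_label[1],
                     confidence = votes$n[1] / nrow(df),
                     mean_distance = mean(df$distance))
    }) |>
    dplyr::ungroup()
}
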