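toy_cells <- function(counts, modality = "reference", labels = NULL) {
  cell_matrix(counts, labels = labels, modality = modality)
}

test_that("shared panel is the sorted gene intersection", {
  ref <- toy_cells(matrix(1L, 2, 3, dimnames = list(c("r1", "r2"),
                                                    c("A", "B", "C"))))
  iss <- toy_cells(matrix(1L, 2, 3, dimnames = list(c("i1", "i2"),
                                                    c("B", "C", "D"))),
                   "iss")
  expect_equal(suppressMessages(shared_panel(ref, iss)), c("B", "C"))
  expect_equal(suppressMessages(shared_panel(ref, ref)), c("A", "B", "C"))
  disjoint <- toy_cells(matrix(1L, 2, 2, dimnames = list(c("i1", "i2"),
                                                         c("X", "Y"))), "iss")
  expect_error(shared_panel(ref, disjoint), class = "osteoatlas_value_error")
})

test_that("panel normalization scales to the median total then z-scores", {
  counts <- matrix(c(4L, 8L, 12L,
                     6L, 12L, 18L,
                     0L, 0L, 30L), nrow = 3, byrow = TRUE,
                   dimnames = list(c("c1", "c2", "c3"),
                                   c("gA", "gB", "gC")))
  m <- toy_cells(counts)
  # totals (24, 36, 30): scale factors 30/24, 30/36, 1 before log
  x <- normalize_panel(m, c("gA", "gB", "gC"))
  expect_equal(colMeans(x), c(gA = 0, gB = 0, gC = 0), tolerance = 1e-9)
  expect_equal(apply(x, 2, sd)[c("gA", "gB")], c(gA = 1, gB = 1),
               tolerance = 1e-9)
  # reconstruct scale factors from the pre-z-score definition
  totals <- rowSums(counts)
  scaled <- log1p(counts * (median(totals) / totals))
  expect_equal(scaled[1, "gA"], log1p(4 * 30 / 24))
  # constant gene across cells becomes an all-zero column
  counts2 <- cbind(counts, gD = c(5L, 5L, 5L))
  x2 <- normalize_panel(toy_cells(counts2), colnames(counts2))
  expect_false(all(x2[, "gD"] == 0))  # totals differ, so gD varies after scaling
  counts3 <- matrix(c(2L, 7L, 2L, 7L, 2L, 7L), 3, 2, byrow = TRUE,
                    dimnames = list(c("c1", "c2", "c3"), c("gA", "gB")))
  x3 <- normalize_panel(toy_cells(counts3), c("gA", "gB"))
  expect_equal(unname(x3[, "gA"]), c(0, 0, 0))
})

test_that("exact KNN matches the brute-force oracle with ordered ties", {
  withr::with_seed(10, {
    ref <- matrix(rnorm(200 * 30), 200, 30,
                  dimnames = list(sprintf("r%03d", 1:200),
                                  sprintf("g%d", 1:30)))
    iss <- matrix(rnorm(40 * 30), 40, 30,
                  dimnames = list(sprintf("i%02d", 1:40),
                                  sprintf("g%d", 1:30)))
  })
  nmap <- knn_match(iss, ref, k = 15)
  oracle <- brute_knn(iss, ref, 15)
  for (i in seq_len(nrow(iss))) {
    sub <- nmap[nmap$cell == rownames(iss)[i], ]
    expect_equal(sub$neighbor, rownames(ref)[oracle[[i]]$idx])
    expect_equal(sub$distance, unname(oracle[[i]]$dist), tolerance = 1e-10)
    expect_true(all(diff(sub$distance) >= -1e-12))
  }
  # identical cell at k = 1 is its own neighbour at distance 0
  nm1 <- knn_match(ref[3, , drop = FALSE], ref, k = 1)
  expect_equal(nm1$neighbor, "r003")
  expect_equal(nm1$distance, 0)
  # k equal to the reference size returns everything sorted
  nm_all <- knn_match(iss[1, , drop = FALSE], ref, k = 200)
  expect_equal(nrow(nm_all), 200)
  expect_true(!is.unsorted(nm_all$distance))
  expect_error(knn_match(iss, ref, k = 201), class = "osteoatlas_value_error")
})

test_that("imputation is the exact neighbour mean of raw counts", {
  counts <- matrix(c(7L, 1L,
                     0L, 2L,
                     3L, 4L,
                     6L, 8L), 4, 2, byrow = TRUE,
                   dimnames = list(sprintf("r%d", 1:4), c("gX", "gY")))
  ref <- toy_cells(counts)
  nmap <- structure(
    tibble::tibble(cell = c("i1", "i1", "i1"),
                   rank = 1:3, neighbor = c("r1", "r2", "r4"),
                   distance = c(0.1, 0.2, 0.3)),
    k = 3, class = c("neighbor_map", "tbl_df", "tbl", "data.frame"))
  imp <- impute_counts(nmap, ref, c("gX", "gY"))
  expect_equal(imp["i1", "gX"], mean(c(7, 0, 6)))
  expect_equal(imp["i1", "gY"], mean(c(1, 2, 8)))
  # k = 1 copies the neighbour's counts exactly
  nm1 <- structure(tibble::tibble(cell = "i1", rank = 1L, neighbor = "r1",
                                  distance = 0),
                   k = 1, class = class(nmap))
  expect_equal(impute_counts(nm1, ref, "gX")["i1", "gX"], 7)
  # imputed values lie within the neighbours' count range, and a random
  # fixture matches the independent row-mean oracle
  withr::with_seed(4, {
    big <- matrix(rnbinom(50 * 6, mu = 3, size = 2), 50, 6,
                  dimnames = list(sprintf("r%d", 1:50), sprintf("g%d", 1:6)))
  })
  big[rowSums(big) == 0, 1] <- 1L
  bigref <- toy_cells(big)
  norm <- normalize_panel(bigref, sprintf("g%d", 1:6))
  nm <- knn_match(norm[1:10, ], norm, k = 5)
  imp2 <- impute_counts(nm, bigref, sprintf("g%d", 1:6))
  for (cellname in rownames(imp2)) {
    nbs <- nm$neighbor[nm$cell == cellname]
    expect_equal(unname(imp2[cellname, ]),
                 unname(colMeans(bigref$counts[nbs, ])))
    expect_true(all(imp2[cellname, ] >=
                      apply(bigref$counts[nbs, ], 2, min) - 1e-12))
    expect_true(all(imp2[cellname, ] <=
                      apply(bigref$counts[nbs, ], 2, max) + 1e-12))
  }
})

test_that("label transfer takes the majority with deterministic tie-breaks", {
  mk_nmap <- function(labels, dists) {
    structure(
      tibble::tibble(cell = "i1", rank = seq_along(labels),
                     neighbor = sprintf("r%d", seq_along(labels)),
                     distance = dists),
      k = length(labels), class = c("neighbor_map", "tbl_df", "tbl",
                                    "data.frame"))
  }
  ref_labels <- function(labels) setNames(labels,
                                          sprintf("r%d", seq_along(labels)))
  # unanimity
  lab <- rep("Chon", 15)
  out <- transfer_labels(mk_nmap(lab, seq(0.1, 1.5, by = 0.1)),
                         ref_labels(lab))
  expect_equal(out$label, "Chon")
  expect_equal(out$confidence, 1)
  # 8 vs 7 majority
  lab <- c(rep("A", 8), rep("B", 7))
  out <- transfer_labels(mk_nmap(lab, seq_len(15) / 10), ref_labels(lab))
  expect_equal(out$label, "A")
  expect_equal(out$confidence, 8 / 15)
  # 5/5 tie: smaller summed distance wins
  lab <- c(rep("far", 5), rep("near", 5))
  dists <- c(rep(2, 5), rep(1, 5))
  out <- transfer_labels(mk_nmap(lab, dists), ref_labels(lab))
  expect_equal(out$label, "near")
  # full tie (labels and distances): lexicographic
  lab <- c("B", "A")
  out <- transfer_labels(mk_nmap(lab, c(1, 1)), ref_labels(lab))
  expect_equal(out$label, "A")
  # unlabelled neighbour is an integrity error
  expect_error(transfer_labels(mk_nmap(c("A", "B"), c(1, 2)),
                               c(r1 = "A")),
               class = "osteoatlas_integrity_error")
})

test_that("self-mapping at k = 1 reproduces labels and counts exactly", {
  spec <- synthetic_spec(seed = 6, n_clusters = 3, cells_per_cluster = 20,
                         n_expr_genes = 60, panel_size = 30)
  expr <- simulate_expression(spec)
  panel <- suppressMessages(shared_panel(expr$ref, expr$ref))
  norm <- normalize_panel(expr$ref, panel)
  nmap <- knn_match(norm, norm, k = 1)
  labs <- transfer_labels(nmap, expr$ref$labels)
  expect_equal(setNames(labs$label, labs$cell)[names(expr$ref$labels)],
               expr$ref$labels)
  imp <- impute_counts(nmap, expr$ref, colnames(expr$ref$counts))
  expect_equal(imp[rownames(expr$ref$counts), colnames(expr$ref$counts)],
               expr$ref$counts + 0)
})

test_that("imputation is invariant to reference cell order", {
  spec <- synthetic_spec(seed = 8, n_clusters = 2, cells_per_cluster = 15,
                         n_expr_genes = 40, panel_size = 20)
  expr <- simulate_expression(spec)
  panel <- suppressMessages(shared_panel(expr$ref, expr$iss))
  miss <- setdiff(colnames(expr$ref$counts), panel)
  norm_iss <- normalize_panel(expr$iss, panel)
  imp1 <- impute_counts(knn_match(norm_iss, normalize_panel(expr$ref, panel),
                                  k = 5), expr$ref, miss)
  perm <- withr::with_seed(1, sample(nrow(expr$ref$counts)))
  ref2 <- cell_matrix(expr$ref$counts[perm, ], labels = expr$ref$labels[perm],
                      modality = "reference")
  imp2 <- impute_counts(knn_match(norm_iss, normalize_panel(ref2, panel),
                                  k = 5), ref2, miss)
  expect_equal(imp1, imp2[rownames(imp1), colnames(imp1)])
})
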