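two_band_image <- function(nr = 60, nc = 60, px = 1, band = 5) {
  spec <- synthetic_spec(seed = 1, image_size = c(nr, nc),
                        image_pixel_size = px)
  simulate_label_image(spec, structures = list(
    list(name = "suture", level = 1, value = 1, cols = c(1, band)),
    list(name = "bone", level = 1, value = 2, cols = c(nc - band + 1, nc))))
}

test_that("hex grid geometry is exact: pitch, spacing, nearest neighbour", {
  grid <- build_hex_grid(c(0, 100, 0, 100))
  ys <- sort(unique(grid$y))
  expect_equal(diff(ys), rep(15 * sqrt(3) / 2, length(ys) - 1))
  # nearest-centre distance is the spacing everywhere
  xy <- cbind(grid$x, grid$y)
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  expect_equal(unname(apply(d, 1, min)), rep(15, nrow(grid)),
               tolerance = 1e-9)
  # geometry oracle for the centre count on small bounds: rows at pitch
  # p fit floor(60/p)+1 times; alternate rows lose the half-spacing offset
  g2 <- build_hex_grid(c(0, 60, 0, 60))
  pitch <- 15 * sqrt(3) / 2
  n_rows <- floor(60 / pitch) + 1
  expected <- sum(vapply(seq_len(n_rows), function(i) {
    offset <- if (i %% 2 == 0) 7.5 else 0
    length(seq(offset, 60, by = 15))
  }, numeric(1)))
  expect_equal(nrow(g2), expected)
  expect_error(build_hex_grid(c(0, 0, 0, 10)),
               class = "osteoatlas_value_error")
})

test_that("label migration takes the lower median over the centre disc", {
  img <- two_band_image()
  uniform <- label_image(matrix(3L, 20, 20), 1,
                         tibble::tibble(value = 3L, name = "all", level = 1L))
  grid <- build_hex_grid(c(0, 20, 0, 20))
  ml <- migrate_labels(uniform, grid)
  expect_true(all(ml$label == 3))
  # spots deep inside a band get that band's label
  grid2 <- build_hex_grid(c(0, 60, 0, 60))
  ml2 <- migrate_labels(img, grid2)
  expect_true(all(ml2$label[ml2$x < 3] == 1))
  expect_true(all(ml2$label[ml2$x > 57] == 2))
  expect_true(all(ml2$label[ml2$x > 10 & ml2$x < 50] == 0))

  # straddling disc: enumerate pixels and check the lower median by hand
  half <- matrix(0L, 10, 10)
  half[, 1:5] <- 4L
  img_half <- label_image(half, 1, tibble::tibble(value = 4L, name = "left",
                                                  level = 1L))
  g1 <- structure(tibble::tibble(spot = "s1", x = 5.0, y = 5.0),
                  diameter = 15, spacing = 15,
                  class = c("hex_grid", "tbl_df", "tbl", "data.frame"))
  # disc radius 1.875 around (5,5): pixel centres within are at x in
  # {3.5, 4.5, 5.5, 6.5} and y likewise, filtered by distance
  cand <- expand.grid(cx = seq(0.5, 9.5), cy = seq(0.5, 9.5))
  inside <- (cand$cx - 5)^2 + (cand$cy - 5)^2 <= 1.875^2
  vals <- sort(ifelse(cand$cx[inside] < 5, 4L, 0L))
  expect_equal(migrate_labels(img_half, g1)$label,
               vals[floor((length(vals) + 1) / 2)])

  # sub-pixel disc falls back to the nearest pixel with a warning
  coarse <- label_image(matrix(c(1L, 2L), 1, 2), 10,
                        tibble::tibble(value = c(1L, 2L),
                                       name = c("a", "b"), level = 1L))
  gsub <- structure(tibble::tibble(spot = "s1", x = 2.5, y = 2.5),
                    diameter = 15, spacing = 15,
                    class = c("hex_grid", "tbl_df", "tbl", "data.frame"))
  expect_warning(out <- migrate_labels(coarse, gsub), "nearest pixel")
  expect_equal(out$label, 1L)
})

test_that("labels are equivariant under legend relabelling", {
  img <- two_band_image()
  grid <- build_hex_grid(c(0, 60, 0, 60))
  ml <- migrate_labels(img, grid)
  swapped <- img
  swapped$pixels[img$pixels == 1L] <- 7L
  swapped$pixels[img$pixels == 2L] <- 5L
  swapped$legend <- tibble::tibble(value = c(7L, 5L),
                                   name = c("suture", "bone"),
                                   level = 1L)
  ml2 <- migrate_labels(swapped, grid)
  remap <- c("0" = 0L, "1" = 7L, "2" = 5L)
  expect_equal(ml2$label, unname(remap[as.character(ml$label)]))
  expect_equal(ml2$structure, ml$structure)
})

test_that("structure distances match exhaustive sort-and-average oracles", {
  withr::with_seed(21, {
    pix <- matrix(0L, 40, 40)
    pts <- cbind(sample(40, 50, replace = TRUE),
                 sample(40, 50, replace = TRUE))
    pix[unique(pts)] <- 1L
    img <- label_image(pix, 1.5, tibble::tibble(value = 1L, name = "S",
                                                level = 0L))
    grid <- build_hex_grid(c(0, 60, 0, 60), diameter = 10, spacing = 10)
    d0 <- structure_distances(grid, img, level = 0)
    idx <- which(pix == 1L, arr.ind = TRUE)
    centres <- cbind((idx[, "col"] - 0.5) * 1.5, (idx[, "row"] - 0.5) * 1.5)
    for (i in seq_len(nrow(grid))) {
      all_d <- sort(sqrt((centres[, 1] - grid$x[i])^2 +
                           (centres[, 2] - grid$y[i])^2))
      expect_equal(d0$d_S[i], mean(all_d[seq_len(min(10, length(all_d)))]),
                   tolerance = 1e-10)
    }
    # level 1 uses the single nearest point
    img1 <- label_image(pix, 1.5, tibble::tibble(value = 1L, name = "S",
                                                 level = 1L))
    d1 <- structure_distances(grid, img1, level = 1)
    for (i in seq_len(nrow(grid))) {
      expect_equal(d1$d_S[i],
                   min(sqrt((centres[, 1] - grid$x[i])^2 +
                              (centres[, 2] - grid$y[i])^2)),
                   tolerance = 1e-10)
    }
  })
  # single-pixel structure: level-0 mean falls back to that one distance
  one <- matrix(0L, 10, 10)
  one[5, 5] <- 2L
  img_one <- label_image(one, 1, tibble::tibble(value = 2L, name = "dot",
                                                level = 0L))
  g <- structure(tibble::tibble(spot = "s1", x = 1, y = 1),
                 diameter = 15, spacing = 15,
                 class = c("hex_grid", "tbl_df", "tbl", "data.frame"))
  d <- structure_distances(g, img_one, level = 0)
  expect_equal(d$d_dot, sqrt((4.5 - 1)^2 + (4.5 - 1)^2))
  # a spot centred on a structure pixel has level-1 distance 0
  img_one$legend$level <- 1L
  g2 <- structure(tibble::tibble(spot = "s1", x = 4.5, y = 4.5),
                  diameter = 15, spacing = 15,
                  class = c("hex_grid", "tbl_df", "tbl", "data.frame"))
  expect_equal(structure_distances(g2, img_one, level = 1)$d_dot, 0)
  # absent structure errors by name
  expect_error(structure_distances(g, img_one, level = 1,
                                   structures = "ghost"),
               "ghost", class = "osteoatlas_value_error")
})

test_that("Visium mapping inherits the nearest grid spot within max_dist", {
  img <- two_band_image()
  grid <- build_hex_grid(c(0, 60, 0, 60))
  ann <- migrate_labels(img, grid)
  ann <- dplyr::left_join(
    ann, structure_distances(grid, img, 1)[, c("spot", "d_suture", "d_bone")],
    by = "spot")
  # a coincident spot inherits exactly
  vis <- tibble::tibble(barcode = c("co", "far"),
                        x = c(grid$x[10], 500), y = c(grid$y[10], 500))
  out <- map_to_visium(ann, vis, max_dist = 15)
  expect_equal(out$label[1], ann$label[10])
  expect_equal(out$d_suture[1], ann$d_suture[10])
  expect_true(is.na(out$label[2]))
  # random spots match the exhaustive nearest-neighbour oracle
  withr::with_seed(3, {
    visr <- tibble::tibble(barcode = sprintf("b%d", 1:100),
                           x = runif(100, 0, 60), y = runif(100, 0, 60))
  })
  outr <- map_to_visium(ann, visr, max_dist = 1e9)
  for (i in seq_len(nrow(visr))) {
    d <- sqrt((ann$x - visr$x[i])^2 + (ann$y - visr$y[i])^2)
    expect_equal(outr$label[i], ann$label[which.min(d)])
  }
})

test_that("axis is bounded, anchored and strictly monotone between bands", {
  img <- two_band_image()
  grid <- build_hex_grid(c(0, 60, 0, 60))
  dd <- structure_distances(grid, img, level = 1)
  ann <- compute_axis(dd, "suture", "bone")
  expect_true(all(ann$axis >= 0 & ann$axis <= 1))
  # anchored near 0 on the origin band and near 1 on the target band
  # (distances are to pixel centres, so a spot inside a band sits within
  # half a pixel of one)
  expect_lt(max(ann$axis[ann$x < 4]), 0.05)
  expect_gt(min(ann$axis[ann$x > 56]), 0.95)
  # strictly increasing along the perpendicular between the bands
  mid_row <- ann[abs(ann$y - ann$y[which.min(abs(ann$y - 30))]) < 1e-9, ]
  mid_row <- mid_row[order(mid_row$x), ]
  between <- mid_row[mid_row$x > 5 & mid_row$x < 55, ]
  expect_true(all(diff(between$axis) > 0))
  # equidistant point scores 0.5
  eq <- compute_axis(tibble::tibble(spot = "s", x = 0, y = 0,
                                    d_suture = 3, d_bone = 3),
                     "suture", "bone")
  expect_equal(eq$axis, 0.5)
  expect_error(compute_axis(dd[, c("spot", "x", "y", "d_suture")],
                            "suture", "bone"),
               class = "osteoatlas_integrity_error")
})

test_that("axis is invariant under rigid motions of the whole scene", {
  withr::with_seed(13, {
    spots <- cbind(runif(40, 0, 50), runif(40, 0, 50))
    origin_pts <- cbind(runif(30, 0, 5), runif(30, 0, 50))
    target_pts <- cbind(runif(30, 45, 50), runif(30, 0, 50))
  })
  axis_of <- function(sp, op, tp) {
    d_o <- nearest_point_distances(sp, op, 1)
    d_t <- nearest_point_distances(sp, tp, 1)
    d_o / (d_o + d_t)
  }
  base <- axis_of(spots, origin_pts, target_pts)
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  move <- function(m) sweep(m %*% rot, 2, c(100, -40), "+")
  moved <- axis_of(move(spots), move(origin_pts), move(target_pts))
  expect_equal(moved, base, tolerance = 1e-6)
})

test_that("label images round-trip through PNG + JSON legend", {
  img <- two_band_image()
  png_path <- withr::local_tempfile(fileext = ".png")
  leg_path <- withr::local_tempfile(fileext = ".json")
  write_label_image(img, png_path, leg_path)
  back <- read_label_image(png_path, leg_path)
  expect_equal(back$pixels, img$pixels)
  expect_equal(back$pixel_size, img$pixel_size)
  expect_equal(dplyr::arrange(back$legend, value),
               dplyr::arrange(img$legend, value))
})
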