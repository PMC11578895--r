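#' Construct an annotated label image
#'
#' A single-channel raster of integer annotation labels (0 = unannotated
#' background) with a physical pixel size and a legend mapping label
#' values to structure names and annotation levels. Image coordinates use
#' the raster convention: origin top-left, x right, y down, and the pixel
#' at row i, column j has its centre at `((j - 0.5), (i - 0.5)) *
#' pixel_size` micrometres.
#'
#' @param pixels Integer matrix (rows = y, columns = x).
#' @param pixel_size Micrometres per pixel (> 0).
#' @param legend Data frame with columns `value` (integer), `name`
#'   (structure name), `level` (0 or 1). Must cover every nonzero value
#'   present in `pixels`.
#' @return An object of class `label_image`.
#' @export
label_image <- function(pixels, pixel_size, legend) {
  pixels <- as.matrix(pixels)
  if (any(pixels != round(pixels)) || any(pixels < 0)) {
    abort("pixel values must be non-negative integers",
          class = "osteoatlas_value_error")
  }
  stopifnot(pixel_size > 0)
  legend <- tibble::as_tibble(legend)
  stopifnot(all(c("value", "name", "level") %in% names(legend)))
  present <- setdiff(unique(as.integer(pixels)), 0L)
  uncovered <- setdiff(present, legend$value)
  if (length(uncovered) > 0) {
    abort(sprintf("legend does not cover pixel value(s): %s",
                  paste(uncovered, collapse = ", ")),
          class = "osteoatlas_integrity_error")
  }
  structure(list(pixels = pixels, pixel_size = pixel_size, legend = legend),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("<label_image> %d x %d px at %.3g um/px; structures: %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              paste(x$legend$name, collapse = ", ")))
  invisible(x)
}

#' Write / read a label image as PNG plus a JSON legend
#'
#' The raster is stored as an 8-bit grayscale PNG (label values must be
#' below 256) and the legend as a JSON document
#' `{value: {name, level}, ...}` together with the pixel size.
#'
#' @param img A [label_image()].
#' @param png_path,legend_path Output paths.
#' @return Invisibly, the paths written.
#' @export
write_label_image <- function(img, png_path, legend_path) {
  stopifnot(inherits(img, "label_image"), max(img$pixels) < 256)
  png::writePNG(img$pixels / 255, png_path)
  legend <- setNames(
    purrr::map2(img$legend$name, img$legend$level,
                function(n, l) list(name = n, level = l)),
    as.character(img$legend$value))
  jsonlite::write_json(list(pixel_size_um = img$pixel_size, legend = legend),
                       legend_path, auto_unbox = TRUE, digits = NA)
  invisible(c(png_path, legend_path))
}

#' @rdname write_label_image
#' @export
read_label_image <- function(png_path, legend_path) {
  raw <- png::readPNG(png_path)
  if (length(dim(raw)) == 3) raw <- raw[, , 1]
  pixels <- round(raw * 255)
  meta <- jsonlite::read_json(legend_path)
  legend <- tibble::tibble(
    value = as.integer(names(meta$legend)),
    name = unname(vapply(meta$legend, function(x) x$name, "")),
    level = unname(vapply(meta$legend, function(x) as.integer(x$level), 0L)))
  label_image(pixels, meta$pixel_size_um, legend)
}

#' Build a hexagonal high-resolution spot grid
#'
#' Rows of spot centres run along x at `spacing` intervals; successive
#' rows sit `spacing * sqrt(3) / 2` apart in y, with every second row
#' offset by `spacing / 2`, so the nearest-centre distance equals
#' `spacing` everywhere (the 15-um diameter / 15-um pitch convention
#' leaves no gap between spots).
#'
#' @param bounds Numeric `c(xmin, xmax, ymin, ymax)` in micrometres.
#' @param diameter Spot diameter in micrometres (default 15).
#' @param spacing Centre-to-centre distance in micrometres (default 15).
#' @return A `hex_grid`: tibble `spot`, `x`, `y` with attributes
#'   `diameter` and `spacing`.
#' @export
build_hex_grid <- function(bounds, diameter = 15, spacing = 15) {
  stopifnot(length(bounds) == 4, diameter > 0, spacing > 0)
  xmin <- bounds[1]; xmax <- bounds[2]; ymin <- bounds[3]; ymax <- bounds[4]
  if (!(xmax > xmin && ymax > ymin)) {
    abort("degenerate bounds: need xmax > xmin and ymax > ymin",
          class = "osteoatlas_value_error")
  }
  pitch <- spacing * sqrt(3) / 2
  ys <- seq(ymin, ymax, by = pitch)
  rows <- lapply(seq_along(ys), function(i) {
    offset <- if (i %% 2 == 0) spacing / 2 else 0
    xs <- seq(xmin + offset, xmax, by = spacing)
    if (length(xs) == 0) return(NULL)
    tibble::tibble(x = xs, y = ys[i])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    abort("bounds too small to place any spot",
          class = "osteoatlas_value_error")
  }
  out <- tibble::tibble(spot = sprintf("spot%d", seq_len(nrow(out))),
                        x = out$x, y = out$y)
  structure(out, diameter = diameter, spacing = spacing,
            class = c("hex_grid", class(out)))
}

#' Migrate raster annotations onto a spot grid
#'
#' Each spot is labelled with the median pixel value inside a disc of
#' radius `(diameter / 2) / 4` around its centre (background 0 included;
#' for an even pixel count the lower median is taken, so the result is
#' always a valid label). If the disc captures no pixel centre the single
#' nearest pixel is used instead, with a warning. Spots outside the image
#' extent are labelled background.
#'
#' @param img A [label_image()].
#' @param grid A [build_hex_grid()] grid in the same micrometre frame.
#' @return Tibble `spot`, `x`, `y`, `label`, `structure` (legend name or
#'   NA for background).
#' @export
migrate_labels <- function(img, grid) {
  stopifnot(inherits(img, "label_image"), inherits(grid, "hex_grid"))
  px <- img$pixel_size
  disc_r <- (attr(grid, "diameter") / 2) / 4
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  fell_back <- FALSE
  lab <- vapply(seq_len(nrow(grid)), function(s) {
    cx <- grid$x[s]; cy <- grid$y[s]
    if (cx < 0 || cy < 0 || cx > nc * px || cy > nr * px) return(0L)
    # candidate pixel index ranges covering the disc (may be empty when the
    # disc falls between pixel centres)
    j_lo <- max(1, ceiling((cx - disc_r) / px + 0.5))
    j_hi <- min(nc, floor((cx + disc_r) / px + 0.5))
    i_lo <- max(1, ceiling((cy - disc_r) / px + 0.5))
    i_hi <- min(nr, floor((cy + disc_r) / px + 0.5))
    inside <- FALSE
    if (j_hi >= j_lo && i_hi >= i_lo) {
      cand <- expand.grid(i = i_lo:i_hi, j = j_lo:j_hi)
      dx <- (cand$j - 0.5) * px - cx
      dy <- (cand$i - 0.5) * px - cy
      inside <- dx^2 + dy^2 <= disc_r^2
    }
    if (!any(inside)) {
      fell_back <<- TRUE
      i <- min(max(round(cy / px + 0.5), 1), nr)
      j <- min(max(round(cx / px + 0.5), 1), nc)
      return(as.integer(img$pixels[i, j]))
    }
    vals <- sort(img$pixels[cbind(cand$i[inside], cand$j[inside])])
    as.integer(vals[floor((length(vals) + 1) / 2)])
  }, integer(1))
  if (fell_back) {
    warn("disc smaller than a pixel for some spots; used the nearest pixel")
  }
  name_of <- setNames(img$legend$name, as.character(img$legend$value))
  tibble::tibble(spot = grid$spot, x = grid$x, y = grid$y, label = lab,
                 structure = unname(name_of[as.character(lab)]))
}

#' Mean distance to the n nearest points of a structure
#'
#' Workhorse for the structure-distance features: for each query point,
#' the mean Euclidean distance to its `n_nearest` closest points of a
#' point set (all points if fewer). `n_nearest = 1` gives the
#' nearest-point distance.
#'
#' @param query Two-column matrix/data frame of query x,y (micrometres).
#' @param points Two-column matrix/data frame of structure points.
#' @param n_nearest Number of nearest points to average over.
#' @return Numeric vector, one value per query point.
#' @export
nearest_point_distances <- function(query, points, n_nearest = 1) {
  query <- as.matrix(query); points <- as.matrix(points)
  stopifnot(ncol(query) == 2, ncol(points) == 2, nrow(points) >= 1)
  n <- min(n_nearest, nrow(points))
  vapply(seq_len(nrow(query)), function(i) {
    d2 <- (points[, 1] - query[i, 1])^2 + (points[, 2] - query[i, 2])^2
    mean(sqrt(sort(d2, partial = n)[seq_len(n)]))
  }, numeric(1))
}

#' Distance features from spots to annotated structures
#'
#' For every structure of the requested annotation level, computes a
#' per-spot distance feature: level 0 structures use the mean Euclidean
#' distance to the ten nearest annotated pixel centres (all pixels if
#' fewer than ten); level 1 structures use the distance to the closest
#' annotated pixel centre.
#'
#' @param grid A [build_hex_grid()] grid (or any tibble with `spot`, `x`,
#'   `y`).
#' @param img A [label_image()].
#' @param level Annotation level (0 or 1) selecting the structures.
#' @param structures Optional subset of structure names at that level.
#' @return Tibble `spot`, `x`, `y` plus one `d_<structure>` column per
#'   structure, in micrometres.
#' @export
structure_distances <- function(grid, img, level, structures = NULL) {
  stopifnot(inherits(img, "label_image"))
  leg <- img$legend[img$legend$level == level, , drop = FALSE]
  if (!is.null(structures)) {
    missing_s <- setdiff(structures, leg$name)
    if (length(missing_s) > 0) {
      abort(sprintf("structure(s) not at level %d: %s", level,
                    paste(missing_s, collapse = ", ")),
            class = "osteoatlas_value_error")
    }
    leg <- leg[leg$name %in% structures, , drop = FALSE]
  }
  px <- img$pixel_size
  out <- tibble::tibble(spot = grid$spot, x = grid$x, y = grid$y)
  q <- cbind(grid$x, grid$y)
  n_nearest <- if (level == 0) 10 else 1
  for (r in seq_len(nrow(leg))) {
    idx <- which(img$pixels == leg$value[r], arr.ind = TRUE)
    if (nrow(idx) == 0) {
      abort(sprintf("structure '%s' has no annotated pixel", leg$name[r]),
            class = "osteoatlas_value_error")
    }
    pts <- cbind((idx[, "col"] - 0.5) * px, (idx[, "row"] - 0.5) * px)
    out[[paste0("d_", leg$name[r])]] <-
      nearest_point_distances(q, pts, n_nearest)
  }
  out
}

#' Map grid annotations onto Visium spots by proximity
#'
#' Each Visium spot inherits every annotation column of the nearest grid
#' spot; Visium spots farther than `max_dist` from any grid spot are left
#' unannotated (NA).
#'
#' @param spot_ann Annotation tibble with `spot`, `x`, `y` plus feature
#'   columns (labels, distances, axis).
#' @param visium_coords Data frame `barcode`, `x`, `y` in the same
#'   micrometre frame.
#' @param max_dist Maximum matching distance in micrometres (default 15).
#' @return `visium_coords` with the inherited annotation columns and
#'   `grid_dist`, the distance to the matched grid spot.
#' @export
map_to_visium <- function(spot_ann, visium_coords, max_dist = 15) {
  if (nrow(spot_ann) == 0) {
    abort("empty annotation grid", class = "osteoatlas_value_error")
  }
  visium_coords <- tibble::as_tibble(visium_coords)
  d2 <- outer(visium_coords$x^2 + visium_coords$y^2,
              spot_ann$x^2 + spot_ann$y^2, "+") -
    2 * (cbind(visium_coords$x, visium_coords$y) %*%
           t(cbind(spot_ann$x, spot_ann$y)))
  nearest <- max.col(-d2, ties.method = "first")
  dist <- sqrt(pmax(0, d2[cbind(seq_len(nrow(visium_coords)), nearest)]))
  feat <- spot_ann[nearest, setdiff(names(spot_ann), c("spot", "x", "y")),
                   drop = FALSE]
  feat[dist > max_dist, ] <- NA
  dplyr::bind_cols(visium_coords, feat, tibble::tibble(grid_dist = dist))
}

#' Continuous tissue axis between two structures
#'
#' Builds a bounded axis from the nearest-point distances to an origin and
#' a target structure: `axis = d_origin / (d_origin + d_target)`, 0 on the
#' origin, 1 on the target. Spots with both distances 0 get 0.5 with a
#' warning.
#'
#' @param spot_ann Tibble containing `d_<origin_structure>` and
#'   `d_<target_structure>` columns (level-1 nearest distances from
#'   [structure_distances()]).
#' @param origin_structure,target_structure Structure names.
#' @return `spot_ann` with an added `axis` column in \[0, 1\].
#' @export
compute_axis <- function(spot_ann, origin_structure, target_structure) {
  oc <- paste0("d_", origin_structure)
  tc <- paste0("d_", target_structure)
  missing_col <- setdiff(c(oc, tc), names(spot_ann))
  if (length(missing_col) > 0) {
    abort(sprintf("missing distance column(s): %s",
                  paste(missing_col, collapse = ", ")),
          class = "osteoatlas_integrity_error")
  }
  d_o <- spot_ann[[oc]]
  d_t <- spot_ann[[tc]]
  both0 <- d_o == 0 & d_t == 0
  if (any(both0, na.rm = TRUE)) {
    warn(sprintf("%d spot(s) at distance 0 from both structures; axis = 0.5",
                 sum(both0, na.rm = TRUE)))
  }
  ax <- d_o / (d_o + d_t)
  ax[both0] <- 0.5
  spot_ann$axis <- ax
  spot_ann
}
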