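#' Inverse-distance-weighted interpolation
#'
#' Shepard interpolation of scattered site values onto query points:
#' `sum(w_i * v_i) / sum(w_i)` with `w_i = d_i^-power`. A query within
#' `epsilon` of a site returns that site's value exactly (the nearest one if
#' several fall inside the radius), which keeps the interpolant defined and
#' exact at the data. Results are convex combinations of the site values,
#' so they never leave the observed range.
#'
#' @param sites Data frame with columns `x`, `y`, `value` (>= 1 row).
#'   Duplicate coordinates carrying different values are an error; average
#'   them first (as [idw_raster()] does per site).
#' @param x,y Query coordinates (vectorized, equal length).
#' @param power Positive distance-decay exponent; 2 by default, the common
#'   GIS default.
#' @param epsilon Exact-hit radius in coordinate units.
#' @param k Optional neighborhood size: use only the `k` nearest sites per
#'   query. `NULL` (default) uses all sites.
#' @return Numeric vector of interpolated values.
#' @export
#' @examples
#' sites <- data.frame(x = c(0, 1), y = 0, value = c(0, 10))
#' idw_interpolate(sites, 0.5, 0) # midpoint symmetry: 5
idw_interpolate <- function(sites, x, y, power = 2, epsilon = 1e-9,
                            k = NULL) {
  if (nrow(sites) < 1) {
    abort("idw needs at least one site", class = "metalrisk_domain_error")
  }
  if (power <= 0) {
    abort("idw power must be > 0", class = "metalrisk_domain_error")
  }
  dup <- duplicated(sites[c("x", "y")]) | duplicated(sites[c("x", "y")],
    fromLast = TRUE
  )
  if (any(dup)) {
    conflict <- stats::aggregate(
      value ~ x + y, data = sites[dup, , drop = FALSE],
      FUN = function(v) length(unique(v))
    )
    bad <- conflict[conflict$value > 1, , drop = FALSE]
    if (nrow(bad) > 0) {
      abort(
        sprintf(
          "conflicting values at duplicated coordinate (%g, %g)",
          bad$x[1], bad$y[1]
        ),
        class = "metalrisk_validation_error"
      )
    }
    sites <- sites[!duplicated(sites[c("x", "y")]), , drop = FALSE]
  }
  stopifnot(length(x) == length(y))
  vapply(seq_along(x), function(i) {
    d <- sqrt((sites$x - x[i])^2 + (sites$y - y[i])^2)
    hit <- which(d <= epsilon)
    if (length(hit) > 0) {
      return(sites$value[hit[which.min(d[hit])]])
    }
    v <- sites$value
    if (!is.null(k) && k < length(d)) {
      keep <- order(d)[seq_len(k)]
      d <- d[keep]
      v <- v[keep]
    }
    w <- d^(-power)
    sum(w * v) / sum(w)
  }, numeric(1))
}

#' Rasterize one metal's samples onto a regular grid by IDW
#'
#' Builds a regular grid over (or covering) the sites' bounding box and
#' evaluates [idw_interpolate()] at every cell center. Repeat measurements
#' at the same site are averaged before interpolation.
#'
#' @param samples A `water_samples` tibble with coordinates.
#' @param metal Element symbol to rasterize.
#' @param nx,ny Cell counts along x and y.
#' @param power,epsilon,k Passed to [idw_interpolate()].
#' @param bbox Optional `c(xmin, xmax, ymin, ymax)`; defaults to the sites'
#'   bounding box.
#' @return A `grid_field`: list with `metal`, `origin` (lower-left corner),
#'   `cell_size` (length-2), `nx`, `ny`, and `values`, an `ny x nx` matrix
#'   (row 1 = southernmost row of cell centers).
#' @export
idw_raster <- function(samples, metal, nx = 50, ny = 50, power = 2,
                       epsilon = 1e-9, k = NULL, bbox = NULL) {
  sub <- samples[samples$metal == metal, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort(paste0("no samples for metal '", metal, "'"),
      class = "metalrisk_validation_error"
    )
  }
  if (!all(c("x", "y") %in% names(sub)) || anyNA(sub$x) || anyNA(sub$y)) {
    abort("samples must carry complete coordinates for rasterization",
      class = "metalrisk_validation_error"
    )
  }
  sites <- stats::aggregate(
    concentration_ug_L ~ x + y,
    data = sub, FUN = mean
  )
  names(sites)[3] <- "value"

  if (is.null(bbox)) {
    bbox <- c(min(sites$x), max(sites$x), min(sites$y), max(sites$y))
  }
  # degenerate extents (single site) get a unit-sized box around the point
  if (bbox[1] == bbox[2]) bbox[1:2] <- bbox[1] + c(-0.5, 0.5)
  if (bbox[3] == bbox[4]) bbox[3:4] <- bbox[3] + c(-0.5, 0.5)
  cell <- c((bbox[2] - bbox[1]) / nx, (bbox[4] - bbox[3]) / ny)
  cx <- bbox[1] + (seq_len(nx) - 0.5) * cell[1]
  cy <- bbox[3] + (seq_len(ny) - 0.5) * cell[2]
  grid <- expand.grid(x = cx, y = cy)
  vals <- idw_interpolate(sites, grid$x, grid$y,
    power = power,
    epsilon = epsilon, k = k
  )
  structure(
    list(
      metal = metal, origin = c(bbox[1], bbox[3]), cell_size = cell,
      nx = nx, ny = ny,
      values = matrix(vals, nrow = ny, ncol = nx, byrow = TRUE)
    ),
    class = "grid_field"
  )
}

#' @export
print.grid_field <- function(x, ...) {
  cat(
    "<grid_field>", x$metal, ":", x$ny, "x", x$nx, "cells, origin (",
    x$origin[1], ",", x$origin[2], "), cell", x$cell_size[1], "x",
    x$cell_size[2], "\n"
  )
  cat(sprintf(
    "  values in [%.4g, %.4g] ug/L\n", min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Coordinates of the grid cell with the largest value
#'
#' @param field A `grid_field` from [idw_raster()].
#' @return Named numeric `c(x, y)` of the maximizing cell center.
#' @export
grid_argmax <- function(field) {
  idx <- which(field$values == max(field$values), arr.ind = TRUE)[1, ]
  c(
    x = field$origin[1] + (idx[["col"]] - 0.5) * field$cell_size[1],
    y = field$origin[2] + (idx[["row"]] - 0.5) * field$cell_size[2]
  )
}

#' Write a grid field as ESRI ASCII raster text
#'
#' Plain-text raster with the conventional 6-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows from north
#' to south. The convention assumes square cells; refuse non-square grids.
#'
#' @param field A `grid_field`.
#' @param path Output file path.
#' @param nodata Sentinel for missing cells.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(field, path, nodata = -9999) {
  if (abs(field$cell_size[1] - field$cell_size[2]) >
    1e-9 * max(field$cell_size)) {
    abort("ESRI ASCII grids require square cells; choose nx/ny accordingly",
      class = "metalrisk_validation_error"
    )
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", field$nx),
    paste("nrows", field$ny),
    paste("xllcorner", field$origin[1]),
    paste("yllcorner", field$origin[2]),
    paste("cellsize", field$cell_size[1]),
    paste("NODATA_value", nodata)
  ), con)
  vals <- field$values
  vals[is.na(vals)] <- nodata
  for (r in rev(seq_len(field$ny))) {
    writeLines(paste(vals[r, ], collapse = " "), con)
  }
  invisible(path)
}
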