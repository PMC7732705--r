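#' Raster height grid (profilometer data model)
#'
#' A single-valued height map z(x, y): one z per grid node, which is exactly
#' what a raster profilometer records and why such an instrument cannot
#' represent undercuts. Missing cells (no return) are `NA` and are dropped,
#' never interpolated — interpolation is the intraoral-scanner artifact
#' under study and must not leak into the profilometer path.
#'
#' @param heights matrix of z-values in mm (rows = y, cols = x); `NA` for
#'   missing cells.
#' @param x_step,y_step grid spacing in um (default 50, a typical
#'   profilometer step-over).
#' @param origin length-2 (x, y) position of `heights[1, 1]` in mm.
#' @return object of class `raster_grid`.
#' @export
raster_grid <- function(heights, x_step = 50, y_step = 50, origin = c(0, 0)) {
  heights <- as.matrix(heights)
  stopifnot(x_step > 0, y_step > 0, length(origin) == 2)
  if (all(is.na(heights))) stop("raster grid has no valid cells")
  structure(list(heights = heights, x_step = x_step, y_step = y_step,
                 origin = as.numeric(origin)),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat("raster_grid:", nrow(x$heights), "x", ncol(x$heights),
      "cells, step", x$x_step, "x", x$y_step, "um,",
      sum(is.na(x$heights)), "missing\n")
  invisible(x)
}

#' Triangulate a raster grid into a surface scan
#'
#' Each grid quad whose four corners are all valid is split into two
#' triangles; quads touching a missing cell are skipped entirely. Triangles
#' are wound counter-clockwise seen from +z so normals point up. All
#' vertices are labelled `"other"`; labels are assigned by the caller
#' afterwards (e.g. transferred from the source mesh).
#'
#' @param grid a [raster_grid()].
#' @return a [surface_scan()] (coordinates in mm).
#' @export
grid_to_scan <- function(grid) {
  stopifnot(inherits(grid, "raster_grid"))
  h <- grid$heights
  nr <- nrow(h)
  nc <- ncol(h)
  if (nr < 2 || nc < 2) stop("grid must be at least 2 x 2")
  valid <- is.finite(h)
  if (!any(valid)) stop("raster grid has no valid cells")

  dx <- grid$x_step / UM_PER_MM
  dy <- grid$y_step / UM_PER_MM
  # vertex index for each valid cell
  vid <- matrix(0L, nr, nc)
  vid[valid] <- seq_len(sum(valid))
  ij <- which(valid, arr.ind = TRUE)
  verts <- cbind(grid$origin[1] + (ij[, 2] - 1) * dx,
                 grid$origin[2] + (ij[, 1] - 1) * dy,
                 h[valid])

  # quads with all 4 corners valid
  qv <- valid[-nr, -nc, drop = FALSE] & valid[-1, -nc, drop = FALSE] &
    valid[-nr, -1, drop = FALSE] & valid[-1, -1, drop = FALSE]
  qi <- which(qv, arr.ind = TRUE)
  if (nrow(qi) == 0) stop("no complete quads in grid")
  a <- vid[cbind(qi[, 1], qi[, 2])]        # (i, j)
  b <- vid[cbind(qi[, 1], qi[, 2] + 1)]    # (i, j+1): +x
  c_ <- vid[cbind(qi[, 1] + 1, qi[, 2] + 1)]  # +x +y
  d <- vid[cbind(qi[, 1] + 1, qi[, 2])]    # +y
  faces <- rbind(cbind(a, b, c_), cbind(a, c_, d))
  surface_scan(verts, faces,
               provenance = list(capture_model = "profilometer"))
}

#' Read / write raster grids as plain text
#'
#' Two encodings are supported: long form with header `x_um,y_um,z_mm`
#' (missing cells simply absent) and matrix form whose first line is
#' `x_step_um,y_step_um` followed by a CSV matrix of z values in mm
#' (`NA` for missing).
#'
#' @param path file path.
#' @return a [raster_grid()].
#' @export
read_raster_grid <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("x_um", first)) {
    tb <- read.csv(path)
    xs <- sort(unique(tb$x_um))
    ys <- sort(unique(tb$y_um))
    step_x <- if (length(xs) > 1) min(diff(xs)) else 50
    step_y <- if (length(ys) > 1) min(diff(ys)) else 50
    i <- round((tb$y_um - ys[1]) / step_y) + 1
    j <- round((tb$x_um - xs[1]) / step_x) + 1
    h <- matrix(NA_real_, max(i), max(j))
    h[cbind(i, j)] <- tb$z_mm
    raster_grid(h, step_x, step_y,
                origin = c(xs[1], ys[1]) / UM_PER_MM)
  } else {
    steps <- as.numeric(strsplit(first, ",")[[1]])
    h <- as.matrix(read.csv(path, skip = 1, header = FALSE))
    raster_grid(h, steps[1], steps[2])
  }
}

#' @rdname read_raster_grid
#' @param grid a [raster_grid()].
#' @export
write_raster_grid <- function(grid, path) {
  writeLines(paste(grid$x_step, grid$y_step, sep = ","), path)
  suppressWarnings(write.table(grid$heights, path, sep = ",", append = TRUE,
                               row.names = FALSE, col.names = FALSE))
  invisible(path)
}
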