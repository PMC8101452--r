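#' Grid geometry for planar equal-area raster stacks
#'
#' Describes the common geometry of every raster in an analysis: a regular
#' planar grid of `n_rows * n_cols` square cells of constant area. Cells are
#' treated as uniform equal-area units (no latitude-dependent correction), so
#' areas are simply cell counts times `cell_area`.
#'
#' The grid origin is the *top-left corner*. Cell `(r, c)` covers the
#' half-open box `[x0 + (c-1) res, x0 + c res)` in x and
#' `(y0 - r res, y0 - (r-1) res]` in y, so every point of the plane inside
#' the grid belongs to exactly one cell; points exactly on the outer right or
#' bottom edge are assigned to the adjacent interior cell.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param cell_area Area of one cell in km^2 (> 0).
#' @param x_origin,y_origin Planar coordinates of the top-left corner.
#' @param resolution Cell edge length in the planar units of the origin.
#' @param nodata_fraction Fraction of cells masked as nodata, in [0, 1).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_area = 1, x_origin = 0,
                      y_origin = n_rows * resolution, resolution = 1,
                      nodata_fraction = 0) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_area > 0, resolution > 0)
  if (nodata_fraction < 0 || nodata_fraction >= 1)
    stop("nodata_fraction must lie in [0, 1)")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_area = cell_area, x_origin = x_origin,
                 y_origin = y_origin, resolution = resolution,
                 nodata_fraction = nodata_fraction),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, res %g, cell area %g km^2\n",
              x$n_rows, x$n_cols, x$resolution, x$cell_area))
  invisible(x)
}

#' Multi-layer raster stack of bioclimatic variables
#'
#' A lightweight in-memory raster stack: a named list of numeric matrices
#' (`n_rows x n_cols`), one per variable, sharing one validity mask and one
#' [grid_spec()]. Nodata cells hold `NA` in every layer.
#'
#' @param layers Named list of numeric matrices, all of identical dimension.
#' @param grid A [grid_spec()] matching the matrix dimensions.
#' @param mask Logical matrix, `TRUE` at valid cells. Defaults to cells that
#'   are non-`NA` in every layer.
#' @return An object of class `bioclim_stack`.
#' @export
bioclim_stack <- function(layers, grid, mask = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1, !is.null(names(layers)))
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != grid$n_rows) || any(dims[2, ] != grid$n_cols))
    stop("all layers must be n_rows x n_cols matrices matching the grid_spec")
  if (is.null(mask)) {
    mask <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
  }
  stopifnot(is.logical(mask), all(dim(mask) == c(grid$n_rows, grid$n_cols)))
  layers <- lapply(layers, function(m) { m[!mask] <- NA_real_; m })
  structure(list(layers = layers, mask = mask, grid = grid),
            class = "bioclim_stack")
}

#' @export
print.bioclim_stack <- function(x, ...) {
  cat(sprintf("bioclim_stack: %d layers (%s%s), %d x %d, %d valid cells\n",
              length(x$layers), paste(utils::head(names(x$layers), 3),
                                      collapse = ", "),
              if (length(x$layers) > 3) ", ..." else "",
              x$grid$n_rows, x$grid$n_cols, sum(x$mask)))
  invisible(x)
}

#' Stack of principal-component score layers
#'
#' Like [bioclim_stack()] but holding k score layers `PC1...PCk` produced by
#' [to_env_space()]; carries a back-reference to the fitted transform.
#'
#' @param layers Named list of score matrices (`PC1`, `PC2`, ...).
#' @param grid A [grid_spec()].
#' @param mask Logical validity matrix.
#' @param transform The `climate_transform` that produced the scores.
#' @return An object of class `pc_stack`.
#' @export
pc_stack <- function(layers, grid, mask, transform = NULL) {
  obj <- bioclim_stack(layers, grid, mask)
  obj$transform <- transform
  class(obj) <- c("pc_stack", "bioclim_stack")
  obj
}

#' Number of valid (non-nodata) cells
#' @param x A `bioclim_stack` or `pc_stack`.
#' @return Integer count.
#' @export
n_valid_cells <- function(x) sum(x$mask)

#' Total valid study area in km^2
#' @param x A `bioclim_stack` or `pc_stack`.
#' @return Valid cell count times `cell_area`.
#' @export
study_area_km2 <- function(x) sum(x$mask) * x$grid$cell_area

#' Extract the valid-cell value matrix of a stack
#'
#' @param x A `bioclim_stack` or `pc_stack`.
#' @param layers Optional character vector of layer names (default: all).
#' @return Numeric matrix with one row per valid cell (in cell-index order,
#'   column-major over the grid) and one column per layer; row names are the
#'   cell indices.
#' @export
stack_values <- function(x, layers = names(x$layers)) {
  idx <- which(x$mask)
  out <- vapply(layers, function(nm) x$layers[[nm]][idx], numeric(length(idx)))
  out <- matrix(out, nrow = length(idx),
                dimnames = list(idx, layers))
  out
}

## cell index <-> (row, col) <-> planar coordinates --------------------------

cell_rowcol <- function(grid, cell) {
  cell <- as.integer(cell)
  r <- ((cell - 1L) %% grid$n_rows) + 1L
  c <- ((cell - 1L) %/% grid$n_rows) + 1L
  cbind(row = r, col = c)
}

cell_index <- function(grid, row, col) {
  (as.integer(col) - 1L) * grid$n_rows + as.integer(row)
}

#' Planar center coordinates of grid cells
#' @param grid A [grid_spec()].
#' @param cell Integer cell indices (column-major).
#' @return Two-column matrix `x`, `y` of cell centers.
#' @export
cell_centers <- function(grid, cell) {
  rc <- cell_rowcol(grid, cell)
  cbind(x = grid$x_origin + (rc[, "col"] - 0.5) * grid$resolution,
        y = grid$y_origin - (rc[, "row"] - 0.5) * grid$resolution)
}

#' Locate planar points on a grid
#'
#' Cells are half-open (`[x0, x0 + res)` by `(y0 - res, y0]`); points exactly
#' on the grid's outer right/bottom edge are assigned to the adjacent interior
#' cell. Points outside the grid map to `NA`.
#'
#' @param grid A [grid_spec()].
#' @param x,y Planar coordinates.
#' @return Integer vector of cell indices (`NA` where outside the grid).
#' @export
cell_from_xy <- function(grid, x, y) {
  res <- grid$resolution
  col <- floor((x - grid$x_origin) / res) + 1
  row <- floor((grid$y_origin - y) / res) + 1
  col[x == grid$x_origin + grid$n_cols * res] <- grid$n_cols  # outer edge
  row[y == grid$y_origin - grid$n_rows * res] <- grid$n_rows
  bad <- !is.finite(x) | !is.finite(y) |
    col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  out <- cell_index(grid, pmax(pmin(row, grid$n_rows), 1),
                    pmax(pmin(col, grid$n_cols), 1))
  out[bad] <- NA_integer_
  as.integer(out)
}

stopifnot_same_grid <- function(a, b) {
  ga <- a$grid; gb <- b$grid
  if (ga$n_rows != gb$n_rows || ga$n_cols != gb$n_cols ||
      ga$resolution != gb$resolution)
    stop("stacks do not share grid geometry")
  if (!identical(a$mask, b$mask))
    stop("stacks do not share the nodata mask")
  invisible(TRUE)
}
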