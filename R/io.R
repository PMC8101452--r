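## On-disk formats. Raster stacks are stored as one plain CSV grid per layer
## (n_rows x n_cols, empty fields at nodata) plus a `stack.json` sidecar with
## the grid geometry, layer order and class — a text format with an exact
## round trip. Transforms, ensembles and tables use JSON/CSV.

#' Write a raster stack to a directory
#'
#' One `<LAYER>.csv` value grid per layer (17 significant digits, blank at
#' nodata) and a `stack.json` sidecar (grid geometry, layer names, stack
#' class, latent elevation if present).
#'
#' @param stack A [bioclim_stack()] or [pc_stack()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_grid <- function(m, path) {
    utils::write.table(
      matrix(ifelse(is.na(m), "", formatC(m, digits = 17, format = "g")),
             nrow(m), ncol(m)),
      path, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  for (nm in names(stack$layers))
    write_grid(stack$layers[[nm]], file.path(dir, paste0(nm, ".csv")))
  if (!is.null(stack$elevation))
    write_grid(stack$elevation, file.path(dir, "ELEVATION.csv"))
  g <- stack$grid
  side <- list(class = class(stack)[1], layers = names(stack$layers),
               n_rows = g$n_rows, n_cols = g$n_cols, cell_area = g$cell_area,
               x_origin = g$x_origin, y_origin = g$y_origin,
               resolution = g$resolution,
               nodata_fraction = g$nodata_fraction,
               has_elevation = !is.null(stack$elevation))
  jsonlite::write_json(side, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a raster stack written by [write_stack()]
#' @param dir Directory containing `stack.json` and the layer CSV grids.
#' @return A [bioclim_stack()] or [pc_stack()] (per the sidecar's class).
#' @export
read_stack <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "stack.json"),
                              simplifyVector = TRUE)
  g <- grid_spec(side$n_rows, side$n_cols, side$cell_area, side$x_origin,
                 side$y_origin, side$resolution, side$nodata_fraction)
  read_grid <- function(path) {
    m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                     colClasses = "numeric",
                                     na.strings = ""))
    dimnames(m) <- NULL
    m
  }
  layers <- lapply(side$layers, function(nm)
    read_grid(file.path(dir, paste0(nm, ".csv"))))
  names(layers) <- side$layers
  mask <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
  st <- if (identical(side$class, "pc_stack")) pc_stack(layers, g, mask)
  else bioclim_stack(layers, g, mask)
  if (isTRUE(side$has_elevation))
    st$elevation <- read_grid(file.path(dir, "ELEVATION.csv"))
  st
}

#' Write a climate transform as JSON
#' @param transform A `climate_transform`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path) {
  obj <- list(var_names = transform$var_names, log_vars = transform$log_vars,
              center = as.numeric(transform$center),
              scale = as.numeric(transform$scale),
              loadings_full = transform$loadings_full,
              variance_fraction = transform$variance_fraction,
              eigenvalues = transform$eigenvalues,
              k = transform$k, n_cells = transform$n_cells)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a climate transform written by [write_transform()]
#' @param path JSON path.
#' @return A `climate_transform`.
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(obj$var_names)
  lf <- matrix(unlist(obj$loadings_full), p, p,
               dimnames = list(obj$var_names, paste0("PC", seq_len(p))))
  center <- stats::setNames(obj$center, obj$var_names)
  scale_ <- stats::setNames(obj$scale, obj$var_names)
  structure(list(var_names = obj$var_names, log_vars = obj$log_vars,
                 center = center, scale = scale_,
                 loadings = lf[, seq_len(obj$k), drop = FALSE],
                 loadings_full = lf,
                 variance_fraction = obj$variance_fraction,
                 eigenvalues = obj$eigenvalues, k = as.integer(obj$k),
                 n_cells = obj$n_cells),
            class = "climate_transform")
}
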