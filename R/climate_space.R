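## PCA environmental space. The current-climate stack defines the transform
## (log rainfall -> z-scores -> principal components); every other stack,
## including futures, is projected with that same frozen transform so all
## scenarios live in one common environmental space.

#' Default set of rainfall variables to log-transform
#'
#' The precipitation-based bioclims BIO12-BIO19. Precipitation distributions
#' are right-skewed, so these are log-transformed (log1p, to admit zeros)
#' before z-scoring.
#'
#' @return Character vector of layer names.
#' @export
default_log_vars <- function() paste0("BIO", 12:19)

#' Fit the climate-space transform on the current climate
#'
#' Applies `log1p` to the rainfall variables, z-scores every variable over
#' the valid study-area cells, and runs a PCA via eigen-decomposition of the
#' covariance of the z-scores (the correlation matrix of the transformed
#' variables, denominator n - 1). The first `k` loading columns are retained;
#' variance fractions are reported for all components. Each loading column's
#' sign is fixed so that its largest-absolute loading is positive, making
#' scores reproducible across eigen-solvers.
#'
#' @param stack A [bioclim_stack()] of the current climate; its mask defines
#'   the study area used for fitting.
#' @param log_vars Layer names to log1p-transform (default
#'   [default_log_vars()]); must be non-negative at all valid cells.
#' @param k Number of components to retain (default 3).
#' @return An object of class `climate_transform` with fields `var_names`,
#'   `log_vars`, `center`, `scale`, `loadings` (p x k), `variance_fraction`
#'   (length p, non-increasing, summing to 1), `k`, `n_cells`.
#' @export
fit_climate_transform <- function(stack, log_vars = default_log_vars(),
                                  k = 3) {
  stopifnot(inherits(stack, "bioclim_stack"))
  vars <- names(stack$layers)
  p <- length(vars)
  if (k < 1 || k > p) stop("k must be between 1 and the number of layers")
  missing_log <- setdiff(log_vars, vars)
  if (length(missing_log) > 0)
    stop("log_vars not present in the stack: ",
         paste(missing_log, collapse = ", "))
  x <- stack_values(stack)
  if (nrow(x) < k + 1) stop("need at least k + 1 valid cells to fit")
  for (nm in log_vars) {
    if (any(x[, nm] < 0))
      stop(sprintf("variable %s has negative values; cannot log-transform", nm))
    x[, nm] <- log1p(x[, nm])
  }
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  zero <- scale_ <= 0 | !is.finite(scale_)
  if (any(zero))
    stop("variable(s) constant over valid cells: ",
         paste(vars[zero], collapse = ", "))
  z <- sweep(sweep(x, 2, center), 2, scale_, `/`)
  cv <- stats::cov(z)                      # correlation matrix, n - 1
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  load_full <- eg$vectors
  # sign convention: largest-|loading| entry of each column is positive
  for (j in seq_len(p)) {
    i <- which.max(abs(load_full[, j]))
    if (load_full[i, j] < 0) load_full[, j] <- -load_full[, j]
  }
  dimnames(load_full) <- list(vars, paste0("PC", seq_len(p)))
  structure(list(var_names = vars, log_vars = log_vars,
                 center = center, scale = scale_,
                 loadings = load_full[, seq_len(k), drop = FALSE],
                 loadings_full = load_full,
                 variance_fraction = ev / sum(ev),
                 eigenvalues = ev, k = as.integer(k),
                 n_cells = nrow(x)),
            class = "climate_transform")
}

#' @export
print.climate_transform <- function(x, ...) {
  cat(sprintf(
    "climate_transform: %d variables, k = %d (%.1f%% of variance), %d cells\n",
    length(x$var_names), x$k,
    100 * sum(x$variance_fraction[seq_len(x$k)]), x$n_cells))
  invisible(x)
}

#' Cumulative variance explained by the retained components
#' @param transform A `climate_transform`.
#' @return Fraction in (0, 1].
#' @export
variance_explained <- function(transform) {
  sum(transform$variance_fraction[seq_len(transform$k)])
}

#' Project a bioclim stack into the fitted environmental space
#'
#' Applies the *current-climate* transform (same log set, centers, scales and
#' loadings) to any stack, so future climates are expressed in the same PC
#' space; values outside the training range extrapolate linearly. The nodata
#' mask propagates to every score layer.
#'
#' @param stack A [bioclim_stack()] holding all variables of the transform.
#' @param transform A `climate_transform` from [fit_climate_transform()].
#' @param n_components Number of score layers to produce (default the
#'   transform's `k`; up to the full variable count for diagnostics).
#' @return A [pc_stack()] with layers `PC1`...`PCk`.
#' @export
to_env_space <- function(stack, transform, n_components = transform$k) {
  stopifnot(inherits(stack, "bioclim_stack"),
            inherits(transform, "climate_transform"))
  missing_vars <- setdiff(transform$var_names, names(stack$layers))
  if (length(missing_vars) > 0)
    stop("stack is missing variable(s): ", paste(missing_vars, collapse = ", "))
  p <- length(transform$var_names)
  stopifnot(n_components >= 1, n_components <= p)
  x <- stack_values(stack, transform$var_names)
  for (nm in transform$log_vars) x[, nm] <- log1p(x[, nm])
  z <- sweep(sweep(x, 2, transform$center), 2, transform$scale, `/`)
  scores <- z %*% transform$loadings_full[, seq_len(n_components),
                                          drop = FALSE]
  idx <- which(stack$mask)
  layers <- lapply(seq_len(n_components), function(j) {
    m <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
    m[idx] <- scores[, j]
    m
  })
  names(layers) <- paste0("PC", seq_len(n_components))
  out <- pc_stack(layers, stack$grid, stack$mask, transform)
  if (!is.null(stack$elevation)) out$elevation <- stack$elevation
  out
}

# Test-only inverse: reconstruct z-scores from a full-rank score matrix.
env_space_inverse <- function(scores, transform) {
  scores %*% t(transform$loadings_full[, seq_len(ncol(scores)), drop = FALSE])
}

#' Core-climate ellipsoid of an environmental space
#'
#' Summarises the climate available in a region as the ellipsoid of points
#' whose within-cloud chi-square probability is at least `p_level`, using the
#' mean and sample covariance of the cell scores. Because probability
#' `>= p` is equivalent to Mahalanobis `D^2 <=` the chi-square quantile at
#' `1 - p`, the `p = 0.75` core ellipsoid contains about 25% of a
#' multivariate-normal cell cloud.
#'
#' @param env A [pc_stack()].
#' @param p_level Probability level in (0, 1) (default 0.75).
#' @return An object of class `core_ellipsoid` with `center`, `covariance`,
#'   `p_level`, `d2_threshold` and `df`.
#' @export
climate_core_ellipsoid <- function(env, p_level = 0.75) {
  stopifnot(inherits(env, "pc_stack"), p_level > 0, p_level < 1)
  scores <- stack_values(env)
  k <- ncol(scores)
  if (nrow(scores) < k + 1) stop("need at least k + 1 valid cells")
  ctr <- colMeans(scores)
  cv <- stats::cov(scores)
  if (min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values) <= 1e-12)
    stop("degenerate score covariance; cannot form a core ellipsoid")
  structure(list(center = ctr, covariance = cv, p_level = p_level,
                 d2_threshold = stats::qchisq(p_level, df = k,
                                              lower.tail = FALSE),
                 df = k),
            class = "core_ellipsoid")
}

#' Fraction of cells inside a core ellipsoid
#' @param ellipsoid A `core_ellipsoid`.
#' @param env A [pc_stack()] of matching dimension.
#' @return Fraction of valid cells with Mahalanobis `D^2 <= d2_threshold`.
#' @export
core_inside_fraction <- function(ellipsoid, env) {
  scores <- stack_values(env)
  d2 <- mahalanobis_d2_raw(ellipsoid$center, ellipsoid$covariance, scores)
  mean(d2 <= ellipsoid$d2_threshold)
}

#' Per-variable distribution diagnostics before transform choice
#'
#' Reports skewness (moment coefficient) and a coarse bimodality signal
#' (bimodality coefficient) for each layer on the raw and, for rainfall
#' variables, the log1p scale — a screening aid for choosing which
#' variables to log-transform; it does not gate the fit.
#'
#' @param stack A [bioclim_stack()].
#' @param log_vars Variables also reported on the log1p scale.
#' @return Data frame with columns `variable`, `scale`, `skewness`,
#'   `bimodality`.
#' @export
climate_skew_report <- function(stack, log_vars = default_log_vars()) {
  x <- stack_values(stack)
  skew <- function(v) {
    v <- v - mean(v); s <- stats::sd(v)
    if (s == 0) return(0)
    mean(v^3) / s^3
  }
  kurt <- function(v) {
    v <- v - mean(v); s <- stats::sd(v)
    if (s == 0) return(3)
    mean(v^4) / s^4
  }
  rows <- list()
  for (nm in colnames(x)) {
    v <- x[, nm]
    rows[[length(rows) + 1]] <- data.frame(
      variable = nm, scale = "raw", skewness = skew(v),
      bimodality = (skew(v)^2 + 1) / kurt(v), stringsAsFactors = FALSE)
    if (nm %in% log_vars && all(v >= 0)) {
      lv <- log1p(v)
      rows[[length(rows) + 1]] <- data.frame(
        variable = nm, scale = "log1p", skewness = skew(lv),
        bimodality = (skew(lv)^2 + 1) / kurt(lv), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
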