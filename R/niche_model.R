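## Fundamental-niche ellipsoids. A niche model is the multivariate-normal
## summary (mu, sigma) of a species' occurrence scores in PC space; the
## squared Mahalanobis distance of a climate from mu, referred to a
## chi-square with k degrees of freedom, gives the probability of being
## within the fundamental niche (1 at the centroid, decaying outwards).
## Bootstrap resampling of the occurrences propagates sampling uncertainty
## into an ensemble of such ellipsoids.

new_niche_model <- function(mu, sigma, n_points = NA_integer_,
                            bootstrap_id = "point-estimate") {
  sigma <- as.matrix(sigma)
  structure(list(mu = as.numeric(mu), sigma = sigma,
                 df = length(mu), n_points = n_points,
                 bootstrap_id = bootstrap_id),
            class = "niche_model")
}

#' @export
print.niche_model <- function(x, ...) {
  cat(sprintf("niche_model (%s): k = %d, n = %s\n", x$bootstrap_id, x$df,
              if (is.na(x$n_points)) "?" else x$n_points))
  invisible(x)
}

# D^2 via Cholesky factorization + triangular solve (no explicit inverse).
# x: n x k matrix (or k-vector). Returns length-n vector.
mahalanobis_d2_raw <- function(mu, sigma, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  R <- chol(sigma)
  z <- backsolve(R, t(sweep(x, 2, mu)), transpose = TRUE)
  colSums(z^2)
}

check_spd <- function(sigma, tol = 1e-12) {
  ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  min(ev) > tol * max(abs(ev), 1)
}

#' Fit a fundamental-niche ellipsoid to occurrence scores
#'
#' `mu` is the componentwise mean and `sigma` the sample covariance
#' (denominator n - 1) of the points.
#'
#' @param points Numeric matrix, one row per occurrence, k columns of PC
#'   scores (a plain vector is treated as 1-D points).
#' @param bootstrap_id Label recorded on the model (default
#'   `"point-estimate"`).
#' @return An object of class `niche_model` with `mu`, `sigma`, `df = k`,
#'   `n_points`.
#' @export
fit_niche <- function(points, bootstrap_id = "point-estimate") {
  points <- if (is.matrix(points)) points else matrix(points, ncol = 1)
  k <- ncol(points)
  if (nrow(points) < k + 1)
    stop("need at least k + 1 points to fit a niche")
  mu <- colMeans(points)
  sigma <- stats::cov(points)
  if (!check_spd(sigma)) {
    cond <- simpleCondition("degenerate occurrence covariance")
    class(cond) <- c("nichecast_degenerate", "error", "condition")
    stop(cond)
  }
  new_niche_model(mu, sigma, nrow(points), bootstrap_id)
}

#' Bootstrap ensemble of fundamental niches
#'
#' Draws `B` with-replacement resamples of size n from the occurrence points
#' and fits one niche ellipsoid per resample. A degenerate resample (singular
#' covariance) is redrawn up to 100 times; if still degenerate the covariance
#' is ridge-regularised (adding `1e-8 * trace(sigma)/k` to the diagonal) with
#' a warning. The same seed reproduces the ensemble exactly.
#'
#' @param points Occurrence score matrix (n x k).
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed (a `"bootstrap"` substream is derived from it).
#' @param species_id Label stored on the ensemble.
#' @return An object of class `bootstrap_ensemble`: list with `species_id`,
#'   `models` (length-B list of `niche_model`s), `B`, `seed`.
#' @export
bootstrap_niches <- function(points, B = 1000, seed = 1,
                             species_id = "species") {
  points <- if (is.matrix(points)) points else matrix(points, ncol = 1)
  base_fit <- fit_niche(points)   # refuses degenerate inputs up front
  n <- nrow(points); k <- ncol(points)
  with_seed(substream_seed(seed, paste0("bootstrap/", species_id)), {
    models <- vector("list", B)
    for (b in seq_len(B)) {
      fit <- NULL
      for (try in seq_len(100)) {
        idx <- sample.int(n, n, replace = TRUE)
        fit <- tryCatch(fit_niche(points[idx, , drop = FALSE], b),
                        nichecast_degenerate = function(e) NULL)
        if (!is.null(fit)) break
      }
      if (is.null(fit)) {
        sigma <- stats::cov(points[idx, , drop = FALSE])
        ridge <- 1e-8 * sum(diag(sigma)) / k
        sigma <- sigma + diag(ridge, k)
        warning(sprintf(
          "species '%s' bootstrap %d: degenerate after 100 redraws; ridge-regularised",
          species_id, b))
        fit <- new_niche_model(colMeans(points[idx, , drop = FALSE]),
                               sigma, n, b)
      }
      models[[b]] <- fit
    }
    structure(list(species_id = species_id, models = models,
                   B = as.integer(B), seed = seed, point_estimate = base_fit),
              class = "bootstrap_ensemble")
  })
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf("bootstrap_ensemble: species '%s', B = %d, k = %d\n",
              x$species_id, x$B, x$models[[1]]$df))
  invisible(x)
}

#' Chi-square probability of being within the fundamental niche
#'
#' Computes the squared Mahalanobis distance
#' `D^2 = (x - mu)' sigma^-1 (x - mu)` (via a triangular factorisation, not
#' an explicit inverse) and returns the upper-tail chi-square probability of
#' `D^2` at `df = k` degrees of freedom: 1 at the centroid, strictly
#' decreasing along any ray leaving it.
#'
#' @param model A `niche_model`.
#' @param x A k-vector, or an n x k matrix of points (vectorised).
#' @return Probability vector in [0, 1].
#' @export
niche_probability <- function(model, x) {
  d2 <- mahalanobis_d2_raw(model$mu, model$sigma, x)
  stats::pchisq(d2, df = model$df, lower.tail = FALSE)
}

#' Squared Mahalanobis distance to a niche centroid
#' @param model A `niche_model`.
#' @param x A k-vector or n x k matrix.
#' @return Nonnegative vector of `D^2` values.
#' @export
mahalanobis_d2 <- function(model, x) {
  mahalanobis_d2_raw(model$mu, model$sigma, x)
}

#' Mahalanobis threshold of a probability contour
#'
#' Returns the `D^2` value at which the within-niche probability equals
#' `p_level`, i.e. the chi-square upper-tail quantile at `df = k`. Contours
#' for p = 0.9, 0.5, 0.1 are strictly nested increasing (high-probability
#' ellipsoids are the smallest).
#'
#' @param model A `niche_model`, or a bare integer degrees of freedom.
#' @param p_level Probability level in (0, 1).
#' @return Nonnegative `D^2` threshold.
#' @export
ellipsoid_threshold <- function(model, p_level) {
  stopifnot(p_level > 0, p_level < 1)
  df <- if (inherits(model, "niche_model")) model$df else as.integer(model)
  stats::qchisq(p_level, df = df, lower.tail = FALSE)
}

#' Serialize a bootstrap ensemble to a flat table
#'
#' One row per bootstrap model: species, bootstrap id, `mu` components and
#' `sigma` entries row-major — sufficient for exact re-runs and audits.
#'
#' @param ensemble A `bootstrap_ensemble`.
#' @return Data frame with columns `species`, `bootstrap_id`, `n_points`,
#'   `mu_1..mu_k`, `sigma_1_1..sigma_k_k`.
#' @export
ensemble_to_table <- function(ensemble) {
  k <- ensemble$models[[1]]$df
  rows <- lapply(ensemble$models, function(m) {
    v <- c(m$mu, as.numeric(t(m$sigma)))
    names(v) <- c(paste0("mu_", seq_len(k)),
                  paste0("sigma_", rep(seq_len(k), each = k), "_",
                         rep(seq_len(k), k)))
    data.frame(species = ensemble$species_id,
               bootstrap_id = m$bootstrap_id, n_points = m$n_points,
               t(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Rebuild a bootstrap ensemble from its serialized table
#' @param tab A data frame produced by [ensemble_to_table()].
#' @return A `bootstrap_ensemble`.
#' @export
table_to_ensemble <- function(tab) {
  k <- sum(grepl("^mu_", names(tab)))
  models <- lapply(seq_len(nrow(tab)), function(i) {
    mu <- as.numeric(tab[i, paste0("mu_", seq_len(k))])
    sigma <- matrix(as.numeric(
      tab[i, paste0("sigma_", rep(seq_len(k), each = k), "_",
                    rep(seq_len(k), k))]), k, k, byrow = TRUE)
    new_niche_model(mu, sigma, tab$n_points[i], tab$bootstrap_id[i])
  })
  structure(list(species_id = tab$species[1], models = models,
                 B = nrow(tab), seed = NA_integer_,
                 point_estimate = NULL),
            class = "bootstrap_ensemble")
}
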