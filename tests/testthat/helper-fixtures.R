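# Fixtures built in code: environmental-score stacks with known properties,
# random SPD matrices, and iid bioclim stacks for PCA sanity checks.

# pc_stack whose score layers are iid normal draws (optionally with nodata)
make_scores_env <- function(n_rows = 12, n_cols = 12, k = 3, seed = 1,
                            n_nodata = 0, sd = 1, center = rep(0, k),
                            cell_area = 1) {
  set.seed(seed)
  mask <- matrix(TRUE, n_rows, n_cols)
  if (n_nodata > 0) mask[sample.int(n_rows * n_cols, n_nodata)] <- FALSE
  layers <- lapply(seq_len(k), function(j) {
    m <- matrix(rnorm(n_rows * n_cols, center[j], sd), n_rows, n_cols)
    m[!mask] <- NA
    m
  })
  names(layers) <- paste0("PC", seq_len(k))
  pc_stack(layers, grid_spec(n_rows, n_cols, cell_area = cell_area), mask)
}

# bioclim_stack of 19 independent unit-variance layers (no rainfall
# structure; used with log_vars = character(0))
make_iid_bioclim <- function(n_rows, n_cols, seed = 1) {
  set.seed(seed)
  layers <- lapply(1:19, function(i)
    matrix(rnorm(n_rows * n_cols), n_rows, n_cols))
  names(layers) <- paste0("BIO", 1:19)
  bioclim_stack(layers, grid_spec(n_rows, n_cols))
}

rand_spd <- function(k, scale = 1) {
  a <- matrix(rnorm(k * k), k, k)
  (a %*% t(a) / k + diag(0.5, k)) * scale
}

# independent chi-square oracles: upper-tail probability by numerical
# integration of the density, and quantile by root finding on it
chisq_upper_oracle <- function(d2, df) {
  if (d2 == 0) return(1)
  stats::integrate(function(t) stats::dchisq(t, df), d2, Inf,
                   rel.tol = 1e-12)$value
}

chisq_upper_quantile_oracle <- function(p, df) {
  stats::uniroot(function(t) chisq_upper_oracle(t, df) - p,
                 c(1e-12, 200), tol = 1e-10)$root
}

# brute-force Mahalanobis D^2 with an explicit matrix inverse (test oracle)
d2_brute <- function(mu, sigma, x) {
  v <- as.numeric(x) - mu
  as.numeric(t(v) %*% solve(sigma) %*% v)
}
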