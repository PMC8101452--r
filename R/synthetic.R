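## Synthetic study systems: virtual bioclim grids, future climate ensembles,
## virtual species with known ellipsoidal niches, and service catalogues.
## These emulate the structure of a WorldClim-style analysis (19 BIO layers,
## GCM x RCP x period futures, presence-only occurrence sets) so that every
## downstream stage has a ground truth to be tested against.

# Smooth random field from a low-order cosine basis, standardised to unit sd
# then scaled; amplitude 0 returns an exactly constant (zero) field.
smooth_field <- function(n_rows, n_cols, amplitude = 1, n_modes = 3) {
  if (amplitude == 0) return(matrix(0, n_rows, n_cols))
  rr <- (seq_len(n_rows) - 0.5) / n_rows
  cc <- (seq_len(n_cols) - 0.5) / n_cols
  f <- matrix(0, n_rows, n_cols)
  for (i in 0:n_modes) for (j in 0:n_modes) {
    if (i == 0 && j == 0) next
    a <- stats::rnorm(1, 0, 1 / (1 + i + j))
    f <- f + a * outer(cos(pi * i * rr + stats::runif(1, 0, 2 * pi)),
                       cos(pi * j * cc + stats::runif(1, 0, 2 * pi)))
  }
  s <- stats::sd(f)
  if (is.finite(s) && s > 0) f <- f / s
  f * amplitude
}

#' Generate a synthetic current-climate bioclim stack
#'
#' Builds the 19 bioclimatic layers (`BIO1`...`BIO19`) over a planar grid from
#' a latent elevation field and a latent moisture field. Temperature follows a
#' linear lapse with elevation (`BIO1 = base_temp - lapse_rate * elev / 1000`),
#' extremes satisfy `BIO5 >= BIO1 >= BIO6` at every valid cell by
#' construction, and precipitation layers are strictly positive (log-normal
#' modulation of an annual total). A `nodata_fraction` of cells is masked
#' identically across all layers.
#'
#' With `relief = 0`, `moisture_sd = 0` and `noise_sd = 0` every layer is
#' spatially constant, which is useful for degenerate-input tests.
#'
#' @param spec A [grid_spec()].
#' @param seed Integer seed (a `"climate"` substream is derived from it).
#' @param base_temp Sea-level annual mean temperature, degrees C.
#' @param lapse_rate Temperature lapse, degrees C per km of elevation.
#' @param relief Amplitude of the latent elevation field, m (0 = flat).
#' @param moisture_sd Amplitude of the latent moisture anomaly field
#'   (dimensionless, log scale for precipitation).
#' @param noise_sd Per-cell independent noise sd on temperature layers,
#'   degrees C (precipitation noise is scaled from it).
#' @return A [bioclim_stack()] with 19 layers; the latent elevation field is
#'   attached as `$elevation` (NA at nodata cells) for elevation cross-checks.
#' @export
generate_current_climate <- function(spec, seed, base_temp = 27,
                                     lapse_rate = 6.5, relief = 2500,
                                     moisture_sd = 0.25, noise_sd = 0.15) {
  nr <- spec$n_rows; nc <- spec$n_cols; n <- nr * nc
  with_seed(substream_seed(seed, "climate"), {
    n_nodata <- floor(spec$nodata_fraction * n)
    if (n - n_nodata < 2)
      stop("nodata_fraction leaves fewer than 2 valid cells")
    mask <- matrix(TRUE, nr, nc)
    if (n_nodata > 0) mask[sample.int(n, n_nodata)] <- FALSE

    elev <- if (relief > 0) {
      f <- smooth_field(nr, nc, 1)
      rng <- range(f)
      if (rng[2] > rng[1]) relief * (f - rng[1]) / (rng[2] - rng[1])
      else matrix(relief / 2, nr, nc)
    } else matrix(0, nr, nc)
    moist <- smooth_field(nr, nc, moisture_sd)
    nz <- function(sd) if (sd > 0) matrix(stats::rnorm(n, 0, sd), nr, nc)
    else matrix(0, nr, nc)

    bio1 <- base_temp - lapse_rate * elev / 1000 + nz(noise_sd)
    warm <- pmax(9 + nz(noise_sd), 0.5)   # BIO5 - BIO1 gap, kept positive
    cold <- pmax(10 + nz(noise_sd), 0.5)  # BIO1 - BIO6 gap, kept positive
    bio5 <- bio1 + warm
    bio6 <- bio1 - cold
    bio7 <- bio5 - bio6
    ratio <- pmin(pmax(0.68 + nz(noise_sd / 10), 0.3), 0.95)
    bio2 <- bio7 * ratio
    bio3 <- 100 * bio2 / bio7
    bio4 <- pmax(60 + 0.01 * elev + 40 * moist + nz(10 * noise_sd), 1)
    bio8 <- bio1 + 1.5 + nz(noise_sd)
    bio9 <- bio1 - 1.5 + nz(noise_sd)
    bio10 <- bio1 + 2.0 + nz(noise_sd)
    bio11 <- bio1 - 2.0 + nz(noise_sd)

    pnz <- function() exp(nz(noise_sd / 5))
    bio12 <- 1200 * exp(0.8 * moist + 0.00012 * elev) * pnz()
    bio13 <- 0.16 * bio12 * pnz()
    bio14 <- 0.02 * bio12 * pnz()
    bio15 <- 45 * exp(0.5 * moist) * pnz()
    bio16 <- 0.42 * bio12 * pnz()
    bio17 <- 0.07 * bio12 * pnz()
    bio18 <- 0.30 * bio12 * pnz()
    bio19 <- 0.10 * bio12 * pnz()

    layers <- list(BIO1 = bio1, BIO2 = bio2, BIO3 = bio3, BIO4 = bio4,
                   BIO5 = bio5, BIO6 = bio6, BIO7 = bio7, BIO8 = bio8,
                   BIO9 = bio9, BIO10 = bio10, BIO11 = bio11, BIO12 = bio12,
                   BIO13 = bio13, BIO14 = bio14, BIO15 = bio15, BIO16 = bio16,
                   BIO17 = bio17, BIO18 = bio18, BIO19 = bio19)
    st <- bioclim_stack(layers, spec, mask)
    elev[!mask] <- NA_real_
    st$elevation <- elev
    st
  })
}

#' Specification of a future-climate scenario ensemble
#'
#' Describes the factorial design of future climates: time periods x RCPs,
#' each with a mean warming offset (degrees C) and a seasonality inflation
#' factor (>= 1, applied multiplicatively to `BIO4` and `BIO15`), realised by
#' `n_gcms` pseudo-GCMs that disagree through smooth spatial noise fields of
#' sd `gcm_noise_sd` added to the temperature layers.
#'
#' Default warming offsets follow ensemble-mean global warming levels for
#' mid- and late-century under RCP 2.6/4.5/6.0/8.5; defaults are stated in
#' the methods vignette.
#'
#' @param periods Integer vector of period labels.
#' @param rcps Numeric vector of RCP labels.
#' @param warming Matrix `length(periods) x length(rcps)` of mean offsets in
#'   degrees C, dimnames matching `periods`/`rcps`.
#' @param inflation Matrix of seasonality inflation factors (>= 1), same shape.
#' @param n_gcms Number of pseudo-GCMs per scenario (>= 1).
#' @param gcm_noise_sd Spatial sd of GCM disagreement, degrees C.
#' @return An object of class `future_delta_spec`.
#' @export
future_delta_spec <- function(periods = c(2050L, 2070L),
                              rcps = c(2.6, 4.5, 6.0, 8.5),
                              warming = NULL, inflation = NULL,
                              n_gcms = 10, gcm_noise_sd = 0.4) {
  dn <- list(as.character(periods), sprintf("%.1f", rcps))
  if (is.null(warming)) {
    warming <- matrix(c(1.0, 1.4, 1.3, 2.0,
                        1.0, 1.8, 2.2, 3.7),
                      nrow = 2, byrow = TRUE,
                      dimnames = list(c("2050", "2070"),
                                      c("2.6", "4.5", "6.0", "8.5")))
    warming <- warming[dn[[1]], dn[[2]], drop = FALSE]
  }
  if (is.null(inflation)) {
    inflation <- 1 + outer(ifelse(periods == 2070, 1, 0.6), rcps / 8.5) * 0.1
    dimnames(inflation) <- dn
  }
  stopifnot(all(dim(warming) == c(length(periods), length(rcps))),
            all(dim(inflation) == dim(warming)))
  if (any(inflation < 1)) stop("seasonality inflation factors must be >= 1")
  if (n_gcms < 1) stop("n_gcms must be >= 1")
  structure(list(periods = as.integer(periods), rcps = rcps,
                 warming = warming, inflation = inflation,
                 n_gcms = as.integer(n_gcms), gcm_noise_sd = gcm_noise_sd),
            class = "future_delta_spec")
}

scenario_label <- function(period, rcp) sprintf("%s_rcp%.1f", period, rcp)

scenario_key <- function(period, rcp, gcm) {
  sprintf("%s_gcm%02d", scenario_label(period, rcp), gcm)
}

# Layers that shift additively with mean warming; shifting them all by the
# same per-cell delta preserves BIO5 >= BIO1 >= BIO6.
.temp_shift_layers <- c("BIO1", "BIO5", "BIO6", "BIO8", "BIO9",
                        "BIO10", "BIO11")
.seasonality_layers <- c("BIO4", "BIO15")

#' Generate a future-climate ensemble from a current stack
#'
#' Produces one [bioclim_stack()] per scenario (period x RCP) x GCM. Each
#' pseudo-GCM perturbs the scenario's mean warming with its own smooth
#' spatial noise field (added to all additively-shifted temperature layers,
#' preserving the BIO5/BIO1/BIO6 ordering) and the scenario's seasonality
#' inflation multiplies `BIO4` and `BIO15`. The nodata mask is preserved
#' exactly.
#'
#' @param current Current-climate [bioclim_stack()].
#' @param deltas A [future_delta_spec()].
#' @param seed Integer seed (a `"gcm"` substream is derived from it).
#' @return An object of class `scenario_ensemble`: list with `stacks` (named
#'   list of stacks keyed `<period>_rcp<RCP>_gcm<NN>`) and `index`
#'   (data frame with `period`, `rcp`, `gcm_id`, `scenario`, `key`).
#' @export
generate_future_ensemble <- function(current, deltas, seed) {
  stopifnot(inherits(current, "bioclim_stack"),
            inherits(deltas, "future_delta_spec"))
  nr <- current$grid$n_rows; nc <- current$grid$n_cols
  with_seed(substream_seed(seed, "gcm"), {
    stacks <- list()
    idx <- list()
    for (pi in seq_along(deltas$periods)) for (ri in seq_along(deltas$rcps)) {
      period <- deltas$periods[pi]; rcp <- deltas$rcps[ri]
      offset <- deltas$warming[pi, ri]
      infl <- deltas$inflation[pi, ri]
      for (g in seq_len(deltas$n_gcms)) {
        delta <- offset + smooth_field(nr, nc, deltas$gcm_noise_sd)
        layers <- current$layers
        for (nm in intersect(.temp_shift_layers, names(layers)))
          layers[[nm]] <- layers[[nm]] + delta
        for (nm in intersect(.seasonality_layers, names(layers)))
          layers[[nm]] <- layers[[nm]] * infl
        key <- scenario_key(period, rcp, g)
        stacks[[key]] <- bioclim_stack(layers, current$grid, current$mask)
        idx[[key]] <- data.frame(period = period, rcp = rcp, gcm_id = g,
                                 scenario = scenario_label(period, rcp),
                                 key = key, stringsAsFactors = FALSE)
      }
    }
    structure(list(stacks = stacks, index = do.call(rbind, c(idx, list(
      make.row.names = FALSE)))), class = "scenario_ensemble")
  })
}

#' @export
print.scenario_ensemble <- function(x, ...) {
  cat(sprintf("scenario_ensemble: %d stacks (%d scenarios x %d GCMs)\n",
              length(x$stacks), length(unique(x$index$scenario)),
              max(x$index$gcm_id)))
  invisible(x)
}

#' Ground-truth niche of a virtual species
#'
#' @param species_id Species label.
#' @param mu_true Niche center, k-vector in PC units.
#' @param sigma_true k x k symmetric positive-definite niche covariance.
#' @param n_occurrences Number of occurrence records to simulate.
#' @return An object of class `true_niche`.
#' @export
true_niche <- function(species_id, mu_true, sigma_true, n_occurrences) {
  sigma_true <- as.matrix(sigma_true)
  stopifnot(length(mu_true) == nrow(sigma_true),
            nrow(sigma_true) == ncol(sigma_true), n_occurrences >= 1)
  if (max(abs(sigma_true - t(sigma_true))) > 1e-8)
    stop("sigma_true must be symmetric")
  if (min(eigen(sigma_true, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("sigma_true must be positive definite")
  structure(list(species_id = as.character(species_id),
                 mu_true = as.numeric(mu_true), sigma_true = sigma_true,
                 n_occurrences = as.integer(n_occurrences)),
            class = "true_niche")
}

#' Simulate presence-only occurrences of virtual species
#'
#' For each species, grid cells are sampled *without replacement* with
#' selection weight equal to the species' chi-square within-niche probability
#' at the cell (so the generated records already satisfy the
#' one-record-per-cell rule). Records carry the cell-center coordinates, and
#' the latent elevation where the environmental stack provides one.
#'
#' @param env A [pc_stack()] of environmental scores.
#' @param niches List of [true_niche()] objects with `mu_true` of dimension k.
#' @param seed Integer seed (a `"species"` substream is derived from it).
#' @param duplicate_n Number of extra duplicated records to append per
#'   species (a corruption option for testing the occurrence cleaner;
#'   default 0).
#' @return Data frame with columns `species`, `decimalLongitude`,
#'   `decimalLatitude`, `elevation` (NA when the stack has no latent
#'   elevation).
#' @export
generate_virtual_species <- function(env, niches, seed, duplicate_n = 0) {
  stopifnot(inherits(env, "pc_stack"))
  scores <- stack_values(env)
  k <- ncol(scores)
  cells <- as.integer(rownames(scores))
  with_seed(substream_seed(seed, "species"), {
    out <- list()
    for (ni in niches) {
      stopifnot(inherits(ni, "true_niche"))
      if (length(ni$mu_true) != k)
        stop("niche dimension does not match the environmental space")
      model <- new_niche_model(ni$mu_true, ni$sigma_true)
      w <- niche_probability(model, scores)
      if (sum(w) <= 1e-12)
        stop(sprintf(paste("species '%s': all cell selection weights are",
                           "~zero; its niche does not intersect the grid's",
                           "climate"), ni$species_id))
      n <- ni$n_occurrences
      if (n > length(cells))
        stop(sprintf("species '%s': %d occurrences requested but only %d valid cells",
                     ni$species_id, n, length(cells)))
      pick <- if (n == length(cells)) seq_along(cells)
      else sample.int(length(cells), n, prob = w)
      if (duplicate_n > 0)
        pick <- c(pick, sample(pick, duplicate_n, replace = TRUE))
      xy <- cell_centers(env$grid, cells[pick])
      elev <- if (!is.null(env$elevation)) env$elevation[cells[pick]]
      else NA_real_
      out[[ni$species_id]] <- data.frame(
        species = ni$species_id, decimalLongitude = xy[, "x"],
        decimalLatitude = xy[, "y"], elevation = elev,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

#' The default pool of ecosystem services (19 level-2 in 4 level-1 classes)
#'
#' Level-1 classes are cultural, provisioning, regulating and supporting;
#' the 19 level-2 services follow the standard use-to-service classification
#' for useful plants.
#'
#' @return Data frame with columns `es_level1`, `es_level2` (19 rows).
#' @export
default_es2_pool <- function() {
  data.frame(
    es_level1 = rep(c("cultural", "provisioning", "regulating", "supporting"),
                    times = c(3, 5, 6, 5)),
    es_level2 = c("leisure", "magic or religious", "social",
                  "food for animals", "gene sources", "food for humans",
                  "material", "medicinal",
                  "agroforestry", "biological control", "erosion regulation",
                  "pollination", "restoration", "water regulation",
                  "aesthetic values", "barriers/windbreaks/support",
                  "conservation", "nutrient cycling", "soil formation"),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic species-to-ecosystem-service catalogue
#'
#' Each species receives between `services_per_species[1]` and
#' `services_per_species[2]` distinct level-2 services, drawn with count
#' weights whose default gives a median of two services per species (the
#' typical multiplicity for useful-plant catalogues). Every level-2 service
#' carries its level-1 parent from the pool.
#'
#' @param species_ids Character vector of species labels.
#' @param es2_pool Data frame with columns `es_level1`, `es_level2`
#'   (default [default_es2_pool()]).
#' @param services_per_species Length-2 integer range (min, max).
#' @param seed Integer seed (a `"catalogue"` substream is derived from it).
#' @param count_weights Sampling weights over `min:max` service counts.
#' @return Data frame with columns `species`, `use`, `es_level1`,
#'   `es_level2`, of class `service_catalogue`.
#' @export
generate_service_catalogue <- function(species_ids,
                                       es2_pool = default_es2_pool(),
                                       services_per_species = c(1, 4),
                                       seed = 1,
                                       count_weights = c(0.3, 0.35, 0.2, 0.15)) {
  stopifnot(nrow(es2_pool) >= 1,
            all(c("es_level1", "es_level2") %in% names(es2_pool)))
  lo <- services_per_species[1]
  hi <- services_per_species[length(services_per_species)]
  if (hi > nrow(es2_pool))
    stop("services_per_species exceeds the size of the es2 pool")
  counts <- lo:hi
  w <- rep_len(count_weights, length(counts))
  with_seed(substream_seed(seed, "catalogue"), {
    rows <- lapply(species_ids, function(sp) {
      n <- if (length(counts) == 1) counts else sample(counts, 1, prob = w)
      sel <- sample.int(nrow(es2_pool), n)
      data.frame(species = sp,
                 use = paste("use of", es2_pool$es_level2[sel]),
                 es_level1 = es2_pool$es_level1[sel],
                 es_level2 = es2_pool$es_level2[sel],
                 stringsAsFactors = FALSE)
    })
    cat_df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    class(cat_df) <- c("service_catalogue", "data.frame")
    cat_df
  })
}
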