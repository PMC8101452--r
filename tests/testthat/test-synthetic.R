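test_that("current-climate generation is deterministic and seed-sensitive", {
  spec <- grid_spec(15, 15, nodata_fraction = 0.1)
  a <- generate_current_climate(spec, seed = 42)
  b <- generate_current_climate(spec, seed = 42)
  expect_identical(a, b)
  c <- generate_current_climate(spec, seed = 43)
  expect_false(identical(a$layers$BIO1, c$layers$BIO1))
})

test_that("degenerate gradients give spatially constant layers", {
  spec <- grid_spec(8, 10)
  st <- generate_current_climate(spec, seed = 1, relief = 0,
                                 moisture_sd = 0, noise_sd = 0)
  for (nm in names(st$layers)) {
    v <- st$layers[[nm]][st$mask]
    expect_equal(max(v) - min(v), 0, info = nm)
  }
})

test_that("temperature follows the configured lapse with elevation", {
  spec <- grid_spec(20, 20)
  st <- generate_current_climate(spec, seed = 5, base_temp = 24,
                                 lapse_rate = 6, noise_sd = 0)
  expect_equal(st$layers$BIO1[st$mask],
               24 - 6 * st$elevation[st$mask] / 1000, tolerance = 1e-12)
  # higher latent elevation -> strictly cooler BIO1
  e <- st$elevation[st$mask]; t1 <- st$layers$BIO1[st$mask]
  o <- order(e)
  expect_true(all(diff(t1[o]) <= 0))
})

test_that("BIO5 >= BIO1 >= BIO6 and positive precipitation hold everywhere", {
  for (seed in c(1, 9)) {
    spec <- grid_spec(12, 14, nodata_fraction = 0.2)
    st <- generate_current_climate(spec, seed = seed)
    expect_true(all(st$layers$BIO5[st$mask] >= st$layers$BIO1[st$mask]))
    expect_true(all(st$layers$BIO1[st$mask] >= st$layers$BIO6[st$mask]))
    for (nm in paste0("BIO", 12:19))
      expect_true(all(st$layers[[nm]][st$mask] > 0), info = nm)
    # nodata cells consistent across layers
    for (nm in names(st$layers))
      expect_identical(is.na(st$layers[[nm]]), !st$mask)
    # futures preserve the ordering and the mask
    fut <- generate_future_ensemble(
      st, future_delta_spec(n_gcms = 2, gcm_noise_sd = 0.6), seed = seed)
    f1 <- fut$stacks[[1]]
    expect_identical(f1$mask, st$mask)
    expect_true(all(f1$layers$BIO5[f1$mask] >= f1$layers$BIO1[f1$mask]))
    expect_true(all(f1$layers$BIO1[f1$mask] >= f1$layers$BIO6[f1$mask]))
  }
})

test_that("a nodata fraction leaving fewer than 2 valid cells is refused", {
  expect_error(generate_current_climate(grid_spec(1, 2,
                                                  nodata_fraction = 0.9),
                                        seed = 1),
               "fewer than 2 valid cells")
})

test_that("future ensembles have the factorial size and honest deltas", {
  st <- generate_current_climate(grid_spec(14, 14), seed = 3)
  deltas <- future_delta_spec(n_gcms = 10)
  fut <- generate_future_ensemble(st, deltas, seed = 3)
  expect_length(fut$stacks, 2 * 4 * 10)
  expect_equal(nrow(fut$index), 80)

  # identity deltas reproduce the current climate exactly
  ident <- future_delta_spec(
    periods = 2050L, rcps = 4.5,
    warming = matrix(0, 1, 1, dimnames = list("2050", "4.5")),
    inflation = matrix(1, 1, 1, dimnames = list("2050", "4.5")),
    n_gcms = 1, gcm_noise_sd = 0)
  fut0 <- generate_future_ensemble(st, ident, seed = 3)
  expect_equal(fut0$stacks[[1]]$layers, st$layers)

  # Monte-Carlo: GCM-averaged warming matches the configured offset
  d20 <- future_delta_spec(periods = 2050L, rcps = 8.5,
                           warming = matrix(2, 1, 1,
                                            dimnames = list("2050", "8.5")),
                           inflation = matrix(1, 1, 1,
                                              dimnames = list("2050", "8.5")),
                           n_gcms = 20, gcm_noise_sd = 0.3)
  futw <- generate_future_ensemble(st, d20, seed = 11)
  dbar <- mean(vapply(futw$stacks, function(f)
    mean(f$layers$BIO1[f$mask] - st$layers$BIO1[st$mask]), 0))
  expect_lt(abs(dbar - 2), 3 * 0.3 / sqrt(20))

  # seasonality inflation multiplies BIO4/BIO15
  infl <- future_delta_spec(periods = 2050L, rcps = 8.5,
                            warming = matrix(0, 1, 1,
                                             dimnames = list("2050", "8.5")),
                            inflation = matrix(1.1, 1, 1,
                                               dimnames = list("2050", "8.5")),
                            n_gcms = 1, gcm_noise_sd = 0)
  futi <- generate_future_ensemble(st, infl, seed = 2)
  expect_equal(futi$stacks[[1]]$layers$BIO4, st$layers$BIO4 * 1.1)
  expect_equal(futi$stacks[[1]]$layers$BIO15, st$layers$BIO15 * 1.1)
})

test_that("virtual-species sampling follows the niche-probability weights", {
  env <- make_scores_env(30, 30, k = 2, seed = 8)
  scores <- stack_values(env)
  mu <- colMeans(scores)
  sigma <- cov(scores) * 0.5
  # empty support: a niche far outside the climate cloud is refused
  far <- true_niche("far", mu + 100, diag(1e-4, 2), 10)
  expect_error(generate_virtual_species(env, list(far), seed = 1),
               "weights")
  # exhaustive sampling uses every valid cell exactly once
  nall <- true_niche("all", mu, sigma, nrow(scores))
  occ <- generate_virtual_species(env, list(nall), seed = 1)
  cells <- cell_from_xy(env$grid, occ$decimalLongitude, occ$decimalLatitude)
  expect_setequal(cells, as.integer(rownames(scores)))
  # occurrence mean approaches the exact weighted mean of the cell cloud
  n <- 500
  sp <- true_niche("sp", mu, sigma, n)
  occ <- generate_virtual_species(env, list(sp), seed = 4)
  occ_cells <- cell_from_xy(env$grid, occ$decimalLongitude,
                            occ$decimalLatitude)
  occ_scores <- scores[match(occ_cells, as.integer(rownames(scores))), ]
  w <- niche_probability(new_niche_model(mu, sigma), scores)
  w <- w / sum(w)
  m_w <- colSums(scores * w)
  sd_w <- sqrt(colSums(sweep(scores, 2, m_w)^2 * w))
  expect_true(all(abs(colMeans(occ_scores) - m_w) < 3 * sd_w / sqrt(n)))
})

test_that("single-cell draw frequencies match the exact selection weights", {
  # n = 1 without replacement is exactly weighted categorical sampling,
  # so long-run cell frequencies must pass a chi-square goodness of fit
  env <- make_scores_env(3, 3, k = 2, seed = 2)
  scores <- stack_values(env)
  mu <- colMeans(scores)
  sigma <- cov(scores)
  w <- niche_probability(new_niche_model(mu, sigma), scores)
  w <- w / sum(w)
  sp <- true_niche("sp", mu, sigma, 1)
  counts <- integer(nrow(scores))
  for (r in 1:600) {
    occ <- generate_virtual_species(env, list(sp), seed = 1000 + r)
    cell <- cell_from_xy(env$grid, occ$decimalLongitude, occ$decimalLatitude)
    i <- match(cell, as.integer(rownames(scores)))
    counts[i] <- counts[i] + 1L
  }
  expect_gt(suppressWarnings(chisq.test(counts, p = w)$p.value), 0.01)
})

test_that("service catalogues meet their counting contracts", {
  ids <- sprintf("sp%03d", 1:101)
  one <- generate_service_catalogue(ids, services_per_species = c(1, 1),
                                    seed = 1)
  expect_equal(nrow(one), 101)
  expect_equal(anyDuplicated(one$species), 0)
  expect_identical(generate_service_catalogue(ids, seed = 9),
                   generate_service_catalogue(ids, seed = 9))
  expect_error(generate_service_catalogue(ids,
                                          services_per_species = c(1, 25)),
               "pool")
  # default multiplicity: a median of two level-2 services per species
  cat_df <- read_catalogue(generate_service_catalogue(ids, seed = 2))
  expect_equal(median(catalogue_summary(cat_df)$n_es2), 2)
  # every es_level2 carries its parent from the pool
  pool <- default_es2_pool()
  expect_true(all(paste(cat_df$es_level1, cat_df$es_level2) %in%
                    paste(pool$es_level1, pool$es_level2)))
})
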