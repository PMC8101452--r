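make_env_for_cleaning <- function() {
  # 4 x 4 grid, unit resolution, one nodata cell at (row 1, col 1)
  env <- make_scores_env(4, 4, k = 2, seed = 3)
  env$mask[1, 1] <- FALSE
  for (nm in names(env$layers)) env$layers[[nm]][1, 1] <- NA
  env
}

test_that("occurrence CSVs parse faithfully and count malformed rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,decimalLongitude,decimalLatitude,elevation",
               "Espeletia sp1,1.5,2.5,3100",
               "Espeletia sp1,2.5,3.5,",
               "Espeletia sp2,0.5,0.5,2900"), path)
  occ <- read_occurrences(path)
  expect_equal(nrow(occ), 3)
  expect_equal(attr(occ, "n_malformed"), 0)
  expect_equal(occ$decimalLongitude, c(1.5, 2.5, 0.5))
  expect_true(is.na(occ$elevation[2]))

  writeLines(c("species,lon,lat", "sp1,1.5,2.5", "sp1,abc,2.5"), path)
  expect_message(occ2 <- read_occurrences(path), "malformed")
  expect_equal(nrow(occ2), 1)
  expect_equal(attr(occ2, "n_malformed"), 1)

  writeLines("species,decimalLongitude,decimalLatitude", path)
  occ3 <- read_occurrences(path)
  expect_equal(nrow(occ3), 0)
  expect_equal(attr(occ3, "n_malformed"), 0)

  writeLines(c("species,decimalLongitude", "sp1,1.5"), path)
  expect_error(read_occurrences(path), "decimalLatitude")
})

test_that("the cleaning rules remove exactly the right records, in order", {
  env <- make_env_for_cleaning()
  # 5 records: two share cell (2,2); one falls on the nodata cell; two more
  # in distinct valid cells
  occ <- data.frame(
    species = "sp1",
    decimalLongitude = c(1.2, 1.8, 0.5, 2.5, 3.5),
    decimalLatitude  = c(2.5, 2.2, 3.5, 1.5, 0.5),
    elevation = NA_real_, stringsAsFactors = FALSE)
  clean <- clean_occurrences(occ, env)
  expect_equal(nrow(clean$points$sp1), 3)
  rep <- clean$report
  expect_equal(rep$n_removed[rep$rule == "nodata_cell"], 1)
  expect_equal(rep$n_removed[rep$rule == "duplicate_cell"], 1)
  expect_equal(rep$n_removed[rep$rule == "out_of_bounds"], 0)
  # conservation: retained + removed = input
  expect_equal(nrow(clean$points$sp1) + sum(rep$n_removed), nrow(occ))
  # survivors: record 1 (first of the duplicate pair), records 4 and 5
  expect_equal(clean$points$sp1$cell,
               cell_from_xy(env$grid, c(1.2, 2.5, 3.5), c(2.5, 1.5, 0.5)))
})

test_that("cleaning an already-clean set is a no-op", {
  env <- make_env_for_cleaning()
  occ <- data.frame(species = "sp1",
                    decimalLongitude = c(0.5, 1.5, 2.5),
                    decimalLatitude = c(0.5, 1.5, 2.5),
                    elevation = NA_real_)
  c1 <- clean_occurrences(occ, env)
  expect_equal(nrow(c1$points$sp1), 3)
  # rebuild records from the retained cell centers and clean again
  xy <- cell_centers(env$grid, c1$points$sp1$cell)
  occ2 <- data.frame(species = "sp1", decimalLongitude = xy[, "x"],
                     decimalLatitude = xy[, "y"], elevation = NA_real_)
  c2 <- clean_occurrences(occ2, env)
  expect_equal(c2$points$sp1, c1$points$sp1)
  expect_true(all(c2$report$n_removed == 0))
})

test_that("bounds filtering and empty input behave", {
  env <- make_env_for_cleaning()
  occ <- data.frame(species = "sp1",
                    decimalLongitude = c(0.5, 10), decimalLatitude = c(0.5, 10),
                    elevation = NA_real_)
  clean <- clean_occurrences(occ, env, bounds = c(0, 4, 0, 4))
  expect_equal(clean$report$n_removed[clean$report$rule == "out_of_bounds"], 1)
  empty <- clean_occurrences(occ[0, ], env)
  expect_length(empty$points, 0)
  expect_equal(sum(empty$report$n_removed), 0)
})

test_that("the elevation cross-check flags, and optionally drops, mismatches", {
  env <- make_env_for_cleaning()
  dem <- matrix(3000, 4, 4)
  occ <- data.frame(species = "sp1",
                    decimalLongitude = c(0.5, 1.5, 2.5),
                    decimalLatitude = c(0.5, 1.5, 2.5),
                    elevation = c(2900, 1200, NA))  # 2nd off by 1800 m
  flagged <- clean_occurrences(occ, env, dem = dem, max_elev_diff = 500)
  expect_equal(nrow(flagged$points$sp1), 3)   # flag-only by default
  expect_length(flagged$flagged, 1)
  dropped <- clean_occurrences(occ, env, dem = dem, max_elev_diff = 500,
                               drop_on_elev_flag = TRUE)
  expect_equal(nrow(dropped$points$sp1), 2)   # record without label kept
  rep <- dropped$report
  expect_equal(rep$n_removed[rep$rule == "elevation_mismatch"], 1)
})

test_that("the minimum-record criterion excludes species at the threshold", {
  env <- make_scores_env(10, 10, k = 2, seed = 1)
  xy19 <- cell_centers(env$grid, 1:19)
  xy25 <- cell_centers(env$grid, 21:45)
  occ <- rbind(
    data.frame(species = "rare", decimalLongitude = xy19[, "x"],
               decimalLatitude = xy19[, "y"], elevation = NA_real_),
    data.frame(species = "common", decimalLongitude = xy25[, "x"],
               decimalLatitude = xy25[, "y"], elevation = NA_real_))
  clean <- clean_occurrences(occ, env)
  kept <- apply_min_records(clean, min_n = 20)
  expect_named(kept$points, "common")
  excl <- attr(kept, "excluded")
  expect_equal(excl$species, "rare")
  expect_equal(excl$n_cells, 19)
  all_kept <- apply_min_records(clean, min_n = 0)
  expect_length(all_kept$points, 2)
})

test_that("grid edge conventions assign outer-edge points to interior cells", {
  g <- grid_spec(4, 4)
  expect_equal(cell_from_xy(g, 0, 4), 1L)          # top-left origin corner
  expect_equal(cell_from_xy(g, 4, 0), 16L)         # outer right/bottom edge
  expect_equal(cell_from_xy(g, 1, 3), cell_from_xy(g, 1.5, 2.5))
  expect_true(is.na(cell_from_xy(g, -0.1, 2)))
  expect_true(is.na(cell_from_xy(g, 4.1, 2)))
})
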