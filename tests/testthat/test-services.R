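# Small hand-built area tables: areas in km^2 with pct already as % of a
# 100-km^2 study area, so expected deltas are easy to enumerate.
make_area_table <- function(species, B, cur_pct, fut_pct, scenarios) {
  rows <- list()
  for (si in seq_along(species)) for (b in seq_len(B)) {
    rows[[length(rows) + 1]] <- data.frame(
      species = species[si], bootstrap_id = b, scenario = "current",
      period = NA_integer_, rcp = NA_real_, gcm_id = NA_integer_,
      area = cur_pct[si], pct = cur_pct[si])
    for (s in seq_len(nrow(scenarios)))
      rows[[length(rows) + 1]] <- data.frame(
        species = species[si], bootstrap_id = b,
        scenario = scenarios$scenario[s], period = scenarios$period[s],
        rcp = scenarios$rcp[s], gcm_id = 1L,
        area = fut_pct[si], pct = fut_pct[si])
  }
  out <- do.call(rbind, rows)
  class(out) <- c("area_sample", "data.frame")
  out
}

scen1 <- data.frame(period = 2050L, rcp = 2.6, scenario = "2050_rcp2.6")

test_that("catalogue reading normalises, collapses and validates", {
  d <- data.frame(
    species = c("sp1", "sp1", "sp1", "sp2"),
    use = c("firewood", "fuel", "medicine", "ornament"),
    es_level1 = c("Provisioning", "provisioning", "provisioning", "cultural"),
    es_level2 = c("Material", " material", "medicinal", "aesthetic values"))
  cat_df <- read_catalogue(d)
  expect_equal(nrow(cat_df), 3)            # duplicate (sp1, material) collapsed
  expect_equal(attr(cat_df, "n_collapsed"), 1)
  expect_true(all(cat_df$es_level2 == tolower(cat_df$es_level2)))
  # conflicting level-1 parents are refused by name
  bad <- data.frame(species = c("a", "b"), es_level1 = c("cultural",
                                                         "supporting"),
                    es_level2 = c("leisure", "leisure"))
  expect_error(read_catalogue(bad), "leisure")
  # empty catalogue is valid
  expect_equal(nrow(read_catalogue(d[0, ])), 0)
  # per-species service counts surface maxima
  wide <- data.frame(species = "sp9", es_level1 = "provisioning",
                     es_level2 = paste0("svc", 1:11))
  expect_equal(max(catalogue_summary(read_catalogue(wide))$n_es2), 11)
  expect_error(read_catalogue(data.frame(species = "a")), "es_level1")
})

test_that("area percentages scale areas by the study area", {
  tab <- make_area_table("sp1", 2, 10, 8, scen1)
  tab$area <- c(5766.5, 0)[c(1, 2, 1, 2)]
  out <- area_percentages(tab, study_area = 57665)
  expect_equal(out$pct, c(10, 0, 10, 0))
  expect_error(area_percentages(tab, 0))
})

test_that("pooled change distributions enumerate the paired deltas", {
  cat_df <- read_catalogue(data.frame(
    species = c("sp1", "sp2", "sp1"),
    es_level1 = c("provisioning", "provisioning", "cultural"),
    es_level2 = c("medicinal", "medicinal", "leisure")))
  # constant case: 20% -> 15% gives -5 pp everywhere
  tab <- make_area_table(c("sp1", "sp2"), 3, c(20, 30), c(15, 26), scen1)
  dists <- change_distributions(tab, cat_df, level = 2)
  med <- dists[[which(vapply(dists, `[[`, "", "es_name") == "medicinal")]]
  expect_length(med$values, 6)             # 2 species x 3 bootstraps
  expect_equal(sort(unique(med$values)), c(-5, -4))
  expect_equal(med$n_memberships, 2)
  lei <- dists[[which(vapply(dists, `[[`, "", "es_name") == "leisure")]]
  expect_equal(lei$values, rep(-5, 3))     # singleton service = own deltas
  # level-1 pool equals the multiset union of its level-2 children
  d1 <- change_distributions(tab, cat_df, level = 1)
  prov <- d1[[which(vapply(d1, `[[`, "", "es_name") == "provisioning")]]
  expect_equal(sort(prov$values), sort(med$values))
  cult <- d1[[which(vapply(d1, `[[`, "", "es_name") == "cultural")]]
  expect_equal(sort(cult$values), sort(lei$values))
  # bound: deltas lie in [-pct_current, 100 - pct_current]
  for (d in dists)
    expect_true(all(d$values >= -30 & d$values <= 100 - 20))
})

test_that("ragged or uncatalogued species are handled loudly", {
  cat_df <- read_catalogue(data.frame(
    species = "sp1", es_level1 = "provisioning", es_level2 = "medicinal"))
  tab <- make_area_table(c("sp1", "sp2"), 2, c(20, 10), c(15, 8), scen1)
  expect_warning(d <- change_distributions(tab, cat_df), "sp2")
  expect_equal(attr(d, "skipped_species"), "sp2")
  # a species missing one scenario refuses (ragged pooling)
  tab2 <- make_area_table("sp1", 2, 20, 15, scen1)
  tab2 <- tab2[-nrow(tab2), ]
  class(tab2) <- c("area_sample", "data.frame")
  expect_error(change_distributions(tab2, cat_df), "lacks scenario")
})

test_that("summaries and long tables conserve the pooled values", {
  cat_df <- read_catalogue(data.frame(
    species = c("sp1", "sp2"), es_level1 = "provisioning",
    es_level2 = "medicinal"))
  tab <- make_area_table(c("sp1", "sp2"), 4, c(20, 30), c(18, 25), scen1)
  dists <- change_distributions(tab, cat_df, level = 2)
  long <- pooled_changes_table(dists)
  expect_equal(nrow(long), sum(vapply(dists, function(d)
    length(d$values), 0L)))
  s <- change_summary(dists)
  expect_equal(s$n_values, 8)              # memberships x B
  expect_equal(s$q50, median(c(rep(-2, 4), rep(-5, 4))))
})
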