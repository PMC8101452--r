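## End-to-end orchestration: one declarative config drives
## climate_space -> occurrences -> niche_model -> projection -> services,
## with every source of randomness derived from a single root seed, and
## beanplot-style summaries of the pooled change distributions.

#' Pipeline configuration
#'
#' Collects paths, parameters and flags for [run_pipeline()]. Two input
#' modes: `simulate` (a fully synthetic study system, the default) or
#' `inputs` (paths to a current-climate stack directory, a directory of
#' future stack directories, an occurrence CSV and a catalogue CSV, as
#' written by [write_stack()] and plain CSV).
#'
#' @param seed Root integer seed; all stage substreams derive from it.
#' @param out_dir Output directory (`NULL` = return results only).
#' @param simulate Named list of synthetic-study settings (grid size,
#'   nodata fraction, number of species, occurrence-count range, GCM count
#'   and noise, periods/RCPs); see defaults in the function body.
#' @param inputs Named list of paths (`climate_dir`, `future_dir`,
#'   `occurrences`, `catalogue`) for file-based runs; `NULL` for simulation.
#' @param k Retained principal components (default 3).
#' @param log_vars Rainfall variables to log-transform.
#' @param min_n Minimum records per species (default 20).
#' @param B Bootstrap resamples per species (default 1000).
#' @param p_levels Probability contours reported for core-climate ellipsoids.
#' @param max_elev_diff Elevation cross-check tolerance, m.
#' @param drop_on_elev_flag Drop (not just flag) elevation mismatches.
#' @param bounds Optional coordinate bounds `c(xmin, xmax, ymin, ymax)`.
#' @param export_maps Write per-species mean probability surfaces.
#' @param render_figures Render the bean figure (default `TRUE` when
#'   `out_dir` is set).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = NULL,
                            simulate = list(), inputs = NULL,
                            k = 3, log_vars = default_log_vars(),
                            min_n = 20, B = 1000,
                            p_levels = c(0.1, 0.5, 0.75, 0.9),
                            max_elev_diff = 500, drop_on_elev_flag = FALSE,
                            bounds = NULL, export_maps = FALSE,
                            render_figures = !is.null(out_dir)) {
  stopifnot(B >= 1, k >= 1, k <= 19, min_n >= 0)
  if (is.null(inputs)) {
    sim_defaults <- list(n_rows = 60, n_cols = 60, cell_area = 1,
                         nodata_fraction = 0.05, n_species = 12,
                         occ_range = c(60, 400), n_gcms = 10,
                         gcm_noise_sd = 0.4, relief = 2500,
                         moisture_sd = 0.25, noise_sd = 0.15,
                         periods = c(2050L, 2070L),
                         rcps = c(2.6, 4.5, 6.0, 8.5),
                         services_per_species = c(1, 4))
    simulate <- utils::modifyList(sim_defaults, simulate)
  } else {
    need <- c("climate_dir", "future_dir", "occurrences", "catalogue")
    miss <- setdiff(need, names(inputs))
    if (length(miss) > 0) stop("inputs missing: ", paste(miss, collapse = ", "))
    for (p in unlist(inputs[need])) if (!file.exists(p))
      stop("input path does not exist: ", p)
    simulate <- NULL
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 simulate = simulate, inputs = inputs, k = k,
                 log_vars = log_vars, min_n = min_n, B = as.integer(B),
                 p_levels = p_levels, max_elev_diff = max_elev_diff,
                 drop_on_elev_flag = drop_on_elev_flag, bounds = bounds,
                 export_maps = export_maps,
                 render_figures = render_figures),
            class = "pipeline_config")
}

# Draw ground-truth niches for the simulated species from the environmental
# cloud: centers at sampled cell scores, covariances random SPD scaled to a
# fraction of the cloud spread.
simulate_true_niches <- function(env, n_species, occ_range, seed) {
  scores <- stack_values(env)
  k <- ncol(scores)
  sds <- apply(scores, 2, stats::sd)
  with_seed(substream_seed(seed, "niche-truth"), {
    lapply(seq_len(n_species), function(i) {
      mu <- scores[sample.int(nrow(scores), 1), ] +
        stats::rnorm(k, 0, 0.2 * sds)
      a <- matrix(stats::rnorm(k * k, 0, 1), k, k)
      base <- a %*% t(a) / k
      scl <- diag(stats::runif(k, 0.25, 0.6) * sds, k)
      sigma <- scl %*% (base + diag(0.3, k)) %*% scl
      n <- sample(seq(occ_range[1], occ_range[2]), 1)
      true_niche(sprintf("species_%02d", i), mu, sigma, n)
    })
  })
}

#' Run the full climate-niche / ecosystem-service pipeline
#'
#' Executes, in order: environmental-space fitting on the current climate,
#' projection of all stacks into that space, occurrence cleaning and the
#' minimum-record filter, per-species bootstrap niche ensembles, the
#' bootstrap x scenario area table (with random GCM draws), and pooling of
#' percentage-point changes by ecosystem service at levels 1 and 2. When
#' `out_dir` is set, writes all tables as CSV, the transform as JSON, a run
#' log and a `manifest.json`; reruns with the same config and seed reproduce
#' every CSV bit-identically.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the fitted `transform`, `current_env`,
#'   `clean`, `ensembles`, `areas`, `distributions_l1`, `distributions_l2`,
#'   `summary_l1`, `summary_l2`, `catalogue`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
    message(sprintf(...))
  }
  seed <- config$seed

  if (!is.null(config$simulate)) {
    s <- config$simulate
    say("stage climate: simulating %dx%d grid (%d GCMs)",
        s$n_rows, s$n_cols, s$n_gcms)
    gspec <- grid_spec(s$n_rows, s$n_cols, cell_area = s$cell_area,
                       nodata_fraction = s$nodata_fraction)
    current <- generate_current_climate(gspec, seed, relief = s$relief,
                                        moisture_sd = s$moisture_sd,
                                        noise_sd = s$noise_sd)
    deltas <- future_delta_spec(periods = s$periods, rcps = s$rcps,
                                n_gcms = s$n_gcms,
                                gcm_noise_sd = s$gcm_noise_sd)
    futures <- generate_future_ensemble(current, deltas, seed)
  } else {
    say("stage climate: reading stacks from %s", config$inputs$climate_dir)
    current <- read_stack(config$inputs$climate_dir)
    dirs <- list.dirs(config$inputs$future_dir, recursive = FALSE)
    stacks <- lapply(dirs, read_stack)
    names(stacks) <- basename(dirs)
    m <- regmatches(names(stacks),
                    regexec("^(\\d+)_rcp([0-9.]+)_gcm(\\d+)$", names(stacks)))
    if (any(lengths(m) != 4))
      stop("future stack directories must be named <period>_rcp<RCP>_gcm<NN>")
    index <- do.call(rbind, lapply(seq_along(m), function(i) data.frame(
      period = as.integer(m[[i]][2]), rcp = as.numeric(m[[i]][3]),
      gcm_id = as.integer(m[[i]][4]),
      scenario = scenario_label(as.integer(m[[i]][2]),
                                as.numeric(m[[i]][3])),
      key = names(stacks)[i], stringsAsFactors = FALSE)))
    futures <- structure(list(stacks = stacks, index = index),
                         class = "scenario_ensemble")
  }

  say("stage climate_space: fitting transform (k = %d)", config$k)
  transform <- fit_climate_transform(current, config$log_vars, config$k)
  say("  retained %d PCs explaining %.1f%% of variance over %d cells",
      config$k, 100 * variance_explained(transform), transform$n_cells)
  current_env <- to_env_space(current, transform)
  future_envs <- future_env_spaces(futures, transform)

  if (!is.null(config$simulate)) {
    niches <- simulate_true_niches(current_env, config$simulate$n_species,
                                   config$simulate$occ_range, seed)
    occ <- generate_virtual_species(current_env, niches, seed)
    catalogue <- read_catalogue(generate_service_catalogue(
      vapply(niches, `[[`, "", "species_id"),
      services_per_species = config$simulate$services_per_species,
      seed = seed))
  } else {
    occ <- read_occurrences(config$inputs$occurrences)
    catalogue <- read_catalogue(config$inputs$catalogue)
    niches <- NULL
  }

  say("stage occurrences: cleaning %d records of %d species",
      nrow(occ), length(unique(occ$species)))
  clean <- clean_occurrences(occ, current_env, bounds = config$bounds,
                             max_elev_diff = config$max_elev_diff,
                             drop_on_elev_flag = config$drop_on_elev_flag)
  clean <- apply_min_records(clean, config$min_n)
  excl <- attr(clean, "excluded")
  say("  %d species retained, %d excluded below %d records",
      length(clean$points), nrow(excl), config$min_n)

  say("stage niche_model + projection: B = %d bootstraps per species",
      config$B)
  ensembles <- list()
  area_list <- list()
  for (sp in names(clean$points)) {
    pts <- occurrence_scores(clean, sp)
    ens <- bootstrap_niches(pts, B = config$B, seed = seed, species_id = sp)
    ensembles[[sp]] <- ens
    area_list[[sp]] <- scenario_area_table(ens, current_env, future_envs,
                                           seed = seed)
    say("  %s: n = %d cells, median current area %.1f%% of study area",
        sp, nrow(pts), stats::median(
          area_list[[sp]]$pct[area_list[[sp]]$scenario == "current"]))
  }
  areas <- do.call(rbind, c(area_list, list(make.row.names = FALSE)))
  class(areas) <- c("area_sample", "data.frame")
  gcm_draws <- do.call(rbind, lapply(area_list, attr, "gcm_draws"))
  rownames(gcm_draws) <- NULL

  say("stage services: pooling changes across %d species",
      length(clean$points))
  dist2 <- change_distributions(areas, catalogue, level = 2)
  dist1 <- change_distributions(areas, catalogue, level = 1)
  sum2 <- change_summary(dist2)
  sum1 <- change_summary(dist1)

  manifest <- list(
    package = "nichecast",
    version = as.character(utils::packageVersion("nichecast")),
    seed = seed,
    mode = if (is.null(config$simulate)) "files" else "simulate",
    parameters = list(k = config$k, B = config$B, min_n = config$min_n,
                      log_vars = config$log_vars,
                      max_elev_diff = config$max_elev_diff),
    n_cells = n_valid_cells(current_env),
    study_area_km2 = study_area_km2(current_env),
    variance_explained = variance_explained(transform),
    n_species_modelled = length(clean$points),
    n_area_rows = nrow(areas),
    complete = TRUE)
  if (!is.null(config$inputs))
    manifest$input_md5 <- lapply(config$inputs, function(p)
      if (file.exists(p) && !dir.exists(p))
        unname(tools::md5sum(p)) else NA_character_)

  result <- list(transform = transform, current_env = current_env,
                 futures_index = future_envs$index, clean = clean,
                 ensembles = ensembles, areas = areas,
                 gcm_draws = gcm_draws,
                 distributions_l1 = dist1, distributions_l2 = dist2,
                 summary_l1 = sum1, summary_l2 = sum2,
                 catalogue = catalogue, true_niches = niches,
                 manifest = manifest, log = log_lines)

  if (!is.null(config$out_dir)) {
    out <- config$out_dir
    tdir <- file.path(out, "tables")
    dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(d, nm) utils::write.csv(
      d, file.path(tdir, nm), row.names = FALSE)
    wcsv(as.data.frame(areas), "area_samples.csv")
    wcsv(gcm_draws, "gcm_draws.csv")
    wcsv(clean$report, "cleaning_report.csv")
    wcsv(excl, "excluded_species.csv")
    wcsv(as.data.frame(catalogue), "catalogue.csv")
    wcsv(pooled_changes_table(dist2), "pooled_changes_es2.csv")
    wcsv(pooled_changes_table(dist1), "pooled_changes_es1.csv")
    wcsv(sum2, "change_summary_es2.csv")
    wcsv(sum1, "change_summary_es1.csv")
    wcsv(do.call(rbind, c(lapply(ensembles, ensemble_to_table),
                          list(make.row.names = FALSE))),
         "niche_ensembles.csv")
    write_transform(transform, file.path(out, "transform.json"))
    if (config$export_maps) {
      mdir <- file.path(out, "maps")
      for (sp in names(ensembles)) {
        mp <- mean_niche_map(ensembles[[sp]], current_env)
        dir.create(file.path(mdir, sp), recursive = TRUE,
                   showWarnings = FALSE)
        utils::write.table(mp$prob, file.path(mdir, sp, "mean_current.csv"),
                           sep = ",", row.names = FALSE, col.names = FALSE)
      }
    }
    if (config$render_figures) {
      fdir <- file.path(out, "figures")
      dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
      render_change_beans(dist2, file.path(fdir, "change_beans_es2"))
      render_change_beans(dist1, file.path(fdir, "change_beans_es1"))
    }
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out, "run.log"))
  }
  invisible(result)
}

#' Render beanplot-style change summaries
#'
#' One panel per ecosystem service; per scenario (ordered period then RCP) a
#' mirrored-density bean of the pooled percentage-point changes with a strip
#' of raw values, a median bar, and a zero-change reference line. A
#' degenerate (constant) distribution collapses to its median bar. The exact
#' plotted values are exported as CSV so the figure is auditable.
#'
#' @param distributions List from [change_distributions()].
#' @param out_path Optional path stem: writes `<out_path>.pdf` and
#'   `<out_path>_data.csv`.
#' @param max_strip_points Strip points drawn per bean (deterministically
#'   thinned when a bean has more values; the CSV always holds all values).
#' @return List with `plot` (a ggplot) and `data` (the plotted-value table),
#'   invisibly.
#' @export
render_change_beans <- function(distributions, out_path = NULL,
                                max_strip_points = 200) {
  if (length(distributions) == 0) stop("no distributions to plot")
  for (d in distributions)
    if (length(d$values) == 0)
      stop(sprintf("empty change distribution for service '%s', scenario '%s'",
                   d$es_name, d$scenario))
  meta <- unique(data.frame(
    scenario = vapply(distributions, `[[`, "", "scenario"),
    period = vapply(distributions, function(d) as.integer(d$period), 0L),
    rcp = vapply(distributions, function(d) as.numeric(d$rcp), 0)))
  meta <- meta[order(meta$period, meta$rcp), ]
  scen <- meta$scenario
  polys <- list(); meds <- list(); strips <- list()
  for (d in distributions) {
    x0 <- match(d$scenario, scen)
    v <- d$values
    if (length(unique(v)) >= 2) {
      dd <- stats::density(v)
      w <- 0.42 * dd$y / max(dd$y)
      polys[[length(polys) + 1]] <- data.frame(
        es_name = d$es_name, scenario = d$scenario,
        x = c(x0 - w, rev(x0 + w)), y = c(dd$x, rev(dd$x)),
        id = paste(d$es_name, d$scenario))
    }
    meds[[length(meds) + 1]] <- data.frame(
      es_name = d$es_name, x0 = x0 - 0.45, x1 = x0 + 0.45,
      med = stats::median(v))
    vs <- if (length(v) > max_strip_points)
      v[round(seq(1, length(v), length.out = max_strip_points))] else v
    strips[[length(strips) + 1]] <- data.frame(
      es_name = d$es_name, x = x0, y = vs)
  }
  poly_df <- do.call(rbind, polys)
  med_df <- do.call(rbind, meds)
  strip_df <- do.call(rbind, strips)
  p <- ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    (if (!is.null(poly_df))
      ggplot2::geom_polygon(data = poly_df,
                            ggplot2::aes(x = x, y = y, group = id),
                            fill = "#3B7A57", alpha = 0.6)) +
    ggplot2::geom_point(data = strip_df, ggplot2::aes(x = x, y = y),
                        size = 0.2, alpha = 0.25, colour = "grey20") +
    ggplot2::geom_segment(data = med_df,
                          ggplot2::aes(x = x0, xend = x1,
                                       y = med, yend = med),
                          linewidth = 0.5, colour = "black") +
    ggplot2::scale_x_continuous(breaks = seq_along(scen), labels = scen) +
    ggplot2::facet_wrap(~es_name) +
    ggplot2::labs(x = NULL, y = "potential-niche area change (pp)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
  data <- pooled_changes_table(distributions)
  if (!is.null(out_path)) {
    grDevices::pdf(paste0(out_path, ".pdf"), width = 11, height = 8)
    print(p)
    grDevices::dev.off()
    utils::write.csv(data, paste0(out_path, "_data.csv"), row.names = FALSE)
  }
  invisible(list(plot = p, data = data))
}
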