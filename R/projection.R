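## Geographic projection of fundamental niches: per-cell within-niche
## probability surfaces (the potential niche = the fundamental niche
## intersected with the environments actually present), their areas
## (sum of probabilities x cell area), and the bootstrap x scenario area
## table with one random GCM draw per future scenario per bootstrap.

#' Map a fundamental niche onto a geographic grid
#'
#' The potential-niche surface: each valid cell receives the chi-square
#' within-niche probability of its climate; nodata propagates.
#'
#' @param model A `niche_model`.
#' @param env A [pc_stack()] whose dimension equals the model's `df`.
#' @return An object of class `niche_map`: list with `prob` (matrix in
#'   [0, 1], NA at nodata), `mask`, `grid`, `provenance`.
#' @export
project_niche <- function(model, env) {
  stopifnot(inherits(model, "niche_model"), inherits(env, "pc_stack"))
  if (length(env$layers) != model$df)
    stop("environmental-space dimension does not match the model")
  scores <- stack_values(env)
  p <- niche_probability(model, scores)
  prob <- matrix(NA_real_, env$grid$n_rows, env$grid$n_cols)
  prob[env$mask] <- p
  structure(list(prob = prob, mask = env$mask, grid = env$grid,
                 provenance = list(bootstrap_id = model$bootstrap_id)),
            class = "niche_map")
}

#' Potential-niche area of a probability surface
#'
#' Area is the sum of the per-cell probabilities over valid cells times the
#' cell area — a probability-weighted area, bounded by the total valid area.
#'
#' @param map A `niche_map`.
#' @param cell_area Cell area in km^2 (default taken from the map's grid).
#' @return Area in km^2.
#' @export
niche_area <- function(map, cell_area = map$grid$cell_area) {
  sum(map$prob[map$mask]) * cell_area
}

#' A set of future environmental-space stacks keyed by scenario and GCM
#'
#' @param stacks Named list of [pc_stack()]s keyed `<period>_rcp<RCP>_gcm<NN>`.
#' @param index Data frame with columns `period`, `rcp`, `gcm_id`,
#'   `scenario`, `key` matching `stacks` names.
#' @return An object of class `scenario_envs`.
#' @export
scenario_envs <- function(stacks, index) {
  stopifnot(all(index$key %in% names(stacks)))
  structure(list(stacks = stacks, index = index), class = "scenario_envs")
}

#' Project a future ensemble into environmental space
#'
#' Transforms every member stack of a [generate_future_ensemble()] result
#' with the *current-climate* transform.
#'
#' @param ensemble A `scenario_ensemble` of bioclim stacks.
#' @param transform A `climate_transform`.
#' @return A [scenario_envs()] of [pc_stack()]s.
#' @export
future_env_spaces <- function(ensemble, transform) {
  stopifnot(inherits(ensemble, "scenario_ensemble"))
  stacks <- lapply(ensemble$stacks, to_env_space, transform = transform)
  scenario_envs(stacks, ensemble$index)
}

#' Bootstrap x scenario potential-niche area table
#'
#' For each bootstrap niche model: the current-climate area is computed, and
#' for each future scenario (period x RCP) one GCM is drawn uniformly at
#' random and the area computed on that GCM's climate — a paired design in
#' which the same bootstrap model yields its own current and future areas, so
#' per-bootstrap change distributions are meaningful. GCM draws are
#' independent per (species, bootstrap, scenario) and logged.
#'
#' @param ensemble A `bootstrap_ensemble`.
#' @param current_env Current-climate [pc_stack()].
#' @param future_envs A [scenario_envs()] sharing grid and dimension.
#' @param seed Integer seed for the GCM draws (a `"scenario/<species>"`
#'   substream is derived from it).
#' @return Data frame of class `area_sample`: columns `species`,
#'   `bootstrap_id`, `scenario` (`"current"` or `<period>_rcp<RCP>`),
#'   `period`, `rcp`, `gcm_id` (NA for current), `area` (km^2), `pct`
#'   (% of the valid study area). The GCM-draw log is attached as
#'   `attr(, "gcm_draws")`.
#' @export
scenario_area_table <- function(ensemble, current_env, future_envs, seed = 1) {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"),
            inherits(current_env, "pc_stack"),
            inherits(future_envs, "scenario_envs"))
  idx <- future_envs$index
  scenarios <- unique(idx[, c("period", "rcp", "scenario")])
  if (nrow(scenarios) == 0) stop("future_envs contains no scenarios")
  for (s in scenarios$scenario)
    if (sum(idx$scenario == s) < 1) stop("scenario without GCM stacks: ", s)
  for (st in future_envs$stacks) stopifnot_same_grid(current_env, st)

  cell_area <- current_env$grid$cell_area
  total <- study_area_km2(current_env)
  cur_scores <- stack_values(current_env)
  fut_scores <- lapply(future_envs$stacks, stack_values)
  B <- ensemble$B
  area_of <- function(model, scores) {
    sum(niche_probability(model, scores)) * cell_area
  }
  with_seed(substream_seed(seed, paste0("scenario/", ensemble$species_id)), {
    # pre-draw GCMs: one uniform draw per (bootstrap, scenario)
    draws <- matrix(NA_integer_, B, nrow(scenarios))
    for (j in seq_len(nrow(scenarios))) {
      pool <- idx$gcm_id[idx$scenario == scenarios$scenario[j]]
      draws[, j] <- pool[sample.int(length(pool), B, replace = TRUE)]
    }
    rows <- vector("list", B * (1 + nrow(scenarios)))
    ri <- 0L
    for (b in seq_len(B)) {
      m <- ensemble$models[[b]]
      a <- area_of(m, cur_scores)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        species = ensemble$species_id, bootstrap_id = m$bootstrap_id,
        scenario = "current", period = NA_integer_, rcp = NA_real_,
        gcm_id = NA_integer_, area = a, pct = 100 * a / total,
        stringsAsFactors = FALSE)
      for (j in seq_len(nrow(scenarios))) {
        g <- draws[b, j]
        key <- scenario_key(scenarios$period[j], scenarios$rcp[j], g)
        a <- area_of(m, fut_scores[[key]])
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          species = ensemble$species_id, bootstrap_id = m$bootstrap_id,
          scenario = scenarios$scenario[j], period = scenarios$period[j],
          rcp = scenarios$rcp[j], gcm_id = g, area = a,
          pct = 100 * a / total, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    class(out) <- c("area_sample", "data.frame")
    log_df <- data.frame(
      species = ensemble$species_id,
      bootstrap_id = rep(seq_len(B), each = nrow(scenarios)),
      scenario = rep(scenarios$scenario, B),
      gcm_id = as.integer(t(draws)), stringsAsFactors = FALSE)
    attr(out, "gcm_draws") <- log_df
    attr(out, "study_area_km2") <- total
    out
  })
}

#' Mean potential-niche probability surface across bootstraps
#'
#' Optional figure-level export: the per-cell mean of the bootstrap
#' probability surfaces for one environmental stack.
#'
#' @param ensemble A `bootstrap_ensemble`.
#' @param env A [pc_stack()].
#' @return A `niche_map` whose `prob` is the bootstrap mean.
#' @export
mean_niche_map <- function(ensemble, env) {
  scores <- stack_values(env)
  acc <- numeric(nrow(scores))
  for (m in ensemble$models) acc <- acc + niche_probability(m, scores)
  prob <- matrix(NA_real_, env$grid$n_rows, env$grid$n_cols)
  prob[env$mask] <- acc / length(ensemble$models)
  structure(list(prob = prob, mask = env$mask, grid = env$grid,
                 provenance = list(bootstrap_id = "mean",
                                   species = ensemble$species_id)),
            class = "niche_map")
}
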