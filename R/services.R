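## Ecosystem-service aggregation: map species to level-1/level-2 services
## and pool bootstrap percentage-point area changes into per-service change
## distributions. Pooling weighs species by membership: a species contributes
## its B bootstrap changes once per service it provides, so a level-1 pool's
## n is the count of species-service memberships, not of distinct species.

normalize_label <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Read a species-to-ecosystem-service catalogue from CSV
#'
#' Expects columns `species`, `use` (optional), `es_level1`, `es_level2`.
#' Labels are normalised (case, whitespace); duplicate `(species, es_level2)`
#' pairs are collapsed with a count report; a level-2 service mapped to two
#' different level-1 parents is an error.
#'
#' @param path CSV file path, or a data frame with the same columns.
#' @return Data frame of class `service_catalogue` with normalised columns
#'   `species`, `use`, `es_level1`, `es_level2`; attributes `n_collapsed`
#'   and `summary` (per-species ES2 counts).
#' @export
read_catalogue <- function(path) {
  d <- if (is.data.frame(path)) path
  else utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("species", "es_level1", "es_level2")
  miss <- setdiff(req, names(d))
  if (length(miss) > 0)
    stop("catalogue is missing column(s): ", paste(miss, collapse = ", "))
  if (!"use" %in% names(d)) d$use <- NA_character_
  d$species <- trimws(d$species)
  d$es_level1 <- normalize_label(d$es_level1)
  d$es_level2 <- normalize_label(d$es_level2)
  # one parent per level-2 service
  par <- unique(d[, c("es_level1", "es_level2")])
  bad <- par$es_level2[duplicated(par$es_level2)]
  if (length(bad) > 0)
    stop("es_level2 mapped to multiple es_level1 parents: ",
         paste(unique(bad), collapse = ", "))
  dup <- duplicated(d[, c("species", "es_level2")])
  out <- d[!dup, c("species", "use", "es_level1", "es_level2")]
  rownames(out) <- NULL
  class(out) <- c("service_catalogue", "data.frame")
  attr(out, "n_collapsed") <- sum(dup)
  attr(out, "summary") <- catalogue_summary(out)
  out
}

#' Per-species service counts of a catalogue
#' @param catalogue A `service_catalogue`.
#' @return Data frame `species`, `n_es2`; useful for the median/maximum
#'   services-per-species summaries.
#' @export
catalogue_summary <- function(catalogue) {
  tab <- table(catalogue$species)
  data.frame(species = names(tab), n_es2 = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Convert potential-niche areas to percentages of the study area
#'
#' @param areas An `area_sample` table.
#' @param study_area Total study area in km^2 (> 0).
#' @return The table with `pct = 100 * area / study_area`.
#' @export
area_percentages <- function(areas, study_area) {
  stopifnot(study_area > 0)
  areas$pct <- 100 * areas$area / study_area
  areas
}

#' Pool bootstrap area changes by ecosystem service
#'
#' For species s, bootstrap i and future scenario sigma the change is
#' `delta(s, i, sigma) = pct_future(s, i, sigma) - pct_current(s, i)` in
#' percentage points of the study area (paired within bootstrap). Per
#' service and scenario the pooled vector concatenates these deltas over all
#' member species and bootstraps; at level 1 a species contributes once per
#' member level-2 service.
#'
#' Species present in `areas` but absent from the catalogue are reported and
#' skipped; a species missing some scenario is an error (ragged pooling
#' would bias the distributions).
#'
#' @param areas An `area_sample` covering `"current"` plus future scenarios.
#' @param catalogue A `service_catalogue`.
#' @param level 1 or 2: pool by `es_level1` or `es_level2`.
#' @return List of objects of class `change_distribution`, one per
#'   service x scenario: fields `es_level`, `es_name`, `es_parent`,
#'   `scenario`, `period`, `rcp`, `values` (pooled percentage points),
#'   `n_memberships`, `n_species`, `B`. Skipped species are attached to the
#'   list as `attr(, "skipped_species")`.
#' @export
change_distributions <- function(areas, catalogue, level = 2) {
  stopifnot(level %in% c(1, 2))
  sp_areas <- unique(areas$species)
  sp_cat <- unique(catalogue$species)
  skipped <- setdiff(sp_areas, sp_cat)
  if (length(skipped) > 0)
    warning("species absent from the catalogue, skipped: ",
            paste(skipped, collapse = ", "))
  sp_use <- setdiff(sp_areas, skipped)
  scen <- unique(areas$scenario[areas$scenario != "current"])
  if (length(scen) == 0) stop("areas contain no future scenarios")

  # per-species change matrices (B x scenarios), paired on bootstrap_id
  deltas <- list()
  for (sp in sp_use) {
    a <- areas[areas$species == sp, ]
    cur <- a[a$scenario == "current", ]
    cur <- cur[order(cur$bootstrap_id), ]
    m <- matrix(NA_real_, nrow(cur), length(scen),
                dimnames = list(NULL, scen))
    for (s in scen) {
      f <- a[a$scenario == s, ]
      if (nrow(f) != nrow(cur))
        stop(sprintf("species '%s' lacks scenario '%s' for some bootstraps",
                     sp, s))
      f <- f[order(f$bootstrap_id), ]
      m[, s] <- f$pct - cur$pct
    }
    deltas[[sp]] <- m
  }

  key <- if (level == 2) catalogue$es_level2 else catalogue$es_level1
  members <- split(catalogue$species, key)
  scen_meta <- unique(areas[areas$scenario != "current",
                            c("scenario", "period", "rcp")])
  out <- list()
  for (es in names(members)) {
    mem <- members[[es]][members[[es]] %in% sp_use]
    if (length(mem) == 0) next
    parent <- if (level == 2)
      catalogue$es_level1[match(es, catalogue$es_level2)] else es
    for (s in scen) {
      vals <- unlist(lapply(mem, function(sp) deltas[[sp]][, s]),
                     use.names = FALSE)
      meta <- scen_meta[scen_meta$scenario == s, ]
      out[[length(out) + 1]] <- structure(list(
        es_level = level, es_name = es, es_parent = parent,
        scenario = s, period = meta$period[1], rcp = meta$rcp[1],
        values = vals, n_memberships = length(mem),
        n_species = length(unique(mem)),
        B = length(deltas[[mem[1]]][, s])),
        class = "change_distribution")
    }
  }
  attr(out, "skipped_species") <- skipped
  out
}

#' @export
print.change_distribution <- function(x, ...) {
  cat(sprintf(
    "change_distribution: %s (%s), n = %d species, %d values, median %+.2f pp\n",
    x$es_name, x$scenario, x$n_memberships, length(x$values),
    stats::median(x$values)))
  invisible(x)
}

#' Long table of pooled change values
#' @param distributions List from [change_distributions()].
#' @return Data frame `es_level`, `es_name`, `scenario`, `period`, `rcp`,
#'   `delta_pp` — the exact values behind the beanplots.
#' @export
pooled_changes_table <- function(distributions) {
  rows <- lapply(distributions, function(d) data.frame(
    es_level = d$es_level, es_name = d$es_name, scenario = d$scenario,
    period = d$period, rcp = d$rcp, delta_pp = d$values,
    stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Quantile summary of per-service change distributions
#' @param distributions List from [change_distributions()].
#' @param probs Quantile probabilities (default 2.5/25/50/75/97.5%).
#' @return Data frame, one row per service x scenario with quantile columns
#'   `q2.5` ... and `n_memberships`, `n_values`.
#' @export
change_summary <- function(distributions,
                           probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  rows <- lapply(distributions, function(d) {
    q <- stats::quantile(d$values, probs, names = FALSE)
    df <- data.frame(es_level = d$es_level, es_name = d$es_name,
                     scenario = d$scenario, n_memberships = d$n_memberships,
                     n_values = length(d$values), stringsAsFactors = FALSE)
    qd <- as.data.frame(as.list(q))
    names(qd) <- paste0("q", probs * 100)
    cbind(df, qd)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
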