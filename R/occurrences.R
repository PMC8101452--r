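## Occurrence handling: read Darwin-Core-ish CSVs, filter to the study area,
## cross-check label elevations against a DEM, and thin to one record per
## climate cell before niche fitting.

.occ_aliases <- list(
  species = c("species", "scientificname", "scientific_name", "taxon"),
  decimalLongitude = c("decimallongitude", "longitude", "lon", "x"),
  decimalLatitude = c("decimallatitude", "latitude", "lat", "y"),
  elevation = c("elevation", "elev", "altitude", "verbatimelevation"),
  source = c("source", "institutioncode", "basisofrecord"))

#' Read species occurrence records from CSV
#'
#' Accepts Darwin-Core-style column names with configurable aliases
#' (case-insensitive). Rows with a missing species or a non-numeric
#' coordinate are excluded from the table but *counted*: the number of
#' malformed rows is attached as `attr(, "n_malformed")` and reported.
#'
#' @param path CSV file with at least species and coordinate columns.
#' @param aliases Named list of accepted column names per canonical field.
#' @return Data frame with columns `species`, `decimalLongitude`,
#'   `decimalLatitude`, `elevation`, `source`; attribute `n_malformed`.
#' @export
read_occurrences <- function(path, aliases = .occ_aliases) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  nm <- tolower(trimws(names(raw)))
  pick <- function(field, required = TRUE) {
    hit <- which(nm %in% aliases[[field]])
    if (length(hit) == 0) {
      if (required) stop("required column missing: ", field)
      return(NULL)
    }
    raw[[hit[1]]]
  }
  species <- pick("species")
  lon <- suppressWarnings(as.numeric(pick("decimalLongitude")))
  lat <- suppressWarnings(as.numeric(pick("decimalLatitude")))
  elev_raw <- pick("elevation", required = FALSE)
  elev <- if (is.null(elev_raw)) rep(NA_real_, nrow(raw))
  else suppressWarnings(as.numeric(elev_raw))
  src_raw <- pick("source", required = FALSE)
  src <- if (is.null(src_raw)) rep(NA_character_, nrow(raw)) else src_raw

  ok <- !is.na(species) & nzchar(trimws(species)) &
    is.finite(lon) & is.finite(lat)
  out <- data.frame(species = trimws(species[ok]),
                    decimalLongitude = lon[ok], decimalLatitude = lat[ok],
                    elevation = elev[ok], source = src[ok],
                    stringsAsFactors = FALSE)
  attr(out, "n_malformed") <- sum(!ok)
  if (sum(!ok) > 0)
    message(sum(!ok), " malformed occurrence row(s) excluded")
  out
}

#' Clean occurrence records into per-species sets of PC-space points
#'
#' Applies, in order: (1) a coordinate bounds filter; (2) removal of records
#' falling on nodata cells or outside the grid; (3) an optional elevation
#' cross-check against a DEM — records whose label elevation differs from
#' the DEM by more than `max_elev_diff` are flagged (and dropped only when
#' `drop_on_elev_flag = TRUE`; records without a label elevation are never
#' flagged); (4) deduplication to one record per species per climate cell,
#' keeping the first record in input order. Removal counts per rule are
#' reported per species.
#'
#' @param occ Occurrence data frame as from [read_occurrences()] (the
#'   coordinate columns are interpreted in the planar units of the grid).
#' @param env A [pc_stack()]; its mask defines valid climate cells.
#' @param bounds Optional numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @param dem Optional elevation matrix congruent with the grid; the check
#'   runs only when a DEM is supplied.
#' @param max_elev_diff Elevation mismatch tolerance in m (default 500).
#' @param drop_on_elev_flag Drop flagged records instead of only reporting
#'   them (default `FALSE`).
#' @return An object of class `clean_occurrences`: list with `points` (named
#'   list per species of data frames `cell`, `row`, `col`, `PC1..PCk`),
#'   `report` (data frame `species`, `rule`, `n_removed`), `flagged`
#'   (row indices of elevation-flagged records), `k`.
#' @export
clean_occurrences <- function(occ, env, bounds = NULL, dem = NULL,
                              max_elev_diff = 500,
                              drop_on_elev_flag = FALSE) {
  stopifnot(inherits(env, "pc_stack"))
  k <- length(env$layers)
  score_mat <- stack_values(env)
  cell_of_score <- as.integer(rownames(score_mat))
  species_all <- unique(occ$species)
  report <- list()
  note <- function(sp, rule, n) {
    report[[length(report) + 1]] <<- data.frame(
      species = sp, rule = rule, n_removed = n, stringsAsFactors = FALSE)
  }
  points <- list()
  flagged_all <- integer(0)
  for (sp in species_all) {
    rows <- which(occ$species == sp)
    d <- occ[rows, , drop = FALSE]
    # (1) bounds
    if (!is.null(bounds)) {
      inb <- d$decimalLongitude >= bounds[1] & d$decimalLongitude <= bounds[2] &
        d$decimalLatitude >= bounds[3] & d$decimalLatitude <= bounds[4]
    } else inb <- rep(TRUE, nrow(d))
    note(sp, "out_of_bounds", sum(!inb))
    d <- d[inb, , drop = FALSE]; rows <- rows[inb]
    # (2) grid membership + nodata
    cell <- cell_from_xy(env$grid, d$decimalLongitude, d$decimalLatitude)
    valid <- !is.na(cell) & env$mask[ifelse(is.na(cell), 1L, cell)]
    note(sp, "nodata_cell", sum(!valid))
    d <- d[valid, , drop = FALSE]; rows <- rows[valid]
    cell <- cell[valid]
    # (3) elevation cross-check
    dem_use <- if (!is.null(dem)) dem else NULL
    if (!is.null(dem_use) && nrow(d) > 0) {
      dem_elev <- dem_use[cell]
      has_label <- is.finite(d$elevation)
      flag <- has_label & is.finite(dem_elev) &
        abs(dem_elev - d$elevation) > max_elev_diff
      flagged_all <- c(flagged_all, rows[flag])
      if (drop_on_elev_flag) {
        note(sp, "elevation_mismatch", sum(flag))
        d <- d[!flag, , drop = FALSE]; rows <- rows[!flag]
        cell <- cell[!flag]
      } else note(sp, "elevation_mismatch", 0L)
    } else note(sp, "elevation_mismatch", 0L)
    # (4) one record per climate cell, first in input order survives
    dup <- duplicated(cell)
    note(sp, "duplicate_cell", sum(dup))
    cell <- cell[!dup]
    rc <- cell_rowcol(env$grid, cell)
    sc <- score_mat[match(cell, cell_of_score), , drop = FALSE]
    pts <- data.frame(cell = cell, row = rc[, "row"], col = rc[, "col"],
                      sc, row.names = NULL)
    names(pts)[-(1:3)] <- colnames(score_mat)
    points[[sp]] <- pts
    if (nrow(pts) == 0)
      warning("species '", sp, "': no records survived cleaning")
  }
  report_df <- if (length(report) == 0)
    data.frame(species = character(0), rule = character(0),
               n_removed = integer(0))
  else do.call(rbind, c(report, list(make.row.names = FALSE)))
  structure(list(points = points, report = report_df,
                 flagged = flagged_all, k = k),
            class = "clean_occurrences")
}

#' @export
print.clean_occurrences <- function(x, ...) {
  n <- vapply(x$points, nrow, integer(1))
  cat(sprintf("clean_occurrences: %d species, %d cells total (k = %d)\n",
              length(n), sum(n), x$k))
  invisible(x)
}

#' Occurrence score matrix of one species
#' @param clean A `clean_occurrences`.
#' @param species Species label.
#' @return Numeric matrix of PC scores (one row per retained cell).
#' @export
occurrence_scores <- function(clean, species) {
  pts <- clean$points[[species]]
  if (is.null(pts)) stop("unknown species: ", species)
  as.matrix(pts[, -(1:3), drop = FALSE])
}

#' Apply the minimum-record-count criterion
#'
#' Species retaining fewer than `min_n` distinct climate cells after
#' cleaning are excluded from modelling and listed in the exclusion report.
#'
#' @param clean A `clean_occurrences`.
#' @param min_n Minimum number of retained cells (default 20).
#' @return A `clean_occurrences` containing only qualifying species;
#'   excluded species and their counts in `attr(, "excluded")`.
#' @export
apply_min_records <- function(clean, min_n = 20) {
  stopifnot(min_n >= 0)
  n <- vapply(clean$points, nrow, integer(1))
  keep <- n >= min_n
  out <- clean
  out$points <- clean$points[keep]
  attr(out, "excluded") <- data.frame(
    species = names(n)[!keep], n_cells = unname(n[!keep]),
    stringsAsFactors = FALSE)
  out
}
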