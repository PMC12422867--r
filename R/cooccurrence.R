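#' Count checklists recording two species together
#'
#' @param checklists A [checklist_table()].
#' @param species_a,species_b Species names.
#' @return List with `n_checklists` (checklists listing both species),
#'   `n_localities` (unique localities among them), and `per_year` (named
#'   integer vector of co-listed checklists per year).
#' @export
find_cooccurrences <- function(checklists, species_a, species_b) {
  both <- has_species(checklists, species_a) & has_species(checklists, species_b)
  hits <- checklists[both, , drop = FALSE]
  yr <- format(hits$date, "%Y")
  per_year <- if (nrow(hits)) table(yr) else table(character(0))
  list(n_checklists = nrow(hits),
       n_localities = length(unique(hits$locality_id)),
       per_year = setNames(as.integer(per_year), names(per_year)))
}

#' Filter species observations by locality-retention criteria
#'
#' Retains a species observation iff its locality satisfies either
#' criterion: (1) the species was reported there in at least `min_years`
#' separate years inside the window, or (2) the species was detected on at
#' least `min_rate` of all checklists ever submitted at the locality (the
#' all-time denominator, which limits vagrant records without biasing
#' toward heavily surveyed sites).
#'
#' @param checklists A [checklist_table()].
#' @param species Species name.
#' @param window `c(start, end)` dates (coerced with `as.Date`) bounding
#'   criterion 1.
#' @param min_years Minimum distinct detection years in the window.
#' @param min_rate Minimum all-time detection rate at the locality.
#' @return A `locality_filter`: list with `retained` (detection rows at
#'   passing localities), `removed` (detection rows at failing localities),
#'   and `locality_summary` (per-locality `n_years_window`,
#'   `alltime_checklists`, `alltime_detections`, `rate`, `crit1`, `crit2`,
#'   `retained`).
#' @export
filter_localities <- function(checklists, species,
                              window = c("2019-01-01", "2023-05-31"),
                              min_years = 2, min_rate = 0.5) {
  window <- as.Date(window)
  if (length(window) != 2 || window[2] < window[1]) stop("invalid window")
  det <- has_species(checklists, species)
  obs <- checklists[det, , drop = FALSE]

  loc <- sort(unique(checklists$locality_id))
  in_win <- obs$date >= window[1] & obs$date <= window[2]
  yrs <- tapply(format(obs$date[in_win], "%Y"), obs$locality_id[in_win],
                function(y) length(unique(y)))
  n_all <- table(checklists$locality_id)
  n_det <- table(obs$locality_id)
  summary <- data.frame(
    locality_id = loc,
    n_years_window = as.integer(ifelse(is.na(yrs[loc]), 0L, yrs[loc])),
    alltime_checklists = as.integer(n_all[loc]),
    alltime_detections = as.integer(ifelse(is.na(n_det[loc]), 0L, n_det[loc])),
    stringsAsFactors = FALSE
  )
  summary$rate <- summary$alltime_detections / summary$alltime_checklists
  summary$crit1 <- summary$n_years_window >= min_years
  summary$crit2 <- summary$rate >= min_rate
  summary$retained <- summary$crit1 | summary$crit2

  good <- summary$locality_id[summary$retained]
  structure(
    list(retained = obs[obs$locality_id %in% good, , drop = FALSE],
         removed = obs[!obs$locality_id %in% good, , drop = FALSE],
         locality_summary = summary,
         species = species),
    class = "locality_filter"
  )
}

#' @export
print.locality_filter <- function(x, ...) {
  cat("Locality filter for", x$species, ":",
      nrow(x$retained), "observations retained,",
      nrow(x$removed), "removed\n")
  invisible(x)
}

#' Thin points to at most one per square grid cell
#'
#' Points are binned into `cell_km` x `cell_km` cells of an equal-distance
#' approximation -- latitude cells of `cell_km`, and longitude cells of
#' `cell_km` at the centre of each point's 1-degree latitude band -- and
#' one point per occupied cell is kept, chosen uniformly at random under
#' `seed`. Cell membership depends only on a point's own coordinates, so
#' thinning is idempotent: thinned points occupy distinct cells and a
#' second pass returns them unchanged.
#'
#' @param points Data frame with `lon` and `lat` columns (rows preserved).
#' @param cell_km Cell edge in km (default 10).
#' @param seed Optional integer seed.
#' @param center_lat Optional fixed latitude for the longitude scaling
#'   (replaces the per-band cosine).
#' @return Subset of `points` rows, in original order.
#' @export
thin_grid <- function(points, cell_km = 10, seed = NULL, center_lat = NULL) {
  if (!nrow(points)) return(points)
  cell <- .grid_cells(points$lon, points$lat, cell_km, center_lat)
  keep <- with_seed(seed, {
    vapply(split(seq_len(nrow(points)), cell), resample, numeric(1), size = 1L)
  })
  points[sort(unname(keep)), , drop = FALSE]
}

# point-intrinsic grid-cell labels for spatial thinning
.grid_cells <- function(lon, lat, cell_km, center_lat = NULL) {
  dlat <- cell_km / .KM_PER_DEG
  band <- if (is.null(center_lat)) floor(lat) else
    rep(floor(center_lat), length(lat))
  dlon <- cell_km / (.KM_PER_DEG * cos((band + 0.5) * pi / 180))
  paste(band, floor(lon / dlon), floor(lat / dlat))
}

#' Localities qualifying as species absences
#'
#' An absence locality was surveyed in every listed year (at least one
#' checklist per year) yet never recorded the species in that period.
#'
#' @param checklists A [checklist_table()].
#' @param species Species name.
#' @param years Integer vector of years that must each be surveyed.
#' @return Data frame of absence localities (`locality_id`, `lon`, `lat`).
#' @export
build_absence_set <- function(checklists, species, years = 2019:2023) {
  if (!length(years)) stop("years must be non-empty")
  yr <- as.integer(format(checklists$date, "%Y"))
  in_period <- yr %in% years
  cl <- checklists[in_period, , drop = FALSE]
  yr <- yr[in_period]
  cov <- tapply(yr, cl$locality_id, function(y) all(years %in% y))
  det <- has_species(cl, species)
  seen <- unique(cl$locality_id[det])
  good <- names(cov)[!is.na(cov) & cov]
  good <- setdiff(good, seen)
  out <- unique(checklists[checklists$locality_id %in% good,
                           c("locality_id", "lon", "lat")])
  rownames(out) <- NULL
  out
}
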