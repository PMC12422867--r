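#' Simulate a citizen-science checklist table
#'
#' Generates birding-style survey checklists at fixed localities: each
#' locality has fixed coordinates inside `extent`, a residency status for
#' each of two focal species, and a yearly stream of checklists. A resident
#' species is detected on a checklist with its locality's detection rate; a
#' non-resident species appears as a vagrant record with probability
#' `vagrancy_rate` per checklist. Ground truth (residency per locality and
#' per-record vagrant labels) is retained for filter-validation tests.
#'
#' @param n_localities Number of localities (>= 1).
#' @param n_years Number of survey years, starting at `start_year`.
#' @param detection_rate Per-checklist detection probability for a resident
#'   species; scalar or vector recycled over localities.
#' @param cooccurrence_rate Fraction of localities where both species are
#'   resident.
#' @param vagrancy_rate Per-checklist probability that a non-resident
#'   species is recorded (a vagrant record).
#' @param checklists_per_year Mean checklists per locality-year (Poisson).
#' @param species Character vector of the two focal species names.
#' @param other_species Optional extra species names sprinkled onto lists.
#' @param start_year First survey year.
#' @param extent `c(lon_min, lon_max, lat_min, lat_max)` in decimal degrees.
#' @param prop_complete Probability a checklist is flagged complete.
#' @param seed Optional integer seed.
#' @return A `checklist_table`: data frame with one row per checklist
#'   (`checklist_id`, `locality_id`, `lon`, `lat`, `date`, `complete`,
#'   `species` as a `";"`-separated detection list), with attributes
#'   `residency` (data frame of per-locality residency truth) and
#'   `vagrant_records` (data frame `checklist_id`, `species` of true
#'   vagrant records).
#' @examples
#' cl <- simulate_checklists(20, 3, seed = 1)
#' head(cl, 3)
#' @export
simulate_checklists <- function(n_localities = 60, n_years = 5,
                                detection_rate = 0.7,
                                cooccurrence_rate = 0.15,
                                vagrancy_rate = 0.01,
                                checklists_per_year = 6,
                                species = c("green_jay", "blue_jay"),
                                other_species = c("northern_cardinal",
                                                  "great_kiskadee"),
                                start_year = 2019,
                                extent = c(-105, -93, 20, 35),
                                prop_complete = 0.9, seed = NULL) {
  n_localities <- as.integer(n_localities)
  if (is.na(n_localities) || n_localities < 1) stop("n_localities must be >= 1")
  for (r in c(detection_rate, cooccurrence_rate, vagrancy_rate, prop_complete))
    if (any(r < 0 | r > 1)) stop("rates must lie in [0, 1]")
  stopifnot(length(species) == 2, n_years >= 1)

  with_seed(seed, {
    loc_id <- sprintf("L%04d", seq_len(n_localities))
    lon <- runif(n_localities, extent[1], extent[2])
    lat <- runif(n_localities, extent[3], extent[4])
    det <- rep_len(detection_rate, n_localities)

    n_both <- round(cooccurrence_rate * n_localities)
    rest <- n_localities - n_both
    n_a <- floor(rest * 0.4)
    n_b <- floor(rest * 0.4)
    status <- c(rep("both", n_both), rep("a_only", n_a), rep("b_only", n_b),
                rep("neither", rest - n_a - n_b))
    status <- resample(status)  # shuffle over localities
    residency <- data.frame(
      locality_id = loc_id, lon = lon, lat = lat,
      resident_a = status %in% c("both", "a_only"),
      resident_b = status %in% c("both", "b_only"),
      stringsAsFactors = FALSE
    )

    years <- start_year + seq_len(n_years) - 1L
    rows <- vector("list", n_localities * n_years)
    vagrants <- list()
    cl_counter <- 0L
    k <- 0L
    for (i in seq_len(n_localities)) {
      for (y in years) {
        n_cl <- rpois(1L, checklists_per_year)
        if (n_cl == 0L) next
        for (j in seq_len(n_cl)) {
          cl_counter <- cl_counter + 1L
          id <- sprintf("CL%06d", cl_counter)
          date <- as.Date(sprintf("%d-01-01", y)) +
            resample(0:364, 1L)
          listed <- resample(other_species,
                             rbinom(1L, length(other_species), 0.5))
          for (s in 1:2) {
            res <- if (s == 1) residency$resident_a[i] else residency$resident_b[i]
            if (res) {
              if (runif(1) < det[i]) listed <- c(listed, species[s])
            } else if (runif(1) < vagrancy_rate) {
              listed <- c(listed, species[s])
              vagrants[[length(vagrants) + 1L]] <-
                data.frame(checklist_id = id, species = species[s],
                           stringsAsFactors = FALSE)
            }
          }
          k <- k + 1L
          rows[[k]] <- data.frame(
            checklist_id = id, locality_id = loc_id[i],
            lon = lon[i], lat = lat[i], date = date,
            complete = runif(1) < prop_complete,
            species = paste(listed, collapse = ";"),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    tab <- do.call(rbind, rows[seq_len(k)])
    checklist_table(tab,
      residency = residency,
      vagrant_records = if (length(vagrants)) do.call(rbind, vagrants)
        else data.frame(checklist_id = character(0), species = character(0)))
  })
}

#' Construct a checklist table
#'
#' @param x Data frame with columns `checklist_id`, `locality_id`, `lon`,
#'   `lat`, `date`, `complete`, `species` (a `";"`-separated species list).
#' @param residency,vagrant_records Optional ground-truth attributes from
#'   the simulator.
#' @return A `checklist_table` (data frame subclass).
#' @export
checklist_table <- function(x, residency = NULL, vagrant_records = NULL) {
  need <- c("checklist_id", "locality_id", "lon", "lat", "date", "complete",
            "species")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing checklist columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$checklist_id)) stop("checklist_id must be unique")
  # a locality has fixed coordinates across rows
  crd <- unique(x[, c("locality_id", "lon", "lat")])
  if (anyDuplicated(crd$locality_id))
    stop("locality_id must map to fixed coordinates")
  x$date <- as.Date(x$date)
  structure(x, class = c("checklist_table", "data.frame"),
            residency = residency, vagrant_records = vagrant_records)
}

# does each checklist's species list contain `sp`?
has_species <- function(checklists, sp) {
  vapply(strsplit(checklists$species, ";", fixed = TRUE),
         function(s) sp %in% s, logical(1))
}
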