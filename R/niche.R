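#' Construct a suitability surface
#'
#' A regular lon/lat grid of climatic-suitability values in `[0, 1]`. The
#' suitability model behind the values is pluggable; the bundled
#' [fit_envelope_model()] is a simple distance-envelope scorer used to
#' exercise thresholding and overlap accounting.
#'
#' @param values Numeric matrix (rows = latitudes, columns = longitudes) of
#'   suitabilities in `[0, 1]`.
#' @param lon,lat Cell-centre coordinate vectors (regular spacing).
#' @return A `suitability_surface`: list with `values`, `lon`, `lat`,
#'   `cell_deg`, `extent`.
#' @export
suitability_surface <- function(values, lon, lat) {
  values <- as.matrix(values)
  if (nrow(values) != length(lat) || ncol(values) != length(lon))
    stop("values must be a length(lat) x length(lon) matrix")
  if (any(values < 0 | values > 1, na.rm = TRUE))
    stop("suitability values must lie in [0, 1]")
  dl <- if (length(lon) > 1) diff(lon[1:2]) else
    if (length(lat) > 1) diff(lat[1:2]) else 1
  structure(
    list(values = values, lon = lon, lat = lat, cell_deg = dl,
         extent = c(min(lon) - dl / 2, max(lon) + dl / 2,
                    min(lat) - dl / 2, max(lat) + dl / 2)),
    class = "suitability_surface"
  )
}

#' @export
print.suitability_surface <- function(x, ...) {
  cat("Suitability surface:", length(x$lat), "x", length(x$lon),
      "cells of", x$cell_deg, "deg\n")
  invisible(x)
}

#' Fit a simple climate-envelope suitability model
#'
#' A pluggable stand-in for an external niche model: suitability of a cell
#' is a Gaussian kernel of its distance (in degrees, longitude scaled by
#' cos latitude) to the nearest presence point. It produces smooth `[0, 1]`
#' surfaces adequate for exercising threshold selection and overlap
#' geometry; it is not a covariate-based niche model.
#'
#' @param points Data frame of presence points (`lon`, `lat`).
#' @param extent `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param cell_deg Grid cell size in degrees.
#' @param bandwidth Kernel bandwidth in degrees.
#' @return A [suitability_surface()].
#' @export
fit_envelope_model <- function(points, extent = c(-105, -93, 20, 35),
                               cell_deg = 0.1, bandwidth = 0.75) {
  if (!nrow(points)) stop("no presence points")
  lon <- seq(extent[1] + cell_deg / 2, extent[2] - cell_deg / 2, by = cell_deg)
  lat <- seq(extent[3] + cell_deg / 2, extent[4] - cell_deg / 2, by = cell_deg)
  cl <- cos(mean(lat) * pi / 180)
  vals <- matrix(0, nrow = length(lat), ncol = length(lon))
  for (k in seq_len(nrow(points))) {
    dx <- outer(rep(1, length(lat)), (lon - points$lon[k]) * cl)
    dy <- outer(lat - points$lat[k], rep(1, length(lon)))
    vals <- pmax(vals, exp(-(dx^2 + dy^2) / (2 * bandwidth^2)))
  }
  suitability_surface(vals, lon, lat)
}

#' Suitability values at point locations
#'
#' @param surface A [suitability_surface()].
#' @param lon,lat Point coordinates.
#' @return Numeric vector of nearest-cell suitabilities (NA outside the
#'   extent).
#' @export
surface_scores <- function(surface, lon, lat) {
  i <- round((lat - surface$lat[1]) / surface$cell_deg) + 1L
  j <- round((lon - surface$lon[1]) / surface$cell_deg) + 1L
  ok <- i >= 1 & i <= length(surface$lat) & j >= 1 & j <= length(surface$lon)
  out <- rep(NA_real_, length(lon))
  out[ok] <- surface$values[cbind(i[ok], j[ok])]
  out
}

#' Threshold maximizing sensitivity plus specificity
#'
#' Selects the suitability cutoff maximizing sensitivity + specificity
#' (Youden's J) over all midpoints between consecutive observed scores,
#' classifying `score >= threshold` as presence. Ties are broken
#' deterministically toward the lowest such threshold.
#'
#' @param scores Numeric suitability values.
#' @param labels Logical (or 0/1) presence labels, same length.
#' @return The selected threshold, with attributes `sensitivity`,
#'   `specificity` and `youden_j`.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  if (!any(labels) || all(labels))
    stop("both presence and absence labels are required")
  us <- sort(unique(scores))
  if (length(us) < 2)
    stop("degenerate scores: no separating cutpoint exists")
  cand <- (us[-length(us)] + us[-1]) / 2
  j <- vapply(cand, function(thr) {
    sens <- mean(scores[labels] >= thr)
    spec <- mean(scores[!labels] < thr)
    sens + spec
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)[1]
  thr <- cand[best]
  structure(thr,
            sensitivity = mean(scores[labels] >= thr),
            specificity = mean(scores[!labels] < thr),
            youden_j = j[best])
}

#' Binarize two suitability surfaces and measure their overlap
#'
#' Converts each surface to presence (1) where its value is at or above its
#' threshold, takes the cell-wise AND, and reports the overlap area (sum of
#' spherical-rectangle cell areas, latitude-corrected, in km^2) and its
#' area-weighted centroid.
#'
#' @param surface_a,surface_b Two [suitability_surface()]s on identical
#'   grids.
#' @param thr_a,thr_b Binarization thresholds (e.g. from
#'   [youden_threshold()]).
#' @return An `overlap_result`: list with `binary_a`, `binary_b`, `overlap`
#'   (logical matrices), `area_a_km2`, `area_b_km2`, `area_km2`, `centroid`
#'   (`c(lon, lat)`, or `NULL` when the overlap is empty), `n_cells`, and
#'   the grid coordinates.
#' @export
binarize_and_overlap <- function(surface_a, surface_b, thr_a, thr_b) {
  stopifnot(inherits(surface_a, "suitability_surface"),
            inherits(surface_b, "suitability_surface"))
  if (!isTRUE(all.equal(surface_a$lon, surface_b$lon)) ||
      !isTRUE(all.equal(surface_a$lat, surface_b$lat)))
    stop("surfaces must share an identical grid")
  ba <- surface_a$values >= as.numeric(thr_a)
  bb <- surface_b$values >= as.numeric(thr_b)
  ov <- ba & bb
  cell_area <- .cell_areas(surface_a)  # per-latitude-row areas, km^2
  area_of <- function(m) sum(cell_area[row(m)[m]])
  area <- area_of(ov)
  centroid <- NULL
  if (any(ov)) {
    w <- cell_area[row(ov)[ov]]
    centroid <- c(lon = sum(surface_a$lon[col(ov)[ov]] * w) / sum(w),
                  lat = sum(surface_a$lat[row(ov)[ov]] * w) / sum(w))
  }
  structure(
    list(binary_a = ba, binary_b = bb, overlap = ov,
         area_a_km2 = area_of(ba), area_b_km2 = area_of(bb),
         area_km2 = area, centroid = centroid, n_cells = sum(ov),
         lon = surface_a$lon, lat = surface_a$lat,
         cell_deg = surface_a$cell_deg),
    class = "overlap_result"
  )
}

# spherical-rectangle area of one cell in each latitude row, km^2
.cell_areas <- function(surface) {
  half <- surface$cell_deg / 2
  dlam <- surface$cell_deg * pi / 180
  .EARTH_R^2 * dlam *
    (sin((surface$lat + half) * pi / 180) - sin((surface$lat - half) * pi / 180))
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Niche overlap:", x$n_cells, "cells,",
      sprintf("%.2f km^2", x$area_km2), "\n")
  if (!is.null(x$centroid))
    cat("  centroid: (", sprintf("%.5f", x$centroid["lat"]), ", ",
        sprintf("%.5f", x$centroid["lon"]), ")\n", sep = "")
  invisible(x)
}

#' Overlap cells as rectangles
#'
#' @param result An `overlap_result`.
#' @return Data frame of overlap-cell bounding boxes (`lon_min`, `lon_max`,
#'   `lat_min`, `lat_max`).
#' @export
overlap_polygons <- function(result) {
  stopifnot(inherits(result, "overlap_result"))
  idx <- which(result$overlap, arr.ind = TRUE)
  half <- result$cell_deg / 2
  data.frame(
    lon_min = result$lon[idx[, 2]] - half, lon_max = result$lon[idx[, 2]] + half,
    lat_min = result$lat[idx[, 1]] - half, lat_max = result$lat[idx[, 1]] + half
  )
}

#' Write overlap polygons as GeoJSON
#'
#' @param result An `overlap_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_overlap_geojson <- function(result, path) {
  rects <- overlap_polygons(result)
  feats <- lapply(seq_len(nrow(rects)), function(i) {
    r <- rects[i, ]
    ring <- list(c(r$lon_min, r$lat_min), c(r$lon_max, r$lat_min),
                 c(r$lon_max, r$lat_max), c(r$lon_min, r$lat_max),
                 c(r$lon_min, r$lat_min))
    list(type = "Feature", properties = list(cell = i),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
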