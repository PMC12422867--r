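test_that("co-occurrence counting matches hand counts", {
  cl <- make_checklists(
    list("c1", "L1", -98, 27, "2021-04-01", "green_jay;blue_jay"),
    list("c2", "L1", -98, 27, "2021-05-01", "green_jay"),
    list("c3", "L2", -97, 28, "2022-04-01", "green_jay;blue_jay;great_kiskadee"),
    list("c4", "L2", -97, 28, "2022-05-01", "blue_jay"),
    list("c5", "L1", -98, 27, "2023-04-01", "blue_jay;green_jay"))
  co <- find_cooccurrences(cl, "green_jay", "blue_jay")
  expect_identical(co$n_checklists, 3L)
  expect_identical(co$n_localities, 2L)
  expect_identical(co$per_year,
                   c("2021" = 1L, "2022" = 1L, "2023" = 1L))

  none <- find_cooccurrences(cl, "green_jay", "northern_cardinal")
  expect_identical(none$n_checklists, 0L)
  expect_identical(none$n_localities, 0L)
  expect_length(none$per_year, 0)
})

test_that("locality retention applies the two criteria as a disjunction", {
  # L1: species in two separate years (criterion 1), low rate
  # L2: 5 of 10 checklists in a single year (criterion 2)
  # L3: 1 of 20 checklists, single year -> removed
  rows <- list()
  add <- function(id, loc, date, sp) rows[[length(rows) + 1]] <<-
    list(id, loc, -98, 27, date, sp)
  add("a1", "L1", "2019-05-01", "green_jay")
  add("a2", "L1", "2021-05-01", "green_jay")
  for (i in 1:8) add(paste0("a", i + 2), "L1", "2022-06-01", "none_sp")
  for (i in 1:5) add(paste0("b", i), "L2", "2020-05-01", "green_jay")
  for (i in 1:5) add(paste0("b", i + 5), "L2", "2020-06-01", "none_sp")
  add("c1", "L3", "2020-05-01", "green_jay")
  for (i in 1:19) add(paste0("c", i + 1), "L3", "2020-06-01", "none_sp")
  cl <- do.call(make_checklists, rows)

  fl <- filter_localities(cl, "green_jay")
  sm <- fl$locality_summary
  expect_true(sm$crit1[sm$locality_id == "L1"])
  expect_false(sm$crit2[sm$locality_id == "L1"])
  expect_true(sm$retained[sm$locality_id == "L1"])
  expect_false(sm$crit1[sm$locality_id == "L2"])
  expect_true(sm$crit2[sm$locality_id == "L2"])
  expect_true(sm$retained[sm$locality_id == "L2"])
  expect_false(sm$retained[sm$locality_id == "L3"])
  expect_setequal(unique(fl$retained$locality_id), c("L1", "L2"))
  expect_true(all(fl$removed$locality_id == "L3"))

  # adding detections never removes a retained locality
  extra <- rbind(as.data.frame(cl),
                 data.frame(checklist_id = "z1", locality_id = "L1",
                            lon = -98, lat = 27, date = as.Date("2022-07-01"),
                            complete = TRUE, species = "green_jay"))
  fl2 <- filter_localities(checklist_table(extra), "green_jay")
  sm2 <- fl2$locality_summary
  expect_true(all(sm$locality_id[sm$retained] %in%
                    sm2$locality_id[sm2$retained]))
})

test_that("grid thinning keeps one point per cell and is idempotent", {
  # two points in one 10-km cell, one far away
  pts <- data.frame(lon = c(-98.00, -98.01, -90.00),
                    lat = c(27.00, 27.005, 30.00))
  th <- thin_grid(pts, cell_km = 10, seed = 1)
  expect_identical(nrow(th), 2L)
  expect_true(-90 %in% th$lon)

  # all points in distinct cells: identity
  far <- data.frame(lon = seq(-100, -94, by = 1), lat = rep(27, 7))
  expect_identical(thin_grid(far, cell_km = 10, seed = 2), far)

  # pigeonhole: 1000 uniform points on an extent of exactly 5 x 5 cells
  # (edges aligned to cell boundaries, inside one 1-degree latitude band)
  set.seed(3)
  km_deg <- pi * 6371.0088 / 180
  dlat <- 10 / km_deg
  dlon <- 10 / (km_deg * cos(27.5 * pi / 180))
  lat0 <- ceiling(27 / dlat) * dlat
  lon0 <- ceiling(-98 / dlon) * dlon
  many <- data.frame(lon = runif(1000, lon0, lon0 + 5 * dlon),
                     lat = runif(1000, lat0, lat0 + 5 * dlat))
  th2 <- thin_grid(many, cell_km = 10, seed = 4)
  expect_lte(nrow(th2), 25)
  expect_lte(nrow(th2), nrow(many))

  # idempotence and seed reproducibility
  expect_identical(thin_grid(th2, cell_km = 10, seed = 99), th2)
  expect_identical(thin_grid(many, cell_km = 10, seed = 4), th2)
})

test_that("absence localities are surveyed every year without detections", {
  rows <- list()
  add <- function(id, loc, date, sp) rows[[length(rows) + 1]] <<-
    list(id, loc, -98, 27, date, sp)
  k <- 0
  for (y in 2019:2023) {
    k <- k + 1
    add(paste0("p", k), "Lfull", paste0(y, "-05-01"), "none_sp")
    if (y != 2021) add(paste0("q", k), "Lgap", paste0(y, "-05-01"), "none_sp")
    add(paste0("r", k), "Lseen", paste0(y, "-05-01"),
        if (y == 2020) "green_jay" else "none_sp")
  }
  cl <- do.call(make_checklists, rows)
  ab <- build_absence_set(cl, "green_jay", years = 2019:2023)
  expect_identical(ab$locality_id, "Lfull")
})

test_that("the max sens+spec threshold matches brute-force search", {
  # perfectly separated toy scores
  thr <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE))
  expect_gt(thr, 0.2)
  expect_lt(thr, 0.8)
  expect_equal(attr(thr, "youden_j"), 2)

  # overlapping toy set of 8 labeled scores
  sc8 <- c(0.1, 0.3, 0.35, 0.4, 0.45, 0.6, 0.7, 0.9)
  lb8 <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  o <- youden_oracle(sc8, lb8)
  t8 <- youden_threshold(sc8, lb8)
  expect_equal(as.numeric(t8), o$threshold)
  expect_equal(attr(t8, "youden_j"), o$j)

  # random instances agree with the oracle
  set.seed(5)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    lb <- runif(n) < 0.5
    if (!any(lb)) lb[1] <- TRUE
    if (all(lb)) lb[1] <- FALSE
    sc <- round(runif(n), 2) + ifelse(lb, 0.2, 0)
    o <- youden_oracle(sc, lb)
    t_ <- youden_threshold(sc, lb)
    expect_equal(as.numeric(t_), o$threshold)
    expect_equal(attr(t_, "youden_j"), o$j)
  }

  expect_error(youden_threshold(rep(0.5, 6), c(TRUE, TRUE, TRUE, FALSE,
                                               FALSE, FALSE)), "degenerate")
  expect_error(youden_threshold(1:5, rep(TRUE, 5)), "both")
})

test_that("binarized overlap geometry matches cell arithmetic", {
  lon <- seq(-98.95, -98.05, by = 0.1)
  lat <- seq(27.05, 27.95, by = 0.1)
  za <- matrix(0, 10, 10)
  zb <- matrix(0, 10, 10)
  za[5, 5] <- 1; zb[5, 5] <- 1          # one shared cell
  za[2, 2] <- 1; zb[9, 9] <- 1          # non-shared suitable cells
  sa <- suitability_surface(za, lon, lat)
  sb <- suitability_surface(zb, lon, lat)
  ov <- binarize_and_overlap(sa, sb, 0.5, 0.5)
  expect_identical(ov$n_cells, 1L)
  cell_km2 <- (pi * 6371.0088 / 180 * 0.1)^2 * cos(lat[5] * pi / 180)
  expect_equal(ov$area_km2, cell_km2, tolerance = 1e-4)
  expect_equal(unname(ov$centroid), c(lon[5], lat[5]))

  # two equal-latitude shared cells: centroid at their midpoint
  zb2 <- zb; zb2[5, 5] <- 1; zb2[5, 7] <- 1
  za2 <- za; za2[5, 7] <- 1
  ov2 <- binarize_and_overlap(suitability_surface(za2, lon, lat),
                              suitability_surface(zb2, lon, lat), 0.5, 0.5)
  expect_identical(ov2$n_cells, 2L)
  expect_equal(unname(ov2$centroid["lon"]), mean(lon[c(5, 7)]))

  # disjoint surfaces: zero area, no centroid
  zb3 <- matrix(0, 10, 10); zb3[9, 9] <- 1
  ov3 <- binarize_and_overlap(sa, suitability_surface(zb3, lon, lat),
                              0.5, 0.5)
  expect_equal(ov3$area_km2, 0)
  expect_null(ov3$centroid)

  # overlap is symmetric and bounded by either footprint
  ovs <- binarize_and_overlap(sb, sa, 0.5, 0.5)
  expect_equal(ovs$area_km2, ov$area_km2)
  expect_lte(ov$area_km2, min(ov$area_a_km2, ov$area_b_km2))

  bad <- suitability_surface(za[1:5, 1:5], lon[1:5], lat[1:5])
  expect_error(binarize_and_overlap(sa, bad, 0.5, 0.5), "identical grid")
})

test_that("envelope surfaces support end-to-end threshold selection", {
  set.seed(6)
  pres <- data.frame(lon = runif(30, -99, -97), lat = runif(30, 26, 28))
  abs_ <- data.frame(lon = runif(30, -95, -93.2), lat = runif(30, 32, 34.5))
  surf <- fit_envelope_model(pres, extent = c(-105, -93, 20, 35),
                             cell_deg = 0.2, bandwidth = 0.75)
  sc <- c(surface_scores(surf, pres$lon, pres$lat),
          surface_scores(surf, abs_$lon, abs_$lat))
  lab <- rep(c(TRUE, FALSE), each = 30)
  thr <- youden_threshold(sc, lab)
  # presences score high near their own kernel, absences far away score low
  expect_equal(attr(thr, "youden_j"), 2, tolerance = 0.05)
})
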