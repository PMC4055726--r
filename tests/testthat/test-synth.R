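test_that("terrain is flat without hills and peaks at planted hills", {
  cfg <- synthetic_config(seed = 5, extent = 400, cell_size = 4,
                          n_hills = 0, building_cover = 0, canopy_cover = 0)
  z <- generate_terrain(cfg)
  expect_true(all(z$values == 0))
  # deterministic per seed
  cfg2 <- synthetic_config(seed = 9, extent = 400, cell_size = 4)
  expect_identical(generate_terrain(cfg2)$values, generate_terrain(cfg2)$values)
  # a single dominant hill rises toward its configured height
  cfg3 <- synthetic_config(seed = 3, extent = 400, cell_size = 4, n_hills = 1,
                           hill_height = c(50, 50), hill_radius = c(120, 120),
                           building_cover = 0, canopy_cover = 0)
  z3 <- generate_terrain(cfg3)
  expect_gt(max(z3$values), 45)   # peak within a cell of the centre
  expect_lt(max(z3$values), 50 + 1e-6)
})

test_that("landscapes carry disjoint in-range ponds and consistent wiring", {
  cfg <- synthetic_config(seed = 17, coarse = TRUE)
  land <- generate_landscape(cfg)
  ponds <- land$ponds$features
  expect_equal(length(ponds), 64)
  areas <- vapply(ponds, polygon_area, 0)
  expect_true(all(areas >= 685 - 1e-6 & areas <= 111626 + 1e-6))
  # pairwise disjoint: no vertex of one pond falls inside another
  for (i in seq_along(ponds)) {
    for (j in seq_along(ponds)) {
      if (i == j) next
      expect_false(any(point_in_polygon(ponds[[j]],
                                        ponds[[i]]$exterior[, 1],
                                        ponds[[i]]$exterior[, 2])))
    }
  }
  # connectivity classes near the configured wiring fractions (0.30 / 0.22)
  cls <- vapply(ponds, function(p) connectivity_class(p$id, land$canals), 0L)
  expect_lt(abs(sum(cls == 2) - 0.30 * 64), 3 * sqrt(64 * 0.30 * 0.70) + 1)
  expect_lt(abs(sum(cls == 1) - 0.22 * 64), 3 * sqrt(64 * 0.22 * 0.78) + 1)
  # attributes within the configured chlorophyll range
  expect_true(all(land$attrs$chl_a >= 1.9 & land$attrs$chl_a <= 438.8))
  # land-use raster marks pond water
  expect_true(any(land$landuse$values == landuse_codes()["water"]))
})

test_that("planted presence rules close over their inputs", {
  n <- 40
  f <- data.frame(pond_id = sprintf("p%02d", 1:n),
                  visibility = seq(0, 3900, length.out = n),
                  connectivity = rep(2, n),
                  chl_a = rep(50, n))
  rules <- list(tau_v = 1000, tau_c = 38.25, p_intro = 0.6)
  lab <- simulate_presence(f, rules, noise_rate = 0, seed = 1)
  expect_true(all(lab$present_bluegill == 1))   # all connected
  expect_true(all(lab$present_bass == 0))       # chl above the ceiling
  # visibility-only rule engages beyond the threshold
  f$connectivity <- 0
  lab2 <- simulate_presence(f, rules, noise_rate = 0, seed = 1)
  expect_equal(lab2$present_bluegill, as.integer(f$visibility >= 1000))
  # flip fraction matches the nominal noise rate (binomial tolerance)
  f3 <- data.frame(pond_id = as.character(1:10000),
                   visibility = 0, connectivity = 2, chl_a = 1)
  clean <- simulate_presence(f3, rules, noise_rate = 0, seed = 2)
  noisy <- simulate_presence(f3, rules, noise_rate = 0.1, seed = 2)
  flips <- mean(clean$present_bluegill != noisy$present_bluegill)
  expect_lt(abs(flips - 0.1), 3 * sqrt(0.1 * 0.9 / 10000))
})

test_that("study datasets satisfy the schema and are reproducible", {
  cfg <- synthetic_config(seed = 23, coarse = TRUE, extent = 1500,
                          n_ponds = 16, pond_area_range = c(685, 8000))
  ds <- generate_study_dataset(cfg)
  f <- ds$features
  expect_equal(nrow(f), 16)
  expect_true(all(c("pond_id", "visibility", "road_density", "urban_ratio",
                    "river_density_500", "connectivity", "area", "chl_a",
                    "drained", "present_bluegill", "present_bass")
                  %in% names(f)))
  expect_true(all(f$visibility >= 0))
  expect_true(is.factor(f$connectivity) && is.factor(f$drained))
  expect_true(all(f$urban_ratio >= 0 & f$urban_ratio <= 1))
  expect_true(all(f$area > 0))
  expect_gt(stats::var(f$visibility), 0)
  # same seed, same bytes
  ds2 <- generate_study_dataset(cfg)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(ds$features, f1)
  write_feature_csv(ds2$features, f2)
  expect_identical(readLines(f1), readLines(f2))
  # landscape files round-trip
  dir <- withr::local_tempdir()
  write_landscape(ds$landscape, dir)
  expect_true(all(file.exists(file.path(dir,
    c("dsm.asc", "landuse.asc", "roads.geojson", "rivers.geojson",
      "ponds.geojson", "canals.csv", "attrs.csv", "config.json")))))
  dsm2 <- read_raster(file.path(dir, "dsm.asc"))
  expect_equal(dsm2$values, ds$landscape$dsm$values)
  g2 <- read_canal_graph(file.path(dir, "canals.csv"))
  p1 <- ds$landscape$ponds$features[[1]]$id
  if (p1 %in% names(g2$kinds))
    expect_equal(connectivity_class(p1, g2),
                 as.integer(as.character(f$connectivity[f$pond_id == p1])))
})

test_that("visibility is damped where buildings or canopy intervene", {
  # urban ponds sit among building blocks; farmland ponds lie open
  vis_by_zone <- function(seed) {
    cfg <- synthetic_config(seed = seed, coarse = TRUE, extent = 2000,
                            n_ponds = 24, pond_area_range = c(685, 6000))
    ds <- generate_study_dataset(cfg)
    f <- ds$features
    zone <- ifelse(f$urban_ratio > 0.25, "urban", "open")
    tapply(f$visibility, zone, median)
  }
  v <- vis_by_zone(41)
  if (all(c("urban", "open") %in% names(v)))
    expect_lte(v[["urban"]], v[["open"]] * 1.5)
})
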