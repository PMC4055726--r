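test_that("road density is length over ring area and linear in geometry", {
  pond <- square_poly("p", 450, 450, 100)
  expect_equal(road_density(feature_set("roads", list()), pond), 0)
  road <- polyline("r", rbind(c(-100, 700), c(1100, 700)))
  fs <- feature_set("roads", list(road))
  buf <- buffer_polygon(pond, 500)
  # the horizontal road at y=700 crosses the buffer; clip analytically:
  # ring spans x in [-50, 1050] at that height minus nothing (pond is below)
  d <- road_density(fs, pond)
  expect_equal(d, clip_length(fs, buf) / polygon_area(buf))
  fs2 <- feature_set("roads", list(road, polyline("r2", road$vertices)))
  expect_equal(road_density(fs2, pond), 2 * d, tolerance = 1e-12)
})

test_that("urban ratio covers the unit interval and halves on a half-plane", {
  pond <- square_poly("p", 950, 950, 100)
  n <- 100; cell <- 20   # 2000 m extent
  all_urban <- raster_grid(matrix(landuse_codes()["urban"], n, n),
                           cell_size = cell)
  expect_equal(urban_ratio(all_urban, pond), 1.0)
  none <- raster_grid(matrix(landuse_codes()["farmland"], n, n),
                      cell_size = cell)
  expect_equal(urban_ratio(none, pond), 0.0)
  half <- matrix(landuse_codes()["farmland"], n, n)
  half[1:50, ] <- landuse_codes()["urban"]   # southern half, y < 1000
  hr <- raster_grid(half, cell_size = cell)
  expect_equal(urban_ratio(hr, pond), 0.5, tolerance = 0.03)
  bad <- raster_grid(matrix(9, n, n), cell_size = cell)
  expect_error(urban_ratio(bad, pond), "category")
})

test_that("river-density profile activates buffers by distance", {
  pond <- square_poly("p", 2000, 2000, 60)
  expect_equal(unname(river_density_profile(feature_set("rivers", list()),
                                            pond)),
               rep(0, 8))
  # straight river 300 m from the pond edge: nothing within 250 m,
  # positive at 500 and 1000 m
  river <- feature_set("rivers", list(
    polyline("rv", rbind(c(0, 2360), c(4000, 2360)))))
  prof <- river_density_profile(river, pond)
  expect_true(all(prof[c("5", "10", "25", "50", "100", "250")] == 0))
  expect_true(all(prof[c("500", "1000")] > 0))
  # the 500 m value matches an analytic chord length over the ring area
  buf <- buffer_polygon(pond, 500)
  expect_equal(unname(prof["500"]),
               clip_length(river, buf) / polygon_area(buf))
  expect_error(river_density_profile(river, pond, buffers = c(10, 5)),
               "increasing")
  # translation invariance of densities
  shift <- 777
  pond2 <- square_poly("p2", 2000 + shift, 2000 + shift, 60)
  river2 <- feature_set("rivers", list(
    polyline("rv", river$features[[1]]$vertices + shift)))
  expect_equal(unname(river_density_profile(river2, pond2)), unname(prof),
               tolerance = 1e-9)
})

test_that("connectivity classes follow the path-type definition", {
  kinds <- c(R1 = "reservoir", c1 = "canal", c2 = "canal", p1 = "pond",
             p2 = "pond", f1 = "farmland", p3 = "pond", c3 = "canal",
             c4 = "canal", p4 = "pond")
  edges <- data.frame(
    source = c("R1", "c1", "p1", "c2", "R1", "c3", "f1", "c4"),
    target = c("c1", "p1", "c2", "p2", "c3", "f1", "c4", "p4"))
  g <- canal_graph(edges, kinds)
  expect_equal(connectivity_class("p1", g), 2L)   # reservoir -> canal -> pond
  expect_equal(connectivity_class("p2", g), 1L)   # via upstream pond p1
  expect_equal(connectivity_class("p4", g), 1L)   # via farmland
  expect_equal(connectivity_class("p3", g), 0L)   # isolated
  expect_error(connectivity_class("nope", g), "unknown")
  # direct dominates: add a canal-only route to p2
  edges2 <- rbind(edges, data.frame(source = c("R1", "c9"),
                                    target = c("c9", "p2")))
  g2 <- canal_graph(edges2, c(kinds, c9 = "canal"))
  expect_equal(connectivity_class("p2", g2), 2L)
  # monotone: adding edges never decreases any class
  for (p in c("p1", "p2", "p3", "p4"))
    expect_gte(connectivity_class(p, g2), connectivity_class(p, g))
})

test_that("canal graphs round-trip through CSV", {
  kinds <- c(R1 = "reservoir", c1 = "canal", p1 = "pond")
  g <- canal_graph(data.frame(source = c("R1", "c1"), target = c("c1", "p1")),
                   kinds)
  f <- withr::local_tempfile(fileext = ".csv")
  el <- igraph::as_data_frame(g$graph, what = "edges")
  utils::write.csv(data.frame(source = el$from, target = el$to,
                              source_kind = unname(kinds[el$from]),
                              target_kind = unname(kinds[el$to])),
                   f, row.names = FALSE)
  g2 <- read_canal_graph(f)
  expect_equal(connectivity_class("p1", g2), 2L)
})

test_that("trophic classes split at 8 and 25 ug/L", {
  expect_equal(trophic_class(26.2), "hypertrophic")
  expect_equal(trophic_class(38.25), "hypertrophic")
  expect_equal(trophic_class(7.9), "sub_eutrophic")
  expect_equal(trophic_class(c(8, 24.9, 25)),
               c("eutrophic", "eutrophic", "hypertrophic"))
  expect_error(trophic_class(0), "positive")
})

test_that("feature assembly joins by pond and validates completeness", {
  ids <- sprintf("p%02d", 1:5)
  vis <- data.frame(pond_id = ids, visibility = 1:5)
  metr <- data.frame(pond_id = ids, road_density = 0.001,
                     urban_ratio = 0.1, river_density_500 = 0,
                     connectivity = c(0, 1, 2, 0, 1), area = 1000)
  attrs <- data.frame(pond_id = ids, chl_a = 10, drained = 0)
  tab <- assemble_feature_table(vis, metr, attrs)
  expect_equal(nrow(tab), 5)
  expect_equal(names(tab)[1:4],
               c("pond_id", "visibility", "road_density", "urban_ratio"))
  expect_error(assemble_feature_table(vis[-3, ], metr, attrs), "p03")
  dup <- rbind(vis, vis[1, ])
  expect_error(assemble_feature_table(dup, metr, attrs), "duplicate")
  attrs2 <- attrs; attrs2$chl_a[2] <- NA
  expect_error(assemble_feature_table(vis, metr, attrs2), "p02")
  # CSV round trip preserves values (densities via the 10^-3 display unit)
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(tab, f)
  back <- read_feature_csv(f)
  expect_equal(back$road_density, tab$road_density, tolerance = 1e-12)
  expect_equal(back$visibility, tab$visibility)
})
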