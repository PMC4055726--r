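test_that("densify_polyline places points at exact arc-length intervals", {
  l <- polyline("a", rbind(c(0, 0), c(250, 0)))
  expect_equal(densify_polyline(l, 100),
               rbind(c(0, 0), c(100, 0), c(200, 0)))
  # shorter than spacing: just the first vertex
  s <- polyline("b", rbind(c(0, 0), c(30, 40)))
  expect_equal(densify_polyline(s, 100), rbind(c(0, 0)))
  # L-shape: third point is 50 m up the second leg
  L <- polyline("c", rbind(c(0, 0), c(150, 0), c(150, 150)))
  expect_equal(densify_polyline(L, 100),
               rbind(c(0, 0), c(100, 0), c(150, 50)))
  # a point at exactly the total length is excluded
  e <- polyline("d", rbind(c(0, 0), c(200, 0)))
  expect_equal(densify_polyline(e, 100), rbind(c(0, 0), c(100, 0)))
  expect_error(densify_polyline(l, 0), "spacing")
  # property: consecutive points are exactly `spacing` apart in arc length
  set.seed(3)
  for (r in 1:5) {
    v <- cbind(cumsum(runif(6, 10, 80)), cumsum(runif(6, -40, 40)))
    pts <- densify_polyline(polyline("p", v), 25)
    gaps <- sqrt(rowSums(diff(pts)^2))
    # straight-segment chords can only shorten at corners, never lengthen
    expect_true(all(gaps <= 25 + 1e-9))
  }
})

test_that("rasterize_polygon uses the cell-centre rule", {
  tpl <- flat_dsm(20)
  sq <- square_poly(x0 = 3, y0 = 4, side = 10)
  m <- rasterize_polygon(sq, tpl)
  expect_equal(sum(m), 100)
  # fully outside
  far <- square_poly(x0 = 100, y0 = 100, side = 5)
  expect_equal(sum(rasterize_polygon(far, tpl)), 0)
  # right triangle with legs 4: compare with the analytic membership of
  # each cell centre (x >= 0, y >= 0, x + y <= 4, boundary inside)
  tri <- simple_polygon("t", rbind(c(0, 0), c(4, 0), c(0, 4)))
  mt <- rasterize_polygon(tri, tpl)
  gg <- expand.grid(r = 1:20, c = 1:20)
  ctr <- cell_centers(tpl, gg$r, gg$c)
  expected <- ctr[, 1] >= 0 & ctr[, 2] >= 0 & ctr[, 1] + ctr[, 2] <= 4
  expect_equal(as.vector(mt[cbind(gg$r, gg$c)]), as.vector(expected))
})

test_that("rasterized area converges to polygon area as cells shrink", {
  poly <- simple_polygon("p", rbind(c(2.2, 1.1), c(11.7, 2.4),
                                    c(13.1, 9.9), c(4.8, 12.3)))
  a <- polygon_area(poly)
  per <- sum(sqrt(rowSums(diff(rbind(poly$exterior,
                                     poly$exterior[1, ]))^2)))
  for (cs in c(1, 0.5, 0.25)) {
    tpl <- flat_dsm(n = round(16 / cs), cell = cs)
    est <- sum(rasterize_polygon(poly, tpl)) * cs^2
    expect_lt(abs(est - a), 2 * per * cs)
  }
})

test_that("buffer_polygon matches the rounded-rectangle closed form", {
  sq <- square_poly(side = 100)
  buf <- buffer_polygon(sq, 500)
  exact <- (100 + 2 * 500)^2 - 100^2 - 4 * (1 - pi / 4) * 500^2
  expect_lt(abs(polygon_area(buf) - exact) / exact, 0.005)
  # ring area tends to 0 with the distance
  expect_lt(polygon_area(buffer_polygon(sq, 0.01)), 100 * 4 * 0.011 * 2)
  expect_error(buffer_polygon(sq, -1), "distance")
  # boundary offset points of a convex polygon fall inside the buffer
  hexv <- cbind(3 + 2 * cos(seq(0, 2 * pi, length.out = 7)[-7]),
                4 + 2 * sin(seq(0, 2 * pi, length.out = 7)[-7]))
  hx <- simple_polygon("h", hexv)
  buf2 <- buffer_polygon(hx, 3)
  mid <- colMeans(hexv)
  out_pts <- t(apply(hexv, 1, function(v)
    v + (v - mid) / sqrt(sum((v - mid)^2)) * 1.5))
  expect_true(all(point_in_polygon(buf2, out_pts[, 1], out_pts[, 2])))
  # the pond surface itself is excluded (ring buffer) ...
  expect_false(point_in_polygon(buf2, mid[1], mid[2]))
  # ... unless the filled variant is requested
  filled <- buffer_polygon(hx, 3, exclude_interior = FALSE)
  expect_true(point_in_polygon(filled, mid[1], mid[2]))
  expect_equal(polygon_area(filled), polygon_area(buf2) + polygon_area(hx),
               tolerance = 1e-9)
})

test_that("clip_length is exact on straight crossings and additive", {
  box <- square_poly(side = 1000)
  expect_equal(clip_length(list(), box), 0)
  crossing <- list(polyline("l", rbind(c(-10, 500), c(1010, 500))))
  expect_equal(clip_length(crossing, box), 1000, tolerance = 1e-9)
  unit <- square_poly(side = 1)
  diagl <- list(polyline("d", rbind(c(-1, -1), c(2, 2))))
  expect_equal(clip_length(diagl, unit), sqrt(2), tolerance = 1e-9)
  # additivity over disjoint regions
  left <- square_poly("L", 0, 0, 500)
  right <- square_poly("R", 500.000001, 0, 499.99)
  l2 <- list(polyline("m", rbind(c(-5, 250), c(1005, 250))))
  la <- clip_length(l2, left); lb <- clip_length(l2, right)
  expect_equal(la + lb, clip_length(l2, box), tolerance = 1e-3)
  # duplicated geometry doubles the clipped length
  expect_equal(clip_length(c(crossing, crossing), box), 2000,
               tolerance = 1e-9)
})

test_that("feature sets enforce unique ids and homogeneous kinds", {
  a <- polyline("x", rbind(c(0, 0), c(1, 0)))
  expect_error(feature_set("roads", list(a, a)), "duplicate")
  expect_error(feature_set("roads", list(a, square_poly())), "single geometry")
  expect_silent(feature_set("roads", list(a)))
  expect_error(simple_polygon("z", rbind(c(0, 0), c(1, 0), c(2, 0))),
               "degenerate|area")
})

test_that("geojson features round-trip", {
  fs <- feature_set("ponds", list(square_poly("p1"),
                                  square_poly("p2", 30, 30, 5)))
  f <- withr::local_tempfile(fileext = ".geojson")
  write_features_geojson(fs, f)
  back <- read_features_geojson(f, "ponds")
  expect_equal(length(back$features), 2)
  expect_equal(back$features[[1]]$id, "p1")
  expect_equal(back$features[[2]]$exterior, fs$features[[2]]$exterior)
  rd <- feature_set("roads", list(polyline("r1", rbind(c(0, 0), c(10, 5)))))
  f2 <- withr::local_tempfile(fileext = ".geojson")
  write_features_geojson(rd, f2)
  back2 <- read_features_geojson(f2, "roads")
  expect_equal(back2$features[[1]]$vertices, rd$features[[1]]$vertices)
})
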