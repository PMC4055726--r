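#' Configuration of the synthetic study landscape
#'
#' Bundles every tunable of the artificial landscape and pond dataset.  The
#' defaults emulate the study conditions the pipeline is meant to model: a
#' 3 km x 3 km planar landscape, 64 ponds with surface areas spanning
#' 685-111,626 m^2, a southern urbanised strip (18% of the extent) backed by
#' farmland and a woodland belt (36%), roads on a jittered grid with
#' observation at 100 m intervals, about half of the ponds supplied by
#' reservoir water (30% directly, 22% indirectly), chlorophyll a spanning
#' 1.9-438.8 ug/L, and 42% of ponds drained in winter.  Presence labels are
#' planted: the bluegill-like species follows connectivity OR a visibility
#' threshold (the 0.75 visibility quantile), the bass-like species a
#' chlorophyll ceiling of 38.25 ug/L gated by a Bernoulli(0.7) introduction
#' event; labels are then flipped with probability `noise_rate`.
#'
#' @param seed master seed; all randomness flows from it through named
#'   substreams (terrain / buildings / roads / ponds / rivers / canals /
#'   attrs / labels).
#' @param extent side length of the square landscape, m.
#' @param cell_size DSM cell size, m; `coarse = TRUE` overrides to 5 m.
#' @param coarse use desk-scale resolution (5 m DSM cells, 20 m land-use
#'   cells) so the full pipeline runs in seconds.
#' @param n_ponds number of ponds.
#' @param pond_area_range min/max pond surface area, m^2 (log-uniform).
#' @param n_hills,hill_height,hill_radius terrain relief controls.
#' @param building_cover fraction of the urban strip covered by building
#'   blocks; `building_height` their height range, m.
#' @param canopy_cover,canopy_height woodland canopy cover fraction and
#'   height range, m.
#' @param road_spacing,urban_road_spacing,road_jitter road-grid controls, m.
#' @param landuse_fracs named fractions (woodland, farmland, urban) summing
#'   to 1.
#' @param n_reservoirs,p_direct,p_indirect canal wiring controls.
#' @param chl_meanlog,chl_sdlog,chl_range chlorophyll a log-normal
#'   parameters and truncation range, ug/L.
#' @param drained_p probability a pond is drained in winter.
#' @param vis_quantile visibility quantile defining the planted visibility
#'   threshold (used when `tau_v` is `NULL`).
#' @param tau_v optional absolute planted visibility threshold (viewshed
#'   points).
#' @param tau_c planted chlorophyll ceiling, ug/L.
#' @param p_intro introduction probability for the bass-like species.
#' @param noise_rate label flip probability.
#' @export
synthetic_config <- function(seed = 1, extent = 3000, cell_size = 1,
                             coarse = FALSE,
                             n_ponds = 64,
                             pond_area_range = c(685, 111626),
                             n_hills = 12, hill_height = c(10, 80),
                             hill_radius = c(150, 600),
                             building_cover = 0.25,
                             building_height = c(5, 15),
                             canopy_cover = 0.7, canopy_height = c(5, 15),
                             road_spacing = 500, urban_road_spacing = 250,
                             road_jitter = 30,
                             landuse_fracs = c(woodland = 0.36,
                                               farmland = 0.46, urban = 0.18),
                             n_reservoirs = 3, p_direct = 0.30,
                             p_indirect = 0.22,
                             chl_meanlog = log(26.2), chl_sdlog = 1.25,
                             chl_range = c(1.9, 438.8),
                             drained_p = 27 / 64,
                             vis_quantile = 0.75, tau_v = NULL,
                             tau_c = 38.25, p_intro = 0.7,
                             noise_rate = 0.10) {
  if (coarse) cell_size <- 5
  landuse_cell <- if (coarse) 20 else 4 * cell_size
  if (abs(sum(landuse_fracs) - 1) > 1e-9)
    stop("landuse_fracs must sum to 1")
  if (extent %% cell_size != 0) stop("extent must be a multiple of cell_size")
  structure(as.list(environment()), class = "synthetic_config")
}

# independent named substreams from one master seed (31-bit)
seed_for <- function(seed, stream) {
  offs <- c(terrain = 1L, buildings = 2L, roads = 3L, ponds = 4L,
            rivers = 5L, canals = 6L, attrs = 7L, labels = 8L)
  (as.integer(seed) %% 2000003L) * 1000L + offs[[stream]]
}

# zone boundaries: urban strip in the south, woodland belt in the north
zone_bounds <- function(config) {
  list(urban_top = config$landuse_fracs[["urban"]] * config$extent,
       wood_bottom = (1 - config$landuse_fracs[["woodland"]]) * config$extent)
}

# road-grid coordinate lines; deterministic given the config seed
road_lines <- function(config) {
  with_seed(seed_for(config$seed, "roads"), {
    zb <- zone_bounds(config)
    sp <- config$road_spacing
    vx <- seq(sp / 2, config$extent - sp / 4, by = sp)
    hy <- seq(sp / 2, config$extent - sp / 4, by = sp)
    vx <- pmin(pmax(vx + stats::runif(length(vx), -1, 1) * config$road_jitter,
                    10), config$extent - 10)
    hy <- pmin(pmax(hy + stats::runif(length(hy), -1, 1) * config$road_jitter,
                    10), config$extent - 10)
    # denser grid inside the urban strip
    uy <- if (zb$urban_top >= config$urban_road_spacing / 2)
      seq(config$urban_road_spacing / 2, zb$urban_top,
          by = config$urban_road_spacing)
    else numeric()
    uy <- setdiff(round(uy, 3), round(hy, 3))
    list(vx = sort(vx), hy = sort(unique(c(hy, uy))), urban_top = zb$urban_top)
  })
}

roads_as_features <- function(config) {
  rl <- road_lines(config)
  feats <- c(
    lapply(seq_along(rl$vx), function(i)
      polyline(sprintf("road_v%02d", i),
               rbind(c(rl$vx[i], 0), c(rl$vx[i], config$extent)))),
    lapply(seq_along(rl$hy), function(i)
      polyline(sprintf("road_h%02d", i),
               rbind(c(0, rl$hy[i]), c(config$extent, rl$hy[i])))))
  feature_set("roads", feats)
}

#' Synthetic terrain (digital surface model)
#'
#' A smooth base relief (sum of seeded Gaussian hills) plus rectangular
#' building blocks inside the urban strip and blocky woodland canopy, both
#' carved away from road corridors and from any polygons in `exclude`
#' (ponds).  Deterministic per config seed.
#'
#' @param config a [synthetic_config()].
#' @param exclude optional list of [simple_polygon()]s kept free of
#'   buildings and canopy (their cells carry the bare relief).
#' @return a [raster_grid()] of surface elevations, m.
#' @export
generate_terrain <- function(config, exclude = list()) {
  cs <- config$cell_size
  n <- as.integer(config$extent / cs)
  xs <- (seq_len(n) - 0.5) * cs
  ys <- (seq_len(n) - 0.5) * cs
  z <- matrix(0, n, n)               # row = south -> north (y), col = x
  with_seed(seed_for(config$seed, "terrain"), {
    if (config$n_hills > 0) {
      hx <- stats::runif(config$n_hills, 0, config$extent)
      hy <- stats::runif(config$n_hills, 0, config$extent)
      hh <- stats::runif(config$n_hills, config$hill_height[1],
                         config$hill_height[2])
      hr <- stats::runif(config$n_hills, config$hill_radius[1],
                         config$hill_radius[2])
      for (i in seq_len(config$n_hills)) {
        sig <- hr[i] / 2
        gy <- exp(-(ys - hy[i])^2 / (2 * sig^2))
        gx <- exp(-(xs - hx[i])^2 / (2 * sig^2))
        z <- z + hh[i] * outer(gy, gx)
      }
    }
  })
  rl <- road_lines(config)
  road_free <- outer(rep(TRUE, n), rep(TRUE, n))
  near_road_x <- vapply(xs, function(x) any(abs(x - rl$vx) < 8), TRUE)
  near_road_y <- vapply(ys, function(y) any(abs(y - rl$hy) < 8), TRUE)
  corridor <- outer(rep(TRUE, n), near_road_x) | outer(near_road_y, rep(TRUE, n))
  excluded <- matrix(FALSE, n, n)
  if (length(exclude)) {
    template <- raster_grid(z, 0, 0, cs)
    for (p in exclude) excluded <- excluded | rasterize_polygon(p, template)
  }
  zb <- zone_bounds(config)
  obst <- matrix(0, n, n)
  with_seed(seed_for(config$seed, "buildings"), {
    # buildings: random blocks until the target cover of the urban strip
    strip_area <- zb$urban_top * config$extent
    target <- config$building_cover * strip_area
    placed <- 0
    guard <- 0
    while (placed < target && guard < 20000) {
      guard <- guard + 1
      w <- stats::runif(1, 12, 40); h <- stats::runif(1, 12, 40)
      bx <- stats::runif(1, 0, config$extent - w)
      by <- stats::runif(1, 0, max(zb$urban_top - h, 1))
      ht <- stats::runif(1, config$building_height[1],
                         config$building_height[2])
      ci <- which(xs >= bx & xs <= bx + w)
      ri <- which(ys >= by & ys <= by + h)
      if (length(ci) && length(ri)) obst[ri, ci] <- pmax(obst[ri, ci], ht)
      placed <- placed + w * h
    }
    # canopy: blocky patches over the woodland belt
    patch <- 40
    np <- ceiling(config$extent / patch)
    on <- matrix(stats::runif(np * np) < config$canopy_cover, np, np)
    phh <- matrix(stats::runif(np * np, config$canopy_height[1],
                               config$canopy_height[2]), np, np)
    pr <- pmin(floor(ys / patch) + 1, np)
    pc <- pmin(floor(xs / patch) + 1, np)
    wood_rows <- which(ys > zb$wood_bottom)
    if (length(wood_rows)) {
      can <- matrix(0, n, n)
      can[wood_rows, ] <- ifelse(on[cbind(rep(pr[wood_rows], n),
                                          rep(pc, each = length(wood_rows)))],
                                 phh[cbind(rep(pr[wood_rows], n),
                                           rep(pc, each = length(wood_rows)))],
                                 0)
      obst <- pmax(obst, can)
    }
  })
  obst[corridor | excluded] <- 0
  raster_grid(z + obst, x_origin = 0, y_origin = 0, cell_size = cs)
}

# one convex pond polygon of exactly the requested area
make_pond_polygon <- function(id, cx, cy, area, aspect, angle, n_vert = 16) {
  th <- seq(0, 2 * pi, length.out = n_vert + 1)[-(n_vert + 1)]
  a <- sqrt(aspect); b <- 1 / sqrt(aspect)
  px <- a * cos(th); py <- b * sin(th)
  rx <- px * cos(angle) - py * sin(angle)
  ry <- px * sin(angle) + py * cos(angle)
  poly_area <- abs(sum(rx * c(ry[-1], ry[1]) - c(rx[-1], rx[1]) * ry)) / 2
  s <- sqrt(area / poly_area)
  simple_polygon(id, cbind(cx + s * rx, cy + s * ry))
}

#' Generate a complete synthetic landscape
#'
#' Places the road grid, non-overlapping convex ponds with log-uniform
#' areas, meandering rivers, the land-use raster (urban strip / farmland /
#' woodland belt / water), the DSM with buildings and canopy, the
#' reservoir-canal graph, and the pond attribute table (chlorophyll a,
#' drainage).  Everything is deterministic given the config seed.
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_landscape` with elements `dsm`,
#'   `roads`, `rivers`, `ponds`, `landuse`, `canals`, `attrs`, `config`.
#' @export
generate_landscape <- function(config) {
  rl <- road_lines(config)
  ponds <- with_seed(seed_for(config$seed, "ponds"), {
    out <- list()
    centers <- matrix(0, 0, 2)
    radii <- numeric()
    lo <- log(config$pond_area_range[1]); hi <- log(config$pond_area_range[2])
    for (i in seq_len(config$n_ponds)) {
      placed <- FALSE
      for (try in seq_len(2000)) {
        area <- exp(stats::runif(1, lo, hi))
        aspect <- stats::runif(1, 1, 2)
        angle <- stats::runif(1, 0, pi)
        R <- sqrt(area / pi) * sqrt(aspect) * 1.1
        margin <- R + 25
        if (2 * margin >= config$extent) next
        cx <- stats::runif(1, margin, config$extent - margin)
        cy <- stats::runif(1, margin, config$extent - margin)
        if (min(abs(cx - rl$vx)) < R + 12 || min(abs(cy - rl$hy)) < R + 12)
          next
        if (nrow(centers) &&
            any(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) <
                radii + R + 20))
          next
        out[[i]] <- make_pond_polygon(sprintf("pond_%03d", i), cx, cy,
                                      area, aspect, angle)
        centers <- rbind(centers, c(cx, cy))
        radii <- c(radii, R)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place pond ", i,
             " after 2000 tries; use fewer or smaller ponds")
    }
    out
  })
  pond_fs <- feature_set("ponds", ponds)

  rivers <- with_seed(seed_for(config$seed, "rivers"), {
    feats <- lapply(1:2, function(i) {
      y0 <- stats::runif(1, 0.25, 0.75) * config$extent
      amp <- stats::runif(1, 100, 300)
      lam <- stats::runif(1, 1200, 2500)
      xs <- seq(0, config$extent, by = 50)
      ys <- y0 + amp * sin(2 * pi * xs / lam + stats::runif(1, 0, 2 * pi)) +
        cumsum(stats::rnorm(length(xs), 0, 4))
      ys <- pmin(pmax(ys, 5), config$extent - 5)
      polyline(sprintf("river_%d", i), cbind(xs, ys))
    })
    feature_set("rivers", feats)
  })

  # land-use category raster
  lc <- config$landuse_cell
  nl <- as.integer(ceiling(config$extent / lc))
  zb <- zone_bounds(config)
  ly <- (seq_len(nl) - 0.5) * lc
  lu <- matrix(landuse_codes()["farmland"], nl, nl)
  lu[ly < zb$urban_top, ] <- landuse_codes()["urban"]
  lu[ly > zb$wood_bottom, ] <- landuse_codes()["woodland"]
  landuse <- raster_grid(lu, 0, 0, lc)
  for (p in ponds) {
    m <- rasterize_polygon(p, landuse)
    landuse$values[m] <- landuse_codes()["water"]
  }

  dsm <- generate_terrain(config, exclude = ponds)

  canals <- with_seed(seed_for(config$seed, "canals"), {
    res_ids <- sprintf("res_%d", seq_len(config$n_reservoirs))
    kinds <- stats::setNames(rep("reservoir", length(res_ids)), res_ids)
    pond_ids <- vapply(ponds, `[[`, "", "id")
    kinds[pond_ids] <- "pond"
    u <- stats::runif(length(pond_ids))
    wiring <- ifelse(u < config$p_direct, "direct",
                     ifelse(u < config$p_direct + config$p_indirect,
                            "indirect", "none"))
    edges <- data.frame(source = character(), target = character())
    direct_ponds <- pond_ids[wiring == "direct"]
    for (p in direct_ponds) {
      res <- res_ids[sample.int(length(res_ids), 1)]
      cn <- paste0("canal_d_", p)
      kinds[cn] <- "canal"
      edges <- rbind(edges, data.frame(source = c(res, cn), target = c(cn, p)))
    }
    for (p in pond_ids[wiring == "indirect"]) {
      cn <- paste0("canal_i_", p)
      kinds[cn] <- "canal"
      if (length(direct_ponds) && stats::runif(1) < 0.5) {
        m <- direct_ponds[sample.int(length(direct_ponds), 1)]
        edges <- rbind(edges, data.frame(source = c(m, cn), target = c(cn, p)))
      } else {
        fl <- paste0("farm_", p)
        cn2 <- paste0("canal_f_", p)
        kinds[fl] <- "farmland"
        kinds[cn2] <- "canal"
        res <- res_ids[sample.int(length(res_ids), 1)]
        edges <- rbind(edges,
                       data.frame(source = c(res, cn2, fl, cn),
                                  target = c(cn2, fl, cn, p)))
      }
    }
    canal_graph(edges, kinds)
  })

  attrs <- with_seed(seed_for(config$seed, "attrs"), {
    n <- length(ponds)
    plo <- stats::plnorm(config$chl_range[1], config$chl_meanlog,
                         config$chl_sdlog)
    phi <- stats::plnorm(config$chl_range[2], config$chl_meanlog,
                         config$chl_sdlog)
    chl <- stats::qlnorm(stats::runif(n, plo, phi), config$chl_meanlog,
                         config$chl_sdlog)
    data.frame(pond_id = vapply(ponds, `[[`, "", "id"),
               chl_a = chl,
               drained = stats::rbinom(n, 1, config$drained_p))
  })

  structure(list(dsm = dsm, roads = roads_as_features(config),
                 rivers = rivers, ponds = pond_fs, landuse = landuse,
                 canals = canals, attrs = attrs, config = config),
            class = "synthetic_landscape")
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat(sprintf("synthetic_landscape: %g m extent, %g m cells, %d ponds, seed %d\n",
              x$config$extent, x$config$cell_size,
              length(x$ponds$features), x$config$seed))
  invisible(x)
}

#' Planted presence labels
#'
#' Applies the planted decision rules to a feature table and flips each
#' label independently with probability `noise_rate`.  The bluegill-like
#' species is present when the pond is connected to a reservoir
#' (connectivity >= 1) OR its visibility reaches `tau_v`; the bass-like
#' species when chlorophyll a is at most `tau_c` AND a Bernoulli(`p_intro`)
#' introduction event occurs.
#'
#' @param features data frame with `visibility`, `connectivity`, `chl_a`.
#' @param rules list with `tau_v` (or `vis_quantile` to derive it),
#'   `tau_c`, `p_intro`.
#' @param noise_rate label flip probability.
#' @param seed integer seed.
#' @return data frame `pond_id, present_bluegill, present_bass` with
#'   attributes `tau_v` and `tau_c`.
#' @export
simulate_presence <- function(features, rules, noise_rate, seed) {
  tau_v <- rules$tau_v
  if (is.null(tau_v))
    tau_v <- stats::quantile(features$visibility, rules$vis_quantile,
                             names = FALSE)
  conn <- as.integer(as.character(features$connectivity))
  a <- conn >= 1 | features$visibility >= tau_v
  with_seed(seed, {
    intro <- stats::runif(nrow(features)) < rules$p_intro
    b <- features$chl_a <= rules$tau_c & intro
    flip_a <- stats::runif(nrow(features)) < noise_rate
    flip_b <- stats::runif(nrow(features)) < noise_rate
    out <- data.frame(pond_id = features$pond_id,
                      present_bluegill = as.integer(xor(a, flip_a)),
                      present_bass = as.integer(xor(b, flip_b)))
    attr(out, "tau_v") <- tau_v
    attr(out, "tau_c") <- rules$tau_c
    out
  })
}

#' Generate the full synthetic study dataset
#'
#' Runs the whole measurement pipeline over a generated landscape:
#' observation points along roads, per-pond viewshed visibility, road
#' density, urban ratio, the river-density profile, connectivity classes,
#' areas, attributes, and finally the planted presence labels.
#'
#' @param config a [synthetic_config()].
#' @param params a [visibility_params()].
#' @return list with `landscape`, `features` (modelling table with labels)
#'   and `truth` (realised `tau_v`, `tau_c`, planted variables per species).
#' @export
generate_study_dataset <- function(config, params = visibility_params()) {
  land <- generate_landscape(config)
  observers <- generate_observer_points(land$roads, land$dsm, params)
  ponds <- land$ponds$features
  vis <- vapply(ponds, function(p) {
    mask <- rasterize_polygon(p, land$dsm)
    cells <- which(mask, arr.ind = TRUE)
    if (!nrow(cells)) return(0L)
    sum(compute_viewshed_counts(land$dsm, observers, params, cells = cells))
  }, 0L)
  vis_df <- data.frame(pond_id = vapply(ponds, `[[`, "", "id"),
                       visibility = vis)
  metr <- lapply(ponds, function(p) {
    prof <- river_density_profile(land$rivers, p)
    out <- data.frame(pond_id = p$id,
                      road_density = road_density(land$roads, p),
                      urban_ratio = urban_ratio(land$landuse, p),
                      connectivity = connectivity_class(p$id, land$canals),
                      area = polygon_area(p))
    for (b in names(prof)) out[[paste0("river_density_", b)]] <- prof[[b]]
    out
  })
  metr <- do.call(rbind, metr)
  features <- assemble_feature_table(vis_df, metr, land$attrs)
  rules <- list(tau_v = config$tau_v, vis_quantile = config$vis_quantile,
                tau_c = config$tau_c, p_intro = config$p_intro)
  labels <- simulate_presence(features, rules, config$noise_rate,
                              seed_for(config$seed, "labels"))
  features <- merge(features, labels, by = "pond_id")
  features <- features[order(features$pond_id), , drop = FALSE]
  rownames(features) <- NULL
  features$connectivity <- factor(features$connectivity, levels = c(0, 1, 2))
  features$drained <- factor(features$drained, levels = c(0, 1))
  list(landscape = land, features = features,
       truth = list(tau_v = attr(labels, "tau_v"),
                    tau_c = attr(labels, "tau_c"),
                    planted = list(bluegill = c("connectivity", "visibility"),
                                   bass = "chl_a")))
}

#' Write a synthetic landscape to plain-text files
#'
#' Writes `dsm.asc`, `landuse.asc`, `roads.geojson`, `rivers.geojson`,
#' `ponds.geojson`, `canals.csv`, `attrs.csv` and `config.json` under `dir`.
#'
#' @param landscape a [generate_landscape()] result.
#' @param dir output directory (created if needed).
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_raster(landscape$dsm, file.path(dir, "dsm.asc"))
  write_raster(landscape$landuse, file.path(dir, "landuse.asc"))
  write_features_geojson(landscape$roads, file.path(dir, "roads.geojson"))
  write_features_geojson(landscape$rivers, file.path(dir, "rivers.geojson"))
  write_features_geojson(landscape$ponds, file.path(dir, "ponds.geojson"))
  g <- landscape$canals
  el <- igraph::as_data_frame(g$graph, what = "edges")
  utils::write.csv(
    data.frame(source = el$from, target = el$to,
               source_kind = unname(g$kinds[el$from]),
               target_kind = unname(g$kinds[el$to])),
    file.path(dir, "canals.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(landscape$attrs, file.path(dir, "attrs.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- landscape$config
  jsonlite::write_json(cfg[setdiff(names(cfg), "")],
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(NULL)
}
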