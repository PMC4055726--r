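#' Polyline in planar metres
#'
#' @param id character id.
#' @param vertices two-column matrix of (x, y), at least two rows,
#'   consecutive vertices distinct.
#' @export
polyline <- function(id, vertices) {
  vertices <- as_coord_matrix(vertices)
  if (nrow(vertices) < 2) stop("polyline needs at least 2 vertices")
  d <- diff(vertices)
  if (any(rowSums(abs(d)) == 0)) stop("polyline has repeated consecutive vertices")
  structure(list(id = as.character(id), vertices = vertices),
            class = "polyline")
}

#' Simple polygon (optionally with holes)
#'
#' Rings are two-column coordinate matrices; the closing vertex may be
#' repeated or omitted (it is normalised away).  Even-odd membership is used
#' throughout, so ring orientation does not matter.
#'
#' @param id character id.
#' @param exterior exterior ring.
#' @param holes optional list of interior rings.
#' @export
simple_polygon <- function(id, exterior, holes = list()) {
  exterior <- normalize_ring(exterior)
  holes <- lapply(holes, normalize_ring)
  if (abs(ring_area(exterior)) <= 0) stop("degenerate polygon: zero area")
  structure(list(id = as.character(id), exterior = exterior, holes = holes),
            class = "simple_polygon")
}

as_coord_matrix <- function(v) {
  v <- as.matrix(v)
  if (ncol(v) != 2) stop("coordinates must be a two-column (x, y) matrix")
  storage.mode(v) <- "double"
  unname(v)
}

normalize_ring <- function(ring) {
  ring <- as_coord_matrix(ring)
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  if (nrow(ring) < 3) stop("ring needs at least 3 distinct vertices")
  ring
}

# signed area of an open ring (shoelace); positive if counter-clockwise
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area
#'
#' Shoelace area of the exterior ring minus any holes, m^2.
#' @param poly a [simple_polygon()].
#' @export
polygon_area <- function(poly) {
  a <- abs(ring_area(poly$exterior))
  if (length(poly$holes))
    a <- a - sum(vapply(poly$holes, function(h) abs(ring_area(h)), 0))
  a
}

#' Polyline length
#' @param line a [polyline()].
#' @return total arc length, m.
#' @export
polyline_length <- function(line) {
  d <- diff(line$vertices)
  sum(sqrt(rowSums(d^2)))
}

#' Points at fixed arc-length intervals along a polyline
#'
#' Emits points at arc-length positions `0, spacing, 2 spacing, ...` measured
#' from the first vertex; the first vertex is always included and positions
#' at or beyond the total length are excluded, so a 250 m line at 100 m
#' spacing yields points at 0, 100 and 200 m.
#'
#' @param line a [polyline()].
#' @param spacing interval, m (> 0).
#' @return two-column matrix of (x, y).
#' @export
densify_polyline <- function(line, spacing) {
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be > 0")
  v <- line$vertices
  seg <- diff(v)
  seglen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  t <- seq(0, by = spacing, length.out = ceiling(total / spacing))
  t <- t[t < total - 1e-9]
  if (!length(t)) t <- 0
  idx <- findInterval(t, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(seg))
  frac <- (t - cum[idx]) / seglen[idx]
  unname(v[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac)
}

# Even-odd membership of points in a set of rings; points exactly on a ring
# edge count as inside (compiled kernel).
points_in_rings <- function(px, py, rings) {
  cpp_points_in_rings(as.numeric(px), as.numeric(py), rings, TRUE)
}

#' Point-in-polygon test
#'
#' Even-odd rule over the exterior and hole rings; boundary points count as
#' inside.
#'
#' @param poly a [simple_polygon()].
#' @param x,y coordinate vectors.
#' @return logical vector.
#' @export
point_in_polygon <- function(poly, x, y) {
  points_in_rings(x, y, c(list(poly$exterior), poly$holes))
}

#' Rasterize a polygon onto a template grid
#'
#' The mask is `TRUE` exactly for cells whose *centre* lies inside the
#' polygon (boundary counts as inside).
#'
#' @param poly a [simple_polygon()].
#' @param template a [raster_grid()] supplying geometry.
#' @return logical matrix with the template's dimensions.
#' @export
rasterize_polygon <- function(poly, template) {
  mask <- matrix(FALSE, template$n_rows, template$n_cols)
  ext <- rbind(poly$exterior, do.call(rbind, c(poly$holes, list(NULL))))
  cs <- template$cell_size
  cmin <- max(1L, floor((min(ext[, 1]) - template$x_origin) / cs - 0.5) + 1L)
  cmax <- min(template$n_cols, ceiling((max(ext[, 1]) - template$x_origin) / cs + 0.5))
  rmin <- max(1L, floor((min(ext[, 2]) - template$y_origin) / cs - 0.5) + 1L)
  rmax <- min(template$n_rows, ceiling((max(ext[, 2]) - template$y_origin) / cs + 0.5))
  if (cmin > cmax || rmin > rmax) return(mask)
  rows <- rmin:rmax; cols <- cmin:cmax
  gg <- expand.grid(r = rows, c = cols)
  ctr <- cell_centers(template, gg$r, gg$c)
  hit <- point_in_polygon(poly, ctr[, 1], ctr[, 2])
  mask[cbind(gg$r, gg$c)] <- hit
  mask
}

#' Outward ring buffer of a convex polygon
#'
#' Returns the region within `distance` outward of the polygon's edge,
#' *excluding* the polygon itself: the result's exterior is the convex
#' offset boundary (edges translated outward, vertices joined by sampled
#' circular arcs) and the original exterior becomes a hole.  Arc sampling
#' keeps the chord sagitta below `arc_tol` (default `distance / 256`, which
#' keeps the area error of a fully rounded corner below 0.5%).
#'
#' @param poly a convex [simple_polygon()] without holes.
#' @param distance buffer distance, m (> 0).
#' @param arc_tol arc approximation tolerance, m.
#' @param exclude_interior keep the polygon itself out of the buffer (ring
#'   buffer, the default); `FALSE` returns the filled offset region.
#' @return a [simple_polygon()] (ring region; its [polygon_area()] is the
#'   ring area).
#' @export
buffer_polygon <- function(poly, distance, arc_tol = distance / 256,
                           exclude_interior = TRUE) {
  if (!is.numeric(distance) || distance <= 0) stop("buffer distance must be > 0")
  if (length(poly$holes)) stop("buffer_polygon expects a polygon without holes")
  ring <- poly$exterior
  if (ring_area(ring) < 0) ring <- ring[nrow(ring):1, , drop = FALSE]  # force CCW
  n <- nrow(ring)
  nxt <- c(2:n, 1)
  ed <- ring[nxt, , drop = FALSE] - ring
  elen <- sqrt(rowSums(ed^2))
  # outward normal of a CCW ring is the direction vector rotated -90 degrees
  nrm <- cbind(ed[, 2], -ed[, 1]) / elen
  cross <- ed[, 1] * ed[nxt, 2] - ed[, 2] * ed[nxt, 1]
  if (any(cross < -1e-9 * elen * elen[nxt]))
    stop("buffer_polygon requires a convex exterior ring")
  dtheta <- 2 * acos(max(0, 1 - min(arc_tol, distance) / distance))
  out <- list()
  for (i in seq_len(n)) {
    prev <- if (i == 1) n else i - 1
    a1 <- atan2(nrm[prev, 2], nrm[prev, 1])
    a2 <- atan2(nrm[i, 2], nrm[i, 1])
    sweep <- (a2 - a1) %% (2 * pi)
    nseg <- max(1, ceiling(sweep / dtheta))
    ang <- a1 + sweep * seq(0, 1, length.out = nseg + 1)
    arc <- cbind(ring[i, 1] + distance * cos(ang),
                 ring[i, 2] + distance * sin(ang))
    out[[i]] <- arc
  }
  exterior <- do.call(rbind, out)
  keep <- c(TRUE, rowSums(abs(diff(exterior))) > 1e-12)
  exterior <- exterior[keep, , drop = FALSE]
  simple_polygon(paste0(poly$id, "_buffer"), exterior,
                 holes = if (exclude_interior) list(ring) else list())
}

#' Total line length inside a region
#'
#' Sums the arc length of every portion of the given polylines that falls
#' inside the region (even-odd membership, holes respected): each segment is
#' cut at every ring-edge crossing and sub-intervals whose midpoints fall
#' inside are summed.  Empty input yields 0; the result is additive over
#' disjoint regions.
#'
#' @param lines a [feature_set()] of polylines, or a list of [polyline()]s.
#' @param region a [simple_polygon()].
#' @return length in m.
#' @export
clip_length <- function(lines, region) {
  feats <- if (inherits(lines, "feature_set")) lines$features else lines
  if (!length(feats)) return(0)
  rings <- c(list(region$exterior), region$holes)
  bb <- apply(do.call(rbind, rings), 2, range)
  segs <- do.call(rbind, lapply(feats, function(ln) {
    v <- ln$vertices
    n <- nrow(v)
    cbind(v[-n, 1], v[-n, 2], v[-1, 1], v[-1, 2])
  }))
  keep <- !(pmax(segs[, 1], segs[, 3]) < bb[1, 1] |
              pmin(segs[, 1], segs[, 3]) > bb[2, 1] |
              pmax(segs[, 2], segs[, 4]) < bb[1, 2] |
              pmin(segs[, 2], segs[, 4]) > bb[2, 2])
  if (!any(keep)) return(0)
  cpp_clip_length(segs[keep, , drop = FALSE], rings)
}

#' Homogeneous collection of vector features
#'
#' @param kind one of `"roads"`, `"rivers"`, `"ponds"`, `"landuse"`.
#' @param features list of [polyline()] or [simple_polygon()] objects with
#'   unique ids.
#' @export
feature_set <- function(kind, features) {
  kind <- match.arg(kind, c("roads", "rivers", "ponds", "landuse"))
  classes <- unique(vapply(features, function(f) class(f)[1], ""))
  if (length(features) && length(classes) != 1)
    stop("feature_set must hold a single geometry kind")
  ids <- vapply(features, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate feature ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(kind = kind, features = features), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set '%s' with %d features\n", x$kind, length(x$features)))
  invisible(x)
}
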