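#' Viewshed analysis parameters
#'
#' @param spacing interval between observation points along roads, m.
#' @param eye_height observer eye height above the surface, m.
#' @param max_distance longest sight-line distance (horizontal), m.
#' @param los_step sight-line sampling step, m; defaults to half the DSM
#'   cell size at use.
#' @export
visibility_params <- function(spacing = 100, eye_height = 1.5,
                              max_distance = 500, los_step = NULL) {
  stopifnot(spacing > 0, eye_height > 0, max_distance > 0,
            is.null(los_step) || los_step > 0)
  structure(list(spacing = spacing, eye_height = eye_height,
                 max_distance = max_distance, los_step = los_step),
            class = "visibility_params")
}

los_step_for <- function(params, dsm) {
  s <- params$los_step
  if (is.null(s)) s <- dsm$cell_size / 2
  if (s > dsm$cell_size) stop("los_step must not exceed the DSM cell size")
  s
}

#' Observation points along roads
#'
#' Densifies every road polyline at `params$spacing` and places an observer
#' at each point, `params$eye_height` above the bilinearly interpolated
#' surface.
#'
#' @param roads a [feature_set()] of kind `"roads"`.
#' @param dsm surface-elevation [raster_grid()].
#' @param params a [visibility_params()].
#' @return data frame with columns `x`, `y`, `eye_z`.
#' @export
generate_observer_points <- function(roads, dsm, params = visibility_params()) {
  ext <- raster_extent(dsm)
  pts <- lapply(roads$features, function(rd) {
    v <- rd$vertices
    if (any(v[, 1] < ext["xmin"]) || any(v[, 1] > ext["xmax"]) ||
        any(v[, 2] < ext["ymin"]) || any(v[, 2] > ext["ymax"]))
      stop("road '", rd$id, "' extends outside the DSM extent")
    densify_polyline(rd, params$spacing)
  })
  pts <- do.call(rbind, c(pts, list(matrix(0, 0, 2))))
  z <- surface_at(dsm, pts[, 1], pts[, 2])
  if (anyNA(z) && nrow(pts))
    stop("observer over nodata surface")
  data.frame(x = pts[, 1], y = pts[, 2], eye_z = z + params$eye_height)
}

#' Line-of-sight test (reference definition)
#'
#' Plain-R reference implementation of the sight-line rule: the surface is
#' sampled by bilinear interpolation every `los_step` strictly between the
#' observer's eye and the target cell centre (endpoints excluded); the target
#' is visible unless some sample lies strictly above the straight line from
#' the eye to the target cell's stored surface elevation.  The observer's own
#' cell is always visible; nodata samples block nothing; a nodata target is
#' never visible.  [compute_viewshed_counts()] uses a compiled kernel with
#' the identical definition; this function is the independent oracle.
#'
#' @param dsm surface [raster_grid()].
#' @param obs list or one-row data frame with `x`, `y`, `eye_z`.
#' @param target_cell `(row, col)` of the target (1-based, row 1 = south).
#' @param params a [visibility_params()].
#' @return logical.
#' @export
line_of_sight <- function(dsm, obs, target_cell, params = visibility_params()) {
  r <- target_cell[[1]]; c <- target_cell[[2]]
  tz <- dsm$values[r, c]
  if (is.na(tz)) return(FALSE)
  step <- los_step_for(params, dsm)
  ctr <- cell_centers(dsm, r, c)
  dx <- ctr[1] - obs$x; dy <- ctr[2] - obs$y
  d <- sqrt(dx^2 + dy^2)
  if (d > params$max_distance + 1e-9)
    stop("target cell beyond max_distance")
  orow <- floor((obs$y - dsm$y_origin) / dsm$cell_size) + 1
  ocol <- floor((obs$x - dsm$x_origin) / dsm$cell_size) + 1
  if (orow == r && ocol == c) return(TRUE)
  if (d <= 0) return(TRUE)
  k <- seq_len(max(0, ceiling((d - 1e-9) / step) - 1))
  if (!length(k)) return(TRUE)
  t <- k * step / d
  t <- t[k * step < d - 1e-9]
  if (!length(t)) return(TRUE)
  sz <- surface_at(dsm, obs$x + dx * t, obs$y + dy * t)
  lz <- obs$eye_z + (tz - obs$eye_z) * t
  !any(sz > lz, na.rm = TRUE)
}

#' Cumulative viewshed counts
#'
#' For each requested cell, counts the observation points within
#' `max_distance` (horizontal distance to the cell centre) whose sight line
#' to the cell is unobstructed under the [line_of_sight()] definition.
#' Computed by a compiled kernel; exact with respect to that definition.
#'
#' @param dsm surface [raster_grid()].
#' @param observers data frame with `x`, `y`, `eye_z`
#'   (see [generate_observer_points()]).
#' @param params a [visibility_params()].
#' @param cells optional two-column matrix of (row, col) targets (1-based);
#'   default all cells.
#' @return if `cells` is `NULL`, a [raster_grid()] of integer counts;
#'   otherwise an integer vector aligned with `cells`.
#' @export
compute_viewshed_counts <- function(dsm, observers,
                                    params = visibility_params(),
                                    cells = NULL) {
  step <- los_step_for(params, dsm)
  full <- is.null(cells)
  if (full)
    cells <- as.matrix(expand.grid(row = seq_len(dsm$n_rows),
                                   col = seq_len(dsm$n_cols)))
  obs <- as.matrix(observers[, c("x", "y", "eye_z"), drop = FALSE])
  counts <- cpp_viewshed_counts(dsm$values, dsm$x_origin, dsm$y_origin,
                                dsm$cell_size, obs,
                                as.integer(cells[, 1] - 1L),
                                as.integer(cells[, 2] - 1L),
                                params$max_distance, step)
  if (!full) return(counts)
  m <- matrix(0L, dsm$n_rows, dsm$n_cols)
  m[cells] <- counts
  raster_grid(m, dsm$x_origin, dsm$y_origin, dsm$cell_size, nodata = -1)
}

#' Reference viewshed counts (independent oracle)
#'
#' Per-cell, per-observer evaluation of [line_of_sight()] in plain R; an
#' independent code path from the compiled kernel behind
#' [compute_viewshed_counts()], used to validate it.
#'
#' @inheritParams compute_viewshed_counts
#' @return a [raster_grid()] of integer counts.
#' @export
viewshed_counts_reference <- function(dsm, observers,
                                      params = visibility_params()) {
  m <- matrix(0L, dsm$n_rows, dsm$n_cols)
  ox <- as.numeric(observers$x)
  oy <- as.numeric(observers$y)
  oz <- as.numeric(observers$eye_z)
  for (r in seq_len(dsm$n_rows)) {
    for (c in seq_len(dsm$n_cols)) {
      ctr <- cell_centers(dsm, r, c)
      cnt <- 0L
      for (j in seq_along(ox)) {
        o <- list(x = ox[j], y = oy[j], eye_z = oz[j])
        if ((ctr[1] - o$x)^2 + (ctr[2] - o$y)^2 > params$max_distance^2) next
        if (line_of_sight(dsm, o, c(r, c), params)) cnt <- cnt + 1L
      }
      m[r, c] <- cnt
    }
  }
  raster_grid(m, dsm$x_origin, dsm$y_origin, dsm$cell_size, nodata = -1)
}

#' Pond visibility score (viewshed points)
#'
#' Sums the viewshed counts of all cells whose centres fall inside the pond
#' polygon: the pond's visibility score.
#'
#' @param counts a count [raster_grid()] from [compute_viewshed_counts()].
#' @param pond a [simple_polygon()].
#' @return non-negative integer.
#' @export
pond_visibility <- function(counts, pond) {
  mask <- rasterize_polygon(pond, counts)
  ext <- raster_extent(counts)
  bb <- apply(pond$exterior, 2, range)
  if (bb[1, 1] > ext["xmax"] || bb[2, 1] < ext["xmin"] ||
      bb[1, 2] > ext["ymax"] || bb[2, 2] < ext["ymin"])
    stop("pond '", pond$id, "' lies entirely outside the count grid")
  sum(counts$values[mask], na.rm = TRUE)
}
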