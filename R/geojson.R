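#' Read a GeoJSON FeatureCollection of lines or polygons
#'
#' Supports `LineString` and `Polygon` geometries; each feature's id is taken
#' from its `id` member or an `id` property.  Coordinates are planar metres.
#'
#' @param path GeoJSON file.
#' @param kind the [feature_set()] kind to attach.
#' @return a [feature_set()].
#' @export
read_features_geojson <- function(path, kind) {
  if (!file.exists(path)) stop("no such file: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  feats <- lapply(seq_along(gj$features), function(i) {
    f <- gj$features[[i]]
    id <- f$id
    if (is.null(id)) id <- f$properties$id
    if (is.null(id)) id <- as.character(i)
    g <- f$geometry
    coords_to_matrix <- function(cc)
      do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))
    switch(g$type,
      LineString = polyline(id, coords_to_matrix(g$coordinates)),
      Polygon = {
        rings <- lapply(g$coordinates, coords_to_matrix)
        simple_polygon(id, rings[[1]],
                       holes = if (length(rings) > 1) rings[-1] else list())
      },
      stop("unsupported geometry type: ", g$type))
  })
  feature_set(kind, feats)
}

#' Write a feature set as GeoJSON
#'
#' @param fs a [feature_set()].
#' @param path output file.
#' @export
write_features_geojson <- function(fs, path) {
  close_ring <- function(r) rbind(r, r[1, , drop = FALSE])
  mat_to_coords <- function(m) lapply(seq_len(nrow(m)), function(i) m[i, ])
  features <- lapply(fs$features, function(f) {
    geom <- if (inherits(f, "polyline")) {
      list(type = "LineString", coordinates = mat_to_coords(f$vertices))
    } else {
      rings <- c(list(f$exterior), f$holes)
      list(type = "Polygon",
           coordinates = lapply(rings, function(r) mat_to_coords(close_ring(r))))
    }
    list(type = "Feature", properties = list(id = f$id), geometry = geom)
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
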