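#' Road density around a pond
#'
#' Total road length inside the ring buffer (`buffer_m` outward of the pond
#' edge, pond surface excluded) divided by the ring area.
#'
#' @param roads a [feature_set()] of roads.
#' @param pond a [simple_polygon()].
#' @param buffer_m buffer distance, m.
#' @return density in m/m^2.
#' @export
road_density <- function(roads, pond, buffer_m = 500) {
  buf <- buffer_polygon(pond, buffer_m)
  clip_length(roads, buf) / polygon_area(buf)
}

#' Urban land-use ratio around a pond
#'
#' Fraction of the ring buffer covered by urban land, computed on a
#' category raster: urban cells with centres inside the buffer over all
#' cells with centres inside the buffer.
#'
#' @param landuse category [raster_grid()]; cell values are codes of
#'   [landuse_codes()].
#' @param pond a [simple_polygon()].
#' @param buffer_m buffer distance, m.
#' @return fraction in \[0, 1\].
#' @export
urban_ratio <- function(landuse, pond, buffer_m = 500) {
  codes <- unique(as.vector(landuse$values))
  codes <- codes[!is.na(codes)]
  if (!all(codes %in% landuse_codes()))
    stop("unknown land-use category codes: ",
         paste(setdiff(codes, landuse_codes()), collapse = ", "))
  buf <- buffer_polygon(pond, buffer_m)
  mask <- rasterize_polygon(buf, landuse)
  n_in <- sum(mask)
  if (n_in == 0) return(0)
  sum(landuse$values[mask] == landuse_codes()["urban"], na.rm = TRUE) / n_in
}

#' Land-use category codes
#'
#' Integer codes used in category rasters: woodland 1, farmland 2, urban 3,
#' water 4.
#' @return named integer vector.
#' @export
landuse_codes <- function() {
  c(woodland = 1L, farmland = 2L, urban = 3L, water = 4L)
}

#' River-density profile over graded buffers
#'
#' River length per ring-buffer area for each buffer distance.
#'
#' @param rivers a [feature_set()] of rivers.
#' @param pond a [simple_polygon()].
#' @param buffers strictly increasing positive distances, m.
#' @return named numeric vector of densities (m/m^2), one per buffer.
#' @export
river_density_profile <- function(rivers, pond,
                                  buffers = c(5, 10, 25, 50, 100, 250, 500, 1000)) {
  if (any(buffers <= 0) || any(diff(buffers) <= 0))
    stop("buffers must be strictly increasing and positive")
  out <- vapply(buffers, function(b) {
    buf <- buffer_polygon(pond, b)
    clip_length(rivers, buf) / polygon_area(buf)
  }, 0)
  names(out) <- as.character(buffers)
  out
}

#' Canal-network graph
#'
#' Directed water-flow graph over reservoirs, canals, ponds and farmland
#' parcels.
#'
#' @param edges data frame with columns `source`, `target`.
#' @param kinds named character vector mapping node id to kind
#'   (`"reservoir"`, `"canal"`, `"pond"`, `"farmland"`).
#' @export
canal_graph <- function(edges, kinds) {
  stopifnot(all(c("source", "target") %in% names(edges)))
  ids <- unique(c(as.character(edges$source), as.character(edges$target),
                  names(kinds)))
  if (!all(ids %in% names(kinds)))
    stop("node kinds missing for: ",
         paste(setdiff(ids, names(kinds)), collapse = ", "))
  if (!all(kinds %in% c("reservoir", "canal", "pond", "farmland")))
    stop("unknown node kind")
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$source),
               to = as.character(edges$target)),
    directed = TRUE,
    vertices = data.frame(name = names(kinds), kind = unname(kinds)))
  structure(list(graph = g, kinds = kinds), class = "canal_graph")
}

#' Read a canal edge list from CSV
#'
#' Columns `source, target, source_kind, target_kind`.
#' @param path CSV file.
#' @return a [canal_graph()].
#' @export
read_canal_graph <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  kinds <- c(stats::setNames(df$source_kind, df$source),
             stats::setNames(df$target_kind, df$target))
  kinds <- kinds[!duplicated(names(kinds))]
  canal_graph(df[, c("source", "target")], kinds)
}

#' Reservoir-connectivity class of a pond
#'
#' 2 if reservoir water reaches the pond by a directed path whose
#' intermediate nodes are canals only (direct supply); 1 if the pond is
#' reachable from some reservoir but only through intermediate ponds or
#' farmland (indirect); 0 if unreachable.  A pond with both a direct and a
#' mediated path is class 2.
#'
#' @param pond_id pond node id.
#' @param graph a [canal_graph()].
#' @return integer 0, 1 or 2.
#' @export
connectivity_class <- function(pond_id, graph) {
  pond_id <- as.character(pond_id)
  if (!pond_id %in% names(graph$kinds)) stop("unknown pond id: ", pond_id)
  g <- graph$graph
  kinds <- graph$kinds
  reservoirs <- names(kinds)[kinds == "reservoir"]
  if (!length(reservoirs)) return(0L)
  reach_from <- function(gg) {
    if (!pond_id %in% igraph::V(gg)$name) return(FALSE)
    res_in <- intersect(reservoirs, igraph::V(gg)$name)
    if (!length(res_in)) return(FALSE)
    d <- igraph::distances(gg, v = res_in, to = pond_id, mode = "out")
    any(is.finite(d))
  }
  # direct: only reservoirs, canals and the pond itself may appear on the path
  keep <- names(kinds)[kinds %in% c("reservoir", "canal") |
                         names(kinds) == pond_id]
  direct <- reach_from(igraph::induced_subgraph(g, intersect(keep, igraph::V(g)$name)))
  if (direct) return(2L)
  if (reach_from(g)) return(1L)
  0L
}

#' Trophic state from chlorophyll a
#'
#' Hypertrophic at 25 ug/L and above, eutrophic in 8-25 ug/L,
#' sub-eutrophic below 8 ug/L.
#'
#' @param chl_a chlorophyll a concentration, ug/L (> 0); vectorised.
#' @return character vector of labels.
#' @export
trophic_class <- function(chl_a) {
  if (any(!is.finite(chl_a)) || any(chl_a <= 0))
    stop("chl_a must be positive")
  ifelse(chl_a >= 25, "hypertrophic",
         ifelse(chl_a >= 8, "eutrophic", "sub_eutrophic"))
}

#' Assemble the pond modelling table
#'
#' Joins the visibility scores, landscape metrics and pond attributes into
#' one record per pond with a deterministic column order.
#'
#' @param visibility data frame `pond_id, visibility`.
#' @param metrics data frame with `pond_id`, `road_density`, `urban_ratio`,
#'   `river_density_<b>` for each buffer, `connectivity`, `area`.
#' @param attributes data frame with `pond_id`, `chl_a`, `drained` and any
#'   presence columns (`present_*`).
#' @return data frame, one row per pond, ordered by `pond_id`.
#' @export
assemble_feature_table <- function(visibility, metrics, attributes) {
  parts <- list(visibility = visibility, metrics = metrics,
                attributes = attributes)
  ids <- lapply(parts, function(p) as.character(p$pond_id))
  for (nm in names(parts)) {
    if (anyDuplicated(ids[[nm]]))
      stop("duplicate pond ids in ", nm, " input: ",
           paste(unique(ids[[nm]][duplicated(ids[[nm]])]), collapse = ", "))
  }
  universe <- sort(unique(unlist(ids)))
  for (nm in names(parts)) {
    missing <- setdiff(universe, ids[[nm]])
    if (length(missing))
      stop("ponds missing from ", nm, " input: ",
           paste(missing, collapse = ", "))
  }
  out <- merge(merge(visibility, metrics, by = "pond_id"), attributes,
               by = "pond_id")
  out <- out[order(as.character(out$pond_id)), , drop = FALSE]
  rownames(out) <- NULL
  required <- c("visibility", "road_density", "urban_ratio", "connectivity",
                "area", "chl_a", "drained")
  miss <- setdiff(required, names(out))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(out[required]))
    stop("missing values for ponds: ",
         paste(out$pond_id[!stats::complete.cases(out[required])],
               collapse = ", "))
  lead <- c("pond_id", "visibility", "road_density", "urban_ratio",
            grep("^river_density_", names(out), value = TRUE),
            "connectivity", "area", "chl_a", "drained")
  out[, c(lead, setdiff(names(out), lead)), drop = FALSE]
}

#' Write the feature table as CSV
#'
#' Road and river densities are exported in the display unit of
#' 10^-3 m/m^2 (column names carry the `_e3` suffix); the in-memory table
#' keeps plain m/m^2.
#'
#' @param features feature table from [assemble_feature_table()].
#' @param path output CSV.
#' @export
write_feature_csv <- function(features, path) {
  out <- features
  dens <- grep("^(road_density|river_density_)", names(out), value = TRUE)
  for (cc in dens) out[[cc]] <- out[[cc]] * 1e3
  names(out)[names(out) %in% dens] <- paste0(dens, "_e3")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Read a feature CSV written by [write_feature_csv()]
#' @param path CSV file.
#' @return feature table in internal units (densities m/m^2).
#' @export
read_feature_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  dens <- grep("^(road_density|river_density_).*_e3$", names(out), value = TRUE)
  for (cc in dens) out[[cc]] <- out[[cc]] / 1e3
  names(out)[names(out) %in% dens] <- sub("_e3$", "", dens)
  out
}
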