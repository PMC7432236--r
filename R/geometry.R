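# Planar rectangle geometry. All coordinates live in a local projected metric
# frame; buildings, zones and grid cells are axis-aligned rectangles, so
# areas and intersections are exact.

rect <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax >= xmin, ymax >= ymin)
  c(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax)
}

rect_area <- function(r) {
  unname((r[["xmax"]] - r[["xmin"]]) * (r[["ymax"]] - r[["ymin"]]))
}

# Intersection area of two axis-aligned rectangles (exact; 0 if disjoint).
rect_intersection_area <- function(a, b) {
  dx <- min(a[["xmax"]], b[["xmax"]]) - max(a[["xmin"]], b[["xmin"]])
  dy <- min(a[["ymax"]], b[["ymax"]]) - max(a[["ymin"]], b[["ymin"]])
  if (dx <= 0 || dy <= 0) return(0)
  dx * dy
}

rect_centroid <- function(r) {
  c(x = (r[["xmin"]] + r[["xmax"]]) / 2, y = (r[["ymin"]] + r[["ymax"]]) / 2)
}

rect_from_row <- function(df, i) {
  rect(df$xmin[i], df$ymin[i], df$xmax[i], df$ymax[i])
}

rect_polygon_coords <- function(r) {
  # closed ring, counter-clockwise (GeoJSON convention)
  list(list(
    c(r[["xmin"]], r[["ymin"]]), c(r[["xmax"]], r[["ymin"]]),
    c(r[["xmax"]], r[["ymax"]]), c(r[["xmin"]], r[["ymax"]]),
    c(r[["xmin"]], r[["ymin"]])
  ))
}

#' Write rectangles with attributes as a GeoJSON FeatureCollection
#'
#' Geometry columns `xmin`, `ymin`, `xmax`, `ymax` become Polygon features;
#' every other column becomes a feature property. Coordinates are in the
#' local planar metric frame of the scene (no CRS is attached).
#'
#' @param df data frame with rectangle bounds and attribute columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geojson_rects <- function(df, path) {
  geom_cols <- c("xmin", "ymin", "xmax", "ymax")
  stopifnot(all(geom_cols %in% names(df)))
  prop_cols <- setdiff(names(df), geom_cols)
  features <- lapply(seq_len(nrow(df)), function(i) {
    r <- rect_from_row(df, i)
    props <- as.list(df[i, prop_cols, drop = FALSE])
    props <- lapply(props, function(v) if (is.factor(v)) as.character(v) else v)
    list(
      type = "Feature",
      properties = props,
      geometry = list(type = "Polygon", coordinates = rect_polygon_coords(r))
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
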