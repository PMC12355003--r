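# Planar polygon and polyline helpers. Polygons are two-column matrices
# (x, y) of vertices; the closing edge back to vertex 1 is implicit.
# Polylines use the same representation without closure.

#' Point-in-polygon test
#'
#' Even-odd ray casting; points exactly on a boundary edge count as inside
#' (the test is used for HBA membership, where the ban applies on the
#' boundary).
#'
#' @param x,y point coordinates (equal-length vectors).
#' @param poly two-column matrix of polygon vertices.
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  stopifnot(n >= 3L, ncol(poly) == 2L, length(x) == length(y))
  px <- poly[, 1]; py <- poly[, 2]
  qx <- px[c(2:n, 1)]; qy <- py[c(2:n, 1)]
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  for (e in seq_len(n)) {
    x1 <- px[e]; y1 <- py[e]; x2 <- qx[e]; y2 <- qy[e]
    # boundary: collinear and within the segment's bounding box
    cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    onb <- abs(cross) <= 1e-9 * max(1, abs(x2 - x1) + abs(y2 - y1)) &
      x >= pmin(x1, x2) - 1e-12 & x <= pmax(x1, x2) + 1e-12 &
      y >= pmin(y1, y2) - 1e-12 & y <= pmax(y1, y2) + 1e-12
    on_edge <- on_edge | onb
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' @rdname point_in_polygon
#' @return `point_in_any_polygon()`: logical vector, `TRUE` where the point
#'   falls in at least one polygon of the list.
#' @export
point_in_any_polygon <- function(x, y, polys) {
  hit <- rep(FALSE, length(x))
  for (p in polys) hit <- hit | point_in_polygon(x, y, p)
  hit
}

polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  i2 <- c(2:n, 1)
  abs(sum(poly[, 1] * poly[i2, 2] - poly[i2, 1] * poly[, 2])) / 2
}

#' Rasterize polygons to a binary mask
#'
#' Cell membership is decided at the cell center (the package-wide
#' convention for categorical layers).
#'
#' @param polys list of two-column vertex matrices.
#' @param template a [grid_raster()] defining the target grid.
#' @return a [grid_raster()] with values in {0, 1}.
#' @export
rasterize_polygons <- function(polys, template) {
  cc <- cell_centers(template)
  xs <- rep(cc$x, each = template$n_rows)
  ys <- rep(cc$y, times = template$n_cols)
  hit <- point_in_any_polygon(xs, ys, polys)
  grid_raster(matrix(as.numeric(hit), template$n_rows, template$n_cols),
              origin = c(template$origin_x, template$origin_y),
              cell_size = template$cell_size)
}

# Cells crossed by a set of polylines: points are sampled along each
# segment at cell_size/4 spacing and mapped to owning cells.
rasterize_polylines <- function(lines, template) {
  cs <- template$cell_size
  hits <- matrix(FALSE, template$n_rows, template$n_cols)
  for (ln in lines) {
    ln <- as.matrix(ln)
    for (i in seq_len(nrow(ln) - 1L)) {
      p <- ln[i, ]; q <- ln[i + 1L, ]
      len <- sqrt(sum((q - p)^2))
      n <- max(2L, ceiling(len / (cs / 4)) + 1L)
      t <- seq(0, 1, length.out = n)
      xs <- p[1] + t * (q[1] - p[1]); ys <- p[2] + t * (q[2] - p[2])
      cc <- floor((xs - template$origin_x) / cs) + 1L
      rr <- floor((ys - template$origin_y) / cs) + 1L
      ok <- cc >= 1L & cc <= template$n_cols & rr >= 1L & rr <= template$n_rows
      hits[cbind(rr[ok], cc[ok])] <- TRUE
    }
  }
  hits
}

#' Read and write GeoJSON vector layers
#'
#' Minimal GeoJSON support for the package's own polygon/polyline layers
#' (planar coordinates in meters, no CRS handling).
#'
#' @param geoms list of two-column vertex matrices.
#' @param type `"Polygon"` or `"LineString"`.
#' @param path file path.
#' @export
write_geojson <- function(geoms, type = c("Polygon", "LineString"), path) {
  type <- match.arg(type)
  feats <- lapply(geoms, function(g) {
    g <- as.matrix(g)
    coords <- lapply(seq_len(nrow(g)), function(i) c(g[i, 1], g[i, 2]))
    if (type == "Polygon") {
      if (!all(g[1, ] == g[nrow(g), ])) coords <- c(coords, coords[1])
      coords <- list(coords)
    }
    list(type = "Feature", properties = NULL,
         geometry = list(type = type, coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_geojson
#' @return `read_geojson()`: list of two-column vertex matrices.
#' @export
read_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  lapply(fc$features, function(f) {
    geom <- f$geometry
    coords <- geom$coordinates
    if (identical(geom$type, "Polygon")) coords <- coords[[1]]
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    # drop the duplicated closing vertex of polygons
    if (identical(geom$type, "Polygon") && nrow(m) > 1 &&
        all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  })
}
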