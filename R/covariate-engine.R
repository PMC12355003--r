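#' Slope from a DEM (Horn's method)
#'
#' Horn 3x3 finite-difference gradient with edge cells using clamped
#' (replicated) neighbours; slope in degrees, `atan(|grad z|)`. Any
#' `NA` in a cell's 3x3 window propagates to `NA`.
#'
#' @param elevation a [grid_raster()] DEM in meters; at least 3x3 cells.
#' @return a [grid_raster()] of slope in `[0, 90)` degrees.
#' @export
slope_from_dem <- function(elevation) {
  if (elevation$n_rows < 3L || elevation$n_cols < 3L)
    stop2("slope needs a DEM of at least 3x3 cells")
  Z <- elevation$values
  cs <- elevation$cell_size
  nr <- nrow(Z); nc <- ncol(Z)
  up <- c(2:nr, nr); dn <- c(1, 1:(nr - 1))   # clamped row shifts (north/south)
  rt <- c(2:nc, nc); lf <- c(1, 1:(nc - 1))   # clamped col shifts (east/west)
  # neighbours named by compass direction; row 1 is the southern edge
  zN <- Z[up, ]; zS <- Z[dn, ]
  zE <- Z[, rt]; zW <- Z[, lf]
  zNE <- Z[up, rt]; zNW <- Z[up, lf]; zSE <- Z[dn, rt]; zSW <- Z[dn, lf]
  dzdx <- ((zNE + 2 * zE + zSE) - (zNW + 2 * zW + zSW)) / (8 * cs)
  dzdy <- ((zNE + 2 * zN + zNW) - (zSE + 2 * zS + zSW)) / (8 * cs)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  slope[is.na(Z)] <- NA_real_            # nodata center -> nodata out
  grid_raster(slope, origin = c(elevation$origin_x, elevation$origin_y),
              cell_size = elevation$cell_size)
}

#' Topography-aware path distance from trails
#'
#' Multi-source shortest-path distance on the 8-connected cell graph.
#' The weight of an edge between adjacent cell centers is the surface
#' length `sqrt(planar^2 + delta_elevation^2)` (planar = cell size, or
#' cell size * sqrt(2) diagonally), so distances grow in steep terrain —
#' the path-distance notion of GIS cost surfaces, as opposed to planar
#' Euclidean distance. Sources are all cells intersected by a trail
#' polyline (distance 0 there).
#'
#' @param trails list of polyline vertex matrices.
#' @param elevation a [grid_raster()] DEM.
#' @return a [grid_raster()] of distances in meters.
#' @export
trail_path_distance <- function(trails, elevation) {
  src <- rasterize_polylines(trails, elevation)
  if (!any(src)) stop2("no trail intersects the raster extent")
  nr <- elevation$n_rows; nc <- elevation$n_cols
  cs <- elevation$cell_size
  Z <- elevation$values
  id <- function(r, c) (c - 1L) * nr + r
  edges <- list(); wts <- list(); k <- 0L
  moves <- list(c(1L, 0L, cs), c(0L, 1L, cs),
                c(1L, 1L, cs * sqrt(2)), c(1L, -1L, cs * sqrt(2)))
  for (mv in moves) {
    dr <- mv[1]; dc <- mv[2]; planar <- mv[3]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq(1L - dc, nc)
    from_r <- rep(r1, times = length(c1)); from_c <- rep(c1, each = length(r1))
    to_r <- from_r + dr; to_c <- from_c + dc
    dz <- Z[cbind(to_r, to_c)] - Z[cbind(from_r, from_c)]
    k <- k + 1L
    edges[[k]] <- rbind(id(from_r, from_c), id(to_r, to_c))
    wts[[k]] <- sqrt(planar^2 + dz^2)
  }
  ev <- as.vector(do.call(cbind, edges))
  w <- unlist(wts)
  # one virtual super-source tied to every trail cell at zero cost turns
  # the multi-source problem into a single Dijkstra run
  super <- nr * nc + 1L
  src_ids <- which(as.vector(src))
  ev <- c(ev, as.vector(rbind(rep(super, length(src_ids)), src_ids)))
  w <- c(w, rep(0, length(src_ids)))
  g <- igraph::make_graph(ev, n = super, directed = FALSE)
  d <- igraph::distances(g, v = super, weights = w)[1, seq_len(nr * nc)]
  grid_raster(matrix(d, nr, nc),
              origin = c(elevation$origin_x, elevation$origin_y),
              cell_size = cs)
}

#' Build the covariate stack from a world bundle
#'
#' Assembles the aligned raster stack used by all model stages:
#' tree cover (%), trail path distance (m), slope (deg), elevation (m) and
#' the binary HBA mask, plus landscape-wide mean/sd of the continuous
#' layers (attribute `landscape_stats`), which define the simulator's
#' standardized scale.
#'
#' @param world a `world_bundle` from [generate_landscape()].
#' @return named list of [grid_raster()]s with class `covariate_stack`.
#' @export
build_covariate_stack <- function(world) {
  elev <- world$elevation
  stack <- list(
    tree_cover = world$tree_cover,
    trail_distance = trail_path_distance(world$trail_lines, elev),
    slope = slope_from_dem(elev),
    elevation = elev,
    hba_mask = rasterize_polygons(world$hba_polygons, elev))
  stopifnot(all(vapply(stack, same_grid, logical(1), b = elev)))
  cont <- c("tree_cover", "trail_distance", "slope", "elevation")
  stats_tab <- t(vapply(cont, function(nm) {
    v <- as.vector(stack[[nm]]$values)
    c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
  }, c(mean = 0, sd = 0)))
  attr(stack, "landscape_stats") <- stats_tab
  class(stack) <- "covariate_stack"
  stack
}

#' Extract covariate values at points
#'
#' Continuous layers are sampled bilinearly, the categorical HBA mask at
#' the owning cell. Points outside the extent yield `NA`, which marks the
#' design row for removal downstream.
#'
#' @param points two-column matrix/data.frame of positions.
#' @param stack a [build_covariate_stack()] result.
#' @return data.frame with one column per layer.
#' @export
extract_covariates <- function(points, stack) {
  pts <- as.matrix(points[, 1:2, drop = FALSE])
  out <- data.frame(
    tree_cover = raster_extract(stack$tree_cover, pts[, 1], pts[, 2]),
    trail_distance = raster_extract(stack$trail_distance, pts[, 1], pts[, 2]),
    slope = raster_extract(stack$slope, pts[, 1], pts[, 2]),
    elevation = raster_extract(stack$elevation, pts[, 1], pts[, 2]),
    hba = raster_extract(stack$hba_mask, pts[, 1], pts[, 2], method = "nearest"))
  out
}

#' Standardize continuous covariates over the rows of one model fit
#'
#' Centers and scales each named continuous covariate over *all* supplied
#' rows (used and available pooled — the rows entering one fit, not the
#' whole landscape), and records the table needed to back-transform and to
#' define the "average habitat" reference (0 on the standardized scale).
#'
#' @param rows data.frame of design rows.
#' @param covariates names of the continuous columns to scale.
#' @return `rows` with scaled columns; the standardization table (columns
#'   `mean`, `sd`, rownames = covariate) is attached as attribute
#'   `standardization`.
#' @export
zstandardize <- function(rows, covariates = c("tree_cover", "trail_distance",
                                              "slope", "elevation")) {
  tab <- matrix(NA_real_, length(covariates), 2,
                dimnames = list(covariates, c("mean", "sd")))
  for (nm in covariates) {
    v <- rows[[nm]]
    m <- mean(v, na.rm = TRUE); s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop2("covariate '", nm, "' is constant over the fit rows; ",
            "it cannot be standardized (or identified)")
    rows[[nm]] <- (v - m) / s
    tab[nm, ] <- c(m, s)
  }
  attr(rows, "standardization") <- tab
  rows
}

#' @rdname zstandardize
#' @param x standardized values; `table` the attached standardization table;
#'   `covariate` the row name to use.
#' @return `unstandardize()`: values on the natural scale.
#' @export
unstandardize <- function(x, table, covariate) {
  x * table[covariate, "sd"] + table[covariate, "mean"]
}
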