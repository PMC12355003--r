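#' Kernel utilization distribution
#'
#' Isotropic bivariate Gaussian kernel density of a point set, evaluated at
#' the cell centers of a regular grid and normalized so that
#' `sum(density) * cell_area = 1`. The automatic bandwidth is the reference
#' rule `h = sigma * n^(-1/6)` with
#' `sigma = sqrt((var(x) + var(y)) / 2)`.
#'
#' @param points two-column matrix or data.frame of positions (meters).
#' @param grid a [grid_raster()] template, or `NULL` to span the points
#'   with `margin` on each side at resolution `cell_size`.
#' @param bandwidth kernel sd in meters, or `"auto"` for the reference rule.
#' @param cell_size,margin grid construction parameters when `grid` is
#'   `NULL`; the default margin is three bandwidths, keeping essentially
#'   all kernel mass on the grid.
#' @return a `utilization_distribution`: list with `grid` (a
#'   [grid_raster()] of densities, 1/m^2) and `bandwidth` (m).
#' @export
kde_ud <- function(points, grid = NULL, bandwidth = "auto",
                   cell_size = NULL, margin = NULL) {
  pts <- as.matrix(points[, 1:2])
  n <- nrow(pts)
  if (n < 5L) stop2("kernel UD needs at least 5 points")
  sigma <- sqrt((stats::var(pts[, 1]) + stats::var(pts[, 2])) / 2)
  if (sigma == 0) stop2("degenerate input: all points identical (zero variance)")
  h <- if (identical(bandwidth, "auto")) sigma * n^(-1 / 6) else as.numeric(bandwidth)
  if (h <= 0) stop2("bandwidth must be positive")
  if (is.null(grid)) {
    if (is.null(margin)) margin <- 3 * h
    if (is.null(cell_size)) cell_size <- max(h / 4, 1e-6)
    xr <- range(pts[, 1]) + c(-margin, margin)
    yr <- range(pts[, 2]) + c(-margin, margin)
    nc <- max(8L, ceiling(diff(xr) / cell_size))
    nr <- max(8L, ceiling(diff(yr) / cell_size))
    grid <- grid_raster(matrix(0, nr, nc), origin = c(xr[1], yr[1]),
                        cell_size = cell_size)
  }
  cc <- cell_centers(grid)
  # MASS::kde2d evaluates a Gaussian product kernel with sd = h/4 on an
  # equally spaced grid; lims are set to the cell-center range so its grid
  # coincides with ours.
  kd <- MASS::kde2d(pts[, 1], pts[, 2], h = 4 * h,
                    n = c(grid$n_cols, grid$n_rows),
                    lims = c(range(cc$x), range(cc$y)))
  dens <- t(kd$z)                      # -> rows = y (south first), cols = x
  area <- grid$cell_size^2
  tot <- sum(dens) * area
  if (tot <= 0) stop2("all density mass fell outside the grid")
  dens <- dens / tot
  structure(list(grid = grid_raster(dens, origin = c(grid$origin_x, grid$origin_y),
                                    cell_size = grid$cell_size),
                 bandwidth = h),
            class = "utilization_distribution")
}

#' Isopleth region of a utilization distribution
#'
#' The smallest set of grid cells (highest density first, ties broken by
#' grid index) whose cumulative mass reaches `level` — the conventional
#' kernel home-range polygon at, e.g., the 99 % level.
#'
#' @param ud a [kde_ud()] result.
#' @param level mass fraction in (0, 1).
#' @return an `isopleth_region`: list with `level`, `cells` (two-column
#'   matrix of row/col indices), `cell_xy` (their center coordinates),
#'   `mass` (enclosed mass), `area_m2`, and the parent `grid` geometry.
#' @export
isopleth_region <- function(ud, level = 0.99) {
  if (!(level > 0 && level < 1)) stop2("isopleth level must lie in (0, 1)")
  g <- ud$grid
  area <- g$cell_size^2
  dens <- as.vector(g$values)
  ord <- order(dens, decreasing = TRUE)   # order() is stable: ties by index
  mass <- cumsum(dens[ord]) * area
  k <- which(mass >= level)[1]
  if (is.na(k)) k <- length(ord)
  sel <- ord[seq_len(k)]
  rc <- cbind(row = ((sel - 1L) %% g$n_rows) + 1L,
              col = ((sel - 1L) %/% g$n_rows) + 1L)
  cc <- cell_centers(g)
  structure(list(level = level, cells = rc,
                 cell_xy = cbind(x = cc$x[rc[, "col"]], y = cc$y[rc[, "row"]]),
                 mass = mass[k], area_m2 = k * area,
                 grid = g[c("origin_x", "origin_y", "cell_size",
                            "n_rows", "n_cols")]),
            class = "isopleth_region")
}

#' Does a home range overlap any hunting-ban area?
#'
#' The study's inclusion rule: an animal enters the analysis only if its
#' 99 % kernel home range overlaps an HBA. Overlap is tested at cell-center
#' resolution — `TRUE` iff any member cell center of the isopleth region
#' lies inside (or on the boundary of) any HBA polygon; the approximation
#' error is bounded by one cell.
#'
#' @param region an [isopleth_region()].
#' @param hba_polygons list of polygon vertex matrices.
#' @return logical: retain the animal?
#' @export
hba_overlap_filter <- function(region, hba_polygons) {
  if (!length(hba_polygons)) return(FALSE)
  any(point_in_any_polygon(region$cell_xy[, "x"], region$cell_xy[, "y"],
                           hba_polygons))
}
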