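#' Regular planar raster
#'
#' A `grid_raster` carries one covariate surface (elevation, tree cover,
#' an HBA mask, trail distance, ...) on a regular grid in planar metric
#' coordinates. Row 1 of `values` is the **southernmost** row and column 1
#' the westernmost; sampling is at cell centers. The cell with index
#' `[r, c]` owns the half-open square
#' `[origin_x + (c-1)*cell_size, origin_x + c*cell_size)` (likewise in y).
#'
#' @param values numeric matrix (rows = south to north).
#' @param origin numeric length-2: x, y of the lower-left corner (meters).
#' @param cell_size cell edge length in meters; must be positive.
#' @param nodata value standing for missing cells (stored as `NA` internally).
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, origin = c(0, 0), cell_size, nodata = NA_real_) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), length(origin) == 2L)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop2("cell_size must be a single positive number")
  if (!is.na(nodata)) values[values == nodata] <- NA_real_
  structure(
    list(origin_x = as.numeric(origin[1]), origin_y = as.numeric(origin[2]),
         cell_size = as.numeric(cell_size),
         n_rows = nrow(values), n_cols = ncol(values),
         values = values),
    class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("<grid_raster> %d x %d cells of %g m, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values in [%g, %g], %d NA cells\n",
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' @rdname grid_raster
#' @param r a `grid_raster`.
#' @return `raster_extent()`: named vector `xmin, xmax, ymin, ymax`.
#' @export
raster_extent <- function(r) {
  c(xmin = r$origin_x, xmax = r$origin_x + r$n_cols * r$cell_size,
    ymin = r$origin_y, ymax = r$origin_y + r$n_rows * r$cell_size)
}

#' @rdname grid_raster
#' @return `cell_centers()`: list with vectors `x` (per column) and `y` (per row).
#' @export
cell_centers <- function(r) {
  list(x = r$origin_x + (seq_len(r$n_cols) - 0.5) * r$cell_size,
       y = r$origin_y + (seq_len(r$n_rows) - 0.5) * r$cell_size)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(c(a$origin_x, a$origin_y, a$cell_size, a$n_rows, a$n_cols),
                   c(b$origin_x, b$origin_y, b$cell_size, b$n_rows, b$n_cols)))
}

#' Sample a raster at arbitrary points
#'
#' Continuous surfaces are sampled bilinearly between the four surrounding
#' cell centers (clamped to the edge inside the outer half-cell ring);
#' categorical surfaces use the owning (nearest) cell. Points outside the
#' raster extent return `NA`.
#'
#' @param r a [grid_raster()].
#' @param x,y point coordinates in meters (vectors of equal length).
#' @param method `"bilinear"` (continuous) or `"nearest"` (categorical).
#' @return numeric vector of sampled values.
#' @export
raster_extract <- function(r, x, y, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ext <- raster_extent(r)
  inside <- x >= ext["xmin"] & x < ext["xmax"] & y >= ext["ymin"] & y < ext["ymax"]
  out <- rep(NA_real_, length(x))
  if (!any(inside)) return(out)
  xi <- x[inside]; yi <- y[inside]
  if (method == "nearest") {
    cc <- pmin(pmax(floor((xi - r$origin_x) / r$cell_size) + 1L, 1L), r$n_cols)
    rr <- pmin(pmax(floor((yi - r$origin_y) / r$cell_size) + 1L, 1L), r$n_rows)
    out[inside] <- r$values[cbind(rr, cc)]
    return(out)
  }
  # fractional coordinates in units of cell centers (0-based)
  u <- (xi - r$origin_x) / r$cell_size - 0.5
  v <- (yi - r$origin_y) / r$cell_size - 0.5
  u <- pmin(pmax(u, 0), r$n_cols - 1)
  v <- pmin(pmax(v, 0), r$n_rows - 1)
  c0 <- pmin(floor(u), r$n_cols - 2); c0 <- pmax(c0, 0)
  r0 <- pmin(floor(v), r$n_rows - 2); r0 <- pmax(r0, 0)
  if (r$n_cols == 1L) c0 <- rep(0, length(u))
  if (r$n_rows == 1L) r0 <- rep(0, length(v))
  fu <- u - c0; fv <- v - r0
  c1 <- pmin(c0 + 1, r$n_cols - 1); r1 <- pmin(r0 + 1, r$n_rows - 1)
  V <- r$values
  z00 <- V[cbind(r0 + 1, c0 + 1)]; z01 <- V[cbind(r0 + 1, c1 + 1)]
  z10 <- V[cbind(r1 + 1, c0 + 1)]; z11 <- V[cbind(r1 + 1, c1 + 1)]
  out[inside] <- (1 - fv) * ((1 - fu) * z00 + fu * z01) +
    fv * ((1 - fu) * z10 + fu * z11)
  out
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster interchange. The on-disk format stores rows north to
#' south; conversion to the package's south-first convention happens here.
#'
#' @param r a [grid_raster()].
#' @param path file path.
#' @param nodata value written for `NA` cells.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  hdr <- c(
    sprintf("ncols %d", r$n_cols),
    sprintf("nrows %d", r$n_rows),
    sprintf("xllcorner %.10g", r$origin_x),
    sprintf("yllcorner %.10g", r$origin_y),
    sprintf("cellsize %.10g", r$cell_size),
    sprintf("NODATA_value %.10g", nodata))
  V <- r$values[rev(seq_len(r$n_rows)), , drop = FALSE]
  V[is.na(V)] <- nodata
  rows <- apply(V, 1L, function(z) paste(format(z, trim = TRUE, digits = 12),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @return `read_ascii_grid()`: a [grid_raster()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- as.numeric(kv[, 2]); names(vals) <- tolower(kv[, 1])
  body <- lines[-(1:6)]
  V <- do.call(rbind, lapply(body, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  V[V == vals[["nodata_value"]]] <- NA_real_
  V <- V[rev(seq_len(nrow(V))), , drop = FALSE]
  grid_raster(V, origin = c(vals[["xllcorner"]], vals[["yllcorner"]]),
              cell_size = vals[["cellsize"]])
}
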