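#' Generate a synthetic mountain landscape with trails and hunting-ban areas
#'
#' Builds the full world bundle every downstream stage needs: a spatially
#' autocorrelated elevation surface (smoothed Gaussian random field plus a
#' V-shaped valley trend), a correlated tree-cover surface squashed to
#' [0, 100] %, 1-3 trail polylines that follow low-elevation terrain, 1-3
#' hunting-ban polygons covering 10-30 % of the extent, a hunting calendar,
#' and a reference latitude/longitude for solar computations. Everything is
#' a pure function of the seed.
#'
#' @param seed integer RNG seed.
#' @param extent side length of the square study area in meters.
#' @param cell_size raster cell size in meters; `extent / cell_size` must
#'   give at least 50 cells per side.
#' @param smoothness correlation length of the random fields in meters;
#'   `Inf` gives the degenerate constant-field limit.
#' @param ref_latlon reference (latitude, longitude) in degrees for the
#'   day/night classifier; default is an eastern-Alps location.
#' @param years calendar years for which hunting-season intervals are laid
#'   down (Sep 1 - Oct 20, inside the Aug 15 - Oct 31 analysis window).
#' @return A `world_bundle`: list with `elevation`, `tree_cover`
#'   ([grid_raster()]s on one grid), `trail_lines`, `hba_polygons` (lists of
#'   vertex matrices), `hunting_calendar` (data.frame of date intervals),
#'   `ref_lat`, `ref_lon`.
#' @export
generate_landscape <- function(seed, extent = 5000, cell_size = 50,
                               smoothness = 400,
                               ref_latlon = c(46.6, 10.2),
                               years = 2018:2026) {
  n <- extent / cell_size
  if (abs(n - round(n)) > 1e-9) stop2("extent must be a multiple of cell_size")
  n <- as.integer(round(n))
  if (n < 50L) stop2("extent too small: need at least 50x50 cells, got ", n, "x", n)
  if (!is.finite(smoothness) && smoothness > 0) {
    # degenerate limit: a single field value everywhere
    f1 <- matrix(0, n, n); f2 <- matrix(0, n, n)
    return(with_seed(seed, assemble_world(f1, f2, n, cell_size, ref_latlon,
                                          years, degenerate = TRUE)))
  }
  if (smoothness <= 0) stop2("smoothness must be positive")
  with_seed(seed, {
    f1 <- gaussian_field(n, smoothness / cell_size)
    raw <- gaussian_field(n, smoothness / cell_size)
    rho <- -0.4                      # denser forest on valley flanks
    f2 <- rho * f1 + sqrt(1 - rho^2) * raw
    assemble_world(f1, f2, n, cell_size, ref_latlon, years, degenerate = FALSE)
  })
}

# Smoothed Gaussian random field via FFT convolution with a Gaussian
# kernel of sd `len` cells (circulant boundary), normalized to sd 1.
gaussian_field <- function(n, len) {
  w <- matrix(stats::rnorm(n * n), n, n)
  d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) # frequencies as lags
  g1 <- exp(-d^2 / (2 * len^2))
  K <- outer(g1, g1)
  f <- Re(stats::fft(stats::fft(w) * stats::fft(K / sum(K)), inverse = TRUE)) / n^2
  s <- stats::sd(as.vector(f))
  if (s > 0) f <- (f - mean(f)) / s
  f
}

assemble_world <- function(f1, f2, n, cell_size, ref_latlon, years, degenerate) {
  extent <- n * cell_size
  ys <- (seq_len(n) - 0.5) * cell_size
  valley <- if (degenerate) 0 else 0.25 * abs(ys - extent / 2) # m per m cross-valley
  elevation <- 1500 + 350 * f1 + matrix(valley, n, n, byrow = FALSE)
  tree <- 100 * stats::plogis(1.3 * f2)
  if (degenerate) tree <- matrix(tree[1, 1], n, n)
  elev_r <- grid_raster(elevation, origin = c(0, 0), cell_size = cell_size)
  tree_r <- grid_raster(tree, origin = c(0, 0), cell_size = cell_size)
  trails <- make_trails(elev_r, n_trails = sample(1:3, 1))
  hba <- make_hba_polygons(extent, n_polys = sample(1:3, 1))
  cal <- data.frame(
    start = as.Date(sprintf("%d-09-01", years)),
    end = as.Date(sprintf("%d-10-20", years)))
  structure(list(elevation = elev_r, tree_cover = tree_r,
                 trail_lines = trails, hba_polygons = hba,
                 hunting_calendar = cal,
                 ref_lat = ref_latlon[1], ref_lon = ref_latlon[2]),
            class = "world_bundle")
}

# Trails run west->east, greedily preferring the lowest-elevation of the
# three eastward neighbours (valley-bottom paths).
make_trails <- function(elev, n_trails) {
  n <- elev$n_rows
  cs <- elev$cell_size
  V <- elev$values
  lapply(seq_len(n_trails), function(i) {
    r <- sample(seq(max(1, n %/% 4), min(n, 3 * n %/% 4)), 1)
    rows <- integer(elev$n_cols)
    rows[1] <- r
    for (c in 2:elev$n_cols) {
      cand <- unique(pmin(pmax(r + (-1:1), 1L), n))
      r <- cand[which.min(V[cand, c] + stats::rnorm(length(cand), sd = 1))]
      rows[c] <- r
    }
    cbind(x = (seq_len(elev$n_cols) - 0.5) * cs, y = (rows - 0.5) * cs)
  })
}

# Axis-aligned rectangular ban areas totalling 10-30 % of the extent.
make_hba_polygons <- function(extent, n_polys) {
  target <- stats::runif(1, 0.12, 0.28)
  per <- target / n_polys
  lapply(seq_len(n_polys), function(i) {
    aspect <- stats::runif(1, 0.6, 1.6)
    a <- sqrt(per * extent^2 * aspect)   # width
    b <- per * extent^2 / a              # height
    a <- min(a, 0.9 * extent); b <- min(b, 0.9 * extent)
    x0 <- stats::runif(1, 0, extent - a)
    y0 <- stats::runif(1, 0, extent - b)
    cbind(x = c(x0, x0 + a, x0 + a, x0), y = c(y0, y0, y0 + b, y0 + b))
  })
}

#' True selection model for simulation
#'
#' Ground truth for the generator: day and night coefficient vectors over
#' the covariates (tree_cover, trail_distance, slope, elevation,
#' hba) — the continuous four on the landscape-standardized scale — plus the
#' movement kernel steps are drawn from, and the number of candidate end
#' points per step.
#'
#' @param beta_day,beta_night named numeric vectors with entries
#'   `tree_cover`, `trail_distance`, `slope`, `elevation`, `hba`.
#' @param kernel a [movement_kernel()].
#' @param M candidate count per step for the importance-sampling simulator
#'   (>= 50; larger M approximates the exact redistribution kernel better).
#' @return object of class `true_model`.
#' @export
true_model <- function(beta_day, beta_night, kernel, M = 200L) {
  nm <- c("tree_cover", "trail_distance", "slope", "elevation", "hba")
  beta_day <- beta_day[nm]; beta_night <- beta_night[nm]
  if (anyNA(beta_day) || anyNA(beta_night))
    stop2("beta_day and beta_night must be named vectors over: ",
          paste(nm, collapse = ", "))
  if (M < 50) stop2("candidate count M must be >= 50")
  stopifnot(inherits(kernel, "movement_kernel"))
  structure(list(beta_day = beta_day, beta_night = beta_night,
                 kernel = kernel, M = as.integer(M)),
            class = "true_model")
}

#' Simulate a trajectory from a known step-selection function
#'
#' At each step, `M` candidate end points are drawn from the movement
#' kernel (gamma length, von Mises turn relative to the current heading)
#' and one is selected with probability proportional to
#' `exp(beta . z(end))`, where `beta` is the day or night vector according
#' to the solar classifier at the step's timestamp. Candidates outside the
#' raster extent get zero weight; if all `M` fall outside, the draw is
#' retried (bounded), then the simulation aborts naming the step. This is
#' an importance-sampling approximation of the true redistribution kernel;
#' its accuracy grows with `M`.
#'
#' @param world a `world_bundle` from [generate_landscape()].
#' @param model a [true_model()].
#' @param start numeric (x, y) start position in meters, inside the extent.
#' @param heading initial heading in radians; `NULL` draws uniformly on
#'   `[-pi, pi)`.
#' @param n_steps number of steps (>= 0; the track has `n_steps + 1` fixes).
#' @param fix_interval hours between fixes.
#' @param start_time POSIXct (UTC) timestamp of the first fix.
#' @param seed integer RNG seed.
#' @param stack optional precomputed [build_covariate_stack()] for `world`
#'   (built internally when absent; pass it when simulating many tracks).
#' @param animal_id id string for the output track.
#' @param max_retries redraw budget when all candidates fall outside.
#' @return data.frame track: `animal_id`, `timestamp` (POSIXct UTC),
#'   `x`, `y`.
#' @export
simulate_issf_track <- function(world, model, start, heading = NULL,
                                n_steps = 100L, fix_interval = 3,
                                start_time = as.POSIXct("2021-06-01 00:00:00",
                                                        tz = "UTC"),
                                seed = NULL, stack = NULL,
                                animal_id = "sim1", max_retries = 50L) {
  ext <- raster_extent(world$elevation)
  if (start[1] < ext["xmin"] || start[1] >= ext["xmax"] ||
      start[2] < ext["ymin"] || start[2] >= ext["ymax"])
    stop2("start position lies outside the landscape extent")
  if (n_steps < 0) stop2("n_steps must be >= 0")
  if (is.null(stack)) stack <- build_covariate_stack(world)
  with_seed(seed, {
    simulate_issf_track_impl(world, model, start, heading, n_steps,
                             fix_interval, as_utc(start_time), stack,
                             animal_id, max_retries)
  })
}

simulate_issf_track_impl <- function(world, model, start, heading, n_steps,
                                     fix_interval, start_time, stack,
                                     animal_id, max_retries) {
  M <- model$M
  kern <- model$kernel
  std <- attr(stack, "landscape_stats")
  xs <- numeric(n_steps + 1L); ys <- numeric(n_steps + 1L)
  xs[1] <- start[1]; ys[1] <- start[2]
  if (is.null(heading)) heading <- stats::runif(1, -pi, pi)
  times <- start_time + (0:n_steps) * fix_interval * 3600
  if (n_steps == 0L)
    return(data.frame(animal_id = animal_id, timestamp = times,
                      x = xs, y = ys))
  diel <- classify_day_night(times[seq_len(n_steps)], world$ref_lat,
                             world$ref_lon)
  for (i in seq_len(n_steps)) {
    beta <- if (diel[i] == "day") model$beta_day else model$beta_night
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      draw <- sample_kernel(kern, M)
      brg <- heading + draw$ta
      cx <- xs[i] + draw$sl * cos(brg)
      cy <- ys[i] + draw$sl * sin(brg)
      z <- extract_standardized(stack, cx, cy, std)
      w <- exp(as.vector(z %*% beta))
      w[!is.finite(w) | is.na(rowSums(z))] <- 0
      if (any(w > 0)) {
        j <- sample.int(M, 1L, prob = w)
        xs[i + 1L] <- cx[j]; ys[i + 1L] <- cy[j]
        heading <- brg[j]
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop2("simulation cornered at step ", i,
            ": all candidates fell outside the landscape after ",
            max_retries, " redraws")
  }
  data.frame(animal_id = animal_id, timestamp = times, x = xs, y = ys)
}

# candidate covariate matrix on the true model's (landscape-standardized)
# scale; columns tree_cover, trail_distance, slope, elevation, hba
extract_standardized <- function(stack, x, y, std) {
  cont <- c("tree_cover", "trail_distance", "slope", "elevation")
  z <- vapply(cont, function(nm) {
    (raster_extract(stack[[nm]], x, y) - std[nm, "mean"]) / std[nm, "sd"]
  }, numeric(length(x)))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  hba <- raster_extract(stack$hba_mask, x, y, method = "nearest")
  cbind(z, hba = hba)
}

#' Degrade a clean track with fix dropout and gross positional outliers
#'
#' Emulates real collar data: each fix is independently dropped with
#' probability `dropout_rate`; each surviving non-terminal fix is displaced
#' by `outlier_displacement` meters in a uniformly random direction with
#' probability `outlier_rate`. The input track is untouched; a manifest of
#' the affected original fix indices is returned alongside.
#'
#' @param track data.frame with `animal_id`, `timestamp`, `x`, `y`.
#' @param dropout_rate,outlier_rate probabilities in `[0, 1)`.
#' @param outlier_displacement displacement magnitude in meters.
#' @param seed integer RNG seed.
#' @return list with `track` (corrupted copy) and `manifest`
#'   (`dropped`, `outliers`: integer indices into the input track).
#' @export
corrupt_track <- function(track, dropout_rate = 0, outlier_rate = 0,
                          outlier_displacement = 50000, seed = NULL) {
  if (dropout_rate < 0 || dropout_rate >= 1 || outlier_rate < 0 || outlier_rate >= 1)
    stop2("dropout_rate and outlier_rate must lie in [0, 1)")
  with_seed(seed, {
    n <- nrow(track)
    drop <- stats::runif(n) < dropout_rate
    keep_idx <- which(!drop)
    out <- track[keep_idx, , drop = FALSE]
    is_out <- stats::runif(length(keep_idx)) < outlier_rate
    if (any(is_out)) {
      ang <- stats::runif(sum(is_out), -pi, pi)
      out$x[is_out] <- out$x[is_out] + outlier_displacement * cos(ang)
      out$y[is_out] <- out$y[is_out] + outlier_displacement * sin(ang)
    }
    rownames(out) <- NULL
    list(track = out,
         manifest = list(dropped = which(drop),
                         outliers = keep_idx[is_out]))
  })
}
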