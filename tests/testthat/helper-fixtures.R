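# Shared fixtures, built once when the helpers are sourced. The small
# world is the default study-condition landscape at reduced extent so the
# expensive layers (path distance) are computed a single time.

fx <- new.env()

fixture_world <- function() {
  if (is.null(fx$world)) {
    fx$world <- dielssf::generate_landscape(seed = 42, extent = 5000,
                                            cell_size = 50)
    fx$stack <- dielssf::build_covariate_stack(fx$world)
  }
  list(world = fx$world, stack = fx$stack)
}

# A regular 3-h synthetic GPS table (no movement model; geometry only)
make_regular_track <- function(n = 80, interval_h = 3, start = "2021-06-01",
                               animal_id = "a1", step = 120, seed = 1,
                               bounds = c(1200, 3800)) {
  set.seed(seed)
  ts <- as.POSIXct(start, tz = "UTC") + (0:(n - 1)) * interval_h * 3600
  ang <- cumsum(stats::runif(n, -0.5, 0.5))
  reflect <- function(v) {
    span <- bounds[2] - bounds[1]
    w <- (v - bounds[1]) %% (2 * span)
    bounds[1] + ifelse(w > span, 2 * span - w, w)
  }
  data.frame(animal_id = animal_id, timestamp = ts,
             x = reflect(2500 + cumsum(step * cos(ang))),
             y = reflect(2500 + cumsum(step * sin(ang))))
}
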