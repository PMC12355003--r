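# Independent oracles used by the tests. Each reimplements the checked
# quantity through a different algorithm or by brute force; none shares
# code with the package.

# Solar elevation by the Michalsky (1988) Astronomical Almanac algorithm
# (accuracy ~0.01 deg, 1950-2050) — independent of the package's
# NOAA-calculator implementation.
oracle_solar_elevation <- function(time, lat, lon) {
  d2r <- pi / 180
  jd <- as.numeric(time) / 86400 + 2440587.5
  n <- jd - 2451545
  ut_hours <- (as.numeric(time) %% 86400) / 3600
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- (357.528 + 0.9856003 * n) %% 360
  lambda <- (L + 1.915 * sin(g * d2r) + 0.020 * sin(2 * g * d2r)) %% 360
  eps <- 23.439 - 0.0000004 * n
  ra <- atan2(cos(eps * d2r) * sin(lambda * d2r), cos(lambda * d2r)) / d2r
  ra <- ra %% 360
  dec <- asin(sin(eps * d2r) * sin(lambda * d2r)) / d2r
  gmst <- (6.697375 + 0.0657098242 * n + ut_hours) %% 24
  lmst <- (gmst + lon / 15) %% 24
  ha <- lmst * 15 - ra
  ha <- ((ha + 180) %% 360) - 180
  el <- asin(sin(dec * d2r) * sin(lat * d2r) +
               cos(dec * d2r) * cos(lat * d2r) * cos(ha * d2r)) / d2r
  el
}

# Brute-force single-source shortest paths on a raster's 8-connected cell
# graph with surface-length weights: O(V^2) textbook Dijkstra, no heap,
# no igraph.
oracle_path_distance <- function(elev_values, cell_size, source_cells) {
  nr <- nrow(elev_values); nc <- ncol(elev_values)
  nv <- nr * nc
  dist <- rep(Inf, nv)
  dist[source_cells] <- 0
  done <- rep(FALSE, nv)
  idx <- function(r, c) (c - 1L) * nr + r
  for (iter in seq_len(nv)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    r <- ((u - 1L) %% nr) + 1L
    c <- ((u - 1L) %/% nr) + 1L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      v <- idx(r2, c2)
      planar <- cell_size * sqrt(dr^2 + dc^2)
      w <- sqrt(planar^2 + (elev_values[r2, c2] - elev_values[r, c])^2)
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  matrix(dist, nr, nc)
}

# Direct-sum Gaussian kernel density at given grid centers (used to check
# the FFT/Matrix implementation behind kde_ud on small cases).
oracle_kde <- function(pts, xs, ys, h) {
  dens <- matrix(0, length(ys), length(xs))
  for (i in seq_len(nrow(pts))) {
    dx <- stats::dnorm(xs, pts[i, 1], h)
    dy <- stats::dnorm(ys, pts[i, 2], h)
    dens <- dens + outer(dy, dx)
  }
  dens / nrow(pts)
}

# Numeric von Mises CDF (mean 0) for KS tests.
oracle_vonmises_cdf <- function(kappa) {
  grid <- seq(-pi, pi, length.out = 4001)
  dens <- exp(kappa * cos(grid)) / (2 * pi * besselI(kappa, 0))
  cdf <- cumsum(c(0, diff(grid) * (dens[-1] + dens[-length(dens)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  stats::approxfun(grid, cdf, yleft = 0, yright = 1)
}

# Simulate a matched-stratum choice design directly from the conditional
# logit law: K+1 rows per stratum with N(0,1) covariates, the "used" row
# drawn with probability proportional to exp(X beta).
sim_choice_design <- function(n_strata, K, beta, seed = NULL,
                              extra_cols = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- length(beta)
  n <- n_strata * (K + 1L)
  X <- matrix(stats::rnorm(n * k), n, k)
  colnames(X) <- names(beta) %||% paste0("x", seq_len(k))
  stratum <- rep(seq_len(n_strata), each = K + 1L)
  used <- logical(n)
  eta <- as.vector(X %*% beta)
  for (s in seq_len(n_strata)) {
    rows <- ((s - 1L) * (K + 1L)) + seq_len(K + 1L)
    p <- exp(eta[rows] - max(eta[rows]))
    used[rows[sample.int(K + 1L, 1L, prob = p)]] <- TRUE
  }
  out <- data.frame(stratum = stratum, used = used, X, check.names = FALSE)
  if (!is.null(extra_cols)) for (nm in names(extra_cols))
    out[[nm]] <- extra_cols[[nm]]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Movement-only iSSF design: used steps drawn from `true_kern`, available
# steps from `tent_kern` (the tentative-kernel mismatch that the
# movement-term coefficients must absorb).
sim_kernel_design <- function(n_steps, K, true_kern, tent_kern, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  used_sl <- stats::rgamma(n_steps, true_kern$shape, rate = true_kern$rate)
  used_ta <- dielssf::rvonmises(n_steps, true_kern$kappa)
  av_sl <- stats::rgamma(n_steps * K, tent_kern$shape, rate = tent_kern$rate)
  av_ta <- dielssf::rvonmises(n_steps * K, tent_kern$kappa)
  sl <- as.vector(rbind(used_sl, matrix(av_sl, K)))
  ta <- as.vector(rbind(used_ta, matrix(av_ta, K)))
  data.frame(stratum = rep(seq_len(n_steps), each = K + 1L),
             used = rep(c(TRUE, rep(FALSE, K)), n_steps),
             sl = sl, log_sl = log(sl), cos_ta = cos(ta))
}

# survival::clogit cross-check on a design data.frame
oracle_survival_clogit <- function(design, terms) {
  X <- dielssf:::design_matrix(design, terms)
  df <- data.frame(used = design$used, stratum = design$stratum, X,
                   check.names = FALSE)
  names(df) <- c("used", "stratum", paste0("v", seq_len(ncol(X))))
  # coxph with one event per stratum: the Breslow partial likelihood is
  # exactly the conditional-logit likelihood
  df$surv <- survival::Surv(rep(1, nrow(df)), df$used)
  fml <- stats::as.formula(paste(
    "surv ~", paste(paste0("v", seq_len(ncol(X))), collapse = " + "),
    "+ survival::strata(stratum)"))
  fit <- survival::coxph(fml, data = df, method = "breslow")
  stats::setNames(stats::coef(fit), terms)
}
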