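#' Movement kernel: gamma step lengths, von Mises turning angles
#'
#' The tentative (and, after correction, updated) movement law of an iSSF:
#' step lengths follow a gamma(shape, rate) distribution and turning
#' angles a von Mises distribution with mean 0 and concentration kappa.
#'
#' @param shape gamma shape (dimensionless, > 0).
#' @param rate gamma rate (1/m, > 0); mean step length is `shape / rate`.
#' @param kappa von Mises concentration (>= 0; 0 is uniform turning).
#' @return object of class `movement_kernel`.
#' @export
movement_kernel <- function(shape, rate, kappa) {
  if (!is.finite(shape) || shape <= 0) stop2("gamma shape must be > 0")
  if (!is.finite(rate) || rate <= 0) stop2("gamma rate must be > 0")
  if (!is.finite(kappa) || kappa < 0) stop2("von Mises kappa must be >= 0")
  structure(list(shape = shape, rate = rate, kappa = kappa),
            class = "movement_kernel")
}

#' @export
print.movement_kernel <- function(x, ...) {
  cat(sprintf(
    "<movement_kernel> step length ~ gamma(shape=%.4g, rate=%.4g) [mean %.1f m]\n",
    x$shape, x$rate, x$shape / x$rate))
  cat(sprintf("                  turning angle ~ von Mises(0, kappa=%.4g)\n", x$kappa))
  invisible(x)
}

#' Sample von Mises angles
#'
#' Best & Fisher (1979) rejection sampler; mean direction 0. `kappa = 0`
#' falls back to uniform on `[-pi, pi)`.
#'
#' @param n number of draws.
#' @param kappa concentration (>= 0).
#' @return numeric vector of angles in `[-pi, pi)`.
#' @export
rvonmises <- function(n, kappa) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    f <- f[keep]; u3 <- u3[keep]
    k <- length(f)
    if (k) {
      theta <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
      out[(got + 1L):(got + k)] <- theta
      got <- got + k
    }
  }
  wrap_angle(out)
}

# von Mises density with mean 0 (used by tests and fitting)
dvonmises <- function(theta, kappa) {
  exp(kappa * (cos(theta) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

# Draw (length, turn) pairs from a kernel
sample_kernel <- function(kernel, n) {
  list(sl = stats::rgamma(n, shape = kernel$shape, rate = kernel$rate),
       ta = rvonmises(n, kernel$kappa))
}
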