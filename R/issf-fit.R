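#' Fit the tentative movement kernel from observed steps
#'
#' Maximum-likelihood gamma fit to step lengths (Newton iteration on the
#' digamma score in log-shape, method-of-moments start) and von Mises
#' concentration from turning angles by inverting the Bessel ratio
#' `A(kappa) = I1(kappa)/I0(kappa) = mean(cos(ta))` (Newton with the
#' standard series start). Zero-length steps are replaced by half the
#' minimum positive length before the log transform.
#'
#' @param sl numeric step lengths (m); at least 30 positive values.
#' @param ta turning angles in radians (`NA` allowed; e.g. first steps of
#'   bursts).
#' @return a [movement_kernel()].
#' @export
fit_tentative_kernel <- function(sl, ta) {
  sl <- sl[is.finite(sl)]
  if (sum(sl > 0) < 30L) stop2("need at least 30 positive step lengths")
  if (any(sl < 0)) stop2("negative step lengths")
  if (any(sl == 0)) {
    repl <- min(sl[sl > 0]) / 2
    message(sum(sl == 0), " zero-length steps replaced by ", signif(repl, 3), " m")
    sl[sl == 0] <- repl
  }
  if (stats::sd(sl) == 0) stop2("all step lengths identical; gamma fit undefined")
  gam <- fit_gamma_ml(sl)
  ta <- ta[is.finite(ta)]
  if (length(ta) < 5L) stop2("need at least 5 defined turning angles")
  kappa <- fit_vonmises_kappa(ta)
  movement_kernel(shape = unname(gam["shape"]), rate = unname(gam["rate"]),
                  kappa = kappa)
}

# Gamma MLE: solve log(k) - digamma(k) = log(mean) - mean(log x)
fit_gamma_ml <- function(x) {
  s <- log(mean(x)) - mean(log(x))
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)  # Choi-Wette start
  for (i in 1:100) {
    f <- log(k) - digamma(k) - s
    fp <- 1 / k - trigamma(k)
    step <- f / fp
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-12 * max(1, k)) { k <- k_new; break }
    k <- k_new
  }
  c(shape = k, rate = k / mean(x))
}

# von Mises concentration: invert A(kappa) = mean resultant length
fit_vonmises_kappa <- function(theta) {
  r <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  # mean direction fixed at 0 by the kernel definition: use mean cosine,
  # floored at 0 (angles pointing backwards on average => kappa ~ 0)
  rc <- max(mean(cos(theta)), 0)
  if (rc >= 1 - 1e-10)
    stop2("degenerate turning angles: all mass at 0, kappa unbounded")
  if (rc == 0) return(0)
  # series starts (Fisher 1993)
  k <- if (rc < 0.53) 2 * rc + rc^3 + 5 * rc^5 / 6
  else if (rc < 0.85) -0.4 + 1.39 * rc + 0.43 / (1 - rc)
  else 1 / (rc^3 - 4 * rc^2 + 3 * rc)
  A <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  for (i in 1:100) {
    a <- A(k)
    da <- 1 - a^2 - a / k
    step <- (a - rc) / da
    k_new <- k - step
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-12 * max(1, k)) { k <- k_new; break }
    k <- k_new
  }
  k
}

#' Draw available steps from the tentative kernel
#'
#' Generates `K` candidate end points for one used step: lengths from the
#' gamma law, turning angles von Mises around the incoming bearing (drawn
#' uniformly when the bearing is undefined, e.g. at the first step of a
#' burst).
#'
#' @param start numeric (x, y) step start.
#' @param bearing incoming bearing in radians, or `NA`/`NULL` if undefined.
#' @param kernel a [movement_kernel()].
#' @param K number of candidates (default 10).
#' @param seed optional RNG seed.
#' @return data.frame `x`, `y`, `sl`, `ta` (turn relative to the incoming
#'   bearing), `bearing` (absolute).
#' @export
draw_available_steps <- function(start, bearing, kernel, K = 10L, seed = NULL) {
  if (K < 1) stop2("K must be >= 1")
  with_seed(seed, {
    no_bearing <- is.null(bearing) || !is.finite(bearing)
    base <- if (no_bearing) stats::runif(1, -pi, pi) else bearing
    d <- sample_kernel(kernel, K)
    if (no_bearing) d$ta <- stats::runif(K, -pi, pi)
    brg <- base + d$ta
    data.frame(x = start[1] + d$sl * cos(brg),
               y = start[2] + d$sl * sin(brg),
               sl = d$sl, ta = wrap_angle(d$ta), bearing = wrap_angle(brg))
  })
}

#' Build the matched used/available step design
#'
#' One stratum per observed step: the used row plus `K` available rows
#' drawn from the tentative kernel. Every row carries end-point covariates
#' (continuous ones standardized over all rows entering the fit), its own
#' movement terms (`sl`, `log_sl`, `cos_ta` — unscaled), the diel class and
#' month of the step, and the HBA / hunting factors as 0-1 indicators
#' (`hba_in`, `hunting_yes`). Available rows with missing covariates
#' (off-raster end points) are dropped; a stratum survives while it keeps
#' its used row and at least one available row.
#'
#' @param track preprocessed track (regular bursts, flags removed — see
#'   [drop_flagged()]); needs `burst_id`.
#' @param stack a [build_covariate_stack()] result.
#' @param kernel the tentative [movement_kernel()].
#' @param K available steps per used step (default 10).
#' @param seed RNG seed for the candidate draws.
#' @param ref_lat,ref_lon coordinates for the diel classifier.
#' @param hunting_calendar data.frame of `start`/`end` dates, or `NULL`
#'   (hunting factor all "no").
#' @param standardize scale continuous covariates over this design's rows
#'   (the per-fit scaling convention); set `FALSE` only for diagnostics.
#' @return a `step_design` data.frame; attributes `standardization`,
#'   `kernel`, `K`, `n_dropped_strata`.
#' @export
build_step_design <- function(track, stack, kernel, K = 10L, seed = NULL,
                              ref_lat = 46.6, ref_lon = 10.2,
                              hunting_calendar = NULL, standardize = TRUE) {
  if (is.null(track$burst_id)) track$burst_id <- 1L
  steps <- track_steps(track)
  if (!nrow(steps)) stop2("no usable steps in track")
  with_seed(seed, {
    rows <- vector("list", nrow(steps))
    for (i in seq_len(nrow(steps))) {
      st <- steps[i, ]
      av <- draw_available_steps(c(st$x0, st$y0), st$bearing_in, kernel, K)
      used <- data.frame(x = st$x1, y = st$y1, sl = st$sl,
                         ta = st$ta, bearing = st$bearing)
      all_pts <- rbind(used[, c("x", "y", "sl", "ta")],
                       av[, c("x", "y", "sl", "ta")])
      all_pts$used <- c(TRUE, rep(FALSE, K))
      all_pts$stratum <- i
      rows[[i]] <- all_pts
    }
    des <- do.call(rbind, rows)
    des <- cbind(des, extract_covariates(des[, c("x", "y")], stack))
    des$animal_id <- track$animal_id[1]
    t0 <- rep(as_utc(steps$t0), each = K + 1L)
    des$timestamp <- t0
    des$diel <- classify_day_night(t0, ref_lat, ref_lon)
    des$month <- as.integer(format(t0, "%m", tz = "UTC"))
    des$hba_in <- des$hba
    des$hba <- NULL
    des$hunting_yes <- as.numeric(hunting_active(as.Date(t0, tz = "UTC"),
                                                 hunting_calendar))
    # movement terms: cos(ta); first-step strata keep the used row with the
    # undefined cosine imputed as 0 (flagged for kernel updating)
    des$cos_ta <- cos(des$ta)
    des$first_step <- rep(!is.finite(steps$bearing_in), each = K + 1L)
    des$cos_ta[des$used & !is.finite(des$cos_ta)] <- 0
    des$log_sl <- log(des$sl)
    # drop rows with missing covariates; keep strata with used + >=1 available
    cov_cols <- c("tree_cover", "trail_distance", "slope", "elevation", "hba_in")
    ok <- stats::complete.cases(des[, cov_cols]) & is.finite(des$log_sl)
    des <- des[ok | des$used, , drop = FALSE]
    bad_used <- des$stratum[des$used &
                              !stats::complete.cases(des[, cov_cols])]
    tab <- table(des$stratum)
    keep_strata <- setdiff(as.integer(names(tab)[tab >= 2L]), bad_used)
    n_dropped <- nrow(steps) - length(keep_strata)
    if (n_dropped > 0)
      message(n_dropped, " strata dropped (missing used-row covariates or no available rows)")
    des <- des[des$stratum %in% keep_strata, , drop = FALSE]
    if (!nrow(des)) stop2("empty design after filtering")
    if (standardize) des <- zstandardize(des)
    attr(des, "kernel") <- kernel
    attr(des, "K") <- K
    attr(des, "n_dropped_strata") <- n_dropped
    class(des) <- c("step_design", "data.frame")
    des
  })
}

#' Observed steps of a burst-structured track
#'
#' Converts consecutive fixes within each burst into steps: start and end
#' positions, start timestamp, step length `sl` (m), absolute bearing,
#' incoming bearing and turning angle `ta` (radians; `NA` at the first
#' step of a burst). These are the movement statistics the tentative
#' kernel is fitted from.
#'
#' @param track track with a `burst_id` column.
#' @return data.frame of steps.
#' @export
track_steps <- function(track) {
  out <- list()
  for (b in unique(track$burst_id)) {
    seg <- track[track$burst_id == b, , drop = FALSE]
    n <- nrow(seg)
    if (n < 2L) next
    dx <- diff(seg$x); dy <- diff(seg$y)
    brg <- atan2(dy, dx)
    brg_in <- c(NA_real_, brg[-(n - 1L)])
    ta <- wrap_angle(brg - brg_in)
    out[[length(out) + 1L]] <- data.frame(
      x0 = seg$x[-n], y0 = seg$y[-n], x1 = seg$x[-1], y1 = seg$y[-1],
      t0 = seg$timestamp[-n], sl = sqrt(dx^2 + dy^2),
      bearing = brg, bearing_in = brg_in, ta = ta)
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}

#' Is a date inside the hunting season?
#'
#' @param dates Date vector.
#' @param calendar data.frame with `start` and `end` Date columns
#'   (inclusive intervals), or `NULL` for "never".
#' @return logical vector.
#' @export
hunting_active <- function(dates, calendar = NULL) {
  if (is.null(calendar) || !nrow(calendar)) return(rep(FALSE, length(dates)))
  act <- rep(FALSE, length(dates))
  for (i in seq_len(nrow(calendar)))
    act <- act | (dates >= calendar$start[i] & dates <= calendar$end[i])
  act
}

# Numeric model matrix from term names; "a:b" builds a product column.
design_matrix <- function(design, terms) {
  cols <- lapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    v <- design[[parts[1]]]
    if (is.null(v)) stop2("unknown design column '", parts[1], "'")
    for (p in parts[-1]) {
      v2 <- design[[p]]
      if (is.null(v2)) stop2("unknown design column '", p, "'")
      v <- v * v2
    }
    v
  })
  X <- do.call(cbind, cols)
  colnames(X) <- terms
  X
}

default_movement_terms <- function(include_log_sl = TRUE) {
  c("sl", if (include_log_sl) "log_sl", "cos_ta")
}

#' Conditional logistic regression over matched strata
#'
#' The estimation core: maximizes the stratified conditional log-likelihood
#' `sum_s [beta . x_used - log sum_j exp(beta . x_j)]` — the model in which
#' each stratum has its own (eliminated) intercept — by Newton-Raphson with
#' the analytic gradient and Hessian, starting at `beta = 0`, with
#' step-halving on any likelihood decrease. Convergence at max |gradient|
#' < 1e-8, at most 100 iterations. The covariance is the inverse negative
#' Hessian at the optimum; p-values are two-sided Wald.
#'
#' @param design a [build_step_design()] result (or any data.frame with a
#'   `stratum` id, logical `used`, and the term columns).
#' @param terms character vector of model terms; `"a:b"` denotes a product
#'   (interaction) column.
#' @return an `issf_fit`: list with `coef`, `vcov`, `se`, `z`, `p`,
#'   `loglik`, `iterations`, `converged`, `n_strata`, `terms`, and the
#'   design's standardization table.
#' @export
fit_conditional_logit <- function(design,
                                  terms = c("tree_cover", "trail_distance",
                                            "slope", "elevation", "hba_in",
                                            "sl", "log_sl", "cos_ta")) {
  prep <- clogit_prepare(design, terms)
  res <- clogit_newton(prep$X, prep$stratum, prep$used)
  make_issf_fit(res, terms, prep, method = "conditional_logit")
}

clogit_prepare <- function(design, terms) {
  X <- design_matrix(design, terms)
  if (anyNA(X)) {
    keep <- stats::complete.cases(X)
    design <- design[keep, , drop = FALSE]
    X <- X[keep, , drop = FALSE]
  }
  stratum <- match(design$stratum, unique(design$stratum))
  used <- as.logical(design$used)
  cnt <- tabulate(stratum)
  used_cnt <- tabulate(stratum[used], nbins = max(stratum))
  if (any(used_cnt != 1L))
    stop2("every stratum must contain exactly one used row")
  informative <- cnt >= 2L
  keep <- informative[stratum]
  X <- X[keep, , drop = FALSE]
  used <- used[keep]
  stratum <- match(stratum[keep], unique(stratum[keep]))
  if (max(stratum) < 2L) stop2("need at least 2 informative strata")
  # identifiability: columns constant within every stratum carry no signal
  # (within-stratum centering must not collapse a column, judged against
  # the raw column scale, then a QR catches remaining collinearity)
  Xc <- X - rowsum(X, stratum)[stratum, , drop = FALSE] / cnt[cnt >= 2L][stratum]
  scale_raw <- pmax(sqrt(colSums(X^2)), 1e-12)
  flat <- sqrt(colSums(Xc^2)) <= 1e-8 * scale_raw
  if (any(flat))
    stop2("non-identifiable term(s): ",
          paste(colnames(X)[flat], collapse = ", "),
          " (constant within strata or collinear)")
  qrr <- qr(Xc)
  if (qrr$rank < ncol(X)) {
    bad <- setdiff(colnames(X), colnames(X)[qrr$pivot[seq_len(qrr$rank)]])
    stop2("non-identifiable term(s): ", paste(bad, collapse = ", "),
          " (constant within strata or collinear)")
  }
  list(X = X, stratum = stratum, used = used,
       std = attr(design, "standardization"))
}

clogit_newton <- function(X, stratum, used, max_iter = 100L, tol = 1e-8) {
  k <- ncol(X)
  n_str <- max(stratum)
  beta <- rep(0, k)
  ll_fun <- function(beta) {
    eta <- as.vector(X %*% beta)
    str_max <- as.vector(tapply(eta, stratum, max))
    w <- exp(eta - str_max[stratum])
    denom <- rowsum(w, stratum)[, 1]
    list(ll = sum(eta[used]) - sum(log(denom) + str_max),
         p = w / denom[stratum], eta = eta)
  }
  cur <- ll_fun(beta)
  iter <- 0L
  converged <- FALSE
  separation <- FALSE
  repeat {
    p <- cur$p
    grad <- colSums(X[used, , drop = FALSE]) - colSums(X * p)
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    B <- rowsum(X * p, stratum)                  # per-stratum weighted mean
    H <- crossprod(X, X * p) - crossprod(B)      # negative Hessian
    step <- tryCatch(solve(H, grad), error = function(e)
      stop2("singular Hessian in conditional-logit fit: ", conditionMessage(e)))
    # step-halving on likelihood decrease
    s <- 1
    repeat {
      cand <- beta + s * step
      new <- ll_fun(cand)
      if (new$ll >= cur$ll - 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    beta <- beta + s * step
    cur <- new
    iter <- iter + 1L
    if (any(abs(beta) > 15)) separation <- TRUE
  }
  if (separation)
    warn2("possible separation: |beta| exceeded 15 during fitting")
  if (!converged)
    warn2("conditional-logit fit did not converge in ", max_iter, " iterations")
  p <- cur$p
  B <- rowsum(X * p, stratum)
  H <- crossprod(X, X * p) - crossprod(B)
  vcov <- solve(H)
  list(beta = beta, vcov = vcov, loglik = cur$ll, iterations = iter,
       converged = converged, n_strata = n_str)
}

make_issf_fit <- function(res, terms, prep, method) {
  se <- sqrt(pmax(diag(res$vcov), 0))
  z <- res$beta / se
  names(res$beta) <- terms
  dimnames(res$vcov) <- list(terms, terms)
  names(se) <- names(z) <- terms
  structure(list(coef = res$beta, vcov = res$vcov, se = se, z = z,
                 p = 2 * stats::pnorm(-abs(z)), loglik = res$loglik,
                 iterations = res$iterations, converged = res$converged,
                 n_strata = res$n_strata, terms = terms,
                 standardization = prep$std, method = method),
            class = "issf_fit")
}

#' @export
print.issf_fit <- function(x, ...) {
  cat(sprintf("<issf_fit> %s, %d strata, loglik %.3f, %s in %d iterations\n",
              x$method, x$n_strata, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(data.frame(coef = x$coef, se = x$se, z = x$z, p = signif(x$p, 3)))
  invisible(x)
}

#' Poisson likelihood with profiled stratum intercepts
#'
#' An independent estimation path for the same model: the used/available
#' indicator is treated as a Poisson response with one free intercept per
#' stratum. Profiling the intercepts out of the Poisson likelihood yields
#' the conditional-logit likelihood up to a beta-free constant, so the two
#' estimators must agree — the package's central internal consistency
#' check. The implementation alternates closed-form intercept profiling
#' with Newton steps in beta whose gradient and information are assembled
#' from the full Poisson quantities (`mu`, and the Schur complement of the
#' diagonal intercept block); the covariance is that Schur complement
#' inverted at the optimum.
#'
#' @inheritParams fit_conditional_logit
#' @return an `issf_fit` (loglik is the profiled Poisson log-likelihood,
#'   which differs from the conditional-logit one by a beta-free constant).
#' @export
poisson_profile_fit <- function(design,
                                terms = c("tree_cover", "trail_distance",
                                          "slope", "elevation", "hba_in",
                                          "sl", "log_sl", "cos_ta"),
                                max_iter = 500L, tol = 1e-10) {
  prep <- clogit_prepare(design, terms)
  X <- prep$X; stratum <- prep$stratum; used <- prep$used
  y <- as.numeric(used)
  k <- ncol(X)
  beta <- rep(0, k)
  pois_state <- function(beta) {
    eta <- as.vector(X %*% beta)
    str_max <- as.vector(tapply(eta, stratum, max))
    w <- exp(eta - str_max[stratum])
    S <- rowsum(w, stratum)[, 1]
    alpha <- -(log(S) + str_max)                    # profiled intercepts
    mu <- exp(alpha[stratum] + eta)                 # sums to 1 per stratum
    list(alpha = alpha, mu = mu, eta = eta,
         ll = sum(y * (alpha[stratum] + eta) - mu))
  }
  cur <- pois_state(beta)
  for (iter in seq_len(max_iter)) {
    mu <- cur$mu
    grad <- colSums(X * (y - mu))
    if (max(abs(grad)) < tol) break
    # profiled information: Schur complement of the diagonal alpha block
    Hbb <- crossprod(X, X * mu)
    M <- rowsum(X * mu, stratum)
    s_a <- rowsum(mu, stratum)[, 1]
    step <- solve(Hbb - crossprod(M / s_a, M), grad)
    s <- 1
    repeat {
      new <- pois_state(beta + s * step)
      if (new$ll >= cur$ll - 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    beta <- beta + s * step
    cur <- new
  }
  eta <- as.vector(X %*% beta)
  str_max <- as.vector(tapply(eta, stratum, max))
  w <- exp(eta - str_max[stratum])
  S <- rowsum(w, stratum)[, 1]
  alpha <- -(log(S) + str_max)
  mu <- exp(alpha[stratum] + eta)
  # Schur complement of the (diagonal) intercept block
  H_bb <- crossprod(X, X * mu)
  M <- rowsum(X * mu, stratum)                     # I_{beta,alpha} columns
  s_a <- rowsum(mu, stratum)[, 1]                  # I_{alpha,alpha} diagonal
  H_prof <- H_bb - crossprod(M / s_a, M)
  ll <- sum(y * (alpha[stratum] + eta) - mu)
  res <- list(beta = beta, vcov = solve(H_prof), loglik = ll,
              iterations = iter, converged = max(abs(grad)) < tol * 10,
              n_strata = max(stratum))
  make_issf_fit(res, terms, prep, method = "poisson_profile")
}

#' Pool per-individual fits (DerSimonian-Laird random effects)
#'
#' Two-stage surrogate for the random-slopes mixed model: each
#' individual-year is fitted separately, then coefficients are pooled per
#' term with the DerSimonian-Laird estimator, giving a population mean, its
#' variance, and a between-individual variance tau^2 per coefficient.
#'
#' @param fits list of convergent `issf_fit` objects sharing term names.
#' @return list with `coef`, `se`, `z`, `p`, `tau2`, `k` (number of fits),
#'   class `pooled_fit`.
#' @export
pool_individual_fits <- function(fits) {
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(fits)) stop2("no convergent fits to pool")
  terms <- fits[[1]]$terms
  for (f in fits) stopifnot(identical(f$terms, terms))
  K <- length(fits)
  pool_one <- function(nm) {
    b <- vapply(fits, function(f) f$coef[[nm]], 0)
    v <- vapply(fits, function(f) f$se[[nm]]^2, 0)
    w <- 1 / v
    b_fe <- sum(w * b) / sum(w)
    Q <- sum(w * (b - b_fe)^2)
    tau2 <- if (K > 1) max(0, (Q - (K - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
    wr <- 1 / (v + tau2)
    c(coef = sum(wr * b) / sum(wr), var = 1 / sum(wr), tau2 = tau2)
  }
  res <- t(vapply(terms, pool_one, c(coef = 0, var = 0, tau2 = 0)))
  se <- sqrt(res[, "var"])
  z <- res[, "coef"] / se
  structure(list(coef = res[, "coef"], se = se, z = z,
                 p = 2 * stats::pnorm(-abs(z)), tau2 = res[, "tau2"],
                 k = K, terms = terms),
            class = "pooled_fit")
}

#' Update the tentative kernel with fitted movement coefficients
#'
#' The "integrated" correction of iSSF: the coefficients of the movement
#' terms adjust the tentative gamma / von Mises parameters —
#' `shape' = shape + beta_log_sl`, `rate' = rate - beta_sl`,
#' `kappa' = kappa + beta_cos_ta`.
#'
#' @param tentative the tentative [movement_kernel()].
#' @param fit an `issf_fit` containing `sl` and `cos_ta` (and usually
#'   `log_sl`) coefficients.
#' @return the updated [movement_kernel()].
#' @export
update_movement_kernel <- function(tentative, fit) {
  b <- fit$coef
  if (!all(c("sl", "cos_ta") %in% names(b)))
    stop2("fit must contain movement terms 'sl' and 'cos_ta'")
  shape <- tentative$shape + if ("log_sl" %in% names(b)) b[["log_sl"]] else 0
  rate <- tentative$rate - b[["sl"]]
  kappa <- tentative$kappa + b[["cos_ta"]]
  if (shape <= 0 || rate <= 0)
    stop2(sprintf(
      "updated kernel infeasible: shape = %.4g, rate = %.4g (must be > 0)",
      shape, rate))
  movement_kernel(shape = shape, rate = rate, kappa = max(kappa, 0))
}

#' Selection coefficients on the natural covariate scale
#'
#' Divides each standardized coefficient (and its standard error) by the
#' covariate's fitting-scale sd, so fits standardized over different row
#' sets become comparable and simulation truths can be checked in natural
#' units.
#'
#' @param fit an `issf_fit` with a standardization table.
#' @param terms which coefficients to convert (default: all in the table).
#' @return data.frame `term`, `coef_natural`, `se_natural`.
#' @export
coef_natural <- function(fit, terms = NULL) {
  std <- fit$standardization
  if (is.null(std)) stop2("fit carries no standardization table")
  if (is.null(terms)) terms <- intersect(names(fit$coef), rownames(std))
  sds <- vapply(terms, function(tm)
    if (tm %in% rownames(std)) std[tm, "sd"] else 1, 0)
  data.frame(term = terms,
             coef_natural = fit$coef[terms] / sds,
             se_natural = fit$se[terms] / sds,
             row.names = NULL)
}
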