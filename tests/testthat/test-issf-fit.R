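test_that("gamma MLE recovers simulated kernels and matches an independent MLE", {
  set.seed(101)
  sl <- rgamma(10000, shape = 2, rate = 1 / 150)
  ta <- rvonmises(10000, 1.0)
  kern <- fit_tentative_kernel(sl, ta)
  expect_gt(kern$shape, 1.9); expect_lt(kern$shape, 2.1)
  fd <- suppressWarnings(MASS::fitdistr(sl, "gamma"))
  expect_equal(kern$shape, unname(fd$estimate["shape"]), tolerance = 1e-3)
  expect_equal(kern$rate, unname(fd$estimate["rate"]), tolerance = 1e-3)
  expect_gt(kern$kappa, 0.9); expect_lt(kern$kappa, 1.1)
})

test_that("uniform angles give near-zero kappa; degenerate angles error", {
  set.seed(7)
  sl <- rgamma(10000, 2, rate = 1 / 100)
  kern <- fit_tentative_kernel(sl, runif(10000, -pi, pi))
  expect_lt(kern$kappa, 0.05)
  expect_error(fit_tentative_kernel(sl, rep(0, 100)), "unbounded|degenerate")
  expect_error(fit_tentative_kernel(sl[1:10], runif(10, -pi, pi)),
               "at least 30")
  # zero lengths are replaced, with a message
  sl2 <- c(sl[1:100], 0, 0)
  expect_message(fit_tentative_kernel(sl2, runif(102, -pi, pi)),
                 "zero-length")
})

test_that("available steps: count, kernel law, and concentration limit", {
  kern <- movement_kernel(2, 1 / 150, 1)
  av <- draw_available_steps(c(0, 0), 0.3, kern, K = 10, seed = 1)
  expect_equal(nrow(av), 10L)
  # pooled candidate lengths follow the gamma law
  sl <- unlist(lapply(1:1000, function(s)
    draw_available_steps(c(0, 0), 0, kern, K = 10, seed = s)$sl))
  ks <- suppressWarnings(ks.test(sl, pgamma, shape = 2, rate = 1 / 150))
  expect_gt(ks$p.value, 0.01)
  # kappa -> 1e6: bearings glued to the incoming bearing
  tight <- draw_available_steps(c(0, 0), 0.7,
                                movement_kernel(2, 1 / 150, 1e6), K = 50,
                                seed = 2)
  expect_lt(max(abs(tight$bearing - 0.7)), 0.01)
  expect_error(draw_available_steps(c(0, 0), 0, kern, K = 0), "K")
})

test_that("the step design has K+1 rows per stratum with one used row", {
  fw <- fixture_world()
  kern <- movement_kernel(2, 1 / 50, 1)    # short steps: no off-raster drops
  tr <- make_regular_track(n = 101, step = 50)
  tr$burst_id <- 1L
  des <- build_step_design(tr, fw$stack, kern, K = 10, seed = 5)
  expect_equal(nrow(des), 100 * 11)
  expect_true(all(tapply(des$used, des$stratum, sum) == 1))
  expect_true(all(tapply(des$used, des$stratum, length) == 11))
  # covariates of sampled rows equal direct extraction (after back-transform)
  std <- attr(des, "standardization")
  set.seed(3)
  pick <- sample(nrow(des), 20)
  direct <- extract_covariates(des[pick, c("x", "y")], fw$stack)
  for (nm in c("tree_cover", "trail_distance", "slope", "elevation")) {
    expect_equal(unstandardize(des[[nm]][pick], std, nm), direct[[nm]],
                 tolerance = 1e-9)
  }
  expect_equal(des$hba_in[pick], direct$hba)
})

test_that("a 5-stratum toy fit matches grid-search likelihood maximization", {
  des <- sim_choice_design(5, 3, beta = c(x1 = 0.7), seed = 12)
  fit <- fit_conditional_logit(des, terms = "x1")
  # enumerate the conditional likelihood on a fine grid
  ll <- function(b) {
    eta <- b * des$x1
    sum(tapply(seq_len(nrow(des)), des$stratum, function(i)
      eta[i][des$used[i]] - log(sum(exp(eta[i])))))
  }
  grid <- seq(-3, 3, by = 1e-4)
  b_grid <- grid[which.max(vapply(grid, ll, 0))]
  expect_equal(unname(fit$coef), b_grid, tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("simulation recovery: coefficients land within 3 se of truth", {
  beta <- c(x1 = 0.5, x2 = -0.3)
  des <- sim_choice_design(5000, 10, beta, seed = 77)
  fit <- fit_conditional_logit(des, terms = c("x1", "x2"))
  expect_true(all(abs(fit$coef - beta) < 3 * fit$se))
  # cross-check against the survival package's conditional logit
  cf <- oracle_survival_clogit(des, c("x1", "x2"))
  expect_equal(fit$coef, cf, tolerance = 1e-5)
})

test_that("the null log-likelihood is -sum(log(stratum size)) exactly", {
  des <- sim_choice_design(50, 10, c(x1 = 0.4), seed = 3)
  prep <- dielssf:::clogit_prepare(des, "x1")
  res <- suppressWarnings(
    dielssf:::clogit_newton(prep$X, prep$stratum, prep$used, max_iter = 0L))
  expect_equal(res$loglik, -50 * log(11), tolerance = 1e-12)
})

test_that("stratum order does not affect the estimate", {
  des <- sim_choice_design(200, 5, c(x1 = 0.4, x2 = 0.2), seed = 8)
  fit1 <- fit_conditional_logit(des, terms = c("x1", "x2"))
  set.seed(1)
  des2 <- des[order(sample(des$stratum)), ]
  fit2 <- fit_conditional_logit(des2, terms = c("x1", "x2"))
  expect_equal(fit1$coef, fit2$coef, tolerance = 1e-12)
})

test_that("within-stratum-constant covariates raise a named rank error", {
  des <- sim_choice_design(20, 4, c(x1 = 0.3), seed = 5)
  des$bad <- rep(rnorm(20), each = 5)   # constant within every stratum
  expect_error(fit_conditional_logit(des, terms = c("x1", "bad")), "bad")
})

test_that("Poisson-profile and conditional-logit estimates coincide", {
  for (s in 1:3) {
    des <- sim_choice_design(300, 10, c(x1 = 0.6, x2 = -0.4, x3 = 0), seed = s)
    f1 <- fit_conditional_logit(des, terms = c("x1", "x2", "x3"))
    f2 <- poisson_profile_fit(des, terms = c("x1", "x2", "x3"))
    expect_lt(max(abs(f1$coef - f2$coef)), 1e-6)
    expect_equal(f1$se, f2$se, tolerance = 1e-6)
    # profiled Poisson log-likelihood differs by the beta-free constant -n
    expect_equal(f2$loglik, f1$loglik - f1$n_strata, tolerance = 1e-8)
  }
  # interaction specs preserve the equivalence
  des <- sim_choice_design(300, 10, c(x1 = 0.5, x2 = 0.2), seed = 9)
  f1 <- fit_conditional_logit(des, terms = c("x1", "x2", "x1:x2"))
  f2 <- poisson_profile_fit(des, terms = c("x1", "x2", "x1:x2"))
  expect_lt(max(abs(f1$coef - f2$coef)), 1e-6)
})

test_that("likelihood is monotone over Newton iterations", {
  des <- sim_choice_design(500, 10, c(x1 = 1.5, x2 = -1), seed = 4)
  prep <- dielssf:::clogit_prepare(des, c("x1", "x2"))
  lls <- vapply(0:6, function(k)
    suppressWarnings(dielssf:::clogit_newton(prep$X, prep$stratum, prep$used,
                                             max_iter = k))$loglik, 0)
  expect_true(all(diff(lls) >= -1e-10))
})

test_that("DerSimonian-Laird pooling matches hand arithmetic", {
  mk_fit <- function(b, v) {
    structure(list(coef = c(x1 = b), se = c(x1 = sqrt(v)), terms = "x1",
                   converged = TRUE), class = "issf_fit")
  }
  # singleton: pooled = the fit, tau2 = 0
  p1 <- pool_individual_fits(list(mk_fit(0.4, 0.04)))
  expect_equal(unname(p1$coef), 0.4)
  expect_equal(unname(p1$tau2), 0)
  # two identical fits: mean unchanged, variance halves
  p2 <- pool_individual_fits(list(mk_fit(0.4, 0.04), mk_fit(0.4, 0.04)))
  expect_equal(unname(p2$coef), 0.4)
  expect_equal(unname(p2$se^2), 0.02)
  expect_equal(unname(p2$tau2), 0)
  # three spread fits: hand DerSimonian-Laird
  b <- c(0.2, 0.5, 0.8); v <- rep(0.01, 3)
  w <- 1 / v
  bfe <- sum(w * b) / sum(w)
  Q <- sum(w * (b - bfe)^2)
  tau2 <- max(0, (Q - 2) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (v + tau2)
  p3 <- pool_individual_fits(list(mk_fit(0.2, 0.01), mk_fit(0.5, 0.01),
                                  mk_fit(0.8, 0.01)))
  expect_equal(unname(p3$coef), sum(wr * b) / sum(wr), tolerance = 1e-12)
  expect_equal(unname(p3$se^2), 1 / sum(wr), tolerance = 1e-12)
  expect_equal(unname(p3$tau2), tau2, tolerance = 1e-12)
  expect_error(pool_individual_fits(list()), "no convergent")
})

test_that("kernel updating: identity, arithmetic and infeasibility", {
  tent <- movement_kernel(2, 0.01, 1)
  zero <- structure(list(coef = c(sl = 0, log_sl = 0, cos_ta = 0)),
                    class = "issf_fit")
  up <- update_movement_kernel(tent, zero)
  expect_equal(up$shape, 2); expect_equal(up$rate, 0.01); expect_equal(up$kappa, 1)
  f <- structure(list(coef = c(sl = -0.002, log_sl = 0.3, cos_ta = 0.2)),
                 class = "issf_fit")
  up2 <- update_movement_kernel(tent, f)
  expect_equal(up2$rate, 0.012)
  expect_equal(up2$shape, 2.3)
  expect_equal(up2$kappa, 1.2)
  expect_lt(up2$shape / up2$rate, tent$shape / tent$rate)  # mean step shrinks
  bad <- structure(list(coef = c(sl = 0.02, log_sl = 0, cos_ta = 0)),
                   class = "issf_fit")
  expect_error(update_movement_kernel(tent, bad), "infeasible")
})

test_that("kernel updating recovers the true movement law from a mismatched tentative fit", {
  truth <- movement_kernel(2.5, 1 / 200, 1)
  tent <- movement_kernel(2, 1 / 150, 0.6)
  des <- sim_kernel_design(5000, 10, truth, tent, seed = 19)
  fit <- fit_conditional_logit(des, terms = c("sl", "log_sl", "cos_ta"))
  up <- update_movement_kernel(tent, fit)
  expect_lt(abs(up$shape - 2.5) / 2.5, 0.1)
  expect_lt(abs(up$rate - 1 / 200) / (1 / 200), 0.1)
  expect_lt(abs(up$kappa - 1) / 1, 0.1)
})

test_that("Wald intervals attain near-nominal coverage", {
  beta <- c(x1 = 0.5, x2 = -0.3)
  hits <- matrix(FALSE, 60, 2)
  for (r in seq_len(nrow(hits))) {
    des <- sim_choice_design(400, 10, beta, seed = 1000 + r)
    fit <- fit_conditional_logit(des, terms = c("x1", "x2"))
    hits[r, ] <- abs(fit$coef - beta) <= 1.96 * fit$se
  }
  cov <- colMeans(hits)
  expect_true(all(cov >= 0.85 & cov <= 1))   # coarse screen; the full
  # 200-replicate calibration runs in the acceptance suite
})
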