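mk_fit2 <- function() {
  # deterministic two-covariate fit object for log-RSS algebra
  terms <- c("tree_cover", "slope", "sl", "cos_ta")
  vcov <- diag(c(0.04, 0.01, 1e-6, 1e-4)) +
    matrix(c(0, 0.005, 0, 0, 0.005, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0), 4, 4)
  dimnames(vcov) <- list(terms, terms)
  structure(list(
    coef = c(tree_cover = log(2), slope = -0.5, sl = 0.001, cos_ta = 0.1),
    vcov = vcov, terms = terms, converged = TRUE),
    class = "issf_fit")
}

test_that("log-RSS: identity, closed form, antisymmetry, dimension check", {
  fit <- mk_fit2()
  id <- log_rss(fit, c(tree_cover = 1), c(tree_cover = 1))
  expect_equal(id$estimate, 0)
  expect_lte(id$lower, 0); expect_gte(id$upper, 0)
  # one sd increase under beta = ln 2 doubles the selection strength
  one <- log_rss(fit, c(tree_cover = 1))
  expect_equal(one$estimate, log(2))
  expect_equal(one$se, 0.2)
  expect_equal(one$lower, log(2) - 1.96 * 0.2)
  a <- log_rss(fit, c(tree_cover = 1.3, slope = -0.4), c(slope = 1))
  b <- log_rss(fit, c(slope = 1), c(tree_cover = 1.3, slope = -0.4))
  expect_equal(a$estimate, -b$estimate, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
  expect_error(log_rss(fit, c(sl = 1)), "not selection terms")
  expect_error(log_rss(fit, c(nope = 1)), "not selection terms")
})

test_that("Holm adjustment reproduces the worked example and its properties", {
  expect_equal(holm_adjust(c(0.01, 0.03, 0.04)), c(0.03, 0.06, 0.06))
  # order invariance
  p <- c(0.04, 0.01, 0.03)
  expect_equal(holm_adjust(p), c(0.06, 0.03, 0.06))
  set.seed(2)
  for (i in 1:10) {
    q <- runif(7)
    perm <- sample(7)
    expect_equal(holm_adjust(q)[perm], holm_adjust(q[perm]), tolerance = 1e-15)
  }
  # singleton family: identity capped at 1
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(1), 1)
  # m exceeding the list length scales the first factors up
  expect_equal(holm_adjust(c(0.01, 0.03), m = 5), c(0.05, 0.12))
  expect_error(holm_adjust(c(0.1, 0.2), m = 1), "m must be")
  # agrees with stats::p.adjust when m = length(p)
  q <- runif(20)
  expect_equal(holm_adjust(q), p.adjust(q, method = "holm"), tolerance = 1e-15)
  # monotone and never below raw
  adj <- holm_adjust(q)
  expect_true(all(adj >= q))
  o <- order(q)
  expect_true(all(diff(adj[o]) >= -1e-15))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

# a month x diel design built directly from the conditional-logit law
sim_grid_design <- function(months, beta_day, beta_night, n_strata, K = 5,
                            seed = 1) {
  set.seed(seed)
  parts <- list()
  s0 <- 0L
  for (m in months) for (dc in c("day", "night")) {
    beta <- if (dc == "day") beta_day else beta_night
    d <- sim_choice_design(n_strata, K, beta)
    d$stratum <- d$stratum + s0
    s0 <- s0 + n_strata
    d$month <- m
    d$diel <- dc
    parts[[length(parts) + 1L]] <- d
  }
  do.call(rbind, parts)
}

test_that("planted day/night contrasts surface in the monthly effect grid", {
  des <- sim_grid_design(6:8, beta_day = c(tree_cover = 0.8, slope = 0),
                         beta_night = c(tree_cover = -0.8, slope = 0),
                         n_strata = 300, seed = 42)
  grid <- monthly_effect_grid(des, covariates = c("tree_cover", "slope"),
                              movement_terms = character(0))
  expect_setequal(unique(na.omit(grid$class)),
                  c("positive", "negative", "nonsignificant"))
  tree <- grid[grid$covariate == "tree_cover", ]
  expect_true(all(tree$class[tree$diel == "day"] == "positive"))
  expect_true(all(tree$class[tree$diel == "night"] == "negative"))
  # classification is reproducible from stored p and sign
  recls <- ifelse(grid$p_holm < 0.05,
                  ifelse(grid$beta > 0, "positive", "negative"),
                  "nonsignificant")
  expect_equal(recls, grid$class)
  expect_equal(attr(grid, "family_size"), sum(!is.na(grid$p_raw)))
})

test_that("null monthly grids keep the family-wise error rate near alpha", {
  false_hits <- vapply(1:20, function(r) {
    des <- sim_grid_design(7, beta_day = c(x1 = 0, x2 = 0),
                           beta_night = c(x1 = 0, x2 = 0),
                           n_strata = 150, seed = 500 + r)
    g <- monthly_effect_grid(des, covariates = c("x1", "x2"),
                             movement_terms = character(0))
    any(g$class != "nonsignificant", na.rm = TRUE)
  }, logical(1))
  expect_lte(mean(false_hits), 0.05 + 2 * sqrt(0.05 * 0.95 / 20))
})

# September designs with an HBA factor and optional interaction
sim_hba_design <- function(n_strata, K, b_out, b_in, seed = 1) {
  set.seed(seed)
  n <- n_strata * (K + 1)
  x <- rnorm(n)
  hba <- rbinom(n, 1, 0.5)
  eta <- ifelse(hba == 1, b_in, b_out) * x + 0.3 * hba
  stratum <- rep(seq_len(n_strata), each = K + 1)
  used <- logical(n)
  for (s in seq_len(n_strata)) {
    rows <- (s - 1) * (K + 1) + seq_len(K + 1)
    p <- exp(eta[rows] - max(eta[rows]))
    used[rows[sample.int(K + 1, 1, prob = p)]] <- TRUE
  }
  data.frame(stratum = stratum, used = used, tree_cover = x, hba_in = hba,
             month = 9L, diel = "day")
}

test_that("September HBA contrast: null and planted interactions behave", {
  # identical selection inside and outside: interaction near zero
  d0 <- sim_hba_design(800, 5, b_out = 0.5, b_in = 0.5, seed = 3)
  r0 <- september_hba_contrast(d0, covariates = "tree_cover",
                               movement_terms = character(0))
  expect_lt(abs(r0$interactions$beta), 3 * r0$interactions$se)
  # weaker selection inside the ban area: negative interaction, flatter curve
  d1 <- sim_hba_design(800, 5, b_out = 0.6, b_in = 0.2, seed = 4)
  r1 <- september_hba_contrast(d1, covariates = "tree_cover",
                               movement_terms = character(0))
  expect_true(r1$interactions$significant)
  expect_lt(r1$interactions$beta, 0)
  slope_of <- function(cv, lev) {
    cu <- r1$curves[r1$curves$covariate == cv & r1$curves$hba == lev, ]
    coef(lm(estimate ~ x, cu))[["x"]]
  }
  expect_lt(slope_of("tree_cover", "inside"), slope_of("tree_cover", "outside"))
  # reference identity at both levels
  f <- r1$fit
  for (lev in c(0, 1)) {
    x1 <- setNames(c(0, lev, 0), c("tree_cover", "hba_in", "tree_cover:hba_in"))
    x2 <- setNames(c(lev, 0), c("hba_in", "tree_cover:hba_in"))
    expect_equal(log_rss(f, x1, x2)$estimate, 0)
  }
  # guards
  expect_error(september_hba_contrast(transform(d0, month = 8),
                                      covariates = "tree_cover",
                                      movement_terms = character(0)),
               "September")
  d0$hba_in <- 0
  expect_error(september_hba_contrast(d0, covariates = "tree_cover",
                                      movement_terms = character(0)),
               "does not vary")
})

# Aug 15 - Oct 31 design with an HBA-by-hunting interaction
sim_hunt_design <- function(n_strata, K, b_hba, b_int, seed = 1,
                            p_hunt = 0.5) {
  set.seed(seed)
  n <- n_strata * (K + 1)
  x <- rnorm(n)
  hba <- rbinom(n, 1, 0.5)
  hunt <- rep(rbinom(n_strata, 1, p_hunt), each = K + 1)  # per-stratum day
  eta <- 0.3 * x + b_hba * hba + b_int * hba * hunt
  stratum <- rep(seq_len(n_strata), each = K + 1)
  used <- logical(n)
  for (s in seq_len(n_strata)) {
    rows <- (s - 1) * (K + 1) + seq_len(K + 1)
    p <- exp(eta[rows] - max(eta[rows]))
    used[rows[sample.int(K + 1, 1, prob = p)]] <- TRUE
  }
  data.frame(stratum = stratum, used = used, tree_cover = x, hba_in = hba,
             hunting_yes = hunt)
}

test_that("the HBA-by-hunting interaction is recovered and guarded", {
  des <- sim_hunt_design(900, 5, b_hba = 0.2, b_int = 0.8, seed = 11)
  res <- hunting_activity_interaction(des, covariates = "tree_cover",
                                      movement_terms = character(0))
  int <- res$effects[res$effects$term == "hba_in:hunting_yes", ]
  expect_lt(abs(int$beta - 0.8), 3 * int$se)
  expect_gt(int$beta, 0)
  # hunting never active -> single-level factor error
  des0 <- sim_hunt_design(100, 5, 0.2, 0.8, seed = 2, p_hunt = 0)
  expect_error(hunting_activity_interaction(des0, covariates = "tree_cover",
                                            movement_terms = character(0)),
               "single level")
})

test_that("the planted interaction beats its permutation null", {
  des <- sim_hunt_design(400, 5, b_hba = 0.2, b_int = 0.8, seed = 21)
  fit_z <- function(d) {
    f <- fit_conditional_logit(d, terms = c("tree_cover", "hba_in",
                                            "hba_in:hunting_yes"))
    f$z[["hba_in:hunting_yes"]]
  }
  z_obs <- fit_z(des)
  hunt_by_stratum <- tapply(des$hunting_yes, des$stratum, function(v) v[1])
  set.seed(33)
  z_perm <- vapply(1:200, function(i) {
    d <- des
    d$hunting_yes <- rep(sample(hunt_by_stratum), each = 6)
    fit_z(d)
  }, 0)
  expect_gt(z_obs, quantile(abs(z_perm), 0.95))
})

test_that("log-RSS interval width shrinks like one over root strata", {
  widths <- vapply(c(250, 1000), function(n) {
    des <- sim_choice_design(n, 5, c(x1 = 0.4), seed = n)
    fit <- fit_conditional_logit(des, terms = "x1")
    r <- log_rss(fit, c(x1 = 1))
    r$upper - r$lower
  }, 0)
  ratio <- widths[1] / widths[2]     # expect ~2 for a 4x stratum increase
  expect_gt(ratio, 1.4); expect_lt(ratio, 2.8)
})
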