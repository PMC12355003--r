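#' Log relative selection strength between two habitat points
#'
#' `log-RSS(x1, x2) = beta^T (x1 - x2)` over the selection (non-movement)
#' terms: the log of the relative probability of choosing habitat `x1`
#' over `x2` when both are equally available. The 95 % CI is the delta
#' method (`se = sqrt(d' Sigma d)`, normal 1.96 quantile). Points are
#' named vectors on the model's (standardized) covariate scale; terms not
#' named are taken at the reference — 0, i.e. the "average habitat" and
#' factor reference levels — so the default `x2` *is* the average habitat.
#'
#' @param fit an `issf_fit`.
#' @param x1,x2 named numeric vectors over (a subset of) the fit's
#'   selection terms.
#' @return one-row data.frame `estimate`, `se`, `lower`, `upper`.
#' @export
log_rss <- function(fit, x1, x2 = numeric(0)) {
  sel <- setdiff(fit$terms, c("sl", "log_sl", "cos_ta"))
  bad <- setdiff(unique(c(names(x1), names(x2))), sel)
  if (length(bad))
    stop2("not selection terms of this fit: ", paste(bad, collapse = ", "))
  to_full <- function(x) {
    v <- stats::setNames(rep(0, length(sel)), sel)
    v[names(x)] <- x
    v
  }
  d <- to_full(x1) - to_full(x2)
  est <- sum(fit$coef[sel] * d)
  se <- sqrt(as.numeric(t(d) %*% fit$vcov[sel, sel, drop = FALSE] %*% d))
  data.frame(estimate = est, se = se,
             lower = est - 1.96 * se, upper = est + 1.96 * se)
}

#' Holm-Bonferroni adjustment
#'
#' Step-down multiple-testing correction: with the p-values sorted
#' ascending, `adj(i) = max_{j <= i} min(1, (m - j + 1) * p(j))`, mapped
#' back to the input order. `m` may exceed the number supplied, supporting
#' families spread over several model files.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param m family size (>= `length(p)`; default `length(p)`).
#' @return adjusted p-values in input order.
#' @export
holm_adjust <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop2("p-values must lie in [0, 1]")
  if (m < length(p)) stop2("family size m must be >= length(p)")
  if (!length(p)) return(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- cummax(pmin(1, (m - seq_along(ps) + 1) * ps))
  out <- numeric(length(p))
  out[ord] <- adj
  out
}

#' Month-by-diel effect grid
#'
#' Fits one selection model per (month, diel) cell of a design, collects
#' the per-covariate Wald p-values, Holm-adjusts them across the whole
#' family, and classifies each effect as `"positive"`, `"negative"` or
#' `"nonsignificant"` at the adjusted alpha — the traffic-light overview
#' of monthly day/night habitat selection.
#'
#' @param design a [build_step_design()] result with `month` and `diel`.
#' @param covariates selection terms entering every cell's model.
#' @param movement_terms movement terms included in every model.
#' @param m Holm family size; default = number of tests in this grid.
#' @param alpha significance level (default 0.05).
#' @return data.frame `month`, `diel`, `covariate`, `beta`, `se`, `p_raw`,
#'   `p_holm`, `class` (`NA` rows mark non-convergent cells); attribute
#'   `family_size` records `m`.
#' @export
monthly_effect_grid <- function(design,
                                covariates = c("tree_cover", "trail_distance",
                                               "slope", "elevation", "hba_in"),
                                movement_terms = default_movement_terms(),
                                m = NULL, alpha = 0.05) {
  cells <- unique(design[, c("month", "diel")])
  cells <- cells[order(cells$month, cells$diel), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- design[design$month == cells$month[i] & design$diel == cells$diel[i], ,
                  drop = FALSE]
    fit <- tryCatch({
      sub <- zstandardize(unstd_copy(sub, design), covariates_present(covariates))
      fit_conditional_logit(sub, terms = c(covariates, movement_terms))
    }, error = function(e) NULL, warning = function(w) NULL)
    for (cv in covariates) {
      rows[[length(rows) + 1L]] <- data.frame(
        month = cells$month[i], diel = cells$diel[i], covariate = cv,
        beta = if (is.null(fit)) NA_real_ else unname(fit$coef[cv]),
        se = if (is.null(fit)) NA_real_ else unname(fit$se[cv]),
        p_raw = if (is.null(fit)) NA_real_ else unname(fit$p[cv]))
    }
  }
  grid <- do.call(rbind, rows)
  if (is.null(m)) m <- sum(!is.na(grid$p_raw))
  ok <- !is.na(grid$p_raw)
  grid$p_holm <- NA_real_
  grid$p_holm[ok] <- holm_adjust(grid$p_raw[ok], m = max(m, sum(ok)))
  grid$class <- ifelse(!ok, NA_character_,
                       ifelse(grid$p_holm < alpha,
                              ifelse(grid$beta > 0, "positive", "negative"),
                              "nonsignificant"))
  attr(grid, "family_size") <- m
  attr(grid, "alpha") <- alpha
  grid
}

# re-standardizing a subset requires the natural-scale values: invert the
# parent design's table first (cells are fits of their own, scaled on
# their own rows)
unstd_copy <- function(sub, parent) {
  std <- attr(parent, "standardization")
  if (is.null(std)) return(sub)
  for (nm in rownames(std)) sub[[nm]] <- unstandardize(sub[[nm]], std, nm)
  attr(sub, "standardization") <- NULL
  sub
}

covariates_present <- function(covariates) {
  setdiff(covariates, "hba_in")
}

#' September inside/outside-HBA selection contrast
#'
#' Fits the hunting-season interaction model — every covariate interacted
#' with the HBA factor — on September strata, and emits, per covariate, a
#' pair of log-RSS curves (inside and outside HBAs, each relative to the
#' average habitat at its own HBA level) over the observed covariate
#' range, with pointwise 95 % CIs, plus Holm-adjusted tests of the
#' interaction coefficients.
#'
#' @param design a [build_step_design()] result restricted to September.
#' @param covariates continuous selection terms to interact with HBA.
#' @param movement_terms movement terms.
#' @param n_grid evaluation points per curve.
#' @param m Holm family size for the interaction tests (default = number
#'   of interactions).
#' @param alpha significance level.
#' @return list with `fit`, `curves` (data.frame `covariate`, `x`
#'   (standardized scale), `hba`, `estimate`, `lower`, `upper`) and
#'   `interactions` (coefficient, se, p_raw, p_holm, significant).
#' @export
september_hba_contrast <- function(design,
                                   covariates = c("tree_cover", "trail_distance",
                                                  "slope", "elevation"),
                                   movement_terms = default_movement_terms(),
                                   n_grid = 25, m = NULL, alpha = 0.05) {
  if (!all(design$month == 9L))
    stop2("design must be restricted to September strata")
  if (length(unique(design$hba_in[design$used])) < 2L &&
      length(unique(design$hba_in)) < 2L)
    stop2("HBA factor does not vary: interaction model is non-identifiable")
  inter <- paste0(covariates, ":hba_in")
  fit <- fit_conditional_logit(design,
                               terms = c(covariates, "hba_in", inter,
                                         movement_terms))
  if (is.null(m)) m <- length(inter)
  p_holm <- holm_adjust(unname(fit$p[inter]), m = max(m, length(inter)))
  interactions <- data.frame(
    covariate = covariates, term = inter,
    beta = unname(fit$coef[inter]), se = unname(fit$se[inter]),
    p_raw = unname(fit$p[inter]), p_holm = p_holm,
    significant = p_holm < alpha)
  curves <- list()
  for (cv in covariates) {
    xr <- range(design[[cv]], na.rm = TRUE)
    xs <- seq(xr[1], xr[2], length.out = n_grid)
    for (lev in c(0, 1)) {
      pts <- lapply(xs, function(g) {
        x1 <- stats::setNames(c(g, lev, g * lev), c(cv, "hba_in",
                                                    paste0(cv, ":hba_in")))
        x2 <- stats::setNames(c(lev, 0), c("hba_in", paste0(cv, ":hba_in")))
        log_rss(fit, x1, x2)
      })
      pts <- do.call(rbind, pts)
      curves[[length(curves) + 1L]] <- data.frame(
        covariate = cv, x = xs, hba = ifelse(lev == 1, "inside", "outside"),
        estimate = pts$estimate, lower = pts$lower, upper = pts$upper)
    }
  }
  list(fit = fit, curves = do.call(rbind, curves), interactions = interactions)
}

#' HBA-by-hunting-activity interaction
#'
#' On a design covering the Aug 15 - Oct 31 window, fits the model with
#' HBA and the HBA-by-hunting interaction (plus the environmental
#' covariates and movement terms) and reports the focal coefficients. The
#' hunting-activity *main* effect is a property of the step's date, hence
#' constant within every stratum and absorbed by the stratum intercepts —
#' it is not estimable in a matched-stratum design and is not included. A
#' positive interaction means the selection for hunting-ban areas
#' strengthens on days with hunting activity.
#'
#' @param design a [build_step_design()] result with a `hunting_yes`
#'   column taking both values.
#' @param covariates environmental terms kept in the model.
#' @param movement_terms movement terms.
#' @param m Holm family size for the three focal tests.
#' @param alpha significance level.
#' @return list with `fit` and `effects` (data.frame for `hba_in` and
#'   `hba_in:hunting_yes`).
#' @export
hunting_activity_interaction <- function(design,
                                         covariates = c("tree_cover",
                                                        "trail_distance",
                                                        "slope", "elevation"),
                                         movement_terms = default_movement_terms(),
                                         m = NULL, alpha = 0.05) {
  if (length(unique(design$hunting_yes)) < 2L)
    stop2("hunting factor has a single level in this design; ",
          "the hunting calendar must yield both levels inside the window")
  focal <- c("hba_in", "hba_in:hunting_yes")
  fit <- fit_conditional_logit(design,
                               terms = c(covariates, focal, movement_terms))
  if (is.null(m)) m <- length(focal)
  p_holm <- holm_adjust(unname(fit$p[focal]), m = max(m, length(focal)))
  effects <- data.frame(term = focal, beta = unname(fit$coef[focal]),
                        se = unname(fit$se[focal]),
                        p_raw = unname(fit$p[focal]), p_holm = p_holm,
                        significant = p_holm < alpha)
  list(fit = fit, effects = effects)
}
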