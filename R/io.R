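#' Read and write track tables
#'
#' Tracks travel as CSV with columns `animal_id`, `timestamp` (ISO-8601
#' UTC), `x`, `y` and any extra columns (`burst_id`, `diel`, QC flags)
#' round-tripped verbatim.
#'
#' @param track track data.frame.
#' @param path file path.
#' @export
write_track_csv <- function(track, path) {
  out <- track
  out$timestamp <- format(as_utc(out$timestamp), "%Y-%m-%dT%H:%M:%SZ")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$timestamp <- as.POSIXct(x$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")
  x
}

#' Write a fit result as JSON
#'
#' Serializes coefficients, standard errors, Wald statistics, the
#' covariance matrix and convergence diagnostics.
#'
#' @param fit an `issf_fit`.
#' @param path file path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    method = fit$method, terms = fit$terms,
    coef = as.list(fit$coef), se = as.list(fit$se), z = as.list(fit$z),
    p = as.list(fit$p), vcov = unname(fit$vcov), loglik = fit$loglik,
    iterations = fit$iterations, converged = fit$converged,
    n_strata = fit$n_strata),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the simulation truth manifest
#'
#' Records everything needed to audit a synthetic run: the day and night
#' coefficient vectors, kernel parameters, candidate count and seed.
#'
#' @param model a [true_model()].
#' @param seed the seed used.
#' @param path file path.
#' @export
write_truth_manifest <- function(model, seed, path) {
  jsonlite::write_json(list(
    beta_day = as.list(model$beta_day),
    beta_night = as.list(model$beta_night),
    kernel = list(shape = model$kernel$shape, rate = model$kernel$rate,
                  kappa = model$kernel$kappa),
    M = model$M, seed = seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot a month-by-diel effect grid
#'
#' The traffic-light panel: one tile per (month, diel, covariate) with a
#' plus for significant positive, minus for significant negative and a
#' circle for nonsignificant effects (after Holm adjustment).
#'
#' @param grid a [monthly_effect_grid()] result.
#' @return a ggplot object.
#' @export
plot_effect_grid <- function(grid) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop2("plot_effect_grid needs the ggplot2 package")
  grid$sym <- c(positive = "+", negative = "−",
                nonsignificant = "o")[grid$class]
  ggplot2::ggplot(grid, ggplot2::aes(x = factor(month), y = covariate)) +
    ggplot2::geom_tile(ggplot2::aes(fill = class), colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = sym), size = 5) +
    ggplot2::facet_wrap(~diel) +
    ggplot2::scale_fill_manual(
      values = c(positive = "#7fbf7b", negative = "#bdbdbd",
                 nonsignificant = "#ffffbf"), na.value = "white") +
    ggplot2::labs(x = "month", y = NULL, fill = NULL)
}
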