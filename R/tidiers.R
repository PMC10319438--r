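# Broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @describeIn fit_diffusion_model One row per parameter (`term`,
#'   `estimate`).
#' @param x,object A fitted object.
#' @param ... Unused.
#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates),
                 estimate = unlist(x$estimates, use.names = FALSE))
}

#' @describeIn fit_diffusion_model One-row model summary.
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(n_states = x$n_states, rss = x$rss, n_jumps = x$n_jumps,
                 sigma = x$sigma, dZ = x$dZ)
}

#' @describeIn fit_diffusion_model Jump-length histograms with the fitted
#'   density overlaid, faceted by lag.
#' @export
autoplot.diffusion_fit <- function(object, ...) {
  h <- object$hist
  dat <- h$data
  dat$density <- dat$count / (h$n_jumps[dat$lag] * h$bin_width)
  d_names <- grep("^D", names(object$estimates), value = TRUE)
  D <- unlist(object$estimates[d_names], use.names = FALSE)
  names(D) <- d_names
  f <- unlist(object$estimates[paste0("F", sub("^D", "", d_names))],
              use.names = FALSE)
  Zs <- if (identical(object$defocus, "pair")) {
    matrix(vapply(unname(D), defocus_pair_retention, numeric(h$n_lags),
                  n_max = h$n_lags, dt = h$frame_interval, dZ = object$dZ),
           nrow = h$n_lags)
  } else NULL
  fit <- dplyr::group_by(dat, .data$lag)
  fit <- dplyr::mutate(fit, fitted = model_density(
    .data$r_mid, .data$lag[1], h$frame_interval, unname(D), f,
    sigma = object$sigma, dZ = object$dZ,
    Z = if (is.null(Zs)) NULL else Zs[.data$lag[1], ]))
  fit <- dplyr::ungroup(fit)
  ggplot2::ggplot(fit, ggplot2::aes(x = .data$r_mid)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$density),
                      width = h$bin_width, fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::facet_wrap(~lag, labeller = ggplot2::label_both) +
    ggplot2::coord_cartesian(xlim = c(0, stats::quantile(
      rep(fit$r_mid, pmax(fit$count, 0)), 0.999))) +
    ggplot2::labs(x = "jump length (um)", y = "probability density")
}

#' @describeIn fit_biexponential One row per parameter.
#' @param x,object A fitted object.
#' @param ... Unused.
#' @export
tidy.biexp_fit <- function(x, ...) {
  tibble::tibble(term = c("t_half_fast", "t_half_slow", "fraction_slow"),
                 estimate = c(x$t_half_fast, x$t_half_slow, x$fraction_slow))
}

#' @describeIn fit_biexponential One-row fit summary.
#' @export
glance.biexp_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, rss = x$rss,
                 n = nrow(x$curve))
}

#' @describeIn fit_biexponential Survival curve with the fitted decay
#'   (log-scaled y).
#' @export
autoplot.biexp_fit <- function(object, ...) {
  cv <- object$curve
  u <- cv$tau_s - object$tau0
  cv$fitted <- (1 - object$fraction_slow) * 2^(-u / object$t_half_fast) +
    object$fraction_slow * 2^(-u / object$t_half_slow)
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$tau_s)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$survival)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "residence time (s)", y = "survival probability")
}

#' @describeIn survival_curve Step plot of the survival probability.
#' @param object A `survival_curve`.
#' @param ... Unused.
#' @export
autoplot.survival_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tau_s, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "track duration (s)", y = "survival probability")
}

#' @describeIn fit_one_phase One row per parameter.
#' @param x,object A fitted object.
#' @param ... Unused.
#' @export
tidy.one_phase_fit <- function(x, ...) {
  tibble::tibble(term = c("K", "t_half_s"), estimate = c(x$K, x$t_half_s))
}

#' @describeIn fit_one_phase One-row fit summary.
#' @export
glance.one_phase_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, rss = x$rss, n = nrow(x$curve))
}

#' @describeIn fit_one_phase Recruitment curve with the fitted one-phase
#'   association.
#' @export
autoplot.one_phase_fit <- function(object, ...) {
  cv <- object$curve
  cv$fitted <- ifelse(cv$time_s > 0, 1 - exp(-object$K * cv$time_s), 0)
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity_norm), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "time after irradiation (s)",
                  y = "normalized intensity")
}

#' @describeIn fit_standard_curve Slope, intercept and R-squared as rows.
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble::tibble(term = c("slope", "intercept", "r_squared"),
                 estimate = c(x$slope, x$intercept, x$r_squared))
}

#' @describeIn bleach_half_life Half-life and rate as rows.
#' @param x A `bleach_fit`.
#' @param ... Unused.
#' @export
tidy.bleach_fit <- function(x, ...) {
  tibble::tibble(term = c("half_life_s", "rate_per_s"),
                 estimate = c(x$half_life_s, x$rate_per_s))
}
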