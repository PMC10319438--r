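# Residence-time analysis of chromatin-bound molecules: constrained tracking
# on frame-averaged movies, survival curves of track durations, biexponential
# decay fitting, and photobleach calibration.

#' Track low-mobility molecules on a frame-averaged movie
#'
#' Runs detection and linking with the search radius generated from
#' `D_max_bound` and, by default, no gap allowance, so only molecules that
#' stay put frame after frame are linked. The input should already be
#' frame-averaged ([average_frames()]), which blurs out mobile molecules and
#' amplifies static ones.
#'
#' @param movie An [spt_movie()] after frame averaging.
#' @param threshold Detection intensity threshold (see [detect_spots()]).
#' @param D_max_bound Maximum expected diffusion coefficient of bound
#'   molecules, um^2/s (default 0.5).
#' @param max_gaps Gap allowance (default 0: residence times are not inflated
#'   by bridging dark frames).
#' @param min_track_length Minimum localizations per track.
#' @param psf_sigma_px PSF standard deviation in pixels.
#' @param nuclear_mask Optional logical matrix restricting localizations.
#' @param margin Search-radius factor; 1 (the default) treats `D_max_bound`
#'   as a hard mobility constraint, which is what excludes molecules moving
#'   faster than the bound population.
#' @return Trajectory tibble with attribute `"frame_interval_s"`.
#' @export
track_bound <- function(movie, threshold, D_max_bound = 0.5, max_gaps = 0,
                        min_track_length = 3, psf_sigma_px = 1.0,
                        nuclear_mask = NULL, margin = 1) {
  params <- linking_params(D_max = D_max_bound, max_gaps = max_gaps,
                           min_track_length = min_track_length,
                           margin = margin)
  tr <- track_movie(movie, threshold, psf_sigma_px, params, nuclear_mask)
  attr(tr, "frame_interval_s") <- frame_interval(movie)
  tr
}

#' Track durations in seconds
#'
#' Duration counts from first to last frame inclusive:
#' `(last - first + 1) * frame_interval`.
#'
#' @param tracks Trajectory tibble.
#' @param frame_interval Effective frame interval, seconds (taken from the
#'   `"frame_interval_s"` attribute if absent).
#' @return Numeric vector of durations, one per track.
#' @export
track_durations <- function(tracks, frame_interval = NULL) {
  if (is.null(frame_interval)) {
    frame_interval <- attr(tracks, "frame_interval_s")
  }
  check_number(frame_interval, "frame_interval", min = 1e-12)
  d <- dplyr::summarise(dplyr::group_by(tracks, .data$track_id),
                        n_frames = max(.data$frame) - min(.data$frame) + 1)
  d$n_frames * frame_interval
}

#' Survival curve of track durations
#'
#' `S(tau) = #(durations > tau) / n` evaluated at each observed duration
#' (1 minus the empirical cumulative distribution of track lengths).
#'
#' @param durations Positive durations, seconds.
#' @return A `survival_curve` tibble (`tau_s`, `survival`) with `n_tracks`
#'   attribute; `S` is non-increasing and reaches 0 at the longest duration.
#' @export
survival_curve <- function(durations) {
  if (length(durations) == 0L || !is.numeric(durations)) {
    stop_spt("`durations` must be a non-empty numeric vector.",
             class = "sptkinetics_bad_argument")
  }
  taus <- sort(unique(durations))
  n <- length(durations)
  surv <- vapply(taus, function(t) sum(durations > t) / n, numeric(1))
  out <- tibble::new_tibble(
    list(tau_s = taus, survival = surv),
    n_tracks = n, class = "survival_curve")
  out
}

#' Fit a two-component exponential decay to a survival curve
#'
#' Least-squares fit of
#' `S(tau) = (1 - f) * 2^(-(tau - tau0) / t_fast) + f * 2^(-(tau - tau0) / t_slow)`
#' where `tau0` is the minimum trackable duration (the shortest observed
#' duration), `f` is the slow fraction and the half-lives are in seconds.
#' Deterministic multi-start via [minpack.lm::nlsLM()]; components are
#' reported ordered (`t_half_fast <= t_half_slow`).
#'
#' @param curve A [survival_curve()] (>= 5 distinct durations).
#' @return A `biexp_fit` object: `t_half_fast`, `t_half_slow`,
#'   `fraction_slow`, `r_squared`, `rss`. Supports [tidy()] and [glance()].
#' @export
fit_biexponential <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  if (nrow(curve) < 5L) {
    stop_spt("need at least 5 distinct durations to fit two components",
             class = "sptkinetics_bad_argument")
  }
  tau0 <- min(curve$tau_s)
  u <- curve$tau_s - tau0
  s <- curve$survival
  span <- max(u[s > 0], max(u) / 4)
  starts <- expand.grid(f = c(0.1, 0.3, 0.6, 0.9),
                        t_fast = span * c(0.02, 0.1, 0.3),
                        t_slow = span * c(0.5, 1, 3))
  dat <- data.frame(u = u, s = s)
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      s ~ (1 - f) * 2^(-u / t_fast) + f * 2^(-u / t_slow),
      data = dat,
      start = as.list(starts[k, ]),
      lower = c(f = 0, t_fast = 1e-6, t_slow = 1e-6),
      upper = c(f = 1, t_fast = Inf, t_slow = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop_spt("biexponential fit failed to converge from every start",
             class = "sptkinetics_fit_failure")
  }
  p <- coef(best$fit)
  t1 <- unname(p["t_fast"]); t2 <- unname(p["t_slow"]); f <- unname(p["f"])
  if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp; f <- 1 - f }
  r2 <- 1 - best$rss / sum((s - mean(s))^2)
  structure(list(t_half_fast = t1, t_half_slow = t2, fraction_slow = f,
                 r_squared = r2, rss = best$rss, tau0 = tau0,
                 curve = curve),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(
    "<biexp_fit> t_1/2 fast = %.3g s, t_1/2 slow = %.3g s, slow fraction = %.2f, R^2 = %.4f\n",
    x$t_half_fast, x$t_half_slow, x$fraction_slow, x$r_squared))
  invisible(x)
}

#' Photobleaching half-life from integrated nuclear intensity
#'
#' Integrates the masked (nuclear) signal per frame, subtracts the
#' out-of-mask background, and fits a single exponential decay
#' `I(t) = I0 * exp(-k * t)`; the half-life is `log(2) / k`. Calibrated on a
#' stably chromatin-incorporated protein (e.g. histone H2B), this bounds how
#' long any binding event can remain observable.
#'
#' @param x An [spt_movie()], or a numeric intensity series.
#' @param nuclear_mask Logical matrix selecting nuclear pixels (required for
#'   movies).
#' @param time_s Time points for a numeric series (seconds).
#' @return A `bleach_fit` object: `half_life_s`, `rate_per_s`, `rss`.
#'   A non-decaying signal raises an error of class
#'   `"sptkinetics_no_decay"`.
#' @export
bleach_half_life <- function(x, nuclear_mask = NULL, time_s = NULL) {
  if (inherits(x, "spt_movie")) {
    if (is.null(nuclear_mask) || !any(nuclear_mask)) {
      stop_spt("a non-empty `nuclear_mask` is required",
               class = "sptkinetics_bad_argument")
    }
    nt <- n_frames(x)
    sig <- vapply(seq_len(nt), function(k) {
      fr <- unclass(x)[, , k]
      bg <- if (all(nuclear_mask)) 0 else mean(fr[!nuclear_mask])
      sum(fr[nuclear_mask] - bg)
    }, numeric(1))
    time_s <- (seq_len(nt) - 1L) * frame_interval(x)
  } else {
    sig <- as.numeric(x)
    if (is.null(time_s)) time_s <- seq_along(sig) - 1
  }
  if (length(sig) < 3L) {
    stop_spt("need at least 3 time points", class = "sptkinetics_bad_argument")
  }
  pos <- sig > 0
  if (sum(pos) < 3L || stats::coef(lm(log(sig[pos]) ~ time_s[pos]))[2] >= 0) {
    stop_spt("signal does not decay; cannot estimate a bleaching half-life",
             class = "sptkinetics_no_decay")
  }
  lmfit <- lm(log(sig[pos]) ~ time_s[pos])
  start <- list(I0 = exp(coef(lmfit)[[1]]), k = -coef(lmfit)[[2]])
  dat <- data.frame(t = time_s, y = sig)
  fit <- minpack.lm::nlsLM(y ~ I0 * exp(-k * t), data = dat, start = start,
                           lower = c(I0 = 0, k = 1e-12))
  k <- coef(fit)[["k"]]
  structure(list(half_life_s = log(2) / k, rate_per_s = k,
                 rss = sum(stats::residuals(fit)^2)),
            class = "bleach_fit")
}

#' @export
print.bleach_fit <- function(x, ...) {
  cat(sprintf("<bleach_fit> half-life = %.3g s (rate %.4g /s)\n",
              x$half_life_s, x$rate_per_s))
  invisible(x)
}

#' Fraction of durations exceeding an observation window
#'
#' @param durations Durations, seconds.
#' @param T_s Window length, seconds (>= 0).
#' @return `#(durations > T_s) / n`.
#' @export
fraction_exceeding <- function(durations, T_s) {
  check_number(T_s, "T_s", min = 0)
  if (length(durations) == 0L) {
    stop_spt("`durations` must be non-empty.",
             class = "sptkinetics_bad_argument")
  }
  sum(durations > T_s) / length(durations)
}

#' Sample durations from a biexponential residence model
#'
#' Inverse-transform sampling of the mixture
#' `(1 - f) * Exp(log(2)/t_fast) + f * Exp(log(2)/t_slow)`; the reference
#' distribution used to validate [fit_biexponential()] round trips.
#'
#' @param n Number of durations.
#' @param fraction_slow Mixture weight of the slow component.
#' @param t_half_fast,t_half_slow Component half-lives, seconds.
#' @param seed Optional seed.
#' @return Numeric vector of durations.
#' @export
sample_biexponential <- function(n, fraction_slow, t_half_fast, t_half_slow,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  slow <- runif(n) < fraction_slow
  rate <- ifelse(slow, log(2) / t_half_slow, log(2) / t_half_fast)
  rexp(n, rate)
}
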