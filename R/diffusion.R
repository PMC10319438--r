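# Jump-length distribution analysis: histogram construction, the Brownian
# mixture probability density with axial defocus correction, and bounded
# multi-start least-squares fitting of two- and three-state models.

#' Build jump-length histograms from trajectories
#'
#' For each lag `n` in `1..n_lags`, collects displacement magnitudes between
#' localizations `n` frames apart with no gap inside the span (i.e. all
#' intermediate frames localized), taking at most `jumps_to_consider` jumps
#' per trajectory per lag (the first ones), and bins them with `bin_width`
#' wide bins. Jumps beyond `max_jump` still count toward the per-lag totals
#' used to normalize densities but are not binned.
#'
#' @param tracks Trajectory tibble (`track_id`, `frame`, `x_um`, `y_um`).
#' @param frame_interval Frame interval, seconds.
#' @param n_lags Number of lag times used (8 time points = 7 intervals).
#' @param jumps_to_consider Maximum jumps per trajectory per lag.
#' @param bin_width Histogram bin width, micrometers.
#' @param max_jump Upper edge of the binned range, micrometers.
#' @return A `jump_histograms` object: tibble `data` (`lag`, `r_mid`, `count`)
#'   plus the per-lag jump totals and settings.
#' @export
compute_jump_histograms <- function(tracks, frame_interval, n_lags = 7,
                                    jumps_to_consider = 4, bin_width = 0.01,
                                    max_jump = 3) {
  n_lags <- check_count(n_lags, "n_lags", min = 1L)
  jumps_to_consider <- check_count(jumps_to_consider, "jumps_to_consider",
                                   min = 1L)
  check_number(bin_width, "bin_width", min = 1e-9)
  check_number(frame_interval, "frame_interval", min = 1e-12)
  stopifnot(all(c("track_id", "frame", "x_um", "y_um") %in% names(tracks)))
  tracks <- dplyr::arrange(tracks, .data$track_id, .data$frame)
  edges <- seq(0, max_jump, by = bin_width)
  mids <- edges[-1] - bin_width / 2
  all_lags <- vector("list", n_lags)
  n_jumps <- integer(n_lags)
  tid <- tracks$track_id; fr <- tracks$frame
  x <- tracks$x_um; y <- tracks$y_um
  N <- length(tid)
  for (n in seq_len(n_lags)) {
    if (N > n) {
      i1 <- seq_len(N - n); i2 <- i1 + n
      # Eligible pairs: same track and all intermediate frames present, which
      # for strictly increasing frames reduces to a frame span of exactly n.
      ok <- tid[i2] == tid[i1] & (fr[i2] - fr[i1]) == n
      # First `jumps_to_consider` eligible jumps per trajectory.
      rank_in_track <- stats::ave(as.numeric(ok), tid[i1], FUN = cumsum)
      sel <- ok & rank_in_track <= jumps_to_consider
      r <- sqrt((x[i2[sel]] - x[i1[sel]])^2 + (y[i2[sel]] - y[i1[sel]])^2)
    } else {
      r <- numeric()
    }
    if (length(r) == 0L) {
      stop_spt(sprintf("no eligible jumps at lag %d", n),
               class = "sptkinetics_no_jumps")
    }
    n_jumps[n] <- length(r)
    counts <- tabulate(findInterval(r, edges, rightmost.closed = TRUE,
                                    all.inside = FALSE),
                       nbins = length(mids))
    all_lags[[n]] <- tibble::tibble(lag = n, r_mid = mids, count = counts)
  }
  structure(list(data = dplyr::bind_rows(all_lags),
                 n_jumps = n_jumps,
                 frame_interval = frame_interval,
                 bin_width = bin_width,
                 n_lags = n_lags,
                 jumps_to_consider = jumps_to_consider,
                 max_jump = max_jump),
            class = "jump_histograms")
}

#' @export
print.jump_histograms <- function(x, ...) {
  cat(sprintf("<jump_histograms> %d lags, dt = %.5g s, bin %.3g um, jumps: %s\n",
              x$n_lags, x$frame_interval, x$bin_width,
              paste(x$n_jumps, collapse = "/")))
  invisible(x)
}

#' Fraction of particles remaining in the axial detection slice
#'
#' Survival probability of a 1D Brownian particle with diffusion coefficient
#' `D`, started uniformly inside the slice `[-dZ/2, +dZ/2]` with absorbing
#' boundaries, after time `n * dt`. Computed from the absorbing-slab
#' eigenfunction series `S(t) = sum_{m odd} 8 / (m^2 pi^2) *
#' exp(-m^2 pi^2 D t / dZ^2)`, truncated when terms fall below `tol`. This is
#' the correction factor by which fast-diffusing molecules are depleted from
#' jump-length statistics at long lags.
#'
#' @param D Diffusion coefficient, um^2/s.
#' @param n Lag in frames (vectorized).
#' @param dt Frame interval, seconds.
#' @param dZ Slice depth, micrometers (`Inf` returns 1).
#' @param tol Series truncation tolerance.
#' @return Survival fraction(s) in `[0, 1]`, strictly decreasing in `n` and
#'   in `D`; `D = 0` gives 1.
#' @export
defocus_fraction <- function(D, n, dt, dZ, tol = 1e-12) {
  check_number(D, "D", min = 0)
  check_number(dt, "dt", min = 1e-12)
  check_number(dZ, "dZ", min = 1e-12, allow_inf = TRUE)
  if (D == 0 || !is.finite(dZ)) return(rep(1, length(n)))
  vapply(n, function(ni) {
    cc <- pi^2 * D * ni * dt / dZ^2
    m_max <- max(15, ceiling(sqrt(max(-log(tol), 1) / cc)))
    m <- seq(1, 2 * m_max + 1, by = 2)
    s <- sum(8 / (m^2 * pi^2) * exp(-m^2 * cc))
    min(s, 1)
  }, numeric(1))
}

#' Defocus retention for frame-sampled pairs
#'
#' Probability that a particle observed in the detection slice remains
#' observable for the next `1..n_max` frames, under discrete-frame
#' observation: a frame is observable when both interval endpoints lie inside
#' the slice and the Brownian bridge between them did not cross a slice
#' boundary. Unlike [defocus_fraction()], which starts the particle uniformly
#' inside the slice, this propagates the exact stationary distribution of
#' axial positions at observed frames (new entries concentrate near the
#' slice boundaries), which is the relevant start distribution for
#' jump-length statistics compiled from tracked particles. Computed by
#' numerical propagation of the absorbing transition kernel on a grid.
#'
#' @param D Diffusion coefficient, um^2/s.
#' @param n_max Largest lag, frames.
#' @param dt Frame interval, seconds.
#' @param dZ Slice depth, micrometers (`Inf` returns 1s).
#' @param m Grid resolution.
#' @return Numeric vector of retention fractions for lags `1..n_max`.
#' @export
defocus_pair_retention <- function(D, n_max, dt, dZ, m = 81) {
  check_number(D, "D", min = 0)
  if (D == 0 || !is.finite(dZ)) return(rep(1, n_max))
  h <- dZ / 2
  z <- seq(-h, h, length.out = m)
  dz <- z[2] - z[1]
  s2 <- 2 * D * dt
  G <- outer(z, z, function(a, b) dnorm(b, a, sqrt(s2)))
  cross <- outer(z, z, function(a, b)
    exp(-2 * pmax(h - a, 0) * pmax(h - b, 0) / s2) +
      exp(-2 * pmax(h + a, 0) * pmax(h + b, 0) / s2))
  A <- G * pmax(1 - cross, 0) * dz
  # Simpson-free trapezoid correction at the slab edges.
  A[, c(1L, m)] <- A[, c(1L, m)] / 2
  # Stationary axial density at observed frames: the overall axial chain is
  # uniform at steady state, so condition a uniform pre-frame position on
  # the observation event.
  w0 <- rep(1, m); w0[c(1L, m)] <- 0.5
  p <- as.numeric(w0 %*% A)
  p <- p / sum(p)
  out <- numeric(n_max)
  v <- p
  for (k in seq_len(n_max)) {
    v <- as.numeric(v %*% A)
    out[k] <- sum(v)
  }
  pmin(out, 1)
}

#' Jump-length probability density of a Brownian state mixture
#'
#' Density of 2D displacement magnitudes over `n` frames for a mixture of
#' Brownian states: `sum_s w_s(n) * r / (2 a_s) * exp(-r^2 / (4 a_s))` with
#' `a_s = D_s * n * dt + sigma^2` (static localization error inflates the
#' apparent jump variance). State weights are the global fractions scaled by
#' the defocus survival factor of each state and renormalized to sum to one,
#' so the density integrates to 1 for any admissible parameters.
#'
#' @param r Displacement magnitudes, micrometers (>= 0).
#' @param lag Lag in frames.
#' @param dt Frame interval, seconds.
#' @param D Vector of state diffusion coefficients, um^2/s.
#' @param fractions State fractions (same length as `D`, summing to 1).
#' @param sigma Localization error s.d. per axis, micrometers.
#' @param dZ Axial slice depth, micrometers (`Inf` disables the correction).
#' @param Z Optional per-state defocus survival factors at this lag
#'   (overrides the default [defocus_fraction()] computation).
#' @return Density values at `r`.
#' @export
model_density <- function(r, lag, dt, D, fractions, sigma = 0.035, dZ = 0.7,
                          Z = NULL) {
  stopifnot(length(D) == length(fractions), all(r >= 0))
  a <- D * lag * dt + sigma^2
  if (any(a <= 0)) {
    stop_spt("non-positive jump variance; check D, dt and sigma",
             class = "sptkinetics_bad_argument")
  }
  z <- if (is.null(Z)) {
    vapply(D, defocus_fraction, numeric(1), n = lag, dt = dt, dZ = dZ)
  } else Z
  w <- fractions * z
  w <- w / sum(w)
  dens <- numeric(length(r))
  for (s in seq_along(D)) {
    dens <- dens + w[s] * r / (2 * a[s]) * exp(-r^2 / (4 * a[s]))
  }
  dens
}

default_bounds <- function(n_states) {
  if (n_states == 2L) {
    list(D_free = c(0.5, 25), D_bound = c(0.0001, 0.5))
  } else {
    list(D_free = c(0.5, 25), D_free2 = c(0.15, 5), D_bound = c(0.0001, 0.5))
  }
}

# Sum over lags of squared differences between empirical bin densities and
# the model density at bin centers. `defocus` selects the survival factor:
# "pair" (discrete-observation retention, the fitting default) or "slab"
# (uniform-start absorbing-slab series).
diffusion_rss <- function(hist, D, fractions, sigma, dZ,
                          defocus = "slab") {
  dat <- hist$data
  Zs <- if (defocus == "pair") {
    vapply(D, defocus_pair_retention, numeric(hist$n_lags),
           n_max = hist$n_lags, dt = hist$frame_interval, dZ = dZ)
  } else {
    vapply(D, defocus_fraction, numeric(hist$n_lags),
           n = seq_len(hist$n_lags), dt = hist$frame_interval, dZ = dZ)
  }
  Zs <- matrix(Zs, nrow = hist$n_lags)
  rss <- 0
  for (n in seq_len(hist$n_lags)) {
    rows <- dat$lag == n
    emp <- dat$count[rows] / (hist$n_jumps[n] * hist$bin_width)
    mod <- model_density(dat$r_mid[rows], n, hist$frame_interval,
                         D, fractions, sigma, dZ, Z = Zs[n, ])
    rss <- rss + sum((emp - mod)^2)
  }
  rss
}

#' Fit a two- or three-state diffusion model to jump-length histograms
#'
#' Bounded least-squares minimization (PDF fitting) of the summed squared
#' differences between empirical bin densities and [model_density()] across
#' all lags, started from a deterministic lattice of points spanning the
#' bounds; the best converged fit is returned (ties broken by lowest residual
#' then lowest `D_free`). The two-state model estimates `D_free`, `D_bound`,
#' and the bound fraction `F_bound`; the three-state model adds an
#' intermediate-mobility state (`D_free2`, fraction `F_free2`). The
#' localization error `sigma` is a fixed input, not a fitted parameter.
#'
#' @param hist A [compute_jump_histograms()] result.
#' @param n_states 2 or 3.
#' @param bounds Named list of `c(lower, upper)` per diffusion coefficient;
#'   defaults to `D_free` in `[0.5, 25]`, `D_bound` in `[0.0001, 0.5]` (and
#'   `D_free2` in `[0.15, 5]` for three states).
#' @param sigma Localization error s.d., micrometers.
#' @param dZ Axial detection slice depth, micrometers.
#' @param defocus Defocus survival factor used in the model: `"slab"`
#'   ([defocus_fraction()], uniform-start absorbing-slab series; the default)
#'   or `"pair"` ([defocus_pair_retention()], the exact frame-sampled pair
#'   retention). The slab factor under-counts free-pair survival in a way
#'   that partially offsets the opposite-signed weight distortions of the
#'   minimum-track-length filter, and recovers simulated truth more
#'   accurately overall (see the methods vignette).
#' @return A `diffusion_fit` object with elements `estimates`, `rss`,
#'   `n_states`, `bounds`, and the settings used. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
fit_diffusion_model <- function(hist, n_states = 2, bounds = NULL,
                                sigma = 0.035, dZ = 0.7,
                                defocus = c("slab", "pair")) {
  defocus <- match.arg(defocus)
  stopifnot(inherits(hist, "jump_histograms"))
  n_states <- check_count(n_states, "n_states", min = 2L)
  if (!n_states %in% c(2L, 3L)) {
    stop_spt("`n_states` must be 2 or 3.", class = "sptkinetics_bad_argument")
  }
  if (is.null(bounds)) bounds <- default_bounds(n_states)
  check_number(sigma, "sigma", min = 0)

  if (n_states == 2L) {
    obj <- function(p) {
      diffusion_rss(hist, D = c(p[1], p[2]), fractions = c(1 - p[3], p[3]),
                    sigma = sigma, dZ = dZ, defocus = defocus)
    }
    lower <- c(bounds$D_free[1], bounds$D_bound[1], 0)
    upper <- c(bounds$D_free[2], bounds$D_bound[2], 1)
    grid3 <- function(b) exp(seq(log(max(b[1], 1e-4)), log(b[2]),
                                 length.out = 3))
    starts <- as.matrix(expand.grid(D_free = grid3(bounds$D_free),
                                    D_bound = grid3(bounds$D_bound),
                                    F_bound = c(0.15, 0.5, 0.85)))
  } else {
    obj <- function(p) {
      f <- c(1 - p[4] - p[5], p[5], p[4])  # free, free2, bound
      pen <- if (p[4] + p[5] > 1) 1e6 * (p[4] + p[5] - 1)^2 else 0
      f <- pmax(f, 1e-12); f <- f / sum(f)
      diffusion_rss(hist, D = c(p[1], p[2], p[3]), fractions = f,
                    sigma = sigma, dZ = dZ, defocus = defocus) + pen
    }
    lower <- c(bounds$D_free[1], bounds$D_free2[1], bounds$D_bound[1], 0, 0)
    upper <- c(bounds$D_free[2], bounds$D_free2[2], bounds$D_bound[2], 1, 1)
    starts <- as.matrix(expand.grid(
      D_free = c(1, 4, 15), D_free2 = c(0.3, 1.5),
      D_bound = c(0.005, 0.1), F_bound = c(0.2, 0.6), F_free2 = c(0.1, 0.35)))
    init_rss <- apply(starts, 1, obj)
    starts <- starts[order(init_rss)[seq_len(10)], , drop = FALSE]
  }

  fits <- lapply(seq_len(nrow(starts)), function(k) {
    res <- try(optim(starts[k, ], obj, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = 500)), silent = TRUE)
    if (inherits(res, "try-error")) NULL else res
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0L) {
    stop_spt("diffusion model fit failed from every starting point",
             class = "sptkinetics_fit_failure")
  }
  vals <- vapply(fits, `[[`, numeric(1), "value")
  dfree <- vapply(fits, function(f) f$par[1], numeric(1))
  best <- fits[[order(vals, dfree)[1]]]
  p <- best$par
  est <- if (n_states == 2L) {
    list(D_free = p[1], D_bound = p[2], F_bound = p[3], F_free = 1 - p[3])
  } else {
    fb <- min(p[4], 1); ff2 <- min(p[5], 1 - fb)
    list(D_free = p[1], D_free2 = p[2], D_bound = p[3],
         F_bound = fb, F_free2 = ff2, F_free = max(1 - fb - ff2, 0))
  }
  structure(list(estimates = est, rss = best$value, n_states = n_states,
                 bounds = bounds, sigma = sigma, dZ = dZ, defocus = defocus,
                 frame_interval = hist$frame_interval,
                 n_jumps = sum(hist$n_jumps), hist = hist),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("<diffusion_fit> %d-state, %d jumps, rss = %.4g\n",
              x$n_states, x$n_jumps, x$rss))
  cat(sprintf("  D_free = %.3g um^2/s, D_bound = %.3g um^2/s, F_bound = %.1f%%\n",
              e$D_free, e$D_bound, 100 * e$F_bound))
  if (x$n_states == 3L) {
    cat(sprintf("  D_free2 = %.3g um^2/s, F_free2 = %.1f%%\n",
                e$D_free2, 100 * e$F_free2))
  }
  invisible(x)
}

#' Split trajectories by a binary focus mask
#'
#' A track is assigned to the overlapping set if at least one of its
#' localizations falls inside the mask; the partition is exhaustive and
#' exclusive. Used to separate trajectories inside DNA-repair foci from the
#' rest of the nucleus.
#'
#' @param tracks Trajectory tibble.
#' @param mask Logical matrix on the image pixel grid (rows = y).
#' @param pixel_size_um Pixel size of the mask grid, micrometers.
#' @return List with `overlapping` and `non_overlapping` trajectory tibbles.
#' @export
split_by_mask <- function(tracks, mask, pixel_size_um) {
  stopifnot(is.matrix(mask))
  col <- round(tracks$x_um / pixel_size_um) + 1L
  row <- round(tracks$y_um / pixel_size_um) + 1L
  if (nrow(tracks) > 0L &&
      (max(row) > nrow(mask) || max(col) > ncol(mask) ||
       min(row) < 1L || min(col) < 1L)) {
    stop_spt("trajectory coordinates fall outside the mask grid",
             class = "sptkinetics_grid_mismatch")
  }
  inside <- mask_index(tracks$x_um, tracks$y_um, mask, pixel_size_um)
  hit <- unique(tracks$track_id[inside])
  list(overlapping = tracks[tracks$track_id %in% hit, , drop = FALSE],
       non_overlapping = tracks[!tracks$track_id %in% hit, , drop = FALSE])
}

#' Per-cell diffusion fits plus a pooled fit
#'
#' Fits the diffusion model independently for each cell and on the merged
#' jump statistics of all cells; cells without eligible jumps are skipped
#' with a warning.
#'
#' @param tracks Trajectory tibble with a `cell` column.
#' @param frame_interval Frame interval, seconds.
#' @param ... Passed on to [compute_jump_histograms()] and
#'   [fit_diffusion_model()] (`n_states`, `sigma`, `dZ`, ...).
#' @return Tibble with one row per cell and a final `"pooled"` row
#'   (`cell_id`, `D_free`, `D_bound`, `F_bound`, `n_jumps`, `rss`); the fit
#'   objects are attached as attribute `"fits"`.
#' @export
per_cell_fit <- function(tracks, frame_interval, ...) {
  stopifnot("cell" %in% names(tracks))
  dots <- list(...)
  hist_args <- dots[names(dots) %in%
    c("n_lags", "jumps_to_consider", "bin_width", "max_jump")]
  fit_args <- dots[names(dots) %in% c("n_states", "bounds", "sigma", "dZ")]
  fit_one <- function(tr) {
    h <- do.call(compute_jump_histograms,
                 c(list(tr, frame_interval), hist_args))
    do.call(fit_diffusion_model, c(list(h), fit_args))
  }
  cells <- unique(tracks$cell)
  if (length(cells) < 1L) {
    stop_spt("no cells with trajectories", class = "sptkinetics_bad_argument")
  }
  fits <- list()
  rows <- list()
  for (cl in cells) {
    tr <- tracks[tracks$cell == cl, , drop = FALSE]
    f <- tryCatch(fit_one(tr), sptkinetics_no_jumps = function(e) NULL)
    if (is.null(f)) {
      warning(sprintf("cell %s skipped: no eligible jumps", cl))
      next
    }
    fits[[as.character(cl)]] <- f
    rows[[as.character(cl)]] <- tibble::tibble(
      cell_id = as.character(cl), D_free = f$estimates$D_free,
      D_bound = f$estimates$D_bound, F_bound = f$estimates$F_bound,
      n_jumps = f$n_jumps, rss = f$rss)
  }
  if (length(fits) == 0L) {
    stop_spt("no cell had eligible jumps", class = "sptkinetics_no_jumps")
  }
  pooled <- fit_one(tracks)
  fits[["pooled"]] <- pooled
  rows[["pooled"]] <- tibble::tibble(
    cell_id = "pooled", D_free = pooled$estimates$D_free,
    D_bound = pooled$estimates$D_bound, F_bound = pooled$estimates$F_bound,
    n_jumps = pooled$n_jumps, rss = pooled$rss)
  out <- dplyr::bind_rows(rows)
  attr(out, "fits") <- fits
  out
}
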