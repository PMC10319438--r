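#' Configuration for the two-state single-particle simulator
#'
#' Describes an acquisition of 2D Brownian particles that switch between a
#' chromatin-bound state (diffusion coefficient `D_bound`) and a freely
#' diffusing state (`D_free`) via a continuous-time two-state Markov chain,
#' observed through a thin axial detection slice of depth `dZ_um` with static
#' localization error and exponential photobleaching. Defaults mirror a
#' typical HILO single-molecule acquisition: 7.24 ms frame interval, 0.16 um
#' pixels, 0.700 um detection slice, 3000 frames.
#'
#' The state-switching rates satisfy detailed balance with the stationary
#' bound occupancy: `f_bound = k_bind / (k_bind + k_unbind)`. `k_bind` is
#' derived from `f_bound` and `k_unbind`.
#'
#' @param n_particles Number of particles.
#' @param duration_frames Number of frames in the acquisition.
#' @param frame_interval Frame interval, seconds.
#' @param pixel_size Pixel size, micrometers.
#' @param field_px Field size as `c(nx, ny)` pixels.
#' @param D_free,D_bound Diffusion coefficients, um^2/s.
#' @param f_bound Stationary bound-state occupancy in `[0, 1]`.
#' @param k_unbind Bound -> free switching rate, 1/s.
#' @param loc_error_sigma Static localization error s.d. per axis, um.
#' @param dZ Axial detection slice depth, um (`Inf` disables defocus loss).
#' @param nuclear_height Axial extent available to the particles, um; the
#'   axial walk reflects at `+/- nuclear_height / 2` so the steady-state
#'   axial distribution is uniform over the nucleus and the detection slice
#'   samples bound and free molecules at their global fractions. Must be
#'   `>= dZ`.
#' @param bleach_halflife Photobleaching half-life, seconds (`Inf` disables).
#' @param seed Master seed; expands deterministically to per-particle streams
#'   so changing `n_particles` does not reshuffle existing particles.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_particles = 100,
                       duration_frames = 3000,
                       frame_interval = 0.00724,
                       pixel_size = 0.16,
                       field_px = c(170, 140),
                       D_free = 2.0,
                       D_bound = 0.01,
                       f_bound = 0.5,
                       k_unbind = 0.2,
                       loc_error_sigma = 0.035,
                       dZ = 0.700,
                       nuclear_height = 2.0,
                       bleach_halflife = 0.025,
                       seed = 1L) {
  check_count(n_particles, "n_particles", min = 1L)
  check_count(duration_frames, "duration_frames", min = 1L)
  check_number(frame_interval, "frame_interval", min = 1e-9)
  check_number(pixel_size, "pixel_size", min = 1e-9)
  check_number(D_free, "D_free", min = 0)
  check_number(D_bound, "D_bound", min = 0)
  check_number(f_bound, "f_bound", min = 0, max = 1)
  check_number(k_unbind, "k_unbind", min = 0)
  check_number(loc_error_sigma, "loc_error_sigma", min = 0)
  check_number(dZ, "dZ", min = 1e-9, allow_inf = TRUE)
  check_number(nuclear_height, "nuclear_height", min = 1e-9, allow_inf = TRUE)
  if (is.finite(dZ) && nuclear_height < dZ) {
    stop_spt("`nuclear_height` must be at least `dZ`.",
             class = "sptkinetics_bad_argument")
  }
  check_number(bleach_halflife, "bleach_halflife", min = 1e-9, allow_inf = TRUE)
  if (length(field_px) != 2L || any(field_px < 1)) {
    stop_spt("`field_px` must be c(nx, ny) with positive entries.",
             class = "sptkinetics_bad_argument")
  }
  # Degenerate occupancies pin the chain in one state.
  if (f_bound >= 1) k_unbind <- 0
  k_bind <- if (f_bound >= 1) Inf else k_unbind * f_bound / (1 - f_bound)
  structure(list(
    n_particles = as.integer(n_particles),
    duration_frames = as.integer(duration_frames),
    frame_interval = frame_interval,
    pixel_size = pixel_size,
    field_px = as.integer(field_px),
    D_free = D_free, D_bound = D_bound,
    f_bound = f_bound, k_unbind = k_unbind, k_bind = k_bind,
    loc_error_sigma = loc_error_sigma,
    dZ = dZ, nuclear_height = nuclear_height,
    bleach_halflife = bleach_halflife,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Piecewise-constant state path of the two-state chain over [0, t_total].
# Returns breakpoints (starting at 0) and the state on each piece
# (TRUE = bound). Rates of 0/Inf handle the degenerate pure-state configs.
sim_state_path <- function(bound0, k_unbind, k_bind, t_total) {
  t <- 0
  bound <- bound0
  brk <- 0
  states <- bound0
  repeat {
    rate <- if (bound) k_unbind else k_bind
    if (!is.finite(rate) || rate <= 0) break
    dwell <- rexp(1L, rate)
    t <- t + dwell
    if (t >= t_total) break
    bound <- !bound
    brk <- c(brk, t)
    states <- c(states, bound)
  }
  list(breaks = c(brk, t_total), bound = states)
}

# Dominant state (TRUE = bound) of each frame interval [k*dt, (k+1)*dt).
dominant_states <- function(path, n_intervals, dt) {
  n_seg <- length(path$bound)
  if (n_seg == 1L) return(rep(path$bound, n_intervals))
  occ <- numeric(n_intervals)
  lo <- path$breaks[-(n_seg + 1L)]
  hi <- path$breaks[-1L]
  for (s in seq_len(n_seg)) {
    if (!path$bound[s]) next
    k0 <- floor(lo[s] / dt)
    k1 <- min(ceiling(hi[s] / dt) - 1, n_intervals - 1)
    if (k1 < k0) next
    ks <- k0:k1
    occ[ks + 1L] <- occ[ks + 1L] +
      pmin(hi[s], (ks + 1) * dt) - pmax(lo[s], ks * dt)
  }
  occ >= dt / 2
}

#' Simulate ground-truth particle tracks
#'
#' Realizes the two-state diffusion model of `config`: per frame interval each
#' particle takes Gaussian steps with per-axis variance `2 * D(state) * dt`
#' where the state is the dominant state of the interval under the
#' continuous-time chain; the axial coordinate performs 1D Brownian motion
#' with the same coefficient, and a particle is flagged out of the detection
#' slice in a frame if its axial path left `[-dZ/2, +dZ/2]` during the
#' preceding interval (Brownian-bridge boundary crossings are sampled so the
#' flag reflects the continuous path, not just the frame-instant position) or
#' sits outside it at the frame instant; it may later return. Photobleaching
#' removes particles after an exponential lifetime. Observed positions add
#' Gaussian localization error per axis.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per particle per unbleached frame: `particle`,
#'   `frame` (0-based), true `x_um`, `y_um`, `z_um`, `state` ("bound"/"free"),
#'   `in_slice`, `visible`, and observed `obs_x_um`, `obs_y_um`. The config is
#'   attached as attribute `"config"`.
#' @examples
#' cfg <- sim_config(n_particles = 5, duration_frames = 50, seed = 7)
#' tr <- simulate_tracks(cfg)
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dt <- config$frame_interval
  nfr <- config$duration_frames
  h <- config$dZ / 2
  fx <- (config$field_px[1] - 1) * config$pixel_size
  fy <- (config$field_px[2] - 1) * config$pixel_size
  bleach_rate <- log(2) / config$bleach_halflife

  Hh <- config$nuclear_height / 2

  one_particle <- function(i) {
    set.seed(as.integer(derive_seed(config$seed, i)))
    life_s <- if (bleach_rate > 0) rexp(1L, bleach_rate) else Inf
    n_alive <- min(nfr, floor(life_s / dt) + 1)
    if (n_alive < 1L) return(NULL)
    bound0 <- runif(1L) < config$f_bound
    path <- sim_state_path(bound0, config$k_unbind, config$k_bind, n_alive * dt)
    st <- dominant_states(path, n_alive, dt)        # state of interval k->k+1
    D <- ifelse(st, config$D_bound, config$D_free)
    sdxy <- sqrt(2 * D * dt)
    x <- cumsum(c(runif(1L, 0, fx), rnorm(n_alive - 1L, 0, sdxy[-n_alive])))
    y <- cumsum(c(runif(1L, 0, fy), rnorm(n_alive - 1L, 0, sdxy[-n_alive])))
    z0 <- if (is.finite(Hh)) runif(1L, -Hh, Hh) else if (is.finite(h)) {
      runif(1L, -h, h)
    } else 0
    z <- cumsum(c(z0, rnorm(n_alive - 1L, 0, sdxy[-n_alive])))
    if (is.finite(Hh)) {
      # Reflecting boundaries at +/- Hh via triangle folding of the free walk.
      w <- (z + Hh) %% (4 * Hh)
      z <- ifelse(w <= 2 * Hh, w, 4 * Hh - w) - Hh
    }
    inside <- abs(z) <= h
    in_slice <- inside
    if (n_alive > 1L && is.finite(h)) {
      za <- z[-n_alive]; zb <- z[-1L]
      both_in <- inside[-n_alive] & inside[-1L]
      a <- 2 * D[-n_alive] * dt
      p_up <- exp(-2 * pmax(h - za, 0) * pmax(h - zb, 0) / a)
      p_dn <- exp(-2 * pmax(h + za, 0) * pmax(h + zb, 0) / a)
      p_nocross <- pmax((1 - p_up) * (1 - p_dn), 0)
      crossed <- runif(n_alive - 1L) > p_nocross
      in_slice[-1L] <- both_in & !crossed
    }
    sig <- config$loc_error_sigma
    list(particle = rep(i, n_alive), frame = 0:(n_alive - 1L),
         x_um = x, y_um = y, z_um = z,
         state = ifelse(st, "bound", "free"),
         in_slice = in_slice,
         obs_x_um = x + rnorm(n_alive, 0, sig),
         obs_y_um = y + rnorm(n_alive, 0, sig))
  }

  parts <- lapply(seq_len(config$n_particles), one_particle)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  out <- tibble::as_tibble(lapply(setNames(nm = names(parts[[1]])),
                                  function(f) unlist(lapply(parts, `[[`, f),
                                                     use.names = FALSE)))
  out$visible <- out$in_slice
  attr(out, "config") <- config
  out
}

#' Convert ground-truth tracks to observed trajectories
#'
#' Emulates an ideal tracker on the simulator output: per particle, visible
#' frames are linked into trajectories, allowing up to `max_gaps` consecutive
#' invisible frames inside a track (gap frames contribute no localization);
#' longer invisible runs split the track. Tracks with fewer than
#' `min_track_length` localizations are dropped. Observed (noisy) positions
#' are reported.
#'
#' @param truth Output of [simulate_tracks()].
#' @param max_gaps Maximum number of consecutive missing frames bridged.
#' @param min_track_length Minimum number of localizations per track.
#' @return A trajectory tibble (`track_id`, `frame`, `x_um`, `y_um`,
#'   `intensity`, plus `particle` for oracle comparisons).
#' @export
truth_to_trajectories <- function(truth, max_gaps = 2, min_track_length = 3) {
  max_gaps <- check_count(max_gaps, "max_gaps", min = 0L)
  vis <- dplyr::filter(truth, .data$visible)
  if (nrow(vis) == 0L) {
    return(tibble::tibble(track_id = integer(), frame = integer(),
                          x_um = numeric(), y_um = numeric(),
                          intensity = numeric(), particle = integer()))
  }
  vis <- dplyr::arrange(vis, .data$particle, .data$frame)
  vis <- dplyr::group_by(vis, .data$particle)
  vis <- dplyr::mutate(vis,
    new_track = c(TRUE, diff(.data$frame) > max_gaps + 1L))
  vis <- dplyr::ungroup(vis)
  vis$track_id <- cumsum(vis$new_track)
  vis <- dplyr::group_by(vis, .data$track_id)
  vis <- dplyr::filter(vis, dplyr::n() >= min_track_length)
  vis <- dplyr::ungroup(vis)
  if (nrow(vis) > 0L) vis$track_id <- match(vis$track_id, unique(vis$track_id))
  tibble::tibble(track_id = vis$track_id, frame = vis$frame,
                 x_um = vis$obs_x_um, y_um = vis$obs_y_um,
                 intensity = 1, particle = vis$particle)
}

#' Render ground-truth tracks into a synthetic movie
#'
#' Each visible particle is drawn as a 2D Gaussian spot whose intensity is
#' integrated over pixel areas, so the summed above-background signal of an
#' isolated spot equals `photons` (up to slice truncation). Poisson shot noise
#' and Gaussian read noise are optional. An empty track set yields a
#' background-only movie.
#'
#' @param truth Output of [simulate_tracks()] (uses true positions).
#' @param photons Expected photon count per spot per frame.
#' @param psf_sigma_px PSF standard deviation in pixels.
#' @param background Constant background level per pixel.
#' @param poisson_noise Apply Poisson shot noise?
#' @param read_noise_sd Gaussian read noise s.d. (0 disables).
#' @param n_frames Number of frames to render (default: the config duration).
#' @param seed Seed for the noise draws.
#' @return An [spt_movie()].
#' @export
render_movie <- function(truth, photons = 500, psf_sigma_px = 1.0,
                         background = 10, poisson_noise = TRUE,
                         read_noise_sd = 0, n_frames = NULL, seed = 1L) {
  config <- attr(truth, "config")
  stopifnot(!is.null(config))
  nx <- config$field_px[1]; ny <- config$field_px[2]
  px <- config$pixel_size
  if (is.null(n_frames)) n_frames <- config$duration_frames
  set.seed(as.integer(seed))
  vis <- dplyr::filter(truth, .data$visible, .data$frame < n_frames)
  w <- ceiling(4 * psf_sigma_px)
  arr <- array(background, c(ny, nx, n_frames))
  if (nrow(vis) > 0L) {
    cx <- vis$x_um / px   # 0-based pixel coordinates of spot centers
    cy <- vis$y_um / px
    for (r in seq_len(nrow(vis))) {
      c0 <- round(cx[r]); r0 <- round(cy[r])
      if (c0 + w < 0 || c0 - w > nx - 1 || r0 + w < 0 || r0 - w > ny - 1) {
        next   # spot entirely outside the field
      }
      cols <- max(0, c0 - w):min(nx - 1, c0 + w)
      rows <- max(0, r0 - w):min(ny - 1, r0 + w)
      gx <- pnorm(cols + 0.5, cx[r], psf_sigma_px) -
            pnorm(cols - 0.5, cx[r], psf_sigma_px)
      gy <- pnorm(rows + 0.5, cy[r], psf_sigma_px) -
            pnorm(rows - 0.5, cy[r], psf_sigma_px)
      k <- vis$frame[r] + 1L
      arr[rows + 1L, cols + 1L, k] <- arr[rows + 1L, cols + 1L, k] +
        photons * outer(gy, gx)
    }
  }
  if (poisson_noise) arr[] <- rpois(length(arr), arr)
  if (read_noise_sd > 0) arr[] <- arr + rnorm(length(arr), 0, read_noise_sd)
  spt_movie(arr, frame_interval_s = config$frame_interval, pixel_size_um = px)
}

#' Simulate a recruitment intensity time series
#'
#' Pre-irradiation frames sit at `baseline`; post-irradiation frames follow a
#' one-phase association `plateau * (1 - exp(-log(2) * t / t_half))` plus
#' Gaussian noise, with `t` measured from the irradiation event (the first
#' post-irradiation frame is at `t = frame_interval`).
#'
#' @param t_half Half-time of accumulation, seconds (> 0).
#' @param plateau Asymptotic intensity increase.
#' @param noise_sd Gaussian noise s.d.
#' @param n_frames Total number of frames.
#' @param frame_interval Sampling interval, seconds.
#' @param baseline_frames Number of pre-irradiation frames.
#' @param baseline Pre-irradiation intensity level.
#' @param seed Seed for the noise draws (`NULL` leaves the RNG state alone).
#' @return Tibble with `frame` (0-based), `time_s` (<= 0 pre-irradiation), and
#'   `intensity`.
#' @export
simulate_recruitment_series <- function(t_half, plateau = 1, noise_sd = 0,
                                        n_frames = 300, frame_interval = 1,
                                        baseline_frames = 10, baseline = 0,
                                        seed = NULL) {
  check_number(t_half, "t_half", min = 1e-12)
  check_number(noise_sd, "noise_sd", min = 0)
  n_frames <- check_count(n_frames, "n_frames", min = 2L)
  baseline_frames <- check_count(baseline_frames, "baseline_frames", min = 1L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  frame <- 0:(n_frames - 1L)
  time_s <- (frame - baseline_frames + 1L) * frame_interval
  signal <- ifelse(time_s <= 0, baseline,
                   baseline + plateau * (1 - exp(-log(2) * time_s / t_half)))
  noise <- if (noise_sd > 0) rnorm(n_frames, 0, noise_sd) else 0
  tibble::tibble(frame = frame, time_s = time_s, intensity = signal + noise)
}

#' Render a recruitment series as a small movie
#'
#' Builds a synthetic laser-microirradiation movie: a constant background
#' field plus a rectangular damage stripe whose added intensity follows the
#' given series, with optional Gaussian noise. Useful to exercise the full
#' recruitment pipeline (registration, ROI extraction, normalization, fit).
#'
#' @param series Output of [simulate_recruitment_series()].
#' @param ny,nx Movie dimensions in pixels.
#' @param roi Stripe as `list(xmin, xmax, ymin, ymax)` in 1-based pixels.
#' @param background Background level.
#' @param amplitude Stripe intensity gain multiplying the series.
#' @param noise_sd Per-pixel Gaussian noise s.d.
#' @param frame_interval Frame interval, seconds (defaults to series spacing).
#' @param pixel_size_um Pixel size, micrometers.
#' @param seed Seed for the noise draws.
#' @return An [spt_movie()].
#' @export
simulate_recruitment_movie <- function(series, ny = 24, nx = 24,
                                       roi = list(xmin = 9, xmax = 16,
                                                  ymin = 1, ymax = 24),
                                       background = 100, amplitude = 50,
                                       noise_sd = 0, frame_interval = NULL,
                                       pixel_size_um = 0.16, seed = 1L) {
  if (is.null(frame_interval)) frame_interval <- diff(series$time_s[1:2])
  set.seed(as.integer(seed))
  nt <- nrow(series)
  arr <- array(background, c(ny, nx, nt))
  rows <- roi$ymin:roi$ymax; cols <- roi$xmin:roi$xmax
  for (k in seq_len(nt)) {
    arr[rows, cols, k] <- arr[rows, cols, k] + amplitude * series$intensity[k]
  }
  if (noise_sd > 0) arr[] <- arr + rnorm(length(arr), 0, noise_sd)
  spt_movie(arr, frame_interval_s = frame_interval,
            pixel_size_um = pixel_size_um)
}

#' Simulate an in-gel fluorescence dataset
#'
#' Generates lane signals for a quantification gel: protein standards of
#' known femtomole amounts, cell-number standards read out on the
#' loading-control (stain-free) channel, and sample lanes whose fluorescent
#' signal corresponds to `cells * true_molecules_per_cell` molecules
#' converted to femtomoles via the Avogadro constant.
#'
#' @param standard_fmol Femtomole amounts of the protein-standard lanes.
#' @param standard_cells Cell counts of the cell-number standard lanes.
#' @param sample_cells Cell counts loaded in the sample lanes.
#' @param true_molecules_per_cell Ground-truth abundance.
#' @param slope_fmol Fluorescent signal per femtomole.
#' @param slope_cells Loading signal per cell.
#' @param intercept Background fluorescent signal.
#' @param noise_sd Gaussian noise s.d. added to every signal.
#' @param tev_factor Migration attenuation of the fusion-protein signal: the
#'   sample lanes emit `1 / tev_factor` of the signal an equimolar free-tag
#'   standard would, emulating the effect corrected by
#'   [tev_correction_factor()].
#' @param seed Seed for the noise draws.
#' @return Lane tibble: `lane_id`, `role` (standard/cells/sample), `amount`,
#'   `signal`, `loading_signal`.
#' @export
simulate_gel <- function(standard_fmol = c(0.25, 0.5, 1, 2, 4),
                         standard_cells = c(5000, 10000, 20000, 40000),
                         sample_cells = rep(20000, 3),
                         true_molecules_per_cell = 5e4,
                         slope_fmol = 1000, slope_cells = 0.05,
                         intercept = 0, noise_sd = 0, tev_factor = 1,
                         seed = 1L) {
  stopifnot(all(standard_fmol >= 0), all(standard_cells >= 0),
            all(sample_cells >= 0), true_molecules_per_cell >= 0)
  set.seed(as.integer(seed))
  noise <- function(n) if (noise_sd > 0) rnorm(n, 0, noise_sd) else rep(0, n)
  std <- tibble::tibble(
    role = "standard", amount = standard_fmol,
    signal = slope_fmol * standard_fmol + intercept + noise(length(standard_fmol)),
    loading_signal = NA_real_)
  cells <- tibble::tibble(
    role = "cells", amount = standard_cells,
    signal = slope_cells * standard_cells + noise(length(standard_cells)),
    loading_signal = NA_real_)
  check_number(tev_factor, "tev_factor", min = 1e-12)
  fmol_true <- sample_cells * true_molecules_per_cell / N_AVOGADRO * 1e15
  smp <- tibble::tibble(
    role = "sample", amount = NA_real_,
    signal = slope_fmol * fmol_true / tev_factor + intercept +
      noise(length(sample_cells)),
    loading_signal = slope_cells * sample_cells + noise(length(sample_cells)))
  out <- dplyr::bind_rows(std, cells, smp)
  out$lane_id <- seq_len(nrow(out))
  dplyr::select(out, "lane_id", "role", "amount", "signal", "loading_signal")
}
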