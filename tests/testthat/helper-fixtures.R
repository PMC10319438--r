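# Shared fixtures, built in code at test time.

# Ground truth for sparse, well-separated static particles on a grid, in the
# same shape simulate_tracks() produces (so render_movie() accepts it).
# Separation avoids overlapping PSFs, which sub-pixel Gaussian fitting cannot
# resolve.
static_grid_truth <- function(nx_spots = 4, ny_spots = 3, spacing_px = 14,
                              n_frames = 20, D = 0.01, dt = 0.00724,
                              pixel = 0.16, field = c(64, 56), seed = 1) {
  set.seed(seed)
  centers <- expand.grid(
    x = (seq_len(nx_spots) * spacing_px - spacing_px / 2) * pixel,
    y = (seq_len(ny_spots) * spacing_px - spacing_px / 2) * pixel)
  rows <- lapply(seq_len(nrow(centers)), function(i) {
    tibble::tibble(
      particle = i, frame = 0:(n_frames - 1L),
      x_um = centers$x[i] + cumsum(c(0, rnorm(n_frames - 1, 0, sqrt(2 * D * dt)))),
      y_um = centers$y[i] + cumsum(c(0, rnorm(n_frames - 1, 0, sqrt(2 * D * dt)))),
      z_um = 0, state = "bound", in_slice = TRUE, visible = TRUE)
  })
  out <- dplyr::bind_rows(rows)
  out$obs_x_um <- out$x_um
  out$obs_y_um <- out$y_um
  attr(out, "config") <- sim_config(
    n_particles = nrow(centers), duration_frames = n_frames,
    frame_interval = dt, pixel_size = pixel, field_px = field,
    f_bound = 1, D_bound = D, loc_error_sigma = 0, dZ = Inf,
    nuclear_height = Inf, bleach_halflife = Inf, seed = seed)
  out
}

# Gaussian spot image with pixel-integrated intensity, 0-based center coords.
spot_image <- function(cx, cy, ny = 24, nx = 24, amplitude = 500,
                       sigma = 1, background = 10) {
  img <- matrix(background, ny, nx)
  for (i in seq_along(cx)) {
    gx <- pnorm(0:(nx - 1) + 0.5, cx[i], sigma) -
      pnorm(0:(nx - 1) - 0.5, cx[i], sigma)
    gy <- pnorm(0:(ny - 1) + 0.5, cy[i], sigma) -
      pnorm(0:(ny - 1) - 0.5, cy[i], sigma)
    img <- img + amplitude * outer(gy, gx)
  }
  img
}

# Localization table for a spot visible in the given frames.
static_locs <- function(frames, x = 1, y = 1) {
  tibble::tibble(frame = frames, x_um = x, y_um = y, intensity = 1)
}

# Monte-Carlo oracle for the absorbing-slab survival probability: walkers
# start uniform in the slab and are absorbed on any boundary crossing
# (sub-stepped with Brownian-bridge crossing tests). Independent of the
# package's series implementation.
mc_slab_survival <- function(D, n_frames, dt, dZ, n_walkers = 1e5,
                             substeps = 10, seed = 1) {
  set.seed(seed)
  h <- dZ / 2
  delta <- dt / substeps
  sdstep <- sqrt(2 * D * delta)
  z <- runif(n_walkers, -h, h)
  alive <- rep(TRUE, n_walkers)
  out <- numeric(n_frames)
  for (k in seq_len(n_frames)) {
    for (s in seq_len(substeps)) {
      idx <- which(alive)
      if (length(idx) == 0L) break
      zn <- z[idx] + rnorm(length(idx), 0, sdstep)
      exited <- abs(zn) > h
      surv <- !exited
      zi <- z[idx][surv]; zf <- zn[surv]
      a <- 2 * D * delta
      p_cross <- exp(-2 * pmax(h - zi, 0) * pmax(h - zf, 0) / a) +
        exp(-2 * pmax(h + zi, 0) * pmax(h + zf, 0) / a)
      crossed <- runif(length(zi)) < pmin(p_cross, 1)
      alive[idx[exited]] <- FALSE
      alive[idx[surv][crossed]] <- FALSE
      z[idx[surv]] <- zf
    }
    out[k] <- mean(alive)
  }
  out
}
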