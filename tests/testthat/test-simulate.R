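# Ground-truth simulator: diffusion statistics, state kinetics, bleaching,
# determinism, and movie rendering.

test_that("pure-bound particles reproduce the 2D Brownian MSD", {
  cfg <- sim_config(n_particles = 150, duration_frames = 100, f_bound = 1,
                    D_bound = 0.01, loc_error_sigma = 0, dZ = Inf,
                    nuclear_height = Inf, bleach_halflife = Inf, seed = 3)
  tr <- simulate_tracks(cfg)
  msd <- tr |>
    dplyr::group_by(particle) |>
    dplyr::summarise(m = mean(diff(x_um)^2 + diff(y_um)^2)) |>
    dplyr::pull(m) |>
    mean()
  expect_equal(msd, 4 * 0.01 * cfg$frame_interval, tolerance = 0.05)
})

test_that("equal seeds give bit-identical track sets", {
  cfg <- sim_config(n_particles = 40, duration_frames = 50, seed = 11)
  expect_identical(simulate_tracks(cfg), simulate_tracks(cfg))
})

test_that("per-particle streams are stable when n_particles changes", {
  cfg_small <- sim_config(n_particles = 10, duration_frames = 30, seed = 7)
  cfg_big <- sim_config(n_particles = 25, duration_frames = 30, seed = 7)
  small <- simulate_tracks(cfg_small)
  big <- simulate_tracks(cfg_big)
  expect_equal(dplyr::filter(big, particle <= 10), small,
               ignore_attr = TRUE)
})

test_that("bound-state occupancy matches the stationary distribution", {
  # k_bind = k_unbind = 1/s  =>  f_bound = 0.5; >= 1e5 particle-frames.
  cfg <- sim_config(n_particles = 300, duration_frames = 400, f_bound = 0.5,
                    k_unbind = 1, dZ = Inf, nuclear_height = Inf,
                    bleach_halflife = Inf, seed = 5)
  tr <- simulate_tracks(cfg)
  expect_gt(nrow(tr), 1e5)
  # Oracle: direct two-state chain simulation at the frame scale.
  set.seed(99)
  p_switch <- 1 - exp(-1 * cfg$frame_interval)
  s <- logical(1e5); s[1] <- TRUE
  for (i in 2:1e5) s[i] <- xor(s[i - 1], runif(1) < p_switch)
  expect_equal(mean(s), 0.5, tolerance = 0.02)
  expect_equal(mean(tr$state == "bound"), 0.5, tolerance = 0.01)
})

test_that("free-state step variance includes localization error", {
  cfg <- sim_config(n_particles = 120, duration_frames = 150, f_bound = 0,
                    D_free = 2, loc_error_sigma = 0.035, dZ = Inf,
                    nuclear_height = Inf, bleach_halflife = Inf, seed = 7)
  tr <- simulate_tracks(cfg)
  steps <- tr |>
    dplyr::group_by(particle) |>
    dplyr::summarise(v = var(diff(obs_x_um)), n = dplyr::n())
  v_hat <- mean(steps$v)
  v_true <- 2 * 2 * cfg$frame_interval + 2 * 0.035^2
  n_steps <- sum(steps$n) - nrow(steps)
  expect_gt(n_steps, 1e4)
  se <- v_true * sqrt(2 / n_steps)
  expect_lt(abs(v_hat - v_true), 3 * se)
})

test_that("observed lifetimes are exponential with the bleach half-life", {
  cfg <- sim_config(n_particles = 1500, duration_frames = 3000, f_bound = 1,
                    D_bound = 0.01, dZ = Inf, nuclear_height = Inf,
                    bleach_halflife = 0.5, seed = 13)
  tr <- simulate_tracks(cfg)
  life <- tr |>
    dplyr::group_by(particle) |>
    dplyr::summarise(dur = (max(frame) + 1) * cfg$frame_interval)
  fit <- bleach_half_life(
    vapply(seq(0, 2, by = 0.05),
           function(t) sum(life$dur > t), numeric(1)),
    time_s = seq(0, 2, by = 0.05))
  expect_equal(fit$half_life_s, 0.5, tolerance = 0.1)
})

test_that("rendered spots carry the configured photon count", {
  truth <- static_grid_truth(nx_spots = 1, ny_spots = 1, n_frames = 3,
                             D = 0, field = c(28, 28))
  mv <- render_movie(truth, photons = 800, psf_sigma_px = 1, background = 5,
                     poisson_noise = FALSE, seed = 1)
  total <- sum(unclass(mv)[, , 1] - 5)
  expect_equal(total, 800, tolerance = 0.01)
})

test_that("a static centered particle is the brightest pixel in every frame", {
  truth <- static_grid_truth(nx_spots = 1, ny_spots = 1, spacing_px = 14,
                             n_frames = 5, D = 0, field = c(28, 28))
  mv <- render_movie(truth, photons = 500, background = 2,
                     poisson_noise = FALSE, seed = 1)
  px <- attr(truth, "config")$pixel_size
  want_col <- round(truth$x_um[1] / px) + 1
  want_row <- round(truth$y_um[1] / px) + 1
  for (k in 1:5) {
    pk <- which(unclass(mv)[, , k] == max(unclass(mv)[, , k]), arr.ind = TRUE)
    expect_equal(unname(pk[1, ]), c(want_row, want_col))
  }
})

test_that("zero particles render a background-only movie", {
  truth <- static_grid_truth(n_frames = 4, field = c(20, 20))
  truth <- truth[0, ]
  attr(truth, "config") <- sim_config(n_particles = 1, duration_frames = 4,
                                      field_px = c(20, 20), seed = 1)
  mv <- render_movie(truth, background = 7, poisson_noise = FALSE, seed = 1)
  expect_true(all(mv == 7))
})

test_that("recruitment series follows the one-phase association form", {
  ser <- simulate_recruitment_series(t_half = 10, plateau = 2, noise_sd = 0,
                                     n_frames = 100, frame_interval = 1,
                                     baseline_frames = 5)
  at_half <- ser$intensity[ser$time_s == 10]
  expect_equal(at_half, 1)                 # plateau / 2 at t = t_half
  expect_equal(ser$intensity[nrow(ser)], 2, tolerance = 0.01)
  expect_true(all(ser$intensity[ser$time_s <= 0] == 0))
})

test_that("gel simulation is linear and zero lanes are clean", {
  lanes <- simulate_gel(standard_fmol = c(0, 1, 2), noise_sd = 0)
  std <- lanes[lanes$role == "standard", ]
  expect_equal(std$signal[std$amount == 0], 0)
  expect_equal(diff(std$signal), c(1000, 1000))
})

test_that("doubling the gel slope leaves recovered abundance unchanged", {
  a1 <- quantify_gel(simulate_gel(slope_fmol = 1000, noise_sd = 0))
  a2 <- quantify_gel(simulate_gel(slope_fmol = 2000, noise_sd = 0))
  expect_equal(a1$molecules_per_cell, a2$molecules_per_cell)
})

test_that("invalid simulator parameters are rejected", {
  expect_error(sim_config(D_free = -1), class = "sptkinetics_bad_argument")
  expect_error(sim_config(f_bound = 1.2), class = "sptkinetics_bad_argument")
  expect_error(sim_config(frame_interval = 0),
               class = "sptkinetics_bad_argument")
  expect_error(sim_config(dZ = 0.7, nuclear_height = 0.5),
               class = "sptkinetics_bad_argument")
})
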