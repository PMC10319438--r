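# Residence-time analysis: survival curves, biexponential decay fitting,
# photobleach calibration, and constrained bound-molecule tracking.

test_that("survival curve reproduces hand counts and is non-increasing", {
  sc <- survival_curve(c(1, 2, 4))
  expect_equal(sc$tau_s, c(1, 2, 4))
  expect_equal(sc$survival, c(2 / 3, 1 / 3, 0))
  set.seed(12)
  rnd <- survival_curve(rexp(500, 0.3))
  expect_true(all(diff(rnd$survival) <= 0))
  expect_equal(rnd$survival[nrow(rnd)], 0)
  # all equal durations: single step 1 -> 0
  eq <- survival_curve(rep(2.5, 10))
  expect_equal(nrow(eq), 1L)
  expect_equal(eq$survival, 0)
  expect_error(survival_curve(numeric()), class = "sptkinetics_bad_argument")
})

test_that("biexponential fit recovers a known mixture within 15%", {
  d <- sample_biexponential(1e4, fraction_slow = 0.3, t_half_fast = 0.5,
                            t_half_slow = 5, seed = 9)
  fit <- fit_biexponential(survival_curve(d))
  expect_lt(abs(fit$t_half_fast / 0.5 - 1), 0.15)
  expect_lt(abs(fit$t_half_slow / 5 - 1), 0.15)
  expect_lt(abs(fit$fraction_slow - 0.3), 0.3 * 0.15)
  expect_gt(fit$r_squared, 0.99)
  expect_lte(fit$t_half_fast, fit$t_half_slow)
})

test_that("single-exponential data yields a degenerate but sane biexp fit", {
  set.seed(21)
  d <- rexp(5000, log(2) / 2)            # pure t_half = 2 s
  fit <- fit_biexponential(survival_curve(d))
  # either the two components merge or one fraction is extreme
  merged <- abs(fit$t_half_fast / fit$t_half_slow - 1) < 0.5
  extreme <- fit$fraction_slow < 0.1 || fit$fraction_slow > 0.9
  expect_true(merged || extreme)
  expect_gt(fit$r_squared, 0.99)
})

test_that("survival sampling round-trips fitted parameters", {
  d <- sample_biexponential(2e4, 0.4, 1, 8, seed = 77)
  fit <- fit_biexponential(survival_curve(d))
  d2 <- sample_biexponential(2e4, fit$fraction_slow, fit$t_half_fast,
                             fit$t_half_slow, seed = 78)
  fit2 <- fit_biexponential(survival_curve(d2))
  expect_lt(abs(fit2$t_half_slow / fit$t_half_slow - 1), 0.1)
  expect_lt(abs(fit2$fraction_slow - fit$fraction_slow), 0.05)
})

test_that("bleach half-life matches the closed form and flags non-decay", {
  t <- seq(0, 30, by = 0.2)
  fit <- bleach_half_life(500 * exp(-0.0900 * t), time_s = t)
  expect_equal(fit$half_life_s, log(2) / 0.09, tolerance = 1e-6)
  expect_equal(round(fit$half_life_s, 1), 7.7)
  expect_error(bleach_half_life(rep(3, 50), time_s = seq_len(50)),
               class = "sptkinetics_no_decay")
})

test_that("bleach half-life from a noisy series is within 5%", {
  errs <- vapply(1:5, function(s) {
    set.seed(s)
    t <- seq(0, 30, by = 0.2)
    y <- 500 * exp(-0.09 * t) * (1 + rnorm(length(t), 0, 0.05))
    bleach_half_life(y, time_s = t)$half_life_s / (log(2) / 0.09) - 1
  }, numeric(1))
  expect_true(all(abs(errs) < 0.05))
})

test_that("bleach half-life integrates nuclear signal from a movie", {
  nt <- 60
  arr <- array(2, c(16, 16, nt))
  mask <- matrix(FALSE, 16, 16); mask[5:12, 5:12] <- TRUE
  for (k in seq_len(nt)) {
    arr[, , k][mask] <- 2 + 50 * exp(-0.09 * (k - 1) * 0.5)
  }
  mv <- spt_movie(arr, frame_interval_s = 0.5, pixel_size_um = 0.16)
  fit <- bleach_half_life(mv, nuclear_mask = mask)
  expect_equal(fit$half_life_s, log(2) / 0.09, tolerance = 0.01)
  expect_error(bleach_half_life(mv, nuclear_mask = matrix(FALSE, 16, 16)),
               class = "sptkinetics_bad_argument")
})

test_that("fraction exceeding the observation window is a plain proportion", {
  expect_equal(fraction_exceeding(c(10, 23, 25), 22), 2 / 3)
  expect_equal(fraction_exceeding(c(1, 2, 3), 0), 1)
  expect_equal(fraction_exceeding(c(1, 2, 3), 10), 0)
})

test_that("track durations count first to last frame inclusive", {
  tr <- tibble::tibble(track_id = c(1, 1, 1, 2, 2),
                       frame = c(0, 1, 4, 10, 11),
                       x_um = 0, y_um = 0, intensity = 1)
  expect_equal(track_durations(tr, 0.1), c(0.5, 0.2))
})

test_that("track_bound keeps a static particle for the whole movie", {
  truth <- static_grid_truth(nx_spots = 2, ny_spots = 2, spacing_px = 20,
                             n_frames = 80, D = 0.001, field = c(48, 48),
                             seed = 6)
  raw <- render_movie(truth, photons = 600, background = 10,
                      poisson_noise = FALSE, seed = 2)
  av <- average_frames(raw, 10)
  tk <- track_bound(av, threshold = 30, D_max_bound = 0.5)
  expect_equal(dplyr::n_distinct(tk$track_id), 4L)
  durs <- track_durations(tk)
  expect_equal(durs, rep(movie_duration(av), 4))
})

test_that("frame averaging suppresses fast-diffusing molecules", {
  cfg <- sim_config(n_particles = 25, duration_frames = 200, f_bound = 0,
                    D_free = 3, loc_error_sigma = 0, dZ = Inf,
                    nuclear_height = Inf, bleach_halflife = Inf,
                    field_px = c(64, 64), seed = 8)
  truth <- simulate_tracks(cfg)
  raw <- render_movie(truth, photons = 600, background = 10,
                      poisson_noise = TRUE, seed = 3)
  av <- average_frames(raw, 10)
  tk <- track_bound(av, threshold = 40, D_max_bound = 0.5)
  n_long <- if (nrow(tk) == 0) 0 else dplyr::n_distinct(tk$track_id)
  expect_lte(n_long, ceiling(0.1 * 25))   # >= 90% suppressed
})

test_that("residence pipeline on bleach-limited bound molecules returns the bleach half-life", {
  # True residence >> observation window; signal loss is photobleaching.
  cfg <- sim_config(n_particles = 4000, duration_frames = 300, f_bound = 1,
                    D_bound = 0.005, frame_interval = 10 / 138,
                    loc_error_sigma = 0.02, dZ = Inf, nuclear_height = Inf,
                    bleach_halflife = 7.7, seed = 15)
  tracks <- truth_to_trajectories(simulate_tracks(cfg), max_gaps = 0)
  durs <- track_durations(tracks, cfg$frame_interval)
  fit <- fit_biexponential(survival_curve(durs))
  expect_lt(abs(fit$t_half_slow / 7.7 - 1), 0.15)
})
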