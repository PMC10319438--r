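# Jump-length histograms, the mixture density, defocus factors, model
# fitting, and mask-based trajectory splitting.

test_that("jump histograms reproduce hand-computed displacements", {
  tr <- tibble::tibble(track_id = 1L, frame = 0:2,
                       x_um = c(0, 0.032, 0.064), y_um = 0, intensity = 1)
  h <- compute_jump_histograms(tr, 0.00724, n_lags = 2, bin_width = 0.01)
  lag1 <- h$data[h$data$lag == 1 & h$data$count > 0, ]
  lag2 <- h$data[h$data$lag == 2 & h$data$count > 0, ]
  expect_equal(h$n_jumps, c(2L, 1L))
  expect_equal(lag1$count, 2L)
  expect_true(abs(lag1$r_mid - 0.032) <= 0.005)   # both lag-1 jumps = 0.032
  expect_true(abs(lag2$r_mid - 0.064) <= 0.005)   # single lag-2 jump = 0.064
})

test_that("a static track puts all mass in the first bin at every lag", {
  tr <- tibble::tibble(track_id = 1L, frame = 0:19, x_um = 1, y_um = 2,
                       intensity = 1)
  h <- compute_jump_histograms(tr, 0.00724, n_lags = 4)
  agg <- dplyr::summarise(dplyr::group_by(h$data, lag),
                          first_bin = count[1], total = sum(count))
  expect_true(all(agg$first_bin == agg$total))
})

test_that("only the first jumps_to_consider jumps count per lag", {
  tr <- tibble::tibble(track_id = 1L, frame = 0:100,
                       x_um = cumsum(runif(101, 0, 0.01)), y_um = 0,
                       intensity = 1)
  h <- compute_jump_histograms(tr, 0.00724, n_lags = 3, jumps_to_consider = 4)
  expect_equal(h$n_jumps, c(4L, 4L, 4L))
})

test_that("gaps inside a jump span exclude the pair", {
  tr <- tibble::tibble(track_id = 1L, frame = c(0, 1, 3, 4),
                       x_um = c(0, 0.01, 0.03, 0.04), y_um = 0, intensity = 1)
  h <- compute_jump_histograms(tr, 0.00724, n_lags = 1)
  expect_equal(h$n_jumps[1], 2L)  # 0-1 and 3-4; 1-3 spans the gap
  # frames 1 and 3 are 2 apart but frame 2 is a gap inside the span, so
  # there is no eligible lag-2 jump at all
  expect_error(compute_jump_histograms(tr, 0.00724, n_lags = 2),
               class = "sptkinetics_no_jumps")
})

test_that("model density integrates to one and peaks where theory says", {
  dt <- 0.00724
  for (lag in c(1, 4)) {
    dens <- function(r) model_density(r, lag, dt, D = c(2, 0.01),
                                      fractions = c(0.4, 0.6),
                                      sigma = 0.035, dZ = 0.7)
    expect_equal(stats::integrate(dens, 0, Inf, rel.tol = 1e-8)$value, 1,
                 tolerance = 1e-6)
  }
  # single state: peak at sqrt(2 (D n dt + sigma^2))
  rs <- seq(0.001, 1, by = 1e-4)
  d <- model_density(rs, 1, dt, D = 2, fractions = 1, sigma = 0.035, dZ = Inf)
  a2 <- 2 * dt + 0.035^2
  expect_equal(rs[which.max(d)], sqrt(2 * a2), tolerance = 1e-2)
})

test_that("degenerate mixtures collapse to the pure state density", {
  r <- seq(0, 1, by = 0.01)
  mix <- model_density(r, 2, 0.00724, D = c(2, 0.01), fractions = c(1, 0),
                       sigma = 0.035, dZ = 0.7)
  pure <- model_density(r, 2, 0.00724, D = 2, fractions = 1,
                        sigma = 0.035, dZ = 0.7)
  expect_equal(mix, pure)
})

test_that("defocus fraction is 1 at D = 0 and decreases in n and D", {
  expect_equal(defocus_fraction(0, 1:5, 0.00724, 0.7), rep(1, 5))
  s1 <- defocus_fraction(1, 1:7, 0.00724, 0.7)
  s2 <- defocus_fraction(3, 1:7, 0.00724, 0.7)
  expect_true(all(diff(s1) < 0))
  expect_true(all(s2 < s1))
  expect_true(all(s1 > 0 & s1 < 1))
})

test_that("slab survival series matches an independent Monte-Carlo oracle", {
  mc <- mc_slab_survival(2, 4, 0.00724, 0.7, n_walkers = 2e5, seed = 7)
  ser <- defocus_fraction(2, 1:4, 0.00724, 0.7)
  expect_lt(max(abs(mc - ser)), 0.005)
})

test_that("pair retention matches simulated ground-truth pair statistics", {
  cfg <- sim_config(n_particles = 8000, duration_frames = 60, f_bound = 0,
                    D_free = 2, loc_error_sigma = 0, dZ = 0.7,
                    nuclear_height = 2, bleach_halflife = Inf, seed = 5)
  tr <- dplyr::arrange(simulate_tracks(cfg), particle, frame)
  tid <- tr$particle; fr <- tr$frame; vis <- tr$visible
  N <- nrow(tr)
  emp <- numeric(4)
  denom <- numeric(4)
  for (n in 1:4) {
    i1 <- seq_len(N - n); i2 <- i1 + n
    ok <- tid[i2] == tid[i1] & (fr[i2] - fr[i1]) == n
    allvis <- vis[i1]
    for (k in 1:n) allvis <- allvis & vis[i1 + k]
    emp[n] <- sum(ok & allvis)
    # denominator: visible frames that have n subsequent frames in the record
    denom[n] <- sum(vis[i1] & ok)
  }
  pred <- defocus_pair_retention(2, 4, 0.00724, 0.7)
  expect_lt(max(abs(emp / denom - pred)), 0.02)
})

test_that("two-state fit recovers simulated parameters at moderate scale", {
  cfg <- sim_config(n_particles = 25000, duration_frames = 60, f_bound = 0.66,
                    D_free = 2, D_bound = 0.01, seed = 31)
  tracks <- truth_to_trajectories(simulate_tracks(cfg), max_gaps = 2)
  h <- compute_jump_histograms(tracks, cfg$frame_interval)
  fit <- fit_diffusion_model(h, n_states = 2)
  expect_lt(abs(fit$estimates$F_bound - 0.66), 0.05)
  expect_lt(abs(fit$estimates$D_free / 2 - 1), 0.15)
  expect_lt(abs(fit$estimates$D_bound - 0.01), 0.01)
})

test_that("all-static data drives the bound fraction to one", {
  cfg <- sim_config(n_particles = 5000, duration_frames = 40, f_bound = 1,
                    D_bound = 0.01, bleach_halflife = 0.1, seed = 17)
  tracks <- truth_to_trajectories(simulate_tracks(cfg), max_gaps = 2)
  h <- compute_jump_histograms(tracks, cfg$frame_interval)
  fit <- fit_diffusion_model(h, n_states = 2)
  expect_gte(fit$estimates$F_bound, 0.95)
})

test_that("estimates never escape the stated bounds", {
  cfg <- sim_config(n_particles = 500, duration_frames = 40, f_bound = 0.3,
                    D_free = 8, seed = 23)
  tracks <- truth_to_trajectories(simulate_tracks(cfg), max_gaps = 2)
  h <- compute_jump_histograms(tracks, cfg$frame_interval)
  fit <- fit_diffusion_model(h, n_states = 2)
  e <- fit$estimates
  expect_true(e$D_free >= 0.5 && e$D_free <= 25)
  expect_true(e$D_bound >= 0.0001 && e$D_bound <= 0.5)
  expect_true(e$F_bound >= 0 && e$F_bound <= 1)
})

test_that("ignoring the defocus correction inflates the bound fraction", {
  cfg <- sim_config(n_particles = 20000, duration_frames = 60, f_bound = 0.5,
                    D_free = 2, seed = 41)
  tracks <- truth_to_trajectories(simulate_tracks(cfg), max_gaps = 2)
  h <- compute_jump_histograms(tracks, cfg$frame_interval)
  with_corr <- fit_diffusion_model(h, n_states = 2, dZ = 0.7)
  without <- fit_diffusion_model(h, n_states = 2, dZ = Inf)
  expect_gt(without$estimates$F_bound, with_corr$estimates$F_bound)
})

test_that("three-state fit on two-state data is not worse than two-state", {
  cfg <- sim_config(n_particles = 8000, duration_frames = 60, f_bound = 0.5,
                    D_free = 2, seed = 43)
  tracks <- truth_to_trajectories(simulate_tracks(cfg), max_gaps = 2)
  h <- compute_jump_histograms(tracks, cfg$frame_interval)
  two <- fit_diffusion_model(h, n_states = 2)
  three <- fit_diffusion_model(h, n_states = 3)
  expect_lte(three$rss, two$rss * 1.02)
  fr3 <- with(three$estimates, c(F_bound, F_free2, F_free))
  expect_equal(sum(fr3), 1, tolerance = 1e-6)
})

test_that("split_by_mask partitions tracks by single-frame overlap", {
  tracks <- tibble::tibble(
    track_id = rep(1:3, each = 3), frame = rep(0:2, 3),
    x_um = c(0.16, 0.16, 0.16,   1.6, 1.6, 1.6,   1.6, 1.6, 0.16),
    y_um = 0.16, intensity = 1)
  mask <- matrix(FALSE, 16, 16)
  mask[1:3, 1:3] <- TRUE
  sp <- split_by_mask(tracks, mask, 0.16)
  expect_setequal(unique(sp$overlapping$track_id), c(1L, 3L))
  expect_setequal(unique(sp$non_overlapping$track_id), 2L)
  # empty and full masks
  none <- split_by_mask(tracks, matrix(FALSE, 16, 16), 0.16)
  all_in <- split_by_mask(tracks, matrix(TRUE, 16, 16), 0.16)
  expect_equal(nrow(none$overlapping), 0L)
  expect_equal(nrow(all_in$non_overlapping), 0L)
  # mismatched grid
  expect_error(split_by_mask(tracks, matrix(TRUE, 2, 2), 0.16),
               class = "sptkinetics_grid_mismatch")
})

test_that("per-cell fits agree with the pooled fit on homogeneous cells", {
  tracks <- dplyr::bind_rows(lapply(1:3, function(cell) {
    cfg <- sim_config(n_particles = 6000, duration_frames = 60,
                      f_bound = 0.5, D_free = 2, seed = 100 + cell)
    tr <- truth_to_trajectories(simulate_tracks(cfg), max_gaps = 2)
    tr$cell <- cell
    tr$track_id <- paste(cell, tr$track_id)
    tr
  }))
  res <- per_cell_fit(tracks, 0.00724, n_states = 2)
  expect_equal(nrow(res), 4L)
  pooled <- res$F_bound[res$cell_id == "pooled"]
  per_cell <- res$F_bound[res$cell_id != "pooled"]
  expect_lt(abs(median(per_cell) - pooled), 0.05)
  expect_true(all(abs(per_cell - pooled) < 0.1))
})

test_that("one cell's fit equals the pooled fit", {
  cfg <- sim_config(n_particles = 2000, duration_frames = 50, seed = 3)
  tr <- truth_to_trajectories(simulate_tracks(cfg), max_gaps = 2)
  tr$cell <- "A"
  res <- per_cell_fit(tr, 0.00724)
  expect_equal(res$F_bound[1], res$F_bound[2])
  expect_equal(res$D_free[1], res$D_free[2])
})
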