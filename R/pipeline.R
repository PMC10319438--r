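# End-to-end pipelines chaining the analysis stages, with parameter logging
# and deterministic seeding.

PIPELINE_KEYS <- c(
  "pipeline", "seed", "frame_interval_s", "pixel_size_um", "dZ_um",
  "n_particles", "duration_frames", "D_free", "D_bound", "f_bound",
  "k_unbind", "loc_error_sigma", "bleach_halflife_s",
  "residence_bleach_halflife_s",
  "n_states", "sigma_um",
  "average_window", "D_max_bound", "threshold",
  "t_half_s", "n_cells", "baseline_frames", "recruit_frame_interval_s",
  "recruit_n_frames", "noise_sd",
  "true_molecules_per_cell", "tev_factor",
  "trajectories_file")

#' Build a validated pipeline configuration
#'
#' A flat list of acquisition metadata and stage parameters shared by the
#' pipelines; unknown keys are rejected so typos fail loudly. All physical
#' parameters must be positive.
#'
#' @param pipeline One of "diffusion", "residence", "recruitment",
#'   "abundance".
#' @param ... Key-value overrides of the defaults (see `PIPELINE_KEYS`).
#' @return A named `pipeline_config` list.
#' @export
pipeline_config <- function(pipeline = "diffusion", ...) {
  pipeline <- match.arg(pipeline,
                        c("diffusion", "residence", "recruitment", "abundance"))
  cfg <- list(
    pipeline = pipeline, seed = 1,
    frame_interval_s = 0.00724, pixel_size_um = 0.16, dZ_um = 0.700,
    n_particles = 2000, duration_frames = 60,
    D_free = 2.0, D_bound = 0.01, f_bound = 0.5, k_unbind = 0.2,
    loc_error_sigma = 0.035, bleach_halflife_s = 0.025,
    residence_bleach_halflife_s = 7.7,
    n_states = 2, sigma_um = 0.035,
    average_window = 10, D_max_bound = 0.5, threshold = 50,
    t_half_s = 22.1, n_cells = 5, baseline_frames = 10,
    recruit_frame_interval_s = 1, recruit_n_frames = 150, noise_sd = 0.02,
    true_molecules_per_cell = 5e4, tev_factor = 1.5,
    trajectories_file = "")
  dots <- list(...)
  unknown <- setdiff(names(dots), PIPELINE_KEYS)
  if (length(unknown) > 0L) {
    stop_spt(sprintf("unknown config key(s): %s",
                     paste(unknown, collapse = ", ")),
             class = "sptkinetics_bad_argument")
  }
  cfg[names(dots)] <- dots
  for (key in c("frame_interval_s", "pixel_size_um", "dZ_um")) {
    check_number(cfg[[key]], key, min = 1e-12)
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

log_params <- function(cfg, con) {
  for (k in names(cfg)) {
    line <- sprintf("param %s=%s", k, format(cfg[[k]], digits = 17))
    writeLines(line, con)
    message(line)
  }
}

write_table_out <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Run an analysis pipeline end to end
#'
#' Executes one of the four pipelines on synthetic data generated from the
#' config (or, for the diffusion pipeline, on a trajectory file if
#' `trajectories_file` is set), writing per-stage intermediates, final result
#' tables, and a run log listing every parameter used to `out_dir`. Results
#' are deterministic for a given config and seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage results; on disk, tab-delimited
#'   result tables plus `run.log`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (nzchar(config$trajectories_file) &&
      !file.exists(config$trajectories_file)) {
    stop_spt(sprintf("input trajectories not found: %s",
                     config$trajectories_file),
             class = "sptkinetics_missing_input")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  log_params(config, log_con)
  set.seed(as.integer(config$seed))
  res <- switch(config$pipeline,
    diffusion = pipeline_diffusion(config, out_dir),
    residence = pipeline_residence(config, out_dir),
    recruitment = pipeline_recruitment(config, out_dir),
    abundance = pipeline_abundance(config, out_dir))
  writeLines("status done", log_con)
  invisible(res)
}

pipeline_diffusion <- function(cfg, out_dir) {
  if (nzchar(cfg$trajectories_file)) {
    tracks <- read_trajectories(cfg$trajectories_file)
  } else {
    sim <- sim_config(
      n_particles = cfg$n_particles, duration_frames = cfg$duration_frames,
      frame_interval = cfg$frame_interval_s, pixel_size = cfg$pixel_size_um,
      D_free = cfg$D_free, D_bound = cfg$D_bound, f_bound = cfg$f_bound,
      k_unbind = cfg$k_unbind, loc_error_sigma = cfg$loc_error_sigma,
      dZ = cfg$dZ_um, bleach_halflife = cfg$bleach_halflife_s,
      seed = cfg$seed)
    tracks <- truth_to_trajectories(simulate_tracks(sim), max_gaps = 2)
    write_trajectories(tracks, file.path(out_dir, "trajectories.tsv"))
  }
  hist <- compute_jump_histograms(tracks, cfg$frame_interval_s)
  fit <- fit_diffusion_model(hist, n_states = cfg$n_states,
                             sigma = cfg$sigma_um, dZ = cfg$dZ_um)
  write_table_out(tidy(fit), file.path(out_dir, "diffusion_fit.tsv"))
  write_config(fit$estimates, file.path(out_dir, "diffusion_fit.txt"))
  fit
}

pipeline_residence <- function(cfg, out_dir) {
  sim <- sim_config(
    n_particles = cfg$n_particles, duration_frames = cfg$duration_frames,
    frame_interval = cfg$frame_interval_s * cfg$average_window,
    pixel_size = cfg$pixel_size_um,
    D_free = cfg$D_free, D_bound = cfg$D_bound, f_bound = 1,
    loc_error_sigma = cfg$loc_error_sigma, dZ = Inf, nuclear_height = Inf,
    bleach_halflife = cfg$residence_bleach_halflife_s, seed = cfg$seed)
  tracks <- truth_to_trajectories(simulate_tracks(sim), max_gaps = 0)
  durations <- track_durations(tracks, sim$frame_interval)
  curve <- survival_curve(durations)
  write_table_out(curve, file.path(out_dir, "survival_curve.tsv"))
  fit <- fit_biexponential(curve)
  write_config(list(t_half_fast_s = fit$t_half_fast,
                    t_half_slow_s = fit$t_half_slow,
                    fraction_slow = fit$fraction_slow,
                    r_squared = fit$r_squared),
               file.path(out_dir, "residence_fit.txt"))
  fit
}

pipeline_recruitment <- function(cfg, out_dir) {
  movies <- lapply(seq_len(cfg$n_cells), function(i) {
    series <- simulate_recruitment_series(
      t_half = cfg$t_half_s, noise_sd = cfg$noise_sd,
      n_frames = cfg$recruit_n_frames,
      frame_interval = cfg$recruit_frame_interval_s,
      baseline_frames = cfg$baseline_frames,
      seed = derive_seed(cfg$seed, i))
    simulate_recruitment_movie(series, seed = derive_seed(cfg$seed, i + 1000))
  })
  fit <- recruitment_pipeline(movies,
                              roi = list(xmin = 9, xmax = 16,
                                         ymin = 1, ymax = 24),
                              baseline_frames = cfg$baseline_frames,
                              register = FALSE)
  write_table_out(fit$curve[, c("time_s", "intensity_norm")],
                  file.path(out_dir, "recruitment_curve.tsv"))
  write_config(list(K_per_s = fit$K, t_half_s = fit$t_half_s,
                    r_squared = fit$r_squared),
               file.path(out_dir, "recruitment_fit.txt"))
  fit
}

pipeline_abundance <- function(cfg, out_dir) {
  lanes <- simulate_gel(true_molecules_per_cell = cfg$true_molecules_per_cell,
                        noise_sd = cfg$noise_sd, tev_factor = cfg$tev_factor,
                        seed = cfg$seed)
  write_table_out(lanes, file.path(out_dir, "lanes.tsv"))
  res <- quantify_gel(lanes, tev_factor = cfg$tev_factor)
  write_table_out(res, file.path(out_dir, "abundance.tsv"))
  res
}

#' Run the bundled demonstration pipeline
#'
#' Executes the diffusion pipeline on the packaged demo configuration
#' (a small synthetic two-state acquisition) and returns the fit.
#'
#' @param out_dir Output directory.
#' @return The `diffusion_fit` for the demo data.
#' @export
run_demo <- function(out_dir = tempfile("sptkinetics_demo_")) {
  cfg_file <- system.file("extdata", "demo_config.txt",
                          package = "sptkinetics")
  cfg <- do.call(pipeline_config, read_config(cfg_file))
  run_pipeline(cfg, out_dir)
}
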