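# sptkinetics

Quantitative analysis of the biophysical behaviour of nuclear proteins —
built around the measurements used to characterize HaloTagged DNA damage
response factors in living cells:

* **Diffusion and chromatin binding** from single-particle tracking:
  jump-length distributions over lags of 1–7 frames are fitted with a
  two-state (bound/free) Brownian mixture,

  p(r; n) = Σₛ wₛ(n) · r/(2aₛ) · exp(−r²/4aₛ),  aₛ = Dₛ·n·Δt + σ²,

  with an axial defocus correction for free molecules leaving the
  detection slice (depth dZ = 0.7 µm), yielding D_free, D_bound, and the
  bound fraction F_bound. A three-state variant resolves
  intermediate-mobility molecules inside repair foci.
* **Residence times** of chromatin-bound molecules: 10-frame averaged
  movies (138 → 13.8 fps), mobility-constrained tracking, survival curves
  of track durations, and two-component exponential decay fits bounded by
  a measured photobleaching half-life.
* **Recruitment kinetics** at laser-microirradiation sites: drift
  correction, ROI extraction, baseline subtraction, per-cell and average
  normalization, and one-phase association fits
  (Y = 1 − exp(−K·t), t½ = ln2/K).
* **Absolute abundance** (molecules per cell) from in-gel fluorescence
  standard curves with TEV and western-blot correction factors, and the
  Pearson comparison against flow cytometry.
* **A ground-truth simulator** for all of the above: two-state switching
  Brownian particles in a reflecting nucleus observed through a thin
  detection slice with photobleaching and localization error, movie
  rendering with Poisson noise, recruitment series, and synthetic gels —
  so every pipeline is testable without microscope data.

Everything takes and returns tibbles, fitted objects have broom-style
`tidy()`/`glance()` methods and `autoplot()` figures, and the stages
compose with the pipe.

## Worked example

Simulate a chromatin-binding factor (66% bound, D_free = 2 µm²/s) at
7.24 ms frames, build jump-length histograms, and fit the two-state model:

```r
library(sptkinetics)

cfg <- sim_config(n_particles = 20000, duration_frames = 60,
                  f_bound = 0.66, D_free = 2, D_bound = 0.01, seed = 42)
tracks <- truth_to_trajectories(simulate_tracks(cfg), max_gaps = 2)
hist <- compute_jump_histograms(tracks, cfg$frame_interval)
fit <- fit_diffusion_model(hist, n_states = 2)
fit
#> <diffusion_fit> 2-state, 55166 jumps, rss = 11.44
#>   D_free = 1.83 um^2/s, D_bound = 0.0104 um^2/s, F_bound = 61.9%
tidy(fit)
#> # A tibble: 4 × 2
#>   term    estimate
#>   <chr>      <dbl>
#> 1 D_free    1.83
#> 2 D_bound   0.0104
#> 3 F_bound   0.619
#> 4 F_free    0.381
```

The fitted bound fraction (61.9%) and D_free (1.83 µm²/s) recover the
simulated truth to within the sampling and protocol tolerances discussed
in the methods vignette; `autoplot(fit)` overlays the fitted densities on
the per-lag histograms.

Residence-time fitting works the same way on track durations:

```r
d <- sample_biexponential(1e4, fraction_slow = 0.3,
                          t_half_fast = 0.5, t_half_slow = 5, seed = 1)
fit_biexponential(survival_curve(d))
#> <biexp_fit> t_1/2 fast = 0.506 s, t_1/2 slow = 5.08 s,
#>             slow fraction = 0.29, R^2 = 1.0000
```

`run_demo()` executes a bundled end-to-end diffusion pipeline;
`run_pipeline(pipeline_config("residence"), out_dir)` and friends chain
the other stages and write result tables plus a parameter log. A thin
command-line wrapper lives at `inst/cli/sptkinetics.R`.

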