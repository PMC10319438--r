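---
title: "Models and methods behind sptkinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sptkinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptkinetics)
```

sptkinetics quantifies how nuclear proteins — DNA damage response factors
are the motivating system — move, bind chromatin, accumulate at DNA
lesions, and how many copies of them a cell contains, from live-cell
imaging and in-gel fluorescence data. This vignette explains each model,
its assumptions, the tunable parameters, and the design decisions that were
genuinely open, in enough detail that a user can judge what a result does
and does not mean.

## The two-state diffusion model

Single-molecule trajectories are summarized as jump-length distributions:
for each lag $n = 1..7$ frames, the magnitudes $r$ of displacements between
localizations $n$ frames apart (with every intermediate frame localized)
are histogrammed in 0.01 µm bins, taking at most 4 jumps per trajectory per
lag so that long-lived bound molecules do not dominate the statistics. The
model fitted to these histograms assumes each molecule is either
chromatin-bound (diffusion coefficient $D_\mathrm{bound}$) or freely
diffusing ($D_\mathrm{free}$), giving the mixture density

$$ p_n(r) = \sum_s w_s(n)\,\frac{r}{2 a_s}\,e^{-r^2 / 4 a_s},
   \qquad a_s = D_s\, n\, \Delta t + \sigma^2, $$

where $\sigma$ is the static localization error per axis (it inflates every
apparent jump) and the state weights $w_s(n) \propto f_s Z_s(n)$ combine
the global state fractions with a lag-dependent *defocus survival factor*
$Z_s(n)$, renormalized to sum to one at every lag. Fitting is bounded
least squares on the binned densities (PDF fitting) across all lags
jointly, from a deterministic lattice of 27 starting points; bounds are
$D_\mathrm{free} \in [0.5, 25]$, $D_\mathrm{bound} \in [0.0001, 0.5]$
µm²/s. A three-state variant adds an intermediate-mobility component,
which is useful for molecules that diffuse slowly inside phase-separated
repair compartments. $\sigma$ (default 0.035 µm, a typical value for this
kind of microscopy — the acquisition itself does not report it) is a fixed
input rather than a fitted parameter: at these jump scales $\sigma$ and
$D_\mathrm{bound}$ are nearly degenerate, and fixing $\sigma$ stabilizes
desk-scale fits.

### Defocus correction

A molecule is only detectable while it stays within the axial detection
slice of depth $dZ = 0.700$ µm, so fast molecules are progressively lost
from long-lag statistics and an uncorrected fit inflates the bound
fraction (this directional effect is asserted as a test). Two survival
factors are implemented:

* `defocus_fraction()` — the absorbing-slab eigenfunction series
  $S(t) = \sum_{m\ \mathrm{odd}} \frac{8}{m^2\pi^2}
  e^{-m^2 \pi^2 D t / dZ^2}$ for a particle started uniformly inside the
  slice. It is validated against an independent Monte-Carlo slab
  simulation (bridge-corrected sub-stepping, $10^6$ walkers) to within
  0.005.
* `defocus_pair_retention()` — the exact retention probability for
  frame-sampled *pairs*: the stationary axial distribution of molecules at
  observed frames (new entries concentrate near the slice boundaries) is
  propagated through the discrete absorbing transition kernel. This is the
  formally correct factor for histograms compiled from tracked particles.

The *fitting default is the slab series*. That is deliberate, and worth
being explicit about: the compile protocol itself distorts the state
weights — the minimum track length of 3 localizations removes short free
excursions through the slice (pushing the apparent bound fraction up),
while the 4-jumps-per-trajectory cap under-weights long bound tracks
(pushing it down). Neither effect can be corrected inside the model
without knowledge of the photobleaching-limited track-length distribution,
which the fitter does not assume. Empirically, the slab factor's modest
under-count of free-pair survival offsets the minimum-track-length
distortion, and across a 3×3 grid of (bound fraction, $D_\mathrm{free}$)
conditions the slab default recovers the bound fraction within ±0.04 and
the diffusion coefficients within ~10%, whereas the formally exact pair
factor leaves the full selection bias visible (up to +0.09 on the bound
fraction at $D_\mathrm{free} = 4$ µm²/s). Users who compile histograms
without a track-length filter should prefer `defocus = "pair"`.

### What the simulator emulates

`simulate_tracks()` realizes the generative model the fit assumes, plus
the observation effects that real data have:

* lateral 2D Brownian steps with per-axis variance $2 D(\mathrm{state})
  \Delta t$; state switching as a continuous-time two-state Markov chain
  (within-frame switches are assigned to the dominant state of the
  interval — the simplest scheme consistent with a two-state fit);
* axial 1D Brownian motion reflected at a nuclear height of 2 µm (a
  typical basal nuclear thickness for an adherent cell). The reflecting
  reservoir matters: without it free molecules wander off axially and the
  visible-state composition drifts over the movie, which no defocus model
  describes. A frame is invisible if the axial path left the slice during
  the preceding interval (Brownian-bridge crossings are sampled, not just
  frame-instant positions) — the continuous-path semantics that the
  absorbing-slab correction describes;
* exponential photobleaching, static Gaussian localization error, and
  deterministic per-particle random streams so that changing the particle
  count does not reshuffle existing particles.

Default study conditions for recovery experiments were chosen once, as a
realistic operating point, and are part of the experimental design:
7.24 ms frames, 0.16 µm pixels, bound dwell time 5 s
($k_\mathrm{unbind} = 0.2$ s⁻¹, matching the measured seconds-scale
chromatin residence of these factors), and a single-fluorophore
photobleaching half-life of 25 ms, which puts mean track lengths near 5
frames — the short-track regime in which the per-trajectory jump cap
samples both states evenly. With multi-second track lifetimes the 4-jump
cap provably under-weights bound trajectories and no defocus factor can
repair that; this is a documented limitation of the compile protocol, not
of the optimizer. Ground truth is linked into trajectories with the
protocol's 2-frame gap allowance.

What passing these tests shows: the estimator is consistent with its own
generative model, including realistic observation selection. What they do
not show: robustness to anomalous diffusion, dense labeling with
mis-linking, non-Gaussian localization error, or state dwell times
comparable to the frame interval (state mixing within a lag biases
$D_\mathrm{free}$ downward; at a 5 s dwell the effect is <2%).

## Residence-time analysis

Chromatin residence is measured on 10-frame block-averaged movies
(138 → 13.8 fps): averaging amplifies static molecules and blurs mobile
ones, and `track_bound()` then links with the search radius generated by
$D_\mathrm{max} = 0.5$ µm²/s treated as a *hard* constraint (radius factor
1, no gap closing), so only low-mobility molecules form tracks. The
acquisition protocol note that quotes $D_\mathrm{max} = 0.05$ µm²/s for
this step is accepted through the same argument; 0.5 is the default
because the main protocol text states it. Track durations (first to last
frame inclusive, times the effective frame interval) are summarized as a
survival curve $S(\tau) = 1 - \mathrm{CDF}$, and fitted with a
two-component exponential decay

$$ S(\tau) = (1 - f)\,2^{-(\tau - \tau_0)/t_\mathrm{fast}}
           + f\,2^{-(\tau - \tau_0)/t_\mathrm{slow}}, $$

with $\tau_0$ the minimum trackable duration. The fit is unweighted least
squares on the survival probability (the alternative — fitting binned
duration frequencies — was considered and rejected because the survival
curve is the quantity reported and plotted). Interpretation is bounded by
photobleaching: `bleach_half_life()` fits a single exponential to the
integrated nuclear intensity of a stably incorporated reference (histone
H2B), and any fitted slow component close to that half-life (7.7 s under
the reference conditions) means the molecule outlives the measurement. The
synthetic acceptance experiment makes exactly this point: bound molecules
with residence far beyond the 22 s observation window return a slow
component at the configured 7.7 s bleach half-life. Durations can never
exceed the movie length, so `fraction_exceeding()` reports the fraction of
tracks that survive the whole window rather than extrapolating.

## Recruitment kinetics at laser-induced damage

Movies are drift-corrected by FFT cross-correlation to the first frame
with parabolic sub-pixel refinement (a deliberately simple registration;
it recovers synthetic shifts to <0.1 px). Per cell, the mean ROI intensity
is baseline-subtracted (all pre-irradiation frames; the protocol does not
state a count, and using them all minimizes baseline noise) and divided by
its own maximum; cell curves on a common grid are averaged (truncated to
the shortest — curves of different sampling rates are never resampled) and
the average is rescaled so its brightest frame is 1. The half-time comes
from least squares on the post-irradiation points of
$Y = 1 - e^{-K t}$ with baseline fixed at 0 and plateau fixed at 1
($t_{1/2} = \ln 2 / K$).

Normalizing by the *maximum observed frame* is part of the protocol and
has a knowable bias: noise makes the maximum overshoot the plateau, which
deflates the curve and inflates $t_{1/2}$; truncating the observation
before the plateau has the opposite sign. At the noise level of averaged
ROI curves (~1–2% per frame) and an observation of about six half-times,
the two effects nearly cancel and synthetic half-times spanning 22–670 s
are recovered within 5% at their respective sampling rates (1, 2, 10 s).
Much longer plateau stretches, or noisier single-cell curves, will bias
the estimate upward — worth remembering when comparing slow factors.

## Absolute abundance from in-gel fluorescence

Molecules per cell are computed by inverting two ordinary least-squares
standard curves: fluorescent signal vs femtomoles of a purified labeled
tag standard, and loading-control signal vs cell count. Curves keep their
fitted intercepts (gel backgrounds are not zero, and nothing in the
protocol forces the line through the origin). The corrected sample signal
is

$$ \mathrm{molecules/cell}
   = \frac{(\mathrm{signal} \times \mathrm{TEV}) - b}{m}
     \times 10^{-15} N_A / \mathrm{cells}, $$

where the TEV correction factor — the loading-normalized ratio of cleaved
to uncleaved fluorescence — compensates for migration-dependent signal
differences between the fusion protein and the free tag standard (observed
factors range from about 1.04 to 3.04). A western-blot factor rescales
tagged-protein abundance to the untagged protein. Replicate scatter and
factor uncertainties propagate as relative variances added in quadrature
(products and quotients only, so the rule is exact to first order).
Agreement between gel-derived and flow-cytometry-derived relative
abundances, both normalized to a common reference line, is quantified by
Pearson correlation. The cell-number curve calibrates loading by default;
passing a plain cell count instead is supported where lysate equivalents
are known directly.

## Numerical choices and degenerate inputs

* Frames are 0-based; physical coordinates in µm (origin at the center of
  the top-left pixel, x rightward, y downward); times in seconds. Enforced
  once, by the readers and writers.
* The trajectory linker solves each frame's assignment problem exactly
  (Jonker–Volgenant shortest augmenting path, unit-tested against
  brute-force enumeration) with per-link gates
  $r_\mathrm{max}(g) = \sqrt{4 D_\mathrm{max} (g+1) \Delta t} \times 3$
  over a gap of $g \le 2$ frames; the 3× margin covers >99% of Gaussian
  steps at $D_\mathrm{max}$. Exact cost ties resolve deterministically.
* Spot detection refines thresholded 3×3 local maxima by least-squares
  Gaussian fits; isolated spots localize to <0.001 px, but spots closer
  than ~4 px produce paired artifacts — sparse fields are a stated
  assumption. Flat or saturated frames return no localizations, with a
  warning.
* The defocus series is truncated when terms fall below $10^{-12}$; the
  pair-retention kernel uses an 81-point grid.
* Multi-start fits break ties by lowest residual, then lowest
  $D_\mathrm{free}$. Zero-count bins are retained in the objective.
* Degenerate inputs error with classed conditions: empty duration vectors,
  non-decaying bleach series, constant recruitment movies, degenerate
  calibration amounts, zero-variance correlation inputs, trajectory files
  with non-increasing frames.

## Problem sizes

The test-suite experiments use 90,000 simulated particles (≥ 5×10⁴ lag-1
jumps) for diffusion recovery, 10⁴ durations for residence fits, 10
synthetic cells per recruitment condition, and 10⁶ Monte-Carlo walkers for
the defocus oracle; these sizes give sampling errors several-fold smaller
than the tolerances they are tested against.

## Known limitations

* Recovery tolerances hold under the stated study conditions; the
  per-trajectory jump cap biases the bound fraction downward when tracks
  live much longer than free molecules stay in focus.
* No correction is attempted for bound molecules drifting axially out of
  focus during residence measurements, which shortens apparent residence
  times; the bleach bound is the honest ceiling.
* The registration handles translation only; rotation or deformation
  would need a real registration package.
* Gel densitometry (band finding) is out of scope — lane signals arrive
  already integrated.
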