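# Absolute protein abundance from in-gel fluorescence: standard curves,
# TEV and western correction factors, Avogadro conversion, and the
# gel-vs-flow-cytometry comparison.

#' Fit a linear standard curve
#'
#' Ordinary least squares of signal on amount (femtomoles for protein
#' standards, cell count for cell-number standards). The intercept is fitted,
#' not forced through the origin, because gel backgrounds are nonzero.
#'
#' @param amount Known amounts (>= 3 distinct values).
#' @param signal Measured signals.
#' @return A `standard_curve` object: `slope`, `intercept`, `r_squared`.
#' @export
fit_standard_curve <- function(amount, signal) {
  stopifnot(length(amount) == length(signal))
  if (length(amount) < 3L) {
    stop_spt("need at least 3 calibration points",
             class = "sptkinetics_bad_argument")
  }
  if (var(amount) == 0) {
    stop_spt("calibration amounts are degenerate (zero variance)",
             class = "sptkinetics_bad_argument")
  }
  fit <- lm(signal ~ amount)
  tss <- sum((signal - mean(signal))^2)
  r2 <- if (tss == 0) 0 else 1 - sum(stats::residuals(fit)^2) / tss
  slope <- coef(fit)[["amount"]]
  if (slope <= 0) warning("standard curve slope is not positive")
  structure(list(slope = slope, intercept = coef(fit)[["(Intercept)"]],
                 r_squared = r2, model = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> slope = %.4g, intercept = %.4g, R^2 = %.4f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' TEV correction factor
#'
#' Ratio of loading-normalized fluorescent signal after versus before
#' cleaving the tag off the fusion protein with TEV protease:
#' `(cleaved / loading_cleaved) / (uncleaved / loading_uncleaved)`. It
#' corrects for migration-dependent differences in in-gel fluorescence
#' between the fusion protein and the free tag standard, and is applied
#' multiplicatively to the fusion signal.
#'
#' @param signal_cleaved,signal_uncleaved Fluorescent signals of the
#'   TEV-digested and undigested sample.
#' @param loading_cleaved,loading_uncleaved Loading-control (stain-free)
#'   signals of the same lanes.
#' @return The correction factor (1 means no migration effect).
#' @export
tev_correction_factor <- function(signal_cleaved, signal_uncleaved,
                                  loading_cleaved = 1,
                                  loading_uncleaved = 1) {
  for (v in c(signal_cleaved, signal_uncleaved,
              loading_cleaved, loading_uncleaved)) {
    if (!is.finite(v) || v <= 0) {
      stop_spt("all signals and loading controls must be positive",
               class = "sptkinetics_bad_argument")
    }
  }
  (signal_cleaved / loading_cleaved) / (signal_uncleaved / loading_uncleaved)
}

#' Molecules per cell from a gel signal
#'
#' Converts a fluorescent lane signal into absolute abundance: the
#' TEV-corrected signal is mapped to femtomoles through the protein standard
#' curve, and to molecules per cell via the Avogadro constant and the number
#' of cells loaded (given directly, or derived from a cell-number standard
#' curve and the lane's loading signal). Replicate scatter and the correction
#' factor uncertainty propagate in quadrature on the relative scale.
#'
#' @param sample_signal Fluorescent signal(s) of the sample lane(s);
#'   replicates are averaged and their s.d. propagated.
#' @param std_curve Protein [fit_standard_curve()] (signal per femtomole).
#' @param cells Number of cells loaded, or a list
#'   `list(curve = <standard_curve>, loading_signal = <numeric>)` to derive
#'   it from the loading channel.
#' @param tev_factor Multiplicative TEV correction factor.
#' @param tev_sd Standard deviation of the TEV factor.
#' @return An `abundance_result` tibble row: `molecules_per_cell`, `sd`,
#'   `tev_factor`, `western_factor` (NA until [western_correction()] is
#'   applied), `n_replicates`.
#' @export
molecules_per_cell <- function(sample_signal, std_curve, cells,
                               tev_factor = 1, tev_sd = 0) {
  stopifnot(inherits(std_curve, "standard_curve"))
  check_number(tev_factor, "tev_factor", min = 1e-12)
  check_number(tev_sd, "tev_sd", min = 0)
  if (is.list(cells)) {
    stopifnot(inherits(cells$curve, "standard_curve"))
    n_cells <- (mean(cells$loading_signal) - cells$curve$intercept) /
      cells$curve$slope
  } else {
    n_cells <- cells
  }
  check_number(n_cells, "cells", min = 1e-12)
  sig <- mean(sample_signal)
  sig_sd <- if (length(sample_signal) > 1L) sd(sample_signal) else 0
  fmol <- (sig * tev_factor - std_curve$intercept) / std_curve$slope
  if (fmol <= 0) {
    stop_spt("signal does not exceed the blank; abundance not quantifiable",
             class = "sptkinetics_below_blank")
  }
  mols <- fmol * 1e-15 * N_AVOGADRO / n_cells
  rel_var <- (if (sig > 0) (sig_sd / sig)^2 else 0) + (tev_sd / tev_factor)^2
  tibble::new_tibble(
    list(molecules_per_cell = mols, sd = mols * sqrt(rel_var),
         tev_factor = tev_factor, western_factor = NA_real_,
         n_replicates = length(sample_signal)),
    class = "abundance_result")
}

#' Western-blot correction to untagged abundance
#'
#' Rescales a tagged-protein abundance by the untagged:tagged expression
#' ratio measured by quantitative western blotting, propagating the ratio's
#' uncertainty in quadrature.
#'
#' @param result An [molecules_per_cell()] result.
#' @param ratio Untagged-to-tagged expression ratio (> 0).
#' @param ratio_sd Standard deviation of the ratio.
#' @return An `abundance_result` with corrected `molecules_per_cell` and
#'   `sd`, and `western_factor` recorded.
#' @export
western_correction <- function(result, ratio, ratio_sd = 0) {
  stopifnot(inherits(result, "abundance_result"))
  check_number(ratio, "ratio", min = 1e-12)
  check_number(ratio_sd, "ratio_sd", min = 0)
  m <- result$molecules_per_cell * ratio
  rel_var <- (if (result$molecules_per_cell > 0)
    (result$sd / result$molecules_per_cell)^2 else 0) + (ratio_sd / ratio)^2
  out <- result
  out$molecules_per_cell <- m
  out$sd <- m * sqrt(rel_var)
  out$western_factor <- ratio
  out
}

#' Pearson correlation between gel- and flow-derived relative abundances
#'
#' Both vectors should be normalized to the same reference protein before
#' comparison.
#'
#' @param gel_values,flow_values Paired relative abundances (n >= 3).
#' @return Pearson correlation coefficient.
#' @export
method_correlation <- function(gel_values, flow_values) {
  stopifnot(length(gel_values) == length(flow_values))
  if (length(gel_values) < 3L) {
    stop_spt("need at least 3 paired values",
             class = "sptkinetics_bad_argument")
  }
  if (var(gel_values) == 0 || var(flow_values) == 0) {
    stop_spt("zero variance input; correlation undefined",
             class = "sptkinetics_bad_argument")
  }
  cor(gel_values, flow_values, method = "pearson")
}

#' Quantify a gel lane table end to end
#'
#' Convenience pipeline over a lane tibble in the package interchange format
#' (`lane_id`, `role`, `amount`, `signal`, `loading_signal` with roles
#' `standard`, `cells`, `sample`): fits the protein and cell-number standard
#' curves and converts each sample lane's signal to molecules per cell.
#'
#' @param lanes Lane tibble (see [simulate_gel()]).
#' @param tev_factor,tev_sd TEV correction factor and its s.d.
#' @return An `abundance_result` row (replicate sample lanes are combined).
#' @export
quantify_gel <- function(lanes, tev_factor = 1, tev_sd = 0) {
  need <- c("role", "amount", "signal", "loading_signal")
  stopifnot(all(need %in% names(lanes)))
  std <- lanes[lanes$role == "standard", , drop = FALSE]
  cel <- lanes[lanes$role == "cells", , drop = FALSE]
  smp <- lanes[lanes$role == "sample", , drop = FALSE]
  if (nrow(smp) == 0L) {
    stop_spt("no sample lanes found", class = "sptkinetics_bad_argument")
  }
  std_curve <- fit_standard_curve(std$amount, std$signal)
  cell_curve <- fit_standard_curve(cel$amount, cel$signal)
  molecules_per_cell(
    smp$signal, std_curve,
    cells = list(curve = cell_curve, loading_signal = smp$loading_signal),
    tev_factor = tev_factor, tev_sd = tev_sd)
}
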