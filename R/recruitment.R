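# Laser-microirradiation recruitment kinetics: drift registration, ROI
# intensity extraction with baseline subtraction and per-cell normalization,
# cell averaging, and one-phase association fitting.

# FFT cross-correlation shift of frame b relative to frame a, with parabolic
# sub-pixel refinement of the correlation peak. Returns c(dx, dy) in pixels.
estimate_shift <- function(a, b) {
  ny <- nrow(a); nx <- ncol(a)
  fa <- stats::fft(a - mean(a))
  fb <- stats::fft(b - mean(b))
  cc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  refine <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (abs(den) < .Machine$double.eps) 0 else 0.5 * (cm - cp) / den
  }
  r0 <- pk[1]; c0 <- pk[2]
  rm <- if (r0 == 1) ny else r0 - 1; rp <- if (r0 == ny) 1 else r0 + 1
  cm <- if (c0 == 1) nx else c0 - 1; cp <- if (c0 == nx) 1 else c0 + 1
  dy <- (r0 - 1) + refine(cc[rm, c0], cc[r0, c0], cc[rp, c0])
  dx <- (c0 - 1) + refine(cc[r0, cm], cc[r0, c0], cc[r0, cp])
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  # The correlation peak encodes the displacement of `a` relative to `b`;
  # report the shift applied to `a` that produces `b`.
  c(dx = -dx, dy = -dy)
}

# Translate an image by (dx, dy) pixels with bilinear interpolation; samples
# that fall outside the frame take the image median.
shift_image <- function(im, dx, dy) {
  ny <- nrow(im); nx <- ncol(im)
  fill <- median(im)
  xs <- (seq_len(nx)) - dx
  ys <- (seq_len(ny)) - dy
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  gx <- function(ix) pmin(pmax(ix, 1L), nx)
  gy <- function(iy) pmin(pmax(iy, 1L), ny)
  out <- matrix(fill, ny, nx)
  v00 <- im[gy(y0), gx(x0), drop = FALSE]
  v01 <- im[gy(y0), gx(x0 + 1L), drop = FALSE]
  v10 <- im[gy(y0 + 1L), gx(x0), drop = FALSE]
  v11 <- im[gy(y0 + 1L), gx(x0 + 1L), drop = FALSE]
  wfx <- matrix(fx, ny, nx, byrow = TRUE)
  wfy <- matrix(fy, ny, nx)
  interp <- (1 - wfy) * ((1 - wfx) * v00 + wfx * v01) +
    wfy * ((1 - wfx) * v10 + wfx * v11)
  valid_x <- xs >= 1 & xs <= nx
  valid_y <- ys >= 1 & ys <= ny
  ok <- outer(valid_y, valid_x, `&`)
  out[ok] <- interp[ok]
  out
}

#' Drift-correct a movie by cross-correlation registration
#'
#' Estimates a per-frame translation relative to the first frame by FFT
#' cross-correlation with parabolic sub-pixel refinement, then applies the
#' inverse shift with bilinear interpolation. Featureless (flat) frames get
#' identity shifts with a warning.
#'
#' @param movie An [spt_movie()] with at least 2 frames.
#' @return The registered [spt_movie()]; the estimated shifts (pixels) are
#'   attached as attribute `"shifts"` (tibble `frame`, `dx_px`, `dy_px`).
#' @export
register_movie <- function(movie) {
  stopifnot(inherits(movie, "spt_movie"))
  nt <- n_frames(movie)
  if (nt < 2L) {
    stop_spt("registration needs at least 2 frames",
             class = "sptkinetics_bad_argument")
  }
  ref <- unclass(movie)[, , 1]
  flat_ref <- max(ref) - min(ref) <= .Machine$double.eps * max(abs(ref), 1)
  out <- unclass(movie)
  shifts <- matrix(0, nt, 2)
  for (k in 2:nt) {
    fr <- out[, , k]
    flat <- max(fr) - min(fr) <= .Machine$double.eps * max(abs(fr), 1)
    if (flat || flat_ref) {
      warning(sprintf("frame %d is featureless; identity shift used", k - 1L))
      next
    }
    sh <- estimate_shift(ref, fr)
    shifts[k, ] <- sh
    if (any(abs(sh) > 1e-3)) out[, , k] <- shift_image(fr, -sh[1], -sh[2])
  }
  res <- spt_movie(out, frame_interval_s = frame_interval(movie),
                   pixel_size_um = pixel_size(movie))
  attr(res, "shifts") <- tibble::tibble(frame = 0:(nt - 1L),
                                        dx_px = shifts[, 1],
                                        dy_px = shifts[, 2])
  res
}

roi_mask <- function(roi, ny, nx) {
  if (is.matrix(roi)) {
    stopifnot(nrow(roi) == ny, ncol(roi) == nx)
    return(roi)
  }
  stopifnot(all(c("xmin", "xmax", "ymin", "ymax") %in% names(roi)))
  if (roi$xmin < 1 || roi$xmax > nx || roi$ymin < 1 || roi$ymax > ny) {
    stop_spt("ROI extends outside the field",
             class = "sptkinetics_bad_argument")
  }
  m <- matrix(FALSE, ny, nx)
  m[roi$ymin:roi$ymax, roi$xmin:roi$xmax] <- TRUE
  m
}

#' Extract a normalized per-cell recruitment curve
#'
#' Mean ROI intensity per frame, minus the mean over the pre-irradiation
#' baseline frames, divided by its own maximum, so every cell's brightest
#' frame is 1. The result is invariant to rescaling all intensities.
#'
#' @param movie A registered [spt_movie()].
#' @param roi `list(xmin, xmax, ymin, ymax)` in 1-based pixels, or a logical
#'   mask matrix on the movie grid.
#' @param baseline_frames Number of pre-irradiation frames (>= 1).
#' @return Tibble `frame`, `time_s` (0 at irradiation), `intensity_norm`.
#'   Raises `"sptkinetics_no_signal"` if the background-subtracted maximum is
#'   not positive (no recruitment signal).
#' @export
extract_normalized_curve <- function(movie, roi, baseline_frames) {
  stopifnot(inherits(movie, "spt_movie"))
  baseline_frames <- check_count(baseline_frames, "baseline_frames", min = 1L)
  nt <- n_frames(movie)
  if (baseline_frames >= nt) {
    stop_spt("`baseline_frames` must leave post-irradiation frames",
             class = "sptkinetics_bad_argument")
  }
  m <- roi_mask(roi, dim(movie)[1], dim(movie)[2])
  raw <- vapply(seq_len(nt), function(k) mean(unclass(movie)[, , k][m]),
                numeric(1))
  corr <- raw - mean(raw[seq_len(baseline_frames)])
  if (max(corr) <= 0) {
    stop_spt("no recruitment signal: ROI intensity never exceeds baseline",
             class = "sptkinetics_no_signal")
  }
  tibble::tibble(
    frame = 0:(nt - 1L),
    time_s = (0:(nt - 1L) - baseline_frames + 1L) * frame_interval(movie),
    intensity_norm = corr / max(corr))
}

#' Average per-cell recruitment curves
#'
#' Pointwise mean across cells on a common frame grid, then rescaled so the
#' brightest average frame equals 1. Curves of unequal length are truncated
#' to the shortest; mismatched time grids are an error.
#'
#' @param curves List of [extract_normalized_curve()] tibbles.
#' @return A `recruitment_curve` tibble (`time_s`, `intensity_norm`,
#'   `n_cells`).
#' @export
average_curves <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  n_min <- min(vapply(curves, nrow, integer(1)))
  curves <- lapply(curves, function(cv) cv[seq_len(n_min), , drop = FALSE])
  t0 <- curves[[1]]$time_s
  for (cv in curves[-1]) {
    if (max(abs(cv$time_s - t0)) > 1e-9) {
      stop_spt("recruitment curves are not on a common time grid",
               class = "sptkinetics_grid_mismatch")
    }
  }
  avg <- rowMeans(vapply(curves, function(cv) cv$intensity_norm,
                         numeric(n_min)))
  out <- tibble::new_tibble(
    list(time_s = t0, intensity_norm = avg / max(avg),
         n_cells = rep(length(curves), n_min)),
    class = "recruitment_curve")
  out
}

#' Fit a one-phase association model to a recruitment curve
#'
#' Least-squares fit of `Y = 1 - exp(-K * t)` on the post-irradiation points
#' (`t > 0`), with the baseline fixed at 0 and the plateau fixed at 1; the
#' recruitment half-time is `t_half = log(2) / K`.
#'
#' @param curve A [average_curves()] result or any tibble with `time_s` and
#'   `intensity_norm` (>= 5 post-irradiation points).
#' @return A `one_phase_fit` object: `K` (1/s), `t_half_s`, `rss`,
#'   `r_squared`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_one_phase <- function(curve) {
  post <- curve[curve$time_s > 0, , drop = FALSE]
  if (nrow(post) < 5L) {
    stop_spt("need at least 5 post-irradiation points",
             class = "sptkinetics_bad_argument")
  }
  dat <- data.frame(t = post$time_s, y = post$intensity_norm)
  # Initial K from the earliest rise; fall back to the curve midpoint.
  y_mid <- dat$y[which.min(abs(dat$y - 0.5))]
  t_mid <- dat$t[which.min(abs(dat$y - 0.5))]
  k0 <- if (y_mid < 1 && y_mid > 0) -log(1 - y_mid) / t_mid else 1 / max(dat$t)
  fit <- minpack.lm::nlsLM(y ~ 1 - exp(-K * t), data = dat,
                           start = list(K = max(k0, 1e-6)),
                           lower = c(K = 1e-12))
  K <- coef(fit)[["K"]]
  rss <- sum(stats::residuals(fit)^2)
  r2 <- 1 - rss / sum((dat$y - mean(dat$y))^2)
  structure(list(K = K, t_half_s = log(2) / K, rss = rss, r_squared = r2,
                 curve = curve),
            class = "one_phase_fit")
}

#' @export
print.one_phase_fit <- function(x, ...) {
  cat(sprintf("<one_phase_fit> K = %.4g /s, t_1/2 = %.4g s, R^2 = %.4f\n",
              x$K, x$t_half_s, x$r_squared))
  invisible(x)
}

#' Run the full recruitment pipeline on a set of movies
#'
#' Registers each movie, extracts the baseline-subtracted, self-normalized
#' ROI curve per cell, averages across cells, and fits the one-phase
#' association model.
#'
#' @param movies List of [spt_movie()] objects (one per cell).
#' @param roi ROI passed to [extract_normalized_curve()].
#' @param baseline_frames Pre-irradiation frames per movie.
#' @param register Run drift correction first?
#' @return A `one_phase_fit`; the averaged curve is in `$curve`.
#' @export
recruitment_pipeline <- function(movies, roi, baseline_frames,
                                 register = TRUE) {
  curves <- lapply(movies, function(mv) {
    if (register) mv <- suppressWarnings(register_movie(mv))
    extract_normalized_curve(mv, roi, baseline_frames)
  })
  fit_one_phase(average_curves(curves))
}
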