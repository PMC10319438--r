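# Spot detection and trajectory linking.
#
# Detection: thresholded 3x3 local maxima refined to sub-pixel precision by a
# least-squares 2D Gaussian fit in a small window. Linking: frame-to-frame
# optimal bipartite assignment (Jonker-Volgenant shortest augmenting path)
# minimizing total squared displacement, with a per-link search radius
# r_max(g) = sqrt(4 * D_max * (g + 1) * dt) * margin over a gap of g frames.

#' Detect single-molecule spots in one frame
#'
#' Candidate spots are pixels exceeding `background + threshold` that are
#' strict 3x3 local maxima; each candidate is refined to sub-pixel position
#' by least-squares fitting a 2D Gaussian (amplitude, center, width, offset)
#' in a window of `ceiling(3 * psf_sigma_px)` pixels.
#'
#' @param image Numeric matrix (rows = y, columns = x).
#' @param threshold Intensity above local background required for a
#'   candidate maximum.
#' @param psf_sigma_px Expected PSF standard deviation in pixels.
#' @param pixel_size_um Pixel size used to report physical coordinates.
#' @return Tibble of localizations: `x_um`, `y_um` (origin at the center of
#'   the top-left pixel), `intensity` (fitted amplitude), `fit_sigma_um`.
#'   A flat or saturated image returns an empty tibble with a warning.
#' @export
detect_spots <- function(image, threshold, psf_sigma_px = 1.0,
                         pixel_size_um = 0.16) {
  stopifnot(is.matrix(image), is.numeric(image))
  empty <- tibble::tibble(x_um = numeric(), y_um = numeric(),
                          intensity = numeric(), fit_sigma_um = numeric())
  if (max(image) - min(image) <= .Machine$double.eps * max(abs(image), 1)) {
    warning("flat or saturated frame; no spots detected")
    return(empty)
  }
  ny <- nrow(image); nx <- ncol(image)
  bg <- median(image)
  cand <- which(image > bg + threshold, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  is_max <- vapply(seq_len(nrow(cand)), function(k) {
    r <- cand[k, 1]; c <- cand[k, 2]
    nb <- image[max(1, r - 1):min(ny, r + 1), max(1, c - 1):min(nx, c + 1)]
    image[r, c] >= max(nb)
  }, logical(1))
  cand <- cand[is_max, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  # Collapse plateau maxima closer than one PSF sigma to a single candidate.
  keep <- rep(TRUE, nrow(cand))
  if (nrow(cand) > 1L) {
    d <- as.matrix(stats::dist(cand))
    for (k in seq_len(nrow(cand))) {
      if (!keep[k]) next
      close <- which(d[k, ] < max(1, psf_sigma_px) & seq_len(nrow(cand)) > k)
      keep[close] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  w <- max(2L, ceiling(3 * psf_sigma_px))
  fits <- lapply(seq_len(nrow(cand)), function(k) {
    r0 <- cand[k, 1]; c0 <- cand[k, 2]
    rows <- max(1, r0 - w):min(ny, r0 + w)
    cols <- max(1, c0 - w):min(nx, c0 + w)
    patch <- image[rows, cols]
    # 0-based pixel coordinates of the window
    xs <- rep(cols - 1L, each = length(rows))
    ys <- rep(rows - 1L, times = length(cols))
    zs <- as.numeric(patch)
    obj <- function(p) {
      mu <- p[5] + p[3] * exp(-((xs - p[1])^2 + (ys - p[2])^2) / (2 * p[4]^2))
      sum((zs - mu)^2)
    }
    start <- c(c0 - 1, r0 - 1, image[r0, c0] - bg, psf_sigma_px, bg)
    fit <- try(optim(start, obj, method = "L-BFGS-B",
                     lower = c(min(cols) - 1, min(rows) - 1, 0, 0.3, -Inf),
                     upper = c(max(cols) - 1, max(rows) - 1, Inf,
                               3 * w, Inf)), silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    p <- unname(fit$par)
    if (p[3] <= 0) return(NULL)
    c(x = p[1], y = p[2], A = p[3], s = p[4])
  })
  fits <- do.call(rbind, fits[!vapply(fits, is.null, logical(1))])
  if (is.null(fits) || nrow(fits) == 0L) return(empty)
  tibble::tibble(x_um = fits[, "x"] * pixel_size_um,
                 y_um = fits[, "y"] * pixel_size_um,
                 intensity = fits[, "A"],
                 fit_sigma_um = fits[, "s"] * pixel_size_um)
}

#' Detect spots in every frame of a movie
#'
#' @inheritParams detect_spots
#' @param movie An [spt_movie()].
#' @return Localization tibble with a 0-based `frame` column.
#' @export
detect_spots_movie <- function(movie, threshold, psf_sigma_px = 1.0) {
  px <- pixel_size(movie)
  res <- lapply(seq_len(n_frames(movie)), function(k) {
    loc <- suppressWarnings(
      detect_spots(unclass(movie)[, , k], threshold, psf_sigma_px, px))
    if (nrow(loc) > 0L) loc$frame <- k - 1L
    loc
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(x_um = numeric(), y_um = numeric(),
                          intensity = numeric(), fit_sigma_um = numeric(),
                          frame = integer())
  }
  dplyr::relocate(out, "frame")
}

# Jonker-Volgenant shortest-augmenting-path solution of the rectangular
# assignment problem (n rows <= m columns). Returns, for each row, the
# assigned column index. Costs must be finite; use a large penalty for
# forbidden pairs.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, all(is.finite(cost)))
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)      # p[j + 1]: row assigned to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_j <- which(!used[-1L])        # candidate real columns
      cur <- cost[i0, free_j] - u[i0 + 1L] - v[free_j + 1L]
      upd <- cur < minv[free_j + 1L]
      minv[free_j[upd] + 1L] <- cur[upd]
      way[free_j[upd] + 1L] <- j0
      j1 <- free_j[which.min(minv[free_j + 1L])]
      delta <- minv[j1 + 1L]
      iu <- which(used)
      u[p[iu] + 1L] <- u[p[iu] + 1L] + delta
      v[iu] <- v[iu] - delta
      minv[which(!used)] <- minv[which(!used)] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}

#' Linking parameters
#'
#' @param D_max Maximum expected diffusion coefficient, um^2/s; generates the
#'   search radius `r_max(g) = sqrt(4 * D_max * (g + 1) * dt) * margin` for a
#'   link spanning `g` skipped frames.
#' @param max_gaps Maximum number of consecutive frames a particle may go
#'   undetected within one track.
#' @param min_track_length Minimum number of localizations per reported track.
#' @param margin Search-radius safety factor (3 covers > 99 percent of
#'   Gaussian steps at `D_max`).
#' @return A `linking_params` list.
#' @export
linking_params <- function(D_max = 5, max_gaps = 2, min_track_length = 3,
                           margin = 3) {
  check_number(D_max, "D_max", min = 1e-12)
  max_gaps <- check_count(max_gaps, "max_gaps", min = 0L)
  min_track_length <- check_count(min_track_length, "min_track_length", min = 1L)
  check_number(margin, "margin", min = 1e-6)
  structure(list(D_max = D_max, max_gaps = max_gaps,
                 min_track_length = min_track_length, margin = margin),
            class = "linking_params")
}

#' Link localizations into trajectories
#'
#' Processes frames in order; at each frame, open track ends (last seen at
#' most `max_gaps + 1` frames ago) and current localizations are matched by
#' optimal bipartite assignment minimizing total squared displacement, with
#' each candidate link gated by the gap-dependent search radius. Unmatched
#' localizations seed new tracks. Gap-closed frames contribute no
#' localization. Tracks shorter than `min_track_length` localizations are
#' discarded, and every localization belongs to at most one track.
#'
#' @param localizations Tibble with `frame` (0-based), `x_um`, `y_um`, and
#'   optionally `intensity`.
#' @param params A [linking_params()].
#' @param frame_interval Frame interval in seconds (converts `D_max` into a
#'   search radius).
#' @return Trajectory tibble: `track_id`, `frame`, `x_um`, `y_um`, `intensity`.
#' @export
link_trajectories <- function(localizations, params = linking_params(),
                              frame_interval) {
  stopifnot(inherits(params, "linking_params"))
  check_number(frame_interval, "frame_interval", min = 1e-12)
  empty <- tibble::tibble(track_id = integer(), frame = integer(),
                          x_um = numeric(), y_um = numeric(),
                          intensity = numeric())
  if (is.null(localizations) || nrow(localizations) == 0L) return(empty)
  loc <- dplyr::arrange(localizations, .data$frame)
  if (!"intensity" %in% names(loc)) loc$intensity <- NA_real_
  rmax2 <- function(g) 4 * params$D_max * (g + 1) * frame_interval *
    params$margin^2
  BIG <- 1e12

  # Track state: id, last frame, last position, accumulated rows.
  tracks <- list()
  open_idx <- integer()   # indices into `tracks` that can still be extended
  next_id <- 1L

  for (f in sort(unique(loc$frame))) {
    dets <- loc[loc$frame == f, , drop = FALSE]
    nd <- nrow(dets)
    # Retire ends that are too old to link.
    if (length(open_idx) > 0L) {
      last <- vapply(tracks[open_idx], function(t) t$last_frame, numeric(1))
      open_idx <- open_idx[f - last - 1 <= params$max_gaps]
    }
    ne <- length(open_idx)
    matched_det <- rep(FALSE, nd)
    if (ne > 0L && nd > 0L) {
      ex <- vapply(tracks[open_idx], function(t) t$x, numeric(1))
      ey <- vapply(tracks[open_idx], function(t) t$y, numeric(1))
      gap <- f - vapply(tracks[open_idx], function(t) t$last_frame, numeric(1)) - 1
      d2 <- outer(ex, dets$x_um, `-`)^2 + outer(ey, dets$y_um, `-`)^2
      lim <- rmax2(gap)
      cost <- matrix(BIG, ne, nd)
      ok <- d2 <= lim            # recycles lim down columns (rows = ends)
      cost[ok] <- d2[ok]
      # One dummy column per track end allows "no link" at the gate cost.
      cost <- cbind(cost, diag(lim, ne) + (1 - diag(ne)) * BIG)
      assign <- solve_assignment(cost)
      for (e in seq_len(ne)) {
        j <- assign[e]
        if (j >= 1L && j <= nd && cost[e, j] < lim[e] &&
            cost[e, j] < BIG) {
          ti <- open_idx[e]
          tracks[[ti]]$rows <- c(tracks[[ti]]$rows, which(loc$frame == f)[j])
          tracks[[ti]]$last_frame <- f
          tracks[[ti]]$x <- dets$x_um[j]
          tracks[[ti]]$y <- dets$y_um[j]
          matched_det[j] <- TRUE
        }
      }
    }
    # Unmatched detections start new tracks.
    for (j in which(!matched_det)) {
      tracks[[length(tracks) + 1L]] <- list(
        id = next_id, last_frame = f,
        x = dets$x_um[j], y = dets$y_um[j],
        rows = which(loc$frame == f)[j])
      open_idx <- c(open_idx, length(tracks))
      next_id <- next_id + 1L
    }
  }

  keep <- vapply(tracks, function(t) length(t$rows) >= params$min_track_length,
                 logical(1))
  tracks <- tracks[keep]
  if (length(tracks) == 0L) return(empty)
  out <- dplyr::bind_rows(lapply(seq_along(tracks), function(k) {
    rows <- tracks[[k]]$rows
    tibble::tibble(track_id = k, frame = loc$frame[rows],
                   x_um = loc$x_um[rows], y_um = loc$y_um[rows],
                   intensity = loc$intensity[rows])
  }))
  dplyr::arrange(out, .data$track_id, .data$frame)
}

#' Detect and link a whole movie
#'
#' Convenience wrapper running [detect_spots_movie()] then
#' [link_trajectories()], optionally restricting localizations to a nuclear
#' mask before linking (only nuclear tracks are analyzed downstream).
#'
#' @inheritParams detect_spots_movie
#' @inheritParams link_trajectories
#' @param nuclear_mask Optional logical matrix on the movie pixel grid;
#'   localizations outside it are dropped before linking.
#' @return Trajectory tibble.
#' @export
track_movie <- function(movie, threshold, psf_sigma_px = 1.0,
                        params = linking_params(), nuclear_mask = NULL) {
  loc <- detect_spots_movie(movie, threshold, psf_sigma_px)
  if (!is.null(nuclear_mask)) {
    loc <- filter_by_mask(loc, nuclear_mask, pixel_size(movie))
  }
  link_trajectories(loc, params, frame_interval(movie))
}

#' Keep localizations inside a binary mask
#'
#' @param localizations Tibble with `x_um`, `y_um`.
#' @param mask Logical matrix (rows = y, columns = x) on the image pixel grid.
#' @param pixel_size_um Pixel size of the mask grid.
#' @return The filtered tibble.
#' @export
filter_by_mask <- function(localizations, mask, pixel_size_um) {
  stopifnot(is.matrix(mask))
  idx <- mask_index(localizations$x_um, localizations$y_um,
                    mask, pixel_size_um)
  localizations[idx, , drop = FALSE]
}

# TRUE for coordinates whose nearest pixel falls inside the mask.
mask_index <- function(x_um, y_um, mask, pixel_size_um) {
  col <- round(x_um / pixel_size_um) + 1L
  row <- round(y_um / pixel_size_um) + 1L
  inside <- row >= 1L & row <= nrow(mask) & col >= 1L & col <= ncol(mask)
  out <- rep(FALSE, length(x_um))
  out[inside] <- mask[cbind(row[inside], col[inside])]
  out
}
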