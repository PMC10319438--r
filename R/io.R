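# Trajectory interchange format and flat key=value configs.
#
# Conventions enforced here, once, for the whole package: frames are 0-based,
# physical coordinates are micrometers, times are seconds.

TRAJ_COLS <- c("track_id", "frame", "x_um", "y_um", "intensity")

#' Read and write trajectory tables
#'
#' Trajectories travel between stages as tab-delimited text with a header
#' (`track_id`, `frame`, `x_um`, `y_um`, `intensity`). Reading validates the
#' format strictly: malformed rows raise an error naming the offending line,
#' and frames must be strictly increasing within each track.
#'
#' @param path File path.
#' @param tracks Trajectory tibble.
#' @return `read_trajectories()` returns the trajectory tibble (an empty file
#'   with a header yields an empty tibble); `write_trajectories()` returns
#'   `path` invisibly, and a write/read round trip is lossless.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) {
    stop_spt(sprintf("Trajectory file not found: %s", path),
             class = "sptkinetics_missing_input")
  }
  lines <- readLines(path)
  if (length(lines) == 0L) {
    stop_spt(sprintf("%s: empty file (missing header)", path),
             class = "sptkinetics_bad_format")
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header[seq_along(TRAJ_COLS)], TRAJ_COLS)) {
    stop_spt(sprintf("%s: line 1: expected header %s", path,
                     paste(TRAJ_COLS, collapse = ", ")),
             class = "sptkinetics_bad_format")
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(tibble::tibble(track_id = integer(), frame = integer(),
                          x_um = numeric(), y_um = numeric(),
                          intensity = numeric()))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  bad <- which(n_fields != length(header))
  if (length(bad) > 0L) {
    stop_spt(sprintf("%s: line %d: expected %d fields, found %d",
                     path, bad[1] + 1L, length(header), n_fields[bad[1]]),
             class = "sptkinetics_bad_format")
  }
  mat <- do.call(rbind, parts)
  num <- suppressWarnings(apply(mat[, 1:5, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 5)
  bad <- which(apply(num[, 1:4, drop = FALSE], 1, function(r) any(is.na(r))))
  if (length(bad) > 0L) {
    stop_spt(sprintf("%s: line %d: non-numeric value", path, bad[1] + 1L),
             class = "sptkinetics_bad_format")
  }
  out <- tibble::tibble(track_id = as.integer(num[, 1]),
                        frame = as.integer(num[, 2]),
                        x_um = num[, 3], y_um = num[, 4],
                        intensity = num[, 5])
  chk <- dplyr::group_by(out, .data$track_id)
  chk <- dplyr::summarise(chk, ok = all(diff(.data$frame) > 0) ||
                            dplyr::n() == 1L)
  if (!all(chk$ok)) {
    stop_spt(sprintf("%s: frames are not strictly increasing in track %s",
                     path, chk$track_id[!chk$ok][1]),
             class = "sptkinetics_bad_format")
  }
  out
}

#' @rdname read_trajectories
#' @export
write_trajectories <- function(tracks, path) {
  stopifnot(all(TRAJ_COLS %in% names(tracks)))
  df <- as.data.frame(tracks[, TRAJ_COLS])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read and write flat key=value configuration files
#'
#' @param path File path.
#' @param config Named list of scalar values.
#' @return `read_config()` returns a named list (numbers parsed as numeric);
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop_spt(sprintf("Config file not found: %s", path),
             class = "sptkinetics_missing_input")
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad) > 0L) {
    stop_spt(sprintf("%s: malformed line %d (expected key=value)",
                     path, bad[1]), class = "sptkinetics_bad_format")
  }
  vals <- lapply(kv, function(x) {
    v <- trimws(x[2])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  setNames(vals, vapply(kv, function(x) trimws(x[1]), character(1)))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  writeLines(sprintf("%s=%s", names(config),
                     vapply(config, function(v) format(v, digits = 17),
                            character(1))), path)
  invisible(path)
}
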