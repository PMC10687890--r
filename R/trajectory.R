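#' Construct a trajectory
#'
#' A trajectory is one animal's timestamped positions in projected meters.
#' Timestamps must be strictly increasing and coordinates finite. A
#' trajectory may be an irregular fix record or a regular interpolated grid
#' (flagged with its interval).
#'
#' @param animal_id character scalar
#' @param time POSIXct (UTC), strictly increasing
#' @param x,y numeric, projected meters
#' @param error_sd optional per-fix GPS error SD in meters (scalar or vector)
#' @param regular logical; TRUE for an interpolated regular grid
#' @param interval_min grid interval in minutes when `regular`
#' @return an object of class `trajectory` (a data.frame with metadata)
#' @export
trajectory <- function(animal_id, time, x, y, error_sd = NULL,
                       regular = FALSE, interval_min = NA_real_) {
  assert_that(length(time) == length(x) && length(x) == length(y),
              "invalid_argument", "time, x, y must have equal length")
  assert_that(length(time) > 0, "invalid_argument", "empty trajectory")
  assert_that(all(is.finite(x)) && all(is.finite(y)),
              "invalid_argument", "non-finite coordinates")
  tn <- as.numeric(time)
  assert_that(!is.unsorted(tn, strictly = TRUE),
              "invalid_argument", "timestamps must be strictly increasing")
  out <- data.frame(animal_id = as.character(animal_id), time = time,
                    x = as.numeric(x), y = as.numeric(y))
  attr(out, "error_sd") <- error_sd
  attr(out, "regular") <- isTRUE(regular)
  attr(out, "interval_min") <- interval_min
  class(out) <- c("trajectory", "data.frame")
  out
}

is_regular <- function(track) isTRUE(attr(track, "regular"))

track_interval <- function(track) attr(track, "interval_min")

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory %s: %d fixes, %s to %s%s>\n",
              x$animal_id[1], nrow(x),
              format_utc(x$time[1]), format_utc(x$time[nrow(x)]),
              if (is_regular(x)) sprintf(", regular %g min", track_interval(x)) else ""))
  invisible(x)
}

#' Write / read trajectories as CSV
#'
#' The on-disk dialect has columns `animal_id`, `timestamp` (ISO-8601 UTC),
#' `x`, `y`.
#'
#' @param tracks a trajectory or list of trajectories
#' @param path CSV path
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "trajectory")) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(animal_id = tr$animal_id, timestamp = format_utc(tr$time),
               x = sprintf("%.6f", tr$x), y = sprintf("%.6f", tr$y))
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @param error_sd optional error SD attached to every track on read
#' @return `read_tracks`: a named list of trajectories, one per animal
#' @export
read_tracks <- function(path, error_sd = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  assert_that(all(c("animal_id", "timestamp", "x", "y") %in% names(df)),
              "invalid_argument", "tracks CSV must have animal_id, timestamp, x, y")
  split_df <- split(df, df$animal_id)
  out <- lapply(split_df, function(d) {
    d <- d[order(d$timestamp), ]
    trajectory(d$animal_id[1], parse_utc(d$timestamp), d$x, d$y,
               error_sd = error_sd)
  })
  out[order(names(out))]
}
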