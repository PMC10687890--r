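#' Joint tracking window of a dyad
#'
#' Closed intersection of two trajectories' tracking windows. An empty
#' intersection is signaled distinctly by returning `NULL`.
#'
#' @param track_a,track_b trajectories
#' @return POSIXct vector `c(start, end)`, or `NULL` when disjoint
#' @export
temporal_intersection <- function(track_a, track_b) {
  assert_that(nrow(track_a) > 0 && nrow(track_b) > 0,
              "invalid_argument", "empty trajectory")
  start <- max(track_a$time[1], track_b$time[1])
  end <- min(track_a$time[nrow(track_a)], track_b$time[nrow(track_b)])
  if (start > end) return(NULL)
  c(start, end)
}

clip_track <- function(track, window) {
  keep <- track$time >= window[1] & track$time <= window[2]
  if (!any(keep)) return(NULL)
  out <- track[keep, , drop = FALSE]
  attributes(out)[c("error_sd", "regular", "interval_min")] <-
    attributes(track)[c("error_sd", "regular", "interval_min")]
  class(out) <- class(track)
  out
}

#' Detect direct contacts between two interpolated trajectories
#'
#' A direct contact is the co-location of the two animals at the same
#' (discretized) timestamp within a spatial buffer accounting for GPS
#' error. One contact event is emitted per shared grid timestamp whose
#' Euclidean distance is at or below the buffer (inclusive); the contact
#' location is the midpoint of the two simultaneous positions. Symmetric
#' in argument order after canonical pair ordering.
#'
#' @param itrack_a,itrack_b regular trajectories on the same interval
#'   (from [interpolate()])
#' @param buffer_m spatial buffer in meters (default 10)
#' @return a `contact_events` data.frame: `id_a`, `id_b` (lexicographic),
#'   `time`, `x`, `y` (midpoint), `distance`, ordered by time
#' @export
detect_contacts <- function(itrack_a, itrack_b, buffer_m = 10) {
  assert_that(is_regular(itrack_a) && is_regular(itrack_b),
              "invalid_argument", "both tracks must be regular grids")
  assert_that(identical(track_interval(itrack_a), track_interval(itrack_b)),
              "invalid_argument", "mismatched grid intervals")
  ids <- sort(c(itrack_a$animal_id[1], itrack_b$animal_id[1]))
  ia <- match(as.numeric(itrack_b$time), as.numeric(itrack_a$time))
  shared <- !is.na(ia)
  a <- itrack_a[ia[shared], ]; b <- itrack_b[shared, ]
  d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
  hit <- d <= buffer_m
  ev <- data.frame(id_a = rep(ids[1], sum(hit)),
                   id_b = rep(ids[2], sum(hit)),
                   time = a$time[hit],
                   x = (a$x[hit] + b$x[hit]) / 2,
                   y = (a$y[hit] + b$y[hit]) / 2,
                   distance = d[hit])
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("contact_events", "data.frame")
  ev
}

#' Write contacts as CSV
#' @param events a `contact_events` data.frame
#' @param path CSV path
#' @export
write_contacts <- function(events, path) {
  df <- data.frame(pair_a = events$id_a, pair_b = events$id_b,
                   timestamp = format_utc(events$time),
                   x = sprintf("%.6f", events$x),
                   y = sprintf("%.6f", events$y),
                   distance_m = sprintf("%.6f", events$distance))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Classify a weekly overlap series into a dyad relationship.
# within: tracking-period aggregate (mean) overlap above threshold.
# temporary: a run of more than min_weeks consecutive weeks above the
#   threshold inside an otherwise below-threshold record; the run is
#   excluded from the analysis window.
# between: everything else.
classify_overlap_series <- function(overlap, threshold = 0.5,
                                    min_weeks = 12) {
  if (mean(overlap) > threshold)
    return(list(relationship = "within", excluded = integer(0)))
  above <- overlap > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values & r$lengths > min_weeks)
  if (length(runs)) {
    excl <- unlist(lapply(runs, function(i) starts[i]:ends[i]))
    return(list(relationship = "temporary", excluded = sort(excl)))
  }
  list(relationship = "between", excluded = integer(0))
}

#' Classify a dyad as within-group, between-group, or temporarily same-group
#'
#' Female-male and male-male dyads are assumed between-group. For
#' female-female dyads, per-ISO-week kernel-density core areas (default
#' 50% isopleth) are computed over the joint tracking window and the
#' weekly overlap index (core intersection over the smaller core) is
#' aggregated by its mean: above the threshold the pair is within-group;
#' a run of more than `min_consecutive_weeks` consecutive above-threshold
#' weeks inside an otherwise below-threshold record marks a temporarily
#' merged pair, and those weeks are excluded from the analysis window;
#' otherwise the pair is between-group.
#'
#' @param track_a,track_b trajectories (interpolated or raw)
#' @param sexes length-2 character, e.g. `c("F", "F")`
#' @param grid analysis grid for the weekly KDEs
#' @param core_isopleth core-area isopleth level (default 0.50)
#' @param overlap_threshold overlap index threshold (default 0.5)
#' @param min_consecutive_weeks run length defining a temporary merge
#' @param contacts optional `contact_events` for this dyad, counted within
#'   the analysis windows into `n_contacts`
#' @return a `pair_record`
#' @export
classify_pair <- function(track_a, track_b, sexes, grid = NULL,
                          core_isopleth = 0.50, overlap_threshold = 0.5,
                          min_consecutive_weeks = 12, contacts = NULL) {
  ids <- c(track_a$animal_id[1], track_b$animal_id[1])
  ord <- order(ids)
  if (ord[1] == 2) {
    tmp <- track_a; track_a <- track_b; track_b <- tmp
    sexes <- sexes[2:1]; ids <- ids[2:1]
  }
  sex_class <- paste(sort(sexes), collapse = "")
  window <- temporal_intersection(track_a, track_b)
  assert_that(!is.null(window), "insufficient_data",
              "tracking windows do not overlap")

  if (sex_class %in% c("FM", "MM")) {
    rec <- new_pair_record(ids, sex_class, "between", window,
                           weekly = NULL, analysis_windows = list(window))
    return(count_contacts(rec, contacts))
  }

  assert_that(!is.null(grid), "invalid_argument",
              "grid is required for female-female classification")
  a <- clip_track(track_a, window); b <- clip_track(track_b, window)
  wk_a <- iso_week(a$time); wk_b <- iso_week(b$time)
  weeks <- sort(intersect(unique(wk_a), unique(wk_b)))
  assert_that(length(weeks) >= 2, "insufficient_data",
              "need at least 2 joint weeks of data to classify")
  ol <- vapply(weeks, function(w) {
    pa <- a[wk_a == w, c("x", "y")]; pb <- b[wk_b == w, c("x", "y")]
    if (nrow(pa) < 30 || nrow(pb) < 30) return(NA_real_)
    ha <- tryCatch(kde_homerange(pa, grid, core_isopleth, animal_id = ids[1]),
                   crsf_error = function(e) NULL)
    hb <- tryCatch(kde_homerange(pb, grid, core_isopleth, animal_id = ids[2]),
                   crsf_error = function(e) NULL)
    if (is.null(ha) || is.null(hb)) return(NA_real_)
    overlap_index(ha, hb, core_isopleth)
  }, 0)
  ok <- !is.na(ol)
  assert_that(sum(ok) >= 2, "insufficient_data",
              "fewer than 2 weeks support a core-area estimate")
  weeks <- weeks[ok]; ol <- ol[ok]
  cls <- classify_overlap_series(ol, overlap_threshold,
                                 min_consecutive_weeks)
  keep_weeks <- if (length(cls$excluded)) weeks[-cls$excluded] else weeks
  analysis_windows <- if (cls$relationship == "within") list() else
    week_windows(keep_weeks, window)
  rec <- new_pair_record(ids, sex_class, cls$relationship, window,
                         weekly = data.frame(week = weeks, overlap = ol),
                         analysis_windows = analysis_windows)
  count_contacts(rec, contacts)
}

iso_week <- function(time) format(time, "%G-W%V")

# Monday of an ISO week label ("2020-W05"): ISO week 1 always contains Jan 4
iso_week_monday <- function(labels) {
  y <- as.integer(substr(labels, 1, 4))
  w <- as.integer(substr(labels, 7, 8))
  jan4 <- as.Date(sprintf("%d-01-04", y))
  wd <- as.integer(format(jan4, "%u"))  # 1 = Monday
  jan4 - (wd - 1) + (w - 1) * 7
}

# contiguous ISO weeks -> closed time intervals clipped to the window
week_windows <- function(weeks, window) {
  if (!length(weeks)) return(list())
  mon <- as.POSIXct(paste(iso_week_monday(weeks), "00:00:00"), tz = "UTC")
  runs <- split(mon, cumsum(c(1, diff(mon) > 7)))
  lapply(runs, function(r) {
    lo <- max(min(r), window[1])
    hi <- min(max(r) + 7 * 86400 - 1, window[2])
    c(lo, hi)
  })
}

new_pair_record <- function(ids, sex_class, relationship, window, weekly,
                            analysis_windows) {
  structure(list(id_a = ids[1], id_b = ids[2], sex_class = sex_class,
                 relationship = relationship, window = window,
                 weekly = weekly, analysis_windows = analysis_windows,
                 n_contacts = NA_integer_, included = FALSE),
            class = "pair_record")
}

count_contacts <- function(rec, contacts) {
  if (is.null(contacts)) return(rec)
  inwin <- rep(FALSE, nrow(contacts))
  for (w in rec$analysis_windows)
    inwin <- inwin | (contacts$time >= w[1] & contacts$time <= w[2])
  rec$n_contacts <- sum(inwin)
  rec
}

#' @export
print.pair_record <- function(x, ...) {
  cat(sprintf("<pair %s-%s [%s]: %s, %s contacts%s>\n", x$id_a, x$id_b,
              x$sex_class, x$relationship,
              ifelse(is.na(x$n_contacts), "?", x$n_contacts),
              if (x$included) ", included" else ""))
  invisible(x)
}

#' Retain analyzable between-group pairs
#'
#' Keeps records whose relationship is between-group (or the
#' between-group window of a temporarily merged pair) with strictly more
#' than `min_contacts` direct contacts.
#'
#' @param records list of `pair_record`
#' @param min_contacts threshold (default 10; a pair with exactly 10 is
#'   excluded)
#' @return the retained records, `included` flag set
#' @export
filter_pairs <- function(records, min_contacts = 10) {
  keep <- list()
  for (rec in records) {
    if (!rec$relationship %in% c("between", "temporary")) next
    if (is.na(rec$n_contacts) || rec$n_contacts <= min_contacts) next
    rec$included <- TRUE
    keep[[length(keep) + 1]] <- rec
  }
  keep
}

#' Serialize pair records as JSON lines
#' @param records list of `pair_record`
#' @param path output path
#' @export
write_pair_records <- function(records, path) {
  lines <- vapply(records, function(r) {
    r$window <- format_utc(r$window)
    r$analysis_windows <- lapply(r$analysis_windows, format_utc)
    as.character(jsonlite::toJSON(unclass(r), auto_unbox = TRUE, digits = NA,
                                  na = "null"))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
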