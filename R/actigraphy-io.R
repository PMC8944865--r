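#' Read and write sleep/wake series CSV
#'
#' The interchange format is a two-column CSV, `timestamp` (ISO-8601) and
#' `state` (`S`/`W`/`M`). Gzip-compressed paths are handled transparently.
#'
#' @param series An [sw_series].
#' @param path File path (`.csv` or `.csv.gz`).
#' @return `write_sleepwake()` returns `path` invisibly; `read_sleepwake()`
#'   returns an [sw_series].
#' @export
write_sleepwake <- function(series, path) {
  df <- tibble::tibble(
    timestamp = format(series$time, "%Y-%m-%dT%H:%M:%S"),
    state = series$state
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_sleepwake
#' @export
read_sleepwake <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    timestamp = readr::col_character(), state = readr::col_character()
  ))
  bad <- which(!df$state %in% c("S", "W", "M"))
  if (length(bad) > 0) {
    stop("unknown state symbol '", df$state[bad[1]], "' at row ", bad[1])
  }
  tm <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(tm)) stop("unparseable timestamp at row ", which(is.na(tm))[1])
  dt <- as.numeric(diff(tm))
  if (any(dt <= 0)) {
    stop("non-monotone or duplicate timestamps at row ", which(dt <= 0)[1] + 1)
  }
  if (length(dt) > 0 && any(abs(dt - dt[1]) > 1e-6)) {
    stop("irregular epoch grid at row ", which(abs(dt - dt[1]) > 1e-6)[1] + 1)
  }
  el <- if (length(dt) > 0) dt[1] else 30
  new_sw_series(tibble::tibble(time = tm, state = df$state), el)
}

#' Read and write triaxial acceleration CSV
#'
#' Four columns: `timestamp` (ISO-8601 with fractional seconds) and `x`,
#' `y`, `z` in g. Sampling must be uniform.
#'
#' @param record An `accel_record` (see [synthesize_acceleration]).
#' @param path File path (`.csv` or `.csv.gz`).
#' @return `write_accel()` returns `path` invisibly; `read_accel()` an
#'   `accel_record`.
#' @export
write_accel <- function(record, path) {
  tm <- record$start_time + (seq_along(record$x) - 1) / record$sampling_hz
  df <- tibble::tibble(
    timestamp = format(tm, "%Y-%m-%dT%H:%M:%OS3"),
    x = record$x, y = record$y, z = record$z
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_accel
#' @export
read_accel <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    timestamp = readr::col_character(),
    x = readr::col_double(), y = readr::col_double(),
    z = readr::col_double()
  ))
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    stop("non-finite acceleration values")
  }
  tm <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  if (anyNA(tm)) stop("unparseable timestamp at row ", which(is.na(tm))[1])
  dt <- as.numeric(diff(tm))
  if (any(dt <= 0)) {
    stop("non-monotone or duplicate timestamps at row ", which(dt <= 0)[1] + 1)
  }
  hz <- 1 / stats::median(dt)
  if (any(abs(dt - 1 / hz) > 0.2 / hz)) {
    stop("irregular sampling beyond tolerance")
  }
  structure(
    list(start_time = tm[1], sampling_hz = hz,
         x = df$x, y = df$y, z = df$z),
    class = "accel_record"
  )
}

#' Detect nonwear periods from raw acceleration
#'
#' Slides a window over the record; a window is flagged nonwear when, on at
#' least `axes_required` axes, the acceleration SD is below `sd_thresh` OR
#' the range is below `range_thresh` (strict comparisons). Flags are
#' propagated to every epoch the window covers and unioned over the stepped
#' windows.
#'
#' @param record An `accel_record`.
#' @param window Window length, minutes.
#' @param step Window step, minutes.
#' @param sd_thresh Per-axis SD threshold, milli-g.
#' @param range_thresh Per-axis range threshold, milli-g.
#' @param axes_required Number of axes that must look idle.
#' @param epoch_len Epoch grid (seconds) of the output mask.
#' @return A logical vector of class `nonwear_mask` (TRUE = nonwear), with
#'   attributes `epoch_len` and `start_time`.
#' @export
detect_nonwear <- function(record, window = 60, step = 15, sd_thresh = 13,
                           range_thresh = 50, axes_required = 2,
                           epoch_len = 30) {
  if (window < step) stop("window must be >= step")
  if (sd_thresh <= 0 || range_thresh <= 0) stop("thresholds must be positive")
  hz <- record$sampling_hz
  n <- length(record$x)
  win_n <- as.integer(round(window * 60 * hz))
  step_n <- as.integer(round(step * 60 * hz))
  if (n <= win_n) stop("record shorter than one window")
  n_epochs <- as.integer(ceiling(n / (epoch_len * hz)))
  mask <- rep(FALSE, n_epochs)
  starts <- seq(1L, n - win_n + 1L, by = step_n)
  axes <- list(record$x * 1000, record$y * 1000, record$z * 1000) # mg
  for (s in starts) {
    idx <- s:(s + win_n - 1L)
    idle <- 0L
    for (a in axes) {
      v <- a[idx]
      if (stats::sd(v) < sd_thresh || (max(v) - min(v)) < range_thresh) {
        idle <- idle + 1L
      }
    }
    if (idle >= axes_required) {
      e0 <- as.integer(floor((s - 1) / (epoch_len * hz))) + 1L
      e1 <- min(n_epochs, as.integer(ceiling((s + win_n - 1) / (epoch_len * hz))))
      mask[e0:e1] <- TRUE
    }
  }
  structure(mask, epoch_len = epoch_len, start_time = record$start_time,
            class = "nonwear_mask")
}

#' Apply a nonwear mask to a sleep/wake series
#'
#' Epochs flagged nonwear become missing (`M`).
#'
#' @param series An [sw_series].
#' @param mask A `nonwear_mask` on the same epoch grid.
#' @return The masked [sw_series].
#' @export
apply_nonwear <- function(series, mask) {
  if (abs(attr(mask, "epoch_len") - sw_epoch_len(series)) > 1e-9 ||
      length(mask) != nrow(series)) {
    stop("mask grid does not align with series grid")
  }
  st <- series$state
  st[as.logical(mask)] <- "M"
  new_sw_series(tibble::tibble(time = series$time, state = st),
                sw_epoch_len(series))
}

#' Segment a series into noon-to-noon days
#'
#' Analysis days run from local noon to the next noon, so nightly sleep is
#' not split. Partial leading/trailing days are dropped. Nonwear hours per
#' day come from the mask when given, otherwise from `M` epochs (missing
#' epochs count as nonwear either way).
#'
#' @param series An [sw_series].
#' @param mask Optional `nonwear_mask` aligned to the series.
#' @param max_nonwear Validity threshold, hours: a day is valid when its
#'   nonwear time is strictly below this.
#' @return A tibble with one row per whole day: `day_index`, `day_start`,
#'   `day_end`, `nonwear_hours`, `valid`.
#' @export
segment_noon_days <- function(series, mask = NULL, max_nonwear = 5) {
  el <- sw_epoch_len(series)
  n <- nrow(series)
  nonwear <- if (is.null(mask)) {
    series$state == "M"
  } else {
    if (length(mask) != n) stop("mask length does not match series")
    as.logical(mask) | series$state == "M"
  }
  t0 <- series$time[1]
  first_noon <- noon_before(t0)
  if (first_noon < t0) first_noon <- first_noon + 86400
  end_time <- series$time[n] + el
  per_day <- as.integer(86400 / el)
  n_days <- floor(as.numeric(difftime(end_time, first_noon, units = "days")))
  if (n_days < 1) {
    return(tibble::tibble(day_index = integer(), day_start = t0[0],
                          day_end = t0[0], nonwear_hours = numeric(),
                          valid = logical()))
  }
  offset <- as.integer(round(as.numeric(
    difftime(first_noon, t0, units = "secs")
  ) / el))
  purrr::map(seq_len(n_days) - 1L, function(d) {
    i0 <- offset + d * per_day + 1L
    i1 <- offset + (d + 1L) * per_day
    nw <- sum(nonwear[i0:i1]) * el / 3600
    tibble::tibble(
      day_index = d,
      day_start = first_noon + d * 86400,
      day_end = first_noon + (d + 1) * 86400,
      nonwear_hours = nw,
      valid = nw < max_nonwear
    )
  }) |> purrr::list_rbind()
}

#' Select the analysable span of consecutive valid days
#'
#' Returns the longest run of consecutive valid days (nonwear strictly below
#' the threshold), capped at `max_days`; empty when the longest run is
#' shorter than `min_consecutive_days`. Ties break to the earliest start.
#'
#' @param days Output of [segment_noon_days].
#' @param max_nonwear Hours of nonwear above which (inclusive) a day is
#'   invalid.
#' @param min_consecutive_days Minimum run length to accept.
#' @param max_days Cap on the returned span length.
#' @return Integer vector of `day_index` values (possibly empty).
#' @export
select_valid_span <- function(days, max_nonwear = 5,
                              min_consecutive_days = 4, max_days = 7) {
  if (nrow(days) == 0) return(integer())
  ok <- days$nonwear_hours < max_nonwear
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  if (length(runs) == 0) return(integer())
  lens <- pmin(r$lengths[runs], max_days)
  best <- runs[which.max(lens)] # which.max takes the earliest maximum
  len <- min(r$lengths[best], max_days)
  if (len < min_consecutive_days) return(integer())
  days$day_index[starts[best]:(starts[best] + len - 1)]
}

#' Export a nonwear mask as half-open intervals
#'
#' @param mask A `nonwear_mask`.
#' @return Tibble with `start`, `end` (POSIXct, half-open) and `label`.
#' @export
nonwear_intervals <- function(mask) {
  el <- attr(mask, "epoch_len")
  t0 <- attr(mask, "start_time")
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  tibble::tibble(
    start = t0 + (starts[keep] - 1) * el,
    end = t0 + ends[keep] * el,
    label = "nonwear"
  )
}
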