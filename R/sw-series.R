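#' Epoch-level sleep/wake series
#'
#' The central intermediate of the pipeline: a tibble with one row per scoring
#' epoch, a `time` column (epoch start, POSIXct, timezone-naive UTC clock) and
#' a `state` column over the alphabet `"S"` (sleep), `"W"` (wake), `"M"`
#' (missing / nonwear). The epoch length in seconds is carried as an
#' attribute so the grid never has to be re-inferred.
#'
#' @param states Character vector of epoch states, each one of `"S"`, `"W"`,
#'   `"M"`.
#' @param start_time POSIXct start of the first epoch. Series conventionally
#'   start at local noon so that a night's sleep is never split across
#'   analysis days.
#' @param epoch_len Epoch length in seconds (default 30, the standard sleep
#'   scoring epoch). Must divide 24 h.
#' @return A tibble of class `sw_series` with columns `time` and `state`.
#' @examples
#' x <- sw_series(rep(c("W", "S"), each = 10))
#' sw_epoch_len(x)
#' @export
sw_series <- function(states,
                      start_time = as.POSIXct("2024-01-01 12:00:00", tz = "UTC"),
                      epoch_len = 30) {
  states <- as.character(states)
  bad <- which(!states %in% c("S", "W", "M"))
  if (length(bad) > 0) {
    stop("unknown state symbol '", states[bad[1]], "' at epoch ", bad[1])
  }
  if (epoch_len <= 0 || (86400 %% epoch_len) != 0) {
    stop("epoch_len must be a positive divisor of 24 h (86400 s)")
  }
  out <- tibble::tibble(
    time = start_time + (seq_along(states) - 1L) * epoch_len,
    state = states
  )
  new_sw_series(out, epoch_len)
}

new_sw_series <- function(df, epoch_len) {
  attr(df, "epoch_len") <- as.numeric(epoch_len)
  class(df) <- c("sw_series", class(tibble::tibble()))
  df
}

#' @rdname sw_series
#' @param x An object.
#' @export
is_sw_series <- function(x) inherits(x, "sw_series")

#' @rdname sw_series
#' @export
sw_epoch_len <- function(x) {
  el <- attr(x, "epoch_len")
  if (is.null(el)) {
    if (nrow(x) < 2) stop("cannot infer epoch length from a 1-row series")
    el <- as.numeric(difftime(x$time[2], x$time[1], units = "secs"))
  }
  el
}

#' @rdname sw_series
#' @export
sw_start_time <- function(x) x$time[1]

# hours represented by one epoch
epoch_hours <- function(x) sw_epoch_len(x) / 3600

#' Raster plot of a sleep/wake series
#'
#' Renders the series day by day (noon-to-noon rows), in the style of an
#' actogram: sleep dark, wake light, missing grey.
#'
#' @param object An [sw_series].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sw_series <- function(object, ...) {
  el <- sw_epoch_len(object)
  origin <- noon_before(object$time[1])
  off_h <- as.numeric(difftime(object$time, origin, units = "hours"))
  df <- tibble::tibble(
    day = floor(off_h / 24),
    hour = off_h %% 24,
    state = factor(object$state, levels = c("S", "W", "M"),
                   labels = c("sleep", "wake", "missing"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$day,
                                   fill = .data$state)) +
    ggplot2::geom_tile(width = el / 3600, height = 0.9) +
    ggplot2::scale_y_reverse(breaks = unique(df$day)) +
    ggplot2::scale_fill_manual(values = c(sleep = "grey15", wake = "white",
                                          missing = "#2ca089")) +
    ggplot2::labs(x = "hours after noon", y = "day", fill = NULL) +
    ggplot2::theme_minimal()
}

# Most recent noon at or before `t` (clock convention: naive local time).
noon_before <- function(t) {
  day <- trunc(t, units = "days")
  noon <- day + 12 * 3600
  noon[noon > t] <- noon[noon > t] - 86400
  noon
}
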