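#' Build sleep windows by bridging short wake gaps
#'
#' Maximal sleep runs are merged into a single window whenever the wake gap
#' between consecutive runs is at most `max_gap` minutes (inclusive) and
#' contains no missing epochs (a missing epoch conservatively breaks the
#' window). A window's onset/offset are the first sleep epoch's start and
#' the last sleep epoch's end, so `st + wt` equals the window length
#' exactly.
#'
#' @param series An [sw_series] (normally already smoothed with
#'   [smooth_series]).
#' @param max_gap Largest bridged wake gap, minutes.
#' @return A tibble of class `sleep_windows`: `onset`, `offset` (POSIXct),
#'   `length_h`, `st` and `wt` (hours), ordered and disjoint. Empty when
#'   the series contains no sleep.
#' @export
build_windows <- function(series, max_gap = 60) {
  el <- sw_epoch_len(series)
  st <- series$state
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  sleep_runs <- which(r$values == "S")
  empty <- tibble::tibble(
    onset = series$time[0], offset = series$time[0],
    length_h = numeric(), st = numeric(), wt = numeric()
  )
  if (length(sleep_runs) == 0) {
    return(structure(empty, class = c("sleep_windows", class(empty))))
  }
  max_gap_epochs <- max_gap * 60 / el

  # group consecutive sleep runs whose separating run is all-wake and short
  group <- integer(length(sleep_runs))
  g <- 1L
  group[1] <- g
  for (i in seq_along(sleep_runs)[-1]) {
    between <- (sleep_runs[i - 1] + 1):(sleep_runs[i] - 1)
    gap_states <- r$values[between]
    gap_len <- sum(r$lengths[between])
    if (all(gap_states == "W") && gap_len <= max_gap_epochs) {
      group[i] <- g
    } else {
      g <- g + 1L
      group[i] <- g
    }
  }

  out <- purrr::map(split(sleep_runs, group), function(runs) {
    i0 <- starts[runs[1]]
    i1 <- ends[runs[length(runs)]]
    n_sleep <- sum(st[i0:i1] == "S")
    n_wake <- sum(st[i0:i1] == "W")
    tibble::tibble(
      onset = series$time[i0],
      offset = series$time[i1] + el,
      length_h = (i1 - i0 + 1) * el / 3600,
      st = n_sleep * el / 3600,
      wt = n_wake * el / 3600
    )
  }) |> purrr::list_rbind()
  out <- out[order(out$onset), ]
  structure(out, class = c("sleep_windows", class(empty)))
}

#' Label windows long or short
#'
#' A window is long when strictly longer than the threshold, short
#' otherwise (a window of exactly the threshold length is short).
#'
#' @param windows A `sleep_windows` tibble.
#' @param threshold Long/short boundary, hours.
#' @return The windows tibble with a `label` column (`"long"`/`"short"`).
#' @export
label_windows <- function(windows, threshold = 3.75) {
  windows$label <- ifelse(windows$length_h > threshold, "long", "short")
  windows
}

#' Per-day sleep metrics
#'
#' Computes, for every noon-to-noon day, ST/WT/length/count of long and
#' short sleep windows (a window belongs to the day containing its onset;
#' windows crossing noon are not split), the sleep percentage (all sleep
#' epochs in the day, inside or outside windows, as % of 24 h), and
#' midawake counts: wake bouts between the day's first window onset and
#' last window offset, long-term when >= 60 min, short-term when < 60 min.
#'
#' @param days Output of [segment_noon_days].
#' @param windows Labelled windows from [label_windows].
#' @param series The [sw_series] the windows were built from.
#' @param midawake_split Long/short midawake boundary, minutes.
#' @return Tibble with one row per day: `day_index`, `st_long`, `wt_long`,
#'   `st_short`, `wt_short`, `n_long`, `n_short`, `len_long`, `len_short`,
#'   `sleep_percentage`, `n_midawake_long`, `n_midawake_short`.
#' @export
daily_metrics <- function(days, windows, series, midawake_split = 60) {
  el <- sw_epoch_len(series)
  purrr::map(seq_len(nrow(days)), function(i) {
    d <- days[i, ]
    in_day <- windows$onset >= d$day_start & windows$onset < d$day_end
    w <- windows[in_day, ]
    long <- w[w$label == "long", ]
    short <- w[w$label == "short", ]
    ep_in_day <- series$time >= d$day_start & series$time < d$day_end
    sleep_h <- sum(series$state[ep_in_day] == "S") * el / 3600

    n_ma_long <- n_ma_short <- 0
    if (nrow(w) > 0) {
      span <- series$time >= min(w$onset) & series$time < max(w$offset)
      r <- rle(series$state[span])
      wake_runs_min <- r$lengths[r$values == "W"] * el / 60
      # runs at the span boundaries cannot occur: span starts/ends on sleep
      n_ma_long <- sum(wake_runs_min >= midawake_split)
      n_ma_short <- sum(wake_runs_min < midawake_split)
    }
    tibble::tibble(
      day_index = d$day_index,
      st_long = sum(long$st), wt_long = sum(long$wt),
      st_short = sum(short$st), wt_short = sum(short$wt),
      n_long = nrow(long), n_short = nrow(short),
      len_long = sum(long$length_h), len_short = sum(short$length_h),
      sleep_percentage = 100 * sleep_h / 24,
      n_midawake_long = n_ma_long, n_midawake_short = n_ma_short
    )
  }) |> purrr::list_rbind()
}

# fixed 21-index registry: 3 general features + MN/SD of 9 daily features
daily_index_fields <- c("phase", "st_long", "wt_long", "st_short", "wt_short",
                        "sleep_percentage", "len_long", "len_short", "n_long")

#' Names of the 21 sleep indexes, in canonical order
#' @return Character vector of length 21.
#' @export
sleep_index_names <- function() {
  c("period", "amplitude", "total_windows",
    paste0(rep(daily_index_fields, each = 2), c("_mn", "_sd")))
}

#' Assemble the 21-index vector for one subject
#'
#' General features (period, amplitude, total window count) are computed
#' once over the whole valid span; the nine daily features (phase, ST/WT
#' long and short, sleep percentage, window lengths and long-window count)
#' contribute their mean (MN) and SD over valid days. SD uses the n-1
#' denominator and is 0 for a single day.
#'
#' @param daily Output of [daily_metrics] restricted to the valid days.
#' @param rhythm Output of [rhythm_summary] on the same span.
#' @param total_windows Total number of sleep windows over the span.
#' @return A one-row tibble with the 21 named index columns of
#'   [sleep_index_names].
#' @export
compute_index_vector <- function(daily, rhythm, total_windows) {
  if (nrow(daily) == 0) stop("no valid days")
  mn_sd <- function(x) {
    c(mean(x), if (length(x) < 2) 0 else stats::sd(x))
  }
  vals <- c(rhythm$period, rhythm$amplitude, total_windows)
  daily$phase <- rhythm$phase_by_day
  for (f in daily_index_fields) vals <- c(vals, mn_sd(daily[[f]]))
  out <- tibble::as_tibble(as.list(stats::setNames(vals, sleep_index_names())))
  out
}
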