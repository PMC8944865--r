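#' Sleep archetype specification
#'
#' Parameters of one simulated sleep phenotype. The simulator is structural:
#' each night's sleep bout is drawn explicitly (onset, duration), then
#' midawake bouts and daytime naps are planted inside/outside it, so the
#' ground truth of every planted event is known exactly.
#'
#' @param name Archetype label carried through to cohort tables.
#' @param sleep_onset_mean Mean sleep onset clock hour (e.g. 23 = 11 PM;
#'   values > 24 denote after-midnight onsets).
#' @param onset_jitter_sd Night-to-night SD of onset, hours.
#' @param sleep_duration_mean,sleep_duration_sd Nightly sleep duration mean
#'   and SD, hours.
#' @param midawake_rate Expected number of within-sleep wake bouts per night
#'   (Poisson).
#' @param midawake_duration Length-2 numeric `(mean, sd)` of short-term
#'   midawake bout duration, minutes (truncated to \[1, 59\] min).
#' @param long_midawake_prob Probability that a planted bout is long-term
#'   (>= 60 min; duration 60 + Exp(mean 15) min).
#' @param nap_prob Probability of a daytime nap per day.
#' @param nap_duration Length-2 numeric `(mean, sd)` of nap duration, minutes.
#' @param circadian_period Intrinsic sleep/wake cycle period in hours
#'   (default 24); onsets drift by `circadian_period - 24` h per day.
#' @param weekday_weekend_shift Additional onset delay (hours) on Friday and
#'   Saturday nights, emulating social jet lag; 0 for regular archetypes.
#' @return A list of class `archetype_spec`.
#' @export
archetype_spec <- function(name,
                           sleep_onset_mean = 23,
                           onset_jitter_sd = 0.5,
                           sleep_duration_mean = 8,
                           sleep_duration_sd = 0.5,
                           midawake_rate = 1,
                           midawake_duration = c(15, 5),
                           long_midawake_prob = 0.1,
                           nap_prob = 0.15,
                           nap_duration = c(40, 15),
                           circadian_period = 24,
                           weekday_weekend_shift = 0) {
  stopifnot(
    is.character(name), length(name) == 1,
    onset_jitter_sd >= 0,
    sleep_duration_mean > 0, sleep_duration_sd >= 0,
    midawake_rate >= 0,
    length(midawake_duration) == 2, all(midawake_duration[1] > 0),
    long_midawake_prob >= 0, long_midawake_prob <= 1,
    nap_prob >= 0, nap_prob <= 1,
    length(nap_duration) == 2, nap_duration[1] > 0,
    circadian_period >= 5, circadian_period <= 35
  )
  structure(
    list(
      name = name,
      sleep_onset_mean = sleep_onset_mean,
      onset_jitter_sd = onset_jitter_sd,
      sleep_duration_mean = sleep_duration_mean,
      sleep_duration_sd = sleep_duration_sd,
      midawake_rate = midawake_rate,
      midawake_duration = midawake_duration,
      long_midawake_prob = long_midawake_prob,
      nap_prob = nap_prob,
      nap_duration = nap_duration,
      circadian_period = circadian_period,
      weekday_weekend_shift = weekday_weekend_shift
    ),
    class = "archetype_spec"
  )
}

#' Built-in archetypes
#'
#' Four contrasting phenotypes used throughout the test suite: a regular
#' sleeper, fragmented short sleep with frequent midawake (insomnia-like), a
#' phase-delayed "night person", and a sleeper with a 25-h sleep/wake cycle.
#'
#' @return Named list of [archetype_spec] objects.
#' @export
archetype_presets <- function() {
  list(
    regular = archetype_spec(
      "regular",
      sleep_onset_mean = 23, onset_jitter_sd = 0.3,
      sleep_duration_mean = 8, sleep_duration_sd = 0.3,
      midawake_rate = 0.5, long_midawake_prob = 0.05, nap_prob = 0.1
    ),
    fragmented_insomnia = archetype_spec(
      "fragmented_insomnia",
      sleep_onset_mean = 23.5, onset_jitter_sd = 0.8,
      sleep_duration_mean = 5, sleep_duration_sd = 1.2,
      midawake_rate = 4, midawake_duration = c(25, 10),
      long_midawake_prob = 0.35, nap_prob = 0.4, nap_duration = c(60, 20)
    ),
    night_person = archetype_spec(
      "night_person",
      sleep_onset_mean = 27.5, onset_jitter_sd = 0.4,
      sleep_duration_mean = 7.5, sleep_duration_sd = 0.4,
      midawake_rate = 0.5, long_midawake_prob = 0.05, nap_prob = 0.15
    ),
    long_period = archetype_spec(
      "long_period",
      sleep_onset_mean = 23, onset_jitter_sd = 0.3,
      sleep_duration_mean = 8, sleep_duration_sd = 0.3,
      midawake_rate = 0.5, long_midawake_prob = 0.05, nap_prob = 0.1,
      circadian_period = 25
    )
  )
}

#' Simulate one subject's sleep/wake series with ground truth
#'
#' Produces a multi-day binary sleep/wake series that starts and ends at
#' noon. Each night carries one intended sleep bout drawn from the archetype;
#' midawake bouts are planted inside the bout and naps during the day. All
#' planted parameters are returned as ground truth.
#'
#' @param archetype An [archetype_spec].
#' @param n_days Number of noon-to-noon days (>= 1).
#' @param epoch_len Epoch length in seconds; must divide 24 h.
#' @param seed Integer seed; identical seeds give identical output.
#' @param start_time Noon POSIXct at which the series starts.
#' @return A list with elements `series` ([sw_series]) and `truth` (list with
#'   per-night onsets/offsets/durations, midawake and nap interval tables,
#'   `period_h`, per-day `phase_h` = hours from each day's starting noon to
#'   mid-sleep, and the archetype label).
#' @export
generate_subject <- function(archetype, n_days, epoch_len = 30, seed = 1,
                             start_time = as.POSIXct("2024-01-01 12:00:00",
                                                     tz = "UTC")) {
  stopifnot(inherits(archetype, "archetype_spec"))
  if (n_days < 1) stop("n_days must be >= 1")
  if (epoch_len <= 0 || 86400 %% epoch_len != 0) {
    stop("epoch_len must divide 24 h")
  }
  a <- archetype
  n_epochs <- as.integer(n_days * 86400 / epoch_len)
  state <- rep("W", n_epochs)

  # weekend nights: onset on Friday/Saturday calendar days gets the shift
  day_dates <- as.Date(start_time) + seq_len(n_days) - 1
  is_weekend_night <- format(day_dates, "%u") %in% c("5", "6")

  eph <- epoch_len / 3600
  to_epoch <- function(h) as.integer(round(h / eph)) # hours after start -> idx

  onsets_h <- offsets_h <- durations_h <- numeric(n_days)
  mids <- list()
  naps <- list()
  with_seed(seed, for (k in seq_len(n_days) - 1L) {
    onset_clock <- a$sleep_onset_mean +
      (a$circadian_period - 24) * k +
      stats::rnorm(1, 0, a$onset_jitter_sd) +
      if (is_weekend_night[k + 1]) a$weekday_weekend_shift else 0
    onset_h <- k * 24 + (onset_clock - 12) # hours after starting noon
    dur_h <- max(0.5, stats::rnorm(1, a$sleep_duration_mean,
                                   a$sleep_duration_sd))
    offset_h <- onset_h + dur_h
    onsets_h[k + 1] <- onset_h
    offsets_h[k + 1] <- offset_h
    durations_h[k + 1] <- dur_h

    i0 <- max(0L, to_epoch(onset_h))
    i1 <- min(n_epochs, to_epoch(offset_h))
    if (i1 > i0) state[(i0 + 1):i1] <- "S"

    # planted midawake bouts inside the sleep bout
    n_ma <- stats::rpois(1, a$midawake_rate)
    for (j in seq_len(n_ma)) {
      long <- stats::runif(1) < a$long_midawake_prob
      dur_min <- if (long) {
        60 + stats::rexp(1, rate = 1 / 15)
      } else {
        min(59, max(1, stats::rnorm(1, a$midawake_duration[1],
                                    a$midawake_duration[2])))
      }
      d_h <- dur_min / 60
      slack <- dur_h - d_h - 0.5
      if (slack <= 0) next
      s_h <- onset_h + 0.25 + stats::runif(1) * slack
      j0 <- max(0L, to_epoch(s_h))
      j1 <- min(n_epochs, to_epoch(s_h + d_h))
      if (j1 > j0) {
        state[(j0 + 1):j1] <- "W"
        mids[[length(mids) + 1]] <-
          c(night = k, start_h = s_h, end_h = s_h + d_h, long = as.numeric(long))
      }
    }

    # optional daytime nap (early afternoon of day k)
    if (stats::runif(1) < a$nap_prob) {
      nap_min <- max(10, stats::rnorm(1, a$nap_duration[1], a$nap_duration[2]))
      s_h <- k * 24 + 1 + stats::runif(1) * 5 # between 13:00 and 18:00
      j0 <- max(0L, to_epoch(s_h))
      j1 <- min(n_epochs, to_epoch(s_h + nap_min / 60))
      if (j1 > j0) {
        state[(j0 + 1):j1] <- "S"
        naps[[length(naps) + 1]] <- c(day = k, start_h = s_h,
                                      end_h = s_h + nap_min / 60)
      }
    }
  })

  series <- sw_series(state, start_time = start_time, epoch_len = epoch_len)
  truth <- list(
    archetype = a$name,
    period_h = a$circadian_period,
    onsets_h = onsets_h,
    offsets_h = offsets_h,
    durations_h = durations_h,
    # subjective midnight proxy: mid-sleep, hours after that day's noon
    phase_h = ((onsets_h + durations_h / 2) %% 24),
    midawakes = if (length(mids)) {
      tibble::as_tibble(do.call(rbind, mids))
    } else {
      tibble::tibble(night = numeric(), start_h = numeric(),
                     end_h = numeric(), long = numeric())
    },
    naps = if (length(naps)) {
      tibble::as_tibble(do.call(rbind, naps))
    } else {
      tibble::tibble(day = numeric(), start_h = numeric(), end_h = numeric())
    }
  )
  list(series = series, truth = truth)
}

#' Simulate a labeled cohort
#'
#' @param specs List of `list(archetype = <archetype_spec>, n = <count>)`
#'   entries.
#' @param n_days Days per subject.
#' @param seed Master seed. Subject `j` of archetype `a` uses the seed
#'   `seed + name_offset(a) + j`, where `name_offset` depends only on the
#'   archetype name; cohorts are therefore reproducible, extensible subject
#'   by subject, and invariant to the order of spec entries.
#' @param epoch_len Epoch length, seconds.
#' @return A tibble with one row per subject: `subject_id`, `archetype`,
#'   list-columns `series` and `truth`.
#' @export
generate_cohort <- function(specs, n_days = 6, seed = 1, epoch_len = 30) {
  if (length(specs) == 0) stop("empty archetype spec list")
  for (s in specs) {
    if (is.null(s$archetype) || is.null(s$n) || s$n < 1) {
      stop("each spec entry needs an archetype and a count >= 1")
    }
  }
  arche <- purrr::list_flatten(purrr::map(specs, function(s) {
    rep(list(s$archetype), s$n)
  }))
  labels <- purrr::map_chr(arche, "name")
  within_idx <- stats::ave(seq_along(labels), labels, FUN = seq_along)
  subj <- purrr::map(seq_along(arche), function(i) {
    generate_subject(
      arche[[i]], n_days = n_days, epoch_len = epoch_len,
      seed = seed + archetype_seed_offset(labels[i]) + within_idx[i]
    )
  })
  tibble::tibble(
    subject_id = sprintf("s%04d", seq_along(subj)),
    archetype = labels,
    series = purrr::map(subj, "series"),
    truth = purrr::map(subj, "truth")
  )
}

# Deterministic small offset from an archetype name so per-subject seeds
# depend on (master seed, archetype, within-archetype index) only.
archetype_seed_offset <- function(name) {
  codes <- utf8ToInt(name)
  sum(codes * seq_along(codes)) %% 100003L * 1000L
}

#' Synthesize a triaxial acceleration trace for a sleep/wake series
#'
#' Emits gravity-baseline Gaussian noise whose SD depends on the epoch state
#' (wake noisier than sleep), sporadic 1-10 s high-amplitude movement bursts
#' during wake (Poisson arrivals), and near-constant signal inside declared
#' nonwear spans. This reproduces the qualitative accelerometry signature
#' that sleep shows lower jerk and power-spectrum amplitude than wake.
#'
#' @param series An [sw_series].
#' @param sampling_hz Sampling rate, Hz.
#' @param noise_sd_sleep,noise_sd_wake Per-axis Gaussian noise SD in g during
#'   sleep and wake; `noise_sd_wake > noise_sd_sleep >= 0`.
#' @param burst_rate_hz Poisson arrival rate of wake movement bursts (per
#'   second of wake).
#' @param nonwear_spans Optional list of `c(start_h, end_h)` offsets (hours
#'   from series start) during which the device is off-wrist; samples there
#'   are baseline plus 1 mg noise.
#' @param seed Integer seed.
#' @return A list of class `accel_record`: `start_time`, `sampling_hz`, and
#'   numeric vectors `x`, `y`, `z` in g.
#' @export
synthesize_acceleration <- function(series, sampling_hz = 10,
                                    noise_sd_sleep = 0.015,
                                    noise_sd_wake = 0.06,
                                    burst_rate_hz = 0.02,
                                    nonwear_spans = NULL, seed = 1) {
  if (sampling_hz <= 0) stop("sampling_hz must be positive")
  if (!(noise_sd_wake > noise_sd_sleep && noise_sd_sleep >= 0)) {
    stop("require noise_sd_wake > noise_sd_sleep >= 0")
  }
  if (!is.null(nonwear_spans) && length(nonwear_spans) > 1) {
    ss <- t(sapply(nonwear_spans, identity))
    ss <- ss[order(ss[, 1]), , drop = FALSE]
    if (any(ss[-1, 1] < ss[-nrow(ss), 2])) stop("overlapping nonwear spans")
  }
  el <- sw_epoch_len(series)
  n_ep <- nrow(series)
  per_ep <- as.integer(round(el * sampling_hz))
  n <- n_ep * per_ep
  sd_ep <- ifelse(series$state == "S", noise_sd_sleep,
                  ifelse(series$state == "W", noise_sd_wake, 0.001))
  sd_samp <- rep(sd_ep, each = per_ep)

  base <- c(x = 0, y = 0, z = 1) # gravity along z at rest
  with_seed(seed, {
  axes <- lapply(c(x = 1, y = 2, z = 3), function(i) {
    base[i] + stats::rnorm(n, 0, sd_samp)
  })

  # movement bursts during wake: Poisson arrivals, 1-10 s, large amplitude
  wake_sec <- sum(series$state == "W") * el
  n_burst <- stats::rpois(1, burst_rate_hz * wake_sec)
  if (n_burst > 0) {
    wake_idx <- which(series$state == "W")
    for (b in seq_len(n_burst)) {
      ep <- sample(wake_idx, 1)
      s0 <- (ep - 1) * per_ep + sample.int(per_ep, 1)
      len <- as.integer(round(stats::runif(1, 1, 10) * sampling_hz))
      idx <- s0:min(n, s0 + len - 1)
      f <- stats::runif(1, 0.5, 3) # burst oscillation frequency, Hz
      amp <- stats::runif(1, 0.2, 1.0)
      wobble <- amp * sin(2 * pi * f * seq_along(idx) / sampling_hz)
      ax <- sample(1:3, 1)
      axes[[ax]][idx] <- axes[[ax]][idx] + wobble
    }
  }

  if (!is.null(nonwear_spans)) {
    for (sp in nonwear_spans) {
      i0 <- max(1L, as.integer(floor(sp[1] * 3600 * sampling_hz)) + 1L)
      i1 <- min(n, as.integer(ceiling(sp[2] * 3600 * sampling_hz)))
      if (i1 >= i0) {
        m <- i1 - i0 + 1
        for (ax in 1:3) {
          axes[[ax]][i0:i1] <- base[ax] + stats::rnorm(m, 0, 0.001)
        }
      }
    }
  }
  })

  structure(
    list(start_time = series$time[1], sampling_hz = sampling_hz,
         x = axes[[1]], y = axes[[2]], z = axes[[3]]),
    class = "accel_record"
  )
}

#' Corrupt a clean series with short spurious runs
#'
#' Inserts short wake runs into sleep (and sleep runs into wake) to emulate
#' classification noise; used to calibrate the bout-smoothing threshold. The
#' clean input is the ground truth.
#'
#' @param series Clean [sw_series].
#' @param flip_rate Probability that any epoch seeds a spurious run.
#' @param max_flip_run Maximum inserted run length, epochs (>= 1); lengths
#'   are drawn uniformly on `1:max_flip_run`.
#' @param seed Integer seed.
#' @return List with `series` (corrupted) and `truth` (the clean series).
#' @export
generate_pseudo_flip_series <- function(series, flip_rate, max_flip_run = 10,
                                        seed = 1) {
  if (flip_rate < 0 || flip_rate > 1) stop("flip_rate must be in [0, 1]")
  if (max_flip_run < 1) stop("max_flip_run must be >= 1")
  st <- series$state
  n <- length(st)
  flip_to <- c(S = "W", W = "S")
  out <- st
  with_seed(seed, {
    starts <- which(st != "M" & stats::runif(n) < flip_rate)
    for (i in starts) {
      len <- if (max_flip_run == 1) 1L else sample.int(max_flip_run, 1)
      idx <- i:min(n, i + len - 1L)
      idx <- idx[st[idx] == st[i]] # stay within the original run / skip M
      out[idx] <- flip_to[[st[i]]]
    }
  })
  corrupted <- new_sw_series(
    tibble::tibble(time = series$time, state = out), sw_epoch_len(series)
  )
  list(series = corrupted, truth = series)
}
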