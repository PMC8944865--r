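# Shared fixtures and independent brute-force oracles.
# Oracles deliberately use naive epoch-by-epoch scans so they share no code
# with the package implementations they check.

NOON <- as.POSIXct("2024-01-01 12:00:00", tz = "UTC")

# build a series from run-length pairs: mk_series("S", 10, "W", 5, ...)
mk_series <- function(..., epoch_len = 30, start_time = NOON) {
  args <- list(...)
  states <- character()
  for (i in seq(1, length(args), by = 2)) {
    states <- c(states, rep(args[[i]], args[[i + 1]]))
  }
  sw_series(states, start_time = start_time, epoch_len = epoch_len)
}

random_states <- function(n, p = c(S = 0.45, W = 0.45, M = 0.1)) {
  sample(names(p), n, replace = TRUE, prob = p)
}

# --- smoothing oracle: literal two-pass scan over epoch indices -------------
oracle_smooth <- function(states, min_epochs) {
  flip_pass <- function(st, from, to) {
    n <- length(st)
    out <- st
    i <- 1
    while (i <= n) {
      if (st[i] != from) { i <- i + 1; next }
      j <- i
      while (j < n && st[j + 1] == from) j <- j + 1
      left <- if (i == 1) NA else st[i - 1]
      right <- if (j == n) NA else st[j + 1]
      len <- j - i + 1
      left_ok <- is.na(left) || left == to
      right_ok <- is.na(right) || right == to
      has_to <- identical(left, to) || identical(right, to)
      if (len < min_epochs && left_ok && right_ok && has_to) {
        out[i:j] <- to
      }
      i <- j + 1
    }
    out
  }
  st <- flip_pass(states, "W", "S")
  flip_pass(st, "S", "W")
}

# --- window-merging oracle: iterated pairwise interval merge ----------------
# returns a data frame of (start_idx, end_idx) over epochs, 1-based inclusive
oracle_windows <- function(states, max_gap_epochs) {
  n <- length(states)
  runs <- list()
  i <- 1
  while (i <= n) {
    if (states[i] == "S") {
      j <- i
      while (j < n && states[j + 1] == "S") j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(runs) == 0) {
    return(data.frame(start_idx = integer(), end_idx = integer()))
  }
  merged <- TRUE
  while (merged) {
    merged <- FALSE
    k <- 1
    while (k < length(runs)) {
      gap_idx <- (runs[[k]][2] + 1):(runs[[k + 1]][1] - 1)
      gap_states <- states[gap_idx]
      if (length(gap_idx) <= max_gap_epochs && all(gap_states == "W")) {
        runs[[k]] <- c(runs[[k]][1], runs[[k + 1]][2])
        runs[[k + 1]] <- NULL
        merged <- TRUE
      } else {
        k <- k + 1
      }
    }
  }
  data.frame(
    start_idx = vapply(runs, function(r) as.integer(r[1]), integer(1)),
    end_idx = vapply(runs, function(r) as.integer(r[2]), integer(1))
  )
}

# --- ARI from the contingency-table formula ---------------------------------
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# --- direct Qp evaluation (plain loops) -------------------------------------
oracle_qp <- function(x, k) {
  n <- length(x)
  gm <- mean(x)
  m_h <- numeric(k)
  cnt <- integer(k)
  for (i in seq_len(n)) {
    h <- ((i - 1) %% k) + 1
    m_h[h] <- m_h[h] + x[i]
    cnt[h] <- cnt[h] + 1
  }
  m_h <- m_h / cnt
  n * k * sum((m_h - gm)^2) / sum((x - gm)^2)
}

# circular difference in hours on a 24-h clock
circ_diff <- function(a, b) {
  d <- abs(a - b) %% 24
  pmin(d, 24 - d)
}

# a noiseless square-wave series with planted period (in 10-min bins)
square_wave_series <- function(period_bins, n_days = 6, duty = 1 / 3,
                               epoch_len = 30) {
  per_bin <- 600 / epoch_len
  low_bins <- round(period_bins * duty)
  cycle <- rep(c("W", "S"), times = c(period_bins - low_bins, low_bins))
  states <- rep(rep(cycle, each = per_bin),
                length.out = n_days * 86400 / epoch_len)
  sw_series(states, epoch_len = epoch_len)
}

# binned activity built directly (bypasses bin_wake)
mk_binned <- function(values, bin_len = 10) {
  out <- tibble::tibble(
    bin_start = NOON + (seq_along(values) - 1) * bin_len * 60,
    wake_min = values,
    coverage_min = bin_len
  )
  attr(out, "bin_len") <- bin_len
  class(out) <- c("binned_activity", class(tibble::tibble()))
  out
}

# quiet archetype: fully deterministic sleep 23:00-07:00
quiet_archetype <- function(...) {
  archetype_spec("quiet", sleep_onset_mean = 23, onset_jitter_sd = 0,
                 sleep_duration_mean = 8, sleep_duration_sd = 0,
                 midawake_rate = 0, nap_prob = 0, long_midawake_prob = 0,
                 ...)
}
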