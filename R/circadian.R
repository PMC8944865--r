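#' Bin wake amount per fixed interval
#'
#' Converts an epoch series to wake minutes per bin (default 10-minute
#' bins), the input of both the chi-square periodogram and the CV
#' amplitude. Missing epochs contribute zero wake; per-bin coverage of
#' non-missing time is returned alongside.
#'
#' @param series An [sw_series].
#' @param bin_len Bin length in minutes; must be a multiple of the epoch
#'   length.
#' @return A tibble of class `binned_activity`: `bin_start`, `wake_min`,
#'   `coverage_min`; attribute `bin_len`.
#' @export
bin_wake <- function(series, bin_len = 10) {
  el <- sw_epoch_len(series)
  per_bin <- bin_len * 60 / el
  if (abs(per_bin - round(per_bin)) > 1e-9) {
    stop("bin_len must be a multiple of the epoch length")
  }
  per_bin <- as.integer(round(per_bin))
  n_bins <- nrow(series) %/% per_bin
  idx <- rep(seq_len(n_bins), each = per_bin)
  st <- series$state[seq_len(n_bins * per_bin)]
  wake <- tapply(st == "W", idx, sum) * el / 60
  cov <- tapply(st != "M", idx, sum) * el / 60
  out <- tibble::tibble(
    bin_start = series$time[1] + (seq_len(n_bins) - 1) * per_bin * el,
    wake_min = as.numeric(wake),
    coverage_min = as.numeric(cov)
  )
  attr(out, "bin_len") <- bin_len
  class(out) <- c("binned_activity", class(tibble::tibble()))
  out
}

#' Chi-square periodogram
#'
#' For every candidate period that is an integer number of bins between
#' `p_min` and `p_max` hours, the binned series is folded into that many
#' columns and the statistic
#' \deqn{Q_p = \frac{N K \sum_h (M_h - \bar M)^2}{\sum_i (x_i - \bar M)^2}}
#' is computed, where the \eqn{M_h} are the K column means and \eqn{\bar M}
#' the grand mean. The significance curve is the chi-square
#' \eqn{1-\alpha} quantile with \eqn{K - 1} degrees of freedom; the
#' estimated period maximises \eqn{Q_p - sig(P)} (ties to the smallest
#' period).
#'
#' @param binned A `binned_activity` from [bin_wake].
#' @param p_min,p_max Candidate period range, hours.
#' @param alpha Significance level of the reference curve.
#' @return An object of class `sw_periodogram`: tibble columns `period_h`,
#'   `qp`, `sig`, with attributes `best_period` and `alpha`.
#' @export
chi_square_periodogram <- function(binned, p_min = 5, p_max = 35,
                                   alpha = 0.01) {
  bin_len <- attr(binned, "bin_len")
  x <- binned$wake_min
  n <- length(x)
  gm <- mean(x)
  denom <- sum((x - gm)^2)
  if (denom == 0) stop("zero-variance series: periodogram undefined")
  bins_per_h <- 60 / bin_len
  k_min <- as.integer(ceiling(p_min * bins_per_h))
  k_max <- as.integer(floor(p_max * bins_per_h))
  if (k_max > n %/% 2) k_max <- n %/% 2
  if (k_min > k_max) stop("series too short for the requested period range")
  ks <- k_min:k_max
  qp <- vapply(ks, function(k) {
    # fold into k columns via a padded matrix (pad contributes no sum)
    n_rows <- ceiling(n / k)
    xp <- c(x, rep(0, n_rows * k - n))
    cnt <- c(rep(n_rows, n %% k), rep(n_rows - (n %% k > 0), k - n %% k))
    if (n %% k == 0) cnt <- rep(n_rows, k)
    m_h <- rowSums(matrix(xp, nrow = k)) / cnt
    n * k * sum((m_h - gm)^2) / denom
  }, numeric(1))
  sig <- stats::qchisq(1 - alpha, df = ks - 1)
  period_h <- ks / bins_per_h
  best <- period_h[which.max(qp - sig)] # earliest maximum on ties
  out <- tibble::tibble(period_h = period_h, qp = qp, sig = sig)
  attr(out, "best_period") <- best
  attr(out, "alpha") <- alpha
  class(out) <- c("sw_periodogram", class(tibble::tibble()))
  out
}

#' @export
tidy.sw_periodogram <- function(x, ...) {
  tibble::tibble(period_h = x$period_h, qp = x$qp, sig = x$sig,
                 excess = x$qp - x$sig)
}

#' @export
glance.sw_periodogram <- function(x, ...) {
  tibble::tibble(best_period = attr(x, "best_period"),
                 alpha = attr(x, "alpha"),
                 max_excess = max(x$qp - x$sig))
}

#' @export
autoplot.sw_periodogram <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period_h)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$qp), colour = "black") +
    ggplot2::geom_line(ggplot2::aes(y = .data$sig), colour = "grey60") +
    ggplot2::geom_vline(xintercept = attr(object, "best_period"),
                        linetype = "dashed", colour = "deeppink") +
    ggplot2::labs(x = "period (h)", y = "Qp") +
    ggplot2::theme_minimal()
}

#' Coefficient-of-variation amplitude
#'
#' Amplitude of the circadian output to sleep, defined as the population SD
#' divided by the mean of wake minutes per bin over the whole record. A
#' 24-h square wave over \{0, 10\} minutes with duty 1/3 has amplitude
#' sqrt(2); one over \{3, 7\} has 4*sqrt(2)/13.
#'
#' @param binned A `binned_activity`.
#' @return Unitless amplitude.
#' @export
amplitude_cv <- function(binned) {
  x <- binned$wake_min
  m <- mean(x)
  if (m <= 0) stop("zero-mean series: amplitude undefined")
  sd_pop(x) / m
}

#' Normalized van der Pol limit-cycle waveform
#'
#' Integrates the van der Pol oscillator
#' \eqn{\ddot x - \mu (1 - x^2)\dot x + \omega^2 x = 0} to its limit cycle,
#' rescales time so one cycle lasts `period` hours, min-max normalizes the
#' waveform to \[0, 1\] and rotates it so the minimum sits at phase 0. For
#' small \eqn{\mu} the shape approaches `(1 - cos)/2`; larger \eqn{\mu}
#' gives the relaxation shape used to model the circadian sleep/wake
#' alternation.
#'
#' @param mu Damping parameter (> 0).
#' @param period Cycle length after rescaling, hours.
#' @param resolution Sampling resolution of the returned waveform, minutes.
#' @return Tibble of class `vdp_waveform`: `t_h` in `[0, period)` and
#'   `value` in `[0, 1]`; attributes `mu`, `period`.
#' @export
vdp_limit_cycle <- function(mu = 1.0, period = 24, resolution = 1) {
  if (mu <= 0) stop("mu must be positive")
  deriv <- function(t, y, parms) {
    list(c(y[2], parms$mu * (1 - y[1]^2) * y[2] - y[1]))
  }
  # natural time units: omega = 1 (period ~ 2*pi); rescaled afterwards
  t_transient <- 40 * 2 * pi
  dt <- 2 * pi / 2000
  sol <- deSolve::ode(
    y = c(x = 2, v = 0), times = c(0, t_transient), func = deriv,
    parms = list(mu = mu), method = "lsoda", rtol = 1e-10, atol = 1e-10,
    maxsteps = 500000
  )
  y0 <- sol[nrow(sol), c("x", "v")]
  times <- seq(0, 6 * 2 * pi, by = dt)
  sol <- deSolve::ode(y = y0, times = times, func = deriv,
                      parms = list(mu = mu), method = "lsoda",
                      rtol = 1e-10, atol = 1e-10, maxsteps = 500000)
  xs <- sol[, "x"]
  # successive interior minima delimit one full cycle
  is_min <- which(diff(sign(diff(xs))) > 0) + 1L
  if (length(is_min) < 2) stop("limit cycle not reached within integration cap")
  i0 <- is_min[length(is_min) - 1]
  i1 <- is_min[length(is_min)]
  cyc_t <- times[i0:i1] - times[i0]
  cyc_x <- xs[i0:i1]
  cyc_x[length(cyc_x)] <- cyc_x[1] # close the cycle for periodic spline
  cycle_len <- cyc_t[length(cyc_t)]
  n_out <- as.integer(round(period * 60 / resolution))
  t_out <- seq(0, period, length.out = n_out + 1)[seq_len(n_out)]
  v <- stats::spline(cyc_t / cycle_len * period, cyc_x, xout = t_out,
                     method = "periodic")$y
  v <- (v - min(v)) / (max(v) - min(v))
  # rotate so the sampled minimum sits exactly at t = 0
  shift <- which.min(v) - 1L
  if (shift > 0) v <- c(v[(shift + 1):n_out], v[seq_len(shift)])
  out <- tibble::tibble(t_h = t_out, value = v)
  attr(out, "mu") <- mu
  attr(out, "period") <- period
  class(out) <- c("vdp_waveform", class(tibble::tibble()))
  out
}

# memoized default waveform (mu = 1, 24 h, 1 min)
.sleepscape_cache <- new.env(parent = emptyenv())

default_waveform <- function(mu = 1.0, period = 24, resolution = 1) {
  key <- paste(mu, period, resolution, sep = "|")
  if (is.null(.sleepscape_cache[[key]])) {
    .sleepscape_cache[[key]] <- vdp_limit_cycle(mu, period, resolution)
  }
  .sleepscape_cache[[key]]
}

#' Fit circadian phase to one noon-to-noon day
#'
#' Encodes the day's epochs as wake = 1, sleep = 0, missing = 0.5, then
#' grid-searches the circular shift of the limit-cycle waveform minimising
#' the sum of squared errors. The phase is the elapsed time from the last
#' noon preceding the fitted minimum to the minimum itself, in (0, 24\]
#' hours; a minimum at midnight gives phase 12. Ties in SSE resolve to the
#' smallest shift.
#'
#' @param day_series An [sw_series] spanning exactly one noon-to-noon day.
#' @param waveform A `vdp_waveform` (default: mu = 1, 24 h).
#' @param grid_min Shift grid resolution, minutes (must be a multiple of
#'   the epoch length for the fast path).
#' @param min_coverage Minimum fraction of non-missing epochs required.
#' @return A list of class `phase_fit`: `phase` (hours), `shift_h`, `sse`,
#'   `mu`.
#' @export
fit_phase <- function(day_series, waveform = NULL, grid_min = 1,
                      min_coverage = 0.5) {
  if (is.null(waveform)) waveform <- default_waveform()
  st <- day_series$state
  if (mean(st != "M") < min_coverage) {
    stop("insufficient non-missing coverage for phase fitting")
  }
  el <- sw_epoch_len(day_series)
  n <- length(st)
  e <- ifelse(st == "W", 1, ifelse(st == "S", 0, 0.5))
  period <- attr(waveform, "period") %||% 24

  # waveform sampled on the epoch grid (epoch centres), minimum at t = 0
  t_ep <- ((seq_len(n) - 0.5) * el / 3600) %% period
  w0 <- stats::approx(c(waveform$t_h, period),
                      c(waveform$value, waveform$value[1]),
                      xout = t_ep)$y

  # SSE over all circular epoch shifts via FFT cross-correlation
  # shifted waveform w_tau(t) = w0(t - tau); sum w_tau^2 is shift-invariant
  cc <- Re(stats::fft(stats::fft(e) * Conj(stats::fft(w0)), inverse = TRUE)) / n
  # cc[tau+1] = sum_t e[t] * w0[t - tau] (circular)
  sse <- sum(w0^2) + sum(e^2) - 2 * cc

  shift_epochs <- round(grid_min * 60 / el)
  if (shift_epochs < 1) shift_epochs <- 1
  cand <- seq(1, n, by = shift_epochs)
  best <- cand[which.min(sse[cand])]
  tau_h <- (best - 1) * el / 3600
  phase <- tau_h %% 24
  if (phase == 0) phase <- 24
  structure(
    list(phase = phase, shift_h = tau_h, sse = sse[best],
         mu = attr(waveform, "mu") %||% NA_real_),
    class = "phase_fit"
  )
}

#' @export
tidy.phase_fit <- function(x, ...) {
  tibble::tibble(phase = x$phase, shift_h = x$shift_h, sse = x$sse,
                 mu = x$mu)
}

#' Rhythm-related index summary for one subject
#'
#' Period (chi-square periodogram) and amplitude (CV) are computed once on
#' the whole selected span; phase is fitted per valid day and summarised by
#' its (naive, non-circular) mean and SD.
#'
#' @param series An [sw_series] covering the selected span.
#' @param days Valid-day rows from [segment_noon_days] (already filtered to
#'   the selected span).
#' @param bin_len Bin length for the periodogram/amplitude, minutes.
#' @param p_min,p_max,alpha Periodogram settings.
#' @param mu Van der Pol damping for phase fitting.
#' @param grid_min Phase shift grid, minutes.
#' @return A list: `period`, `amplitude`, `phase_mn`, `phase_sd`,
#'   `phase_by_day`, and the full `periodogram` object.
#' @export
rhythm_summary <- function(series, days, bin_len = 10, p_min = 5, p_max = 35,
                           alpha = 0.01, mu = 1.0, grid_min = 1) {
  binned <- bin_wake(series, bin_len)
  pg <- chi_square_periodogram(binned, p_min, p_max, alpha)
  amp <- amplitude_cv(binned)
  wf <- default_waveform(mu = mu)
  phases <- purrr::map_dbl(seq_len(nrow(days)), function(i) {
    d <- days[i, ]
    sub <- window_slice(series, d$day_start, d$day_end)
    fit_phase(sub, wf, grid_min = grid_min)$phase
  })
  list(
    period = attr(pg, "best_period"),
    amplitude = amp,
    phase_mn = mean(phases),
    phase_sd = if (length(phases) < 2) 0 else stats::sd(phases),
    phase_by_day = phases,
    periodogram = pg
  )
}
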