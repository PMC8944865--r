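#' Jerk of an acceleration record
#'
#' Jerk is the first difference of acceleration scaled by the sampling rate,
#' `jerk[i] = (a[i+1] - a[i]) * hz`, per axis. Movement shows up as
#' high-amplitude jerk, while the gravity component (and any constant offset)
#' cancels, which is what makes jerk a robust wake signature.
#'
#' @param record An `accel_record`.
#' @return A list of class `jerk_record`: `start_time`, `sampling_hz`,
#'   vectors `x`, `y`, `z` (g/s), each of length `n - 1`.
#' @export
compute_jerk <- function(record) {
  if (length(record$x) < 2) stop("need at least 2 samples")
  hz <- record$sampling_hz
  structure(
    list(start_time = record$start_time, sampling_hz = hz,
         x = diff(record$x) * hz, y = diff(record$y) * hz,
         z = diff(record$z) * hz),
    class = "jerk_record"
  )
}

#' Per-epoch jerk power-spectrum features
#'
#' Splits each axis's jerk into fixed-length epochs, computes the
#' rectangular-window periodogram per epoch, and integrates power into
#' `n_bands` log-spaced frequency bands from 0.1 Hz to Nyquist. A per-axis
#' total-power column (the epoch variance; Parseval) is appended, giving
#' `3 * (n_bands + 1)` features per epoch.
#'
#' @param jerk A `jerk_record` from [compute_jerk].
#' @param epoch_len Epoch length, seconds.
#' @param n_bands Number of log-spaced bands.
#' @param f_min Lower edge of the first band, Hz.
#' @return A tibble (class `epoch_features`): `time` plus feature columns
#'   `{x,y,z}_band{1..n_bands}` and `{x,y,z}_total`.
#' @export
epoch_features <- function(jerk, epoch_len = 30, n_bands = 8, f_min = 0.1) {
  hz <- jerk$sampling_hz
  per_ep <- as.integer(round(epoch_len * hz))
  if (per_ep < 2 * n_bands) stop("epoch too short for requested band count")
  nyq <- hz / 2
  if (f_min >= nyq) stop("f_min must be below Nyquist")
  edges <- exp(seq(log(f_min), log(nyq), length.out = n_bands + 1))

  n_ep <- length(jerk$x) %/% per_ep
  if (n_ep < 1) stop("record shorter than one epoch")
  freqs <- (seq_len(per_ep %/% 2)) * hz / per_ep # positive frequencies
  band_of <- findInterval(freqs, edges, rightmost.closed = TRUE)

  feat_axis <- function(v) {
    m <- matrix(v[seq_len(n_ep * per_ep)], nrow = per_ep)
    m <- sweep(m, 2, colMeans(m)) # remove epoch DC
    sp <- stats::mvfft(m)
    # one-sided power so that the sum over positive freqs equals the variance
    p <- Mod(sp[2:(per_ep %/% 2 + 1), , drop = FALSE])^2 / per_ep^2
    if (per_ep %% 2 == 0) {
      p[-nrow(p), ] <- 2 * p[-nrow(p), ]
    } else {
      p <- 2 * p
    }
    total <- colSums(p)
    bands <- vapply(seq_len(n_bands), function(b) {
      rows <- which(band_of == b)
      if (length(rows) == 0) rep(0, n_ep) else colSums(p[rows, , drop = FALSE])
    }, numeric(n_ep))
    cbind(matrix(bands, nrow = n_ep), total)
  }

  fx <- feat_axis(jerk$x)
  fy <- feat_axis(jerk$y)
  fz <- feat_axis(jerk$z)
  nm <- function(ax) c(paste0(ax, "_band", seq_len(n_bands)),
                       paste0(ax, "_total"))
  out <- cbind(fx, fy, fz)
  colnames(out) <- c(nm("x"), nm("y"), nm("z"))
  res <- tibble::as_tibble(out)
  res <- tibble::add_column(
    res, time = jerk$start_time + (seq_len(n_ep) - 1) * epoch_len,
    .before = 1
  )
  attr(res, "epoch_len") <- epoch_len
  class(res) <- c("epoch_features", class(tibble::tibble()))
  res
}

feature_matrix <- function(features) {
  as.matrix(features[, setdiff(names(features), "time")])
}

#' Train the gradient-boosted sleep/wake classifier
#'
#' Fits an XGBoost tree model on epoch features with binary sleep/wake
#' labels. The model is scored on a held-out fraction by the training
#' objective accuracy + F measure (sleep positive), which is the criterion
#' used to tune the pipeline's classifier.
#'
#' @param features An `epoch_features` tibble (or any data frame whose
#'   non-`time` columns are numeric features).
#' @param labels Character/factor vector over `"S"`/`"W"` (or logical,
#'   TRUE = sleep), one per feature row.
#' @param params List of XGBoost hyperparameters; defaults: `max_depth` 4,
#'   `nrounds` 200, `eta` 0.1.
#' @param holdout Fraction of epochs held out for the reported objective.
#' @param seed Integer seed (model and split are deterministic given it).
#' @return A list of class `sleep_classifier`: the fitted booster, feature
#'   names, and held-out `accuracy`, `f_measure`, `objective`.
#' @export
train_classifier <- function(features, labels,
                             params = list(max_depth = 4, nrounds = 200,
                                           eta = 0.1),
                             holdout = 0.25, seed = 1) {
  X <- feature_matrix(features)
  y <- if (is.logical(labels)) labels else as.character(labels) == "S"
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  if (length(unique(y)) < 2) stop("both classes must be present")
  n <- nrow(X)
  with_seed(seed, {
    test_idx <- sample.int(n, max(1, round(holdout * n)))
    dtrain <- xgboost::xgb.DMatrix(X[-test_idx, , drop = FALSE],
                                   label = as.numeric(y[-test_idx]))
    booster <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth %||% 4,
                    eta = params$eta %||% 0.1,
                    nthread = 1, seed = seed),
      data = dtrain,
      nrounds = params$nrounds %||% 200,
      verbose = 0
    )
    pred <- stats::predict(booster,
                           xgboost::xgb.DMatrix(X[test_idx, , drop = FALSE]))
    ph <- pred > 0.5
    yt <- y[test_idx]
    acc <- mean(ph == yt)
    tp <- sum(ph & yt); fp <- sum(ph & !yt); fn <- sum(!ph & yt)
    f <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    structure(
      list(booster = booster, feature_names = colnames(X),
           accuracy = acc, f_measure = f, objective = acc + f,
           params = params, seed = seed),
      class = "sleep_classifier"
    )
  })
}

#' @export
glance.sleep_classifier <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, f_measure = x$f_measure,
                 objective = x$objective)
}

#' @export
tidy.sleep_classifier <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  tibble::tibble(feature = imp$Feature, gain = imp$Gain)
}

#' Classify epochs into a sleep/wake series
#'
#' Applies a trained classifier to epoch features; epochs flagged by the
#' nonwear mask are set to missing regardless of the model output.
#'
#' @param model A `sleep_classifier`.
#' @param features An `epoch_features` tibble.
#' @param mask Optional `nonwear_mask` aligned with the feature rows.
#' @return An [sw_series].
#' @export
classify <- function(model, features, mask = NULL) {
  X <- feature_matrix(features)[, model$feature_names, drop = FALSE]
  p <- stats::predict(model$booster, xgboost::xgb.DMatrix(X))
  st <- ifelse(p > 0.5, "S", "W")
  if (!is.null(mask)) {
    if (length(mask) != length(st)) {
      stop("mask grid does not align with feature grid")
    }
    st[as.logical(mask)] <- "M"
  }
  new_sw_series(tibble::tibble(time = features$time, state = st),
                attr(features, "epoch_len") %||% 30)
}

#' Smooth short bouts in a sleep/wake series
#'
#' Two fixed passes over the run-length encoding: (1) every maximal wake run
#' strictly shorter than `min_bout` whose neighbours are sleep (a series
#' boundary plus one sleep neighbour also qualifies) is flipped to sleep;
#' (2) the same rule is then applied to short sleep runs, flipping them to
#' wake. Missing epochs break runs and are never flipped.
#'
#' @param series An [sw_series].
#' @param min_bout Minimum bout length, minutes; runs of `min_bout` or more
#'   are always preserved (the threshold is strict).
#' @return The smoothed [sw_series].
#' @export
smooth_series <- function(series, min_bout = 10) {
  st <- series$state
  el <- sw_epoch_len(series)
  min_epochs <- min_bout * 60 / el
  st <- flip_short_runs(st, from = "W", to = "S", min_epochs = min_epochs)
  st <- flip_short_runs(st, from = "S", to = "W", min_epochs = min_epochs)
  new_sw_series(tibble::tibble(time = series$time, state = st), el)
}

flip_short_runs <- function(st, from, to, min_epochs) {
  r <- rle(st)
  k <- length(r$values)
  for (i in seq_len(k)) {
    if (r$values[i] != from || r$lengths[i] >= min_epochs) next
    left <- if (i == 1) NA_character_ else r$values[i - 1]
    right <- if (i == k) NA_character_ else r$values[i + 1]
    left_ok <- is.na(left) || left == to
    right_ok <- is.na(right) || right == to
    # at least one true `to` neighbour, and no `M`/opposite-state flank
    if (left_ok && right_ok && (identical(left, to) || identical(right, to))) {
      r$values[i] <- to
    }
  }
  inverse.rle(r)
}

#' TST and WASO within a main sleep window
#'
#' Total sleep time is the sleep accumulated inside the window; wake after
#' sleep onset is the wake accumulated strictly inside it. With no missing
#' epochs the two sum to the window length.
#'
#' @param series An [sw_series].
#' @param window One row of a [build_windows] table (or any list with
#'   POSIXct `onset` and `offset`).
#' @return Named numeric `c(tst = , waso = )` in hours.
#' @export
compute_tst_waso <- function(series, window) {
  el <- sw_epoch_len(series)
  end_time <- series$time[nrow(series)] + el
  if (window$onset < series$time[1] || window$offset > end_time) {
    stop("window lies outside the series span")
  }
  inside <- series$time >= window$onset & series$time < window$offset
  st <- series$state[inside]
  c(tst = sum(st == "S") * el / 3600, waso = sum(st == "W") * el / 3600)
}

#' Epoch-level classification metrics
#'
#' Compares a predicted series against ground truth on the shared grid,
#' excluding pairs where either is missing. Sensitivity is the percentage of
#' true sleep epochs predicted sleep; specificity the percentage of true
#' wake epochs predicted wake; F uses sleep as the positive class. TST/WASO
#' biases are Bland-Altman style mean differences (predicted minus true,
#' minutes) of per-day main-window summaries.
#'
#' @param pred,truth Aligned [sw_series] objects.
#' @param with_bias Compute per-day TST/WASO biases (requires both series to
#'   contain scoreable sleep windows).
#' @return One-row tibble: `sensitivity`, `specificity`, `accuracy` (in %),
#'   `f_measure`, `tst_bias`, `waso_bias` (minutes; NA when not computed).
#' @export
evaluate_classification <- function(pred, truth, with_bias = FALSE) {
  if (nrow(pred) != nrow(truth)) stop("series grids differ")
  ok <- pred$state != "M" & truth$state != "M"
  if (!any(ok)) stop("no overlapping non-missing epochs")
  p <- pred$state[ok] == "S"
  t <- truth$state[ok] == "S"
  tp <- sum(p & t); tn <- sum(!p & !t); fp <- sum(p & !t); fn <- sum(!p & t)
  sens <- if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp)
  acc <- 100 * (tp + tn) / (tp + tn + fp + fn)
  f <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)

  tst_bias <- waso_bias <- NA_real_
  if (with_bias) {
    bias <- day_window_bias(pred, truth)
    tst_bias <- bias["tst"]
    waso_bias <- bias["waso"]
  }
  tibble::tibble(sensitivity = sens, specificity = spec, accuracy = acc,
                 f_measure = f, tst_bias = unname(tst_bias),
                 waso_bias = unname(waso_bias))
}

# mean per-day (pred - truth) TST and WASO over days where both series have
# a main (longest) sleep window
day_window_bias <- function(pred, truth) {
  days <- segment_noon_days(truth)
  if (nrow(days) == 0) return(c(tst = NA_real_, waso = NA_real_))
  diffs <- purrr::map(seq_len(nrow(days)), function(i) {
    d <- days[i, ]
    sub_p <- window_slice(pred, d$day_start, d$day_end)
    sub_t <- window_slice(truth, d$day_start, d$day_end)
    wp <- build_windows(sub_p)
    wt <- build_windows(sub_t)
    if (nrow(wp) == 0 || nrow(wt) == 0) return(NULL)
    main_p <- wp[which.max(as.numeric(wp$offset - wp$onset)), ]
    main_t <- wt[which.max(as.numeric(wt$offset - wt$onset)), ]
    mp <- compute_tst_waso(sub_p, main_p)
    mt <- compute_tst_waso(sub_t, main_t)
    (mp - mt) * 60
  }) |> purrr::compact()
  if (length(diffs) == 0) return(c(tst = NA_real_, waso = NA_real_))
  colMeans(do.call(rbind, diffs))
}

window_slice <- function(series, from, to) {
  keep <- series$time >= from & series$time < to
  new_sw_series(series[keep, c("time", "state")], sw_epoch_len(series))
}

#' Smoothing-threshold sensitivity/specificity sweep
#'
#' Applies [smooth_series] at each candidate threshold to a corrupted series
#' and scores it against the clean series; used to justify the default
#' 10-minute bout-smoothing threshold.
#'
#' @param clean,corrupted Aligned [sw_series] objects.
#' @param thresholds Numeric vector of candidate thresholds, minutes;
#'   threshold 0 scores the raw corrupted series.
#' @return Tibble with `threshold`, `sensitivity`, `specificity`, `accuracy`.
#' @export
evaluate_smoothing_threshold <- function(clean, corrupted,
                                         thresholds = c(0, 2, 5, 10, 15, 20)) {
  if (length(thresholds) == 0) stop("empty threshold list")
  purrr::map(thresholds, function(th) {
    sm <- if (th <= 0) corrupted else smooth_series(corrupted, min_bout = th)
    m <- evaluate_classification(sm, clean)
    tibble::tibble(threshold = th, sensitivity = m$sensitivity,
                   specificity = m$specificity, accuracy = m$accuracy)
  }) |> purrr::list_rbind()
}
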