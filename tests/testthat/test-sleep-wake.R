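test_that("jerk is the scaled first difference and kills constant offsets", {
  rec <- structure(list(start_time = NOON, sampling_hz = 100,
                        x = rep(0.5, 1000), y = rep(-0.2, 1000),
                        z = rep(1, 1000)),
                   class = "accel_record")
  j <- compute_jerk(rec)
  expect_true(all(j$x == 0) && all(j$z == 0))
  expect_length(j$x, 999)

  ramp <- structure(list(start_time = NOON, sampling_hz = 100,
                         x = seq(0, 10, by = 0.01), y = rep(0, 1001),
                         z = rep(1, 1001)),
                    class = "accel_record")
  expect_equal(compute_jerk(ramp)$x, rep(1, 1000), tolerance = 1e-9)

  # sinusoid: jerk amplitude ~ 2*pi*f at high sampling rate
  f <- 2
  t <- seq(0, 10, by = 1 / 1000)
  sine <- structure(list(start_time = NOON, sampling_hz = 1000,
                         x = sin(2 * pi * f * t), y = 0 * t, z = 0 * t + 1),
                    class = "accel_record")
  expect_equal(max(abs(compute_jerk(sine)$x)), 2 * pi * f, tolerance = 0.01)

  expect_error(compute_jerk(structure(list(x = 1, sampling_hz = 10),
                                      class = "accel_record")),
               "2 samples")

  # translation invariance: adding a constant changes nothing downstream
  rec2 <- structure(list(start_time = NOON, sampling_hz = 10,
                         x = rnorm(3000), y = rnorm(3000),
                         z = 1 + rnorm(3000)),
                    class = "accel_record")
  rec3 <- rec2
  rec3$x <- rec3$x + 0.123
  f2 <- epoch_features(compute_jerk(rec2))
  f3 <- epoch_features(compute_jerk(rec3))
  expect_equal(as.data.frame(f2), as.data.frame(f3), tolerance = 1e-12)
})

test_that("epoch features satisfy Parseval and band localisation", {
  # zero jerk -> all-zero feature row
  rec0 <- structure(list(start_time = NOON, sampling_hz = 10,
                         x = rep(0, 600), y = rep(0, 600), z = rep(1, 600)),
                    class = "accel_record")
  f0 <- epoch_features(compute_jerk(rec0))
  expect_true(all(as.matrix(f0[, -1]) == 0))

  # white noise: total power equals epoch variance within 5%
  set.seed(2)
  jerk <- structure(list(start_time = NOON, sampling_hz = 20,
                         x = rnorm(20 * 30 * 4), y = rnorm(20 * 30 * 4),
                         z = rnorm(20 * 30 * 4)),
                    class = "jerk_record")
  f <- epoch_features(jerk, epoch_len = 30)
  m <- matrix(jerk$x[seq_len(4 * 600)], nrow = 600)
  v <- apply(m, 2, function(col) mean((col - mean(col))^2))
  expect_equal(f$x_total, v, tolerance = 1e-9) # total = epoch variance
  band_sum <- rowSums(as.matrix(f[, paste0("x_band", 1:8)]))
  expect_true(all(abs(band_sum - f$x_total) / f$x_total < 0.05))

  # pure 1 Hz tone: >= 90% of power in the band containing 1 Hz
  t <- seq(0, 30 - 1 / 20, by = 1 / 20)
  tone <- structure(list(start_time = NOON, sampling_hz = 20,
                         x = sin(2 * pi * 1 * t), y = 0 * t, z = 0 * t),
                    class = "jerk_record")
  ft <- epoch_features(tone, epoch_len = 30)
  edges <- exp(seq(log(0.1), log(10), length.out = 9))
  b1 <- findInterval(1, edges, rightmost.closed = TRUE)
  expect_gt(ft[[paste0("x_band", b1)]][1] / ft$x_total[1], 0.9)
})

test_that("classifier separates separable data and is seed-deterministic", {
  set.seed(3)
  n <- 2000
  X <- tibble::tibble(a = c(rnorm(n / 2, 0), rnorm(n / 2, 8)),
                      b = rnorm(n))
  y <- rep(c("W", "S"), each = n / 2)
  m <- train_classifier(X, y, seed = 1)
  expect_gte(m$objective, 1.9)

  m2 <- train_classifier(X, y, seed = 1)
  expect_identical(
    stats::predict(m$booster, xgboost::xgb.DMatrix(as.matrix(X))),
    stats::predict(m2$booster, xgboost::xgb.DMatrix(as.matrix(X)))
  )
  expect_error(train_classifier(X, rep("S", n)), "both classes")
})

test_that("shuffled labels give chance-level accuracy", {
  set.seed(4)
  n <- 10000
  X <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- sample(rep(c("S", "W"), each = n / 2))
  m <- train_classifier(X, y, params = list(max_depth = 3, nrounds = 50,
                                            eta = 0.1), seed = 2)
  expect_lt(abs(m$accuracy - 0.5), 0.05)
})

test_that("classify respects the nonwear mask", {
  set.seed(5)
  X <- tibble::tibble(a = c(rnorm(200, 0), rnorm(200, 6)), b = rnorm(400))
  y <- rep(c("W", "S"), each = 200)
  m <- train_classifier(X, y, params = list(nrounds = 20), seed = 1)
  feats <- X
  feats$time <- NOON + (seq_len(400) - 1) * 30
  attr(feats, "epoch_len") <- 30

  all_mask <- structure(rep(TRUE, 400), epoch_len = 30, start_time = NOON,
                        class = "nonwear_mask")
  expect_true(all(classify(m, feats, all_mask)$state == "M"))

  alt <- structure(rep(c(TRUE, FALSE), 200), epoch_len = 30,
                   start_time = NOON, class = "nonwear_mask")
  sw <- classify(m, feats, alt)
  expect_true(all(sw$state[seq(1, 400, 2)] == "M"))
  expect_true(all(sw$state[seq(2, 400, 2)] != "M"))

  no_mask <- classify(m, feats)
  expect_true(all(no_mask$state %in% c("S", "W")))
  expect_error(classify(m, feats, structure(rep(TRUE, 10),
                                            class = "nonwear_mask")),
               "align")
})

test_that("bout smoothing follows the strict two-pass rule", {
  # 9.5 min wake run between sleep: flipped
  s <- mk_series("S", 20, "W", 19, "S", 20)
  expect_true(all(smooth_series(s)$state == "S"))

  # exactly 10 min: preserved
  s10 <- mk_series("S", 20, "W", 20, "S", 20)
  expect_equal(smooth_series(s10)$state, s10$state)

  # missing epochs break runs and are never flipped
  sm <- mk_series("S", 20, "M", 2, "W", 5, "S", 20)
  out <- smooth_series(sm)
  expect_equal(out$state[21:22], c("M", "M"))
  expect_equal(out$state[23:27], rep("W", 5)) # flanked by M, not flipped
})

test_that("smoothing matches the brute-force two-pass oracle", {
  set.seed(6)
  for (trial in 1:1000) {
    st <- random_states(sample(30:120, 1))
    s <- sw_series(st)
    expect_identical(smooth_series(s, min_bout = 5)$state,
                     oracle_smooth(st, min_epochs = 10))
  }
})

test_that("smoothing agreement is monotone in min_bout for short artifacts", {
  clean <- generate_subject(quiet_archetype(), 3, seed = 7)$series
  corrupted <- generate_pseudo_flip_series(clean, flip_rate = 0.01,
                                           max_flip_run = 16, seed = 8)$series
  agree <- vapply(c(2, 4, 6, 8, 10), function(th) {
    mean(smooth_series(corrupted, min_bout = th)$state == clean$state)
  }, numeric(1))
  expect_true(all(diff(agree) >= 0))
})

test_that("TST/WASO sum to the window length and match hand cases", {
  # 22:00-07:00 window with one 30-min wake run
  # noon -> 22:00 wake, 1 h sleep, 30 min wake, sleep until 07:00, then wake
  s <- mk_series("W", 1200, "S", 120, "W", 60, "S", 900, "W", 600)
  w <- build_windows(s)
  expect_equal(nrow(w), 1)
  tw <- compute_tst_waso(s, w[1, ])
  expect_equal(unname(tw["tst"]), 8.5)
  expect_equal(unname(tw["waso"]), 0.5)

  s8 <- mk_series("W", 120, "S", 8 * 120, "W", 120)
  w8 <- build_windows(s8)
  expect_equal(unname(compute_tst_waso(s8, w8[1, ])), c(8, 0))

  expect_error(
    compute_tst_waso(s8, list(onset = NOON - 3600, offset = NOON)),
    "outside"
  )

  # conservation on random series without missing epochs
  set.seed(9)
  for (trial in 1:200) {
    st <- sample(c("S", "W"), 400, replace = TRUE)
    s <- sw_series(st)
    w <- build_windows(s)
    if (nrow(w) == 0) next
    i <- sample.int(nrow(w), 1)
    tw <- compute_tst_waso(s, w[i, ])
    expect_equal(sum(tw), as.numeric(w$offset[i] - w$onset[i], units = "hours"))
  }
})

test_that("classification metrics match their definitions", {
  truth <- sw_series(rep(c("S", "W"), c(100, 100)))
  m <- evaluate_classification(truth, truth)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)
  expect_equal(m$f_measure, 1)

  all_sleep <- sw_series(rep("S", 200))
  m2 <- evaluate_classification(all_sleep, truth)
  expect_equal(m2$sensitivity, 100)
  expect_equal(m2$specificity, 0)

  # constructed 2x2: TP=90 FN=10 TN=80 FP=20
  truth3 <- sw_series(rep(c("S", "W"), c(100, 100)))
  pred3 <- sw_series(c(rep("S", 90), rep("W", 10), rep("S", 20), rep("W", 80)))
  m3 <- evaluate_classification(pred3, truth3)
  expect_equal(m3$sensitivity, 90)
  expect_equal(m3$specificity, 80)
  expect_equal(m3$accuracy, 85)

  # missing epochs are excluded pairwise
  pm <- sw_series(c(rep("M", 100), rep("W", 100)))
  m4 <- evaluate_classification(pm, truth)
  expect_equal(m4$specificity, 100)
  expect_true(is.na(m4$sensitivity))
  expect_error(evaluate_classification(sw_series(rep("M", 200)), truth),
               "non-missing")
})

test_that("smoothing-threshold sweep recovers sub-threshold corruption", {
  clean <- generate_subject(quiet_archetype(), 3, seed = 10)$series
  sweep0 <- evaluate_smoothing_threshold(clean, clean, thresholds = c(0, 5, 10))
  expect_true(all(sweep0$sensitivity == 100))
  expect_true(all(sweep0$specificity == 100))

  # corruption away from true transitions: flips planted inside homogeneous
  # sleep and wake blocks, so sub-threshold smoothing must heal them exactly
  clean2 <- sw_series(c(rep("S", 4320), rep("W", 4320)))
  flip_sleep <- generate_pseudo_flip_series(
    sw_series(rep("S", 4320)), flip_rate = 0.003, max_flip_run = 4, seed = 11
  )$series
  flip_wake <- generate_pseudo_flip_series(
    sw_series(rep("W", 4320)), flip_rate = 0.003, max_flip_run = 4, seed = 12
  )$series
  corrupted <- sw_series(c(flip_sleep$state, flip_wake$state))
  tab <- evaluate_smoothing_threshold(clean2, corrupted,
                                      thresholds = c(0, 5, 10))
  raw <- evaluate_classification(corrupted, clean2)
  expect_equal(tab$sensitivity[1], raw$sensitivity)
  # inserted runs are < 5 min (at most 2x4 epochs = 4 min if merged):
  # threshold 5 heals everything
  r5 <- tab[tab$threshold == 5, ]
  expect_equal(r5$sensitivity, 100)
  expect_equal(r5$specificity, 100)
  expect_error(evaluate_smoothing_threshold(clean2, corrupted, numeric()),
               "empty")
})
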