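test_that("pr_baseline averages the PR segment with documented fallbacks", {
  fs <- 500
  fid <- data.frame(P_on = 80L, P_peak = 90L, P_off = 100L,
                    Q_peak = NA_integer_, QRS_on = 120L, R_peak = 140L,
                    S_peak = NA_integer_, QRS_off = 160L,
                    T_on = 200L, T_peak = 250L, T_off = 300L)
  expect_equal(pr_baseline(numeric(400), fid, 1, fs), 0)
  expect_equal(pr_baseline(rep(0.1, 400), fid, 1, fs), 0.1)

  ramp <- numeric(400)
  ramp[100:119] <- seq(0, 0.2, length.out = 20)
  expect_equal(pr_baseline(ramp, fid, 1, fs), 0.1, tolerance = 0.01)

  # P absent: 40-10 ms pre-QRS fallback
  fid2 <- fid; fid2$P_off <- NA_integer_
  x <- rep(0.25, 400)
  expect_equal(pr_baseline(x, fid2, 1, fs), 0.25)
  # nothing usable: missing
  fid3 <- fid2; fid3$QRS_on <- NA_integer_; fid3$R_peak <- NA_integer_
  expect_true(is.na(pr_baseline(x, fid3, 1, fs)))
})

test_that("wave amplitudes follow the sign conventions and median rule", {
  fs <- 500
  x <- rep(0.2, 3000)                        # constant 0.2 mV baseline
  rpk <- c(500L, 1500L, 2500L)
  x[rpk] <- x[rpk] + c(0.9, 1.0, 1.4)        # R peaks above baseline
  x[rpk + 30L] <- x[rpk + 30L] - 0.3         # S nadirs
  fid <- data.frame(P_on = NA_integer_, P_peak = NA_integer_,
                    P_off = NA_integer_, Q_peak = NA_integer_,
                    QRS_on = rpk - 20L, R_peak = rpk, S_peak = rpk + 30L,
                    QRS_off = rpk + 40L, T_on = NA_integer_,
                    T_peak = NA_integer_, T_off = NA_integer_)
  amps <- wave_amplitudes(x, fid, fs)
  expect_equal(amps[["R"]], 1.0)            # median of 0.9, 1.0, 1.4
  expect_equal(amps[["S"]], 0.3)            # absolute convention
  expect_true(is.na(amps[["P"]]))

  # amplitudes are invariant to a constant baseline shift
  amps2 <- wave_amplitudes(x + 5, fid, fs)
  expect_equal(amps2[["R"]], amps[["R"]])
  expect_equal(amps2[["S"]], amps[["S"]])
})

test_that("rs_ratio applies the denominator floor", {
  expect_equal(rs_ratio(0.5, 0.1), 5.0)
  expect_equal(rs_ratio(0.5, 0), 50.0)
  expect_equal(rs_ratio(0.5, NA), 50.0)
  expect_equal(rs_ratio(0, 0.2), 0.0)
  expect_true(is.na(rs_ratio(NA, 0.2)))
})

test_that("interval features derive from the global windows", {
  gw <- structure(list(P_on_rel = -200, P_peak_rel = -150, P_off_rel = -100,
                       QRS_on_rel = -50, QRS_off_rel = 50,
                       T_on_rel = 200, T_peak_rel = 400, T_off_rel = 500),
                  class = "global_windows")
  iv <- interval_features(gw, r_peaks = c(500L, 1000L, 1500L), fs = 500)
  expect_equal(iv[["P_duration"]], 100)
  expect_equal(iv[["PR_interval"]], 150)
  expect_equal(iv[["QRS_duration"]], 100)
  expect_equal(iv[["QT_interval"]], 550)
  expect_equal(iv[["T_upslope"]], 200)
  expect_equal(iv[["T_downslope"]], 100)
  expect_equal(iv[["T_index"]], 2.0)
  expect_equal(iv[["median_RR"]], 1000)
  expect_equal(iv[["heart_rate"]], 60)
  # representative frame starts 40 ms before P onset
  expect_equal(iv[["frame_QRS_onset"]], -50 - (-200 - 40))
  expect_equal(iv[["frame_QRS_end"]], 50 - (-200 - 40))

  # symmetric T gives index 1
  gw$T_peak_rel <- 350
  expect_equal(interval_features(gw, c(500L, 1000L), 500)[["T_index"]], 1.0)
})

test_that("spectral features recover tone frequencies", {
  fs <- 500
  t <- (0:(10 * fs - 1)) / fs
  sp <- spectral_features(sin(2 * pi * 10 * t), fs)
  expect_equal(sp[["mean_freq"]], 10, tolerance = 0.1)

  two <- sin(2 * pi * 5 * t) + sin(2 * pi * 15 * t)
  sp2 <- spectral_features(two, fs)
  expect_equal(sp2[["mean_freq"]], 10, tolerance = 0.1)
  expect_equal(sp2[["spec_spread"]], 5, tolerance = 0.2)

  expect_true(all(is.na(spectral_features(rep(1, 10 * fs), fs))))
  expect_error(spectral_features(numeric(100), fs), "2 s")
})

test_that("moment features match closed forms", {
  t <- (0:99999) / 1000
  s <- sin(2 * pi * 5 * t)
  m <- moment_features(s)
  expect_equal(m[["skewness"]], 0, tolerance = 0.01)
  expect_equal(m[["excess_kurtosis"]], -1.5, tolerance = 0.01)

  set.seed(4)
  g <- rnorm(200000)
  mg <- moment_features(g)
  se_sk <- sqrt(6 / length(g)); se_ku <- sqrt(24 / length(g))
  expect_lt(abs(mg[["skewness"]]), 3 * se_sk)
  expect_lt(abs(mg[["excess_kurtosis"]]), 3 * se_ku)

  expect_true(all(is.na(moment_features(rep(2, 100)))))
})

test_that("assemble_features keeps the registry order and passthrough", {
  reg <- feature_registry()
  expect_false(anyDuplicated(reg$name) > 0)

  lead_feats <- stats::setNames(lapply(vcg_lead_names(), function(l) {
    c(P = 0.1, Q = 0.05, R = 1, S = 0.2, T = 0.3, RS_ratio = 5,
      mean_freq = 8, spec_spread = 4, spec_skewness = 0.5,
      skewness = 0.1, excess_kurtosis = 2)
  }), vcg_lead_names())
  iv <- stats::setNames(rep(1, 12),
                        c("P_duration", "PR_interval", "QRS_duration",
                          "QT_interval", "T_duration", "T_upslope",
                          "T_downslope", "T_index", "frame_QRS_onset",
                          "frame_QRS_end", "median_RR", "heart_rate"))
  vcg <- stats::setNames(rep(0.5, 41), vcg_feature_names())
  row <- assemble_features("r1", lead_feats, iv, vcg,
                           machine_numeric = c(qrs_duration = 98),
                           machine_flags = c(lvh = TRUE))
  expect_equal(row$record_id, "r1")
  expect_equal(row$R_amp_V5, 1)
  expect_equal(row$machine_qrs_duration, 98)
  expect_true(row$flag_lvh)
  # identical inputs give identical rows
  row2 <- assemble_features("r1", lead_feats, iv, vcg,
                            machine_numeric = c(qrs_duration = 98),
                            machine_flags = c(lvh = TRUE))
  expect_identical(row, row2)

  # a missing family stays missing, others intact
  lf2 <- lead_feats
  lf2$II[c("P", "Q", "R", "S", "T")] <- NA_real_
  row3 <- assemble_features("r2", lf2, iv, vcg)
  expect_true(is.na(row3$R_amp_II))
  expect_equal(row3$R_amp_V5, 1)
})
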