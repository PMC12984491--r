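test_that("detect_r_peaks finds impulse trains exactly and warns on flat input", {
  fs <- 500
  x <- numeric(10 * fs)
  at <- 250 + fs * (0:9)
  x[at] <- 1
  peaks <- detect_r_peaks(x, fs)
  expect_equal(peaks, at)

  expect_warning(empty <- detect_r_peaks(numeric(10 * fs), fs), "quality")
  expect_length(empty, 0)
  expect_error(detect_r_peaks(numeric(100), fs), "2 s")
})

test_that("detected peaks honour the refractory period and stay ascending", {
  fs <- 500
  x <- numeric(10 * fs)
  x[c(1000, 1030, 2000, 2950)] <- 1   # 1030 is inside the 200 ms refractory
  peaks <- detect_r_peaks(x, fs)
  expect_true(all(diff(peaks) >= 0.2 * fs))
  expect_true(!is.unsorted(peaks, strictly = TRUE))
})

test_that("prominence delineation recovers Gaussian P and T peaks", {
  lead <- make_test_lead()
  fid <- delineate_prominence(lead$x, lead$fs, lead$r)
  expect_true(fiducials_ordered(fid))
  tol <- 2   # samples = 4 ms at 500 Hz
  expect_true(all(abs(fid$P_peak - (lead$r - 0.18 * lead$fs)) <= tol))
  expect_true(all(abs(fid$T_peak - (lead$r + 0.30 * lead$fs)) <= tol))

  # zero-amplitude P: landmarks absent, never fabricated
  flat_p <- make_test_lead(p_amp = 0)
  fid0 <- delineate_prominence(flat_p$x, flat_p$fs, flat_p$r)
  expect_true(all(is.na(fid0$P_peak)))
  expect_true(all(is.na(fid0$P_on)))

  expect_error(delineate_prominence(lead$x, lead$fs, lead$r[1]), "2 R peaks")
})

test_that("T offset lands at the right-hand base of the T peak", {
  # truncated Gaussian (exactly flat after +3 sigma): the flanking
  # minimum is the first sample of the flat stretch
  lead <- make_test_lead(t_sigma_ms = 50)
  fid <- delineate_prominence(lead$x, lead$fs, lead$r)
  expected_toff <- lead$r + round((300 + 3 * 50) / 1000 * lead$fs)
  expect_true(all(abs(fid$T_off - expected_toff) <= 3))  # 6 ms
})

test_that("DWT refinement recovers known QRS support", {
  fs <- 500
  n <- 10 * fs
  x <- numeric(n)
  r <- fs * (1:8)
  # biphasic complex with support exactly [-40, +60] ms around R
  for (rk in r) {
    i0 <- rk - 0.04 * fs; i1 <- rk + 0.06 * fs
    s <- seq(0, 1, length.out = i1 - i0 + 1)
    x[i0:i1] <- 1.2 * sin(pi * s) * sin(2 * pi * s * 1.5)
  }
  fid <- delineate_prominence(x, fs, r)
  fid <- refine_qrs_bounds_dwt(x, fs, fid)
  expect_true(all(abs(fid$QRS_on - (r - 0.04 * fs)) <= 3))   # 6 ms
  expect_true(all(abs(fid$QRS_off - (r + 0.06 * fs)) <= 3))
  expect_true(fiducials_ordered(fid))

  # small additive noise moves neither bound by more than 2 samples
  set.seed(11)
  xn <- x + rnorm(n, 0, 0.005)
  fidn <- delineate_prominence(xn, fs, r)
  fidn <- refine_qrs_bounds_dwt(xn, fs, fidn)
  expect_true(all(abs(fidn$QRS_on - fid$QRS_on) <= 2))
  expect_true(all(abs(fidn$QRS_off - fid$QRS_off) <= 2))
})

test_that("single-sample spike yields tight, flagged bounds", {
  fs <- 500
  x <- numeric(6 * fs)
  r <- fs * (1:5)
  x[r] <- 1
  fid <- delineate_prominence(x, fs, r)
  fid <- refine_qrs_bounds_dwt(x, fs, fid)
  expect_true(all(abs(fid$QRS_on - r) <= 2))
  expect_true(all(abs(fid$QRS_off - r) <= 2))
  expect_true(all(nzchar(fid$qrs_flag)))
})

test_that("aggregate_global_windows takes medians over beats then leads", {
  offs <- c(30, 30, 31, 31, 32, 33, 33, 34)
  fs <- 500
  fids <- lapply(offs, function(o) {
    data.frame(P_on = NA_integer_, P_peak = NA_integer_, P_off = NA_integer_,
               Q_peak = NA_integer_, QRS_on = 975L, R_peak = 1000L,
               S_peak = NA_integer_, QRS_off = 1000L + o,
               T_on = NA_integer_, T_peak = NA_integer_, T_off = NA_integer_)
  })
  names(fids) <- vcg_independent_leads()
  gw <- aggregate_global_windows(fids, fs,
                                 required = c("QRS_on", "QRS_off"))
  expect_equal(gw$QRS_off_rel, 63)          # median 31.5 samples -> 63 ms
  expect_equal(gw$QRS_on_rel, -50)          # -25 samples at 500 Hz

  # a lead missing T contributes nothing to the T medians
  fids2 <- fids
  for (i in seq_along(fids2)) {
    fids2[[i]]$T_on <- 1100L; fids2[[i]]$T_peak <- 1150L
    fids2[[i]]$T_off <- 1200L
  }
  fids2[[3]]$T_on <- fids2[[3]]$T_peak <- fids2[[3]]$T_off <- NA_integer_
  gw2 <- aggregate_global_windows(fids2, fs)
  expect_equal(gw2$T_off_rel, 400)

  # landmark absent everywhere is an error naming the landmark
  for (i in seq_along(fids2)) fids2[[i]]$T_on <- NA_integer_
  expect_error(aggregate_global_windows(fids2, fs), "T_on")
})

test_that("aggregation refuses to silently repair ordering violations", {
  fids <- list(II = data.frame(
    P_on = NA_integer_, P_peak = NA_integer_, P_off = NA_integer_,
    Q_peak = NA_integer_, QRS_on = 1030L, R_peak = 1000L,
    S_peak = NA_integer_, QRS_off = 1040L, T_on = 1100L,
    T_peak = 1150L, T_off = 1200L))
  expect_error(aggregate_global_windows(fids, 500), "ordering")
})

test_that("delineation is deterministic", {
  lead <- make_test_lead()
  a <- delineate_prominence(lead$x, lead$fs, lead$r)
  b <- delineate_prominence(lead$x, lead$fs, lead$r)
  expect_identical(a, b)
})

test_that("fiducials export to tidy long form", {
  lead <- make_test_lead()
  fid <- delineate_prominence(lead$x, lead$fs, lead$r)
  tidy <- fiducials_tidy(list(II = fid), lead$fs, "rec1")
  expect_true(all(c("record_id", "lead", "beat", "landmark",
                    "sample_index", "time_ms") %in% names(tidy)))
  expect_true(all(!is.na(tidy$sample_index)))
  expect_equal(unique(tidy$lead), "II")
})
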