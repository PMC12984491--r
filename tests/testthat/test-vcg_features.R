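# helper: wrap a points matrix as a vcg_trajectory
as_traj <- function(pts, fs = 500, r_index = 1L, windows = NULL) {
  structure(pts, fs = fs, r_index = r_index, windows = windows,
            class = c("vcg_trajectory", "matrix", "array"))
}

rand_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

test_that("kors_transform is the exact linear projection", {
  K <- kors_matrix()
  zeros <- matrix(0, 8, 425)
  expect_true(all(kors_transform(zeros, K) == 0))

  # right-inverse round trip: leads = L v recovers v through K
  L <- kors_right_inverse(K)
  expect_equal(K %*% L, diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  set.seed(2)
  for (i in 1:5) {
    v <- matrix(rnorm(300), 100, 3)
    leads <- L %*% t(v)
    back <- kors_transform(leads, K)
    expect_lt(max(abs(unclass(back) - v)), 1e-9)
  }

  # linearity
  leads <- matrix(rnorm(8 * 50), 8, 50)
  expect_equal(unclass(kors_transform(2 * leads, K)),
               2 * unclass(kors_transform(leads, K)), tolerance = 1e-12)
  expect_error(kors_transform(matrix(0, 7, 10), K), "shape")
})

test_that("extract_loop windows samples and translates to the onset", {
  pts <- matrix(rnorm(425 * 3), 425, 3)
  traj <- as_traj(pts, r_index = 200L)
  loop <- extract_loop(traj, c(-50, 60))
  expect_equal(nrow(loop), 55L)
  expect_equal(loop[1L, ], c(X = 0, Y = 0, Z = 0), ignore_attr = TRUE)

  # translation invariance
  traj2 <- as_traj(sweep(pts, 2, c(1, -2, 3), `+`), r_index = 200L)
  expect_equal(unclass(extract_loop(traj2, c(-50, 60))), unclass(loop))

  # constant trajectory -> all-zero loop
  traj3 <- as_traj(matrix(1, 425, 3), r_index = 200L)
  expect_true(all(extract_loop(traj3, c(-50, 60)) == 0))
  expect_error(extract_loop(traj, c(10, 10)), "empty window")
})

test_that("loop_svd: circle, collinear and rotation-invariance cases", {
  th <- 2 * pi * (0:99) / 100
  circ <- cbind(cos(th), sin(th), 0)
  sv <- loop_svd(circ)
  expect_equal(sv$sigma2_over_sigma1, 1, tolerance = 1e-6)
  expect_lt(sv$planarity, 1e-9)

  seg <- cbind(seq(0, 1, length.out = 50), 0, 0)
  svc <- loop_svd(seg)
  expect_equal(svc$sigma2, 0, tolerance = 1e-12)
  expect_equal(svc$sigma2_over_sigma1, 0)
  expect_true(is.na(svc$ln_nondipolar_ratio))

  set.seed(3)
  loop <- matrix(rnorm(150), 50, 3)
  base <- loop_svd(loop)
  for (i in 1:10) {
    R <- rand_rotation()
    rot <- loop_svd(loop %*% R)
    expect_lt(max(abs(c(rot$sigma1 - base$sigma1, rot$sigma2 - base$sigma2,
                        rot$sigma3 - base$sigma3))), 1e-9)
  }
  # sample reversal and amplitude covariance
  rev_sv <- loop_svd(loop[50:1, ])
  expect_equal(rev_sv$sigma1, base$sigma1, tolerance = 1e-12)
  sc <- loop_svd(2.5 * loop)
  expect_equal(sc$sigma1, 2.5 * base$sigma1, tolerance = 1e-12)

  # eigenvectors orthonormal, sign tied to the mean vector
  V <- cbind(base$eigvec1, base$eigvec2, base$eigvec3)
  expect_equal(t(V) %*% V, diag(3), tolerance = 1e-10)
  expect_gte(sum(base$eigvec1 * base$mean_vector), 0)
})

test_that("loop magnitude features match closed forms", {
  fs <- 500
  # constant (1,0,0) over 100 ms
  const <- matrix(rep(c(1, 0, 0), each = 50), 50, 3)
  mf <- loop_magnitude_features(const, fs)
  expect_equal(mf$peak_magnitude, 1)
  expect_equal(mf$time_voltage_area, 100)
  expect_equal(mf$max_to_mean_ratio, 1)
  expect_equal(mf$mean_vector, c(1, 0, 0))
  expect_equal(mf$time_to_peak, 0)   # argmax at window start

  # half-sine magnitude profile: area = (2/pi) A T within 1%
  A <- 0.8; Tms <- 200
  n <- Tms / 1000 * fs
  prof <- cbind(A * sin(pi * (seq_len(n) - 0.5) / n), 0, 0)
  mfh <- loop_magnitude_features(prof, fs)
  expect_equal(mfh$time_voltage_area, 2 / pi * A * Tms,
               tolerance = 0.01)

  z <- loop_magnitude_features(matrix(0, 10, 3), fs)
  expect_equal(z$peak_magnitude, 0)
  expect_true(is.na(z$max_to_mean_ratio))
})

test_that("spatial_angle covers the quadrant examples", {
  expect_equal(spatial_angle(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(spatial_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(spatial_angle(c(1, 0, 0), c(-1, 0, 0)), 180)
  expect_true(is.na(spatial_angle(c(0, 0, 0), c(1, 0, 0))))
})

test_that("ventricular gradient integrates and orients correctly", {
  fs <- 500
  traj <- as_traj(matrix(rep(c(1, 0, 0), each = 50), 50, 3),
                  r_index = 1L)
  vg <- ventricular_gradient(traj, c(0, 100))
  expect_equal(unname(vg$vg), c(100, 0, 0))
  expect_equal(vg$elevation_3d_deg, 0)
  expect_equal(vg$azimuth_horizontal_deg, 0)
  expect_true(is.na(vg$sin_sagittal))    # sagittal projection is (0,0)

  traj2 <- as_traj(matrix(rep(c(0, 0, 0.5), each = 50), 50, 3),
                   r_index = 1L)
  vg2 <- ventricular_gradient(traj2, c(0, 100))
  expect_equal(vg2$elevation_3d_deg, 90)
  expect_equal(vg2$sin_sagittal, 1)

  # antisymmetric trajectory cancels
  t <- seq(-1, 1, length.out = 100)
  anti <- cbind(t, t^3, -t)
  vg3 <- ventricular_gradient(as_traj(anti, r_index = 1L), c(0, 200))
  expect_lt(vg3$magnitude, 1e-9)
  expect_true(is.na(vg3$elevation_3d_deg))
})

test_that("ventricular gradient is additive over concatenated windows", {
  set.seed(9)
  traj <- as_traj(matrix(rnorm(300), 100, 3), r_index = 1L)
  whole <- ventricular_gradient(traj, c(0, 200))$vg
  a <- ventricular_gradient(traj, c(0, 80))$vg
  b <- ventricular_gradient(traj, c(80, 200))$vg
  expect_equal(whole, a + b, tolerance = 1e-9)
})

test_that("vcg_lead_scalars takes the signed extremum from window onset", {
  fs <- 500
  n <- 425
  pts <- matrix(0, n, 3)
  pts[200:225, 2] <- seq(0, 0.5, length.out = 26)   # Y ramp inside QRS
  gw <- structure(list(P_on_rel = NA, P_peak_rel = NA, P_off_rel = NA,
                       QRS_on_rel = 0, QRS_off_rel = 52, T_on_rel = NA,
                       T_peak_rel = NA, T_off_rel = NA),
                  class = "global_windows")
  traj <- as_traj(pts, r_index = 200L, windows = gw)
  sc <- vcg_lead_scalars(traj)
  expect_equal(sc[["Y"]], 0.5)
  neg <- vcg_lead_scalars(as_traj(-pts, r_index = 200L, windows = gw))
  expect_equal(neg[["Y"]], -0.5)
  zero <- vcg_lead_scalars(as_traj(matrix(0, n, 3), r_index = 200L,
                                   windows = gw))
  expect_equal(unname(zero), c(0, 0, 0))
})

test_that("compute_all_vcg_features has a stable 41-name registry", {
  expect_length(vcg_feature_names(), 41L)
  expect_false(anyDuplicated(vcg_feature_names()) > 0)

  out <- synthesize_record(cohort_presets()$NORMAL, 8L)
  del <- delineate_record(out$record)
  beats <- lapply(del$clean[vcg_independent_leads()], function(x) {
    build_mean_beat(x, del$r_ref, 500)
  })
  mbm <- assemble_calibrated_matrix(beats, del$gw, v5_r_index = 151L)
  f1 <- compute_all_vcg_features(mbm)
  f2 <- compute_all_vcg_features(mbm)
  expect_identical(names(f1), vcg_feature_names())
  expect_identical(f1, f2)

  # absent P loop: P features missing, others intact
  gw2 <- attr(mbm, "windows")
  gw2$P_on_rel <- gw2$P_off_rel <- gw2$P_peak_rel <- NA_real_
  attr(mbm, "windows") <- gw2
  f3 <- compute_all_vcg_features(mbm)
  expect_true(all(is.na(f3[grep("^P_", names(f3))])))
  expect_true(is.na(f3["angle_P_QRS_mean_deg"]))
  expect_false(is.na(f3["QRS_peak_magnitude_mV"]))
})
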