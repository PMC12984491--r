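# Vectorcardiographic feature extraction: Kors projection, P/QRS/T loop
# singular-value summaries, spatial angles, ventricular gradient geometry
# and derived-lead scalars.  Axis convention: X positive leftward, Y
# positive inferior, Z positive posterior; horizontal plane = X-Z,
# sagittal plane = Y-Z; plane angles are measured from the first named
# axis of the plane toward +Z.

#' Project a median-beat matrix into VCG space
#'
#' points(t) = K leads(t) for every sample; linear in the leads.
#'
#' @param matrix a [assemble_calibrated_matrix()] result (8 x W) or any
#'   8 x W numeric matrix in lead order I, II, V1..V6.
#' @param K 3 x 8 transform, default [kors_matrix()].
#' @return a `vcg_trajectory`: W x 3 matrix (columns X, Y, Z, mV) with
#'   attributes `fs`, `r_index`, `windows` carried over.
#' @export
kors_transform <- function(matrix, K = kors_matrix()) {
  if (nrow(matrix) != ncol(K)) stop("shape mismatch: need ", ncol(K),
                                    " lead rows, got ", nrow(matrix))
  pts <- t(K %*% matrix)
  colnames(pts) <- c("X", "Y", "Z")
  structure(pts, fs = attr(matrix, "fs"), r_index = attr(matrix, "r_index"),
            windows = attr(matrix, "windows"),
            class = c("vcg_trajectory", "matrix", "array"))
}

#' Extract a wave loop from a trajectory
#'
#' Takes the samples of the half-open window `[on, off)` (ms relative to
#' the R index) and translates them so the window-onset point is the
#' origin, making the loop invariant to constant offsets.
#'
#' @param traj a `vcg_trajectory`.
#' @param window `"P"`, `"QRS"` or `"T"` (resolved from the attached
#'   global windows), or a numeric `c(on_ms, off_ms)` pair.
#' @param translate shift the loop so the window-onset sample is the
#'   origin (default).  With `FALSE` the points keep the trajectory's
#'   own (isoelectric, PR-referenced) origin -- the two coincide when
#'   the onset lands on the isoelectric level, but a delineated onset a
#'   few ms inside the wave support would otherwise displace the origin
#'   into the wave.
#' @return M x 3 matrix of loop points (mV) with attributes `fs` and
#'   `onset_rel_ms`.
#' @export
extract_loop <- function(traj, window, translate = TRUE) {
  fs <- attr(traj, "fs"); r <- attr(traj, "r_index")
  if (is.character(window)) {
    gw <- attr(traj, "windows")
    if (is.null(gw)) stop("trajectory carries no global windows")
    window <- switch(window,
      P = c(gw$P_on_rel, gw$P_off_rel),
      QRS = c(gw$QRS_on_rel, gw$QRS_off_rel),
      T = c(gw$T_on_rel, gw$T_off_rel),
      stop("unknown window name"))
  }
  if (any(is.na(window))) stop("window limits undefined")
  i0 <- r + round(window[1L] / 1000 * fs)
  i1 <- r + round(window[2L] / 1000 * fs)   # exclusive
  i0 <- max(1L, i0); i1 <- min(nrow(traj) + 1L, i1)
  if (i1 - i0 < 1L) stop("empty window")
  pts <- traj[i0:(i1 - 1L), , drop = FALSE]
  if (translate) pts <- sweep(pts, 2L, pts[1L, ])
  structure(unclass(pts), fs = fs, onset_rel_ms = window[1L])
}

#' Loop singular-value summary
#'
#' Singular values of the M x 3 loop matrix scaled by 1/sqrt(M) so they
#' are amplitude-like and invariant to sampling density; the loop is not
#' mean-centered (the origin is the isoelectric window-onset point), so
#' sigma1 is a dipolar amplitude.  Eigenvector signs are fixed to a
#' non-negative dot product with the loop mean vector (ties: first
#' non-zero coordinate positive).
#'
#' @param loop M x 3 loop points (M >= 3).
#' @return list with `sigma1..3`, `eigvec1..3`, `sigma2_over_sigma1`,
#'   `ln_nondipolar_ratio` (= ln((s2+s3)/s1), `NA` when undefined --
#'   never -Inf), `ln_sigma1`, `planarity` (= s3/s1) and `mean_vector`.
#' @export
loop_svd <- function(loop) {
  M <- nrow(loop)
  if (is.null(M) || M < 3L) stop("need at least 3 loop points")
  sv <- svd(loop)
  sigma <- sv$d / sqrt(M)
  mv <- colMeans(loop)
  vecs <- lapply(1:3, function(i) {
    v <- sv$v[, i]
    dp <- sum(v * mv)
    if (abs(dp) > 1e-12) v * sign(dp)
    else {
      nz <- which(abs(v) > 1e-12)[1L]
      if (!is.na(nz) && v[nz] < 0) -v else v
    }
  })
  s1 <- sigma[1L]; s2 <- sigma[2L]; s3 <- sigma[3L]
  degener <- s1 < 1e-12
  list(
    sigma1 = s1, sigma2 = s2, sigma3 = s3,
    eigvec1 = vecs[[1L]], eigvec2 = vecs[[2L]], eigvec3 = vecs[[3L]],
    sigma2_over_sigma1 = if (degener) NA_real_ else s2 / s1,
    ln_nondipolar_ratio = if (degener || s2 + s3 < 1e-12) NA_real_ else
      log((s2 + s3) / s1),
    ln_sigma1 = if (degener) NA_real_ else log(s1),
    planarity = if (degener) NA_real_ else s3 / s1,
    mean_vector = mv)
}

#' Loop magnitude and timing features
#'
#' @param loop M x 3 loop points.
#' @param fs Hz.
#' @return list with `peak_magnitude` (max spatial magnitude, mV),
#'   `time_to_peak` (ms from window onset; for the QRS loop this is the
#'   ventricular activation time), `time_voltage_area` (mV.ms),
#'   `max_to_mean_ratio` and `mean_vector`.
#' @export
loop_magnitude_features <- function(loop, fs = attr(loop, "fs")) {
  mag <- sqrt(rowSums(loop^2))
  dt <- 1000 / fs
  peak <- max(mag)
  list(
    peak_magnitude = peak,
    time_to_peak = (which.max(mag) - 1L) * dt,
    time_voltage_area = sum(mag) * dt,
    max_to_mean_ratio = if (peak < 1e-12) NA_real_ else peak / mean(mag),
    mean_vector = colMeans(loop))
}

#' Spatial angle between two 3-vectors
#'
#' @param a,b numeric 3-vectors.
#' @return angle in degrees in `[0, 180]`; `NA` when either vector is
#'   (numerically) zero.
#' @export
spatial_angle <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (!is.finite(na) || !is.finite(nb) || na < 1e-12 || nb < 1e-12) {
    return(NA_real_)
  }
  acos(min(1, max(-1, sum(a * b) / (na * nb)))) * 180 / pi
}

#' Ventricular gradient
#'
#' The time integral of the instantaneous heart vector over
#' `[QRS_on, T_off)` relative to the isoelectric (PR-baseline) origin.
#' Angle conventions: horizontal azimuth is the angle of the (X, Z)
#' projection measured from +X toward +Z; the sagittal angle is the angle
#' of the (Y, Z) projection from +Y toward +Z; 3D elevation is
#' `asin(Z/|vg|)`, measured from the XY plane.
#'
#' @param traj a `vcg_trajectory` with windows attached, or a plain
#'   matrix restricted to the integration window.
#' @param window integration window `c(on_ms, off_ms)` relative to R;
#'   default `[QRS_on, T_off)` from the attached windows.
#' @return list with `vg` (3-vector, mV.ms), `magnitude`,
#'   `azimuth_horizontal_deg`, `sagittal_angle_deg`,
#'   `sin_azimuth_horizontal`, `sin_sagittal`, `elevation_3d_deg`.
#'   Angles are `NA` when the relevant projection (or the whole vector)
#'   is numerically zero.
#' @export
ventricular_gradient <- function(traj, window = NULL) {
  fs <- attr(traj, "fs")
  if (is.null(window)) {
    gw <- attr(traj, "windows")
    if (is.null(gw) || is.na(gw$QRS_on_rel) || is.na(gw$T_off_rel)) {
      stop("QRS_on and T_off must be defined")
    }
    window <- c(gw$QRS_on_rel, gw$T_off_rel)
  }
  r <- attr(traj, "r_index")
  i0 <- max(1L, r + round(window[1L] / 1000 * fs))
  i1 <- min(nrow(traj) + 1L, r + round(window[2L] / 1000 * fs))
  seg <- traj[i0:(i1 - 1L), , drop = FALSE]
  vg <- colSums(seg) * 1000 / fs
  mag <- sqrt(sum(vg^2))
  if (mag < 1e-6) {
    return(list(vg = vg, magnitude = mag,
                azimuth_horizontal_deg = NA_real_,
                sagittal_angle_deg = NA_real_,
                sin_azimuth_horizontal = NA_real_,
                sin_sagittal = NA_real_, elevation_3d_deg = NA_real_))
  }
  hor <- sqrt(vg[1L]^2 + vg[3L]^2)
  sag <- sqrt(vg[2L]^2 + vg[3L]^2)
  list(
    vg = vg, magnitude = mag,
    azimuth_horizontal_deg = if (hor < 1e-9) NA_real_ else
      atan2(vg[3L], vg[1L]) * 180 / pi,
    sagittal_angle_deg = if (sag < 1e-9) NA_real_ else
      atan2(vg[3L], vg[2L]) * 180 / pi,
    sin_azimuth_horizontal = if (hor < 1e-9) NA_real_ else vg[3L] / hor,
    sin_sagittal = if (sag < 1e-9) NA_real_ else vg[3L] / sag,
    elevation_3d_deg = asin(min(1, max(-1, vg[3L] / mag))) * 180 / pi)
}

#' Scalar amplitudes of the derived VCG leads
#'
#' Signed extremum (largest absolute excursion, sign kept) of each VCG
#' axis within the QRS window, referenced to the window-onset value --
#' e.g. the R amplitude in lead Y.
#'
#' @param traj a `vcg_trajectory` with a QRS window attached, or pass
#'   `window = c(on_ms, off_ms)`.
#' @param window optional explicit QRS window.
#' @return named numeric vector `c(X = , Y = , Z = )` in mV.
#' @export
vcg_lead_scalars <- function(traj, window = NULL) {
  if (is.null(window)) {
    gw <- attr(traj, "windows")
    if (is.null(gw)) stop("trajectory carries no global windows")
    window <- c(gw$QRS_on_rel, gw$QRS_off_rel)
  }
  loop <- extract_loop(traj, window)
  vapply(1:3, function(j) {
    v <- loop[, j]
    v[which.max(abs(v))]
  }, numeric(1)) -> out
  names(out) <- c("X", "Y", "Z")
  out
}

#' Registry of the 41 VCG-derived features
#'
#' @return character vector of the 41 feature names, order stable.
#' @export
vcg_feature_names <- function() {
  per_loop <- c("ln_sigma1", "ln_sigma2", "sigma3", "sigma2_over_sigma1",
                "ln_nondipolar_ratio", "planarity", "peak_magnitude_mV",
                "time_to_peak_ms", "time_voltage_area_mVms",
                "max_to_mean_ratio")
  c(paste0(rep(c("P", "QRS", "T"), each = length(per_loop)), "_",
           rep(per_loop, 3L)),
    "angle_P_QRS_mean_deg", "angle_QRS_T_mean_deg",
    "angle_QRS_T_eigvec1_deg",
    "vg_magnitude_mVms", "vg_azimuth_horizontal_deg",
    "vg_sagittal_angle_deg", "vg_sin_azimuth_horizontal",
    "vg_sin_sagittal", "vg_elevation_deg",
    "R_amp_Y_mV", "R_amp_Z_mV")
}

#' Compute all 41 VCG features
#'
#' Deterministic registry covering, per P/QRS/T loop: log dipolar
#' amplitude (ln sigma1), ln sigma2, sigma3, sigma2/sigma1, ln
#' non-dipolar-to-dipolar ratio, planarity (sigma3/sigma1), peak spatial
#' magnitude, time-to-peak (ventricular activation time for QRS),
#' time-voltage area, max-to-mean spatial ratio; plus P-QRS and QRS-T
#' mean-vector angles, the QRS-T first-eigenvector angle, ventricular
#' gradient magnitude/direction, and the R amplitudes in derived leads Y
#' and Z.  Absent loops (e.g. no detectable P wave) yield missing values,
#' never fabricated numbers.
#'
#' @param matrix a [assemble_calibrated_matrix()] result (with windows
#'   attached).
#' @param K 3 x 8 transform, default [kors_matrix()].
#' @return named numeric vector of length 41 (names =
#'   [vcg_feature_names()]).
#' @export
compute_all_vcg_features <- function(matrix, K = kors_matrix()) {
  traj <- kors_transform(matrix, K)
  gw <- attr(traj, "windows")
  if (is.null(gw)) stop("median-beat matrix carries no global windows")
  out <- stats::setNames(rep(NA_real_, length(vcg_feature_names())),
                         vcg_feature_names())
  loops <- list()
  for (w in c("P", "QRS", "T")) {
    lims <- switch(w, P = c(gw$P_on_rel, gw$P_off_rel),
                   QRS = c(gw$QRS_on_rel, gw$QRS_off_rel),
                   T = c(gw$T_on_rel, gw$T_off_rel))
    if (any(is.na(lims))) next
    # isoelectric origin: the median beats are PR-referenced, and a
    # delineated onset a few ms inside the wave support must not
    # displace the loop origin into the wave
    loop <- try(extract_loop(traj, lims, translate = FALSE),
                silent = TRUE)
    if (inherits(loop, "try-error") || nrow(loop) < 3L) next
    sv <- loop_svd(loop)
    mf <- loop_magnitude_features(loop, attr(traj, "fs"))
    loops[[w]] <- list(sv = sv, mf = mf)
    pre <- paste0(w, "_")
    out[paste0(pre, "ln_sigma1")] <- sv$ln_sigma1
    out[paste0(pre, "ln_sigma2")] <- if (sv$sigma2 < 1e-12) NA_real_ else
      log(sv$sigma2)
    out[paste0(pre, "sigma3")] <- sv$sigma3
    out[paste0(pre, "sigma2_over_sigma1")] <- sv$sigma2_over_sigma1
    out[paste0(pre, "ln_nondipolar_ratio")] <- sv$ln_nondipolar_ratio
    out[paste0(pre, "planarity")] <- sv$planarity
    out[paste0(pre, "peak_magnitude_mV")] <- mf$peak_magnitude
    out[paste0(pre, "time_to_peak_ms")] <- mf$time_to_peak
    out[paste0(pre, "time_voltage_area_mVms")] <- mf$time_voltage_area
    out[paste0(pre, "max_to_mean_ratio")] <- mf$max_to_mean_ratio
  }
  if (!is.null(loops$P) && !is.null(loops$QRS)) {
    out["angle_P_QRS_mean_deg"] <-
      spatial_angle(loops$P$mf$mean_vector, loops$QRS$mf$mean_vector)
  }
  if (!is.null(loops$QRS) && !is.null(loops$T)) {
    out["angle_QRS_T_mean_deg"] <-
      spatial_angle(loops$QRS$mf$mean_vector, loops$T$mf$mean_vector)
    out["angle_QRS_T_eigvec1_deg"] <-
      spatial_angle(loops$QRS$sv$eigvec1, loops$T$sv$eigvec1)
  }
  if (!is.na(gw$QRS_on_rel) && !is.na(gw$T_off_rel)) {
    vg <- ventricular_gradient(traj)
    out["vg_magnitude_mVms"] <- vg$magnitude
    out["vg_azimuth_horizontal_deg"] <- vg$azimuth_horizontal_deg
    out["vg_sagittal_angle_deg"] <- vg$sagittal_angle_deg
    out["vg_sin_azimuth_horizontal"] <- vg$sin_azimuth_horizontal
    out["vg_sin_sagittal"] <- vg$sin_sagittal
    out["vg_elevation_deg"] <- vg$elevation_3d_deg
  }
  if (!is.na(gw$QRS_on_rel) && !is.na(gw$QRS_off_rel)) {
    sc <- vcg_lead_scalars(traj)
    out["R_amp_Y_mV"] <- sc[["Y"]]
    out["R_amp_Z_mV"] <- sc[["Z"]]
  }
  out
}
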