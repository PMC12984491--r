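# Synthetic 12-lead ECG cohorts from parametric 3D dipole loops.  Each
# wave (P, QRS, T) is a planar-ish loop
#   v(t) = b1(t) w1 + b2(t) w2 + b3(t) w3
# with b1 = e(s) cos(phi), b2 = e(s) sin(phi), b3 = e(s) sin(2 phi),
# phi = pi (2 s - 1), and a half-sine envelope e(s) = sin(pi s^gamma)
# (gamma skews the wave; gamma = 1 is symmetric).  w1, w2, w3 are
# orthogonal dipole vectors; their magnitudes are calibrated numerically
# so injected targets (lead R amplitudes, loop sigma2/sigma1, T-loop
# ln sigma1, ventricular-gradient direction) are achieved by measurement.
# Leads are the Moore-Penrose right-inverse projection of the Kors
# matrix, so the Kors transform recovers the dipole exactly.

wave_basis <- function(n, gamma = 1) {
  s <- (seq_len(n) - 0.5) / n
  e <- sin(pi * s^gamma)
  phi <- pi * (2 * s - 1)
  b1 <- e * cos(phi); b2 <- e * sin(phi); b3 <- e * sin(2 * phi)
  # remove the net time integral of the secondary axes (projected onto
  # the main-axis profile) so only w1 carries net area: this makes the
  # ventricular-gradient contribution of a wave exactly
  # sum(b1) * w1 * dt, which the direction steering relies on
  s1 <- sum(b1)
  if (abs(s1) > 1e-9) {
    b2 <- b2 - (sum(b2) / s1) * b1
    b3 <- b3 - (sum(b3) / s1) * b1
  }
  cbind(b1 = b1, b2 = b2, b3 = b3)
}

# second-moment (Gram) matrix of the basis, used for sigma calibration
wave_gram <- function(n, gamma = 1) {
  B <- wave_basis(n, gamma)
  crossprod(B) / n
}

# achieved singular values (unit main amplitude) for scales (1, ecc, beta)
wave_sigmas <- function(G, ecc, beta) {
  S <- diag(c(1, ecc, beta))
  sqrt(pmax(eigen(S %*% G %*% S, symmetric = TRUE,
                  only.values = TRUE)$values, 0))
}

# calibrate the internal eccentricity so the measured sigma2/sigma1 of the
# loop equals the target ratio
calibrate_ecc <- function(G, ratio, beta) {
  if (ratio <= 0) return(0)
  f <- function(e) {
    sg <- wave_sigmas(G, e, beta)
    sg[2L] / sg[1L] - ratio
  }
  hi <- 1.5
  if (f(hi) < 0) return(hi)
  if (f(0) >= 0) return(0)   # non-planarity floor already exceeds target
  stats::uniroot(f, c(0, hi), tol = 1e-6)$root
}

#' Resolved per-wave loop parameters
#'
#' Low-level constructor for one wave of the forward model.
#'
#' @param t_on_ms,t_off_ms support relative to the R time (signed ms).
#' @param w1,w2,w3 orthogonal dipole vectors (mV); `w1` is the main axis.
#' @param gamma envelope skew (1 = symmetric; > 1 late peak).
#' @return list of class `wave_loop_params`.
#' @export
wave_loop_params <- function(t_on_ms, t_off_ms, w1, w2 = c(0, 0, 0),
                             w3 = c(0, 0, 0), gamma = 1) {
  stopifnot(t_on_ms < t_off_ms)
  structure(list(t_on_ms = t_on_ms, t_off_ms = t_off_ms, w1 = w1,
                 w2 = w2, w3 = w3, gamma = gamma),
            class = "wave_loop_params")
}

#' Build one beat's 3D dipole trajectory
#'
#' Renders the configured waves into an 850 ms trajectory with the R time
#' at `pre_ms` (default 300 ms) from window start.  Overlapping wave
#' supports are an error.
#'
#' @param params named list of `wave_loop_params` (e.g. P, QRS, T).
#' @param fs Hz.
#' @param pre_ms,post_ms window split around R; must total 850 ms.
#' @return W x 3 matrix (mV) with attributes `fs`, `r_index`.
#' @export
make_beat_trajectory <- function(params, fs, pre_ms = 300, post_ms = 550) {
  W <- round((pre_ms + post_ms) / 1000 * fs)
  r <- round(pre_ms / 1000 * fs) + 1L
  v <- matrix(0, W, 3L)
  spans <- t(vapply(params, function(p) c(p$t_on_ms, p$t_off_ms),
                    numeric(2)))
  if (nrow(spans) > 1L) {
    o <- order(spans[, 1L])
    if (any(spans[o, 1L][-1L] < spans[o, 2L][-nrow(spans)] - 1e-9)) {
      stop("overlapping wave supports")
    }
  }
  for (p in params) {
    i0 <- r + round(p$t_on_ms / 1000 * fs)
    i1 <- r + round(p$t_off_ms / 1000 * fs) - 1L
    if (i0 < 1L || i1 > W) stop("wave support outside the beat window")
    n <- i1 - i0 + 1L
    if (n < 2L) next
    B <- wave_basis(n, p$gamma)
    v[i0:i1, ] <- v[i0:i1, ] +
      B %*% rbind(p$w1, p$w2, p$w3)
  }
  structure(v, fs = fs, r_index = r,
            dimnames = list(NULL, c("X", "Y", "Z")))
}

#' Project a dipole trajectory onto the 8 independent leads
#'
#' leads = L v with L the Moore-Penrose right-inverse of K, so
#' `kors_transform(project_to_leads(v))` returns `v` exactly.
#'
#' @param v N x 3 trajectory (mV).
#' @param K 3 x 8 transform.
#' @return named list of 8 lead series.
#' @export
project_to_leads <- function(v, K = kors_matrix()) {
  L <- kors_right_inverse(K)
  out <- L %*% t(v)
  stats::setNames(lapply(seq_len(nrow(out)), function(i) out[i, ]),
                  vcg_independent_leads())
}

# truncated-normal draw (simple clip; SDs are small relative to bounds)
rnorm_clip <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Phenotype profile for the synthetic generator
#'
#' Central values and dispersions for every generator parameter.  The
#' presets in [cohort_presets()] encode the group differences reported
#' for hypertrophic vs dilated cardiomyopathy phenotypes; this
#' constructor exposes every knob for custom worlds.
#'
#' @param name profile/label name.
#' @param rr_mean_ms,rr_sd_ms between-record RR centre and SD;
#'   `rr_jitter_ms` within-record beat-to-beat SD.
#' @param tachy_prob,tachy_rr_ms probability and RR centre of a
#'   sinus-tachycardia record.
#' @param noise_sd_mv,wander_amp_mv,wander_freq_hz additive white noise
#'   and sinusoidal baseline wander.
#' @param qrs_targets named centres: lead R amplitudes (named by lead),
#'   `y_amp` (R amplitude in derived lead Y), optional `sv1` (S depth in
#'   V1).  `qrs_targets_sd` the matching SDs.
#' @param qrs_dur_ms,p_dur_ms,t_dur_ms wave durations (centre, sd).
#' @param qrs_ecc,t_ecc,p_ecc loop sigma2/sigma1 targets (centre, sd).
#' @param beta non-planarity weight (centre, sd).
#' @param t_ln_sigma1 T-loop log dipolar amplitude target (centre, sd).
#' @param t_index T upslope/downslope ratio (centre, sd).
#' @param p_amp_mv P-loop peak magnitude (centre, sd).
#' @param vg_sin_sagittal,vg_sin_horizontal ventricular-gradient
#'   direction targets (sines of the plane angles); `vg_jitter_deg`
#'   per-record angular jitter.
#' @param pr_gap_ms,st_gap_ms isoelectric gaps (centre, sd).
#' @param n_records default cohort size for this profile.
#' @return list of class `phenotype_profile`.
#' @export
phenotype_profile <- function(name,
                              rr_mean_ms = c(850, 80), rr_jitter_ms = 10,
                              tachy_prob = 0.1, tachy_rr_ms = c(545, 25),
                              noise_sd_mv = 0.01, wander_amp_mv = 0.05,
                              wander_freq_hz = 0.25,
                              qrs_targets = c(I = 0.55, V5 = 0.84,
                                              y_amp = 0.5),
                              qrs_targets_sd = c(I = 0.18, V5 = 0.25,
                                                 y_amp = 0.15),
                              qrs_dur_ms = c(86, 10),
                              p_dur_ms = c(110, 12),
                              t_dur_ms = c(265, 25),
                              qrs_ecc = c(0.38, 0.1),
                              t_ecc = c(0.18, 0.06),
                              p_ecc = c(0.4, 0.08),
                              beta = c(0.1, 0.03),
                              t_ln_sigma1 = c(-0.04, 0.3),
                              t_index = c(1.13, 0.2),
                              p_amp_mv = c(0.12, 0.03),
                              vg_sin_sagittal = -0.06,
                              vg_sin_horizontal = -0.04,
                              vg_jitter_deg = 9,
                              pr_gap_ms = c(48, 8), st_gap_ms = c(80, 10),
                              n_records = 50L) {
  rr_sd_ms <- rr_mean_ms[2L]; rr_mean_ms <- rr_mean_ms[1L]
  structure(as.list(environment()), class = "phenotype_profile")
}

#' Phenotype presets
#'
#' Preset central values follow the reported group medians (lead
#' amplitudes, QRS durations, T-loop log amplitudes, ventricular-gradient
#' angle sines, RR and tachycardia fractions for the dilated phenotypes;
#' V6/V1 amplitudes, sigma2/sigma1 and P duration for the obstructive vs
#' non-obstructive split); dispersions come from the printed
#' interquartile ranges where available, otherwise a 20% coefficient of
#' variation.
#'
#' @return named list of [phenotype_profile()] objects: HCM, DCM_I,
#'   DCM_NI, NORMAL, HOCM, HNCM.
#' @export
cohort_presets <- function() {
  list(
    HCM = phenotype_profile(
      "HCM",
      qrs_targets = c(I = 0.76, V5 = 0.80, y_amp = 0.55),
      qrs_targets_sd = c(I = 0.25, V5 = 0.30, y_amp = 0.20),
      qrs_dur_ms = c(92, 14), qrs_ecc = c(0.38, 0.10),
      t_ln_sigma1 = c(-0.01, 0.35), t_ecc = c(0.25, 0.08),
      t_index = c(1.27, 0.25), t_dur_ms = c(270, 28),
      vg_sin_sagittal = 0.31, vg_sin_horizontal = 0.23,
      rr_mean_ms = c(850, 90), tachy_prob = 0.12),
    DCM_I = phenotype_profile(
      "DCM_I",
      qrs_targets = c(I = 0.41, V5 = 0.39, y_amp = 0.30),
      qrs_targets_sd = c(I = 0.18, V5 = 0.18, y_amp = 0.15),
      qrs_dur_ms = c(107, 15), qrs_ecc = c(0.40, 0.10),
      t_ln_sigma1 = c(-0.53, 0.35), t_ecc = c(0.32, 0.10),
      t_index = c(1.40, 0.30), t_dur_ms = c(260, 26),
      vg_sin_sagittal = 0.87, vg_sin_horizontal = 0.77,
      rr_mean_ms = c(820, 90), tachy_prob = 0.12),
    DCM_NI = phenotype_profile(
      "DCM_NI",
      qrs_targets = c(I = 0.51, V5 = 0.76, y_amp = 0.35),
      qrs_targets_sd = c(I = 0.20, V5 = 0.25, y_amp = 0.15),
      qrs_dur_ms = c(102, 14), qrs_ecc = c(0.40, 0.10),
      t_ln_sigma1 = c(-0.58, 0.35), t_ecc = c(0.31, 0.10),
      t_index = c(2.24, 0.40), t_dur_ms = c(230, 24),
      vg_sin_sagittal = 0.86, vg_sin_horizontal = 0.68,
      rr_mean_ms = c(681, 70), tachy_prob = 0.27),
    NORMAL = phenotype_profile(
      "NORMAL",
      qrs_targets = c(I = 0.55, V5 = 0.84, y_amp = 0.50),
      qrs_targets_sd = c(I = 0.18, V5 = 0.25, y_amp = 0.15),
      qrs_dur_ms = c(86, 10), qrs_ecc = c(0.38, 0.10),
      t_ln_sigma1 = c(-0.04, 0.30), t_ecc = c(0.18, 0.06),
      t_index = c(1.13, 0.20), t_dur_ms = c(265, 25),
      vg_sin_sagittal = -0.06, vg_sin_horizontal = -0.04,
      rr_mean_ms = c(900, 90), tachy_prob = 0.05),
    HOCM = phenotype_profile(
      "HOCM",
      qrs_targets = c(I = 0.70, V6 = 0.88, y_amp = 0.35, sv1 = 0.86),
      qrs_targets_sd = c(I = 0.25, V6 = 0.49, y_amp = 0.38, sv1 = 0.50),
      qrs_dur_ms = c(96, 13), qrs_ecc = c(0.32, 0.20),
      p_dur_ms = c(108, 15.6),
      t_ln_sigma1 = c(-0.10, 0.30), t_ecc = c(0.25, 0.08),
      t_index = c(1.27, 0.25),
      vg_sin_sagittal = 0.31, vg_sin_horizontal = 0.23,
      rr_mean_ms = c(850, 90), tachy_prob = 0.12),
    HNCM = phenotype_profile(
      "HNCM",
      qrs_targets = c(I = 0.55, V6 = 0.66, y_amp = 0.19, sv1 = 0.66),
      qrs_targets_sd = c(I = 0.25, V6 = 0.36, y_amp = 0.36, sv1 = 0.47),
      qrs_dur_ms = c(96, 13), qrs_ecc = c(0.44, 0.21),
      p_dur_ms = c(120, 19.6),
      t_ln_sigma1 = c(-0.10, 0.30), t_ecc = c(0.25, 0.08),
      t_index = c(1.27, 0.25),
      vg_sin_sagittal = 0.31, vg_sin_horizontal = 0.23,
      rr_mean_ms = c(850, 90), tachy_prob = 0.12))
}

# unit direction with the requested plane-angle sines
vg_direction_from_sines <- function(sin_sag, sin_hor) {
  sgn <- if (sin_sag + sin_hor >= 0) 1 else -1
  z <- sgn
  sh <- max(abs(sin_hor), 1e-3); ss <- max(abs(sin_sag), 1e-3)
  x <- abs(z) * sqrt(1 - min(sin_hor^2, 1)) / sh
  y <- abs(z) * sqrt(1 - min(sin_sag^2, 1)) / ss
  d <- c(x, y, z)
  d / sqrt(sum(d^2))
}

jitter_direction <- function(d, sd_deg) {
  d <- d + stats::rnorm(3L, 0, sin(sd_deg * pi / 180))
  d / sqrt(sum(d^2))
}

# orthonormal basis of the plane perpendicular to unit vector u
perp_basis <- function(u) {
  a <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2L] * e1[3L] - u[3L] * e1[2L],
          u[3L] * e1[1L] - u[1L] * e1[3L],
          u[1L] * e1[2L] - u[2L] * e1[1L])
  cbind(e1, e2)
}

# resolve one record's drawn parameters into wave_loop_params + targets
draw_record_params <- function(profile, fs) {
  pf <- profile
  for (attempt in 1:20) {
    tachy <- stats::runif(1) < pf$tachy_prob
    rr <- if (tachy) {
      rnorm_clip(1, pf$tachy_rr_ms[1L], pf$tachy_rr_ms[2L], 480, 595)
    } else {
      rnorm_clip(1, pf$rr_mean_ms, pf$rr_sd_ms, 605, 1400)
    }
    qrs_dur <- rnorm_clip(1, pf$qrs_dur_ms[1L], pf$qrs_dur_ms[2L], 60, 160)
    p_dur <- rnorm_clip(1, pf$p_dur_ms[1L], pf$p_dur_ms[2L], 70, 170)
    t_dur <- rnorm_clip(1, pf$t_dur_ms[1L], pf$t_dur_ms[2L], 150, 360)
    pr_gap <- rnorm_clip(1, pf$pr_gap_ms[1L], pf$pr_gap_ms[2L], 25, 90)
    st_gap <- rnorm_clip(1, pf$st_gap_ms[1L], pf$st_gap_ms[2L], 40, 130)
    # shorten repolarization at high rate so consecutive beats never
    # collide (rate-dependent QT)
    t_off <- qrs_dur / 2 + st_gap + t_dur
    t_off_max <- 0.45 * rr
    if (t_off > t_off_max) {
      sc <- (t_off_max - qrs_dur / 2) / (st_gap + t_dur)
      if (sc < 0.55) next               # infeasibly fast for this beat
      st_gap <- st_gap * sc; t_dur <- t_dur * sc
      t_off <- qrs_dur / 2 + st_gap + t_dur
    }
    p_off <- -qrs_dur / 2 - pr_gap
    p_on <- p_off - p_dur
    if (p_on < -290 || p_off > -qrs_dur / 2 - 20) next
    if (rr - t_off < p_dur + pr_gap + qrs_dur / 2 + 30) next
    break
  }
  if (attempt == 20L && (t_off > 0.45 * rr + 1e-6 || p_on < -290)) {
    stop("infeasible parameter draw for ", pf$name)
  }

  L <- kors_right_inverse()
  # main QRS dipole from lead-amplitude targets (3 linear constraints)
  tg <- pf$qrs_targets; tg_sd <- pf$qrs_targets_sd
  lead_tg <- setdiff(names(tg), c("y_amp", "sv1"))
  drawn <- stats::setNames(vapply(names(tg), function(nm) {
    stats::rnorm(1, tg[[nm]], tg_sd[[nm]])
  }, numeric(1)), names(tg))
  M <- rbind(L[lead_tg[1L], ], L[lead_tg[2L], ], c(0, 1, 0))
  rhs <- c(drawn[[lead_tg[1L]]], drawn[[lead_tg[2L]]], drawn[["y_amp"]])
  w1q <- as.numeric(solve(M, rhs))
  Aq <- sqrt(sum(w1q^2))
  if (Aq < 0.05) { w1q <- w1q * (0.05 / max(Aq, 1e-9)); Aq <- 0.05 }
  u1q <- w1q / Aq
  nq <- max(4L, round(qrs_dur / 1000 * fs))
  Gq <- wave_gram(nq, 1)
  ecc_q <- rnorm_clip(1, pf$qrs_ecc[1L], pf$qrs_ecc[2L], 0.02, 0.9)
  beta_q <- rnorm_clip(1, pf$beta[1L], pf$beta[2L], 0.01, 0.35)
  ecc_int <- calibrate_ecc(Gq, ecc_q, beta_q)
  P2 <- perp_basis(u1q)
  theta <- stats::runif(1, 0, 2 * pi)
  if ("sv1" %in% names(tg)) {
    # phase the secondary axis so the late loop limb projects onto V1
    # with the requested S depth
    B <- wave_basis(nq, 1)
    m_pos <- max(B[, "b2"])
    q_target <- -drawn[["sv1"]] / max(m_pos, 1e-9)
    a <- as.numeric(L["V1", ] %*% P2)     # c(c1, c2)
    rho <- sqrt(sum(a^2)) * Aq * ecc_int
    theta0 <- atan2(a[2L], a[1L])
    if (rho > 1e-9) {
      cosd <- max(-1, min(1, q_target / rho))
      theta <- theta0 + acos(cosd)
    }
  }
  u2q <- as.numeric(P2 %*% c(cos(theta), sin(theta)))
  u3q <- c(u1q[2L] * u2q[3L] - u1q[3L] * u2q[2L],
           u1q[3L] * u2q[1L] - u1q[1L] * u2q[3L],
           u1q[1L] * u2q[2L] - u1q[2L] * u2q[1L])
  qrs <- wave_loop_params(-qrs_dur / 2, qrs_dur / 2, w1 = Aq * u1q,
                          w2 = Aq * ecc_int * u2q, w3 = Aq * beta_q * u3q)

  # T wave: amplitude from the ln sigma1 target, direction steering the
  # ventricular gradient toward the profile's target orientation
  ti <- rnorm_clip(1, pf$t_index[1L], pf$t_index[2L], 0.6, 3.5)
  s_pk <- ti / (1 + ti)
  gamma_t <- log(0.5) / log(s_pk)
  nt <- max(4L, round(t_dur / 1000 * fs))
  Gt <- wave_gram(nt, gamma_t)
  ecc_t <- rnorm_clip(1, pf$t_ecc[1L], pf$t_ecc[2L], 0.02, 0.8)
  beta_t <- rnorm_clip(1, pf$beta[1L], pf$beta[2L], 0.01, 0.35) * 0.6
  ecc_t_int <- calibrate_ecc(Gt, ecc_t, beta_t)
  lns1 <- stats::rnorm(1, pf$t_ln_sigma1[1L], pf$t_ln_sigma1[2L])
  sg_unit <- wave_sigmas(Gt, ecc_t_int, beta_t)
  At <- exp(lns1) / max(sg_unit[1L], 1e-9)
  dt_ms <- 1000 / fs
  Bq <- wave_basis(nq, 1)
  iq <- colSums(Bq %*% rbind(qrs$w1, qrs$w2, qrs$w3)) * dt_ms
  Bt <- wave_basis(nt, gamma_t)
  c1 <- At * sum(Bt[, "b1"]) * dt_ms
  # jitter the plane angles themselves (not the Cartesian components,
  # whose perturbation would blow up the sines near small values)
  jr <- pf$vg_jitter_deg * pi / 180
  th_s <- asin(max(-1, min(1, pf$vg_sin_sagittal))) + stats::rnorm(1, 0, jr)
  th_h <- asin(max(-1, min(1, pf$vg_sin_horizontal))) + stats::rnorm(1, 0, jr)
  dvg <- vg_direction_from_sines(sin(th_s), sin(th_h))
  dp <- sum(dvg * iq)
  disc <- dp^2 - sum(iq^2) + c1^2
  u1t <- if (disc >= 0) {
    m <- dp + sqrt(disc)
    w <- m * dvg - iq
    w / sqrt(sum(w^2))
  } else {
    w <- dp * dvg - iq
    w / sqrt(sum(w^2))
  }
  P2t <- perp_basis(u1t)
  th_t <- stats::runif(1, 0, 2 * pi)
  u2t <- as.numeric(P2t %*% c(cos(th_t), sin(th_t)))
  u3t <- c(u1t[2L] * u2t[3L] - u1t[3L] * u2t[2L],
           u1t[3L] * u2t[1L] - u1t[1L] * u2t[3L],
           u1t[1L] * u2t[2L] - u1t[2L] * u2t[1L])
  tw <- wave_loop_params(qrs_dur / 2 + st_gap,
                         qrs_dur / 2 + st_gap + t_dur,
                         w1 = At * u1t, w2 = At * ecc_t_int * u2t,
                         w3 = At * beta_t * u3t, gamma = gamma_t)

  # P wave: modest left-inferior loop
  Ap <- rnorm_clip(1, pf$p_amp_mv[1L], pf$p_amp_mv[2L], 0.06, 0.3)
  u1p <- jitter_direction(c(0.45, 0.85, 0.2) / sqrt(sum(c(0.45, 0.85,
                                                          0.2)^2)), 8)
  np <- max(4L, round(p_dur / 1000 * fs))
  ecc_p <- rnorm_clip(1, pf$p_ecc[1L], pf$p_ecc[2L], 0.05, 0.8)
  ecc_p_int <- calibrate_ecc(wave_gram(np, 1.1), ecc_p, 0.02)
  P2p <- perp_basis(u1p)
  th_p <- stats::runif(1, 0, 2 * pi)
  u2p <- as.numeric(P2p %*% c(cos(th_p), sin(th_p)))
  pw <- wave_loop_params(p_on, p_off, w1 = Ap * u1p,
                         w2 = Ap * ecc_p_int * u2p, gamma = 1.1)

  list(waves = list(P = pw, QRS = qrs, T = tw),
       rr_ms = rr, tachy = tachy, qrs_dur_ms = qrs_dur,
       p_dur_ms = p_dur, t_dur_ms = t_dur, t_index = ti,
       drawn_targets = drawn, vg_target_dir = dvg,
       vg_steer_feasible = disc >= 0)
}

#' Synthesize one labeled ECG record with ground truth
#'
#' Draws record parameters from the profile distributions, tiles beats
#' at jittered RR intervals across a 10 s, 500 Hz record, projects the
#' dipole onto the 8 independent leads (plus Goldberger limb leads), and
#' adds white noise and sinusoidal baseline wander.  Deterministic given
#' `(profile, seed)`.
#'
#' @param profile a [phenotype_profile()].
#' @param seed integer seed.
#' @param duration_s record length.
#' @param fs Hz.
#' @param K 3 x 8 lead transform.
#' @return list with `record` (an [ecg_record()]) and `truth`: record-
#'   level feature ground truth (`features`), the realized wave supports
#'   (`windows_ms`, ms relative to R), absolute R times (`r_times`),
#'   per-lead per-beat clean-signal peak locations (`lead_peaks`), and
#'   the drawn parameters (`params`).
#' @export
synthesize_record <- function(profile, seed, duration_s = 10, fs = 500,
                              K = kors_matrix()) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed %% 2147483647L))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  par <- draw_record_params(profile, fs)
  N <- round(duration_s * fs)
  wv <- par$waves
  p_on_s <- round(wv$P$t_on_ms / 1000 * fs)
  t_off_s <- round(wv$T$t_off_ms / 1000 * fs)

  # beat times
  r_times <- integer(0)
  r <- round(0.5 * fs) + abs(p_on_s)
  repeat {
    if (r + t_off_s + 5L > N) break
    r_times <- c(r_times, r)
    rr_k <- max(450, par$rr_ms + stats::rnorm(1, 0, profile$rr_jitter_ms))
    r <- r + round(rr_k / 1000 * fs)
  }
  if (length(r_times) < 3L) stop("record too short for the drawn RR")

  # render the dipole trajectory
  v <- matrix(0, N, 3L)
  wave_cache <- lapply(wv, function(p) {
    n <- round(p$t_off_ms / 1000 * fs) - round(p$t_on_ms / 1000 * fs)
    if (n < 2L) return(NULL)
    wave_basis(n, p$gamma) %*% rbind(p$w1, p$w2, p$w3)
  })
  for (r in r_times) {
    for (nm in names(wv)) {
      seg <- wave_cache[[nm]]
      if (is.null(seg)) next
      i0 <- r + round(wv[[nm]]$t_on_ms / 1000 * fs)
      idx <- i0:(i0 + nrow(seg) - 1L)
      v[idx, ] <- v[idx, ] + seg
    }
  }

  leads8 <- project_to_leads(v, K)
  clean8 <- leads8
  tvec <- seq_len(N) / fs
  for (nm in names(leads8)) {
    x <- leads8[[nm]]
    if (profile$wander_amp_mv > 0) {
      x <- x + profile$wander_amp_mv *
        sin(2 * pi * profile$wander_freq_hz * tvec + stats::runif(1, 0, 2 * pi))
    }
    if (profile$noise_sd_mv > 0) {
      x <- x + stats::rnorm(N, 0, profile$noise_sd_mv)
    }
    leads8[[nm]] <- x
  }
  rec <- ecg_record(leads8, fs, record_id = sprintf("%s_%06d",
                                                    profile$name, seed),
                    label = profile$name,
                    report_text = "sinus rhythm, synthetic record")

  truth <- synth_truth(v, clean8, wv, r_times, par, fs, K)
  list(record = rec, truth = truth)
}

# ground truth computed from the clean forward model (true windows, true
# trajectory) -- independent of the detection pipeline
synth_truth <- function(v, clean8, wv, r_times, par, fs, K) {
  r0 <- r_times[2L]                # a fully interior beat
  W <- round(0.85 * fs)
  pre <- round(0.3 * fs)
  beat <- v[(r0 - pre):(r0 - pre + W - 1L), , drop = FALSE]
  traj <- structure(beat, fs = fs, r_index = pre + 1L,
                    class = c("vcg_trajectory", "matrix", "array"))
  win <- list(P = c(wv$P$t_on_ms, wv$P$t_off_ms),
              QRS = c(wv$QRS$t_on_ms, wv$QRS$t_off_ms),
              T = c(wv$T$t_on_ms, wv$T$t_off_ms))
  feats <- list()
  for (nm in names(win)) {
    loop <- extract_loop(traj, win[[nm]], translate = FALSE)
    sv <- loop_svd(loop)
    mf <- loop_magnitude_features(loop, fs)
    feats[[paste0(nm, "_sigma2_over_sigma1")]] <- sv$sigma2_over_sigma1
    feats[[paste0(nm, "_ln_sigma1")]] <- sv$ln_sigma1
    feats[[paste0(nm, "_peak_magnitude_mV")]] <- mf$peak_magnitude
  }
  vg <- ventricular_gradient(traj, c(wv$QRS$t_on_ms, wv$T$t_off_ms))
  feats$vg_azimuth_horizontal_deg <- vg$azimuth_horizontal_deg
  feats$vg_sagittal_angle_deg <- vg$sagittal_angle_deg
  feats$vg_sin_sagittal <- vg$sin_sagittal
  feats$vg_sin_azimuth_horizontal <- vg$sin_azimuth_horizontal
  feats$vg_elevation_deg <- vg$elevation_3d_deg

  ms2s <- function(x) round(x / 1000 * fs)
  # per-lead true peak/amplitude values from the clean lead signals
  all_leads <- c(clean8, derive_augmented_leads(clean8$I, clean8$II))
  lead_peaks <- lapply(all_leads, function(x) {
    do.call(rbind, lapply(r_times, function(r) {
      seg_idx <- function(a, b) (r + ms2s(a)):(r + ms2s(b) - 1L)
      pk <- function(w) {
        i <- seg_idx(wv[[w]]$t_on_ms, wv[[w]]$t_off_ms)
        i[which.max(abs(x[i]))]
      }
      qi <- seg_idx(wv$QRS$t_on_ms, wv$QRS$t_off_ms)
      # same R convention as the extraction: positive deflection when one
      # exists, else the dominant (QS) deflection
      rj <- if (max(x[qi]) > 0.015) which.max(x[qi]) else
        which.max(abs(x[qi]))
      # the measurable per-lead QRS support: where this lead's projection
      # exceeds the pipeline's amplitude floor (a lead can vanish faster
      # than the nominal support at the edges)
      vis <- which(abs(x[qi]) > 0.02)
      qrs_on_l <- if (length(vis)) qi[vis[1L]] else qi[1L]
      qrs_off_l <- if (length(vis)) qi[vis[length(vis)]] else
        qi[length(qi)]
      data.frame(r_center = r, P_peak = pk("P"), R_peak = qi[rj],
                 T_peak = pk("T"),
                 QRS_on = qrs_on_l, QRS_off = qrs_off_l,
                 R_amp = x[qi[rj]],
                 S_amp = max(0, -min(x[qi])))
    }))
  })
  feats$QRS_duration <- par$qrs_dur_ms
  feats$P_duration <- par$p_dur_ms
  feats$T_index <- par$t_index
  feats$median_RR <- par$rr_ms
  for (lead in c("I", "V5", "V6")) {
    feats[[paste0("R_amp_", lead)]] <-
      stats::median(lead_peaks[[lead]]$R_amp)
  }
  feats$S_amp_V1 <- stats::median(lead_peaks$V1$S_amp)
  list(features = unlist(feats), windows_ms = win, r_times = r_times,
       lead_peaks = lead_peaks, tachy = par$tachy, params = par)
}

#' Generate a labeled synthetic cohort
#'
#' @param profiles named list of [phenotype_profile()]s (duplicate names
#'   are an error).
#' @param n_per records per profile (recycled; default each profile's
#'   `n_records`).
#' @param seed master seed; record seeds are derived deterministically.
#' @param dir if non-`NULL`, records are also written as WFDB (or CSV)
#'   under this directory and the manifest's `path` column points at
#'   them.
#' @param format `"wfdb"` or `"csv"` when `dir` is given.
#' @return list with `records` (list of [ecg_record()]), `manifest`
#'   (data.frame), `truth` (data.frame of ground-truth features, one row
#'   per record) and `truth_full` (per-record truth objects).
#' @export
generate_cohort <- function(profiles, n_per = NULL, seed = 20250719L,
                            dir = NULL, format = c("wfdb", "csv")) {
  format <- match.arg(format)
  if (anyDuplicated(names(profiles))) stop("duplicate profile names")
  if (is.null(n_per)) {
    n_per <- vapply(profiles, function(p) as.integer(p$n_records),
                    integer(1))
  } else {
    n_per <- rep_len(as.integer(n_per), length(profiles))
  }
  records <- list(); truth_full <- list()
  man <- list(); tr <- list()
  k <- 0L
  for (j in seq_along(profiles)) {
    pf <- profiles[[j]]
    for (i in seq_len(n_per[j])) {
      k <- k + 1L
      rec_seed <- (seed + 7919L * j + i) %% 2147483647L
      out <- synthesize_record(pf, rec_seed)
      rid <- sprintf("%s_%03d", pf$name, i)
      out$record$record_id <- rid
      out$record$patient_id <- rid
      path <- ""
      if (!is.null(dir)) {
        if (format == "wfdb") {
          path <- paste0(write_wfdb(out$record, dir), ".hea")
        } else {
          path <- file.path(dir, paste0(rid, ".csv"))
          n <- length(out$record$leads[[1L]])
          tab <- data.frame(time_s = (seq_len(n) - 1L) /
                              out$record$sampling_rate)
          for (ld in vcg_lead_names()) tab[[ld]] <- out$record$leads[[ld]]
          utils::write.csv(tab, path, row.names = FALSE)
        }
      }
      records[[rid]] <- out$record
      truth_full[[rid]] <- out$truth
      man[[k]] <- data.frame(record_id = rid, patient_id = rid,
                             path = path, label = pf$name,
                             report_text = out$record$report_text,
                             seed = rec_seed)
      tr[[k]] <- cbind(data.frame(record_id = rid, label = pf$name,
                                  tachy = out$truth$tachy),
                       as.data.frame(as.list(out$truth$features)))
    }
  }
  list(records = records, manifest = do.call(rbind, man),
       truth = do.call(rbind, tr), truth_full = truth_full)
}
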