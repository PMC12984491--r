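# Per-lead amplitude, interval, spectral and statistical-moment features,
# all amplitudes referenced to the isoelectric PR baseline, plus the
# record-level feature assembly.

#' PR-segment baseline for one beat
#'
#' Mean of the `[P_off, QRS_on)` segment; if that segment is empty or the
#' P wave is absent, the fallback is the 40--10 ms window before QRS
#' onset; if neither is available the baseline is missing.
#'
#' @param signal lead series in mV.
#' @param fiducials fiducials data.frame for the lead.
#' @param beat beat row index.
#' @param fs Hz.
#' @return baseline in mV, or `NA`.
#' @export
pr_baseline <- function(signal, fiducials, beat, fs) {
  poff <- fiducials$P_off[beat]
  qon <- fiducials$QRS_on[beat]
  if (!is.na(poff) && !is.na(qon) && qon - poff >= 2L) {
    return(mean(signal[poff:(qon - 1L)]))
  }
  if (!is.na(qon)) {
    a <- qon - round(0.040 * fs); b <- qon - round(0.010 * fs)
    if (a >= 1L && b > a) return(mean(signal[a:b]))
  }
  # last resort: a fixed pre-R window (QRS onset itself unresolved)
  r <- fiducials$R_peak[beat]
  if (!is.na(r)) {
    a <- r - round(0.110 * fs); b <- r - round(0.060 * fs)
    if (a >= 1L && b > a) return(mean(signal[a:b]))
  }
  NA_real_
}

#' Median wave amplitudes for one lead
#'
#' Per beat, amplitude = signal at the wave peak minus that beat's PR
#' baseline; the median is taken across beats.  R, P and T are reported
#' signed; Q and S as the absolute magnitude of their negative
#' deflection.
#'
#' @param signal lead series in mV.
#' @param fiducials fiducials data.frame for the lead.
#' @param fs Hz.
#' @return named numeric vector `c(P, Q, R, S, T)` in mV (`NA` where the
#'   landmark is absent in all beats).
#' @export
wave_amplitudes <- function(signal, fiducials, fs) {
  bl <- vapply(seq_len(nrow(fiducials)), function(b) {
    pr_baseline(signal, fiducials, b, fs)
  }, numeric(1))
  amp_at <- function(col, absval = FALSE) {
    idx <- fiducials[[col]]
    v <- signal[idx] - bl
    v <- v[!is.na(idx) & !is.na(bl)]
    if (!length(v)) return(NA_real_)
    if (absval) v <- abs(pmin(v, 0))
    stats::median(v)
  }
  c(P = amp_at("P_peak"), Q = amp_at("Q_peak", TRUE),
    R = amp_at("R_peak"), S = amp_at("S_peak", TRUE),
    T = amp_at("T_peak"))
}

#' R/S amplitude ratio
#'
#' @param r_amp signed R amplitude (mV).
#' @param s_amp absolute S amplitude (mV; missing treated as 0).
#' @param floor denominator floor in mV.
#' @return `r_amp / max(s_amp, floor)`, or `NA` if `r_amp` is missing.
#' @export
rs_ratio <- function(r_amp, s_amp, floor = 0.01) {
  if (is.na(r_amp)) return(NA_real_)
  if (is.na(s_amp)) s_amp <- 0
  r_amp / max(s_amp, floor)
}

#' Global interval and timing features
#'
#' Durations in ms from the fixed global windows; the T upslope/downslope
#' use the global T-peak median; the representative-beat frame starts
#' 40 ms before the global P onset.  Intervals are deliberately not
#' rate-corrected.
#'
#' @param global_windows a [aggregate_global_windows()] result.
#' @param r_peaks R-peak indices of the reference lead.
#' @param fs Hz.
#' @return named numeric vector: P_duration, PR_interval, QRS_duration,
#'   QT_interval, T_duration, T_upslope, T_downslope, T_index,
#'   frame_QRS_onset, frame_QRS_end (ms), median_RR (ms), heart_rate
#'   (bpm).
#' @export
interval_features <- function(global_windows, r_peaks, fs) {
  gw <- global_windows
  rr <- if (length(r_peaks) >= 2L) {
    stats::median(diff(r_peaks)) * 1000 / fs
  } else NA_real_
  up <- gw$T_peak_rel - gw$T_on_rel
  down <- gw$T_off_rel - gw$T_peak_rel
  c(P_duration = gw$P_off_rel - gw$P_on_rel,
    PR_interval = gw$QRS_on_rel - gw$P_on_rel,
    QRS_duration = gw$QRS_off_rel - gw$QRS_on_rel,
    QT_interval = gw$T_off_rel - gw$QRS_on_rel,
    T_duration = gw$T_off_rel - gw$T_on_rel,
    T_upslope = up, T_downslope = down,
    T_index = if (is.na(up) || is.na(down) || down <= 0) NA_real_ else
      up / down,
    frame_QRS_onset = gw$QRS_on_rel - (gw$P_on_rel - 40),
    frame_QRS_end = gw$QRS_off_rel - (gw$P_on_rel - 40),
    median_RR = rr,
    heart_rate = if (is.na(rr) || rr <= 0) NA_real_ else 60000 / rr)
}

#' Power-spectral features of one lead
#'
#' Periodogram of the linearly detrended signal, DC bin excluded; the
#' mean frequency is power-weighted, and the spread/skewness are the
#' corresponding higher moments of the spectral density.
#'
#' @param signal lead series in mV (>= 2 s).
#' @param fs Hz.
#' @return named numeric vector: mean_freq (Hz), spec_spread (Hz),
#'   spec_skewness; all `NA` for a (near-)zero-power signal.
#' @export
spectral_features <- function(signal, fs) {
  n <- length(signal)
  if (n < 2 * fs) stop("need at least 2 s of signal")
  x <- detrend_linear(signal)
  P <- Mod(stats::fft(x))^2
  half <- seq(2L, n %/% 2L + 1L)   # positive frequencies, DC excluded
  p <- P[half]
  f <- (half - 1L) * fs / n
  tot <- sum(p)
  if (tot < 1e-12) {
    return(c(mean_freq = NA_real_, spec_spread = NA_real_,
             spec_skewness = NA_real_))
  }
  w <- p / tot
  mf <- sum(w * f)
  sp <- sqrt(sum(w * (f - mf)^2))
  sk <- if (sp < 1e-12) NA_real_ else sum(w * (f - mf)^3) / sp^3
  c(mean_freq = mf, spec_spread = sp, spec_skewness = sk)
}

#' Time-domain moment features of one lead
#'
#' Third and fourth standardized central moments of the full cleaned
#' signal; kurtosis is reported as excess (normal = 0).
#'
#' @param signal lead series in mV.
#' @return named numeric vector: skewness, excess_kurtosis (`NA` for a
#'   zero-variance signal).
#' @export
moment_features <- function(signal) {
  m <- mean(signal)
  v <- mean((signal - m)^2)
  if (v < 1e-18) {
    return(c(skewness = NA_real_, excess_kurtosis = NA_real_))
  }
  c(skewness = mean((signal - m)^3) / v^1.5,
    excess_kurtosis = mean((signal - m)^4) / v^2 - 3)
}

#' Feature registry
#'
#' Ordered registry of every numeric feature the extraction pipeline
#' produces, with unit and family tags.  Machine passthrough columns
#' (7 numeric measurements, 11 Boolean flags) are appended dynamically
#' when present in the input.
#'
#' @return data.frame with columns name, unit, family.
#' @export
feature_registry <- function() {
  leads <- vcg_lead_names()
  amp <- expand.grid(wave = c("P", "Q", "R", "S", "T"), lead = leads,
                     stringsAsFactors = FALSE)
  amp_names <- sprintf("%s_amp_%s", amp$wave, amp$lead)
  rs_names <- sprintf("RS_ratio_%s", leads)
  spec_names <- as.vector(t(outer(
    c("mean_freq", "spec_spread", "spec_skewness"), leads, paste, sep = "_")))
  mom_names <- as.vector(t(outer(
    c("skewness", "excess_kurtosis"), leads, paste, sep = "_")))
  iv_names <- c("P_duration", "PR_interval", "QRS_duration", "QT_interval",
                "T_duration", "T_upslope", "T_downslope", "T_index",
                "frame_QRS_onset", "frame_QRS_end", "median_RR",
                "heart_rate")
  rbind(
    data.frame(name = amp_names, unit = "mV", family = "lead_amplitude"),
    data.frame(name = rs_names, unit = "ratio", family = "lead_amplitude"),
    data.frame(name = iv_names,
               unit = c(rep("ms", 7L), "ratio", "ms", "ms", "ms", "bpm"),
               family = "interval"),
    data.frame(name = spec_names, unit = "Hz", family = "spectral"),
    data.frame(name = mom_names, unit = "dimensionless",
               family = "moment"),
    data.frame(name = vcg_feature_names(), unit = "mixed", family = "vcg"))
}

#' Assemble a record's feature vector
#'
#' Concatenates the per-lead scalar features, global interval features,
#' VCG features and (unchanged) machine passthrough values into a single
#' named row following the registry order.  Missing stays missing --
#' never a silent zero.
#'
#' @param record_id identifier.
#' @param lead_features named list (by lead) of named numeric vectors
#'   (amplitudes, RS ratio, spectral, moments).
#' @param intervals [interval_features()] output.
#' @param vcg [compute_all_vcg_features()] output.
#' @param machine_numeric,machine_flags optional passthrough vectors.
#' @return one-row data.frame.
#' @export
assemble_features <- function(record_id, lead_features, intervals, vcg,
                              machine_numeric = NULL, machine_flags = NULL) {
  reg <- feature_registry()
  vals <- stats::setNames(rep(NA_real_, nrow(reg)), reg$name)
  for (lead in names(lead_features)) {
    lf <- lead_features[[lead]]
    for (nm in names(lf)) {
      key <- if (nm %in% c("P", "Q", "R", "S", "T")) {
        sprintf("%s_amp_%s", nm, lead)
      } else if (nm == "RS_ratio") {
        sprintf("RS_ratio_%s", lead)
      } else sprintf("%s_%s", nm, lead)
      if (key %in% names(vals)) vals[key] <- lf[[nm]]
    }
  }
  vals[names(intervals)] <- intervals
  vals[names(vcg)] <- vcg
  row <- as.data.frame(as.list(vals), check.names = FALSE)
  if (!is.null(machine_numeric) && length(machine_numeric)) {
    mn <- as.list(machine_numeric)
    names(mn) <- paste0("machine_", sub("^machine_", "", names(mn)))
    row <- cbind(row, as.data.frame(mn, check.names = FALSE))
  }
  if (!is.null(machine_flags) && length(machine_flags)) {
    mf <- as.list(as.logical(machine_flags))
    names(mf) <- paste0("flag_", sub("^(machine_)?flag_?", "",
                                     names(machine_flags)))
    row <- cbind(row, as.data.frame(mf, check.names = FALSE))
  }
  cbind(data.frame(record_id = record_id), row)
}
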