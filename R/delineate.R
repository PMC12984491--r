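# Wave delineation: energy-based R detection, prominence-based P/QRS/T
# landmarking per lead, and a wavelet (a-trous) refinement of the QRS
# onset/offset.  All sample indices are 1-based (R convention);
# millisecond conversions use ms = (samples) * 1000 / fs.

LANDMARKS <- c("P_on", "P_peak", "P_off", "Q_peak", "QRS_on", "R_peak",
               "S_peak", "QRS_off", "T_on", "T_peak", "T_off")

#' Delineation configuration
#'
#' Defaults for every tunable of the delineation stage.  The search
#' windows and thresholds are physiological defaults (the prominence
#' method itself does not prescribe them) and are fully configurable.
#'
#' @param refractory_ms minimum R-R separation for the peak detector.
#' @param p_window_ms,t_window_ms P/T search windows in ms relative to the
#'   R peak (capped at the neighbouring beat midpoints).
#' @param min_prominence_mv minimum peak prominence for a P/T landmark to
#'   be reported; below it the landmark is absent, never fabricated.
#' @param qs_min_mv minimum depth of a Q/S deflection below baseline.
#' @param dwt_levels a-trous decomposition depth; `dwt_detail_levels`
#'   selects the detail scales whose modulus bounds the QRS.
#' @param dwt_threshold fraction of the in-beat modulus maximum below
#'   which the QRS bound is declared.
#' @param amp_floor_mv amplitude floor for the outward push of the QRS
#'   bounds.
#' @return a named list.
#' @export
delineate_config <- function(refractory_ms = 200,
                             p_window_ms = c(-300, -60),
                             t_window_ms = c(80, 500),
                             min_prominence_mv = 0.05,
                             qs_min_mv = 0.015,
                             dwt_levels = 4L,
                             dwt_detail_levels = c(3L, 4L),
                             dwt_threshold = 0.05,
                             amp_floor_mv = 0.02) {
  list(refractory_ms = refractory_ms, p_window_ms = p_window_ms,
       t_window_ms = t_window_ms, min_prominence_mv = min_prominence_mv,
       qs_min_mv = qs_min_mv, dwt_levels = dwt_levels,
       dwt_detail_levels = dwt_detail_levels, dwt_threshold = dwt_threshold,
       amp_floor_mv = amp_floor_mv)
}

#' Detect R peaks
#'
#' Band-pass (5--25 Hz), squared-derivative energy with a ~120 ms
#' integration window, adaptive threshold and a refractory period.  Peak
#' locations are refined to the extremum of the cleaned signal.
#'
#' @param signal lead series in mV.
#' @param fs sampling rate, Hz.
#' @param refractory_ms minimum separation between peaks.
#' @return strictly ascending integer sample indices (possibly empty; a
#'   flat or unusable signal yields an empty result with a quality
#'   warning).
#' @export
detect_r_peaks <- function(signal, fs, refractory_ms = 200) {
  if (length(signal) < 2 * fs) stop("need at least 2 s of signal")
  bp <- bandpass_fft(signal, fs, 5, 25)
  energy <- moving_average(c(0, diff(bp))^2, round(0.12 * fs))
  emax <- max(energy)
  if (emax < 1e-10) {
    warning("signal quality: no QRS energy detected")
    return(integer(0))
  }
  thr <- 0.2 * stats::quantile(energy[energy > 0.05 * emax], 0.9,
                               names = FALSE)
  n <- length(energy)
  cand <- which(energy > thr)
  cand <- cand[energy[cand] >= c(energy[pmax(cand - 1L, 1L)])]
  cand <- cand[energy[cand] >= c(energy[pmin(cand + 1L, n)])]
  if (!length(cand)) {
    warning("signal quality: no peaks above threshold")
    return(integer(0))
  }
  refr <- round(refractory_ms / 1000 * fs)
  keep <- integer(0)
  for (i in cand[order(-energy[cand])]) {
    if (!length(keep) || all(abs(keep - i) >= refr)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  # refine to the extremum of the cleaned signal near each energy peak
  half <- as.integer(round(0.10 * fs))
  peaks <- vapply(keep, function(i) {
    lo <- max(1L, i - half); hi <- min(length(signal), i + half)
    seg <- signal[lo:hi] - stats::median(signal[lo:hi])
    as.integer(lo + which.max(abs(seg)) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  # discriminate QRS from tall T waves: a QRS burst carries most of its
  # energy above 10 Hz, a T wave below 8 Hz; drop T-like candidates
  if (length(peaks) > 1L) {
    hf <- bandpass_fft(signal, fs, 10, 30)
    lf <- bandpass_fft(signal, fs, 2.5, 8)
    w <- round(0.05 * fs)
    ratio <- vapply(peaks, function(p) {
      i <- max(1L, p - w):min(length(signal), p + w)
      sqrt(mean(hf[i]^2)) / (sqrt(mean(lf[i]^2)) + 1e-9)
    }, numeric(1))
    keepers <- ratio >= 0.3 * max(ratio)
    if (any(keepers)) peaks <- peaks[keepers]
  }
  # enforce refractory after refinement
  if (length(peaks) > 1L) {
    out <- peaks[1L]
    for (p in peaks[-1L]) if (p - out[length(out)] >= refr) out <- c(out, p)
    peaks <- out
  }
  peaks
}

#' Detect R peaks on a multi-lead high-frequency envelope
#'
#' Pipeline-internal detector: builds the root-sum-of-squares envelope of
#' the 10--30 Hz content of the supplied leads (a band where the QRS has
#' most of its energy and even tall T waves have almost none), smooths
#' it, and returns the envelope bump maxima above an adaptive threshold
#' with a refractory period.
#'
#' @param leads named list of cleaned lead series (mV).
#' @param fs Hz.
#' @param refractory_ms minimum separation.
#' @return strictly ascending sample indices (possibly empty, with a
#'   quality warning).
#' @export
detect_r_composite <- function(leads, fs, refractory_ms = 200) {
  env <- sqrt(Reduce(`+`, lapply(leads, function(x) {
    bandpass_fft(x, fs, 10, 30)^2
  })))
  env_lf <- sqrt(Reduce(`+`, lapply(leads, function(x) {
    bandpass_fft(x, fs, 2.5, 8)^2
  })))
  env_s <- moving_average(env, round(0.08 * fs))
  env_lf <- moving_average(env_lf, round(0.08 * fs))
  n <- length(env_s)
  loc <- which(diff(sign(diff(env_s))) < 0) + 1L
  if (!length(loc) || max(env_s) < 1e-6) {
    warning("signal quality: no QRS energy detected")
    return(integer(0))
  }
  tops <- sort(env_s[loc], decreasing = TRUE)
  thr <- 0.35 * stats::median(tops[seq_len(min(10L, length(tops)))])
  cand <- loc[env_s[loc] > thr]
  if (!length(cand)) {
    warning("signal quality: no peaks above threshold")
    return(integer(0))
  }
  refr <- round(refractory_ms / 1000 * fs)
  keep <- integer(0)
  for (i in cand[order(-env_s[cand])]) {
    if (!length(keep) || all(abs(keep - i) >= refr)) keep <- c(keep, i)
  }
  # discriminate QRS bumps from residual T bumps.  A frequency score
  # (envelope height times high-to-low-frequency energy ratio) removes
  # obvious T bumps; the decisive filter is periodicity: the envelope
  # autocorrelation gives the true beat period, and only the candidate
  # lattice anchored at the best-scoring bump is kept, which rejects
  # same-period bumps at a fixed off-phase latency (T waves).
  keep <- sort(keep)
  if (length(keep) > 3L) {
    score <- env_s[keep]^2 / (env_lf[keep] + 1e-9)
    keep <- keep[score >= 0.3 * max(score)]
    score <- score[score >= 0.3 * max(score)]
    period <- envelope_period(env_s, fs)
    if (!is.na(period) && length(keep) > 3L) {
      tol <- 0.2 * period
      anchor <- keep[which.max(score)]
      sel <- logical(length(keep))
      for (dir in c(-1, 1)) {
        expected <- anchor
        repeat {
          d <- abs(keep - expected)
          j <- which.min(d)
          if (d[j] <= tol) { sel[j] <- TRUE; expected <- keep[j] }
          expected <- expected + dir * period
          if (expected < min(keep) - period ||
              expected > max(keep) + period) break
        }
      }
      if (sum(sel) >= 3L) keep <- keep[sel]
    }
  }
  sort(keep)
}

# dominant beat period of the QRS envelope via autocorrelation over the
# physiological RR range; NA when no clear peak exists
envelope_period <- function(env_s, fs, rr_range_s = c(0.4, 1.8)) {
  x <- env_s - mean(env_s)
  n <- length(x)
  lags <- round(rr_range_s[1] * fs):round(rr_range_s[2] * fs)
  lags <- lags[lags < n - 10L]
  if (!length(lags)) return(NA_real_)
  X <- stats::fft(c(x, numeric(n)))
  ac <- Re(stats::fft(X * Conj(X), inverse = TRUE))[seq_len(n)]
  if (ac[1L] <= 0) return(NA_real_)
  ac <- ac / ac[1L]
  best <- lags[which.max(ac[lags + 1L])]
  if (ac[best + 1L] < 0.2) return(NA_real_)
  best
}

# prominence of local maxima of a non-negative series within a window;
# returns for the best candidate its index, prominence, and the flanking
# base indices (nearest flanking minima).  Peaks are located on the raw
# series; the base walk runs on a lightly smoothed copy so small-sample
# noise does not stop the descent prematurely.
best_prominent_peak <- function(m, tol = 0.004, smooth = 5L) {
  n <- length(m)
  if (n < 3L) return(NULL)
  msm <- if (smooth > 1L && n > smooth) moving_average(m, smooth) else m
  loc <- which(diff(sign(diff(m))) < 0) + 1L
  if (m[1L] > m[2L]) loc <- c(1L, loc)
  if (m[n] > m[n - 1L]) loc <- c(loc, n)
  if (!length(loc)) loc <- which.max(m)
  cands <- lapply(loc, function(j) {
    lb <- walk_to_base(msm, j, -1L, tol)
    rb <- walk_to_base(msm, j, +1L, tol)
    list(index = j, prominence = m[j] - max(msm[lb], msm[rb]),
         left = lb, right = rb)
  })
  proms <- vapply(cands, `[[`, numeric(1), "prominence")
  # among comparably prominent lobes (a biphasic wave), take the taller
  # one -- "the most prominent extremum" with an amplitude tie-break
  elig <- which(proms >= 0.6 * max(proms))
  best <- elig[which.max(m[loc[elig]])]
  cands[[best]]
}

# walk from a peak outward to its flanking minimum.  The walk continues
# while the series descends (within a noise tolerance) or is still above
# a floor fraction of the peak height; it stops at the first tolerated
# rise once the floor has been reached, and returns the running minimum.
# On a noise-free wave followed by flat baseline this is exactly the
# first sample where the descending limb reaches its minimum.
walk_to_base <- function(m, j, step, tol = 0.002, floor_frac = 0.08) {
  n <- length(m)
  # reference height from the peak's local neighbourhood: when walking a
  # smoothed copy the smoothed maximum may sit a sample off the raw peak
  ref <- max(m[max(1L, j - 2L):min(n, j + 2L)])
  eps <- max(2 * tol, floor_frac * ref)
  k <- j
  best <- j
  while (TRUE) {
    nxt <- k + step
    if (nxt < 1L || nxt > n) break
    if (m[nxt] > m[best] + tol && m[nxt] <= eps) break
    if (m[nxt] > ref) break            # ran into a higher wave
    k <- nxt
    if (m[k] < m[best]) best <- k
  }
  best
}

#' Prominence-based delineation of one lead
#'
#' For every beat, the P and T peaks are the most prominent local extrema
#' of the baseline-referenced signal within configurable search windows
#' before/after the R peak (capped at the neighbouring beat midpoints);
#' each wave's onset/offset is the adjacent prominence base, i.e. the
#' nearest flanking minimum of `|signal - baseline|` (so the T offset is
#' the right-hand base of the T peak).  Landmarks that fail the
#' prominence threshold are absent.  Q and S peaks are the deepest
#' deflections below baseline flanking the R peak; provisional QRS bounds
#' are their prominence bases and are meant to be refined by
#' [refine_qrs_bounds_dwt()].
#'
#' @param signal lead series in mV (cleaned).
#' @param fs Hz.
#' @param r_peaks ascending R-peak indices (>= 2).
#' @param config see [delineate_config()].
#' @param ref_peaks optional beat-structure anchors (e.g. the shared
#'   multi-lead R reference): the P/T search windows and the outer Q/S
#'   limits are placed relative to these, so a displaced lead-specific R
#'   label cannot drag the windows into a neighbouring wave.  Defaults
#'   to `r_peaks`.
#' @return a `fiducials` data.frame with one row per beat and one column
#'   per landmark (`NA` = absent).
#' @export
delineate_prominence <- function(signal, fs, r_peaks,
                                 config = delineate_config(),
                                 ref_peaks = r_peaks) {
  if (length(r_peaks) < 2L) stop("need at least 2 R peaks")
  stopifnot(length(ref_peaks) == length(r_peaks))
  n <- length(signal)
  ms <- function(x) round(x / 1000 * fs)
  nb <- length(r_peaks)
  # noise-adaptive floor for Q/S deflections: a dip must clear both the
  # configured minimum and ~4 robust noise SDs to count as a wave
  sigma_n <- stats::median(abs(diff(signal))) / 0.6745 / sqrt(2)
  qs_min <- max(config$qs_min_mv, 4 * sigma_n)
  out <- as.data.frame(matrix(NA_integer_, nb, length(LANDMARKS),
                              dimnames = list(NULL, LANDMARKS)))
  rr_half <- if (nb > 1L) {
    as.integer(stats::median(diff(ref_peaks)) %/% 2L)
  } else as.integer(round(0.5 * fs))
  for (b in seq_len(nb)) {
    r <- r_peaks[b]
    ref <- ref_peaks[b]
    # first/last beats: cap the span at half the median RR so long
    # record-edge tails cannot skew the local baseline
    prev_mid <- if (b > 1L) (ref + ref_peaks[b - 1L]) %/% 2L else
      max(1L, ref - rr_half)
    next_mid <- if (b < nb) (ref + ref_peaks[b + 1L]) %/% 2L else
      min(n, ref + rr_half)
    span <- max(1L, prev_mid):min(n, next_mid)
    base <- stats::median(signal[span])
    d <- signal - base
    out$R_peak[b] <- r

    # Q and S deflections; the outer limits are anchored to the beat
    # reference and stay clear of the P and T search regions, so a
    # neighbouring wave is never mislabelled
    q_lo <- ref + ms(max(-80, config$p_window_ms[2L] + 15))
    s_hi <- ref + ms(min(100, config$t_window_ms[1L] - 25))
    q_win <- max(prev_mid, q_lo):max(prev_mid, r - 1L)
    s_win <- min(next_mid, r + 1L):min(next_mid, max(r + 1L, s_hi))
    if (length(q_win) > 1L) {
      qi <- q_win[which.min(d[q_win])]
      if (d[qi] < -qs_min) out$Q_peak[b] <- qi
    }
    if (length(s_win) > 1L) {
      si <- s_win[which.min(d[s_win])]
      if (d[si] < -qs_min) out$S_peak[b] <- si
    }

    # provisional QRS bounds: prominence bases walked from the dominant
    # intra-QRS extremum (the labelled R peak may be a secondary positive
    # deflection in rS-type leads)
    qrs_lo <- max(prev_mid, ref + ms(-120))
    qrs_hi <- min(next_mid, ref + ms(140))
    m <- abs(d[qrs_lo:qrs_hi])
    ctr_lo <- max(qrs_lo, ref + ms(-60)) - qrs_lo + 1L
    ctr_hi <- min(qrs_hi, ref + ms(60)) - qrs_lo + 1L
    pk <- (ctr_lo:ctr_hi)[which.max(m[ctr_lo:ctr_hi])]
    out$QRS_on[b] <- qrs_lo + walk_to_base(m, pk, -1L) - 1L
    out$QRS_off[b] <- qrs_lo + walk_to_base(m, pk, +1L) - 1L

    # P wave
    p_lo <- max(prev_mid, ref + ms(config$p_window_ms[1L]))
    p_hi <- min(r - 1L, ref + ms(config$p_window_ms[2L]))
    if (p_hi - p_lo > 3L) {
      m <- abs(d[p_lo:p_hi])
      bp <- best_prominent_peak(m)
      if (!is.null(bp) && bp$prominence >= config$min_prominence_mv) {
        out$P_peak[b] <- p_lo + bp$index - 1L
        out$P_on[b] <- p_lo + bp$left - 1L
        out$P_off[b] <- p_lo + bp$right - 1L
      }
    }

    # T wave
    t_lo <- max(r + 1L, ref + ms(config$t_window_ms[1L]))
    t_hi <- min(next_mid, ref + ms(config$t_window_ms[2L]), n)
    if (t_hi - t_lo > 3L) {
      m <- abs(d[t_lo:t_hi])
      bt <- best_prominent_peak(m)
      if (!is.null(bt) && bt$prominence >= config$min_prominence_mv) {
        out$T_peak[b] <- t_lo + bt$index - 1L
        out$T_on[b] <- t_lo + bt$left - 1L
        out$T_off[b] <- t_lo + bt$right - 1L
      }
    }
  }
  enforce_fiducial_order(out)
}

# drop or clip landmarks that violate the within-beat ordering so the
# ordering invariant holds on every return path
enforce_fiducial_order <- function(fid) {
  for (b in seq_len(nrow(fid))) {
    r <- fid$R_peak[b]
    if (is.na(r)) next
    if (!is.na(fid$QRS_on[b]) && fid$QRS_on[b] > r) fid$QRS_on[b] <- r
    if (!is.na(fid$QRS_off[b]) && fid$QRS_off[b] < r) fid$QRS_off[b] <- r
    # bounds must contain the Q/S deflections: extend outward, never
    # relocate a found deflection
    if (!is.na(fid$Q_peak[b])) {
      if (fid$Q_peak[b] > r) fid$Q_peak[b] <- NA_integer_
      else if (!is.na(fid$QRS_on[b])) {
        fid$QRS_on[b] <- min(fid$QRS_on[b], fid$Q_peak[b])
      }
    }
    if (!is.na(fid$S_peak[b])) {
      if (fid$S_peak[b] < r) fid$S_peak[b] <- NA_integer_
      else if (!is.na(fid$QRS_off[b])) {
        fid$QRS_off[b] <- max(fid$QRS_off[b], fid$S_peak[b])
      }
    }
    qon <- fid$QRS_on[b]
    if (!is.na(fid$P_off[b]) && !is.na(qon) && fid$P_off[b] > qon) {
      fid$P_off[b] <- qon
    }
    if (!is.na(fid$P_peak[b]) && !is.na(fid$P_off[b]) &&
        fid$P_peak[b] > fid$P_off[b]) {
      fid[b, c("P_on", "P_peak", "P_off")] <- NA_integer_
    }
    qoff <- fid$QRS_off[b]
    if (!is.na(fid$T_on[b]) && !is.na(qoff) && fid$T_on[b] < qoff) {
      fid$T_on[b] <- qoff
    }
    if (!is.na(fid$T_peak[b]) && !is.na(fid$T_on[b]) &&
        fid$T_peak[b] < fid$T_on[b]) {
      fid[b, c("T_on", "T_peak", "T_off")] <- NA_integer_
    }
  }
  class(fid) <- c("fiducials", class(fid))
  fid
}

#' Validate the within-beat landmark ordering
#'
#' @param fid a fiducials data.frame.
#' @return `TRUE` if every beat's present landmarks are ordered
#'   P_on <= P_peak <= P_off <= QRS_on <= R_peak <= QRS_off <= T_on <=
#'   T_peak <= T_off, else `FALSE`.
#' @export
fiducials_ordered <- function(fid) {
  seqn <- c("P_on", "P_peak", "P_off", "QRS_on", "R_peak", "QRS_off",
            "T_on", "T_peak", "T_off")
  for (b in seq_len(nrow(fid))) {
    v <- as.numeric(fid[b, seqn])
    v <- v[!is.na(v)]
    if (is.unsorted(v)) return(FALSE)
    if (!is.na(fid$Q_peak[b]) &&
        (isTRUE(fid$Q_peak[b] < fid$QRS_on[b]) ||
         isTRUE(fid$Q_peak[b] > fid$R_peak[b]))) return(FALSE)
    if (!is.na(fid$S_peak[b]) &&
        (isTRUE(fid$S_peak[b] > fid$QRS_off[b]) ||
         isTRUE(fid$S_peak[b] < fid$R_peak[b]))) return(FALSE)
  }
  TRUE
}

# a-trous (undecimated) dyadic wavelet details.  Scaling filter
# (1,2,1)/4 and derivative-like wavelet filter (-1,0,1)/2, both
# zero-phase, dilated by 2^(j-1) at level j.  Returns a list of detail
# series; their modulus peaks at steep deflections (QRS slopes).
atrous_details <- function(x, levels = 4L) {
  n <- length(x)
  a <- x
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    dil <- 2L^(j - 1L)
    d <- (shift_series(a, -dil) - shift_series(a, dil)) / 2
    a <- (shift_series(a, -dil) + 2 * a + shift_series(a, dil)) / 4
    details[[j]] <- d
  }
  details
}

# shift with edge replication (k > 0 shifts right)
shift_series <- function(x, k) {
  n <- length(x)
  if (k == 0L) return(x)
  if (k > 0L) c(rep(x[1L], k), x[seq_len(n - k)])
  else c(x[seq.int(-k + 1L, n)], rep(x[n], -k))
}

#' Refine QRS bounds with a discrete wavelet stage
#'
#' The modulus of a band-limited detail reconstruction (sum of the
#' configured a-trous detail levels) is scanned outward from the QRS
#' slope maxima; a bound is declared where the modulus falls below a
#' fraction of its in-beat maximum, then pushed outward while the signal
#' stays above an amplitude floor relative to the local PR baseline.  Q
#' and S deflections are guaranteed to fall inside the returned bounds.
#'
#' @param signal lead series in mV (cleaned).
#' @param fs Hz.
#' @param fiducials a fiducials data.frame with `R_peak` present.
#' @param config see [delineate_config()].
#' @return the fiducials with `QRS_on`/`QRS_off` replaced; degenerate
#'   beats (no deflection above the floor) get bounds at R +- 1 sample
#'   and a `qrs_flag` column notes them.
#' @export
refine_qrs_bounds_dwt <- function(signal, fs, fiducials,
                                  config = delineate_config()) {
  if (any(is.na(fiducials$R_peak))) stop("R_peak required for every beat")
  det <- atrous_details(signal, config$dwt_levels)
  d34 <- Reduce(`+`, det[config$dwt_detail_levels])
  m <- abs(d34)
  n <- length(signal)
  ms <- function(x) round(x / 1000 * fs)
  hold <- max(2L, ms(10))   # sustained-below-threshold run length
  fiducials$qrs_flag <- ""
  push_max <- ms(60)          # maximum outward travel of the amplitude push
  # amplitude quietness is judged by the local signal RANGE (max - min
  # over a ~20 ms one-sided window): a true isoelectric gap is flat
  # regardless of any residual baseline offset, while slurred tails,
  # internal plateaus and slow T feet all wiggle above the floor.  The
  # window is directional -- trailing for the onset side, leading for
  # the offset side -- so the bound is not biased outward by the wave
  # entering a centred window.  The floor adapts to the noise level so
  # white noise does not mask the gaps.
  w20 <- ms(20)
  maxL <- signal; minL <- signal; maxR <- signal; minR <- signal
  for (sft in seq_len(w20)) {
    sl <- shift_series(signal, sft)    # values to the left
    sr <- shift_series(signal, -sft)   # values to the right
    maxL <- pmax(maxL, sl); minL <- pmin(minL, sl)
    maxR <- pmax(maxR, sr); minR <- pmin(minR, sr)
  }
  sigma_n <- stats::median(abs(diff(signal))) / 0.6745 / sqrt(2)
  qfloor <- max(config$amp_floor_mv, 5.5 * sigma_n)
  # a quiet sample is flat AND near the (baseline-subtracted) zero
  # level: flatness alone would accept an in-wave plateau, level alone
  # would accept a slow limb crossing zero
  level_ok <- abs(signal) <= 2 * qfloor
  quiet_on <- (maxL - minL) <= qfloor & level_ok
  quiet_off <- (maxR - minR) <= qfloor & level_ok
  quiet_both <- quiet_on & quiet_off
  for (b in seq_len(nrow(fiducials))) {
    r <- fiducials$R_peak[b]
    lo <- max(1L, r + ms(-150)); hi <- min(n, r + ms(150))
    # beat-local baseline guard: record-edge filter transients shift the
    # local level away from the global median, and the push must stop
    # when either estimate says "baseline"
    prb2 <- stats::median(signal[lo:hi])
    mwin <- m[lo:hi]
    mmax <- max(mwin)
    if (mmax < 1e-9) {
      fiducials$QRS_on[b] <- max(1L, r - 1L)
      fiducials$QRS_off[b] <- min(n, r + 1L)
      fiducials$qrs_flag[b] <- "degenerate"
      next
    }
    thr <- config$dwt_threshold * mmax
    ri <- r - lo + 1L
    # the slope-maximum anchors are searched close to R only: a P or T
    # wave of comparable amplitude in a weak-QRS lead must not capture
    # the scan
    near <- ms(90)
    left <- mwin[seq_len(ri)]
    l0 <- max(1L, ri - near)
    # anchor on the strong detail nearest R (a sharp P across a short PR
    # gap can carry a comparable modulus further out)
    strong <- which(left[l0:ri] >= 0.5 * max(left[l0:ri]))
    il <- l0 + strong[length(strong)] - 1L
    on <- NA_integer_                          # absent if no clear bound
    k <- il
    run <- 0L
    while (k > 1L) {
      k <- k - 1L
      run <- if (left[k] < thr) run + 1L else 0L
      if (run >= hold) { on <- lo + (k + run - 1L) - 1L; break }
    }
    right <- mwin[ri:length(mwin)]
    r1 <- min(length(right), near)
    ir <- which(right[1L:r1] >= 0.5 * max(right[1L:r1]))[1L]
    off <- NA_integer_
    k <- ir
    run <- 0L
    while (k < length(right)) {
      k <- k + 1L
      run <- if (right[k] < thr) run + 1L else 0L
      if (run >= hold) { off <- lo + (ri - 1L) + (k - run + 1L) - 1L; break }
    }
    # amplitude-based runs complement the wavelet scan: against a tall,
    # fast T wave the detail modulus may never go quiet between QRS and
    # T, while the isoelectric ST amplitude gap still exists.  The inner
    # (closer to R) of the two bounds wins; the outward push below heals
    # any quiet notch this pulls inside the complex.
    k <- lo + il - 1L
    run <- 0L
    on_amp <- NA_integer_
    while (k > lo) {
      k <- k - 1L
      run <- if (quiet_on[k]) run + 1L else 0L
      if (run >= hold) { on_amp <- k + run - 1L; break }
    }
    k <- lo + (ri - 1L) + ir - 1L
    run <- 0L
    off_amp <- NA_integer_
    while (k < hi) {
      k <- k + 1L
      run <- if (quiet_off[k]) run + 1L else 0L
      if (run >= hold) { off_amp <- k - run + 1L; break }
    }
    on <- if (is.na(on) && is.na(on_amp)) NA_integer_ else
      as.integer(max(c(on, on_amp), na.rm = TRUE))
    off <- if (is.na(off) && is.na(off_amp)) NA_integer_ else
      as.integer(min(c(off, off_amp), na.rm = TRUE))
    if (is.na(on) || is.na(off)) {
      # no quiet run on either criterion: keep the provisional
      # prominence bounds (never the window edges, which would bias the
      # global medians) and flag the beat
      fiducials$qrs_flag[b] <- "unbounded"
      next
    }
    if (all(quiet_both[max(lo, r + ms(-60)):min(hi, r + ms(60))])) {
      fiducials$QRS_on[b] <- max(1L, r - 1L)
      fiducials$QRS_off[b] <- min(n, r + 1L)
      fiducials$qrs_flag[b] <- "degenerate"
      next
    }
    # outward amplitude push: capture slurred tails just below the
    # wavelet threshold; travel bounded so the push can never walk
    # across the baseline into a neighbouring wave
    on0 <- on; off0 <- off
    while (on > max(lo, on0 - push_max) && !quiet_on[on - 1L]) {
      on <- on - 1L
    }
    while (off < min(hi, off0 + push_max) && !quiet_off[off + 1L]) {
      off <- off + 1L
    }
    # inward trim: the wavelet filters smear the detail modulus a few
    # samples beyond the wave support, so drop quiet padding inside the
    # bound (the trim stops at the first non-quiet sample, i.e. where
    # the wave actually moves)
    while (on < r && quiet_on[on]) on <- on + 1L
    while (off > r && quiet_off[off]) off <- off - 1L
    if (!is.na(fiducials$Q_peak[b])) on <- min(on, fiducials$Q_peak[b])
    if (!is.na(fiducials$S_peak[b])) off <- max(off, fiducials$S_peak[b])
    fiducials$QRS_on[b] <- min(on, r)
    fiducials$QRS_off[b] <- max(off, r)
    if (off - on <= 2L) fiducials$qrs_flag[b] <- "narrow"
  }
  enforce_fiducial_order(fiducials)
}

#' Aggregate per-lead fiducials into fixed global windows
#'
#' Each relative landmark is the median over leads of the per-lead median
#' over beats of (landmark - R_peak), converted to ms.  The ordering
#' invariant is enforced: a violation raises an error rather than being
#' silently repaired.
#'
#' @param fiducial_sets named list (by lead) of fiducials data.frames.
#' @param fs Hz.
#' @param required landmarks that must be present in at least one lead;
#'   others (e.g. the P wave) may be absent and come back as `NA`.
#' @return a `global_windows` list with elements `P_on_rel`, `P_off_rel`,
#'   `QRS_on_rel`, `QRS_off_rel`, `T_on_rel`, `T_off_rel` (and the peak
#'   medians `P_peak_rel`, `T_peak_rel` as auxiliaries), all in signed ms
#'   relative to the R peak.
#' @export
aggregate_global_windows <- function(fiducial_sets, fs,
                                     required = c("QRS_on", "QRS_off",
                                                  "T_on", "T_off")) {
  fiducial_sets <- Filter(Negate(is.null), fiducial_sets)
  if (!length(fiducial_sets)) stop("no leads contribute fiducials")
  marks <- c("P_on", "P_peak", "P_off", "QRS_on", "QRS_off",
             "T_on", "T_peak", "T_off")
  rel <- vapply(marks, function(mk) {
    per_lead <- vapply(fiducial_sets, function(fid) {
      v <- (fid[[mk]] - fid$R_peak)
      stats::median(v[!is.na(v)])
    }, numeric(1))
    per_lead <- per_lead[!is.na(per_lead)]
    if (!length(per_lead)) NA_real_ else stats::median(per_lead)
  }, numeric(1))
  for (mk in required) {
    if (is.na(rel[[mk]])) stop("landmark ", mk, " absent in all leads")
  }
  gw <- as.list(rel * 1000 / fs)
  names(gw) <- paste0(marks, "_rel")
  ord <- unlist(gw[c("P_on_rel", "P_off_rel", "QRS_on_rel", "QRS_off_rel",
                     "T_on_rel", "T_off_rel")])
  ord <- ord[!is.na(ord)]
  if (is.unsorted(ord, strictly = FALSE)) {
    stop("global window ordering violated: ",
         paste(sprintf("%s=%.1f", names(ord), ord), collapse = ", "))
  }
  if (!is.na(gw$QRS_on_rel) && gw$QRS_on_rel > 0) {
    stop("global window ordering violated: QRS onset after R peak")
  }
  structure(gw, class = "global_windows")
}

#' Export fiducials in tidy long form
#'
#' @param fiducial_sets named list (by lead) of fiducials data.frames.
#' @param fs Hz.
#' @param record_id record identifier for the `record_id` column.
#' @return data.frame with columns record_id, lead, beat, landmark,
#'   sample_index, time_ms.
#' @export
fiducials_tidy <- function(fiducial_sets, fs, record_id = "record") {
  rows <- lapply(names(fiducial_sets), function(lead) {
    fid <- fiducial_sets[[lead]]
    do.call(rbind, lapply(seq_len(nrow(fid)), function(b) {
      idx <- as.integer(fid[b, LANDMARKS])
      data.frame(record_id = record_id, lead = lead, beat = b,
                 landmark = LANDMARKS, sample_index = idx,
                 time_ms = (idx - 1L) * 1000 / fs)
    }))
  })
  out <- do.call(rbind, rows)
  out[!is.na(out$sample_index), ]
}
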