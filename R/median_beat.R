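# R-aligned 850 ms mean beats and the calibrated 8-lead matrix that feeds
# the Kors projection.

#' Build a mean heartbeat for one lead
#'
#' Extracts R-aligned windows of `pre_ms + post_ms` (= 850 ms) around each
#' R peak, shifts each segment by its own PR-segment mean so the average
#' is referenced to the isoelectric level, and returns the pointwise
#' arithmetic mean (or median with `method = "median"`).  Windows crossing
#' the record edge are dropped.
#'
#' @param signal lead series in mV.
#' @param r_peaks ascending R-peak sample indices.
#' @param fs Hz.
#' @param pre_ms,post_ms window split around the R peak; must sum to the
#'   850 ms beat length (default 300/550).
#' @param pr_rel_ms PR-segment window in ms relative to R used for the
#'   per-segment baseline shift.
#' @param method `"mean"` (default) or `"median"`.
#' @return numeric series of length `round(0.001 * (pre_ms + post_ms) * fs)`
#'   with attribute `n_beats_used`.
#' @export
build_mean_beat <- function(signal, r_peaks, fs, pre_ms = 300, post_ms = 550,
                            pr_rel_ms = c(-90, -50),
                            method = c("mean", "median")) {
  method <- match.arg(method)
  pre <- round(pre_ms / 1000 * fs)
  post <- round(post_ms / 1000 * fs)
  W <- pre + post
  n <- length(signal)
  ok <- r_peaks[r_peaks - pre >= 1L & r_peaks + post - 1L <= n]
  if (length(ok) < 2L) stop("fewer than 2 complete ", pre_ms + post_ms,
                            " ms windows")
  pr0 <- round(pr_rel_ms[1L] / 1000 * fs)
  pr1 <- round(pr_rel_ms[2L] / 1000 * fs)
  segs <- vapply(ok, function(r) {
    seg <- signal[(r - pre):(r + post - 1L)]
    seg - mean(signal[max(1L, r + pr0):max(1L, r + pr1)])
  }, numeric(W))
  beat <- if (method == "mean") rowMeans(segs) else
    apply(segs, 1L, stats::median)
  attr(beat, "n_beats_used") <- length(ok)
  beat
}

#' Assemble the calibrated 8-lead median-beat matrix
#'
#' Stacks the eight mean beats (lead order I, II, V1..V6) into an 8 x W
#' matrix whose single R index is taken from the lead V5 alignment -- the
#' reference lead with clear, large R waves.  If `v5_r_index` is omitted
#' it is re-detected as the extremum of the V5 mean beat.
#'
#' @param mean_beats named list of the 8 independent-lead mean beats, all
#'   length W.
#' @param global_windows a [aggregate_global_windows()] result, attached
#'   to the output for downstream windowing.
#' @param v5_r_index calibrated R sample index within the window
#'   (1-based); default re-detected from V5 near `expected_r_index`.
#' @param expected_r_index where R alignment is expected (defaults to the
#'   300 ms mark); the V5 re-detection searches within `search_ms` of it
#'   so a large T wave cannot capture the calibration.
#' @param search_ms half-width of the V5 re-detection window.
#' @param fs Hz.
#' @return a `median_beat_matrix`: 8 x W numeric matrix with attributes
#'   `r_index`, `fs`, `windows`, `n_beats_used`.
#' @export
assemble_calibrated_matrix <- function(mean_beats, global_windows = NULL,
                                       v5_r_index = NULL,
                                       expected_r_index = NULL,
                                       search_ms = 60, fs = 500) {
  leads <- vcg_independent_leads()
  miss <- setdiff(leads, names(mean_beats))
  if (length(miss)) stop("mean beat missing for lead ",
                         paste(miss, collapse = ", "))
  W <- unique(vapply(mean_beats[leads], length, integer(1)))
  if (length(W) != 1L) stop("mean beats have unequal lengths")
  v5 <- mean_beats[["V5"]]
  if (max(abs(v5 - stats::median(v5))) < 0.05) {
    stop("V5 calibration failed: flat or missing V5 mean beat")
  }
  if (is.null(v5_r_index)) {
    if (is.null(expected_r_index)) {
      expected_r_index <- round(0.300 * fs) + 1L
    }
    half <- round(search_ms / 1000 * fs)
    lo <- max(1L, expected_r_index - half)
    hi <- min(W, expected_r_index + half)
    v5_r_index <- lo + which.max(abs(v5[lo:hi] - stats::median(v5))) - 1L
  }
  if (v5_r_index < 1L || v5_r_index > W) {
    stop("V5 calibration failed: r_index outside the beat window")
  }
  mat <- do.call(rbind, mean_beats[leads])
  rownames(mat) <- leads
  structure(mat, r_index = as.integer(v5_r_index), fs = fs,
            windows = global_windows,
            n_beats_used = vapply(mean_beats[leads], function(b) {
              nb <- attr(b, "n_beats_used")
              if (is.null(nb)) NA_integer_ else as.integer(nb)
            }, integer(1)),
            class = c("median_beat_matrix", "matrix", "array"))
}
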