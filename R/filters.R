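# Signal conditioning: zero-phase FFT-domain band-pass, detrending and
# resampling.  Implemented on the frequency domain rather than IIR sections
# so the filters are exactly zero-phase and need no external DSP package.

#' Zero-phase band-pass filter
#'
#' Filters a uniformly sampled series in the frequency domain with a
#' raised-cosine-edged band mask, which is zero-phase by construction.
#' The default 0.5--40 Hz band is the cleaning filter applied before
#' feature extraction; the R-peak detector uses a 5--25 Hz band.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz; `low = 0` disables the high-pass side,
#'   `high = Inf` the low-pass side.
#' @param edge transition width in Hz of the cosine roll-off; the two
#'   sides can be set independently with `edge_low`/`edge_high` (a sharp
#'   high-side cutoff would ring across sharp QRS edges, so its default
#'   transition is wide).
#' @param edge_low,edge_high per-side transition widths.
#' @return filtered numeric series, same length as `x`.
#' @export
bandpass_fft <- function(x, fs, low = 0.5, high = 40, edge = 0.5,
                         edge_low = edge, edge_high = max(edge, 8)) {
  n <- length(x)
  if (n < 4L) return(x - mean(x))
  # reflect-pad to reduce wrap-around transients
  pad <- min(n, max(16L, as.integer(fs)))
  xe <- c(rev(x[seq_len(pad)]), x, rev(x[seq.int(n - pad + 1L, n)]))
  ne <- length(xe)
  f <- seq(0L, ne - 1L) / ne * fs
  f <- pmin(f, fs - f)          # two-sided frequency axis
  mask <- rep(1, ne)
  if (low > 0) {
    mask <- mask * cos_step(f, low - edge_low, low)
  }
  if (is.finite(high)) {
    mask <- mask * (1 - cos_step(f, high, high + edge_high))
  }
  y <- Re(stats::fft(stats::fft(xe) * mask, inverse = TRUE)) / ne
  y[seq.int(pad + 1L, pad + n)]
}

# smooth 0->1 step between f0 and f1 (raised-cosine edge)
cos_step <- function(f, f0, f1) {
  s <- (f - f0) / max(f1 - f0, 1e-12)
  s <- pmin(pmax(s, 0), 1)
  0.5 * (1 - cos(pi * s))
}

#' Resample a series to a new sampling rate
#'
#' FFT-domain resampling (band-limited interpolation) used to bring
#' non-500 Hz input records onto the 500 Hz grid the pipeline constants
#' assume.
#'
#' @param x numeric series.
#' @param fs_in,fs_out input and output sampling rates in Hz.
#' @return numeric series of length `round(length(x) * fs_out / fs_in)`.
#' @export
resample_series <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) return(x)
  n <- length(x)
  m <- as.integer(round(n * fs_out / fs_in))
  X <- stats::fft(x)
  half <- n %/% 2L
  Y <- complex(m)
  keep <- min(half, m %/% 2L)
  Y[seq_len(keep + 1L)] <- X[seq_len(keep + 1L)]
  if (keep > 0L) {
    Y[seq.int(m - keep + 1L, m)] <- X[seq.int(n - keep + 1L, n)]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Linear detrend
#'
#' @param x numeric series.
#' @return `x` minus its least-squares line.
#' @export
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 2L) return(x - mean(x))
  t <- seq_len(n)
  stats::lsfit(t, x)$residuals
}

# simple moving-average smoother with reflected edges (odd width)
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L) return(x)
  h <- width %/% 2L
  xe <- c(rev(x[seq_len(h)]), x, rev(x[seq.int(length(x) - h + 1L, length(x))]))
  as.numeric(stats::filter(xe, rep(1 / width, width), sides = 2L))[
    seq.int(h + 1L, h + length(x))]
}
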