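#' Resample and band-pass filter a recording
#'
#' The analysis chain applied before burst detection: rational-ratio
#' anti-aliased resampling to `fs_out`, followed by a zero-phase Butterworth
#' band-pass.  An order-8 \[6, 15\] Hz band-pass at 128 Hz isolates the alpha
#' band while suppressing slow eye-movement artifacts (< 6 Hz) and muscle
#' activity (> 15 Hz), which is what lets a very low-order AR model describe
#' the filtered signal.  Zero-phase (forward-backward) filtering preserves
#' burst timing; it doubles the effective filter order.
#'
#' @param x an `eeg_recording`, a channels-by-samples matrix, or a vector.
#' @param fs_in input sampling rate (Hz); taken from the recording when `x`
#'   is one.
#' @param band `c(low, high)` pass band in Hz; both edges must lie below
#'   `fs_out / 2`.
#' @param order Butterworth band-pass order (even; default 8, i.e. 4 pole
#'   pairs per edge).
#' @param fs_out output sampling rate (Hz, default 128).
#' @return same shape as the input, resampled and filtered; recordings come
#'   back as recordings with updated `fs` (any `"truth"` attribute is
#'   carried over — event times are in seconds and unaffected).
#' @export
preprocess <- function(x, fs_in = NULL, band = c(6, 15), order = 8,
                       fs_out = 128) {
  if (inherits(x, "eeg_recording")) {
    truth <- attr(x, "truth")
    out <- recording(
      preprocess(x$data, fs_in = x$fs, band = band, order = order,
                 fs_out = fs_out),
      fs = fs_out, channel_labels = x$channel_labels, meta = x$meta)
    attr(out, "truth") <- truth
    return(out)
  }
  if (is.null(fs_in)) stop("`fs_in` is required for matrix/vector input")
  if (any(band <= 0) || any(band >= fs_out / 2))
    stop("`band` edges must lie strictly inside (0, fs_out/2)")
  if (order %% 2 != 0) stop("`order` must be even for a band-pass")
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, preprocess, fs_in = fs_in, band = band,
                   order = order, fs_out = fs_out))
    return(out)
  }
  y <- resample_rational(as.numeric(x), fs_in, fs_out)
  bf <- signal::butter(order / 2, band / (fs_out / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, y))
}

# anti-aliased resampling by the rational factor fs_out/fs_in
resample_rational <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) return(x)
  fr <- rational_approx(fs_out / fs_in)
  n_out <- floor(length(x) * fs_out / fs_in)
  y <- as.numeric(signal::resample(x, fr$p, fr$q))
  length(y) <- min(length(y), n_out)
  y
}

# small continued-fraction rational approximation of a ratio
rational_approx <- function(ratio, max_den = 1000L) {
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(ratio * q)
    if (p < 1) next
    e <- abs(ratio - p / q)
    if (e < err - 1e-15) { err <- e; best <- c(p, q) }
    if (err < 1e-12) break
  }
  list(p = best[1L], q = best[2L])
}
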