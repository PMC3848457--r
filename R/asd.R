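#' Amplitude spectral density of a 1-second Hamming-windowed segment
#'
#' Computes the one-sided amplitude spectrum of a 1 s data window after
#' Hamming tapering, the quantity the sliding-window baseline spindle
#' detector operates on.  With a 1 s window the native frequency resolution
#' is 1 Hz; `zero_pad` interpolates the spectrum onto a finer grid
#' (resolution `1/zero_pad` Hz), which stabilizes the peak and
#' half-maximum-crossing searches without changing the underlying
#' resolution.
#'
#' @param window_samples numeric vector of exactly `round(fs)` samples (1 s).
#' @param fs sampling rate in Hz.
#' @param zero_pad integer zero-padding factor (default 4).
#' @return list with `freq` (Hz) and `asd` (amplitude per taper-coherent
#'   gain; a unit-amplitude sinusoid has ASD about 1 at its frequency).
#' @export
asd_spectrum <- function(window_samples, fs, zero_pad = 4L) {
  n <- round(fs)
  if (length(window_samples) != n)
    stop("`window_samples` must contain exactly 1 s of data (", n,
         " samples at fs = ", fs, " Hz)")
  w <- signal::hamming(n)
  xw <- (window_samples - mean(window_samples)) * w
  nfft <- n * as.integer(zero_pad)
  X <- fft(c(xw, numeric(nfft - n)))
  half <- seq_len(nfft %/% 2L + 1L)
  amp <- 2 * Mod(X[half]) / sum(w)       # coherent-gain normalization
  list(freq = (half - 1L) * fs / nfft, asd = amp)
}

#' Fit an exponential noise model to a spectrum
#'
#' Estimates the shape parameter `gamma` of `f(x) = exp(gamma * x)` by
#' minimizing the sum of squared errors to the observed amplitude spectral
#' density, a one-parameter stand-in for the 1/f-like background of EEG
#' spectra.  `form = "power"` selects the alternative reading
#' `f(x) = exp(x^gamma)`.
#'
#' @param freqs frequencies (Hz).
#' @param asd observed amplitude spectral density at `freqs`.
#' @param exclude optional `c(lo, hi)` frequency band to leave out of the
#'   fit (the peak's FWHM band, when the fit feeds the oscillation index).
#' @param form `"rate"` (default) for `exp(gamma x)`; `"power"` for
#'   `exp(x^gamma)`.
#' @return the fitted scalar `gamma`.
#' @export
fit_noise_exponential <- function(freqs, asd, exclude = NULL,
                                  form = c("rate", "power")) {
  form <- match.arg(form)
  keep <- is.finite(freqs) & is.finite(asd)
  if (!is.null(exclude))
    keep <- keep & !(freqs >= exclude[1] & freqs <= exclude[2])
  x <- freqs[keep]; y <- asd[keep]
  if (length(x) < 3L) stop("need at least 3 points to fit the noise model")
  fmodel <- if (form == "rate") function(g) exp(g * x)
            else function(g) exp(x^g)
  sse <- function(g) sum((y - fmodel(g))^2)
  lo <- if (form == "rate") -5 else -10
  opt <- optimize(sse, interval = c(lo, 5), tol = 1e-10)
  if (!is.finite(opt$objective))
    stop("exponential noise fit did not converge (objective = ",
         opt$objective, ")")
  opt$minimum
}

#' Classify a 1-second window as spindle or not by its spectral peak shape
#'
#' Finds the maximum of the amplitude spectral density in \[3, 40\] Hz.  If
#' the peak lies in the alpha range \[8, 13\] Hz, the full width at half
#' maximum (FWHM) of the peak is measured by linear interpolation of the
#' half-maximum crossings around the peak; the window is a spindle iff the
#' FWHM is below twice the Hamming window's noise bandwidth (2 x 1.37 =
#' 2.74 Hz), i.e. the peak is essentially as narrow as a pure tone.  The
#' oscillation index — the area under the ASD across the FWHM band divided
#' by the area under the exponential noise fit there — is reported as a
#' spectral SNR proxy but not used for gating.
#'
#' The decision is invariant to scaling the window by a positive constant
#' (peak location and relative width do not change).
#'
#' @param window 1 s of samples.
#' @param fs sampling rate (Hz).
#' @param zero_pad spectrum interpolation factor, see [asd_spectrum()].
#' @param search_band peak search band, default `c(3, 40)` Hz.
#' @param alpha_band spindle gate band, default `c(8, 13)` Hz.
#' @param fwhm_max spindle criterion, default `2 * 1.37` Hz.
#' @return list of class `asd_window`: `peak_freq_hz`, `fwhm_hz` (NA when
#'   undefined), `gamma`, `oscillation_index`, `is_spindle`.
#' @export
asd_classify_window <- function(window, fs, zero_pad = 4L,
                                search_band = c(3, 40),
                                alpha_band = c(8, 13),
                                fwhm_max = 2 * 1.37) {
  sp <- asd_spectrum(window, fs, zero_pad)
  inb <- sp$freq >= search_band[1] & sp$freq <= search_band[2]
  f <- sp$freq[inb]; a <- sp$asd[inb]
  ipk <- which.max(a)
  peak_f <- f[ipk]; peak_a <- a[ipk]
  out <- list(peak_freq_hz = peak_f, fwhm_hz = NA_real_, gamma = NA_real_,
              oscillation_index = NA_real_, is_spindle = FALSE)
  class(out) <- "asd_window"
  if (peak_f < alpha_band[1] || peak_f > alpha_band[2]) return(out)

  half <- peak_a / 2
  # walk outward from the peak to the half-maximum crossings
  lo_f <- NA_real_; hi_f <- NA_real_
  interp_cross <- function(f0, a0, f1, a1) {
    if (a1 == a0) return(f0)
    f0 + (half - a0) / (a1 - a0) * (f1 - f0)
  }
  if (ipk > 1L) for (i in (ipk - 1L):1L) {
    if (a[i] <= half) {
      lo_f <- interp_cross(f[i], a[i], f[i + 1L], a[i + 1L])
      break
    }
  }
  if (ipk < length(a)) for (i in (ipk + 1L):length(a)) {
    if (a[i] <= half) {
      hi_f <- interp_cross(f[i], a[i], f[i - 1L], a[i - 1L])
      break
    }
  }
  if (is.na(lo_f) || is.na(hi_f)) return(out)   # crossing not found in band

  fwhm <- hi_f - lo_f
  out$fwhm_hz <- fwhm
  out$is_spindle <- fwhm < fwhm_max
  gam <- tryCatch(fit_noise_exponential(f, a, exclude = c(lo_f, hi_f)),
                  error = function(e) NA_real_)
  out$gamma <- gam
  if (!is.na(gam)) {
    band <- f >= lo_f & f <= hi_f
    if (sum(band) >= 2L) {
      area_sig <- trapz_area(f[band], a[band])
      area_noise <- trapz_area(f[band], exp(gam * f[band]))
      out$oscillation_index <- if (area_noise > 0) area_sig / area_noise
                               else Inf
    }
  }
  out
}

trapz_area <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Sliding-window spindle detection from spectral peak width
#'
#' Applies [asd_classify_window()] to 1 s windows slid by `step_s`
#' (default 250 ms); each spindle-positive window claims its full 1 s span
#' and overlapping spans are unioned, then the same 250 ms merge/prune
#' post-processing as the discounted-AR detector is applied for a fair
#' comparison.
#'
#' @param signal single-channel numeric vector, at least 1 s long.
#' @param fs sampling rate (Hz).
#' @param step_s window slide in seconds (default 0.25).
#' @param merge_gap_s,min_dur_s post-processing, see [postprocess_events()].
#' @param ... passed to [asd_classify_window()].
#' @return an [event_list()]; per-window diagnostics (`t_start_s`,
#'   `peak_freq_hz`, `fwhm_hz`, `oscillation_index`, `is_spindle`) are
#'   attached as attribute `"windows"`.
#' @export
asd_detect <- function(signal, fs, step_s = 0.25, merge_gap_s = 0.250,
                       min_dur_s = 0.250, ...) {
  n <- length(signal)
  wlen <- round(fs)
  if (n < wlen) stop("`signal` must be at least 1 s long")
  starts <- seq(1L, n - wlen + 1L, by = max(1L, round(step_s * fs)))
  res <- lapply(starts, function(s) {
    cls <- asd_classify_window(signal[s:(s + wlen - 1L)], fs, ...)
    data.frame(t_start_s = (s - 1L) / fs, peak_freq_hz = cls$peak_freq_hz,
               fwhm_hz = cls$fwhm_hz,
               oscillation_index = cls$oscillation_index,
               is_spindle = cls$is_spindle)
  })
  diag_df <- do.call(rbind, res)
  pos <- diag_df$is_spindle
  ev <- if (any(pos)) {
    on <- diag_df$t_start_s[pos]; off <- on + 1
    union_intervals(on, off, source = "asd")
  } else event_list(source = "asd")
  ev <- postprocess_events(ev, merge_gap_s, min_dur_s)
  attr(ev, "windows") <- diag_df
  ev
}

# union possibly-overlapping [on, off) intervals into an event_list
union_intervals <- function(on, off, source = "union") {
  o <- order(on)
  on <- on[o]; off <- off[o]
  m_on <- on[1L]; m_off <- off[1L]
  res_on <- c(); res_off <- c()
  if (length(on) > 1L) for (k in 2L:length(on)) {
    if (on[k] <= m_off) m_off <- max(m_off, off[k])
    else { res_on <- c(res_on, m_on); res_off <- c(res_off, m_off)
           m_on <- on[k]; m_off <- off[k] }
  }
  event_list(c(res_on, m_on), c(res_off, m_off), source = source)
}
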