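#' Specification of a piecewise AR change-point process
#'
#' Describes a concatenation of stationary AR segments with Gaussian
#' innovations; the coefficient vector and/or innovation standard deviation
#' change at the segment boundaries (the known change points).
#'
#' @param segments list of segments, each a list with `coef` (AR coefficient
#'   vector in the convention `x_t = sum_i coef_i x_{t-i} + e_t`), `sd`
#'   (innovation standard deviation) and `n` (segment length in samples).
#' @param seed integer RNG seed.
#' @param burn_in samples discarded before segment 1 (default 500).
#' @return object of class `ar_change_spec`.
#' @export
ar_change_spec <- function(segments, seed = 1L, burn_in = 500L) {
  stopifnot(length(segments) >= 1L)
  for (s in segments) {
    stopifnot(is.numeric(s$coef), s$sd >= 0, s$n > 0)
    # stationarity: roots of 1 - a1 z - ... - ap z^p outside the unit circle
    rts <- polyroot(c(1, -s$coef))
    if (any(Mod(rts) <= 1))
      stop("non-stationary AR segment: characteristic root inside the ",
           "unit circle")
  }
  structure(list(segments = segments, seed = as.integer(seed),
                 burn_in = as.integer(burn_in)),
            class = "ar_change_spec")
}

#' The two canonical AR(2) change-point study specifications
#'
#' `model1_spec()` changes the AR coefficients from (0.6, -0.2) to
#' (0.4, -0.6) at sample 2000 with unit innovation variance throughout;
#' `model2_spec()` keeps the coefficients at (0.6, -0.2) and raises the
#' innovation variance from 1 to 4 (sd 1 to 2) at sample 2000.  Both run to
#' sample 4000.
#'
#' @param seed integer RNG seed.
#' @return an [ar_change_spec()].
#' @export
model1_spec <- function(seed = 1L) {
  ar_change_spec(list(list(coef = c(0.6, -0.2), sd = 1, n = 2000L),
                      list(coef = c(0.4, -0.6), sd = 1, n = 2000L)),
                 seed = seed)
}

#' @rdname model1_spec
#' @export
model2_spec <- function(seed = 1L) {
  ar_change_spec(list(list(coef = c(0.6, -0.2), sd = 1, n = 2000L),
                      list(coef = c(0.6, -0.2), sd = 2, n = 2000L)),
                 seed = seed)
}

#' Simulate a piecewise AR change-point series
#'
#' Generates the concatenated AR segments of a spec with continuous lag
#' carry-over across segment boundaries (the process state is not reset at a
#' change point), after discarding a burn-in so segment 1 starts in its
#' stationary regime.  Bit-reproducible given the spec's seed.
#'
#' @param spec an [ar_change_spec()].
#' @return list with `signal` (numeric vector, total segment length) and
#'   `changepoints` (1-based sample indices of the first sample of each
#'   segment after the first).
#' @export
simulate_ar_changepoint <- function(spec) {
  stopifnot(inherits(spec, "ar_change_spec"))
  set.seed(spec$seed)
  p <- max(vapply(spec$segments, function(s) length(s$coef), integer(1)))
  state <- numeric(p)                   # newest first
  # burn-in under segment 1's dynamics
  s1 <- spec$segments[[1L]]
  for (k in seq_len(spec$burn_in)) {
    xt <- sum(s1$coef * state[seq_along(s1$coef)]) + rnorm(1L, 0, s1$sd)
    state <- c(xt, state[-p])
  }
  total <- sum(vapply(spec$segments, `[[`, integer(1), "n"))
  x <- numeric(total)
  i <- 0L
  for (s in spec$segments) {
    eps <- rnorm(s$n, 0, s$sd)
    cf <- s$coef
    for (k in seq_len(s$n)) {
      xt <- sum(cf * state[seq_along(cf)]) + eps[k]
      state <- c(xt, state[-p])
      i <- i + 1L
      x[i] <- xt
    }
  }
  ns <- vapply(spec$segments, `[[`, integer(1), "n")
  cps <- if (length(ns) > 1L) cumsum(ns)[-length(ns)] + 1L else integer()
  list(signal = x, changepoints = cps)
}

# 33-channel 10-10 electrode mosaic used by the spindle simulator
mosaic33 <- c("Fp1", "Fpz", "Fp2",
              "F7", "F3", "Fz", "F4", "F8",
              "FC5", "FC1", "FC2", "FC6",
              "T7", "C3", "Cz", "C4", "T8",
              "CP5", "CP1", "CP2", "CP6",
              "P7", "P3", "Pz", "P4", "P8",
              "PO7", "PO3", "POz", "PO4", "PO8",
              "O1", "O2")

# spatial gain of the posterior alpha source at each electrode row:
# a smooth anterior fall-off peaking over parietal/occipital sites,
# standing in for a two-dipole forward model
row_gain <- c(Fp = 0.02, F = 0.05, FC = 0.10, T = 0.20, C = 0.20,
              CP = 0.40, P = 0.80, PO = 1.00, O = 1.00)

channel_row <- function(labels) {
  sub("^(Fp|FC|CP|PO|F|T|C|P|O).*$", "\\1", labels)
}

#' Specification of the multichannel alpha-spindle simulation
#'
#' Describes the ground-truth spindle study: a posterior alpha source emits
#' a `burst_freq_hz` sinusoidal burst of `burst_dur_s` every
#' `burst_period_s`, starting at `first_burst_s`, over independent white
#' Gaussian background noise of `noise_rms_uv` RMS per channel.  The burst's
#' peak amplitude on the strongest channels is `snr * noise_rms_uv`; other
#' channels receive the burst scaled by a fixed spatial gain that peaks over
#' parietal/occipital electrodes and falls off anteriorly.
#'
#' @param snr amplitude factor over the noise RMS (e.g. an amplitude factor
#'   of 6 over 3 uV RMS noise is SNR 2).
#' @param seed integer RNG seed.
#' @param fs_gen generation sampling rate, Hz (default 300).
#' @param n_channels number of electrodes (default 33; the built-in 10-10
#'   mosaic).
#' @param burst_freq_hz burst carrier frequency (default 10 Hz).
#' @param burst_dur_s burst duration (default 0.5 s).
#' @param burst_period_s burst spacing (default 5 s).
#' @param first_burst_s onset of the first burst (default 10 s).
#' @param n_bursts number of bursts (default 20).
#' @param noise_rms_uv background noise RMS per channel, microvolts
#'   (default 3).
#' @param duration_s total recording length; default runs 9.5 s past the
#'   last burst.
#' @return object of class `spindle_sim_spec`.
#' @export
spindle_sim_spec <- function(snr, seed = 1L, fs_gen = 300, n_channels = 33L,
                             burst_freq_hz = 10, burst_dur_s = 0.5,
                             burst_period_s = 5, first_burst_s = 10,
                             n_bursts = 20L, noise_rms_uv = 3,
                             duration_s = NULL) {
  stopifnot(snr > 0, noise_rms_uv > 0, n_channels >= 1L,
            n_channels <= length(mosaic33))
  last_end <- first_burst_s + (n_bursts - 1L) * burst_period_s + burst_dur_s
  if (is.null(duration_s)) duration_s <- last_end + 9.5
  if (duration_s < last_end)
    stop("`duration_s` ends before the last burst")
  labels <- mosaic33[seq_len(n_channels)]
  gains <- unname(row_gain[channel_row(labels)])
  structure(list(snr = snr, seed = as.integer(seed), fs_gen = fs_gen,
                 n_channels = as.integer(n_channels),
                 channel_labels = labels, channel_gains = gains,
                 burst_freq_hz = burst_freq_hz, burst_dur_s = burst_dur_s,
                 burst_period_s = burst_period_s,
                 first_burst_s = first_burst_s,
                 n_bursts = as.integer(n_bursts),
                 noise_rms_uv = noise_rms_uv, duration_s = duration_s),
            class = "spindle_sim_spec")
}

# 10%-cosine (Tukey) taper: 5% raised-cosine ramps at each end
tukey_taper <- function(n, alpha = 0.1) {
  w <- rep(1, n)
  m <- floor(alpha * (n - 1) / 2)
  if (m >= 1) {
    k <- 0:(m - 1)
    ramp <- 0.5 * (1 + cos(pi * (2 * k / (alpha * (n - 1)) - 1)))
    w[1:m] <- ramp
    w[(n - m + 1):n] <- rev(ramp)
  }
  w
}

#' Simulate multichannel EEG with scheduled alpha bursts
#'
#' Generates the recording described by a [spindle_sim_spec()]: independent
#' white Gaussian noise of the specified RMS on every channel, plus 10 Hz
#' sinusoidal bursts with a 10% cosine taper at the scheduled onsets, with
#' peak amplitude `snr * noise_rms_uv * channel_gain`.  The returned truth
#' labeling is the burst schedule itself.
#'
#' @param spec a [spindle_sim_spec()].
#' @return object of class `eeg_recording` (see [recording()]) with the
#'   ground-truth [event_list()] attached as attribute `"truth"`.
#' @examples
#' rec <- simulate_spindle_eeg(spindle_sim_spec(snr = 3, seed = 42))
#' attr(rec, "truth")[1:3, ]
#' @export
simulate_spindle_eeg <- function(spec) {
  stopifnot(inherits(spec, "spindle_sim_spec"))
  set.seed(spec$seed)
  fs <- spec$fs_gen
  n <- round(spec$duration_s * fs)
  nc <- spec$n_channels
  data <- matrix(rnorm(nc * n, 0, spec$noise_rms_uv), nrow = nc)
  onsets <- spec$first_burst_s + spec$burst_period_s * (seq_len(spec$n_bursts) - 1)
  blen <- round(spec$burst_dur_s * fs)
  taper <- tukey_taper(blen)
  tt <- (seq_len(blen) - 1L) / fs
  amp0 <- spec$snr * spec$noise_rms_uv
  for (on in onsets) {
    i0 <- round(on * fs) + 1L
    idx <- i0:(i0 + blen - 1L)
    burst <- amp0 * taper * sin(2 * pi * spec$burst_freq_hz * tt)
    data[, idx] <- data[, idx] +
      outer(spec$channel_gains, burst)
  }
  truth <- event_list(onsets, onsets + spec$burst_dur_s, source = "truth")
  rec <- recording(data, fs = fs, channel_labels = spec$channel_labels,
                   meta = list(generator = "simulate_spindle_eeg",
                               snr = spec$snr, seed = spec$seed))
  attr(rec, "truth") <- truth
  rec
}
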