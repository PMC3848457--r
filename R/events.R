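#' Event interval lists
#'
#' An `event_list` is a data frame of ordered, pairwise-disjoint half-open
#' intervals `\[onset, offset)` in seconds, with a `source` attribute naming
#' the channel (or `"voted"` for multi-channel detections).
#'
#' @param onset,offset numeric vectors of equal length, `offset > onset`.
#' @param source provenance string.
#' @return data frame of class `event_list` with columns `onset`, `offset`.
#' @export
event_list <- function(onset = numeric(), offset = numeric(),
                       source = "unknown") {
  if (length(onset) != length(offset))
    stop("`onset` and `offset` must have equal length")
  ord <- order(onset)
  onset <- as.numeric(onset[ord]); offset <- as.numeric(offset[ord])
  if (any(offset <= onset))
    stop("all offsets must exceed their onsets")
  if (length(onset) > 1L && any(onset[-1L] < offset[-length(offset)]))
    stop("intervals must be pairwise disjoint")
  structure(data.frame(onset = onset, offset = offset),
            source = source, class = c("event_list", "data.frame"))
}

n_events <- function(ev) nrow(ev)

#' Smooth a loss trace with a centered moving average
#'
#' Reduces the impact of isolated loss outliers before thresholding.  The
#' default 5-sample window sets the effective temporal resolution of the
#' detector.  Edges use shrunken (still centered) windows so the output has
#' the input's length.
#'
#' @param psi non-negative numeric vector of per-sample losses.
#' @param window odd positive integer window length (default 5).
#' @return numeric vector, same length as `psi`.
#' @export
smooth_loss <- function(psi, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("`window` must be an odd positive integer")
  n <- length(psi)
  if (window > n) stop("`window` exceeds the signal length")
  h <- window %/% 2L
  cs <- cumsum(c(0, psi))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Per-channel loss trace
#'
#' Bundles a channel's per-sample quadratic loss with its smoothed version
#' and sampling rate, the unit the detector thresholds.
#'
#' @param psi numeric vector of per-sample losses (non-negative).
#' @param fs sampling rate in Hz.
#' @param channel_id channel label.
#' @param window smoothing window passed to [smooth_loss()].
#' @return object of class `loss_trace`: list with `channel_id`, `fs`,
#'   `psi`, `psi_smooth`.
#' @export
loss_trace <- function(psi, fs, channel_id = "ch", window = 5L) {
  if (any(psi < 0)) stop("losses must be non-negative")
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive")
  structure(list(channel_id = as.character(channel_id), fs = fs,
                 psi = as.numeric(psi),
                 psi_smooth = smooth_loss(psi, window)),
            class = "loss_trace")
}

# boolean above-threshold mask for one trace
trace_mask <- function(trace, tau) trace$psi_smooth > tau

# convert a boolean sample mask to half-open event intervals (seconds)
events_from_mask <- function(mask, fs, source = "mask") {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  event_list(onset = (starts[keep] - 1L) / fs, offset = ends[keep] / fs,
             source = source)
}

#' Threshold a smoothed loss trace into events
#'
#' Maximal runs of samples whose smoothed loss exceeds `tau` become
#' half-open intervals `\[onset, offset)`; sample `i` (1-based) spans
#' `[(i-1)/fs, i/fs)`.
#'
#' @param trace a [loss_trace()].
#' @param tau non-negative threshold on the smoothed loss.
#' @return an [event_list()].
#' @export
threshold_events <- function(trace, tau) {
  stopifnot(inherits(trace, "loss_trace"))
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    stop("`tau` must be a single non-negative number")
  events_from_mask(trace_mask(trace, tau), trace$fs,
                   source = trace$channel_id)
}

#' Combine per-channel detection masks by voting
#'
#' A sample is flagged iff at least `ceiling(fraction * n_channels)` channels
#' flag it.  With the default 1/3 vote, 2 of 6 channels suffice.  Voting
#' suppresses isolated single-channel outliers.
#'
#' @param masks logical matrix (channels in columns) or list of equal-length
#'   logical vectors.
#' @param fraction required fraction of channels in (0, 1].
#' @return logical vector.
#' @export
vote_channels <- function(masks, fraction = 1 / 3) {
  if (is.list(masks)) {
    if (length(masks) == 0L) stop("no channel masks supplied")
    if (length(unique(lengths(masks))) != 1L)
      stop("all masks must have equal length")
    masks <- do.call(cbind, masks)
  }
  if (is.null(dim(masks)) || ncol(masks) == 0L)
    stop("no channel masks supplied")
  if (!(fraction > 0 && fraction <= 1))
    stop("`fraction` must be in (0, 1]")
  need <- ceiling(fraction * ncol(masks))
  rowSums(masks) >= need
}

#' Merge close events and drop short ones
#'
#' Post-processing of detected spindle regions: intervals separated by less
#' than `merge_gap_s` are merged into a single event, then isolated events
#' shorter than `min_dur_s` are removed (merge first, so a short fragment
#' close to a large event survives via merging).  Alpha spindles last
#' roughly 0.5-2 s, hence the 250 ms defaults.  Idempotent.
#'
#' @param events an [event_list()].
#' @param merge_gap_s gaps strictly below this (seconds) are merged.
#' @param min_dur_s events strictly shorter than this (seconds) are dropped.
#' @return an [event_list()].
#' @export
postprocess_events <- function(events, merge_gap_s = 0.250,
                               min_dur_s = 0.250) {
  stopifnot(inherits(events, "event_list"))
  src <- attr(events, "source")
  if (nrow(events) == 0L) return(events)
  on <- events$onset; off <- events$offset
  if (nrow(events) > 1L) {
    keep_on <- on[1L]; m_on <- c(); m_off <- c()
    cur_off <- off[1L]
    for (k in 2L:length(on)) {
      if (on[k] - cur_off < merge_gap_s) {
        cur_off <- max(cur_off, off[k])
      } else {
        m_on <- c(m_on, keep_on); m_off <- c(m_off, cur_off)
        keep_on <- on[k]; cur_off <- off[k]
      }
    }
    on <- c(m_on, keep_on); off <- c(m_off, cur_off)
  }
  dur <- off - on
  keep <- dur >= min_dur_s
  event_list(on[keep], off[keep], source = src)
}

#' Choose the loss threshold by maximizing the weighted F-measure
#'
#' Sweeps candidate thresholds over the pooled smoothed-loss distribution;
#' for each candidate the full detection chain is run (per-channel
#' thresholding, channel voting, merge/prune post-processing) and the
#' detections are compared against labeled ground-truth intervals with
#' [compare_labels()].  Returns the threshold maximizing
#' \eqn{F_\beta} (ties broken toward the smallest threshold) and the full
#' threshold--F curve.  `beta = 2` weights recall above precision, suited to
#' rare events where missing one costs more than a false alarm.
#'
#' @param traces list of [loss_trace()] objects (one per channel, equal
#'   length and sampling rate).
#' @param truth ground-truth [event_list()]; must be non-empty.
#' @param beta F-measure weight (default 2).
#' @param fuzzy_s fuzzy boundary-tolerance window in seconds for the
#'   comparison (default 0).
#' @param grid numeric vector of candidate thresholds; default 200
#'   quantile-spaced candidates over the pooled smoothed losses.
#' @param vote_fraction channel-voting fraction (default 1/3).
#' @param merge_gap_s,min_dur_s post-processing parameters, see
#'   [postprocess_events()].
#' @param total_dur_s total compared duration in seconds; defaults to the
#'   trace length.
#' @return list with `tau` (optimal threshold), `fbeta` (its F value),
#'   `events` (detections at `tau`), and `curve` (data frame of `tau`,
#'   `fbeta`, `precision`, `recall`, `specificity` per candidate).
#' @export
optimize_threshold <- function(traces, truth, beta = 2, fuzzy_s = 0,
                               grid = NULL, vote_fraction = 1 / 3,
                               merge_gap_s = 0.250, min_dur_s = 0.250,
                               total_dur_s = NULL) {
  if (inherits(traces, "loss_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L, inherits(truth, "event_list"))
  if (nrow(truth) == 0L)
    stop("`truth` is empty: the F-measure is undefined with no positives")
  fs <- traces[[1L]]$fs
  n <- length(traces[[1L]]$psi_smooth)
  if (is.null(total_dur_s)) total_dur_s <- n / fs
  if (is.null(grid)) {
    pooled <- unlist(lapply(traces, `[[`, "psi_smooth"))
    grid <- unique(quantile(pooled, probs = seq(0, 1, length.out = 200),
                            names = FALSE))
  }
  grid <- sort(unique(grid))
  eval_tau <- function(tau) {
    det <- detect_at_threshold(traces, tau, vote_fraction,
                               merge_gap_s, min_dur_s)
    cmp <- compare_labels(truth, det, fuzzy_s = fuzzy_s,
                          total_dur_s = total_dur_s, fs = fs)
    c(fbeta = f_beta(cmp$precision, cmp$recall, beta),
      precision = cmp$precision, recall = cmp$recall,
      specificity = cmp$specificity)
  }
  res <- t(vapply(grid, eval_tau, numeric(4)))
  curve <- data.frame(tau = grid, res)
  best <- which.max(curve$fbeta)        # ties -> smallest tau (first index)
  tau_star <- grid[best]
  list(tau = tau_star, fbeta = curve$fbeta[best],
       events = detect_at_threshold(traces, tau_star, vote_fraction,
                                    merge_gap_s, min_dur_s),
       curve = curve)
}

# threshold -> vote -> postprocess, shared by the sweep and the final call
detect_at_threshold <- function(traces, tau, vote_fraction = 1 / 3,
                                merge_gap_s = 0.250, min_dur_s = 0.250) {
  masks <- vapply(traces, trace_mask, logical(length(traces[[1L]]$psi)),
                  tau = tau)
  if (is.null(dim(masks))) masks <- matrix(masks, ncol = length(traces))
  voted <- vote_channels(masks, vote_fraction)
  postprocess_events(events_from_mask(voted, traces[[1L]]$fs,
                                      source = "voted"),
                     merge_gap_s, min_dur_s)
}
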