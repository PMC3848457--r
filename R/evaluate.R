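#' Time-based comparison of two labeled interval sets
#'
#' Classifies every instant of the recording into one of four states by set
#' arithmetic between a ground-truth labeling and a detected labeling:
#' Agreement (both mark an event), Null Agreement (neither does), False
#' Negative (truth only) and False Positive (detection only).  State
#' durations always partition the total compared duration.
#'
#' An optional fuzzy window forgives small boundary disagreements: False
#' Negative and False Positive time lying within `fuzzy_s` seconds of an
#' Agreement run is treated as Agreement, so that detections that are merely
#' shifted or slightly too narrow/wide at their edges are not penalized.
#' A truth event with no overlapping detection receives no forgiveness.
#'
#' All interval arithmetic is carried out on the discrete sample grid at
#' `fs`, which makes the duration sums exact; interval endpoints are rounded
#' to the nearest sample.
#'
#' @param truth,detected [event_list()] objects with intervals inside
#'   `[0, total_dur_s]`.
#' @param fuzzy_s fuzzy window in seconds (default 0: exact comparison).
#' @param total_dur_s total duration compared, seconds.
#' @param fs evaluation grid rate in Hz (default 128).
#' @return object of class `comparison_summary`: list with state durations
#'   `t_agree`, `t_null`, `t_fp`, `t_fn` (seconds), event counts `n_truth`,
#'   `n_hit`, and derived `precision`, `recall` (= sensitivity),
#'   `specificity`, `hit_rate`, `ste_s` (temporal error: FN time per truth
#'   event).
#' @export
compare_labels <- function(truth, detected, fuzzy_s = 0, total_dur_s,
                           fs = 128) {
  stopifnot(inherits(truth, "event_list"), inherits(detected, "event_list"))
  if (!is.numeric(total_dur_s) || total_dur_s <= 0)
    stop("`total_dur_s` must be positive")
  n <- round(total_dur_s * fs)
  tm <- rasterize_events(truth, fs, n)
  dm <- rasterize_events(detected, fs, n)

  agree <- tm & dm
  fn <- tm & !dm
  fp <- !tm & dm

  if (fuzzy_s > 0 && any(agree)) {
    w <- round(fuzzy_s * fs)
    if (w > 0) {
      zone <- dilate_mask(agree, w) & !agree   # fuzzy extension of agreement
      agree <- agree | (zone & (fn | fp))
      fn <- fn & !agree
      fp <- fp & !agree
    }
  }
  null_ <- !agree & !fn & !fp

  n_truth <- nrow(truth)
  n_hit <- if (n_truth == 0L) 0L else
    sum(vapply(seq_len(n_truth), function(k) {
      any(detected$offset > truth$onset[k] & detected$onset < truth$offset[k])
    }, logical(1)))

  t_agree <- sum(agree) / fs; t_null <- sum(null_) / fs
  t_fp <- sum(fp) / fs; t_fn <- sum(fn) / fs
  precision <- safe_ratio(t_agree, t_agree + t_fp)
  recall <- safe_ratio(t_agree, t_agree + t_fn)
  specificity <- safe_ratio(t_null, t_null + t_fp)
  structure(list(t_agree = t_agree, t_null = t_null, t_fp = t_fp,
                 t_fn = t_fn, n_truth = n_truth, n_hit = n_hit,
                 precision = precision, recall = recall,
                 sensitivity = recall, specificity = specificity,
                 hit_rate = if (n_truth > 0L) n_hit / n_truth else NA_real_,
                 ste_s = if (n_truth > 0L) t_fn / n_truth else NA_real_,
                 total_dur_s = n / fs, fs = fs, fuzzy_s = fuzzy_s),
            class = "comparison_summary")
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

# boolean sample mask of an event list on an n-sample grid at fs
rasterize_events <- function(events, fs, n) {
  mask <- logical(n)
  if (nrow(events) == 0L) return(mask)
  i0 <- pmax(round(events$onset * fs) + 1L, 1L)
  i1 <- pmin(round(events$offset * fs), n)
  for (k in seq_along(i0)) if (i0[k] <= i1[k]) mask[i0[k]:i1[k]] <- TRUE
  mask
}

# widen TRUE runs by w samples on each side
dilate_mask <- function(mask, w) {
  n <- length(mask)
  out <- mask
  idx <- which(mask)
  if (length(idx) == 0L || w == 0L) return(out)
  r <- rle(mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    lo <- max(1L, starts[k] - w); hi <- min(n, ends[k] + w)
    out[lo:hi] <- TRUE
  }
  out
}

#' Weighted F-measure
#'
#' \eqn{F_\beta = (1+\beta^2)\,PR / (\beta^2 P + R)}.  `beta = 1` is the
#' usual harmonic mean; `beta = 2` emphasizes recall, `beta = 0.5`
#' precision.  Defined as 0 when precision and recall are both 0.
#'
#' @param precision,recall values in \[0, 1\].
#' @param beta non-negative weight.
#' @return the weighted F-measure.
#' @export
f_beta <- function(precision, recall, beta = 1) {
  if (is.na(precision) || is.na(recall)) return(0)
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1,
            beta >= 0)
  den <- beta^2 * precision + recall
  if (den == 0) return(0)
  (1 + beta^2) * precision * recall / den
}

#' Time-based ROC curve over a threshold grid
#'
#' For each candidate threshold the full detection chain is run and
#' compared against the truth labeling; the true-positive rate is the
#' time-based recall and the false-positive rate is one minus the
#' specificity.
#'
#' @inheritParams optimize_threshold
#' @return data frame with columns `tau`, `fpr`, `tpr`, sorted by `tau`.
#' @export
roc_curve <- function(traces, truth, fuzzy_s = 0, grid = NULL,
                      vote_fraction = 1 / 3, merge_gap_s = 0.250,
                      min_dur_s = 0.250, total_dur_s = NULL) {
  if (inherits(traces, "loss_trace")) traces <- list(traces)
  stopifnot(nrow(truth) > 0L)
  fs <- traces[[1L]]$fs
  n <- length(traces[[1L]]$psi_smooth)
  if (is.null(total_dur_s)) total_dur_s <- n / fs
  if (is.null(grid)) {
    pooled <- unlist(lapply(traces, `[[`, "psi_smooth"))
    grid <- unique(quantile(pooled, probs = seq(0, 1, length.out = 200),
                            names = FALSE))
  }
  grid <- sort(unique(grid))
  pts <- t(vapply(grid, function(tau) {
    det <- detect_at_threshold(traces, tau, vote_fraction,
                               merge_gap_s, min_dur_s)
    cmp <- compare_labels(truth, det, fuzzy_s = fuzzy_s,
                          total_dur_s = total_dur_s, fs = fs)
    c(fpr = 1 - cmp$specificity, tpr = cmp$recall)
  }, numeric(2)))
  data.frame(tau = grid, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}

#' @export
print.comparison_summary <- function(x, ...) {
  cat("Labeled-interval comparison (fuzzy window ",
      format(x$fuzzy_s), " s)\n", sep = "")
  cat(sprintf("  Sensitivity/Recall  %.3f\n", x$recall))
  cat(sprintf("  Specificity         %.3f\n", x$specificity))
  cat(sprintf("  Precision           %.3f\n", x$precision))
  if (!is.na(x$hit_rate))
    cat(sprintf("  Hit Rate            %.2f%% (%d/%d)\n", 100 * x$hit_rate,
                x$n_hit, x$n_truth))
  if (!is.na(x$ste_s))
    cat(sprintf("  Temporal Error      ~%.0f ms\n", 1000 * x$ste_s))
  cat(sprintf("  Agreement           %.3f s\n", x$t_agree))
  cat(sprintf("  Null Agreement      %.3f s\n", x$t_null))
  cat(sprintf("  False Negative      %.3f s\n", x$t_fn))
  cat(sprintf("  False Positive      %.3f s\n", x$t_fp))
  invisible(x)
}
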