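#' Initialize the sequential discounted AR recursion
#'
#' Sets up the recursion state at time `t = p` from the first `p` samples and
#' a Burg estimate of the AR parameters on a training segment: the gain
#' matrix starts at the identity, the moment vector at the Burg coefficients,
#' and the model variance at the Burg innovation variance.
#'
#' @param x_first_p numeric vector: the first `p` samples of the series, in
#'   temporal order.
#' @param burg a [burg_fit()] result (or a list with elements `A`, `sigma2`).
#' @param r discounting rate in (0, 1); past samples are down-weighted by
#'   `(1 - r)^(t - i)`.
#' @return an object of class `sdar_state` with fields `p`, `r`, `t`, `A`,
#'   `M`, `V`, `c`, `mu`, `sigma2` and `lag_buffer` (newest first).
#' @seealso [sdar_step()], [sdar_run()]
#' @export
sdar_init <- function(x_first_p, burg, r) {
  p <- length(burg$A)
  if (length(x_first_p) != p)
    stop("`x_first_p` must have exactly p = ", p, " samples")
  if (!is.numeric(r) || length(r) != 1L || !(r > 0 && r < 1))
    stop("`r` must be a single number in (0, 1)")
  if (!is.numeric(burg$sigma2) || burg$sigma2 < 0)
    stop("invalid initial variance")
  xb <- rev(as.numeric(x_first_p))        # lag buffer, newest first
  V <- diag(p)
  M <- as.numeric(burg$A)
  structure(list(p = p, r = r, t = p,
                 A = as.numeric(V %*% M), M = M, V = V,
                 c = r * sum(xb^2), mu = NA_real_,
                 sigma2 = as.numeric(burg$sigma2),
                 lag_buffer = xb),
            class = "sdar_state")
}

#' Advance the discounted AR recursion by one sample
#'
#' Applies one update of the sequential discounted AR recursion: the gain
#' scalar, moment vector, gain matrix and coefficients are refreshed with the
#' incoming sample, then the predictive mean, the exponentially weighted
#' model variance, and the quadratic loss \eqn{\psi_t = (x_t - \mu_t)^2} are
#' computed.  The coefficient update deliberately precedes the mean
#' computation, so the loss is a partially in-sample residual (the
#' difference from a strict one-step-ahead residual is of order `r`).
#'
#' @param state an `sdar_state` from [sdar_init()] or a previous step.
#' @param x_t the new sample (finite scalar).
#' @return list with elements `state` (the advanced `sdar_state`) and `psi`
#'   (the quadratic loss at this sample).
#' @export
sdar_step <- function(state, x_t) {
  stopifnot(inherits(state, "sdar_state"))
  if (length(x_t) != 1L || !is.finite(x_t))
    stop("`x_t` must be a single finite number")
  r <- state$r
  xb <- state$lag_buffer
  Vx <- as.numeric(state$V %*% xb)
  cc <- r * sum(xb * Vx)
  denom <- 1 - r + cc
  if (denom <= 0 || !is.finite(denom))
    stop("degenerate gain: 1 - r + c_t is not positive")
  M <- (1 - r) * state$M + r * xb * x_t
  V <- (state$V - (r / denom) * tcrossprod(Vx)) / (1 - r)
  V <- (V + t(V)) / 2
  A <- as.numeric(V %*% M)
  mu <- sum(A * xb)
  sigma2 <- max((1 - r) * state$sigma2 + r * (x_t - mu)^2, 1e-12)
  psi <- (x_t - mu)^2
  state$A <- A; state$M <- M; state$V <- V; state$c <- cc
  state$mu <- mu; state$sigma2 <- sigma2
  state$lag_buffer <- c(x_t, xb[-state$p])
  state$t <- state$t + 1L
  list(state = state, psi = psi)
}

#' Run the SDAR change-point filter over a series
#'
#' Fits a Burg AR model to an initial training segment, initializes the
#' discounted recursion at `t = p`, and filters the whole series, returning
#' the per-sample quadratic loss together with the traces of the estimated
#' coefficients, predictive mean and model variance.  The quadratic loss
#' spikes when the discounted model mispredicts, i.e. at abrupt changes in
#' the series' statistical structure — the detection statistic for
#' oscillatory burst onsets.
#'
#' The training-segment mean is subtracted from the whole series before
#' filtering (`demean = TRUE`), since the AR model assumes a zero-mean
#' series; band-passed EEG is already near zero-mean.
#'
#' @param signal numeric vector.
#' @param p model order (1 or 2 are typical for narrowband EEG).
#' @param r discounting rate in (0, 1); about 0.01 to 0.001 works well for
#'   data sampled at 128 Hz, smaller for higher sampling rates.
#' @param train_len number of leading samples used for the Burg
#'   initialization fit; default 1280 (10 s at 128 Hz), capped at the signal
#'   length.  Ignored when `init` is supplied.
#' @param init optional explicit initializer (a `burg_estimate` or list with
#'   `A` and `sigma2`) overriding the training fit; useful for degenerate
#'   inputs a Burg fit rejects, e.g. constant segments.
#' @param demean subtract the training-segment mean first (default TRUE).
#' @return object of class `sdar_fit`: list with `loss` (psi, zero for
#'   `t <= p`), `mu`, `sigma2`, `coefficients` (n x p matrix), `V` (final
#'   gain matrix), `p`, `r`, `train_len`, `init`, `valid_from` (= p + 1).
#' @examples
#' set.seed(1)
#' x <- as.numeric(arima.sim(list(ar = c(0.6, -0.2)), 1500))
#' fit <- sdar_run(x, p = 2, r = 0.01, train_len = 500)
#' colMeans(fit$coefficients[1000:1500, ])
#' @export
sdar_run <- function(signal, p, r, train_len = NULL, init = NULL,
                     demean = TRUE) {
  p <- as.integer(p)
  n <- length(signal)
  if (is.null(init)) {
    if (is.null(train_len)) train_len <- min(n, 1280L)
    train_len <- as.integer(train_len)
    if (train_len < 2L * p + 1L)
      stop("`train_len` must be at least 2p + 1 = ", 2L * p + 1L)
    if (n < train_len)
      stop("signal shorter than the training segment")
    mu0 <- if (demean) mean(signal[seq_len(train_len)]) else 0
    x <- signal - mu0
    init <- burg_fit(x[seq_len(train_len)], p)
  } else {
    if (length(init$A) != p) stop("`init` has wrong order")
    train_len <- if (is.null(train_len)) 0L else as.integer(train_len)
    mu0 <- 0
    x <- signal
  }
  out <- .sdar_filter_cpp(as.numeric(x), p, r, as.numeric(init$A),
                          as.numeric(init$sigma2))
  structure(list(loss = out$psi, mu = out$mu, sigma2 = out$sigma2,
                 coefficients = out$coefficients, V = out$V,
                 max_asymmetry = out$max_asymmetry,
                 p = p, r = r, train_len = train_len, init = init,
                 center = mu0, valid_from = p + 1L),
            class = "sdar_fit")
}

#' @export
print.sdar_fit <- function(x, ...) {
  n <- length(x$loss)
  cat("SDAR fit: order", x$p, " r =", x$r, " n =", n, "\n")
  cat("  final coefficients:",
      format(x$coefficients[n, ], digits = 4), "\n")
  cat("  final model variance:", format(x$sigma2[n], digits = 4), "\n")
  invisible(x)
}

#' @export
plot.sdar_fit <- function(x, which = c("loss", "coefficients", "sigma2"),
                          ...) {
  which <- match.arg(which)
  n <- length(x$loss)
  idx <- seq_len(n)
  switch(which,
    loss = plot(idx, x$loss, type = "l", xlab = "sample",
                ylab = expression(psi[t]), ...),
    coefficients = {
      matplot_y <- x$coefficients
      plot(idx, matplot_y[, 1], type = "l", ylim = range(matplot_y),
           xlab = "sample", ylab = "AR coefficient", ...)
      if (ncol(matplot_y) > 1)
        for (j in 2:ncol(matplot_y)) lines(idx, matplot_y[, j], lty = j)
    },
    sigma2 = plot(idx, x$sigma2, type = "l", xlab = "sample",
                  ylab = expression(sigma[t]^2), ...))
  invisible(x)
}
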