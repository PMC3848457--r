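#' Burg AR parameter estimate
#'
#' Fits an autoregressive model of fixed order by the Burg (lattice /
#' reflection coefficient) method, in the prediction convention
#' \eqn{x_t = \sum_i A_i x_{t-i} + \epsilon_t}.  Used to initialize the
#' sequential discounted AR recursion from a training segment.
#'
#' The series is treated as zero-mean: its sample mean is subtracted before
#' fitting.
#'
#' @param signal numeric vector, length > `2 * p`.
#' @param p positive integer model order.
#' @return an object of class `burg_estimate`: a list with elements
#'   `A` (length-`p` coefficient vector), `sigma2` (innovation variance
#'   estimate) and `p`.
#' @examples
#' set.seed(1)
#' x <- as.numeric(arima.sim(list(ar = c(0.6, -0.2)), 2000))
#' burg_fit(x, 2)
#' @export
burg_fit <- function(signal, p) {
  p <- as.integer(p)
  if (length(p) != 1L || is.na(p) || p < 1L)
    stop("`p` must be a positive integer")
  if (!is.numeric(signal) || anyNA(signal) || any(!is.finite(signal)))
    stop("`signal` must be finite numeric")
  if (length(signal) <= 2L * p)
    stop("`signal` too short for order ", p, ": need more than ", 2L * p,
         " samples")
  x <- signal - mean(signal)
  if (sd(x) == 0)
    stop("`signal` is constant; AR coefficients are undefined")
  fit <- stats::ar.burg(x, aic = FALSE, order.max = p, demean = FALSE)
  structure(list(A = as.numeric(fit$ar), sigma2 = as.numeric(fit$var.pred),
                 p = p),
            class = "burg_estimate")
}

#' @export
print.burg_estimate <- function(x, ...) {
  cat("Burg AR(", x$p, ") estimate\n", sep = "")
  cat("  coefficients:", format(x$A, digits = 4), "\n")
  cat("  innovation variance:", format(x$sigma2, digits = 4), "\n")
  invisible(x)
}
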