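# Independent oracles and fixture builders shared across tests.

# Batch discounted least squares: the coefficient vector minimizing
#   sum_{i=p+1..t} (1-r)^(t-i) (x_i - A' xbar_i)^2
# by explicitly solving the weighted normal equations.  Independent of the
# sequential recursion it cross-checks.
batch_discounted_ls <- function(x, p, r, t) {
  idx <- (p + 1L):t
  X <- vapply(seq_len(p), function(j) x[idx - j], numeric(length(idx)))
  w <- (1 - r)^(t - idx)
  G <- crossprod(X * w, X)
  b <- colSums(X * (w * x[idx]))
  as.numeric(solve(G, b))
}

# Stationary variance of an AR(2) process x_t = a1 x_{t-1} + a2 x_{t-2} + e,
# innovation variance s2 (Yule-Walker closed form).
ar2_stationary_var <- function(a1, a2, s2 = 1) {
  s2 * (1 - a2) / ((1 + a2) * ((1 - a2)^2 - a1^2))
}

# Random list of disjoint grid-aligned intervals on [0, total_s] at fs.
random_event_list <- function(total_s, fs, max_events = 6L) {
  n <- round(total_s * fs)
  k <- sample.int(max_events, 1L)
  pts <- sort(sample.int(n + 1L, 2L * k) - 1L) / fs
  event_list(pts[seq(1L, 2L * k, by = 2L)], pts[seq(2L, 2L * k, by = 2L)],
             source = "random")
}

# Loss traces with a known separable structure: background loss ~0, loss = hi
# inside the given truth intervals, on every channel.
separable_traces <- function(truth, total_s, fs, n_channels = 3L,
                             hi = 10, lo = 0.01) {
  n <- round(total_s * fs)
  mask <- rasterize_events_test(truth, fs, n)
  lapply(seq_len(n_channels), function(i) {
    psi <- ifelse(mask, hi, lo)
    loss_trace(psi, fs = fs, channel_id = paste0("ch", i), window = 1L)
  })
}

# local re-implementation of grid rasterization (kept independent of the
# package internals on purpose)
rasterize_events_test <- function(events, fs, n) {
  mask <- logical(n)
  for (k in seq_len(nrow(events))) {
    i0 <- round(events$onset[k] * fs) + 1L
    i1 <- round(events$offset[k] * fs)
    if (i0 <= i1) mask[i0:min(i1, n)] <- TRUE
  }
  mask
}

# Sample a stationary AR(p) series by direct recursion after burn-in.
gen_ar <- function(coefs, n, sd = 1, burn = 300L) {
  p <- length(coefs)
  x <- numeric(n + burn + p)
  e <- rnorm(n + burn + p, 0, sd)
  for (t in (p + 1L):length(x))
    x[t] <- sum(coefs * x[t - seq_len(p)]) + e[t]
  x[(burn + p + 1L):length(x)]
}
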