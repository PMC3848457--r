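burg_stub <- function(A, sigma2) list(A = A, sigma2 = sigma2, p = length(A))

test_that("sdar_init applies the initialization formulas", {
  st <- sdar_init(2, burg_stub(0.5, 1.0), r = 0.01)
  expect_equal(st$A, 0.5)
  expect_equal(st$c, 0.04)              # r * x^2 = 0.01 * 4
  expect_equal(st$V, diag(1))
  expect_equal(st$sigma2, 1.0)
  expect_equal(st$t, 1L)

  # zero first samples give zero gain scalar
  st0 <- sdar_init(c(0, 0), burg_stub(c(0.6, -0.2), 1), r = 0.1)
  expect_equal(st0$c, 0)
  # with V = I the coefficients start at the Burg estimate
  expect_equal(st0$A, c(0.6, -0.2))
  expect_equal(st0$lag_buffer, c(0, 0))

  expect_error(sdar_init(2, burg_stub(0.5, 1), r = 1.5), "in \\(0, 1\\)")
  expect_error(sdar_init(c(1, 2), burg_stub(0.5, 1), r = 0.1), "exactly")
})

test_that("sdar_step reproduces a hand-unrolled two-step recursion", {
  # p = 1, r = 0.5, V0 = 1, M0 = 0, buffer = [1]; feed x = 1 twice.
  # Unrolled by hand:
  #  step 1: c = 0.5; M = 0.5; V = (1 - 0.5/1)/0.5 = 1; A = 0.5
  #          mu = 0.5; psi = 0.25; sigma2 = 0.5*1 + 0.5*0.25 = 0.625
  #  step 2: c = 0.5; M = 0.75; V = 1; A = 0.75
  #          mu = 0.75; psi = 0.0625; sigma2 = 0.5*0.625 + 0.5*0.0625
  st <- sdar_init(1, burg_stub(0, 1.0), r = 0.5)
  s1 <- sdar_step(st, 1)
  expect_equal(s1$state$A, 0.5)
  expect_equal(s1$state$V, matrix(1))
  expect_equal(s1$psi, 0.25)
  expect_equal(s1$state$sigma2, 0.625)
  s2 <- sdar_step(s1$state, 1)
  expect_equal(s2$state$A, 0.75)
  expect_equal(s2$psi, 0.0625)
  expect_equal(s2$state$sigma2, 0.34375)

  # trivial identities
  stz <- sdar_init(c(0, 0), burg_stub(c(0.3, 0.1), 1), r = 0.1)
  rz <- sdar_step(stz, 0)
  expect_equal(rz$state$mu, 0)
  expect_equal(rz$psi, 0)
  expect_error(sdar_step(stz, NaN), "finite")
})

test_that("R step recursion and the compiled filter agree", {
  set.seed(21)
  x <- gen_ar(c(0.5, -0.3), 120)
  p <- 2; r <- 0.05
  init <- burg_fit(x[1:60], p)
  fit <- sdar_run(x, p, r, train_len = 60, demean = FALSE)
  st <- sdar_init(x[1:p], init, r)
  for (t in (p + 1):length(x)) {
    res <- sdar_step(st, x[t])
    st <- res$state
    expect_equal(res$psi, fit$loss[t], tolerance = 1e-12)
    expect_equal(st$A, fit$coefficients[t, ], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_equal(st$V, fit$V, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("sequential coefficients match batch discounted least squares", {
  set.seed(22)
  p <- 2; r <- 0.1
  x <- gen_ar(c(0.6, -0.2), 200)
  fit <- sdar_run(x, p, r, train_len = 50, demean = FALSE)
  for (t in c(60, 100, 150, 200)) {
    oracle <- batch_discounted_ls(x, p, r, t)
    expect_lt(max(abs(fit$coefficients[t, ] - oracle)), 0.05)
  }
})

test_that("sigma2 trace is exactly the exponentially weighted residual", {
  set.seed(23)
  x <- gen_ar(0.4, 500)
  r <- 0.02
  fit <- sdar_run(x, 1, 0.02, train_len = 100, demean = FALSE)
  s <- fit$init$sigma2
  for (t in 2:500) {
    s <- max((1 - r) * s + r * (x[t] - fit$mu[t])^2, 1e-12)
    expect_equal(fit$sigma2[t], s, tolerance = 1e-12)
  }
})

test_that("gain matrix stays symmetric over long random runs", {
  set.seed(24)
  x <- rnorm(1e5)
  fit <- sdar_run(x, 3, 0.01, train_len = 1000)
  expect_lt(fit$max_asymmetry, 1e-9)
  expect_equal(fit$V, t(fit$V))
})

test_that("long-run coefficient averages recover stationary AR truth", {
  set.seed(25)
  for (coefs in list(0.7, c(0.6, -0.2), c(0.3, 0.2))) {
    p <- length(coefs)
    x <- gen_ar(coefs, 20000)
    fit <- sdar_run(x, p, r = 0.01, train_len = 1000, demean = FALSE)
    est <- colMeans(fit$coefficients[10001:20000, , drop = FALSE])
    # small-sample bias of the discounted estimator (effective sample
    # size about 2/r) keeps this from being exact; 0.04 is about 3 SE of
    # the time-averaged estimate plus that bias
    expect_lt(max(abs(est - coefs)), 0.04)
  }
})

test_that("constant-zero input yields zero loss and decaying variance", {
  fit <- sdar_run(numeric(300), p = 1, r = 0.05,
                  init = burg_stub(0.5, 1.0))
  expect_true(all(fit$loss == 0))
  # sigma2 decays geometrically (floored far below this horizon)
  expect_equal(fit$sigma2[100], (1 - 0.05)^99, tolerance = 1e-9)
  expect_true(all(diff(fit$sigma2) <= 0))
  expect_gte(min(fit$sigma2), 1e-12)
})

test_that("sdar_run validates its inputs", {
  expect_error(sdar_run(rnorm(100), 2, r = 1.2, train_len = 50), "\\(0, 1\\)")
  expect_error(sdar_run(rnorm(100), 2, r = 0.1, train_len = 3),
               "train_len")
  expect_error(sdar_run(rnorm(30), 2, r = 0.1, train_len = 50),
               "shorter")
})
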