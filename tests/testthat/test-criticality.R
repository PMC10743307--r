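test_that("power-law fits are exact on clean data and RMA = LS/|r|", {
  x <- 10^seq(-3, 0, length.out = 8)
  f <- fit_power_law(x, x^-2)
  expect_equal(f$exponent, -2, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit_power_law(x, x^-2, method = "RMA")$exponent, -2,
               tolerance = 1e-12)
  # noisy data: the reduced-major-axis identity holds programmatically
  set.seed(7)
  y <- x^-0.5 * 10^rnorm(8, sd = 0.2)
  ls <- fit_power_law(x, y, "LS")
  rma <- fit_power_law(x, y, "RMA")
  expect_equal(rma$exponent, ls$exponent / abs(ls$r), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(rma$exponent, ls$exponent)))
  expect_error(fit_power_law(c(-1, 2, 3), c(1, 2, 3)), "positive")
  expect_error(fit_power_law(1:2, 1:2), ">= 3")
})

test_that("critical-curve minimizers are recovered from synthetic objectives", {
  beta <- 10^seq(-4, -1, length.out = 13)
  # log-parabolic correlation time with known minimum at 1e-2.5
  tau <- 10^(0.7 + 1.5 * (log10(beta) + 2.5)^2)
  scan <- data.frame(beta = beta, tau_kc = tau, t_m = tau)
  bc <- find_beta_c(scan)
  expect_equal(log10(bc$beta_c), -2.5, tolerance = 0.02)
  expect_true(bc$refined)
  # monotone objective: bracket failure
  expect_error(find_beta_c(data.frame(beta = beta, tau_kc = beta)),
               "boundary")
  # synthetic unimodal susceptibility
  chi <- 10^(2 - 2 * (log10(beta) + 2)^2)
  bm <- find_beta_m(data.frame(beta = beta, chi = chi))
  expect_equal(log10(bm$beta_m), -2, tolerance = 0.02)
  expect_error(find_beta_m(data.frame(beta = beta, chi = beta)), "boundary")
})

test_that("the exponent suite recovers planted power laws exactly", {
  beta_c <- 10^seq(-4, -2.5, length.out = 5)
  pts <- data.frame(
    n = 1:5, eta = 0.5,
    beta_c = beta_c,
    beta_m = beta_c / 0.035,
    xi = 2.0 * beta_c^-0.30,
    chi_m = 0.5 * (beta_c / 0.035)^-0.78,
    W = 1.3 * beta_c^0.42,
    k_c = (2.0 * beta_c^-0.30)^-1,
    lambda1 = 0.8 * beta_c^0.29)
  pts$tau_kc <- 3 * pts$k_c^-0.99
  pts$chi <- pts$chi_m
  es <- exponent_suite(pts)
  expect_equal(es$nu$LS$exponent, 0.30, tolerance = 1e-10)
  expect_equal(es$gamma$LS$exponent, 0.78, tolerance = 1e-10)
  expect_equal(es$b$LS$exponent, 0.42, tolerance = 1e-10)
  expect_equal(es$z$LS$exponent, 0.99, tolerance = 1e-10)
  expect_equal(es$phi$LS$exponent, 0.29, tolerance = 1e-10)
  expect_equal(es$phi$RMA$exponent, 0.29, tolerance = 1e-10)
  expect_error(exponent_suite(pts[1:2, ]), ">= 3")
  pts2 <- pts; pts2$eta[2] <- 0.1
  expect_error(exponent_suite(pts2), "mix")
})

test_that("synthetic critical curves in noise recover amplitude and exponent", {
  eta <- seq(0.1, 0.5, by = 0.1)
  beta_c <- 0.017 * eta^2.1
  f <- fit_power_law(eta, beta_c)
  expect_equal(f$exponent, 2.1, tolerance = 1e-10)
  expect_equal(f$amplitude, 0.017, tolerance = 1e-10)
})

test_that("scaling collapse detects the true dynamic exponent", {
  master <- function(s) exp(-s) * cos(s / 3)
  k_c <- c(0.05, 0.1, 0.2, 0.4)
  z <- 1.2
  curves <- lapply(k_c, function(k) {
    lag <- 0:300
    data.frame(lag = lag, g = master(k^z * lag))
  })
  # residual dispersion at the true exponent is pure interpolation error
  good <- collapse_check(curves, k_c, z = z, s_max = 4)
  expect_lt(good$dispersion, 5e-3)
  bad <- collapse_check(curves, k_c, z = 0.6, s_max = 4)
  expect_gt(bad$dispersion, 20 * good$dispersion)
  # identical curves collapse for any exponent
  same <- collapse_check(curves[c(1, 1)], c(0.1, 0.1), z = 0.77)
  expect_equal(same$dispersion, 0)
})

test_that("run manifests are reproducible and seed substreams are stable", {
  p <- hcvm_params(n = 10, beta = 1)
  m1 <- run_manifest(p, seed = 5, steps = 100, transient = 10)
  m2 <- run_manifest(p, seed = 5, steps = 100, transient = 10)
  expect_identical(m1, m2)
  s1 <- seed_streams(42)
  s2 <- seed_streams(42)
  expect_identical(s1, s2)
  expect_false(any(duplicated(s1)))
})
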