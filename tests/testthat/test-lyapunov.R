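test_that("tangent propagation is linear and zero-preserving", {
  p <- hcvm_params(n = 10, beta = 1.5, eta = 0.3)
  s <- init_swarm(p, seed = 7)
  xi <- runif(10, -0.15, 0.15)
  z <- list(dpos = matrix(0, 10, 2), dvel = matrix(0, 10, 2))
  tz <- tangent_step(s, z, p, xi)
  expect_equal(tz$norm, 0)
  set.seed(1)
  d <- random_tangent(10)
  t1 <- tangent_step(s, d, p, xi)
  d3 <- list(dpos = 3 * d$dpos, dvel = 3 * d$dvel)
  t3 <- tangent_step(s, d3, p, xi)
  expect_equal(t3$dpos, 3 * t1$dpos, tolerance = 1e-12)
  expect_equal(t3$dvel, 3 * t1$dvel, tolerance = 1e-12)
})

test_that("tangent map agrees with a finite-difference oracle of the update", {
  set.seed(42)
  p <- hcvm_params(n = 12, beta = 2, eta = 0)
  s <- init_swarm(p, 3)
  for (i in 1:20) s <- hcvm_step(s, p, rep(0, 12))
  noise <- rep(0, 12)
  dx <- matrix(rnorm(24), 12, 2)
  dth <- rnorm(12)
  # heading perturbations induce velocity perturbations tangent to |v| = v0
  dv <- cbind(-sin(s$headings) * dth, cos(s$headings) * dth)
  tan1 <- tangent_step(s, list(dpos = dx, dvel = dv), p, noise)
  phi <- function(st) {
    ns <- hcvm_step(st, p, noise)
    list(pos = ns$positions, v = cbind(cos(ns$headings), sin(ns$headings)))
  }
  base <- phi(s)
  errs <- sapply(c(1e-3, 1e-4, 1e-5), function(h) {
    sp <- swarm_state(s$positions + h * dx, s$headings + h * dth)
    pert <- phi(sp)
    max(abs(c((pert$pos - base$pos) / h - tan1$dpos,
              (pert$v - base$v) / h - tan1$dvel)))
  })
  # first-order convergence: error scales like h
  expect_lt(errs[2], errs[1] / 5)
  expect_lt(errs[3], errs[2] / 5)
  expect_lt(errs[3], 1e-5)
})

test_that("compiled Benettin co-evolution matches an R-level reference loop", {
  n <- 8
  p <- hcvm_params(n = n, beta = 1.2, eta = 0.4)
  seed <- 21
  streams <- seed_streams(seed, c("init", "noise", "tangent"))
  res <- benettin_lle(p, n_steps = 60, transient = 10, seed = seed)
  # replay with shared noise draws at R level
  s <- init_swarm(p, seed = streams[["init"]])
  set.seed(streams[["tangent"]])
  d <- random_tangent(n)
  set.seed(streams[["noise"]])
  la <- numeric(60)
  for (t in 1:60) {
    xi <- runif(n, -0.2, 0.2)
    d <- tangent_step(s, d, p, xi)
    s <- hcvm_step(s, p, xi)
    la[t] <- log(d$norm)
    d$dpos <- d$dpos / d$norm
    d$dvel <- d$dvel / d$norm
  }
  expect_equal(res$lambda1, mean(la[11:60]), tolerance = 1e-10)
})

test_that("Benettin estimates are insensitive to the initial tangent direction", {
  p <- hcvm_params(n = 24, beta = 0.05, eta = 0.5)
  # same base orbit and noise realization, different initial tangent vectors
  lles <- vapply(1:4, function(k) {
    benettin_lle(p, n_steps = 2500, transient = 500, seed = 100,
                 tangent_seed = 1000 + k)$lambda1
  }, numeric(1))
  expect_lt(diff(range(lles)), 0.35 * max(abs(lles)) + 0.005)
})

test_that("non-chaotic deterministic dynamics yields a non-positive exponent", {
  p <- hcvm_params(n = 64, beta = 99.52, eta = 0)
  r <- benettin_lle(p, n_steps = 4000, transient = 1000, seed = 1)
  expect_lt(r$lambda1, 0.005)
})

test_that("delay embedding produces the expected lagged vectors", {
  E <- embed_series(c(1, 2, 3, 4), m = 2, tau = 1)
  expect_equal(unname(E[, 1]), c(1, 2, 3))
  expect_equal(unname(E[, 2]), c(2, 3, 4))
  E1 <- embed_series(1:5, m = 1)
  expect_equal(as.numeric(E1), 1:5)
  expect_error(embed_series(1:10, m = 6, tau = 9), "too short")
  E2 <- embed_series(rnorm(200), m = 6, tau = 9)
  expect_equal(nrow(E2), 200 - 45)
})

test_that("Gao-Zheng slope recovers log(2) on the logistic map", {
  set.seed(2)
  x <- logistic_series(4000)
  gz <- gz_lambda(embed_series(x, m = 2, tau = 1), k_max = 12)
  expect_equal(gz$lle, log(2), tolerance = 0.1)
  expect_gt(gz$n_pairs, 100)
  # constant series: all separations stay zero
  gzc <- gz_lambda(matrix(1, 500, 2), k_max = 10)
  expect_equal(gzc$Lambda, rep(0, 11))
  expect_equal(gzc$lle, 0)
})

test_that("compiled pair kernels match naive R loops on a small series", {
  set.seed(9)
  x <- cumsum(rnorm(260))
  E <- embed_series(x, m = 2, tau = 1)
  theiler <- 2L
  n <- nrow(E)
  # naive Lambda(k)
  k_max <- 5
  r_star <- 1.0
  num <- matrix(NA_real_, 0, k_max + 1)
  for (a in 1:(n - k_max)) for (b in 1:(n - k_max)) {
    if (b - a <= theiler) next
    d0 <- sqrt(sum((E[a, ] - E[b, ])^2))
    if (d0 > 0 && d0 < r_star) {
      num <- rbind(num, sapply(0:k_max, function(k)
        log(sqrt(sum((E[a + k, ] - E[b + k, ])^2)) / d0)))
    }
  }
  gz <- gz_lambda(E, r_star = r_star, k_max = k_max, theiler = theiler)
  expect_equal(gz$Lambda, colMeans(num), tolerance = 1e-10)
  expect_equal(gz$n_pairs, nrow(num))
})

test_that("SDLE shows a log(2) plateau for the logistic map and zero for periodic motion", {
  set.seed(3)
  x <- logistic_series(4000)
  prof <- sdle(embed_series(x, m = 2, tau = 1), horizon = 30)
  expect_false(is.null(prof$plateau))
  expect_equal(prof$plateau$value, log(2), tolerance = 0.1)
  expect_gte(log10(prof$plateau$eps2 / prof$plateau$eps1), 0.5)
  expect_equal(prof$label, "deterministic_chaos")
  # periodic series: no systematic growth at any scale
  xp <- sin(2 * pi * (1:3000) / 17)
  pp <- sdle(embed_series(xp, m = 4, tau = 1), horizon = 30)
  expect_lt(stats::median(abs(pp$shells$lambda)), 0.05)
  expect_equal(pp$label, "nonchaotic")
  # i.i.d. noise: lambda decays like -gamma*log(eps), no qualifying plateau
  set.seed(4)
  xn <- rnorm(4000)
  pn <- sdle(embed_series(xn, m = 4, tau = 1), horizon = 10)
  fit <- stats::lm(lambda ~ log(eps), data = pn$shells)
  expect_lt(stats::coef(fit)[2], -0.05)
  expect_equal(pn$label, "noise_dominated")
})

test_that("SDLE is equivariant under rescaling of the series", {
  set.seed(5)
  x <- logistic_series(1500)
  p1 <- sdle(embed_series(x, 2, 1), horizon = 20, max_vectors = 600)
  p2 <- sdle(embed_series(10 * x, 2, 1), horizon = 20, max_vectors = 600)
  expect_equal(p2$shells$eps, 10 * p1$shells$eps, tolerance = 1e-10)
  expect_equal(p2$shells$lambda, p1$shells$lambda, tolerance = 1e-10)
})

test_that("embedding dimension above saturation does not move the estimates", {
  set.seed(6)
  x <- logistic_series(4000)
  p3 <- sdle(embed_series(x, 3, 1), horizon = 30)
  p5 <- sdle(embed_series(x, 5, 1), horizon = 30)
  expect_false(is.null(p3$plateau))
  expect_false(is.null(p5$plateau))
  expect_equal(p3$plateau$value, p5$plateau$value, tolerance = 0.15)
})

test_that("plateau-width classification follows the half-decade criterion", {
  mk <- function(width_decades, lam = 0.5) {
    eps <- 10^seq(-3, 0, length.out = 25)
    lambda <- rep(0.01, 25)
    in_pl <- eps >= 1e-2 & eps <= 1e-2 * 10^width_decades
    lambda[in_pl] <- lam
    sh <- data.frame(eps = eps,
                     eps_lo = eps / 1.1, eps_hi = eps * 1.1,
                     lambda = lambda, se = rep(1e-4, 25),
                     n_pairs = 100, n_obs = 1000)
    prof <- structure(list(shells = sh, plateau = NULL, dt = 1),
                      class = "sdle_profile")
    # plateau over the flat run only
    prof$plateau <- swarmchaos:::find_plateau(sh[in_pl, , drop = FALSE])
    prof
  }
  wide <- mk(0.62)
  expect_equal(classify_dynamics(wide), "deterministic_chaos")
  narrow <- mk(0.25)
  expect_false(classify_dynamics(narrow) %in%
                 c("deterministic_chaos", "noisy_chaos"))
})
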