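test_that("velocity fluctuations obey the sum rules", {
  # two particles with opposite velocities along x
  v <- rbind(c(1, 0), c(-1, 0))
  dv <- velocity_fluctuations(v)
  expect_equal(dv, rbind(c(1, 0), c(-1, 0)))
  # random state: zero mean and unit mean square, to machine precision
  p <- hcvm_params(n = 40, beta = 1, eta = 0.6)
  s <- init_swarm(p, 5)
  dh <- velocity_fluctuations(s)
  expect_equal(colSums(dh), c(0, 0), tolerance = 1e-12)
  expect_equal(mean(rowSums(dh^2)), 1, tolerance = 1e-12)
  # perfectly aligned swarm has no defined normalization
  expect_error(velocity_fluctuations(swarm_state(matrix(rnorm(20), 10, 2),
                                                 rep(0.3, 10))),
               "zero fluctuation variance")
})

test_that("binned correlation function matches the double-loop reference", {
  p <- hcvm_params(n = 12, beta = 0.4, eta = 0.8)
  traj <- simulate_hcvm(p, 40, 10, seed = 3)
  arrays <- swarmchaos:::traj_analysis_arrays(traj)
  for (lag in c(0L, 3L)) {
    got <- dccf(traj, lags = lag, max_origins = 8)
    h <- swarmchaos:::corr_histograms(traj, lag, 50L, max_origins = 8)
    t0s <- seq(1, arrays$n_frames - lag,
               by = max(1, floor((arrays$n_frames - lag) / 8)))
    ref <- ref_dccf(arrays$pos, arrays$dvhat, t0s, lag, 50, h$rmax)
    want <- ifelse(ref$CNT > 0, ref$W / ref$CNT, NA_real_)
    expect_equal(got$C, want, tolerance = 1e-10)
    expect_equal(got$n_pairs, ref$CNT)
  }
})

test_that("cumulative correlation satisfies the sum rule and locates r0", {
  # constructed two-cluster configuration: aligned inside clusters,
  # anti-aligned across; first zero of C(r) sits between the cluster size
  # and the cluster separation
  base <- rbind(c(0, 0), c(0.3, 0), c(0, 0.3), c(0.3, 0.3))
  pos1 <- rbind(base, sweep(base, 2, c(6, 0), "+"))
  th <- c(rep(pi / 2, 4), rep(-pi / 2, 4))
  pos_arr <- array(rep(t(cbind(pos1)), each = 2), c(2, 8, 2))
  pos_arr[1, , ] <- pos1; pos_arr[2, , ] <- pos1
  head_mat <- rbind(th, th)
  p <- hcvm_params(n = 8, beta = 0, eta = 0)
  traj <- fake_trajectory(pos_arr, head_mat, p)
  prof <- cumulative_corr(traj, nbins = 60, max_origins = 2)
  expect_gt(prof$r0, 0.3 * sqrt(2))
  expect_lt(prof$r0, 6)
  # Q at the largest distances is the squared sum of fluctuations: zero
  expect_equal(utils::tail(prof$table$Q, 1), 0, tolerance = 1e-10)
  # chi equals the correlated cluster weight: each particle correlates
  # positively with its 4-particle cluster: Q(r0) = 4 * |dvhat|^2 / ... = 4
  expect_equal(prof$chi, 4, tolerance = 0.2)
})

test_that("no sign change of C(r) raises the no-zero error", {
  # two coincident anti-aligned particles: every pair contribution sits at
  # r = 0 where self and cross terms cancel exactly, so C(r) is never
  # positive and has no first zero
  pos <- matrix(0, 2, 2)
  th <- c(0, pi)
  pos_arr <- array(0, c(2, 2, 2))
  traj <- fake_trajectory(pos_arr, rbind(th, th),
                          hcvm_params(n = 2, beta = 0))
  expect_error(cumulative_corr(traj, nbins = 10, max_origins = 2),
               "no sign change")
})

test_that("spectral correlation obeys its structural identities", {
  p <- hcvm_params(n = 30, beta = 0.05, eta = 0.5)
  traj <- simulate_hcvm(p, 600, 100, seed = 8)
  sc <- spectral_corr(traj, lags = 0:40, max_origins = 10)
  # g(0) = 1 by construction
  expect_equal(sc$g$g[1], 1)
  # sum rule: Chat(k -> 0, 0) -> (1/N)|sum dvhat|^2 = 0
  expect_lt(abs(sc$C_hat[1, 1]), 0.05 * sc$chi)
  # correlation length from the spectral side tracks the real-space one
  prof <- cumulative_corr(traj, max_origins = 10)
  expect_gt(1 / sc$k_c, 0.2 * prof$r0)
  expect_lt(1 / sc$k_c, 5 * prof$r0)
})

test_that("spectral kernel matches a direct double sum on a frozen state", {
  # single-frame trajectory duplicated: exact check of the sinc transform
  set.seed(10)
  pos <- matrix(rnorm(60, sd = 2), 30, 2)
  th <- runif(30, -pi, pi)
  pos_arr <- array(0, c(2, 30, 2)); pos_arr[1, , ] <- pos; pos_arr[2, , ] <- pos
  traj <- fake_trajectory(pos_arr, rbind(th, th), hcvm_params(n = 30, beta = 0))
  sc <- spectral_corr(traj, k_grid = c(0.3, 0.9, 2.0), lags = 0:1,
                      nbins = 4000, max_origins = 1)
  a <- sweep(pos, 2, colMeans(pos))
  dv <- velocity_fluctuations(swarm_state(pos, th))
  for (ki in 1:3) {
    k <- c(0.3, 0.9, 2.0)[ki]
    direct <- 0
    for (i in 1:30) for (j in 1:30) {
      r <- sqrt(sum((a[i, ] - a[j, ])^2))
      direct <- direct + sum(dv[i, ] * dv[j, ]) *
        (if (r == 0) 1 else sin(k * r) / (k * r))
    }
    expect_equal(sc$C_hat[1, ki], direct / 30, tolerance = 2e-3)
  }
})

test_that("correlation time solves the arctan identity for exponential decay", {
  # dense sampling relative to the decay time: the discretization bias of
  # the t >= 1 sum is O(1/tau0)
  tau0 <- 200
  g <- exp(-(0:8000) / tau0)
  tau <- correlation_time(g)
  expect_equal(tau, tau0, tolerance = 0.02)
  # time dilation rescales tau accordingly
  g2 <- exp(-(0:8000) / (2 * tau0))
  expect_equal(correlation_time(g2), 2 * tau0, tolerance = 0.02)
  # monotone under dilation
  expect_gt(correlation_time(g2), tau)
  # unreachable bracket raises the no-solution error
  expect_error(correlation_time(g, tau_range = c(1e5, 9e5)),
               "no solution")
})

test_that("polarization and swarm size have the right limits", {
  # all aligned: W = 1
  pos <- matrix(rnorm(20), 10, 2)
  pos_arr <- array(0, c(2, 10, 2)); pos_arr[1, , ] <- pos; pos_arr[2, , ] <- pos
  aligned <- fake_trajectory(pos_arr, matrix(0.7, 2, 10),
                             hcvm_params(n = 10, beta = 0))
  expect_equal(polarization(aligned), 1, tolerance = 1e-12)
  # equal and opposite headings: W = 0
  th <- rep(c(0.2, 0.2 + pi), 5)
  opp <- fake_trajectory(pos_arr, rbind(th, th), hcvm_params(n = 10, beta = 0))
  expect_equal(polarization(opp), 0, tolerance = 1e-12)
  # two static particles at distance d
  d <- 3.7
  pp <- array(0, c(2, 2, 2)); pp[, 2, 1] <- d
  two <- fake_trajectory(pp, matrix(0, 2, 2), hcvm_params(n = 2, beta = 0))
  expect_equal(swarm_size(two), d)
  # coincident particles: L = 0
  zz <- fake_trajectory(array(1, c(2, 3, 2)), matrix(0, 2, 3),
                        hcvm_params(n = 3, beta = 0))
  expect_equal(swarm_size(zz), 0)
})

test_that("correlation observables are invariant under rotation + translation", {
  p <- hcvm_params(n = 25, beta = 0.05, eta = 0.5)
  traj <- simulate_hcvm(p, 400, 100, seed = 12)
  th <- 1.1; shift <- c(5, -3)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pos2 <- traj$positions
  for (t in seq_len(dim(pos2)[1])) {
    pos2[t, , ] <- sweep(traj$positions[t, , ] %*% t(R), 2, shift, "+")
  }
  traj2 <- fake_trajectory(pos2, traj$headings + th, p,
                           transient = traj$transient)
  a <- cumulative_corr(traj, max_origins = 8)
  b <- cumulative_corr(traj2, max_origins = 8)
  expect_equal(b$r0, a$r0, tolerance = 1e-8)
  expect_equal(b$chi, a$chi, tolerance = 1e-8)
  expect_equal(polarization(traj2), polarization(traj), tolerance = 1e-12)
  expect_equal(swarm_size(traj2), swarm_size(traj), tolerance = 1e-8)
})
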