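test_that("nondimensionalization reproduces the observational constants", {
  # observed midge swarm: v = 0.195 m/s, dt = 0.24 s, r1 = 4.68 cm -> v0 = 1
  u <- nondimensionalize(dt_seconds = 0.24, nn_distance_m = 0.0468,
                         speed_mps = 0.195, beta0_per_second = 2)
  expect_equal(u$speed, 1.0, tolerance = 1e-12)
  expect_equal(u$confinement, 0.48)
  # v = r1/dt gives v0 = 1 by definition
  expect_equal(nondimensionalize(0.1, 0.5, 5)$speed, 1.0)
  expect_error(nondimensionalize(-1, 0.05, 0.2), "invalid units")
})

test_that("parameter validation lists all violations at once", {
  expect_error(hcvm_params(n = 0, beta = -1, eta = 10),
               "n must be.*\n.*beta.*\n.*eta")
  expect_s3_class(hcvm_params(n = 10, beta = 0.5), "hcvm_params")
})

test_that("initialization is uniform in the unit disc with outward headings", {
  p <- hcvm_params(n = 10000, beta = 1)
  s <- init_swarm(p, seed = 11)
  r <- sqrt(rowSums(s$positions^2))
  expect_true(all(r <= 1))
  expect_equal(s$headings, atan2(s$positions[, 2], s$positions[, 1]))
  # radial CDF of the uniform disc law is r^2
  ks <- suppressWarnings(stats::ks.test(r^2, "punif"))
  expect_gt(ks$p.value, 0.01)
  # determinism: same seed gives bit-identical states
  s2 <- init_swarm(p, seed = 11)
  expect_identical(s$positions, s2$positions)
  expect_identical(s$headings, s2$headings)
})

test_that("alignment force matches hand examples and the double-loop oracle", {
  # two coincident particles moving along +x, beta = 0
  s <- swarm_state(matrix(0, 2, 2), c(0, 0))
  p <- hcvm_params(n = 2, beta = 0, v0 = 1)
  expect_equal(alignment_force(s, p), matrix(c(2, 2, 0, 0), 2, 2))
  # single particle at (1, 0) heading +y, beta = 3
  s1 <- swarm_state(matrix(c(1, 0), 1, 2), pi / 2)
  p1 <- hcvm_params(n = 1, beta = 3)
  expect_equal(alignment_force(s1, p1), matrix(c(-3, 1), 1, 2),
               tolerance = 1e-12)
  # random states against the brute-force reference, both conventions
  set.seed(5)
  for (fc in c("focal_once", "per_neighbor")) {
    p <- hcvm_params(n = 40, beta = 2.5, eta = 0.3, r0 = 0.6,
                     force_convention = fc)
    s <- init_swarm(p, seed = 8)
    expect_equal(alignment_force(s, p),
                 ref_force(s$positions, s$headings, 1, 2.5, 0.6,
                           fc == "per_neighbor"),
                 tolerance = 1e-12)
  }
})

test_that("one step matches the reference and its rotation-matrix form", {
  # free particle moves in a straight line
  p <- hcvm_params(n = 1, beta = 0, v0 = 0.7)
  s <- swarm_state(matrix(c(0, 0), 1, 2), 0.3)
  for (i in 1:5) s <- hcvm_step(s, p, 0)
  expect_equal(as.numeric(s$positions),
               5 * 0.7 * c(cos(0.3), sin(0.3)), tolerance = 1e-12)
  expect_equal(s$headings, 0.3)
  # overwhelming confinement turns the velocity toward the origin
  p2 <- hcvm_params(n = 1, beta = 1e9)
  s2 <- hcvm_step(swarm_state(matrix(c(1, 0), 1, 2), pi / 2), p2, 0)
  expect_equal(abs(atan2(sin(s2$headings), cos(s2$headings))), pi,
               tolerance = 1e-6)
  # full swarm against the naive implementation, several steps
  p3 <- hcvm_params(n = 30, beta = 1.2, eta = 0.4, r0 = 0.8)
  s3 <- init_swarm(p3, seed = 2)
  rp <- s3$positions; rh <- s3$headings
  set.seed(31)
  for (i in 1:10) {
    xi <- runif(30, -0.2, 0.2)
    s3 <- hcvm_step(s3, p3, xi)
    ref <- ref_step(rp, rh, xi, 1, 1.2, 0.8)
    rot <- ref_step_rotmat(rp, rh, xi, 1, 1.2, 0.8)
    rp <- ref$positions; rh <- ref$headings
    expect_equal(s3$positions, rp, tolerance = 1e-12)
    # Arg form and rotation-matrix form agree
    expect_equal(ref$positions, rot$positions, tolerance = 1e-10)
  }
})

test_that("speed is conserved exactly along trajectories", {
  p <- hcvm_params(n = 25, beta = 0.8, eta = 0.7, v0 = 1.3)
  traj <- simulate_hcvm(p, 60, 0, seed = 4)
  d <- sqrt(apply(traj$positions[, , 1], 2, diff)^2 +
            apply(traj$positions[, , 2], 2, diff)^2)
  expect_equal(as.numeric(d), rep(1.3, length(d)), tolerance = 1e-12)
})

test_that("trajectories are deterministic, permutation- and rotation-covariant", {
  p <- hcvm_params(n = 20, beta = 1.5, eta = 0.5)
  t1 <- simulate_hcvm(p, 80, 0, seed = 9)
  t2 <- simulate_hcvm(p, 80, 0, seed = 9)
  expect_identical(t1$positions, t2$positions)
  # permutation invariance (eta = 0 so no draw-order dependence)
  p0 <- hcvm_params(n = 20, beta = 1.5, eta = 0)
  s0 <- init_swarm(p0, seed = 3)
  perm <- sample(20)
  sp <- swarm_state(s0$positions[perm, ], s0$headings[perm])
  a <- simulate_hcvm(p0, 40, 0, seed = 1, init_state = s0)
  b <- simulate_hcvm(p0, 40, 0, seed = 1, init_state = sp)
  expect_equal(a$positions[41, perm, ], b$positions[41, , ],
               tolerance = 1e-10)
  # rotational covariance at eta = 0
  th <- 0.77
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sr <- swarm_state(s0$positions %*% t(R), s0$headings + th)
  cr <- simulate_hcvm(p0, 40, 0, seed = 1, init_state = sr)
  expect_equal(cr$positions[41, , ], a$positions[41, , ] %*% t(R),
               tolerance = 1e-8)
})

test_that("center-of-mass series matches the position mean", {
  p <- hcvm_params(n = 12, beta = 0.6, eta = 0.2)
  traj <- simulate_hcvm(p, 50, 20, seed = 6)
  expect_equal(traj$cm$X, rowMeans(traj$positions[, , 1]))
  expect_equal(traj$cm$x_sum, traj$cm$X + traj$cm$Y)
  cm <- cm_series(traj)
  expect_equal(cm$step[1], 20)
  expect_equal(nrow(cm), 31)
  # single particle: CM is the particle path
  p1 <- hcvm_params(n = 1, beta = 0.5)
  t1 <- simulate_hcvm(p1, 10, 0, seed = 2)
  expect_equal(t1$cm$X, as.numeric(t1$positions[, 1, 1]))
  # zero-step request returns just the initial state
  t0 <- simulate_hcvm(p1, 0, 0, seed = 2)
  expect_equal(nrow(t0$cm), 1)
})

test_that("mirror-symmetric pairs keep the center of mass at the origin", {
  # two particles opposite to each other with opposite headings, eta = 0:
  # symmetry is preserved by the update, so X(t) = 0 for all t (strong
  # confinement keeps the single-particle motion regular, so rounding
  # asymmetries cannot amplify)
  p <- hcvm_params(n = 2, beta = 1000, eta = 0, r0 = 0.1)
  s <- swarm_state(rbind(c(0.5, 0.2), c(-0.5, -0.2)),
                   c(atan2(0.2, 0.5), atan2(-0.2, -0.5)))
  traj <- simulate_hcvm(p, 30, 0, seed = 1, init_state = s)
  expect_equal(max(abs(traj$cm$X)), 0, tolerance = 1e-10)
  expect_equal(max(abs(traj$cm$x_sum)), 0, tolerance = 1e-10)
})

test_that("config files parse with defaults and reject bad input", {
  path <- withr::local_tempfile(fileext = ".toml")
  writeLines(c("[model]", "n = 128", "beta = 99.52", "eta = 0.5",
               "[run]", "steps = 500"), path)
  cfg <- load_config(path)
  expect_equal(cfg$params$n, 128L)
  expect_equal(cfg$params$v0, 1)
  expect_equal(cfg$params$r0, 0.472)
  expect_equal(cfg$steps, 500L)
  writeLines(c("[model]", "n = 10", "beta = 1", "eta = -1"), path)
  expect_error(load_config(path), "eta")
  writeLines(c("[model]", "n = 10", "beta = 1", "banana = 2"), path)
  expect_error(load_config(path), "banana")
})

test_that("scenario presets carry the canonical parameter sets", {
  pr <- scenario_preset("fig7_critical")
  expect_true(3e-4 %in% pr$beta_values)
  expect_equal(pr$n, 500)
  pr5 <- scenario_preset("fig5_noise_chaos")
  expect_equal(pr5$beta, 99.52)
  expect_equal(pr5$n, 128)
  expect_error(scenario_preset("nope"), "fig1_gallery")
})

test_that("trajectory CSV round-trips", {
  p <- hcvm_params(n = 6, beta = 1, eta = 0.4)
  traj <- simulate_hcvm(p, 20, 5, seed = 13)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  back <- read_trajectory_csv(path, p, transient = 5)
  expect_equal(back$positions, traj$positions, tolerance = 1e-10)
  expect_equal(back$cm$x_sum, traj$cm$x_sum, tolerance = 1e-10)
})
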