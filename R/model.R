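#' Initialize a swarm state
#'
#' Places `n` particles uniformly at random in the unit disc with headings
#' pointing radially outward (a particle falling exactly on the origin gets a
#' uniformly random heading).
#'
#' @param params An [hcvm_params()] object.
#' @param seed Integer seed for the initialization stream.
#' @return An object of class `swarm_state`: list with `time` (integer step
#'   index), `positions` (`n x 2` matrix) and `headings` (length-`n` vector of
#'   angles in radians).
#' @examples
#' s <- init_swarm(hcvm_params(n = 5, beta = 1), seed = 1)
#' sqrt(rowSums(s$positions^2)) <= 1
#' @export
init_swarm <- function(params, seed = NULL) {
  stopifnot(inherits(params, "hcvm_params"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- params$n
  # uniform in the unit disc: r = sqrt(u), angle uniform
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(stats::runif(n))
  pos <- cbind(r * cos(phi), r * sin(phi))
  head <- ifelse(r > 0, atan2(pos[, 2], pos[, 1]),
                 stats::runif(n, -pi, pi))
  swarm_state(pos, head, time = 0L)
}

#' Construct a swarm state from positions and headings
#'
#' @param positions `n x 2` matrix of particle coordinates.
#' @param headings Length-`n` vector of heading angles (radians).
#' @param time Integer step index.
#' @return A `swarm_state` object.
#' @export
swarm_state <- function(positions, headings, time = 0L) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2 || !all(is.finite(positions))) {
    stop("positions must be a finite n x 2 matrix", call. = FALSE)
  }
  if (length(headings) != nrow(positions) || !all(is.finite(headings))) {
    stop("headings must be finite with one angle per particle", call. = FALSE)
  }
  structure(list(time = as.integer(time), positions = positions,
                 headings = as.numeric(headings)),
            class = "swarm_state")
}

#' Velocities of a swarm state
#'
#' @param state A `swarm_state`.
#' @param v0 Particle speed.
#' @return `n x 2` matrix `v0 * (cos(theta), sin(theta))`.
#' @export
state_velocities <- function(state, v0 = 1) {
  v0 * cbind(cos(state$headings), sin(state$headings))
}

#' @export
print.swarm_state <- function(x, ...) {
  cat("<swarm_state>  N =", nrow(x$positions), " t =", x$time, "\n")
  invisible(x)
}

#' Alignment force on every particle
#'
#' For each focal particle `i`, sums the velocities of all particles within
#' the metric radius (strict `< r0`, self included) and adds the confinement
#' term according to the force convention of `params` (see [hcvm_params()]).
#'
#' @param state A `swarm_state`.
#' @param params An [hcvm_params()] object.
#' @return `n x 2` matrix of force vectors.
#' @export
alignment_force <- function(state, params) {
  stopifnot(inherits(state, "swarm_state"), inherits(params, "hcvm_params"))
  cpp_alignment_force(state$positions, state$headings, params$v0,
                      params$beta, params$r0,
                      params$force_convention == "per_neighbor")
}

#' Advance a swarm state by one step
#'
#' Synchronous update: every alignment force is evaluated from the state at
#' time `t` before any particle moves. The new velocity of particle `i` is
#' `v0 * R(noise_i) F_i / |F_i|` and the position advances by the new
#' velocity. A particle with exactly zero force keeps its previous heading
#' (before the noise rotation).
#'
#' @param state A `swarm_state`.
#' @param params An [hcvm_params()] object.
#' @param noise_angles Length-`n` vector of angular kicks, drawn by the
#'   caller (uniform on `[-eta/2, eta/2]`). Exposing the draws lets tangent
#'   propagation reuse the identical realization.
#' @return The updated `swarm_state` at `time + 1`.
#' @export
hcvm_step <- function(state, params, noise_angles = NULL) {
  stopifnot(inherits(state, "swarm_state"), inherits(params, "hcvm_params"))
  n <- nrow(state$positions)
  if (is.null(noise_angles)) {
    noise_angles <- if (params$eta > 0) {
      stats::runif(n, -params$eta / 2, params$eta / 2)
    } else {
      rep(0, n)
    }
  }
  stopifnot(length(noise_angles) == n)
  res <- cpp_step(state$positions, state$headings, noise_angles,
                  params$v0, params$beta, params$r0,
                  params$force_convention == "per_neighbor")
  swarm_state(res$positions, res$headings, time = state$time + 1L)
}

#' Simulate an HCVM trajectory
#'
#' Iterates the update rule from a random (or supplied) initial state. Noise
#' angles are drawn from the `noise` substream of the master seed so that
#' realizations are replayable. Steps `1..transient` are kept in the stored
#' arrays but flagged so analysis views can drop them.
#'
#' @param params An [hcvm_params()] object.
#' @param n_steps Number of update steps (`>= 0`).
#' @param transient Number of initial steps excluded from analysis views.
#' @param seed Master seed; spawns `init` and `noise` substreams.
#' @param init_state Optional `swarm_state` to start from instead of the
#'   random disc initialization.
#' @param record `"states"` stores all positions and headings
#'   (`(n_steps+1) x n x 2`); `"cm"` stores only the center-of-mass series
#'   (for long runs at large `n`).
#' @return An object of class `hcvm_trajectory` with elements `params`,
#'   `seed`, `transient`, `cm` (data frame `step, X, Y, x_sum`), and (when
#'   recorded) `positions`, `headings`.
#' @examples
#' traj <- simulate_hcvm(hcvm_params(n = 32, beta = 1, eta = 0.3),
#'                       n_steps = 100, transient = 50, seed = 7)
#' head(cm_series(traj))
#' @export
simulate_hcvm <- function(params, n_steps, transient = 0, seed = 1,
                          init_state = NULL,
                          record = c("states", "cm")) {
  stopifnot(inherits(params, "hcvm_params"), n_steps >= 0,
            transient >= 0, transient <= n_steps)
  record <- match.arg(record)
  streams <- seed_streams(seed)
  if (is.null(init_state)) {
    init_state <- init_swarm(params, seed = streams[["init"]])
  }
  stopifnot(nrow(init_state$positions) == params$n)
  set.seed(streams[["noise"]])
  if (n_steps == 0) {
    res <- list(cmx = mean(init_state$positions[, 1]),
                cmy = mean(init_state$positions[, 2]),
                positions = array(init_state$positions,
                                  c(1, params$n, 2)),
                headings = matrix(init_state$headings, nrow = 1))
  } else {
    res <- cpp_run(init_state$positions, init_state$headings,
                   as.integer(n_steps), params$v0, params$beta, params$eta,
                   params$r0, params$force_convention == "per_neighbor",
                   record == "states")
  }
  cm <- data.frame(step = 0:n_steps, X = res$cmx, Y = res$cmy)
  cm$x_sum <- cm$X + cm$Y
  out <- list(params = params, seed = seed, n_steps = as.integer(n_steps),
              transient = as.integer(transient), cm = cm)
  if (record == "states") {
    out$positions <- res$positions
    out$headings <- res$headings
    if (n_steps == 0) {
      dim(out$positions) <- c(1L, params$n, 2L)
      dim(out$headings) <- c(1L, params$n)
    }
  }
  structure(out, class = "hcvm_trajectory")
}

#' @export
print.hcvm_trajectory <- function(x, ...) {
  cat("<hcvm_trajectory>  N =", x$params$n,
      " steps =", x$n_steps,
      " transient =", x$transient,
      " beta =", format(x$params$beta),
      " eta =", format(x$params$eta), "\n")
  invisible(x)
}

#' Center-of-mass series of a trajectory
#'
#' Returns the center-of-mass path `X(t) = mean_j x_j(t)` and the scalar
#' series `x(t) = X(t) + Y(t)` used for delay embedding, over the
#' post-transient window by default.
#'
#' @param traj An `hcvm_trajectory`.
#' @param drop_transient Drop the first `traj$transient` steps?
#' @return Data frame with columns `step`, `X`, `Y`, `x_sum`.
#' @export
cm_series <- function(traj, drop_transient = TRUE) {
  stopifnot(inherits(traj, "hcvm_trajectory"))
  cm <- traj$cm
  if (drop_transient && traj$transient > 0) {
    cm <- cm[cm$step >= traj$transient, , drop = FALSE]
    rownames(cm) <- NULL
  }
  cm
}

#' Extract one frame of a trajectory as a swarm state
#'
#' @param traj An `hcvm_trajectory` recorded with `record = "states"`.
#' @param step Step index (0-based, as in the `cm` table).
#' @return A `swarm_state`.
#' @export
trajectory_state <- function(traj, step) {
  stopifnot(inherits(traj, "hcvm_trajectory"))
  if (is.null(traj$positions)) {
    stop("trajectory was recorded with record = \"cm\"; no states stored",
         call. = FALSE)
  }
  t <- as.integer(step) + 1L
  stopifnot(t >= 1, t <= dim(traj$positions)[1])
  swarm_state(traj$positions[t, , , drop = TRUE],
              traj$headings[t, ], time = as.integer(step))
}

# Post-transient frame indices (1-based into the stored arrays).
analysis_frames <- function(traj) {
  (traj$transient + 1L):(traj$n_steps + 1L)
}
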