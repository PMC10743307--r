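#' Model parameters for the harmonically confined Vicsek model
#'
#' Bundles the dimensionless parameters of the 2D harmonically confined
#' Vicsek model (HCVM): `n` particles move at constant speed `v0`, align with
#' all neighbors inside a metric radius `r0` (strict inequality, the focal
#' particle always counts as its own neighbor), feel a linear restoring force
#' `-beta * x` toward the origin, and receive an angular kick drawn uniformly
#' from `[-eta/2, eta/2]` after the heading update.
#'
#' @param n Number of particles (positive integer).
#' @param beta Dimensionless confinement (spring) parameter, `beta >= 0`.
#' @param eta Full width of the uniform angular-noise interval, in
#'   `[0, 2*pi]`.
#' @param v0 Dimensionless particle speed, `v0 > 0`. The default 1
#'   corresponds to the nondimensionalization of observed midge swarms (see
#'   [nondimensionalize()]).
#' @param r0 Dimensionless metric interaction radius, `r0 > 0`.
#' @param force_convention How the confinement term enters the alignment
#'   force. `"focal_once"` (default) applies `-beta * x_i` once to the focal
#'   particle: `F_i = sum_j v_j - beta * x_i`. `"per_neighbor"` applies it to
#'   every neighbor: `F_i = sum_j (v_j - beta * x_j)`. The default matches
#'   the linearized dynamics (a single confinement term per particle) and the
#'   harmonic-potential reading of the model.
#'
#' @return An object of class `hcvm_params`.
#' @examples
#' p <- hcvm_params(n = 128, beta = 99.52, eta = 0.5)
#' p
#' @export
hcvm_params <- function(n, beta, eta = 0, v0 = 1, r0 = 0.472,
                        force_convention = c("focal_once", "per_neighbor")) {
  force_convention <- match.arg(force_convention)
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(is.numeric(n) && length(n) == 1 && is.finite(n) && n >= 1 &&
        n == round(n), "n must be a positive integer")
  chk(is.numeric(beta) && length(beta) == 1 && is.finite(beta) && beta >= 0,
      "beta must be a finite non-negative number")
  chk(is.numeric(eta) && length(eta) == 1 && is.finite(eta) && eta >= 0 &&
        eta <= 2 * pi, "eta must lie in [0, 2*pi]")
  chk(is.numeric(v0) && length(v0) == 1 && is.finite(v0) && v0 > 0,
      "v0 must be a positive number")
  chk(is.numeric(r0) && length(r0) == 1 && is.finite(r0) && r0 > 0,
      "r0 must be a positive number")
  if (length(problems) > 0) {
    stop("invalid model parameters:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(
    list(n = as.integer(n), beta = beta, eta = eta, v0 = v0, r0 = r0,
         force_convention = force_convention),
    class = "hcvm_params"
  )
}

#' @export
print.hcvm_params <- function(x, ...) {
  cat("<hcvm_params>  N =", x$n,
      " beta =", format(x$beta),
      " eta =", format(x$eta),
      " v0 =", format(x$v0),
      " r0 =", format(x$r0),
      " [", x$force_convention, "]\n")
  invisible(x)
}

#' Nondimensionalize swarm observation constants
#'
#' Converts dimensional swarm observables to the dimensionless speed and
#' confinement of the model. Times are measured in units of the sampling
#' interval `dt_seconds`, lengths in units of the time-averaged
#' nearest-neighbor distance `nn_distance_m`, so
#' `v0 = speed_mps * dt_seconds / nn_distance_m` and
#' `beta = beta0_per_second * dt_seconds`.
#'
#' @param dt_seconds Sampling time step in seconds.
#' @param nn_distance_m Time-averaged nearest-neighbor distance in meters.
#' @param speed_mps Mean particle speed in meters per second.
#' @param beta0_per_second Dimensional spring constant in 1/s (optional).
#'
#' @return List with elements `speed` (v0) and, when `beta0_per_second` is
#'   given, `confinement` (beta).
#' @examples
#' # observed midge swarm: 0.195 m/s, 0.24 s frames, 4.68 cm spacing -> v0 = 1
#' nondimensionalize(dt_seconds = 0.24, nn_distance_m = 0.0468,
#'                   speed_mps = 0.195)$speed
#' @export
nondimensionalize <- function(dt_seconds, nn_distance_m, speed_mps,
                              beta0_per_second = NULL) {
  vals <- c(dt_seconds, nn_distance_m, speed_mps, beta0_per_second)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("invalid units: all inputs must be finite and positive",
         call. = FALSE)
  }
  out <- list(speed = speed_mps * dt_seconds / nn_distance_m)
  if (!is.null(beta0_per_second)) {
    out$confinement <- beta0_per_second * dt_seconds
  }
  out
}

#' Derive named random substreams from one master seed
#'
#' One master seed deterministically spawns named sub-seeds (initialization,
#' per-step noise, analysis resampling), so that e.g. a noise realization can
#' be replayed for tangent-space propagation independently of how the initial
#' condition was drawn.
#'
#' @param seed Master seed (integer).
#' @param streams Character vector of stream names.
#' @return Named integer vector of sub-seeds.
#' @export
seed_streams <- function(seed, streams = c("init", "noise", "analysis")) {
  stopifnot(length(seed) == 1, is.finite(seed))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sub <- sample.int(.Machine$integer.max - 1L, length(streams))
  names(sub) <- streams
  sub
}
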