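#' Advance a tangent-space perturbation by one step
#'
#' Linearized image of [hcvm_step()] around `state`, with the neighborhood
#' graph frozen from the base state and the noise rotations shared with it.
#' The velocity perturbation is projected orthogonal to the alignment force
#' (the constant-speed constraint removes growth along the heading) and
#' divided by the force modulus:
#' `dv_i(t+1) = v0 R(xi_i) (I - Fhat Fhat') (sum_j dv_j - beta dx_i) / |F_i|`,
#' then `dx_i(t+1) = dx_i(t) + dv_i(t+1)`. A particle with exactly zero force
#' passes its velocity perturbation through unchanged (paired with the
#' degenerate-heading rule of the base step).
#'
#' @param state The base `swarm_state` at time `t`.
#' @param tangent List with `dpos` and `dvel` (`n x 2` matrices).
#' @param params An [hcvm_params()] object.
#' @param noise_angles The same angular kicks used for the paired base step.
#' @return List with updated `dpos`, `dvel` and `norm` (length of the
#'   concatenated 4n perturbation vector).
#' @export
tangent_step <- function(state, tangent, params, noise_angles) {
  stopifnot(inherits(state, "swarm_state"), inherits(params, "hcvm_params"))
  n <- nrow(state$positions)
  stopifnot(nrow(tangent$dpos) == n, nrow(tangent$dvel) == n,
            length(noise_angles) == n)
  res <- cpp_tangent_step(state$positions, state$headings,
                          tangent$dpos, tangent$dvel, noise_angles,
                          params$v0, params$beta, params$r0,
                          params$force_convention == "per_neighbor")
  list(dpos = res$dpos, dvel = res$dvel,
       norm = sqrt(sum(res$dpos^2) + sum(res$dvel^2)))
}

#' Random unit tangent vector
#'
#' Draws the initial perturbation `(dx_1..n, dv_1..n)` uniformly on the unit
#' sphere of dimension `4n`.
#'
#' @param n Number of particles.
#' @return List with `dpos`, `dvel` matrices (`n x 2`).
#' @export
random_tangent <- function(n) {
  v <- stats::rnorm(4 * n)
  v <- v / sqrt(sum(v^2))
  list(dpos = matrix(v[1:(2 * n)], n, 2),
       dvel = matrix(v[(2 * n + 1):(4 * n)], n, 2))
}

#' Largest Lyapunov exponent by tangent-space propagation (Benettin)
#'
#' Co-evolves the model and its linearization with shared noise draws,
#' renormalizing the 4n-dimensional perturbation to unit length every step
#' and accumulating `lambda1 = mean(log(alpha_t))` over the post-transient
#' steps, where `alpha_t` is the per-step growth factor.
#'
#' Convergence is diagnosed from the running mean: over the final third of
#' the accumulation window its variation must stay below `tol` relative to
#' the final value (with a small absolute floor for exponents near zero).
#' The algorithm is known not to converge at very small confinement; the
#' result is then flagged `converged = FALSE`, never silently returned.
#'
#' @param params An [hcvm_params()] object.
#' @param n_steps Total steps to iterate.
#' @param transient Steps discarded before accumulating `log(alpha_t)`.
#' @param seed Master seed (spawns init/noise/tangent substreams).
#' @param init_state Optional starting `swarm_state`.
#' @param tangent_seed Optional separate seed for the initial tangent
#'   direction (defaults to a substream of `seed`); the estimate should not
#'   depend on it.
#' @param tol Relative convergence tolerance (default 2%).
#' @return Object of class `lle_result`: list with `lambda1`, `running`
#'   (running-mean series), `n_steps`, `converged`, `tolerance_achieved`.
#' @examples
#' \donttest{
#' p <- hcvm_params(n = 64, beta = 99.52, eta = 0.5)
#' benettin_lle(p, n_steps = 3000, transient = 500, seed = 1)$lambda1
#' }
#' @export
benettin_lle <- function(params, n_steps, transient = 1000, seed = 1,
                         init_state = NULL, tangent_seed = NULL,
                         tol = 0.02) {
  stopifnot(inherits(params, "hcvm_params"), n_steps > transient + 10)
  streams <- seed_streams(seed, c("init", "noise", "tangent"))
  if (is.null(init_state)) {
    init_state <- init_swarm(params, seed = streams[["init"]])
  }
  set.seed(if (is.null(tangent_seed)) streams[["tangent"]] else tangent_seed)
  delta0 <- random_tangent(params$n)
  set.seed(streams[["noise"]])
  res <- cpp_benettin(init_state$positions, init_state$headings,
                      delta0$dpos, delta0$dvel,
                      as.integer(n_steps), as.integer(transient),
                      params$v0, params$beta, params$eta, params$r0,
                      params$force_convention == "per_neighbor")
  la <- res$logalpha
  l <- length(la)
  running <- cumsum(la) / seq_len(l)
  lambda1 <- running[l]
  final_third <- running[max(1L, floor(2 * l / 3)):l]
  spread <- max(final_third) - min(final_third)
  achieved <- spread / max(abs(lambda1), 0.025)
  structure(list(lambda1 = lambda1, running = running, n_steps = l,
                 converged = achieved < tol, tolerance_achieved = achieved,
                 seed = seed, params = params),
            class = "lle_result")
}

#' @export
print.lle_result <- function(x, ...) {
  cat("<lle_result>  lambda1 =", format(x$lambda1, digits = 4),
      " (", x$n_steps, "steps,",
      if (x$converged) "converged" else "NOT converged", ")\n")
  invisible(x)
}

#' Delay embedding of a scalar series
#'
#' Builds all lagged vectors
#' `X_a = (x(a), x(a + tau), ..., x(a + (m-1) tau))`.
#'
#' @param x Scalar time series.
#' @param m Embedding dimension (`>= 1`).
#' @param tau Integer delay (`>= 1`).
#' @return Matrix with one lagged vector per row (`(length(x) - (m-1)*tau)`
#'   rows) with attributes `m` and `tau`.
#' @examples
#' embed_series(1:4, m = 2, tau = 1)
#' @export
embed_series <- function(x, m, tau = 1) {
  stopifnot(m >= 1, tau >= 1)
  n <- length(x) - (m - 1) * tau
  if (n < 1) {
    stop(sprintf(
      "series too short: need length > (m-1)*tau = %d, got %d",
      (m - 1) * tau, length(x)), call. = FALSE)
  }
  E <- vapply(0:(m - 1), function(j) x[(1 + j * tau):(n + j * tau)],
              numeric(n))
  E <- matrix(E, nrow = n)
  attr(E, "m") <- as.integer(m)
  attr(E, "tau") <- as.integer(tau)
  E
}

default_theiler <- function(emb) {
  m <- attr(emb, "m"); tau <- attr(emb, "tau")
  if (is.null(m) || is.null(tau)) 1L else (m - 1L) * tau + 1L
}

# Evenly spaced 0-based column subsample of usable vector origins.
subsample_idx <- function(n_usable, max_vectors) {
  if (n_usable <= max_vectors) return(0:(n_usable - 1))
  unique(round(seq(0, n_usable - 1, length.out = max_vectors)))
}

#' Largest Lyapunov exponent by the Gao-Zheng pair-separation slope
#'
#' Averages `Lambda(k) = < ln(||X_{a+k} - X_{b+k}|| / ||X_a - X_b||) >` over
#' all vector pairs closer than `r_star` (and separated in time by more than
#' the Theiler window); the slope of the initial linear segment of
#' `Lambda(k)` estimates the largest Lyapunov exponent. The fit window is
#' chosen by maximizing the linear-fit R^2 over candidate windows before the
#' curve saturates.
#'
#' @param emb Embedded series from [embed_series()] (or any numeric matrix of
#'   lagged vectors, one per row).
#' @param r_star Pair-selection radius; default the 5th percentile of the
#'   admissible pair distances.
#' @param k_max Longest evolution time of the pairs.
#' @param theiler Minimum temporal index separation between pair members;
#'   default `(m-1)*tau + 1`.
#' @param max_vectors,max_pairs Computational caps (evenly strided vector
#'   subsample; pair count cap).
#' @return Object of class `gz_curve`: `k_grid`, `Lambda`, `lle` (slope),
#'   `stderr`, `window`, `r_squared`, `r_star`, `n_pairs`.
#' @export
gz_lambda <- function(emb, r_star = NULL, k_max = 60, theiler = NULL,
                      max_vectors = 4000, max_pairs = 50000) {
  emb <- as.matrix(emb)
  if (is.null(theiler)) theiler <- default_theiler(emb)
  n <- nrow(emb)
  n_usable <- n - k_max
  if (n_usable < 50) stop("series too short for k_max", call. = FALSE)
  idx <- subsample_idx(n_usable, max_vectors)
  tE <- t(emb)
  if (max(abs(emb - emb[1, 1])) == 0) {
    # constant series: all pair separations stay zero
    return(structure(list(k_grid = 0:k_max, Lambda = rep(0, k_max + 1),
                          lle = 0, stderr = 0, window = c(1L, k_max),
                          r_squared = NA_real_, r_star = 0, n_pairs = 0L),
                     class = "gz_curve"))
  }
  if (is.null(r_star)) {
    d <- cpp_pair_dist_sample(tE, idx[seq(1, length(idx),
                                          length.out = min(1500, length(idx)))],
                              as.integer(theiler))
    d <- d[d > 0]
    if (length(d) == 0) stop("no admissible pairs", call. = FALSE)
    r_star <- stats::quantile(d, 0.05, names = FALSE)
  }
  res <- cpp_gz(tE, as.integer(idx), r_star, as.integer(k_max),
                as.integer(theiler), as.integer(max_pairs))
  if (res$n_pairs < 100) {
    stop(sprintf(
      "only %d pairs below r_star = %g; raise r_star or supply more data",
      res$n_pairs, r_star), call. = FALSE)
  }
  Lambda <- res$Lambda
  k_grid <- 0:k_max
  if (max(Lambda, na.rm = TRUE) - Lambda[2] < 1e-8) {
    stop("Lambda(k) is saturated from the start; no initial slope to fit",
         call. = FALSE)
  }
  # fit the initial linear segment: exclude the saturated tail of the curve
  cap <- Lambda[1] + 0.9 * (max(Lambda, na.rm = TRUE) -
                              Lambda[1])
  fit <- tryCatch(
    best_linear_window(k_grid, Lambda, min_len = 5L, max_start = 5L,
                       y_cap = cap),
    error = function(e)
      best_linear_window(k_grid, Lambda,
                         min_len = min(5L, length(k_grid)),
                         max_start = 5L))
  structure(list(k_grid = k_grid, Lambda = Lambda, lle = fit$slope,
                 stderr = fit$stderr, window = fit$window,
                 r_squared = fit$r_squared, r_star = r_star,
                 n_pairs = res$n_pairs),
            class = "gz_curve")
}

#' @export
print.gz_curve <- function(x, ...) {
  cat("<gz_curve>  lle =", format(x$lle, digits = 4),
      "+/-", format(x$stderr, digits = 2),
      " window = [", x$window[1], ",", x$window[2], "]",
      " pairs =", x$n_pairs, "\n")
  invisible(x)
}

# Best-R^2 linear window search over (x, y): candidate windows start at index
# start <= max_start+1, contain at least min_len points, and (optionally)
# stay below y_cap -- the pre-saturation segment of a growth curve.
best_linear_window <- function(x, y, min_len = 5L, max_start = 5L,
                               y_cap = Inf) {
  ok <- is.finite(y) & y <= y_cap
  best <- list(r_squared = -Inf)
  n <- length(x)
  if (n < min_len) stop("no linear window found", call. = FALSE)
  for (s in 1:min(max_start + 1, n - min_len + 1)) {
    for (e in (s + min_len - 1):n) {
      sel <- s:e
      sel <- sel[ok[sel]]
      if (length(sel) < min_len) next
      if (!all(ok[s:e])) next
      xx <- x[sel]; yy <- y[sel]
      sxx <- sum((xx - mean(xx))^2)
      if (sxx == 0) next
      slope <- sum((xx - mean(xx)) * (yy - mean(yy))) / sxx
      fitted <- mean(yy) + slope * (xx - mean(xx))
      ssr <- sum((yy - fitted)^2)
      sst <- sum((yy - mean(yy))^2)
      r2 <- if (sst > 0) 1 - ssr / sst else 0
      if (r2 > best$r_squared) {
        se <- if (length(sel) > 2) sqrt(ssr / (length(sel) - 2) / sxx) else NA_real_
        best <- list(slope = slope, stderr = se,
                     window = c(x[min(sel)], x[max(sel)]), r_squared = r2)
      }
    }
  }
  if (!is.finite(best$r_squared)) stop("no linear window found", call. = FALSE)
  best
}

#' Scale-dependent Lyapunov exponent (SDLE)
#'
#' Groups embedded-vector pairs by their current separation shell and
#' averages the one-step log-separation growth within each shell:
#' `lambda(eps) = < ln d(t + dt) - ln d(t) >_shell / dt`. Shells are
#' geometrically spaced (factor `10^(1/8)`, 8 shells per decade) between the
#' observed pair-distance extremes. A pair stops contributing once its
#' separation saturates at the attractor size (`> eps_max / 2`).
#'
#' In deterministic chaos `lambda(eps)` shows a positive plateau spanning at
#' least half a decade; pure noise decays like `-gamma * ln(eps)` with no
#' qualifying plateau; periodic dynamics give `lambda` near zero.
#'
#' @inheritParams gz_lambda
#' @param dt Evolution horizon Delta t of the growth increments (steps).
#' @param horizon Maximum pair-evolution time.
#' @param shells_per_decade Geometric shell resolution.
#' @param min_pairs Shells sampled by fewer pairs are dropped (recorded in
#'   the returned table).
#' @return Object of class `sdle_profile`: data frame `shells` with columns
#'   `eps` (geometric shell center), `lambda`, `se`, `n_pairs`, `n_obs`,
#'   plus `plateau` (bounds/value or NULL) and `label`.
#' @export
sdle <- function(emb, dt = 1, theiler = NULL, horizon = 100,
                 shells_per_decade = 8, min_pairs = 50,
                 max_vectors = 2500, max_pairs = 4e6) {
  emb <- as.matrix(emb)
  if (is.null(theiler)) theiler <- default_theiler(emb)
  n <- nrow(emb)
  n_usable <- n - horizon - dt
  if (n_usable < 100) stop("series too short for the SDLE horizon",
                           call. = FALSE)
  idx <- subsample_idx(n_usable, max_vectors)
  tE <- t(emb)
  d <- cpp_pair_dist_sample(tE, idx[seq(1, length(idx),
                                        length.out = min(1200, length(idx)))],
                            as.integer(theiler))
  d <- d[d > 0]
  if (length(d) == 0) stop("all pair separations are zero", call. = FALSE)
  eps_max <- max(d)
  # floor the smallest shell well above numerically degenerate separations
  # (periodic series produce pair distances at machine precision)
  eps_min <- max(stats::quantile(d, 0.001, names = FALSE), 1e-8 * eps_max)
  n_shell <- max(ceiling(log10(eps_max / eps_min) * shells_per_decade), 4)
  bounds <- eps_min * 10^(seq(0, log10(eps_max / eps_min),
                              length.out = n_shell + 1))
  res <- cpp_sdle(tE, as.integer(idx), bounds, as.integer(theiler),
                  as.integer(dt), as.integer(horizon), eps_max / 2,
                  as.integer(max_pairs))
  lambda <- ifelse(res$counts > 0, res$sums / res$counts / dt, NA_real_)
  varr <- ifelse(res$counts > 1,
                 (res$sums2 - res$sums^2 / res$counts) /
                   (res$counts - 1), NA_real_)
  se <- sqrt(pmax(varr, 0) / pmax(res$counts, 1)) / dt
  shells <- data.frame(
    eps = sqrt(bounds[-length(bounds)] * bounds[-1]),
    eps_lo = bounds[-length(bounds)], eps_hi = bounds[-1],
    lambda = lambda, se = se,
    n_pairs = res$n_pairs, n_obs = res$counts)
  kept <- shells[shells$n_pairs >= min_pairs & is.finite(shells$lambda), ,
                 drop = FALSE]
  if (nrow(kept) == 0) stop("all SDLE shells are empty", call. = FALSE)
  plateau <- find_plateau(kept)
  prof <- structure(list(shells = kept, all_shells = shells,
                         plateau = plateau, dt = dt,
                         n_dropped = nrow(shells) - nrow(kept)),
                    class = "sdle_profile")
  prof$label <- classify_dynamics(prof)
  prof
}

#' @export
print.sdle_profile <- function(x, ...) {
  cat("<sdle_profile> ", nrow(x$shells), "shells; label =", x$label, "\n")
  if (!is.null(x$plateau)) {
    cat("  plateau: lambda =", format(x$plateau$value, digits = 4),
        " eps in [", format(x$plateau$eps1, digits = 3), ",",
        format(x$plateau$eps2, digits = 3), "] width =",
        format(x$plateau$width_decades, digits = 3), "decades\n")
  }
  invisible(x)
}

# Longest run of consecutive shells with positive lambda all within 10% of
# the run median; returns bounds/value or NULL.
find_plateau <- function(shells) {
  n <- nrow(shells)
  best <- NULL
  for (s in seq_len(n)) {
    if (s + 1 > n) break
    for (e in (s + 1):n) {
      lam <- shells$lambda[s:e]
      if (any(lam <= 0)) break
      med <- stats::median(lam)
      if (any(abs(lam - med) > 0.1 * med)) break
      width <- log10(shells$eps_hi[e] / shells$eps_lo[s])
      if (is.null(best) || width > best$width_decades) {
        best <- list(eps1 = shells$eps_lo[s], eps2 = shells$eps_hi[e],
                     value = stats::weighted.mean(lam, shells$n_obs[s:e]),
                     width_decades = width, from = s, to = e)
      }
    }
  }
  best
}

#' Classify dynamics from an SDLE profile
#'
#' Applies the plateau-width criterion `log10(eps2/eps1) >= 1/2`:
#' a qualifying positive plateau with no noise wings is deterministic chaos;
#' the same plateau flanked by `-gamma * ln(eps)` decay at smaller scales is
#' noisy chaos; without a qualifying plateau, a profile dominated by the
#' `-gamma * ln(eps)` decay is noise-dominated, and a profile with `lambda`
#' near zero on all scales (no plateau, no systematic decay) is nonchaotic.
#'
#' @param profile An `sdle_profile`.
#' @return One of `"deterministic_chaos"`, `"noisy_chaos"`,
#'   `"noise_dominated"`, `"nonchaotic"`.
#' @export
classify_dynamics <- function(profile) {
  stopifnot(inherits(profile, "sdle_profile"))
  sh <- profile$shells
  pl <- profile$plateau
  pooled_se <- stats::median(sh$se, na.rm = TRUE)
  if (!is.null(pl) && pl$width_decades >= 0.5 &&
      pl$value > max(0.01, 2 * pooled_se)) {
    # wing check: lambda at scales below the plateau rising like
    # -gamma * ln(eps) marks noise superposed on the chaotic signal
    left <- sh[sh$eps < pl$eps1, , drop = FALSE]
    wing <- FALSE
    if (nrow(left) >= 3) {
      slope <- stats::coef(stats::lm(left$lambda ~ log(left$eps)))[2]
      wing <- is.finite(slope) && slope < 0 &&
        mean(utils::head(left$lambda, 3)) > 1.25 * pl$value
    }
    return(if (wing) "noisy_chaos" else "deterministic_chaos")
  }
  # no qualifying plateau: noise shows a systematic decay of lambda across
  # scales; periodic/quasiperiodic profiles hover near zero everywhere
  k <- min(3L, nrow(sh))
  decay <- mean(utils::head(sh$lambda, k)) - mean(utils::tail(sh$lambda, k))
  if (decay > 0.05 && max(sh$lambda) > 0.05) "noise_dominated"
  else "nonchaotic"
}
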