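#' Multifractal dimension spectrum of a planar point set
#'
#' Generalized (Renyi) dimensions from order-q correlation integrals
#' `C_q(r) = mean_i [ p_i(r) ]^(q-1)` with `p_i(r)` the fraction of points
#' within distance `r` of point `i` (self included). For `q != 1`,
#' `D_q = slope of ln C_q(r) vs ln r / (q - 1)`; `q = 1` uses the
#' information-dimension limit `D_1 = slope of mean_i ln p_i(r)`. The
#' scaling window is chosen per q as the best-R^2 linear window spanning at
#' least one decade; fits with `R^2 < 0.98` are flagged unreliable.
#'
#' @param points `M x 2` matrix (or a numeric vector for sets on a line).
#' @param q_grid Orders q (default `-10..10` in steps of 0.5, q = 1 via the
#'   entropy limit).
#' @param r_grid Radii at which the correlation integrals are evaluated;
#'   default 60 log-spaced values spanning the 0.1%..75% pair-distance
#'   quantiles.
#' @param min_decade Minimum width (decades) of the scaling window.
#' @return Object of class `dq_spectrum`: data frame `q`, `Dq`, `r_lo`,
#'   `r_hi`, `r_squared`, `reliable`, plus aliases `D0`, `D1`, `D2`.
#' @examples
#' \donttest{
#' x <- cbind(runif(3000), runif(3000))   # filled square: Dq = 2
#' dq_spectrum(x, q_grid = c(0, 2))$table$Dq
#' }
#' @export
dq_spectrum <- function(points, q_grid = seq(-10, 10, 0.5), r_grid = NULL,
                        min_decade = 1) {
  if (is.null(dim(points))) points <- cbind(as.numeric(points), 0)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  M <- nrow(points)
  if (M < 100) stop("need at least 100 points", call. = FALSE)
  if (is.null(r_grid)) {
    i <- sample.int(M, min(M, 1500))
    d <- as.numeric(stats::dist(points[i, ]))
    d <- d[d > 0]
    r_grid <- 10^seq(log10(stats::quantile(d, 0.001, names = FALSE)),
                     log10(stats::quantile(d, 0.75, names = FALSE)),
                     length.out = 60)
  }
  r_grid <- sort(r_grid)
  res <- cpp_corr_integral(points[, 1], points[, 2], r_grid, q_grid)
  lr <- log(r_grid)
  rows <- lapply(seq_along(q_grid), function(qi) {
    q <- q_grid[qi]
    y <- if (q == 1) res$mean_log_p else log(res$Cq[, qi]) / (q - 1)
    ok <- is.finite(y)
    if (sum(ok) < 5) {
      return(data.frame(q = q, Dq = NA_real_, r_lo = NA, r_hi = NA,
                        r_squared = NA, reliable = FALSE))
    }
    fit <- best_scaling_window(lr[ok], y[ok], min_decade = min_decade)
    data.frame(q = q, Dq = fit$slope, r_lo = exp(fit$window[1]),
               r_hi = exp(fit$window[2]), r_squared = fit$r_squared,
               reliable = fit$r_squared >= 0.98)
  })
  table <- do.call(rbind, rows)
  alias <- function(qv) {
    i <- which(abs(table$q - qv) < 1e-9)
    if (length(i) == 1) table$Dq[i] else NA_real_
  }
  structure(list(table = table, D0 = alias(0), D1 = alias(1),
                 D2 = alias(2), n_points = M, r_grid = r_grid),
            class = "dq_spectrum")
}

#' @export
print.dq_spectrum <- function(x, ...) {
  cat("<dq_spectrum>  M =", x$n_points,
      " D0 =", format(x$D0, digits = 3),
      " D1 =", format(x$D1, digits = 3),
      " D2 =", format(x$D2, digits = 3), "\n")
  invisible(x)
}

# Best linear window on (lx, y) among windows spanning >= min_decade decades
# (base-10) of lx; maximizes R^2.
best_scaling_window <- function(lx, y, min_decade = 1) {
  n <- length(lx)
  span <- min_decade * log(10)
  best <- NULL
  for (s in 1:(n - 4)) {
    for (e in (s + 4):n) {
      if (lx[e] - lx[s] < span) next
      xx <- lx[s:e]; yy <- y[s:e]
      sxx <- sum((xx - mean(xx))^2)
      slope <- sum((xx - mean(xx)) * (yy - mean(yy))) / sxx
      sst <- sum((yy - mean(yy))^2)
      r2 <- if (sst > 0) {
        1 - sum((yy - mean(yy) - slope * (xx - mean(xx)))^2) / sst
      } else 1
      if (is.null(best) || r2 > best$r_squared) {
        best <- list(slope = slope, window = c(lx[s], lx[e]),
                     r_squared = r2)
      }
    }
  }
  if (is.null(best)) {
    # no window long enough: use the full range
    xx <- lx; yy <- y
    sxx <- sum((xx - mean(xx))^2)
    slope <- sum((xx - mean(xx)) * (yy - mean(yy))) / sxx
    best <- list(slope = slope, window = range(lx), r_squared = NA_real_)
  }
  best
}

#' Detect the period of a scalar series
#'
#' Smallest `p <= max_period` with
#' `max_t |x(t + p) - x(t)| < tol * range(x)`; a constant series has period
#' 1; otherwise the series is aperiodic (`NA`).
#'
#' @param series Post-transient scalar series.
#' @param max_period Largest period tried.
#' @param tol Relative tolerance (default `1e-6`, suitable for
#'   deterministic dynamics; use ~`1e-2` for noisy recurrence labeling).
#' @return Integer period or `NA_integer_` (aperiodic).
#' @examples
#' detect_period(sin(2 * pi * (1:200) / 7))  # 7
#' @export
detect_period <- function(series, max_period = 64, tol = 1e-6) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 2 * max_period) max_period <- floor(n / 2)
  rng <- diff(range(x))
  if (rng == 0) return(1L)
  for (p in seq_len(max_period)) {
    if (max(abs(x[(p + 1):n] - x[1:(n - p)])) < tol * rng) {
      return(as.integer(p))
    }
  }
  NA_integer_
}

#' Count particle clusters
#'
#' Number of connected components of the graph linking particles closer
#' than `link_distance` (default the interaction radius: the interaction
#' graph defines dynamical connectivity).
#'
#' @param state A `swarm_state`.
#' @param link_distance Linking threshold.
#' @return Integer cluster count.
#' @export
count_clusters <- function(state, link_distance = 0.472) {
  stopifnot(inherits(state, "swarm_state"))
  n <- nrow(state$positions)
  if (n == 1) return(1L)
  adj <- as.matrix(stats::dist(state$positions)) < link_distance
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::count_components(g)
}

#' Bifurcation diagram of the center-of-mass coordinate
#'
#' For each confinement value, simulates the deterministic (or noisy) model
#' and samples the post-transient scalar center-of-mass series
#' `x(t) = X(t) + Y(t)`; attaches a period label per branch.
#'
#' @param beta_grid Confinement values.
#' @param n Particles.
#' @param eta Noise (0 for the deterministic diagram).
#' @param n_steps,transient Run length and discarded transient.
#' @param n_sample Post-transient samples kept per beta.
#' @param seed Master seed (same for every beta).
#' @param max_period,tol Passed to [detect_period()].
#' @param r0,v0 Model geometry.
#' @return List with `samples` (data frame `beta`, `x`) and `periods`
#'   (data frame `beta`, `period`); diverged runs are recorded in
#'   `failures` and skipped.
#' @export
bifurcation_diagram <- function(beta_grid, n = 128, eta = 0,
                                n_steps = 1500, transient = 1000,
                                n_sample = 100, seed = 1,
                                max_period = 64, tol = 1e-6,
                                r0 = 0.472, v0 = 1) {
  samples <- list(); periods <- list(); failures <- character()
  for (b in beta_grid) {
    params <- hcvm_params(n = n, beta = b, eta = eta, v0 = v0, r0 = r0)
    traj <- tryCatch(
      simulate_hcvm(params, n_steps = n_steps, transient = transient,
                    seed = seed, record = "cm"),
      error = function(e) {
        failures <<- c(failures, sprintf("beta = %g: %s", b,
                                         conditionMessage(e)))
        NULL
      })
    if (is.null(traj)) next
    x <- cm_series(traj)$x_sum
    p <- detect_period(x, max_period = max_period, tol = tol)
    samples[[length(samples) + 1]] <-
      data.frame(beta = b, x = utils::tail(x, n_sample))
    periods[[length(periods) + 1]] <- data.frame(beta = b, period = p)
  }
  list(samples = do.call(rbind, samples),
       periods = do.call(rbind, periods),
       failures = failures)
}

#' Attractor label for one parameter point
#'
#' Combines period detection on the center-of-mass series, the sign of the
#' Benettin Lyapunov exponent and the SDLE classifier into one label.
#'
#' @param params An [hcvm_params()] object.
#' @param n_steps,transient Run length.
#' @param seed Master seed.
#' @param period_tol Tolerance passed to [detect_period()] (relative);
#'   loosened automatically for noisy runs.
#' @return List with `kind` (one of `periodic`, `quasiperiodic`, `chaotic`,
#'   `noisy_chaotic`, `noise_dominated`, `unknown`), `period`,
#'   `lambda1`, `converged`, `sdle_label`.
#' @export
classify_attractor <- function(params, n_steps = 4000, transient = 1000,
                               seed = 1, period_tol = NULL) {
  if (is.null(period_tol)) {
    period_tol <- if (params$eta == 0) 1e-6 else 1e-2
  }
  traj <- simulate_hcvm(params, n_steps = n_steps, transient = transient,
                        seed = seed, record = "cm")
  x <- cm_series(traj)$x_sum
  period <- detect_period(x, tol = period_tol)
  if (!is.na(period) && params$eta == 0) {
    return(list(kind = "periodic", period = period, lambda1 = NA_real_,
                converged = NA, sdle_label = NA_character_))
  }
  lle <- benettin_lle(params, n_steps = n_steps, transient = transient,
                      seed = seed)
  prof <- tryCatch(sdle(embed_series(x, m = 6, tau = 9)),
                   error = function(e) NULL)
  sdle_label <- if (is.null(prof)) NA_character_ else prof$label
  kind <- if (!lle$converged && is.na(sdle_label)) {
    "unknown"
  } else if (!is.na(period)) {
    "periodic"
  } else if (identical(sdle_label, "noise_dominated")) {
    "noise_dominated"
  } else if (lle$converged && lle$lambda1 > 0) {
    if (identical(sdle_label, "noisy_chaos")) "noisy_chaotic" else "chaotic"
  } else if (identical(sdle_label, "noisy_chaos")) {
    "noisy_chaotic"
  } else if (identical(sdle_label, "deterministic_chaos")) {
    "chaotic"
  } else {
    "quasiperiodic"
  }
  list(kind = kind, period = period, lambda1 = lle$lambda1,
       converged = lle$converged, sdle_label = sdle_label)
}

#' Phase diagram over a confinement-noise grid
#'
#' Labels every `(beta, eta)` cell with [classify_attractor()].
#'
#' @param beta_grid Confinement values (log-spaced).
#' @param eta_grid Noise values (linear).
#' @param n Particles.
#' @inheritParams classify_attractor
#' @return Data frame `beta`, `eta`, `kind`, `period`, `lambda1`.
#' @export
phase_diagram <- function(beta_grid, eta_grid, n = 500, n_steps = 3000,
                          transient = 1000, seed = 1) {
  rows <- list()
  for (eta in eta_grid) {
    for (b in beta_grid) {
      params <- hcvm_params(n = n, beta = b, eta = eta)
      lab <- tryCatch(
        classify_attractor(params, n_steps = n_steps,
                           transient = transient, seed = seed),
        error = function(e) list(kind = "unknown", period = NA_integer_,
                                 lambda1 = NA_real_))
      rows[[length(rows) + 1]] <- data.frame(
        beta = b, eta = eta, kind = lab$kind,
        period = if (is.null(lab$period)) NA_integer_ else lab$period,
        lambda1 = lab$lambda1)
    }
  }
  do.call(rbind, rows)
}

#' Poincare point set of the center-of-mass attractor
#'
#' Samples the 2D center-of-mass point `(X(t), Y(t))` every iteration after
#' the transient -- the point set whose multifractal spectrum characterizes
#' the attractor.
#'
#' @param traj An `hcvm_trajectory`.
#' @return `M x 2` matrix of center-of-mass positions.
#' @export
cm_poincare <- function(traj) {
  cm <- cm_series(traj)
  cbind(cm$X, cm$Y)
}
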