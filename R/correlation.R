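#' Dimensionless velocity fluctuations of one state
#'
#' Removes the mean velocity and normalizes by the root mean square
#' fluctuation: `dv_i = v_i - V`, `dvhat_i = dv_i / sqrt(mean_k |dv_k|^2)`.
#' By construction `sum_i dvhat_i = 0` and `mean_i |dvhat_i|^2 = 1`.
#'
#' @param state A `swarm_state` (or an `n x 2` velocity matrix).
#' @param v0 Particle speed used to derive velocities from headings.
#' @return `n x 2` matrix of normalized fluctuations.
#' @export
velocity_fluctuations <- function(state, v0 = 1) {
  v <- if (inherits(state, "swarm_state")) state_velocities(state, v0)
       else as.matrix(state)
  if (nrow(v) < 2) stop("need at least 2 particles", call. = FALSE)
  dv <- sweep(v, 2, colMeans(v))
  ms <- mean(rowSums(dv^2))
  if (ms == 0) {
    stop("zero fluctuation variance: swarm is perfectly aligned, ",
         "normalized fluctuations are undefined", call. = FALSE)
  }
  dv / sqrt(ms)
}

# Post-transient positions and normalized velocity fluctuations as
# T x N x 2 arrays (T = number of analysis frames).
traj_analysis_arrays <- function(traj) {
  stopifnot(inherits(traj, "hcvm_trajectory"))
  if (is.null(traj$positions)) {
    stop("trajectory must be recorded with record = \"states\"",
         call. = FALSE)
  }
  frames <- analysis_frames(traj)
  pos <- traj$positions[frames, , , drop = FALSE]
  th <- traj$headings[frames, , drop = FALSE]
  v0 <- traj$params$v0
  vx <- v0 * cos(th); vy <- v0 * sin(th)
  dvx <- vx - rowMeans(vx); dvy <- vy - rowMeans(vy)
  ms <- rowMeans(dvx^2 + dvy^2)
  if (any(ms == 0)) {
    stop("zero fluctuation variance in frame(s) ",
         paste(utils::head(which(ms == 0), 3), collapse = ", "),
         ": normalized fluctuations are undefined", call. = FALSE)
  }
  s <- sqrt(ms)
  dvhat <- array(c(dvx / s, dvy / s), dim = dim(pos))
  list(pos = pos, dvhat = dvhat, n_frames = dim(pos)[1],
       n = dim(pos)[2])
}

# Shared pair-histogram pass. Returns weighted sums W[lag, bin], pair counts,
# origin counts, bin centers.
corr_histograms <- function(traj, lags, nbins, max_origins = 25,
                            arrays = NULL) {
  if (is.null(arrays)) arrays <- traj_analysis_arrays(traj)
  T <- arrays$n_frames
  max_lag <- max(lags)
  if (max_lag >= T) stop("lag exceeds the analysis window", call. = FALSE)
  n_avail <- T - max_lag
  stride <- max(1L, floor(n_avail / max_origins))
  t0_idx <- seq(0L, n_avail - 1L, by = stride)
  # strict upper bound on any pair distance in the center-of-mass frame
  cm1 <- apply(arrays$pos, c(1, 3), mean)
  rel_max <- sqrt(max((arrays$pos[, , 1] - cm1[, 1])^2 +
                      (arrays$pos[, , 2] - cm1[, 2])^2))
  rmax <- 2 * rel_max * (1 + 1e-12) + 1e-12
  res <- cpp_corr_hist(arrays$pos, arrays$dvhat, as.integer(t0_idx),
                       as.integer(lags), as.integer(nbins), rmax)
  list(W = res$W, CNT = res$CNT, n_origins = res$n_origins,
       lags = lags, rmax = rmax, dr = rmax / nbins,
       r = (seq_len(nbins) - 0.5) * rmax / nbins,
       n = arrays$n, arrays = arrays)
}

#' Dynamic connected correlation function C(r, t)
#'
#' Bins the products `dvhat_i(t0) . dvhat_j(t0 + t)` by the center-of-mass
#' frame distance `r_ij(t0, t) = |r_i(t0) - r_j(t0 + t)|` and normalizes each
#' bin by its pair count, averaging over time origins `t0`. At lag 0 the
#' self-pairs sit at r = 0 and do not enter bins at r > 0; at positive
#' lags `r_ii` is generally nonzero and the `i = j` terms are retained (the
#' double sum runs over all ordered pairs).
#'
#' @param traj An `hcvm_trajectory` (recorded states).
#' @param lags Integer vector of time lags `t`.
#' @param dr Bin width; default `max(r_ij)/50`.
#' @param max_origins Cap on the number of time origins averaged.
#' @return Data frame with columns `lag`, `r`, `C`, `n_pairs`; empty bins
#'   carry `NA` (recorded, never interpolated).
#' @export
dccf <- function(traj, lags = 0, dr = NULL, max_origins = 25) {
  nbins <- if (is.null(dr)) 50L else NULL
  h <- if (is.null(dr)) {
    corr_histograms(traj, lags, 50L, max_origins)
  } else {
    # choose bin count so that the bin width equals dr over [0, rmax]
    a <- traj_analysis_arrays(traj)
    cm1 <- apply(a$pos, c(1, 3), mean)
    rel_max <- sqrt(max((a$pos[, , 1] - cm1[, 1])^2 +
                        (a$pos[, , 2] - cm1[, 2])^2))
    corr_histograms(traj, lags, max(2L, ceiling(2 * rel_max / dr)),
                    max_origins, arrays = a)
  }
  out <- do.call(rbind, lapply(seq_along(lags), function(l) {
    C <- ifelse(h$CNT[l, ] > 0, h$W[l, ] / h$CNT[l, ], NA_real_)
    data.frame(lag = lags[l], r = h$r, C = C, n_pairs = h$CNT[l, ])
  }))
  rownames(out) <- NULL
  out
}

#' Static correlation profile: C(r), Q(r), correlation length, susceptibility
#'
#' The static connected correlation `C(r) = C(r, 0)` and the cumulative
#' correlation `Q(r) = (1/N) < sum_ij dvhat_i . dvhat_j theta(r - r_ij) >`.
#' The correlation length `xi` is the first zero `r0` of `C(r)` (located by
#' linear interpolation between bin centers), which is also the first
#' maximum of `Q`; the susceptibility is `chi = Q(xi)`.
#'
#' @inheritParams dccf
#' @param nbins Number of radial bins.
#' @return Object of class `corr_profile`: list with the binned table
#'   (`r`, `C`, `Q`, `n_pairs`), `r0`, `xi`, `chi`, `dr`.
#' @export
cumulative_corr <- function(traj, nbins = 50, max_origins = 25) {
  h <- corr_histograms(traj, 0L, as.integer(nbins), max_origins)
  W <- h$W[1, ]; CNT <- h$CNT[1, ]
  n_t0 <- h$n_origins[1]
  C <- ifelse(CNT > 0, W / CNT, NA_real_)
  Q <- cumsum(W) / (h$n * n_t0)
  # first zero of C(r) beyond r = 0 (skip the self-pair bin content at r=0
  # by starting the search at the first bin with C > 0)
  r0 <- first_zero_crossing(h$r, C)
  if (is.na(r0)) {
    stop("C(r) has no sign change in range: domain too small or ",
         "non-critical state", call. = FALSE)
  }
  chi <- stats::approx(h$r, Q, xout = r0, rule = 2)$y
  structure(list(table = data.frame(r = h$r, C = C, Q = Q, n_pairs = CNT),
                 r0 = r0, xi = r0, chi = chi, dr = h$dr,
                 n_origins = n_t0),
            class = "corr_profile")
}

#' @export
print.corr_profile <- function(x, ...) {
  cat("<corr_profile>  xi =", format(x$xi, digits = 4),
      " chi =", format(x$chi, digits = 4), "\n")
  invisible(x)
}

# First downward zero crossing of y(x), searched from the first finite
# positive value on; linear interpolation, NA when there is none.
first_zero_crossing <- function(x, y) {
  ok <- which(is.finite(y))
  start <- ok[which(y[ok] > 0)[1]]
  if (is.na(start)) return(NA_real_)
  prev <- start
  for (i in ok[ok > start]) {
    if (y[i] <= 0) {
      # interpolate between prev (positive) and i
      x0 <- x[prev]; x1 <- x[i]; y0 <- y[prev]; y1 <- y[i]
      return(x0 + (0 - y0) * (x1 - x0) / (y1 - y0))
    }
    prev <- i
  }
  NA_real_
}

#' Spectral correlation function and NDCCF
#'
#' Computes `Chat(k, t) = (1/N) < sum_ij sinc(k r_ij(t0, t))
#' dvhat_i(t0) . dvhat_j(t0 + t) >`, the critical wavenumber
#' `k_c = argmax_k Chat(k, 0)`, the susceptibility `chi = max_k Chat(k, 0)`,
#' the normalized dynamic correlation `g(t) = Chat(k_c, t) / Chat(k_c, 0)`
#' and the first zero `t_m` of `g`.
#'
#' @inheritParams dccf
#' @param k_grid Wavenumber grid; default 200 log-spaced points in
#'   `[0.5/L, pi]` with `L` the swarm size.
#' @param lags Lags at which the NDCCF is evaluated (default `0:80`).
#' @param nbins Radial bins of the internal pair histogram.
#' @return Object of class `spectral_corr`: `k_grid`, `C_hat` (matrix lag x
#'   k), `k_c`, `chi`, `g` (data frame `lag`, `g`), `t_m`, `L`.
#' @export
spectral_corr <- function(traj, k_grid = NULL, lags = 0:80, nbins = 400,
                          max_origins = 25) {
  if (!0 %in% lags) lags <- sort(unique(c(0L, lags)))
  h <- corr_histograms(traj, lags, as.integer(nbins), max_origins)
  L <- swarm_size(traj)
  if (is.null(k_grid)) {
    k_grid <- 10^seq(log10(0.5 / L), log10(pi), length.out = 200)
  }
  # sinc transform of the binned pair weights
  sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)
  K <- outer(h$r, k_grid, function(r, k) sinc(k * r))  # nbins x nk
  C_hat <- (h$W %*% K) / (h$n * h$n_origins)           # nlag x nk
  i0 <- which(lags == 0)
  ic <- which.max(C_hat[i0, ])
  if (ic == 1 || ic == length(k_grid)) {
    stop("argmax of Chat(k, 0) at the grid boundary: widen k_grid",
         call. = FALSE)
  }
  k_c <- k_grid[ic]
  chi <- C_hat[i0, ic]
  g <- C_hat[, ic] / chi
  t_m <- first_zero_crossing(lags, g)
  structure(list(k_grid = k_grid, C_hat = C_hat, lags = lags,
                 k_c = k_c, chi = chi,
                 g = data.frame(lag = lags, g = g),
                 t_m = t_m, L = L),
            class = "spectral_corr")
}

#' @export
print.spectral_corr <- function(x, ...) {
  cat("<spectral_corr>  k_c =", format(x$k_c, digits = 4),
      " chi =", format(x$chi, digits = 4),
      " t_m =", format(x$t_m, digits = 4), "\n")
  invisible(x)
}

#' Correlation time from the NDCCF
#'
#' Solves for `tau_k` in
#' `sum_{t >= 1} (1/t) sin(t / tau_k) g(t) = pi / 4`.
#' The `t = 0` term of the printed sum is singular and its continuum-limit
#' contribution vanishes, so it is excluded (documented convention). For
#' `g(t) = exp(-t / tau0)` and dense sampling the identity
#' `integral sin(a t) exp(-b t) / t dt = arctan(a / b)` makes `tau_k = tau0`
#' exact.
#'
#' @param g NDCCF values at integer lags. Either a numeric vector with
#'   `g[1] = g(0)`, or the `g` data frame of a [spectral_corr()] result.
#' @param tau_range Search interval for the root (default
#'   `[0.05, 50 * t_max]`).
#' @param n_scan Size of the logarithmic scan grid used to bracket the root.
#' @return The correlation time `tau_k` (scalar).
#' @export
correlation_time <- function(g, tau_range = NULL, n_scan = 400) {
  if (is.data.frame(g)) {
    t <- g$lag; gv <- g$g
  } else {
    gv <- as.numeric(g); t <- seq_along(gv) - 1
  }
  keep <- t >= 1
  t <- t[keep]; gv <- gv[keep]
  if (length(t) < 3) stop("need g sampled at several positive lags",
                          call. = FALSE)
  objective <- function(tau) sum(sin(t / tau) * gv / t) - pi / 4
  if (is.null(tau_range)) tau_range <- c(0.05, 50 * max(t))
  taus <- 10^seq(log10(tau_range[1]), log10(tau_range[2]),
                 length.out = n_scan)
  vals <- vapply(taus, objective, numeric(1))
  sgn <- sign(vals)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  # the objective oscillates spuriously at small tau; the physical solution
  # (arctan identity: objective decreasing through pi/4) is the largest root
  flip <- flip[length(flip)]
  if (length(flip) == 0) {
    i <- which.min(abs(vals))
    if (abs(vals[i]) < 0.05 * pi / 4) {
      warning("no exact bracket; returning nearest-scan value")
      return(taus[i])
    }
    stop("no solution: objective does not cross pi/4 on the scan grid",
         call. = FALSE)
  }
  i <- flip
  stats::uniroot(objective, lower = taus[i], upper = taus[i + 1],
                 tol = 1e-10)$root
}

#' Polarization order parameter
#'
#' `W(t) = |sum_j v_j| / (N v0)`, averaged over the post-transient window.
#'
#' @param traj An `hcvm_trajectory` (recorded states).
#' @return Time-averaged polarization in `[0, 1]`.
#' @export
polarization <- function(traj) {
  stopifnot(inherits(traj, "hcvm_trajectory"))
  if (is.null(traj$headings)) {
    stop("trajectory must be recorded with record = \"states\"",
         call. = FALSE)
  }
  th <- traj$headings[analysis_frames(traj), , drop = FALSE]
  mean(sqrt(rowMeans(cos(th))^2 + rowMeans(sin(th))^2))
}

#' Swarm size
#'
#' Time average of the maximum interparticle distance over the
#' post-transient window.
#'
#' @param traj An `hcvm_trajectory` (recorded states).
#' @param max_frames Number of evenly spaced frames entering the average.
#' @return Mean maximum interparticle distance.
#' @export
swarm_size <- function(traj, max_frames = 50) {
  stopifnot(inherits(traj, "hcvm_trajectory"))
  if (is.null(traj$positions)) {
    stop("trajectory must be recorded with record = \"states\"",
         call. = FALSE)
  }
  frames <- analysis_frames(traj)
  if (length(frames) > max_frames) {
    frames <- frames[unique(round(seq(1, length(frames),
                                      length.out = max_frames)))]
  }
  pos <- traj$positions
  mean(cpp_max_pairdist(pos, as.integer(frames - 1L)))
}
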