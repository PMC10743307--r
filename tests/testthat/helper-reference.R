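# Independent brute-force reference implementations used as oracles.
# Deliberately written as plain double loops, sharing no code with the
# package internals.

ref_force <- function(pos, headings, v0, beta, r0, per_neighbor = FALSE) {
  n <- nrow(pos)
  v <- v0 * cbind(cos(headings), sin(headings))
  F <- matrix(0, n, 2)
  for (i in 1:n) {
    acc <- c(0, 0)
    for (j in 1:n) {
      d <- sqrt(sum((pos[j, ] - pos[i, ])^2))
      if (d < r0) {
        acc <- acc + if (per_neighbor) v[j, ] - beta * pos[j, ] else v[j, ]
      }
    }
    if (!per_neighbor) acc <- acc - beta * pos[i, ]
    F[i, ] <- acc
  }
  F
}

ref_step <- function(pos, headings, noise, v0, beta, r0,
                     per_neighbor = FALSE) {
  F <- ref_force(pos, headings, v0, beta, r0, per_neighbor)
  n <- nrow(pos)
  nth <- numeric(n)
  for (i in 1:n) {
    ang <- if (sum(F[i, ]^2) == 0) headings[i] else atan2(F[i, 2], F[i, 1])
    nth[i] <- ang + noise[i]
  }
  list(positions = pos + v0 * cbind(cos(nth), sin(nth)), headings = nth)
}

# Rotation-matrix form of the update: v(t+1) = v0 R(xi) F / |F|.
ref_step_rotmat <- function(pos, headings, noise, v0, beta, r0) {
  F <- ref_force(pos, headings, v0, beta, r0)
  n <- nrow(pos)
  npos <- pos; nth <- numeric(n)
  for (i in 1:n) {
    f <- F[i, ]
    u <- if (sum(f^2) == 0) c(cos(headings[i]), sin(headings[i]))
         else f / sqrt(sum(f^2))
    R <- matrix(c(cos(noise[i]), sin(noise[i]),
                  -sin(noise[i]), cos(noise[i])), 2, 2)
    vnew <- v0 * as.numeric(R %*% u)
    npos[i, ] <- pos[i, ] + vnew
    nth[i] <- atan2(vnew[2], vnew[1])
  }
  list(positions = npos, headings = nth)
}

# Union-find connected components over the < link graph.
ref_clusters <- function(pos, link) {
  n <- nrow(pos)
  parent <- 1:n
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((pos[i, ] - pos[j, ])^2)) < link) {
      parent[find(i)] <- find(j)
    }
  }
  length(unique(vapply(1:n, find, integer(1))))
}

# Naive binned equal-time/lagged connected correlation (CM frame).
ref_dccf <- function(pos_arr, dvhat_arr, t0s, lag, nbins, rmax) {
  W <- numeric(nbins); CNT <- numeric(nbins)
  N <- dim(pos_arr)[2]
  for (t0 in t0s) {
    t1 <- t0 + lag
    a <- pos_arr[t0, , ]; b <- pos_arr[t1, , ]
    a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
    for (i in 1:N) for (j in 1:N) {
      r <- sqrt(sum((a[i, ] - b[j, ])^2))
      bin <- min(floor(r / rmax * nbins) + 1, nbins)
      W[bin] <- W[bin] + sum(dvhat_arr[t0, i, ] * dvhat_arr[t1, j, ])
      CNT[bin] <- CNT[bin] + 1
    }
  }
  list(W = W, CNT = CNT)
}

# Logistic-map series on the fully chaotic branch (LLE = log 2).
logistic_series <- function(n, x0 = 0.2, transient = 100) {
  x <- x0
  for (i in seq_len(transient)) x <- 4 * x * (1 - x)
  out <- numeric(n)
  for (i in seq_len(n)) { x <- 4 * x * (1 - x); out[i] <- x }
  out
}

# Two-scale Cantor product measure on the triadic Cantor set: digits 0/2
# chosen with probabilities (p, 1-p). Closed-form generalized dimensions:
# D_q = log(p^q + (1-p)^q) / ((q - 1) * log(1/3)), D_1 by the entropy limit.
cantor_points <- function(m, p = 0.3, depth = 30) {
  x <- numeric(m)
  for (k in 1:depth) {
    digit <- stats::rbinom(m, 1, 1 - p) * 2
    x <- x + digit * 3^(-k)
  }
  x
}

cantor_dq_exact <- function(q, p = 0.3) {
  ifelse(abs(q - 1) < 1e-12,
         (p * log(p) + (1 - p) * log(1 - p)) / log(1 / 3),
         log(p^q + (1 - p)^q) / ((q - 1) * log(1 / 3)))
}

# Build a minimal hcvm_trajectory from explicit positions/headings arrays.
fake_trajectory <- function(pos_arr, head_mat, params, transient = 0) {
  cm <- data.frame(step = 0:(dim(pos_arr)[1] - 1),
                   X = apply(pos_arr[, , 1, drop = FALSE], 1, mean),
                   Y = apply(pos_arr[, , 2, drop = FALSE], 1, mean))
  cm$x_sum <- cm$X + cm$Y
  structure(list(params = params, seed = NA_integer_,
                 n_steps = dim(pos_arr)[1] - 1L,
                 transient = as.integer(transient), cm = cm,
                 positions = pos_arr, headings = head_mat),
            class = "hcvm_trajectory")
}
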