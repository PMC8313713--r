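# Shared fixtures and independent oracles for the test suite.

# Build a snapshot_set directly from coordinate matrices (bookkeeping tests).
make_snapshot_set <- function(frames, box) {
  frames <- lapply(frames, function(fr) {
    fr$box <- box
    fr
  })
  structure(list(frames = frames, box = box, n_frames = length(frames),
                 spec = NULL),
            class = "snapshot_set")
}

# Thickness map evaluated from an arbitrary analytic field at cell centers.
analytic_thickness_map <- function(field_fun, grid, h_bulk = 4.76) {
  xc <- (seq_len(grid$nx) - 0.5) * grid$box_x / grid$nx
  yc <- (seq_len(grid$ny) - 0.5) * grid$box_y / grid$ny
  th <- outer(xc, yc, field_fun)
  structure(list(grid = grid, mean_thickness = th,
                 n_obs = matrix(1L, grid$nx, grid$ny),
                 interpolated = matrix(FALSE, grid$nx, grid$ny),
                 h_bulk = h_bulk),
            class = "thickness_map")
}

# Free-energy profile object from an analytic F(x) on a uniform grid.
analytic_profile <- function(F_fun, from, to, n = 400L, temperature = 320) {
  x <- seq(from, to, length.out = n)
  structure(list(x = x, F = F_fun(x), sigma_F = NULL,
                 n = rep(1L, n), breaks = NULL, temperature = temperature,
                 kT = kT_kcal(temperature), iterations = 0L,
                 window_offsets = NULL, populated = rep(TRUE, n)),
            class = "free_energy_profile")
}

# Independent WHAM oracle: direct maximization of the binned WHAM
# log-likelihood over log bin probabilities (scale-invariant
# parametrization), a different route to the same estimator than the
# package's self-consistent iteration.
oracle_wham_ml <- function(dataset, breaks, temperature = 320) {
  kT <- kT_kcal(temperature)
  B <- length(breaks) - 1L
  xb <- (breaks[-1] + breaks[-length(breaks)]) / 2
  W <- length(dataset$windows)
  n_ib <- matrix(0, W, B)
  for (i in seq_len(W)) {
    bi <- findInterval(dataset$windows[[i]]$series, breaks,
                       rightmost.closed = TRUE)
    n_ib[i, ] <- tabulate(bi[bi >= 1 & bi <= B], nbins = B)
  }
  centers <- vapply(dataset$windows, `[[`, 0, "center")
  ks <- vapply(dataset$windows, `[[`, 0, "k") / 4.184
  c_ib <- exp(-0.5 * ks * sweep(matrix(xb, W, B, byrow = TRUE), 1, centers)^2 / kT)
  N_i <- rowSums(n_ib)
  M_b <- colSums(n_ib)
  keep <- M_b > 0
  negll <- function(theta) {
    p <- exp(theta)
    s_i <- as.numeric(c_ib[, keep, drop = FALSE] %*% p)
    -(sum(M_b[keep] * theta) - sum(N_i * log(s_i)))
  }
  grad <- function(theta) {
    p <- exp(theta)
    s_i <- as.numeric(c_ib[, keep, drop = FALSE] %*% p)
    -(M_b[keep] - as.numeric(crossprod(c_ib[, keep, drop = FALSE], N_i / s_i)) * p)
  }
  th0 <- log(M_b[keep] / sum(M_b))
  fit <- stats::optim(th0, negll, grad, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  F <- rep(NA_real_, B)
  F[keep] <- -kT * fit$par
  list(x = xb, F = F - min(F, na.rm = TRUE), populated = keep)
}

# Rejection sampler from a biased Boltzmann density (iid oracle).
oracle_biased_iid <- function(pmf, center, k, n, temperature = 320) {
  kT <- kT_kcal(temperature)
  dens <- function(z) exp(-(pmf_eval(pmf, z) +
                              0.5 * (k / 4.184) * (z - center)^2) / kT)
  M <- stats::optimize(dens, pmf$domain, maximum = TRUE)$objective
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::runif(4L * n, pmf$domain[1], pmf$domain[2])
    out <- c(out, cand[stats::runif(4L * n) < dens(cand) / M])
  }
  out[seq_len(n)]
}
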