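# Free-energy profiles from umbrella-sampling windows via the weighted
# histogram analysis method (WHAM), with integrated-autocorrelation-time
# estimation, Monte-Carlo bootstrap uncertainties drawing only the effective
# (uncorrelated) number of points per window, and end-state binding free
# energies from Boltzmann-weighted integrals of the profile.

#' Integrated autocorrelation time of a series
#'
#' tau_int = 1/2 + sum_t rho(t), with the sum truncated at the first lag
#' where the autocorrelation estimate turns negative (initial-positive-
#' sequence rule). The effective sample size is N / (2 tau_int).
#'
#' @param series Numeric series, length >= 100, non-constant.
#' @return A list with `tau_int` (samples) and `n_eff`.
#' @export
autocorrelation_time <- function(series) {
  n <- length(series)
  if (n < 100L) stop("series too short for autocorrelation analysis (n = ",
                     n, ", need >= 100)")
  if (stats::sd(series) == 0)
    stop("constant series: autocorrelation undefined")
  lag_max <- min(n - 1L, 1000L)
  repeat {
    rho <- as.numeric(stats::acf(series, lag.max = lag_max,
                                 plot = FALSE)$acf)[-1]
    neg <- which(rho < 0)
    if (length(neg) > 0L || lag_max >= n - 1L) break
    lag_max <- min(n - 1L, lag_max * 4L)
  }
  t_stop <- if (length(neg) > 0L) neg[1] - 1L else length(rho)
  tau <- 0.5 + if (t_stop > 0L) sum(rho[seq_len(t_stop)]) else 0
  tau <- max(tau, 0.5)
  list(tau_int = tau, n_eff = n / (2 * tau))
}

# Shared histogram/bias setup for WHAM.
.wham_setup <- function(dataset, bins, temperature, burn_in, breaks) {
  stopifnot(inherits(dataset, "umbrella_dataset"))
  series_list <- lapply(dataset$windows, function(w) {
    s <- w$series
    if (burn_in > 0) {
      if (burn_in >= length(s))
        stop("burn_in removes the entire series of the window at ",
             w$center, " nm")
      s <- s[-seq_len(burn_in)]
    }
    s
  })
  if (is.null(breaks)) {
    rng <- range(unlist(series_list))
    breaks <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = bins + 1L)
  }
  B <- length(breaks) - 1L
  xb <- (breaks[-1] + breaks[-length(breaks)]) / 2
  W <- length(dataset$windows)
  n_ib <- matrix(0, W, B)
  for (i in seq_len(W)) {
    bi <- findInterval(series_list[[i]], breaks, rightmost.closed = TRUE)
    bi <- bi[bi >= 1L & bi <= B]
    n_ib[i, ] <- tabulate(bi, nbins = B)
  }
  centers <- vapply(dataset$windows, `[[`, 0, "center")
  ks <- vapply(dataset$windows, `[[`, 0, "k")
  kT <- kT_kcal(temperature)
  # bin-averaged bias Boltzmann factors: with stiff springs the bias varies
  # substantially across a bin, and evaluating it only at the bin center
  # tilts the window coupling; average over quadrature nodes instead
  nodes <- (seq_len(8L) - 0.5) / 8L
  c_ib <- matrix(0, W, B)
  for (q in nodes) {
    xq <- breaks[-length(breaks)] + q * diff(breaks)
    c_ib <- c_ib + exp(-0.5 * spring_kcal(ks) *
                         sweep(matrix(xq, W, B, byrow = TRUE), 1, centers)^2 / kT)
  }
  c_ib <- c_ib / length(nodes)
  # adjacent windows must share at least one populated bin
  ord <- order(centers)
  for (s in seq_len(W - 1L)) {
    a <- ord[s]; b <- ord[s + 1L]
    if (!any(n_ib[a, ] > 0 & n_ib[b, ] > 0))
      stop(sprintf(
        "no histogram overlap between windows centered at %.3f and %.3f nm",
        centers[a], centers[b]))
  }
  list(n_ib = n_ib, c_ib = c_ib, xb = xb, breaks = breaks, kT = kT,
       N_i = rowSums(n_ib), centers = centers)
}

#' Weighted histogram analysis method
#'
#' Standard WHAM self-consistency: the unbiased bin probability is
#' p_b = sum_i n_ib / sum_i N_i f_i c_ib with c_ib the Boltzmann factor of
#' window i's harmonic bias at bin b and f_i^-1 = sum_b c_ib p_b, iterated
#' until the maximum change of the window offsets -kT ln f_i falls below
#' `tol`. The profile is F_b = -kT ln p_b, shifted so its minimum is zero.
#'
#' @param dataset An `umbrella_dataset`.
#' @param bins Number of histogram bins over the sampled range (default 200).
#' @param temperature Kelvin; defaults to the dataset's temperature.
#' @param tol Convergence tolerance on the window offsets, kcal/mol.
#' @param burn_in Samples removed from the start of every window before
#'   analysis (equilibration of the biased windows).
#' @param max_iter Iteration cap.
#' @param breaks Optional explicit histogram breaks (used by the bootstrap to
#'   keep replicate profiles on the reference binning).
#' @param zero `"min"` shifts the profile minimum to zero; `"none"` leaves
#'   the WHAM offset.
#' @return A `free_energy_profile` with bin centers `x` (nm), `F` (kcal/mol,
#'   `NA` in unpopulated bins), per-bin counts `n`, and the converged window
#'   offsets.
#' @export
wham <- function(dataset, bins = 200L, temperature = NULL, tol = 1e-6,
                 burn_in = 0L, max_iter = 1e5, breaks = NULL,
                 zero = c("min", "none")) {
  zero <- match.arg(zero)
  if (is.null(temperature))
    temperature <- if (!is.null(dataset$temperature)) dataset$temperature else 320
  su <- .wham_setup(dataset, bins, temperature, burn_in, breaks)
  nb <- colSums(su$n_ib)
  kT <- su$kT
  W <- nrow(su$n_ib)
  f <- rep(1, W)
  g_old <- rep(0, W)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- as.numeric(crossprod(su$c_ib, su$N_i * f))
    p <- ifelse(denom > 0, nb / denom, 0)
    p <- p / sum(p)
    f <- 1 / as.numeric(su$c_ib %*% p)
    g <- -kT * log(f)
    g <- g - g[1]
    if (max(abs(g - g_old)) < tol) break
    if (iter >= max_iter)
      stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kcal/mol)",
                   iter, max(abs(g - g_old))))
    g_old <- g
  }
  F <- ifelse(p > 0, -kT * log(p), NA_real_)
  if (zero == "min") F <- F - min(F, na.rm = TRUE)
  structure(list(x = su$xb, F = F, sigma_F = NULL, n = nb,
                 breaks = su$breaks, temperature = temperature, kT = kT,
                 iterations = iter, window_offsets = g,
                 populated = nb > 0),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf(
    "<free_energy_profile: %d bins over [%.3f, %.3f] nm, max F %.2f kcal/mol, %d WHAM iterations>\n",
    length(x$x), min(x$x), max(x$x), max(x$F, na.rm = TRUE), x$iterations))
  invisible(x)
}

#' Monte-Carlo bootstrap uncertainty of a WHAM profile
#'
#' Estimates each window's integrated autocorrelation time, then for every
#' bootstrap replicate draws only N_eff = N/(2 tau_int) points per window
#' (with replacement from the window's empirical distribution), reruns WHAM
#' on the reference binning, aligns each replicate profile to the reference
#' by its mean over the commonly populated bins, and reports the per-bin
#' standard deviation across replicates.
#'
#' @param dataset An `umbrella_dataset`.
#' @param n_boot Number of replicates (>= 20 for production, >= 2 to run).
#' @param seed Integer seed.
#' @inheritParams wham
#' @return A `wham_bootstrap`: the reference `profile` with `sigma_F` filled
#'   in, the replicate profile matrix, and per-window `tau_int` / `n_eff`.
#' @export
bootstrap_uncertainty <- function(dataset, n_boot = 50L, seed = 1L,
                                  bins = 200L, temperature = NULL,
                                  tol = 1e-6, burn_in = 0L, breaks = NULL) {
  if (n_boot < 2L) stop("n_boot must be at least 2")
  ref <- wham(dataset, bins = bins, temperature = temperature, tol = tol,
              burn_in = burn_in, breaks = breaks)
  post <- lapply(dataset$windows, function(w)
    if (burn_in > 0) w$series[-seq_len(burn_in)] else w$series)
  ac <- lapply(post, autocorrelation_time)
  n_eff <- vapply(ac, function(a) max(4L, floor(a$n_eff)), 0)
  temperature <- ref$temperature
  reps <- matrix(NA_real_, length(ref$x), n_boot)
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_boot)) {
      bs <- Map(function(s, m) sample(s, m, replace = TRUE), post, n_eff)
      ds <- umbrella_dataset(bs,
                             centers = vapply(dataset$windows, `[[`, 0, "center"),
                             k = vapply(dataset$windows, `[[`, 0, "k"),
                             temperature = temperature)
      pr <- tryCatch(
        wham(ds, temperature = temperature, tol = tol, breaks = ref$breaks),
        error = function(e) NULL)
      if (is.null(pr)) next
      common <- ref$populated & pr$populated
      off <- mean(pr$F[common] - ref$F[common])
      reps[, r] <- pr$F - off
    }
  })
  sigma <- apply(reps, 1L, function(v) {
    v <- v[is.finite(v)]
    if (length(v) >= 2L) stats::sd(v) else NA_real_
  })
  ref$sigma_F <- sigma
  structure(list(profile = ref, sigma_F = sigma, replicates = reps,
                 tau_int = vapply(ac, `[[`, 0, "tau_int"), n_eff = n_eff,
                 n_boot = n_boot, seed = as.integer(seed)),
            class = "wham_bootstrap")
}

#' @export
print.wham_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<wham_bootstrap: %d replicates, tau_int %s, median sigma_F %.3f kcal/mol>\n",
    x$n_boot, paste(signif(x$tau_int, 3), collapse = ", "),
    stats::median(x$sigma_F, na.rm = TRUE)))
  invisible(x)
}

# Boltzmann-weighted integral of exp(-F/kT) over bins inside an interval.
.boltzmann_integral <- function(profile, interval, kT, F = profile$F) {
  sel <- which(profile$x >= interval[1] & profile$x <= interval[2] &
                 is.finite(F))
  if (length(sel) < 2L)
    stop(sprintf("interval [%.3f, %.3f] nm is outside the profile support",
                 interval[1], interval[2]))
  pracma::trapz(profile$x[sel], exp(-F[sel] / kT))
}

#' Binding free energy from a free-energy profile
#'
#' Delta G_bind = -kT ln of the ratio of Boltzmann-weighted integrals of the
#' profile over the bound and reference (unbound) intervals, by trapezoidal
#' integration on the bin centers. When a `wham_bootstrap` is supplied, the
#' same functional is evaluated on every replicate profile and its standard
#' deviation reported as the uncertainty.
#'
#' @param profile A `free_energy_profile`.
#' @param bound,reference Length-2 intervals (nm), disjoint, inside the
#'   profile support.
#' @param boot Optional `wham_bootstrap` for uncertainty propagation.
#' @return A `binding_result` with `dg` and `sigma` (kcal/mol).
#' @export
binding_free_energy <- function(profile, bound, reference, boot = NULL) {
  stopifnot(inherits(profile, "free_energy_profile"),
            length(bound) == 2L, length(reference) == 2L)
  if (!(bound[2] <= reference[1] || reference[2] <= bound[1]))
    stop("bound and reference intervals must be disjoint")
  kT <- profile$kT
  dg <- -kT * log(.boltzmann_integral(profile, bound, kT) /
                    .boltzmann_integral(profile, reference, kT))
  sigma <- NA_real_
  if (!is.null(boot)) {
    stopifnot(inherits(boot, "wham_bootstrap"))
    dgs <- apply(boot$replicates, 2L, function(Fr) {
      tryCatch(-kT * log(.boltzmann_integral(profile, bound, kT, F = Fr) /
                           .boltzmann_integral(profile, reference, kT, F = Fr)),
               error = function(e) NA_real_)
    })
    sigma <- stats::sd(dgs[is.finite(dgs)])
  }
  structure(list(dg = dg, sigma = sigma, bound = bound,
                 reference = reference, kT = kT,
                 temperature = profile$temperature),
            class = "binding_result")
}

# "x.y(z)" style: uncertainty in units of the last printed digit.
.format_parenthetical <- function(value, sigma) {
  if (!is.finite(sigma) || sigma <= 0) return(sprintf("%.2f", value))
  digits <- max(0L, -floor(log10(sigma)))
  sprintf("%.*f(%d)", digits, value, round(sigma * 10^digits))
}

#' @export
print.binding_result <- function(x, ...) {
  cat(sprintf(
    "<binding_result: Delta G = %s kcal/mol (bound [%.2f, %.2f] nm vs reference [%.2f, %.2f] nm)>\n",
    .format_parenthetical(x$dg, x$sigma), x$bound[1], x$bound[2],
    x$reference[1], x$reference[2]))
  invisible(x)
}
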