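# Synthetic umbrella-sampling window time series. Each window draws from the
# biased Boltzmann density p_i(x) ~ exp(-[F(x) + k/2 (x - x0_i)^2] / kT)
# via an inverse-CDF Gaussian-copula AR(1) scheme: a stationary AR(1) latent
# series is mapped through pnorm and the biased density's quantile function,
# so the stationary marginal is the biased density EXACTLY (to grid
# resolution) while the autocorrelation length is tuned by corr_len.

.biased_quantile_fun <- function(pmf, center, k_kcal, kT, n_grid = NULL) {
  # grid must resolve the narrowest density feature (the biased sd under a
  # stiff spring) or the inverse CDF distorts window marginals
  sigma_w <- sqrt(kT / max(k_kcal, 1e-12))
  width <- diff(pmf$domain)
  if (is.null(n_grid))
    n_grid <- min(2e5L, max(4000L, ceiling(width / (sigma_w / 400))))
  xs <- seq(pmf$domain[1], pmf$domain[2], length.out = n_grid)
  u_bias <- pmf_eval(pmf, xs) + 0.5 * k_kcal * (xs - center)^2
  w <- exp(-(u_bias - min(u_bias)) / kT)
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0)
    stop("biased density is not normalizable on the PMF domain")
  # trapezoidal cumulative: O(dx^2) CDF error instead of O(dx)
  cdf <- c(0, cumsum((w[-1] + w[-length(w)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  keep <- c(TRUE, diff(cdf) > 0)
  xs <- xs[keep]; cdf <- cdf[keep]
  function(u) stats::approx(cdf, xs, xout = u, rule = 2)$y
}

#' Generate umbrella-window time series from a known free-energy profile
#'
#' @param pmf A `pmf_spec` ground-truth profile.
#' @param centers Window centers x0 (nm), all within the PMF domain.
#'   The reference layout is 8 equally spaced windows 0.1 nm apart.
#' @param k Harmonic spring constant, kJ mol^-1 nm^-2 (default 3500).
#' @param n_steps Samples per window (>= 100).
#' @param corr_len Autocorrelation length of the series in steps; the latent
#'   AR(1) lag-1 correlation is exp(-1/corr_len). `corr_len = 0` gives i.i.d.
#'   samples.
#' @param seed Integer seed; the generator is a pure function of
#'   (arguments, seed).
#' @param n_grid Grid resolution of the quantile inversion; by default
#'   scaled so the grid spacing is a small fraction of the biased-window
#'   standard deviation sqrt(kT/k).
#' @return An `umbrella_dataset`: `windows` (each with `center`, `k`,
#'   `series`), `temperature`, and the generating `pmf`.
#' @export
gen_umbrella_series <- function(pmf, centers, k = 3500, n_steps,
                                corr_len = 1, seed = 1L, n_grid = NULL) {
  stopifnot(inherits(pmf, "pmf_spec"), k > 0, n_steps >= 100, corr_len >= 0)
  if (any(centers < pmf$domain[1] | centers > pmf$domain[2]))
    stop("window centers must lie within the PMF domain")
  kT <- kT_kcal(pmf$temperature)
  k_kcal <- spring_kcal(k)
  rho <- if (corr_len > 0) exp(-1 / corr_len) else 0
  withr::with_seed(as.integer(seed), {
    windows <- lapply(centers, function(x0) {
      qf <- .biased_quantile_fun(pmf, x0, k_kcal, kT, n_grid)
      innov <- stats::rnorm(n_steps) * sqrt(1 - rho^2)
      z <- as.numeric(stats::filter(innov, rho, method = "recursive",
                                    init = stats::rnorm(1L)))
      list(center = x0, k = k, series = qf(stats::pnorm(z)))
    })
    structure(list(windows = windows, temperature = pmf$temperature,
                   pmf = pmf, corr_len = corr_len, seed = as.integer(seed)),
              class = "umbrella_dataset")
  })
}

#' Assemble an umbrella dataset from raw series
#'
#' @param series_list List of numeric reaction-coordinate series (nm).
#' @param centers,k Window centers (nm) and spring constants
#'   (kJ mol^-1 nm^-2, recycled).
#' @param temperature Kelvin.
#' @return An `umbrella_dataset`.
#' @export
umbrella_dataset <- function(series_list, centers, k, temperature = 320) {
  stopifnot(length(series_list) == length(centers), all(k > 0))
  k <- rep_len(k, length(centers))
  windows <- Map(function(s, x0, kk) {
    stopifnot(is.numeric(s), length(s) >= 2L)
    list(center = x0, k = kk, series = as.numeric(s))
  }, series_list, centers, k)
  structure(list(windows = windows, temperature = temperature, pmf = NULL),
            class = "umbrella_dataset")
}

#' @export
print.umbrella_dataset <- function(x, ...) {
  cat(sprintf("<umbrella_dataset: %d windows, centers %s nm, %d samples/window, T = %g K>\n",
              length(x$windows),
              paste(signif(vapply(x$windows, `[[`, 0, "center"), 3),
                    collapse = ", "),
              length(x$windows[[1]]$series), x$temperature))
  invisible(x)
}
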