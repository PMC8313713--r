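# Analytic 1D free-energy profiles (PMFs) serving as exactly known ground
# truth for the umbrella-sampling / WHAM stage. Energies kcal/mol, x in nm.

.new_pmf <- function(form, params, domain, temperature) {
  stopifnot(is.numeric(domain), length(domain) == 2L, domain[1] < domain[2],
            temperature > 0)
  p <- structure(list(form = form, params = params,
                      domain = as.numeric(domain),
                      temperature = temperature),
                 class = "pmf_spec")
  xs <- seq(domain[1], domain[2], length.out = 512L)
  if (any(!is.finite(pmf_eval(p, xs))))
    stop("free energy must be finite on the domain")
  p
}

#' Flat (zero) free-energy profile
#' @param domain Length-2 numeric, (x_min, x_max) in nm.
#' @param temperature Kelvin (default 320).
#' @return A `pmf_spec`.
#' @export
pmf_zero <- function(domain, temperature = 320)
  .new_pmf("zero", list(), domain, temperature)

#' Harmonic free-energy profile F(x) = c/2 (x - x0)^2
#' @param curvature Curvature c in kcal mol^-1 nm^-2.
#' @param x0 Minimum position (nm); default domain midpoint.
#' @inheritParams pmf_zero
#' @return A `pmf_spec`.
#' @export
pmf_harmonic <- function(curvature, domain, x0 = mean(domain),
                         temperature = 320) {
  stopifnot(curvature >= 0)
  .new_pmf("harmonic", list(curvature = curvature, x0 = x0), domain,
           temperature)
}

#' Square-well free-energy profile
#'
#' F = -depth for |x - center| < width/2, else 0.
#' @param depth Well depth epsilon in kcal/mol (> 0 means attractive well).
#' @param width Well width (nm).
#' @param center Well center (nm); default domain midpoint.
#' @inheritParams pmf_zero
#' @return A `pmf_spec`.
#' @export
pmf_square_well <- function(depth, width, domain, center = mean(domain),
                            temperature = 320) {
  stopifnot(width > 0)
  .new_pmf("square_well", list(depth = depth, width = width, center = center),
           domain, temperature)
}

#' Symmetric-quartic double-well free-energy profile
#'
#' F(x) = barrier * (u^2 - 1)^2 + tilt * u with u = (x - center)/half_width;
#' minima near center +/- half_width, barrier height `barrier` at the center
#' (for tilt = 0), and `tilt` controlling the well-depth asymmetry.
#'
#' @param center Barrier position (nm).
#' @param half_width Half distance between the wells (nm).
#' @param barrier Barrier height (kcal/mol).
#' @param tilt Linear asymmetry (kcal/mol per unit u), default 0.
#' @inheritParams pmf_zero
#' @return A `pmf_spec`.
#' @export
pmf_double_well <- function(center, half_width, barrier, domain, tilt = 0,
                            temperature = 320) {
  stopifnot(half_width > 0, barrier >= 0)
  .new_pmf("double_well",
           list(center = center, half_width = half_width, barrier = barrier,
                tilt = tilt), domain, temperature)
}

#' Tabulated free-energy profile (linear interpolation)
#' @param x,F Numeric vectors of positions (nm) and energies (kcal/mol).
#' @param domain Domain; default `range(x)`.
#' @inheritParams pmf_zero
#' @return A `pmf_spec`.
#' @export
pmf_tabulated <- function(x, F, domain = range(x), temperature = 320) {
  stopifnot(length(x) == length(F), length(x) >= 2L, all(is.finite(F)))
  o <- order(x)
  .new_pmf("tabulated", list(x = x[o], F = F[o]), domain, temperature)
}

#' Evaluate a free-energy profile
#' @param pmf A `pmf_spec`.
#' @param x Positions (nm), vectorized.
#' @return F(x) in kcal/mol.
#' @export
pmf_eval <- function(pmf, x) {
  stopifnot(inherits(pmf, "pmf_spec"))
  p <- pmf$params
  switch(pmf$form,
         zero = rep(0, length(x)),
         harmonic = 0.5 * p$curvature * (x - p$x0)^2,
         square_well = ifelse(abs(x - p$center) < p$width / 2, -p$depth, 0),
         double_well = {
           u <- (x - p$center) / p$half_width
           p$barrier * (u^2 - 1)^2 + p$tilt * u
         },
         tabulated = stats::approx(p$x, p$F, xout = x, rule = 2)$y)
}

#' @export
print.pmf_spec <- function(x, ...) {
  cat(sprintf("<pmf_spec: %s on [%.3g, %.3g] nm, T = %g K>\n",
              x$form, x$domain[1], x$domain[2], x$temperature))
  invisible(x)
}
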