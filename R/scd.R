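# Deuterium order parameters. For a C-H bond at angle theta to the membrane
# normal (+z), S_CD = 0.5 <3 cos^2 theta - 1>, averaged over bonds and
# frames. S_CD is bounded in [-0.5, 1]: -0.5 for bonds perpendicular to the
# normal, 0 at the magic angle (54.7356 deg) or for isotropic orientations.

#' Deuterium order parameter profile
#'
#' Computes per-carbon S_CD over a spatial selection of bonds: `"near"` keeps
#' bonds whose lipid xy position lies within `cutoff` (periodic, in-plane) of
#' `reference_xy`; `"bulk"` is the exact complement, so near and bulk
#' partition the ensemble; `"all"` uses every bond.
#'
#' @param chains A `chain_set` (see [gen_chain_ensemble()]).
#' @param selection `"all"`, `"near"` or `"bulk"`.
#' @param reference_xy Numeric length 2 (nm); required for near/bulk.
#' @param cutoff In-plane selection radius (nm), default 1.6 nm.
#' @return An `scd_profile` data frame with columns `carbon`, `s_cd`,
#'   `n_bonds`.
#' @export
scd_profile <- function(chains, selection = c("all", "near", "bulk"),
                        reference_xy = NULL, cutoff = 1.6) {
  stopifnot(inherits(chains, "chain_set"))
  selection <- match.arg(selection)
  keep <- rep(TRUE, nrow(chains$vectors))
  if (selection != "all") {
    if (is.null(reference_xy))
      stop("selection '", selection, "' requires reference_xy")
    dx <- .periodic_delta(chains$lipid_xy[, 1] - reference_xy[1], chains$box[1])
    dy <- .periodic_delta(chains$lipid_xy[, 2] - reference_xy[2], chains$box[2])
    near <- sqrt(dx^2 + dy^2) <= cutoff
    keep <- if (selection == "near") near else !near
  }
  if (!any(keep))
    stop("empty selection: no bonds match selection '", selection, "'")
  v <- chains$vectors[keep, , drop = FALSE]
  cos2 <- (v[, 3] / sqrt(rowSums(v^2)))^2
  s_bond <- 0.5 * (3 * cos2 - 1)
  carbon <- chains$carbon[keep]
  agg <- tapply(s_bond, carbon, mean)
  n <- tapply(s_bond, carbon, length)
  out <- data.frame(carbon = as.integer(names(agg)),
                    s_cd = as.numeric(agg),
                    n_bonds = as.integer(n))
  stopifnot(all(out$s_cd >= -0.5 - 1e-12), all(out$s_cd <= 1 + 1e-12))
  class(out) <- c("scd_profile", "data.frame")
  out
}

#' Block-averaged standard error of the mean
#'
#' Splits a per-frame series into consecutive blocks of `block_length`
#' frames (discarding an incomplete trailing block) and returns the standard
#' deviation of block means divided by sqrt(number of blocks). Blocks longer
#' than the correlation time give an honest SEM for correlated series.
#'
#' @param series Numeric per-frame values.
#' @param block_length Frames per block.
#' @return SEM (same units as `series`).
#' @export
block_uncertainty <- function(series, block_length) {
  stopifnot(is.numeric(series), block_length >= 1)
  n_blocks <- floor(length(series) / block_length)
  if (n_blocks < 2L)
    stop("need at least 2 complete blocks (series length ",
         length(series), ", block length ", block_length, ")")
  used <- series[seq_len(n_blocks * block_length)]
  means <- colMeans(matrix(used, nrow = block_length))
  stats::sd(means) / sqrt(n_blocks)
}

#' @export
print.scd_profile <- function(x, ...) {
  cat(sprintf("<scd_profile: %d carbons, S_CD in [%.4f, %.4f]>\n",
              nrow(x), min(x$s_cd), max(x$s_cd)))
  print.data.frame(x, ...)
  invisible(x)
}
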