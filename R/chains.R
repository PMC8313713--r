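# Synthetic C-H bond ensembles with prescribed orientational statistics,
# feeding the deuterium order-parameter stage. The order parameter of a bond
# at angle theta to the membrane normal is 0.5 (3 cos^2 theta - 1).

#' Fixed-angle bond orientation distribution
#' @param theta_deg Angle to the membrane normal, degrees.
#' @return An `angle_dist` object.
#' @export
angle_dist_fixed <- function(theta_deg) {
  stopifnot(is.numeric(theta_deg), length(theta_deg) == 1L,
            theta_deg >= 0, theta_deg <= 180)
  th <- theta_deg * pi / 180
  structure(list(kind = "fixed", theta = th,
                 ground_truth = 0.5 * (3 * cos(th)^2 - 1)),
            class = "angle_dist")
}

#' Isotropic bond orientation distribution
#'
#' Directions uniform on the sphere; the spherical average of
#' 0.5 (3 cos^2 theta - 1) is exactly 0.
#' @return An `angle_dist` object.
#' @export
angle_dist_isotropic <- function() {
  structure(list(kind = "isotropic", ground_truth = 0), class = "angle_dist")
}

#' Custom bond orientation distribution
#' @param sampler Function of `n` returning `n` angles theta in radians.
#' @param ground_truth Optional known expectation of 0.5 (3 cos^2 theta - 1)
#'   under the distribution; when `NULL` it is estimated by Monte Carlo
#'   (2e5 draws) and flagged as an estimate.
#' @return An `angle_dist` object.
#' @export
angle_dist_sampler <- function(sampler, ground_truth = NULL) {
  stopifnot(is.function(sampler))
  structure(list(kind = "sampler", sampler = sampler,
                 ground_truth = ground_truth), class = "angle_dist")
}

.sample_theta <- function(dist, n) {
  switch(dist$kind,
         fixed = rep(dist$theta, n),
         # cos(theta) uniform on [-1, 1] gives the sphere's surface measure
         isotropic = acos(stats::runif(n, -1, 1)),
         sampler = {
           th <- dist$sampler(n)
           if (length(th) != n || any(!is.finite(th)))
             stop("invalid angle sampler: must return n finite angles")
           th
         })
}

#' Generate a C-H bond ensemble with prescribed orientational order
#'
#' @param target_angle_dist An [angle_dist_fixed()], [angle_dist_isotropic()]
#'   or [angle_dist_sampler()].
#' @param n_chains Number of bonds (>= 1).
#' @param seed Integer seed.
#' @param box In-plane box (Lx, Ly) nm for the attached lipid xy positions.
#' @param n_carbons Bonds are cycled over carbon indices 1..n_carbons.
#' @return A `chain_set` with unit `vectors` (n x 3), `theta`, `carbon`,
#'   `lipid_xy`, `box` and the analytic `ground_truth_scd`.
#' @export
gen_chain_ensemble <- function(target_angle_dist, n_chains, seed = 1L,
                               box = c(10, 10), n_carbons = 1L) {
  stopifnot(inherits(target_angle_dist, "angle_dist"), n_chains >= 1)
  withr::with_seed(as.integer(seed), {
    theta <- .sample_theta(target_angle_dist, n_chains)
    phi <- stats::runif(n_chains, 0, 2 * pi)
    v <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    gt <- target_angle_dist$ground_truth
    gt_estimated <- FALSE
    if (is.null(gt)) {
      th <- .sample_theta(target_angle_dist, 2e5)
      gt <- mean(0.5 * (3 * cos(th)^2 - 1))
      gt_estimated <- TRUE
    }
    structure(list(vectors = v, theta = theta,
                   carbon = rep_len(seq_len(n_carbons), n_chains),
                   lipid_xy = cbind(stats::runif(n_chains, 0, box[1]),
                                    stats::runif(n_chains, 0, box[2])),
                   box = box, ground_truth_scd = gt,
                   ground_truth_estimated = gt_estimated),
              class = "chain_set")
  })
}

#' @export
print.chain_set <- function(x, ...) {
  cat(sprintf("<chain_set: %d bonds, %d carbons, ground-truth S_CD = %.4f%s>\n",
              nrow(x$vectors), max(x$carbon), x$ground_truth_scd,
              if (x$ground_truth_estimated) " (MC estimate)" else ""))
  invisible(x)
}
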