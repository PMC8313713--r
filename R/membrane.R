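# Synthetic membrane model: a bilayer of bulk phosphorus-phosphorus thickness
# h0 with Gaussian thinning wells anchored at inclusion footprints,
#   h(x, y) = h0 - sum_i A_i exp(-d_i^2 / (2 sigma_i^2)),
# where d_i is the in-plane distance to footprint i's boundary (0 inside).
# Measuring the well from the boundary (not the center) makes larger
# inclusions carry wider thinned annuli, the geometry the perimeter
# analysis downstream depends on.

#' Describe one membrane inclusion
#'
#' @param footprint A [footprint_disk()], [footprint_polygon()] or
#'   [footprint_horseshoe()].
#' @param well_depth Thinning amplitude A at the footprint boundary (nm, >= 0).
#' @param well_width Gaussian decay length sigma of the thinning well (nm, > 0).
#' @return An `inclusion` object.
#' @export
inclusion <- function(footprint, well_depth = 0.4, well_width = 1.5) {
  stopifnot(inherits(footprint, "footprint"),
            well_depth >= 0, well_width > 0)
  structure(list(footprint = footprint, well_depth = well_depth,
                 well_width = well_width), class = "inclusion")
}

#' Generative parameters of a synthetic membrane
#'
#' @param box_x,box_y In-plane box dimensions (nm).
#' @param bulk_thickness Bulk phosphorus-phosphorus thickness h0 (nm).
#'   Default 4.76 nm, a cholesterol-rich DPPC bilayer at 320 K.
#' @param inclusions List of [inclusion()] objects (may be empty).
#' @param roughness_sd Per-lipid thermal roughness of each leaflet surface
#'   (nm, Gaussian sd). Default 0.1 nm.
#' @param areal_density Lipids per nm^2 per leaflet. Default 1.5, a typical
#'   all-atom bilayer value.
#' @param seed Integer seed making the generator a pure function of the spec.
#' @return A `membrane_spec` object.
#' @export
membrane_spec <- function(box_x, box_y, bulk_thickness = 4.76,
                          inclusions = list(), roughness_sd = 0.1,
                          areal_density = 1.5, seed = 1L) {
  stopifnot(box_x > 0, box_y > 0, bulk_thickness > 0,
            roughness_sd >= 0, areal_density > 0)
  inclusions <- lapply(inclusions, function(inc) {
    if (inherits(inc, "footprint")) inc <- inclusion(inc)
    stopifnot(inherits(inc, "inclusion"))
    inc
  })
  for (inc in inclusions) {
    bb <- .footprint_bbox(inc$footprint)
    if (bb["xmin"] < 0 || bb["ymin"] < 0 || bb["xmax"] > box_x ||
        bb["ymax"] > box_y)
      stop("inclusion footprint extends outside the box")
  }
  if (length(inclusions) >= 2L) {
    for (i in seq_len(length(inclusions) - 1L))
      for (j in seq(i + 1L, length(inclusions)))
        if (.footprints_overlap(inclusions[[i]]$footprint,
                                inclusions[[j]]$footprint))
          stop(sprintf("inclusion footprints %d and %d overlap", i, j))
  }
  structure(list(box_x = box_x, box_y = box_y,
                 bulk_thickness = bulk_thickness, inclusions = inclusions,
                 roughness_sd = roughness_sd, areal_density = areal_density,
                 seed = as.integer(seed)),
            class = "membrane_spec")
}

#' Analytic thickness field of a membrane spec
#'
#' Evaluates h(x, y) = h0 - sum_i A_i exp(-d_i^2 / (2 sigma_i^2)) with d_i the
#' in-plane distance to the boundary of footprint i (0 inside). This closed
#' form is the ground truth every mapping and segmentation stage is tested
#' against.
#'
#' @param spec A [membrane_spec()].
#' @param x,y Coordinates (nm), vectorized.
#' @return Thickness in nm.
#' @export
analytic_thickness <- function(spec, x, y) {
  stopifnot(inherits(spec, "membrane_spec"))
  h <- rep(spec$bulk_thickness, length(x))
  for (inc in spec$inclusions) {
    d <- footprint_boundary_distance(inc$footprint, x, y)
    h <- h - inc$well_depth * exp(-d^2 / (2 * inc$well_width^2))
  }
  h
}

# Uniform points inside a footprint by rejection from its bounding box.
.sample_in_footprint <- function(fp, n) {
  bb <- .footprint_bbox(fp)
  out <- matrix(numeric(0), ncol = 2L)
  while (nrow(out) < n) {
    m <- max(2L * n, 32L)
    px <- stats::runif(m, bb["xmin"], bb["xmax"])
    py <- stats::runif(m, bb["ymin"], bb["ymax"])
    keep <- footprint_contains(fp, px, py)
    out <- rbind(out, cbind(px[keep], py[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate membrane snapshots from a membrane spec
#'
#' Per frame, lipid phosphorus xy positions are drawn from a spatial Poisson
#' process of the spec's areal density per leaflet, excluding footprint
#' interiors. Leaflet z is +/- h(x, y)/2 plus Gaussian roughness. Protein
#' atoms rasterize each footprint as a static membrane-spanning slab
#' (`protein_density` atoms per nm^3); only occupancy maps consume them.
#'
#' @param spec A [membrane_spec()].
#' @param n_frames Number of frames (>= 1).
#' @param protein_density Rasterization density of protein slabs, atoms/nm^3.
#' @return A `snapshot_set`: list of frames, each with `upper_P`, `lower_P`
#'   and `protein_atoms` coordinate matrices (columns x, y, z in nm) and a
#'   `box` of (Lx, Ly, Lz).
#' @export
gen_membrane_snapshots <- function(spec, n_frames, protein_density = 10) {
  stopifnot(inherits(spec, "membrane_spec"), n_frames >= 1)
  area <- spec$box_x * spec$box_y
  free_area <- area - sum(vapply(spec$inclusions,
                                 function(i) footprint_area(i$footprint), 0))
  if (spec$areal_density * free_area < 10)
    stop("degenerate statistics: expected fewer than 10 lipids per leaflet")

  h0 <- spec$bulk_thickness
  box <- c(spec$box_x, spec$box_y, 2 * h0)
  withr::with_seed(spec$seed, {
    protein <- matrix(numeric(0), ncol = 3L,
                      dimnames = list(NULL, c("x", "y", "z")))
    for (inc in spec$inclusions) {
      n_at <- max(1L, round(protein_density * footprint_area(inc$footprint) * h0))
      xy <- .sample_in_footprint(inc$footprint, n_at)
      protein <- rbind(protein,
                       cbind(x = xy[, 1], y = xy[, 2],
                             z = stats::runif(n_at, -h0 / 2, h0 / 2)))
    }
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      leaf <- lapply(c(upper = 1, lower = -1), function(sgn) {
        n <- stats::rpois(1L, spec$areal_density * area)
        px <- stats::runif(n, 0, spec$box_x)
        py <- stats::runif(n, 0, spec$box_y)
        keep <- rep(TRUE, n)
        for (inc in spec$inclusions)
          keep <- keep & !footprint_contains(inc$footprint, px, py)
        px <- px[keep]; py <- py[keep]
        h <- analytic_thickness(spec, px, py)
        z <- sgn * h / 2
        if (spec$roughness_sd > 0)
          z <- z + stats::rnorm(length(z), sd = spec$roughness_sd)
        cbind(x = px, y = py, z = z)
      })
      frames[[f]] <- list(upper_P = leaf$upper, lower_P = leaf$lower,
                          protein_atoms = protein, box = box)
    }
    structure(list(frames = frames, box = box, n_frames = n_frames,
                   spec = spec),
              class = "snapshot_set")
  })
}

#' @export
print.snapshot_set <- function(x, ...) {
  n_up <- mean(vapply(x$frames, function(f) nrow(f$upper_P), 0))
  cat(sprintf(
    "<snapshot_set: %d frames, box %.2f x %.2f nm, ~%.0f lipids/leaflet, %d protein atoms>\n",
    x$n_frames, x$box[1], x$box[2], n_up, nrow(x$frames[[1]]$protein_atoms)))
  invisible(x)
}
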