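# Thinned-region segmentation and line-tension energetics. Membrane regions
# thinner than h_bulk - delta and not occupied by protein are segmented;
# their boundary is extracted as sub-cell iso-contours of the thickness
# field (marching squares with linear interpolation, via
# grDevices::contourLines) and partitioned into bulk-facing and
# protein-facing components. Treating the thinned region as a disordered
# phase, the free-energy change on complexation is the perimeter change
# times the ordered/disordered line tension.

# Periodic Gaussian smoothing of an nx x ny field via FFT convolution.
.smooth_periodic <- function(m, sigma_cells) {
  if (sigma_cells <= 0) return(m)
  nx <- nrow(m); ny <- ncol(m)
  kx <- stats::dnorm(pmin(0:(nx - 1), nx - (0:(nx - 1))), sd = sigma_cells)
  ky <- stats::dnorm(pmin(0:(ny - 1), ny - (0:(ny - 1))), sd = sigma_cells)
  K <- outer(kx, ky)
  K <- K / sum(K)
  Re(stats::fft(stats::fft(m) * stats::fft(K), inverse = TRUE)) / (nx * ny)
}

# 4-connected component labels (non-periodic) for a logical matrix.
.label_components <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack) > 0L) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- ((p - 1L) %% nx) + 1L
      j <- ((p - 1L) %/% nx) + 1L
      for (q in c(if (i > 1L) p - 1L, if (i < nx) p + 1L,
                  if (j > 1L) p - nx, if (j < ny) p + nx)) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          stack <- c(stack, q)
        }
      }
    }
  }
  lab
}

# Length of edges shared between TRUE cells of a and TRUE cells of b
# (periodic adjacency).
.shared_edge_length <- function(a, b, grid) {
  shift <- function(m, di, dj) {
    nx <- nrow(m); ny <- ncol(m)
    m[((seq_len(nx) - 1L - di) %% nx) + 1L, ((seq_len(ny) - 1L - dj) %% ny) + 1L]
  }
  # x-neighbours share an edge of length dy, y-neighbours of length dx
  sum(a & shift(b, 1L, 0L)) * grid$dy + sum(a & shift(b, -1L, 0L)) * grid$dy +
    sum(a & shift(b, 0L, 1L)) * grid$dx + sum(a & shift(b, 0L, -1L)) * grid$dx
}

.polyline_lengths <- function(x, y) {
  sqrt(diff(x)^2 + diff(y)^2)
}

# Min distance from points to a set of cell centers (periodic).
.min_dist_to_cells <- function(px, py, cx, cy, grid) {
  if (length(cx) == 0L) return(rep(Inf, length(px)))
  dmin <- rep(Inf, length(px))
  for (start in seq(1L, length(cx), by = 2048L)) {
    ii <- start:min(start + 2047L, length(cx))
    dx <- .periodic_delta(outer(px, cx[ii], `-`), grid$box_x)
    dy <- .periodic_delta(outer(py, cy[ii], `-`), grid$box_y)
    dmin <- pmin(dmin, sqrt(apply(dx^2 + dy^2, 1L, min)))
  }
  dmin
}

#' Segment the protein-perturbed (thinned) membrane region
#'
#' Cells whose thickness is at most `h_bulk - delta` and that are not
#' occupied by protein form the perturbed mask. The region boundary is the
#' iso-contour of the thickness field at level `h_bulk - delta`, extracted
#' with sub-cell accuracy; contour segments whose midpoint lies within one
#' cell of an occupied cell are classified protein-facing, as is the
#' occupied-region boundary adjoining the mask. Connected components smaller
#' than `min_cells` cells are discarded as thermal speckle.
#'
#' @param tmap A [thickness_map()].
#' @param omap Optional [occupancy_map()] on the same grid.
#' @param delta Thinning threshold (nm), default 0.15.
#' @param min_cells Minimum component size kept (cells), default 4.
#' @param smooth_sigma Optional periodic Gaussian pre-smoothing of the
#'   thickness field, in cells (0 = none). A sigma of 1-2 cells suppresses
#'   speckle from finite sampling while biasing a smooth Gaussian-well
#'   contour radius negligibly.
#' @return A `perturbed_region` with the mask, contour polylines, and
#'   `perimeter_total`, `perimeter_bulk_facing`, `perimeter_protein_facing`
#'   (nm).
#' @export
segment_perturbed_region <- function(tmap, omap = NULL, delta = 0.15,
                                     min_cells = 4L, smooth_sigma = 0) {
  stopifnot(inherits(tmap, "thickness_map"), delta > 0)
  grid <- tmap$grid
  occupied <- matrix(FALSE, grid$nx, grid$ny)
  if (!is.null(omap)) {
    stopifnot(inherits(omap, "occupancy_map"))
    if (!.grids_match(grid, omap$grid))
      stop("grid mismatch between thickness and occupancy maps")
    occupied <- omap$occupied
  }
  if (all(occupied)) stop("all cells are protein-occupied; nothing to segment")

  field <- .smooth_periodic(tmap$mean_thickness, smooth_sigma)
  level <- tmap$h_bulk - delta
  mask <- (field <= level) & !occupied

  empty <- structure(list(grid = grid, mask = mask, contours = list(),
                          perimeter_total = 0, perimeter_bulk_facing = 0,
                          perimeter_protein_facing = 0, delta = delta,
                          h_bulk = tmap$h_bulk, level = level),
                     class = "perturbed_region")
  if (!any(mask)) return(empty)

  lab <- .label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep_comp <- which(sizes >= min_cells)
  mask <- matrix(lab %in% keep_comp, grid$nx, grid$ny)
  if (!any(mask)) return(empty)

  xc <- .cell_centers_x(grid)
  yc <- .cell_centers_y(grid)
  cell_tol <- 1.5 * max(grid$dx, grid$dy)
  mask_idx <- which(mask, arr.ind = TRUE)
  mx <- xc[mask_idx[, 1]]; my <- yc[mask_idx[, 2]]
  occ_idx <- which(occupied, arr.ind = TRUE)
  ox <- xc[occ_idx[, 1]]; oy <- yc[occ_idx[, 2]]

  cl <- if (min(field) < level && max(field) > level)
    grDevices::contourLines(xc, yc, field, levels = level)
  else list()  # field never crosses the level: no iso-contour exists
  contours <- list()
  p_bulk <- 0
  p_prot <- 0
  for (cc in cl) {
    # attach contour to the retained mask; drop speckle contours
    vmin <- .min_dist_to_cells(cc$x, cc$y, mx, my, grid)
    if (!any(vmin <= cell_tol)) next
    contours[[length(contours) + 1L]] <- cc
    seg_len <- .polyline_lengths(cc$x, cc$y)
    if (length(seg_len) == 0L) next
    midx <- (cc$x[-1] + cc$x[-length(cc$x)]) / 2
    midy <- (cc$y[-1] + cc$y[-length(cc$y)]) / 2
    near_prot <- .min_dist_to_cells(midx, midy, ox, oy, grid) <=
      max(grid$dx, grid$dy)
    p_prot <- p_prot + sum(seg_len[near_prot])
    p_bulk <- p_bulk + sum(seg_len[!near_prot])
  }
  # protein/disordered interface: occupied cells adjoining the mask
  p_prot <- p_prot + .shared_edge_length(occupied, mask, grid)

  structure(list(grid = grid, mask = mask, contours = contours,
                 perimeter_total = p_bulk + p_prot,
                 perimeter_bulk_facing = p_bulk,
                 perimeter_protein_facing = p_prot,
                 delta = delta, h_bulk = tmap$h_bulk, level = level),
            class = "perturbed_region")
}

#' @export
print.perturbed_region <- function(x, ...) {
  cat(sprintf(paste0("<perturbed_region: %d cells, perimeter %.2f nm ",
                     "(bulk-facing %.2f, protein-facing %.2f), delta %.2f nm>\n"),
              sum(x$mask), x$perimeter_total, x$perimeter_bulk_facing,
              x$perimeter_protein_facing, x$delta))
  invisible(x)
}

#' Perimeter of a perturbed region
#'
#' `bulk_only` returns the disordered/bulk interface length (the convention
#' used for an isolated substrate); `with_protein_interface` adds the
#' protein/disordered interface (the convention used for the enzyme, whose
#' thinned annulus wraps the protein).
#'
#' @param region A `perturbed_region`.
#' @param mode `"bulk_only"` or `"with_protein_interface"`.
#' @return Perimeter in nm.
#' @export
region_perimeter <- function(region,
                             mode = c("bulk_only", "with_protein_interface")) {
  stopifnot(inherits(region, "perturbed_region"))
  mode <- match.arg(mode)
  if (mode == "bulk_only") region$perimeter_bulk_facing
  else region$perimeter_total
}

#' Perimeter change on protein complexation
#'
#' Delta p = sum(isolated perimeters) - associated perimeter; positive
#' values mean the thinned boundary shrinks when the proteins associate.
#'
#' @param isolated Numeric vector of perimeters for the isolated proteins (nm).
#' @param associated Perimeter of the associated/complex state (nm).
#' @return Delta p in nm.
#' @export
perimeter_change <- function(isolated, associated) {
  stopifnot(is.numeric(isolated), is.numeric(associated),
            all(isolated >= 0), associated >= 0)
  sum(isolated) - associated
}

#' Line-tension free energy of a perimeter change
#'
#' Treating the thinned region as a disordered phase bordered by the bulk
#' liquid-ordered phase, the mismatch contribution to the binding free
#' energy is -Delta p * gamma, with gamma the ordered/disordered line
#' tension. Experimental gamma spans 1-3 pN, so the result is an interval:
#' [-Delta p * gamma_high, -Delta p * gamma_low] in kcal/mol
#' (1 pN nm = 0.14393 kcal/mol).
#'
#' @param delta_p Perimeter change (nm).
#' @param gamma_low,gamma_high Line-tension bounds (pN), 0 < low <= high.
#' @param precision Decimals the interval is rounded to (default 1, matching
#'   the precision such estimates are conventionally reported at).
#' @return An `energy_interval` with `dg_low`, `dg_high` (kcal/mol).
#' @export
mismatch_free_energy <- function(delta_p, gamma_low = 1, gamma_high = 3,
                                 precision = 1L) {
  stopifnot(is.numeric(delta_p), gamma_low > 0, gamma_low <= gamma_high)
  dg_low <- round(-delta_p * gamma_high * .PN_NM_TO_KCAL, precision)
  dg_high <- round(-delta_p * gamma_low * .PN_NM_TO_KCAL, precision)
  structure(list(dg_low = dg_low, dg_high = dg_high, delta_p = delta_p,
                 gamma_range = c(gamma_low, gamma_high),
                 precision = as.integer(precision)),
            class = "energy_interval")
}

#' @export
print.energy_interval <- function(x, ...) {
  cat(sprintf(
    "<energy_interval: Delta p = %.2f nm, gamma %g-%g pN -> [%.*f, %.*f] kcal/mol>\n",
    x$delta_p, x$gamma_range[1], x$gamma_range[2],
    x$precision, x$dg_low, x$precision, x$dg_high))
  invisible(x)
}
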