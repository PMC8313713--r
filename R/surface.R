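# Gridded leaflet surfaces, 2D thickness maps, protein occupancy maps and
# local thickness distributions. Phosphorus z positions of each leaflet are
# averaged per periodic grid cell over lipids and frames; thickness is the
# distance between the upper and lower surface grids.

# Accumulate per-cell sums and counts of z for one coordinate set.
.accumulate_cells <- function(grid, sums, counts, pts) {
  if (nrow(pts) == 0L) return(list(sums = sums, counts = counts))
  lin <- .cell_lin(grid, pts[, 1], pts[, 2])
  counts <- counts + tabulate(lin, nbins = grid$nx * grid$ny)
  s <- rowsum(pts[, 3], lin)
  idx <- as.integer(rownames(s))
  sums[idx] <- sums[idx] + s[, 1]
  list(sums = sums, counts = counts)
}

# Inverse-distance interpolation of empty cells from the k nearest observed
# cells (periodic metric). Chunked to bound memory.
.fill_empty_cells <- function(grid, mean_v, counts, k = 8L) {
  obs <- which(counts > 0L)
  emp <- which(counts == 0L)
  if (length(emp) == 0L) return(mean_v)
  xc <- .cell_centers_x(grid)
  yc <- .cell_centers_y(grid)
  cell_x <- xc[((seq_len(grid$nx * grid$ny) - 1L) %% grid$nx) + 1L]
  cell_y <- yc[((seq_len(grid$nx * grid$ny) - 1L) %/% grid$nx) + 1L]
  ox <- cell_x[obs]; oy <- cell_y[obs]; oz <- mean_v[obs]
  k <- min(k, length(obs))
  for (start in seq(1L, length(emp), by = 512L)) {
    ii <- emp[start:min(start + 511L, length(emp))]
    dxm <- .periodic_delta(outer(cell_x[ii], ox, `-`), grid$box_x)
    dym <- .periodic_delta(outer(cell_y[ii], oy, `-`), grid$box_y)
    d2 <- dxm^2 + dym^2
    mean_v[ii] <- vapply(seq_along(ii), function(r) {
      nn <- order(d2[r, ])[seq_len(k)]
      w <- 1 / pmax(d2[r, nn], 1e-12)
      sum(w * oz[nn]) / sum(w)
    }, 0)
  }
  mean_v
}

#' Map leaflet phosphorus surfaces onto a periodic grid
#'
#' Per cell, the time-and-lipid average z of the phosphorus atoms assigned to
#' that cell (periodic wrapping). Cells never visited by a phosphorus are
#' filled by inverse-distance interpolation from the k = 8 nearest observed
#' cells and flagged as interpolated.
#'
#' @param snapshots A `snapshot_set`.
#' @param grid A [grid_spec()].
#' @param k_interp Number of neighbours used to fill empty cells.
#' @return A list with `upper` and `lower` surface fields; each carries
#'   `mean` (nx x ny matrix, nm), `n_obs`, and an `interpolated` flag matrix.
#' @export
map_leaflet_surfaces <- function(snapshots, grid, k_interp = 8L) {
  stopifnot(inherits(snapshots, "snapshot_set"), inherits(grid, "grid_spec"))
  if (length(snapshots$frames) < 1L) stop("need at least one frame")
  nb <- grid$nx * grid$ny
  out <- lapply(c(upper = "upper_P", lower = "lower_P"), function(fld) {
    sums <- numeric(nb); counts <- integer(nb)
    for (fr in snapshots$frames) {
      acc <- .accumulate_cells(grid, sums, counts, fr[[fld]])
      sums <- acc$sums; counts <- acc$counts
    }
    if (sum(counts) == 0L)
      stop(sprintf("leaflet '%s' contains no phosphorus atoms in any frame",
                   sub("_P", "", fld)))
    mean_v <- ifelse(counts > 0L, sums / pmax(counts, 1L), NA_real_)
    mean_v <- .fill_empty_cells(grid, mean_v, counts, k_interp)
    structure(list(grid = grid,
                   mean = matrix(mean_v, grid$nx, grid$ny),
                   n_obs = matrix(counts, grid$nx, grid$ny),
                   interpolated = matrix(counts == 0L, grid$nx, grid$ny)),
              class = "surface_field")
  })
  out
}

#' Build a 2D membrane thickness map from leaflet surfaces
#'
#' Per-cell thickness is the upper-surface z minus the lower-surface z; the
#' map carries the bulk reference thickness used downstream for thresholding.
#'
#' @param upper,lower `surface_field` objects on the same grid.
#' @param h_bulk Bulk reference thickness (nm), default 4.76.
#' @return A `thickness_map` with `mean_thickness` (nx x ny, nm), `n_obs`,
#'   `interpolated` flags and `h_bulk`.
#' @export
thickness_map <- function(upper, lower, h_bulk = 4.76) {
  stopifnot(inherits(upper, "surface_field"), inherits(lower, "surface_field"))
  if (!.grids_match(upper$grid, lower$grid))
    stop("grid mismatch between leaflet surfaces")
  th <- upper$mean - lower$mean
  if (any(th <= 0))
    stop("leaflet inversion: upper surface below lower surface somewhere")
  structure(list(grid = upper$grid, mean_thickness = th,
                 n_obs = pmin(upper$n_obs, lower$n_obs),
                 interpolated = upper$interpolated | lower$interpolated,
                 h_bulk = h_bulk),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map: %d x %d, mean %.3f nm (bulk ref %.2f nm), %d interpolated cells>\n",
              x$grid$nx, x$grid$ny, mean(x$mean_thickness), x$h_bulk,
              sum(x$interpolated)))
  invisible(x)
}

#' Protein occupancy map
#'
#' Per cell, the fraction of frames in which at least one protein atom
#' (optionally restricted to a z range) falls in the cell; a cell is
#' "occupied" when that fraction reaches `threshold`.
#'
#' @param snapshots A `snapshot_set`.
#' @param grid A [grid_spec()].
#' @param z_range Optional (zmin, zmax) in nm restricting which atoms count.
#' @param threshold Occupied-cell threshold on the fraction, default 0.5.
#' @return An `occupancy_map` with `fraction` and logical `occupied` matrices.
#' @export
occupancy_map <- function(snapshots, grid, z_range = NULL, threshold = 0.5) {
  stopifnot(inherits(snapshots, "snapshot_set"), inherits(grid, "grid_spec"))
  nb <- grid$nx * grid$ny
  hit <- integer(nb)
  any_protein <- FALSE
  for (fr in snapshots$frames) {
    at <- fr$protein_atoms
    if (!is.null(z_range) && nrow(at) > 0L)
      at <- at[at[, 3] >= z_range[1] & at[, 3] <= z_range[2], , drop = FALSE]
    if (nrow(at) == 0L) next
    any_protein <- TRUE
    lin <- unique(.cell_lin(grid, at[, 1], at[, 2]))
    hit[lin] <- hit[lin] + 1L
  }
  if (!any_protein)
    warning("no protein atoms in any frame; occupancy map is all zero")
  frac <- hit / length(snapshots$frames)
  structure(list(grid = grid,
                 fraction = matrix(frac, grid$nx, grid$ny),
                 occupied = matrix(frac >= threshold, grid$nx, grid$ny),
                 threshold = threshold),
            class = "occupancy_map")
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat(sprintf("<occupancy_map: %d x %d, %d occupied cells (threshold %.2f)>\n",
              x$grid$nx, x$grid$ny, sum(x$occupied), x$threshold))
  invisible(x)
}

#' Local distribution of membrane thickness near a reference point
#'
#' Collects per-frame, per-cell thickness values for unoccupied cells whose
#' center lies within `cutoff` (in-plane, periodic) of the reference point,
#' and returns the normalized distribution. This is the local-thickness
#' probability view of the membrane near a binding site.
#'
#' @param snapshots A `snapshot_set`.
#' @param grid A [grid_spec()].
#' @param reference_xy Numeric length 2 (nm).
#' @param cutoff Selection radius (nm); must exceed one cell diagonal.
#' @param breaks Histogram breaks passed to [hist()].
#' @return A `thickness_distribution` with raw `values`, the normalized
#'   histogram (`mids`, `density`), and the sample `mean`.
#' @export
local_thickness_distribution <- function(snapshots, grid, reference_xy,
                                         cutoff, breaks = 50) {
  stopifnot(inherits(snapshots, "snapshot_set"), inherits(grid, "grid_spec"),
            cutoff > 0)
  diag_len <- sqrt(grid$dx^2 + grid$dy^2)
  if (cutoff < diag_len)
    stop("cutoff smaller than one cell diagonal: degenerate selection")
  occ <- suppressWarnings(occupancy_map(snapshots, grid))
  sel <- .center_distance(grid, reference_xy) <= cutoff & !occ$occupied
  if (!any(sel)) stop("no unoccupied cells within cutoff of the reference")
  sel_lin <- which(as.vector(sel))
  nb <- grid$nx * grid$ny
  vals <- vector("list", length(snapshots$frames))
  for (f in seq_along(snapshots$frames)) {
    fr <- snapshots$frames[[f]]
    up <- .accumulate_cells(grid, numeric(nb), integer(nb), fr$upper_P)
    lo <- .accumulate_cells(grid, numeric(nb), integer(nb), fr$lower_P)
    ok <- sel_lin[up$counts[sel_lin] > 0L & lo$counts[sel_lin] > 0L]
    vals[[f]] <- up$sums[ok] / up$counts[ok] - lo$sums[ok] / lo$counts[ok]
  }
  values <- unlist(vals)
  if (length(values) == 0L)
    stop("no thickness observations in the selected cells")
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  structure(list(values = values, mids = h$mids, density = h$density,
                 mean = mean(values), cutoff = cutoff,
                 reference_xy = reference_xy),
            class = "thickness_distribution")
}

#' @export
print.thickness_distribution <- function(x, ...) {
  cat(sprintf("<thickness_distribution: %d observations, mean %.3f nm, cutoff %.2f nm>\n",
              length(x$values), x$mean, x$cutoff))
  invisible(x)
}
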