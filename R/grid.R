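# Periodic 2D analysis grid over the membrane plane. Cells are half-open in
# each axis with centers at ((i - 1/2) Lx/nx, (j - 1/2) Ly/ny); coordinates
# wrap periodically, so the grid is translation-invariant modulo the box.

#' Define a periodic analysis grid over the membrane plane
#'
#' @param nx,ny Number of cells per axis (>= 8). The reference maps use
#'   500 x 500; synthetic tests use coarser grids.
#' @param box_x,box_y Box dimensions (nm).
#' @return A `grid_spec`.
#' @export
grid_spec <- function(nx, ny, box_x, box_y) {
  stopifnot(nx >= 8, ny >= 8, box_x > 0, box_y > 0)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 box_x = box_x, box_y = box_y,
                 dx = box_x / nx, dy = box_y / ny),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec: %d x %d cells over %.2f x %.2f nm (cell %.3g x %.3g nm)>\n",
              x$nx, x$ny, x$box_x, x$box_y, x$dx, x$dy))
  invisible(x)
}

.grids_match <- function(a, b) {
  a$nx == b$nx && a$ny == b$ny &&
    isTRUE(all.equal(c(a$box_x, a$box_y), c(b$box_x, b$box_y)))
}

# Periodic cell assignment: i = floor(x nx / Lx) mod nx, 1-based.
# Computed so that translating by a whole box length maps to the same cell.
.cell_ij <- function(grid, x, y) {
  i <- as.integer(floor(x * grid$nx / grid$box_x)) %% grid$nx
  j <- as.integer(floor(y * grid$ny / grid$box_y)) %% grid$ny
  list(i = i + 1L, j = j + 1L)
}

.cell_lin <- function(grid, x, y) {
  ij <- .cell_ij(grid, x, y)
  (ij$j - 1L) * grid$nx + ij$i
}

.cell_centers_x <- function(grid) (seq_len(grid$nx) - 0.5) * grid$dx
.cell_centers_y <- function(grid) (seq_len(grid$ny) - 0.5) * grid$dy

# Minimum-image periodic distance between scalars/vectors.
.periodic_delta <- function(d, L) {
  d <- abs(d) %% L
  pmin(d, L - d)
}

# Periodic in-plane distance from all cell centers to a reference point;
# returns an nx x ny matrix.
.center_distance <- function(grid, ref_xy) {
  dx <- .periodic_delta(.cell_centers_x(grid) - ref_xy[1], grid$box_x)
  dy <- .periodic_delta(.cell_centers_y(grid) - ref_xy[2], grid$box_y)
  sqrt(outer(dx^2, dy^2, `+`))
}
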