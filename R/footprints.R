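# Inclusion footprints: in-plane cross-sections of membrane-embedded proteins.
# Disks are kept analytic; polygons and horseshoes share the polygon machinery.
# All lengths in nm.

#' Disk-shaped inclusion footprint
#'
#' @param center Numeric length 2, footprint center (nm).
#' @param radius Disk radius (nm), > 0.
#' @return A `footprint` object.
#' @export
footprint_disk <- function(center, radius) {
  stopifnot(is.numeric(center), length(center) == 2L,
            is.numeric(radius), length(radius) == 1L, radius > 0)
  structure(list(shape = "disk", center = as.numeric(center),
                 radius = as.numeric(radius)),
            class = "footprint")
}

#' Polygonal inclusion footprint
#'
#' @param vertices Two-column matrix of polygon vertices (nm), in order,
#'   without a repeated closing vertex.
#' @return A `footprint` object.
#' @export
footprint_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(is.numeric(vertices), ncol(vertices) == 2L, nrow(vertices) >= 3L)
  if (abs(.shoelace_area(vertices[, 1], vertices[, 2])) <= 0)
    stop("footprint area must be > 0")
  structure(list(shape = "polygon", vertices = vertices), class = "footprint")
}

#' Horseshoe-shaped inclusion footprint
#'
#' An annular sector with an angular opening, mimicking the horseshoe-shaped
#' transmembrane cross-section of a multi-subunit membrane protein.
#'
#' @param center Numeric length 2 (nm).
#' @param outer_r,inner_r Outer and inner radii (nm), `outer_r > inner_r > 0`.
#' @param opening_angle Angular width of the opening in radians, in (0, 2*pi).
#' @param orientation Direction of the opening (radians, default 0).
#' @param n_arc Number of points used to discretize each arc.
#' @return A `footprint` object (polygonal representation).
#' @export
footprint_horseshoe <- function(center, outer_r, inner_r, opening_angle,
                                orientation = 0, n_arc = 64L) {
  stopifnot(is.numeric(center), length(center) == 2L,
            outer_r > inner_r, inner_r > 0,
            opening_angle > 0, opening_angle < 2 * pi)
  a0 <- orientation + opening_angle / 2
  a1 <- orientation + 2 * pi - opening_angle / 2
  ang <- seq(a0, a1, length.out = n_arc)
  outer <- cbind(center[1] + outer_r * cos(ang), center[2] + outer_r * sin(ang))
  inner <- cbind(center[1] + inner_r * cos(rev(ang)),
                 center[2] + inner_r * sin(rev(ang)))
  fp <- footprint_polygon(rbind(outer, inner))
  fp$shape <- "horseshoe"
  fp$center <- as.numeric(center)
  fp
}

.shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  0.5 * sum(x[j] * y - x * y[j])
}

#' Footprint area
#' @param fp A `footprint`.
#' @return Area in nm^2.
#' @export
footprint_area <- function(fp) {
  stopifnot(inherits(fp, "footprint"))
  if (fp$shape == "disk") return(pi * fp$radius^2)
  abs(.shoelace_area(fp$vertices[, 1], fp$vertices[, 2]))
}

# Even-odd crossing test, vectorized over query points.
.in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    denom <- vy[j] - vy[i]
    if (denom != 0) {
      crosses <- ((vy[i] > py) != (vy[j] > py)) &
        (px < (vx[j] - vx[i]) * (py - vy[i]) / denom + vx[i])
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside
}

# Distance from points to a polyline segment set; vectorized over points.
.dist_to_segments <- function(px, py, vx, vy, closed = TRUE) {
  n <- length(vx)
  idx <- if (closed) c(seq_len(n), 1L) else seq_len(n)
  dmin <- rep(Inf, length(px))
  for (s in seq_len(length(idx) - 1L)) {
    x1 <- vx[idx[s]]; y1 <- vy[idx[s]]
    x2 <- vx[idx[s + 1L]]; y2 <- vy[idx[s + 1L]]
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    t <- if (L2 > 0) pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2)) else 0
    dd <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    dmin <- pmin(dmin, dd)
  }
  sqrt(dmin)
}

#' Test whether points lie inside a footprint
#' @param fp A `footprint`.
#' @param x,y Point coordinates (nm), vectorized.
#' @return Logical vector.
#' @export
footprint_contains <- function(fp, x, y) {
  stopifnot(inherits(fp, "footprint"))
  if (fp$shape == "disk") {
    (x - fp$center[1])^2 + (y - fp$center[2])^2 <= fp$radius^2
  } else {
    .in_polygon(x, y, fp$vertices[, 1], fp$vertices[, 2])
  }
}

#' In-plane distance from points to the footprint boundary
#'
#' Zero for points inside the footprint; this is the distance entering the
#' Gaussian thinning well of the synthetic membrane model.
#'
#' @param fp A `footprint`.
#' @param x,y Point coordinates (nm), vectorized.
#' @return Distances in nm (0 inside the footprint).
#' @export
footprint_boundary_distance <- function(fp, x, y) {
  stopifnot(inherits(fp, "footprint"))
  if (fp$shape == "disk") {
    d <- sqrt((x - fp$center[1])^2 + (y - fp$center[2])^2) - fp$radius
    return(pmax(0, d))
  }
  d <- .dist_to_segments(x, y, fp$vertices[, 1], fp$vertices[, 2])
  d[footprint_contains(fp, x, y)] <- 0
  d
}

# Points on the footprint boundary, for overlap/containment checks.
.footprint_boundary_points <- function(fp, n = 128L) {
  if (fp$shape == "disk") {
    a <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    cbind(fp$center[1] + fp$radius * cos(a), fp$center[2] + fp$radius * sin(a))
  } else {
    fp$vertices
  }
}

.footprint_bbox <- function(fp) {
  p <- .footprint_boundary_points(fp)
  c(xmin = min(p[, 1]), xmax = max(p[, 1]),
    ymin = min(p[, 2]), ymax = max(p[, 2]))
}

# TRUE if two footprints overlap (boundary of one inside the other).
.footprints_overlap <- function(a, b) {
  pa <- .footprint_boundary_points(a)
  pb <- .footprint_boundary_points(b)
  any(footprint_contains(b, pa[, 1], pa[, 2])) ||
    any(footprint_contains(a, pb[, 1], pb[, 2]))
}

#' @export
print.footprint <- function(x, ...) {
  cat(sprintf("<footprint: %s, area %.3f nm^2>\n", x$shape, footprint_area(x)))
  invisible(x)
}
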