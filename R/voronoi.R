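# Periodic 2-D Voronoi tessellation by half-plane clipping.
#
# Each generator's cell starts as a large square and is clipped by the
# perpendicular bisector against every other generator, including the 8
# periodic ghost replicas of all generators (and of the point itself).
# The cells of the central replica then tile the box exactly, so their
# areas sum to box_x * box_y — asserted by area_per_lipid().

# Sutherland-Hodgman clip of polygon (matrix nx2) against half-plane
# dot(p - m, d) <= 0.
clip_halfplane <- function(poly, m, d) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  s <- as.numeric((poly[, 1] - m[1]) * d[1] + (poly[, 2] - m[2]) * d[2])
  keep <- s <= 0
  if (all(keep)) return(poly)
  if (!any(keep)) return(poly[0, , drop = FALSE])
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (keep[i]) out <- rbind(out, poly[i, ])
    if (keep[i] != keep[j]) {
      t <- s[i] / (s[i] - s[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Periodic Voronoi cell areas in two dimensions
#'
#' Computes the Voronoi cell area of each generator point under periodic
#' boundary conditions in a `box_x` x `box_y` box, by clipping each cell
#' against the bisectors of all generators and their 8 periodic replicas.
#' The areas of the cells of the central replica tile the box, so they sum
#' to the box area (up to floating-point rounding). Coincident generators
#' are perturbed by 1e-6 with a warning.
#'
#' @param xy n x 2 matrix of generator positions (same length unit as box).
#' @param box_x,box_y Box lengths (positive).
#' @return Numeric vector of per-generator cell areas.
#' @export
periodic_voronoi_areas <- function(xy, box_x, box_y) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, box_x > 0, box_y > 0)
  n <- nrow(xy)
  if (n < 3) stop("need at least 3 generators")
  # wrap into the box
  xy[, 1] <- xy[, 1] %% box_x
  xy[, 2] <- xy[, 2] %% box_y
  if (anyDuplicated(round(xy, 9))) {
    warning("coincident generator positions perturbed by 1e-6")
    dup <- duplicated(round(xy, 9))
    xy[dup, ] <- xy[dup, ] + matrix(runif(2 * sum(dup), -1e-6, 1e-6),
                                    ncol = 2)
  }
  shifts <- as.matrix(expand.grid(sx = c(-1, 0, 1), sy = c(-1, 0, 1)))
  ghosts <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(k) {
    cbind(xy[, 1] + shifts[k, 1] * box_x, xy[, 2] + shifts[k, 2] * box_y)
  }))
  # index of the central replica of point i within ghosts: (4)*n + i
  central_offset <- which(shifts[, 1] == 0 & shifts[, 2] == 0)
  L <- max(box_x, box_y)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    p <- xy[i, ]
    poly <- cbind(p[1] + c(-L, L, L, -L) * 1.5, p[2] + c(-L, -L, L, L) * 1.5)
    dx <- ghosts[, 1] - p[1]; dy <- ghosts[, 2] - p[2]
    d2 <- dx^2 + dy^2
    self <- (central_offset - 1L) * n + i
    ord <- order(d2)
    ord <- ord[ord != self & d2[ord] > 0]
    # clip nearest-first; stop once remaining bisectors cannot cut the cell
    maxr2 <- max((poly[, 1] - p[1])^2 + (poly[, 2] - p[2])^2)
    for (j in ord) {
      if (d2[j] > 4 * maxr2) break
      m <- c(p[1] + dx[j] / 2, p[2] + dy[j] / 2)
      poly <- clip_halfplane(poly, m, c(dx[j], dy[j]))
      if (nrow(poly) < 3) break
      maxr2 <- max((poly[, 1] - p[1])^2 + (poly[, 2] - p[2])^2)
    }
    areas[i] <- polygon_area(poly)
  }
  areas
}
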