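# Planar geometry primitives used by the gridding and Thiessen modules.
# Polygons are closed rings given as two-column matrices (x, y); the closing
# vertex may be present or absent. A "polygon set" is a list of rings.

ring_matrix <- function(ring) {
  m <- as.matrix(ring)
  storage.mode(m) <- "double"
  if (nrow(m) >= 2 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

#' Signed and absolute polygon area (shoelace formula)
#'
#' @param ring two-column matrix of vertices (closing vertex optional).
#' @return Signed area in the square of the coordinate unit; positive for
#'   counter-clockwise rings.
#' @keywords internal
ring_area_signed <- function(ring) {
  m <- ring_matrix(ring)
  n <- nrow(m)
  if (n < 3) return(0)
  x <- m[, 1]; y <- m[, 2]
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

polygon_area <- function(rings) {
  if (is.matrix(rings) || is.data.frame(rings)) rings <- list(rings)
  sum(vapply(rings, function(r) abs(ring_area_signed(r)), 0))
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' Vectorized over points. A list of rings is treated with the even-odd
#' rule, so holes cancel.
#'
#' @param px,py point coordinates.
#' @param rings a ring matrix or list of ring matrices.
#' @return logical vector.
#' @keywords internal
point_in_polygon <- function(px, py, rings) {
  if (is.matrix(rings) || is.data.frame(rings)) rings <- list(rings)
  inside <- rep(FALSE, length(px))
  for (r in rings) {
    m <- ring_matrix(r)
    n <- nrow(m)
    if (n < 3) next
    xs <- m[, 1]; ys <- m[, 2]
    xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
    for (k in seq_len(n)) {
      crosses <- ((ys[k] > py) != (ye[k] > py))
      if (any(crosses)) {
        xint <- xs[k] + (py[crosses] - ys[k]) / (ye[k] - ys[k]) * (xe[k] - xs[k])
        idx <- which(crosses)[px[crosses] < xint]
        inside[idx] <- !inside[idx]
      }
    }
  }
  inside
}

# Clip a (possibly concave) subject ring against a single half-plane
# {p : dot(p - a, nrm) <= 0}. Sutherland-Hodgman step.
clip_ring_halfplane <- function(ring, a, nrm) {
  m <- ring_matrix(ring)
  n <- nrow(m)
  if (n == 0) return(m)
  d <- (m[, 1] - a[1]) * nrm[1] + (m[, 2] - a[2]) * nrm[2]
  if (all(d <= 0)) return(m)
  if (all(d > 0)) return(m[0, , drop = FALSE])
  out <- matrix(0, n * 2, 2)
  cnt <- 0L
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    dk <- d[k]; dk2 <- d[k2]
    if (dk <= 0) {
      cnt <- cnt + 1L; out[cnt, ] <- m[k, ]
      if (dk2 > 0) {
        t <- dk / (dk - dk2)
        cnt <- cnt + 1L; out[cnt, ] <- m[k, ] + t * (m[k2, ] - m[k, ])
      }
    } else if (dk2 <= 0) {
      t <- dk / (dk - dk2)
      cnt <- cnt + 1L; out[cnt, ] <- m[k, ] + t * (m[k2, ] - m[k, ])
    }
  }
  out[seq_len(cnt), , drop = FALSE]
}

#' Clip a polygon against a convex clip polygon (Sutherland-Hodgman)
#'
#' The clip polygon must be convex; the subject may be concave (the result
#' can then contain degenerate connecting edges, which do not affect area).
#'
#' @param subject ring matrix.
#' @param clip convex ring matrix, any orientation.
#' @return ring matrix of the intersection (possibly empty).
#' @keywords internal
clip_polygon_convex <- function(subject, clip) {
  cm <- ring_matrix(clip)
  if (ring_area_signed(cm) < 0) cm <- cm[rev(seq_len(nrow(cm))), , drop = FALSE]
  out <- ring_matrix(subject)
  n <- nrow(cm)
  for (k in seq_len(n)) {
    if (nrow(out) == 0) break
    a <- cm[k, ]
    b <- cm[if (k == n) 1L else k + 1L, ]
    e <- b - a
    nrm <- c(e[2], -e[1])  # outward normal of a CCW edge
    out <- clip_ring_halfplane(out, a, nrm)
  }
  out
}

# Length of the part of segment (x1,y1)-(x2,y2) inside the axis-aligned
# rectangle [xmin,xmax] x [ymin,ymax] (Liang-Barsky).
segment_length_in_rect <- function(x1, y1, x2, y2, xmin, xmax, ymin, ymax) {
  dx <- x2 - x1; dy <- y2 - y1
  t0 <- 0; t1 <- 1
  p <- c(-dx, dx, -dy, dy)
  q <- c(x1 - xmin, xmax - x1, y1 - ymin, ymax - y1)
  for (k in 1:4) {
    if (p[k] == 0) {
      if (q[k] < 0) return(0)
    } else {
      r <- q[k] / p[k]
      if (p[k] < 0) t0 <- max(t0, r) else t1 <- min(t1, r)
    }
  }
  if (t0 > t1) return(0)
  (t1 - t0) * sqrt(dx^2 + dy^2)
}

#' Lambert azimuthal equal-area projection
#'
#' Projects lon/lat (degrees) to planar km so that areas are preserved.
#' Used to make Thiessen polygon areas meaningful in km^2.
#'
#' @param lon,lat coordinates in degrees.
#' @param lon0,lat0 projection center in degrees.
#' @param R sphere radius in km.
#' @return two-column matrix (x, y) in km.
#' @export
laea_project <- function(lon, lat, lon0, lat0, R = 6371) {
  to <- pi / 180
  lam <- lon * to; phi <- lat * to
  lam0 <- lon0 * to; phi0 <- lat0 * to
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  k <- sqrt(2 / denom)
  cbind(x = R * k * cos(phi) * sin(lam - lam0),
        y = R * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0)))
}

#' Bounded Voronoi (Thiessen) diagram by half-plane intersection
#'
#' Each cell is built by clipping a bounding box by the perpendicular
#' bisector against every other generator. O(n^2), adequate for the
#' sampled-cell counts this package handles.
#'
#' @param pts two-column matrix of generator coordinates.
#' @param bbox c(xmin, xmax, ymin, ymax) enclosing all generators.
#' @return list of convex ring matrices, one per generator.
#' @keywords internal
voronoi_polygons <- function(pts, bbox) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  base <- cbind(c(bbox[1], bbox[2], bbox[2], bbox[1]),
                c(bbox[3], bbox[3], bbox[4], bbox[4]))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cell <- base
    pi_ <- pts[i, ]
    d2 <- (pts[, 1] - pi_[1])^2 + (pts[, 2] - pi_[2])^2
    for (j in order(d2)) {
      if (j == i || nrow(cell) == 0) next
      if (identical(all.equal(d2[j], 0), TRUE)) next  # coincident generator
      mid <- (pi_ + pts[j, ]) / 2
      nrm <- pts[j, ] - pi_  # keep the side nearer to generator i
      cell <- clip_ring_halfplane(cell, mid, nrm)
    }
    out[[i]] <- cell
  }
  out
}
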