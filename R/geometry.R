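# Planar geometry engine. Regions are lists of rings; a ring is
# list(x=, y=) of vertex coordinates (unclosed). Boolean operations are
# delegated to polyclip (Clipper) with nonzero fill, so a region may carry
# holes as opposite-orientation rings; areas are signed-sum shoelace.
# All projected coordinates in this package are kilometres.

#' Construct a polygon ring
#'
#' Builds a single ring (simple polygon boundary) from vertex coordinates,
#' dropping a repeated closing vertex and normalizing orientation to
#' counter-clockwise.
#'
#' @param x,y numeric vertex coordinates (at least 3 distinct vertices).
#' @return a ring: `list(x =, y =)`.
#' @export
ring <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) > 1 && x[1] == x[length(x)] && y[1] == y[length(y)]) {
    x <- x[-length(x)]
    y <- y[-length(y)]
  }
  if (length(x) < 3) stop("a ring needs at least 3 vertices")
  if (anyNA(x) || anyNA(y)) stop("ring coordinates contain NA")
  r <- list(x = as.numeric(x), y = as.numeric(y))
  if (ring_signed_area(r) < 0) r <- list(x = rev(r$x), y = rev(r$y))
  r
}

#' @rdname ring
#' @param xmin,ymin,xmax,ymax rectangle bounds.
#' @export
rect_ring <- function(xmin, ymin, xmax, ymax) {
  ring(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

#' @rdname ring
#' @param cx,cy ellipse centre.
#' @param a,b semi-axes.
#' @param theta rotation angle (radians).
#' @param n number of vertices used to discretize the ellipse.
#' @export
ellipse_ring <- function(cx, cy, a, b, theta = 0, n = 96) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x0 <- a * cos(t)
  y0 <- b * sin(t)
  ring(cx + x0 * cos(theta) - y0 * sin(theta),
       cy + x0 * sin(theta) + y0 * cos(theta))
}

# signed shoelace area of one ring (positive = counter-clockwise)
ring_signed_area <- function(r) {
  x <- r$x; y <- r$y
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

#' Coerce to a region (list of rings)
#'
#' @param g a ring, a region (list of rings), or NULL (empty region).
#' @return list of rings (possibly empty).
#' @export
as_region <- function(g) {
  if (is.null(g) || length(g) == 0) return(list())
  if (!is.null(g$x)) return(list(g))
  stopifnot(all(vapply(g, function(r) !is.null(r$x) && !is.null(r$y), TRUE)))
  g
}

#' Region boolean operations
#'
#' Thin wrappers around Clipper (via polyclip) with nonzero fill on both
#' operands. `region_union(a)` dissolves a single collection of possibly
#' overlapping rings; contained rings disappear into their containers, so the
#' result matches the mapping convention that nested polygons are dissolved.
#'
#' @param a,b regions (lists of rings) or single rings.
#' @return a dissolved region; rings carry Clipper's consistent orientation
#'   (holes opposite to shells), so [region_area()] of the result is the net
#'   covered area.
#' @export
region_union <- function(a, b = NULL) {
  a <- as_region(a)
  b <- as_region(b)
  if (length(b) == 0) {
    if (length(a) == 0) return(list())
    b <- a[1]
  }
  polyclip::polyclip(a, b, op = "union", fillA = "nonzero", fillB = "nonzero")
}

#' @rdname region_union
#' @export
region_intersect <- function(a, b) {
  a <- as_region(a); b <- as_region(b)
  if (length(a) == 0 || length(b) == 0) return(list())
  polyclip::polyclip(a, b, op = "intersection",
                     fillA = "nonzero", fillB = "nonzero")
}

#' @rdname region_union
#' @export
region_diff <- function(a, b) {
  a <- as_region(a); b <- as_region(b)
  if (length(a) == 0) return(list())
  if (length(b) == 0) return(a)
  polyclip::polyclip(a, b, op = "minus", fillA = "nonzero", fillB = "nonzero")
}

#' Net area of a region
#'
#' Signed-sum shoelace over rings. Correct for dissolved regions (as returned
#' by the boolean wrappers), where holes carry opposite orientation; raw
#' overlapping collections must be passed through [region_union()] first.
#'
#' @param region a region.
#' @return nonnegative area in squared coordinate units (km^2 here).
#' @export
region_area <- function(region) {
  region <- as_region(region)
  if (length(region) == 0) return(0)
  abs(sum(vapply(region, ring_signed_area, 0)))
}

#' Bounding box of a region
#' @param region a region.
#' @return named vector xmin, ymin, xmax, ymax.
#' @export
region_bbox <- function(region) {
  region <- as_region(region)
  if (length(region) == 0) stop("empty region has no bounding box")
  xs <- unlist(lapply(region, `[[`, "x"))
  ys <- unlist(lapply(region, `[[`, "y"))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

#' Point-in-region test (closed region)
#'
#' Even-odd parity across rings, so holes in dissolved regions are handled;
#' points on any ring boundary count as inside (closed-region convention).
#' For this parity rule to be meaningful the region must be dissolved
#' (non-crossing rings), which all regions produced by this package are.
#'
#' @param x,y point coordinates (vectorized).
#' @param region a region.
#' @param tol points within this distance of a ring boundary also count as
#'   inside (useful because Clipper quantizes coordinates at about 1e-9 of
#'   their magnitude, which can push a boundary point marginally outside).
#' @return logical vector.
#' @export
point_in_region <- function(x, y, region, tol = 0) {
  region <- as_region(region)
  n <- length(x)
  if (length(region) == 0) return(rep(FALSE, n))
  parity <- integer(n)
  boundary <- rep(FALSE, n)
  for (r in region) {
    code <- sp::point.in.polygon(x, y, r$x, r$y)
    parity <- parity + (code == 1L)
    boundary <- boundary | code >= 2L
  }
  inside <- boundary | (parity %% 2L == 1L)
  if (tol > 0 && any(!inside)) {
    for (i in which(!inside)) {
      inside[i] <- nearest_point_on_boundary(c(x[i], y[i]), region)$dist <= tol
    }
  }
  inside
}

# --- nearest-point utilities ------------------------------------------------

# nearest point on segment set; X1, X2 are n x 2 matrices of endpoints
nearest_point_on_segments <- function(p, X1, X2) {
  d <- X2 - X1
  len2 <- rowSums(d^2)
  w <- cbind(p[1] - X1[, 1], p[2] - X1[, 2])
  t <- ifelse(len2 > 0, (w[, 1] * d[, 1] + w[, 2] * d[, 2]) / len2, 0)
  t <- pmin(pmax(t, 0), 1)
  px <- X1[, 1] + t * d[, 1]
  py <- X1[, 2] + t * d[, 2]
  dist2 <- (p[1] - px)^2 + (p[2] - py)^2
  i <- which.min(dist2)
  list(point = c(px[i], py[i]), dist = sqrt(dist2[i]), segment = i)
}

ring_edge_matrices <- function(r) {
  X1 <- cbind(r$x, r$y)
  X2 <- X1[c(2:nrow(X1), 1), , drop = FALSE]
  list(X1 = X1, X2 = X2)
}

#' Nearest point on a region's boundary
#'
#' @param p length-2 numeric point.
#' @param region a region (all ring boundaries are searched).
#' @return list with `point`, `dist` and `ring` index.
#' @export
nearest_point_on_boundary <- function(p, region) {
  region <- as_region(region)
  if (length(region) == 0) stop("empty region has no boundary")
  best <- NULL
  for (i in seq_along(region)) {
    e <- ring_edge_matrices(region[[i]])
    cand <- nearest_point_on_segments(p, e$X1, e$X2)
    if (is.null(best) || cand$dist < best$dist) {
      best <- cand
      best$ring <- i
    }
  }
  best
}

# --- equal-area projection --------------------------------------------------

#' Cylindrical equal-area projection specification
#'
#' Lambert cylindrical equal-area on a spherical earth: `x = R * (lon -
#' lon_0)` in radians, `y = R * sin(lat)`. With the default standard parallel
#' at the equator this preserves spherical areas exactly. Units are km.
#'
#' @param lon_0 central meridian in degrees (105 centres the projection on
#'   China; synthetic landscapes use 0).
#' @param R spherical earth radius in km.
#' @return object of class `eoo_projection`.
#' @export
eoo_projection <- function(lon_0 = 105, R = 6371.0072) {
  structure(list(lon_0 = lon_0, R = R), class = "eoo_projection")
}

#' Project lon/lat to the equal-area plane (and back)
#'
#' @param lon,lat coordinates in decimal degrees WGS84 (spherical model).
#' @param proj an [eoo_projection()].
#' @return two-column matrix (x, y in km; or lon, lat in degrees for the
#'   inverse).
#' @export
project_equal_area <- function(lon, lat, proj = eoo_projection()) {
  dlon <- (lon - proj$lon_0) %% 360
  dlon <- ifelse(dlon > 180, dlon - 360, dlon)
  cbind(x = proj$R * dlon * pi / 180,
        y = proj$R * sin(lat * pi / 180))
}

#' @rdname project_equal_area
#' @param x,y planar coordinates in km.
#' @export
unproject_equal_area <- function(x, y, proj = eoo_projection()) {
  lon <- proj$lon_0 + (x / proj$R) * 180 / pi
  lon <- ((lon + 180) %% 360) - 180
  s <- y / proj$R
  if (any(abs(s) > 1 + 1e-12)) stop("y outside the projectable range")
  cbind(lon = lon, lat = asin(pmin(pmax(s, -1), 1)) * 180 / pi)
}

#' Project a lon/lat region to the equal-area plane
#'
#' Fails if a ring straddles the projection's antimeridian cut (longitude
#' `lon_0 + 180`); move the central meridian in that case.
#'
#' @param region region with rings in lon/lat degrees.
#' @param proj an [eoo_projection()].
#' @return region in projected km.
#' @export
project_region <- function(region, proj = eoo_projection()) {
  region <- as_region(region)
  lapply(region, function(r) {
    xy <- project_equal_area(r$x, r$y, proj)
    # a ring crossing the cut shows consecutive-vertex jumps near the full width
    if (any(abs(diff(c(xy[, 1], xy[1, 1]))) > proj$R * pi * 0.95)) {
      stop("ring crosses the projection's antimeridian cut; ",
           "choose a different central meridian (lon_0)")
    }
    list(x = xy[, 1], y = xy[, 2])
  })
}

#' @rdname project_region
#' @export
unproject_region <- function(region, proj = eoo_projection()) {
  region <- as_region(region)
  lapply(region, function(r) {
    ll <- unproject_equal_area(r$x, r$y, proj)
    list(x = ll[, 1], y = ll[, 2])
  })
}
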