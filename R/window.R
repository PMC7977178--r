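#' Study windows
#'
#' A study window is the planar region over which point patterns live and all
#' surfaces are evaluated. Coordinates are abstract planar units (typically
#' projected kilometers); the package performs no geodetic projection.
#'
#' Three constructors are provided: an axis-aligned rectangle, a disc, and a
#' general polygon (possibly with holes). Discs and rectangles use exact
#' analytic containment; polygons use an even-odd ray cast. Containment is
#' boundary-inclusive everywhere: a point exactly on the window edge belongs
#' to the window, so simulated points landing on a circular rim are kept.
#'
#' @param xmin,xmax,ymin,ymax Rectangle extent.
#' @param center Numeric length-2, disc center.
#' @param radius Disc radius (> 0).
#' @param nvertex Number of vertices of the polygonal outline stored for
#'   plotting/export of a disc window (containment stays analytic).
#' @param rings A single two-column matrix of vertices, or a list of such
#'   matrices; the first ring is the exterior boundary, subsequent rings are
#'   holes. Rings need not be closed (the closing edge is implied).
#'
#' @return An object of class `study_window` with elements `kind`
#'   (`"rectangle"`, `"disc"` or `"polygon"`), `rings` (vertex matrices),
#'   `bbox` (`xmin`, `ymin`, `xmax`, `ymax`) and `area`.
#'
#' @examples
#' w <- disc_window(c(0, 0), 10)
#' window_area(w)                      # pi * 100
#' contains(w, cbind(c(0, 10, 11), c(0, 0, 0)))
#' @name study_window
NULL

new_window <- function(kind, rings, bbox, area, extra = list()) {
  if (!is.finite(area) || area <= 0) {
    stop("invalid window: boundary must enclose a strictly positive area",
         call. = FALSE)
  }
  structure(c(list(kind = kind, rings = rings, bbox = bbox, area = area),
              extra),
            class = "study_window")
}

#' @rdname study_window
#' @export
rectangle_window <- function(xmin, ymin, xmax, ymax) {
  stopifnot(is.numeric(xmin), is.numeric(ymin), is.numeric(xmax),
            is.numeric(ymax))
  if (xmax <= xmin || ymax <= ymin) {
    stop("invalid window: rectangle has non-positive extent", call. = FALSE)
  }
  ring <- cbind(x = c(xmin, xmax, xmax, xmin),
                y = c(ymin, ymin, ymax, ymax))
  new_window("rectangle", list(ring),
             bbox = c(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax),
             area = (xmax - xmin) * (ymax - ymin))
}

#' @rdname study_window
#' @export
disc_window <- function(center, radius, nvertex = 256L) {
  stopifnot(length(center) == 2, is.numeric(center), is.numeric(radius))
  if (radius <= 0) stop("invalid window: disc radius must be > 0", call. = FALSE)
  th <- seq(0, 2 * pi, length.out = nvertex + 1L)[-(nvertex + 1L)]
  ring <- cbind(x = center[1] + radius * cos(th),
                y = center[2] + radius * sin(th))
  new_window("disc", list(ring),
             bbox = c(xmin = center[1] - radius, ymin = center[2] - radius,
                      xmax = center[1] + radius, ymax = center[2] + radius),
             area = pi * radius^2,
             extra = list(center = as.numeric(center), radius = radius))
}

#' @rdname study_window
#' @export
polygon_window <- function(rings) {
  if (is.matrix(rings) || is.data.frame(rings)) rings <- list(as.matrix(rings))
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    storage.mode(r) <- "double"
    if (ncol(r) != 2 || nrow(r) < 3) {
      stop("invalid window: each ring needs >= 3 vertices and 2 columns",
           call. = FALSE)
    }
    # drop an explicit closing vertex
    if (all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    if (nrow(r) < 3) {
      stop("invalid window: degenerate ring", call. = FALSE)
    }
    colnames(r) <- c("x", "y")
    r
  })
  if (ring_self_intersects(rings[[1]])) {
    stop("invalid window: exterior ring is self-intersecting", call. = FALSE)
  }
  area <- abs(shoelace(rings[[1]]))
  if (length(rings) > 1) {
    area <- area - sum(vapply(rings[-1], function(r) abs(shoelace(r)), 0))
  }
  xs <- unlist(lapply(rings, function(r) r[, 1]))
  ys <- unlist(lapply(rings, function(r) r[, 2]))
  new_window("polygon", rings,
             bbox = c(xmin = min(xs), ymin = min(ys),
                      xmax = max(xs), ymax = max(ys)),
             area = area)
}

#' Read a study window from a GeoJSON file
#'
#' Accepts a `Polygon` or `MultiPolygon` geometry (bare geometry, `Feature`,
#' or the first feature of a `FeatureCollection`). The first ring of the
#' (first) polygon is the exterior boundary; subsequent rings are holes.
#' Coordinates are taken as-is in planar units.
#'
#' @param path Path to a GeoJSON file.
#' @return A `study_window`.
#' @export
read_window_geojson <- function(path) {
  if (!file.exists(path)) stop("window file not found: ", path, call. = FALSE)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (identical(gj$type, "FeatureCollection")) gj <- gj$features[[1]]
  if (identical(gj$type, "Feature")) gj <- gj$geometry
  coords <- gj$coordinates
  if (identical(gj$type, "MultiPolygon")) coords <- coords[[1]]
  else if (!identical(gj$type, "Polygon")) {
    stop("unsupported GeoJSON geometry type: ", gj$type, call. = FALSE)
  }
  rings <- lapply(coords, function(ring) {
    do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  })
  polygon_window(rings)
}

# signed area (shoelace); vertices in order, unclosed
shoelace <- function(r) {
  x <- r[, 1]; y <- r[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# O(E^2) segment-crossing check; fine for boundary rings of modest size
ring_self_intersects <- function(r) {
  n <- nrow(r)
  a1 <- r
  a2 <- r[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]  # skip edges sharing a vertex
    if (!length(js)) next
    if (any(segments_cross(a1[i, ], a2[i, ], a1[js, , drop = FALSE],
                           a2[js, , drop = FALSE]))) {
      return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(p1, p2, q1, q2) {
  d1 <- (p2[1] - p1[1]) * (q1[, 2] - p1[2]) - (p2[2] - p1[2]) * (q1[, 1] - p1[1])
  d2 <- (p2[1] - p1[1]) * (q2[, 2] - p1[2]) - (p2[2] - p1[2]) * (q2[, 1] - p1[1])
  d3 <- (q2[, 1] - q1[, 1]) * (p1[2] - q1[, 2]) -
        (q2[, 2] - q1[, 2]) * (p1[1] - q1[, 1])
  d4 <- (q2[, 1] - q1[, 1]) * (p2[2] - q1[, 2]) -
        (q2[, 2] - q1[, 2]) * (p2[1] - q1[, 1])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Window containment
#'
#' Tests whether points lie inside a study window. Containment is
#' boundary-inclusive: points on the boundary count as inside.
#'
#' @param window A `study_window`.
#' @param points A two-column matrix (or length-2 vector) of coordinates.
#' @param tol Absolute snap tolerance for the on-boundary test.
#' @return Logical vector, one entry per point.
#' @export
contains <- function(window, points, tol = 1e-9) {
  stopifnot(inherits(window, "study_window"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  points <- as.matrix(points)
  x <- as.numeric(points[, 1]); y <- as.numeric(points[, 2])
  switch(window$kind,
    rectangle = {
      b <- window$bbox
      x >= b["xmin"] - tol & x <= b["xmax"] + tol &
        y >= b["ymin"] - tol & y <= b["ymax"] + tol
    },
    disc = {
      (x - window$center[1])^2 + (y - window$center[2])^2 <=
        (window$radius + tol)^2
    },
    polygon = {
      inside <- points_in_ring(x, y, window$rings[[1]], tol)
      if (length(window$rings) > 1) {
        for (hole in window$rings[-1]) {
          in_hole <- points_in_ring(x, y, hole, tol)
          on_edge <- points_on_ring(x, y, hole, tol)
          inside <- inside & (!in_hole | on_edge)
        }
      }
      inside
    })
}

# even-odd ray cast, boundary-inclusive via explicit on-edge test
points_in_ring <- function(x, y, ring, tol) {
  n <- nrow(ring)
  xi <- ring[, 1]; yi <- ring[, 2]
  xj <- xi[c(n, seq_len(n - 1L))]; yj <- yi[c(n, seq_len(n - 1L))]
  inside <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    crosses <- ((yi[k] > y) != (yj[k] > y))
    if (any(crosses)) {
      xint <- (xj[k] - xi[k]) * (y[crosses] - yi[k]) / (yj[k] - yi[k]) + xi[k]
      flip <- x[crosses] < xint
      inside[crosses][flip] <- !inside[crosses][flip]
    }
  }
  inside | points_on_ring(x, y, ring, tol)
}

points_on_ring <- function(x, y, ring, tol) {
  n <- nrow(ring)
  xi <- ring[, 1]; yi <- ring[, 2]
  xj <- xi[c(2:n, 1)]; yj <- yi[c(2:n, 1)]
  on <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    dx <- xj[k] - xi[k]; dy <- yj[k] - yi[k]
    len2 <- dx * dx + dy * dy
    if (len2 == 0) next
    t <- ((x - xi[k]) * dx + (y - yi[k]) * dy) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (x - (xi[k] + t * dx))^2 + (y - (yi[k] + t * dy))^2
    on <- on | d2 <= tol^2
  }
  on
}

#' @rdname study_window
#' @param window A `study_window`.
#' @export
window_area <- function(window) {
  stopifnot(inherits(window, "study_window"))
  window$area
}

#' @export
print.study_window <- function(x, ...) {
  b <- x$bbox
  cat(sprintf("study window (%s): bbox [%.4g, %.4g] x [%.4g, %.4g], area %.6g\n",
              x$kind, b["xmin"], b["xmax"], b["ymin"], b["ymax"], x$area))
  invisible(x)
}
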