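# Rib centerline geometry: arc-length parameterized polylines.
#
# Convention used throughout: the first vertex of a rib curve is the
# costovertebral landmark (posterior, 0% of the rib) and the last vertex is
# the costochondral landmark (anterior, 100%). For the floating ribs 11-12,
# which have no costochondral junction, the anatomical rib tip plays the
# role of the 100% landmark.

#' Construct a rib centerline curve
#'
#' A `rib_curve` is an ordered 3D polyline (mm) running from the
#' costovertebral joint (posterior end, 0%) to the costochondral junction
#' (anterior end, 100%), together with its cumulative arc length.
#'
#' @param rib_index Integer rib number, 1 (uppermost) to 12.
#' @param side `"left"` or `"right"` (aliases `"L"`/`"R"` accepted).
#' @param vertices Numeric matrix with 3 columns (x, y, z in mm) and at
#'   least 2 rows; consecutive duplicate vertices are rejected because they
#'   break the strict monotonicity of the arc-length parameterization.
#'
#' @return An object of class `rib_curve`: a list with elements
#'   `rib_index`, `side`, `vertices`, `cumulative_length` (mm, starting at
#'   0 and strictly increasing) and `length` (total arc length, mm).
#' @seealso [arc_length()], [point_at_percent()], [percent_at_point()]
#' @export
#' @examples
#' chain <- rib_curve(5, "left", rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0)))
#' chain$length  # 3 mm
rib_curve <- function(rib_index, side, vertices) {
  rib_index <- check_rib_index(rib_index)
  side <- normalize_side(side)
  vertices <- as_vertex_matrix(vertices)
  if (nrow(vertices) < 2L) {
    stop("a rib curve needs at least 2 vertices", call. = FALSE)
  }
  seg <- segment_lengths(vertices)
  if (any(seg == 0)) {
    stop("consecutive duplicate vertices are not allowed in a rib curve",
         call. = FALSE)
  }
  structure(
    list(
      rib_index = rib_index,
      side = side,
      vertices = vertices,
      cumulative_length = c(0, cumsum(seg)),
      length = sum(seg)
    ),
    class = "rib_curve"
  )
}

#' @export
print.rib_curve <- function(x, ...) {
  cat(sprintf("<rib_curve> rib %d (%s): %d vertices, arc length %.1f mm\n",
              x$rib_index, x$side, nrow(x$vertices), x$length))
  invisible(x)
}

#' Polyline arc length
#'
#' Total length of an ordered 3D polyline, i.e. the sum of the Euclidean
#' lengths of its segments. This is the package's realization of an
#' along-the-rib surface distance: fracture positions are one-dimensional
#' fractions of this length.
#'
#' @param vertices Numeric matrix with 3 columns and at least 2 rows, or a
#'   [rib_curve()] object.
#' @return Non-negative length in the units of `vertices` (mm by
#'   convention).
#' @export
#' @examples
#' arc_length(rbind(c(0, 0, 0), c(10, 0, 0)))  # 10
arc_length <- function(vertices) {
  if (inherits(vertices, "rib_curve")) {
    return(vertices$length)
  }
  vertices <- as_vertex_matrix(vertices)
  if (nrow(vertices) < 2L) {
    stop("arc_length needs at least 2 vertices", call. = FALSE)
  }
  sum(segment_lengths(vertices))
}

#' Locate the 3D point at a percentage position along a rib
#'
#' Maps a percentage position (0 = costovertebral joint, 100 =
#' costochondral junction) to the corresponding 3D point on the rib
#' centerline, linearly interpolated within the containing segment.
#'
#' @param curve A [rib_curve()].
#' @param p Percentage position(s) in \[0, 100\]; may be a vector.
#' @return A numeric matrix with one row per element of `p` and columns
#'   x, y, z. For scalar `p` a single-row matrix.
#' @export
point_at_percent <- function(curve, p) {
  stopifnot(inherits(curve, "rib_curve"))
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 100)) {
    stop("percentage positions must lie in [0, 100]", call. = FALSE)
  }
  target <- p / 100 * curve$length
  cl <- curve$cumulative_length
  # index of the segment containing each target arc length
  i <- findInterval(target, cl, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(curve$vertices) - 1L)
  t <- (target - cl[i]) / (cl[i + 1L] - cl[i])
  pts <- curve$vertices[i, , drop = FALSE] * (1 - t) +
    curve$vertices[i + 1L, , drop = FALSE] * t
  dimnames(pts) <- list(NULL, c("x", "y", "z"))
  pts
}

#' Percentage position of a 3D point on (or near) a rib curve
#'
#' Inverse of [point_at_percent()]: projects `point` onto the polyline,
#' takes the nearest on-curve point, and returns its arc-length fraction
#' as a percentage. Intended for importing fracture sites given as 3D
#' coordinates and for round-trip checks.
#'
#' @param curve A [rib_curve()].
#' @param point Numeric length-3 vector (mm).
#' @param tolerance Maximum allowed distance (mm) between `point` and the
#'   curve; beyond it the point is considered not to belong to this rib.
#' @return Percentage in \[0, 100\].
#' @export
percent_at_point <- function(curve, point, tolerance = 5) {
  stopifnot(inherits(curve, "rib_curve"))
  point <- as.numeric(point)
  if (length(point) != 3L || any(!is.finite(point))) {
    stop("point must be a finite length-3 vector", call. = FALSE)
  }
  v <- curve$vertices
  a <- v[-nrow(v), , drop = FALSE]
  d <- v[-1L, , drop = FALSE] - a
  seg2 <- rowSums(d^2)
  # parameter of the orthogonal projection onto each segment, clamped
  t <- (sweep(a, 2L, point, "-") * d)
  t <- pmin(pmax(-rowSums(t) / seg2, 0), 1)
  nearest <- a + d * t
  dist2 <- rowSums(sweep(nearest, 2L, point, "-")^2)
  i <- which.min(dist2)
  if (sqrt(dist2[i]) > tolerance) {
    stop(sprintf(
      "point is %.2f mm from the curve, beyond the %.2f mm tolerance",
      sqrt(dist2[i]), tolerance), call. = FALSE)
  }
  s <- curve$cumulative_length[i] + t[i] * sqrt(seg2[i])
  100 * s / curve$length
}

#' Per-vertex percentage positions of a rib curve
#'
#' @param curve A [rib_curve()].
#' @return Numeric vector, one value per vertex, from 0 to 100.
#' @keywords internal
#' @export
vertex_percents <- function(curve) {
  stopifnot(inherits(curve, "rib_curve"))
  pmin(pmax(100 * curve$cumulative_length / curve$length, 0), 100)
}

# ---- internal helpers -------------------------------------------------------

as_vertex_matrix <- function(vertices) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) {
    stop("vertices must have 3 columns (x, y, z)", call. = FALSE)
  }
  if (any(!is.finite(vertices))) {
    stop("vertices must be finite", call. = FALSE)
  }
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  vertices
}

segment_lengths <- function(vertices) {
  d <- diff(vertices)
  sqrt(rowSums(d^2))
}

check_rib_index <- function(rib_index) {
  rib_index <- as.integer(rib_index)
  if (length(rib_index) != 1L || is.na(rib_index) ||
      rib_index < 1L || rib_index > 12L) {
    stop("rib_index must be a single integer between 1 and 12",
         call. = FALSE)
  }
  rib_index
}

normalize_side <- function(side) {
  s <- tolower(trimws(as.character(side)))
  out <- character(length(s))
  out[s %in% c("left", "l")] <- "left"
  out[s %in% c("right", "r")] <- "right"
  if (any(out == "")) {
    stop(sprintf("unrecognized side value(s): %s",
                 paste(unique(s[out == ""]), collapse = ", ")),
         call. = FALSE)
  }
  out
}
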