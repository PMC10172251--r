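## Planar geometry primitives for traced contours and marker point pairs.
## Polygons are n x 2 numeric matrices (columns x, y), implicitly closed.

as_polygon <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.list(p) && !is.matrix(p)) p <- do.call(rbind, lapply(p, as.numeric))
  p <- as.matrix(p)
  if (!is.numeric(p) || ncol(p) != 2)
    stop("polygon must be an n x 2 numeric matrix of (x, y) vertices", call. = FALSE)
  if (!all(is.finite(p)))
    stop("polygon vertices must be finite", call. = FALSE)
  if (nrow(p) < 3)
    stop("invalid geometry: polygon needs at least 3 vertices", call. = FALSE)
  ## drop a duplicated closing vertex
  if (isTRUE(all.equal(p[1, ], p[nrow(p), ], check.attributes = FALSE)))
    p <- p[-nrow(p), , drop = FALSE]
  if (nrow(p) < 3)
    stop("invalid geometry: polygon needs at least 3 distinct vertices", call. = FALSE)
  dimnames(p) <- list(NULL, c("x", "y"))
  p
}

## signed shoelace area (positive for one winding, negative for the other)
.signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area (shoelace formula)
#'
#' Absolute enclosed area of a closed polygon given as an n x 2 matrix of
#' vertices in pixel coordinates. Winding-independent.
#'
#' @param p polygon: n x 2 numeric matrix (columns x, y), n >= 3; the last
#'   vertex implicitly joins the first.
#' @return area in pixels squared (> 0).
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
#' @export
polygon_area <- function(p) {
  p <- as_polygon(p)
  a <- abs(.signed_area(p))
  if (a <= 0 || !is.finite(a))
    stop("invalid geometry: degenerate (zero-area) polygon", call. = FALSE)
  a
}

#' Polygon centroid (area-weighted)
#'
#' Geometric centre of the enclosed region via the shoelace moment formula,
#' not the vertex average; the two differ for irregular vertex spacing.
#'
#' @inheritParams polygon_area
#' @return numeric length-2 vector c(x, y) in pixels.
#' @export
polygon_centroid <- function(p) {
  p <- as_polygon(p)
  a <- .signed_area(p)
  if (abs(a) <= 0 || !is.finite(a))
    stop("invalid geometry: degenerate (zero-area) polygon", call. = FALSE)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  c(x = sum((x + xn) * cr) / (6 * a), y = sum((y + yn) * cr) / (6 * a))
}

#' Vector between two points
#'
#' Displacement vector from `a` to `b` in the image frame (x right, y down),
#' with its length and its angle in degrees wrapped to \[-180, 180).
#'
#' @param a,b numeric length-2 points c(x, y) in pixels.
#' @return list with `dx`, `dy`, `length`, `angle_deg` (NA for a zero-length
#'   vector, where direction is undefined).
#' @export
vector_between <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == 2, length(b) == 2)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("points must have finite coordinates", call. = FALSE)
  dx <- b[1] - a[1]; dy <- b[2] - a[2]
  len <- sqrt(dx^2 + dy^2)
  ang <- if (len > 0) wrap_angle(atan2(dy, dx) * 180 / pi) else NA_real_
  list(dx = dx, dy = dy, length = len, angle_deg = ang)
}
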