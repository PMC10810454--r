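# Planar polygon helpers built on pracma. Polygons are 2-column vertex
# matrices, implicitly closed; coordinates are metres (no geodesy).

polygonArea <- function(poly) {
  abs(pracma::polyarea(poly[, 1], poly[, 2]))
}

# Vectorised containment; points on the closed polygon count as inside.
pointsInPolygon <- function(x, y, poly) {
  pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = TRUE)
}

# strict-interior variant for overlap checks (shared edges are not overlap)
pointsInPolygonStrict <- function(x, y, poly) {
  pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = FALSE)
}

# Minimum distance from (x, y) to the polygon outline (closed ring).
distanceToPolygon <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  qx <- c(px[-1], px[1]); qy <- c(py[-1], py[1])
  dx <- qx - px; dy <- qy - py
  len2 <- dx^2 + dy^2
  t <- ((x - px) * dx + (y - py) * dy) / pmax(len2, .Machine$double.eps)
  t <- pmin(pmax(t, 0), 1)
  sqrt(min((x - (px + t * dx))^2 + (y - (py + t * dy))^2))
}

# Closest point on the polygon outline to (x, y).
nearestPointOnPolygon <- function(x, y, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  qx <- c(px[-1], px[1]); qy <- c(py[-1], py[1])
  dx <- qx - px; dy <- qy - py
  len2 <- dx^2 + dy^2
  t <- ((x - px) * dx + (y - py) * dy) / pmax(len2, .Machine$double.eps)
  t <- pmin(pmax(t, 0), 1)
  cx <- px + t * dx; cy <- py + t * dy
  i <- which.min((x - cx)^2 + (y - cy)^2)
  c(cx[i], cy[i])
}

rectanglePolygon <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

polygonCentroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  c(sum((x + xs) * cr) / (6 * a), sum((y + ys) * cr) / (6 * a))
}
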