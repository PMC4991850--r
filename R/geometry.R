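## Minimal planar geometry for rectangular/polygonal resource patches.
## Polygons are two-column matrices of vertices (open ring, metric
## coordinates); no CRS handling, planar throughout.

#' Polygon area (shoelace formula)
#' @param xy Two-column matrix of vertices (ring, not repeated at the end).
#' @return Area in squared input units.
#' @export
poly_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(seq_len(nrow(xy))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

## ray-casting point-in-polygon; px, py vectors
point_in_poly <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]; xj <- xy[j, 1]; yj <- xy[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

## distance from one point to a polygon boundary/interior (0 inside)
dist_point_poly <- function(px, py, xy) {
  if (point_in_poly(px, py, xy)) return(0)
  n <- nrow(xy)
  j <- c(seq_len(n)[-1], 1L)
  x1 <- xy[, 1]; y1 <- xy[, 2]; x2 <- xy[j, 1]; y2 <- xy[j, 2]
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 > 0, ((px - x1) * dx + (py - y1) * dy) / len2, 0)
  t <- pmin(pmax(t, 0), 1)
  min(sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2))
}

## axis-aligned rectangle ring
rect_poly <- function(x0, y0, w, h) {
  cbind(x = c(x0, x0 + w, x0 + w, x0), y = c(y0, y0, y0 + h, y0 + h))
}

## rectangle overlap (strictly positive intersection area)
rects_overlap <- function(a, b) {
  ax <- range(a[, 1]); ay <- range(a[, 2])
  bx <- range(b[, 1]); by <- range(b[, 2])
  (min(ax[2], bx[2]) > max(ax[1], bx[1])) &&
    (min(ay[2], by[2]) > max(ay[1], by[1]))
}

## WKT POLYGON with a single ring <-> vertex matrix
wkt_polygon <- function(xy) {
  ring <- rbind(xy, xy[1, , drop = FALSE])
  sprintf("POLYGON ((%s))",
          paste(sprintf("%.6g %.6g", ring[, 1], ring[, 2]), collapse = ", "))
}

parse_wkt_polygon <- function(s) {
  body <- sub("^\\s*POLYGON\\s*\\(\\(", "", s)
  body <- sub("\\)\\)\\s*$", "", body)
  if (identical(body, s)) stop("malformed WKT polygon: ", substr(s, 1, 40))
  pts <- strsplit(trimws(strsplit(body, ",")[[1]]), "\\s+")
  xy <- t(vapply(pts, function(p) as.numeric(p[1:2]), numeric(2)))
  if (anyNA(xy)) stop("malformed WKT polygon coordinates")
  if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  colnames(xy) <- c("x", "y")
  xy
}
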