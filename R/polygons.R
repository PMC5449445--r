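# Polygon extraction from binary masks and perimeter-to-area cue filtering.

#' Extract closed boundary polygons from a binary mask
#'
#' One polygon per 8-connected foreground component, traced along its outer
#' boundary by border following; inner boundaries (holes) are not emitted.
#' Components whose boundary has fewer than 5 pixels are discarded (too small
#' to form a meaningful polygon, and numerically unstable in the ratio).
#' Polygons are returned in raster-scan discovery order of their components.
#'
#' @param mask logical matrix.
#' @param t optional frame index attached to each polygon.
#' @return list of \code{cuePolygon} objects: each a list with
#'   \code{vertices} (n x 2 matrix, columns x and y, 0-based pixel
#'   coordinates, implicitly closed), \code{t} and \code{j}.
#' @export
findPolygons <- function(mask, t = NA_integer_) {
  lab <- labelComponents(mask)
  if (max(lab) == 0L) return(list())
  contours <- EBImage::ocontour(EBImage::Image(lab))
  out <- list()
  j <- 0L
  for (k in seq_along(contours)) {
    oc <- contours[[k]]
    if (is.null(oc) || nrow(oc) < 5L) next
    j <- j + 1L
    # ocontour coordinates are 0-based (dim1, dim2) = (row, col) = (y, x)
    out[[j]] <- cuePolygon(cbind(x = oc[, 2], y = oc[, 1]), t = t, j = j)
  }
  out
}

#' Construct a cue polygon
#'
#' @param vertices n x 2 numeric matrix (x, y), implicitly closed; n >= 3.
#' @param t,j frame index and within-frame polygon index.
#' @return a \code{cuePolygon}.
#' @export
cuePolygon <- function(vertices, t = NA_integer_, j = NA_integer_) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) stop("a polygon needs at least 3 vertices")
  colnames(vertices) <- c("x", "y")
  structure(list(vertices = vertices, t = t, j = j), class = "cuePolygon")
}

.vertices <- function(p) if (inherits(p, "cuePolygon")) p$vertices else as.matrix(p)

#' Polygon perimeter
#'
#' Sum of Euclidean lengths of consecutive vertex segments, including the
#' closing segment from the last vertex back to the first.
#'
#' @param p a \code{cuePolygon} or an n x 2 vertex matrix.
#' @return perimeter in px.
#' @export
polygonPerimeter <- function(p) {
  v <- .vertices(p)
  if (nrow(v) < 3L) stop("a polygon needs at least 3 vertices")
  d <- v[c(seq_len(nrow(v))[-1], 1L), , drop = FALSE] - v
  sum(sqrt(rowSums(d^2)))
}

#' Polygon area (shoelace)
#'
#' Absolute value of the shoelace sum
#' \eqn{\sum_k (x_{k+1} + x_k)(y_{k+1} - y_k)/2} with wraparound
#' \eqn{(x_{n+1}, y_{n+1}) = (x_1, y_1)}; orientation-independent.
#'
#' @inheritParams polygonPerimeter
#' @return area in px^2.
#' @export
polygonArea <- function(p) {
  v <- .vertices(p)
  if (nrow(v) < 3L) stop("a polygon needs at least 3 vertices")
  nxt <- v[c(seq_len(nrow(v))[-1], 1L), , drop = FALSE]
  abs(sum((nxt[, 1] + v[, 1]) * (nxt[, 2] - v[, 2])) / 2)
}

#' Perimeter-to-area ratio
#'
#' The shape descriptor used to recognize visual cues: for a fixed shape it
#' decreases as 1/scale, so large regular polygons (the chamber spacers) score
#' low while small or convoluted polygons score high.
#'
#' @inheritParams polygonPerimeter
#' @return ratio in 1/px.
#' @export
polygonRatio <- function(p) {
  a <- polygonArea(p)
  if (a <= 0) stop("degenerate polygon: zero area")
  polygonPerimeter(p) / a
}

#' Filter polygons into visual cues
#'
#' Retains polygons whose perimeter-to-area ratio is strictly below
#' \code{threshold}. If no polygon satisfies the threshold, the full input
#' list is retained unchanged (fallback: complex polygons are kept only when
#' nothing simpler is available).
#'
#' @param polygons list of \code{cuePolygon}.
#' @param threshold ratio cutoff (1/px); default 5e-2.
#' @return list of retained polygons (the frame's visual cues).
#' @export
filterCues <- function(polygons, threshold = 5e-2) {
  if (length(polygons) == 0L) return(polygons)
  ratios <- vapply(polygons, function(p) {
    a <- polygonArea(p)
    if (a <= 0) Inf else polygonPerimeter(p) / a
  }, numeric(1))
  keep <- ratios < threshold
  if (!any(keep)) polygons else polygons[keep]
}

#' Tabulate polygon shape statistics
#'
#' @param polygons list of \code{cuePolygon}.
#' @param threshold ratio cutoff used for the retained flag.
#' @return data.frame: t, j, n_vertices, perimeter, area, ratio, retained.
#' @export
polygonStats <- function(polygons, threshold = 5e-2) {
  if (length(polygons) == 0L)
    return(data.frame(t = integer(), j = integer(), n_vertices = integer(),
                      perimeter = numeric(), area = numeric(), ratio = numeric(),
                      retained = logical()))
  rows <- lapply(polygons, function(p) {
    a <- polygonArea(p); s <- polygonPerimeter(p)
    r <- if (a > 0) s / a else Inf
    data.frame(t = p$t, j = p$j, n_vertices = nrow(p$vertices),
               perimeter = s, area = a, ratio = r, retained = r < threshold)
  })
  df <- do.call(rbind, rows)
  if (!any(df$retained)) df$retained <- TRUE  # fallback retention
  df
}
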