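# From cue polygons to per-frame control triples: ordering, oriented bounding
# boxes, the three selection scenarios, and cue correspondence across frames.

#' Cue centroid
#'
#' Area centroid of the closed boundary polygon (first moment of the enclosed
#' region). Unlike the plain mean of the boundary vertices, it is insensitive
#' to the uneven vertex density of pixel-chain boundaries, which makes it
#' markedly more stable under boundary jitter; for clean near-square cues the
#' two differ by less than a pixel. Falls back to the vertex mean when the
#' polygon is degenerate (zero area).
#'
#' @param p a \code{cuePolygon} or n x 2 vertex matrix.
#' @return length-2 numeric (x, y).
#' @export
cueCentroid <- function(p) {
  v <- .vertices(p)
  n <- nrow(v)
  nx <- v[c(seq_len(n)[-1], 1L), , drop = FALSE]
  cr <- v[, 1] * nx[, 2] - nx[, 1] * v[, 2]
  A <- sum(cr) / 2
  if (abs(A) < 1e-9) return(colMeans(v))
  c(x = sum((v[, 1] + nx[, 1]) * cr) / (6 * A),
    y = sum((v[, 2] + nx[, 2]) * cr) / (6 * A))
}

#' Cue anchor point
#'
#' The (min x, min y) corner of the vertex bounding box, used for the stable
#' lexicographic cue ordering.
#'
#' @inheritParams cueCentroid
#' @return length-2 numeric (x, y).
#' @export
cueAnchor <- function(p) {
  v <- .vertices(p)
  c(min(v[, 1]), min(v[, 2]))
}

#' Order cues lexicographically
#'
#' Stable sort by anchor point: minimum y first, ties broken by minimum x.
#' The first cue of frame 1 under this ordering is the reference cue.
#'
#' @param cues list of \code{cuePolygon}.
#' @return the same list, reordered.
#' @export
orderCues <- function(cues) {
  if (length(cues) <= 1L) return(cues)
  anchors <- t(vapply(cues, cueAnchor, numeric(2)))
  cues[order(anchors[, 2], anchors[, 1])]
}

#' Minimum-area oriented bounding box
#'
#' Rotating-calipers over the convex hull: the minimum-area enclosing
#' rectangle is attained with one side parallel to a hull edge. Corners are
#' returned counterclockwise (in the x right / y down pixel frame) starting
#' from the corner nearest the coordinate origin.
#'
#' @inheritParams cueCentroid
#' @return 4 x 2 matrix of corners (x, y).
#' @export
orientedBoundingBox <- function(p) {
  v <- unique(.vertices(p))
  if (nrow(v) < 3L) stop("collinear or degenerate polygon: no oriented bounding box")
  h <- v[chull(v), , drop = FALSE]
  if (nrow(h) < 3L) stop("collinear polygon: no oriented bounding box")
  edges <- h[c(seq_len(nrow(h))[-1], 1L), , drop = FALSE] - h
  angles <- unique(atan2(edges[, 2], edges[, 1]) %% (pi / 2))
  best <- NULL; best_area <- Inf
  for (a in angles) {
    ca <- cos(a); sa <- sin(a)
    rx <- h[, 1] * ca + h[, 2] * sa
    ry <- -h[, 1] * sa + h[, 2] * ca
    area <- (max(rx) - min(rx)) * (max(ry) - min(ry))
    if (area < best_area - 1e-12) {
      best_area <- area
      best <- list(a = a, x0 = min(rx), x1 = max(rx), y0 = min(ry), y1 = max(ry))
    }
  }
  corn <- rbind(c(best$x0, best$y0), c(best$x1, best$y0),
                c(best$x1, best$y1), c(best$x0, best$y1))
  ca <- cos(best$a); sa <- sin(best$a)
  corners <- cbind(corn[, 1] * ca - corn[, 2] * sa,
                   corn[, 1] * sa + corn[, 2] * ca)
  # orient counterclockwise (positive shoelace in the x-right/y-down frame)
  nxt <- corners[c(2:4, 1), , drop = FALSE]
  if (sum((nxt[, 1] + corners[, 1]) * (nxt[, 2] - corners[, 2])) < 0)
    corners <- corners[4:1, , drop = FALSE]
  start <- which.min(rowSums(corners^2))
  corners <- corners[((seq_len(4) + start - 2L) %% 4L) + 1L, , drop = FALSE]
  colnames(corners) <- c("x", "y")
  corners
}

# corner (2..4) of the first cue's OBB spanning the largest triangle with the
# two cues' first corners
.thirdCorner <- function(b1, b2) {
  areas <- vapply(2:4, function(k) .triangleArea(rbind(b1[1, ], b2[1, ], b1[k, ])),
                  numeric(1))
  1L + which.max(areas)
}

.triangleArea <- function(pts) {
  abs((pts[2, 1] - pts[1, 1]) * (pts[3, 2] - pts[1, 2]) -
      (pts[3, 1] - pts[1, 1]) * (pts[2, 2] - pts[1, 2])) / 2
}

#' Derive the three control points of a frame
#'
#' Reduces a frame's cues to the ordered control triple driving the affine
#' solve, by cue count J: \describe{
#'   \item{J = 1 (scenario a)}{the first three corners of the cue's oriented
#'     bounding box;}
#'   \item{J = 2 (scenario b)}{the first OBB corner of each cue plus the
#'     corner of the first cue's OBB that spans the largest triangle with
#'     the two first corners (deterministic and non-collinear whenever the
#'     OBB is non-degenerate);}
#'   \item{J >= 3 (scenario c)}{the centroids of the first three cues in
#'     \code{\link{orderCues}} order.}
#' }
#'
#' @param cues list of \code{cuePolygon} (a frame's visual cues).
#' @param t frame index recorded on the result.
#' @param tol minimum triangle area (px^2) below which the triple is rejected
#'   as collinear.
#' @return a \code{controlTriple}: list with \code{points} (3 x 2 matrix),
#'   \code{t} and \code{scenario} ("a", "b" or "c").
#' @export
controlPoints <- function(cues, t = NA_integer_, tol = 1) {
  J <- length(cues)
  if (J == 0L) stop("no cues: frame is unregistrable")
  cues <- orderCues(cues)
  if (J == 1L) {
    pts <- orientedBoundingBox(cues[[1]])[1:3, , drop = FALSE]
    scenario <- "a"
  } else if (J == 2L) {
    b1 <- orientedBoundingBox(cues[[1]])
    b2 <- orientedBoundingBox(cues[[2]])
    pts <- rbind(b1[1, ], b2[1, ], b1[.thirdCorner(b1, b2), ])
    scenario <- "b"
  } else {
    pts <- t(vapply(cues[1:3], cueCentroid, numeric(2)))
    scenario <- "c"
  }
  colnames(pts) <- c("x", "y")
  if (.triangleArea(pts) < tol)
    stop(sprintf("degenerate control triple (area %.3g px^2 < %g): collinear cues",
                 .triangleArea(pts), tol))
  structure(list(points = pts, t = t, scenario = scenario), class = "controlTriple")
}

.centroidMatrix <- function(cues) {
  if (is.matrix(cues)) return(cues)
  t(vapply(cues, cueCentroid, numeric(2)))
}

#' Match cues between two frames
#'
#' Bijective matching of the smaller cue set into the larger, minimizing the
#' total centroid displacement: exhaustive optimal assignment when the larger
#' set has at most 8 cues, greedy nearest-neighbour with mutual-best check
#' otherwise. Errors if any matched displacement exceeds \code{max_shift}
#' (by default unbounded; the registration driver passes half the image
#' width, beyond which cue identity is no longer guaranteed).
#'
#' @param prev,next_ cue lists (or k x 2 centroid matrices) of two frames.
#' @param max_shift maximum admissible displacement in px.
#' @return data.frame with columns \code{prev}, \code{next_} (indices into
#'   the two inputs) and \code{dist}.
#' @export
matchCues <- function(prev, next_, max_shift = Inf) {
  a <- .centroidMatrix(prev)
  b <- .centroidMatrix(next_)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) stop("no cues to match")
  dm <- outer(seq_len(na), seq_len(nb),
              function(i, j) sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2))
  dm <- matrix(dm, na, nb)
  swap <- na > nb
  if (swap) { dm <- t(dm); tmp <- na; na <- nb; nb <- tmp }
  # na <= nb: assign each row a distinct column
  if (nb <= 8L) {
    assign_best <- .assignExhaustive(dm)
  } else {
    assign_best <- .assignGreedy(dm)
  }
  res <- data.frame(prev = seq_len(na), next_ = assign_best,
                    dist = dm[cbind(seq_len(na), assign_best)])
  if (swap) res[, 1:2] <- res[, 2:1]
  names(res) <- c("prev", "next_", "dist")
  res <- res[order(res$prev), , drop = FALSE]
  rownames(res) <- NULL
  if (any(res$dist > max_shift))
    stop(sprintf("shift too large: cue displacement %.1f px exceeds %.1f px",
                 max(res$dist), max_shift))
  res
}

# exhaustive minimal assignment by depth-first search with pruning (nb <= 8)
.assignExhaustive <- function(dm) {
  na <- nrow(dm); nb <- ncol(dm)
  best_cost <- Inf; best <- integer(na)
  cur <- integer(na); used <- logical(nb)
  rec <- function(i, cost) {
    if (cost >= best_cost) return()
    if (i > na) { best_cost <<- cost; best <<- cur[seq_len(na)]; return() }
    ord <- order(dm[i, ])
    for (j in ord) {
      if (!used[j]) {
        used[j] <<- TRUE; cur[i] <<- j
        rec(i + 1L, cost + dm[i, j])
        used[j] <<- FALSE
      }
    }
  }
  rec(1L, 0)
  best
}

# greedy globally-smallest-distance-first assignment
.assignGreedy <- function(dm) {
  na <- nrow(dm); nb <- ncol(dm)
  assign_v <- integer(na)
  used_r <- logical(na); used_c <- logical(nb)
  ord <- order(dm)
  for (k in ord) {
    i <- ((k - 1L) %% na) + 1L
    j <- ((k - 1L) %/% na) + 1L
    if (!used_r[i] && !used_c[j]) {
      assign_v[i] <- j; used_r[i] <- TRUE; used_c[j] <- TRUE
      if (all(used_r)) break
    }
  }
  assign_v
}
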