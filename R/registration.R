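# Affine estimation from control triples, interval partitioning by cue count,
# chaining of pairwise transforms to the reference frame, and warping.

#' Affine transform constructors
#'
#' \code{affineTransform} wraps a 2x3 matrix; \code{identityAffine},
#' \code{translationAffine} and \code{rotationAffine} build the common special
#' cases. A transform maps (x, y) to (a x + b y + tx, c x + d y + ty) in
#' 0-based pixel coordinates (x = column, y = row).
#'
#' @param m numeric 2x3 matrix \code{[[a, b, tx], [c, d, ty]]}.
#' @return an \linkS4class{AffineTransform2D}.
#' @export
affineTransform <- function(m) {
  m <- matrix(as.numeric(m), 2L, 3L)
  new("AffineTransform2D", m = m)
}

#' @rdname affineTransform
#' @export
identityAffine <- function() affineTransform(cbind(diag(2), c(0, 0)))

#' @rdname affineTransform
#' @param tx,ty translation in px.
#' @export
translationAffine <- function(tx, ty) affineTransform(cbind(diag(2), c(tx, ty)))

#' @rdname affineTransform
#' @param theta rotation angle in radians (positive = from +x towards +y).
#' @param center length-2 rotation center (x, y).
#' @export
rotationAffine <- function(theta, center = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  tr <- center - R %*% center
  affineTransform(cbind(R, tr))
}

#' Apply an affine transform to points
#'
#' @param A an \linkS4class{AffineTransform2D}.
#' @param pts n x 2 matrix (x, y) or length-2 vector.
#' @return transformed points, same shape.
#' @export
applyAffine <- function(A, pts) {
  v <- if (is.matrix(pts)) pts else matrix(pts, 1)
  out <- v %*% t(A@m[, 1:2]) + rep(1, nrow(v)) %*% t(A@m[, 3, drop = FALSE])
  colnames(out) <- c("x", "y")
  if (is.matrix(pts)) out else drop(out)
}

#' Estimate the affine transform mapping one control triple onto another
#'
#' Exact solve of the 6-unknown linear system from three point
#' correspondences (point i of \code{src} maps to point i of \code{dst});
#' the residual on the control points is zero up to round-off.
#'
#' @param src,dst \code{controlTriple}s or 3 x 2 point matrices.
#' @return an \linkS4class{AffineTransform2D} with \code{applyAffine(A, src)
#'   == dst}.
#' @export
estimateAffine <- function(src, dst) {
  s <- if (inherits(src, "controlTriple")) src$points else as.matrix(src)
  d <- if (inherits(dst, "controlTriple")) dst$points else as.matrix(dst)
  stopifnot(nrow(s) == 3L, nrow(d) == 3L)
  if (.triangleArea(s) < 1e-9 || .triangleArea(d) < 1e-9)
    stop("degenerate control triple: collinear points, affine solve is singular")
  X <- cbind(s, 1)
  coef <- tryCatch(solve(X, d),
                   error = function(e) stop("singular affine system: ",
                                            conditionMessage(e)))
  affineTransform(rbind(c(coef[1, 1], coef[2, 1], coef[3, 1]),
                        c(coef[1, 2], coef[2, 2], coef[3, 2])))
}

#' Compose two affine transforms
#'
#' \code{composeAffine(outer, inner)} applies \code{inner} first, then
#' \code{outer} (matrix product of the homogeneous 3x3 forms).
#'
#' @param outer,inner \linkS4class{AffineTransform2D}s.
#' @return the composed \linkS4class{AffineTransform2D}.
#' @export
composeAffine <- function(outer, inner) {
  A <- rbind(outer@m, c(0, 0, 1)) %*% rbind(inner@m, c(0, 0, 1))
  affineTransform(A[1:2, , drop = FALSE])
}

#' Invert an affine transform
#'
#' @param A an \linkS4class{AffineTransform2D}.
#' @return the inverse transform.
#' @export
invertAffine <- function(A) {
  L <- A@m[, 1:2]
  Li <- solve(L)
  affineTransform(cbind(Li, -Li %*% A@m[, 3]))
}

#' Partition a series into constant-cue-count intervals
#'
#' Maximal runs of frames sharing the same visual-cue count J. Runs of length
#' one cannot be registered by same-J pairing and are flagged; the chaining
#' step bridges them through cross-count cue matching where possible.
#'
#' @param counts integer vector: J per frame, length T.
#' @return data.frame: t_start, t_end, J, registrable (run length >= 2 and
#'   J >= 1).
#' @export
partitionIntervals <- function(counts) {
  stopifnot(length(counts) >= 1L)
  r <- rle(as.integer(counts))
  t_end <- cumsum(r$lengths)
  t_start <- t_end - r$lengths + 1L
  data.frame(t_start = t_start, t_end = t_end, J = r$values,
             registrable = r$lengths >= 2L & r$values >= 1L)
}

#' Chain pairwise transforms to the reference frame
#'
#' Left-fold composition: frame 1 gets the identity; frame t gets the
#' composition of all pairwise transforms along 1..t, expressing every frame
#' in reference (frame 1) coordinates. A missing pairwise transform (NULL)
#' breaks the chain: the previous composed transform is carried and all
#' downstream frames are flagged, never silently dropped.
#'
#' @param pairwise list of length T-1; element t is the
#'   \linkS4class{AffineTransform2D} mapping frame t+1 coordinates onto frame
#'   t coordinates, or NULL if that pair was unregistrable.
#' @return list with \code{transforms} (length-T list) and \code{status}
#'   (character: "reference", "registered", "unbridged").
#' @export
chainToReference <- function(pairwise) {
  T <- length(pairwise) + 1L
  transforms <- vector("list", T)
  status <- character(T)
  transforms[[1]] <- identityAffine()
  status[1] <- "reference"
  broken <- FALSE
  for (t in 2:T) {
    A <- pairwise[[t - 1L]]
    if (is.null(A)) broken <- TRUE
    transforms[[t]] <- if (is.null(A)) transforms[[t - 1L]]
                       else composeAffine(transforms[[t - 1L]], A)
    status[t] <- if (broken) "unbridged" else "registered"
  }
  list(transforms = transforms, status = status)
}

#' Warp a frame by an affine transform
#'
#' Inverse-mapped resampling: output pixel p takes the value of the source at
#' \code{invertAffine(A)} applied to p, so the content is moved according to
#' \code{A}. Bilinear interpolation by default (nearest-neighbour keeps binary
#' masks binary); out-of-field samples are filled with \code{fill}. RGB frames
#' are warped channel-wise with the same transform.
#'
#' @param frame grayscale matrix or RGB array.
#' @param A an \linkS4class{AffineTransform2D} mapping source coordinates to
#'   output coordinates.
#' @param interpolation "bilinear" or "nearest".
#' @param fill fill value for out-of-field pixels.
#' @return warped frame, same dimensions and type.
#' @export
warpFrame <- function(frame, A, interpolation = c("bilinear", "nearest"),
                      fill = 0) {
  interpolation <- match.arg(interpolation)
  Minv <- invertAffine(A)@m
  mvec <- c(Minv[1, ], Minv[2, ])
  bil <- interpolation == "bilinear"
  if (length(dim(frame)) == 3L) {
    out <- frame
    for (ch in seq_len(dim(frame)[3]))
      out[, , ch] <- warp_cpp(frame[, , ch], mvec, bil, fill)
    return(out)
  }
  if (is.logical(frame))
    return(warp_cpp(frame * 1, mvec, FALSE, fill) > 0.5)
  warp_cpp(frame, mvec, bil, fill)
}

#' Registration configuration
#'
#' @param preprocess a \code{\link{preprocessConfig}}.
#' @param ratio_threshold perimeter-to-area cutoff for cue retention (1/px).
#' @param interpolation warping interpolation ("bilinear" or "nearest").
#' @param collinearity_tol minimum control-triangle area (px^2).
#' @param max_shift maximum admissible cue displacement between consecutive
#'   frames, px; NULL = half the image width.
#' @param warp if FALSE, skip the image resampling step: transforms, cues and
#'   the log are still computed, and the returned series contains the input
#'   frames unwarped. Useful when only the transforms or metrics are needed.
#' @return a \code{RegistrationConfig} (named list).
#' @export
registrationConfig <- function(preprocess = preprocessConfig(),
                               ratio_threshold = 5e-2,
                               interpolation = "bilinear",
                               collinearity_tol = 1,
                               max_shift = NULL,
                               warp = TRUE) {
  structure(list(preprocess = preprocess, ratio_threshold = ratio_threshold,
                 interpolation = interpolation,
                 collinearity_tol = collinearity_tol, max_shift = max_shift,
                 warp = isTRUE(warp)),
            class = "RegistrationConfig")
}

# Build corresponding control triples for a consecutive frame pair from the
# matched common cues; scenario determined by the number of matched cues.
.controlTriplePair <- function(cues_prev, cues_next, t, max_shift, tol) {
  m <- matchCues(cues_prev, cues_next, max_shift = max_shift)
  cp <- cues_prev[m$prev]
  cn <- cues_next[m$next_]
  # order both by the previous frame's anchors so the triples correspond
  ord <- order(vapply(cp, function(p) cueAnchor(p)[2], numeric(1)),
               vapply(cp, function(p) cueAnchor(p)[1], numeric(1)))
  cp <- cp[ord]; cn <- cn[ord]
  k <- length(cp)
  # the scenario-b third-corner index is chosen on the previous frame and
  # reused on the next so the point correspondence is consistent
  corner3 <- if (k == 2L)
    .thirdCorner(orientedBoundingBox(cp[[1]]), orientedBoundingBox(cp[[2]]))
  else NA_integer_
  triple_from <- function(cs) {
    if (k == 1L) {
      list(points = orientedBoundingBox(cs[[1]])[1:3, , drop = FALSE], scenario = "a")
    } else if (k == 2L) {
      b1 <- orientedBoundingBox(cs[[1]]); b2 <- orientedBoundingBox(cs[[2]])
      list(points = rbind(b1[1, ], b2[1, ], b1[corner3, ]), scenario = "b")
    } else {
      list(points = t(vapply(cs[1:3], cueCentroid, numeric(2))), scenario = "c")
    }
  }
  tp <- triple_from(cp); tn <- triple_from(cn)
  if (.triangleArea(tp$points) < tol || .triangleArea(tn$points) < tol)
    stop(sprintf("degenerate control triple at pair (%d, %d): collinear cues", t, t + 1L))
  list(prev = tp$points, next_ = tn$points, scenario = tp$scenario)
}

#' Register a whole series to its first frame
#'
#' The full pipeline: preprocess each frame to a binary mask, extract and
#' filter cue polygons, derive per-frame control points, estimate the pairwise
#' affine transform of every consecutive pair (frame t+1 onto frame t), chain
#' the transforms to the reference frame I_1, and warp every frame (grayscale
#' and RGB alike) into reference coordinates. Consecutive pairs whose cue
#' counts differ (interval boundaries) are bridged through the matched common
#' cues. Deterministic for fixed input and configuration.
#'
#' @param series a \linkS4class{FrameSeries} with T >= 2.
#' @param config a \code{\link{registrationConfig}}.
#' @return a \linkS4class{RegistrationResult}.
#' @export
registerSeries <- function(series, config = registrationConfig()) {
  stopifnot(is(series, "FrameSeries"))
  T <- nFrames(series)
  if (T < 2L) stop("registration needs at least 2 frames")
  d <- frameDims(series)
  max_shift <- if (is.null(config$max_shift)) d[2] / 2 else config$max_shift

  cues <- vector("list", T)
  J <- integer(T)
  for (t in seq_len(T)) {
    mask <- preprocessFrame(getFrame(series, t), config$preprocess)
    polys <- findPolygons(mask, t = t)
    cues[[t]] <- orderCues(filterCues(polys, config$ratio_threshold))
    J[t] <- length(cues[[t]])
  }
  if (all(J == 0L)) stop("no visual cues found in any frame: series unregistrable")

  pairwise <- vector("list", T - 1L)
  scenario <- rep(NA_character_, T)
  scenario[1] <- "-"
  for (t in seq_len(T - 1L)) {
    if (J[t] == 0L || J[t + 1L] == 0L) next
    pr <- tryCatch(
      .controlTriplePair(cues[[t]], cues[[t + 1L]], t, max_shift,
                         config$collinearity_tol),
      error = function(e) NULL)
    if (is.null(pr)) next
    pairwise[[t]] <- estimateAffine(src = pr$next_, dst = pr$prev)
    scenario[t + 1L] <- pr$scenario
  }
  if (all(vapply(pairwise, is.null, TRUE)))
    stop("no registrable consecutive pair in the series")

  chain <- chainToReference(pairwise)
  warped <- vector("list", T)
  for (t in seq_len(T)) {
    warped[[t]] <- if (chain$status[t] == "reference" || !config$warp)
                     getFrame(series, t)
                   else warpFrame(getFrame(series, t), chain$transforms[[t]],
                                  interpolation = config$interpolation)
  }
  params <- t(vapply(chain$transforms, function(A)
    c(A@m[1, ], A@m[2, ]), numeric(6)))
  log <- data.frame(t = seq_len(T), J = J, scenario = scenario,
                    a = params[, 1], b = params[, 2], tx = params[, 3],
                    c = params[, 4], d = params[, 5], ty = params[, 6],
                    status = chain$status)
  new("RegistrationResult", transforms = chain$transforms,
      series = frameSeries(warped),
      cues = lapply(cues, .centroidMatrix),
      log = log, method = "cueReg")
}
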