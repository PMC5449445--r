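#' @import methods
#' @importFrom stats rnorm runif quantile sd
#' @importFrom utils head read.csv write.csv
NULL

#' FrameSeries: an ordered time-lapse image series
#'
#' Container for an ordered series of frames sharing one set of image
#' dimensions. Each frame is either a grayscale matrix (rows x columns,
#' intensities on the 0--255 scale) or an RGB array (rows x columns x 3).
#' Frame \code{t} is the frame at the \code{t}-th position, \code{t = 1...T}.
#'
#' @slot frames list of numeric matrices and/or 3-channel arrays.
#' @export
setClass("FrameSeries", representation(frames = "list"))

setValidity("FrameSeries", function(object) {
  fr <- object@frames
  if (length(fr) == 0L) return("no frames")
  d0 <- dim(fr[[1]])[1:2]
  for (i in seq_along(fr)) {
    f <- fr[[i]]
    if (!is.numeric(f)) return(sprintf("frame %d is not numeric", i))
    nd <- length(dim(f))
    if (!(nd == 2L || (nd == 3L && dim(f)[3] == 3L)))
      return(sprintf("frame %d must be a matrix or an r x c x 3 array", i))
    if (!all(dim(f)[1:2] == d0))
      return(sprintf("frame %d has dimensions %dx%d, expected %dx%d",
                     i, dim(f)[1], dim(f)[2], d0[1], d0[2]))
  }
  TRUE
})

#' Construct a FrameSeries from a list of frames
#'
#' @param frames list of grayscale matrices or RGB (r x c x 3) arrays, in
#'   temporal order; position in the list defines the time index.
#' @return a \linkS4class{FrameSeries}.
#' @export
frameSeries <- function(frames) {
  if (!is.list(frames)) frames <- list(frames)
  new("FrameSeries", frames = frames)
}

#' @describeIn frameSeries number of frames T.
#' @param x a FrameSeries.
#' @export
nFrames <- function(x) length(x@frames)

#' @describeIn frameSeries image dimensions c(rows, columns).
#' @export
frameDims <- function(x) dim(x@frames[[1]])[1:2]

#' @describeIn frameSeries extract frame t (matrix or RGB array).
#' @param t time index, 1-based.
#' @export
getFrame <- function(x, t) {
  stopifnot(t >= 1, t <= nFrames(x))
  x@frames[[t]]
}

setMethod("show", "FrameSeries", function(object) {
  d <- frameDims(object)
  ch <- if (length(dim(object@frames[[1]])) == 3L) "RGB" else "grayscale"
  cat(sprintf("FrameSeries: T = %d frames, %d x %d px (%s)\n",
              nFrames(object), d[1], d[2], ch))
})

#' AffineTransform2D: a 2-D affine map
#'
#' A 2x3 matrix \code{[[a, b, tx], [c, d, ty]]} mapping a point (x, y) to
#' (a x + b y + tx, c x + d y + ty). Coordinates are 0-based pixel positions
#' with x along columns and y along rows, origin at the top-left pixel.
#'
#' @slot m numeric 2x3 matrix; the linear part must be invertible.
#' @export
setClass("AffineTransform2D", representation(m = "matrix"))

setValidity("AffineTransform2D", function(object) {
  m <- object@m
  if (!is.numeric(m) || !all(dim(m) == c(2L, 3L))) return("m must be a 2x3 matrix")
  if (any(!is.finite(m))) return("non-finite transform entries")
  if (abs(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]) <= 1e-12)
    return("linear part is singular")
  TRUE
})

setMethod("show", "AffineTransform2D", function(object) {
  m <- object@m
  cat(sprintf("AffineTransform2D: [%.6g %.6g | %.6g ; %.6g %.6g | %.6g]\n",
              m[1, 1], m[1, 2], m[1, 3], m[2, 1], m[2, 2], m[2, 3]))
})

#' RegistrationResult: per-frame transforms and warped frames
#'
#' @slot transforms list of \linkS4class{AffineTransform2D}, one per frame,
#'   each mapping that frame's coordinates onto reference (frame 1) coordinates;
#'   the first is the identity.
#' @slot series the warped \linkS4class{FrameSeries} in reference coordinates.
#' @slot cues list of per-frame cue centroid matrices (k x 2, x/y columns) as
#'   detected before warping, in \code{\link{orderCues}} order.
#' @slot log per-frame data.frame: t, J, scenario, transform parameters, status.
#' @slot method label of the producing method.
#' @export
setClass("RegistrationResult",
         representation(transforms = "list", series = "FrameSeries",
                        cues = "list", log = "data.frame", method = "character"))

setValidity("RegistrationResult", function(object) {
  if (length(object@transforms) != nFrames(object@series))
    return("one transform per frame required")
  if (!all(vapply(object@transforms, is, TRUE, "AffineTransform2D")))
    return("transforms must be AffineTransform2D")
  m1 <- object@transforms[[1]]@m
  if (max(abs(m1 - cbind(diag(2), c(0, 0)))) > 1e-9)
    return("reference-frame transform must be the identity")
  TRUE
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult (%s): %d frames, %d registered\n",
              object@method, nrow(object@log),
              sum(object@log$status %in% c("reference", "registered"))))
})

#' @describeIn RegistrationResult-class list of per-frame transforms.
#' @param x a RegistrationResult.
#' @export
frameTransforms <- function(x) x@transforms

#' @describeIn RegistrationResult-class the warped series.
#' @export
registeredSeries <- function(x) x@series

#' @describeIn RegistrationResult-class the per-frame log data.frame.
#' @export
registrationLog <- function(x) x@log

#' @describeIn RegistrationResult-class per-frame detected cue centroids
#'   (pre-warp coordinates).
#' @export
detectedCues <- function(x) x@cues

#' SyntheticScene: a microfluidics-like scene description
#'
#' Holds spacer layout, colony growth model, per-frame ground-truth rigid
#' trajectory and noise parameters for rendering a synthetic time series.
#' Built by \code{\link{makeScene}}; rendered by \code{\link{renderSeries}}.
#'
#' @slot canvas integer c(rows, columns).
#' @slot T number of frames.
#' @slot spacers data.frame: cx, cy (center, 0-based px), side, intensity.
#' @slot spacer_shape "square" or "disc".
#' @slot colony list: positions (cap x 2), orientations, initial, doubling_period,
#'   cap, cell_size (length, width px), intensity.
#' @slot trajectory list of \linkS4class{AffineTransform2D} mapping frame-1
#'   coordinates to frame-t coordinates; element 1 is the identity.
#' @slot background,gradient_amp,noise_sd rendering intensity parameters.
#' @slot schedule integer per-frame count of visible spacers.
#' @slot chamber_edges logical; draw straight chamber walls.
#' @slot rgb logical; render an RGB payload with colony fluorescence in green.
#' @slot seed RNG seed the scene was built from.
#' @export
setClass("SyntheticScene",
         representation(canvas = "integer", T = "integer", spacers = "data.frame",
                        spacer_shape = "character", colony = "list",
                        trajectory = "list", background = "numeric",
                        gradient_amp = "numeric", noise_sd = "numeric",
                        schedule = "integer", chamber_edges = "logical",
                        rgb = "logical", seed = "integer"))

setValidity("SyntheticScene", function(object) {
  if (any(object@canvas < 256L)) return("canvas must be at least 256 x 256")
  if (nrow(object@spacers) < 1L) return("at least one spacer required")
  if (object@T < 1L) return("T must be >= 1")
  if (length(object@trajectory) != object@T) return("one trajectory entry per frame")
  if (length(object@schedule) != object@T) return("one schedule entry per frame")
  if (any(object@schedule > nrow(object@spacers)))
    return("schedule exceeds spacer count")
  m1 <- object@trajectory[[1]]@m
  if (max(abs(m1 - cbind(diag(2), c(0, 0)))) > 0)
    return("trajectory must start at the identity")
  TRUE
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf("SyntheticScene: %d x %d px, T = %d, %d spacers (%s), noise sd = %g\n",
              object@canvas[1], object@canvas[2], object@T,
              nrow(object@spacers), object@spacer_shape, object@noise_sd))
})

#' GroundTruth: exact transforms and anchors of a rendered scene
#'
#' @slot transforms list of \linkS4class{AffineTransform2D} (frame-1 to frame-t).
#' @slot anchors list of k_t x 2 matrices of true spacer centers (x, y) in
#'   frame-t coordinates, for the spacers visible in frame t.
#' @slot colony list of n_t x 2 matrices of cell centers per frame.
#' @export
setClass("GroundTruth",
         representation(transforms = "list", anchors = "list", colony = "list"))

#' @describeIn GroundTruth-class true per-frame transforms.
#' @param x a GroundTruth.
#' @export
trueTransforms <- function(x) x@transforms

#' @describeIn GroundTruth-class true per-frame spacer anchors.
#' @export
trueAnchors <- function(x) x@anchors
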