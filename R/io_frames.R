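# Reading/writing ordered TIFF series and grayscale conversion.
#
# Repo-wide coordinate convention: (row, col), 0-based, origin top-left;
# x == col and y == row wherever transform math is involved.

#' Read an ordered TIFF series
#'
#' Reads uncompressed 8-bit TIFF images into a \linkS4class{FrameSeries}. The
#' caller-supplied order is authoritative (no lexicographic re-sorting); the
#' time index t is the position in \code{paths}.
#'
#' @param paths character vector of file paths, in temporal order.
#' @return a \linkS4class{FrameSeries}; pixel values on the 0--255 scale.
#' @export
readFrameSeries <- function(paths) {
  if (length(paths) == 0L) stop("no frames: empty path list")
  frames <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[i]
    if (!file.exists(p)) stop(sprintf("cannot read frame %d: no such file '%s'", i, p))
    img <- tryCatch(tiff::readTIFF(p),
                    error = function(e) stop(sprintf("cannot decode TIFF '%s': %s",
                                                     p, conditionMessage(e))))
    if (length(dim(img)) == 3L && dim(img)[3] >= 3L) img <- img[, , 1:3, drop = FALSE]
    frames[[i]] <- img * 255
  }
  d0 <- dim(frames[[1]])[1:2]
  for (i in seq_along(frames))
    if (!all(dim(frames[[i]])[1:2] == d0))
      stop(sprintf("dimension mismatch at frame %d ('%s'): %dx%d, expected %dx%d",
                   i, paths[i], dim(frames[[i]])[1], dim(frames[[i]])[2], d0[1], d0[2]))
  frameSeries(frames)
}

#' Write a FrameSeries as uncompressed TIFF files
#'
#' One 8-bit uncompressed TIFF per frame, named \code{<prefix>_<t>.tif} with a
#' zero-padded time index. Reading the files back reproduces the (rounded
#' 8-bit) pixel data exactly.
#'
#' @param series a \linkS4class{FrameSeries}.
#' @param dir output directory (created if absent).
#' @param prefix filename prefix.
#' @return character vector of written paths, in temporal order.
#' @export
writeFrameSeries <- function(series, dir, prefix = "frame") {
  stopifnot(is(series, "FrameSeries"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory '%s'", dir))
  T <- nFrames(series)
  width <- max(3L, nchar(as.character(T)))
  paths <- character(T)
  for (t in seq_len(T)) {
    f <- pmin(pmax(getFrame(series, t), 0), 255) / 255
    paths[t] <- file.path(dir, sprintf("%s_%0*d.tif", prefix, width, t))
    ok <- tryCatch({
      tiff::writeTIFF(f, paths[t], bits.per.sample = 8L, compression = "none")
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop(sprintf("cannot write '%s'", paths[t]))
  }
  paths
}

#' Convert a frame to grayscale
#'
#' Luminance-weighted RGB combination with the ITU-R 601 weights
#' (0.299, 0.587, 0.114), rounded to the nearest integer intensity.
#' Grayscale input is returned unchanged (idempotent).
#'
#' @param frame a grayscale matrix or an r x c x 3 RGB array (0--255 scale).
#' @return a grayscale matrix, same dimensions, values in [0, 255].
#' @export
toGrayscale <- function(frame) {
  nd <- length(dim(frame))
  if (nd == 2L) return(frame)
  if (nd == 3L && dim(frame)[3] == 3L) {
    g <- 0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
    return(round(pmin(pmax(g, 0), 255)))
  }
  stop(sprintf("frame must have 1 or 3 channels, got dim %s",
               paste(dim(frame), collapse = "x")))
}
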