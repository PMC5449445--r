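# Seven-step preprocessing pipeline: grayscale -> bilateral denoise -> CLAHE ->
# adaptive mean threshold -> dilation -> border clearing -> circular masking.
# Output is a binary mask exposing the chamber's spacer polygons.

#' Preprocessing configuration
#'
#' Parameters of the spacer-exposing preprocessing pipeline. Defaults follow
#' the moderate settings appropriate for 1004 x 1002 px phase-contrast frames:
#' bilateral filter with spatial and radiometric sigmas of 75 over a 10 px
#' neighbourhood diameter, CLAHE with 100 x 100 px tiles (a ~10 x 10 tile
#' grid on a 1004 px frame) and contrast limit 2,
#' adaptive mean thresholding over 11 x 11 px blocks with constant 2, a 3 x 3
#' dilation window, and a retained circle of diameter 0.6 r centred in the
#' image.
#'
#' @param sigma_spatial bilateral spatial closeness sigma (px).
#' @param sigma_range bilateral radiometric similarity sigma (intensity levels).
#' @param bilateral_diameter neighbourhood diameter (px) of the bilateral filter.
#' @param clahe_tile CLAHE tile side (px).
#' @param clahe_clip CLAHE contrast (clip) limit.
#' @param thresh_block adaptive-threshold block side (px); odd, >= 3.
#' @param thresh_const constant subtracted from the local mean.
#' @param dilation_window dilation structuring-element side (px); odd, >= 1.
#' @param mask_diameter_fraction retained-circle diameter as a fraction of the
#'   image row count r; in (0, 1.5].
#' @param invert if TRUE (default) foreground is darker than the local mean
#'   (pixel < mean - const), capturing dark spacer structures; if FALSE,
#'   foreground is brighter (pixel > mean + const).
#' @return a \code{PreprocessConfig} (validated named list).
#' @export
preprocessConfig <- function(sigma_spatial = 75, sigma_range = 75,
                             bilateral_diameter = 10, clahe_tile = 100,
                             clahe_clip = 2, thresh_block = 11,
                             thresh_const = 2, dilation_window = 3,
                             mask_diameter_fraction = 0.6, invert = TRUE) {
  if (thresh_block %% 2 == 0 || thresh_block < 3)
    stop("thresh_block must be odd and >= 3")
  if (dilation_window %% 2 == 0 || dilation_window < 1)
    stop("dilation_window must be odd and >= 1")
  if (mask_diameter_fraction <= 0 || mask_diameter_fraction > 1.5)
    stop("mask_diameter_fraction must be in (0, 1.5]")
  structure(list(sigma_spatial = sigma_spatial, sigma_range = sigma_range,
                 bilateral_diameter = as.integer(bilateral_diameter),
                 clahe_tile = as.integer(clahe_tile), clahe_clip = clahe_clip,
                 thresh_block = as.integer(thresh_block),
                 thresh_const = thresh_const,
                 dilation_window = as.integer(dilation_window),
                 mask_diameter_fraction = mask_diameter_fraction,
                 invert = isTRUE(invert)),
            class = "PreprocessConfig")
}

.assertGray <- function(frame, what) {
  if (length(dim(frame)) != 2L)
    stop(sprintf("%s requires a single-channel frame", what))
}

#' Edge-preserving bilateral denoising
#'
#' Smooths while preserving edges by weighting each neighbour with the product
#' of a spatial Gaussian and a radiometric (intensity-difference) Gaussian.
#' Borders are handled by reflection.
#'
#' @param frame grayscale matrix (0--255 scale).
#' @param cfg a \code{\link{preprocessConfig}}.
#' @return denoised matrix, same dimensions.
#' @export
denoiseBilateral <- function(frame, cfg = preprocessConfig()) {
  .assertGray(frame, "denoiseBilateral")
  bilateral_cpp(frame, cfg$sigma_spatial, cfg$sigma_range, cfg$bilateral_diameter)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Per-tile histogram equalization with bins clipped at the contrast limit and
#' the excess redistributed, bilinearly blended across tile boundaries. The
#' image is reflect-padded to a whole number of tiles and cropped back.
#'
#' @inheritParams denoiseBilateral
#' @return contrast-enhanced matrix, values in [0, 255].
#' @export
claheEqualize <- function(frame, cfg = preprocessConfig()) {
  .assertGray(frame, "claheEqualize")
  d <- dim(frame)
  tile <- cfg$clahe_tile
  if (tile > min(d)) stop("CLAHE tile size larger than image")
  pr <- ceiling(d[1] / tile) * tile
  pc <- ceiling(d[2] / tile) * tile
  padded <- .padReflect(frame, pr - d[1], pc - d[2])
  nx <- nrow(padded) / tile
  ny <- ncol(padded) / tile
  if (nx < 2 || ny < 2) stop("CLAHE needs at least a 2 x 2 tile grid")
  eq <- EBImage::clahe(EBImage::Image(padded / 255), nx = nx, ny = ny,
                       bins = 256, limit = cfg$clahe_clip)
  out <- EBImage::imageData(eq)[seq_len(d[1]), seq_len(d[2])] * 255
  pmin(pmax(out, 0), 255)
}

# reflect-pad bottom/right by (dr, dc) rows/cols
.padReflect <- function(m, dr, dc) {
  if (dr > 0) m <- rbind(m, m[nrow(m) - seq_len(dr), , drop = FALSE])
  if (dc > 0) m <- cbind(m, m[, ncol(m) - seq_len(dc), drop = FALSE])
  m
}

#' Adaptive mean thresholding
#'
#' Binarizes against the local block mean: with \code{invert = TRUE} (default)
#' a pixel is foreground iff its intensity is strictly below
#' (local mean - const), capturing structures darker than their surroundings;
#' with \code{invert = FALSE}, strictly above (local mean + const). The local
#' mean is computed over a block x block neighbourhood with reflected borders.
#'
#' @inheritParams denoiseBilateral
#' @return logical matrix (TRUE = foreground).
#' @export
adaptiveMeanThreshold <- function(frame, cfg = preprocessConfig()) {
  .assertGray(frame, "adaptiveMeanThreshold")
  if (cfg$thresh_block %% 2 == 0) stop("thresh_block must be odd")
  mu <- .boxMean(frame, cfg$thresh_block)
  if (cfg$invert) frame < mu - cfg$thresh_const else frame > mu + cfg$thresh_const
}

# local mean over an odd b x b block, reflect-101 padding, via integral image
.boxMean <- function(m, b) {
  rad <- (b - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(rad) + 1L), seq_len(nr), nr - seq_len(rad))
  ci <- c(rev(seq_len(rad) + 1L), seq_len(nc), nc - seq_len(rad))
  p <- m[ri, ci, drop = FALSE]
  s <- apply(p, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  s <- rbind(0, cbind(0, s))
  i1 <- seq_len(nr); j1 <- seq_len(nc)
  # window rows i..i+b-1 of padded == original row i - rad .. i + rad
  tot <- s[i1 + b, j1 + b, drop = FALSE] - s[i1, j1 + b, drop = FALSE] -
    s[i1 + b, j1, drop = FALSE] + s[i1, j1, drop = FALSE]
  tot / (b * b)
}

#' Morphological dilation of a binary mask
#'
#' Square structuring element of side \code{dilation_window}; the foreground
#' never shrinks.
#'
#' @param mask logical matrix.
#' @param cfg a \code{\link{preprocessConfig}}.
#' @return logical matrix, superset of the input foreground.
#' @export
dilateMask <- function(mask, cfg = preprocessConfig()) {
  stopifnot(is.logical(mask), length(dim(mask)) == 2L)
  w <- cfg$dilation_window
  if (w <= 1L) return(mask)
  kern <- EBImage::makeBrush(w, shape = "box")
  out <- EBImage::dilate(EBImage::Image(mask * 1), kern)
  EBImage::imageData(out) > 0
}

#' Label connected components (8-connectivity)
#'
#' Integer labels 1..n in raster-scan discovery order; 0 is background.
#' Diagonal neighbours belong to the same component.
#'
#' @param mask logical matrix.
#' @return integer matrix of labels.
#' @export
labelComponents <- function(mask) {
  stopifnot(is.logical(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n > 1L) {
    # bwlabel is 4-connected; merge labels across diagonal adjacencies
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
    keep1 <- a1 > 0L & b1 > 0L & a1 != b1
    keep2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2])))
    if (nrow(pairs) > 0L) {
      parent <- seq_len(n)
      find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(n), find, integer(1))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  # renumber by first occurrence in row-major (raster) order
  if (max(lab) > 0L) {
    nr <- nrow(lab)
    fg <- which(lab > 0L)
    rm_idx <- ((fg - 1L) %% nr) * ncol(lab) + ((fg - 1L) %/% nr)  # row-major rank
    first <- tapply(rm_idx, lab[fg], min)
    old <- as.integer(names(first))
    newid <- integer(max(old))
    newid[old[order(first)]] <- seq_along(old)
    lab[lab > 0L] <- newid[lab[lab > 0L]]
  }
  lab
}

#' Remove components touching the image border
#'
#' Every 8-connected component with a pixel on any image border is set to
#' background; interior components are untouched.
#'
#' @param mask logical matrix.
#' @return logical matrix, subset of the input foreground.
#' @export
clearBorder <- function(mask) {
  lab <- labelComponents(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  if (length(border)) mask[lab %in% border] <- FALSE
  mask
}

#' Keep only components fully inside the central circle
#'
#' A circle of diameter \code{mask_diameter_fraction * r} centred at
#' (r/2, c/2); any 8-connected component with at least one pixel strictly
#' outside the circle is removed entirely (component-level decision, no pixel
#' clipping).
#'
#' @inheritParams dilateMask
#' @return logical matrix, subset of the input foreground.
#' @export
applyCircleMask <- function(mask, cfg = preprocessConfig()) {
  nr <- nrow(mask); nc <- ncol(mask)
  radius <- cfg$mask_diameter_fraction * nr / 2
  cy <- nr / 2; cx <- nc / 2
  yy <- (seq_len(nr) - 0.5) - cy    # pixel centers, 0-based + 0.5
  xx <- (seq_len(nc) - 0.5) - cx
  outside <- outer(yy^2, xx^2, "+") > radius^2
  lab <- labelComponents(mask)
  bad <- unique(lab[outside & lab > 0L])
  if (length(bad)) mask[lab %in% bad] <- FALSE
  mask
}

#' Run the full preprocessing pipeline on one frame
#'
#' Composition, in order: grayscale conversion (if RGB), bilateral denoising,
#' CLAHE, adaptive mean thresholding, dilation, border clearing, circular
#' masking. Deterministic for a fixed (frame, config).
#'
#' @param frame grayscale matrix or RGB array.
#' @param cfg a \code{\link{preprocessConfig}}.
#' @return logical matrix: the binary mask exposing candidate spacer polygons.
#' @export
preprocessFrame <- function(frame, cfg = preprocessConfig()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("preprocess stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
  }
  g <- stage("grayscale", toGrayscale(frame))
  g <- stage("bilateral", denoiseBilateral(g, cfg))
  g <- stage("clahe", claheEqualize(g, cfg))
  m <- stage("threshold", adaptiveMeanThreshold(g, cfg))
  m <- stage("dilate", dilateMask(m, cfg))
  m <- stage("clear_border", clearBorder(m))
  stage("circle_mask", applyCircleMask(m, cfg))
}
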