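# Registration quality metrics (cue-position rmsd, image closeness), timing,
# and the probabilistic Hough transform (PHT) baseline for benchmarking.

#' Root mean square difference of cue positions vs. the reference frame
#'
#' Per frame, matches that frame's cue anchor points onto the reference
#' frame's anchors (minimal-displacement assignment) and computes the RMS of
#' the matched Euclidean distances, in px. The reported mean is taken over
#' frames 2..T (the reference's self-comparison is excluded); frames with no
#' matchable cues yield NA and are excluded from the mean.
#'
#' @param anchors list of k_t x 2 matrices (x, y), one per frame; element 1 is
#'   conventionally the reference frame itself.
#' @param reference k x 2 matrix of reference anchors; defaults to
#'   \code{anchors[[1]]}.
#' @return list with \code{per_frame} (numeric, length T) and \code{mean}.
#' @export
cueRmsd <- function(anchors, reference = anchors[[1]]) {
  T <- length(anchors)
  per <- rep(NA_real_, T)
  for (t in seq_len(T)) {
    a <- anchors[[t]]
    if (is.null(a) || nrow(a) == 0L || nrow(reference) == 0L) next
    m <- matchCues(reference, a)
    per[t] <- sqrt(mean(m$dist^2))
  }
  usable <- per[-1]
  list(per_frame = per,
       mean = if (all(is.na(usable))) NA_real_ else mean(usable, na.rm = TRUE))
}

#' Image closeness
#'
#' The registration quality score \eqn{\Phi = 100 - rmsd \cdot 100 / r}, in
#' percent, where r is the image row count. Affine and strictly decreasing in
#' the rmsd; 100 for a perfect registration.
#'
#' @param mean_rmsd average cue-position rmsd in px (>= 0).
#' @param r image row count in px (> 0).
#' @return closeness in percent.
#' @export
imageCloseness <- function(mean_rmsd, r) {
  if (r <= 0) stop("r must be positive")
  if (any(mean_rmsd < 0)) stop("rmsd must be non-negative")
  100 - mean_rmsd * 100 / r
}

#' Mean elapsed processing time per frame
#'
#' @param samples numeric vector of per-frame wall-clock timings, seconds.
#' @return mean seconds per frame.
#' @export
elapsedPerFrame <- function(samples) {
  stopifnot(length(samples) >= 1L)
  mean(samples)
}

#' Detect cue anchor points in every frame
#'
#' Runs the preprocessing + polygon + ratio-filter pipeline on each frame and
#' returns the ordered cue centroids, without registering anything. Used for
#' evaluation (before/after comparisons) and by \code{\link{benchmarkMethods}}.
#'
#' @param series a \linkS4class{FrameSeries}.
#' @param config a \code{\link{registrationConfig}}.
#' @return list of k_t x 2 centroid matrices, one per frame.
#' @export
detectCues <- function(series, config = registrationConfig()) {
  lapply(seq_len(nFrames(series)), function(t) {
    mask <- preprocessFrame(getFrame(series, t), config$preprocess)
    polys <- orderCues(filterCues(findPolygons(mask, t = t), config$ratio_threshold))
    .centroidMatrix(polys)
  })
}

#' Evaluate a registration against frame-1 cue positions
#'
#' Applies each frame's recovered transform to that frame's detected cue
#' anchors and computes the rmsd against the reference frame's anchors, plus
#' the same quantity without any transform ("before"). Image closeness is
#' derived from both with r = image row count.
#'
#' @param result a \linkS4class{RegistrationResult}.
#' @param cues optional list of per-frame cue centroid matrices; defaults to
#'   the cues detected during registration (\code{detectedCues(result)}).
#' @param r image row count; defaults to the series' row dimension.
#' @return list: rmsd_before, rmsd_after, closeness_before, closeness_after,
#'   per_frame_rmsd (after).
#' @export
evaluateRegistration <- function(result, cues = NULL, r = NULL) {
  if (is.null(cues)) cues <- detectedCues(result)
  if (length(cues) == 0L) stop("no cue sets available for evaluation")
  if (is.null(r)) r <- frameDims(registeredSeries(result))[1]
  tr <- frameTransforms(result)
  after <- lapply(seq_along(cues), function(t) {
    a <- cues[[t]]
    if (is.null(a) || nrow(a) == 0L) return(a)
    applyAffine(tr[[t]], a)
  })
  rb <- cueRmsd(cues)
  ra <- cueRmsd(after, reference = cues[[1]])
  list(rmsd_before = rb$mean, rmsd_after = ra$mean,
       closeness_before = imageCloseness(rb$mean, r),
       closeness_after = imageCloseness(ra$mean, r),
       per_frame_rmsd = ra$per_frame)
}

# ---- PHT baseline ----------------------------------------------------------

# gradient-magnitude edge map (Gaussian blur + central differences)
.edgeMap <- function(gray, quantile_cut = 0.99, min_mag = 8) {
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(gray), sigma = 1.5))
  nr <- nrow(sm); nc <- ncol(sm)
  gx <- (sm[, c(2:nc, nc)] - sm[, c(1, 1:(nc - 1))]) / 2
  gy <- (sm[c(2:nr, nr), ] - sm[c(1, 1:(nr - 1)), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  mag[c(1, 2, nr - 1, nr), ] <- 0
  mag[, c(1, 2, nc - 1, nc)] <- 0
  thr <- max(quantile(mag, quantile_cut), min_mag)
  which(mag > thr, arr.ind = TRUE)  # (row, col) 1-based
}

# Hough line accumulator over sampled edge points; returns peak lines.
.houghPeaks <- function(pts_xy, dims, n_sample = 4000, rho_step = 2,
                        min_votes = 100, max_lines = 6, seed = 1) {
  n <- nrow(pts_xy)
  if (n > n_sample) {
    rs <- .Random.seed_save()
    on.exit(.Random.seed_restore(rs), add = TRUE)
    set.seed(seed)
    pts_s <- pts_xy[sample.int(n, n_sample), , drop = FALSE]
  } else pts_s <- pts_xy
  thetas <- seq(0, 179) * pi / 180
  diag_len <- sqrt(sum(dims^2))
  nbins <- ceiling(2 * diag_len / rho_step) + 1L
  acc <- matrix(0L, length(thetas), nbins)
  for (i in seq_along(thetas)) {
    rho <- pts_s[, 1] * cos(thetas[i]) + pts_s[, 2] * sin(thetas[i])
    bins <- floor((rho + diag_len) / rho_step) + 1L
    acc[i, ] <- tabulate(bins, nbins)
  }
  peaks <- list()
  nth <- length(thetas)
  for (k in seq_len(max_lines)) {
    mx <- max(acc)
    if (mx < min_votes) break
    idx <- which(acc == mx, arr.ind = TRUE)[1, ]
    th_i <- idx[1]; rh_i <- idx[2]
    peaks[[k]] <- list(theta = thetas[th_i],
                       rho = (rh_i - 0.5) * rho_step - diag_len,
                       votes = mx)
    # suppress the peak neighbourhood; a wrapped theta index refers to the
    # same line with negated rho, so the mirrored rho band is zeroed there
    for (dth in -6:6) {
      ti <- th_i + dth
      mirrored <- ti < 1L || ti > nth
      ti <- ((ti - 1L) %% nth) + 1L
      ri <- if (mirrored) nbins + 1L - rh_i else rh_i
      acc[ti, pmax(1L, pmin(nbins, ri + seq(-6L, 6L)))] <- 0L
    }
  }
  peaks
}

# refine a quantized Hough line by total-least-squares (PCA) on its inlier
# edge points. Two passes: a wide band first, so that a physical line drawn
# with finite width contributes BOTH of its gradient edges (the fit then
# settles on the stable centerline instead of flipping between the two
# edges across frames), then a tighter band around the refined line.
.refineLine <- function(pts_xy, theta, rho, bands = c(5, 3)) {
  for (band in bands) {
    d <- pts_xy[, 1] * cos(theta) + pts_xy[, 2] * sin(theta) - rho
    sel <- pts_xy[abs(d) <= band, , drop = FALSE]
    if (nrow(sel) < 10L) break
    ctr <- colMeans(sel)
    sv <- svd(sweep(sel, 2, ctr))
    nrm <- sv$v[, 2]                     # normal = least-variance direction
    th <- atan2(nrm[2], nrm[1])
    rh <- sum(ctr * nrm)
    if (th < 0) { th <- th + pi; rh <- -rh }
    if (th >= pi) { th <- th - pi; rh <- -rh }
    theta <- th; rho <- rh
  }
  list(theta = theta, rho = rho)
}

# pairwise intersections of sufficiently non-parallel detected lines, scored
# by their vote sums; at most four points, de-duplicated and inside the field
.lineIntersections <- function(peaks, dims, min_angle_sep, max_points = 4) {
  pts <- NULL; score <- NULL
  n <- length(peaks)
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- peaks[[i]]; b <- peaks[[j]]
    dth <- abs(a$theta - b$theta); dth <- min(dth, pi - dth)
    if (dth < min_angle_sep) next
    M <- rbind(c(cos(a$theta), sin(a$theta)), c(cos(b$theta), sin(b$theta)))
    p <- tryCatch(drop(solve(M, c(a$rho, b$rho))), error = function(e) NULL)
    if (is.null(p)) next
    if (p[1] < -50 || p[2] < -50 || p[1] > dims[2] + 50 || p[2] > dims[1] + 50) next
    pts <- rbind(pts, p); score <- c(score, a$votes + b$votes)
  }
  if (is.null(pts)) return(NULL)
  ord <- order(-score)
  keep <- NULL
  for (k in ord) {
    if (!is.null(keep) &&
        any(sqrt(rowSums((pts[keep, , drop = FALSE] -
                          matrix(pts[k, ], length(keep), 2, byrow = TRUE))^2)) < 20))
      next
    keep <- c(keep, k)
    if (length(keep) >= max_points) break
  }
  pts[keep, , drop = FALSE]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(rs) {
  if (is.null(rs)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", rs, envir = globalenv())
}

# least-squares rigid (rotation + translation, scale = 1) fit src -> dst
.rigidFit <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  H <- t(sweep(src, 2, cs)) %*% sweep(dst, 2, cd)
  sv <- svd(H)
  R <- sv$v %*% t(sv$u)
  if (det(R) < 0) {
    V <- sv$v; V[, 2] <- -V[, 2]
    R <- V %*% t(sv$u)
  }
  tr <- cd - R %*% cs
  affineTransform(cbind(R, tr))
}

#' Probabilistic Hough transform baseline registration
#'
#' The classical line-based baseline: (a) reduce each frame to an edge set,
#' (b) detect straight lines with a (sampled) Hough accumulator, (c) retain a
#' best-fitted subset of up to four points (the intersections of the
#' strongest, sufficiently non-parallel lines -- for a rectangular chamber,
#' its corners), and (d) fit a least-squares rigid transform (rotation +
#' translation, scale locked to 1) mapping each frame's points onto the
#' reference frame's. Fails with a "no lines detected" error whenever a frame
#' yields fewer than two strong lines or fewer than two usable intersection
#' points, which is the expected behaviour on scenes without straight
#' structures.
#'
#' @param series a \linkS4class{FrameSeries} with T >= 2.
#' @param min_votes minimum Hough votes for a line peak; NULL (default) picks
#'   max(100, 4% of the sampled edge points), which separates genuine wall
#'   lines from the tangent alignments of curved structures.
#' @param min_angle_sep minimum angular separation (radians) between lines
#'   whose intersection is used.
#' @param seed seed for the probabilistic edge-point sampling.
#' @return a \linkS4class{RegistrationResult} with method "PHT".
#' @export
phtRegister <- function(series, min_votes = NULL, min_angle_sep = 20 * pi / 180,
                        seed = 1) {
  stopifnot(is(series, "FrameSeries"))
  T <- nFrames(series)
  if (T < 2L) stop("registration needs at least 2 frames")
  d <- frameDims(series)
  max_shift <- d[2] / 2

  frame_pts <- vector("list", T)
  for (t in seq_len(T)) {
    gray <- toGrayscale(getFrame(series, t))
    e <- .edgeMap(gray)
    if (nrow(e) < 10L)
      stop(sprintf("no lines detected in frame %d: too few edge points", t))
    pts <- cbind(x = e[, 2] - 1, y = e[, 1] - 1)
    mv <- if (is.null(min_votes)) max(100, 0.04 * min(nrow(pts), 4000)) else min_votes
    peaks <- .houghPeaks(pts, d, min_votes = mv, seed = seed + t)
    if (length(peaks) < 2L)
      stop(sprintf("no lines detected in frame %d: %d strong Hough peak(s), need 2",
                   t, length(peaks)))
    peaks <- lapply(peaks, function(p) {
      r <- .refineLine(pts, p$theta, p$rho)
      list(theta = r$theta, rho = r$rho, votes = p$votes)
    })
    ip <- .lineIntersections(peaks, d, min_angle_sep)
    if (is.null(ip) || nrow(ip) < 2L)
      stop(sprintf("no lines detected in frame %d: no usable line intersections", t))
    frame_pts[[t]] <- ip
  }

  ref_pts <- frame_pts[[1]]
  transforms <- vector("list", T)
  transforms[[1]] <- identityAffine()
  status <- c("reference", rep("registered", T - 1L))
  for (t in 2:T) {
    cand <- frame_pts[[t]]
    # match each reference point to its nearest candidate, uniquely
    m <- matchCues(ref_pts, cand, max_shift = max_shift)
    if (nrow(m) < 2L)
      stop(sprintf("no lines detected in frame %d: reference points lost", t))
    transforms[[t]] <- .rigidFit(cand[m$next_, , drop = FALSE],
                                 ref_pts[m$prev, , drop = FALSE])
  }

  warped <- vector("list", T)
  warped[[1]] <- getFrame(series, 1)
  for (t in 2:T)
    warped[[t]] <- warpFrame(getFrame(series, t), transforms[[t]])
  params <- t(vapply(transforms, function(A) c(A@m[1, ], A@m[2, ]), numeric(6)))
  log <- data.frame(t = seq_len(T), J = NA_integer_, scenario = "pht",
                    a = params[, 1], b = params[, 2], tx = params[, 3],
                    c = params[, 4], d = params[, 5], ty = params[, 6],
                    status = status)
  new("RegistrationResult", transforms = transforms,
      series = frameSeries(warped), cues = list(), log = log, method = "PHT")
}

#' Benchmark registration methods on one series
#'
#' Runs each requested method, times it, and evaluates the cue-position rmsd
#' and image closeness of its transforms against the cue anchors detected by
#' the visual-cue pipeline on the original series. Method failures are
#' recorded with status "failed" (metrics NA), never as zeros.
#'
#' @param series a \linkS4class{FrameSeries}.
#' @param methods character subset of c("cueReg", "PHT").
#' @param dataset label written into the report.
#' @param config a \code{\link{registrationConfig}} for the cue pipeline.
#' @return data.frame: dataset, method, mean_elapsed_s, mean_rmsd_px,
#'   closeness_pct, status.
#' @export
benchmarkMethods <- function(series, methods = c("cueReg", "PHT"),
                             dataset = "synthetic",
                             config = registrationConfig()) {
  stopifnot(length(methods) >= 1L)
  T <- nFrames(series)
  r <- frameDims(series)[1]
  cues <- detectCues(series, config)
  rows <- lapply(methods, function(meth) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      switch(meth,
             cueReg = registerSeries(series, config),
             PHT = phtRegister(series),
             stop(sprintf("unknown method '%s'", meth))),
      error = function(e) e)
    elapsed <- (proc.time()[["elapsed"]] - t0) / T
    if (inherits(res, "error"))
      return(data.frame(dataset = dataset, method = meth,
                        mean_elapsed_s = NA_real_, mean_rmsd_px = NA_real_,
                        closeness_pct = NA_real_, status = "failed"))
    ev <- evaluateRegistration(res, cues = cues, r = r)
    data.frame(dataset = dataset, method = meth, mean_elapsed_s = elapsed,
               mean_rmsd_px = ev$rmsd_after, closeness_pct = ev$closeness_after,
               status = "ok")
  })
  do.call(rbind, rows)
}
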