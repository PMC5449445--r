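# Synthetic microfluidics-like scenes: square-like spacer cues fixed to the
# chamber, an exponentially doubling bacterial colony as a structured
# distractor, slow rigid drift of the whole field, background gradient and
# additive Gaussian noise, with exact ground truth by construction.

#' Build a synthetic scene
#'
#' The default preset emulates a 1004 x 1002 px phase-contrast chamber series:
#' four dark square spacers of side 90--120 px arranged around the chamber
#' center (inside the central retained circle), a colony of bright rod-shaped
#' cells doubling every 10 frames from a single cell (capped at 300
#' individuals), a cumulative random-walk drift of at most 3 px translation
#' and 0.3 degrees rotation per frame, a mild background gradient and additive
#' Gaussian noise of sigma 8 intensity levels. All randomness flows from
#' \code{seed}; the same (arguments, seed) give a bit-identical scene.
#'
#' @param canvas c(rows, columns), each >= 256.
#' @param frames number of frames T.
#' @param n_spacers number of spacer polygons.
#' @param spacer_side length-2 range of spacer sides, px (sides above 80 px
#'   keep the perimeter-to-area ratio of a square below the 0.05 cue cutoff).
#' @param spacer_shape "square" (straight-edged cues) or "disc" (line-free
#'   cues, used to exercise line-based baselines' failure mode).
#' @param spacer_intensity,background,gradient_amp intensity levels (0--255).
#' @param spacer_ring_radius distance of spacer centers from the canvas
#'   center; NULL = a default that keeps spacers inside the central circle of
#'   diameter 0.6 r with a drift margin.
#' @param colony list overriding any of: initial (cells at t = 1),
#'   doubling_period (frames), cap, cell_size c(length, width) px, intensity,
#'   origin c(x, y).
#' @param max_step,max_rot_deg per-frame drift bounds (px, degrees).
#' @param noise_sd additive Gaussian noise sigma, intensity levels.
#' @param cue_count_schedule optional integer vector (length \code{frames}) of
#'   visible-spacer counts per frame; NULL = all spacers visible throughout.
#' @param chamber_edges draw straight chamber walls (a dark rectangle), giving
#'   line-based methods something to work with.
#' @param rgb render an RGB payload (colony fluorescence added in green).
#' @param seed integer RNG seed.
#' @return a \linkS4class{SyntheticScene}.
#' @export
makeScene <- function(canvas = c(1004, 1002), frames = 30, n_spacers = 4,
                      spacer_side = c(90, 120), spacer_shape = c("square", "disc"),
                      spacer_intensity = 90, background = 150, gradient_amp = 20,
                      spacer_ring_radius = NULL, colony = list(),
                      max_step = 3, max_rot_deg = 0.3, noise_sd = 8,
                      cue_count_schedule = NULL, chamber_edges = FALSE,
                      rgb = TRUE, seed = 1) {
  spacer_shape <- match.arg(spacer_shape)
  canvas <- as.integer(canvas)
  if (any(canvas < 256L)) stop("canvas must be at least 256 x 256")
  if (n_spacers < 1L) stop("at least one spacer required")
  frames <- as.integer(frames)

  col_def <- list(initial = 1L, doubling_period = 10L, cap = 300L,
                  cell_size = c(24, 8), intensity = 210,
                  origin = c((canvas[2] - 1) / 2, (canvas[1] - 1) / 2))
  col_def[names(colony)] <- colony

  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs), add = TRUE)
  set.seed(as.integer(seed))

  r <- canvas[1]; cc <- canvas[2]
  smax <- max(spacer_side)
  if (is.null(spacer_ring_radius))
    spacer_ring_radius <- max(0.3 * r - 0.75 * smax - 25, 0.1 * r)
  ang0 <- runif(1, 0, 2 * pi)
  angles <- ang0 + (seq_len(n_spacers) - 1) * 2 * pi / n_spacers
  cx <- (cc - 1) / 2 + spacer_ring_radius * cos(angles) + runif(n_spacers, -8, 8)
  cy <- (r - 1) / 2 + spacer_ring_radius * sin(angles) + runif(n_spacers, -8, 8)
  sides <- runif(n_spacers, spacer_side[1], max(spacer_side))
  spacers <- data.frame(cx = cx, cy = cy, side = sides,
                        intensity = spacer_intensity)

  half <- sides / 2 + 2
  if (any(abs(cx - col_def$origin[1]) <= half & abs(cy - col_def$origin[2]) <= half))
    stop("infeasible scene: a spacer overlaps the colony seed position")

  # colony layout: sunflower packing around the origin with jitter
  cap <- col_def$cap
  colony_radius <- sqrt(cap * prod(col_def$cell_size) * 0.8 / pi)
  idx <- seq_len(cap)
  golden <- pi * (3 - sqrt(5))
  rad <- colony_radius * sqrt((idx - 0.5) / cap)
  th <- idx * golden + runif(cap, -0.2, 0.2)
  pos <- cbind(x = col_def$origin[1] + rad * cos(th) + runif(cap, -2, 2),
               y = col_def$origin[2] + rad * sin(th) + runif(cap, -2, 2))
  col_def$positions <- pos
  col_def$orientations <- runif(cap, 0, pi)

  # cumulative random-walk rigid drift about the canvas center
  center <- c((cc - 1) / 2, (r - 1) / 2)
  trajectory <- vector("list", frames)
  trajectory[[1]] <- identityAffine()
  if (frames > 1L) {
    for (t in 2:frames) {
      step <- composeAffine(
        translationAffine(runif(1, -max_step, max_step),
                          runif(1, -max_step, max_step)),
        rotationAffine(runif(1, -1, 1) * max_rot_deg * pi / 180, center))
      trajectory[[t]] <- composeAffine(step, trajectory[[t - 1L]])
    }
  }

  schedule <- if (is.null(cue_count_schedule)) rep(n_spacers, frames)
              else as.integer(cue_count_schedule)
  if (length(schedule) != frames)
    stop("cue_count_schedule must have one entry per frame")

  new("SyntheticScene", canvas = canvas, T = frames, spacers = spacers,
      spacer_shape = spacer_shape, colony = col_def, trajectory = trajectory,
      background = background, gradient_amp = gradient_amp,
      noise_sd = noise_sd, schedule = as.integer(schedule),
      chamber_edges = isTRUE(chamber_edges), rgb = isTRUE(rgb),
      seed = as.integer(seed))
}

#' Render a scene into a frame series with ground truth
#'
#' Frame t shows the frame-1 content mapped by the scene's trajectory: the
#' background gradient, spacers and chamber walls move rigidly with the
#' chamber, the colony doubles per period (capped), and per-frame sensor
#' noise is added after the geometric mapping. Two renders of the same scene
#' are bit-identical.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param noise_free if TRUE, omit the additive noise (useful for oracles).
#' @return list with \code{series} (a \linkS4class{FrameSeries}) and
#'   \code{truth} (a \linkS4class{GroundTruth}).
#' @export
renderSeries <- function(scene, noise_free = FALSE) {
  stopifnot(is(scene, "SyntheticScene"))
  r <- scene@canvas[1]; cc <- scene@canvas[2]
  T <- scene@T
  X <- matrix(rep(0:(cc - 1), each = r), r, cc)
  Y <- matrix(rep(0:(r - 1), cc), r, cc)

  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs), add = TRUE)
  set.seed(scene@seed %% 1000000L + 77771L)

  cell_half <- scene@colony$cell_size / 2
  frames <- vector("list", T)
  anchors <- vector("list", T)
  colony_pos <- vector("list", T)

  for (t in seq_len(T)) {
    Tt <- scene@trajectory[[t]]
    Mi <- invertAffine(Tt)@m
    U <- Mi[1, 1] * X + Mi[1, 2] * Y + Mi[1, 3]
    V <- Mi[2, 1] * X + Mi[2, 2] * Y + Mi[2, 3]

    img <- scene@background +
      scene@gradient_amp * ((U / (cc - 1) + V / (r - 1)) - 1)

    if (scene@chamber_edges) {
      x0 <- 0.15 * cc; x1 <- 0.85 * cc; y0 <- 0.15 * r; y1 <- 0.85 * r
      inx <- U >= x0 - 1.5 & U <= x1 + 1.5
      iny <- V >= y0 - 1.5 & V <= y1 + 1.5
      wall <- ((abs(U - x0) <= 1.5 | abs(U - x1) <= 1.5) & iny) |
              ((abs(V - y0) <= 1.5 | abs(V - y1) <= 1.5) & inx)
      img[wall] <- 70
    }

    k <- scene@schedule[t]
    if (k > 0L) for (s in seq_len(k)) {
      sp <- scene@spacers[s, ]
      sel <- if (scene@spacer_shape == "square") {
        abs(U - sp$cx) <= sp$side / 2 & abs(V - sp$cy) <= sp$side / 2
      } else {
        (U - sp$cx)^2 + (V - sp$cy)^2 <= (sp$side / 2)^2
      }
      img[sel] <- sp$intensity
    }

    n_t <- min(scene@colony$cap,
               scene@colony$initial * 2^((t - 1) %/% scene@colony$doubling_period))
    rot_t <- atan2(Tt@m[2, 1], Tt@m[1, 1])
    pos_t <- applyAffine(Tt, scene@colony$positions[seq_len(n_t), , drop = FALSE])
    colony_add <- matrix(0, r, cc)
    for (i in seq_len(n_t)) {
      ctr <- pos_t[i, ]
      ai <- scene@colony$orientations[i] + rot_t
      hw <- cell_half[1] + 2
      xr <- max(1L, floor(ctr[1] - hw) + 1L):min(cc, ceiling(ctr[1] + hw) + 1L)
      yr <- max(1L, floor(ctr[2] - hw) + 1L):min(r, ceiling(ctr[2] + hw) + 1L)
      dx <- outer(rep(1, length(yr)), xr - 1 - ctr[1])
      dy <- outer(yr - 1 - ctr[2], rep(1, length(xr)))
      du <- dx * cos(ai) + dy * sin(ai)
      dv <- -dx * sin(ai) + dy * cos(ai)
      inside <- (du / cell_half[1])^2 + (dv / cell_half[2])^2 <= 1
      sub <- colony_add[yr, xr, drop = FALSE]
      sub[inside] <- 60
      colony_add[yr, xr] <- sub
      sub2 <- img[yr, xr, drop = FALSE]
      sub2[inside] <- scene@colony$intensity
      img[yr, xr] <- sub2
    }

    if (!noise_free && scene@noise_sd > 0)
      img <- img + rnorm(r * cc, 0, scene@noise_sd)
    img <- round(pmin(pmax(img, 0), 255))

    if (scene@rgb) {
      arr <- array(0, dim = c(r, cc, 3))
      arr[, , 1] <- img
      arr[, , 2] <- pmin(img + colony_add, 255)
      arr[, , 3] <- img
      frames[[t]] <- arr
    } else {
      frames[[t]] <- img
    }

    ctrs <- unname(as.matrix(scene@spacers[seq_len(max(k, 0L)), c("cx", "cy"),
                                           drop = FALSE]))
    dimnames(ctrs) <- list(NULL, c("x", "y"))
    anchors[[t]] <- if (k > 0L) applyAffine(Tt, ctrs) else ctrs[0, , drop = FALSE]
    colony_pos[[t]] <- pos_t
  }

  list(series = frameSeries(frames),
       truth = new("GroundTruth", transforms = scene@trajectory,
                   anchors = anchors, colony = colony_pos))
}

#' Mean recovery error of a registration against ground truth
#'
#' For every non-reference frame, maps the true frame-t spacer anchors through
#' the recovered frame-to-reference transform and measures the distance to the
#' true frame-1 anchor positions; returns the mean over all frames and cues,
#' in px. Only the spacers visible in both the frame and the reference are
#' used.
#'
#' @param result a \linkS4class{RegistrationResult}.
#' @param truth a \linkS4class{GroundTruth}.
#' @return mean anchor recovery error, px.
#' @export
recoveryError <- function(result, truth) {
  tr <- frameTransforms(result)
  ref <- truth@anchors[[1]]
  errs <- c()
  for (t in 2:length(tr)) {
    at <- truth@anchors[[t]]
    k <- min(nrow(at), nrow(ref))
    if (k == 0L) next
    mapped <- applyAffine(tr[[t]], at[seq_len(k), , drop = FALSE])
    errs <- c(errs, sqrt(rowSums((mapped - ref[seq_len(k), , drop = FALSE])^2)))
  }
  mean(errs)
}
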