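# Independent brute-force oracles used by the property-style tests. These are
# deliberately naive (double loops, exhaustive enumeration) and share no code
# with the package implementation.

# naive double-loop bilateral filter, reflect-101 borders, integer-rounded
# radiometric differences (same kernel definition, independent evaluation)
oracle_bilateral <- function(img, sigma_s, sigma_r, d) {
  rad <- d %/% 2
  nr <- nrow(img); nc <- ncol(img)
  refl <- function(i, n) { while (i < 1 || i > n) { if (i < 1) i <- 2 - i; if (i > n) i <- 2 * n - i }; i }
  out <- img
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    num <- 0; den <- 0
    for (dy in -rad:rad) for (dx in -rad:rad) {
      v <- img[refl(i + dy, nr), refl(j + dx, nc)]
      k <- round(abs(v - img[i, j]))
      w <- exp(-(dx^2 + dy^2) / (2 * sigma_s^2)) * exp(-k^2 / (2 * sigma_r^2))
      num <- num + w * v; den <- den + w
    }
    out[i, j] <- num / den
  }
  out
}

# naive local block mean with reflect-101 borders
oracle_local_mean <- function(img, b) {
  rad <- (b - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  refl <- function(i, n) { while (i < 1 || i > n) { if (i < 1) i <- 2 - i; if (i > n) i <- 2 * n - i }; i }
  out <- img
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (dy in -rad:rad) for (dx in -rad:rad)
      s <- s + img[refl(i + dy, nr), refl(j + dx, nc)]
    out[i, j] <- s / b^2
  }
  out
}

# dilation as the union of shifted copies of the mask
oracle_dilate <- function(mask, w) {
  rad <- (w - 1) / 2
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (dy in -rad:rad) for (dx in -rad:rad) {
    src_r <- seq_len(nr) - dy; src_c <- seq_len(nc) - dx
    ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
    out[ok_r, ok_c] <- out[ok_r, ok_c] | mask[src_r[ok_r], src_c[ok_c]]
  }
  out
}

# flood fill from all border foreground pixels (8-connectivity); returns the
# mask with border-connected components removed
oracle_clear_border <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  stack <- which(mask & (row(mask) %in% c(1, nr) | col(mask) %in% c(1, nc)))
  while (length(stack)) {
    p <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[p]) next
    seen[p] <- TRUE
    i <- ((p - 1) %% nr) + 1; j <- ((p - 1) %/% nr) + 1
    for (dy in -1:1) for (dx in -1:1) {
      ii <- i + dy; jj <- j + dx
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && mask[ii, jj] && !seen[ii, jj])
        stack <- c(stack, (jj - 1) * nr + ii)
    }
  }
  mask & !seen
}

# polygon perimeter by explicit pairwise distances
oracle_perimeter <- function(v) {
  n <- nrow(v); s <- 0
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1 else k + 1
    s <- s + sqrt(sum((v[k2, ] - v[k, ])^2))
  }
  s
}

# convex polygon area by fan triangulation from the first vertex
oracle_fan_area <- function(v) {
  a <- 0
  for (k in 2:(nrow(v) - 1)) {
    u <- v[k, ] - v[1, ]; w <- v[k + 1, ] - v[1, ]
    a <- a + abs(u[1] * w[2] - u[2] * w[1]) / 2
  }
  a
}

# minimum-area enclosing rectangle by exhaustive angle sweep
oracle_obb_area <- function(v, step_deg = 0.1) {
  best <- Inf
  for (a in seq(0, 90 - step_deg, by = step_deg) * pi / 180) {
    rx <- v[, 1] * cos(a) + v[, 2] * sin(a)
    ry <- -v[, 1] * sin(a) + v[, 2] * cos(a)
    best <- min(best, (max(rx) - min(rx)) * (max(ry) - min(ry)))
  }
  best
}

# exhaustive minimal assignment over all permutations (small n)
oracle_assignment <- function(dm) {
  n <- nrow(dm)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(ncol(dm)))) {
    cost <- sum(dm[cbind(seq_len(n), p[seq_len(n)])])
    if (cost < best_cost) { best_cost <- cost; best <- p[seq_len(n)] }
  }
  list(assignment = best, cost = best_cost)
}

# homogeneous 3x3 composition of a list of 2x3 matrices (applied right-to-left)
oracle_chain <- function(mats) {
  acc <- diag(3)
  for (m in mats) acc <- acc %*% rbind(m, c(0, 0, 1))
  acc[1:2, ]
}

# random convex polygon with n vertices: distinct angles on a random ellipse
random_convex_polygon <- function(n, scale = 50) {
  ang <- sort(runif(n, 0, 2 * pi))
  while (min(diff(c(ang, ang[1] + 2 * pi))) < 1e-3) ang <- sort(runif(n, 0, 2 * pi))
  a <- runif(1, 0.3, 1) * scale
  b <- runif(1, 0.3, 1) * scale
  unname(cbind(a * cos(ang) + runif(1, 50, 100),
               b * sin(ang) + runif(1, 50, 100)))
}

# small fast synthetic scene for unit tests (512 x 512)
small_scene <- function(seed = 3, frames = 4, n_spacers = 3, ...) {
  makeScene(canvas = c(512, 512), frames = frames, n_spacers = n_spacers,
            spacer_side = c(85, 105), spacer_ring_radius = 120,
            colony = list(cap = 40), rgb = FALSE, seed = seed, ...)
}

# config whose central circle covers the small scene's spacer ring
small_config <- function(warp = FALSE, ...) {
  registrationConfig(preprocess = preprocessConfig(mask_diameter_fraction = 1.2),
                     warp = warp, ...)
}
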