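test_that("cue ordering is lexicographic by (min y, min x) and stable", {
  sq <- function(x0, y0) cuePolygon(rbind(c(x0, y0), c(x0 + 10, y0),
                                          c(x0 + 10, y0 + 10), c(x0, y0 + 10)))
  cues <- list(sq(10, 50), sq(10, 20), sq(5, 80))
  ord <- orderCues(cues)
  expect_equal(vapply(ord, function(p) cueAnchor(p)[2], numeric(1)), c(20, 50, 80))
  expect_identical(orderCues(cues[1]), cues[1])
  # ties keep original relative order (stable sort)
  a <- sq(3, 3); b <- sq(3, 3); b$j <- 99L
  expect_equal(orderCues(list(a, b))[[2]]$j, 99L)
})

test_that("oriented bounding box is minimal, tight and well-ordered", {
  sq <- rbind(c(2, 3), c(12, 3), c(12, 13), c(2, 13))
  obb <- orientedBoundingBox(sq)
  expect_equal(obb[1, ], c(x = 2, y = 3))       # fixed point: its own corners
  expect_equal(sort(obb[, 1]), c(2, 2, 12, 12))
  # rotated square: side lengths and area preserved
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- sq %*% t(R)
  obb2 <- orientedBoundingBox(rot)
  sides <- sqrt(rowSums((obb2[c(2, 3, 4, 1), ] - obb2)^2))
  expect_equal(sides, rep(10, 4), tolerance = 1e-6)
  a2 <- polygonArea(obb2)
  expect_equal(a2, oracle_obb_area(rot), tolerance = 1e-3)
  # thin rectangle at 45 degrees: OBB area ~ 200, far below the AABB's
  thin <- rbind(c(0, 0), c(100, 0), c(100, 2), c(0, 2)) %*%
    t(matrix(c(cos(pi / 4), sin(pi / 4), -sin(pi / 4), cos(pi / 4)), 2, 2))
  obb3 <- orientedBoundingBox(thin)
  expect_equal(polygonArea(obb3), 200, tolerance = 1e-6)
  aabb <- prod(apply(thin, 2, function(z) diff(range(z))))
  expect_lt(polygonArea(obb3), aabb / 10)
  expect_error(orientedBoundingBox(rbind(c(0, 0), c(1, 1), c(2, 2))), "collinear")
})

test_that("OBB area never exceeds the axis-aligned bounding box area", {
  set.seed(41)
  for (i in 1:20) {
    v <- random_convex_polygon(sample(4:10, 1))
    obb <- orientedBoundingBox(v)
    aabb <- prod(apply(v, 2, function(z) diff(range(z))))
    expect_lte(polygonArea(obb), aabb + 1e-9)
    # all vertices inside or on the rectangle (within tolerance)
    expect_equal(oracle_obb_area(v), polygonArea(obb), tolerance = 1e-2)
  }
})

test_that("control points follow the three selection scenarios", {
  sq <- function(x0, y0, s = 10)
    cuePolygon(rbind(c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s), c(x0, y0 + s)))
  # scenario a: first three OBB corners of the single cue
  cp1 <- controlPoints(list(sq(0, 0)))
  expect_equal(cp1$scenario, "a")
  expect_equal(unname(cp1$points), rbind(c(0, 0), c(10, 0), c(10, 10)))
  # scenario c: centroids of the first three cues in order
  cues3 <- list(sq(5, 5), sq(45, 5), sq(25, 55))
  cp3 <- controlPoints(cues3)
  expect_equal(cp3$scenario, "c")
  expect_equal(unname(cp3$points), rbind(c(10, 10), c(50, 10), c(30, 60)))
  # scenario b: three points, non-collinear, reproducible
  cp2 <- controlPoints(list(sq(0, 0), sq(40, 0)))
  expect_equal(cp2$scenario, "b")
  expect_equal(dim(cp2$points), c(3L, 2L))
  expect_gt(abs((cp2$points[2, 1] - cp2$points[1, 1]) *
                (cp2$points[3, 2] - cp2$points[1, 2]) -
                (cp2$points[3, 1] - cp2$points[1, 1]) *
                (cp2$points[2, 2] - cp2$points[1, 2])) / 2, 1)  # non-collinear
  expect_identical(cp2$points, controlPoints(list(sq(0, 0), sq(40, 0)))$points)
  # scenario-b rule implemented independently: first OBB corner of each cue
  # plus the corner of the first OBB spanning the largest triangle with them
  b1 <- orientedBoundingBox(sq(0, 0)); b2 <- orientedBoundingBox(sq(40, 0))
  tri_area <- function(p) abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
                              (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) / 2
  areas <- sapply(2:4, function(k) tri_area(rbind(b1[1, ], b2[1, ], b1[k, ])))
  want3 <- b1[1 + which.max(areas), ]
  expect_equal(unname(cp2$points), unname(rbind(b1[1, ], b2[1, ], want3)))
  expect_error(controlPoints(list()), "no cues")
  # collinear centroids: degeneracy error
  coll <- list(sq(0, 0), sq(20, 20), sq(40, 40))
  expect_error(controlPoints(coll), "collinear")
})

test_that("control points are equivariant under translation in all scenarios", {
  sq <- function(x0, y0, s = 12)
    cuePolygon(rbind(c(x0, y0), c(x0 + s, y0), c(x0 + s, y0 + s), c(x0, y0 + s)))
  set.seed(42)
  # translations keep the cues in the positive quadrant: the OBB corner
  # ordering is anchored at the coordinate origin, as it is for image data
  for (rep in 1:5) {
    v <- runif(2, 0, 40)
    layouts <- list(list(sq(10, 10)),
                    list(sq(10, 10), sq(60, 30)),
                    list(sq(10, 10), sq(60, 10), sq(35, 70), sq(80, 80)))
    for (cues in layouts) {
      moved <- lapply(cues, function(p) cuePolygon(p$vertices +
        matrix(v, nrow(p$vertices), 2, byrow = TRUE)))
      p0 <- controlPoints(cues)$points
      p1 <- controlPoints(moved)$points
      expect_equal(p1, p0 + matrix(v, 3, 2, byrow = TRUE), tolerance = 1e-9)
    }
  }
})

test_that("cue matching recovers correspondences and flags large shifts", {
  set.seed(43)
  a <- cbind(runif(4, 0, 100), runif(4, 0, 100))
  # identity on identical sets
  m0 <- matchCues(a, a)
  expect_equal(m0$next_, m0$prev)
  expect_equal(m0$dist, rep(0, 4))
  # rigid translation by (3, 4): identity matching, displacement 5
  b <- a + matrix(c(3, 4), 4, 2, byrow = TRUE)
  m1 <- matchCues(a, b)
  expect_equal(m1$next_, m1$prev)
  expect_equal(m1$dist, rep(5, 4))
  # jittered and permuted: equals the exhaustive assignment oracle
  for (rep in 1:5) {
    a <- cbind(runif(4, 0, 200), runif(4, 0, 200))
    perm <- sample(4)
    b <- a[perm, ] + matrix(runif(8, -2, 2), 4, 2)
    m <- matchCues(a, b)
    dm <- as.matrix(dist(rbind(a, b)))[1:4, 5:8]
    want <- oracle_assignment(dm)$assignment
    expect_equal(m$next_[order(m$prev)], want)
  }
  expect_error(matchCues(a, a + 100, max_shift = 50), "shift too large")
})

test_that("matching a rigidly moved copy recovers identity below half-spacing", {
  set.seed(44)
  a <- rbind(c(20, 20), c(120, 30), c(60, 110), c(140, 140))
  spacing <- min(dist(a))
  for (rep in 1:5) {
    sh <- runif(2, -1, 1) * spacing / 3
    b <- a + matrix(sh, 4, 2, byrow = TRUE)
    m <- matchCues(a, b)
    expect_equal(m$next_, m$prev)
  }
})
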