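test_that("preprocessConfig validates its invariants", {
  expect_error(preprocessConfig(thresh_block = 10), "odd")
  expect_error(preprocessConfig(thresh_block = 1), "odd")
  expect_error(preprocessConfig(dilation_window = 4), "odd")
  expect_error(preprocessConfig(mask_diameter_fraction = 0), "mask_diameter_fraction")
  expect_error(preprocessConfig(mask_diameter_fraction = 2), "mask_diameter_fraction")
})

test_that("bilateral filter preserves constants and matches the naive oracle", {
  cfg <- preprocessConfig()
  const <- matrix(120, 20, 20)
  expect_equal(denoiseBilateral(const, cfg), const)
  expect_error(denoiseBilateral(array(0, c(4, 4, 3)), cfg), "single-channel")

  set.seed(21)
  # step edge of height 200 plus an impulse, 32 x 32
  img <- matrix(20, 32, 32); img[, 17:32] <- 220
  img[8, 8] <- 250
  got <- denoiseBilateral(img, cfg)
  want <- oracle_bilateral(img, cfg$sigma_spatial, cfg$sigma_range,
                           cfg$bilateral_diameter)
  expect_equal(got, want, tolerance = 1e-10)
  # edge position preserved within 1 px: midpoint crossing stays at 16/17
  expect_true(all(got[, 15] < 120) && all(got[, 18] > 120))
  # impulse attenuated below 50% of its original deviation
  expect_lt(got[8, 8] - 20, 0.5 * (250 - 20))

  # random image equals the oracle too
  rnd <- matrix(round(runif(32 * 32, 0, 255)), 32, 32)
  expect_equal(denoiseBilateral(rnd, cfg),
               oracle_bilateral(rnd, 75, 75, 10), tolerance = 1e-10)
})

test_that("CLAHE keeps constants flat, widens contrast, respects range", {
  cfg <- preprocessConfig(clahe_tile = 16)
  const <- matrix(100, 64, 64)
  out <- claheEqualize(const, cfg)
  expect_equal(max(out) - min(out), 0)           # still constant
  # two-valued image: dynamic range widened or preserved
  half <- matrix(50, 64, 64); half[, 33:64] <- 200
  out2 <- claheEqualize(half, cfg)
  # dynamic range preserved (up to tile-blend rounding) or widened
  expect_gte(max(out2) - min(out2), 149)
  # range contract on random noise
  set.seed(7)
  noise <- matrix(runif(64 * 64, 0, 255), 64, 64)
  out3 <- claheEqualize(noise, cfg)
  expect_true(min(out3) >= 0 && max(out3) <= 255)
  expect_error(claheEqualize(matrix(0, 8, 8), preprocessConfig(clahe_tile = 100)),
               "larger than image")
})

test_that("adaptive mean threshold matches the double-loop local-mean oracle", {
  cfg <- preprocessConfig(thresh_block = 11)
  # constant image: nothing falls below mean - const
  expect_false(any(adaptiveMeanThreshold(matrix(80, 20, 20), cfg)))
  # dark 3x3 square on bright background: exactly the square (+-1 px boundary)
  img <- matrix(200, 11, 11); img[5:7, 5:7] <- 40
  got <- adaptiveMeanThreshold(img, cfg)
  mu <- oracle_local_mean(img, 11)
  expect_identical(got, img < mu - 2)
  expect_true(all(got[5:7, 5:7]))
  expect_false(any(got[c(1, 2, 10, 11), ]))
  # checkerboard of period 2: deterministic, equals the oracle
  cb <- matrix(c(0, 255), 12, 12)
  cb <- (row(cb) + col(cb)) %% 2 * 255
  cfg3 <- preprocessConfig(thresh_block = 3)
  expect_identical(adaptiveMeanThreshold(cb, cfg3), cb < oracle_local_mean(cb, 3) - 2)
  # non-inverted polarity: bright structures become foreground
  cfgb <- preprocessConfig(invert = FALSE)
  img2 <- matrix(40, 11, 11); img2[5:7, 5:7] <- 200
  gotb <- adaptiveMeanThreshold(img2, cfgb)
  expect_true(all(gotb[5:7, 5:7]))
  expect_false(any(gotb[c(1, 11), ]))
})

test_that("dilation is the union of shifts and never shrinks foreground", {
  cfg <- preprocessConfig(dilation_window = 3)
  single <- matrix(FALSE, 11, 11); single[6, 6] <- TRUE
  got <- dilateMask(single, cfg)
  expect_equal(sum(got), 9)
  expect_true(all(got[5:7, 5:7]))
  expect_false(any(dilateMask(matrix(FALSE, 8, 8), cfg)))
  set.seed(13)
  for (i in 1:5) {
    m <- matrix(runif(400) < 0.15, 20, 20)
    got <- dilateMask(m, cfg)
    expect_true(all(got[m]))                     # superset
    expect_identical(got, oracle_dilate(m, 3))
  }
})

test_that("border clearing removes whole border-connected components", {
  m <- matrix(FALSE, 12, 12)
  m[1, 3:5] <- TRUE                 # touches top border
  m[6:8, 6:8] <- TRUE               # interior
  got <- clearBorder(m)
  expect_false(any(got[1, ]))
  expect_true(all(got[6:8, 6:8]))
  # L-shaped component entering from the border into the center: fully removed
  L <- matrix(FALSE, 15, 15)
  L[1:8, 7] <- TRUE; L[8, 7:12] <- TRUE
  expect_false(any(clearBorder(L)))
  set.seed(17)
  for (i in 1:5) {
    m <- matrix(runif(625) < 0.2, 25, 25)
    expect_identical(clearBorder(m), oracle_clear_border(m))
  }
})

test_that("circle mask drops whole components with any pixel outside", {
  cfg <- preprocessConfig(mask_diameter_fraction = 0.6)
  m <- matrix(FALSE, 100, 100)
  m[48:52, 48:52] <- TRUE           # fully inside the r=30 circle
  m[5:8, 5:8] <- TRUE               # fully outside
  m[48:52, 72:82] <- TRUE           # straddles the boundary (x from 71..81)
  got <- applyCircleMask(m, cfg)
  expect_true(all(got[48:52, 48:52]))
  expect_false(any(got[5:8, 5:8]))
  expect_false(any(got[48:52, 72:82]))  # component-level removal, no clipping
  # oracle: per-component containment via labels
  lab <- labelComponents(m)
  rad <- 0.6 * 100 / 2
  outside <- outer(((1:100) - 0.5 - 50)^2, ((1:100) - 0.5 - 50)^2, "+") > rad^2
  keep <- setdiff(unique(lab[lab > 0]), unique(lab[outside & lab > 0]))
  expect_identical(got, matrix(lab %in% keep, 100, 100))
})

test_that("labelComponents uses 8-connectivity with raster-order labels", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE      # diagonal pair: one component
  m[6, 6] <- TRUE
  lab <- labelComponents(m)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_equal(sort(unique(lab[lab > 0])), c(1L, 2L))
  expect_lt(lab[2, 2], lab[6, 6])       # discovered first in raster order
})

test_that("the full pipeline is deterministic, shape-preserving and finds spacers", {
  scene <- small_scene(seed = 9, frames = 2)
  rn <- renderSeries(scene)
  cfg <- preprocessConfig(mask_diameter_fraction = 1.2)
  f <- getFrame(rn$series, 1)
  m1 <- preprocessFrame(f, cfg)
  m2 <- preprocessFrame(f, cfg)
  expect_identical(m1, m2)                      # pure function
  expect_equal(dim(m1), dim(f)[1:2])
  # all rendered spacers appear among the mask's components
  cues <- filterCues(findPolygons(m1))
  centroids <- t(vapply(cues, cueCentroid, numeric(2)))
  truth <- rn$truth@anchors[[1]]
  for (s in seq_len(nrow(truth))) {
    d <- sqrt(rowSums((centroids - matrix(truth[s, ], nrow(centroids), 2,
                                          byrow = TRUE))^2))
    expect_lt(min(d), 5)
  }
  # an all-zero frame yields an empty mask
  expect_false(any(preprocessFrame(matrix(0, 300, 300), cfg)))
})
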