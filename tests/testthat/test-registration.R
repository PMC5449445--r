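test_that("interval partitioning finds maximal constant-J runs", {
  p1 <- partitionIntervals(c(3, 3, 3, 3))
  expect_equal(nrow(p1), 1)
  expect_equal(unlist(p1[1, 1:3]), c(t_start = 1, t_end = 4, J = 3))
  p2 <- partitionIntervals(c(3, 3, 4, 4, 4))
  expect_equal(p2$t_start, c(1, 3))
  expect_equal(p2$t_end, c(2, 5))
  expect_equal(p2$J, c(3, 4))
  expect_true(all(p2$registrable))
  # run-length-encoding oracle on a random sequence; length-1 runs flagged
  set.seed(51)
  counts <- sample(2:4, 30, TRUE)
  p <- partitionIntervals(counts)
  r <- rle(counts)
  expect_equal(p$J, r$values)
  expect_equal(p$t_end - p$t_start + 1L, r$lengths)
  expect_equal(p$registrable, r$lengths >= 2)
  expect_equal(p$t_start[1], 1L)
  expect_equal(p$t_end[nrow(p)], 30L)
  expect_true(all(p$t_start[-1] == p$t_end[-nrow(p)] + 1L))  # contiguous cover
  p3 <- partitionIntervals(c(2, 3, 2))
  expect_false(any(p3$registrable))
})

test_that("affine estimation is exact on its control points", {
  tri <- rbind(c(10, 10), c(200, 30), c(80, 150))
  # identity
  A0 <- estimateAffine(tri, tri)
  expect_equal(A0@m, cbind(diag(2), c(0, 0)), tolerance = 1e-12)
  # pure translation
  A1 <- estimateAffine(tri, tri + matrix(c(7, -3), 3, 2, byrow = TRUE))
  expect_equal(A1@m, rbind(c(1, 0, 7), c(0, 1, -3)), tolerance = 1e-9)
  # rotation about a point: equals the closed-form matrix
  R10 <- rotationAffine(10 * pi / 180, center = c(100, 100))
  A2 <- estimateAffine(tri, applyAffine(R10, tri))
  expect_equal(A2@m, R10@m, tolerance = 1e-9)
  # residual on its own control points < 1e-9
  expect_lt(max(abs(applyAffine(A2, tri) - applyAffine(R10, tri))), 1e-9)
  expect_error(estimateAffine(rbind(c(0, 0), c(1, 1), c(2, 2)), tri), "collinear")
})

test_that("composition, inversion and chaining follow the homogeneous product", {
  A <- rotationAffine(0.3, c(50, 20))
  expect_equal(composeAffine(identityAffine(), A)@m, A@m)
  expect_equal(composeAffine(translationAffine(1, 2), translationAffine(3, 4))@m,
               translationAffine(4, 6)@m)
  expect_equal(composeAffine(A, invertAffine(A))@m, identityAffine()@m,
               tolerance = 1e-9)
  # chain of random small rigid transforms vs the 3x3 product oracle
  set.seed(52)
  steps <- lapply(1:10, function(i)
    composeAffine(translationAffine(runif(1, -2, 2), runif(1, -2, 2)),
                  rotationAffine(runif(1, -0.01, 0.01), c(500, 500))))
  chain <- chainToReference(steps)
  expect_equal(chain$transforms[[1]]@m, identityAffine()@m)
  expect_equal(chain$status[1], "reference")
  for (t in 2:11) {
    want <- oracle_chain(lapply(steps[seq_len(t - 1)], function(s) s@m))
    expect_equal(chain$transforms[[t]]@m, want, tolerance = 1e-9)
  }
  # translations compose additively
  tr <- chainToReference(rep(list(translationAffine(1, 0)), 4))
  expect_equal(tr$transforms[[5]]@m, translationAffine(4, 0)@m)
  # a NULL pair breaks the chain: downstream frames flagged, not dropped
  broken <- chainToReference(list(translationAffine(1, 0), NULL,
                                  translationAffine(1, 0)))
  expect_equal(broken$status, c("reference", "registered", "unbridged", "unbridged"))
  expect_equal(broken$transforms[[3]]@m, broken$transforms[[2]]@m)
})

test_that("warping is exact for identity and reversible for translations", {
  set.seed(53)
  img <- matrix(round(runif(64 * 64, 0, 255)), 64, 64)
  expect_identical(warpFrame(img, identityAffine()), img)
  # constant image stays constant in the interior
  const <- matrix(99, 64, 64)
  w <- warpFrame(const, translationAffine(3, 2))
  expect_true(all(w[10:60, 10:60] == 99))
  expect_true(all(w[, 1:3] == 0))      # out-of-field fill
  # translate there and back: interior recovered within interpolation tolerance
  back <- warpFrame(warpFrame(img, translationAffine(5, 0)),
                    translationAffine(-5, 0))
  expect_lte(max(abs(back[, 7:58] - img[, 7:58])), 1)
  # integer translation with bilinear interpolation is exact
  sh <- warpFrame(img, translationAffine(4, 7))
  expect_equal(sh[(1:50) + 7, (1:50) + 4], img[1:50, 1:50])
  # RGB frames are warped channel-wise with the same transform
  arr <- array(runif(32 * 32 * 3, 0, 255), dim = c(32, 32, 3))
  wa <- warpFrame(arr, translationAffine(2, 3))
  for (ch in 1:3)
    expect_equal(wa[, , ch], warpFrame(arr[, , ch], translationAffine(2, 3)))
})

test_that("registering a synthetic drifting series recovers the trajectory", {
  scene <- small_scene(seed = 7, frames = 5)
  rn <- renderSeries(scene)
  res <- registerSeries(rn$series, small_config())
  log <- registrationLog(res)
  expect_equal(log$status[1], "reference")
  expect_true(all(log$status == c("reference", rep("registered", 4))))
  expect_equal(frameTransforms(res)[[1]]@m, identityAffine()@m)
  expect_lt(recoveryError(res, rn$truth), 0.5)
  # warped series has unchanged dimensions
  expect_equal(frameDims(registeredSeries(res)), c(512L, 512L))
})

test_that("re-registering an already registered series is a near-no-op", {
  scene <- small_scene(seed = 19, frames = 4)
  rn <- renderSeries(scene)
  res1 <- registerSeries(rn$series, small_config(warp = TRUE))
  res2 <- registerSeries(registeredSeries(res1), small_config())
  corners <- rbind(c(100, 100), c(400, 100), c(400, 400), c(100, 400))
  for (t in 2:4) {
    moved <- applyAffine(frameTransforms(res2)[[t]], corners)
    expect_lt(max(sqrt(rowSums((moved - corners)^2))), 0.5)
  }
})

test_that("registration degrades gracefully when a frame has no cues", {
  scene <- small_scene(seed = 23, frames = 4)
  rn <- renderSeries(scene)
  frames <- lapply(seq_len(4), function(t) getFrame(rn$series, t))
  frames[[3]] <- matrix(0, 512, 512)    # featureless frame: J = 0
  res <- registerSeries(frameSeries(frames), small_config())
  log <- registrationLog(res)
  expect_equal(log$J[3], 0L)
  expect_true(all(log$status[3:4] == "unbridged"))
  expect_equal(log$status[2], "registered")
  # a series with no cues anywhere is a hard error
  blank <- frameSeries(replicate(3, matrix(0, 300, 300), simplify = FALSE))
  expect_error(registerSeries(blank, registrationConfig()), "unregistrable")
})
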