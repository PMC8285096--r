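test_that("slab streamlines recover the gap within one Euler step", {
  f <- slabField(0.5, 3)
  lab <- wallLabels(f)
  w <- which(lab == 2L, arr.ind = TRUE)
  set.seed(1)
  starts <- w[sample(nrow(w), 25), , drop = FALSE]
  for (i in seq_len(nrow(starts))) {
    tr <- traceStreamline(f, starts[i, ], step = 0.1)
    expect_equal(tr$flag, 0L)
    expect_lt(abs(tr$length_mm - 3), 0.1)
  }
})

test_that("fine-grid sphere thickness is 2 mm within 5% nearly everywhere", {
  th <- sphereThickness(0.25, step = 0.1)
  v <- thicknessValues(th)
  v <- v[!is.na(v)]
  expect_gte(mean(abs(v - 2) <= 0.1), 0.95)
  expect_lt(abs(meanThickness(th) - 2) / 2, 0.05)
})

test_that("starts outside the wall are rejected", {
  f <- slabField(0.5, 3)
  lab <- wallLabels(f)
  lumenVoxel <- which(lab == 1L, arr.ind = TRUE)[1, ]
  expect_error(traceStreamline(f, lumenVoxel), "not in the wall")
  expect_error(traceStreamline(f, c(0, 1, 1)), "outside the grid")
})

test_that("swapping endo and epi roles leaves thickness unchanged", {
  ph <- spherePhantom(0.5)
  lab <- wallLabels(ph$mask)
  swapped <- lab
  swapped[lab == 1L] <- 0L
  swapped[lab == 0L] <- 1L
  m2 <- WallMask(swapped, voxelSpacing(ph$mask))
  f1 <- sphereField(0.5)
  f2 <- solveLaplace(m2)
  t1 <- sphereThickness(0.5)
  t2 <- thicknessMap(f2)
  v1 <- thicknessValues(t1)
  v2 <- thicknessValues(t2)
  wall <- wallLabels(f1) == 2L
  ok <- wall & !is.na(v1) & !is.na(v2)
  step <- t1@diagnostics$stepMm
  expect_gt(sum(ok) / sum(wall), 0.99)
  expect_lt(max(abs(v1[ok] - v2[ok])), step + 1e-6)
})

test_that("streamline length is at least the endpoint distance", {
  f <- sphereField(0.5)
  w <- which(wallLabels(f) == 2L, arr.ind = TRUE)
  set.seed(2)
  starts <- w[sample(nrow(w), 500), , drop = FALSE]
  res <- lawstress:::traceAll(f, starts, step = 0.1)
  ok <- res$flag == 0L
  expect_true(all(res$length_mm[ok] >= res$euclid_mm[ok] - 0.1 - 1e-9))
})

test_that("wall regions without a usable gradient are flagged", {
  # an isolated wall island inside the lumen converges to potential 0:
  # flat gradient, so its voxels are excluded from the average
  ph <- shellPhantom("concentric", rInner = 6, rOuter = 8,
                     spacing = c(1, 1, 1))
  lab <- wallLabels(ph$mask)
  ctr <- round(dim(lab) / 2)
  lab[ctr[1] + (-1:1), ctr[2] + (-1:1), ctr[3] + (-1:1)] <- 2L
  m <- WallMask(lab, voxelSpacing(ph$mask))
  f <- solveLaplace(m)
  th <- thicknessMap(f)
  expect_gt(th@diagnostics$flaggedFraction, 0)
  expect_true(all(is.na(thicknessValues(th)[flaggedVoxels(th)])))
  expect_true(is.finite(meanThickness(th)))
})

test_that("a mostly-flat field triggers the flagged-fraction warning", {
  lab <- array(0L, c(10, 10, 10))
  lab[2:9, 2:9, 2:9] <- 2L
  lab[5:6, 5:6, 5:6] <- 1L
  # wall shell around a tiny lumen: most outer-corner voxels sit far from
  # the lumen; shrink the step cap so traces cannot finish
  m <- WallMask(lab, c(1, 1, 1))
  f <- solveLaplace(m)
  expect_warning(thicknessMap(f, step = 0.01, maxSteps = 5L),
                 "flagged")
})

test_that("mean per-voxel thickness error shrinks under grid refinement", {
  errs <- vapply(c(0.5, 0.25), function(res) {
    v <- thicknessValues(sphereThickness(res))
    mean(abs(v[!is.na(v)] - 2))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  # slab is exact at every resolution
  for (res in c(0.5, 0.25)) {
    f <- solveLaplace(shellPhantom("slab", slabGap = 3,
                                   spacing = rep(res, 3))$mask)
    expect_lt(abs(meanThickness(thicknessMap(f)) - 3), 1e-6)
  }
})
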