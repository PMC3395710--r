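test_that("RF centers are centroid computations over the probe grid", {
  probes <- stimulusGrid(3, 3, 0.2)
  # single positive entry: center is that probe
  rf <- rep(0, 9); rf[4] <- 0.7
  expect_equal(rfCenter(rf, probes), unname(probes[4, ]))
  # two equal entries: midpoint
  rf2 <- rep(0, 9); rf2[c(1, 9)] <- 0.5
  expect_equal(rfCenter(rf2, probes),
               unname((probes[1, ] + probes[9, ]) / 2))
  # random RF equals a hand-rolled weighted mean
  set.seed(21)
  rf3 <- runif(9)
  hand <- c(sum(probes[, 1] * rf3), sum(probes[, 2] * rf3)) / sum(rf3)
  expect_equal(rfCenter(rf3, probes), hand, tolerance = 1e-12)
  # all-zero RF: undefined center, flagged as missing
  expect_true(all(is.na(rfCenter(rep(0, 9), probes))))
})

test_that("RF centroids lie inside the bounding box of their positive probes", {
  set.seed(22)
  probes <- stimulusGrid(5, 5)
  for (i in 1:25) {
    rf <- runif(25) * rbinom(25, 1, 0.4)
    if (sum(rf) == 0) next
    ctr <- rfCenter(rf, probes)
    pos <- probes[rf > 0, , drop = FALSE]
    expect_gte(ctr[1], min(pos[, 1])); expect_lte(ctr[1], max(pos[, 1]))
    expect_gte(ctr[2], min(pos[, 2])); expect_lte(ctr[2], max(pos[, 2]))
  }
})

test_that("RF size is the positive fraction of the probe grid", {
  expect_equal(rfSize(rep(0, 100)), 0)
  expect_equal(rfSize(rep(0.3, 100)), 1)
  expect_equal(rfSize(c(rep(0.5, 50), rep(0, 50))), 0.5)
})

test_that("size histograms conserve counts and report moments", {
  h <- rfSizeHistogram(rep(0.345, 77))
  expect_equal(sum(h$count), 77L)
  expect_equal(sum(h$count > 0), 1L)
  expect_equal(nrow(h), 100L)
  set.seed(23)
  sz <- runif(256)
  h2 <- rfSizeHistogram(sz, bins = 10)
  expect_equal(sum(h2$count), 256L)
  expect_equal(attr(h2, "mean"), mean(sz))
})

test_that("probing is side-effect free and deterministic", {
  p <- tinyParams()
  model <- newFieldModel(p, tinyPatch(), seed = 2)
  W_before <- model$W
  probes <- stimulusGrid(3, 3)
  a <- computeReceptiveFields(model, probes)
  b <- computeReceptiveFields(model, probes)
  expect_identical(model$W, W_before)
  expect_identical(a$rf, b$rf)
})

test_that("dead cortical units have all-zero RFs and size zero", {
  p <- tinyParams()
  model <- newFieldModel(p, tinyPatch(), seed = 2)
  mask <- matrix(FALSE, p$m, p$m); mask[2, 3] <- TRUE
  model$cortical_mask <- mask
  rfs <- computeReceptiveFields(model, stimulusGrid(3, 3))
  dead <- which(as.vector(mask))
  expect_true(all(rfs$rf[dead, ] == 0))
  expect_equal(rfs$sizes[dead], 0)
  expect_false(rfs$defined[dead])
})

test_that("topographic order is 1 for the identity map and signed under reflections", {
  up <- unitPositions(8)
  ord <- topographicOrder(up, up)
  expect_equal(unname(ord$r), c(1, 1), tolerance = 1e-12)
  expect_equal(ord$mean_displacement, 0)
  mirrored <- cbind(1 - up[, 1], up[, 2])
  ord2 <- topographicOrder(mirrored, up)
  expect_equal(unname(ord2$r), c(-1, 1), tolerance = 1e-12)
})

test_that("topographic order sees through a 90-degree map rotation", {
  up <- unitPositions(8)
  rotated <- cbind(up[, 2], 1 - up[, 1])
  ord <- topographicOrder(rotated, up)
  expect_true(ord$axes_swapped)
  expect_equal(abs(unname(ord$r)), c(1, 1), tolerance = 1e-12)
})

test_that("shuffled centers have near-zero order", {
  set.seed(24)
  up <- unitPositions(16)
  shuffled <- up[sample(nrow(up)), ]
  ord <- topographicOrder(shuffled, up)
  expect_lt(max(abs(ord$r)), 0.2)
})

test_that("too few defined centers is an error", {
  up <- unitPositions(4)
  centers <- up; centers[6:16, ] <- NA
  expect_error(topographicOrder(centers, up), "fewer than 10")
})

test_that("response maps cover the validation grid and honor cortical lesions", {
  p <- tinyParams()
  model <- newFieldModel(p, tinyPatch(), seed = 2)
  rm0 <- responseMap(model, stimulusGrid(2, 2))
  expect_equal(dim(rm0), c(8, 8, 4))
  mask <- matrix(FALSE, 8, 8); mask[1:3, ] <- TRUE
  model$cortical_mask <- mask
  rm1 <- responseMap(model, stimulusGrid(2, 2))
  expect_true(all(rm1[rep(mask, 4)] == 0))
})

test_that("RF summaries serialize to CSV", {
  p <- tinyParams()
  model <- newFieldModel(p, tinyPatch(), seed = 2)
  rfs <- computeReceptiveFields(model, stimulusGrid(3, 3))
  f <- tempfile(fileext = ".csv")
  writeRFSummary(rfs, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), 64L)
  expect_named(back, c("unit_row", "unit_col", "center_x", "center_y",
                       "size", "defined"))
  unlink(f)
})
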