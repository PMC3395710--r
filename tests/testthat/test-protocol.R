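test_that("stimulus grids have the documented sizes and spans", {
  expect_equal(nrow(stimulusGrid(16, 16)), 256L)
  expect_equal(nrow(stimulusGrid(10, 10)), 100L)
  g <- stimulusGrid(2, 2, 0.1)
  expect_setequal(g[, 1], c(0.1, 0.9))
  expect_setequal(g[, 2], c(0.1, 0.9))
  expect_error(stimulusGrid(4, 4, 0.5), "margin")
})

test_that("training with gamma = 0 conserves the weights exactly", {
  p <- tinyParams(gamma = 0)
  model <- newFieldModel(p, tinyPatch(), seed = 3)
  W0 <- model$W
  fit <- trainModel(model, trainingConfig(epochs = 5, train_grid = c(3L, 3L),
                                          tracked_units = c(1L, 10L)),
                    seed = 4)
  expect_identical(fit$model$W, W0)
  expect_true(all(fit$history[, grep("delta_w", names(fit$history))] == 0))
})

test_that("training is bit-reproducible for identical seed and config", {
  p <- tinyParams()
  cfg <- trainingConfig(epochs = 8, train_grid = c(3L, 3L))
  m1 <- trainModel(newFieldModel(p, tinyPatch(), seed = 5), cfg, seed = 6)
  m2 <- trainModel(newFieldModel(p, tinyPatch(), seed = 5), cfg, seed = 6)
  m3 <- trainModel(newFieldModel(p, tinyPatch(), seed = 5), cfg, seed = 7)
  expect_identical(m1$model$W, m2$model$W)
  expect_identical(m1$history, m2$history)
  expect_false(identical(m1$model$W, m3$model$W))
})

test_that("training history records one row per epoch with the drawn stimulus", {
  p <- tinyParams()
  fit <- trainModel(newFieldModel(p, tinyPatch(), seed = 1),
                    trainingConfig(epochs = 6, train_grid = c(2L, 2L),
                                   tracked_units = 5L), seed = 2)
  expect_equal(nrow(fit$history), 6L)
  expect_true(all(fit$history$stimulus %in% 1:4))
  expect_true(all(fit$history$delta_w_unit5 >= 0))
})

test_that("a single repeated stimulus pulls bump-unit weights onto its pattern", {
  p <- tinyParams()
  patch <- tinyPatch(6, 6)
  model <- newFieldModel(p, patch, seed = 11)
  cfg <- trainingConfig(epochs = 300, train_grid = c(1L, 1L), margin = 0.45)
  fit <- trainModel(model, cfg, seed = 12)
  s <- receptorResponse(patch, c(0.45, 0.45), p$sigma_s)  # the grid's single center
  I <- feedforwardInput(fit$model$W, s, fit$model$G)
  st <- settleField(matrix(0, p$m, p$m), I, fit$model$kernels, p)
  bump <- which(as.vector(rectify(st$V)) > 0.5 * max(st$V))
  l1 <- rowMeans(abs(fit$model$W[bump, , drop = FALSE] -
                     rep(s, each = length(bump))))
  expect_true(all(l1 < 0.05))
})

test_that("the field is reset between epochs (no carry-over between stimuli)", {
  # with a 1-stimulus training set the drawn sequence is fixed, so a
  # 2-epoch run must equal two consecutive 1-epoch runs; a carried-over V
  # would make the second epoch settle from a non-rest state and diverge
  p <- tinyParams()
  model <- newFieldModel(p, tinyPatch(), seed = 1)
  cfg1 <- trainingConfig(epochs = 1, train_grid = c(1L, 1L), margin = 0.2)
  cfg2 <- trainingConfig(epochs = 2, train_grid = c(1L, 1L), margin = 0.2)
  once_twice <- trainModel(trainModel(model, cfg1, seed = 3)$model, cfg1,
                           seed = 4)$model$W
  straight <- trainModel(model, cfg2, seed = 5)$model$W
  expect_equal(straight, once_twice, tolerance = 1e-14)
})

test_that("the match property holds at several levels in 1-D and 2-D", {
  tab <- matchPropertyCheck(fieldParams(m = 32L), levels = c(0.25, 0.5, 0.75))
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$abs_error < 0.05))
  # monotonicity: larger input level, larger settled maximum
  for (d in unique(tab$dims)) {
    sub <- tab[tab$dims == d, ]
    expect_true(all(diff(sub$max_activity[order(sub$level)]) > 0))
  }
})

test_that("calibration reproduces the cached lateral gain", {
  g <- calibrateLateralGain(fieldParams(m = 32L), dims = 1L, lo = 0.1, hi = 2,
                            max_steps = 3000L, tol = 1e-9)
  expect_equal(g, defaultLateralGain(32L, dims = 1L), tolerance = 1e-3)
})

test_that("lesion experiments validate their inputs", {
  p <- tinyParams()
  model <- newFieldModel(p, tinyPatch(), seed = 1)
  spec <- lesionSpec("cortex", "I", 0.25, grid_shape = c(99L, 99L))
  expect_error(runLesionExperiment(model, spec, trainingConfig(epochs = 1)),
               "match the field lattice")
})
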