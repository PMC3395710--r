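# Shared fixtures for the test suite. Everything is generated in code.

# small, fast parameter sets
tinyParams <- function(m = 8L, ...) fieldParams(m = m, ...)

tinyPatch <- function(rows = 4L, cols = 4L, jitter = 0, seed = 1L) {
  buildSkinPatch(rows, cols, jitter, seed)
}

# reduced-scale study conditions: 16 x 16 field, 16 x 16 training grid,
# 2000 epochs. Trained models are expensive, so they are memoized per seed
# for the whole test run.
.trained_cache <- new.env(parent = emptyenv())

reducedParams <- function() fieldParams(m = 16L)

reducedConfig <- function(epochs = 2000L) trainingConfig(epochs = epochs)

trainedReducedModel <- function(seed) {
  key <- paste0("m16_", seed)
  if (is.null(.trained_cache[[key]])) {
    model <- newFieldModel(reducedParams(), buildSkinPatch(seed = 11L),
                           seed = seed)
    fit <- trainModel(model, reducedConfig(), seed = seed + 100L)
    .trained_cache[[key]] <- fit$model
  }
  .trained_cache[[key]]
}

# number of modes of a kernel-density estimate with a fixed, generous
# bandwidth; used for the "unimodal away from the zero bin" check on
# receptive-field size distributions
countModes <- function(x, bw = 0.02, min_height = 0.1) {
  d <- stats::density(x, bw = bw, n = 256)
  y <- d$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  sum(y[peaks] >= min_height * max(y))
}

# direct O(m^4) circular convolution oracle, independent of the package's
# direct path (written as an explicit wrap-and-sum over source cells)
bruteCircularConv <- function(F, w_centered, m) {
  out <- matrix(0, m, m)
  for (i in 1:m) for (j in 1:m) {
    acc <- 0
    for (a in 1:m) for (b in 1:m) {
      di <- i - a; dj <- j - b
      # min-image integer offset
      di <- ((di + m %/% 2) %% m) - m %/% 2
      dj <- ((dj + m %/% 2) %% m) - m %/% 2
      acc <- acc + w_centered[di + m, dj + m] * F[a, b]
    }
    out[i, j] <- acc
  }
  out
}
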