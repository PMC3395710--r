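#' Regular grid of stimulus centers
#'
#' Stimulus centers on a `rows x cols` lattice spanning
#' \eqn{[margin, 1-margin]^2}. The default margin of 0.1 keeps every
#' stimulus (pressure spread \eqn{\sigma = 0.15}) essentially on the patch.
#' Training uses a 16 x 16 grid (256 stimuli) and validation a 10 x 10
#' grid (100 stimuli).
#'
#' @param rows,cols grid dimensions.
#' @param margin border exclusion in normalized units, in `[0, 0.5)`.
#' @return A `(rows*cols) x 2` matrix of centers.
#' @export
stimulusGrid <- function(rows, cols, margin = 0.1) {
  if (margin < 0 || margin >= 0.5)
    stop("margin must lie in [0, 0.5)", call. = FALSE)
  u <- seq(margin, 1 - margin, length.out = rows)
  v <- seq(margin, 1 - margin, length.out = cols)
  cbind(x = rep(u, times = cols), y = rep(v, each = rows))
}

#' Training configuration
#'
#' Bundles the protocol choices of a training run. `epochs = 10000` is the
#' full-scale default; reduced-scale experiments (a 16-unit field) use
#' 2000.
#'
#' @param epochs number of stimulus presentations.
#' @param train_grid `(rows, cols)` of the training stimulus grid.
#' @param probe_grid `(rows, cols)` of the receptive-field probe grid.
#' @param validation_grid `(rows, cols)` of the response-map grid.
#' @param margin border exclusion for all stimulus grids.
#' @param max_steps,tol settling control per epoch.
#' @param per_step if `TRUE` the plasticity rule is applied at every Euler
#'   step (scaled by `dt`) instead of once on the settled activity.
#' @param tracked_units integer vector of unit indices whose weight
#'   evolution is recorded each epoch.
#' @param init_range range of the uniform feed-forward weight
#'   initialization.
#' @return A list of class `TrainingConfig`.
#' @export
trainingConfig <- function(epochs = 10000L,
                           train_grid = c(16L, 16L),
                           probe_grid = c(25L, 25L),
                           validation_grid = c(10L, 10L),
                           margin = 0.1,
                           max_steps = 50L, tol = 1e-6,
                           per_step = FALSE,
                           tracked_units = integer(0),
                           init_range = c(0, 1)) {
  stopifnot(epochs >= 1L, margin >= 0, margin < 0.5)
  structure(list(epochs = as.integer(epochs),
                 train_grid = as.integer(train_grid),
                 probe_grid = as.integer(probe_grid),
                 validation_grid = as.integer(validation_grid),
                 margin = margin, max_steps = as.integer(max_steps),
                 tol = tol, per_step = isTRUE(per_step),
                 tracked_units = as.integer(tracked_units),
                 init_range = init_range),
            class = "TrainingConfig")
}

#' Create an untrained cortical field model
#'
#' Assembles the field (lattice, kernels, corrective gain, resolved
#' lateral gain) together with its skin patch and a freshly initialized
#' feed-forward weight tensor. Weights are i.i.d. uniform on `init_range`
#' (default the full `[0, 1]` weight scale, matching the range of the
#' receptor activations).
#'
#' @param params a [fieldParams()] object.
#' @param patch a [buildSkinPatch()] object.
#' @param seed integer seed for the weight initialization.
#' @param init_range length-2 numeric within `[0, 1]`.
#' @return An object of class `FieldModel`.
#' @export
newFieldModel <- function(params, patch = buildSkinPatch(), seed = 1L,
                          init_range = c(0, 1)) {
  stopifnot(inherits(params, "FieldParams"), inherits(patch, "SkinPatch"))
  m <- params$m
  n <- nrow(patch$positions)
  if (is.null(params$lateral_gain))
    params$lateral_gain <- defaultLateralGain(m)
  W <- withLocalSeed(seed, {
    matrix(stats::runif(m * m * n, init_range[1], init_range[2]),
           nrow = m * m, ncol = n)
  })
  structure(list(params = params,
                 patch = patch,
                 W = W,
                 kernels = lateralKernels(params),
                 G = correctiveGain(params),
                 cortical_mask = NULL,
                 seed = as.integer(seed)),
            class = "FieldModel")
}

#' @export
print.FieldModel <- function(x, ...) {
  m <- x$params$m
  cat("Cortical field model: ", m, "x", m, " units, ",
      ncol(x$W), " receptors", sep = "")
  if (!is.null(x$cortical_mask))
    cat(", ", sum(x$cortical_mask), " units lesioned", sep = "")
  cat("\n")
  invisible(x)
}

# receptor responses for every stimulus of a grid (k x n matrix), honoring
# the patch's active mask
stimulusSet <- function(patch, grid, sigma) {
  t(apply(grid, 1L, function(cc) receptorResponse(patch, cc, sigma)))
}

#' Train the field on randomly drawn grid stimuli
#'
#' Runs the self-organization protocol: each epoch draws one stimulus
#' uniformly from the fixed training set, computes the receptor
#' activations and the feed-forward input, integrates the field from rest
#' to its settled state, applies the plasticity rule gated by the lateral
#' excitation of the settled activity, then resets the field (the removal
#' of pressure from the skin). The run is bit-reproducible given
#' `(seed, config)`.
#'
#' @param model a [newFieldModel()] object (possibly already trained or
#'   lesioned).
#' @param config a [trainingConfig()].
#' @param seed integer seed for the stimulus draws.
#' @return A list with the trained `model` and a `history` data frame
#'   (`epoch`, `stimulus`, and one `delta_w` column per tracked unit).
#' @export
trainModel <- function(model, config = trainingConfig(), seed = 1L) {
  stopifnot(inherits(model, "FieldModel"), inherits(config, "TrainingConfig"))
  p <- model$params
  m <- p$m
  grid <- stimulusGrid(config$train_grid[1], config$train_grid[2],
                       config$margin)
  S <- stimulusSet(model$patch, grid, p$sigma_s)
  k <- nrow(S)
  W <- model$W
  mask <- model$cortical_mask
  kern <- model$kernels
  G <- model$G
  tracked <- config$tracked_units
  hist_dw <- if (length(tracked))
    matrix(NA_real_, config$epochs, length(tracked)) else NULL
  drawn <- integer(config$epochs)

  gain <- p$lateral_gain
  a <- p$alpha * gain
  dtau <- p$dt / p$tau
  circ <- p$boundary == "circular"
  kf <- attr(kern, "fft_full")
  mm <- m * m

  withLocalSeed(seed, {
    for (e in seq_len(config$epochs)) {
      i <- sample.int(k, 1L)
      drawn[e] <- i
      s <- S[i, ]
      I <- matrix(as.vector(G) * (1 - rowMeans(abs(W - rep(s, each = mm)))),
                  m, m)
      V <- matrix(0, m, m)
      W_prev <- if (length(tracked)) W[tracked, , drop = FALSE] else NULL
      for (t in seq_len(config$max_steps)) {
        Fv <- rectify(V)
        L <- if (circ) Re(stats::fft(stats::fft(Fv) * kf, inverse = TRUE)) / mm
             else latticeConvolve(Fv, kern, boundary = "linear")
        Vn <- V + dtau * (-V + a * L + I)
        if (!is.null(mask)) Vn[mask] <- 0
        if (config$per_step) {
          Le <- lateralExcitation(Fv, kern, p)
          W <- W + (p$gamma * p$dt * as.vector(Le)) * (rep(s, each = mm) - W)
        }
        d <- max(abs(Vn - V))
        V <- Vn
        if (!all(is.finite(V)))
          stop(sprintf("integration diverged at epoch %d", e), call. = FALSE)
        if (d < config$tol) break
      }
      if (!config$per_step) {
        Le <- lateralExcitation(rectify(V), kern, p)
        W <- W + (p$gamma * as.vector(Le)) * (rep(s, each = mm) - W)
      }
      if (length(tracked))
        hist_dw[e, ] <- rowMeans(abs(W[tracked, , drop = FALSE] - W_prev))
      # field reset to rest happens implicitly: V is rebuilt next epoch
    }
  })

  model$W <- W
  history <- data.frame(epoch = seq_len(config$epochs), stimulus = drawn)
  if (length(tracked)) {
    dw <- as.data.frame(hist_dw)
    names(dw) <- paste0("delta_w_unit", tracked)
    history <- cbind(history, dw)
  }
  class(history) <- c("TrainingHistory", "data.frame")
  list(model = model, history = history)
}

#' Lesion the model and retrain it
#'
#' Applies a skin or cortical lesion to a trained model and reruns the
#' training protocol with the same stimulus grid. For a skin lesion the
#' stimulus set is unchanged but silenced receptors transmit zeros (the
#' stimuli are larger than the lesion and still recruit its neighbors);
#' for a cortical lesion the affected units are nullified at every
#' integration step.
#'
#' @param model a trained `FieldModel`.
#' @param spec a [lesionSpec()]; for `target = "cortex"` its `grid_shape`
#'   must match the field lattice.
#' @param config a [trainingConfig()] for the retraining phase.
#' @param seed integer seed for the retraining stimulus draws.
#' @return As [trainModel()]: list with the reorganized `model` (carrying
#'   the lesion) and the retraining `history`.
#' @export
runLesionExperiment <- function(model, spec, config = trainingConfig(),
                                seed = 1L) {
  stopifnot(inherits(model, "FieldModel"), inherits(spec, "LesionSpec"))
  mask <- makeLesionMask(spec)
  if (spec$target == "skin") {
    model$patch <- applySkinLesion(model$patch, mask)
  } else {
    if (!all(attr(mask, "spec")$grid_shape == model$params$m))
      stop("cortical lesion grid must match the field lattice", call. = FALSE)
    prev <- model$cortical_mask
    lm <- unclass(mask)
    model$cortical_mask <- if (is.null(prev)) lm else (prev | lm)
  }
  trainModel(model, config, seed = seed)
}

#' Verify the input-matching property of the field
#'
#' With the default parameter set, the settled field neither amplifies nor
#' attenuates a uniform input: for a uniform input at level `c` (fed
#' through the corrective gain, as all input is) the maximum rectified
#' activity of the settled field equals `c`. The check integrates the
#' field from rest for each requested level, in one- and/or
#' two-dimensional mode.
#'
#' @param params a [fieldParams()] object.
#' @param levels input levels in `(0, 1]`.
#' @param dims integer vector, subset of `c(1, 2)`.
#' @param max_steps,tol settling control (the bump emerges from a nearly
#'   uniform state, which takes far longer than stimulus-driven settling).
#' @return A data frame with columns `dims`, `level`, `max_activity` and
#'   `abs_error`.
#' @export
matchPropertyCheck <- function(params = fieldParams(),
                               levels = c(0.25, 0.5, 0.75),
                               dims = c(1L, 2L),
                               max_steps = 4000L, tol = 1e-10) {
  stopifnot(all(levels > 0), all(levels <= 1))
  out <- do.call(rbind, lapply(dims, function(d) {
    mx <- vapply(levels, function(cc)
      settledUniformMax(params, dims = d, level = cc,
                        max_steps = max_steps, tol = tol), numeric(1))
    data.frame(dims = d, level = levels, max_activity = mx,
               abs_error = abs(mx - levels))
  }))
  rownames(out) <- NULL
  out
}
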