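#' Lateral excitation received across the field
#'
#' The total excitation received at each unit is the lattice convolution of
#' the excitatory lobe of the lateral weight function with the rectified
#' field activity, scaled by the same calibrated lateral gain as the field
#' integration. Its support extends beyond the active bump, which is what
#' lets sub-threshold neighbors of the winning population learn.
#'
#' Unlike the field integration (whose circular FFT is a numerical device,
#' corrected at the input by the corrective Gaussian), the learning
#' neighborhood is a physical cortical neighborhood and does not wrap:
#' the default boundary here is zero-padded. Letting it wrap allows border
#' units to learn from bumps on the opposite edge of the sheet, which
#' seeds fold defects in the map.
#'
#' @param F `m x m` rectified (non-negative) activity map.
#' @param kernels a [lateralKernels()] object.
#' @param params a [fieldParams()] object (uses `lateral_gain`).
#' @param boundary convolution boundary for the excitation; `"linear"`
#'   (zero-padded, default) or `"circular"`.
#' @return An `m x m` non-negative excitation map.
#' @export
lateralExcitation <- function(F, kernels, params,
                              boundary = c("linear", "circular")) {
  boundary <- match.arg(boundary)
  if (any(F < 0))
    stop("activity must be rectified before computing lateral excitation",
         call. = FALSE)
  gain <- params$lateral_gain
  if (is.null(gain)) gain <- defaultLateralGain(kernels$m)
  Le <- gain * latticeConvolve(F, kernels, part = "exc", boundary = boundary)
  rectify(Le)  # clears FFT round-off below zero
}

#' Oja-style update of the feed-forward weights
#'
#' Moves every unit's weight vector toward the current receptor activation
#' pattern, at a rate set by the lateral excitation the unit receives:
#' \deqn{w_{f,i}(x) \leftarrow w_{f,i}(x) +
#'   \gamma\,L_e(x)\,(s_i - w_{f,i}(x))}
#' The pre-synaptic difference term gives Hebbian growth where the stimulus
#' exceeds the weight and anti-Hebbian decay where it falls short; the
#' post-synaptic factor \eqn{L_e} replaces the firing rate of the original
#' Oja rule, so units below firing threshold still learn if they are
#' excited. While \eqn{\gamma L_e(x) \le 1} the move is convex and weights
#' stay in `[0, 1]`; beyond that the update overshoots and a warning is
#' raised (boundedness is monitored, never enforced by clipping).
#'
#' @param W `m^2 x n` feed-forward weights.
#' @param s receptor activations, length `n` (silenced receptors contribute
#'   `s_i = 0` and so drag their weights toward zero — the mechanism of
#'   receptive-field migration after a skin lesion).
#' @param Le lateral excitation from [lateralExcitation()] (`m x m` matrix
#'   or length-`m^2` vector).
#' @param gamma learning rate.
#' @return The updated weight matrix.
#' @export
updateWeights <- function(W, s, Le, gamma) {
  if (gamma < 0) stop("gamma must be non-negative", call. = FALSE)
  le <- as.vector(Le)
  if (length(le) != nrow(W) || length(s) != ncol(W))
    stop("weights, activations and excitation disagree in shape",
         call. = FALSE)
  rate <- gamma * le
  if (length(rate) && max(rate) > 1)
    warning(sprintf("gamma * max(Le) = %.3f > 1: overshoot regime, weights may leave [0,1]",
                    max(rate)), call. = FALSE)
  W + rate * (rep(s, each = nrow(W)) - W)
}

#' Mean absolute weight change of one unit
#'
#' The per-epoch weight-evolution diagnostic: the mean over receptors of
#' the absolute difference between a unit's current and previous weight
#' vectors.
#'
#' @param W_now,W_prev `m^2 x n` weight matrices of identical shape.
#' @param unit unit index (row).
#' @return A single non-negative number.
#' @export
weightChangeMetric <- function(W_now, W_prev, unit) {
  if (!all(dim(W_now) == dim(W_prev)))
    stop("weight tensors must have identical shapes", call. = FALSE)
  mean(abs(W_now[unit, ] - W_prev[unit, ]))
}
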