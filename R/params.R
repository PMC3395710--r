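#' Model parameters for the cortical field
#'
#' Constructs the parameter set governing the dynamic neural field and the
#' skin model. Defaults are the published parameter set for which the field
#' exhibits the input-matching property (the settled maximum activity of the
#' field equals the level of a uniform input).
#'
#' All spatial scales are expressed in normalized units: the skin patch and
#' the cortical sheet both live on the unit square, and the Gaussians use the
#' convention \eqn{\exp(-d^2 / (2\sigma^2))} throughout.
#'
#' @param Ke,Ki amplitudes of the excitatory and inhibitory lobes of the
#'   difference-of-Gaussians lateral weight function.
#' @param sigma_e,sigma_i widths of the excitatory and inhibitory lobes, in
#'   normalized field units. `sigma_e < sigma_i` is required (short-range
#'   excitation, long-range inhibition).
#' @param mu_c,sigma_c radial offset and width of the corrective Gaussian
#'   gain applied to the feed-forward input to compensate boundary
#'   side-effects of the lattice convolution.
#' @param sigma_s spatial scale of the pressure spread of a point stimulus
#'   on the skin, in normalized patch units.
#' @param dt Euler integration step.
#' @param alpha scaling factor of the lateral interaction term.
#' @param tau membrane time constant.
#' @param gamma learning rate of the plasticity rule.
#' @param m side length of the square cortical lattice (units per side).
#' @param lateral_gain dimensionless gain of the lattice convolution. The
#'   default `NULL` resolves to a calibrated value for the lattice via
#'   [defaultLateralGain()]; see [calibrateLateralGain()] for how these are
#'   obtained.
#' @param boundary convolution boundary rule: `"circular"` (default; the
#'   corrective Gaussian compensates the wrap) or `"linear"` (zero-padded).
#'
#' @return An object of class `FieldParams` (a validated named list).
#' @examples
#' p <- fieldParams()
#' p$Ke - p$Ki   # central value of the lateral kernel
#' @export
fieldParams <- function(Ke = 3.65, Ki = 2.40,
                        sigma_e = 0.1, sigma_i = 1.0,
                        mu_c = 0.0, sigma_c = 2.1,
                        sigma_s = 0.15,
                        dt = 0.2, alpha = 0.1, tau = 1.0,
                        gamma = 0.05,
                        m = 32L,
                        lateral_gain = NULL,
                        boundary = c("circular", "linear")) {
  boundary <- match.arg(boundary)
  p <- list(Ke = Ke, Ki = Ki, sigma_e = sigma_e, sigma_i = sigma_i,
            mu_c = mu_c, sigma_c = sigma_c, sigma_s = sigma_s,
            dt = dt, alpha = alpha, tau = tau, gamma = gamma,
            m = as.integer(m), lateral_gain = lateral_gain,
            boundary = boundary)
  validateFieldParams(p)
  class(p) <- "FieldParams"
  p
}

validateFieldParams <- function(p) {
  stopifnot(is.numeric(p$Ke), is.numeric(p$Ki))
  if (p$sigma_e <= 0 || p$sigma_i <= 0 || p$sigma_c <= 0 || p$sigma_s <= 0)
    stop("all Gaussian widths must be positive", call. = FALSE)
  if (p$sigma_e >= p$sigma_i)
    stop("sigma_e must be smaller than sigma_i ",
         "(short-range excitation, long-range inhibition)", call. = FALSE)
  if (p$tau <= 0 || p$dt <= 0)
    stop("tau and dt must be positive", call. = FALSE)
  if (p$gamma < 0) stop("gamma must be non-negative", call. = FALSE)
  if (p$m < 2) stop("field must have at least 2 units per side", call. = FALSE)
  if (!is.null(p$lateral_gain) && p$lateral_gain <= 0)
    stop("lateral_gain must be positive", call. = FALSE)
  invisible(p)
}

#' @export
print.FieldParams <- function(x, ...) {
  cat("Field parameters (", x$m, "x", x$m, " lattice, ",
      x$boundary, " convolution)\n", sep = "")
  cat(sprintf("  DoG:    Ke=%.2f Ki=%.2f sigma_e=%.2f sigma_i=%.2f\n",
              x$Ke, x$Ki, x$sigma_e, x$sigma_i))
  cat(sprintf("  gain:   mu_c=%.2f sigma_c=%.2f  stimulus sigma=%.2f\n",
              x$mu_c, x$sigma_c, x$sigma_s))
  cat(sprintf("  dynamics: dt=%.2f alpha=%.2f tau=%.2f gamma=%.3f\n",
              x$dt, x$alpha, x$tau, x$gamma))
  g <- if (is.null(x$lateral_gain)) "auto" else sprintf("%.4f", x$lateral_gain)
  cat("  lateral gain: ", g, "\n", sep = "")
  invisible(x)
}

# Calibrated lattice gains for the default parameter set, obtained with
# calibrateLateralGain() (bisection on the settled response to a uniform
# unit input fed through the corrective gain). Keyed by "<dims>D<m>".
.somatomap_gains <- new.env(parent = emptyenv())

#' Default lateral gain for a lattice
#'
#' The lattice convolution used by the field is a raw FFT lattice sum; its
#' overall scale therefore depends on the lattice resolution. A single
#' dimensionless gain multiplies the convolution, chosen so that the field
#' with default parameters exhibits the input-matching property. Calibrated
#' values for common lattices are cached in the package; other lattices are
#' calibrated on the fly (and memoized for the session).
#'
#' @param m units per side of the lattice.
#' @param dims 1 or 2, dimensionality of the field.
#' @return The gain as a single number.
#' @seealso [calibrateLateralGain()]
#' @export
defaultLateralGain <- function(m, dims = 2L) {
  key <- paste0(dims, "D", m)
  cached <- c("2D16" = 0.89523217, "2D32" = 0.17390352, "1D32" = 0.58623680)
  if (key %in% names(cached)) return(unname(cached[[key]]))
  if (!is.null(.somatomap_gains[[key]])) return(.somatomap_gains[[key]])
  g <- calibrateLateralGain(fieldParams(m = m), dims = dims)
  .somatomap_gains[[key]] <- g
  g
}

#' Calibrate the lattice-convolution gain against the matching property
#'
#' For the published parameter set the field should neither amplify nor
#' attenuate a uniform input: the settled maximum of the rectified activity
#' equals the input level. Because the rectified dynamics are positively
#' homogeneous, it suffices to enforce this at unit level; the property then
#' holds at every level. This function finds by bisection the convolution
#' gain at which the settled maximum response to a uniform unit input (fed
#' through the corrective gain, as every input is) equals 1.
#'
#' @param params a [fieldParams()] object (its `lateral_gain` is ignored).
#' @param dims field dimensionality, 1 or 2.
#' @param lo,hi bisection bracket for the gain.
#' @param iters number of bisection iterations.
#' @param max_steps,tol settling control for each probe integration.
#' @return The calibrated gain.
#' @export
calibrateLateralGain <- function(params, dims = 2L, lo = 0.01, hi = 8,
                                 iters = 26L, max_steps = 4000L, tol = 1e-10) {
  f <- function(g) {
    p <- params
    p$lateral_gain <- g
    # divergence counts as exceeding the target level
    tryCatch(settledUniformMax(p, dims = dims, level = 1,
                               max_steps = max_steps, tol = tol),
             error = function(e) Inf)
  }
  if (f(lo) >= 1) stop("bracket does not enclose the matching gain (lo)")
  if (f(hi) <= 1) stop("bracket does not enclose the matching gain (hi)")
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 1) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
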