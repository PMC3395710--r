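#' Rectified firing
#'
#' The firing function of the field is a simple rectification,
#' \eqn{f(V) = \max(V, 0)} — the simplest choice that stabilizes the field.
#'
#' @param V numeric matrix (or vector) of membrane potentials.
#' @return `pmax(V, 0)`, same shape.
#' @export
rectify <- function(V) {
  V[V < 0] <- 0
  V
}

#' Corrective Gaussian gain over the cortical sheet
#'
#' A fixed radial Gaussian \eqn{G(x) = \exp(-(r(x)-\mu_c)^2 / 2\sigma_c^2)},
#' where \eqn{r(x)} is the distance of unit \eqn{x} from the field center,
#' multiplied into the feed-forward input to correct the boundary
#' side-effects of the lattice convolution (with the default circular
#' convolution, the wrap would otherwise make the sheet effectively toric).
#' With the defaults (\eqn{\mu_c = 0}, \eqn{\sigma_c = 2.1}) the gain is 1
#' at the center and about 0.945 at the corners.
#'
#' @param params a [fieldParams()] object.
#' @param m lattice side; defaults to `params$m`.
#' @return An `m x m` matrix of gains in `(0, 1]`.
#' @export
correctiveGain <- function(params, m = params$m) {
  x <- seq(0, 1, length.out = m)
  r <- sqrt(outer((x - 0.5)^2, (x - 0.5)^2, `+`))
  exp(-(r - params$mu_c)^2 / (2 * params$sigma_c^2))
}

#' Feed-forward input of the field
#'
#' For every cortical unit, the input measures how well the unit's
#' feed-forward weight vector matches the current receptor activation
#' pattern:
#' \deqn{I(x) = G(x) \left(1 - \frac{1}{n} \sum_i |s_i - w_{f,i}(x)|\right)}
#' so \eqn{I(x) \in [0, G(x)]} whenever weights and activations lie in
#' `[0,1]`, and a perfect match yields \eqn{I = G}.
#'
#' @param W feed-forward weights, an `m^2 x n` matrix (units in
#'   column-major lattice order, one row per unit).
#' @param s receptor activations, length `n`.
#' @param G corrective gain from [correctiveGain()] (an `m x m` matrix).
#' @return An `m x m` input map.
#' @export
feedforwardInput <- function(W, s, G) {
  if (ncol(W) != length(s))
    stop("weight tensor and activation vector disagree on receptor count",
         call. = FALSE)
  if (nrow(W) != length(G))
    stop("weight tensor and gain map disagree on unit count", call. = FALSE)
  mismatch <- rowMeans(abs(W - rep(s, each = nrow(W))))
  matrix(as.vector(G) * (1 - mismatch), nrow(G), ncol(G))
}

#' One forward-Euler step of the field equation
#'
#' Advances the membrane potential by
#' \deqn{V \leftarrow V + \frac{dt}{\tau}\left(-V +
#'   \alpha\,\kappa\,(w \star f(V)) + I\right)}
#' where \eqn{\star} is the lattice convolution of [latticeConvolve()],
#' \eqn{\kappa} the calibrated lateral gain, and \eqn{f} the rectification.
#' Units marked dead in `mask` are nullified after the step.
#'
#' @param V `m x m` membrane potentials.
#' @param I `m x m` input map.
#' @param kernels a [lateralKernels()] object.
#' @param params a [fieldParams()] object (uses `dt`, `tau`, `alpha`,
#'   `lateral_gain`, `boundary`).
#' @param mask optional `m x m` logical; `TRUE` marks a dead (lesioned)
#'   unit whose potential is forced to 0.
#' @return The updated potential matrix.
#' @export
fieldStep <- function(V, I, kernels, params, mask = NULL) {
  gain <- params$lateral_gain
  if (is.null(gain)) gain <- defaultLateralGain(kernels$m)
  L <- latticeConvolve(rectify(V), kernels, part = "full",
                       boundary = params$boundary)
  V <- V + (params$dt / params$tau) * (-V + params$alpha * gain * L + I)
  if (!is.null(mask)) V[mask] <- 0
  if (!all(is.finite(V)))
    stop("field integration became non-finite; check dt, tau and the kernel",
         call. = FALSE)
  V
}

#' Integrate the field to its settled state
#'
#' Applies [fieldStep()] until the largest potential change falls below
#' `tol` or `max_steps` is reached. The default window (50 steps of
#' `dt = 0.2` at `tau = 1`) spans 10 membrane time constants.
#'
#' @inheritParams fieldStep
#' @param max_steps maximum number of Euler steps (at least 1).
#' @param tol convergence tolerance on `max |dV|`.
#' @return A list with `V` (settled potentials), `steps` (steps taken) and
#'   `converged` (logical).
#' @export
settleField <- function(V, I, kernels, params, mask = NULL,
                        max_steps = 50L, tol = 1e-6) {
  stopifnot(max_steps >= 1L, tol >= 0)
  steps <- 0L
  converged <- FALSE
  # fast path: inline the step to avoid re-dispatch per iteration
  gain <- params$lateral_gain
  if (is.null(gain)) gain <- defaultLateralGain(kernels$m)
  a <- params$alpha * gain
  dtau <- params$dt / params$tau
  circ <- params$boundary == "circular"
  kf <- attr(kernels, "fft_full")
  mm <- kernels$m^2
  for (t in seq_len(max_steps)) {
    Fv <- rectify(V)
    L <- if (circ) Re(stats::fft(stats::fft(Fv) * kf, inverse = TRUE)) / mm
         else latticeConvolve(Fv, kernels, boundary = "linear")
    Vn <- V + dtau * (-V + a * L + I)
    if (!is.null(mask)) Vn[mask] <- 0
    d <- max(abs(Vn - V))
    V <- Vn
    steps <- t
    if (!all(is.finite(V)))
      stop("field integration became non-finite; check dt, tau and the kernel",
           call. = FALSE)
    if (d < tol) { converged <- TRUE; break }
  }
  list(V = V, steps = steps, converged = converged)
}

# settled maximum rectified activity for a uniform input level fed through
# the corrective gain; used by the match check and gain calibration.
settledUniformMax <- function(params, dims = 2L, level = 1,
                              max_steps = 4000L, tol = 1e-10) {
  if (dims == 2L) {
    k <- lateralKernels(params)
    G <- correctiveGain(params)
    st <- settleField(matrix(0, params$m, params$m), level * G, k, params,
                      max_steps = max_steps, tol = tol)
    return(max(rectify(st$V)))
  }
  # one-dimensional field on [0,1] with the same conventions
  m <- params$m
  h <- 1 / (m - 1)
  off <- minImageIndex(m) * h
  w <- params$Ke * exp(-off^2 / (2 * params$sigma_e^2)) -
       params$Ki * exp(-off^2 / (2 * params$sigma_i^2))
  kf <- stats::fft(w)
  x <- seq(0, 1, length.out = m)
  G <- exp(-(abs(x - 0.5) - params$mu_c)^2 / (2 * params$sigma_c^2))
  gain <- params$lateral_gain
  if (is.null(gain)) gain <- defaultLateralGain(m, dims = 1L)
  a <- params$alpha * gain
  dtau <- params$dt / params$tau
  V <- numeric(m)
  I <- level * G
  for (t in seq_len(max_steps)) {
    Fv <- pmax(V, 0)
    L <- Re(stats::fft(stats::fft(Fv) * kf, inverse = TRUE)) / m
    Vn <- V + dtau * (-V + a * L + I)
    if (!all(is.finite(Vn)))
      stop("field integration became non-finite; check dt, tau and the kernel",
           call. = FALSE)
    d <- max(abs(Vn - V))
    V <- Vn
    if (d < tol) break
  }
  max(pmax(V, 0))
}
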