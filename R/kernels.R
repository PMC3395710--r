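#' Difference-of-Gaussians lateral kernels
#'
#' Samples the lateral weight function
#' \deqn{w(\Delta) = K_e e^{-\|\Delta\|^2/2\sigma_e^2} -
#'                   K_i e^{-\|\Delta\|^2/2\sigma_i^2}}
#' on the lattice offsets of an `m x m` field whose units live on a
#' normalized \eqn{[0,1]^2} lattice (spacing \eqn{1/(m-1)}). `w_full` and
#' `w_exc` are centered odd-sized matrices over all offsets
#' \eqn{-(m-1)..(m-1)}; the circular min-image samplings used by the FFT
#' path are cached in attributes.
#'
#' @param params a [fieldParams()] object.
#' @param m lattice side; defaults to `params$m`.
#' @return An object of class `LateralKernels` with elements `w_full`,
#'   `w_exc` (both `(2m-1) x (2m-1)`), and `offsets` (the offset coordinates
#'   in normalized units).
#' @examples
#' k <- lateralKernels(fieldParams())
#' k$w_full[k$m, k$m]  # central value, Ke - Ki
#' @export
lateralKernels <- function(params, m = params$m) {
  if (params$sigma_e <= 0 || params$sigma_i <= 0)
    stop("kernel widths must be positive", call. = FALSE)
  h <- 1 / (m - 1)
  off <- seq.int(-(m - 1), m - 1) * h
  r2 <- outer(off^2, off^2, `+`)
  w_exc <- params$Ke * exp(-r2 / (2 * params$sigma_e^2))
  w_inh <- params$Ki * exp(-r2 / (2 * params$sigma_i^2))
  k <- list(w_full = w_exc - w_inh, w_exc = w_exc, offsets = off, m = m)
  # circular (min-image) samplings, origin at index 1, plus their FFTs
  ci <- minImageIndex(m)
  circ_full <- k$w_full[ci + m, ci + m, drop = FALSE]
  circ_exc <- w_exc[ci + m, ci + m, drop = FALSE]
  attr(k, "fft_full") <- stats::fft(circ_full)
  attr(k, "fft_exc") <- stats::fft(circ_exc)
  # padded arrangements for the zero-padded (non-wrapping) linear path
  attr(k, "fft_full_pad") <- stats::fft(padKernel(k$w_full, m))
  attr(k, "fft_exc_pad") <- stats::fft(padKernel(w_exc, m))
  class(k) <- "LateralKernels"
  k
}

# embed a centered (2m-1) offset kernel in a 2m x 2m grid with the origin
# at [1,1] (negative offsets wrapped to the end) for linear convolution
padKernel <- function(w, m) {
  p <- 2L * m
  Wp <- matrix(0, p, p)
  for (a in seq.int(-(m - 1), m - 1)) for (b in seq.int(-(m - 1), m - 1)) {
    Wp[(a %% p) + 1L, (b %% p) + 1L] <- w[a + m, b + m]
  }
  Wp
}

# integer offsets in FFT order: 0, 1, ..., floor((m-1)/2), -ceiling((m-1)/2), ..., -1
minImageIndex <- function(m) {
  i <- seq.int(0L, m - 1L)
  ifelse(i <= (m %/% 2), i, i - m)
}

#' @export
print.LateralKernels <- function(x, ...) {
  cat("DoG lateral kernels on a ", x$m, "x", x$m,
      " lattice (central value ", format(x$w_full[x$m, x$m]), ")\n", sep = "")
  invisible(x)
}

#' Lattice convolution of an activity map with a lateral kernel
#'
#' Circular convolution on the field lattice, computed either through the
#' FFT (the fast path used by the integrator) or by a direct double loop
#' (the reference oracle; `O(m^4)`). Both produce the raw lattice sum
#' \eqn{(w \star F)(x) = \sum_y w(x - y) F(y)} with offsets taken modulo the
#' lattice (min-image). With `boundary = "linear"` the sum is zero-padded
#' instead of wrapped.
#'
#' @param F an `m x m` numeric matrix (typically rectified activity).
#' @param kernels a [lateralKernels()] object for the same lattice.
#' @param part `"full"` for the DoG, `"exc"` for the excitatory lobe alone.
#' @param boundary `"circular"` or `"linear"`.
#' @param method `"fft"` or `"direct"`.
#' @return An `m x m` matrix.
#' @export
latticeConvolve <- function(F, kernels, part = c("full", "exc"),
                            boundary = c("circular", "linear"),
                            method = c("fft", "direct")) {
  part <- match.arg(part)
  boundary <- match.arg(boundary)
  method <- match.arg(method)
  m <- kernels$m
  stopifnot(is.matrix(F), nrow(F) == m, ncol(F) == m)
  w <- if (part == "full") kernels$w_full else kernels$w_exc

  if (boundary == "circular") {
    if (method == "fft") {
      kf <- attr(kernels, if (part == "full") "fft_full" else "fft_exc")
      return(Re(stats::fft(stats::fft(F) * kf, inverse = TRUE)) / (m * m))
    }
    ci <- minImageIndex(m)            # integer offset of each index
    out <- matrix(0, m, m)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      acc <- 0
      for (a in seq_len(m)) for (b in seq_len(m)) {
        di <- (i - a) %% m            # wrapped offset, then min-image value
        dj <- (j - b) %% m
        acc <- acc + w[ci[di + 1L] + m, ci[dj + 1L] + m] * F[a, b]
      }
      out[i, j] <- acc
    }
    return(out)
  }

  # zero-padded linear convolution, same-size crop
  if (method == "direct") {
    out <- matrix(0, m, m)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      acc <- 0
      for (a in seq_len(m)) for (b in seq_len(m)) {
        acc <- acc + w[(i - a) + m, (j - b) + m] * F[a, b]
      }
      out[i, j] <- acc
    }
    return(out)
  }
  p <- 2L * m                          # pad so linear conv does not wrap
  Fp <- matrix(0, p, p); Fp[1:m, 1:m] <- F
  wf <- attr(kernels, if (part == "full") "fft_full_pad" else "fft_exc_pad")
  if (is.null(wf)) wf <- stats::fft(padKernel(w, m))
  full <- Re(stats::fft(stats::fft(Fp) * wf, inverse = TRUE)) / (p * p)
  full[1:m, 1:m]
}
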