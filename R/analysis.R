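#' Receptive fields of every cortical unit
#'
#' Presents each probe stimulus to the model with learning disabled,
#' settles the field from rest, and records every unit's settled rectified
#' activity. The per-unit receptive field (RF) is the resulting matrix of
#' activities over the probe grid; its center of mass and normalized size
#' summarize where on the skin the unit listens and how broadly.
#' Probing is side-effect free: the weight tensor is read, never written.
#'
#' @param model a `FieldModel`.
#' @param probes probe stimulus centers, typically [stimulusGrid()]
#'   (default 25 x 25 with the standard margin).
#' @param max_steps,tol settling control per probe.
#' @return An object of class `RFSummary`: list with `rf` (an
#'   `m^2 x q^2` matrix, one row per unit), `probes`, `centers`
#'   (`m^2 x 2`, `NA` where undefined), `sizes` (length `m^2`), and
#'   `defined` (logical).
#' @export
computeReceptiveFields <- function(model, probes = NULL,
                                   max_steps = 50L, tol = 1e-6) {
  stopifnot(inherits(model, "FieldModel"))
  if (is.null(probes)) probes <- stimulusGrid(25L, 25L)
  p <- model$params
  m <- p$m
  q2 <- nrow(probes)
  rf <- matrix(0, m * m, q2)
  for (j in seq_len(q2)) {
    s <- receptorResponse(model$patch, probes[j, ], p$sigma_s)
    I <- feedforwardInput(model$W, s, model$G)
    st <- settleField(matrix(0, m, m), I, model$kernels, p,
                      mask = model$cortical_mask,
                      max_steps = max_steps, tol = tol)
    rf[, j] <- as.vector(rectify(st$V))
  }
  sizes <- apply(rf, 1L, rfSize)
  centers <- t(apply(rf, 1L, rfCenter, probe_positions = probes))
  structure(list(rf = rf, probes = probes, centers = centers,
                 sizes = sizes, defined = !is.na(centers[, 1]), m = m),
            class = "RFSummary")
}

#' @export
print.RFSummary <- function(x, ...) {
  cat("Receptive fields of ", x$m^2, " units over ", nrow(x$probes),
      " probes: ", sum(x$defined), " defined, mean size ",
      signif(mean(x$sizes[x$defined]), 3), "\n", sep = "")
  invisible(x)
}

#' Center of mass of one receptive field
#'
#' \deqn{c = \sum_j p_j a_j / \sum_j a_j} over the probe stimuli, where
#' \eqn{a_j} is the unit's settled activity for probe \eqn{j} at position
#' \eqn{p_j}. An all-zero RF has no center and returns `NA` (reported as
#' missing, not an error).
#'
#' @param rf numeric vector of activities over the probes.
#' @param probe_positions `q^2 x 2` matrix of probe centers.
#' @return Length-2 numeric (`c(NA, NA)` if undefined).
#' @export
rfCenter <- function(rf, probe_positions) {
  tot <- sum(rf)
  if (tot <= 0) return(c(NA_real_, NA_real_))
  c(sum(probe_positions[, 1] * rf), sum(probe_positions[, 2] * rf)) / tot
}

#' Normalized size of one receptive field
#'
#' The fraction of probes with a strictly positive response. Positivity is
#' taken relative to the unit's own maximum (`threshold` times the map
#' maximum) so that FFT round-off at the 1e-16 level does not count.
#'
#' @param rf numeric vector of activities over the probes.
#' @param threshold relative positivity threshold.
#' @return A number in `[0, 1]`.
#' @export
rfSize <- function(rf, threshold = 1e-6) {
  mx <- max(rf)
  if (mx <= 0) return(0)
  mean(rf > threshold * mx)
}

#' Histogram of receptive-field sizes
#'
#' Counts per equal-width bin over `[0, 1]` (100 bins by default, as in
#' the reference figures), with nothing excluded — the near-zero component
#' from mostly silent border units is reported as-is.
#'
#' @param sizes numeric vector of RF sizes in `[0, 1]`.
#' @param bins number of bins.
#' @return A data frame `(bin_left, bin_right, count)` with attributes
#'   `mean` and `sd` of the sizes.
#' @export
rfSizeHistogram <- function(sizes, bins = 100L) {
  stopifnot(bins >= 1L)
  br <- seq(0, 1, length.out = bins + 1L)
  idx <- pmin(bins, findInterval(sizes, br, rightmost.closed = TRUE))
  idx <- pmax(1L, idx)
  cnt <- tabulate(idx, nbins = bins)
  structure(data.frame(bin_left = br[-length(br)], bin_right = br[-1],
                       count = cnt),
            mean = mean(sizes), sd = stats::sd(sizes))
}

#' Settled response maps for a validation stimulus grid
#'
#' The data behind the response-mosaic panels: for each validation
#' stimulus, the settled rectified field activity with learning disabled.
#'
#' @param model a `FieldModel`.
#' @param grid validation stimulus centers (default 10 x 10).
#' @param max_steps,tol settling control.
#' @return An `m x m x k` array of rectified settled activities.
#' @export
responseMap <- function(model, grid = NULL, max_steps = 50L, tol = 1e-6) {
  stopifnot(inherits(model, "FieldModel"))
  if (is.null(grid)) grid <- stimulusGrid(10L, 10L)
  p <- model$params
  m <- p$m
  out <- array(0, c(m, m, nrow(grid)))
  for (j in seq_len(nrow(grid))) {
    s <- receptorResponse(model$patch, grid[j, ], p$sigma_s)
    I <- feedforwardInput(model$W, s, model$G)
    st <- settleField(matrix(0, m, m), I, model$kernels, p,
                      mask = model$cortical_mask,
                      max_steps = max_steps, tol = tol)
    out[, , j] <- rectify(st$V)
  }
  out
}

#' Lattice coordinates of the cortical units
#'
#' Unit positions on the normalized \eqn{[0,1]^2} lattice, in the same
#' (column-major) order as the rows of the weight tensor.
#'
#' @param m lattice side.
#' @return An `m^2 x 2` matrix.
#' @export
unitPositions <- function(m) {
  x <- seq(0, 1, length.out = m)
  cbind(x = rep(x, times = m), y = rep(x, each = m))
}

#' Topographic order of a receptive-field map
#'
#' Pearson correlation, per axis, between each unit's lattice coordinate
#' and its RF center coordinate, over units with defined centers. A
#' perfect topographic map scores +1 or -1 on each axis; shuffled centers
#' score near 0. The orientation of a self-organized map is arbitrary
#' among the eight symmetries of the square, so the correlations are also
#' computed with the center axes swapped (the diagonal reflections) and
#' the axis assignment with the larger minimum `|r|` is reported, with a
#' flag. Signs are kept (axis reversals are visible in the sign). Also
#' reports the mean Euclidean displacement between unit position and RF
#' center under the identity assignment.
#'
#' @param centers `m^2 x 2` matrix of RF centers (`NA` rows allowed).
#' @param unit_positions `m^2 x 2` matrix from [unitPositions()].
#' @return A list with `r` (length-2 signed correlations under the chosen
#'   assignment), `axes_swapped` (logical), `mean_displacement`, and `n`
#'   (units used).
#' @export
topographicOrder <- function(centers, unit_positions) {
  ok <- !is.na(centers[, 1]) & !is.na(centers[, 2])
  if (sum(ok) < 10L)
    stop("fewer than 10 units have defined receptive-field centers",
         call. = FALSE)
  up <- unit_positions[ok, , drop = FALSE]
  ce <- centers[ok, , drop = FALSE]
  ident <- c(x = stats::cor(up[, 1], ce[, 1]),
             y = stats::cor(up[, 2], ce[, 2]))
  swap <- c(x = stats::cor(up[, 1], ce[, 2]),
            y = stats::cor(up[, 2], ce[, 1]))
  swapped <- min(abs(swap)) > min(abs(ident))
  disp <- mean(sqrt(rowSums((up - ce)^2)))
  list(r = if (swapped) swap else ident,
       axes_swapped = swapped,
       mean_displacement = disp, n = sum(ok))
}

#' Write a receptive-field summary as CSV
#'
#' Columns `unit_row, unit_col, center_x, center_y, size, defined`, units
#' in column-major lattice order.
#'
#' @param summary an `RFSummary`.
#' @param path file path.
#' @export
writeRFSummary <- function(summary, path) {
  m <- summary$m
  df <- data.frame(unit_row = rep(seq_len(m), times = m),
                   unit_col = rep(seq_len(m), each = m),
                   center_x = summary$centers[, 1],
                   center_y = summary$centers[, 2],
                   size = summary$sizes,
                   defined = summary$defined)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
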