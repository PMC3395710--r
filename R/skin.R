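#' Build a skin patch of Merkel-ending receptors
#'
#' Places `rows * cols` slowly-adapting mechanoreceptors (Merkel ending
#' complexes) on the unit square: a regular lattice spanning
#' \eqn{[0,1]^2} plus independent uniform position jitter per coordinate,
#' clipped to the patch. The default 16 x 16 arrangement gives the 256
#' receptors of a roughly 1 mm^2 fingertip patch at natural Merkel density.
#'
#' @param rows,cols lattice dimensions (each at least 2).
#' @param jitter_amplitude half-width of the uniform jitter, in normalized
#'   patch units.
#' @param seed integer seed; the patch is deterministic given the seed.
#' @return An object of class `SkinPatch`: a list with `positions` (an
#'   `n x 2` matrix), `grid_shape`, `jitter_amplitude`, `active` (logical
#'   vector, `FALSE` marks a silenced receptor), and `seed`.
#' @examples
#' p <- buildSkinPatch()
#' nrow(p$positions)  # 256
#' @export
buildSkinPatch <- function(rows = 16L, cols = 16L, jitter_amplitude = 0.01,
                           seed = 1L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 2L || cols < 2L)
    stop("skin grid needs at least 2 rows and 2 columns", call. = FALSE)
  if (jitter_amplitude < 0)
    stop("jitter_amplitude must be non-negative", call. = FALSE)
  gx <- rep(seq(0, 1, length.out = rows), times = cols)
  gy <- rep(seq(0, 1, length.out = cols), each = rows)
  n <- rows * cols
  jit <- withLocalSeed(seed, {
    matrix(stats::runif(2L * n, -jitter_amplitude, jitter_amplitude),
           ncol = 2L)
  })
  pos <- cbind(x = gx, y = gy) + jit
  pos[] <- pmin(pmax(pos, 0), 1)
  structure(list(positions = pos,
                 grid_shape = c(rows, cols),
                 jitter_amplitude = jitter_amplitude,
                 active = rep(TRUE, n),
                 seed = as.integer(seed)),
            class = "SkinPatch")
}

# evaluate expr with a temporary RNG state seeded by `seed`
withLocalSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.SkinPatch <- function(x, ...) {
  cat("Skin patch: ", nrow(x$positions), " receptors (",
      x$grid_shape[1], "x", x$grid_shape[2], " grid, jitter ",
      x$jitter_amplitude, "), ", sum(!x$active), " silenced\n", sep = "")
  invisible(x)
}

#' Receptor activations for a point stimulus
#'
#' The mechanics of the skin spread a point press to nearby locations: an
#' active receptor at distance \eqn{d} from the stimulus center responds
#' with \eqn{\exp(-d^2 / 2\sigma^2)}. Silenced (lesioned) receptors
#' transmit exactly 0.
#'
#' @param patch a [buildSkinPatch()] object.
#' @param center length-2 numeric, stimulus center in \eqn{[0,1]^2}.
#' @param sigma pressure-spread scale; defaults to the stimulus width of
#'   [fieldParams()].
#' @return Numeric vector of length `n` with values in `[0, 1]`.
#' @export
receptorResponse <- function(patch, center, sigma = 0.15) {
  stopifnot(inherits(patch, "SkinPatch"))
  center <- as.numeric(center)
  if (length(center) != 2L || any(center < 0) || any(center > 1))
    stop("stimulus center must lie on the skin patch [0,1]^2", call. = FALSE)
  if (sigma <= 0) stop("stimulus sigma must be positive", call. = FALSE)
  d2 <- (patch$positions[, 1] - center[1])^2 +
        (patch$positions[, 2] - center[2])^2
  s <- exp(-d2 / (2 * sigma^2))
  s[!patch$active] <- 0
  s
}

#' Silence the receptors inside a lesioned skin region
#'
#' Marks as inactive every receptor whose position falls inside the
#' lesioned region of `mask` (closed regions: receptors on the boundary are
#' silenced). Positions are unchanged; applying the same mask twice is a
#' no-op.
#'
#' @param patch a [buildSkinPatch()] object.
#' @param mask a [makeLesionMask()] object with `target = "skin"`.
#' @return The patch with an updated `active` vector.
#' @export
applySkinLesion <- function(patch, mask) {
  stopifnot(inherits(patch, "SkinPatch"), inherits(mask, "LesionMask"))
  inside <- lesionAt(mask, patch$positions)
  if (all(inside))
    warning("lesion silences every receptor; the field will receive null input",
            call. = FALSE)
  patch$active <- patch$active & !inside
  patch
}

#' Write / read a skin patch as a columnar text table
#'
#' Round-trips the patch through CSV with columns
#' `receptor_id, x, y, active` (plus grid shape and jitter as a header
#' comment), bit-compatibly for the positions.
#'
#' @param patch a `SkinPatch`.
#' @param path file path.
#' @return `readSkinPatch` returns the reconstructed `SkinPatch`.
#' @export
writeSkinPatch <- function(patch, path) {
  stopifnot(inherits(patch, "SkinPatch"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rows=%d cols=%d jitter=%.17g seed=%d",
                     patch$grid_shape[1], patch$grid_shape[2],
                     patch$jitter_amplitude, patch$seed), con)
  df <- data.frame(receptor_id = seq_len(nrow(patch$positions)),
                   x = sprintf("%.17g", patch$positions[, 1]),
                   y = sprintf("%.17g", patch$positions[, 2]),
                   active = as.integer(patch$active))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSkinPatch
#' @export
readSkinPatch <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-z]+=[-0-9.e+]+", hdr))[[1]]
  vals <- stats::setNames(
    as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  df <- utils::read.csv(path, comment.char = "#")
  structure(list(positions = cbind(x = df$x, y = df$y),
                 grid_shape = as.integer(c(vals["rows"], vals["cols"])),
                 jitter_amplitude = unname(vals["jitter"]),
                 active = df$active == 1L,
                 seed = as.integer(vals["seed"])),
            class = "SkinPatch")
}
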