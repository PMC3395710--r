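#' Specify a typed lesion
#'
#' Three lesion geometries with distinct topological signatures are
#' studied, for either the skin or the cortical sheet:
#' \describe{
#'   \item{type I}{an axis-aligned rectangle touching the domain border;
#'     the surviving region is a single component topologically equivalent
#'     to the intact domain.}
#'   \item{type II}{a full-width band that splits the surviving region
#'     into two disconnected components.}
#'   \item{type III}{an interior rectangle touching no border; the
#'     surviving region stays connected but acquires a hole.}
#' }
#'
#' @param target `"skin"` or `"cortex"`.
#' @param type `"I"`, `"II"` or `"III"`.
#' @param fraction fraction of the domain area lesioned, in `(0, 1)`.
#'   Defaults: 0.25 for types I and II, 0.10 for type III.
#' @param orientation for type II, `"vertical"` (band of columns, the
#'   default) or `"horizontal"`.
#' @param grid_shape rasterization grid `(rows, cols)`; for a cortical
#'   lesion this must equal the field lattice.
#' @return An object of class `LesionSpec`.
#' @export
lesionSpec <- function(target = c("skin", "cortex"),
                       type = c("I", "II", "III"),
                       fraction = NULL,
                       orientation = c("vertical", "horizontal"),
                       grid_shape = c(32L, 32L)) {
  target <- match.arg(target)
  type <- match.arg(type)
  orientation <- match.arg(orientation)
  if (is.null(fraction)) fraction <- if (type == "III") 0.10 else 0.25
  if (fraction <= 0 || fraction >= 1)
    stop("lesion fraction must lie strictly between 0 and 1", call. = FALSE)
  structure(list(target = target, type = type, fraction = fraction,
                 orientation = orientation,
                 grid_shape = as.integer(grid_shape)),
            class = "LesionSpec")
}

#' Rasterize a lesion specification into a boolean mask
#'
#' Produces a deterministic logical grid (`TRUE` = lesioned) realizing the
#' requested type and fraction to within one row/column of cells, and
#' satisfying the type's topological signature (see [maskTopology()]).
#'
#' @param spec a [lesionSpec()].
#' @return An object of class `LesionMask`: the logical `rows x cols`
#'   matrix with the spec attached as attribute `"spec"`.
#' @export
makeLesionMask <- function(spec) {
  stopifnot(inherits(spec, "LesionSpec"))
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  mk <- matrix(FALSE, nr, nc)
  f <- spec$fraction
  if (spec$type == "II") {
    # full-width band through the middle
    if (spec$orientation == "vertical") {
      w <- max(1L, round(f * nc))
      if (w >= nc) stop("type II band would span the whole domain", call. = FALSE)
      j0 <- floor((nc - w) / 2) + 1L
      mk[, j0:(j0 + w - 1L)] <- TRUE
    } else {
      w <- max(1L, round(f * nr))
      if (w >= nr) stop("type II band would span the whole domain", call. = FALSE)
      i0 <- floor((nr - w) / 2) + 1L
      mk[i0:(i0 + w - 1L), ] <- TRUE
    }
  } else if (spec$type == "I") {
    # near-square rectangle anchored at the domain border (lower-left corner)
    a <- max(1L, round(sqrt(f * nr * nc)))
    a <- min(a, nr - 1L, nc - 1L)
    mk[1:a, 1:a] <- TRUE
  } else {
    # type III: centered interior rectangle, clear of every border
    a <- max(1L, round(sqrt(f * nr * nc)))
    a <- min(a, nr - 2L, nc - 2L)
    i0 <- floor((nr - a) / 2) + 1L
    j0 <- floor((nc - a) / 2) + 1L
    i0 <- max(2L, i0); j0 <- max(2L, j0)
    mk[i0:(i0 + a - 1L), j0:(j0 + a - 1L)] <- TRUE
  }
  structure(mk, spec = spec, class = c("LesionMask", "matrix", "array"))
}

#' @export
print.LesionMask <- function(x, ...) {
  s <- attr(x, "spec")
  cat("Lesion mask type ", s$type, " on ", s$target, ": ",
      sum(x), "/", length(x), " cells lesioned\n", sep = "")
  invisible(x)
}

#' Topological signature of a lesion mask
#'
#' Counts the 4-connected components of the unlesioned region and reports
#' whether any lesioned cell lies on the domain border. The expected
#' signatures are `(1, TRUE)` for type I, `(2, TRUE)` for type II and
#' `(1, FALSE)` for type III.
#'
#' @param mask a [makeLesionMask()] object (or any logical matrix with
#'   `TRUE` marking lesioned cells).
#' @return A list with `components_unlesioned` and `lesion_touches_border`.
#' @export
maskTopology <- function(mask) {
  m <- unclass(mask)
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  comp <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (m[i, j] || lab[i, j] != 0L) next
    comp <- comp + 1L
    # flood fill (iterative; explicit stack)
    stack <- list(c(i, j))
    lab[i, j] <- comp
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      ci <- cur[1]; cj <- cur[2]
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ni <- ci + d[1]; nj <- cj + d[2]
        if (ni >= 1L && ni <= nr && nj >= 1L && nj <= nc &&
            !m[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- comp
          stack[[length(stack) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  border <- any(m[1, ]) || any(m[nr, ]) || any(m[, 1]) || any(m[, nc])
  list(components_unlesioned = comp, lesion_touches_border = border)
}

# TRUE for each point (rows of an k x 2 matrix of [0,1]^2 coordinates)
# falling inside a lesioned cell of the rasterized mask. Cells partition
# the unit square; boundaries belong to the higher-index cell except at 1.
lesionAt <- function(mask, points) {
  nr <- nrow(mask); nc <- ncol(mask)
  i <- pmin(nr, floor(points[, 1] * nr) + 1L)
  j <- pmin(nc, floor(points[, 2] * nc) + 1L)
  mask[cbind(i, j)]
}

#' Evaluate a lesion mask at skin coordinates
#'
#' Maps receptor positions on the unit square to raster cells of the mask
#' and reports which fall in the lesioned region.
#'
#' @param mask a [makeLesionMask()] object.
#' @param points `k x 2` matrix of coordinates in \eqn{[0,1]^2}.
#' @return Logical vector of length `k`.
#' @export
lesionCovers <- function(mask, points) {
  stopifnot(inherits(mask, "LesionMask"))
  lesionAt(mask, points)
}

#' Serialize a lesion mask as a 0/1 CSV grid
#' @param mask a `LesionMask`.
#' @param path file path.
#' @export
writeLesionMask <- function(mask, path) {
  utils::write.table(matrix(as.integer(mask), nrow(mask), ncol(mask)),
                     path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
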