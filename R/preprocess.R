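# Pre-processing: denoising, binarization, morphological repair of the
# skin band, upper-boundary extraction, and removal of the chest-wall
# organs below a fitted parabola.

#' Median-filter a slice
#'
#' Exact sliding-window median with edge replication, implemented as a
#' vectorized sorting network so that results are exact in double
#' precision (histogram-based median filters quantize intensities).
#' `window = 1` is the identity.
#'
#' @param slice a [new_slice()] or numeric matrix.
#' @param window odd window size in pixels.
#' @return same type as the input.
#' @export
denoise <- function(slice, window = 3L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 1", call. = FALSE)
  m <- as_pixel_matrix(slice)
  if (window == 1L) return(slice)
  r <- (window - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  ridx <- pmin(pmax(seq(1L - r, nr + r), 1L), nr)
  cidx <- pmin(pmax(seq(1L - r, nc + r), 1L), nc)
  pad <- m[ridx, cidx, drop = FALSE]
  k <- window * window
  s <- matrix(0, nr * nc, k)
  idx <- 1L
  for (dc in 0:(window - 1L)) for (dr in 0:(window - 1L)) {
    s[, idx] <- pad[(1L + dr):(nr + dr), (1L + dc):(nc + dc)]
    idx <- idx + 1L
  }
  # full bubble sorting network over the k window samples
  for (i in seq_len(k - 1L)) for (j in seq_len(k - i)) {
    a <- s[, j]; b <- s[, j + 1L]
    s[, j] <- pmin(a, b); s[, j + 1L] <- pmax(a, b)
  }
  med <- matrix(s[, (k + 1L) %/% 2L], nr, nc)
  if (inherits(slice, "breast_slice")) { slice$pixels <- med; slice }
  else med
}

#' Binarize a slice with Otsu's threshold
#'
#' Foreground is every pixel at or above the threshold maximizing the
#' between-class variance of the intensity histogram. A constant slice has
#' no threshold; it yields an empty foreground with a warning.
#'
#' @param slice a [new_slice()] or numeric matrix with values in `[0, 1]`.
#' @param levels number of histogram bins.
#' @return logical matrix with attribute `"threshold"`.
#' @export
binarize <- function(slice, levels = 256L) {
  m <- as_pixel_matrix(slice)
  if (diff(range(m)) < .Machine$double.eps) {
    warning("constant image: no Otsu threshold exists, returning empty foreground")
    out <- matrix(FALSE, nrow(m), ncol(m))
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  th <- EBImage::otsu(m, range = c(0, 1), levels = as.integer(levels))
  out <- m >= th
  attr(out, "threshold") <- th
  out
}

# Euclidean disk structuring element: all offsets with dr^2 + dc^2 <= r^2.
# For radius 1 this is the 4-neighborhood cross, which preserves slanted
# 3-px bands that a full 3x3 box erodes.
disc_kernel <- function(radius) {
  d <- seq(-radius, radius)
  k <- outer(d^2, d^2, `+`) <= radius^2
  matrix(as.numeric(k), length(d), length(d))
}

#' Morphological repair of the binarized skin
#'
#' Opening (removes speckles) then closing (bridges breaks) with a disk
#' structuring element. The default radius of 1 keeps skin bands of 3 px
#' and thicker intact; larger radii erase any structure thinner than
#' `2*radius + 1` px during the opening.
#'
#' @param mask logical matrix.
#' @param radius structuring-element radius in pixels (>= 1).
#' @return logical matrix of the same shape.
#' @export
repair_skin <- function(mask, radius = 1L) {
  radius <- as.integer(radius)
  if (radius < 1L) stop("`radius` must be >= 1", call. = FALSE)
  kern <- disc_kernel(radius)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  m <- EBImage::closing(EBImage::opening(m, kern), kern)
  matrix(as.numeric(m) > 0.5, nrow(mask), ncol(mask))
}

#' Extract the skin's upper boundary from a binary mask
#'
#' For each column, the boundary is the smallest row index with
#' foreground; columns without foreground are filled by linear
#' interpolation between their neighbors (flat extrapolation at the ends).
#' Fails unless at least half the columns contain foreground.
#'
#' @param mask logical matrix.
#' @return an object of class `skin_boundary` with fields `row` (numeric,
#'   possibly subpixel) and `col` (1..ncol).
#' @export
extract_upper_boundary <- function(mask) {
  nc <- ncol(mask)
  top <- apply(mask, 2, function(colv) {
    w <- which(colv)
    if (length(w) == 0L) NA_real_ else as.numeric(w[1])
  })
  if (sum(!is.na(top)) < nc / 2)
    stop("boundary not found: fewer than half the columns contain foreground",
         call. = FALSE)
  structure(list(row = fill_na_linear(top), col = seq_len(nc)),
            class = "skin_boundary")
}

# Lowest-row envelope of a mask, with the same gap interpolation as the
# upper boundary. Used to seed the snake at the inner edge of the
# binarized skin component.
extract_lower_envelope <- function(mask) {
  nc <- ncol(mask)
  bot <- apply(mask, 2, function(colv) {
    w <- which(colv)
    if (length(w) == 0L) NA_real_ else as.numeric(w[length(w)])
  })
  if (sum(!is.na(bot)) < nc / 2)
    stop("envelope not found: fewer than half the columns contain foreground",
         call. = FALSE)
  structure(list(row = fill_na_linear(bot), col = seq_len(nc)),
            class = "skin_boundary")
}

#' Locate the organ extrema A (lowest-left) and B (highest-middle)
#'
#' On the supplied binary mask, `A` is the lowest (largest-row) foreground
#' point within the left third of the columns and `B` the highest
#' (smallest-row) foreground point within the middle third. Ties for `A`
#' are broken by the smallest column (the extreme anchors the cut's
#' reach); ties for `B` by the central tied column, since the top of a
#' rasterized dome is a flat plateau and an off-center vertex skews the
#' cut. In the pipeline the mask holds the
#' organ-candidate components (foreground not connected to the skin), so
#' `B` is the top of the chest-wall mass and `A` its lowest left extent.
#'
#' @param mask logical matrix.
#' @return list with `A = c(x, y)` and `B = c(x, y)` where x is the
#'   column and y the row.
#' @export
locate_organ_extrema <- function(mask) {
  nc <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  third <- floor(nc / 3)
  left <- idx[idx[, 2] <= third, , drop = FALSE]
  mid <- idx[idx[, 2] > third & idx[, 2] <= 2 * third, , drop = FALSE]
  if (nrow(left) == 0L)
    stop("extrema not found: empty left third", call. = FALSE)
  if (nrow(mid) == 0L)
    stop("extrema not found: empty middle third", call. = FALSE)
  pick <- function(pts, decreasing, tie = c("first", "central")) {
    tie <- match.arg(tie)
    o <- order(pts[, 1], decreasing = decreasing)
    cand <- pts[o[1], 1]
    sel <- pts[pts[, 1] == cand, , drop = FALSE]
    cols <- sort(sel[, 2])
    col_pick <- if (tie == "first") cols[1]
                else cols[ceiling(length(cols) / 2)]
    sel[match(col_pick, sel[, 2]), ]
  }
  a <- pick(left, TRUE, "first")    # max row, leftmost on ties
  b <- pick(mid, FALSE, "central")  # min row, central tied column
  list(A = c(x = unname(a[2]), y = unname(a[1])),
       B = c(x = unname(b[2]), y = unname(b[1])))
}

#' Fit the organ-removal parabola through A with vertex B
#'
#' The cut is `y = -c (x - x_h)^2 + y_h` with vertex `(x_h, y_h) = B`
#' and curvature chosen so the curve passes through `A`:
#' `c = (y_h - y_A) / (x_A - x_h)^2`. On a row-down raster with the organ
#' mass below the breast, `y_A > y_h` makes `c` negative and the curve
#' opens toward larger rows on both sides of the vertex (the inverted-U
#' of the displayed image).
#'
#' @param A,B points as `c(x, y)` (column, row), e.g. from
#'   [locate_organ_extrema()].
#' @return an object of class `parabola_cut` with fields `x_h`, `y_h`,
#'   `c` and `A`.
#' @export
fit_parabola <- function(A, B) {
  x_a <- A[[1]]; y_a <- A[[2]]
  x_h <- B[[1]]; y_h <- B[[2]]
  if (x_a == x_h)
    stop("degenerate fit: A and B share the same column", call. = FALSE)
  cc <- (y_h - y_a) / (x_a - x_h)^2
  structure(list(x_h = x_h, y_h = y_h, c = cc,
                 A = c(x = x_a, y = y_a)),
            class = "parabola_cut")
}

#' Evaluate a parabola cut at given columns
#' @param cut a [fit_parabola()] object.
#' @param x column positions.
#' @return row of the cut at each column.
#' @export
parabola_row <- function(cut, x) {
  -cut$c * (x - cut$x_h)^2 + cut$y_h
}

#' Remove internal organs below a parabola cut
#'
#' Zeroes every pixel whose row is at or below the cut (row >= curve at
#' that column). Idempotent.
#'
#' @param slice a [new_slice()] or numeric matrix.
#' @param cut a [fit_parabola()] object.
#' @return list with `slice` (cleaned, same type as input) and
#'   `organ_mask` (logical matrix of removed pixels).
#' @export
remove_organs <- function(slice, cut) {
  m <- as_pixel_matrix(slice)
  ycut <- parabola_row(cut, seq_len(ncol(m)))
  organ <- outer(seq_len(nrow(m)), ycut, `>=`)
  m[organ] <- 0
  if (inherits(slice, "breast_slice")) slice$pixels <- m else slice <- m
  list(slice = slice, organ_mask = organ)
}
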