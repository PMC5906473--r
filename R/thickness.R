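# Skin-thickness continuity analysis.
#
# The rough active-contour segmentation cannot distinguish vessels and
# mammary glands adherent to the skin's inner side: where they attach,
# the segmented band is abruptly thicker. Genuine skin thickens and thins
# gradually, so thickness is measured along the boundary normals and
# discontinuous jumps are replaced by the locally continuous (running
# median) thickness. The final skin mask is swept from the boundary using
# the corrected thickness, leaving the adherent structures in place.

#' Order the upper boundary into a numbered point sequence
#'
#' Points are numbered left to right (increasing column); right-to-left
#' input is reversed and duplicated columns are collapsed to their mean
#' row.
#'
#' @param boundary a `skin_boundary` or an n x 2 (row, col) matrix.
#' @return n x 2 matrix of (row, col) points ordered by column.
#' @export
order_boundary <- function(boundary) {
  pts <- if (inherits(boundary, "skin_boundary"))
    cbind(boundary$row, boundary$col) else as.matrix(boundary)
  dimnames(pts) <- NULL
  if (nrow(pts) == 0L) stop("empty boundary", call. = FALSE)
  cols <- pts[, 2]
  if (anyDuplicated(cols)) {
    rows <- tapply(pts[, 1], cols, mean)
    pts <- cbind(as.numeric(rows), as.numeric(names(rows)))
  }
  pts[order(pts[, 2]), , drop = FALSE]
}

#' Tangents and inward normals along the boundary
#'
#' The tangent at point i is the normalized forward difference
#' `p[i+1] - p[i]` (backward at the last point). The normal is the
#' tangent rotated 90 degrees — clockwise on the displayed row-down
#' raster, `(t_row, t_col) -> (t_col, -t_row)` — and flipped if needed so
#' it points toward increasing row, i.e. into the breast interior below
#' the upper boundary.
#'
#' @param sequence ordered n x 2 (row, col) matrix from
#'   [order_boundary()], n >= 2.
#' @return an object of class `normal_field`: list of n x 2 matrices
#'   `tangent` and `normal`, both unit length.
#' @export
normals <- function(sequence) {
  pts <- as.matrix(sequence)
  n <- nrow(pts)
  if (n < 2L) stop("need at least 2 boundary points", call. = FALSE)
  d <- diff(pts)
  d <- rbind(d, d[n - 1L, , drop = FALSE])  # backward difference at the end
  len <- sqrt(rowSums(d^2))
  zero <- len < 1e-12
  if (any(zero)) {  # coincident consecutive points: borrow a neighbor
    for (i in which(zero)) {
      j <- which(!zero)
      if (length(j) == 0L) stop("degenerate boundary", call. = FALSE)
      k <- j[which.min(abs(j - i))]
      d[i, ] <- d[k, ]; len[i] <- len[k]
    }
  }
  tang <- d / len
  nrm <- cbind(tang[, 2], -tang[, 1])
  flip <- nrm[, 1] < 0
  nrm[flip, ] <- -nrm[flip, , drop = FALSE]
  structure(list(tangent = tang, normal = nrm), class = "normal_field")
}

#' Measure raw skin thickness along boundary normals
#'
#' From each boundary point, marches into the mask along the inward
#' normal in `march_step` px increments, sampling the mask bilinearly
#' (inside = value >= 0.5). The raw thickness is the distance at which
#' the ray first leaves the mask; points that start outside the mask
#' record 0.
#'
#' @param rough_mask logical matrix (the rough snake segmentation).
#' @param sequence ordered boundary points ([order_boundary()]).
#' @param normal_field matching [normals()].
#' @param march_step step size in px.
#' @param max_march maximum march distance in px.
#' @return an object of class `thickness_profile` with fields `raw`,
#'   `corrected` (NULL until [correct_thickness()]), and the points used.
#' @export
measure_thickness <- function(rough_mask, sequence, normal_field,
                              march_step = 0.5, max_march = 60) {
  pts <- as.matrix(sequence)
  nrm <- normal_field$normal
  stopifnot(nrow(pts) == nrow(nrm))
  m <- matrix(as.numeric(rough_mask), nrow(rough_mask), ncol(rough_mask))
  s <- seq(0, max_march, by = march_step)
  rr <- outer(nrm[, 1], s) + pts[, 1]
  cc <- outer(nrm[, 2], s) + pts[, 2]
  inside <- matrix(bilinear_sample(m, as.numeric(rr), as.numeric(cc)) >= 0.5,
                   nrow(pts), length(s))
  # positions that leave the frame count as outside
  off <- rr < 1 | rr > nrow(m) | cc < 1 | cc > ncol(m)
  inside[off] <- FALSE
  raw <- apply(inside, 1, function(z) {
    if (!z[1]) return(0)
    ex <- which(!z)
    if (length(ex) == 0L) return(s[length(s)])
    s[ex[1]]
  })
  structure(list(raw = as.numeric(raw), corrected = NULL,
                 points = pts, march_step = march_step),
            class = "thickness_profile")
}

#' Correct a thickness profile by skin-thickness continuity
#'
#' Computes the running median of the raw profile; where the raw
#' thickness exceeds `k` times the running median (a discontinuous jump,
#' i.e. an adherent vessel or gland) it is replaced by the median.
#' Gradual thickening and thinning pass through unchanged. Zeros are
#' filled by linear interpolation and the result is smoothed with a
#' 3-point mean.
#'
#' @param profile a [measure_thickness()] result (or numeric vector).
#' @param window odd running-median window (shrunk to the profile length
#'   when necessary).
#' @param k outlier factor (> 1).
#' @return the profile with `corrected` filled in.
#' @export
correct_thickness <- function(profile, window = 9L, k = 2.0) {
  raw <- if (inherits(profile, "thickness_profile")) profile$raw
         else as.numeric(profile)
  if (k <= 1) stop("`k` must be > 1", call. = FALSE)
  n <- length(raw)
  w <- odd_leq(min(as.integer(window), n))
  if (w < 1L) w <- 1L
  med <- if (w >= 3L) stats::runmed(raw, w, endrule = "median") else raw
  corrected <- ifelse(raw > k * med, med, raw)
  corrected[corrected <= 0] <- NA_real_
  corrected <- fill_na_linear(corrected)
  corrected[is.na(corrected)] <- 0  # all-zero profile: nothing to recover
  if (n >= 3L) {
    corrected <- (c(corrected[1], corrected[-n]) + corrected +
                    c(corrected[-1], corrected[n])) / 3
  }
  if (!inherits(profile, "thickness_profile"))
    profile <- structure(list(raw = raw, corrected = NULL, points = NULL,
                              march_step = NA_real_),
                         class = "thickness_profile")
  profile$corrected <- as.numeric(corrected)
  profile$window <- w
  profile$k <- k
  profile
}

#' Rasterize the final skin mask from the corrected thickness
#'
#' Sweeps each boundary point along its inward normal for its corrected
#' thickness (half-open band: distances `0 <= s < corrected`), unions the
#' swept pixels and applies a radius-1 morphological closing to seal
#' rasterization gaps.
#'
#' @param sequence ordered boundary points.
#' @param normal_field matching [normals()].
#' @param corrected corrected thickness per point (or a
#'   `thickness_profile` with `corrected` set).
#' @param shape (rows, cols) of the output mask.
#' @param march_step rasterization step along the normal, in px.
#' @param close_radius radius of the sealing closing; 0 disables.
#' @return logical matrix.
#' @export
skin_mask <- function(sequence, normal_field, corrected, shape,
                      march_step = 0.5, close_radius = 1L) {
  if (inherits(corrected, "thickness_profile")) {
    if (is.null(corrected$corrected))
      stop("profile has no corrected thickness yet", call. = FALSE)
    corrected <- corrected$corrected
  }
  pts <- as.matrix(sequence)
  nrm <- normal_field$normal
  nr <- shape[1]; nc <- shape[2]
  mask <- matrix(FALSE, nr, nc)
  if (any(corrected > 0)) {
    s_all <- seq(0, max(corrected), by = march_step)
    rr <- outer(nrm[, 1], s_all) + pts[, 1]
    cc <- outer(nrm[, 2], s_all) + pts[, 2]
    keep <- outer(corrected, s_all, `>`)
    ri <- floor(rr[keep] + 1e-9)
    ci <- round(cc[keep])
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    ri <- ri[ok]; ci <- ci[ok]
    # the band never extends above the boundary: clamp each swept pixel
    # to the boundary row of the column it actually falls in
    u_col <- rep(NA_real_, nc)
    bc <- round(pts[, 2])
    for (i in seq_len(nrow(pts))) {
      b <- bc[i]
      if (b >= 1 && b <= nc && (is.na(u_col[b]) || pts[i, 1] < u_col[b]))
        u_col[b] <- pts[i, 1]
    }
    u_col <- fill_na_linear(u_col)
    keep2 <- ri >= ceiling(u_col[ci] - 1e-9)
    mask[cbind(ri[keep2], ci[keep2])] <- TRUE
    if (close_radius >= 1L) {
      kern <- EBImage::makeBrush(2L * as.integer(close_radius) + 1L, "disc")
      m <- EBImage::closing(matrix(as.numeric(mask), nr, nc), kern)
      mask <- matrix(as.numeric(m) > 0.5, nr, nc)
    }
  }
  mask
}

#' Remove the segmented skin from a slice
#'
#' Skin pixels are set to zero; everything else — including vessels and
#' glands adjacent to the skin — keeps its original intensity.
#'
#' @param slice a [new_slice()] or numeric matrix.
#' @param mask logical skin mask of the same shape.
#' @return same type as the input.
#' @export
remove_skin <- function(slice, mask) {
  m <- as_pixel_matrix(slice)
  if (!identical(dim(m), dim(mask)))
    stop("slice and mask shapes differ", call. = FALSE)
  m[mask] <- 0
  if (inherits(slice, "breast_slice")) { slice$pixels <- m; slice }
  else m
}
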