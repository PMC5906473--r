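# Open active-contour (snake) model for the rough skin segmentation.
#
# The snake minimizes int 1/2(alpha|v'|^2 + beta|v''|^2) + E_ext(v) ds
# with the Kass semi-implicit update: internal forces are treated
# implicitly through the pentadiagonal stiffness matrix of an open curve
# with fixed endpoints, external forces explicitly as -grad E_ext sampled
# bilinearly at the contour points.

#' Snake parameters
#'
#' @param alpha stretch (first-derivative) weight; resists elongation.
#' @param beta curvature (second-derivative) weight; resists bending.
#' @param w_line,w_edge,w_term weights of the three image-energy terms:
#'   raw intensity, negative squared gradient magnitude, and level-line
#'   curvature of a slightly smoothed image.
#' @param step evolution step size (gamma).
#' @param max_iter maximum number of iterations.
#' @param tol mean point displacement (px) below which the snake is
#'   declared converged.
#' @param smooth_sigma Gaussian sigma (px) of the "slightly smoothed"
#'   image used by the termination energy; 0 skips smoothing.
#' @param resample_every check/restore ~1 px point spacing every this
#'   many iterations (keeps |v'| well conditioned).
#' @param eps floor on the termination-energy denominator.
#' @return an object of class `snake_params`.
#' @export
snake_params <- function(alpha = 0.1, beta = 1.0, w_line = 0, w_edge = 1,
                         w_term = 0.5, step = 1, max_iter = 500L,
                         tol = 0.1, smooth_sigma = 2,
                         resample_every = 10L, eps = 1e-8) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0", call. = FALSE)
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  if (tol < 0) stop("tol must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, w_line = w_line,
                 w_edge = w_edge, w_term = w_term, step = step,
                 max_iter = as.integer(max_iter), tol = tol,
                 smooth_sigma = smooth_sigma,
                 resample_every = as.integer(resample_every), eps = eps),
            class = "snake_params")
}

#' External energy fields of a slice
#'
#' Computes `e_line = I`, `e_edge = -|grad I|^2` (central differences),
#' and the termination energy
#' `e_term = (C_yy C_x^2 - 2 C_xy C_x C_y + C_xx C_y^2) / (C_x^2 + C_y^2)^(3/2)`
#' — the curvature of the level lines of the Gaussian-smoothed image `C` —
#' with the denominator floored at `eps`. The combined field is
#' `e_ext = w_line e_line + w_edge e_edge + w_term e_term` (the constraint
#' energy of the general model is an extension hook and contributes zero).
#'
#' @param slice a [new_slice()] or numeric matrix (`x` = column,
#'   `y` = row).
#' @param params a [snake_params()].
#' @return an object of class `energy_field` with fields `e_line`,
#'   `e_edge`, `e_term`, `e_ext`.
#' @export
external_energy <- function(slice, params = snake_params()) {
  i_img <- as_pixel_matrix(slice)
  gx <- grad_col(i_img); gy <- grad_row(i_img)
  e_line <- i_img
  e_edge <- -(gx^2 + gy^2)
  c_img <- gaussian_blur(i_img, params$smooth_sigma)
  cx <- grad_col(c_img); cy <- grad_row(c_img)
  cxx <- grad_col(cx); cyy <- grad_row(cy); cxy <- grad_row(cx)
  denom <- pmax((cx^2 + cy^2)^1.5, params$eps)
  e_term <- (cyy * cx^2 - 2 * cxy * cx * cy + cxx * cy^2) / denom
  e_ext <- params$w_line * e_line + params$w_edge * e_edge +
    params$w_term * e_term
  structure(list(e_line = e_line, e_edge = e_edge, e_term = e_term,
                 e_ext = e_ext),
            class = "energy_field")
}

# Internal stiffness matrix K (n x n) for an open curve: K = alpha A1 +
# beta A2 with A1 = D1' D1 (first differences) and A2 = D2' D2 (second
# differences), i.e. natural boundary conditions at the free interior and
# identity rows at the two fixed endpoints.
snake_system <- function(n, params) {
  d1 <- diff(diag(n))
  a1 <- crossprod(d1)
  a2 <- if (n >= 3) crossprod(diff(diag(n), differences = 2)) else 0 * a1
  m <- diag(n) + params$step * (params$alpha * a1 + params$beta * a2)
  m[1, ] <- 0; m[1, 1] <- 1
  m[n, ] <- 0; m[n, n] <- 1
  m
}

# Gradient fields of e_ext, cached for evolve().
energy_gradients <- function(field) {
  list(gr = grad_row(field$e_ext), gc = grad_col(field$e_ext))
}

#' One semi-implicit snake iteration
#'
#' Solves `(I + step K) v_new = v_old + step F(v_old)` for the open-curve
#' stiffness matrix `K` with fixed endpoints, where the external force
#' `F = -grad e_ext` is sampled bilinearly at the contour points. Points
#' are clamped to the image bounds.
#'
#' @param contour n x 2 matrix of (row, col) points, n >= 3.
#' @param field an [external_energy()] object.
#' @param params a [snake_params()].
#' @param system optional precomputed inverse of the system matrix.
#' @param grads optional precomputed gradients of `e_ext`.
#' @return n x 2 matrix of updated points.
#' @export
snake_step <- function(contour, field, params, system = NULL, grads = NULL) {
  n <- nrow(contour)
  if (n < 3L) stop("a snake needs at least 3 points", call. = FALSE)
  if (is.null(grads)) grads <- energy_gradients(field)
  fr <- -bilinear_sample(grads$gr, contour[, 1], contour[, 2])
  fc <- -bilinear_sample(grads$gc, contour[, 1], contour[, 2])
  fr[c(1, n)] <- 0; fc[c(1, n)] <- 0
  rhs <- contour + params$step * cbind(fr, fc)
  rhs[1, ] <- contour[1, ]; rhs[n, ] <- contour[n, ]
  new <- if (is.null(system)) {
    m <- snake_system(n, params)
    tryCatch(solve(m, rhs), error = function(e)
      stop("singular snake system: ", conditionMessage(e), call. = FALSE))
  } else {
    system %*% rhs
  }
  nr <- nrow(field$e_ext); nc <- ncol(field$e_ext)
  new[, 1] <- pmin(pmax(new[, 1], 1), nr)
  new[, 2] <- pmin(pmax(new[, 2], 1), nc)
  dimnames(new) <- NULL
  new
}

# Resample an open contour to roughly `spacing` px arc-length spacing,
# keeping the endpoints.
resample_contour <- function(pts, spacing = 1) {
  seg <- sqrt(rowSums(diff(pts)^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  if (total < spacing) return(pts)
  n_new <- max(3L, round(total / spacing) + 1L)
  s_out <- seq(0, total, length.out = n_new)
  cbind(stats::approx(arc, pts[, 1], xout = s_out, ties = mean)$y,
        stats::approx(arc, pts[, 2], xout = s_out, ties = mean)$y)
}

# Discrete total energy: finite-difference internal energy plus the
# external field sampled at the points.
snake_energy <- function(pts, field, params) {
  internal <- 0.5 * params$alpha * sum(diff(pts)^2)
  if (nrow(pts) >= 3)
    internal <- internal +
      0.5 * params$beta * sum(diff(pts, differences = 2)^2)
  external <- sum(bilinear_sample(field$e_ext, pts[, 1], pts[, 2]))
  internal + external
}

#' Evolve a snake to convergence
#'
#' Iterates [snake_step()] until the mean point displacement drops below
#' `tol` or `max_iter` is reached. The step size is adapted by a
#' backtracking safeguard: an iteration that would increase the total
#' discrete energy is retried with half the step, so the energy trace is
#' non-increasing by construction; after successful iterations the step
#' grows back toward its configured value. The initial contour is
#' resampled to ~1 px spacing; spacing is checked every `resample_every`
#' iterations and restored when it drifts. Deterministic: no randomness
#' is involved.
#'
#' @param initial n x 2 matrix (row, col) or a `skin_boundary`; typically
#'   the skin's upper boundary or the binarized skin's inner envelope.
#' @param field an [external_energy()] object.
#' @param params a [snake_params()].
#' @return an object of class `snake_fit`: list with `contour` (final
#'   points), `n_iter`, and `energy` (total discrete energy per accepted
#'   iteration).
#' @export
evolve <- function(initial, field, params = snake_params()) {
  pts <- if (inherits(initial, "skin_boundary"))
    cbind(initial$row, initial$col) else as.matrix(initial)
  dimnames(pts) <- NULL
  pts <- resample_contour(pts, 1)
  grads <- energy_gradients(field)
  sys_cache <- new.env(parent = emptyenv())
  get_sys <- function(n, step) {
    key <- sprintf("%d_%.12g", n, step)
    if (!exists(key, envir = sys_cache)) {
      p <- params; p$step <- step
      assign(key, solve(snake_system(n, p)), envir = sys_cache)
    }
    get(key, envir = sys_cache)
  }
  step <- params$step
  energy <- numeric(0)
  e_prev <- snake_energy(pts, field, params)
  n_iter <- 0L
  for (it in seq_len(params$max_iter)) {
    n_iter <- it
    accepted <- FALSE
    for (try in 1:20) {
      p <- params; p$step <- step
      new <- snake_step(pts, field, p, system = get_sys(nrow(pts), step),
                        grads = grads)
      e_new <- snake_energy(new, field, params)
      if (e_new <= e_prev + 1e-12 * (1 + abs(e_prev))) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) break  # no descent direction left: converged
    disp <- mean(sqrt(rowSums((new - pts)^2)))
    pts <- new
    e_prev <- e_new
    energy <- c(energy, e_new)
    step <- min(params$step, step * 1.2)
    if (disp < params$tol) break
    if (it %% params$resample_every == 0L) {
      seg <- sqrt(rowSums(diff(pts)^2))
      if (max(seg) > 1.6 || min(seg) < 0.4) {
        pts <- resample_contour(pts, 1)
        e_prev <- snake_energy(pts, field, params)
      }
    }
  }
  structure(list(contour = pts, n_iter = n_iter, energy = energy),
            class = "snake_fit")
}

#' @export
print.snake_fit <- function(x, ...) {
  cat(sprintf("<snake_fit> %d points, %d iterations, final energy %.5g\n",
              nrow(x$contour), x$n_iter,
              if (length(x$energy)) x$energy[length(x$energy)] else NA))
  invisible(x)
}

#' Rasterize the band between the upper boundary and the evolved contour
#'
#' For each column spanned by both curves, marks the pixels with
#' `upper <= row < lower` as rough skin. Where the contours cross
#' (lower above upper) the band is clipped to zero thickness and the
#' crossing is flagged in the `"crossed"` attribute.
#'
#' @param upper a `skin_boundary` (one point per column).
#' @param lower an evolved contour (n x 2 matrix or `snake_fit`).
#' @param shape (rows, cols) of the output mask.
#' @return logical matrix.
#' @export
contour_to_band <- function(upper, lower, shape) {
  if (inherits(lower, "snake_fit")) lower <- lower$contour
  nr <- shape[1]; nc <- shape[2]
  lc <- lower[, 2]; lr <- lower[, 1]
  o <- order(lc)
  lo_row <- rep(NA_real_, nc)
  cls <- seq_len(nc)
  span <- cls >= ceiling(min(lc)) & cls <= floor(max(lc))
  lo_row[span] <- stats::approx(lc[o], lr[o], xout = cls[span],
                                ties = mean)$y
  mask <- matrix(FALSE, nr, nc)
  crossed <- FALSE
  for (cc in cls) {
    u <- upper$row[cc]; l <- lo_row[cc]
    if (is.na(l)) next
    if (l < u) { crossed <- TRUE; next }
    r0 <- max(1L, ceiling(u)); r1 <- min(nr, ceiling(l) - 1L)
    if (r1 >= r0) mask[r0:r1, cc] <- TRUE
  }
  attr(mask, "crossed") <- crossed
  mask
}
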