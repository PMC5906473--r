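# Internal numerical helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so generators never perturb user code.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a per-slice seed from a master seed; kept below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 1e6 * 2099 + index * 7919 + 17) %% 2147483647)
}

#' Bilinear interpolation of a matrix at subpixel positions
#'
#' Samples `mat` at fractional (row, col) positions using bilinear
#' interpolation; positions are clamped to the matrix extent first.
#'
#' @param mat numeric matrix.
#' @param r,c numeric vectors of row and column positions (1-based).
#' @return numeric vector of interpolated values, one per position.
#' @keywords internal
bilinear_sample <- function(mat, r, c) {
  nr <- nrow(mat); nc <- ncol(mat)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  if (nr == 1L) r0 <- rep(1, length(r))
  if (nc == 1L) c0 <- rep(1, length(c))
  fr <- r - r0; fc <- c - c0
  r1 <- pmin(r0 + 1, nr); c1 <- pmin(c0 + 1, nc)
  i00 <- (c0 - 1) * nr + r0
  i10 <- (c0 - 1) * nr + r1
  i01 <- (c1 - 1) * nr + r0
  i11 <- (c1 - 1) * nr + r1
  mat[i00] * (1 - fr) * (1 - fc) + mat[i10] * fr * (1 - fc) +
    mat[i01] * (1 - fr) * fc + mat[i11] * fr * fc
}

# Central-difference gradients with replicated edges. grad_row is d/drow
# (the paper-style "y" derivative on a row-down raster), grad_col is d/dcol.
grad_row <- function(m) {
  nr <- nrow(m)
  up <- m[c(1, seq_len(nr - 1)), , drop = FALSE]
  dn <- m[c(seq_len(nr)[-1], nr), , drop = FALSE]
  (dn - up) / 2
}

grad_col <- function(m) {
  nc <- ncol(m)
  lf <- m[, c(1, seq_len(nc - 1)), drop = FALSE]
  rt <- m[, c(seq_len(nc)[-1], nc), drop = FALSE]
  (rt - lf) / 2
}

# Gaussian smoothing with replicated borders (sigma in pixels; 0 = identity).
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  size <- min(size, 2L * (min(dim(m)) %/% 2L) - 1L)
  if (size < 3L) return(m)
  f <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  out <- EBImage::filter2(m, f, boundary = "replicate")
  matrix(as.numeric(out), nrow(m), ncol(m))
}

# Linear interpolation over NA runs of a numeric vector; flat extrapolation.
fill_na_linear <- function(x) {
  ok <- which(!is.na(x))
  if (length(ok) == 0L) return(x)
  if (length(ok) == length(x)) return(x)
  stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
}

as_pixel_matrix <- function(x) {
  if (inherits(x, "breast_slice")) x$pixels
  else if (is.matrix(x)) x
  else stop("expected a breast_slice or a numeric matrix", call. = FALSE)
}

odd_leq <- function(n) {
  n <- as.integer(n)
  if (n %% 2L == 0L) n - 1L else n
}
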