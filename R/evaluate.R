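# Evaluation: Dice volume similarity, GLCM texture features of a region
# before/after skin removal, and the paired t-test across cases.

#' Dice's coefficient between two binary masks or volumes
#'
#' `2|A intersect B| / (|A| + |B|)`; two empty masks are defined as
#' perfectly similar (1.0).
#'
#' @param a,b logical/0-1 arrays of identical shape.
#' @return numeric in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("mask shapes differ", call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1.0)
  2 * sum(a & b) / denom
}

#' Haralick texture features from a gray-level co-occurrence matrix
#'
#' Quantizes the patch to `levels` gray levels over a fixed intensity
#' range (default `[0, 1]`, the package's normalized intensity scale, so
#' that features of different patches share the same gray-level bins and
#' are comparable in paired tests; pass `range = NULL` to use the patch's
#' own min-max range), accumulates the symmetric co-occurrence matrix for
#' the given
#' pixel offset, normalizes it to probabilities p(i, j), and returns:
#' angular second moment `sum p^2` (homogeneity), entropy
#' `-sum p log p` (disorder; natural log by default), contrast
#' `sum (i-j)^2 p` (local variation), and the standard GLCM correlation
#' `sum (i - mu_x)(j - mu_y) p / (sigma_x sigma_y)` (texture
#' consistency). A constant patch has a single-cell GLCM: ASM 1, entropy
#' 0, contrast 0 and undefined correlation (`NaN`, with a warning).
#'
#' @param patch numeric matrix, at least 2 x 2 (1-row/1-column patches are
#'   accepted when the offset fits).
#' @param levels number of gray levels (>= 2).
#' @param offset integer `c(drow, dcol)` co-occurrence displacement.
#' @param log_base base of the entropy logarithm.
#' @param range intensity range mapped onto the gray levels (values are
#'   clamped to it); `NULL` uses the patch's own range.
#' @return an object of class `texture_features` with fields `asm`,
#'   `entropy`, `contrast`, `correlation`.
#' @export
glcm_features <- function(patch, levels = 8L, offset = c(0L, 1L),
                          log_base = exp(1), range = c(0, 1)) {
  if (levels < 2L) stop("`levels` must be >= 2", call. = FALSE)
  m <- as_pixel_matrix(patch)
  rng <- if (is.null(range)) base::range(m) else base::range(range)
  m <- pmin(pmax(m, rng[1]), rng[2])
  q <- if (diff(rng) <= 0) matrix(0L, nrow(m), ncol(m)) else {
    qq <- floor((m - rng[1]) / diff(rng) * levels)
    matrix(as.integer(pmin(qq, levels - 1)), nrow(m), ncol(m))
  }
  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])
  nr <- nrow(q); nc <- ncol(q)
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(r1) < 1L || length(c1) < 1L || min(r1) > max(r1))
    stop("offset larger than the patch", call. = FALSE)
  i <- q[r1, c1, drop = FALSE]
  j <- q[r1 + dr, c1 + dc, drop = FALSE]
  counts <- matrix(tabulate(as.integer(i) * levels + as.integer(j) + 1L,
                            nbins = levels * levels),
                   levels, levels, byrow = TRUE)
  counts <- counts + t(counts)  # symmetric GLCM
  p <- counts / sum(counts)
  lv <- seq_len(levels) - 1
  px <- rowSums(p); py <- colSums(p)
  mx <- sum(lv * px); my <- sum(lv * py)
  sx <- sqrt(sum((lv - mx)^2 * px)); sy <- sqrt(sum((lv - my)^2 * py))
  asm <- sum(p^2)
  entropy <- -sum(ifelse(p > 0, p * log(p, base = log_base), 0))
  contrast <- sum(outer(lv, lv, function(a, b) (a - b)^2) * p)
  correlation <- if (sx <= 0 || sy <= 0) {
    warning("constant patch: GLCM correlation is undefined")
    NaN
  } else sum(outer(lv - mx, lv - my) * p) / (sx * sy)
  structure(list(asm = asm, entropy = entropy, contrast = contrast,
                 correlation = correlation),
            class = "texture_features")
}

#' Paired two-sided t-test
#'
#' Student's t on the paired differences `d = x - y`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom.
#' Zero-variance differences are handled explicitly: all-zero differences
#' give `t = 0, p = 1`; constant nonzero differences give an infinite
#' statistic and `p = 0`.
#'
#' @param x,y paired samples of equal length, n >= 2.
#' @return an object of class `paired_ttest` with fields `t_statistic`,
#'   `dof`, `p_value`, `mean_with`, `mean_without`, `sd_with`,
#'   `sd_without` (x is the "with", y the "without" condition).
#' @export
paired_ttest <- function(x, y) {
  n <- length(x)
  if (n < 2L || length(y) != n)
    stop("need paired samples of equal length, n >= 2", call. = FALSE)
  d <- x - y
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) { t_stat <- 0; p <- 1 }
    else { t_stat <- sign(mean(d)) * Inf; p <- 0 }
  } else {
    t_stat <- mean(d) / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  structure(list(t_statistic = t_stat, dof = n - 1L, p_value = p,
                 mean_with = mean(x), mean_without = mean(y),
                 sd_with = stats::sd(x), sd_without = stats::sd(y)),
            class = "paired_ttest")
}

#' @export
print.paired_ttest <- function(x, ...) {
  cat(sprintf("Paired t-test: t = %.4f, df = %d, p = %.4g\n",
              x$t_statistic, x$dof, x$p_value))
  cat(sprintf("  with: %.4g +/- %.4g   without: %.4g +/- %.4g\n",
              x$mean_with, x$sd_with, x$mean_without, x$sd_without))
  invisible(x)
}

#' Texture assessment of a tumor region with and without the skin
#'
#' For each case, computes the slice-axis MIP with and without skin
#' removal, extracts the tumor region of interest, and measures its GLCM
#' texture features; then runs a paired t-test per feature across cases.
#' Mirrors the observability argument: a skin layer in front of the tumor
#' makes the projected region more homogeneous (higher ASM, lower entropy
#' and contrast) than the unobstructed view.
#'
#' @param with_cases list of [new_case_stack()] (skin present).
#' @param without_cases list of the same cases after skin removal.
#' @param roi `c(row1, row2, col1, col2)` region of interest, or a list
#'   of one ROI per case.
#' @param levels,offset passed to [glcm_features()].
#' @return list with `features` (data frame, one row per case and
#'   condition) and `tests` (named list of [paired_ttest()] results for
#'   asm, entropy, contrast, correlation).
#' @export
assess_cases <- function(with_cases, without_cases, roi,
                         levels = 8L, offset = c(0L, 1L)) {
  n <- length(with_cases)
  if (length(without_cases) != n)
    stop("with/without case lists differ in length", call. = FALSE)
  if (n < 2L)
    stop("paired texture assessment needs at least 2 cases", call. = FALSE)
  rois <- if (is.list(roi)) roi else rep(list(roi), n)
  one <- function(case, rr) {
    proj <- mip(stack_case(case), "slice")
    if (rr[1] < 1 || rr[3] < 1 || rr[2] > nrow(proj) || rr[4] > ncol(proj))
      stop("ROI outside the frame", call. = FALSE)
    glcm_features(proj[rr[1]:rr[2], rr[3]:rr[4]], levels, offset)
  }
  fw <- lapply(seq_len(n), function(i) one(with_cases[[i]], rois[[i]]))
  fo <- lapply(seq_len(n), function(i) one(without_cases[[i]], rois[[i]]))
  feat_names <- c("asm", "entropy", "contrast", "correlation")
  grab <- function(lst, f) vapply(lst, function(x) x[[f]], numeric(1))
  features <- do.call(rbind, lapply(feat_names, function(f)
    data.frame(feature = f, case = seq_len(n),
               with_skin = grab(fw, f), without_skin = grab(fo, f))))
  tests <- lapply(feat_names, function(f) {
    xw <- grab(fw, f); xo <- grab(fo, f)
    ok <- is.finite(xw) & is.finite(xo)
    if (sum(ok) < 2L) return(NULL)
    paired_ttest(xw[ok], xo[ok])
  })
  names(tests) <- feat_names
  list(features = features, tests = tests)
}
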