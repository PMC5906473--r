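#' Construct a single DCE-MRI slice
#'
#' A slice is the unit of segmentation: one 2-D grayscale image with its
#' pixel spacing and position in the stack. The whole package uses the
#' (row, col) raster convention with rows increasing downward, 1-based
#' indices; the "x" of the parabola and snake equations is the column and
#' "y" is the row.
#'
#' @param pixels numeric matrix of intensities. Volumes loaded through
#'   [read_case()] are rescaled to `[0, 1]`; the constructor only requires
#'   finite values so that analytic test images can be built directly.
#' @param row_spacing,col_spacing pixel size in mm/pixel; must be positive.
#' @param index position of the slice in its stack (0-based, matching the
#'   acquisition order).
#' @return an object of class `breast_slice`.
#' @export
new_slice <- function(pixels, row_spacing = 1, col_spacing = 1, index = 0L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("slice pixels must all be finite", call. = FALSE)
  if (row_spacing <= 0 || col_spacing <= 0)
    stop("pixel spacing must be positive", call. = FALSE)
  structure(
    list(pixels = pixels, row_spacing = row_spacing,
         col_spacing = col_spacing, index = as.integer(index)),
    class = "breast_slice")
}

#' @export
print.breast_slice <- function(x, ...) {
  cat(sprintf("<breast_slice> %d x %d px, spacing %.3g x %.3g mm, index %d\n",
              nrow(x$pixels), ncol(x$pixels),
              x$row_spacing, x$col_spacing, x$index))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Construct an ordered stack of slices (a case)
#'
#' @param slices list of [new_slice()] objects, all with the same shape,
#'   ordered by acquisition; slice indices are renumbered consecutively.
#' @param case_id identifier string for the case.
#' @return an object of class `case_stack`.
#' @export
new_case_stack <- function(slices, case_id = "case") {
  if (length(slices) < 1L) stop("a case needs at least one slice", call. = FALSE)
  if (!all(vapply(slices, inherits, logical(1), "breast_slice")))
    stop("`slices` must be a list of breast_slice objects", call. = FALSE)
  shp <- dim(slices[[1]]$pixels)
  same <- vapply(slices, function(s) identical(dim(s$pixels), shp), logical(1))
  if (!all(same)) stop("all slices in a case must have the same shape", call. = FALSE)
  for (i in seq_along(slices)) slices[[i]]$index <- i - 1L
  structure(list(slices = slices, case_id = as.character(case_id)),
            class = "case_stack")
}

#' @export
print.case_stack <- function(x, ...) {
  shp <- dim(x$slices[[1]]$pixels)
  cat(sprintf("<case_stack> '%s': %d slices of %d x %d px\n",
              x$case_id, length(x$slices), shp[1], shp[2]))
  invisible(x)
}

#' @export
length.case_stack <- function(x) length(x$slices)

#' Construct a ground-truth label map
#'
#' Integer raster aligned with a slice. Label codes: 0 background,
#' 1 skin, 2 vessel/gland, 3 tumor, 4 organ/chest wall.
#'
#' @param labels integer matrix with values in `0:4`.
#' @return an object of class `label_map` (an integer matrix).
#' @export
new_label_map <- function(labels) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  lab <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (anyNA(lab) || any(lab < 0L) || any(lab > 4L))
    stop("labels must be integers in 0..4", call. = FALSE)
  structure(lab, class = c("label_map", class(lab)))
}

#' Names of the phantom label codes
#' @return character vector mapping label value + 1 to its meaning.
#' @export
label_names <- function() c("background", "skin", "vessel", "tumor", "organ")
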