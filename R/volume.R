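# 3-D assembly of per-slice results and maximum intensity projection.

#' Stack a case into a volume
#'
#' @param case a [new_case_stack()].
#' @return an object of class `breast_volume`: list with `voxels`
#'   (3-D array indexed slice, row, col) and `spacing`
#'   (slice, row, col in mm; slice spacing defaults to 1).
#' @export
stack_case <- function(case) {
  if (!inherits(case, "case_stack")) stop("expected a case_stack", call. = FALSE)
  shp <- dim(case$slices[[1]]$pixels)
  vox <- array(0, dim = c(length(case$slices), shp[1], shp[2]))
  for (i in seq_along(case$slices)) vox[i, , ] <- case$slices[[i]]$pixels
  structure(list(voxels = vox,
                 spacing = c(1, case$slices[[1]]$row_spacing,
                             case$slices[[1]]$col_spacing),
                 case_id = case$case_id),
            class = "breast_volume")
}

#' Unstack a volume back into a case
#' @param volume a [stack_case()] object.
#' @return a [new_case_stack()].
#' @export
unstack_volume <- function(volume) {
  slices <- lapply(seq_len(dim(volume$voxels)[1]), function(i)
    new_slice(volume$voxels[i, , ], volume$spacing[2], volume$spacing[3],
              i - 1L))
  new_case_stack(slices, volume$case_id %||% "volume")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximum intensity projection
#'
#' Projects the brightest voxel along each ray of the chosen axis.
#'
#' @param volume a [stack_case()] object or 3-D array (slice, row, col).
#' @param axis `"slice"`, `"row"`, or `"col"`.
#' @return 2-D numeric matrix.
#' @export
mip <- function(volume, axis = c("slice", "row", "col")) {
  axis <- match.arg(axis)
  vox <- if (inherits(volume, "breast_volume")) volume$voxels else volume
  if (length(dim(vox)) != 3L) stop("expected a 3-D volume", call. = FALSE)
  switch(axis,
    slice = Reduce(pmax, lapply(seq_len(dim(vox)[1]),
                                function(i) vox[i, , ])),
    row = apply(vox, c(1, 3), max),
    col = apply(vox, c(1, 2), max))
}

#' Write a MIP as an 8-bit grayscale PNG
#'
#' Applies the same per-volume min-max normalization as [read_case()]
#' before writing.
#'
#' @param projection matrix from [mip()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mip <- function(projection, path) {
  rng <- range(projection)
  img <- if (diff(rng) <= 0) projection * 0
         else (projection - rng[1]) / diff(rng)
  png::writePNG(img, target = path)
  invisible(path)
}
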