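# Readers and writers for the formats the pipeline touches: DICOM series
# (one file per slice), NIfTI-1 volumes, and directories of PNG/TIFF
# grayscale slices. NIfTI volumes are stored with array dimensions
# (row, col, slice).

#' Read a case (ordered slice stack) from disk
#'
#' Accepts a DICOM series directory (`*.dcm`), a directory of PNG or TIFF
#' slices, or a NIfTI file (`*.nii`, `*.nii.gz`). DICOM slices are ordered
#' by InstanceNumber with a filename-sort fallback; image directories are
#' ordered by filename. Intensities are min-max rescaled to `[0, 1]` over
#' the whole volume (not per slice) so that the snake's energy weights do
#' not depend on the case's intensity scale; a constant volume maps to all
#' zeros by convention.
#'
#' @param path directory or NIfTI file path.
#' @return a [new_case_stack()] object.
#' @export
read_case <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, full.names = TRUE)
    ext <- tolower(tools::file_ext(files))
    if (any(ext == "dcm")) {
      read_case_dicom(sort(files[ext == "dcm"]), basename(path))
    } else if (any(ext %in% c("png", "tif", "tiff"))) {
      read_case_images(sort(files[ext %in% c("png", "tif", "tiff")]),
                       basename(path))
    } else if (sum(ext %in% c("nii", "gz")) == 1L) {
      read_case_nifti(files[ext %in% c("nii", "gz")], basename(path))
    } else {
      stop("no readable slices (.dcm, .png, .tif, .nii) found in ", path,
           call. = FALSE)
    }
  } else if (file.exists(path)) {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    if (ext == "nii") read_case_nifti(path, basename(path))
    else stop("unsupported file format: ", path, call. = FALSE)
  } else {
    stop("path does not exist: ", path, call. = FALSE)
  }
}

rescale_volume <- function(mats) {
  lo <- min(vapply(mats, min, numeric(1)))
  hi <- max(vapply(mats, max, numeric(1)))
  if (hi <= lo) return(lapply(mats, function(m) m * 0))
  lapply(mats, function(m) (m - lo) / (hi - lo))
}

read_case_dicom <- function(files, case_id) {
  dcms <- lapply(files, read_dicom)
  inst <- vapply(dcms, function(d) d$instance_number, integer(1))
  ord <- if (anyNA(inst)) seq_along(dcms) else order(inst)
  dcms <- dcms[ord]
  shapes <- vapply(dcms, function(d) paste(dim(d$pixels), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L)
    stop("DICOM series has mixed slice shapes", call. = FALSE)
  mats <- rescale_volume(lapply(dcms, function(d) d$pixels + 0))
  sp <- dcms[[1]]$pixel_spacing
  if (anyNA(sp)) sp <- c(1, 1)
  slices <- lapply(seq_along(mats), function(i)
    new_slice(mats[[i]], sp[1], sp[2], i - 1L))
  new_case_stack(slices, case_id)
}

read_slice_image <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- tryCatch({
    if (ext == "png") png::readPNG(file) else tiff::readTIFF(file)
  }, error = function(e)
    stop("unreadable image file ", file, ": ", conditionMessage(e),
         call. = FALSE))
  if (length(dim(img)) == 3L) img <- img[, , 1]  # first channel of RGB(A)
  img
}

read_case_images <- function(files, case_id) {
  mats <- lapply(files, read_slice_image)
  shapes <- vapply(mats, function(m) paste(dim(m), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L)
    stop("slice images have mixed shapes", call. = FALSE)
  mats <- rescale_volume(mats)
  slices <- lapply(seq_along(mats), function(i)
    new_slice(mats[[i]], 1, 1, i - 1L))
  new_case_stack(slices, case_id)
}

read_case_nifti <- function(file, case_id) {
  img <- tryCatch(RNifti::readNifti(file), error = function(e)
    stop("unreadable NIfTI file ", file, ": ", conditionMessage(e),
         call. = FALSE))
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L)
    stop("expected a 2-D or 3-D NIfTI volume", call. = FALSE)
  pd <- attr(img, "pixdim")
  if (is.null(pd) || length(pd) < 2L) pd <- c(1, 1)
  mats <- rescale_volume(lapply(seq_len(dim(arr)[3]),
                                function(k) arr[, , k]))
  slices <- lapply(seq_along(mats), function(i)
    new_slice(mats[[i]], pd[1], pd[2], i - 1L))
  new_case_stack(slices, case_id)
}

# Gray-level step used to encode the 5 phantom labels in 8-bit PNG masks:
# label k is stored as gray value 51*k (0, 51, ..., 204) so the code
# round-trips exactly through round(x*255)/255 encoding.
LABEL_GRAY_STEP <- 51L

#' Write a binary mask or label map to disk
#'
#' Binary masks are written as 0/255 8-bit grayscale PNG or uint8 NIfTI;
#' label maps (integer values 0..4) are written as distinct gray levels
#' (multiples of 51) in PNG or as their integer values in NIfTI. Reading
#' the file back with [read_mask()] / [read_label_map()] recovers the
#' array exactly.
#'
#' @param mask logical/0-1 matrix, or a [new_label_map()] object.
#' @param path output path.
#' @param format `"png"` or `"nifti"`; inferred from the extension when
#'   missing.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext == "nii") "nifti" else "png"
  }
  format <- match.arg(format, c("png", "nifti"))
  is_labels <- inherits(mask, "label_map") || any(mask > 1)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  out <- tryCatch({
    if (format == "png") {
      img <- if (is_labels) m * LABEL_GRAY_STEP / 255 else m
      png::writePNG(img, target = path)
    } else {
      RNifti::writeNifti(RNifti::asNifti(array(m, c(dim(m), 1L)),
                                         datatype = "uint8"), path)
    }
  }, error = function(e)
    stop("cannot write mask to ", path, ": ", conditionMessage(e),
         call. = FALSE))
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#' @param path PNG or NIfTI path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  m <- read_mask_numeric(path)
  m > 0.5 * max(1, max(m))
}

#' Read a label map written by [write_mask()]
#' @param path PNG or NIfTI path.
#' @return a [new_label_map()] object.
#' @export
read_label_map <- function(path) {
  m <- read_mask_numeric(path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  lab <- if (ext == "nii") round(m)
         else round(m * 255 / LABEL_GRAY_STEP)
  new_label_map(lab)
}

read_mask_numeric <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "nii") {
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) == 3L) arr <- arr[, , 1]
    arr
  } else {
    read_slice_image(path)
  }
}

#' Write a case stack to a directory of grayscale PNG slices
#'
#' @param case a [new_case_stack()] object (pixels in `[0, 1]`).
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return the vector of written paths, invisibly.
#' @export
write_case_png <- function(case, dir, prefix = "slice") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(case$slices))
  for (i in seq_along(case$slices)) {
    paths[i] <- file.path(dir, sprintf("%s_%03d.png", prefix, i - 1L))
    px <- pmin(pmax(case$slices[[i]]$pixels, 0), 1)
    png::writePNG(px, target = paths[i], dpi = NULL)
  }
  invisible(paths)
}
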