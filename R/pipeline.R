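# End-to-end driver: configuration, per-slice segmentation, and the
# whole-case pipeline (preprocess -> snake -> thickness -> skin removal
# -> volume/MIP). Per-slice failures are recorded and skipped so that
# long clinical stacks with empty edge slices degrade gracefully.

#' Default pipeline configuration
#'
#' A nested list mirroring the module parameters: `preprocess`
#' (`median_window`, `morph_radius`, `otsu_levels`), `snake` (all
#' [snake_params()] fields), and `thickness` (`window`, `k`,
#' `march_step`, `max_march`, `close_radius`).
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(
    preprocess = list(median_window = 3L, morph_radius = 1L,
                      otsu_levels = 256L),
    snake = unclass(snake_params()),
    thickness = list(window = 61L, k = 1.5, march_step = 0.5,
                     max_march = 60, close_radius = 1L)
  )
}

#' Validate a configuration against the default schema
#'
#' Unknown keys at either level are rejected; missing keys are filled
#' from the defaults.
#'
#' @param config nested list (possibly partial), or a YAML file path.
#' @return the completed configuration.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  ref <- default_config()
  bad <- setdiff(names(config), names(ref))
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (sec in names(config)) {
    badk <- setdiff(names(config[[sec]]), names(ref[[sec]]))
    if (length(badk))
      stop("unknown key(s) in config section '", sec, "': ",
           paste(badk, collapse = ", "), call. = FALSE)
    ref[[sec]][names(config[[sec]])] <- config[[sec]]
  }
  ref
}

#' Segment the skin in a single slice
#'
#' Runs the full per-slice chain: median denoising, Otsu binarization,
#' morphological repair, upper-boundary extraction, organ localization
#' and parabolic removal, snake evolution from the binarized skin's inner
#' envelope, thickness measurement along boundary normals, continuity
#' correction, and final skin-mask rasterization.
#'
#' Components of the binary foreground are split into the skin component
#' (connected to the upper boundary; adherent vessels and glands belong
#' to it) and organ candidates (components touching the bottom edge of
#' the frame, e.g. the chest wall); the parabola is fitted to the organ
#' candidates only. Slices without such a component skip organ removal.
#'
#' @param slice a [new_slice()].
#' @param config a configuration from [validate_config()].
#' @return list with `skin_mask`, `rough_mask`, `organ_mask`, `boundary`,
#'   `snake` (the [evolve()] fit), `profile` (corrected
#'   [measure_thickness()]), `cleaned` (slice with organs and skin
#'   removed) and `threshold`.
#' @export
segment_slice <- function(slice, config = default_config()) {
  pp <- config$preprocess
  sp <- do.call(snake_params, config$snake)
  tp <- config$thickness
  shape <- dim(slice$pixels)

  den <- denoise(slice, pp$median_window)
  bin <- binarize(den, pp$otsu_levels)
  if (!any(bin)) stop("empty binarization: no foreground in slice", call. = FALSE)
  rep_mask <- repair_skin(bin, pp$morph_radius)
  boundary <- extract_upper_boundary(rep_mask)

  comp <- EBImage::bwlabel(matrix(as.numeric(rep_mask), shape[1], shape[2]))
  comp <- matrix(as.integer(comp), shape[1], shape[2])
  bidx <- cbind(pmin(pmax(round(boundary$row), 1), shape[1]), boundary$col)
  skin_labels <- setdiff(unique(comp[bidx]), 0L)
  skin_comp <- matrix(comp %in% skin_labels, shape[1], shape[2])
  bottom_labels <- setdiff(unique(comp[shape[1], ]), c(0L, skin_labels))

  organ_mask <- matrix(FALSE, shape[1], shape[2])
  work <- den
  if (length(bottom_labels)) {
    cand <- matrix(comp %in% bottom_labels, shape[1], shape[2])
    res <- tryCatch({
      ex <- locate_organ_extrema(cand)
      remove_organs(den, fit_parabola(ex$A, ex$B))
    }, error = function(e) NULL)
    if (!is.null(res)) { work <- res$slice; organ_mask <- res$organ_mask }
  }

  seed <- extract_lower_envelope(skin_comp)
  field <- external_energy(work, sp)
  fit <- evolve(seed, field, sp)
  rough <- contour_to_band(boundary, fit, shape)

  # dense (~0.5 px arc spacing) resampling so that slanted boundary
  # stretches are swept without rasterization gaps; the continuity window
  # is specified in boundary pixels and converted to samples
  spacing <- 0.5
  dense <- resample_contour(cbind(boundary$row, boundary$col), spacing)
  seqp <- order_boundary(dense)
  nf <- normals(seqp)
  prof <- measure_thickness(rough, seqp, nf, tp$march_step, tp$max_march)
  wsamp <- max(3L, odd_leq(round(tp$window / spacing)))
  prof <- correct_thickness(prof, wsamp, tp$k)
  sm <- skin_mask(seqp, nf, prof, shape, tp$march_step, tp$close_radius)

  cleaned <- remove_skin(work, sm)
  list(skin_mask = sm, rough_mask = rough, organ_mask = organ_mask,
       boundary = boundary, snake = fit, profile = prof,
       cleaned = cleaned, threshold = attr(bin, "threshold"))
}

#' Segment a whole case
#'
#' Applies [segment_slice()] to every slice, assembles the skin-removed
#' volume and its slice-axis MIP, and optionally writes results to disk
#' (PNG slices, skin masks, MIP and a JSON run log). A slice that fails
#' any stage is flagged and passed through unsegmented; the run log
#' records per-slice convergence and thickness statistics. The pipeline
#' is deterministic: identical input and configuration give identical
#' output.
#'
#' @param input a [new_case_stack()] or a path readable by [read_case()].
#' @param config configuration (validated with [validate_config()]).
#' @param output_dir optional output directory.
#' @return (invisibly) list with `results` (per-slice [segment_slice()]
#'   outputs or `NULL` for failed slices), `cleaned` (skin-removed
#'   case stack), `skin_masks`, `mip`, `failures` (indices of failed
#'   slices) and `status` (0 ok, 1 partial, 2 fatal).
#' @export
segment_case <- function(input, config = list(), output_dir = NULL) {
  case <- if (inherits(input, "case_stack")) input else read_case(input)
  config <- validate_config(config)
  n <- length(case$slices)
  results <- vector("list", n)
  cleaned <- case
  masks <- vector("list", n)
  failures <- integer(0)
  log <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch(segment_slice(case$slices[[i]], config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, i)
      masks[[i]] <- matrix(FALSE, nrow(case$slices[[i]]$pixels),
                           ncol(case$slices[[i]]$pixels))
      log[[i]] <- list(slice = i - 1L, ok = FALSE,
                       error = conditionMessage(res))
    } else {
      results[[i]] <- res
      cleaned$slices[[i]] <- res$cleaned
      masks[[i]] <- res$skin_mask
      log[[i]] <- list(
        slice = i - 1L, ok = TRUE,
        snake_iterations = res$snake$n_iter,
        final_energy = res$snake$energy[length(res$snake$energy)],
        thickness_mean = mean(res$profile$corrected),
        thickness_max = max(res$profile$corrected))
    }
  }
  status <- if (length(failures) == 0L) 0L
            else if (length(failures) < n) 1L else 2L
  proj <- mip(stack_case(cleaned), "slice")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_case_png(cleaned, file.path(output_dir, "skin_removed"))
    mdir <- file.path(output_dir, "skin_masks")
    dir.create(mdir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n))
      write_mask(masks[[i]],
                 file.path(mdir, sprintf("mask_%03d.png", i - 1L)))
    write_mip(proj, file.path(output_dir, "mip.png"))
    jsonlite::write_json(
      list(case_id = case$case_id, status = status, config = config,
           slices = log),
      file.path(output_dir, "run_log.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(list(results = results, cleaned = cleaned, skin_masks = masks,
                 mip = proj, failures = failures, status = status))
}
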