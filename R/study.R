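# Reproducible phantom studies: the package's own evaluation protocol run
# end to end on synthetic cases. These functions are what the acceptance
# script and the worked examples call.

#' Segmentation study on seeded phantom cases
#'
#' Generates `n_cases` phantom cases (256 x 256 slices; 8-16 slices, 2-5
#' adherent vessels and the skin-thickness range varying by case seed;
#' additive noise sd 0.02), runs the full pipeline on each, and scores
#' the final skin mask and the rough ACM-only mask against the
#' ground-truth labels.
#'
#' @param n_cases number of phantom cases.
#' @param seed master seed; case seeds are derived from it.
#' @param config pipeline configuration.
#' @param shape,n_slices_range,n_vessels_range,noise_sigma study
#'   conditions; defaults are the package's standard benchmark.
#' @return data frame with one row per case: `seed`, `n_slices`,
#'   `n_vessels`, `dice_full` (3-D Dice of the corrected skin mask),
#'   `dice_acm` (3-D Dice of the rough active-contour band),
#'   `vessel_retention` (fraction of ground-truth vessel pixels not
#'   removed by the skin or organ masks), `organ_coverage` and
#'   `skin_over_organ_cut` (fractions scoring the parabolic organ
#'   removal), `failures`.
#' @export
phantom_study <- function(n_cases = 20L, seed = 0L, config = list(),
                          shape = c(256L, 256L),
                          n_slices_range = c(8L, 16L),
                          n_vessels_range = c(2L, 5L),
                          noise_sigma = 0.02) {
  config <- validate_config(config)
  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    cseed <- derive_seed(seed, i)
    nsl <- n_slices_range[1] +
      cseed %% (n_slices_range[2] - n_slices_range[1] + 1L)
    nvs <- n_vessels_range[1] +
      (cseed %/% 7L) %% (n_vessels_range[2] - n_vessels_range[1] + 1L)
    spec <- phantom_spec(shape = shape, n_slices = nsl, n_vessels = nvs,
                         noise_sigma = noise_sigma, seed = cseed)
    ph <- generate_case(spec)
    seg <- segment_case(ph$case, config)
    gt_skin <- simplify2array(lapply(ph$labels, function(l) l == 1L))
    gt_vess <- simplify2array(lapply(ph$labels, function(l) l == 2L))
    gt_org <- simplify2array(lapply(ph$labels, function(l) l == 4L))
    final <- simplify2array(seg$skin_masks)
    rough <- simplify2array(lapply(seq_along(seg$results), function(k) {
      r <- seg$results[[k]]
      if (is.null(r)) seg$skin_masks[[k]] else r$rough_mask
    }))
    organ <- simplify2array(lapply(seq_along(seg$results), function(k) {
      r <- seg$results[[k]]
      if (is.null(r)) seg$skin_masks[[k]] & FALSE else r$organ_mask
    }))
    rows[[i]] <- data.frame(
      seed = cseed, n_slices = nsl, n_vessels = nvs,
      dice_full = dice(final, gt_skin),
      dice_acm = dice(rough, gt_skin),
      vessel_retention = sum(gt_vess & !final & !organ) / max(1, sum(gt_vess)),
      organ_coverage = sum(gt_org & organ) / max(1, sum(gt_org)),
      skin_over_organ_cut = sum(gt_skin & organ) / max(1, sum(gt_skin)),
      failures = length(seg$failures))
  }
  do.call(rbind, rows)
}

#' Texture observability study on seeded phantom cases
#'
#' Generates `n_cases` phantoms in which the drifting skin band occludes
#' the tumor's position in the slice-axis MIP, runs the pipeline, and
#' compares GLCM texture features of the tumor region of interest (the
#' ground-truth tumor bounding box) between the original and the
#' skin-removed projections, with a paired t-test per feature.
#'
#' @param n_cases number of phantom cases (>= 2).
#' @param seed master seed.
#' @param n_slices slices per case; enough slices are needed for the
#'   through-slice drift to sweep the skin band across the tumor.
#' @param config pipeline configuration.
#' @return an [assess_cases()] result (features data frame + per-feature
#'   paired t-tests).
#' @export
texture_study <- function(n_cases = 10L, seed = 0L, n_slices = 16L,
                          config = list()) {
  config <- validate_config(config)
  with_cases <- vector("list", n_cases)
  without_cases <- vector("list", n_cases)
  rois <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    spec <- phantom_spec(n_slices = n_slices,
                         seed = derive_seed(seed + 1000L, i))
    ph <- generate_case(spec)
    seg <- segment_case(ph$case, config)
    tu <- which(simplify2array(lapply(ph$labels, function(l) l == 3L)),
                arr.ind = TRUE)
    if (nrow(tu) == 0L) stop("phantom has no tumor", call. = FALSE)
    rois[[i]] <- c(range(tu[, 1]), range(tu[, 2]))
    with_cases[[i]] <- ph$case
    without_cases[[i]] <- seg$cleaned
  }
  assess_cases(with_cases, without_cases, rois)
}
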