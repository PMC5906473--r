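# Synthetic breast DCE-MRI phantom.
#
# The phantom reproduces the structures that make automated skin removal
# hard on clinical slices: a thin bright skin band of smoothly varying
# thickness under a curved breast contour, bright vessels/glands adherent
# to the skin's inner side (with intensity close to the skin's), a tumor
# blob in the breast interior, a chest-wall/organ mass in the lower middle
# of the frame, and additive noise. Every structure is recorded in a
# noise-free ground-truth label map so downstream modules can be scored.

#' Specify a synthetic phantom case
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: 256x256 slices, skin 3-9 px thick, three adherent vessels, a
#' tumor, and Gaussian noise with sd 0.02.
#'
#' @param shape integer (rows, cols) of each slice.
#' @param n_slices number of slices in the case.
#' @param skin_thickness_range (min, max) skin thickness in pixels.
#' @param skin_intensity,vessel_intensity,tumor_intensity,organ_intensity,background_intensity
#'   mean intensities in `[0, 1]`. Vessel intensity defaults close to skin
#'   intensity, which is the core difficulty the thickness analysis solves.
#' @param n_vessels number of vessels attached to the skin's inner edge.
#' @param tumor `TRUE` for an automatically placed tumor, `FALSE`/`NULL`
#'   for none, or a list with `center = c(row, col)` (or `NULL` for
#'   automatic placement just under the skin), `radii = c(r_row, r_col)`,
#'   and optionally `center_slice` and `slice_radius` describing the
#'   ellipsoid's extent along the stack.
#' @param noise_sigma sd of additive Gaussian noise (0 disables).
#' @param salt_pepper fraction of pixels corrupted by salt-and-pepper
#'   speckles (0 disables); these are the speckles the median filter
#'   targets.
#' @param seed master seed; per-slice seeds are derived from it.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(256L, 256L), n_slices = 16L,
                         skin_thickness_range = c(3, 9),
                         skin_intensity = 0.85, vessel_intensity = 0.8,
                         tumor_intensity = 0.6, organ_intensity = 0.7,
                         background_intensity = 0.08,
                         n_vessels = 3L, tumor = TRUE,
                         noise_sigma = 0.02, salt_pepper = 0,
                         seed = 0L) {
  tr <- skin_thickness_range
  if (length(tr) != 2L || tr[1] <= 0 || tr[1] > tr[2])
    stop("need 0 < min thickness <= max thickness", call. = FALSE)
  ints <- c(skin_intensity, vessel_intensity, tumor_intensity,
            organ_intensity, background_intensity)
  if (any(ints < 0) || any(ints > 1))
    stop("intensities must be in [0, 1]", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (isTRUE(tumor)) tumor <- list(center = NULL, radii = c(7, 10))
  if (isFALSE(tumor)) tumor <- NULL
  structure(list(
    shape = as.integer(shape), n_slices = as.integer(n_slices),
    skin_thickness_range = as.numeric(tr),
    skin_intensity = skin_intensity, vessel_intensity = vessel_intensity,
    tumor_intensity = tumor_intensity, organ_intensity = organ_intensity,
    background_intensity = background_intensity,
    n_vessels = as.integer(n_vessels), tumor = tumor,
    noise_sigma = noise_sigma, salt_pepper = salt_pepper,
    seed = as.integer(seed)), class = "phantom_spec")
}

# Breast upper contour for one slice: a wide parabola whose vertex drifts
# smoothly across the stack (the 3-D breast surface curves in the slice
# direction too, so across a stack the skin band sweeps a wide row range),
# plus two low-frequency sinusoids whose phases are fixed per case (seeded
# by the master seed). Returns real-valued rows.
phantom_contour <- function(spec, slice_index, drift_on = TRUE) {
  nr <- spec$shape[1]; nc <- spec$shape[2]
  pert <- with_seed(derive_seed(spec$seed, 0L) + 1L, {
    list(a = stats::runif(2, 1.5, 3.5), f = sample(2:4, 2),
         ph = stats::runif(2, 0, 2 * pi))
  })
  drift <- if (drift_on) phantom_drift(spec, slice_index) else 0
  cm <- (nc + 1) / 2
  cols <- seq_len(nc)
  base <- 0.18 * nr + drift + 0.22 * nr * ((cols - cm) / cm)^2
  wob <- pert$a[1] * sin(2 * pi * pert$f[1] * cols / nc + pert$ph[1]) +
    pert$a[2] * sin(2 * pi * pert$f[2] * cols / nc + pert$ph[2])
  pmin(pmax(base + wob, 6), 0.5 * nr)
}

# Smooth per-column thickness profile: a Gaussian-smoothed random walk
# rescaled into the requested range, then rounded to integer pixels.
# Successive columns differ by at most 2 px.
phantom_thickness <- function(spec, slice_seed) {
  nc <- spec$shape[2]
  tr <- spec$skin_thickness_range
  if (tr[1] == tr[2]) return(rep(round(tr[1]), nc))
  with_seed(slice_seed, {
    w <- cumsum(stats::rnorm(nc))
    k <- stats::dnorm(seq(-24, 24), sd = 8)
    wp <- c(rep(w[1], 24), w, rep(w[nc], 24))
    ws <- stats::convolve(wp, rev(k / sum(k)), type = "filter")
    rng <- range(ws)
    t_real <- if (diff(rng) < 1e-9) rep(mean(tr), nc)
              else tr[1] + (tr[2] - tr[1]) * (ws - rng[1]) / diff(rng)
    round(t_real)
  })
}

# Monotone through-slice drift of the breast surface: the dome recedes
# (contour moves to larger rows) toward the far end of the stack. The
# quadratic ramp keeps per-slice steps below the minimum skin thickness,
# so the union of skin bands over the stack covers a contiguous row range
# (this is what hides an interior tumor in the slice-axis MIP).
phantom_drift <- function(spec, slice_index) {
  nref <- max(spec$n_slices, 8L)
  amp <- min(0.09 * spec$shape[1], 1.5 * (nref - 1L))
  amp * (slice_index / (nref - 1L))^2
}

phantom_organ_boundary <- function(spec) {
  nr <- spec$shape[1]; nc <- spec$shape[2]
  y_b <- round(0.62 * nr); x_b <- round(nc / 2)
  cc <- (nr - y_b) / (x_b - 1)^2
  cols <- seq_len(nc)
  y_b + cc * (cols - x_b)^2
}

#' Generate one phantom slice with its ground-truth label map
#'
#' Structures are painted in priority order skin > vessel > tumor > organ,
#' so the labels partition the frame. With `noise_sigma = 0` and
#' `salt_pepper = 0` the image is a deterministic function of the label
#' map and the spec intensities.
#'
#' @param spec a [phantom_spec()].
#' @param slice_index 0-based slice position (selects the contour drift and
#'   the per-slice random state).
#' @return list with elements `slice` ([new_slice()]) and `labels`
#'   ([new_label_map()]).
#' @export
generate_slice <- function(spec, slice_index = 0L) {
  nr <- spec$shape[1]; nc <- spec$shape[2]
  if (nr < 32L || nc < 32L)
    stop("phantom frames must be at least 32 x 32 px", call. = FALSE)
  sseed <- derive_seed(spec$seed, slice_index + 1L)
  contour <- phantom_contour(spec, slice_index)
  thick <- phantom_thickness(spec, sseed)
  top <- round(contour)
  lab <- matrix(0L, nr, nc)

  for (cc in seq_len(nc)) {
    rows <- top[cc]:min(top[cc] + thick[cc] - 1L, nr)
    lab[rows, cc] <- 1L
  }
  inner <- top + thick  # first row below the skin, per column

  if (spec$n_vessels > 0L) {
    lab <- with_seed(sseed + 1L, {
      lo <- round(0.3 * nc); hi <- round(0.7 * nc)
      if (hi - lo < 2L * spec$n_vessels)
        stop("frame too small to place the requested vessels", call. = FALSE)
      starts <- sort(sample(seq(lo, hi), spec$n_vessels))
      for (s in starts) {
        len <- sample(14:24, 1)
        wv <- sample(2:3, 1)
        r <- inner[s]; cpos <- s
        for (step in seq_len(len)) {
          cols <- cpos:min(cpos + wv - 1L, nc)
          ok <- r >= 1 & r <= nr
          if (!ok) break
          sel <- lab[r, cols] == 0L
          lab[r, cols[sel]] <- 2L
          r <- r + 1L
          cpos <- min(max(cpos + sample(c(-1L, 0L, 0L, 1L), 1), 1L), nc - wv + 1L)
        }
      }
      lab
    })
  }

  if (!is.null(spec$tumor)) {
    # the tumor is an ellipsoid spanning a few slices near the start of
    # the stack (where the surface drift is still small), fixed in 3-D:
    # its (row, col) footprint is swept over by the skin band of the
    # far-drift slices, which is what occludes it in the slice-axis MIP
    ctr <- spec$tumor$center
    radii <- spec$tumor$radii
    if (is.null(ctr)) {
      base <- phantom_contour(spec, 0L, drift_on = FALSE)
      ct <- round(0.34 * nc)
      ctr <- c(round(base[ct] + mean(spec$skin_thickness_range) +
                       radii[1] + 4), ct)
    }
    s0 <- spec$tumor$center_slice %||%
      max(0L, round(0.15 * (spec$n_slices - 1L)))
    rs <- spec$tumor$slice_radius %||% max(2L, round(0.25 * spec$n_slices))
    shrink2 <- 1 - ((slice_index - s0) / rs)^2
    if (shrink2 > 0) {
      sc <- sqrt(shrink2)
      ob <- phantom_organ_boundary(spec)
      if (ctr[1] + radii[1] >= ob[ctr[2]] - 2 || ctr[1] - radii[1] <= 1 ||
          ctr[2] - radii[2] <= 1 || ctr[2] + radii[2] >= nc)
        stop("tumor does not fit inside the breast interior", call. = FALSE)
      rr <- matrix(seq_len(nr), nr, nc)
      ccm <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      inside <- ((rr - ctr[1]) / (sc * radii[1]))^2 +
        ((ccm - ctr[2]) / (sc * radii[2]))^2 <= 1
      lab[inside & lab == 0L] <- 3L
    }
  }

  ob <- phantom_organ_boundary(spec)
  for (cc in seq_len(nc)) {
    r0 <- ceiling(ob[cc])
    if (r0 <= nr) {
      rows <- r0:nr
      sel <- lab[rows, cc] == 0L
      lab[rows[sel], cc] <- 4L
    }
  }

  ints <- c(spec$background_intensity, spec$skin_intensity,
            spec$vessel_intensity, spec$tumor_intensity,
            spec$organ_intensity)
  img <- matrix(ints[lab + 1L], nr, nc)
  if (spec$noise_sigma > 0 || spec$salt_pepper > 0) {
    img <- with_seed(sseed + 2L, {
      if (spec$noise_sigma > 0)
        img <- img + stats::rnorm(length(img), 0, spec$noise_sigma)
      if (spec$salt_pepper > 0) {
        n_sp <- round(spec$salt_pepper * length(img))
        if (n_sp > 0) {
          idx <- sample(length(img), n_sp)
          img[idx] <- stats::rbinom(n_sp, 1, 0.5)
        }
      }
      img
    })
  }
  img <- pmin(pmax(img, 0), 1)
  list(slice = new_slice(img, 1, 1, slice_index),
       labels = new_label_map(lab))
}

#' Generate a full phantom case
#'
#' @param spec a [phantom_spec()].
#' @return list with `case` (a [new_case_stack()]) and `labels` (list of
#'   [new_label_map()], one per slice).
#' @export
generate_case <- function(spec) {
  out <- lapply(seq_len(spec$n_slices) - 1L,
                function(i) generate_slice(spec, i))
  case <- new_case_stack(lapply(out, `[[`, "slice"),
                         sprintf("phantom-seed%d", spec$seed))
  list(case = case, labels = lapply(out, `[[`, "labels"))
}

#' Write a phantom case to disk (PNG slices + label PNGs + JSON spec)
#'
#' @param spec a [phantom_spec()].
#' @param dir output directory.
#' @return the generated phantom, invisibly.
#' @export
write_phantom_case <- function(spec, dir) {
  ph <- generate_case(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_case_png(ph$case, file.path(dir, "slices"))
  lab_dir <- file.path(dir, "labels")
  dir.create(lab_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ph$labels))
    write_mask(ph$labels[[i]],
               file.path(lab_dir, sprintf("labels_%03d.png", i - 1L)))
  rec <- spec
  class(rec) <- NULL
  jsonlite::write_json(rec, file.path(dir, "phantom_spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(ph)
}
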