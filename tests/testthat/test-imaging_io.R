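test_that("PNG slice directories load with per-volume rescaling", {
  d <- withr::local_tempdir()
  # constant volume: rescale has no dynamic range, maps to all zeros
  for (i in 1:3)
    png::writePNG(matrix(128 / 255, 8, 10), file.path(d, sprintf("s%d.png", i)))
  cs <- read_case(d)
  expect_s3_class(cs, "case_stack")
  expect_length(cs$slices, 3)
  for (s in cs$slices) expect_true(all(s$pixels == 0))
})

test_that("NIfTI volumes are min-max rescaled over the whole volume", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  arr <- array(0, c(4, 5, 2))
  arr[1, 1, 1] <- 50; arr[2, 2, 2] <- 100
  RNifti::writeNifti(RNifti::asNifti(arr), f)
  cs <- read_case(f)
  expect_equal(cs$slices[[1]]$pixels[1, 1], 0.5)
  expect_equal(cs$slices[[2]]$pixels[2, 2], 1.0)
  expect_equal(sort(unique(c(cs$slices[[1]]$pixels, cs$slices[[2]]$pixels))),
               c(0, 0.5, 1))
})

test_that("rescaling is monotone in pixel intensity", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  set.seed(42)
  arr <- array(runif(4 * 5 * 3, 0, 1000), c(4, 5, 3))
  RNifti::writeNifti(RNifti::asNifti(arr), f)
  cs <- read_case(f)
  loaded <- simplify2array(lapply(cs$slices, `[[`, "pixels"))
  expect_equal(order(as.numeric(arr)), order(as.numeric(loaded)))
})

test_that("DICOM series order follows InstanceNumber, not filename", {
  d <- withr::local_tempdir()
  set.seed(7)
  mats <- lapply(1:4, function(i) matrix(sample(0:4000, 6 * 6), 6, 6))
  # filenames shuffled relative to instance numbers
  fname <- c("d_c.dcm", "a_x.dcm", "z_b.dcm", "m_q.dcm")
  inst <- c(3L, 1L, 4L, 2L)
  for (k in 1:4)
    write_dicom(mats[[k]], file.path(d, fname[k]), instance_number = inst[k],
                pixel_spacing = c(0.5, 0.5))
  cs <- read_case(d)
  # oracle: sort the generated headers by instance number by hand
  expected_order <- order(inst)
  lo <- min(unlist(mats)); hi <- max(unlist(mats))
  for (k in 1:4) {
    expect_equal(cs$slices[[k]]$pixels,
                 (mats[[expected_order[k]]] - lo) / (hi - lo))
  }
  expect_equal(cs$slices[[1]]$row_spacing, 0.5)
})

test_that("mixed slice shapes raise a shape error", {
  d <- withr::local_tempdir()
  png::writePNG(matrix(0.5, 8, 8), file.path(d, "a.png"))
  png::writePNG(matrix(0.5, 9, 8), file.path(d, "b.png"))
  expect_error(read_case(d), "mixed")
})

test_that("masks round-trip exactly through PNG and NIfTI", {
  d <- withr::local_tempdir()
  zero <- matrix(FALSE, 7, 9)
  write_mask(zero, file.path(d, "zero.png"))
  expect_equal(read_mask(file.path(d, "zero.png")), zero)
  set.seed(0)
  rnd <- matrix(runif(7 * 9) > 0.5, 7, 9)
  write_mask(rnd, file.path(d, "rnd.png"))
  expect_equal(read_mask(file.path(d, "rnd.png")), rnd)
  write_mask(rnd, file.path(d, "rnd.nii.gz"))
  expect_equal(read_mask(file.path(d, "rnd.nii.gz")), rnd)
})

test_that("label maps are written as distinct gray levels and recovered", {
  d <- withr::local_tempdir()
  set.seed(1)
  lab <- new_label_map(matrix(sample(0:4, 60, TRUE), 6, 10))
  write_mask(lab, file.path(d, "lab.png"))
  back <- read_label_map(file.path(d, "lab.png"))
  expect_equal(unclass(back), unclass(lab), ignore_attr = TRUE)
  # brute-force check of the level <-> label table: 8-bit gray values must
  # be exact multiples of the level step
  raw_png <- png::readPNG(file.path(d, "lab.png"))
  grays <- sort(unique(round(as.numeric(raw_png) * 255)))
  expect_true(all(grays %in% (0:4 * 51)))
  for (g in grays) {
    expect_equal(sum(round(raw_png * 255) == g), sum(lab == g / 51))
  }
})

test_that("slice and case constructors enforce their invariants", {
  expect_error(new_slice(matrix(c(1, NA), 1, 2)), "finite")
  expect_error(new_slice(matrix(1, 2, 2), row_spacing = 0), "spacing")
  s1 <- new_slice(matrix(0.5, 3, 3))
  s2 <- new_slice(matrix(0.5, 4, 3))
  expect_error(new_case_stack(list(s1, s2)), "same shape")
  expect_error(new_label_map(matrix(5L, 2, 2)), "0..4")
})
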