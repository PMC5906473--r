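test_that("median filtering matches the brute-force sorted median", {
  expect_error(denoise(matrix(1, 4, 4), 2), "odd")
  m <- matrix(runif(25), 5, 5)
  expect_equal(denoise(m, 1), m)                       # window 1 = identity
  expect_equal(denoise(matrix(0.7, 6, 6), 3), matrix(0.7, 6, 6))
  spike <- matrix(0, 5, 5); spike[3, 3] <- 1
  expect_equal(denoise(spike, 3), matrix(0, 5, 5))     # lone outlier removed
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(runif(49), 7, 7)
    expect_equal(denoise(m, 3), brute_median(m, 3))
    m2 <- matrix(runif(81), 9, 9)
    expect_equal(denoise(m2, 5), brute_median(m2, 5))
  }
})

test_that("Otsu binarization separates a bimodal image and flags constants", {
  m <- matrix(0.2, 10, 10); m[1:4, ] <- 0.8
  b <- binarize(m)
  expect_equal(matrix(b, 10, 10), m == 0.8)
  expect_warning(bc <- binarize(matrix(0.4, 5, 5)), "constant")
  expect_false(any(bc))
  expect_true(is.na(attr(bc, "threshold")))
})

test_that("the Otsu threshold attains the exhaustive between-class maximum", {
  # 16-bin synthetic histogram
  set.seed(3)
  vals <- sample(seq(1 / 32, 1 - 1 / 32, by = 1 / 16), 64, TRUE,
                 prob = c(rep(4, 6), rep(1, 4), rep(3, 6)))
  m <- matrix(vals, 8, 8)
  b <- binarize(m, levels = 16L)
  th <- attr(b, "threshold")
  expect_equal(otsu_objective(m, th, 16L), brute_otsu_best(m, 16L))
  for (s in 1:6) {
    set.seed(s)
    m <- matrix(runif(64), 8, 8)
    th <- attr(binarize(m), "threshold")
    expect_equal(otsu_objective(m, th), brute_otsu_best(m), tolerance = 1e-12)
  }
})

test_that("morphological repair is stable, removes specks and bridges gaps", {
  # a big disc is already open-and-closed w.r.t. the element
  d <- seq(-8, 8)
  blob <- outer(d^2, d^2, `+`) <= 36
  expect_equal(repair_skin(blob, 1), blob)
  # an isolated pixel is erased by the opening
  lone <- matrix(FALSE, 9, 9); lone[5, 5] <- TRUE
  expect_false(any(repair_skin(lone, 2)))
  # a skin band with a 2-px break is re-connected by the closing (the
  # band must be thick enough to survive the opening: >= 5 px here)
  band <- matrix(FALSE, 15, 24)
  band[5:9, ] <- TRUE
  band[, 11:12] <- FALSE
  rep_ <- repair_skin(band, 1)
  lab <- EBImage::bwlabel(matrix(as.numeric(rep_), 15, 24))
  expect_true(any(rep_[, 3]) && any(rep_[, 22]))
  expect_equal(lab[7, 3], lab[7, 22])  # single 8-connected component
})

test_that("upper boundaries are per-column minima with interpolated gaps", {
  bar <- matrix(FALSE, 20, 12); bar[10, ] <- TRUE
  b <- extract_upper_boundary(bar)
  expect_equal(b$row, rep(10, 12))
  bar[10, 5] <- FALSE
  expect_equal(extract_upper_boundary(bar)$row, rep(10, 12))
  # staircase vs brute-force column scan
  stair <- matrix(FALSE, 30, 10)
  for (cc in 1:10) stair[(2 + cc):(6 + cc), cc] <- TRUE
  expect_equal(extract_upper_boundary(stair)$row,
               sapply(1:10, function(cc) min(which(stair[, cc]))))
  sparse <- matrix(FALSE, 10, 10); sparse[3, 1:4] <- TRUE
  expect_error(extract_upper_boundary(sparse), "boundary not found")
})

test_that("organ extrema follow the stated search windows and tie rules", {
  m <- matrix(FALSE, 128, 256)
  m[90, 10] <- TRUE; m[40, 128] <- TRUE
  ex <- locate_organ_extrema(m)
  expect_equal(ex$A, c(x = 10, y = 90))
  expect_equal(ex$B, c(x = 128, y = 40))
  # full-width bar: exhaustive scan with the same tie rules
  bar <- matrix(FALSE, 60, 90); bar[20:30, ] <- TRUE
  ex <- locate_organ_extrema(bar)
  expect_equal(ex$A, c(x = 1, y = 30))     # leftmost of the lowest row
  mid_cols <- 31:60                        # middle third
  expect_equal(ex$B, c(x = mid_cols[ceiling(length(mid_cols) / 2)], y = 20))
  empty_left <- matrix(FALSE, 30, 30); empty_left[15, 20] <- TRUE
  expect_error(locate_organ_extrema(empty_left), "left third")
})

test_that("the parabola passes through A with vertex B", {
  cut <- fit_parabola(A = c(10, 20), B = c(50, 80))
  expect_equal(cut$c, 0.0375)
  expect_equal(parabola_row(cut, 10), 20)
  expect_equal(parabola_row(cut, 50), 80)
  flat <- fit_parabola(A = c(10, 80), B = c(50, 80))
  expect_equal(flat$c, 0)
  expect_equal(parabola_row(flat, 33), 80)
  set.seed(4)
  for (i in 1:20) {
    a <- c(runif(1, 1, 40), runif(1, 1, 200))
    b <- c(runif(1, 60, 120), runif(1, 1, 200))
    expect_equal(parabola_row(fit_parabola(a, b), a[1]), a[2],
                 tolerance = 1e-9)
  }
  expect_error(fit_parabola(c(5, 1), c(5, 9)), "degenerate")
})

test_that("organ removal zeroes at/below the cut and is idempotent", {
  m <- matrix(0.5, 40, 30)
  below <- fit_parabola(A = c(1, 41), B = c(15, 41))
  expect_equal(remove_organs(m, below)$slice, m)    # cut below the frame
  all_cut <- fit_parabola(A = c(1, 0), B = c(15, 0))
  expect_equal(remove_organs(m, all_cut)$slice, matrix(0, 40, 30))
  cut <- fit_parabola(A = c(2, 35), B = c(15, 18))
  res <- remove_organs(m, cut)
  # per-column brute force of removed-pixel counts
  for (cc in c(1, 8, 15, 23, 30)) {
    yc <- parabola_row(cut, cc)
    expect_equal(sum(res$slice[, cc] == 0), sum((1:40) >= yc))
  }
  twice <- remove_organs(res$slice, cut)
  expect_equal(twice$slice, res$slice)
  expect_equal(dim(res$slice), dim(m))
})

test_that("on phantoms the organ cut removes organs but spares the skin", {
  for (s in c(4, 17)) {
    ph <- generate_slice(phantom_spec(seed = s), 0L)
    res <- segment_slice(ph$slice)
    organ <- ph$labels == 4L
    skin <- ph$labels == 1L
    expect_gte(sum(organ & res$organ_mask) / sum(organ), 0.95)
    expect_lt(sum(skin & res$organ_mask) / sum(skin), 0.05)
  }
})
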