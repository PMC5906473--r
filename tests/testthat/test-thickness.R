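test_that("boundary ordering normalizes direction and duplicates", {
  pts <- cbind(c(5, 6, 7), c(1, 2, 3))
  expect_equal(order_boundary(pts), pts)
  rev_pts <- pts[3:1, ]
  expect_equal(order_boundary(rev_pts), pts)
  dup <- rbind(pts, c(9, 2))  # duplicated column 2 collapses to the mean
  out <- order_boundary(dup)
  expect_equal(nrow(out), 3)
  expect_equal(out[2, 1], (6 + 9) / 2)
  expect_error(order_boundary(matrix(numeric(0), 0, 2)), "empty")
})

test_that("normals are unit, orthogonal and point into the breast", {
  horiz <- cbind(rep(4, 5), 1:5)
  nf <- normals(horiz)
  expect_equal(nf$tangent[1, ], c(0, 1))
  expect_equal(nf$normal[1, ], c(1, 0))      # straight down
  desc <- cbind(1:5, 1:5)                    # 45 degrees, descending
  nd <- normals(desc)
  expect_equal(nd$normal[2, ], c(sqrt(2) / 2, -sqrt(2) / 2))
  expect_equal(sum(nd$normal[2, ] * nd$tangent[2, ]), 0)
  set.seed(3)
  cols <- seq(1, 40, by = 0.8)
  rows <- 20 + 5 * sin(cols / 6) + cumsum(rnorm(length(cols), 0, 0.1))
  nf2 <- normals(cbind(rows, cols))
  expect_equal(sqrt(rowSums(nf2$normal^2)), rep(1, length(cols)),
               tolerance = 1e-9)
  expect_equal(rowSums(nf2$normal * nf2$tangent), rep(0, length(cols)),
               tolerance = 1e-9)
  expect_true(all(nf2$normal[, 1] > 0))
})

test_that("raw thickness is the normal-ray distance to the mask exit", {
  mask <- matrix(FALSE, 30, 15)
  mask[10:13, ] <- TRUE                      # constant 4-px band
  seqp <- cbind(rep(10, 15), 1:15)
  nf <- normals(seqp)
  prof <- measure_thickness(mask, seqp, nf)
  expect_true(all(abs(prof$raw - 4) <= 0.5))
  # vessel bump: local thickness 12 over 5 columns, baseline 4
  bump <- mask
  bump[10:21, 6:10] <- TRUE
  pb <- measure_thickness(bump, seqp, nf)
  expect_true(all(abs(pb$raw[6:10] - 12) <= 0.5))
  expect_true(all(abs(pb$raw[c(1:4, 12:15)] - 4) <= 0.5))
  empty <- measure_thickness(matrix(FALSE, 30, 15), seqp, nf)
  expect_equal(empty$raw, rep(0, 15))
})

test_that("continuity correction rejects jumps but passes gradual change", {
  const <- correct_thickness(rep(5, 40), 7, 2)
  expect_equal(const$corrected, rep(5, 40))
  spiky <- rep(4, 41); spiky[21] <- 20
  cs <- correct_thickness(spiky, 7, 2)
  med <- stats::runmed(spiky, 7, endrule = "median")  # brute-force oracle
  expect_equal(med[21], 4)
  expect_equal(cs$corrected[21], mean(c(cs$corrected[20], 4,
                                        cs$corrected[22])), tolerance = 1e-9)
  expect_true(all(abs(cs$corrected - 4) < 0.5))
  # smooth ramp 3 -> 9 over 100 points: only the 3-point smoothing acts
  ramp <- seq(3, 9, length.out = 100)
  cr <- correct_thickness(ramp, 9, 2)
  oracle <- (c(ramp[1], ramp[-100]) + ramp + c(ramp[-1], ramp[100])) / 3
  expect_equal(cr$corrected, oracle, tolerance = 1e-12)
  expect_error(correct_thickness(ramp, 9, 0.5), "`k`")
})

test_that("continuity correction is idempotent and never raises the maximum", {
  set.seed(8)
  for (i in 1:5) {
    raw <- pmax(0.5, 5 + cumsum(rnorm(80, 0, 0.2)))
    raw[sample(80, 3)] <- 25
    p1 <- correct_thickness(raw, 9, 2)
    p2 <- correct_thickness(p1$corrected, 9, 2)
    expect_lt(max(abs(p2$corrected - p1$corrected)), 0.5)
    expect_lte(max(p1$corrected), max(raw))
    expect_true(all(p1$corrected > 0))
  }
})

test_that("zeros in the raw profile are filled by interpolation", {
  raw <- c(4, 4, 0, 0, 4, 4, 4)
  p <- correct_thickness(raw, 3, 2)
  expect_true(all(p$corrected > 3 & p$corrected <= 4.5))
})

test_that("skin_mask sweeps the corrected band and seals gaps", {
  seqp <- cbind(rep(10, 20), 1:20)
  nf <- normals(seqp)
  m <- skin_mask(seqp, nf, rep(3, 20), c(30, 20))
  expect_equal(unname(colSums(m)), rep(3, 20))
  expect_equal(which(m[, 5]), 10:12)
  expect_false(any(skin_mask(seqp, nf, rep(0, 20), c(30, 20))))
  # curved boundary: area within 10% of the thickness line integral
  cols <- seq(1, 60, by = 0.5)
  rows <- 25 + 8 * sin(cols / 9)
  sq <- cbind(rows, cols)
  nfc <- normals(sq)
  corr <- 4 + 2 * cos(cols / 11)
  mc <- skin_mask(sq, nfc, corr, c(60, 60))
  seg_len <- sqrt(rowSums(diff(sq)^2))
  integral <- sum((corr[-1] + corr[-length(corr)]) / 2 * seg_len)
  expect_lt(abs(sum(mc) - integral) / integral, 0.1)
})

test_that("skin removal zeroes the mask and nothing else", {
  set.seed(2)
  img <- matrix(runif(64), 8, 8)
  expect_equal(remove_skin(img, matrix(FALSE, 8, 8)), img)
  expect_equal(remove_skin(img, matrix(TRUE, 8, 8)), matrix(0, 8, 8))
  expect_error(remove_skin(img, matrix(FALSE, 8, 9)), "shape")
})

test_that("vessels adherent to the skin survive the skin removal", {
  for (s in c(3, 12)) {
    ph <- generate_slice(phantom_spec(seed = s), 0L)
    res <- segment_slice(ph$slice)
    vess <- ph$labels == 2L
    cleaned <- remove_skin(ph$slice, res$skin_mask | res$organ_mask)
    kept <- sum(cleaned$pixels[vess] == ph$slice$pixels[vess])
    expect_gte(kept / sum(vess), 0.9)
  }
})
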