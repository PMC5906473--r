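test_that("external energy vanishes where the image is flat or linear", {
  p <- snake_params(smooth_sigma = 0)
  f <- external_energy(matrix(0.3, 12, 12), p)
  expect_equal(f$e_edge, matrix(0, 12, 12))
  expect_equal(f$e_term, matrix(0, 12, 12))
  ramp <- matrix(rep(seq(0, 1, length.out = 15), each = 15), 15, 15,
                 byrow = TRUE)  # I = x (column direction)
  fr <- external_energy(ramp, p)
  expect_equal(fr$e_term, matrix(0, 15, 15), tolerance = 1e-12)
  expect_true(all(fr$e_edge <= 0))
})

test_that("termination energy equals the level-line curvature 1/r on a cone", {
  # C = x^2 + y^2 around the grid center; central differences are exact
  # for quadratics, so E_term = 1/r exactly up to the denominator floor
  n <- 41; ctr <- 21
  xs <- matrix(rep(1:n - ctr, each = n), n, n)  # col coordinate
  ys <- matrix(rep(1:n - ctr, times = n), n, n) # row coordinate
  cimg <- xs^2 + ys^2
  f <- external_energy(cimg, snake_params(smooth_sigma = 0, w_term = 1))
  for (pt in list(c(3, 4), c(6, 8), c(-5, 12), c(0, 10))) {
    r <- ctr + pt[2]; cc <- ctr + pt[1]
    expect_equal(f$e_term[r, cc], 1 / sqrt(sum(pt^2)), tolerance = 0.05)
  }
})

test_that("external energy is linear in the three weights", {
  set.seed(2)
  img <- matrix(runif(100), 10, 10)
  p1 <- snake_params(w_line = 0.3, w_edge = 0.7, w_term = 0.2)
  p2 <- snake_params(w_line = 0.6, w_edge = 1.4, w_term = 0.4)
  expect_equal(2 * external_energy(img, p1)$e_ext,
               external_energy(img, p2)$e_ext)
})

test_that("snake_step has the contracted fixed points", {
  flat <- structure(list(e_ext = matrix(0, 20, 20)), class = "energy_field")
  ct <- cbind(seq(5, 15, length.out = 7), seq(3, 17, length.out = 7))
  # alpha = beta = 0, no field: nothing moves
  p0 <- snake_params(alpha = 0, beta = 0)
  expect_equal(snake_step(ct, flat, p0), ct)
  # straight evenly spaced line is the internal-energy minimizer
  p1 <- snake_params(alpha = 0.5, beta = 0.8)
  expect_equal(snake_step(ct, flat, p1), ct, tolerance = 1e-12)
  # step -> 0 leaves the contour unchanged
  set.seed(5)
  img <- matrix(runif(400), 20, 20)
  f <- external_energy(img, snake_params())
  tiny <- snake_step(ct, f, snake_params(step = 1e-9))
  expect_lt(max(sqrt(rowSums((tiny - ct)^2))), 1e-6)
})

test_that("snake_step matches a dense linear-algebra oracle", {
  for (s in 1:20) {
    set.seed(s)
    img <- matrix(runif(100), 10, 10)
    p <- snake_params(alpha = runif(1, 0, 0.5), beta = runif(1, 0, 1),
                      step = runif(1, 0.2, 1.5))
    f <- external_energy(img, p)
    n <- sample(5:7, 1)
    ct <- cbind(runif(n, 2, 9), sort(runif(n, 2, 9)))
    expect_equal(snake_step(ct, f, p),
                 brute_snake_step(ct, f$e_ext, p$alpha, p$beta, p$step),
                 tolerance = 1e-9)
  }
})

test_that("evolution stops immediately at an equilibrium and is deterministic", {
  flat <- structure(list(e_ext = matrix(0, 30, 30)), class = "energy_field")
  line <- cbind(rep(10, 12), seq(2, 28, length.out = 12))
  p <- snake_params(alpha = 0.3, beta = 0)
  fit <- evolve(line, flat, p)
  expect_equal(fit$n_iter, 1L)
  expect_equal(fit$contour[, 1], rep(10, nrow(fit$contour)))
  ph <- generate_slice(phantom_spec(seed = 21), 0L)
  sp <- snake_params()
  f <- external_energy(ph$slice$pixels, sp)
  init <- cbind(rep(60, 50), seq(10, 246, length.out = 50))
  f1 <- evolve(init, f, sp)
  f2 <- evolve(init, f, sp)
  expect_identical(f1$contour, f2$contour)
  expect_identical(f1$energy, f2$energy)
})

test_that("the evolved contour finds the inner skin edge on phantoms", {
  hits <- numeric(0)
  for (s in 1:3) {
    spec <- phantom_spec(n_slices = 1L, n_vessels = 0L, seed = s)
    ph <- generate_slice(spec, 0L)
    res <- segment_slice(ph$slice)
    inner <- apply(ph$labels == 1L, 2, function(z) rev(which(z))[1]) + 1
    sr <- stats::approx(res$snake$contour[, 2], res$snake$contour[, 1],
                        xout = seq_len(256), ties = mean)$y
    hits <- c(hits, mean(abs(sr - inner) <= 2, na.rm = TRUE))
  }
  expect_true(all(hits >= 0.9))
})

test_that("rough masks on clean vessel-free phantoms overlap the true skin", {
  for (s in c(1, 6)) {
    spec <- phantom_spec(n_slices = 1L, n_vessels = 0L, noise_sigma = 0,
                         seed = s)
    ph <- generate_slice(spec, 0L)
    res <- segment_slice(ph$slice)
    expect_gte(dice(res$rough_mask, ph$labels == 1L), 0.85)
  }
})

test_that("contour_to_band rasterizes the inter-contour band per column", {
  ub <- structure(list(row = rep(10, 20), col = 1:20),
                  class = "skin_boundary")
  lower <- cbind(rep(13, 20), 1:20)
  band <- contour_to_band(ub, lower, c(30, 20))
  expect_equal(unname(colSums(band)), rep(3, 20))
  expect_equal(which(band[, 7]), 10:12)
  empty <- contour_to_band(ub, cbind(rep(10, 20), 1:20), c(30, 20))
  expect_false(any(empty))
  # random monotone pair vs per-column brute force
  set.seed(9)
  urow <- runif(20, 5, 10)
  lrow <- urow + runif(20, 0, 8)
  ub2 <- structure(list(row = urow, col = 1:20), class = "skin_boundary")
  band2 <- contour_to_band(ub2, cbind(lrow, 1:20), c(30, 20))
  for (cc in 1:20) {
    expect_equal(sum(band2[, cc]),
                 sum(seq_len(30) >= urow[cc] & seq_len(30) < lrow[cc]))
  }
  # crossing contours are clipped and flagged
  crossed <- contour_to_band(ub, cbind(rep(8, 20), 1:20), c(30, 20))
  expect_false(any(crossed))
  expect_true(attr(crossed, "crossed"))
})
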