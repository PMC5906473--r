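# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately use naive loops and base R only, so they share no
# code path with the package's implementations.

# per-pixel sorted-median filter with edge replication
brute_median <- function(m, window) {
  r <- (window - 1) / 2
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- numeric(0)
    for (di in -r:r) for (dj in -r:r) {
      ii <- min(max(i + di, 1), nr)
      jj <- min(max(j + dj, 1), nc)
      vals <- c(vals, m[ii, jj])
    }
    out[i, j] <- median(vals)
  }
  out
}

# exhaustive Otsu: maximize between-class variance over all histogram cut
# points; returns the maximal objective value
brute_otsu_best <- function(x, levels = 256L) {
  breaks <- seq(0, 1, length.out = levels + 1)
  h <- hist(as.numeric(x), breaks = breaks, plot = FALSE)$counts
  mids <- (breaks[-(levels + 1)] + breaks[-1]) / 2
  best <- -Inf
  for (k in seq_len(levels - 1)) {
    w0 <- sum(h[1:k]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:k] * mids[1:k]) / w0
    m1 <- sum(h[(k + 1):levels] * mids[(k + 1):levels]) / w1
    best <- max(best, w0 * w1 * (m0 - m1)^2)
  }
  best
}

# objective value attained by an arbitrary threshold
otsu_objective <- function(x, th, levels = 256L) {
  breaks <- seq(0, 1, length.out = levels + 1)
  h <- hist(as.numeric(x), breaks = breaks, plot = FALSE)$counts
  mids <- (breaks[-(levels + 1)] + breaks[-1]) / 2
  lo <- mids < th
  w0 <- sum(h[lo]); w1 <- sum(h) - w0
  if (w0 == 0 || w1 == 0) return(0)
  m0 <- sum((h * mids)[lo]) / w0
  m1 <- sum((h * mids)[!lo]) / w1
  w0 * w1 * (m0 - m1)^2
}

# double-loop symmetric GLCM features with fixed-range quantization
brute_glcm <- function(patch, levels, offset, rng = c(0, 1)) {
  m <- pmin(pmax(patch, rng[1]), rng[2])
  q <- floor((m - rng[1]) / (rng[2] - rng[1]) * levels)
  q[q == levels] <- levels - 1
  counts <- matrix(0, levels, levels)
  nr <- nrow(q); nc <- ncol(q)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    i2 <- i + offset[1]; j2 <- j + offset[2]
    if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc) {
      a <- q[i, j] + 1; b <- q[i2, j2] + 1
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  p <- counts / sum(counts)
  lv <- 0:(levels - 1)
  px <- rowSums(p); py <- colSums(p)
  mx <- sum(lv * px); my <- sum(lv * py)
  sx <- sqrt(sum((lv - mx)^2 * px)); sy <- sqrt(sum((lv - my)^2 * py))
  ent <- 0; con <- 0; cor <- 0; asm <- 0
  for (a in seq_len(levels)) for (b in seq_len(levels)) {
    pp <- p[a, b]
    asm <- asm + pp^2
    if (pp > 0) ent <- ent - pp * log(pp)
    con <- con + (lv[a] - lv[b])^2 * pp
    cor <- cor + (lv[a] - mx) * (lv[b] - my) * pp
  }
  list(asm = asm, entropy = ent, contrast = con,
       correlation = if (sx > 0 && sy > 0) cor / (sx * sy) else NaN)
}

# triple-loop maximum intensity projection along the first axis
brute_mip_slice <- function(vox) {
  d <- dim(vox)
  out <- matrix(-Inf, d[2], d[3])
  for (i in seq_len(d[1])) for (r in seq_len(d[2])) for (cc in seq_len(d[3]))
    out[r, cc] <- max(out[r, cc], vox[i, r, cc])
  out
}

# one semi-implicit snake iteration built from explicit dense matrices
brute_snake_step <- function(contour, e_ext, alpha, beta, step) {
  n <- nrow(contour)
  d1 <- matrix(0, n - 1, n)
  for (i in seq_len(n - 1)) { d1[i, i] <- -1; d1[i, i + 1] <- 1 }
  d2 <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) {
    d2[i, i] <- 1; d2[i, i + 1] <- -2; d2[i, i + 2] <- 1
  }
  k <- alpha * t(d1) %*% d1 + beta * t(d2) %*% d2
  m <- diag(n) + step * k
  m[1, ] <- 0; m[1, 1] <- 1
  m[n, ] <- 0; m[n, n] <- 1
  # central-difference gradient of the energy field, replicated edges
  nr <- nrow(e_ext); nc <- ncol(e_ext)
  gr <- matrix(0, nr, nc); gc <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    gr[r, cc] <- (e_ext[min(r + 1, nr), cc] - e_ext[max(r - 1, 1), cc]) / 2
    gc[r, cc] <- (e_ext[r, min(cc + 1, nc)] - e_ext[r, max(cc - 1, 1)]) / 2
  }
  bil <- function(g, r, cc) {
    r <- min(max(r, 1), nr); cc <- min(max(cc, 1), nc)
    r0 <- min(floor(r), nr - 1); c0 <- min(floor(cc), nc - 1)
    fr <- r - r0; fc <- cc - c0
    g[r0, c0] * (1 - fr) * (1 - fc) + g[r0 + 1, c0] * fr * (1 - fc) +
      g[r0, c0 + 1] * (1 - fr) * fc + g[r0 + 1, c0 + 1] * fr * fc
  }
  rhs <- contour
  for (i in 2:(n - 1)) {
    rhs[i, 1] <- contour[i, 1] - step * bil(gr, contour[i, 1], contour[i, 2])
    rhs[i, 2] <- contour[i, 2] - step * bil(gc, contour[i, 1], contour[i, 2])
  }
  out <- qr.solve(m, rhs)
  out[, 1] <- pmin(pmax(out[, 1], 1), nr)
  out[, 2] <- pmin(pmax(out[, 2], 1), nc)
  out
}

# 8-connected flood fill from a set of start pixels; returns reachable mask
flood8 <- function(mask, starts) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  queue <- starts[mask[starts], , drop = FALSE]
  seen[queue] <- TRUE
  while (nrow(queue) > 0) {
    p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
    for (dr in -1:1) for (dc in -1:1) {
      r <- p[1] + dr; cc <- p[2] + dc
      if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
          mask[r, cc] && !seen[r, cc]) {
        seen[r, cc] <- TRUE
        queue <- rbind(queue, c(r, cc))
      }
    }
  }
  seen
}

# small phantom spec used where full 256x256 frames are unnecessary
tiny_phantom <- function(seed = 1, ...) {
  phantom_spec(shape = c(96L, 96L), n_slices = 1L, n_vessels = 0L,
               tumor = FALSE, noise_sigma = 0, seed = seed, ...)
}
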