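# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

# textbook Pearson correlation by explicit double loop over masked pixels
bf_pearson <- function(a, b, mask) {
  va <- c(); vb <- c()
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    if (mask[i, j]) { va <- c(va, a[i, j]); vb <- c(vb, b[i, j]) }
  }
  ma <- sum(va) / length(va); mb <- sum(vb) / length(vb)
  num <- 0; da2 <- 0; db2 <- 0
  for (k in seq_along(va)) {
    num <- num + (va[k] - ma) * (vb[k] - mb)
    da2 <- da2 + (va[k] - ma)^2
    db2 <- db2 + (vb[k] - mb)^2
  }
  num / sqrt(da2 * db2)
}

# Manders overlap by explicit loop
bf_manders <- function(a, b, mask) {
  num <- 0; a2 <- 0; b2 <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    if (mask[i, j]) {
      num <- num + a[i, j] * b[i, j]
      a2 <- a2 + a[i, j]^2
      b2 <- b2 + b[i, j]^2
    }
  }
  num / sqrt(a2 * b2)
}

# dense 2-D convolution with mirror-reflected boundaries, by direct loops;
# kernel built from first principles as a normalized sampled Gaussian
bf_gauss_conv <- function(img, sigma) {
  r <- ceiling(3 * sigma)
  g <- dnorm(seq(-r, r), sd = sigma)
  k <- outer(g, g); k <- k / sum(k)
  refl <- function(i, n) {
    i <- (i - 1) %% (2 * n)
    if (i >= n) i <- 2 * n - 1 - i
    i + 1
  }
  out <- img * 0
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    s <- 0
    for (di in -r:r) for (dj in -r:r) {
      s <- s + k[di + r + 1, dj + r + 1] *
        img[refl(i + di, nrow(img)), refl(j + dj, ncol(img))]
    }
    out[i, j] <- s
  }
  out
}

# a filled disk on a zero background, as a quick nucleus stand-in
disk_image <- function(n, cy, cx, r, value = 1000) {
  m <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- value
  m
}

# map ground-truth nucleus labels to segmentation labels via the nucleus
# centre pixel
truth_to_mask_label <- function(truth, mask) {
  vapply(seq_len(nrow(truth$nuclei)), function(i) {
    mask$labels[round(truth$nuclei$row[i]), round(truth$nuclei$col[i])]
  }, integer(1))
}

# per-nucleus minimum pairwise distance between planted channel-A foci
min_focus_spacing_per_nucleus <- function(truth) {
  vapply(split(truth$foci_A, truth$foci_A$nucleus), function(f) {
    if (nrow(f) < 2) return(Inf)
    min(dist(cbind(f$row, f$col)))
  }, numeric(1))
}
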