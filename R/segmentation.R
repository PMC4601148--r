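#' Gaussian blur with mirror-reflected boundaries
#'
#' Convolves a 2-D intensity matrix with an isotropic Gaussian kernel of
#' standard deviation `sigma` (kernel radius `2*ceiling(3*sigma) + 1`
#' pixels). The image is mirror-padded before convolution so borders see
#' reflected image content rather than zeros or wrap-around, avoiding the
#' dark-edge artifacts that would bias difference-of-Gaussians values for
#' foci near the nucleus border.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels, > 0.
#' @return Blurred matrix of the same dimensions.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma > 0)
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  k <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  k <- k / sum(k)
  r <- (size - 1L) %/% 2L
  padded <- img[reflect_index(nrow(img), r), reflect_index(ncol(img), r)]
  out <- EBImage::filter2(padded, k, boundary = "circular")
  out[r + seq_len(nrow(img)), r + seq_len(ncol(img))]
}

# mirror-reflected index sequence of length n + 2r (edge pixel included in
# the reflection, scipy "reflect" style); valid for any pad length
reflect_index <- function(n, r) {
  i <- (seq.int(1L - r, n + r) - 1L) %% (2L * n)
  i <- ifelse(i >= n, 2L * n - 1L - i, i)
  i + 1L
}

#' Parameters of difference-of-Gaussians enhancement
#'
#' The "radius" of each Gaussian kernel is its standard deviation in
#' pixels. The small radius matches the spatial scale of pixel noise
#' (default 1 px); the big radius matches the maximum focal-signal size
#' (default 30 px at 30-nm pixels).
#'
#' @param sigma_small small Gaussian sigma, pixels.
#' @param sigma_big big Gaussian sigma, pixels; must exceed `sigma_small`.
#' @param normalize if `TRUE` (default) rescale so the in-mask maximum is 1.
#' @return A `DoGParams` object.
#' @export
dog_params <- function(sigma_small = 1, sigma_big = 30, normalize = TRUE) {
  if (!(is.numeric(sigma_small) && is.numeric(sigma_big) &&
        sigma_small > 0 && sigma_small < sigma_big))
    stop("need 0 < sigma_small < sigma_big")
  structure(list(sigma_small = sigma_small, sigma_big = sigma_big,
                 normalize = isTRUE(normalize)),
            class = "DoGParams")
}

#' Segment nuclei from the DNA counterstain channel
#'
#' The DNA channel is lightly smoothed (Gaussian, `smooth_sigma`),
#' thresholded with Otsu's method, hole-filled, and labeled into connected
#' components; components smaller than `min_area` pixels are dropped, and
#' components touching the image border can optionally be dropped too. A
#' contrast-free (constant) image yields an empty mask with zero nuclei,
#' not an error.
#'
#' @param dna_channel 2-D intensity matrix.
#' @param min_area minimum nucleus area in pixels.
#' @param smooth_sigma pre-threshold smoothing sigma in pixels.
#' @param drop_border drop nuclei touching the image border.
#' @return A `NucleusMask`: list with `labels` (integer matrix, 0 =
#'   background), `n_nuclei`, and `areas` (pixels per nucleus, named by
#'   label).
#' @export
segment_nuclei <- function(dna_channel, min_area = 200, smooth_sigma = 2,
                           drop_border = FALSE) {
  stopifnot(is.matrix(dna_channel), length(dna_channel) > 0)
  rng <- range(dna_channel)
  if (diff(rng) == 0) return(nucleus_mask(matrix(0L, nrow(dna_channel),
                                                 ncol(dna_channel))))
  sm <- gaussian_blur(dna_channel, smooth_sigma)
  sm <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- EBImage::otsu(sm, range = c(0, 1), levels = 256)
  bw <- EBImage::fillHull(sm > thr)
  lab <- label_components(bw, connectivity = 8L)
  areas <- tabulate(lab[lab > 0L])
  drop <- which(areas < min_area)
  if (drop_border) {
    border_labs <- unique(c(lab[1L, ], lab[nrow(lab), ],
                            lab[, 1L], lab[, ncol(lab)]))
    drop <- union(drop, border_labs[border_labs > 0L])
  }
  if (length(drop)) lab[lab %in% drop] <- 0L
  # relabel 1..k in top-left raster order of first occurrence
  keep <- sort(unique(lab[lab > 0L]))
  lab <- matrix(match(lab, keep, nomatch = 0L), nrow(lab), ncol(lab))
  nucleus_mask(lab)
}

nucleus_mask <- function(labels) {
  stopifnot(is.matrix(labels))
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  n <- max(labels)
  areas <- if (n > 0L) tabulate(labels[labels > 0L], nbins = n) else integer(0)
  names(areas) <- if (n > 0L) seq_len(n) else character(0)
  structure(list(labels = labels, n_nuclei = n, areas = areas),
            class = "NucleusMask")
}

#' @export
print.NucleusMask <- function(x, ...) {
  cat("NucleusMask: ", x$n_nuclei, " nuclei in ",
      nrow(x$labels), " x ", ncol(x$labels), " px",
      if (x$n_nuclei > 0)
        paste0("; areas ", min(x$areas), "-", max(x$areas), " px"),
      "\n", sep = "")
  invisible(x)
}

#' Label connected components of a binary image
#'
#' 4- or 8-connected labeling. The 8-connected variant augments
#' [EBImage::bwlabel()]'s 4-connected components by merging labels that
#' touch diagonally, so diagonal pixel chains count as one blob, matching
#' the usual behaviour of blob-measurement tools.
#'
#' @param bw logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return Integer label matrix, 0 = background.
#' @export
label_components <- function(bw, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  lab <- EBImage::bwlabel(bw * 1)
  storage.mode(lab) <- "integer"
  lab <- matrix(lab, nrow(bw), ncol(bw))
  n <- max(lab)
  if (connectivity == 4L || n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs (both >0, different labels)
  p1 <- rbind(cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L])),
              cbind(as.vector(lab[-nr, -1L]), as.vector(lab[-1L, -nc])))
  p1 <- p1[p1[, 1L] > 0L & p1[, 2L] > 0L & p1[, 1L] != p1[, 2L], ,
           drop = FALSE]
  if (!nrow(p1)) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(p1))) {
    a <- find(p1[k, 1L]); b <- find(p1[k, 2L])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  remap <- match(root, sort(unique(root)))
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

mask_labels <- function(mask) {
  if (inherits(mask, "NucleusMask")) mask$labels
  else if (is.logical(mask)) matrix(as.integer(mask), nrow(mask), ncol(mask))
  else mask
}

#' Difference-of-Gaussians enhancement of focal signals
#'
#' Computes `blur(sigma_small) - blur(sigma_big)`, clips negative values to
#' zero (removing noise and smooth background), zeroes all pixels outside
#' the nucleus mask, and — when `params$normalize` — rescales so the
#' in-mask maximum equals 1 (an all-zero result is left as zeros).
#'
#' @param channel 2-D intensity matrix.
#' @param params a [dog_params()] object.
#' @param mask a `NucleusMask` or logical matrix; pixels outside are set
#'   to 0. `NULL` keeps the whole image.
#' @return Nonnegative matrix, max 1 inside the mask when normalized.
#' @export
dog_segment <- function(channel, params = dog_params(), mask = NULL) {
  stopifnot(is.matrix(channel), inherits(params, "DoGParams"))
  dog <- gaussian_blur(channel, params$sigma_small) -
         gaussian_blur(channel, params$sigma_big)
  # clip negatives; also floor FFT round-off so a featureless channel stays
  # exactly zero instead of being amplified by normalization
  eps <- 1e-9 * max(1, max(abs(channel)))
  dog[dog < eps] <- 0
  if (!is.null(mask)) {
    lab <- mask_labels(mask)
    stopifnot(all(dim(lab) == dim(channel)))
    dog[lab == 0L] <- 0
  }
  if (params$normalize) {
    m <- max(dog)
    if (m > 0) dog <- dog / m
  }
  dog
}

#' Verify the plateau of colocalization coefficients over DoG radii
#'
#' Repeats DoG segmentation of both channels over a series of big-Gaussian
#' radii, computes per-nucleus Pearson (`Rr`) and Manders overlap (`R`)
#' coefficients at each radius, averages them over nuclei, and reports the
#' maximum relative deviation from the reference radius within a stated
#' radius window. Stable coefficients across the window indicate the
#' segmentation scale is not driving the colocalization estimate.
#'
#' @param channelA,channelB 2-D intensity matrices.
#' @param mask a `NucleusMask`.
#' @param radii increasing vector of big-Gaussian sigmas (pixels).
#' @param sigma_small small Gaussian sigma; all radii must exceed it.
#' @param reference radius against which deviations are measured
#'   (default 30).
#' @param window `(lo, hi)` radius range over which the deviation is taken
#'   (default `c(30, 55)`).
#' @return List with `table` (data.frame: radius, mean Rr, mean R over
#'   nuclei), `max_rel_dev` (maximum of `|c(r) - c(ref)| / |c(ref)|` over
#'   window radii and both coefficients), `reference`, and `window`.
#' @export
plateau_check <- function(channelA, channelB, mask,
                          radii = seq(10, 55, by = 5), sigma_small = 1,
                          reference = 30, window = c(30, 55)) {
  if (!length(radii)) stop("'radii' must be nonempty")
  if (is.unsorted(radii, strictly = TRUE))
    stop("'radii' must be strictly increasing")
  if (any(radii <= sigma_small))
    stop("all radii must exceed sigma_small")
  if (!reference %in% radii)
    stop("'reference' must be one of 'radii'")
  rows <- lapply(radii, function(r) {
    res <- coloc_per_nucleus_mats(channelA, channelB, mask,
                                  dog_params(sigma_small, r))
    ok <- !res$undefined
    data.frame(radius = r, Rr = mean(res$Rr[ok]), R = mean(res$R[ok]),
               n_nuclei = sum(ok))
  })
  tab <- do.call(rbind, rows)
  ref <- tab[tab$radius == reference, ]
  inwin <- tab$radius >= window[1] & tab$radius <= window[2]
  dev <- pmax(abs(tab$Rr[inwin] - ref$Rr) / abs(ref$Rr),
              abs(tab$R[inwin] - ref$R) / abs(ref$R))
  list(table = tab, max_rel_dev = max(dev), reference = reference,
       window = window)
}
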