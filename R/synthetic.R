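#' Specification of a synthetic microscopy scene
#'
#' Describes a two- or three-channel fluorescence scene: elliptical nuclei
#' (DNA counterstain channel `dna`) containing discrete Gaussian-profile
#' repair-protein foci in immunofluorescence channels `A` and `B`. A
#' controllable fraction of channel-A foci is duplicated at the same
#' position in channel B (true colocalization); additional channel-B foci
#' can be planted independently. A fraction of nuclei can be rendered with
#' dense pan-nuclear staining in channel A, emulating the apoptotic-type
#' uniformly stained cells that focus counting must exclude.
#'
#' Defaults emulate the projected-image geometry used for focus counting:
#' 0.285 um pixels, nuclei of 4-7 um radius, ~10 foci per nucleus with
#' sub-micrometre footprints, 16-bit intensities, and additive Gaussian
#' read noise well below the focus amplitude.
#'
#' @param image_shape integer (rows, cols) in pixels.
#' @param pixel_size pixel edge in micrometres.
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_radius_range (min, max) semi-axis range in pixels; the two
#'   semi-axes of each elliptical nucleus are drawn independently.
#' @param foci_per_nucleus either a single nonnegative integer (fixed count)
#'   or `list(poisson = mean)` for Poisson-distributed counts.
#' @param focus_sigma_range (min, max) Gaussian profile sigma in pixels.
#' @param min_focus_spacing minimum centre-to-centre distance in pixels
#'   between foci planted in the same nucleus (same channel). 0 (default)
#'   places foci independently; a positive value emulates resolvable,
#'   countable foci. Best-effort: if a spacing-respecting position cannot
#'   be found in 200 draws, the best candidate is used.
#' @param focus_amplitude peak intensity added by one focus.
#' @param coloc_fraction fraction in `[0, 1]` of channel-A foci duplicated
#'   at identical positions in channel B.
#' @param independent_foci_B extra channel-B foci per nucleus at random
#'   positions, unrelated to channel A.
#' @param coloc_jitter standard deviation in pixels of positional jitter
#'   added to duplicated B foci (0 = exact same centre).
#' @param background_level constant offset added to channels A and B.
#' @param noise_sigma Gaussian read-noise standard deviation (all channels).
#' @param shot_noise if `TRUE`, Poisson-resample the noise-free signal.
#' @param pan_nuclear_fraction fraction of nuclei rendered with dense
#'   uniform channel-A staining (at 1.5 x `focus_amplitude`) instead of
#'   discrete foci.
#' @param dna_level intensity of the nucleus interior in the DNA channel.
#' @param bit_depth 8 or 16; output is clipped (never wrapped) to range.
#' @param seed integer seed; identical spec + seed gives a bit-identical
#'   scene and ground truth.
#' @return A validated `SceneSpec` object.
#' @export
scene_spec <- function(image_shape = c(512L, 512L),
                       pixel_size = 0.285,
                       n_nuclei = 10L,
                       nucleus_radius_range = c(16, 26),
                       foci_per_nucleus = 10L,
                       focus_sigma_range = c(1, 1.8),
                       min_focus_spacing = 0,
                       focus_amplitude = 10000,
                       coloc_fraction = 0,
                       independent_foci_B = 0L,
                       coloc_jitter = 0,
                       background_level = 1000,
                       noise_sigma = 500,
                       shot_noise = FALSE,
                       pan_nuclear_fraction = 0,
                       dna_level = 20000,
                       bit_depth = 16L,
                       seed = 1L) {
  chk <- function(ok, field, msg)
    if (!ok) stop("invalid '", field, "': ", msg, call. = FALSE)
  chk(length(image_shape) == 2L && all(image_shape >= 32),
      "image_shape", "need (rows, cols) each >= 32")
  chk(is.numeric(pixel_size) && pixel_size > 0, "pixel_size", "must be > 0")
  chk(n_nuclei >= 0, "n_nuclei", "must be >= 0")
  chk(length(nucleus_radius_range) == 2L &&
        nucleus_radius_range[1] > 0 && diff(nucleus_radius_range) >= 0,
      "nucleus_radius_range", "need 0 < min <= max")
  if (is.list(foci_per_nucleus)) {
    chk(!is.null(foci_per_nucleus$poisson) && foci_per_nucleus$poisson >= 0,
        "foci_per_nucleus", "list form must be list(poisson = mean >= 0)")
  } else {
    chk(length(foci_per_nucleus) == 1L && foci_per_nucleus >= 0,
        "foci_per_nucleus", "must be a single count >= 0")
  }
  chk(length(focus_sigma_range) == 2L && focus_sigma_range[1] > 0 &&
        diff(focus_sigma_range) >= 0,
      "focus_sigma_range", "need 0 < min <= max")
  chk(min_focus_spacing >= 0, "min_focus_spacing", "must be >= 0")
  chk(focus_amplitude >= 0, "focus_amplitude", "must be >= 0")
  chk(coloc_fraction >= 0 && coloc_fraction <= 1,
      "coloc_fraction", "must lie in [0, 1]")
  chk(independent_foci_B >= 0, "independent_foci_B", "must be >= 0")
  chk(coloc_jitter >= 0, "coloc_jitter", "must be >= 0")
  chk(background_level >= 0, "background_level", "must be >= 0")
  chk(noise_sigma >= 0, "noise_sigma", "must be >= 0")
  chk(pan_nuclear_fraction >= 0 && pan_nuclear_fraction <= 1,
      "pan_nuclear_fraction", "must lie in [0, 1]")
  chk(bit_depth %in% c(8L, 16L), "bit_depth", "must be 8 or 16")
  spec <- list(image_shape = as.integer(image_shape),
               pixel_size = pixel_size, n_nuclei = as.integer(n_nuclei),
               nucleus_radius_range = nucleus_radius_range,
               foci_per_nucleus = foci_per_nucleus,
               focus_sigma_range = focus_sigma_range,
               min_focus_spacing = min_focus_spacing,
               focus_amplitude = focus_amplitude,
               coloc_fraction = coloc_fraction,
               independent_foci_B = as.integer(independent_foci_B),
               coloc_jitter = coloc_jitter,
               background_level = background_level,
               noise_sigma = noise_sigma, shot_noise = isTRUE(shot_noise),
               pan_nuclear_fraction = pan_nuclear_fraction,
               dna_level = dna_level, bit_depth = as.integer(bit_depth),
               seed = as.integer(seed))
  class(spec) <- "SceneSpec"
  spec
}

#' Scene preset emulating high-resolution colocalization acquisitions
#'
#' One nucleus per field at 30-nm pixels (the scale at which repair-protein
#' colocalization is measured), with ~10 foci per channel whose footprints
#' reach the ~25-30 px maximum focal-signal size that motivates the 30-px
#' big-Gaussian radius. By default 70 % of channel-A foci are duplicated in
#' channel B and B is topped up with independent foci so both channels
#' carry the same focus count; read noise is a tenth of the focus
#' amplitude.
#'
#' @param seed integer seed.
#' @param coloc_fraction planted colocalized fraction (default 0.7).
#' @param foci_per_nucleus foci per channel (default 10).
#' @param noise_sigma read-noise SD (default 1000, i.e. amplitude/10).
#' @return A `SceneSpec` for a single-nucleus 256 x 256 scene.
#' @export
coloc_scene_spec <- function(seed = 1L, coloc_fraction = 0.7,
                             foci_per_nucleus = 10L, noise_sigma = 1000) {
  n_dup <- round(coloc_fraction * foci_per_nucleus)
  scene_spec(image_shape = c(256L, 256L), pixel_size = 0.03,
             n_nuclei = 1L, nucleus_radius_range = c(90, 110),
             foci_per_nucleus = foci_per_nucleus,
             focus_sigma_range = c(4, 8), min_focus_spacing = 25,
             focus_amplitude = 10000,
             coloc_fraction = coloc_fraction,
             independent_foci_B = max(0L, foci_per_nucleus - n_dup),
             background_level = 1000, noise_sigma = noise_sigma,
             seed = seed)
}

n_foci_draw <- function(fspec, n) {
  if (is.list(fspec)) stats::rpois(n, fspec$poisson)
  else rep.int(as.integer(fspec), n)
}

# membership of pixel grid in a rotated ellipse; returns logical matrix for
# the patch rows/cols given
ellipse_patch <- function(rows, cols, cy, cx, a, b, theta) {
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  (u / a)^2 + (v / b)^2 <= 1
}

sample_nuclei <- function(spec) {
  sh <- spec$image_shape
  rr <- spec$nucleus_radius_range
  n <- spec$n_nuclei
  out <- data.frame(label = integer(0), row = numeric(0), col = numeric(0),
                    a = numeric(0), b = numeric(0), theta = numeric(0))
  max_attempts <- 200L * max(n, 1L)
  attempts <- 0L
  while (nrow(out) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not place ", n, " non-overlapping nuclei in a ",
           sh[1], "x", sh[2], " image after ", max_attempts, " attempts",
           call. = FALSE)
    a <- stats::runif(1, rr[1], rr[2])
    b <- stats::runif(1, rr[1], rr[2])
    theta <- stats::runif(1, 0, pi)
    rmax <- max(a, b)
    if (2 * rmax + 4 >= min(sh)) {
      stop("nuclei of radius ", round(rmax, 1),
           " px do not fit a ", sh[1], "x", sh[2], " image", call. = FALSE)
    }
    cy <- stats::runif(1, rmax + 2, sh[1] - rmax - 2)
    cx <- stats::runif(1, rmax + 2, sh[2] - rmax - 2)
    if (nrow(out)) {
      d <- sqrt((out$row - cy)^2 + (out$col - cx)^2)
      if (any(d < pmax(out$a, out$b) + rmax + 2)) next
    }
    out <- rbind(out, data.frame(label = nrow(out) + 1L, row = cy, col = cx,
                                 a = a, b = b, theta = theta))
  }
  out
}

# uniform point inside an ellipse, slightly inset so the focus core stays
# within the nucleus
point_in_ellipse <- function(nuc, inset = 0.9) {
  ang <- stats::runif(1, 0, 2 * pi)
  rho <- sqrt(stats::runif(1)) * inset
  u <- rho * nuc$a * cos(ang)
  v <- rho * nuc$b * sin(ang)
  c(row = nuc$row + sin(nuc$theta) * u + cos(nuc$theta) * v,
    col = nuc$col + cos(nuc$theta) * u - sin(nuc$theta) * v)
}

# k points in a nucleus honouring a minimum pairwise spacing (best-effort:
# after 200 draws the candidate farthest from existing points is kept)
sample_focus_points <- function(nuc, k, spacing) {
  pts <- matrix(NA_real_, k, 2L)
  for (j in seq_len(k)) {
    best <- NULL; best_d <- -Inf
    for (try in seq_len(if (spacing > 0) 200L else 1L)) {
      p <- point_in_ellipse(nuc)
      d <- if (j == 1L) Inf
           else min(sqrt((pts[seq_len(j - 1L), 1L] - p[1L])^2 +
                         (pts[seq_len(j - 1L), 2L] - p[2L])^2))
      if (d > best_d) { best <- p; best_d <- d }
      if (d >= spacing) break
    }
    pts[j, ] <- best
  }
  pts
}

sample_truth <- function(spec) {
  nuclei <- sample_nuclei(spec)
  n <- nrow(nuclei)
  n_pan <- round(spec$pan_nuclear_fraction * n)
  pan_labels <- if (n_pan > 0) sort(sample(nuclei$label, n_pan)) else integer(0)
  nuclei$pan_nuclear <- nuclei$label %in% pan_labels

  counts <- n_foci_draw(spec$foci_per_nucleus, n)
  counts[nuclei$pan_nuclear] <- 0L  # dense staining replaces discrete foci

  foci_A <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- counts[i]
    if (k == 0L) return(NULL)
    pts <- sample_focus_points(nuclei[i, ], k, spec$min_focus_spacing)
    data.frame(nucleus = nuclei$label[i], row = pts[, 1], col = pts[, 2],
               sigma = stats::runif(k, spec$focus_sigma_range[1],
                                    spec$focus_sigma_range[2]),
               amplitude = spec$focus_amplitude)
  }))
  if (is.null(foci_A))
    foci_A <- data.frame(nucleus = integer(0), row = numeric(0),
                         col = numeric(0), sigma = numeric(0),
                         amplitude = numeric(0))
  foci_A$id <- seq_len(nrow(foci_A))
  foci_A$colocalized <- rep(FALSE, nrow(foci_A))

  n_pairs <- round(spec$coloc_fraction * nrow(foci_A))
  pair_ids <- if (n_pairs > 0) sort(sample(foci_A$id, n_pairs)) else integer(0)
  foci_A$colocalized[foci_A$id %in% pair_ids] <- TRUE

  dup <- foci_A[foci_A$colocalized, , drop = FALSE]
  if (nrow(dup) && spec$coloc_jitter > 0) {
    dup$row <- dup$row + stats::rnorm(nrow(dup), 0, spec$coloc_jitter)
    dup$col <- dup$col + stats::rnorm(nrow(dup), 0, spec$coloc_jitter)
  }
  dup$paired_with <- dup$id

  indep <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- spec$independent_foci_B
    if (k == 0L) return(NULL)
    pts <- sample_focus_points(nuclei[i, ], k, spec$min_focus_spacing)
    data.frame(nucleus = nuclei$label[i], row = pts[, 1], col = pts[, 2],
               sigma = stats::runif(k, spec$focus_sigma_range[1],
                                    spec$focus_sigma_range[2]),
               amplitude = spec$focus_amplitude, id = NA_integer_,
               colocalized = FALSE, paired_with = NA_integer_)
  }))
  foci_B <- rbind(dup, indep)
  if (is.null(foci_B))
    foci_B <- data.frame(nucleus = integer(0), row = numeric(0),
                         col = numeric(0), sigma = numeric(0),
                         amplitude = numeric(0), id = integer(0),
                         colocalized = logical(0), paired_with = integer(0))
  foci_B$id <- seq_len(nrow(foci_B))
  rownames(foci_A) <- rownames(foci_B) <- NULL

  structure(list(nuclei = nuclei,
                 foci_A = foci_A[c("id", "nucleus", "row", "col", "sigma",
                                   "amplitude", "colocalized")],
                 foci_B = foci_B[c("id", "nucleus", "row", "col", "sigma",
                                   "amplitude", "paired_with")],
                 colocalized_pairs = data.frame(
                   focus_A = dup$paired_with,
                   focus_B = foci_B$id[match(dup$paired_with,
                                             foci_B$paired_with)]),
                 pan_nuclear_labels = pan_labels),
            class = "GroundTruth")
}

add_gaussian_spot <- function(img, row0, col0, sigma, amplitude) {
  r <- ceiling(4 * sigma)
  rows <- max(1L, floor(row0 - r)):min(nrow(img), ceiling(row0 + r))
  cols <- max(1L, floor(col0 - r)):min(ncol(img), ceiling(col0 + r))
  if (!length(rows) || !length(cols)) return(img)
  gy <- exp(-(rows - row0)^2 / (2 * sigma^2))
  gx <- exp(-(cols - col0)^2 / (2 * sigma^2))
  img[rows, cols] <- img[rows, cols] + amplitude * outer(gy, gx)
  img
}

render_scene <- function(spec, truth) {
  sh <- spec$image_shape
  rows <- seq_len(sh[1]); cols <- seq_len(sh[2])
  nuc_mask <- matrix(0L, sh[1], sh[2])
  for (i in seq_len(nrow(truth$nuclei))) {
    nu <- truth$nuclei[i, ]
    inside <- ellipse_patch(rows, cols, nu$row, nu$col, nu$a, nu$b, nu$theta)
    nuc_mask[inside] <- nu$label
  }
  dna <- matrix(0, sh[1], sh[2])
  dna[nuc_mask > 0L] <- spec$dna_level

  chanA <- matrix(0, sh[1], sh[2])
  for (i in seq_len(nrow(truth$foci_A))) {
    f <- truth$foci_A[i, ]
    chanA <- add_gaussian_spot(chanA, f$row, f$col, f$sigma, f$amplitude)
  }
  for (lab in truth$pan_nuclear_labels)
    chanA[nuc_mask == lab] <- chanA[nuc_mask == lab] + 1.5 * spec$focus_amplitude

  chanB <- matrix(0, sh[1], sh[2])
  for (i in seq_len(nrow(truth$foci_B))) {
    f <- truth$foci_B[i, ]
    chanB <- add_gaussian_spot(chanB, f$row, f$col, f$sigma, f$amplitude)
  }

  # focal signal is clipped at nucleus borders; background is global
  inside <- nuc_mask > 0L
  chanA[!inside] <- 0
  chanB[!inside] <- 0
  chanA <- chanA + spec$background_level
  chanB <- chanB + spec$background_level

  arr <- array(0, c(sh[1], sh[2], 3L))
  arr[, , 1L] <- dna; arr[, , 2L] <- chanA; arr[, , 3L] <- chanB
  if (spec$shot_noise)
    arr[] <- stats::rpois(length(arr), lambda = arr)
  if (spec$noise_sigma > 0)
    arr <- arr + stats::rnorm(length(arr), 0, spec$noise_sigma)
  maxval <- 2^spec$bit_depth - 1
  arr <- round(pmin(pmax(arr, 0), maxval))
  image_stack(arr, c("dna", "A", "B"), spec$pixel_size,
              bit_depth = spec$bit_depth)
}

#' Generate a synthetic scene with ground truth
#'
#' Renders the scene described by a [scene_spec()]: elliptical nuclei in the
#' DNA channel, planted Gaussian foci in channels A/B (pan-nuclear nuclei
#' get dense uniform channel-A staining instead), then optional shot noise,
#' Gaussian read noise, and clipping to the declared bit depth. The same
#' spec and seed always produce a bit-identical scene.
#'
#' @param spec a `SceneSpec`.
#' @return `list(scene = ImageStack with channels dna/A/B,
#'   truth = GroundTruth)`. The ground truth records nucleus geometry, every
#'   planted focus (position, sigma, amplitude, nucleus label), the
#'   A-B colocalized pairs, and the pan-nuclear nucleus labels.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "SceneSpec"))
  withr::with_seed(spec$seed, {
    truth <- sample_truth(spec)
    scene <- render_scene(spec, truth)
    list(scene = scene, truth = truth)
  })
}

#' Generate a repair-kinetics timecourse of scenes
#'
#' Samples one base scene, then for each later timepoint independently
#' retains each planted channel-A focus with the given retention
#' probability, emulating focus loss as double-strand breaks are repaired.
#' Channel-B duplicates of dropped foci are dropped with them; independent
#' channel-B foci persist. Each timepoint is re-rendered with fresh noise.
#'
#' @param base_spec a `SceneSpec` describing the scene at the reference time.
#' @param timepoints numeric vector of times (hours), increasing.
#' @param retention named numeric vector/list mapping each timepoint (as
#'   character) to a retention fraction in `[0, 1]`; the first timepoint
#'   must have retention 1.
#' @param seed integer seed for the survival draws and noise.
#' @return A list with one element per timepoint:
#'   `list(time_h, scene, truth)`.
#' @export
generate_timecourse <- function(base_spec, timepoints, retention,
                                seed = base_spec$seed) {
  stopifnot(inherits(base_spec, "SceneSpec"))
  ret <- unlist(retention)[as.character(timepoints)]
  if (anyNA(ret))
    stop("retention must name every timepoint")
  if (any(ret < 0 | ret > 1))
    stop("retention values must lie in [0, 1]")
  if (ret[1] != 1)
    stop("retention at the first timepoint must be 1")

  truth0 <- withr::with_seed(seed, sample_truth(base_spec))
  lapply(seq_along(timepoints), function(i) {
    withr::with_seed(seed + 7919L * i, {
      keep <- stats::runif(nrow(truth0$foci_A)) <= ret[i]
      tr <- truth0
      kept_ids <- truth0$foci_A$id[keep]
      tr$foci_A <- truth0$foci_A[keep, , drop = FALSE]
      dropB <- !is.na(tr$foci_B$paired_with) &
        !(tr$foci_B$paired_with %in% kept_ids)
      tr$foci_B <- tr$foci_B[!dropB, , drop = FALSE]
      tr$colocalized_pairs <-
        tr$colocalized_pairs[tr$colocalized_pairs$focus_A %in% kept_ids, ,
                             drop = FALSE]
      list(time_h = timepoints[i], scene = render_scene(base_spec, tr),
           truth = tr)
    })
  })
}

#' Write a ground-truth focus table as CSV
#'
#' One row per planted focus in either channel: focus id, channel, nucleus
#' label, centre (row, col), sigma, and whether it belongs to a planted
#' colocalized pair.
#'
#' @param truth a `GroundTruth`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  a <- truth$foci_A
  a$channel <- rep("A", nrow(a))
  b <- truth$foci_B
  b$channel <- rep("B", nrow(b))
  b$colocalized <- !is.na(b$paired_with)
  cols <- c("id", "channel", "nucleus", "row", "col", "sigma", "colocalized")
  utils::write.csv(rbind(a[cols], b[cols]), path, row.names = FALSE)
  invisible(path)
}
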