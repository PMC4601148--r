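#' Flag pan-nuclear (densely stained) nuclei
#'
#' Apoptotic-type cells show homogeneous high signal across the whole
#' nucleus instead of discrete foci and must be excluded from focus
#' counting. A nucleus is flagged when the fraction of its area above an
#' image-wide intensity cutoff exceeds `coverage_cutoff`. The cutoff is
#' `background + threshold * (max - background)` computed over ALL in-mask
#' pixels of the image: a per-nucleus relative cutoff would be blind to
#' uniform staining (inside such a nucleus max equals min).
#'
#' @param channel 2-D intensity matrix (maximal projection).
#' @param mask a `NucleusMask`.
#' @param coverage_cutoff fraction in (0, 1); default 0.5.
#' @param threshold fraction of the image-wide in-mask dynamic range.
#' @return Named logical vector, one element per nucleus label.
#' @export
flag_pan_nuclear <- function(channel, mask, coverage_cutoff = 0.5,
                             threshold = 0.5) {
  stopifnot(inherits(mask, "NucleusMask"),
            all(dim(channel) == dim(mask$labels)))
  if (!(coverage_cutoff > 0 && coverage_cutoff < 1))
    stop("'coverage_cutoff' must lie in (0, 1)")
  lab <- mask$labels
  flags <- stats::setNames(logical(mask$n_nuclei),
                           as.character(seq_len(mask$n_nuclei)))
  if (mask$n_nuclei == 0L) return(flags)
  vals <- channel[lab > 0L]
  bg <- min(vals)
  cutoff <- bg + threshold * (max(vals) - bg)
  if (max(vals) == bg) return(flags)  # contrast-free image: nothing to flag
  for (k in seq_len(mask$n_nuclei)) {
    sel <- lab == k
    flags[k] <- mean(channel[sel] > cutoff) > coverage_cutoff
  }
  flags
}

#' Detect and measure foci within each nucleus
#'
#' Per nucleus, the channel is binarized at
#' `background + threshold * (max - background)` where background and max
#' are the minimum and maximum intensity inside that nucleus (so detection
#' is invariant under rescaling the whole image); 8-connected components of
#' the suprathreshold pixels are candidate foci; components with projected
#' area below `min_area_px` pixels (default 3, i.e. 0.24 um^2 at 0.285 um
#' pixels) are discarded as noise. Pan-nuclear nuclei are flagged via
#' [flag_pan_nuclear()] and excluded: they contribute no focus records and
#' their focus count is `NA`.
#'
#' When several images of one experiment series must share a single
#' threshold — the original protocol applied "the same thresholds for all
#' images" — derive an absolute cutoff from the reference image with
#' [series_cutoff()] and pass it as `absolute_cutoff`; the per-nucleus
#' relative rule is then bypassed. This also avoids the failure mode of
#' relative thresholding on a nucleus that has lost all its foci, where
#' the threshold would fall inside the noise band.
#'
#' @param channel 2-D intensity matrix (maximal projection).
#' @param mask a `NucleusMask`.
#' @param pixel_size pixel edge in micrometres, for area conversion.
#' @param threshold fraction in (0, 1) of the per-nucleus dynamic range.
#' @param min_area_px noise floor in pixels (components below are dropped).
#' @param pan_coverage_cutoff passed to [flag_pan_nuclear()].
#' @param absolute_cutoff intensity value; when given, pixels strictly
#'   above it are foreground in every nucleus and `threshold` is ignored
#'   for binarization (it still parameterizes the pan-nuclear flag).
#' @return list with `records` (data.frame: `nucleus_label`, `area_px`,
#'   `area_um2`, `centroid_row`, `centroid_col`, `mean_intensity`) and
#'   `summaries` (data.frame: `nucleus_label`, `focus_count`,
#'   `pan_nuclear`, `excluded`).
#' @export
detect_foci <- function(channel, mask, pixel_size, threshold = 0.5,
                        min_area_px = 3L, pan_coverage_cutoff = 0.5,
                        absolute_cutoff = NULL) {
  stopifnot(inherits(mask, "NucleusMask"))
  if (!all(dim(channel) == dim(mask$labels)))
    stop("channel and mask shapes differ")
  if (!(threshold > 0 && threshold < 1))
    stop("'threshold' must lie in (0, 1)")
  stopifnot(pixel_size > 0)

  pan <- flag_pan_nuclear(channel, mask, pan_coverage_cutoff, threshold)
  lab <- mask$labels
  recs <- list()
  summ <- vector("list", mask$n_nuclei)
  for (k in seq_len(mask$n_nuclei)) {
    if (pan[k]) {
      summ[[k]] <- data.frame(nucleus_label = k, focus_count = NA_integer_,
                              pan_nuclear = TRUE, excluded = TRUE)
      next
    }
    sel <- lab == k
    vals <- channel[sel]
    if (is.null(absolute_cutoff)) {
      bg <- min(vals)
      cutoff <- bg + threshold * (max(vals) - bg)
    } else {
      cutoff <- absolute_cutoff
    }
    bw <- matrix(FALSE, nrow(channel), ncol(channel))
    bw[sel] <- channel[sel] > cutoff
    flab <- label_components(bw, connectivity = 8L)
    nfoci <- 0L
    if (max(flab) > 0L) {
      fareas <- tabulate(flab[flab > 0L])
      keep <- which(fareas >= min_area_px)
      nfoci <- length(keep)
      if (nfoci) {
        idx <- which(flab > 0L, arr.ind = TRUE)
        fl <- flab[flab > 0L]
        ok <- fl %in% keep
        idx <- idx[ok, , drop = FALSE]; fl <- fl[ok]
        inten <- channel[cbind(idx[, 1L], idx[, 2L])]
        recs[[length(recs) + 1L]] <- data.frame(
          nucleus_label = k,
          area_px = as.integer(fareas[keep]),
          area_um2 = fareas[keep] * pixel_size^2,
          centroid_row = as.vector(tapply(idx[, 1L], fl, mean)),
          centroid_col = as.vector(tapply(idx[, 2L], fl, mean)),
          mean_intensity = as.vector(tapply(inten, fl, mean)))
      }
    }
    summ[[k]] <- data.frame(nucleus_label = k, focus_count = nfoci,
                            pan_nuclear = FALSE, excluded = FALSE)
  }
  records <- if (length(recs)) do.call(rbind, recs)
             else data.frame(nucleus_label = integer(0), area_px = integer(0),
                             area_um2 = numeric(0), centroid_row = numeric(0),
                             centroid_col = numeric(0),
                             mean_intensity = numeric(0))
  rownames(records) <- NULL
  list(records = records, summaries = do.call(rbind, summ))
}

#' Series-wide segmentation cutoff from a reference image
#'
#' Returns `background + threshold * (max - background)` computed over the
#' in-mask pixels of the whole image (background = in-mask minimum). Use
#' the value as `absolute_cutoff` in [detect_foci()] for every image of
#' the same experiment series, so all timepoints are segmented with one
#' fixed threshold.
#'
#' @param channel 2-D intensity matrix of the reference image.
#' @param mask a `NucleusMask`.
#' @param threshold fraction in (0, 1) of the in-mask dynamic range.
#' @return Intensity cutoff (scalar).
#' @export
series_cutoff <- function(channel, mask, threshold = 0.5) {
  stopifnot(inherits(mask, "NucleusMask"),
            all(dim(channel) == dim(mask$labels)),
            threshold > 0, threshold < 1)
  vals <- channel[mask$labels > 0L]
  if (!length(vals)) stop("empty nucleus mask")
  min(vals) + threshold * (max(vals) - min(vals))
}

#' Histogram of projected focus areas (PAF)
#'
#' Bins focus areas into half-open 0.1-um^2 bins starting at 0.2 um^2
#' (so the 0.24 um^2 noise floor falls in the first bin), with a final
#' open bin for areas at or above `overflow_at`. Areas below the first bin
#' edge, possible at very small pixel sizes, are collected in an underflow
#' bin. Reports counts, fractions, the peak bin, and the mean area.
#'
#' @param areas_um2 numeric vector of focus areas, or the `records`
#'   data.frame from [detect_foci()].
#' @param bin_width bin width in um^2.
#' @param start first bin edge in um^2.
#' @param overflow_at lower edge of the open top bin in um^2.
#' @return list with `table` (data.frame: `bin_low`, `bin_high` (`Inf` for
#'   the top bin), `count`, `fraction`), `peak_bin` (`c(low, high)` of the
#'   most-populated bin, ties to the smaller), `mean_um2`, and `n`. Empty
#'   input gives an empty table and `mean_um2 = NA`.
#' @export
paf_histogram <- function(areas_um2, bin_width = 0.1, start = 0.2,
                          overflow_at = 5.0) {
  if (is.data.frame(areas_um2)) areas_um2 <- areas_um2$area_um2
  stopifnot(bin_width > 0, start >= 0, overflow_at > start)
  edges <- seq(start, overflow_at, by = bin_width)
  lows <- c(if (start > 0) 0, edges)
  highs <- c(if (start > 0) start, edges[-1], Inf)
  n <- length(areas_um2)
  if (n == 0L) {
    return(list(table = data.frame(bin_low = numeric(0),
                                   bin_high = numeric(0),
                                   count = integer(0), fraction = numeric(0)),
                peak_bin = c(NA_real_, NA_real_), mean_um2 = NA_real_, n = 0L))
  }
  counts <- vapply(seq_along(lows), function(i)
    sum(areas_um2 >= lows[i] & areas_um2 < highs[i]), integer(1))
  tab <- data.frame(bin_low = lows, bin_high = highs, count = counts,
                    fraction = counts / n)
  peak <- which.max(tab$count)
  list(table = tab, peak_bin = c(tab$bin_low[peak], tab$bin_high[peak]),
       mean_um2 = mean(areas_um2), n = n)
}

#' Mean focus count per nucleus with standard error
#'
#' Arithmetic mean of focus counts over included nuclei, with the standard
#' error of the mean (`sd / sqrt(n)`) and its tripled value for plotting
#' with +/- 3 SE error bars. Pan-nuclear (excluded) nuclei are omitted by
#' default.
#'
#' @param summaries data.frame from [detect_foci()].
#' @param exclude_flagged drop nuclei with `excluded = TRUE` (default).
#' @return list: `mean`, `se`, `se3`, `n`. `se` is `NA` (with a warning)
#'   when fewer than two nuclei are included.
#' @export
mean_foci_per_nucleus <- function(summaries, exclude_flagged = TRUE) {
  x <- summaries
  if (exclude_flagged) x <- x[!x$excluded, , drop = FALSE]
  counts <- x$focus_count[!is.na(x$focus_count)]
  n <- length(counts)
  if (n < 2L) {
    warning("fewer than 2 included nuclei; SE undefined")
    return(list(mean = if (n) mean(counts) else NA_real_, se = NA_real_,
                se3 = NA_real_, n = n))
  }
  se <- stats::sd(counts) / sqrt(n)
  list(mean = mean(counts), se = se, se3 = 3 * se, n = n)
}
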