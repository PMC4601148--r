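#' Pearson colocalization coefficient over a masked region
#'
#' Mean-centred pixel-intensity correlation between two channels,
#' `Rr = sum((a - mean(a)) * (b - mean(b))) /
#'  sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))`,
#' over the in-mask pixels. Values near 1 indicate reliable
#' colocalization; the range is `[-1, 1]`. A channel that is constant
#' within the mask makes the coefficient undefined: `NA` is returned
#' (flagged, never silently zero).
#'
#' @param a,b equal-shape numeric matrices.
#' @param mask logical matrix selecting the region (e.g. one nucleus), or
#'   `NULL` for the whole image.
#' @return `Rr`, or `NA_real_` when undefined.
#' @export
pearson_rr <- function(a, b, mask = NULL) {
  v <- masked_pair(a, b, mask)
  if (length(v$a) < 2L) return(NA_real_)
  da <- v$a - mean(v$a); db <- v$b - mean(v$b)
  den <- sqrt(sum(da^2) * sum(db^2))
  if (den == 0) return(NA_real_)
  sum(da * db) / den
}

#' Manders overlap coefficient over a masked region
#'
#' Non-centred normalized intensity product
#' `R = sum(a * b) / sqrt(sum(a^2) * sum(b^2))` over in-mask pixels.
#' `R = 0` means no colocalization, `R = 1` perfect colocalization. A
#' channel with zero energy in the mask makes `R` undefined (`NA`).
#'
#' @inheritParams pearson_rr
#' @return `R` in `[0, 1]`, or `NA_real_` when undefined.
#' @export
manders_overlap <- function(a, b, mask = NULL) {
  v <- masked_pair(a, b, mask)
  if (!length(v$a)) return(NA_real_)
  den <- sqrt(sum(v$a^2) * sum(v$b^2))
  if (den == 0) return(NA_real_)
  sum(v$a * v$b) / den
}

#' Manders split coefficients M1 and M2
#'
#' `M1` is the fraction of channel-A intensity found at pixels where
#' channel B is above zero, and `M2` the converse. Zero intensity
#' thresholds are used.
#'
#' @inheritParams pearson_rr
#' @return `c(M1, M2)`, `NA` where the corresponding channel has zero
#'   total intensity.
#' @export
manders_split <- function(a, b, mask = NULL) {
  v <- masked_pair(a, b, mask)
  sa <- sum(v$a); sb <- sum(v$b)
  c(M1 = if (sa > 0) sum(v$a[v$b > 0]) / sa else NA_real_,
    M2 = if (sb > 0) sum(v$b[v$a > 0]) / sb else NA_real_)
}

masked_pair <- function(a, b, mask) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
  if (is.null(mask)) return(list(a = as.vector(a), b = as.vector(b)))
  stopifnot(all(dim(mask) == dim(a)))
  sel <- mask > 0
  list(a = a[sel], b = b[sel])
}

# per-nucleus coefficients on already-available matrices; shared by
# coloc_per_nucleus and plateau_check
coloc_per_nucleus_mats <- function(channelA, channelB, mask, params,
                                   raw = FALSE) {
  stopifnot(inherits(mask, "NucleusMask"))
  if (mask$n_nuclei == 0L) stop("empty nucleus mask")
  if (raw) {
    segA <- channelA; segB <- channelB
  } else {
    segA <- dog_segment(channelA, params, mask)
    segB <- dog_segment(channelB, params, mask)
  }
  lab <- mask$labels
  out <- do.call(rbind, lapply(seq_len(mask$n_nuclei), function(k) {
    sel <- lab == k
    rr <- pearson_rr(segA, segB, sel)
    r <- manders_overlap(segA, segB, sel)
    m <- manders_split(segA, segB, sel)
    data.frame(nucleus_label = k, Rr = rr, R = r, M1 = m[["M1"]],
               M2 = m[["M2"]], n_pixels = sum(sel),
               undefined = is.na(rr) || is.na(r))
  }))
  rownames(out) <- NULL
  out
}

#' Per-nucleus colocalization of a channel pair
#'
#' Runs the full colocalization procedure on one scene: each channel is
#' DoG-enhanced (clipped, normalized, zeroed outside the nucleus mask),
#' then Pearson `Rr`, Manders overlap `R`, and split coefficients `M1`/`M2`
#' are computed over each nucleus separately — one coefficient set per
#' cell, matching the per-cell-then-group-mean reporting convention.
#' Nuclei with undefined coefficients (constant or zero-energy channels)
#' are flagged in the `undefined` column and should be excluded from group
#' summaries.
#'
#' @param stack a 2-D `ImageStack` (project z first).
#' @param mask a `NucleusMask` for the scene.
#' @param channel_pair two channel names, e.g. `c("A", "B")`.
#' @param params a [dog_params()] object.
#' @param raw if `TRUE`, compute coefficients on raw intensities instead of
#'   DoG-enhanced images (for comparison only).
#' @return data.frame: `nucleus_label`, `Rr`, `R`, `M1`, `M2`, `n_pixels`,
#'   `undefined`.
#' @export
coloc_per_nucleus <- function(stack, mask, channel_pair = c("A", "B"),
                              params = dog_params(), raw = FALSE) {
  stopifnot(inherits(stack, "ImageStack"), length(channel_pair) == 2L)
  missing_ch <- setdiff(channel_pair, stack$channel_names)
  if (length(missing_ch))
    stop("channel(s) not in stack: ", paste(missing_ch, collapse = ", "))
  coloc_per_nucleus_mats(get_channel(stack, channel_pair[1]),
                         get_channel(stack, channel_pair[2]),
                         mask, params, raw = raw)
}

#' Group summary of colocalization coefficients
#'
#' Arithmetic mean and standard error of `Rr` and `R` per group, over
#' nuclei with defined coefficients. Undefined nuclei are counted in
#' `n_undefined` so exclusions are visible rather than silent.
#'
#' @param results data.frame as from [coloc_per_nucleus()], plus a grouping
#'   column.
#' @param group name of the grouping column (default `"group"`).
#' @return data.frame: group, `n`, `n_undefined`, `Rr_mean`, `Rr_se`,
#'   `R_mean`, `R_se`. SE is `NA` (with a warning) for groups with n < 2.
#' @export
summarize_coloc <- function(results, group = "group") {
  stopifnot(group %in% names(results))
  se <- function(x) stats::sd(x) / sqrt(length(x))
  out <- do.call(rbind, lapply(split(results, results[[group]]), function(g) {
    ok <- !g$undefined
    n <- sum(ok)
    if (n < 2L) warning("group '", g[[group]][1], "' has n < 2; SE undefined")
    data.frame(group = g[[group]][1], n = n, n_undefined = sum(!ok),
               Rr_mean = mean(g$Rr[ok]), Rr_se = if (n >= 2) se(g$Rr[ok]) else NA_real_,
               R_mean = mean(g$R[ok]), R_se = if (n >= 2) se(g$R[ok]) else NA_real_)
  }))
  rownames(out) <- NULL
  names(out)[1] <- group
  out
}
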