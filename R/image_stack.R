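#' Multichannel image stack with pixel-size metadata
#'
#' An `ImageStack` bundles a multichannel (optionally z-stacked) intensity
#' array with the acquisition metadata every downstream stage needs: square
#' pixel size in micrometres, channel names, optional z-step, and bit depth.
#' Array layout is `(row, col, channel)` for 2-D data and
#' `(row, col, channel, z)` for z-series; coordinates are row-major with
#' pixel centres at integer positions.
#'
#' @param data numeric array, `(row, col, channel[, z])`. A plain matrix is
#'   promoted to a single-channel 2-D stack.
#' @param channel_names character vector, one name per channel.
#' @param pixel_size pixel edge length in micrometres (square pixels).
#' @param z_step z spacing in micrometres, or `NULL` for 2-D stacks.
#' @param bit_depth 8 or 16; intensities must lie in `[0, 2^bit_depth - 1]`.
#' @return An object of class `ImageStack`.
#' @export
image_stack <- function(data, channel_names, pixel_size, z_step = NULL,
                        bit_depth = 16L) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  nd <- length(dim(data))
  if (nd < 3L || nd > 4L)
    stop("'data' must have dimensions (row, col, channel[, z])")
  if (length(channel_names) != dim(data)[3L])
    stop("length(channel_names) must equal the number of channels")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (micrometres)")
  if (!bit_depth %in% c(8L, 16L)) stop("'bit_depth' must be 8 or 16")
  maxval <- 2^bit_depth - 1
  if (min(data) < 0 || max(data) > maxval)
    stop("intensities outside declared bit depth [0, ", maxval, "]")
  if (nd == 3L) z_step <- NULL
  structure(
    list(data = data, channel_names = as.character(channel_names),
         pixel_size = pixel_size, z_step = z_step,
         bit_depth = as.integer(bit_depth)),
    class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat("ImageStack: ", d[1L], " x ", d[2L], " px, ",
      d[3L], " channel(s) [", paste(x$channel_names, collapse = ", "), "]",
      if (has_z(x)) paste0(", ", d[4L], " z-slices") else "",
      "\n  pixel size ", x$pixel_size, " um, ", x$bit_depth, "-bit\n",
      sep = "")
  invisible(x)
}

#' @rdname image_stack
#' @param stack an `ImageStack`.
#' @export
has_z <- function(stack) length(dim(stack$data)) == 4L

#' Extract one channel of a 2-D stack as a matrix
#'
#' @param stack an `ImageStack` without a z axis (project first).
#' @param channel channel name or index.
#' @return Intensity matrix `(row, col)`.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "ImageStack"))
  if (has_z(stack)) stop("stack has a z axis; apply max_project() first")
  idx <- if (is.character(channel)) match(channel, stack$channel_names)
         else as.integer(channel)
  if (is.na(idx) || idx < 1L || idx > dim(stack$data)[3L])
    stop("unknown channel: ", channel)
  stack$data[, , idx]
}

#' Maximum-intensity projection over z
#'
#' Collapses a z-series to a single 2-D image per channel by taking the
#' per-pixel maximum across slices — the standard projection applied to
#' confocal section series before counting foci. Metadata is preserved
#' except the z step, which no longer applies.
#'
#' @param stack an `ImageStack` with a z axis.
#' @return A 2-D `ImageStack`.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "ImageStack"))
  if (!has_z(stack)) stop("stack has no z axis to project")
  d <- dim(stack$data)
  proj <- apply(stack$data, c(1L, 2L, 3L), max)
  image_stack(proj, stack$channel_names, stack$pixel_size,
              z_step = NULL, bit_depth = stack$bit_depth)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image stack as multi-page TIFF plus metadata sidecar
#'
#' Pages are written channel-fastest (channel 1..C for z1, then z2, ...),
#' matching the usual hyperstack ordering. Because plain baseline TIFF
#' carries no reliable pixel-size field across tools, the pixel size,
#' channel names, z step and bit depth are also written to a plain-text
#' JSON sidecar at `<path>.json`, which [read_stack()] consumes.
#'
#' @param stack an `ImageStack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  maxval <- 2^stack$bit_depth - 1
  d <- dim(stack$data)
  nz <- if (has_z(stack)) d[4L] else 1L
  pages <- vector("list", d[3L] * nz)
  k <- 1L
  for (z in seq_len(nz)) {
    for (ch in seq_len(d[3L])) {
      m <- if (has_z(stack)) stack$data[, , ch, z] else stack$data[, , ch]
      pages[[k]] <- m / maxval
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                  compression = "LZW", reduce = FALSE)
  meta <- list(pixel_size_um = stack$pixel_size,
               channel_names = stack$channel_names,
               z_step_um = stack$z_step,
               bit_depth = stack$bit_depth,
               n_z = nz)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a multi-page TIFF into an ImageStack
#'
#' Pixel size is taken, in order of preference, from the TIFF resolution
#' tags (square pixels required), from a `<path>.json` sidecar written by
#' [write_stack()], or from `pixel_size_override`; if none is available the
#' read fails rather than guessing. Without a sidecar, all pages are
#' treated as channels of a 2-D image.
#'
#' @param path TIFF path.
#' @param pixel_size_override pixel size in micrometres used when the file
#'   itself carries none.
#' @return An `ImageStack`.
#' @export
read_stack <- function(path, pixel_size_override = NULL) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)

  meta <- NULL
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)

  xres <- attr(pages[[1L]], "x.resolution")
  yres <- attr(pages[[1L]], "y.resolution")
  unit <- attr(pages[[1L]], "resolution.unit")
  pixel_size <- NULL
  if (!is.null(xres) && !is.null(unit) && unit %in% c("cm", "inch")) {
    if (!is.null(yres) && abs(xres - yres) > 1e-6 * xres)
      stop("anisotropic pixels (x and y resolution differ); ",
           "square pixels are required")
    per_um <- if (unit == "cm") xres / 1e4 else xres / 25400
    pixel_size <- 1 / per_um
  }
  if (is.null(pixel_size) && !is.null(meta$pixel_size_um))
    pixel_size <- meta$pixel_size_um
  if (is.null(pixel_size)) pixel_size <- pixel_size_override
  if (is.null(pixel_size))
    stop("no pixel size: file carries no resolution tag or sidecar and ",
         "no 'pixel_size_override' was given")

  bit_depth <- attr(pages[[1L]], "bits.per.sample")
  if (is.null(bit_depth)) bit_depth <- if (!is.null(meta)) meta$bit_depth else 16L
  maxval <- 2^bit_depth - 1

  n_pages <- length(pages)
  nz <- if (!is.null(meta$n_z)) meta$n_z else 1L
  n_ch <- n_pages / nz
  if (n_ch != round(n_ch))
    stop("page count ", n_pages, " not divisible by z count ", nz)
  n_ch <- as.integer(n_ch)

  dm <- dim(pages[[1L]])
  arr <- array(0, c(dm[1L], dm[2L], n_ch, nz))
  k <- 1L
  for (z in seq_len(nz)) for (ch in seq_len(n_ch)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1L]  # collapse grey-as-RGB
    arr[, , ch, z] <- round(pg * maxval)
    k <- k + 1L
  }
  if (nz == 1L) dim(arr) <- dm <- c(dm[1L], dm[2L], n_ch)

  ch_names <- if (!is.null(meta$channel_names)) meta$channel_names
              else paste0("ch", seq_len(n_ch))
  z_step <- if (nz > 1L && !is.null(meta$z_step_um)) meta$z_step_um else NULL
  image_stack(arr, ch_names, pixel_size, z_step = z_step,
              bit_depth = as.integer(bit_depth))
}

#' Read a CSV manifest of images to analyse
#'
#' Expected columns: `path`, `group`, `timepoint_h`, `pixel_size_um`.
#' Relative paths are resolved against the manifest's own directory.
#'
#' @param path CSV file.
#' @return A data.frame with the four columns above.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "group", "timepoint_h", "pixel_size_um")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m[need]
}
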