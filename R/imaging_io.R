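# Core raster containers and stack I/O. Coordinates are 0-based (row y,
# column x) throughout the package; storage is plain R matrices indexed
# [y + 1, x + 1].

#' Construct a single-channel image
#'
#' @param pixels 2-D numeric matrix of intensities in [0, 65535]
#' @param channel_name free-text channel label, e.g. "PGP9.5" or "TRPV1"
#' @param pixel_size_um micrometres per pixel (default 0.16, i.e. 160 nm)
#' @return a `channel_image` object
#' @export
channel_image <- function(pixels, channel_name = "", pixel_size_um = 0.16) {
  stopifnot(is.matrix(pixels), pixel_size_um > 0)
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 65535))
    stop("intensities must lie in [0, 65535]")
  structure(list(pixels = pixels, channel_name = channel_name,
                 pixel_size_um = pixel_size_um),
            class = "channel_image")
}

#' Construct a binary mask
#'
#' @param pixels 2-D logical matrix (nonzero numeric is coerced to TRUE)
#' @param pixel_size_um micrometres per pixel
#' @return a `binary_mask` object
#' @export
binary_mask <- function(pixels, pixel_size_um = 0.16) {
  stopifnot(is.matrix(pixels), pixel_size_um > 0)
  m <- pixels != 0
  storage.mode(m) <- "logical"
  structure(list(pixels = m, pixel_size_um = pixel_size_um),
            class = "binary_mask")
}

#' Construct an image stack
#'
#' @param voxels 3-D (z, y, x) or 4-D (c, z, y, x) array of intensities
#' @param axis_order "ZYX" or "CZYX"
#' @param pixel_size_um micrometres per pixel
#' @param z_step_um z spacing in micrometres
#' @return an `image_stack` object
#' @export
image_stack <- function(voxels, axis_order = c("ZYX", "CZYX"),
                        pixel_size_um = 0.16, z_step_um = 1.0) {
  axis_order <- match.arg(axis_order)
  nd <- length(dim(voxels))
  if (axis_order == "ZYX" && nd != 3L)
    stop("axis_order ZYX requires a 3-D array")
  if (axis_order == "CZYX" && nd != 4L)
    stop("axis_order CZYX requires a 4-D array")
  stopifnot(pixel_size_um > 0, z_step_um > 0)
  if (anyNA(voxels) || any(voxels < 0) || any(voxels > 65535))
    stop("intensities must lie in [0, 65535]")
  structure(list(voxels = voxels, axis_order = axis_order,
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um),
            class = "image_stack")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image '%s' %dx%d px, %.3f um/px>\n",
              x$channel_name, nrow(x$pixels), ncol(x$pixels),
              x$pixel_size_um))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %dx%d px, %d true, %.3f um/px>\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              x$pixel_size_um))
  invisible(x)
}

#' Load a TIFF z-stack
#'
#' Reads a single- or multi-page grayscale TIFF into an image stack.
#' For `"CZYX"` the pages are assumed channel-fastest: page index
#' `c + z * n_channels` (channels interleaved within each z plane),
#' the ImageJ hyperstack default ordering.
#'
#' @param path readable TIFF file
#' @param axis_order "ZYX" (one channel) or "CZYX"
#' @param pixel_size_um micrometres per pixel
#' @param n_channels number of channels (required for "CZYX")
#' @param z_step_um z spacing in micrometres
#' @return an `image_stack`; intensities are preserved bit-exactly
#' @export
load_stack <- function(path, axis_order = c("ZYX", "CZYX"),
                       pixel_size_um = 0.16, n_channels = 1L,
                       z_step_um = 1.0) {
  axis_order <- match.arg(axis_order)
  pages <- read_tiff(path)
  np <- length(pages)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("pages have inconsistent shapes")
  h <- dims[1, 1]; w <- dims[2, 1]
  if (axis_order == "ZYX") {
    if (n_channels != 1L)
      stop("axis_order ZYX implies a single channel")
    vox <- array(0, dim = c(np, h, w))
    for (z in seq_len(np)) vox[z, , ] <- pages[[z]]
  } else {
    if (np %% n_channels != 0L)
      stop("page count ", np, " not divisible by n_channels ", n_channels)
    nz <- np %/% n_channels
    vox <- array(0, dim = c(n_channels, nz, h, w))
    for (z in seq_len(nz)) for (ch in seq_len(n_channels))
      vox[ch, z, , ] <- pages[[(z - 1L) * n_channels + ch]]
  }
  image_stack(vox, axis_order, pixel_size_um, z_step_um)
}

#' Maximum-intensity projection
#'
#' Collapses the z axis by taking, per pixel and channel, the maximum
#' intensity over all slices. All downstream quantification operates on
#' these projections.
#'
#' @param stack an `image_stack`
#' @param channel_names optional character vector naming the channels
#' @return a list of `channel_image`, one per channel
#' @export
max_project <- function(stack, channel_names = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$axis_order == "ZYX") {
    chans <- list(apply(stack$voxels, c(2, 3), max))
  } else {
    nc <- dim(stack$voxels)[1]
    chans <- lapply(seq_len(nc), function(ch)
      apply(stack$voxels[ch, , , , drop = FALSE][1, , , ], c(2, 3), max))
  }
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_along(chans) - 1L)
  stopifnot(length(channel_names) == length(chans))
  mapply(function(px, nm)
    channel_image(px, nm, stack$pixel_size_um),
    chans, channel_names, SIMPLIFY = FALSE)
}

#' Read a binary mask from TIFF or PNG
#'
#' Any nonzero pixel is interpreted as TRUE.
#'
#' @param path single-page TIFF or PNG file
#' @param pixel_size_um micrometres per pixel
#' @param reference_shape optional c(height, width) the mask must match
#' @return a `binary_mask`
#' @export
read_mask <- function(path, pixel_size_um = 0.16, reference_shape = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L) px <- px[, , 1]
    m <- px != 0
  } else {
    pages <- read_tiff(path)
    if (length(pages) != 1L) stop("mask TIFF must be single-page")
    m <- pages[[1]] != 0
  }
  storage.mode(m) <- "logical"
  if (!is.null(reference_shape) &&
      !identical(dim(m), as.integer(reference_shape)))
    stop(sprintf("mask shape %dx%d does not match reference %dx%d",
                 nrow(m), ncol(m), reference_shape[1], reference_shape[2]))
  binary_mask(m, pixel_size_um)
}

#' Write a binary mask as an 8-bit TIFF (0 / 255)
#'
#' @param mask a `binary_mask` or logical matrix
#' @param path output path
#' @return `path`, invisibly
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "binary_mask")) mask$pixels else mask
  stopifnot(is.matrix(m))
  write_tiff(matrix(ifelse(m != 0, 255L, 0L), nrow(m), ncol(m)),
             path, bits = 8L)
  invisible(path)
}

# internal: coerce channel_image / matrix to matrix
.as_pixels <- function(x) {
  if (inherits(x, "channel_image")) x$pixels
  else if (inherits(x, "binary_mask")) x$pixels
  else if (is.matrix(x)) x
  else stop("expected a matrix, channel_image or binary_mask")
}
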