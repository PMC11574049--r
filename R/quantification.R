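# Per-image quantification: punctum count, mean fluorescence intensity
# (MFI, in AU) over the fiber mask, and fiber area in square micrometres.

#' Mean fluorescence intensity over a mask
#'
#' Arithmetic mean of the channel intensities over all true mask pixels.
#'
#' @param channel `channel_image` or matrix
#' @param mask `binary_mask` or logical matrix, same shape
#' @return scalar MFI in AU
#' @export
measure_mfi <- function(channel, mask) {
  img <- .as_pixels(channel)
  m <- .as_pixels(mask)
  if (!identical(dim(img), dim(m)))
    stop("channel and mask shapes differ")
  if (!any(m)) stop("empty fiber mask")
  mean(img[m])
}

#' Fiber area in square micrometres
#'
#' @param mask a `binary_mask` (or logical matrix plus `pixel_size_um`)
#' @param pixel_size_um used only when `mask` is a bare matrix
#' @return true-pixel count times pixel_size_um squared
#' @export
measure_area <- function(mask, pixel_size_um = NULL) {
  if (inherits(mask, "binary_mask")) {
    px_um <- mask$pixel_size_um
    m <- mask$pixels
  } else {
    if (is.null(pixel_size_um)) stop("pixel_size_um required")
    px_um <- pixel_size_um
    m <- mask != 0
  }
  stopifnot(px_um > 0)
  sum(m) * px_um^2
}

#' Quantify one image
#'
#' Runs mask-restricted maxima detection on the puncta channel, then MFI
#' and fiber area, and assembles one record (the row type of a
#' per-image, per-method results table).
#'
#' @param trpv1 puncta channel (`channel_image`)
#' @param seg a `segmentation_result` (or `binary_mask` used directly)
#' @param threshold detection threshold in AU (default 200)
#' @param method method label, e.g. "rf", "external", "manual"
#' @param image_id image label
#' @param connectivity maxima connectivity (default 8)
#' @return one-row data.frame: image_id, method, n_puncta, mfi_au,
#'   fiber_area_um2, threshold, pixel_size_um
#' @export
quantify_image <- function(trpv1, seg, threshold = 200, method = "rf",
                           image_id = "", connectivity = 8L) {
  mask <- if (inherits(seg, "segmentation_result")) seg$mask
          else if (inherits(seg, "binary_mask")) seg
          else binary_mask(.as_pixels(seg))
  px_um <- if (inherits(trpv1, "channel_image")) trpv1$pixel_size_um
           else mask$pixel_size_um
  spots <- detect_maxima(trpv1, mask, threshold, connectivity, image_id)
  mfi <- measure_mfi(trpv1, mask)
  area <- sum(mask$pixels) * px_um^2
  data.frame(image_id = image_id, method = method,
             n_puncta = nrow(spots$spots), mfi_au = mfi,
             fiber_area_um2 = area, threshold = threshold,
             pixel_size_um = px_um, stringsAsFactors = FALSE)
}

# resolve a manifest argument: list (from generate_dataset) or a path to
# manifest.json
.resolve_manifest <- function(manifest) {
  if (is.character(manifest)) {
    path <- manifest
    if (dir.exists(path)) path <- file.path(path, "manifest.json")
    if (!file.exists(path)) stop("manifest not found: ", path)
    m <- jsonlite::read_json(path)
    m$dir <- dirname(path)
    m
  } else manifest
}

#' Quantify a whole dataset
#'
#' One record per image and backend. Backends are named list entries:
#' the string `"truth"` (use the dataset's ground-truth mask — the
#' external-mask branch), a `pixel_classifier`, or a function
#' `(image_id, pgp95_channel) -> segmentation_result / binary_mask`.
#' Per-image failures are logged as warnings and the batch continues.
#'
#' @param manifest dataset manifest (list or path to `manifest.json`)
#' @param backends named list of backends; names become method labels
#' @param threshold detection threshold in AU (default 200)
#' @param out_csv optional path; the table is written deterministically
#' @return data.frame of records; failures in `attr(, "failures")`
#' @export
quantify_batch <- function(manifest, backends, threshold = 200,
                           out_csv = NULL) {
  m <- .resolve_manifest(manifest)
  stopifnot(is.list(backends), length(backends) >= 1L,
            !is.null(names(backends)))
  rows <- list()
  failures <- character(0)
  for (im in m$images) {
    rec <- tryCatch({
      px_um <- as.numeric(im$pixel_size_um)
      trp_px <- read_tiff(file.path(m$dir, im$trpv1))[[1]]
      trpv1 <- channel_image(trp_px, "TRPV1", px_um)
      pgp <- channel_image(read_tiff(file.path(m$dir, im$pgp95))[[1]],
                           "PGP9.5", px_um)
      truth <- read_mask(file.path(m$dir, im$truth_mask), px_um)
      out <- lapply(names(backends), function(nm) {
        b <- backends[[nm]]
        seg <- if (identical(b, "truth")) truth
          else if (inherits(b, "pixel_classifier")) segment(pgp, b)
          else if (inherits(b, "external_mask_backend")) segment(pgp, b)
          else if (is.function(b)) b(im$id, pgp)
          else stop("unknown backend: ", nm)
        quantify_image(trpv1, seg, threshold, nm, im$id)
      })
      do.call(rbind, out)
    }, error = function(e) {
      failures <<- c(failures,
                     sprintf("%s: %s", im$id, conditionMessage(e)))
      NULL
    })
    if (!is.null(rec)) rows[[length(rows) + 1L]] <- rec
  }
  for (f in failures) warning("quantification failed for ", f,
                              call. = FALSE)
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(0), method = character(0),
               n_puncta = integer(0), mfi_au = numeric(0),
               fiber_area_um2 = numeric(0), threshold = numeric(0),
               pixel_size_um = numeric(0))
  rownames(tab) <- NULL
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  attr(tab, "failures") <- failures
  tab
}
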