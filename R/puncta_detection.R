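# Mask-restricted punctum detection: local intensity maxima strictly above
# a threshold (default 200 AU), counted only where the reported maximum
# pixel lies inside the nerve-fiber mask. Plateaus (connected regions of
# equal intensity strictly above all outside neighbors) are reported once.

.spot_list <- function(df, image_id, threshold, params) {
  rownames(df) <- NULL
  structure(list(spots = df, image_id = image_id, threshold = threshold,
                 params = params),
            class = "spot_list")
}

#' @export
print.spot_list <- function(x, ...) {
  cat(sprintf("<spot_list '%s': %d spots, threshold %g>\n",
              x$image_id, nrow(x$spots), x$threshold))
  invisible(x)
}

#' Number of detected spots
#' @param x a `spot_list`
#' @param ... unused
#' @export
length.spot_list <- function(x) nrow(x$spots)

.check_detect_args <- function(channel, mask, threshold, connectivity) {
  img <- .as_pixels(channel)
  m <- .as_pixels(mask)
  if (!identical(dim(img), dim(m)))
    stop("channel and mask shapes differ")
  stopifnot(threshold >= 0, connectivity %in% c(4L, 8L))
  list(img = img, mask = m)
}

.filter_spots <- function(cand, m, threshold) {
  # cand: matrix with columns y, x, value (0-based coords)
  if (nrow(cand) == 0L)
    return(data.frame(y = integer(0), x = integer(0),
                      intensity = numeric(0), in_mask = logical(0)))
  keep <- cand[, 3] > threshold &
    m[cbind(cand[, 1] + 1L, cand[, 2] + 1L)]
  cand <- cand[keep, , drop = FALSE]
  data.frame(y = as.integer(cand[, 1]), x = as.integer(cand[, 2]),
             intensity = cand[, 3],
             in_mask = rep(TRUE, nrow(cand)))
}

#' Detect puncta as strict local maxima within a mask
#'
#' A punctum is a pixel strictly greater than all of its neighbors under
#' the chosen connectivity, or a connected plateau of equal values
#' strictly greater than all plateau neighbors, reported once at the
#' plateau's rounded centroid (falling back to the top-left plateau
#' member when the rounded centroid is off-plateau). A candidate is
#' retained iff its intensity is strictly greater than `threshold` and
#' its reported pixel lies inside `mask`. Image borders use only
#' existing neighbors. Spots are ordered row-major by (y, x), 0-based.
#'
#' @param channel `channel_image` or matrix (the puncta channel)
#' @param mask `binary_mask` or logical matrix (the fiber ROI)
#' @param threshold strict intensity threshold in AU (default 200)
#' @param connectivity 4 or 8 (default 8, the ImageJ convention)
#' @param image_id label carried into the result
#' @return a `spot_list`
#' @export
detect_maxima <- function(channel, mask, threshold = 200,
                          connectivity = 8L, image_id = "") {
  a <- .check_detect_args(channel, mask, threshold, connectivity)
  cand <- plateau_maxima(a$img, as.integer(connectivity))
  df <- .filter_spots(cand, a$mask, threshold)
  .spot_list(df, image_id, threshold,
             list(connectivity = connectivity, algorithm = "plateau_fill"))
}

#' Exhaustive reference detector (independent oracle)
#'
#' Same contract as [detect_maxima()], implemented in plain R by direct
#' per-pixel comparison against the neighborhood (with per-pixel plateau
#' flood fill). Deliberately unoptimized; exists so the fast detector can
#' be validated against it.
#'
#' @inheritParams detect_maxima
#' @return a `spot_list`
#' @export
brute_force_maxima <- function(channel, mask, threshold = 200,
                               connectivity = 8L, image_id = "") {
  a <- .check_detect_args(channel, mask, threshold, connectivity)
  img <- a$img
  h <- nrow(img); w <- ncol(img)
  if (connectivity == 4L) {
    offs <- cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1))
    offs <- offs[!(offs[, 1] == 0L & offs[, 2] == 0L), , drop = FALSE]
  }
  res <- NULL
  for (y in seq_len(h)) for (x in seq_len(w)) {
    v <- img[y, x]
    # flood the plateau containing (y, x), checking outside neighbors
    plateau <- matrix(FALSE, h, w)
    plateau[y, x] <- TRUE
    queue <- list(c(y, x))
    is_max <- TRUE
    members <- c(y, x)
    while (length(queue) > 0L) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        ny <- p[1] + offs[k, 1]; nx <- p[2] + offs[k, 2]
        if (ny < 1L || ny > h || nx < 1L || nx > w) next
        nv <- img[ny, nx]
        if (nv > v) is_max <- FALSE
        else if (nv == v && !plateau[ny, nx]) {
          plateau[ny, nx] <- TRUE
          queue <- c(queue, list(c(ny, nx)))
          members <- rbind(members, c(ny, nx))
        }
      }
    }
    members <- matrix(members, ncol = 2)
    # report only from the top-left plateau member, once
    first <- members[order(members[, 1], members[, 2])[1], ]
    if (!is_max || first[1] != y || first[2] != x) next
    cy <- floor(mean(members[, 1]) + 0.5)
    cx <- floor(mean(members[, 2]) + 0.5)
    if (!plateau[cy, cx]) { cy <- first[1]; cx <- first[2] }
    res <- rbind(res, c(cy - 1L, cx - 1L, v))
  }
  if (is.null(res)) res <- matrix(numeric(0), ncol = 3)
  res <- res[order(res[, 1], res[, 2]), , drop = FALSE]
  df <- .filter_spots(res, a$mask, threshold)
  .spot_list(df, image_id, threshold,
             list(connectivity = connectivity, algorithm = "brute_force"))
}

#' Greedy de-duplication of nearby spots
#'
#' Keeps brighter spots first and removes any spot whose Euclidean
#' distance to an already-kept spot is below `min_separation_px`.
#' Ties break by (intensity descending, y, x).
#'
#' @param spots a `spot_list`
#' @param min_separation_px non-negative separation radius
#' @return a `spot_list` (still ordered row-major)
#' @export
spot_filter <- function(spots, min_separation_px) {
  stopifnot(inherits(spots, "spot_list"), min_separation_px >= 0)
  df <- spots$spots
  if (min_separation_px == 0 || nrow(df) <= 1L) return(spots)
  ord <- order(-df$intensity, df$y, df$x)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0L ||
        all((df$y[kept] - df$y[i])^2 + (df$x[kept] - df$x[i])^2 >=
              min_separation_px^2)) kept <- c(kept, i)
  }
  out <- df[sort(kept), , drop = FALSE]
  .spot_list(out, spots$image_id, spots$threshold,
             c(spots$params, list(min_separation_px = min_separation_px)))
}
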