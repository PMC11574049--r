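# Trainable pixel classification of curvilinear fiber structures:
# a multi-scale filter bank (Gaussian, gradient magnitude, Laplacian of
# Gaussian, Hessian eigenvalues, difference of Gaussians) feeding a bagged
# decision-tree ensemble, in the spirit of the classic trainable-Weka-style
# segmentation workflow.

.gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, 0, sigma)
  k / sum(k)
}

# 1-D convolution along rows (axis = 1) or columns (axis = 2) with
# symmetric (edge-duplicating) reflection padding
.conv1 <- function(m, k, axis) {
  r <- (length(k) - 1L) %/% 2L
  if (axis == 2L) return(t(.conv1(t(m), k, 1L)))
  h <- nrow(m)
  idx <- c(pmin(r:1, h), 1:h, pmax(h - seq_len(r) + 1L, 1L))
  pad <- m[idx, , drop = FALSE]
  out <- matrix(0, h, ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * pad[j:(j + h - 1L), , drop = FALSE]
  out
}

.gauss_smooth <- function(m, sigma) {
  k <- .gauss_kernel(sigma)
  .conv1(.conv1(m, k, 1L), k, 2L)
}

# central differences (zero at borders via edge replication)
.diff_y <- function(m) {
  h <- nrow(m)
  (m[c(2:h, h), , drop = FALSE] - m[c(1, 1:(h - 1)), , drop = FALSE]) / 2
}
.diff_x <- function(m) t(.diff_y(t(m)))

#' Compute the multi-scale feature stack of an image
#'
#' For every scale sigma: Gaussian smoothing, gradient magnitude of the
#' smoothed image, Laplacian of Gaussian, the two Hessian eigenvalues
#' (sorted, largest first), and the difference of Gaussians (sigma vs
#' 2*sigma); plus the raw intensities. Derivatives are central differences
#' of the Gaussian-smoothed image, so every derivative-type feature of a
#' constant image is exactly zero.
#'
#' @param image a `channel_image` or numeric matrix
#' @param scales ascending positive smoothing scales in pixels
#' @return a `feature_stack`: list with `features` (3-D array
#'   n_features x height x width), `feature_names`, `source_shape`
#' @export
compute_features <- function(image, scales = c(1, 2, 4, 8, 16)) {
  px <- .as_pixels(image)
  if (!is.matrix(px)) stop("image must be 2-D")
  stopifnot(length(scales) >= 1, all(scales > 0), !is.unsorted(scales))
  h <- nrow(px); w <- ncol(px)
  n_feat <- 6L * length(scales) + 1L
  feats <- array(0, dim = c(n_feat, h, w))
  nms <- character(n_feat)
  feats[1, , ] <- px
  nms[1] <- "raw"
  smooth_cache <- list()
  smooth_at <- function(s) {
    key <- format(s, digits = 12)
    if (is.null(smooth_cache[[key]]))
      smooth_cache[[key]] <<- .gauss_smooth(px, s)
    smooth_cache[[key]]
  }
  f <- 1L
  for (s in scales) {
    g <- smooth_at(s)
    gy <- .diff_y(g); gx <- .diff_x(g)
    gyy <- .diff_y(gy); gxx <- .diff_x(gx); gxy <- .diff_x(gy)
    tr <- gxx + gyy
    disc <- sqrt(pmax((gxx - gyy)^2 + 4 * gxy^2, 0))
    bank <- list(
      gaussian = g,
      gradient = sqrt(gx^2 + gy^2),
      log = tr,
      hessian_e1 = (tr + disc) / 2,
      hessian_e2 = (tr - disc) / 2,
      dog = g - smooth_at(2 * s))
    for (nm in names(bank)) {
      f <- f + 1L
      feats[f, , ] <- bank[[nm]]
      nms[f] <- sprintf("%s_s%g", nm, s)
    }
  }
  structure(list(features = feats, feature_names = nms,
                 source_shape = c(h, w)),
            class = "feature_stack")
}

# feature stack -> (n_pixels x n_features) design matrix, column-major
# pixel order (R matrix order)
.design_matrix <- function(fs) {
  nf <- dim(fs$features)[1]
  h <- fs$source_shape[1]; w <- fs$source_shape[2]
  X <- matrix(0, h * w, nf)
  for (f in seq_len(nf)) X[, f] <- as.vector(fs$features[f, , ])
  colnames(X) <- fs$feature_names
  X
}

#' Train the random-forest pixel classifier
#'
#' Fits a bagged ensemble of Gini decision trees on the feature vectors of
#' labeled pixels only (sparse strokes suffice). Both classes must be
#' represented; a pixel labeled as both fiber and background is an error.
#'
#' @param images list of `channel_image` (or matrices)
#' @param labels list (parallel to `images`) of lists with elements
#'   `fiber` and `background`, each a `binary_mask` or logical matrix of
#'   label strokes
#' @param scales filter-bank scales, see [compute_features()]
#' @param n_trees number of trees (default 100)
#' @param mtry candidate features per split, default floor(sqrt(p))
#' @param min_node minimum samples per leaf
#' @param max_depth maximum tree depth
#' @param seed RNG seed for bootstrap and feature sampling (default 0)
#' @return a `pixel_classifier`
#' @export
train_classifier <- function(images, labels, scales = c(1, 2, 4, 8, 16),
                             n_trees = 100L, mtry = NULL, min_node = 1L,
                             max_depth = 25L, seed = 0L) {
  if (!is.list(images) || !is.list(labels) ||
      length(images) != length(labels))
    stop("images and labels must be parallel lists")
  Xs <- list(); ys <- list()
  for (i in seq_along(images)) {
    px <- .as_pixels(images[[i]])
    fib <- .as_pixels(labels[[i]]$fiber)
    bg <- .as_pixels(labels[[i]]$background)
    if (!identical(dim(px), dim(fib)) || !identical(dim(px), dim(bg)))
      stop("label raster shape mismatch on image ", i)
    if (any(fib & bg))
      stop("pixels labeled as both classes on image ", i)
    fs <- compute_features(px, scales)
    X <- .design_matrix(fs)
    sel <- as.vector(fib) | as.vector(bg)
    Xs[[i]] <- X[sel, , drop = FALSE]
    ys[[i]] <- as.integer(as.vector(fib)[sel])
  }
  X <- do.call(rbind, Xs)
  y <- unlist(ys)
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L)
    stop("class underrepresented: need labeled pixels of both classes")
  p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  forest <- rf_fit(X, y, as.integer(n_trees), as.integer(mtry),
                   as.integer(min_node), as.integer(max_depth),
                   as.integer(seed))
  structure(list(
    forest = forest,
    feature_config = list(scales = scales),
    class_labels = c("background", "fiber"),
    params = list(n_trees = n_trees, mtry = mtry, min_node = min_node,
                  max_depth = max_depth, seed = seed),
    n_train = length(y),
    version = "punctafiber-classifier-1"),
    class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf(
    "<pixel_classifier: %d trees, scales {%s}, %d training pixels>\n",
    x$params$n_trees, paste(x$feature_config$scales, collapse = ","),
    x$n_train))
  invisible(x)
}

#' Predict per-pixel fiber probability
#'
#' The probability is the fraction of trees voting "fiber".
#'
#' @param clf a `pixel_classifier`
#' @param image a `channel_image` or matrix
#' @return numeric matrix of probabilities in [0, 1]
#' @export
predict_probability <- function(clf, image) {
  stopifnot(inherits(clf, "pixel_classifier"))
  px <- .as_pixels(image)
  fs <- compute_features(px, clf$feature_config$scales)
  X <- .design_matrix(fs)
  matrix(rf_predict(clf$forest, X), nrow(px), ncol(px))
}

#' Binarize a probability map
#'
#' Thresholds at `threshold` (inclusive) and removes 8-connected
#' components smaller than `min_object_px`.
#'
#' @param probability numeric matrix in [0, 1]
#' @param threshold inclusive probability cut (default 0.5)
#' @param min_object_px minimum component size kept (default 64)
#' @param pixel_size_um micrometres per pixel for the returned mask
#' @return a `binary_mask`
#' @export
postprocess_mask <- function(probability, threshold = 0.5,
                             min_object_px = 64L, pixel_size_um = 0.16) {
  stopifnot(is.matrix(probability))
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  m <- probability >= threshold
  if (min_object_px > 1L && any(m)) {
    lab <- cc_label(m, 8L)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_object_px)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  binary_mask(m, pixel_size_um)
}

#' External-mask segmentation backend
#'
#' Wraps a precomputed fiber mask (e.g. produced by an outside
#' deep-learning tool) so it can be used wherever a trained classifier
#' can; downstream quantification is identical for both branches.
#'
#' @param mask a `binary_mask` or logical matrix
#' @param name backend label recorded in results
#' @return an `external_mask_backend`
#' @export
external_mask_backend <- function(mask, name = "external") {
  structure(list(mask = mask, name = name),
            class = "external_mask_backend")
}

#' Segment the fiber channel
#'
#' @param image a `channel_image` or matrix
#' @param backend a `pixel_classifier` or an [external_mask_backend()]
#' @param threshold probability threshold for the classifier backend
#' @param min_object_px small-object removal for the classifier backend
#' @return a `segmentation_result`: list with `probability` (matrix),
#'   `mask` (`binary_mask`), `backend_name`
#' @export
segment <- function(image, backend, threshold = 0.5, min_object_px = 64L) {
  px <- .as_pixels(image)
  px_um <- if (inherits(image, "channel_image")) image$pixel_size_um
           else 0.16
  if (inherits(backend, "external_mask_backend")) {
    m <- .as_pixels(backend$mask)
    if (!identical(dim(m), dim(px)))
      stop("external mask shape does not match the image")
    res <- list(probability = m * 1.0,
                mask = binary_mask(m, px_um),
                backend_name = backend$name)
  } else if (inherits(backend, "pixel_classifier")) {
    prob <- predict_probability(backend, px)
    res <- list(probability = prob,
                mask = postprocess_mask(prob, threshold, min_object_px,
                                        px_um),
                backend_name = "rf")
  } else stop("unknown segmentation backend")
  structure(res, class = "segmentation_result")
}

#' Save / load a trained classifier
#'
#' Single-file serialization with the feature configuration embedded, so a
#' loaded classifier refuses images computed under a different config.
#'
#' @param clf a `pixel_classifier`
#' @param path file path
#' @return `path` (save) or the classifier (load)
#' @export
save_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "pixel_classifier"))
  saveRDS(clf, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  clf <- readRDS(path)
  if (!inherits(clf, "pixel_classifier") ||
      !identical(clf$version, "punctafiber-classifier-1"))
    stop("not a punctafiber classifier file: ", path)
  clf
}
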