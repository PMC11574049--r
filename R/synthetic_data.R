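# Seeded synthetic two-channel image generator. Emulates the quantification
# scenario: curvilinear nerve-fiber structures in one channel (PGP9.5-like)
# and punctate Gaussian spots in the other (TRPV1-like), with full ground
# truth (fiber mask, spot table) so every downstream stage can be validated.

# run expr with a temporary RNG state seeded at `seed`
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stated counter scheme for child seeds: LCG-style mix, always < 2^31
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 48271 + as.numeric(k) * 9973) %%
               2147483647)
}

#' Specification of one synthetic two-channel image
#'
#' Defaults state the standard simulated world used throughout the test
#' suite: 16-bit-range intensities, punctum peak 1000 AU over background
#' 50 AU with Gaussian read noise of sd 10 AU, so that planted puncta are
#' far above the 200 AU detection threshold while background noise stays
#' far below it.
#'
#' @param image_shape c(height, width) in pixels
#' @param n_fibers number of curvilinear fibers
#' @param fiber_thickness_px fiber width in pixels
#' @param fiber_amplitude fiber intensity (AU) in the fiber channel
#' @param n_puncta_on puncta planted with centers on the fiber mask
#' @param n_puncta_off puncta planted with centers off the mask
#' @param punctum_sigma_px Gaussian spot sd in pixels
#' @param punctum_amplitude spot peak intensity (AU)
#' @param background_level constant background (AU), both channels
#' @param noise_sd Gaussian noise sd (AU)
#' @param pixel_size_um micrometres per pixel
#' @param seed integer seed; all generation is a pure function of the spec
#' @return a `synthetic_spec` object
#' @export
synthetic_spec <- function(image_shape = c(128L, 128L), n_fibers = 3L,
                           fiber_thickness_px = 5L, fiber_amplitude = 1000,
                           n_puncta_on = 7L, n_puncta_off = 5L,
                           punctum_sigma_px = 1.5, punctum_amplitude = 1000,
                           background_level = 50, noise_sd = 10,
                           pixel_size_um = 0.16, seed = 1L) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 8L),
            n_fibers >= 0L, fiber_thickness_px >= 1L,
            n_puncta_on >= 0L, n_puncta_off >= 0L,
            punctum_sigma_px > 0, noise_sd >= 0, pixel_size_um > 0)
  if (fiber_amplitude + punctum_amplitude + background_level > 65535)
    stop("amplitudes plus background exceed the 16-bit range")
  if (n_fibers == 0L && n_puncta_on > 0L)
    stop("n_puncta_on must be 0 when n_fibers is 0")
  structure(as.list(environment()), class = "synthetic_spec")
}

# binary dilation by a disk of radius r (shifted-copy OR)
.dilate_disk <- function(m, r) {
  if (r <= 0) return(m)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (dy in -r:r) for (dx in -r:r) {
    if (dy * dy + dx * dx > r * r) next
    ys <- pmin(pmax(seq_len(h) - dy, 1L), h)
    xs <- pmin(pmax(seq_len(w) - dx, 1L), w)
    sy <- seq_len(h); sx <- seq_len(w)
    yi <- sy[sy - dy >= 1L & sy - dy <= h]
    xi <- sx[sx - dx >= 1L & sx - dx <= w]
    out[yi, xi] <- out[yi, xi] | m[yi - dy, xi - dx, drop = FALSE]
  }
  out
}

#' Generate the ground-truth fiber mask
#'
#' Each fiber is a smooth random-walk curve: control points with jittered
#' ordinates are interpolated by a cubic spline spanning the full shorter
#' image dimension, rasterized, and dilated to the requested thickness.
#' Deterministic given `spec$seed`.
#'
#' @param spec a `synthetic_spec`
#' @return a `binary_mask`
#' @export
generate_fiber_mask <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  m <- matrix(FALSE, h, w)
  if (spec$n_fibers > 0L) {
    .with_seed(derive_seed(spec$seed, 0L), {
      for (f in seq_len(spec$n_fibers)) {
        transpose <- runif(1) < 0.5
        ww <- if (transpose) h else w
        hh <- if (transpose) w else h
        n_ctrl <- 6L
        cx <- seq(0, ww - 1, length.out = n_ctrl)
        cy <- numeric(n_ctrl)
        cy[1] <- runif(1, 0.15 * hh, 0.85 * hh)
        for (i in 2:n_ctrl)
          cy[i] <- min(max(cy[i - 1] + rnorm(1, 0, 0.12 * hh), 2), hh - 3)
        t_dense <- seq(0, ww - 1, length.out = 4L * ww)
        y_dense <- stats::spline(cx, cy, xout = t_dense)$y
        y_dense <- pmin(pmax(y_dense, 0), hh - 1)
        yy <- round(y_dense); xx <- round(t_dense)
        if (transpose) { tmp <- yy; yy <- xx; xx <- tmp }
        m[cbind(yy + 1L, xx + 1L)] <- TRUE
      }
    })
    m <- .dilate_disk(m, floor(spec$fiber_thickness_px / 2))
  }
  binary_mask(m, spec$pixel_size_um)
}

#' Generate ground truth (fiber mask plus planted spot table)
#'
#' Spot centers are placed with a minimum center-to-center separation of
#' `max(3, ceiling(4 * punctum_sigma_px))` pixels so the planted count
#' equals the resolvable count; on-fiber centers lie inside the mask,
#' off-fiber centers outside it.
#'
#' @param spec a `synthetic_spec`
#' @return list with `fiber_mask` (`binary_mask`), `spots`
#'   (data.frame y, x, on_fiber, amplitude; 0-based coordinates) and `spec`
#' @export
generate_ground_truth <- function(spec) {
  mask <- generate_fiber_mask(spec)
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  min_sep <- max(3, ceiling(4 * spec$punctum_sigma_px))
  margin <- ceiling(2 * spec$punctum_sigma_px)
  spots <- .with_seed(derive_seed(spec$seed, 1L), {
    interior <- matrix(FALSE, h, w)
    interior[(margin + 1):(h - margin), (margin + 1):(w - margin)] <- TRUE
    pick <- function(candidates, n, taken) {
      if (n == 0L) return(taken)
      ord <- sample.int(nrow(candidates))
      got <- 0L
      for (i in ord) {
        p <- candidates[i, ]
        if (nrow(taken) == 0L ||
            all((taken[, 1] - p[1])^2 + (taken[, 2] - p[2])^2 >=
                  min_sep^2)) {
          taken <- rbind(taken, p)
          got <- got + 1L
          if (got == n) break
        }
      }
      if (got < n) stop("could not place ", n, " spots at separation ",
                        min_sep, "; reduce counts or enlarge image")
      taken
    }
    on_cand <- which(mask$pixels & interior, arr.ind = TRUE)
    off_cand <- which(!mask$pixels & interior, arr.ind = TRUE)
    taken <- matrix(numeric(0), ncol = 2)
    taken <- pick(on_cand, spec$n_puncta_on, taken)
    taken <- pick(off_cand, spec$n_puncta_off, taken)
    n_tot <- spec$n_puncta_on + spec$n_puncta_off
    if (n_tot == 0L) {
      data.frame(y = integer(0), x = integer(0), on_fiber = logical(0),
                 amplitude = numeric(0))
    } else {
      data.frame(y = as.integer(taken[, 1] - 1L),
                 x = as.integer(taken[, 2] - 1L),
                 on_fiber = rep(c(TRUE, FALSE),
                                c(spec$n_puncta_on, spec$n_puncta_off)),
                 amplitude = rep(spec$punctum_amplitude, n_tot))
    }
  })
  list(fiber_mask = mask, spots = spots, spec = spec)
}

# add a 2-D Gaussian bump (peak = amplitude at 0-based (y0, x0)) in place
.add_gaussian <- function(img, y0, x0, amplitude, sigma) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(4 * sigma)
  ys <- max(0, y0 - r):min(h - 1, y0 + r)
  xs <- max(0, x0 - r):min(w - 1, x0 + r)
  g <- outer(exp(-(ys - y0)^2 / (2 * sigma^2)),
             exp(-(xs - x0)^2 / (2 * sigma^2)))
  img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + amplitude * g
  img
}

#' Render the two channels from ground truth
#'
#' The fiber channel is `fiber_amplitude` on the mask plus background plus
#' Gaussian noise; the puncta channel is the sum of 2-D Gaussian spots
#' (peak `amplitude` at each planted center) plus background plus noise.
#' Values are rounded to integers and clipped to [0, 65535], emulating
#' 16-bit storage. Deterministic given the spec seed.
#'
#' @param truth result of [generate_ground_truth()]
#' @return list with `pgp95` and `trpv1` (`channel_image`s)
#' @export
render_image <- function(truth) {
  spec <- truth$spec
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  pgp <- matrix(spec$background_level, h, w) +
    spec$fiber_amplitude * truth$fiber_mask$pixels
  trp <- matrix(spec$background_level, h, w)
  sp <- truth$spots
  if (nrow(sp) > 0L) for (i in seq_len(nrow(sp)))
    trp <- .add_gaussian(trp, sp$y[i], sp$x[i], sp$amplitude[i],
                         spec$punctum_sigma_px)
  .with_seed(derive_seed(spec$seed, 2L), {
    if (spec$noise_sd > 0) {
      pgp <- pgp + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
      trp <- trp + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    }
  })
  clipr <- function(m) matrix(pmin(pmax(round(m), 0), 65535), h, w)
  list(pgp95 = channel_image(clipr(pgp), "PGP9.5", spec$pixel_size_um),
       trpv1 = channel_image(clipr(trp), "TRPV1", spec$pixel_size_um))
}

#' Specification of a simulated annotator
#'
#' @param sensitivity probability a true (fiber) pixel is kept
#' @param specificity probability a false (background) pixel stays false
#' @param boundary_jitter_px max rigid translation (pixels) applied to the
#'   truth before the pixelwise flips; 0 disables it
#' @param seed integer seed
#' @return a `rater_sim_spec` object
#' @export
rater_sim_spec <- function(sensitivity, specificity,
                           boundary_jitter_px = 0L, seed = 1L) {
  stopifnot(sensitivity > 0, sensitivity <= 1,
            specificity > 0, specificity <= 1, boundary_jitter_px >= 0)
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 boundary_jitter_px = boundary_jitter_px,
                 seed = as.integer(seed)),
            class = "rater_sim_spec")
}

#' Simulate an expert annotation of a truth mask
#'
#' Independent pixel flips: each true pixel is retained with probability
#' `sensitivity`, each false pixel is flipped on with probability
#' `1 - specificity` — the conditional-independence model assumed by
#' STAPLE, so estimated rater parameters are directly interpretable.
#'
#' @param truth_mask a `binary_mask` or logical matrix
#' @param rspec a `rater_sim_spec`
#' @return a `binary_mask`
#' @export
simulate_rater <- function(truth_mask, rspec) {
  stopifnot(inherits(rspec, "rater_sim_spec"))
  px_um <- if (inherits(truth_mask, "binary_mask"))
    truth_mask$pixel_size_um else 0.16
  m <- .as_pixels(truth_mask)
  h <- nrow(m); w <- ncol(m)
  .with_seed(rspec$seed, {
    j <- rspec$boundary_jitter_px
    if (j > 0) {
      dy <- sample(-j:j, 1L); dx <- sample(-j:j, 1L)
      shifted <- matrix(FALSE, h, w)
      ys <- seq_len(h); xs <- seq_len(w)
      yi <- ys[ys - dy >= 1L & ys - dy <= h]
      xi <- xs[xs - dx >= 1L & xs - dx <= w]
      shifted[yi, xi] <- m[yi - dy, xi - dx]
      m <- shifted
    }
    u <- matrix(stats::runif(h * w), h, w)
    out <- matrix(FALSE, h, w)
    out[m] <- u[m] < rspec$sensitivity
    out[!m] <- u[!m] < (1 - rspec$specificity)
    binary_mask(out, px_um)
  })
}

#' Generate a dataset of synthetic images on disk
#'
#' Writes, per spec, the two channel TIFFs (16-bit), the truth-mask TIFF,
#' a spot CSV (`y,x,on_fiber,amplitude`), and one JSON manifest recording
#' ids, file names and full specs. Re-running with identical specs
#' reproduces byte-identical files.
#'
#' @param specs list of `synthetic_spec`
#' @param out_dir writable output directory (created if missing)
#' @return the manifest, invisibly (also written as `manifest.json`)
#' @export
generate_dataset <- function(specs, out_dir) {
  stopifnot(is.list(specs))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  images <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    stopifnot(inherits(spec, "synthetic_spec"))
    id <- sprintf("img_%03d", i)
    truth <- generate_ground_truth(spec)
    ch <- render_image(truth)
    f_pgp <- paste0(id, "_pgp95.tif")
    f_trp <- paste0(id, "_trpv1.tif")
    f_mask <- paste0(id, "_truth_mask.tif")
    f_spots <- paste0(id, "_spots.csv")
    write_tiff(ch$pgp95$pixels, file.path(out_dir, f_pgp))
    write_tiff(ch$trpv1$pixels, file.path(out_dir, f_trp))
    write_mask(truth$fiber_mask, file.path(out_dir, f_mask))
    utils::write.csv(truth$spots, file.path(out_dir, f_spots),
                     row.names = FALSE)
    images[[i]] <- list(id = id, pgp95 = f_pgp, trpv1 = f_trp,
                        truth_mask = f_mask, spots = f_spots,
                        pixel_size_um = spec$pixel_size_um,
                        seed = spec$seed,
                        spec = unclass(spec))
  }
  manifest <- list(format = "punctafiber-manifest-1", dir = out_dir,
                   n_images = length(specs), images = images)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
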