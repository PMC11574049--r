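# End-to-end pipeline: simulate -> train -> segment/quantify -> compare,
# driven by one JSON config with a master seed. Every run writes a
# provenance sidecar (config hash, seed, package version).

.default_config <- function() {
  list(
    schema = "punctafiber-config-1",
    seed = 1L,
    out_dir = "punctafiber_run",
    pixel_size_um = 0.16,
    threshold = 200,
    connectivity = 8L,
    channels = list(pgp95 = 0L, trpv1 = 1L),
    images = list(n_images = 10L, image_shape = c(128L, 128L),
                  n_fibers = 3L, fiber_thickness_px = 5L,
                  fiber_amplitude = 1000, n_puncta_on = 7L,
                  n_puncta_off = 5L, punctum_sigma_px = 1.5,
                  punctum_amplitude = 1000, background_level = 50,
                  noise_sd = 10),
    backend = list(type = "rf", n_trees = 100L,
                   scales = c(1, 2, 4, 8, 16), prob_threshold = 0.5,
                   min_object_px = 64L, n_train_images = 3L),
    staple = list(max_iter = 100L, tol = 1e-6),
    stats = list(icc_type = "single")
  )
}

# recursive merge of user values over defaults, rejecting unknown keys
.merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults))
      stop("unknown config key: ", full)
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        !is.null(names(defaults[[key]])))
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]], full)
    else defaults[[key]] <- user[[key]]
  }
  defaults
}

#' Validate and normalize a pipeline config
#'
#' Fills defaults (threshold 200 AU, pixel size 0.16 um, connectivity 8),
#' rejects unknown keys (typo protection) and type-checks the values.
#'
#' @param config path to a JSON config file, or a list
#' @return normalized config list
#' @export
validate_config <- function(config) {
  user <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else config
  if (!is.list(user)) stop("config must be a JSON object")
  cfg <- .merge_config(.default_config(), user)
  if (!identical(cfg$schema, "punctafiber-config-1"))
    stop("unsupported config schema: ", cfg$schema)
  if (!is.numeric(cfg$threshold) || cfg$threshold < 0)
    stop("invalid value for key 'threshold': must be a number >= 0")
  if (!is.numeric(cfg$pixel_size_um) || cfg$pixel_size_um <= 0)
    stop("invalid value for key 'pixel_size_um': must be > 0")
  if (!cfg$connectivity %in% c(4, 8))
    stop("invalid value for key 'connectivity': must be 4 or 8")
  if (!is.numeric(cfg$seed)) stop("invalid value for key 'seed'")
  if (cfg$images$n_images < 1)
    stop("invalid value for key 'images.n_images'")
  if (!cfg$backend$type %in% c("rf", "truth"))
    stop("invalid value for key 'backend.type': use 'rf' or 'truth'")
  cfg
}

.image_spec_from_config <- function(cfg, seed) {
  im <- cfg$images
  synthetic_spec(image_shape = as.integer(im$image_shape),
                 n_fibers = im$n_fibers,
                 fiber_thickness_px = im$fiber_thickness_px,
                 fiber_amplitude = im$fiber_amplitude,
                 n_puncta_on = im$n_puncta_on,
                 n_puncta_off = im$n_puncta_off,
                 punctum_sigma_px = im$punctum_sigma_px,
                 punctum_amplitude = im$punctum_amplitude,
                 background_level = im$background_level,
                 noise_sd = im$noise_sd,
                 pixel_size_um = cfg$pixel_size_um, seed = seed)
}

# training strokes derived from a ground truth: fiber strokes = eroded
# truth, background strokes = everything beyond a thin unlabeled band
# around the truth (margin 2 px keeps the learned boundary centered)
.strokes_from_truth <- function(truth_mask, margin = 2L) {
  m <- .as_pixels(truth_mask)
  fiber <- !.dilate_disk(!m, 1L)          # erosion by 1
  if (!any(fiber)) fiber <- m
  background <- !.dilate_disk(m, margin)
  list(fiber = fiber, background = background)
}

#' Train the default classifier on synthetic images
#'
#' Generates `n_train` fresh synthetic images (child seeds derived from
#' the config's master seed, offset from the analysis images), derives
#' sparse strokes from their ground truth, and fits the random-forest
#' pixel classifier.
#'
#' @param cfg validated config
#' @param n_train number of training images (default from config)
#' @return a `pixel_classifier`
#' @export
train_from_config <- function(cfg, n_train = NULL) {
  if (is.null(n_train)) n_train <- cfg$backend$n_train_images
  imgs <- list(); labs <- list()
  for (i in seq_len(n_train)) {
    spec <- .image_spec_from_config(cfg, derive_seed(cfg$seed,
                                                     100000L + i))
    truth <- generate_ground_truth(spec)
    ch <- render_image(truth)
    imgs[[i]] <- ch$pgp95
    labs[[i]] <- .strokes_from_truth(truth$fiber_mask)
  }
  train_classifier(imgs, labs, scales = cfg$backend$scales,
                   n_trees = cfg$backend$n_trees, seed = 0L)
}

#' Run the pipeline
#'
#' Stages (in dependency order): `simulate` (synthetic dataset with
#' ground truth), `train` (random-forest classifier; skipped for the
#' "truth" backend), `quantify` (segment + detect + measure, one row per
#' image and method: the chosen backend plus the ground-truth external
#' branch), `compare` (agreement report). Identical (config, seed) gives
#' byte-identical CSV/JSON artifacts.
#'
#' @param config path to JSON config or config list
#' @param stages character subset of
#'   c("simulate", "train", "quantify", "compare")
#' @return list of artifact paths, invisibly
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "train", "quantify",
                                    "compare")) {
  cfg <- validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  img_dir <- file.path(out, "images")
  clf_path <- file.path(out, "classifier.rds")
  quant_path <- file.path(out, "quant.csv")
  report_path <- file.path(out, "report.json")

  # provenance: config hash + seed
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  prov <- list(config_md5 = unname(tools::md5sum(tmp)),
               seed = cfg$seed,
               package_version =
                 as.character(utils::packageVersion("punctafiber")))
  unlink(tmp)
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  if ("simulate" %in% stages) {
    specs <- lapply(seq_len(cfg$images$n_images), function(i)
      .image_spec_from_config(cfg, derive_seed(cfg$seed, i)))
    generate_dataset(specs, img_dir)
    message("simulate: wrote ", cfg$images$n_images, " images to ",
            img_dir)
  }

  if ("train" %in% stages && cfg$backend$type == "rf") {
    clf <- train_from_config(cfg)
    save_classifier(clf, clf_path)
    message("train: classifier saved to ", clf_path)
  }

  if ("quantify" %in% stages) {
    manifest_path <- file.path(img_dir, "manifest.json")
    if (!file.exists(manifest_path))
      stop("missing upstream artifact ", manifest_path,
           ": run stage 'simulate' first")
    backends <- list(truth = "truth")
    if (cfg$backend$type == "rf") {
      if (!file.exists(clf_path))
        stop("missing upstream artifact ", clf_path,
             ": run stage 'train' first")
      backends$rf <- load_classifier(clf_path)
    }
    tab <- quantify_batch(manifest_path, backends,
                          threshold = cfg$threshold,
                          out_csv = quant_path)
    message("quantify: ", nrow(tab), " records -> ", quant_path)
  }

  if ("compare" %in% stages) {
    if (!file.exists(quant_path))
      stop("missing upstream artifact ", quant_path,
           ": run stage 'quantify' first")
    tab <- utils::read.csv(quant_path, stringsAsFactors = FALSE)
    report <- build_report(tab)
    write_report(report, report_path, file.path(out, "report.csv"))
    message("compare: report -> ", report_path)
  }

  invisible(list(images = img_dir, classifier = clf_path,
                 quant = quant_path, report = report_path))
}
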