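# Shared fixtures: small seeded synthetic worlds used across test files.

fixture_truth <- function(seed = 7L, ...) {
  generate_ground_truth(synthetic_spec(seed = seed, ...))
}

fixture_rendered <- function(seed = 7L, ...) {
  truth <- fixture_truth(seed, ...)
  c(truth, render_image(truth))
}

# random integer test image + random mask, used by the detection oracle
random_instance <- function(h = 32L, w = 32L, max_val = 400L,
                            plateau_prone = FALSE) {
  vals <- if (plateau_prone) sample(0:8, h * w, replace = TRUE) * 50L
          else sample(0:max_val, h * w, replace = TRUE)
  list(img = matrix(vals, h, w),
       mask = matrix(stats::runif(h * w) < 0.6, h, w))
}
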