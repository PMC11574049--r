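# agreement_stats: overlap scores, rank statistics and ICC against
# independent oracles, plus report assembly

# --- independent oracles -------------------------------------------------

spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)              # base midranks
  rho <- stats::cor(rx, ry)
  n <- length(x)
  p <- if (abs(rho) >= 1 - 1e-12) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p)
}

icc_oracle <- function(m) {
  # mean squares via stats::aov, a codepath foreign to the implementation
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(v = as.vector(m),
                  subj = factor(rep(seq_len(n), k)),
                  meth = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(v ~ subj + meth, data = d))[[1]]$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

kw_oracle <- function(groups) {
  # tie-corrected H via the rank-variance identity:
  # H = (N-1) * SS_between(ranks) / SS_total(ranks)
  pooled <- unlist(groups)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), vapply(groups, length, 1L))
  rbar <- tapply(r, idx, mean)
  ni <- tabulate(idx)
  (length(r) - 1) * sum(ni * (rbar - mean(r))^2) /
    sum((r - mean(r))^2)
}

dunn_oracle <- function(groups) {
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), vapply(groups, length, 1L))
  rbar <- tapply(r, idx, mean)
  ni <- tabulate(idx)
  ties <- table(pooled)
  vt <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  k <- length(groups)
  z <- c()
  for (i in 1:(k - 1)) for (j in (i + 1):k)
    z <- c(z, (rbar[i] - rbar[j]) /
             sqrt(vt * (1 / ni[i] + 1 / ni[j])))
  unname(z)
}

# --- overlap scores ------------------------------------------------------

test_that("iou and dice follow their set formulas", {
  a <- matrix(FALSE, 4, 4); a[1, 1:4] <- TRUE          # |A| = 4
  b <- matrix(FALSE, 4, 4); b[1, 3:4] <- TRUE; b[2, 1:2] <- TRUE
  expect_equal(iou(a, a), 1.0)
  expect_equal(dice(a, a), 1.0)
  disj <- matrix(FALSE, 4, 4); disj[4, ] <- TRUE
  expect_equal(iou(a, disj), 0.0)
  expect_equal(iou(a, b), 2 / 6)                       # overlap 2
  expect_equal(dice(a, b), 0.5)
  empty <- matrix(FALSE, 4, 4)
  expect_equal(iou(empty, empty), 1.0)
  expect_equal(dice(empty, empty), 1.0)
  expect_error(iou(a, matrix(TRUE, 2, 2)), "shapes differ")
})

test_that("dice = 2*iou/(1+iou) on random mask pairs", {
  set.seed(10)
  for (rep in 1:20) {
    a <- matrix(stats::runif(100) < 0.4, 10, 10)
    b <- matrix(stats::runif(100) < 0.4, 10, 10)
    i <- iou(a, b)
    expect_equal(dice(a, b), 2 * i / (1 + i), tolerance = 1e-12)
  }
})

# --- spearman ------------------------------------------------------------

test_that("spearman_rho: monotone and tied cases, oracle agreement", {
  expect_equal(spearman_rho(1:3, c(2, 4, 6))$rho, 1)
  expect_equal(spearman_rho(1:3, c(2, 4, 6))$p, 0)
  expect_equal(spearman_rho(1:3, c(6, 4, 2))$rho, -1)
  tied <- spearman_rho(c(1, 2, 2, 3), c(1, 3, 2, 4))
  orc <- spearman_oracle(c(1, 2, 2, 3), c(1, 3, 2, 4))
  expect_equal(tied$rho, orc$rho, tolerance = 1e-12)
  expect_equal(tied$p, orc$p, tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), "n >= 3")
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  set.seed(11)
  x <- stats::rnorm(15); y <- stats::rnorm(15)
  base <- spearman_rho(x, y)$rho
  expect_equal(spearman_rho(exp(x), y)$rho, base, tolerance = 1e-12)
  expect_equal(spearman_rho(x, y^3 + 5 * y)$rho, base,
               tolerance = 1e-12)
})

# --- ICC -----------------------------------------------------------------

test_that("icc_two_way_mixed_absolute matches the aov oracle", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(4:10, 1); k <- sample(2:4, 1)
    m <- matrix(stats::rnorm(n * k, 10, 3), n, k)
    expect_equal(icc_two_way_mixed_absolute(m)$estimate, icc_oracle(m),
                 tolerance = 1e-10)
  }
})

test_that("ICC closed-form behaviors", {
  v <- c(3, 7, 11, 2, 9, 15)
  m <- cbind(v, v)
  expect_equal(icc_two_way_mixed_absolute(m)$estimate, 1.0)
  # constant shift between methods is penalized (absolute agreement)
  m2 <- cbind(v, v + 4)
  expect_lt(icc_two_way_mixed_absolute(m2)$estimate, 1.0)
  # common affine rescaling of ALL methods leaves the estimate unchanged
  set.seed(13)
  r <- matrix(stats::rnorm(24, 20, 5), 8, 3)
  expect_equal(icc_two_way_mixed_absolute(2.5 * r + 7)$estimate,
               icc_two_way_mixed_absolute(r)$estimate, tolerance = 1e-10)
  # degenerate: all identical
  expect_warning(
    res <- icc_two_way_mixed_absolute(matrix(5, 4, 2)),
    "degenerate")
  expect_equal(res$estimate, 1.0)
  expect_error(icc_two_way_mixed_absolute(matrix(1:4, 2, 2)), "n >= 3")
})

test_that("icc_band reproduces the qualitative cut-offs", {
  expect_equal(icc_band(0.795), "good")
  expect_equal(icc_band(0.977), "excellent")
  expect_equal(icc_band(0.859), "good")
  expect_equal(icc_band(0.5), "moderate")    # left-inclusive boundary
  expect_equal(icc_band(0.75), "good")
  expect_equal(icc_band(0.9), "excellent")
  expect_equal(icc_band(0.4999), "poor")
  expect_error(icc_band(1.2), NULL)
})

# --- Kruskal-Wallis and Dunn ---------------------------------------------

test_that("kruskal_wallis: hand-computed and degenerate cases", {
  expect_equal(kruskal_wallis(list(1:3, 4:6, 7:9))$H, 7.2)
  identical3 <- list(c(2, 2), c(2, 2), c(2, 2))
  res0 <- kruskal_wallis(identical3)
  expect_equal(res0$H, 0)
  expect_equal(res0$p, 1)
  expect_error(kruskal_wallis(list(1:3)), NULL)
  expect_error(kruskal_wallis(list(1:3, 5)), ">= 2 values")
})

test_that("kruskal_wallis tie correction matches the rank-variance oracle", {
  set.seed(14)
  for (rep in 1:20) {
    groups <- lapply(1:3, function(i)
      sample(1:5, sample(3:8, 1), replace = TRUE))
    if (length(unique(unlist(groups))) == 1L) next
    expect_equal(kruskal_wallis(groups)$H, kw_oracle(groups),
                 tolerance = 1e-10)
  }
})

test_that("kruskal_wallis H is invariant under monotone transforms", {
  set.seed(15)
  groups <- lapply(1:3, function(i) stats::rnorm(6, i))
  h <- kruskal_wallis(groups)$H
  expect_equal(kruskal_wallis(lapply(groups, exp))$H, h,
               tolerance = 1e-12)
})

test_that("dunn_posthoc matches its formula and Bonferroni arithmetic", {
  groups <- list(a = 1:3, b = 4:6, c = 7:9)
  res <- dunn_posthoc(groups)
  expect_equal(res$z, dunn_oracle(groups), tolerance = 1e-10)
  expect_equal(res$p_adjusted, pmin(1, 3 * res$p_raw))
  # identical groups: z = 0, p = 1
  res0 <- dunn_posthoc(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_true(all(res0$z == 0))
  expect_true(all(res0$p_raw == 1))
  # tied random instances
  set.seed(16)
  for (rep in 1:10) {
    g <- lapply(1:3, function(i) sample(1:4, 5, replace = TRUE))
    if (length(unique(unlist(g))) == 1L) next
    expect_equal(dunn_posthoc(g)$z, dunn_oracle(g), tolerance = 1e-10)
  }
})

# --- report assembly -----------------------------------------------------

make_quant <- function(n = 8, methods = c("rf", "truth"), noise = 0,
                       seed = 17) {
  set.seed(seed)
  base <- data.frame(image_id = sprintf("img_%02d", 1:n),
                     n_puncta = sample(3:40, n),
                     mfi_au = stats::runif(n, 50, 150),
                     fiber_area_um2 = stats::runif(n, 20, 80))
  do.call(rbind, lapply(methods, function(m) {
    d <- base
    d$method <- m
    if (m != methods[1] && noise > 0) {
      d$n_puncta <- d$n_puncta + round(stats::rnorm(n, 0, noise))
      d$mfi_au <- d$mfi_au + stats::rnorm(n, 0, noise)
      d$fiber_area_um2 <- d$fiber_area_um2 + stats::rnorm(n, 0, noise)
    }
    d[, c("image_id", "method", "n_puncta", "mfi_au", "fiber_area_um2")]
  }))
}

test_that("identical methods give ICC 1 and Kruskal-Wallis p = 1", {
  rep0 <- build_report(make_quant(noise = 0))
  expect_equal(rep0$icc$n_puncta$estimate, 1.0)
  expect_equal(rep0$icc$mfi_au$estimate, 1.0)
  expect_equal(rep0$kruskal$p, 1)
  expect_equal(rep0$spearman[["rf vs truth"]]$rho, 1)
})

test_that("ICC decreases monotonically with added method noise", {
  iccs <- vapply(c(0, 2, 6, 15), function(s)
    build_report(make_quant(n = 12, noise = s, seed = 18))$
      icc$n_puncta$estimate, 1.0)
  expect_true(all(diff(iccs) < 0))
})

test_that("manual counts join the rank comparisons only", {
  q <- make_quant(noise = 1)
  manual <- do.call(rbind, lapply(1:3, function(r)
    data.frame(image_id = sprintf("img_%02d", 1:8), rater = r,
               n_puncta = sample(3:40, 8))))
  rep1 <- build_report(q, manual_counts = manual)
  expect_true("manual" %in% rep1$methods)
  expect_true(any(grepl("manual", names(rep1$spearman))))
  # ICC stays between the automated methods
  expect_equal(rep1$icc$n_puncta$k, 2L)
  expect_equal(nrow(rep1$dunn), 3L)          # 3 methods -> 3 pairs
})

test_that("report round-trips through JSON and warns on missing cells", {
  q <- make_quant(noise = 1)
  rep1 <- build_report(q)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_report(rep1, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$icc$n_puncta$estimate, rep1$icc$n_puncta$estimate)
  expect_equal(back$kruskal$H, rep1$kruskal$H)

  q_missing <- q[-3, ]                       # drop one cell
  expect_warning(rep2 <- build_report(q_missing), "missing cells")
  expect_equal(rep2$n_images, 7)

  expect_error(build_report(q[q$image_id %in% c("img_01", "img_02"), ]),
               ">= 3 images")
})

test_that("mask_pairs produce mean IoU / Dice segmentation scores", {
  a <- matrix(stats::runif(64) < 0.5, 8, 8)
  pairs <- list(list(truth = a, pred = a),
                list(truth = a, pred = !a))
  rep1 <- build_report(make_quant(noise = 1), mask_pairs = pairs)
  expect_equal(rep1$segmentation$mean_iou, 0.5)
  expect_equal(rep1$segmentation$n, 2)
})
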