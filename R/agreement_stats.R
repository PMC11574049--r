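# Method-agreement statistics: overlap scores (IoU / Dice), Spearman rank
# correlation, two-way mixed absolute-agreement ICC with qualitative
# bands, and Kruskal-Wallis with Dunn post-hoc (tie-corrected).

#' Intersection over union (Jaccard index)
#'
#' `|A intersect B| / |A union B|`; defined as 1 when both masks are
#' empty.
#'
#' @param a,b `binary_mask` or logical matrices of identical shape
#' @return scalar in [0, 1]
#' @export
iou <- function(a, b) {
  ma <- .as_pixels(a); mb <- .as_pixels(b)
  if (!identical(dim(ma), dim(mb))) stop("mask shapes differ")
  u <- sum(ma | mb)
  if (u == 0) return(1.0)
  sum(ma & mb) / u
}

#' Dice coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty. Identity: dice = 2 iou / (1 + iou).
#'
#' @inheritParams iou
#' @return scalar in [0, 1]
#' @export
dice <- function(a, b) {
  ma <- .as_pixels(a); mb <- .as_pixels(b)
  if (!identical(dim(ma), dim(mb))) stop("mask shapes differ")
  s <- sum(ma) + sum(mb)
  if (s == 0) return(1.0)
  2 * sum(ma & mb) / s
}

# midranks computed from scratch (independent of base::rank)
.midrank <- function(x) {
  n <- length(x)
  o <- order(x)
  r <- numeric(n)
  i <- 1L
  sx <- x[o]
  while (i <= n) {
    j <- i
    while (j < n && sx[j + 1L] == sx[i]) j <- j + 1L
    r[o[i:j]] <- (i + j) / 2
    i <- j + 1L
  }
  r
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Midranks for ties; rho is the Pearson correlation of the ranks; the
#' two-tailed p comes from `t = rho sqrt((n-2) / (1-rho^2))` on n-2 df
#' (the SPSS-style approximation). `rho = +/-1` returns p = 0.
#'
#' @param x,y numeric vectors of equal length, n >= 3
#' @return list(rho, p, n)
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y lengths differ")
  if (n < 3L) stop("need n >= 3")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("constant series: rho undefined")
  rx <- .midrank(x); ry <- .midrank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Two-way mixed-effects ICC with absolute agreement
#'
#' From the two-way ANOVA decomposition (rows = subjects, columns =
#' methods/raters): the single-measure absolute-agreement estimate
#' (McGraw-Wong ICC(A,1))
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`,
#' or the average-measure form `(MS_R - MS_E) / (MS_R + (MS_C - MS_E)/n)`
#' with `type = "average"`. The p-value tests ICC = 0 via
#' `F = MS_R / MS_E` on (n-1, (n-1)(k-1)) df.
#'
#' @param values n x k numeric matrix (n subjects, k methods)
#' @param type "single" (default) or "average"
#' @return list(estimate, p, band, ms = list(msr, msc, mse), n, k)
#' @export
icc_two_way_mixed_absolute <- function(values, type = c("single",
                                                        "average")) {
  type <- match.arg(type)
  stopifnot(is.matrix(values))
  n <- nrow(values); k <- ncol(values)
  if (n < 3L) stop("need n >= 3 subjects")
  if (k < 2L) stop("need k >= 2 methods")
  if (anyNA(values)) stop("missing cells not allowed; drop rows first")
  g <- mean(values)
  rm_ <- rowMeans(values); cm <- colMeans(values)
  ss_r <- k * sum((rm_ - g)^2)
  ss_c <- n * sum((cm - g)^2)
  ss_t <- sum((values - g)^2)
  ss_e <- ss_t - ss_r - ss_c
  msr <- ss_r / (n - 1)
  msc <- ss_c / (k - 1)
  mse <- ss_e / ((n - 1) * (k - 1))
  if (ss_t < 1e-300) {
    warning("degenerate variance: all values identical; ICC set to 1")
    est <- 1.0
    p <- NA_real_
  } else {
    est <- if (type == "single")
      (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    else (msr - mse) / (msr + (msc - mse) / n)
    p <- if (mse <= 0) 0 else
      stats::pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  list(estimate = est, p = p, band = icc_band(est),
       ms = list(msr = msr, msc = msc, mse = mse), n = n, k = k)
}

#' Qualitative ICC band
#'
#' Below 0.5 poor; 0.5 to below 0.75 moderate; 0.75 to below 0.9 good;
#' 0.9 and above excellent.
#'
#' @param estimate ICC estimate (<= 1)
#' @return one of "poor", "moderate", "good", "excellent"
#' @export
icc_band <- function(estimate) {
  stopifnot(estimate <= 1)
  if (estimate < 0.5) "poor"
  else if (estimate < 0.75) "moderate"
  else if (estimate < 0.9) "good"
  else "excellent"
}

# tie-correction term sum(t^3 - t) over tie groups of the pooled sample
.tie_term <- function(pooled) {
  t <- table(pooled)
  sum(t^3 - t)
}

#' Kruskal-Wallis rank test (tie-corrected)
#'
#' `H = 12 / (N(N+1)) * sum n_i (rbar_i - (N+1)/2)^2`, divided by
#' `1 - sum(t^3 - t) / (N^3 - N)` for ties; p from chi-square on k-1 df.
#' All-identical input returns H = 0, p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values)
#' @return list(H, df, p)
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs >= 2 values")
  k <- length(groups)
  pooled <- unlist(groups)
  N <- length(pooled)
  if (length(unique(pooled)) == 1L)
    return(list(H = 0, df = k - 1L, p = 1))
  r <- .midrank(pooled)
  idx <- rep(seq_len(k), vapply(groups, length, 1L))
  rbar <- tapply(r, idx, mean)
  ni <- tabulate(idx)
  H <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
  corr <- 1 - .tie_term(pooled) / (N^3 - N)
  H <- H / corr
  list(H = H, df = k - 1L,
       p = stats::pchisq(H, k - 1L, lower.tail = FALSE))
}

#' Dunn post-hoc pairwise comparisons
#'
#' `z_ij = (rbar_i - rbar_j) / sqrt((N(N+1)/12 -
#' sum(t^3 - t)/(12(N-1))) (1/n_i + 1/n_j))`, two-tailed normal p,
#' Bonferroni-adjusted over all pairs (raw p also reported).
#'
#' @param groups list of numeric vectors, optionally named
#' @return data.frame: group_i, group_j, z, p_raw, p_adjusted
#' @export
dunn_posthoc <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs >= 2 values")
  k <- length(groups)
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("group", seq_len(k))
  pooled <- unlist(groups)
  N <- length(pooled)
  ni <- vapply(groups, length, 1L)
  degenerate <- length(unique(pooled)) == 1L
  r <- .midrank(pooled)
  idx <- rep(seq_len(k), ni)
  rbar <- tapply(r, idx, mean)
  varterm <- N * (N + 1) / 12 - .tie_term(pooled) / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  out <- data.frame(group_i = nms[pairs[1, ]], group_j = nms[pairs[2, ]],
                    z = numeric(m), p_raw = numeric(m),
                    p_adjusted = numeric(m), stringsAsFactors = FALSE)
  for (c_ in seq_len(m)) {
    i <- pairs[1, c_]; j <- pairs[2, c_]
    if (degenerate || varterm <= 0) {
      z <- 0
    } else {
      z <- (rbar[i] - rbar[j]) /
        sqrt(varterm * (1 / ni[i] + 1 / ni[j]))
    }
    p <- 2 * stats::pnorm(-abs(z))
    out$z[c_] <- z
    out$p_raw[c_] <- p
    out$p_adjusted[c_] <- min(1, m * p)
  }
  out
}

#' Assemble the full method-agreement report
#'
#' From a long quantification table (columns image_id, method, n_puncta,
#' mfi_au, fiber_area_um2): per-method descriptives (mean, sd), pairwise
#' Spearman correlations of punctum counts across all methods (including
#' manual counts if supplied, collapsed to their per-image mean),
#' absolute-agreement ICC for counts, MFI and area between automated
#' methods, and Kruskal-Wallis plus Dunn across all methods' counts.
#' Rows (images) with missing cells are dropped with a warning.
#'
#' @param quant_table data.frame as produced by [quantify_batch()]
#' @param manual_counts optional data.frame (image_id, rater, n_puncta)
#' @param mask_pairs optional list of list(truth =, pred =) mask pairs;
#'   mean IoU and Dice are reported
#' @return an `agreement_report` (list; see fields)
#' @export
build_report <- function(quant_table, manual_counts = NULL,
                         mask_pairs = NULL) {
  need <- c("image_id", "method", "n_puncta", "mfi_au", "fiber_area_um2")
  if (!all(need %in% names(quant_table)))
    stop("quant_table must have columns: ", paste(need, collapse = ", "))
  auto_methods <- sort(unique(quant_table$method))

  pivot <- function(measure) {
    wide <- stats::reshape(
      quant_table[, c("image_id", "method", measure)],
      idvar = "image_id", timevar = "method", direction = "wide")
    m <- as.matrix(wide[, -1, drop = FALSE])
    colnames(m) <- sub(paste0("^", measure, "\\."), "", colnames(m))
    rownames(m) <- wide$image_id
    m[, auto_methods, drop = FALSE]
  }
  counts <- pivot("n_puncta")
  mfi <- pivot("mfi_au")
  area <- pivot("fiber_area_um2")
  complete <- stats::complete.cases(counts) & stats::complete.cases(mfi) &
    stats::complete.cases(area)
  if (!all(complete))
    warning("dropping ", sum(!complete), " image(s) with missing cells")
  counts <- counts[complete, , drop = FALSE]
  mfi <- mfi[complete, , drop = FALSE]
  area <- area[complete, , drop = FALSE]

  # manual counts: per-image mean over raters, as one more counts column
  count_cols <- counts
  if (!is.null(manual_counts)) {
    stopifnot(all(c("image_id", "rater", "n_puncta") %in%
                    names(manual_counts)))
    man <- tapply(manual_counts$n_puncta, manual_counts$image_id, mean)
    shared <- intersect(rownames(counts), names(man))
    if (length(shared) < 3L)
      stop("insufficient overlap with manual counts; missing: ",
           paste(setdiff(rownames(counts), names(man)), collapse = ", "))
    count_cols <- cbind(counts[shared, , drop = FALSE],
                        manual = as.numeric(man[shared]))
  }
  if (nrow(count_cols) < 3L || ncol(count_cols) < 2L)
    stop("need >= 2 methods sharing >= 3 images; have ",
         nrow(count_cols), " image(s)")

  descriptives <- do.call(rbind, lapply(auto_methods, function(mt) {
    sub <- quant_table[quant_table$method == mt, ]
    data.frame(method = mt, n = nrow(sub),
               count_mean = mean(sub$n_puncta),
               count_sd = stats::sd(sub$n_puncta),
               mfi_mean = mean(sub$mfi_au),
               mfi_sd = stats::sd(sub$mfi_au),
               area_mean = mean(sub$fiber_area_um2),
               area_sd = stats::sd(sub$fiber_area_um2))
  }))

  meths <- colnames(count_cols)
  spearman <- list()
  for (i in seq_along(meths)) for (j in seq_along(meths)) {
    if (i >= j) next
    key <- paste(meths[i], meths[j], sep = " vs ")
    spearman[[key]] <- tryCatch(
      spearman_rho(count_cols[, i], count_cols[, j]),
      error = function(e) list(rho = NA_real_, p = NA_real_,
                               n = nrow(count_cols)))
  }

  icc <- list()
  if (ncol(counts) >= 2L && nrow(counts) >= 3L) {
    icc$n_puncta <- icc_two_way_mixed_absolute(counts)
    icc$mfi_au <- icc_two_way_mixed_absolute(mfi)
    icc$fiber_area_um2 <- icc_two_way_mixed_absolute(area)
  }

  glist <- lapply(seq_len(ncol(count_cols)),
                  function(j) count_cols[, j])
  names(glist) <- meths
  kruskal <- kruskal_wallis(glist)
  dunn <- dunn_posthoc(glist)

  seg_scores <- NULL
  if (!is.null(mask_pairs)) {
    ious <- vapply(mask_pairs, function(p) iou(p$truth, p$pred), 1.0)
    dices <- vapply(mask_pairs, function(p) dice(p$truth, p$pred), 1.0)
    seg_scores <- list(mean_iou = mean(ious), mean_dice = mean(dices),
                       n = length(ious))
  }

  structure(list(descriptives = descriptives, spearman = spearman,
                 icc = icc, kruskal = kruskal, dunn = dunn,
                 segmentation = seg_scores,
                 n_images = nrow(count_cols), methods = meths),
            class = "agreement_report")
}

#' Serialize an agreement report
#'
#' Writes the report as JSON (lossless for reload) and, optionally, the
#' descriptives table as CSV.
#'
#' @param report an `agreement_report`
#' @param json_path output JSON path
#' @param csv_path optional CSV path for the descriptives
#' @return `json_path`, invisibly
#' @export
write_report <- function(report, json_path, csv_path = NULL) {
  stopifnot(inherits(report, "agreement_report"))
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  if (!is.null(csv_path))
    utils::write.csv(report$descriptives, csv_path, row.names = FALSE)
  invisible(json_path)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report: %d images, methods: %s>\n",
              x$n_images, paste(x$methods, collapse = ", ")))
  for (nm in names(x$spearman))
    cat(sprintf("  spearman %s: rho=%.3f p=%.3g\n", nm,
                x$spearman[[nm]]$rho, x$spearman[[nm]]$p))
  for (nm in names(x$icc))
    cat(sprintf("  icc %s: %.3f (%s)\n", nm, x$icc[[nm]]$estimate,
                x$icc[[nm]]$band))
  cat(sprintf("  kruskal-wallis: H=%.3f df=%d p=%.3g\n",
              x$kruskal$H, x$kruskal$df, x$kruskal$p))
  invisible(x)
}
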