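# STAPLE (Simultaneous Truth And Performance Level Estimation) for binary
# masks: EM fusion of multiple raters' annotations into a consensus
# probability map while estimating each rater's sensitivity p_j and
# specificity q_j.

#' Fuse expert annotations with binary STAPLE
#'
#' E-step: per-pixel consensus weight
#' `W_i = a_i / (a_i + b_i)` with
#' `a_i = prior * prod_j p_j^d_ij (1-p_j)^(1-d_ij)` and
#' `b_i = (1-prior) * prod_j (1-q_j)^d_ij q_j^(1-d_ij)`;
#' M-step: `p_j = sum W_i d_ij / sum W_i`,
#' `q_j = sum (1-W_i)(1-d_ij) / sum (1-W_i)`.
#' Iterates until the largest parameter change drops below `tol` or
#' `max_iter` is reached. Parameters are clamped to
#' `[1e-6, 1 - 1e-6]`; clamping (e.g. at unanimity) is flagged.
#'
#' @param masks list of `binary_mask` or logical matrices, same shape
#' @param rater_ids optional character ids (default rater1..R)
#' @param prior scalar prior probability of foreground, or a matrix of
#'   per-pixel priors; default: mean annotation fraction
#' @param max_iter maximum EM iterations (default 100)
#' @param tol convergence tolerance on max |delta p, delta q|
#' @return a `staple_result`: `consensus_probability` (matrix),
#'   `consensus_mask` (`binary_mask`, probability >= 0.5),
#'   `sensitivities`, `specificities`, `n_iterations`, `converged`,
#'   `clamped`, `log_likelihood` (per-iteration trajectory)
#' @export
staple_fuse <- function(masks, rater_ids = NULL, prior = NULL,
                        max_iter = 100L, tol = 1e-6) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  mats <- lapply(masks, .as_pixels)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("annotation masks must share one shape")
  R <- length(mats)
  if (is.null(rater_ids)) rater_ids <- paste0("rater", seq_len(R))
  px_um <- if (inherits(masks[[1]], "binary_mask"))
    masks[[1]]$pixel_size_um else 0.16
  h <- dims[1, 1]; w <- dims[2, 1]
  D <- vapply(mats, function(m) as.numeric(m), numeric(h * w))
  D <- matrix(D, ncol = R)

  if (is.null(prior)) prior <- mean(D)
  if (is.matrix(prior)) {
    stopifnot(identical(dim(prior), c(h, w)))
    prior <- as.vector(prior)
  }
  if (any(prior <= 0) || any(prior >= 1))
    prior <- pmin(pmax(prior, 1e-6), 1 - 1e-6)

  eps <- 1e-6
  clamp <- function(x) pmin(pmax(x, eps), 1 - eps)
  p <- rep(0.99999, R)
  q <- rep(0.99999, R)
  clamped <- FALSE
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  W <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    la <- log(prior) + D %*% log(p) + (1 - D) %*% log(1 - p)
    lb <- log(1 - prior) + D %*% log(1 - q) + (1 - D) %*% log(q)
    mx <- pmax(la, lb)
    loglik <- c(loglik, sum(mx + log(exp(la - mx) + exp(lb - mx))))
    W <- as.vector(1 / (1 + exp(lb - la)))
    sw <- sum(W); sw0 <- sum(1 - W)
    p_new <- if (sw > 0) colSums(W * D) / sw else p
    q_new <- if (sw0 > 0) colSums((1 - W) * (1 - D)) / sw0 else q
    if (any(p_new < eps | p_new > 1 - eps) ||
        any(q_new < eps | q_new > 1 - eps)) clamped <- TRUE
    p_new <- clamp(p_new); q_new <- clamp(q_new)
    delta <- max(abs(p_new - p), abs(q_new - q))
    p <- p_new; q <- q_new
    if (delta < tol) { converged <- TRUE; break }
  }
  prob <- matrix(as.vector(W), h, w)
  structure(list(
    consensus_probability = prob,
    consensus_mask = binary_mask(prob >= 0.5, px_um),
    sensitivities = stats::setNames(p, rater_ids),
    specificities = stats::setNames(q, rater_ids),
    n_iterations = iter,
    converged = converged,
    clamped = clamped,
    log_likelihood = loglik),
    class = "staple_result")
}

#' @export
print.staple_result <- function(x, ...) {
  cat(sprintf(
    "<staple_result: %d raters, %d iterations%s%s>\n",
    length(x$sensitivities), x$n_iterations,
    if (x$converged) ", converged" else "",
    if (x$clamped) ", clamped" else ""))
  cat("  sensitivity:", sprintf("%.4f", x$sensitivities), "\n")
  cat("  specificity:", sprintf("%.4f", x$specificities), "\n")
  invisible(x)
}

#' Strict majority vote over annotations
#'
#' A pixel is foreground iff strictly more than half of the raters mark
#' it; ties (even R) resolve to background.
#'
#' @param masks list of `binary_mask` or logical matrices, same shape
#' @return a `binary_mask`
#' @export
majority_vote <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  mats <- lapply(masks, .as_pixels)
  px_um <- if (inherits(masks[[1]], "binary_mask"))
    masks[[1]]$pixel_size_um else 0.16
  s <- Reduce(`+`, mats)
  binary_mask(s > length(mats) / 2, px_um)
}
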