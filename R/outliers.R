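# Influential-observation detection on the training set.
#
# Stage 1 (base_pvalues): K = 3 per-observation two-sided p-values from
# residual diagnostics of an inner cross-validated GBLUP fit on the training
# fold. Stage 2 (combine_*): the four meta-analytic p-value combination
# statistics with their classical null distributions. Stage 3
# (flag_outliers): thresholding of the combined p-values; removal of the
# flagged lines from the training set is performed by the evaluation module.

BASE_TEST_NAMES <- c("oof_normal", "oof_student", "rank_mahalanobis")

#' Per-observation base p-values from cross-validated residual diagnostics
#'
#' Fits REML GBLUP in an inner k-fold cross-validation over the training
#' lines to obtain an out-of-fold prediction for every training observation,
#' then converts the residuals into three two-sided p-values per line:
#' \enumerate{
#'   \item residual standardized by median/MAD, referred to N(0, 1);
#'   \item studentized residual (centered and scaled by the residual SD)
#'     referred to t with m - 2 degrees of freedom, m being the inner-fold
#'     training size;
#'   \item a rank-based Mahalanobis distance of the (observed, predicted)
#'     pair — normal scores of the ranks, quadratic form with their
#'     correlation — referred to chi-square with 2 df.
#' }
#' All p-values are floored at 1e-300.
#'
#' @param phenotypes_train Named numeric vector over the training lines.
#' @param grm A [compute_grm()] result covering at least those lines.
#' @param n_inner_folds Inner CV folds (default 5).
#' @param seed Seed for the inner fold assignment.
#' @return Numeric matrix (n_train x 3) of p-values in (0, 1], rownames =
#'   line IDs, colnames = the base-test labels.
#' @export
base_pvalues <- function(phenotypes_train, grm, n_inner_folds = 5L,
                         seed = 1L) {
  ids <- names(phenotypes_train)
  n <- length(phenotypes_train)
  if (n < 10L) {
    stop("need at least 10 training lines for outlier diagnostics",
         call. = FALSE)
  }
  y <- as.numeric(phenotypes_train)

  fold_of <- with_seed(seed, sample(rep_len(seq_len(n_inner_folds), n)))
  yhat <- numeric(n)
  m_sizes <- integer(n_inner_folds)
  for (f in seq_len(n_inner_folds)) {
    hold <- which(fold_of == f)
    keep <- which(fold_of != f)
    m_sizes[f] <- length(keep)
    sp <- train_test_split(ids[keep], ids[hold])
    fit <- fit_gblup(phenotypes_train, grm, sp, method = "reml")
    yhat[hold] <- fit$predictions[ids[hold]]
  }
  r <- y - yhat

  s_mad <- stats::mad(r)
  if (s_mad < .Machine$double.eps) {
    stop("residual MAD is zero (degenerate phenotypes); diagnostics undefined",
         call. = FALSE)
  }
  z <- (r - stats::median(r)) / s_mad
  p1 <- 2 * stats::pnorm(-abs(z))

  m <- floor(mean(m_sizes))
  s <- (r - mean(r)) / stats::sd(r)
  p2 <- 2 * stats::pt(-abs(s), df = m - 2)

  z1 <- stats::qnorm((rank(y) - 0.5) / n)
  z2 <- stats::qnorm((rank(yhat) - 0.5) / n)
  rho <- stats::cor(z1, z2)
  rho <- max(min(rho, 1 - 1e-12), -(1 - 1e-12))
  d2 <- (z1^2 - 2 * rho * z1 * z2 + z2^2) / (1 - rho^2)
  p3 <- stats::pchisq(d2, df = 2, lower.tail = FALSE)

  P <- cbind(p1, p2, p3)
  P <- pmin(pmax(P, P_FLOOR), 1)
  dimnames(P) <- list(ids, BASE_TEST_NAMES)
  P
}

# Coerce a vector row to a 1 x K matrix and validate.
as_pmatrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  if (ncol(p) < 2L) {
    stop("p-value combination requires K >= 2 tests", call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p
}

combined_result <- function(method, statistic, combined_p, df_or_null,
                            ids = NULL, weights = NULL) {
  if (!is.null(ids)) {
    names(statistic) <- ids
    names(combined_p) <- ids
  }
  structure(
    list(method = method, statistic = statistic,
         combined_p = pmin(pmax(combined_p, 0), 1),
         weights = weights, df_or_null = df_or_null),
    class = "combined_outlier_result"
  )
}

#' Fisher's inverse chi-square combination
#'
#' L = sum_k -2 log p_k, referred to the upper tail of chi-square with 2K df.
#'
#' @param p Numeric vector of K p-values (one observation) or an n x K
#'   matrix (rowwise combination).
#' @return A `combined_outlier_result` with per-row `statistic` and
#'   `combined_p`.
#' @export
combine_invchi <- function(p) {
  p <- as_pmatrix(p)
  K <- ncol(p)
  L <- rowSums(-2 * log(clip_pvalues(p)))
  combined_result("invchi", L,
                  stats::pchisq(L, df = 2 * K, lower.tail = FALSE),
                  sprintf("chi2_%d", 2 * K), rownames(p))
}

#' Mudholkar-George logit combination
#'
#' Raw statistic S = sum_k log(p_k / (1 - p_k)); the test statistic is
#' T = -S / C with the scaling constant
#' C = sqrt(K pi^2 (5K + 2) / (3 (5K + 4))), referred to the upper tail of
#' t with 5K + 4 df. (The scaling is required for the statistic to follow
#' that null.)
#'
#' @inheritParams combine_invchi
#' @return A `combined_outlier_result`.
#' @export
combine_logit <- function(p) {
  p <- as_pmatrix(p)
  K <- ncol(p)
  S <- rowSums(log(clip_pvalues(p) / (1 - clip_pvalues(p))))
  C <- sqrt(K * pi^2 * (5 * K + 2) / (3 * (5 * K + 4)))
  Tstat <- -S / C
  combined_result("logit", Tstat,
                  stats::pt(Tstat, df = 5 * K + 4, lower.tail = FALSE),
                  sprintf("t_%d", 5 * K + 4), rownames(p))
}

#' Edgington mean-p combination
#'
#' W = (0.5 - mean(p)) sqrt(12 K), referred to the upper tail of N(0, 1)
#' (CLT approximation to the sum of uniforms).
#'
#' @inheritParams combine_invchi
#' @return A `combined_outlier_result`.
#' @export
combine_meanp <- function(p) {
  p <- as_pmatrix(p)
  K <- ncol(p)
  W <- (0.5 - rowMeans(p)) * sqrt(12 * K)
  combined_result("meanp", W, stats::pnorm(W, lower.tail = FALSE),
                  "N(0,1)", rownames(p))
}

#' Stouffer sum-Z combination
#'
#' Z = sum_k w_k z(p_k) / sqrt(sum_k w_k^2) with z(p) = qnorm(1 - p),
#' referred to the upper tail of N(0, 1). Default weights are all 1; the
#' statistic is invariant to rescaling all weights by a common factor.
#'
#' @inheritParams combine_invchi
#' @param weights Positive weights of length K (recycled default 1).
#' @return A `combined_outlier_result`.
#' @export
combine_sumz <- function(p, weights = NULL) {
  p <- as_pmatrix(p)
  K <- ncol(p)
  if (is.null(weights)) weights <- rep(1, K)
  if (length(weights) != K || any(weights <= 0)) {
    stop("`weights` must be K positive reals", call. = FALSE)
  }
  z <- stats::qnorm(1 - clip_pvalues(p))
  Z <- drop(z %*% weights) / sqrt(sum(weights^2))
  combined_result("sumz", Z, stats::pnorm(Z, lower.tail = FALSE),
                  "N(0,1)", rownames(p), weights)
}

#' Combine a p-value matrix with a named method
#'
#' @param p n x K p-value matrix.
#' @param method One of `"invchi"`, `"logit"`, `"meanp"`, `"sumz"`.
#' @param weights Optional weights (sum-Z only).
#' @return A `combined_outlier_result`.
#' @export
combine_pvalues <- function(p, method = c("invchi", "logit", "meanp", "sumz"),
                            weights = NULL) {
  method <- match.arg(method)
  switch(method,
         invchi = combine_invchi(p),
         logit = combine_logit(p),
         meanp = combine_meanp(p),
         sumz = combine_sumz(p, weights))
}

#' Flag influential observations by thresholding combined p-values
#'
#' @param combined Either a `combined_outlier_result` or a named numeric
#'   vector of combined p-values.
#' @param alpha Significance threshold (default 0.01, unadjusted); lines
#'   with combined p < alpha are flagged.
#' @param adjust Optional multiple-testing adjustment applied before
#'   thresholding (`"none"`, `"bonferroni"`, `"BH"`).
#' @return An `outlier_report`: `flagged_ids`, `alpha`, `proportion_flagged`,
#'   `method`, and the (possibly adjusted) per-line p-values.
#' @export
flag_outliers <- function(combined, alpha = 0.01,
                          adjust = c("none", "bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot_scalar_prob(alpha, "alpha")
  if (inherits(combined, "combined_outlier_result")) {
    pvals <- combined$combined_p
    method <- combined$method
  } else {
    pvals <- combined
    method <- "unspecified"
  }
  if (is.null(names(pvals))) {
    names(pvals) <- sprintf("obs%04d", seq_along(pvals))
  }
  padj <- if (adjust == "none") pvals else stats::p.adjust(pvals, adjust)
  flagged <- names(padj)[padj < alpha]
  structure(
    list(flagged_ids = flagged,
         alpha = alpha,
         adjust = adjust,
         proportion_flagged = length(flagged) / length(pvals),
         method = method,
         pvalues = padj),
    class = "outlier_report"
  )
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Outlier report (%s, alpha = %g, adjust = %s): %d/%d flagged (%.1f%%)\n",
              x$method, x$alpha, x$adjust, length(x$flagged_ids),
              length(x$pvalues), 100 * x$proportion_flagged))
  invisible(x)
}
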