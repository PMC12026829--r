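# GBLUP mixed-model engine.
#
# Model: y_i = mu + g_i + e_i with g ~ N(0, sigma_g^2 G) and
# e ~ N(0, sigma^2 I). Two fitting paths share one eigendecomposition-based
# parameterization:
#   * REML: profile restricted likelihood over the variance ratio
#     delta = sigma^2 / sigma_g^2 on the training block of G; test lines are
#     predicted by the conditional mean
#     g_test = G_ts (G_tt + delta I)^-1 (y_train - mu).
#   * Gibbs: scaled-inverse-chi-square priors on both variances, test
#     phenotypes treated as missing and imputed each iteration, predictions
#     are posterior means of mu + g_i.

#' Sampler / optimizer settings for [fit_gblup()]
#'
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Discarded initial iterations (must be < `n_iter`).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param df_prior Degrees of freedom of the scaled-inverse-chi-square priors
#'   on both variance components.
#' @param r2 Prior partition of the phenotypic variance: each prior's mode is
#'   set to `r2` (genetic) and `1 - r2` (residual) times the training
#'   phenotypic variance.
#' @param seed Seed for the Gibbs chain.
#' @return A list of class `gblup_settings`.
#' @export
gblup_settings <- function(n_iter = 12000L, burn_in = 2000L, thin = 5L,
                           df_prior = 5, r2 = 0.5, seed = 1L) {
  if (burn_in >= n_iter) {
    stop("`burn_in` must be smaller than `n_iter`", call. = FALSE)
  }
  if (thin < 1L) stop("`thin` must be >= 1", call. = FALSE)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), df_prior = df_prior, r2 = r2,
                 seed = as.integer(seed)),
            class = "gblup_settings")
}

#' Train/test split of line identifiers
#'
#' @param train_ids,test_ids Disjoint, non-empty character vectors of line
#'   IDs that together cover the dataset under analysis.
#' @return A list of class `train_test_split`.
#' @export
train_test_split <- function(train_ids, test_ids) {
  train_ids <- as.character(train_ids)
  test_ids <- as.character(test_ids)
  if (length(train_ids) == 0L || length(test_ids) == 0L) {
    stop("train and test sets must both be non-empty", call. = FALSE)
  }
  if (length(intersect(train_ids, test_ids)) > 0L) {
    stop("train and test sets overlap", call. = FALSE)
  }
  structure(list(train_ids = train_ids, test_ids = test_ids),
            class = "train_test_split")
}

# REML profile restricted log-likelihood for the transformed model
# (eigenbasis of the training-block G). Returns the components needed to
# finish the fit at the optimum.
reml_profile <- function(log_delta, d, ys, xs) {
  delta <- exp(log_delta)
  v <- d + delta
  xx <- sum(xs^2 / v)
  mu <- sum(xs * ys / v) / xx
  r <- ys - mu * xs
  n <- length(ys)
  sg2 <- sum(r^2 / v) / (n - 1)
  ll <- -0.5 * ((n - 1) * log(sg2) + sum(log(v)) + log(xx) + (n - 1))
  list(loglik = ll, mu = mu, sg2 = sg2, delta = delta)
}

#' Fit the GBLUP model and predict held-out lines
#'
#' @param phenotypes Named numeric vector of phenotypes; must cover
#'   `split$train_ids` (values for other lines are ignored).
#' @param grm A [compute_grm()] result covering all lines in `split`.
#' @param split A [train_test_split()].
#' @param method `"reml"` (default; deterministic) or `"gibbs"`.
#' @param settings A [gblup_settings()] (used by the Gibbs path; its `seed`
#'   also seeds the chain).
#' @param variance_components Optional `c(sigma_g2, sigma_e2)`; when given,
#'   the REML search is skipped and BLUP is computed at these fixed values
#'   (used e.g. to check the ridge-regression equivalence).
#' @return An object of class `gblup_fit`: `mu_hat`, `sigma_g2`, `sigma_e2`,
#'   `g_hat` (all lines), `predictions` (mu_hat + g_hat for all lines,
#'   including unobserved ones), `method`, `loglik` (REML only),
#'   `mcmc_diagnostics` (Gibbs only), and the split.
#' @export
fit_gblup <- function(phenotypes, grm, split,
                      method = c("reml", "gibbs"),
                      settings = gblup_settings(),
                      variance_components = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(grm, "gblupqm_grm"), inherits(split, "train_test_split"))
  all_ids <- grm$line_ids
  if (!all(split$train_ids %in% all_ids) || !all(split$test_ids %in% all_ids)) {
    stop("split refers to line IDs absent from the GRM", call. = FALSE)
  }
  y <- phenotypes[split$train_ids]
  if (anyNA(y) || any(!is.finite(y))) {
    stop("training phenotypes must be finite and present for all train IDs",
         call. = FALSE)
  }
  if (method == "reml") {
    fit_gblup_reml(y, grm, split, variance_components)
  } else {
    fit_gblup_gibbs(y, grm, split, settings)
  }
}

fit_gblup_reml <- function(y, grm, split, variance_components = NULL) {
  Greg <- grm_regularized(grm)
  tr <- split$train_ids
  Gtt <- Greg[tr, tr, drop = FALSE]
  eg <- eigen(Gtt, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  n <- length(y)
  ys <- drop(crossprod(U, y))
  xs <- drop(crossprod(U, rep(1, n)))

  if (is.null(variance_components)) {
    if (stats::var(y) < 1e-12) {
      # Degenerate response: no genetic variance identifiable.
      mu <- mean(y)
      sg2 <- 0
      se2 <- max(stats::var(y), .Machine$double.eps)
      g_all <- stats::setNames(rep(0, length(grm$line_ids)), grm$line_ids)
      return(new_gblup_fit(mu, sg2, se2, g_all, "reml", split,
                           loglik = NA_real_))
    }
    opt <- stats::optimize(function(ld) reml_profile(ld, d, ys, xs)$loglik,
                           interval = c(-12, 12), maximum = TRUE,
                           tol = 1e-8)
    prof <- reml_profile(opt$maximum, d, ys, xs)
    mu <- prof$mu
    sg2 <- prof$sg2
    delta <- prof$delta
    se2 <- sg2 * delta
    loglik <- prof$loglik
  } else {
    sg2 <- variance_components[1]
    se2 <- variance_components[2]
    if (sg2 <= 0) stop("fixed sigma_g2 must be positive", call. = FALSE)
    delta <- se2 / sg2
    v <- d + delta
    mu <- sum(xs * ys / v) / sum(xs^2 / v)
    loglik <- NA_real_
  }

  # alpha = (G_tt + delta I)^-1 (y - mu); g = G[, train] alpha for all lines.
  r <- ys - mu * xs
  alpha <- drop(U %*% (r / (d + delta)))
  g_all <- drop(Greg[, tr, drop = FALSE] %*% alpha)
  names(g_all) <- grm$line_ids
  new_gblup_fit(mu, sg2, se2, g_all, "reml", split, loglik = loglik)
}

fit_gblup_gibbs <- function(y, grm, split, settings) {
  stopifnot(inherits(settings, "gblup_settings"))
  Greg <- grm_regularized(grm)
  all_ids <- grm$line_ids
  n_all <- length(all_ids)
  tr_idx <- match(split$train_ids, all_ids)
  te_idx <- setdiff(seq_len(n_all), tr_idx)

  eg <- eigen(Greg, symmetric = TRUE)
  d <- pmax(eg$values, 1e-10)
  U <- eg$vectors

  vy <- stats::var(y)
  if (vy < 1e-12) vy <- 1e-12
  df0 <- settings$df_prior
  # Scale chosen so each prior's mode equals its share of phenotypic variance
  # (mode of scaled-inv-chi2(df, S) is df * S / (df + 2)).
  Sg <- settings$r2 * vy * (df0 + 2) / df0
  Se <- (1 - settings$r2) * vy * (df0 + 2) / df0

  keep <- seq(settings$burn_in + settings$thin, settings$n_iter,
              by = settings$thin)
  n_keep <- length(keep)

  res <- with_seed(settings$seed, {
    yc <- numeric(n_all)
    yc[tr_idx] <- y
    mu <- mean(y)
    yc[te_idx] <- mu
    sg2 <- settings$r2 * vy
    se2 <- (1 - settings$r2) * vy
    a <- numeric(n_all)
    g <- numeric(n_all)

    sum_mu <- 0; sum_sg2 <- 0; sum_se2 <- 0
    sum_g <- numeric(n_all)
    kept <- 0L

    for (it in seq_len(settings$n_iter)) {
      # intercept
      mu <- stats::rnorm(1, mean(yc - g), sqrt(se2 / n_all))
      # genetic values on the eigenbasis: y - mu = U a + e
      yt <- drop(crossprod(U, yc - mu))
      c_i <- sg2 * d / (sg2 * d + se2)
      a <- stats::rnorm(n_all, c_i * yt, sqrt(c_i * se2))
      g <- drop(U %*% a)
      # variance components
      sse <- sum((yc - mu - g)^2)
      se2 <- (sse + df0 * Se) / stats::rchisq(1, df0 + n_all)
      ssa <- sum(a^2 / d)
      sg2 <- (ssa + df0 * Sg) / stats::rchisq(1, df0 + n_all)
      # impute missing (test) phenotypes
      if (length(te_idx) > 0) {
        yc[te_idx] <- mu + g[te_idx] +
          stats::rnorm(length(te_idx), 0, sqrt(se2))
      }
      if (it > settings$burn_in &&
          (it - settings$burn_in) %% settings$thin == 0L) {
        kept <- kept + 1L
        sum_mu <- sum_mu + mu
        sum_sg2 <- sum_sg2 + sg2
        sum_se2 <- sum_se2 + se2
        sum_g <- sum_g + g
      }
    }
    list(mu = sum_mu / kept, sg2 = sum_sg2 / kept, se2 = sum_se2 / kept,
         g = sum_g / kept, kept = kept)
  })

  g_all <- stats::setNames(res$g, all_ids)
  fit <- new_gblup_fit(res$mu, res$sg2, res$se2, g_all, "gibbs", split)
  fit$mcmc_diagnostics <- list(n_iter = settings$n_iter,
                               burn_in = settings$burn_in,
                               thin = settings$thin,
                               n_saved = res$kept)
  fit
}

new_gblup_fit <- function(mu, sg2, se2, g_all, method, split,
                          loglik = NA_real_) {
  structure(
    list(mu_hat = mu,
         sigma_g2 = max(sg2, 0),
         sigma_e2 = se2,
         g_hat = g_all,
         predictions = mu + g_all,
         method = method,
         loglik = loglik,
         mcmc_diagnostics = list(),
         train_ids = split$train_ids,
         test_ids = split$test_ids),
    class = "gblup_fit"
  )
}

#' @export
print.gblup_fit <- function(x, ...) {
  h2 <- x$sigma_g2 / (x$sigma_g2 + x$sigma_e2)
  cat(sprintf("GBLUP fit (%s): mu = %.4f, sigma_g2 = %.4f, sigma_e2 = %.4f, h2 = %.3f\n",
              x$method, x$mu_hat, x$sigma_g2, x$sigma_e2, h2))
  cat(sprintf("%d training lines, %d predicted lines\n",
              length(x$train_ids), length(x$predictions)))
  invisible(x)
}

#' Estimated narrow-sense heritability from a fit
#'
#' @param fit A `gblup_fit`.
#' @return sigma_g2 / (sigma_g2 + sigma_e2).
#' @export
heritability <- function(fit) {
  fit$sigma_g2 / (fit$sigma_g2 + fit$sigma_e2)
}

#' Ridge-regression (RR-BLUP) predictions on centered markers
#'
#' Ridge regression of the training phenotypes on the dosage matrix centered
#' by twice the full-data allele frequencies, with penalty `lambda`; the
#' intercept is the GLS estimate under the implied covariance. With
#' `lambda = (sigma_e2 / sigma_g2) * 2 * sum p (1 - p)` this reproduces the
#' fixed-variance GBLUP predictions built from the VanRaden G on the same
#' markers — the classical GBLUP / RR-BLUP equivalence, used here as an
#' independent check of the mixed-model engine.
#'
#' @param markers Dosage matrix covering all lines in `split`.
#' @param phenotypes Named numeric vector covering `split$train_ids`.
#' @param split A [train_test_split()].
#' @param lambda Positive ridge penalty.
#' @return Named numeric vector of predictions (intercept + marker score) for
#'   every line in `markers`.
#' @export
predict_rrblup <- function(markers, phenotypes, split, lambda) {
  stopifnot(lambda >= 0, inherits(split, "train_test_split"))
  p <- allele_frequencies(markers)
  poly <- p > 0 & p < 1
  W <- sweep(markers[, poly, drop = FALSE], 2L, 2 * p[poly], "-")
  tr <- split$train_ids
  Wt <- W[tr, , drop = FALSE]
  y <- phenotypes[tr]
  n <- length(y)
  K <- tcrossprod(Wt) + diag(lambda, n)
  Kinv_1 <- solve(K, rep(1, n))
  Kinv_y <- solve(K, y)
  mu <- sum(Kinv_y) / sum(Kinv_1)
  b <- drop(crossprod(Wt, solve(K, y - mu)))
  preds <- mu + drop(W %*% b)
  names(preds) <- rownames(markers)
  preds
}
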