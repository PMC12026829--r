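# Cross-validated evaluation of the ten model variants.
#
# The grid crosses plain GBLUP with (a) quantile-mapping calibration of the
# test predictions and (b) removal of training observations flagged by one
# of the four p-value-combination statistics: GBLUP, QM, Invchi, Logit,
# Meanp, SumZ, QM_Invchi, QM_Logit, QM_Meanp, QM_SumZ. Variants share fold
# splits, the GRM, and — per fold — the base p-value matrix, so paired
# comparisons differ only in the stage under study.

#' The ten model variants
#'
#' @return A data.frame with columns `name`, `uses_qm`, `outlier_method`.
#' @export
model_variants <- function() {
  om <- c("none", "invchi", "logit", "meanp", "sumz")
  plain <- c("GBLUP", "Invchi", "Logit", "Meanp", "SumZ")
  qm <- c("QM", "QM_Invchi", "QM_Logit", "QM_Meanp", "QM_SumZ")
  data.frame(
    name = c(plain, qm),
    uses_qm = rep(c(FALSE, TRUE), each = 5L),
    outlier_method = rep(om, 2L),
    stringsAsFactors = FALSE
  )
}

#' Repeated train/test partitions
#'
#' Monte Carlo cross-validation: `n_reps` independent seeded random splits,
#' each holding out `test_fraction` of the lines (the default emulates
#' repeated 80/20 splitting). A standard k-fold scheme (folds partitioning
#' the lines, k = round(1 / test_fraction)) is available via `scheme`.
#'
#' @param line_ids Character vector of line identifiers.
#' @param n_reps Number of splits (default 10; ignored by `"kfold"`, which
#'   produces k folds).
#' @param test_fraction Fraction held out per split (default 0.2).
#' @param master_seed Master seed; per-split seeds derive from it.
#' @param scheme `"mc"` (default) or `"kfold"`.
#' @return A `fold_assignment`: list of [train_test_split()]s plus the
#'   settings.
#' @export
make_partitions <- function(line_ids, n_reps = 10L, test_fraction = 0.2,
                            master_seed = 1L, scheme = c("mc", "kfold")) {
  scheme <- match.arg(scheme)
  line_ids <- as.character(line_ids)
  n <- length(line_ids)
  if (n < 5L) stop("too few lines to partition", call. = FALSE)
  stopifnot_scalar_prob(test_fraction, "test_fraction", 0.01, 0.5)

  splits <- if (scheme == "mc") {
    n_test <- max(1L, round(test_fraction * n))
    seeds <- derive_seeds(master_seed, n_reps)
    lapply(seq_len(n_reps), function(i) {
      test <- with_seed(seeds[i], sample(line_ids, n_test))
      train_test_split(setdiff(line_ids, test), test)
    })
  } else {
    k <- max(2L, round(1 / test_fraction))
    fold_of <- with_seed(master_seed, sample(rep_len(seq_len(k), n)))
    lapply(seq_len(k), function(f) {
      train_test_split(line_ids[fold_of != f], line_ids[fold_of == f])
    })
  }
  structure(list(splits = splits, n_reps = length(splits),
                 test_fraction = test_fraction, master_seed = master_seed,
                 scheme = scheme),
            class = "fold_assignment")
}

#' Pearson correlation between observed and predicted values
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2).
#' @return The sample correlation, or `NA` (with a warning) when either
#'   vector is constant — such folds are excluded from averages.
#' @export
pearson_cor <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  if (stats::sd(observed) < 1e-14 || stats::sd(predicted) < 1e-14) {
    warning("constant vector: Pearson correlation undefined, returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(observed, predicted)
}

#' Normalized root mean square error
#'
#' RMSE divided by a scale of the observed values: their mean (default),
#' standard deviation, or range.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @param normalization `"mean"`, `"sd"` or `"range"`.
#' @return Non-negative scalar.
#' @export
nrmse <- function(observed, predicted,
                  normalization = c("mean", "sd", "range")) {
  normalization <- match.arg(normalization)
  stopifnot(length(observed) == length(predicted), length(observed) >= 1L)
  rmse <- sqrt(mean((observed - predicted)^2))
  denom <- switch(normalization,
                  mean = mean(observed),
                  sd = stats::sd(observed),
                  range = diff(range(observed)))
  if (!is.finite(denom) || denom <= 0) {
    stop(sprintf(
      "NRMSE normalizer '%s' of the observed values is %.3g (not positive); choose another normalization",
      normalization, denom), call. = FALSE)
  }
  rmse / denom
}

#' Relative efficiency in correlation, percent
#'
#' `100 * (cor_ref - cor_other) / cor_other`: how much greater the reference
#' method's correlation is than the comparison method's, in percent of the
#' comparison value.
#'
#' @param cor_ref,cor_other Correlations of the reference and comparison
#'   methods.
#' @return Percent difference.
#' @export
relative_efficiency_cor <- function(cor_ref, cor_other) {
  100 * (cor_ref - cor_other) / cor_other
}

#' Relative efficiency in NRMSE, percent
#'
#' `100 * (nrmse_other - nrmse_ref) / nrmse_ref`: how much larger the
#' comparison method's error is than the reference method's, in percent of
#' the reference value.
#'
#' @param nrmse_ref,nrmse_other NRMSE of the reference and comparison
#'   methods.
#' @return Percent difference.
#' @export
relative_efficiency_nrmse <- function(nrmse_ref, nrmse_other) {
  100 * (nrmse_other - nrmse_ref) / nrmse_ref
}

#' Evaluation settings
#'
#' @param engine `"reml"` (deterministic; default) or `"gibbs"`.
#' @param gblup [gblup_settings()] for the Gibbs path.
#' @param alpha Outlier threshold passed to [flag_outliers()].
#' @param adjust Multiple-testing adjustment for the combined p-values.
#' @param n_knots,extrapolation_policy Quantile-mapping settings
#'   (see [build_transfer()]).
#' @param n_inner_folds Inner CV folds for [base_pvalues()].
#' @param nrmse_normalization Normalizer for [nrmse()].
#' @param min_train Folds whose filtered training set falls below this size
#'   are marked failed and excluded from averages.
#' @param sumz_weights Optional weights for the sum-Z combiner.
#' @return A list of class `eval_settings`.
#' @export
eval_settings <- function(engine = c("reml", "gibbs"),
                          gblup = gblup_settings(),
                          alpha = 0.01,
                          adjust = "none",
                          n_knots = NULL,
                          extrapolation_policy = "constant_offset",
                          n_inner_folds = 5L,
                          nrmse_normalization = "mean",
                          min_train = 10L,
                          sumz_weights = NULL) {
  engine <- match.arg(engine)
  structure(list(engine = engine, gblup = gblup, alpha = alpha,
                 adjust = adjust, n_knots = n_knots,
                 extrapolation_policy = extrapolation_policy,
                 n_inner_folds = as.integer(n_inner_folds),
                 nrmse_normalization = nrmse_normalization,
                 min_train = as.integer(min_train),
                 sumz_weights = sumz_weights),
            class = "eval_settings")
}

# Fit GBLUP on a (possibly reduced) training set and return predictions for
# the test lines and for the full original training set of the fold.
fit_stage <- function(phenotypes, grm, train_ids, test_ids, settings,
                      fold_seed) {
  sp <- train_test_split(train_ids, test_ids)
  gs <- settings$gblup
  gs$seed <- fold_seed
  fit_gblup(phenotypes, grm, sp, method = settings$engine, settings = gs)
}

#' Run one model variant on one fold
#'
#' Pipeline order: (a) if the variant filters, compute base p-values on the
#' training fold, combine them, and remove flagged lines from the training
#' set; (b) fit GBLUP on the (possibly reduced) training set, predicting the
#' test set and the training set; (c) if the variant calibrates, build the
#' quantile-mapping transfer from this fit's training (predicted, observed)
#' pairs and apply it to the test predictions; (d) score COR and NRMSE on
#' the test set.
#'
#' @param variant One row of [model_variants()] (or a variant name).
#' @param phenotypes Named numeric vector covering all lines in the split.
#' @param grm A [compute_grm()] result.
#' @param split A [train_test_split()].
#' @param settings An [eval_settings()].
#' @param fold_seed Seed for the fold's stochastic stages.
#' @return A one-row data.frame: `variant`, `cor`, `nrmse`, `n_train`,
#'   `n_removed`, `failed`.
#' @export
run_variant <- function(variant, phenotypes, grm, split,
                        settings = eval_settings(), fold_seed = 1L) {
  if (is.character(variant)) {
    mv <- model_variants()
    i <- match(variant, mv$name)
    if (is.na(i)) stop(sprintf("unknown variant '%s'", variant), call. = FALSE)
    variant <- mv[i, ]
  }
  train_ids <- split$train_ids
  n_removed <- 0L
  if (variant$outlier_method != "none") {
    P <- base_pvalues(phenotypes[train_ids], grm,
                      n_inner_folds = settings$n_inner_folds,
                      seed = fold_seed)
    comb <- combine_pvalues(P, variant$outlier_method,
                            weights = settings$sumz_weights)
    report <- flag_outliers(comb, alpha = settings$alpha,
                            adjust = settings$adjust)
    train_ids <- setdiff(train_ids, report$flagged_ids)
    n_removed <- length(report$flagged_ids)
  }
  if (length(train_ids) < settings$min_train) {
    return(data.frame(variant = variant$name, cor = NA_real_,
                      nrmse = NA_real_, n_train = length(train_ids),
                      n_removed = n_removed, failed = TRUE,
                      stringsAsFactors = FALSE))
  }
  fit <- fit_stage(phenotypes, grm, train_ids, split$test_ids, settings,
                   fold_seed)
  pred_test <- fit$predictions[split$test_ids]
  if (variant$uses_qm) {
    tf <- build_transfer(phenotypes[train_ids], fit$predictions[train_ids],
                         n_knots = settings$n_knots,
                         extrapolation_policy = settings$extrapolation_policy)
    pred_test <- apply_transfer(tf, pred_test)
  }
  obs_test <- phenotypes[split$test_ids]
  data.frame(variant = variant$name,
             cor = pearson_cor(obs_test, pred_test),
             nrmse = nrmse(obs_test, pred_test,
                           settings$nrmse_normalization),
             n_train = length(train_ids),
             n_removed = n_removed,
             failed = FALSE,
             stringsAsFactors = FALSE)
}

#' Run the full model grid over all folds
#'
#' All ten variants share each fold's split, the GRM, and the base p-value
#' matrix (so e.g. SumZ and QM_SumZ remove identical training lines); each
#' distinct filtered training set is fitted once per fold and reused by the
#' calibrated and uncalibrated variants.
#'
#' @param phenotypes Named numeric vector over all lines.
#' @param grm A [compute_grm()] result.
#' @param folds A [make_partitions()] result.
#' @param settings An [eval_settings()].
#' @param dataset Label recorded in the output rows.
#' @param variants Optional subset of variant names.
#' @return An `evaluation_table`: `folds` (long data.frame dataset, variant,
#'   fold, cor, nrmse, n_train, n_removed, failed) and `summary`
#'   (per-variant fold-averages, failed/constant folds excluded).
#' @export
run_grid <- function(phenotypes, grm, folds, settings = eval_settings(),
                     dataset = "dataset", variants = NULL) {
  stopifnot(inherits(folds, "fold_assignment"))
  mv <- model_variants()
  if (!is.null(variants)) {
    if (!all(variants %in% mv$name)) {
      stop("unknown variant name(s): ",
           paste(setdiff(variants, mv$name), collapse = ", "), call. = FALSE)
    }
    mv <- mv[mv$name %in% variants, , drop = FALSE]
  }
  fold_seeds <- derive_seeds(folds$master_seed + 1L, folds$n_reps)
  need_pvals <- any(mv$outlier_method != "none")

  rows <- vector("list", folds$n_reps)
  for (f in seq_len(folds$n_reps)) {
    split <- folds$splits[[f]]
    fseed <- fold_seeds[f]

    # Stage shared across variants: one base p-value matrix per fold.
    flagged <- list(none = character(0))
    if (need_pvals) {
      P <- base_pvalues(phenotypes[split$train_ids], grm,
                        n_inner_folds = settings$n_inner_folds,
                        seed = fseed)
      for (om in unique(mv$outlier_method[mv$outlier_method != "none"])) {
        comb <- combine_pvalues(P, om, weights = settings$sumz_weights)
        report <- flag_outliers(comb, alpha = settings$alpha,
                                adjust = settings$adjust)
        flagged[[om]] <- report$flagged_ids
      }
    }

    # One GBLUP fit per distinct filtered training set.
    fits <- list()
    fold_rows <- vector("list", nrow(mv))
    for (v in seq_len(nrow(mv))) {
      om <- mv$outlier_method[v]
      train_ids <- setdiff(split$train_ids, flagged[[om]])
      n_removed <- length(split$train_ids) - length(train_ids)
      if (length(train_ids) < settings$min_train) {
        fold_rows[[v]] <- data.frame(
          dataset = dataset, variant = mv$name[v], fold = f,
          cor = NA_real_, nrmse = NA_real_, n_train = length(train_ids),
          n_removed = n_removed, failed = TRUE, stringsAsFactors = FALSE)
        next
      }
      if (is.null(fits[[om]])) {
        fits[[om]] <- fit_stage(phenotypes, grm, train_ids, split$test_ids,
                                settings, fseed)
      }
      fit <- fits[[om]]
      pred_test <- fit$predictions[split$test_ids]
      if (mv$uses_qm[v]) {
        tf <- build_transfer(phenotypes[train_ids],
                             fit$predictions[train_ids],
                             n_knots = settings$n_knots,
                             extrapolation_policy =
                               settings$extrapolation_policy)
        pred_test <- apply_transfer(tf, pred_test)
      }
      obs_test <- phenotypes[split$test_ids]
      fold_rows[[v]] <- data.frame(
        dataset = dataset, variant = mv$name[v], fold = f,
        cor = pearson_cor(obs_test, pred_test),
        nrmse = nrmse(obs_test, pred_test, settings$nrmse_normalization),
        n_train = length(train_ids), n_removed = n_removed, failed = FALSE,
        stringsAsFactors = FALSE)
    }
    rows[[f]] <- do.call(rbind, fold_rows)
  }
  long <- do.call(rbind, rows)
  rownames(long) <- NULL
  new_evaluation_table(long, settings, folds)
}

new_evaluation_table <- function(long, settings = NULL, folds = NULL) {
  ok <- !long$failed & !is.na(long$cor)
  summary <- do.call(rbind, lapply(split(long[ok, , drop = FALSE],
                                         long$variant[ok]), function(df) {
    data.frame(dataset = df$dataset[1], variant = df$variant[1],
               cor = mean(df$cor), nrmse = mean(df$nrmse),
               n_folds = nrow(df), stringsAsFactors = FALSE)
  }))
  if (!is.null(summary)) {
    summary <- summary[order(match(summary$variant, model_variants()$name)), ]
    rownames(summary) <- NULL
  }
  structure(list(folds = long, summary = summary, settings = settings,
                 fold_assignment = folds),
            class = "evaluation_table")
}

#' @export
print.evaluation_table <- function(x, digits = 4, ...) {
  cat(sprintf("Evaluation over %d fold-rows (%d variants)\n",
              nrow(x$folds), length(unique(x$folds$variant))))
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Average evaluation summaries across datasets
#'
#' Unweighted mean of the per-dataset per-variant fold-averages.
#'
#' @param tables List of `evaluation_table`s (one per dataset).
#' @return An `evaluation_table` whose `summary` holds the across-dataset
#'   means (dataset label `"across"`) and whose `folds` slot stacks the
#'   per-dataset summaries.
#' @export
summarize_across <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, TRUE, "evaluation_table")))
  per <- do.call(rbind, lapply(tables, function(t) t$summary))
  agg <- do.call(rbind, lapply(split(per, per$variant), function(df) {
    data.frame(dataset = "across", variant = df$variant[1],
               cor = mean(df$cor), nrmse = mean(df$nrmse),
               n_folds = sum(df$n_folds), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(match(agg$variant, model_variants()$name)), ]
  rownames(agg) <- NULL
  structure(list(folds = per, summary = agg, settings = NULL,
                 fold_assignment = NULL),
            class = "evaluation_table")
}

#' Narrative relative-efficiency report
#'
#' Renders a plain-text summary of an evaluation: the best variant by COR
#' and by NRMSE, with percent differences to every other variant computed
#' by [relative_efficiency_cor()] and [relative_efficiency_nrmse()].
#'
#' @param table An `evaluation_table`.
#' @return Character vector of report lines (also of class
#'   `evaluation_report`).
#' @export
render_report <- function(table) {
  s <- table$summary
  if (is.null(s) || nrow(s) < 2L) {
    stop("need at least two summarized variants to compare", call. = FALSE)
  }
  lines <- character(0)
  best_cor <- s[which.max(s$cor), ]
  lines <- c(lines, sprintf(
    "Best by correlation: %s (COR = %.4f).", best_cor$variant, best_cor$cor))
  others <- s[s$variant != best_cor$variant, ]
  for (i in seq_len(nrow(others))) {
    lines <- c(lines, sprintf(
      "  %s: COR = %.4f (%s %.4f%% greater than %s)",
      others$variant[i], others$cor[i], best_cor$variant,
      relative_efficiency_cor(best_cor$cor, others$cor[i]),
      others$variant[i]))
  }
  best_nrmse <- s[which.min(s$nrmse), ]
  lines <- c(lines, sprintf(
    "Best by NRMSE: %s (NRMSE = %.4f).", best_nrmse$variant,
    best_nrmse$nrmse))
  others <- s[s$variant != best_nrmse$variant, ]
  for (i in seq_len(nrow(others))) {
    lines <- c(lines, sprintf(
      "  %s: NRMSE = %.4f (%.4f%% worse than %s)",
      others$variant[i], others$nrmse[i],
      relative_efficiency_nrmse(best_nrmse$nrmse, others$nrmse[i]),
      best_nrmse$variant))
  }
  structure(lines, class = c("evaluation_report", "character"))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(x, sep = "\n")
  invisible(x)
}
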