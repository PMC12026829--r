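test_that("Monte Carlo partitions have the right size and determinism", {
  ids <- sprintf("L%03d", 1:100)
  fa <- make_partitions(ids, n_reps = 10, test_fraction = 0.2,
                        master_seed = 5)
  expect_length(fa$splits, 10L)
  for (sp in fa$splits) {
    expect_length(sp$test_ids, 20L)
    expect_setequal(c(sp$train_ids, sp$test_ids), ids)
  }
  fa2 <- make_partitions(ids, n_reps = 10, test_fraction = 0.2,
                         master_seed = 5)
  expect_identical(fa, fa2)
  # independent splits: test sets are not forced to partition the lines
  expect_gt(length(intersect(fa$splits[[1]]$test_ids,
                             fa$splits[[2]]$test_ids)) +
              length(intersect(fa$splits[[2]]$test_ids,
                               fa$splits[[3]]$test_ids)), 0)
})

test_that("k-fold partitions exhaustively cover the lines", {
  ids <- sprintf("L%03d", 1:100)
  fa <- make_partitions(ids, test_fraction = 0.2, master_seed = 6,
                        scheme = "kfold")
  expect_length(fa$splits, 5L)
  expect_setequal(unlist(lapply(fa$splits, `[[`, "test_ids")), ids)
})

test_that("metrics match hand-computed references and guard degeneracy", {
  expect_equal(pearson_cor(1:10, 1:10), 1)
  expect_equal(pearson_cor(1:10, -(1:10)), -1)
  expect_equal(pearson_cor(c(1, 2, 3), c(1, 2, 4)),
               0.9819805, tolerance = 1e-6)
  expect_warning(r <- pearson_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r))

  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nrmse(c(2, 2, 2, 2), c(3, 3, 3, 3)), 0.5)
  # scale invariance of mean- and range-normalized NRMSE
  o <- c(2, 4, 9)
  p <- c(3, 3, 8)
  expect_equal(nrmse(2 * o, 2 * p), nrmse(o, p))
  expect_equal(nrmse(2 * o, 2 * p, "range"), nrmse(o, p, "range"))
  expect_error(nrmse(c(-1, 1), c(0, 0)), "normalization")
})

test_that("relative-efficiency conventions match their definitions", {
  expect_equal(relative_efficiency_cor(0.3, 0.3), 0)
  expect_equal(relative_efficiency_nrmse(0.5, 0.5), 0)
  expect_equal(relative_efficiency_cor(0.22, 0.2), 10)
  expect_equal(relative_efficiency_nrmse(0.2, 0.25), 25)
})

test_that("the model grid has exactly ten coherent variants", {
  mv <- model_variants()
  expect_identical(nrow(mv), 10L)
  expect_identical(sum(mv$uses_qm), 5L)
  expect_setequal(mv$outlier_method,
                  c("none", "invchi", "logit", "meanp", "sumz"))
  expect_true(all(mv$uses_qm == grepl("^QM", mv$name)))
})

test_that("plain variants compose exactly from their stages", {
  ds <- test_dataset(n_lines = 120, n_markers = 300, seed = 19)
  sp <- head_tail_split(names(ds$phenotypes))
  st <- eval_settings()
  row <- run_variant("GBLUP", ds$phenotypes, ds$grm, sp, st, fold_seed = 3)
  fit <- fit_gblup(ds$phenotypes, ds$grm, sp)
  expect_equal(row$cor,
               pearson_cor(ds$phenotypes[sp$test_ids],
                           fit$predictions[sp$test_ids]))
  expect_equal(row$nrmse,
               nrmse(ds$phenotypes[sp$test_ids],
                     fit$predictions[sp$test_ids]))
  expect_identical(row$n_removed, 0L)

  # paired filtered variants share the flagged training lines
  r1 <- run_variant("SumZ", ds$phenotypes, ds$grm, sp, st, fold_seed = 3)
  r2 <- run_variant("QM_SumZ", ds$phenotypes, ds$grm, sp, st, fold_seed = 3)
  expect_identical(r1$n_removed, r2$n_removed)
  expect_identical(r1$n_train, r2$n_train)
})

test_that("an identity transfer leaves QM predictions unchanged", {
  ds <- test_dataset(n_lines = 100, n_markers = 250, seed = 20)
  sp <- head_tail_split(names(ds$phenotypes))
  fit <- fit_gblup(ds$phenotypes, ds$grm, sp)
  tf <- build_transfer(fit$predictions[sp$train_ids],
                       fit$predictions[sp$train_ids])
  expect_equal(apply_transfer(tf, fit$predictions[sp$test_ids]),
               fit$predictions[sp$test_ids], tolerance = 1e-10)
})

test_that("an affine transfer leaves the Pearson correlation unchanged", {
  # single-segment strictly increasing piecewise-linear maps are affine on
  # the probe range, and Pearson correlation is affine-invariant
  tf <- build_transfer(c(10, 30), c(0, 1), n_knots = 2)
  set.seed(33)
  obs <- rnorm(50)
  pred <- obs + rnorm(50)
  inside <- pmin(pmax(pred, 0), 1)
  expect_equal(pearson_cor(obs, apply_transfer(tf, inside)),
               pearson_cor(obs, inside), tolerance = 1e-12)
})

test_that("the full grid is complete, consistent and deterministic", {
  ds <- test_dataset(n_lines = 150, n_markers = 300, seed = 21)
  folds <- make_partitions(names(ds$phenotypes), n_reps = 3,
                           master_seed = 11)
  tab <- run_grid(ds$phenotypes, ds$grm, folds, dataset = "sim")
  expect_identical(nrow(tab$folds), 30L)
  expect_identical(nrow(tab$summary), 10L)
  expect_true(all(tab$folds$cor >= -1 & tab$folds$cor <= 1, na.rm = TRUE))
  expect_true(all(tab$folds$nrmse >= 0, na.rm = TRUE))
  # summary rows equal the mean of their fold rows
  for (v in tab$summary$variant) {
    rows <- tab$folds[tab$folds$variant == v & !tab$folds$failed, ]
    expect_equal(tab$summary$cor[tab$summary$variant == v], mean(rows$cor),
                 tolerance = 1e-12)
    expect_equal(tab$summary$nrmse[tab$summary$variant == v],
                 mean(rows$nrmse), tolerance = 1e-12)
  }
  # filtered pairs share flagged lines within each fold
  for (f in 1:3) {
    a <- tab$folds[tab$folds$fold == f & tab$folds$variant == "Meanp", ]
    b <- tab$folds[tab$folds$fold == f & tab$folds$variant == "QM_Meanp", ]
    expect_identical(a$n_removed, b$n_removed)
  }
  tab2 <- run_grid(ds$phenotypes, ds$grm, folds, dataset = "sim")
  expect_identical(tab$folds, tab2$folds)
})

test_that("with no removals a filtered variant equals plain GBLUP", {
  # the near-equivalence of filtered and unfiltered variants on clean data
  # holds exactly when the threshold flags nothing
  ds <- test_dataset(n_lines = 120, n_markers = 300, seed = 22)
  folds <- make_partitions(names(ds$phenotypes), n_reps = 2,
                           master_seed = 12)
  st <- eval_settings(alpha = 1e-12)
  tab <- run_grid(ds$phenotypes, ds$grm, folds, settings = st,
                  variants = c("GBLUP", "Meanp"))
  expect_true(all(tab$folds$n_removed == 0L))
  expect_equal(tab$summary$cor[tab$summary$variant == "Meanp"],
               tab$summary$cor[tab$summary$variant == "GBLUP"],
               tolerance = 1e-12)
})

test_that("filtering helps under heavy contamination", {
  diffs <- numeric(0)
  for (s in 1:10) {
    cfg <- sim_config(n_lines = 250, n_markers = 500, heritability = 0.5,
                      outlier_fraction = 0.10, outlier_magnitude = 6,
                      seed = 5000 + s)
    ds <- simulate_dataset(cfg)
    grm <- compute_grm(ds$markers)
    folds <- make_partitions(names(ds$phenotypes), n_reps = 2,
                             master_seed = s)
    tab <- run_grid(ds$phenotypes, grm, folds,
                    variants = c("GBLUP", "Invchi", "Logit", "Meanp",
                                 "SumZ"))
    s2 <- tab$summary
    base <- s2$cor[s2$variant == "GBLUP"]
    diffs <- c(diffs, s2$cor[s2$variant != "GBLUP"] - base)
  }
  # every filtered variant should at least not hurt (mean over seeds)
  per_variant <- matrix(diffs, nrow = 4)
  expect_true(all(rowMeans(per_variant) >= -0.02))
})

test_that("across-dataset summaries are unweighted variant means", {
  mk <- function(cor_val, nrmse_val, ds_name) {
    long <- data.frame(dataset = ds_name,
                       variant = c("GBLUP", "QM"), fold = 1L,
                       cor = cor_val, nrmse = nrmse_val,
                       n_train = 10L, n_removed = 0L, failed = FALSE,
                       stringsAsFactors = FALSE)
    gblupqm:::new_evaluation_table(long)
  }
  t1 <- mk(c(0.2, 0.1), c(0.5, 0.6), "d1")
  t2 <- mk(c(0.4, 0.3), c(0.7, 0.8), "d2")
  across <- summarize_across(list(t1, t2))
  expect_equal(across$summary$cor[across$summary$variant == "GBLUP"], 0.3)
  expect_equal(across$summary$cor[across$summary$variant == "QM"], 0.2)
  expect_equal(across$summary$nrmse[across$summary$variant == "GBLUP"], 0.6)
  # single table: across equals that table's averages
  single <- summarize_across(list(t1))
  expect_equal(single$summary$cor, t1$summary$cor)
})

test_that("the narrative report carries the percent differences", {
  long <- data.frame(dataset = "d", variant = c("GBLUP", "QM"), fold = 1L,
                     cor = c(0.1766, 0.1751), nrmse = c(0.4313, 0.5234),
                     n_train = 10L, n_removed = 0L, failed = FALSE,
                     stringsAsFactors = FALSE)
  tab <- gblupqm:::new_evaluation_table(long)
  report <- render_report(tab)
  expect_true(any(grepl("0.8567", report)))
  expect_true(any(grepl("21.354", report)))
})
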