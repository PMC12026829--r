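test_that("combiner statistics match their closed-form null references", {
  # boundary / symmetry cases
  r <- combine_invchi(c(1, 1, 1))
  expect_equal(unname(r$statistic), 0)
  expect_equal(unname(r$combined_p), 1)
  expect_equal(unname(combine_logit(c(0.5, 0.5, 0.5))$combined_p), 0.5)
  expect_equal(unname(combine_meanp(c(0.5, 0.5))$combined_p), 0.5)
  expect_equal(unname(combine_sumz(c(0.5, 0.5, 0.5))$combined_p), 0.5)

  # inverse chi-square against the chi-square survival function, K = 2
  p <- c(0.05, 0.05)
  L <- -2 * (log(0.05) + log(0.05))
  r <- combine_invchi(p)
  expect_equal(unname(r$statistic), L)
  expect_equal(unname(r$combined_p), pchisq(L, df = 4, lower.tail = FALSE))

  # logit with the Mudholkar-George scaling, K = 3 -> t with 19 df
  p <- c(0.01, 0.02, 0.03)
  S <- sum(log(p / (1 - p)))
  C <- sqrt(3 * pi^2 * (5 * 3 + 2) / (3 * (5 * 3 + 4)))
  r <- combine_logit(p)
  expect_equal(unname(r$statistic), -S / C)
  expect_equal(unname(r$combined_p), pt(-S / C, df = 19, lower.tail = FALSE))
  expect_identical(r$df_or_null, "t_19")

  # mean-p: K = 12, pbar = 0.25 gives W = 0.25 * sqrt(144) = 3 exactly
  r <- combine_meanp(rep(0.25, 12))
  expect_equal(unname(r$statistic), 3)
  expect_equal(unname(r$combined_p), pnorm(3, lower.tail = FALSE))

  # sum-Z: four p-values at z = 2 combine to Z = 4 * 2 / sqrt(4) = 4
  p4 <- rep(pnorm(2, lower.tail = FALSE), 4)
  r <- combine_sumz(p4)
  expect_equal(unname(r$statistic), 4, tolerance = 1e-10)
  # weight scale invariance
  r_w <- combine_sumz(p4, weights = rep(7.3, 4))
  expect_equal(r_w$statistic, r$statistic, tolerance = 1e-12)
})

test_that("all four combiners are calibrated and uniform under the null", {
  P <- with_seed(31, matrix(runif(10000 * 5), 10000, 5))
  for (m in c("invchi", "logit", "meanp", "sumz")) {
    cp <- combine_pvalues(P, m)$combined_p
    expect_gt(mean(cp < 0.05), 0.04)
    expect_lt(mean(cp < 0.05), 0.06)
    ks <- max(abs(sort(cp) - (seq_along(cp) - 0.5) / length(cp)))
    expect_lt(ks, 0.02)
  }
})

test_that("combiners are monotone: lowering any p never raises combined p", {
  with_seed(32, {
    for (m in c("invchi", "logit", "meanp", "sumz")) {
      for (i in 1:50) {
        p <- runif(4)
        k <- sample(4, 1)
        p2 <- p
        p2[k] <- p[k] * runif(1)
        expect_lte(unname(combine_pvalues(rbind(p2), m)$combined_p),
                   unname(combine_pvalues(rbind(p), m)$combined_p) + 1e-12)
      }
    }
  })
})

test_that("combiner input validation", {
  expect_error(combine_invchi(0.5), "K >= 2")
  expect_error(combine_invchi(c(0, 0.5)), "p-values")
  expect_error(combine_invchi(c(0.5, 1.2)), "p-values")
  expect_error(combine_sumz(c(0.2, 0.3), weights = c(1, -1)), "weights")
})

test_that("base p-values are near-uniform on clean data", {
  ds <- test_dataset(n_lines = 250, n_markers = 600, seed = 11)
  P <- base_pvalues(ds$phenotypes, ds$grm, seed = 2)
  expect_identical(dim(P), c(250L, 3L))
  expect_true(all(P > 0 & P <= 1))
  for (k in 1:3) {
    expect_gt(mean(P[, k]), 0.45)
    expect_lt(mean(P[, k]), 0.55)
  }
})

test_that("a large shifted observation is detected with high probability", {
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(n_lines = 200, n_markers = 400, heritability = 0.5,
                      seed = 3000 + s)
    ds <- simulate_dataset(cfg)
    grm <- compute_grm(ds$markers)
    y <- ds$phenotypes
    sigma_e <- sqrt(1 - 0.5) * 1
    y[17] <- y[17] + 6 * sigma_e
    P <- base_pvalues(y, grm, seed = s)
    min(P[17, ]) < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("degenerate phenotypes raise an informative diagnostic error", {
  ds <- test_dataset(n_lines = 40, n_markers = 100, seed = 17)
  y <- setNames(rep(5, 40), names(ds$phenotypes))
  expect_error(base_pvalues(y, ds$grm), "MAD|degenerate")
  expect_error(base_pvalues(ds$phenotypes[1:5], ds$grm), "at least 10")
})

test_that("flagging thresholds combined p-values as specified", {
  r0 <- flag_outliers(setNames(c(0.001, 0.2, 0.04), c("a", "b", "c")),
                      alpha = 0)
  expect_length(r0$flagged_ids, 0)
  r <- flag_outliers(setNames(c(0.001, 0.2, 0.04), c("a", "b", "c")),
                     alpha = 0.05)
  expect_setequal(r$flagged_ids, c("a", "c"))
  expect_equal(r$proportion_flagged, 2 / 3)
  # Bonferroni adjustment is available and more conservative
  rb <- flag_outliers(setNames(c(0.001, 0.2, 0.04), c("a", "b", "c")),
                      alpha = 0.05, adjust = "bonferroni")
  expect_setequal(rb$flagged_ids, "a")
})

test_that("contaminated lines are recovered with decent precision and recall", {
  prec <- rec <- numeric(0)
  for (s in 1:20) {
    cfg <- sim_config(n_lines = 300, n_markers = 600, heritability = 0.5,
                      outlier_fraction = 0.05, outlier_magnitude = 5,
                      seed = 4000 + s)
    ds <- simulate_dataset(cfg)
    grm <- compute_grm(ds$markers)
    P <- base_pvalues(ds$phenotypes, grm, seed = s)
    truth <- names(which(ds$true_outlier_flags))
    for (m in c("invchi", "logit", "meanp", "sumz")) {
      r <- flag_outliers(combine_pvalues(P, m))
      tp <- length(intersect(r$flagged_ids, truth))
      prec <- c(prec, tp / max(1, length(r$flagged_ids)))
      rec <- c(rec, tp / length(truth))
    }
  }
  expect_gt(mean(prec), 0.5)
  expect_gt(mean(rec), 0.5)
})

test_that("outlier reports serialize to CSV", {
  ds <- test_dataset(n_lines = 50, n_markers = 150, seed = 18)
  P <- base_pvalues(ds$phenotypes, ds$grm, seed = 4)
  comb <- combine_pvalues(P, "sumz")
  rep <- flag_outliers(comb, alpha = 0.05)
  path <- withr::local_tempfile(fileext = ".csv")
  write_outlier_report(rep, comb, P, path)
  back <- read.csv(path)
  expect_identical(nrow(back), 50L)
  expect_setequal(back$line_id[back$flagged], rep$flagged_ids)
  expect_equal(back$combined_p, unname(comb$combined_p), tolerance = 1e-6)
})
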