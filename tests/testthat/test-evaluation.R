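# synthetic metric blobs emulating solved / unsolved solution clouds
blob_records <- function(n_solved = 40, n_unsolved = 25, rng_seed = 1) {
  phaseseed:::with_rng(rng_seed, {
    data.frame(
      MPE_final = c(stats::rnorm(n_solved, 10, 3), stats::rnorm(n_unsolved, 85, 5)),
      CORR_final = c(stats::rnorm(n_solved, 0.95, 0.02), stats::rnorm(n_unsolved, 0.1, 0.05)),
      R_f = c(stats::rnorm(n_solved, 0.05, 0.01), stats::rnorm(n_unsolved, 0.5, 0.05)),
      MPE_seed = c(stats::rnorm(n_solved, 12, 4), stats::rnorm(n_unsolved, 80, 15)),
      CORR_seed = c(stats::rnorm(n_solved, 0.93, 0.04), stats::rnorm(n_unsolved, 0.2, 0.1)),
      truth = rep(c(TRUE, FALSE), c(n_solved, n_unsolved)))
  })
}

test_that("two-means clustering recovers separable solution clouds", {
  rec <- blob_records()
  cl <- cluster_solved(rec)
  expect_identical(cl$solved, rec$truth)
  expect_gt(cl$mean_silhouette, 0.8)
  expect_false(cl$degenerate)
  # permutation invariance of the labelling
  perm <- rev(seq_len(nrow(rec)))
  cl2 <- cluster_solved(rec[perm, ])
  expect_identical(cl2$solved, rec$truth[perm])
  # degenerate input is flagged
  flat <- rec[rep(1, 10), ]
  expect_true(cluster_solved(flat)$degenerate)
})

test_that("efficiency arithmetic is exact", {
  e <- efficiency(13, 15)
  expect_equal(e$E, 100 * 13 / 15, tolerance = 1e-12)
  expect_equal(round(e$E, 1), 86.7)
  expect_identical(efficiency(10, 10)$sigma_E, 0)
  expect_equal(efficiency(50, 100)$sigma_E, 5, tolerance = 1e-12)
  set.seed(2)
  for (r in 1:20) {
    n <- sample(5:500, 1); d <- sample(0:n, 1)
    e <- efficiency(d, n)
    expect_equal(e$E, 100 * d / n, tolerance = 1e-12)
    expect_equal(e$sigma_E, sqrt(e$E * (100 - e$E) / n), tolerance = 1e-12)
  }
  expect_error(efficiency(1, 0), "positive")
})

test_that("class thresholds use type-7 quartiles with inclusive boundaries", {
  rec <- data.frame(MPE_seed = c(10, 20, 30, 40, 17.5, 5),
                    CORR_seed = c(0.9, 0.8, 0.3, 0.2, 0.95, 0.99))
  solved <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  th <- class_thresholds(rec, solved)
  expect_equal(th$Q1, 17.5)  # quartile of {10,20,30,40}
  expect_equal(th$Q3, stats::quantile(c(0.9, 0.8, 0.3, 0.2), 0.75,
                                      names = FALSE))
  # a record exactly at Q1 with CORR_seed >= Q3 is Class 1 (inclusive)
  expect_true(th$class1[5])
  expect_true(th$green[5])
  expect_false(th$green[2])  # CORR_seed = 0.8 is not > 0.8
  expect_error(class_thresholds(rec[1:3, ], rep(TRUE, 3)), "unsolved")
})

test_that("random forest classification recovers the generative features", {
  # cohort whose success depends on maxW (up), N_asym (down), Vol (down)
  n <- 300
  rec <- phaseseed:::with_rng(31, {
    data.frame(
      N_asym = sample(10:55, n, TRUE),
      maxCellSize = stats::runif(n, 10.7, 43.1),
      minCellSize = stats::runif(n, 3.7, 14.8),
      Perc = stats::runif(n, 5, 54),
      Compl = stats::runif(n, 30, 100),
      maxW = sample(c(12, 16, 32, 56, 80, 127, 184), n, TRUE),
      Pseudo = stats::runif(n, 0, 96),
      N_refl = sample(1500:20000, n, TRUE),
      RES = stats::runif(n, 0.49, 0.98),
      REFLEC_seed = sample(894:1042, n, TRUE),
      RES_seed = stats::runif(n, 0.6, 1.4),
      Vol = stats::runif(n, 1005, 3495))
  })
  lin <- with(rec, 1.8 * scale(maxW) - 1.6 * scale(N_asym) - 1.4 * scale(Vol))
  lab <- phaseseed:::with_rng(32, stats::rbinom(n, 1, stats::plogis(lin)))
  rf <- rf_classify(rec, lab, rng_seed = 5, ntree = 300)
  expect_gt(rf$auc, 0.8)
  expect_setequal(names(rf$importance)[1:3], c("maxW", "N_asym", "Vol"))
  expect_gte(rf$specificity, 0.8)
  expect_equal(dim(rf$confusion), c(2, 2))
  expect_identical(rf_classify(rec, lab, rng_seed = 5, ntree = 300)$auc, rf$auc)

  # separable labels give near-perfect discrimination
  lab2 <- as.integer(rec$maxW > 50)
  rf2 <- rf_classify(rec, lab2, rng_seed = 6, ntree = 200)
  expect_gt(rf2$auc, 0.99)

  # label permutation destroys the signal
  auc0 <- mean(vapply(1:3, function(s) {
    labp <- phaseseed:::with_rng(100 + s, sample(lab))
    rf_classify(rec, labp, rng_seed = s, ntree = 150, k = 5)$auc
  }, numeric(1)))
  expect_gt(auc0, 0.38); expect_lt(auc0, 0.62)

  expect_error(rf_classify(rec, rep(1, n)), "both classes")
})

test_that("stratified CORR_seed distributions follow the printed bins", {
  set.seed(4)
  rec <- data.frame(maxW = sample(c(12, 16, 32, 56, 80, 127, 184), 200, TRUE))
  rec$CORR_seed <- stats::plogis((rec$maxW - 60) / 30) +
    stats::rnorm(200, 0, 0.02)
  out <- stratified_distributions(rec, "maxW", c(50, 100))
  expect_equal(nrow(out), 3)
  expect_true(all(diff(out$median) > 0))
  # right-closed rule: a value at the edge goes into the lower bin
  rec2 <- data.frame(maxW = c(50, 50.001), CORR_seed = c(0.1, 0.9))
  out2 <- suppressWarnings(stratified_distributions(rec2, "maxW", c(50, 100)))
  expect_equal(out2$n, c(1, 1, 0))
  expect_warning(stratified_distributions(rec2, "maxW", c(50, 100)), "empty")
})

test_that("cohort runs produce complete, well-formed trial records", {
  sts <- generate_cohort(2, rng_seed = 5, vol_range = c(1000, 1500),
                         n_asym_range = c(10, 14))
  rec <- run_cohort(sts, providers = c("true", "random"), rng_seed = 5)
  expect_equal(nrow(rec), 4)
  need <- c("N_asym", "maxCellSize", "minCellSize", "Perc", "Compl", "maxW",
            "Pseudo", "N_refl", "RES", "REFLEC_seed", "RES_seed", "Vol",
            "MPE_seed", "CORR_seed", "MPE_final", "CORR_final", "R_f")
  expect_true(all(need %in% names(rec)))
  expect_true(all(is.finite(as.matrix(rec[, need]))))
  tr <- rec[rec$provider == "true", ]
  rn <- rec[rec$provider == "random", ]
  expect_true(all(tr$MPE_final < rn$MPE_final))
})
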