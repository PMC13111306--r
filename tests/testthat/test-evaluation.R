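test_that("fold plans partition, balance, stratify and reproduce", {
  ids <- sprintf("E%02d", 1:20)
  fp <- makeFolds(ids, 5, seed = 7)
  expect_equal(sort(unique(fp$assignments)), 1:5)
  expect_true(all(table(fp$assignments) == 4))
  expect_setequal(names(fp$assignments), ids)
  expect_identical(makeFolds(ids, 5, seed = 7)$assignments, fp$assignments)
  expect_false(identical(makeFolds(ids, 5, seed = 8)$assignments,
                         fp$assignments))
  # stratified 10/10 -> two of each class per fold
  labs <- rep(c("a", "b"), each = 10)
  fs <- makeFolds(ids, 5, seed = 7, labels = labs)
  for (f in 1:5) {
    inFold <- names(fs$assignments)[fs$assignments == f]
    expect_equal(unname(table(labs[match(inFold, ids)])), c(2L, 2L),
                 ignore_attr = TRUE)
  }
  expect_error(makeFolds(ids[1:3], 5, seed = 1), "folds")
  expect_error(makeFolds(ids, 1, seed = 1), ">= 2")
})

test_that("confusion metrics match the hand-computed example exactly", {
  m <- confusionMetrics(c(1, 1, 1, 0, 0), c(1, 1, 0, 0, 0))
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$f1, 0.8)
  expect_equal(m$tp + m$tn + m$fp + m$fn, 5)
  # perfect predictions
  p <- confusionMetrics(c(1, 0, 1), c(1, 0, 1))
  expect_true(all(unlist(p[c("sensitivity", "specificity", "accuracy", "f1")]) == 1))
  # degenerate case: defined sentinel plus warning, never a silent zero
  ws <- capture_warnings(d <- confusionMetrics(c(0, 0, 0), c(0, 1, 0)))
  expect_true(any(grepl("sensitivity", ws)))
  expect_true(is.nan(d$sensitivity))
  expect_error(confusionMetrics(numeric(0), numeric(0)), "empty")
  expect_error(confusionMetrics(c(1, 0), c(1)), "mismatch")
})

test_that("accuracy identity holds on random instances", {
  withr::with_seed(42, for (i in 1:20) {
    n <- sample(5:40, 1)
    y <- rbinom(n, 1, 0.5); p <- rbinom(n, 1, 0.5)
    m <- suppressWarnings(confusionMetrics(y, p))
    expect_identical(m$accuracy, (m$tp + m$tn) / n)
  })
})

test_that("AUC matches hand examples and the tie convention", {
  r <- rocAuc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2), nBoot = 0)
  expect_equal(r$auc, 0.75)
  expect_equal(rocAuc(c(1, 1, 0), c(0.9, 0.8, 0.1), nBoot = 0)$auc, 1.0)
  expect_equal(rocAuc(c(1, 0, 1, 0), rep(0.5, 4), nBoot = 0)$auc, 0.5)
  expect_error(rocAuc(c(1, 1), c(0.2, 0.3), nBoot = 0), "both classes")
  # curve is anchored and monotone
  expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[1], 0)
  expect_equal(tail(r$curve$fpr, 1), 1); expect_equal(tail(r$curve$tpr, 1), 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("AUC equals exhaustive pair enumeration on random tied instances", {
  withr::with_seed(11, for (i in 1:60) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))       # force both classes
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(rocAuc(y, s, nBoot = 0)$auc, aucByPairEnumeration(y, s),
                 tolerance = 1e-12)
  })
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(13, {
    y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
    s <- rnorm(40)
    a0 <- rocAuc(y, s, nBoot = 0)$auc
    for (f in list(function(x) 2 * x + 3, exp, function(x) x^3,
                   function(x) plogis(x)))
      expect_equal(rocAuc(y, f(s), nBoot = 0)$auc, a0, tolerance = 1e-12)
  })
})

test_that("AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(17, for (i in 1:10) {
    y <- c(0, 1, rbinom(28, 1, 0.5))
    s <- rnorm(30)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    expect_equal(rocAuc(y, s, nBoot = 0)$auc, ref, tolerance = 1e-12)
  })
})

test_that("bootstrap CI is seeded, ordered, and narrows with n", {
  withr::with_seed(19, {
    y <- rbinom(80, 1, 0.5); y[1:2] <- c(0, 1)
    s <- y + rnorm(80)
    r1 <- rocAuc(y, s, nBoot = 300, seed = 5)
    r2 <- rocAuc(y, s, nBoot = 300, seed = 5)
    expect_identical(r1$auc_ci, r2$auc_ci)
    expect_lte(r1$auc_ci[1], r1$auc_ci[2])
    widths <- vapply(c(40, 400), function(n) {
      yy <- rbinom(n, 1, 0.5); yy[1:2] <- c(0, 1)
      ss <- yy + rnorm(n)
      ci <- rocAuc(yy, ss, nBoot = 300, seed = 5)$auc_ci
      ci[2] - ci[1]
    }, numeric(1))
    expect_lt(widths[2], widths[1])
  })
})

test_that("Cohen's kappa matches hand computation and a reference", {
  expect_equal(cohensKappa(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1.0)
  # p_obs = 0.5, p_exp = 0.5 -> kappa = 0
  expect_equal(cohensKappa(c(1, 1, 0, 0), c(1, 0, 0, 1)), 0.0)
  # independent raters: kappa ~ 0 at large n
  withr::with_seed(23, {
    a <- rbinom(4000, 1, 0.5); b <- rbinom(4000, 1, 0.5)
    expect_lt(abs(cohensKappa(a, b)), 0.05)
  })
  expect_warning(k <- cohensKappa(c(1, 1), c(1, 1)), "undefined")
  expect_true(is.nan(k))
  skip_if_not_installed("e1071")
  withr::with_seed(29, for (i in 1:5) {
    a <- sample(0:2, 50, replace = TRUE)
    b <- ifelse(rbinom(50, 1, 0.7) == 1, a, sample(0:2, 50, replace = TRUE))
    expect_equal(cohensKappa(a, b),
                 e1071::classAgreement(table(a, b))$kappa, tolerance = 1e-12)
  })
})

test_that("cross-validation guards leakage, stays deterministic, and scales", {
  b <- symbolicCVBenchmark()
  co20 <- b$cohort[1:20]
  recs <- b$records[1:20]
  labels <- b$labels[1:20]
  res <- suppressMessages(runCVExperiment(recs, labels, k = 5, seed = 7,
                                          nBoot = 50))
  # 5 folds of exactly 4 test eyes
  expect_equal(unname(table(res$scores$fold)), rep(4L, 5), ignore_attr = TRUE)
  expect_setequal(res$scores$eye_id, vapply(co20, eyeId, character(1)))
  # determinism: identical summary files on rerun
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  suppressMessages(runCVExperiment(recs, labels, k = 5, seed = 7,
                                   nBoot = 50, outDir = d1))
  suppressMessages(runCVExperiment(recs, labels, k = 5, seed = 7,
                                   nBoot = 50, outDir = d2))
  expect_identical(unname(tools::md5sum(file.path(d1, "metrics.json"))),
                   unname(tools::md5sum(file.path(d2, "metrics.json"))))
  for (f in c("roc_points.csv", "folds.json", "config_snapshot.json"))
    expect_true(file.exists(file.path(d1, f)))
  # label-free scoring: labels are required up front but unused until scored
  expect_error(suppressMessages(
    runCVExperiment(recs, labels[1:10], k = 5, seed = 7)), "label")
})
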