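test_that("SMOTE balances classes with convex-combination synthetics", {
  set.seed(20)
  X <- matrix(rnorm(100 * 4), 100, 4)
  y <- c(rep("astro", 10), rep("gbm", 90))
  bal <- smote_resample(X, y, seed = 1)
  expect_equal(unname(table(bal$y)), c(90L, 90L), ignore_attr = TRUE)
  expect_identical(bal$X[1:100, ], X)             # originals preserved
  expect_identical(bal$y[1:100], y)

  # every synthetic point lies on a segment between two minority originals
  Xm <- X[y == "astro", ]
  syn <- bal$X[101:nrow(bal$X), , drop = FALSE]
  for (s in seq_len(nrow(syn))) {
    dmin <- Inf
    for (i in 1:9) for (j in (i + 1):10) {
      a <- Xm[i, ]; b <- Xm[j, ]
      ab <- b - a
      t <- sum((syn[s, ] - a) * ab) / sum(ab^2)
      if (t >= -1e-9 && t <= 1 + 1e-9) {
        dmin <- min(dmin, sqrt(sum((syn[s, ] - (a + t * ab))^2)))
      }
    }
    expect_lt(dmin, 1e-9)
  }

  balanced <- smote_resample(X[1:20, ], rep(c("a", "b"), 10), seed = 1)
  expect_identical(balanced$X, X[1:20, ])          # already balanced: no-op
  expect_error(smote_resample(X, rep("gbm", 100), seed = 1), "two classes")
  expect_error(smote_resample(X[1:10, ], c("a", rep("b", 9)), seed = 1),
               "minority")
  b2 <- smote_resample(X, y, seed = 7)
  b3 <- smote_resample(X, y, seed = 7)
  expect_identical(b2, b3)                         # seeded determinism
})

test_that("stratified folds cover every subject with balanced classes", {
  y <- c(rep("astro", 13), rep("gbm", 47))
  folds <- stratified_folds(y, k = 5, seed = 3)
  expect_length(folds, 60)
  expect_setequal(unique(folds), 1:5)
  for (f in 1:5) {
    expect_true(abs(sum(folds == f & y == "astro") - 13 / 5) <= 1)
    expect_true(abs(sum(folds == f & y == "gbm") - 47 / 5) <= 1)
  }
  expect_identical(folds, stratified_folds(y, k = 5, seed = 3))
  expect_error(stratified_folds(c("a", rep("b", 10)), k = 5), "fewer")
})

test_that("metrics match hand-computed confusion and curve values", {
  y <- c("gbm", "astro", "gbm", "astro")
  p <- c(0.9, 0.8, 0.4, 0.1)
  m <- compute_metrics(y, p)
  expect_equal(m$acc, 0.5)       # TP=1 FP=1 FN=1 TN=1
  expect_equal(m$precision, 0.5)
  expect_equal(m$sen, 0.5)
  expect_equal(m$spe, 0.5)
  expect_equal(m$recall, m$sen)
  expect_equal(m$auc, 0.75)      # 3 of 4 concordant pairs
  expect_equal(m$auprc, 0.5 * 1 + 0.5 * (2 / 3))  # stepwise AP

  perfect <- compute_metrics(y, c(0.9, 0.1, 0.8, 0.2))
  expect_equal(perfect$auprc, 1)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$f1, 1)

  expect_warning(flat <- compute_metrics(y, rep(0.5, 4)), "constant")
  expect_equal(flat$auprc, 0.5)  # prevalence of the positive class
  expect_equal(flat$auc, 0.5)
})

test_that("rank-based AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  y <- sample(c("astro", "gbm"), 80, replace = TRUE, prob = c(0.3, 0.7))
  p <- runif(80) + 0.4 * (y == "gbm")
  ours <- compute_metrics(y, p)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = p, levels = c("astro", "gbm"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("weighted probability fusion is a normalized convex combination", {
  p1 <- c(0.2, 0.6); p2 <- c(0.4, 0.6); p3 <- c(0.9, 0.6)
  expect_equal(mdt_fuse(list(p1, p2, p3), c(1, 1, 2)),
               c((0.2 + 0.4 + 1.8) / 4, 0.6))
  expect_equal(mdt_fuse(list(p1, p1, p1), c(2, 3, 4)), p1)
  expect_equal(mdt_fuse(list(p1, p2, p3), c(1, 0, 0)), p1)
  expect_error(mdt_fuse(list(p1, p2), c(0, 0)), "weights")
})

test_that("the cross-validated grid evaluates 24 specs on shared folds", {
  tabs <- fixture("grid_tabs", {
    make_synthetic_tables(n_astro = 10, n_gbm = 25, p = 12, effect = 1.2,
                          seed = 30)
  })
  res <- fixture("grid_res", {
    suppressWarnings(run_cv_grid(tabs, config = grid_config(seed = 7)))
  })
  expect_s3_class(res, "cv_grid_result")
  expect_equal(nrow(res$fold_metrics), 24 * 5)
  expect_equal(length(unique(res$fold_metrics$spec)), 24)
  expect_equal(sort(res$mean_metrics$rank), 1:24)
  expect_equal(anyDuplicated(res$mean_metrics$spec), 0L)
  expect_length(res$top_specs, 3)
  expect_equal(sum(res$fusion_weights), 1)
  expect_true(all(res$fusion_weights >= 0))
  expect_true(all(is.finite(res$oof_probs)))
  # ranking is ordered by mean AUPRC (ties by AUC then name)
  expect_true(all(diff(res$mean_metrics$auprc) <= 1e-12))
  # every subject held out exactly once
  expect_equal(sort(unique(res$folds)), 1:5)
  expect_length(res$fused_oof, 35)
})

test_that("no training signal leaks into held-out predictions", {
  tabs <- fixture("grid_tabs", {
    make_synthetic_tables(n_astro = 10, n_gbm = 25, p = 12, effect = 1.2,
                          seed = 30)
  })
  labels <- tabs[[1]]$label
  test_idx <- 1:7
  train_idx <- 8:35
  config <- grid_config(seed = 7)
  r1 <- cv_fold_eval(tabs, labels, train_idx, test_idx, config)
  tampered <- labels
  tampered[test_idx] <- sample(tampered[test_idx])
  tampered[test_idx[1]] <- setdiff(c("astro", "gbm"),
                                   tampered[test_idx[1]])[1]
  r2 <- cv_fold_eval(tabs, tampered, train_idx, test_idx, config)
  expect_identical(r1$fused_test, r2$fused_test)
  expect_identical(r1$selections, r2$selections)
  expect_identical(r1$probs, r2$probs)
})

test_that("paired bootstrap AUPRC comparison behaves under null and signal", {
  set.seed(23)
  y <- c(rep("astro", 30), rep("gbm", 90))
  p_strong <- 0.2 + 0.6 * (y == "gbm") + 0.1 * runif(120)
  p_rand <- runif(120)
  self <- compare_auprc(y, p_strong, p_strong, n_boot = 200, seed = 1)
  expect_equal(self$p_value, 1)
  expect_equal(self$delta, 0)
  ab <- compare_auprc(y, p_strong, p_rand, n_boot = 500, seed = 2)
  ba <- compare_auprc(y, p_rand, p_strong, n_boot = 500, seed = 2)
  expect_equal(ab$p_value, ba$p_value)   # two-sided symmetry
  expect_equal(ab$delta, -ba$delta)
  # a clearly better model is detected across seeds
  detected <- vapply(1:5, function(s) {
    compare_auprc(y, p_strong, p_rand, n_boot = 400, seed = s)$p_value
  }, numeric(1))
  expect_true(all(detected < 0.05))
  expect_error(compare_auprc(y, p_strong[-1], p_rand), "match")
})

test_that("null band simulation brackets uninformative grids", {
  y <- c(rep("astro", 8), rep("gbm", 32))
  folds <- stratified_folds(y, 5, seed = 1)
  band <- null_auprc_band(y, folds, n_specs = 24, n_rep = 60, seed = 3)
  prev <- mean(y == "gbm")
  expect_true(abs(mean(band$single) - prev) < 0.1)
  expect_true(all(band$best >= band$single - 1e-12))
  expect_true(all(band$top_mean <= band$best + 1e-12))
  expect_identical(band$single,
                   null_auprc_band(y, folds, n_specs = 24, n_rep = 60,
                                   seed = 3)$single)
})
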