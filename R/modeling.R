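# Model grid: SMOTE class balancing, six selectors x four tree-ensemble
# classifiers, stratified five-fold cross-validation ranked by mean AUPRC,
# and weighted fusion of the top three models' predicted probabilities.

#' SMOTE minority oversampling
#'
#' Balances the two classes by synthesizing minority samples as convex
#' combinations of a minority point and one of its k nearest minority
#' neighbors. Original rows are preserved; synthetic rows are appended until
#' both classes reach the majority count. k is capped at (minority size - 1).
#'
#' @param X numeric matrix (rows = samples).
#' @param y class labels (2 classes).
#' @param seed integer seed.
#' @param k neighbors considered per minority point (default 5).
#' @return list with `X` and `y` of the balanced data.
#' @export
smote_resample <- function(X, y, seed = 1L, k = 5L) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop_hab("SMOTE requires exactly two classes")
  counts <- table(y)
  if (counts[1] == counts[2]) return(list(X = X, y = y))
  minority <- names(counts)[which.min(counts)]
  n_min <- min(counts); n_maj <- max(counts)
  if (n_min < 2) stop_hab("SMOTE needs at least 2 minority samples")
  Xm <- X[y == minority, , drop = FALSE]
  k_eff <- min(k, n_min - 1)
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k_eff)]))
  n_syn <- n_maj - n_min
  syn <- with_seed(seed, {
    base <- sample(rep_len(seq_len(n_min), n_syn))
    nbr_pick <- sample.int(k_eff, n_syn, replace = TRUE)
    gap <- stats::runif(n_syn)
    t(vapply(seq_len(n_syn), function(s) {
      a <- Xm[base[s], ]
      b <- Xm[nn[base[s], nbr_pick[s]], ]
      a + gap[s] * (b - a)
    }, numeric(ncol(X))))
  })
  list(X = rbind(X, syn), y = c(y, rep(minority, n_syn)))
}

classifier_names <- function() {
  c("extra_trees", "gradient_boosting", "xgboost", "leafwise_boosting")
}

# Fit one of the four tree-ensemble classifiers; returns a closure scoring
# P(positive) on new rows. All learners are seeded and single-threaded so
# runs are reproducible.
fit_classifier <- function(name, X, y01, seed = 1L) {
  if (name == "extra_trees") {
    df <- as.data.frame(X)
    colnames(df) <- paste0("f", seq_len(ncol(X)))
    df$.y <- factor(y01, levels = c(0, 1))
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = df, probability = TRUE,
      num.trees = 300, splitrule = "extratrees", num.random.splits = 1,
      replace = FALSE, sample.fraction = 1, seed = seed, num.threads = 1
    )
    function(Xnew) {
      dn <- as.data.frame(Xnew)
      colnames(dn) <- paste0("f", seq_len(ncol(Xnew)))
      stats::predict(fit, data = dn, num.threads = 1)$predictions[, "1"]
    }
  } else {
    params <- switch(name,
      gradient_boosting = list(objective = "binary:logistic", eta = 0.1,
                               max_depth = 3, tree_method = "exact",
                               nthread = 1, seed = seed),
      xgboost = list(objective = "binary:logistic", eta = 0.3, max_depth = 6,
                     tree_method = "hist", nthread = 1, seed = seed),
      leafwise_boosting = list(objective = "binary:logistic", eta = 0.1,
                               max_depth = 0, max_leaves = 31,
                               grow_policy = "lossguide",
                               tree_method = "hist", nthread = 1,
                               seed = seed),
      stop_hab("unknown classifier: ", name)
    )
    dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y01)
    fit <- xgboost::xgb.train(params = params, data = dtrain, nrounds = 100,
                              verbose = 0)
    function(Xnew) {
      stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(Xnew)))
    }
  }
}

#' Stratified k-fold assignment
#'
#' Each subject appears in exactly one test fold; class proportions per fold
#' are within one subject of the global proportions.
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed integer seed for the within-class shuffle.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  y <- as.character(labels)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < k) {
        stop_hab("class ", cl, " has fewer subjects than folds; ",
                 "re-stratify with fewer folds or more subjects")
      }
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Classification metric suite
#'
#' AUPRC is the average precision (step-wise integral of the precision-recall
#' curve); AUC is the Mann-Whitney rank statistic; the thresholded metrics
#' use `threshold` on the predicted probability of the positive class.
#' Sensitivity and recall coincide by construction. Constant probabilities
#' are degenerate: AUC is 0.5 and AUPRC equals the positive-class prevalence
#' (a warning is raised).
#'
#' @param labels true class labels.
#' @param probabilities predicted probabilities of the positive class.
#' @param threshold decision threshold (default 0.5).
#' @param positive positive class name (default `"gbm"`, the majority class).
#' @return Named list of metrics (`auprc`, `auc`, `acc`, `sen`, `spe`, `f1`,
#'   `precision`, `recall`) plus the threshold and positive class used.
#' @export
compute_metrics <- function(labels, probabilities, threshold = 0.5,
                            positive = "gbm") {
  y <- as.integer(as.character(labels) == positive)
  if (length(unique(y)) < 2) stop_hab("both classes required in labels")
  p <- as.numeric(probabilities)
  if (max(p) == min(p)) {
    warning("constant probabilities; AUPRC equals prevalence, AUC = 0.5")
  }
  n1 <- sum(y); n0 <- sum(1 - y)

  # average precision over distinct thresholds, descending
  ord <- order(-p)
  ys <- y[ord]; ps <- p[ord]
  grp <- cumsum(!duplicated(ps))
  tp_cum <- cumsum(ys)
  pos_cum <- seq_along(ys)
  last_of_grp <- !duplicated(grp, fromLast = TRUE)
  tp <- tp_cum[last_of_grp]
  np <- pos_cum[last_of_grp]
  prec <- tp / np
  rec <- tp / n1
  ap <- sum(diff(c(0, rec)) * prec)

  r <- rank(p)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  pred <- as.integer(p >= threshold)
  tp_ <- sum(pred == 1 & y == 1); fp_ <- sum(pred == 1 & y == 0)
  fn_ <- sum(pred == 0 & y == 1); tn_ <- sum(pred == 0 & y == 0)
  sen <- tp_ / (tp_ + fn_)
  spe <- tn_ / (tn_ + fp_)
  precision <- if (tp_ + fp_ > 0) tp_ / (tp_ + fp_) else 0
  f1 <- if (precision + sen > 0) 2 * precision * sen / (precision + sen) else 0
  list(auprc = ap, auc = auc, acc = (tp_ + tn_) / length(y), sen = sen,
       spe = spe, f1 = f1, precision = precision, recall = sen,
       threshold = threshold, positive = positive)
}

#' Weighted fusion of model probabilities
#'
#' Consensus prediction: the weighted average `sum(w_i p_i) / sum(w_i)` of
#' the top models' probability series.
#'
#' @param probabilities list (or matrix columns) of equal-length probability
#'   vectors.
#' @param weights non-negative weights, not all zero.
#' @return Fused probability vector in `[0, 1]`.
#' @export
mdt_fuse <- function(probabilities, weights) {
  if (is.list(probabilities)) probabilities <- do.call(cbind, probabilities)
  weights <- as.numeric(weights)
  if (any(weights < 0) || sum(weights) <= 0) {
    stop_hab("weights must be non-negative and not all zero")
  }
  as.numeric(probabilities %*% weights) / sum(weights)
}

#' Run one cross-validation fold of the full pipeline
#'
#' The leakage-auditable unit of [run_cv_grid()]: fits the fusion transform
#' on the training subjects only, applies SMOTE to the fused training set
#' only, runs every selector on the balanced training data, fits every
#' classifier on the selected features, and scores the held-out subjects.
#' Test-subject labels are never consulted, so perturbing them cannot change
#' any fused feature, selection or prediction.
#'
#' @param tables named list of `feature_table` per sequence (already
#'   restricted to the sequence combination in use).
#' @param labels class labels for all subjects.
#' @param train_idx,test_idx row indices of the training and held-out sets.
#' @param config pipeline configuration from [grid_config()].
#' @return List with `fused_test` (matrix), `selections` (per selector),
#'   and `probs` (matrix n_test x 24 of positive-class probabilities, one
#'   column per spec id).
#' @export
cv_fold_eval <- function(tables, labels, train_idx, test_idx, config) {
  labels <- as.character(labels)
  train_tabs <- lapply(tables, function(tb) tb[train_idx, , drop = FALSE])
  test_tabs <- lapply(tables, function(tb) tb[test_idx, , drop = FALSE])
  ft <- fit_fusion(train_tabs, labels[train_idx], r = config$fusion_r,
                   method = config$fusion_method)
  fused_train <- apply_fusion(ft, train_tabs)
  fused_test <- apply_fusion(ft, test_tabs)
  feats <- feature_columns(fused_train)
  Xtr <- as.matrix(fused_train[, feats, drop = FALSE])
  ytr <- labels[train_idx]
  if (isTRUE(config$smote) && length(unique(ytr)) == 2 &&
      min(table(ytr)) >= 2 && diff(range(table(ytr))) > 0) {
    bal <- smote_resample(Xtr, ytr, seed = config$seed_smote)
    Xtr <- bal$X; ytr <- bal$y
  }
  train_df <- data.frame(subject_id = sprintf("s%04d", seq_len(nrow(Xtr))),
                         label = ytr, Xtr, check.names = FALSE,
                         stringsAsFactors = FALSE)
  class(train_df) <- c("feature_table", class(train_df))
  selections <- lapply(config$selectors, function(m) {
    score_features(train_df, ytr, method = m, k = config$k_features,
                   bins = config$bins)$selected
  })
  names(selections) <- config$selectors
  Xte <- as.matrix(fused_test[, feats, drop = FALSE])
  y01 <- as.integer(ytr == config$positive)
  probs <- matrix(NA_real_, nrow = length(test_idx),
                  ncol = length(config$selectors) * length(config$classifiers))
  spec_ids <- character(0)
  col <- 0L
  for (sel in config$selectors) {
    sel_feats <- selections[[sel]]
    Xtr_s <- Xtr[, sel_feats, drop = FALSE]
    Xte_s <- Xte[, sel_feats, drop = FALSE]
    for (clf in config$classifiers) {
      col <- col + 1L
      scorer <- fit_classifier(clf, Xtr_s, y01, seed = config$seed_clf)
      probs[, col] <- scorer(Xte_s)
      spec_ids <- c(spec_ids, paste(sel, clf, sep = "|"))
    }
  }
  colnames(probs) <- spec_ids
  list(fused_test = Xte, selections = selections, probs = probs)
}

#' Configuration for the cross-validated model grid
#'
#' @param seed master seed; fold splits, SMOTE and classifiers derive their
#'   seeds from it.
#' @param n_folds folds for stratified cross-validation (default 5).
#' @param k_features features selected per model (default 10).
#' @param bins equal-frequency bins for MI estimation (default 5).
#' @param selectors,classifiers grid axes (defaults: all 6 x all 4).
#' @param fusion_r,fusion_method passed to [fit_fusion()].
#' @param smote apply SMOTE inside training folds (default TRUE).
#' @param threshold decision threshold for thresholded metrics.
#' @param positive positive class (default `"gbm"`).
#' @param top_n models fused by weighted consensus (default 3).
#' @return A named list of settings.
#' @export
grid_config <- function(seed = 42L, n_folds = 5L, k_features = 10L,
                        bins = 5L, selectors = selector_methods(),
                        classifiers = classifier_names(), fusion_r = 1L,
                        fusion_method = "fisher", smote = TRUE,
                        threshold = 0.5, positive = "gbm", top_n = 3L) {
  list(seed = as.integer(seed), n_folds = as.integer(n_folds),
       k_features = as.integer(k_features), bins = as.integer(bins),
       selectors = selectors, classifiers = classifiers,
       fusion_r = as.integer(fusion_r), fusion_method = fusion_method,
       smote = smote, threshold = threshold, positive = positive,
       top_n = as.integer(top_n),
       seed_folds = derive_seed(seed, 1L),
       seed_smote = derive_seed(seed, 2L),
       seed_clf = derive_seed(seed, 3L))
}

#' Cross-validated selector-classifier grid
#'
#' Evaluates every (selector, classifier) spec of the grid on identical
#' stratified folds: per fold the fusion transform is fitted on training
#' subjects only, SMOTE balances the fused training set, each selector picks
#' `k_features` features, each classifier is fitted and the held-out fold is
#' scored. Specs are ranked by mean AUPRC across folds (ties by mean AUC,
#' then spec id) and the top `top_n` are combined with AUPRC-proportional
#' weights into a consensus prediction.
#'
#' @param tables named list of `feature_table` per sequence (all four, or
#'   any subset).
#' @param combo character vector of sequence names to use (default: all of
#'   `names(tables)`).
#' @param config a [grid_config()].
#' @return An object of class `cv_grid_result` with per-fold and mean
#'   metrics, ranking, selection logs, top-spec ids, fusion weights and the
#'   out-of-fold consensus probabilities.
#' @export
run_cv_grid <- function(tables, combo = names(tables),
                        config = grid_config()) {
  tables <- tables[combo]
  labels <- as.character(tables[[1]]$label)
  n <- length(labels)
  folds <- stratified_folds(labels, k = config$n_folds,
                           seed = config$seed_folds)
  spec_ids <- as.vector(t(outer(config$selectors, config$classifiers,
                                paste, sep = "|")))
  fold_metrics <- list()
  selection_log <- list()
  oof_probs <- matrix(NA_real_, nrow = n, ncol = length(spec_ids),
                      dimnames = list(tables[[1]]$subject_id, spec_ids))
  for (f in seq_len(config$n_folds)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    res <- cv_fold_eval(tables, labels, train_idx, test_idx, config)
    oof_probs[test_idx, colnames(res$probs)] <- res$probs
    for (sid in colnames(res$probs)) {
      mt <- compute_metrics(labels[test_idx], res$probs[, sid],
                            threshold = config$threshold,
                            positive = config$positive)
      fold_metrics[[length(fold_metrics) + 1L]] <- data.frame(
        spec = sid, fold = f, auprc = mt$auprc, auc = mt$auc, acc = mt$acc,
        sen = mt$sen, spe = mt$spe, f1 = mt$f1, precision = mt$precision,
        recall = mt$recall, stringsAsFactors = FALSE)
    }
    selection_log[[f]] <- res$selections
  }
  fm <- do.call(rbind, fold_metrics)
  metric_cols <- c("auprc", "auc", "acc", "sen", "spe", "f1", "precision",
                   "recall")
  mean_metrics <- stats::aggregate(fm[metric_cols], by = list(spec = fm$spec),
                                   FUN = mean)
  ord <- order(-mean_metrics$auprc, -mean_metrics$auc, mean_metrics$spec)
  mean_metrics <- mean_metrics[ord, ]
  mean_metrics$rank <- seq_len(nrow(mean_metrics))
  rownames(mean_metrics) <- NULL
  top <- mean_metrics$spec[seq_len(min(config$top_n, nrow(mean_metrics)))]
  w <- mean_metrics$auprc[seq_along(top)]
  if (sum(w) <= 0) w <- rep(1, length(top))
  w <- w / sum(w)
  fused_oof <- mdt_fuse(oof_probs[, top, drop = FALSE], w)
  fused_fold <- lapply(seq_len(config$n_folds), function(f) {
    idx <- which(folds == f)
    mt <- compute_metrics(labels[idx], fused_oof[idx],
                          threshold = config$threshold,
                          positive = config$positive)
    data.frame(fold = f, auprc = mt$auprc, auc = mt$auc, acc = mt$acc,
               sen = mt$sen, spe = mt$spe, f1 = mt$f1,
               precision = mt$precision, recall = mt$recall)
  })
  fused_fold <- do.call(rbind, fused_fold)
  structure(list(
    fold_metrics = fm, mean_metrics = mean_metrics, rank = mean_metrics$spec,
    top_specs = top, fusion_weights = stats::setNames(w, top),
    oof_probs = oof_probs, fused_oof = fused_oof,
    fused_fold_metrics = fused_fold,
    fused_mean = colMeans(fused_fold[, -1, drop = FALSE]),
    selection_log = selection_log, folds = folds, labels = labels,
    subject_ids = tables[[1]]$subject_id, combo = combo, config = config
  ), class = "cv_grid_result")
}

#' @export
print.cv_grid_result <- function(x, ...) {
  cat(sprintf("<cv_grid_result: %d specs x %d folds on %d subjects (%s)>\n",
              length(unique(x$fold_metrics$spec)), x$config$n_folds,
              length(x$labels), paste(x$combo, collapse = "+")))
  cat("top specs:\n")
  print(utils::head(x$mean_metrics[, c("spec", "auprc", "auc", "rank")], 3))
  invisible(x)
}

#' Paired bootstrap comparison of two models' AUPRC
#'
#' Two-sided p-value for the difference in average precision between two
#' probability series scored on the same subjects, from a stratified paired
#' bootstrap over subjects (both classes are resampled separately so every
#' replicate is scorable).
#'
#' @param labels true labels.
#' @param probs_a,probs_b probability series for the same subjects.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @param positive positive class.
#' @return List with `p_value`, `delta` (observed AUPRC difference) and the
#'   bootstrap quantiles of the difference.
#' @export
compare_auprc <- function(labels, probs_a, probs_b, n_boot = 2000L,
                          seed = 1L, positive = "gbm") {
  if (length(probs_a) != length(labels) ||
      length(probs_b) != length(labels)) {
    stop_hab("probability series must match the subjects")
  }
  y <- as.character(labels)
  ap <- function(idx, p) {
    compute_metrics(y[idx], p[idx], positive = positive)$auprc
  }
  all_idx <- seq_along(y)
  delta_obs <- ap(all_idx, probs_a) - ap(all_idx, probs_b)
  pos_idx <- which(y == positive); neg_idx <- which(y != positive)
  deltas <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(pos_idx, replace = TRUE),
               sample(neg_idx, replace = TRUE))
      suppressWarnings(ap(idx, probs_a) - ap(idx, probs_b))
    }, numeric(1))
  })
  p <- min(1, 2 * min(mean(deltas <= 0), mean(deltas >= 0)))
  list(p_value = p, delta = delta_obs,
       ci = stats::quantile(deltas, c(0.025, 0.975), names = FALSE))
}

#' Monte-Carlo null band for grid AUPRC under label-score independence
#'
#' Simulates the cross-validated mean AUPRC of uninformative models (iid
#' uniform scores) on the given labels and fold structure, and returns the
#' simulated distributions for a single spec, for the best of `n_specs`
#' independent specs, and for the top-`top_n` mean — the references against
#' which an observed grid result on null data is judged.
#'
#' @param labels class labels.
#' @param folds fold assignment (as from [stratified_folds()]).
#' @param n_specs number of independent specs emulated (default 24).
#' @param top_n size of the fused top set (default 3).
#' @param n_rep Monte-Carlo replicates.
#' @param seed integer seed.
#' @param positive positive class.
#' @return List of numeric vectors `single`, `best`, `top_mean`.
#' @export
null_auprc_band <- function(labels, folds, n_specs = 24L, top_n = 3L,
                            n_rep = 400L, seed = 1L, positive = "gbm") {
  y <- as.character(labels)
  k <- max(folds)
  with_seed(seed, {
    single <- numeric(n_rep); best <- numeric(n_rep); topm <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      means <- vapply(seq_len(n_specs), function(s) {
        p <- stats::runif(length(y))
        mean(vapply(seq_len(k), function(f) {
          idx <- folds == f
          compute_metrics(y[idx], p[idx], positive = positive)$auprc
        }, numeric(1)))
      }, numeric(1))
      single[r] <- means[1]
      best[r] <- max(means)
      topm[r] <- mean(sort(means, decreasing = TRUE)[seq_len(top_n)])
    }
    list(single = single, best = best, top_mean = topm)
  })
}
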