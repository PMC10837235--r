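# Top-feature frequency ranking across folds and models, the M-threshold
# discrimination summary, and report file generation.

#' Selection-frequency ranking of features
#'
#' Counts how often each feature was selected across (spec, fold) runs. By
#' default only the top-ranked specs contribute (the models that form the
#' consensus); set `population = "all"` to count over the whole grid. Ties
#' break lexicographically by feature name.
#'
#' @param grid a `cv_grid_result`.
#' @param top_n number of features to return (default 10).
#' @param population `"top"` (default: the fused top specs) or `"all"`.
#' @return Data frame with `feature` and `frequency`, ordered by decreasing
#'   frequency.
#' @export
feature_frequency <- function(grid, top_n = 10L,
                              population = c("top", "all")) {
  population <- match.arg(population)
  if (length(grid$selection_log) == 0) stop_hab("no selection logs in grid")
  specs <- if (population == "top") grid$top_specs else {
    grid$mean_metrics$spec
  }
  counts <- new.env(parent = emptyenv())
  for (fold_sel in grid$selection_log) {
    for (sid in specs) {
      sel <- fold_sel[[strsplit(sid, "|", fixed = TRUE)[[1]][1]]]
      for (f in sel) {
        assign(f, (get0(f, envir = counts) %||% 0) + 1, envir = counts)
      }
    }
  }
  feats <- ls(counts)
  freq <- vapply(feats, function(f) get(f, envir = counts), numeric(1))
  ord <- order(-freq, feats)
  out <- data.frame(feature = feats[ord], frequency = freq[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  utils::head(out, top_n)
}

#' M-threshold discrimination summary for one feature
#'
#' M is the average of the two class means. For each class the fraction of
#' subjects strictly below M and at-or-above M is reported (values equal to
#' M count as above), together with a two-sided Mann-Whitney U p-value.
#'
#' @param values numeric feature values.
#' @param labels class labels (2 classes).
#' @return List with `M`, `class_means`, `pct_below`/`pct_above` (named
#'   percentages per class) and `p_value`.
#' @export
m_threshold_summary <- function(values, labels) {
  y <- as.character(labels)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop_hab("exactly two classes required")
  means <- vapply(classes, function(cl) mean(values[y == cl]), numeric(1))
  M <- mean(means)
  pct_below <- vapply(classes, function(cl) {
    100 * mean(values[y == cl] < M)
  }, numeric(1))
  pct_above <- 100 - pct_below
  p <- suppressWarnings(stats::wilcox.test(
    values[y == classes[1]], values[y == classes[2]],
    alternative = "two.sided", exact = FALSE)$p.value)
  list(M = M, class_means = means, pct_below = pct_below,
       pct_above = pct_above, p_value = p)
}

#' Signature table for the most frequently selected features
#'
#' @param grid a `cv_grid_result`.
#' @param table a fused `feature_table` holding the feature values used for
#'   the summary (e.g. fusion applied to the full cohort).
#' @param top_n features summarized (default 10).
#' @return Data frame with one row per feature: family, selection frequency,
#'   M, per-class below/above percentages and Mann-Whitney p-value.
#' @export
signature_table <- function(grid, table, top_n = 10L) {
  freq <- feature_frequency(grid, top_n = top_n)
  fam <- feature_families()
  labels <- table$label
  rows <- lapply(seq_len(nrow(freq)), function(i) {
    f <- freq$feature[i]
    s <- m_threshold_summary(table[[f]], labels)
    cls <- names(s$class_means)
    data.frame(
      feature = f,
      family = unname(fam[f]) %||% NA_character_,
      frequency = freq$frequency[i],
      p_value = s$p_value,
      M = s$M,
      pct_below_1 = s$pct_below[1], pct_above_1 = s$pct_above[1],
      pct_below_2 = s$pct_below[2], pct_above_2 = s$pct_above[2],
      class_1 = cls[1], class_2 = cls[2],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the report files for a completed run
#'
#' Produces, under `out_dir`: `leaderboard.csv` (mean metrics and rank for
#' every spec), `pr_curve_<spec>.csv` for each top spec plus the consensus
#' (precision-recall points from the out-of-fold probabilities),
#' `heatmap_matrix.csv` (subjects x top features, standardized fused values)
#' and `signatures.csv` (the M-threshold table). Outputs are plain CSV and
#' regeneration from the same run is byte-identical.
#'
#' @param grid a `cv_grid_result`.
#' @param table fused `feature_table` for the signature summary and heatmap.
#' @param out_dir output directory.
#' @param top_n features in the signature table/heatmap.
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(grid, table, out_dir, top_n = 10L) {
  if (is.null(grid$mean_metrics) || is.null(table)) {
    stop_hab("render_report needs a completed grid result and fused table")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  lb <- file.path(out_dir, "leaderboard.csv")
  utils::write.csv(grid$mean_metrics, lb, row.names = FALSE)
  files <- c(files, lb)

  pr_points <- function(y, p, positive) {
    ord <- order(-p)
    ys <- as.integer(as.character(y[ord]) == positive)
    tp <- cumsum(ys)
    data.frame(recall = tp / sum(ys), precision = tp / seq_along(ys))
  }
  for (sid in grid$top_specs) {
    pr <- pr_points(grid$labels, grid$oof_probs[, sid],
                    grid$config$positive)
    f <- file.path(out_dir, paste0("pr_curve_",
                                   gsub("[^A-Za-z0-9]+", "_", sid), ".csv"))
    utils::write.csv(pr, f, row.names = FALSE)
    files <- c(files, f)
  }
  prf <- file.path(out_dir, "pr_curve_consensus.csv")
  utils::write.csv(pr_points(grid$labels, grid$fused_oof,
                             grid$config$positive), prf, row.names = FALSE)
  files <- c(files, prf)

  sig <- signature_table(grid, table, top_n = top_n)
  sf <- file.path(out_dir, "signatures.csv")
  utils::write.csv(sig, sf, row.names = FALSE)
  files <- c(files, sf)

  hm_feats <- sig$feature
  hm <- scale(as.matrix(table[, hm_feats, drop = FALSE]))
  hm_df <- data.frame(subject_id = table$subject_id, label = table$label,
                      hm, check.names = FALSE)
  hf <- file.path(out_dir, "heatmap_matrix.csv")
  utils::write.csv(hm_df, hf, row.names = FALSE)
  files <- c(files, hf)
  invisible(files)
}
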