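# Independent oracle: plug-in MI computed by direct summation over the
# empirical joint distribution, never through the package's fast kernels.
mi_oracle <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  unname(s)
}

entropy_oracle <- function(x) {
  p <- table(x) / length(x)
  -sum(p[p > 0] * log2(p[p > 0]))
}

# Greedy forward selection re-implemented from the criterion definitions,
# entirely on top of the oracle MI.
greedy_oracle <- function(D, y, method, k) {
  feats <- colnames(D)
  S <- character(0)
  for (step in seq_len(k)) {
    rem <- setdiff(feats, S)
    crit <- vapply(rem, function(f) {
      rel <- mi_oracle(D[, f], y)
      if (length(S) == 0) {
        if (method == "DISR") {
          h <- entropy_oracle(D[, f]); if (h > 0) rel / h else 0
        } else rel
      } else {
        switch(method,
          MIM = rel,
          JMI = sum(vapply(S, function(s) {
            mi_oracle(paste(D[, f], D[, s]), y)
          }, numeric(1))),
          DISR = sum(vapply(S, function(s) {
            j <- paste(D[, f], D[, s])
            h <- entropy_oracle(j)
            if (h > 0) mi_oracle(j, y) / h else 0
          }, numeric(1))),
          CMIM = min(vapply(S, function(s) {
            # I(f;Y|s) by conditioning on each stratum of s
            sum(vapply(unique(D[, s]), function(z) {
              idx <- D[, s] == z
              w <- mean(idx)
              xi <- D[idx, f]; yi <- y[idx]
              if (length(unique(xi)) < 2 || length(unique(yi)) < 2) return(0)
              w * mi_oracle(xi, yi)
            }, numeric(1)))
          }, numeric(1))),
          ICAP = rel - sum(vapply(S, function(s) {
            red <- mi_oracle(D[, f], D[, s])
            cond <- sum(vapply(unique(y), function(z) {
              idx <- y == z
              w <- mean(idx)
              xi <- D[idx, f]; si <- D[idx, s]
              if (length(unique(xi)) < 2 || length(unique(si)) < 2) return(0)
              w * mi_oracle(xi, si)
            }, numeric(1)))
            max(0, red - cond)
          }, numeric(1)))
        )
      }
    }, numeric(1))
    ord <- order(-crit, rem)
    S <- c(S, rem[ord[1]])
  }
  S
}

as_ft <- function(X, labels) {
  tb <- data.frame(subject_id = sprintf("s%03d", seq_along(labels)),
                   label = labels, X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  class(tb) <- c("feature_table", class(tb))
  tb
}

test_that("plug-in mutual information matches direct summation", {
  y <- rep(c(0, 1), 20)
  expect_equal(estimate_mi(y, y), 1)              # I(X;X) = H(X) = 1 bit
  x_ind <- rep(c(0, 0, 1, 1), 10)
  y_ind <- rep(c(0, 1, 0, 1), 10)                 # product table: independent
  expect_equal(estimate_mi(x_ind, y_ind), 0)
  # joint counts [[2,1],[1,2]]
  x <- c(0, 0, 0, 1, 1, 1)
  yy <- c(0, 0, 1, 0, 1, 1)
  expect_equal(estimate_mi(x, yy), mi_oracle(x, yy), tolerance = 1e-12)
  p <- matrix(c(2, 1, 1, 2) / 6, 2)
  by_hand <- sum(p * log2(p / (rowSums(p) %o% colSums(p))))
  expect_equal(estimate_mi(x, yy), by_hand, tolerance = 1e-12)
  expect_error(estimate_mi(1:3, 1:4), "lengths")
  expect_gte(estimate_mi(rnorm(50) > 0, rnorm(50) > 0), 0)
})

test_that("a feature equal to the label is ranked first by all MI methods", {
  set.seed(13)
  n <- 60
  labels <- rep(c("astro", "gbm"), each = n / 2)
  X <- cbind(perfect = as.numeric(labels == "gbm") + 0.001 * rnorm(n),
             noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  tab <- as_ft(X, labels)
  for (m in c("MIM", "JMI", "CMIM", "DISR", "ICAP")) {
    expect_equal(score_features(tab, method = m, k = 2)$selected[1],
                 "perfect", info = m)
  }
})

test_that("CMIM demotes a duplicated feature below complementary information", {
  set.seed(14)
  n <- 200
  labels <- rep(c("astro", "gbm"), each = n / 2)
  strong <- as.numeric(labels == "gbm") + 0.2 * rnorm(n)
  weak <- as.numeric(labels == "gbm") + 2.5 * rnorm(n)
  X <- cbind(strong = strong, copy = strong, weak = weak)
  tab <- as_ft(X, labels)
  mim <- score_features(tab, method = "MIM", k = 3)
  expect_setequal(mim$selected[1:2], c("strong", "copy"))
  cmim <- score_features(tab, method = "CMIM", k = 3)
  # identical columns tie on the first pick and break lexicographically
  expect_true(cmim$selected[1] %in% c("strong", "copy"))
  expect_equal(cmim$selected[2], "weak")   # duplicate carries no new info
})

test_that("greedy selection agrees with an independent oracle (p <= 8, k <= 3)", {
  for (seed in 1:3) {
    set.seed(100 + seed)
    n <- 80
    labels <- rep(c("astro", "gbm"), each = n / 2)
    p <- 6
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("f%02d", 1:p)))
    X[labels == "gbm", 1:2] <- X[labels == "gbm", 1:2] + 0.8
    tab <- as_ft(X, labels)
    D <- apply(X, 2, function(col) {
      as.integer(ceiling(rank(col, ties.method = "first") * 5 / n))
    })
    for (m in c("MIM", "JMI", "CMIM", "DISR", "ICAP")) {
      got <- score_features(tab, method = m, k = 3)$selected
      want <- greedy_oracle(D, labels, m, 3)
      expect_equal(got, want, info = paste(m, seed))
    }
  }
})

test_that("selection is invariant to strictly monotone feature transforms", {
  tabs <- make_synthetic_tables(n_astro = 12, n_gbm = 24, p = 8, seed = 15)
  tab <- tabs[[1]]
  tab2 <- tab
  tab2$feat_01 <- exp(tab2$feat_01)
  tab2$feat_02 <- tab2$feat_02^3 + 5 * tab2$feat_02   # strictly increasing
  for (m in c("MIM", "JMI", "CMIM", "DISR", "ICAP")) {
    expect_identical(score_features(tab, method = m, k = 4)$selected,
                     score_features(tab2, method = m, k = 4)$selected,
                     info = m)
  }
})

test_that("SPEC ranks by spectral consistency, deterministically", {
  set.seed(16)
  n <- 60
  labels <- rep(c("astro", "gbm"), each = n / 2)
  # one feature aligned with the dominant cluster structure, others noise
  aligned <- as.numeric(labels == "gbm") * 3 + 0.3 * rnorm(n)
  X <- cbind(aligned = aligned, n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  tab <- as_ft(X, labels)
  r1 <- score_features(tab, method = "SPEC", k = 2)
  r2 <- score_features(tab, method = "SPEC", k = 2)
  expect_identical(r1$selected, r2$selected)
  expect_true(all(is.finite(r1$scores)))
  expect_equal(r1$selected[1], "aligned")
  expect_length(r1$ranking, 4)
  expect_setequal(r1$ranking, colnames(X))
})

test_that("selector contracts are enforced", {
  tabs <- make_synthetic_tables(seed = 17)
  expect_error(score_features(tabs[[1]], method = "RELIEF", k = 2), "unknown")
  expect_error(score_features(tabs[[1]], method = "MIM", k = 999), "exceeds")
})
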