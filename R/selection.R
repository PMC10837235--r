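# Information-theoretic and spectral feature selection.
#
# Continuous features are discretized to equal-frequency bins (rank-based,
# hence exactly invariant to strictly monotone transforms of any single
# feature) before plug-in mutual-information estimation in bits. Five greedy
# forward filters (MIM, JMI, CMIM, DISR, ICAP) and a spectral ranking (SPEC)
# share a common interface; ties on the criterion break lexicographically by
# feature name for reproducibility.

#' Plug-in mutual information between two discrete series
#'
#' `I(X;Y) = sum p(x,y) log2( p(x,y) / (p(x) p(y)) )` from the empirical
#' joint distribution, in bits.
#'
#' @param x,y vectors of equal length (coerced to factors).
#' @return Non-negative mutual information in bits.
#' @export
estimate_mi <- function(x, y) {
  if (length(x) != length(y)) stop_hab("series lengths differ")
  if (length(x) < 2) stop_hab("need at least 2 observations")
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / (px[row(p)[nz]] * py[col(p)[nz]])))
}

entropy_bits <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# I(X;Y | Z) = sum_z p(z) I(X;Y | Z = z)
conditional_mi <- function(x, y, z) {
  zs <- split(seq_along(x), z)
  total <- 0
  for (idx in zs) {
    if (length(idx) < 1) next
    w <- length(idx) / length(x)
    if (length(unique(x[idx])) < 2 || length(unique(y[idx])) < 2) next
    total <- total + w * estimate_mi(x[idx], y[idx])
  }
  total
}

joint_code <- function(a, b) paste(a, b, sep = "\r")

# ---- fast integer-code MI kernels -----------------------------------------
# All selector criteria reduce to plug-in entropies of small contingency
# tables over integer codes; tabulate() keeps the greedy loop O(n) per
# criterion evaluation.

entropy_counts <- function(cnt) {
  n <- sum(cnt)
  p <- cnt[cnt > 0] / n
  -sum(p * log2(p))
}

# I(A;B) for integer series a in 1..na, b in 1..nb
mi_int <- function(a, na, b, nb) {
  hab <- entropy_counts(tabulate((a - 1L) * nb + b, nbins = na * nb))
  ha <- entropy_counts(tabulate(a, nbins = na))
  hb <- entropy_counts(tabulate(b, nbins = nb))
  max(0, ha + hb - hab)
}

# I(A;B | C) = H(A,C) + H(B,C) - H(A,B,C) - H(C)
cmi_int <- function(a, na, b, nb, cc, nc) {
  hac <- entropy_counts(tabulate((a - 1L) * nc + cc, nbins = na * nc))
  hbc <- entropy_counts(tabulate((b - 1L) * nc + cc, nbins = nb * nc))
  habc <- entropy_counts(tabulate(((a - 1L) * nb + b - 1L) * nc + cc,
                                  nbins = na * nb * nc))
  hc <- entropy_counts(tabulate(cc, nbins = nc))
  max(0, hac + hbc - habc - hc)
}

# Equal-frequency binning via ranks; deterministic under ties.
equal_frequency_bins <- function(x, bins = 5L) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * bins / length(x)))
}

discretize_table <- function(X, bins) {
  apply(X, 2, equal_frequency_bins, bins = bins)
}

selector_methods <- function() c("CMIM", "DISR", "ICAP", "JMI", "MIM", "SPEC")

# Criterion value of candidate feature f given the selected set S (list of
# integer-coded columns in 1..bins); y is integer-coded in 1..ny. Shared by
# the greedy loop and the exhaustive oracle used in tests.
mi_criterion <- function(method, f, y, S, bins, ny = 2L) {
  rel <- mi_int(f, bins, y, ny)
  if (length(S) == 0) {
    return(switch(method,
                  MIM = rel, JMI = rel, CMIM = rel, ICAP = rel,
                  DISR = {
                    h <- entropy_counts(tabulate(f, nbins = bins))
                    if (h > 0) rel / h else 0
                  }))
  }
  b2 <- bins * bins
  switch(method,
    MIM = rel,
    JMI = sum(vapply(S, function(s) {
      mi_int((f - 1L) * bins + s, b2, y, ny)
    }, numeric(1))),
    DISR = sum(vapply(S, function(s) {
      fs <- (f - 1L) * bins + s
      h <- entropy_counts(tabulate(fs, nbins = b2))
      if (h > 0) mi_int(fs, b2, y, ny) / h else 0
    }, numeric(1))),
    CMIM = min(vapply(S, function(s) {
      cmi_int(f, bins, y, ny, s, bins)
    }, numeric(1))),
    ICAP = rel - sum(vapply(S, function(s) {
      max(0, mi_int(f, bins, s, bins) - cmi_int(f, bins, s, bins, y, ny))
    }, numeric(1)))
  )
}

#' Rank and select features with one of six selector methods
#'
#' `MIM`, `JMI`, `CMIM`, `DISR` and `ICAP` perform greedy forward selection
#' under their respective mutual-information criteria; `SPEC` ranks all
#' features at once by spectral consistency with the normalized graph
#' Laplacian of an RBF sample-similarity graph (bandwidth = median pairwise
#' distance) and takes the top `k`.
#'
#' @param table a `feature_table` (fused or raw).
#' @param labels class labels aligned with the rows of `table` (defaults to
#'   the table's `label` column).
#' @param method one of `"CMIM"`, `"DISR"`, `"ICAP"`, `"JMI"`, `"MIM"`,
#'   `"SPEC"`.
#' @param k number of features to select.
#' @param bins equal-frequency bins for MI estimation.
#' @return An object of class `selector_result`: list with `method`,
#'   `selected` (character(k)), `scores` (criterion value at selection),
#'   `ranking` (full permutation for SPEC/MIM; selection order otherwise),
#'   `k` and `bins`.
#' @export
score_features <- function(table, labels = NULL, method, k = 10L, bins = 5L) {
  if (!method %in% selector_methods()) {
    stop_hab("unknown selector method: ", method)
  }
  feats <- feature_columns(table)
  p <- length(feats)
  if (k > p) stop_hab("k exceeds the number of features")
  if (is.null(labels)) labels <- table$label
  y <- as.character(labels)
  X <- as.matrix(table[, feats, drop = FALSE])

  if (method == "SPEC") {
    sc <- spec_scores(X)
    ord <- order(sc, feats)  # smaller = more consistent; ties by name
    ranking <- feats[ord]
    return(structure(list(method = method, selected = ranking[seq_len(k)],
                          scores = sc[ord][seq_len(k)], ranking = ranking,
                          k = as.integer(k), bins = as.integer(bins)),
                     class = "selector_result"))
  }

  D <- discretize_table(X, bins)
  cols <- lapply(seq_len(p), function(j) D[, j])
  names(cols) <- feats
  yi <- as.integer(factor(y, levels = sort(unique(y))))
  ny <- max(yi)
  selected <- character(0)
  sel_scores <- numeric(0)
  S <- list()
  remaining <- feats
  for (step in seq_len(k)) {
    crit <- vapply(remaining, function(f) {
      mi_criterion(method, cols[[f]], yi, S, bins = bins, ny = ny)
    }, numeric(1))
    ord <- order(-crit, remaining)
    best <- remaining[ord[1]]
    selected <- c(selected, best)
    sel_scores <- c(sel_scores, crit[ord[1]])
    S <- c(S, cols[best])
    remaining <- setdiff(remaining, best)
  }
  structure(list(method = method, selected = selected, scores = sel_scores,
                 ranking = selected, k = as.integer(k),
                 bins = as.integer(bins)),
            class = "selector_result")
}

# SPEC ranking score (second variant of the spectral feature-selection
# family): phi2(f) = (f~' L~ f~) / (1 - (f~' xi1)^2) with f~ the
# degree-weighted normalized feature and xi1 the principal eigenvector of
# the normalized similarity. Smaller is better.
spec_scores <- function(X) {
  n <- nrow(X)
  Z <- scale(X)
  Z[!is.finite(Z)] <- 0
  d2 <- as.matrix(stats::dist(Z))^2
  med <- stats::median(d2[upper.tri(d2)])
  if (!is.finite(med) || med <= 0) med <- 1
  W <- exp(-d2 / (2 * med))
  diag(W) <- 1
  deg <- rowSums(W)
  Dhalf <- 1 / sqrt(deg)
  S <- W * tcrossprod(Dhalf)          # D^-1/2 W D^-1/2
  xi1 <- sqrt(deg) / sqrt(sum(deg))   # principal eigenvector of S
  vapply(seq_len(ncol(X)), function(j) {
    f <- X[, j]
    fh <- sqrt(deg) * f                 # D^1/2 f
    nrm <- sqrt(sum(fh^2))
    if (nrm == 0) return(Inf)
    fh <- fh / nrm
    num <- sum(fh * fh) - as.numeric(t(fh) %*% S %*% fh)  # fh' L~ fh
    den <- 1 - sum(fh * xi1)^2
    if (den <= 1e-12) Inf else num / den
  }, numeric(1))
}
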