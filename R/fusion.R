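#' Fit the per-feature multisequence fusion transform
#'
#' For each radiomic feature, the values observed on the m input sequences
#' form an n x m matrix (after per-sequence standardization with training
#' statistics). Fusion learns, from training labels only, a projection
#' w (||w|| = 1) of that matrix onto `r` fused coordinates that maximizes the
#' Fisher criterion — the ratio of between-class to (regularized)
#' within-class scatter — so class structure is concentrated in the fused
#' value and between-class correlation across sequences is reduced. With a
#' single input sequence the transform is the identity on the standardized
#' feature. A simpler between-class-only variant (`method = "between"`) that
#' projects onto the standardized class-mean difference is available.
#'
#' @param tables named list of `feature_table`, one per sequence, with
#'   identical subjects (same order) and features.
#' @param labels factor-like vector of class labels (2 classes required).
#' @param r fused dimension per feature (default 1; at most m).
#' @param method `"fisher"` (default) or `"between"`.
#' @param lambda within-class scatter ridge, as a fraction of trace(Sw)/m.
#' @return An object of class `fusion_transform`.
#' @export
fit_fusion <- function(tables, labels, r = 1L, method = c("fisher", "between"),
                       lambda = 1e-3) {
  method <- match.arg(method)
  m <- length(tables)
  if (m < 1) stop_hab("at least one sequence table required")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop_hab("fusion requires exactly two classes")
  feats <- feature_columns(tables[[1]])
  n <- nrow(tables[[1]])
  for (tb in tables) {
    if (!identical(feature_columns(tb), feats) || nrow(tb) != n) {
      stop_hab("sequence tables must share subjects and features")
    }
  }
  if (r > max(m, 1L)) stop_hab("fused dimension r cannot exceed m")
  if (m == 1L && r == 1L) {
    # identity on the standardized single sequence
  }

  # per sequence-feature standardization constants from the training data
  mats <- lapply(tables, function(tb) as.matrix(tb[, feats, drop = FALSE]))
  mus <- lapply(mats, colMeans)
  sds <- lapply(mats, function(X) apply(X, 2, stats::sd))
  zero_sd <- Reduce(`|`, lapply(sds, function(s) !is.finite(s) | s == 0))
  if (any(zero_sd)) {
    warning(sum(zero_sd), " constant feature(s) pass through fusion as 0")
  }

  std <- function(k) {
    X <- sweep(mats[[k]], 2, mus[[k]])
    s <- sds[[k]]
    s[!is.finite(s) | s == 0] <- 1
    sweep(X, 2, s, `/`)
  }
  Z <- lapply(seq_len(m), std)
  g1 <- labels == classes[1]

  weights <- vector("list", length(feats))
  names(weights) <- feats
  for (jf in seq_along(feats)) {
    V <- vapply(Z, function(z) z[, jf], numeric(n))  # n x m
    if (m == 1L) {
      w <- matrix(1, 1, 1)
    } else {
      w <- fisher_direction(V, g1, r = r, method = method, lambda = lambda)
    }
    weights[[jf]] <- w
  }

  structure(list(
    weights = weights, mus = mus, sds = sds, sequences = names(tables),
    features = feats, classes = classes, r = as.integer(r), method = method,
    lambda = lambda, fitted = TRUE
  ), class = "fusion_transform")
}

# Top-r Fisher discriminant directions of an n x m matrix V with binary
# grouping g1; columns are unit-norm with the first nonzero entry positive.
fisher_direction <- function(V, g1, r = 1L, method = "fisher",
                              lambda = 1e-3) {
  m <- ncol(V)
  mu1 <- colMeans(V[g1, , drop = FALSE])
  mu2 <- colMeans(V[!g1, , drop = FALSE])
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
  d <- mu1 - mu2
  if (method == "between") {
    w <- if (sum(d^2) > 0) d / sqrt(sum(d^2)) else c(1, rep(0, m - 1))
    return(fix_sign(matrix(w, ncol = 1)))
  }
  C1 <- V[g1, , drop = FALSE]; C2 <- V[!g1, , drop = FALSE]
  Sw <- (crossprod(sweep(C1, 2, mu1)) + crossprod(sweep(C2, 2, mu2))) / n
  Sb <- (n1 / n) * (n2 / n) * tcrossprod(d)
  Swr <- Sw + diag(lambda * max(sum(diag(Sw)), .Machine$double.eps) / m, m)
  if (r == 1L) {
    w <- solve(Swr, d)
    nr <- sqrt(sum(w^2))
    w <- if (nr > 0) w / nr else c(1, rep(0, m - 1))
    return(fix_sign(matrix(w, ncol = 1)))
  }
  # r > 1: generalized eigenvectors of (Swr, Sb) via whitening
  R <- chol(Swr)
  Ri <- backsolve(R, diag(m))
  M <- t(Ri) %*% Sb %*% Ri
  E <- eigen((M + t(M)) / 2, symmetric = TRUE)
  W <- Ri %*% E$vectors[, seq_len(r), drop = FALSE]
  W <- apply(W, 2, function(w) {
    nr <- sqrt(sum(w^2)); if (nr > 0) w / nr else w
  })
  fix_sign(matrix(W, ncol = r))
}

# Resolve eigenvector sign ambiguity: first nonzero component positive.
fix_sign <- function(W) {
  for (k in seq_len(ncol(W))) {
    nz <- which(abs(W[, k]) > 1e-12)
    if (length(nz) && W[nz[1], k] < 0) W[, k] <- -W[, k]
  }
  W
}

# Fisher criterion of a 1-D series under binary grouping, with the same
# regularized denominator used when fitting (used by tests and diagnostics).
fisher_ratio_1d <- function(x, g1, lambda = 0) {
  mu1 <- mean(x[g1]); mu2 <- mean(x[!g1])
  n1 <- sum(g1); n2 <- sum(!g1); n <- length(x)
  sw <- (sum((x[g1] - mu1)^2) + sum((x[!g1] - mu2)^2)) / n
  sb <- (n1 / n) * (n2 / n) * (mu1 - mu2)^2
  sb / (sw + lambda)
}

#' Apply a fitted fusion transform
#'
#' Standardizes each sequence table with the training constants and projects
#' each feature's per-sequence values onto the learned directions. Labels of
#' the applied set are never used, so held-out data cannot leak.
#'
#' @param ft a fitted `fusion_transform`.
#' @param tables named list of `feature_table` per sequence, with the same
#'   sequences and features as at fit time.
#' @return A `feature_table` of fused features (names suffixed `.f2`, ...
#'   when `r > 1`).
#' @export
apply_fusion <- function(ft, tables) {
  if (!isTRUE(ft$fitted)) stop_hab("fusion transform is not fitted")
  if (!identical(names(tables), ft$sequences)) {
    stop_hab("sequence set differs from the fitted transform")
  }
  feats <- ft$features
  for (tb in tables) {
    if (!identical(feature_columns(tb), feats)) {
      stop_hab("feature set differs from the fitted transform")
    }
  }
  n <- nrow(tables[[1]])
  m <- length(tables)
  Z <- lapply(seq_len(m), function(k) {
    X <- as.matrix(tables[[k]][, feats, drop = FALSE])
    X <- sweep(X, 2, ft$mus[[k]])
    s <- ft$sds[[k]]
    s[!is.finite(s) | s == 0] <- 1
    sweep(X, 2, s, `/`)
  })
  r <- ft$r
  out_names <- if (r == 1L) feats else {
    as.vector(vapply(feats, function(f) {
      c(f, paste0(f, ".f", 2:r))
    }, character(r)))
  }
  out <- matrix(0, n, length(out_names),
                dimnames = list(rownames(tables[[1]]), out_names))
  for (jf in seq_along(feats)) {
    V <- vapply(Z, function(z) z[, jf], numeric(n))
    if (is.null(dim(V))) V <- matrix(V, nrow = n)
    proj <- V %*% ft$weights[[jf]]
    cols <- if (r == 1L) jf else ((jf - 1L) * r + 1L):(jf * r)
    out[, cols] <- proj
  }
  res <- data.frame(subject_id = tables[[1]]$subject_id,
                    label = tables[[1]]$label,
                    out, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(res) <- res$subject_id
  class(res) <- c("feature_table", class(res))
  res
}

#' Enumerate the 15 sequence combinations
#'
#' All non-empty subsets of the four MRI sequences: 4 singletons, 6 pairs,
#' 4 triples and the full quadruple, canonically ordered by subset size then
#' lexicographic index. Combo labels follow the `F_seq^{...}` superscript
#' convention, e.g. `F_seq^1,2,3,4` for the quadruple.
#'
#' @param sequences character(4) of distinct sequence names.
#' @return A list of character vectors; names are the combo labels.
#' @export
enumerate_sequence_combos <- function(sequences = phantom_sequences()) {
  if (length(sequences) != 4 || anyDuplicated(sequences)) {
    stop_hab("need 4 distinct sequence names")
  }
  combos <- unlist(lapply(1:4, function(k) {
    apply(utils::combn(4L, k), 2, identity, simplify = FALSE)
  }), recursive = FALSE)
  out <- lapply(combos, function(idx) sequences[idx])
  names(out) <- vapply(combos, function(idx) {
    paste0("F_seq^", paste(idx, collapse = ","))
  }, character(1))
  out
}

#' Serialize / restore a fusion transform as JSON
#'
#' @param ft a `fusion_transform`.
#' @param path JSON file path.
#' @return `read_fusion()` returns the transform; the writer returns the
#'   path invisibly.
#' @export
write_fusion <- function(ft, path) {
  payload <- list(
    sequences = ft$sequences, features = ft$features, classes = ft$classes,
    r = ft$r, method = ft$method, lambda = ft$lambda,
    weights = lapply(ft$weights, function(w) as.numeric(w)),
    mus = ft$mus, sds = ft$sds
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fusion
#' @export
read_fusion <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- length(p$sequences)
  structure(list(
    weights = lapply(p$weights, function(w) matrix(w, nrow = m)),
    mus = lapply(p$mus, unlist), sds = lapply(p$sds, unlist),
    sequences = p$sequences, features = p$features, classes = p$classes,
    r = as.integer(p$r), method = p$method, lambda = p$lambda, fitted = TRUE
  ), class = "fusion_transform")
}
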