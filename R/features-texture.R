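# Gray-level texture-matrix features: GLCM (24), GLRLM (16), GLSZM (16),
# GLDM (14) and NGTDM (5), computed in 3-D over the 13 unique direction
# offsets at distance 1 (26-connectivity). Co-occurrence is symmetric and the
# per-direction matrices are summed (merged) before feature computation; run
# and zone counts are likewise accumulated over directions. Gray levels come
# from in-mask discretization (fixed bin count by default).

#' Discretization settings for gray-level features
#'
#' @param mode `"fixed_bin_count"` (default, robust on arbitrary-scale data)
#'   or `"fixed_bin_width"`.
#' @param value number of bins (default 32) or the bin width.
#' @return An object of class `discretization_settings`.
#' @export
discretization_settings <- function(mode = c("fixed_bin_count",
                                             "fixed_bin_width"),
                                    value = NULL) {
  mode <- match.arg(mode)
  if (is.null(value)) value <- if (mode == "fixed_bin_count") 32 else 16
  if (value <= 0) stop_hab("discretization value must be positive")
  structure(list(mode = mode, value = value),
            class = "discretization_settings")
}

# Map raw intensities to integer gray levels 1..Ng.
discretize_values <- function(x, disc) {
  if (disc$mode == "fixed_bin_count") {
    rng <- range(x)
    if (rng[2] <= rng[1]) return(rep(1L, length(x)))
    nb <- as.integer(disc$value)
    lv <- floor((x - rng[1]) / (rng[2] - rng[1]) * nb) + 1L
    pmin.int(lv, nb)
  } else {
    lv <- floor(x / disc$value)
    as.integer(lv - min(lv) + 1L)
  }
}

# The 13 unique direction offsets at distance 1 in 3-D (half of the 26
# neighbors; the other half are their negations).
offsets_13 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  keep <- apply(g, 1, function(d) {
    nz <- d[d != 0]
    nz[1] > 0
  })
  m <- g[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

# Linear indices of all (a, b = a + d) voxel pairs inside the grid.
offset_pairs <- function(dimv, d) {
  rng <- lapply(1:3, function(k) {
    base <- seq_len(max(0L, dimv[k] - abs(d[k])))
    if (d[k] < 0) base - d[k] else base
  })
  idx <- array(seq_len(prod(dimv)), dim = dimv)
  a <- idx[rng[[1]], rng[[2]], rng[[3]]]
  b <- idx[rng[[1]] + d[1], rng[[2]] + d[2], rng[[3]] + d[3]]
  list(a = as.integer(a), b = as.integer(b))
}

# Discretized level array with NA outside the mask, cropped to the mask
# bounding box (plus one voxel) — texture statistics only involve in-mask
# voxels and their immediate neighbors, and cropping keeps the per-offset
# array passes proportional to the lesion, not the scan.
level_array <- function(volume, mask, disc) {
  sub <- which(mask$voxels, arr.ind = TRUE)
  lo <- pmax(apply(sub, 2, min) - 1L, 1L)
  hi <- pmin(apply(sub, 2, max) + 1L, dim(volume))
  vol_c <- volume[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  msk_c <- mask$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  idx <- which(msk_c)
  la <- array(NA_integer_, dim = dim(vol_c))
  lv <- discretize_values(vol_c[idx], disc)
  la[idx] <- lv
  list(la = la, ng = max(lv), n_vox = length(idx))
}

# ---------------------------------------------------------------- GLCM ----

glcm_matrix <- function(la, ng, dimv) {
  counts <- numeric(ng * ng)
  offs <- offsets_13()
  for (r in seq_len(nrow(offs))) {
    d <- offs[r, ]
    pr <- offset_pairs(dimv, d)
    a <- la[pr$a]; b <- la[pr$b]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    a <- a[ok]; b <- b[ok]
    counts <- counts + tabulate((a - 1L) * ng + b, nbins = ng * ng) +
      tabulate((b - 1L) * ng + a, nbins = ng * ng)
  }
  m <- matrix(counts, ng, ng, byrow = TRUE)
  if (sum(m) == 0) m[1, 1] <- 1   # degenerate: single isolated voxel
  m / sum(m)
}

glcm_features <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(seq_len(ng) * px); mu_y <- sum(seq_len(ng) * py)
  sd_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(ng) - mu_y)^2 * py))
  eps <- .Machine$double.eps
  # difference distribution p_{|i-j|}, k = 0..ng-1
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  da <- sum(k_diff * p_diff)
  # sum distribution p_{i+j}, k = 2..2*ng
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), numeric(1))
  hxy <- -sum(P[P > 0] * log2(P[P > 0]))
  pxy <- px[i] * py[j]
  hxy1 <- -sum(P[pxy > 0] * log2(pxy[pxy > 0]))
  hxy2 <- -sum(pxy[pxy > 0] * log2(pxy[pxy > 0]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  mcc <- if (ng == 1L) 1 else {
    # Q[i, j] = sum_k P(i,k) P(j,k) / (px(i) py(k)); MCC is the square root
    # of its second-largest eigenvalue.
    W <- sweep(P, 2, ifelse(py > 0, py, 1), `/`)   # P(j,k)/py(k) columns
    Q <- sweep(P %*% t(W), 1, ifelse(px > 0, px, 1), `/`)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) > 1) sqrt(max(0, min(ev[2], 1))) else 1
  }
  corr <- if (sd_x > eps && sd_y > eps) {
    (sum(i * j * P) - mu_x * mu_y) / (sd_x * sd_y)
  } else 1
  off_diag <- i != j
  c(
    Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - mu_x - mu_y)^4 * P),
    ClusterShade = sum((i + j - mu_x - mu_y)^3 * P),
    ClusterTendency = sum((i + j - mu_x - mu_y)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(p_diff[p_diff > 0] * log2(p_diff[p_diff > 0])),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / ng)^2)),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(P[off_diag] / (i[off_diag] - j[off_diag])^2),
    JointAverage = mu_x,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(k_sum * p_sum),
    SumEntropy = -sum(p_sum[p_sum > 0] * log2(p_sum[p_sum > 0])),
    SumSquares = sum((i - mu_x)^2 * P)
  )
}

# --------------------------------------------------------------- GLRLM ----

# Run-length counts along one direction: dynamic programming on the chain
# v -> v + d, processed in decreasing projection order so successors are
# resolved first.
run_lengths_direction <- function(la, dimv, d) {
  n <- prod(dimv)
  pr <- offset_pairs(dimv, d)
  a <- pr$a
  b <- pr$b
  same <- !is.na(la[a]) & !is.na(la[b]) & la[a] == la[b]
  succ <- rep(NA_integer_, n)
  succ[a[same]] <- b[same]
  has_pred <- logical(n)
  has_pred[b[same]] <- TRUE

  # chain length by walking from run starts
  starts <- which(!is.na(la) & !has_pred)
  lens <- integer(length(starts))
  cur <- starts
  alive <- seq_along(starts)
  while (length(alive)) {
    lens[alive] <- lens[alive] + 1L
    nxt <- succ[cur]
    keep <- !is.na(nxt)
    cur <- nxt[keep]
    alive <- alive[keep]
  }
  list(level = la[starts], length = lens)
}

glrlm_matrix <- function(la, ng, dimv) {
  offs <- offsets_13()
  levels <- integer(0)
  lens <- integer(0)
  for (r in seq_len(nrow(offs))) {
    rl <- run_lengths_direction(la, dimv, offs[r, ])
    levels <- c(levels, rl$level)
    lens <- c(lens, rl$length)
  }
  nr <- max(lens)
  m <- matrix(0, ng, nr)
  for (q in seq_along(levels)) m[levels[q], lens[q]] <- m[levels[q], lens[q]] + 1
  m
}

rle_style_features <- function(m, n_vox, n_dir, prefix) {
  # Shared feature math for GLRLM (runs) and GLSZM (zones): m[level, size].
  nr <- sum(m)
  p <- m / nr
  i <- row(m); j <- col(m)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  pj <- colSums(m); pi <- rowSums(m)
  pnz <- p[p > 0]
  vals <- c(
    sum(m / j^2) / nr,                    # short emphasis
    sum(m * j^2) / nr,                    # long emphasis
    sum(pi^2) / nr,                       # gray-level non-uniformity
    sum(pi^2) / nr^2,                     # ... normalized
    sum(pj^2) / nr,                       # size non-uniformity
    sum(pj^2) / nr^2,                     # ... normalized
    nr / (n_vox * n_dir),                 # percentage
    sum(p * (i - mu_i)^2),                # gray-level variance
    sum(p * (j - mu_j)^2),                # size variance
    -sum(pnz * log2(pnz)),                # entropy
    sum(m / i^2) / nr,                    # low gray-level emphasis
    sum(m * i^2) / nr,                    # high gray-level emphasis
    sum(m / (i^2 * j^2)) / nr,            # short + low
    sum((m * i^2) / j^2) / nr,            # short + high
    sum((m * j^2) / i^2) / nr,            # long + low
    sum(m * i^2 * j^2) / nr               # long + high
  )
  names(vals) <- paste0(prefix, c(
    "ShortEmphasis", "LongEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "SizeNonUniformity",
    "SizeNonUniformityNormalized", "Percentage", "GrayLevelVariance",
    "SizeVariance", "Entropy", "LowGrayLevelEmphasis",
    "HighGrayLevelEmphasis", "ShortLowGrayLevelEmphasis",
    "ShortHighGrayLevelEmphasis", "LongLowGrayLevelEmphasis",
    "LongHighGrayLevelEmphasis"))
  vals
}

glrlm_features <- function(m, n_vox) {
  v <- rle_style_features(m, n_vox, n_dir = 13, prefix = "")
  c(
    ShortRunEmphasis = unname(v["ShortEmphasis"]),
    LongRunEmphasis = unname(v["LongEmphasis"]),
    GrayLevelNonUniformity = unname(v["GrayLevelNonUniformity"]),
    GrayLevelNonUniformityNormalized =
      unname(v["GrayLevelNonUniformityNormalized"]),
    RunLengthNonUniformity = unname(v["SizeNonUniformity"]),
    RunLengthNonUniformityNormalized =
      unname(v["SizeNonUniformityNormalized"]),
    RunPercentage = unname(v["Percentage"]),
    GrayLevelVariance = unname(v["GrayLevelVariance"]),
    RunVariance = unname(v["SizeVariance"]),
    RunEntropy = unname(v["Entropy"]),
    LowGrayLevelRunEmphasis = unname(v["LowGrayLevelEmphasis"]),
    HighGrayLevelRunEmphasis = unname(v["HighGrayLevelEmphasis"]),
    ShortRunLowGrayLevelEmphasis = unname(v["ShortLowGrayLevelEmphasis"]),
    ShortRunHighGrayLevelEmphasis = unname(v["ShortHighGrayLevelEmphasis"]),
    LongRunLowGrayLevelEmphasis = unname(v["LongLowGrayLevelEmphasis"]),
    LongRunHighGrayLevelEmphasis = unname(v["LongHighGrayLevelEmphasis"])
  )
}

# --------------------------------------------------------------- GLSZM ----

glszm_matrix <- function(la, ng, dimv) {
  in_idx <- which(!is.na(la))
  vid <- rep(NA_integer_, prod(dimv))
  vid[in_idx] <- seq_along(in_idx)
  offs <- offsets_13()
  ea <- integer(0); eb <- integer(0)
  for (r in seq_len(nrow(offs))) {
    pr <- offset_pairs(dimv, offs[r, ])
    ok <- !is.na(la[pr$a]) & !is.na(la[pr$b]) & la[pr$a] == la[pr$b]
    ea <- c(ea, vid[pr$a[ok]])
    eb <- c(eb, vid[pr$b[ok]])
  }
  g <- igraph::make_graph(rbind(ea, eb), n = length(in_idx), directed = FALSE)
  comp <- igraph::components(g)
  zone_level <- la[in_idx][match(seq_len(comp$no), comp$membership)]
  zone_size <- comp$csize
  ns <- max(zone_size)
  m <- matrix(0, ng, ns)
  for (q in seq_along(zone_size)) {
    m[zone_level[q], zone_size[q]] <- m[zone_level[q], zone_size[q]] + 1
  }
  m
}

glszm_features <- function(m, n_vox) {
  v <- rle_style_features(m, n_vox, n_dir = 1, prefix = "")
  nz <- sum(m)
  c(
    SmallAreaEmphasis = unname(v["ShortEmphasis"]),
    LargeAreaEmphasis = unname(v["LongEmphasis"]),
    GrayLevelNonUniformity = unname(v["GrayLevelNonUniformity"]),
    GrayLevelNonUniformityNormalized =
      unname(v["GrayLevelNonUniformityNormalized"]),
    SizeZoneNonUniformity = unname(v["SizeNonUniformity"]),
    SizeZoneNonUniformityNormalized =
      unname(v["SizeNonUniformityNormalized"]),
    ZonePercentage = nz / n_vox,
    GrayLevelVariance = unname(v["GrayLevelVariance"]),
    ZoneVariance = unname(v["SizeVariance"]),
    ZoneEntropy = unname(v["Entropy"]),
    LowGrayLevelZoneEmphasis = unname(v["LowGrayLevelEmphasis"]),
    HighGrayLevelZoneEmphasis = unname(v["HighGrayLevelEmphasis"]),
    SmallAreaLowGrayLevelEmphasis = unname(v["ShortLowGrayLevelEmphasis"]),
    SmallAreaHighGrayLevelEmphasis = unname(v["ShortHighGrayLevelEmphasis"]),
    LargeAreaLowGrayLevelEmphasis = unname(v["LongLowGrayLevelEmphasis"]),
    LargeAreaHighGrayLevelEmphasis = unname(v["LongHighGrayLevelEmphasis"])
  )
}

# ---------------------------------------------------------------- GLDM ----

# Dependence: for each in-mask voxel, 1 + the number of its 26-neighbors in
# the mask with the same gray level (alpha = 0); the center voxel always
# depends on itself.
gldm_matrix <- function(la, ng, dimv) {
  n <- prod(dimv)
  dep <- integer(n)
  offs <- offsets_13()
  for (r in seq_len(nrow(offs))) {
    pr <- offset_pairs(dimv, offs[r, ])
    ok <- !is.na(la[pr$a]) & !is.na(la[pr$b]) & la[pr$a] == la[pr$b]
    aa <- pr$a[ok]; bb <- pr$b[ok]
    dep <- dep + tabulate(aa, nbins = n) + tabulate(bb, nbins = n)
  }
  in_idx <- which(!is.na(la))
  jj <- dep[in_idx] + 1L
  nd <- max(jj)
  m <- matrix(0, ng, nd)
  for (q in seq_along(in_idx)) m[la[in_idx[q]], jj[q]] <- m[la[in_idx[q]], jj[q]] + 1
  m
}

gldm_features <- function(m) {
  nz <- sum(m)
  p <- m / nz
  i <- row(m); j <- col(m)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  pi <- rowSums(m); pj <- colSums(m)
  pnz <- p[p > 0]
  c(
    SmallDependenceEmphasis = sum(m / j^2) / nz,
    LargeDependenceEmphasis = sum(m * j^2) / nz,
    GrayLevelNonUniformity = sum(pi^2) / nz,
    DependenceNonUniformity = sum(pj^2) / nz,
    DependenceNonUniformityNormalized = sum(pj^2) / nz^2,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    DependenceVariance = sum(p * (j - mu_j)^2),
    DependenceEntropy = -sum(pnz * log2(pnz)),
    LowGrayLevelEmphasis = sum(m / i^2) / nz,
    HighGrayLevelEmphasis = sum(m * i^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(m / (i^2 * j^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum((m * i^2) / j^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum((m * j^2) / i^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(m * i^2 * j^2) / nz
  )
}

# --------------------------------------------------------------- NGTDM ----

ngtdm_table <- function(la, ng, dimv) {
  n <- prod(dimv)
  nbr_sum <- numeric(n)
  nbr_cnt <- integer(n)
  offs <- offsets_13()
  for (r in seq_len(nrow(offs))) {
    pr <- offset_pairs(dimv, offs[r, ])
    ok <- !is.na(la[pr$a]) & !is.na(la[pr$b])
    aa <- pr$a[ok]; bb <- pr$b[ok]
    nbr_sum <- nbr_sum + tabulate2(aa, la[bb], n) + tabulate2(bb, la[aa], n)
    nbr_cnt <- nbr_cnt + tabulate(aa, nbins = n) + tabulate(bb, nbins = n)
  }
  in_idx <- which(!is.na(la))
  in_idx <- in_idx[nbr_cnt[in_idx] > 0]
  lv <- la[in_idx]
  abar <- nbr_sum[in_idx] / nbr_cnt[in_idx]
  dev <- abs(lv - abar)
  n_i <- tabulate(lv, nbins = ng)
  s_i <- vapply(seq_len(ng), function(g) sum(dev[lv == g]), numeric(1))
  list(n = n_i, s = s_i, nvp = length(in_idx))
}

# weighted tabulate: sum w over positions idx
tabulate2 <- function(idx, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(as.numeric(w), idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

ngtdm_features <- function(tb, ng) {
  p <- tb$n / tb$nvp
  s <- tb$s
  act <- which(p > 0)
  ngp <- length(act)
  i <- seq_len(ng)
  eps <- .Machine$double.eps
  coarse_den <- sum(p * s)
  coarseness <- if (coarse_den > eps) 1 / coarse_den else 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(p[act], p[act]) * outer(i[act], i[act], `-`)^2) /
       (ngp * (ngp - 1))) * (sum(s) / tb$nvp)
  } else 0
  busy_den <- sum(abs(outer(i[act] * p[act], i[act] * p[act], `-`)))
  busyness <- if (busy_den > eps) sum(p * s) / busy_den else 0
  complexity <- if (ngp > 0) {
    pi_ <- p[act]; ii <- i[act]; si <- s[act]
    num <- outer(ii, ii, function(a, b) abs(a - b)) *
      (outer(pi_ * si, rep(1, ngp)) + outer(rep(1, ngp), pi_ * si)) /
      (outer(pi_, rep(1, ngp)) + outer(rep(1, ngp), pi_))
    sum(num) / tb$nvp
  } else 0
  strength <- if (sum(s) > eps) {
    pi_ <- p[act]; ii <- i[act]
    sum((outer(pi_, rep(1, ngp)) + outer(rep(1, ngp), pi_)) *
          outer(ii, ii, `-`)^2) / sum(s)
  } else 0
  c(Busyness = busyness, Coarseness = coarseness, Complexity = complexity,
    Contrast = contrast, Strength = strength)
}

#' Extract the 75 texture features
#'
#' GLCM (24), GLRLM (16), GLSZM (16), GLDM (14) and NGTDM (5) features over
#' the discretized in-mask intensities, using the 13 unique 3-D direction
#' offsets at distance 1 with symmetric co-occurrence, matrices merged over
#' directions. A mask whose voxels fall into a single gray level after
#' discretization yields the analytic single-level limits (e.g. GLCM
#' Contrast 0) with a warning.
#'
#' @param volume 3-D numeric array.
#' @param mask a `subregion_mask` with at least 2 voxels.
#' @param disc [discretization_settings()].
#' @return Named numeric vector of length 75, names prefixed by family
#'   (`glcm_`, `glrlm_`, `glszm_`, `gldm_`, `ngtdm_`).
#' @export
extract_texture <- function(volume, mask, disc = discretization_settings()) {
  if (sum(mask$voxels) < 2) stop_hab("texture extraction needs >= 2 voxels")
  lv <- level_array(volume, mask, disc)
  if (lv$ng == 1L) {
    warning("single gray level after discretization; texture features take ",
            "their degenerate limits")
  }
  dimv <- dim(lv$la)
  glcm <- glcm_features(glcm_matrix(lv$la, lv$ng, dimv))
  glrlm <- glrlm_features(glrlm_matrix(lv$la, lv$ng, dimv), lv$n_vox)
  glszm <- glszm_features(glszm_matrix(lv$la, lv$ng, dimv), lv$n_vox)
  gldm <- gldm_features(gldm_matrix(lv$la, lv$ng, dimv))
  ngtdm <- ngtdm_features(ngtdm_table(lv$la, lv$ng, dimv), lv$ng)
  c(stats::setNames(glcm, paste0("glcm_", names(glcm))),
    stats::setNames(glrlm, paste0("glrlm_", names(glrlm))),
    stats::setNames(glszm, paste0("glszm_", names(glszm))),
    stats::setNames(gldm, paste0("gldm_", names(gldm))),
    stats::setNames(ngtdm, paste0("ngtdm_", names(ngtdm))))
}
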