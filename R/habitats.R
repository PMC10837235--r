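#' Min-max intensity normalization inside a mask
#'
#' Rescales the in-mask voxels of a volume to `[0, 1]` per subject, leaving
#' out-of-mask voxels untouched. Min-max (rather than z-scoring) keeps the
#' high/low split symmetric and comparable across subjects. A constant
#' in-mask signal maps to all zeros and is flagged as degenerate via the
#' `"degenerate"` attribute.
#'
#' @param volume 3-D numeric array.
#' @param mask a `subregion_mask` with at least one voxel.
#' @return The volume with in-mask voxels rescaled; attribute `degenerate`
#'   is `TRUE` when the in-mask signal was constant.
#' @export
normalize_intensity <- function(volume, mask) {
  idx <- which(mask$voxels)
  if (length(idx) == 0) stop_hab("cannot normalize inside an empty mask")
  vals <- volume[idx]
  rng <- range(vals)
  degenerate <- rng[2] <= rng[1]
  volume[idx] <- if (degenerate) 0 else (vals - rng[1]) / (rng[2] - rng[1])
  attr(volume, "degenerate") <- degenerate
  volume
}

# Exact deterministic 1-D two-class K-means. In one dimension the optimal
# 2-means partition is a split of the sorted values, so the global optimum
# is found by enumerating all splits at strict value increases (prefix-sum
# within-cluster sums of squares); no seed, no iteration, no local optima.
# Values equal to the boundary value join the low cluster.
kmeans_1d_2 <- function(values) {
  xs <- sort(values)
  n <- length(xs)
  if (xs[1] == xs[n]) {
    stop_hab("two-class K-means needs at least 2 distinct values")
  }
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  k <- seq_len(n - 1)
  ss_lo <- cs2[k] - cs[k]^2 / k
  ss_hi <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  obj <- ss_lo + ss_hi
  valid <- xs[k] < xs[k + 1]            # splits inside tied runs are never optimal
  obj[!valid] <- Inf
  s <- which.min(obj)                   # first optimum on ties: deterministic
  cut <- xs[s]
  high <- values > cut
  list(high = high,
       centroids = c(mean(values[!high]), mean(values[high])))
}

#' Split normalized in-mask intensities into high and low by 2-means
#'
#' One-dimensional K-means with a preset K = 2 over the in-mask intensities;
#' the cluster with the larger centroid is labeled "high". The optimizer is
#' exact: in one dimension the optimal 2-means partition is a split of the
#' sorted intensities, found by enumerating all splits, so the result is the
#' global optimum and reproducible without a seed. Values equal to the split
#' boundary join the low cluster.
#'
#' @param volume 3-D numeric array (typically min-max normalized).
#' @param mask a `subregion_mask`.
#' @return A list with `high` (3-D logical array, `TRUE` for in-mask voxels
#'   in the high cluster) and `centroids` (sorted numeric(2)).
#' @export
binarize_kmeans <- function(volume, mask) {
  idx <- which(mask$voxels)
  if (length(idx) == 0) stop_hab("cannot binarize inside an empty mask")
  km <- kmeans_1d_2(volume[idx])
  high <- array(FALSE, dim = dim(volume))
  high[idx] <- km$high
  list(high = high, centroids = km$centroids)
}

#' Combine per-sequence high/low maps into four habitats
#'
#' The two binarized sequences (post-contrast T1 and T2-FLAIR) are combined
#' voxelwise with AND into four habitats covering the whole-lesion mask:
#' H1 = high T1WIC & high FLAIR, H2 = high T1WIC & low FLAIR,
#' H3 = low T1WIC & high FLAIR, H4 = low T1WIC & low FLAIR. The habitats
#' partition the mask exactly.
#'
#' @param high_t1c,high_flair 3-D logical arrays from [binarize_kmeans()].
#' @param mask the whole-lesion `subregion_mask` (VOI_123).
#' @param centroids optional list with the per-sequence centroid pairs,
#'   carried along for reporting.
#' @return An object of class `habitat_labeling`: list with `label_map`
#'   (3-D integer array, 0 outside the mask, 1..4 = H1..H4), `centroids`,
#'   `spacing` and `mask_name`.
#' @export
build_habitats <- function(high_t1c, high_flair, mask, centroids = NULL) {
  if (!identical(dim(high_t1c), dim(mask$voxels)) ||
      !identical(dim(high_flair), dim(mask$voxels))) {
    stop_hab("high/low maps and mask have mismatched geometry")
  }
  lab <- array(0L, dim = dim(mask$voxels))
  m <- mask$voxels
  lab[m & high_t1c & high_flair] <- 1L
  lab[m & high_t1c & !high_flair] <- 2L
  lab[m & !high_t1c & high_flair] <- 3L
  lab[m & !high_t1c & !high_flair] <- 4L
  structure(list(label_map = lab, centroids = centroids,
                 spacing = mask$spacing, mask_name = mask$name),
            class = "habitat_labeling")
}

#' Run the full habitat segmentation for one subject
#'
#' Normalizes post-contrast T1 and T2-FLAIR inside the whole-lesion mask,
#' binarizes each with two-class K-means, and combines into H1..H4.
#'
#' @param vs a `volume_set`.
#' @param mask whole-lesion `subregion_mask` (VOI_123).
#' @return A `habitat_labeling` object.
#' @export
segment_habitats <- function(vs, mask) {
  check_alignment(vs, mask)
  t1c <- normalize_intensity(vs$volumes[["T1WIC"]], mask)
  flair <- normalize_intensity(vs$volumes[["T2FLAIR"]], mask)
  b1 <- binarize_kmeans(t1c, mask)
  b2 <- binarize_kmeans(flair, mask)
  build_habitats(b1$high, b2$high, mask,
                 centroids = list(T1WIC = b1$centroids,
                                  T2FLAIR = b2$centroids))
}

#' Enumerate the fifteen habitat-union subregions
#'
#' All `2^4 - 1` unions of the four habitats, named by sorted index
#' concatenation (`H_1`, ..., `H_34`, ..., `H_1234`). `H_1234` equals the
#' whole-lesion mask. Empty unions are allowed and flagged via the
#' `"empty"` attribute for downstream exclusion.
#'
#' @param h a `habitat_labeling`.
#' @return Named list of 15 `subregion_mask` objects.
#' @export
enumerate_habitat_unions <- function(h) {
  combos <- unlist(lapply(1:4, function(k) {
    apply(utils::combn(4L, k), 2, identity, simplify = FALSE)
  }), recursive = FALSE)
  out <- lapply(combos, function(idx) {
    vox <- array(h$label_map %in% idx, dim = dim(h$label_map))
    nm <- paste0("H_", paste(idx, collapse = ""))
    m <- new_subregion_mask(vox, nm, h$spacing)
    attr(m, "empty") <- !any(vox)
    m
  })
  names(out) <- vapply(combos, function(idx) {
    paste0("H_", paste(idx, collapse = ""))
  }, character(1))
  out
}

#' All 22 candidate subregions for one subject
#'
#' Convenience wrapper producing the seven manual subregions (from the three
#' compartment masks) plus the fifteen habitat unions.
#'
#' @param vs a `volume_set`.
#' @param net,et,pte the three compartment masks.
#' @return Named list of 22 `subregion_mask` objects.
#' @export
all_subregions <- function(vs, net, et, pte) {
  manual <- manual_voi_algebra(net, et, pte)
  hab <- segment_habitats(vs, manual$VOI_123)
  c(manual, enumerate_habitat_unions(hab))
}
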