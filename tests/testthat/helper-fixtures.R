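# Shared fixtures, built in code and memoized across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Mid-size phantom geometry (32 voxel grid) for single-subject checks.
params32 <- function(...) {
  phantom_params(grid_shape = c(32, 32, 32), core_semi_axes = c(4, 3.5, 3),
                 rim_semi_axes = c(7, 6, 5), edema_semi_axes = c(11, 9.5, 8),
                 ...)
}

# Cohort-scale geometry (24 voxel grid) used by the acceptance suite.
params24 <- function(...) {
  phantom_params(grid_shape = c(24, 24, 24), core_semi_axes = c(3, 2.7, 2.4),
                 rim_semi_axes = c(5.2, 4.7, 4.2),
                 edema_semi_axes = c(8.5, 7.7, 7), ...)
}

# Smallest admissible geometry (16 voxel grid) for many-replicate checks.
params16 <- function(...) {
  phantom_params(grid_shape = c(16, 16, 16), core_semi_axes = c(2.2, 2, 1.8),
                 rim_semi_axes = c(3.8, 3.4, 3),
                 edema_semi_axes = c(6.2, 5.6, 5), ...)
}

one_subject32 <- function() {
  fixture("one_subject32", {
    ph <- generate_phantom(params32(), "gbm", seed = 7)
    subs <- all_subregions(ph$volume_set, ph$masks$core, ph$masks$rim,
                           ph$masks$edema)
    list(ph = ph, subs = subs)
  })
}

# H_34 masks for every subject of a cohort.
h34_masks <- function(cohort) {
  lapply(cohort, function(s) {
    all_subregions(s$volume_set, s$masks$core, s$masks$rim,
                   s$masks$edema)$H_34
  })
}

# Synthetic per-sequence feature tables with a controllable class effect,
# for fusion/selection/modeling tests that do not need the image pipeline.
# `effect` is the per-sequence standardized mean shift on the first
# `n_informative` features.
make_synthetic_tables <- function(n_astro = 10, n_gbm = 20, p = 12,
                                  effect = 1, n_informative = 3, seed = 1,
                                  sequences = c("T1WI", "T1WIC", "T2WI",
                                                "T2FLAIR")) {
  labels <- c(rep("astro", n_astro), rep("gbm", n_gbm))
  ids <- sprintf("s%03d", seq_along(labels))
  feats <- sprintf("feat_%02d", seq_len(p))
  set.seed(seed)
  out <- lapply(seq_along(sequences), function(k) {
    X <- matrix(stats::rnorm(length(labels) * p), length(labels), p,
                dimnames = list(ids, feats))
    X[labels == "gbm", seq_len(n_informative)] <-
      X[labels == "gbm", seq_len(n_informative)] + effect
    tab <- data.frame(subject_id = ids, label = labels, X,
                      check.names = FALSE, stringsAsFactors = FALSE)
    class(tab) <- c("feature_table", class(tab))
    tab
  })
  names(out) <- sequences
  out
}

# A small cube mask on a flat grid for mask-algebra tests.
cube_mask <- function(dim3, from, to, name = "m", spacing = c(1, 1, 1)) {
  v <- array(FALSE, dim = dim3)
  v[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  new_subregion_mask(v, name, spacing)
}
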