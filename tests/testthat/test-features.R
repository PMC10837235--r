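test_that("the feature vector has exactly 109 features split 19/15/75", {
  fam <- feature_families()
  expect_length(fam, 109)
  counts <- table(fam)
  expect_equal(unname(counts["first_order"]), 19, ignore_attr = TRUE)
  expect_equal(unname(counts["shape"]), 15, ignore_attr = TRUE)
  expect_equal(sum(counts[c("glcm", "glrlm", "glszm", "gldm", "ngtdm")]), 75)
  expect_equal(unname(counts[c("glcm", "glrlm", "glszm", "gldm", "ngtdm")]),
               c(24, 16, 16, 14, 5), ignore_attr = TRUE)

  sub <- one_subject32()
  fv <- extract_features(sub$ph$volume_set$volumes$T2FLAIR, sub$subs$H_34)
  expect_identical(names(fv), names(fam))
  expect_true(all(is.finite(fv)))
})

test_that("first-order statistics follow their closed forms", {
  d <- c(3, 1, 1)
  mk <- cube_mask(d, c(1, 1, 1), c(3, 1, 1))
  fo <- extract_first_order(array(c(1, 2, 3), d), mk)
  expect_equal(fo[["Mean"]], 2)
  expect_equal(fo[["Energy"]], 14)          # 1 + 4 + 9
  expect_equal(fo[["Range"]], 2)
  expect_equal(fo[["Skewness"]], 0)         # symmetric values
  expect_equal(fo[["Median"]], 2)
  expect_equal(fo[["RootMeanSquared"]], sqrt(14 / 3))

  # Monte-Carlo: N(5, 2^2) sample moments within 3 standard errors
  set.seed(3)
  n <- 1000
  dd <- c(10, 10, 10)
  mkd <- new_subregion_mask(array(TRUE, dd), "all", c(1, 1, 1))
  x <- stats::rnorm(n, 5, 2)
  fo2 <- extract_first_order(array(x, dd), mkd)
  expect_lt(abs(fo2[["Mean"]] - 5), 3 * 2 / sqrt(n))
  expect_lt(abs(fo2[["Variance"]] - 4), 3 * 4 * sqrt(2 / n))
  expect_equal(fo2[["Kurtosis"]], 3, tolerance = 0.2)  # non-excess kurtosis
})

test_that("intensity translation shifts Mean and preserves Variance exactly", {
  sub <- one_subject32()
  vol <- sub$ph$volume_set$volumes$T1WI
  mk <- sub$subs$VOI_3
  a <- extract_first_order(vol, mk)
  b <- extract_first_order(vol + 17.5, mk)
  expect_equal(b[["Mean"]], a[["Mean"]] + 17.5, tolerance = 1e-12)
  expect_equal(b[["Median"]], a[["Median"]] + 17.5, tolerance = 1e-12)
  expect_equal(b[["Variance"]], a[["Variance"]], tolerance = 1e-9)
  expect_equal(b[["Skewness"]], a[["Skewness"]], tolerance = 1e-9)
})

test_that("shape features follow voxel and mesh geometry", {
  d <- c(5, 5, 5)
  single <- cube_mask(d, c(3, 3, 3), c(3, 3, 3))
  s1 <- extract_shape(single)
  expect_equal(s1[["VoxelVolume"]], 1)
  expect_gt(s1[["SurfaceArea"]], 0)

  two <- cube_mask(d, c(3, 3, 3), c(4, 3, 3))
  s2 <- extract_shape(two)
  expect_equal(s2[["Maximum3DDiameter"]], 1)  # voxel-center convention
  expect_equal(s2[["VoxelVolume"]], 2)

  # anisotropic spacing scales the voxel volume
  an <- cube_mask(c(4, 4, 4), c(2, 2, 2), c(3, 3, 3), spacing = c(1, 2, 3))
  expect_equal(extract_shape(an)[["VoxelVolume"]], 8 * 6)

  # digital sphere of radius 10 voxels: near-unit sphericity, and the
  # reciprocal identity with SphericalDisproportion is exact
  n <- 25
  cc <- (1:n) - (n + 1) / 2
  r2 <- outer(outer(cc^2, cc^2, `+`), cc^2, `+`)
  sphere <- new_subregion_mask(r2 <= 100, "sphere", c(1, 1, 1))
  ss <- extract_shape(sphere)
  expect_gte(ss[["Sphericity"]], 0.95)
  expect_lte(ss[["Sphericity"]], 1.0)
  expect_equal(ss[["SphericalDisproportion"]], 1 / ss[["Sphericity"]],
               tolerance = 1e-12)
  expect_equal(ss[["MeshVolume"]], 4 / 3 * pi * 1000, tolerance = 0.05)
  expect_equal(ss[["SurfaceArea"]], 4 * pi * 100, tolerance = 0.05)
  # near-spherical: principal axes nearly equal, elongation/flatness near 1
  expect_equal(ss[["Elongation"]], 1, tolerance = 0.05)
  expect_equal(ss[["MajorAxisLength"]], 2 * 10, tolerance = 0.15)
})

test_that("GLCM probabilities match exhaustive pair enumeration", {
  # 4 x 4 x 1 toy with 2 gray levels; oracle enumerates every voxel pair
  vol <- array(c(1, 1, 2, 2,
                 1, 2, 2, 1,
                 2, 2, 1, 1,
                 1, 2, 1, 2), c(4, 4, 1))
  mk <- new_subregion_mask(array(TRUE, c(4, 4, 1)), "toy", c(1, 1, 1))
  disc <- discretization_settings("fixed_bin_count", 2)

  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  counts <- matrix(0, 2, 2)
  d <- dim(vol)
  for (i in 1:4) for (j in 1:4) for (r in seq_len(nrow(offs))) {
    ii <- i + offs[r, 1]; jj <- j + offs[r, 2]; kk <- 1 + offs[r, 3]
    if (ii >= 1 && ii <= 4 && jj >= 1 && jj <= 4 && kk == 1) {
      a <- vol[i, j, 1]; b <- vol[ii, jj, kk]
      counts[a, b] <- counts[a, b] + 1
    }
  }
  P_oracle <- counts / sum(counts)
  lv <- habitomics:::level_array(vol, mk, disc)
  P <- habitomics:::glcm_matrix(lv$la, lv$ng, dim(lv$la))
  expect_equal(P, P_oracle, tolerance = 1e-9, ignore_attr = TRUE)

  # and a feature computed from the oracle matrix agrees
  tx <- extract_texture(vol, mk, disc)
  i2 <- row(P_oracle); j2 <- col(P_oracle)
  expect_equal(tx[["glcm_Contrast"]], sum((i2 - j2)^2 * P_oracle),
               tolerance = 1e-9)
  expect_equal(tx[["glcm_JointEnergy"]], sum(P_oracle^2), tolerance = 1e-9)
})

test_that("GLRLM run counts match hand enumeration", {
  # 1 x 8 x 1 row [1,1,1,2,2,3,3,3]: runs 1:len3, 2:len2, 3:len3 along the
  # row; every other direction sees each voxel as a length-1 run
  vol <- array(c(1, 1, 1, 2, 2, 3, 3, 3), c(1, 8, 1))
  mk <- new_subregion_mask(array(TRUE, c(1, 8, 1)), "row", c(1, 1, 1))
  disc <- discretization_settings("fixed_bin_count", 3)
  lv <- habitomics:::level_array(vol, mk, disc)
  rl <- habitomics:::run_lengths_direction(lv$la, dim(lv$la), c(0L, 1L, 0L))
  expect_equal(rl$length[order(rl$level)], c(3L, 2L, 3L))
  expect_equal(sort(rl$level), c(1L, 2L, 3L))

  m <- habitomics:::glrlm_matrix(lv$la, lv$ng, dim(lv$la))
  expected <- matrix(0, 3, 3)
  expected[1, 1] <- 12 * 3   # 12 off-row directions, 3 voxels of level 1
  expected[2, 1] <- 12 * 2
  expected[3, 1] <- 12 * 3
  expected[1, 3] <- 1
  expected[2, 2] <- 1
  expected[3, 3] <- 1
  expect_equal(m, expected, ignore_attr = TRUE)
})

test_that("degenerate texture inputs take their analytic limits", {
  d <- c(3, 3, 1)
  mk <- cube_mask(d, c(1, 1, 1), c(3, 3, 1))
  expect_warning(tx <- extract_texture(array(5, d), mk), "single gray level")
  expect_equal(tx[["glcm_Contrast"]], 0)
  expect_equal(tx[["glcm_JointEnergy"]], 1)
  expect_equal(tx[["glcm_MCC"]], 1)
  expect_equal(tx[["ngtdm_Contrast"]], 0)
})

test_that("fixed-bin-count texture is invariant to affine rescaling", {
  sub <- one_subject32()
  vol <- sub$ph$volume_set$volumes$T2WI
  mk <- sub$subs$VOI_3
  a <- extract_texture(vol, mk)
  b <- extract_texture(2.5 * vol + 100, mk)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("feature tables are deterministic with shared shape columns", {
  p <- params16(edema_effect_size = 1)
  coh <- generate_cohort(2, 2, p, seed = 21)
  masks <- h34_masks(coh)
  tabs <- extract_sequence_tables(coh, masks)
  expect_named(tabs, c("T1WI", "T1WIC", "T2WI", "T2FLAIR"))
  expect_equal(dim(tabs$T1WI), c(4, 111))   # subject_id + label + 109
  expect_identical(feature_columns(tabs$T1WI), names(feature_families()))

  tabs2 <- extract_sequence_tables(coh, masks)
  expect_identical(tabs, tabs2)

  shape_cols <- grep("^shape_", colnames(tabs$T1WI), value = TRUE)
  expect_identical(tabs$T1WI[, shape_cols], tabs$T2FLAIR[, shape_cols])
  expect_false(identical(tabs$T1WI$firstorder_Mean,
                         tabs$T2FLAIR$firstorder_Mean))

  # single-voxel subregions are excluded with a log, not an error
  masks2 <- masks
  masks2[[1]]$voxels[] <- FALSE
  t3 <- extract_feature_table(coh, masks2, "T1WI")
  expect_equal(nrow(t3), 3)
  expect_equal(attr(t3, "excluded"), coh[[1]]$volume_set$subject_id)
})
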