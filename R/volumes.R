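#' Construct a volume set
#'
#' A volume set holds one subject's co-registered scalar volumes (one per MRI
#' sequence) together with their common voxel spacing, the subject id and the
#' class label. All sequences must share shape and spacing: the pipeline
#' assumes the inputs were aligned and resampled to a common geometry
#' upstream, and only verifies that assumption.
#'
#' @param volumes named list of 3-D numeric arrays, one per sequence; all
#'   four sequences (T1WI, T1WIC, T2WI, T2FLAIR) must be present.
#' @param spacing numeric(3), mm per voxel.
#' @param subject_id subject identifier.
#' @param label class label (`"astro"` or `"gbm"`), or `NA` when unknown.
#' @return An object of class `volume_set`.
#' @export
new_volume_set <- function(volumes, spacing, subject_id, label = NA_character_) {
  required <- phantom_sequences()
  if (!all(required %in% names(volumes))) {
    stop_hab("volume set must contain all four sequences: ",
             paste(required, collapse = ", "))
  }
  ref_dim <- dim(volumes[[required[1]]])
  for (sq in required) {
    if (!identical(dim(volumes[[sq]]), ref_dim)) {
      stop_hab("sequence ", sq, " is not aligned with the other sequences")
    }
  }
  structure(list(volumes = volumes[required], spacing = as.numeric(spacing),
                 subject_id = subject_id, label = label),
            class = "volume_set")
}

#' Construct a named binary subregion mask
#'
#' @param voxels 3-D logical (or 0/1) array.
#' @param name subregion name (e.g. `VOI_3`, `H_34`).
#' @param spacing numeric(3) mm, matching the parent volume set.
#' @return An object of class `subregion_mask`.
#' @export
new_subregion_mask <- function(voxels, name, spacing) {
  structure(list(name = name,
                 voxels = array(as.logical(voxels), dim = dim(voxels)),
                 spacing = as.numeric(spacing)),
            class = "subregion_mask")
}

#' @export
print.subregion_mask <- function(x, ...) {
  cat(sprintf("<subregion_mask %s: %d voxels, grid %s, spacing %s mm>\n",
              x$name, sum(x$voxels), paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

mask_count <- function(m) sum(m$voxels)

#' Dice similarity coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks agree vacuously and score 1.
#'
#' @param a,b `subregion_mask` objects on the same geometry.
#' @return A fraction in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check_same_geometry(dim(a$voxels), a$spacing, dim(b$voxels), b$spacing,
                      what = "masks")
  na <- sum(a$voxels)
  nb <- sum(b$voxels)
  if (na + nb == 0) return(1)
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' Consensus of two raters' segmentations
#'
#' When the Dice coefficient between the two delineations reaches
#' `threshold`, the consensus is their voxelwise intersection. Below the
#' threshold no automatic consensus is formed: the disagreement must be
#' resolved by discussion, and the result is flagged accordingly.
#'
#' @param a,b `subregion_mask` objects on the same geometry.
#' @param threshold Dice threshold for automatic consensus (default 0.9).
#' @return A list with `agreed` (logical), `dice` (the coefficient) and, when
#'   agreed, `mask` (the intersection `subregion_mask`).
#' @export
consensus_mask <- function(a, b, threshold = 0.9) {
  d <- dice(a, b)
  if (d >= threshold) {
    list(agreed = TRUE, dice = d,
         mask = new_subregion_mask(a$voxels & b$voxels, a$name, a$spacing))
  } else {
    list(agreed = FALSE, dice = d, mask = NULL)
  }
}

#' Seven manual subregions from the three delineated compartments
#'
#' From the non-enhanced tumor (nET), enhanced tumor (ET) and peritumoral
#' edema (pTE) masks, Boolean algebra defines seven regions: the three inputs
#' (`VOI_1` = nET, `VOI_2` = ET, `VOI_3` = pTE) and the unions `VOI_12`,
#' `VOI_13`, `VOI_23` and `VOI_123`. When the raw masks overlap, voxels are
#' assigned by the precedence ET > nET > pTE (enhancement being the most
#' specific radiographic signal), so the three base regions are disjoint and
#' `|VOI_123| = |VOI_1| + |VOI_2| + |VOI_3|`.
#'
#' @param net,et,pte `subregion_mask` objects on the same geometry.
#' @return Named list of seven `subregion_mask` objects.
#' @export
manual_voi_algebra <- function(net, et, pte) {
  check_same_geometry(dim(net$voxels), net$spacing, dim(et$voxels), et$spacing,
                      what = "nET/ET masks")
  check_same_geometry(dim(net$voxels), net$spacing, dim(pte$voxels),
                      pte$spacing, what = "nET/pTE masks")
  for (m in list(nET = net, ET = et, pTE = pte)) {
    if (sum(m$voxels) == 0) {
      stop_hab("empty input mask: ", m$name)
    }
  }
  sp <- net$spacing
  v2 <- et$voxels                       # ET wins every overlap
  v1 <- net$voxels & !v2                # nET minus ET
  v3 <- pte$voxels & !v2 & !net$voxels  # pTE minus both tumors
  out <- list(
    VOI_1 = v1, VOI_2 = v2, VOI_3 = v3,
    VOI_12 = v1 | v2, VOI_13 = v1 | v3, VOI_23 = v2 | v3,
    VOI_123 = v1 | v2 | v3
  )
  mapply(function(vox, nm) new_subregion_mask(vox, nm, sp),
         out, names(out), SIMPLIFY = FALSE)
}

#' Read / write scalar volumes and masks as NIfTI
#'
#' Volumes are stored as float32 NIfTI, masks as unsigned 8-bit NIfTI with
#' values {0, 1}. A round trip preserves shape, spacing (to 1e-6 mm) and
#' values to float32 precision.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param data 3-D numeric array to write.
#' @param spacing numeric(3) voxel size in mm.
#' @return `read_volume()` returns a list with `data` (3-D array) and
#'   `spacing`; the writers return the path invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  list(data = array(as.numeric(img), dim = dim(img)), spacing = as.numeric(sp))
}

#' @rdname read_volume
#' @export
write_volume <- function(data, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.numeric(data), dim = dim(data)))
  RNifti::pixdim(img) <- as.numeric(spacing)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname read_volume
#' @param mask a `subregion_mask` to write.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$voxels),
                               dim = dim(mask$voxels)))
  RNifti::pixdim(img) <- as.numeric(mask$spacing)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname read_volume
#' @param name subregion name to attach to the mask read from `path`.
#' @export
read_mask <- function(path, name = basename(path)) {
  v <- read_volume(path)
  new_subregion_mask(v$data > 0.5, name, v$spacing)
}

#' Verify that a mask and a volume set are aligned
#'
#' @param vs a `volume_set`.
#' @param mask a `subregion_mask`.
#' @param tol spacing tolerance in mm.
#' @return `TRUE` invisibly; raises an alignment error otherwise.
#' @export
check_alignment <- function(vs, mask, tol = 1e-6) {
  check_same_geometry(dim(vs$volumes[[1]]), vs$spacing, dim(mask$voxels),
                      mask$spacing, what = "volume set and mask", tol = tol)
}
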