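#' Parameters for the multisequence tumor phantom
#'
#' Defines the geometry and signal model of a synthetic lesion used to
#' validate the subregion/radiomics pipeline. The lesion is a set of three
#' nested ellipsoids on an isotropic grid: a central core (non-enhanced
#' tumor), an enhancing rim shell, and an outer edema shell. Each of the four
#' MRI sequences gets a compartment-specific mean intensity plus spatially
#' correlated Gaussian noise, so that texture-matrix features are non-trivial.
#' Class signal (grade 4 astrocytoma vs glioblastoma) is injected into the
#' edema shell as a standardized mean shift and a variance ratio, mirroring
#' the observation that edematous subregions carry the discriminative signal.
#'
#' The default contrasts guarantee the habitat structure the pipeline expects:
#' the rim is bright on post-contrast T1 (T1WIC) and dark on T2-FLAIR, the
#' edema is bright on T2-FLAIR and dark on T1WIC, and the core is low on both.
#'
#' @param grid_shape integer(3), voxels per axis (each >= 16).
#' @param spacing numeric(3), voxel size in mm.
#' @param core_semi_axes,rim_semi_axes,edema_semi_axes numeric(3), ellipsoid
#'   semi-axes in mm; must be strictly nested (core < rim < edema).
#' @param compartment_means 4 x 4 numeric matrix, rows = sequences
#'   (T1WI, T1WIC, T2WI, T2FLAIR), columns = compartments
#'   (background, core, rim, edema); arbitrary units.
#' @param compartment_sds matrix like `compartment_means` with the in-
#'   compartment noise standard deviations (all >= 0).
#' @param edema_effect_size standardized mean difference between the two
#'   classes in the edema compartment; scalar (applied to every sequence) or
#'   numeric(4) per sequence. The glioblastoma class gets the shifted mean.
#' @param edema_sd_ratio multiplicative factor on the edema noise sd for the
#'   glioblastoma class (variance ratio component of the class signal).
#' @param texture_correlation_length Gaussian smoothing length of the noise
#'   field, in voxels; 0 gives white noise.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(64L, 64L, 64L),
                           spacing = c(1, 1, 1),
                           core_semi_axes = c(8, 7, 6),
                           rim_semi_axes = c(14, 12, 10),
                           edema_semi_axes = c(22, 19, 16),
                           compartment_means = NULL,
                           compartment_sds = NULL,
                           edema_effect_size = 1.5,
                           edema_sd_ratio = 1.25,
                           texture_correlation_length = 2) {
  sequences <- phantom_sequences()
  compartments <- c("background", "core", "rim", "edema")
  if (is.null(compartment_means)) {
    compartment_means <- rbind(
      T1WI    = c(20, 35, 45, 40),
      T1WIC   = c(20, 30, 90, 40),
      T2WI    = c(30, 60, 55, 75),
      T2FLAIR = c(25, 40, 45, 80)
    )
  }
  if (is.null(compartment_sds)) {
    compartment_sds <- matrix(8, 4, 4, dimnames = list(sequences, compartments))
    compartment_sds[, "background"] <- 4
  }
  dimnames(compartment_means) <- list(sequences, compartments)
  dimnames(compartment_sds) <- list(sequences, compartments)
  if (length(edema_effect_size) == 1L) {
    edema_effect_size <- rep(edema_effect_size, 4L)
  }
  names(edema_effect_size) <- sequences
  p <- structure(list(
    grid_shape = as.integer(grid_shape),
    spacing = as.numeric(spacing),
    core_semi_axes = as.numeric(core_semi_axes),
    rim_semi_axes = as.numeric(rim_semi_axes),
    edema_semi_axes = as.numeric(edema_semi_axes),
    compartment_means = compartment_means,
    compartment_sds = compartment_sds,
    edema_effect_size = stats::setNames(as.numeric(edema_effect_size),
                                        sequences),
    edema_sd_ratio = as.numeric(edema_sd_ratio),
    texture_correlation_length = as.numeric(texture_correlation_length)
  ), class = "phantom_params")
  validate_phantom_params(p)
  p
}

phantom_sequences <- function() c("T1WI", "T1WIC", "T2WI", "T2FLAIR")

phantom_labels <- function() c("astro", "gbm")

validate_phantom_params <- function(p) {
  if (length(p$grid_shape) != 3L || any(p$grid_shape < 16L)) {
    stop_hab("grid_shape must have 3 axes with at least 16 voxels each")
  }
  if (any(p$spacing <= 0)) stop_hab("spacing must be positive")
  if (!(all(p$core_semi_axes < p$rim_semi_axes) &&
        all(p$rim_semi_axes < p$edema_semi_axes))) {
    stop_hab("semi-axes must be strictly nested: core < rim < edema")
  }
  if (any(p$compartment_sds < 0)) stop_hab("compartment sds must be >= 0")
  if (p$edema_sd_ratio <= 0) stop_hab("edema_sd_ratio must be positive")
  if (p$texture_correlation_length < 0) {
    stop_hab("texture_correlation_length must be >= 0")
  }
  invisible(p)
}

# Ellipsoid indicator on the voxel-center grid, centered on the volume.
ellipsoid_mask <- function(grid_shape, spacing, semi_axes) {
  coords <- lapply(1:3, function(k) {
    (seq_len(grid_shape[k]) - (grid_shape[k] + 1) / 2) * spacing[k]
  })
  q1 <- (coords[[1]] / semi_axes[1])^2
  q2 <- (coords[[2]] / semi_axes[2])^2
  q3 <- (coords[[3]] / semi_axes[3])^2
  arr <- outer(outer(q1, q2, `+`), q3, `+`)
  arr <= 1
}

# Unit-variance Gaussian random field with the given correlation length,
# built by separable circular Gaussian smoothing of white noise.
smooth_noise_field <- function(grid_shape, corr_len) {
  noise <- array(stats::rnorm(prod(grid_shape)), dim = grid_shape)
  if (corr_len <= 0) return(noise)
  half <- max(1L, as.integer(ceiling(3 * corr_len)))
  kern <- stats::dnorm(seq(-half, half), sd = corr_len)
  kern <- kern / sum(kern)
  for (axis in 1:3) {
    perm <- c(axis, setdiff(1:3, axis))
    arr <- aperm(noise, perm)
    d <- dim(arr)
    m <- matrix(arr, nrow = d[1])
    m <- stats::filter(m, kern, method = "convolution", sides = 2,
                       circular = TRUE)
    arr <- array(as.numeric(m), dim = d)
    noise <- aperm(arr, order(perm))
  }
  # restore unit variance (separable smoothing shrinks the sd by a known
  # factor per axis)
  noise / sqrt(sum(kern^2))^3
}

#' Generate one phantom subject
#'
#' Builds a four-sequence volume set plus the ground-truth compartment masks
#' (core, rim shell, edema shell — pairwise disjoint). Identical parameters
#' and seed give bit-identical output.
#'
#' @param params a [phantom_params()] object.
#' @param label class label, `"astro"` or `"gbm"`.
#' @param seed integer seed for the subject's noise fields.
#' @param subject_id subject identifier string.
#' @return A list with elements `volume_set` (class `volume_set`) and
#'   `masks` (named list of `subregion_mask`: `core`, `rim`, `edema`).
#' @export
generate_phantom <- function(params, label = c("astro", "gbm"), seed = 1L,
                             subject_id = "phantom_001") {
  validate_phantom_params(params)
  label <- match.arg(label)
  gs <- params$grid_shape
  inner_core  <- ellipsoid_mask(gs, params$spacing, params$core_semi_axes)
  inner_rim   <- ellipsoid_mask(gs, params$spacing, params$rim_semi_axes)
  inner_edema <- ellipsoid_mask(gs, params$spacing, params$edema_semi_axes)
  core  <- inner_core
  rim   <- inner_rim & !inner_core
  edema <- inner_edema & !inner_rim
  compartment <- array("background", dim = gs)
  compartment[core] <- "core"
  compartment[rim] <- "rim"
  compartment[edema] <- "edema"

  means <- params$compartment_means
  sds <- params$compartment_sds
  volumes <- with_seed(seed, {
    out <- list()
    for (sq in phantom_sequences()) {
      mu <- means[sq, ][compartment]
      sd <- sds[sq, ][compartment]
      if (label == "gbm") {
        in_edema <- compartment == "edema"
        mu[in_edema] <- mu[in_edema] +
          params$edema_effect_size[[sq]] * sds[sq, "edema"]
        sd[in_edema] <- sd[in_edema] * params$edema_sd_ratio
      }
      field <- smooth_noise_field(gs, params$texture_correlation_length)
      vol <- array(mu + sd * as.numeric(field), dim = gs)
      out[[sq]] <- vol
    }
    out
  })

  vs <- new_volume_set(volumes, spacing = params$spacing,
                       subject_id = subject_id, label = label)
  masks <- list(
    core = new_subregion_mask(core, "core", params$spacing),
    rim = new_subregion_mask(rim, "rim", params$spacing),
    edema = new_subregion_mask(edema, "edema", params$spacing)
  )
  list(volume_set = vs, masks = masks)
}

#' Generate a phantom cohort
#'
#' @param n_astro,n_gbm subjects per class (each >= 1).
#' @param params a [phantom_params()] object.
#' @param seed master seed; per-subject seeds are derived deterministically.
#' @return A list of per-subject lists as returned by [generate_phantom()],
#'   with unique subject ids (`astro_###`, `gbm_###`).
#' @export
generate_cohort <- function(n_astro, n_gbm, params = phantom_params(),
                            seed = 1L) {
  if (n_astro < 1 || n_gbm < 1) {
    stop_hab("both classes need at least one subject")
  }
  labels <- c(rep("astro", n_astro), rep("gbm", n_gbm))
  ids <- c(sprintf("astro_%03d", seq_len(n_astro)),
           sprintf("gbm_%03d", seq_len(n_gbm)))
  lapply(seq_along(labels), function(i) {
    generate_phantom(params, labels[i], seed = derive_seed(seed, i),
                     subject_id = ids[i])
  })
}

#' Write a phantom cohort to disk as NIfTI plus a CSV manifest
#'
#' One `.nii.gz` file per sequence and per compartment mask, and a
#' `manifest.csv` with subject id, label and file paths.
#'
#' @param cohort list returned by [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(subj) {
    vs <- subj$volume_set
    row <- list(subject_id = vs$subject_id, label = vs$label)
    for (sq in names(vs$volumes)) {
      path <- file.path(dir, sprintf("%s_%s.nii.gz", vs$subject_id, sq))
      write_volume(vs$volumes[[sq]], path, spacing = vs$spacing)
      row[[sq]] <- path
    }
    for (mk in names(subj$masks)) {
      path <- file.path(dir, sprintf("%s_mask_%s.nii.gz", vs$subject_id, mk))
      write_mask(subj$masks[[mk]], path)
      row[[paste0("mask_", mk)]] <- path
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv` and the NIfTI files.
#' @return A cohort list in the same shape as [generate_cohort()] output.
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    volumes <- list()
    spacing <- NULL
    for (sq in phantom_sequences()) {
      v <- read_volume(row[[sq]])
      volumes[[sq]] <- v$data
      spacing <- v$spacing
    }
    masks <- list()
    for (mk in c("core", "rim", "edema")) {
      col <- paste0("mask_", mk)
      if (!is.null(row[[col]])) {
        m <- read_volume(row[[col]])
        masks[[mk]] <- new_subregion_mask(m$data > 0.5, mk, m$spacing)
      }
    }
    list(
      volume_set = new_volume_set(volumes, spacing = spacing,
                                  subject_id = row$subject_id,
                                  label = row$label),
      masks = masks
    )
  })
}
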