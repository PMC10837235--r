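# Shape (morphology) features.
#
# Surface area and mesh volume come from an isosurface mesh of the mask's
# (lightly smoothed) occupancy field, extracted by interpolating marching
# tetrahedra at iso-level 0.5; the enclosed volume follows from the
# divergence theorem over the closed oriented surface. Diameters use
# voxel-center coordinates of boundary voxels; axis lengths come from a PCA
# of all voxel-center coordinates (4 * sqrt(eigenvalue) convention).

shape_names <- function() {
  c("MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
    "Sphericity", "SphericalDisproportion", "Maximum3DDiameter",
    "Maximum2DDiameterSlice", "Maximum2DDiameterColumn",
    "Maximum2DDiameterRow", "MajorAxisLength", "MinorAxisLength",
    "LeastAxisLength", "Elongation", "Flatness")
}

# The six tetrahedra of the unit cube sharing the main diagonal, as corner
# indices into the 8 cube corners ordered (i,j,k) in {0,1}^3 with i fastest.
# corner index = 1 + i + 2j + 4k.
cube_tetrahedra <- function() {
  list(c(1L, 2L, 4L, 8L), c(1L, 4L, 3L, 8L), c(1L, 3L, 7L, 8L),
       c(1L, 7L, 5L, 8L), c(1L, 5L, 6L, 8L), c(1L, 6L, 2L, 8L))
}

cube_corner_offsets <- function() {
  m <- as.matrix(expand.grid(i = 0:1, j = 0:1, k = 0:1))
  storage.mode(m) <- "double"
  m
}

# Vectorized cross product and triangle quantities on row-matrices.
cross_rows <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# Area and signed-volume (divergence theorem, outward orientation)
# contributions of triangles (m1, m2, m3); `ref` is an absolute point on the
# inside of the surface, used to orient the normal outward.
triangle_contrib <- function(m1, m2, m3, ref) {
  nrm <- cross_rows(m2 - m1, m3 - m1)
  area <- 0.5 * sqrt(rowSums(nrm^2))
  flip <- rowSums(nrm * (ref - m1)) > 0
  raw <- rowSums(m1 * cross_rows(m2, m3)) / 6
  vol <- ifelse(flip, -raw, raw)
  list(area = sum(area), vol = sum(vol))
}

# Surface area and enclosed volume of the level-0.5 isosurface of a scalar
# occupancy field, by marching tetrahedra with linear edge interpolation.
# Each grid cube is split into the six Kuhn tetrahedra around its main
# diagonal; the in/out pattern of each tetrahedron yields one or two
# triangles whose vertices interpolate the field along the crossing edges.
# Volume comes from the divergence theorem over the closed oriented surface.
field_mesh_measures <- function(occ, spacing, level = 0.5) {
  pd <- dim(occ)
  sub <- function(off) occ[(1 + off[1]):(pd[1] - 1 + off[1]),
                           (1 + off[2]):(pd[2] - 1 + off[2]),
                           (1 + off[3]):(pd[3] - 1 + off[3])]
  corner_off <- cube_corner_offsets()
  corner_vals <- vector("list", 8L)
  for (c8 in 1:8) corner_vals[[c8]] <- sub(corner_off[c8, ])
  cmax <- pmax(corner_vals[[1]], corner_vals[[2]])
  cmin <- pmin(corner_vals[[1]], corner_vals[[2]])
  for (c8 in 3:8) {
    cmax <- pmax(cmax, corner_vals[[c8]])
    cmin <- pmin(cmin, corner_vals[[c8]])
  }
  mixed <- which(cmax > level & cmin <= level)
  if (length(mixed) == 0) return(list(area = 0, volume = 0))
  cube_sub <- arrayInd(mixed, pd - 1L)
  vals <- matrix(0, nrow = length(mixed), ncol = 8)
  for (c8 in 1:8) vals[, c8] <- corner_vals[[c8]][mixed]

  corner_mm <- corner_off %*% diag(spacing)
  origins <- sweep(cube_sub - 1, 2, spacing, `*`)

  area <- 0; volume <- 0
  tets <- cube_tetrahedra()
  # the Kuhn 6-tetrahedra decomposition is face-consistent across
  # neighboring cubes, so the extracted surface is closed
  {
    cm <- corner_mm
    v8 <- vals
    org <- origins
    for (t6 in 1:6) {
      tc <- tets[[t6]]
      tv <- v8[, tc, drop = FALSE]
      pts <- cm[tc, , drop = FALSE]    # 4 x 3 local corner coords
      inside <- tv > level
      s <- rowSums(inside)
      # absolute position of corner a for selected rows
      abs_pt <- function(sel, a) org[sel, , drop = FALSE] +
        matrix(pts[a, ], length(sel), 3, byrow = TRUE)
      # interpolated crossing point on edge a->b
      interp <- function(sel, a, b) {
        ta <- tv[sel, a]; tb <- tv[sel, b]
        t <- (ta - level) / (ta - tb)
        pa <- abs_pt(sel, a)
        pa + t * (matrix(pts[b, ] - pts[a, ], length(sel), 3, byrow = TRUE))
      }
      for (apex in 1:4) {
        oth <- setdiff(1:4, apex)
        # one corner inside
        sel <- which(s == 1 & inside[, apex])
        if (length(sel)) {
          m1 <- interp(sel, apex, oth[1])
          m2 <- interp(sel, apex, oth[2])
          m3 <- interp(sel, apex, oth[3])
          ct <- triangle_contrib(m1, m2, m3, abs_pt(sel, apex))
          area <- area + ct$area; volume <- volume + ct$vol
        }
        # one corner outside
        sel <- which(s == 3 & !inside[, apex])
        if (length(sel)) {
          m1 <- interp(sel, oth[1], apex)
          m2 <- interp(sel, oth[2], apex)
          m3 <- interp(sel, oth[3], apex)
          ct <- triangle_contrib(m1, m2, m3, abs_pt(sel, oth[1]))
          area <- area + ct$area; volume <- volume + ct$vol
        }
      }
      # two corners inside: quad split into two triangles
      pairs <- utils::combn(4L, 2L)
      for (q in seq_len(ncol(pairs))) {
        ins <- pairs[, q]
        out <- setdiff(1:4, ins)
        sel <- which(s == 2 & inside[, ins[1]] & inside[, ins[2]])
        if (length(sel)) {
          a <- interp(sel, ins[1], out[1]); b <- interp(sel, ins[1], out[2])
          cc <- interp(sel, ins[2], out[2]); dd <- interp(sel, ins[2], out[1])
          # each triangle is oriented against the inside corner it is cut
          # from; the other inside corner can sit on either side of its plane
          ct1 <- triangle_contrib(a, b, cc, abs_pt(sel, ins[1]))
          ct2 <- triangle_contrib(a, cc, dd, abs_pt(sel, ins[2]))
          area <- area + ct1$area + ct2$area
          volume <- volume + ct1$vol + ct2$vol
        }
      }
    }
  }
  list(area = area, volume = abs(volume))
}

# Surface area and enclosed volume of a binary mask. The occupancy field is
# smoothed with a separable binomial [1, 2, 1]/4 kernel before meshing, which
# removes the voxelization faceting that would otherwise inflate the surface
# area (a rasterized sphere of radius 10 voxels measures within 1% of its
# true area); very small or one-voxel-thin masks whose smoothed field never
# crosses the iso-level fall back to meshing the raw binary field.
mask_mesh_measures <- function(vox, spacing) {
  d <- dim(vox)
  pad <- array(0, dim = d + 4L)   # 2-voxel pad so smoothing closes the surface
  pad[3:(d[1] + 2), 3:(d[2] + 2), 3:(d[3] + 2)] <- as.numeric(vox)
  sm <- pad
  kern <- c(1, 2, 1) / 4
  for (axis in 1:3) {
    perm <- c(axis, setdiff(1:3, axis))
    arr <- aperm(sm, perm)
    dd <- dim(arr)
    m <- matrix(arr, nrow = dd[1])
    m <- stats::filter(m, kern, method = "convolution", sides = 2)
    m[is.na(m)] <- 0
    sm <- aperm(array(as.numeric(m), dim = dd), order(perm))
  }
  res <- field_mesh_measures(sm, spacing)
  if (res$area == 0) res <- field_mesh_measures(pad, spacing)
  res
}

# Boundary voxels: in-mask voxels with at least one 6-neighbor outside.
boundary_voxels <- function(vox) {
  d <- dim(vox)
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- vox
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  core & !nb
}

max_pairwise_distance <- function(coords) {
  n <- nrow(coords)
  if (n < 2) return(0)
  best <- 0
  block <- 512L
  for (s in seq(1, n, by = block)) {
    e <- min(s + block - 1L, n)
    d2 <- outer(rowSums(coords[s:e, , drop = FALSE]^2), rowSums(coords^2),
                `+`) - 2 * tcrossprod(coords[s:e, , drop = FALSE], coords)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' Extract the 15 shape features
#'
#' Shape depends only on the mask and its spacing, never on intensities, so
#' the values are identical across MRI sequences for the same subregion.
#'
#' @param mask a `subregion_mask` with at least one voxel.
#' @return Named numeric vector of length 15.
#' @export
extract_shape <- function(mask) {
  sp <- mask$spacing
  n <- sum(mask$voxels)
  if (n == 0) stop_hab("empty mask in shape extraction")
  # all shape quantities are translation-invariant; crop to the bounding box
  sub0 <- which(mask$voxels, arr.ind = TRUE)
  lo <- pmax(apply(sub0, 2, min) - 1L, 1L)
  hi <- pmin(apply(sub0, 2, max) + 1L, dim(mask$voxels))
  vox <- mask$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  mesh <- mask_mesh_measures(vox, sp)
  area <- mesh$area
  mvol <- mesh$volume
  voxvol <- n * prod(sp)
  sphericity <- if (area > 0) (36 * pi * mvol^2)^(1 / 3) / area else 0

  idx <- which(vox, arr.ind = TRUE)
  coords <- sweep(idx, 2, sp, `*`)
  ctr <- colMeans(coords)
  cc <- sweep(coords, 2, ctr)
  cov3 <- crossprod(cc) / n
  ev <- sort(pmax(eigen(cov3, symmetric = TRUE, only.values = TRUE)$values, 0),
             decreasing = TRUE)
  axes <- 4 * sqrt(ev)

  bidx <- which(boundary_voxels(vox), arr.ind = TRUE)
  bc <- sweep(bidx, 2, sp, `*`)
  max3d <- max_pairwise_distance(bc)
  plane_diameter <- function(fixed_axis) {
    keep <- setdiff(1:3, fixed_axis)
    vals <- unique(bidx[, fixed_axis])
    best <- 0
    for (v in vals) {
      pc <- bc[bidx[, fixed_axis] == v, keep, drop = FALSE]
      best <- max(best, max_pairwise_distance(pc))
    }
    best
  }

  c(
    MeshVolume = mvol,
    VoxelVolume = voxvol,
    SurfaceArea = area,
    SurfaceVolumeRatio = if (mvol > 0) area / mvol else 0,
    Sphericity = sphericity,
    SphericalDisproportion = if (sphericity > 0) 1 / sphericity else 0,
    Maximum3DDiameter = max3d,
    Maximum2DDiameterSlice = plane_diameter(3L),   # in-plane, axial
    Maximum2DDiameterColumn = plane_diameter(2L),  # coronal
    Maximum2DDiameterRow = plane_diameter(1L),     # sagittal
    MajorAxisLength = axes[1],
    MinorAxisLength = axes[2],
    LeastAxisLength = axes[3],
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  )
}
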