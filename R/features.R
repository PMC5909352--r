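#' Slice area of a lesion cross-section
#'
#' `A_k = n_k * dx * dy`: foreground voxel count of the k-th slice times the
#' in-plane voxel footprint.
#'
#' @param slice_mask Logical 2D matrix (one z-slice of the VOI).
#' @param dx,dy In-plane spacing (mm).
#' @return Area in mm^2.
#' @export
slice_area <- function(slice_mask, dx, dy) {
  n <- sum(slice_mask)
  if (n == 0L) stopf("empty slice mask")
  n * dx * dy
}

#' Slice perimeter of a lesion cross-section
#'
#' `P_k`: the number of boundary voxels in the slice — foreground voxels
#' with at least one of their 4 edge-neighbours outside the mask (the grid
#' border counts as outside). A plain count; multiply by the in-plane
#' spacing via the `perimeter_mm` config flag if a length is wanted.
#'
#' @param slice_mask Logical 2D matrix.
#' @return Boundary-voxel count.
#' @export
slice_perimeter <- function(slice_mask) {
  if (!any(slice_mask)) stopf("empty slice mask")
  sum(boundary_mask_2d(slice_mask))
}

#' 3D compactness of a VOI
#'
#' `COMP = S^2 / V` with the surface `S = B * v_size * slice_th` (B = 3D
#' boundary-voxel count under 6-connectivity, `v_size` the in-plane linear
#' spacing `dx`) and the volume `V = n * dx * dy * dz`. Grows roughly
#' linearly with diameter for solid shapes and faster for irregular ones.
#'
#' @param v A [voi()].
#' @param dx,dy In-plane spacing (mm).
#' @param slice_th Slice thickness (mm), also the through-plane spacing `dz`.
#' @return Compactness (mm).
#' @export
compactness_3d <- function(v, dx, dy, slice_th) {
  if (nrow(v$coords) == 0L) stopf("empty VOI")
  m <- coords_to_mask(v$coords, v$grid_dim)
  b <- sum(boundary_mask_3d(m))
  s <- b * dx * slice_th
  vol <- nrow(v$coords) * dx * dy * slice_th
  s^2 / vol
}

#' 3D eccentricity of a VOI
#'
#' `ECC = sqrt(a^2 - b^2) / a` where `a` and `b` are the largest and
#' smallest principal semi-axis lengths of the voxel-centre point cloud in
#' physical coordinates (semi-axis taken as `2 * sqrt(eigenvalue)` of the
#' second-moment tensor). 0 for sphere-symmetric clouds; approaches 1 for
#' elongated ones.
#'
#' @param v A [voi()] with at least 4 non-coplanar voxels.
#' @param dx,dy,slice_th Voxel spacing (mm).
#' @return Eccentricity in `[0, 1)`.
#' @export
eccentricity_3d <- function(v, dx, dy, slice_th) {
  co <- v$coords
  if (nrow(co) < 4L) stopf("degenerate VOI: need >= 4 voxels for eccentricity")
  phys <- cbind(co[, 1] * dx, co[, 2] * dy, co[, 3] * slice_th)
  centered <- sweep(phys, 2, colMeans(phys))
  mom <- crossprod(centered) / nrow(phys)
  ev <- eigen(mom, symmetric = TRUE, only.values = TRUE)$values
  if (ev[3] <= 1e-9 * ev[1]) {
    stopf("degenerate VOI: collinear or coplanar voxel cloud")
  }
  a <- 2 * sqrt(ev[1])
  b <- 2 * sqrt(ev[3])
  sqrt(a^2 - b^2) / a
}

#' Morphological feature vector of a VOI
#'
#' Area and perimeter are computed on every z-slice the VOI intersects and
#' summarised by their median (even slice count: mean of the two middle
#' values); compactness and eccentricity are computed once on the whole 3D
#' VOI.
#'
#' @param v A [voi()].
#' @param series The parent [dce_series()] (spacing).
#' @param perimeter_mm Multiply the boundary count by the in-plane spacing.
#' @return One-row tibble: `area_median` (mm^2), `perimeter_median`,
#'   `compactness`, `eccentricity`. For a VOI confined to one slice the
#'   eccentricity falls back to the in-plane principal axes (the 3D cloud is
#'   coplanar there).
#' @export
morph_feature_vector <- function(v, series, perimeter_mm = FALSE) {
  m <- coords_to_mask(v$coords, v$grid_dim)
  zs <- sort(unique(v$coords[, 3]))
  areas <- vapply(zs, function(z) slice_area(m[, , z], series$dx, series$dy),
                  numeric(1))
  perims <- vapply(zs, function(z) slice_perimeter(m[, , z]), numeric(1))
  if (perimeter_mm) perims <- perims * series$dx
  ecc <- tryCatch(
    eccentricity_3d(v, series$dx, series$dy, series$slice_th),
    error = function(e) eccentricity_planar(v, series$dx, series$dy)
  )
  tibble::tibble(
    area_median = stats::median(areas),
    perimeter_median = stats::median(perims),
    compactness = compactness_3d(v, series$dx, series$dy, series$slice_th),
    eccentricity = ecc
  )
}

# In-plane eccentricity from the 2D second-moment axes; used when the voxel
# cloud is coplanar (single-slice VOI) and the 3D axes are degenerate.
eccentricity_planar <- function(v, dx, dy) {
  phys <- cbind(v$coords[, 1] * dx, v$coords[, 2] * dy)
  centered <- sweep(phys, 2, colMeans(phys))
  ev <- eigen(crossprod(centered) / nrow(phys), symmetric = TRUE,
              only.values = TRUE)$values
  if (ev[2] <= 1e-9 * max(ev[1], 1e-12)) {
    warn("degenerate VOI: eccentricity undefined for a collinear cloud")
    return(NA_real_)
  }
  sqrt(ev[1] - ev[2]) / sqrt(ev[1])
}

#' Basal signal of a time-intensity curve
#'
#' The pre-contrast signal intensity. A zero basal signal is returned with a
#' warning since relative enhancement is undefined there.
#'
#' @param tic A [tic()].
#' @return Scalar intensity (a.u.).
#' @export
basal_signal <- function(tic) {
  if (tic$pre == 0) warn("basal signal is 0: relative enhancement undefined for this voxel")
  tic$pre
}

#' Relative enhancement at one post-contrast scan
#'
#' `RE(t_i) = (SI(t_i) - BS) / BS`.
#'
#' @param tic A [tic()].
#' @param i Post-contrast scan index (1..T).
#' @return Dimensionless fraction.
#' @export
relative_enhancement <- function(tic, i) {
  if (tic$pre == 0) stopf("relative enhancement undefined: basal signal is 0")
  if (i < 1L || i > length(tic$post)) stopf("scan index out of range")
  (tic$post[i] - tic$pre) / tic$pre
}

#' Relative-enhancement slope
#'
#' Ordinary least-squares slope of `RE(t_i)` against `t_i` over all
#' post-contrast scans: the overall enhancement trend in 1/s (positive for
#' rising curves, near zero or negative once wash-out dominates the series).
#'
#' @param tic A [tic()].
#' @return Slope in 1/s.
#' @export
re_slope <- function(tic) {
  if (tic$pre == 0) stopf("relative enhancement undefined: basal signal is 0")
  if (length(tic$post) < 2L) stopf("need >= 2 post-contrast scans for a slope")
  re <- (tic$post - tic$pre) / tic$pre
  t <- tic$times
  tc <- t - mean(t)
  sum(tc * re) / sum(tc^2)
}

#' Per-voxel dynamic feature vectors of a VOI
#'
#' One row per VOI voxel (in coordinate order): basal signal `bs`,
#' relative-enhancement slope `re_slope` and `sod`. Voxels with zero basal
#' signal are dropped with a warning (their dynamic features are undefined).
#'
#' @param v A [voi()].
#' @param series The parent [dce_series()].
#' @return Tibble with columns `x`, `y`, `z`, `bs`, `re_slope`, `sod`.
#' @export
dyn_feature_vector <- function(v, series) {
  co <- v$coords
  n_frames <- series$n_post + 1L
  si <- vapply(seq_len(n_frames), function(f) {
    series$voxels[cbind(co, f)]
  }, numeric(nrow(co)))
  si <- matrix(si, nrow = nrow(co))
  bs <- si[, 1]
  sod <- bs + rowSums(abs(si[, -1, drop = FALSE] -
                          si[, -n_frames, drop = FALSE]))
  t <- series$times[-1]
  tc <- t - mean(t)
  ok <- bs > 0
  slope <- rep(NA_real_, nrow(co))
  if (any(ok)) {
    re <- (si[ok, -1, drop = FALSE] - bs[ok]) / bs[ok]
    slope[ok] <- as.vector(re %*% tc) / sum(tc^2)
  }
  out <- tibble::tibble(x = co[, 1], y = co[, 2], z = co[, 3],
                        bs = bs, re_slope = slope, sod = sod)
  if (!all(ok)) {
    warn(sprintf("dropping %d voxel(s) with zero basal signal", sum(!ok)))
    out <- out[ok, ]
  }
  out
}

#' Extract the per-voxel time-intensity curve at a coordinate
#'
#' @param series A [dce_series()].
#' @param x,y,z Voxel indices.
#' @return A [tic()].
#' @export
voxel_tic <- function(series, x, y, z) {
  si <- series$voxels[x, y, z, ]
  tic(pre = si[1], post = si[-1], times = series$times[-1])
}
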