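#' Sum of intensity differences for one voxel
#'
#' The SOD parametric value summarises the whole enhancement history of a
#' voxel: the pre-contrast intensity plus the total absolute inter-scan
#' variation, `SOD = Pre + sum_i |Post(i) - Post(i-1)|` with `Post(0)` taken
#' as the pre-contrast value (so a flat curve gives `SOD = Pre`).
#'
#' @param tic A [tic()].
#' @return Scalar SOD (a.u.).
#' @export
sod_voxel <- function(tic) {
  if (length(tic$post) < 1L) stopf("empty post-contrast sequence")
  tic$pre + sum(abs(diff(c(tic$pre, tic$post))))
}

#' SOD parametric map of a series
#'
#' Voxel-wise [sod_voxel()] over the full 4D series. The map is everywhere
#' at least the pre-contrast volume.
#'
#' @param series A [dce_series()].
#' @return 3D numeric array with the series' spatial shape.
#' @export
sod_map <- function(series) {
  v <- series$voxels
  d <- dim(v)
  out <- get_frame(v, 1L)
  for (f in 2:d[4]) out <- out + abs(get_frame(v, f) - get_frame(v, f - 1L))
  out
}

# One time frame as a 3D array (singleton spatial dimensions preserved).
get_frame <- function(v, f) {
  array(v[, , , f], dim = dim(v)[1:3])
}

#' Otsu threshold on a 1D sample
#'
#' Builds a 256-bin equal-width histogram over `[min, max]` and returns the
#' bin-edge threshold maximising the between-class variance; ties are broken
#' toward the lowest threshold. The downstream classification rule is
#' `value > threshold` = foreground.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @param bins Histogram bin count (default 256).
#' @return The threshold (a bin edge, strictly between min and max).
#' @export
otsu_threshold <- function(values, bins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (length(values) < 2L || rng[1] == rng[2]) {
    stopf("degenerate input: need >= 2 distinct values for Otsu thresholding")
  }
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  idx <- findInterval(values, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = bins)
  centers <- (edges[-1] + edges[-(bins + 1L)]) / 2
  n <- length(values)
  w0 <- cumsum(counts)[-bins] / n
  m0 <- cumsum(counts * centers)[-bins]
  mu_t <- sum(counts * centers) / n
  # between-class variance at each interior bin edge k (classes: bins <= k)
  mu0 <- ifelse(w0 > 0, m0 / (n * w0), 0)
  w1 <- 1 - w0
  mu1 <- ifelse(w1 > 0, (mu_t - w0 * mu0) / w1, 0)
  sigma_b <- w0 * w1 * (mu0 - mu1)^2
  k <- which.max(sigma_b)  # first maximum = lowest threshold on ties
  edges[k + 1L]
}

#' Breast mask from the SOD map
#'
#' The first two steps of the automatic segmentation: Otsu-threshold the SOD
#' parametric map (air vs enhancing tissue), then clean the binary volume
#' with (a) morphological closing by a discrete ball, (b) hole filling
#' (2D slice-wise, then 3D), and (c) erosion by the same ball to undo the
#' closing dilation.
#'
#' @param sod 3D SOD map from [sod_map()].
#' @param struct_radius Ball structuring-element radius in voxels (default 2).
#' @return A list: `mask` (logical 3D array) and `threshold`.
#' @export
breast_mask <- function(sod, struct_radius = 2L) {
  thr <- otsu_threshold(as.vector(sod))
  m <- sod > thr
  if (!any(m)) stopf("degenerate input: empty mask after Otsu thresholding")
  offs <- ball_offsets(struct_radius)
  m <- close_mask(m, offs)
  m <- fill_holes(m)
  m <- erode_mask(m, offs, pad = TRUE)
  list(mask = m, threshold = thr)
}

#' Kinetic suspicious-voxel extraction
#'
#' The third segmentation step. A voxel inside the breast mask is suspicious
#' iff (C1) the maximum of its relative-enhancement curve
#' `RE(t_i) = (SI(t_i) - BS)/BS` exceeds `re_threshold`, and (C2) the
#' maximum post-contrast signal is first reached strictly before the final
#' scan (the plateau / wash-out patterns; a curve still rising at the last
#' scan is the persistent benign pattern and is excluded). Voxels with
#' `BS = 0` (non-tissue) are never suspicious.
#'
#' @param series A [dce_series()].
#' @param within Logical 3D mask restricting the search (breast mask).
#' @param re_threshold C1 threshold on max relative enhancement (default 0.3).
#' @return Logical 3D array (subset of `within`).
#' @export
suspicious_voxels <- function(series, within, re_threshold = 0.3) {
  d <- spatial_dim(series)
  if (!all(dim(within) == d)) stopf("mask shape mismatch")
  v <- series$voxels
  n_post <- series$n_post
  bs <- get_frame(v, 1L)
  max_post <- get_frame(v, 2L)
  argmax <- array(1L, dim = d)
  for (f in 2:(n_post + 1L)) {
    post <- get_frame(v, f)
    better <- post > max_post  # strict: keeps the FIRST attainment
    argmax[better] <- f - 1L
    max_post[better] <- post[better]
  }
  ok_bs <- bs > 0
  max_re <- array(0, dim = d)
  max_re[ok_bs] <- (max_post[ok_bs] - bs[ok_bs]) / bs[ok_bs]
  within & ok_bs & (max_re > re_threshold) & (argmax < n_post)
}

#' Group suspicious voxels into candidate lesion VOIs
#'
#' 26-connected components of the suspicious mask, size-filtered and
#' returned largest-first with provenance `"automatic"`.
#'
#' @param suspicious Logical 3D mask.
#' @param min_size Smallest reported component, in voxels (default 10).
#' @return List of [voi()] objects (possibly empty).
#' @export
extract_vois <- function(suspicious, min_size = 10L) {
  lab <- label_components(suspicious)
  k <- max(lab)
  if (k == 0L) return(list())
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  keep <- which(sizes >= min_size)
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  lapply(keep, function(id) {
    voi(mask_to_coords(lab == id), dim(suspicious), provenance = "automatic",
        check_connected = FALSE)
  })
}

#' Run the full automatic segmentation on one series
#'
#' SOD map, Otsu breast mask with morphological cleanup, suspicious-voxel
#' extraction, and connected-component VOI formation.
#'
#' @param series A [dce_series()].
#' @param config Configuration list (see [default_config()], section
#'   `segmentation`).
#' @return A list with `sod`, `threshold`, `breast`, `suspicious` and
#'   `vois` (largest-first).
#' @export
segment_series <- function(series, config = default_config()) {
  cfg <- config$segmentation
  sod <- sod_map(series)
  bm <- breast_mask(sod, struct_radius = cfg$struct_radius)
  susp <- suspicious_voxels(series, bm$mask, re_threshold = cfg$re_threshold)
  list(sod = sod, threshold = bm$threshold, breast = bm$mask,
       suspicious = susp, vois = extract_vois(susp, min_size = cfg$min_voi_size))
}
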