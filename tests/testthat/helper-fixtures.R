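# Fixtures are built in code: tiny series/masks with known geometry and
# curves, plus brute-force oracles kept independent of the implementation.

# A series where every voxel shares one time-intensity curve.
uniform_series <- function(curve, dims = c(2, 2, 2),
                           times = seq(0, by = 60, length.out = length(curve))) {
  vox <- array(rep(curve, each = prod(dims)), dim = c(dims, length(curve)))
  dce_series(vox, dx = 1, dy = 1, slice_th = 1, times = times)
}

# A series with per-voxel curves: `curves` is a list indexed like the flat
# spatial grid; unspecified voxels are flat at `background`.
curve_series <- function(curves, dims, n_frames, background = 100,
                         times = seq(0, by = 60, length.out = n_frames)) {
  vox <- array(background, dim = c(dims, n_frames))
  for (nm in names(curves)) {
    idx <- as.integer(strsplit(nm, ",")[[1]])
    vox[idx[1], idx[2], idx[3], ] <- curves[[nm]]
  }
  dce_series(vox, dx = 1, dy = 1, slice_th = 1, times = times)
}

mask_from_coords <- function(coords, dims) {
  m <- array(FALSE, dim = dims)
  m[matrix(coords, ncol = 3)] <- TRUE
  m
}

# Exhaustive Otsu oracle: scan all interior bin edges of a 256-bin histogram
# and maximise the between-class variance by direct two-group statistics.
otsu_oracle <- function(values, bins = 256L) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  idx <- findInterval(values, edges, rightmost.closed = TRUE, all.inside = TRUE)
  centers <- (edges[-1] + edges[-(bins + 1L)]) / 2
  v <- centers[idx]  # binned representation, as the histogram method sees it
  best <- -Inf
  best_k <- NA_integer_
  for (k in 1:(bins - 1L)) {
    lo <- v[idx <= k]
    hi <- v[idx > k]
    if (length(lo) == 0L || length(hi) == 0L) sb <- 0 else {
      w0 <- length(lo) / length(v)
      sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    }
    if (sb > best + 1e-12) { best <- sb; best_k <- k }
  }
  edges[best_k + 1L]
}

# Independent boundary-voxel count (6-connectivity, border = background).
boundary_count_oracle <- function(mask) {
  d <- dim(mask)
  count <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    on_bound <- any(vapply(nb, function(p) {
      any(p < 1) || any(p > d) || !mask[p[1], p[2], p[3]]
    }, logical(1)))
    if (on_bound) count <- count + 1L
  }
  count
}

# Lesion feature table with known structure for selection tests.
informative_table <- function(n = 40, seed = 11) {
  withr::with_seed(seed, {
    label <- rep(c("benign", "malignant"), each = n / 2)
    y <- as.numeric(label == "malignant")
    tibble::tibble(
      signal_a = y * 4 + rnorm(n, sd = 0.3),
      signal_b = -y * 3 + rnorm(n, sd = 0.3),
      noise_a = rnorm(n),
      noise_b = rnorm(n),
      noise_c = rnorm(n),
      label = label
    )
  })
}
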