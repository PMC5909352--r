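#' Time-intensity curve container
#'
#' One voxel's dynamic signal: the pre-contrast (basal) value plus `T`
#' post-contrast values and their acquisition times.
#'
#' @param pre Pre-contrast signal intensity (a.u., >= 0).
#' @param post Numeric vector of post-contrast intensities (length `T` >= 1).
#' @param times Post-contrast acquisition times in seconds (strictly
#'   increasing, all > 0).
#' @return An object of class `tic`.
#' @export
tic <- function(pre, post, times) {
  if (length(post) < 1L) stopf("post-contrast sequence must be non-empty")
  if (length(times) != length(post)) stopf("times must match post length")
  if (any(diff(c(0, times)) <= 0)) stopf("times must be strictly increasing and > 0")
  structure(list(pre = pre, post = as.numeric(post), times = as.numeric(times)),
            class = "tic")
}

#' Kinetic parameters for the phantom enhancement model
#'
#' The phantom realises the two clinical curve archetypes with a
#' wash-in/wash-out product: `SI(t) = BS0 * (1 + A * (1 - exp(-k_in t)) *
#' exp(-k_out t))`. `k_out = 0` gives slow persistent enhancement (the benign
#' archetype); `k_out > 0` gives an early peak followed by wash-out (the
#' malignant archetype).
#'
#' @param bs0 Baseline (pre-contrast) intensity, a.u., > 0.
#' @param amp Uptake amplitude `A` as a fraction of baseline, >= 0.
#' @param k_in Uptake rate, 1/s, > 0.
#' @param k_out Washout rate, 1/s, >= 0.
#' @param noise_sd Additive Gaussian noise SD, a.u., >= 0.
#' @return A `kinetic_params` list.
#' @export
kinetic_params <- function(bs0 = 100, amp = 1, k_in = 0.02, k_out = 0,
                           noise_sd = 0) {
  stopifnot(is.finite(bs0), bs0 > 0, amp >= 0, k_in > 0, k_out >= 0,
            noise_sd >= 0)
  structure(list(bs0 = bs0, amp = amp, k_in = k_in, k_out = k_out,
                 noise_sd = noise_sd), class = "kinetic_params")
}

# Noiseless enhancement fraction at time t (SI = bs0 * (1 + amp * g(t))).
enhancement_fraction <- function(t, k_in, k_out) {
  (1 - exp(-k_in * t)) * exp(-k_out * t)
}

#' Simulate one voxel's time-intensity curve
#'
#' @param p A [kinetic_params()].
#' @param times Scan times in seconds including the pre-contrast scan:
#'   strictly increasing with `times[1] = 0`.
#' @param seed Optional integer seed for the noise draw.
#' @return A [tic()] with `pre = SI(0)` and the post-contrast samples.
#' @export
kinetic_curve <- function(p, times, seed = NULL) {
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  if (times[1] != 0) stopf("times[1] must be 0 (pre-contrast)")
  si <- p$bs0 * (1 + p$amp * enhancement_fraction(times, p$k_in, p$k_out))
  si[1] <- p$bs0  # g(0) = 0 exactly
  draw <- function() si + stats::rnorm(length(si), 0, p$noise_sd)
  si <- if (p$noise_sd > 0) {
    if (is.null(seed)) draw() else with_seed(seed, draw())
  } else si
  si <- pmax(si, 0)
  tic(pre = si[1], post = si[-1], times = times[-1])
}

#' Specification of one synthetic lesion
#'
#' @param centre Length-3 voxel coordinates of the lesion centre.
#' @param radius Nominal radius in voxels (>= 2).
#' @param class `"benign"` or `"malignant"`.
#' @param rho Shape irregularity amplitude in `[0, 1]`: 0 gives an exact
#'   discrete ball, larger values modulate the radius direction-by-direction
#'   with smooth low-order angular perturbations (irregular margin).
#' @param kinetics A [kinetic_params()].
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(centre, radius, class, rho = 0,
                        kinetics = kinetic_params()) {
  check_labels(class, "lesion class")
  if (radius < 2) stopf("lesion radius must be >= 2 voxels")
  if (rho < 0 || rho > 1) stopf("rho must be in [0, 1]")
  structure(list(centre = as.numeric(centre), radius = radius, class = class,
                 rho = rho, kinetics = kinetics), class = "lesion_spec")
}

# Low-order angular modulation field on unit directions: a seeded random
# combination of degree-2/3 spherical-harmonic-like monomials, scaled so
# max |f| = 1 over the supplied directions.
angular_modulation <- function(u, seed) {
  basis <- cbind(
    u[, 1]^2 - 1 / 3, u[, 2]^2 - 1 / 3,
    u[, 1] * u[, 2], u[, 1] * u[, 3], u[, 2] * u[, 3],
    u[, 1] * (u[, 2]^2 - u[, 3]^2),
    u[, 2] * (u[, 3]^2 - u[, 1]^2),
    u[, 3] * (u[, 1]^2 - u[, 2]^2)
  )
  coef <- with_seed(seed, stats::rnorm(ncol(basis)))
  f <- drop(basis %*% coef)
  mx <- max(abs(f))
  if (mx > 0) f / mx else f
}

#' Rasterise a synthetic lesion mask
#'
#' For `rho = 0` the mask is the exact discrete ball (voxel centres within
#' `radius` of the centre). For `rho > 0` the inclusion radius is modulated
#' per direction by a seeded smooth angular field of relative amplitude
#' `rho` (floored at 1.2 voxels so a core always exists); the 26-connected
#' component containing the centre is returned, so the mask is always
#' connected.
#'
#' @param spec A [lesion_spec()].
#' @param grid_dim Length-3 spatial grid dimensions.
#' @param seed Integer seed for the shape perturbation (deterministic:
#'   same seed + spec gives the same mask).
#' @param z_scale Anisotropy factor: the z-offset of a voxel is multiplied
#'   by this before the radius test, so a physically round lesion on
#'   anisotropic voxels uses `z_scale = slice_th / dx`. Default 1 (isotropic
#'   discrete ball).
#' @return Logical 3D array.
#' @export
make_lesion_mask <- function(spec, grid_dim, seed = 1, z_scale = 1) {
  d <- as.integer(grid_dim)
  r <- spec$radius
  core <- c(r, r, r / z_scale)
  if (any(floor(spec$centre) - ceiling(core) < 1L) ||
      any(ceiling(spec$centre) + ceiling(core) > d)) {
    stopf("lesion exceeds grid")
  }
  bb <- ceiling(r * (1 + spec$rho)) + 1L
  bbz <- ceiling(r * (1 + spec$rho) / z_scale) + 1L
  lo <- pmax(floor(spec$centre) - c(bb, bb, bbz), 1L)
  hi <- pmin(ceiling(spec$centre) + c(bb, bb, bbz), d)
  g <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
  delta <- cbind(g$x - spec$centre[1], g$y - spec$centre[2],
                 (g$z - spec$centre[3]) * z_scale)
  dist <- sqrt(rowSums(delta^2))
  if (spec$rho == 0) {
    keep <- dist <= r
  } else {
    u <- delta / pmax(dist, 1e-12)
    f <- angular_modulation(u, seed)
    r_dir <- pmax(r * (1 + spec$rho * f), 1.2)
    keep <- dist <= r_dir
  }
  m <- array(FALSE, d)
  m[cbind(g$x, g$y, g$z)[keep, , drop = FALSE]] <- TRUE
  if (spec$rho > 0) {
    lab <- label_components(m)
    ctr <- round(spec$centre)
    keep_lab <- lab[ctr[1], ctr[2], ctr[3]]
    if (keep_lab == 0L) keep_lab <- lab[m][which.max(tabulate(lab[m]))]
    m <- lab == keep_lab
  }
  m
}

#' Phantom cohort parameter profiles
#'
#' Class-conditional parameter ranges for [generate_cohort()]. The
#' `"default"` profile makes the two archetypes cleanly distinct (malignant:
#' strong uptake peaking early with wash-out, irregular margins; benign:
#' moderate persistent uptake peaking at the final scan, smooth margins).
#' The `"hard"` profile overlaps the amplitude, rate and shape ranges and
#' gives benign lesions a mild wash-out so both classes pass the
#' suspicious-voxel rules and neither channel is trivially separable.
#'
#' @param profile `"default"` or `"hard"`.
#' @return Nested list of ranges (`c(lo, hi)` drawn uniformly) per class,
#'   plus baseline, background and noise settings.
#' @export
phantom_params <- function(profile = c("default", "hard")) {
  profile <- match.arg(profile)
  base <- list(
    bs0 = 100, noise_sd = 2, voxel_jitter_sd = 0,
    background = list(amp = 0.08, k_in = 0.005, k_out = 0),
    radius = c(3, 4.5)
  )
  cls <- if (profile == "default") {
    list(
      benign = list(amp = c(0.35, 0.8), k_in = c(0.01, 0.02),
                    k_out = c(0, 0), rho = c(0, 0.25)),
      malignant = list(amp = c(0.8, 1.5), k_in = c(0.02, 0.04),
                       k_out = c(4e-4, 1e-3), rho = c(0.35, 0.7))
    )
  } else {
    base$noise_sd <- 4
    base$voxel_jitter_sd <- 0.12
    list(
      benign = list(amp = c(0.5, 1.0), k_in = c(0.01, 0.02),
                    k_out = c(5e-4, 1.5e-3), rho = c(0.05, 0.45)),
      malignant = list(amp = c(0.7, 1.4), k_in = c(0.015, 0.04),
                       k_out = c(1e-3, 4e-3), rho = c(0.25, 0.65))
    )
  }
  c(base, cls, list(profile = profile))
}

# Breast region: half-ellipsoid seated on the y = 1 face of the grid.
breast_region <- function(grid_dim) {
  d <- grid_dim
  cx <- (d[1] + 1) / 2; cz <- (d[3] + 1) / 2
  ax <- 0.45 * d[1]; ay <- 0.75 * d[2]; az <- 0.48 * d[3]
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  v <- ((g$x - cx) / ax)^2 + ((g$y - 1) / ay)^2 + ((g$z - cz) / az)^2
  array(v <= 1, dim = d)
}

draw_range <- function(r) if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])

#' Generate a synthetic DCE-MRI cohort
#'
#' Builds one 4D series per lesion: a half-ellipsoid "breast" of baseline
#' tissue with mild enhancement, a single lesion following its
#' class-conditional kinetics and shape, Gaussian noise inside the tissue
#' (air stays exactly zero), and a stratified train/test split. Fully
#' reproducible from `seed`: lesion `i` draws from substream `seed + i`, so
#' enlarging the cohort never reshuffles existing lesions.
#'
#' @param n_benign,n_malignant Lesion counts (>= 1 each).
#' @param grid_dim Spatial grid, default `c(32, 32, 10)`.
#' @param times Scan times (s) including pre-contrast at 0; default 1 pre +
#'   9 post at 56 s spacing.
#' @param params A [phantom_params()] profile.
#' @param seed Integer seed.
#' @param noise_sd Override the profile's noise SD (e.g. 0 for noiseless).
#' @param train_counts Optional `c(benign =, malignant =)` training-set
#'   sizes; default `round(2/3 * n)` per class (clamped so both splits are
#'   non-empty when a class has >= 2 lesions).
#' @return A `dce_cohort` list: `series` (list of [dce_series()]), `masks`
#'   (ground-truth lesion masks), `manifest` (tibble: lesion_id, label,
#'   split), `params` (tibble of drawn per-lesion parameters), and the
#'   generation settings.
#' @export
generate_cohort <- function(n_benign, n_malignant, grid_dim = c(32, 32, 10),
                            times = seq(0, 504, by = 56),
                            params = phantom_params(), seed = 1,
                            noise_sd = NULL, train_counts = NULL) {
  if (n_benign < 1 || n_malignant < 1) stopf("need >= 1 lesion per class")
  nsd <- noise_sd %||% params$noise_sd
  labels <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  n <- length(labels)
  breast <- breast_region(grid_dim)
  # lesions are placed at least the morphological-cleanup scale inside the
  # breast so segmentation erosion never clips lesion voxels
  interior <- erode_mask(breast, ball_offsets(2L))
  series <- masks <- vector("list", n)
  drawn <- vector("list", n)

  for (i in seq_len(n)) {
    made <- with_seed(seed + i, {
      cl <- labels[i]
      pr <- params[[cl]]
      kp <- kinetic_params(
        bs0 = params$bs0, amp = draw_range(pr$amp),
        k_in = draw_range(pr$k_in), k_out = draw_range(pr$k_out),
        noise_sd = nsd
      )
      radius <- draw_range(params$radius)
      rho <- draw_range(pr$rho)
      z_scale <- 2  # slice_th / dx of the rendered series
      r_ax <- c(radius, radius, radius / z_scale)
      mask <- NULL
      for (attempt in 1:200) {
        ctr <- vapply(1:3, function(j) {
          stats::runif(1, 1 + r_ax[j] + 1.5, grid_dim[j] - r_ax[j] - 1.5)
        }, numeric(1))
        sp <- lesion_spec(ctr, radius, cl, rho, kp)
        # shape realization is redrawn with the centre so that strongly
        # irregular lesions can still find a pose that fits the breast
        cand <- make_lesion_mask(sp, grid_dim,
                                 seed = seed * 1000L + i + 7L * attempt,
                                 z_scale = z_scale)
        if (all(interior[cand])) { mask <- cand; break }
      }
      if (is.null(mask)) stopf("could not place lesion %d inside the breast", i)
      list(mask = mask, kp = kp, radius = radius, rho = rho,
           series = render_series(mask, breast, kp, params, times, grid_dim))
    })
    masks[[i]] <- made$mask
    series[[i]] <- made$series
    drawn[[i]] <- tibble::tibble(
      lesion_id = sprintf("lesion%02d", i), label = labels[i],
      amp = made$kp$amp, k_in = made$kp$k_in, k_out = made$kp$k_out,
      radius = made$radius, rho = made$rho, n_voxels = sum(made$mask)
    )
  }

  split <- with_seed(seed, {
    out <- character(n)
    for (cl in c("benign", "malignant")) {
      idx <- which(labels == cl)
      k <- if (!is.null(train_counts)) train_counts[[cl]] else round(2 / 3 * length(idx))
      if (length(idx) >= 2) k <- max(1L, min(length(idx) - 1L, k))
      out[sample(idx, k)] <- "train"
    }
    out[out == ""] <- "test"
    out
  })

  manifest <- tibble::tibble(
    lesion_id = sprintf("lesion%02d", seq_len(n)),
    label = labels, split = split
  )
  structure(list(series = series, masks = masks, manifest = manifest,
                 params = dplyr::bind_rows(drawn), grid_dim = grid_dim,
                 times = times, breast = breast, seed = seed,
                 profile = params$profile),
            class = "dce_cohort")
}

# Assemble the 4D volume for one lesion. Lesion voxels get a per-voxel
# amplitude jitter (multiplicative, floored) when the profile asks for
# heterogeneity; air is exactly zero (so basal signal 0 marks non-tissue).
render_series <- function(mask, breast, kp, params, times, grid_dim) {
  n_frames <- length(times)
  g_les <- enhancement_fraction(times, kp$k_in, kp$k_out)
  bg <- params$background
  g_bg <- enhancement_fraction(times, bg$k_in, bg$k_out)
  tissue <- breast | mask
  n_tis <- sum(tissue)
  n_les <- sum(mask)
  jitter <- if (params$voxel_jitter_sd > 0) {
    pmax(0.3, 1 + stats::rnorm(n_les, 0, params$voxel_jitter_sd))
  } else rep(1, n_les)
  vox <- array(0, dim = c(grid_dim, n_frames))
  les_in_tissue <- mask[tissue]
  for (f in seq_len(n_frames)) {
    vol <- array(0, dim = grid_dim)
    vals <- rep(kp$bs0 * (1 + bg$amp * g_bg[f]), n_tis)
    vals[les_in_tissue] <- kp$bs0 * (1 + kp$amp * jitter * g_les[f])
    if (kp$noise_sd > 0) vals <- vals + stats::rnorm(n_tis, 0, kp$noise_sd)
    vol[tissue] <- pmax(vals, 0)
    vox[, , , f] <- vol
  }
  dce_series(vox, dx = 1, dy = 1, slice_th = 2, times = times)
}

#' Write a cohort to disk (NIfTI series + masks, CSV manifest, JSON params)
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$series <- sprintf("%s_series.nii.gz", man$lesion_id)
  man$mask <- sprintf("%s_mask.nii.gz", man$lesion_id)
  for (i in seq_len(nrow(man))) {
    write_dce_series(cohort$series[[i]], file.path(dir, man$series[i]))
    write_mask(cohort$masks[[i]], cohort$series[[i]], file.path(dir, man$mask[i]))
  }
  man <- man[, c("lesion_id", "series", "mask", "label", "split")]
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  jsonlite::write_json(cohort$params, file.path(dir, "params.json"),
                       dataframe = "rows", digits = NA)
  invisible(path)
}
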