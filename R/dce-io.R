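#' Construct a DCE-MRI series object
#'
#' A `dce_series` holds one dynamic acquisition: a 4D intensity array indexed
#' `(x, y, z, frame)` where frame 1 is the pre-contrast scan and frames
#' `2..T+1` are the `T` post-contrast scans, together with the voxel spacing
#' and the acquisition time of each frame. The frame-1 = pre-contrast
#' convention is fixed here and relied on by every downstream stage; nothing
#' re-infers it.
#'
#' @param voxels 4D numeric array `(x, y, z, frame)`, finite and non-negative.
#' @param dx,dy In-plane voxel spacing in mm (> 0).
#' @param slice_th Slice thickness in mm (> 0); also used as the through-plane
#'   voxel spacing `dz`.
#' @param times Numeric vector of acquisition times in seconds, one per frame,
#'   strictly increasing, `times[1] = 0` for the pre-contrast scan.
#' @return An object of class `dce_series` with fields `voxels`, `dx`, `dy`,
#'   `slice_th`, `times` and convenience element `n_post` (the number of
#'   post-contrast frames, `T`).
#' @export
dce_series <- function(voxels, dx, dy, slice_th, times) {
  if (length(dim(voxels)) != 4L) stopf("voxels must be a 4D array")
  n_frames <- dim(voxels)[4]
  if (n_frames < 3L) stopf("series must contain pre + post frames (>= 2 post-contrast scans)")
  if (length(times) != n_frames) stopf("times must have one entry per frame")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  for (nm in c("dx", "dy", "slice_th")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stopf("spacing field '%s' must be a single positive number", nm)
    }
  }
  if (anyNA(voxels) || any(!is.finite(voxels))) stopf("voxels must be finite")
  if (any(voxels < 0)) stopf("voxels must be non-negative")
  structure(
    list(voxels = voxels, dx = dx, dy = dy, slice_th = slice_th,
         times = as.numeric(times), n_post = n_frames - 1L),
    class = "dce_series"
  )
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<dce_series> %d x %d x %d voxels, 1 pre + %d post-contrast frames\n",
              d[1], d[2], d[3], x$n_post))
  cat(sprintf("  spacing %.3g x %.3g mm, slice %.3g mm; times %s s\n",
              x$dx, x$dy, x$slice_th, paste(signif(x$times, 4), collapse = " ")))
  invisible(x)
}

spatial_dim <- function(series) dim(series$voxels)[1:3]

#' Read a 4D DCE-MRI series from a NIfTI-1 file
#'
#' Spacing is taken from the header `pixdim`; frame times default to the
#' header's temporal step (`pixdim[4]`) on a uniform grid starting at 0, and
#' can be overridden.
#'
#' @param path Path to a 4D NIfTI-1 file (1 pre- + >= 2 post-contrast frames).
#' @param times Optional explicit frame times (s); default uses the header
#'   temporal spacing.
#' @return A [dce_series()].
#' @export
read_dce_series <- function(path, times = NULL) {
  if (!file.exists(path)) stopf("series file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stopf("series must be 4D (got %dD): %s", length(d), path)
  if (d[4] < 3L) stopf("series must contain pre + post frames")
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || any(pd[1:3] <= 0)) {
    stopf("non-positive voxel spacing in header of %s (pixdim = %s)",
          path, paste(signif(pd, 4), collapse = ", "))
  }
  if (is.null(times)) {
    tr <- if (length(pd) >= 4 && is.finite(pd[4]) && pd[4] > 0) pd[4] else 1
    times <- seq(0, by = tr, length.out = d[4])
  }
  dce_series(array(as.numeric(img), dim = d),
             dx = pd[1], dy = pd[2], slice_th = pd[3], times = times)
}

#' Write a DCE-MRI series to a NIfTI-1 file
#'
#' The inverse of [read_dce_series()]: voxel data round-trip exactly, spacing
#' to header precision. Frame times are encoded as the (uniform) temporal
#' `pixdim`; irregular times should be carried separately.
#'
#' @param series A [dce_series()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_dce_series <- function(series, path) {
  tr <- if (series$n_post >= 1) series$times[2] - series$times[1] else 1
  img <- RNifti::asNifti(series$voxels)
  RNifti::pixdim(img) <- c(series$dx, series$dy, series$slice_th, tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D binary lesion/breast mask
#'
#' Any nonzero voxel is foreground. The mask must share its spatial grid with
#' the parent series.
#'
#' @param path Path to a 3D NIfTI-1 file.
#' @param series The parent [dce_series()] (shape check).
#' @return A logical 3D array.
#' @export
read_mask <- function(path, series) {
  if (!file.exists(path)) stopf("mask file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1]
    d <- dim(img)
  }
  if (length(d) != 3L) stopf("mask must be 3D: %s", path)
  sd3 <- spatial_dim(series)
  if (!all(d == sd3)) {
    stopf("mask shape (%s) does not match series spatial shape (%s)",
          paste(d, collapse = ","), paste(sd3, collapse = ","))
  }
  array(img != 0, dim = d)
}

#' Write a 3D binary mask as unsigned 8-bit NIfTI
#'
#' @param mask Logical (or 0/1) 3D array.
#' @param series Parent [dce_series()] supplying the voxel spacing.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, series, path) {
  if (length(dim(mask)) != 3L) stopf("mask must be 3D")
  img <- RNifti::asNifti(array(as.integer(mask != 0), dim = dim(mask)))
  RNifti::pixdim(img) <- c(series$dx, series$dy, series$slice_th)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Construct a volume of interest (VOI)
#'
#' A VOI is one lesion: a non-empty, 26-connected set of unique in-bounds
#' voxel coordinates within a given spatial grid, with a provenance flag
#' (drawn manually vs found by the automatic segmentation) and an optional
#' histology label.
#'
#' @param coords Integer matrix with columns x, y, z (1-based voxel indices).
#' @param grid_dim Length-3 spatial grid dimensions.
#' @param provenance `"manual"` or `"automatic"`.
#' @param label `"benign"`, `"malignant"` or `"unknown"`.
#' @param check_connected Verify 26-connectivity (default TRUE).
#' @return An object of class `voi`.
#' @export
voi <- function(coords, grid_dim, provenance = c("manual", "automatic"),
                label = "unknown", check_connected = TRUE) {
  provenance <- match.arg(provenance)
  coords <- matrix(as.integer(coords), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  if (nrow(coords) == 0L) stopf("VOI must be non-empty")
  if (anyDuplicated(paste(coords[, 1], coords[, 2], coords[, 3]))) {
    stopf("VOI coordinates must be unique")
  }
  for (j in 1:3) {
    if (any(coords[, j] < 1L | coords[, j] > grid_dim[j])) {
      stopf("VOI coordinates out of bounds on axis %d", j)
    }
  }
  if (!label %in% c("benign", "malignant", "unknown")) {
    stopf("label must be benign, malignant or unknown")
  }
  if (check_connected && nrow(coords) > 1L) {
    m <- coords_to_mask(coords, grid_dim)
    if (max(label_components(m)) != 1L) stopf("VOI must be 26-connected")
  }
  structure(list(coords = coords, grid_dim = as.integer(grid_dim),
                 provenance = provenance, label = label),
            class = "voi")
}

#' @export
print.voi <- function(x, ...) {
  cat(sprintf("<voi> %d voxels (%s, label: %s) in grid %s\n",
              nrow(x$coords), x$provenance, x$label,
              paste(x$grid_dim, collapse = "x")))
  invisible(x)
}

#' Convert between coordinate matrices and binary masks
#'
#' @param coords Integer matrix of 1-based voxel coordinates (columns x, y, z).
#' @param grid_dim Length-3 spatial grid dimensions.
#' @return `coords_to_mask()`: a logical 3D array; `mask_to_coords()`: the
#'   coordinate matrix of the TRUE voxels.
#' @export
coords_to_mask <- function(coords, grid_dim) {
  m <- array(FALSE, dim = grid_dim)
  m[coords] <- TRUE
  m
}

#' @rdname coords_to_mask
#' @param mask Logical 3D array.
#' @export
mask_to_coords <- function(mask) {
  which(mask, arr.ind = TRUE) |>
    `colnames<-`(c("x", "y", "z"))
}

#' Turn a binary lesion mask into a VOI
#'
#' @param mask Logical 3D array (one lesion).
#' @inheritParams voi
#' @return A [voi()].
#' @export
voi_from_mask <- function(mask, provenance = "manual", label = "unknown") {
  voi(mask_to_coords(mask), dim(mask), provenance = provenance, label = label,
      check_connected = FALSE)
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with columns `lesion_id`, `series`, `mask`
#' (a path or `"auto"` for automatic segmentation), `label`
#' (benign/malignant) and `split` (train/test). Paths are resolved relative
#' to the manifest's directory and checked for existence.
#'
#' @param path Manifest CSV path.
#' @return A tibble with the columns above (paths made absolute).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lesion_id", "series", "mask", "label", "split")
  if (!all(need %in% names(df))) {
    stopf("manifest must have columns: %s", paste(need, collapse = ", "))
  }
  check_labels(df$label, "manifest labels")
  if (!all(df$split %in% c("train", "test"))) stopf("split must be train or test")
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(p == "auto", p, file.path(base, p))
  df$series <- resolve(df$series)
  df$mask <- resolve(df$mask)
  missing <- c(df$series[!file.exists(df$series)],
               setdiff(df$mask[df$mask != "auto"],
                       df$mask[df$mask == "auto" | file.exists(df$mask)]))
  if (length(missing)) stopf("manifest refers to missing files: %s",
                             paste(missing, collapse = ", "))
  tibble::as_tibble(df)
}

#' Write the per-lesion and per-voxel feature tables
#'
#' Writes one CSV row per lesion (id, split, label, the four morphological
#' features, and the mean over lesion voxels of each dynamic feature) plus a
#' sidecar CSV (`*_voxels.csv`) holding the individual per-voxel dynamic
#' feature rows that the voxel-level classifier consumes.
#'
#' @param features A cohort feature set as returned by [cohort_features()]:
#'   a list with tibbles `lesions` and `voxels`.
#' @param path Output CSV path for the lesion table.
#' @return Invisibly, the two paths written.
#' @export
write_feature_table <- function(features, path) {
  if (is.null(features$lesions) || nrow(features$lesions) == 0L) {
    stopf("nothing to write: empty feature set")
  }
  vox_path <- sub("\\.csv$", "", path)
  vox_path <- paste0(vox_path, "_voxels.csv")
  utils::write.csv(features$lesions, path, row.names = FALSE)
  utils::write.csv(features$voxels, vox_path, row.names = FALSE)
  invisible(c(lesions = path, voxels = vox_path))
}

#' Read feature tables written by [write_feature_table()]
#'
#' @param path Lesion-table CSV path.
#' @return A list with tibbles `lesions` and `voxels`.
#' @export
read_feature_table <- function(path) {
  vox_path <- paste0(sub("\\.csv$", "", path), "_voxels.csv")
  list(
    lesions = tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE)),
    voxels = tibble::as_tibble(utils::read.csv(vox_path, stringsAsFactors = FALSE))
  )
}

#' Default pipeline configuration
#'
#' One flat namespace per module; every tunable documented in the methods
#' vignette appears here with its default. [read_config()] merges a user YAML
#' over these defaults.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    segmentation = list(
      re_threshold = 0.3,       # min max-relative-enhancement for a suspicious voxel
      otsu_bins = 256L,
      struct_radius = 2L,       # ball radius (voxels) for closing/erosion
      min_voi_size = 10L        # smallest reported component (voxels)
    ),
    features = list(
      perimeter_mm = FALSE      # multiply boundary count by in-plane spacing
    ),
    selection = list(
      bins = 10L,               # equal-width bins for the consistency score
      stall_limit = 5L,         # best-first: stop after this many non-improving expansions
      cap = 10L                 # ranking cut cap
    ),
    classify = list(
      confidence_factor = 0.25,
      pruned = FALSE,
      min_leaf = 2L,
      kernel_estimator = FALSE,
      folds = 10L
    ),
    fusion = list(
      alpha_step = 0.05,
      alpha_on_test = FALSE     # TRUE: pick alpha on the test split (leaks test data)
    ),
    evaluate = list(
      exact_limit = 25L         # exact binomial McNemar below this discordant count
    )
  )
}

#' Read a YAML configuration, merged over the defaults
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (mod in names(user)) {
    for (key in names(user[[mod]])) cfg[[mod]][[key]] <- user[[mod]][[key]]
  }
  cfg
}
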