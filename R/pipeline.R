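#' Extract the feature tables for a whole cohort
#'
#' For each lesion, obtains a VOI either from the ground-truth/manual mask
#' (`segmentation = "manual"`) or by running the automatic segmentation on
#' its series and keeping the largest candidate (`"auto"`), then computes
#' the lesion-level morphological features and per-voxel dynamic features.
#' Lesions the automatic segmentation does not detect get `detected =
#' FALSE` and `NA` features (downstream they are predicted benign: no
#' suspicious enhancement was found).
#'
#' @param cohort A [generate_cohort()] result, or a compatible list with
#'   `series`, `masks` and `manifest`.
#' @param segmentation `"auto"` or `"manual"`.
#' @param config Configuration list ([default_config()]).
#' @return List of tibbles: `lesions` (one row per lesion: id, split,
#'   label, detected, n_voxels, the four morphological features, and
#'   voxel-mean `bs`, `re_slope`, `sod`) and `voxels` (one row per VOI
#'   voxel: id, split, label, `bs`, `re_slope`, `sod`).
#' @export
cohort_features <- function(cohort, segmentation = c("auto", "manual"),
                            config = default_config()) {
  segmentation <- match.arg(segmentation)
  man <- cohort$manifest
  lesion_rows <- vector("list", nrow(man))
  voxel_rows <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    series <- cohort$series[[i]]
    v <- if (segmentation == "manual") {
      voi_from_mask(cohort$masks[[i]], provenance = "manual",
                    label = man$label[i])
    } else {
      seg <- segment_series(series, config)
      if (length(seg$vois) == 0L) NULL else {
        v0 <- seg$vois[[1]]
        v0$label <- man$label[i]
        v0
      }
    }
    base <- tibble::tibble(lesion_id = man$lesion_id[i], split = man$split[i],
                           label = man$label[i])
    if (is.null(v)) {
      lesion_rows[[i]] <- dplyr::mutate(
        base, detected = FALSE, n_voxels = 0L,
        area_median = NA_real_, perimeter_median = NA_real_,
        compactness = NA_real_, eccentricity = NA_real_,
        bs = NA_real_, re_slope = NA_real_, sod = NA_real_)
      next
    }
    morph <- morph_feature_vector(v, series,
                                  perimeter_mm = config$features$perimeter_mm)
    dyn <- dyn_feature_vector(v, series)
    lesion_rows[[i]] <- dplyr::bind_cols(
      dplyr::mutate(base, detected = TRUE, n_voxels = nrow(dyn)),
      morph,
      dplyr::summarise(dyn, bs = mean(.data$bs), re_slope = mean(.data$re_slope),
                       sod = mean(.data$sod)))
    voxel_rows[[i]] <- dplyr::bind_cols(
      base[rep(1, nrow(dyn)), ],
      dyn[, c("bs", "re_slope", "sod")])
  }
  list(lesions = dplyr::bind_rows(lesion_rows),
       voxels = dplyr::bind_rows(voxel_rows))
}

morph_feature_names <- c("area_median", "perimeter_median", "compactness",
                         "eccentricity")
dyn_feature_names <- c("bs", "re_slope", "sod")

#' Run the full multiple-classifier-system pipeline on a cohort
#'
#' Segments (or ingests masks), extracts features, trains the decision tree
#' on lesion-level morphological features and the Gaussian naive Bayes on
#' voxel-level dynamic features (training split only), computes per-lesion
#' channel probabilities `(D_m, D_b)` and `(M_m, M_b)`, selects the fusion
#' coefficient `alpha` by leave-one-out accuracy on the training split
#' (unless `fusion$alpha_on_test` is set), and evaluates the fused and
#' single-channel decisions on the test split.
#'
#' @param cohort A [generate_cohort()] result.
#' @param segmentation `"auto"` or `"manual"`.
#' @param config Configuration list ([default_config()]).
#' @param seed Seed for the cross-validation folds.
#' @return An `mcs_result`: list with `features`, `tree`, `nb`, `lesions`
#'   (per-lesion tibble with channel probabilities and predictions),
#'   `alpha` (an `alpha_selection` on the selection split), `test_curve`
#'   (accuracy-vs-alpha on the test split), `test_metrics` (named list of
#'   [metrics()] tibbles for `fused`, `dynamic`, `morphological`) and
#'   `cv` (10-fold training accuracies per channel).
#' @export
run_mcs <- function(cohort, segmentation = c("auto", "manual"),
                    config = default_config(), seed = 1) {
  segmentation <- match.arg(segmentation)
  feats <- cohort_features(cohort, segmentation, config)
  les <- feats$lesions
  ccf <- config$classify
  train_les <- dplyr::filter(les, .data$split == "train", .data$detected)
  train_vox <- dplyr::filter(feats$voxels,
                             .data$lesion_id %in% train_les$lesion_id)
  if (length(unique(train_les$label)) < 2L) {
    stopf("training split must contain detected lesions of both classes")
  }
  tree <- train_tree(train_les[, c(morph_feature_names, "label")],
                     confidence_factor = ccf$confidence_factor,
                     pruned = ccf$pruned, min_leaf = ccf$min_leaf)
  nb <- train_nb(train_vox[, c(dyn_feature_names, "label")],
                 kernel_estimator = ccf$kernel_estimator)

  les$M_m <- NA_real_
  les$D_m <- NA_real_
  for (i in seq_len(nrow(les))) {
    if (!les$detected[i]) {
      # nothing suspicious found: both channels fall back to a benign call
      les$M_m[i] <- 0
      les$D_m[i] <- 0
      next
    }
    les$M_m[i] <- predict_proba(tree, les[i, morph_feature_names])$p_malignant
    vox <- dplyr::filter(feats$voxels, .data$lesion_id == les$lesion_id[i])
    les$D_m[i] <- voxel_dynamic_probabilities(
      vox[, dyn_feature_names], nb)$D_m
  }
  les$M_b <- 1 - les$M_m
  les$D_b <- 1 - les$D_m

  if (isTRUE(config$fusion$alpha_on_test)) {
    sel_tbl <- dplyr::filter(les, .data$split == "test")
  } else {
    # leave-one-lesion-out channel probabilities on the training split, so
    # alpha is chosen against out-of-sample evidence (an unpruned tree is
    # perfect on resubstitution and would otherwise always dominate)
    sel_tbl <- dplyr::filter(les, .data$split == "train")
    for (j in seq_len(nrow(sel_tbl))) {
      id <- sel_tbl$lesion_id[j]
      if (!sel_tbl$detected[j]) {
        sel_tbl$M_m[j] <- 0; sel_tbl$D_m[j] <- 0
        next
      }
      rest_les <- dplyr::filter(train_les, .data$lesion_id != id)
      rest_vox <- dplyr::filter(train_vox, .data$lesion_id != id)
      if (length(unique(rest_les$label)) < 2L) next  # keep full-model value
      tr_j <- train_tree(rest_les[, c(morph_feature_names, "label")],
                         confidence_factor = ccf$confidence_factor,
                         pruned = ccf$pruned, min_leaf = ccf$min_leaf)
      nb_j <- train_nb(rest_vox[, c(dyn_feature_names, "label")],
                       kernel_estimator = ccf$kernel_estimator)
      sel_tbl$M_m[j] <- predict_proba(tr_j, sel_tbl[j, morph_feature_names])$p_malignant
      vox_j <- dplyr::filter(feats$voxels, .data$lesion_id == id)
      sel_tbl$D_m[j] <- voxel_dynamic_probabilities(
        vox_j[, dyn_feature_names], nb_j)$D_m
    }
  }
  alpha_sel <- select_alpha(sel_tbl, step = config$fusion$alpha_step)
  fused <- fuse(les$D_m, les$M_m, alpha_sel$alpha)
  les$pred_fused <- fused$predicted
  les$pred_dynamic <- ifelse(les$D_m >= les$D_b, "malignant", "benign")
  les$pred_morph <- ifelse(les$M_m >= les$M_b, "malignant", "benign")

  test <- dplyr::filter(les, .data$split == "test")
  test_curve <- select_alpha(test, step = config$fusion$alpha_step)
  test_metrics <- list(
    fused = metrics(confusion(test$label, test$pred_fused)),
    dynamic = metrics(confusion(test$label, test$pred_dynamic)),
    morphological = metrics(confusion(test$label, test$pred_morph))
  )
  try_cv <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  cv <- list(
    morphological = try_cv(
      cross_validate(train_les[, c(morph_feature_names, "label")],
                     kind = "tree", folds = min(ccf$folds, nrow(train_les)),
                     seed = seed, pruned = ccf$pruned,
                     min_leaf = ccf$min_leaf)$accuracy),
    dynamic = try_cv(
      cross_validate(train_vox[, c(dyn_feature_names, "label")],
                     kind = "nb", folds = ccf$folds, seed = seed)$accuracy)
  )
  structure(list(features = feats, tree = tree, nb = nb, lesions = les,
                 alpha = alpha_sel, test_curve = test_curve,
                 test_metrics = test_metrics, cv = cv,
                 segmentation = segmentation, config = config),
            class = "mcs_result")
}

test_accuracy <- function(m) m$value[m$metric == "accuracy"] / 100

#' @export
print.mcs_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<mcs_result> %s segmentation, alpha* = %.3f\n",
              x$segmentation, g$alpha))
  cat(sprintf("  test accuracy: fused %.1f%%, dynamic %.1f%%, morphological %.1f%%\n",
              100 * g$accuracy_fused, 100 * g$accuracy_dynamic,
              100 * g$accuracy_morph))
  invisible(x)
}

#' @rdname run_mcs
#' @param x An `mcs_result`.
#' @param ... Unused.
#' @export
tidy.mcs_result <- function(x, ...) {
  x$lesions[, c("lesion_id", "split", "label", "detected", "n_voxels",
                "D_m", "D_b", "M_m", "M_b",
                "pred_dynamic", "pred_morph", "pred_fused")]
}

#' @rdname run_mcs
#' @export
glance.mcs_result <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha$alpha,
    accuracy_fused = test_accuracy(x$test_metrics$fused),
    accuracy_dynamic = test_accuracy(x$test_metrics$dynamic),
    accuracy_morph = test_accuracy(x$test_metrics$morphological),
    cv_accuracy_morph = x$cv$morphological,
    cv_accuracy_dynamic = x$cv$dynamic,
    n_train = sum(x$lesions$split == "train"),
    n_test = sum(x$lesions$split == "test")
  )
}

#' @rdname run_mcs
#' @param object An `mcs_result`.
#' @export
autoplot.mcs_result <- function(object, ...) {
  autoplot(object$test_curve) +
    ggplot2::labs(subtitle = sprintf("test split, alpha* (train) = %.2f",
                                     object$alpha$alpha))
}
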