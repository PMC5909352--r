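#' Train the morphological-channel decision tree
#'
#' An axis-aligned binary tree grown by information-gain splits on numeric
#' thresholds (candidates are midpoints between sorted distinct values).
#' Growth stops at pure nodes, at nodes smaller than `min_leaf`, or when no
#' split has positive gain. Leaf class probabilities are Laplace-smoothed
#' frequencies `(count + 1) / (n + 2)`. With `pruned = FALSE` (the default
#' used throughout) the tree is left unpruned; with `pruned = TRUE` a
#' C4.5-style pessimistic subtree-replacement pruning is applied using
#' `confidence_factor` as the upper binomial confidence level.
#'
#' @param table Data frame with numeric feature columns and a `label`
#'   column (benign/malignant), one row per lesion.
#' @param features Feature columns to use (default: all non-label columns).
#' @param confidence_factor Pruning confidence (default 0.25; inert when
#'   unpruned).
#' @param pruned Apply pruning (default FALSE).
#' @param min_leaf Smallest node size eligible for splitting (default 2).
#' @return An object of class `mcs_tree`.
#' @export
train_tree <- function(table, features = NULL, confidence_factor = 0.25,
                       pruned = FALSE, min_leaf = 2L) {
  if (confidence_factor <= 0 || confidence_factor >= 1) {
    stopf("confidence_factor must be in (0, 1)")
  }
  features <- features %||% sort(setdiff(names(table), "label"))
  check_labels(table$label)
  if (length(unique(table$label)) < 2L) stopf("need >= 2 instances per class")
  y <- table$label
  X <- as.data.frame(table[, features, drop = FALSE])
  root <- grow_tree(X, y, features, min_leaf)
  if (pruned) root <- prune_tree(root, confidence_factor)
  structure(list(root = root, features = features,
                 confidence_factor = confidence_factor, pruned = pruned,
                 min_leaf = min_leaf, n = nrow(X)),
            class = "mcs_tree")
}

entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

class_counts <- function(y) {
  c(benign = sum(y == "benign"), malignant = sum(y == "malignant"))
}

make_leaf <- function(y) {
  n <- length(y)
  n_m <- sum(y == "malignant")
  list(type = "leaf", n = n, n_malignant = n_m,
       p_malignant = (n_m + 1) / (n + 2))
}

grow_tree <- function(X, y, features, min_leaf) {
  n <- length(y)
  counts <- class_counts(y)
  if (any(counts == 0L) || n < min_leaf) return(make_leaf(y))
  h <- entropy(counts)
  best <- NULL
  for (f in features) {  # features pre-sorted: lexicographic tie-break
    v <- X[[f]]
    sv <- sort(unique(v))
    if (length(sv) < 2L) next
    thresholds <- (sv[-1] + sv[-length(sv)]) / 2
    for (thr in thresholds) {
      left <- v <= thr
      nl <- sum(left)
      gain <- h - (nl / n) * entropy(class_counts(y[left])) -
        ((n - nl) / n) * entropy(class_counts(y[!left]))
      if (is.null(best) || gain > best$gain + 1e-12) {
        best <- list(feature = f, threshold = thr, gain = gain)
      }
    }
  }
  if (is.null(best) || best$gain <= 1e-12) return(make_leaf(y))
  left <- X[[best$feature]] <= best$threshold
  list(type = "split", feature = best$feature, threshold = best$threshold,
       n = n, n_malignant = counts[["malignant"]],
       left = grow_tree(X[left, , drop = FALSE], y[left], features, min_leaf),
       right = grow_tree(X[!left, , drop = FALSE], y[!left], features, min_leaf))
}

# C4.5-style pessimistic error: upper confidence bound on the error rate of
# a node misclassifying e of n at confidence cf (Clopper-Pearson upper).
pessimistic_errors <- function(e, n, cf) {
  n * stats::qbeta(1 - cf, e + 1, pmax(n - e, 0))
}

prune_tree <- function(node, cf) {
  if (node$type == "leaf") return(node)
  node$left <- prune_tree(node$left, cf)
  node$right <- prune_tree(node$right, cf)
  subtree_err <- function(nd) {
    if (nd$type == "leaf") {
      e <- min(nd$n_malignant, nd$n - nd$n_malignant)
      return(pessimistic_errors(e, nd$n, cf))
    }
    subtree_err(nd$left) + subtree_err(nd$right)
  }
  e_here <- min(node$n_malignant, node$n - node$n_malignant)
  if (pessimistic_errors(e_here, node$n, cf) <= subtree_err(node)) {
    return(list(type = "leaf", n = node$n, n_malignant = node$n_malignant,
                p_malignant = (node$n_malignant + 1) / (node$n + 2)))
  }
  node
}

#' Train the dynamic-channel Gaussian naive-Bayes classifier
#'
#' Class priors are empirical frequencies; class-conditional densities are
#' independent Gaussians with per-class mean and (sample) variance, floored
#' at `var_floor`; posteriors are computed by Bayes' rule in log space.
#' `kernel_estimator` is accepted for interface completeness and must be
#' FALSE (parametric Gaussian conditionals).
#'
#' @param table Data frame with numeric feature columns and a `label`
#'   column, one row per instance (for the dynamic channel: per voxel, each
#'   voxel inheriting its lesion's label).
#' @param features Feature columns to use (default: all non-label columns).
#' @param kernel_estimator Must be FALSE.
#' @param var_floor Variance floor (default 1e-9).
#' @return An object of class `mcs_nb`.
#' @export
train_nb <- function(table, features = NULL, kernel_estimator = FALSE,
                     var_floor = 1e-9) {
  if (isTRUE(kernel_estimator)) {
    stopf("kernel density conditionals are not implemented (kernel_estimator must be FALSE)")
  }
  features <- features %||% sort(setdiff(names(table), "label"))
  check_labels(table$label)
  if (length(unique(table$label)) < 2L) stopf("need >= 2 instances per class")
  classes <- c("benign", "malignant")
  stats_by_class <- lapply(classes, function(cl) {
    sub <- table[table$label == cl, features, drop = FALSE]
    v <- vapply(sub, stats::var, numeric(1))
    v[is.na(v)] <- 0  # single-instance class: no spread information
    list(
      prior = nrow(sub) / nrow(table),
      mean = vapply(sub, mean, numeric(1)),
      var = pmax(v, var_floor)
    )
  })
  names(stats_by_class) <- classes
  structure(list(classes = classes, features = features,
                 stats = stats_by_class, n = nrow(table)),
            class = "mcs_nb")
}

check_query <- function(x, features) {
  x <- as.data.frame(x)
  missing <- setdiff(features, names(x))
  if (length(missing)) {
    stopf("query is missing model feature(s): %s", paste(missing, collapse = ", "))
  }
  x[, features, drop = FALSE]
}

#' Class probabilities from a trained channel model
#'
#' Deterministic probability pair(s) `(p_malignant, p_benign)` summing to 1.
#'
#' @param model An `mcs_tree` or `mcs_nb`.
#' @param x A data frame (or coercible) of query rows holding all model
#'   features.
#' @return Tibble with one row per query: `p_malignant`, `p_benign`.
#' @export
predict_proba <- function(model, x) UseMethod("predict_proba")

#' @export
predict_proba.mcs_tree <- function(model, x) {
  x <- check_query(x, model$features)
  p <- vapply(seq_len(nrow(x)), function(i) {
    node <- model$root
    while (node$type == "split") {
      node <- if (x[[node$feature]][i] <= node$threshold) node$left else node$right
    }
    node$p_malignant
  }, numeric(1))
  tibble::tibble(p_malignant = p, p_benign = 1 - p)
}

#' @export
predict_proba.mcs_nb <- function(model, x) {
  x <- check_query(x, model$features)
  n <- nrow(x)
  loglik <- vapply(model$classes, function(cl) {
    st <- model$stats[[cl]]
    ll <- rep(log(st$prior), n)
    for (f in model$features) {
      ll <- ll + stats::dnorm(x[[f]], st$mean[[f]], sqrt(st$var[[f]]), log = TRUE)
    }
    ll
  }, numeric(n))
  loglik <- matrix(loglik, nrow = n)
  m <- apply(loglik, 1, max)
  post <- exp(loglik - m)
  post <- post / rowSums(post)
  tibble::tibble(p_malignant = post[, 2], p_benign = post[, 1])
}

#' Lesion-level dynamic probabilities from voxel votes
#'
#' Every suspicious voxel of the lesion is hard-labelled by its maximum
#' naive-Bayes posterior (ties to malignant), and the lesion-level dynamic
#' probabilities are the vote fractions `D_m = n_m / N`, `D_b = n_b / N`
#' over the `N` voxels.
#'
#' @param dyn Per-voxel dynamic feature tibble ([dyn_feature_vector()]).
#' @param model A trained `mcs_nb` on the same features.
#' @return Tibble row: `D_m`, `D_b`, `n_voxels`.
#' @export
voxel_dynamic_probabilities <- function(dyn, model) {
  if (nrow(dyn) == 0L) stopf("no voxels to classify")
  p <- predict_proba(model, dyn)
  n_m <- sum(p$p_malignant >= p$p_benign)  # tie -> malignant
  n <- nrow(dyn)
  tibble::tibble(D_m = n_m / n, D_b = (n - n_m) / n, n_voxels = n)
}

#' Stratified k-fold cross-validated accuracy
#'
#' Shuffles within class (seeded), deals instances round-robin into folds,
#' and returns the mean held-out accuracy. If some training fold lacks a
#' class the refold is retried with a fresh seed (max 5 attempts).
#'
#' @param table Feature table with `label`.
#' @param kind `"tree"` or `"nb"`.
#' @param features Feature columns (default all non-label).
#' @param folds Fold count (default 10; reduced to `n` if `n < folds`).
#' @param seed Integer seed for the shuffling.
#' @param ... Passed to the trainer.
#' @return List: `accuracy` (mean over folds), `per_fold`.
#' @export
cross_validate <- function(table, kind = c("tree", "nb"), features = NULL,
                           folds = 10L, seed = 1, ...) {
  kind <- match.arg(kind)
  n <- nrow(table)
  if (n < folds) stopf("need n >= folds")
  trainer <- switch(kind, tree = train_tree, nb = train_nb)
  for (attempt in 0:5) {
    fold_id <- with_seed(seed + attempt, {
      id <- integer(n)
      for (cl in unique(table$label)) {
        idx <- sample(which(table$label == cl))
        id[idx] <- rep_len(seq_len(folds), length(idx))
      }
      id
    })
    ok <- all(vapply(seq_len(folds), function(k) {
      length(unique(table$label[fold_id != k])) == 2L
    }, logical(1)))
    if (ok) break
    if (attempt == 5L) stopf("could not form folds with both classes in every training set")
  }
  per_fold <- vapply(seq_len(folds), function(k) {
    tr <- table[fold_id != k, , drop = FALSE]
    te <- table[fold_id == k, , drop = FALSE]
    if (nrow(te) == 0L) return(NA_real_)
    model <- trainer(tr, features = features, ...)
    p <- predict_proba(model, te)
    pred <- ifelse(p$p_malignant >= p$p_benign, "malignant", "benign")
    mean(pred == te$label)
  }, numeric(1))
  list(accuracy = mean(per_fold, na.rm = TRUE), per_fold = per_fold)
}

#' @rdname train_tree
#' @param x An `mcs_tree`.
#' @param ... Unused.
#' @export
tidy.mcs_tree <- function(x, ...) {
  rows <- list()
  walk <- function(nd, depth, path) {
    if (nd$type == "leaf") {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        node = path, depth = depth, type = "leaf", feature = NA_character_,
        threshold = NA_real_, n = nd[["n"]], p_malignant = nd$p_malignant)
    } else {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        node = path, depth = depth, type = "split", feature = nd$feature,
        threshold = nd$threshold, n = nd[["n"]], p_malignant = NA_real_)
      walk(nd$left, depth + 1L, paste0(path, "L"))
      walk(nd$right, depth + 1L, paste0(path, "R"))
    }
  }
  walk(x$root, 0L, "*")
  dplyr::bind_rows(rows)
}

#' @rdname train_tree
#' @export
glance.mcs_tree <- function(x, ...) {
  nodes <- tidy(x)
  tibble::tibble(n = x$n, n_leaves = sum(nodes$type == "leaf"),
                 depth = max(nodes$depth), pruned = x$pruned)
}

#' @rdname train_nb
#' @param x An `mcs_nb`.
#' @param ... Unused.
#' @export
tidy.mcs_nb <- function(x, ...) {
  purrr::map_dfr(x$classes, function(cl) {
    st <- x$stats[[cl]]
    tibble::tibble(class = cl, feature = x$features,
                   mean = unname(st$mean[x$features]),
                   sd = sqrt(unname(st$var[x$features])), prior = st$prior)
  })
}

#' @rdname train_nb
#' @export
glance.mcs_nb <- function(x, ...) {
  tibble::tibble(n = x$n, n_features = length(x$features),
                 prior_malignant = x$stats$malignant$prior)
}

#' @export
print.mcs_tree <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<mcs_tree> %d leaves, depth %d, trained on %d lesions%s\n",
              g$n_leaves, g$depth, g$n, if (x$pruned) " (pruned)" else ""))
  invisible(x)
}

#' @export
print.mcs_nb <- function(x, ...) {
  cat(sprintf("<mcs_nb> Gaussian naive Bayes on %s (n = %d)\n",
              paste(x$features, collapse = ", "), x$n))
  invisible(x)
}
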