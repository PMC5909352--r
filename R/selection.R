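#' Correlation-based feature selection (CFS) merit of a subset
#'
#' `merit = k * r_cf / sqrt(k + k (k - 1) * r_ff)` where `r_cf` is the mean
#' absolute Pearson correlation of each subset feature with the 0/1-coded
#' label (benign = 0, malignant = 1) and `r_ff` the mean absolute pairwise
#' correlation within the subset (`0` for singletons). High merit means
#' label-relevant and mutually non-redundant features.
#'
#' @param subset Character vector of feature names (non-empty).
#' @param table Data frame with numeric feature columns and a `label`
#'   column of benign/malignant.
#' @return The merit (scalar).
#' @export
cfs_merit <- function(subset, table) {
  if (length(subset) == 0L) stopf("subset must be non-empty")
  y <- as.numeric(table$label == "malignant")
  keep <- vapply(subset, function(f) {
    v <- stats::var(table[[f]])
    if (!is.finite(v) || v == 0) {
      warn(sprintf("excluding zero-variance feature '%s' from CFS merit", f))
      FALSE
    } else TRUE
  }, logical(1))
  subset <- subset[keep]
  if (length(subset) == 0L) return(0)
  k <- length(subset)
  r_cf <- mean(vapply(subset, function(f) abs(stats::cor(table[[f]], y)),
                      numeric(1)))
  r_ff <- if (k == 1L) 0 else {
    pairs <- utils::combn(subset, 2)
    mean(vapply(seq_len(ncol(pairs)), function(j) {
      abs(stats::cor(table[[pairs[1, j]]], table[[pairs[2, j]]]))
    }, numeric(1)))
  }
  k * r_cf / sqrt(k + k * (k - 1) * r_ff)
}

#' Consistency score of a feature subset
#'
#' Each feature is discretised into `bins` equal-width bins over its range;
#' instances are grouped by their discretised pattern; the inconsistency is
#' the number of instances not in their pattern's majority class. Returns
#' `1 - inconsistency / n`, i.e. 1 when every pattern is class-pure.
#'
#' @inheritParams cfs_merit
#' @param bins Equal-width bin count per feature (default 10).
#' @return Score in `[0, 1]`.
#' @export
consistency_score <- function(subset, table, bins = 10L) {
  if (length(subset) == 0L) stopf("subset must be non-empty")
  n <- nrow(table)
  if (n <= 1L) return(1)
  disc <- vapply(subset, function(f) {
    v <- table[[f]]
    rng <- range(v)
    if (rng[1] == rng[2]) return(rep(1L, n))
    edges <- seq(rng[1], rng[2], length.out = bins + 1L)
    findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  }, integer(n))
  pattern <- apply(matrix(disc, nrow = n), 1, paste, collapse = "|")
  inconsistent <- sum(vapply(split(table$label, pattern), function(lab) {
    length(lab) - max(tabulate(factor(lab, c("benign", "malignant"))))
  }, numeric(1)))
  1 - inconsistent / n
}

subset_key <- function(s) paste(sort(s), collapse = "|")

# Score a subset under either selection method.
subset_score <- function(subset, table, method, bins) {
  if (length(subset) == 0L) return(-Inf)
  switch(method,
         cfs = cfs_merit(subset, table),
         consistency = consistency_score(subset, table, bins))
}

#' Select a feature subset
#'
#' Subset selection with two scoring methods (CFS merit, consistency) and
#' five search strategies. `forward`, `backward` and `bidirectional` are
#' best-first searches (expand the best-scoring open subset by adding,
#' removing, or both; stop after `stall_limit` consecutive expansions that
#' fail to improve the best score). `greedy` is pure hill climbing from the
#' empty set, stopping at the first non-improving step. `ranking` orders
#' features by their singleton score and cuts at the largest consecutive
#' score drop, or at `cap` features, whichever comes first. All searches are
#' deterministic: ties are broken by lexicographic feature-name order.
#'
#' @inheritParams cfs_merit
#' @param method `"cfs"` or `"consistency"`.
#' @param search `"forward"`, `"backward"`, `"bidirectional"`, `"greedy"`
#'   or `"ranking"`.
#' @param cap Maximum subset size for the ranking cut (default 10).
#' @param bins Discretisation bins for the consistency score.
#' @param stall_limit Best-first patience (default 5).
#' @return A `selection_result`: list with `method`, `search`, `selected`
#'   (feature names, sorted), `score`, and the per-candidate trace.
#' @export
select_features <- function(table, method = c("cfs", "consistency"),
                            search = c("forward", "backward", "bidirectional",
                                       "greedy", "ranking"),
                            cap = 10L, bins = 10L, stall_limit = 5L) {
  method <- match.arg(method)
  search <- match.arg(search)
  feats <- sort(setdiff(names(table), "label"))
  if (length(feats) == 0L) stopf("table has no feature columns")
  score <- function(s) subset_score(s, table, method, bins)

  result <- if (search == "ranking") {
    single <- vapply(feats, function(f) score(f), numeric(1))
    ord <- order(-single, feats)
    sc <- single[ord]
    cut <- if (length(sc) > 1L) {
      drops <- sc[-length(sc)] - sc[-1]
      if (max(drops) > 0) which.max(drops) else length(sc)
    } else 1L
    cut <- min(cut, cap)
    sel <- feats[ord][seq_len(cut)]
    list(selected = sel, score = score(sel))
  } else if (search == "greedy") {
    current <- character(0)
    best <- -Inf
    repeat {
      cand <- setdiff(feats, current)
      if (length(cand) == 0L) break
      scores <- vapply(cand, function(f) score(c(current, f)), numeric(1))
      ord <- order(-scores, cand)
      if (scores[ord[1]] > best) {
        best <- scores[ord[1]]
        current <- c(current, cand[ord[1]])
      } else break
    }
    list(selected = current, score = best)
  } else {
    best_first_search(feats, score, direction = search, stall_limit = stall_limit)
  }

  if (length(result$selected) == 0L) {
    # degenerate (e.g. all features uninformative): fall back to best singleton
    single <- vapply(feats, function(f) score(f), numeric(1))
    result$selected <- feats[order(-single, feats)][1]
    result$score <- max(single)
  }
  structure(list(method = method, search = search,
                 selected = sort(result$selected), score = result$score),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s / %s search\n", x$method, x$search))
  cat(sprintf("  selected: %s (score %.4f)\n",
              paste(x$selected, collapse = ", "), x$score))
  invisible(x)
}

#' @rdname select_features
#' @param x A `selection_result`.
#' @param ... Unused.
#' @export
tidy.selection_result <- function(x, ...) {
  tibble::tibble(method = x$method, search = x$search,
                 feature = x$selected, score = x$score)
}

best_first_search <- function(feats, score, direction, stall_limit) {
  start <- switch(direction, forward = character(0), backward = feats,
                  bidirectional = character(0))
  open <- list()
  push <- function(open, s, sc) {
    open[[subset_key(s)]] <- list(subset = s, score = sc)
    open
  }
  start_score <- if (length(start)) score(start) else -Inf
  open <- push(open, start, start_score)
  closed <- character(0)
  best <- list(subset = start, score = start_score)
  stall <- 0L
  while (length(open) > 0L && stall < stall_limit) {
    scores <- vapply(open, `[[`, numeric(1), "score")
    keys <- names(open)
    pick <- keys[order(-scores, keys)][1]
    node <- open[[pick]]
    open[[pick]] <- NULL
    closed <- c(closed, pick)
    succ <- list()
    if (direction %in% c("forward", "bidirectional")) {
      for (f in setdiff(feats, node$subset)) succ <- c(succ, list(c(node$subset, f)))
    }
    if (direction %in% c("backward", "bidirectional")) {
      for (f in node$subset) succ <- c(succ, list(setdiff(node$subset, f)))
    }
    improved <- FALSE
    for (s in succ) {
      if (length(s) == 0L) next
      key <- subset_key(s)
      if (key %in% closed || !is.null(open[[key]])) next
      sc <- score(s)
      open <- push(open, s, sc)
      if (sc > best$score + 1e-12) {
        best <- list(subset = s, score = sc)
        improved <- TRUE
      }
    }
    stall <- if (improved) 0L else stall + 1L
  }
  list(selected = best$subset, score = best$score)
}
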