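#' Fuse the dynamic and morphological channel probabilities
#'
#' The weighted-probability ensemble rule: with `beta = 1 - alpha`, a lesion
#' is called malignant iff `alpha * D_m + beta * M_m > alpha * D_b +
#' beta * M_b`; exact ties resolve to malignant (favouring sensitivity in a
#' screening context). `alpha = 1` is the dynamic channel alone, `alpha = 0`
#' the morphological channel alone.
#'
#' @param D_m,D_b Dynamic-channel (voxel-vote) probabilities; `D_b`
#'   defaults to `1 - D_m`. Vectorised over lesions.
#' @param M_m,M_b Morphological-channel probabilities; `M_b` defaults to
#'   `1 - M_m`.
#' @param alpha Dynamic-channel weight in `[0, 1]`.
#' @return Tibble with one row per lesion: the inputs, `alpha`, `beta`,
#'   `score_m`, `score_b` and `predicted`.
#' @export
fuse <- function(D_m, M_m, alpha, D_b = 1 - D_m, M_b = 1 - M_m) {
  if (length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stopf("alpha must be a single value in [0, 1]")
  }
  beta <- 1 - alpha
  score_m <- alpha * D_m + beta * M_m
  score_b <- alpha * D_b + beta * M_b
  tibble::tibble(
    D_m = D_m, D_b = D_b, M_m = M_m, M_b = M_b,
    alpha = alpha, beta = beta, score_m = score_m, score_b = score_b,
    # tolerance keeps exact ties (score_m = score_b up to rounding) malignant
    predicted = ifelse(score_m >= score_b - 1e-12, "malignant", "benign")
  )
}

#' Choose the fusion coefficient alpha by accuracy maximisation
#'
#' Evaluates leave-one-out accuracy of the fused decision on an alpha grid
#' over `[0, 1]` (each lesion's channel probabilities are fixed; with a
#' fixed alpha the held-out decision does not depend on the other lesions,
#' so the LOO estimate equals the plain accuracy). The selected `alpha*` is
#' the midpoint of the widest contiguous run of grid points attaining the
#' maximal accuracy (first such run if several tie), which turns a
#' high-performance plateau into a single stable coefficient.
#'
#' @param lesions Tibble with columns `D_m`, `M_m` and `label`
#'   (benign/malignant), one row per lesion.
#' @param step Grid step (default 0.05).
#' @return An `alpha_selection`: list with `alpha`, `accuracy` (at
#'   `alpha*`), `curve` (tibble `alpha`, `accuracy`) and `n_breakpoints`
#'   (number of value changes along the grid).
#' @export
select_alpha <- function(lesions, step = 0.05) {
  check_labels(lesions$label)
  if (length(unique(lesions$label)) < 2L) {
    stopf("need lesions of both classes to select alpha")
  }
  alphas <- seq(0, 1, by = step)
  acc <- vapply(alphas, function(a) {
    mean(fuse(lesions$D_m, lesions$M_m, a)$predicted == lesions$label)
  }, numeric(1))
  is_max <- abs(acc - max(acc)) < 1e-12
  runs <- rle(is_max)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  widest <- which(runs$values)[which.max(runs$lengths[runs$values])]
  a_star <- (alphas[starts[widest]] + alphas[ends[widest]]) / 2
  structure(list(alpha = a_star, accuracy = max(acc),
                 curve = tibble::tibble(alpha = alphas, accuracy = acc),
                 n_breakpoints = sum(diff(acc) != 0)),
            class = "alpha_selection")
}

#' @export
print.alpha_selection <- function(x, ...) {
  cat(sprintf("<alpha_selection> alpha* = %.3f (accuracy %.3f, %d breakpoints)\n",
              x$alpha, x$accuracy, x$n_breakpoints))
  invisible(x)
}

#' @rdname select_alpha
#' @param object An `alpha_selection`.
#' @param ... Unused.
#' @export
autoplot.alpha_selection <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$alpha,
                                             y = 100 * .data$accuracy)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$alpha, linetype = "dashed") +
    ggplot2::labs(x = expression(alpha),
                  y = "Correctly classified lesions (%)",
                  title = "Fused accuracy vs dynamic-channel weight") +
    ggplot2::theme_minimal()
}

#' @rdname select_alpha
#' @param x An `alpha_selection`.
#' @export
tidy.alpha_selection <- function(x, ...) x$curve

#' @rdname select_alpha
#' @export
glance.alpha_selection <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, accuracy = x$accuracy,
                 n_breakpoints = x$n_breakpoints)
}
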