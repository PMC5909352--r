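#' @importFrom rlang abort warn .data
#' @importFrom stats var sd cor median pbinom pchisq setNames
#' @importFrom utils head tail
NULL

# Run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards. All package randomness funnels through this so
# cohorts are reproducible and extensible (per-lesion substreams).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Half-up rounding to `digits` decimals (base round() is half-even; the
# display convention for the metric tables is half-up).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopf <- function(...) abort(sprintf(...))

`%||%` <- function(a, b) if (is.null(a)) b else a

is_label <- function(x) all(x %in% c("benign", "malignant"))

check_labels <- function(x, arg = "labels") {
  if (!is_label(x)) {
    stopf("%s must be 'benign' or 'malignant' (got: %s)", arg,
          paste(unique(setdiff(x, c("benign", "malignant"))), collapse = ", "))
  }
  invisible(x)
}
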