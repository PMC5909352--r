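# Small binary-morphology toolkit on logical 3D arrays. Grids in this
# pipeline are modest (a breast volume at dynamic resolution), so shifted-
# array composition is fast enough and keeps the operator definitions
# transparent.

# Shift a logical array by integer offset `s`; `pad` is the value assumed
# outside the grid.
shift_mask <- function(m, s, pad = FALSE) {
  d <- dim(m)
  out <- array(pad, d)
  src <- dst <- vector("list", length(d))
  for (j in seq_along(d)) {
    if (s[j] >= 0) {
      if (s[j] >= d[j]) return(out)
      src[[j]] <- 1:(d[j] - s[j]); dst[[j]] <- (1 + s[j]):d[j]
    } else {
      if (-s[j] >= d[j]) return(out)
      src[[j]] <- (1 - s[j]):d[j]; dst[[j]] <- 1:(d[j] + s[j])
    }
  }
  do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(m), src)))))
}

# Integer offsets of a discrete ball of radius r (voxel units), 3D.
ball_offsets <- function(r) {
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  as.matrix(g[g$x^2 + g$y^2 + g$z^2 <= r^2, , drop = FALSE])
}

offsets_2d <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
offsets_6 <- c(offsets_2d, list(c(0, 0, 1), c(0, 0, -1)))
offsets_26 <- local({
  g <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  g <- g[!(g$x == 0 & g$y == 0 & g$z == 0), ]
  lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
})

dilate_mask <- function(m, offsets) {
  out <- m
  for (i in seq_len(nrow(offsets))) out <- out | shift_mask(m, offsets[i, ])
  out
}

# `pad = TRUE` treats out-of-grid as foreground, so structures touching the
# image border are only eroded at their real (in-image) boundary.
erode_mask <- function(m, offsets, pad = FALSE) {
  out <- m
  for (i in seq_len(nrow(offsets))) out <- out & shift_mask(m, -offsets[i, ], pad)
  out
}

# Closing erodes with border padding so it is extensive (never removes
# foreground) even for structures touching the image border.
close_mask <- function(m, offsets) {
  erode_mask(dilate_mask(m, offsets), offsets, pad = TRUE)
}

# Flood the background from the grid border through the given neighbourhood;
# anything in `background` not reached is a hole.
flood_from_border <- function(background, neighb) {
  d <- dim(background)
  seed <- array(FALSE, d)
  seed[1, , ] <- TRUE; seed[d[1], , ] <- TRUE
  seed[, 1, ] <- TRUE; seed[, d[2], ] <- TRUE
  if (length(d) == 3 && !all(vapply(neighb, function(o) o[3] == 0, logical(1)))) {
    seed[, , 1] <- TRUE; seed[, , d[3]] <- TRUE
  }
  seed <- seed & background
  repeat {
    grown <- seed
    for (o in neighb) grown <- grown | shift_mask(seed, o)
    grown <- grown & background
    if (identical(grown, seed)) return(seed)
    seed <- grown
  }
}

# Fill interior holes: slice-wise in 2D (4-connectivity) first, then in full
# 3D (6-connectivity). The 2D pass closes tunnels that are holes per slice
# but open along z; the 3D pass fills genuinely enclosed cavities.
fill_holes <- function(m) {
  d <- dim(m)
  for (z in seq_len(d[3])) {
    sl <- array(m[, , z], dim = c(d[1], d[2], 1))
    reach <- flood_from_border(!sl, offsets_2d)
    m[, , z] <- sl | (!sl & !reach)
  }
  reach <- flood_from_border(!m, offsets_6)
  m | (!m & !reach)
}

#' Label connected components of a 3D binary mask (26-connectivity)
#'
#' @param mask Logical 3D array.
#' @return Integer array of the same shape: 0 outside the mask, components
#'   numbered 1, 2, ... (arbitrary order; use [extract_vois()] for
#'   largest-first VOIs).
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(Inf, d)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    new <- lab
    for (o in offsets_26) {
      sh <- shift_label(lab, o, d)
      new <- pmin(new, sh)
    }
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- array(0L, d)
  ids <- sort(unique(lab[mask]))
  out[mask] <- match(lab[mask], ids)
  out
}

# Shift a numeric label array, padding with Inf (neutral for pmin).
shift_label <- function(lab, s, d) {
  out <- array(Inf, d)
  src <- dst <- vector("list", 3)
  for (j in 1:3) {
    if (s[j] >= 0) {
      if (s[j] >= d[j]) return(out)
      src[[j]] <- 1:(d[j] - s[j]); dst[[j]] <- (1 + s[j]):d[j]
    } else {
      if (-s[j] >= d[j]) return(out)
      src[[j]] <- (1 - s[j]):d[j]; dst[[j]] <- 1:(d[j] + s[j])
    }
  }
  do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(lab), src)))))
}

# Boundary voxels of a 3D mask under 6-connectivity; out-of-grid is background.
boundary_mask_3d <- function(m) {
  interior <- m
  for (o in offsets_6) interior <- interior & shift_mask(m, o)
  m & !interior
}

# Boundary voxels of a 2D slice (stored as nx x ny matrix), 4-connectivity.
boundary_mask_2d <- function(sl) {
  m <- array(sl, dim = c(dim(sl), 1))
  interior <- m
  for (o in offsets_2d) interior <- interior & shift_mask(m, o)
  (m & !interior)[, , 1]
}
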