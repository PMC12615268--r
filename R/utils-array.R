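# Internal array helpers shared across modules.
#
# All volumes use canonical axis order (z, y, x): axis 1 = z, axis 2 = y,
# axis 3 = x. A voxel is the unit cube at its 0-based integer index.

# Symmetric (reflect) boundary index: ... c b a | a b c ... | c b a
# `i` may be any integer (1-based); returns an index in 1..n.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# Take a slab of `x` along `axis` using index vector `idx` (same length as
# the axis). Works for 2D and 3D arrays without dropping dimensions.
index_axis <- function(x, axis, idx) {
  d <- dim(x)
  if (length(d) == 2L) {
    if (axis == 1L) x[idx, , drop = FALSE] else x[, idx, drop = FALSE]
  } else {
    switch(axis,
      x[idx, , , drop = FALSE],
      x[, idx, , drop = FALSE],
      x[, , idx, drop = FALSE])
  }
}

# 1D correlation along one axis with reflect boundary handling.
filter_axis <- function(x, axis, kernel) {
  n <- dim(x)[axis]
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim(x))
  for (k in seq_along(kernel)) {
    off <- k - r - 1L
    idx <- reflect_index(seq_len(n) + off, n)
    out <- out + kernel[k] * index_axis(x, axis, idx)
  }
  out
}

# Separable filter: same 1D kernel applied along every axis.
separable_filter <- function(x, kernel) {
  for (axis in seq_along(dim(x))) x <- filter_axis(x, axis, kernel)
  x
}

gaussian_kernel1d <- function(sigma, truncate = 4) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  k <- exp(-0.5 * (seq(-r, r) / sigma)^2)
  k / sum(k)
}

# Gaussian smoothing of a 2D or 3D array (sigma in voxels, isotropic).
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  separable_filter(x, gaussian_kernel1d(sigma))
}

# Uniform (box) mean over a P^d window, reflect edges. P odd.
box_mean <- function(x, P) {
  if (P <= 1L) return(x)
  separable_filter(x, rep(1 / P, P))
}

# Local population standard deviation over a P^d window.
local_sd <- function(x, P) {
  if (P <= 1L) return(array(0, dim(x)))
  m <- box_mean(x, P)
  m2 <- box_mean(x * x, P)
  sqrt(pmax(m2 - m * m, 0))
}

# Finite central differences along `axis` (spacing 1), one-sided at edges.
central_diff <- function(x, axis) {
  n <- dim(x)[axis]
  fwd <- index_axis(x, axis, pmin(seq_len(n) + 1L, n))
  bwd <- index_axis(x, axis, pmax(seq_len(n) - 1L, 1L))
  denom <- rep(2, n)
  denom[c(1L, n)] <- 1
  d <- fwd - bwd
  sweep_axis(d, axis, 1 / denom, `*`)
}

# Central differences restricted to a validity mask: one-sided where only
# one neighbour is valid, zero where neither is.
masked_diff <- function(x, valid, axis) {
  n <- dim(x)[axis]
  idx_f <- pmin(seq_len(n) + 1L, n)
  idx_b <- pmax(seq_len(n) - 1L, 1L)
  xf <- index_axis(x, axis, idx_f); xb <- index_axis(x, axis, idx_b)
  vf <- index_axis(valid, axis, idx_f); vb <- index_axis(valid, axis, idx_b)
  # at the array edge the "neighbour" is the pixel itself: not usable
  edge_f <- sweep_axis(array(0, dim(x)), axis, as.numeric(idx_f == seq_len(n)), `+`) > 0
  edge_b <- sweep_axis(array(0, dim(x)), axis, as.numeric(idx_b == seq_len(n)), `+`) > 0
  vf <- vf & !edge_f; vb <- vb & !edge_b
  out <- array(0, dim(x))
  both <- vf & vb
  out[both] <- (xf[both] - xb[both]) / 2
  fo <- vf & !vb; out[fo] <- xf[fo] - x[fo]
  bo <- vb & !vf; out[bo] <- x[bo] - xb[bo]
  out
}

# sweep() that broadcasts a per-index vector along one axis of a 2D/3D array.
sweep_axis <- function(x, axis, v, op) {
  d <- dim(x)
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x, perm)
  xp <- op(xp, v)   # recycles along first axis
  aperm(xp, order(perm))
}

# Bounding box (list of index ranges) of non-zero entries, padded.
bounding_box <- function(mask, pad = 0L) {
  d <- dim(mask)
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  lapply(seq_along(d), function(a) {
    lo <- max(1L, min(idx[, a]) - pad)
    hi <- min(d[a], max(idx[, a]) + pad)
    lo:hi
  })
}

crop_box <- function(x, box) {
  if (length(box) == 2L) x[box[[1]], box[[2]], drop = FALSE]
  else x[box[[1]], box[[2]], box[[3]], drop = FALSE]
}

`paste_box<-` <- function(x, box, value) {
  if (length(box) == 2L) x[box[[1]], box[[2]]] <- value
  else x[box[[1]], box[[2]], box[[3]]] <- value
  x
}

# Connected components of the non-zero voxels of a 2D/3D array.
# Adjacent voxels join only when they carry the same input value.
label_components <- function(x, connectivity = if (length(dim(x)) == 2L) 8L else 26L) {
  storage.mode(x) <- "integer"
  .cc_label(x, as.integer(connectivity))
}
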