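# 2D distance transforms and their unit gradient fields.
#
# Transform kinds: "edt" and "poisson" erode to the implicit medial-axis
# attractor; "poisson_point"/"geodesic_point" attract to a single interior
# point; "poisson_skeleton"/"geodesic_skeleton" attract to the 2D
# medial-axis skeleton. All fields are stored pointing TOWARD the
# attractor and unit-normalised, so descent code is sign-free.

TRANSFORM_KINDS <- c("edt", "poisson", "poisson_point", "poisson_skeleton",
                     "geodesic_point", "geodesic_skeleton")

#' 2D Euclidean distance transform of a binary mask
#'
#' Per-pixel Euclidean distance to the nearest background pixel; the image
#' border counts as background (the mask is evaluated inside a zero ring).
#'
#' @param mask 2D logical/0-1 matrix with at least one foreground pixel.
#' @return Numeric matrix of distances (0 on background).
#' @export
edt2d <- function(mask) {
  m <- mask != 0
  if (!any(m)) stop("empty mask")
  d <- dim(m)
  padded <- matrix(0, d[1] + 2L, d[2] + 2L)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L)] <- m
  dist <- EBImage::distmap(padded, metric = "euclidean")
  as.matrix(dist)[2:(d[1] + 1L), 2:(d[2] + 1L)]
}

# Sparse 5-point Laplacian solve on the foreground pixels of a 2D mask.
# Dirichlet phi = 0 on the first background pixel (and outside the image).
# rhs: per-foreground-pixel right-hand side of -lap(phi) = rhs.
solve_poisson_2d <- function(mask, rhs) {
  idx <- which(mask)
  n <- length(idx)
  node <- matrix(0L, nrow(mask), ncol(mask))
  node[idx] <- seq_len(n)
  ij <- which(mask, arr.ind = TRUE)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  rows <- c(rows, seq_len(n)); cols <- c(cols, seq_len(n)); vals <- c(vals, rep(4, n))
  for (off in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    ni <- ij[, 1] + off[1]; nj <- ij[, 2] + off[2]
    ok <- ni >= 1L & ni <= nrow(mask) & nj >= 1L & nj <= ncol(mask)
    nb <- integer(n)
    nb[ok] <- node[cbind(ni[ok], nj[ok])]
    sel <- nb > 0L
    rows <- c(rows, which(sel)); cols <- c(cols, nb[sel]); vals <- c(vals, rep(-1, sum(sel)))
  }
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
  phi <- as.numeric(Matrix::solve(A, rhs))
  out <- matrix(0, nrow(mask), ncol(mask))
  out[idx] <- phi
  out
}

#' Poisson (diffusion) distance transform of a 2D cell mask
#'
#' Discrete 5-point-stencil solve with Dirichlet `phi = 0` on and outside
#' the boundary ring. The implicit variant (`source = "none"`) solves
#' `lap(phi) = -1` everywhere inside, eroding to the medial axis; the
#' explicit variants solve Laplace's equation with a unit source only on
#' the designated interior point or skeleton set, whose pixels attain the
#' interior maximum. For a point source with `power != 1` the result is
#' `(phi - min(phi))^power`. Masks of 1-2 pixels fall back to the EDT
#' (the explicit systems degenerate).
#'
#' @param mask 2D logical/0-1 matrix.
#' @param source `"none"`, `"point"` or `"skeleton"`.
#' @param src_idx linear indices of source pixels (defaults to
#'   [select_point_source()] / [medial_skeleton2d()]).
#' @param power exponent for the point-source power transform (default 1).
#' @return List: `phi` (matrix), `kind`, `source_idx`.
#' @export
poisson_transform <- function(mask, source = c("none", "point", "skeleton"),
                              src_idx = NULL, power = 1) {
  source <- match.arg(source)
  m <- mask != 0
  if (!any(m)) stop("empty mask")
  kind <- switch(source, none = "poisson", point = "poisson_point",
                 skeleton = "poisson_skeleton")
  if (source == "none") {   # implicit solve is well posed down to 1 pixel
    phi <- solve_poisson_2d(m, rep(1, sum(m)))
    return(list(phi = phi, kind = kind, source_idx = integer(0)))
  }
  if (sum(m) <= 2L) {       # explicit systems degenerate on tiny masks
    return(list(phi = edt2d(m), kind = kind, source_idx = integer(0)))
  }
  if (is.null(src_idx)) {
    src_idx <- if (source == "point") select_point_source(m)
               else which(medial_skeleton2d(m))
  }
  if (any(!m[src_idx])) stop("source pixels lie outside the mask")
  rhs <- numeric(sum(m))
  node <- integer(length(m)); node[which(m)] <- seq_len(sum(m))
  rhs[node[src_idx]] <- 1
  phi <- solve_poisson_2d(m, rhs)
  if (source == "point" && power != 1) {
    pmin_in <- min(phi[m])
    phi[m] <- (phi[m] - pmin_in)^power
  }
  list(phi = phi, kind = kind, source_idx = src_idx)
}

#' Geodesic (Eikonal) distance transform with an explicit source
#'
#' Travel time under unit speed restricted to the mask, computed by
#' multi-source Dijkstra on the 8-neighbour pixel graph with Euclidean edge
#' weights (a first-order approximation to the fast-marching solution; the
#' discretisation error is bounded by the metrication of the 8-neighbour
#' graph). The source set is held at time zero (the attracting extreme)
#' and its gradients are later zeroed to enforce the limiting behaviour.
#'
#' @param mask 2D logical/0-1 matrix.
#' @param source `"point"` or `"skeleton"`.
#' @param src_idx linear indices of source pixels.
#' @return List: `phi` (travel time, attractor at its minimum), `kind`,
#'   `source_idx`.
#' @export
geodesic_transform <- function(mask, source = c("point", "skeleton"),
                               src_idx = NULL) {
  source <- match.arg(source)
  m <- mask != 0
  if (!any(m)) stop("empty mask")
  kind <- if (source == "point") "geodesic_point" else "geodesic_skeleton"
  if (sum(m) <= 2L)
    return(list(phi = edt2d(m), kind = kind, source_idx = integer(0),
                attractor = "max"))
  if (is.null(src_idx)) {
    src_idx <- if (source == "point") select_point_source(m)
               else which(medial_skeleton2d(m))
  }
  if (any(!m[src_idx])) stop("source pixels lie outside the mask")
  mi <- matrix(0L, nrow(m), ncol(m)); mi[m] <- 1L
  phi <- .geodesic_dijkstra(mi, as.integer(src_idx))
  phi[!is.finite(phi)] <- 0   # unreachable mask islands: stationary
  list(phi = phi, kind = kind, source_idx = src_idx, attractor = "min")
}

#' Select an interior point source for explicit transforms
#'
#' Among foreground pixels whose EDT exceeds the `pct`-th percentile of the
#' foreground EDT values, returns the pixel nearest (Euclidean) to the
#' coordinate-wise median of all foreground pixels — an interior point even
#' for crescents whose centroid falls outside the mask.
#'
#' @param mask 2D logical/0-1 matrix.
#' @param pct percentile threshold on EDT (default 10).
#' @return Linear index of the chosen pixel.
#' @export
select_point_source <- function(mask, pct = 10) {
  m <- mask != 0
  if (!any(m)) stop("empty mask")
  ed <- edt2d(m)
  fg <- which(m)
  if (length(fg) == 1L) return(fg)
  thr <- stats::quantile(ed[fg], pct / 100, names = FALSE)
  cand <- fg[ed[fg] > thr]
  if (length(cand) == 0L) {
    message("point source: empty candidate set, falling back to EDT argmax")
    return(fg[which.max(ed[fg])])
  }
  coords <- which(m, arr.ind = TRUE)
  med <- apply(coords, 2, stats::median)
  ccand <- arrayInd(cand, dim(m))
  d2 <- (ccand[, 1] - med[1])^2 + (ccand[, 2] - med[2])^2
  cand[which.min(d2)]
}

# One Zhang-Suen thinning pass (sub = 1 or 2); returns the updated mask.
zs_pass <- function(m, sub) {
  d <- dim(m)
  p <- matrix(0L, d[1] + 2L, d[2] + 2L)
  p[2:(d[1] + 1L), 2:(d[2] + 1L)] <- m
  ctr <- 2:(d[1] + 1L); cc <- 2:(d[2] + 1L)
  P2 <- p[ctr - 1L, cc];      P3 <- p[ctr - 1L, cc + 1L]
  P4 <- p[ctr, cc + 1L];      P5 <- p[ctr + 1L, cc + 1L]
  P6 <- p[ctr + 1L, cc];      P7 <- p[ctr + 1L, cc - 1L]
  P8 <- p[ctr, cc - 1L];      P9 <- p[ctr - 1L, cc - 1L]
  B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
  A <- (P2 == 0L & P3 == 1L) + (P3 == 0L & P4 == 1L) + (P4 == 0L & P5 == 1L) +
       (P5 == 0L & P6 == 1L) + (P6 == 0L & P7 == 1L) + (P7 == 0L & P8 == 1L) +
       (P8 == 0L & P9 == 1L) + (P9 == 0L & P2 == 1L)
  if (sub == 1L) {
    cond <- P2 * P4 * P6 == 0L & P4 * P6 * P8 == 0L
  } else {
    cond <- P2 * P4 * P8 == 0L & P2 * P6 * P8 == 0L
  }
  del <- m == 1L & B >= 2L & B <= 6L & A == 1L & cond
  m[del] <- 0L
  m
}

#' 2D medial-axis skeleton by iterative thinning
#'
#' The mask is Gaussian-smoothed (`sigma_skel`, default 3) and rebinarised
#' by mean-value thresholding to suppress spurious boundary branches, then
#' thinned by iteratively removing border pixels (Zhang-Suen passes) until
#' stable. If smoothing erases the mask, the unsmoothed mask is thinned
#' instead.
#'
#' @param mask 2D logical/0-1 matrix.
#' @param sigma_skel pre-smoothing Gaussian width in pixels.
#' @return Logical matrix: the skeleton (subset of the smoothed mask).
#' @export
medial_skeleton2d <- function(mask, sigma_skel = 3) {
  m <- mask != 0
  if (!any(m)) stop("empty mask")
  base <- m
  if (sigma_skel > 0) {
    sm <- gaussian_smooth(m * 1, sigma_skel)
    smb <- sm > mean(sm)
    if (any(smb)) base <- smb
    else message("skeleton: mask vanished after smoothing, thinning unsmoothed mask")
  }
  mi <- matrix(0L, nrow(m), ncol(m)); mi[base] <- 1L
  repeat {
    before <- mi
    mi <- zs_pass(mi, 1L)
    mi <- zs_pass(mi, 2L)
    if (identical(mi, before)) break
  }
  mi == 1L
}

#' Unit gradient field of a distance map
#'
#' Central first-order differences of `phi`, oriented toward the attractor
#' (ascending `phi` for interior-maximum transforms, descending for
#' source-minimum geodesic transforms), unit-normalised, and zeroed outside
#' the mask, on explicit source pixels, and on flat regions (0/0 guard).
#'
#' @param phi 2D distance map (matrix).
#' @param mask foreground support.
#' @param attractor `"max"` (EDT/Poisson) or `"min"` (geodesic).
#' @param source_idx linear indices where the field is forced to zero.
#' @return List `gr`, `gc`: row/col components, magnitudes in \{0, 1\}.
#' @export
gradient_field <- function(phi, mask, attractor = c("max", "min"),
                           source_idx = integer(0)) {
  attractor <- match.arg(attractor)
  m <- mask != 0
  if (attractor == "min") {
    # travel-time maps are undefined outside the mask: use masked
    # (one-sided at the boundary) differences so the boundary ring never
    # points out of the cell
    gr <- masked_diff(phi, m, 1L)
    gc <- masked_diff(phi, m, 2L)
  } else {
    gr <- central_diff(phi, 1L)
    gc <- central_diff(phi, 2L)
  }
  if (attractor == "min") { gr <- -gr; gc <- -gc }
  mag <- sqrt(gr^2 + gc^2)
  ok <- m & mag > 1e-12
  gr <- ifelse(ok, gr / pmax(mag, 1e-300), 0)
  gc <- ifelse(ok, gc / pmax(mag, 1e-300), 0)
  if (length(source_idx)) { gr[source_idx] <- 0; gc[source_idx] <- 0 }
  list(gr = gr, gc = gc)
}

# Compute the transform for one cell footprint mask (full-slice logical).
cell_transform <- function(mask, kind, power = 1, sigma_skel = 3) {
  if (sum(mask) <= 2L && kind != "poisson") {
    # tiny cells: EDT path (explicit systems degenerate)
    return(list(phi = edt2d(mask), attractor = "max", source_idx = integer(0)))
  }
  switch(kind,
    edt = list(phi = edt2d(mask), attractor = "max", source_idx = integer(0)),
    poisson = {
      tr <- poisson_transform(mask, "none")
      list(phi = tr$phi, attractor = "max", source_idx = integer(0))
    },
    poisson_point = {
      tr <- poisson_transform(mask, "point", power = power)
      list(phi = tr$phi, attractor = "max", source_idx = tr$source_idx)
    },
    poisson_skeleton = {
      sk <- which(medial_skeleton2d(mask, sigma_skel) & mask)
      if (length(sk) == 0L) sk <- select_point_source(mask)
      tr <- poisson_transform(mask, "skeleton", src_idx = sk)
      list(phi = tr$phi, attractor = "max", source_idx = sk)
    },
    geodesic_point = {
      tr <- geodesic_transform(mask, "point")
      list(phi = tr$phi, attractor = tr$attractor %||% "min",
           source_idx = tr$source_idx)
    },
    geodesic_skeleton = {
      sk <- which(medial_skeleton2d(mask, sigma_skel) & mask)
      if (length(sk) == 0L) sk <- select_point_source(mask)
      tr <- geodesic_transform(mask, "skeleton", src_idx = sk)
      list(phi = tr$phi, attractor = tr$attractor %||% "min",
           source_idx = tr$source_idx)
    },
    stop("unknown transform kind '", kind, "'"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a 2D label slice to a composite gradient field and proxy
#'
#' Computes the chosen distance transform independently on each 2D cell
#' footprint (cropped to its padded bounding box, so distant cells never
#' interact) and composites the per-cell unit gradient fields into one
#' slice-wide field, plus a foreground-probability proxy: the per-cell
#' max-normalised EDT in `[0, 1]`.
#'
#' @param slice_labels 2D integer label image.
#' @param kind one of `r paste(TRANSFORM_KINDS, collapse=", ")`.
#' @param power point-source Poisson power-transform exponent.
#' @param sigma_skel skeleton pre-smoothing width.
#' @return List `gr`, `gc` (slice-wide unit components) and `proxy`.
#' @export
labels_to_gradients <- function(slice_labels, kind = "edt", power = 1,
                                sigma_skel = 3) {
  kind <- match.arg(kind, TRANSFORM_KINDS)
  d <- dim(slice_labels)
  gr <- matrix(0, d[1], d[2]); gc <- matrix(0, d[1], d[2])
  proxy <- matrix(0, d[1], d[2])
  ids <- setdiff(unique(as.vector(slice_labels)), 0L)
  for (id in ids) {
    m_full <- slice_labels == id
    box <- bounding_box(m_full, pad = 1L)
    m <- crop_box(m_full, box)
    tr <- cell_transform(m, kind, power, sigma_skel)
    g <- gradient_field(tr$phi, m, tr$attractor, tr$source_idx)
    sel <- which(m)
    gr_c <- crop_box(gr, box); gc_c <- crop_box(gc, box); px_c <- crop_box(proxy, box)
    gr_c[sel] <- g$gr[sel]; gc_c[sel] <- g$gc[sel]
    ed <- edt2d(m)
    px_c[sel] <- ed[sel] / max(ed[sel])
    paste_box(gr, box) <- gr_c
    paste_box(gc, box) <- gc_c
    paste_box(proxy, box) <- px_c
  }
  list(gr = gr, gc = gc, proxy = proxy)
}

#' Per-view slice-wise gradient stacks from label orthoviews
#'
#' Applies [labels_to_gradients()] to every slice of every view of a label
#' orthoview set.
#'
#' @param ovs `orthoview_set` of kind `"label"`.
#' @inheritParams labels_to_gradients
#' @return Named list per view: `gr`, `gc`, `proxy` view-ordered 3D arrays.
#' @export
orthoview_gradients <- function(ovs, kind = "edt", power = 1, sigma_skel = 3) {
  stopifnot(inherits(ovs, "orthoview_set"), ovs$kind == "label")
  out <- lapply(names(ovs$views), function(v) {
    st <- ovs$views[[v]]
    nd <- dim(st)
    gr <- array(0, nd); gc <- array(0, nd); proxy <- array(0, nd)
    for (s in seq_len(nd[1])) {
      if (!any(st[s, , ] != 0L)) next
      g <- labels_to_gradients(st[s, , ], kind, power, sigma_skel)
      gr[s, , ] <- g$gr; gc[s, , ] <- g$gc; proxy[s, , ] <- g$proxy
    }
    list(gr = gr, gc = gc, proxy = proxy)
  })
  names(out) <- names(ovs$views)
  out
}
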