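# Quality-control filters and guide-image refinement: size filter,
# gradient-consistency filter, statistical large-cell filter, label
# diffusion, guided filter. The recommended chain is
# small -> inconsistent -> large -> diffuse -> guided.

label_sizes <- function(a) {
  mx <- max(a)
  if (mx == 0L) return(integer(0))
  tabulate(a[a > 0L], nbins = mx)
}

#' Remove small cells and enforce spatial contiguity
#'
#' Deletes labels occupying fewer than `min_size` voxels and reduces every
#' surviving label to its largest connected component (a segmented cell
#' should be one contiguous object).
#'
#' @param labels a `label_volume`.
#' @param min_size voxel threshold (default 200).
#' @param connectivity component connectivity (default 26).
#' @return Filtered `label_volume`.
#' @export
filter_small <- function(labels, min_size = 200L, connectivity = 26L) {
  a <- vol_data(labels)
  sizes <- label_sizes(a)
  kill <- which(sizes > 0L & sizes < min_size)
  if (length(kill)) a[a %in% kill] <- 0L
  # keep only the largest component of each label (value-aware CC)
  cc <- label_components(a, connectivity)
  if (max(cc) > 0L) {
    cc_size <- tabulate(cc[cc > 0L], nbins = max(cc))
    sel <- cc > 0L
    cc_lab <- a[sel]
    keep_cc <- rep(FALSE, max(cc))
    for (id in unique(cc_lab)) {
      comps <- unique(cc[sel][cc_lab == id])
      keep_cc[comps[which.max(cc_size[comps])]] <- TRUE
    }
    drop <- sel
    drop[sel] <- !keep_cc[cc[sel]]
    a[drop] <- 0L
  }
  as_label_volume(a)
}

#' Remove cells inconsistent with the descent gradient field
#'
#' For each cell, its binary mask is re-sliced into the orthoviews, 2D
#' transforms of the same kind are recomputed and fused to a 3D field, and
#' the mean absolute per-component error against the field actually used
#' for descent is measured over the cell's voxels. Cells whose
#' `MAE > mae_threshold` (default 0.85, tuned for `sigma_post = 1`) were
#' not shaped by their own gradients — typically spurious aggregations —
#' and are removed.
#'
#' @param labels a `label_volume`.
#' @param field_in the `gradient_field3d` used for descent.
#' @param kind 2D transform kind used in reconstruction.
#' @param mae_threshold removal threshold (default 0.85).
#' @param sigma_pre,sigma_post fusion smoothing used in reconstruction.
#' @param pad crop padding (voxels).
#' @return Filtered `label_volume` with attribute `mae` (named per label).
#' @export
filter_gradient_inconsistent <- function(labels, field_in, kind = "edt",
                                         mae_threshold = 0.85,
                                         sigma_pre = 1, sigma_post = 1,
                                         pad = 2L) {
  a <- vol_data(labels)
  ids <- setdiff(sort(unique(as.vector(a))), 0L)
  mae <- stats::setNames(numeric(length(ids)), ids)
  for (i in seq_along(ids)) {
    id <- ids[i]
    m_full <- a == id
    box <- bounding_box(m_full, pad = pad)
    m <- crop_box(m_full, box)
    cell_lab <- as_label_volume(array(as.integer(m), dim(m)))
    ovs <- slice_orthoviews(cell_lab)
    vg <- orthoview_gradients(ovs, kind)
    f_cell <- fuse_gradients(vg, dim(m), sigma_pre = sigma_pre,
                             sigma_post = sigma_post, mask = m)
    sel <- which(m)
    err <- (abs(f_cell$z[sel] - crop_box(field_in$z, box)[sel]) +
            abs(f_cell$y[sel] - crop_box(field_in$y, box)[sel]) +
            abs(f_cell$x[sel] - crop_box(field_in$x, box)[sel])) / 3
    mae[i] <- mean(err)
    if (mae[i] > mae_threshold) a[m_full] <- 0L
  }
  out <- as_label_volume(a)
  attr(out, "mae") <- mae
  out
}

#' Remove statistically improbably large cells
#'
#' Assuming cell volumes are approximately normal, removes labels whose
#' volume exceeds `mean(volumes) + k_vol * sd(volumes)` (strict
#' inequality, so equal-volume sets are untouched). Identity when fewer
#' than two cells are present.
#'
#' @param labels a `label_volume`.
#' @param k_vol cutoff factor (default 5).
#' @return Filtered `label_volume`.
#' @export
filter_large <- function(labels, k_vol = 5) {
  stopifnot(k_vol > 0)
  a <- vol_data(labels)
  sizes <- label_sizes(a)
  present <- which(sizes > 0L)
  if (length(present) < 2L) return(labels)
  vols <- sizes[present]
  cutoff <- mean(vols) + k_vol * stats::sd(vols)
  kill <- present[vols > cutoff]
  if (length(kill)) a[a %in% kill] <- 0L
  as_label_volume(a)
}

#' Blend a normalized image and its ridge enhancement into a guide image
#'
#' `I_guide = alpha * I_norm + (1 - alpha) * I_ridge`: the convex blend
#' used to drive diffusion and guided filtering toward both bulk intensity
#' and thin protrusive features.
#'
#' @param I_norm,I_ridge arrays or `volume`s of equal shape.
#' @param alpha_guide blend weight in `[0, 1]`.
#' @return Array (or `volume`) of the same shape.
#' @export
make_guide <- function(I_norm, I_ridge, alpha_guide = 0.5) {
  stopifnot(alpha_guide >= 0, alpha_guide <= 1)
  a <- if (inherits(I_norm, "volume")) vol_data(I_norm) else I_norm
  b <- if (inherits(I_ridge, "volume")) vol_data(I_ridge) else I_ridge
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  out <- alpha_guide * a + (1 - alpha_guide) * b
  if (inherits(I_norm, "volume")) as_volume(out, vol_spacing(I_norm)) else out
}

# Sparse neighbour-pair index matrix (6- or 26-connectivity) for a crop.
neighbour_edges <- function(shape, connectivity = 6L) {
  offs <- list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  if (connectivity == 26L) {
    offs <- list()
    for (a in -1:1) for (b in -1:1) for (cc in -1:1) {
      v <- c(a, b, cc)
      if (all(v == 0L)) next
      if (a > 0 || (a == 0 && (b > 0 || (b == 0 && cc > 0))))  # half-space
        offs <- c(offs, list(v))
    }
  }
  n1 <- shape[1]; n2 <- shape[2]; n3 <- shape[3]
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    r1 <- seq_len(n1 - abs(o[1])); r2 <- seq_len(n2 - abs(o[2])); r3 <- seq_len(n3 - abs(o[3]))
    if (o[1] < 0) r1 <- r1 + abs(o[1])
    if (o[2] < 0) r2 <- r2 + abs(o[2])
    if (o[3] < 0) r3 <- r3 + abs(o[3])
    g <- expand.grid(i = r1, j = r2, k = r3)
    f <- g$i + n1 * (g$j - 1L + n2 * (g$k - 1L))
    t <- (g$i + o[1]) + n1 * (g$j + o[2] - 1L + n2 * (g$k + o[3] - 1L))
    from <- c(from, f); to <- c(to, t)
  }
  cbind(c(from, to), c(to, from))   # symmetric
}

#' Refine cell masks by label diffusion on an affinity graph
#'
#' Semi-supervised label spreading adapted to segmentation: each cell
#' (treated independently as binary against a background source) is
#' one-hot encoded in its padded crop and diffused for `T_diff` iterations
#' on a row-normalised affinity matrix blending guide-intensity similarity
#' (`exp(-D^2 / (2 mean(D)^2)` on neighbour differences `D`) with pure
#' spatial adjacency; the clamping factor `gamma_clamp` preserves the
#' original labelling (`gamma_clamp = 1` or `T_diff = 0` is the identity).
#' Voxels go to the argmax source, and each refined cell is reduced to its
#' largest connected component.
#'
#' @param labels a `label_volume`.
#' @param guide co-registered guide image (array or `volume`).
#' @param alpha_mix intensity-vs-adjacency affinity weight in `[0, 1]`.
#' @param gamma_clamp clamping factor in `[0, 1]` (default 0.75).
#' @param T_diff diffusion iterations (default 25).
#' @param pad crop padding in voxels (default 25; binary mode only).
#' @param connectivity affinity neighbour system: 6 (default) or 26.
#' @param mode `"binary"` (default; each cell refined independently against
#'   a background source, scalable) or `"joint"` (all cells and the
#'   background compete simultaneously on one affinity graph).
#' @return Refined `label_volume`.
#' @export
diffuse_labels <- function(labels, guide, alpha_mix = 0.5, gamma_clamp = 0.75,
                           T_diff = 25L, pad = 25L, connectivity = 6L,
                           mode = c("binary", "joint")) {
  mode <- match.arg(mode)
  stopifnot(alpha_mix >= 0, alpha_mix <= 1, gamma_clamp >= 0, gamma_clamp <= 1)
  if (T_diff == 0L || gamma_clamp == 1) return(labels)
  a <- vol_data(labels)
  g <- if (inherits(guide, "volume")) vol_data(guide) else guide
  if (!identical(dim(a), dim(g))) stop("guide not co-registered with labels")
  if (mode == "joint")
    return(diffuse_joint(a, g, alpha_mix, gamma_clamp, T_diff, connectivity))
  out <- a
  ids <- setdiff(sort(unique(as.vector(a))), 0L)
  for (id in ids) {
    m_full <- a == id
    box <- bounding_box(m_full, pad = pad)
    m <- crop_box(m_full, box)
    others <- crop_box(a, box) != 0L & !m
    L <- cbind(as.numeric(!m), as.numeric(m))   # background | cell one-hot
    z <- diffuse_iterate(L, crop_box(g, box), dim(m), alpha_mix,
                         gamma_clamp, T_diff, connectivity)
    refined <- array(z[, 2] > z[, 1], dim(m))
    refined[others] <- FALSE    # other cells are competing sources
    # enforce contiguity
    cc <- label_components(refined * 1L, 26L)
    if (max(cc) > 0L) {
      keep <- which.max(tabulate(cc[cc > 0L], nbins = max(cc)))
      refined <- cc == keep
    }
    sub <- crop_box(out, box)
    sub[m & sub == id] <- 0L
    sub[refined & (sub == 0L)] <- id
    paste_box(out, box) <- sub
  }
  as_label_volume(out)
}

# Row-normalised affinity iteration z <- (1-gamma) A z + gamma L.
diffuse_iterate <- function(L, guide, shape, alpha_mix, gamma_clamp,
                            T_diff, connectivity) {
  n <- prod(shape)
  edges <- neighbour_edges(shape, connectivity)
  D <- abs(guide[edges[, 1]] - guide[edges[, 2]])
  mD <- mean(D)
  w_int <- if (mD > 0) exp(-D^2 / (2 * mD^2)) else rep(1, length(D))
  w_lap <- rep(exp(-0.5), length(D))
  w <- alpha_mix * w_int + (1 - alpha_mix) * w_lap
  A <- Matrix::sparseMatrix(i = edges[, 1], j = edges[, 2], x = w,
                            dims = c(n, n)) + Matrix::Diagonal(n)
  A <- Matrix::Diagonal(n, 1 / Matrix::rowSums(A)) %*% A
  z <- matrix(0, n, ncol(L))
  for (t in seq_len(T_diff)) z <- as.matrix((1 - gamma_clamp) * (A %*% z) +
                                            gamma_clamp * L)
  z
}

# Joint multi-label diffusion over the whole volume: columns are
# background plus every cell ID; each voxel goes to its argmax source.
diffuse_joint <- function(a, g, alpha_mix, gamma_clamp, T_diff, connectivity) {
  ids <- setdiff(sort(unique(as.vector(a))), 0L)
  L <- cbind(as.numeric(a == 0L),
             vapply(ids, function(id) as.numeric(a == id),
                    numeric(length(a))))
  z <- diffuse_iterate(L, g, dim(a), alpha_mix, gamma_clamp, T_diff,
                       connectivity)
  win <- max.col(z, ties.method = "first")
  out <- array(0L, dim(a))
  out[win > 1L] <- ids[win[win > 1L] - 1L]
  as_label_volume(out)
}

#' Recover boundary features with an edge-preserving guided filter
#'
#' Filters each cell's binary mask with the standard local-linear guided
#' filter (cubic box window of half-width `r`, regulariser `eps_gf`)
#' against the guide image on a padded crop: the result is a feathered
#' mask whose border zone inherits guide structure (protrusions, fingers),
#' which is rebinarised by two-class Otsu. Voxels of other cells are
#' masked out; voxels farther than `r + pad` from the cell are never
#' touched.
#'
#' @param labels a `label_volume`.
#' @param guide co-registered guide image.
#' @param r box window half-width in voxels (default 35; the maximum
#'   protrusion length that can be recovered).
#' @param eps_gf regulariser (default 1e-4); large values approach a plain
#'   box blur of the mask.
#' @param pad crop padding (default 25).
#' @return Refined `label_volume`.
#' @export
guided_filter_refine <- function(labels, guide, r = 35L, eps_gf = 1e-4,
                                 pad = 25L) {
  stopifnot(r >= 1, eps_gf > 0)
  a <- vol_data(labels)
  g <- if (inherits(guide, "volume")) vol_data(guide) else guide
  if (!identical(dim(a), dim(g))) stop("guide not co-registered with labels")
  out <- a
  ids <- setdiff(sort(unique(as.vector(a))), 0L)
  for (id in ids) {
    m_full <- a == id
    box <- bounding_box(m_full, pad = pad)
    p <- crop_box(m_full, box) * 1
    I <- crop_box(g, box)
    others <- crop_box(a, box) != 0L & !(crop_box(a, box) == id)
    W <- min(2L * r + 1L, min(dim(p)))
    if (W %% 2L == 0L) W <- W - 1L
    mean_I <- box_mean(I, W); mean_p <- box_mean(p, W)
    cov_Ip <- box_mean(I * p, W) - mean_I * mean_p
    var_I <- box_mean(I * I, W) - mean_I^2
    acoef <- cov_Ip / (var_I + eps_gf)
    bcoef <- mean_p - acoef * mean_I
    q <- box_mean(acoef, W) * I + box_mean(bcoef, W)
    rng <- range(q)
    qn <- if (rng[2] > rng[1]) (q - rng[1]) / (rng[2] - rng[1]) else q * 0
    thr <- tryCatch(otsu_thresholds(qn, 2L), error = function(e) 0.5)
    refined <- qn > thr
    refined[others] <- FALSE
    sub <- crop_box(out, box)
    sub[p > 0 & sub == id] <- 0L
    sub[refined & sub == 0L] <- id
    paste_box(out, box) <- sub
  }
  as_label_volume(out)
}

#' Run the recommended postprocessing chain
#'
#' small-cell filter, gradient-consistency filter, large-cell filter, then
#' (when a guide image is given) label diffusion and guided-filter
#' refinement, in that order.
#'
#' @param labels a `label_volume`.
#' @param field_in descent field for the consistency filter (skipped when
#'   `NULL`).
#' @param guide optional guide image enabling the refinement stages.
#' @param min_size,mae_threshold,k_vol,kind filter settings.
#' @param diffusion list of [diffuse_labels()] settings (or `NULL` to skip).
#' @param guided list of [guided_filter_refine()] settings (or `NULL`).
#' @return Postprocessed `label_volume` with attribute `qc_removed`
#'   (counts removed per stage).
#' @export
postprocess_chain <- function(labels, field_in = NULL, guide = NULL,
                              min_size = 200L, mae_threshold = 0.85,
                              k_vol = 5, kind = "edt",
                              diffusion = NULL, guided = NULL) {
  count <- function(l) length(setdiff(unique(as.vector(l)), 0L))
  removed <- c(small = 0L, inconsistent = 0L, large = 0L)
  n0 <- count(labels)
  labels <- filter_small(labels, min_size)
  removed["small"] <- n0 - count(labels)
  if (!is.null(field_in)) {
    n0 <- count(labels)
    labels <- filter_gradient_inconsistent(labels, field_in, kind, mae_threshold)
    removed["inconsistent"] <- n0 - count(labels)
  }
  n0 <- count(labels)
  labels <- filter_large(labels, k_vol)
  removed["large"] <- n0 - count(labels)
  if (!is.null(guide) && !is.null(diffusion))
    labels <- do.call(diffuse_labels, c(list(labels, guide), diffusion))
  if (!is.null(guide) && !is.null(guided))
    labels <- do.call(guided_filter_refine, c(list(labels, guide), guided))
  attr(labels, "qc_removed") <- removed
  labels
}
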