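# Instance-matching evaluation: IoU, optimal one-to-one matching, AP and
# F1 curves over 11 IoU thresholds, and the fair-evaluation restriction to
# the reference foreground.

#' Intersection over union of two voxel sets
#'
#' @param a,b logical arrays (same shape) or integer index vectors.
#' @return `|A and B| / |A or B|`; 0 when both are empty.
#' @export
iou <- function(a, b) {
  if (is.logical(a) || is.array(a)) a <- which(a != 0)
  if (is.logical(b) || is.array(b)) b <- which(b != 0)
  inter <- length(intersect(a, b))
  uni <- length(a) + length(b) - inter
  if (uni == 0L) return(0)
  inter / uni
}

# O(n^3) Hungarian algorithm (potentials formulation) for a square cost
# matrix; returns for each column the assigned row.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1L)          # row potentials, index i+0 (1..n), u[n+1] spare
  v <- numeric(n + 1L)          # col potentials, index j+1 (col 0 virtual at 1)
  p <- integer(n + 1L)          # p[j+1]: row assigned to col j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_j <- which(!used[2:(n + 1L)])          # actual columns 1..n
      cur <- cost[i0, free_j] - u[i0] - v[free_j + 1L]
      upd <- cur < minv[free_j + 1L]
      if (any(upd)) {
        minv[free_j[upd] + 1L] <- cur[upd]
        way[free_j[upd] + 1L] <- j0
      }
      k <- which.min(minv[free_j + 1L])
      delta <- minv[free_j[k] + 1L]
      j1 <- free_j[k]
      used_idx <- which(used)
      u[p[used_idx]] <- u[p[used_idx]] + delta
      v[used_idx] <- v[used_idx] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  p[2:(n + 1L)]    # row assigned to each column
}

# Label centroids (0-based voxel coordinates), rows ordered by label ID.
label_centroids <- function(a, ids) {
  if (length(ids) == 0L) return(matrix(0, 0, 3))
  idx <- which(a > 0L, arr.ind = TRUE)
  lab <- a[a > 0L]
  t(vapply(ids, function(id) colMeans(idx[lab == id, , drop = FALSE]) - 1,
           numeric(3)))
}

# Pairwise intersection counts between two label arrays, as a tibble of
# (pred, ref, inter).
overlap_counts <- function(p, r) {
  sel <- p > 0L & r > 0L
  if (!any(sel)) return(tibble::tibble(pred = integer(0), ref = integer(0),
                                       inter = integer(0)))
  key <- paste(p[sel], r[sel])
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  tibble::tibble(pred = as.integer(parts[, 1]), ref = as.integer(parts[, 2]),
                 inter = as.integer(tab))
}

#' Optimal one-to-one matching of predicted and reference instances
#'
#' Builds the IoU matrix between predicted and reference cells (candidate
#' pairs restricted to the `k_nn` nearest reference centroids per
#' predicted cell when object counts exceed `dense_limit`; exact dense
#' matching otherwise), solves the linear sum assignment minimising
#' `1 - IoU`, and keeps only spatially overlapping pairs (`IoU > 0`).
#'
#' @param pred,ref co-registered `label_volume`s (or integer arrays).
#' @param k_nn candidate reference cells per predicted cell (default 10).
#' @param dense_limit use the full dense IoU matrix when both counts are
#'   at most this (default 50).
#' @return A `match_result`: tibble `pairs` (`pred`, `ref`, `iou`) plus
#'   `n_pred`, `n_ref`.
#' @export
match_instances <- function(pred, ref, k_nn = 10L, dense_limit = 50L) {
  p <- if (inherits(pred, "label_volume")) vol_data(pred) else pred
  r <- if (inherits(ref, "label_volume")) vol_data(ref) else ref
  if (!identical(dim(p), dim(r))) stop("volumes are not co-registered")
  pid <- setdiff(sort(unique(as.vector(p))), 0L)
  rid <- setdiff(sort(unique(as.vector(r))), 0L)
  M <- length(pid); N <- length(rid)
  empty <- structure(list(pairs = tibble::tibble(pred = integer(0),
                                                 ref = integer(0),
                                                 iou = numeric(0)),
                          n_pred = M, n_ref = N), class = "match_result")
  if (M == 0L || N == 0L) return(empty)
  ov <- overlap_counts(p, r)
  psize <- tabulate(p[p > 0L], nbins = max(pid))
  rsize <- tabulate(r[r > 0L], nbins = max(rid))
  iou_mat <- matrix(0, M, N, dimnames = list(pid, rid))
  if (nrow(ov)) {
    pi_ <- match(ov$pred, pid); ri_ <- match(ov$ref, rid)
    iou_mat[cbind(pi_, ri_)] <-
      ov$inter / (psize[ov$pred] + rsize[ov$ref] - ov$inter)
  }
  if (M > dense_limit || N > dense_limit) {
    # zero out IoU entries outside each predicted cell's k-nearest
    # reference centroids (centroid-kNN candidate restriction)
    cp <- label_centroids(p, pid); cr <- label_centroids(r, rid)
    for (i in seq_len(M)) {
      d2 <- rowSums(sweep(cr, 2, cp[i, ])^2)
      keep <- order(d2)[seq_len(min(k_nn, N))]
      drop <- setdiff(seq_len(N), keep)
      iou_mat[i, drop] <- 0
    }
  }
  n <- max(M, N)
  cost <- matrix(1, n, n)
  cost[seq_len(M), seq_len(N)] <- 1 - iou_mat
  row_of_col <- solve_assignment(cost)
  pairs <- tibble::tibble(pred = integer(0), ref = integer(0), iou = numeric(0))
  for (j in seq_len(N)) {
    i <- row_of_col[j]
    if (i <= M && iou_mat[i, j] > 0)
      pairs <- rbind(pairs, tibble::tibble(pred = pid[i], ref = rid[j],
                                           iou = iou_mat[i, j]))
  }
  structure(list(pairs = pairs, n_pred = M, n_ref = N),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> ", nrow(x$pairs), " matched of ", x$n_pred,
      " predicted / ", x$n_ref, " reference cells\n", sep = "")
  invisible(x)
}

# Relabel sequentially after an indirect stable sort on (z,y,x) centroids,
# making the matching invariant to input ID permutation.
relabel_by_centroid <- function(a) {
  ids <- setdiff(sort(unique(as.vector(a))), 0L)
  if (length(ids) == 0L) return(a)
  ctr <- label_centroids(a, ids)
  ord <- order(ctr[, 1], ctr[, 2], ctr[, 3])
  lut <- integer(max(ids))
  lut[ids[ord]] <- seq_along(ids)
  out <- a
  out[a > 0L] <- lut[a[a > 0L]]
  out
}

#' AP and F1 curves over IoU thresholds
#'
#' Relabels both volumes sequentially after a stable centroid sort,
#' matches instances once, and evaluates at each IoU threshold tau:
#' matched pairs with `IoU >= tau` are true positives, unmatched predicted
#' cells false positives, unmatched reference cells false negatives;
#' `AP = TP / (TP + FP + FN)` and `F1 = 2 TP / (2 TP + FP + FN)`. When
#' both volumes are empty the score is 1 at every threshold (no objects,
#' no errors); an empty prediction against a non-empty reference (or vice
#' versa) scores 0.
#'
#' @param pred,ref co-registered `label_volume`s.
#' @param restrict optional overlap fraction for
#'   [restrict_to_reference_foreground()] applied to `pred` first (e.g.
#'   0.25, or 0.01 for thin vessel data); `NULL` to skip.
#' @param thresholds IoU cutoffs (default 11 values equisampling
#'   `[0.5, 1]`).
#' @param k_nn,dense_limit passed to [match_instances()].
#' @return A `metric_curves` tibble: `threshold`, `ap`, `f1`, `tp`, `fp`,
#'   `fn`, with `mean_matched_iou` attribute. `tidy()`, `glance()` and
#'   `autoplot()` methods are provided.
#' @export
ap_f1_curve <- function(pred, ref, restrict = NULL,
                        thresholds = seq(0.5, 1, by = 0.05),
                        k_nn = 10L, dense_limit = 50L) {
  if (!is.null(restrict))
    pred <- restrict_to_reference_foreground(pred, ref, restrict)
  p <- relabel_by_centroid(if (inherits(pred, "label_volume")) vol_data(pred) else pred)
  r <- relabel_by_centroid(if (inherits(ref, "label_volume")) vol_data(ref) else ref)
  mr <- match_instances(p, r, k_nn, dense_limit)
  M <- mr$n_pred; N <- mr$n_ref
  curve <- lapply(thresholds, function(tau) {
    if (M == 0L && N == 0L) return(c(tp = 0L, fp = 0L, fn = 0L, ap = 1, f1 = 1))
    tp <- sum(mr$pairs$iou >= tau)
    fp <- M - tp; fn <- N - tp
    c(tp = tp, fp = fp, fn = fn,
      ap = tp / (tp + fp + fn),
      f1 = 2 * tp / (2 * tp + fp + fn))
  })
  curve <- do.call(rbind, curve)
  out <- tibble::tibble(threshold = thresholds,
                        ap = curve[, "ap"], f1 = curve[, "f1"],
                        tp = as.integer(curve[, "tp"]),
                        fp = as.integer(curve[, "fp"]),
                        fn = as.integer(curve[, "fn"]))
  structure(out,
            mean_matched_iou = if (nrow(mr$pairs)) mean(mr$pairs$iou) else NA_real_,
            match = mr,
            class = c("metric_curves", class(out)))
}

#' Restrict predicted cells to the reference foreground
#'
#' Keeps only predicted cells belonging to connected components of the
#' predicted binary foreground that share at least `overlap_frac` of their
#' voxels with the reference foreground (0.25 by default; 0.01 for thin
#' vessel-like data, where components are mostly empty space). With
#' `overlap_frac = 0` this is the identity.
#'
#' @param pred,ref co-registered `label_volume`s.
#' @param overlap_frac minimum overlap fraction in `[0, 1]`.
#' @return Filtered `pred` as a `label_volume`.
#' @export
restrict_to_reference_foreground <- function(pred, ref, overlap_frac = 0.25) {
  if (overlap_frac <= 0) return(pred)
  p <- if (inherits(pred, "label_volume")) vol_data(pred) else pred
  r <- if (inherits(ref, "label_volume")) vol_data(ref) else ref
  comp <- label_components((p > 0L) * 1L, 26L)
  if (max(comp) == 0L) return(as_label_volume(p))
  comp_size <- tabulate(comp[comp > 0L], nbins = max(comp))
  inter <- tabulate(comp[comp > 0L & r > 0L], nbins = max(comp))
  ok <- inter / comp_size >= overlap_frac
  out <- p
  sel <- comp > 0L
  drop <- sel
  drop[sel] <- !ok[comp[sel]]
  out[drop] <- 0L
  as_label_volume(out)
}
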