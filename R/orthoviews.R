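# Orthoview sets: per-view stacks of 2D slices covering one volume.

#' Bundle per-view 2D slice stacks into an orthoview set
#'
#' @param views named list (`xy`/`xz`/`yz`) of view-ordered 3D arrays
#'   (see [transpose_to_view()]); all must restack to the same canonical
#'   shape.
#' @param kind what the slices hold: 2D instance labels (`"label"`),
#'   normalised probabilities (`"prob"`) or raw logits (`"logit"`).
#' @return An `orthoview_set`.
#' @export
orthoview_set <- function(views, kind = c("label", "prob", "logit")) {
  kind <- match.arg(kind)
  if (length(views) == 0L) stop("at least one view must be present")
  bad <- setdiff(names(views), VIEW_NAMES)
  if (length(bad)) stop("unknown view name(s): ", paste(bad, collapse = ", "))
  shapes <- lapply(names(views), function(v) dim(restack(views[[v]], v)))
  shape <- shapes[[1]]
  if (!all(vapply(shapes, function(s) identical(s, shape), logical(1))))
    stop("views disagree on the canonical (z,y,x) shape")
  if (kind == "label")
    views <- lapply(views, function(a) { storage.mode(a) <- "integer"; a })
  structure(list(views = views, shape = shape, kind = kind),
            class = "orthoview_set")
}

#' @export
print.orthoview_set <- function(x, ...) {
  cat("<orthoview_set> kind=", x$kind, ", shape ",
      paste(x$shape, collapse = " x "), " (z,y,x), views: ",
      paste(names(x$views), collapse = ", "), "\n", sep = "")
  invisible(x)
}

ov_views <- function(ovs) names(ovs$views)

#' Slice a 3D label volume into per-view stacks of 2D instance masks
#'
#' Emulates slice-by-slice 2D segmentation of a labelled volume: in every
#' 2D slice of every requested view, each contiguous in-plane region of a
#' single 3D object becomes its own 2D "cell", with IDs unique within the
#' slice and no identity preserved across slices. Touching 3D objects stay
#' distinct 2D cells (contiguity is evaluated per source label).
#'
#' @param labels a [as_label_volume()] object.
#' @param views character subset of `c("xy","xz","yz")`.
#' @param connectivity in-plane connectivity for contiguous regions (8
#'   default, or 4).
#' @return An `orthoview_set` of kind `"label"`.
#' @export
slice_orthoviews <- function(labels, views = VIEW_NAMES, connectivity = 8L) {
  stopifnot(inherits(labels, "label_volume"))
  bad <- setdiff(views, VIEW_NAMES)
  if (length(bad)) stop("unknown view name(s): ", paste(bad, collapse = ", "))
  a <- vol_data(labels)
  out <- lapply(views, function(v) {
    st <- transpose_to_view(a, v)
    for (s in seq_len(dim(st)[1])) {
      st[s, , ] <- label_components(st[s, , ], connectivity)
    }
    st
  })
  names(out) <- views
  orthoview_set(out, "label")
}

#' Inject controlled corruption into 2D label stacks
#'
#' Models imperfect slice-wise 2D segmentation: dropped cells, cells split
#' by a random line, merged touching cells, and boundary jitter by
#' dilation/erosion. Applied per slice in the fixed order
#' drop, split, merge, jitter so a seed reproduces the corruption exactly.
#'
#' @param ovs an `orthoview_set` of kind `"label"`.
#' @param drop_rate probability that any given 2D label is deleted.
#' @param split_rate probability that any given 2D label is cut in two by a
#'   random line through its centroid.
#' @param merge_rate probability that a touching label pair is merged.
#' @param jitter_px maximum boundary dilation/erosion radius (pixels).
#' @param seed integer RNG seed.
#' @return A corrupted `orthoview_set`.
#' @export
corrupt_views <- function(ovs, drop_rate = 0, split_rate = 0, merge_rate = 0,
                          jitter_px = 0L, seed = 1L) {
  stopifnot(inherits(ovs, "orthoview_set"), ovs$kind == "label")
  rates <- c(drop_rate, split_rate, merge_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0,1]")
  if (jitter_px < 0) stop("jitter_px must be non-negative")
  views <- ovs$views
  withr_seed <- .Random.seed_exists()
  set.seed(seed)
  for (v in names(views)) {
    st <- views[[v]]
    for (s in seq_len(dim(st)[1])) {
      st[s, , ] <- corrupt_slice(st[s, , ], drop_rate, split_rate,
                                 merge_rate, jitter_px)
    }
    views[[v]] <- st
  }
  orthoview_set(views, "label")
}

.Random.seed_exists <- function() exists(".Random.seed", envir = globalenv())

corrupt_slice <- function(sl, drop_rate, split_rate, merge_rate, jitter_px) {
  ids <- setdiff(sort(unique(as.vector(sl))), 0L)
  if (length(ids) == 0L) return(sl)
  # drop: each label independently
  if (drop_rate > 0) {
    kill <- ids[stats::runif(length(ids)) < drop_rate]
    sl[sl %in% kill] <- 0L
    ids <- setdiff(ids, kill)
  }
  # split: each label independently, cut by a random line through centroid
  if (split_rate > 0 && length(ids)) {
    for (id in ids[stats::runif(length(ids)) < split_rate]) {
      pix <- which(sl == id, arr.ind = TRUE)
      if (nrow(pix) < 2L) next
      ctr <- colMeans(pix)
      th <- stats::runif(1, 0, pi)
      nvec <- c(cos(th), sin(th))
      side <- (pix[, 1] - ctr[1]) * nvec[1] + (pix[, 2] - ctr[2]) * nvec[2] > 0
      if (any(side) && !all(side)) {
        new_id <- max(sl) + 1L
        sl[pix[side, , drop = FALSE]] <- new_id
      }
    }
    ids <- setdiff(sort(unique(as.vector(sl))), 0L)
  }
  # merge: each touching pair with prob merge_rate
  if (merge_rate > 0 && length(ids) >= 2L) {
    pairs <- touching_pairs(sl, ids)
    if (nrow(pairs)) {
      for (k in seq_len(nrow(pairs))) {
        if (stats::runif(1) < merge_rate) {
          a <- pairs[k, 1]; b <- pairs[k, 2]
          sl[sl == b] <- a
        }
      }
    }
  }
  # jitter: per-label dilate (+) or erode (-) by up to jitter_px
  if (jitter_px > 0) {
    ids <- setdiff(sort(unique(as.vector(sl))), 0L)
    for (id in ids) {
      amt <- sample.int(2L * jitter_px + 1L, 1L) - jitter_px - 1L
      if (amt == 0L) next
      m <- sl == id
      brush <- EBImage::makeBrush(2L * abs(amt) + 1L, "disc")
      if (amt > 0) {
        grown <- EBImage::dilate(m * 1, brush) > 0
        sl[grown & sl == 0L] <- id   # only claim background
      } else {
        shrunk <- EBImage::erode(m * 1, brush) > 0
        sl[m & !shrunk] <- 0L
      }
    }
  }
  sl
}

# Pairs of label IDs with 8-adjacent pixels in a 2D slice.
touching_pairs <- function(sl, ids) {
  d <- dim(sl)
  out <- matrix(integer(0), 0, 2)
  for (sh in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    i1 <- seq_len(d[1] - abs(sh[1]))
    j1 <- if (sh[2] >= 0) seq_len(d[2] - sh[2]) else (1L - sh[2]):d[2]
    if (length(i1) == 0L || length(j1) == 0L) next
    a <- sl[i1, j1, drop = FALSE]
    b <- sl[i1 + sh[1], j1 + sh[2], drop = FALSE]
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) out <- rbind(out, cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel])))
  }
  unique(out)
}

#' Synthesize raw cell-probability (logit) slices from label stacks
#'
#' Produces unnormalised logit maps, positive inside labels and negative
#' outside, scaled by `sharpness`, plus optional Gaussian noise: the style
#' of raw probability output a 2D network predictor would provide. With
#' `noise_sd = 0`, normalising with [normalize_probability()] and
#' thresholding at 0.5 recovers the label foreground exactly.
#'
#' @param ovs an `orthoview_set` of kind `"label"`.
#' @param sharpness positive logit scale.
#' @param noise_sd Gaussian noise standard deviation (logit units).
#' @param seed integer RNG seed.
#' @return An `orthoview_set` of kind `"logit"`.
#' @export
synth_probability <- function(ovs, sharpness = 4, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(ovs, "orthoview_set"), ovs$kind == "label",
            sharpness > 0, noise_sd >= 0)
  set.seed(seed)
  views <- lapply(ovs$views, function(st) {
    lg <- sharpness * ifelse(st > 0, 1, -1)
    if (noise_sd > 0) lg <- lg + stats::rnorm(length(lg), sd = noise_sd)
    array(lg, dim(st))
  })
  orthoview_set(views, "logit")
}
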