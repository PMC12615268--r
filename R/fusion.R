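# Content-based fusion of orthoview stacks into a consensus 3D foreground
# and 3D gradient field.

#' Content-based (inverse local deviation) averaging
#'
#' Fuses co-registered grids with per-voxel weights `1 / (sd_N + alpha)`,
#' where `sd_N` is the local population standard deviation over a `P^d`
#' window: views that are locally inconsistent (high variance) are
#' down-weighted. With `P = 1` every `sd_N` is zero and the result is the
#' arithmetic mean of the views (up to the `epsilon` guard).
#'
#' @param volumes list of arrays with identical shape (>= 1).
#' @param P odd neighbourhood width (default 1).
#' @param alpha pseudo-count added to the local deviation (default 0.5).
#' @param epsilon tiny guard against division by zero (default 1e-20).
#' @return Fused array of the common shape.
#' @export
content_average <- function(volumes, P = 1L, alpha = 0.5, epsilon = 1e-20) {
  if (length(volumes) < 1L) stop("need at least one volume")
  if (P %% 2L == 0L) stop("P must be odd")
  shape <- dim(volumes[[1]])
  if (!all(vapply(volumes, function(v) identical(dim(v), shape), logical(1))))
    stop("volume shapes differ")
  num <- array(0, shape); den <- array(0, shape)
  for (v in volumes) {
    w <- 1 / (local_sd(v, P) + alpha)
    num <- num + w * v
    den <- den + w
  }
  num / (den + epsilon)
}

# Restack one view of an orthoview set as a [0,1] foreground image.
view_foreground_3d <- function(ovs, v) {
  st <- ovs$views[[v]]
  img <- switch(ovs$kind,
    label = (st > 0) * 1,
    prob  = st,
    logit = normalize_probability(st))
  restack(array(as.numeric(img), dim(st)), v)
}

#' Fuse per-view foregrounds into a consensus 3D binary
#'
#' Each view's stack is restacked to 3D (labels become binaries, logits are
#' normalised), fused with [content_average()] (default `P = 3`, which
#' bridges slicewise dropouts), and binarised: a numeric `fg_threshold`,
#' or `"auto"` for multi-class Otsu on the fused probabilities. The default
#' threshold is 0.5 (majority vote) for label/binary inputs and `"auto"`
#' for probability inputs.
#'
#' @param ovs an `orthoview_set` (any non-empty subset of views).
#' @param P,alpha,epsilon content-averaging parameters (foreground default
#'   `P = 3`).
#' @param fg_threshold numeric in `(0,1)`, `"auto"`, or `NULL` for the
#'   kind-dependent default.
#' @param otsu_classes,otsu_pick,otsu_floor passed to
#'   [auto_threshold_probability()] when thresholding automatically.
#' @return Logical 3D array `B`: the domain of gradient descent.
#' @export
fuse_foreground <- function(ovs, P = 3L, alpha = 0.5, epsilon = 1e-20,
                            fg_threshold = NULL, otsu_classes = 2L,
                            otsu_pick = "only", otsu_floor = 0.25) {
  stopifnot(inherits(ovs, "orthoview_set"))
  if (is.null(fg_threshold))
    fg_threshold <- if (ovs$kind == "label") 0.5 else "auto"
  vols <- lapply(ov_views(ovs), function(v) view_foreground_3d(ovs, v))
  fused <- content_average(vols, P, alpha, epsilon)
  thr <- if (identical(fg_threshold, "auto")) {
    auto_threshold_probability(pmin(pmax(fused, 0), 1), otsu_classes,
                               otsu_pick, otsu_floor)
  } else fg_threshold
  fused > thr
}

# Which views observe each canonical 3D component, and whether that
# component is the view's in-plane row or col axis.
component_sources <- function(views_present) {
  all_map <- list(
    z = list(xy = NULL, xz = "gr", yz = "gr"),
    y = list(xy = "gr", xz = NULL, yz = "gc"),
    x = list(xy = "gc", xz = "gc", yz = NULL))
  lapply(all_map, function(comp) {
    comp <- comp[names(comp) %in% views_present]
    comp[!vapply(comp, is.null, logical(1))]
  })
}

#' Fuse per-view 2D gradient stacks into a 3D unit gradient field
#'
#' Each 2D component stack is Gaussian pre-filtered per slice
#' (`sigma_pre`), restacked, and each 3D component is content-averaged
#' from the views that observe it (x from xy+xz, y from xy+yz, z from
#' xz+yz; absent views contribute nothing and unobserved components are
#' zero before smoothing). The fused field is post-filtered in 3D
#' (`sigma_post`) and unit-normalised on the foreground support.
#'
#' @param view_grads named list per view of `gr`/`gc` view-ordered stacks
#'   (as from [orthoview_gradients()] or predicted 2D gradients).
#' @param shape canonical `(z,y,x)` shape.
#' @param P,alpha,epsilon content-averaging parameters (gradient default
#'   `P = 1`).
#' @param sigma_pre per-slice 2D Gaussian width before fusion (default 1).
#' @param sigma_post 3D Gaussian width after fusion (default 1); larger
#'   values merge nearby attractors (fewer, coarser objects).
#' @param mask optional logical support (`B`); the unit field is zeroed
#'   outside it.
#' @return A `gradient_field3d`: list of arrays `z`, `y`, `x` with voxel
#'   magnitudes in \{0, 1\}.
#' @export
fuse_gradients <- function(view_grads, shape, P = 1L, alpha = 0.5,
                           epsilon = 1e-20, sigma_pre = 1, sigma_post = 1,
                           mask = NULL) {
  views <- names(view_grads)
  bad <- setdiff(views, VIEW_NAMES)
  if (length(bad)) stop("unknown view name(s): ", paste(bad, collapse = ", "))
  # per-slice 2D pre-filtering within each view stack
  pre <- lapply(view_grads, function(g) {
    if (sigma_pre > 0) {
      for (comp in c("gr", "gc")) {
        st <- g[[comp]]
        for (s in seq_len(dim(st)[1])) st[s, , ] <- gaussian_smooth(st[s, , ], sigma_pre)
        g[[comp]] <- st
      }
    }
    g
  })
  srcs <- component_sources(views)
  comps <- lapply(srcs, function(src) {
    if (length(src) == 0L) return(array(0, shape))
    vols <- lapply(names(src), function(v) restack(pre[[v]][[src[[v]]]], v))
    content_average(vols, P, alpha, epsilon)
  })
  if (sigma_post > 0) comps <- lapply(comps, gaussian_smooth, sigma = sigma_post)
  normalize_field3d(comps, mask)
}

# Unit-normalise a 3-component field; zero where magnitude ~ 0 or outside mask.
normalize_field3d <- function(comps, mask = NULL) {
  mag <- sqrt(comps$z^2 + comps$y^2 + comps$x^2)
  ok <- mag > 1e-12
  if (!is.null(mask)) ok <- ok & (mask != 0)
  inv <- ifelse(ok, 1 / pmax(mag, 1e-300), 0)
  structure(list(z = comps$z * inv, y = comps$y * inv, x = comps$x * inv),
            class = "gradient_field3d")
}

#' @export
print.gradient_field3d <- function(x, ...) {
  cat("<gradient_field3d> ", paste(dim(x$z), collapse = " x "),
      " (z,y,x), ", sum(x$z != 0 | x$y != 0 | x$x != 0),
      " non-zero voxels\n", sep = "")
  invisible(x)
}
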