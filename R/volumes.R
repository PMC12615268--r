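#' @useDynLib orthoseg3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# ---- axis conventions ---------------------------------------------------
# Canonical axis order is (z, y, x). View "xy" slices along z, "xz" along y,
# "yz" along x. In view-permuted arrays the first axis is the slice index
# and the remaining two are the in-plane (row, col) axes:
#   xy: (z | y, x)   xz: (y | z, x)   yz: (x | z, y)

VIEW_NAMES <- c("xy", "xz", "yz")

view_perm <- function(view) {
  switch(view,
    xy = c(1L, 2L, 3L),
    xz = c(2L, 1L, 3L),
    yz = c(3L, 1L, 2L),
    stop("unknown view '", view, "' (expected xy, xz or yz)"))
}

# Canonical axis indices (1=z, 2=y, 3=x) of the in-plane (row, col) axes.
view_plane_axes <- function(view) view_perm(view)[2:3]

#' Construct an intensity volume
#'
#' A `volume` is a 3D numeric array in canonical `(z, y, x)` axis order with
#' a physical voxel `spacing` attribute (units per voxel, also `(z, y, x)`).
#'
#' @param data 3D numeric array, axis order `(z, y, x)`.
#' @param spacing numeric length-3, physical units per voxel along `(z, y, x)`.
#' @return A `volume` object.
#' @export
as_volume <- function(data, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(data)) == 3L, all(is.finite(spacing)), all(spacing > 0))
  if (any(!is.finite(data))) stop("volume values must be finite")
  structure(data, spacing = as.numeric(spacing), class = "volume")
}

#' Construct a label volume
#'
#' Non-negative integer labels in `(z, y, x)` order; 0 is background. Each
#' positive ID is intended to be one object; spatial contiguity is only
#' enforced after postprocessing.
#'
#' @param data 3D array of non-negative integers.
#' @return A `label_volume` object.
#' @export
as_label_volume <- function(data) {
  stopifnot(length(dim(data)) == 3L)
  if (any(data < 0)) stop("labels must be non-negative")
  storage.mode(data) <- "integer"
  structure(data, class = "label_volume")
}

vol_data <- function(v) {
  a <- unclass(v)
  attr(a, "spacing") <- NULL
  a
}

vol_spacing <- function(v) {
  s <- attr(v, "spacing")
  if (is.null(s)) c(1, 1, 1) else s
}

#' @export
print.volume <- function(x, ...) {
  cat("<volume> ", paste(dim(x), collapse = " x "),
      " (z,y,x), spacing ", paste(signif(vol_spacing(x), 4), collapse = ","),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  ids <- setdiff(unique(as.vector(x)), 0L)
  cat("<label_volume> ", paste(dim(x), collapse = " x "),
      " (z,y,x), ", length(ids), " labels\n", sep = "")
  invisible(x)
}

# ---- TIFF IO ------------------------------------------------------------

#' Read a 3D volume from a multipage TIFF
#'
#' Pages are stacked along z (z-major). Labels are read bit-exactly without
#' interpolation; intensity pages are returned as a float grid preserving
#' the stored sample values (8/16-bit integer TIFFs keep their integer
#' values). Spacing metadata is not parsed from TIFF tags; it defaults to
#' `(1,1,1)` and can be overridden.
#'
#' @param path TIFF file path.
#' @param kind `"intensity"` or `"label"`.
#' @param spacing voxel spacing to attach, `(z, y, x)`.
#' @return A [as_volume()] or [as_label_volume()] object.
#' @export
read_volume <- function(path, kind = c("intensity", "label"), spacing = c(1, 1, 1)) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, is.matrix, logical(1))))
    stop("not a 3D volume: multi-channel pages are unsupported")
  if (length(pages) < 2L)
    stop("not a 3D volume: file has a single page")
  bits <- attr(pages[[1]], "bits.per.sample") %||% 8L
  fmt <- attr(pages[[1]], "sample.format") %||% "uint"
  # 32-bit pages are IEEE float (the only float depth the writer emits)
  if (bits >= 32L) fmt <- "float"
  if (!identical(fmt, "float")) {
    # integer samples come back scaled to [0,1]; restore the stored values
    pages <- lapply(pages, function(p) round(p * (2^bits - 1)))
  }
  a <- aperm(simplify2array(pages), c(3L, 1L, 2L))  # (page, row, col) = (z, y, x)
  if (kind == "label") {
    as_label_volume(round(a))
  } else {
    storage.mode(a) <- "double"
    as_volume(a, spacing)
  }
}

#' Write a 3D volume to a multipage TIFF
#'
#' Label volumes are stored as 16-bit integer pages (bit-exact round trip
#' for IDs up to 65535). Intensity volumes are stored as 32-bit float pages;
#' values must lie in `[0, 1]` (the normalised working range of the
#' pipeline) because the TIFF writer clamps to that range.
#'
#' @param v a `volume` or `label_volume`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  a <- vol_data(v)
  pages <- lapply(seq_len(dim(a)[1]), function(z) a[z, , ])
  if (inherits(v, "label_volume")) {
    if (max(a) > 65535L) stop("label IDs above 65535 are not storable")
    tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                    bits.per.sample = 16L)
  } else {
    if (min(a) < 0 || max(a) > 1)
      stop("intensity volumes must be in [0,1] for TIFF storage; normalize first")
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  invisible(path)
}

# ---- restack / transpose ------------------------------------------------

#' Permute a canonical volume array into a view-ordered stack
#'
#' Returns a 3D array whose first axis is the slice index of `view` and
#' whose remaining axes are the in-plane (row, col) axes: `xy` gives
#' `(z | y, x)`, `xz` gives `(y | z, x)`, `yz` gives `(x | z, y)`.
#'
#' @param a 3D array in canonical `(z, y, x)` order (or a `volume`).
#' @param view one of `"xy"`, `"xz"`, `"yz"`.
#' @return A view-ordered 3D array.
#' @export
transpose_to_view <- function(a, view) {
  if (inherits(a, "volume") || inherits(a, "label_volume")) a <- vol_data(a)
  stopifnot(length(dim(a)) == 3L)
  aperm(a, view_perm(view))
}

#' Restack a view-ordered stack into canonical `(z, y, x)` order
#'
#' Inverse of [transpose_to_view()]: `restack(transpose_to_view(a, v), v)`
#' is the identity for every view.
#'
#' @param stack view-ordered 3D array.
#' @param view one of `"xy"`, `"xz"`, `"yz"`.
#' @return A 3D array in canonical order.
#' @export
restack <- function(stack, view) {
  stopifnot(length(dim(stack)) == 3L)
  aperm(stack, order(view_perm(view)))
}

# ---- isotropic resize ---------------------------------------------------

# Separable resample of one axis to length n_out; pixel-centre alignment.
resample_axis <- function(x, axis, n_out, method) {
  n_in <- dim(x)[axis]
  if (n_out == n_in) return(x)
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5  # 0-based input coord
  if (method == "nearest") {
    idx <- pmin(pmax(round(pos), 0), n_in - 1) + 1L
    return(index_axis(x, axis, idx))
  }
  lo <- pmin(pmax(floor(pos), 0), n_in - 1)
  hi <- pmin(lo + 1, n_in - 1)
  w <- pos - lo
  w[hi == lo] <- 0
  a <- index_axis(x, axis, lo + 1L)
  b <- index_axis(x, axis, hi + 1L)
  sweep_axis(a, axis, 1 - w, `*`) + sweep_axis(b, axis, w, `*`)
}

#' Rescale a volume to isotropic voxels
#'
#' Resamples so that output spacing is isotropic, with an optional extra
#' uniform zoom (`target_scale`): the new shape is
#' `shape * spacing / min(spacing) * target_scale`. Intensity volumes are
#' resampled with linear interpolation, label volumes with nearest
#' neighbour (no interpolation of IDs).
#'
#' @param v a `volume` or `label_volume`.
#' @param target_scale positive scalar zoom applied uniformly after
#'   isotropisation (1 keeps the finest original sampling).
#' @param spacing spacing override for label volumes (which carry none).
#' @return Same kind of object as `v`, with isotropic spacing.
#' @export
resize_isotropic <- function(v, target_scale = 1, spacing = NULL) {
  if (target_scale <= 0) stop("target_scale must be positive")
  is_label <- inherits(v, "label_volume")
  sp <- if (!is.null(spacing)) as.numeric(spacing) else vol_spacing(v)
  a <- vol_data(v)
  storage.mode(a) <- "double"
  s_out <- min(sp) / target_scale
  n_out <- pmax(1L, as.integer(round(dim(a) * sp / s_out)))
  method <- if (is_label) "nearest" else "linear"
  for (axis in 1:3) a <- resample_axis(a, axis, n_out[axis], method)
  if (is_label) as_label_volume(a) else as_volume(a, rep(s_out, 3))
}
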