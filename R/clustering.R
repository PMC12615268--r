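# Attractor identification by image-based density clustering, and label
# back-mapping from the eroded space to the original voxels.

#' Clustering parameter set
#'
#' @param sigma Gaussian width for the point-density map (default 1);
#'   larger values fuzzily merge nearby attractors (fewer labels).
#' @param k density threshold offset: attractors are voxels with
#'   `rho > mean(rho) + k * sd(rho)`. Default 0 (the working setting);
#'   `k = 1` is the conservative alternative.
#' @param connectivity attractor component connectivity (6, 18 or 26).
#' @param min_size_attractor drop attractor components smaller than this
#'   many voxels (default 0 = keep all).
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(sigma = 1, k = 0, connectivity = 26L,
                           min_size_attractor = 0L) {
  stopifnot(sigma > 0, connectivity %in% c(6L, 18L, 26L),
            min_size_attractor >= 0)
  structure(list(sigma = sigma, k = k, connectivity = as.integer(connectivity),
                 min_size_attractor = as.integer(min_size_attractor)),
            class = "cluster_params")
}

#' Rasterize advected points into a smoothed density map
#'
#' Final positions are floored onto the voxel grid and clipped to the
#' volume; each point contributes one count, and the count grid is
#' Gaussian-smoothed (a fast approximation to a Gaussian kernel density).
#' Total mass approximately equals the number of points (up to boundary
#' loss of the smoothing kernel).
#'
#' @param traj a `trajectory_set`.
#' @param shape volume shape (defaults to the trajectory's).
#' @param sigma Gaussian width.
#' @return 3D non-negative density array `rho`.
#' @export
rasterize_density <- function(traj, shape = traj$shape, sigma = 1) {
  if (nrow(traj$coordsT) == 0L) stop("empty trajectory set")
  iz <- pmin(pmax(floor(traj$coordsT[, 1]), 0), shape[1] - 1)
  iy <- pmin(pmax(floor(traj$coordsT[, 2]), 0), shape[2] - 1)
  ix <- pmin(pmax(floor(traj$coordsT[, 3]), 0), shape[3] - 1)
  lin <- 1 + iz + shape[1] * (iy + shape[2] * ix)
  rho <- array(tabulate(lin, nbins = prod(shape)), shape)
  gaussian_smooth(rho, sigma)
}

#' Threshold a density map into an attractor mask
#'
#' Global threshold `mean(rho) + k * sd(rho)`.
#'
#' @param rho density array.
#' @param k offset factor (see [cluster_params()]).
#' @return Logical array.
#' @export
threshold_density <- function(rho, k = 0) {
  rho > mean(rho) + k * stats::sd(as.vector(rho))
}

#' Label connected attractor components
#'
#' @param mask logical attractor mask.
#' @param connectivity 6, 18 or 26.
#' @param min_size drop components smaller than this many voxels.
#' @return A [as_label_volume()] of attractor IDs.
#' @export
label_attractors <- function(mask, connectivity = 26L, min_size = 0L) {
  lab <- label_components(mask * 1L, connectivity)
  if (min_size > 0L && max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    kill <- which(sizes < min_size)
    if (length(kill)) lab[lab %in% kill] <- 0L
  }
  as_label_volume(lab)
}

#' Map attractor IDs back to the initial voxels
#'
#' Each initial voxel receives the attractor label found at its final
#' (floored, clipped) position; points landing on sub-threshold density
#' receive 0 and are counted.
#'
#' @param traj a `trajectory_set`.
#' @param attractors attractor `label_volume`.
#' @return A `label_volume` over the t=0 voxels, with attributes
#'   `n_unassigned` and `frac_unassigned`.
#' @export
assign_labels <- function(traj, attractors) {
  shape <- dim(attractors)
  iz <- pmin(pmax(floor(traj$coordsT[, 1]), 0), shape[1] - 1)
  iy <- pmin(pmax(floor(traj$coordsT[, 2]), 0), shape[2] - 1)
  ix <- pmin(pmax(floor(traj$coordsT[, 3]), 0), shape[3] - 1)
  lin <- 1 + iz + shape[1] * (iy + shape[2] * ix)
  ids <- vol_data(attractors)[lin]
  out <- array(0L, shape)
  lin0 <- 1 + traj$coords0[, 1] + shape[1] * (traj$coords0[, 2] + shape[2] * traj$coords0[, 3])
  out[lin0] <- ids
  n0 <- sum(ids == 0L)
  res <- as_label_volume(out)
  attr(res, "n_unassigned") <- n0
  attr(res, "frac_unassigned") <- n0 / length(ids)
  res
}

#' Segment a consensus foreground by descent and density clustering
#'
#' Composition of the erosion pipeline: advect all `B = 1` voxels along
#' the field, rasterize the final positions into a smoothed density map,
#' threshold it, label the connected attractor components, and map the
#' labels back to the initial voxels. With `T = 0` no point moves and the
#' result is exactly the connected-component labelling of `B`.
#'
#' @param B logical 3D foreground mask.
#' @param field `gradient_field3d`.
#' @param dp [descent_params()].
#' @param cp [cluster_params()].
#' @param tile_shape optional: use [advect_tiled()] with this tile size.
#' @param overlap_frac tile overlap fraction.
#' @return List (class `consensus_segmentation`): `labels`
#'   (a `label_volume`), `traj`, `density`, `attractors`, `n_unassigned`,
#'   `frac_unassigned`.
#' @export
segment_volume <- function(B, field, dp = descent_params(),
                           cp = cluster_params(), tile_shape = NULL,
                           overlap_frac = 0.25) {
  if (!any(B != 0)) {
    empty <- as_label_volume(array(0L, dim(B)))
    return(structure(list(labels = empty, traj = NULL, density = NULL,
                          attractors = NULL, n_unassigned = 0L,
                          frac_unassigned = 0),
                     class = "consensus_segmentation"))
  }
  if (dp$T == 0L) {   # iteration 0 == connected components of B
    labels <- as_label_volume(label_components(B * 1L, cp$connectivity))
    return(structure(list(labels = labels, traj = NULL, density = NULL,
                          attractors = NULL, n_unassigned = 0L,
                          frac_unassigned = 0),
                     class = "consensus_segmentation"))
  }
  traj <- if (is.null(tile_shape)) {
    coords0 <- which(B != 0, arr.ind = TRUE) - 1L
    colnames(coords0) <- NULL
    advect(coords0, field, dp)
  } else {
    advect_tiled(B, field, dp, tile_shape, overlap_frac)
  }
  rho <- rasterize_density(traj, dim(B), cp$sigma)
  att_mask <- threshold_density(rho, cp$k)
  attractors <- label_attractors(att_mask, cp$connectivity, cp$min_size_attractor)
  labels <- assign_labels(traj, attractors)
  structure(list(labels = labels, traj = traj, density = rho,
                 attractors = attractors,
                 n_unassigned = attr(labels, "n_unassigned"),
                 frac_unassigned = attr(labels, "frac_unassigned")),
            class = "consensus_segmentation")
}

#' @export
print.consensus_segmentation <- function(x, ...) {
  n <- length(setdiff(unique(as.vector(x$labels)), 0L))
  cat("<consensus_segmentation> ", n, " labels, ",
      x$n_unassigned, " unassigned points\n", sep = "")
  invisible(x)
}
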