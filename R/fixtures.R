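# Synthetic 3D morphotype generator: convex packings, branched tubes and
# thin vessel networks, plus rasterization primitives. All generators are
# pure functions of their arguments and the seed.

#' Rasterize spheres into a label volume
#'
#' Voxel membership: voxel centre within the radius (`dist <= r`), so the
#' voxel count of a digital sphere is reproducible. Earlier spheres win
#' where spheres would overlap.
#'
#' @param shape integer length-3 `(z, y, x)` volume shape.
#' @param centers matrix (n x 3) of 0-based `(z, y, x)` centres.
#' @param radii numeric vector of radii (voxels).
#' @return A [as_label_volume()] object with labels `1..n`.
#' @export
rasterize_spheres <- function(shape, centers, radii) {
  a <- array(0L, shape)
  for (i in seq_len(nrow(centers))) {
    r <- radii[i]; ctr <- centers[i, ]
    box <- lapply(1:3, function(ax) {
      lo <- max(0, floor(ctr[ax] - r)); hi <- min(shape[ax] - 1, ceiling(ctr[ax] + r))
      lo:hi
    })
    dz <- box[[1]] - ctr[1]; dy <- box[[2]] - ctr[2]; dx <- box[[3]] - ctr[3]
    d2 <- outer(outer(dz^2, dy^2, `+`), dx^2, `+`)
    sub <- a[box[[1]] + 1L, box[[2]] + 1L, box[[3]] + 1L, drop = FALSE]
    sub[d2 <= r^2 & sub == 0L] <- i
    a[box[[1]] + 1L, box[[2]] + 1L, box[[3]] + 1L] <- sub
  }
  as_label_volume(a)
}

#' Rasterize tubes (polyline segments with a radius) into a mask
#'
#' A voxel belongs to a tube when its centre lies within `radius` of the
#' segment (distance-to-polyline rasterization, matching thin vessel
#' morphologies).
#'
#' @param shape integer length-3 `(z, y, x)`.
#' @param segments matrix (n x 6): rows `(z0, y0, x0, z1, y1, x1)`, 0-based.
#' @param radius tube radius, recycled over segments.
#' @return Logical 3D array.
#' @export
rasterize_tubes <- function(shape, segments, radius) {
  mask <- array(FALSE, shape)
  radius <- rep_len(radius, nrow(segments))
  for (i in seq_len(nrow(segments))) {
    p0 <- segments[i, 1:3]; p1 <- segments[i, 4:6]; r <- radius[i]
    lo <- pmax(0, floor(pmin(p0, p1) - r))
    hi <- pmin(shape - 1, ceiling(pmax(p0, p1) + r))
    if (any(hi < lo)) next
    box <- lapply(1:3, function(ax) lo[ax]:hi[ax])
    g <- expand.grid(z = box[[1]], y = box[[2]], x = box[[3]])
    v <- p1 - p0
    len2 <- sum(v^2)
    w <- cbind(g$z - p0[1], g$y - p0[2], g$x - p0[3])
    t_par <- if (len2 > 0) pmin(pmax(as.vector(w %*% v) / len2, 0), 1) else 0
    dvec <- w - outer(t_par, v)
    inside <- rowSums(dvec^2) <= r^2
    sub <- mask[box[[1]] + 1L, box[[2]] + 1L, box[[3]] + 1L, drop = FALSE]
    sub <- sub | array(inside, dim(sub))
    mask[box[[1]] + 1L, box[[2]] + 1L, box[[3]] + 1L] <- sub
  }
  mask
}

#' Generate a synthetic 3D label volume of a given morphotype
#'
#' Three super-morphotypes span the range from convex cells to vessel
#' networks: `"convex"` packs non-overlapping spheres (optionally nearly
#' touching), `"branched"` builds tube objects whose 2-5 segments meet at a
#' junction (Y-like shapes whose in-plane slices near the fork split into
#' multiple 2D regions), and `"network"` grows a random tree of thin tubes
#' (radius 1-3). Deterministic given the seed.
#'
#' @param morphotype `"convex"`, `"branched"` or `"network"`.
#' @param shape integer length-3 `(z, y, x)`, each component >= 16.
#' @param n_objects number of objects to place.
#' @param radius_range length-2 `(min, max)` object radius in voxels
#'   (sphere radius / tube half-thickness).
#' @param seed integer RNG seed.
#' @param min_gap minimum gap between convex objects (voxels).
#' @return A [as_label_volume()] with labels `1..n_objects`.
#' @export
synthetic_labels <- function(morphotype = c("convex", "branched", "network"),
                             shape = c(64L, 64L, 64L), n_objects = 4L,
                             radius_range = c(8, 12), seed = 1L,
                             min_gap = 2) {
  morphotype <- match.arg(morphotype)
  shape <- as.integer(shape)
  if (any(shape < 16L)) stop("shape components must be >= 16")
  if (radius_range[1] > radius_range[2]) stop("radius_range min must be <= max")
  set.seed(seed)
  switch(morphotype,
    convex   = synth_convex(shape, n_objects, radius_range, min_gap),
    branched = synth_branched(shape, n_objects, radius_range),
    network  = synth_network(shape, n_objects, radius_range))
}

synth_convex <- function(shape, n_objects, radius_range, min_gap) {
  centers <- matrix(0, 0, 3)
  radii <- numeric(0)
  for (i in seq_len(n_objects)) {
    placed <- FALSE
    for (try in seq_len(500L)) {
      r <- stats::runif(1, radius_range[1], radius_range[2])
      if (any(shape - 1 < 2 * r + 2)) next
      ctr <- vapply(1:3, function(ax) stats::runif(1, r + 1, shape[ax] - r - 2), 0)
      ok <- !length(radii) ||
        all(sqrt(rowSums(sweep(centers, 2, ctr)^2)) >= radii + r + min_gap)
      if (ok) {
        centers <- rbind(centers, ctr); radii <- c(radii, r)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("placement failure: could not fit ", n_objects,
           " objects of radius ", radius_range[1], "-", radius_range[2],
           " into shape ", paste(shape, collapse = "x"))
  }
  rasterize_spheres(shape, centers, radii)
}

# One branched object: a stem descending in z from a junction, and 1-4
# branches ascending at 30-60 degrees from +z, distinct azimuths.
branched_segments <- function(ctr, extent, n_branch) {
  dir_stem <- c(-1, stats::runif(1, -0.2, 0.2), stats::runif(1, -0.2, 0.2))
  dir_stem <- dir_stem / sqrt(sum(dir_stem^2))
  len <- extent * stats::runif(1, 0.55, 0.8)
  segs <- matrix(c(ctr, ctr + dir_stem * len), 1, 6)
  az0 <- stats::runif(1, 0, 2 * pi)
  for (b in seq_len(n_branch)) {
    polar <- stats::runif(1, pi / 6, pi / 3)
    az <- az0 + 2 * pi * (b - 1) / n_branch + stats::runif(1, -0.3, 0.3)
    d <- c(cos(polar), sin(polar) * cos(az), sin(polar) * sin(az))
    len_b <- extent * stats::runif(1, 0.55, 0.85)
    segs <- rbind(segs, c(ctr, ctr + d * len_b))
  }
  segs
}

synth_branched <- function(shape, n_objects, radius_range) {
  a <- array(0L, shape)
  cells <- partition_regions(shape, n_objects)
  for (i in seq_len(n_objects)) {
    reg <- cells[[i]]
    r <- stats::runif(1, radius_range[1], radius_range[2])
    ctr <- (reg$lo + reg$hi) / 2 + stats::runif(3, -2, 2)
    extent <- min(reg$hi - reg$lo) / 2 - r - 1
    if (extent < 4) stop("placement failure: region too small for branched object")
    n_branch <- sample(1:4, 1)
    segs <- branched_segments(ctr, extent, n_branch)
    m <- rasterize_tubes(shape, segs, r)
    a[m & a == 0L] <- i
  }
  as_label_volume(a)
}

synth_network <- function(shape, n_objects, radius_range) {
  a <- array(0L, shape)
  cells <- partition_regions(shape, n_objects)
  r_lo <- max(1, radius_range[1]); r_hi <- min(3, max(radius_range[2], 1))
  if (r_hi < r_lo) r_hi <- r_lo
  for (i in seq_len(n_objects)) {
    reg <- cells[[i]]
    margin <- r_hi + 1
    n_nodes <- sample(5:9, 1)
    nodes <- vapply(1:3, function(ax)
      stats::runif(n_nodes, reg$lo[ax] + margin, reg$hi[ax] - margin),
      numeric(n_nodes))
    segs <- NULL
    for (k in 2:n_nodes) {   # random tree: attach to nearest earlier node
      prev <- matrix(nodes[seq_len(k - 1), ], ncol = 3)
      d <- sqrt(rowSums(sweep(prev, 2, nodes[k, ])^2))
      j <- which.min(d)
      segs <- rbind(segs, c(prev[j, ], nodes[k, ]))
    }
    radius <- stats::runif(nrow(segs), r_lo, r_hi)
    m <- rasterize_tubes(shape, segs, radius)
    a[m & a == 0L] <- i
  }
  as_label_volume(a)
}

# Partition the volume into n roughly equal boxes (greedy splits of the
# longest axis) so multiple tube objects never intersect.
partition_regions <- function(shape, n) {
  regions <- list(list(lo = c(0, 0, 0), hi = shape - 1))
  while (length(regions) < n) {
    sizes <- vapply(regions, function(r) prod(r$hi - r$lo + 1), 0)
    k <- which.max(sizes)
    reg <- regions[[k]]
    ax <- which.max(reg$hi - reg$lo)
    mid <- floor((reg$lo[ax] + reg$hi[ax]) / 2)
    r1 <- reg; r1$hi[ax] <- mid
    r2 <- reg; r2$lo[ax] <- mid + 1
    regions <- c(regions[-k], list(r1, r2))
  }
  regions[seq_len(n)]
}
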