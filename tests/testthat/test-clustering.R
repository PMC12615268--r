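# Density rasterization, attractor thresholds, component labelling and
# label back-mapping.

traj_from <- function(coords0, coordsT, shape) {
  structure(list(coords0 = coords0, coordsT = coordsT, shape = shape),
            class = "trajectory_set")
}

test_that("density rasterization conserves mass, floors and clips", {
  shape <- c(16, 16, 16)
  pts <- matrix(rep(c(8, 8, 8), 100), ncol = 3, byrow = TRUE)
  tr <- traj_from(pts, pts, shape)
  rho <- rasterize_density(tr, shape, sigma = 1)
  expect_equal(sum(rho), 100, tolerance = 1e-6)
  expect_equal(which.max(rho), which(array(seq_len(16^3), shape) ==
                                     1 + 8 + 16 * (8 + 16 * 8)))
  # two groups 20 voxels apart give two local maxima
  shape2 <- c(8, 8, 32)
  pts2 <- rbind(matrix(rep(c(4, 4, 5), 50), ncol = 3, byrow = TRUE),
                matrix(rep(c(4, 4, 25), 50), ncol = 3, byrow = TRUE))
  rho2 <- rasterize_density(traj_from(pts2, pts2, shape2), shape2, 1)
  expect_equal(rho2[5, 5, 6], max(rho2[, , 1:16]))
  expect_equal(rho2[5, 5, 26], max(rho2[, , 17:32]))
  # floor then clip: (-0.4, 5.2, 7.9) lands at voxel (0, 5, 7)
  tr3 <- traj_from(rbind(c(0, 5, 7)), rbind(c(-0.4, 5.2, 7.9)), shape)
  rho3 <- rasterize_density(tr3, shape, sigma = 0)
  expect_equal(which(rho3 != 0), 1 + 0 + 16 * (5 + 16 * 7))
})

test_that("the mean + k sd threshold separates cluster cores from background", {
  shape <- c(12, 12, 24)
  pts <- rbind(matrix(rep(c(6, 6, 5), 60), ncol = 3, byrow = TRUE),
               matrix(rep(c(6, 6, 18), 60), ncol = 3, byrow = TRUE))
  rho <- rasterize_density(traj_from(pts, pts, shape), shape, 1)
  m <- threshold_density(rho, k = 0)
  expect_identical(m > 0, rho > mean(rho) + 0 * sd(rho))  # definition
  expect_true(m[7, 7, 6]); expect_true(m[7, 7, 19])
  expect_false(m[2, 2, 12])
  # monotone in k, and empty for huge k
  m1 <- threshold_density(rho, k = 1)
  expect_true(all(!m1 | m))
  expect_false(any(threshold_density(rho, k = 1e6)))
})

test_that("attractor labelling matches a flood-fill oracle on random masks", {
  set.seed(16)
  for (rep in 1:5) {
    m <- array(runif(20^3) < 0.08, c(20, 20, 20))
    lab <- label_attractors(m, connectivity = 6L)
    # 3D flood-fill oracle via repeated 2D union is messy; use a simple
    # 6-neighbour BFS here
    oracle <- array(0L, dim(m)); nid <- 0L
    for (s in which(m)) {
      if (oracle[s] != 0L) next
      nid <- nid + 1L; queue <- s; oracle[s] <- nid
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        idx <- arrayInd(cur, dim(m))
        for (ax in 1:3) for (dd in c(-1L, 1L)) {
          nb <- idx; nb[ax] <- nb[ax] + dd
          if (any(nb < 1L) || any(nb > dim(m))) next
          q <- nb[1] + 20L * (nb[2] - 1L + 20L * (nb[3] - 1L))
          if (m[q] && oracle[q] == 0L) { oracle[q] <- nid; queue <- c(queue, q) }
        }
      }
    }
    expect_identical(max(unclass(lab)), nid)
  }
  # two disjoint blobs -> labels {1, 2}; empty mask -> none
  m2 <- array(FALSE, c(10, 10, 10)); m2[2:3, 2:3, 2:3] <- TRUE; m2[7:8, 7:8, 7:8] <- TRUE
  expect_setequal(setdiff(unique(c(unclass(label_attractors(m2)))), 0L), 1:2)
  expect_identical(max(unclass(label_attractors(array(FALSE, c(4, 4, 4))))), 0L)
})

test_that("labels map back to the initial voxels with zero-assignment accounting", {
  shape <- c(10, 10, 20)
  att <- array(0L, shape); att[5:6, 5:6, 3:4] <- 1L; att[5:6, 5:6, 16:17] <- 2L
  att <- as_label_volume(att)
  coords0 <- rbind(c(1, 1, 1), c(8, 8, 18), c(0, 0, 10))
  coordsT <- rbind(c(4.2, 4.7, 2.3), c(5.1, 4.9, 16.4), c(0, 0, 10))
  tr <- traj_from(coords0, coordsT, shape)
  out <- assign_labels(tr, att)
  a <- unclass(out)
  expect_identical(a[2, 2, 2], 1L)
  expect_identical(a[9, 9, 19], 2L)
  expect_identical(a[1, 1, 11], 0L)   # landed on sub-threshold density
  expect_identical(attr(out, "n_unassigned"), 1L)
  expect_equal(attr(out, "frac_unassigned"), 1 / 3)
})

test_that("segmentation with T = 0 equals connected components of B", {
  pair <- touching_sphere_pair(c(32, 32, 64), r = 9)
  B <- unclass(pair)[, , ] > 0L
  f <- structure(list(z = array(0, dim(B)), y = array(0, dim(B)),
                      x = array(0, dim(B))), class = "gradient_field3d")
  seg <- segment_volume(B, f, descent_params(T = 0))
  cc <- orthoseg3d:::label_components(B * 1L, 26L)
  expect_identical(unclass(seg$labels)[, , ], cc[, , ])
  expect_identical(max(cc), 1L)   # touching spheres form one component
})

test_that("ideal convex fixtures segment to one label per object on B exactly", {
  lab <- synthetic_labels("convex", c(48, 48, 48), 4, c(6, 8), seed = 17)
  ovs <- slice_orthoviews(lab)
  B <- fuse_foreground(ovs)
  f <- fuse_gradients(orthoview_gradients(ovs, "edt"), dim(B), mask = B)
  seg <- segment_volume(B, f, descent_params(T = 200, tau = 0.5))
  a <- unclass(seg$labels)
  expect_identical(length(setdiff(unique(as.vector(a)), 0L)), 4L)
  # voxel conservation: positive labels exactly on B minus unassigned
  expect_identical(sum(a > 0L) + seg$n_unassigned, sum(B))
  expect_true(all(a[!B] == 0L))
  # per-object IoU = 1 for separated spheres
  expect_true(all(matched_ious(seg$labels, lab) == 1))
})

test_that("larger density smoothing merges attractors monotonically", {
  pair <- touching_sphere_pair(c(36, 36, 72), r = 10)
  ovs <- slice_orthoviews(pair)
  B <- fuse_foreground(ovs)
  f <- fuse_gradients(orthoview_gradients(ovs, "edt"), dim(B), mask = B)
  coords <- which(B, arr.ind = TRUE) - 1
  colnames(coords) <- NULL
  tr <- advect(coords, f, descent_params(T = 150, tau = 0.5))
  n_lab <- vapply(c(0.5, 1, 1.2, 2), function(sg) {
    rho <- rasterize_density(tr, dim(B), sg)
    att <- label_attractors(threshold_density(rho, 0), 26L)
    max(unclass(assign_labels(tr, att)))
  }, 0L)
  expect_true(all(diff(n_lab) <= 0L))
})
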