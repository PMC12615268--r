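# QC filters, label diffusion and guided-filter refinement.

test_that("small cells are removed and labels reduced to one component", {
  a <- array(0L, c(20, 20, 20))
  a[2:11, 2:11, 2:6] <- 1L          # 500 voxels
  a[15:17, 15:17, 15:17] <- 2L      # 27 voxels
  a[2:4, 15:17, 15:17] <- 1L        # disconnected 27-voxel shard of label 1
  out <- filter_small(as_label_volume(a), min_size = 100L)
  b <- unclass(out)
  expect_identical(sort(unique(as.vector(b))), c(0L, 1L))   # label 2 gone
  expect_identical(sum(b == 1L), 500L)                       # shard gone
  # min_size 0 with contiguous labels is the identity
  c0 <- array(0L, c(8, 8, 8)); c0[2:4, 2:4, 2:4] <- 1L
  expect_identical(unclass(filter_small(as_label_volume(c0), 0L))[, , ],
                   c0[, , ])
})

test_that("gradient-consistency keeps self-consistent cells, drops random ones", {
  lab <- rasterize_spheres(c(32, 32, 32), rbind(c(15, 15, 15)), 10)
  ovs <- slice_orthoviews(lab)
  B <- unclass(lab)[, , ] > 0L
  field <- fuse_gradients(orthoview_gradients(ovs, "edt"), dim(B), mask = B)
  kept <- filter_gradient_inconsistent(lab, field, "edt", 0.85)
  expect_identical(unclass(kept)[, , ], unclass(lab)[, , ])
  expect_lt(attr(kept, "mae")[["1"]], 0.05)   # self-consistency: MAE ~ 0
  # Monte-Carlo expectation of the MAE for two independent random unit
  # fields (per-component absolute difference, averaged)
  set.seed(20)
  ru <- function(n) {
    v <- matrix(rnorm(3 * n), n, 3)
    v / sqrt(rowSums(v^2))
  }
  mc <- mean(abs(ru(20000) - ru(20000)))
  expect_gt(mc, 0.6)   # expected per-component error of unrelated unit fields
  # a cell whose descent field was pure noise scores the random-pair MAE
  # and is removed once the threshold sits below that expectation
  set.seed(21)
  rnd <- array(rnorm(3 * length(B)), c(dim(B), 3))
  mag <- sqrt(rnd[, , , 1]^2 + rnd[, , , 2]^2 + rnd[, , , 3]^2)
  rand_field <- structure(list(z = rnd[, , , 1] / mag * B,
                               y = rnd[, , , 2] / mag * B,
                               x = rnd[, , , 3] / mag * B),
                          class = "gradient_field3d")
  dropped <- filter_gradient_inconsistent(lab, rand_field, "edt", 0.5)
  expect_identical(max(unclass(dropped)), 0L)
  expect_lt(abs(attr(dropped, "mae")[["1"]] - mc), 0.1)  # MAE ~ MC oracle
  # an infinite threshold is the identity
  keep_all <- filter_gradient_inconsistent(lab, rand_field, "edt", Inf)
  expect_identical(unclass(keep_all)[, , ], unclass(lab)[, , ])
})

test_that("the statistical large-cell filter removes only outliers", {
  # one giant among 40 small cells: only then can a single cell exceed
  # mean + 5 sd (the max z-score of one outlier among n cells is ~sqrt(n))
  a <- array(0L, c(24, 40, 60))
  for (i in 1:40) {   # forty 27-voxel cells
    z <- 2 + (i - 1) %/% 8 * 4; x <- 2 + (i - 1) %% 8 * 4
    a[z:(z + 2), 2:4, x:(x + 2)] <- i
  }
  a[12:21, 8:31, 8:37] <- 41L   # one giant cell (10 x 24 x 30 voxels)
  vols <- tabulate(a[a > 0], 41)
  cutoff <- mean(vols) + 5 * sd(vols)
  expect_gt(vols[41], cutoff)   # the construction really is an outlier
  out <- filter_large(as_label_volume(a), k_vol = 5)
  expect_false(41L %in% unique(as.vector(unclass(out))))
  expect_setequal(setdiff(unique(as.vector(unclass(out))), 0L), 1:40)
  # equal volumes: sd = 0, nothing removed
  eq <- array(0L, c(10, 10, 10))
  eq[2:3, 2:3, 2:3] <- 1L; eq[6:7, 6:7, 6:7] <- 2L
  expect_identical(unclass(filter_large(as_label_volume(eq)))[, , ], eq[, , ])
  # single cell: identity
  one <- array(0L, c(8, 8, 8)); one[2:6, 2:6, 2:6] <- 1L
  expect_identical(unclass(filter_large(as_label_volume(one)))[, , ], one[, , ])
})

test_that("guide blending is the stated convex combination", {
  a <- array(runif(4^3), c(4, 4, 4)); b <- array(runif(4^3), c(4, 4, 4))
  expect_identical(make_guide(a, b, 1), a)
  expect_identical(make_guide(a, b, 0), b)
  expect_equal(make_guide(a, b, 0.5), (a + b) / 2)
  expect_error(make_guide(a, array(1, c(2, 2, 2))), "mismatch")
})

test_that("label diffusion is the identity when clamped and respects edges", {
  lab <- rasterize_spheres(c(20, 20, 20), rbind(c(9, 9, 9)), 6)
  guide <- array(runif(20^3), c(20, 20, 20))
  expect_identical(unclass(diffuse_labels(lab, guide, gamma_clamp = 1))[, , ],
                   unclass(lab)[, , ])
  expect_identical(unclass(diffuse_labels(lab, guide, T_diff = 0L))[, , ],
                   unclass(lab)[, , ])
  # joint mode, uniform guide, two seeds in a corridor: by symmetry the
  # cell-vs-cell decision boundary sits at the spatial midline
  a <- array(0L, c(5, 5, 21))
  a[2:4, 2:4, 2:4] <- 1L
  a[2:4, 2:4, 18:20] <- 2L
  flat <- array(1, c(5, 5, 21))
  outj <- diffuse_labels(as_label_volume(a), flat, alpha_mix = 0.5,
                         gamma_clamp = 0.25, T_diff = 40L, mode = "joint")
  bj <- unclass(outj)
  expect_true(all(which(bj == 1L, arr.ind = TRUE)[, 3] <= 11))
  expect_true(all(which(bj == 2L, arr.ind = TRUE)[, 3] >= 11))
  expect_identical(sum(bj == 1L), sum(bj == 2L))   # mirror symmetry
  # binary mode with a step-edge guide: the refined cell stays confined
  # by the intensity edge while keeping its core
  a1 <- array(0L, c(5, 5, 21)); a1[2:4, 2:4, 2:6] <- 1L
  g2 <- flat; g2[, , 9:21] <- 0
  out2 <- diffuse_labels(as_label_volume(a1), g2, alpha_mix = 1,
                         gamma_clamp = 0.25, T_diff = 40L, pad = 25L)
  b2 <- unclass(out2)
  expect_true(all(b2[2:4, 2:4, 3:5] == 1L))    # core kept
  expect_true(all(b2[, , 10:21] == 0L))        # never crosses the edge
})

test_that("guided filtering returns the mask for a self-guide and blurs for huge eps", {
  lab <- rasterize_spheres(c(24, 24, 24), rbind(c(11, 11, 11)), 7)
  m <- unclass(lab)[, , ] > 0L
  out <- guided_filter_refine(lab, m * 1, r = 4L, eps_gf = 1e-9, pad = 6L)
  expect_gte(iou(unclass(out)[, , ] == 1L, m), 0.99)
  # huge eps ignores the guide: result approaches Otsu of the box-blurred mask
  out2 <- guided_filter_refine(lab, m * 1, r = 4L, eps_gf = 1e6, pad = 6L)
  blur <- orthoseg3d:::box_mean(orthoseg3d:::box_mean(m * 1, 9L), 9L)
  ref <- blur > orthoseg3d:::otsu_thresholds((blur - min(blur)) /
                                             diff(range(blur)), 2L) *
         diff(range(blur)) + min(blur)
  expect_gte(iou(unclass(out2)[, , ] == 1L, ref), 0.8)
  # a bright finger in the guide is recovered into the mask
  a <- array(0L, c(16, 16, 30)); a[5:12, 5:12, 3:12] <- 1L
  guide <- array(0, c(16, 16, 30))
  guide[a == 1L] <- 1
  guide[8:9, 8:9, 13:20] <- 1       # finger of length 8 < r
  out3 <- guided_filter_refine(as_label_volume(a), guide, r = 10L,
                               eps_gf = 1e-4, pad = 8L)
  b3 <- unclass(out3)
  expect_true(all(b3[8:9, 8:9, 14:19] == 1L))
  # voxels far from the cell are never touched
  expect_true(all(b3[, , 29:30] == 0L))
})

test_that("the QC chain reports per-stage removals", {
  a <- array(0L, c(24, 24, 24))
  a[2:11, 2:11, 2:11] <- 1L        # 1000 voxels
  a[14:15, 14:15, 14:15] <- 2L     # 8 voxels: removed as small
  out <- postprocess_chain(as_label_volume(a), min_size = 50L)
  expect_identical(attr(out, "qc_removed")[["small"]], 1L)
  expect_setequal(setdiff(unique(as.vector(unclass(out))), 0L), 1L)
})
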