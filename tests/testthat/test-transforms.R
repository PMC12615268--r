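# 2D distance transforms, attractor sources, skeletons and gradient fields.

disk_mask <- function(n = 21, r = 8) {
  ij <- expand.grid(i = 1:n, j = 1:n)
  matrix((ij$i - (n + 1) / 2)^2 + (ij$j - (n + 1) / 2)^2 <= r^2, n, n)
}

test_that("EDT matches the brute-force oracle on canonical shapes", {
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(edt2d(one)[3, 3], 1)
  sq <- matrix(FALSE, 7, 7); sq[2:6, 2:6] <- TRUE
  expect_equal(edt2d(sq), edt_oracle(sq))
  expect_equal(edt2d(sq)[2, 2], 1)   # corner
  expect_equal(edt2d(sq)[4, 4], 3)   # centre
  bar <- matrix(FALSE, 3, 7); bar[2, 2:6] <- TRUE
  expect_equal(edt2d(bar), edt_oracle(bar))
  expect_true(all(edt2d(bar)[bar] == 1))
  expect_error(edt2d(matrix(FALSE, 4, 4)), "empty mask")
})

test_that("implicit Poisson solves the 5-point stencil exactly", {
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  # single unknown: 4 phi = 1
  expect_equal(poisson_transform(matrix(c(rep(FALSE, 12), TRUE, rep(FALSE, 12)),
                                        5, 5), "none")$phi[3, 3], 0.25)
  # 1 x N bar: matches the direct tridiagonal solve
  for (N in c(3, 7, 15)) {
    bar <- matrix(FALSE, 3, N + 2); bar[2, 2:(N + 1)] <- TRUE
    phi <- poisson_transform(bar, "none")$phi
    A <- diag(4, N)
    for (i in seq_len(N - 1)) { A[i, i + 1] <- -1; A[i + 1, i] <- -1 }
    expect_lt(max(abs(phi[2, 2:(N + 1)] - solve(A, rep(1, N)))), 1e-8)
  }
  # solid disk: radially symmetric with argmax at the centre
  m <- disk_mask()
  phi <- poisson_transform(m, "none")$phi
  expect_equal(which(phi == max(phi), arr.ind = TRUE)[1, ], c(row = 11L, col = 11L))
  expect_equal(phi, t(phi))        # symmetry under transposition
})

test_that("explicit sources attain the interior maximum and carry zero gradient", {
  m <- disk_mask()
  pt <- select_point_source(m)
  tr <- poisson_transform(m, "point", src_idx = pt)
  expect_equal(which.max(tr$phi), pt)
  g <- gradient_field(tr$phi, m, "max", tr$source_idx)
  expect_equal(g$gr[pt], 0); expect_equal(g$gc[pt], 0)
  # power transform keeps the maximiser
  tr2 <- poisson_transform(m, "point", src_idx = pt, power = 2)
  expect_equal(which.max(tr2$phi), pt)
  expect_gte(min(tr2$phi[m]), 0)
  # skeleton variant: maximum lies on the skeleton set
  rect <- matrix(FALSE, 9, 41); rect[3:7, 3:39] <- TRUE
  sk <- which(medial_skeleton2d(rect, 1) & rect)
  trs <- poisson_transform(rect, "skeleton", src_idx = sk)
  expect_true(which.max(trs$phi) %in% sk)
  expect_error(poisson_transform(m, "point", src_idx = 1L), "outside the mask")
})

test_that("geodesic transform orders pixels by within-mask travel time", {
  m <- disk_mask()
  pt <- select_point_source(m)
  tr <- geodesic_transform(m, "point", src_idx = pt)
  expect_equal(tr$phi[pt], 0)
  # agreement with the O(V^2) Dijkstra oracle
  expect_equal(tr$phi[m], dijkstra_oracle(m, pt)[m])
  # L-shaped mask: geodesic, not Euclidean, ordering
  L <- matrix(FALSE, 20, 20); L[2:19, 2:5] <- TRUE; L[16:19, 2:19] <- TRUE
  src <- which(row(L) == 2 & col(L) == 3)[1]
  trL <- geodesic_transform(L, "point", src_idx = src)
  expect_equal(trL$phi[L], dijkstra_oracle(L, src)[L])
  # far arm tip is geodesically farther than Euclidean distance
  tip <- c(17, 18)
  eu <- sqrt((tip[1] - 2)^2 + (tip[2] - 3)^2)
  expect_gt(trL$phi[tip[1], tip[2]], eu)
  # gradients vanish on all source pixels
  sk <- which(medial_skeleton2d(m) & m)
  trs <- geodesic_transform(m, "skeleton", src_idx = sk)
  g <- gradient_field(trs$phi, m, "min", trs$source_idx)
  expect_true(all(g$gr[sk] == 0 & g$gc[sk] == 0))
})

test_that("point source selection stays inside the mask", {
  m <- disk_mask()
  pt <- select_point_source(m)
  expect_equal(arrayInd(pt, dim(m))[1, ], c(11L, 11L))
  # half-annulus whose centroid falls in background
  ij <- expand.grid(i = 1:31, j = 1:31)
  d2 <- (ij$i - 16)^2 + (ij$j - 16)^2
  cres <- matrix(d2 >= 100 & d2 <= 196 & ij$j <= 16, 31, 31)
  ctr <- round(colMeans(which(cres, arr.ind = TRUE)))
  expect_false(cres[ctr[1], ctr[2]])   # centroid is outside the crescent
  expect_true(cres[select_point_source(cres)])
  single <- matrix(FALSE, 4, 4); single[2, 3] <- TRUE
  expect_equal(select_point_source(single), which(single))
})

test_that("skeletons are thin, spanning, and stabilised by smoothing", {
  rect <- matrix(FALSE, 9, 54); rect[3:7, 3:52] <- TRUE
  sk <- medial_skeleton2d(rect, 1)
  expect_true(all(rect[sk]))          # subset of the mask
  # a horizontal path spans the rectangle's long axis interior
  cols_hit <- range(which(apply(sk, 2, any)))
  expect_lt(cols_hit[1], 10); expect_gt(cols_hit[2], 45)
  expect_identical(max(cc2d_oracle(sk * 1L)), 1L)   # connected
  dsk <- medial_skeleton2d(disk_mask(), 1)
  expect_lte(sum(dsk), 12)            # disk erodes to a few central pixels
  # boundary noise: smoothing yields fewer skeleton branch pixels
  set.seed(9)
  noisy <- rect
  edge <- which(rect & !rect[c(2:9, 9), ])
  noisy[sample(edge, 20)] <- FALSE
  branches <- function(s) {
    nb <- orthoseg3d:::box_mean(s * 1, 3) * 9 - s
    sum(s & nb >= 3)                  # junction pixels
  }
  expect_lte(branches(medial_skeleton2d(noisy, 3)),
             branches(medial_skeleton2d(noisy, 0)))
})

test_that("gradient fields are unit-norm, attractor-oriented and masked", {
  m <- disk_mask()
  g <- gradient_field(edt2d(m), m, "max")
  mag <- sqrt(g$gr^2 + g$gc^2)
  expect_true(all(abs(mag[mag > 0] - 1) < 1e-6))
  expect_true(all(mag[!m] == 0))
  # field points inward (toward the centre) off-centre
  ij <- which(m & mag > 0, arr.ind = TRUE)
  to_ctr <- cbind(11 - ij[, 1], 11 - ij[, 2])
  to_ctr <- to_ctr / pmax(sqrt(rowSums(to_ctr^2)), 1e-9)
  dots <- rowSums(cbind(g$gr[m & mag > 0], g$gc[m & mag > 0]) * to_ctr)
  expect_gt(mean(dots > 0), 0.95)
  # flat regions give exact zero vectors
  flat <- matrix(1, 7, 7)
  g0 <- gradient_field(matrix(2, 7, 7), flat, "max")
  expect_true(all(g0$gr == 0 & g0$gc == 0))
})

test_that("per-cell transforms are independent and composited per slice", {
  sl <- matrix(0L, 40, 40)
  ij <- expand.grid(i = 1:40, j = 1:40)
  sl[(ij$i - 10)^2 + (ij$j - 10)^2 <= 36] <- 1L
  g1 <- labels_to_gradients(sl, "edt")
  sl2 <- sl
  sl2[(ij$i - 30)^2 + (ij$j - 30)^2 <= 36] <- 2L
  g2 <- labels_to_gradients(sl2, "edt")
  sel <- sl == 1L
  expect_equal(g1$gr[sel], g2$gr[sel])     # distant cell leaves field unchanged
  expect_equal(g1$gc[sel], g2$gc[sel])
  expect_true(all(g2$proxy >= 0 & g2$proxy <= 1))
  expect_equal(max(g2$proxy[sl2 == 2L]), 1)
  # empty slice: all-zero field and proxy
  g0 <- labels_to_gradients(matrix(0L, 8, 8), "edt")
  expect_true(all(g0$gr == 0 & g0$gc == 0 & g0$proxy == 0))
})

test_that("touching cells' fields point away from the shared boundary", {
  sl <- matrix(0L, 21, 42)
  ij <- expand.grid(i = 1:21, j = 1:42)
  sl[(ij$i - 11)^2 + (ij$j - 11)^2 <= 81] <- 1L
  sl[sl == 0L & (ij$i - 11)^2 + (ij$j - 29)^2 <= 81] <- 2L
  g <- labels_to_gradients(sl, "edt")
  # on the contact column, cell 1 pixels point to lower j, cell 2 to higher j
  contact <- which(sl[, 20] == 1L)
  expect_true(all(g$gc[cbind(contact, 20)] < 0))
  contact2 <- which(sl[, 21] == 2L)
  expect_true(all(g$gc[cbind(contact2, 21)] > 0))
})

test_that("iterated 2D advection converges to the explicit source set", {
  shapes <- list(disk = disk_mask(),
                 bar = { b <- matrix(FALSE, 7, 31); b[2:6, 2:30] <- TRUE; b },
                 ell = { L <- matrix(FALSE, 24, 24); L[2:23, 2:7] <- TRUE
                         L[18:23, 2:23] <- TRUE; L })
  gs <- orthoseg3d:::gaussian_smooth
  for (nm in names(shapes)) {
    m <- shapes[[nm]]
    for (kind in c("poisson_point", "geodesic_point",
                   "poisson_skeleton", "geodesic_skeleton")) {
      tr <- orthoseg3d:::cell_transform(m, kind)
      g <- gradient_field(tr$phi, m, tr$attractor, tr$source_idx)
      # mirror the pipeline: light post-smoothing keeps boundary-hugging
      # points from freezing just outside the mask, then renormalise
      gr <- gs(g$gr, 1); gc <- gs(g$gc, 1)
      mag <- sqrt(gr^2 + gc^2); ok <- mag > 1e-9
      gr <- ifelse(ok, gr / pmax(mag, 1e-300), 0)
      gc <- ifelse(ok, gc / pmax(mag, 1e-300), 0)
      gr[tr$source_idx] <- 0; gc[tr$source_idx] <- 0
      field <- structure(list(z = array(0, c(1, dim(m))),
                              y = array(gr, c(1, dim(m))),
                              x = array(gc, c(1, dim(m)))),
                         class = "gradient_field3d")
      fg <- which(m, arr.ind = TRUE)
      coords <- cbind(0, fg[, 1] - 1, fg[, 2] - 1)
      tra <- advect(coords, field, descent_params(T = 200, mu = 0, tau = 0))
      src <- arrayInd(tr$source_idx, dim(m)) - 1
      dmin <- vapply(seq_len(nrow(tra$coordsT)), function(i)
        min(sqrt((tra$coordsT[i, 2] - src[, 1])^2 +
                 (tra$coordsT[i, 3] - src[, 2])^2)), 0)
      expect_lt(quantile(dmin, 0.99), 2)
    }
  }
})
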