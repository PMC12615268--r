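# Shared fixtures and independent brute-force oracles for the test suite.
# Oracles here deliberately avoid the package's own implementations.

# Brute-force 2D connected components by BFS flood fill.
cc2d_oracle <- function(mask, connectivity = 8L) {
  d <- dim(mask)
  lab <- matrix(0L, d[1], d[2])
  offs <- expand.grid(di = -1:1, dj = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  if (connectivity == 4L) offs <- offs[abs(offs$di) + abs(offs$dj) == 1, ]
  nid <- 0L
  for (s in which(mask != 0)) {
    if (lab[s] != 0L) next
    nid <- nid + 1L
    queue <- s
    lab[s] <- nid
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      i <- (cur - 1L) %% d[1] + 1L
      j <- (cur - 1L) %/% d[1] + 1L
      for (k in seq_len(nrow(offs))) {
        ii <- i + offs$di[k]; jj <- j + offs$dj[k]
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2]) next
        q <- ii + (jj - 1L) * d[1]
        if (mask[q] != 0 && lab[q] == 0L) {
          lab[q] <- nid
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# Brute-force Euclidean distance to the nearest background pixel
# (image border counts as background).
edt_oracle <- function(mask) {
  d <- dim(mask)
  pad <- matrix(0, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- mask
  bg <- which(pad == 0, arr.ind = TRUE)
  out <- matrix(0, d[1], d[2])
  for (s in which(mask != 0)) {
    i <- (s - 1L) %% d[1] + 2L
    j <- (s - 1L) %/% d[1] + 2L
    out[s] <- sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2))
  }
  out
}

# O(V^2) Dijkstra on the 8-neighbour pixel graph restricted to a mask.
dijkstra_oracle <- function(mask, sources) {
  d <- dim(mask)
  n <- length(mask)
  dist <- rep(Inf, n)
  dist[sources] <- 0
  done <- rep(FALSE, n)
  done[mask == 0] <- TRUE
  repeat {
    open <- which(!done & is.finite(dist))
    if (!length(open)) break
    cur <- open[which.min(dist[open])]
    done[cur] <- TRUE
    i <- (cur - 1L) %% d[1] + 1L
    j <- (cur - 1L) %/% d[1] + 1L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2]) next
      q <- ii + (jj - 1L) * d[1]
      if (mask[q] == 0) next
      w <- sqrt(di^2 + dj^2)
      if (dist[cur] + w < dist[q]) dist[q] <- dist[cur] + w
    }
  }
  matrix(dist, d[1], d[2])
}

# Best total-IoU assignment by exhaustive permutation enumeration.
assignment_oracle <- function(iou_mat) {
  M <- nrow(iou_mat); N <- ncol(iou_mat)
  n <- max(M, N)
  full <- matrix(0, n, n)
  full[seq_len(M), seq_len(N)] <- iou_mat
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  best <- 0
  for (p in perms(seq_len(n))) {
    tot <- sum(full[cbind(seq_len(n), p)])
    if (tot > best) best <- tot
  }
  best
}

# Two spheres touching along x (integer centres so the contact voxel exists
# and the union is one connected component).
touching_sphere_pair <- function(shape = c(48, 48, 96), r = 12) {
  mid <- floor((shape[1:2] - 1) / 2)
  cx <- floor(shape[3] / 2)
  rasterize_spheres(shape,
                    rbind(c(mid[1], mid[2], cx - r), c(mid[1], mid[2], cx + r)),
                    c(r, r))
}

# Per-object IoU of matched prediction/reference pairs.
matched_ious <- function(pred, ref) {
  mr <- match_instances(pred, ref)
  mr$pairs$iou
}

# Reconstruct a label volume through the full indirect pipeline.
quick_recon <- function(lab, tau = 0.5, T = 250L, transform = "edt", ...) {
  reconstruct_from_reference(
    lab, reconstruction_config(tau = tau, transform = transform,
                               descent = list(T = T), ...))
}
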