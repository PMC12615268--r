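# Intensity conditioning and the semiautomated tuning scores that adapt an
# external 2D predictor: percentile normalization, ratiometric illumination
# correction, gamma correction, ridge enhancement, probability
# normalization/thresholding and diameter scanning.

#' Percentile contrast normalization
#'
#' Linearly maps the `p_lower` percentile of the intensities to 0 and the
#' `p_upper` percentile to 1, clipping outside `[0, 1]`. The defaults
#' (2, 99.8) zero faint background and clip sporadic saturated intensities
#' typical of fluorescence imaging.
#'
#' @param v a `volume` (or plain numeric array).
#' @param p_lower,p_upper percentiles in `[0, 100]`, `p_lower < p_upper`.
#' @return Same shape, values in `[0, 1]`.
#' @export
normalize_percentile <- function(v, p_lower = 2, p_upper = 99.8) {
  stopifnot(p_lower < p_upper)
  a <- if (inherits(v, "volume")) vol_data(v) else v
  if (length(unique(as.vector(a))) < 2L)
    stop("constant image: percentile normalization is undefined")
  q <- stats::quantile(a, c(p_lower, p_upper) / 100, names = FALSE)
  if (q[2] <= q[1]) stop("degenerate percentiles: image nearly constant")
  out <- pmin(pmax((a - q[1]) / (q[2] - q[1]), 0), 1)
  if (inherits(v, "volume")) as_volume(out, vol_spacing(v)) else out
}

#' Ratiometric uneven-illumination correction
#'
#' Divides the image by a smooth background estimate and restores the mean
#' intensity: `mean(I) * I / I_bg`, where `I_bg` is the image downsampled
#' by `ds`, Gaussian-smoothed with `sigma_bg`, and upsampled back.
#'
#' @param v non-negative `volume` or array.
#' @param sigma_bg Gaussian width of the background estimate (voxels at the
#'   downsampled scale). Default 5.
#' @param ds integer downsampling factor (1 = smooth at full resolution).
#'   Default 8.
#' @param eps small additive guard against division by zero.
#' @return Corrected image, same shape.
#' @export
correct_illumination <- function(v, sigma_bg = 5, ds = 8L, eps = 1e-8) {
  stopifnot(sigma_bg > 0, ds >= 1)
  a <- if (inherits(v, "volume")) vol_data(v) else v
  if (min(a) < 0) stop("image must be non-negative")
  d <- dim(a)
  bg <- a
  if (ds > 1) {
    small <- pmax(1L, as.integer(round(d / ds)))
    for (ax in seq_along(d)) bg <- resample_axis(bg, ax, small[ax], "linear")
  }
  bg <- gaussian_smooth(bg, sigma_bg)
  if (ds > 1) for (ax in seq_along(d)) bg <- resample_axis(bg, ax, d[ax], "linear")
  n_zero <- sum(bg <= 0)
  if (n_zero > 0)
    message("illumination correction: ", n_zero,
            " background voxels <= 0 guarded by eps")
  out <- mean(a) * a / (bg + eps)
  if (inherits(v, "volume")) as_volume(out, vol_spacing(v)) else out
}

#' Gamma correction
#'
#' Rescales the image linearly to `[0, 1]` by its min/max and raises it to
#' the power `g` in `(0, 1]`, non-linearly amplifying low intensities.
#'
#' @param v `volume` or array.
#' @param g exponent in `(0, 1]`.
#' @return Corrected image in `[0, 1]`.
#' @export
gamma_correct <- function(v, g) {
  if (g <= 0 || g > 1) stop("g must lie in (0, 1]")
  a <- if (inherits(v, "volume")) vol_data(v) else v
  rng <- range(a)
  scaled <- if (rng[2] > rng[1]) (a - rng[1]) / (rng[2] - rng[1]) else array(0, dim(a))
  out <- scaled^g
  if (inherits(v, "volume")) as_volume(out, vol_spacing(v)) else out
}

# 2D Hessian-eigenvalue ridge response at one scale.
# Bright ridges have a strongly negative cross-sectional eigenvalue; the
# response is sigma^2 * max(-lambda_min, 0) (scale-normalised second
# derivative, the Meijering-family measure without its neighbour mixing).
ridge_response_2d <- function(sl, sigma) {
  s <- gaussian_smooth(sl, sigma)
  d1 <- central_diff(s, 1L); d2 <- central_diff(s, 2L)
  h11 <- central_diff(d1, 1L); h22 <- central_diff(d2, 2L)
  h12 <- central_diff(d1, 2L)
  tr <- h11 + h22
  disc <- sqrt(pmax((h11 - h22)^2 + 4 * h12^2, 0))
  lambda_min <- (tr - disc) / 2
  sigma^2 * pmax(-lambda_min, 0)
}

#' Ridge (vessel-like feature) enhancement
#'
#' Hessian-eigenvalue ridge filter pooling the maximum response over a set
#' of Gaussian scales. 3D volumes are processed slice-by-slice in-plane
#' (z-slices). Response is non-negative and zero on flat regions.
#'
#' @param v `volume`, 3D array or 2D matrix.
#' @param sigmas Gaussian scales (voxels), at least one.
#' @return Non-negative response, same shape.
#' @export
enhance_ridges <- function(v, sigmas = c(1, 2, 3)) {
  stopifnot(length(sigmas) >= 1, all(sigmas > 0))
  a <- if (inherits(v, "volume")) vol_data(v) else v
  one <- function(sl) {
    out <- array(0, dim(sl))
    for (s in sigmas) out <- pmax(out, ridge_response_2d(sl, s))
    out
  }
  if (length(dim(a)) == 2L) {
    out <- one(a)
  } else {
    out <- a
    for (z in seq_len(dim(a)[1])) out[z, , ] <- one(a[z, , ])
  }
  if (inherits(v, "volume")) as_volume(out, vol_spacing(v)) else out
}

#' Normalize raw cell-probability logits to [0, 1]
#'
#' Clips to `[-88.72, 88.72]` (the IEEE float32 overflow guard) and applies
#' the logistic transform `1 / (1 + exp(-p))`. Strictly increasing.
#'
#' @param p_raw numeric array of raw logits.
#' @return Same shape, values in `(0, 1)`.
#' @export
normalize_probability <- function(p_raw) {
  p <- pmin(pmax(p_raw, -88.72), 88.72)
  1 / (1 + exp(-p))
}

# Multi-class Otsu on a 256-bin histogram of values in [0,1].
# Returns 1 threshold (classes=2) or 2 thresholds (classes=3), as bin-edge
# values maximizing the between-class variance.
otsu_thresholds <- function(p, classes = 2L, n_bins = 256L) {
  if (length(unique(as.vector(p))) < 2L)
    stop("constant probability map: Otsu threshold undefined")
  h <- tabulate(pmin(pmax(floor(p * n_bins), 0), n_bins - 1) + 1L, n_bins)
  w <- h / sum(h)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  cw <- cumsum(w)
  cm <- cumsum(w * centers)
  total_mean <- cm[n_bins]
  class_stat <- function(lo, hi) {  # bins lo..hi (1-based, inclusive)
    wk <- cw[hi] - if (lo > 1) cw[lo - 1] else 0
    mk <- cm[hi] - if (lo > 1) cm[lo - 1] else 0
    ifelse(wk > 0, mk^2 / wk, 0)
  }
  if (classes == 2L) {
    t_cand <- seq_len(n_bins - 1L)
    crit <- vapply(t_cand, function(t) class_stat(1L, t) + class_stat(t + 1L, n_bins), 0)
    # empty bins leave the criterion flat: take the middle of the plateau
    plateau <- which(crit >= max(crit) - 1e-12)
    best <- t_cand[plateau[ceiling(length(plateau) / 2)]]
    return(best / n_bins)
  }
  best_val <- -Inf; best_pair <- c(1L, 2L)
  for (t1 in seq_len(n_bins - 2L)) {
    t2 <- (t1 + 1L):(n_bins - 1L)
    crit <- class_stat(1L, t1) +
      vapply(t2, function(b) class_stat(t1 + 1L, b) + class_stat(b + 1L, n_bins), 0)
    k <- which.max(crit)
    if (crit[k] > best_val) { best_val <- crit[k]; best_pair <- c(t1, t2[k]) }
  }
  best_pair / n_bins
}

#' Automatic probability threshold via multi-class Otsu
#'
#' Computes a 2- or 3-class Otsu threshold on the histogram of a normalised
#' probability map. For 3 classes, `pick` selects the lower or higher of
#' the two thresholds (use the lower when segmentation only partially
#' captures cells, the higher when too much area is segmented). The result
#' is floored at `floor` (a minimum threshold suppressing spurious
#' foreground on empty images) and optionally rounded down to one decimal.
#'
#' @param p probability map in `[0, 1]`.
#' @param classes 2 or 3.
#' @param pick `"only"` (2-class), `"lower"` or `"higher"` (3-class).
#' @param floor minimum returned threshold (default 0.25).
#' @param round_down round the threshold down to the nearest 0.1.
#' @return A single threshold in `[0, 1]`.
#' @export
auto_threshold_probability <- function(p, classes = 2L,
                                       pick = c("only", "lower", "higher"),
                                       floor = 0.25, round_down = FALSE) {
  pick <- match.arg(pick)
  stopifnot(classes %in% c(2L, 3L))
  if (min(p) < 0 || max(p) > 1) stop("p must lie in [0, 1]")
  th <- otsu_thresholds(p, classes)
  sel <- if (classes == 2L) th[1] else switch(pick,
    only = stop("pick = 'only' requires classes = 2"),
    lower = th[1], higher = th[2])
  out <- max(sel, floor)
  if (round_down) out <- base::floor(out * 10) / 10
  out
}

#' Gradient-sharpness contrast score
#'
#' Mean over pixels of `w * (sd_N(gx) + sd_N(gy))`, where `sd_N` is the
#' local population standard deviation over a `P x P` window (symmetric
#' edge padding) and `w` the per-pixel weight (`p` when `use_p`, else 1).
#' Zero iff both gradient components are locally constant everywhere.
#'
#' @param gx,gy 2D gradient component images (same shape).
#' @param p optional per-pixel weights (normalised probability).
#' @param P odd window width (>= 1).
#' @param use_p weight by `p` instead of 1.
#' @return Non-negative scalar.
#' @export
contrast_score <- function(gx, gy, p = NULL, P = 3L, use_p = !is.null(p)) {
  if (!identical(dim(gx), dim(gy))) stop("gx and gy shapes differ")
  if (P < 1L || P %% 2L == 0L) stop("P must be an odd positive integer")
  w <- if (use_p) {
    if (is.null(p)) stop("use_p = TRUE but no p given")
    if (!identical(dim(p), dim(gx))) stop("p shape differs")
    p
  } else 1
  mean(w * (local_sd(gx, P) + local_sd(gy, P)))
}

# Centered moving average with symmetric edge padding.
moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  r <- (window - 1L) %/% 2L
  idx <- vapply(seq_along(x), function(i)
    mean(x[reflect_index((i - r):(i + r), length(x))]), 0)
  idx
}

#' Scan predictor diameters by contrast score
#'
#' Runs an external 2D predictor callback over a range of object diameters
#' and scores the sharpness of its predicted gradients; the smoothed score
#' curve peaks at the diameter best matched to the image's object scale.
#'
#' @param predictor `function(image2d, diameter)` returning a list with
#'   elements `gx`, `gy` and (optionally) `p_raw` (raw logits).
#' @param image2d the 2D image handed to the predictor.
#' @param d_low,d_high,step diameter range and increment (defaults 10, 120).
#' @param P local-deviation window width for the score.
#' @param window centred moving-average window for smoothing (odd; 1 keeps
#'   the raw scores).
#' @param use_p weight the score by the predictor's normalised probability.
#' @return A `diameter_scan` object: a tibble of `diameter`, `score` and
#'   `smoothed`, with the optimum in `attr(, "d_opt")`. `tidy()`,
#'   `glance()` and `autoplot()` methods are provided.
#' @export
scan_diameter <- function(predictor, image2d, d_low = 10, d_high = 120,
                          step = 2.5, P = 3L, window = 5L, use_p = FALSE) {
  stopifnot(is.function(predictor), d_low < d_high)
  ds <- seq(d_low, d_high, by = step)
  scores <- vapply(ds, function(d) {
    out <- tryCatch(predictor(image2d, d), error = function(e)
      stop("predictor failed at diameter ", d, ": ", conditionMessage(e)))
    p <- if (use_p && !is.null(out$p_raw)) normalize_probability(out$p_raw) else NULL
    contrast_score(out$gx, out$gy, p = p, P = P, use_p = use_p && !is.null(p))
  }, 0)
  smoothed <- moving_average(scores, window)
  curve <- tibble::tibble(diameter = ds, score = scores, smoothed = smoothed)
  structure(curve, d_opt = ds[which.max(smoothed)], window = window,
            class = c("diameter_scan", class(curve)))
}

#' Pick a reference slice from a volume
#'
#' @param v a `volume`.
#' @param strategy `"focus"` (highest mean Sobel gradient magnitude),
#'   `"intensity"` (highest mean intensity), `"mid"` (middle slice) or
#'   `"index"` (user-chosen).
#' @param index slice index for `strategy = "index"` (1-based).
#' @return 1-based z-slice index.
#' @export
select_reference_slice <- function(v, strategy = c("focus", "intensity", "mid", "index"),
                                   index = NULL) {
  strategy <- match.arg(strategy)
  a <- if (inherits(v, "volume")) vol_data(v) else v
  nz <- dim(a)[1]
  switch(strategy,
    mid = nz %/% 2L + 1L,
    index = {
      if (is.null(index) || index < 1L || index > nz) stop("index out of range")
      as.integer(index)
    },
    intensity = which.max(vapply(seq_len(nz), function(z) mean(a[z, , ]), 0)),
    focus = which.max(vapply(seq_len(nz), function(z) {
      sl <- a[z, , ]
      gx <- filter_axis(filter_axis(sl, 1L, c(-1, 0, 1)), 2L, c(1, 2, 1) / 4)
      gy <- filter_axis(filter_axis(sl, 2L, c(-1, 0, 1)), 1L, c(1, 2, 1) / 4)
      mean(sqrt(gx^2 + gy^2))
    }, 0)))
}
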