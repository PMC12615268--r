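# Broom-style tidiers and ggplot2 autoplot methods for the tabular result
# types (metric curves, diameter scans, segmentations).

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy metric_curves
#' @export
tidy.metric_curves <- function(x, ...) {
  tibble::tibble(threshold = rep(x$threshold, 2),
                 metric = rep(c("AP", "F1"), each = nrow(x)),
                 value = c(x$ap, x$f1))
}

#' @method glance metric_curves
#' @export
glance.metric_curves <- function(x, ...) {
  tibble::tibble(ap_0.5 = x$ap[1], f1_0.5 = x$f1[1],
                 mean_ap = mean(x$ap), mean_f1 = mean(x$f1),
                 mean_matched_iou = attr(x, "mean_matched_iou"))
}

#' @method autoplot metric_curves
#' @export
autoplot.metric_curves <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "IoU threshold", y = "score", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method tidy diameter_scan
#' @export
tidy.diameter_scan <- function(x, ...) tibble::as_tibble(unclass(x))

#' @method glance diameter_scan
#' @export
glance.diameter_scan <- function(x, ...) {
  tibble::tibble(d_opt = attr(x, "d_opt"),
                 max_score = max(x$smoothed),
                 window = attr(x, "window"))
}

#' @method autoplot diameter_scan
#' @export
autoplot.diameter_scan <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diameter)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$score), colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(object, "d_opt"), linetype = 2) +
    ggplot2::labs(x = "diameter (px)", y = "contrast score") +
    ggplot2::theme_minimal()
}

#' @method glance consensus_segmentation
#' @export
glance.consensus_segmentation <- function(x, ...) {
  a <- vol_data(x$labels)
  ids <- setdiff(unique(as.vector(a)), 0L)
  tibble::tibble(n_labels = length(ids),
                 n_foreground = sum(a > 0L),
                 frac_unassigned = x$frac_unassigned)
}

#' @method tidy consensus_segmentation
#' @export
tidy.consensus_segmentation <- function(x, ...) {
  a <- vol_data(x$labels)
  ids <- setdiff(sort(unique(as.vector(a))), 0L)
  if (length(ids) == 0L)
    return(tibble::tibble(label = integer(0), voxels = integer(0),
                          z = numeric(0), y = numeric(0), x = numeric(0)))
  ctr <- label_centroids(a, ids)
  tibble::tibble(label = ids, voxels = label_sizes(a)[ids],
                 z = ctr[, 1], y = ctr[, 2], x = ctr[, 3])
}

#' Plot a z-slice of a label volume
#'
#' @param labels a `label_volume` (or array).
#' @param z 1-based slice index (middle slice by default).
#' @return A ggplot object (tiles coloured by label).
#' @export
plot_label_slice <- function(labels, z = NULL) {
  a <- if (inherits(labels, "label_volume")) vol_data(labels) else labels
  if (is.null(z)) z <- dim(a)[1] %/% 2L + 1L
  sl <- a[z, , ]
  df <- expand.grid(y = seq_len(nrow(sl)), x = seq_len(ncol(sl)))
  df$label <- factor(as.vector(sl))
  ggplot2::ggplot(df[df$label != "0", ],
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$label)) +
    ggplot2::geom_tile(show.legend = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0("z = ", z)) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 .data
NULL
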