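# End-to-end orchestration: reconstruct a consensus 3D segmentation from
# per-view 2D inputs (indirect: label masks; direct: predicted gradients
# and probabilities), with optional postprocessing and evaluation.

#' Default reconstruction configuration
#'
#' Bundles the per-stage parameter blocks with the pipeline's working
#' defaults (descent `T = 250`, `mu = 0.95`, `delta = 1`;
#' `sigma_pre = sigma_post = 1`; fusion `alpha = 0.5`, `P = 1` for
#' gradients and 3 for foreground; clustering `sigma = 1`, `k = 0`).
#' Morphotype presets adjust the step-decay `tau`: 0.5 suits convex
#' packings, 2 thin networks.
#'
#' @param mode `"indirect"` (2D label masks in, transform chosen by
#'   `transform`) or `"direct"` (predicted gradients + probabilities in).
#' @param transform 2D transform kind for the indirect mode.
#' @param views views to integrate.
#' @param tau step decay (overridden by `preset`).
#' @param preset optional `"convex"`, `"branched"` or `"network"`.
#' @param ... overrides for any nested block: `fusion`, `descent`,
#'   `cluster`, `qc` (lists).
#' @return Nested configuration list.
#' @export
reconstruction_config <- function(mode = c("indirect", "direct"),
                                  transform = "edt", views = VIEW_NAMES,
                                  tau = 0.5, preset = NULL, ...) {
  mode <- match.arg(mode)
  if (!is.null(preset))
    tau <- switch(preset, convex = 0.5, branched = 0.5, network = 2,
                  stop("unknown preset"))
  cfg <- list(
    mode = mode, transform = transform, views = views,
    fusion = list(P_fg = 3L, P_grad = 1L, alpha = 0.5, epsilon = 1e-20,
                  sigma_pre = 1, sigma_post = 1, fg_threshold = NULL),
    descent = list(T = 250L, delta = 1, mu = 0.95, tau = tau,
                   tile_shape = NULL, overlap_frac = 0.25),
    cluster = list(sigma = 1, k = 0, connectivity = 26L),
    qc = NULL)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  cfg
}

#' Reconstruct a 3D segmentation from 2D orthoview inputs
#'
#' The full consensus pipeline: per-slice 2D gradients (recomputed from
#' label masks in the indirect mode, or supplied in the direct mode),
#' content-based fusion of foreground and gradients, suppressed gradient
#' descent of all foreground voxels, density clustering of the attractors,
#' and back-mapping of cluster IDs to the initial voxels; optionally
#' followed by the QC chain. Deterministic: identical inputs and
#' configuration give identical labels.
#'
#' @param ovs an `orthoview_set` — label kind for the indirect mode,
#'   prob/logit kind for the direct mode.
#' @param config a [reconstruction_config()] list.
#' @param view_grads direct mode: named per-view list of `gr`/`gc` stacks
#'   of predicted 2D gradients (view-ordered, pointing toward cell
#'   centres).
#' @param guide optional guide volume for postprocessing.
#' @return List (class `reconstruction`): `labels`, `B`, `field`,
#'   `segmentation`, `report` (stage parameters and timings).
#' @export
run_reconstruction <- function(ovs, config = reconstruction_config(),
                               view_grads = NULL, guide = NULL) {
  stopifnot(inherits(ovs, "orthoview_set"))
  t_all <- proc.time()[3]
  timings <- c()
  tick <- function(nm, t0) {
    timings[nm] <<- round(proc.time()[3] - t0, 3)
  }
  keep <- intersect(config$views, ov_views(ovs))
  if (length(keep) == 0L) stop("no requested view present in the input")
  ovs <- orthoview_set(ovs$views[keep], ovs$kind)
  fus <- config$fusion
  if (config$mode == "indirect") {
    if (ovs$kind != "label") stop("indirect mode requires label stacks")
    t0 <- proc.time()[3]
    vg <- orthoview_gradients(ovs, config$transform,
                              power = config$power %||% 1)
    tick("gradients", t0)
  } else {
    if (is.null(view_grads)) stop("direct mode requires view_grads")
    if (ovs$kind == "label") stop("direct mode requires probability stacks")
    vg <- view_grads[intersect(names(view_grads), keep)]
  }
  t0 <- proc.time()[3]
  B <- fuse_foreground(ovs, P = fus$P_fg, alpha = fus$alpha,
                       epsilon = fus$epsilon, fg_threshold = fus$fg_threshold)
  field <- fuse_gradients(vg, ovs$shape, P = fus$P_grad, alpha = fus$alpha,
                          epsilon = fus$epsilon, sigma_pre = fus$sigma_pre,
                          sigma_post = fus$sigma_post, mask = B)
  tick("fusion", t0)
  dp <- descent_params(T = config$descent$T, delta = config$descent$delta,
                       mu = config$descent$mu, tau = config$descent$tau)
  cp <- cluster_params(sigma = config$cluster$sigma, k = config$cluster$k,
                       connectivity = config$cluster$connectivity)
  t0 <- proc.time()[3]
  seg <- segment_volume(B, field, dp, cp,
                        tile_shape = config$descent$tile_shape,
                        overlap_frac = config$descent$overlap_frac)
  tick("segment", t0)
  labels <- seg$labels
  if (!is.null(config$qc)) {
    t0 <- proc.time()[3]
    labels <- do.call(postprocess_chain,
                      c(list(labels, field_in = field, guide = guide),
                        config$qc))
    tick("postprocess", t0)
  }
  timings["total"] <- round(proc.time()[3] - t_all, 3)
  structure(list(labels = labels, B = B, field = field, segmentation = seg,
                 report = list(config = config, views = keep,
                               n_labels = length(setdiff(unique(as.vector(labels)), 0L)),
                               frac_unassigned = seg$frac_unassigned,
                               timings = timings)),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat("<reconstruction> ", x$report$n_labels, " labels from views ",
      paste(x$report$views, collapse = ","), " (",
      x$report$timings["total"], " s)\n", sep = "")
  invisible(x)
}

#' Reconstruct directly from a reference label volume
#'
#' Convenience driver for the slice-and-reconstruct protocol: slices the
#' reference into orthoviews and reconstructs it, returning the
#' reconstruction together with its AP/F1 curves against the reference.
#'
#' @param labels reference `label_volume`.
#' @param config a [reconstruction_config()].
#' @param evaluate also compute [ap_f1_curve()] against `labels`.
#' @return List: `recon` (see [run_reconstruction()]) and `metrics`.
#' @export
reconstruct_from_reference <- function(labels, config = reconstruction_config(),
                                       evaluate = TRUE) {
  ovs <- slice_orthoviews(labels, config$views)
  recon <- run_reconstruction(ovs, config)
  metrics <- if (evaluate) ap_f1_curve(recon$labels, labels) else NULL
  list(recon = recon, metrics = metrics)
}

# ---- config files and thin CLI drivers ----------------------------------

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [reconstruction_config()] (`mode`, `transform`,
#' `views`, `fusion`, `descent`, `cluster`, `qc`) plus optional `synth`
#' and `eval` blocks used by the corresponding drivers.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        c("mode", "transform", "views", "tau", "preset",
                          "fusion", "descent", "cluster", "qc", "power"))]
  cfg <- do.call(reconstruction_config, args)
  cfg$synth <- raw$synth
  cfg$eval <- raw$eval
  cfg
}

#' Generate and write a synthetic fixture volume
#'
#' @param cfg list with `morphotype`, `shape`, `n_objects`, `radius_range`,
#'   `seed`.
#' @param out output TIFF path.
#' @return The generated `label_volume`, invisibly.
#' @export
run_synth <- function(cfg, out) {
  lab <- synthetic_labels(cfg$morphotype %||% "convex",
                          shape = unlist(cfg$shape %||% c(64, 64, 64)),
                          n_objects = cfg$n_objects %||% 4L,
                          radius_range = unlist(cfg$radius_range %||% c(8, 12)),
                          seed = cfg$seed %||% 1L)
  write_volume(lab, out)
  invisible(lab)
}

#' Evaluate a predicted against a reference label TIFF
#'
#' @param pred_path,ref_path label TIFF paths.
#' @param restrict optional foreground-restriction overlap fraction.
#' @param out optional JSON output path for the curves.
#' @return The `metric_curves` tibble, invisibly.
#' @export
run_eval <- function(pred_path, ref_path, restrict = NULL, out = NULL) {
  pred <- read_volume(pred_path, "label")
  ref <- read_volume(ref_path, "label")
  mc <- ap_f1_curve(pred, ref, restrict = restrict)
  if (!is.null(out)) {
    jsonlite::write_json(list(
      thresholds = mc$threshold, ap = mc$ap, f1 = mc$f1,
      ap_0.5 = mc$ap[1], f1_0.5 = mc$f1[1],
      mean_matched_iou = attr(mc, "mean_matched_iou")),
      out, auto_unbox = TRUE, digits = NA)
  }
  invisible(mc)
}
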