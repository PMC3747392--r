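#' Experiment configuration
#'
#' Bundles everything the two phantom experiments need: the phantom
#' geometry, the degradation protocol variants (one per decimation axis for
#' the upsampling study; a single motion-bearing protocol for the
#' registration study), the kernel and cost lists, the registration model
#' size and histogram bins.
#'
#' @param shape phantom grid (default `c(64, 64, 64)`, a desk-scale stand-in
#'   for a full acquisition).
#' @param spacing phantom voxel size in mm.
#' @param seed phantom texture / noise seed.
#' @param axes decimation axes for the upsampling experiment.
#' @param factor decimation factor.
#' @param kernels character vector of kernel names (see [kernel_names()]).
#' @param costs character vector of cost names (see [cost_names()]).
#' @param registration_degradation a [degradation_spec()] describing how the
#'   moving image is produced for the registration experiment.
#' @param max_dof registration model size.
#' @param bins histogram bins for entropies and histogram costs.
#' @param window_radius windowed-sinc half width.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(shape = c(64, 64, 64),
                              spacing = c(1, 1, 1.3),
                              seed = 1L,
                              axes = c("z", "x", "y"),
                              factor = 2L,
                              kernels = kernel_names(),
                              costs = cost_names(),
                              registration_degradation =
                                degradation_spec(seed = seed),
                              max_dof = 12L,
                              bins = 64L,
                              window_radius = 4L) {
  stopifnot(all(kernels %in% kernel_names()), all(costs %in% cost_names()))
  structure(list(shape = as.integer(shape), spacing = as.double(spacing),
                 seed = as.integer(seed), axes = axes,
                 factor = as.integer(factor),
                 kernels = kernels, costs = costs,
                 registration_degradation = registration_degradation,
                 max_dof = as.integer(max_dof), bins = as.integer(bins),
                 window_radius = as.integer(window_radius)),
            class = "experiment_config")
}

#' Load an experiment configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of
#' [experiment_config()]; keys under `registration_degradation` are passed
#' to [degradation_spec()]. Missing keys take the defaults.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the `yaml` package is required to read YAML configs", call. = FALSE)
  y <- yaml::read_yaml(path)
  if (!is.null(y$registration_degradation))
    y$registration_degradation <- do.call(degradation_spec,
                                          y$registration_degradation)
  do.call(experiment_config, y)
}

#' Upsampling comparison across kernels and decimation axes
#'
#' For each decimation axis and kernel: decimates the phantom by the
#' configured factor along that axis (pure decimation, no motion, noise or
#' blur, so the measured error isolates the interpolation), upsamples back
#' to the reference grid with the kernel, and scores MSE and PSNR against
#' the reference.
#'
#' @param cfg an [experiment_config()].
#' @return A data frame with one row per `(axis, kernel)` pair and columns
#'   `axis`, `kernel`, `mse`, `psnr_db`, plus metadata in attributes
#'   (`phantom_seed`, `shape`, `spacing`, `factor`).
#' @export
run_upsampling_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  ref <- generate_phantom(cfg$shape, cfg$spacing, cfg$seed)
  rows <- list()
  for (axis in cfg$axes) {
    dspec <- degradation_spec(subsample_axis = axis,
                              subsample_factor = cfg$factor,
                              rotation_deg = 0, translation_mm = c(0, 0, 0),
                              noise_sd = 0, blur_radius = 0, seed = cfg$seed)
    lr <- degrade(ref, dspec)
    ai <- match(axis, c("x", "y", "z"))
    for (kn in cfg$kernels) {
      ks <- kernel_spec(kn, window_radius = cfg$window_radius)
      up <- resample_volume(lr, dim(ref$data), ref$spacing,
                            identity_transform(), ks)
      rows[[length(rows) + 1L]] <-
        data.frame(axis = axis, kernel = kn,
                   mse = mse_3d(ref, up), psnr_db = psnr(ref, up),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "phantom_seed") <- cfg$seed
  attr(out, "shape") <- cfg$shape
  attr(out, "spacing") <- cfg$spacing
  attr(out, "factor") <- cfg$factor
  out
}

#' Registration comparison across kernels and costs
#'
#' For each `(kernel, cost)` pair: degrades the phantom with the configured
#' motion-bearing protocol, registers the degraded volume back to the
#' reference using that kernel and cost, reformats with the same kernel,
#' and records MSE, PSNR, joint entropy, the four cross-evaluated
#' similarity values and the recovered motion parameters. A registration
#' failure is recorded in the row and the experiment continues.
#'
#' @param cfg an [experiment_config()].
#' @param control a [register_control()].
#' @return A data frame with one row per pair: `kernel`, `cost`, `mse`,
#'   `psnr_db`, `joint_entropy_bits`, `cr`, `ls`, `ncc_cost`, `nmi_cost`,
#'   recovered parameters (`rx_deg`, `ry_deg`, `rz_deg`, `tx_mm`, `ty_mm`,
#'   `tz_mm`), `n_evals`, `failed`. The unregistered baseline metrics are in
#'   attributes `baseline_mse` and `baseline_joint_entropy`.
#' @export
run_registration_experiment <- function(cfg, control = register_control()) {
  stopifnot(inherits(cfg, "experiment_config"))
  ref <- generate_phantom(cfg$shape, cfg$spacing, cfg$seed)
  moving <- degrade(ref, cfg$registration_degradation)
  # unregistered baseline on the reference grid (identity resample)
  unreg <- resample_volume(moving, dim(ref$data), ref$spacing,
                           identity_transform(), kernel_spec("trilinear"))
  baseline_mse <- mse_3d(ref, unreg)
  baseline_je <- joint_entropy(ref, unreg, cfg$bins)

  rows <- list()
  for (kn in cfg$kernels) {
    ks <- kernel_spec(kn, window_radius = cfg$window_radius)
    for (cn in cfg$costs) {
      cspec <- cost_spec(cn, bins = cfg$bins)
      res <- tryCatch(
        register_volumes(ref, moving, cost = cspec, kernel = ks,
                         max_dof = cfg$max_dof, control = control),
        error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <-
          data.frame(kernel = kn, cost = cn, mse = NA_real_,
                     psnr_db = NA_real_, joint_entropy_bits = NA_real_,
                     cr = NA_real_, ls = NA_real_, ncc_cost = NA_real_,
                     nmi_cost = NA_real_, rx_deg = NA_real_,
                     ry_deg = NA_real_, rz_deg = NA_real_, tx_mm = NA_real_,
                     ty_mm = NA_real_, tz_mm = NA_real_, n_evals = NA_integer_,
                     failed = TRUE, stringsAsFactors = FALSE)
        next
      }
      reg <- apply_registration(res, moving, ref, ks)
      p <- res$final_params
      rows[[length(rows) + 1L]] <-
        data.frame(kernel = kn, cost = cn,
                   mse = mse_3d(ref, reg), psnr_db = psnr(ref, reg),
                   joint_entropy_bits = joint_entropy(ref, reg, cfg$bins),
                   cr = correlation_ratio(ref, reg, cfg$bins),
                   ls = least_squares(ref, reg),
                   ncc_cost = normalized_cross_correlation(ref, reg),
                   nmi_cost = normalized_mutual_information(ref, reg, cfg$bins),
                   rx_deg = p$rotation[1], ry_deg = p$rotation[2],
                   rz_deg = p$rotation[3], tx_mm = p$translation[1],
                   ty_mm = p$translation[2], tz_mm = p$translation[3],
                   n_evals = res$n_evals, failed = FALSE,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "phantom_seed") <- cfg$seed
  attr(out, "shape") <- cfg$shape
  attr(out, "degradation") <- cfg$registration_degradation
  attr(out, "baseline_mse") <- baseline_mse
  attr(out, "baseline_joint_entropy") <- baseline_je
  out
}

#' Write an experiment report
#'
#' Writes the rows as CSV and, alongside, a JSON file carrying the rows
#' plus the metadata attributes, so any row can be re-run in isolation.
#'
#' @param report a data frame from one of the experiment runners.
#' @param path CSV output path; the JSON goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  meta <- attributes(report)
  meta <- meta[setdiff(names(meta), c("names", "row.names", "class"))]
  meta$degradation <- if (!is.null(meta$degradation)) unclass(meta$degradation)
  jsonlite::write_json(list(rows = report, metadata = meta),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
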