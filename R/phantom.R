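#' Configuration for the synthetic thoracic phantom
#'
#' Defines a pair of thoracic CT volumes (air / body / two lung
#' compartments with Gaussian HU noise), an SBRT-like dose block with a
#' sharp radial falloff, a known rigid mis-alignment between the planning
#' and follow-up scans, and a ground-truth sigmoid HU response to local
#' dose. All randomness is driven by the single `seed`.
#'
#' The dose profile is a generalized-Gaussian radial falloff
#' `D(r) = dose_max * exp(-ln2 (r/r50)^falloff_q)` centered at the
#' isocenter, so the dose at `r50` is half the maximum and the default
#' block comfortably encompasses the 20% isodose surface.
#'
#' @param shape CT volume shape in voxels.
#' @param spacing CT voxel spacing in mm (use `c(0.94, 0.94, 3)` to mimic a
#'   clinical chest protocol).
#' @param hu_air,hu_body,hu_lung Mean HU of the three compartments.
#' @param hu_noise_sd Gaussian HU noise SD added independently to each scan.
#' @param body_center,body_semiaxes Body ellipsoid, in mm (defaults scale
#'   with the volume).
#' @param lung_centers,lung_semiaxes Lists of lung ellipsoid centers and
#'   semi-axes in mm.
#' @param isocenter Dose-block center in world mm; must lie inside a lung.
#' @param dose_max Maximum dose in Gy at the isocenter.
#' @param r50 Radius (mm) at which dose falls to half of `dose_max`.
#' @param falloff_q Sharpness exponent of the radial falloff.
#' @param dose_block_mm Physical edge lengths (mm) of the dose block.
#' @param dose_spacing Dose grid spacing in mm (default 1 mm isotropic).
#' @param true_model,true_d50,true_gamma50 Ground-truth response model and
#'   parameters.
#' @param delta_hu_max Maximal HU increase (at saturating dose) in lung.
#' @param misalignment [rigid_transform()] mapping follow-up world points
#'   into the planning frame (the follow-up scan is resampled under it).
#' @param seed Integer seed fixing all randomness.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(96, 96, 96),
                           spacing = c(1, 1, 1),
                           hu_air = -1000, hu_body = 40, hu_lung = -800,
                           hu_noise_sd = 20,
                           body_center = NULL, body_semiaxes = NULL,
                           lung_centers = NULL, lung_semiaxes = NULL,
                           isocenter = NULL,
                           dose_max = 60, r50 = 18, falloff_q = 2,
                           dose_block_mm = c(64, 64, 64),
                           dose_spacing = c(1, 1, 1),
                           true_model = "lyman", true_d50 = 35.29,
                           true_gamma50 = 1.35,
                           delta_hu_max = 200,
                           misalignment = rigid_transform(),
                           seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 8), length(spacing) == 3L,
            all(spacing > 0), hu_noise_sd >= 0, dose_max > 0, r50 > 0,
            falloff_q > 0, delta_hu_max >= 0, all(dose_block_mm > 0),
            all(dose_spacing > 0))
  extent <- (shape - 1) * spacing
  ctr <- extent / 2
  if (is.null(body_center)) body_center <- ctr
  if (is.null(body_semiaxes)) body_semiaxes <- extent * c(0.42, 0.34, 0.46)
  if (is.null(lung_centers))
    lung_centers <- list(ctr + c(-0.21, 0, 0) * extent[1],
                         ctr + c(+0.21, 0, 0) * extent[1])
  if (is.null(lung_semiaxes))
    lung_semiaxes <- rep(list(extent * c(0.14, 0.19, 0.36)), length(lung_centers))
  if (is.null(isocenter)) isocenter <- lung_centers[[1]] + c(6, 0, 0)
  cfg <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
              hu_air = hu_air, hu_body = hu_body, hu_lung = hu_lung,
              hu_noise_sd = hu_noise_sd,
              body_center = as.numeric(body_center),
              body_semiaxes = as.numeric(body_semiaxes),
              lung_centers = lapply(lung_centers, as.numeric),
              lung_semiaxes = lapply(lung_semiaxes, as.numeric),
              isocenter = as.numeric(isocenter),
              dose_max = dose_max, r50 = r50, falloff_q = falloff_q,
              dose_block_mm = as.numeric(dose_block_mm),
              dose_spacing = as.numeric(dose_spacing),
              true_model = parse_model(true_model),
              true_d50 = true_d50, true_gamma50 = true_gamma50,
              delta_hu_max = delta_hu_max,
              misalignment = misalignment, seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  cfg
}

# squared normalized ellipsoid coordinate, evaluated on the voxel grid by
# separable outer sums
grid_axis <- function(shape, spacing, k) (seq_len(shape[k]) - 1) * spacing[k]

radial_sq_field <- function(shape, spacing, center, scale = c(1, 1, 1)) {
  ex <- ((grid_axis(shape, spacing, 1) - center[1]) / scale[1])^2
  ey <- ((grid_axis(shape, spacing, 2) - center[2]) / scale[2])^2
  ez <- ((grid_axis(shape, spacing, 3) - center[3]) / scale[3])^2
  outer(outer(ex, ey, "+"), ez, "+")
}

point_in_ellipsoid <- function(p, center, semiaxes) {
  sum(((p - center) / semiaxes)^2) <= 1
}

#' Generate the SBRT-like dose block
#'
#' Dose grid (default 1 mm isotropic) centered at the isocenter with a
#' generalized-Gaussian radial falloff:
#' `D(r) = dose_max * exp(-ln2 (r / r50)^falloff_q)`.
#'
#' @param config A [phantom_config()].
#' @param check_inside If `TRUE` (default), error when the dose block
#'   extends outside the CT volume extent.
#' @return An [image_volume()] of kind `"Gy"`.
#' @export
generate_dose_block <- function(config, check_inside = TRUE) {
  stopifnot(inherits(config, "phantom_config"))
  nvox <- pmax(as.integer(round(config$dose_block_mm / config$dose_spacing)), 2L)
  origin <- config$isocenter - (nvox - 1) / 2 * config$dose_spacing
  if (check_inside) {
    ct_lo <- rep(0, 3)
    ct_hi <- (config$shape - 1) * config$spacing
    blk_hi <- origin + (nvox - 1) * config$dose_spacing
    if (any(origin < ct_lo - 1e-9) || any(blk_hi > ct_hi + 1e-9))
      stop("dose block extends outside the CT volume extent; reduce ",
           "`dose_block_mm` or move `isocenter`", call. = FALSE)
  }
  r2 <- radial_sq_field(nvox, config$dose_spacing,
                        config$isocenter - origin)
  d <- config$dose_max * exp(-log(2) * (sqrt(r2) / config$r50)^config$falloff_q)
  image_volume(d, spacing = config$dose_spacing, origin = origin, kind = "Gy")
}

# analytic dose of the phantom evaluated at arbitrary world points
phantom_dose_at <- function(config, shape, spacing) {
  r2 <- radial_sq_field(shape, spacing, config$isocenter)
  config$dose_max * exp(-log(2) * (sqrt(r2) / config$r50)^config$falloff_q)
}

#' Generate a planning/follow-up CT pair with known ground truth
#'
#' Builds the planning CT (air, body ellipsoid, two lung ellipsoids, plus
#' Gaussian HU noise), the follow-up CT (planning structure plus a
#' dose-driven HU increase `delta_hu_max * P_true(D(x))` inside the lungs
#' plus independent noise, then resampled under the configured
#' mis-alignment), and the dose block. The true lung mask and all
#' ground-truth parameters are returned alongside.
#'
#' @param config A [phantom_config()].
#' @return A list of class `phantom_pair` with elements `planning`,
#'   `followup`, `dose` ([image_volume()]s), `lung_mask` (truth mask on the
#'   planning grid) and `truth` (a `phantom_truth` list).
#' @export
generate_ct_pair <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  shape <- config$shape; spacing <- config$spacing
  in_lung <- array(FALSE, shape)
  for (i in seq_along(config$lung_centers)) {
    in_lung <- in_lung |
      (radial_sq_field(shape, spacing, config$lung_centers[[i]],
                       config$lung_semiaxes[[i]]) <= 1)
  }
  in_body <- radial_sq_field(shape, spacing, config$body_center,
                             config$body_semiaxes) <= 1
  iso_ok <- any(vapply(seq_along(config$lung_centers), function(i)
    point_in_ellipsoid(config$isocenter, config$lung_centers[[i]],
                       config$lung_semiaxes[[i]]), logical(1)))
  if (!iso_ok)
    stop("isocenter lies outside every lung compartment", call. = FALSE)

  structure_hu <- array(config$hu_air, shape)
  structure_hu[in_body] <- config$hu_body
  structure_hu[in_lung] <- config$hu_lung

  n <- prod(shape)
  planning_arr <- structure_hu
  if (config$hu_noise_sd > 0)
    planning_arr <- planning_arr + array(stats::rnorm(n, 0, config$hu_noise_sd), shape)

  dose_ct <- phantom_dose_at(config, shape, spacing)
  followup_arr <- structure_hu
  followup_arr[in_lung] <- followup_arr[in_lung] + config$delta_hu_max *
    ntcp_prob_unchecked(config$true_model, dose_ct[in_lung],
                        config$true_d50, config$true_gamma50)
  if (config$hu_noise_sd > 0)
    followup_arr <- followup_arr + array(stats::rnorm(n, 0, config$hu_noise_sd), shape)

  planning <- image_volume(planning_arr, spacing, kind = "HU")
  followup <- image_volume(followup_arr, spacing, kind = "HU")
  if (!is_identity_transform(config$misalignment))
    followup <- resample_volume(followup, followup, config$misalignment,
                                method = "trilinear", fill = config$hu_air)

  truth <- structure(list(
    model = config$true_model, d50 = config$true_d50,
    gamma50 = config$true_gamma50,
    delta_hu_max = config$delta_hu_max,
    misalignment_matrix = config$misalignment$matrix,
    hu_means = c(air = config$hu_air, body = config$hu_body,
                 lung = config$hu_lung),
    hu_noise_sd = config$hu_noise_sd,
    isocenter = config$isocenter, dose_max = config$dose_max,
    r50 = config$r50, falloff_q = config$falloff_q,
    seed = config$seed), class = "phantom_truth")

  structure(list(planning = planning, followup = followup,
                 dose = generate_dose_block(config),
                 lung_mask = image_volume(in_lung, spacing, kind = "mask"),
                 truth = truth),
            class = "phantom_pair")
}

#' Generate a pre-binned dose-response curve directly from a model
#'
#' Bypasses the imaging pipeline: evaluates the chosen model at the bin
#' midpoints and adds optional Gaussian noise. Responses are on the 0-1
#' probability scale (the `normalized` flag is `FALSE`; see
#' [fit_model()]'s `probability_scale` argument).
#'
#' @inheritParams ntcp_prob
#' @param bin_edges Strictly increasing dose bin edges in Gy.
#' @param noise_sd Gaussian noise SD added to each bin response (>= 0).
#' @param seed Optional integer seed.
#' @param patient_id Label stored on the curve.
#' @return A [dose_response_curve()].
#' @export
generate_binned_curve <- function(model, d50, gamma50 = NULL,
                                  bin_edges = seq(0, 60, by = 6),
                                  noise_sd = 0, seed = NULL,
                                  patient_id = "synthetic") {
  model <- parse_model(model)
  if (inherits(d50, "ntcp_params")) {
    gamma50 <- d50$gamma50
    d50 <- d50$d50
  }
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0))
    stop("`bin_edges` must be strictly increasing", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mid <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  resp <- ntcp_prob(model, mid, d50, gamma50)
  if (noise_sd > 0) resp <- resp + stats::rnorm(length(mid), 0, noise_sd)
  dose_response_curve(bin_edges = bin_edges, response = resp,
                      pixel_count = rep(1L, length(mid)),
                      normalized = FALSE, patient_id = patient_id)
}

#' Write phantom volumes and ground truth to disk
#'
#' Emits `planning.nii.gz`, `followup.nii.gz`, `dose.nii.gz`,
#' `lung_mask.nii.gz` and a `truth.json` sidecar.
#'
#' @param pair A `phantom_pair` from [generate_ct_pair()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the five file paths, invisibly.
#' @export
write_phantom <- function(pair, dir) {
  stopifnot(inherits(pair, "phantom_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(planning = file.path(dir, "planning.nii.gz"),
             followup = file.path(dir, "followup.nii.gz"),
             dose = file.path(dir, "dose.nii.gz"),
             lung_mask = file.path(dir, "lung_mask.nii.gz"),
             truth = file.path(dir, "truth.json"))
  write_volume(pair$planning, paths[["planning"]])
  write_volume(pair$followup, paths[["followup"]])
  write_volume(pair$dose, paths[["dose"]])
  write_volume(pair$lung_mask, paths[["lung_mask"]])
  write_phantom_truth(pair$truth, paths[["truth"]])
  invisible(paths)
}

#' @rdname write_phantom
#' @param truth A `phantom_truth` object.
#' @param path JSON output path.
#' @export
write_phantom_truth <- function(truth, path) {
  stopifnot(inherits(truth, "phantom_truth"))
  x <- unclass(truth)
  x$misalignment_matrix <- as.vector(x$misalignment_matrix)
  x$hu_means <- as.list(x$hu_means)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$misalignment_matrix <- matrix(x$misalignment_matrix, 4, 4)
  x$hu_means <- unlist(x$hu_means)
  structure(x, class = "phantom_truth")
}
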