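#' Per-bin dose-response curve
#'
#' Holds the binned dose versus CT-intensity-change response: dose bin
#' edges (default 6-Gy bins from 0 to 60 Gy), a representative dose per bin
#' (the bin midpoint), the mean Hounsfield-unit change per bin (raw, or
#' scaled to `[0, 1]` when `normalized`), and the number of contributing
#' pixels per bin.
#'
#' @param bin_edges Strictly increasing bin edges in Gy.
#' @param response Mean response per bin (length `length(bin_edges) - 1`);
#'   `NA` for empty bins.
#' @param pixel_count Number of pixels per bin (>= 0).
#' @param normalized Logical flag: `TRUE` when the responses have been
#'   scaled so the maximum bin equals 1.
#' @param patient_id Label for the originating data set.
#' @param bin_dose Representative dose per bin; defaults to midpoints.
#' @param bin_dose_mean Optional member-mean dose per bin (diagnostic).
#' @return An object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(bin_edges, response, pixel_count,
                                normalized = FALSE, patient_id = NA_character_,
                                bin_dose = NULL, bin_dose_mean = NULL) {
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0))
    stop("`bin_edges` must be strictly increasing", call. = FALSE)
  nb <- length(bin_edges) - 1L
  if (is.null(bin_dose))
    bin_dose <- (bin_edges[-1] + bin_edges[-(nb + 1)]) / 2
  response <- as.numeric(response)
  pixel_count <- as.integer(pixel_count)
  stopifnot(length(bin_dose) == nb, length(response) == nb,
            length(pixel_count) == nb, all(pixel_count >= 0, na.rm = TRUE))
  if (isTRUE(normalized)) {
    mx <- suppressWarnings(max(response[pixel_count > 0], na.rm = TRUE))
    if (!isTRUE(all.equal(mx, 1)))
      stop("a normalized curve must have maximum response exactly 1",
           call. = FALSE)
  }
  structure(list(bin_edges = bin_edges, bin_dose = as.numeric(bin_dose),
                 response = response, pixel_count = pixel_count,
                 normalized = isTRUE(normalized),
                 patient_id = as.character(patient_id),
                 bin_dose_mean = if (!is.null(bin_dose_mean))
                   as.numeric(bin_dose_mean)),
            class = "dose_response_curve")
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("<dose_response_curve> %s, %d bins [%g, %g] Gy, %s\n",
              x$patient_id, length(x$bin_dose), min(x$bin_edges),
              max(x$bin_edges),
              if (x$normalized) "normalized" else "raw"))
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' @export
as.data.frame.dose_response_curve <- function(x, ...) {
  nb <- length(x$bin_dose)
  data.frame(patient_id = rep(x$patient_id, nb),
             bin_lo_gy = x$bin_edges[-(nb + 1)],
             bin_hi_gy = x$bin_edges[-1],
             bin_dose_gy = x$bin_dose,
             response = x$response,
             pixel_count = x$pixel_count,
             normalized = rep(x$normalized, nb))
}

#' Plot a dose-response curve, optionally with fitted models
#'
#' @param x A [dose_response_curve()].
#' @param fits Optional list of [fit_model()] results to overlay.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dose_response_curve <- function(x, fits = NULL, ...) {
  graphics::plot(x$bin_dose, x$response, pch = 16, col = "steelblue",
                 xlab = "Dose (Gy)",
                 ylab = if (x$normalized) "Normalized ΔHU" else "Response",
                 ...)
  if (!is.null(fits)) {
    if (inherits(fits, "ntcp_fit")) fits <- list(fits)
    dd <- seq(max(min(x$bin_edges), 1e-6), max(x$bin_edges), length.out = 200)
    for (i in seq_along(fits)) {
      f <- fits[[i]]
      graphics::lines(dd, ntcp_prob(f$model, dd, f$d50, f$gamma50),
                      col = i + 1, lwd = 2)
    }
    graphics::legend("bottomright",
                     legend = vapply(fits, function(f) f$model, character(1)),
                     col = seq_along(fits) + 1, lwd = 2, bty = "n")
  }
  invisible(x)
}

#' Pixel-wise CT intensity change between follow-up and planning scans
#'
#' In the default `pixelwise` mode, the planning CT is sampled with
#' trilinear interpolation at the registered position of each follow-up
#' voxel and subtracted: `dHU(x) = HU_followup(x) - HU_planning(T(x))`.
#' In `block_mean` mode a single baseline, the mean planning-lung HU inside
#' the dose block, is subtracted from every follow-up voxel.
#'
#' @param followup,planning [image_volume()]s of kind `"HU"`.
#' @param registration [rigid_transform()] mapping follow-up world
#'   coordinates into planning world coordinates.
#' @param mode `"pixelwise"` (default) or `"block_mean"`.
#' @param planning_mask Lung mask on the planning grid (required for
#'   `block_mean`).
#' @param dose Dose block [image_volume()] (required for `block_mean`; its
#'   extent defines the baseline region).
#' @return An [image_volume()] of HU changes on the follow-up grid (`NA`
#'   where the registered position falls outside the planning volume).
#' @export
compute_hu_change <- function(followup, planning,
                              registration = rigid_transform(),
                              mode = c("pixelwise", "block_mean"),
                              planning_mask = NULL, dose = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(followup, "image_volume"), inherits(planning, "image_volume"))
  if (mode == "pixelwise") {
    base <- resample_volume(planning, followup, registration,
                            method = "trilinear", fill = NA_real_)
    if (!any(is.finite(base$data)))
      stop("registration maps every follow-up voxel outside the planning volume",
           call. = FALSE)
    delta <- followup$data - base$data
  } else {
    if (is.null(planning_mask) || is.null(dose))
      stop("`block_mean` mode requires `planning_mask` and `dose`",
           call. = FALSE)
    pts <- voxel_centers(planning)
    lo <- dose$origin - dose$spacing / 2
    hi <- dose$origin + (dim(dose$data) - 1 + 0.5) * dose$spacing
    inside <- pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
      pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
      pts[, 3] >= lo[3] & pts[, 3] <= hi[3]
    sel <- as.vector(planning_mask$data) & inside
    if (!any(sel))
      stop("no planning-lung voxel lies inside the dose block", call. = FALSE)
    baseline <- mean(planning$data[sel])
    delta <- followup$data - baseline
  }
  image_volume(delta, spacing = followup$spacing, origin = followup$origin,
               kind = "HU")
}

#' Bin pixel-wise HU change by dose
#'
#' Pixels inside the lung mask with a valid (non-`NA`) mapped dose are
#' assigned to half-open dose bins `[lo, hi)`; doses at or above the top
#' edge are clamped into the top bin by default (set `clamp_above = FALSE`
#' to exclude them). The per-bin response is the mean HU change of its
#' member pixels; the representative bin dose is the midpoint.
#'
#' @param delta HU-change [image_volume()] (from [compute_hu_change()]).
#' @param dose Mapped dose [image_volume()] on the same grid (`NA` outside
#'   the dose block).
#' @param mask Lung mask [image_volume()] on the same grid.
#' @param bin_edges Dose bin edges in Gy (default 0, 6, ..., 60).
#' @param clamp_above Clamp doses >= the top edge into the top bin.
#' @param patient_id Label stored on the curve.
#' @return A raw (unnormalized) [dose_response_curve()]. Attributes
#'   `n_masked`, `n_no_dose` record how many pixels were considered and how
#'   many were excluded for lacking a valid dose.
#' @export
bin_curve <- function(delta, dose, mask, bin_edges = seq(0, 60, by = 6),
                      clamp_above = TRUE, patient_id = NA_character_) {
  stopifnot(inherits(delta, "image_volume"), inherits(dose, "image_volume"),
            inherits(mask, "image_volume"))
  if (!all(dim(delta$data) == dim(dose$data)) ||
      !all(dim(delta$data) == dim(mask$data)))
    stop("`delta`, `dose` and `mask` must share the same grid", call. = FALSE)
  bin_edges <- as.numeric(bin_edges)
  nb <- length(bin_edges) - 1L
  m <- as.vector(mask$data)
  d <- as.vector(dose$data)
  y <- as.vector(delta$data)
  n_masked <- sum(m)
  sel <- m & is.finite(d) & is.finite(y)
  n_no_dose <- n_masked - sum(sel)
  d <- d[sel]; y <- y[sel]
  if (!length(d))
    stop("no masked pixel has a valid dose; cannot build a curve",
         call. = FALSE)
  idx <- findInterval(d, bin_edges)
  if (clamp_above) idx[idx > nb] <- nb
  ok <- idx >= 1L & idx <= nb
  idx <- idx[ok]; d <- d[ok]; y <- y[ok]
  pixel_count <- tabulate(idx, nbins = nb)
  response <- rep(NA_real_, nb)
  dose_mean <- rep(NA_real_, nb)
  nz <- which(pixel_count > 0L)
  sums_y <- vapply(split(y, factor(idx, levels = seq_len(nb))), sum, numeric(1))
  sums_d <- vapply(split(d, factor(idx, levels = seq_len(nb))), sum, numeric(1))
  response[nz] <- sums_y[nz] / pixel_count[nz]
  dose_mean[nz] <- sums_d[nz] / pixel_count[nz]
  out <- dose_response_curve(bin_edges = bin_edges, response = response,
                             pixel_count = pixel_count, normalized = FALSE,
                             patient_id = patient_id,
                             bin_dose_mean = dose_mean)
  attr(out, "n_masked") <- n_masked
  attr(out, "n_no_dose") <- n_no_dose
  out
}

#' Normalize a dose-response curve to its maximum bin
#'
#' Divides all responses by the largest bin response (typically the top,
#' 54-60 Gy, bin), so the maximum equals 1. Negative noisy bins are
#' retained. Idempotent.
#'
#' @param curve A [dose_response_curve()].
#' @return The normalized curve.
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "dose_response_curve"))
  use <- curve$pixel_count > 0L & is.finite(curve$response)
  if (!any(use)) stop("curve has no nonempty bins", call. = FALSE)
  mx <- max(curve$response[use])
  if (!(mx > 0))
    stop("no detectable radiographic change: maximum bin response is <= 0",
         call. = FALSE)
  curve$response <- curve$response / mx
  curve$normalized <- TRUE
  curve
}

#' Pool patient-normalized curves into a cumulative curve
#'
#' Per-bin unweighted mean of the normalized responses over the curves
#' with at least one pixel in that bin, renormalized so the maximum pooled
#' bin equals 1 (a no-op when every patient's maximum sits in the same
#' bin).
#'
#' @param curves List of normalized [dose_response_curve()]s with identical
#'   bin edges.
#' @return A pooled, normalized [dose_response_curve()] with
#'   `patient_id = "pooled"`.
#' @export
pool_curves <- function(curves) {
  if (inherits(curves, "dose_response_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "dose_response_curve")))
  edges <- curves[[1]]$bin_edges
  for (cv in curves) {
    if (!isTRUE(all.equal(cv$bin_edges, edges)))
      stop("curves have mismatched bin edges and cannot be pooled",
           call. = FALSE)
    if (!cv$normalized)
      stop("all curves must be normalized before pooling", call. = FALSE)
  }
  nb <- length(edges) - 1L
  rmat <- vapply(curves, function(cv) {
    r <- cv$response
    r[cv$pixel_count == 0L] <- NA_real_
    r
  }, numeric(nb))
  rmat <- matrix(rmat, nrow = nb)
  response <- rowMeans(rmat, na.rm = TRUE)
  response[is.nan(response)] <- NA_real_
  counts <- rowSums(matrix(vapply(curves, function(cv) cv$pixel_count,
                                  integer(nb)), nrow = nb))
  mx <- max(response[counts > 0], na.rm = TRUE)
  if (!(mx > 0)) stop("pooled curve has no positive response", call. = FALSE)
  if (abs(mx - 1) > 1e-12)
    message(sprintf("pooled curve renormalized by its maximum (%.4f)", mx))
  dose_response_curve(bin_edges = edges, response = response / mx,
                      pixel_count = counts, normalized = TRUE,
                      patient_id = "pooled")
}

#' Write/read dose-response curves as CSV
#'
#' Columns: `patient_id, bin_lo_gy, bin_hi_gy, bin_dose_gy, response,
#' pixel_count, normalized`.
#'
#' @param curves A [dose_response_curve()] or list thereof.
#' @param path CSV file path.
#' @return `path` invisibly (writer); a list of curves (reader).
#' @export
write_curves_csv <- function(curves, path) {
  if (inherits(curves, "dose_response_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves_csv
#' @export
read_curves_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "bin_lo_gy", "bin_hi_gy", "bin_dose_gy",
            "response", "pixel_count", "normalized")
  if (!all(need %in% names(df)))
    stop("curve CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(split(df, df$patient_id), function(g) {
    g <- g[order(g$bin_lo_gy), ]
    dose_response_curve(bin_edges = c(g$bin_lo_gy, g$bin_hi_gy[nrow(g)]),
                        response = g$response,
                        pixel_count = g$pixel_count,
                        normalized = all(g$normalized),
                        patient_id = g$patient_id[1],
                        bin_dose = g$bin_dose_gy)
  })
}
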