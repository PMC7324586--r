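# --- low-level binary 3D morphology helpers ------------------------------

# 6-connected component labelling of a logical 3D array via igraph.
# Returns an integer array: 0 outside the mask, component id inside.
label_components_3d <- function(mask) {
  d <- dim(mask)
  n <- prod(d)
  lin <- array(seq_len(n), d)
  edges <- vector("list", 3L)
  a <- lin[-d[1], , , drop = FALSE]; b <- lin[-1, , , drop = FALSE]
  keep <- mask[a] & mask[b]
  edges[[1]] <- rbind(a[keep], b[keep])
  a <- lin[, -d[2], , drop = FALSE]; b <- lin[, -1, , drop = FALSE]
  keep <- mask[a] & mask[b]
  edges[[2]] <- rbind(a[keep], b[keep])
  a <- lin[, , -d[3], drop = FALSE]; b <- lin[, , -1, drop = FALSE]
  keep <- mask[a] & mask[b]
  edges[[3]] <- rbind(a[keep], b[keep])
  g <- igraph::make_graph(edges = as.vector(do.call(cbind, edges)),
                          n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  lab <- array(0L, d)
  idx <- which(mask)
  lab[idx] <- as.integer(memb[idx])
  lab
}

# Ellipsoidal (ball in mm) structuring element as a 0/1 array, odd dims.
ball_kernel <- function(radius_mm, spacing) {
  rv <- pmax(floor(radius_mm / spacing), 0)
  ax <- lapply(1:3, function(k) ((-rv[k]):(rv[k])) * spacing[k])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  (r2 <= radius_mm^2 + 1e-9) * 1
}

# Circular FFT convolution of a logical volume with a small centered kernel.
fft_convolve <- function(mask, kern) {
  d <- dim(mask)
  kd <- dim(kern)
  stopifnot(all(kd <= d))
  kp <- array(0, d)
  ctr <- (kd + 1) / 2
  off <- lapply(1:3, function(k) ((seq_len(kd[k]) - ctr[k]) %% d[k]) + 1L)
  kp[off[[1]], off[[2]], off[[3]]] <- kern
  Re(stats::fft(stats::fft(mask * 1) * stats::fft(kp), inverse = TRUE)) / prod(d)
}

dilate3d <- function(mask, kern) fft_convolve(mask, kern) > 0.5
erode3d <- function(mask, kern) fft_convolve(mask, kern) > sum(kern) - 0.5

# Fill in-plane (axial-slice) holes: background regions not 4-connected to
# the slice border are absorbed into the mask.
fill_holes_slicewise <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  reach <- bg & border
  repeat {
    grown <- reach
    grown[-1, , ] <- grown[-1, , ] | reach[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | reach[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | reach[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | reach[, -1, ]
    grown <- grown & bg
    if (!any(grown & !reach)) break
    reach <- grown
  }
  mask | (bg & !reach)
}

# --- lung segmentation ----------------------------------------------------

#' Segment the lungs from a chest CT
#'
#' Histogram-threshold segmentation with morphological cleanup:
#' \enumerate{
#'   \item threshold voxels below `hu_threshold` (air and lung parenchyma);
#'   \item discard 6-connected components touching the in-plane volume
#'     boundary (external air);
#'   \item keep components of at least `min_component_volume` mm^3;
#'   \item morphological closing with a ball of radius `closing_radius` mm,
#'     then slice-wise hole filling, so dense structures (vessels, nodules)
#'     inside the lung border are included.
#' }
#'
#' @param ct An [image_volume()] of kind `"HU"`.
#' @param hu_threshold HU threshold separating lung from soft tissue
#'   (default -400 HU).
#' @param min_component_volume Minimum component volume in mm^3 kept as
#'   lung (default 50 cm^3; reduce for small phantoms).
#' @param closing_radius Ball radius in mm for morphological closing
#'   (default 3 mm; 0 disables).
#' @return An [image_volume()] of kind `"mask"` on `ct`'s grid.
#' @export
segment_lungs <- function(ct, hu_threshold = -400,
                          min_component_volume = 50000,
                          closing_radius = 3) {
  stopifnot(inherits(ct, "image_volume"))
  d <- dim(ct$data)
  fg <- ct$data < hu_threshold
  lab <- label_components_3d(fg)
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids)) {
    sizes <- tabulate(lab[lab > 0L])
    vox_mm3 <- prod(ct$spacing)
    boundary_ids <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ]))
    keep <- setdiff(ids, boundary_ids)
    keep <- keep[sizes[keep] * vox_mm3 >= min_component_volume]
  } else keep <- integer(0)
  if (!length(keep)) {
    sizes_mm3 <- if (length(ids)) sort(tabulate(lab[lab > 0L])[ids] * prod(ct$spacing),
                                       decreasing = TRUE) else numeric(0)
    cond <- structure(
      class = c("segmentation_failed", "error", "condition"),
      list(message = paste0(
             "lung segmentation failed: no interior component of at least ",
             min_component_volume, " mm^3 below ", hu_threshold, " HU"),
           call = sys.call(-1), component_sizes_mm3 = sizes_mm3))
    stop(cond)
  }
  m <- array(lab %in% keep, d)
  if (closing_radius > 0) {
    kern <- ball_kernel(closing_radius, ct$spacing)
    if (all(dim(kern) <= d) && sum(kern) > 1)
      m <- erode3d(dilate3d(m, kern), kern)
  }
  m <- fill_holes_slicewise(m)
  image_volume(m, spacing = ct$spacing, origin = ct$origin, kind = "mask")
}
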