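#' Normalized cross-correlation of two samples
#'
#' @param a,b Numeric vectors of equal length (pairs with missing values
#'   are dropped).
#' @return NCC in `[-1, 1]`, or `NA` if degenerate.
#' @export
ncc <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2L) return(NA_real_)
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(NA_real_)
  sum(a * b) / den
}

# NCC between moving voxel values and the fixed volume sampled at the
# transformed moving voxel centers; pts/vals are precomputed subsets.
ncc_at <- function(par, fixed, pts, vals, center, translation_only,
                   min_overlap) {
  tf <- if (translation_only)
    rigid_transform(translation = par[1:3], center = center)
  else
    rigid_transform(translation = par[1:3], rotation_deg = par[4:6],
                    center = center)
  s <- sample_volume(fixed, transform_points(tf, pts), method = "trilinear")
  if (sum(is.finite(s)) < min_overlap) return(NA_real_)
  ncc(vals, s)
}

#' Rigid registration by normalized cross-correlation
#'
#' Finds the rigid transform mapping `moving`-frame world points into the
#' `fixed` frame that maximizes the normalized cross-correlation between
#' the moving intensities and the fixed volume sampled at the transformed
#' moving voxel centers. The search is coarse-to-fine: mean-pooled pyramid
#' levels (default downsampling factors 4, 2, 1), an exhaustive translation
#' grid of +/- `coarse_range_mm` at the coarsest level, then local
#' Nelder-Mead simplex refinement of all degrees of freedom at each finer
#' level. Rotations are about the fixed volume's center; set
#' `translation_only = TRUE` to restrict to the 3 translational degrees of
#' freedom. The identity transform is always kept as a candidate, so the
#' returned NCC is never below the NCC at identity.
#'
#' @param fixed,moving [image_volume()]s of kind `"HU"` with overlapping
#'   fields of view (`fixed` is typically the planning CT, `moving` the
#'   follow-up CT, so the result maps follow-up into planning coordinates).
#' @param levels Integer downsampling factors, coarse to fine.
#' @param coarse_range_mm Half-width of the exhaustive translation search
#'   at the coarsest level, in mm.
#' @param translation_only Restrict to translations.
#' @param min_overlap Minimum number of overlapping voxels required at the
#'   evaluation resolution.
#' @param max_points Cap on the number of moving voxels used per NCC
#'   evaluation (strided subsampling keeps evaluation fast at full
#'   resolution without biasing the optimum).
#' @return A list with `transform` (the [rigid_transform()]), `ncc`
#'   (achieved NCC) and `par` (the optimal parameter vector).
#' @export
register_rigid <- function(fixed, moving, levels = c(4, 2, 1),
                           coarse_range_mm = 20, translation_only = FALSE,
                           min_overlap = 500, max_points = 150000) {
  stopifnot(inherits(fixed, "image_volume"), inherits(moving, "image_volume"))
  levels <- as.integer(sort(unique(levels), decreasing = TRUE))
  center <- volume_center(fixed)
  npar <- if (translation_only) 3L else 6L
  par <- rep(0, npar)

  level_data <- function(f) {
    fx <- downsample_volume(fixed, f)
    mv <- downsample_volume(moving, f)
    pts <- voxel_centers(mv)
    vals <- as.vector(mv$data)
    if (nrow(pts) > max_points) {
      stride <- ceiling(nrow(pts) / max_points)
      sel <- seq(1L, nrow(pts), by = stride)
      pts <- pts[sel, , drop = FALSE]
      vals <- vals[sel]
    }
    list(fixed = fx, pts = pts, vals = vals,
         mo = min(min_overlap, max(2L, floor(length(vals) / 4))))
  }

  # coarsest level: exhaustive integer translation grid
  f0 <- levels[1]
  ld <- level_data(f0)
  step <- max(fixed$spacing * f0)
  offs <- seq(-coarse_range_mm, coarse_range_mm, by = step)
  grid <- as.matrix(expand.grid(x = offs, y = offs, z = offs))
  scores <- apply(grid, 1L, function(tr)
    ncc_at(c(tr, rep(0, npar - 3L)), ld$fixed, ld$pts, ld$vals, center,
           translation_only, ld$mo))
  if (all(is.na(scores)))
    stop("registration failed: no translation with sufficient overlap",
         call. = FALSE)
  par[1:3] <- unname(grid[which.max(scores), ])

  # finer levels: local simplex refinement
  for (f in levels[-1]) {
    ld <- level_data(f)
    obj <- function(p) {
      v <- ncc_at(p, ld$fixed, ld$pts, ld$vals, center, translation_only, ld$mo)
      if (is.na(v)) 1 else -v
    }
    init_step <- c(rep(max(fixed$spacing * f), 3L),
                   rep(1, npar - 3L))
    opt <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(maxit = 400L,
                                       parscale = init_step,
                                       reltol = 1e-10))
    par <- opt$par
  }

  # score final candidates at the finest level, keeping identity as floor
  ld <- level_data(levels[length(levels)])
  cand <- list(par, rep(0, npar))
  scores <- vapply(cand, function(p)
    ncc_at(p, ld$fixed, ld$pts, ld$vals, center, translation_only, ld$mo),
    numeric(1))
  if (all(is.na(scores)))
    stop("registration failed: insufficient overlap between volumes",
         call. = FALSE)
  best <- which.max(scores)
  par <- cand[[best]]
  tf <- if (translation_only)
    rigid_transform(translation = par[1:3], center = center)
  else
    rigid_transform(translation = par[1:3], rotation_deg = par[4:6],
                    center = center)
  list(transform = tf, ncc = scores[best], par = par)
}

#' Map a dose grid into follow-up image space
#'
#' For each voxel center of `followup_geometry`, applies the
#' follow-up-to-planning `registration` and samples the dose grid at the
#' nearest grid point (the dose grid is finer than the CT, so
#' nearest-neighbour lookup introduces at most half a dose-voxel of
#' positional error and never interpolates new dose values). Voxels
#' mapping outside the dose block receive `NA` and are excluded from all
#' downstream binning.
#'
#' @param dose [image_volume()] of kind `"Gy"` in the planning frame.
#' @param registration [rigid_transform()] mapping follow-up world
#'   coordinates into planning world coordinates.
#' @param followup_geometry [image_volume()] defining the output grid.
#' @param method `"nearest"` (default, matches the dose-lookup contract) or
#'   `"trilinear"`.
#' @return An [image_volume()] of kind `"Gy"` on the follow-up grid with
#'   `NA` outside the dose block.
#' @export
map_dose_to_followup <- function(dose, registration, followup_geometry,
                                 method = c("nearest", "trilinear")) {
  method <- match.arg(method)
  out <- resample_volume(dose, followup_geometry, registration,
                         method = method, fill = NA_real_)
  if (!any(is.finite(out$data)))
    stop("no follow-up voxel maps inside the dose block", call. = FALSE)
  out
}
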