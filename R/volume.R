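#' 3D image volume with voxel geometry
#'
#' Container for a 3D scalar grid (CT Hounsfield units, dose in Gy, or a
#' binary mask) plus the voxel geometry needed to place it in a world
#' coordinate frame (mm, LPS). A voxel at 0-based index `i` has its center
#' at `origin + i * spacing`.
#'
#' @param data 3D numeric (or logical, for masks) array.
#' @param spacing Voxel spacing in mm per axis, all > 0.
#' @param origin World coordinates (mm) of the center of voxel (0,0,0).
#' @param kind One of `"HU"`, `"Gy"`, `"mask"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         kind = c("HU", "Gy", "mask")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  stopifnot(length(spacing) == 3L, length(origin) == 3L,
            all(is.finite(spacing)), all(spacing > 0),
            all(is.finite(origin)))
  if (kind == "mask") {
    storage.mode(data) <- "logical"
  } else {
    storage.mode(data) <- "double"
  }
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), kind = kind),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume [%s]> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              x$kind, d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' World coordinates of every voxel center
#'
#' @param vol An [image_volume()].
#' @return Numeric matrix (one row per voxel, column-major voxel order).
#' @export
voxel_centers <- function(vol) {
  d <- dim(vol$data)
  ax <- lapply(1:3, function(k) vol$origin[k] + (seq_len(d[k]) - 1) * vol$spacing[k])
  cbind(rep(ax[[1]], times = d[2] * d[3]),
        rep(rep(ax[[2]], each = d[1]), times = d[3]),
        rep(ax[[3]], each = d[1] * d[2]))
}

#' World center of a volume
#' @param vol An [image_volume()].
#' @return Length-3 numeric, the world midpoint of the voxel-center grid.
#' @export
volume_center <- function(vol) {
  vol$origin + (dim(vol$data) - 1) / 2 * vol$spacing
}

#' Sample a volume at world points
#'
#' @param vol An [image_volume()].
#' @param points World points (mm), one per row.
#' @param method `"trilinear"` interpolation or `"nearest"` neighbour.
#' @param fill Value for points outside the voxel-center extent
#'   (default `NA`).
#' @return Numeric vector of sampled values.
#' @export
sample_volume <- function(vol, points, method = c("trilinear", "nearest"),
                          fill = NA_real_) {
  method <- match.arg(method)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  d <- dim(vol$data)
  # continuous 1-based voxel index
  u1 <- (points[, 1] - vol$origin[1]) / vol$spacing[1] + 1
  u2 <- (points[, 2] - vol$origin[2]) / vol$spacing[2] + 1
  u3 <- (points[, 3] - vol$origin[3]) / vol$spacing[3] + 1
  out <- rep(as.numeric(fill), nrow(points))
  if (method == "nearest") {
    i1 <- round(u1); i2 <- round(u2); i3 <- round(u3)
    ok <- i1 >= 1 & i1 <= d[1] & i2 >= 1 & i2 <= d[2] & i3 >= 1 & i3 <= d[3]
    if (any(ok))
      out[ok] <- vol$data[cbind(i1[ok], i2[ok], i3[ok])]
  } else {
    ok <- u1 >= 1 & u1 <= d[1] & u2 >= 1 & u2 <= d[2] & u3 >= 1 & u3 <= d[3]
    if (any(ok)) {
      v1 <- u1[ok]; v2 <- u2[ok]; v3 <- u3[ok]
      i1 <- pmin(floor(v1), d[1] - 1); i1 <- pmax(i1, 1)
      i2 <- pmin(floor(v2), d[2] - 1); i2 <- pmax(i2, 1)
      i3 <- pmin(floor(v3), d[3] - 1); i3 <- pmax(i3, 1)
      if (d[1] == 1L) i1 <- rep(1, length(v1))
      if (d[2] == 1L) i2 <- rep(1, length(v2))
      if (d[3] == 1L) i3 <- rep(1, length(v3))
      f1 <- v1 - i1; f2 <- v2 - i2; f3 <- v3 - i3
      a <- vol$data
      n1 <- pmin(i1 + 1, d[1]); n2 <- pmin(i2 + 1, d[2]); n3 <- pmin(i3 + 1, d[3])
      val <-
        a[cbind(i1, i2, i3)] * (1 - f1) * (1 - f2) * (1 - f3) +
        a[cbind(n1, i2, i3)] * f1 * (1 - f2) * (1 - f3) +
        a[cbind(i1, n2, i3)] * (1 - f1) * f2 * (1 - f3) +
        a[cbind(n1, n2, i3)] * f1 * f2 * (1 - f3) +
        a[cbind(i1, i2, n3)] * (1 - f1) * (1 - f2) * f3 +
        a[cbind(n1, i2, n3)] * f1 * (1 - f2) * f3 +
        a[cbind(i1, n2, n3)] * (1 - f1) * f2 * f3 +
        a[cbind(n1, n2, n3)] * f1 * f2 * f3
      out[ok] <- val
    }
  }
  out
}

#' Resample a volume onto a target grid under a rigid transform
#'
#' For each voxel center `x` of `geometry`, samples `vol` at
#' `transform(x)`.
#'
#' @param vol Source [image_volume()].
#' @param geometry [image_volume()] whose grid defines the output.
#' @param transform [rigid_transform()] mapping target world points into
#'   the source frame.
#' @param method Interpolation method, see [sample_volume()].
#' @param fill Fill value outside the source extent.
#' @return An `image_volume` on `geometry`'s grid with `vol`'s value kind.
#' @export
resample_volume <- function(vol, geometry, transform = rigid_transform(),
                            method = c("trilinear", "nearest"),
                            fill = NA_real_) {
  method <- match.arg(method)
  pts <- voxel_centers(geometry)
  if (!is_identity_transform(transform)) pts <- transform_points(transform, pts)
  vals <- sample_volume(vol, pts, method = method, fill = fill)
  image_volume(array(vals, dim(geometry$data)), spacing = geometry$spacing,
               origin = geometry$origin, kind = vol$kind)
}

# Mean-pooling downsample by an integer factor (used by the multiresolution
# registration pyramid). Trailing voxels that do not fill a block are cropped.
downsample_volume <- function(vol, factor) {
  stopifnot(factor >= 1, factor == as.integer(factor))
  factor <- as.integer(factor)
  if (factor == 1L) return(vol)
  d <- dim(vol$data)
  d2 <- d %/% factor
  stopifnot(all(d2 >= 1))
  a <- vol$data[seq_len(d2[1] * factor), seq_len(d2[2] * factor),
                seq_len(d2[3] * factor), drop = FALSE]
  a <- array(a, dim = c(factor, d2[1], factor, d2[2], factor, d2[3]))
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  m <- array(colMeans(matrix(a, nrow = factor^3)), dim = d2)
  image_volume(m, spacing = vol$spacing * factor,
               origin = vol$origin + (factor - 1) / 2 * vol$spacing,
               kind = vol$kind)
}

#' Write a volume to NIfTI
#'
#' Stores the voxel spacing in the NIfTI pixdim and the origin in the
#' sform/qform translation, so the volume round-trips through
#' [read_volume()].
#'
#' @param vol An [image_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  a <- vol$data
  if (vol$kind == "mask") storage.mode(a) <- "integer"
  xform <- diag(4)
  diag(xform)[1:3] <- vol$spacing
  xform[1:3, 4] <- vol$origin
  img <- RNifti::asNifti(a)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  img <- RNifti::`sform<-`(img, structure(xform, code = 2L))
  img <- RNifti::`qform<-`(img, structure(xform, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path Path to a `.nii`/`.nii.gz` file written by [write_volume()]
#'   or any axis-aligned NIfTI volume.
#' @param kind Value kind to tag the volume with.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, kind = c("HU", "Gy", "mask")) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  sf <- RNifti::xform(img)
  a <- as.array(img)
  if (length(dim(a)) != 3L) stop("expected a 3D NIfTI volume", call. = FALSE)
  a <- array(as.numeric(a), dim(a))  # drop RNifti's internal attributes
  spacing <- abs(c(sf[1, 1], sf[2, 2], sf[3, 3]))
  if (any(spacing == 0)) spacing <- RNifti::pixdim(img)[1:3]
  image_volume(if (kind == "mask") a > 0.5 else a,
               spacing = spacing, origin = sf[1:3, 4], kind = kind)
}
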