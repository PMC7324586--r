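#' Rigid-body transform between world coordinate frames
#'
#' A 6-degree-of-freedom mapping of world points (mm, LPS):
#' `p' = R (p - c) + c + t`, where `R` is the rotation `Rz Ry Rx` built
#' from angles in degrees, `c` the rotation center (typically the fixed
#' volume's center) and `t` the translation in mm.
#'
#' @param translation Numeric length-3, translation in mm.
#' @param rotation_deg Numeric length-3, rotations about x, y, z in degrees,
#'   applied in the order `Rz %*% Ry %*% Rx`.
#' @param center Numeric length-3, rotation center in world mm.
#' @return An object of class `rigid_transform` carrying the 4x4
#'   homogeneous matrix and, when constructed directly, its parameters.
#' @export
rigid_transform <- function(translation = c(0, 0, 0),
                            rotation_deg = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(translation) == 3L, length(rotation_deg) == 3L,
            length(center) == 3L,
            all(is.finite(translation)), all(is.finite(rotation_deg)),
            all(is.finite(center)))
  translation <- as.numeric(translation)
  rotation_deg <- as.numeric(rotation_deg)
  center <- as.numeric(center)
  R <- rotation_matrix(rotation_deg)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- center + translation - R %*% center
  structure(list(matrix = M, translation = translation,
                 rotation_deg = rotation_deg, center = center),
            class = "rigid_transform")
}

rotation_matrix <- function(rotation_deg) {
  a <- rotation_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

transform_from_matrix <- function(M) {
  stopifnot(is.matrix(M), all(dim(M) == c(4L, 4L)))
  structure(list(matrix = M, translation = NULL, rotation_deg = NULL,
                 center = NULL),
            class = "rigid_transform")
}

#' Apply a rigid transform to world points
#'
#' @param transform A [rigid_transform()].
#' @param points Numeric matrix, one world point (mm) per row.
#' @return Transformed points, same shape.
#' @export
transform_points <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  M <- transform$matrix
  out <- points %*% t(M[1:3, 1:3])
  out[, 1] <- out[, 1] + M[1, 4]
  out[, 2] <- out[, 2] + M[2, 4]
  out[, 3] <- out[, 3] + M[3, 4]
  out
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` applies `b` first, then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return The composed `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  transform_from_matrix(a$matrix %*% b$matrix)
}

#' Invert a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  transform_from_matrix(solve(transform$matrix))
}

#' Add a pure translation to a rigid transform
#'
#' Used by the registration-robustness experiment to perturb a baseline
#' registration along one anatomical axis.
#'
#' @param transform A [rigid_transform()].
#' @param delta Numeric length-3 translation increment in mm.
#' @return The shifted `rigid_transform`.
#' @export
shift_transform <- function(transform, delta) {
  stopifnot(inherits(transform, "rigid_transform"), length(delta) == 3L,
            all(is.finite(delta)))
  M <- transform$matrix
  M[1:3, 4] <- M[1:3, 4] + as.numeric(delta)
  out <- transform_from_matrix(M)
  if (!is.null(transform$translation)) {
    out$translation <- transform$translation + as.numeric(delta)
    out$rotation_deg <- transform$rotation_deg
    out$center <- transform$center
  }
  out
}

is_identity_transform <- function(transform, tol = 1e-12) {
  max(abs(transform$matrix - diag(4))) <= tol
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  if (!is.null(x$translation)) {
    cat("  translation (mm):", paste(signif(x$translation, 6), collapse = ", "),
        "\n  rotation (deg): ", paste(signif(x$rotation_deg, 6), collapse = ", "),
        "\n  center (mm):    ", paste(signif(x$center, 6), collapse = ", "), "\n")
  } else {
    cat("  matrix:\n")
    print(signif(x$matrix, 6))
  }
  invisible(x)
}
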