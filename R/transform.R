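#' Rigid transform (rotation + translation)
#'
#' Six-parameter rigid map from moving to fixed physical coordinates:
#' `T(p) = R (p - c) + c + t`, with `R` built from intrinsic x-y-z rotation
#' angles (applied as `Rx %*% Ry %*% Rz` to column vectors), `c` the rotation
#' centre in mm and `t` the translation in mm. This parameterization is the
#' package's transform-file convention and is recorded verbatim in JSON
#' output.
#'
#' @param angles_deg rotation angles (degrees) about x, y, z.
#' @param translation_mm translation (mm) per axis.
#' @param center_mm rotation centre (mm).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(angles_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  angles_deg <- as.numeric(angles_deg)
  translation_mm <- as.numeric(translation_mm)
  center_mm <- as.numeric(center_mm)
  if (length(angles_deg) != 3L || length(translation_mm) != 3L ||
      length(center_mm) != 3L)
    stop("angles, translation and center must each have length 3")
  if (any(!is.finite(c(angles_deg, translation_mm, center_mm))))
    stop("rigid transform parameters must be finite")
  structure(list(angles_deg = angles_deg, translation_mm = translation_mm,
                 center_mm = center_mm, convention = "intrinsic-xyz/Rx.Ry.Rz"),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat(sprintf("  angles (deg):      %s\n", paste(signif(x$angles_deg, 6), collapse = ", ")))
  cat(sprintf("  translation (mm):  %s\n", paste(signif(x$translation_mm, 6), collapse = ", ")))
  cat(sprintf("  center (mm):       %s\n", paste(signif(x$center_mm, 6), collapse = ", ")))
  invisible(x)
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  ca <- cos(a[1]); sa <- sin(a[1])
  cb <- cos(a[2]); sb <- sin(a[2])
  cg <- cos(a[3]); sg <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, ca, -sa), c(0, sa, ca))
  Ry <- rbind(c(cb, 0, sb), c(0, 1, 0), c(-sb, 0, cb))
  Rz <- rbind(c(cg, -sg, 0), c(sg, cg, 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

rotation_angles <- function(R) {
  # inverse of rotation_matrix for the intrinsic x-y-z convention
  b <- asin(max(-1, min(1, R[1, 3])))
  if (abs(cos(b)) > 1e-10) {
    a <- atan2(-R[2, 3], R[3, 3])
    g <- atan2(-R[1, 2], R[1, 1])
  } else {          # gimbal lock: fold everything into the x angle
    a <- atan2(R[2, 1], R[2, 2])
    g <- 0
  }
  c(a, b, g) * 180 / pi
}

transform_offset <- function(t) {
  R <- rotation_matrix(t$angles_deg)
  list(R = R, o = as.numeric(t$center_mm + t$translation_mm - R %*% t$center_mm))
}

#' Apply a rigid transform to physical points
#'
#' @param t a [rigid_transform()].
#' @param pts n x 3 matrix of mm coordinates.
#' @return n x 3 matrix of transformed coordinates.
#' @export
transform_points <- function(t, pts) {
  m <- transform_offset(t)
  pts <- rbind(pts)
  sweep(pts %*% t(m$R), 2L, m$o, `+`)
}

#' Compose two rigid transforms
#'
#' `compose_transform(t1, t2)` is the transform that applies `t2` first and
#' then `t1`. The result is expressed about `t1`'s rotation centre.
#'
#' @param t1,t2 [rigid_transform()] objects.
#' @export
compose_transform <- function(t1, t2) {
  m1 <- transform_offset(t1); m2 <- transform_offset(t2)
  R <- m1$R %*% m2$R
  o <- as.numeric(m1$R %*% m2$o + m1$o)
  c0 <- t1$center_mm
  rigid_transform(rotation_angles(R), o - c0 + as.numeric(R %*% c0), c0)
}

#' Invert a rigid transform
#'
#' @param t a [rigid_transform()].
#' @export
invert_transform <- function(t) {
  m <- transform_offset(t)
  Rt <- t(m$R)
  o <- as.numeric(-Rt %*% m$o)
  c0 <- t$center_mm
  rigid_transform(rotation_angles(Rt), o - c0 + as.numeric(Rt %*% c0), c0)
}

#' Resample a volume under a rigid transform
#'
#' `t` maps the input volume's physical coordinates into the reference
#' frame; the input is resampled onto the reference grid so that
#' `out(p) = vol(T^-1(p))` for every reference voxel centre `p`.
#' Voxels mapping outside the input field of view are set to `background`.
#'
#' @param vol the volume to resample.
#' @param t a [rigid_transform()] mapping `vol` coordinates to reference
#'   coordinates.
#' @param reference the volume whose grid defines the output (defaults to
#'   `vol` itself).
#' @param interpolation `"linear"` (default) or `"nearest"`.
#' @param background value for out-of-field voxels (default 0).
#' @return the resampled `mct_volume` on the reference grid.
#' @export
apply_transform <- function(vol, t, reference = vol,
                            interpolation = c("linear", "nearest"),
                            background = 0) {
  stopifnot_volume(vol); stopifnot_volume(reference)
  interpolation <- match.arg(interpolation)
  d <- dim(reference$data)
  inv <- transform_offset(invert_transform(t))
  # reference voxel centres -> physical -> back through T^-1 -> vol voxel idx
  ii <- seq_len(d[1]) - 1L; jj <- seq_len(d[2]) - 1L; kk <- seq_len(d[3]) - 1L
  px <- reference$origin[1] + ii * reference$spacing[1]
  py <- reference$origin[2] + jj * reference$spacing[2]
  pz <- reference$origin[3] + kk * reference$spacing[3]
  grid <- cbind(rep(px, times = d[2] * d[3]),
                rep(rep(py, each = d[1]), times = d[3]),
                rep(pz, each = d[1] * d[2]))
  src <- sweep(grid %*% t(inv$R), 2L, inv$o, `+`)
  src_idx <- sweep(sweep(src, 2L, vol$origin, `-`), 2L, vol$spacing, `/`)
  vals <- if (interpolation == "linear")
    cpp_trilinear_sample(vol$data, dim(vol$data), src_idx, background)
  else
    cpp_nearest_sample(vol$data, dim(vol$data), src_idx, background)
  volume(array(vals, d), reference$spacing, reference$origin)
}

#' Write / read a rigid transform as JSON
#'
#' @param t a [rigid_transform()].
#' @param path JSON file path.
#' @export
write_transform <- function(t, path) {
  jsonlite::write_json(unclass(t), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$angles_deg, x$translation_mm, x$center_mm)
}
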