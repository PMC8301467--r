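#' Construct a 3D volume with physical spacing
#'
#' The basic imaging container of the package: a 3D scalar grid (attenuation
#' in arbitrary units, or a \{0,1\} mask) with per-axis voxel spacing and a
#' physical origin, all in millimetres. Axis order is documented as
#' x = left-right, y = rostral-caudal, z = ventral-dorsal. Voxel indexing is
#' zero-based and half-open throughout; the physical coordinate of voxel
#' (i, j, k) is its centre, `origin + c(i, j, k) * spacing`.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length 3, mm per voxel along each axis (all > 0).
#'   A scalar is recycled to all three axes.
#' @param origin numeric length 3, physical coordinate (mm) of voxel (0,0,0).
#' @return An object of class `mct_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @export
volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop("volume grid must be non-empty")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm/voxel)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "mct_volume")
}

#' @export
print.mct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mct_volume> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing (mm): %s\n", paste(signif(x$spacing, 6), collapse = " x ")))
  cat(sprintf("  origin  (mm): %s\n", paste(signif(x$origin, 6), collapse = ", ")))
  cat(sprintf("  intensity:    [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.mct_volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "mct_volume")

stopifnot_volume <- function(x) {
  if (!is_volume(x)) stop("expected an `mct_volume` (see `volume()`)")
  invisible(x)
}

#' Physical coordinates of voxel indices
#'
#' @param vol an [volume()].
#' @param idx n x 3 matrix of zero-based voxel indices (may be fractional).
#' @return n x 3 matrix of physical mm coordinates (voxel centres).
#' @export
voxel_to_physical <- function(vol, idx) {
  stopifnot_volume(vol)
  idx <- rbind(idx)
  dimnames(idx) <- NULL
  sweep(sweep(idx, 2L, vol$spacing, `*`), 2L, vol$origin, `+`)
}

#' Voxel indices (fractional, zero-based) of physical coordinates
#'
#' @inheritParams voxel_to_physical
#' @param pts n x 3 matrix of physical mm coordinates.
#' @export
physical_to_voxel <- function(vol, pts) {
  stopifnot_volume(vol)
  pts <- rbind(pts)
  dimnames(pts) <- NULL
  sweep(sweep(pts, 2L, vol$origin, `-`), 2L, vol$spacing, `/`)
}

#' Bounding box in voxel indices
#'
#' Zero-based, half-open interval `[lo, hi)` per axis.
#'
#' @param lo,hi integer vectors of length 3 with `lo < hi`.
#' @export
bounding_box <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L) stop("lo/hi must have length 3")
  if (any(lo < 0L)) stop("bounding box lo must be >= 0")
  if (any(hi <= lo)) stop("empty bounding box rejected: need lo < hi on every axis")
  structure(list(lo = lo, hi = hi), class = "mct_bbox")
}

#' Crop a volume to a bounding box
#'
#' The origin is shifted so every retained voxel keeps its physical
#' coordinate (the spacing/origin contract of the package).
#'
#' @param vol an [volume()].
#' @param box a [bounding_box()] in zero-based half-open voxel indices.
#' @return the cropped `mct_volume`.
#' @export
crop <- function(vol, box) {
  stopifnot_volume(vol)
  if (!inherits(box, "mct_bbox")) stop("`box` must be a bounding_box()")
  d <- dim(vol$data)
  if (any(box$hi > d)) stop("bounding box exceeds the volume grid")
  sub <- vol$data[(box$lo[1] + 1L):box$hi[1],
                  (box$lo[2] + 1L):box$hi[2],
                  (box$lo[3] + 1L):box$hi[3], drop = FALSE]
  volume(sub, vol$spacing, vol$origin + box$lo * vol$spacing)
}

#' Binarize a volume at an intensity threshold
#'
#' @param vol an [volume()].
#' @param threshold intensity (a.u.); mask is 1 where `data >= threshold`.
#' @return an `mct_volume` mask containing only 0/1.
#' @export
binarize <- function(vol, threshold) {
  stopifnot_volume(vol)
  m <- array(0, dim(vol$data))
  m[vol$data >= threshold] <- 1
  volume(m, vol$spacing, vol$origin)
}

#' Surface voxels of a binary mask
#'
#' A mask voxel belongs to the surface when at least one of its six
#' face-connected neighbours is background (voxels on the grid border count
#' their missing neighbours as background). This is the display/measurement
#' oriented "skeletonization" of the pipeline, not a medial-axis transform.
#'
#' @param mask an `mct_volume` mask (0/1).
#' @return an `mct_volume` mask of surface voxels (empty input gives an empty
#'   surface).
#' @export
extract_surface <- function(mask) {
  stopifnot_volume(mask)
  m <- mask$data != 0
  d <- dim(m)
  interior <- array(TRUE, d)
  shift_and <- function(acc, ax, dir) {
    pad <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (dir > 0) {
      idx_dst[[ax]] <- seq_len(d[ax] - 1L)
      idx_src[[ax]] <- 2:d[ax]
    } else {
      idx_dst[[ax]] <- 2:d[ax]
      idx_src[[ax]] <- seq_len(d[ax] - 1L)
    }
    do.call(`[<-`, c(list(pad), idx_dst, list(do.call(`[`, c(list(m), idx_src)))))
  }
  for (ax in 1:3) for (dir in c(-1, 1)) {
    if (d[ax] == 1L) {
      interior[] <- FALSE   # border along a singleton axis: all surface
    } else {
      interior <- interior & shift_and(interior, ax, dir)
    }
  }
  # border voxels of the grid are never interior
  if (d[1] > 1L) interior[c(1L, d[1]), , ] <- FALSE else interior[] <- FALSE
  if (d[2] > 1L) interior[, c(1L, d[2]), ] <- FALSE
  if (d[3] > 1L) interior[, , c(1L, d[3])] <- FALSE
  surf <- array(0, d)
  surf[m & !interior] <- 1
  volume(surf, mask$spacing, mask$origin)
}

#' Label 6-connected components of a binary mask
#'
#' @param mask an `mct_volume` mask (0/1).
#' @return an `mct_volume` whose data holds integer labels 0 (background),
#'   1..k, with an attribute `n_components`.
#' @export
label_components <- function(mask) {
  stopifnot_volume(mask)
  lab <- cpp_label6(mask$data != 0, dim(mask$data))
  out <- volume(array(as.numeric(lab), dim(mask$data)), mask$spacing, mask$origin)
  attr(out, "n_components") <- max(lab)
  out
}
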