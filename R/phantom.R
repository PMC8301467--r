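# Voxel hemi-mandible phantoms with analytically known incisor geometry.
#
# The phantom world: axis x = left-right (left at +x), y = rostral-caudal
# (+y rostral), z = ventral-dorsal (+z dorsal), units mm. A whole-mandible
# phantom is two mirrored hemi-mandibles separated by a non-bony symphysis
# gap. Each hemi-mandible is a tooth-bearing body box, a taller posterior
# ramus box, a molar row whose buccal cusp tips are coplanar (they define
# the occlusal plane), and an elodont incisor: a tube of radius r_tube
# around a planar circular-arc centerline in the sagittal plane, ending in
# a planar bevel cut whose edge on the lingual surface is the gnaw ridge.
# The erupted crown is the part of the tube rostral to the flat anterior
# face of the body box (the alveolus plane).
#
# Intensities: background 0, bone 1000, teeth 1400 a.u., with a one-voxel
# partial-volume ramp at surfaces (CT-like edge profile, and what makes
# sub-voxel measurement honest). Binarization threshold 500 separates bone
# from background; 1200 separates teeth from bone.

#' Default segmentation thresholds of the phantom world
#'
#' @return list with `bone` (500 a.u.) and `tooth` (1200 a.u.) thresholds
#'   and the nominal `bone_intensity` (1000) / `tooth_intensity` (1400).
#' @export
default_thresholds <- function() {
  list(bone = 500, tooth = 1200, bone_intensity = 1000, tooth_intensity = 1400)
}

species_preset <- function(species) {
  switch(species,
    rat = list(
      voxel_mm = 0.046,
      body_y = c(0, 14), body_z = c(0, 7), body_w = 3.5, gap = 1.2,
      ramus_y = c(-6, 0), ramus_z = c(0, 12),
      incisor = list(R = 8.5, r_tube = 0.8, bevel_deg = 40,
                     crown_labial_mm = 12.66, theta_alv_deg = 8,
                     theta_root_deg = -12, emergence_z = 4),
      molars = list(labels = c("#1", "#2", "#3"), y_center = c(6, 8.5, 11),
                    size_y = 1.8, size_x = 2.6, heights = c(2, 2, 2),
                    occlusal_z = 9, root_depth = 1, cusp_relief = 0.6,
                    collar_pad = 1.2),
      margin = 0.8),
    rabbit = list(
      voxel_mm = 0.09,
      body_y = c(0, 30), body_z = c(0, 13), body_w = 5, gap = 2,
      ramus_y = c(-14, 0), ramus_z = c(0, 27),
      incisor = list(R = 10, r_tube = 1.1, bevel_deg = 45,
                     crown_labial_mm = 11.5, theta_alv_deg = 8,
                     theta_root_deg = -20, emergence_z = 5),
      molars = list(labels = c("#2", "#3", "#4", "#5"),
                    y_center = c(17, 14, 11, 8),
                    size_y = 2.2, size_x = 2.4,
                    heights = c(5.3, 3.4, 4.1, 3.0),
                    occlusal_z = 18.5, root_depth = 2, cusp_relief = 0.8,
                    collar_pad = 1.2),
      margin = 0.9),
    stop("unknown species preset: ", species)
  )
}

#' Specify a hemi-mandible phantom
#'
#' Builds a fully resolved phantom description from a species preset plus
#' overrides. The rat preset voxel size is 0.046 mm and the rabbit preset
#' 0.09 mm (0.18 mm is the low-resolution survey setting); tests and demos
#' typically override `voxel_mm` upwards for speed.
#'
#' @param species `"rat"` or `"rabbit"`.
#' @param voxel_mm isotropic voxel edge (mm); default from the preset.
#' @param sides `"both"`, `"left"` or `"right"`.
#' @param noise_sd additive Gaussian noise SD as a fraction of the bone
#'   intensity dynamic range (0-1000 a.u.); 0.05 means SD 50 a.u.
#' @param seed integer seed for the noise generator.
#' @param incisor named list of per-side incisor overrides. Entries apply to
#'   both sides unless wrapped in `list(left = ..., right = ...)`. Fields:
#'   `R` (centerline arc radius mm), `r_tube` (tube radius mm), `bevel_deg`
#'   (angle between the occlusal facet and the labial tangent at the tip,
#'   in (0, 90)), `crown_labial_mm` (erupted labial path length mm),
#'   `theta_alv_deg`, `theta_root_deg`, `emergence_z`.
#' @param molars named list of molar-row overrides (see `species_preset`).
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(species = c("rat", "rabbit"), voxel_mm = NULL,
                         sides = c("both", "left", "right"), noise_sd = 0,
                         seed = 1L, incisor = list(), molars = list()) {
  species <- match.arg(species)
  sides <- match.arg(sides)
  p <- species_preset(species)
  if (!is.null(voxel_mm)) p$voxel_mm <- voxel_mm
  if (length(p$voxel_mm) != 1L || p$voxel_mm <= 0)
    stop("voxel_mm must be a single positive value")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  per_side <- function(ov, side) {
    base <- p$incisor
    flat <- ov[setdiff(names(ov), c("left", "right"))]
    base <- utils::modifyList(base, flat)
    if (!is.null(ov[[side]])) base <- utils::modifyList(base, ov[[side]])
    base
  }
  inc <- list(left = per_side(incisor, "left"),
              right = per_side(incisor, "right"))
  for (side in names(inc)) {
    ip <- inc[[side]]
    if (ip$r_tube <= 0 || ip$R <= ip$r_tube)
      stop("incisor tube radius must be positive and smaller than the arc ",
           "radius (self-intersecting centerline)")
    if (ip$crown_labial_mm < 0) stop("crown length must be >= 0")
    if (ip$bevel_deg <= 0 || ip$bevel_deg >= 90)
      stop("bevel angle must lie in (0, 90) degrees")
    if (p$voxel_mm > ip$r_tube)
      stop("voxel size (", p$voxel_mm, " mm) larger than the incisor tube ",
           "radius (", ip$r_tube, " mm): geometry unresolvable")
    incisor_truth(ip, p$body_y[2])   # validates bevel/crown geometry
  }
  p$molars <- utils::modifyList(p$molars, molars)
  structure(list(species = species, voxel_mm = p$voxel_mm, sides = sides,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 geometry = p, incisor = inc),
            class = "phantom_spec")
}

#' Specify a surgical defect for the phantom
#'
#' Geometric defect modes (no healing biology): `CSD` critical-size defect
#' (rat: 5 mm sphere; rabbit: 8 x 8 mm through-cylinder) in the anterior
#' ramus; `ID` intermediate ramus defect preserving a dorsal strut (rat
#' 5 x 9 mm, rabbit 23 mm ventral-dorsal); `CRO_narrow` / `CRO_wide`
#' complete ramus osteotomy with a 1 mm / 3 mm gap separating the
#' tooth-bearing body from the ramus; `BODY` 10 x 12 mm body defect under
#' the cheek teeth (rabbit).
#'
#' @param type defect type.
#' @param side `"left"` (the demo default; defects are created unilaterally)
#'   or `"right"`.
#' @param size_mm optional named list overriding the per-type default
#'   dimensions (`diameter`, `width_y`, `extent_z`, `gap`).
#' @export
defect_spec <- function(type = c("none", "CSD", "ID", "CRO_narrow",
                                 "CRO_wide", "BODY"),
                        side = c("left", "right"), size_mm = list()) {
  type <- match.arg(type)
  side <- match.arg(side)
  structure(list(type = type, side = side, size_mm = size_mm),
            class = "defect_spec")
}

side_sign <- function(side) if (side == "left") 1 else -1

# Closed-form incisor landmark geometry for one side.
# Angles are measured from the ventral-most point of the arc, increasing
# rostrally/dorsally: centerline point p(theta) = c + R (sin theta, -cos theta)
# in the (y, z) sagittal plane.
incisor_truth <- function(ip, y_face) {
  A <- ip$R + ip$r_tube
  B <- ip$R - ip$r_tube
  cz <- ip$emergence_z + A * cos(ip$theta_alv_deg * pi / 180)
  cy <- y_face - A * sin(ip$theta_alv_deg * pi / 180)
  th_alv_out <- asin((y_face - cy) / A)
  th_alv_in <- asin((y_face - cy) / B)
  th_tip <- th_alv_out + ip$crown_labial_mm / A
  if (th_tip >= pi / 2 + 0.35)
    stop("crown length sweeps the arc past vertical; increase R or shorten crown")
  beta <- ip$bevel_deg * pi / 180
  tip <- c(cy, cz) + A * c(sin(th_tip), -cos(th_tip))
  u <- -c(cos(th_tip - beta), sin(th_tip - beta))     # facet direction, tip -> ridge
  disc <- A^2 * sin(beta)^2 - (A^2 - B^2)
  if (disc < 0)
    stop("bevel angle too shallow: the occlusal facet never reaches the ",
         "lingual surface (increase bevel_deg or r_tube)")
  s_occ <- A * sin(beta) - sqrt(disc)
  ridge <- tip + s_occ * u
  th_ridge <- atan2(ridge[1] - cy, cz - ridge[2])
  list(center = c(cy, cz), A = A, B = B,
       theta_alv_out = th_alv_out, theta_alv_in = th_alv_in,
       theta_tip = th_tip, theta_ridge = th_ridge,
       theta_root = ip$theta_root_deg * pi / 180,
       tip = tip, ridge = ridge,
       alv_labial = c(cy, cz) + A * c(sin(th_alv_out), -cos(th_alv_out)),
       alv_lingual = c(cy, cz) + B * c(sin(th_alv_in), -cos(th_alv_in)),
       facet_u = u, facet_normal = c(u[2], -u[1]),
       labial_mm = ip$crown_labial_mm,
       lingual_mm = B * (th_ridge - th_alv_in),
       occlusal_mm = s_occ,
       occlusal_angle_deg = atan2(tip[2] - ridge[2], abs(tip[1] - ridge[1])) *
         180 / pi)
}

phantom_truth <- function(spec) {
  g <- spec$geometry
  sides <- if (spec$sides == "both") c("left", "right") else spec$sides
  out <- list()
  for (side in sides) {
    it <- incisor_truth(spec$incisor[[side]], g$body_y[2])
    heights <- g$molars$heights
    names(heights) <- g$molars$labels
    out[[side]] <- list(
      labial_mm = it$labial_mm, lingual_mm = it$lingual_mm,
      occlusal_mm = it$occlusal_mm,
      occlusal_angle_deg = it$occlusal_angle_deg,
      cheek_heights_mm = heights, arc = it)
  }
  structure(list(sides = out, occlusal_plane_z = g$molars$occlusal_z,
                 applied_pose = rigid_transform(),
                 defect_removed_mm3 = 0),
            class = "phantom_truth")
}

ramp01 <- function(d, h) pmin(pmax(0.5 - d / h, 0), 1)

# Per-slice union of box signed distances. xs, ys are 1D coord vectors; zv a
# scalar. boxes: list of list(x = c(lo, hi), y = c(lo, hi), z = c(lo, hi)).
slice_box_dist <- function(xs, ys, zv, boxes) {
  d <- matrix(Inf, length(xs), length(ys))
  for (b in boxes) {
    dz <- max(b$z[1] - zv, zv - b$z[2])
    if (dz > 1) next                     # slice far from the box
    dx <- pmax(b$x[1] - xs, xs - b$x[2])
    dy <- pmax(b$y[1] - ys, ys - b$y[2])
    db <- pmax(outer(dx, dy, pmax), dz)
    d <- pmin(d, db)
  }
  d
}

slice_incisor_dist <- function(xs, ys, zv, it, x_inc, r_tube) {
  cy <- it$center[1]; cz <- it$center[2]
  rho <- sqrt((ys - cy)^2 + (zv - cz)^2)
  theta <- atan2(ys - cy, cz - zv)
  dr <- abs(rho - (it$A + it$B) / 2)     # distance to centerline radius R
  dx <- abs(xs - x_inc)
  d <- sqrt(outer(dx^2, dr^2, `+`)) - r_tube
  # clip at the root end (radial plane at theta_root)
  d_root <- ((it$A + it$B) / 2) * (it$theta_root - theta)
  d <- pmax(d, matrix(d_root, nrow = length(xs), ncol = length(ys),
                      byrow = TRUE))
  # bevel cut, applied only beyond the gnaw-ridge angle
  s_bev <- it$facet_normal[1] * (ys - it$tip[1]) +
    it$facet_normal[2] * (zv - it$tip[2])
  s_bev[theta < it$theta_ridge - 0.02] <- -Inf
  pmax(d, matrix(s_bev, nrow = length(xs), ncol = length(ys), byrow = TRUE))
}

hemi_primitives <- function(spec, side) {
  g <- spec$geometry
  s <- side_sign(side)
  x_lo <- g$gap / 2; x_hi <- g$gap / 2 + g$body_w
  xr <- sort(s * c(x_lo, x_hi))
  x_c <- s * (x_lo + x_hi) / 2
  m <- g$molars
  bone <- list(list(x = xr, y = g$body_y, z = g$body_z),
               list(x = xr, y = g$ramus_y, z = g$ramus_z))
  tooth <- list()
  body_top <- g$body_z[2]
  for (i in seq_along(m$labels)) {
    collar_z <- m$occlusal_z - m$heights[i]
    yr <- m$y_center[i] + c(-1, 1) * m$size_y / 2
    xt <- sort(x_c + c(-1, 1) * m$size_x / 2)
    if (collar_z > body_top + 1e-9) {
      pad <- m$collar_pad / 2
      bone[[length(bone) + 1L]] <-
        list(x = sort(x_c + c(-1, 1) * (m$size_x / 2 + pad)),
             y = yr + c(-pad, pad), z = c(body_top, collar_z))
    }
    # crown body (lingual relief) plus a buccal cusp reaching occlusal_z
    tooth[[length(tooth) + 1L]] <-
      list(x = xt, y = yr, z = c(collar_z - m$root_depth,
                                 m$occlusal_z - m$cusp_relief))
    buccal <- if (s > 0) c(x_c, xt[2]) else c(xt[1], x_c)
    tooth[[length(tooth) + 1L]] <-
      list(x = buccal, y = yr, z = c(collar_z - m$root_depth, m$occlusal_z))
  }
  it <- incisor_truth(spec$incisor[[side]], g$body_y[2])
  list(bone = bone, tooth = tooth, incisor = it, x_inc = x_c,
       r_tube = spec$incisor[[side]]$r_tube)
}

phantom_grid <- function(spec) {
  g <- spec$geometry
  v <- spec$voxel_mm
  mar <- g$margin
  tips <- lapply(c("left", "right"), function(sd)
    incisor_truth(spec$incisor[[sd]], g$body_y[2]))
  y_hi <- max(vapply(tips, function(t) t$tip[1], 0)) + mar
  z_hi <- max(vapply(tips, function(t) t$tip[2], 0),
              g$molars$occlusal_z, g$ramus_z[2]) + mar
  y_lo <- g$ramus_y[1] - mar
  z_lo <- g$body_z[1] - mar
  x_out <- g$gap / 2 + g$body_w + mar
  if (spec$sides == "both") {
    nx <- 2L * as.integer(ceiling(x_out / v))
    xs <- (seq_len(nx) - (nx + 1) / 2) * v       # symmetric about x = 0
  } else {
    x_in <- max(g$gap / 2 - 2 * v, 0)
    nxh <- as.integer(ceiling((x_out - x_in) / v))
    xs <- x_in + (seq_len(nxh) - 0.5) * v
    if (spec$sides == "right") xs <- rev(-xs)
  }
  ny <- as.integer(ceiling((y_hi - y_lo) / v))
  nz <- as.integer(ceiling((z_hi - z_lo) / v))
  ys <- y_lo + (seq_len(ny) - 0.5) * v
  zs <- z_lo + (seq_len(nz) - 0.5) * v
  list(xs = xs, ys = ys, zs = zs)
}

#' Generate a hemi-mandible voxel phantom
#'
#' Rasterizes the phantom described by `spec` (optionally with a surgical
#' defect) into a grayscale volume, and returns the analytic ground truth
#' computed from the specification, never from the voxelization.
#'
#' @param spec a [phantom_spec()].
#' @param defect a [defect_spec()] (default: none).
#' @return list with `volume` (an [volume()] carrying a `phantom_geometry`
#'   attribute used for defect placement), `truth` (a `phantom_truth`:
#'   per-side labial/lingual/occlusal path lengths, occlusal angle,
#'   cheek-tooth heights, and landmark geometry), and if a defect was
#'   applied, `removed_mm3` and `component_count` from [apply_defect()].
#' @export
make_phantom <- function(spec, defect = defect_spec("none")) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec()")
  grid <- phantom_grid(spec)
  xs <- grid$xs; ys <- grid$ys; zs <- grid$zs
  sides <- if (spec$sides == "both") c("left", "right") else spec$sides
  prim <- lapply(sides, function(sd) hemi_primitives(spec, sd))
  h <- spec$voxel_mm
  thr <- default_thresholds()
  arr <- array(0, c(length(xs), length(ys), length(zs)))
  for (k in seq_along(zs)) {
    zv <- zs[k]
    gray <- matrix(0, length(xs), length(ys))
    for (p in prim) {
      db <- slice_box_dist(xs, ys, zv, p$bone)
      dt <- slice_box_dist(xs, ys, zv, p$tooth)
      di <- slice_incisor_dist(xs, ys, zv, p$incisor, p$x_inc, p$r_tube)
      gray <- pmax(gray, thr$bone_intensity * ramp01(db, h),
                   thr$tooth_intensity * ramp01(pmin(dt, di), h))
    }
    arr[, , k] <- gray
  }
  vol <- volume(arr, spec$voxel_mm,
                c(xs[1], ys[1], zs[1]))
  attr(vol, "phantom_geometry") <- list(spec_species = spec$species,
                                        geometry = spec$geometry,
                                        sides = sides)
  truth <- phantom_truth(spec)
  res <- list(volume = vol, truth = truth)
  if (defect$type != "none") {
    mask <- binarize(vol, thr$bone)
    dres <- apply_defect(vol, mask, defect)
    res$volume <- dres$volume
    res$removed_mm3 <- dres$removed_mm3
    res$component_count <- dres$component_count
    res$truth$defect_removed_mm3 <- dres$removed_mm3
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    res$volume$data <- res$volume$data +
      array(stats::rnorm(length(res$volume$data), 0,
                         spec$noise_sd * thr$bone_intensity),
            dim(res$volume$data))
  }
  res
}

defect_region_params <- function(defect, geom) {
  g <- geom$geometry
  s <- side_sign(defect$side)
  x_slab <- sort(s * c(g$gap / 2 - 1, g$gap / 2 + g$body_w + 1))
  ry <- g$ramus_y; rz <- g$ramus_z
  sz <- defect$size_mm
  species <- geom$spec_species
  d <- switch(defect$type,
    CSD = if (species == "rat") {
      list(kind = "sphere", center = c(s * (g$gap / 2 + g$body_w / 2),
                                       mean(ry), mean(rz)),
           radius = (sz$diameter %||% 5) / 2)
    } else {
      list(kind = "cylinder_x", center_yz = c(mean(ry), mean(rz)),
           radius = (sz$diameter %||% 8) / 2, x = x_slab)
    },
    ID = {
      wy <- sz$width_y %||% (if (species == "rat") 5 else 8)
      ez <- sz$extent_z %||% (if (species == "rat") 9 else 23)
      z_lo <- rz[1] + 0.75
      list(kind = "box", x = x_slab, y = mean(ry) + c(-1, 1) * wy / 2,
           z = c(z_lo, z_lo + ez))
    },
    CRO_narrow = list(kind = "box", x = x_slab,
                      y = c(-(sz$gap %||% 1), 0),
                      z = c(rz[1] - 1, rz[2] + 1)),
    CRO_wide = list(kind = "box", x = x_slab,
                    y = c(-(sz$gap %||% 3), 0),
                    z = c(rz[1] - 1, rz[2] + 1)),
    BODY = {
      wy <- sz$width_y %||% 12
      ez <- sz$extent_z %||% 10
      yc <- mean(range(g$molars$y_center))
      list(kind = "box", x = x_slab, y = yc + c(-1, 1) * wy / 2,
           z = c(g$body_z[1] - 1, g$body_z[1] + ez))
    },
    stop("unsupported defect type: ", defect$type)
  )
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a surgical defect to a phantom volume
#'
#' Sets every voxel inside the defect geometry to background and reports the
#' removed physical bone volume and the number of 6-connected bone
#' components on the defect side (a complete ramus osteotomy separates the
#' tooth-bearing body from the ramus, giving two components; an intermediate
#' defect leaves the dorsal strut and a single component).
#'
#' @param vol grayscale phantom volume (must carry the `phantom_geometry`
#'   attribute from [make_phantom()] unless the defect provides its own
#'   placement).
#' @param mask bone mask volume (1 where bone/tooth).
#' @param defect a [defect_spec()].
#' @return list with `volume` (defected), `removed_mm3`, `component_count`.
#' @export
apply_defect <- function(vol, mask, defect) {
  stopifnot_volume(vol); stopifnot_volume(mask)
  if (!inherits(defect, "defect_spec")) stop("`defect` must be a defect_spec()")
  if (defect$type == "none")
    return(list(volume = vol, removed_mm3 = 0,
                component_count = NA_integer_))
  geom <- attr(vol, "phantom_geometry")
  if (is.null(geom))
    stop("volume lacks phantom geometry metadata; defects can only be ",
         "placed on make_phantom() output")
  reg <- defect_region_params(defect, geom)
  d <- dim(vol$data)
  xs <- vol$origin[1] + (seq_len(d[1]) - 1L) * vol$spacing[1]
  ys <- vol$origin[2] + (seq_len(d[2]) - 1L) * vol$spacing[2]
  zs <- vol$origin[3] + (seq_len(d[3]) - 1L) * vol$spacing[3]
  inside <- switch(reg$kind,
    sphere = {
      outer(outer((xs - reg$center[1])^2, (ys - reg$center[2])^2, `+`),
            (zs - reg$center[3])^2, `+`) <= reg$radius^2
    },
    cylinder_x = {
      inplane <- outer((ys - reg$center_yz[1])^2,
                       (zs - reg$center_yz[2])^2, `+`) <= reg$radius^2
      xin <- xs >= reg$x[1] & xs <= reg$x[2]
      outer(xin, inplane, `&`)
    },
    box = {
      xin <- xs >= reg$x[1] & xs <= reg$x[2]
      yin <- ys >= reg$y[1] & ys <= reg$y[2]
      zin <- zs >= reg$z[1] & zs <= reg$z[2]
      outer(outer(xin, yin, `&`), zin, `&`)
    })
  dim(inside) <- d
  removed <- sum(mask$data != 0 & inside)
  out <- vol
  out$data[inside] <- 0
  new_mask <- mask$data != 0 & !inside
  s <- side_sign(defect$side)
  side_sel <- if (s > 0) xs > 0 else xs < 0
  side_mask <- new_mask[side_sel, , , drop = FALSE]
  lab <- cpp_label6(side_mask, dim(side_mask))
  sizes <- tabulate(lab[lab > 0])
  comp <- sum(sizes > 20)
  attr(out, "phantom_geometry") <- geom
  list(volume = out, removed_mm3 = removed * prod(vol$spacing),
       component_count = comp)
}

#' Perturb the pose of a volume (simulated repositioning between scans)
#'
#' Resamples the volume under a rigid transform on its own grid, emulating
#' animal repositioning between longitudinal scans. Perturbations are capped
#' at +-10 degrees / +-5 mm: the registration capture range is documented,
#' not unlimited.
#'
#' @param vol an [volume()].
#' @param transform a [rigid_transform()]; if `NULL`, one is drawn uniformly
#'   within `max_rot_deg` / `max_trans_mm` using `seed`.
#' @param seed integer seed for a random pose.
#' @param max_rot_deg,max_trans_mm pose caps (defaults 10 deg / 5 mm).
#' @param interpolation `"linear"` or `"nearest"`.
#' @return the resampled volume; the pose is recorded in the
#'   `applied_pose` attribute.
#' @export
perturb_pose <- function(vol, transform = NULL, seed = NULL,
                         max_rot_deg = 10, max_trans_mm = 5,
                         interpolation = c("linear", "nearest")) {
  stopifnot_volume(vol)
  interpolation <- match.arg(interpolation)
  center <- vol$origin + (dim(vol$data) - 1) / 2 * vol$spacing
  if (is.null(transform)) {
    if (!is.null(seed)) set.seed(seed)
    transform <- rigid_transform(stats::runif(3, -max_rot_deg, max_rot_deg),
                                 stats::runif(3, -max_trans_mm, max_trans_mm),
                                 center)
  }
  if (any(abs(transform$angles_deg) > max_rot_deg + 1e-9) ||
      any(abs(transform$translation_mm) > max_trans_mm + 1e-9))
    stop("pose perturbation exceeds the documented capture range (+-",
         max_rot_deg, " deg / +-", max_trans_mm, " mm)")
  geom <- attr(vol, "phantom_geometry")
  out <- apply_transform(vol, transform, vol, interpolation = interpolation)
  attr(out, "applied_pose") <- transform
  attr(out, "phantom_geometry") <- geom
  out
}
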