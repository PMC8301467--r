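# Dental morphometry in the occlusal-plane frame.
#
# The measurement frame is defined by the molars: the total-least-squares
# plane through the buccal cusp tips becomes the horizontal plane. Incisor
# metrics are taken in the mid-sagittal slice of each incisor: path length
# along the labial surface from the alveolar bone edge to the tip, along
# the lingual surface from the alveolar edge to the gnaw ridge, and along
# the occlusal facet from gnaw ridge to tip; plus the occlusal inclination
# angle between the facet and the horizontal plane. Cheek-tooth heights run
# from the edge of the bony alveolus to the tip of the highest buccal cusp.
#
# Landmark operators (the anatomy does not define them as algorithms):
#  * tip: contour point farthest along the eruption (dorsal) direction;
#  * alveolar edge: contour point nearest the most dorsal bone voxel
#    touching that side (labial/lingual) of the incisor outline;
#  * gnaw ridge: end of the maximal straight (bevel facet) run of contour
#    points leaving the tip on the lingual side, refined to the
#    intersection of the facet line with the lingual arc.

#' Total-least-squares plane through 3D points
#'
#' @param points n x 3 matrix of mm coordinates (n >= 3, non-collinear).
#' @return an `mct_plane`: `point` (centroid) and unit `normal` oriented
#'   dorsally (positive z component).
#' @export
fit_occlusal_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("plane fit needs at least 3 points")
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2L, ctr, `-`))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-12))
    stop("degenerate (collinear) points: occlusal plane undefined")
  n <- sv$v[, 3]
  if (n[3] < 0) n <- -n
  if (abs(n[3]) < 1e-12 && (n[1] < 0 || (n[1] == 0 && n[2] < 0))) n <- -n
  structure(list(point = ctr, normal = n / sqrt(sum(n^2))), class = "mct_plane")
}

#' Reorient a volume so a plane becomes horizontal
#'
#' Applies the rotation taking the plane normal to the +z axis, about the
#' plane point, and resamples on the original grid.
#'
#' @param vol an [volume()].
#' @param plane an `mct_plane` from [fit_occlusal_plane()].
#' @param interpolation passed to [apply_transform()].
#' @return list with `volume` (reoriented) and `transform` (the
#'   [rigid_transform()] used).
#' @export
reorient_to_occlusal <- function(vol, plane,
                                 interpolation = c("linear", "nearest")) {
  stopifnot_volume(vol)
  interpolation <- match.arg(interpolation)
  n <- plane$normal / sqrt(sum(plane$normal^2))
  z <- c(0, 0, 1)
  a <- c(n[2] * z[3] - n[3] * z[2], n[3] * z[1] - n[1] * z[3],
         n[1] * z[2] - n[2] * z[1])
  s <- sqrt(sum(a^2)); cth <- sum(n * z)
  if (s < 1e-12) {
    R <- if (cth > 0) diag(3) else rotation_matrix(c(180, 0, 0))
  } else {
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    R <- diag(3) + K + K %*% K * ((1 - cth) / s^2)
  }
  t <- rigid_transform(rotation_angles(R), c(0, 0, 0), plane$point)
  geom <- attr(vol, "phantom_geometry")
  out <- apply_transform(vol, t, vol, interpolation = interpolation)
  attr(out, "phantom_geometry") <- geom
  list(volume = out, transform = t)
}

# Connected tooth components with centroids (voxel and mm).
tooth_components <- function(vol, tooth_threshold = default_thresholds()$tooth,
                             min_voxels = 20L) {
  lab <- cpp_label6(vol$data >= tooth_threshold, dim(vol$data))
  idx <- which(lab > 0L)
  if (!length(idx))
    return(list(labels = lab, stats = data.frame()))
  ids <- lab[idx]
  d <- dim(vol$data)
  i0 <- (idx - 1L) %% d[1]
  j0 <- ((idx - 1L) %/% d[1]) %% d[2]
  k0 <- (idx - 1L) %/% (d[1] * d[2])
  n <- tabulate(ids)
  sums <- rowsum(cbind(i0, j0, k0), ids)
  keep <- which(n >= min_voxels)
  cent <- sums[as.character(keep), , drop = FALSE] / n[keep]
  st <- data.frame(id = keep, n = n[keep],
                   cx = vol$origin[1] + cent[, 1] * vol$spacing[1],
                   cy = vol$origin[2] + cent[, 2] * vol$spacing[2],
                   cz = vol$origin[3] + cent[, 3] * vol$spacing[3],
                   cx_idx = cent[, 1])
  st$side <- ifelse(st$cx > 0, "left", "right")
  list(labels = lab, stats = st)
}

# Split components into incisor (most rostral per side) and molar rows.
classify_teeth <- function(comp) {
  st <- comp$stats
  if (!nrow(st)) stop("no tooth components found")
  out <- list()
  for (side in unique(st$side)) {
    s <- st[st$side == side, ]
    inc <- s$id[which.max(s$cy)]
    mol <- s[s$id != inc, ]
    mol <- mol[order(-mol$cy), ]
    out[[side]] <- list(incisor = inc, molars = mol)
  }
  out
}

#' Occlusal surface points of the molar rows
#'
#' For every molar component (all tooth components except the most rostral
#' one of each side, i.e. the incisors), returns the centroid of its
#' dorsal-most voxels (cusp tip).
#'
#' @param vol grayscale volume.
#' @param tooth_threshold intensity separating teeth from bone.
#' @return m x 3 matrix of mm points suitable for [fit_occlusal_plane()].
#' @export
occlusal_surface_points <- function(vol,
                                    tooth_threshold = default_thresholds()$tooth) {
  comp <- tooth_components(vol, tooth_threshold)
  cls <- classify_teeth(comp)
  d <- dim(vol$data)
  pts <- list()
  for (side in names(cls)) {
    mol <- cls[[side]]$molars
    for (id in mol$id) {
      idx <- which(comp$labels == id)
      k0 <- (idx - 1L) %/% (d[1] * d[2])
      top <- idx[k0 >= max(k0) - 1L]
      i0 <- (top - 1L) %% d[1]
      j0 <- ((top - 1L) %/% d[1]) %% d[2]
      kk <- (top - 1L) %/% (d[1] * d[2])
      pts[[length(pts) + 1L]] <- vol$origin +
        c(mean(i0), mean(j0), mean(kk)) * vol$spacing
    }
  }
  if (length(pts) < 3L)
    stop("fewer than 3 molar cusp points found; cannot define the occlusal plane")
  do.call(rbind, pts)
}

## ---- 2D helpers for the sagittal slice ----------------------------------

shift2 <- function(A, dr, dc, fill = 0) {
  n <- nrow(A); m <- ncol(A)
  out <- matrix(fill, n, m)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(m, m + dc)
  out[rs, cs] <- A[rs - dr, cs - dc]
  out
}

blur3 <- function(A) {
  acc <- matrix(0, nrow(A), ncol(A))
  for (dr in -1:1) for (dc in -1:1) acc <- acc + shift2(A, dr, dc, fill = NA)
  cnt <- matrix(0, nrow(A), ncol(A))
  one <- matrix(1, nrow(A), ncol(A))
  acc[is.na(acc)] <- 0
  for (dr in -1:1) for (dc in -1:1) cnt <- cnt + shift2(one, dr, dc, fill = 0)
  # redo sum ignoring NA border contributions
  acc <- matrix(0, nrow(A), ncol(A))
  for (dr in -1:1) for (dc in -1:1) acc <- acc + shift2(A, dr, dc, fill = 0)
  acc / cnt
}

dilate8 <- function(M, r = 1L) {
  for (it in seq_len(r)) {
    acc <- M
    for (dr in -1:1) for (dc in -1:1)
      if (dr || dc) acc <- acc | shift2(M, dr, dc, fill = FALSE)
    M <- acc
  }
  M
}

nbr_count8 <- function(M) {
  acc <- matrix(0, nrow(M), ncol(M))
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) acc <- acc + shift2(M, dr, dc, fill = FALSE)
  acc
}

bilinear2 <- function(A, pts) {
  n <- nrow(A); m <- ncol(A)
  r <- pmin(pmax(pts[, 1], 1), n)
  c <- pmin(pmax(pts[, 2], 1), m)
  r0 <- pmin(floor(r), n - 1L); c0 <- pmin(floor(c), m - 1L)
  fr <- r - r0; fc <- c - c0
  A[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    A[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    A[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    A[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# Moore-neighbour boundary tracing of a single connected 2D component.
# Returns an ordered (clockwise or counter-clockwise) cycle of pixel
# coordinates (row, col), 1-based.
moore_trace <- function(M) {
  dirs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  idx <- which(M, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask: no contour")
  ord <- order(idx[, 1], idx[, 2])
  start <- idx[ord[1], ]                 # topmost, then leftmost pixel
  if (nrow(idx) == 1L) return(rbind(start))
  inside <- function(p) p[1] >= 1 && p[1] <= nrow(M) &&
    p[2] >= 1 && p[2] <= ncol(M) && M[p[1], p[2]]
  contour <- list(start)
  cur <- start
  back_dir <- 7L                         # came from the west
  first_move <- NULL
  steps <- 0L
  max_steps <- 4L * nrow(idx) + 16L
  repeat {
    found <- FALSE
    for (t in 1:8) {
      d <- ((back_dir + t - 1L) %% 8L) + 1L
      cand <- cur + dirs[d, ]
      if (inside(cand)) {
        if (is.null(first_move)) first_move <- d
        else if (all(cur == start) && d == first_move) return(do.call(rbind, contour[-length(contour)]))
        contour[[length(contour) + 1L]] <- cand
        back_dir <- ((d + 3L) %% 8L) + 1L   # direction pointing back to cur
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) return(rbind(start))      # isolated pixel
    steps <- steps + 1L
    if (steps > max_steps) stop("contour tracing failed to close")
  }
}

cyc <- function(i, n) ((i - 1L) %% n) + 1L

tls_line <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2L, ctr, `-`))
  dir <- sv$v[, 1]
  list(center = ctr, dir = dir,
       resid = abs(sweep(pts, 2L, ctr, `-`) %*% sv$v[, 2]))
}

line_circle_intersect <- function(p0, dir, center, R, near) {
  f <- p0 - center
  b <- sum(f * dir); c0 <- sum(f^2) - R^2
  disc <- b^2 - c0
  if (disc < 0) return(NULL)
  ts <- c(-b - sqrt(disc), -b + sqrt(disc))
  cand <- rbind(p0 + ts[1] * dir, p0 + ts[2] * dir)
  cand[which.min(rowSums(sweep(cand, 2L, near, `-`)^2)), ]
}

kasa_circle <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  sol <- tryCatch(qr.solve(A, x^2 + y^2), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  list(center = sol[1:2], R = sqrt(max(sol[3] + sol[1]^2 + sol[2]^2, 0)))
}

#' Construct a sagittal incisor profile
#'
#' An ordered open polyline tracing the incisor outline in its mid-sagittal
#' plane, running alveolar edge (labial) -> tip -> gnaw ridge -> alveolar
#' edge (lingual), with named landmark indices. Usually produced by
#' [extract_sagittal_profile()]; the constructor is exported so profiles
#' can be built from manual landmarks or analytic curves.
#'
#' @param points n x 2 matrix of (y, z) mm coordinates, n >= 2.
#' @param landmarks named list/vector of indices into `points`:
#'   `alveolus_edge`, `tip`, and optionally `gnaw_ridge`,
#'   `alveolus_edge_lingual`. Must be ordered
#'   `alveolus_edge <= tip <= gnaw_ridge <= alveolus_edge_lingual`.
#' @param side `"left"` or `"right"`.
#' @param spacing in-plane voxel spacing (mm), for tolerance bookkeeping.
#' @param slice_x_mm physical x position of the slice.
#' @export
sagittal_profile <- function(points, landmarks, side = "left",
                             spacing = NA_real_, slice_x_mm = NA_real_) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("profile needs at least 2 points")
  lm <- as.list(landmarks)
  for (need in c("alveolus_edge", "tip"))
    if (is.null(lm[[need]])) stop("profile landmarks must include `", need, "`")
  ord <- unlist(lm[c("alveolus_edge", "tip", "gnaw_ridge",
                     "alveolus_edge_lingual")])
  ord <- ord[!is.na(ord)]
  if (any(ord < 1 | ord > nrow(points)))
    stop("landmark indices out of range")
  if (is.unsorted(ord))
    stop("landmarks must be ordered alveolus_edge <= tip <= gnaw_ridge ",
         "<= alveolus_edge_lingual along the profile")
  structure(list(points = points, landmarks = lm, side = side,
                 spacing = spacing, slice_x_mm = slice_x_mm),
            class = "sagittal_profile")
}

#' @export
print.sagittal_profile <- function(x, ...) {
  cat(sprintf("<sagittal_profile> side %s, %d points\n", x$side, nrow(x$points)))
  cat("  landmarks:", paste(names(x$landmarks), unlist(x$landmarks),
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Extract the mid-sagittal profile of one incisor
#'
#' Locates the side's incisor as the most rostral tooth component, takes
#' the sagittal slice through its centroid, traces the outline with
#' sub-voxel refinement of the threshold crossing, and places the
#' landmarks (see the module header for the operator definitions).
#'
#' @param vol grayscale volume in the occlusal-plane frame.
#' @param side `"left"` or `"right"`.
#' @param bone_threshold,tooth_threshold segmentation thresholds
#'   (phantom defaults 500 / 1200 a.u.).
#' @param smooth_window odd moving-average window (contour points) applied
#'   after sub-voxel refinement; default 3.
#' @return a [sagittal_profile()].
#' @export
extract_sagittal_profile <- function(vol, side = c("left", "right"),
                                     bone_threshold = default_thresholds()$bone,
                                     tooth_threshold = default_thresholds()$tooth,
                                     smooth_window = 3L) {
  stopifnot_volume(vol)
  side <- match.arg(side)
  comp <- tooth_components(vol, tooth_threshold)
  if (!nrow(comp$stats) || !side %in% comp$stats$side)
    stop("incisor component not found on side `", side, "`")
  cls <- classify_teeth(comp)
  inc_id <- cls[[side]]$incisor
  st <- comp$stats[comp$stats$id == inc_id, ]
  xi <- as.integer(round(st$cx_idx)) + 1L
  d <- dim(vol$data)
  slice_has <- function(i) i >= 1L && i <= d[1] && any(comp$labels[i, , ] == inc_id)
  if (!slice_has(xi)) {
    cand <- xi + c(-1L, 1L, -2L, 2L)
    xi <- c(cand[vapply(cand, slice_has, logical(1))], NA)[1]
    if (is.na(xi)) stop("incisor component not found on side `", side, "`")
  }
  G <- vol$data[xi, , ]
  M <- comp$labels[xi, , ] == inc_id
  px <- moore_trace(M)
  sp <- vol$spacing[2:3]
  vox <- max(sp)
  # sub-voxel refinement: move each contour pixel along the local gradient
  # to the tooth-threshold crossing of the (lightly blurred) gray slice
  Gs <- blur3(G)
  gy <- (shift2(Gs, 1, 0, NA) - shift2(Gs, -1, 0, NA)) / 2
  gz <- (shift2(Gs, 0, 1, NA) - shift2(Gs, 0, -1, NA)) / 2
  refine_one <- function(p) {
    g <- c(gy[p[1], p[2]], gz[p[1], p[2]])
    if (anyNA(g) || sum(g^2) < 1e-12) return(p)
    nrm <- g / sqrt(sum(g^2))
    ss <- seq(-1.2, 1.2, by = 0.3)
    # gradient direction from the blurred slice; crossing from the raw one
    # (blurring widens the edge ramp and would bias the crossing inward).
    # The level is the local half-maximum between the two phases, so both
    # tooth-air and tooth-bone interfaces land on the true surface.
    ray <- cbind(p[1] + ss * nrm[1], p[2] + ss * nrm[2])
    vals <- bilinear2(G, ray)
    level <- (max(vals) + min(vals)) / 2
    samp <- vals - level
    sgn <- sign(samp)
    cross <- which(sgn[-1] * sgn[-length(sgn)] <= 0 & sgn[-1] != sgn[-length(sgn)])
    if (!length(cross)) return(p)
    j <- cross[which.min(abs(ss[cross] + 0.15))]
    s0 <- ss[j] - samp[j] * (ss[j + 1] - ss[j]) / (samp[j + 1] - samp[j])
    if (!is.finite(s0) || abs(s0) > 1) return(p)
    p + s0 * nrm
  }
  ref <- t(apply(px, 1L, refine_one))
  # to physical (y, z) mm
  P <- cbind(vol$origin[2] + (ref[, 1] - 1) * sp[1],
             vol$origin[3] + (ref[, 2] - 1) * sp[2])
  if (smooth_window > 1L && nrow(P) > smooth_window) {
    w <- smooth_window
    ker <- rep(1 / w, w)
    smooth_circ <- function(v) {
      ext <- c(utils::tail(v, w), v, utils::head(v, w))
      stats::filter(ext, ker, sides = 2)[(w + 1):(w + length(v))]
    }
    P <- cbind(smooth_circ(P[, 1]), smooth_circ(P[, 2]))
  }
  n <- nrow(P)
  if (n < 8L) stop("incisor contour too small to measure on side `", side, "`")
  # landmark: tip = most dorsal contour point (ties: most rostral)
  i_tip <- which.max(P[, 2] + 1e-9 * P[, 1])
  # choose the labial direction: larger mean radius about the global circle fit
  circ <- kasa_circle(P)
  if (is.null(circ)) stop("degenerate incisor contour on side `", side, "`")
  probe <- 4:min(24, floor(n / 3))
  rad <- function(pts) sqrt(rowSums(sweep(pts, 2L, circ$center, `-`)^2))
  r_fwd <- mean(rad(P[cyc(i_tip + probe, n), , drop = FALSE]))
  r_bwd <- mean(rad(P[cyc(i_tip - probe, n), , drop = FALSE]))
  lab_step <- if (r_fwd >= r_bwd) 1L else -1L
  half <- floor(n / 2)
  walkL <- P[cyc(i_tip + lab_step * (0:half), n), , drop = FALSE]  # labial walk
  walkF <- P[cyc(i_tip - lab_step * (0:half), n), , drop = FALSE]  # facet/lingual walk
  # alveolar margins as air/bone/tooth triple junctions: air pixels near
  # both solid (non-surface, non-tooth) bone and the incisor. Partial-volume
  # surface voxels around the free crown sit in the bone intensity band (and
  # resampled volumes smear that shell to ~2 px), so "solid bone" is the
  # bone mask eroded twice against air; the dilation radius matches so the
  # junction still reaches the air beside the true bone surface.
  solid <- G >= bone_threshold
  B2 <- solid
  for (it in 1:2) {
    er <- B2
    for (dr in c(-1L, 1L)) er <- er & shift2(B2, dr, 0L, FALSE)
    for (dc in c(-1L, 1L)) er <- er & shift2(B2, 0L, dc, FALSE)
    B2 <- er
  }
  B2 <- B2 & G < tooth_threshold
  junction <- (G < bone_threshold) & dilate8(B2, 3L) & dilate8(M, 2L)
  tb <- which(junction, arr.ind = TRUE)
  if (!nrow(tb))
    stop("no alveolar margin (air/bone/tooth junction) found on side `",
         side, "`")
  tb_mm <- cbind(vol$origin[2] + (tb[, 1] - 1) * sp[1],
                 vol$origin[3] + (tb[, 2] - 1) * sp[2])
  # nearest walk index (labial and facet/lingual) for every junction px
  nearest_idx <- function(walk, pts) {
    vapply(seq_len(nrow(pts)), function(i)
      which.min(colSums((t(walk) - pts[i, ])^2)), integer(1))
  }
  dist_to_walk <- function(walk, pts, idx)
    sqrt(rowSums((walk[idx, , drop = FALSE] - pts)^2))
  iL <- nearest_idx(walkL, tb_mm); dL <- dist_to_walk(walkL, tb_mm, iL)
  iF <- nearest_idx(walkF, tb_mm); dF <- dist_to_walk(walkF, tb_mm, iF)
  on_labial <- dL <= dF
  if (!any(on_labial) || !any(!on_labial))
    stop("could not locate both alveolar edges on side `", side, "`")
  crestL <- which(on_labial)[which.max(tb_mm[on_labial, 2])]
  crestF <- which(!on_labial)[which.max(tb_mm[!on_labial, 2])]
  alvL_walk <- iL[crestL]                 # index into walkL
  alvF_walk <- iF[crestF]                 # index into walkF
  # gnaw ridge: split the tip -> lingual-edge walk into a straight facet
  # followed by the lingual arc; the split index minimizing the combined
  # line + circle residual is the ridge (scale-free corner detector)
  ridge_walk <- NA_integer_
  if (alvF_walk >= 12L) {
    ks <- seq(5L, alvF_walk - 6L,
              by = max(1L, (alvF_walk - 10L) %/% 60L))
    rss <- vapply(ks, function(k) {
      lin <- tls_line(walkF[2:k, , drop = FALSE])
      arc_pts <- walkF[(k + 1L):alvF_walk, , drop = FALSE]
      circ2 <- kasa_circle(arc_pts)
      if (is.null(circ2) || !is.finite(circ2$R)) return(Inf)
      rr <- sqrt(rowSums(sweep(arc_pts, 2L, circ2$center, `-`)^2)) - circ2$R
      sum(lin$resid^2) + sum(rr^2)
    }, numeric(1))
    if (any(is.finite(rss))) ridge_walk <- ks[which.min(rss)]
  }
  have_ridge <- !is.na(ridge_walk) && ridge_walk >= 4L &&
    ridge_walk < alvF_walk
  # refine tip and ridge to facet-line / arc intersections
  tipP <- walkL[1, ]; ridgeP <- if (have_ridge) walkF[ridge_walk, ] else NULL
  if (have_ridge && ridge_walk >= 9L) {
    fit <- tls_line(walkF[3:max(ridge_walk - 3L, 6L), , drop = FALSE])
    labfit_rng <- 4:min(alvL_walk, 80L)
    cl <- if (length(labfit_rng) >= 8L)
      kasa_circle(walkL[labfit_rng, , drop = FALSE]) else NULL
    if (!is.null(cl)) {
      tp <- line_circle_intersect(fit$center, fit$dir, cl$center, cl$R, tipP)
      if (!is.null(tp) && sum((tp - tipP)^2) < (6 * vox)^2) tipP <- tp
    }
    linfit_rng <- (ridge_walk + 4L):min(alvF_walk, ridge_walk + 80L)
    cn <- if (length(linfit_rng) >= 8L)
      kasa_circle(walkF[linfit_rng, , drop = FALSE]) else NULL
    if (!is.null(cn)) {
      rp <- line_circle_intersect(fit$center, fit$dir, cn$center, cn$R, ridgeP)
      if (!is.null(rp) && sum((rp - ridgeP)^2) < (6 * vox)^2) ridgeP <- rp
    }
  }
  # assemble the open profile: labial alveolar edge -> tip -> ridge -> lingual edge
  labial_seg <- walkL[alvL_walk:1, , drop = FALSE]
  labial_seg[nrow(labial_seg), ] <- tipP
  pts_out <- labial_seg
  lm <- list(alveolus_edge = 1L, tip = nrow(labial_seg))
  if (have_ridge) {
    facet_seg <- walkF[2:ridge_walk, , drop = FALSE]
    facet_seg[nrow(facet_seg), ] <- ridgeP
    lingual_seg <- walkF[(ridge_walk + 1L):alvF_walk, , drop = FALSE]
    pts_out <- rbind(pts_out, facet_seg, lingual_seg)
    lm$gnaw_ridge <- nrow(labial_seg) + nrow(facet_seg)
    lm$alveolus_edge_lingual <- nrow(pts_out)
  }
  sagittal_profile(pts_out, lm, side = side, spacing = vox,
                   slice_x_mm = vol$origin[1] + (xi - 1) * vol$spacing[1])
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Path length along a named incisor surface
#'
#' Polyline arc length between two landmarks of a [sagittal_profile()]:
#' labial (alveolar edge to tip), occlusal (gnaw ridge to tip), lingual
#' (gnaw ridge to lingual alveolar edge).
#'
#' @param profile a [sagittal_profile()].
#' @param surface `"labial"`, `"occlusal"` or `"lingual"`.
#' @param from_landmark,to_landmark optional explicit landmark names
#'   overriding the surface defaults.
#' @return length in mm.
#' @export
path_length <- function(profile, surface = c("labial", "occlusal", "lingual"),
                        from_landmark = NULL, to_landmark = NULL) {
  if (!inherits(profile, "sagittal_profile")) stop("need a sagittal_profile()")
  surface <- match.arg(surface)
  defaults <- switch(surface,
    labial = c("alveolus_edge", "tip"),
    occlusal = c("gnaw_ridge", "tip"),
    lingual = c("gnaw_ridge", "alveolus_edge_lingual"))
  from_landmark <- from_landmark %||% defaults[1]
  to_landmark <- to_landmark %||% defaults[2]
  lm <- profile$landmarks
  for (nm in c(from_landmark, to_landmark))
    if (is.null(lm[[nm]]))
      stop("profile has no `", nm, "` landmark (gnaw ridge not identified?)")
  i <- sort(c(lm[[from_landmark]], lm[[to_landmark]]))
  polyline_length(profile$points[i[1]:i[2], , drop = FALSE])
}

#' Occlusal inclination angle of the erupted incisor crown
#'
#' Signed angle between the total-least-squares line through the occlusal
#' facet points (tip to gnaw ridge) and the horizontal plane; positive when
#' the tip is dorsal to the ridge. Mirroring left/right preserves the sign.
#'
#' @param profile a [sagittal_profile()] with a gnaw-ridge landmark.
#' @return angle in degrees, in (-90, 90].
#' @export
occlusal_angle <- function(profile) {
  if (!inherits(profile, "sagittal_profile")) stop("need a sagittal_profile()")
  lm <- profile$landmarks
  if (is.null(lm$gnaw_ridge))
    stop("profile has no gnaw-ridge landmark: occlusal facet unavailable")
  i <- sort(c(lm$tip, lm$gnaw_ridge))
  pts <- profile$points[i[1]:i[2], , drop = FALSE]
  if (nrow(pts) < 3L) stop("occlusal facet has fewer than 3 points")
  if (nrow(pts) >= 10L) {      # trim corner-rounded ends (10% each)
    k <- max(1L, floor(nrow(pts) * 0.1))
    pts <- pts[(1L + k):(nrow(pts) - k), , drop = FALSE]
  }
  fit <- tls_line(pts)
  dir <- fit$dir
  tipv <- profile$points[lm$tip, ] - profile$points[lm$gnaw_ridge, ]
  if (sum(dir * tipv) < 0) dir <- -dir
  asin(max(-1, min(1, dir[2]))) * 180 / pi
}

#' Cheek-tooth height from the alveolar edge to the highest buccal cusp
#'
#' @param vol grayscale volume in the occlusal-plane frame.
#' @param tooth_label which cheek tooth: an ordinal integer (1 = most
#'   rostral) or a label like `"#2"` (`"#2"` is the most rostral cheek
#'   tooth unless `labels` says otherwise).
#' @param side `"left"` or `"right"`.
#' @param labels optional character vector naming the molar row from
#'   rostral to caudal.
#' @param bone_threshold,tooth_threshold segmentation thresholds.
#' @return list (class `cheek_tooth_height`) with `tooth_label`, `side`,
#'   `height_mm`, `cusp_z_mm`, `alveolus_z_mm`.
#' @export
cheek_tooth_height <- function(vol, tooth_label, side = c("left", "right"),
                               labels = NULL,
                               bone_threshold = default_thresholds()$bone,
                               tooth_threshold = default_thresholds()$tooth) {
  stopifnot_volume(vol)
  side <- match.arg(side)
  comp <- tooth_components(vol, tooth_threshold)
  if (!nrow(comp$stats) || !side %in% comp$stats$side)
    stop("no tooth components on side `", side, "`")
  cls <- classify_teeth(comp)
  mol <- cls[[side]]$molars
  if (!nrow(mol)) stop("no cheek teeth found on side `", side, "`")
  if (is.null(labels)) labels <- paste0("#", seq_len(nrow(mol)) + 1L)
  ordinal <- if (is.numeric(tooth_label)) as.integer(tooth_label)
             else match(as.character(tooth_label), labels)
  if (is.na(ordinal) || ordinal < 1L || ordinal > nrow(mol))
    stop("cheek tooth `", tooth_label, "` not found on side `", side, "`")
  id <- mol$id[ordinal]
  d <- dim(vol$data)
  idx <- which(comp$labels == id)
  i0 <- (idx - 1L) %% d[1]
  j0 <- ((idx - 1L) %/% d[1]) %% d[2]
  k0 <- (idx - 1L) %/% (d[1] * d[2])
  x_mm <- vol$origin[1] + i0 * vol$spacing[1]
  cx <- mean(x_mm)
  buccal <- abs(x_mm) >= abs(cx)           # lateral half of the crown
  cusp_k <- max(k0[buccal])
  cusp_z <- vol$origin[3] + cusp_k * vol$spacing[3]
  # alveolar edge: top of the (de-shelled) bone within the expanded
  # xy-footprint of the tooth
  bone <- vol$data >= bone_threshold
  interior <- bone
  for (ax in 1:3) for (dr in c(-1L, 1L)) {
    perm <- bone
    if (ax == 1L) {
      if (dr > 0) perm[1:(d[1] - 1), , ] <- bone[2:d[1], , ] else perm[2:d[1], , ] <- bone[1:(d[1] - 1), , ]
    } else if (ax == 2L) {
      if (dr > 0) perm[, 1:(d[2] - 1), ] <- bone[, 2:d[2], ] else perm[, 2:d[2], ] <- bone[, 1:(d[2] - 1), ]
    } else {
      if (dr > 0) perm[, , 1:(d[3] - 1)] <- bone[, , 2:d[3]] else perm[, , 2:d[3]] <- bone[, , 1:(d[3] - 1)]
    }
    interior <- interior & perm
  }
  solid_bone <- interior & !(vol$data >= tooth_threshold)
  pad <- 3L
  ir <- range(i0); jr <- range(j0)
  sel_i <- max(1L, ir[1] + 1L - pad):min(d[1], ir[2] + 1L + pad)
  sel_j <- max(1L, jr[1] + 1L - pad):min(d[2], jr[2] + 1L + pad)
  sub <- solid_bone[sel_i, sel_j, , drop = FALSE]
  if (!any(sub)) stop("no alveolar bone near cheek tooth `", tooth_label, "`")
  kz <- which(apply(sub, 3L, any))
  alv_z <- vol$origin[3] + (max(kz) - 1L) * vol$spacing[3]
  structure(list(tooth_label = if (is.numeric(tooth_label))
                   labels[ordinal] else as.character(tooth_label),
                 side = side, height_mm = cusp_z - alv_z,
                 cusp_z_mm = cusp_z, alveolus_z_mm = alv_z),
            class = "cheek_tooth_height")
}

#' Measure incisor metrics of one or both sides
#'
#' Convenience wrapper: extracts the sagittal profile per side and returns
#' the labial/lingual/occlusal path lengths and the occlusal angle as a
#' long metrics table.
#'
#' @param vol grayscale volume in the occlusal-plane frame.
#' @param sides character vector of sides (default both).
#' @param ... passed to [extract_sagittal_profile()].
#' @return data.frame with columns `side`, `metric`, `value`, `units`.
#' @export
measure_incisors <- function(vol, sides = c("left", "right"), ...) {
  rows <- list()
  for (side in sides) {
    pr <- extract_sagittal_profile(vol, side, ...)
    vals <- c(labial = path_length(pr, "labial"),
              lingual = if (!is.null(pr$landmarks$gnaw_ridge))
                path_length(pr, "lingual") else NA_real_,
              occlusal = if (!is.null(pr$landmarks$gnaw_ridge))
                path_length(pr, "occlusal") else NA_real_,
              occlusal_angle = if (!is.null(pr$landmarks$gnaw_ridge))
                occlusal_angle(pr) else NA_real_)
    rows[[side]] <- data.frame(side = side, metric = names(vals),
                               value = as.numeric(vals),
                               units = c("mm", "mm", "mm", "deg"),
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
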