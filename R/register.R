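# Rigid co-registration by mutual-information maximization.
#
# The similarity uses every overlapping voxel (no landmarks): the moving
# volume is sampled on the fixed grid under the candidate transform, the two
# intensity samples are binned into a joint histogram with min-max
# normalization, and MI in bits is maximized over the 6 rigid parameters
# with a Nelder-Mead simplex. Bin count, interpolation and convergence rule
# are configuration, not inferences about any particular scanner software.

#' Joint intensity histogram of two volumes under a rigid transform
#'
#' Samples are the fixed-grid voxels (optionally strided) whose position,
#' mapped through `t^-1`, falls inside the moving volume; moving intensities
#' are interpolated there. Both intensity axes are binned linearly between
#' each volume's global min and max.
#'
#' @param fixed,moving [volume()] objects.
#' @param t a [rigid_transform()] mapping moving to fixed coordinates.
#' @param bins number of bins per axis (>= 2).
#' @param stride integer voxel stride on the fixed grid (1 = all voxels).
#' @param interpolation `"linear"` or `"nearest"` sampling of the moving
#'   volume.
#' @param out_of_field `"drop"` (default): only fixed voxels mapping inside
#'   the moving volume contribute; `"background"`: out-of-field samples are
#'   binned at the moving background (lowest) intensity, keeping the sample
#'   count constant. The optimizer uses `"background"`: with `"drop"` the MI
#'   maximum is biased away from the true pose because shifting background
#'   voxels out of the overlap raises the entropy of what remains.
#' @return a `joint_histogram` object: `counts` (bins x bins matrix, fixed
#'   along rows), `bins`, `fixed_range`, `moving_range`, `n` (sum of counts).
#' @export
joint_histogram <- function(fixed, moving, t = rigid_transform(), bins = 64L,
                            stride = 1L,
                            interpolation = c("linear", "nearest"),
                            out_of_field = c("drop", "background")) {
  stopifnot_volume(fixed); stopifnot_volume(moving)
  interpolation <- match.arg(interpolation)
  out_of_field <- match.arg(out_of_field)
  bins <- as.integer(bins)
  if (bins < 2L) stop("`bins` must be >= 2")
  fr <- range(fixed$data); mr <- range(moving$data)
  samp <- fixed_grid_samples(fixed, stride)
  joint_histogram_impl(samp, fixed_range = fr, moving = moving,
                       moving_range = mr, t = t, bins = bins,
                       interpolation = interpolation,
                       out_of_field = out_of_field)
}

# Precompute the strided fixed-grid sample set (physical coords + values).
# With content_box = TRUE, samples are restricted to the bounding box of
# above-background fixed voxels (padded by 2 voxels): the MI of the bare
# overlap is not pose-invariant at the margins (dropping background voxels
# from the overlap inflates the entropy of what remains), and sampling a
# content-tight box keeps the sample set constant near the optimum.
fixed_grid_samples <- function(fixed, stride = 1L, content_box = FALSE) {
  d <- dim(fixed$data)
  lo <- c(1L, 1L, 1L); hi <- d
  if (content_box) {
    thr <- min(fixed$data) + 0.01 * diff(range(fixed$data))
    idx <- which(fixed$data > thr, arr.ind = TRUE)
    if (nrow(idx)) {
      lo <- pmax(apply(idx, 2L, min) - 2L, 1L)
      hi <- pmin(apply(idx, 2L, max) + 2L, d)
    }
  }
  ii <- seq(lo[1], hi[1], by = stride); jj <- seq(lo[2], hi[2], by = stride)
  kk <- seq(lo[3], hi[3], by = stride)
  vals <- fixed$data[ii, jj, kk, drop = FALSE]
  px <- fixed$origin[1] + (ii - 1L) * fixed$spacing[1]
  py <- fixed$origin[2] + (jj - 1L) * fixed$spacing[2]
  pz <- fixed$origin[3] + (kk - 1L) * fixed$spacing[3]
  n1 <- length(ii); n2 <- length(jj); n3 <- length(kk)
  pts <- cbind(rep(px, times = n2 * n3),
               rep(rep(py, each = n1), times = n3),
               rep(pz, each = n1 * n2))
  list(points = pts, values = as.vector(vals))
}

joint_histogram_impl <- function(samp, fixed_range, moving, moving_range,
                                 t, bins, interpolation,
                                 out_of_field = "drop") {
  inv <- transform_offset(invert_transform(t))
  src <- sweep(samp$points %*% t(inv$R), 2L, inv$o, `+`)
  src_idx <- sweep(sweep(src, 2L, moving$origin, `-`), 2L, moving$spacing, `/`)
  mv <- if (interpolation == "linear")
    cpp_trilinear_sample(moving$data, dim(moving$data), src_idx, NA_real_)
  else
    cpp_nearest_sample(moving$data, dim(moving$data), src_idx, NA_real_)
  inside <- !is.na(mv)
  if (!any(inside))
    stop("empty overlap between fixed and moving volume under the candidate ",
         "transform: outside the registration capture range")
  if (out_of_field == "background") {
    mv[!inside] <- moving_range[1]
    keep <- rep(TRUE, length(mv))
  } else {
    keep <- inside
  }
  fb <- intensity_bin(samp$values[keep], fixed_range, bins)
  mb <- intensity_bin(mv[keep], moving_range, bins)
  counts <- matrix(tabulate((mb - 1L) * bins + fb, nbins = bins * bins),
                   nrow = bins)
  structure(list(counts = counts, bins = bins, fixed_range = fixed_range,
                 moving_range = moving_range, n = sum(counts)),
            class = "joint_histogram")
}

intensity_bin <- function(v, rng, bins) {
  w <- rng[2] - rng[1]
  if (w <= 0) return(rep(1L, length(v)))
  b <- floor((v - rng[1]) / w * bins) + 1L
  pmin(pmax(as.integer(b), 1L), bins)
}

#' Mutual information of a joint histogram, in bits
#'
#' `MI = sum p(i,j) log2( p(i,j) / (p(i) p(j)) )`, with zero cells
#' contributing zero.
#'
#' @param h a [joint_histogram()] (or a plain count matrix).
#' @return MI in bits.
#' @export
mutual_information <- function(h) {
  counts <- if (inherits(h, "joint_histogram")) h$counts else as.matrix(h)
  n <- sum(counts)
  if (n <= 0) stop("joint histogram has no counts")
  p <- counts / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

# Overlap-invariant normalized mutual information (Studholme 1999):
# (H(fixed) + H(moving)) / H(joint). Used as the optimization similarity
# because plain MI over the voxel overlap is not pose-invariant at the
# volume margins (dropping background samples inflates it), which biases
# the maximum away from the true pose.
normalized_mi <- function(h) {
  counts <- if (inherits(h, "joint_histogram")) h$counts else as.matrix(h)
  p <- counts / sum(counts)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hj <- ent(as.vector(p))
  if (hj == 0) return(1)
  (ent(rowSums(p)) + ent(colSums(p))) / hj
}

marginal_entropy <- function(h, margin = 1L) {
  p <- if (margin == 1L) rowSums(h$counts) else colSums(h$counts)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Rigid registration by mutual-information maximization
#'
#' Nelder-Mead simplex maximization of the mutual-information similarity
#' over the six rigid parameters (three rotation angles in degrees, three
#' translations in mm) about the fixed-volume centroid. The optimized
#' similarity is the overlap-invariant normalized MI
#' `(H(fixed)+H(moving))/H(joint)`; the reported `mi` is
#' [mutual_information()] in bits at the returned transform. Deterministic
#' given `init` and `opts`; optional multi-start adds seeded jittered
#' starts (within +-5 deg / +-2.5 mm) and keeps the best final similarity,
#' ties broken by smaller parameter norm.
#'
#' @param fixed,moving [volume()] objects (must be non-constant).
#' @param init initial [rigid_transform()] (default identity about the fixed
#'   centroid). Its centre is replaced by the fixed-volume centroid so that
#'   transform files are unambiguous.
#' @param opts list of options: `bins` (64), `stride` (1), `interpolation`
#'   ("linear"), `max_iter` (500), `tol` simplex size in normalized units
#'   (1e-3; 1 unit = 1 degree = 1 mm), `step` initial simplex step
#'   (c(rep(2,3), rep(1,3))), `starts` extra jittered starts (0), `seed`.
#' @return list with `transform`, `mi` (bits, at the returned transform),
#'   `nmi` (the optimized similarity), `trace` (data.frame of iteration and
#'   best-vertex normalized MI), `converged`, `n_eval`.
#' @export
register_rigid <- function(fixed, moving, init = NULL, opts = list()) {
  stopifnot_volume(fixed); stopifnot_volume(moving)
  if (diff(range(fixed$data)) == 0 || diff(range(moving$data)) == 0)
    stop("registration requires non-constant fixed and moving volumes")
  o <- utils::modifyList(list(bins = 64L, stride = 1L, interpolation = "linear",
                              max_iter = 500L, tol = 1e-3,
                              step = c(2, 2, 2, 1, 1, 1),
                              restarts = 4L, restart_tol = 1e-4,
                              starts = 0L, seed = 1L), opts)
  center <- fixed$origin + (dim(fixed$data) - 1) / 2 * fixed$spacing
  if (is.null(init)) init <- rigid_transform(center_mm = center)
  x0 <- c(init$angles_deg, init$translation_mm)
  samp <- fixed_grid_samples(fixed, o$stride, content_box = TRUE)
  fr <- range(fixed$data); mr <- range(moving$data)
  objective <- function(x) {
    t <- rigid_transform(x[1:3], x[4:6], center)
    h <- tryCatch(
      joint_histogram_impl(samp, fr, moving, mr, t, o$bins, o$interpolation),
      error = function(e) NULL)
    if (is.null(h)) return(Inf)     # empty overlap: reject vertex
    -normalized_mi(h)
  }
  starts <- list(x0)
  if (o$starts > 0L) {
    rng <- local({set.seed(o$seed)
      lapply(seq_len(o$starts), function(i)
        x0 + c(stats::runif(3, -5, 5), stats::runif(3, -2.5, 2.5)))})
    starts <- c(starts, rng)
  }
  run_one <- function(x) {
    # simplex restarts: re-span a fresh simplex at the incumbent optimum
    # until the MI gain drops below restart_tol (simplex minimization is
    # local and a collapsed simplex can stall short of the peak)
    fit <- nelder_mead(objective, x, step = o$step, tol = o$tol,
                       max_iter = o$max_iter)
    for (r in seq_len(max(o$restarts - 1L, 0L))) {
      nxt <- nelder_mead(objective, fit$par, step = o$step / 2, tol = o$tol,
                         max_iter = o$max_iter)
      nxt$trace <- c(fit$trace, nxt$trace)
      nxt$n_eval <- fit$n_eval + nxt$n_eval
      improved <- fit$value - nxt$value
      fit <- nxt
      if (improved < o$restart_tol) break
    }
    fit
  }
  best <- NULL
  for (s in starts) {
    fit <- run_one(s)
    if (is.null(best) || fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 &&
         sum(fit$par^2) < sum(best$par^2)))
      best <- fit
  }
  t_best <- rigid_transform(best$par[1:3], best$par[4:6], center)
  trace <- data.frame(iteration = seq_along(best$trace),
                      best_nmi = -best$trace)
  mi_final <- mutual_information(
    joint_histogram_impl(samp, fr, moving, mr, t_best, o$bins,
                         o$interpolation))
  list(transform = t_best, mi = mi_final, nmi = -best$value, trace = trace,
       converged = best$converged, n_eval = best$n_eval)
}

# Plain Nelder-Mead minimizer with per-iteration best-vertex trace.
# Convergence: simplex size (max vertex distance from the best vertex,
# infinity norm in normalized parameter units) below `tol`.
nelder_mead <- function(fn, x0, step, tol = 1e-3, max_iter = 500L) {
  n <- length(x0)
  simplex <- matrix(rep(x0, n + 1L), nrow = n + 1L, byrow = TRUE)
  for (i in seq_len(n)) simplex[i + 1L, i] <- simplex[i + 1L, i] + step[i]
  fv <- apply(simplex, 1L, fn)
  n_eval <- n + 1L
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ord <- order(fv)
    simplex <- simplex[ord, , drop = FALSE]; fv <- fv[ord]
    trace <- c(trace, fv[1])
    size <- max(abs(sweep(simplex[-1, , drop = FALSE], 2L, simplex[1, ], `-`)))
    if (size < tol) { converged <- TRUE; break }
    centroid <- colMeans(simplex[seq_len(n), , drop = FALSE])
    xr <- centroid + (centroid - simplex[n + 1L, ])
    fr <- fn(xr); n_eval <- n_eval + 1L
    if (fr < fv[1]) {
      xe <- centroid + 2 * (centroid - simplex[n + 1L, ])
      fe <- fn(xe); n_eval <- n_eval + 1L
      if (fe < fr) { simplex[n + 1L, ] <- xe; fv[n + 1L] <- fe }
      else { simplex[n + 1L, ] <- xr; fv[n + 1L] <- fr }
    } else if (fr < fv[n]) {
      simplex[n + 1L, ] <- xr; fv[n + 1L] <- fr
    } else {
      xc <- centroid + 0.5 * (simplex[n + 1L, ] - centroid)
      fc <- fn(xc); n_eval <- n_eval + 1L
      if (fc < fv[n + 1L]) { simplex[n + 1L, ] <- xc; fv[n + 1L] <- fc }
      else {
        for (i in 2:(n + 1L)) {
          simplex[i, ] <- simplex[1, ] + 0.5 * (simplex[i, ] - simplex[1, ])
          fv[i] <- fn(simplex[i, ])
        }
        n_eval <- n_eval + n
      }
    }
  }
  ord <- order(fv)
  list(par = simplex[ord[1], ], value = fv[ord[1]], trace = trace,
       converged = converged, n_eval = n_eval)
}
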