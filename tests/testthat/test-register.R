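test_that("joint histogram matches hand enumeration on toy volumes", {
  # binary half/half image against itself: diagonal counts, equal halves
  a <- array(rep(c(0, 1), each = 8), c(4, 4, 1))
  v <- volume(a, 1)
  h <- joint_histogram(v, v, rigid_transform(), bins = 2)
  expect_equal(h$counts, diag(c(8, 8)))
  expect_equal(h$n, 16)

  # whole-voxel shift of a constant image: a single nonzero cell
  cv <- volume(array(7, c(4, 4, 2)), 1)
  hs <- joint_histogram(cv, cv, rigid_transform(translation_mm = c(1, 0, 0)),
                        bins = 4)
  expect_equal(sum(hs$counts > 0), 1)

  # 4x4x1 toy pair: exhaustive voxel-pair oracle
  set.seed(6)
  fa <- array(runif(16, 0, 10), c(4, 4, 1))
  ma <- array(runif(16, 0, 10), c(4, 4, 1))
  vf <- volume(fa, 1); vm <- volume(ma, 1)
  bins <- 3
  h2 <- joint_histogram(vf, vm, rigid_transform(), bins = bins)
  bin_of <- function(x, rng) min(max(floor((x - rng[1]) / diff(rng) * bins) + 1, 1), bins)
  oracle <- matrix(0, bins, bins)
  for (i in seq_len(16)) {
    fb <- bin_of(as.vector(fa)[i], range(fa))
    mb <- bin_of(as.vector(ma)[i], range(ma))
    oracle[fb, mb] <- oracle[fb, mb] + 1
  }
  expect_equal(h2$counts, oracle)
})

test_that("joint histogram errors on empty overlap", {
  v <- volume(array(1:8, c(2, 2, 2)), 1)
  far <- rigid_transform(translation_mm = c(100, 0, 0))
  expect_error(joint_histogram(v, v, far), "overlap|capture")
})

test_that("mutual information equals the direct formula", {
  # independent marginals: exactly zero bits
  p <- outer(c(4, 6), c(3, 7))
  expect_equal(mutual_information(p), 0, tolerance = 1e-12)

  # identical binary image with itself at p = (0.5, 0.5): MI = H = 1 bit
  expect_equal(mutual_information(diag(c(8, 8))), 1, tolerance = 1e-12)

  # counts [[2,1],[1,4]]: direct formula evaluation, term by term
  cm <- matrix(c(2, 1, 1, 4), 2, 2, byrow = TRUE)
  n <- sum(cm); pj <- cm / n
  px <- rowSums(pj); py <- colSums(pj)
  direct <- 0
  for (i in 1:2) for (j in 1:2)
    direct <- direct + pj[i, j] * log2(pj[i, j] / (px[i] * py[j]))
  expect_equal(mutual_information(cm), direct, tolerance = 1e-12)
})

test_that("MI is symmetric and bounded by the marginal entropies", {
  set.seed(7)
  for (i in 1:20) {
    cm <- matrix(rpois(16, 5), 4, 4)
    if (sum(cm) == 0) next
    mi <- mutual_information(cm)
    expect_equal(mi, mutual_information(t(cm)), tolerance = 1e-12)
    ent <- function(p) { p <- p[p > 0] / sum(p); -sum(p * log2(p)) }
    expect_gte(mi, -1e-12)
    expect_lte(mi, min(ent(rowSums(cm)), ent(colSums(cm))) + 1e-12)
  }
})

test_that("registering a volume to itself returns the identity", {
  ph <- rat_left_030()
  v <- ph$volume
  res <- register_rigid(v, v, opts = list(stride = 3, restarts = 2))
  expect_lt(max(abs(res$transform$angles_deg)), 0.1)
  expect_lt(max(abs(res$transform$translation_mm)), 0.1 * v$spacing[1])
  expect_true(res$converged)
})

test_that("simplex trace is monotone and non-convergence is flagged", {
  ph <- rat_left_030()
  v <- ph$volume
  moving <- apply_transform(
    v, rigid_transform(c(0, 0, 2), c(0.5, 0, 0),
                       v$origin + (dim(v$data) - 1) / 2 * v$spacing), v)
  res <- register_rigid(v, moving, opts = list(stride = 3))
  expect_false(is.unsorted(res$trace$best_nmi))
  short <- register_rigid(v, moving,
                          opts = list(stride = 3, max_iter = 3, restarts = 1))
  expect_false(short$converged)
  expect_error(register_rigid(volume(array(1, c(3, 3, 3)), 1), v),
               "non-constant")
})
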