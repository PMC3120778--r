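# Gaussian shape model: exponents, lookup table, analytic overlap vs
# quadrature, shape Tanimoto, and the grid estimate.

test_that("gaussian exponent matches the hard-sphere calibration", {
  # closed form at r = 1
  expect_equal(gaussian_exponent(1), pi * (3 * 2.7 / (4 * pi))^(2 / 3))
  # doubling the radius quarters the exponent
  expect_equal(gaussian_exponent(2), gaussian_exponent(1) / 4)
  expect_error(gaussian_exponent(0), "positive")
  # isolated-atom integral equals the hard-sphere volume (quadrature, r = 1.7)
  r <- 1.7
  a <- gaussian_exponent(r)
  h <- 0.15
  g <- seq(-6 + h / 2, 6, by = h)
  G <- as.matrix(expand.grid(g, g, g))
  integral <- sum(2.7 * exp(-a * rowSums(G^2))) * h^3
  expect_equal(integral, 4 / 3 * pi * r^3, tolerance = 0.001)
})

test_that("exponent lookup table has 6001 exact nodes and bounded lookup error", {
  lut <- exp_lut()
  expect_length(lut, 6001)
  xs <- seq(-12, 0, by = 0.002)
  expect_equal(lut, exp(xs))  # nodes are exact
  # nearest-entry evaluation error is at most half-step * max|d exp/dx| = 0.001
  set.seed(3)
  x <- runif(20000, -12, 0)
  approx_val <- lut[round((x + 12) / 0.002) + 1]
  expect_lt(max(abs(approx_val - exp(x))), 0.001)
})

test_that("pairwise overlap matches closed forms and decays to zero", {
  cc <- conformer("C", matrix(0, 1, 3))
  aC <- gaussian_exponent(1.7)
  closed <- 2.7^2 * (pi / (2 * aC))^1.5
  expect_equal(pairwise_overlap_volume(cc, cc), closed, tolerance = 1e-6)
  expect_equal(self_overlap_volume(cc), closed, tolerance = 1e-6)
  far <- rigid_transform(t = c(50, 0, 0))
  expect_equal(pairwise_overlap_volume(cc, cc, far), 0)
})

test_that("analytic overlap agrees with 3-D quadrature on single pairs", {
  cc <- conformer("C", matrix(0, 1, 3))
  c2 <- conformer("C", matrix(c(1, 0, 0), 1, 3))
  v <- pairwise_overlap_volume(cc, c2)
  q <- quadrature_overlap(matrix(0, 1, 3), 1.7, matrix(c(1, 0, 0), 1, 3),
                          1.7, h = 0.15)
  expect_equal(v, q, tolerance = 0.005)
})

test_that("self overlap is invariant under rigid rotation", {
  k <- make_toy_conformer("chain", 7)
  v0 <- self_overlap_volume(k)
  set.seed(5)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  k2 <- k
  k2$coords <- rt_apply(rigid_transform(q), k$coords)
  expect_equal(self_overlap_volume(k2), v0, tolerance = 1e-6)
})

test_that("overlap is symmetric under argument swap with inverted transform", {
  pairs <- small_pair_suite(seed = 2)[c(1, 5, 9, 13)]
  for (p in pairs) {
    set.seed(p$a$cid)
    tr <- random_transform()
    v1 <- pairwise_overlap_volume(p$a, p$b, tr)
    v2 <- pairwise_overlap_volume(p$b, p$a, rt_invert(tr))
    expect_equal(v1, v2, tolerance = 1e-9)
  }
})

test_that("shape Tanimoto arithmetic and validity", {
  expect_equal(shape_tanimoto(30, 30, 15), 1 / 3)
  expect_equal(shape_tanimoto(10, 10, 10), 1)
  expect_equal(shape_tanimoto(20, 40, 0), 0)
  expect_error(shape_tanimoto(10, 10, 25), "invalid")
  k <- prepare_conformer(make_toy_conformer("chain", 6))
  expect_identical(
    shape_tanimoto(k$self_volume, k$self_volume,
                   k$self_volume), 1)
})

test_that("shape grid stores probe overlaps and reproduces analytic values", {
  cc <- prepare_conformer(conformer("C", matrix(c(3, 4, 5), 1, 3)))
  g <- build_shape_grid(cc)
  expect_equal(g$spacing, 0.25)
  expect_true(all(g$values >= 0))
  # value at the atom center equals the single-pair overlap at d = 0
  aC <- gaussian_exponent(1.7)
  center_idx <- which.max(g$values)
  expect_equal(max(g$values), 2.7^2 * (pi / (2 * aC))^1.5, tolerance = 1e-3)
  # decays to near zero on box faces (cutoff boundary contributions only)
  nx <- g$dims[1]; ny <- g$dims[2]
  face <- g$values[seq_len(nx * ny)]  # z = origin face
  expect_lt(max(face), 0.01)
  expect_lt(max(face) / max(g$values), 1e-3)
})

test_that("grid overlap estimates track the analytic overlap", {
  # identity self-overlap within 10 percent
  k <- prepare_conformer(make_toy_conformer("chain", 6))
  g <- build_shape_grid(k)
  est <- grid_overlap_volume(g, k)
  expect_equal(est, k$self_volume, tolerance = 0.1)
  # far translation: zero
  expect_equal(grid_overlap_volume(g, k, rigid_transform(t = c(100, 0, 0))), 0)
  # monotone decay along a translation axis for a two-atom rod
  rod <- prepare_conformer(make_toy_conformer("rod", 2))
  gr <- build_shape_grid(rod)
  vals <- vapply(seq(0, 3, by = 0.5), function(d) {
    grid_overlap_volume(gr, rod, rigid_transform(t = c(0, d, 0)))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("grid vs analytic deviation is small across random fixture pairs", {
  set.seed(9)
  devs <- c()
  for (p in small_pair_suite(seed = 4)) {
    a <- prepare_conformer(p$a)
    b <- prepare_conformer(p$b)
    g <- build_shape_grid(a)
    for (rep in 1:2) {
      tr <- rigid_transform(rnorm(4), runif(3, -1, 1))
      exact <- pairwise_overlap_volume(a, b, tr)
      if (exact < 1) next  # skip near-zero overlaps (relative dev unstable)
      est <- grid_overlap_volume(g, b, tr)
      devs <- c(devs, abs(est - exact) / exact)
    }
  }
  expect_gt(length(devs), 15)
  expect_lt(stats::median(devs), 0.05)
})
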