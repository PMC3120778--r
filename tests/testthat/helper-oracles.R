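# Independent numerical oracles shared across test files.  These never call
# the package's overlap kernels: densities are summed with exact exp() on a
# midpoint-rule lattice.

GAUSS_P_ORACLE <- 2.70

oracle_alpha <- function(radius) {
  pi * (3 * GAUSS_P_ORACLE / (4 * pi))^(2 / 3) / radius^2
}

# midpoint-rule quadrature of the product of two Gaussian density sums
quadrature_overlap <- function(XA, radiiA, XB, radiiB, h = 0.25, pad = 4.0) {
  XA <- as.matrix(XA); XB <- as.matrix(XB)
  aA <- oracle_alpha(radiiA)
  aB <- oracle_alpha(radiiB)
  lo <- pmin(apply(XA, 2, min), apply(XB, 2, min)) - pad
  hi <- pmax(apply(XA, 2, max), apply(XB, 2, max)) + pad
  gx <- seq(lo[1] + h / 2, hi[1], by = h)
  gy <- seq(lo[2] + h / 2, hi[2], by = h)
  gz <- seq(lo[3] + h / 2, hi[3], by = h)
  G <- as.matrix(expand.grid(gx, gy, gz))
  density <- function(X, a) {
    rho <- numeric(nrow(G))
    for (i in seq_len(nrow(X))) {
      d2 <- (G[, 1] - X[i, 1])^2 + (G[, 2] - X[i, 2])^2 + (G[, 3] - X[i, 3])^2
      rho <- rho + GAUSS_P_ORACLE * exp(-a[i] * d2)
    }
    rho
  }
  sum(density(XA, aA) * density(XB, aB)) * h^3
}

quadrature_overlap_conf <- function(confA, confB, ...) {
  hA <- !confA$is_h; hB <- !confB$is_h
  quadrature_overlap(confA$coords[hA, , drop = FALSE], confA$radius[hA],
                     confB$coords[hB, , drop = FALSE], confB$radius[hB], ...)
}

# angle (degrees) between the rotations of two unit quaternions
quat_angle_deg <- function(q1, q2) {
  d <- min(1, abs(sum(q1 * q2)))
  2 * acos(d) * 180 / pi
}

random_transform <- function(tmax = 2) {
  q <- rnorm(4)
  rigid_transform(q / sqrt(sum(q^2)), runif(3, -tmax, tmax))
}

# acetate-like fixture: CH3-COO(H) heavy atoms with a carboxyl group
acetate_fixture <- function() {
  conformer(
    c("C", "C", "O", "O"),
    rbind(c(-1.5, 0, 0), c(0, 0, 0), c(0.65, 1.1, 0), c(0.65, -1.1, 0)),
    bonds = rbind(c(1, 2, 1), c(2, 3, 2), c(2, 4, 1)),
    cid = 9, lid = 0)
}

small_pair_suite <- function(seed = 1) {
  # deterministic list of conformer pairs spanning sizes and heteroatoms
  pairs <- list()
  templates <- c("rod", "chain", "ring", "ring_tail", "branched",
                 "donor_acceptor", "featureless")
  k <- 0
  for (tpl in templates) {
    for (n in c(5, 7)) {
      k <- k + 1
      a <- make_toy_conformer(tpl, n, cid = 1000 + k, lid = 0)
      b <- perturb_conformer(a, 0.3, seed = seed + k)
      b$cid <- 2000 + k
      pairs[[k]] <- list(a = a, b = b)
    }
  }
  pairs
}
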