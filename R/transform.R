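# Rigid-transform algebra (unit quaternion + translation) and the canonical
# inertial frame used before any similarity computation.

#' Construct a rigid transform
#'
#' @param q Unit quaternion `c(w, x, y, z)` (normalized on construction).
#' @param t Translation 3-vector (angstrom).
#' @return An object of class `rigid_transform` mapping `x -> R(q) x + t`.
#' @export
rigid_transform <- function(q = c(1, 0, 0, 0), t = c(0, 0, 0)) {
  q <- as.numeric(q); t <- as.numeric(t)
  stopifnot(length(q) == 4, length(t) == 3)
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("zero quaternion")
  structure(list(q = q / n, t = t), class = "rigid_transform")
}

#' Identity rigid transform
#' @return The identity `rigid_transform`.
#' @export
rt_identity <- function() rigid_transform()

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform q=(%.4f, %.4f, %.4f, %.4f) t=(%.3f, %.3f, %.3f)>\n",
              x$q[1], x$q[2], x$q[3], x$q[4], x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

quat_from_rotvec <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-12) return(c(1, 0, 0, 0))
  c(cos(th / 2), r / th * sin(th / 2))
}

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` applies `b` first, then `a`:
#' `x -> R_a (R_b x + t_b) + t_a`.
#'
#' @param a,b `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(quat_multiply(a$q, b$q),
                  as.vector(quat_to_matrix(a$q) %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param tr A `rigid_transform`.
#' @return Its inverse.
#' @export
rt_invert <- function(tr) {
  qi <- quat_conjugate(tr$q)
  rigid_transform(qi, -as.vector(quat_to_matrix(qi) %*% tr$t))
}

#' Apply a rigid transform to coordinates
#' @param tr A `rigid_transform`.
#' @param X n x 3 coordinate matrix.
#' @return Transformed n x 3 matrix.
#' @export
rt_apply <- function(tr, X) {
  X <- as.matrix(X)
  sweep(X %*% t(quat_to_matrix(tr$q)), 2, -tr$t)
}

#' Canonicalize a conformer's frame of reference
#'
#' Moves the non-hydrogen steric center (unweighted mean) to the origin and
#' rotates into the principal axes of the unweighted gyration tensor, ordered
#' by descending eigenvalue.  The sign of each of the first two axes is fixed
#' by making its largest-magnitude component positive; the third axis is the
#' cross product of the first two (right-handed).  Near-degenerate tensors
#' (symmetric tops, single atoms) are only centered and flagged via the
#' `frame_degenerate` field.
#'
#' @param conf A `conformer`.
#' @return The conformer expressed in its canonical frame.
#' @export
canonical_frame <- function(conf) {
  X <- heavy_coords(conf)
  ctr <- colMeans(X)
  conf$coords <- sweep(conf$coords, 2, ctr)
  X <- heavy_coords(conf)
  if (nrow(X) == 1) {
    conf$frame_degenerate <- TRUE
    return(conf)
  }
  G <- crossprod(X) / nrow(X)
  eg <- eigen(G, symmetric = TRUE)
  ev <- eg$values
  scale <- max(abs(ev), 1e-12)
  tol <- 1e-7 * scale
  d12 <- ev[1] - ev[2] < tol
  d23 <- ev[2] - ev[3] < tol
  if (d12 && d23) {
    # spherical top: no preferred axes, keep input orientation
    conf$frame_degenerate <- TRUE
    return(conf)
  }
  fix_sign <- function(v) if (v[which.max(abs(v))] < 0) -v else v
  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  # deterministic unit vector orthogonal to v (for degenerate subspaces)
  perp_to <- function(v) {
    e <- diag(3)[, which.min(abs(v))]
    w <- e - sum(e * v) * v
    fix_sign(w / sqrt(sum(w^2)))
  }
  if (!d12 && !d23) {
    v1 <- fix_sign(eg$vectors[, 1])
    v2 <- fix_sign(eg$vectors[, 2])
    v3 <- cross3(v1, v2)
    conf$frame_degenerate <- FALSE
  } else if (d23) {
    # prolate (rod-like): long axis well defined, transverse pair arbitrary
    v1 <- fix_sign(eg$vectors[, 1])
    v2 <- perp_to(v1)
    v3 <- cross3(v1, v2)
    conf$frame_degenerate <- TRUE
  } else {
    # oblate (disk-like): short axis well defined, in-plane pair arbitrary
    v3 <- fix_sign(eg$vectors[, 3])
    v1 <- perp_to(v3)
    v2 <- cross3(v3, v1)
    conf$frame_degenerate <- TRUE
  }
  conf$coords <- conf$coords %*% cbind(v1, v2, v3)
  conf
}
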