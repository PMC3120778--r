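# Shape-overlap maximization between conformer pairs and the combined
# shape + feature (combo) score.

#' Default optimizer starts: identity plus the three principal-axis flips
#'
#' For canonicalized conformers the inertial frame is defined only up to
#' 180-degree flips about the principal axes; starting the local optimizer
#' from the identity and the three flips is the standard remedy.
#'
#' @return List of four `rigid_transform` starts.
#' @export
default_starts <- function() {
  list(rt_identity(),
       rigid_transform(c(0, 1, 0, 0)),
       rigid_transform(c(0, 0, 1, 0)),
       rigid_transform(c(0, 0, 0, 1)))
}

#' Dense rotational starts: the 24 orientations of the cube group
#'
#' Used by the brute-force validation oracle; covers rotational space far
#' more densely than [default_starts()].
#'
#' @return List of 24 `rigid_transform` starts.
#' @export
cube_rotation_starts <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) {
    for (sx in c(1, -1)) for (sy in c(1, -1)) for (sz in c(1, -1)) {
      R <- matrix(0, 3, 3)
      R[1, p[1]] <- sx; R[2, p[2]] <- sy; R[3, p[3]] <- sz
      if (abs(det(R) - 1) < 1e-9) {
        out[[length(out) + 1L]] <- rigid_transform(matrix_to_quat(R))
      }
    }
  }
  out
}

.optimize_overlap_xyz <- function(XA, aA, XB, aB, starts,
                                  max_optimized = Inf) {
  lut <- exp_lut()
  p2 <- GAUSS_P^2
  if (is.finite(max_optimized) && length(starts) > max_optimized) {
    v0 <- vapply(starts, function(s) {
      cpp_overlap_transformed(XA, aA, XB, aB, p2, lut, s$q, s$t)
    }, numeric(1))
    starts <- starts[order(-v0)[seq_len(max_optimized)]]
  }
  best <- NULL; best_v <- -Inf
  for (s in starts) {
    fit <- tryCatch(
      optim(rep(0, 6), cpp_neg_overlap_par, q0 = s$q, t0 = s$t,
            A = XA, aA = aA, B = XB, aB = aB, p2 = p2, lut = lut,
            method = "Nelder-Mead",
            control = list(maxit = OPT_MAXIT, reltol = OPT_RELTOL)),
      error = function(e) NULL)
    if (is.null(fit)) next
    v <- -fit$value
    if (v > best_v) {
      best_v <- v
      best <- rigid_transform(quat_multiply(s$q, quat_from_rotvec(fit$par[1:3])),
                              s$t + fit$par[4:6])
    }
  }
  if (is.null(best)) stop("all optimizer starts failed")
  list(transform = best, vab = best_v)
}

#' Maximize the shape overlap between two conformers
#'
#' Derivative-free local maximization of the analytic pairwise overlap
#' volume over the six rigid degrees of freedom (axis-angle rotation and
#' translation of B), run from each start; the best local optimum is
#' returned.  Deterministic for fixed inputs (Nelder-Mead with a fixed
#' iteration and tolerance policy).  Feature atoms never enter the
#' objective.
#'
#' @param confA,confB `conformer` objects (canonicalized).
#' @param starts List of `rigid_transform` starts (default
#'   [default_starts()]).
#' @param max_optimized If finite, starts are first ranked by single-point
#'   overlap and only the best `max_optimized` are optimized (used with
#'   dense start sets).
#' @return List with `transform` (maps B's frame into A's) and `vab` (the
#'   maximized overlap volume).
#' @export
optimize_shape_overlap <- function(confA, confB, starts = default_starts(),
                                   max_optimized = Inf) {
  .optimize_overlap_xyz(heavy_coords(confA), heavy_alpha(confA),
                        heavy_coords(confB), heavy_alpha(confB),
                        starts, max_optimized)
}

#' Shape, color, and combo Tanimoto of a conformer pair
#'
#' Optimizes the shape overlap (shape only; features never drive the
#' optimization), then evaluates the color Tanimoto as a single point at the
#' ST-optimal transform.  The combo Tanimoto is `ST + CT`, with the CT term
#' contributing zero when either conformer is featureless.
#'
#' @param confA,confB Prepared `conformer` objects (see
#'   [prepare_conformer()]).
#' @param starts Optimizer starts (default [default_starts()]).
#' @return List with `st`, `ct` (`NA` when both conformers are featureless),
#'   `combo`, and the optimal `transform`.
#' @export
combo_tanimoto <- function(confA, confB, starts = default_starts()) {
  stopifnot(isTRUE(confA$prepared), isTRUE(confB$prepared))
  opt <- optimize_shape_overlap(confA, confB, starts)
  st <- shape_tanimoto(confA$self_volume, confB$self_volume, opt$vab)
  ab <- color_overlap_volumes(confA$features, confB$features, opt$transform)
  ct <- color_tanimoto(confA$self_color_volumes, confB$self_color_volumes, ab)
  combo <- st + if (is.na(ct)) 0 else ct
  list(st = st, ct = ct, combo = combo, transform = opt$transform)
}
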