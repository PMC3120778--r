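# Grant-Pickup first-order Gaussian shape overlap, shape Tanimoto, and the
# grid-based O(N) overlap estimate.

#' Pairwise Gaussian shape-overlap volume of two conformers
#'
#' First-order (pairwise product) Gaussian overlap between the non-hydrogen
#' atoms of `confA` and the transformed non-hydrogen atoms of `confB`:
#' the sum over atom pairs of
#' `p^2 (pi/(a_i+a_j))^(3/2) exp(-(a_i a_j/(a_i+a_j)) d_ij^2)`,
#' with the exponentials evaluated through the shared lookup table
#' ([exp_lut()]).
#'
#' @param confA,confB `conformer` objects.
#' @param transform `rigid_transform` mapping B's frame into A's (default
#'   identity).
#' @return Overlap volume `V_AB` in cubic angstrom.
#' @export
pairwise_overlap_volume <- function(confA, confB, transform = rt_identity()) {
  cpp_overlap_transformed(
    heavy_coords(confA), heavy_alpha(confA),
    heavy_coords(confB), heavy_alpha(confB),
    GAUSS_P^2, exp_lut(), transform$q, transform$t)
}

#' Shape Tanimoto from overlap volumes
#'
#' `ST = V_AB / (V_AA + V_BB - V_AB)`; equals 1 for a conformer against
#' itself at the identity.
#'
#' @param vaa,vbb Self-overlap volumes of A and B (> 0).
#' @param vab Cross overlap volume (>= 0).
#' @return The shape Tanimoto.
#' @export
shape_tanimoto <- function(vaa, vbb, vab) {
  stopifnot(vaa > 0, vbb > 0, vab >= 0)
  den <- vaa + vbb - vab
  if (den <= 0) stop("invalid overlap: V_AB >= V_AA + V_BB")
  vab / den
}

#' Build the shape grid of a conformer
#'
#' A 3-D lattice (0.25 angstrom spacing) storing, at each point, the Gaussian
#' overlap volume of a single carbon probe atom centered there with the
#' conformer; atoms farther than 4.5 angstrom from a point contribute
#' nothing.  The lattice covers the heavy-atom bounding box dilated by the
#' cutoff.  Used only for the cheap stage-2 overlap estimate.
#'
#' @param conf A `conformer` (canonicalized).
#' @return An object of class `grid_map` with fields `origin`, `spacing`,
#'   `dims`, `values`.
#' @export
build_shape_grid <- function(conf) {
  X <- heavy_coords(conf)
  a <- heavy_alpha(conf)
  lo <- apply(X, 2, min) - GRID_CUTOFF
  hi <- apply(X, 2, max) + GRID_CUTOFF
  dims <- as.integer(ceiling((hi - lo) / GRID_SPACING)) + 1L
  vals <- cpp_build_grid(X, a, gaussian_exponent(BONDI_RADII[["C"]]),
                         GAUSS_P^2, exp_lut(), lo, dims, GRID_SPACING,
                         GRID_CUTOFF)
  structure(list(origin = lo, spacing = GRID_SPACING, dims = dims,
                 values = vals), class = "grid_map")
}

#' @export
print.grid_map <- function(x, ...) {
  cat(sprintf("<grid_map %d x %d x %d at %.2f A spacing>\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing))
  invisible(x)
}

#' Estimate a shape overlap from a precomputed grid
#'
#' Sums the trilinearly interpolated grid value of `gridA` at each
#' transformed non-hydrogen atom of `confB`.  The grid stores carbon-probe
#' overlaps; a non-carbon query atom's contribution is scaled by the
#' prefactor ratio `((2 a_C)/(a_C + a_j))^(3/2)` (exact for the amplitude
#' term, approximate for the exponent).  Atoms landing outside the grid
#' contribute zero.  This is an estimate used for stage-2 screening only,
#' never for final scores.
#'
#' @param gridA `grid_map` built from conformer A.
#' @param confB Query `conformer`.
#' @param transform `rigid_transform` mapping B's frame into A's.
#' @return Estimated overlap volume in cubic angstrom.
#' @export
grid_overlap_volume <- function(gridA, confB, transform = rt_identity()) {
  aC <- gaussian_exponent(BONDI_RADII[["C"]])
  aB <- heavy_alpha(confB)
  scale <- (2 * aC / (aC + aB))^1.5
  cpp_grid_overlap(gridA$values, gridA$origin, gridA$dims, gridA$spacing,
                   heavy_coords(confB), scale, transform$q, transform$t)
}
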