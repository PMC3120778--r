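# Tiered reference-shape libraries, sparse shape fingerprints with retained
# packed alignments, and alignment recycling.

#' The seven volume regions of the shape-fingerprint design
#'
#' Integer-bounded volume bands with fingerprint shape-Tanimoto thresholds
#' decreasing from 0.75 to 0.45 in steps of 0.05 as conformer volume grows.
#'
#' @return A data.frame with columns `lo`, `hi` (cubic angstrom) and
#'   `st_thresh`.
#' @export
region_table <- function() {
  data.frame(
    lo = c(1, 166, 200, 239, 286, 345, 433),
    hi = c(165, 199, 238, 285, 344, 432, 999),
    st_thresh = c(0.75, 0.70, 0.65, 0.60, 0.55, 0.50, 0.45)
  )
}

#' Volume region for a conformer self volume
#'
#' Bands are contiguous with integer-labeled bounds; a non-integer volume
#' falls in the first band whose upper bound is at least `v`, and volumes
#' below 1 clamp into the first band.  Volumes above 999 are outside the
#' supported molecule size range and rejected.
#'
#' @param v Self shape volume in cubic angstrom (> 0).
#' @return List with `index`, `lo`, `hi`, `st_thresh`.
#' @export
region_for_volume <- function(v) {
  stopifnot(v > 0)
  rt <- region_table()
  if (v > max(rt$hi)) {
    stop("conformer volume ", round(v, 1),
         " exceeds the supported range (<= 999 cubic angstrom)")
  }
  i <- which(rt$hi >= v)[1]
  list(index = i, lo = rt$lo[i], hi = rt$hi[i], st_thresh = rt$st_thresh[i])
}

.ref_geometry <- function(conf) {
  list(coords = heavy_coords(conf), alpha = heavy_alpha(conf),
       volume = self_overlap_volume(conf))
}

#' Build a tiered reference-shape library by leader clustering
#'
#' Streams conformers in order; a conformer becomes a new reference shape of
#' its volume region when its optimized shape Tanimoto to every existing
#' reference in that region is below the region threshold.  The result is
#' order-dependent (leader clustering); the stream order is recorded as
#' provenance.
#'
#' @param conformers List of prepared `conformer` objects, in stream order.
#' @param starts Optimizer starts used for the reference comparisons.
#' @return An object of class `reference_library`: list of references (id,
#'   region index, leader geometry, self volume) plus the region table.
#' @export
build_reference_library <- function(conformers, starts = default_starts()) {
  refs <- list()
  for (conf in conformers) {
    if (!isTRUE(conf$prepared)) conf <- prepare_conformer(conf)
    v <- conf$self_volume
    reg <- region_for_volume(v)
    is_new <- TRUE
    for (ref in refs) {
      if (ref$region != reg$index) next
      opt <- .optimize_overlap_xyz(ref$coords, ref$alpha,
                                   heavy_coords(conf), heavy_alpha(conf),
                                   starts)
      st <- shape_tanimoto(ref$volume, v, opt$vab)
      if (st >= reg$st_thresh) {
        is_new <- FALSE
        break
      }
    }
    if (is_new) {
      refs[[length(refs) + 1L]] <- list(
        id = length(refs) + 1L, region = reg$index,
        coords = heavy_coords(conf), alpha = heavy_alpha(conf),
        volume = v, st_thresh = reg$st_thresh,
        leader = conformer_id_hex(conf))
    }
  }
  structure(list(references = refs, regions = region_table(),
                 n_streamed = length(conformers)),
            class = "reference_library")
}

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf("<reference_library: %d reference shape(s) from %d conformer(s)>\n",
              length(x$references), x$n_streamed))
  invisible(x)
}

# Volume prefilter for fingerprint bits.  The minimum overlap needed to
# reach the region threshold is ab_min = T (A+B)/(1+T) (Tanimoto solved for
# the overlap).  Two caps bound the attainable overlap at any transform:
# the Cauchy-Schwarz cap sqrt(A*B) (exact for the first-order Gaussian
# overlap, which is an L2 inner product of densities), and the empirical
# 1.5 * min(A, B) cap (the same window the stage-1 shape filter trusts;
# Gaussian overlap can exceed the smaller self volume, but not by more).
# References whose ab_min exceeds either cap are skipped.
.volume_prefilter_pass <- function(va, vb, st_thresh) {
  ab_min <- st_thresh * (va + vb) / (1 + st_thresh)
  ab_min <= sqrt(va * vb) && ab_min <= 1.5 * min(va, vb)
}

#' Compute the shape fingerprint of a conformer
#'
#' For each library reference surviving the volume prefilter, the
#' conformer-to-reference shape superposition is optimized; when the
#' optimized shape Tanimoto reaches the reference's region threshold, the
#' corresponding bit is set and the alignment is retained in packed 64-bit
#' form.  The prefilter is provably sound (Cauchy-Schwarz bound on Gaussian
#' overlap), so no bit a brute-force pass would set is ever suppressed.
#'
#' @param conf A prepared `conformer`.
#' @param library A `reference_library`.
#' @param starts Optimizer starts (default [default_starts()]).
#' @param prefilter Apply the volume prefilter (default `TRUE`; `FALSE`
#'   forces the brute-force pass over every reference, used to audit
#'   prefilter soundness).
#' @return An object of class `shape_fingerprint`: the owner's packed ID
#'   (hex), and `bits`, a named list mapping reference id to the packed
#'   conformer-to-reference `uint64` alignment.
#' @export
compute_fingerprint <- function(conf, library, starts = default_starts(),
                                prefilter = TRUE) {
  stopifnot(isTRUE(conf$prepared), inherits(library, "reference_library"))
  v <- conf$self_volume
  XB <- heavy_coords(conf); aB <- heavy_alpha(conf)
  bits <- list()
  for (ref in library$references) {
    if (prefilter && !.volume_prefilter_pass(ref$volume, v, ref$st_thresh)) next
    opt <- .optimize_overlap_xyz(ref$coords, ref$alpha, XB, aB, starts)
    st <- shape_tanimoto(ref$volume, v, opt$vab)
    if (st >= ref$st_thresh) {
      bits[[as.character(ref$id)]] <- encode_superposition(opt$transform)
    }
  }
  structure(list(owner = conformer_id_hex(conf), bits = bits),
            class = "shape_fingerprint")
}

#' @export
print.shape_fingerprint <- function(x, ...) {
  cat(sprintf("<shape_fingerprint of %s: %d bit(s) set>\n", x$owner,
              length(x$bits)))
  invisible(x)
}

#' Recycle a conformer-pair alignment through a common reference shape
#'
#' Given two fingerprints sharing reference `ref_id`, composes the stored
#' (decoded) conformer-to-reference alignments into an approximate
#' conformer-to-conformer superposition: `invert(T_A) o T_B`, mapping B's
#' frame into A's.
#'
#' @param fpA,fpB `shape_fingerprint` objects.
#' @param ref_id Reference id set in both fingerprints.
#' @return A `rigid_transform`.
#' @export
recycled_transform <- function(fpA, fpB, ref_id) {
  key <- as.character(ref_id)
  ta <- fpA$bits[[key]]; tb <- fpB$bits[[key]]
  if (is.null(ta) || is.null(tb)) {
    stop("reference ", ref_id, " is not set in both fingerprints")
  }
  rt_compose(rt_invert(decode_superposition(ta)), decode_superposition(tb))
}

common_reference_ids <- function(fpA, fpB) {
  intersect(names(fpA$bits), names(fpB$bits))
}
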