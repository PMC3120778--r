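# Core molecular types: conformers, compound records, conformer identity,
# and coordinate quantization for the compact binary format.

#' Construct a conformer
#'
#' A conformer is a single rigid 3-D geometry of a compound: an ordered atom
#' list with elements, coordinates and Bondi radii, an optional bond graph
#' (needed for pharmacophore feature typing), and its identity (CID, LID).
#' Hydrogens are kept in the structure but flagged; every shape and feature
#' computation uses only the non-hydrogen atoms.
#'
#' @param elements Character vector of element symbols.
#' @param coords Numeric n x 3 matrix of coordinates (angstrom).
#' @param bonds Optional integer matrix with columns `a`, `b`, `order`
#'   (1-based atom indices; order 4 denotes an aromatic bond).
#' @param cid Compound identifier (non-negative, < 2^32).
#' @param lid Local conformer identifier (non-negative, < 2^16).
#' @param energy Optional relative conformer energy (kcal/mol).
#' @return An object of class `conformer`.
#' @export
conformer <- function(elements, coords, bonds = NULL, cid = 0, lid = 0,
                      energy = NA_real_) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  stopifnot(ncol(coords) == 3, nrow(coords) == length(elements))
  is_h <- elements == "H"
  if (all(is_h)) stop("conformer must have at least one non-hydrogen atom")
  if (!is.null(bonds)) {
    bonds <- as.matrix(bonds)
    stopifnot(ncol(bonds) >= 3)
    colnames(bonds) <- c("a", "b", "order")[seq_len(ncol(bonds))]
  }
  structure(list(
    cid = as.numeric(cid), lid = as.numeric(lid),
    elements = as.character(elements), coords = coords,
    radius = bondi_radius(elements), is_h = is_h,
    bonds = bonds, energy = as.numeric(energy),
    prepared = FALSE
  ), class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer CID %s LID %s: %d atoms (%d heavy)%s>\n",
              format(x$cid, scientific = FALSE), x$lid, length(x$elements),
              sum(!x$is_h),
              if (isTRUE(x$prepared)) sprintf(", V=%.1f A^3", x$self_volume)
              else ""))
  invisible(x)
}

heavy_coords <- function(conf) conf$coords[!conf$is_h, , drop = FALSE]
heavy_alpha <- function(conf) gaussian_exponent(conf$radius[!conf$is_h])
n_heavy <- function(conf) sum(!conf$is_h)

#' Prepare a conformer for similarity computation
#'
#' Canonicalizes the frame (steric center at the origin, axes along the
#' principal axes of the unweighted gyration tensor), assigns and merges
#' pharmacophore features, and caches the self shape volume and per-type
#' self color volumes.
#'
#' @param conf A `conformer`.
#' @param canonicalize Rotate/translate into the canonical frame (default
#'   `TRUE`); with `FALSE` only the derived quantities are cached.
#' @return The prepared `conformer` with cached fields `self_volume`,
#'   `features`, `self_color_volumes`.
#' @export
prepare_conformer <- function(conf, canonicalize = TRUE) {
  stopifnot(inherits(conf, "conformer"))
  if (canonicalize) conf <- canonical_frame(conf)
  X <- heavy_coords(conf)
  if (any(abs(X) >= 50)) {
    stop("canonicalized coordinates outside (-50, +50) angstrom")
  }
  a <- heavy_alpha(conf)
  conf$self_volume <- cpp_overlap(X, a, X, a, GAUSS_P^2, exp_lut())
  conf$features <- merge_proximate_features(assign_features(conf))
  conf$self_color_volumes <- feature_self_volumes(conf$features)
  conf$prepared <- TRUE
  conf
}

#' Self shape-overlap volume of a conformer
#'
#' Gaussian overlap of the conformer with itself at the identity transform
#' (the `V_AA` of the shape Tanimoto).  Cached by [prepare_conformer()].
#'
#' @param conf A `conformer`.
#' @return Self overlap volume in cubic angstrom.
#' @export
self_overlap_volume <- function(conf) {
  if (isTRUE(conf$prepared)) return(conf$self_volume)
  X <- heavy_coords(conf)
  a <- heavy_alpha(conf)
  cpp_overlap(X, a, X, a, GAUSS_P^2, exp_lut())
}

#' Construct a compound record
#'
#' Groups the conformer ensemble of one compound.  Compound-level feature
#' counts are derived from the molecular graph alone (pre-merge), so they are
#' identical across conformers and usable for compound-pair filtering.
#'
#' @param cid Compound identifier.
#' @param conformers List of `conformer` objects (same topology), ordered by
#'   LID.
#' @return An object of class `compound_record`.
#' @export
compound_record <- function(cid, conformers) {
  stopifnot(length(conformers) >= 1)
  lids <- vapply(conformers, function(k) k$lid, numeric(1))
  conformers <- conformers[order(lids)]
  structure(list(
    cid = as.numeric(cid),
    conformers = conformers,
    feature_counts = topological_feature_counts(conformers[[1]])
  ), class = "compound_record")
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf("<compound CID %s: %d conformer(s)>\n",
              format(x$cid, scientific = FALSE), length(x$conformers)))
  invisible(x)
}

# ---- conformer identity ----------------------------------------------------

#' Pack a compound/conformer identity into 64 bits
#'
#' The packed ID holds the compound identifier (CID) in the 32 high bits and
#' the local conformer identifier (LID) in the 16 low bits; bits 16-31 are
#' zero.
#'
#' @param cid Compound identifier, integer in `[0, 2^32)`.
#' @param lid Local conformer identifier, integer in `[0, 2^16)`.
#' @return A `uint64` packed identity.
#' @export
make_conformer_id <- function(cid, lid) {
  cid <- as.numeric(cid); lid <- as.numeric(lid)
  if (is.na(cid) || cid < 0 || cid >= 2^32 || cid != floor(cid)) {
    stop("cid must be an integer in [0, 2^32)")
  }
  if (is.na(lid) || lid < 0 || lid >= 2^16 || lid != floor(lid)) {
    stop("lid must be an integer in [0, 2^16)")
  }
  new_uint64(cid, lid)
}

#' Unpack a 64-bit conformer identity
#'
#' Exact inverse of [make_conformer_id()]; bits 16-31 of a valid packed
#' identity are zero.
#'
#' @param packed A `uint64` packed identity (or a 16-character hex string).
#' @return List with elements `cid` and `lid`.
#' @export
parse_conformer_id <- function(packed) {
  if (is.character(packed)) packed <- uint64_from_hex(packed)
  stopifnot(is_uint64(packed))
  if (packed$lo >= 2^16) stop("bits 16-31 of a packed conformer ID must be zero")
  list(cid = packed$hi, lid = packed$lo)
}

conformer_id_hex <- function(conf) uint64_hex(make_conformer_id(conf$cid, conf$lid))

# ---- coordinate quantization ----------------------------------------------

COORD_STEP <- 100 / 2^16

#' Quantize a coordinate to a signed 16-bit level
#'
#' Coordinates are restricted to (-50, +50) angstrom and stored on a uniform
#' lattice with step `100 / 2^16` (about 0.0015 angstrom), so the round-trip
#' error is at most half a step.
#'
#' @param x Numeric vector of coordinates in (-50, 50).
#' @return Integer vector of levels in `[-32768, 32767]`.
#' @export
quantize_coordinate <- function(x) {
  if (any(abs(x) >= 50)) stop("coordinate outside (-50, +50) angstrom")
  pmin(pmax(round_hafz(x / COORD_STEP), -32768), 32767)
}

#' Dequantize a signed 16-bit coordinate level
#'
#' @param level Integer vector of levels from [quantize_coordinate()].
#' @return Numeric coordinates in angstrom.
#' @export
dequantize_coordinate <- function(level) level * COORD_STEP
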