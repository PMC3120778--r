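# The staged "similar conformers" search: cheap Tanimoto-bound volume
# filters, fingerprint/alignment-recycling screen, final optimization and
# neighbor decision, plus compound-level aggregation.

#' Search configuration for 3-D neighboring
#'
#' Thresholds follow the neighboring definition: a featured conformer pair
#' is a neighbor when the optimized superposition has `ST >= 0.795` and
#' `CT >= 0.495` (the nominal 0.8/0.5 after rounding to the nearest 0.01);
#' a pair of featureless conformers needs `ST >= 0.925` (nominal 0.93).
#' Stage 2 discards pairs whose recycled-alignment ST is not greater than
#' 0.735; the stage-1 shape-volume filter requires both `AB_min/A` and
#' `AB_min/B` (at the nominal 0.8 threshold) to lie in `[0.75, 1.50]`.
#'
#' @param st_threshold Final shape-Tanimoto threshold (default 0.795).
#' @param ct_threshold Final color-Tanimoto threshold (default 0.495).
#' @param featureless_st_threshold ST threshold for featureless pairs
#'   (default 0.925).
#' @param recycling_gate Stage-2 exact-ST gate (default 0.735, strict).
#' @param st_nominal Nominal ST threshold used by the stage-1 volume filter
#'   (default 0.8).
#' @param st_ratio_low,st_ratio_high Volume-ratio window (defaults 0.75,
#'   1.50).
#' @param n_diverse_query,n_diverse_search Number of diverse conformers
#'   considered per compound on each side (default 2).
#' @param thorough Seed the final optimization with the full flip start set
#'   in addition to the recycled alignment (default `FALSE`).
#' @return An object of class `search_config`.
#' @export
search_config <- function(st_threshold = 0.795, ct_threshold = 0.495,
                          featureless_st_threshold = 0.925,
                          recycling_gate = 0.735, st_nominal = 0.8,
                          st_ratio_low = 0.75, st_ratio_high = 1.50,
                          n_diverse_query = 2L, n_diverse_search = 2L,
                          thorough = FALSE) {
  cfg <- list(st_threshold = st_threshold, ct_threshold = ct_threshold,
              featureless_st_threshold = featureless_st_threshold,
              recycling_gate = recycling_gate, st_nominal = st_nominal,
              st_ratio_low = st_ratio_low, st_ratio_high = st_ratio_high,
              n_diverse_query = as.integer(n_diverse_query),
              n_diverse_search = as.integer(n_diverse_search),
              thorough = isTRUE(thorough))
  stopifnot(all(unlist(cfg[1:7]) >= 0), all(unlist(cfg[1:7]) <= 1.5))
  structure(cfg, class = "search_config")
}

# ---- stage-1 filters -------------------------------------------------------

#' Color-volume filter (minimum-overlap bound)
#'
#' From the Tanimoto equation solved for the overlap, the minimum color
#' overlap needed to reach `threshold` is
#' `AB_min = threshold (A + B) / (1 + threshold)`; if `AB_min` exceeds
#' either self color volume the pair can never reach the threshold
#' (elimination is strict: equality passes).
#'
#' @param vaa_color,vbb_color Total self color volumes (sums over the six
#'   types) of the two conformers.
#' @param threshold Color-Tanimoto threshold.
#' @return `TRUE` (pass) or `FALSE` (eliminate).  Not applicable to
#'   featureless pairs (callers route those separately).
#' @export
ct_min_overlap_filter <- function(vaa_color, vbb_color, threshold = 0.495) {
  ab_min <- threshold * (vaa_color + vbb_color) / (1 + threshold)
  !(ab_min > vaa_color || ab_min > vbb_color)
}

#' Feature-count filter (compound-pair level)
#'
#' Using per-type feature counts, the best conceivable color Tanimoto is
#' `CT_max = sum_t min(A_t, B_t) / (sum_t A_t + sum_t B_t - sum_t min)`.
#' Pairs with `CT_max` below the threshold are eliminated (boundary kept).
#' Because counts are topological, one evaluation covers every conformer
#' pair of a compound pair.
#'
#' @param countsA,countsB Per-type feature-count vectors.
#' @param threshold Color-Tanimoto threshold.
#' @return `TRUE` (pass) or `FALSE` (eliminate).
#' @export
ct_feature_count_filter <- function(countsA, countsB, threshold = 0.495) {
  common <- sum(pmin(countsA, countsB))
  total <- sum(countsA) + sum(countsB)
  if (total == 0) return(TRUE)  # featureless pair: filter not applicable
  ct_max <- common / (total - common)
  ct_max >= threshold
}

#' Shape-volume ratio filter
#'
#' With `AB_min = st_nominal (A + B) / (1 + st_nominal)` (the minimum shape
#' overlap needed at the nominal 0.8 threshold), both ratios `AB_min/A` and
#' `AB_min/B` must lie within `[0.75, 1.50]` for the pair to possibly be a
#' neighbor (Gaussian shape overlap can exceed the self volumes, hence the
#' asymmetric window rather than a hard cap).
#'
#' @param vaa,vbb Self shape volumes.
#' @param config A `search_config`.
#' @return `TRUE` (pass) or `FALSE` (eliminate).
#' @export
st_volume_ratio_filter <- function(vaa, vbb, config = search_config()) {
  ab_min <- config$st_nominal * (vaa + vbb) / (1 + config$st_nominal)
  r1 <- ab_min / vaa
  r2 <- ab_min / vbb
  r1 >= config$st_ratio_low && r1 <= config$st_ratio_high &&
    r2 >= config$st_ratio_low && r2 <= config$st_ratio_high
}

# ---- stage-2 ---------------------------------------------------------------

#' Combined shape + feature overlap at a recycled alignment
#'
#' The stage-2 estimate: grid-interpolated shape overlap (0.25 angstrom
#' lattice) plus the sum of the six per-type feature overlaps computed with
#' the inflated 1.25 angstrom feature radius (to be forgiving of proximate
#' color atoms).  Evaluated once per common reference; the caller keeps the
#' alignment with the largest value.
#'
#' @param confA,confB Prepared `conformer` objects.
#' @param transform Recycled `rigid_transform` (B into A's frame).
#' @param gridA `grid_map` prebuilt from `confA`.
#' @return The combined overlap estimate in cubic angstrom.
#' @export
combo_overlap_recycled <- function(confA, confB, transform, gridA) {
  ab_shape <- grid_overlap_volume(gridA, confB, transform)
  ab_feature <- sum(color_overlap_volumes(confA$features, confB$features,
                                          transform,
                                          radius = FEATURE_RADIUS_STAGE2))
  ab_shape + ab_feature
}

#' Stage-2 recycling gate on the exact shape overlap
#'
#' After the best recycled alignment is chosen, the shape overlap is
#' recomputed analytically (no grid) and the pair passes only when the
#' resulting shape Tanimoto is strictly greater than the gate (0.735).
#'
#' @param vaa,vbb Self shape volumes.
#' @param ab_shape_exact Analytic shape overlap at the recycled alignment.
#' @param config A `search_config`.
#' @return `TRUE` (pass) or `FALSE` (eliminate).
#' @export
recycling_gate <- function(vaa, vbb, ab_shape_exact,
                           config = search_config()) {
  shape_tanimoto(vaa, vbb, ab_shape_exact) > config$recycling_gate
}

# ---- stage-3 ---------------------------------------------------------------

#' Final neighbor decision
#'
#' Featured pairs are neighbors iff `ST >= st_threshold` and
#' `CT >= ct_threshold`; pairs of two featureless conformers are neighbors
#' iff `ST >= featureless_st_threshold`; mixed featured/featureless pairs
#' are never neighbors.
#'
#' @param st Shape Tanimoto at the final superposition.
#' @param ct Color Tanimoto at the same superposition, or `NA` for a
#'   both-featureless pair.
#' @param featurelessA,featurelessB Whether each conformer is featureless.
#' @param config A `search_config`.
#' @return `TRUE` if the pair is a neighbor.
#' @export
final_decision <- function(st, ct, featurelessA = FALSE, featurelessB = FALSE,
                           config = search_config()) {
  if (featurelessA && featurelessB) {
    return(st >= config$featureless_st_threshold)
  }
  if (featurelessA || featurelessB) return(FALSE)
  st >= config$st_threshold && ct >= config$ct_threshold
}

# ---- preparation -----------------------------------------------------------

#' Prepare a compound record for neighboring
#'
#' Prepares every conformer (canonical frame, features, cached volumes),
#' computes the diverse ordering, keeps the first `n_diverse` diverse
#' conformers, and computes their shape fingerprints against `library`.
#'
#' @param record A `compound_record`.
#' @param library A `reference_library` (or `NULL` to skip fingerprints).
#' @param n_diverse Number of diverse conformers to keep (default all).
#' @return The record with fields `kept` (prepared conformers in diverse
#'   order) and `fingerprints`.
#' @export
prepare_compound <- function(record, library = NULL, n_diverse = Inf) {
  stopifnot(inherits(record, "compound_record"))
  record$conformers <- lapply(record$conformers, function(k) {
    if (isTRUE(k$prepared)) k else prepare_conformer(k)
  })
  ord <- diverse_order(record)
  keep <- ord$order[seq_len(min(n_diverse, length(ord$order)))]
  record$diverse <- ord
  record$kept <- record$conformers[keep]
  record$fingerprints <- if (is.null(library)) NULL else {
    lapply(record$kept, compute_fingerprint, library = library)
  }
  record
}

.featureless <- function(conf) length(conf$features$types) == 0

new_filter_stats <- function() {
  as.list(stats::setNames(rep(0, 10), c(
    "total_pairs", "elim_feature_count", "elim_ct_volume", "elim_st_volume",
    "elim_no_common_ref", "elim_recycling_gate", "optimized",
    "elim_final_st", "elim_final_ct", "neighbors")))
}

# ---- the search ------------------------------------------------------------

#' Three-stage similar-conformers search
#'
#' Runs the staged neighbor search of `query` against `search`:
#' compound-level feature-count filter, per-pair color- and shape-volume
#' filters, common-reference fingerprint lookup with alignment recycling and
#' the exact-ST gate, and a final shape optimization seeded at the recycled
#' alignment (plus an identity safeguard; the full flip set with
#' `thorough = TRUE`) followed by the neighbor decision.  Emitted pairs
#' carry ST, CT and the packed 64-bit superposition.
#'
#' @param query,search Lists of `compound_record` objects (prepared records
#'   from [prepare_compound()] are used as-is; raw records are prepared
#'   against `library` with the configured diverse counts).
#' @param library The shared `reference_library` both sides are
#'   fingerprinted against.
#' @param config A `search_config`.
#' @return List with `pairs` (data.frame: cidA, lidA, cidB, lidB, st, ct,
#'   featureless, packed) and `stats` (per-filter elimination counts; the
#'   elimination counts and `optimized` sum to `total_pairs`, and the
#'   final-stage rejections plus `neighbors` sum to `optimized`).  Conformer
#'   pairs within one compound (same CID) are examined and reported like any
#'   others and flagged by [compound_pairs_from_conformer_pairs()].
#' @export
neighbor_search <- function(query, search, library,
                            config = search_config()) {
  if (inherits(query, "compound_record")) query <- list(query)
  if (inherits(search, "compound_record")) search <- list(search)
  prep <- function(records, n) {
    lapply(records, function(r) {
      if (!is.null(r$kept) && !is.null(r$fingerprints)) r
      else prepare_compound(r, library, n)
    })
  }
  query <- prep(query, config$n_diverse_query)
  search <- prep(search, config$n_diverse_search)
  stats <- new_filter_stats()
  grids <- new.env(parent = emptyenv())
  grid_for <- function(conf) {
    key <- conformer_id_hex(conf)
    if (is.null(grids[[key]])) grids[[key]] <- build_shape_grid(conf)
    grids[[key]]
  }
  seen <- new.env(parent = emptyenv())
  rows <- list()
  for (qc in query) {
    for (sc in search) {
      count_pass <- ct_feature_count_filter(qc$feature_counts,
                                            sc$feature_counts,
                                            config$ct_threshold)
      for (qi in seq_along(qc$kept)) {
        for (si in seq_along(sc$kept)) {
          A <- qc$kept[[qi]]; B <- sc$kept[[si]]
          ka <- conformer_id_hex(A); kb <- conformer_id_hex(B)
          key <- if (ka <= kb) paste(ka, kb) else paste(kb, ka)
          if (!is.null(seen[[key]])) next
          seen[[key]] <- TRUE
          stats$total_pairs <- stats$total_pairs + 1
          flA <- .featureless(A); flB <- .featureless(B)
          if (!count_pass) {
            stats$elim_feature_count <- stats$elim_feature_count + 1
            next
          }
          if (!(flA && flB) &&
              !ct_min_overlap_filter(sum(A$self_color_volumes),
                                     sum(B$self_color_volumes),
                                     config$ct_threshold)) {
            stats$elim_ct_volume <- stats$elim_ct_volume + 1
            next
          }
          if (!st_volume_ratio_filter(A$self_volume, B$self_volume, config)) {
            stats$elim_st_volume <- stats$elim_st_volume + 1
            next
          }
          fpA <- qc$fingerprints[[qi]]; fpB <- sc$fingerprints[[si]]
          common <- common_reference_ids(fpA, fpB)
          if (length(common) == 0) {
            stats$elim_no_common_ref <- stats$elim_no_common_ref + 1
            next
          }
          gridA <- grid_for(A)
          best_t <- NULL; best_combo <- -Inf
          for (rid in common) {
            tr <- recycled_transform(fpA, fpB, rid)
            cmb <- combo_overlap_recycled(A, B, tr, gridA)
            if (cmb > best_combo) {
              best_combo <- cmb; best_t <- tr
            }
          }
          ab_exact <- pairwise_overlap_volume(A, B, best_t)
          if (!recycling_gate(A$self_volume, B$self_volume, ab_exact,
                              config)) {
            stats$elim_recycling_gate <- stats$elim_recycling_gate + 1
            next
          }
          stats$optimized <- stats$optimized + 1
          starts <- c(list(best_t, rt_identity()),
                      if (config$thorough) default_starts()[-1])
          opt <- optimize_shape_overlap(A, B, starts)
          st <- shape_tanimoto(A$self_volume, B$self_volume, opt$vab)
          ab_color <- color_overlap_volumes(A$features, B$features,
                                            opt$transform)
          ct <- color_tanimoto(A$self_color_volumes, B$self_color_volumes,
                               ab_color)
          if (!final_decision(st, ct, flA, flB, config)) {
            if (st < config$st_threshold ||
                (flA && flB && st < config$featureless_st_threshold)) {
              stats$elim_final_st <- stats$elim_final_st + 1
            } else {
              stats$elim_final_ct <- stats$elim_final_ct + 1
            }
            next
          }
          stats$neighbors <- stats$neighbors + 1
          rows[[length(rows) + 1L]] <- data.frame(
            cidA = A$cid, lidA = A$lid, cidB = B$cid, lidB = B$lid,
            st = st, ct = ct, featureless = flA && flB,
            packed = uint64_hex(encode_superposition(opt$transform)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else data.frame(
    cidA = numeric(0), lidA = numeric(0), cidB = numeric(0),
    lidB = numeric(0), st = numeric(0), ct = numeric(0),
    featureless = logical(0), packed = character(0),
    stringsAsFactors = FALSE)
  list(pairs = pairs, stats = stats)
}

#' Aggregate conformer neighbor pairs into compound pairs
#'
#' A compound pair is a neighbor pair when at least one of its conformer
#' pairs is; pairs within a single compound (same CID) are flagged rather
#' than aggregated.
#'
#' @param pairs The `pairs` data.frame from [neighbor_search()].
#' @return A data.frame with columns `cidA`, `cidB` (unordered, `cidA <=
#'   cidB`), `n_conformer_pairs`, and `self` (same-CID flag).
#' @export
compound_pairs_from_conformer_pairs <- function(pairs) {
  if (nrow(pairs) == 0) {
    return(data.frame(cidA = numeric(0), cidB = numeric(0),
                      n_conformer_pairs = integer(0), self = logical(0)))
  }
  lo <- pmin(pairs$cidA, pairs$cidB)
  hi <- pmax(pairs$cidA, pairs$cidB)
  key <- paste(lo, hi)
  agg <- tapply(seq_along(key), key, length)
  first <- match(names(agg), key)
  out <- data.frame(cidA = lo[first], cidB = hi[first],
                    n_conformer_pairs = as.integer(agg),
                    self = lo[first] == hi[first])
  out[order(out$cidA, out$cidB), , drop = FALSE]
}
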