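# Diverse-conformer ordering: greedy max-dissimilarity permutation of a
# compound's conformer ensemble by combo Tanimoto.

#' Pairwise combo-Tanimoto matrix of an ensemble
#'
#' Symmetric matrix of [combo_tanimoto()] scores over a compound's prepared
#' conformers; the diagonal is the self combo (2 for featured compounds, 1
#' for featureless ones).
#'
#' @param conformers List of prepared `conformer` objects.
#' @return Numeric n x n matrix.
#' @export
pairwise_combo_matrix <- function(conformers) {
  n <- length(conformers)
  stopifnot(n >= 1)
  featureless <- length(conformers[[1]]$features$types) == 0
  M <- diag(if (featureless) 1 else 2, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        M[i, j] <- M[j, i] <- combo_tanimoto(conformers[[i]],
                                             conformers[[j]])$combo
      }
    }
  }
  M
}

#' Diverse ordering of a conformer ensemble
#'
#' Orders conformers by combined shape + feature dissimilarity.  The
#' lowest-energy conformer seeds the ordering (lowest LID when energies are
#' absent); each subsequent pick is the unassigned conformer with the least
#' sum of combo Tanimoto to the already-selected conformers.  Ties (equality
#' within 1e-9) go to the conformer with the largest sum of combo Tanimoto
#' to all remaining unassigned conformers, then to the least LID.
#'
#' @param record A `compound_record` whose conformers are prepared, or a
#'   list of prepared conformers.
#' @return List with `order` (indices into the ensemble, diverse-first),
#'   `lids` (the corresponding LIDs), and `scores` (per-step selection
#'   sums; `NA` for the seed).
#' @export
diverse_order <- function(record) {
  conformers <- if (inherits(record, "compound_record")) record$conformers
                else record
  n <- length(conformers)
  lids <- vapply(conformers, function(k) k$lid, numeric(1))
  energies <- vapply(conformers, function(k) k$energy, numeric(1))
  if (n == 1) {
    return(list(order = 1L, lids = lids, scores = NA_real_))
  }
  M <- pairwise_combo_matrix(conformers)
  out <- .diverse_order_from_matrix(M, lids, energies)
  out$lids <- lids[out$order]
  out
}

# greedy ordering given a precomputed combo matrix (separable for testing)
.diverse_order_from_matrix <- function(M, lids, energies = NULL) {
  n <- nrow(M)
  if (is.null(energies)) energies <- rep(NA_real_, n)
  seed <- if (all(is.na(energies))) {
    which.min(lids)
  } else {
    cand <- which(energies == min(energies, na.rm = TRUE))
    cand[which.min(lids[cand])]
  }
  selected <- seed
  remaining <- setdiff(seq_len(n), seed)
  scores <- NA_real_
  while (length(remaining)) {
    s <- vapply(remaining, function(k) sum(M[k, selected]), numeric(1))
    lo <- min(s)
    tied <- remaining[s <= lo + 1e-9]
    if (length(tied) > 1) {
      # largest sum of combo to all unassigned conformers
      u <- vapply(tied, function(k) {
        others <- setdiff(remaining, k)
        if (length(others)) sum(M[k, others]) else 0
      }, numeric(1))
      hi <- max(u)
      tied <- tied[u >= hi - 1e-9]
      if (length(tied) > 1) tied <- tied[which.min(lids[tied])]
    }
    pick <- tied[1]
    scores <- c(scores, sum(M[pick, selected]))
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  list(order = selected, scores = scores)
}
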