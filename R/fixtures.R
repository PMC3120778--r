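# Deterministic synthetic conformers and the brute-force neighbor oracle.
# Geometries are chemically plausible heavy-atom skeletons (1.5 angstrom
# C-C scale) with synthetic bond graphs sufficient for feature typing; no
# attempt is made at force-field-quality geometry.

.zigzag_chain <- function(n, step = 1.5, angle = 112 * pi / 180) {
  # planar zig-zag backbone in the xy plane
  X <- matrix(0, n, 3)
  if (n >= 2) {
    dirs <- c(angle / 2, -angle / 2)
    for (i in 2:n) {
      th <- dirs[(i %% 2) + 1]
      X[i, ] <- X[i - 1, ] + step * c(cos(th), sin(th), 0)
    }
  }
  X
}

.chain_bonds <- function(n, order = 1) {
  if (n < 2) return(NULL)
  cbind(seq_len(n - 1), 2:n, order)
}

#' Generate a deterministic toy conformer
#'
#' Templates:
#' \describe{
#'   \item{`rod`}{`n` collinear carbons, 1.5 angstrom spacing.}
#'   \item{`chain`}{`n`-carbon zig-zag alkane.}
#'   \item{`ring`}{planar aromatic `n`-ring (1.4 angstrom edges).}
#'   \item{`ring_tail`}{aromatic 6-ring with an `n`-carbon aliphatic tail.}
#'   \item{`branched`}{central carbon with four methyl-like arms extended to
#'     `n` atoms total.}
#'   \item{`donor_acceptor`}{hydroxy-aldehyde chain: HO-C-(C)n-C=O, one
#'     donor and two acceptors.}
#'   \item{`featureless`}{fluorinated chain: `n` backbone carbons each
#'     bearing one fluorine, so no hydrophobe cluster forms and the
#'     molecule carries no features at all.}
#' }
#'
#' @param template Template name.
#' @param n Size parameter (atoms in the backbone/ring; template-specific
#'   minimum).
#' @param jitter Gaussian coordinate jitter magnitude in angstrom (default
#'   0).
#' @param seed Seed for the jitter stream.
#' @param cid,lid Identity given to the conformer.
#' @return A `conformer` (not yet prepared).
#' @export
make_toy_conformer <- function(template = c("rod", "chain", "ring",
                                            "ring_tail", "branched",
                                            "donor_acceptor", "featureless"),
                               n = 6, jitter = 0, seed = 1, cid = 1,
                               lid = 0) {
  template <- match.arg(template)
  if (n < 1) stop("n must be >= 1")
  if (template == "rod") {
    conf <- conformer(rep("C", n), cbind(1.5 * (seq_len(n) - 1), 0, 0),
                      bonds = .chain_bonds(n), cid = cid, lid = lid)
  } else if (template == "chain") {
    conf <- conformer(rep("C", n), .zigzag_chain(n),
                      bonds = .chain_bonds(n), cid = cid, lid = lid)
  } else if (template == "ring") {
    if (n < 3) stop("ring needs n >= 3")
    R <- 1.4 / (2 * sin(pi / n))
    th <- 2 * pi * (seq_len(n) - 1) / n
    bonds <- rbind(.chain_bonds(n, order = 4), c(n, 1, 4))
    conf <- conformer(rep("C", n), cbind(R * cos(th), R * sin(th), 0),
                      bonds = bonds, cid = cid, lid = lid)
  } else if (template == "ring_tail") {
    ring <- make_toy_conformer("ring", 6)
    tail_n <- max(n, 2)
    zz <- .zigzag_chain(tail_n + 1)
    tail <- zz[-1, , drop = FALSE]
    # place the first tail atom 1.5 angstrom radially out from ring atom 1
    shift <- ring$coords[1, ] + c(1.5, 0, 0) - zz[2, ]
    tail <- sweep(tail, 2, -shift)
    elements <- c(ring$elements, rep("C", tail_n))
    bonds <- rbind(ring$bonds, c(1, 7, 1), .chain_bonds(tail_n)[, ] + c(6, 6, 0))
    conf <- conformer(elements, rbind(ring$coords, tail), bonds = bonds,
                      cid = cid, lid = lid)
  } else if (template == "branched") {
    if (n < 5) stop("branched needs n >= 5")
    arms <- matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1), 4, 3,
                   byrow = TRUE) / sqrt(3)
    X <- matrix(0, 1, 3)
    bonds <- NULL
    parent <- c(1, 1, 1, 1)
    arm_tip <- c(1, 1, 1, 1)
    k <- 1
    while (nrow(X) < n) {
      arm <- ((k - 1) %% 4) + 1
      tip <- arm_tip[arm]
      newpos <- X[tip, ] + 1.5 * arms[arm, ] * (1 + 0.12 * ((k - 1) %/% 4))
      X <- rbind(X, newpos)
      bonds <- rbind(bonds, c(tip, nrow(X), 1))
      arm_tip[arm] <- nrow(X)
      k <- k + 1
    }
    conf <- conformer(rep("C", nrow(X)), X, bonds = bonds, cid = cid,
                      lid = lid)
  } else if (template == "donor_acceptor") {
    m <- max(n, 3)  # backbone carbons
    back <- .zigzag_chain(m + 2)  # positions for O, C..., O
    elements <- c("O", rep("C", m), "O", "C")
    # methyl branch on the second backbone carbon breaks the end-to-end
    # shape symmetry so the ST optimum is unambiguous
    methyl <- back[3, ] + c(0, 0, 1.5)
    bonds <- rbind(.chain_bonds(m + 1), c(m + 1, m + 2, 2),
                   c(3, m + 3, 1))
    conf <- conformer(elements, rbind(back, methyl), bonds = bonds,
                      cid = cid, lid = lid)
  } else {  # featureless
    m <- max(n, 2)
    back <- .zigzag_chain(m)
    fl <- back + matrix(rep(c(0, 0, 1.35), each = m), m, 3)
    elements <- c(rep("C", m), rep("F", m))
    bonds <- rbind(.chain_bonds(m), cbind(seq_len(m), m + seq_len(m), 1))
    conf <- conformer(elements, rbind(back, fl), bonds = bonds, cid = cid,
                      lid = lid)
  }
  if (jitter > 0) conf <- perturb_conformer(conf, jitter, seed)
  conf
}

#' Add seeded Gaussian jitter to heavy-atom coordinates
#'
#' @param conf A `conformer`.
#' @param sigma Per-axis jitter standard deviation in angstrom (`sigma = 0`
#'   returns the input unchanged).
#' @param seed Seed for the jitter stream (same seed, same jitter).
#' @return The perturbed `conformer`.
#' @export
perturb_conformer <- function(conf, sigma, seed = 1) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(conf)
  noise <- with_seed(seed, matrix(rnorm(3 * nrow(conf$coords), sd = sigma),
                                  ncol = 3))
  conf$coords <- conf$coords + noise
  conf$prepared <- FALSE
  conf
}

# rotate the sub-tree beyond bond (a, b) about the a->b axis (torsion)
.apply_torsion <- function(conf, a, b, angle) {
  g <- .bond_lists(conf)
  n <- length(conf$elements)
  side <- rep(FALSE, n)
  side[b] <- TRUE
  queue <- b
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in g$nb[[u]]) {
      if (v == a || side[v]) next
      side[v] <- TRUE; queue <- c(queue, v)
    }
  }
  axis <- conf$coords[b, ] - conf$coords[a, ]
  axis <- axis / sqrt(sum(axis^2))
  q <- quat_from_rotvec(axis * angle)
  Rm <- quat_to_matrix(q)
  idx <- which(side & seq_len(n) != b)
  if (length(idx)) {
    rel <- sweep(conf$coords[idx, , drop = FALSE], 2, conf$coords[b, ])
    conf$coords[idx, ] <- sweep(rel %*% t(Rm), 2, -conf$coords[b, ])
  }
  conf
}

#' Generate a deterministic toy conformer ensemble
#'
#' Builds `n` conformers (LIDs `0..n-1`) of one compound by progressively
#' torsioning rotatable backbone bonds and jittering the base geometry, so
#' all conformers share a topology (hence feature counts) while spanning a
#' range of shapes.
#'
#' @param template Template name for [make_toy_conformer()].
#' @param size Template size parameter.
#' @param n Number of conformers.
#' @param cid Compound identifier.
#' @param seed Base seed; conformer `i` uses `seed + i`.
#' @param jitter Jitter magnitude applied to every conformer after the
#'   first (default 0.05 angstrom).
#' @param energies Optional energy vector (length `n`).
#' @return A `compound_record`.
#' @export
make_toy_ensemble <- function(template, size = 6, n = 3, cid = 1, seed = 1,
                              jitter = 0.05, energies = NULL) {
  stopifnot(n >= 1)
  base <- make_toy_conformer(template, size, cid = cid, lid = 0)
  confs <- vector("list", n)
  for (i in seq_len(n)) {
    k <- base
    k$lid <- i - 1
    if (i > 1) {
      rot <- if (!is.null(k$bonds)) {
        ok <- k$bonds[, 3] == 1 &
          !(k$elements[k$bonds[, 1]] == "F" | k$elements[k$bonds[, 2]] == "F")
        which(ok)
      } else integer(0)
      # interior single bonds only (torsion about terminal bonds is a no-op
      # for collinear rods but harmless)
      angles <- with_seed(seed + i, runif(length(rot), -pi / 3, pi / 3))
      step <- 0
      for (bidx in rot) {
        step <- step + 1
        if (step %% 2 == 0) next  # torsion alternate bonds only
        k <- .apply_torsion(k, k$bonds[bidx, 1], k$bonds[bidx, 2],
                            angles[step])
      }
      k <- perturb_conformer(k, jitter, seed = seed * 1000 + i)
    }
    if (!is.null(energies)) k$energy <- energies[i]
    confs[[i]] <- k
  }
  compound_record(cid, confs)
}

#' The standard fixture suite
#'
#' A deterministic set of small compound records spanning the feature
#' types: torsioned alkane chains (hydrophobes), an aromatic ring and a
#' ring-with-tail, a branched alkane, a donor/acceptor hydroxy-aldehyde
#' with a geometric near-duplicate under a different CID (guaranteeing
#' cross-compound neighbors), and a fluorinated featureless pair exercising
#' the featureless route.
#'
#' @param seed Base seed (default 1).
#' @return A list of `compound_record` objects (about 30 conformers).
#' @export
standard_fixture_suite <- function(seed = 1) {
  near_copy <- function(rec, cid, sigma, seedoff) {
    confs <- lapply(rec$conformers, function(k) {
      k2 <- perturb_conformer(k, sigma, seed = seedoff + k$lid)
      k2$cid <- cid
      k2
    })
    compound_record(cid, confs)
  }
  ch <- make_toy_ensemble("chain", 7, n = 4, cid = 101, seed = seed,
                          energies = c(0.2, 0.0, 0.7, 1.1))
  list(
    ch,
    near_copy(ch, 102, 0.08, seed + 500),
    make_toy_ensemble("ring", 6, n = 3, cid = 103, seed = seed + 1),
    make_toy_ensemble("ring_tail", 3, n = 4, cid = 104, seed = seed + 2),
    make_toy_ensemble("branched", 7, n = 3, cid = 105, seed = seed + 3),
    make_toy_ensemble("donor_acceptor", 3, n = 4, cid = 106,
                      seed = seed + 4),
    near_copy(make_toy_ensemble("donor_acceptor", 3, n = 4, cid = 107,
                                seed = seed + 4), 107, 0.08, seed + 600),
    make_toy_ensemble("featureless", 5, n = 3, cid = 108, seed = seed + 5),
    near_copy(make_toy_ensemble("featureless", 5, n = 3, cid = 109,
                                seed = seed + 5), 109, 0.08, seed + 700)
  )
}

#' Brute-force neighbor oracle
#'
#' Validation twin of [neighbor_search()]: no filters, no fingerprints.
#' Every conformer pair is shape-optimized from the dense 24-orientation
#' start set ([cube_rotation_starts()]) and thresholded with
#' [final_decision()].  Intended for desk-scale fixture suites only.
#'
#' @param query,search Lists of `compound_record` objects; the first
#'   `n_diverse_query` / `n_diverse_search` diverse conformers per compound
#'   are considered, as in the pipeline.
#' @param config A `search_config`.
#' @param max_optimized Optionally optimize only the best `max_optimized`
#'   starts after a single-point prescreen (default: optimize all 24).
#' @return A data.frame like the `pairs` element of [neighbor_search()]
#'   (without packed superpositions).
#' @export
brute_force_neighbor_oracle <- function(query, search,
                                        config = search_config(),
                                        max_optimized = Inf) {
  if (inherits(query, "compound_record")) query <- list(query)
  if (inherits(search, "compound_record")) search <- list(search)
  prep <- function(records, n) {
    lapply(records, function(r) {
      if (!is.null(r$kept)) r else prepare_compound(r, NULL, n)
    })
  }
  query <- prep(query, config$n_diverse_query)
  search <- prep(search, config$n_diverse_search)
  starts <- cube_rotation_starts()
  seen <- new.env(parent = emptyenv())
  rows <- list()
  for (qc in query) {
    for (sc in search) {
      for (A in qc$kept) {
        for (B in sc$kept) {
          ka <- conformer_id_hex(A); kb <- conformer_id_hex(B)
          key <- if (ka <= kb) paste(ka, kb) else paste(kb, ka)
          if (!is.null(seen[[key]])) next
          seen[[key]] <- TRUE
          opt <- optimize_shape_overlap(A, B, starts,
                                        max_optimized = max_optimized)
          st <- shape_tanimoto(A$self_volume, B$self_volume, opt$vab)
          ab <- color_overlap_volumes(A$features, B$features, opt$transform)
          ct <- color_tanimoto(A$self_color_volumes, B$self_color_volumes,
                               ab)
          flA <- .featureless(A); flB <- .featureless(B)
          if (final_decision(st, if (is.na(ct)) 0 else ct, flA, flB,
                             config)) {
            rows[[length(rows) + 1L]] <- data.frame(
              cidA = A$cid, lidA = A$lid, cidB = B$cid, lidB = B$lid,
              st = st, ct = ct, featureless = flA && flB,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else data.frame(
    cidA = numeric(0), lidA = numeric(0), cidB = numeric(0),
    lidB = numeric(0), st = numeric(0), ct = numeric(0),
    featureless = logical(0), stringsAsFactors = FALSE)
}
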