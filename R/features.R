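# Pharmacophore ("color") feature typing, proximity merging, and the color
# Tanimoto.  Typing is an explicit rule table over the molecular graph: it
# names the same six types the field's implicit force fields produce, but the
# rules here are this package's own, versioned definition (see the methods
# vignette); users can judge and substitute them via `feature_typing_rules()`.

#' The feature typing rule table
#'
#' Returns the rule set used by [assign_features()], as data: one row per
#' rule with the feature type and a human-readable description of the graph
#' pattern.  Exposed so the typing is transparent and auditable.
#'
#' @return A data.frame with columns `type` and `pattern`.
#' @export
feature_typing_rules <- function() {
  data.frame(
    type = c("anion", "anion", "cation", "cation", "donor", "acceptor",
             "acceptor", "hydrophobe", "ring"),
    pattern = c(
      "carboxylate/carboxylic acid: C with two terminal O, one double-bonded; parents = the two O",
      "sulfonate/phosphate: S or P with >= 2 terminal O; parents = the terminal O",
      "amidinium/guanidinium: C with >= 2 N neighbours, a C=N bond, no O neighbour; parents = the N",
      "aliphatic amine: non-aromatic N, all single bonds, not adjacent to a carbonyl C; parents = {N}",
      "N or O bearing >= 1 (explicit or valence-implied) hydrogen; parents = {atom}",
      "any O; parents = {O}",
      "N with no hydrogen, a free lone pair, and not amide N; parents = {N}",
      "connected cluster (>= 2 atoms) of non-aromatic C bonded only to C/H; parents = cluster",
      "each smallest ring (SSSR); parents = ring atoms"),
    stringsAsFactors = FALSE
  )
}

# ---- graph helpers ---------------------------------------------------------

.bond_lists <- function(conf) {
  n <- length(conf$elements)
  nb <- vector("list", n)
  ord <- vector("list", n)
  if (!is.null(conf$bonds) && nrow(conf$bonds) > 0) {
    for (k in seq_len(nrow(conf$bonds))) {
      a <- conf$bonds[k, 1]; b <- conf$bonds[k, 2]; o <- conf$bonds[k, 3]
      nb[[a]] <- c(nb[[a]], b); ord[[a]] <- c(ord[[a]], o)
      nb[[b]] <- c(nb[[b]], a); ord[[b]] <- c(ord[[b]], o)
    }
  }
  list(nb = nb, ord = ord)
}

.default_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1,
                      Br = 1, I = 1, B = 3, Si = 4)

# implicit + explicit hydrogen count per heavy atom (aromatic bonds count 1.5)
.h_counts <- function(conf, g) {
  n <- length(conf$elements)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (conf$is_h[i]) next
    nbrs <- g$nb[[i]]; ords <- g$ord[[i]]
    expl <- sum(conf$is_h[nbrs])
    heavy <- !conf$is_h[nbrs]
    bsum <- sum(ifelse(ords[heavy] == 4, 1.5, ords[heavy]))
    val <- .default_valence[conf$elements[i]]
    if (is.na(val)) val <- 0
    out[i] <- expl + max(0, floor(val - bsum - expl + 1e-9))
  }
  out
}

.is_aromatic <- function(conf, g) {
  vapply(seq_along(conf$elements),
         function(i) any(g$ord[[i]] == 4), logical(1))
}

# smallest rings: for every non-tree edge of a spanning forest, take the
# shortest cycle through that edge (shortest path in the graph minus the
# edge); deduplicated.  Standard SSSR approximation for small molecules.
.sssr <- function(conf, g) {
  n <- length(conf$elements)
  if (is.null(conf$bonds) || nrow(conf$bonds) == 0) return(list())
  edges <- conf$bonds[, 1:2, drop = FALSE]
  # spanning forest via BFS
  intree <- rep(FALSE, nrow(edges))
  visited <- rep(FALSE, n)
  for (root in seq_len(n)) {
    if (visited[root]) next
    visited[root] <- TRUE
    queue <- root
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (k in seq_len(nrow(edges))) {
        if (intree[k]) next
        v <- if (edges[k, 1] == u) edges[k, 2]
             else if (edges[k, 2] == u) edges[k, 1] else next
        if (!visited[v]) {
          visited[v] <- TRUE; intree[k] <- TRUE; queue <- c(queue, v)
        }
      }
    }
  }
  rings <- list()
  for (k in which(!intree)) {
    u <- edges[k, 1]; v <- edges[k, 2]
    path <- .shortest_path(g, u, v, skip_edge = k, edges = edges)
    if (is.null(path)) next
    ring <- sort(path)
    key <- paste(ring, collapse = ",")
    if (!key %in% names(rings)) rings[[key]] <- path
  }
  unname(rings)
}

.shortest_path <- function(g, from, to, skip_edge, edges) {
  n <- length(g$nb)
  prev <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  visited[from] <- TRUE
  queue <- from
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    if (u == to) break
    for (idx in seq_along(g$nb[[u]])) {
      v <- g$nb[[u]][idx]
      if ((u == edges[skip_edge, 1] && v == edges[skip_edge, 2]) ||
          (u == edges[skip_edge, 2] && v == edges[skip_edge, 1])) next
      if (!visited[v]) {
        visited[v] <- TRUE; prev[v] <- u; queue <- c(queue, v)
      }
    }
  }
  if (!visited[to]) return(NULL)
  path <- to
  while (path[1] != from) path <- c(prev[path[1]], path)
  path
}

# ---- feature assignment ----------------------------------------------------

new_feature_set <- function(types, positions, parents, atom_coords) {
  structure(list(types = types, positions = positions, parents = parents,
                 atom_coords = atom_coords), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  if (length(x$types) == 0) cat("<feature_set: featureless>\n")
  else cat("<feature_set:", paste(sprintf("%s x%d", names(feature_counts(x)),
           feature_counts(x))[feature_counts(x) > 0], collapse = ", "), ">\n")
  invisible(x)
}

#' Per-type feature counts of a feature set
#' @param fs A `feature_set`.
#' @return Named integer vector over the six feature types.
#' @export
feature_counts <- function(fs) {
  cnt <- integer(length(FEATURE_TYPES))
  names(cnt) <- FEATURE_TYPES
  tb <- table(fs$types)
  cnt[names(tb)] <- as.integer(tb)
  cnt
}

.steric_center <- function(coords, idx) colMeans(coords[idx, , drop = FALSE])

#' Assign pharmacophore feature atoms to a conformer
#'
#' Applies the rule table of [feature_typing_rules()] to the molecular graph
#' and places one fictitious feature atom per match at the steric center
#' (unweighted mean) of its parent real atoms.  Molecules may legitimately
#' yield no features ("featureless").  Counts depend only on topology, so
#' they agree across conformers of a compound; positions follow geometry.
#'
#' @param conf A `conformer` with a bond graph.
#' @return A `feature_set` (not yet proximity-merged; see
#'   [merge_proximate_features()]).
#' @export
assign_features <- function(conf) {
  n <- length(conf$elements)
  g <- .bond_lists(conf)
  el <- conf$elements
  arom <- .is_aromatic(conf, g)
  hc <- .h_counts(conf, g)
  heavy_nb <- function(i) g$nb[[i]][!conf$is_h[g$nb[[i]]]]
  heavy_ord <- function(i) g$ord[[i]][!conf$is_h[g$nb[[i]]]]
  types <- character(0); parents <- list()
  add <- function(type, par) {
    types[[length(types) + 1L]] <<- type
    parents[[length(parents) + 1L]] <<- sort(unique(par))
  }
  is_terminal_o <- function(i) el[i] == "O" && length(heavy_nb(i)) == 1
  is_carbonyl_c <- function(i) {
    el[i] == "C" && any(el[heavy_nb(i)] == "O" & heavy_ord(i) == 2)
  }
  anion_parents <- integer(0)
  for (i in seq_len(n)) {
    if (conf$is_h[i]) next
    nb <- heavy_nb(i); od <- heavy_ord(i)
    if (el[i] == "C") {
      os <- nb[el[nb] == "O" & vapply(nb, is_terminal_o, logical(1))]
      if (length(os) == 2 && any(od[match(os, nb)] == 2)) {
        add("anion", os); anion_parents <- c(anion_parents, os)
      }
    }
    if (el[i] %in% c("S", "P")) {
      os <- nb[el[nb] == "O" & vapply(nb, is_terminal_o, logical(1))]
      if (length(os) >= 2) {
        add("anion", os); anion_parents <- c(anion_parents, os)
      }
    }
  }
  cation_n <- integer(0)
  for (i in seq_len(n)) {
    if (conf$is_h[i] || el[i] != "C") next
    nb <- heavy_nb(i); od <- heavy_ord(i)
    ns <- nb[el[nb] == "N"]
    if (length(ns) >= 2 && any(od[el[nb] == "N"] == 2) &&
        !any(el[nb] == "O")) {
      add("cation", c(i, ns)); cation_n <- c(cation_n, ns)
    }
  }
  for (i in seq_len(n)) {
    if (conf$is_h[i]) next
    nb <- heavy_nb(i); od <- heavy_ord(i)
    if (el[i] == "N" && !(i %in% cation_n)) {
      amide <- any(vapply(nb, is_carbonyl_c, logical(1)))
      if (!arom[i] && length(od) > 0 && all(od == 1) && !amide) {
        add("cation", i)
      }
      lone_pair <- sum(ifelse(od == 4, 1.5, od)) + hc[i] <= 3 + 1e-9
      if (hc[i] >= 1) add("donor", i)
      else if (lone_pair && !amide && !arom[i]) add("acceptor", i)
      else if (arom[i] && hc[i] == 0) add("acceptor", i)
    }
    if (el[i] == "O") {
      if (hc[i] >= 1) add("donor", i)
      add("acceptor", i)
    }
  }
  # hydrophobes: clusters of aliphatic carbons (only C/H neighbours, no
  # aromatic bond), connected components of size >= 2
  aliph <- which(!conf$is_h & el == "C" & !arom &
                 vapply(seq_len(n), function(i) {
                   nb <- heavy_nb(i)
                   length(nb) == 0 || all(el[nb] == "C")
                 }, logical(1)))
  seen <- logical(n)
  for (s in aliph) {
    if (seen[s]) next
    comp <- s; queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in heavy_nb(u)) {
        if (v %in% aliph && !seen[v]) {
          seen[v] <- TRUE; comp <- c(comp, v); queue <- c(queue, v)
        }
      }
    }
    if (length(comp) >= 2) add("hydrophobe", comp)
  }
  for (ring in .sssr(conf, g)) add("ring", ring)
  pos <- if (length(types)) {
    do.call(rbind, lapply(parents, function(p) .steric_center(conf$coords, p)))
  } else matrix(numeric(0), ncol = 3)
  new_feature_set(types, pos, parents, conf$coords)
}

#' Merge proximate same-type features
#'
#' Iteratively replaces any pair of same-type features closer than 1.0
#' angstrom by a single feature whose parents are the union and whose
#' position is the steric center of the union, until no pair qualifies.
#' Pairs are visited in order of increasing distance, ties broken by lowest
#' parent-atom index, so the fixed point is deterministic.
#'
#' @param fs A `feature_set`.
#' @return The merged `feature_set` (idempotent).
#' @export
merge_proximate_features <- function(fs) {
  repeat {
    m <- length(fs$types)
    if (m < 2) return(fs)
    best <- NULL; bestkey <- c(Inf, Inf)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (fs$types[i] != fs$types[j]) next
        d <- sqrt(sum((fs$positions[i, ] - fs$positions[j, ])^2))
        if (d >= FEATURE_MERGE_DIST) next
        key <- c(d, min(fs$parents[[i]], fs$parents[[j]]))
        if (key[1] < bestkey[1] - 1e-12 ||
            (abs(key[1] - bestkey[1]) <= 1e-12 && key[2] < bestkey[2])) {
          bestkey <- key; best <- c(i, j)
        }
      }
    }
    if (is.null(best)) return(fs)
    i <- best[1]; j <- best[2]
    par <- sort(unique(c(fs$parents[[i]], fs$parents[[j]])))
    fs$parents[[i]] <- par
    fs$positions[i, ] <- .steric_center(fs$atom_coords, par)
    fs$types <- fs$types[-j]
    fs$parents[j] <- NULL
    fs$positions <- fs$positions[-j, , drop = FALSE]
  }
}

topological_feature_counts <- function(conf) {
  feature_counts(assign_features(conf))
}

# ---- color overlap and Tanimoto -------------------------------------------

feature_self_volumes <- function(fs, radius = FEATURE_RADIUS) {
  alpha <- gaussian_exponent(radius)
  out <- numeric(length(FEATURE_TYPES))
  names(out) <- FEATURE_TYPES
  for (tp in FEATURE_TYPES) {
    P <- fs$positions[fs$types == tp, , drop = FALSE]
    if (nrow(P) == 0) next
    a <- rep(alpha, nrow(P))
    out[tp] <- cpp_overlap(P, a, P, a, GAUSS_P^2, exp_lut())
  }
  out
}

#' Per-type color overlap volumes between two feature sets
#'
#' Gaussian pairwise overlap of same-type feature atoms only (cross-type
#' overlap is never counted), with B's features carried through `transform`.
#'
#' @param fsA,fsB `feature_set` objects.
#' @param transform `rigid_transform` mapping B's frame into A's.
#' @param radius Feature atom radius: 1.08265 for scoring, 1.25 for the
#'   stage-2 estimate.
#' @return Named numeric vector of overlap volumes over the six types.
#' @export
color_overlap_volumes <- function(fsA, fsB, transform = rt_identity(),
                                  radius = FEATURE_RADIUS) {
  alpha <- gaussian_exponent(radius)
  out <- numeric(length(FEATURE_TYPES))
  names(out) <- FEATURE_TYPES
  for (tp in FEATURE_TYPES) {
    PA <- fsA$positions[fsA$types == tp, , drop = FALSE]
    PB <- fsB$positions[fsB$types == tp, , drop = FALSE]
    if (nrow(PA) == 0 || nrow(PB) == 0) next
    out[tp] <- cpp_overlap_transformed(PA, rep(alpha, nrow(PA)),
                                       PB, rep(alpha, nrow(PB)),
                                       GAUSS_P^2, exp_lut(),
                                       transform$q, transform$t)
  }
  out
}

#' Color Tanimoto from per-type overlap volumes
#'
#' `CT = sum_t AB_t / (sum_t A_t + sum_t B_t - sum_t AB_t)` over the six
#' feature types.  If both molecules are featureless the CT is undefined and
#' reported as `NA` (the "featureless" marker, handled separately by the
#' neighboring rules); a featured-vs-featureless pair scores 0.
#'
#' @param selfA,selfB Per-type self color volumes.
#' @param ab Per-type cross overlap volumes.
#' @return The color Tanimoto in `[0, 1]`, or `NA` if both sets are
#'   featureless.
#' @export
color_tanimoto <- function(selfA, selfB, ab) {
  sa <- sum(selfA); sb <- sum(selfB); sab <- sum(ab)
  if (sa == 0 && sb == 0) return(NA_real_)
  if (sa == 0 || sb == 0) return(0)
  den <- sa + sb - sab
  if (den <= 0) stop("invalid color overlap: AB >= A + B")
  sab / den
}
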