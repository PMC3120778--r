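# Feature typing rules, proximity merging, color overlap and color Tanimoto.

test_that("benzene-like ring yields exactly one ring feature at the centroid", {
  r <- make_toy_conformer("ring", 6)
  fs <- merge_proximate_features(assign_features(r))
  cnt <- feature_counts(fs)
  expect_equal(unname(cnt["ring"]), 1L)
  expect_equal(sum(cnt), 1L)  # no donors/acceptors/ions/hydrophobes
  expect_equal(unname(fs$positions[1, ]), unname(colMeans(r$coords)),
               tolerance = 1e-9)
  expect_setequal(fs$parents[[1]], 1:6)
})

test_that("a single carbon is featureless", {
  m <- make_toy_conformer("rod", 1)
  fs <- assign_features(m)
  expect_length(fs$types, 0)
})

test_that("acetate carries an anion feature at the carboxyl oxygens' steric center", {
  ac <- acetate_fixture()
  fs <- merge_proximate_features(assign_features(ac))
  cnt <- feature_counts(fs)
  expect_equal(unname(cnt["anion"]), 1L)
  expect_gte(unname(cnt["acceptor"]), 1L)
  anion_pos <- fs$positions[fs$types == "anion", ]
  expect_equal(unname(anion_pos), unname(colMeans(ac$coords[3:4, ])),
               tolerance = 1e-9)
})

test_that("feature counts are topological: identical across ensemble conformers", {
  for (tpl in c("chain", "ring_tail", "donor_acceptor", "featureless")) {
    rec <- make_toy_ensemble(tpl, 5, n = 4, cid = 3, seed = 8)
    counts <- lapply(rec$conformers, function(k) {
      feature_counts(assign_features(k))
    })
    for (j in 2:4) expect_equal(counts[[j]], counts[[1]])
    expect_equal(rec$feature_counts, counts[[1]])
  }
})

test_that("proximate same-type features merge; distant ones do not", {
  coords <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(5, 0, 0))
  mk <- function(i, j) p3dnbr:::new_feature_set(
    c("donor", "donor"), coords[c(i, j), , drop = FALSE],
    list(i, j), coords)
  close_fs <- merge_proximate_features(mk(1, 2))
  expect_length(close_fs$types, 1)
  expect_equal(unname(close_fs$positions[1, ]), c(0.25, 0, 0))
  expect_equal(close_fs$parents[[1]], c(1L, 2L))
  far_fs <- merge_proximate_features(mk(1, 3))
  expect_length(far_fs$types, 2)
  # mixed types never merge even when coincident
  mixed <- p3dnbr:::new_feature_set(
    c("donor", "acceptor"), coords[c(1, 1), , drop = FALSE],
    list(1L, 1L), coords)
  expect_length(merge_proximate_features(mixed)$types, 2)
})

test_that("merging converges deterministically and is idempotent", {
  # chain of three at 0.8 spacing: the closest tied pair with the lowest
  # parent index merges first (1, 2), after which the merged feature at 0.4
  # sits 1.2 from the third -- the fixed point keeps two features
  coords <- rbind(c(0, 0, 0), c(0.8, 0, 0), c(1.6, 0, 0))
  fs <- p3dnbr:::new_feature_set(rep("acceptor", 3), coords,
                                 list(1L, 2L, 3L), coords)
  merged <- merge_proximate_features(fs)
  expect_length(merged$types, 2)
  canon <- function(m) {
    keys <- vapply(seq_along(m$types), function(i) {
      paste(m$types[i], paste(sort(m$parents[[i]]), collapse = "+"),
            paste(round(m$positions[i, ], 9), collapse = ","))
    }, character(1))
    sort(keys)
  }
  expect_true(any(vapply(merged$parents, function(p) {
    identical(sort(p), c(1L, 2L))
  }, logical(1))))
  # idempotent
  expect_equal(canon(merge_proximate_features(merged)), canon(merged))
  # permuted input order reaches the same fixed point
  perm <- p3dnbr:::new_feature_set(rep("acceptor", 3), coords[c(3, 1, 2), ],
                                   list(3L, 1L, 2L), coords)
  expect_equal(canon(merge_proximate_features(perm)), canon(merged))
  # a genuinely collapsing chain: 0.6 spacing merges to one feature
  coords2 <- rbind(c(0, 0, 0), c(0.6, 0, 0), c(1.2, 0, 0))
  fs2 <- p3dnbr:::new_feature_set(rep("donor", 3), coords2,
                                  list(1L, 2L, 3L), coords2)
  merged2 <- merge_proximate_features(fs2)
  expect_length(merged2$types, 1)
  expect_equal(unname(merged2$positions[1, ]), c(0.6, 0, 0))
})

test_that("color overlap counts same-type pairs only", {
  coords <- matrix(0, 1, 3)
  donorA <- p3dnbr:::new_feature_set("donor", coords, list(1L), coords)
  donorB <- p3dnbr:::new_feature_set("donor", coords, list(1L), coords)
  acceptorB <- p3dnbr:::new_feature_set("acceptor", coords, list(1L), coords)
  af <- gaussian_exponent(1.08265)
  single_self <- 2.7^2 * (pi / (2 * af))^1.5
  ab <- color_overlap_volumes(donorA, donorB)
  expect_equal(unname(ab["donor"]), single_self, tolerance = 1e-6)
  expect_equal(sum(ab) - ab["donor"], c(donor = 0))
  expect_true(all(color_overlap_volumes(donorA, acceptorB) == 0))
})

test_that("two-feature color overlap matches quadrature", {
  coords <- rbind(c(0, 0, 0), c(1.2, 0.3, 0))
  fsA <- p3dnbr:::new_feature_set(c("ring", "ring"), coords,
                                  list(1L, 2L), coords)
  coordsB <- coords + 0.4
  fsB <- p3dnbr:::new_feature_set(c("ring", "ring"), coordsB,
                                  list(1L, 2L), coordsB)
  got <- sum(color_overlap_volumes(fsA, fsB))
  want <- quadrature_overlap(coords, rep(1.08265, 2), coordsB,
                             rep(1.08265, 2), h = 0.1, pad = 3)
  expect_equal(got, want, tolerance = 0.005)
})

test_that("color Tanimoto arithmetic, featureless marker, and symmetry", {
  a <- c(10, 0, 0, 0, 0, 0)
  expect_equal(color_tanimoto(a, a, c(5, 0, 0, 0, 0, 0)), 1 / 3)
  expect_equal(color_tanimoto(a, a, a), 1)
  # disjoint types: zero overlap
  b <- c(0, 10, 0, 0, 0, 0)
  expect_equal(color_tanimoto(a, b, rep(0, 6)), 0)
  # featureless-vs-featureless is undefined (marker), featured-vs-featureless is 0
  z <- rep(0, 6)
  expect_true(is.na(color_tanimoto(z, z, z)))
  expect_equal(color_tanimoto(a, z, z), 0)
  expect_error(color_tanimoto(a, a, c(25, 0, 0, 0, 0, 0)), "invalid")
})
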