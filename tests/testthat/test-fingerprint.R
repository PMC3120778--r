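# Volume regions, reference-library leader clustering, fingerprints with
# retained alignments, and alignment recycling.

test_that("volume regions follow the seven-band design", {
  rt <- region_table()
  expect_equal(nrow(rt), 7)
  expect_equal(rt$st_thresh, seq(0.75, 0.45, by = -0.05))
  expect_equal(region_for_volume(100)$st_thresh, 0.75)
  expect_equal(region_for_volume(300)$st_thresh, 0.55)
  # integer-labeled contiguous bands: 165.5 falls in the second band
  expect_equal(region_for_volume(165.5)$index, 2)
  expect_equal(region_for_volume(165)$index, 1)
  # below-range volumes clamp into the first band; above-range rejected
  expect_equal(region_for_volume(0.2)$index, 1)
  expect_error(region_for_volume(1500), "exceeds")
})

test_that("leader clustering admits one reference per distinct shape", {
  k <- prepare_conformer(make_toy_conformer("chain", 6, cid = 1))
  lib1 <- build_reference_library(list(k))
  expect_length(lib1$references, 1)
  # N exact copies collapse onto one reference
  copies <- lapply(1:4, function(i) {
    prepare_conformer(make_toy_conformer("chain", 6, cid = i))
  })
  libN <- build_reference_library(copies)
  expect_length(libN$references, 1)
})

test_that("dissimilar shapes each become references, independent of stream order", {
  shapes <- list(
    prepare_conformer(make_toy_conformer("rod", 6, cid = 1)),
    prepare_conformer(make_toy_conformer("ring_tail", 2, cid = 2)),
    prepare_conformer(make_toy_conformer("branched", 8, cid = 3)))
  lib_fwd <- build_reference_library(shapes)
  lib_rev <- build_reference_library(rev(shapes))
  expect_equal(length(lib_fwd$references), length(lib_rev$references))
  # mutual dissimilarity invariant: optimized ST between same-region
  # references stays below the region threshold
  refs <- lib_fwd$references
  if (length(refs) > 1) {
    for (i in seq_len(length(refs) - 1)) {
      for (j in (i + 1):length(refs)) {
        if (refs[[i]]$region != refs[[j]]$region) next
        opt <- p3dnbr:::.optimize_overlap_xyz(
          refs[[i]]$coords, refs[[i]]$alpha,
          refs[[j]]$coords, refs[[j]]$alpha, default_starts())
        st <- shape_tanimoto(refs[[i]]$volume, refs[[j]]$volume, opt$vab)
        expect_lt(st, refs[[i]]$st_thresh)
      }
    }
  }
})

test_that("a conformer identical to a reference sets that bit with ST near 1", {
  k <- prepare_conformer(make_toy_conformer("ring_tail", 3, cid = 21))
  lib <- build_reference_library(list(k))
  fp <- compute_fingerprint(k, lib)
  expect_true("1" %in% names(fp$bits))
  tr <- decode_superposition(fp$bits[["1"]])
  vab <- pairwise_overlap_volume(k, k, tr)
  expect_equal(shape_tanimoto(k$self_volume, k$self_volume, vab), 1,
               tolerance = 0.02)
})

test_that("the volume prefilter alone prunes grossly mismatched volumes", {
  # needed overlap at threshold .45 for (100, 600) exceeds 1.5 * min
  expect_false(p3dnbr:::.volume_prefilter_pass(600, 100, 0.45))
  expect_false(p3dnbr:::.volume_prefilter_pass(100, 600, 0.45))
  # equal volumes always pass
  expect_true(p3dnbr:::.volume_prefilter_pass(300, 300, 0.55))
})

test_that("prefiltered fingerprints equal the brute-force pass", {
  confs <- lapply(seq_along(tpl <- c("rod", "chain", "ring_tail", "branched",
                                     "donor_acceptor")), function(i) {
    prepare_conformer(make_toy_conformer(tpl[i], 5 + i %% 3, cid = 30 + i))
  })
  lib <- build_reference_library(confs)
  for (k in confs) {
    with_pf <- compute_fingerprint(k, lib, prefilter = TRUE)
    no_pf <- compute_fingerprint(k, lib, prefilter = FALSE)
    expect_setequal(names(with_pf$bits), names(no_pf$bits))
  }
})

test_that("recycled transforms reproduce synthetically composed alignments", {
  set.seed(17)
  for (rep in 1:10) {
    ta <- random_transform(); tb <- random_transform()
    fpA <- structure(list(owner = "a", bits = list(`7` = encode_superposition(ta))),
                     class = "shape_fingerprint")
    fpB <- structure(list(owner = "b", bits = list(`7` = encode_superposition(tb))),
                     class = "shape_fingerprint")
    got <- recycled_transform(fpA, fpB, 7)
    want <- rt_compose(rt_invert(ta), tb)
    expect_lt(quat_angle_deg(got$q, want$q), 2.5)
    expect_lt(max(abs(got$t - want$t)), 0.05)
  }
  fpA <- structure(list(owner = "a", bits = list()), class = "shape_fingerprint")
  expect_error(recycled_transform(fpA, fpA, 7), "not set")
})

test_that("same-conformer fingerprints recycle to the identity", {
  k <- prepare_conformer(make_toy_conformer("branched", 7, cid = 41))
  lib <- build_reference_library(list(k))
  fp <- compute_fingerprint(k, lib)
  tr <- recycled_transform(fp, fp, names(fp$bits)[1])
  expect_lt(quat_angle_deg(tr$q, c(1, 0, 0, 0)), 1.5)
  expect_lt(max(abs(tr$t)), 0.05)
})

test_that("recycled ST on a near-duplicate pair approaches the optimized ST", {
  a <- prepare_conformer(make_toy_conformer("ring_tail", 3, cid = 51))
  b0 <- perturb_conformer(make_toy_conformer("ring_tail", 3, cid = 52), 0.1,
                          seed = 3)
  b <- prepare_conformer(b0)
  lib <- build_reference_library(list(a))
  fpA <- compute_fingerprint(a, lib)
  fpB <- compute_fingerprint(b, lib)
  common <- intersect(names(fpA$bits), names(fpB$bits))
  expect_gte(length(common), 1)
  tr <- recycled_transform(fpA, fpB, common[1])
  st_rec <- shape_tanimoto(a$self_volume, b$self_volume,
                           pairwise_overlap_volume(a, b, tr))
  opt <- optimize_shape_overlap(a, b)
  st_opt <- shape_tanimoto(a$self_volume, b$self_volume, opt$vab)
  expect_gte(st_rec, 0.9 * st_opt)
})

test_that("fingerprints are sparse relative to a multi-region library", {
  confs <- list(
    prepare_conformer(make_toy_conformer("rod", 3, cid = 61)),
    prepare_conformer(make_toy_conformer("chain", 6, cid = 62)),
    prepare_conformer(make_toy_conformer("ring_tail", 4, cid = 63)),
    prepare_conformer(make_toy_conformer("branched", 10, cid = 64)),
    prepare_conformer(make_toy_conformer("branched", 14, cid = 65)))
  lib <- build_reference_library(confs)
  regions <- vapply(lib$references, `[[`, numeric(1), "region")
  expect_gte(length(unique(regions)), 3)
  nbits <- vapply(confs, function(k) {
    length(compute_fingerprint(k, lib)$bits)
  }, numeric(1))
  expect_lt(mean(nbits), length(lib$references))
  expect_true(all(nbits >= 1))  # every conformer matches at least its leader
})
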