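# Conformer identity packing, coordinate quantization, SDF and binary I/O.

test_that("conformer ID packing places CID in the high 32 bits and LID in the low 16", {
  expect_equal(uint64_hex(make_conformer_id(0, 0)), "0000000000000000")
  expect_equal(uint64_hex(make_conformer_id(1, 0)), "0000000100000000")
  id <- make_conformer_id(2244, 3)
  expect_equal(id$hi, 2244)
  expect_equal(id$lo, 3)
  expect_equal(uint64_hex(id), "000008c400000003")
  expect_error(make_conformer_id(-1, 0), "cid")
  expect_error(make_conformer_id(2^32, 0), "cid")
  expect_error(make_conformer_id(0, 2^16), "lid")
  # middle bits must be zero on parse
  expect_error(parse_conformer_id(p3dnbr:::new_uint64(1, 2^16)), "zero")
})

test_that("conformer ID packing is a bijection over random (cid, lid) pairs", {
  withr_seed <- 42
  set.seed(withr_seed)
  cids <- floor(runif(10000, 0, 2^32))
  lids <- floor(runif(10000, 0, 2^16))
  for (k in seq_along(cids)) {
    got <- parse_conformer_id(make_conformer_id(cids[k], lids[k]))
    if (got$cid != cids[k] || got$lid != lids[k]) {
      fail(sprintf("round trip failed at cid=%.0f lid=%.0f", cids[k], lids[k]))
    }
  }
  succeed()
  # hex round trip too
  id <- make_conformer_id(cids[1], lids[1])
  expect_true(uint64_from_hex(uint64_hex(id)) == id)
})

test_that("coordinate quantization has step 100/2^16 and half-step error", {
  step <- 100 / 2^16
  expect_equal(quantize_coordinate(0), 0)
  expect_equal(dequantize_coordinate(quantize_coordinate(0)), 0)
  # boundary: 49.999 maps to the max level, error at most half a step
  lvl <- quantize_coordinate(49.999)
  expect_equal(lvl, 32767)
  expect_lt(abs(dequantize_coordinate(lvl) - 49.999), step / 2 + 1e-12)
  expect_error(quantize_coordinate(50), "outside")
  expect_error(quantize_coordinate(-50.2), "outside")
  set.seed(7)
  x <- runif(1e5, -50 + 1e-9, 50 - 1e-9)
  err <- abs(dequantize_coordinate(quantize_coordinate(x)) - x)
  expect_lt(max(err), step / 2 + 1e-12)
  expect_gt(max(err), 0.49 * step)  # the sweep reaches the worst case
})

test_that("SDF write/read round-trips elements, coordinates, and grouping", {
  path <- tempfile(fileext = ".sdf")
  suite <- standard_fixture_suite(seed = 1)[c(1, 3, 6)]
  write_sdf(suite, path)
  back <- read_sdf(path)
  expect_length(back, 3)
  for (i in seq_along(suite)) {
    expect_equal(back[[i]]$cid, suite[[i]]$cid)
    expect_length(back[[i]]$conformers, length(suite[[i]]$conformers))
    for (j in seq_along(suite[[i]]$conformers)) {
      a <- suite[[i]]$conformers[[j]]
      b <- back[[i]]$conformers[[j]]
      expect_equal(b$lid, a$lid)
      expect_equal(b$elements, a$elements)
      expect_lt(max(abs(b$coords - a$coords)), 1e-4 + 1e-9)
    }
  }
})

test_that("SDF records sharing a CID group into one compound record", {
  path <- tempfile(fileext = ".sdf")
  c0 <- make_toy_conformer("ring", 6, cid = 77, lid = 0)
  c1 <- make_toy_conformer("ring", 6, cid = 77, lid = 1)
  write_sdf(list(compound_record(77, list(c0, c1))), path)
  back <- read_sdf(path)
  expect_length(back, 1)
  expect_length(back[[1]]$conformers, 2)
  expect_equal(sum(!back[[1]]$conformers[[1]]$is_h), 6)
  # one $$$$ delimiter per conformer record
  expect_equal(sum(readLines(path) == "$$$$"), 2)
})

test_that("writing an empty record list yields a valid empty file", {
  path <- tempfile(fileext = ".sdf")
  write_sdf(list(), path)
  expect_true(file.exists(path))
  expect_length(readLines(path), 0)
})

test_that("binary set round-trip preserves identity, elements, and quantized coordinates", {
  path <- tempfile(fileext = ".bin")
  write_binary_set(list(), path)
  expect_equal(file.size(path), 16)  # magic + count only

  rec <- make_toy_ensemble("donor_acceptor", 4, n = 2, cid = 55, seed = 3)
  write_binary_set(list(rec), path)
  back <- read_binary_set(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$cid, 55)
  prepped <- lapply(rec$conformers, prepare_conformer)
  step <- 100 / 2^16
  for (j in 1:2) {
    a <- prepped[[j]]; b <- back[[1]]$conformers[[j]]
    expect_equal(b$elements[!b$is_h], a$elements[!a$is_h])
    expect_lt(max(abs(b$coords - a$coords[!a$is_h, ])), step / 2 + 1e-12)
    expect_equal(b$self_volume, a$self_volume, tolerance = 1e-6)
    expect_equal(unname(b$self_color_volumes), unname(a$self_color_volumes),
                 tolerance = 1e-6)
  }
  # 64-bit alignment: file size exactly predictable from atom/feature counts
  n_atoms <- vapply(prepped, function(k) sum(!k$is_h), numeric(1))
  n_feat <- vapply(prepped, function(k) length(k$features$types), numeric(1))
  expect_equal(file.size(path), 16 + sum(48 + 8 * n_atoms + 8 * n_feat))
})

test_that("binary round-trip leaves recomputed self volumes within 0.1 percent", {
  path <- tempfile(fileext = ".bin")
  set.seed(11)
  confs <- lapply(1:100, function(k) {
    tpl <- c("chain", "ring_tail", "branched", "donor_acceptor")[(k %% 4) + 1]
    prepare_conformer(make_toy_conformer(tpl, 4 + (k %% 4), jitter = 0.2,
                                         seed = k, cid = k, lid = 0))
  })
  recs <- lapply(confs, function(k) compound_record(k$cid, list(k)))
  write_binary_set(recs, path)
  back <- read_binary_set(path)
  expect_length(back, 100)
  for (r in back) {
    k <- r$conformers[[1]]
    recomputed <- self_overlap_volume(conformer(k$elements, k$coords))
    expect_lt(abs(recomputed - k$self_volume) / k$self_volume, 0.001)
  }
})

test_that("bad magic is rejected", {
  path <- tempfile()
  writeBin(charToRaw("NOTMAGIC"), path)
  expect_error(read_binary_set(path), "magic")
})
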