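# Compact binary conformer-set format ("P3DNBR01" dialect).
#
# Little-endian, 64-bit aligned.  Header: 8-byte magic "P3DNBR01", then a
# uint64 record count.  Per record:
#   packed conformer ID        8 bytes (uint64: CID << 32 | LID)
#   non-hydrogen atom count n  2 bytes (uint16)
#   feature count f            2 bytes (uint16)
#   flags                      2 bytes (bit 0: degenerate frame)
#   pad                        2 bytes (zero)
#   self shape volume          4 bytes (float32)
#   per-type self color volumes 6 x 4 bytes (float32)
#   4 bytes pad (to realign to 8)
#   n atom entries: element number (1B) + 3 x int16 quantized coords (6B)
#     + 1B pad = 8 bytes each
#   f feature entries: type index (1B) + 3 x int16 quantized coords (6B)
#     + parent count (1B) = 8 bytes each
#
# Conformers must be canonicalized (steric center at the origin) so the
# quantized (-50, +50) angstrom range always suffices.  The format stores
# the derived feature atoms, not the bond graph: read-back conformers carry
# their stored features and cached volumes.

BINARY_MAGIC <- "P3DNBR01"

.write_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2,
                                        endian = "little")
.write_i16 <- function(con, x) writeBin(as.integer(x), con, size = 2,
                                        endian = "little")
.write_u32 <- function(con, x) {
  # value < 2^32 held in a double; emit as two uint16 limbs
  .write_u16(con, x %% 65536)
  .write_u16(con, x %/% 65536)
}
.write_u64 <- function(con, u) {
  .write_u32(con, u$lo)
  .write_u32(con, u$hi)
}
.read_u16 <- function(con) readBin(con, "integer", size = 2, signed = FALSE,
                                   endian = "little")
.read_i16 <- function(con, n = 1) readBin(con, "integer", n = n, size = 2,
                                          signed = TRUE, endian = "little")
.read_u32 <- function(con) {
  lo <- .read_u16(con); hi <- .read_u16(con)
  lo + hi * 65536
}
.read_u64 <- function(con) {
  lo <- .read_u32(con); hi <- .read_u32(con)
  new_uint64(hi, lo)
}

#' Write compound records to the compact binary set format
#'
#' Conformers are prepared (canonicalized, features assigned, volumes
#' cached) if they are not already; coordinates are quantized to the signed
#' 16-bit (-50, +50) angstrom lattice.
#'
#' @param records List of `compound_record` objects.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_binary_set <- function(records, path) {
  if (inherits(records, "compound_record")) records <- list(records)
  confs <- list()
  for (r in records) {
    for (k in r$conformers) {
      confs <- c(confs, list(if (isTRUE(k$prepared)) k
                             else prepare_conformer(k)))
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(BINARY_MAGIC), con)
  .write_u64(con, new_uint64(0, length(confs)))
  for (k in confs) {
    X <- heavy_coords(k)
    el <- k$elements[!k$is_h]
    fs <- k$features
    f <- length(fs$types)
    .write_u64(con, make_conformer_id(k$cid, k$lid))
    .write_u16(con, nrow(X))
    .write_u16(con, f)
    .write_u16(con, as.integer(isTRUE(k$frame_degenerate)))
    .write_u16(con, 0L)
    writeBin(c(k$self_volume, unname(k$self_color_volumes)), con, size = 4,
             endian = "little")
    writeBin(as.integer(0), con, size = 4, endian = "little")  # realign pad
    for (i in seq_len(nrow(X))) {
      writeBin(as.raw(ATOMIC_NUMBERS[[el[i]]]), con)
      .write_i16(con, quantize_coordinate(X[i, ]))
      writeBin(as.raw(0), con)
    }
    for (i in seq_len(f)) {
      writeBin(as.raw(match(fs$types[i], FEATURE_TYPES)), con)
      .write_i16(con, quantize_coordinate(fs$positions[i, ]))
      writeBin(as.raw(min(length(fs$parents[[i]]), 255)), con)
    }
  }
  invisible(path)
}

#' Read a compact binary conformer set
#'
#' Inverse of [write_binary_set()] up to coordinate quantization.  The bond
#' graph is not stored, so the returned conformers carry their stored
#' feature atoms (with parent counts only) and cached volumes rather than
#' re-derivable topology.
#'
#' @param path Path to a file written by [write_binary_set()].
#' @return A list of `compound_record` objects.
#' @export
read_binary_set <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8))
  if (!identical(magic, BINARY_MAGIC)) {
    stop("not a ", BINARY_MAGIC, " file (bad magic)")
  }
  count <- .read_u64(con)
  if (count$hi != 0) stop("unreasonable record count")
  confs <- vector("list", count$lo)
  inv_elements <- stats::setNames(names(ATOMIC_NUMBERS), ATOMIC_NUMBERS)
  for (r in seq_len(count$lo)) {
    id <- parse_conformer_id(.read_u64(con))
    n <- .read_u16(con)
    f <- .read_u16(con)
    flags <- .read_u16(con)
    .read_u16(con)  # pad
    vols <- readBin(con, "double", n = 7, size = 4, endian = "little")
    readBin(con, "integer", size = 4, endian = "little")  # realign pad
    el <- character(n)
    X <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      el[i] <- inv_elements[[as.character(as.integer(readBin(con, "raw", 1)))]]
      X[i, ] <- dequantize_coordinate(.read_i16(con, 3))
      readBin(con, "raw", 1)
    }
    ftypes <- character(f)
    fpos <- matrix(0, f, 3)
    fparents <- vector("list", f)
    for (i in seq_len(f)) {
      ftypes[i] <- FEATURE_TYPES[as.integer(readBin(con, "raw", 1))]
      fpos[i, ] <- dequantize_coordinate(.read_i16(con, 3))
      fparents[[i]] <- rep(NA_integer_, as.integer(readBin(con, "raw", 1)))
    }
    k <- conformer(el, X, cid = id$cid, lid = id$lid)
    k$self_volume <- vols[1]
    k$self_color_volumes <- stats::setNames(vols[2:7], FEATURE_TYPES)
    k$features <- new_feature_set(ftypes, fpos, fparents, X)
    k$frame_degenerate <- bitwAnd(flags, 1L) == 1L
    k$prepared <- TRUE
    confs[[r]] <- k
  }
  cids <- vapply(confs, function(x) x$cid, numeric(1))
  lapply(sort(unique(cids)), function(cid) {
    recs <- confs[cids == cid]
    rec <- structure(list(cid = cid, conformers = recs,
                          feature_counts = feature_counts(recs[[1]]$features)),
                     class = "compound_record")
    rec
  })
}
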