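# Minimal exact unsigned 64-bit integer, stored as two 32-bit limbs kept in
# doubles (each limb < 2^32 is exactly representable).  Only what the packing
# code needs: construction, limb access, hex rendering, equality.

new_uint64 <- function(hi, lo) {
  hi <- as.numeric(hi); lo <- as.numeric(lo)
  if (length(hi) != 1L || length(lo) != 1L ||
      is.na(hi) || is.na(lo) ||
      hi < 0 || lo < 0 || hi >= 2^32 || lo >= 2^32 ||
      hi != floor(hi) || lo != floor(lo)) {
    stop("uint64 limbs must be integers in [0, 2^32)")
  }
  structure(list(hi = hi, lo = lo), class = "uint64")
}

#' Test for the package's unsigned 64-bit value type
#' @param x Object to test.
#' @return `TRUE` if `x` is a packed 64-bit value.
#' @export
is_uint64 <- function(x) inherits(x, "uint64")

.hex32 <- function(v) {
  sprintf("%04x%04x", as.integer(v %/% 65536), as.integer(v %% 65536))
}

#' Render a packed 64-bit value as 16 lowercase hex characters
#' @param x A `uint64` value (e.g. a packed conformer ID or superposition).
#' @return A 16-character lowercase hex string.
#' @export
uint64_hex <- function(x) {
  stopifnot(is_uint64(x))
  paste0(.hex32(x$hi), .hex32(x$lo))
}

#' Parse a 16-character hex string into a packed 64-bit value
#' @param s A 16-character hex string.
#' @return A `uint64` value.
#' @export
uint64_from_hex <- function(s) {
  s <- tolower(s)
  if (!grepl("^[0-9a-f]{16}$", s)) stop("expected 16 hex characters")
  quad <- strtoi(substring(s, c(1, 5, 9, 13), c(4, 8, 12, 16)), base = 16L)
  new_uint64(quad[1] * 65536 + quad[2], quad[3] * 65536 + quad[4])
}

#' @export
print.uint64 <- function(x, ...) {
  cat("<uint64 0x", uint64_hex(x), ">\n", sep = "")
  invisible(x)
}

#' @export
`==.uint64` <- function(e1, e2) {
  stopifnot(is_uint64(e1), is_uint64(e2))
  e1$hi == e2$hi && e1$lo == e2$lo
}
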