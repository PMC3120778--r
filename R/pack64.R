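# 64-bit superposition codec: 8-bit quaternion components (32 bits), three
# translation sign bits, and a 29-bit mixed-radix field of three log-scale
# translation magnitudes (812 levels per axis; 812^3 = 535,387,328 < 2^29).

TRANS_LEVELS <- 812
TRANS_SCALE <- TRANS_LEVELS / log(101)  # levels per unit of log(1 + |t|)

#' Encode a quaternion component into an 8-bit level
#'
#' Components lie in (-1, 1) after normalization; the level is
#' `round((v + 1)/2 * 255)` (half away from zero), so adjacent decoded
#' values are `2/255 = 0.00784` apart.
#'
#' @param v Quaternion component(s) in `[-1, 1]`.
#' @return Integer level(s) in `[0, 255]`.
#' @export
encode_quaternion_component <- function(v) {
  pmin(pmax(round_hafz((v + 1) / 2 * 255), 0), 255)
}

#' Decode an 8-bit quaternion component level
#' @param level Integer level(s) in `[0, 255]`.
#' @return Decoded component(s): `level/255 * 2 - 1`.
#' @export
decode_quaternion_component <- function(level) level / 255 * 2 - 1

#' Encode a translation axis value (log scale)
#'
#' The magnitude is mapped through `log(1 + |t|)` onto 812 uniform levels
#' over (0, 100) angstrom, plus a sign bit.  The log scale concentrates
#' precision near zero (round-trip error about +/- 0.0028 angstrom) at the
#' expense of the far range (about +/- 0.29 angstrom near 100).
#'
#' @param t Translation component in (-100, 100) angstrom.
#' @return List with `sign` (0 positive, 1 negative; zero encodes positive)
#'   and `level` in `[0, 811]`.
#' @export
encode_translation_axis <- function(t) {
  if (abs(t) >= 100) stop("translation magnitude must be < 100 angstrom")
  level <- min(max(round_hafz(log1p(abs(t)) * TRANS_SCALE), 0),
               TRANS_LEVELS - 1)
  list(sign = if (t < 0) 1L else 0L, level = as.integer(level))
}

#' Decode a translation axis value
#' @param sign 0 (positive) or 1 (negative).
#' @param level Integer level in `[0, 811]`.
#' @return The decoded translation component in angstrom.
#' @export
decode_translation_axis <- function(sign, level) {
  mag <- expm1(level / TRANS_SCALE)
  if (sign == 1) -mag else mag
}

#' Pack a rigid superposition into an unsigned 64-bit integer
#'
#' Layout: bits 63..32 hold the four 8-bit quaternion levels (w, x, y, z
#' from high to low); bits 31..29 hold the x, y, z translation sign bits;
#' bits 28..0 hold the mixed-radix combination
#' `E = e_x + 812 e_y + 812^2 e_z` of the three translation levels.
#' The quaternion is normalized before encoding.
#'
#' @param transform A `rigid_transform` with translation components in
#'   (-100, 100) angstrom.
#' @return A `uint64` packed superposition.
#' @export
encode_superposition <- function(transform) {
  q <- transform$q / sqrt(sum(transform$q^2))
  lev <- encode_quaternion_component(q)
  # stabilize against the decode-side renormalization so that
  # encode(decode(code)) reproduces the code exactly
  for (iter in 1:8) {
    qd <- decode_quaternion_component(lev)
    lev2 <- encode_quaternion_component(qd / sqrt(sum(qd^2)))
    if (all(lev2 == lev)) break
    lev <- lev2
  }
  hi <- ((lev[1] * 256 + lev[2]) * 256 + lev[3]) * 256 + lev[4]
  ax <- lapply(transform$t, encode_translation_axis)
  E <- ax[[1]]$level + TRANS_LEVELS * ax[[2]]$level +
    TRANS_LEVELS^2 * ax[[3]]$level
  lo <- ax[[1]]$sign * 2^31 + ax[[2]]$sign * 2^30 + ax[[3]]$sign * 2^29 + E
  new_uint64(hi, lo)
}

#' Unpack a 64-bit superposition
#'
#' Inverse of [encode_superposition()]; the decoded quaternion is
#' renormalized.  `encode(decode(encode(x)))` equals `encode(x)` (the codec
#' is idempotent on its code space).
#'
#' @param packed A `uint64` (or 16-character hex string).
#' @return The decoded `rigid_transform`.
#' @export
decode_superposition <- function(packed) {
  if (is.character(packed)) packed <- uint64_from_hex(packed)
  stopifnot(is_uint64(packed))
  hi <- packed$hi
  lev <- numeric(4)
  for (k in 4:1) {
    lev[k] <- hi %% 256
    hi <- hi %/% 256
  }
  q <- decode_quaternion_component(lev)
  lo <- packed$lo
  signs <- c(lo %/% 2^31 %% 2, lo %/% 2^30 %% 2, lo %/% 2^29 %% 2)
  E <- lo %% 2^29
  ex <- E %% TRANS_LEVELS
  ey <- (E %/% TRANS_LEVELS) %% TRANS_LEVELS
  ez <- E %/% TRANS_LEVELS^2
  t <- c(decode_translation_axis(signs[1], ex),
         decode_translation_axis(signs[2], ey),
         decode_translation_axis(signs[3], ez))
  rigid_transform(q, t)
}
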