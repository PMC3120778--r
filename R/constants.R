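#' @useDynLib p3dnbr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim rnorm runif sd
#' @importFrom utils head
NULL

# All tunable numerical constants of the shape model live here so they can be
# audited in one place.

# Gaussian amplitude of the atom-centered density (Grant-Pickup hard-sphere
# calibrated choice); the exponent prefactor follows so that an isolated
# atom's Gaussian integral equals its hard-sphere volume (4/3) pi r^3.
GAUSS_P <- 2.70
GAUSS_KAPPA <- pi * (3 * GAUSS_P / (4 * pi))^(2 / 3)

# Fictitious feature ("color") atom radii: scoring radius, and the inflated
# radius used only for the stage-2 recycled-alignment overlap estimate.
FEATURE_RADIUS <- 1.08265
FEATURE_RADIUS_STAGE2 <- 1.25

FEATURE_TYPES <- c("anion", "cation", "donor", "acceptor", "hydrophobe", "ring")

# Same-type features closer than this are merged (parents pooled).
FEATURE_MERGE_DIST <- 1.0

# Shape grid parameters for the O(N) overlap estimate.
GRID_SPACING <- 0.25
GRID_CUTOFF <- 4.5

# Local shape optimizer stopping policy (declared, deterministic).
OPT_MAXIT <- 200L
OPT_RELTOL <- 1e-8

# Bondi van der Waals radii (angstrom); elements outside the table fall back
# to the carbon radius with a warning.
BONDI_RADII <- c(
  H = 1.20, He = 1.40, Li = 1.82, Be = 1.53, B = 1.92, C = 1.70, N = 1.55,
  O = 1.52, F = 1.47, Ne = 1.54, Na = 2.27, Mg = 1.73, Al = 1.84, Si = 2.10,
  P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88, K = 2.75, Ca = 2.31, Ga = 1.87,
  Ge = 2.11, As = 1.85, Se = 1.90, Br = 1.85, Kr = 2.02, Rb = 3.03, Sr = 2.49,
  In = 1.93, Sn = 2.17, Sb = 2.06, Te = 2.06, I = 1.98, Xe = 2.16
)

ATOMIC_NUMBERS <- c(
  H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L,
  Ne = 10L, Na = 11L, Mg = 12L, Al = 13L, Si = 14L, P = 15L, S = 16L,
  Cl = 17L, Ar = 18L, K = 19L, Ca = 20L, Ga = 31L, Ge = 32L, As = 33L,
  Se = 34L, Br = 35L, Kr = 36L, Rb = 37L, Sr = 38L, In = 49L, Sn = 50L,
  Sb = 51L, Te = 52L, I = 53L, Xe = 54L
)

.lut_env <- new.env(parent = emptyenv())

#' Exponential lookup table used by all shape kernels
#'
#' Precomputed values of `exp(x)` for `x` from -12 to 0 in increments of
#' 0.002 (6,001 entries).  All Gaussian overlap kernels evaluate their
#' exponentials by nearest-entry lookup in this table; arguments below -12
#' evaluate to zero (the Gaussian tail is negligible there) and arguments
#' never exceed zero by construction.
#'
#' @return Numeric vector of length 6001; `exp_lut()[k]` is
#'   `exp(-12 + 0.002 * (k - 1))`.
#' @export
exp_lut <- function() {
  if (is.null(.lut_env$lut)) {
    .lut_env$lut <- exp(seq(-12, 0, by = 0.002))
  }
  .lut_env$lut
}

#' Bondi van der Waals radius for an element
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of radii in angstrom.  Unknown elements fall back
#'   to the carbon radius (1.70) with a warning.
#' @export
bondi_radius <- function(element) {
  r <- unname(BONDI_RADII[element])
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(element[is.na(r)]), collapse = ", "),
            "; using carbon Bondi radius 1.70")
    r[is.na(r)] <- BONDI_RADII[["C"]]
  }
  r
}

#' Gaussian exponent for an atomic radius
#'
#' Exponent alpha (1/angstrom^2) of the atom-centered Gaussian
#' `p * exp(-alpha |r|^2)` calibrated so the isolated-atom integral equals
#' the hard-sphere volume `(4/3) pi r^3` at amplitude `p = 2.70`.
#'
#' @param radius Atomic radius in angstrom (> 0).
#' @return `pi * (3 p / (4 pi))^(2/3) / radius^2`.
#' @export
gaussian_exponent <- function(radius) {
  if (any(radius <= 0)) stop("radius must be positive")
  GAUSS_KAPPA / radius^2
}

# deterministic seeded evaluation that does not disturb the global RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# round half away from zero (base round() is round-half-even)
round_hafz <- function(x) sign(x) * floor(abs(x) + 0.5)
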