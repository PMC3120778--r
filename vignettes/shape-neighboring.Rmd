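---
title: "Gaussian shape and pharmacophore neighboring of 3-D conformers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian shape and pharmacophore neighboring of 3-D conformers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p3dnbr)
```

## The problem

Given millions of small-molecule conformers, which pairs have nearly the
same 3-D shape *and* present the same pharmacophore features in the same
places?  Answering that at scale requires (a) a similarity model cheap
enough to evaluate billions of times, (b) filters that discard the
overwhelming majority of pairs without ever superposing them, and (c) a
storage format compact enough that the results (including the superposition
itself) fit in a few bytes per pair.  `p3dnbr` implements that entire
pipeline at desk scale: the scoring model, the staged filtered search, and
the bit-exact 64-bit packing of rigid superpositions.

## The similarity model

Each non-hydrogen atom is an isotropic Gaussian density
$p\,e^{-\alpha r^2}$ with amplitude $p = 2.70$ and exponent
$\alpha = \pi\,(3p/4\pi)^{2/3}/r^2$ chosen so that an isolated atom
integrates to its hard-sphere volume $\tfrac43\pi r^3$ (Bondi van der Waals
radii).  The overlap volume of conformers $A$ and $B$ at a relative rigid
transform is the first-order (pairwise product) sum

$$V_{AB} \;=\; \sum_{i\in A}\sum_{j\in B} p^2
\left(\frac{\pi}{\alpha_i+\alpha_j}\right)^{3/2}
e^{-\frac{\alpha_i\alpha_j}{\alpha_i+\alpha_j} d_{ij}^2},$$

and the **shape Tanimoto** is $ST = V_{AB}/(V_{AA}+V_{BB}-V_{AB})$.
Higher-order intersection corrections are omitted — the common
hard-sphere-calibrated practice, which keeps $V_{AB}$ analytic in the
transform.  Because $V_{AB}$ is an $L^2$ inner product of the two total
densities, $V_{AB} \le \sqrt{V_{AA} V_{BB}}$ at *any* transform; several
filters below lean on that bound.

Pharmacophores are modeled as fictitious **feature ("color") atoms** of six
types — anion, cation, hydrogen-bond donor, hydrogen-bond acceptor,
hydrophobe, ring — placed at the steric center (unweighted mean) of their
parent real atoms, all with radius 1.08265 Å for scoring.  The **color
Tanimoto** has the same form as ST but sums the six per-type overlaps;
cross-type overlap is never counted.  Same-type features closer than 1.0 Å
are merged iteratively (parents pooled, position recomputed), visiting
pairs in order of increasing distance with ties to the lowest parent index,
so the fixed point is deterministic.

All exponentials in the overlap kernels go through a 6,001-entry lookup
table of $e^x$ for $x \in [-12, 0]$ in 0.002 steps (nearest entry, no
interpolation; arguments below $-12$ are zero and arguments are never
positive).  The worst-case lookup error is $10^{-3}$ absolute, which is
invisible at the 0.01 score granularity the thresholds are stated in but
does make the objective surface minutely rough — the reason a conformer's
optimized ST against itself can exceed 1 by a few parts in $10^4$.

### Feature typing rules

The feature types are identified in the field by an implicit force field
inside a proprietary toolkit; no reproducible parameter set is published.
This package instead ships an explicit, versioned rule table over the
molecular graph (`feature_typing_rules()`): carboxylate/sulfonate/phosphate
anions, amine and amidinium/guanidinium cations, N–H/O–H donors (hydrogen
counts inferred from valence when hydrogens are implicit), N/O acceptors
excluding amide nitrogens, hydrophobes at the centroids of connected
clusters (≥ 2 atoms) of non-aromatic carbons bonded only to C/H, and one
ring feature per smallest ring (SSSR via shortest-path completion of the
fundamental cycles).  The hydrophobe rule is the least constrained by
precedent and deliberately strict: a halogenated carbon never joins a
cluster, which is also how the test fixtures obtain arbitrarily large
genuinely featureless molecules.  Scores are reproducible *within this
artifact*; they are not expected to match any specific commercial typing
numerically.

## Superposition

Conformers are first put in a canonical frame: heavy-atom steric center at
the origin, axes along the eigenvectors of the unweighted gyration tensor
in descending eigenvalue order, each of the first two axes signed so its
largest-magnitude component is positive, the third the right-handed cross
product.  Prolate and oblate degeneracies keep the well-defined axis and
complete the frame deterministically; spherical tops are only centered and
flagged.

Shape optimization is a Nelder–Mead search over the six rigid degrees of
freedom (axis-angle about the start rotation, plus translation), run from
the identity and the three 180° principal-axis flips — the standard remedy
for the sign ambiguity of inertial frames.  The stopping policy is fixed
(relative tolerance $10^{-8}$, at most 200 iterations), so results are
deterministic.  Features never enter the objective; CT is always a single
point evaluated at the ST-optimal transform.  The **combo Tanimoto**
ST + CT (CT term zero when either molecule is featureless) drives the
**diverse ordering** of a compound's ensemble: the lowest-energy conformer
seeds the order (lowest LID when energies are absent — arbitrary SDF input
has none), and each pick minimizes the summed combo to the already-picked
set, with ties resolved by the largest summed combo to the unpicked set and
then the least LID.  Equality within $10^{-9}$ counts as a tie.

## The staged search

A conformer pair is a **neighbor** when the optimized superposition gives
ST ≥ 0.795 and CT ≥ 0.495 (the nominal 0.8/0.5 after rounding to the
nearest 0.01).  Pairs of two featureless conformers use ST ≥ 0.925
(nominal 0.93) instead; mixed featureless/featured pairs are never
neighbors.  The search avoids optimizing almost all pairs:

1. **Count and volume filters.**  Solving the Tanimoto equation for the
   overlap gives the minimum overlap needed,
   $AB_{\min} = T(A+B)/(1+T)$.  For color volumes, $AB_{\min}$ larger than
   either self color volume is fatal (strict).  Per-type feature *counts*
   bound the best conceivable CT,
   $CT_{\max} = \sum_t \min(A_t,B_t) / (\sum_t A_t + \sum_t B_t - \sum_t
   \min(A_t,B_t))$; since counts are topological this filter runs once per
   *compound* pair.  For shape, Gaussian overlap can exceed a self volume,
   so instead both ratios $AB_{\min}/A$ and $AB_{\min}/B$ (at the nominal
   0.8 threshold) must fall within $[0.75, 1.50]$.
2. **Fingerprints and alignment recycling.**  A tiered reference-shape
   library covers seven volume regions with fingerprint thresholds falling
   from 0.75 to 0.45 in 0.05 steps (bands 1–165, 166–199, 200–238,
   239–285, 286–344, 345–432, 433–999 Å$^3$).  The library is built by
   greedy leader clustering in stream order: a conformer becomes a new
   reference when its optimized ST to every same-region reference is below
   the region threshold.  Each conformer's **shape fingerprint** sets one
   bit per reference reached at threshold, retaining the packed alignment.
   A pair with no common bit is discarded.  Otherwise each common
   reference's alignments are composed ("recycled") into a candidate
   superposition, scored cheaply as grid shape overlap (0.25 Å lattice of
   carbon-probe overlaps, 4.5 Å atom cutoff) plus feature overlap at an
   inflated 1.25 Å feature radius; the best candidate's *exact* shape
   overlap must then give ST > 0.735 (strict) to survive.
3. **Final optimization.**  Seeded at the recycled alignment (plus an
   identity safeguard; a `thorough` flag adds the full flip set), then the
   neighbor decision above.  Emitted pairs carry ST, CT and the packed
   64-bit superposition.

Design choices worth flagging: the volume prefilter inside fingerprint
generation combines the provable Cauchy–Schwarz cap $\sqrt{AB}$ with the
same $1.5\times\min(A,B)$ cap the stage-1 window trusts — the first is
exact, the second empirical, and the tests audit that no bit a brute-force
pass would set is ever suppressed on the fixture sets.  Filter boundaries
follow mixed strict/inclusive semantics: "greater than" eliminations are
strict, threshold passes are inclusive.  The stage-2 grid stores
carbon-probe overlaps; non-carbon query atoms are scaled by the amplitude
prefactor ratio $((2\alpha_C)/(\alpha_C+\alpha_j))^{3/2}$, an approximation
confined to the stage-2 estimate and never touching final scores.

## 64-bit superpositions

A rigid superposition packs into one unsigned 64-bit integer: the
normalized quaternion's four components quantized to 8 bits each over
$(-1,1)$ (resolution $2/255 = 0.00784$, round half away from zero) in the
high 32 bits (w, x, y, z); three translation sign bits; and a 29-bit
mixed-radix field $e_x + 812\,e_y + 812^2 e_z$ of per-axis log-scale
magnitudes, $e = \mathrm{round}(\ln(1+|t|)\cdot 812/\ln 101)$ clamped to
$[0, 811]$ ($812^3 = 535{,}387{,}328$ just fits 29 bits).  The log scale
concentrates precision at the origin — a half-step of ±0.0028 Å on the
first quantization step, widening to ±0.29 Å on the last interval below
100 Å — which is the right trade-off because superposed conformers sit at
their steric centers, so translations are small.  The phrase "divided by
812" fixes the scale only up to the range convention; $812/\ln 101$ is
adopted because it uniquely reproduces both printed precision figures.
Encoding stabilizes the quaternion levels against the decode-side
renormalization so the codec is idempotent on its code space.  Decoding a
stored superposition and rescoring moves ST only rarely by more than
0.01 and CT more often — features are sparse, small, and peripheral, so
rotation quantization torques them further — and the errors are signed and
centered on zero, which the acceptance suite checks on $10^4$ perturbed
near-optimal alignments.

The conformer identity itself packs as CID in the 32 high bits and LID in
the 16 low bits (bits 16–31 zero — the natural reading of a 32-high/16-low
layout inside 64 bits).  The compact binary set format (`P3DNBR01`,
documented in `?write_binary_set`) quantizes coordinates to a signed
16-bit lattice over $(-50, 50)$ Å — step $100/2^{16} \approx 0.0015$ Å,
so at most half a step of round-trip error — and stores derived feature
atoms and cached volumes rather than the bond graph.

## The synthetic generator, and what the tests do and do not show

All tests run on deterministic toy conformers (`make_toy_conformer`,
`make_toy_ensemble`, `standard_fixture_suite`): rods, zig-zag alkane
chains, aromatic rings with and without tails, branched alkanes, a
hydroxy-aldehyde donor/acceptor template (with a methyl branch so its
ST optimum is not flip-degenerate), and fluorinated featureless chains —
heavy atoms only, 1.5 Å C–C scale, synthetic bond graphs sufficient for
typing, torsioned and jittered per conformer from explicit seeds.
Ensembles of 3–4 conformers per compound and a suite of nine compounds
(about 30 conformers) keep the brute-force oracle — every pair optimized
from 24 rotational starts, no filters — affordable; quadrature oracles use
midpoint sums at 0.15–0.25 Å, where the integrand's smoothness makes the
rule effectively exact.  These fixtures exercise every code path
(all six feature types, the featureless route, multi-region libraries,
near-duplicate neighbors) but they are not real chemistry: no force-field
geometries, no conformer-ensemble energetics, no tautomers or charges, and
volumes concentrated in the lower fingerprint regions.  Passing tests
demonstrate internal correctness of the model and pipeline — filter
soundness, oracle containment, determinism, codec accuracy — not that
scores reproduce any production system's numbers on real compounds.

## Known limitations

* Feature typing is rule-based and intentionally conservative; aromatic
  perception relies on explicit aromatic (order 4) bonds.
* The reference library is built from user data by order-dependent leader
  clustering; no canonical reference set ships with the package.
* The optimizer is local; recall against the brute-force oracle is
  measured (≥ 0.9 on the standard suite), not guaranteed.
* Compound-level feature counts are pre-merge topological counts, while
  per-conformer CT uses post-merge features; the count filter is an upper
  bound either way.
* Very large molecules (self shape volume above 999 Å$^3$) are outside the
  fingerprint design and rejected.
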