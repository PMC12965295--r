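---
title: "Pigment geometry, Förster networks, and TA global analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pigment geometry, Förster networks, and TA global analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psifret)
```

This vignette is the package's account of its science: what is modelled,
which conventions and parameters were chosen where the field leaves a
choice open, and what the synthetic generators do and do not emulate.

## The system

Photosystem I (PSI) supercomplexes of secondary-endosymbiotic algae such as
*Euglena gracilis* bind an unusually large peripheral antenna: on the order
of sixteen light-harvesting proteins (diadinoxanthin–Chl a/b-binding
"LHCE"-type antennae) ringing an eight-subunit core, together carrying
roughly three hundred chlorophylls plus carotenoids, phylloquinones,
Fe₄S₄ clusters and structural lipids. Three computational questions follow
from such a model: the *inventory* (who binds what, and where the notable
contacts are), the *energy-transfer network* implied by the pigment
geometry, and the *kinetics* measured by femtosecond transient absorption.

## Structure input and the pigment registry

Coordinates are read from mmCIF or PDB through bio3d; all ATOM/HETATM
records are kept, with alternate locations collapsed to a single atom
(highest occupancy, then alternate-label order — a deterministic
tie-break). Coordinates are Ångström throughout; nothing downstream
converts units.

Residue codes map to pigment classes through a registry
(CLA→Chl a, CHL→Chl b, BCR→β-carotene, DD6/DDX→diadinoxanthin, PQN/PHQ→
phylloquinone, SF4→Fe₄S₄, SQD/LHG/LMG/DGD→lipid). The registry is fully
overridable (programmatically or by YAML), because deposited models name
cofactors by chemical-component code while the literature names them
chemically, and codes vary between depositions. Chlorins missing both the
Mg and the four macrocycle nitrogens, and carotenoids with fewer than four
backbone carbons, are extracted but flagged *degenerate*: geometric
operations refuse them explicitly rather than silently guessing.

Site labels follow the green-lineage antenna nomenclature: chlorins with
residue numbers 600–699 are labelled `a603`/`b606` style; everything else
`chain:resnum`.

## Pigment geometry conventions

* **Anchor point.** The transition dipole is anchored at the Mg atom (the
  N₄ centroid when Mg is unmodelled). The donor–acceptor distance `R` is
  the Mg–Mg distance, so one anchor serves both distance and orientation.
* **Qy direction.** Unit vector along the macrocycle NB→ND axis. This is
  the widely used convention for the chlorophyll Qy transition; because
  published analyses differ on the exact atom pair, the registry accepts
  NA→NC instead. The sign of the axis is immaterial: κ² is even in each
  dipole.
* **Ring plane.** Least-squares plane through the macrocycle N and ring C
  atoms via SVD; the normal's sign is fixed deterministically (positive z,
  then y, then x component). Interplane angles are folded to [0°, 90°].
* **Cis/trans carotenoids.** For each backbone bond *i* (between atoms
  C*i* and C*i+1*) the torsion over C*i−1*…C*i+2* is computed; a bond is
  *cis* when |torsion| ≤ 90° (the boundary maps to cis — a symmetric,
  deterministic rule; the choice matters only on the measure-zero
  boundary). Positions are reported in backbone bond indices; mapping to
  IUPAC carotenoid numbering is left to the registry's backbone naming,
  since deposited atom names already follow the carotenoid scheme.
  Missing backbone atoms suppress only the bonds that need them and are
  listed as gaps.

## The Förster network

Rates follow the point-dipole expression `k = Cκ²/(n⁴R⁶)` with
`κ = μ̂_D·μ̂_A − 3(μ̂_D·R̂)(μ̂_A·R̂)`. Defaults and their reasons:

* `C = 1` (rate·Å⁶) per class pair. The overlap-integral factor and the
  refractive index used in published tables of absolute rates for such
  complexes are typically not printed; without them only *relative* rates
  are defensible. `C` accepts per-class-pair values
  (e.g. `"CHL_B>CHL_A"`) because the spectral overlap of Chl b donors
  with Chl a acceptors differs from the a→a case.
* `n = 1.55`, a common choice for a protein interior; configurable.
* `r_max = 30 Å` edge cutoff. Whether published analyses pruned pairs by
  distance is usually unstated, so the cutoff is exposed; at 30 Å the
  R⁻⁶ law has suppressed rates by ~4 orders of magnitude relative to
  10 Å contacts.
* Pairs with κ² = 0 are excluded from the network rather than kept with
  infinite transfer time, so path search terminates cleanly.

**Pathways.** The default path cost is the summed per-hop transfer time
Σ 1/k — the mean first-passage time of a chain under irreversible hopping.
This makes "fastest path" well defined without a master-equation model of
the full network (deliberately out of scope). An alternative
−log(branching-probability) cost ranks paths by the probability that a
random walker takes them; it is available behind a flag. Ties break by
fewer hops, then lexicographic node order, so results are reproducible to
the byte. Path search adds zero-weight virtual source/sink vertices and
runs Yen's k-shortest-paths (igraph); tests verify equality with
exhaustive simple-path enumeration on all graphs up to 10 nodes.

**Red-pair detection.** Candidate red-shifted Chl a dimers (the a603–a609
motif) are flagged purely geometrically: Mg–Mg ≤ 10 Å and interplane angle
≤ 35°. The thresholds capture a tightly stacked, near-parallel
("parallelogram-like") arrangement while excluding ordinary neighbours;
they are arguments, not constants, since the motif definition is
qualitative.

## Inventory conventions

* "Chromophores" = Chl a + Chl b + β-Car + Ddx; "cofactors" = all
  registry-mapped residues. Published pigment totals for such complexes
  can differ from the sum of the itemised classes depending on which
  classes are counted as "pigments", so both totals are emitted and their
  definitions printed with the output.
* Chl a/b ratios per chain; chains with zero Chl b are reported `a_only`
  (the Lhca-type behaviour) rather than dividing by zero.
* Mass estimates use average (not monoisotopic) amino-acid residue masses
  plus one water per chain, and registry cofactor masses (free-molecule
  averages: Chl a 893.49 Da, Chl b 907.47, β-carotene 536.87, Ddx 582.85,
  phylloquinone 450.70, Fe₄S₄ 351.64, nominal lipid masses). Residues
  without a mass entry are excluded and listed in a gap report. The
  estimate is a modelled-content mass, not a measured molecular weight:
  unmodelled loops, detergent and partially occupied sites are invisible
  to it.
* Chain→subunit naming (e.g. which chain is which antenna position) is
  not derivable from coordinates and must be user-supplied; groupings
  default to chains.

## TA global analysis

The parallel model treats the surface as a sum of independent
IRF-convolved exponentials. The convolution has the closed form

$$D(t) = \tfrac12\,
  e^{\sigma^2/2\tau^2 - (t-t_0)/\tau}\,
  \operatorname{erfc}\!\Big(\frac{\sigma}{\sqrt2\,\tau} -
  \frac{t-t_0}{\sqrt2\,\sigma}\Big),$$

evaluated through the scaled complementary error function where the
direct product would overflow (an asymptotic expansion takes over for
arguments above 25, with relative truncation error below 1e−8).

Numerical choices in `fit_parallel_model()`:

* **Variable projection.** The DADS are eliminated exactly at each outer
  iterate by a QR-based per-wavelength linear solve; the outer
  Levenberg–Marquardt problem then only sees the lifetimes, t₀ and σ.
  At the returned optimum, re-running the inner solve reproduces the
  returned DADS exactly (tested).
* **Log-space lifetimes** with box bounds [1e−3, 1e5] ps, because the
  components span four decades. A rank-deficient basis (lifetimes
  collapsing onto each other) is handled by returning a large residual,
  which steers the optimizer away.
* **Single global t₀ and σ** by default; per-wavelength time zero is the
  job of `dispersion_correct()` (polynomial chirp up to order 5, linear
  re-interpolation with edge values held). IRF handling conventions vary
  between labs; this one keeps the nonlinear parameter count minimal.
* **Flags, not silent answers.** Components whose lifetime sits at a
  bound or whose DADS norm is < 0.1 % of the largest are flagged, which
  is how overfitting (more components than the data support) surfaces.
* Component count is user-chosen; SVD-based rank selection is
  deliberately not provided.

**Five-component convention.** Realistic simulations and the acceptance
script use lifetimes {0.36, 3, 15, 72, 2500} ps: the sub-picosecond
intradomain equilibration, a few-picosecond bulk→red antenna transfer
(3 ps is this package's declared convention for a component characterised
only as "a few picoseconds"), 15 and 72 ps equilibration/trapping
components, and a ~2.5 ns tail from kinetically uncoupled pigments.
Ordering is ascending, so "the dominant trapping component" is index 4 of
5. The associated spectra are single Gaussians (centres 686/706/694/700/
682 nm, widths 10–14 nm, amplitudes −0.8/+0.5/−0.6/−1.0/−0.3) mixing
ground-state bleach and excited-state absorption signs with the trapping
component dominant — a caricature of published decay-associated spectra
sufficient for parameter-recovery studies, not a spectral model.

**Trapping efficiency.** `trapping_efficiency()` implements
φ = 1 − τ_trap/τ_intrinsic with a *user-set* intrinsic lifetime; published
efficiency figures for such complexes rest on kinetic models whose inputs
(and formula) are typically not printed, so no particular literature value
is claimed to be reproduced. With τ_trap ≈ 72 ps and τ_intrinsic = 2 ns
the expression gives ≈ 0.964.

## Synthetic data: what it does and does not show

The generators exist so that every extraction and fitting operation can be
checked against planted truth:

* `make_chlorin()` builds a minimal chlorin (Mg, four N at the 2.05 Å
  coordination distance, four methine C) with prescribed center, ring
  normal and Qy axis; the geometry operations invert it to 1e−6.
* `make_polyene()` builds an internal-coordinate zig-zag backbone with
  180° torsions except 0° at the planted cis bonds.
* `make_toy_complex()` packs randomly oriented chlorins by rejection
  sampling (minimum Mg–Mg separation enforced) and ships an edge table
  computed by an explicit double loop — an oracle independent of the
  vectorised network path. `make_supercomplex_toy()` instantiates the
  16-antenna + 88-chlorophyll-core architecture at realistic packing
  density.
* `simulate_ta()` emits IRF-convolved multi-exponential surfaces with
  Gaussian bands and homoscedastic Gaussian noise (default 1 % of peak
  signal — a reasonable shot-to-shot noise scale for averaged
  femtosecond data; real TA noise is neither white in λ nor
  homoscedastic, and no coherent artifact is simulated).

Passing these tests therefore demonstrates correctness of the geometry,
network and fitting mathematics on data whose generative model is known.
It does not validate the point-dipole approximation itself (which degrades
for closely coupled pigments such as red-Chl dimers, where excitonic
treatment would be required), nor spectral assignments, nor the absolute
rate scale — those require a calibrated `C`, measured spectra, and a real
deposited model.

Problem sizes used by the shipped tests and the acceptance script were
chosen to be comfortable on a laptop: toy complexes up to 150 pigments for
oracle-equality checks, 8–10-node graphs for exhaustive path enumeration
(the count of simple paths explodes combinatorially beyond that), 1000
polyenes for the isomer sweep, and twenty 150×60 TA surfaces for the
lifetime-recovery study.

## Known limitations

* No excitonic coupling, site energies or master-equation kinetics: the
  network is a geometric Förster map, not a spectroscopic simulation.
* Absolute rates require user-supplied `C` and `n`; published rate tables
  cannot be checked without them.
* PDB output is limited to single-character chain ids (use mmCIF beyond
  62 chains); occupancies are preserved, B-factors are not meaningful
  fields in this pipeline and are written as zero.
* `mass_estimate()` measures modelled content only.
* Subunit identification (which chain is which antenna) is intentionally
  out of scope; supply a grouping vector.
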