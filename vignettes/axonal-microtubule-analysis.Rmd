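---
title: "Quantifying axonal microtubule architecture in synthetic cryo-electron tomograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying axonal microtubule architecture in synthetic cryo-electron tomograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonmt)
```

## What this package models

Axonal microtubules (MTs) are hollow polymers of alpha/beta-tubulin dimers
arranged in protofilaments (pfs): 13 of them in mammalian neurons, with an
8-nm dimer repeat along each pf and a 3-start helical stagger (0.92 nm rise
per pf for 13 pfs, which also creates the lattice seam). Cryo-electron
tomography images these polymers in place, but each tomogram is corrupted
by strong noise and by the missing wedge: a single-axis tilt series only
measures Fourier components within the tilt range (here +/-60 degrees
about the y axis), so a wedge-shaped region of reciprocal space is absent
and densities are smeared along the beam direction.

`axonmt` implements the quantitative questions one asks of such data —
which way does each MT point (polarity)? how many protofilaments does it
have, and does that number change along its length? how dense are the
globular particles in its lumen (MIPs), and are they retained at lattice
breaks and ends? how do protofilaments behave at MT ends? — and pairs every
method with a synthetic-scene generator so that each answer can be checked
against exact ground truth.

## The synthetic generator and what it emulates

`lattice_spec()` + `filament_spec()` + `scene_manifest()` describe a scene;
`render_scene()` converts it to a density volume (protein positive) and
`corrupt()` applies noise and the wedge.

Geometry defaults (all in nm) are chosen to match mammalian axonal MTs:
wall radius 10.6 (peak-to-peak wall diameter about 21 nm), dimer rise 8,
monomer offset 4, monomer blob sigma 2, 1-nm voxels, zero supertwist for
13 pfs. Non-13 pf numbers scale the wall radius proportionally so the
inter-pf spacing is constant. Alpha and beta monomers are rendered with a
modest amplitude contrast (1.12 vs 0.88); without some distinguishing
feature the 4-nm axial register of the lattice would be ambiguous to
alignment, which in turn scrambles every register-dependent cue. Real
tubulin monomers are not identical either, and per-particle alignment in
real data resolves the dimer register the same way.

**The polarity cue.** In projections of real MT averages the tubulin
densities appear rotationally sheared ("slewed"), clockwise when viewed
from the minus end. The physical origin of that appearance is not part of
this model; the generator produces a minimal parametric surrogate: each
dimer's beta monomer is displaced tangentially (sign set by polarity) and
radially outward by `monomer_offset * sin(slew_tilt)` (default tilt 15
degrees), symmetric about the wall radius. The surrogate reproduces the
operational content of the cue — an angular lag between the inner-wall and
outer-wall intensity profiles whose sign flips with polarity and under
mirror reflection — while preserving the mean wall diameter. The
radial component is required: a purely tangential offset leaves inner and
outer radii in phase and no projection method could read a handedness from
it.

**Luminal particles.** MIPs are rendered as six 1.3-sigma blobs on a
3.2-nm ring (9-nm outer diameter with a central pore), randomly oriented.
Placement along the lumen draws a Poisson count at `mip_rate` per
micrometer (default scenes use 72/um, the reported mean abundance in
mammalian axons) and then positions that many points uniformly under a
9-nm hard-core constraint (the particle diameter). The hard core is
enforced by conditional placement rather than by discarding draws, so the
realized density equals the nominal rate — plain thinning would silently
reduce a 72/um process to roughly 50/um and every downstream density
comparison would inherit that bias.

**Other content.** Actin-like filaments are zig-zag blob chains with a
6-nm lateral repeat (oscillating in the tomogram plane, where projections
can see it); thick filaments are hollow 8.5-nm tubes; thin filaments are
plain blob chains. Lattice breaks remove monomers inside an arclength
interval; per-pf end tapers truncate each protofilament at its own
terminal arclength.

**Corruption.** White Gaussian noise is scaled so that the variance of the
noiseless density over its support mask (voxels above 10% of the maximum)
divided by the noise variance equals the requested SNR; then the Fourier
amplitudes inside the wedge (`|atan2(kz, kx)| > tilt_range`, tilt axis y)
are zeroed. This reproduces the two dominant corruptions of real
tomograms. It does not model the contrast transfer function, dose
fractionation, tilt-dependent thickness, alignment errors or
reconstruction artifacts — so passing tests here demonstrates that the
measurement logic is correct under noise and anisotropic information loss,
not that the pipeline is robust to every pathology of real data.

## The averaging engine

Particles are picked every 8 nm (a tubulin dimer; 4 nm for monomer-level
work — the spacing is a parameter) along each filament model, with box z
along the local tangent and the in-plane basis referenced to the tomogram
axes, so the missing wedge sits at a predictable orientation in every box.
Alignment (`align()`) is a grid search over in-plane rotation and shifts
within stated limits (defaults: 2-degree steps, half-voxel shifts, 2.2-nm
axial limit, 28-degree in-plane limit where the full circle is not
needed), maximizing masked normalized cross-correlation. Two numerical
details matter:

* both reference and particles are band-limited by a 0.6-voxel Gaussian
  before scoring — trilinear resampling smooths fractional-grid bank
  entries but not the identity entry, and without equalizing that, weakly
  contrasted searches (e.g. the nearly z-invariant MT wall) systematically
  favor unshifted grid points;
* the scoring mask is tapered at the box faces by the shift limit, since a
  shifted reference cannot fill those voxels and the zero-fill would
  otherwise penalize large shifts.

`average()` resamples particles into the common frame; with
`wedge_compensation` the Fourier sum is divided by the per-voxel wedge
coverage (floored at 10% of its maximum). `fsc()` and `resolution_at()`
implement shell correlation with half-sets split by filament, so particles
from one MT never land in both halves.

## Polarity determination

`determine_polarity()` follows the classification flow: one alignment pass
against a rendered reference, multivariate statistical analysis (PCA of
the masked, aligned boxes), a scan of the leading eigenvectors for the one
that separates polarity, one round of two-reference classification, 80%
per-MT cc cleaning, and a strict >70% vote per MT.

Three design choices were genuinely open and are resolved as follows:

* **Achiral initial reference.** The phase/register lock uses a rendered
  lattice with `slew_tilt = 0`. A chirality-bearing reference imprints its
  own handedness onto every noisy particle (reference bias), which
  measurably erases the polarity signal at SNR 0.5.
* **Wedge mean imputation before PCA.** Each particle's unmeasured Fourier
  region is filled with the particle-set mean spectrum. Without it the
  per-particle wedge orientation (which rotates with the spin lock)
  dominates the covariance and the polarity eigenvector is not found. Full
  constrained PCA is out of scope.
* **Per-MT coordinate clustering and cross-validated references.** The
  eigenvector scan clusters per-MT mean coordinates (1-D 2-means, fixed
  deterministic initialization) rather than single particles — polarity is
  a per-filament property, and at desk scale (hundreds of particles rather
  than tens of thousands) averaging the coordinate over each MT's
  particles is what makes the scan reliable. The classification round then
  rebuilds each class reference excluding the filament being scored, so no
  MT's own particles bias its references; scoring is masked normalized
  correlation in the imputed aligned frame.

The class averages are labeled plus/minus by `slew_sign()` — the angular
lag between inner (9 nm) and outer (12.5 nm) wall profiles, measured on a
cross-section projected over one full dimer repeat (a thinner slab samples
alpha and beta monomers unevenly across pfs because of the helical stagger
and degrades the lag estimate). The same reading applied to per-MT
averages is the automated equivalent of per-MT visual inspection and is
reported alongside the vote for the two-route consistency check.

## Protofilament number and transitions

`detect_pf_transitions()` aligns particles to a common reference, then
runs three rounds of multireference alignment against rendered 12- and
13-pf references (particles may switch classes each round; emptied classes
freeze their reference). Per-MT assignment follows the two-stage rule:
strictly more than 95% in one class assigns automatically; otherwise each
class's per-MT average must display its own architecture (angular-power
count restricted to the candidate classes, since the wedge throws +/-2
harmonic sidebands, e.g. 11/15 around a true 13), and a transition is
called only when both classes pass and each forms a contiguous run of more
than 20 particles (isolated flips shorter than 3 particles are suppressed
first). The transition position is the midpoint between the facing run
ends — unbiased under symmetric noise. `count_pfs()` itself reports ND
when the peak-to-runner-up angular power ratio is below 1.5, when the
winning harmonic does not clear the neighboring spectral background, or
when two independent one-repeat half-slabs of the average disagree on the
winning harmonic — the bare ratio rule alone lets pure noise "win" about a
third of the time, which the extra consistency checks reduce to a few
percent. The wall annulus is located from the radial intensity profile, or
taken at the canonical lattice radius when the geometry is known.

## Luminal particle quantification

`detect_mips()` samples every 2 voxels along the lumen and scores a
masked normalized correlation against a soft-sphere reference
(bootstrapped over 5 rounds from the best-scoring positions). Particle
positions are then extracted from the correlation profile by greedy
matching pursuit: take the highest residual peak, subtract a
single-particle response kernel (triangular, 6-nm half-width, measured
from isolated particles), repeat until the residual falls below
threshold. At the near-hard-core packing a busy lumen reaches (gaps close
to the 9-nm particle diameter), a plain local-maximum rule fuses
neighbors into one plateau and can miss a third of the particles on the
densest MTs; the pursuit separates them. Each accepted spike is emitted
together with one companion sample on the side away from its nearest
neighbor, so the cleaning rule ("at least 2 particles within 5 nm" keeps
the best one) receives the support it expects without bridging adjacent
particles into one cluster. Two gates replace the manual cleaning step of
an interactive workflow, both calibrated on synthetic receiver-operating
curves against planted ground truth and then frozen: a correlation
threshold of 0.10, and a density-contrast gate requiring the spherical
shell where the ring motif lives to rise at least 20% of a
wall-calibrated particle amplitude above the local luminal baseline (a
running lower quartile over 120 nm, so lattice-break regions — where less
wall density leaks into the lumen — keep a fair baseline). The contrast
gate is what rejects correlation peaks in an empty lumen, where
normalized correlation alone is meaningless. At SNR 1 this yields
precision 0.99 and recall 0.98 against planted particles; at SNR 0.5,
precision 0.99 and recall 0.97.

Densities are counts over filament length; the break/end analysis counts
within the break interval and in 100-nm windows starting at the break or
end boundary (windows truncated at the MT, the two break sides averaged),
and compares expected vs observed with paired two-tailed t-tests.
`average_mips()` performs a free-orientation (coarse cone grid) alignment
under a spherical mask and reports the half-set FSC at the 0.5 cutoff.

## End morphology

Ends are described by traced per-pf contours whose first two points define
the straight wall segment. The end axis is the mean wall-segment direction
(not a global filament fit, matching the contour convention); deviation
paths emit points whose radial distance from the wall exceeds 2 nm (about
one monomer radius — the threshold is a parameter) as (axial advance,
outward deviation) pairs measured from the end of the wall segment; taper
length is the axial spread of the contour terminal points, with no
extrapolation beyond the last traced point. `make_end_contours()`
generates contours with known straight lengths and circular-arc flares so
taper and curvature recovery can be tested round-trip.

## Statistics and reporting

Summary statistics are mean and SD (n-1); group comparisons use the
classic pooled-variance two-tailed t-test (paired where stated), with the
degenerate all-equal case defined as p = 1. Percentages and densities are
rounded to 2 significant figures only at the report layer; internals keep
full precision. No multiple-testing correction is applied.

## Problem sizes and determinism

The shipped analyses and tests run at desk scale, chosen so the full suite
completes on a single CPU: polarity cohorts of 20 MTs of 400 nm (about
1,000 particles), transition detection on 1-um MTs over 20 seeds, density
recovery on 100-150 MTs of 0.8-1.2 um, and 33-voxel boxes at 1-nm voxels
throughout. Every stochastic step (scene content, noise, particle
placement, clustering initialization) is seeded, and identical
configurations reproduce identical outputs bit for bit.

## Known limitations

* The slew surrogate is a stand-in for an empirically observed projection
  cue; recovering polarity here shows the classification machinery works,
  not that the surrogate is the physical mechanism.
* No CTF, dose weighting, or tilt-series reconstruction cycle: the wedge
  is applied directly in Fourier space.
* The MSA wedge handling is mean imputation, not constrained PCA.
* pf counting assumes an approximately circular cross-section; strongly
  deformed MTs would need ellipse correction before polar unwrapping.
* Break boundaries and end contours come from ground truth (or a user's
  tracing); automatic pf tracing from raw volumes is not attempted.
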