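---
title: "Subtomogram averaging of synthetic centrioles: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtomogram averaging of synthetic centrioles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(centriotome)
```

# Scope

`centriotome` implements, end to end and on synthetic data with known
ground truth, the workflow by which centriole microtubule-blade structures
are solved from cryo-electron tomograms: build a parametric centriole,
image it through a single-axis tilt scheme, reconstruct, pick and extract
sub-volumes along the nine blades, align and average them under the
missing wedge, classify along the proximal-distal axis and by B-tubule
completeness, and measure the restored 9-fold geometry. Because every
stage consumes the output of a generator whose parameters are known, every
downstream measurement is a parameter-recovery experiment.

# The generative model

## Lattices, tubules, blades

A microtubule wall is a ring of protofilaments, each an 8 nm-repeat stack
of tubulin dimers (two 4 nm monomers). The generator represents every
monomer as an isotropic 3-D Gaussian blob (default sigma 1.2 nm, unit
mass) on a cylinder: 13 protofilaments at wall-centre radius 12.5 nm for
the A-tubule, 10 at 11.5 nm for the incomplete B- and C-tubules. A
3-start helical rise (`3 * monomerOffset / nPf` per protofilament) is
applied modulo the dimer repeat; it is a convention of microtubule
geometry and none of the recovered quantities depend on it. The lattice
seam is modelled as an enlarged angular gap (default +5 deg) between
protofilaments A09 and A10.

Attached tubules are placed so that their two junction protofilaments
coincide exactly with the parent wall (the B-tubule spans the chord
between A10 and A13, the C-tubule between B07 and B10); incomplete
tubules simply omit protofilaments from the same lattice circle, which is
why the partial-B stubs (B01-B02 and B07-B10, the biogenesis
intermediate produced by `makePartialB()`) retain the curvature of the
complete tube.

Decorations are 1-4 Gaussian blobs anchored to named protofilaments,
replicated axially at a 4/8/16/24 nm period with Bernoulli occupancy:
the pinhead on A03 (elaborated in the fly doublet), the two A-C linker
halves (proximal CHO), the L-shaped linker and A09 foot (distal CHO),
the A-A hinge and wishbone (fly), and lumenal MIPs on A09/A10 (seam),
A11, B01/B02 and C01/C02. Their shapes are deliberately generic: only
anchor, offset, period and occupancy matter to the pipeline. The
linker geometries are computed from the assembled 9-fold layout so that
the two A-C linker halves meet midway between neighbouring blades and
the distal foot terminates at the neighbour's C07/C08 wall - this is
what makes "linkage closure" a measurable property of the symmetrized
ensemble rather than an assertion.

Two reported asymmetries are modelled as defaults: the A11 MIP is
proximal-only (the published text and figure panels disagree on which
domain retains it; we follow the text, and the choice is a constructor
argument), and the distal C-tubule keeps protofilaments C01-C08.

## Presets and calibration

`choPreset()` describes the hamster centriole: 440 nm long, proximal
triplet blades for the first 200 nm, distal blades (partial C, different
decorations) beyond, blade tilt 50 deg from the local tangent proximally
and 65 deg distally (the 15 deg inward rotation; the absolute tilt is
not a published number, so 50 deg is a package default - only the
change is compared to anything). `s2Preset()` is the 176 nm fly doublet
(the nearest dimer multiple to the mean 175 nm length) at the proximal
tilt. Blade reference radii (109.6 / 99.7 / 96.0 nm) are not free
knobs: they were calibrated once, with the exported
`calibrateBladeRadius()`, so that the package's own diameter convention
(below) yields the nominal ensemble diameters of 235, 220 and 210 nm,
and then frozen into the presets and the shipped YAML configs.

## Flattening

Ice-sheet flattening is modelled as an area-preserving remap of the
blade-centre ring: coordinates along the kept axis scale by (1+e),
along the squash axis by 1/(1+e), so a circle of radius R becomes an
ellipse with semi-axes R(1+e) and R/(1+e) (max/min centre distance
ratio (1+e)^2, area preserved). Blades stay rigid - only their centres
and in-plane orientations (re-tangented to the ellipse) move - which
mirrors the observation that the triplets themselves are unaffected by
whole-centriole flattening. With nine discrete blades none generally
sits on the squash axis, so the realized max/min ratio is slightly
below (1+e)^2; the tests assert the exact discrete closed form.

A separate generator preset, `distortATubule()`, bakes a 10% elliptical
distortion into the A-tubule wall itself, for the ellipticity-recovery
experiment.

# Imaging model

Volumes are rasterized analytically (each blob evaluated to 4 sigma), so
integrated mass is conserved. The tilt series is the ideal line-integral
projection after rotation about the y (tilt) axis - +60 to -60 deg at
1 deg sampling by default, 121 images - with no CTF and no dose model;
noise is white Gaussian added per image, scaled so that
(signal variance within the support mask) / (noise variance) equals the
stated SNR. Reconstruction is weighted back-projection with an exact
|f| ramp filter and bilinear interpolation. The default samplings are
1-1.5 nm voxels for sub-volume work and 2 nm (4 nm for tracing-only
runs) for whole tomograms; these are desk-scale choices, stated here
once, and every experiment in the package runs at them.

The missing wedge is handled analytically throughout: a frequency f
passes a (possibly rotated) wedge test iff R f lies in the region swept
by the tilt range, i.e. the fold of atan2(-fz, fx) into (-90, 90] lies
inside [theta_min, theta_max]. This replaces mask resampling with an
exact point test; on even grids the Nyquist planes alias +f and -f onto
one voxel, so masks are additionally symmetrized (a self-aliased
frequency passes only if both aliases do), which keeps every mask
exactly Friedel-symmetric - without this the constrained correlation is
no longer exactly a real-space correlation of wedge-filtered volumes.

# Alignment and averaging

All similarity is constrained cross-correlation: Fourier-restricted to
the intersection of both inputs' wedges and the alignment low-pass, DC
excluded (mean subtraction), variance-normalized within the region. The
implementation is verified against an independent real-space oracle
(Pearson correlation of wedge-filtered copies) to 1e-3 on random
volumes.

`alignParticles()` runs an exhaustive local grid search over the three
ZYZ Euler offsets (intrinsic, reference-to-tomogram, stated once and
used everywhere), with ties broken toward the smallest total offset and
then lexicographically, followed by an FFT translational search with
parabolic sub-voxel refinement inside the shift window. Two
implementation choices matter:

* the wedge filter is applied to the reference once per particle at the
  particle's current orientation, not re-applied per candidate rotation;
  over a local (+/-8 deg) search the wedge rotates negligibly, and this
  turns an FFT per candidate into one FFT per particle. The recovery
  properties (90% of particles within one grid step at SNR 0.5) are what
  the tests check, and they hold.
* the orientation search operates on content de-shifted by the current
  translational estimate; without this, true shifts of 1-2 voxels bias
  the angular search (we measured up to ~6 deg on noiseless data), and
  with it noiseless recovery is within one grid step.

Defaults: +/-8 deg at 2 deg for the three angles, +/-6 nm shifts at
1 nm, 2.5 nm low-pass during alignment (4-5 nm when the data are
sampled at 1.5-2 nm), final maps unfiltered. A data-derived starting
reference triggers a coarse in-plane (psi) pre-scan at the first
iteration; the pipeline also uses that pre-scan to absorb the in-plane
error that flattening induces in tangent-derived initial orientations.

Averaging accumulates each aligned sub-volume's Fourier transform and
its analytically rotated wedge, and divides by the accumulated coverage
floored at 1% of its maximum. Half-sets are assigned by a seeded
shuffle then alternation; from the second iteration each half refines
against its own half-map (gold standard), and `computeFSC()` reports
the 0.143 crossing by linear interpolation between shells.

Decoration periodicity uses 40 nm (5-heterodimer) boxes: the scaled
tubulin-only model is subtracted, the positive residual integrated per
axial slice, and the biased (divide-by-N) autocorrelation evaluated at
the 4/8/16/24 nm candidates. The biased normalization is deliberate:
with unbiased normalization all harmonics of the true period tie on
clean data, while the biased estimator decays with lag and lets the
fundamental win.

Protofilament counting samples the maximum density on an annulus around
the tubule wall as a function of angle (over the central 24 nm), smooths
circularly (sigma 4 deg, well under half the ~28 deg peak spacing), and
counts cyclic local maxima by prominence relative to the 5-95 percentile
span. Prominence rather than an absolute threshold is essential: the
junction protofilaments carry double density (two walls coincide), so
peak heights vary several-fold across one ring.

# Classification

`maskedClassify()` is deterministic hard-assignment classification
without alignment: wedge-filled (missing-wedge voxels replaced by the
current global average, so wedge orientation cannot drive clustering)
masked voxel vectors are reduced by PCA and k-means seeds the classes;
then up to 100 rounds alternate rebuild-class-averages /
reassign-to-max-masked-CC, stopping when assignments are stable. An
emptied class is re-seeded from the most dissimilar particle (logged).
This replaces marginalized-likelihood classification with a
deterministic, desk-scale equivalent that produces the same qualitative
object: stable classes under a tight mask. "100 rounds" is implemented
as at most 100 iterations with convergence early-exit. Under a mask
over the B03-B06 wall it separates partial-B from complete blades at
>= 90% agreement at SNR 0.5; `selectClass()` picks the
minimum-masked-density class and flags the selection low-confidence
when the class densities are indistinguishable.

# Geometry

`refitPositions()` projects refined particle centres onto the plane
perpendicular to the centriole axis. The axis is the mean of per-rod
principal directions - a global PCA would pick a cross-section direction
whenever the ring diameter exceeds the sampled axial extent (as it does
for a 200 nm domain of a 220 nm-wide centriole).

Ellipse fitting is the direct least-squares conic fit constrained to
ellipses (the numerically stable 3x3 block formulation), on centred and
scaled coordinates. Map ellipticity extracts the per-angle wall radius
(parabolic sub-sample refinement), discards angles whose peak is weak
relative to the median per-angle peak, trims radial outliers around the
median radius (lumenal MIPs and external linkers otherwise hijack
specific angles coherently), and fits. Ellipticity is reported as
100 (a - b) / a; the alternative 100 (a/b - 1) convention is one line
away, and the fitted axes are returned so either can be formed.

`symmetrize()` places a blade at nine 40 deg azimuths at the supplied
radius, oriented so the blade long axis sits at the supplied tilt from
the local tangent. The long axis of a density map is measured by
ring-template matching of the tubule centres (grid search with
parabolic refinement, constrained by the rigid inter-tubule distances
of the canonical lattice - for partial C-tubules an unconstrained
search locks onto spurious rings). Symmetry parameters are inputs,
mirroring the use of externally published geometry: the package never
estimates 9-fold geometry from flattened data. A blade *point model*
can be symmetrized instead of a map, in which case the 9-fold symmetry
of the construction is exact (rigid transforms of the blob set); on
density, rotation tests are limited by trilinear interpolation error
(of order h^2 / 8 sigma^2, several percent at these samplings), which
is why the density-level symmetry test uses correlation rather than a
pointwise RMS criterion.

Measurement conventions, stated once:

* **diameter** - threshold at 20% of the density maximum; per 2 deg
  azimuth bin take the outermost above-threshold radius; the diameter is
  the mean over azimuths of the through-axis chord. The preset radii are
  calibrated against exactly this convention.
* **blade tilt** - angle between the blade long axis (A-tubule centre to
  outermost tubule centre) and the local tangent at the tubule-centroid
  azimuth, positive when the outer end rotates toward the axis. On
  ensembles the nine-fold-folded, axially collapsed density is measured;
  `tiltChange(proximal, distal)` is the inward rotation between domains.

`rebuildComposite()` resamples each particle's class map back into
tomogram coordinates at its refined pose, averaging overlaps, and
reports per-rod run-length statistics of the class labels - the
observable behind "entire rods are complete or partial".

# What the synthetic data do and do not show

The generator reproduces the geometry and decoration logic of real
centrioles, the missing wedge, and white noise at variance-ratio SNR. It
does not model the contrast transfer function, dose-dependent damage,
alignment errors of the tilt series itself, gold fiducials, crowding by
pericentriolar material, or conformational heterogeneity beyond the
explicit partial-B and domain switches. Passing tests therefore
demonstrate that the pipeline's estimators are unbiased and precise
under the stated imaging model - not that they would survive every
pathology of real micrographs. Conversely, because acceptance is
parameter recovery, any systematic bias in an estimator (we found and
fixed two this way: the shift-coupled angular search and the
quantization of tubule-centre location) is visible immediately.

# Problem sizes and determinism

All experiments are sized for a single CPU: 200 segments of 48^3 at
1.5 nm for architecture and ellipticity recovery, full-length centrioles
rasterized at 2 nm (4 nm for tracing) for the pipeline runs, 32-48^3
boxes for the property suites. Every stochastic step draws from a named
seed in the run config (model, noise, halves, classify); re-running a
config reproduces particle tables bit-identically, and the test suite
asserts this end to end.

# Known limitations

* The alignment wedge approximation (filter at the current orientation)
  is only valid for local searches; a global orientation search would
  need per-candidate wedge handling.
* Rod tracing assumes rods roughly parallel to the tilt axis, as in the
  simulated geometry; strongly tilted centrioles would need a generic
  filament tracer.
* The hard-assignment classifier needs a sensible k; it does not select
  class counts automatically.
* Tubule-centre location assumes the canonical lattice radii; exotic
  protofilament numbers would require passing custom radii.
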