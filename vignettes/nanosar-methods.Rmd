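---
title: "Methods: quantifying ssDNA-SWCNT sensor responses and binding dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying ssDNA-SWCNT sensor responses and binding dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanosar)
library(dplyr)
```

nanosar implements the computational layer of a structure-activity study
of catecholamine sensing by single-walled carbon nanotubes (SWCNTs)
noncovalently wrapped in single-stranded DNA. The sensor readout is the
near-infrared excitonic emission of the nanotube; an analyte that binds
the DNA-nanotube corona modulates that emission, and the relative
intensity change ΔF/F = (F − F₀)/F₀ is the response. The package covers
four analysis stages — fluorescence screening, descriptor correlation,
protonation modelling, and molecular-dynamics trajectory metrics — plus
a seeded synthetic-data generator that stands in for raw spectra and
microsecond trajectories, which are not deposited with the study.

## Screening model

Each plate well is read as an emission spectrum before analyte addition
(the baseline, F₀) and at a series of timepoints afterwards. The
response read defaults to 30 minutes, the read the screen is scored on;
it is a parameter of `screen_plate()` because the same trends hold at
other timepoints. Processing is:

1. blank subtraction, pointwise, against the mean spectrum of the
   plate's blank wells at the matching timepoint. Negative intensities
   are kept — clipping would bias the integrals;
2. trapezoidal integration over wavelength, either the full grid or a
   chirality window (the (9,4) peak window, since only that species is
   modelled in the MD arm of the study);
3. ΔF/F per well, averaged over the (default three) replicate wells;
4. normalization to the plate-matched dopamine mean, so dopamine is
   exactly 1.00. Two replicate conventions are exposed: the default
   divides the replicate-mean ΔF/F by the dopamine replicate mean
   ("ratio of means"); the alternative pairs replicate *i* with
   dopamine replicate *i* and averages the ratios. They coincide in the
   noise-free limit and differ only at second order in the noise; the
   ratio-of-means default is the convention that makes the reference
   exactly 1 regardless of replicate balance;
5. categorization: group I (≥ 1.00), II (0.75–1.00), III (0.15–0.50,
   closed), IV (< 0.10). The published category definition leaves
   (0.10, 0.15) and (0.50, 0.75) undefined; `classify_response()`
   returns `"unassigned"` there rather than silently extending a bin,
   so the ambiguity stays visible downstream.

```{r screening}
lib <- tibble::tibble(analyte_id = c("DA", "T", "1", "OO"),
                      true_normalized = c(1, 0.208, -0.056, 0))
ds <- generate_screen_dataset(lib, noise_sd = 0, seed = 11)
screen_plate(ds$plate, ds$map, window = peak94_window())
```

The `0.208` and `-0.056` rows are the printed normalized responses of
catechol (ortho-dihydroxy, modest response, group III) and resorcinol
(meta-dihydroxy, no response, group IV) — the pair that anchors the
structural rule below.

## Descriptor correlations

`correlate_descriptors()` joins a response table with a descriptor
table (Hammett σ, computed HOMO energies, experimental reduction
potentials) and reports, per descriptor, Pearson's r with the two-sided
p from the t transform, plus the least-squares line. Analytes missing a
descriptor are dropped pairwise and counted — the study analyzes
overlapping compound subsets (9 compounds with measured reduction
potentials, 18 with Hammett values, the full library for HOMO) rather
than imputing. No multiple-testing correction is applied by default,
matching how raw r/p values are reported; a Bonferroni option exists.

Group comparisons (charged vs neutral analytes) use the equal-variance
Student's t test by default with Welch as a flag; the published
analyses do not state the flavor, and with the group sizes involved the
two rarely disagree materially — both are available so either
convention can be reproduced.

`heuristic_response_rule()` encodes the study's necessary condition for
a response: vicinal (ortho) hydrogen-bond donors on a π-conjugated
scaffold. It is necessary, not sufficient — satisfying it does not
guarantee a response, but no high-response compound violates it.

## Protonation microspecies over pH

Sensor responses collapse at high pH, tracking analyte deprotonation.
With site pKa values consumed as inputs, `fraction_protonated()` is the
Henderson–Hasselbalch fraction and `microspecies_profile()` enumerates
all 2^k protonation microstates under an **independent-site
approximation**: each microstate's fraction is the product of its
per-site fractions. Site-site coupling (microstate-specific pKa shifts)
is not modelled — the commercial predictors used to obtain pKa values
do capture coupling, so profiles for strongly coupled polyprotic
analytes are approximate. Fractions sum to 1 at every grid point by
construction (asserted to 1e−9 in the tests). The default grid is pH 2
to 13 in steps of 0.1, the experimentally measured range.

The juxtaposition of ΔF(pH) profiles against microspecies transitions
was a visual argument in the source study; `overlay_transition()`
operationalizes it as the Pearson correlation between ΔF and the
selected microspecies fraction, interpolated onto the measured pH
values. ΔF (not ΔF/F) is the default response variable, following the
published presentation; ΔF/F is a flag. The printed anchor values: the
dopamine ammonium (pKa 9.31) is still 99.0% protonated two pH units
below its pKa, while the low-pKa ammonium (4.96) of the fluorinated
analogue is 0.99% protonated two units above — which is why one sensor
response survives physiological pH and the other does not.

## Trajectory metrics

All metrics operate on a `trajectory_bundle`: an atom table, named
atom-index groups (nanotube; DNA with backbone tags P, O1P, O2P, O3′,
O4′, O5′; per-molecule aryl-ring and polar-group subsets), a frame
array in Å, the orthorhombic box and the time between stored frames.
`read_trajectory()` fills one from PDB/DCD via bio3d; the synthetic
module builds them in memory.

**Contact areas.** The buried-surface contact area between selections A
and B is (s_A + s_B − s_AB)/2, with each SASA computed by Shrake–Rupley
**in isolation** (only atoms of the selection occlude). The isolation
convention is what makes the formula meaningful: if other atoms
occluded, s_A + s_B − s_AB would not measure the buried interface. The
radius convention deserves a note: the source methods describe setting
"the van der Waals radius of atoms" to 1.4 Å in the VMD SASA plug-in,
which matches that tool's *probe radius* (`srad`) idiom. Read literally
it would make carbon smaller than a water molecule, so the default here
is the standard interpretation — per-element Bondi radii plus a 1.4 Å
solvent probe — with a strict-literal mode (all radii 1.4 Å, probe 0)
available for comparison. Tiny negative contact areas from finite
sphere sampling are clipped to zero. Sphere sampling uses a Fibonacci
lattice; 128 points per atom is the series default (≈1 Å² resolution
per atom), with more points available where single-call accuracy
matters.

**Surface distances.** Distances to the nanotube surface are cylindrical:
d = r_analyte − r_SWNT, the radial distance of a center of mass from
the tube axis minus the tube radius (negative inside the wall). The
axis and radius come from `fit_cylinder()` — principal axis of the
(unwrapped) nanotube coordinates, radius the mean perpendicular
distance — and the fitted (9,4) radius agrees with the chirality
closed form a·√(n² + nm + m²)/(2π) ≈ 4.52 Å to well within 2%.

**Bound time and residence time.** A molecule counts as "in proximity"
in a frame when its contact area with the target exceeds 1 Å²;
`bound_fraction()` reports the percentage of such frames. Binding
*events* are stricter: maximal runs of frames with contact area above
30 Å², and — for molecules carrying amine/ammonium groups — the group's
surface distance below 10.5 Å. Predicates are applied frame-wise with
no smoothing: a single failing frame ends an event, because the
published criteria state thresholds only and any gap tolerance would be
an undocumented parameter (it is exposed as `gap_tolerance`, default
0). The residence time τ_R = Σᵢ tᵢnᵢ / Σⱼ nⱼ is the mean event duration
pooled over the six molecules of an analyte — algebraically total bound
time over event count, equivalently the inverse dissociation rate.

**Distributions.** Polar-group distance distributions are normalized
histograms (bin width 0.1 Å) of the group-COM surface distance over
frames within 10.0 Å (closed bound), pooled over molecules; the 4 Å
area-under-the-curve is the proximity statistic, and when a molecule
carries several groups of one class the per-group AUCs are summed.
g(r) uses minimum-image pair distances normalized by the ideal-gas
shell expectation at the box density, and hydrogen bonds use the
geometric criterion D···A ≤ 3.5 Å with D–H···A within 30° of linear.

**Binding modes.** The published mode assignment (stacking on DNA,
stacking on exposed nanotube, insertion under the corona, mixtures) was
by visual inspection; `classify_binding_mode()` is an explicit
operationalization with config thresholds: per bound frame (contact >
30 Å²), a frame is SWCNT-stacking when the aryl ring sits within 5 Å of
the surface and nanotube contact dominates, DNA-stacking when DNA
contact dominates with the ring beyond 5 Å, and insertion when the ring
is at the surface under DNA contact while an ammonium projects past the
DNA shell (7 Å). The molecule's mode is the state holding > 50% of
bound frames, an even stacking split is "both", anything else "mixed".
Because the reference assignment was visual, the classifier is
validated against synthetic ground truth only.

## The synthetic world

The generator is a kinematic stand-in, not physics: the analysis layer
consumes geometry, so fidelity targets the estimators. `build_world()`
lays carbon pseudo-atoms on a cylinder at the (9,4) chirality radius (a
4 nm segment), winds three 12-nucleotide pseudo-DNA strands over the
central 60% of the segment at 3.3 Å above the surface — incomplete
coverage is deliberate, since real (GT)₆ coronas leave exposed tube and
the SWCNT-stacking mode needs somewhere to exist — and adds six copies
of a rigid analyte template (hexagonal aryl ring, vicinal hydroxy
oxygens, optional ammonium tail).

`simulate_trajectory()` drives each molecule independently through a
continuous-time Markov chain (discrete-time embedding, refused when
dt × fastest rate exceeds 0.1) and draws coordinates conditional on
state: stacked aryl rings sit at a surface offset of N(3.4, 0.2) Å
(tangent plane, anchored on an exposed patch for SWCNT stacking, over a
strand at N(6.5, 0.3) Å for DNA stacking, tail tilted radially outward
for insertion), and free molecules scatter uniformly at ≥ 12 Å from the
surface — far enough that contact areas are exactly zero. Within one
bound run the angular/axial anchor persists with small jitter, so bound
geometry is frame-coherent. A full-budget simulation would be 10⁵
frames at dt = 0.06 ns (6 μs, the study's trajectory length); the
packaged tests run coordinate worlds of 25–60 frames, which already
give hundreds of contact-area evaluations, and validate the kinetic
estimators instead on `simulate_markov_contacts()` — directly emitted
contact series with known two-state kinetics (bound areas N(60, 8) Å²,
unbound near zero; dwell times geometric with means 1/p_off and
1/p_on), 2.5 × 10⁴ frames × 6 molecules, ≈ 2 × 10³ events. At those
sizes the residence-time estimator recovers the 25-frame mean dwell
within a few percent and the bound fraction lands within sampling error
of the stationary occupancy p_on/(p_on + p_off).

What passing these tests shows — and does not. The generator emulates
binding *kinetics* and bound-pose *geometry* with known ground truth;
it does not emulate force-field energetics, DNA conformational
dynamics, solvent, or the correlation structure of real MD noise.
Estimator recovery on this world validates the measurement code
(segmentation, Eq.-level arithmetic, geometry), not claims about real
trajectories. The study's headline correlations (e.g. % bound vs ΔF/F)
depend on its 6 μs production runs, which are not deposited and are not
re-derivable at desk scale.

## Numerical choices and limitations

- Trapezoidal spectral integration; window bounds inclusive; an empty
  window overlap is an error, not a zero.
- Pearson p-values use the t transform with |r| = 1 mapped to p = 0;
  zero-variance input is an error surfaced to the caller (a flat ΔF(pH)
  profile is "non-correlatable", not r = 0).
- Cylinder fitting refuses near-spherical clouds (leading eigenvalue
  ratio < 1.5).
- Histogram conventions: left-closed bins, last bin closed, so samples
  at exactly 10.0 Å are kept.
- `segment_binding_events()` treats molecules absent from the
  amine-distance table as amine-free, per the criterion applying only
  to molecules with amine groups.
- The (9,4) emission window has no published wavelength; the package
  convention is a 1096–1160 nm window around a 1128 nm synthetic peak,
  and every analysis references the window rather than a hard-coded
  wavelength.
- Event durations are quantized in units of dt; halving the frame rate
  doubles the quantization but leaves bound fractions unbiased.
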