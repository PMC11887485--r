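# nanosar

Structure–activity analysis for ssDNA–SWCNT optical nanosensors.

Single-walled carbon nanotubes (SWCNTs) wrapped in single-stranded DNA
emit in the near infrared, and that emission is modulated when small
analytes — catecholamines and related aryl compounds — bind the
DNA–nanotube corona. nanosar is the computational pipeline for studies
of this sensor class: it turns plate-reader emission spectra into
dopamine-normalized optical responses with response categories,
correlates those responses with molecular descriptors (Hammett σ, HOMO
energies, reduction potentials), models analyte protonation
microspecies over pH, and computes the full set of molecular-dynamics
trajectory metrics used to rationalize responses — SASA-based contact
areas, cylindrical surface distances, bound-time percentages, binding
residence times, aryl stacking distances, polar-group distance
distributions with 4 Å areas-under-the-curve, radial distribution
functions, hydrogen-bond counts, and binding-mode assignment. A seeded
synthetic-data module generates spectra with prescribed ΔF/F and
cylinder-world trajectories with known Markov binding kinetics, so
every estimator is validated against ground truth.

Intended users: researchers analyzing nanotube-based optical sensor
screens and the MD simulations that accompany them.

## The statistics at the core

- **Optical response.** ΔF/F = (F − F₀)/F₀ from blank-subtracted,
  trapezoid-integrated spectra (full range or one chirality window),
  normalized so dopamine = 1.00 on each plate, then categorized:
  group I ≥ 1.00, II ∈ [0.75, 1.00), III ∈ [0.15, 0.50], IV < 0.10,
  with the published definition's gaps returned as `unassigned`.
- **Contact area.** s_contact = (s_A + s_B − s_AB)/2, each term a
  Shrake–Rupley solvent-accessible surface area of the selection in
  isolation (Bondi radii + 1.4 Å probe).
- **Surface distance.** d(t) = r_analyte(t) − r_SWNT in cylindrical
  coordinates around the fitted tube axis.
- **Residence time.** τ_R = Σᵢ tᵢnᵢ / Σⱼ nⱼ — the mean duration of
  binding events (contact > 30 Å², amine-group distance < 10.5 Å where
  applicable), pooled over the six simulated copies of an analyte;
  equivalently 1/k_off.
- **Correlation statistics.** Pearson r with two-sided p from the t
  transform; unpaired Student's/Welch's t for group contrasts;
  Henderson–Hasselbalch microspecies fractions for pH overlays.

## Worked example

Screen a small library whose true normalized responses include the
catechol/resorcinol pair (0.208 and −0.056), then recover them:

```r
library(nanosar)

lib <- tibble::tibble(analyte_id = c("DA", "T", "1", "OO"),
                      true_normalized = c(1, 0.208, -0.056, 0))
ds  <- generate_screen_dataset(lib, noise_sd = 0, seed = 11)
screen_plate(ds$plate, ds$map, window = peak94_window())
#> # A tibble: 4 × 9
#>   analyte_id    F0     F     dff dff_peak94 normalized category     n    sd
#>   <chr>      <dbl> <dbl>   <dbl>      <dbl>      <dbl> <fct>    <int> <dbl>
#> 1 1           69.4  68.5 -0.0140    -0.0140    -0.0560 IV           3     0
#> 2 DA          69.4  86.8  0.25       0.250      1      I            3     0
#> 3 OO          69.4  69.4  0          0          0      IV           3     0
#> 4 T           69.4  73.0  0.0520     0.0520     0.208  III          3     0
```

Dopamine normalizes to exactly 1 (group I); catechol's modest 0.208
lands in group III; resorcinol's −0.056 is group IV (no response) —
moving the hydroxy donors from ortho to meta abolishes the response.

Binding kinetics from a contact series with known two-state rates
(mean dwell 25 frames bound, stationary occupancy 1/3):

```r
sim <- simulate_markov_contacts(p_on = 1/50, p_off = 1/25,
                                n_frames = 25000, dt = 1, seed = 7)
ev  <- segment_binding_events(sim$series, area_threshold = 30, dt = 1)
residence_time(ev)
#> Residence time tau_R = 24.6 ns over 2037 events
bf <- bound_fraction(sim$series)
attr(bf, "pooled")
#> 33.4   # percent; stationary expectation 33.3
```

The residence-time estimator recovers the 25-frame mean dwell within
2%, and the bound fraction sits within sampling error of
k_on/(k_on + k_off).

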