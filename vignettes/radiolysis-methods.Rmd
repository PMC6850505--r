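---
title: "Models and methods: track-structure transport and water-radiolysis chemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: track-structure transport and water-radiolysis chemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackchem)
```

`trackchem` simulates what ionising radiation does to liquid water at the
nanometre/picosecond scale, in three coupled stages, and reports the
standard observables of radiation chemistry: G-values (molecules per 100 eV
of deposited energy), their time profiles from 1 ps to 1 µs, radial dose
distributions, and the dependence of yields on linear energy transfer
(LET). This vignette explains the models, the parameters that matter, the
numerical choices, and the limitations — in particular what the synthetic
track generator does and does not emulate.

## Stage 1: discrete physics transport

Charged particles (electrons, protons, neutral hydrogen, the three helium
charge states) are transported interaction by interaction: every elastic
scattering, electronic excitation, ionization, vibrational excitation,
dissociative attachment and charge-changing collision is an explicit,
discrete event. Condensed-history grouping is deliberately not used — the
spatial structure of the track at nanometre resolution *is* the quantity
of interest, because the clustering of ionizations drives all the
chemistry that follows.

Per process, an exponential free path is sampled from the tabulated total
cross section at the particle's energy (`sample_step_and_process()`); the
shortest path wins and the interaction is applied
(`apply_interaction()`). Energy bookkeeping is exact per interaction: the
primary's energy loss equals the local deposit plus secondary kinetic
energy. Binding and excitation energies are counted as locally deposited,
which is also what the G-value normalisation ("energy deposition in the
target") expects. Atomic de-excitation (Auger cascades, fluorescence) is
not modelled; the binding-energy remainder is deposited at the ionization
site.

Particles are tracked down to a kind-specific cut (7.4 eV for electrons,
100 eV for protons/hydrogen, 1 keV for helium) and then deposit their
remaining energy locally. Electrons are special: once their energy falls
to 8.22 eV — the lowest electronic excitation level of liquid water — they
can no longer excite the medium and leave the transport loop as *solvation
candidates*, to become hydrated electrons in stage 2. The 7.4 eV cut is
retained as the hard lower edge for exotic table configurations; with the
default constants the 8.22 eV hand-off always fires first for electrons.

Cross sections are consumed as data, not computed from models. The bundled
toy tables (`toy_xs_tables()`) are simple constants and gentle power laws
with fixed-loss samplers: they are schema-complete and exercise every code
path (all five electron processes, proton/hydrogen charge exchange, the
helium charge-state cycle), and they are deliberately *not* a quantitative
liquid-water model. Externally produced tables in the same YAML schema
drop in without code changes. Density scaling multiplies the molecule
number density in the free-path sampling only; the chemistry tables are
fixed to liquid water.

## Stage 2: physicochemical conversion

Activated water decays within femtoseconds into the seven tracked species
(H3O+, ·OH, H·, e_aq, OH-, H2, H2O2). The branching table is:
ionized water always gives H3O+ + ·OH (after proton transfer to a
neighbour); the A1B1 excitation dissociates to ·OH + H· (65%) or relaxes
(35%); the B1A1 excitation auto-ionizes (55%, giving H3O+ + ·OH and a
hydrated electron), dissociates to 2·OH + H2 (15%) or relaxes (30%);
Rydberg/diffuse-band excitations auto-ionize (50%) or relax (50%);
dissociative attachment always gives ·OH + OH- + H2. Relaxation returns
the molecule to the ground state and deposits the excess energy locally.

Two placement rules carry all the spatial information this stage adds:

* **Fragment separation.** Dissociation fragments are placed back-to-back
  along a random axis, 0.8 nm apart (configurable). The fragments are born
  with kinetic energy and migrate while thermalising, so the relevant
  scale is the thermal migration distance, not the O–H bond length. A
  bond-length-scale separation (0.24 nm) was rejected during development
  on a qualitative ground: it puts the A1B1 siblings ·OH + H· essentially
  at contact (their reaction radius is 0.19 nm), so G(H·) *falls* with
  time, while every published table shows it rising slightly as
  e_aq + H3O+ replenishes H·.
* **Electron thermalisation.** Solvation candidates are displaced
  isotropically with an exponentially distributed radial magnitude of mean
  6 nm (configurable) before becoming e_aq at 1 ps. Published estimates of
  sub-excitation electron thermalisation in liquid water span roughly
  2.5–12 nm depending on the model; 6 nm is mid-range. This is the single
  most influential free parameter of the package: it controls how much of
  the early e_aq population survives recombination with ·OH and H3O+.

## Stage 3: step-by-step diffusion–reaction chemistry

From 1 ps to 1 µs the population evolves by repeating four kernels
(`run_chemical_stage()`):

1. **Pair search and contact reactions.** All reactive pairs are found
   with their distances. A pair closer than its reaction radius reacts
   immediately. Radii come from the Smoluchowski relation
   $R = k / (4\pi N_A D_{sum})$ applied to the tabulated rate constants —
   e.g. 0.506 nm for e_aq + ·OH but only 0.104 nm for ·OH + ·OH.
   Conflicts (a molecule wanted by two reactions in the same step) are
   resolved greedily by increasing pair distance with a stable index
   tie-break; each molecule reacts at most once per step.
2. **Dynamic time step.**
   $\Delta t = (d_{min}-R)^2 / \bigl(8(\sqrt{D_A}+\sqrt{D_B})^2\bigr)$
   for the closest surviving pair (reducing to $(d_{min}-R)^2/32D$ at
   equal coefficients), so that diffusion over $\Delta t$ is unlikely to
   carry any pair across its reaction radius unnoticed. The step is
   clamped below at $\Delta t_{min} = 1$ ps and capped so output
   checkpoint times are hit exactly.
3. **Diffusion.** Every molecule takes an isotropic Gaussian step with
   per-axis standard deviation $\sqrt{2D\Delta t}$ (so the mean squared
   displacement is exactly $6D\Delta t$). Molecules leaving the box are
   removed permanently; with the default geometries the 1 µs r.m.s.
   displacement (53–134 nm across the diffusion-coefficient table) is
   small against the box, and losses are rare.
4. **Brownian-bridge check.** Only when the step was clamped (the step
   actually taken exceeds the safe step) can pairs cross during
   diffusion. Each surviving candidate pair then reacts with probability
   $p = \exp\bigl(-(d_i-R)(d_f-R)/((D_A+D_B)\Delta t)\bigr)$, clipped to
   $[0,1]$ and set to 1 whenever an endpoint is inside $R$. Accepted
   events are resolved with the same conflict rule; products are placed at
   the parents' path midpoints.

Product placement is: one product at the reactants' midpoint, two products
on the parent positions (first product to the first-listed reactant),
the third product of the bimolecular 2 e_aq channel at the midpoint.

### Numerical and design choices

* **Internal units** are nm, ps and eV. SI-configured quantities are
  converted once at registry build time (1 m²/s = 10⁶ nm²/ps), which keeps
  all hot-loop arithmetic near magnitude one.
* **Identical-reactant channels** (2 e_aq, ·OH + ·OH, H· + H·) use the
  printed rate constants with no statistical factor in the radius
  derivation. Whether a factor of 2 belongs in the Smoluchowski relation
  for identical pairs is a genuine convention ambiguity; the no-factor
  reading is the package default and `build_registry(identical_reactant_factor = 2)`
  exposes the alternative. Empirically, the default under-produces the
  molecular products H2 and H2O2 by some 20–30% against the reference
  1 µs yields while leaving all other species within ~10% — precisely the
  signature the factor would remove — so this is the leading suspect for
  that residual.
* **Pair-search acceleration.** The production engine uses a hashed cell
  grid with a 4 nm cutoff: large enough to contain every contact radius
  and every bridge pair whose acceptance probability exceeds 10⁻³⁰. The
  exact global minimum distance (needed for the time step) is recovered by
  widening the cutoff geometrically until a reactive pair is found or the
  implied step already exceeds the checkpoint cap. An exhaustive
  O(N²/2) reference engine (in C++ and again in pure R) consumes the
  identical RNG stream; the test suite asserts bit-identical trajectories
  across all three for the same seed, so the acceleration is
  observationally invisible.
* **RNG discipline.** A single R random stream with a fixed consumption
  order: diffusion draws in storage order (x, y, z per molecule), one
  uniform per bridge pair with p above the floor, pairs in index order.
  Given the seed, results are bit-reproducible; per-event substreams are
  simply per-event seeds.
* **Step-scheme accuracy.** The 1 ps clamp plus bridge check is the
  algorithm's dense-track workhorse and its known approximation: the
  bridge expression is the exact crossing probability for the 1D
  half-line, and in 3D it slightly over-accepts. In a deliberately dense
  homogeneous box (every step clamped) the effective bimolecular rate
  constant runs ~10–15% above the tabulated k; in the dilute regime,
  where the adaptive step resolves encounters, the fitted rate sits within
  the diffusion transient (~+7% over a 1–10 ns window) of the tabulated
  value. The kinetics acceptance test therefore measures in the dilute
  regime; isolated-pair reaction probabilities reproduce the exact
  absorption result $P = R/r_0$ within Monte-Carlo error at all tested
  separations.

## The synthetic track generator

High-fidelity 1 ps species distributions require high-fidelity cross
sections, which are external data. To make the chemical stage quantitative
without them, `simplified_track()` generates 1 ps populations that are
*calibrated in yield* and *modelled in space*:

* **Yields.** `calibrate()` solves the per-100 eV frequencies of the four
  product channels ({H3O+, ·OH, e_aq}, {·OH, H·}, {2·OH, H2},
  {·OH, OH-, H2}) from target 1 ps G-values by least squares — exactly
  solvable because each channel's products are fixed; the three
  ionization-like channels are degenerate in yield space and are
  aggregated. Presets carry the published 1 ps columns for 750 keV
  electrons and 20 MeV protons; the 5 MeV proton preset reuses the 20 MeV
  yields (1 ps yields are insensitive to LET in this range) with its own
  LET.
* **Space.** Energy is deposited in *spurs* of 62.5 eV on average, spaced
  exponentially along a straight track axis with mean spacing
  (spur energy)/LET; each spur receives Poisson numbers of channel events;
  activation sites spread around the spur centre with an exponential
  radial profile of mean 1 nm; sites dissociate with the stage-2 placement
  rules. LET values for the presets are standard liquid-water stopping
  powers (0.185 eV/nm for 750 keV electrons; 2.61 and 7.91 eV/nm for 20
  and 5 MeV protons), log-log interpolated from a small built-in table for
  the LET scan.

What this emulates: the right number of molecules per unit energy, the
spur-clustering that drives intra-track recombination, and the
LET-controlled spur overlap that makes radical yields fall and molecular
yields rise with LET. What it does not emulate: delta-ray branches,
track-end Bragg-peak structure, the energy-loss straggling of real
inelastic collisions, and the true (unpublished) spatial correlations of
the reference simulations. Passing the chemistry tests therefore
demonstrates that the diffusion–reaction machinery reproduces reference
yields *given a faithful 1 ps configuration*, not that the toy physics
stage produces one.

Known residuals with the frozen defaults, at the reduced problem sizes the
tests use (10 × 10 keV electron events, 12–20 proton segments, ~1–7 × 10³
molecules per event): radical species and OH- land within ±10% of the
reference 1 µs columns; H2 and H2O2 sit 20–30% low (see the
identical-reactant note above); below ~1 eV/nm the H2O2-vs-LET trend
flattens inside a very large event-to-event spread (the reference codes
also report their largest standard deviations at low LET); and OH- shows
a real few-ps dip while spur-core H3O+ neutralises the small
attachment-born population, before e_aq-driven production takes over.

## Observables

`g_value()` is the literal definition (100 × count / eV deposited, with
the deposit measured inside the scoring target). `aggregate_events()`
reports the per-event mean and sample standard deviation at each output
time (the deposit-weighted pooled mean is available as an option; the
per-event mean is the default and the standard deviation is the
event-to-event spread, not the error of the mean). `radial_dose()` scores
deposits into 100 logarithmic cylindrical shells between 1 and 250 nm
around the beam axis over a 10 µm height, normalised per incident
particle, and `compute_let()` divides the mean per-event deposit by the
traversed path length (eV/nm ≡ keV/µm). Output checkpoints default to 10
points per decade on a log grid.

## Problem sizes and determinism

The bundled validation runs are scaled to a desk: the acceptance script
evolves ten ~50 keV electron track segments (~7–8 × 10³ molecules each)
and twenty 1 µm proton segments to 1 µs, a few × 10⁴ time steps per
event; the test suite uses 10 keV electron events. All randomness flows
from the single seed argument; identical configuration and seed give
bit-identical outputs.
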