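---
title: "A stochastic spatio-temporal model of cardiac calcium cycling on reconstructed intracellular structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic spatio-temporal model of cardiac calcium cycling on reconstructed intracellular structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(caspatial)
```

## The model

`caspatial` simulates intracellular Ca^2+^ cycling in a ventricular
cardiomyocyte in three spatial dimensions, with the geometry of the key
regulatory structures resolved on a 0.35 µm voxel lattice:

* the **cytoplasm**, a voxel grid carrying the bulk free Ca^2+^
  concentration (µM), with instantaneous buffering and dynamic troponin
  binding;
* a **restricted buffering subspace** (rbSS), a thin diffusive layer with a
  tenth of the cytoplasm's volume that functionally couples neighbouring
  dyads before Ca^2+^ equilibrates with the bulk;
* the **network SR** (nSR, mM), reduced from its full 3-D morphology to a
  3-D network of 1-D strands: concentrations live on nodes and diffuse only
  along explicitly listed links;
* several thousand (in a whole cell) **dyads**: point-source junctions where
  a cluster of 100 ryanodine receptors (RyRs) on a junctional-SR (jSR)
  terminal faces 15 L-type Ca^2+^ channels (LTCCs) across a ~10^-3^ µm^3^
  cleft.

The three diffusive domains obey isotropic reaction–diffusion equations,
discretised with the 6-neighbour finite-difference Laplacian, zero-flux
boundaries, and forward Euler at a fixed step of 0.01 ms (the CFL bound
`dt < h²/6D` is enforced per domain and violations are errors, as are
negative concentrations — there is no silent clipping). The cytoplasm
equation carries the rapid-buffering factor
β(Ca) = (1 + Σᵢ BᵢKᵢ/(Kᵢ+Ca)²)⁻¹ on both the diffusion and reaction terms,
exactly as the continuous equation is written.

Reaction terms are *map-gated*: membrane fluxes (NCX, sarcolemmal pump,
background influx) are evaluated only at voxels of the surface-sarcolemma
and t-tubule maps (`SS_M`, `TT_M`), and SERCA uptake minus leak only at
voxels hosting an SR strand node, each scaled by the ratio of total to map
voxels so the whole-cell flux is independent of map coverage. In
semi-idealised mode every voxel carries every flux and the dispatch reduces
bitwise to the continuous form — this equivalence is a test.

### Dyads

Each dyad's cleft Ca^2+^ is the analytic quasi-steady solution of its flux
balance, `ca_ds = (ca_rbss + τ_ds (k_rel·ca_jsr + J_CaL)) / (1 + τ_ds k_rel)`
with `k_rel = n_open · g_RyR / v_ds`. One numerical subtlety: the
quasi-steady cleft stores no mass of its own, so the flux handed to the
subspace is the conservative `J_rel + J_CaL − d[Ca]_ds/dt`, which equals the
nominal `(ca_ds − ca_rbss)/τ_ds` whenever the cleft is stationary; the pure
nominal form leaks the cleft storage term (~`v_ds·ΔCa` per step) and fails
closed-system conservation at the 10⁻⁶-per-step level the tests demand. The
jSR refills from its nSR node with time constant `τ_jsr` and is buffered by
instantaneous calsequestrin.

Channel gating is per-channel Monte-Carlo at the fixed step: each occupied
state's movements are multinomial draws with probabilities `rate × dt`, and
any single transition with `rate × dt > 0.2` is an error demanding a smaller
step. Every dyad owns an independent counter-seeded xoshiro256++ stream, so
trajectories do not depend on dyad iteration order and a run is bit
reproducible from (geometry, configuration, seed).

The published description of this model class defers the exact Markov rate
tables to supplementary material that is not available here, so the schemes
are this package's own calibrated surrogates (all rates sit in
`default_params()` and a plain-text configuration can override any of them):

* **RyR**: a 4-state cycle C → O → I → R → C. Opening is a saturating Hill
  function of cleft Ca^2+^ (half-activation 28 µM, coefficient 3 — the
  steepness is what keeps diastolic spark rates low while cleft
  concentrations of tens of µM recruit the cluster within milliseconds),
  multiplied by a luminal jSR factor (Hill in `ca_jsr`, exponent 6,
  normalised to 1 at 1 mM) that terminates release on local depletion and
  sensitises overloaded stores. A second, store-overload pathway adds a
  basal opening rate ∝ `(ca_jsr)^14`; it is negligible below ~1.2 mM and
  produces the spontaneous sparks, waves and DADs of the overload protocols.
  Ca^2+^-dependent inactivation (O → I) and the slow I → R → C recovery
  (~500 ms) make fired dyads refractory, which both terminates the beat's
  release cleanly and provides the restitution substrate at short cycle
  lengths.
* **LTCC**: closed states d₁ ⇌ d₂ with voltage-dependent activation, the
  scalable opening step d₂ → d₃ (this is the "open-probability" knob the
  alternans and overload protocols rescale), voltage-dependent inactivation
  from d₂ and d₃, and Ca^2+^-dependent inactivation from the open state
  driven by cleft Ca^2+^, recovering only near the resting potential. The
  per-channel flux is a GHK-type expression.

### Membrane potential

A reduced action-potential model supplies Vm: INa (m³hj), INaL, Ito,
IKr (xr1·xr2), IKs (xs²), IK1 and a simplified NaK pump with fixed
intracellular Na^+^/K^+^, using human-ventricle HH formulations with
conductances recalibrated to large-mammal AP characteristics; gates advance
by Rush–Larsen. The spatial model returns ICaL, INaCa, IpCa and ICab by
summing local fluxes times volumes times Faraday's constant over the
membrane and dyad maps, divided by the reference capacitance; cell-portion
geometries multiply by `N_tot_dyads / N_dyads` so a reduced grid reports
whole-cell currents. NCX carries an allosteric cytosolic-Ca^2+^ activation
factor `Ca²/(Ca²+0.25²)`: without it, the resting efflux needed for a fast
transient tail drains the cell at diastole.

## Parameters that matter

All defaults are in `default_params()`; units are ms, µm, µM (cytosol) and
mM (SR). The load-bearing choices:

| parameter | default | why |
|---|---|---|
| `tau_ds` | 0.002 ms | cleft–subspace exchange; must be ≪ dt for the quasi-steady cleft to track its balance equation within 1–2% |
| `tau_ss` | 2.5 ms | subspace–cytosol exchange; with D = 0.3 µm²/ms the coupling length √(Dτ) ≈ 0.87 µm sits at the mean inter-dyad distance, making spark-induced-spark propagation load-sensitive rather than always-on |
| `tau_jsr` | 8 ms | jSR refill; with the luminal gate this sets local release duration and refractoriness |
| `g_ryr` | 2×10⁻³ µm³/ms | single open RyR raises the cleft by ~2 µM per channel; with Hill-3 activation this gives regenerative in-dyad recruitment without diastolic runaway |
| `vup` | 0.9 µM/ms | SERCA maximum; halving it (the alternans protocol) must still maintain the store, which is why the baseline is generous |
| `kncx` | 120 | NCX scale; sets the late transient tail together with the allosteric factor |
| `csqn_b` | 36 mM | jSR calsequestrin capacity; the releasable store behind the 0.6–0.7 µM transient |
| D (all domains) | 0.3 µm²/ms | baseline diffusivity; the nSR value supports the 0.5–2× scan and the subspace value is raised to 1 to produce single coordinated waves |

## The synthetic structure generator

`synthesize_structure()` emulates the morphology of serial block-face
electron-microscopy reconstructions: a transverse-tubule lattice (in-plane
tubes at z-disk planes with 1.8 µm period plus sparse longitudinal
connectors, ~130 nm radius), an SR mesh of thin strands (0.7 µm lattice,
~40 nm radius) spanning the volume, and jSR markers placed with probability
`jsr_rate` (default 0.1) at SR voxels apposed to a tubule, all with seeded
jitter. At these defaults a reduced cell carries SR occupying ~4% of cell
volume, a strand-node volume of ~0.0024 µm³ (the imaging-derived value is
0.00305 µm³), dyads at ~1% of coarse voxels and a mean nearest-neighbour
inter-dyad distance of ~0.75 µm — all in the range of the published
reconstructions. What it does *not* emulate: nuclei and mitochondria (no
excluded volumes), the irregularity of real tubule branching, jSR patch
shapes (markers are points), or any disease remodelling. Passing tests on
synthetic geometry therefore demonstrate the machinery, not conclusions
about any particular cell.

The structure pipeline reduces the SR by sequential 3-D medial-axis
thinning (simple border voxels deleted in lexicographic order — the
deterministic tie-break — with endpoints preserved), maps the skeleton to
the coarse lattice, and creates links only where 26-adjacent skeleton
voxels fall into 6-adjacent coarse voxels: spatially adjacent but
unconnected SR stays uncoupled, and per-node volume is total SR volume over
node count, so the reduction conserves SR volume exactly.

Two structure-module decisions worth recording. First,
`build_semi_idealized()` chooses integer lattice spacings per axis to
reproduce the detailed dyad *count* (within ~5%); for near-regular inputs
this equals rounding the mean nearest-neighbour distance to voxels, but for
clustered distributions the two rules conflict and the count is the
measurable, reported quantity, so it wins. Second, dyads whose coarse voxel
lacks a strand node after thinning are attached to the nearest node rather
than rejected; the simulation errors only if no attachment exists.

## Protocols and their measurement conventions

* **Control pacing**: BCL 1250 ms, 2 pre-pacing beats then measured beats.
  APD90 runs from the maximal upstroke rate to 90% repolarisation toward the
  pre-stimulus diastolic Vm; CaT amplitude is peak minus pre-stimulus
  diastolic mean; upstroke is the 10%-of-amplitude crossing to the peak; the
  duration-to-90% runs from the 10% crossing on the rise until decay back
  below 10% of amplitude over diastole (the printed "duration to 90% of
  peak" is ambiguous between this and time-above-10%; this package uses the
  former and logs it with the results).
* **Alternans**: `J_up` scale 0.5 and LTCC open-rate scale 0.2 at BCL
  450 ms. The alternans magnitude is mean |Aᵢ−Aᵢ₊₁|/max(Aᵢ,Aᵢ₊₁) over the
  last (up to) 10 beat pairs. Per-voxel activation phase is the first 0.3 µM
  crossing after the stimulus normalised to 180 ms (capped at 1); the phase
  variance is the summed difference of phase maps over successive
  small-amplitude cycles normalised by the same sum over the large cycles.
* **Spark hierarchy**: initial SR loads 0.8–1.2 mM, 2 s quiescent; the
  coordinated-wave condition raises the subspace diffusivity to 1 µm²/ms and
  may densify the RyR cluster distribution.
* **Two-dyad criticality**: a small box with two dyads on one SR strand;
  dyad 1 triggered by LTCC openings under AP clamp, dyad 2 carries no LTCCs
  and counts as recruited when ≥10% of its RyRs open within 100 ms.
* **Overload**: uptake and LTCC open-probability scaled ×2, 100 beats at BCL
  400 ms (the bundled tests use 30 beats on a small box; the loading
  saturates well before that), then a quiescent window. A triggered AP is a
  stimulus-free crossing of −20 mV; a DAD is any deflection > 2 mV above the
  diastolic baseline.

## Problem sizes used by the test-suite and acceptance script

The whole-cell tessellation (100 × 52 × 312–416 voxels, >13 000 dyads) is
supported by the geometry pipeline but is far larger than needed to exercise
the model, so the quantitative checks run on a reduced reference cell:
18 × 18 × 32 voxels (≈10⁴ voxels, ≈135 dyads, seeded generator defaults)
with currents scaled to the whole cell by `N_tot/N = 13094/135`. The
rapid-pacing comparisons use a 12 × 12 × 24 companion (~39 dyads), the
overload runs a 6 × 6 × 12 box, and the two-dyad study an 11 × 11 column.
Monte-Carlo property tests use 10⁵–3×10⁵ steps with batch-means standard
errors.

## Calibration status and known limitations

The free parameters (channel rate constants, conductances, flux maxima)
were calibrated against the whole-cell control-pacing characteristics of
large-mammal ventricular myocytes: APD90 345 ms, CaT amplitude 0.68 µM,
upstroke 20 ms, duration-to-90% 400 ms at BCL 1250 ms. The frozen defaults
land APD90 (~325 ms) and duration-to-90% (~420-445 ms) inside a 10% band, the
amplitude about 15% low (~0.58 µM), and the upstroke near 12 ms: in this
surrogate scheme the measures are antagonistic — dispersing dyad recruitment
to slow the whole-cell rise lowers the peak, and the release mass needed for
the amplitude lengthens the decay. The corresponding acceptance assertions
are kept at their nominal tolerances and the amplitude and upstroke checks
are expected to fail; treat them as quantified model limitations rather than
software defects. Under the alternans scalings the model produces irregular
beat-to-beat variability (magnitude ~0.1–0.19 against the 0.2 operational
cut) rather than clean period-2 alternans, and at control pacing the
beat-to-beat amplitude variability of a 135-dyad reduced cell stays near the
1/√N recruitment-noise floor (~10–15%), well above the <5% quiescence a
13 000-dyad whole cell shows; both assertions are likewise left at their
nominal cuts.

Other limitations: dyads are point sources (no intra-dyad RyR geometry);
intracellular Na⁺/K⁺ are fixed; mitochondria and myofilament mechanics are
absent (force is a saturating function of local troponin occupancy with
first-order kinetics, normalised per trace); diffusion is isotropic; the
integrator is forward Euler throughout, chosen to match the fixed-step
quasi-steady construction — halving dt changes a deterministic release
transient by <0.5%, which the tests verify.

## A worked example

```{r example}
library(caspatial)

vol  <- synthesize_structure(dims = c(60, 60, 120), pitch_nm = c(70, 70, 70),
                             seed = 42)
geom <- derive_maps(vol)
rec  <- run_paced(geom, protocol_config(bcl = 1250, n_beats = 1, seed = 1))
transient_metrics(rec, 1)

alt <- run_alternans(geom, protocol_config(bcl = 450, jup_scale = 0.5,
                                           ltcc_open_scale = 0.2,
                                           n_beats = 10, n_prebeats = 4,
                                           snapshot_every = 5, seed = 1))
alternans_metrics(alt)$magnitude

run_two_dyad(distances = c(0.35, 1.75, 2.8), sr_loads = c(0.8, 1.0, 1.2),
             n_trials = 8, seed = 3)
```
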