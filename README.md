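# caspatial

Stochastic spatio-temporal simulation of intracellular Ca²⁺ cycling in
ventricular cardiomyocytes, on voxel geometries derived from (or emulating)
serial block-face electron-microscopy reconstructions of the transverse
tubules and sarcoplasmic reticulum.

## Who this is for

Cardiac electrophysiology modellers who want to study how *intracellular
structure* — the t-tubule network, the network-SR morphology, and the 3-D
distribution of dyads — shapes Ca²⁺ sparks, waves, transient alternans and
afterdepolarisations at the whole-cell scale, without committing to an
idealised geometry.

## The model

Three diffusively coupled domains are solved on a 0.35 µm lattice with a
6-neighbour finite-difference Laplacian and forward Euler at Δt = 0.01 ms:

- cytoplasm: d[Ca]c/dt = β(Ca) (D ∇²[Ca]c + Φc), with the rapid-buffering
  factor β = (1 + Σᵢ BᵢKᵢ/(Kᵢ+Ca)²)⁻¹ and dynamic troponin binding;
- restricted buffering subspace (rbSS): a thin layer exchanging with the
  cytosol with time constant τ_ss, through which neighbouring dyads couple;
- network SR: reduced to a 3-D network of 1-D strands by medial-axis
  thinning of the full-resolution reconstruction; nodes exchange Ca²⁺ only
  along explicitly listed links, so spatially adjacent but unconnected SR
  stays uncoupled.

Reaction terms are gated to structure maps: membrane fluxes (NCX with
allosteric Ca activation, sarcolemmal pump, background influx) act on the
surface-sarcolemma and t-tubule maps SS_M and TT_M; SERCA uptake minus leak
acts at SR-node voxels. Each dyad couples a 100-channel ryanodine-receptor
cluster and a 15-channel L-type Ca²⁺ channel cluster (per-channel
Monte-Carlo Markov chains, one counter-seeded RNG stream per dyad) through
an analytically quasi-steady cleft,

    [Ca]_ds = ([Ca]_rbSS + τ_ds (k_rel [Ca]_jSR + J_CaL)) / (1 + τ_ds k_rel),
    k_rel   = n_open · g_RyR / v_ds,

with a calsequestrin-buffered jSR refilled from its strand node. A reduced
human-ventricle-derived action-potential model (INa, INaL, Ito, IKr, IKs,
IK1, INaK, background Na⁺; Rush–Larsen gating) supplies Vm; the spatial
fluxes are converted to whole-cell currents by I = Cm⁻¹ z Σ (J · F · v) over
the membrane and dyad maps, scaled by N_tot/N for cell-portion geometries.

The full scientific account — schemes, parameters, calibration status and
known limitations — is in the methods vignette,
`vignettes/calcium-cycling-model.Rmd`.

## Worked example

```r
library(caspatial)

# a reduced synthetic cell: ~3.5k voxels, ~45 dyads
vol  <- synthesize_structure(dims = c(60, 60, 120), pitch_nm = c(70, 70, 70),
                             seed = 42)
geom <- derive_maps(vol)
geom
#> cell_geometry (detailed): 12 x 12 x 24 voxels @ 0.35 um
#>   cytoplasm voxels: 3456 | SS_M: 1256 | TT_M: 500
#>   dyads: 45 | SR nodes: 1722

rec <- run_paced(geom, protocol_config(bcl = 1250, n_beats = 1,
                                       n_prebeats = 2, seed = 1))
unlist(transient_metrics(rec, 1)[c("apd90", "cat_amplitude",
                                   "upstroke_ms", "duration90_ms")])
#>         apd90 cat_amplitude   upstroke_ms duration90_ms
#>         315.7         0.572          13.8         442.6
```

APD₉₀ ≈ 316 ms, a 0.57 µM Ca²⁺ transient rising in ~14 ms and decaying to
10% of its amplitude ~440 ms after the upstroke — large-mammal ventricular
behaviour at a slow cycle length. Spark-induced-spark propagation between
two dyads on one SR strand decays steeply with separation and steepens with
SR load:

```r
run_two_dyad(distances = c(0.35, 1.75, 2.45), sr_loads = c(0.8, 1.0, 1.2),
             n_trials = 8, seed = 3)
#>   distance_um sr_load probability n_trials successes
#>          0.35     0.8       0.500        8         4
#>          0.35     1.0       0.875        8         7
#>          0.35     1.2       1.000        8         8
#>          1.75     0.8       0.000        8         0
#>          1.75     1.0       0.375        8         3
#>          1.75     1.2       0.750        8         6
#>          2.45     0.8       0.000        8         0
#>          2.45     1.0       0.125        8         1
#>          2.45     1.2       0.000        8         0
```

Rapid pacing with doubled uptake and LTCC open probability loads the store
until it releases spontaneously in a quiescent window:

```r
g <- derive_maps(synthesize_structure(dims = c(30, 30, 60),
                                      pitch_nm = c(70, 70, 70), seed = 3))
over <- run_overload_release(g, protocol_config(bcl = 400, n_prebeats = 30,
                                                jup_scale = 2,
                                                ltcc_open_scale = 2,
                                                ncx_scale = 1, seed = 4))
over$events[c("dad", "ta", "n_dads")]
#> $dad: TRUE   $ta: FALSE   $n_dads: 4
# ... and with ncx_scale = 2 the same protocol yields $ta: TRUE
```

A thin command-line interface over the same functions is installed at
`inst/cli/caspatial` (`structure synth|reduce|tessellate|perturb|stats`,
`simulate --protocol ...`, `analyze`).

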