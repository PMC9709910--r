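# tagcryst

Crystallinity and polymorph metrics for molecular dynamics simulations of
triacylglycerides (TAGs).

When a simulated fat such as 1-palmitoyl-2-oleoyl-3-stearoyl-*sn*-glycerol
(*sn*-POSt) melts or crystallizes, the interesting questions — *how many
molecules are crystalline, which ones, and in which polymorph* — are not
answered by densities or unit-cell parameters, which barely differ between
the β₁ and β₂ packings. `tagcryst` answers them from coordinates alone,
for anyone analyzing GROMACS (or similar) trajectories of TAG systems:

* **Intramolecular criteria.** A molecule is *parallel* when both the
  tail–tail (C1–1) and mid–mid (C1–2) distances between its palmitic
  (*sn*-1) and stearic (*sn*-3) chains lie within calibrated bands
  μ ± 2σ, and *stretched* when the last oleic atom is at crystalline
  distance from both chain tails (C2–1, C2–2). Bands are calibrated once
  on a perfect reference crystal (`calibrate()`).
* **Near-neighbor occupancy (NNO).** For molecule *i*, the number of
  molecules within 1 nm (between middle oleic atoms, minimum-imaged) of
  *i* in two subsequent frames. High and stable in crystals, low in
  melts; plotted as a per-molecule heat map over time.
* **Four-body polymorph detection.** Candidate 4-molecule unit cells are
  found from banded P1 (side pair, oleic-mid) and P2–1…P2–5
  (palmitic-tail) distances with the role-fixing conditions
  P2–1 < P2–2 and P2–4 > P2–5, then classified by the rotation signature
  of the oleic kinks: each molecule's chain-plane normal is the cross
  product of its two oleic half-chain vectors, and sign(nᵢ·nⱼ) = ±1
  compares rotations. Sides pointing the same way ⇒ β₂, opposite ⇒ β₁.
  A per-molecule ledger absorbs double counting; majority resolution
  yields per-polymorph percentages. The naive search is
  n(n−1)(n−2)(n−3) ≈ 10¹² tuples at n = 1000; the implementation prunes
  with periodic cell lists and is validated against an exhaustive
  compiled oracle on small systems.

A synthetic generator builds idealized β₁/β₂ lattices, melt molecules and
melting pseudo-trajectories, so the whole pipeline is testable without
running MD. Readers are provided for GRO (multi-frame) and a plain
whitespace trajectory format; XTC/TRR are not supported.

## Worked example

```r
library(tagcryst)

## calibrate all distance bands once, on a thermally jittered pure lattice
ref <- calibrate_reference(seed = 1)

## box 1: 168-molecule beta-2 crystal (84%) + 32 melt molecules
sys <- build_box1(seed = 42)
traj <- trajectory(list(sys$frame), sys$selection)
crystallinity_timeseries(traj, ref)$summary
#>   time_ps pct_parallel pct_stretched
#> 1       0           84            84

## box 2: 1200 molecules, two crystals + 600 melts
sys2 <- build_box2(seed = 42)
pm <- polymorph_timeseries(trajectory(list(sys2$frame), sys2$selection), ref)
pm$summary
#>   time_ps pct_beta1 pct_beta2
#> 1       0  33.33333  16.66667
table(pm$assignments[, 1], sys2$labels)
#>         crystal_beta1 crystal_beta2 melt
#>   beta1           400             0    0
#>   beta2             0           200    0
#>   melt              0             0  600
```

The first result says every constructed crystal molecule (168 of 200 =
84%) satisfies both intramolecular criteria and every melt fails them; the
second recovers the constructed polymorph composition (400/1200 = 33.33%
β₁, 200/1200 = 16.67% β₂) with no melt molecule misassigned.

For melting dynamics, generate a pseudo-trajectory and watch both the
crystallinity percentages and the NNO heat map collapse:

```r
traj <- make_pseudo_trajectory(sys, n_frames = 30, melt_onset_frame = 10,
                               melt_ramp_frames = 10, seed = 1)
cr <- crystallinity_timeseries(traj, ref)
plot_crystallinity(cr, "crystallinity.png")
nno_heatmap(nno_matrix(traj), "nno.png")
```

A command-line wrapper is installed at `inst/scripts/tagcryst.R`
(subcommands `run`, `synth`, `calibrate`, `intra`, `nno`, `polymorph`,
driven by a YAML config); see `vignettes/crystallinity-metrics.Rmd` for
the methods description.

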