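---
title: "Quantifying TAG crystallinity and polymorphism in MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying TAG crystallinity and polymorphism in MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagcryst)
```

## The problem

Molecular dynamics simulations of triacylglycerides (TAGs) such as
1-palmitoyl-2-oleoyl-3-stearoyl-*sn*-glycerol (*sn*-POSt) are used to study
melting and crystallization of the fats that determine the texture and
stability of food products. Two questions are hard to answer from raw
trajectories: *how many, and which, molecules are crystalline at a given
time*, and *which polymorph — the β₁ or β₂ packing — a crystalline region
is in*. Densities and unit-cell parameters of the two β forms are too
similar to discriminate them, so the actual orientation of molecules in
space has to be interrogated. `tagcryst` implements three geometric metrics
that answer both questions from coordinates alone.

## Distance bands and calibration

Every criterion in the package is a distance with a calibrated acceptance
band. Calibration (`calibrate()`) measures the relevant distance for all
molecules (or all crystallographically equivalent molecule pairs) of a
defect-free reference crystal over a short trajectory, and stores the mean
μ and standard deviation σ. A distance *d* then satisfies the criterion
when |d − μ| ≤ kσ with k = 2 by default (`tolerance_multiplier`,
configurable per call). Calibration runs once per system; references are
serialized to a flat text file (`write_reference()`).

Numerical choices worth knowing:

* σ uses the n−1 (sample) denominator. With the hundreds to thousands of
  pooled samples of a real calibration the distinction from the population
  formula is far below every band width; the choice is fixed so results are
  reproducible to the bit.
* The band check is inclusive at the boundary and adds a 10⁻⁹ nm absolute
  slack. The slack exists for one reason: a perfect static lattice
  calibrated on itself has σ = 0, and the point band must still accept the
  lattice's own distances in floating point. It is ten thousand times
  smaller than a picometer and can never change a physical decision.
* σ = 0 with k > 0 produces a warning ("band collapses to a point") rather
  than an error, since self-classification of a static lattice is a
  legitimate validation exercise.

## Metric 1: parallel and stretched molecules

A fully crystalline *sn*-POSt molecule has a characteristic conformation:
the palmitic (*sn*-1) and stearic (*sn*-3) chains pack side by side, and
the molecule spans its full extension with the oleic (*sn*-2) chain
pointing away. Two intramolecular criteria capture this:

* **parallel (C1)** — the palmitic-tail/stearic-tail distance (C1–1,
  between the 16th palmitic and 18th stearic chain atoms) *and* the
  mid-chain distance (C1–2, 9th palmitic / 11th stearic atoms) are both in
  band. Two distances are required because a single one is also satisfied
  by chains that are merely randomly close.
* **stretched (C2)** — the distances from the last oleic atom to the
  stearic tail (C2–1) and to the palmitic tail (C2–2) are both in band,
  i.e. the molecule spans its crystalline length.

`crystallinity_timeseries()` evaluates both criteria independently per
molecule per frame and reports percentages over *all* molecules in the box
(the per-molecule booleans are retained so users can see which molecules
melt first). Intramolecular distances are deliberately *not*
minimum-imaged; molecules are re-joined across the periodic boundary on
load (`make_molecules_whole()`) instead. A caveat inherited from the
method itself: molecules at a crystal surface have more chain freedom, so
under thermal motion these metrics undercount the crystal fraction
(surface molecules fail the bands while still sitting on lattice sites).
This is documented behavior, not corrected for.

## Metric 2: near-neighbor occupancy (NNO)

For molecule *i*, the NNO at frame transition t → t+s is the number of
molecules within a cutoff of *i* in **both** frames. Because a TAG is
elongated, the inter-molecule distance is the minimum-imaged distance
between middle oleic chain atoms; the default cutoff is 1.0 nm and the
default stride s = 1. Crystalline molecules keep their neighbors (high,
stable NNO); melted molecules exchange them (low NNO). `nno_matrix()`
computes the molecule × transition matrix with a periodic cell list (bin
size ≥ cutoff), and `nno_heatmap()` renders the standard visualization —
molecules on the ordinate, time on the abscissa, brightness increasing
with NNO, color normalized to the observed maximum.

Absolute NNO values depend on the lattice spacing and on how often frames
were saved, so outputs record the inter-frame times; comparisons should be
made within a run. On our idealized lattice, interior molecules
out-coordinate corner molecules (asserted in the test-suite); the absolute
interior/surface values of a real crystal are not reproduced.

## Metric 3: four-body polymorph detection

Both β polymorphs of *sn*-POSt have four-molecule unit cells whose two
molecule *pairs* ("sides") differ between polymorphs only in the rotation
of the kinked oleic chain. Detection proceeds in two stages.

**Geometry.** A candidate cell is an ordered 4-tuple (m1, m2, m3, m4) with

* (m1, m2) and (m3, m4) within the P1 band — the side pairs, measured
  between middle oleic atoms;
* the five palmitic-tail distances P2–1 (1,2), P2–2 (1,3), P2–3 (1,4),
  P2–4 (2,4), P2–5 (3,4) each within band; and
* strictly P2–1 < P2–2 and P2–4 > P2–5, which pins down the role geometry
  and makes the (2,3) distance redundant.

The P2 distances fall into three crystallographically distinct classes —
the sides {P2–1, P2–5}, the crossings {P2–2, P2–4} and the diagonal
{P2–3} — and the package calibrates each class separately, pooling the
equivalent pairs declared by the lattice builder. This is a deliberate
design decision: a single band pooled over all five distances would have
σ > 0 even on a perfect static crystal (the classes genuinely differ) and,
worse, would be wide enough to accept tuples whose side roles are swapped,
which flips the apparent kink pattern and mislabels the polymorph.
Per-class bands reject those role permutations on distance alone.

**Orientation.** The cross product of the two oleic half-chain vectors
(first→kink, kink→last) gives the normal to the oleic-chain plane
(`orientation_normal()`); the dot product of two normals, divided by its
own magnitude, gives a relative rotation of +1 or −1 (`rotation_sign()`).
With molecule 1 as the reference, the signs (s12, s13, s14) form the
signature. The default table encodes: the kinks of the two sides point the
same way in β₂ (s13 = +1) and opposite ways in β₁ (s13 = −1), with
s14 = s12·s13 required for internal consistency, and s12 itself left free
(within a side the two molecules oppose each other; the consistency
condition enforces this relationally without fixing an absolute
handedness). The exact sign pattern is configuration, not code
(`read_signature_table()`): the synthetic generator uses the same
convention, making the test-suite self-consistent, and users calibrating
against real crystal structures can override the table. Degenerate
normals (collinear chain, ‖n‖ < 10⁻⁹ nm²) and indeterminate rotations
(normalized |dot| < 10⁻⁹) disqualify a candidate rather than guessing.

**Search.** All ordered 4-tuples of n molecules number n(n−1)(n−2)(n−3) —
about 10¹² at n = 1000 — so the search is pruned: side pairs come from a
cell-list neighbor search at the P1 upper bound, and two sides are joined
only when their role-1 palmitic tails are within the P2–2 upper bound.
The tuple and its within-side relabeling (m2, m1, m4, m3) describe the
same detection event and are collapsed via a canonical key. An exhaustive
compiled O(n⁴) scan (`brute_force_unit_cells()`, capped at 60 molecules)
is retained purely as a testing oracle and is checked for set-equality
against the pruned search on randomized fixtures.

**Ledger.** Tolerance bands and side-by-side cells make double counting
unavoidable, so per molecule a ledger accumulates +1 for every detection
in either polymorph. At resolution: β₁ > β₂ scores (1, 0); β₁ < β₂ scores
(0, 1); both zero is a melt, (0, 0); a nonzero tie scores (0.5, 0.5).
Percentages are the summed scores over all molecules.
`polymorph_timeseries()` defaults to an independent ledger per frame (so
the series reacts to melting immediately); a cumulative mode is available
behind a flag.

## The synthetic generator

`build_lattice()` and `build_box()` construct idealized crystals so every
metric can be validated without running MD. The molecule template is a
geometric idealization of a united-atom C16/C18:1/C18 TAG: ~4.5 nm long
axis, 0.45 nm intramolecular chain spacing, 0.55 nm within-pair spacing, a
0.12 nm oleic-kink deflection whose sign sets the chain-plane normal. The
four-molecule cell places two sides 1.15 nm apart along the chain axis
(cell 1.35 × 0.90 × 2.60 nm); β₂ repeats the kink pattern (+,−,+,−) on
both sides, β₁ mirrors it (+,−,−,+). These dimensions were chosen once so
that (a) each template cell satisfies its own polymorph's signature, (b)
the three P2 classes are well separated from one another and from all
cross-cell distances, and (c) the nearest non-side oleic-mid pair (0.835
nm) sits far outside any plausible P1 band. Published unit-cell
coordinates are *not* reproduced — all validation is self-calibrated, so
only internal consistency matters.

Melt molecules are placed by rejection sampling: conformations start from
the template, fold the oleic chain back (35–60% of its length) and
displace the stearic chain, and are re-sampled until every C1 and C2
distance misses its reference by at least max(0.08 nm, 15%) — far outside
any calibrated band, so phase separability is guaranteed by construction.
Melt positions keep each melt's oleic-mid at least 0.8 nm (1.2 × the P1
upper bound) from every other molecule's, so a melt can never participate
in a unit-cell side. `make_pseudo_trajectory()` adds per-frame Gaussian
jitter for attached crystal molecules, a PBC-wrapped random walk for
melts, and progressive melting: from an onset frame, crystal molecules
detach in random order over a ramp, receive a melt conformation and
diffuse. Everything is reproducible bit-for-bit from the seed.

What the generator does *not* emulate: thermal physics (no energies or
thermostat), realistic liquid densities (melts are kept at metric-safe
separations), surface-chain disorder, and experimental unit-cell
parameters. Consequently, passing tests demonstrate that the metrics
recover constructed ground truth exactly; they do not demonstrate band
widths or NNO magnitudes for any real force field — those require
calibrating on a real equilibrated crystal, which is exactly what the
calibration design supports.

## Reference systems and test problem sizes

Two standard compositions are built in: `build_box1()` — a 7×1×6-cell β₂
lattice (168 molecules, 84%) plus 32 melts; and `build_box2()` — 1200
molecules, of which 400 (33.33%) form a 10×1×10 β₁ crystal, 200 (16.67%)
a 10×1×5 β₂ crystal, and 600 are melts. The static box-1 frame classifies
as exactly 84% parallel and 84% stretched when calibrated on its own
jittered lattice; the box-2 pipeline recovers 33.33% / 16.67% with every
melt assigned melt. The test-suite uses small lattices (1–3 cells per
axis, ≤ 60 molecules) wherever a brute-force oracle is compared, 20
randomized mixed fixtures for the pruning-equivalence property, 30-frame
jittered trajectories for calibration-coverage checks, and the full box-1
and box-2 systems for the composition checks above.

## Worked example

```{r example, eval = FALSE}
library(tagcryst)

## calibrate once on a small jittered beta-2 lattice
ref <- calibrate_reference(seed = 1)

## reconstruct the 84%-crystalline box and classify its static frame
sys <- build_box1(seed = 42)
traj <- trajectory(list(sys$frame), sys$selection)
crystallinity_timeseries(traj, ref)$summary
#>   time_ps pct_parallel pct_stretched
#> 1       0           84            84

## polymorph ratios in the two-crystal box
sys2 <- build_box2(seed = 42)
fr <- polymorph_frame(extract_key_positions(sys2$frame, sys2$selection), ref)
c(beta1 = fr$pct_beta1, beta2 = fr$pct_beta2)
#>    beta1    beta2
#> 33.33333 16.66667
```

## Known limitations

* Orthorhombic boxes only; triclinic boxes are rejected at load time.
* Binary GROMACS trajectories (XTC/TRR) are not read; use multi-frame GRO
  or the plain whitespace format.
* The signature table defaults encode one consistent reading of the
  β₁/β₂ kink geometry; users matching real crystal structures should
  verify (and can override) the table.
* Absolute NNO values depend on frame-saving frequency; only relative
  comparisons within a run are meaningful.
* Surface molecules under thermal motion undercount the intramolecular
  crystal fraction, as discussed above.
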