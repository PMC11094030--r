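---
title: "Nanocluster recruitment: methods and model"
author: "nanotrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nanocluster recruitment: methods and model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanotrap)
```

# The scientific problem

During clathrin-mediated endocytosis, dynamin must accumulate at the
neck of a forming vesicle fast enough to drive scission. Two routes are
possible: direct recruitment from the cytosol (a 3D search) and
*dimensional reduction* — recruitment to the membrane at large,
followed by 2D lateral diffusion into the endocytic site, where the
molecule is trapped. sptPALM experiments resolve this at the
single-molecule level: thousands of short trajectories per cell reveal
mobility, spatiotemporal nanoclusters, and trajectories that visibly
diffuse in 2D before becoming confined. This package implements the
corresponding analyses and a minimal reaction–diffusion model of
cluster growth, driven entirely by a synthetic-data generator so every
stage is testable against known ground truth.

# The synthetic sptPALM generator

`simulateTracks()` emulates a 50 Hz acquisition (20 ms frames) of a
square membrane ROI:

* **Appearances** are a Poisson process with rate
  `recruitmentRatePre` stepping to `recruitmentRatePost` at `stimTime`
  (appearances·µm⁻²·s⁻¹). The bulk/early phase of recruitment is this
  step; the concentration phase emerges from trapping.
* **Motion** is 2D Brownian with per-axis step variance
  `2·dFree·frameTime`; defaults `dFree = 0.045`, `dConfined = 0.005`
  µm²/s span the measured membrane-mobility range (0.02–0.05 µm²/s).
* **Clusters** are disks (default radius 0.083 µm at 0.54 µm⁻²,
  uniformly placed or on a regular grid) with a common birth/death
  window. A molecule crossing a live footprint from outside is captured
  with `trapProbability`; once captured it diffuses at `dConfined` with
  reflection at the disk boundary until escape (`escapeRate`) or
  bleaching.
* **Enriched appearance at cluster sites.** `clusterAppearanceBoost`
  (default 20) multiplies the appearance intensity inside live
  footprints while keeping the total ROI rate fixed; molecules
  appearing inside a footprint roll the same capture probability
  (ground-truth entry step 0 marks these direct-recruitment events).
  This channel is the generative counterpart of the model's
  solution→activator binding: without it, any background density low
  enough for density-based clustering to resolve individual sites
  yields fewer than one laterally trapped trajectory per cluster, so no
  site can ever reach the published three-trajectory cluster threshold.
  Purely lateral capture cannot, on its own, reproduce per-cluster
  trajectory rates of the observed magnitude (~0.3–1 trajectories/s
  during a cluster lifetime); direct recruitment can and does.
* **Photophysics.** Track lengths are geometric (per-frame survival
  `exp(-bleachRate·frameTime)`; default mean ≈ 20 detections, matching
  the 8–100 detection band used downstream), and every detection gets
  isotropic Gaussian localization noise (default 0.02 µm). Blinking is
  collapsed into the single bleach process because all analyses filter
  to ≥8-detection tracks.
* **Reproducibility.** A single mandatory seed drives everything;
  identical configs give bit-identical output.

What the generator does *not* emulate: camera noise and PSF rendering,
detection/linking errors, drift, anisotropic motion, and blinking-gap
re-linking. Tests passing on this generator therefore validate the
analysis logic, not the upstream localization pipeline.

# Trajectory screening and mobility

`filterTracks()` retains 8–100-detection tracks (shorter tracks are
tracking background) and flags whole sets above 50 trajectories/µm²,
where mistracking becomes likely. `msdCurve()` estimates the
time-origin-averaged MSD; D comes from a least-squares fit of
`MSD = 4Dτ + c` over the first 4 lags — the free intercept absorbs
localization-noise offset — and is floored at 1e-5 µm²/s before
`log10`. The AUC of the MSD is a trapezoidal integral over the first 8
lags (0.16 s). `mobilityMetrics()` bins Log₁₀D on fixed breaks
(−5.1 to 1.1, width 0.2, ends clipped) and splits mobile from immobile
at Log₁₀D = −1.45 by default; the exact threshold used with
PALM-Tracer data is not published, so it is a configuration knob here,
as are the fit window and AUC range.

# Spatiotemporal clustering

`pseudoSpatialTransform()` maps detections to
`(x, y, t·ε/τ_w)` so that two co-located detections one time window
apart are exactly ε apart: one DBSCAN radius then applies in space and
transformed time. `dbscan3d()` is a standard DBSCAN (closed
neighborhoods, core if ≥ `minPoints` including the point itself) with a
uniform-grid neighbor index; border points join the first-discovered
cluster, and the input is canonically sorted by (t, id) so labels are
deterministic. Presets: `"boosh"` (ε = 0.05 µm, minPoints 3 — 8 for
neuronal data — time window 10 s, size screen 0.15 µm) and `"nastic"`
(time threshold 20 s, radius factor 1.2, cluster threshold 3).

Cluster radius is the RMS member distance from the centroid; clusters
wider than the size screen or with fewer member trajectories than the
cluster threshold are discarded (the published threshold of 3 is
counted in trajectories here; a detections interpretation is available
by setting `minPoints`). The `radiusFactor` multiplies the footprint
used for membership tests (trajectory rates, trapping), not the
reported radius. Hotspots are clusters whose centroids lie within the
sum of radii of another cluster with a *strictly* disjoint lifetime
interval. Per-cluster trajectory rates count distinct trajectories with
a detection in the footprint during the lifetime, and in the
equal-length window immediately before (clipped at t = 0 and
renormalized; zero-lifetime clusters are skipped with a warning).

# Lateral trapping

`findTrappedTrajectories()` certifies, per cluster, trajectories whose
first detection is outside, whose last detection is inside, and which
never touch the footprint before their entry step; by default they
must also stay inside from entry until the cluster's end
("confined for the duration"), and a stricter mode additionally
rejects segment-level pass-throughs between consecutive pre-entry
detections (the detection-resolution rule is the default because the
published pipeline operates on detections). Entry step is the 0-based
index of the first in-cluster detection, so it is ≥ 1 by rule 1; in
the displacement profile, the displacement leaving detection
`entryStep + s` is assigned relative step `s` — step 0 is the first
confined displacement. The denominator of the entry percentages is
every trajectory with at least one detection in any surviving cluster
footprint during its lifetime.

# Recruitment kinetics

`analyzeTrace()` smooths with a centered moving average (default 5 s;
the window shrinks at the trace edges), takes the baseline as the mean
FI over the 30 s before stimulation, the peak as the post-stimulation
argmax of the smoothed trace, and the decay slope from a least-squares
line over a 100 s post-peak window (both windows configurable; the
published fitting windows are not stated). A peak is flagged
unresolved when the argmax falls within half a smoothing window of the
trace end or the trace never rises above baseline.
`compareDecayToBleach()` fits both slopes on log-FI when possible, so
exponential decay constants are compared independent of intensity
scale. `cumulativeTrackRate()` counts track first-appearances per µm²,
blocks the cumulative curve (30 s default, to avoid under-sampling)
and differentiates with central differences.

# The reaction–diffusion model

Six species: dynamin in solution `Dsol` (µM), a uniform membrane
recruiter `Rmem` and membrane-bound dynamin `Dmem` (copies/µm² over
the patch), a cluster-restricted activator `Aclus` and cluster-bound
dynamin `Dclus`/`D2dclus` (copies/µm² over the disk; the last two are
identical molecules tagged by 3D vs 2D arrival). Seven reactions:

1. `Dsol + Rmem ⇌ Dmem` (k_frev, k_b)
2. `Dmem + Aclus → D2dclus` (k_mem/h)
3. `Dsol + Aclus → Dclus` (k_mem)
4. `Dmem + D2dclus → 2·D2dclus` (k_dyn/h)
5. `Dsol + Dclus → 2·Dclus` (k_dyn)
6. `Dmem + Dclus → D2dclus + Dclus` (k_dyn/h)
7. `Dsol + D2dclus → Dclus + D2dclus` (k_dyn)

Geometry: evenly spaced clusters let one disk of radius `R_clus` in a
patch of side `1/√density` represent the whole membrane; the solution
column above has `V/A = 1.9 µm` (a representative mammalian-cell
value) and `h = 10 nm` converts 3D to 2D rate constants. The off-rate
`k_b = k_frev·[D]_sol·[R]_mem/[D]_mem` makes the cluster-free system an
exact steady state, so all dynamics are cluster-driven.

**Unit scheme.** The ODE solves all species in µM — surface densities
are converted to copies over their own area and then to concentrations
via V — with the purely-2D reactions (2, 4, 6) multiplied by
`DF = V/(A·h)`. Densities remain the user-facing inputs/outputs, with
exact linear conversions (`convertUnits`, round-trip identity at
1e-12). A second, density-native right-hand side was deliberately not
maintained: the two representations differ by a fixed linear change of
variables, so duplicating the kinetics would add code without adding a
check. The optional `kMem2D`/`kDyn2D` overrides decouple the lateral
channels (e.g. set them to 0 to isolate 3D arrival).

**Stimulation transform** (`applyStimulation`): new geometry from the
increased cluster density (0.54 → 3.1 µm⁻², radius 0.083 → 0.096 µm),
membrane dynamin scaled up with the solution pool reduced so total
copies per unit membrane are conserved, and `k_mem` replaced by its
post-stimulation value. The published membrane-density scale factor
for the short-tail isoform is in supplementary material not available
to this implementation; the preset uses 2.0, which keeps the initial
density inside the stated 10–80 copies/µm² search range and the
initial in-cluster occupancy inside the stated 0.2–2 copy window. The
headline bound (peak copies ≤ 80 over the 4 s formation window) is
insensitive to this choice across the plausible 1–3 range.

**Simulators.**

* `simulateODE()`: stiff-capable `lsoda`, tolerances 1e-9/1e-7,
  negative states beyond tolerance abort.
* `simulateSSA()`: exact Gillespie in copy numbers (initial copies
  rounded to integers). Dynamin–dynamin binding is booked per site —
  each activated dynamin exposes 4 sites reacting at `k_dyn/4` — which
  equals mass action in total propensity while supporting the oligomer
  interpretation. An optional 0th-order titration (100 µM/s) plus
  1st-order degradation (10 s⁻¹) pins the solution pool near 10 µM
  when a truncated volume is simulated; without it total dynamin is
  conserved exactly. The stochastic preset uses `k_memPost = 0.006`
  µM⁻¹s⁻¹ (versus 0.0024 deterministic) because discrete simulations
  cannot amplify from fractional copy numbers.
* `simulateMembranePDE()`: the full 3D solution volume is reduced to a
  well-mixed bath coupled to every surface cell — solution diffusion
  (7 µm²/s) homogenizes the 1.9 µm column two orders of magnitude
  faster than membrane transport moves material between cluster and
  bulk, and the deterministic kinetics are known to be nearly
  spatially uniform. Membrane species diffuse on an L×L periodic grid
  (0.015 µm target cells; the disk must be resolved by ≥5 cells);
  cluster species are confined to the disk mask, with the activator
  total normalized to the exact disk area. Time stepping is operator
  split: midpoint (RK2) reactions, then implicit-Euler diffusion via a
  pre-factorized sparse periodic Laplacian (unconditionally stable, so
  the well-mixed limit can be probed with arbitrarily large D). The
  default 0.01 s step is well below the 0.1 s cap and the fastest
  reaction timescale (~3 s).

**Observables** (`observables`): `RelDensity(t)` normalizes the summed
dynamin concentrations to the initial membrane density
(`RelDensity(0) = 1`); `DynCopies(t)` is the copy number inside the
disk (cluster species plus the in-disk share of `Dmem`);
`fraction2D(t)` is the laterally arrived share of cluster dynamin
(defined as 0 while the cluster is empty). Experimental traces are
normalized as `RelIntensity = (I − Δ)/(I(0) − Δ)`; `chooseOffset()`
solves the background offset Δ in closed form so the peak relative
intensity matches the fold increase measured independently from
single-particle track counts.

**Fitting.** `chi2Objective()` weights squared residuals by
per-timepoint experimental SEM (zeros are an error — floor them
first). `fitGA()` is a real-coded genetic algorithm: tournament
selection (size 3), two-point crossover (p = 0.6), per-gene Gaussian
mutation (p = 0.2 default, sd 10 % of the range annealed tenfold over
the run), elitism (2), and an optional log₁₀ transform for rate
constants spanning decades. No GA hyperparameters are published; these
defaults are the package's own. The published rate-constant search
ranges are likewise unavailable, so the default box is 1e-4–1 µM⁻¹s⁻¹
for bimolecular rates — an assumption, flagged as such.

# Numerical choices and degenerate inputs

* DBSCAN ties: border points go to the first-discovered cluster; input
  is sorted by (t, id), so results are reproducible.
* Whether a published cluster threshold of 3 counts trajectories or
  detections is ambiguous; trajectories is the default, `minPoints`
  covers the other reading.
* M/IMM is mobile/immobile: 0 when nothing is mobile, and an `Inf`
  sentinel (with a warning) when nothing is immobile.
* Zero-lifetime clusters are skipped in rate computations; clipped
  before-windows renormalize by their actual length.
* D is floored at 1e-5 µm²/s before log10; empty traces, degenerate
  ranges, zero SEMs and missing seeds are errors, not silent defaults.
* The SSA rounds initial densities to integer copies; comparisons
  against the ODE feed both simulators the rounded values (and the
  matching equilibrium off-rate) so they solve the same system.

# Problem sizes used by the test suite

The suite runs on one CPU in a few minutes: oracle-equivalence checks
use ≤500-point DBSCAN instances and 200-track × 50-cluster trapping
scenes; estimator checks use 500 Brownian tracks; stochastic–
deterministic agreement uses 48 SSA runs on a 10×-area geometry (mean
within 3 SE of the ODE — the mean-field claim is asymptotic in copy
number, so it is tested in the enlarged-copy regime); the well-mixed
PDE limit uses D = 50 µm²/s against the ODE at 2 %; parameter recovery
plants (k_mem, k_dyn), fits with a 30×40 GA budget and requires
recovery within 25 %. Cluster-recovery experiments use ~26 planted
sites with 10 s lifetimes and enriched recruitment, reflecting the
regime in which density-based detection is well-posed.

# Known limitations

* The spatial model is 2D + bath; it cannot represent solution-side
  gradients normal to the membrane (negligible here by the timescale
  argument, but untested for slowly diffusing solutes).
* The generator's trapping is binary capture/escape; no partial
  confinement, no hop diffusion, no cluster growth feedback on capture
  probability.
* Cluster lifetimes in the generator are a shared birth/death window,
  not per-cluster stochastic lifetimes; hotspot statistics on synthetic
  data are therefore stylized.
* The GA is a general-purpose minimizer; for the smooth 2-parameter
  recovery problems tested it converges reliably, but multi-modal
  landscapes with more free parameters would need larger budgets or
  restarts.
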