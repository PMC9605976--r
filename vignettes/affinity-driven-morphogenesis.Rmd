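---
title: "Affinity-driven soma-germline matching: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Affinity-driven soma-germline matching: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eggchamber)
```

## The biological system and what the package models

A *Drosophila* egg chamber is a germline cyst of 16 cells — 1 oocyte and
15 nurse cells — wrapped by a monolayer epithelium of roughly 850
follicle cells (FCs). About 10% of FCs adopt anterior fate (AFCs) and
must eventually cover the nurse-cell compartment, while the remaining
main-body and posterior cells (MBFCs, PFCs) must cover the oocyte.
Morphogenesis divides into three phases classified by the medial-section
germline area: phase 1 below 6500 µm², phase 2 up to 31500 µm², phase 3
beyond. The transcriptional co-regulator Eya, expressed in FCs, acts in
this framework as a proxy for cell–cell *affinity*: the energetic
preference of a cell for contact with a given surface. Two signed
summaries organize everything:

* per-FC affinity for nurse cells grows with that cell's Eya level;
* the *effective* germline affinity for the epithelium changes sign at
  an Eya level of 72 arb. units, read out geometrically by the contact
  angle where the oocyte–nurse-cell interface meets the epithelium
  (90° = balanced; >90° effective nurse-cell affinity; <90° effective
  oocyte affinity, i.e. oocyte wetting).

The package implements (i) a seeded generator of synthetic egg-chamber
sections with this statistical structure, (ii) a 24-parameter
morphometric pipeline with phase assignment, (iii) the PCA/UMAP
trajectory embedding and a permutation-based divergence detector,
(iv) the statistical procedures (LOESS curves, interaction regression
with additive fallback, critical-size ANOVA with Šídák contrasts,
angle-versus-Eya regression), and (v) two phase-field models: a
multicellular model of FC redistribution and a two-phase model of the
oocyte/nurse compartment.

## Eya schedules and affinities

Row-wise Eya dynamics are summarized per anterior FC row (rows 1–6 are
AFC rows; the row-7 dynamic stands in for all posterior cells). Mean
intensities per developmental stage are interpolated over a 36-hour
window by a 6th-order polynomial constrained to have vanishing first
derivatives at t = 0 and t = 36 h (`fit_schedule()`, an
equality-constrained least-squares problem solved in a scaled basis).
Stage durations are not printed in the source material; the shipped
table (`stage_table()`) assigns 6 h to stages 5–8 and 3 h to 9e, 9m,
10a, 10b, placing the phase boundaries at mid stage 7 (15 h) and mid
stage 10a (31.5 h). The stage table is an editable argument everywhere
it is used.

The shipped per-stage means (`default_stage_means()`) are a synthetic
family: uniform high intensity (~112) through phase 1, then a logistic
divergence (centre 18 h, width 3 h) to graded end levels of 128 down to
78 across rows 1–6 and 15 for row 7, so that row 7 crosses the 72-unit
zero point shortly after the phase-1/2 boundary. Measured per-stage
values exist only in figure form and are deliberately not hard-coded.

Affinity maps (`eya_to_affinity()`): the FC model uses a non-negative
linear map `a = E / 130`; the germline model uses the signed map
`g = (E - 72) / 60`. Both scales were fixed once against the wild-type
simulations and are reused unchanged in every perturbation scenario.

Because germline area is the progression variable while simulations run
on the stage clock, `area_time_map()` links the two with an exponential
growth curve anchored so that 6500 µm² falls at 15 h and 31500 µm² at
31.5 h.

## The synthetic-data generator

`generate_chamber()` builds one medial section as an ellipse whose
anterior–posterior aspect ratio rises from 1.5 (phase 1) to 2.0 (late
phase 3). The oocyte is the posterior segment whose area fraction
follows a smoothstep from 1/16 below 6500 µm² to a plateau of 0.40 at
31500 µm². Follicle cells are perimeter samples (74 per section by
default): uniformly spaced in phase 1, and progressively reallocated so
that by phase 3 the six most anterior cells per side tile the
nurse-adjacent arc (AFC flattening, with a transient anterior-high
extent gradient peaking mid-phase 2), leaving 62/74 ≈ 84% of section
cells over the oocyte — the published phase-3 proportion. Per-cell Eya
follows the row schedules at the chamber's mapped time, with
multiplicative log-normal noise; contours receive additive Gaussian
noise; a single root seed feeds documented per-chamber streams.

The oocyte–nurse-cell interface is drawn as a straight chord with
endpoint-localized "hooks" whose tangents realize the target contact
angle; the enclosed area is made exact by iterating the chord position.
A global arc was rejected because realizing obtuse angles on a small
posterior cap would displace far more area than the cap contains. The
target angle itself is `90 + 0.35 × (E_boundary − 72)` degrees, where
`E_boundary` is the Eya level of the nurse-side boundary cells; the
slope is a generator design choice (the 72-unit zero point is exact and
is what the analysis estimates), chosen so that phase-1 angles (~104°)
remain geometrically realizable; realized angles are clamped to ±70° of
deflection about the local chord angle.

Genotype rules switch fields only beyond their critical sizes:
`mirr_eya` gives MBFCs ectopic Eya and freezes the transition above
11650 µm²; `gr1_eyaRNAi` collapses Eya above 1600 µm², prematurely
advancing the oocyte and disorganizing the sectioned nurse cells;
`tj_egfr` removes anterior fate and turns the epithelium Eya-negative
from phase 2 onward, so the oocyte never halts. These choices are what
the embedding and statistics modules are expected to detect; they are
fixed study conditions, not tuning knobs.

What the generator does *not* emulate: real image segmentation noise
and its spatial correlations, three-dimensional curvature, per-cell
shape variability beyond arc extents, germarium/stage-1 assembly, and
nurse-cell dumping. Passing tests therefore demonstrate that the
pipeline recovers the structure the generator encodes — not that it
would behave identically on segmented micrographs.

## Morphometrics

`measure()` computes 24 parameters per section: areas (polygon
integration of the stored contours), compartment fractions, section and
total FC counts, count- and length-based contact proportions, interface
lengths, the interface angle, the anterior row count on nurse cells,
aspect ratio, anterior/posterior apical-extent summaries, Eya summaries
(boundary cells, anterior rows, posterior rows), nurse-cell coefficient
of variation statistics, and the perimeter. The published supplementary
table defining the original 24-parameter schema is not part of the
available text; this schema is a documented reconstruction covering
every named descriptor.

Phases use left-closed intervals ([0, 6500), [6500, 31500), [31500, ∞)),
fixing the source's inconsistent strict/non-strict captions. The
interface angle is measured through the oocyte and averaged over both
triple points, with contour tangents from local quadratic fits over a
±5% perimeter window; the side convention makes <90° equivalent to
oocyte wetting. "Rows" are equal-arc-length bins from the anterior pole
with bin width equal to the mean apical extent of the current anterior
cells — a reproducible stand-in for visual row counting, applied
identically to generated sections and simulation readouts.

## Embedding and divergence detection

Cohorts are z-scored per column (`standardize()`; wild type alone, or
pooled with the control for manipulated genotypes), reduced by PCA with
the smallest number of components exceeding 90% cumulative variance
(`pca_select()`), and embedded by UMAP with n_neighbors = 15 and
min_dist = 0.2 (`umap_embed()`, seeded). The developmental ordering is
the geodesic distance along the 15-nearest-neighbour graph of the
embedding from the smallest chamber — a reproducible replacement for
visual trajectory reading; on default cohorts its Spearman correlation
with germline area exceeds 0.9.

`divergence_point()` pools control and mutant records, projects them
into a joint PC space, and scans half-overlapping area-ordered windows
for the first one where the mutant chambers' mean distance to their
control neighbours exceeds a permutation null band. Family-wise error
is controlled by comparing against the permutation distribution of the
*maximum* window statistic (B = 200 by default), so the wild-type
versus wild-type false-positive rate is at most the nominal α by
construction. The reported divergence area is the lower edge of the
first significant window.

## Statistics

`compare_genotypes()` fits `Y ~ size + genotype + size:genotype` with a
0/1 genotype indicator and falls back to the additive model when the
interaction p-value is ≥ 0.05, reporting the branch taken. It agrees
with the closed-form normal-equations solution to 10⁻⁸ (tested).
`critical_size_anova()` groups chambers below/above a critical size,
fits the two-way ANOVA, and reports Šídák-adjusted genotype contrasts
per group via `emmeans`. `loess_curve()` uses span 0.75 (unstated in
the source; configurable) with a pointwise t-based confidence band —
pointwise rather than simultaneous, as the narrower, more common
reading. `angle_vs_eya()` is an ordinary linear fit whose 90°-crossing
solves to the effective-affinity zero point; a zero slope flags the
crossing as undefined.

## The follicle-cell phase-field model

N cells are indicator fields φᵢ on a 256 × 64 strip whose bottom row is
the germline surface, split into an affine (nurse-cell, anterior 55%)
and non-affine (oocyte) compartment. The original model formulation is
in supplementary material not available here, so the functional is a
reconstruction constrained by the described behaviour:

F = Σᵢ ∫ [ D/2 |∇φᵢ|² + w φᵢ²(1−φᵢ)² ] + Σᵢ αᵥ/2 · V⁰ᵢ (1 − Vᵢ/V⁰ᵢ)²
    + β/2 ∫ Σᵢ≠ⱼ h(φᵢ)h(φⱼ) − Σᵢ ∫ᵦₒₜₜₒₘ (a_bg + aᵢ(t)·𝟙_affine) h(φᵢ)

with h(φ) = φ²(3−2φ), so that every non-gradient force carries
h′(φ) = 6φ(1−φ) and vanishes in the bulk phases. Volumes are
soft-constrained (drift stays below 2%), affinity is a boundary
contact-energy reward *linear in the affinity*, and a_bg is a
non-specific adhesion of every cell for the germline surface. Dynamics
are explicit relaxational gradient flow (energy non-increase is tested);
side walls are Dirichlet so cells do not spuriously wet them. Cells are
seeded side by side with equal volumes; the per-cell affinities follow
the scenario's Eya schedules over the 36-hour window.

The wild-type calibration (D = 4, w = 0.5, αᵥ = 4, β = 3, a_bg = 0.7,
affinity scale E/130, cell volume ≈ 13 × 18 grid units, dt = 0.05,
48000 steps) was fixed once and reused for all perturbations. With it,
the wild type ends with exactly six cells on the affine compartment and
cell 8 transitioned onto the oocyte side; uniform high AFC affinity
detaches cells 7 and 8; a row-3 knockdown detaches cell 3; ectopic high
affinity in rows 6–8 keeps those cells on the nurse side. Detachment is
declared when a cell's total boundary contact stays below 1% of its
perimeter measure over the final tenth of the run; attached cells are
assigned to their majority compartment.

Known limitation: in the wild-type run cell 7 detaches rather than
sliding onto the oocyte compartment. Under purely relaxational dynamics
with constant volumes, a squeezed cell pinches off before the packed
posterior train yields; a broad parameter exploration (adhesion, cell
volume, compartment split, overlap stiffness, interface tension,
several-fold longer relaxation) found no regime in which cell 7
completes the transition while the other scenario outcomes are
preserved. The count on the affine compartment — the quantity of
record — is unaffected.

## The germline phase-field model

A single order parameter ψ (1 = oocyte, 0 = nurse compartment) lives in
a fixed ellipse (160 × 108 grid, domain aspect ≈ 1.5) whose boundary
band carries the signed field g(s, t) built by interpolating per-row
effective affinities at their time-dependent positions
(`boundary_affinity_field()`); posterior of row 7's position the
(Eya-low) row-7 value applies. Anterior row positions advance as
flattening proceeds — the posterior edge of row 6 moves from 0.40 to
0.52 of the boundary through phases 1–2 and accelerates to 0.64 in
phase 3, when completed AFC flattening carries Eya-positive territory
over the nurse-cell–oocyte boundary. That late advance is what pushes
the contact line into positive-g territory and returns the angle above
90° in phase 3.

ψ is non-conserved: the energy is the same interfacial form plus a
boundary wetting term `cwet · g(s,t) · h(ψ)` (positive g penalizes
oocyte–boundary contact). Three reconstruction choices make the
relative oocyte volume an emergent output with the described behaviour:

1. the volume component of the *bulk* force is projected out each step,
   suppressing curvature-driven shrinkage of the minority phase — the
   stand-in for active germline growth;
2. the volume response is one-sided: boundary wetting can raise the
   oocyte's share but net shrinkage is projected away (the oocyte's
   relative share never falls below its 1/16 start);
3. the share's relative growth rate is capped at 0.15 h⁻¹, a
   physiological bound without which the strongly Eya-negative
   scenarios consume the whole domain before phase 3.

Energy is non-increasing whenever the volume constraint is passive
(neutral and de-wetting boundaries; tested). During wetting-driven
growth the stabilization does work against curvature — deliberately, as
it models growth — so monotone dissipation is not asserted there.

The interface angle of a ψ field is a *mesoscopic secant* angle: the
ψ = 0.5 level set interior to the domain is the interface, and at each
triple point the interface direction is the secant to the point 20% of
the interface length inward (≤ 14 px), compared with the boundary
tangent oriented towards the posterior. A local tangent is deliberately
avoided: at the posterior pole a small cap is geometrically frustrated
and the diffuse interface curves continuously, making local tangents
scale-dependent; the secant mirrors how an angle tool is applied to
micrographs. By symmetry the measurement is exact at g = 0, and the
measured angle is monotone in uniform g with the analytic crossing
(cos θ = −cwet·g/σ, σ = √(2Dw)/6) recovered to a few degrees.

Scenarios: `germline_wt` (schedules as measured), `premature_loss`
(epithelium-wide collapse from a germline size of 1600 µm², i.e.
t ≈ 0.4 h), `ectopic_nc_affinity` (row-7 territory keeps high Eya from
the phase-1/2 boundary), `all_negative` (everything Eya-low from the
phase-1/2 boundary). Under the single wild-type calibration these
reproduce, respectively: the >90° / <90° / >90° angle course with an
oocyte share rising from 1/16 to ~0.45 and plateauing at the phase-2/3
boundary; a premature sub-90° angle and early expansion within phase 1;
a flat 1/16 share with the angle pinned above 90°; and a persistently
sub-90° angle with expansion continuing into phase 3.

## Numerical choices and problem sizes

Explicit Euler steps with stability guards (dt·M·(4D + 2w) bounded);
interface width 2–5 grid units; fields clipped to [−0.1, 1.1]; schedule
updates every 40–500 steps. The shipped problem sizes are the ones used
throughout the tests and the acceptance script: 20-chamber phase-1
ensembles and 500-chamber cohorts for the pipeline; 14-cell runs at
256 × 64 with 48000 steps for the wild type and 24000 for the
perturbation scenarios (whose outcomes are converged by then); germline
runs at 160 × 108 with 90000 steps; reduced 96 × 40 / 96 × 64 grids for
property-style tests. Divergence nulls use B = 60–200 permutations
depending on context.

## Reproducing the workflow

```{r workflow, eval = FALSE}
## one-command configured runs; every run echoes its config and writes
## a log with the package version and seed
run_workflow(list(command = "generate", seed = 0, out = "out/wt",
                  generator = list(n_chambers = 126)))
run_workflow(list(command = "embed", seed = 0, out = "out/embed",
                  generator = list(n_chambers = 500)))
run_workflow(list(command = "simulate-fc", seed = 0, out = "out/fc",
                  scenario = "wt"))
```

The same commands are available from a shell via
`Rscript inst/cli/eggchamber.R <command> --out <dir>` or with a YAML
config file.
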