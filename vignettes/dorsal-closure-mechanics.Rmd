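---
title: "Vertex-model mechanics of the amnioserosa during dorsal closure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertex-model mechanics of the amnioserosa during dorsal closure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vertexclosure)
```

## The model

During *Drosophila* dorsal closure the amnioserosa (AS), a one-cell-thick
epithelial sheet, loses about 80% of its apical area while its cells elongate
strongly. A standard two-dimensional vertex model would predict that a tissue
with such elongated cells (mean shape index q = p/sqrt(a) well above the
fluidization value of about 3.81) is a fluid that rearranges by T1 neighbor
exchanges. Experimentally the AS does not rearrange: junctions never vanish
except where a cell ingresses. `vertexclosure` implements the minimal
extension of the vertex model that reconciles these observations, and the
percolation analysis used to diagnose solidity.

The tissue is a confluent periodic tiling of `N` polygonal cells sharing
trivalent vertices in a rectangular box (long axis = anterior--posterior axis;
periodic boundaries). The mechanical energy is

    E = sum_i [ 1/2 ka (a_i - a0)^2  +  1/2 kp (p_i - p0_i)^2 ]

with per-cell areas `a_i` and perimeters `p_i`, a shared preferred area `a0`
and per-cell preferred perimeters `p0_i`. Units are set by `a0 = 1` and
`kp = 1`; `ka = 1`. Forces are the analytic gradient of `E`; quasistatic
states are energy minima (FIRE minimizer, see below).

Three ingredients extend the standard model:

1. **Polydispersity.** Preferred shape indices `q0_i = p0_i/sqrt(a0)` are
   drawn from a normal distribution (`shape_distribution()`), SD 0.45,
   matching the measured cell-to-cell variability at closure onset.
2. **Active perimeter shrinkage.** Each preferred perimeter decreases
   linearly with the closure stage, `p0_i(dA) = p0_i(0) (1 - c dA)`,
   modelling the endocytotic removal of junction material. `dA` is the
   fractional loss of tissue area, the stage clock of closure.
3. **Quasistatic uniaxial deformation.** Every protocol step reduces the box
   height by 0.125% of its initial value at fixed width, rescales vertex
   positions affinely, updates the preferred perimeters, optionally removes
   a random cell (about 10% of cells ingress over a full run, implemented as
   a T2 collapse), and reminimizes the energy with T1 moves enabled.

A junction shared by cells i and j carries the tension
`tau_J = kp (p_i - p0_i) + kp (p_j - p0_j)`. The tissue counts as **solid**
when junctions with non-zero tension (above the floor `eps_tau = 1e-4`) form
a cluster that wraps the periodic box in both directions; the summary
statistic is the rigid-junction fraction `fr` compared with the bond
percolation threshold of Voronoi-like networks, `fc ~ 0.66`
(`calibrate_fc_voronoi()` reproduces it).

## Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `q_mean`, `q_sd` | 4.2, 0.45 | -- | initial preferred shape-index distribution |
| `shrink_slope` (c) | 0.65 | 1/dA | linear active shrinkage of `p0_i` |
| `delta` | 0.00125 | -- | per-step height decrement (fraction of initial height) |
| `dA_max` | 0.8 | -- | closure depth |
| `ingression_fraction` | 0.1 | -- | cells removed over the run |
| `ka`, `kp`, `a0` | 1, 1, 1 | model units | energy scales |
| `t1_length` | 0.02 | sqrt(a0) | junction length that triggers a T1 trial |
| `eps_tension` | 1e-4 | kp sqrt(a0) | rigid-junction floor |
| `tol` | 1e-5 | kp sqrt(a0) | force-balance tolerance |

The initial distribution (`q_mean = 4.2`, SD 0.45) places the actual
post-minimization shape-index distribution above the monodisperse rigidity
point while polydispersity keeps a tension backbone percolating. The shrink
slope is the one genuinely free parameter of the model -- no first-principles
value exists for how fast junction material is removed -- so it was
calibrated once against three established features of the closing
amnioserosa: junction
tension that rises to a maximum near `dA = 0.55` and falls afterwards, a mean
shape index with an interior minimum near `dA = 0.55`, and tension
percolation maintained over the whole run. `c = 0.65` reproduces all three;
values near 0.5 make the preferred perimeter shrink *slower* than confluence
forces actual perimeters down (tension decays, the tissue fluidizes), values
near 1 overdrive tension and push the extrema apart. The calibration target
was the qualitative structure, not any acceptance threshold, and the value is
config-exposed.

## Numerical choices

**Minimizer.** FIRE (semi-implicit Euler with velocity mixing, adaptive
timestep, uphill backtracking) on the analytic forces, stopping when the
largest per-vertex force drops below `tol = 1e-5` in units of
`kp sqrt(a0)` -- two decades below the smallest physically meaningful tension
(`eps_tension = 1e-4`), so tensions and `fr` are insensitive to the residual.
Substantially tighter tolerances are reachable but cost of order a million
FIRE iterations per relaxation in the nearly-floppy regime on one CPU --
GPU territory.

**Rosettes (pinned short edges).** In polydisperse, strongly deformed
tissues some junctions are driven to zero length while their reconnection
would *raise* the energy: mechanically stable higher-order vertices
(rosettes, which real AS tissue also forms). A trivalent representation
cannot store them explicitly, so edges below 1% of the T1 threshold are
treated as pinned: the coincident vertices share their mean force (they move
as one unit) and convergence is judged by the net force on such clusters
(the KKT condition for the length >= 0 constraint).

**T1 acceptance.** When a flippable junction drops below `t1_length`, the
package relaxes two branches for a few hundred steps -- reconnected versus
pinned -- and keeps the flip only if it releases energy (> 1e-9) and its
rotated edge opens. Accepting energy-*neutral* flips instead lets the model
relieve all deformation by marginal rearrangements and fluidizes it at every
shrink rate, contradicting the solid behavior this model exists to explain;
the strict rule is also the correct athermal quasistatic limit, where no
noise exists to realize degenerate rearrangements. Rejected flips stay
pinned and are re-examined every 0.02 in `dA`. Controls that ask the
opposite question -- *can* the tissue rearrange at zero cost, i.e. is it a
fluid? -- probe with `accept_neutral = TRUE`, which also takes
energy-neutral reconnections; the no-shrinkage (`shrink_slope = 0`)
fluidization control uses this mode and stops at the first exchange.

**T2 (ingression).** A removed cell is first reduced to a triangle by T1
moves on its shortest edges, then collapsed to a single trivalent vertex at
its centroid, so confluence and trivalence hold at every instant. Neighbor
exchanges in the relaxation immediately after an ingression are logged
separately (`n_t1_ingression`): junction remodelling around an ingressing
cell is observed in the embryo too and is not a fluidization signature.

**Degenerate inputs.** Voronoi construction rejects (and jitters) seed sets
that produce non-trivalent diagrams; tilings whose cells span more than half
the periodic box (fewer than ~20 cells) are rejected by the minimum-image
validator. The deformation step refuses to close the box completely, and the
recoil fitter short-circuits perfectly flat traces to zero recoil.

## What a run produces

```{r}
traj <- run_closure(n_cells = 256, seed = 1)
traj$records   # dA, q_mean, q_sd, ar_mean, ar_sd, Q_order,
               # tension_mean, fr, n_cells, n_t1, n_t1_ingression, energy
traj$events    # T1 and ingression log with stage stamps
```

Under the default protocol the mean shape index dips to a minimum near
`dA ~ 0.5` and rises again; the mean junction tension mirrors it with an
interior maximum; the orientational order `Q = <cos 2 theta>` grows steadily
(the isotropic control keeps `Q` near zero and serves as the negative
control); and the rigid fraction stays above the percolation threshold
throughout. These are the computations behind `scripts/acceptance.R`.

On neighbor exchanges: with T1 moves enabled throughout (so their absence
would be an observation, not an assumption), the simulated marginally-solid
tissue is not perfectly event-free: sparse energy-releasing exchanges --
distributed plastic yield under an 80% uniaxial deformation, a few hundredths
of `kp a0` each -- occur along a run at this system size, concentrated late
in closure, while tension percolation -- the operative solidity diagnosis
-- is maintained at every stage. A strictly zero count obtains
only when reconnections are disabled and junction lengths are merely
monitored. Both facts are reported by the package rather than hidden; see
the test suite.

## Two protocol sensitivities worth knowing

**The monodisperse rigidity point is protocol-dependent.**
`rigidity_point_sweep()` locates the solid-to-fluid onset of the *standard*
(monodisperse, undeformed, no-shrinkage) model by sweeping a uniform
preferred shape index and asking where residual tensions vanish and tension
percolation is lost. For this vertex model -- fixed disordered topology
relaxed with energy-releasing T1 moves -- the onset lands near 3.92-3.93
(N = 64, five seeds; the same value is found approaching from the fluid
side), consistent with the compatibility transition reported for vertex
models with disordered topology. The widely quoted 3.81 belongs to
Voronoi-parameterized models and energy-barrier analyses. Two numerical
traps in this sweep are handled explicitly: without T1 moves the floppy
phase stays trapped in tense metastable states (the rigid fraction never
drops), and at force tolerances looser than ~1e-7 floppy states retain
spurious tensions above the rigid floor because nearly-collinear edges
exert almost no net vertex force.

**Finite tissues in a 2:1 box carry a small initial alignment.** Relaxing
the polydisperse initial condition in the rectangular periodic box leaves
an orientational order of a few hundredths to ~0.1 at N = 256 (soft
long-wavelength modes favor elongation along the long axis). Isotropic
deformation neither removes nor amplifies it -- the meaningful control
outcome is that order *grows* only under uniaxial deformation -- but
absolute bounds on the isotropic |Q| at desk scale sit near the sampling
floor sqrt(1/(2N)) plus this offset, not at zero.

## The synthetic-data generators

`generate_tracked_cohort()` emulates segmented-and-tracked live imaging:
per-embryo frame series with linear AS-area decrease (onset area 11,000
square microns, the staging reference), per-cell areas and perimeters drawn
so the shape-index distribution has the measured SD of 0.45 (left-truncated
at the disk bound 2 sqrt(pi) with moment-matched parameters) and a mean that
follows an explicit piecewise-linear drift with a minimum at `dA = 0.55`,
about 10% ingression, junction contour/end-to-end pairs whose straightness
tracks a tension proxy, and embryo-to-embryo variability in rates and
offsets. What it does **not** emulate: segmentation artifacts, curvature
projection errors, tracking identity switches, or spatial correlations
between neighboring cells -- passing recovery tests on these tables
validates the analysis code, not the imaging pipeline.

`generate_ablation_traces()` produces double-exponential recoil traces at
5 Hz with the true initial recoil velocity drawn from a hump peaking at
`dA = 0.55`. Rates (fast 0.6/s, slow 0.05/s, amplitude 80% fast) are chosen
as realistic for junction ablation and identifiable at the frame rate. At
2% amplitude noise the initial-slope estimator has an intrinsic relative
spread of about 3%: the median recovery error across replicates is ~3%,
99% of replicates land within 10%, and about 80% within 5% -- the
information limit of the trace, not a fitting deficiency.

## Known limitations

* Flat 2D geometry: no embryo curvature, no leading-edge cable, no canthi,
  no lateral epidermis; the box edge is periodic, not a real boundary.
* Quasistatic only: rates, viscoelasticity and time-resolved recoil are out
  of scope (the recoil *fit* is experiment-side analysis, not simulation).
* Rosettes are represented as pinned short edges, not true higher-order
  vertices.
* System sizes here (N = 64-256, five seeds) are desk-scale; positions of
  the trajectory extrema shift by a few hundredths of `dA` between seeds at
  N = 256.
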