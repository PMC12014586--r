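---
title: "A hybrid cell/ECM model of spheroid growth under collagen stiffening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid cell/ECM model of spheroid growth under collagen stiffening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroidECM)
```

## The model

spheroidECM simulates the growth and invasion of a tumour spheroid embedded
in a collagen matrix whose stiffness has been raised by ribose-induced
glycation (non-enzymatic cross-linking of collagen fibres). It is a hybrid
discrete–continuous model in the centre-based, off-lattice tradition: each
cell is a sphere identified by its centre, and the extracellular matrix (ECM)
is a continuum density field $\rho \in [0,1]$ stored on a single layer of
cubic voxels. Cells move freely in the $xy$-plane but not in $z$
(a "constrained 3D" or pseudo-2D setting, matching a single confocal
$z$-slice of a real spheroid).

Three processes are coupled:

**ECM remodelling.** A cell in contact with a voxel degrades its density at
rate $r_\mathrm{deg}$ (exactly integrated per step,
$\rho \leftarrow \rho e^{-r_\mathrm{deg}\Delta t}$). Cross-linking makes the
matrix harder to degrade, which we model as exponential attenuation with
ribose concentration:
$r_{\mathrm{deg},rib} = r_{\mathrm{deg},0}\, e^{-\delta\, rib}$.
The voxel a *moving* cell degrades is the one nearest its **front** — the
point on the cell surface in the direction of motion — reflecting
protrusion-localised MMP secretion; a stationary cell uses the voxel nearest
its centre.

**Cell movement.** The velocity of cell $i$ is
$v_i = (v_{i,cc} + v_{i,cma})(1 - \rho)$, with $\rho$ read from the same
front voxel. Here $v_{i,cc}$ collects standard centre-based pairwise
adhesion ($-c_{cca}(1 - d/(R_{i,A}+R_{j,A}))^2\,\hat u$ inside the
interaction distance) and repulsion
($+c_{ccr}(1 - d/(R_i+R_j))^2\,\hat u$ inside contact). The cell–matrix
adhesion term is $v_{i,cma} = 4 S_{rib}\,\rho\, d_i$, linear in density
(more fibres, more adhesion sites), directed along a persistent random unit
vector $d_i$ resampled each mechanics step with probability
$\Delta t_\mathrm{mech}/T_\mathrm{per}$. The factor $(1-\rho)$ is the
matrix's steric resistance: at $\rho = 1$ the ECM is a wall and the total
velocity vanishes; at $\rho = 0$ there is nothing to pull on, so an isolated
cell's speed $4 S_{rib}\rho(1-\rho)$ is zero at both extremes and peaks at
$\rho = 0.5$ with value exactly $S_{rib}$. Stiffening also slows migration:
$S_{rib} = S_0 e^{-\sigma\, rib}$.

**Proliferation.** Every phenotype step a cell divides with probability
$r_\mathrm{div}\, f_\mathrm{IP}\, \Delta t_\mathrm{cell}$, where the
inhibition factor $f_\mathrm{IP}$ is 0 when the neighbour count reaches the
overcrowding threshold $N_\mathrm{max}$ and $1-\rho$ otherwise ($\rho$ at
the voxel nearest the cell position). Daughters each take half the parent
volume, are placed at $\pm R/2$ along a random direction, and relax back to
the target volume exponentially. There is no cell death.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `rdeg0` | 0.0032 | min⁻¹ | base ECM degradation rate (0 mM ribose) |
| `delta` | 0.02 | mM⁻¹ | ribose sensitivity of degradation |
| `S0` | 0.7 | µm·min⁻¹ | max cell–ECM speed (0 mM ribose) |
| `sigma` | 0.035 | mM⁻¹ | ribose sensitivity of speed |
| `rdiv` | 0.00072 | min⁻¹ | proliferation rate (MCF10A live-cycle default) |
| `Nmax` | 6 | – | overcrowding threshold (hexagonal packing in-plane) |
| `Tper` | 10 | min | persistence time of the motility direction |
| `dt_mech` / `dt_cell` | 0.1 / 6 | min | mechanics / phenotype time steps |
| `cell_volume_max` | 2494 | µm³ | target cell volume (radius ≈ 8.41 µm) |
| `adhesion_radius_multiple` | 1.25 | – | interaction radius / cell radius |
| `ccca` / `cccr` | 0.4 / 10 | µm·min⁻¹ | cell–cell adhesion / repulsion strengths |
| `voxel_size` | 20 | µm | ECM voxel edge |
| `domain_half_width` | 500 | µm | square domain half-width |
| `raster_n` | 5000 | – | area-raster resolution per axis |

The scenario presets encode the two cell lines and the drug condition:
non-invasive (`rdeg0 = 1e-4`, `S0 = 0.1`), invasive (`0.0032`, `0.7`), and
GM6001 (invasive with `rdeg0 = 4e-4`; the pan-MMP inhibitor blocks enzymatic
degradation but not mechanical remodelling, hence a reduced, non-zero rate).

The persistence time deserves a note: it is the one motility parameter for
which no published value exists for this model, and the mid-degradation
scenarios (50 mM invasive, GM6001) are the most sensitive to it. The default
of 10 min gives cells a persistence length of a few microns at full speed.
With the 1-min default of the PhysiCell platform the 72–96 h growth of those
two scenarios drops by roughly 10 %; both values are defensible, the default
here is deliberately kept fixed across all shipped analyses, and `Tper` is
exposed for sensitivity studies.

## Initial conditions

A spheroid of diameter $D$ is seeded as a hexagonally packed disc of cells
at full volume, with the ECM density 0 at voxels whose centres fall inside
the disc and 1 elsewhere (the matrix is homogeneous and undisturbed outside
the spheroid). The packing spacing is not free: it is calibrated by scanning
$[1.8R, 2.0R]$ for the value at which a 100-µm disc holds exactly 139 cells,
the count corresponding to a 200-µm spheroid; the midpoint of the admissible
sub-interval (≈ 16.23 µm ≈ 1.93 R) is used and recorded in the run metadata.
The calibration pins the initial cell density to the experimental anchor
while keeping neighbouring cells slightly compressed, as in a real spheroid.

```{r init}
st <- init_spheroid(200, model_params())
nrow(st$cells)
st$meta$hex_spacing
```

## Numerical choices

* **Degradation** uses the exact exponential per step rather than forward
  Euler: unconditionally stable, preserves $\rho \ge 0$, and identical to
  first order at the model's small rates. Updates from several cells on one
  voxel commute, so the per-cell application order is immaterial.
* **Integration** of positions is forward Euler at `dt_mech = 0.1` min. At
  the model's speeds (≤ 0.7 µm·min⁻¹) a step moves a cell by at most
  0.07 µm — far below any behavioural tolerance — so a multistep scheme
  would change nothing observable.
* **Step order** (fixed for reproducibility): voxel selection → degradation
  → direction resampling → synchronous velocity evaluation from pre-step
  positions → move; on phenotype steps, division first, then volume growth.
* **Tie-breaks**: a point equidistant between voxel centres goes to the
  smaller row-major index; coincident cell centres repel along a fixed axis
  and are counted.
* **RNG discipline**: one stream per replicate (replicate $k$ seeds at
  `base_seed + k`); draws are consumed in cell order — direction resamples,
  then division trials — so runs are bit-reproducible given (config, seed).
* **Degenerate inputs**: Delaunay statistics on fewer than three distinct or
  collinear centres are recorded as missing rather than erroring; cell
  fronts leaving the lattice are clamped to the boundary voxel and counted.

## Measurements

The measurement stack is a pure function of recorded snapshots:

* **Rasterized area**: the domain is divided into a 5000×5000 grid; elements
  whose centre lies in at least one cell disk count once (overlaps ignored),
  and the count is rescaled to µm². **Relative growth** divides by the
  area at $t=0$.
* **Cell count** per timepoint.
* **Delaunay mean distance**: mean edge length of the Delaunay
  triangulation of cell centres (via the `deldir` triangulation), a
  compactness statistic — denser spheroid, shorter edges.
* Replicates are aggregated as mean and 25th/75th percentiles (linear
  interpolation) every 60 min.

## A worked run

The shipped analyses use desk-scale problem sizes — 3 replicates per
condition and the 200-µm spheroid — which keep a full 96 h condition under
a few minutes on one core while leaving the replicate-to-replicate spread
far smaller than the effects of interest. Here is a deliberately small
illustration (a 100-µm spheroid for 6 h):

```{r run}
p <- model_params(domain_half_width = 200, spheroid_diameter = 100)
sim <- simulate_spheroid(p, t_end = 6 * 60, seed = 1)
sim$metrics
```

```{r plot, fig.width = 5, fig.height = 4}
ggplot2::autoplot(sim)
```

The scenario drivers reproduce the study conditions end to end:

```{r scenario, eval = FALSE}
inv0 <- run_scenario("invasive", rib = 0, n_reps = 3, base_seed = 0)
plot_growth_curves(inv0)
```

## What the generator does and does not emulate

The simulations are fully self-generating: the initial state is the packed
disc above, and all stochasticity is the persistence-driven direction
resampling and the division trials. The model reproduces the qualitative
biology — growth suppressed by stiffening in invasive cells, insensitivity
in non-invasive cells, reduced growth under MMP inhibition, non-monotone
response to the degradation rate — and quantitatively tracks the published
population-level summaries at the default parameters. It does **not**
represent fibre orientation or contact guidance, ECM deposition, nutrient
limitation, or cell death; replicate variability is therefore much smaller
than in vitro, and conclusions from passing tests transfer to real data
only at the level of means, not variances or extremes.

## Known limitations

* The ECM degrades toward zero density with no floor; at very high
  degradation rates the matrix empties so fast that migration stalls
  (speed peaks at $\rho = 0.5$), which the model family reports as a real
  but untested-in-vitro prediction.
* `Tper` is unconstrained by published values (see above).
* The pseudo-2D plane cannot capture out-of-plane invasion; counts and
  areas correspond to a single slice.
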