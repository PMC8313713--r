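---
title: "Membrane mismatch energetics and PMF reconstruction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane mismatch energetics and PMF reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mismatchlab)
```

## The scientific problem

A membrane protein whose hydrophobic span is shorter than the bilayer's
hydrophobic thickness (negative hydrophobic mismatch) thins the membrane
around itself. When two such inclusions associate, their thinned annuli
merge and the total boundary between the perturbed (disordered-like) region
and the unperturbed liquid-ordered bulk shrinks. Treating that boundary as
a phase boundary with line tension $\gamma$, the mismatch contribution to
the association free energy is

$$\Delta G = -\,\Delta p \cdot \gamma,$$

where $\Delta p$ is the reduction of the boundary length on complexation
(sum of isolated-state perimeters minus the complex perimeter). With
experimental line tensions of 1–3 pN between ordered and disordered lipid
phases and $1\ \mathrm{pN\,nm} = 0.14393\ \mathrm{kcal\,mol^{-1}}$, a
perimeter reduction of a few nanometres is worth one to a few
kcal/mol — the same order as the total binding affinity of a
transmembrane substrate for an intramembrane protease, which is why this
lipid-mediated term matters.

The package implements the full measurement chain on coordinate data:

1. **surface mapping** — phosphorus z positions of each leaflet averaged on
   a periodic 2D grid; thickness = upper minus lower surface;
2. **occupancy mapping** — which grid cells the protein occupies;
3. **segmentation** — cells thinner than $h_\mathrm{bulk} - \delta$ and not
   protein-occupied, with the boundary extracted as a sub-cell iso-contour
   and split into bulk-facing and protein-facing parts;
4. **energetics** — $\Delta p$ and the interval
   $[-\Delta p\,\gamma_\mathrm{high},\, -\Delta p\,\gamma_\mathrm{low}]$;
5. **order parameters** — $S_{CD} = \tfrac12\langle 3\cos^2\theta - 1\rangle$
   near the protein vs bulk, with block-averaged uncertainties;
6. **PMF reconstruction** — WHAM over umbrella-sampling windows with
   autocorrelation-aware bootstrap errors and end-state binding free
   energies.

## Key parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `h_bulk` | 4.76 | nm | bulk phosphorus–phosphorus thickness of the cholesterol-rich reference bilayer at 320 K |
| `delta` | 0.15 | nm | thinning threshold defining the perturbed region |
| `cutoff` | 1.6 | nm | in-plane proximity radius for "near-protein" lipid selections |
| `temperature` | 320 | K | thermostat temperature; kT = 0.6359 kcal/mol |
| `gamma` | 1–3 | pN | ordered/disordered line-tension range |
| `k` | 3500 | kJ mol⁻¹ nm⁻² | umbrella spring constant; biased-window sd ≈ 0.028 nm |
| grid | 500×500 | cells | reference mapping resolution (tests use 32–192 for speed) |

All of these are carried in a single validated configuration
(`analysis_config()` / `read_config()`, YAML on disk); unknown keys are
rejected so a typo cannot silently fall back to a default, and every JSON
report echoes the exact thresholds used, because the headline numbers are
threshold-sensitive.

## The synthetic membrane model

`gen_membrane_snapshots()` emulates the *outputs* of membrane MD — never
the dynamics. Lipid phosphorus positions are a spatial Poisson process
(default 1.5 lipids/nm² per leaflet, a typical all-atom bilayer density)
outside the protein footprints; leaflet heights are
$\pm h(x,y)/2$ plus Gaussian thermal roughness (default 0.1 nm, a free
synthetic parameter of the model, chosen as a realistic per-lipid
out-of-plane amplitude), with

$$h(x, y) = h_0 - \sum_i A_i \exp\!\big(-d_i^2 / 2\sigma_i^2\big),$$

where $d_i$ is the in-plane distance to the *boundary* of footprint $i$
(zero inside). Anchoring the well at the boundary rather than the centre
makes larger inclusions carry wider thinned annuli, which is the geometry
the perimeter analysis must reproduce. The closed form gives exact oracles:
a point-like well crosses the threshold $\delta$ at radius
$r^* = \sigma\sqrt{2\ln(A/\delta)}$, so the extracted contour perimeter can
be checked against $2\pi r^*$ to within grid discretization.

Protein atoms are rasterized as a static membrane-spanning slab (default
10 atoms/nm³); only occupancy maps consume them. What the generator does
*not* emulate: lipid chemical identity (DPPC vs cholesterol molecules are
not distinguished — only the emergent thickness and order fields),
curvature coupling, correlated undulations, protein conformational
dynamics. Tests passing on this model therefore validate the *measurement
chain*, not force-field realism.

## The umbrella-series generator

`gen_umbrella_series()` draws window time series whose stationary marginal
is **exactly** the biased Boltzmann density
$p_i(x) \propto e^{-[F(x) + \frac{k}{2}(x - x_{0,i})^2]/kT}$, via an
inverse-CDF Gaussian-copula AR(1) scheme: a stationary AR(1) latent series
with lag-1 correlation $e^{-1/\mathrm{corr\_len}}$ is mapped through the
normal CDF and the biased density's quantile function. Only the stationary
density and a tunable correlation length matter for testing the analysis;
this construction delivers both without simulating any dynamics, and is
reproducible bit-for-bit from (spec, seed).

Two numerical details proved load-bearing. The CDF is accumulated
trapezoidally (a left-Riemann cumulative sum biases the quantile map at
$O(\Delta x)$), and the inversion grid is refined until its spacing is a
small fraction of the biased-window standard deviation $\sqrt{kT/k}$ —
with stiff springs a too-coarse quantile grid distorts window marginals
enough to tilt the reconstructed profile by several hundredths of a
kcal/mol.

## Segmentation and perimeters

The perturbed-region boundary is extracted as the iso-contour of the
(optionally smoothed) thickness field at level $h_\mathrm{bulk} - \delta$
using marching squares with linear interpolation
(`grDevices::contourLines`). Sub-cell contours are essential: counting
pixel edges of the binary mask overestimates smooth perimeters by up to
$4/\pi$.

Decisions taken where the procedure is genuinely open:

* **Speckle control.** Thermal roughness creates spurious below-threshold
  cells; connected components smaller than `min_cells` (default 4) are
  discarded, and an optional periodic Gaussian pre-smoothing of the field
  (`smooth_sigma`, in cells) suppresses contour noise. Smoothing a Gaussian
  well of width $\sigma$ with a kernel of 1–2 cells changes $r^*$
  negligibly (the widened well has proportionally reduced amplitude), so
  smoothing trades variance for essentially no bias on smooth wells; the
  smoothing width used is always reported.
* **Boundary classes.** Contour segments whose midpoint lies within one
  cell of an occupied cell are protein-facing; the occupied-region boundary
  adjoining the mask is also protein-facing. For an isolated substrate the
  relevant perimeter is the bulk-facing class only; for the enzyme both
  classes are included. `region_perimeter()` exposes both so the assumption
  that the protein–membrane interface stays constant on binding can be
  tested rather than asserted.
* **Periodicity.** Cell assignment, distances and smoothing are fully
  periodic; the marching-squares contour itself is extracted on the plain
  grid, so a region crossing the box boundary contributes no artificial
  contour there (it is bounded by the periodic images). Analyses should
  keep wells away from the box edge, as the synthetic generator does.

## WHAM and its uncertainties

The profile solves the standard self-consistency
$p_b = \sum_i n_{ib} \,/\, \sum_i N_i f_i c_{ib}$,
$f_i^{-1} = \sum_b c_{ib} p_b$, iterated until the window offsets
$-kT\ln f_i$ change by less than `tol` (default $10^{-6}$ kcal/mol,
`max_iter` $10^5$). The bias factors $c_{ib}$ are *bin-averaged* over eight
quadrature nodes rather than evaluated at bin centres: with k = 3500
kJ mol⁻¹ nm⁻² the bias varies by ~0.1 kcal/mol across a default bin, and
centre evaluation visibly tilts the window coupling. The test suite
cross-checks the iteration against an independent maximum-likelihood
formulation (direct BFGS optimization of the binned WHAM likelihood); the
two routes agree to well under 0.01 kcal/mol per bin.

Uncertainties follow the Monte-Carlo bootstrap with the effective sample
size: each window's integrated autocorrelation time is estimated by the
initial-positive-sequence rule
($\tau_\mathrm{int} = \tfrac12 + \sum_t \rho(t)$ truncated at the first
negative $\rho$), and every bootstrap replicate redraws only
$N_\mathrm{eff} = N/(2\tau_\mathrm{int})$ points per window before
rerunning WHAM on the reference binning; replicate profiles are aligned on
the commonly populated bins and the per-bin standard deviation across
replicates is $\sigma_F$. Against a brute-force oracle (many fully
regenerated datasets) this calibrates to well within a factor of two per
bin, with a mild tendency to *over*-estimate in sparsely sampled bins,
where the uniform $N_\mathrm{eff}$ deflation over-penalizes rare-visit
statistics.

Binding free energies are ratios of Boltzmann-weighted trapezoidal
integrals of the profile over a bound and a reference interval,
$\Delta G = -kT \ln \int_\mathrm{bound} e^{-F/kT} /
\int_\mathrm{ref} e^{-F/kT}$, with the same functional evaluated on every
bootstrap replicate for the error bar. The estimator deliberately takes
*both* intervals as explicit arguments — how "bound" and "unbound" are
delimited is a reporting convention, not something the profile itself
fixes — and both intervals should lie inside the window-covered range,
since bins at the coverage edge carry large, skewed errors. Known
limitation: log-histogram estimates are biased upward in low-count bins
(by about $kT/2n_b$), which can shift a sharp-well $\Delta G$ by a few
hundredths of a kcal/mol at moderate sampling; this is visible as a small
systematic in the square-well recovery and shrinks with longer series.

## Order parameters

$S_{CD}$ is computed per carbon from C–H unit vectors against the global
z-axis (the membrane normal; local-normal correction is out of scope and
flagged). Bond values are bounded in $[-0.5, 1]$ by construction — $-0.5$
perpendicular, $0$ at the magic angle $54.7356^\circ$ or for isotropic
orientations, $1$ parallel — so profile values are too. Uncertainties use
block averaging: the series is cut into consecutive blocks
(`frames_per_block` maps a physical block length, e.g. 100 ns, to frames),
incomplete trailing blocks are discarded, and the SEM is the standard
deviation of block means over $\sqrt{n_\mathrm{blocks}}$.

## Problem sizes used in the shipped tests

Synthetic membranes: 12×12 nm boxes, 96–128² grids, 50–600 frames —
chosen so that per-cell thickness SEM after smoothing is well below the
0.15 nm threshold contrast, which is what the 2 % perimeter tolerance
requires. Umbrella data: 8 windows × 0.1 nm at k = 3500 kJ mol⁻¹ nm⁻²
with 2–5·10⁴ samples/window and correlation lengths 0–5; at these sizes
the double-well RMSE target (0.15 kT) has comfortable statistical margin,
while inter-well depth differences at 0.1 kT resolution need the shorter
correlation lengths (the long-range tilt error scales as
$\sqrt{2\tau_\mathrm{int}/N}$ per window coupling). The bootstrap
calibration compares 100 bootstrap replicates against 50 regenerated
datasets on 60 bins spanning the window-covered range.

## Limitations

* The synthetic membrane has uncorrelated per-lipid roughness; real
  bilayers have spectrally correlated undulations that would lower the
  effective number of independent observations per cell.
* Multi-model PDB output requires identical atom counts per frame (a
  format constraint); per-frame GRO files carry varying lipid counts.
* The contour extractor treats the grid as non-periodic; regions wrapping
  the box boundary are supported for masks and areas but their wrapped
  contour is not stitched across images.
* WHAM assumes windows are independent given their biases; replica-exchange
  structure in the data only changes autocorrelation, which
  $\tau_\mathrm{int}$ absorbs.
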