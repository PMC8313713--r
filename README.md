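# mismatchlab

Membrane-biophysics analysis for protein–lipid interaction studies: how much
does a transmembrane inclusion perturb the bilayer around it, and what does
that perturbation contribute to binding thermodynamics?

The package is aimed at people analysing (or emulating) molecular-dynamics
data of membrane proteins — for example an intramembrane protease and its
substrate in a cholesterol-rich bilayer, where cholesterol thickens the
membrane, creates negative hydrophobic mismatch with both proteins, and the
resulting lipid-mediated attraction contributes a large fraction of the
binding affinity.

## What it computes

**Mismatch energetics.** A protein shorter than the bilayer's hydrophobic
thickness thins the membrane around itself. The thinned region (thickness
below `h_bulk − δ`, default 4.76 − 0.15 nm, protein-occupied cells excluded)
is segmented from gridded 2D thickness maps; its boundary is extracted as a
sub-cell iso-contour (marching squares) and split into bulk-facing and
protein-facing parts. Treating the thinned region as a disordered phase with
line tension γ against the ordered bulk, the mismatch contribution of a
perimeter change Δp on complexation is

    ΔG = −Δp · γ,    γ ∈ [1, 3] pN,    1 pN·nm = 0.14393 kcal/mol

**PMF reconstruction.** Umbrella-sampling window series (spring constant
k = 3500 kJ mol⁻¹ nm⁻², 0.1 nm window spacing by default) are combined by
the weighted histogram analysis method (WHAM); per-window integrated
autocorrelation times set the effective sample counts for a Monte-Carlo
bootstrap of the profile, and binding free energies are Boltzmann-weighted
integrals over explicit bound/reference intervals.

**Order parameters.** Deuterium order parameters
S_CD = ½⟨3cos²θ − 1⟩ for C–H bonds near a protein versus bulk, with
block-averaged uncertainties.

**Synthetic data with exact ground truth.** Generators for membrane
snapshots (Gaussian thinning wells around disk / polygon / horseshoe
footprints, Poisson lipid fields, thermal roughness), chain ensembles with
prescribed orientational order, and umbrella series drawn exactly from the
biased Boltzmann density of an analytic free-energy profile with tunable
autocorrelation. Every analysis stage is tested against these closed forms.

## Worked example

Perimeters measured from thickness maps of the isolated proteins (13.6 and
7.1 nm) and of the complex (13.3 nm) convert into a line-tension free-energy
interval:

```r
library(mismatchlab)

dp <- perimeter_change(isolated = c(13.6, 7.1), associated = 13.3)
mismatch_free_energy(dp, gamma_low = 1, gamma_high = 3)
#> <energy_interval: Delta p = 7.40 nm, gamma 1-3 pN -> [-3.2, -1.1] kcal/mol>
```

i.e. the complex is stabilized by 1.1–3.2 kcal/mol purely by shortening the
disordered-region boundary by 7.4 nm.

Reconstructing a binding free energy from synthetic umbrella windows with a
known square-well profile (depth 2 kT at 320 K = 1.27 kcal/mol):

```r
kT  <- kT_kcal(320)
pmf <- pmf_square_well(depth = 2 * kT, width = 0.3,
                       domain = c(1.0, 1.9), center = 1.25)
ds   <- gen_umbrella_series(pmf, centers = seq(1.05, 1.75, by = 0.1),
                            k = 3500, n_steps = 2e4, corr_len = 3, seed = 7)
boot <- bootstrap_uncertainty(ds, n_boot = 30, seed = 8, bins = 150)
binding_free_energy(boot$profile, bound = c(1.1, 1.4),
                    reference = c(1.45, 1.75), boot = boot)
#> <binding_result: Delta G = -1.31(7) kcal/mol (bound [1.10, 1.40] nm vs reference [1.45, 1.75] nm)>
```

The estimate −1.31(7) kcal/mol (uncertainty in the last digit) covers the
ground truth −1.27 kcal/mol. End-to-end pipelines (`run_pipeline()`) chain
coordinate reading (GRO / multi-model PDB), mapping, segmentation and
energetics — or window manifests, WHAM and bootstrap — from a single
validated YAML config and write JSON reports carrying the exact thresholds
used.

## Vignette

`vignettes/mismatchlab-methods.Rmd` documents the models, the estimators,
the numerical choices (bin-averaged bias factors in WHAM, trapezoidal
quantile inversion in the generator, contour smoothing) and the known
limitations.
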