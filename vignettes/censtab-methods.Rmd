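---
title: "Models and numerical choices in censtab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in censtab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(censtab)
```

censtab packages the bespoke quantifications of HAC-based chromosome
stability work: the per-division rate of HAC loss with a mixture-fitted
division index, the per-cell median-focus readout for FISH and
immunofluorescence, an object-based 3D colocalization pipeline, and
circularity-filtered colony counting. This vignette documents the models
behind each estimator, the parameters that matter, what the synthetic-data
generators do and do not emulate, and the numerical conventions the
implementation pins down.

## Rate of HAC loss

A HAC carries a destabilized GFP reporter, so a cell that loses the HAC
goes GFP-negative within a cell cycle. If a fraction $P_0$ of live cells is
GFP+ at baseline and $P_{si}$ after a treatment spanning $n$ divisions, and
the HAC is lost independently with probability $R$ per division, then
$P_{si}/P_0 = (1 - R/2)^n$, giving

$$R = 2 - 2\,(P_{si}/P_0)^{1/n}.$$

`hac_loss_rate()` evaluates this closed form. It is exactly 0 at
$P_{si}=P_0$, strictly decreasing in $P_{si}$, and tends to 2 (all
daughters HAC-free) as $P_{si} \to 0$. The ratio is scale-invariant, so
percentages and fractions give identical rates; the package stores
fractions and converts percentage input only at the boundary. $P_{si} >
P_0$ is allowed but flagged (a negative rate means apparent gain, usually
gating drift).

Live/dead gating uses the viability dye (dead cells take it up, so *live*
means below threshold) and conserves counts: live + dead = total at every
threshold. When no manual gate is given, the gate defaults to the valley
between a two-component log-normal mixture fitted by EM to the channel —
the automated stand-in for the manual valley gate set in flow software.

## Division index from dye dilution

A proliferation dye halves with each division, so log-fluorescence of a
population is a Gaussian mixture with component means $\mu_0 + g
\log(\rho)$ for generations $g = 0, 1, \dots$ and peak ratio $\rho = 0.5$.
`fit_dye_dilution()` keeps the conventional constraints of proliferation
software: $\rho$ fixed (default 0.5), the common log-domain SD $\sigma$
fixed from the undivided reference population, 7 peaks by default (6–8 is
the conventional range), and only the generation weights $w_g$ free. The
weights are fitted by maximum likelihood with EM on the weight simplex —
with means and $\sigma$ fixed the component densities never change, so
each EM iteration is a cheap reweighting and the fit is stable. The anchor
$\mu_0$ is refined within $\pm 0.5\sigma$ of the reference mean by
profile-likelihood search, and kept at the reference mean if refinement
does not improve the likelihood.

Two division-index conventions are exposed, because the reduction from
weights to "mean divisions" is ambiguous and proliferation tools differ:

* **precursor-weighted** (default): each generation's event count is
  divided by $2^g$ to count founder cells,
  $DI = \sum_g g\,(w_g/2^g) / \sum_g (w_g/2^g)$;
* **event-weighted**: $DI = \sum_g g\,w_g$ over measured events.

Both coincide for a synchronously dividing population. The default is the
precursor-weighted form, which matches the sanity check that a culture at
its doubling time for 72 h reads DI ≈ 4.

The generator `sim_dye_dilution()` draws events per generation from the
same log-domain mixture, using the CV directly as the log-SD (exact to
first order for CV ≤ 0.15); the fit estimates $\sigma$ empirically from
the reference, so generator and estimator share no hidden constant.
`generation_weights_from_di()` maps a target DI to weights through a
binomial founder model, $G \sim \mathrm{Binom}(6, DI/6)$ — the simplest
asynchronous-division model; its precursor-weighted mean equals the target
exactly, which makes parameter-recovery experiments well-posed. The
recovery suite simulates 10,000 events per experiment and averages 10
seeds per condition; recovered DI is within ±0.05 of the target at the
reported values (3.33, 2.80, 3.62).

## Median-focus quantification

The per-cell readout for FISH/IF fields proceeds in fixed steps:

1. **Detection**: foci are 8-connected components of `channel >=
   threshold` restricted to nucleus pixels, with area ≥ `min_area`
   (default 2 px, suppressing single-pixel noise; the threshold itself is
   a free parameter, typically 300–600 a.u. on 12-bit-like data).
2. **Boxes**: an even box of side $s$ (10–20 px, one size per run) is cut
   around each focus centroid. Coordinates are 1-based (row, col), origin
   top-left; the box spans rows $r - s/2$ to $r + s/2 - 1$, so the
   centroid sits at patch position $(s/2+1, s/2+1)$. Boxes crossing the
   image border are dropped and logged rather than padded — padding would
   bias the perimeter background.
3. **Median focus**: pixel-wise median across the cell's boxes; an even
   count uses the mean of the two central order statistics.
4. **Background**: the median of the box's outermost one-pixel ring
   ($4(s-1)$ values).
5. **Signal**: $\sum (\text{patch} - \text{background})$, unclamped.
   Negative sums are retained; as a consequence the signal is exactly
   invariant to adding a constant to the whole patch, which the test suite
   asserts on integer-valued patches where floating-point arithmetic is
   exact.

`anchored_quantify()` re-uses the boxes defined by an anchor channel for
every signal channel and reports each signal as a per-cell ratio to the
anchor. `normalize_to_control()` divides by the control-condition mean, so
the control maps to exactly 1.

## 3D colocalization

Nuclei are segmented by one global Otsu threshold computed on a 256-bin
histogram of the whole DNA channel (not per slice), and all channels are
zeroed outside the mask. Otsu always returns *some* split, even on pure
noise, so the segmentation additionally requires the Otsu effectiveness
(between-class over total variance) to reach 0.75; below that the stack is
declared background-only and an empty mask is returned with a warning.
This guard is what makes "no nuclei" a possible answer.

Individualization follows the max-Z projection of the mask: holes filled,
8-connected 2D components, one record per component with its Z-stack crop
(bounding box padded 2 px laterally, full depth). QC then applies the
automatic rules — projection touching a lateral image border (`edge`;
Z truncation is inherent to stacks and not an exclusion), projected area
above 300 µm² (`too_large`, measured on the projection) — and honours
annotation-driven flags (`mitotic`, `overlapping`, `out_of_focus`,
`bad_segmentation`, `apoptotic`), which were human judgments in the
original workflow and are deliberately not automated heuristics. Every
exclusion carries its reason code, and selection (`select_nuclei()`)
uniformly shuffles the survivors with a per-condition seed and keeps the
first 100.

Foci are segmented by seeded region growing: Gaussian smoothing
(separable; by default almost none along Z, whose 0.71 µm spacing already
undersamples diffraction-limited foci), 26-connected local maxima above a
seed threshold (plateaus collapsed to one seed), then 26-connected
breadth-first growth down to an include threshold. Contended voxels go to
the seed that reaches them first; wavefront ties break toward the brighter
seed, making the labeling deterministic. Spots outside volume bounds are
discarded. Both thresholds apply to smoothed intensities and are exposed
as free parameters, to be set against reference images.

Colocalization is object-based only: for each reference focus, the
fraction of its voxel volume intersected by each partner focus. The
reference channel is the denominator by convention (direction is chosen by
argument order), and events below 10% overlap are removed as chance
apposition — the boundary is inclusive, so an exact 10% overlap survives.
Summaries report the per-nucleus event count, the fraction of nuclei with
at least one event, mean events per nucleus, the overlap-fraction
distribution, and per-channel focus counts.

## Colony counting

Colonies are 8-connected components above an 8-bit threshold, filtered to
circularity $4\pi A/P^2 \in [0.01, 1.00]$. Circularity is dominated by the
perimeter estimator, so the estimator is pinned: the outer boundary is
traced through pixel centers (Moore neighbourhood), axial steps count 1
and diagonal steps $\sqrt 2$, plus a half-pixel convexity correction of
$\pi$ (the true outline runs half a pixel outside the center chain). Under
this definition a large rasterized disk measures circularity ≈ 0.95
(within [0.85, 1.05]), a 1-px streak of length $L$ has $P = 2(L-1) + \pi$
— length 1000 gives circularity ≈ 0.0031, excluded by the filter — and a
single isolated pixel (perimeter $\pi$, circularity $4/\pi > 1$) is
excluded as sub-resolution. A plain crack-length (edge-count) perimeter
was rejected because it caps disk circularity at $\pi^2/16 \approx 0.62$,
which would defeat a filter whose upper bound is meant to *keep* round
colonies.

## What the generators emulate — and what they do not

The simulators produce data with the statistical structure the estimators
assume, plus complete ground truth (every focus amplitude and position,
every spot voxel set, every engineered overlap fraction realized on the
voxel grid and recorded exactly, realized GFP+/dead fractions, true DI
under both definitions):

* 2D fields: disk nuclei on a jittered grid, isotropic Gaussian foci of
  known amplitude at integer pixel positions, flat background, additive
  Gaussian noise clipped at 0.
* Z-stacks: ellipsoidal nuclei, spherical (voxelized) foci, default
  geometry of 15 slices spanning 10.65 µm with 0.1 µm lateral pixels
  (the lateral size is a free default; acquisition metadata should
  override it for real data).
* Flow tables: log-normal intensity populations for GFP±, live/dead and
  dye-dilution generations.

They deliberately do **not** model optics (no PSF), camera noise
statistics, spectral bleed-through, chromatic shift, FCS file structure,
or irregular nucleus shapes. Passing the recovery suites therefore shows
the estimators are correct for the model they assume — it does not certify
thresholds or spot-segmentation parameters for any particular microscope,
which must still be chosen against reference images of real data.

Packing is explicit about feasibility: generators fail with a
`censtab_packing_error` rather than silently overlapping objects, and
engineered overlaps fail as unrealizable when the two channels' spot radii
differ (equal-shape balls are what makes an exact lattice overlap
constructible; the achieved fraction, realized within about one voxel of
target, is always recorded).

## Problem sizes and runtime

The test suite and acceptance script run at desk scale by design:
dye-dilution recovery uses 10,000-event experiments (10 seeds × 3
conditions, a few seconds); oracle-equivalence suites use 1,000 random
patch sets and 1,000 random voxel-set pairs; the end-to-end colocalization
cohort uses 54 nuclei in a 380×340×15 stack (about a minute); exo-FISH
monotonicity uses 54 cells per amplitude level. These sizes were chosen so
the statistical assertions (binomial error, ±0.05 DI recovery, exact
cohort counts) are comfortably powered.

## Known limitations

* The constrained mixture assumes a common peak CV; strongly
  generation-dependent CVs (dye toxicity, autofluorescence floors) bias
  late-generation weights.
* Threshold-based focus detection merges foci closer than the threshold
  contour allows; the generators enforce a minimum focus separation, real
  data need not.
* Volume overlap is voxel-based: fractions on coarse grids are quantized
  (refining the grid changes engineered-sphere fractions by a few
  percent), and anisotropic voxels make small spots effectively
  single-slice.
* The 2D pipeline takes nucleus masks as input (from the generator or an
  external segmenter); it does not segment nuclei from DAPI itself.
* Statistical testing across conditions (t tests, ANOVA) is out of scope;
  `condition_table()` exposes per-replicate means so standard tools can be
  applied downstream.
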