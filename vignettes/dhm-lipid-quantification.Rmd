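---
title: "Label-free lipid droplet quantification from phase images: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free lipid droplet quantification from phase images: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhmlipid)
```

## The measurement model

Digital holographic microscopy delivers, per pixel, the optical path
difference

$$\mathrm{OPD}(x, y) = d(x, y) \, \big[ n_c(x, y) - n_m \big],$$

where $d$ is the cell thickness, $n_c$ the z-integrated intracellular
refractive index, and $n_m$ the refractive index of the culture medium. The
package expresses OPD in nanometers. Two facts make this a lipid readout:
lipid droplets have a markedly higher refractive index than cytoplasm, so a
droplet-laden adipocyte produces more OPD per unit thickness; and the
measurement requires no stain, so the same fragile, differentiation-prone
cells can be measured repeatedly without the washing and staining steps
that perturb them.

Everything downstream of the reconstructed phase image is implemented
here: segmentation, per-cell features, phenotype classification
(undifferentiated / adipocytic / dead / error), well aggregation, the
fluorescence comparison branch, and screening statistics (Z′, linear
correlation, four-parameter logistic dose-response fits with censoring).
Hologram recording and numerical reconstruction are upstream of this
package and out of scope, as is any diffraction or point-spread modeling.

## The synthetic field generator

There is no public deposit of raw phase images for this assay, so the
package ships a physics-based generator that produces ground-truthed
fields on which every stage of the measurement chain can be validated.

Cells are spherical-cap thickness profiles,
$t(r) = t_{\max}\sqrt{1 - r^2}$ in normalized elliptical radius, placed by
rejection sampling under a minimum centroid-separation constraint
(`min_sep_factor`, default 1.05 times the sum of outer radii; the
constraint is waived when a field is too crowded to satisfy it, so dense
fields contain touching cells as a confluent monolayer does). The three
phenotypes follow their qualitative definitions:

* **undifferentiated** — large (semi-major axis 15–30 µm, axis ratio up to
  1.5), moderately thick (3–6 µm), cytoplasmic index only;
* **adipocytic** — same footprint, slightly thicker (4–6 µm), with
  circular droplet inclusions (radius 1–5 µm) at elevated index covering a
  target 25–45% of the cell area (the realized area fraction is recorded
  as the cell's droplet volume fraction);
* **dead** — small (radius 4–7 µm), round, thick (6–10 µm) caps at a
  condensed, elevated index.

Refractive indices are not reported for this system; the defaults are
literature-typical values chosen once to preserve the qualitative contrast
ordering: medium 1.337, cytoplasm 1.365, lipid droplet 1.470, condensed
dead-cell cytoplasm 1.390. The dead-cell index and the 4–7 µm radius range
were fixed so that the three phenotype regimes are well separated in the
(area, roundness, mean-OPD) feature space: with qualitative phenotype
definitions only, a generator whose phenotypes overlap in feature space
would make "ground truth" ill-defined at the boundary. With these
defaults, per-cell mean OPD spans roughly 55–110 nm for cytoplasm-only
cells and 165–355 nm for droplet-bearing ones (measured over ten noiseless
fields), an empty gap into which the classification cutoff is placed.

Rendering adds Gaussian OPD noise (default SD 4 nm) and a smooth random
second-order polynomial background drift (default peak 8 nm), the simplest
model under which "a threshold slightly higher than the background" is a
nontrivial operation. Pixel size defaults are 0.65 µm (10×) and 0.325 µm
(20×) over a 512×512 field; the objectives' magnifications are known but
the camera pixel pitch is not, so these are conventions. Absolute OPD
magnitudes for this cell system are likewise unavailable; the simulator's
magnitudes are conventions, and all validation is therefore structural
(recovery, ordering, correlation) rather than a comparison of absolute nm
values.

The fluorescence counterpart renders a nuclear channel (one Gaussian blob
per cell), a lipid channel (faint cytoplasm, a diffuse component
proportional to the droplet volume fraction standing in for sub-resolution
droplets, and resolved droplets whose brightness also grows with the
cell's droplet load — stain fluorescence integrates over z, so heavier
droplets are brighter per pixel, not just more numerous), and a death
channel bright only over
dead cells; a multiplicative illumination gradient (default ±30% peak) and
additive detector noise are applied to all channels, and a `stain_failure`
flag rescales the lipid channel globally to emulate a failed staining
round. Channels are background-subtracted intensities: there is no
autofluorescence pedestal, no bleaching, and no spectral cross-talk.
Passing tests on these fields therefore demonstrates that the measurement
chain is correct under the stated noise model — not that it is robust to
every artifact of real microscopy.

## Segmentation and quantification choices

"Slightly higher than the background" is quantified as
median + `offset_sd` × (1.4826 × MAD) with `offset_sd = 3`; the robust
estimates make the threshold insensitive to the cells themselves as long
as the field is sub-confluent. Components are 8-connected; objects below
20 µm² are discarded as noise (well below the dead-cell scale). No
declumping is attempted — touching cells count as one object, which is
also why cell counting is only validated in the sub-confluent regime.

Edge-touching objects are excluded from counting and classification
(their shape and area are truncated) but still contribute pixels to the
pooled well-level mean OPD: truncation biases shape statistics, but a
truncated cell's pixels are still valid OPD signal. The
well OPD is the pooled pixel mean over all segmented pixels of a field
(one threshold, all cells), averaged over the four fields of a well;
fields with an empty mask are dropped from the average, and a well whose
fields are all empty is flagged rather than zeroed.

The Ridler–Calvard threshold is the classic iterative intermeans fixed
point $t = (\mu_{\le t} + \mu_{> t})/2$, initialized at the midrange,
iterated to $10^{-8}$; a constant image is a degenerate histogram and an
error. Its test oracle enumerates every cut between consecutive gray
levels and checks the fixed-point condition exhaustively.

Per-cell features are area, crack-boundary perimeter scaled by π/4
(unbiased for convex digitized shapes), form factor 4π·area/perimeter²,
moment-based eccentricity, and mean/integrated OPD. The rule classifier
encodes the phenotype definitions directly: dead ⇔ small (< 200 µm²) and
round (form factor > 0.85) and high OPD; adipocytic ⇔ large and high OPD;
undifferentiated ⇔ large and low OPD; everything else (e.g. small dim
debris) is "error". The OPD cutoff (135 nm) was calibrated once from
simulator truth, placed inside the empty gap between the cytoplasm-only
and droplet-bearing per-cell OPD distributions rather than at the midpoint
of their means, because the adipocytic distribution's lower tail reaches
below that midpoint. The machine-learning classifiers (random forest, 100
trees; k-nearest neighbors, k = 5 on standardized features) train on
simulator truth labels — by construction the generator knows every cell's
phenotype, so no manual annotation step exists — and report out-of-bag /
leave-one-out accuracy.

## The fluorescence comparison branch

Illumination correction divides a channel by a heavily smoothed version of
itself (Gaussian, default σ = 100 µm, computed on a block-averaged pyramid
level and upsampled) and rescales to preserve the global median. Two
numerical details matter. First, the Gaussian support exceeds the field at
these scales, so the blur runs on an odd-reflection (antisymmetric) padded
frame, which continues linear gradients across the boundary instead of
flattening them. Second, the normalized correction field is clipped to
[1/1.5, 1.5]: real illumination gradients are bounded, and on a sparse
dark-background channel an unclipped single-image estimate is dominated by
the cells themselves and would suppress signal in crowded regions.
Division (not subtraction) was chosen because the emulated artifact is
multiplicative.

Nuclei are detected by an intermeans threshold floored at a robust
background ceiling (median + 3 MAD — without the floor, a signal-free
channel is split within its own noise), labeled, and size-filtered. The
lipid readout is the median intensity in a 20 µm disk around each nucleus
(the disk includes the nucleus region; nuclei nearer than the radius to
the field edge are measured on the clipped disk and flagged), summarized
as the median over cells and averaged over the four fields of a well. The
Nile Red branch builds a cytoplasm mask from the faint membrane staining
with the same background-anchored rule as the phase segmentation
(median + 3 MAD, floored at a 5 AU detector noise level, with a 50 µm²
minimum component size so noise cannot masquerade as cytoplasm). An
intermeans threshold was considered for this mask and rejected: with
three brightness classes in the histogram (background, faint
undifferentiated cytoplasm, bright droplet-laden cells) it settles
between the two cell classes and silently drops every dim cell. The
droplet threshold within the mask is found by intermeans, and the readout
is the field median over all cells of the per-cell median droplet
intensity, with droplet-free cells contributing their cytoplasm level so
they pull the median down rather than dropping out; a field with no
cell-sized mask component is flagged, reproducing the failure mode of an
unsuccessful staining round. The Et-HD positivity cutoff is fixed
(default 50 AU) and sits far above the 99.9th percentile of
negative-control intensities (a calibration helper is provided) and far
below dead-cell signal.

## Screening statistics

Z′ uses the standard screening-window coefficient
$1 - 3(\sigma_{+} + \sigma_{-}) / |\mu_{+} - \mu_{-}|$ on well-level
replicates, the convention for plate QC. Equal arm means are flagged
rather than divided by zero.

Dose-response curves are four-parameter logistics fit by bounded
Levenberg–Marquardt least squares in log10 concentration, multi-started
from three deterministic midpoint initializations (quartiles of the tested
log-range) with the hill sign taken from the empirical trend; the best
sum-of-squares fit wins, and the parameterization is canonicalized to
top ≥ bottom afterward (the 4PL family is symmetric under swapping
asymptotes and negating the hill). The reported potency is the fitted
inflection (relative EC50). A fit is censored — reported as an inequality
with no number — when the fitted midpoint lies outside the tested range:
"> max tested" when it exceeds the top concentration or the fitted
dynamic range is within twice the residual SD (a flat curve), and
"< min tested" when the curve is claimed to saturate before the lowest
dose, an equally unidentifiable fit that otherwise reports potencies
orders of magnitude below the tested range. A failed optimization returns
`converged = FALSE`, never a silent value. Slope p-values in the linear correlations use the t
distribution with no multiple-testing correction (single planned
comparisons).

## Study conditions and problem sizes

The generator's defaults encode the study conditions: ~5% spontaneous
differentiation in non-induced wells; induced wells following
$f(d) = 0.05 + 0.65\,(1 - e^{-0.8 (d-1)})$ so the adipocytic fraction
plateaus (~0.70) around day 4–5; a background 2% dead fraction; four
imaging fields per well; six wells per arm in the time course. The
dose-response panel uses the six reference compounds with generating
potencies set to their established values (T0070907 1.49 µM, GW9662 4.49 µM,
rosiglitazone 19.5 nM, pioglitazone 1.23 µM, indomethacin 2.77 µM) and a
BADGE truth midpoint (250 µM) placed beyond the tested range, whose fits
are expected to censor; antagonists gain dead cells above 10 µM
(+0.25 dead fraction per decade, capped at 0.6). Doses are 14 geometric
steps from 100 µM to 4.6 nM (the dilution ratio is fixed by the
endpoints), four replicate wells per concentration, and well-level
Gaussian response noise with SD 5% of each compound's dynamic range, on
top of the per-field multinomial sampling of phenotypes.

Plate-scale simulations use a reduced 256×256 px field with ~9 cells
(matching the ~40% confluence of the full-size fields): the pooled OPD
readout does not require resolving individual cells, and this keeps a
full recovery study — 20 independent simulated experiments of 56 wells ×
4 fields per compound — tractable on a single core. Agonist midpoints
near the bottom of the dose range (rosiglitazone) leave the lower
asymptote weakly constrained, so individual replicate fits scatter more
there; the reported quantity is the median over replicates, which is
robust to the occasional degenerate fit.

## Known limitations

* No declumping: confluent fields undercount cells, and counting is only
  claimed monotone sub-confluence.
* The phantom places rigid elliptical caps; real differentiating
  adipocytes spread, retract and overlap in ways that stress segmentation
  more than these tests do.
* Single-image illumination correction is only identifiable up to the
  clip bound on dark-background channels; a production pipeline would
  estimate the illumination function across many fields.
* The stain model omits autofluorescence, bleaching, and concentration
  dependence; the stain-failure flag is a single global scalar.
* Absolute OPD magnitudes are conventions (see above), so cross-study
  comparisons of nm values are not meaningful; within-study contrasts,
  correlations, and potency recoveries are.
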