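---
title: "Methods: flow modelling and image quantification for microvascular networks on chip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flow modelling and image quantification for microvascular networks on chip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipvasc)
```

chipvasc quantifies stromal-cell-supported microvascular networks grown
in gravity-perfused microfluidic chips. This vignette explains the
models and procedures, the parameters that matter, what the synthetic
generators emulate, and the numerical and design choices behind the
implementation.

## The gravity-driven drainage model

Daily medium changes place unequal volumes in the two medium channels —
90 µl in each of the two inlet reservoirs and 50 µl in each of the two
outlet reservoirs. The liquid-plug height difference across cylindrical
reservoirs of diameter $d$ (area $A = \pi d^2/4$) is
$\Delta h = (V_\mathrm{in} - V_\mathrm{out})/A$ per reservoir, and the
hydrostatic pressure it generates, $\Delta p(t) = \rho g \Delta h(t)$,
drives interstitial flow through the hydrogel. The hydraulic resistance
of the chip–gel system is assumed constant and calibrated from one
measured initial flow rate: $R_\mathrm{hyd} = \Delta p(0) / Q(0)$, so
that $Q(t) = \Delta h(t)/\Delta h(0) \cdot Q(0)$.

The conservation closure is that each reservoir pair drains or fills
uniformly: with two reservoirs per side sharing the flow $Q$, each
inlet reservoir loses volume at $Q/2$ and each outlet reservoir gains
$Q/2$, giving $\mathrm{d}\Delta h/\mathrm{d}t = -Q/A$ with $A$ the
*single*-reservoir area. The system then reduces to a linear
first-order decay,

$$Q(t) = Q(0)\, e^{-t/\tau}, \qquad
  \tau = \frac{A\,\Delta h(0)}{Q(0)} = \frac{V_\mathrm{in} -
  V_\mathrm{out}}{Q(0)},$$

which for the 90/50 condition makes $\tau$ simply 40 µl divided by the
initial flow rate. `drainage_closed_form()` implements this analytic
solution and serves as the oracle for `simulate_drainage()`, which
integrates the coupled reservoir-volume system numerically
(`deSolve::lsoda`, tolerances $10^{-10}$, reported on a fixed grid of
$\tau/1000$ by default). A linear decay has no stiffness; the numerical
route exists so that the model structure (volumes, heights, pressures)
stays inspectable and extensible, and it agrees with the closed form to
well below 0.1%.

In practice flow stops early due to small friction losses, so the
simulation ends when $Q$ first falls below a stop threshold of
0.02 µl/min; the stop time is the reported flow duration,
$\tau \ln(Q(0)/Q_\mathrm{min})$ up to one grid step. Duration is
independent of the fluid density (it cancels between pressure and
resistance); density enters only the reported pressures, for which
water at 1000 kg/m³ is the convention.

```{r}
fs <- simulate_drainage(3.1)   # day-0 measured initial flow rate
fs
flow_duration(fs, "h", round_hours = TRUE)
```

With measured initial rates of 3.1–3.2 µl/min the model gives ≈ 1 h of
flow; 1.1 and 0.55 µl/min give ≈ 2 h and ≈ 4 h; 0.35 and 0.25 µl/min
give 5.5 h and 6.7 h.

Wall shear from interstitial flow through a porous matrix is estimated
from the Darcy permeability as $\tau_w = \mu v / \sqrt{K_p}$
(Darcy–Brinkman boundary-layer form). With the medium treated as
water-like at 37 °C ($\mu = 0.6913$ mPa·s), a fibrin permeability
$K_p = 6.67 \times 10^{-12}\,\mathrm{m}^2$, and a peak interstitial
velocity of 0.024 mm/s, the estimate is ≈ 0.0064 Pa — within the
physiological interstitial range. Note the formula is a scaling
estimate: it assumes Darcy flow and reports the boundary-layer shear
scale, not a resolved velocity profile.

## Flow-front velocimetry

The interstitial flow is measured by tracking a fluorescent dextran
front across the hydrogel in a time-lapse (default 5 s intervals,
0.615 µm pixels). Frames are min–max normalized *per stack* — not per
frame, so photobleaching drift cannot reverse the apparent front — and
binarized at 0.5. For each pixel line perpendicular to the flow axis
the front is the farthest foreground pixel contiguous with the inlet
edge; contiguity makes detached bright specks irrelevant. The per-frame
front is the mean over lines carrying signal, and frames in which fewer
than 10% of lines carry signal (start-up frames before dye entry) are
flagged invalid. Front positions are reported as run lengths from the
inlet edge (a plug filling the first $k$ columns has front $k$).

Velocity is the per-interval front displacement times pixel size over
frame interval; flow rate multiplies by the hydrogel cross-section
(10.8 mm × 250 µm = 2.7 mm²). No smoothing is applied by default — the
oscillation of the measured flow rate at low flow, where the per-frame
front movement falls below a pixel, is a real property of the method
and is reported, not suppressed; an optional moving-average window is
available.

The chip orientation relative to the image axes is a free parameter
(`flow_axis`, `flow_direction`) because acquisitions differ in how the
chip is placed on the stage.

## Vessel morphometry

The vessel (GFP) channel of a confocal z-stack is quantified per
region of interest as:

1. maximum-intensity projection over z;
2. display-range clip–rescale to [0, 1] (the window/level adjustment),
   then Gaussian denoising (σ = 3 px by default);
3. triangle-threshold binarization on a 256-bin histogram over the
   image's own min–max range (hence invariant to affine intensity
   rescales);
4. mask cleaning: one 3×3 binary erosion, then removal of bright
   outliers (disk median, radius 5 px) and filling of dark outliers
   (disk median, radius 10 px) — on binary images the disk median is
   computed exactly as a majority vote over the disk;
5. metrics: vasculature area (pixel count × pixel area) and area
   percentage of the ROI; total network length as the calibrated
   length of the Zhang–Suen skeleton; mean vessel diameter as total
   area / total length.

Skeleton length sums inter-pixel steps along the skeleton (1 px
orthogonal, √2 px diagonal, staircase corners not double-counted); a
pixel-count mode is available for comparability with implementations
that count skeleton pixels. Thinning approximates the medial axis, so
a blunt-ended bar of width $w$ loses about $w/2$ of skeleton at each
end; tubes with rounded ends (and real vessels, which end in rounded
tips or junctions) do not show this artifact.

Two parameter conventions deserve note. First, the window/level pair
"(35/70)" does not uniquely define a display range; the package
default treats it as the range (35, 70) and every pipeline constant is
overridable and recorded in outputs. Triangle thresholding depends
only on histogram shape, which limits — but does not remove — the
sensitivity of downstream metrics to this choice. Second, the
denoising blur interacts with thresholding: the triangle construction
places the threshold near the foot of the background peak, so blurring
an edge by σ widens the segmented object by roughly 2–3σ. On real
confocal data the blur is needed against shot noise and the bias is
absorbed into the (relative) group comparison; on synthetic phantoms,
whose noise is controlled by construction, the validation therefore
runs with the blur disabled and the display range spanning the
phantom's dynamic range, isolating the accuracy of
threshold + cleaning + skeleton + metrics. Under those settings,
capsule phantoms of width 20–80 px recover total length and mean
diameter to within a few percent.

```{r}
segs <- data.frame(x0 = 60, y0 = 100, x1 = 540, y1 = 100, width = 40)
g <- synth_tube_network(segs, canvas_px = c(200, 600), noise_sd = 5,
                        psf_sigma = 1, seed = 3)
res <- quantify_vessel_stack(g$image, display_range = c(0, 140), sigma = 0)
res$metrics
g$truth
```

## Pericyte coverage

Mesenchymal stromal cells that have taken a perivascular fate are
identified by α-SMA signal. Two quantities are reported per ROI: the
pericyte area percentage (α-SMA-positive area over ROI area) and the
pericyte coverage — the AND overlap of the α-SMA and vessel masks
divided by the vessel area, i.e. the fraction of the vasculature
wrapped by pericytes. Coverage is bounded in [0, 100]% and is monotone
under dilation of the pericyte mask; an empty vessel mask makes it
undefined (returned as `NA` with a warning).

## Relative qPCR quantification and statistics

Gene expression is quantified by the $2^{-\Delta\Delta C_t}$ method.
Technical replicates are averaged; $\Delta C_t$ subtracts the mean
$C_t$ of the reference genes (arithmetic mean of their $C_t$ values,
equivalent to normalizing expression by their geometric mean);
$\Delta\Delta C_t$ is taken relative to the average $\Delta C_t$ of
the baseline co-culture group; fold change is $2^{-\Delta\Delta C_t}$.
Two reference panels are supported via `normalization_scheme()`: a
housekeeping panel (18S + GAPDH) for general targets, and PECAM1 for
endothelial-specific targets so that differences in endothelial
content between co-cultures do not masquerade as expression changes.
Donor-by-gene mean $\Delta C_t$ matrices feed hierarchical clustering
on Euclidean distances (complete linkage by default, matching the R
heatmap stack such figures are drawn with; single and average linkage
are options).

Group comparisons use the classical unpaired pooled-variance t-test on
donor-level $\Delta\Delta C_t$ values (three donors per group; a Welch
option exists because the software used for such analyses does not
state which form it applies). Multiplicity across genes is controlled
with the two-stage step-up FDR procedure of Benjamini, Krieger and
Yekutieli: a Benjamini–Hochberg pass at $q' = q/(1+q)$ estimates the
number of true nulls $\hat m_0 = m - r_1$ from its rejection count
$r_1$, and a second BH pass runs at $q'\,m/\hat m_0$ (rejecting
nothing if $r_1 = 0$, everything if $r_1 = m$). Reported adjusted
values are scaled so that `adjusted <= q` reproduces the stage-2
decisions. Under the global null the procedure's any-rejection rate is
$q/(1+q) < q$, which the test suite verifies by simulation.

## Synthetic data: what it emulates and what it does not

Every pipeline stage has a seeded generator producing inputs with the
statistical or physical structure the stage assumes, so the whole
package is testable without any imaging data:

- `synth_tube_network()` renders capsule-shaped tubes of known width
  with Gaussian point-spread blur and additive Gaussian intensity
  noise (clipped to the dynamic range). Ground truth (area = union of
  capsules on the pixel grid, length = centerline sum, diameter =
  area/length) uses the same metric container as the analysis output.
- `synth_flow_stack()` renders a fluorescent front whose motion
  integrates the drainage model. The front edge is anti-aliased (the
  boundary pixel carries the partial-coverage intensity) and carries a
  small linear slant across rows (2 px by default): real fronts are
  not perfectly flat, and a slant spanning an integer pixel count acts
  as a uniform dither, letting the row-averaged tracker resolve
  sub-pixel front motion. This is what makes 5% flow-rate recovery
  attainable down to ~1 px/frame displacements; below that, recovery
  degrades into the characteristic low-flow oscillation.
- `synth_overlap_pair()` constructs mask pairs whose overlap fraction
  is exact by pixel count.
- `synth_ct_table()` shifts target-gene $C_t$ by $-\log_2$(fold) in
  the treatment group, keeps reference genes group-invariant, and adds
  Gaussian replicate noise on the $C_t$ scale (σ = 0.3 cycles is a
  typical technical-replicate spread; an optional donor-level shift
  models between-donor baselines).

The generators are deliberately idealized: no photon-counting noise,
no uneven illumination, no 3D lumen structure, no front distortion by
the cell-laden matrix, no amplification-efficiency variation. Passing
round-trip tests therefore demonstrates the correctness and internal
consistency of the analysis chain under its stated assumptions — not
its robustness to every real-data artifact.

## Problem sizes and defaults used in validation

Validation runs use phantoms of 200×600 px with tube widths 20–80 px,
flow stacks of 12–40 frames at either the native 0.615 µm or a coarser
20 µm pixel size (to probe the ~1 px/frame regime), 1,000 random
p-vectors against a brute-force two-stage trace plus 10,000
global-null vectors of length 12, and Ct designs with 3 donors × 3
replicates per group — the study's own scale. All generators are
seeded; rerunning a configuration reproduces identical outputs, and
every pipeline table carries the configuration hash of the run that
produced it.

## Known limitations

- The hydraulic resistance is assumed constant over a drainage; cell
  growth makes it drift over days, which is why each day is calibrated
  from its own measured initial flow rate.
- The shear estimate is a porous-medium scaling, not a resolved
  luminal wall shear; after vessels become perfusable the interstitial
  model no longer describes the (luminal) flow path.
- Front tracking assumes a single connected front; luminal flow
  through formed vessels makes the front ragged and the method
  inapplicable (as observed at late culture days).
- Skeleton-based length slightly depends on thinning artifacts at
  junctions; diameters are area/length ratios, not per-vessel
  measurements.
- The triangle threshold is a global method; strong illumination
  gradients would require local thresholding, which is out of scope.
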