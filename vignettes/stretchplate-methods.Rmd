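---
title: "Models and methods behind stretchplate"
author: "stretchplate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stretchplate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stretchplate)
```

# The experimental system

`stretchplate` analyzes a 96-well in vitro model of traumatic axonal injury:
human iPSC-derived neurons cultured on a silicone membrane bonded to a
96-well plate top are stretched by pressing the plate onto an array of rigid
posts. Indentation by a cylindrical post produces a spatially homogeneous,
equibiaxial strain field in the well bottom, so every cell receives the same
mechanical insult regardless of orientation. Wells C4, D4, E4, F4, C9, D9,
E9 and F9 have their posts omitted and serve as unstretched controls; the
edge rows (A, H) and columns (1, 12) are excluded from analysis to avoid
edge effects.

The package implements four analysis stages — strain mechanics, live-cell
morphometry, compartmentalized synaptophysin density, and dose–response
fitting — plus a synthetic-data module that generates every input with known
ground truth, since validation against real images requires data that the
package cannot ship.

# Strain mechanics

The membrane strain is measured from a 1.5 mm fiducial dot stamped in each
well: its width and height are read off high-speed video frames before and
at peak stretch. With shear neglected (justified for this loading geometry),
the axial Green–Lagrange strain reduces to

$$E = \frac{u}{X} + \frac{1}{2}\left(\frac{u}{X}\right)^2,$$

where $X$ is the initial dot dimension and $u$ the change. `well_strain()`
computes $E_{xx}$ from widths and $E_{yy}$ from heights and defines the well
strain $E$ as their average, because randomly oriented neurons weight both
directions equally. Replicates are aggregated by averaging per-replicate
*strains* (not dimensions), and dispersion uses the sample ($n-1$) standard
deviation; neither convention is dictated by the physics, so both are fixed
here as package policy and exposed in the outputs. The inverse map
$\lambda = \sqrt{1 + 2E}$ is exact, which the synthetic dot generator
exploits: a round trip through `gen_dot_measurements()` and
`plate_strain_map()` recovers the generating strain to numerical precision
when replicate noise is zero.

`displacement_strain_curve()` fits an ordinary least-squares line through
(stage displacement, mean strain) pairs and flags levels whose strain falls
below 0.02 (configurable): the membrane engages the posts only after a
finite displacement, so the lowest amplitude typically produces essentially
no strain and would otherwise distort the line.

# Live-cell morphometry

Live cultures are imaged in two channels: Hoechst 33342 (all nuclei) and
calcein AM (viable cytoplasm). The pipeline is:

1. **Preprocessing** (`preprocess_live`): 3×3 median filter, then
   illumination correction. The background surface is estimated by a
   morphological opening with a disk (radius 15 px by default) wider than
   any cell body; only its non-uniform part is subtracted, so a flat
   background is left unchanged while a tilted one is levelled.
2. **Nuclei** (`segment_nuclei`): global threshold, hole filling, watershed
   declumping on the distance map, minimum area 20 µm².
3. **Cell bodies** (`segment_cells`): candidate somata are connected
   components of the thresholded viability channel after an opening (disk
   radius 3 px) that strips neurites. A candidate is a viable cell iff it
   overlaps a nucleus *and* reaches the minimum soma area (60 µm²);
   candidates failing either rule are recorded as rejected — this is what
   discards neurite beads (bright, nucleus-free) as cell bodies. Nuclei
   with essentially no calcein over them are dead cells, which also rejects
   extracellular nuclei. Two thresholds are used: a tight (Otsu) threshold
   for the candidate mask, and half that value for the full cell mask so
   that dim, thinned, injured neurites are retained. Thresholding at the
   lower level alone would inflate somata (their point-spread halo), while
   the tight level alone would lose injured neurites.
4. **Neurite tracing** (`trace_neurites`): the cell mask minus the (slightly
   dilated) somata is skeletonized by sequential morphological thinning
   with the eight rotated Golay "L" structuring elements. The popular
   two-subiteration parallel scheme was evaluated first and rejected: it
   annihilates thin diagonal limbs outright, which is fatal for thinned,
   injured neurites. Arc length is computed per skeleton component as an
   orthogonal-first spanning tree over 8-adjacency (orthogonal step 1 px,
   diagonal $\sqrt2$), which removes the duplicate triangle adjacencies a
   thinned staircase carries; free endpoints add back the local half-width
   (distance-map value, capped at the component's median half-width so a
   terminal swelling cannot inflate the length). Terminal spurs up to 4 px
   are pruned before counting. A *process* is a cluster of skeleton pixels
   inside the soma proximity band; a *branch* is a cluster of
   crossing-number ≥ 3 pixels outside that band. Fragments touching no soma
   count toward totals but not per-cell values — severed fragments are a
   real injury outcome (secondary axotomy).
5. **Metrics** (`well_injury_metrics`): the nine per-well phenotypes
   (viable and dead cells per image; total and per-cell neurite length,
   process count, branch count; cell viability as a percentage of a
   user-supplied reference count, since the assay's reference denominator
   is an experimental constant the image cannot supply).

# Compartmentalized synaptophysin density

Fixed cultures stained for MAP2, synaptophysin and Hoechst are analyzed as
prescribed for this assay: 2×2 median filter on all channels; the MAP2
channel thresholded with the *background method* — twice the mode of the
256-bin intensity histogram — to give the cell mask; soma mask by erosion
with a disk (radius 4 px default — the assay specifies the operation but
not the size, so it is a config parameter that must exceed the neurite
half-width); neurite mask as the cell mask minus the soma mask dilated by
3 px (disk, chosen for isotropy), which guarantees disjoint compartments.

Within each compartment the synaptophysin channel is thresholded by
*maximum-correlation thresholding*: after 1 px Gaussian smoothing,
intensities are quantized to 256 levels and the threshold maximizing the
correlation between the intensities and the binarized image is found by
enumeration — the correlation with an indicator is the point-biserial
coefficient $\propto (m_1 - m_0)\sqrt{p(1-p)}$, so the search is a single
pass over cumulative sums. The density of each compartment is the ratio of
synaptophysin-positive to total area. Density is used instead of punctum
counts deliberately: injury beads make a uniform stain look punctate, so
counting puncta per neurite length would confound beading with synapse
redistribution. Control and injured groups are compared per compartment
with Welch t-tests (the variant is unstated in the assay description;
unequal variance is the safer default) at the Bonferroni-corrected level
0.05/3.

A degenerate case is handled explicitly: a compartment whose in-mask
intensities are constant cannot be split by a correlation criterion, so its
ratio falls back to 1 when the constant level exceeds the image's
background threshold and 0 otherwise.

# Dose–response model

Each injury metric $y$ is modeled against well strain $E$ with the
four-parameter generalized logistic

$$y(E) = y_f + \frac{y_0 - y_f}{1 + e^{k (E - E_t)}},$$

where $y_0$ is the zero-strain value, $y_f$ the high-strain asymptote, $k$
a dimensionless rate constant and $E_t$ the transition strain at which the
metric is halfway between its asymptotes. This is the unique standard form
consistent with all of those parameter roles; note $y(0) = y_0$ holds only
asymptotically, with error $(y_0 - y_f)e^{-kE_t}$ — negligible whenever
$kE_t \gg 1$, as in all reference fits. `fit_logistic()` minimizes squared
error with Levenberg–Marquardt (`minpack.lm::nlsLM`), auto-initialized from
the data (tertile means for $y_0, y_f$; strain nearest the midpoint for
$E_t$; $k = 15$). Confidence intervals are asymptotic (Jacobian covariance
× t-quantile) and $R^2 = 1 - SS_{res}/SS_{tot}$; non-convergence and flat
metrics are flagged rather than raised, and `fit_all_metrics()` reports the
$E_t$ range over converged fits only. Control wells enter the fits as
strain-0 observations.

# The synthetic-data module

All tests and the acceptance analysis run on generated data with known
truth.

**Dot deformations.** Each non-excluded well draws a true strain — mean
0.45, well-to-well sd 0.051 in the aligned configuration, matching the
characterized plate; a linear column gradient (default 0.04 per column) in
the misaligned configuration, which reproduces the left-to-right strain
ramp a deliberately misaligned post array produces. Post dimensions are
pre × $\sqrt{1+2E}$, equal in x and y. Draws implying a negative stretch
ratio are rejected and resampled.

**Well-metric tables.** Metrics are evaluated on the logistic curve at each
well's strain plus Gaussian noise. The simulated experiment defaults to 152
injured wells with true strains evenly spread over [0.02, 0.62] — the
spectrum produced by combining several displacement levels with the
misaligned gradient — plus 40 strain-0 controls (8 control wells × 5
plates). Noise is calibrated per metric so a perfect fit reproduces the
reference $R^2$: for additive noise, $R^2 \approx \mathrm{Var}(\hat y) /
(\mathrm{Var}(\hat y) + \sigma^2)$, giving $\sigma =
\sqrt{\mathrm{Var}(\hat y)(1-R^2)/R^2}$ over the design strains.

**Culture scenes.** Somata (radius 7–9 px at 1 µm/px) with concentric
nuclei sit on a jittered grid whose pitch guarantees neighbouring arbors
cannot touch — deliberately sparser than a real culture so that ground
truth is unambiguous. Each soma grows 1–3 straight neurites (30–50 px,
thickness 2 px) at well-separated angles; half carry one side branch; bead
slots are laid down along each neurite (≈4 per 100 px, radius 2.5–3.5 px —
the assay literature does not characterize bead geometry, so these are free
generator parameters chosen to look like the published examples).
Injury level $\ell \in [0,1]$ acts deterministically on a fixed scene:
lengths scale by $1 - 0.6\ell$, thickness by $1 - 0.5\ell$, a fraction
$0.6\ell$ of cells dies in a fixed per-scene order (nucleus kept, calcein
lost), and the first $\lceil \ell \cdot n \rceil$ bead slots become
visible. Ground-truth totals are therefore monotone in $\ell$ by
construction. Channels are drawn as anti-aliased disks and thick segments,
blurred with a 1 px Gaussian point-spread, and given background (0.05),
optional linear illumination gradient and additive Gaussian noise
(sd 0.02). The renderer models no photobleaching, shot noise, or
out-of-focus light; passing tests therefore validate the geometry and
logic of the pipeline, not its robustness to every real-world artifact.

# Validation scope and numerical choices

Problem sizes were chosen so the full suite runs comfortably on a laptop:
scenes are 480×480 px with 9 cells, dose–response recoveries use 50 seeded
repetitions of the 192-well experiment, and the strain round trip uses the
60-well characterization layout. On generated scenes, viable and dead
counts are recovered exactly across injury levels; total neurite length is
within 5% in aggregate and for typical scenes (per-scene errors up to
~10% occur at high injury, where beads and short stubs make skeleton
measurement noisiest — the same regime where any tracer is least reliable);
process and branch counts are exact on uninjured morphology, while under
heavy beading branch detection is conservative (bead-induced spurs and true
short branches cannot always be distinguished at 4 px pruning, a tie-break
we resolve toward never inventing branches).

Other deliberate choices: strain draws are truncated at $E > -0.5$ (real
stretch ratios); the logistic fit caps at 200 LM iterations; thresholds
quantize to 256 bins; skeleton spur pruning is 4 px; the soma proximity
band for process counting is 5 px beyond the subtracted margin. Each is a
config argument with its default stated in the function documentation.

# Known limitations

- Segmentation equivalence is claimed against synthetic ground truth only,
  not against any proprietary high-content package.
- The synthetic scenes are sparse and planar; dense cultures with crossing
  neurites would require assignment heuristics the package does not claim.
- The logistic fit reports asymptotic CIs only (no bootstrap), matching the
  common statistics-package workflow this assay used.
- The reference count behind the viability percentage is user-supplied; the
  package cannot derive it from images.
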