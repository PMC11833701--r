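---
title: "Quantifying meiotic crossover regulation: models and methods"
author: "meioquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying meiotic crossover regulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meioquant)
```

# Overview

During meiosis, crossovers (COs) between homologous chromosomes are
tightly regulated: CO assurance guarantees at least one CO per homolog
pair, and CO interference spaces neighbouring COs further apart than
chance. `meioquant` implements three quantitative pipelines around these
phenomena in the *C. elegans* germline, together with a synthetic-data
generator that plants known ground truth so every stage can be verified
by parameter recovery:

1. **interference** — the gamma shape factor of inter-focus (cytological)
   or inter-CO (genetic) distance distributions;
2. **comap** — CO mapping and ploidy classification in single backcross
   F2 embryos from strain-specific read counts in genomic windows;
3. **imagequant / tracing** — 3D quantification of synaptonemal-complex
   (SC) loading, focus detection, germline straightening, and mapping of
   foci onto traced chromosomes.

This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic data do and do
not emulate.

# The gamma model of crossover interference

Consecutive inter-focus distances on a chromosome, normalized by the
chromosome (or SC trace) length, are pooled across chromosomes and
nuclei of a genotype and fitted with a two-parameter gamma distribution
by maximum likelihood. The fitted shape factor is the interference
statistic: a stationary renewal process with exponential gaps (shape 1)
is memoryless, i.e. no interference; larger shapes correspond to more
regular spacing, i.e. positive interference.

The gamma likelihood admits an analytic profile: for fixed shape $k$ the
maximizing scale is $\hat\theta(k) = \bar x / k$, so the maximum reduces
to the one-dimensional root of
$\log k - \psi(k) = \log \bar x - \overline{\log x}$,
which is solved by Newton iteration with the analytic gradient
$1/k - \psi'(k)$ (falling back to bounded bisection if a step leaves the
feasible region). The standard error of the shape uses the observed
Fisher information with the scale profiled out,
$\mathrm{SE}(\hat k) = 1 / \sqrt{n\,(\psi'(\hat k) - 1/\hat k)}$.

Two boundary conventions matter:

* **shape cap** (`shapeCap`, default 1000): for degenerate inputs (for
  example all distances identical) the likelihood increases without
  bound in the shape; the fit is then reported at the cap with
  `capped = TRUE` and no standard error. Biological fits are far below
  the cap.
* **pooling**: distances from all chromosomes of a genotype enter one
  fit. Whether multi-focus chromosomes should be weighted differently is
  genuinely open; pooling is the single per-genotype fit convention and
  is what the per-trace statistics of the tracing module feed.

A calibration subtlety: on a finite chromosome, gaps are only observed
when both foci fall inside the chromosome, which thins long gaps and
biases the fitted shape slightly above 1 for a memoryless process at
low focus counts (about +0.05 at 5 foci per chromosome). The package's
calibration runs therefore use 10 foci per unit chromosome, where this
edge effect is negligible; the bias is a property of normalized-gap
sampling on finite chromosomes, not of the estimator, which matches a
dense grid-search maximizer of the likelihood to better than $10^{-3}$
relative.

# Crossover mapping in single F2 embryos

The mapping pipeline consumes tables of reads mapping exclusively to the
Bristol (N2) or Hawaiian (CB4856) genome in 5-kb windows, plus total
depth in 50-kb windows, from single embryos of a backcross between a
Bristol/Hawaiian hybrid hermaphrodite and a Hawaiian male. The maternal
chromosome is a Bristol/Hawaiian mosaic whose breakpoints are the
crossovers of the hybrid's meiosis; the paternal chromosome is always
Hawaiian. Heterozygous regions therefore show a Bristol fraction around
0.5 and Hawaiian-homozygous regions around 0.

* **Gliding ratio** (`glidingRatio`, span 100 windows): the Bristol
  fraction of informative reads in a centered window span, computed as a
  ratio of sums (robust to empty windows) and truncated — not padded —
  at chromosome ends. Windows whose span holds no informative read are
  `UNINFORMATIVE`. A centered rather than trailing window is used; both
  interpretations are reasonable and the span is configurable.
* **Genotype classes** (`classifyGenotype`): ratio > 0.9 homozygous
  Bristol, < 0.25 homozygous Hawaiian, otherwise heterozygous. The
  published thresholds are strict inequalities for the homozygous
  classes, so the boundary values 0.9 and 0.25 classify as HET.
* **CO calls** (`callCrossovers`, `minReads = 1500`,
  `minFlank = 15000`): a crossover is a boundary between genotype runs
  with at least 15 kb of consistent genotype on each side and strictly
  more than 1500 informative reads summed over the two flanking runs.
  The read-support accounting is not fully determined by the published
  rule ("supported by >1500 reads"); summing over the flanking runs is
  the conservative reading and both the threshold and its scope are
  configurable. Short `UNINFORMATIVE` stretches are bridged into the
  left neighbouring run (so the reported interval spans them); stretches
  of 15 kb or more break run continuity. The breakpoint is reported as
  the interval between the flanking runs with its midpoint as point
  estimate.
* **Ploidy** (`estimateCopyNumber`, `classifyPloidy`): per-window copy
  number is `2 * depth / baseline` on 50-kb windows, with the baseline
  the median per-window depth over autosomes (a depth-normalized
  estimator standing in for mappability-corrected copy-number calling,
  which needs the read data themselves). Mean copy number below 1.45 is
  haploid, within [1.45, 2.5] diploid ("between" read as closed), above
  2.5 triploid. Only diploid chromosomes enter CO calling
  (`analyzeEmbryo`), since a genotype transition on an aneuploid
  chromosome is not interpretable as a simple crossover.

At the study's coverage regime (about 1.8–6.7×), a 100-window span
holds on the order of a thousand informative reads, so the gliding ratio
resolves the three genotype classes cleanly; the localization limit is
set by the span (half-span 250 kb), not by counting noise.

# 3D image quantification

The imaging module consumes multi-channel 3D stacks in `(z, y, x)` voxel
order plus an integer nucleus label volume produced by an external
segmenter; it does not segment nuclei itself.

* **Background** (`backgroundAnnulus`): mean intensity over voxels whose
  within-slice 2D pixel distance to the nearest labeled voxel lies in
  (10, 50] pixels. The distance is computed per z-slice in pixel units
  because stacks are laterally sampled by the camera and axially by the
  z-step; a full 3D voxel distance is available as an option. All
  labeled objects exclude their surroundings, including objects later
  filtered out.
* **Axis mask** (`segmentAxis`): nucleus voxels whose intensity is
  strictly greater than the mean intensity over the nucleus (mean
  thresholding). Per-channel totals are background-corrected per voxel,
  floored at zero, then summed; the SC-loading readout is the ratio of
  the axis total to the nucleus total, which is 1-bounded whenever the
  axis mask is a subset of the nucleus mask.
* **Sphericity**: $\pi^{1/3}(6V)^{2/3}/A$. No surface-area definition is
  canonical on voxel data; counting exposed voxel faces overestimates
  the area of smooth bodies by up to 50%, so the package integrates the
  gradient magnitude of the Gaussian-smoothed (1 voxel) indicator
  function (the coarea formula). On digital balls of radius ≥ 5 voxels
  this is accurate to a few percent and the sphericity of a ball is
  1.0–1.05.
* **Nucleus filters** (`filterNuclei`): volume strictly between 10 and
  60 µm³, sphericity strictly above 0.4, intensity ratio within
  [0.3, 0.8]. The "intensity ratio" of the filter is interpreted as the
  axis/nucleus ratio of the SC channel — the only ratio the pipeline
  defines — and the filter metric is configurable. Filter decisions
  depend only on the record itself.
* **Germline position** (`straightenPositions`): the germline centre
  line is a loess fit (span 0.5, degree 2, tricube weights) of the
  transverse centroid coordinates against the leading principal axis;
  each nucleus gets the arc length of its projection, mapped linearly so
  the annotated zone start is 0 and the end is 1. Orientation comes from
  the annotations, never from the data. Nuclei outside [0, 1] are
  flagged and excluded by default rather than clamped. Profiles along
  the axis use 11 equal bins with mean ± standard error per bin.
* **Focus detection** (`detectFoci`): per nucleus, intensities inside
  the mask are thresholded on a 256-bin histogram — Otsu for bright
  sparse COSA-1-like foci, Yen for RAD-51-like foci, matching the
  standard formulations of scikit-image to within one histogram bin —
  after a 0.75-voxel Gaussian prefilter that suppresses single-voxel
  noise (the refinement below always fits raw intensities). Connected
  components (6-connectivity) become candidates; touching spots are
  separated by a tolerance watershed that splits a component when its
  intensity profile has several peaks with valleys deeper than 30% of
  the peak contrast. Each candidate is refined by a 3D Gaussian fit
  (amplitude, subvoxel centroid, per-axis sigmas, offset) with sigmas
  bounded by the neighbourhood extent; fits that fail or drift more than
  two voxels from the candidate core fall back to the intensity-weighted
  centroid and are flagged unfitted. Integrated intensity is
  $A\,(2\pi)^{3/2}\sigma_z\sigma_y\sigma_x$. In RAD-51 mode only nuclei
  with equivalent-sphere diameter between 1 and 6 µm are scored.
* **Intensity variability** (`focusIntensityCV`): the sample standard
  deviation over the mean of the integrated intensities of one nucleus's
  foci. Note that a per-nucleus CV from about six foci is a noisy,
  slightly downward-biased statistic of the underlying distribution;
  recovery tests therefore compare against the planted per-nucleus
  sample CVs and use the pooled CV for calibrating against the
  generator parameter.
* **Hexanediol contrast** (`hexanediolContrast`): the genotype effect on
  the axis/nucleus ratio is fitted as a linear mixed-effects model with
  genotype fixed and gonad random (Satterthwaite p-values via lmerTest),
  because nuclei within one gonad are not independent. Genotypes
  represented by a single gonad are rejected: the random effect is
  unidentifiable.

# Chromosome tracing

Traces exported from an interactive tracer arrive as ordered 3D control
points. `resampleTrace` interpolates them with a natural cubic spline
under chord-length parametrization (linear for two distinct points),
then resamples at constant arc-length spacing, default 0.05 µm — well
below the ~100 nm SC width — preserving both endpoints. The chromatic
offset between the focus and trace channels is estimated as the single
translation minimizing the sum of squared distances from shifted focus
centroids to their nearest trace points (`estimateChannelOffset`):
alternating nearest-point assignment with a closed-form translation
update, run from both a zero start and a coarse centroid-difference
start, on a 5× densified polyline so the sampling step does not
quantize the result; a trimmed option ignores the worst 10% of foci.
The estimate is per image by default. `mapFoci` assigns each corrected
centroid to the globally nearest sampled point among the traces of its
own nucleus — never across nuclei — with ties broken towards the lowest
trace id, then the smallest arc position. As the published pipeline
itself cautions, chromatic aberration can still mis-map individual
foci; the trimmed offset option mitigates but does not remove this.
`perTraceFocusStats` turns mappings into per-trace focus counts and
normalized inter-focus gaps, the direct input of the interference fit.

# What the synthetic data emulate — and what they do not

`simulateFocusPlacement` plants foci under three regimes: exactly one
uniform focus per chromosome (the wild-type "one CO per SC" regime), a
homogeneous Poisson process (no interference), and a stationary gamma
renewal process with a chosen shape (tunable interference), realized by
running the renewal over a 25-mean-gap burn-in line and windowing to
the chromosome rather than sampling the equilibrium first-gap law
analytically; at the parameters used in the tests the residual
nonstationarity is not detectable against the recovery tolerances.
Intensities are lognormal with configurable mean and CV.

`simulateF2Embryo` draws maternal-chromatid breakpoints from a chosen
CO model, transmits the X from sperm with probability 1/2, optionally
adds nondisjunction, and emits Poisson read counts: expected reads per
window scale with coverage, window size, read length (150 bp) and local
copy number, and a configurable fraction of reads (default 0.3) is
strain-informative — the true SNV density between the strains is not
modelled, so this fraction is a free knob chosen to give realistic
informative-read counts at the study's coverage. No read-level
sequences, mapping artifacts, GC bias or mappability structure are
simulated; conclusions about those belong to the upstream aligner, not
this package.

`simulateGermlineStack` builds spherical nuclei along a gently curved
row, a smooth random filament per nucleus carrying a planted fraction
of the nuclear signal (the axis channel), and 3D Gaussian spots with
lognormal amplitudes (the focus channel). Noise is Poisson shot noise
plus Gaussian read noise (default floor 5 counts); a finite `snr` adds
read noise so the nominal peak contrast-to-noise ratio equals `snr`,
`noise = FALSE` gives a noise-free stack. Real germline stacks differ
in ways the generator does not attempt: nuclei are not perfect spheres,
the SC is six ribbon-like structures rather than one closed curve,
optics impose an anisotropic PSF, and segmentation errors are absent
because the labels are the planted spheres. Passing the recovery tests
therefore validates the measurement code, not the upstream segmentation
or optics.

All generators are deterministic given their seed and return a
`SyntheticTruth` that serializes to JSON, so round-trip tests can run
from the truth file alone.

# Problem sizes and runtime choices

The shipped tests and the acceptance script run at desk scale by
design: interference calibration on ~2000 distances (225 chromosomes at
10 foci each), shape recovery at n = 500 over 20 seeds, 400 simulated
embryos at 2× coverage for the ploidy calibration, 100 single-CO
chromosomes at 3× for caller localization, and stacks of 50 nuclei
(radius 2 µm at 0.25 µm isotropic voxels) per planted axis ratio.
These sizes keep the full suite in the low minutes on one CPU while
leaving every recovery margin well clear of its tolerance.

# Known limitations

* The interference fit treats pooled distances as i.i.d.; distances
  from the same chromosome are in fact weakly dependent, which the
  standard error does not reflect.
* CO localization is limited by the 100-window gliding span; closely
  spaced double crossovers (under about 0.5 Mb) merge or cancel and are
  not called.
* The copy-number baseline assumes most autosomes are diploid; in
  embryos with pervasive aneuploidy the median baseline itself shifts.
* Focus detection assumes approximately Gaussian, diffraction-limited
  spots; elongated or clustered RAD-51 structures will be under-split
  at the default watershed tolerance.
* The annulus background assumes the neighbourhood of nuclei is
  representative; structured autofluorescence would bias it.
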