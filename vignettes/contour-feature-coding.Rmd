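---
title: "Contour-feature coding: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contour-feature coding: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

contourcode analyzes how visual neurons encode geometric features of
natural contours. This vignette is the package's account of the science
behind each stage: the models and their assumptions, the parameters that
matter, what the synthetic study generator does and does not emulate,
and the design decisions taken where the method left room.

## The analysis problem

A neuron in an intermediate visual area is driven by the part of a
contour that falls inside its classical receptive field (CRF). Given
contour stimuli (ordered pixel point lists with a figure-ground label),
spike counts per (neuron, stimulus, trial), and grating-grid responses
to localize each CRF, the pipeline asks four questions:

1. Which geometric features of the contour inside the CRF — closure,
   signed curvature, symmetry, orientation — does each neuron's firing
   depend on (tuning with permutation significance)?
2. How much information does the response carry about each feature
   (plug-in mutual information, MI)?
3. Do single neurons depend on several features at once (multiple
   significant tunings; similar MI magnitudes across features)?
4. How is the population organized (nonmetric MDS of response patterns;
   what the embedding axes correlate with)?

## The CRF model

The CRF is an axis-aligned two-dimensional Gaussian fitted by bounded
least squares to mean responses on a 5 x 5 grating-patch grid, with a
jointly fitted baseline clipped at zero. The "extent" used to gate all
local feature computations is the open 2-SD ellipse:
`((x-cx)/sx)^2 + ((y-cy)/sy)^2 < 4` (strict, so the boundary is
outside). A rotation term is deliberately omitted: nothing in the
protocol identifies RF orientation from a 5 x 5 grid robustly, and the
axis-aligned form keeps the extent test closed-form. Grids with no
response contrast are flagged unfittable and the neuron is excluded
downstream rather than silently defaulted.

## The four features

**Closure** casts 100 radial rays from the CRF centre at equal angular
steps and reports the fraction whose *first* intersection with the
contour polyline lies inside the extent. It is 1 when the contour
surrounds the centre within the extent and 0 when the rays never reach
the contour there. Closure needs no minimum amount of contour, so it is
always defined; a geometric consequence worth knowing is that any
contour whose interior passes through the ray origin shadows about half
of the directions, so center-crossing contours score near 0.5 and low
closure comes from contours that terminate at the centre.

**Curvature** is measured locally: square windows at five scales (1,
3/4, 2/4, 1/4, 1/10 of the stimulus size) slide in 10-pixel steps, and
wherever at least 10 contour points fall inside both the window and the
CRF extent an algebraic least-squares circle (Kasa's method; exact on
noiseless circles, with a total-least-squares line fallback for
collinear points) is fitted. Fits with an RMS radial residual above the
80th percentile of the (stimulus, neuron) error distribution are
dropped, and at most the 20 lowest-error fits are kept. The raw
curvature 1/R is passed through the odd sigmoid
`c' = 2/(1 + exp(-a c)) - 1` with `a = 20` (so a 20-pixel radius maps
to about 0.46) and signed +1/-1 according to whether the fitted
circle's centre lies on the figure side of the contour — convex versus
concave with respect to the figure. Because figure side is stored as a
signed normal convention on the contour itself, flipping the label
flips every sign and nothing else, which the tests exercise.

The 80th-percentile error cut is computed per (stimulus, neuron): the
candidate fits depend on the CRF, so a per-neuron distribution is the
only self-consistent reading; pooling across neurons is available via
the parameters object for sensitivity analyses. When more than 20 fits
survive, the 20 lowest-error fits are kept — the best-supported local
estimates.

**Symmetry** blurs the contour points into a density map (Gaussian SD 2
px, truncated at 4 SD) and folds the map about each of 24 axes through
the stimulus centre (7.5 degree steps), scoring the overlap as the sum
of the pixel-wise minimum of the map and its reflection (a dot-product
variant is available). The maximum over axes is the raw score; raw
scores are min-max normalized across the stimulus set to [0, 1]. The
raw overlap scales with the amount of contour, so a long symmetric
contour outranks a short one — this is inherent to counting overlapped
points and is absorbed by the across-stimulus normalization. Symmetry
is a global property of the stimulus and is not gated by the CRF.

**Orientation** takes all point pairs separated by five pixels along
the (unit-spacing resampled) contour with both points inside the
extent, and combines the pair angles by the axial circular mean: double
the angles, average the unit vectors, halve the resultant. This removes
the 0/180 wrap artifact a naive arithmetic mean would produce (the
naive mean remains available for strict comparison). The mean resultant
length is attached so nearly isotropic sets — where the axial mean
direction is unstable — can be flagged.

Gated features that cannot be estimated (too little contour inside the
extent) are missing, never defaulted; neurons missing curvature or
orientation values are excluded from those analyses, while closure
analyses keep neurons with partial missingness (closure has no minimum
data requirement, and in practice is always defined here).

## Tuning maps and fits

A tuning map is the mean spike count per feature bin, normalized by the
map maximum. Bin counts are a package choice (the method leaves them
open): closure and symmetry 10 bins on [0, 1], curvature 20 bins on
[-1, 1], orientation 18 bins of 10 degrees. For the multi-valued
curvature feature each stimulus contributes its local-curvature
histogram multiplied by its response; the across-stimulus sums are
divided by the local-curvature counts so the map again reads as mean
spikes per bin (the undivided response histogram is available via
`statistic = "sum"`). Without that division the map is dominated by the
shape of the stimulus set's local-curvature density rather than the
neuron's preference.

Closure and symmetry maps are fitted by a Gaussian
`f(x) = a exp(-(x-b)^2/c^2)` with `0 <= a, b, c <= 1` and *no offset
term*; curvature and orientation maps by a cosine
`f(x) = a cos(x - c) + d` with the frequency fixed at 1, `-1 <= c <= 1`
and `a`, `d` free for curvature, and `0 <= a, d <= 1`, `0 <= c <= pi`
for orientation with bin centres in radians. Tuning strength is `a/c`
for the Gaussian and `a` for the cosine; the optimum is the fitted
peak (for the curvature cosine, the in-range argmax, which handles
negative amplitudes — "dent" maps — correctly). The orientation domain
is treated exactly as the constraint set implies: bin centres on
[0, pi] with a peak at `c`; the cosine with unit frequency is not
pi-periodic over this domain, and the fit follows that form rather
than imposing axial periodicity on the model.

Fitting is deterministic: a profile grid over peak/width (amplitude and
offset solved in closed form at each grid point, box constraints
handled exactly) followed by a bounded quasi-Newton polish of the
reported parameters. Missing bins are excluded from both the fit and
its error; at least four occupied bins are required.

## Permutation significance of tuning

Significance compares the fitting error of the observed map with maps
rebuilt after shuffling the stimulus-response pairing (1,000 shuffles):
tuning is significant when the observed error lies below the bottom 1%
of the shuffled errors. Shuffling the pairing — rather than the map
bins — destroys the feature-response association while preserving the
response marginal, which is the null the test needs; a bin-shuffling
variant would not preserve per-bin occupancies. Both the observed and
the shuffled maps are fitted by the same deterministic grid procedure,
so the compared errors come from an identical pipeline; polishing only
the observed fit would bias the criterion anticonservatively. The
permutation engine is fully vectorized (one matrix product rebuilds all
shuffled maps), which is what makes 1,000-shuffle tests on hundreds of
neurons affordable.

Two structural properties of this criterion are worth understanding.
First, power comes from the map's modulation depth relative to its
mean: after max-normalization, shuffled maps fluctuate around their
mean while a deeply modulated observed map has relatively smaller
residual noise, and only then does its error beat the bottom 1% of the
null. Second, the offset-free Gaussian can only fit maps whose troughs
approach zero: a tuned map riding on a pedestal (as additive
multi-feature drives produce) fits poorly and tends not to reach
significance. Neurons with conjunctive (product) multi-feature drives
keep their troughs near baseline and remain detectable, but their
per-feature significance is still systematically weaker — the
feature-conditional response carries the other features' variation as
structured noise that shuffling removes. This is the same interaction
the tuning analysis of recorded populations shows, and it is why the
package's recovery guarantees are stated for single-feature neurons
(tuned status) and untuned neurons (false positives), while
multi-feature dependence is assessed by mutual information.

## Mutual information

MI between spike counts and each feature uses the plug-in estimator on
an equal-width joint histogram, with `0 log 0 = 0`. The bin count per
axis follows the Sturges-type rule `nbin = ceiling(1 + log2 n)` of the
pair count `n` — the base-2 reading; the literal base-10 form gives
three bins for two hundred points, too few to be meaningful, but is
kept behind an option. Curvature pairs every local curvature with its
stimulus's response (expanding `n`), mirroring the tuning-map
construction; a per-stimulus-mean variant is available. Significance is
by permutation at the stimulus level (1,000 shuffles, p < 0.05), with
the +1-corrected p-value so the floor is 1/1001. Neurons whose total
analyzed spike count is below 15 are excluded (threshold 0 disables
this, changing membership but never a retained neuron's MI — a tested
invariant). No bias correction is applied: the plug-in estimator is the
method's statistic, and all comparisons are within-pipeline.

The per-neuron profile of the four MI values yields the greatest and
least ratios relative to their sum (0.25 each under perfectly even
dependence), compared against 0.25 by a sign-flip one-sample
permutation test with Cliff's delta as effect size, and the
within-neuron variance of the four MI values summarizes how evenly a
neuron's response depends on the features.

## Population analysis

The response matrix holds trial-averaged responses per neuron and
stimulus, each row divided by its maximum (all-zero rows are dropped).
Dissimilarity between neurons is the Euclidean distance between
normalized rows (a correlation distance is available), and the
embedding is nonmetric MDS minimizing Kruskal's Stress-1 with 20
randomized initial configurations plus a classical-scaling start; the
best solution is kept and centred. MDS axes carry no intrinsic order or
sign; axes are oriented so a chosen covariate's regression slope is
positive, and Procrustes alignment to a reference configuration makes
repeated runs comparable.

Natural-to-silhouette preference is
`NSpref = (R_nat - R_sil)/(R_nat + R_sil)`, undefined (and excluded)
when both means are zero. Axis structure is summarized by equal-count
quantile groups (five groups, stable tie-breaking), moving windows of
30 neurons slid along an axis (mean or ratio per window, smoothed by a
15-window centred moving average — the smoothing span is a package
default, exposed as a parameter), and ordinary least-squares
regressions of per-neuron covariates on axis coordinates (R^2, signed
R, p).

## The synthetic study generator

The generator produces the full study at desk scale so every stage is
testable by parameter recovery: 210 contour stimuli (105 selected
patches plus their mirror images, 69 x 69 pixels, every contour passing
within one pixel of the patch centre), each presented as a "natural"
and a "silhouette" variant; a population of Poisson model neurons with
known CRFs and known multi-feature tuning; and 5 x 5 grating grids for
CRF estimation.

Candidate contours come from parametric families chosen to span the
feature space: segments and smooth gentle wiggles through the centre
(closure near 0.5, near-zero curvature), radial arms ending at the
centre (low closure), circular arcs with log-uniform radii from 3 to
250 pixels (every squashed-curvature band reachable by a
constant-curvature contour, with the figure side setting the sign),
"lassos" — a straight spoke joined to a constant-radius loop around the
centre — whose wrap angle sets closure up to ~0.95 while local
curvature stays bimodal and coherent, exactly mirror-symmetric V
shapes populating the upper symmetry range, and a few outward spirals.
Families are kept locally coherent in curvature on purpose: the
curvature analysis conditions on *local* curvature, and stimuli whose
local spectra smear across many bins would blur every neuron's map.
Each candidate is scored under a reference central CRF (SD 12 px), and
a stochastic swap optimizer selects the 105 patches whose combined set
(with mirrors) has: all six pairwise feature correlations within 0.1 in
absolute value, 10-bin marginals with a min/max ratio of at least 0.5,
and no under-populated band in the pooled local-curvature histogram
(a band owned by a single stimulus would make that tuning-map bin a
copy of one response). The generator verifies these targets and errors
— asking for a larger candidate pool — if they cannot be met. Mirror
variants are exact reflections about the central tangent: closure,
signed curvature and symmetry are invariant (tested), orientation
reflects, which is what balances the orientation marginal.

Model neurons have CRFs jittered around the patch centre (SDs 9-14
px), Gaussian kernels over closure and symmetry, unit-frequency cosine
kernels over curvature (evaluated on each local curvature and
averaged) and orientation — the same families the analysis fits — with
each kernel affinely rescaled to span [0, 1] over the stimulus
ensemble, so the firing gain (default 12 spikes above a 0.5-spike
baseline) is the modulation a tuned neuron actually expresses.
Curvature peaks are drawn away from zero (magnitudes 0.5-0.95),
matching the acute-curvature preference of recorded populations and
giving maps the monotone or dent shapes the cosine fits cleanly.
Multi-feature neurons (mostly two features) combine kernels
multiplicatively — conjunctive selectivity, the combination consistent
with the offset-free Gaussian tuning model; an additive rule is
available. Natural presentations are scaled by a per-neuron log-normal
gain (SD 0.15 on the log scale) standing in for surface-texture drive,
and every presentation carries an independent log-normal drive factor
(SD 0.25) emulating stimulus-to-stimulus response variability beyond
Poisson noise. That drive noise is not cosmetic: natural and silhouette
presentations share geometry, so a deterministic kind-gain would build
a response structure that is *less* variable than any shuffled pairing
and would break the exchangeability the permutation tests rest on;
with the per-presentation noise dominating, the tests stay calibrated
(the type-I checks in the test suite verify this). Spike counts are
Poisson per trial, 10 trials per presentation by default.

What the generator does *not* emulate: photographic texture and color
(the natural/silhouette contrast is a scalar gain), human contour
drawing (families are parametric), recording noise beyond Poisson and
log-normal drive, and any spatial correlation between neurons. Passing
the recovery tests therefore demonstrates that the pipeline measures
what it claims on data with known structure — not that real cortical
data satisfy the generator's assumptions.

## Problem sizes and numerical choices

The packaged checks run the full study at 210 stimuli (the study's
stimulus count), 72-neuron populations, 10 trials per presentation, and
1,000 permutations per test; the stimulus generator uses a 2,000-
candidate pool. Population-level properties are checked across seeds
(three for recovery rates, ten for the embedding-axis result) on one
fixed stimulus set, matching a study design in which a single stimulus
set is shown to every recorded neuron. Ties in the profile grid fit are
broken toward the first (lowest-peak) grid point; degenerate inputs —
flat grids, all-equal symmetry scores, zero-variance regressions,
all-zero response rows — are flagged or excluded explicitly rather
than patched. Random-seed plumbing is explicit everywhere: the same
seed reproduces the stimulus set, the spike tables and every
permutation p-value bit for bit.

## Known limitations

- Closure of centre-crossing contours is bounded near 0.5 from below
  by geometry (see above); the low-closure range is populated by
  contours terminating at the centre, which is a modelling choice.
- The curvature analysis inherits the stimulus set's local-curvature
  density; the generator controls it, but on arbitrary external
  contour sets sparse curvature bands will produce unstable map bins.
- Per-feature significance of conjunctive multi-feature neurons is
  structurally conservative under the bottom-1% criterion; use the MI
  profile for multi-feature dependence.
- The orientation tuning model follows the stated constraint set and
  is not axially periodic; orientation preferences near 0/180 fit with
  a peak at the corresponding domain edge.
- Nonmetric MDS recovers configurations only up to rotation,
  reflection and monotone distance transforms; all downstream axis
  statements are therefore made after explicit orientation, and the
  embedding should be read qualitatively.
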