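---
title: "Modelling the comprehension-production vocabulary gap with coupled self-organising maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the comprehension-production vocabulary gap with coupled self-organising maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexisom)
```

## The phenomenon and the model

Children understand far more words than they produce. This
comprehension-production gap is nearly universal in typical development,
but parent-report vocabulary data (Communicative Development Inventories,
CDIs) suggest it is markedly reduced in Williams syndrome (WS): at matched
comprehension levels, children with WS report disproportionately high
production. `lexisom` implements a mechanistic account of how such a
profile can arise from domain-general processing constraints, together with
the statistical machinery needed to quantify the profile in both simulated
and CDI-style cohort data.

The model couples two Kohonen self-organising maps (SOMs). Each map is a
planar grid of neurons with weight vectors in the input space $[0,1]^{10}$.
One map receives auditory word forms, the other visual object exemplars;
the two are fully connected by a Hebbian association matrix. Lexical
knowledge is operationalised directionally:

* **comprehension**: present an auditory exemplar alone, propagate the
  auditory activation field through the bridge, and check whether the
  resulting visual field decodes to the correct category;
* **production**: present a visual exemplar alone and decode the propagated
  auditory field.

The asymmetry between the two directions is not built in; it emerges from
the statistics of the input. Word forms are phonologically stable, so
auditory categories are tight ($\sigma_{aud} = 0.05$ around each category
prototype); object appearances vary widely, so visual categories are broad
and overlapping ($\sigma_{vis} = 0.25$). Production therefore requires a
many-to-one mapping from a diffuse, overlapping visual representation onto
the correct word, while comprehension is a one-to-many mapping from a
crisp auditory representation — the classic computational account of why
comprehension leads.

## Stimuli

The artificial vocabulary is 20 categories ("words") of 8 exemplars per
modality: 160 patterns per modality. Category prototypes are drawn
uniformly on $[0,1]^{10}$ — the same bounded space as the SOM weights, so
the weight-range invariant is provable — and exemplars are Gaussian
perturbations of the prototype, clipped to $[0,1]$. Clipping has a
consequence worth stating: for visual categories the exemplar-cloud mean is
shifted away from the raw prototype (by roughly $\sigma \phi(0) \approx
0.1$ per component at the boundary). The package therefore carries, for
each category, the *centroid* of its exemplar cloud; decoding compares map
responses against centroids, which is what a trained map actually
represents. With $\sigma = 0$ the centroid coincides with the prototype.

Presentation-time input noise (the noise perturbation) is redrawn on every
presentation, modelling unreliable encoding rather than a fixed distortion
of the stimulus set.

## Training

`train_model()` runs 400 epochs. Each epoch shuffles the 160 paired
presentations and re-pairs each auditory exemplar with a random
same-category visual exemplar — hearing "dog" from different speakers
while seeing different dogs. Both maps update with the standard Kohonen
rule $w \leftarrow w + \alpha h (x - w)$ with a Gaussian neighbourhood
kernel on grid distance; the Hebbian bridge accumulates
$\Delta w_{av} = \eta\, a_{aud}(a)\, a_{vis}(v)$ over the two maps'
normalised activation fields, with divisive row normalisation (any
auditory row exceeding total mass one is rescaled to one), which bounds
otherwise unbounded Hebbian growth.

Schedules: the learning rate decays from 0.5 to 0.01 and the neighbourhood
radius from $\max(\mathrm{rows},\mathrm{cols})/2$ to 0.5. Both decay
**exponentially** (geometrically) by default. We initially used linear
decay and found that the radius then remains broad past epoch 200, so the
maps organise too late for the reference model to approach ceiling
comprehension within 400 epochs; with geometric decay — the common choice
in Kohonen practice — the radius passes below the inter-cluster grid
distance early enough for stable category formation. The linear shape
remains available via `decay = "linear"`.

The activation-field sharpness `kappa` (default 0.3) is the parameter that
converts map state into graded co-activation,
$a(i) \propto \exp(-\lVert x - w_i\rVert^2 / 2\kappa^2)$. It is also the
parameter that carries the modality asymmetry into behaviour: at small
`kappa` both fields are effectively one-hot and comprehension and
production become artificially symmetric; at `kappa` comparable to the
visual within-category spread, a visual input's field bleeds across
neighbouring (overlapping) visual clusters while the auditory field stays
category-crisp. The default was calibrated once, when the reference
condition was established, so that the reference model consistently shows
the canonical comprehension advantage; it is config-exposed.

Testing is noise-free by default (all 8 exemplars of each word, strict
majority required to count the word as known) because the noise
perturbation is an encoding-time manipulation; `test_noise = TRUE` enables
noisy testing.

How a propagated activation field is converted into a categorical response
was a genuinely open design point, and we evaluated three readout rules
before freezing the default. A single-winner rule (argmax neuron, nearest
centroid) is the most literal but proved fragile: comprehension and
production then bottleneck on the same single-neuron ambiguity of the
overlapping visual clouds, and for some vocabularies the sign of the
reference gap flips between runs. A region-pooling rule (neurons
partitioned by nearest centroid, mass summed per region) is maximally
robust but erases the competition penalty altogether — production stops
being the harder direction, which removes the very mechanism under study.
The default is the centre-of-mass readout: the field's expected weight
vector $\bar w = \sum_i a(i)\, w_i$ is decoded to its nearest centroid.
It reads out the whole distributed pattern (stable across vocabularies)
while cross-category bleed still drags $\bar w$ toward competing
centroids, preserving the many-to-one competition that delays production.
All three rules are available via the `decode` configuration field.

Two engines produce bit-identical results: a compiled loop (`engine =
"cpp"`, the default) and a pure-R reference implementation built from the
exported unit operations (`engine = "r"`). All accumulations in the
compiled path use extended precision to match base R's summation, which is
what makes exact agreement possible; the equivalence is asserted in the
test suite.

## The perturbation space

Three manipulations, each applicable to either map or both, span the
variant space of `enumerate_model_space()`:

* **size**: 12×12 (144 neurons) reduced to 9×9 (81), constraining
  representational capacity;
* **noise**: presentation-time Gaussian input noise (default SD 0.3 for
  the generic noise variants), simulating unreliable sensory encoding;
* **neighbourhood disruption**: weight updates confined to the BMU. This
  is the strongest reading of a disrupted neighbourhood function, and it
  provably produces exemplar-based maps: with no neighbour updates,
  neurons tune to individual instances and never consolidate shared
  category representations.

The WS composite (`ws_config()`) combines all three channels: both maps
9×9, noise in both modalities, disruption in the visual map only. The two
noise magnitudes are modality-specific. This choice was made once, at the
point the variant space was frozen: auditory encoding noise is what
delays comprehension (auditory categories are tight, so absolute noise
corrupts them proportionally far more), while strong visual noise erodes
the exemplar tuning of the disrupted visual map and with it the
production advantage that defines the WS profile. At the defaults the
composite exhibits delayed comprehension and production with production
relatively spared, a reduced comprehension-production gap, and full
recruitment of the disrupted visual map (categorisation rating 1).

## Metrics

* **AUC**: trapezoidal area under a per-epoch count trajectory; a
  cumulative words-learned measure. Delays appear as negative deltas
  against the reference batch (Welch two-sample t-tests on run-level AUCs,
  Benjamini-Hochberg correction across the model family).
* **Gap**: AUC(comprehension) − AUC(production).
* **Quantisation error**: mean input-to-BMU distance on the noise-free
  exemplar set, per modality.
* **Categorisation rating**: distinct BMUs recruited by the 160 exemplars,
  divided by the neuron count of that map. Low values mean compact
  prototype-like categories; values near 1 mean exemplar-based, fragmented
  representation. The denominator is the map's own neuron count, so the
  reference (144) and reduced (81) maps are compared on a common [0, 1]
  scale.

## Statistical harness

The gap analysis mirrors the one used for empirical CDI data. A monotone
(non-decreasing) smoother of production on comprehension is fitted to the
reference sample — 5 points sampled per run from each of 20 runs, 100
points per model — and each tested model's 100 points are compared against
the fitted line with an exact binomial sign test: `p = P(X >= k)` for `X ~
Binomial(n, 1/2)` over the non-zero residuals, with a one-sided 95%
Clopper-Pearson lower bound on the proportion. Zero residuals are dropped
(the standard sign-test convention; ties carry no directional
information).

The monotone smoother is an I-spline basis (default dimension 3, the
smallest basis that still bends: quadratic I-splines on the data range
with no interior knots; larger dimensions add evenly spaced interior
knots) with coefficients constrained non-negative, plus a free intercept,
fitted by Lawson-Hanson non-negative least squares. Non-negative weights
on monotone basis functions make the fit non-decreasing everywhere, the
analogue of a monotone-positive-increase shape constraint. Gaussian least
squares is used rather than a count family; the response enters only
through the sign of its residuals, which is insensitive to that choice.
Confidence bands, where needed for plotting, come from a
resample-and-refit bootstrap (percentile, default 200 replicates) rather
than analytic standard errors: the bands are presentation-only and the
bootstrap is assumption-light. Outside the fitted domain predictions are
clamped to the boundary value and flagged; the sign test never needs
extrapolated predictions in normal use because the tested models'
comprehension range is contained in the reference model's.

## The synthetic CDI generator

The empirical pipeline is exercised on synthetic cohorts built by
`generate_cdi_dataset()`, with the study's group sizes and age ranges: TD
n = 1210 (12-25 months), WS n = 67 (7-74 months), DS n = 27 (11-40
months), FXS n = 15 (14-47 months); 1319 children in total, scores bounded
by the 418-word checklist.

Per child, comprehension follows a logistic growth curve in age (asymptote
418, group-specific rate and rightward delay shift) plus Gaussian
reporting noise; production is a binomial thinning of comprehension,
`Binomial(comprehension, gamma)`, with a child-level jitter on the
retention probability `gamma`. Thinning guarantees `production <=
comprehension` by construction — the checklist scores as expressive only
words the child both understands and produces — and `gamma` encodes the
group gap structure: raised in WS (reduced gap), equal to TD in DS (the
DS profile mirrors the canonical asymmetry), lowered in FXS (pronounced
expressive deficit). Defaults: TD 0.35, WS 0.47, DS 0.35, FXS 0.15.

The generator emulates the *statistical shape* the pipeline must detect —
monotone growth, a bounded scale, group-specific production given
comprehension — and nothing else. It does not model item-level structure,
semantic categories, reporting biases, or longitudinal dependence, and its
growth-curve parameters are calibration choices, not empirical estimates.
A passing pipeline on synthetic data therefore shows that the machinery
recovers a planted group contrast of realistic size and sample structure;
it says nothing about the true effect sizes in real cohorts.

## Reproducibility and numerical choices

Every stochastic step is a pure function of a seed: batch runs derive
per-run seeds from the master seed, and the batch's vocabulary is drawn
once from the master seed and shared across its runs (the stimulus set is
one fixed artifact per study, and per-run stimulus resampling would
inflate between-run variance of the AUC measures). BMU and decoding
argmin/argmax ties break to the lowest row-major index; flat propagated
fields (an untrained bridge) decode as failures rather than guesses; the
grid is planar, not toroidal. Weight updates with `alpha <= 1` are convex
combinations, so weights stay in `[0,1]` — asserted in the tests, as are
the brute-force BMU oracle, the 2^n sign-test enumeration oracle, and the
matrix-product propagation oracle.

Problem sizes in the test suite: the acceptance-level model comparisons
use 20-run batches of the full 400-epoch model (the study's own scale);
unit and property tests use reduced grids (3×3 to 6×6) and short runs,
which exercise every code path at a fraction of the cost.

## Known limitations

* The mapping from disrupted neighbourhoods to *BMU-only* updating is the
  strongest reading; a graded attenuation would interpolate between the
  reference and disrupted regimes.
* Supplementary implementation constants of the original study (schedules,
  noise magnitudes, Hebbian parameters) are not public; the defaults here
  are the package's own calibration, fixed once and documented above, and
  reproduce the study's qualitative contrasts rather than its printed
  stochastic magnitudes.
* The artificial vocabulary abstracts away phonology, semantics, word
  frequency and referential ambiguity; the synthetic CDI cohorts are
  pipeline fixtures, not data.
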