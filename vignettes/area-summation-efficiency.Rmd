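---
title: "Area summation and population coding efficiency: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Area summation and population coding efficiency: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, the numerical choices, and the design
decisions behind `asfnet`: a pipeline that asks whether the non-linear area
summation function (ASF) of primary visual cortex neurons is associated with
an energy-efficient population code in a biomimetic spiking network.

## The area summation model

The response of a V1 neuron to a centred circular grating of diameter $x$ is
modelled as a ratio of Gaussian center and surround mechanisms,

$$R(x) = \frac{k_c\,L_c(x)}{1 + k_s\,L_s(x)},\qquad
L(x; w) = \left(\tfrac{2}{\sqrt\pi}\int_0^x e^{-(y/w)^2}dy\right)^2
        = w^2\,\mathrm{erf}(x/w)^2 ,$$

with center/surround gains $k_c, k_s \ge 0$ and spatial extents
$w_c < w_s$.  The curve rises while the center integral grows, peaks at the
*summation field* diameter, and declines toward the asymptote
$k_c w_c^2/(1 + k_s w_s^2)$ (*surround suppression*).  `eval_asf()` uses the
closed error-function form; `measure_asf()` characterises any parameter set
by its summation field (the peak diameter), surround diameter (first
diameter past the peak within 5% of the asymptote — the 5% criterion is this
package's operational definition, since none is standard), and suppression
level $(\mathrm{peak}-\mathrm{asymptote})/\mathrm{peak}$.

To spread a curve measured with gratings over arbitrary contrast images, the
ASF is converted to a radial density over the visual field,

$$f(u, v) = \frac{R'(2r)}{\pi r},\qquad r^2 = u^2 + v^2,$$

whose defining property is the *disk-integral identity*:
$\iint_{\|(u,v)\| \le D/2} f\,du\,dv = R(D)$ for every diameter $D$.  The
identity is exact analytically and is the module's oracle: the test suite
and the acceptance script verify it by 2-D numerical quadrature to better
than 0.1%.  At $r \to 0$ the density behaves like $1/r$ (integrable but
unbounded); grid-based consumers therefore give the innermost grid cell the
exact disk integral over an equal-area disk instead of a point evaluation,
which preserves the identity at the center.

### Eccentricity regressions

Summation field, surround diameter and suppression are modelled as linear
functions of eccentricity.  The defaults,

| characteristic | intercept | slope / degree |
|---|---|---|
| summation field (deg) | 0.5 | 0.07 |
| surround diameter (deg) | 1.4 | 0.19 |
| suppression (fraction) | 0.35 | 0 |

are *approximate calibration constants of this package*, chosen so that the
14-degree curve peaks near 1.5 degrees with clearly visible suppression and
reaches its asymptote well inside a 7-degree stimulus.  Two constraints shaped
them.  First, in the ratio-of-Gaussians family the suppression level and the
surround/summation diameter ratio are strongly coupled: at 35% suppression
the family can only realise ratios near 2.7–3, so the two size regressions
keep a fixed ratio of 2.75 and suppression is eccentricity-flat (consistent
with suppression varying little with eccentricity in primate data).  Second,
the surround diameter must stay below the 7-degree integration disk across
the modeled 0.5–27-degree range.  Triples outside the feasible region are
not fittable — `fit_asf_params()` would report non-convergence.

`fit_asf_params()` recovers $(k_s, w_c, w_s)$ from a characteristic triple
by Nelder–Mead on log-parameters (positivity by construction), with $k_c$
fixed at 1 because all three characteristics are invariant to the overall
gain.  Multiple starts plus a restart from the first solution guard against
simplex stalls; the loss is the sum of squared relative characteristic
errors, with convergence declared below $10^{-3}$.  Parameters are fitted
once per 1-degree eccentricity ring (ring centers 1–27 degrees), not per
neuron: single-cell variability is deliberately averaged out.

The two artificial variants multiply $(k_c, k_s)$ by $(4, 0.25)$ — larger
summation field, essentially no suppression — and $(0.25, 4)$ — smaller
summation field, stronger suppression.

## Contrast energy

Images are converted to broad-band contrast energy with a Gabor bank of five
frequencies (1, 2, 4, 8, 16 cycles per 5 degrees of field), eight
orientations over $[0°, 180°)$, and two phases (0/90), i.e. 80 filters, at
82 pixels per 5 degrees at full scale.  Kernels are zero-DC (envelope-
weighted mean subtraction) and unit-norm, with a one-octave envelope
($\sigma = 0.56\lambda$).  Per (frequency, orientation), the 0/90 quadrature
pair is pooled as the sum of squared responses — the standard contrast-energy
convention, and the package's one interpretive choice where the upstream
description says only that normalized filter outputs are summed; a
`rectified` mode is available.  Each band is then normalized by its own
maximum (`l2` optional) and the bands are summed.  The 5-bin frequency
signature is computed from the *raw* band energies (summed over space,
orientation and phase, normalized to unit sum): normalizing per band first
would flatten exactly the frequency differences the signature must capture.

## Retina model and cortical mapping

Midget on-cells tile the left-hemifield sector (0.5–27 degrees) with polar
arc segments: ring widths match the local cell spacing of an
inverse-polynomial density $d(e) = d_0/(1+e/e_2)^2$ ($d_0 = 3900$ cells/deg²,
$e_2 = 2°$, calibrated so the full-scale mosaic holds $\sim 8.4\times10^4$
cells; published human midget densities are not reproduced in detail).
Segments tile without gaps, so image integration is exact bookkeeping: each
cell's center input is its mean intensity (area-normalized — the raw-sum
reading would make the operation resolution-dependent and break the
uniform-field null), the surround subtracts $1/8$ of each of the 8
neighboring segment means, missing edge neighbors substituting the cell's
own mean.  A uniform image therefore yields exactly zero net input.  Cells
finer than the image grid fall back to bilinear sampling.

Net inputs are normalized by their maximum absolute value and squashed by a
logistic into (0, 1).  `retina_output()` defaults to the symmetric operating
point (zero input at 0.5, extremes at 0.05/0.95).  The *pipeline* drives
the network at an ON-rectified operating point instead
(`sim_config()$input_midpoint_rel = 0.15`): with the symmetric midpoint the
spatial mean response to any luminance-balanced pattern equals the
gray-screen response, and because the scaled cortical sheet makes
feedforward pooling span several stimulus periods (below), stimulus drive
cancels almost exactly in the population mean — gratings were invisible to
the network.  A low spontaneous level with strong increments is also the
physiological operating regime of the ON midget pathway.

Cortical positions come from the conformal log-polar map
$w = k \log(1 + z/a)$ with $a = 0.7°$ and $k = 17.3$ mm, giving
magnification $k/(e+a)$ mm/deg; 1 mm of retina is taken to cover 3.8
degrees everywhere, and the foveal inner-segment displacement is compensated
by a small outward receptive-field shift decaying to zero at 3 mm retinal
eccentricity.

## The spiking network and its downscaling

Five groups in three levels: Poisson input layer (one source per mosaic
cell), V1 excitatory 6-compartment pyramidal cells and single-compartment
basket-like inhibitory cells, and an extrastriate excitatory/inhibitory
pair.  Full-scale reference counts (226,206 / 42,849 / 10,713 / 10,713 /
10,713; 9,014 inputs for the low-resolution control) are configuration
reference values; built geometries preserve the ratios at any scale.

Connection probabilities decay with cortical distance: Gaussian
$\sigma = 0.23$ mm for the geniculate feedforward projection, exponential
$\lambda = 1$ mm for lateral V1, $\lambda = 3.3$ mm for the
V1–extrastriate loop.  Two families carry the swept scale factors:
`lateral_EI` ($E_{V1} \to I_{V1}$, $I_{V1} \to E_{V1}$;
$\beta \in [0.1, 2.45]$) and `ffb_X` (the five V1–extrastriate projections;
$\beta \in [0.17, 4.20]$), both on log-spaced grids (25 points per axis at
full scale, 5 at fixture scale).  The $E_X \to I_{V1}$ probability is tied
to $E_X \to E_{V1}$ so 10% of feedback synapses land on inhibitory cells,
and the base probabilities put feedforward and feedback synapse counts
within a few percent of each other.  Base probabilities and synaptic weights
are calibration constants of this implementation (the source architecture
does not print them), chosen once so that the network sits in a
fluctuation-driven regime with evoked V1 rates of order 10–100 Hz over the
sweep.

**Downscaling.**  The desk-scale geometry (~3,900 neurons, `scale_factor
0.0129`) shrinks the map constant $k$ by $\sqrt{\mathrm{scale}}$ rather than
thinning neurons on a full-size sheet.  Thinning would leave the
$\sigma = 0.23$ mm kernel an expected in-degree below one and the
$\lambda = 1$ mm kernels without a reachable inhibitory partner — no weight
rescaling can repair a connection count of zero.  Shrinking the sheet
preserves full-scale neuron densities per mm², in-degrees, and the relative
geometry of all three kernels, with unchanged weights; what is distorted is
the mm-per-degree conversion, so the lateral kernel spans several degrees of
visual field instead of a fraction of a degree.  Consequences: the network's
emergent summation field is much coarser in degrees than the ASF target's,
feedback is effectively global on the small sheet, and the probe grating
(below) must be low-frequency.  These distortions affect absolute pattern
match, not the direction of the efficiency relations the pipeline asserts.

Neurons follow the exponential integrate-and-fire equation (200 pF, 10 nS
leak, $\Delta_T = 2$ mV, threshold −50 mV, reset −60 mV, 2 ms refractory)
with conductance synapses (AMPA-like 5 ms to 0 mV; GABA-A-like 10 ms to −75
mV) — standard cortical constants, configurable, not fitted.  V1 excitatory
cells carry a passive 5-compartment dendritic chain (axial 20 nS, 100 pF /
5 nS per compartment) so that somatic EPSP efficacy decays with synaptic
distance from the soma; feedforward input lands proximally (compartment 1),
lateral excitation at compartment 2, extrastriate feedback distally
(compartment 5), and basket inhibition at the soma.  The pointwise control
replaces the chain by a single compartment.  Integration is forward Euler at
0.1 ms with exponentially decayed conductances and a clamped spike term;
runs are bit-reproducible given a seed (R's RNG drives both the Poisson
input and connectivity sampling).

The protocol is 500 ms: 200 ms baseline (gray-screen drive at the logistic
spontaneous level) then 300 ms of stationary image input; spike counts are
reported over 200–500 ms only.

### The area summation probe

`area_summation_probe()` presents circular grating patches of growing
diameter at 14 degrees eccentricity and averages the response of the 15 V1
excitatory cells nearest the probe center.  The default grating is 0.5
cycles/degree in cosine phase (a luminance peak on the probe center), and
diameters run to 24 degrees: on the shrunk sheet the feedforward pooling
footprint and the lateral kernel correspond to several degrees, so the
"cell-optimal" grating and the summation/suppression scales are
correspondingly coarse.  With strong lateral inhibition
($\beta_{lat} = 2.45$) the curve rises and then falls clearly below its
peak; with the lateral family nearly silent ($\beta_{lat} = 0.1$) it
saturates without suppression.

## Target patterns and efficiency metrics

The target activation of each V1 excitatory neuron is the contrast-energy
image weighted by its ring's $f(u,v)$ and summed over a 7-degree-diameter
disk around its receptive-field center (enough to reach the asymptote; the
test suite checks that widening to 9 degrees moves mid-field targets by
under 1%).  The density is averaged over $3\times3$ sub-pixel points per
cell, boundary cells contribute their inside fraction, and the singular
center cell uses the exact equal-area disk integral; on a uniform
contrast-energy field the summed weights reproduce $c\,R(7°)$ to well within
0.5%.  Neurons whose receptive fields lie within 0.5 degrees of the field
edge are masked from all comparisons, identically for simulated and target
patterns.

Per run, both patterns are normalized by $(x - \min)/(\max - \min)$
(constant patterns map to zero with a degeneracy flag; the literal
divide-by-max variant is available), and

* **DAS** $= \sum_i |S_i - T_i|$ over unmasked neurons,
* **total spikes** (V1 excitatory only) as the linear energy proxy, with an
  optional ATP conversion ($4.4\times10^8$ ATP/s·neuron maintenance,
  $10^9$ ATP/spike),
* **entropy per spike**: counts normalized by their maximum, 256 equal-width
  right-closed bins on $[0,1]$, Shannon entropy over occupied bins divided
  by total spikes (ceiling 8 bits; zero total is an explicit error, not 0),
* **population sparseness**
  $S_p = \bigl(1 - (\sum y/N)^2 / (\sum y^2/N)\bigr) / (1 - 1/N)$,
  0 for uniform, 1 for one-hot.

All three are checked against independent brute-force references to
$10^{-12}$.

## The sweep and its statistics

The manifest is the full image × grid cross product with per-run seeds
derived deterministically from a master seed.  Per run the network is
re-sampled at the row's $\beta$ point and simulated on the row's image;
distance computations and $p_0\cdot\mathrm{decay}(d)$ are precomputed once.
Pooled correlations use raw data points across images (per-image
coefficients are also reported); images are grouped by k-means (k = 2, 50
restarts, fixed seed) on their frequency signatures with the
higher-low-bin-mass cluster labeled "low"; extreme runs are excluded
range-based (top/bottom 15% of the spike-count dynamic range — the literal
reading of "dynamic range"; a quantile variant is one flag away); group
comparisons use the exact rank-sum distribution up to n = 12 per group and
the corrected normal approximation beyond; the input-drive check is a
Friedman test blocked by grid point, with the fully-tied design returning a
zero statistic explicitly.

## Synthetic study inputs

Natural images are emulated by random-phase $1/f^\alpha$ surrogates,
$\alpha = 1.4$ for the predominantly-low-frequency group and $0.9$ for the
mixed group — values fixed once so the two groups separate cleanly under the
k-means signature split (they do, 10/10 on held-out batches, and measured
log–log spectral slopes land within ±0.1 of $-\alpha$).  Surrogates
reproduce second-order statistics only: no edges, occlusions, or
higher-order structure of natural scenes.  Passing the directional
acceptance checks on surrogates therefore demonstrates the mechanism —
lateral inhibition simultaneously shapes ASF-like patterns and improves
efficiency — not full-scale correlation magnitudes on real imagery.

The fixture bundle (6 images, 5×5 grid, ~3,900 neurons, 150 simulations)
was sized for a single CPU: the full sweep plus target construction runs in
roughly two minutes.  The full-scale problem (20 images × 625 points,
~300,000 neurons) is out of desk reach and is represented structurally (the
manifest cardinality, reference counts, and the 25-point grids).

## Known limitations

* The $\sqrt{\mathrm{scale}}$ map shrink preserves network mechanics but
  misaligns the degree-scale of lateral interactions with the ASF target's
  surround; the simulated-vs-target match is qualitative at desk scale.
* The artificial-ASF comparison (no-suppression vs natural) keeps its
  expected direction but with a small margin at fixture scale: DAS variation
  across runs is dominated by the simulated patterns, and the two target
  shapes are spatially correlated, so target discrimination is weak with
  ~500 neurons.
* The surrogate groups differ systematically in total input drive, unlike
  the original image set (the Friedman check reports a significant
  difference), and the low-vs-mixed ordering of correlation strengths is
  not resolved at this scale.
* Off-pathway retina cells are constructed but carry no signal (a config
  flag exists); there is no orientation, disparity or ocular tuning, no
  cortical layering, and no plasticity.
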