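# asfnet

Neurons in primary visual cortex (V1) do not sum stimulus energy linearly:
as a centred grating grows, firing first rises, peaks at the *summation
field*, and then falls toward an asymptote (*surround suppression*).  This
area summation function (ASF) is one of the most robust receptive-field
properties in visual cortex, yet its computational benefit is not obvious.
`asfnet` is an analysis pipeline for a concrete hypothesis: network
configurations whose population response to natural-statistics images looks
ASF-like are also the *energy-efficient* ones.  It is aimed at computational
neuroscientists who want a fully self-contained, desk-scale reimplementation
of that analysis — every input is generated in code, every stage is a tested
package function, and the whole study runs on one CPU in minutes.

## The models at the core

**Area summation.**  The response to a centred circular stimulus of
diameter *x* is a ratio of Gaussian mechanisms,

    R(x) = k_c L_c(x) / (1 + k_s L_s(x)),      L(x; w) = w^2 erf(x/w)^2

with center/surround gains `k_c, k_s` and extents `w_c < w_s`.  For
arbitrary images, `R` is converted into a radial density
`f(u, v) = R'(2r) / (pi r)` whose integral over a disk of diameter `D`
recovers `R(D)` exactly — the pipeline's central analytic identity.  Per
neuron, the *target activation* is the Gabor-bank contrast energy of the
image weighted by `f` over a 7° disk around the receptive-field center.

**Network.**  A recurrent exponential integrate-and-fire model with five
groups in three levels — Poisson retinal/geniculate input through a midget
on-cell mosaic and a log-polar cortical map, V1 excitatory (6-compartment)
and inhibitory cells, and an extrastriate pair — connected by
distance-decaying stochastic kernels (Gaussian σ = 0.23 mm feedforward;
exponential λ = 1 mm lateral, λ = 3.3 mm feedforward/feedback).  Two
connection families are scaled by factors β on log grids: lateral V1
excitatory–inhibitory loops (0.1–2.45) and the V1–extrastriate loop
(0.17–4.20).

**Efficiency vs. distance-to-ASF.**  Each 500 ms run (200 ms baseline,
300 ms image) yields a V1 spike pattern that is normalized and compared with
the normalized target: `DAS = Σ |S_i − T_i|`.  Efficiency is quantified by
total spikes (energy proxy, optionally in ATP), entropy per spike (256-bin
spatial entropy / total spikes), and population sparseness
`(1 − (Σy/N)² / (Σy²/N)) / (1 − 1/N)`.  The pipeline then correlates each
metric with DAS across images × β grid.

## Worked example

Fit ASF parameters at 14° eccentricity from the default eccentricity
regressions and inspect the curve:

```r
library(asfnet)
ch <- characteristics_at_eccentricity(asf_regression(), 14)
p  <- fit_asf_params(ch)
print(p)
#> ASF params (ecc 14.00 deg): k_c=1 k_s=0.1811 w_c=1.075 w_s=2.813
m <- measure_asf(p)
sprintf("summation field %.2f deg, surround diameter %.2f deg, suppression %.2f",
        m$summation_field, m$surround_diameter, m$suppression)
#> "summation field 1.48 deg, surround diameter 4.06 deg, suppression 0.35"
mv <- measure_asf(make_variant_asf(p, 4, 0.25))   # no-suppression variant
sprintf("variant: summation field %.2f deg, suppression %.2f",
        mv$summation_field, mv$suppression)
#> "variant: summation field 1.87 deg, suppression 0.13"
```

The fitted curve peaks at 1.48° and settles 35% below the peak — the
characteristics fed in — and the `(k_c × 4, k_s × 0.25)` variant widens the
summation field while nearly abolishing suppression.

## The analysis workflow

The numbered scripts under `analysis/` run the study end to end and write
tidy tables under `results/`:

| script | what it does |
|---|---|
| `01_fixture_inputs.R` | 1/f<sup>α</sup> surrogate images (two spectral groups), frequency signatures, k-means group split |
| `02_asf_model.R` | per-ring ASF fits, artificial variants, disk-integral check, 14° curves |
| `03_target_patterns.R` | geometry, contrast energy, per-neuron target patterns, border mask |
| `04_network_sweep.R` | 6 images × 5×5 β grid = 150 spiking simulations, efficiency reports |
| `05_efficiency_analysis.R` | pooled/per-image correlations, group and mid-range statistics |
| `06_area_summation_probe.R` | grating-diameter response curves at high/low lateral β |

On the shipped fixture (seed 1) the sweep prints pooled Pearson correlations
against DAS of **+0.97** for total spikes, **−0.90** for entropy per spike,
and **−0.97** for sparseness — the configurations closest to the ASF target
spend the fewest spikes and code most efficiently — and the probe's
grating-diameter curve rises then falls by ~27% at β_lat = 2.45 but
saturates without suppression at β_lat = 0.1.

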