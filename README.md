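# episcope

Analysis of spontaneous glutamate release and population activity in slice
recordings of the rostromedial tegmental nucleus (RMTg), the GABAergic
brainstem nucleus that inhibits midbrain dopamine neurons. The package is
aimed at electrophysiologists and imaging labs quantifying drug effects —
prototypically the nicotinic potentiation of glutamatergic input — on two
kinds of recording:

* **Voltage-clamp current traces** (−70 mV holding, 5 kHz): spontaneous
  excitatory postsynaptic currents (sEPSCs) are detected as inward
  deflections exceeding a noise-scaled threshold, binned into 10-s frequency
  histograms, normalised to the control baseline, and summarised over the
  5-min maximal-effect window; bursts (50–150 ms event clusters) and
  per-cell responsiveness (Mann–Whitney on baseline vs post-drug bins) are
  reported.
* **Calcium-imaging recordings** (4 frames/s, 6-min videos, 280 × 260 µm
  field): circular ROIs (4–30 µm) are extracted from the temporal-SD summary
  image, ΔF/F = (F − F₀)/F₀ transients are detected with the canonical
  2.5 × noise-SD criterion on the signal and its first derivative, onsets
  populate a cells × frames binary raster, and synchrony peaks in the
  coactivity histogram are validated against 1,000 circular-shift surrogates
  (family-wise threshold at α = 0.05).

A synthetic-data module generates both recording types with exported ground
truth (Poisson event trains with exponential-onset drug modulation and
washout persistence; transient trains with planted population ensembles;
rendered TIFF-compatible movies), so every stage of the pipeline is
verifiable end to end. Nonparametric tests (Mann–Whitney U, two-sample
Kolmogorov–Smirnov, Friedman) are implemented with exact small-sample
enumeration.

## The core quantities

For an event train with baseline (control) binned frequency $f_0$, the drug
effect is the percent change of the binned series $f(t)$ normalised to
baseline, $100 \cdot f(t)/f_0$, averaged over the 5-min window that
maximises it after drug onset; +172% means the window mean reached 272% of
baseline. A burst is a run of ≥ 3 events spanning 50–150 ms whose within-run
frequency $(n-1)/\mathrm{span}$ exceeds 1.5× baseline. For a binary raster
$B$ (cells × frames), the coactivity is $c_f = \sum_i B_{if}$; significance
of synchrony peaks is assessed against surrogates that circularly shift each
row by an independent uniform offset, using the per-surrogate maximum
$\max_f c_f$ as the null statistic.

## Worked example

Electrophysiology arm — simulate a three-epoch experiment (10 min control,
10 min drug at rate ratio 2.72 ≙ +172%, amplitude ratio 2.403 ≙ +140.3%,
10 min wash at 80% persistence) and run the full analysis:

```r
library(episcope)

prot <- drugProtocol(control = 600, drug = 600, wash = 600)
sim  <- simulateEpscTrace(epscSimParams(seed = 42), prot)
report <- runEpscPipeline(sim$trace)

report$noiseSd                        # 2.04 pA (generator planted 2 pA)
report$nEvents                        # 12331 detected events
report$frequency$baselineHz           # 3.57 Hz control frequency
report$frequency$effectWindow         # 870 1170  (s; window inside the drug epoch)
report$frequency$percentIncrease      # 164.9  (planted asymptote +172%)
report$amplitude$percentIncrease      # 136.0  (planted asymptote +140.3%)
nrow(report$bursts)                   # 1786 burst clusters
report$responsive                     # TRUE, p = 4.85e-21
```

The recovered +164.9% sits below the +172% asymptote because the 5-min
window still overlaps the exponential onset and the detector loses a few
percent of events to refractory overlap at the elevated rate — both effects
are visible in the ground truth (`sim$truth`).

Calcium arm — 30 cells across the same three conditions with doubled
activity in drug and wash:

```r
prot <- drugProtocol(control = 360, drug = 360, wash = 360)
sim  <- simulateCalciumTraces(calciumSimParams(seed = 42), prot)
rep  <- runCalciumPipeline(sim$traces, prot, seed = 42)

rep$coactivity$threshold              # 9 coactive cells (surrogate threshold)
length(rep$coactivity$significantFrames)  # 38 significant synchrony frames
rep$tests$ks[["control vs drug"]]$pValue  # 1.8e-14
rep$tests$friedman$statistic          # 46.2 (chi-square, p = 9.3e-11)
tapply(rep$activity$fraction, rep$activity$condition, median)
#  control   drug    wash
#   0.0285  0.0486  0.0497          # ~2x activity in drug/wash, as planted
```

`plotReport(report)` renders the standard figures (time-frequency histogram
with drug band, cumulative amplitude fractions, raster with coactivity
histogram and threshold line), and `runExperiment("config.yaml")` drives
both arms from a single YAML configuration.

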