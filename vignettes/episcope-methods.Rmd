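---
title: "Methods: sEPSC event analysis and calcium-imaging population synchrony"
author: "episcope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sEPSC event analysis and calcium-imaging population synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcope)
```

## The scientific problem

Nicotinic agonists can potentiate spontaneous glutamate release onto
GABAergic neurons of the rostromedial tegmental nucleus (RMTg), a brainstem
structure that inhibits midbrain dopamine neurons. Two recording modalities
probe this effect in acute slices:

* **Whole-cell voltage clamp** at a holding potential of −70 mV, sampled at
  5 kHz. Spontaneous excitatory postsynaptic currents (sEPSCs) appear as
  brief inward (negative) deflections; drug effects show up as changes in
  their frequency and amplitude, and as *bursts* — short clusters of events
  reflecting synchronised multivesicular release.
* **Bulk-loaded calcium imaging** at 4 frames/s (250 ms/frame), 6-min videos
  of 1,440 frames over a 280 × 260 µm field. Somatic calcium transients act
  as a proxy for firing; the population question is whether cells become
  more active and more *coactive* (synchronised) under drug.

An experiment runs in three epochs — control, drug, wash — and the analysis
quantifies the drug effect relative to the control baseline in each cell,
then at the population level. `episcope` implements both analysis arms plus
a synthetic-data module that generates both kinds of recording with exported
ground truth, so every stage is testable without the original recordings.

## Drug protocol model

A `DrugProtocol` holds the epoch table and four effect parameters. The drug
effect envelope $e(t)$ is 0 during control, rises as
$1 - \exp(-(t - t_0)/\tau_\mathrm{onset})$ during the drug epoch, and is held
at the constant `washoutPersistence` afterwards. Event rate and amplitude are
multiplied by $1 + (R - 1)\,e(t)$ with $R$ the asymptotic rate (or amplitude)
ratio.

Choices worth noting:

* **Exponential onset** (`onsetTau`, default 60 s): onset latency varies with
  drug diffusion into the slice; a first-order approach is the simplest model
  consistent with the observed gradual time courses.
* **Washout persistence** (default 0.8): the potentiation outlasts the drug
  by tens of minutes, but no washout kinetics are quantified anywhere we can
  calibrate against; persistence is therefore a free parameter, a retained
  *fraction* of the asymptotic effect, not a fitted decay. With
  `washoutPersistence = 1` the wash epoch continues the full asymptotic drug
  effect — the configuration used in recovery tests, because it makes the
  planted effect size unambiguous.
* Default effect sizes `drugRateRatio = 2.72` and `drugAmpRatio = 2.403`
  correspond to +172% frequency and +140.3% amplitude, the magnitude of
  nicotinic potentiation these analyses are designed to resolve.

## Synthetic electrophysiology

`simulateEpscTrace()` draws background events from an inhomogeneous Poisson
process (`baseRate` 3.5 Hz by default, the typical control sEPSC frequency in
this preparation) by thinning, applies a short absolute refractory period
(2 ms), and adds burst clusters at `burstRate`·$e(t)$ — bursts are a
drug-driven phenomenon, so their intensity follows the drug envelope. Burst
geometry (4–8 events at 15–25 ms spacing) gives in-burst frequencies around
50 Hz, matching the burst definition below. Each event is rendered as a
negative biexponential kernel (0.5 ms rise, 3 ms decay — typical AMPA-receptor
kinetics at 5 kHz sampling, which the source recordings do not specify) with
lognormal amplitude (median 20 pA, log-SD 0.45; amplitude histograms of such
recordings are right-skewed) on Gaussian baseline noise (SD 2 pA). The kernel
is aligned so that the ground-truth event time is the *peak* time, which is
what the detector reports. All generation is bit-reproducible given the
parameter object and its seed.

What the generator does **not** emulate: real synaptic noise is not white
(membrane filtering, line pickup), amplitudes within a burst are not
independent, and rundown/access-resistance drift are absent. Passing tests
therefore demonstrate correctness of the estimators under the stated
statistical model, not robustness to every pathology of slice recordings.

## sEPSC analysis

* **Noise model** (`estimateNoise`): robust SD (MAD × 1.4826) of the
  running-median high-pass residual. The high-pass removes offsets and slow
  drift; the MAD resists contamination by the events themselves.
* **Event detection** (`detectEvents`): local peaks of the baseline-subtracted
  inward deviation, briefly smoothed (1 ms boxcar), accepted when the peak
  minus the local pre-event baseline reaches `kThreshold` (default 3) times
  the noise SD. The pre-event baseline is the median of the 2 ms window ending
  2 ms *before* the peak — ending it at the peak itself would overlap the
  event's own rise and deflate amplitudes. Candidates closer than the 2 ms
  refractory keep the larger peak. Detection is deterministic and invariant
  to constant offsets. Amplitudes are read from the smoothed deviation; for
  0.5/3 ms kinetics the boxcar attenuates peaks by ~2%, far below the noise
  bias that a raw-sample maximum would add.
* **Binning** (`binFrequency`, `binAmplitude`): 10-s bins; the last partial
  bin is dropped rather than rescaled so every bin has equal exposure.
* **Normalisation** (`normalizeToBaseline`): percent of the control-epoch
  mean; 272% of baseline is a +172% increase.
* **Maximal-effect window** (`selectEffectWindow`): the 5-min window aligned
  to bin edges, starting at or after drug onset, with the largest mean; ties
  go to the earliest window. Because the maximum is taken over overlapping
  windows, the estimate carries a small positive selection bias even under
  the null — visible in the recovery tests as a few percent of upward drift,
  and inherent to the maximal-effect convention itself.
* **Bursts** (`detectBursts`): at least 3 consecutive events spanning
  50–150 ms whose within-cluster frequency $(n-1)/\mathrm{span}$ is at least
  1.5× the baseline frequency. The qualitative definition ("frequency
  exceeded 50% of baseline") is ambiguous; read literally (≥0.5× baseline) it
  would label nearly all activity as bursting, so we adopt *exceeds baseline
  by 50%* (≥1.5×). A 2-event cluster cannot be distinguished from a chance
  short interval, hence the 3-event minimum. Overlapping candidates are
  resolved by a greedy left-to-right scan extended to the maximal run within
  the 150 ms span.
* **Responsiveness** (`responsiveCell`): a cell is responsive when the
  two-sided Mann–Whitney U test between control-epoch bins and the bins of
  the first 10 min after drug onset is significant at α = 0.05.

Events are detected on the full recording and assigned to epochs afterwards,
avoiding edge artefacts at epoch boundaries. Amplitude statistics are
reported over the maximal-effect window by default (the window convention
used for frequency), since the alternative — all events of the epoch — is
equally defensible but less comparable across cells.

## Synthetic calcium imaging

`simulateCalciumTraces()` builds per-cell fluorescence as a resting level of
1.0 plus transients with instantaneous rise `transientAmp` (default 0.3 ΔF/F)
and exponential decay (`decayTau` 1.5 s), at background Poisson frames
(`bgEventRate` 0.1 Hz per cell — about one transient per 10 s, typical of
spontaneous slice activity) and at ensemble frames where each cell joins with
probability `participationP` (0.6). Per-epoch rate ratios (default doubling
in drug and wash) scale both rates. Gaussian noise (SD 0.03 ΔF/F) gives the
default 10:1 transient-to-noise ratio of a clean bulk-loaded recording. The
generator returns *fluorescence* (baseline 1.0); `computeDff()` converts to
ΔF/F, mirroring the real processing chain. `renderMovie()` optionally paints
the cells as non-overlapping disks (4–30 µm templates; default field
280 × 260 px at 1 µm/px, comfortably above Nyquist for ≥4 µm somata) so the
ROI-extraction stage can be tested end to end.

Not emulated: photobleaching, motion, neuropil contamination, overlapping
cells, and indicator nonlinearity. The end-to-end tests therefore validate
the extraction/detection chain, not robustness to those artefacts (motion
correction and neuropil subtraction are out of scope by design).

## Calcium analysis

* **ROI extraction** (`extractRois`): the summary image is the per-pixel
  temporal SD — activity shows up as variance, so a static bright structure
  yields nothing, which is the desired behaviour for *active*-cell selection.
  Local maxima of the Gaussian-smoothed SD image above a robust floor
  (median + 5 MAD) seed circular templates; each is fitted with the diameter
  (4–30 µm) maximising disk-minus-annulus contrast and accepted greedily in
  decreasing peak order with no overlap.
* **ΔF/F** (`computeDff`): $(F_t - F_0)/F_0$ with $F_0$ the 10th percentile
  of the trace. "Resting fluorescence" is not otherwise specified; a low
  percentile resists contamination by the transients and is the common
  choice. The ratio cancels multiplicative illumination gain exactly.
* **Transient detection** (`detectTransients`): transients and their first
  derivative are the firing indicators. Candidates are frames where the rise
  statistic — the first difference of the 2-frame boxcar-smoothed trace —
  exceeds `kDeriv` (2.5) times its own robust noise SD; a candidate is
  accepted when the following ΔF/F peak reaches `kAmp` (2.5) times the
  per-cell noise SD. Working on the 2-frame mean matters: a single-frame
  difference has noise SD $\sqrt{2}\sigma$, so a 5σ transient would sit only
  ~1σ above a 2.5× criterion and ~15% of genuine events would be missed; the
  smoothed statistic has noise SD σ and recovers ≥95% of isolated 5σ events
  while keeping the candidate false rate at the Gaussian tail of the 2.5-SD
  criterion. Both thresholds stay at the canonical 2.5. Whether the 2.5×SD
  criterion applies to the amplitude, the derivative, or both is
  under-determined; both are exposed and both default to 2.5. Noise SDs are
  MADs computed after masking provisional supra-threshold frames, iterated
  once. A candidate run holding several strong single-frame rises is split
  into one onset per rise, so back-to-back events separated by one frame are
  resolved when their individual rises clear the threshold; in the
  zero-noise limit this degenerates to exact event-frame recovery. Events
  landing in the *same* 250 ms frame remain indistinguishable — a sampling
  resolution limit, not addressed by design (no deconvolution).
* **Raster** (`binarize`): ones exactly at onset frames. Onset-only marking
  is deliberate: the derivative localises firing onsets, and marking whole
  transient durations (6+ frames at these decay times) would inflate
  coactivity counts.
* **Coactivity and significance** (`coactivity`, `monteCarloThreshold`):
  column sums of the raster, tested against 1,000 surrogates in which every
  row is circularly shifted by an independent uniform offset. Circular shifts
  preserve each cell's event count and within-cell timing structure while
  destroying cross-cell alignment — the standard conservative surrogate for
  population synchrony. The per-surrogate statistic is the *maximum*
  per-frame coactivity, giving family-wise control over frames; the
  threshold is the smallest count reached by fewer than α·1,000 surrogate
  maxima. The integer-valued statistic makes the test conservative (the
  realised family-wise rate sits at or below α). With a single cell the
  threshold is undefined; with α ≥ 1 every frame with any activity is
  flagged (degenerate bound, documented for completeness). The exact
  surrogate scheme and peak statistic used by the original acquisition
  software are not described anywhere we can check against; ours is a
  defensible standard choice, not a claimed reproduction.
* **Per-cell activity** (`cellActivity`, `compareActivity`): active-frame
  counts and fractions per condition; both are reported because "cellular
  activity" can mean either. Cross-condition comparison uses two-sample
  Kolmogorov–Smirnov tests against control and a Friedman rank test across
  the paired per-cell triplets.

## Nonparametric tests

`mannWhitneyU()`, `ksTwoSample()` and `friedmanTest()` are implemented with
exact small-sample behaviour: for pooled sizes ≤ 12 (Mann–Whitney) or ≤ 10
(KS), p-values come from exhaustive enumeration of every assignment of the
pooled sample — midranks make the enumeration valid under ties — and are
checkable against brute force to machine precision. Above the cutoff,
Mann–Whitney uses the normal approximation with tie correction and
continuity correction, and KS the asymptotic Kolmogorov distribution.
Two-sided p-values are the doubled smaller tail, capped at 1. The Friedman
statistic uses within-subject ranks with the standard tie correction; the
all-tied degenerate case is reported as statistic 0, p = 1. Sidedness is
two-sided throughout, the conventional default when not otherwise stated.
No multiple-testing correction is applied anywhere, matching the source
analysis conventions.

## Numerical and testing choices

* Problem sizes in the test-suite simulations (10-min epochs at 5 kHz,
  20-seed recovery batches, 200-replicate type-I batches at 20 × 1,000)
  were chosen to give 3σ-separated expectations at a few minutes of compute;
  the package functions themselves have no size limits.
* Rate-ratio recovery is evaluated with `drugAmpRatio = 1` so that detection
  recall is identical across epochs and the recovered percent increase
  isolates the *rate* effect; with amplitudes also scaled, the lognormal
  lower tail crosses the detection threshold more often in control than in
  drug, inflating the ratio by a few percent.
* Tolerances follow the generating process: Poisson counts are checked to
  3σ bands, binomial rates to 3 binomial σ, enumerated p-values to 1e-12.
* Degenerate inputs are errors, not silent results: empty samples, control
  means of zero, F0 ≤ 0, unlabeled frames, protocols without a control
  epoch ahead of the drug epoch.

## Known limitations

* Burst detection is greedy and non-overlapping; a different tie-break could
  split long clusters differently (spans are constrained to 50–150 ms).
* The maximal-effect window inherits the positive selection bias of any
  max-over-windows statistic (a few percent under these conditions).
* ROI extraction assumes circular, non-overlapping, active somata; it is not
  a general segmentation method.
* The calcium transient detector reports onsets, not spike counts; merged
  doublets are counted once.
* At 4 frames/s the raster's notion of "simultaneous" is a 250 ms bin; the
  Monte Carlo threshold inherits that resolution.
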