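---
title: "Dose-response analysis of FUS-evoked afferent activity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response analysis of FUS-evoked afferent activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusafferent)
```

This vignette documents the scientific model behind `fusafferent`, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical and design choices made where
the analysis left genuine freedom.

## The measurement model

A teased-fiber preparation records extracellular voltage (µV, digitized at
20 or 40 kHz) from one or a few afferent fibers while their receptive field
(RF) in the skin, or the nerve trunk (NT) directly, is stimulated. Three
stimulus modalities matter here:

* **FUS**: millisecond bursts of 3.57 MHz focused ultrasound, parameterized
  by intensity (11–743 W/cm²) and duration (0.1–2.0 ms), delivered at a 5 s
  interstimulus interval. Each parameter set is presented 4–10 times.
* **Electrical**: suprathreshold pulses that fire the fiber
  deterministically; used to measure conduction velocity and as the latency
  reference.
* **Mechanical**: calibrated von Frey filaments (ascending forces) and
  sustained 5 s indentations (adaptation typing).

Responses are one-to-one: a stimulus evokes at most one spike. The
per-parameter-set **action-potential probability** is therefore an exact
binomial fraction, and everything downstream — dose-response fits,
thresholds, population profiles — is built from those fractions.

### Sonication energy

Stimulus magnitude is collapsed to one axis, the sonication energy
$E = I \pi r^2 t$ (intensity × focal cross-sectional area × duration),
reported in nJ. The focal radius $r$ defaults to 0.0165 cm (half a 0.33 mm
focal full-width-at-half-maximum) but is deliberately an explicit,
always-visible instrument parameter: reported energies are proportional to
$r^2$, and the effective focal area of a given transducer/coupling-cone
assembly is the least certain number in the chain. Two labs quoting
energies from the same intensities and durations can disagree by orders of
magnitude purely through this area term, so `fusafferent` never hides it.

### The stimulus-response law

Probability over log-energy is modeled with a three-parameter logistic,

$$y(x) = \frac{a}{1 + 10^{(\log_{10} b - x)\,c}}, \qquad x = \log_{10} E,$$

with plateau $a \in (0, 1]$ (`Max_AP`), half-plateau dose $b$ (`EC50`) and
slope $c > 0$. Two derived quantities:

* `E50%Prob` solves $y = 0.5$ in closed form,
  $10^{\log_{10} b - \log_{10}(2a-1)/c}$ — defined only when $a > 0.5$,
  equal to $b$ exactly when $a = 1$ and strictly larger otherwise.
* `E50%Respond` is the same absolute-0.5 point applied to a fitted
  *cumulative population* profile: fraction of fibers (insensitive fibers
  included in the denominator) whose threshold falls at or below each
  stimulus magnitude.

### Thresholds

All thresholds use one rule: the first stimulus magnitude, in ascending
order, that evoked spikes in **strictly more than half** of its
presentations. With 4 presentations, 2/4 fails and 3/4 passes. The same
strictness applies to von Frey series and FUS energy ladders; it is
implemented once and tested against brute-force scans.

## Spike sorting

The sorter is single-electrode template matching:

1. **Detection.** Positive peaks above $k = 5$ robust noise SDs
   (1.4826×MAD), separated by a 1 ms refractory interval, cut into windows
   of 2 ms (A-fibers) / 4 ms (C-fibers) centered on the peak.
2. **Features.** Five per snippet — positive and negative peak amplitude,
   10%-to-peak rise time, positive-lobe width at half maximum, and
   negative-peak decay time back to 10% — with linear interpolation at the
   threshold crossings, giving sub-sample timing resolution.
3. **Template.** Pointwise mean of all candidates; one correlation-filter
   pass; the template is re-averaged from the accepted set and the filter
   applied once more (a single iteration, for determinism).
4. **Acceptance.** Pearson correlation with the template strictly above
   0.97 (A) / 0.85 (C).

Three implementation details make the fixed floors workable at realistic
noise, and they are the sorter's load-bearing design choices:

* **Active-extent restriction.** The correlation is computed only over the
  template's active extent — the contiguous span where the template rises
  above max(2% of its peak, 4× the noise floor estimated from the window
  margins). A 2 ms window is mostly flat baseline; at a signal-to-noise
  ratio of 10 the correlation of a *genuine* spike over the full window
  tops out near 0.94, below the A-fiber floor, because the baseline
  contributes pure noise variance. Restricting to the spike's support
  recovers the discriminative comparison the floor presumes.
* **Band-limiting.** Both template and snippet are smoothed with a 5-sample
  moving average (~4 kHz at 20 kHz sampling) before correlating. Broadband
  noise is suppressed; the spike's spectral content is barely touched.
  Feature extraction always uses the raw snippet.
* **Fixed extent across the re-filter.** The extent is estimated from the
  initial (all-candidate) template and *reused* when the re-averaged
  template is applied. Re-estimating it from a template built from
  filter-accepted snippets is subtly unstable: acceptance correlates with
  the noise realization, the accepted snippets' noise imprints on the new
  template, and its apparent extent widens into baseline, diluting
  correlations unpredictably.

Snippets are aligned to the template at the best integer shift within ±2
samples before scoring, since a peak falling between samples otherwise
costs several correlation points.

For recordings with two interleaved units (a large fast unit and a smaller
slower one on the same strand), the all-candidate mean is a blend of both
shapes and cannot seed either unit; `sort_unit()` accepts an explicit
starting template per unit for this case, mirroring the experimenter's
choice of exemplar spikes.

Each stimulus is assigned at most one accepted spike within its response
window (50 ms A / 200 ms C after onset, covering conduction delays over
~20 mm nerve lengths at each group's velocity range); accepted spikes
assigned to no stimulus are reported as spontaneous.

## Afferent classification

Five classes over conduction velocity (CV = electrode distance / peak
latency; mm/ms ≡ m/s), hair responsiveness and adaptation:

| class | CV (m/s) | criteria |
|---|---|---|
| C | < 1 | any flags |
| DH | 1–10 | responds to zigzag hair movement |
| AM | 1–10 | hair-insensitive, slowly adapting |
| AbRA | > 10 | rapidly adapting, not hair-responsive |
| AbSA | > 10 | slowly adapting, touch-dome/hair-responsive |

Two boundary decisions: the Aδ band is the *closed* interval [1, 10] (its
explicit interval wins over the fuzzy "greater than about 10" of the Aβ
description, so CV = 10 exactly is Aδ), and an Aδ-band, hair-insensitive
fiber with *unknown* adaptation is labeled AM with a low-confidence flag
rather than left unclassified — the label the physiology makes most likely,
flagged honestly. The rapid/slow adaptation call uses a 200 ms dynamic-phase
window at step onset and offset; no published value exists for this window,
and 200 ms comfortably contains onset/offset bursts at these firing rates.

## The synthetic-data generator

The generator's purpose is recoverable ground truth: every downstream stage
is tested by simulating data whose true parameters are known, running the
full chain, and comparing.

**What it emulates.** (a) Class-specific biphasic spike waveforms —
difference of two asymmetric-Gaussian lobes *parameterized directly by the
five sorting features*, so noise-free feature extraction inverts the
construction exactly; (b) additive white Gaussian recording noise (default
SD 8 µV ≈ SNR 10 against the 80 µV A-fiber positive peak); (c)
conduction-delay latencies (distance/CV) plus Gaussian jitter (0.05 ms A /
0.2 ms C); (d) a fixed extra FUS transduction delay (default 0.9 ms, the
mechanotransduction timescale); (e) Bernoulli single-spike responses drawn
from each fiber's ground-truth logistic law in sonication energy; (f) a
knockout arm as a paired counterpart cohort with the energy law
right-shifted ×3, mechanical thresholds ×14, and a 20% chance of total FUS
insensitivity per fiber; (g) nerve-trunk stimulation as the same law with
b multiplied ×4 (control) / ×1.8 (knockout) — thresholds at the trunk
exceed those at the receptive field, as a ratio rather than a mechanistic
model; (h) distractor spikes from a neighboring unit at Poisson times with
all three waveform time constants widened ×1.3, to exercise the correlation
filter; (i) an optional linear high-energy failure ramp for non-monotonic
(band-pass) energy tuning — the shape of real suppression is unknown, so
this ramp is an acknowledged invention, off by default.

**What it does not emulate.** Acoustic field physics, electrode drift,
bursting or spontaneous background firing, waveform nonstationarity,
overlapping spikes, non-Gaussian noise, or any dependence of spike shape on
stimulus modality. Passing tests therefore demonstrate correctness of the
*analysis* under the stated statistical assumptions — they do not
demonstrate robustness to every pathology of real recordings.

**Energy scale.** Class EC50 defaults (2.0e4 nJ for D-hair up to 1.1e5 nJ
for AM, ordering: D-hair most sensitive, AM least, low-threshold
mechanoreceptor plateaus above nociceptor plateaus) are expressed on the
energy axis the default 0.0165 cm focal radius actually delivers, so the
default protocol grid (~1e3–1.3e6 nJ) straddles them and dose-response
structure is recoverable. This is a direct consequence of making the focal
radius explicit: EC50 values quoted on a different effective-area
convention must be rescaled by the area ratio before comparison, and the
fit itself is unit-invariant up to exactly that rescaling of b (a tested
property).

All randomness flows through explicit seeds; cohorts, sessions and whole
pipeline runs are bit-reproducible (manifest checksums are tested).

## Numerical choices

* **Fitting.** Bounded Levenberg–Marquardt least squares on parameters
  $(a, \log_{10} b, c)$ with $a \in (0, 1]$, $b, c > 0$; tolerances 1e-10.
  Initialization: $a_0$ = max observed probability, $b_0$ = dose at the
  first crossing of $a_0/2$ (linear interpolation), $c_0 = 1$; three
  perturbed starts ($b_0 \times 3$, $b_0/3$ with halved/doubled slopes, and
  a lowered plateau) guard against local minima; the lowest-SSE solution
  wins. Fits are unweighted by default; per-point weights (e.g. number of
  presentations) are exposed but off, since whether the original analysis
  weighted by repeats is unknowable from the text.
* **Aggregate fits** pool the *mean probability per sampled energy* across
  fibers (not all fiber-level points), matching the display convention of
  aggregate dose-response data; parameter sets delivered to fewer than two
  fibers are dropped before aggregation.
* **Surface interpolation.** The (duration, intensity) → probability
  surface is interpolated linearly on a Delaunay triangulation
  (Bowyer–Watson, coordinates normalized to the unit square first) onto a
  101×101 grid, with no extrapolation outside the convex hull and values
  clamped to [0, 1]. The triangulation is implemented in the package and
  tested against single-triangle analytic cases and node-conservation
  properties.
* **Cumulative profiles** are evaluated on a dense log-spaced grid spanning
  the tested energies (60–80 points) rather than only at the measured
  thresholds: the empirical step function then constrains all three
  logistic parameters instead of a handful of quantized steps.
* **Exact tests.** Fisher's two-sided 2×2 p-value uses the
  point-probability rule (sum of all same-margin tables whose
  hypergeometric probability does not exceed the observed one, with a
  1+1e-7 relative guard against floating-point ties). The signed-rank test
  drops zero differences, average-ranks ties, and enumerates the null
  exactly by dynamic programming over doubled ranks for n ≤ 25 (normal
  approximation with tie correction above). Spearman's rho is the Pearson
  correlation of average ranks with the t approximation for p. Normality
  checking uses the Kolmogorov–Smirnov statistic against the
  sample-estimated normal with a seeded Monte-Carlo null (parameters
  re-estimated per resample), i.e. a simulation-calibrated Lilliefors test
  — the table-based small-sample approximation is replaced by simulation by
  design.
* **Degenerate inputs.** All-zero probability curves are flagged
  insensitive, never fitted; constant samples fail normality with p ≈ 0;
  zero-variance snippets and templates are rejected with reason codes;
  unsorted threshold tables are sorted with a warning, unsorted von Frey
  series are an error (ascending presentation is part of the protocol).

## Session container

Sessions are stored as a directory: each trace as raw little-endian float64
samples with a JSON header (rate, t0, length, units), plus diff-able JSON
sidecars for events, fibers, instrument and provenance. Metadata round-trips
bit-exactly and traces exactly; writing the same session twice is
byte-identical. A hierarchical single-file layout would serve equally well;
the directory layout was chosen so that event/fiber tables remain plain,
reviewable text.

## Problem sizes in the test suite

The suite exercises the chain at deliberately moderate scale: the sorting
benchmark uses one SNR-10 A-fiber with 200 stimuli and Poisson distractors;
parameter recovery uses 150 fibers × 8 energies × 10 repeats (counts drawn
directly from the law); the latency study 12 fibers through full trace
simulation and sorting; the knockout comparison 80 fibers per arm on a
24-step energy ladder. These sizes give the estimators enough data to meet
their stated tolerances while keeping the whole suite fast.

## Known limitations

* The absolute-0.5 definition of `E50%Respond` interacts with unequal
  responsive fractions: when one arm has a lower cumulative plateau (e.g.
  20% of knockout fibers never respond), its absolute-0.5 crossing shifts
  right *beyond* the pure threshold shift, so the fitted
  knockout-to-control ratio systematically overshoots the ground-truth b
  multiplier by ~10–20%. This is a property of the definition, not a bug;
  comparisons across arms with very different responsive fractions should
  report the responsive fraction alongside `E50%Respond`.
* The correlation floor at SNR well below 10 rejects an increasing share of
  genuine spikes (the floor is fixed; the separation between genuine and
  distractor correlations narrows). The sorter reports all scores, so
  marginal units can be audited.
* The single-electrode template matcher does not resolve overlapping spikes
  and needs an explicit template per unit when more than one unit is
  present.
* `detect_nonmonotonic` implements a peak-versus-last-probability margin
  rule (default 0.25); real suppression at high energy has no established
  quantitative shape, and the generator's failure ramp is likewise a
  convenience, so band-pass tuning results should be treated as flags for
  inspection, not measurements.
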