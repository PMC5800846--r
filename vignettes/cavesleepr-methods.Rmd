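---
title: "Scoring sleep from locomotor tracking: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring sleep from locomotor tracking: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavesleepr)
```

# The problem

Adult *Astyanax mexicanus* exists as a river-dwelling surface morph and
several cave-adapted populations (e.g. Pachón) that have lost most of their
sleep. Sleep in adult fish is scored behaviorally: an animal is asleep when
it has been immobile for 60 s or more, a criterion validated against arousal
thresholds. The quantities of interest are total sleep per 24 h, the
architecture of that sleep (how many bouts, how long each), waking swimming
activity, and how these respond to interventions — orexin/hypocretin
receptor antagonists, starvation, lateral-line ablation — in a
population-by-treatment factorial design. Alongside behavior, hypocretin
(HCRT) signaling is quantified two ways: relative *hcrt* transcript
abundance by qPCR (ΔΔCt against *gapdh*), and HCRT-positive somata counted
and measured in confocal z-stacks of the hypothalamus.

This package implements that entire analysis chain as testable code, plus a
synthetic-data generator with known ground truth so that every stage can be
validated by parameter recovery rather than by eye.

# Sleep scoring model

The chain from raw tracking to metrics is:

1. **Speed.** Per-frame speed is the Euclidean displacement between
   consecutive resolved frames divided by the inter-frame interval,
   assigned to the later frame, then smoothed by a rolling median.
2. **Immobility.** A frame is immobile when its smoothed speed is strictly
   below `speed_threshold`. Frames with no speed value (the first frame,
   unresolved gaps) inherit the previous call.
3. **Bouts.** Mobile runs shorter than `min_interrupt_s` flanked by
   immobility on both sides are absorbed; maximal immobile runs of at least
   `min_sleep_s` become sleep; everything else is wake. Intervals are
   frame-edge aligned and half-open, so sleep plus wake always partitions
   the recording exactly.
4. **Metrics.** Total sleep, bout count and mean duration, waking activity
   (time-weighted mean speed over wake intervals only — the control that
   distinguishes more sleep from lethargy), and a binned 24-h profile in
   zeitgeber time (lights on = ZT0–14, dark = ZT14–24, half-open).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_sleep_s` | 60 | s | the arousal-threshold-validated sleep criterion; the one parameter fixed by the biology |
| `speed_threshold` | 4 | mm/s | not fixed by the sleep definition; ~0.1 body length/s for adult fish. Logged in every provenance record; results should be (and in our tests are) monotone in it |
| `smooth_window_s` | 1 | s | suppresses single-frame tracker jitter at 15 Hz without hiding real swimming |
| `min_interrupt_s` | 1 | s | one noisy frame should not split a sleep bout; 0 recovers the strictest reading |
| `max_gap_s` | 1 | s | tracking dropouts up to 1 s are linearly interpolated; longer gaps carry no speed and inherit immobility calls |

Conventions chosen for bit-reproducibility rather than because alternatives
are wrong: strict inequality at the speed threshold; half-open intervals
everywhere; bouts straddling a window contribute their overlap to totals
and profiles but are counted (with their full duration) where their
midpoint falls; mean bout duration is reported as missing when no bout is
counted.

# Statistics layer

Baseline two-group comparisons are the classical pooled-variance unpaired
t-test or the Wilcoxon rank-sum test with normal approximation and tie
correction ("non-parametric t-test" in the field's shorthand). Factorial
questions use a two-way fixed-effects ANOVA of metric on population,
treatment and their interaction; with unbalanced cells each effect is
tested adjusted for all others (partial, Type-III-style sums of squares
with sum-to-zero contrasts), which reduces to the textbook decomposition
for balanced data — the convention of the commercial packages this analysis
is normally run in. Families of follow-up comparisons are corrected by the
step-down Holm-Sidak procedure, implemented directly:
sorted ascending, `1 - (1 - p_(i))^(m - i + 1)`, cumulative maximum, cap
at 1. The comparison family is always an explicit argument — the package
never infers which contrasts a figure intended. OLS regression (e.g. sleep
on number of silenced HCRT neurons) reports slope, R², and the two-sided
slope p.

# Expression quantification

Technical replicates are averaged per sample, run and gene (replicate SD
above 0.5 cycles flags a sample, and never silently drops it). Runs sharing
a calibrator sample are aligned by per-gene additive Ct offsets so the
calibrator reads identically everywhere (offsets are reported). Relative
expression is `2^(-ΔΔCt)` at 100% amplification efficiency (base
`1 + efficiency` otherwise), anchored so the calibrator group's
geometric-mean fold is exactly 1. Anchoring on the group mean ΔCt — an
arithmetic mean in Ct space, hence geometric in fold space — is the choice
that makes "normalized to one relative to surface controls" exact. Which
group anchors the scale is deliberately a required argument: anchoring each
morph to its own control answers a different question than anchoring
everything to surface controls.

# Cell quantification

Stacks imaged at 2 µm z-steps are merged by maximum projection. The study
drew per-cell ROIs by hand; this package substitutes an automated detector
with every parameter exposed, and a label-mask import path so manual ROIs
can be reused unchanged. Detection thresholds at background median plus
`threshold_k` robust SDs, where the background level is the median of the
dimmer half of the image and the spread is the scaled MAD of the whole
image (somata are sparse, so the MAD is a background statistic). Connected
components (8-connectivity) within an area band become cells; a component
carrying two or more prominent local maxima separated by more than
`min_separation` pixels is split by nearest-maximum assignment. Per-cell
fluorescence is reported both as mean and as integrated
background-subtracted intensity, since figure-level "intensity per cell"
does not pin down which.

One numerical subtlety is worth stating: on a maximum projection of an
n-slice noisy stack, background pixels are inflated by the maximum of n
noise draws while soma pixels are dominated by their single brightest
slice. A background level estimated from the projection therefore
over-subtracts from somata. When the stack is available, the median of the
full stack is the right background for projection quantification; the
pipeline does this, and it is why per-cell intensities recover generator
truth within 5% in our tests. ROI dilation was considered for recovering
the sub-threshold Gaussian tail (~2% of the integral) and rejected:
clipping noise-inflated ring pixels at zero overshoots by more than the
tail recovers.

# The synthetic-data generator

`simulate_activity()` is a two-state semi-Markov model: wake and rest bouts
alternate with exponentially distributed durations (truncated at one
frame); while awake the fish swims with gamma frame speeds and a smoothly
drifting heading inside a reflecting arena; at rest it jitters around an
anchor with Gaussian positional noise. A rest bout of 60 s or more is the
generator's ground-truth sleep. Exponential durations are the minimal
(memoryless) model — the study publishes only summary metrics, not bout
distributions, so anything richer would be invented; the parameters are
plausibility anchors for testing, never estimates of real fish.

Preset parameter sets encode the study's qualitative phenotypes: surface
controls rest ~45% of the day in mostly long bouts; cavefish controls rest
under 10% in short fragments; the antagonist rescues cavefish sleep through
both longer rest bouts and shorter wake bouts (bout number and duration
both rise); starvation and lateral-line ablation act like the antagonist in
cavefish only; surface fish are left essentially unchanged by the
antagonist. What the generator deliberately does not emulate: circadian
modulation of bout structure within the day, thigmotaxis and wall-following
geometry, tracker artifacts other than missing frames, and any coupling
between behavior and the qPCR/imaging channels. Passing recovery tests
therefore shows the scoring and statistics are correct on data obeying the
stated bout model — not that 4 mm/s is the right threshold for a given rig,
which remains a per-rig calibration decision.

`simulate_qpcr()` plants group ΔCt shifts (e.g. `-log2(3)` for the
three-fold *hcrt* elevation of cavefish), replicate noise, and additive
per-run offsets recovered by the calibration step. `simulate_stack()`
plants Gaussian-profile somata (in-plane σ = radius/2, centers on the
z-grid) with rejection-sampled positions honoring a minimum separation,
plus Gaussian noise — the high-count approximation to Poisson shot noise.

# Validation strategy and problem sizes

Every operation with a closed-form or enumerable answer is tested against
an independent oracle written for the test: a frame-by-frame bout
enumerator, textbook balanced ANOVA sums of squares from cell means, the
Holm-Sidak formula evaluated directly, normal-equation regression. The
property suite checks partition conservation, monotonicity of total sleep
in `speed_threshold` (up) and `min_sleep_s` (down), ΔΔCt invariance to
per-gene Ct shifts, projection idempotence and slice-order invariance, and
full determinism of all generators under `(params, seed)`.

The simulation sizes are the package's own choices, made once: bout-oracle
equivalence on 1,000 random series of up to 10⁴ frames; scorer-vs-truth
recovery on 50 seeded 24-h recordings for each of the three distinct preset
parameter sets (the starvation and ablation presets share parameters with
the antagonist/control sets and add no new conditions); two-group
discrimination on 200 replicate cohorts of 12 fish per group at 1-h
recordings; ANOVA size under the null on 2,000 replicates at 12 per cell;
and the end-to-end factorial pattern on 100 seeded 2 × 2 cohorts of 12 per
cell at 2-h recordings. Group differences here live in bout structure, so
shorter windows at the full 15 Hz leave the preset group separations far
larger than the between-fish spread while keeping the whole suite fast;
24-h windows are
used exactly where absolute daily totals are the question.

# Known limitations

* The tracker-export adapter is modeled on generic delimited exports; it
  has not been validated against any specific commercial export version.
* "Waking activity" averages over all wake intervals; if the original
  analysis averaged only sustained swimming, values will differ slightly.
* Automated soma detection is a stand-in for manual ROIs; for faithful
  reproduction of hand-drawn analyses, import the label masks.
* Cell counts are reported per stack; aggregation across serial sections of
  one brain is left to the manifest, since per-brain tallying conventions
  vary.
* The unbalanced-ANOVA convention (partial SS, sum-to-zero contrasts) is
  one of several defensible choices; balanced designs are unaffected.
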