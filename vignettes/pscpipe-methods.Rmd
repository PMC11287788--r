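---
title: "Methods: models, algorithms and design choices in pscpipe"
author: "pscpipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, algorithms and design choices in pscpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pscpipe)
```

pscpipe implements the quantitative stages of a crossed stress-physiology
design in female mice: early-life limited bedding and nesting (LBN) versus
standard rearing (STD), crossed with an adult acute layered psychosocial
stress (ALPS) versus control (CON), giving four groups (STD-CON, STD-ALPS,
LBN-CON, LBN-ALPS). The measured endpoints are GABAergic postsynaptic
currents (PSCs) in voltage-clamped GnRH neurons around the expected time of
the preovulatory LH surge, serum LH and corticosterone time courses, and
daily estrous-cycle stages. Because raw recordings and hormone tables from
such experiments are rarely shareable at desk scale, every stage is paired
with a synthetic-data generator that carries ground truth, so the whole
pipeline is testable end to end.

## Synthetic data model

**Traces.** A recording is modelled as a holding-current baseline plus a
homogeneous Poisson event train convolved with a peak-normalized
difference-of-exponentials kinetic template,

$$w(t) = \left(1 - e^{-t/\tau_r}\right) e^{-t/\tau_d},$$

scaled per event by a log-normal amplitude, plus white Gaussian noise.
Overlapping events superpose linearly — the simplest physically plausible
model for summating synaptic conductances. Events are simulated as
positive-going excursions and amplitudes are reported as absolute values,
matching the amplitude definition used throughout (peak minus baseline,
absolute value). The template peaks at
$t^\* = \tau_r \log(1 + \tau_d/\tau_r)$ after onset; ground truth stores
both the Poisson onset and the analytic peak time, since detectors localize
peaks, not onsets.

Defaults are chosen to be *plausible* for GABAergic PSCs in GnRH neurons
rather than calibrated to any particular dataset (no empirical amplitude or
interval distributions are available to calibrate against): 240 s records
at 10 kHz, rates of order 0.1–2 Hz (default 0.5 Hz), amplitudes ~10–50 pA
(log-normal, mean 30 pA, CV 0.4), $\tau_r = 1$ ms, $\tau_d = 15$ ms, noise
SD 3 pA, baseline −20 pA at −65 mV. An optional zero-phase Butterworth
low-pass stands in for the acquisition filter; it is off by default because
a 5 kHz cutoff equals the Nyquist frequency at 10 kHz sampling, where the
filter is a no-op.

**Hormones.** LH profiles give each animal one proestrus-morning (AM)
sample and six afternoon/evening (PM) samples. Surge expression is
Bernoulli per animal; surging animals receive a log-normal peak (median
15 ng/ml) in a random PM slot with adjacent slots at 50%/25% of the peak,
non-surgers stay at the truncated-normal AM baseline (mean 0.8, SD
0.4 ng/ml). All values are censored to the ultrasensitive-assay reportable
range of 0.16–40 ng/ml with flags. Corticosterone is log-normal on the
log10 scale with group baseline (geometric mean 30 ng/ml pre-stress),
post/pre fold changes (defaults 2.9 for CON, 9 for ALPS, consistent with
the relative magnitudes reported for this paradigm), dam and mouse random
intercepts (SD 0.10 log10 units each) and residual noise (SD 0.15),
censored to the EIA range 3.9–1,000 ng/ml.

**Cycles.** Stage sequences over diestrus/proestrus/estrus come from a
first-order Markov chain whose default leaves diestrus with probability
0.4/day and steps P→E→D deterministically, giving a mean cycle length of
$2 + 1/0.4 = 4.5$ d — the typical 4–5 d mouse cycle. Because a memoryless
chain cannot produce patterns like D,D,P,E *deterministically*, the
transition law may alternatively be given as a literal stage pattern that
is repeated verbatim; this is also what makes exact-pattern tests possible.

What the generators deliberately do **not** emulate: correlated or bursty
event trains, rundown and drift, seal instability, multi-exponential decay
mixtures, assay plate effects, and stage-misclassification noise. Passing
tests therefore demonstrate algorithmic correctness under the stated model,
not robustness to every pathology of real recordings.

## PSC detection

Interactive event curation is replaced by a deterministic, parameterized
procedure:

1. boxcar-smooth the trace (9 points by default, the classic "Box 9");
2. form a rise detector as the difference of the smoothed trace across one
   smoothing window (non-overlapping averages, so a rising edge is not
   diluted into single-sample increments);
3. estimate the noise scale of that detector robustly via the SD-scaled
   median absolute deviation, and mark onsets where it crosses
   `threshold_mads` (default 4) noise SDs;
4. climb from each onset to the local maximum, tolerating noise dips
   shorter than 1 ms; merge peaks closer than 5 ms, keeping the larger;
5. take the baseline as the median of the 10 ms pre-onset window and the
   amplitude as |peak − baseline|;
6. apply two plausibility filters in place of manual confirmation: the
   amplitude must exceed `threshold_mads` × the raw-noise SD (estimated
   from first differences), and the trace must return at least halfway to
   baseline within 150 ms of the peak.

On 60 s synthetic traces with amplitude ≥ 5× the noise SD this recovers
events with precision and recall ≥ 0.9 at ±2 ms peak matching (see the
acceptance suite). The procedure is a documented surrogate for rig-specific
custom detection code, not a reproduction of any particular lab's criteria.

Passive properties come from averaged small hyperpolarizing membrane-test
steps (defaults: 16 × 5 mV, 20 ms at 100 kHz): series resistance from the
peak capacitive transient ($R_s = \Delta V / I_{peak}$), input resistance
from the steady-state deflection ($R_{in} = \Delta V / I_{ss}$, Ohm's law),
capacitance as the transient charge above steady state divided by the step
($C = \int (I - I_{ss})\,dt / \Delta V$ — robust to biexponential
transients), and holding current as the pre-step mean. Deflection
magnitudes are used throughout, so the step sign is irrelevant. For
$R_s = 20$ MΩ against $R_{in} = 1$ GΩ the charge method understates $C$ by
$(R_{in}/(R_s+R_{in}))^2 \approx 4\%$, within the 5% recovery target.

## Event metrics

The per-cell summaries follow the field's definitions exactly:

* **frequency** = event count / recording duration, with zero events a
  meaningful zero;
* **interevent interval** = backward interval between an event's peak and
  the previous peak; the first event's interval is unknown and excluded,
  so $n$ events give $n-1$ intervals;
* **amplitude eligibility**: events qualify when the backward interval is
  **at least** 200 ms (inclusive); a first event qualifies when preceded by
  **more than** 200 ms of recording. The asymmetry between the inclusive
  amplitude rule and the strict isolation rule below is preserved
  deliberately rather than harmonized;
* **isolated events** have gaps **strictly greater** than 200 ms to the
  adjacent peaks in both directions; the first/last events use the gap to
  the recording boundaries, symmetric with the first-event amplitude rule.
  Isolated snippets are peak-aligned, averaged, and normalized per cell
  (normalize-then-average across cells is the package's convention when a
  group-level waveform is wanted);
* **80–20% decay time**: time between the first post-peak crossings of 80%
  and 20% of the peak, linearly interpolated between samples — hence
  resolution-independent and equal to $\tau \ln 4$ for a mono-exponential
  decay, the closed form the tests pin down to 1%.

Numerical details: the inclusive 200 ms comparison carries 1 ns of slack so
that binary rounding of peak times cannot flip a boundary case; waveform
snippets that would leave the record are dropped from the average; a cell
whose average waveform never reaches 20% of peak reports `NA` decay rather
than an error inside the pipeline.

## Group comparison

**Anderson–Darling k-sample test.** The criterion is computed from its
defining double sum with midrank tie handling, standardized by the exact
null SD, and referred to interpolated tabulated quantiles
($t_m(\alpha) = b_0 + b_1/\sqrt{m} + b_2/m$, $m = k-1$, seven tabulated
$\alpha$ levels from 0.25 to 0.001; log α is interpolated in $t$ with a
natural spline and extended linearly outside the table). A permutation
option replaces the asymptotic p for very small samples. The statistic is
rank-based, hence invariant under strictly increasing transforms; the
tests verify the statistic against an independent loop-written evaluation
of the defining sum and the asymptotic p against 10,000-permutation p
within 0.02, and its null size at α = 0.05 stays within [0.03, 0.07] over
1,000 simulations.

Post hoc comparisons run exactly the four prespecified pairs —
within-rearing stress effects and within-treatment rearing effects — with
Holm's step-down adjustment over the family of four. Confidence intervals
are reported unadjusted for multiplicity (a Bonferroni option would be the
conservative alternative).

**Hierarchical bootstrap.** Events within a cell are dependent, so the
default resampling unit is the **cell**: each of 5,000 iterations resamples
cells with replacement within each group, pools their events, and records
group means and the prespecified pairwise differences; point estimates are
iteration averages and 95% intervals are the 2.5th/97.5th empirical
percentiles (linear-interpolation quantiles, stable across iteration
counts). The unit is configurable (`mouse`, `event`) because published
descriptions of design-aware bootstraps often leave the unit ambiguous —
with `event` (or one event per unit) the procedure reduces exactly to the
ordinary nonparametric bootstrap, which the tests check. Coverage of the
difference CI on two-group Gaussian data (30 cells/group, 1,000 iterations)
sits in the 93–97% band over 500 simulated datasets.

## Endocrine scoring

The LH surge rule is a strict threshold exceedance: surged if any PM value
is > 3.8 ng/ml, the packaged study constant derived as mean + 3 sample SD
of proestrus-morning values ("any PM value" wordings with ≥ appear in some
descriptions of this rule; the package standardizes on strict >, so
boundary equality is not a surge). `surge_threshold()` always recomputes
mean + 3 SD from supplied AM data; sample SD is used since the population
variant is indistinguishable at realistic n and unstated in the source
conventions. Values censored at the 40 ng/ml assay maximum exceed any
threshold below 40 and therefore count as surges.

Cycle metrics per 21 d window: cycles are days in proestrus preceded by
diestrus or estrus; cycle length is measured between **first days** of
successive proestrous runs (the deterministic convention when a run spans
several days); stage percentages are over all monitored days and always
sum to 100.

Effect-size reconstructions from printed summaries use
$t = (\bar x_1 - \bar x_2)/\sqrt{SEM_1^2 + SEM_2^2}$ with $df = n_1+n_2-2$,
and Cohen's $d$ with SDs recovered as $SEM\sqrt{n}$ and pooled with $n-1$
weights. The familiar identity $t = d/\sqrt{1/n_1 + 1/n_2}$ is exact when
the two group SDs are equal (the pooled-variance case) and only approximate
otherwise; the tests verify it in the equal-SD case. Validation against
printed values uses ±0.02 tolerance because printed inputs are rounded to
1–2 decimals; worked numbers whose printed precision cannot support that
tolerance (e.g. a contrast with |t| ≈ 160 behind a 2-significant-digit SEM,
or ratio-scale contrasts that cannot be reconstructed by linear division)
are excluded from `validate_printed_examples()`.

## Pipeline and reproducibility

`run_pipeline()` composes simulate → detect → summarize → compare → score.
All randomness flows from one master seed through a deterministic
per-stage derivation, so identical configurations reproduce byte-identical
reports and CSVs; the seed and full configuration are echoed into every
report. Stage boundaries log record counts, and zero-event cells are
logged, kept for frequency (as zeros) and excluded from interval
statistics rather than silently dropped. The package is a library rather
than a shell tool: the exported stage functions are the subcommands, and
YAML round-trips (`write_cohort_spec()`, `study_constants()`) carry the
configuration and scoring constants.

Default synthetic-study scale — six recorded mice per group with 2–3 cells
each (~15 cells/group) and 240 s traces — mirrors the cell counts typical
of such experiments. The test suite exercises smaller problem sizes chosen
for statistical sufficiency (20–60 s traces for detection checks; 500
datasets × 1,000 iterations for bootstrap coverage; 1,000 simulations for
the AD null size; 20 null pipeline runs), each asserting the property at
the scale stated in the test.

## Known limitations

* The detector is a single fixed algorithm; real curation pipelines mix
  template matching, deconvolution and human judgment, and the published
  detection criteria behind any given dataset are usually unavailable.
  Agreement with ground truth on the generator's model says nothing about
  rater agreement.
* The asymptotic AD p-value is interpolated (and extrapolated on the logit
  of α outside the tabulated range); p-values far above 0.25 are
  approximate, which matters little since decisions happen near small α.
* The hierarchical bootstrap resamples one level (cell or mouse); full
  multi-level resampling (dam → mouse → cell) is not implemented because
  the group-mean estimand does not require it at the simulated depths.
* Censored hormone values are clipped with flags; no likelihood-based
  treatment of censoring (e.g. Tobit-style models) is attempted, matching
  the binary-outcome strategy used for heavily censored LH data.
* Mixed-model inference (LMM/GLMM families, Kenward–Roger, marginal
  means) is intentionally out of scope; established packages should be
  used on the pipeline's tidy outputs.
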