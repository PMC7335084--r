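---
title: "Methods: MEA spike-train analysis with meaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MEA spike-train analysis with meaflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaflow)
```

meaflow analyzes extracellular recordings of cultured neuronal networks on
multi-electrode arrays (MEAs): planar grids of (typically 60) electrodes,
each picking up the spiking of nearby neurons over a 10-minute epoch. As
cultures mature, activity reorganizes from sporadic single spikes into
*network bursts* — compact volleys of spikes appearing near-simultaneously
on many electrodes — and the degree of cross-electrode synchrony is a key
developmental and pharmacological readout (GABA-A antagonists such as
bicuculline disinhibit the network and intensify coordinated bursting).
This vignette documents the models, parameters and numerical choices behind
each stage.

## The processing chain

Spike tables flow through a fixed cleaning and analysis order:

```
detect_spikes -> detect_heater_events -> purge_heater_spikes ->
filter_low_count_channels -> detect_bursts -> channel/device features
                                           -> device_synchrony
```

The order matters: artifact purging happens before channel QC (a channel's
spike count is assessed after contaminated spikes are gone), and "active
electrodes" — the denominator for synchrony pairs and the numerator of
`% active` — are the channels surviving QC.

## Spike detection

Spikes are negative threshold crossings at $-m \hat\sigma_c$ per channel,
default $m = 4.5$. The noise scale $\hat\sigma_c$ is estimated with the
median absolute deviation scaled to the Gaussian SD,
$\hat\sigma = \mathrm{median}(|v - \mathrm{median}(v)|)/0.6745$: a raw
trace is noise *plus spikes*, and the MAD is nearly insensitive to the
spikes themselves, whereas the plain sample SD (available as
`noise_estimator = "global_sd"`) inflates with activity and so raises the
threshold on exactly the busiest channels. Each sub-threshold excursion
yields one spike at its *trough* (the local minimum), with the trough
voltage as amplitude. Trough timing is jitter-stable; threshold-crossing
times move with noise. Troughs closer than the dead time (1 ms default) are
merged keeping the deeper one, which suppresses double counting of
multiphasic waveforms. Because the threshold is proportional to the noise
estimate, detection is equivariant under trace rescaling.

A Butterworth band-pass (268–8036 Hz, matching the acquisition convention)
is available but off by default: recordings from the supported rigs are
already band-passed in hardware.

## Heater-artifact removal

Stage heaters inject large negative deflections essentially simultaneously
on most electrodes, followed within ~6 ms by decaying afterwaves that naive
thresholding mistakes for spikes. The rule: candidate spikes are detected
spikes with troughs below −200 µV; a 1 ms window sliding over candidate
times flags a *heater event* whenever at least 80% of the device's channels
(boundary inclusive: 48 of 60 qualifies) carry a candidate inside one
window. The window is anchored at candidate spikes rather than stepped
sample-by-sample — identical coverage, far cheaper — and overlapping
qualifying windows coalesce so one physical artifact is one event, timed at
its earliest candidate. Every spike within 6 ms of an event (on any
channel) is then purged.

Two readings of the rule were genuinely open and are configurable:

* **Denominator.** "80% of all channels" is read literally as all
  recordable electrodes (`n_device_channels`, stored per device because
  grounded or broken electrodes vary); `fraction_denominator =
  "channels_with_spikes"` restricts to spike-bearing channels.
* **Purge direction.** Afterwaves trail the event, but the purge window is
  symmetric ±6 ms by default: timestamp jitter between channels makes a
  one-sided window fragile, and the cost of symmetric removal is a handful
  of genuine spikes per event. The boundary is inclusive, with a 1 ns guard
  so decimal timestamps exactly 6 ms away are not saved by floating-point
  representation.

After purging, channels with fewer than 10 spikes are dropped; survivors
are the *active electrodes*.

## Burst detection

Bursts are detected per channel with a five-parameter maximum-interval
rule: a candidate opens where an inter-spike interval (ISI) ≤ 0.1 s,
extends while ISIs ≤ 0.2 s, candidates closer than 0.5 s merge, and
survivors need ≥ 6 spikes and ≥ 0.05 s duration. Merging runs *before*
filtering — the convention associated with exactly this parameter set —
so two sub-threshold candidates separated by 0.4 s can survive as one
burst. During extension of a merged run only the end-ISI bound applies;
the begin-ISI bound is a seeding condition. Burst extent is defined by its
member spikes (start = first, end = last spike). The test suite holds this
implementation to exact agreement with an independently written run-length
reference across a thousand random trains whose ISIs straddle all five
thresholds.

## Features and fold change

Per channel: firing rate (spikes per second over the whole epoch), burst
count and bursts/min, mean burst duration, mean intra-burst ISI (each
burst's mean ISI — its duration over spikes−1 — averaged across bursts),
and the complementary percent of spikes inside/outside bursts. A channel
with no bursts reports *missing* burst features rather than zeros:
inactivity and short bursts are different things, and zeros would drag
device means toward fictitious brevity. Device values are arithmetic means
over channels with defined values, plus `% active electrodes`.

Drug challenges are summarized per device-level feature as the fold change
challenge/baseline (the standard reading of "fold change"; an additive
difference mode is behind a flag). Zero or missing baselines are flagged
undefined rather than reported as infinities, and comparisons across
mismatched burst parameters are refused outright.

## SPIKE-distance synchrony

The SPIKE distance is a time-resolved, parameter-free dissimilarity
between two spike trains. At each instant the profile interpolates, within
each train's current ISI, the distances from the bracketing spikes to the
nearest spike of the other train, weights each train's term by the other's
local ISI, and normalizes by the squared mean ISI; the distance $D$ is the
time average of the profile. $D = 0$ exactly for identical trains; it is
symmetric, nonnegative and invariant under joint rescaling of all times.
Virtual spikes at the epoch edges (0 and $T$) define the profile over the
whole timeline — the standard edge treatment, exposed as `aux_spikes`.

Between consecutive events (the merged spike times of both trains) every
ingredient of the profile is constant, so the profile is linear on each
segment and the integral is evaluated segment-by-segment in closed form.
There is no integration grid and no step-size error; the test suite checks
the closed form against a dense-grid quadrature oracle (10⁻⁴ s step) to
10⁻³ on random Poisson pairs.

Two random trains already look partially "synchronous" to any dissimilarity
measure, so the observed distance is calibrated against a Monte-Carlo null:
`n_random` surrogate pairs (1000 by default) with the same spike counts
$(n_1, n_2)$, drawn as sorted uniform points on the 600 s timeline. The
timeline is fixed at the 10-minute epoch independent of the data span
unless overridden. The published wording of the normalization does not pin
down the arithmetic, so three conventions are computed and reported
side-by-side, with `ratio_of_means` as the default:

* `ratio_of_means`: $1 - D_\mathrm{obs} / \overline{D_\mathrm{rand}}$ —
  chance ≈ 0, identical trains exactly 1;
* `mean_of_ratios`: $1 - \overline{D_\mathrm{obs}/D_\mathrm{rand}}$;
* `unnormalized`: $1 - D_\mathrm{obs}$.

Values slightly below zero (trains farther apart than random) are reported
unclipped by default — they carry information — with an optional clip to
$[0, 1]$. Device synchrony is the arithmetic mean over all unordered pairs
of active electrodes; the aggregation statistic is a choice (the per-device
summary could equally pool profiles), and per-pair diagnostics are always
retained so either can be recovered. Per-pair surrogate seeds are derived
from the channel ids, making the device value independent of channel
ordering.

## Group statistics

Longitudinal comparisons use a two-way ANOVA (culture group × days in
vitro, with interaction) followed by Tukey HSD contrasts on the group
factor; fold changes use a one-way ANOVA with Tukey contrasts and
per-group SEM (SD/√n). α = 0.05. The ANOVA arithmetic is routine and is
delegated to `stats::aov()`/`stats::TukeyHSD()`; the package layer
contributes the table assembly, design checks (empty cells are an explicit
error with guidance, single-device groups are excluded with a warning,
zero-residual fits are flagged degenerate) and tidy output. Devices are
treated as independent across DIV — a plain two-way layout, not repeated
measures, matching how the comparisons are conventionally reported.
Calibration tests guard the wiring: the group-effect type-I error under a
simulated null stays at 0.05 ± 0.02.

## The synthetic-data generator

No public MEA corpus accompanies the analysis conventions this package
implements, so validation rests on a generator that produces data *with
ground truth* exhibiting the structure the pipeline assumes:

* per-channel homogeneous Poisson background (default 0.2 Hz);
* a device-level Poisson process of network-burst events (default 0.1 Hz).
  Each event carries **one** spike pattern — count from a (negative-
  binomial or Poisson) distribution with mean 12, ISIs truncated-
  exponential on [refractory, 0.1 s] with mean 20 ms — shared by every
  participating channel. Channels join an event with probability 0.8 and
  start the pattern at an onset jittered by a 10 ms Gaussian. Sharing the
  pattern is what makes bursting *coordinated*: with zero jitter and full
  participation, channels are exact replicas, and synchrony degrades
  smoothly as jitter grows (a property the tests exploit). The upper ISI
  truncation at 0.1 s keeps ground-truth bursts within the burst
  definition's begin-ISI bound, so parameter-recovery tests can compare
  detected bursts against generator events directly; the lower truncation
  at the refractory period keeps thinning from deflating the configured
  spikes-per-burst distribution.
* a refractory period (2 ms) enforced by keep-first thinning;
* trough amplitudes from a Gaussian (−60 ± 8 µV), so amplitude-based rules
  are exercised;
* optionally, raw-voltage rendering: Gaussian noise (5 µV SD), one biphasic
  template per spike with its trough aligned to the spike time at the
  nearest sample, and heater artifacts — a sub−200 µV deflection on
  ⌈fraction × channels⌉ random channels with damped-oscillation afterwaves
  spanning 6 ms, deliberately large enough to fool naive detection so that
  artifact removal is meaningfully testable. A spike-table-level injector
  (`inject_heater_artifacts()`) provides the same ground truth without
  rendering voltage.

Defaults (12 spike-bearing channels of 60, 10-minute epochs, the rates
above) describe a moderately active bursting culture and are the regime in
which all distributional test expectations were derived. The generator's
rendering runs at 5 kHz by default — the detection logic is rate-agnostic
and the acquisition-grade 22.3 kHz only scales memory and time — and a
drug challenge is modeled as regenerating the epoch with the network-burst
rate multiplied and/or participation shifted, with epoch seeds derived
deterministically from one master seed.

What the generator does *not* emulate: electrode crosstalk and spatial
correlation beyond shared events, waveform variability and overlapping
units (no spike sorting exists downstream to need them), slow drift,
non-stationary rates within an epoch, and biophysical burst shapes.
Passing tests therefore certify the pipeline's arithmetic and its
recovery of the generator's statistical structure — not performance on any
particular laboratory's recordings.

## Numerical choices and scale

* Times are seconds from epoch start, on the closed interval
  [0, duration]; voltages are microvolts everywhere in memory. CSV writers
  print times to 10⁻⁹ s, and reader/writer pairs round-trip to that
  precision.
* Validation-scale problem sizes: test simulations use 4–12 channels and
  60–600 s epochs; the surrogate null is exercised at 100–200 draws in the
  distribution-level tests (the package default stays 1000); oracle
  comparisons run on hundreds of Poisson pairs at T = 60 s. These sizes
  were chosen so the full suite exercises every distributional claim in a
  few minutes on a laptop while keeping Monte-Carlo error well inside each
  test's tolerance.
* Determinism: every stochastic function takes or derives a seed and
  restores the caller's RNG state; one master seed fans out to stage seeds
  by hashing stage names, so any stage can be re-run standalone with the
  stream it had inside the pipeline, and identical configs produce
  byte-identical outputs.

## Known limitations

* Burst counts are biased low at high event rates: consecutive Poisson
  events closer than the 0.5 s minimum inter-burst interval merge into one
  detected burst by definition (≈ 13% of events at 0.24 events/s per
  channel). Estimates of event *rates* from burst counts inherit this
  bias; it is a property of the burst definition, not an estimator defect.
* Fold changes on 10-minute epochs carry irreducible Poisson counting
  noise: at 0.1 events/s, the baseline epoch holds ~60 events, putting a
  ~13% relative SD on any count-based ratio before the pipeline touches
  the data.
* The SPIKE-distance null assumes spike *counts* are the only thing worth
  conditioning on; strongly rate-modulated trains are compared against
  uniform surrogates, which makes bursty pairs look more synchronous than
  a rate-matched null would. This matches the published normalization and
  is kept deliberately.
* Heater detection needs amplitudes; spike tables without troughs cannot
  be cleaned (the reader accepts them, the artifact stage refuses to
  invent candidates).
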