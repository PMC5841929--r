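---
title: "Methods: CA1 linear-track electrophysiology analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CA1 linear-track electrophysiology analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ca1ephys)
```

# Scope and pipeline

`ca1ephys` implements the post-sorting analysis of tetrode recordings from
the dorsal CA1 pyramidal layer of mice running a 170 x 10 cm linear track
bracketed by rest periods: behavioral preprocessing, unit quality control,
place-field and spatial-coding metrics, complex-spike/burst analysis,
ensemble population-vector correlations, spectral and theta phase-locking
analysis of the LFP, and MUA-gated sharp-wave-ripple (SWR) detection,
plus the group-level statistics comparing two cohorts. The pipeline starts
from sorted units: spike sorting itself, recording hardware and histology
are out of scope.

The package is a library, not a shell tool: `simulate_session()`,
`analyze_session()`, `compare_groups()` and the readers/writers
(`read_session()`, `write_session()`, `read_config()`) are the intended
entry points, with `scripts/acceptance.R` as a runnable end-to-end example.

# Behavioral preprocessing

Tracking artifacts (obscured diodes) are detected as samples implying an
instantaneous speed above 150 cm/s — far above mouse running speed, so the
threshold only catches physically impossible jumps — and repaired by linear
interpolation. Positions are then smoothed with a Gaussian kernel of SD
0.05 s. Velocity is the per-sample Euclidean displacement rate smoothed
with a 2.5-sample Gaussian. The two kernel units differ deliberately: the
position kernel is specified in seconds and the velocity kernel in samples,
and both are exposed as arguments, because the upstream convention mixes
the two and neither is recoverable from data.

Laps are traversals from one track-end zone to the other. The end zones
are the outer 10% of the track (a standard choice); a lap runs from the
last sample inside the origin zone to the first sample inside the
destination zone, so brief mid-track reversals do not split a lap, and
excursions that return to the same end are discarded.

Two velocity thresholds recur downstream and derive from the same velocity
trace: 2 cm/s gates rate maps, mean rates and Welch segments; 6 cm/s gates
spike theta phases.

# Unit quality control and classification

Units are excluded when more than 0.5% of their spikes follow another
spike by less than 2 ms (the denominator is the spike count, not the
interval count; the difference is O(1/n)), when they fired fewer than 50
spikes, or when their isolation distance is below 10. Isolation distance
is the squared Mahalanobis distance — with respect to the cluster's mean
and covariance — of the n-th closest non-cluster spike, with n the cluster
size; the noise set is the pooled feature vectors of all other units on
the tetrode. A near-singular cluster covariance is ridge-regularized
(1e-6 of the mean diagonal) with a warning; fewer noise spikes than
cluster spikes yields `Inf` with a warning. Included units are classified
as pyramidal when the mean spike width exceeds 200 microseconds and the
complex spike index is at least 5.

# Spatial coding

Rate maps divide speed-gated spike counts by speed-gated occupancy time in
1 cm bins; unvisited bins are flagged and excluded from every summary.
Both smoothing orders are implemented: the default divides first and then
smooths the rate map with a 1-bin Gaussian over visited bins (normalized
convolution, so missing bins neither leak zeros nor shift mass); the
alternative smooths the count and occupancy maps separately before
division. The track is analyzed in 1D after projecting positions onto the
principal track axis.

The main place field is the maximal contiguous run of bins around the
global peak with rate above 20% of that peak. A unit is a place cell when
the main field spans at least 6 bins, the mean rate exceeds 0.2 Hz, the
peak exceeds 1.0 Hz and the signal-to-noise ratio is positive. SNR is not
given a formula upstream; here it is `log2(infield / outfield)` of the
raw in-/out-field rates, positive exactly when in-field firing exceeds
out-field firing. Field size counts only the contiguous main-field bins
(not all supra-threshold bins track-wide), matching the "contiguous bins
surrounding the peak" construction.

Spatial information is the Skaggs rate, `SI = sum p_i lambda_i log2
(lambda_i / lambda_bar)` in bits/s, zero for a silent map; sparsity is
`1 - (sum p lambda)^2 / (sum p lambda^2)`, 0 for a uniform map and
`1 - 1/N` when all firing sits in one of N bins. The directionality index
`|FR_L - FR_R| / (FR_L + FR_R)` is reported only for place cells whose
main-field peak lies in the middle 80% of the track, using the
direction-mean rates over left and right laps.

A caveat worth knowing: the map peak is the maximum of noisy bin
estimates, so in short sessions it is biased upward (about +30% in a
10-lap session at 8 Hz true peak with ~0.6 s occupancy per bin), and the
20%-of-peak field width is correspondingly biased narrow. The estimators
are consistent — by 100 laps the width recovers the analytic
`2 sd sqrt(2 ln 5)` value within a bin — which is why the geometry
recovery tests run at 100 laps while rate calibration is asserted at the
(unbiased) true-center bin in 10-lap sessions.

# Bursts and the complex spike index

A burst is at least two spikes with consecutive inter-spike intervals of
at most 10 ms; chaining is transitive (spikes at 0, 6 and 12 ms form one
burst). The fixed-bin alternative reading ("within a 10 ms bin") was
rejected because it depends on bin alignment.

The complex spike index scores consecutive pairs with ISI at most 15 ms:
a pair is positive when the ISI also exceeds the 3 ms refractory bound
and the second spike is smaller on the reference channel (the channel
with the largest mean amplitude); pairs violating either rule are
negative. The raw `100 (pos - neg)` is unbounded, which is incompatible
with a classification threshold of "CSI >= 5" on a percentage-like scale;
the index is therefore normalized by the eligible pair count, giving
exactly +/-100 for uniformly attenuating/growing bursts and ~0 for
shuffled amplitudes. ISI histograms use log-spaced bins, 1 ms to 10 s at
50 bins per decade (a choice; nothing upstream fixes it), and the ISI
mode is the geometric center of the tallest bin.

# Population vectors

Per-direction firing-rate curves of all place cells (pooled across
animals within a group, including end-of-track fields) are stacked into
a (2 x bins) x cells matrix, left block first. The correlation matrix is
Spearman's rho between all pairs of bin population vectors; constant
vectors are masked. Same-direction structure lives in the left x left
and right x right quadrants, opposite-direction structure in left x
right. Distance profiles average matrix entries by bin separation —
pooled entries, not quadrant averages, where the two readings differ —
keeping the signed offset for the opposite-direction set so an
asymmetric central peak (prospective coding) remains visible. Group
comparisons run a rank-sum test per distance bin; degenerate bins (the
all-ones diagonal) report p = 1.

# LFP analysis

Wide-band LFP (32556 Hz) is low-passed at half the target rate and
decimated by 20 to 1627.8 Hz; all spectral analysis happens at that rate.
The synthetic generator emits LFP directly at 1627.8 Hz, since nothing
upstream of the decimator is analyzed.

The Welch PSD uses 2048-sample Hamming windows (1.26 s), 50% overlap and
4096-point FFTs (2.52 s); segments are kept when the speed interpolated
at the segment midpoint is at least 2 cm/s (the mapping of "time bins"
to segments is not specified upstream; the midpoint rule is the simplest
deterministic one). Each averaged PSD is normalized by its own mean power
in the 1-3 Hz delta band, removing electrode-dependent scale.

Theta phase uses a zero-phase FIR band-pass at 6-12 Hz (Kaiser window;
the default order of about one second of taps gives >= 40 dB attenuation
at 3 and 20 Hz). All linear-phase filters in the package are applied in
a single FFT pass with exact group-delay compensation — for symmetric
taps this equals forward-backward filtering at half the cost. Peaks and
troughs of the filtered trace anchor phases 0 and 180 degrees, and phase
is interpolated linearly in time within each half-cycle, which makes the
estimate insensitive to theta wave asymmetry. Spike phases (interpolated
at spike times, speed >= 6 cm/s) are summarized as a 36-bin histogram,
circular mean, resultant length, Rayleigh test (standard large-sample
approximation), the Kullback-Leibler divergence from uniform in nats,
and a modulation index KL / ln(36) in [0, 1].

# Sharp-wave-ripple detection

Rest-epoch LFP is band-passed at 80-250 Hz with the 69th-order
Kaiser-window FIR (zero phase). The envelope is the magnitude of the
analytic signal smoothed with a Gaussian kernel of 50 ms total window
(SD 50/6 ms; the "50 ms window" is read as total support — the SD is an
argument). Candidate events exceed mean + 3 SD of the envelope for more
than 30 ms; edges extend to where the envelope returns to the mean;
overlapping events merge. Envelope statistics come from the rest epoch
only. Note the literal 69-tap filter at 1627.8 Hz has a ~70 Hz transition
band, so 60 Hz is attenuated but not annihilated; tests assert the real
response.

Multi-unit activity is the summed spike train in 1 ms bins converted to
a rate and Gaussian-smoothed (SD 5 ms; unspecified upstream), and the
same mean + 3 SD / >30 ms rule detects population bursts. Candidates
without an overlapping MUA burst are discarded. Per-event intrinsic
frequency is the peak, within 80-250 Hz, of a multitaper spectrum (3
Slepian tapers, time-bandwidth 2, computed from the tridiagonal DPSS
formulation) of the filtered, Hanning-windowed event segment.

Event duration is reported two ways: the above-threshold core and the
mean-to-mean extended span (the default `duration_ms`). The extended
span carries a positive bias of roughly +10 to +30 ms because beyond the
packet the envelope rides background noise that sits above the mean
about half the time; the core span is correspondingly conservative. Both
are kept because neither reading is canonical, and group comparisons of
event duration are more sensitive on the core span: the noise-ridden
extended edges contribute variance but no signal, which at a handful of
animals can wash out a real duration difference. A corollary worth
stating plainly: neither span recovers a packet's nominal duration to
within ~15 ms — the extended span over-reads by roughly +25 to +35 ms
and the core under-reads by a similar amount — so absolute durations
from this rule should be compared within, not across, detection
settings. Amplitude is reported in
envelope SD units above the mean (comparable across animals) and raw
units. A threshold sweep (2, 3, 6 SD) and an MUA-only detector (events
from population bursts alone, no LFP) provide the robustness controls;
event sets nest monotonically across thresholds.

# Group statistics

Unit-level metrics (spatial, burst, ripple participation) are compared
with the two-sided Mann-Whitney U test (exact below n = 21 without ties,
normal approximation with continuity correction otherwise — "Wilcoxon
rank-sum" is the same test); session-level ripple metrics (one session =
one animal) with one-way ANOVA; proportions of theta-modulated cells with
Pearson's chi-square on the 2x2 table, one degree of freedom, no
continuity correction (the variant that reproduces the published
p = 0.514 for 121/256 vs 115/259). Stars follow the usual convention
(* <0.05, ** <0.01, *** <0.001); no multiple-testing correction is
applied, matching the source analyses, and the report says so.

# The synthetic session generator

The generator exists so that every stage has ground truth. A session is
a run epoch (n end-to-end traversals) followed by a rest epoch. Defaults
describe one plausible mouse session and were fixed once:

| parameter | default | rationale |
|---|---|---|
| track, laps | 170 cm, 10 | the recorded task geometry |
| running speed | 15 cm/s, +/-25% smooth fluctuation | mid-range mouse running; see below |
| behavioral rate | 30 Hz | typical diode tracking |
| units | 20 | one good tetrode day |
| field width / peak | 10 cm (SD) / 8 Hz | typical CA1 fields |
| directional gain | 0.3 | clear but imperfect directionality |
| theta | 8 Hz, kappa = 1, preferred 180 deg | mid-band theta, moderate locking |
| bursts | p = 0.3; sizes 2:4 at 0.6/0.3/0.1; ISI 5 ms; attenuation 0.85 | complex-spike statistics in the range reported for CA1 |
| rest | 120 s at 0.5 Hz | compressed stand-in for a 30 min rest |
| ripples | 10/min, 150 Hz, 80 ms, 6 SD, 40 Hz/unit MUA | mid-range SWR parameters |
| LFP | 1627.8 Hz, 1/f noise, theta at 2 SD | the analysis rate; pink background |

Three design points matter for interpreting test results. First, running
speed fluctuates smoothly (two slow seeded sinusoids): constant speed
would phase-lock theta to track position (a 1.9 cm spatial period at
15 cm/s and 8 Hz) and alias the theta modulation into rate maps. Second,
the configured tuning is the total spike rate — the emitted event rate
is divided by the expected burst factor 1 + p(E[size] - 1), so burst
expansion does not inflate rates. Third, every train respects a 2.5 ms
absolute refractory period (bursts losing a member are dropped whole);
without it, Bernoulli thinning at 1 kHz produces enough sub-2 ms ISIs
that realistic units fail the 0.5% QC rule.

Spiking is inhomogeneous-Poisson by 1 ms Bernoulli thinning of
rate = Gaussian(position) x direction gain x von Mises(theta phase,
normalized to unit mean). Ripple packets are sinusoids under a
tapered-cosine (Tukey) envelope flat over the central half, scaled so
the envelope peak sits `ripple_amp_sd` SDs of the background smoothed
ripple-band envelope above its mean — the same units as the detection
threshold — and placed without overlap (bounded redraws). A Hanning
envelope was considered and rejected: it spends only ~40% of its nominal
duration above the 3 SD line even at 6 SD, so "an 80 ms ripple" would be
undetectable by the stated rule about half the time and its duration
systematically under-read. Each ripple appends a coincident Poisson MUA
burst to every unit. Per-spike 8-D features form one Gaussian cluster
per unit, supporting isolation-distance tests.

What the generator does not emulate — and hence what green tests do not
show about real data: biophysical waveforms, theta asymmetry and
harmonics, phase precession, replay content inside ripples, inter-neuron
correlations beyond shared ripple times, electrode drift, and EMG or
movement artifacts. Results on real recordings depend additionally on
all of those.

# Numerical choices and degenerate inputs

Gaussian smoothing truncates kernels at 4 SD with reflective edges;
NA-aware smoothing renormalizes over observed bins. FFT convolution pads
to powers of two (R's mixed-radix FFT is pathological at some lengths).
Undefined statistics (CSI with <2 spikes, sparsity of a silent map, DI
with two silent directions, interburst interval with <2 bursts) return
`NA` with a warning rather than erroring; genuinely invalid inputs
(unsorted spike times, non-uniform sampling where uniformity is assumed,
zero occupancy, degenerate 2x2 margins) error with the offending
condition named. Seeded stages (`generate_*`) re-seed from `cfg$seed`
plus a fixed per-stage offset, so stages are independently reproducible
and a full session is bit-identical for identical configurations.

Test problem sizes: the suite simulates sessions of 2-10 laps with 2-20
units and 10-120 s rest epochs, 20-seed recovery studies (100 laps for
field geometry, as justified above), and 10^4-replicate calibration
nulls; these sizes were chosen to make Monte-Carlo error comfortably
smaller than the asserted tolerances.

# Known limitations

Directional rate curves do not implement phase-precession or
prospective-coding analysis (the signed opposite-direction profile merely
keeps such asymmetries visible). The Rayleigh p-value uses the standard
approximation (adequate for n >= 10; the suite's calibration test pins
the type-I rate at 5% +/- 1%). The MUA gate assumes enough simultaneously
recorded units that population bursts stand out at 1 ms resolution — with
very few units the gate becomes conservative. Ripple extended durations
are biased long, as discussed, and the bias grows with smoothing width.
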