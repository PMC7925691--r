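---
title: "Quantifying multi-directed cholinergic transmission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multi-directed cholinergic transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multisyn)
```

# The scientific problem

Starburst amacrine cells release acetylcholine (ACh) from dendritic
varicosities onto direction-selective ganglion cells (DSGCs). The classical
picture is a private wired synapse: one varicosity, one postsynaptic
partner. The alternative this package is built to quantify is
*multi-directed transmission*: a single vesicle's ACh spreads far enough,
fast enough, to activate receptors on several DSGCs whose dendrites
co-fasciculate within a micron of the release site — with comparable
efficacy at each, rather than the steep falloff expected of spillover.

Four independent lines of evidence bear on this claim, and the package
implements the quantitative analysis for each: (1) synchronized quantal
EPSCs across simultaneously recorded DSGC pairs; (2) the sub-micron overlap
of their dendritic arbors; (3) optical mapping of single-site ACh release
and its direction tuning; (4) a biophysical model of whether cleft geometry
and receptor kinetics can equalize responses at 0 and ~1 µm from a release
site. A fifth module generates synthetic data with known ground truth for
all of them.

# Quantal event analysis

Voltage-clamp traces (10 kHz, pA; inward EPSCs sign-flipped to positive at
load) are conditioned with a zero-phase 300-Hz low-pass filter. The
forward–backward Butterworth filter is applied in the frequency domain:
filtering twice with an order-$n$ Butterworth equals multiplying the
spectrum by $|H(f)|^2 = 1/(1+(f/f_c)^{2n})$ with zero phase, which is exact
for the periodic extension and fast on multi-million-sample traces; traces
are long relative to the filter memory, so wraparound effects are
negligible.

Detection is by iterative template subtraction. The trace minus a rolling
50-ms median baseline (end windows extended from the first full window, so
shrinking end-rule medians do not swallow edge events) is scanned for local
maxima above the amplitude threshold (5–7 pA is the standard operating
range). Each accepted peak subtracts a unit-peak difference-of-exponentials
template (rise 0.5 ms, decay equal to the *separation decay constant*,
default 2.5 ms) scaled to the residual amplitude, and the residual is
re-searched, so events riding on a predecessor's decay are recovered; a
1-ms refractory period applies between onsets, and residual bumps pulled
back under threshold by a predecessor's subtraction are discarded. Onset is
the peak time minus the template's analytic peak delay.

Metrics follow standard definitions: per-event baseline is the median of
the 5 ms before onset; the peak is refined within ±0.5 ms of the detected
peak; the 20–80% rise time is linearly interpolated on the rising limb; the
decay constant is a log-linear single-exponential fit from the peak to five
decay constants later (truncated at the next onset, using samples above 5%
of the peak). Events whose windows are clipped by the trace edges keep
their row — they count toward rates — but their kinetics are `NA` rather
than extrapolated.

One caveat on *instantaneous frequency* (the reciprocal inter-event
interval): for Poisson trains the expectation of 1/IEI diverges, so its
sample mean is not a rate estimator and overshoots badly; rates should be
read from counts per unit time (the tests assert exactly this renewal
property).

# Synchrony across paired recordings

The **sEPSC-triggered average (STA)** aligns snippets of the second cell's
current to the peaks of events detected in a reference cell and averages
them; the reference cell's own mean event is computed on the same time
base. Their peak ratio, the **correlation strength**, estimates the shared
quantal fraction: if a fraction $f$ of reference events also occur in the
other cell with the same amplitude distribution, the STA peak is $f$ times
the mean event peak. The snippet window is ±20 ms (the event is over within
~15 ms; the window only needs to contain the peak and a clean baseline
stretch — the window length is not stated by convention, so it is a
configurable default), and per-snippet baselines use the earliest 10 ms of
the pre-window.

Matched coincident events (peaks within ±1 ms, amplitudes ≥ 5 pA in both
cells) are paired greedily by increasing absolute lag with a one-to-one
constraint, ties broken toward the earlier reference event. The 1-ms window
matches the bin width implied by the chance-coincidence arithmetic
($0.003^2 \times 100 = 0.0009\%$ for two independent 3-Hz trains in 1-ms
bins). Properties are z-scored per cell over the matched set before
correlation. Significance uses the Fisher-z comparison of the original
correlation against a one-step *circular* shift of one cell's property
sequence (circular, so $n_\text{shuff} = n_\text{orig}$), with
$|z_\text{observed}| > 1.96$ as the two-tailed 5% gate. Its empirical
type-I error under an independent-data null at $n = 241$ per arm is
measured in the acceptance tests and sits within the 5% ± 2% band (the
Fisher approximation is mildly anticonservative at this $n$, on the order
of half a percentage point).

# Dendritic overlap

Skeletons are centerline node tables (SWC convention: type 1 soma, 3 ON
dendrite, 4 OFF dendrite; dendrite thickness is treated as a rendering
artifact and ignored in geometry). Every unbranched path is resampled by
arc length into 1-µm segments (terminal remainders ≥ 0.5 µm are kept), and
each segment's midpoint-to-midpoint 3-D distance to the nearest segment of
the partner cell is the NND. The midpoint convention can differ from a
closest-approach convention by at most half a segment. Profiles are
directional (A→B ≠ B→A); both are computed. The cumulative fraction of
segments with NND ≤ d, averaged over the ON and OFF strata, is the
*overlap fraction* at distance d; `structure_function_compare()` contrasts
these fractions at 0–3 µm with the per-pair correlation strengths using
two-sided paired t-tests and flags the distance of smallest absolute mean
difference. Degenerate inputs are resolved by limit: all-zero differences
give p = 1, constant non-zero differences give p = 0 (the t statistic
diverges).

Nearest-neighbor search uses a uniform grid-bucket index with
expanding-shell search, exact by construction (a shell at Chebyshev radius
$k$ cannot contain a point closer than $k$ times the cell size); query
points far from every bucket fall back to a vectorized exhaustive scan.
The index is cross-validated against the exhaustive all-pairs oracle on 50
random instances in the acceptance tests.

# Sensor-movie analysis

Movies are conditioned the standard way: per-frame 3×3 Gaussian smoothing
(kernel SD 0.8 px), bilinear down-sampling by 0.8, a 2-frame moving
average, and linear-interpolation resampling to twice the native frame
rate (the resampling factor is not fixed by convention; 2× is the
package's default). ΔF/F uses the mean fluorescence in the 1-s window
before stimulus onset; non-positive baselines flag the pixel invalid.

**Noise-correlation score.** Residuals are each trial's ΔF/F minus the
across-trial mean for that stimulus. For a pixel pair the per-trial
cross-correlation functions (Pearson-normalized per trial) are averaged and
the score is $C = (c_{\tau=0} - M_c)/\mathrm{SD}_c$ over lags up to half
the series (lag 0 included; the lag range is a declared default). For
independent pixels the score is approximately standard normal — the tests
check mean within ±0.2 and SD within [0.8, 1.2] over 500 draws — so the
2.5 threshold is a ~0.6% false-merge gate per comparison.

**ROI formation.** Seeded region growth: the unassigned pixel with the
highest response seeds an ROI; 8-connected neighbors (iteratively, from
accepted pixels) join while their score *with the seed pixel* exceeds 2.5.
Comparing to the seed rather than a running mean keeps the rule
order-independent. The exact agglomeration rule is not fixed by
convention; this one is the simplest that is deterministic given the
response ranking.

**Responsiveness and tuning.** Per ROI and direction, the response $R^i$
is the stimulus-window peak of the trial-averaged ROI trace;
$RI^i = (R^i - (M_0 + 2SD_0))/(R^i + (M_0 + 2SD_0))$ with $M_0, SD_0$ the
mean and SD of the *pooled per-trial* pre-stimulus samples, and an ROI is
responsive if any direction exceeds 0.6. Pooling per-trial baselines
matters: the SD of the trial-averaged trace understates the noise the
response is judged against (by roughly the square root of the trial
count), which lets noise-dominated fragments through the gate — in
synthetic validation such fragments carry preferred-angle errors of tens
of degrees before the gate and are removed by it. The preferred angle is
the quadrant-correct two-argument arctangent of the response-weighted
vector sum (a printed single-argument arctangent loses the quadrant);
$R_\text{pref}/R_\text{null}$ are the responses at the sampled directions
nearest $\theta$ and $\theta + 180°$, with "preferred" assigned to the
larger of the axis pair so that the DSI stays in [0, 1] even for
multi-lobed curves whose resultant points at a local dip; for a perfectly
symmetric curve the resultant vanishes, $\theta$ is flagged `NA`, and the
DSI evaluates to 0. All-zero curves are flagged rather than scored.

**Spatial-scale fits.** The decay of noise correlations with distance is
fit by $A\,e^{-d^2/(2\sigma^2)} + b$ (Levenberg–Marquardt, amplitude and
width bounded positive; starts from the data range and a third of the
distance span), reporting the 1/e half-width $\lambda = \sigma\sqrt{2}$;
flat inputs are rejected (amplitude ≈ 0) rather than fit. Single-site peak
maps are fit by an axis-aligned elliptical Gaussian with offset, and the
space constant is the geometric mean of the two fitted SDs — the "1 SD
contour" scale, deliberately different from the correlation-distance
$\lambda$; both definitions travel with the outputs. Post-peak decays are
single-exponential fits.

**Circular statistics.** The Hodges–Ajne statistic $m$ is the minimum
count in any closed half-circle, computed exactly in $O(n\log n)$ by a
sorted two-pointer sweep evaluated on both sides of each data angle. For
$m < n/3$ the exact tail $p = 2^{1-n}(n-2m)\binom{n}{m}$ applies (at
$m = 0$ this is the classical $n\,2^{1-n}$ probability that all angles fit
in a half-circle); at the maximal statistic $m = \lfloor n/2\rfloor$ the
test returns p = 1; in between, where no closed form exists, a seeded
Monte-Carlo null (default $10^4$ uniform samples, RNG state restored) is
used and labelled as such. Condition comparisons use the two-sided
Wilcoxon signed-rank test, with all-zero difference vectors flagged
degenerate instead of tested.

# Cleft model

Transmitter spread is the instantaneous point-source Green's function with
first-order esterase loss $e^{-kt}$:
planar cleft, $C(r,t) = \frac{N}{4\pi D t\, h} e^{-r^2/4Dt}e^{-kt}$ (sheet
solution divided by cleft height $h$); porous 3-D,
$C(r,t) = \frac{N}{(4\pi D_\text{eff} t)^{3/2}} e^{-r^2/4D_\text{eff}t}e^{-kt}$
with $D_\text{eff} = D/\lambda^2$ (tortuosity factor, default 2.6).
Concentration converts at 1 µM = 602.214 molecules/µm³. Defaults —
$N = 10^4$ molecules, $D = 0.4$ µm²/ms, $h = 20$ nm — are configuration
choices in the round-number physiological range, not literature-fitted
values, and are echoed in outputs. Esterase is first-order, not
Michaelis–Menten: the enzyme is modelled as limiting spread, not as
saturable. For any fixed $(N, D, t)$ the planar geometry's normalized
concentration at 1 µm exceeds the 3-D one — the gradient is shallower in
2-D — and the tests assert this over a $D \times t$ grid.

Receptors follow a canonical two-binding-site scheme
$C \leftrightarrow CA \leftrightarrow CA_2 \leftrightarrow O$ with
desensitization $CA_2 \to D$, $O \to D$ (rate $k_\text{des}$) and recovery
$D \to CA_2$ ($k_\text{res}$); binding is $2k_\text{on}[A]$ then
$k_\text{on}[A]$, unbinding $k_\text{off}$ then $2k_\text{off}$. Two
presets bracket the physiological range — "high" affinity with slow
desensitization (α7-like, sub-µM $K_d$: $k_\text{on} = 0.1$ µM⁻¹ms⁻¹,
$k_\text{off} = 0.05$ ms⁻¹, $k_\text{des} = 0.02$ ms⁻¹) and "low" affinity
with fast desensitization (muscle-like, $K_d$ 50 µM,
$k_\text{des} = 0.5$ ms⁻¹) — and every rate is overridable; no preset is
presented as a measured value. Integration uses `deSolve::lsoda` with
absolute tolerance $10^{-10}$ on occupancies; occupancy normalization is
checked to $10^{-9}$ at every step, the constant-agonist steady state is
checked against the null-space solution of the rate matrix, and the
transient solution is cross-validated against matrix-exponential
propagation on piecewise-constant inputs to $10^{-8}$. `compare_sites()`
reports the distal/proximal peak-open-probability ratio at 0 and 1 µm; the
qualitative ordering — high-affinity, slowly desensitizing receptors give
ratios closer to 1 than low-affinity ones on the same transient — is
asserted over a parameter grid rather than tied to any particular rate set.

# The synthetic-data generators

**Paired trains.** Events are Poisson (default 3 Hz per cell, the typical
spontaneous rate in these cells) over the trace duration; a
`shared_fraction` of cell A's events is copied into cell B within
`coincidence_jitter` (default 0.1 ms — sub-bin diffusion delay), *with the
same amplitude in both cells*, because the shared event is one vesicle
seen at two postsynaptic sites. Amplitudes are log-normal, mean 15 pA, SD
6 pA (CV 0.4), keeping essentially all events above the 5-pA floor while
showing realistic spread; the waveform is the 0.5/2.5-ms
difference-of-exponentials; noise is Gaussian, low-pass filtered at 1 kHz
before addition (recording-system bandwidth without modelling the
amplifier), with `noise_sd` defined post-filter (default 1 pA). All draws
flow from one seeded generator per call, so identical specs are
bit-identical.

**Arbor pairs.** Each cell is a planar random binary tree per stratum (ON
at z = 0, OFF at z = 12 µm; nodes jittered ±`z_jitter`), grown in 2-µm
steps with Gaussian heading jitter and clipped at the field radius. Cell B
shares cell A's branch topology; a `cofasciculation` fraction of its
branches is laid within 1 µm of A's branch (sub-micron lateral offset,
matched depth), the rest regrown with independent geometry from the B-side
attachment point, which keeps the arbor connected. This emulates the
fasciculated plexus geometrically; it does not model self-avoidance,
tiling, or realistic branch statistics.

**Movies.** Release sites have Gaussian spatial footprints *truncated at
2σ*: the sensor reports release only over the finite membrane patch that
expresses it, so each footprint has compact support, and that support is
the ground-truth segmentation mask. Direction tuning is von Mises with
concentration κ (default 0.37, i.e. DSI ≈ tanh κ ≈ 0.35); the temporal
kernel is the sensor response (10-ms rise, 140-ms decay) to a boxcar drive
lasting as long as the moving spot covers the site (300 µm at 1000 µm/s →
0.3 s). Trial-to-trial gain fluctuates with CV 0.2 *shared across a
site's footprint* and independently between sites — this shared
fluctuation is what noise-correlation segmentation detects — plus
independent per-pixel shot noise (default 0.1 ΔF/frame). What the
generator does not emulate: optics (no PSF), photobleaching, motion,
neuropil contamination, overlapping footprints on a shared dendrite.

# Validation design and problem sizes

The test suite validates each stage against independent oracles (closed
forms, exhaustive searches, matrix exponentials, permutation nulls) and
then end-to-end against generator ground truth, at sizes chosen to keep
the full suite within a coffee break on one core:

* shared-fraction recovery: 10-minute pairs at 10 kHz, fractions
  {0, 0.1, 0.25, 0.5, 1}, four seeds each; the seed-mean strength must sit
  within ±0.02 of truth.
* footprint recovery: two well-separated sites, six trials, shot noise
  0.02 ΔF, *without* spatial preprocessing — at this boundary-limited
  signal-to-noise the correlation support ends exactly at the footprint
  edge, so the Jaccard score tests assignment correctness rather than
  noise robustness (which is characterized separately: at the default
  0.1 ΔF the recovered masks shrink toward the footprint core).
* tuning recovery: four sites 9 µm apart on a 40×40 grid at default noise
  through the full preprocessed pipeline; ROIs are scored against the site
  whose footprint contains their seed (only there is a truth angle
  defined). Sites packed closer than ~4σ acquire neighbor-mixture bias in
  peripheral fragments — a real limitation of dense fields, documented
  rather than hidden.
* statistical calibration: 4000 null replicates at n = 241 per arm for
  the z-test; $10^5$ permutation draws for the Hodges–Ajne oracle at
  n ≤ 12.

# Known limitations

Detection kinetics are measured on the filtered trace, so rise times and
decay constants inherit the conditioning bandwidth; the STA estimator
assumes shared events have equal efficacy at both cells (its agreement
with the injected fraction is evidence the statistic works, not that real
synapses satisfy the assumption); the imaging pipeline does not correct
for sensor kinetics, so tuning amplitudes are sensor-filtered; the cleft
model's rate constants are presets spanning a plausible range, and only
orderings — never absolute open probabilities — should be read from it;
and passing tests on synthetic movies bound what the pipeline can do under
the generator's assumptions, not under optical artifacts it does not
model.
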