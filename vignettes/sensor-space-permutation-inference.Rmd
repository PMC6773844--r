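---
title: "Sensor-space spectral inference with mixed models, TFCE and max-statistic permutation"
author: "eegperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensor-space spectral inference with mixed models, TFCE and max-statistic permutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegperm)
```

## The problem

High-density EEG studies of within-subject state manipulations face a hard
statistical problem at very small sample sizes: five participants, six
condition blocks each, 257 channels, and a spectral dependent variable that
is strongly autocorrelated in time and correlated across the scalp.
`eegperm` implements the full analysis chain for this setting:

1. deterministic signal conditioning (high-pass, mains band-stop,
   bad-channel interpolation, average reference);
2. Welch power spectral density over non-overlapping 30-s windows, with
   windows rejected when they overlap marked artifacts for more than 5 s;
3. an RMS-of-log band-power summary per window, channel and band;
4. a linear mixed model per channel with a participant random intercept;
5. threshold-free cluster enhancement (TFCE) of the per-channel T map over
   the sensor adjacency graph;
6. family-wise inference by a max-statistic permutation test that relabels
   whole condition blocks within participants.

Because raw recordings from the motivating study design are not publicly
deposited, the package ships a synthetic-data generator that emulates the
design and gives every stage a ground-truth-known input.

## The model

For channel $c$ and band $b$, the windowed dependent variable is

$$ y_{iwc b} = \sqrt{\tfrac{1}{|B|}\sum_{f \in B} \log^2 P_{iwc}(f)} $$

the root-mean-square of log spectral power over the band's 1-Hz bins, for
participant $i$ and 30-s window $w$. The channel-wise model is

$$ y = X\beta + u_i + \varepsilon, \qquad
   u_i \sim \mathcal N(0, \sigma_b^2), \quad
   \varepsilon \sim \mathcal N(0, \sigma_e^2), $$

with fixed effects drawn from the three within-subject factors — hypnosis
state (NC/HY), recalled memory (NDE/AUTOBIO), recall focus (PE vs OBE/KS) —
their interactions, and the covariates age and SHSS:C score. The random
intercept absorbs the non-independence of windows within a participant and
weights participants by how much usable data they contribute.

All fits maximise the full likelihood (ML, not REML) because the
model-building steps compare fixed-effect structures by likelihood-ratio
tests and AIC, which is only valid under ML. Model selection happens once,
at an a-priori central reference channel, by walking a simplest-to-fullest
ladder of candidates and keeping the simplest model within 2 AIC units of
the minimum (the conventional "indistinguishable" margin; exact ties
resolve to the simpler model). The chosen model is then refit at every
channel independently.

The recall-focus factor deserves a note: its raw labels are nested in the
memory factor (OBE/PE during NDE recall, KS/PE during autobiographical
recall). The model codes it as a two-level factor — PE versus the
non-peacefulness phase — so that it crosses the other factors and can enter
interactions.

### Effect tests

`effectTest()` reports, for each term, the likelihood-ratio chi-squared of
dropping the term *together with its hierarchy dependents* against the
nested model. Degrees of freedom always equal the parameter-count
difference of the nested pair; for instance dropping a two-level main
effect that participates in one interaction costs 2 parameters, hence 2 df.

### Two fitting engines

`fitChannel()` offers `engine = "lmer"` ([lme4]) and `engine = "profile"`,
an in-package profiled-ML solver specialised to the single-random-intercept
structure. For a fixed variance ratio $\rho = \sigma_b^2/\sigma_e^2$ the
GLS coefficients and $\sigma_e^2$ profile out in closed form per
participant block, leaving a smooth one-dimensional deviance minimised by
golden-section search. The two engines agree to numerical precision (this
is asserted in the test suite); the profile engine exists because a
permutation null requires hundreds of thousands of refits, which would be
impractically slow through a general mixed-model optimiser.

## TFCE and the permutation null

TFCE replaces an arbitrary cluster-forming threshold with an integral over
all thresholds,

$$ \mathrm{TFCE}(c) = \int_0^{h_{\max}} e(c, h)^E \, h^H \, dh, $$

where $e(c,h)$ is the size of the connected suprathreshold component of the
adjacency graph containing $c$. Defaults are $E = 0.666$, $H = 2$ — the
values established in the sensor-space EEG TFCE literature — with 100
midpoint-rule integration steps, and two-sided enhancement (the negative
map is enhanced separately and re-signed). The implementation is exact with
respect to a brute-force threshold-loop oracle (tested to $10^{-9}$ on
random graphs) and converges to the closed form $T^{H+1}/(H+1)$ for an
isolated suprathreshold channel.

Significance uses the max-statistic permutation approach: the memory-factor
labels are permuted at the level of whole condition blocks within each
participant (windows within a block stay together — they are strongly
autocorrelated, and relabelling them individually would fabricate degrees
of freedom and inflate the null), the whole channel-wise fit and
enhancement is recomputed, and only the maximum enhanced value over
channels enters the null distribution. Per-channel p-values use the add-one
estimator $p = (1 + \#\{M^* \ge m_c\})/(1 + n_{\mathrm{perm}})$, which can
never return zero. Covariates are held fixed under permutation. When a tiny
design admits fewer distinct relabellings than requested permutations, the
null is enumerated exhaustively instead (with a warning): two blocks per
participant and five participants give exactly $2^5 = 32$ relabellings.

Testing three bands multiplies the comparisons, so the family alpha of
0.05 is divided by 3, giving the 0.016 per-band cut-off.

## The synthetic-data generator

The generator is a first-class module, not a test fixture. Its default
design mirrors the emulated study: five participants (ages 60, 44, 66, 71,
48; SHSS:C scores 6, 9, 8, 9, 4, i.e. three high-hypnotisable, one medium,
one low), 250 Hz sampling, and per participant eight phase blocks crossing
state (NC, HY) and memory (NDE, AUTOBIO), each 20-minute recall split into
two focus phases of 600 s. Tests and worked examples run a scaled-down
version (8 channels, 120-s blocks) purely to keep simulation sizes
reasonable; the preset is `presetEmulationSmall()`.

Two generation paths share one generative equation on log band power:

$$ L_{iwcb} = \mu_b + u_i + \Delta_{cb}(\text{condition}) + \eta_{iwcb}, $$

with participant intercepts $u_i \sim \mathcal N(0, 0.5^2)$ and window
noise $\eta \sim \mathcal N(0, 0.5^2)$ by default.

* `simulateWindowTable()` draws table rows directly from this equation —
  the fast path used by the statistical calibration studies.
* `simulateRecording()` synthesises the continuous signal: per channel,
  coloured noise spectrally shaped to $1/f^{\text{slope}}$ (slope 1 by
  default), plus a sinusoid at each effect-carrying band's centre frequency
  whose per-window amplitude is $\sqrt{2\exp(L)}$, so that Welch band
  power recovers the injected log-power structure. Oscillation-carrying
  bands sit at `baseLogPower` (default 2, i.e. about 7.4 µV²·s of band
  power) which keeps the 1/f background contribution in those bands at the
  few-percent level, so injected contrasts survive the log transform
  essentially unbiased.

Artifacts are contiguous high-amplitude segments with exponential
inter-arrival times and exponential durations (mean 3 s), at a default
load of 2 s per minute (≈3.3%, the middle of the 1–10% per-participant
range a clean seated session produces). Durations longer than 5 s occur
with positive probability, which exercises the window-rejection rule.

What the generator does **not** emulate: volume conduction and realistic
scalp topographies (channels are independent up to the injected effects and
the average reference), EOG/EMG artifact morphology, non-stationary 1/f
slopes, and oscillatory bursting. Passing tests therefore demonstrate the
statistical machinery is correct and calibrated under the assumed model
class — not that the model class captures every property of real EEG.

Because the motivating study reports no per-condition effect sizes on the
power scale, the preset's injected effect magnitude (0.8 log units on a
4-channel frontal patch during NDE recall) was chosen once for statistical
convenience: large enough that a calibrated test should detect it reliably
at the scaled-down size, small enough that detection is not trivial.

## Numerical choices and edge cases

* Filters are Butterworth designs applied forward-backward (zero phase), so
  annotation timestamps remain aligned; the effective gain is the squared
  one-pass magnitude. The mains filter is a second-order band-*stop* 48–52
  Hz: the stated purpose (attenuate 50 Hz) governs its type.
* Natural logarithms throughout; a PSD floor of 1e-12 is applied before
  logs so silent synthetic channels do not produce $-\infty$.
* Spherical-spline interpolation uses stiffness $m = 4$, ridge
  regularisation $10^{-5}$, and a Legendre series truncated at degree 50;
  it refuses to interpolate when more than half the montage is bad.
* Welch: 1-s Hann segments, 50% overlap, mean removal per segment, 1-Hz
  bins; one-sided density scaling so a unit sinusoid integrates to 0.5.
* A window is rejected only when artifact overlap *strictly exceeds* 5 s.
* `proposeBands()` replaces the visual "stands out over 1/f" criterion
  with a reproducible rule: a robust log–log line is fit per region, and
  contiguous runs of bins exceeding the fit by 2 robust SDs (and at least
  0.1 log units, so an exact 1/f spectrum proposes nothing) become bands.
* Wilcoxon signed-rank: zero differences are dropped before ranking
  (Pratt's method is available as an option), ties are variance-corrected,
  and **no continuity correction** is applied — with it, the conventional
  $|Z| = 2.03 \mapsto p = 0.042$ mapping would not hold. The effect size is
  $r = Z/\sqrt{N}$ with $N$ = twice the number of pairs. An exact
  enumeration p-value is reported alongside for small tie-free samples;
  note that with five pairs an exact two-sided p cannot fall below
  $1/16 = 0.0625$, so small-sample p-values in the 0.04 range necessarily
  come from the normal approximation.
* Covariates (age, SHSS) enter z-scored for numerical stability with five
  participants; raw entry is available.

## Calibration evidence

The test suite (`tests/testthat/`) contains the empirical evidence for the
claims above, computed fresh on every run:

* the profile engine reproduces `lme4` coefficients, T-values, log
  likelihoods and LRTs;
* channel-wise LRT p-values are uniform under null simulation (rejection
  rate at 0.05 within [0.02, 0.09] over 200 null fits);
* the family-wise error of the full TFCE max-statistic procedure on the
  scaled-down preset (8 channels, 5 participants, 200 permutations) stays
  at or below the nominal 0.05 over 200 null simulations;
* an injected 0.8-log-unit alpha effect on a connected 4-channel frontal
  patch is detected in at least 80% of 50 replicates, and the mixed-model
  coefficient recovers the injected magnitude within Monte-Carlo error;
* TFCE matches an independent brute-force oracle on 100 random graphs.

The same quantities, plus an end-to-end run of the emulated study through
the signal-synthesis path, are recomputed by `scripts/acceptance.R`.
Simulation sizes in the tests (120-s blocks, 8 channels, 200 permutations,
50–200 replicates) are the package's chosen compromise between Monte-Carlo
resolution and the time a routine test run should take.

## Known limitations

* Random slopes, crossed random effects and Satterthwaite/Kenward–Roger
  corrections are out of scope; T-values use the ML standard errors.
* ICA-based cleaning is accepted as externally produced annotations, not
  computed.
* The discrete TFCE integral ties its step size to the map maximum, so
  enhanced values of *other* channels can shift by $O(1/n_{\text{steps}})$
  when the maximum changes; inference is unaffected because observed and
  null maps use the same rule.
* The EDF writer covers the continuous, equal-rate subset of the format
  (16-bit, 1-s records) with annotations in a CSV sidecar.
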