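---
title: "Context-dependent spiking variability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-dependent spiking variability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In trial-based motor tasks, two kinds of spiking variability dissociate
with the behavioral state. *Local irregularity* asks how unevenly a neuron
spaces its spikes within a trial; *trial-to-trial count variability* asks
how reliably it produces the same number of spikes across repetitions of
the same condition. `spikectx` quantifies both in two task epochs — a
500 ms *wait* window at the start of the preparatory delay (aligned to cue
offset) and a 500 ms *movement* window around movement onset (switch
release, SR) — and links the wait-epoch regularity to the locking of
spikes to local-field-potential (LFP) beta oscillations.

# Measures and their assumptions

**CV.** SD/mean of the inter-spike intervals. Only meaningful under a
stationary rate: any rate drift inflates it. It is computed for long
stationary simulations and calibration, never for task epochs.

**m-values and CV2.** For two consecutive ISIs,
$m = 2\,|ISI - ISI'|/(ISI + ISI')$, bounded in $[0,2]$, equal to 0 only
for identical ISIs. Each m-value is anchored at the time of the middle of
the three spikes involved; it enters an epoch's CV2 when that anchor lies
in the half-open window, even if the first or third spike falls outside.
The CV2 is the arithmetic mean over all m-values pooled across trials
(never spanning the gap between trials). At least 20 m-values are required
per unit, window and trial type; below that the estimate is reported as
missing with a reason code, never as silent `NaN` arithmetic. An
alternative local measure, the LV, is computed per trial (ISIs are never
pooled across trial boundaries) and averaged over trials with at least two
in-window ISIs; mirroring the CV2's pooled averaging instead would be a
defensible alternative, and the per-trial choice is recorded here because
it can matter for very sparse trains.

**Fano factor.** Variance over mean of in-window spike counts across
trials, with the unbiased $n-1$ variance (at 20–40 trials the denominator
choice is visible). Samples with a mean rate below 5 spikes/s are reported
as undefined: for such short windows the finite-window bias would dominate.
For a stationary renewal process FF $\approx$ CV², so the per-unit ratio
FF/CV2² is a renewal test: ratios near 1 are consistent with a renewal
process under stationary conditions, ratios well above 1 indicate
across-trial non-stationarity. A ratio of exactly 1 counts as "not below
1" in the reported fractions. Units with CV2 = 0 in an epoch are excluded
from that epoch's ratios and counted separately.

**Windows.** All windows are half-open `[start, end)` in ms, so abutting
windows partition time and spike counts are additive; the boundary
convention is applied identically to spike counting, m-value anchoring and
phase reading. Spike times are integers at 1 ms resolution; rounding
duplicates are dropped. The movement window is profile-dependent —
`[SR-150, SR+350)` for fast reaction times, `[SR, SR+500)` for slow — so
that it covers the peak of the movement-related rate transient in both
cases.

**Selection.** Units enter with waveform SNR strictly above 2.5 (mean
trough-to-peak over snippets divided by twice the SD of all samples).
Population medians use per-epoch selection (a unit may qualify in one
epoch only); paired per-neuron analyses (scatter, contrast, renewal test,
rate-profile split) require selection in both epochs. Units with more than
1% of ISIs at or below 2 ms are flagged as bursty but kept. In the
rate-profile split, exact rate ties are assigned to the "movement > wait"
side — a deterministic rule needed because integer counts on synthetic
data can tie, while on analog data ties have measure zero; the number of
ties is reported.

**Rank statistics.** Epoch comparisons use the two-sided Wilcoxon rank-sum
test in its normal approximation with tie correction; paired epoch values
are summarised with Spearman's rank correlation. Neurons are pooled
without stratification by session, and the per-unit Rayleigh tests are not
corrected for multiple comparisons: the reported quantity is the fraction
of units exceeding the per-test criterion, not a family-wise claim.

# The LFP phase-locking chain

1. **Neighbor averaging.** Each electrode's LFP is replaced by the
   trial-wise, sample-wise mean over its 8-connected grid neighbors. This
   suppresses channel-private noise (variance roughly 1/K for K channels)
   while keeping the shared oscillation, and removes the trivial
   spike-to-LFP correlation that volume conduction produces on the spike's
   own electrode. The electrode's own channel is therefore *excluded* by
   default; `include_center = TRUE` restores it. On this 10 × 10 array
   with unconnected corners, the neighborhood size including the center
   ranges from 4 to 9 channels — a range that strictly matches the
   center-included reading, which is why both behaviors are implemented
   and the exclusion rationale (volume conduction) decides the default.
2. **Beta peak.** The per-trial periodogram of the extended 1000 ms wait
   window (1 Hz resolution at 1 kHz sampling), averaged over trials, and
   its argmax within 10–45 Hz; ties break toward the lower frequency. The
   plain averaged periodogram was chosen over smoothed or multitaper
   estimators because at 1 Hz resolution and tens of trials it is unbiased
   for a tonal peak and trivially testable.
3. **Filtering.** 4-pole Butterworth bandpass at peak ±5 Hz applied
   forward–backward (zero net phase shift; the effective magnitude
   response is squared, i.e. 8th-order roll-off). The filter runs over the
   entire trial, never per window, so edge transients stay at the trial
   edges, at least 100 ms away from any analysis window.
4. **Phase.** The angle of the FFT-based analytic signal, in $(-\pi,\pi]$;
   phase 0 at an oscillation peak, $+\pi/2$ at the following downward zero
   crossing. A spike at integer time $t$ ms reads the phase at sample
   $t+1$ (sample $k$ covers $[k-1,k)$ ms).
5. **Rayleigh test.** Resultant length $R$, $Z = nR^2$, and the standard
   finite-sample-corrected p-value
   $p = e^{-Z}\bigl(1 + \tfrac{2Z - Z^2}{4n} -
   \tfrac{24Z - 132Z^2 + 76Z^3 - 9Z^4}{288 n^2}\bigr)$. A unit is tested
   in a window when it has more than 30 spikes there; the tested sets may
   differ between windows, and locked fractions are reported per window
   over its own tested set.

# The synthetic session generator

The generator realizes a phenomenological model: a gamma renewal process
(shape $a$, CV $= 1/\sqrt a$, equilibrium-started) whose intensity carries
(i) a task-locked Gaussian rate transient centred on SR, (ii) a slow,
moderate across-trial multiplicative gain, and (iii) a multiplicative von
Mises modulation by the beta phase. Inhomogeneity is implemented by
warping the stationary process through operational time (the cumulative
intensity), which preserves the renewal count statistics exactly.

Key choices, each with its reason:

- **Gamma ISIs** because the shape parameter controls the CV directly and
  contains Poisson as `shape = 1`.
- **Equilibrium start.** The first interval of each trial is drawn from
  the exact forward-recurrence distribution (a closed-form mixture for
  dead-time-shifted gamma ISIs), so windowed Fano factors carry no onset
  transient.
- **Log-normal trial gains** with mean 1 and SD `trial_gain_sd`
  (default 0.4): always positive and scale-free. The gain acts fully
  before GO and fades linearly to 1 by SR, so movement counts stay
  near-renewal while wait counts are over-dispersed. The default SD is a
  calibration choice: it places the population median FF/CV2² in the wait
  epoch clearly above 1.4 — the regime of interest — while movement stays
  near 1. It is tuned, not derived.
- **Multiplicative phase locking**,
  $\lambda(t) \mapsto \lambda(t)\, e^{\kappa\cos(\phi(t)-\phi_0)}/I_0(\kappa)$,
  keeps the cycle-averaged rate invariant, so rate and locking are
  separately controllable, and $\kappa = 0$ reduces *exactly* to the
  unlocked generator.
- **Refractoriness is essential for the regularizing effect of locking.**
  A subtle and, to our knowledge, underappreciated point: for a Poisson or
  gamma base process, multiplicative beta modulation alone *increases* the
  CV2 monotonically in $\kappa$ — the oscillation packs excess spikes into
  the preferred phase, and the resulting within-cycle doublets produce
  large m-values that outweigh the cycle-lattice regularity. Only with a
  relative refractory period (default 15 ms, implemented by discarding
  spikes closer than that to the last kept spike) does entrainment pace
  the train toward one spike per cycle and *lower* the CV2, which is the
  empirically observed direction. The generator therefore treats the
  refractory period as a first-class unit parameter.
- **Locking is confined to the cue/delay period** (ramping up over 100 ms
  at cue onset and off 300 ms before GO), mirroring beta
  desynchronisation around the GO signal. With reaction times truncated at
  100 ms this guarantees the extended movement window contains no
  entrained spikes, so the movement-epoch locked fraction sits at the
  test's false-positive level.
- **Reaction times** are Gaussian, truncated: mean 215 ms (SD 50) for the
  `fast` profile — the midpoint of the two fast animals' reported
  averages — and mean 413 ms (SD 60) for the `slow` profile.
- **LFP.** One common beta component per trial,
  $A(t)\cos(2\pi f t + \theta_{trial})$, with a piecewise-linear envelope
  (high from cue onset through the delay, suppressed during movement,
  rebounding at reward) plus channel-private white noise; neighboring
  channels share the common component, which is what makes neighbor
  averaging meaningful. The spike generator locks to the common
  component's true phase, giving a known ground truth for the recovery
  tests.
- **Population defaults** (median base rate 12 spikes/s; 75% of units
  with movement gain ~1.9, 25% with ~0.55; 75% of units lockable at
  $\kappa = 4.5$; 10% low-SNR decoy units) were fixed once to place the
  synthetic cohort in the qualitative regime described above and are not
  adjusted per analysis.
- **Randomness** is driven by a single integer seed through R's default
  stream, drawn sequentially across trials and units; generation is
  single-threaded and exactly reproducible. (A splittable per-unit stream
  would permit parallel generation but adds machinery with no benefit at
  these problem sizes.)

## What the generator does and does not emulate

It emulates: trial structure with four interleaved trial types; task-locked
rate transients including rate-decreasing minorities; slow across-trial
gain variation; epoch-dependent beta with phase-locked spiking; waveform
SNR metadata with sub-threshold decoys; acquisition constraints (1 ms
resolution, dead time). It does not emulate: spike sorting and waveform
shapes (SNR values are drawn, not computed from waveforms); beta frequency
drift or bursting within an epoch; correlations between units beyond the
shared oscillation; session-to-session heterogeneity; error trials.
Passing the regime tests therefore shows the *analysis chain* is correct
and the *model class* can produce the observed signatures — not that
cortical data are generated this way.

# Numerical conventions and degenerate inputs

- Medians use R's midpoint convention for even n.
- Undefined statistics are `NA` with a reason string; they propagate
  through selection flags, never through arithmetic.
- Empty spike trains align to empty sets without error; windows missing
  their alignment event raise an error naming the trial.
- The Rayleigh p-value is clamped to `(0, 1]`.
- `detect_peak_beta` refuses flat (all-zero) spectra; the bandpass refuses
  bands reaching the Nyquist frequency.
- Analytic-signal phases that fall on the branch cut (negative-zero
  imaginary parts) are mapped to $+\pi$ so the codomain is exactly
  $(-\pi, \pi]$.

# Problem sizes

The shipped tests calibrate the Poisson cohort at 200 units × 40 trials ×
500 ms, the renewal identity on gamma shape-4 trains with 300 five-second
windows, the Rayleigh type-I error on 10,000 draws of 40 phases, and the
full regime reproduction on a generated session of 100 units × 120 trials
(30 per trial type) analyzed in one trial type — the scale of one
recording session, which is where the population medians stabilize while
remaining comfortable to re-run routinely.

```{r}
library(spikectx)
sess <- generate_session(session_gen_spec(n_trials_per_type = 30,
                                          n_units = 100, seed = 7))
run_pipeline(sess, "spikectx_report", trial_types = "SG-HF")
```

# Known limitations

- The movement-epoch FF/CV2² ratio of refractory renewal units sits
  slightly above 1 (≈1.1) because the CV2 systematically underestimates
  the CV for sub-Poisson processes; the wait/movement contrast is
  unaffected.
- With strong locking the post-hoc refractory deletion thins the train by
  up to ~10–15%, so realized rates fall slightly below nominal ones.
- CV2 comparisons across epochs assume comparable spike counts; the
  minimum m-value rule guards the estimate's variance, not its bias.
- The LV across-trial averaging weights trials equally regardless of their
  ISI counts.
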