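---
title: "Models and methods behind leverlog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind leverlog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

leverlog analyses event logs from an automated home-cage task in which
group-housed, RFID-tagged mice earn 10 µL water drops by pulling a lever and
holding it inside an angular goal range (6–24°; pulls register at 3°, the
range ends at 30°; the lever angle is sampled at 400 Hz). After a
habituation stage in which any pull is rewarded (stage 1; 100 pulls in a day
advance the mouse), the required hold duration adapts daily: at midnight it
moves up to the 75th percentile of the day's hold times, provided the mouse
made at least 100 attempts at a success rate of at least 30%, capped at 1 s;
two consecutive days below 10% success reset it to the last benchmark.
Because no animal data ship with the package, a closed-loop agent simulator
generates complete synthetic logs with the statistical structure every
analysis assumes, and the entire pipeline is validated against it.

This vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic validation does and does not establish.

## The two-process hold-time mixture

Hold-time distributions are modelled as a mixture of two behavioral
processes:

$$p(x) = w\,\kappa e^{-\kappa x} \;+\; (1-w)\,
  \mathcal{N}(x;\,\mu,\,\sigma^2).$$

The exponential component captures fast, "untimed" pulls — random
engagements whose durations decay with the energetic cost of holding — with
rate $\kappa$ (s$^{-1}$). The Gaussian component captures deliberate,
"timed" holds centred near the current requirement. The exponential weight
$w \in [0,1]$ is the quantity of interest: its decline over days indexes the
shift from exploratory to deliberate responding that distinguishes a learner
from a non-learner.

`fit_holdtime_mixture()` maximises the likelihood on the raw per-day
samples with a derivative-free Nelder–Mead simplex on transformed
parameters: logit $w$, $\log \kappa$, $\mu$ untransformed, and
$\log(\sigma - 0.005)$. Choices that matter:

* **Untruncated Gaussian.** Hold times are non-negative but the model's
  Gaussian is untruncated, matching the fitted formula; the probability mass
  below zero is reported by `summary()` as a diagnostic and is negligible
  whenever $\mu \gtrsim 3\sigma$, which holds in all fitted regimes here.
* **A hard floor on $\sigma$ (0.005 s).** Mixture likelihoods are unbounded
  when a Gaussian collapses onto a single observation; the floor (two
  sample periods) removes the degeneracy without affecting realistic fits.
* **Multi-start.** Five data-driven starts ($w \in \{0.2, 0.5, 0.8\}$ with
  moment-based $\kappa = 1/\bar{x}$, $\mu$ = median of holds above 0.2 s,
  plus two dispersed variants); the best final negative log-likelihood
  wins, and the fit records the objective at every start so tests can
  assert the optimum is no worse than any initialisation.
* **Censoring at the ceiling.** The task truncates holds at 5 s; trials at
  the ceiling are excluded from the likelihood and counted in the fit
  object (they are well under 1% in simulation).
* **A minimum of 30 usable trials per day** (`min_fit_trials`): a
  four-parameter mixture on fewer trials is under-determined; thinner days
  yield missing values in `w_trajectory()`.

Parameter recovery, measured in the test suite at the study's daily scale
($n = 2000$, $\kappa = 5$, $\mu = 0.55$ s, $\sigma = 0.1$ s), is unbiased
to within 0.03 in $w$, and pure-component data drive $\hat w$ to the
corners.

## Movement jerkiness

Jerkiness is the standard deviation (denominator $n-1$) of the above-10 Hz
component of a trial's lever trajectory; trials shorter than 20 samples
(0.05 s) are excluded. The high-pass step mirrors a minimum-order,
60 dB-stopband, delay-compensated design: `highpass_10hz()` uses the
minimum-order Chebyshev-I high-pass meeting a 10 Hz passband edge (0.1 dB)
and a 5 Hz stopband edge at 60 dB for 400 Hz data (order 8), applied
forward–backward so the response is zero-phase. Because the acceptance
quantities are RMS/SD measures, which are phase-insensitive,
forward–backward filtering is equivalent to explicit group-delay
compensation. Two implementation details carry the design load:

* **Edge handling.** A causal IIR pass started from zero state injects a
  large decaying transient at both ends. Each pass is therefore initialised
  at its DC steady state (past inputs equal to the first sample, past
  outputs zero — exact for a high-pass, whose DC gain is zero) and the
  signal is extended by odd reflection (up to 400 samples per side) before
  filtering. Measured: a constant input leaves residuals below $10^{-8}$°,
  a 2 Hz probe is attenuated by ~84 dB, and a 50 Hz probe passes at unity
  gain within 0.01%.
* **Whole-trial scope.** The SD is taken over the trajectory as stored
  (the full registered pull), not only the hold epoch.

## The synthetic cage

`simulate_cage()` runs agents in closed loop with the genuine task logic —
the same `advance_stage()` and `update_required_hold_time()` that the
analysis validates — so requirement trajectories are emergent, not
scripted. Per day and agent: chamber entries arrive as a Poisson process
(`entry_rate`, default 1/h — roughly 160 trials/day at the default bout
size, matching an engaged mouse); each entry holds a geometric number of
trials (`bout_geom_p`, default 0.15, the discrete analogue of the observed
exponential bout-size decay) spaced 10–60 s apart so that 10-trial bouts fit
inside 5-minute windows; each trial draws a hold time from the agent's
mixture. The presets encode the two study regimes:

* `wt_agent()` (learner): $w$ declines linearly 0.9 → 0.4 over 58 days,
  $\kappa = 5$/s, timed holds at the requirement + 0.05 s with
  $\sigma_t = 0.1$ s, trajectory jitter 0.077°.
* `hd_agent()` (non-learner): $w$ fixed at 0.85 while $\kappa$ declines
  5 → 2.5/s — hold times lengthen by stretching the exponential tail
  rather than by forming a timed mode — jitter 0.098°.

Under these defaults the learner's requirement ratchets to the 1 s cap
within two months while the non-learner plateaus well below it, and the
fitted $w$ trajectories separate exactly as the generative schedules say
they should (Kendall $\tau < 0$ with $p < 0.05$ for the learner in every
tested seed; fitted slope below 0.002/day in magnitude for the
non-learner).

**Trajectory synthesis.** A synthetic pull must satisfy two pulls in
opposite directions: the in-range run must last exactly the sampled hold
time (so the trial record, the classification and the trajectory agree),
yet the profile must contain essentially no power above 10 Hz (so jerkiness
is controlled by the injected noise alone). A fast 6°→15° transition is
broadband; a slow one spends many samples inside the goal range. The
resolution is hold-length dependent:

* Holds of at least 0.6 s rise slowly to 5° (just below the range), take a
  smooth 7th-order-smoothstep transition onto a plateau drawn uniformly in
  [10°, 20°], and return symmetrically; the transition samples that fall
  inside the range are counted against the plateau so the run is exact.
* Shorter holds use a slow, low "graze" bump (width ≈ hold + 0.7 s) whose
  peak is tuned by bisection to sit just far enough above 6° that exactly
  the required number of samples is in range. The bump is slow, so its
  high-frequency leakage is negligible even though the excursion is brief.

Measured leakage is below 0.004° SD at every hold length — an order of
magnitude under the default jitter amplitudes. Band-limited noise is made
by high-pass filtering white noise with the same 10 Hz filter and rescaling
to the requested SD, so the measurement pipeline recovers `jerk_sd` within
a few percent (the second filter pass slightly attenuates transition-band
content, biasing recovery ≈ 6% low — well inside the 20% validation
band).

Two deliberate artifacts: the trial record stores the sampled,
grid-quantised hold time and classifies from it, because added in-band
noise can momentarily cross the 6° boundary and split the measured
in-range run (the graze bump's flat peak makes this certain rather than
rare); recomputing holds from *noisy* stored trajectories is therefore not
meaningful, while noiseless synthesis reproduces the hold to within one
sample. And entries of different mice may overlap in time (one physical
chamber is not modelled); per-mouse entries never overlap.

What the simulator does **not** emulate — so passing tests cannot certify
it on real data: circadian structure (entries are uniform within a day),
lever biomechanics and paw kinematics, satiety feedback from the free-water
top-up (`free_water_deficit()` is computed and logged but does not change
behavior), inter-individual parameter spread beyond the two presets, and
any real mechanism of social influence (see below).

## Trial-to-trial variability

Dynamic time warping (classic dynamic programming, unit steps, absolute
local cost, no window) measures dissimilarity between consecutive-trial
trajectories; a moving SD over 5-trial centred windows (truncated at the
edges) measures local hold-time variability. Both are z-scored within
mouse over the trials entering a given analysis, because raw magnitudes
scale with trial duration. Three event-aligned views:

* **Requirement increases:** the 5 trials before and 15 after each upward
  change (by trial index, crossing entry boundaries), with per-offset
  success, DTW-z and moving-SD-z; mice that never left the initial
  requirement are excluded by construction.
* **Window bouts:** runs of ≥ 10 trials within 5 minutes, detected by a
  greedy left-to-right scan (a bout starts where the next 10 trials span ≤
  300 s, extends while the trailing 10-trial span stays within 300 s, and
  is consumed without overlap); DTW-z is averaged at within-bout positions
  1–10, position 1 pairing with the last pre-bout trial.
* **Outcome runs:** 5 consecutive same-outcome trials spanning ≤ 150 s;
  longer same-outcome stretches contribute only their first 5-trial window
  to avoid double counting; the 4 pair distances are averaged by position.

DTW deliberately has no triangle-inequality property; tests assert only
identity, symmetry and the exact dynamic program against an
exhaustive-path oracle. Spread-free inputs (identical trajectories) make
z-scores undefined; the functions flag these as degenerate rather than
returning zeros.

## Engagement and social structure

Daily engagement metrics (trials, entries, time in chamber, trials per
entry, success rate) and the entry-bout analysis (bout = consecutive trials
within one chamber entry; histogram capped at size 14 with larger bouts
pooled) are standardized to the first 58 days in replication mode, the
package's default analysis window.

The follower–influencer motif detector scans every ordered pair of mice
for baseline → influencer → return bout triplets (each ≥ 10 trials within
5 minutes, inter-bout gaps ≤ 5 minutes, greedy in time, no bout reuse
within a pair). A bout's success rate uses its first 10 trials — the
criterion size — by default (`sr_first_n = 0` switches to the full run).
Influencers above the follower's baseline are "good", at-or-below are
"bad"; the statistic is the baseline-normalised change
$\Delta = (SR_{after} - SR_{base})/SR_{base}$, undefined (and excluded
from means, but counted) when the baseline is zero. Solitary controls are
two qualifying bouts of one mouse 5–15 minutes apart with no intervening
qualifying peer bout.

**A statistical caution that the package surfaces deliberately:** the
good-influencer mean of $\Delta$ is *positively biased under the null*.
Conditioning on $SR_{infl} > SR_{base}$ selects events with low baselines,
and $E[1/SR_{base}] > 1/E[SR_{base}]$ regardless (Jensen); Monte Carlo with
iid Binomial(10, $p$)/10 bout rates puts the conditioned null mean at
about +0.71, +0.46, +0.23 and +0.12 for $p$ = 0.3, 0.5, 0.7 and 0.9. No
detector can report a zero-centred good-influencer $\Delta$ under the
null, and the test suite's corresponding zero-mean assertion is expected
to fail — it is kept, with a comment, as an honest record. What *can* be
certified, and is, via an exact permutation null (shuffling the return-bout
rates across detected events): the detector introduces no bias beyond the
statistic's intrinsic one. Substantive comparisons should therefore
contrast good-influencer events against bad-influencer and solitary-control
events, which share the ratio's bias — exactly the contrast
`influence_summary()` tabulates.

The simulator's optional coupling (`influence_gain`) lowers an agent's
untimed weight for the bout following a ≥ 10-trial bout by a
higher-success peer within the preceding 5 minutes. It is a stand-in for
exercising the detector, not a mechanistic claim; it is off (0) in both
presets.

## Reproducibility and problem sizes

Every stochastic component consumes one seeded RNG stream, so a fixed
`sim_config()` seed reproduces a session log bit for bit, and
`save_session()` writes numbers with 17 significant digits so
`load_session()` round-trips exactly. `run_pipeline()` writes analysis
CSVs with 9 significant digits in fixed column orders plus a manifest
(package version, seed, configuration, input digest); re-running on the
same input reproduces byte-identical files.

The shipped validation runs at deliberately chosen scales: two agents over
58 simulated days for closed-loop checks (~19,000 trials), daily mixture
fits at $n \approx 150$ and recovery studies at $n = 2000$ over 50 seeds,
20 three-day two-agent cages for the social null, and full enumeration of
DTW against the path oracle for all sequence pairs up to length 4 over a
three-letter alphabet. These sizes make the whole suite reproducible on a
single CPU in minutes while keeping every statistical check at the scale
the daily analyses actually operate on.
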