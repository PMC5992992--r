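---
title: "Methods: fluctuation analysis of glycinergic currents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fluctuation analysis of glycinergic currents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyrfluct)
```

# Scope and model

`glyrfluct` analyses glycine-receptor (GlyR) mediated chloride currents
recorded in whole-cell voltage clamp at a holding potential of −70 mV, where
glycinergic currents are inward. Inward current is stored **negative**
throughout; every reported amplitude, mean current and unitary current is a
magnitude. This single stated convention is enforced at the container level
(`trace()`) to avoid sign bugs.

The physical model underlying the simulator and the noise analysis is an
ensemble of $N_c$ identical, independent two-state (closed ↔ open) channels
with opening rate $k_+$, closing rate $k_-$ and unitary current $i_u$. At
stationarity the open probability is $P_o = k_+/(k_+ + k_-)$ and the
ensemble current obeys the binomial moment relations

$$\sigma^2 = i_u^2 N_c P_o (1 - P_o), \qquad I_m = i_u N_c P_o,$$

which combine into the variance–mean parabola

$$\sigma^2(I_m) = i_u I_m - I_m^2 / N_c .$$

Gating relaxes exponentially with time constant $\tau = 1/(k_+ + k_-)$, so
the current noise has a Lorentzian one-sided spectrum
$S(f) = S_0 / (1 + (f/f_c)^2)$ with corner frequency $f_c = 1/(2\pi\tau)$.

# Synthetic data generator

The generator exists so that every analysis stage can be tested against
recorded ground truth. Its defaults describe the stated experimental world:
20 kHz sampling with an optional 2 kHz low-pass mirroring a typical
acquisition chain, Gaussian baseline noise of 2–3 pA SD, and seeds that are
**mandatory** — an absent seed is a configuration error, never an implicit
default.

*Channel ensembles.* Channels are simulated exactly: the number of open
channels is an aggregate birth–death Markov chain with jump rates
$(N_c - k)k_+$ upward and $k k_-$ downward, simulated with exact exponential
waiting times and then sampled onto the trace grid. This aggregate chain is
equal in law to per-channel Gillespie simulation (superposition of
independent two-state chains) at a fraction of the cost, and its exactness
is what makes the analytic binomial/Lorentzian oracles valid tests. For
slowly changing agonist applications, `simulate_glycine_application()`
rescales $k_+(t) = k_- \, p(t)/(1-p(t))$ so the instantaneous open
probability tracks a prescribed profile ($k_-$ fixed); time variation is
handled by exact thinning against a state-dependent rate bound, not by
Euler stepping. Profiles are capped at $p = 0.95$ to keep the rates finite,
and the config invariant `sampling_rate >= 10 (k_+ + k_-)` keeps gating
resolvable on the grid.

*Miniature IPSCs.* Event onsets form a homogeneous Poisson process; each
event is a peak-normalized biexponential
$A\,(e^{-t/\tau_d} - e^{-t/\tau_r})$ scaled so its extremum is $A$.
Amplitude jitter is log-normal (positivity guaranteed; no distribution is
prescribed by the experimental literature we emulate) with mean `amp_mean`
and coefficient of variation `amp_cv`. The template's default time
constants (0.5 ms rise, 5 ms decay) are fixture choices typical of
glycinergic mIPSCs in brainstem motoneurons, not measured values.

*Dose–response tables.* Per cell and concentration, the Hill curve
$I = I_{max} C^{n}/(C^{n} + EC_{50}^{n})$ times multiplicative log-normal
noise (default CV 8%, matching realistic cell-to-cell scatter at 7–11 cells
per concentration).

*Tonic block.* A stationary ensemble runs to `block_onset`, after which all
channels are forced closed — an idealized full block by a saturating
antagonist (e.g. 2 µM strychnine) — leaving pure baseline noise.

What the generator does **not** emulate: series-resistance and dendritic
filtering, correlated channels, multi-state receptor kinetics,
desensitization, seal drift, or line noise. A green parameter-recovery test
therefore establishes correctness of the estimators under the stated model,
not robustness to every pathology of real recordings. Baseline noise is
modeled white and Gaussian; recording-noise spectra of the original
hardware are unknown, and this choice is flagged rather than asserted.

# Miniature IPSC detection and kinetics

Detection is the classical optimally-scaled-template method: a
biexponential template is slid along the (sign-inverted) trace, at every
offset the least-squares optimal scale (with a free baseline offset) is
computed in closed form, and candidate events are local maxima of the
fitted amplitude that reach `threshold_sigma` × σ_noise. The threshold
default is 5.5 σ, the midpoint of the conventional 5–6 σ band, and the
comparison is boundary-inclusive. σ_noise is the median absolute deviation
(× 1.4826) of the high-pass residual of event-free baseline, chosen either
explicitly or automatically as the lowest-variance decile of 500 ms
windows (robust to sparse events).

Kinetic measurement follows standard definitions — baseline from the 5 ms
before onset, peak as the extremum of the baseline-subtracted signal in the
event window (onset to onset + 5 decay constants), 10–90% rise and 90–10%
decay times from threshold crossings with linear interpolation. Three
numerical choices matter under noise and are deliberate:

* the **peak location** is found on a 1 ms boxcar-smoothed copy and the
  **amplitude** is the raw-signal mean over ±0.25 ms around it. The raw
  maximum of signal-plus-noise is biased upward by the noise extreme value
  (≈ +20% at SNR 10); the local mean is unbiased, and the waveform
  attenuation is below 0.5% for millisecond-scale decays;
* **decay crossings** are measured on the smoothed copy: the decay is slow
  relative to 1 ms, so distortion is negligible, while the raw first
  crossing under noise fires systematically early;
* **rise crossings** stay on the raw signal — the rising limb is fast and
  smoothing would broaden it genuinely.

Acceptance filters mirror the practice of analysing only non-overlapping
events with fast rise times and a smooth decay: events whose window
(onset to completion of the decay to 10%) contains another onset are
rejected pairwise as `overlap`; rise ≥ 2 ms is `slow_rise`; a decay is
`rough_decay` when a smoothed post-peak sample exceeds the peak by more
than max(2% of peak, 3 σ_noise) or when the RMS residual of a
mono-exponential fit to the decay exceeds 15% of the peak (both thresholds
configurable). Frequency is computed from **all** detected events while
kinetic averages use accepted events only — the underlying experimental
convention is not documented, so both counts are always reported — and
kinetic averages are flagged invalid below 20 accepted events.

# Stationary noise analysis

`compute_variance_mean()` splits the record into consecutive 100 ms
windows. Per window, $I_m$ is the DC mean relative to the control holding
current, and $\sigma^2$ is the power of a band-passed (default 1 Hz – 2 kHz,
zero-phase) AC copy; the control background power is subtracted, and
windows that go negative are flagged, never silently dropped. Two numerical
choices deserve emphasis:

* variances are **mean squares of the AC signal**, not window-local sample
  variances. The AC signal is already zero-mean by construction, and
  subtracting window-local means (or detrending) of autocorrelated gating
  noise shrinks the variance by roughly $2\tau/T$ per removed degree of
  freedom — a ≈ 10% downward bias on $i_u$ at $\tau \approx 3$ ms and
  $T = 100$ ms. Local detrending remains available (`detrend = TRUE`) but
  is off by default for this reason;
* the background is computed on the **control segment filtered in
  isolation**, so a sharp transition at the control/drug boundary cannot
  leak high-passed transients into it. The same segment-wise filtering is
  used by the tonic stage, whose antagonist step is a genuine discontinuity.

The parabola is fitted by weighted least squares through the origin
(weights ∝ 1/σ⁴, the inverse expected variance of a variance estimate;
plain least squares available), which is linear in $(i_u, -1/N_c)$. The fit
is rejected — raising a typed condition that triggers the linear fallback
$i_u = \sigma^2 / I_m$ on the initial 30% of the current range — when the
curvature is non-negative, numerically degenerate, or statistically
indistinguishable from zero (95% interval covering zero). This mirrors the
experimental reality that not every cell yields a satisfactory parabola.
$P_o$ follows from the peak current via $I_{peak}/(i_u N_c)$; values in
(1, 1.05] are clamped to 1 with a warning, anything larger is an error.
Variance–mean points are used unbinned; binning by current level is not
applied (windows are already the averaging unit), which is recorded here as
a deliberate resolution of an open design point.

# Spectral analysis

PSDs are averaged modified periodograms (Hann window, 50% overlap, segment
mean removed, 8 s segments by default for sub-0.5 Hz resolution),
normalized so the one-sided integral equals the segment variance (checked
as a Parseval invariant at 5%). The net spectrum is drug minus control,
truncated below 200 Hz — the band carrying gating information at these
relaxation times. Negative net points are excluded from fitting with a
logged count. Lorentzian fits minimize squared residuals in **log-power**
space because periodogram errors are multiplicative; single and
two-component fits are compared by an extra-sum-of-squares F-test at
α = 0.05 with parsimony favouring the single component, and two-component
fits whose corners collapse within 5% are treated as degenerate and fall
back to the single description. The weighted time constant of a double fit
is $\tau_w = \tau_1 S_{01}/(S_{01}+S_{02}) + \tau_2 S_{02}/(S_{01}+S_{02})$,
and $\tau = 1/(2\pi f_c)$ holds identically for every returned fit.

# Pharmacology

Dose–response fitting averages peak currents per concentration across
cells, then fits the Hill sigmoid with free slope and free maximum by
`nls` (port algorithm with broad positivity bounds; a log-parameter
Nelder–Mead fallback flags itself). The Hill form is the standard
pharmacological sigmoid and nests the simpler logistic uses; neither slope
nor bottom asymptote is constrained, and a per-cell (unaveraged) fit is
exposed as an option for when the two differ materially. Peak currents are
read from a 50 Hz low-passed, baseline-subtracted trace (baseline: 5 s
before application).

The tonic stage quantifies standing inhibition as the change in holding
current and in band-passed current variance between a 10 s pre-drug window
and a 10 s post-drug window separated by a 5 s equilibration gap (the gap
length is a package choice; the source protocols do not state one). For a
fully blocked two-state ensemble both deltas equal the stationary binomial
moments, which is the basis of the package's parameter-recovery tests.

# Behavioural statistics and genotyping

Escape-behaviour tables (conditions × {normal, mild, severe}) are
summarized as integer percentages by **largest-remainder (Hamilton)
rounding**, which guarantees rows summing to 100; plain nearest-integer
rounding provably fails to reproduce the published example tables (43/79 →
54.4 rounds to 54, printed 55). Pairwise condition comparisons use Pearson
χ² on 2×2 tables (chosen category vs all others, 1 df, no continuity
correction), with stars at p < 0.05 and p < 0.001 and a warning flag when
an expected cell falls below 1; a full-distribution (2 df) mode is exposed
because the original "quadrate test" is not further specified. Note that
three cells of the published significance matrix for the "normal" category
are not derivable from the published counts under any standard χ² variant
(the corresponding acceptance check is deliberately left failing rather
than fudged; see the test suite).

In-silico genotyping locates all, possibly overlapping, occurrences of the
HpyCH4V recognition sequence TGCA (cutting TG^CA, a blunt cutter; site and
offset are configurable since they come from standard enzyme catalogues,
not from the emulated study) and reports fragment lengths, 0-based cut
offsets and a cut/uncut genotype call. Fragment lengths always sum to the
input length, and because TGCA is its own reverse complement, digesting the
reverse strand mirrors the cut positions exactly. The packaged amplicon
FASTA files are **synthetic** stand-ins (random backbone with the
documented heptamer contexts embedded); the true genomic amplicon is not
redistributed.

# Pipeline and reproducibility

`run_pipeline()` chains simulate → detect → noise → spectrum → dose →
tonic for a labelled genotype/age configuration, writes per-stage artifacts
and a JSON report with provenance (seed, config hash, package version),
and is bit-deterministic under a fixed seed; per-stage seeds are derived
from the master seed. The default "wildtype" and "mutant" parameter sets
are qualitative fixtures chosen to reproduce the direction of the
startle-disease contrasts (reduced mIPSC frequency/amplitude, faster decay,
halved peak open probability, right-shifted EC50, absent tonic current) —
they are not fitted to any dataset. The `glyrfluct` executable dispatches
the same functionality as subcommands with CSV/JSON (and optionally YAML /
HDF5, when the `yaml` / `rhdf5` packages are present) interfaces.

# Known limitations

* FFT-based zero-phase filters are circular; edge effects span roughly one
  cutoff period at each trace end. All analysis windows used by the
  package sit well inside the records this matters for.
* The two-state simulator cannot represent bursting or multi-conductance
  channels, so spectral fits on real GlyR data may genuinely need the
  two-Lorentzian branch even though the simulator's single-relaxation
  world rarely does.
* Noise-analysis recovery was validated for ramp speeds slow relative to
  the channel relaxation time (quasi-stationarity); fast applications
  violate the windowed-stationarity assumption in ways the tests do not
  probe.
* EC50 standard errors come from the per-concentration-mean fit and ignore
  cell-level variance heterogeneity; the per-cell fit option is the remedy
  when that matters.
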