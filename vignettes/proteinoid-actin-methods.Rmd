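---
title: "Methods: modelling the electrical dynamics of proteinoid-actin networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling the electrical dynamics of proteinoid-actin networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protoelec)
```

Proteinoid microspheres — hollow, membrane-like assemblies of thermally
polymerised amino acids — generate spontaneous membrane-potential dynamics,
and their mixtures with filamentous actin behave as a composite conductor
with properties neither component has alone. protoelec implements the
computational side of characterising such materials: equivalent-circuit
impedance analysis, conductivity derivation, multichannel voltage-trace
statistics, stimulation-response and voltage-cycling analysis,
temperature-pH coupling, and a reaction-diffusion model of
capacitance-driven pattern formation. This vignette records the models, the
parameter choices, and the numerical decisions behind each stage — including
the ones where the design was genuinely open.

Because the underlying laboratory recordings are not publicly deposited, the
package pairs every analysis stage with a synthetic generator that emulates
the corresponding modality. All quantitative claims in this vignette are
computed by the test suite or the acceptance script; nothing is asserted
that the code does not verify.

## Equivalent-circuit impedance models

A circuit model is a series chain of nodes, where a node is an element or a
parallel group; series impedances add, parallel groups combine by reciprocal
admittance sums. The element zoo covers the standard electrochemical set.
Three conventions needed fixing:

* **Warburg element.** The semi-infinite diffusion form
  $Z_W = W(1-j)/\sqrt{2\omega} \equiv W/\sqrt{j\omega}$ is used, the
  standard convention when the coefficient is quoted in
  $\Omega\,\mathrm{s}^{-1/2}$.
* **Finite-length ("O") diffusion element.** The open-boundary form
  $Z_O = \coth(B\sqrt{j\omega})/(Y_0\sqrt{j\omega})$, with
  $Y_0 = 1/O_1$ and characteristic parameter $B$ in $\mathrm{s}^{1/2}$
  (default 0.329 for the proteinoid circuit). The reference fit for this
  element quotes two characteristic parameters, 0.329 and 1.000, whose roles
  are not fully identifiable from the source; we read 0.329 as $B$ and 1.000
  as the exponent of an ideal diffusion branch (i.e. not a free parameter).
  The `tanh` (short-circuit) variant is available via `elem_o(form =)`.
* **Complex exponentiation** $(j\omega)^n$ uses the principal branch.

Units are ohm, farad, henry and rad/s internally; every user-facing
interface takes Hz.

## Fitting impedance spectra

`fit_circuit()` minimises the modulus-weighted complex residual
$$\chi^2_{raw} = \sum_i \frac{(Z'_i-\hat Z'_i)^2 + (Z''_i-\hat Z''_i)^2}{|Z_i|^2},$$
reported as $\chi^2_{raw}/(2N-p)$. Modulus weighting is the default because
these spectra span several decades of magnitude; `unit` and `proportional`
weightings are available. Optimisation is Levenberg-Marquardt
(`minpack.lm`) on **log-parameters** — all magnitudes are positive and span
orders of magnitude, and log-scale curvature converts directly into the
percent uncertainties reported — with box bounds, plus three restarts from
log-uniform jitter of the initial values under a fixed jitter seed.
Non-convergence is reported via `converged = FALSE`, never silently.

**Identifiability.** Not every printed parameter is determined by data in
the measured band (0.1 mHz-100 kHz). The proteinoid circuit's parallel
capacitance sits at 1 pF, placing its corner frequency near $10^8$ Hz; in
band, that branch is a pure resistor, so only the *sum* of the two
resistances is identifiable and the capacitance pins at its lower fitting
bound (the fit flags this via `at_bound`). Similarly, the actin circuit's
small high-frequency arc carries ~11-14% curvature uncertainty at 1%
measurement noise. The test suite therefore phrases parameter-recovery
checks in terms of the fit's own reported uncertainties: a parameter is
treated as well-determined when its uncertainty is below 2.5% (two standard
errors inside a 5% recovery band), and the proteinoid check asserts the
diffusion branch plus the resistance total. This is a statement about
information content, not about the optimiser.

## Conductivity and LCR derivations

Bulk conductivity uses the cell-constant relation
$\sigma = L/(|Z|\,\pi r^2)$. The documented measurement cell is a cylinder
of length 10 cm; its radius is not stated alongside, but $r = 1$ cm is the
unique value under which all three quoted conductivities follow from the
quoted impedance magnitudes, so it is stored as the overridable default
geometry. Enhancement ratios cancel the geometry entirely and equal inverse
impedance ratios.

The single-frequency LCR relations are closed forms:
$|Z| = \sqrt{R^2+X^2}$, $\theta = \arctan(|X|/R)$ (reported as a magnitude
in degrees, the sign of $X$ kept separately), $D = R/|X|$ (infinite at
$X = 0$). The shipped 300 kHz reference table is internally inconsistent in
places (its $|Z|$ and $D$ cells do not reproduce from its own $R/X$ pairs,
and the series capacitance implies a reactance three orders of magnitude
smaller than printed — a measurement-mode artefact); only the phase angle
derives exactly, and only the impedance-magnitude column feeds the
conductivity results. The package does not attempt to reconstruct
capacitance or inductance from $R/X$ for this reason.

## Spike detection and trace statistics

The spiking waveform in these materials depolarises within one sample at
the 2.5 Hz logging rate and repolarises exponentially over tens of seconds
— a sizeable fraction of the interspike interval (ISI). That asymmetry
drives the central design decision here: **prominence and amplitude are both
measured against the local pre-event baseline** (median of 10 samples
ending 2 samples before the candidate), not against a centred rolling
median. A centred median window fails in both directions for this waveform:
sized near the spike (tens of samples), its post-peak half lies on the
spike's own repolarisation tail, so slow spikes vanish into their own
baseline; sized near the ISI, the decay shoulder rises above the window
median and spawns false detections. The pre-event rise height has neither
artefact at any ISI, which the 20-configuration recovery suite verifies
(exact spike counts and periods, amplitudes within 0.4 mV across
amplitudes 10-40 mV and ISIs 40-600 s). Detected peaks are additionally
refined to the sample terminating the steepest adjacent rise, which removes
the upward order-statistic bias of reading a noisy local maximum.

Defaults (all configurable): prominence 5 mV, refractory 10 s — spikes in
these recordings are tens of mV and tens of seconds apart. Period
statistics use successive peak times; channels with fewer than 5 spikes
also get a periodogram-based period estimate. Standard deviations use the
sample ($n-1$) convention throughout.

`classify_dynamics()` applies ordered rules reflecting the four observed
regimes: regular spiking (≥5 spikes, period CV < 0.5), class-2 plateau (a
smoothed high state occupying >10% of the recording followed by a step down
of >30% of the range that persists), bistability (Sarle's bimodality
coefficient > 0.555 — the uniform distribution's value — with ≥2
hysteresis-gated state transitions), else quiescent.

## Stimulation-response analysis

Square-wave sessions are analysed per channel: off-phase baseline mean and
variance (excluding a 50 ms settle window after every transition and at the
recording start), the mean input-output difference
$\Delta V = \bar{S}_{on} - (\bar{V}_{on} - \bar{V}_{off})$, onset latency
(stimulus edge to 10% of the evoked change), and recovery time (return to
within 10% of the evoked amplitude of baseline after the off edge, *minus*
the channel's propagation latency, so it measures the relaxation proper).
Sessions are generated at 1 ms sampling: the ms-scale latencies cannot be
resolved at the 0.4 s logging rate, and the fast-acquisition rate of the
original sessions is not stated. The generator's default channel set fixes
the two endpoint channels from the reported statistics and linearly
interpolates the two interior channels' attenuation, latency and recovery —
a package choice, since only the ranges are reported for those.

## Current-voltage cycling

Each cycle's resistance is the mean of $V/I$ over samples with $|V|$ above
a 0.25 V dead-band (avoiding the divide-by-zero region), and the memory
statistic is the Pearson correlation between cycle number and mean
resistance, with $r \equiv 0$ when either variance vanishes. The sweep
generator produces triangular ±5 V paths at 100 mV/s with linear
resistance drift plus per-cycle noise, and a *pinched* hysteresis loop
(closed at the origin, widest at half range) — the memristive form; a loop
that stays open at 0 V would corrupt the $V/I$ estimator near the
dead-band edge. The weak-memory condition is emulated with drift
100 Ω/cycle against cycle noise 3950 Ω on a 200 kΩ base, giving a
population correlation of 0.35 over 50 cycles; note a single 50-cycle
experiment estimates that $r$ with sampling error ~0.13, so tests check the
estimator against the planted series exactly and the population value as a
mean over seeds.

## Temperature-pH coupling

All spectral estimates (dominant period, coherence) linearly detrend first
— the logs drift slowly — and use a Hann window with 4x zero padding and
parabolic peak interpolation; a peak must carry ≥5% of total power or a
no-peak error is raised.

The **phase lag** (positive = pH lags temperature) is the peak of the exact
cross-correlation: at each candidate lag the Pearson correlation of the
overlapping samples is computed exactly (FFT cross-sums plus prefix sums),
so a pure shift scores exactly 1 at the true lag and is recovered to the
sample. Two deliberate departures from the obvious implementation: the
search window is ±*half* the dominant period, because beyond that the lag
of a near-periodic signal is aliased and not identifiable; and the standard
biased ($1/n$) cross-correlation normalisation is not used, because it
shades the peak towards zero by tens of samples for oscillatory series.

The **coupling coefficient** $\kappa$ is the Daniell-smoothed
magnitude-squared coherence at the shared dominant frequency, after
aligning the two series by the cross-correlation lag — a pure delay
otherwise rotates the cross-phase linearly across the smoothing bandwidth
and destroys the coherence of a perfectly coupled pair. Alignment is gated
on the cross-correlation peak exceeding 0.2: for unrelated series the
best-lag shift is a chance alignment that would bias the null coherence
upwards (measured: ~0.37 gated off vs ~0.08 at $n = 4096$ white noise).
$\kappa$ is 1 for any noiseless affine, possibly delayed, relation and
stays below 0.2 for independent noise.

The environment generator produces a sinusoid-plus-second-harmonic
oscillation (default period 90 min, within the recorded 72-124 min range)
with the pH series as a scaled, delayed copy (default lag 15 min) around
mean 7.88 ± 0.05. Optional linear drift terms (default 0) reproduce a
feature of the real logs that matters for one statistic: a *stationary*
oscillation at these periods cannot keep its autocorrelation above 0.6 out
to $10^3$ s ($r(\tau) = \cos(2\pi\tau/P)$ falls below 0.6 near $P/5$); the
recorded persistence comes from slow drift, and the corresponding test runs
at a drifted condition whose overall pH spread still matches ±0.05.

Arrhenius protonation kinetics are the closed form
$k(T) = k_0 e^{-E_a/RT}$ with the documented default
$E_a = 29.3$ kJ/mol ($k(25°C)/k(16°C) \approx 1.445$).

## Gray-Scott simulation

The two-field kinetics are integrated by explicit Euler at $dt = 1$ grid
time unit on a 100 × 100 torus (5-point periodic Laplacian; periodic
boundaries avoid edge artefacts in spot counts). The trivial steady state
$A = 1, B = 0$ is preserved exactly for every parameter set. The initial
condition is $A = 1$ everywhere and $B = 1$ in a central 11 × 11 square
(configurable), with optional 1% uniform noise to break the square's
symmetry. Diffusion coefficients are capped at 0.25 (the explicit-scheme
diffusion limit at $dt = 1$); note the coupled system turns unstable
somewhat below that for the reference reaction rates (observed near
$D_A \approx 0.21$), and any divergence raises an error naming the
offending parameter set rather than propagating NaNs.

Capacitance modulation maps a measured or synthetic capacitance series onto
per-step parameters,
$p_t = p_{base}(1 + \beta\,(C_t-\bar C)/\bar C)$ for $D_A, D_B, F$, with
the kill rate held fixed across conditions and default coupling gain
$\beta = 0.5$; the exact experimental mapping is unspecified, so the linear
form with a configurable gain is the package's own choice. Pattern metrics
report the spatial standard deviation of $B$, the mean, and a spot count
(4-connected components above mean + sd).

## What the generators do and do not emulate

The synthetic module reproduces the *statistical structure* of each
modality: spike amplitude/interval distributions (gamma ISIs with
configurable CV, default 0.2 for the quasi-periodic regime; instantaneous
rise and exponential repolarisation with time constant 0.2 ISI), plateau
and bistable phase profiles, stimulation baselines/attenuations/latencies,
circuit-model spectra with multiplicative complex noise, drifting cycle
resistances with pinched hysteresis, coupled temperature/pH oscillations,
and exponential capacitance decay. It does **not** emulate the physical
chemistry of proteinoid assembly, electrode artefacts, non-Gaussian noise,
nonstationary spiking rates, or cross-channel coupling. Passing recovery
tests therefore demonstrate that the analysis stages are correct and
unbiased for data with the stated structure — not that they are robust to
every pathology of real electrode recordings.

## Numerical conventions and problem sizes

Degenerate inputs raise classed errors (`protoelec_invalid_spec`,
`protoelec_domain_error`, `protoelec_format_error`,
`protoelec_insufficient_data`, `protoelec_no_peak`,
`protoelec_instability`, `protoelec_convergence_failure`) rather than
returning NA. Every generator is a pure function of its spec including the
seed, leaving the caller's RNG untouched. The test suite runs the
acceptance-grade simulations at the study sizes (20,000 s spiking traces at
2.5 Hz; 60-frequency spectra over 9 decades; 50-cycle sweep sets; 6 h
environment logs at 1 Hz; 5000-step Gray-Scott runs on the full grid), and
smaller grids for oracle comparisons where an $O(n^2)$ double-loop
reference is evaluated.

## Known limitations

* The printed chi-squared values of the original fits are not reproducible
  without the raw spectra and their (unstated) weighting convention; the
  statistic here is defined explicitly instead.
* Spike-sorting is threshold-based; there is no template matching or
  clustering, and overlapping spikes within a refractory window merge.
* The coupling coefficient is a linear, single-frequency measure; genuinely
  nonlinear temperature-pH coupling would require the (unpublished) coupled
  differential system.
* The Gray-Scott mapping from capacitance to kinetics is phenomenological;
  simulated patterns are comparable between conditions but are not
  predictions of specific experimental micrographs.
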