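---
title: "Analyzing operant reward seeking: schedules, dopamine signals, encoding patterns, tensors, and demand curves"
author: "operantNeuro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing operant reward seeking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operantNeuro)
```

# Scope and design

`operantNeuro` implements the analysis chain of a rodent reward-seeking
experiment in which animals work for food pellets or intravenous opioid
infusions under fixed-ratio (FR), progressive-ratio (PR), behavioral-economic
demand, and go/no-go schedules, while nucleus accumbens (NAc) activity is
monitored by fiber photometry (a dopamine sensor plus an isosbestic control
channel) or multi-electrode single-unit recording. Every stage is exercisable
on seeded synthetic data with planted ground truth, so the full pipeline is
testable without recordings.

The containers are S4 classes (`TrialEvents`, `PhotometryRecording`,
`SpikeSession`, `TrialTensor`, `CPModel`, `DemandFit`, `ClusterModel`) with
validity methods and accessors; analysis results are lightweight lists with
print methods.

# Task schedules

The PR response requirement for trial $i$ is
$\mathrm{round}(5e^{0.2 i}) - 5$, which reproduces the task's printed
16-ratio sequence (1, 2, 4, 6, 9, 12, 15, 20, 25, 32, 40, 50, 62, 77, 95,
118) exactly and extends it beyond trial 16. Whether the in-lab progression
past trial 16 followed the same rule is not documented; we adopt the
generating rule as the natural extension and expose the progression as data.
A PR session ends at the first 10-minute window without a reward; we
implement this as a sliding window measured from the last reward (or session
start), reset at each reward.

```{r pr}
prRequirementSequence(16)
```

Demand sessions divide into fixed-price bins: descending food prices
(180, 90, 45, 15, 5 lever presses per pellet, 10-min bins, chosen to avoid
satiation early in the session) and the ascending remifentanil ladder
(6, 10, 16, 25, 40, 63, 100, 158). Go/no-go sessions present 64 trials, 32
go and 32 no-go, pseudorandomized in blocks of 10--11 trials; we draw block
sizes (two of 10, four of 11), assign near-balanced within-block class
quotas summing to 32/32, and shuffle within blocks under the session seed —
the exact in-lab randomization scheme is unstated, so any scheme satisfying
the block and quota constraints is admissible.

`simulatePRSession()` drives a deliberately simple agent — homogeneous
Poisson pressing with an optional quit rule once the requirement exceeds a
persistence limit. It is scaffolding for generating event streams with
realistic trial counts and timing, not a model of behavior.

# Synthetic data: the stated world

Each generator is a pure function of its specification and seed
(bit-identical replay) and attaches its ground truth to the output.

**Photometry** (`genPhotometrySession`). Both channels share a
multiplicative exponential bleaching trend (default time constant 1200 s)
and an additive band-limited motion artifact (white noise low-passed at
2 Hz, amplitude 2% of baseline, channel-specific gain); dopamine transients
ride only on the 470-nm channel as difference-of-exponentials kernels (rise
0.1 s, decay 0.5 s — typical of the sensor's kinetics), with amplitude in
$\Delta F/F$ fraction. Sampling defaults to 100 Hz (the acquisition rate is
not documented; configurable). The generator does not model hemodynamic or
pH confounds, wavelength-dependent bleaching differences, or sensor
saturation — a green detrending test therefore establishes correct artifact
regression, not robustness to every artifact class real fibers produce.

**Spike sessions** (`genSpikeSession`). Units are inhomogeneous-Poisson with
baseline rates uniform on 2--10 Hz and one planted profile each:
cue-activated or -inhibited (modulation over 0--2 s after cue onset),
reward-activated or -inhibited (2--6 s), press-inhibited (1--4 s), or
nonencoding. Activated units multiply their rate by `gain` (default 3)
inside the window; inhibited units suppress to 15% of baseline. The
modulation kernel is a plateau with 15% cosine ramps, so the
window-averaged rate of a gain-3 unit is close to 3x baseline. A
`trial_drift` function scales modulation across trials to emulate declining
cue responses. Spikes come from thinning, so the planted intensity is exact.

**Trial tensors** (`genTrialTensor`). $X = \sum_r w_r \circ b_r \circ a_r +
\varepsilon$ with smooth within-trial bumps/dips staggered inside the cue
(0--2 s) and reward (2--7 s) windows, monotone or flat trial trends, and
non-negative unit loadings. Two structural choices matter and are made once:
components have equal Frobenius norm (assemblies of comparable strength),
and each unit loads predominantly on one assembly (loading ~1 on its own,
~0.1 background), balanced within treatment groups. This mirrors the
discrete encoding patterns that clustering finds in such data, and it is
what makes the planted components identifiable: with heavily overlapping
loadings, under-factored CP fits collapse onto a unique blended solution
and rank selection has nothing to detect. Noise is i.i.d. Gaussian; `snr`
sets its sd as (signal sd)/snr, with SNR 5 the default.

**Demand observations** (`genDemandObservations`). Consumption follows the
exponential model of demand exactly, perturbed by multiplicative lognormal
noise (consumption is positive and count-like); additive noise is available
behind a flag.

# Photometry processing

Artifact correction scales and regresses the isosbestic channel onto the
dopamine channel by OLS over the full session and reports
$\Delta F/F = (\text{signal} - \widehat{\text{iso}})/\widehat{\text{iso}}$;
a subtraction-only mode is available. Exact idempotence holds for the
subtraction mode (OLS residuals are orthogonal to the regressor); the
divide mode cannot be literally idempotent because its output is centered
near zero, so the corresponding invariant is that refitting the isosbestic
channel to a corrected trace yields a negligible slope. An optional
zero-phase Butterworth low-pass (6 Hz, order 6, the acquisition filter's
parameters) is applied forward--backward so peri-event latencies do not
shift; since no signal-processing package is available in the target
environment, the filter is designed in-package by bilinear transform as a
cascade of second-order sections with reflective padding.

Peri-event PSTHs z-score each trial against its own baseline window (-4 to
-2 s before cue onset), so the baseline mean is exactly 0 and sd exactly 1
per trial by construction; trials whose span is incomplete are dropped with
a warning. Window metrics integrate the trial-averaged trace by the
trapezoidal rule with endpoints interpolated exactly (a constant z = 1 over
a 2-s window gives AUC exactly 2 z s). Spontaneous transients are local
maxima with topographic prominence at least 1, in the trace's own units —
% dF/F for spontaneous analysis, z for PSTH-based analysis; which unit the
original threshold referred to is ambiguous, so both are supported and the
unit is the caller's choice of trace.

# Single-unit encoding patterns

Firing rates are binned at 100 ms (the kernel is documented in bins but the
bin width is not; configurable), normalized to each unit's session-mean
rate, standardized across units per time bin (within-session by default;
cross-unit pooling over sessions is the caller's concatenation choice), and
smoothed with the 8-bin, sigma = 3 truncated Gaussian kernel. The kernel
matrix is balanced to be doubly stochastic (Sinkhorn iteration), so
constant traces pass through unchanged and the trace mean is preserved at
the boundaries to numerical precision.

Four features feed the clustering: (i) the number of transients —
excursions of the trial-averaged z trace beyond a threshold in either
direction, counted with hysteresis (entry 1.5, exit 1.0) so jitter at the
threshold is one event, not several; (ii) time to first transient (span end
as sentinel); (iii) mean cue-window activity (0--2 s); (iv) mean
reward-window activity (2--7 s). The threshold default is 1.5 rather than a
round 2 because cross-unit standardization bounds trial-averaged activated
plateaus near z = 2: a threshold of 2 sits on top of the activated level and
turns features (i)--(ii) into per-unit coin flips, whereas 1.5 falls between
activated (>= 1.8) and inhibited (<= 1.1) levels.

`clusterEncodingPatterns()` grows k-means (standardized features, transient
features down-weighted by 0.5 for their threshold-derived noise, 50
restarts, seeded) and keeps the largest k that introduces a new encoding
pattern, up to `max_k` = 8. Novelty is judged on each centroid's
reconstructed PSTH profile (its cue-window level over 2 s and reward-window
level over 5 s): a centroid repeats an accepted pattern when the best match
has the same shape (cosine >= 0.9) at comparable magnitude (within about
2x). Three guards make this robust: candidates are compared against the
last accepted model (k-means is not nested, so gradual splits accumulate),
clusters below 5% of units are outlier fragments rather than patterns, and
near-flat centroids (profile RMS < 0.25 z) are the nonencoding background
separating out, never a new encoding pattern. Clusters with no appreciable
cue or reward activity are labeled nonencoding and excluded from the
reported k; units farther from their centroid than the 97.5th percentile of
within-cluster distances are likewise nonencoding. Semantic tags
(cue/reward x activated/inhibited, press-inhibited) come from the signs and
relative magnitudes of the centroid's window activities.

On synthetic sessions these defaults recover four planted patterns in
food-PR-like populations and three in drug-PR-like populations, with or
without a 20% nonencoding share; planted-profile assignment agreement
(adjusted Rand index) exceeds 0.9. With a nonencoding share present, flat
units tend to merge into the nearest weak pattern before separating, which
lowers assignment agreement without changing the pattern count — a
limitation of clustering weak patterns under population z-scoring, shared
with the in-vivo procedure.

# Tensor component analysis

`cpALS()` fits the canonical polyadic model
$X_{utp} \approx \sum_r w_{ur} b_{tr} a_{pr}$ by alternating least squares:
each sweep solves the three linear subproblems cyclically, then
concentrates component scale into the unit factors ($b_r$, $a_r$ unit-norm),
resolving the CP scale ambiguity so unit loadings are comparable across
groups. ALS is unconstrained by default (no constraint is documented for the
original fits). Numerical choices: the residual is computed directly (the
Gram-matrix shortcut cancels catastrophically when over-factored components
become collinear); a 1e-12-scaled ridge guards transiently singular
subproblems; a sweep that fails to reduce the residual at machine precision
reverts and stops, so the objective trace is non-increasing; tensors fit to
a relative residual below 1e-12 of the total energy stop as converged.

`factorSimilarity()` matches components one-to-one (exact assignment up to
rank 8, greedy beyond) on the product over modes of absolute cosine
congruences; it is invariant to component permutation and to sign/scale
rebalancing across modes.

`selectRank()` fits `runs_per_candidate` (10) independently seeded models
per candidate rank and calls a candidate converged when the mean pairwise
similarity reaches 0.8. Two facts shape the selection rule. First, small
ranks are always stable: the best blended rank-1 fit of any realistic
tensor is unique, so "smallest rank that converges" would degenerate to 1;
the informative signal is where convergence *breaks down*, so the rank is
grown until runs stop agreeing and the last converging candidate is
selected. Second, pairwise congruence cannot see a component split into
collinear copies (all copies match the single true factor in every mode),
so a run whose own components are mutually congruent (>= 0.95) is counted
as degenerate — it did not recover that many distinct components — and a
candidate fails when most runs are degenerate. Under these rules a
noiseless rank-1 tensor selects 1, pure noise selects nothing, and the
four-assembly world at SNR 5 selects 4.

Tensors are built from the PSTH pipeline above (the same smoothing and
z-scoring as the k-means analysis) truncated to the first eight PR trials,
the largest count completed by every subject, with units concatenated
across subjects. `compareGroupLoadings()` reports per-component group means
and standardized differences of the unit loadings; significance testing on
real data is left to standard tools. `predictLatencyFromLoadings()` is the
response-vigor harness: a seeded 80/20 unit split, an injected regression
strategy (boosted trees in the original; any `fit`/`predict` pair — the
default is least squares because no boosted-tree package is available in
the target environment), and the held-out Pearson correlation. The
original report's correlation on real recordings is a property of those
recordings; the harness is validated on synthetic relations only.

# Demand-curve economics

The exponential model of demand is fitted in log space,
$$\log_{10} Q = \log_{10} Q_0 + k\,(e^{-\alpha Q_0 P} - 1),$$
with $Q_0$ the demand at zero price, $\alpha$ the rate of decline in
relative consumption, and $k$ a scaling constant reflecting the data's
log10 range. The log base is 10 (standard for this framework; the source
writes an unqualified log). `k` policies: `shared_pooled` (default) sets k
to the range of log10 mean consumption, optionally over a pooled dataset;
`fixed` uses a supplied value; `per_subject` fits k freely. Zero-consumption
bins are dropped from the log-space fit by default (replacement with 0.1
reward behind a flag). Optimization is bounded L-BFGS with an analytic
gradient and five deterministic starting points, so fits are reproducible
without a seed.

Derived quantities use the standard closed forms
$EV = 1/(100\,\alpha k^{1.5})$ and
$P_{max} = (0.083k + 0.65)/(Q_0 \alpha k^{1.5})$. The $P_{max}$
approximation tracks the exact unit-elasticity price (the interior maximum
of response output $P \cdot Q(P)$) to within 8% over $k \in [1.5, 4]$,
$\alpha \in [10^{-4}, 10^{-1}]$, $Q_0 \in [5, 100]$. Two model facts bound
its use: for $k \le e/\ln 10 \approx 1.18$ demand never becomes elastic and
no maximum exists (`numericPmax()` returns `NA`), and at very high prices
the $10^{-k}$ consumption floor makes $P \cdot Q$ rise again without bound,
so the numeric check searches the elastic region only.

```{r demand}
obs <- genDemandObservations(list(Q0_true = 50, alpha_true = 0.002,
                                  k_true = 2, noise_sd = 0.05, seed = 1))
fitDemandCurve(obs, k_policy = "fixed", k_fixed = 2)
```

# Bayesian encoding-bias inference

Whether treatment shifts a unit's probability of membership in one encoding
class is tested by Bayesian logistic regression with a mixture-of-g-priors
slope: with the predictor centered, $\beta \mid g \sim N(0, g\,n/\sum z_i^2)$
(unit-information scaling) and the compound confluent hypergeometric prior
(a = 0.5, b = 2, s = 0) on the shrinkage factor $u = 1/(1+g)$, which for
s = 0 reduces to $u \sim \mathrm{Beta}(a, b)$. The intercept has a flat
prior shared by both models, so it cancels in the Bayes factor. The
substitution $u = t^2$ removes the $u^{-1/2}$ endpoint singularity,
leaving a polynomial-weight integrand for Gauss--Legendre quadrature;
coefficients are integrated by Laplace approximation per node (the default)
or by full grid integration — two genuinely different numerical routes that
the tests require to agree within 5%, alongside an external brute-force
Riemann oracle. Credible intervals are equal-tailed 95% from the
numerically marginalized posterior of $\beta$. Quasi-separated tables (an
empty cell) warn and proceed; the prior regularizes the fit. The three
classification steps (encoding vs non, cue vs reward, activated vs
inhibited) are fitted as separate conditional models on the units at each
step. Bayes factors map to Jeffreys categories (anecdotal < 3 <= moderate
< 10 <= strong < 30 <= very strong < 100 <= extreme), with BF10 < 1
classified on the reciprocal in favor of the null.

# Behavioral endophenotypes

`pcaEndophenotype()` decomposes the correlation matrix (metrics have
heterogeneous units, so covariance PCA would let one scale dominate) of the
subjects x metrics behavior table after listwise deletion; loadings are
orthonormal eigenvectors with the largest-magnitude loading of each
component fixed positive, so output is deterministic. Which exact metric
set enters is a column-selection argument, since the original enumeration
("all neuroeconomic parameters, FR1--5, and PR") is ambiguous.

# Pipeline and formats

`runPipelineConfig()` executes requested stages (simulate, photometry,
spikes, tca, demand, bias) in dependency order from a named list or JSON
file, derives per-stage seeds from the master seed, and writes a manifest
with a config hash and output checksums; identical configs replay all
stochastic outputs byte-identically. All I/O is plain text: CSV for events
(`time_s,event,trial_index`, 6-decimal seconds), spikes
(`unit_id,spike_time_s`), photometry (`signal_470,iso_405` plus a JSON
sidecar carrying the sampling rate and ground truth), and JSON for metrics
and manifests. HDF5 variants are not provided because no R HDF5 interface
is available in the target environment; YAML configs likewise fall back to
JSON.

# Known limitations

- The synthetic worlds are stationary within profile class: no
  slow drift of baseline rates, no bursting, no correlated noise across
  units; cluster-recovery results certify the procedure on separable
  planted structure, not performance at arbitrary separations.
- Absolute z-thresholds in the feature extractor interact with population
  composition (standardization is relative); the defaults are tuned to
  balanced mixes and are exposed for other regimes.
- CP rank selection assumes assemblies of comparable strength; a component
  an order of magnitude weaker than the rest will be absorbed before
  convergence breaks down.
- The Bayes-factor model handles a single binary predictor; sex-by-treatment
  interactions are out of scope (group labels can be recoded upstream).
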