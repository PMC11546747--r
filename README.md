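# operantNeuro

Analysis pipeline for rodent reward-seeking experiments: operant task
simulation, fiber-photometry dopamine-signal processing, single-unit
encoding-pattern discovery, trial-tensor decomposition, demand-curve
economics, and Bayesian encoding-bias inference — with seeded synthetic-data
generators that plant ground truth for every stage.

## The problem

In self-administration experiments, rats press a lever for food pellets or
drug infusions under schedules whose response requirement escalates
(progressive ratio, PR) or whose unit price varies within a session
(behavioral-economic demand), while nucleus accumbens activity is recorded
by a dopamine sensor (with a 405-nm isosbestic control channel) or by
multi-electrode arrays. Turning those recordings into claims — "cue-evoked
dopamine is larger in the exposed group", "more units join the cue-encoding
ensemble", "motivation measured as essential value differs" — takes a chain
of analyses that this package implements as tested, reusable functions:

- **Task schedules** (`prRequirementSequence`, `demandPriceSchedule`,
  `simulatePRSession`, `goNogoSessionPlan`): the PR requirement for trial
  *i* is round(5·e^0.2i) − 5 (1, 2, 4, 6, 9, 12, 15, 20, 25, 32, 40, 50,
  62, 77, 95, 118, ...); demand prices 180/90/45/15/5 (food) and
  6/10/16/25/40/63/100/158 (remifentanil); 64-trial go/no-go plans with a
  32/32 split in pseudorandom blocks of 10–11.
- **Photometry** (`detrendIsosbestic`, `eventPSTH`, `windowMetrics`,
  `detectTransients`): isosbestic regression to ΔF/F, optional zero-phase
  6-Hz Butterworth low-pass, per-trial z-scoring against the −4 to −2 s
  baseline, trapezoidal AUC and peak over the cue (0–2 s) and reward
  (2–7 s) windows, and prominence-thresholded transient catalogs.
- **Spike encoding** (`buildUnitPSTHs`, `extractEncodingFeatures`,
  `clusterEncodingPatterns`, `windowAUCz`): session-mean normalization,
  cross-unit z-scoring, 8-bin σ=3 Gaussian smoothing, the four clustering
  features (transient count, first-transient latency, cue- and
  reward-window activity), and iterative k-means that grows k while new
  encoding patterns emerge.
- **Tensor component analysis** (`cpALS`, `factorSimilarity`, `selectRank`,
  `truncateToFirstTrials`, `compareGroupLoadings`): canonical polyadic
  decomposition X ≈ Σ_r w_r ∘ b_r ∘ a_r of unit × trial × time tensors by
  alternating least squares, with rank chosen by cross-run convergence and
  group comparison of unit loadings.
- **Demand economics** (`fitDemandCurve`, `derivedMetrics`,
  `predictConsumption`): the exponential model of demand
  log10 Q = log10 Q0 + k(e^(−αQ0P) − 1), with essential value
  EV = 1/(100·α·k^1.5) and Pmax = (0.083k + 0.65)/(Q0·α·k^1.5).
- **Bayesian bias tests** (`fitBayesLogistic`, `classifyEvidence`):
  logistic regression with a compound confluent hypergeometric prior
  (a = 0.5, b = 2, s = 0) on the g-prior shrinkage factor, Bayes factors by
  numerical integration, Jeffreys evidence categories.
- **Endophenotyping** (`pcaEndophenotype`, `predictLatencyFromLoadings`):
  correlation-matrix PCA of behavioral metrics and a seeded train/test
  harness predicting response vigor from tensor unit loadings.
- **Synthetic data** (`genPhotometrySession`, `genSpikeSession`,
  `genTrialTensor`, `genDemandObservations`): seeded generators with
  planted ground truth attached to every output.

## Worked example

```r
library(operantNeuro)

## simulate a food PR session and inspect it
ev <- simulatePRSession(list(press_rate = 1.5, persistence_limit = 120),
                        scheduleSpec("food_PR"), seed = 1)
ev
#> TrialEvents: 650 events, 17 trials, 1007.6 s span
#>    active_press:568  cue_off:15  cue_on:17  reward:16  trial_end:17  trial_start:17

## photometry with cue-locked transients, detrended and cue-aligned
dur <- max(eventTable(ev)$time_s) + 10
rec <- genPhotometrySession(list(duration = dur, seed = 1), events = ev)
dff <- detrendIsosbestic(rec)
cues <- eventTimes(ev, "cue_on")
ps <- eventPSTH(dff, cues[cues > 4 & cues < dur - 8], samplingRate(rec))
windowMetrics(ps, c(0, 2))
#> cue AUC = 6.50 z*s, peak = 9.22 z

## demand curve from noisy synthetic consumption
obs <- genDemandObservations(list(Q0_true = 50, alpha_true = 0.002,
                                  k_true = 2, noise_sd = 0.05, seed = 1))
fitDemandCurve(obs, k_policy = "fixed", k_fixed = 2)
#> DemandFit: Q0 = 47.127, alpha = 0.0018918, k = 2.000 (fixed)
#>   EV = 1.8689, Pmax = 3.236, r2 = 0.997

## does treatment bias membership in an encoding class?
y <- c(rep(1L, 68), rep(0L, 25), rep(1L, 29), rep(0L, 35))  # class per unit
x <- c(rep(1L, 93), rep(0L, 64))                            # group per unit
fitBayesLogistic(y, x)
#> Bayesian logistic bias test (laplace):
#>   beta = 1.175 [0.502, 1.848] log-odds
#>   BF10 = 35.9 (very strong (H1))
```

The AUC/peak are in baseline-z units: the planted cue transients stand ~9
baseline standard deviations above the pre-cue noise. The demand fit
recovers the planted parameters from five price bins with 5% lognormal
noise; EV and Pmax are the derived motivation indices. The Bayes factor of
35.9 is "very strong" evidence that group membership shifts the class odds
(posterior log-odds ratio 1.18).

A config-driven runner executes whole stage chains reproducibly and writes
a provenance manifest:

```r
runPipelineConfig(list(seed = 7, out = "run1",
                       stages = list(simulate = list(press_rate = 1.2),
                                     spikes = list(n_units = 60),
                                     demand = list())))
```

## Acceptance script

`scripts/acceptance.R` regenerates the pipeline's benchmark quantities from
scratch: it builds a 100 × 8 × 60 trial tensor with four planted cell
assemblies and runs cross-run-convergence rank selection (t2), then
simulates food-PR-like (four planted response profiles plus 20%
nonencoding, 150 units) and drug-PR-like (three profiles plus 20%
nonencoding, 120 units) spike sessions, builds PSTHs and features, and runs
the iterative k-means procedure to report the final pattern counts (t3,
t4):

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`; the JSON maps each target id to the
recomputed value and the problem size used.

## Vignette

`vignettes/reward-seeking-analysis.Rmd` documents the models and their
assumptions, every tunable parameter with units and defaults, what the
synthetic generators emulate (and what they deliberately do not), the
numerical choices, and known limitations.
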