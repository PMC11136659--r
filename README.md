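# wmdrift

Cross-session population decoding and representational-drift analysis for
delayed-association working-memory experiments, with a synthetic-cohort
generator that makes every stage verifiable by parameter recovery.

## The problem

In an olfactory delayed-association task, a mouse smells odour A or B,
holds it over a 5 s delay, smells C or D, and licks only for the rewarded
pairings (AC, BD). Chronic calcium imaging of the same cortical population
over days of training asks two quantitative questions:

1. **Which neurons carry task information, and when?** Per-neuron
   statistics: significant activity fields against a circular-shuffle null,
   odour/choice selectivity by Wilcoxon rank-sum at the 99% level,
   pure/mixed classification, cells tuned to associated rewarded-odour
   pairs.
2. **Is the population code stable across days?** A linear decoder
   (max-margin, per 500 ms bin, stratified 90/10 splits repeated 32 times)
   reads out odour or choice; training on day *i* and testing on day *j*
   over neurons matched by centroid geometry (10 µm ceiling) yields a
   day×day generalization matrix. Drift appears as decay away from the
   diagonal; *crystallization* — stabilization with continued practice —
   appears as a late block of mutually consistent days, tested with a
   one-sided early/late block contrast, a day-identity permutation test,
   and a change-point estimate

   C\* = argmax_c { mean acc(i,j) for i≠j, i,j ≥ c } − { mean acc(i,j) for i≠j, i,j < c }.

Because raw recordings of this kind are rarely redistributable, the package
ships a generator that plants tuning fractions, mixed selectivity,
day-to-day retention ρ with a crystallization day C (ρ = 1 for d ≥ C),
depth gradients of late-delay information, behavioural error rates and
degraded late-delay coding on error trials — all recorded as ground truth,
so calibration, power and recovery are testable properties rather than
hopes.

## Worked example

```r
library(wmdrift)
cfg <- generatorConfig(nAnimals = 1, nDays = 7, nNeurons = 80,
                       trialsPerDay = 100, retention = 0.4,
                       crystallizationDay = 4,
                       effectRateHi = 1.0, effectRateLo = 0.3,
                       noiseRate = 0.3)
cohort <- generateCohort(cfg, seed = 1)
s <- sessions(cohort)[[7]]            # final day
behaviourSummary(s)[c("performance", "dprime", "stage")]
#> performance 0.98, d-prime 4.08, stage "expert"

w <- epochWindows(cfg$task)
grid <- selectivityGrid(s, cfg$task, w)
round(100 * tapply(grid$selective, grid$epoch, mean), 1)
#>       choice  early_delay  first_odour   late_delay second_odour
#>         26.2         20.0         20.0         17.5         16.2
table(classifyProfile(grid)$category)
#> mixed  none  pure
#>    20    29    31

sameDayDecoding(binActivity(s, cfg$task), trialTable(s)$firstOdour, w,
                decodingConfig(nRepeats = 16),
                epochs = c("first_odour", "late_delay"), seed = 2)
#> DecodingResult (A/B; 80 neurons, 16 repeats):
#>         epoch accuracy     se
#> 1 first_odour    0.781 0.0332
#> 2  late_delay    0.736 0.0322

m <- crossDayDecoding(cohort, "m01",
                      config = decodingConfig(nRepeats = 6), seed = 3)
round(m@acc, 2)
#>      1    2    3    4    5    6    7
#> 1 0.79 0.64 0.48 0.52 0.48 0.51 0.50
#> 2 0.68 0.71 0.57 0.46 0.55 0.48 0.45
#> 3 0.55 0.62 0.76 0.48 0.48 0.52 0.54
#> 4 0.46 0.50 0.56 0.85 0.84 0.79 0.80
#> 5 0.50 0.48 0.53 0.75 0.80 0.78 0.75
#> 6 0.53 0.52 0.64 0.79 0.76 0.73 0.74
#> 7 0.52 0.48 0.66 0.75 0.74 0.80 0.77

blockStabilityStat(list(m), 1:3, 5:7)$difference
#> 0.173
estimateCrystallizationDay(m@acc, margin = 0.05)$day
#> 5
```

Read: before the planted crystallization day 4 the code drifts (off-diagonal
accuracy near the 50% chance level), after it the days 4–7 generalize to
each other (0.73–0.84). The block contrast is +17.3 accuracy points and the
change point is estimated at day 5 — one day late, the documented bias of
the block-contrast estimator when the boundary day's cross-pairs drag the
early mean down.

`runPipeline()` chains simulate → behaviour → selectivity → registration →
decoding → stability into per-stage CSV/JSON outputs with a manifest, and
`reportSummary()` renders them as markdown tables.

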