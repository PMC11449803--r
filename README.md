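# OperantABA

Analysis tools for behavioural-pharmacology studies that combine
home-cage operant learning (FED3-style two-port pellet devices), the
activity-based anorexia (ABA) rat paradigm, and RNAscope quantification
of serotonin-receptor transcripts (*Htr1a*/*Htr2a*) in medial
prefrontal cortex. It is written for researchers who have event logs,
daily weight/intake/wheel records, or per-cell puncta tables and need
the standard derived measures, plus seeded synthetic generators to
validate the whole pipeline without animal data.

## What it implements

**Schedule engine.** Deterministic state machines for FR1/3/5, VR5/10/20
(uniform i.i.d. per-trial draws), extinction, magazine training, the
exponential progressive ratio

> req(n) = round(5·e^(0.2·n) − 5), n = 1, 2, 3, … → 1, 2, 4, 6, 9, 12, …

and the re-setting PR variant whose requirement drops to 1 after any
10-min lapse in poking. Un-cued between-session reversals via
`applyReversal()`.

**Session metrics.** Binned accuracy (6 × 30-min bins for a 3-h
session), the learning criterion (≥ 80 target pokes in a 100-poke
moving window), time/pokes to criterion, latencies, reward efficiency
(non-target pokes per pellet), breakpoints and post-reset engagement.

**Synthetic behaving agent.** A softmax Q-learner with separate
learning rates for rewarded and unrewarded pokes, perseveration,
log-normal poke timing and engagement pauses; cohort simulation with
deterministic per-subject seeds; maximum-likelihood refitting of
(α⁺, α⁻, β).

**ABA model.** A toy energy-balance daily-record generator (declared
synthetic) and the paradigm's classification: susceptibility (< 80% of
baseline weight), removal day, days above 85%, food anticipatory
activity (1000–1100 h), intake and running phenotypes.

**Transcript quantification.** Puncta-threshold co-expression classes,
section-then-animal averaged proportions, 50-bin cortical-depth
profiles with trapezoidal AUC, and Htr2a transcripts per positive cell.

**Statistical battery.** Unpaired t (pooled or Welch), two-way ANOVA
with a mixed-effects (random-intercept) route for repeated measures,
and Bonferroni/Sidak/Dunnett adjustment.

## Worked example

```r
library(OperantABA)

# a synthetic learner on a 3-h FR5 session, then scored
spec <- scheduleSpec("FR", ratio = 5, sessionDurationS = 10800)
log  <- simulateSession(agentParams(), spec, seed = 1)
scoreSession(log)[, c("total_pokes", "accuracy_overall", "pellets",
                      "criterion_reached", "criterion_poke_index")]
#>   total_pokes accuracy_overall pellets criterion_reached criterion_poke_index
#> 1        1429        0.7424773     212              TRUE                  478
```

1429 pokes at 74.2% accuracy earned 212 pellets, and the 80-in-100
moving-window criterion was reached at poke 478. The same scoring
applies to real logs read with `readEventLog()` (native layout, or
`dialect = "fed3"` for classic FED3 exports).

```r
# ABA phenotype of one synthetic rat
recs <- simulateAbaRat(ratSimParams(), abaConfig(), seed = 2)
phenotypeMetrics(recs)
#> AbaOutcome for r1: susceptible (removed day 6)
#>   days above 85%: 3; lowest %BW 77.2; mean daily loss 3.80%
#>   FAA change +0.160; mean 7-day intake 9.5 g
```

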