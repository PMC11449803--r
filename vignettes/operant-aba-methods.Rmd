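---
title: "Operant schedules, ABA phenotyping and transcript quantification: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operant schedules, ABA phenotyping and transcript quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OperantABA)
```

# What this package computes

OperantABA is the computational layer for home-cage operant experiments
recorded by two-port pellet-dispensing devices (FED3-style event logs),
for the activity-based anorexia (ABA) paradigm, and for downstream
RNAscope quantification of *Htr1a*/*Htr2a* co-expression. It has three
kinds of components:

1. **Deterministic scoring** — schedule state machines and session
   metrics whose definitions are fixed by the experimental paradigm
   (requirement formulas, the moving-window learning criterion,
   latencies, breakpoints, the ABA susceptibility rule, co-expression
   proportions and depth profiles). These claim fidelity to the
   paradigm's definitions and are tested against independent oracles.
2. **Synthetic generators** — a reinforcement-learning behaving agent, a
   toy energy-balance ABA rat, and a negative-binomial cell-table
   sampler. These are invented stand-ins for animals and tissue: their
   role is to produce data with the statistical structure the scoring
   layer assumes, so that the pipeline can be exercised and validated
   end to end without animal data.
3. **A statistical battery** — the conventional comparisons
   (unpaired t, two-way ANOVA, mixed models, Bonferroni/Sidak/Dunnett
   adjustment) applied to pipeline outputs.

# Operant schedule engine

The device is modelled as a state machine over the event vocabulary
`poke_left`, `poke_right`, `pellet_dispensed`, `pellet_removed`.
Supported tasks:

* **FR-n** — every n-th target poke dispenses a pellet.
* **VR[lo–hi]** — the per-trial requirement is an i.i.d. uniform integer
  draw on [lo, hi] (e.g. 1–5 for VR5, 6–10 for VR10, 11–20 for VR20).
  We deliberately use independent draws rather than a shuffled bag; the
  uniformity of the draws is verified by a chi-squared goodness-of-fit
  test on 10^5 seeded draws.
* **PR** — the exponential progressive ratio
  $\mathrm{req}(n) = \mathrm{round}(s\,e^{rn} - s)$ with rate $r = 0.2$
  and scale $s = 5$, floored at 1, giving 1, 2, 4, 6, 9, 12, …
  Trial numbering starts at 1 (trial 1 rounds 1.107 to 1).
* **R-PR** — the re-setting variant: after any 10-min lapse in poking
  the requirement drops back to 1 *before* the incoming poke is
  processed. "Inactivity" means absence of pokes; pellet retrieval does
  not count as activity, because the breakpoint definition is
  poke-anchored. With an infinite reset window R-PR is event-identical
  to PR (a property the tests assert).
* **EXT** — responding is logged, nothing is ever dispensed.
* **FREE** — magazine training: the well starts loaded and a pellet is
  dispensed each time one is removed.

Two decisions here were genuinely open. First, whether a non-target poke
resets progress toward the current requirement: we default to the
*ratchet* rule (it does not), which matches the public FED3 firmware's
counting and keeps non-target pokes a separate measure rather than a
penalty; a `ratchet = FALSE` dialect switch is provided. Second,
reversals: the paradigm reverses contingencies between sessions only, so
`applyReversal()` produces a new schedule and is never applied mid-log.

# Session metrics

All metrics are computed from the poke stream and are invariant to
appending pellet-retrieval events.

* **Accuracy** is target pokes over all pokes, overall and in 30-min
  bins (a 3-h session gives exactly 6 bins). The denominator is pokes,
  not completed trials. A partial final bin keeps its own (noisier)
  fraction; empty bins are reported absent, never zero.
* **Learning criterion**: the first poke at which the last
  min(k, 100) pokes contain at least 80 target pokes. Before 100 pokes
  exist the window is simply all pokes so far, so 80 consecutive target
  pokes reach criterion at poke 80 — the criterion is attainable within
  the first window. Time to criterion is wall-clock from the first poke
  (the clock does not pause during pauses in responding), and windows
  may span pellet-retrieval interruptions.
* **Latencies**: device access to first poke; access to first target
  poke; first poke to first pellet; first to final poke. Each is absent
  exactly when its defining event never occurred.
* **Reward efficiency**: non-target pokes per pellet (absent and
  flagged at zero pellets).
* **Breakpoint**: the requirement of the last pellet earned before the
  first inter-poke gap of ≥ 10 min, emulating classic session
  termination inside a fixed 3-h access window; the session end counts
  as a terminal, infinitely long gap. R-PR resets are recovered from
  the logged requirement markers (a requirement that drops between
  consecutive pokes), and engagement after the first reset is tallied
  as post-reset target/non-target pokes.

# The synthetic behaving agent

The agent is a standard two-choice value learner with the features the
scoring layer is designed to detect:

* Softmax choice:
  $P(\mathrm{left}) = \sigma\!\big(\beta (Q_L - Q_R) + \kappa\,
  [\mathrm{last}=L] - \kappa\, [\mathrm{last}=R]\big)$, with inverse
  temperature $\beta$ and perseveration bonus $\kappa$.
* Asymmetric delta rule: $Q_a \leftarrow Q_a + \alpha (r - Q_a)$ with
  $\alpha = \alpha^{+}$ on rewarded pokes and $\alpha^{-}$ otherwise.
  Negative feedback is delivered on *every* non-dispensing poke, not
  per completed trial; this per-poke rule gives the moving-window
  criterion a realistic within-session learning curve.
* Engagement: log-normal inter-poke intervals; with a small per-poke
  hazard the agent disengages into a log-normal-duration pause.
  Pellets are retrieved after an exponential delay. All duration draws
  are strictly positive by construction. Timestamps are quantised to
  the device's 0.1 s logging resolution.

A "treated" phenotype is encoded as a higher $\alpha^{-}$ and lower
$\kappa$ — faster learning from negative feedback and weaker
perseveration — and the tests assert only the *direction* of the
resulting group difference (fewer non-target pokes to criterion on the
first reversal session), never a magnitude, because the parameter sets
are illustrative rather than fitted to any animal.

Cohorts derive per-subject seeds deterministically from a master seed,
and action values carry across sessions within a subject, so a reversal
stage meets an agent that has actually learned the old contingency.

## Parameter recovery and its design

`fitAgentParams()` refits $(\alpha^{+}, \alpha^{-}, \beta)$ by maximum
likelihood on the poke-by-poke choices, with $\kappa$ and the initial
values held at their generating values. A single-schedule experiment
leaves a ridge in the likelihood — a larger learning rate trades off
against a smaller $\beta$ almost perfectly. The recovery suite
therefore interleaves FR1 and FR3 sessions with reversals every other
pair: the two schedules pin the learned values at different steady
states, which breaks the ridge and makes the triple identifiable. With
50 two-hour sessions per setting, refits land within 20% of the
generating values; this problem size is the package's validation
choice, stated here so the suite's scope is explicit.

# The ABA model

The protocol constants are fixed by the paradigm: 7 baseline days,
then at most 10 days of 90-min feeding (1100–1230 h, dark-phase onset)
with unlimited wheel access; running during 1000–1100 h is food
anticipatory activity (FAA); a rat is removed (susceptible) when its
weight falls below 80% of baseline, and days above 85% are tallied as
weight maintenance.

Decisions the paradigm leaves open, resolved here and exposed as
configuration: the baseline anchor is the *final* baseline day's weight
(it is the quantity a removal trigger would be computed from), not a
7-day mean; weight is measured once daily immediately before the
feeding window, which fixes the %BW clock; and FAA is reported
primarily as the *proportional* measure (FAA-hour revolutions over the
day's total, absent on zero-running days) with the absolute revolutions
also exposed.

The generator behind the classifier is a deliberately simple
energy-balance model,
$BW_{d+1} = BW_d + g\,\mathrm{intake}_d - c\,\mathrm{revs}_d/1000 -
\ell + \epsilon$, with restriction multiplying the running drive
(starvation-induced hyperactivity) and intake adapting linearly across
days. Defaults describe a ~250 g young female rat running ~6000
revolutions/day at baseline, roughly doubling under restriction, eating
~8 g on ABA day 1 with +0.8 g/day adaptation. These values were chosen
once as field-realistic magnitudes; they are synthetic and the
generator makes no claim of physiological fidelity. Heterogeneous
treatment response is modelled as a two-component mixture (a responder
subgroup with a lower restriction multiplier and steeper appetite
slope), which reproduces the bimodal susceptible/resistant split. The
simulator applies the removal rule to the *recorded* (0.1 g-rounded)
weight, exactly as the classifier does, so generator and classifier can
never disagree about a removal day.

What passing tests show — and what they do not: the classification,
FAA and intake metrics are verified on constructed series against hand
arithmetic, and cohort-level assertions (more days above 85% under a
responder mixture; susceptibility rising with running cost) are
direction-only under fixed seeds. None of this validates the energy
model against real rats.

# Transcript quantification

From per-cell puncta counts (CellProfiler/Imaris-style exports), a cell
is positive for a transcript iff its count reaches `minPuncta`
(default 1 — any detected punctum; the threshold is configuration
because segmentation pipelines differ). The co-expression truth table
gives four classes; negative cells are excluded from every
Htr1/2a-positive denominator.

Aggregation is *section-first*: class proportions are computed per
section — where they sum to 1 across the three positive classes
exactly, by construction — and then averaged unweighted over the
animal's sections (4 per region, 8 combined). Cell pooling across
sections would weight sections by their cell yield; it is available as
an explicitly non-default diagnostic (`pooled = TRUE`) and the tests
assert the two disagree where they should.

The cortical-depth profile bins positive cells by distance from the
Layer I midline into 50 half-open bins over a 2000 µm extent (40 µm
bins place deep-layer signal, ~900–1200 µm, well inside the interior);
both knobs are exposed, since the 50-bin resolution is an analysis
choice, not a tissue property. The area under each class's proportion
curve is the trapezoid rule over bin centres; empty interior bins are
linearly bridged between occupied neighbours and leading/trailing empty
bins are dropped, so the AUC never extrapolates beyond observed depth.
Numerically, the last positive class in each section takes the exact
complement of the others (a ≤ 2-ulp adjustment) so that reported
proportions sum to 1 to the last bit.

# Statistical battery

`unpairedT()` defaults to the pooled-variance test (conventional Prism
output), with Welch behind a flag. `twoWayAnova()` is an ordinary
two-way ANOVA unless a repeated factor is declared, in which case a
subject-level random intercept is fitted (lmerTest, Satterthwaite F);
this mixed-effects route is exactly what remains valid when a subject
is removed mid-experiment and cells go missing. Adjustments: Bonferroni
`min(1, m·p)`; Sidak `1 − (1 − p)^m`; Dunnett via the equicorrelated
(ρ = 0.5, the equal-n case) multivariate t — a documented approximation
when group sizes are unequal. Significance is α = 0.05 with p < 0.10
reported as a trend; neither threshold ever gates pipeline flow.

The battery's calibration is checked by simulation: 2,000 two-group
null comparisons on cohorts drawn from identical parameters, with the
rejection count required to fall in the exact binomial 99% acceptance
region around 0.05. The calibration outcome variable is the mean 7-day
intake, a continuous, approximately normal phenotype for which the
t test's assumptions hold at n = 8 per group; removal-truncated
measures such as mean daily percent loss are skewed at that sample size
and would test the t test's robustness rather than the battery's
correctness.

# Degenerate inputs and numerical conventions

* Zero-poke sessions: accuracy and all latencies absent, criterion
  unreached; zero-pellet sessions: efficiency absent and flagged,
  breakpoint 0 and flagged.
* Sections with no positive cell are excluded from animal averages with
  a warning; zero-running days contribute no FAA fraction.
* Constant-and-equal groups give t = 0, p = 1; constant-and-unequal
  groups are a degenerate-input error rather than an infinite
  statistic.
* Event logs store seconds from device access at 0.1 s resolution with
  ties resolved by row order; the writer is byte-stable so identical
  logs produce identical files.
* All simulators take explicit seeds, restore the caller's RNG state,
  and derive nested seeds deterministically (kept within 32-bit range).

# Known limitations

The agent has no satiety, circadian drift or schedule-specific pacing;
the ABA generator has no pharmacokinetics and models the dosing-day
5-h wheel lock at most as a configuration concern; the cell-table
sampler draws class labels i.i.d. within sections, so it cannot emulate
spatial autocorrelation of cell types. Real FED3 exports vary by
firmware; the `fed3` reader dialect follows the public library's
documented columns and should be treated as a mapping, not ground
truth.
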