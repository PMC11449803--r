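Package: OperantABA
Title: Operant Schedule Scoring, Activity-Based Anorexia Phenotyping and
    RNAscope Transcript Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing home-cage operant behaviour recorded by
    pellet-dispensing devices (FED3-style event logs), together with the
    downstream measures used in behavioural-pharmacology studies of the
    activity-based anorexia (ABA) rat model. Implements deterministic state
    machines for fixed-, variable-, progressive- and re-setting
    progressive-ratio reinforcement schedules, extinction and magazine
    training; session-level scoring (binned accuracy, moving-window learning
    criterion, latencies, reward efficiency, breakpoints); a seeded
    reinforcement-learning agent simulator with asymmetric feedback learning
    rates, perseveration and engagement pauses, plus maximum-likelihood
    refitting; an ABA cohort simulator and the susceptibility phenotype
    classification (removal day, days above 85 percent baseline weight, food
    anticipatory activity); RNAscope per-cell co-expression classification,
    section-then-animal aggregation, cortical-depth spatial profiles with
    area under the curve, and transcript abundance per cell; and the standard
    statistical battery (unpaired t, two-way ANOVA, mixed models,
    Bonferroni/Sidak/Dunnett adjustment).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    mvtnorm,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'aba.R'
    'schedule.R'
    'agent.R'
    'io.R'
    'metrics.R'
    'rnascope.R'
    'stats.R'
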