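# rigcomplexity

Algorithmic complexity of human pseudo-random productions across the
lifespan.

## The problem

Random item generation (RIG) tasks ask people to behave like a random
device — produce 12 coin flips, 10 die rolls, 10 guesses among 5 Zener
cards, 10 pointing choices among 9 circles, or a 3x3 grid pattern that
"looks random".  Such productions tap inhibition, sustained attention and
an intuitive sense of complexity, and their quality changes over the
lifespan.  Classical indices miss the essence: `010101010101` has
maximal first-order entropy yet is algorithmically trivial.  This package
measures response quality by an estimate of algorithmic
(Kolmogorov–Chaitin) complexity and provides the full analysis chain used
to characterize its developmental trajectory — for psychologists studying
randomization behaviour and for anyone who needs complexity estimates of
very short symbolic sequences.

## The method

**Coding theorem method (CTM).**  The algorithmic probability of a string
`s` is approximated by the frequency with which halting small Turing
machines output it.  The package enumerates (or uniformly samples) every
`(n states, k symbols)` machine — `(2kn + k)^(nk)` of them in one
dimension, e.g. `10^4` for (2,2) — runs each from a blank tape, and sets

    K(s) = -log2( count(s) / total_halting )   [bits]

**Block decomposition (BDM).**  Responses longer than a table's coverage
are cut into non-overlapping blocks and charged
`sum over distinct blocks [ K(block) + log2(multiplicity) ]`.

**Normalization.**  Raw K is standardized against the *exact* mean and SD
of K over all `k^L` possible responses of the task, computed by weighting
each symbol-permutation class (restricted growth strings) by `k!/(k-d)!`:

    z = (K - mu) / sigma,   so that mean(z) = 0 and sd(z) = 1
                            over the full string space.

**Analysis.**  Developmental curves are smoothing splines of a score on
age (df = 7) with bootstrap 95% bands and a peak-age estimate; modulating
factors (age + age², sex, education, field, paranormal belief) are
assessed by general linear models with Type II partial eta-squared;
reliability by Cronbach's alpha.  A seeded synthetic cohort generator
(ability peaking at 25, declining after 60, with classic response biases:
repetition avoidance, alternation, cycling) makes the whole chain
testable end to end with no external data.

## Worked example

```r
library(rigcomplexity)

# a desk-scale complexity table: every (2,2) machine, exhaustively
tab22 <- coding_theorem(enumerate_space(machine_space(2, 2)))
tab22
#> <ctm_table> 11 strings, K in [0.606, 10.572] bits, fallback 11.572 bits
#>   source: (2,2) 1-D, exhaustive, step cap 6

# the full instrument (two exhaustive + four sampled spaces, ~40 s)
tables <- build_ctm_tables()

# a human-plausible coin response vs a strictly alternating one
spec <- rig_task("coin")
score_response("010010110100", spec, tables$tm4_2)$z
#> [1] 0.6936448
score_response("010101010101", spec, tables$tm4_2)$z
#> [1] -7.424229
first_order_entropy("010101010101")   # entropy cannot tell them apart
#> [1] 1

# simulate a study-sized cohort, score it, fit the lifespan trajectory
cohort <- sample_cohort(3429, seed = 1)
scores <- score_cohort(cohort, tables)
wide   <- participant_summary(scores, cohort)
fit    <- fit_trajectory(wide, "mean_z", spline_df = 7, seed = 1,
                         bootstrap_reps = 100)
fit
#> <trajectory_fit> mean_z ~ age, df = 7, n = 3429
#>   peak age: 23.5 (fitted value -0.2878)
```

The alternating sequence scores about 7 population SDs *below* the mean
complexity of all 4096 possible coin responses while a typical irregular
response sits near 0 — exactly the structure entropy misses.  On the
synthetic cohort the fitted trajectory of mean normalized complexity
rises through childhood, peaks near the generator's true peak age of 25,
and declines after 60.

The same pipeline runs from the shell:

```sh
rigc simulate --n 3429 --seed 1 -o cohort.csv
rigc run -o runs/demo
```

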