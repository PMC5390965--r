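---
title: "Measuring behavioral complexity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring behavioral complexity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the model behind
each stage, the tunable parameters and why their defaults are what they
are, and the limits of what the synthetic validation can show.

## The measurement problem

Random item generation (RIG) tasks ask a person to behave like a random
device: produce 12 coin flips, 10 die rolls, guesses among 5 cards,
10 pointing choices among 9 circles, or a 3x3 grid pattern that "looks
random".  The quality of such productions cannot be judged by classical
statistics alone: a strictly alternating sequence of heads and tails has
maximal first-order entropy and perfectly balanced frequencies, yet any
observer recognizes it as the opposite of random.  What is missing from
entropy is *algorithmic* structure, captured by Kolmogorov-Chaitin
complexity: the length `K(s)` of the shortest program that outputs the
string `s`.  `K` is uncomputable in general, but for short strings it can
be estimated through algorithmic probability.

## The coding theorem method

Let `m(s)` be the probability that a randomly chosen program outputs
`s`.  The coding theorem ties the two quantities together:
`K(s) = -log2 m(s) + O(1)`.  The package estimates `m(s)` by brute
force: enumerate (or sample) every small Turing machine in a fixed
formalism, run each from a blank tape, and count which outputs the
halting machines produce.  Then

```
K(s)  =  -log2( count(s) / total_halting ).
```

The formalism is the classic one for this line of work: `(n, k)`
machines whose transition entries, indexed by (state, read symbol),
either write a symbol, move and change state, or write and halt.  A 1-D
entry has `2kn + k` options, so the space holds `(2kn + k)^(nk)`
machines — `10^4` for (2,2) and `22^10` for (5,2).  Two-dimensional
machines ("turmites") move in the four cardinal directions on a blank
grid.  The output of a halting run is the tape segment spanned by every
position the head visited (minimal bounding rectangle in 2-D); a machine
halting on its first step outputs the single origin cell.  Runs that do
not halt within `step_cap` steps are excluded from both numerator and
denominator.

Step caps default to the exact maximal halting time of the space where
we could verify it by enumeration with a generous cap — 6 steps for
(2,2) tapes, 21 for (3,2), 6 for (2,2) grids — to the classical bound
107 for (4,2), and to a conservative 500 elsewhere.  At these caps the
halting set is exact for the enumerated spaces: raising the cap changes
nothing (this is asserted in the test suite).

Because the blank symbol is 0, outputs are relabelled to canonical
symbol order (first distinct symbol becomes 0, the next 1, ...), which
also guarantees that complexity is invariant under any permutation of
the alphabet: which die face is called "3" cannot matter.

### Desk-scale tables and the fallback rule

Published full-scale tables rest on enumerations of ~10^13 machines;
this package instead ships a *desk-scale* instrument built in well under
a minute: exhaustive (2,2) and (3,2) tape spaces and the exhaustive
(2,2) grid space, plus sampled spaces — 2 x 10^6 machines each from
(4,2), (2,5), (2,6) and (2,9) — for the alphabets the tasks need.
Sampling draws each transition entry uniformly (with replacement, fixed
seed), so tables are bit-reproducible.  Two golden tables ship as
plain-text fixtures under `inst/extdata/`.

Absolute K values from a desk-scale space differ from full-scale ones by
construction; everything downstream therefore works on *normalized*
scores (below), which are self-calibrating against the table in use.

Strings never produced by a space get a fallback value of
`max(covered K) + 1` bit: anything a space never emits is rarer than
anything it emits, so the ordering is preserved while scores stay
defined.  A response longer than the table's coverage is scored by block
decomposition: cut into non-overlapping blocks (remainders keep their
natural size) and charge `K(block) + log2(multiplicity)` per distinct
block — repeating a block costs its description once plus the bits to
say how often.  The default decompositions are two blocks of 6 for the
coin task (the (4,2) sample covers all 32 binary length-6 classes), two
blocks of 5 for card/die/circles (all 52 length-5 classes covered), and
row-major blocks of 5 for the grid.

Native 2-D scoring of the grid against the (2,2) turmite table is
implemented and tested (1x3 row blocks), but it is not the default: at
desk scale that space halts within 6 steps and therefore only produces
line-shaped outputs — its row complexities are nearly constant (the
all-zero row is no more probable than "010"), which makes grid scores
almost flat.  Whether full-scale grid measurements in this literature
used native 2-D machines or block decomposition is generally not
documented; both routes are provided.

## Normalization: the z identity

Raw K depends on string length and alphabet, so scores are standardized
against the *exact* distribution of K over all `k^L` possible responses
of the task:

```
z = (K - mu) / sigma,     mu, sigma over ALL k^L strings.
```

A z of 0 is the complexity of the average possible response; the
population SD is 1 by construction.  Enumerating `9^10 = 3.5 x 10^9`
strings is unnecessary: scores depend only on the symbol-permutation
class, so the package iterates canonical class representatives
(restricted growth strings; 115,974 of them for 10 draws from 9
symbols) and weights each class with `d` distinct symbols by
`k!/(k-d)!`.  The test suite checks the weighted moments against direct
enumeration where the full space is small, and checks the identity
(weighted mean 0, SD 1, to 1e-9) for every task spec — it holds for
*any* backing table, which is what makes desk-scale tables usable.
Canonicalization happens before scoring; published analyses rarely say
whether they normalized before or after relabelling, but the identity
above is invariant to that choice.

## The synthetic cohort

The generator exists so that the full chain — generate, write, read,
validate, score, fit — is testable end to end without any external
data.  It emulates the structure of a large online lifespan study:
ages from a truncated normal (mean 37.72, SD 13.38) on 4-91, roughly
2:1 male:female, a 7-level education ordinal coarsely consistent with
age, field of education only above age 15, and a uniform 1-6 paranormal
belief rating.

Response quality is driven by a latent *randomization ability* in
[0, 1].  The ability curve over age is a monotone Hermite spline with a
maximum at 25 (`peak_age`), an average decline of `adult_slope` per year
until 60 (`plateau_end`) and a steeper `late_slope` decline afterwards.
Biased responding follows a Markov reweighting model with the classic
heuristics, all scaled by `b = 1 - ability`: repetition avoidance
(immediate repeats damped), alternation excess (the symbol from two
steps back boosted), and cycling (while unused symbols remain, used
ones are damped — the tendency to postpone re-use until every
alternative has appeared).  At ability 1 the process is i.i.d. uniform;
at full bias the cycling rule makes the first `k` die symbols a
permutation and full repetition avoidance makes a binary sequence
strictly alternating (both asserted in tests).

The grid task gets its own response model.  Participants there freely
toggle cells until the pattern looks random, so the observable is a
final configuration shaped by *revision*, not a sequence of inhibited
choices; the number of clicks is 5 plus a geometric excess, and click
positions are biased by perseveration (re-toggling the previous cell,
which cancels clicks and leaves sparse, repetitive patterns) and spatial
clustering (rook-neighbours of the last click).  The grid's effective
ability is only weakly coupled to the shared ability
(`0.55 + 0.5 * ability`): empirically the grid correlates with the
other tasks near zero, consistent with it tapping randomness perception
rather than production.  Paranormal belief lowers grid ability by 0.01
per point above 1 — the injected negative belief-complexity association
on that task only.

Completion times are lognormal with a U-shaped median over age (fastest
at 25, about 2.5x slower at age 4 and 2x at 91) and a multiplicative
male speed factor of 0.93.

### Calibration of the defaults

The latent ability scale is arbitrary; what is observable is the
trajectory of mean normalized complexity.  The default curve parameters
(`peak_ability` 0.55, `child_slope` 0.016, `adult_slope` 0.0077 with the
first post-peak decade front-loaded at 1.7x the average slope,
`late_slope` 0.009, bias strengths 0.9/0.7/0.7) were calibrated so the
synthetic trajectories mimic the canonical lifespan shape: a steep
childhood rise, a maximum localized at 25, a slow steady adult decline
and an accelerated decline after 60.  Two properties of the scoring
chain force these choices.  First, the bias-to-complexity mapping
saturates: near-perfect randomizers are barely distinguishable, so a
peak ability of 0.9 would flatten the adult range into pure noise —
humans are imperfect randomizers even at their peak, and the default
puts the cohort on the informative part of the scale.  Second, a
monotone spline leaves the peak with zero slope, and a df = 7 smoother
applied to a one-sided shoulder drifts its argmax years to the right;
front-loading the early-adult decline restores the curvature that real
smoothed developmental curves show.  With these defaults the test
suite asserts that the df = 7 peak estimate over ten cohorts of
n = 3429 stays within 20-30 with its median in 23-27, and the
acceptance script reports the observed median.  Note that `late_slope > adult_slope` holds in ability units,
while the much larger *observed* acceleration after 60 comes from the
steepening of the bias-to-complexity mapping at low ability.

### What the generator does not emulate

No working-memory or timing process (biases are stationary within a
sequence); no practice, fatigue or drop-out; no cultural or linguistic
variation; education and field affect nothing downstream (matching the
null findings they are meant to test); the click-count model is a
placeholder (its mean is matched, its heavy upper tail is not, and the
calibrated perseveration leaves final grids a little sparser than the
real ones).  Passing tests therefore show that the *pipeline* recovers
what the generator put in — not that the generative model is a true
account of human randomization.

## Trajectory analysis

Developmental curves are cubic smoothing splines of a score on age at
fixed equivalent degrees of freedom (default 7 — df, not the penalty,
is the user-facing parameter), evaluated on a 0.5-year grid, with 95%
pointwise bands from a case-resampling bootstrap (percentile method,
default 500 replicates; percentile was chosen as the
assumption-lightest band construction).
The peak age is the grid argmax; a fit whose range is below 1e-8 is
declared flat and returns no unique peak.  The speed-accuracy path is
the parametric curve (fitted CT(age), fitted z(age)) on the shared grid.

The modulating-factor models are ordinary least-squares GLMs.  "Age
(squared)" is ambiguous between a quadratic term alone and
linear-plus-quadratic; the default includes both centered terms (an
inverse-U needs the quadratic; centering tames collinearity) with a
`quadratic_only` switch.  Sex and field are categorical, education
ordinal-numeric, belief numeric.  Effects are reported with Type II
sums of squares (via `car::Anova`), p-values unadjusted per task as is
conventional, plus a Holm-adjusted column in the pipeline output, and
partial eta-squared `SS_term / (SS_term + SS_residual)`.  When field or
belief is included, the analysis is restricted to participants above
15 — the only ones asked those questions.  Reliability is Cronbach's
alpha on complete cases (the coefficient this literature occasionally
labels "Cohen's alpha" is interpreted as Cronbach's).  Missing data are
handled by complete-case analysis throughout; missing task scores
propagate into the per-participant mean as a smaller divisor, never as
imputed values.

One known interpretive ambiguity: the design property "the injected
belief effect is detected with negative sign in >= 80% of replicates"
is implemented as sign recovery of the estimated coefficient.  A
power analysis shows why: with one grid response per participant the
residual SD of grid z is ~1, so an ability decrement of 0.01 per belief
point (the default) yields an expected |t| near 1 at n = 3429 —
sign recovery succeeds in >80% of replicates, while p < .05 detection
cannot exceed ~30% power for any response model with this score
granularity.  Detecting the effect at conventional significance would
require a larger effect size or repeated grid measurements per
participant.

## Numerical choices and degenerate inputs

* Enumeration refuses spaces above 10^8 machines; sampling requires an
  explicit seed; all sampling uses a self-contained Mersenne Twister
  stream with rejection sampling for bounded draws, so tables are
  identical across platforms.
* `coding_theorem` on an empty distribution (nothing halted) is an
  error, as is a zero step cap.
* A table assigning one constant complexity to every class makes the
  normalization SD zero and is rejected.
* Ties in the trajectory argmax resolve to the youngest age
  (`which.max` on the grid); flat fits return `NA` with a flag.
* Cohort seeds: every stochastic operation takes an explicit seed, and
  per-stage seeds are derived from the root seed by a fixed affine map
  modulo 2^31, so one integer reproduces an entire run.
* Moments are cached per (table, task spec) pair; the cache key hashes
  the table provenance, so swapping tables never reuses stale moments.

## Problem sizes used in validation

The shipped validation uses the desk-scale instrument throughout:
exhaustive (2,2)/(3,2)/(2,2)-grid spaces, 2 x 10^6 samples per large
space, synthetic cohorts of n = 3429 (a realistic large-study size) for peak
recovery and effect detection, n = 400-600 for calibration-style
replicate suites, 200 null replicates for p-value calibration, and 50
replicates for sign recovery and bootstrap coverage.  These sizes were
chosen so the whole suite validates every claim the package makes at
interactive timescales.

## Known limitations

Desk-scale K values are not comparable across tables or to published
full-scale tables (normalized scores are); the grid score has coarse
granularity (a handful of distinct block complexities); the generator's
biases are stationary and the grid model stylized; and the bootstrap
bands are pointwise, not simultaneous.
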