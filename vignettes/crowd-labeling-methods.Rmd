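---
title: "Quality-filtered crowd consensus for lung ultrasound B-line labels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-filtered crowd consensus for B-line labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdbline)
```

## The labeling problem

Each lung ultrasound clip receives one of three ordered labels —
`NO_BLINES` < `DISCRETE` < `CONFLUENT` — graded by the highest B-line
severity visible anywhere in the clip. A gamified contest collects these
labels from an open crowd: labelers see clips in random order, get
immediate right/wrong feedback on *feedback clips* (clips whose label is
known — expert-labeled training clips, plus any clip the crowd itself has
since labeled), and earn prizes by accuracy. The package replays such a
contest from its opinion log and evaluates the resulting labels against
expert panels.

## The aggregation model

**Qscore.** A labeler's quality score is their trailing mean correctness
over their last 50 opinions on feedback clips, forced to 0 until they have
25 such opinions. Two consequences matter for correctness of the replay:
the score is stamped on an opinion *before* that opinion can enter the
history (an opinion never influences its own eligibility), and opinions on
an unlabeled clip given before its promotion are never retro-scored.

**Eligibility.** An opinion counts toward consensus only if the submitting
user's Qscore was ≥ 0.80 (inclusive) at that moment. Discarded opinions are
stamped and logged but never re-admitted, even if the user's score later
rises.

**Consensus.** Eligible opinions on an unlabeled clip accumulate in a
tally holding each user's most recent vote. The clip is promoted when the
top class leads the runner-up by ≥ 3 votes (`LEAD`), or when the tally
reaches 15 opinions (`CAP`; majority label, ties uniform at random). Both
thresholds count the same deduplicated, quality-filtered tally: the live
platform discards ineligible opinions outright, so the cap is interpreted
over the opinions that exist for consensus purposes. A promoted clip's
label is frozen and the clip joins the feedback pool. Logs that end before
a tally resolves can be settled retrospectively (`finalize_exhausted()`,
stop reason `EXHAUSTED`).

Test clips never enter the live stopping rules (they are nonfeedback
clips); their crowd labels are computed retrospectively as the majority of
the full eligible, deduplicated pool (`opinion_pools()` +
`crowd_labels()`).

## Reference standards and evaluation

The reference label of each expert-labeled clip is the majority of the 6
experts, ties broken uniformly at random. Six leave-one-out standards
repeat the construction on the 5 remaining experts so a rater can be scored
against a consensus their own vote did not influence; scoring the crowd
against the leave-one-out set uses the per-clip fraction of the six
standards matched. Each standard draws its tie-breaks from a stream seeded
by `(seed, excluded expert)`, so recomputing one standard never shifts
another's draws; the full and leave-one-out standards are independent
draws (whether the live analysis reused one realization is unknowable from
the outside, and independent streams are the reproducible choice).

Concordance is the percentage of matching labels over a clip set;
per-class concordance stratifies by the *reference* label, and balanced
concordance is the unweighted per-class mean, which removes the ~70%
no-B-line prevalence from the headline number. Crowd-vs-expert differences
use a paired t test on per-clip codings (crowd indicator vs fraction of
experts correct). Internal agreement of a group on a clip is the modal
class share of its opinions — all crowd opinions including repeat visits,
mirroring the learning-curve convention, against the 6 expert opinions —
and feeds a Pearson correlation and a Mann-Whitney comparison (matched vs
unmatched clips, tie-corrected normal approximation; ties are the rule for
agreement fractions). One-vs-rest ROC curves threshold the crowd vote
proportion for each class; by default the vote fractions use the
quality-filtered deduplicated pools (`roc_eligible_only = FALSE` switches
to all opinions — the live analysis does not say which it used).

## Secondary analyses

**Opinions needed.** For each k, 1000 Monte Carlo replicates draw
min(k, pool) opinions per clip *without replacement* (the counterfactual is
"had we collected fewer", not resampling), take the majority with uniform
tie-breaks, and score the across-clip concordance. Only the class
composition of a subsample matters, so the implementation draws subsample
class counts directly from the multivariate hypergeometric distribution
(two chained `rhyper()` calls) — exactly equivalent to sampling opinions,
and vectorized over replicates; tests verify it against exhaustive subset
enumeration on small pools. The curve reports the smallest k within a
configurable margin (default 1 percentage point) of the expected full-pool
concordance; the margin is a display convention, not a claim.

**Learning curves.** Per user, every opinion on a test-set clip (repeat
visits included) is scored against the reference and smoothed by a
trailing window of 25; curve point *i* averages users with at least *i*
test-set opinions and is reported only while ≥ 5 users contribute (the
support floor is configurable; uncapped tails are dominated by one or two
prolific users). *Skilled* users are those with at least one test-clip
opinion stamped with Qscore ≥ 0.80.

## The synthetic crowd

The generator emulates the statistical structure the analysis assumes,
at desk scale by default (600 clips — 200 per split — 100 users, ~20k
opinions; the live deployment's ~99k opinions are reachable via the
config):

* **Clips.** True classes from priors 0.70/0.18/0.12 (the observed
  test-set mix); patients hold ~10 clips and never span splits. A fraction
  of clips is intrinsically *hard*: `ambiguity_fraction = 0.12`, chosen
  because roughly 12% of the deployment's expert-labeled cases lacked a
  two-thirds expert supermajority; hard clips multiply every rater's
  accuracy by `1 − hard_clip_confusability = 0.8`, which is what couples
  crowd and expert disagreement on the same clips.
* **Experts.** Static (non-learning) raters with accuracies
  0.77/0.81/0.85/0.87/0.88/0.91, spanning the deployment's observed
  per-expert range.
* **Crowd.** Each user's accuracy follows an exponential approach
  a(t) = a∞ − (a∞ − a₀)·e^(−λt) in t = feedback opinions seen; any
  saturating form would do and this is the simplest with three
  interpretable parameters. Defaults: a₀ ~ N(0.55, 0.05), a∞ ~ N(0.80,
  0.05) (the observed crowd plateau is 80–81%), λ = 0.05 so a user closes
  ~95% of the gap after ~60 feedback opinions — consistent with plateaus
  appearing after a few dozen test-set cases seen. Engagement is
  negative-binomial (mean 200, shape 2), giving the heavy skew of
  voluntary participation.
* **Errors.** 80% of error mass goes to the severity-adjacent class
  (`DISCRETE` is adjacent to both extremes), matching the observation that
  discrete B-lines dominate confusions.
* **The stream.** Users are interleaved in random order; each alternates
  feedback clips (stratified equally over the three classes currently
  available in the feedback pool, as the live platform samples them) and
  nonfeedback clips (uniform over test and still-unlabeled clips). The
  contest engine runs inline so promotions immediately enlarge the
  feedback pool, and replaying the emitted log reproduces the identical
  contest state.

What the generator does **not** emulate: recruitment and drop-out
dynamics, per-clip opinion-count marginals of the live contest (28–48
users per test clip), inter-clip correlations beyond the binary hard flag,
label-order or fatigue effects, and any dependence of skill on the
medical-experience flag (which is metadata only). A green test on
synthetic data therefore establishes the *mechanics* — filtering,
deduplication, stopping, scoring, statistics — and directional phenomena
(wisdom of crowds, filter enrichment, learning, small subsampling knee),
not the live deployment's headline numbers.

One subtlety in how the test suite checks parameter recovery: the
learning-curve plateau is scored against the generator's latent true
classes, not the simulated expert consensus, because the quantity being
recovered is the generative asymptote a∞. Scored against the expert
consensus the same plateau sits ~2–3 points lower — the hard-clip penalty
and the consensus's own ~3% error rate attenuate it — which is a property
of the measuring instrument, not of the labelers.

## Numerical and design choices

* All randomness flows from integer seeds through named child streams
  (`derive_seed()`); recomputing one stage never shifts another, and every
  pipeline stage is bit-reproducible.
* Three-way tally ties (possible at the cap) are broken uniformly over the
  tied classes.
* Percentages are reported to one decimal; all internal comparisons use
  full precision.
* Paired t on differences with (numerically) zero variance: all-zero
  differences return t = 0, p = 1; constant nonzero differences are
  flagged degenerate with p = NA rather than inventing a statistic.
* A class absent from the scored test set yields an NA AUC instead of an
  error; clips with no eligible opinions are dropped from crowd scoring
  with a warning.
* The published-arithmetic table (`arithmetic_checks()`) compares derived
  SD/SE rows within one unit of the last printed digit because their
  published inputs are themselves rounded — the full-consensus expert SE
  computes to 2.051 from inputs printed to 0.1, which cannot round to the
  published 2.0 under any exact inputs consistent with them. Every other
  row must match exactly after rounding.

## Known limitations

* The interchange schema (global integer `event_index`, canonical
  uppercase label tokens) is a package convention; live platform exports
  need a one-off conversion, and timestamps, if any, are ignored.
* Desk-scale simulated contests leave many unlabeled clips short of the
  3-vote lead; `finalize_exhausted()` settles them, which the live contest
  never needed.
* The internal-agreement correlation between crowd and experts is positive
  but attenuated at desk scale (~0.1 vs 0.70 live): per-clip crowd pools
  of ~10 opinions make modal-share estimates noisy, and measurement noise
  attenuates correlations. Raising opinions per user or the ambiguity
  coupling strengthens it.
* Expert learning curves require an event order the expert table does not
  have; the evaluation assigns each expert a seeded random clip order,
  which is irrelevant for non-learning raters but means expert curve x
  axes are synthetic.
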