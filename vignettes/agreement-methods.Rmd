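---
title: "Methods: agreement between two trial risk-of-bias instruments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: agreement between two trial risk-of-bias instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robagree)
```

## The problem and the data model

Randomized trials of physical-therapy interventions are appraised for risk
of bias by Cochrane reviews (the Cochrane tool: seven core domains rated
low/unclear/high) and by the PEDro database (eleven yes/no items, total
score 0–10). The package quantifies how far the two instruments agree when
both rate the same trials.

The unit of analysis is the trial, but trials arrive nested in reviews,
and a review contributes both its rating style (which blinding variant it
reports, which optional items it evaluates at all) and correlated rating
behaviour. Three structural features drive the whole design:

1. **Clustering.** Trials in one review share raters and conventions, so
   all main confidence intervals resample reviews, not trials.
2. **The "unclear" channel.** The Cochrane tool's middle category mixes
   "poorly reported" with "genuinely uncertain"; its treatment is the
   single biggest analytic choice, so every comparison is run under three
   recoding schemes (unclear as negative — the main analysis; unclear as
   positive; unclear excluded).
3. **Reporting variants.** Reviews report the blinding domains under seven
   different formats. Item-level analyses respect the variant actually
   used; summary scores map variants back onto the seven core domains.

A rating table (`trial_ratings`) carries one row per (trial, review) pair:
twelve Cochrane variant columns (low/unclear/high/not_assessed) and eleven
binary PEDro columns. Trials appearing in several reviews are resolved by
`deduplicate_trials()`: one record is retained uniformly at random
(seeded) for the main set, the next occurrence in a canonical sort of
review ids becomes its reliability partner, later occurrences are dropped.
The random-uniform retention and the canonical-sort choice of "second"
record are package decisions; nothing in the analysis depends on which
record is called second, because the between-review kappa is symmetric up
to transposition of a square table it is computed from.

## Agreement statistics

**Percent exact agreement** is the diagonal share of the paired table.
**Cohen's kappa** is computed from scratch on any square table as
\((P_o - P_e)/(1 - P_e)\) with \(P_e\) the sum of marginal products. A
table whose marginals concentrate all mass in one category has \(P_e = 1\)
and no chance-corrected agreement; the package returns `NA` ("not
calculable") rather than a value, which is exactly the behaviour needed
for sparse between-review items and for extreme threshold-matrix cells.

**ICC(1,1)** is the one-way random-effects intraclass correlation: trials
are random subjects, the two instruments are interchangeable measurements,
\(\mathrm{ICC} = (MS_B - MS_W) / (MS_B + (k-1) MS_W)\). The one-way form
is deliberate — the two "raters" are different instruments, not a crossed
rater panel, so no rater main effect is estimable. Because ICC is
scale-dependent, the PEDro total (0–10) is multiplied by 10 before being
paired with the Cochrane summary score (0–100). This rescaling is a
package decision: an affine mismatch between the scales would otherwise
show up as disagreement that no practitioner would care about.

**Interval estimation.** Main analyses use a percentile bootstrap
clustered by review: each replicate draws as many reviews as observed,
with replacement, keeping every trial of a sampled review; the interval
endpoints are order statistics (type-1 quantiles) of the replicate
distribution. Replicates where the statistic is undefined are dropped and
counted; more than 50% undefined aborts the analysis. The default is 5000
replicates; the interval type (percentile rather than normal or BCa) is a
package decision recorded in the report metadata. Between-review
reliability is intentionally *not* clustered (each pair already spans two
reviews); its kappa CIs use the large-sample delta-method variance of
unweighted kappa, and its summary-score ICC uses the exact one-way F
interval.

**Interpretation labels** follow the Landis–Koch bands for kappa and the
Fleiss bands for ICC. Printed band edges are two-decimal closed ranges, so
boundary values belong to the band in which they are printed: kappa 0.20
is "slight", 0.21 "fair"; ICC 0.40 and 0.75 are both "fair to good".

## Summary scores and the variant-to-domain mapping

The Cochrane summary score of a trial is the percentage of *evaluated*
core domains rated low; domains the review did not evaluate leave the
denominator. Two mapping decisions are the package's own, since the
seven-domain frame does not dictate them:

- participants-only, personnel-only and participants+personnel variants
  all fill the single performance-bias domain; the three
  outcome-assessment variants fill detection bias; the triple combined
  variant fills performance **and** detection with the same rating;
- when one review reports several variants of the same domain for one
  trial, the domain takes the worst rating (high > unclear > low), the
  conservative convention in risk-of-bias work.

An alternative reading would count combined blinding variants as a single
core item; the two-domain mapping was chosen because it keeps the
denominator's meaning ("domains with any evidence") stable across
reporting styles. Summary percentages are kept unrounded internally;
displayed integer percentages use round-half-up.

The PEDro total is the count of yes ratings over the ten scored items
(the inclusion-criteria item is recorded but never counted).

## The 2x2 reconstruction utility

Published item-level results report \(n\), percent agreement and kappa,
while published marginal tables give each instrument's positive counts.
Those four numbers determine the paired table: with agreement count
\(A = n \cdot pct/100\), \(a = (A + m_1 + m_2 - n)/2\) and the rest by
subtraction. A printed percentage has 1-decimal precision, so \(A\) is
allowed ±1 of slack to reach an integral non-negative table; anything
further is reported as an inconsistency instead of a table. This is a
validation tool: it lets the package confirm published kappas (to about
±0.006, the slack implied by the rounding) without trial-level data.

## The synthetic generator and its oracle

No public generative model exists for paired risk-of-bias ratings, so the
package defines the minimal structure that makes every pipeline stage
testable:

- a review-level quality shift \(u_r \sim N(0, \sigma^2)\) on the probit
  scale, giving latent domain-status prevalence
  \(\Phi(\Phi^{-1}(p_d) + u_r)\) — probit keeps probabilities bounded;
- per trial and domain, a latent status \(S\) and a reporting-clarity flag
  \(C\);
- the Cochrane rating is unclear with probability
  \((1-C)(1-\texttt{unclear\_to\_rating})\), otherwise low/high tracking
  \(S\) with error `crob_error`; combined blinding variants track the
  conjunction of their component domains;
- the PEDro item is yes when the report is clear and the status tracks
  with error `pedro_error`, and no whenever the report is unclear — the
  scale requires explicit reporting, so "no" deliberately conflates "not
  done" and "not reported";
- each review draws a blinding reporting style (separate items, combined,
  triple-combined, or subjective/objective outcome split), which produces
  the `not_assessed` structure the pipeline must handle;
- duplicates: a fraction of trials get a second review id whose item
  ratings independently move to another category with probability
  `duplicate_error`.

Because every joint cell probability is linear in the latent prevalence,
the review effect integrates in closed form
(\(\bar p = \Phi(\Phi^{-1}(p)/\sqrt{1+\sigma^2})\)), and
`analytic_joint_distribution()` returns the exact population joint and
the implied kappa per recoding scheme. This is the oracle the estimation
pipeline is tested against: a noiseless configuration must give kappa 1,
`pedro_error = 0.5` with full clarity must give kappa 0 (independence —
note that with partial clarity the shared clarity channel still
correlates the instruments, so the independence limit is stated at
clarity 1), and large simulations must match the joint cell by cell.

Defaults were fixed once from the descriptive shape of a large published
sample of 1442 physical-therapy trials in 108 Cochrane reviews: about a
hundred reviews of 7–22 trials (drawn uniformly — this matches that
sample's interquartile range but not the skew of its size distribution),
participant/therapist blinding rare, assessor blinding in roughly a third
of trials, allocation concealment unclear-heavy. What the generator does
**not** emulate: correlated errors between the instruments beyond the
shared latent status and clarity (real raters read the same sentences),
domain–domain correlation within a trial beyond the review effect,
non-uniform review sizes, drift of rating practice over time, and any
dependence of PEDro completeness on the trial. Passing tests therefore
show the estimators are correct under clustering, missingness-by-design
and an unclear channel — not that real instruments behave like the model.

## Numerical choices and degenerate inputs

- Percentile CIs use type-1 (order-statistic) quantiles.
- Transformed-count display percentages use round-half-up; internal values
  are never rounded.
- Zero denominators (an item nobody rated, a trial with no evaluated core
  domain) yield flagged `NA`s that propagate by pairwise deletion, never
  silent zeros.
- Bootstrap replicates with undefined statistics are dropped and counted;
  >50% undefined is an error.
- All randomness (duplicate retention, bootstraps, generation) is driven
  by explicit seeds through a local-RNG helper, so a pipeline rerun with
  one seed is byte-identical, and library loading order cannot perturb
  results.

## Problem sizes

The test suite runs the full pipeline on generated datasets of roughly
100–1500 trials; oracle-equivalence checks use 1000 random tables and
datasets; the bootstrap-coverage check uses 100 generated datasets of
about 1500 trials (100 reviews of 12–18) at 500 replicates, a size chosen
so the whole suite completes in well under a minute while leaving the
coverage estimate a standard error of about 2 percentage points. The
acceptance script runs the same analyses at 1000 bootstrap replicates
(300 per threshold-matrix cell). Production analyses should use the
5000-replicate default.

## Known limitations

- Kappa on pooled ratings from many rater pairs is treated as a single
  two-rater kappa; no multi-rater generalization is attempted.
- The bootstrap interval is percentile only; no BCa or studentized
  variants.
- Weighted kappa is out of scope: the three-level between-review
  comparison is unweighted, treating low/unclear/high as nominal.
- The reconstruction utility assumes the published marginals refer to the
  same trial subset as the published comparison; items rated in only part
  of the sample cannot be reconstructed from full-sample marginals, and
  the package makes no attempt to.
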