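---
title: "Responder decomposition, ethical losses, and the responder-proportion sweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Responder decomposition, ethical losses, and the responder-proportion sweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethicloss)
```

## The model

A parallel-arm randomized controlled trial with a dichotomous endpoint
(death, say) reports four counts: events and non-events in the control (C)
and experimental (T) arms,

|          | C    | T    |
|----------|------|------|
| event    | a    | b    |
| no event | c    | d    |

with arm sizes $N_c = a + c$ and $N_T = b + d$, event rates $R_c = a/N_c$
and $R_T = b/N_T$, absolute benefit $AB = R_c - R_T$ and relative risk
$RR = R_T / R_c$.

`ethicloss` views this table through a deterministic potential-outcomes
lens. Every participant belongs to one of three latent categories:

* **responder** — dies if untreated, survives if given the experimental
  treatment;
* **non-responder** — dies either way;
* **non-informative** — survives either way.

Two assumptions make the category counts identifiable from the observed
table alone. First, *exchangeability*: randomization makes the two arms
interchangeable, so the control arm tells us what the treatment arm would
have done untreated. Second, *superiority*: the experimental treatment is
at least as good as control ($R_c \ge R_T$); tables violating it get their
responder count clamped at zero with a warning rather than producing
negative categories.

Under these assumptions the treatment arm, left untreated, would have
presented $a N_T / N_c$ events; the shortfall of the observed $b$ against
that expectation is the T-arm responders,

$$ d_1 = \operatorname{round}(a N_T / N_c) - b, $$

and their control-arm counterparts — participants with a responder profile
randomized to C, who by definition die — number
$\operatorname{round}(d_1 N_c / N_T)$. Everything else follows by
bookkeeping: non-responders are the remaining events in both arms,
non-informative participants the remaining non-events,
**unnecessary participants** = non-responders + non-informative (those who
cannot benefit with respect to the endpoint), and **ethical losses** =
everyone except the T-arm responders, $(N_c + N_T) - d_1$ — on a mortality
endpoint the marginal benefits of participation are disregarded and any
enrolled non-beneficiary counts as a loss.

```{r}
decompose_trial(empa_reg_table())
```

For the seed trial — the all-cause-mortality simplification of the
published Empa-REG-Outcome trial (2:1 allocation, 7020 participants) —
only 181 participants have a responder profile and 6899 (98.3%) suffer an
ethical loss.

## Numerical choices

**Rounding.** Participant counts are rounded to the closest unit, halves
away from zero, applied at final counts and never at intermediate rates
(`round_half_away()`; base `round()` rounds half to even, which would be a
surprising convention for people). On the seed table the headline counts
390, 121 and 60 are insensitive to half-up versus half-to-even.

**Order of operations.** The canonical responder count is
$\operatorname{round}(a N_T/N_c) - b$ (the count route, 390 − 269 = 121).
The algebraic rate route $\operatorname{round}((R_c - R_T) N_T)$ gives
120.75 → 121; the tests assert both routes agree on the seed table but the
count route is the implementation.

**Chi-square.** The efficacy test statistic is the standard Pearson
chi-square on the four cells (df = 1, upper-tail p), computed through
`stats::chisq.test`, with no continuity correction by default and Yates'
correction behind a flag; the test suite checks it against a brute-force
expected-count sum on 1,000 random tables. A zero margin is an error, not
a zero.

**Degenerate inputs.** $R_c = 0$ makes the relative risk undefined; it is
returned as `NA` with a warning, never silently zero. Tables whose double
rounding would drive a category negative (possible only at toy sizes, e.g.
$a{=}1, N_c{=}3, N_T{=}2$) raise a structural-inconsistency error naming
the offending category.

## The responder-proportion sweep

`run_sweep()` rebuilds a family of trials on a grid of responder
proportions $p$ (default 0.025 to 1 in steps of 0.025; $p = 0$ is excluded
since the sample size diverges). The published numbers pin down what is
held fixed, but not the reconstruction rule itself, so the rule is this
package's design choice, constrained to reproduce every printed anchor:

* the T-arm responder contingent stays at its seed value (121), its C-arm
  counterpart at the allocation-scaled 60;
* total enrolment is $N = 181 / p$, split between arms by the seed
  allocation ratio 4687 : 2333;
* C-arm potential responders all die; T-arm responders all survive;
* the remaining, unnecessary, participants die with the fixed untreated
  probability $194/2333$ in *both* arms — for them the treatment does
  nothing, and "the control rate stays constant" is read as this fixed
  parameter, not the observed $R_c$ (which cannot be constant: it equals
  1 in the perfect trial).

At $p = 1$ this is the **perfect trial** — 60 controls, all deceased, 121
treated, all alive — whose ethical losses (60, 33.1% of 181) are the
irreducible price of a concurrent control arm. At $p = 0.025$ enrolment is
7240 and the relative risk 0.77.

```{r}
sw <- run_sweep()
sw[sw$p %in% c(0.025, 0.2, 1), ]
```

**Rounding versus trends.** With `round = TRUE` (default) every stage —
$N$, then $N_T$ with $N_c = N - N_T$, then the event counts — is rounded
to whole participants; the arm remainder goes to the control arm. Whole-
participant quantization perturbs the rate ratios by up to one count, which
is enough to break *strict* monotonicity of RR and chi-square at isolated
grid points. The monotone and linear trends are exact properties of the
continuous model, available as `run_sweep(round = FALSE)` (which also
carries the exact C-arm counterpart $d_1 N_c / N_T$ rather than its
rounded value): there $N(p) = R/p$, the ethical-loss percentage
$100\,(1 - p\,d_1/R)$ is exactly linear in $p$, RR is nonincreasing and
chi-square nondecreasing. `trend_check()` reports the verdicts and the
$R^2$ of the linear fits for whichever sweep it is given, flagging constant
(degenerate) inputs.

## The synthetic cohort generator

`generate_cohort()` draws individual participants with latent categories
(independently, with probabilities `p_responder`, `p_nonresponder`,
remainder non-informative), assigns arms Bernoulli(`alloc_T_share`,
default 2/3 to mirror the seed trial's 2:1 design; an exact-split option
fixes the margin instead), fills in the deterministic potential outcomes
per category and realizes the assigned arm's outcome. This is the minimal
generative model under which every decomposition formula is exactly
identified, and it makes exchangeability literal: within a category,
participants are identical.

It emulates none of the complications of real trials — no covariates,
dropout, non-compliance, misclassification, no between-cluster variation
in the responder proportion, no harmed-by-treatment category (superiority
is built in), and untreated event probabilities are constant within a
category rather than varying across subjects. Passing recovery tests
therefore show that the arithmetic of the decomposition is right and its
estimators unbiased *under the model's own assumptions*, not that real
trials satisfy those assumptions.

`recovery_experiment()` runs `n_reps` independent replicates (replicate
$i$ reseeds with `seed + i`, so runs are reproducible and parallelizable
by contract) and checks two estimators against the latent truth: the
absolute benefit, whose expectation equals `p_responder` exactly under the
model, and the decomposition's T-arm responder count against the latent
mean $N \cdot \texttt{alloc\_T\_share} \cdot \texttt{p\_responder}$. Bias
beyond three Monte-Carlo standard errors is flagged. With `p_responder =
0` the count estimator is clamped at zero from below, so its bias is
nonnegative by construction and reported as such.

```{r}
cfg <- cohort_config(N = 10000, p_responder = 0.05, p_nonresponder = 0.05,
                     seed = 1, n_reps = 50)
rec <- recovery_experiment(cfg)
c(ab_bias = rec$ab$bias, ab_se = rec$ab$se, unbiased = rec$ab$unbiased)
```

## Problem sizes and reproducibility

The package's own validation uses desk-scale problems: the 7020-participant
seed table, the 40-point sweep, 1,000 random tables for the chi-square
cross-check, 200-replicate recovery experiments at $N = 10{,}000$, and a
single $N = 10^6$ cohort for the large-sample recovery check. All
randomness flows from explicit seeds; cohorts and sweep CSVs are
byte-reproducible given the same configuration and seed, and the
`analysis/` drivers write their tables under `results/`.

## Known limitations

* The decomposition is exact only under exchangeability, superiority and a
  deterministic three-category world; it quantifies ethical losses within
  that idealization.
* Counts are identified only up to rounding; at toy sample sizes double
  rounding can move a category by a participant or two.
* Confidence intervals for AB/RR and conventional power calculations are
  out of scope, as are continuous or time-to-event endpoints.
* The ethical-loss count weighs a mortality endpoint only; with softer
  endpoints the marginal benefits of participation could not be
  disregarded so bluntly.
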