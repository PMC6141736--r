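---
title: "Modelling moral-dilemma judgments: the CNI processing tree, process dissociation, and the classical stack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling moral-dilemma judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moralcni)
```

## The measurement problem

Hypothetical moral dilemmas ask whether a particular action is acceptable.
The traditional analysis scores only one dilemma form — a proscriptive norm
("do not do this") combined with action benefits that exceed the costs — and
reads acceptance as utilitarian and rejection as deontological. That score
confounds three distinct dispositions: sensitivity to the *consequences* of
acting, sensitivity to the *moral norm*, and a general preference for
*inaction* regardless of either. The battery this package models breaks the
confound with a 2 × 2 within-subject design: six base dilemmas each appear
under a proscriptive and a prescriptive norm, and with benefits that either
exceed or fall short of the costs — 24 items, six per design cell.

## The CNI multinomial processing tree

For each item, the model assumes a sequence of latent binary events:

1. with probability $C$ the response is driven by consequences — act exactly
   when the benefits of action exceed its costs;
2. otherwise, with probability $N$, the response is driven by the norm — act
   exactly when the norm is prescriptive;
3. otherwise a general inaction preference applies: inaction with
   probability $I$, action with probability $1 - I$.

Summing the action paths gives the four cell probabilities (cells in the
fixed canonical order proscriptive/benefits>costs, proscriptive/benefits<costs,
prescriptive/benefits>costs, prescriptive/benefits<costs):

$$
\begin{aligned}
p_1 &= C + (1-C)(1-N)(1-I), & p_2 &= (1-C)(1-N)(1-I),\\
p_3 &= C + (1-C)N + (1-C)(1-N)(1-I), & p_4 &= (1-C)N + (1-C)(1-N)(1-I).
\end{aligned}
$$

Two structural facts follow and are tested as invariants: $p_1 - p_2 = C$,
and $p_3 - p_1 = p_4 - p_2 = (1-C)N$. The model therefore imposes exactly
one constraint on the four free cell proportions, which is why the pooled
single-group fit has one degree of freedom ($4$ cells $-$ $3$ parameters).

`cni_probabilities()` evaluates the tree; `cni_invert()` solves it
algebraically ($C = p_1 - p_2$, $N = (p_3-p_1)/(1-C)$,
$I = 1 - p_2 / ((1-C)(1-N))$), which serves both as an analytic oracle on
model-true proportions and as the default optimizer start.

### Estimation

Following the convention of aggregate multinomial-processing-tree software,
responses are pooled into action/inaction counts per cell within each group
(`cni_counts()`), and `cni_fit()` maximizes the product-binomial
log-likelihood

$$\ell(C,N,I) = \sum_{\text{cells}} \big[ n^{\text{act}} \ln p + n^{\text{inact}} \ln(1-p) \big]$$

with bounded quasi-Newton (`L-BFGS-B`) and an analytic gradient. The
problem is smooth and three-dimensional per group, but boundary traps are
possible, so the moment-inversion start is supplemented by a midpoint start
and 10 uniform random restarts (configurable); the convergence tolerance on
the log-likelihood is at machine-precision scale (`factr = 10`). A cleanly
converged start within $10^{-8}$ of the best objective value is preferred,
because the line search can terminate abnormally at tolerances this tight.

Goodness of fit is the likelihood-ratio statistic
$G^2 = 2\sum \text{obs} \ln(\text{obs}/\text{exp})$ over all $8g$ cells of a
$g$-group table, with $0 \ln 0 \equiv 0$ and expected counts equal to fitted
probabilities times observed cell totals, on $4g - (\text{free parameters})$
degrees of freedom. Nested tests reuse the same machinery:

* `cni_test_reference()` fixes one parameter at a reference value (C or N
  against 0; I against its neutral point 0.5) and reports
  $\Delta G^2 = G^2_{\text{constrained}} - G^2_{\text{free}}$ on 1 df;
* `cni_test_equality()` constrains one parameter equal across two groups,
  also 1 df;
* `anova()` on any pair of nested fits exposes the same comparison.

Confidence intervals are Wald intervals from the observed information at
the MLE (the convention of the aggregate-MPT software this reproduces),
truncated to $[0,1]$; they are flagged `NA` at boundary estimates, where
profile-likelihood intervals (`confint(fit, type = "profile")`) remain
usable. Profiles are implemented for single-group fits — the reference
tests that motivate them are run on the pooled fit; multi-group fits fall
back to Wald with a message.

Missing responses never unbalance the likelihood: counts use whatever
responses exist, and the product-binomial form does not require equal cell
totals.

## Process dissociation

The older two-parameter decomposition uses only the 12 proscriptive items:
incongruent items (benefits exceed costs) put the utilitarian and
deontological principles in conflict; congruent items (costs exceed
benefits) align them. With $q_c$ and $q_i$ a participant's proportions of
*unacceptable* judgments on congruent and incongruent items,

$$U = q_c - q_i, \qquad D = \frac{q_i}{1-U} \ (U < 1),$$

so that $q_c = U + (1-U)D$ and $q_i = (1-U)D$ reconstruct the data exactly —
both identities are asserted to machine precision in the tests. A
participant with $U = 1$ (a "pure utilitarian") has undefined $D$; such
participants are flagged and dropped pairwise from $D$ analyses only, with
the count reported. Noisy per-participant proportions can push $D$ outside
$[0,1]$ (because $U$ can be negative); these values are retained rather than
clipped, since clipping would bias the downstream regressions. $U$ and $D$
are standardized (sample SD) before correlation/regression analyses, the
same z-scoring convention used throughout.

Under the tree above the population value of $U$ equals $C$ — a useful
sanity link: raising the generating $C$ raises mean $U$, which the test
suite checks, while a stress effect confined to $I$ leaves $U$ untouched
but moves $D$ (the known confound of $D$ between norm sensitivity and
inaction preference).

## The classical stack

* **Choice score** (`choice_scores()`): the count of action judgments on
  the six incongruent items, range 0–6, neutral point 3. The score is kept
  as a count rather than a 0–1 mean because the neutral reference 3 and the
  descriptives it is compared against are only coherent on the 6-item sum;
  this is stated prominently because "averaged" phrasing is common for this
  scale.
* **One-sample t** against the neutral point, with $d = |\bar x - \mu|/s$.
* **Pearson correlations** with two-tailed $t$-based p-values.
* **Hierarchical regression** (`hierarchical_regression()`): OLS on
  cumulative blocks (here age + gender, then stress), all variables —
  including the 0/1 gender dummy — z-scored before fitting so coefficients
  match the "Beta" column of standard statistics packages;
  $\Delta R^2_k = R^2_k - R^2_{k-1}$ with the F-change test
  $F = (\Delta R^2/q) / ((1-R^2_k)/(n-k-1))$. Whether published analyses of
  this design z-scored the dummy is typically unstated; this is a
  documented convention, not a claim about any particular study.
* **Cronbach's alpha** for the 10-item stress scale,
  $\alpha = \tfrac{k}{k-1}(1 - \sum s_j^2 / s_T^2)$.
* **Median split** of stress totals: strictly above the sample median is
  "high", at-or-below is "low". With integer totals the at-median ties make
  the low group larger, matching the asymmetric group sizes typical of this
  design; the tie rule is configurable (`ties_high`).

`run_study()` chains all of this — stress descriptives and reliability,
choice score inference, the correlation matrix, three hierarchical
regressions (choice, U, D), the median split, the pooled CNI fit with the
three reference tests, and the two-group fit with three equality tests —
and `write_report()` serializes every statistic with its df/CI/p to JSON
plus a printed text report.

## The synthetic-data generator

No raw data ship with this package, so `simulate_cni_study()` generates
datasets with the statistical structure the analyses assume. Defaults
emulate the study design the package reproduces:

| quantity | default | unit |
|---|---|---|
| participants | 197 | — |
| age | truncated rounded normal, M 19.49, SD 0.83, range 18–22 | years |
| gender | Bernoulli(0.345) | 1 = male |
| stress total | truncated rounded normal, M 26.51, SD 5.33, range 0–40 | PSS sum |
| item-level reliability target | 0.80 | Cronbach's alpha |
| CNI baselines $C_0, N_0, I_0$ | 0.131, 0.145, 0.451 | probability |
| stress links $\beta_C, \beta_N, \beta_I$ | 0 | per SD of stress, logit scale |
| between-subject SD | 0 | logit scale |

Bounded integer scales are produced by rejection sampling a normal and
rounding — the simplest mechanism that respects the bounds. Item-level
stress scores come from a one-factor model
$x_{ij} = \mu + \lambda f_i + e_{ij}$ discretized by rounding and clipping
to 0–4; $\lambda$ and $\mathrm{sd}(e)$ are solved in closed form so the
*continuous* scale hits the target alpha and total SD exactly
($\bar r = \alpha/(k - \alpha(k-1))$, then
$v = \sigma_T^2/(k^2\bar r + k(1-\bar r))$, $\lambda^2 = \bar r v$).
Discretization attenuates reliability mildly; at large $n$ the realized
alpha stays within 0.75–0.85 of the 0.80 target, which the tests verify.

The stress link acts on the logit:
$P_i = \mathrm{logit}^{-1}(\mathrm{logit}(P_0) + \beta_P z_i + \varepsilon_i)$,
with $z_i$ the sample z-score of the stress total and
$\varepsilon_i \sim N(0, \sigma_{\text{bs}})$. This keeps every realized
parameter inside $(0,1)$ for any effect size (which is also why baselines
must be strictly interior). Responses are then independent Bernoulli draws
from the participant's cell probabilities. With all links and noise at
zero the generator is exactly model-true, and pooled cell proportions
converge to the analytic probabilities — the law-of-large-numbers check in
the test suite.

### Effect sizes used in the experiments

The design description gives no generative effect sizes, so the values used
in the package's experiments are explicit choices:

* **Power/qualitative experiment** (`beta_I = 0.5`,
  `between_subject_sd = 0.3`, $n = 197$): chosen by a power analysis of the
  weakest detection so that every element of the expected pattern (negative
  stress–choice correlation, positive stress–D and null stress–U
  association, an I group difference with null C and N differences) is
  reproduced in well over 80% of replicates.
* **Literature-scale illustration** (`beta_I = 0.2`, used by the acceptance
  script): derived analytically, not by iteration — the choice score's
  sensitivity to a one-SD stress shift is
  $6\,(1-C)(1-N)\,I(1-I)\,\beta_I \approx 1.10\,\beta_I$ at the default
  baselines, and dividing by the score SD ($\approx 1.35$ with
  $\sigma_{\text{bs}} = 0.3$) shows $\beta_I \approx 0.2$ corresponds to a
  stress–choice correlation near $-0.17$, the magnitude this literature
  reports. Individual simulated studies scatter widely around that value
  ($\pm 0.07$ at $n = 197$); single-run outputs should be read accordingly.
* `between_subject_sd = 0.3` represents moderate, realistic heterogeneity
  (roughly $\pm 0.07$–$0.15$ SD on the probability scale at these
  baselines).

### What the generator does and does not emulate

It reproduces the design's marginal distributions, the item-level factor
structure of the stress scale, and a configurable stress→disposition link.
It does **not** emulate item-specific difficulty (all items in a cell share
one probability), response dependencies within participants beyond their
shared parameters, ordering or fatigue effects, or careless responding.
Passing tests therefore certify the *statistical machinery* under the
model's own assumptions — they cannot certify that real dilemma data meet
those assumptions.

## Numerical and calibration properties

The test suite establishes, against independent oracles:

* the maximum-likelihood fit inverts exact model-generated proportions to
  $10^{-4}$ with $G^2 < 10^{-6}$, and matches an exhaustive $101^3$
  grid-search oracle (step 0.01) within 0.01 per parameter on random count
  tables, with every reference and equality $\Delta G^2$ within 0.05 of the
  oracle's constrained refits;
* on model-true data (200 participants, 6 trials per cell), the $G^2$ fit
  test and all three equality tests reject at 3–8% at $\alpha = 0.05$ over
  500 replicates, and Wald intervals cover each generating parameter
  90–98% of the time;
* recovery is effectively unbiased ($|\text{bias}| < 0.02$ at 2000
  participants) with RMSE decreasing strictly over $n \in \{50, 200, 2000\}$.

Simulation sizes in the suite (500 calibration replicates, 200 recovery
replicates per condition, 100 replicates per power arm) were chosen as the
smallest runs whose Monte-Carlo error is well inside the asserted bands.

## Known limitations

* **Complete pooling.** Aggregating counts over participants is the
  convention of the software this re-implements and matches its printed
  degrees of freedom, but it treats participants as exchangeable. Under
  participant heterogeneity the pooled counts are overdispersed relative to
  the binomial, and the equality tests become mildly anticonservative (the
  suite's heterogeneous null arm bounds this at a true rejection rate
  noticeably above the nominal 5% but far below any real effect). Users
  comparing groups on strongly heterogeneous data should treat borderline
  p-values with caution; hierarchical MPT extensions are out of scope here.
* **Wald intervals near the boundary** are unreliable; they are flagged and
  profile intervals provided, but only for single-group fits.
* The median split discards information by design; it is provided because
  the aggregate model comparison needs categorical groups, not because it
  is recommended for continuous covariates in general.
* Dilemma text is not modelled: items are metadata labels, and nothing in
  the package can detect content-driven item effects.
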