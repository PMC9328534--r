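---
title: "Methods: sequence segmentation of contraceptive calendars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence segmentation of contraceptive calendars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calseg)
```

## The analysis in one paragraph

`calseg` segments women's retrospective contraceptive calendars — 59-month
sequences over the states `NONE`, `STM`, `LAPM`, `TRAD`, `PREG` — into
behavioral clusters, and then profiles cluster membership against
knowledge, attitude and health-service covariates. The segmentation is
social sequence analysis in its standard form: an optimal-matching (OM)
edit distance between sequences, weighted k-medoids (PAM) on the resulting
dissimilarity matrix, and a quality-metric sweep to choose the number of
clusters. The profiling is design-based logistic regression: one binary
model per cluster, weighted pseudo-likelihood estimates, and
Taylor-linearized variance that respects weights, primary sampling units
(PSUs) and strata.

## Calendar parsing

DHS-style calendars store one character per month with the *leftmost*
non-padding column the most recent month. `calseg` stores sequences the
other way up — month 1 earliest, month 59 the interview month — because the
downstream statistics are easier to read along calendar time. The analysis
window is the 59 months *ending at the interview month*: the window length
and orientation are fixed by the study design, and the interview month is
the only anchor that is always observed.

The month-code map is data, not code: `default_code_map()` ships the DHS
phase-7 dialect (pregnancy/birth/termination → `PREG`; pill, injectable,
condom, female condom, diaphragm, LAM, emergency contraception, Standard
Days, foam/jelly, other modern → `STM`; IUD, implant, sterilization →
`LAPM`; rhythm, withdrawal, abstinence, other traditional → `TRAD`), and a
survey with a different dialect overrides entries rather than the parser.
Two coding choices deserve flagging: the canonical list of short-term
modern methods has six entries, while the survey alphabet has more modern
codes (female condom, diaphragm, foam/jelly); these default to `STM`.

Missing months (`?` or blank) are resolved by a configurable policy. The
default, carry-backward, copies the state of the next *later* observed
month, on the reasoning that a respondent recalling backwards from the
interview tends to anchor spells at their ends; `recode_none` and a strict
`error` policy are available. Real calendars are near-complete, so the
policy is rarely exercised and its choice is not material; the count of
filled months is logged.

Eligibility keeps women aged 15–44 in completed years — `floor((start_cmc −
birth_cmc)/12)` — at the start of the window, the standard demographic
convention; both bounds are inclusive and the filter is idempotent.

## Distances

The OM distance is the minimum total cost of substitutions and
insertions/deletions transforming one sequence into another, computed by
the `(|a|+1) × (|b|+1)` dynamic program. The default cost scheme is the
canonical sequence-analysis constant scheme — every substitution 2, indel 1
— exposed in `cost_scheme()` together with a full 5×5 substitution-matrix
hook. The defaults are a declared assumption, recorded in output metadata:
analyses of this kind conventionally report "a constant cost matrix"
without printing the constants.

Two performance decisions matter for desk-scale runs:

* **Deduplication.** Identical sequences are collapsed before the O(u²·59²)
  distance computation, with survey weights summed onto the unique
  representative. This is exact — weighted PAM, the quality metrics in
  their weight-corrected forms, and all weighted descriptives treat a
  weight-w point identically to w unit-weight copies — and the package
  tests that equivalence end to end. A sample of 10,000 noisy synthetic
  sequences collapses to roughly 8,000 unique ones; real calendar data,
  dominated by a few archetypal patterns, collapses much further.
* **A bit-parallel fast path.** With a constant scheme satisfying
  `sub ≥ 2·indel`, a substitution is never strictly cheaper than a
  deletion plus an insertion, so for equal-length sequences the OM distance
  equals `indel · (2L − 2·LLCS)`. The longest-common-subsequence length of
  two 59-month sequences fits one 64-bit word, so the pairwise matrix uses
  an Allison–Dix bit-parallel kernel in this regime. The fast path is
  verified against the full dynamic program in property tests and is
  disabled automatically for cost schemes where the reduction does not
  hold.

An exhaustive-recursion reference implementation
(`om_distance_reference()`, guarded to length ≤ 8) ships in the package as
the independent oracle for the dynamic program.

## Clustering

`pam()` is weighted partitioning around medoids: a greedy BUILD phase
(each added medoid maximizes the weighted reduction in total cost) followed
by best-improvement SWAP (accept the single best strictly improving
medoid/non-medoid exchange; stop when none exists). Every tie — BUILD
candidates, equal-improvement swaps, nearest-medoid assignment — breaks to
the lowest index, so a given matrix always yields the same solution. The
SWAP loop is capped at 500 iterations as a guard against cycling under
exact ties; the cap has never been observed to bind and a warning fires if
it does.

Single-start PAM is a local search, and on small random instances it
occasionally converges one swap short of the global optimum. `pam()`
therefore restarts the search with each point forced as the initial BUILD
medoid when the matrix is small (u ≤ 50, where the extra cost is trivial)
and keeps the best objective; large matrices use the canonical single
BUILD. In testing, the multi-start version matches brute-force enumeration
over all medoid subsets on hundreds of random instances with u ≤ 8, k ≤ 3.

The number of clusters is chosen by `select_k()`, which fits PAM for each
candidate k and reports three weighted quality metrics:

* **ASW** — weighted average silhouette width, with the own-cluster mean
  distance computed self-excluded in a weight-corrected way (denominator
  `W_own − w_i`), which keeps the metric invariant to rescaling all weights
  and consistent with the duplicate-aggregation view of weights;
* **PBC** — weighted Pearson correlation between pairwise distances and
  the different-cluster indicator;
* **HG** — Hubert's Γ, `(s⁺ − s⁻)/(s⁺ + s⁻)` over weighted concordant and
  discordant (within, between) distance pairs, computed exactly from mass
  histograms of the distinct distance values (ties count in neither).

The default selection criterion is ASW — the most widely reported of the
three — but the full table is always retained and the criterion is
configuration, because the toolkit literature this follows reports several
metrics jointly rather than anointing one. Degenerate structure (all
distances equal, or fewer than three unique sequences) makes selection
abstain with a warning rather than return an arbitrary k.

## Cluster descriptives

`describe_clusters()` assembles what an analyst needs to label clusters:
the medoid sequence, monthly state distributions (the data behind density
plots), weighted mean months per state (which sum to 59 and equal the
column sums of the distribution table), the monthly cross-sectional Shannon
entropy normalized by log 5 (0 = everyone in the same state that month,
1 = uniform; the raw value is available via `normalize = FALSE`), and
Elzinga's turbulence

T(x) = log₂( φ(x) · (s²_max + 1)/(s² + 1) ),

where φ(x) counts the distinct subsequences (including the empty one) of
the distinct-successive-states sequence via the standard last-occurrence
DP, s² is the population variance of spell durations and s²_max its
maximum given the spell count (all spells minimal except one). A constant
sequence scores exactly 1. Descriptives are computed over all cluster
members, not just medoids, and are invariant to weight rescaling.

## Membership profiling

Each cluster is profiled by a separate binary logistic model — membership
vs. not — rather than one multinomial model, so every cluster (including
what would otherwise be the reference) gets a full covariate profile.
Estimation is weighted maximum pseudo-likelihood via IRLS (relative
deviance tolerance 1e-8, 100-iteration cap). The covariance is the
design-based linearization estimator: per-observation score contributions
`x_i w_i (y_i − p̂_i)` are summed to PSU totals, their covariance is
accumulated within strata with the `m_h/(m_h − 1)` correction, the total is
scaled by `(n − 1)/(n − p)`, and the sandwich is completed with the inverse
observed information. Wald p-values use a t reference with design degrees
of freedom (total PSUs minus strata) — the convention of the major survey
packages; with every observation its own PSU in one stratum, the estimator
reduces exactly to the classical HC1 robust covariance, which the tests
verify against an independent optimizer and the `sandwich` package.

Strata containing a single PSU cannot contribute a variance term; they are
collapsed into the nearest stratum by identifier with a warning (the common
certainty-unit fix). Perfect separation and empty covariate cells are
detected and reported as errors naming the offending terms rather than
returned as divergent estimates. `collinearity_check()` reports VIFs and
the design-matrix condition number with the customary warning thresholds
(10 and 30).

## The synthetic generator

The generator exists so that the full pipeline can be exercised, and its
recovery behavior quantified, without access-restricted survey microdata.
It encodes the study conditions the pipeline targets:

* **Six archetypes** (`default_archetypes()`): all-nonuse; two patterns
  with two 9-month pregnancy spells at different timings (months 5–13 and
  24–32 vs. 28–36 and 47–55); and three post-pregnancy adopters (nonuse
  months 1–15, pregnancy 16–24, then short-term modern, long-acting, or
  traditional method to month 59). The *states and their ordering* follow
  the published cluster descriptions; the exact spell boundaries are not
  published (the source figure is an image), so they are configuration
  with these invented defaults.
* **Mixture weights** default to the published cluster shares
  (41.5, 24.9, 18.1, 7.6, 5.6, 2.3 percent).
* **Sequence noise**: independent per-month substitution to a uniformly
  random other state (default probability 0.03) plus uniform spell-boundary
  jitter (default ±2 months, clamped so every spell keeps at least one
  month). This is the simplest model producing within-cluster heterogeneity
  around medoids. The published within-cluster heterogeneity is reported
  only qualitatively, so the defaults were chosen once to make recovery
  non-trivial but achievable, not to match unpublished statistics.
* **Covariates and effects**: categorical covariates with margins matching
  the published sample profile (education 44.8/36.8/18.4, contraceptive
  knowledge low vs. medium/high 29.2/70.8); fertility-desire margins are
  not published and default to (0.25, 0.35, 0.15, 0.25). In the default
  *binary mode*, membership in a focal cluster (the all-nonuse archetype)
  is Bernoulli through a logistic link whose coefficients mirror the
  published odds ratios — log(3.68) for secondary-plus education,
  log(1.10) for primary, log(0.70) for medium/high knowledge, log(0.35),
  log(4.21), log(0.35) for the fertility-desire contrasts — with the
  intercept solved numerically so the marginal focal share equals its
  mixture weight, and the remaining probability split over the other
  archetypes by renormalized mixture weights. Binary mode exists precisely
  so the logistic-recovery experiments have exactly-true coefficients. A
  covariate-free mixture mode and a simple multinomial-logit mode are also
  available.
* **Design**: PSUs and strata assigned round-robin (10 strata × 20 PSUs by
  default) and lognormal weights with mean 1 and CV 0.5, a realistic
  weight dispersion for a stratified two-stage household survey.

All randomness flows through one seed, restored on exit, so generation is
reproducible and side-effect free.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: switching and discontinuation dynamics
beyond the six archetypes (real calendars contain them; in the motivating
analysis they were too infrequent to form clusters), recall error that is
correlated in time rather than independent by month, covariate-dependent
sequence shapes (covariates act only through cluster membership),
intra-PSU correlation of covariates, and item nonresponse.

## Problem sizes and numerical choices

The recovery experiments in `scripts/acceptance.R` use the sizes at which
their Monte-Carlo error is comfortably inside the tolerances being checked:
n = 800 women for the k-selection sweep (about 750 unique sequences after
deduplication), n = 10,000 for mixture-share recovery (binomial sampling
error well under one percentage point per share), and 20 replicates of
n = 10,000 for odds-ratio recovery (reported as the mean estimated OR
across replicates). Distances are stored full precision and never
normalized by length (all sequences share length 59); PAM comparisons use
a 1e-12 tolerance so exact ties resolve by index; entropy treats 0·log 0
as 0; the turbulence subsequence count is exact in double precision for
any 59-month sequence.

## Known limitations

* OM variants (transition-rate-based costs, localized OM, Hamming/LCS as
  distances in their own right) are out of scope beyond the user-supplied
  substitution matrix hook.
* Hierarchical and fuzzy clustering, and subsampling schemes for samples
  far beyond desk scale, are not provided.
* The profiling models are main-effects logistic regressions, matching the
  motivating analysis: no interactions, model selection, or
  multiple-testing adjustment.
* The multinomial-logit robustness companion to the per-cluster logistic
  models is noted but deliberately not implemented.
* Calendar input is delimited text; native fixed-width survey exports
  should be converted upstream, and the reasons-for-discontinuation
  calendar column is not reconciled.
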