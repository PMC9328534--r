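# calseg

Behavioral segmentation of contraceptive calendar histories.

Demographic and Health Surveys (DHS) collect a retrospective *contraceptive
calendar*: one character per month recording whether a woman was pregnant,
using a contraceptive method (and which), or using nothing. `calseg` turns
these month-by-month histories into behavioral segments and composite
profiles, for reproductive-health researchers and program planners who want
to know *which* distinct patterns of contraceptive behavior exist in a
population and *who* the women following each pattern are.

The pipeline:

1. **Parse** DHS-style calendar strings into 59-month sequences over five
   states — nonuse (`NONE`), short-term modern method (`STM`),
   long-acting/permanent method (`LAPM`), traditional method (`TRAD`),
   pregnancy/birth/termination (`PREG`) — with month 1 the earliest month
   and month 59 the interview month.
2. **Compare** sequences with the optimal-matching (OM) edit distance: the
   minimum total cost of substitutions (cost 2 by default) and
   insertions/deletions (cost 1) transforming one sequence into the other,

   d(x, y) = min over alignments of [ Σ sub(x_i, y_j) + indel · (#ins + #del) ],

   computed by the standard dynamic program over the deduplicated set of
   unique sequences, with survey weights aggregated over duplicates.
3. **Cluster** with weighted k-medoids (PAM: greedy BUILD seeding plus
   best-improvement SWAP), choosing the number of clusters by a sweep of
   quality metrics — weighted average silhouette width (ASW), point-biserial
   correlation (PBC) and Hubert's Γ — each in [−1, 1].
4. **Describe** each cluster: medoid sequence, monthly state distributions,
   mean months per state, cross-sectional entropy, and Elzinga's turbulence
   T(x) = log₂( φ(x) · (s²_max + 1)/(s² + 1) ), where φ counts distinct
   subsequences of the spell sequence and s² is the spell-duration variance.
5. **Profile** cluster membership with survey-weighted logistic regression:
   weighted maximum pseudo-likelihood estimates with Taylor-linearized
   (PSU/stratum sandwich) variance and t-based Wald tests on design degrees
   of freedom, so odds ratios and p-values respect a stratified multistage
   design.

Because the microdata that motivated the package are access-restricted, a
first-class synthetic generator reproduces the structure the analysis
assumes — six archetypal sequences (an all-nonuse "Quiet Calendar", two
two-pregnancy "Family Builders" at different timings, and post-pregnancy
adopters of short-term modern, long-acting, and traditional methods),
published mixture weights, sequence noise, covariates linked to membership
through a logistic model with published odds ratios as true effects, and a
stratified two-stage sampling design — so every stage is testable at desk
scale.

## Worked example

```r
library(calseg)

gen  <- generate(generator_config(n_women = 1000, seed = 1))
conv <- records_to_sequences(gen$records)       # parse + 59-month windows
diss <- pairwise_matrix(conv$seqs, conv$records$weight)
diss
#> <calseg_diss: 887 unique sequences (from 1000), sub 2 / indel 1>

report <- select_k(diss, k_range = 2:8, criterion = "ASW")
report
#> <quality_report: criterion ASW, selected k = 6>
#>  k    ASW    PBC     HG objective
#>  2 0.4166 0.4556 0.5813     20802
#>  3 0.5331 0.6857 0.8296     16243
#>  4 0.5775 0.7186 0.8681     12053
#>  5 0.7127 0.7315 0.9663      8183
#>  6 0.7715 0.7544 0.9999      6326
#>  7 0.6470 0.7089 0.9926      5929
#>  8 0.5799 0.6961 0.9923      5747
```

The ASW peaks at k = 6: the sweep recovers the six generating archetypes.
(PBC and HG agree here; all three are reported so the choice can be
reviewed.) Descriptives give each cluster's weight share and volatility:

```r
sol  <- report$solutions[["6"]]
desc <- describe_clusters(conv$seqs, conv$records$weight, diss, sol)
desc
#> <cluster_descriptives: 6 clusters>
#>   cluster 1: share 42.5%, n 422, mean turbulence 5.15
#>   cluster 2: share 14.4%, n 151, mean turbulence 10.20
#>   ...
```

Cluster 1 is the all-nonuse segment (share near the generating 41.5%; its
turbulence is lowest because its sequences are nearly constant). Profiling
membership in that cluster against covariates, with design-based variance:

```r
asgn   <- expand_assignment(diss, sol)
amap   <- match_clusters_to_archetypes(conv$seqs, diss, sol)
design <- svy_design(conv$records$weight, conv$records$psu,
                     conv$records$stratum)
rec <- conv$records
rec$member <- as.numeric(asgn == which(names(amap) == "Quiet Calendar"))
fit_membership(member ~ education + knowledge + fertility_desire, rec,
               design)
#> <membership_fit: n=1000, design df=190>
#>                     term estimate odds_ratio    se     t  p_value
#>              (Intercept)    0.039      1.040 0.193  0.20 8.39e-01
#>         educationprimary    0.150      1.162 0.193  0.78 4.38e-01
#>  educationsecondary_plus    1.254      3.504 0.207  6.06 7.35e-09
#>         knowledgemedhigh   -0.377      0.686 0.150 -2.51 1.29e-02
#>   fertility_desireafter2   -0.844      0.430 0.186 -4.55 9.63e-06
#>   fertility_desireunsure    1.073      2.924 0.264  4.06 7.12e-05
#>   fertility_desirenomore   -0.997      0.369 0.204 -4.89 2.11e-06
```

The estimated odds ratios sit near the generator's true effects (3.68 for
secondary-plus education, 0.70 for medium/high contraceptive knowledge,
4.21 for "wants a child, unsure of timing"); at n = 1000 a single replicate
carries visible sampling noise, which the recovery experiments below average
away.

`run_all(run_config(...))` chains every stage, writes each intermediate
table as CSV and records a JSON run manifest. A thin command-line wrapper
lives at `inst/cli/calseg.R` (`simulate`, `sequences`, `run-all`,
`show-config`).

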