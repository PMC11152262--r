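# elderwell

`elderwell` is an R package for studying how lifelong learning relates to
the subjective wellbeing of older adults from item-level survey responses.
It targets analysts working with instruments such as CASP-19 (19-item
quality of life), the Satisfaction with Life scale (5 items, 1–7) and the
WHO-5 wellbeing index (5 items, 1–6), together with demographic fields and
learning measures (attitude towards learning, classes taken, places
visited).

## The Multidimensional Wellbeing Index

The core of the package is a composite index built with the
normalized-distance methodology of the financial-inclusion index
literature. Each item response `A_j` on an item with bounds `[m_j, M_j]`
is first normalized to the unit interval,

    d_j = (A_j − m_j) / (M_j − m_j)

(reversed for items keyed so that a low raw response is favourable). A
respondent's `k` normalized responses are then aggregated as

    MWI(d) = ½ [ ‖d‖₂ / √k  +  ( 1 − ‖1 − d‖₂ / √k ) ],

the average of the normalized Euclidean distance from the worst possible
answer profile and one minus the distance from the best. The index is

* **unit free** — comparable across respondents and instruments,
* **bounded** in [0, 1], reaching 0 only at the all-worst profile and 1
  only at the all-best profile,
* **monotone** — strictly increasing when any dimension improves,
* **scale invariant** — unchanged by affine rescaling of the raw
  responses and their bounds,

and satisfies the complement symmetry `MWI(d) + MWI(1 − d) = 1`. All four
properties are enforced by the test suite.

Around the index the package provides the full analysis pipeline:
codebook-driven reading and validation of survey CSVs, the categorical
recodings used downstream (wellbeing quartiles, children bands,
binarized activity counts, collapsed health/relationship/education
levels), multiple correspondence analysis of the one-hot indicator matrix
(SVD of standardized residuals, implemented from first principles),
pre-pruned CART regression trees (minimum 20 observations per split,
minimum gain 1% of root SSE), and OLS with heteroskedasticity-robust
(HC0–HC3) standard errors. A synthetic survey generator with known
ground-truth effects makes every stage testable without microdata.

## Worked example

```r
library(elderwell)

gen    <- generate_survey(generator_config(n = 300, seed = 42))
scores <- score_table(gen$table)
coded  <- collapse_levels(gen$table, scores)

round(colMeans(scores[-1]), 3)
#>       mwi_quality  mwi_satisfaction mwi_psychological
#>             0.574             0.635             0.634

round(mwi_correlations(scores), 2)
#>                   mwi_quality mwi_satisfaction mwi_psychological
#> mwi_quality              1.00             0.53              0.51
#> mwi_satisfaction         0.53             1.00              0.68
#> mwi_psychological        0.51             0.68              1.00

regs <- fit_wellbeing_regressions(coded, scores)
table3_layout(regs)
#>               quality   satisfaction psychological
#> learn_elderly 0.0412*** 0.0109       0.0013
#>               (0.0151)  (0.0147)     (0.0147)
#> class_total   0.0517*** 0.0698***    0.0680***
#>               (0.0083)  (0.0079)     (0.0076)
#> ...
#> Observations  292       292          292
#> R-squared     0.263     0.497        0.425

fit_mca(one_hot(coded))
#> <mca_result> 292 cases, 16 variables, 39 categories
#>   total inertia 1.4375 = (J - Q)/Q; first dims explain 10.7%, 7.0%, 6.8%

wellbeing_tree(coded, scores, "quality")
#> 0.57 / 100%
#>   [health_good_not good] 0.52 / 36%
#>     [class_total <= 0.5] 0.49 / 18%
#>     ...
```

The index means sit near 0.6 (each index ranges 0–1 with 1 the best
wellbeing); the three indices correlate at a medium 0.5–0.7, capturing
related but distinct aspects of wellbeing. The regression table shows,
for this synthetic cohort, a positive lifelong-learning-attitude
association with quality of life and class-participation associations
with all three indices — the effect structure the generator plants. The
regressions use 292 of 300 rows because 8 respondents have a missing
learning-attitude answer. Each tree node is labelled with its mean index
value over the sample share shown below it (the root holds 100% of the
sample).

The full pipeline — scoring, recoding, descriptives, MCA, trees,
regressions, with a manifest and log — runs in one call:

```r
run_full_analysis(generator_config(n = 300, seed = 42), "out/")
```

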