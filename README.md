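# etiohet

Supervised discovery of **etiologically distinct tumor subtypes** from
genomic profiles and epidemiologic risk factors.

Classical subtype discovery clusters genomic profiles and keeps the
partition with the best clustering objective. `etiohet` instead asks
which candidate partition is most strongly *predicted by the risk
factors* — smoking, BMI, hypertension, gender, age — in a case-only
series. It is aimed at molecular/genetic epidemiologists working with
case series such as TCGA cohorts joined to chart-review risk-factor
data.

## The statistic

For candidate subtype labels, a polytomous logistic regression of
subtype on the risk factors yields membership probabilities
`u_ji = P(subtype j | covariates of case i)`. The case-only etiologic
heterogeneity statistic is

    D* = (1/N) Σ_i Σ_j (u_ji − π_j)² / π_j ,     0 ≤ D* ≤ m − 1,

the case-average chi-square deviation of the fitted memberships from the
class proportions π. D* is the case-only counterpart of the incremental
risk-prediction measure `D = Σ_j π_j K_j² − K²` built from the
coefficients of variation of subtype-specific risks (`compute_components()`
evaluates D in three algebraically equivalent forms and checks them
against each other at 1e-10).

The pipeline: restarted k-means generates candidate partitions (local
maxima of the between-cluster sum of squares G); every unique partition
is scored with D*; the max-D* solution is selected; permutation of the
case labels (re-pairing genomic and risk profiles) calibrates a test for
the presence of heterogeneity and for the number of subtypes. Post-hoc
tools cover risk-profile tables, mutation associations, cross-platform
congruence, competitive gene-set enrichment and survival summaries, and a
synthetic-data module provides planted-truth worlds for validation.

## Worked example

```r
library(etiohet)

sc <- scenario_config(N = 200, m = 2, effect_scale = 1.5,
                      genomic = list(p = 60, effect = 2,
                                     signal_features = 6), seed = 1)
truth <- generate_population(sc)      # population with planted subtypes
cases <- sample_cases(truth)          # risk-biased case sampling
X     <- generate_genomic(cases$labels, sc)

ens  <- run_restarted_kmeans(X$values, m = 2, n_restarts = 100, seed = 1)
ens  <- score_ensemble(ens, cases$risk)
best <- select_solution(ens, "max_D_star")

length(ens$solutions)                        # 1  (one unique local maximum)
best$D_star                                  # 0.142
adjusted_rand_index(best$labels, cases$labels)  # 1  (planted truth recovered)

het <- heterogeneity_test(X$values, cases$risk, m = 2, B = 199,
                          n_restarts = 100, seed = 1)
het$p_value                                  # 0.01

risk_profile_table(best$labels, cases$risk)
```

```
         factor      level subtype_1 subtype_2
1       smoking      never        36        30
2       smoking     former        39        43
3       smoking    current        25        26
7  hypertension         no        23        39
8  hypertension        yes        77        61
9        gender       male        23        70
10       gender     female        77        30
11          age     median      59.7      57.5
```

Reading the output: the two subtypes split cleanly (ARI 1 against the
planted labels), the selected solution carries heterogeneity D* = 0.142,
and the permutation test rejects "no genomic/risk-factor association" at
p = 0.01. The profile table shows what drives it — subtype 1 is
female-predominant (77% vs 30%) with elevated hypertension (77% vs 61%),
the planted signature; entries are within-subtype percentages that sum to
100 per factor.

A command-line surface wraps the same pipeline
(`simulate | prep | cluster | test-het | test-k | posthoc`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "etiohet.R", package = "etiohet"))')" \
    cluster config.json
```

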