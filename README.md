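# NearestCC

Nearest consensus clustering classification: discover patient subgroups by
consensus over repeated resampled K-means clusterings, fit one gain-ratio
decision tree per discovered subgroup, and classify a new patient with the
tree of their linkage-nearest subgroup.

The package is aimed at clinical modellers working with heterogeneous
diseases (the motivating schema is a systemic-sclerosis registry: continuous
labs such as hemoglobin, creatinine, FVC and DLCO, binary autoantibody
flags, and right-censored times to death or to pulmonary arterial
hypertension) where different patient subgroups follow different — even
opposite — outcome rules, so that a single pooled classifier underperforms.

## Method

For training rows with standardized features:

1. draw B = 10 resamples of 80% of the rows and run one plain K-means on
   each;
2. build the n x n **agreement matrix**: entry (i, j) counts the resampled
   clusterings placing i and j in the same cluster, normalized by the
   number of resamples drawing both;
3. apply K-means to the rows of that matrix (each patient's co-clustering
   profile) to extract K **consensus clusters**;
4. fit one **C4.5-style gain-ratio tree** per cluster (gain ratio
   `gain / splitInfo` with C4.5's average-gain admissibility safeguard),
   plus a fallback tree on all rows.

A new patient is routed to the cluster minimizing the single-linkage
(minimum; complete and average are available) Euclidean distance to the
cluster's members and classified by that cluster's tree. Baselines with the
identical pipeline: **nearest K-means** (one K-means partition, no
consensus) and a **global tree** (no clustering). The package also provides
the repeated stratified 80/20 holdout protocol with confusion metrics and
Welch t-tests, a K sweep, per-cluster Kaplan–Meier curves, pluggable
cluster/classifier combinations (PAM, hierarchical, SVM), and a
planted-subgroup synthetic cohort generator so everything is testable
without clinical data.

## Worked example

```r
library(NearestCC)

sim   <- generateCohort(defaultSscLikeSpec(), seed = 42)   # 600 patients
model <- fitNearestCC(sim$table, k = 3, seed = 42)
model
#> NccModel (nearest-cc): 3 cluster(s), linkage = single
#>   cluster 1: 167 members, tree depth 5
#>   cluster 2: 249 members, tree depth 5
#>   cluster 3: 184 members, tree depth 5
#>   fallback tree depth 5

res <- repeatedHoldout(sim$table,
                       list(nccMethod("nearest-cc"), nccMethod("global-tree"),
                            nccMethod("nearest-kmeans")),
                       repeats = 10, seed = 42)
res
#> ExperimentResult: 10 repeats, test fraction 0.20
#>   global-tree        mean error 0.2758
#>   nearest-cc         mean error 0.1100
#>   nearest-cc.K1      mean error 0.3725
#>   nearest-cc.K2      mean error 0.4483
#>   nearest-cc.K3      mean error 0.4042
#>   nearest-kmeans     mean error 0.2083
#>   nearest-kmeans.K1  mean error 0.3825
#>   nearest-kmeans.K2  mean error 0.4008
#>   nearest-kmeans.K3  mean error 0.4083

welchT(errorVector(res, "nearest-cc"), errorVector(res, "nearest-kmeans"))$p
#> [1] 0.00905
```

Reading the output: the consensus classifier has the lowest held-out error
(0.11); the global tree (0.28) beats every single-cluster tree evaluated on
the whole test set (`*.K1..K3`, 0.37–0.45), because each of those has
learned only one subgroup's rule; nearest K-means (0.21) sits between —
here its single clustering run failed on some repeats, and the Welch test
flags the consensus advantage (p = 0.009). Survival separates by
discovered cluster:

```r
sapply(kmByCluster(model, sim$table), kmSurvivalAt, t = 120)
#>  cluster1  cluster2  cluster3
#> 0.5075578 0.2231832 0.0765070
```

i.e. 120-month event-free fractions of ~51%, ~22% and ~8% for the three
discovered clusters, mirroring the planted hazards.

Command-line entry points (`simulate`, `fit`, `predict`, `evaluate`,
`sweep-k`, `compare`, `km`) live in `inst/scripts/ncc-cli.R` over the same
functions.

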