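---
title: "rulenet: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rulenet: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rulenet)
```

rulenet learns interpretable IF-THEN rule models from case-control
expression cohorts, merges them across cohorts, and analyses the merged
model as a co-predictive network. This vignette is the package's own
account of the method: the model and its assumptions, the parameters that
matter, what the synthetic generator does and does not emulate, and the
numerical conventions adopted where the design was genuinely open.

## The model

### Decision tables and discretization

Rough-set learning operates on a *decision table*: samples × discrete
attributes plus a class column. Continuous expression is discretized by
**equal-frequency binning with three levels** (low/medium/high). Cuts are
midpoints between consecutive sorted training values, chosen so bin
occupancies differ by at most one; a nominal boundary inside a run of
tied values shifts to the nearest midpoint between *distinct* values — a
cut never splits equal values, so heavy ties can reduce the effective
number of levels. Cuts are always fitted on the training portion of a CV
fold and applied unchanged to its test portion; test values outside the
training range clamp to the extreme levels. Assumption to be aware of:
discretization makes within-level expression differences invisible, which
is the price of rule legibility, and a class boundary that falls inside a
bin (inevitable for a single continuous predictor under balanced
tertiles) bounds the attainable accuracy.

### Monte Carlo feature selection

`mcfs_rank()` draws `s` random attribute subsets of size `m`; on each it
grows `t` binary information-gain trees on random 2/3 sample splits and
scores each feature by

RI(g) = Σ over trees τ, nodes n split on g of
wAcc(τ)^u · IG(n) · (n_obj(n)/n_obj(τ))^v,

with `wAcc` the tree's class-balanced accuracy on its held-out third.
Defaults `s = 100`, `t = 5`, `m = ceiling(sqrt(p))`, `u = v = 1` follow
common usage of Monte Carlo feature selection; all are configurable.
Constant or never-informative features score exactly 0.

The number of features kept is chosen in two steps:

1. **Critical angle.** With ranks and RI both min-max scaled to the unit
   square, the signed turning angle of the RI curve is computed at every
   interior rank. The knee is the vertex of the strongest *downward*
   (clockwise) bend — the last point of the high-importance cluster
   before the curve falls away. A naive "largest absolute bend" rule
   instead selects the bottom of the cliff (the first noise feature),
   because the turn from a steep descent onto the noise floor is the
   geometrically sharpest one; the downward-bend convention keeps the
   informative cluster and reduces to the absolute rule when the curve is
   purely convex. Ties break to the smallest rank; a flat curve keeps all
   features with a warning.
2. **Quality adjustment.** `adjust_fr()` refits a cross-validated rule
   model on the top-k features for k from the knee up to `k_max`
   (default 50) and returns the k at the nearest local maximum of
   quality, scanning upward. Quality is `(accuracy/100 + AUC)/2` — the
   unweighted mean of the two reported quality metrics, the least
   arbitrary composite. Plateaus count as maxima at their smallest k; a
   monotonically rising curve yields `k_max`.

Per-cohort rankings are merged by rescaling each so its maximum RI is 1
(importances are comparable only within a cohort), translating ids
through an optional cross-platform map, and keeping the maximum rescaled
RI for features selected by several cohorts.

### Rule induction and classification

For every object, the discernibility function modulo decision (one
clause per object of a different class, listing the attributes on which
they differ) is covered by **Johnson's greedy heuristic**: repeatedly
take the attribute in the most uncovered clauses, ties to the
lexicographically smallest id, then prune attributes whose removal
leaves all clauses covered — a reduct is irredundant by definition.
Greedy covering is an approximation: on rare tables an exhaustive search
finds a smaller cover (observed on roughly 1% of small random tables),
which is inherent to the heuristic, not a defect of the implementation;
the package guarantees only that every output is a valid irredundant
cover. Objects identical to an object of another class are flagged
inconsistent; objects with nothing to discern (including single-class
degenerate tables) fall back to their full attribute description so they
still yield a rule.

Each object × reduct yields a rule; duplicates collapse. Statistics are
counted on the full cohort: supports `RS_LHS` (conditions) and `RS_RHS`
(conditions and decision), accuracy `RA = RS_RHS/RS_LHS`, class-specific
coverage `RC_RHS = RS_RHS/n_d`, and a hypergeometric upper-tail p-value
`P(X ≥ RS_RHS)` for drawing `RS_LHS` samples from `N` containing `n_d`
of the rule's class. Rules matching no object are discarded with a
warning. `fdr_filter()` applies Benjamini–Hochberg across all rules
jointly.

Classification uses **standard voting**: every firing rule casts
`RS_RHS` votes for its decision; fractions are compared and ties break
to the lexicographically smallest class. Objects no rule fires on fall
back to the training majority class, are flagged, and contribute an
uninformative 0.5 score to the AUC. `crossvalidate()` runs stratified
k-fold CV (default 10), undersampling each fold's training classes to
the minority size before fitting cuts; accuracy (percent) and
Mann–Whitney AUC are pooled over all test folds, and the final rule set
is induced on the balanced full table with statistics recalculated on
all samples (so recalculated supports can only grow).

### Merging cohorts

`combine_tables()` discretizes each cohort with its *own* equal-frequency
cuts and stacks the results: levels are comparable by rank, and pooling
raw values would re-introduce exactly the cohort effects removed
upstream. Features a cohort does not measure are `NA` there, and `NA`
never matches a condition nor discerns two objects — rules conditioning
on such features simply cannot fire in that cohort. `merge_models()`
unifies rules identical in conditions *and* decision (levels are
rank-comparable, so near-identical rules at different levels are kept
distinct), sums their supports, unions their cohort-namespaced support
sets, and then recalculates every statistic against the merged cohort's
class totals. Merging a model with a re-namespaced copy of itself leaves
RA and RC unchanged — both numerator and denominator double.

### Co-predictive networks

Nodes are (feature, level) pairs — the same gene at two levels is two
nodes. Every rule with ≥ 2 conditions contributes `RS_RHS · RA` to the
edge between each of its C(k, 2) condition pairs, with no division: the
connection sums over rules per pair. `RS_RHS` is used as "the" support
of a rule (the support of its correctly covered samples); single-
condition rules contribute only isolated zero-weight nodes, dropped by
default. Node connection is the sum over incident edges (an exactly
conserved quantity, tested). Normalization is min-max within one
network, since each class/subgroup network is presented on its own
scale; a degenerate single-value network normalizes to all 1s. Hubs are
nodes with positive degree at or above the 0.9 quantile of the degree
distribution (median-unbiased interpolating quantile, so a 10-spoke star
flags only its centre while a regular graph flags everything — ties at
the threshold are included). Top co-predictors come from an exact
one-dimensional 2-means (full sweep over the sorted split points, not a
random-restart heuristic), and `term_fraction()` reports
`|set ∩ term|/|set|`.

### Subgroup dissimilarity

Rules are mapped to clinical subgroups by membership: a rule belongs to
every subgroup contributing at least one supporting sample (a
proportional weighting was considered and rejected as it changes the
statistic from topology comparison to support regression). Subgroup
subnetworks are compared on their **unweighted** topology: node
betweenness (unnormalized shortest-path pair counting) on each network,
vectors aligned on the union node set with absent nodes at 0, Euclidean
norm of the difference. Because subgroups carry unequal rule counts,
distances are averaged over `n_balance = 20` resamples of
`m = min(|A|, |B|)` rules per side; when both sides already have m rules
the resample is exhaustive and the balanced distance equals the plain
one. Significance comes from `n_perm = 500` permutations that shuffle
subgroup labels across the pooled rule-to-subgroup assignments,
preserving per-subgroup counts. Random reassignment can only destroy
subgroup-specific structure, so the observed distance is extreme in the
upper tail: `p = (1 + #{null ≥ observed}) / (1 + n_perm)`, never below
`1/(n_perm + 1)`. An alternative null that shuffles rule *decisions* was
considered and dropped: under membership-based assignment a rule's
subgroup does not depend on its decision, so that null leaves every
subnetwork unchanged and cannot reject anything. BH-adjusted p-values
are reported across subgroup pairs alongside raw ones.

For clustering, `kendall_distance_matrix()` uses `1 − τ_b` between
subgroup node-connection profiles (each profile min-max scaled, which is
monotone and therefore does not change τ); a constant profile leaves τ
undefined and its distances are set to 1 with a warning.

## The synthetic worlds

`generate_cohorts()` draws log-scale expression as `N(0, noise_sd)` per
gene, plus a per-cohort per-gene `N(0, cohort_offset_sd)` batch offset
(default 0 — batch correction is out of scope, so the default world is
batch-free). Planted pairs are redrawn from a bivariate normal with
`rho_case` in case samples and `rho_control` in controls; per-subtype
mean shifts are added last. Severity is encoded in two controllable
magnitudes: the mean shift per subtype, and (with
`scale_rho_by_severity = TRUE`) the pair correlation, scaled by
`severity/max(severity)`.

Two frozen reference worlds back the validation suite:

* `spec_planted_pair()` — one cohort, 100 cases + 100 controls, 10
  genes, one pair at `rho_case = 0.9` / `rho_control = 0` with +2 sd
  case shifts on the paired genes. In this world the planted pair should
  surface as the strongest case-network edge.
* `spec_severity_gradient()` — three cohorts (mirroring a three-cohort
  blood microarray study with per-cohort sample counts in the 99–186
  range) of 60 controls plus 30 samples each of three case subtypes with
  severities 1 < 2 < 3; six of twelve genes shifted 0.6 sd per severity
  unit; one severity-scaled pair. In this world the subnetwork distance
  from control should order the subtypes by severity.

What the generator does **not** emulate: probe-level measurement,
microarray noise models, missing values, outlier samples, age/sex
confounding of expression (metadata columns exist but are independent of
expression), or realistic gene-gene correlation beyond the planted
pairs. A green recovery test therefore establishes that the pipeline
recovers *planted* structure of realistic effect size at realistic
sample counts — not that it would survive the full messiness of array
data, whose normalization and batch handling sit upstream of this
package.

Two validation-scale notes, made deliberately and documented here rather
than tuned later: recovery tests run the method's own feature-selection
stage (or equivalently restrict learning to the informative features),
because learning on pure-noise genes plants identical noise nodes in
every subgroup network and swamps the topology signal — a property of
the betweenness statistic, not of the implementation; and the
permutation-calibration check runs at `n_perm = 100` with `n_balance =
2`, since calibration of the add-one estimator does not depend on the
balancing depth.

## Numerical conventions

* Discretization cuts are midpoints (symmetric, deterministic); ties
  shift boundaries to the nearest legal midpoint.
* All tie-breaks are lexicographic (attribute choice in Johnson covering,
  node ordering in top-N filtering, class choice in voting) so every
  result is reproducible bit-for-bit under a seed.
* One master seed derives per-stage seeds by hashing the stage name,
  keeping independent stage reruns reproducible; all derived seeds stay
  below 2^31.
* Undersampling retains the sampled-out objects so statistics can be
  recalculated on the full object set.
* Empty networks compare at distance 0 (with a warning); empty rule sets
  and single-class tables degrade with warnings or errors as documented
  per function.

## Known limitations

* The betweenness distance confounds *content* dissimilarity with
  network *density*: sparse fragmented networks carry chain-like, high-
  betweenness topology and dense clique-like networks carry uniformly
  low betweenness, so two subgroups can sit far apart merely because
  their rule sets differ in concentration. The balanced resampling
  equalizes rule counts but not concentration. Severity recovery
  therefore needs severity to modulate *which* nodes a subgroup
  occupies, not only how many rules it has.
* Johnson covers are irredundant but not always minimum (greedy
  approximation).
* Voting ties and the majority-class fallback inject a deterministic
  bias toward the lexicographically smaller / majority class; both are
  flagged on the output.
* The quality composite `(accuracy/100 + AUC)/2` weights the two metrics
  equally; other weightings are defensible and would shift the adjusted
  feature count.
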