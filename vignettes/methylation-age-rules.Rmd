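---
title: "Methods: rule-based discovery of age-associated methylation patterns"
author: "MethylAgeRules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based discovery of age-associated methylation patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MethylAgeRules)
```

# Overview

`MethylAgeRules` discovers combinations of CpG sites whose methylation
state changes between developmental stages. The pipeline discretizes
array beta values into three states, ranks sites by Monte Carlo feature
selection (MCFS) across sliding binary age cuts, groups ages by the
Jaccard distance between per-cut significant-site sets, induces
under-sampling-balanced rough-set IF-THEN rules over the resulting age
classes, filters them by hypergeometric significance, and scores
pairwise condition interactions. This vignette documents the model, the
parameters that matter, the numerical conventions, and what the
synthetic validation does and does not establish.

# Data model and preprocessing

A cohort is a `SummarizedExperiment` subclass holding one `beta` assay
(probes × samples, values in [0, 1]), per-sample `age_years` (fetal
samples carry a single negative age, by default −0.5 years, so that
every age cut is a plain threshold), and per-probe annotations
(chromosome, gene, genomic-region tag, nonspecific and polymorphic
flags).

Three exclusion rules run before any analysis, in this order of
attribution: chromosome-X probes (sex-mixed cohorts make X readouts
unreliable), probes flagged nonspecific or polymorphic, and probes with
sample standard deviation of beta below `sd_cutoff` (default 0.02 on
the beta scale; a probe whose SD *equals* the cutoff is retained — the
comparison is strictly "below"). The retained set is identical under
any rule order; only the report attribution depends on it. Standard
deviation uses the n−1 denominator.

Beta values discretize into `unmethylated` (β ≤ 0.2), `intermediate`
(0.2 < β < 0.8) and `methylated` (β ≥ 0.8). Both boundary values belong
to the extreme states. The three-state reduction reflects the strongly
bimodal distribution of array betas and makes rules readable; it also
deliberately discards within-state drift, which is why a linear
regression cross-check is carried alongside the rules (below).

# Decision tables over sliding age cuts

For every cut age a (default integers 0..60, hence 61 tables) samples
split into `youngerThan`a (age < a) and `olderThan`a (age ≥ a). Fetal
samples are younger than every nonnegative cut, so the cut at 0
discerns fetal from postnatal samples. Sweeps stop at 60 because
typical cohorts are sparse beyond that age; the sweep is configurable.
A cut that leaves an empty side is an error naming the cut.

# Monte Carlo feature selection

MCFS grows many small classification trees, each on a random feature
subset and a random stratified train/test split, and accumulates for
every feature g

$$\mathrm{RI}(g) \;=\; \sum_{\tau}
   \mathrm{wAcc}(\tau)^{u} \sum_{n \in \tau,\; g \text{ splits } n}
   \bigl[\mathrm{IG}(n)\, \tfrac{|n|}{|\tau|}\bigr]^{v},$$

where wAcc is the unweighted mean of per-class sensitivities on the
held-out split (so imbalanced tables do not reward majority dumping)
and IG is the information gain (log base 2) of the node's split.
`ri_norm` divides by the maximum RI.

Implementation choices, fixed and documented here:

* Trees are binary; a split sends one of the three states left and the
  rest right (the three singleton-versus-rest partitions cover all
  binary partitions of a three-value domain). Trees grow to purity with
  a minimum leaf size of 2. The best split maximizes IG; ties (within
  1e-12) go to the lowest feature index, then the lowest state. These
  are the simplest choices consistent with the IG-based RI definition.
* Stratified splits keep every class present in both parts (wAcc is
  undefined otherwise), with per-class training counts
  `round(train_fraction · n_c)` clamped to [1, n_c − 1]; every class
  therefore needs at least 2 samples.
* Defaults: `n_subsets` s = 2000 feature subsets of
  `subset_fraction` = 0.05 of the features (never fewer than 2),
  `n_splits` t = 5 splits per subset, `train_fraction` = 0.66, and
  exponents u = v = 1 — the conventional parameterization of the
  algorithm; all are exposed in `mcfsParams()`. Bundled analyses scale
  s and t down (stated below) since planted signal is recoverable at
  far smaller ensembles.
* Significance: the full procedure is re-run on `n_permutations`
  (default 20) label-permuted copies of the table; all features' null
  RIs pool into one null sample, and each feature's one-sided p-value
  is (1 + #{null ≥ RI}) / (1 + #null). Pooling buys resolution from few
  permutations; the resolution floor is 1/(1 + #null), so with very few
  permutations × features no feature can clear α = 0.05 — `runMCFS`
  callers should keep d · n_permutations ≥ 400 for α = 0.05. No
  multiple-testing correction applies at this stage (correction enters
  at the rule stage); the features with p < α form the cut's
  significant set (SFA).
* One seed drives the whole run (subset draws, splits, permutations), so
  a fixed seed reproduces RI exactly; relabelling feature *ids* (not
  columns) permutes the output identically.

The tree engine is compiled (Rcpp) and can optionally record every
tree's splits and test accuracy; the test suite re-derives RI from such
records to pin the streaming accumulation to its definition.

# Age grouping

Per-cut SFA sets are compared by Jaccard distance
$1 - |A \cap B| / |A \cup B|$, with two conventions the formula leaves
open: two empty sets are at distance 0 (cuts that flag nothing behave
identically) and empty-versus-nonempty is 1. Cut 0 is excluded from the
clustering — the birth transition is qualitatively its own class and
always remains one downstream. The cuts cluster by complete-linkage
agglomeration (`stats::hclust(method = "complete")`, the standard tool
for this task) and the dendrogram is cut into k groups; k is
user-chosen (default 3 postnatal groups, i.e. a four-class design with
fetus). When the groups are contiguous runs of ages, each group's
youngest age becomes an age-group boundary; non-contiguous groups
produce a warning and no boundaries, since boundaries would be
meaningless.

# Rule induction

The age-group table (restricted to the MCFS-significant sites) is
balanced by under-sampling: each of `n_reps` (default 100) replicates
keeps all samples of the smallest class plus an equal-sized random
subset, drawn without replacement, of every other class.

For each replicate, rules come from object-related reducts. For a
sample (object) o, the discernibility family collects — for every
other-class sample — the set of attributes on which the two differ;
pairs that no attribute discerns (contradictions introduced by
discretization) are skipped rather than erroring. A minimal hitting set
of that family is a minimal attribute set distinguishing o from all
discernible other-class samples; substituting o's states yields one
IF-THEN rule. Two reducers are available:

* `exhaustive` (default): all minimal hitting sets per object, by
  branch-and-exclude enumeration over a superset-minimized family with
  a final witness check. This reproduces the full minimal-rule set and
  is what the package's enumeration oracle verifies. A per-object cap
  (`max_reducts`, default 20 000) turns combinatorial blowups into an
  informative error rather than a hang.
* `johnson`: one greedy set-cover reduct per object (highest coverage
  first, ties to the lowest attribute index, redundancy-pruned) — the
  classical scalable choice; its rules are always a subset of the
  exhaustive set.

Both run on 64-bit attribute masks in compiled code up to 64 attributes
(plenty after MCFS selection), with a plain-R fallback beyond. An
object indistinguishable from every discernible other-class sample has
an empty family; by convention it contributes one singleton rule per
attribute (the empty set is vacuously sufficient, so the minimal
non-empty sufficient sets are the singletons). Duplicate (pattern,
class) objects are computed once.

`combineModels()` unions the replicates' distinct rules (same
conditions and decision), counts the replicates containing each rule
(`n_runs`), and re-evaluates accuracy — the fraction of a rule's
matching samples that belong to its decision class — and support — the
number of matching samples — on the *full* table. Full-table
re-evaluation is deliberate: a perfect rule for the smallest class
should report the whole class as support even though each balanced
replicate saw only a subset of the others. On a consistent table every
induced rule is minimal in the strong sense that deleting any condition
strictly lowers its accuracy; when discretization collides samples
across classes, deletion can leave accuracy unchanged, which is why
minimality is defined through discernibility rather than accuracy.

Classification is by voting: every satisfied rule adds
support × accuracy to its class; the largest vote wins, ties going to
the class with more training samples and then alphabetically; a sample
no rule fires on is unclassified. Stratified k-fold cross-validation
(default 10-fold, reduced with a warning when the smallest class is
smaller) counts unclassified samples as errors.

# Rule statistics and filtering

Each rule's enrichment is the hypergeometric right tail
P(X ≥ k) with population N (table size), K class members, n draws (the
rule's support) and k class-concordant matches, computed with
`stats::phyper` and verified in the tests against exhaustive draw
enumeration. Bonferroni correction multiplies by the number of rules in
the model under test — the model is the natural family here, since
every candidate rule of the combined model is examined.

The default filter keeps rules with corrected p < 0.05, accuracy
strictly above 0.75, and support of at least half the decision-class
size (`ceiling(0.5 · |class|)`). The support rule is class-referenced
— a perfect smallest-class rule with support equal to the whole class
passes at any class size — and the fraction is configurable. Filtering
is monotone: relaxing any threshold never removes a kept rule.

As a cross-check, `regressionCheck()` fits ordinary least squares of
age on the raw betas of a rule's sites and reports the overall F-test.
Singleton rules on drifting sites are typically significant there;
XOR-like conjunctive patterns — jointly but not marginally informative
— are not, which is exactly the added value of the rule model.
Zero-variance sites degrade to a warning and a non-significant flag.

# Interaction networks

For each decision class, every conjunctive rule contributes
accuracy × support to all `choose(c, 2)` unordered pairs of its c
conditions; singleton rules contribute nothing. Node identity includes
the state (`cg…=intermediate`), so one probe in two states is two
nodes. Total network strength therefore equals
Σ accuracy · support · C(c, 2) over conjunctive rules — an identity
the tests assert. Edges rank by strength, ties by the number of
contributing rules and then node ids; `topInteractions()` returns the
head of that ranking.

# The synthetic cohort generator

`simulateCohort()` exists so every stage can be validated against known
ground truth. It emulates:

* the bimodal beta distribution of methylation arrays: background
  sites draw a baseline from a mixture with modes near 0.05 and 0.9
  plus a uniform intermediate shoulder (weights 0.45 / 0.35 / 0.20);
* per-site Gaussian noise, truncated to [0, 1] — truncation, not
  re-sampling, keeps a fixed seed bit-reproducible;
* planted sites whose expected beta steps from `low_state_mean` to
  `high_state_mean` (direction `up`, reversed for `down`) at a chosen
  transition age;
* a study-like age design: by default 108 samples from −0.5 to 84
  years with at least a quarter fetal, postnatal ages drawn uniformly
  on the integers with both endpoints forced present so that every cut
  0..60 is two-sided.

Noise is assigned in age-sorted order, so generation commutes with
sample reordering for distinct ages. It does **not** emulate: batch or
chip effects, detection failures, probe cross-hybridization chemistry,
correlated neighbouring probes, within-fetal age structure, or —
importantly — *gradual* methylation drift: planted transitions are
steps. Passing the planted-recovery tests therefore shows the machinery
recovers clean combinatorial state changes; it does not certify
behaviour on slowly drifting or confounded real data.

The bundled fixture (`examplePlantedCohort()`) plants 10 sites, all
transitioning at age 30 (five 0.15 → 0.45, five 0.85 → 0.55, SD 0.10)
among 200 background sites in 100 samples. The low sides straddle the
0.2/0.8 thresholds, as real transitioning sites do, so individual
discretized sites are informative but noisy and rule models must
combine sites — which is what makes the fixture a meaningful test of
the conjunctive machinery.

# Validation design and problem sizes

The test-suite and the acceptance script run everything at reduced but
statistically adequate sizes, chosen as package defaults for desk-scale
validation: MCFS sweeps use 150–400 subsets × 2–3 splits with 5–20
permutations; rule ensembles use 10–20 under-sampling replicates;
cross-validation uses 4–5 folds. The null-model check uses a balanced
four-class table of 20 samples per class with permuted labels; its
expected accuracy is 25 %, with a small finite-sample depression
(≈ (n_c − 1)/(n − 1) ≈ 24 %) because a held-out sample's own label is
missing from its training fold.

# Known limitations

* **Single-age boundary recovery.** With every planted site sharing one
  transition age, a planted site's discretized state correlates with
  the labels of *every* age cut (the step partitions the cohort once;
  any threshold labelling overlaps it substantially). Per-cut
  significance therefore either saturates — all planted sites
  significant at every cut, leaving the SFA Jaccard matrix with no age
  structure beyond false-positive jitter — or, for weaker effects,
  forms a significance *zone* around the transition whose flanks sit
  symmetrically below and above it. In neither regime does k = 2
  complete-linkage clustering of SFA distances lock onto the transition
  age itself, and measured recovered boundaries scatter widely across
  seeds. Recovering age-group boundaries by SFA clustering requires
  sites with *different* transition ages, as real cohorts provide; the
  corresponding single-transition acceptance check documents this
  limitation and is expected to fail.
* **P-value resolution.** Pooled permutation p-values cannot fall below
  1/(1 + #null); small feature sets need proportionally more
  permutations.
* **Exhaustive reducts grow combinatorially** with attribute count and
  contradiction density; the per-object cap and the Johnson reducer are
  the escape hatches.
* **Step-shaped transitions only** in the generator; gradual drift is
  deliberately out of its vocabulary and is instead covered by the
  regression cross-check on real betas.

# Session info

```{r}
sessionInfo()
```
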