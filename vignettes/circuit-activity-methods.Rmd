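---
title: "Mechanistic circuit activity: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic circuit activity: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitact)
```

## The propagation model and its assumptions

A pathway is a signed directed graph; a circuit is the sub-graph of all
nodes with a directed path into one effector. The per-node signal is

$$S_n = v_n \cdot \Big(1 - \prod_{a \in A}(1 - s_a)\Big) \cdot
        \prod_{i \in I}(1 - s_i)$$

with $v_n \in [0,1]$ the node's normalized expression summary, $A$ the
incoming activation signals and $I$ the incoming inhibitions. The model
treats expression as a proxy for active-protein presence, signals as
probabilities of transmission (activations combine as "at least one
active", inhibitions as independent survival factors), and requires the
entire receptor-to-effector chain to be present for signal to arrive.
It is deliberately quasi-mechanistic: no kinetics, no time, no protein
state beyond abundance.

Three conventions close gaps the rule itself leaves open:

* **Receptors.** An empty activation product would make
  $1 - \prod_\emptyset = 0$ and silence every receptor, so nodes with
  no incoming activation edge take an activation term of 1 and emit
  their own $v_n$.
* **Cycles.** The rule is recursive and well defined on acyclic
  circuits, which one topological sweep solves exactly. Feedback loops
  are solved by Jacobi iteration from $S^0 = v$ with tolerance `tol`
  (default 1e-6) and cap `max_iter` (default 1000); iterates stay in
  $[0,1]$ because each update is a product of values in $[0,1]$. The
  contraction is not guaranteed in general, so non-convergence is
  flagged per circuit, never silent; in randomized trials with one
  feedback edge per circuit it converges in well over 99% of cases.
* **Multi-gene nodes.** The within-node summary is the mean of the
  member genes' scaled values (configurable to median or an upper
  percentile); the mean matches the "abundance proxy" reading and keeps
  the node value linear in its genes. Non-function nodes without genes
  (small molecules, unannotated complexes) relay with value 1 rather
  than breaking the chain.

Monotonicity caveats follow from the algebra and shape what the
property tests assert: raising a node helps the effector only if every
downstream route from it is pure activation, and raising an inhibitor
hurts the effector only if its sole influence is the direct inhibition —
double negation legitimately reverses signs. Mixed-sign duplicate edges
between one pair are legal and both terms apply.

## Circuit-length normalization

A chain of $L$ half-active nodes attenuates to $0.5^L$, so raw effector
signals are not comparable across circuits of different depth. The
default correction divides by $0.5^L$, with $L$ the number of nodes on
the longest activation-only path into the effector; an alternative
divides by the circuit's saturated reference signal (all $v = 1$,
inhibitor chains at 0, guarded against zero); `none` disables it. The
exact correction used by the original pathway software is not published
alongside the rule, so both options are exposed — and because any such
correction is a per-circuit positive constant, every downstream
statistic (moderated t, Cox z, ranks) is invariant to the choice, which
a numerical test confirms. The guarded reference mode exists because a
saturated reference is identically 1 on activation chains and can be
degenerate under inhibition.

## Preprocessing

TMM scaling factors follow the published defaults of the
trimmed-mean-of-M-values method: reference sample chosen by
upper-quartile ratio closest to the mean, two-sided trims of 30% on M
and 5% on A, inverse approximate-binomial-variance weights, zero counts
excluded pairwise, and factors rescaled to geometric mean 1. The test
suite pins this implementation against the reference implementation to
1e-10. Log-CPM uses a 0.5 pseudo-count against the factor-adjusted
library size, matching the standard voom transform of normalized log
counts; precision weights are *not* computed, because activity
estimation consumes values only and the differential stage below fits
unweighted least squares on activities, where count-derived weights are
undefined.

Rescaling to [0, 1] is per gene: clip above the per-gene 0.99 quantile
(a guard against single-sample outliers; configurable), then min–max.
Constant genes map to 0.5 — agnostic rather than absent. Pathway genes
missing from the matrix are imputed at the grand mean of all scaled
entries; "average expression of the dataset" is ambiguous between
grand mean, per-sample mean and a fixed 0.5, so the grand mean was
chosen and `impute_value` overrides it.

## Differential activity

Each feature is fitted by OLS on a cell-means condition design plus
batch indicators (tissue source site in the motivating study); the
contrast is case minus control, which with equal group sizes and no
batch is exactly the difference of group means. Residual variances are
shrunk toward a scaled inverse-chi-square prior whose hyperparameters
$(d_0, s_0^2)$ come from method-of-moments on $\log s^2$ (digamma /
trigamma matching, trigamma inverted by Newton). The closed-form fit
was preferred to a marginal-likelihood fit because at the feature
counts involved the difference is immaterial, and the implementation is
pinned by its limits — $d_0 = 0$ reproduces the classical t to 1e-10,
$d_0 = \infty$ pools completely — and by agreement with the reference
empirical-Bayes pipeline on random fixtures. Significance defaults to
FDR < 0.05; the cross-contrast summary keeps features significant with
the same direction in every contrast and averages their log2FC and FDR,
mirroring how multi-subtype studies report "consistently dysregulated"
circuits.

## Survival screening

Outcomes take the maximum of days-to-death and days-to-last-follow-up
with vital status as the event indicator; rows without a usable
positive time are dropped and counted. Each circuit gets a univariate
Cox fit with Efron tie handling (the common default of the survival
package; ties arise from day-rounded times). Hazard ratios are per
activity unit by default — on the narrow activity scale these can be
numerically extreme, which is why `standardize = TRUE` refits on
z-scores — and BH adjustment runs across all screened circuits.
Constant-activity circuits are kept with p = 1 rather than dropped so
the BH denominator is reproducible across datasets. The
proportional-hazards diagnostic is the scaled-Schoenfeld score test
against KM-transformed time. Kaplan–Meier groups use the stated
operational rule — z-scores cut at ±0.5 — which under normality admits
about 31% per tail (not the 25% a percentile reading would suggest);
the z-rule is implemented because it is the operational definition.
Note that within-sample z-scores satisfy $\sum z_i^2 = n - 1$, so "all
samples excluded" cannot actually occur.

## TF target enrichment

Genes are ranked by moderated t (ties broken by gene id), assigned
evenly spaced ranks $r \in [0,1]$, and each regulon is tested by
logistic regression of membership on $r$; the slope is the log-odds
ratio. Rank of t was chosen over the raw statistic for robustness to
heavy tails, and over log2FC because the t incorporates precision; a
`rank_by` flag exposes the alternatives. Fixing $r$ to [0, 1] makes
LORs comparable across gene universes. Wald p-values are used (the
likelihood-ratio alternative differs negligibly at these sizes) and the
IRLS fit is tightened to epsilon 1e-12 so it matches a from-scratch
Newton oracle to 1e-8. Complete separation is reported with a capped
|LOR| and flag. Regulons keep grades A–C (two-source support) and need
at least 5 in-universe targets — the source database's confidence
convention and a minimal-information floor the source text does not
specify.

## Hallmark profiles

Effector genes carry text-mining association scores to the ten
hallmarks; scores ≥ 0.15 are kept (inclusive, reading "cutoff of 0.15
to select" literally; the value corresponds to the upper 5% of scores
in the source annotation). A multi-gene effector node passes if any
member gene passes. Counts are per circuit and per hallmark, so a
multi-hallmark effector contributes several counts; circuits with no
retained annotation are tallied "unannotated". Both counts and
fractions are emitted because radar-style summaries are drawn either
way.

## The synthetic test-bed

The generator defines the fixed conditions every recovery test runs
under: 12 random connected pathway DAGs of 5–9 nodes (about 30
circuits), a feedback edge with probability 0.1, inhibitory edges at
0.15, 1–3 genes per node plus 1000 background genes; 30 case and 30
control samples; log-normal gene means (log-mean log 150, sd 1),
negative-binomial dispersion 0.1, library sizes uniform in 2–6 × 10^5;
three gene-disjoint activation-only circuits planted at log2 effect 1.5
(alternating direction — activation-only so the planted direction
propagates to activity, gene-disjoint so plants never overwrite each
other); a two-site batch effect of sd 0.1 on the log scale assigned
round-robin within condition, hence orthogonal to it unless `confound`
deliberately aliases them; survival times exponential with baseline
hazard 1/1000 per day and log-hazard 1 per standardized activity unit
of the first planted circuit, censored by an independent uniform whose
bound is calibrated to a 30% censored fraction; twenty 20-target
regulons of which one draws targets with weight $e^{16 r}$ over the
midrank-tied true-effect ranking (midranks keep the mass of unaffected
genes at one middling weight, so a strong tilt concentrates on the
genuinely shifted genes), null regulons uniform, grades A–C.

Sample sizes, the planted effect, and the survival coefficient follow
the recovery designs stated for the pipeline's checks (30 vs 30 for
differential recovery at log2FC 1.5; n = 300 and β = 1 for Cox
recovery); sizes with no stated value (pathway count, gene means,
dispersion, library sizes, batch sd, baseline hazard) were chosen once
as typical of bulk RNA-seq cohort data at desk scale. All randomness
derives from one integer seed, with arguments forced before seeding so
nested calls cannot interleave RNG streams; bundles are byte-identical
across runs.

What the generator does *not* emulate — and what passing tests
therefore do not show about real data: realistic pathway topologies
(KEGG graphs are deeper, wider, and full of shared receptor trees),
gene–gene correlation beyond circuit membership, count properties of
real cohorts (GC/length effects, sample quality, outlier libraries),
informative censoring, clinical covariates, or regulons with shared
targets between TFs. Recovery results certify the statistical machinery
at the stated designs, not discovery performance on tumor cohorts.

## Numerical choices and degenerate inputs

Convergence: `tol` 1e-6 with cap 1000 (flagged on cap); logistic IRLS
epsilon 1e-12; trigamma inversion by Newton to 1e-10. Ties: gene-id
tie-breaks in rankings; Efron for event ties. Degenerates: constant
genes rescale to 0.5; constant circuits enter the Cox table with p = 1;
regulons covering the whole universe or intersecting fewer than
`min_targets` genes return NA with a reason; zero-effector graphs warn
and yield empty catalogs; self-loops are rejected (the rule is
ill-defined for them) unless explicitly dropped; an all-zero sample or
a batch aliased with condition is an error naming the offender.

## Problem sizes used by the checks

The automated checks run at the stated designs — 500 random circuits
for the solver oracle, 1000 randomized bound/monotonicity trials, 200
replicates of 2000 null features for t calibration, 100 replicates of
the 20/500-circuit recovery design, 200 Cox replicates at n = 300 plus
100 diagnostic replicates at n = 500, 10,000 samples for the z-rule
tail fraction, and the full default bundle end to end — totalling under
a minute of compute, so the whole suite is practical to run on every
change.

## Known limitations

The activity scale is relative per gene (min–max within cohort), so
activities are not comparable across cohorts without joint
normalization. The propagation rule ignores stoichiometry, dosage and
post-translational state. Cyclic convergence is empirical, not proven.
The survival screen is univariate by design and does not adjust for
clinical covariates. The hallmark profile inherits whatever biases the
upstream text-mining scores carry.
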