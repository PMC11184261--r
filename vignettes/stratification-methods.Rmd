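---
title: "Methods: whole-blood stratification and in-silico druggability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-blood stratification and in-silico druggability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephrostrat)
```

This vignette documents the models, the tunable parameters, the synthetic
study generator, and the numerical and design choices behind the package.
It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The analysis problem

Active lupus nephritis (LN) patients are clinically heterogeneous. The
package stratifies them from whole-blood RNA-seq by (i) measuring how far
each patient's coexpression-module activity deviates from a large
healthy-control (HC) reference, (ii) clustering patients on those deviation
scores, and (iii) simulating the inhibition of candidate drug targets on
signaling graphs to ask which subgroup is expected to benefit. Every stage
is exposed as a function; `run_pipeline()` wires them together.

## Differential expression

Per gene, an ordinary least-squares fit of log2-CPM on group plus age, sex,
sequencing batch and RNA integrity number. Residual variances are moderated
by empirical Bayes: a scaled F distribution is fitted to the $s^2_g$ by
method of moments on $\log s^2_g$ (prior df $d_0$ from a trigamma inverse,
prior variance $s_0^2$), and posterior variances
$\tilde s^2_g = (d_0 s_0^2 + d s^2_g)/(d_0 + d)$ yield moderated t
statistics on $d + d_0$ df. When the observed log-variances show no excess
dispersion beyond $\chi^2$ sampling noise, $d_0 = \infty$ and all variances
shrink to the pooled mean. Voom-style precision weights are deliberately not
estimated: the downstream logic consumes DEG *sets*, which are insensitive
to that refinement at these sample sizes, and the unweighted moderated model
keeps the implementation fully self-contained (it is cross-checked against
an independent implementation in the test suite). Covariates that are
constant within the modeled samples (e.g. sex after same-sex matching of an
all-female case group) are dropped with a message rather than producing a
singular design.

The fold-change gate is strict (`|log2FC| > 0.58`, i.e. fold change below
0.66 or above 1.5), applied on top of BH FDR < 0.05.

## Control matching

Deterministic greedy nearest-age matching within sex at a 1:5 ratio, cases
in input order, ties by pool order, without replacement. Determinism was
preferred over global optimality so that runs are exactly reproducible; at
the default pool size (497 HC for 41 cases) the two strategies select nearly
identical control sets.

## Coexpression modules

Parameters (`network_params()`):

* `beta = 6` — soft-threshold power, the conventional choice for
  unsigned/signed-hybrid networks; `pick_soft_threshold()` implements the
  scale-free criterion (smallest power with fit $R^2 \ge 0.8$ and negative
  slope) for users who prefer a data-driven power.
* `network_type = "signed_hybrid"` — adjacency $a_{ij} = \max(r_{ij},0)^\beta$.
  The signed-hybrid form matters here: in a compositional assay (CPM), an
  up-shifted module depresses every other gene's relative abundance, so an
  unsigned network recruits anti-correlated bystanders into modules.
* `cut_height = 0.90` — static cut on the average-linkage tree of
  $1 - \mathrm{TOM}$. On this scale, blocks of genes with pairwise
  correlation around 0.7 sit at heights roughly 0.8–0.9 while unrelated
  genes merge near 1.0; 0.90 separates module cores across both cohort
  sizes used (26 and 15 patients). A dynamic tree cut is intentionally not
  reimplemented.
* `kme_min = 0.65` — eigengene-membership refinement. Static-cut clusters
  in small cohorts both lose weak true members and absorb chance
  correlates, so after cutting, core members with kME below the gate return
  to the unassigned pool and every unassigned gene is recruited by the
  module for which its kME is maximal (if it reaches the gate). With
  within-module correlations near 0.7, true members have kME ≈ 0.85, well
  above the gate; at 26 samples a chance kME above 0.65 has probability
  around $2\times10^{-4}$ per gene.
* `min_module_size = 30`.

Before network construction the pipeline residualizes log-CPM on age, sex,
batch and RIN, with coefficients estimated on *all* samples (so the small
patient cohorts lose no degrees of freedom). Without this, covariate-driven
gene blocks can align with a module eigengene by cohort-level chance and
contaminate modules. Dysregulation scores and pathway values use the
unadjusted log-CPM.

Replication follows the discovery/replication design: a discovery module is
replicated iff its best Jaccard match among replication modules reaches
0.25 *and* the overlap's hypergeometric FDR (BH across discovery modules)
is below 0.05. The dual gate controls both effect size and significance.
Replicated modules carry their discovery gene sets forward. Annotation
against reference module collections likewise uses a dual gate: Pearson
$|r| \ge 0.5$ between the module eigengene and the reference set's mean
standardized expression, plus overlap FDR < 0.05.

## Dysregulation scores and patient subgroups

For gene $g$ and patient $p$,
$z_{gp} = (x_{gp} - \bar x^{HC}_g)/s^{HC}_g$ with the HC sample standard
deviation (ddof = 1; zero-variance genes are dropped with a warning), and a
module's score is the mean over its genes. Patients are clustered on the
module × patient score matrix with Ward.D2 on Euclidean distances and cut
at $k = 3$; the three-subgroup structure is taken as given, and
$k$ is exposed for sensitivity analyses. Clusters are labeled lo/im/hi by
ascending mean IFN-module score, ties broken by cluster index with a
warning. Patient clustering uses all replicated modules; the
$|\bar z| > 1$ prominence gate (strict) is applied afterwards for
reporting, which resolves the ambiguity of whether the gate precedes or
follows clustering in favor of the more conservative reading.

## Serology association

Spearman correlation for continuous analytes and Mann–Whitney U for binary
serology (negative serology is the reference group). Both implement exact
small-sample p-values by full enumeration — valid under ties, which is why
they are implemented here rather than delegated — and tie-corrected
asymptotics otherwise (t approximation for Spearman beyond n = 8; normal
approximation without continuity correction for U beyond 8 per group).
Below-detection values should be encoded as ties at the floor; rank methods
then handle them naturally. Significance is flagged at p < 0.05 with **no**
multiplicity adjustment — a deliberate choice for a hypothesis-generating
screen; the output column is
named `significant_unadjusted` so the choice cannot be overlooked.

## Regulators and druggability

Chief-regulator ranking is hypergeometric enrichment of regulator target
sets in a module (identical mathematics to the ORA module; the tests assert
the equivalence). Motif-based regulon discovery is out of scope: regulons
arrive as a user-supplied GMT. Drug annotation joins module genes against a
local drug–gene interaction snapshot; genes need subgroup-mean $|z| \ge
0.5$ to be called directed, and counteracting candidates are exactly
(upregulated ∧ inhibitor) ∪ (downregulated ∧ stimulator).

## Pathway perturbation

Expression is min-max scaled per gene to the HC 1st–99th percentile range
and clamped to $[0,1]$ (genes with zero HC range map to 0.5 with a
warning); node values are means over node genes. Signals propagate as

$$S_n = v_n \left(1 - \prod_{a \in act(n)} (1 - S_a)\right)
\prod_{i \in inh(n)} (1 - S_i), \qquad S_{receptor} = v.$$

DAGs are evaluated in topological order; cyclic graphs by damped fixed
point (damping 0.5, tolerance $10^{-9}$, at most 1000 iterations, error on
non-convergence). Inhibition multiplies the target node value by 0.1, and
the response score is the summed absolute change of effector signals. The
"absolute change of gene expression" could also be read as aggregating
subpathway activities or raw post-propagation gene values; effector-signal
deltas were chosen as the closest graph-level reading and the alternative
aggregations can be built from the returned per-node signals. A patient is
an anticipated responder when the score is at or above the cohort mean for
that target (so at least one responder always exists), and subgroup
proportions are compared with Fisher's exact test when any expected cell
count is below 5, else Pearson's chi-square with Yates continuity
correction — the classical rule, which also uniquely reproduces the four
reference p-values (0.004, 0.104, 0.017, ≤0.001) from the reconstructed
response tables.

## The synthetic study generator

`generate_cohort()` emulates the study conditions: 497 HC; 41 active-LN
patients split 26/15 into discovery and replication; 62 active nonrenal
SLE; planted subgroups lo/im/hi of sizes 13/9/19, the unique integers
consistent with the reference subgroup response percentages at n = 41. Counts are negative binomial with
log-normal library sizes (median 8M) and gene-wise dispersions log-normal
around 0.1; age, sex, batch and RIN each perturb a random 10% of genes so
the adjustment machinery is genuinely exercised.

Three 60-gene modules are planted with subgroup mean shifts, in HC-sd
units: IFN (0.5, 2, 4), B cell (−2, +2, −2), plasma cell (−2, +2, +1) for
(lo, im, hi). The signs follow the reported subgroup biology; the
magnitudes are fixed design choices with two constraints: shifts large
enough to be unambiguous against per-gene noise, and subgroup *patterns*
distinct enough that between-module pattern correlation (≤ 0.5 at these
values) stays below within-module correlation (≈ 0.7) — if two planted
modules shared nearly collinear patterns, separating them by coexpression
would be ill-posed for any method. A small residual within-module factor
(correlation 0.05) models co-regulation beyond the subgroup structure;
most of the realized co-expression among patients comes from the subgroup
shifts themselves, which is also what makes the z-noise of a 60-gene
module score small enough (sd ≈ 0.26 per patient) for subgroup means to be
recoverable. Planted baselines are drawn at moderate expression
(log2 CPM ≈ 3.5 ± 1) so the 180 planted genes do not dominate the
2000-gene library, and a per-sample compositional calibration scales the
planted genes so their realized CPM matches the target exactly, with the
(small, realistic) compositional displacement absorbed by the background.

What the generator does *not* emulate: immune-cell composition and
deconvolution structure, batch effects beyond additive shifts, count-level
technical artifacts (GC, length), or the full 20-module architecture of
real blood. Passing recovery tests therefore demonstrates the pipeline's
correctness on data satisfying its assumptions, not performance on real
cohorts.

Pathways are deterministic receptor → intermediates → effectors DAGs (7
nodes by default) whose receptor carries the drug-target gene and whose
downstream nodes carry module genes; serology analytes are linear in module
scores with Gaussian noise, binary analytes thresholded at a target
positivity rate.

## Problem sizes and determinism

The default cohort is 600 samples × 2000 genes; a full pipeline run takes a
few seconds on one core, and the complete test suite (including five
end-to-end recovery runs and the brute-force enumeration oracles for
Fisher/chi-square, Spearman, Mann–Whitney and the hypergeometric test) runs
in under a minute. All randomness flows from a single seed;
per-stage child seeds are derived arithmetically so that stages can be
reproduced in isolation. Re-running the pipeline with the same
configuration writes byte-identical outputs, recorded with MD5 checksums in
the run manifest.

## Known limitations

* The static cut plus kME refinement approximates, but is not, WGCNA's
  dynamic tree cut; very unequal module sizes or nested module structure
  may be split or merged differently.
* The DE stage's moderated t on log-CPM ignores the mean–variance trend
  that voom weights model; at 41 + 205 samples the DEG sets are robust to
  this, but single-digit case counts would not be.
* Response scores compare a patient to the cohort mean, so "responder" is a
  relative, within-cohort label; absolute effect sizes are not modeled, and
  neither are pharmacokinetics or tissue-level effects.
* Serology associations are intentionally unadjusted for multiplicity and
  should be treated as hypothesis-generating.
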