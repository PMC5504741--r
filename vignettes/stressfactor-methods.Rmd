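---
title: "stressfactor: methods and design rationale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stressfactor: methods and design rationale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
# code chunks are illustrative; the vignette is distributed as source only
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`stressfactor` analyses paired transcriptome–metabolome experiments with a
2×2 drought-by-heat factorial design, augmented by an air-humidity arm that
separates the "dry air" from the "temperature" component of heat stress.
This vignette documents the statistical methods, the numerical choices, and
the reasoning behind the less obvious design decisions. Every method below
is exercised by the test suite against an independent oracle (closed-form
algebra, brute-force enumeration, an established reference implementation,
or a planted-truth simulation).

# Experimental structure

Six conditions — `control`, `D` (drought), `H_LrH` / `H_HrH` (heat at low /
high relative air humidity), `DH_LrH` / `DH_HrH` — crossed with genotypes
and replicates. Heat at *low* relative humidity raises the vapor pressure
deficit (the usual chamber situation: hot air is also dry air); heat at
*high* relative humidity holds the vapor pressure deficit near control
levels, isolating the temperature effect. Genotypes are carried through the
design but pooled in all models; the generator plants no genotype effect,
and a test verifies that genotype F-statistics follow their null
distribution.

# Factorial decomposition

## The interaction model

For each variable, on the low-humidity factorial cells
(`control`, `D`, `H_LrH`, `DH_LrH`):

$$y = \beta_0 + \beta_D D + \beta_H H + \beta_{DH} D H + \varepsilon$$

On a balanced design the coefficients are cell-mean contrasts
($\beta_D = \bar y_D - \bar y_{control}$, and $\beta_{DH}$ is the
interaction difference-of-differences), which is how the tests verify the
fit against hand-computed means, besides a brute-force normal-equations
oracle.

## Variance moderation

Per-variable residual variances $s^2$ with $d$ degrees of freedom are
shrunk toward a common prior by an empirical-Bayes scheme: assuming
$s^2 \mid \sigma^2 \sim \sigma^2 \chi^2_d / d$ and a scaled
inverse-chi-square prior with parameters $(d_0, s_0^2)$, the marginal
distribution of $\log s^2$ has known mean and variance in terms of digamma
and trigamma functions. Method-of-moments on $\log s^2$ with a Newton
inversion of the trigamma function yields $(d_0, s_0^2)$, and the posterior
variance $\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ replaces $s^2$ in the
t-statistics, with $d + d_0$ degrees of freedom. The implementation is
independent but is verified to agree with `limma::eBayes` to machine
precision ($d_0$, $s_0^2$, posterior variances, |t|, and p-values); the
infinite-$d_0$ degenerate case is handled explicitly.

## Calls and response groups

A coefficient is called `up`/`down` when both $|\hat\beta| >$ `lfc` (default
1, log2 scale) and the Benjamini–Hochberg adjusted p (computed per
coefficient family) is below `alpha` (default 0.05). The BH step-up
adjustment is implemented in the package and tested against
`stats::p.adjust` and the literal step-up definition.

The call triple maps to a response group by two orthogonal rules:

- **column** (stress specificity): drought-only (`x.1`), shared same-sign
  (`x.2`), heat-only (`x.3`);
- **row** (interaction behavior): no interaction call → additive (`2.x`);
  interaction in the same direction as the single-stress call → enhanced
  (`3.x`); opposite → reduced (`1.x`).

Variables with an interaction call but no single-stress call are
combined-stress specific (group `4`); opposite-sign single-stress calls form
the rare `opp_additive` / `opp_interaction` classes; everything else is
`null`. The classification is exhaustively tested over all 27 call
combinations against a flat lookup oracle.

# Humidity contrasts

`fitConditionContrasts()` fits the one-way six-level condition model with a
pooled residual variance (optionally moderated) and reports every
condition-vs-control contrast. `vennDecompose()` partitions two conditions'
regulated sets direction-wise into `A_only` / `overlap` / `B_only` — the
standard question being how much of the `H_LrH` response survives at
`H_HrH` (vapor pressure deficit held constant), i.e. how much of "heat" is
really "dry air". A consistency test verifies that on the factorial cells
the condition contrasts reproduce the factorial coefficients
(`DH_LrH` contrast $= \beta_D + \beta_H + \beta_{DH}$).

# Regularized canonical correlation analysis

With $p, q \gg n$, classical CCA is degenerate, so the correlation matrices
are ridged: $C_{xx} + \lambda_x I$, $C_{yy} + \lambda_y I$. Canonical
weights are computed from the symmetric eigenproblem of
$M = R_{xx}^{-1/2} C_{xy} R_{yy}^{-1} C_{yx} R_{xx}^{-1/2}$ (with
$R_{xx} = C_{xx} + \lambda_x I$), canonical correlations are the square
roots of its eigenvalues. At $\lambda = 0$ this equals classical CCA and is
tested against `stats::cancor` and a dense generalized-eigenvalue solve to
1e-8.

The shrinkage intensities are estimated analytically
(Schäfer–Strimmer): $\lambda^* = \sum_{i \ne j}
\widehat{\mathrm{Var}}(r_{ij}) / \sum_{i \ne j} r_{ij}^2$, clipped to
$[0,1]$ — the ratio of estimation noise to signal in the off-diagonal
correlations. Tests confirm $\lambda^*$ is large for pure noise with
$p \gg n$ and near zero for strongly correlated low-dimensional data.

Sign indeterminacy is resolved deterministically: within each component the
x-weight vector is flipped so its largest-magnitude entry is positive, and
the y-side is aligned to correlate positively with the x-scores.
`variateVariableCorrelations()` correlates each variable with each canonical
variate (with BH-adjusted p-values per component and layer) to interpret the
components.

In demonstrations and structure-recovery tests the generator plants a
drought-driven and a heat-driven cross-omics factor with the *drought*
loading slightly stronger (1.3 vs 1.0). With exactly symmetric factors the
two leading canonical components span the same plane but may mix the
drivers (any rotation is equally optimal); the asymmetry reflects the usual
dominance of the drought signal in combined-stress data and pins component
1 to drought, making AUC-based recovery assertions well-posed.

# Correlation networks

Node admission follows the gene–mass relation: all genes and masses joined
by a gene–mass correlation with $r >$ `edge_r` (default 0.85; by default the
adjusted-p rule `p.adj <` `edge_alpha` $= 10^{-5}$ applies too) enter the
graph; gene–gene and mass–mass edges are then added among admitted nodes
under the same thresholds. FDR families are per edge class. A gene–gene pair
with high correlation but no qualifying mass edge stays out — the network is
anchored on cross-omics relations.

**Communities** are found by asynchronous label propagation on the
positive-edge subgraph: each node starts with its own label and, in
seeded-random order, adopts the majority label of its neighbors (ties
broken seeded-uniformly) until every node's label is a weak neighborhood
majority. The returned partition always satisfies that fixed-point property
(asserted by `isLabelFixedPoint()` in tests), and the mandatory seed makes
runs reproducible. The implementation is cross-checked against
`igraph::cluster_label_prop` on clear-cut instances and against planted
two-block graphs (ARI ≥ 0.9 in ≥ 90% of seeds).

**Maximal cliques** are enumerated with Bron–Kerbosch with pivoting, on
positive edges, in canonical order (size-descending, then lexicographic),
and verified against brute-force subset enumeration and
`igraph::max_cliques` on random graphs. Enumeration is exponential on
quasi-complete graphs, and the synthetic generator produces exactly those:
same-group variables share their condition-mean pattern, so with noise 0.3
against effects of 2.5 their pairwise correlations cluster near 1 and the
network contains near-complete blocks whose maximal cliques number in the
hundreds of thousands. The pipeline therefore (a) enumerates cliques on the
induced subgraph of masses plus the top-`k` correlated genes per mass
(`top_genes_per_mass`, default 3) — the same reduction used for network
displays — and (b) caps the enumeration (default 20000, configurable;
truncation is flagged in the result attribute and the stage log).
`maximalCliques()` itself remains exhaustive by default.

`crossTargetedEdges()` attaches a targeted metabolomics layer by
correlating given genes against each targeted metabolite over shared
samples, with an optional minimum-connections filter.

# Enrichment

`fisherEnrichment()` computes one-sided hypergeometric over-representation
p-values ($P(X \ge a)$), conditional-MLE odds ratios (via
`stats::fisher.test`), and BH adjustment across terms. Tested against
explicit tail summation to 1e-12 and for null calibration. GMT reading and
writing is implemented directly (the format is three-plus tab-separated
fields per line; duplicate terms and short lines are errors).

# The synthetic generator

`generatePairedDataset()` simulates log2 intensities as

```
baseline + betaD·D + betaH·H + betaDH·D·H + humidity·hiHum
         + batch offset + loading·factor score + N(0, noise_sd)
```

- **Response groups** are planted by assigning each group's sign pattern
  (e.g. `2.1` = $(\pm1, 0, 0)$, `1.2` = $(\pm1, \pm1, \mp1)$) scaled by
  `effect_size` (default 2.5), with a random shared direction per variable.
- **The metabolome** is exponentiated to a raw scale and censored below the
  detection floor (default 5e5): censored cells are missing, and after the
  detection filter the floor value is imputed at log2(floor) with the
  missingness mask retained.
- **Batch offsets** (default 0.6, −0.6, 0; cyclic over replicates) are a
  balanced nuisance removed by `correctBatch()`
  (`limma::removeBatchEffect` with the condition design protected).
- **Latent cross-omics factors** and **humidity responders** are drawn from
  the *null* variables, so the planted factorial groups stay correctly
  specified. Latent factor scores follow their driver (+1 drought / −1
  otherwise, plus noise), inducing the cross-layer correlation that rCCA
  and the network modules are meant to recover. Because latent members
  carry genuine stress-driven signal, `evaluateRecovery()` does not count
  regulated calls on them as false discoveries.

# TIC normalization and composition bias

Total-ion-current normalization divides each sample by its summed observed
intensity. It removes sample-level loading variation but is
*composition-sensitive*: on the raw scale, a planted combined-stress effect
of +7.5 log2 turns a mid-intensity mass into a dominant share of the total,
so in the combined-stress samples the TIC rises by >1 log2 and *every* null
mass is scaled down by that amount. The factorial model then sees
$\beta_{DH} \approx -1$ for null masses — a spurious interaction — and the
pipeline's recovery FDP on the metabolome layer rises accordingly (observed
≈ 0.15–0.27 across seeds at default settings, entirely from null masses
called group 4; without TIC the FDP is ≈ 0 and coefficients are unbiased).
The pipeline keeps TIC because it is part of the standard protocol and
reports its recovery metrics honestly; recovery-oriented analyses (and the
corresponding tests) preprocess with detection filter + floor imputation +
batch correction only, since the generator plants no loading variation for
TIC to remove. This is a known limitation of total-signal scaling whenever
a few features carry very large fold changes.

# Pipeline reproducibility

`runPipeline()` derives per-stage seeds from the single configured seed via
fixed offsets (all below 2^31), writes every stage output as text (TSV /
JSON / GraphML) with 15 significant digits, and records an md5 digest of
every file in `manifest.json` together with the configuration hash and
thresholds. Downstream stages always consume the *serialized* files, so a
rerun from unchanged inputs reproduces every digest exactly; stages whose
recorded outputs are digest-unchanged under an identical configuration are
skipped. Determinism across runs and directories is covered by tests.

# Default thresholds

| name | default | role |
|---|---|---|
| `lfc` | 1 | log2 fold-change call threshold |
| `alpha` | 0.05 | FDR threshold for coefficient calls |
| `edge_r` | 0.85 | network edge correlation threshold |
| `sub_r` | 0.75 | submodule-view correlation threshold |
| `edge_alpha` | 1e-5 | network edge adjusted-p threshold |
| `detect_fraction` | 2/3 | per-condition detection rule |
| `detection_floor` | 5e5 | raw-intensity detection limit |
| `top_variance_k` | 100 | variables per layer entering rCCA |
| `top_genes_per_mass` | 3 | network reduction for display/cliques |

# Limitations

- Identical within-group effect sizes make same-group variables nearly
  collinear; real data show effect-size scatter and sparser networks.
- The detection-floor imputation attenuates strong *down* effects on
  low-baseline masses (the floored value bounds the observable fold
  change), which costs some sensitivity for down-regulated metabolite
  groups.
- Label propagation on near-complete graphs can collapse adjacent blocks
  for unlucky seeds; the seeded interface makes this reproducible and
  consensus over seeds is possible by rerunning.
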