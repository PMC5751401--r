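---
title: "Methods: a random-forest panel for ligand-based target fishing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a random-forest panel for ligand-based target fishing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`targetfisher` treats target identification as a battery of independent
binary classification problems, one per protein target. For target $j$
with active ligand set $A_j$, a random forest $F_j$ of $T$ trees is
trained to separate the fingerprints of $A_j$ from those of *putative
inactives* — ligands in the dataset with no recorded qualifying activity
against $j$. The screening score of ligand $x$ is the vote fraction

$$ s_j(x) = \frac{1}{T}\,\#\{t : \text{tree}_t \text{ votes active}\}, $$

an exact multiple of $1/T$ in $[0,1]$. Because every model emits the same
statistic, the vector $(s_1(x),\dots,s_m(x))$ can be sorted directly to
rank candidate targets, and one global calibration curve can map any
score to an interaction probability.

The central modelling assumptions are:

1. **Similar ligands bind similar targets** (the SAR premise): a target's
   actives occupy one or a few dense regions of fingerprint space that a
   tree ensemble can carve out.
2. **Missing activity ≈ inactivity.** Untested ligand–target pairs are
   treated as negatives. This is wrong for an unknown subset of pairs;
   the Tanimoto exclusion filter (below) removes the most suspicious
   ones, and the vote score degrades gracefully when a few mislabelled
   negatives remain in a 100-tree ensemble.
3. **Scores are comparable across targets.** Vote fractions share a scale
   by construction; a common inactive/active ratio across targets (rather
   than a per-target one) avoids biasing the panel toward data-rich
   targets.

# Data definitions

An **active pair** is a ligand–target pair with at least one IC50, EC50,
Ki or Kd measurement *strictly below* 10 µM (10⁴ nM) after unit
conversion; a measurement at exactly 10 µM does not qualify. When a pair
has conflicting measurements, one qualifying value suffices (the ANY
rule) — activity is defined by the existence of a qualifying assay, which
is also how public bioactivity extracts are usually reduced. Units nM,
µM, mM and M are converted to nM; anything else is rejected loudly rather
than guessed.

A target is **modelled** only if it has at least `min_actives = 10`
distinct active ligands; below that, a 100-tree forest mostly memorises
noise. Targets are decided eligible on the full table, and each
cross-validation fold then rebuilds the datasets from its training
ligands only.

For each modelled target the ligand universe is partitioned into
*positives* (its actives), *excluded* (putative inactives whose nearest
active exceeds the Tanimoto cutoff), and *negatives* (the rest). The
exclusion boundary is strict (`Tc > cutoff` excludes), and lowering the
cutoff can only grow the excluded set.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `activity_threshold_nM` | 10⁴ nM (10 µM) | strict potency cutoff defining an active pair |
| `min_actives` | 10 | minimum distinct actives for a target model |
| `tc_cutoff` | 0.5 | nearest-active Tanimoto above which a putative inactive is excluded; `NA` disables |
| `method` | positive_oversampling | imbalance scheme (`negative_undersampling` is the alternative) |
| `ratio` | 1 | sampled inactive/active count ratio |
| `n_trees` | 100 | trees per forest; score resolution is 1/`n_trees` |
| `radius`, `n_bits` | 2, 2048 | circular fingerprint diameter 4, folded width |
| `k_list` | 1, 4, 8, 11, 33, 66, 88, 110 | rank thresholds for recall@k |
| `cutoffs` | 0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.3, 0.5, 0.7, 0.9 | score cutoffs for calibration points |

The defaults are the benchmark configuration of the method: balanced
ratio, Tc cutoff 0.5, weight-based oversampling, 100 trees. Forest
hyperparameters beyond `n_trees` are the standard classification
defaults — $\sqrt{p}$ candidate features per split, unlimited depth,
bootstrap sampling — and are recorded in each model object and panel
manifest rather than silently assumed.

Both imbalance schemes first draw negatives uniformly without replacement
to `min(pool, ratio × n_positives)`. Undersampling stops there with unit
weights. Positive oversampling additionally gives every active the weight
`n_negatives / n_positives`, so total class weights balance exactly;
weighting replaces literal replication and feeds the forest's weighted
bootstrap. The negative pool is ratio-limited in both schemes, which
keeps `ratio` meaningful as a negative-diversity knob when comparing the
two. Per-target sampling and training seeds are derived from the single
global seed and the target id, so adding or removing one target never
perturbs the others.

# Evaluation protocol

Cross-validation splits *ligands*, not pairs: every active ligand is
assigned to one of five folds (sizes differing by at most one), and all
of its activities move with it. Each fold's panel is rebuilt from scratch
from the training ligands — including re-running the Tc exclusion against
training actives only — so no information about held-out ligands reaches
training. Held-out ligands are screened against every model; a held-out
pair is labelled positive iff it is a known active pair, mirroring the
assumed-inactive convention used in training.

Reported statistics:

- **Per-target AUC**: trapezoidal area under the ROC curve, averaged as a
  scalar over the folds in which the target had held-out actives (scalar
  averaging, not vertical curve averaging — the scalar is what the
  per-target distribution summarises).
- **Overall AUC**: one ROC over all pooled (ligand, target, fold)
  score/label pairs. The trapezoidal implementation groups tied scores,
  making it exactly the rank-sum concordance statistic with ties counted
  half; the test suite checks this equivalence to 1e-9 against a
  brute-force oracle.
- **Mean-score ratio**: mean active score / mean inactive score per
  target. A zero inactive mean with a positive active mean reports `Inf`
  (the separation is perfect at the vote resolution); two zero means
  report `NaN`.
- **Recall@k**: fraction of true pairs whose target ranks in the ligand's
  top $k$, fold-averaged. Ranking ties are broken by ascending target id
  for determinism. The default `k_list` follows the rank grid used for
  panel-scale evaluation; any grid can be configured.
- **Chi-squared comparison**: two pipeline variants are compared by the
  2×2 Pearson test (no continuity correction, 1 df) on their pooled
  TP/FN counts at a fixed rank threshold. If both variants recover every
  pair the statistic is undefined and reported as `NA` at the workflow
  level (the low-level function raises an error instead).

# Score calibration

High-scoring targets are not automatically probable interactions, so
scores are calibrated globally: for each cutoff $c$ in a grid, the
estimated probability is the active fraction among pairs scoring strictly
above $c$; the resulting points are fitted by weighted least squares to

$$ \hat p(c) = \frac{1}{1 + e^{-(\alpha \log_{10} c + \beta)}},
   \qquad \alpha \ge 0, $$

with weights `n_above` (binomial precision: points backed by few pairs
count less). `nlsLM` does the optimisation, started from a clamped
logit-linear regression; $\alpha \ge 0$ enforces a monotone mapping. Two
deliberate boundary rules: the zero cutoff (and zero scores generally)
cannot enter $\log_{10}$ and most inactive pairs score exactly 0, so
score 0 maps to probability 0, and cutoffs retaining no pairs are
dropped. Least squares on the estimated points (rather than a joint
likelihood) was chosen because the points, not the raw pairs, are the
published object of the procedure; the weighting recovers most of the
efficiency difference.

A subtlety in the synthetic calibration harness: the cutoff estimator is
*cumulative* — it averages over all pairs above a cutoff. If synthetic
labels were drawn pointwise with probability $\sigma(\log_{10} s)$, the
estimated curve would be biased upward relative to $\sigma$ and no fit
could recover the generators. `generate_score_labels()` therefore draws
labels with the conditional intensity

$$ \lambda(u) = \sigma(u)\,\bigl(1 + \alpha (u - u_{\max})
   (1 - \sigma(u))\bigr), \qquad u = \log_{10} s, $$

the closed-form solution (for log-uniform scores on
$[u_{\min}, u_{\max}]$) of the requirement
$\mathbb{E}[\lambda \mid u > c] = \sigma(c)$ for every cutoff in the
support. Parameter combinations pushing $\lambda$ outside $[0,1]$ are
rejected. With this construction the recovery experiment is a pure test
of the estimator and fit: at $10^5$ pairs the generating $(\alpha, \beta)
= (1, 2)$ come back within a few percent (recomputed, not quoted, by
`scripts/acceptance.R`).

# The synthetic data generator

`generate_chemogenomics()` emulates the *structure* that makes target
fishing work: each target owns a set of `scaffold_bits` fingerprint bits
(a chemical series in caricature); actives carry the scaffold minus
random losses (`mutation_rate`, default 0.05) plus sparse background bits
(`background_rate`, default 0.01, ≈ 20 of 2048 bits — about the on-bit
count of a drug-like ECFP); decoys carry background only. Assay rows for
actives draw log-uniform potencies in 1 nM – 9.9 µM across the four assay
types and mixed nM/µM units, so the activity definition reconstructs the
planted positives exactly. `cross_target_overlap` makes consecutive
target pairs share scaffold bits, degrading target resolution on demand.

What the generator does **not** emulate: real chemical similarity
geometry (correlated bits from shared substructures, fingerprint
collisions), heavy-tailed class sizes, inter-target activity correlations
(one ligand active on many targets), assay noise and unit errors, and
ChEMBL-scale dimensions (a thousand targets, hundreds of thousands of
ligands). Passing the recovery tests therefore shows the pipeline is
correctly wired and statistically sound on separable data — it does not
certify screening performance on real chemistry, which depends on
database coverage.

One consequence worth stating openly: on this clean fixture the panel is
essentially perfect (AUC and top-1 recall at or near 1.0 — the values are
recomputed by the acceptance script), so the overlap dial degrades
ranking only near complete scaffold sharing. At 0.8 overlap each target
still keeps 20% private scaffold bits, and a forest's own-model vote
margin over the partner model is large compared to vote noise, so top-1
recall barely moves from its ceiling; the degradation shows first in the
overall AUC's fourth decimal. A fixture with weaker scaffolds or added
label noise would show the monotone recall decline at lower overlap.

# Numerical and degenerate-case choices

- Tanimoto of two all-zero fingerprints is 0 (no evidence of similarity),
  avoiding 0/0.
- OpenBabel's hashed ECFP vectors (4096 bits) are folded to `n_bits` by
  index modulo; folding is the standard way to trade collision rate for
  width. Hash values differ from other cheminformatics toolkits, so
  fingerprints are comparable only within one toolchain.
- Standardization keeps the largest fragment by heavy-atom count (ties:
  first in canonical order), neutralizes ±1 charges, removes explicit
  hydrogens, and canonicalizes. OpenBabel has no canonical
  tautomer/mesomer chooser; aromatization during canonicalization unifies
  mesomeric aromatic forms, but genuinely tautomeric inputs can
  standardize to different strings — a known limitation of this
  toolchain. 2D-coordinate cleaning is a depiction concern and a no-op
  for fingerprints.
- Forest determinism: training and prediction run single-threaded with
  explicit seeds; a saved panel reloads to bit-identical score matrices.
- `rank_targets` logs (rather than errors) when `k` exceeds the available
  targets and returns them all.
- AUC with a single class, recall with no true pairs, sampling with an
  empty class, and sigmoid fits with under three distinct positive
  cutoffs all raise typed errors instead of returning silent defaults.

# Problem sizes

The bundled experiments are desk-scale by design: the benchmark fixture
is 20 targets × 30 actives + 2000 decoys (2600 ligands × 2048 bits), the
calibration harness uses 10⁵ pairs, and unit fixtures are smaller still.
These sizes exercise every code path of the pipeline — including
five-fold retraining of the whole panel — while a full run of the test
suite and acceptance script stays in the minutes range on a single CPU.
Scaling to a ChEMBL-sized panel is a matter of compute, not of different
code paths, but no claim at that scale is made here.

# Known limitations

- Assumed-inactive labelling bounds achievable calibration: some
  "negatives" are untested actives, so estimated interaction
  probabilities are conservative.
- One global calibration curve is fitted, not per-target curves; targets
  with unusual score distributions inherit the global mapping.
- The standardizer approximates, rather than reproduces, proprietary
  standardization stacks (see above on tautomers).
- Independence of the per-target models ignores correlations between
  related targets; a ligand of a promiscuous chemotype can rank many
  homologous targets highly.
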