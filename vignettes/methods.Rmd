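---
title: "Two-tier neural-network biomarker screening and interaction inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-tier neural-network biomarker screening and interaction inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anninet)
```

## The problem and the model

`anninet` implements a two-tier strategy for nominating disease biomarkers
from log2-scale expression matrices (genes or probe sets in rows, patient
samples in columns), motivated by the problem of separating sepsis from
non-infectious systemic inflammation (SIRS) in whole-blood transcriptomes.

**Tier 1 — exhaustive single-gene screening.** Every gene in turn is the
single input of a 1-2-1 multilayer perceptron (one input, two sigmoid
hidden nodes, one sigmoid output) trained by online backpropagation to
classify the two disease groups.  Samples are randomly partitioned
0.6:0.2:0.2 into training, test and validation sets; the test partition
drives early stopping, the validation partition measures classification
performance, and the whole split is reshuffled 50 times so that no single
partition biases the result.  Genes are ranked by their signed **standard
residual error (SRE)** — implemented as the across-genes z-score of the
between-class mean difference on the log2 scale — which behaves like a
symmetric, standardized fold change: positive values mean up-regulation in
the class coded 1 (the first-listed group of the comparison).

**Tier 2 — ANNI interaction inference.** On a reduced candidate panel,
each gene in turn is withheld and predicted from the remaining N − 1
genes by a small three-layer network regressing the withheld gene's
min-max-scaled expression.  The trained weights are condensed into a
per-source influence score (the linearized input-to-output weight path,
`sum_h w_in[s,h] * w_out[h]`, which preserves sign) and averaged over 50
random train/test reshuffles.  Positive averaged influence is read as a
stimulatory edge, negative as inhibitory.  Hub genes are those with the
largest total absolute influence, incoming plus outgoing; each hub can
then be "expanded" inside every disease group by exhaustive single-input
regression of the hub from every other gene on that group's platform,
keeping the ten best predictors.

## Parameters that matter

| parameter | default | units / range | rationale |
|---|---|---|---|
| hidden nodes | 2 | count | the fixed screening architecture (1-2-1); shared by ANNI |
| training epochs | 300 | epochs | epoch budget of the screening procedure |
| test window | 100 | epochs | early-stopping patience over test-set MSE |
| min MSE improvement | 0.01 | MSE units | smallest test-MSE gain counted as progress |
| learning rate | 0.1 | gradient step | classic online-backpropagation setting; config-exposed |
| momentum | 0.5 | fraction | same |
| weight init | ±0.5 | uniform half-width | small random symmetric start |
| split ratio | 0.6/0.2/0.2 | fractions | train / early-stop / validation |
| resamples | 50 | count | random reshuffles per gene (both tiers) |
| hubs (k) | 8 | count | hub list length; a parameter because no score threshold is defined |
| expansion top_n | 10 | count | genes kept per (hub, group) |
| similarity cutoff | 0.7 | Pearson r | inclusive, signed |
| BH-FDR cutoff | 0.05 | adjusted p | applied as ≤ |

The early-stopping rule is interpreted as a *sliding patience*: after each
epoch the test-set MSE is evaluated, and training halts once the best test
MSE has failed to improve by at least 0.01 over the last 100 epochs (or at
the 300-epoch budget).  The returned model is always the snapshot with the
lowest test MSE.  An alternative reading — a separate 100-epoch evaluation
phase after training — fits the same words; the patience reading was chosen
because it is the conventional use of a "testing window" with early
stopping, and because it makes the window length meaningful for budgets
shorter than the training budget.

Two further quantities are defined here because their operational
definition is otherwise open:

* **predictive p** of a gene is the two-sided Welch t-test p-value
  comparing the ANN's validation-partition outputs between the two
  classes, pooled across resamples.  High p ⇒ the single-gene model's
  outputs carry no class signal — which is exactly how the value is used
  when ranking housekeeping candidates (most invariant = largest
  `min(predictive p, t-test p)`).  Under label permutation this p is
  slightly conservative (the early-stopped null model collapses towards a
  constant output), which errs on the safe side for housekeeping
  selection.
* **SRE** is computed as `(d_g − mean(d)) / sd(d)` with `d_g` the
  between-class difference of mean log2 expression.  This reproduces
  every downstream use of the score (signed, symmetric about 0, unit
  spread, thresholded at ±1 and ±2, read as a fold-change-like quantity)
  and is exposed so an alternative regression-residual definition can be
  swapped in without touching the ranking code.

## Randomness and determinism

All stochastic operations derive their randomness from one master seed.
Each gene (and each resample within a gene) receives a child seed computed
from the master seed plus a stable hash of the gene identifier, so
per-gene results are independent of screening order — permuting the rows
of the input permutes the results identically.  Training noise (weight
initialization, per-epoch sample shuffles) runs on a self-contained
xorshift generator inside the compiled training loop, making a fixed
(input, config) pair bit-reproducible and leaving R's global RNG state
untouched.  ANNI additionally evaluates each leave-one-out model in a
canonical lexicographic gene order internally, so the influence matrix is
equivariant under row reordering.

Splits are stratified by class with largest-remainder apportionment of the
0.6/0.2/0.2 ratio inside each class, and at least one sample per class per
partition (hence at least three samples per class).  Stratification is
required at these sample sizes: without it, small classes can vanish from
the validation partition and the validation MSE becomes undefined.  Ties in
every ranking (|SRE|, hub score, expansion error, rank products) break
lexicographically on gene identifier, so all orderings are total and
reproducible.

## Numerical conventions and degenerate inputs

* Features and regression targets are min-max scaled to [0, 1] with
  parameters fitted on the training partition only; held-out values
  outside the training range are clipped.  A constant training feature
  maps to 0.5 everywhere.
* Percentiles (75th-percentile normalization) use linear interpolation
  between closest ranks; on log2 data the normalization subtracts, the
  log-scale analogue of per-array scaling.  Both normalizations are
  idempotent.
* Missing expression values are a hard error — no imputation rule is
  defined anywhere in the procedure.
* A two-sample t-test on two equal constant groups returns p = 1 (t = 0);
  one-way ANOVA on identical constant groups likewise.  SRE over genes
  whose class differences are all equal returns all zeros with a warning.
* A zero averaged influence yields no edge rather than an edge of
  undefined sign.
* Probes absent from the annotation are classed "unidentifiable" and
  dropped during collapsing, because sequence-based rescue of unlabelled
  probes is outside this package's scope; the drop report records every
  removal with its reason.

## The synthetic-data generator

`simulate_dataset()` produces the statistical structure the framework
assumes, with ground truth for recovery scoring: independent Gaussian
background genes on the log2 scale (per-gene baseline ~ N(8, 1), noise sd
1.0), differentially expressed genes shifted by 2 noise-sd in the affected
groups (alternating directions), housekeeping genes identically
distributed in all groups, and hub genes whose targets are signed linear
(optionally sigmoidal) functions of the hub plus N(0, 0.3) noise.  A probe
layer re-measures each gene with one or two probes (probe noise sd 0.05)
and injects multi-gene and unannotated probes; a platform-absence list
withholds chosen genes from chosen groups' matrices, emulating markers not
represented on a chip.  Default sizes — 200 genes, 60 samples per group,
2 hubs × 5 targets — keep a full two-tier run in the minutes range on one
CPU, and are the sizes the test suite and the acceptance script use (the
ANNI recovery protocol uses 30 samples per group for its 60-sample panels,
and hub expansion uses one 101-gene group).

What the generator does **not** emulate: array artefacts (spatial effects,
saturation, batch effects), heavy-tailed or correlated background noise,
and the mixed direct/indirect dependency structure of real regulatory
networks.  Passing recovery tests therefore demonstrate internal
correctness of the algorithms under their own idealized assumptions, not
performance on real microarray data.

## Known limitations

* **Hubs inside a tight co-expression block are near-exchangeable.**  A
  hub and its targets form an (up to sign) fully correlated clique when
  target noise is small relative to the hub's variance.  The degree-style
  hub score (total absolute influence) then distinguishes the block from
  the background sharply, but barely distinguishes the hub *within* its
  block: the trained networks spread weight across correlated inputs, and
  gradient descent closes the tiny MSE gap between the diffuse and the
  concentrated solution far too slowly for the configured epoch budgets.
  Even a fully converged linear regression read-out separates hub from
  targets only in most, not all, replicates at these sample sizes.  Hub
  identities returned on such data should be read as "block
  representatives".  The recovery suite reports the measured rates
  honestly rather than hiding this behaviour.
* The ANN influence score is a linearization; strongly non-monotone
  dependencies can cancel across hidden units.
* Screening p-values pool predictions across overlapping resamples; they
  are calibrated (slightly conservative) under the null but are not
  independent test statistics, and are therefore ranked, not interpreted
  as frequencies.
* The similarity screen uses signed Pearson correlation; anti-correlated
  partners are deliberately excluded under the default cutoff.

## A small worked run

```{r, eval = FALSE}
cfg <- pipeline_config(
  seed = 1,
  simulation = simulation_spec(n_per_group = c(sepsis = 15L, SIRS = 15L),
                               n_genes = 40L, n_de = 4L, n_housekeeping = 4L,
                               n_hubs = 2L, targets_per_hub = 2L, seed = 1),
  n_resamples = 5L, n_candidates = 6L, n_housekeeping = 2L, n_hubs = 2L,
  expansion_top_n = 4L, expansion_resamples = 2L, out_dir = "demo_out")
res <- run_pipeline(cfg)
res$hubs
res$accounting$total
```

Every stage writes its table under `out_dir` (screening report,
housekeeping ranking, panel, interaction matrix and edge list, hub table,
expansion accounting, overlap occurrences, SIF network) plus a structured
`pipeline.log`; two runs of the same config and seed produce byte-identical
files.
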