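---
title: "Methods: individualized prognostic signatures from relative expression orderings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individualized prognostic signatures from relative expression orderings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reosig)
```

## The problem

Prognostic transcriptomic models are usually scores: a weighted sum of
signature-gene expression, thresholded at a cohort-level cutoff (mean,
median, or an optimised split). Such thresholds do not transfer between
datasets — batch effects, platform differences and cohort composition move
the score scale — so a patient measured in isolation cannot be classified.
`reosig` implements the alternative strategy of building the classifier
entirely from **within-sample relative expression orderings (REOs)**: the
binary relation $E_i > E_j$ between two genes measured in the *same*
sample. Any strictly increasing transform applied to one sample's
expression vector — which is how monotone batch and platform distortions
act — leaves every REO unchanged, so an REO-based rule classifies one
sample at a time with no reference to any other sample.

The pipeline is motivated by, and validated against, a gastric-cancer
use case: tumours with higher stem-cell-like character carry worse
prognosis, so a stemness-related gene set drives the subtyping, and the
final deliverable is a gene-pair signature that votes each sample into a
high- or low-risk group.

## The model, stage by stage

### 1. Stemness signature genes from single cells

Given a gene-by-cell matrix, a per-cell stemness score in $[0,1]$ (a
differentiation-potential estimate such as CytoTRACE, here supplied or
simulated rather than recomputed) and a malignant/non-malignant label:

* $G_1$ — genes whose expression correlates with the stemness score across
  **malignant** cells: Pearson $r > 0.2$ and Benjamini–Hochberg
  FDR $< 0.05$ (two-sided $t$-transform p-values). Restricting the
  correlation to malignant cells mirrors how the stemness score is defined
  on the malignant compartment; the comparison group of the differential
  test below is configurable because the original analysis does not pin it
  down.
* $G_2$ — genes upregulated in malignant cells: two-sided Wilcoxon
  rank-sum test with
  $\mathrm{lfc} = \log_2\frac{\bar x_\text{mal} + 1}{\bar x_\text{other} + 1} > 0.25$
  and FDR $< 0.05$. The pseudocount of 1 keeps the fold change finite for
  genes silent in one group.
* The signature set is $G_1 \cap G_2$, sorted for determinism.

Zero-variance genes are recorded as untestable rather than erroring:
droplet data legitimately contains all-zero genes.

### 2. Single-sample enrichment and median-split subtyping

Each bulk sample is scored for the signature set with a single-sample
GSEA statistic implemented from its definition: genes are ranked by
decreasing expression (ties broken by gene id so results are
reproducible), and the score is the sum over list positions of the
difference between a weighted empirical CDF of set members (weight =
rank magnitude$^{\tau}$, default $\tau = 0.25$) and the unweighted CDF of
non-members. Cross-sample range normalisation is deliberately omitted:
only the within-cohort ordering of scores feeds the next step, and
omitting it keeps the score a pure per-sample quantity (a `normalize`
flag restores a range-style rescaling for comparability with other
implementations). Per-cell scoring uses an AUCell-style statistic — the
normalised area under the gene-set recovery curve within the top 5% of
ranks — with the same tie rule.

Cohorts are split at the **median** enrichment score: strictly above the
median is high-risk, everything else low-risk. Ties at the median go low;
the rule is arbitrary but must be fixed for determinism. Degenerate
cohorts (all scores identical) are an error, not a silent half-split.

### 3. Stable and reversal gene pairs

Within each subtype of each cohort, a gene pair $(i, j)$ is **stable**
when one ordering dominates: with $k$ informative samples and $s$ of them
showing the majority ordering, the p-value is the upper binomial tail

$$P = 1 - \sum_{m=0}^{s-1} \binom{k}{m} P_e^m (1-P_e)^{k-m}, \qquad P_e = 0.5,$$

BH-adjusted across all tested pairs within that subtype scan
(separately per subtype, matching the design of identifying stable pairs
per group), retained at FDR $< 0.05$. A within-sample tie ($E_i = E_j$)
contributes to neither ordering and reduces that pair's $k$ — the
conservative treatment of an uninformative observation.

A **reversal pair** is stable in both subtypes with opposite orderings;
it is stored directed, so that observing $E_\text{high} > E_\text{low}$
in a new sample votes "high risk". Reversal lists from the two training
cohorts are intersected and only orientation-consistent pairs survive;
the concordant fraction is tested against chance with a two-sided exact
binomial test. The all-pairs scan runs on the genes present in every
cohort (configurable universe); it is exact, with no heuristic pruning.

### 4. Candidate filtering, C-index ranking, forward search

Each surviving pair becomes a candidate if its binary vote is associated
with overall survival: univariate Cox proportional hazards (Efron tie
handling) on the pooled training samples — restricted to surgery-only
samples by default, so adjuvant-treatment effects do not masquerade as
prognosis — with BH FDR $< 0.05$ across pairs. Votes are computed within
each cohort's matrix and pooled at the vote level, so expression scales
never mix across platforms. Candidates are ranked by Harrell's C-index
(descending), ties broken by smaller Cox p-value then lexicographic pair
id.

The signature is built by single-pass greedy **forward search**: start
with the top-ranked pair; for each next candidate, tentatively add it,
re-label all training samples with the half-voting rule, recompute the
C-index of the binary label, and keep the candidate only if the C-index
strictly increases (tolerance $10^{-9}$). No backward elimination and no
re-ranking between acceptances: the procedure is deterministic and its
recorded C-index path is strictly increasing by construction. The
C-index is computed on the binary high/low label rather than the vote
fraction because classification happens before performance measurement;
the vote fraction is available from `classify_samples()` for users who
want a continuous score.

### 5. Classification and evaluation

The **half-voting rule**: a sample is high-risk iff at least half of the
usable signature pairs vote high. Pairs with a missing gene (platform
coverage differs) or a tied value are skipped and shrink the
denominator; a sample with no usable pair is *unclassifiable* — a status
deliberately distinct from low-risk. Classification reads only the one
sample's expression vector: subsetting, permuting or augmenting the
surrounding matrix can never change a label, and any per-sample strictly
increasing distortion leaves all labels unchanged. These two properties
are asserted exactly in the test suite, because they are the point of
the method.

Evaluation reports Kaplan–Meier curves, the log-rank test between
predicted groups, the C-index of the binary label, and univariate (plus
optional multivariate) Cox fits. Kaplan–Meier, log-rank and Cox fitting
are delegated to the `survival` package (Efron ties); Harrell's C is
implemented directly from its definition — a pair of samples is
comparable iff the shorter observed time carries an event; tied risk
scores count one half — and cross-checked against
`survival::concordance()` on tie-free data in the tests.

## The synthetic-data generator

Every downstream stage is validated against data with planted ground
truth, generated by `simulate_single_cell()` and
`simulate_bulk_cohorts()` from one `synth_config()`:

* **Single cell.** A latent stemness score $\sim U(0,1)$ per cell and a
  Bernoulli malignant label. Planted stem genes gain
  `stem_effect` $\times$ stemness $+$ `stem_effect`/2 $\times$ malignant
  on the log2 scale; other genes are independent of both. Gaussian noise
  (sd `sigma`) on the log2 scale, floored at 0, then exponentiated.
* **Bulk.** Samples draw a latent high/low subtype
  (`subtype_prevalence`). Planted reversal pairs share a baseline and
  split by $\pm\delta/2$ with the sign flipped between subtypes, so the
  pair's ordering reverses. The stem-gene set is elevated by
  `stem_bulk_effect` (default $\delta$) in high-risk samples — this is
  the latent subtype structure that the enrichment subtyping recovers;
  setting it to 0 gives a fully signal-free null cohort. Survival is
  exponential with hazard multiplied by `hazard_ratio` for high-risk
  samples (the simplest model consistent with a constant hazard ratio),
  censoring uniform on $(0, \texttt{censor\_max})$, and a surgery-only
  flag drawn per sample.
* **Batch distortion.** `monotone_per_sample` applies
  $x \mapsto a x^b + c$ with $a, b > 0$, $c \ge 0$ drawn per sample —
  strictly increasing on positive values, hence REO-preserving;
  `genewise_shift` adds a per-cohort per-gene log2 offset, which does
  perturb orderings and models non-monotone artefacts.
* **Ties.** A seeded jitter below $10^{-9}$ breaks exact ties so
  orderings are well defined in generated data, while the core handles
  ties explicitly wherever real data could produce them.

The generator makes no attempt at single-cell count realism (no
negative-binomial sampling, no dropout model) or at realistic
gene–gene correlation: genes are conditionally independent given the
planted structure. Passing tests therefore demonstrate that the
machinery recovers planted signal under the stated noise model and exact
invariances — not that effect sizes of this magnitude occur in real
tumours.

### Default study conditions

The defaults are the conditions under which the package documents its
behaviour: 1000 genes; 200 cells with 50 stem genes,
`stem_effect` = 2, `sigma` = 0.5; two cohorts of 150 samples; 60
planted pairs with $\delta = 1.5 = 3\sigma$; `hazard_ratio` = 2.5;
baseline mean survival 60 months with uniform censoring on (0, 180);
70% surgery-only; per-sample monotone batch distortion. Held-out
evaluation uses fresh 200-sample cohorts sharing the planted structure
(`cohort_seed`) but carrying their own samples and distortions. Where
the source analysis gives no noise or effect-size parameters, these
values were chosen once for testability — strong enough that recovery is
expected, weak enough that the multiple-testing machinery matters.

## Numerical and design choices

* **Tie-breaking** in all rankings is by gene id, making every score
  deterministic under permutations of the input.
* **BH everywhere**: every FDR statement uses Benjamini–Hochberg — the
  standard default when a procedure says "FDR" without naming one.
* **Binomial tail** via `pbinom(s - 1, k, pe, lower.tail = FALSE)`;
  $s = 0$ returns 1. Verified against exhaustive enumeration of all
  $2^k$ direction assignments for $k \le 12$ at $10^{-12}$.
* **Even-split votes** (`votes_high = votes_total / 2`) classify high — the
  literal reading of "at least half".
* **Count ties between orderings** inside a stable-pair scan (same count
  in both directions) keep direction "a > b" deterministically; such
  pairs have $p \approx 0.6$ or more and are never retained.
* **Cox diagnostics**: non-convergence warnings and coefficients beyond
  15 flag the fit object (`flagged = TRUE`) rather than silently
  returning; degenerate covariates error.
* **Forward-search tolerance** $10^{-9}$ on strict improvement guards
  against floating-point noise admitting pairs that change nothing.
* **O(G²) cost**: the all-pairs scan accumulates, per sample, the
  matrix of pairwise ordering indicators; at the default 1000-gene
  universe this is ~0.5M pairs per subtype scan and runs in seconds.
  The C-index inside candidate ranking and forward search uses a
  precomputed comparability mask with a closed-form fast path for
  binary risk labels.

## Problem sizes used by the shipped validation

The test suite and the acceptance script size their simulations to the
documented study conditions: the end-to-end run uses the default
configuration above; the null calibration uses 20 seeds of two
100-sample cohorts over 300 genes with no planted pairs, hazard ratio 1
and `stem_bulk_effect` = 0; Cox recovery uses 100 seeds at 300 samples
per arm; exhaustive oracles cap at $2^{12}$ binomial assignments and
$2^8$ candidate subsets. These sizes are the package's own choice of a
desk-scale experiment with non-trivial multiplicity.

## Known limitations

* The stemness score is an input; the package does not reimplement
  CytoTRACE or any other stemness estimator.
* Gene identifiers are opaque strings; probe-to-gene collapsing and
  cross-platform id mapping are out of scope, and cross-cohort matching
  is exact-string.
* The greedy forward search has no optimality guarantee; the tests
  bracket it between the best single pair and the exhaustive subset
  optimum on small instances, which is exactly what a greedy
  strict-improvement pass can promise.
* Survival machinery covers right-censored single-event data only — no
  competing risks, no time-dependent covariates.
* `genewise_shift` distortions are *not* REO-preserving; the method's
  robustness claim covers within-sample monotone distortions only, and
  the generator exists partly to demonstrate that distinction.

## A worked call

```{r example, eval = FALSE}
man <- run_reo_pipeline(list(simulate = list(seed = 1)))
man                                  # per-stage counts
sig <- man$results$signature
glance(sig)                          # pairs, training C-index
autoplot(sig)                        # forward-search path

cfg <- synth_config(seed = 1, n_cohorts = 1, n_samples_per_cohort = 200)
held_out <- simulate_bulk_cohorts(cfg, cohort_seed = 99)
clin <- dplyr::mutate(held_out$clinical, time = os_time, event = os_event)
ev <- evaluate_signature(sig, held_out$expr[[1]], clin)
ev$logrank_p
autoplot(ev$km)
```
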