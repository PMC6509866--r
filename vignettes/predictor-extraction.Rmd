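---
title: "Extracting minimal predictor panels with Granger-directed networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting minimal predictor panels with Granger-directed networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Two-class expression studies (tumour versus normal) routinely yield
thousands of differential genes, far too many to serve as a clinical
biomarker panel. `grangersift` implements a pipeline that whittles such a
list down to a handful of predictor genes while preserving classification
accuracy, by combining three ideas:

1. **Multi-omics differential screening.** A gene is a *diff-gene* if it is
   differentially expressed, differentially methylated, or a preferred
   target of differentially expressed miRNAs. Genes supported by several
   data types are retained even when any single assay would miss them.
2. **Causal directing of the interaction network.** Among diff-genes that
   interact (co-location, physical, or shared-protein-domain evidence),
   time-series expression is used to decide *who drives whom* via Granger
   causality, and only the *globally independent* genes -- the upstream
   drivers -- are kept.
3. **Stepwise wrapper selection.** The independent genes are reduced to a
   minimal panel by a forward-add / conditional-backward-remove search
   wrapped around cross-validated random-forest accuracy.

## Differential screening

Expression and miRNA matrices are expected on the log2 scale; methylation
as beta values in $[0,1]$. Each feature is tested with a two-sided Welch
$t$-test (unequal variances: tumour and normal groups are typically very
unbalanced), and expression p-values are adjusted by Benjamini--Hochberg.
The defaults are the conventional microarray cutoffs:

| parameter | default | meaning |
|---|---|---|
| `logfc_cut` | 1 | minimum \|log2 fold change\| (expression, miRNA) |
| `fdr_cut` | 0.01 | maximum BH-adjusted p (expression, miRNA) |
| `meth_p_cut` | 0.01 | maximum raw p (methylation) |
| `diffmean_cut` | 0.35 | minimum \|mean beta difference\| |
| `target_degree_cut` | 2 | miRNA-target screen: a gene must be targeted by *more than* this many differential miRNAs |

Threshold comparisons on fold changes, mean differences and FDR are
inclusive ($\ge$ / $\le$); degree cuts are strict ($>$), matching the
"degree greater than $k$" phrasing usual for network screens. The log2
fold change is the difference of class means of the already-log2 values.
Genes with zero variance in both classes have no defined $t$; they get
$p = 1$ (or 0 when the constant means still differ) and are flagged.

The diff-gene network keeps parallel edges of different interaction types,
and node degree counts that multiplicity -- two independent lines of
evidence for a pair count twice. Because an absolute degree cutoff is a
function of network density, `feature_degree_cut` has **no default**:
left `NULL`, every diff-gene is a feature gene; alternatively an absolute
strict cut or a `feature_top_k` (ties included) can be set.

## The causality cascade

For each unordered pair of interacting feature genes $(A, B)$ the cascade
runs, in this fixed gate order, on the time-series matrix:

1. **Pearson correlation**, gate $p < 0.01$ (`alpha_pearson`). Uncorrelated
   pairs are never Granger-tested.
2. **Unit-root (augmented Dickey--Fuller) test** on each series, level
   $0.05$ (`alpha_tests`): levels first, then first differences, giving an
   integration order of 0, 1, or "not testable".
3. **Engle--Granger cointegration** when both series are I(1): regress one
   level series on the other, ADF (no constant) on the residuals against
   the two-variable Engle--Granger critical values. Cointegrated pairs are
   Granger-tested on levels; non-cointegrated I(1) pairs (and mixed-order
   pairs) are "not testable" by default, because the cascade treats
   cointegration as a gate rather than a branch. Setting
   `on_nonstationary = "difference"` instead differences integrated series
   and proceeds.
4. **Granger F-tests in both directions**: an $F$-test of the restricted
   autoregression $y_t \sim y_{t-1..L}$ against the unrestricted model
   adding $x_{t-1..L}$. An edge $A \to B$ is emitted only when the forward
   test is significant **and** the reverse is not -- the defining pair of
   conditions for Granger causality. Pairs significant both ways are
   recorded as `bidirectional` and emit no edge by default
   (`bidirectional_as_feedback = TRUE` turns them into 2-cycles instead).

No multiple-testing correction is applied across pairs: each gate uses its
raw per-test level, which keeps the per-pair operating characteristics
interpretable and matches common practice for cascade-gated tests.

**Lag order.** The default is a fixed lag of 1: expression time courses
are short (tens of points), and larger lags cost two observations of
effective sample size each. `lag_selection = "information_criterion"`
instead minimises the summed AIC of the two unrestricted equations over
lags $1..$`max_lag` (default 3) on a common sample.

**Numerical choices.** No Dickey--Fuller distribution is available in the
dependency set, so ADF and Engle--Granger p-values are obtained by
monotone interpolation of the test statistic against the standard
asymptotic quantile tables (Fuller's $\tau$ tables with and without
constant; the MacKinnon two-variable table for cointegration residuals),
linear in the normal-quantile scale with extrapolated, clamped tails.
Interpolated p-values are accurate near the conventional decision levels,
which is all the gates consume; extreme p-values saturate at $10^{-4}$ /
$0.9999$ and should not be read as precise tail probabilities. The
cointegration regression is run in both orientations and the smaller
p-value is used, which makes the test -- and hence the whole cascade --
exactly symmetric under swapping the pair. A numerically exact linear
relation between the two series short-circuits to $p = 0$. Constant
series, too-short series and zero-variance inputs all produce the
`not_testable` verdict rather than errors, so one degenerate pair cannot
abort a network run.

## Globally independent genes

In the directed network, a gene is *globally independent* when nothing
upstream regulates it: its indegree is 0 (a source, or an isolated gene
with no causal edges), or it sits in a **feedback subnetwork** -- a set of
mutually reachable genes, formalised as a nontrivial strongly connected
component (or a self-loop). Members of a feedback loop regulate each other,
so none of them can be discarded as "merely downstream"; the component
rule also covers genes whose only incoming edges come from their own loop.
Feature genes with no directed edges at all are kept as isolated
independents by default (`include_isolated = FALSE` drops them), since a
failed cascade is absence of evidence of dependence, not evidence of
absence.

## Stepwise character selection

Candidates are first ranked by single-gene cross-validated accuracy. The
panel $P$ is seeded with the best single gene, then the loop runs while
$P_{ACC} - ACC_{max} > -\varepsilon$ and candidates remain: snapshot
$ACC_{max}$; **add** the candidate maximising panel accuracy; if the
tolerance condition still holds, evaluate each member's leave-one-out
accuracy and **remove** every member whose removal strictly improves on
the current accuracy (returning it to the candidate pool); recompute
$P_{ACC}$.

The scorer is a random forest with `n_trees = 500` and
`mtry = floor(sqrt(p))` under stratified 5-fold cross-validation; the
out-of-fold predictions of each repetition are pooled into one confusion
matrix and ACC/SN/SP/MCC are averaged over `n_repeats` seeded repetitions.
Every quantity is deterministic given the configuration seed, and scores
are memoised per gene set within a run.

Design points that were genuinely open:

* **Removal semantics.** A literal set-builder reading of the removal step
  ("keep the members whose removal improves accuracy") would retain
  exactly the panel's *least* useful members and discard the best ones.
  The implemented default follows the descriptive semantics -- *abandon*
  the members whose removal improves accuracy -- which is the only reading
  under which the step can help. The literal variant remains available as
  `removal_semantics = "pseudocode"` (guarded against emptying the panel)
  so the two can be compared; the acceptance tests hand-simulate both.
* **Termination.** With memoised deterministic scores, an add that is
  immediately undone by the removal step reproduces the previous state
  exactly and would loop forever; the loop therefore stops when a state
  repeats (or at `max_iterations`) and returns the best-scoring panel
  seen. Normal termination (tolerance violated, or candidates exhausted)
  returns the final panel, as the algorithm defines it.
* **Tie-breaking.** All argmax steps break ties by higher MCC, then
  earlier candidate rank, then gene identifier, making runs reproducible.
* **Tolerance.** $\varepsilon$ defaults to 0.005 -- half a percentage
  point of cross-validated accuracy, roughly the resolution of one pooled
  fold at a few hundred samples -- and is configurable.
* **Multi-member removal** is evaluated leave-one-out against the
  pre-removal accuracy for each member independently, in one pass.

## Validation metrics

ACC, SN, SP and MCC are computed from the pooled confusion matrix
(`confusion_metrics()`); MCC is set to 0 when a marginal factor vanishes.
ROC curves sweep the decision threshold over the unique positive-class
vote fractions (ties grouped), and AUC is the trapezoid area, which equals
the tie-corrected Mann--Whitney statistic. Panel validation on independent
datasets refits the forest within each dataset under cross-validation --
the panel, not a frozen model, is what transfers; a `transfer` mode that
freezes a single trained forest is available for comparison.

## The synthetic study

The generators provide statistically controlled stand-ins for every input:

* **Expression**: Gaussian class-conditional values around per-gene
  baselines ($\mathcal N(7, 1)$, log2 scale), noise sd 1. The default
  study plants **3 discriminative genes among 40**, shifted by
  `effect_size = 3` (i.e. 3 sd) in the tumour class of **60 + 60**
  samples -- the separation of a strong, clinically useful marker; a
  single such gene classifies at roughly 93% accuracy, so recovering the
  planted panel is non-trivial but achievable.
* **Time series**: a VAR(1), $x_t = A x_{t-1} + \varepsilon_t$, over
  **150 time points** after a 50-step burn-in. All genes share an
  autoregressive coefficient `self_coef = 0.5`; each planted gene drives
  `targets_per_source = 2` targets with coupling `causal_coef = 0.8`.
  The persistence value matters: a lag-1 coupling between two white-noise
  series produces *no* contemporaneous correlation and would be
  discarded by the Pearson gate, whereas persistence 0.5 gives planted
  pairs the strong contemporaneous correlation that genuinely co-regulated
  genes show. Stability (spectral radius < 1) is checked, and an unstable
  coupling matrix is an error.
* **Interactions**: each unordered pair is linked with probability
  `edge_density = 0.10` and a random type; planted causal pairs are always
  included so the cascade can find them.
* **Methylation / miRNA layers**: simple planted-shift analogues (beta
  values via a logistic transform; differential miRNAs wired to hub
  targets) sufficient to exercise the screening contracts.

What the generators deliberately do **not** emulate: batch effects and
array-platform artefacts, the bimodality of real beta values, count-like
miRNA distributions, heavy-tailed expression noise, and biologically
structured (scale-free, modular) interaction networks. Passing the planted
-recovery tests therefore demonstrates that the machinery is correct and
calibrated under its stated model, not that any particular accuracy will
be attained on real cohorts.

## Problem sizes used in the validation experiments

The shipped tests and the acceptance script run at sizes chosen to give
stable statistics on one CPU: cascade calibration uses 100 replicate pairs
of 200 time points; network-level structure recovery uses 20-gene networks
with 10 planted directed relations; end-to-end panel recovery runs the
default 40-gene study over 10 independent seeds with 100-tree forests and
2 CV repetitions; the null calibration of the differential screen uses 20
replicates of 200 genes at 30 + 30 samples. Selection on real cohorts
should use the full defaults (500 trees, 10 repetitions).

## Known limitations

* Pairwise Granger tests cannot distinguish direct regulation from a
  shared upstream driver; the interaction-network restriction mitigates
  but does not remove this.
* The ADF/Engle--Granger p-values are asymptotic-table interpolations;
  at very short series (near the 8-point minimum) they are conservative
  at best. Gates, not p-values, are the supported interface.
* Granger precedence on bulk time courses is statistical, not mechanistic,
  evidence of regulation.
* The stepwise search is greedy; it makes no optimality claim over all
  $2^{|G|}$ panels, and with noisy scorers the selected panel can vary
  between seeds even when its accuracy does not.
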