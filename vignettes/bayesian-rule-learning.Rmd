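---
title: "Bayesian rule learning: models, search and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian rule learning: models, search and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brlearn)
```

## The problem

High-dimensional expression studies (thousands of genes, tens to hundreds of
specimens) often admit many classifiers of similar predictive accuracy that
differ greatly in how legibly they summarize the data. `brlearn` targets the
setting where legibility matters — biomarker discovery — by learning a small
set of probabilistic IF-THEN rules: each rule pairs a conjunction of
discretized feature conditions with a predicted class, its training evidence
(TP/FP), a smoothed posterior probability and posterior odds. The rule base
is *mutually exclusive and exhaustive* (ME&E): every possible instance
matches exactly one rule.

## Model

The statistical object behind the rule base is a target-centric Bayesian
network: a set of predictor variables acting as parents of the class node,
whose conditional probability table (CPT) is represented as a decision tree
over parent values. Each leaf holds the class counts of the training
instances routed to it; each root-to-leaf path is a rule antecedent.

Model quality is the K2 Bayesian score — the marginal likelihood of the class
data under a uniform Dirichlet (all hyperparameters 1) prior, factored over
leaves. A leaf with class counts $N_{j1},\dots,N_{jr_t}$ and total $N_j$
contributes

$$\log \frac{(r_t - 1)!}{(N_j + r_t - 1)!} \prod_k N_{jk}!$$

and the model score is the sum over leaves. All arithmetic is done with
`lgamma`, so scores remain finite for counts far beyond any realistic study
size. No structure prior is applied (uniform over structures); the score is
pure marginal likelihood.

Two structure spaces are searched:

* **Global structure (`gss_search`)** — the CPT tree is fully expanded: one
  leaf per joint assignment of the parents, so a model with parents of
  arities $r_1, \dots, r_p$ has $\prod_i r_i$ leaves and as many rules.
* **Local structure (`lss_search`)** — the tree is grown leaf by leaf,
  splitting a variable's value set either into two blocks (*binary split*)
  or one branch per value (*complete split*). Contexts with identical class
  distributions need never be separated, so the rule base can be much
  smaller than the global expansion at the same fit (context-specific
  independence).

A note on binary splits: we enumerate *all* two-block partitions of a
variable's value set, $2^{r-1}-1$ of them. For arity 2 and 3 this coincides
with choosing a pair of values, but for arity 4 and above pair-choosing does
not define a partition of the whole value set, which ME&E requires; the
partition enumeration is used throughout. Arities after supervised
discretization are small, so the cost difference is negligible.

## Supervised discretization (EBD)

Each continuous feature is discretized against the class by maximizing a
Bayesian score over cut-point sets:

* a geometric prior on the number of cut-points $k$,
  $P(k) \propto \left(\lambda/(1+\lambda)\right)^k$, whose mean is
  $\lambda$ — so `lambda` (default 0.5) is interpretable as the expected
  number of cut-points per feature, and each additional cut costs
  $\log(\lambda/(1+\lambda))$ in log score;
* per interval, the multinomial–Dirichlet marginal likelihood of the class
  labels falling in it, with uniform Dirichlet parameter 1 (the same
  functional form as a K2 leaf).

Candidate cut-points are midpoints between consecutive distinct sorted
values across which the class composition changes (a boundary between two
pure runs of the same class can never help, and a threshold between equal
values is unrealizable). The optimum over candidate subsets is found by
dynamic programming over boundaries, capped at `max_intervals` (default 16,
a guard that is not normally binding). The exact prior form is stated here
and recorded in the scheme file because published descriptions of
supervised Bayesian discretization vary in how the prior parameter enters;
the geometric-with-mean-$\lambda$ reading matches the role of "expected
number of cut-points".

Intervals are right-closed: value $v$ maps to code $j$ when
$c_j < v \le c_{j+1}$. A feature's arity is (cut-points + 1) even if an
interval is empty in a particular data split, so a scheme fitted on a
training fold codes held-out data consistently. Features that receive no
cut-points (arity 1) carry no information under the scheme and are excluded
from structure search.

It is worth being explicit that this criterion is permissive: on moderately
sized noise features it will often place a few cut-points (separating chance
runs of one class), because the per-cut penalty at $\lambda = 0.5$ is about
1.1 nats. The searches tolerate this — the K2 score rarely rewards splitting
on such features — but it is the main reason learned global models can carry
many rules.

## Search

Both searches are deterministic: no randomness anywhere, and ties are broken
by (higher score, fewer used variables, fewer leaves, earlier insertion).
Both take `maxConj` (default 8), the maximum number of distinct variables a
model may use, and `beamWidth` (default 1000), the capacity of the
score-ordered model store. Duplicate structures are excluded from the beam
via a canonical tree serialization.

**GSS** seeds the beam with all single-parent models, then explores
variables one at a time — a single explored set shared by the whole beam —
in decreasing order of singleton score. Exploring a variable extends every
beam member that lacks it (subject to `maxConj`) and merges the scored
extensions back into the beam. The best model ever scored is returned. For
four or fewer predictors and a beam wide enough to hold every subset this
reduces to exhaustive parent-set enumeration, which is how it is tested.
Parent-set scores are computed by tabulating only the observed joint parent
cells; unobserved cells of the expanded CPT contribute a unit factor to the
marginal likelihood, so the shortcut is exact.

**LSS** seeds the beam with singleton models (each eligible variable with
its complete split at the root). The loop pops the best unexpanded model
and, for every variable and leaf (the variable must not already lie on that
leaf's path), evaluates every binary split plus the complete split at that
leaf, re-counting only the affected leaf. The best split for a (variable,
leaf) pair is queued only if it *strictly* improves the popped model's
score (improvement must exceed $10^{-9}$ in log score, which prevents
floating-point cycling). The best model ever seen is returned.

Two stopping rules bound the loop beyond queue exhaustion, both package
design choices: a hard cap on expansions (`max_steps`, default 5000) and a
convergence criterion (`patience`, default 100) that halts after that many
consecutive expansions without improvement of the incumbent best model.
Because the queue is score-ordered, a long stale run means the remaining
queued models all trail the incumbent and further expansion almost never
changes the returned model; on the scales exercised in the tests the search
converges one to two orders of magnitude before either bound.

## Rules, smoothing and prediction

`tree_to_rules` emits one rule per leaf. With smoothing factor
$\alpha$ (default 1), a rule predicting class $c$ with TP instances of $c$
and FP instances of other classes reports

$$P = \frac{TP+\alpha}{(TP+\alpha) + (FP+\alpha)}, \qquad
  \text{odds} = \frac{TP+\alpha}{FP+\alpha}.$$

With more than two classes, TP is the count of the predicted class and FP
the sum of all others (odds "against all other classes"). The predicted
class is the argmax of the smoothed leaf distribution; on ties the training
majority class is used, and the same tie rule applies at prediction time.
Zero-evidence leaves are kept (probability 1/2, majority-class prediction):
dropping them would break exhaustiveness. Rules are ordered by posterior
odds for readability only — ME&E makes order irrelevant to prediction.

Serialized models (`write_rulebase(format = "machine")`) embed the
discretization scheme, so a saved model predicts directly on continuous
data. Derived quantities are recomputed from stored counts on read, making
the round trip exact.

## Evaluation harness

`run_cv` performs stratified k-fold cross-validation (default 10-fold):
samples are shuffled within class under a caller-supplied seed and dealt
round-robin, so fold class proportions match the global ones to within one
instance. Per fold, the discretization scheme is refit on the training
split only — a test verifies that cut-points genuinely differ across folds —
then a model is trained and the held-out split scored on four metrics: AUC
(rank-based Mann–Whitney, ties counting one half; one-vs-rest macro average
if more than two classes), accuracy in percent, number of rules, and number
of distinct variables. The summary reports each metric's across-fold mean
and standard error of the mean (sample sd / $\sqrt{k}$).

## Synthetic data

`brl_simulate` emulates the relevant features of expression matrices:
many continuous features, few informative. Noise features are standard
Gaussians independent of the class; informative features get a
class-conditional mean shift expressed in sd units (scale-free effect
size). Depth-2 mode plants an XOR-style pair: only the joint configuration
carries signal, each member being marginally uninformative — useful for
exercising interaction recovery, though note that marginal supervised
discretization cannot see such pairs, so interaction tests discretize at a
fixed threshold. `generate_cell_data` samples discrete instances from
explicit per-cell class distributions (uniform cell marginals), which is how
the leaf-merging behaviour is exercised: two cells sharing a distribution
should collapse into one local-structure leaf.

What the generator does *not* model: probe- or library-size artefacts,
heavy-tailed intensity noise, correlated gene blocks, batch effects.
Passing recovery tests on this generator therefore demonstrates algorithmic
correctness, not robustness to real microarray/RNA-Seq pathologies.

Test and vignette problem sizes (tens to low hundreds of samples, up to ~50
features) were chosen as the smallest scales at which the planted structure
is comfortably identifiable; they are the package's own test design, and the
defaults `maxConj = 8`, `beamWidth = 1000`, `lambda = 0.5`, `alpha = 1`
are the recommended operating point.

## A worked example

```{r example, eval = FALSE}
sim <- brl_simulate(m = 100, n = 51,
                    informative = list(list(index = 10, shift = 4, sd = 1)),
                    seed = 11)
fit <- brl_train(sim$dataset, method = "lss")
print(fit$rulebase)
cv <- run_cv(sim$dataset, method = "lss", k = 10, seed = 3)
print(cv)
```

## Known limitations

* The discretization criterion is permissive on noise (see above); global
  models on weakly informative data can be large, which is precisely the
  parsimony gap the local search addresses.
* Missing feature values are rejected, not imputed.
* The searches are greedy beam searches; neither is guaranteed to find the
  global optimum outside the small spaces where the tests compare them to
  exhaustive enumeration.
* AUC beyond two classes is a one-vs-rest macro average, an extension beyond
  the binary setting the metrics were designed for.
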