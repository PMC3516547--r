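---
title: "Modeling spatio-temporal gene expression from enhancer occupancy, insulators and promoter state"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling spatio-temporal gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crm2gene)
```

## The model

`crm2gene` implements a three-layer probabilistic model of developmental
gene expression, built for data of the kind produced for the *Drosophila*
embryo: quantitative transcription-factor (TF) ChIP occupancy at
cis-regulatory modules (CRMs), insulator-protein binding peaks, promoter
H3K4me3 state, a small set of CRMs with transgenic-reporter activity
annotations, and in-situ expression labels for a subset of genes, all
expressed over ten binary *activity classes* (five tissue classes and five
developmental stage windows).

**Layer 1 → 2 (binding → CRM activity).** Each of the 15 TF/time binding
variables is soft-discretized: a two-component Gaussian mixture is fitted
per variable and the posterior of the higher-mean ("bound") component is
used as soft evidence $p_{\text{bound}} \in [0,1]$. A *bipartite* Bayesian
network connects binding variables to activity-class nodes; no other edges
are allowed. Because class nodes share no edges, each class's parent set
(size $\le$ `max_parents`, default 3) can be found *globally optimally* by
exhaustive subset search under the Bayesian Dirichlet equivalence (BDeu)
score with equivalent sample size `ess` (default 1). Soft evidence and
fractional activity labels enter the score through expected counts: each
CRM spreads its probability mass over the $2^{|S|}$ parent configurations
and over active/inactive. Conditional probability tables (CPTs) are
posterior-mean estimates with the matching Dirichlet smoothing, so an
unseen configuration falls back to the prior mean 0.5. The *forward*
probability of a CRM being active in a class marginalizes the CPT over the
soft parent configuration.

**Layer 2 → 3 (CRM activity → expression).** A CRM at distance $d$ from a
TSS, with $k$ intervening insulator peaks, reaches the promoter with
weight

$$W = \begin{cases}\max(0,\; 1 - d/d_{\max}) & k \le \text{insulator\_limit}\\
0 & \text{otherwise,}\end{cases}$$

i.e. a linear decay that hits zero at $d_{\max}$, with outright blocking
across an insulator boundary (`insulator_limit` defaults to 0: one
intervening peak blocks). Distance is measured from the TSS to the nearest
CRM edge (zero if the TSS lies inside the CRM) and links are tabulated
within a 100 kb window. The promoter responds with probability $R_j$
(`p_high` = 0.95 if its H3K4me3 call is high, `p_low` = 0.05 otherwise;
the raw signal is averaged over the strand-oriented window (−100, +400) bp
around the TSS and thresholded at 0.3). Expression is a noisy-OR gated by
the promoter:

$$P(G_j = 1) \;=\; R_j \Bigl(1 - \prod_i \bigl(1 - A_i W_{ij}\bigr)\Bigr),$$

so a gene needs both a responsive promoter and at least one active CRM
within reach, any active CRM can independently initiate expression, and
$W$ acts as Bernoulli thinning of an active CRM's signal. The likelihood
of the labeled expression data is the product of these Bernoulli terms
(probabilities clamped to $[10^{-9}, 1-10^{-9}]$ so degenerate predictions
stay finite).

**Latent activities and EM.** CRM activity is observed for only a few
percent of CRMs, so the $A_i$ are treated as latent throughout and the
known activities are used for initialization only. Estimation alternates:

* **E-step.** The *forward* probability comes from the network; the
  *backward* probability of $A_i$ is the likelihood of the labeled
  expression of all genes within reach ($W_{ij}>0$), evaluated with every
  other CRM fixed at its current smoothed estimate (a mean-field pass —
  a CRM can only be inactive if each expressed gene in its range is
  explained by another CRM). Smoothing normalizes the product:
  $\hat A_i = f b_1 / (f b_1 + (1-f) b_0)$.
* **M-step.** The network (structure and CPTs) is relearned using the
  smoothed activities of *all* CRMs as fractional labels, and $d_{\max}$
  is found by exhaustive grid search (step 200 bp, the minimal CRM size;
  ties go to the smaller value), maximizing the expression log-likelihood
  *under the assumed (smoothed) activities*.

Iteration stops when the relative likelihood improvement falls below
`tol` (default 2%).

### A generalized-EM safeguard

The mean-field E-step and the BDe-based M-step do not mathematically
guarantee a monotone likelihood. `run_em()` therefore accepts an M-step
proposal only if it does not decrease the tracked log-likelihood;
otherwise the previous parameters are kept and the run terminates. The
reported trace is thus non-decreasing by construction, and any residual
decrease raises an error (it would indicate a genuine bug). Within one
iteration the $d_{\max}$ update *is* guaranteed non-decreasing, because
the previous value lies on the search grid.

Note that the tracked quantity is the likelihood under the current
smoothed activities. Using forward activities instead (a plausible
alternative) makes the $d_{\max}$ estimate biased low by a few grid steps,
because forward probabilities are attenuated relative to the latent binary
states.

### Initialization

Three strategies are provided (`init =`):

* `"cad"` — the network is first learned on the CRMs with experimentally
  measured activity only, and $d_{\max}$ starts at the window limit so no
  CRM is excluded before the data have spoken.
* `"nearest_gene"` — for settings without CRM activity data: every CRM
  within 500 bp of a labeled gene's TSS inherits that gene's labels (a CRM
  near several genes takes the union of their active labels, since
  enhancers are routinely shared between genes).
* `"two_layer"` — a baseline network mapping weight-summed binding
  features of each gene directly to its expression, skipping the CRM
  layer; its gene predictions are turned into weight-averaged fractional
  CRM labels from which the three-layer model starts. The two-layer model
  is also interesting in its own right: it beats chance but consistently
  trails the full model, which is the reason the CRM layer exists.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `window` | 100 000 | bp | link tabulation limit; also the upper end of the $d_{\max}$ grid |
| `dmax_step` | 200 | bp | grid step; the minimal CRM size, finer steps are not identifiable |
| `insulator_limit` | 0 | peaks | one intervening insulator peak blocks an interaction |
| `p_high` / `p_low` | 0.95 / 0.05 | prob. | promoter response for high/low H3K4me3; not fitted by default |
| promoter window | (−100, +400) | bp | strand-oriented averaging window around the TSS |
| promoter threshold | 0.3 | track units | high/low cut on the averaged processed signal; treat as a config value since its scale is that of the processed track |
| `ess` | 1.0 | pseudo-counts | BDeu equivalent sample size |
| `max_parents` | 3 | — | exhaustive search bound; learned parent sets are typically of size 1–2 |
| `tol` | 0.02 | relative | EM convergence threshold |
| `k` | 10 | folds | gene-level cross-validation |

## The synthetic world

`simulate_dataset()` draws a complete dataset from the model's own
generative assumptions: entities are placed uniformly on one chromosome
with minimum gaps (one gene per ~8 kb; CRMs of 200–600 bp that never
overlap, matching how the real CRMs were constructed; promoter windows of
neighboring genes stay disjoint so the written bedGraph tracks re-read to
exactly the simulated calls). Binding states are Bernoulli(0.3) per
variable; occupancy is drawn from the bound/unbound mixture
$N(3, 0.7)/N(1, 0.5)$ truncated at zero — overlapping enough that soft
evidence is genuinely soft. True CRM activities are sampled from a planted
bipartite network whose classes have 1–2 parents and CPTs
$0.1 + 0.8 \cdot (\text{bound parents}/\text{parents})$, i.e. 10%
end-point noise. Promoters are high with probability 0.7 per time window.
Expression labels are *sampled* from the noisy-OR probability — label
noise is real and AUC < 1 by construction. Finally, activity labels are
revealed for 4% of CRMs and expression labels for 35% of genes, mirroring
the coverage of the real data. The planted $d_{\max}$ is 20 kb.

Two constants deserve comment. The real insulator data contain one peak
per ~3 kb, but those peaks are strongly clustered; placing that density
*uniformly* with `insulator_limit = 0` would sever nearly every link
beyond a few kb. The simulator instead uses one peak per 25 kb, which
reproduces the qualitative saturation behaviour of link counts with
distance. And the desk-scale default (800 CRMs, 1500 genes, 1/10 of the
real dimensions) keeps every test suite fast while preserving the class
prevalences (roughly 10–30%).

### What a green test establishes — and what it does not

The oracle suites verify the arithmetic exactly: noisy-OR equals
enumeration over joint CRM states; the BDe score with hard labels equals
the closed-form Dirichlet integral; the structure search equals exhaustive
enumeration; the smoothed posterior equals the exact conditional posterior
with the other CRMs fixed; AUC equals brute-force pair counting. The EM
trace is non-decreasing on twenty desk-scale worlds.

End-to-end *parameter recovery* at desk scale, however, is only partial,
and the package reports this honestly rather than hiding it. With the
full truth the machinery recovers everything: a supervised fit on the true
activities finds all ten planted parent sets, and an M-step fed the true
latent activities recovers $d_{\max}$ within one grid step. But the EM
started from the desk-scale initialization — 4% of 800 CRMs is only ~32
labeled examples — mis-specifies the two-parent classes at the outset and
then converges to a self-consistent local optimum: about half the parent
sets exact, $d_{\max}$ a few kb high, held-out AUC 0.78–0.93 per class.
This is precisely the initialization sensitivity that motivates starting
EM from measured CRM activities in the first place, and it shrinks as the
labeled initialization set grows; the synthetic world itself is not the
limit (ranking genes by the *true* activation probabilities yields AUC
≈ 0.95).

## Numerical choices

* Mixture fits are initialized from a deterministic tertile split, so
  discretization is reproducible without seeds; a constant column falls
  back to a single component with $p_{\text{bound}} = 0.5$ everywhere.
* Structure-search ties resolve to the smaller, lexicographically first
  parent set (subsets are enumerated in that order and replaced only on
  strict improvement).
* All probabilities entering logs are clamped at $10^{-9}$.
* The backward pass computes per-gene leave-one-out products in log space
  and falls back to exact recomputation when a factor underflows
  ($A_i W_{ij} = 1$).
* The $d_{\max}$ grid scan is the one hot loop (grid × links × classes
  inside every EM iteration) and is implemented in C++; an R-level
  re-evaluation serves as its oracle in the tests.
* Every stochastic step flows from a single integer seed; two runs with
  the same config are bitwise identical.

## Design choices where the design was open

* **Likelihood form.** The published likelihood is only described through
  its legend; the noisy-OR-with-promoter-gate above is the reconstruction
  that preserves the two stated semantics (independent initiation by any
  active CRM; both an active promoter and an active CRM required).
* **Distance and counting conventions.** Distance is TSS to nearest CRM
  edge (CRMs have extent); an insulator peak counts when its midpoint lies
  strictly between them; peaks of all insulator factors are pooled.
* **Soft evidence in BDe** enters via expected counts — the natural
  generalization, since the reference tooling's handling is not
  documented.
* **Time-window mapping.** The three H3K4me3 windows map onto the five
  stage classes as 4–8 h → stages 4–6 and 7–8, 8–12 h → 9–10 and 11–12,
  12–16 h → 13–16; spatial classes use the union (high in any window).
  This mapping is configurable because the original is not recorded.
* **Negative labels.** A gene present in the expression database but
  lacking a class term counts as inactive for that class; genes absent
  from the database are unlabeled and contribute nothing to the backward
  pass or the likelihood.
* **Cross-validation** is stratified greedily on each class's positives
  jointly, so rare classes appear in every fold; besides per-fold AUCs the
  harness reports the pooled held-out AUC (each labeled gene scored by the
  fold model that did not train on it), which stays finite even for
  leave-one-out.

## Known limitations

* Repressive CRMs, CRM–CRM interactions and promoter competition are out
  of scope; the noisy-OR is purely activating.
* The mean-field backward pass ignores dependencies among CRMs induced by
  shared target genes; the generalized-EM rule guards the likelihood but
  cannot rescue a poor initialization (see above).
* `p_high`/`p_low` are fixed, not fitted.
* The insulator model is a hard block on a pooled peak count; factor
  identity and peak strength are ignored.

## A worked desk-scale run

```{r example, eval = FALSE}
library(crm2gene)
cfg <- default_paper_scale("desk", seed = 1)
bundle <- simulate_dataset(cfg)
data <- model_data(bundle$occupancy, bundle$links, bundle$R,
                   bundle$gene_labels, bundle$crm_labels)
state <- run_em(data, init = "cad", verbose = TRUE)
state
pred <- predict_from_state(state, data)
held <- setdiff(rownames(bundle$R), unique(bundle$gene_labels$entity_id))
sapply(data$classes, function(cl)
  roc_auc(pred$p[held, cl], bundle$truth$expression[held, cl])$auc)
```

The README shows the actual numbers this prints.
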