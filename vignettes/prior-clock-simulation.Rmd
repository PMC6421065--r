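---
title: "Tree priors, molecular clocks, and diversification-rate estimates: the simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree priors, molecular clocks, and diversification-rate estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

divclock asks a practical question of molecular phylogenetics: when a dated
tree is re-estimated from sequence data under some combination of
branching-process tree prior (Yule or birth–death) and molecular clock
(strict or uncorrelated lognormal, UCLN), how much of that choice leaks into
downstream maximum-likelihood estimates of diversification rates? The
package implements the full simulation loop — trees, branch rates,
sequences, re-estimation, diversification fits, comparison — so that every
number in the study can be recomputed from a single root seed. This
vignette explains the models, the estimators, the defaults and the design
choices; the README shows the worked example.

## The generating models

**Chronograms.** Trees are drawn from a constant-rate birth–death process
with speciation rate $\lambda$ and extinction rate $\mu$, reparameterized as
the net diversification rate $r = \lambda - \mu$ and relative extinction
$\varepsilon = \mu/\lambda$ (the Yule process is $\varepsilon = 0$).
Simulation is conditioned on the crown age $t$, on survival of both crown
lineages, and on exactly $n$ extant tips. Under this conditioning the
$n-2$ post-root speciation times are i.i.d. with distribution function

$$F(s) \;=\; \frac{1-e^{-rs}}{\lambda-\mu e^{-rs}} \Big/
            \frac{1-e^{-rt}}{\lambda-\mu e^{-rt}},
            \qquad s \in [0, t],$$

so `simulate_chronogram()` samples them by closed-form inverse-CDF and
attaches them to a uniformly sampled ranked topology (at each event, a
uniformly chosen extant lineage splits). This is exact and $O(n)$; no
forward simulation, no rejection, and extinct lineages are never
materialized — only the reconstructed tree matters downstream. The test
suite holds this sampler to a brute-force standard: an event-driven forward
birth–death simulation with explicit extinction and rejection on the
conditioning event, compared by two-sample Kolmogorov–Smirnov tests.

The study conditions fix the crown age at 5 time units and set the
generating rate from the deterministic tip-count expectation
$E[N_t] = N_0 e^{rt}$ with $N_0 = 2$: 25 tips give $r = 0.5051$, 100 tips
give $r = 0.7824$ (`expected_net_diversification()`), with
$\varepsilon = 0.5$ in the birth–death conditions.

**Branch rates.** `draw_branch_rates()` implements two clocks, both in
substitutions/site/time unit:

* *strict*: one rate for the whole tree, drawn from a lognormal with
  real-scale mean 0.01 and log-scale standard deviation 0.5;
* *UCLN*: per tree, a real-scale mean $m \sim U(0.005, 0.015)$ and a
  log-scale standard deviation $\sigma$ drawn uniformly from one of three
  heterogeneity presets — low $U(0.17, 0.18)$, medium $U(0.25, 1)$, high
  $U(0.25, 1.75)$ — then one independent lognormal rate per branch.

Two conventions deserve comment. First, "mean" is read as the *real-scale*
mean and "standard deviation" as the *log-scale* sd (so
$\texttt{meanlog} = \ln m - \sigma^2/2$), the convention of the UCLN
hyperparameters `ucld.mean`/`ucld.stdev` in the reference Bayesian
implementation. Under this reading the low preset predicts a branch-rate
coefficient of variation $\sqrt{e^{\sigma^2}-1} \approx 0.172$–$0.182$,
inside the published interval $[0.157, 0.1948]$, which corroborates the
interpretation; the alternative reading would change absolute rates only,
which the later root-height rescaling removes anyway. Second, rates are
drawn from the *continuous* lognormal rather than the discretized one used
by MCMC implementations for proposal convenience: with independent draws
per branch the discretization converges to the continuous law, and the
continuous form has closed-form moments to test against.

**Sequences.** `simulate_alignment()` evolves sites independently down the
phylogram under GTR+$\Gamma$ with the nuclear-rRNA parameter estimates used
as the study's generating model ($\pi$ = 0.1978, 0.2874, 0.3403, 0.1835;
exchangeabilities 1.6493, 2.9172, 0.3969, 0.9164, 8.4170, 1;
$\alpha = 2.3592$). The printed stationary frequencies sum to 1.009, so
they are renormalized exactly at construction. $Q$ is scaled to one
expected substitution per unit branch length; transition matrices come from
the eigendecomposition of the symmetrized reversible generator. Among-site
rates are continuous Gamma($\alpha$, mean 1) draws — the default of the
standard sequence simulator — while *inference* uses the standard
4-category discrete gamma (median per category, normalized to mean 1). The
mismatch is deliberate: it mirrors how real analyses pair a continuous
generating process with a discretized inference model. Alignment lengths in
the study grid are 2500, 5000 (default), and 10000 bp. No gaps, ambiguity
codes, indels, or partitions are generated.

## The re-estimation surrogate

The original workflow re-estimated trees by Bayesian MCMC and summarized
posteriors as maximum-clade-credibility trees. divclock deliberately
replaces that with a deterministic maximum-likelihood / penalized-likelihood
point estimate; this is the package's single largest departure from the
workflow it emulates, and it is what makes the study reproducible on one
CPU in minutes. The downstream quantities depend only on *relative* node
ages after the tree is rescaled to the true root height, which a point
estimate provides. Posterior distributions, credible intervals, MCC
summaries and convergence diagnostics are out of scope by design.

The surrogate pipeline (`infer_dated_tree()`) is:

1. **Topology** (`estimate_topology()`): neighbor joining on pairwise ML
   distances computed under the fixed GTR+$\Gamma$ model; saturated pairs
   are capped at 10 substitutions/site with a warning. The generating
   topology can be passed through instead (`topology_source = "true"`).
2. **Branch lengths** (`ml_branch_lengths()`): all branch lengths jointly
   maximize the pruning-algorithm likelihood. The likelihood kernel is
   compiled code with analytic branch-length gradients (a two-pass scheme:
   tipward partials from the postorder pass, rootward partials from a
   preorder pass, with per-pattern log scalers tracked on both sides), so
   quasi-Newton updates on log branch lengths converge in seconds; the
   optimization stops at a relative log-likelihood change below $10^{-6}$.
3. **Rooting** (`clock_root()`): the root is placed at the point along any
   edge minimizing the variance of root-to-tip path lengths — the
   least-squares strict-clock criterion — with ties broken by the
   lexicographically smallest tip bipartition.
4. **Dating** (`date_strict()` / `date_relaxed()`): node ages are
   parameterized as proportions of the parent's age (root fixed at 1) and
   optimized jointly with the rate(s) against the sequence likelihood under
   the constraint branch length = rate × duration. The strict clock has one
   global rate. The relaxed clock gives every branch its own rate and
   maximizes
   $\log L - \kappa \sum_i (\ln r_i - \overline{\ln r})^2$,
   the penalized-likelihood analogue of the UCLN prior's shrinkage of
   branch rates toward a shared value.
5. **Rescaling** (`rescale_to_root()`): the dated tree is rescaled so its
   root age equals the true crown age, removing absolute-rate and tree-age
   error and isolating relative branching patterns, before diversification
   rates are estimated.

The smoothing weight $\kappa$ defaults to 1. There is no principled mapping
between $\kappa$ and the width of the Bayesian UCLN hyperprior, so no
equivalence is claimed; results can be run across a $\kappa$ grid, and as
$\kappa \to \infty$ the relaxed estimate provably collapses onto the strict
one (tested at $\kappa = 10^4$; at much larger values the penalty gradient
dwarfs the likelihood gradient and the optimizer stalls early, so the
collapse is verified at large-but-finite $\kappa$). The tree-prior label
(`prior_mode`) is carried through the experiment design but does not enter
the surrogate's objective — no branching-process prior term is added. This
operationalizes the headline empirical finding that the tree prior has
little effect, and it preserves the four-condition reporting structure.
Substitution-model parameters are fixed at their generating values during
inference rather than co-estimated: substitution-model misspecification is
a separately studied problem, and fixing halves the optimization dimension.

## Diversification estimation

`yule_mle()` and `bd_mle()` fit constant-rate models to branching times by
maximum likelihood. The likelihood is the reconstructed-process form built
from the same i.i.d. speciation-time density $g = F'/F(t)$ used by the
simulator, under one of two conditioning conventions:

* `"ntaxa"` (default): the tip count is treated as fixed by design, and the
  likelihood is the joint density of the $n-2$ post-root times given $n$
  and the crown age.
* `"survival"`: conditions only on the crown age and survival of both crown
  lineages, so the tip count is informative through the sum of two
  geometric variables with success probability $1-u$, $u = \lambda F(t)$.

The default matters. The study's trees are generated *conditioned on both*
$n$ and crown age, and under that design the survival-conditioned MLE of
$r$ is strongly biased downward (its geometric term centers $u$ at
$(n-2)/n$ regardless of the data; about −35% at 25 tips, −14% at 100 tips
in our measurements), while the $n$-conditioned MLE recovers $r$ to within
a few percent — consistent with the reference distributions of the original
study, whose estimates on the true trees center near the generating rates.
Both conventions are exposed because the original analysis tool's
conditioning flag is not recorded; one documented qualitative property does
depend on the switch. Fitting a *Yule* model to birth–death trees
underestimates $\lambda$ (truth $2r$ at $\varepsilon = 0.5$), and under the
survival conditioning the shortfall shrinks as taxa are added (ratio
$\hat\lambda/2r \approx 0.65 \to 0.70$ from 25 to 125 tips), reproducing
the published taxon-number trend; under the `"ntaxa"` conditioning the
ratio moves the other way. Tests of that trend therefore set
`conditioning = "survival"` explicitly.

`bd_mle()` maximizes over $r \in (10^{-6}, 10]$, $\varepsilon \in
[0, 0.999]$ by Nelder–Mead simplex on transformed coordinates from five
coarse-grid starts (relative tolerance $10^{-8}$). Two numerical facts are
worth knowing. First, for an appreciable fraction of 25-tip trees
(roughly a quarter in our measurements) the likelihood increases along the
ridge $\varepsilon \to 1$, $r \to 0$ with $\lambda$ essentially fixed; the
fit then sits at the $\varepsilon$ cap, is flagged `boundary = TRUE`, and
$\hat r$ is near zero. This is a property of the likelihood, not of the
optimizer — along that ridge only $\lambda$ and the likelihood value are
identified — and it makes the across-tree distribution of $\hat r$ at small
$n$ a mixture with a large standard deviation (about 0.4 at 25 tips), which
is why mean-recovery checks at 25 taxa use thousands of replicate trees.
Second, the grid-refinement oracle used in tests compares $\hat r$ only at
interior optima and compares achieved log-likelihoods on the ridge.

## The experiment layer

`run_experiment()` wires the stages into the factorial design: for each
generating condition (tree model × clock preset × $n$ × $L$) and replicate,
it simulates tree, rates and alignment, fits both clock modes (sharing the
topology, rooting and unconstrained branch lengths between them), records
the result under both tree-prior labels, rescales, and fits both
diversification models — always alongside fits to the original simulated
tree, which form the reference column of every comparison table
(`summarize_experiment()` reports medians and quartiles). Replicates
default to 10 original trees per condition, matching the original design;
the acceptance checks raise this where tolerances require. All randomness
derives from one root seed via a documented counter scheme
(`derive_seed()`), so any replicate is reproducible in isolation and
reruns are bit-identical. Stage failures are caught per replicate and
reported, not fatal. Lineage-through-time overlays (`plot_ltt()`) use a
natural-log lineage-count axis; plots are a view of the tables, never the
source of any number.

Problem sizes used by the shipped checks: the qualitative
prior-versus-clock reproductions run 25 replicates of the 25-taxon, 5000-bp
conditions (low and high heterogeneity); distributional oracles use 5- and
8-tip trees at 2000 replicates; recovery checks use 200–2000 trees
depending on the estimator's across-tree variance. These reduced sizes are
the package's choice of a desk-scale design; the full published grid
(10 replicates of every condition at $n \in \{25, 100\}$) is the default of
`experiment_config()` and runs unattended.

## What the generator does and does not emulate

The synthetic data reproduce the study's stated generating conditions:
conditioned tree shapes, three calibrated levels of lineage-rate
heterogeneity, and a realistic, quickly evolving nuclear marker with strong
among-site rate variation. They do not emulate several features of real
data: alignment error, gaps and indels, substitution-model misspecification
(inference uses the generating GTR+$\Gamma$ family with fixed parameters),
incomplete or biased taxon sampling, extreme rate heterogeneity beyond the
high preset, or lineage-specific diversification-rate shifts. Passing tests
therefore demonstrate internal consistency of the estimators under the
simulation model — not robustness of the conclusions to these violations,
which the original study itself lists among its caveats.

## Known limitations

* The Bayesian layer is a point-estimate surrogate: nothing here speaks to
  posterior widths, HPD intervals, or MCC-tree node support, and the
  published posterior-specific numbers (e.g. coefficient-of-variation HPDs
  under medium/high heterogeneity) are not reproduced.
* The surrogate does not reproduce the relaxed clock's advantage over the
  strict clock under *high* rate heterogeneity. This is structural, and
  worth understanding before using `date_relaxed()` to rescue
  heterogeneous data. With uncorrelated per-branch rates, the sequence
  likelihood constrains only the product rate × duration on each branch;
  in a full Bayesian analysis the branching-process tree prior supplies the
  node-age structure that lets the UCLN model convert fitted rate variation
  into better ages. The surrogate deliberately adds no branching-process
  term to its objective (that choice is what operationalizes the
  tree-prior-doesn't-matter finding), so its relaxed fits reach much higher
  likelihoods than strict fits on heterogeneous data — the rates are real —
  while recovering node ages no better (measured node-age error is
  statistically indistinguishable between the two clock modes at the high
  preset, on estimated and on true topologies, across the smoothing grid).
  The corresponding check in the shipped test suite is accordingly
  expected to fail, and is retained unweakened as a record of this
  boundary of the surrogate design.
* $\hat\varepsilon$ is reported but weakly identified, especially at small
  $n$; conclusions should rest on $\hat r$ and $\hat\lambda$.
* Strict-clock dating assumes the clock-rooting step found the right root;
  on nearly clock-like data with short basal branches the variance
  criterion can be flat across adjacent edges.
* The NJ topology is a point estimate; topological error at deep nodes
  propagates into node ages, which is visible in the LTT overlays exactly
  as in the original study's deep-node discordance.
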