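---
title: "Inferring evolutionary pathways between reproductive ecology and parental care"
author: "evopath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring evolutionary pathways between reproductive ecology and parental care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the two-layer design

Comparative data can show that two binary traits — say, a reproductive-ecology
trait such as terrestrial egg deposition and a care trait such as egg
attendance — co-occur across species more often than chance. Co-occurrence
alone cannot say whether the ecological shift *drove* the origin of care,
whether care came first and enabled the ecological shift, whether the two are
alternative solutions to the same selective problem, or whether they are
simply unrelated. `evopath` implements a two-layer Bayesian analysis that
addresses the ordering question directly:

1. **Screen** (phylogenetic probit): the probability of observing the care
   response is modelled as a function of *all* candidate predictors entered
   jointly, with the phylogeny as a random effect, so that covariation among
   predictors is accounted for and only genuinely associated predictors move
   forward. Collinearity is checked with variance inflation factors (VIF > 5
   flags a problem).
2. **Order** (4-state correlated evolution): for each screened (predictor,
   response) pair, a continuous-time Markov model over the four joint states
   `(0,0), (0,1), (1,0), (1,1)` is estimated by reversible-jump MCMC. The
   dependent model has eight transition rates (each trait's gain and loss can
   depend on the other trait's state); the independent model constrains them
   to four. Dual transitions (both traits changing in one instant) are
   excluded. Marginal likelihoods from stepping-stone sampling compare the two
   models, and the posterior distributions of the eight rates are mapped to an
   explicit verdict.

States are indexed `1 = (0,0)`, `2 = (0,1)`, `3 = (1,0)`, `4 = (1,1)` with
the first position the ecology trait (A) and the second the care trait (B);
`q_ij` denotes the instantaneous rate from state `i` to `j`.

## The verdict rules

With `theta = 0.95` the posterior support threshold (0.75 reported as a
"suggestive" tier) and `pct_zero(q)` the posterior percentage of samples in
which a rate sits in the zero bin:

* **unrelated** — the independent model is supported by the Bayes factor.
* **ecology_first** — `P(q34 > q12) >= theta` (care is gained faster when the
  ecological trait is present), or `P(q13 > q12) >= theta` with
  `pct_zero(q34) < 25` (the ecological trait is gained first from the
  double-absence state and care follows at a meaningfully positive rate).
* **care_first** — the mirror conditions: `P(q24 > q13) >= theta`, or
  `P(q12 > q13) >= theta` with `pct_zero(q24) < 25`.
* **alternative_solutions** — each single-trait state is gained faster than it
  is lost while the both-present state is lost faster than gained:
  `q12 > q21`, `q42 > q24`, `q13 > q31`, `q43 > q34`, each at support
  `>= theta`.
* **unresolved** — no rule fires, or conflicting rules fire (never a silent
  tie-break).

The 25% zero-bin cut-off mirrors the reporting convention of treating a rate
as "estimated to be zero" when more than a quarter of the posterior models
place it in the zero bin. The Bayes-factor grades use the conventional
2·Δ(ln marginal likelihood) scale with thresholds 2 (positive) and 10
(strong); both thresholds are configuration, not constants, because "clear
support" is ultimately a reporting choice.

# The discrete model and its sampler

## Priors

Each value-bin rate has an exponential prior whose mean `m` carries a uniform
hyperprior on (0, 20); `m` is itself sampled (reflective random walk). The
reversible-jump state is a partition of the free rate labels (8 dependent / 4
independent) into a zero bin plus some number of value bins, one positive
value per bin; the prior over partition structures is uniform. Because new
bin values are proposed from their own prior, the structure-move acceptance
reduces to the likelihood ratio times the ratio of available-move counts,
which makes the kernel easy to verify: on data with flat likelihood the chain
must reproduce the uniform distribution over structures exactly (a
chi-squared check in the test-suite) and the rate samples must reproduce the
exponential/uniform mixture (a Kolmogorov–Smirnov check).

## Moves

Per iteration: a multiplicative log-normal walk on one random bin value
(scale auto-tuned to 20–40% acceptance during burnin, then frozen); a *subset
scale* move multiplying a random subset of bin values by a common factor; the
hyperprior-mean walk; and one reversible-jump structure move (zero a label,
resurrect a label into an existing or new bin, merge two bins, split a bin
over an unordered bipartition). The subset scale move exists because the
likelihood surface regularly contains diagonal ridges — for example, a
trait's gain and loss rates falling together while their ratio is conserved —
that coordinate-wise walks cross only through a barrier.

## Likelihood

Felsenstein pruning over a post-order edge list with per-edge rescaling
against underflow. Transition matrices `P(t) = exp(Qt)` come from a cached
eigendecomposition of the generator (a spectral tensor making each branch a
handful of complex exponentials), with scaling-and-squaring as automatic
fallback for defective generators, and `P = I` exactly on zero-length
branches. One subtlety deserves emphasis: cells of `P(t)` that are
*structurally* zero (state `j` unreachable from state `i` through positive
rates) are forced to exact zero via the transitive closure of the rate graph.
Round-off leakage of order 1e-12 into such a cell would otherwise price an
impossible transition at `log(1e-12) ≈ -28` rather than `-Inf`, which is
catastrophic precisely when the zero bin sets rates exactly to zero: spurious
"good" likelihood modes appear and Bayes factors can be corrupted by large
margins. Root states are weighted uniformly by default ("stationary" is a
config option); the root treatment is propagated into all reports.

## Marginal likelihoods

Stepping-stone sampling with the inverse-temperature ladder at quantiles of
Beta(0.3, 1). The ladder is annealed from the posterior down to the prior,
each stone warm-started from the one above: cold-started ladders must recover
from diffuse-prior states (rates of order 10 on a branch-scaled tree) and
stall there on occasion. The estimator reports a Monte-Carlo standard error
from the effective sample size of the per-stone importance weights and flags
stones dominated by a single draw.

## Chain presets

`chain_config(preset = ...)` bundles three scales: `"paper"` (4e8 iterations,
burnin 5e5, thinning 2e5) mirrors published production settings for a
1200-species analysis; `"desk"` (1e6 / 1e5 / 100) is the package default; and
`"rapid"` (3e4 / 5e3 / 25, 8 stones of 1500 draws) is what the test-suite,
the acceptance script and the calibration studies use (the end-to-end
pipeline replicates use a slightly shorter custom config of the same shape).
The rapid preset was chosen so that a full 300-tip dependent fit takes a few
seconds while leaving every calibration check (prior recovery, coverage,
Bayes-factor separation) comfortably passable; the worked analyses in
`analysis/` use `"desk"`.
Before any discrete fit the tree's branch lengths are rescaled so the
all-branch mean is 0.1 (`scale_branch_lengths`), which keeps the
data-supported rates in a range the sampler explores easily; rescaling the
tree by `c` is exactly equivalent to rescaling all rates by `c`, and the
likelihood identity is asserted to 1e-10 in the tests.

# The phylogenetic probit layer

The threshold model: liability `l = X·b + u + e` with `u ~ N(0, sigma2_p·C)`
for the scaled shared-path-length correlation `C`, `e ~ N(0, 1)` (the
residual variance is not identifiable for a binary response and is fixed at
1), and `y = 1` iff `l > 0`. A predictor is associated with the response when
less than 5% of its effect's posterior crosses zero (`Px < 0.05`, two-sided,
sign-of-median convention). Heritability is reported on the liability scale,
`h2 = sigma2_p / (sigma2_p + 1 + L)` with `L = 1` the probit link variance
(toggle `include_link_variance`); it reads like Pagel's lambda.

Two design points matter and are easy to get wrong:

* **The fixed-effect prior must be scale-coupled.** With the residual fixed
  at 1 the liability scale is only weakly identified by binary data: the
  integrated likelihood grows like `(sigma2_p + 1)^(p/2)` if the diffuse
  normal prior (variance 1e8) is placed on raw liability-scale effects, and
  with two or more fixed effects the posterior of `sigma2_p` is improper —
  samplers that mix well along the scale direction drift without bound
  (samplers that mix poorly merely hide it). `evopath` therefore places the
  diffuse prior on liability-standardized effects,
  `b | sigma2_p ~ N(0, prior_var·(sigma2_p + 1 + L))`, which cancels the
  growth exactly, keeps the prior effectively flat at any scale, and leaves
  `Px` (a per-sample sign statistic) untouched.
* **The variance prior is uniform on h2 by default.** `sigma_prior =
  "uniform_h2"` puts a uniform prior on the heritability, i.e.
  `p(sigma2) = k/(sigma2+k)^2` with `k = 1 + L` — a proper prior that is
  approximately a cumulative-uniform on the variance fraction. A heavy-tailed
  half-t on the phylogenetic SD is available (`"half_t"`) but lets the
  variance wander when clades separate perfectly.

The sampler is blocked Gibbs with two accelerations, both validated by a
flat-likelihood prior-recovery test (balanced response on a star tree, where
the `h2` posterior must equal its prior): a *collapsed* update of `sigma2_p`
given the liabilities with the phylogenetic effects integrated out in the
eigenbasis of `C` (avoiding the funnel), and a *group scaling* move that
rescales `(l, b, u, sigma2_p)` jointly — the observation model constrains
only `sign(l)`, so the move accepts on cheap Gaussian terms and lets the
liability scale mix across orders of magnitude. Effects and liabilities are
updated by their exact normal and truncated-normal conditionals; the whole
sweep is O(n²) per iteration after one eigendecomposition of `C`.

# The synthetic-data generator

`simulate_tree` grows a pure-birth (Yule) tree to `n` tips: while `k`
lineages are active it waits `Exp(k·birth_rate)` and splits a random lineage;
after the n-th lineage a final `Exp(n·birth_rate)` stretch runs to the
present. All tips are contemporaneous and the expected root-to-tip depth is
`sum_{k=2..n} 1/(k·birth_rate)`, which the tests verify empirically. Branch
lengths are then rescaled to the pipeline's mean-0.1 convention.
`simulate_history` is an exact Gillespie simulation of the 4-state chain down
the tree; `generate_dataset` draws the root from the generator's stationary
distribution (state 1, with a warning, if the rate graph is reducible).

`regime_rates` provides one named preset per hypothesis. The presets are this
package's own choices — the hypotheses define inequalities, not numbers — and
were designed against two analytic targets computed from each preset's
stationary distribution: a reasonably balanced margin for the ecology trait
(P(eco = 1) ≈ 0.62; a badly skewed margin leaves many simulated datasets with
almost no species on one side of the contrast, which caps the power of any
method) and a strong conditional contrast for care
(P(care | eco = 0) ≈ 0.10 vs P(care | eco = 1) ≈ 0.67):

| preset | rates (q12, q13, q21, q24, q31, q34, q42, q43) | intended verdict |
|---|---|---|
| `ecology_first` | 0, 1.5, 3, 0.5, 2, 3, 0.3, 1.2 | ecology_first |
| `care_first` | 1.5, 0, 2, 3, 3, 0.5, 1.2, 0.3 | care_first |
| `alternative_solutions` | 1.5, 1.5, 0.5, 0.3, 0.5, 0.3, 2.5, 2.5 | alternative_solutions |
| `independent` | gains and losses all 1 (4 free rates) | unrelated |
| `null_care` | care gain/loss 0.1, ecology 1/1, independent | unrelated |

`care_first` is exactly the trait-swap image of `ecology_first` (swap map
`q12<->q13, q21<->q31, q24<->q34, q42<->q43`), so the classifier's swap
symmetry can be tested directly. `generate_study` builds one tree and one
trait column per predictor; the response comes from the pair simulated under
the (at most one) coupled regime, and every other predictor carries its own
independent history. Simulating *two* predictors both coupled to one response
has no defined generator here and raises an error.

## What the generator does and does not emulate

It emulates a time-calibrated tree with contemporaneous tips, binary traits
evolved under the exact model the estimator assumes, and predictors that are
phylogenetically structured yet independent of the response. It does not
emulate real-data features such as tree imbalance or lineage-specific rate
variation, trait-dependent diversification, misclassified states, or sampling
biased by trait value. Passing the recovery tests therefore shows the
estimator is correct and well calibrated *under its own model*; it does not
certify robustness to model violation on empirical data. One practical
consequence visible even inside the model: a single simulated history on a
deep tree can concentrate one trait in one or two clades, leaving the dataset
genuinely uninformative — verdict-recovery rates below 100% reflect that
irreducible variability, not estimator error. Note also that naive
contingency-table tests between two phylogenetically structured traits are
anti-conservative (pseudo-replication), which is precisely why the screen is
a *phylogenetic* probit.

# Numerical choices and degenerate inputs

* Likelihood tolerances: pruning vs enumeration, factorization and rescaling
  identities hold to 1e-10; Chapman–Kolmogorov to 1e-9; transition-matrix
  rows sum to 1 within 1e-10 with negative round-off clamped at zero.
* Zero-length branches use `P = I` without an exponential call; all-zero
  generators are valid (the likelihood is then driven by root weights alone).
* Ambiguous tips (partial-likelihood vectors of ones) are supported
  internally — they make the flat-likelihood calibration checks possible —
  but the pipeline itself uses complete cases only.
* `align_tree_traits` prunes with unifurcation collapsing so patristic
  distances are preserved (required for likelihood invariance); polytomies
  are accepted as-is.
* Trait coding is strict: 1 = presence, 0 = absence; a non-binary non-missing
  value is an error rather than a guess, and rows with missing values are
  dropped and reported.
* Constant predictors are dropped with a warning; a constant response is an
  error; a perfectly collinear predictor reports infinite VIF and is excluded
  (last-listed first) before the probit runs.
* `summarize_rates` reports the mode as 0 when the zero bin holds the
  majority of samples, otherwise as the kernel-density mode of the positive
  samples; credible intervals are central quantile intervals over all
  samples, zeros included.

# Known limitations

* Two traits only; no hidden-rate or covarion extensions; no more than one
  response-coupled predictor per synthetic study.
* The verdict thresholds (`theta`, the 25% zero-bin rule, Bayes-factor
  grades) are explicit configuration standing in for qualitative judgements
  ("overlap substantially") that have no canonical numeric form.
* Stepping-stone standard errors assume approximately independent weights
  after ESS correction; heavily dominated stones are flagged rather than
  repaired.
* The probit layer assumes the threshold model's liability structure; when
  the data are generated by a discrete Markov process (as in the synthetic
  studies) the phylogenetic variance parameter absorbs clade structure and
  `h2` tends towards 1 — a model-mismatch feature, not a bug, and one reason
  the screen's job is only to rank and flag predictors, not to estimate
  effect sizes for interpretation.
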