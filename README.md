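# evopath

Bayesian inference of the evolutionary pathway linking a reproductive-ecology
trait to a parental-care trait on a time-calibrated phylogeny.

Across species, care behaviours such as egg attendance tend to co-occur with
ecological traits such as terrestrial egg deposition. Co-occurrence alone
cannot distinguish four very different histories: the ecological shift drove
the origin of care (*ecology first*), care came first and enabled the
ecological shift (*care first*), the two are alternative solutions to the
same selective problem, or they are unrelated. `evopath` implements, as a
tested R package plus a reproducible analysis workflow, the two-layer
comparative design that addresses the ordering question:

1. **Phylogenetic probit screen.** The binary response (e.g. egg attendance
   by one sex) is modelled against all candidate binary predictors jointly in
   a threshold model: liability `l = X·b + u + e`, `u ~ N(0, σ²_p C)` with
   `C` the scaled shared-ancestry correlation from the tree, `e ~ N(0, 1)`
   (residual fixed at 1), `y = 1` iff `l > 0`. Fixed effects carry a diffuse
   normal prior (variance 1e8, on liability-standardized effects); predictors
   with `Px < 0.05` (the fraction of the effect's posterior crossing zero)
   pass the screen. Collinearity is checked by VIF (> 5 flags a problem), and
   phylogenetic signal is reported as liability-scale heritability
   `h² = σ²_p/(σ²_p + 2)`, read like Pagel's lambda.
2. **4-state correlated-evolution model.** For each screened (predictor,
   response) pair, the joint states `1=(0,0), 2=(0,1), 3=(1,0), 4=(1,1)`
   evolve by a continuous-time Markov chain with eight transition rates
   `q_ij` (dual transitions excluded). Reversible-jump MCMC explores
   rate-equality partitions including a zero bin — `pct_zero(q_ij)` is the
   posterior percentage of models in which a rate is exactly zero — under an
   Exponential(mean m) rate prior with m ~ Uniform(0, 20). Stepping-stone
   marginal likelihoods compare this *dependent* model against the
   *independent* one (4 free rates), and the posterior rate inequalities
   (e.g. `q34 > q12`: care is gained faster when the ecology trait is
   present) are mapped to an explicit verdict:
   `ecology_first`, `care_first`, `alternative_solutions`, `unrelated`, or
   `unresolved`.

Everything runs on synthetic data from the package's own generator (Yule
trees, exact Gillespie trait histories under named regime presets), so every
stage is testable without any external dataset. The methods vignette
(`vignettes/pathway-inference.Rmd`) documents the models, priors, samplers,
numerical choices and limitations.

## Worked example

The `analysis/` directory is a four-stage workflow over the package API.
Stage 1 simulates a 300-tip study with an *ecology-first* predictor `T`
(generating rates `q12 = 0, q13 = 1.5, q21 = 3, q24 = 0.5, q31 = 2,
q34 = 3, q42 = 0.3, q43 = 1.2` — care cannot arise while the ecology trait
is absent) and an uncoupled, phylogenetically evolving predictor `H`:

```sh
Rscript analysis/01_simulate_study.R
Rscript analysis/02_probit_screen.R
Rscript analysis/03_discrete_models.R      # desk-scale chains, ~5 min
Rscript analysis/04_pathway_classification.R
```

Stage 2 (probit screen, 30k iterations) prints:

```
               mean ci_lower ci_upper     Px
(Intercept) -6.7789 -31.7327   4.6915    NA
T            9.5550   2.7261  27.7093 0.0000
H           -0.3205  -4.3549   3.2919 0.4256
h2: mean 0.955  95% CI [ 0.822, 0.999 ]
Significant predictors (Px < 0.05): T
```

Only the truly coupled predictor passes (`Px(T) = 0`, `Px(H) = 0.43`); the
high `h²` reflects the strong clade structure of a trait evolved on the tree.
Stage 3 fits both discrete models to the (T, attendance) pair by RJ-MCMC
(preset `"desk"`, 1e6 iterations) and estimates marginal likelihoods:

```
          mean    median   mode  ci_lower ci_upper  pct_zero
q12      0.032       0.0    0.0       0.0    0.490      90.9
q13      2.174       2.2    2.1       1.2    3.315       0.0
q34      3.252       3.1    2.6       1.6    5.555       0.0
...
lnML dependent = -257.77 (se 0.10); independent = -281.20 (se 0.07)
```

The zero bin identifies the structurally absent transition — 90.9% of
posterior models set `q12` exactly to zero, the generating value — and the
other rates bracket their true values. Stage 4 grades the Bayes factor
(`logBF = 2·ΔlnML = 46.9`, dependent-strong) and evaluates the verdict
rules at support threshold 0.95:

```
pathway verdict: ecology_first (model grade: dependent-strong, logBF = 46.86)
                                       condition  value fired
1                      support(q34>q12) >= theta 0.9989  TRUE
2 support(q13>q12) >= theta & pct_zero(q34) < 25 0.9961  TRUE
3                      support(q24>q13) >= theta 0.5820 FALSE
...
```

Care is gained essentially only after the ecology trait (`P(q34 > q12) =
0.999`) and the ecology trait is gained first from the double-absence state
(`P(q13 > q12) = 0.996`): the generating pathway is recovered. Not every
simulated replicate is this clean — about 1 draw in 20 at 300 tips leaves a
trait concentrated in one or two clades and ends `unresolved`, which is a
property of the data, not the estimator (the acceptance suite quantifies
recovery at 19/20 and 17/20 over the two coupled regimes).

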