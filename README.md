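# poets

Pareto-optimal parameter ensembles for mechanistic models by multiobjective
simulated annealing (Pareto Optimal Ensemble Techniques, POETs).

## The problem this package addresses

Kinetic models in systems biology — and mechanistic models generally — carry
many adjustable parameters estimated from several datasets that pull the fit
in different directions: in a gene-expression circuit, parameters that
improve the mRNA fit degrade the protein fit. A single best-fit vector hides
both this trade-off structure and the "sloppy" directions along which large
parameter changes barely alter the fit. `poets` is for modelers who want the
*ensemble* instead: the cloud of parameter sets that are near-optimal with
respect to all objectives simultaneously, from which one can read off
trade-offs, compensatory parameter correlations (practical identifiability),
and prediction intervals for new conditions.

## The algorithm

For an archive of solutions evaluated on m objectives (all minimized),
solution x_j *strictly dominates* x_i iff

    f_k(x_j) <= f_k(x_i) for all k,  and  f_k(x_j) < f_k(x_i) for some k,

and the dominance-count rank R(x_i) = |{ j : x_j ≺ x_i }| is the energy in a
Metropolis rule: a candidate proposed from the incumbent by a Gaussian
neighbor move is accepted with probability

    min{ 1, exp( −(R_cand − R_inc) / T ) },

with geometric cooling T ← 0.90·T from T = 1. Strict (not weak) dominance
keeps duplicated solutions at rank 0; ranks are maintained incrementally in
O(nm) per candidate with an O(k) revert on rejection (*pop-on-reject*), so
the archive stays bounded between accepted moves. Accepted moves trigger
pruning at a rank cutoff (default 8) and a hard capacity (default 5000).
Independent chains (default 8) from random starts are merged and re-ranked;
the rank ≤ 1 members of the merged cloud form the default working ensemble.
Front quality is scored by hypervolume (exact for 2–3 objectives) and
inverted generational distance against a reference front.

Built-in problems: the constrained Binh–Korn and unconstrained
Fonseca–Fleming analytic benchmarks (with dense reference fronts) and a
two-ODE cell-free gene expression model (Hill promoter activity, decaying
translational capacity, SD-weighted least-squares objectives for mRNA and
protein) with a synthetic time-course generator using multiplicative 15% CV
Gaussian noise in triplicate.

## A worked example

```r
library(poets)

fit <- poets(problem_binh_korn(),
             poets_schedule(Tmin = 1e-4, n_iter = 25, n_max = 2000),
             n_chains = 4, seed = 1)
print(fit)
#> Pareto-optimal ensemble (POETs)
#>   problem: binh_korn (2 parameter(s), 2 objective(s))
#>   chains: 4/4 completed, seed 1, 8804 evaluations (2.3 s)
#>   merged archive: 4266 record(s); Pareto front: 2021; ensemble (rank <= 1): 2593

hypervolume(fit$archive, c(140, 50)) /
  hypervolume(binh_korn_front(10000), c(140, 50))
#> [1] 0.9991208
```

Even this short run covers 99.9% of the dense analytic front's hypervolume,
with a front of ~2000 retained solutions — the density that makes ensemble
statistics meaningful.

The biological use case — recovering cell-free expression parameters from
one noisy synthetic triplicate time course and propagating the ensemble to
prediction bands:

```r
set.seed(1)
obs <- make_synthetic_observations()            # 0,2,4,8,16 h; 15% CV; n = 3
cf  <- poets(problem_cellfree(obs), poets_schedule(), n_chains = 4, seed = 1)

truth <- simulate_cellfree(cellfree_params(), seq(0, 16, 1))
bands <- predict(cf, times = seq(0, 16, 1))     # 95% empirical-quantile bands
coverage_rate(bands$protein, truth$protein)
#> [1] 1
max(bands$protein$mean)                          # ensemble-mean peak protein
#> [1] 370.3234                                   # truth: 390.0  (5.0% error)

round(parameter_correlations(ensemble_parameters(cf)), 2)[1:2, 1:2]
#>             log10_alpha log10_kappa
#> log10_alpha        1.00       -0.78
#> log10_kappa       -0.78        1.00
```

The 95% band brackets the noise-free truth at every time point and the
ensemble-mean peak lands within 5% of it, while individual parameters remain
only loosely determined: the strong log-space correlations (α–κ r = −0.78
through the protein amplitude; α–K r = 0.69 through the promoter occupancy
α·u(K)) are the compensatory structure that lets very different parameter
vectors produce near-identical trajectories.

A command-line interface with `run`, `analyze` and `benchmark` subcommands
wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/poets.R", package = "poets"))')" \
    run --config config.json --out rundir
```

See the methods vignette (`vignettes/ensemble-methods.Rmd`) for the model,
its assumptions, and all tunable parameters.

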