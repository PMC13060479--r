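---
title: "Pareto-optimal parameter ensembles by multiobjective simulated annealing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pareto-optimal parameter ensembles by multiobjective simulated annealing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## Why ensembles instead of best fits

Mechanistic models in systems biology usually carry more adjustable
parameters than any single dataset can pin down, and different datasets pull
the fit in different directions: calibrating a gene-expression model to mRNA
measurements degrades the protein fit, and vice versa. Treating this as a
multiobjective problem, the interesting object is not one best-fit vector
but the *cloud* of parameter sets that are near-optimal with respect to all
objectives at once. The boundary of that cloud in objective space is the
Pareto front; the cloud itself carries the information about what the data
can and cannot constrain, and propagating it through the model yields
prediction intervals whose width reflects that information.

`poets` implements Pareto Optimal Ensemble Techniques: simulated annealing
in which the *dominance-count rank* of a candidate — the number of archive
members that strictly dominate it — plays the role of the energy in a
Metropolis acceptance rule. The output of a run is an archive of evaluated
parameter vectors with their objective vectors and ranks; a rank-filtered
view of that archive (by default rank ≤ 1) is the working ensemble.

## The dominance model

All objectives are minimized (callers negate objectives to maximize).
Solution $x_j$ *strictly dominates* $x_i$ when
$f_k(x_j) \le f_k(x_i)$ for every objective $k$ and $f_k(x_j) < f_k(x_i)$
for at least one. The rank of $x_i$ is
$R(x_i) = \lvert \{ j \ne i : x_j \prec x_i \} \rvert$, so rank-0 solutions
form the front. Strictness matters for the ensemble use case: identical (or
duplicated) solutions do not dominate each other and therefore all keep
rank 0. Under the weak relation (only $\le$ required) duplicates count as
dominating each other, which inflates their ranks and causes good solutions
to be pruned; `pareto_ranks(..., weak = TRUE)` retains that relation purely
as a diagnostic mode, and the test suite asserts the contrast (a $k$-fold
duplicated point has rank 0 strictly, rank $k-1$ weakly).

One consequence of the count definition worth knowing: concatenating
archives (e.g. merging chains) re-counts dominators over the union, so a
dominated record's rank grows when its dominators appear in several chains.
Front membership — rank 0 — is what is invariant under duplication, not the
numeric rank of dominated records.

### Incremental ranking and pop-on-reject

Appending one candidate to an archive of $n$ solutions does not require the
$O(n^2 m)$ pairwise re-rank: a single $O(nm)$ pass tests dominance in both
directions, incrementing the rank of each existing record the candidate
dominates and counting the candidate's own dominators
(`rank_insert()`). The pass records which ranks it incremented, so a
rejected candidate is removed again in $O(k)$ by decrementing exactly those
entries (`rank_revert()`) — the *pop-on-reject* strategy. This keeps the
archive from growing between accepted moves; at no instant does it hold
more than `n_max + 1` records. The dominance kernels are written in C++
(via Rcpp) and are single-threaded and bit-reproducible: ranks are a pure
function of the objective matrix, independent of record order.

After an acceptance, records whose rank meets the cutoff
(`rank_cutoff`, default 8) are removed, and if the archive still exceeds
`n_max` (default 5000) only the `n_max` lowest-rank records are retained,
ties at equal rank keeping the most recently inserted record (later-phase,
cooled solutions are the better-refined ones; the tie rule is a package
convention). The exported `prune_by_cutoff()` and `enforce_capacity()`
re-rank survivors from scratch. Inside the annealing loop the survivors'
ranks are instead carried over unchanged, which is exact: strict dominance
is transitive, so every dominator of a survivor has strictly lower rank and
therefore also survives — removal can never change a survivor's dominator
count. A property test asserts this equivalence against the full re-rank on
random archives, and the oracle-equivalence test exercises the whole
insert/revert/prune/cap cycle against a brute-force double loop.

## The annealing loop

A chain starts from one evaluated solution $(x_0, f(x_0))$ at temperature
$T_0 = 1$. At each level, `n_iter` (default 50) candidates are proposed by
perturbing the incumbent — the most recently accepted solution — with the
neighbor function; the shipped default adds Gaussian noise with standard
deviation `step_scale` (default 0.05) times each bound width and reflects
at the bounds. A candidate that is infeasible or whose evaluation fails
(error, `NA`, `Inf`) consumes a proposal but never enters the archive:
constraint handling is by rejection, which keeps the rank semantics clean,
and silent `Inf` objectives would only hide model failures. Otherwise the
candidate is inserted incrementally and accepted with probability
$\min\{1, \exp(-(R_\text{cand} - R_\text{inc})/T)\}$, both ranks read from
the post-insertion state. The *difference* form makes any non-worsening
move certain and removes sensitivity to the absolute rank scale; the
*absolute* form $\exp(-R_\text{cand}/T)$ is available via
`poets_schedule(acceptance = "absolute")` for users who prefer comparing
against the front itself. The temperature then cools geometrically,
$T \leftarrow \alpha T$ with $\alpha = 0.90$.

### Stopping rule and evaluation budget

Annealing stops when $T$ falls below `Tmin`; a `max_evals` cap is also
available for budget-matched comparisons. The default `Tmin = 1e-11` gives
241 levels and 12,050 evaluations per chain, so a default 8-chain run
spends roughly 100,000 evaluations — the budget scale used for the
package's validation studies. Temperatures below about $10^{-2}$ are an
effectively zero-temperature *quench*: only non-worsening moves are
accepted and the front is refined in place. That refinement phase is not
cosmetic. When the objectives are nearly separable (distinct parameters
control distinct objectives, as in the cell-free model below), the true
front collapses toward a single utopian point, and an under-converged run
leaves behind non-dominated "stragglers" — members that are marginally
better in one objective and very poor in the others. Stragglers distort
ensemble means; deep refinement finds points that dominate them, and the
cutoff pruning then removes them.

### Multiple chains

`poets()` runs `n_chains` (default 8) independent chains from uniform
random in-bounds starts (or user-supplied ones), merges the archives with
chain provenance, and performs one full re-rank of the union. No cutoff or
capacity pruning is applied at the merge — the full cloud is the product —
and the recorded `rank_filter` (default 1) defines the working ensemble.
Chain $i$ seeds R's RNG with `seed + i - 1`, so results are reproducible
bit for bit and independent of how chains would be scheduled; the
implementation runs them serially, which is the reference order any
parallel execution must reproduce.

## Front quality indicators

`hypervolume(front, ref_point)` is the Lebesgue measure of the union of
boxes between front points and the reference point (exact sweep for two
objectives, slicing for three, Monte Carlo above that); points beyond the
reference are clipped with a warning. `igd(front, reference)` is the mean
Euclidean distance from each reference-front point to its nearest computed
point, on the raw objective scale by default (a normalized variant is a
flag, since unnormalized distances are dominated by the widest objective).
Reference points are a per-problem choice recorded with the run — the
package defaults are $(140, 50)$ for Binh–Korn and $(1, 1)$ for
Fonseca–Fleming — because indicator values are only comparable at a fixed
reference. Both built-in benchmarks ship with dense analytic fronts
(`binh_korn_front()`, `fonseca_fleming_front()`) derived from their known
Pareto sets, which the tests cross-check against brute-force non-dominance
on a dense feasible grid.

## The cell-free gene expression model

The built-in biological test problem is a two-state model of cell-free
(in vitro transcription–translation) expression of a reporter protein from
a sigma-70 promoter:

$$\dot m = \alpha\, u(\sigma_{70}) - \delta_m m, \qquad
  \dot p = \kappa\, m\, w(t) - \delta_p p,$$

with Hill promoter activity
$u = \sigma_{70}^{\,n} / (K^n + \sigma_{70}^{\,n})$ and an exponentially
decaying translational capacity $w(t) = e^{-\ln 2 \cdot t/\tau_{1/2}}$,
reflecting the finite lifetime of the extract's translation machinery.
Five parameters are estimated — the maximum transcription rate $\alpha$
(nM/h), translation rate constant $\kappa$ (1/h), mRNA degradation rate
$\delta_m$ (1/h), promoter dissociation constant $K$ (nM), and capacity
half-life $\tau_{1/2}$ (h) — while $\sigma_{70} = 35$ nM, $n = 1.5$ and
$\delta_p = 0.005$ h$^{-1}$ stay fixed at literature values. The system is
integrated with `deSolve::lsoda` at tight tolerances (the mRNA equation has
a closed form against which the solver is verified to below $10^{-6}$
relative error, and the protein solution is checked against an independent
quadrature oracle). The two objectives are SD-weighted sums of squared
errors for the mRNA and protein time courses, and the search runs in
log10 parameter space with bounds of ±1.5 decades around the nominal
values — rate constants are scale parameters, and plausible ranges span
orders of magnitude.

### What the synthetic-data generator emulates

`make_synthetic_observations()` simulates the model at a set of "true"
parameters and applies multiplicative Gaussian noise
$x' = x(1 + \varepsilon)$, $\varepsilon \sim \mathcal N(0, 0.15^2)$, to
`n_reps = 3` replicates per time point on the grid 0, 2, 4, 8, 16 h,
reporting replicate means and SDs — the structure of a typical cell-free
time-course experiment (proportional error, triplicates, a handful of time
points). Negative draws are clipped at zero, and SDs are floored at 1% of
the species' noise-free maximum so that zero-variance points (e.g. $t = 0$,
where the truth is exactly 0) cannot produce infinite weights. The default
truth — $\alpha = 100$ nM/h, $\kappa = 2$/h, $\delta_m = 0.5$/h,
$K = 70$ nM, $\tau_{1/2} = 4$ h — is a package default chosen as realistic
for a reporter circuit of this kind: mRNA rises to ~50 nM within a few
hours, protein accumulates to ~400 nM over 16 h as capacity decays.

What the generator does *not* emulate: model misspecification (the fitted
model is exactly the generating model), correlated residuals, and
measurement-specific artifacts such as calibration drift. Tests that pass
on these data therefore validate the optimizer and the uncertainty
machinery, not the model's adequacy for any real extract.

Two structural features of this problem are worth flagging because they
shape what "success" looks like. First, $\alpha$ and $K$ enter the mRNA
equation only through the product $\alpha\,u(K)$, so they are individually
unidentifiable — since $u$ decreases with $K$, the ensemble exhibits a
compensatory *positive* correlation between $\log\alpha$ and $\log K$
(visible in `parameter_correlations()`, alongside a negative
$\log\alpha$–$\log\kappa$ coupling through the protein amplitude), while
the identifiable combinations are well determined.
This is exactly the compensatory structure ensembles are meant to reveal.
Second, the two objectives are nearly separable — $(\alpha u, \delta_m)$
control the mRNA fit, $(\kappa, \tau_{1/2})$ the protein fit given mRNA —
so with self-consistent synthetic data the trade-off between them is weak
and the front is nearly a point; genuine mRNA/protein trade-offs arise
with real data, where model error forces the objectives into conflict.

## Downstream ensemble analysis

`predict()` on a fitted object simulates each rank-filtered member and
returns, per observable, the pointwise ensemble mean and empirical
quantile band (`prediction_band()`, default 95%, `stats::quantile` type 7).
These are empirical quantiles of ensemble predictions, *not* Bayesian
credible intervals: the ensemble makes no claim about the relative
probability of its members, only that they fit comparably well, and band
calibration depends on how thoroughly the chains explored the near-optimal
region. Bands are pointwise in time rather than simultaneous, matching the
quantile construction. `coverage_rate()` reports the fraction of time
points at which a reference trajectory lies inside the band (inclusive);
`trajectory_features()` extracts lag time, peak value, time of first peak,
and trapezoidal AUC — the area statistic is the analogue of the endogenous
thrombin potential used for thrombin-generation curves. The lag time is
defined here as the first crossing of 5% of the peak (linearly
interpolated); the threshold is a package convention exposed as
`lag_fraction`, since the field uses lag times without one canonical
definition. `parameter_correlations()` works on the search scale (log10
for log-space problems) because compensatory couplings between rate
constants are linear in the log.

## A worked example

```{r, eval = FALSE}
library(poets)

## short demonstration run (the defaults are ~10x longer)
fit <- poets(problem_binh_korn(),
             poets_schedule(Tmin = 1e-4, n_iter = 25, n_max = 2000),
             n_chains = 4, seed = 1)
print(fit)
hypervolume(fit$archive, c(140, 50)) /
  hypervolume(binh_korn_front(10000), c(140, 50))

## synthetic cell-free recovery study
set.seed(1)
obs <- make_synthetic_observations()
cf <- poets(problem_cellfree(obs), poets_schedule(), n_chains = 4, seed = 1)
bands <- predict(cf, times = seq(0, 16, 1))
truth <- simulate_cellfree(cellfree_params(), seq(0, 16, 1))
coverage_rate(bands$protein, truth$protein)
plot(bands$protein, truth = truth$protein,
     xlab = "time (h)", ylab = "protein (nM)")
parameter_correlations(ensemble_parameters(cf))
```

## Numerical choices and degenerate inputs

* Objective values must be finite; `NA`/`Inf`/errors at evaluation become
  rejected moves (and a startup error at $x_0$).
* Proposals are reflected at the box bounds (period-$2w$ fold), so the
  neighbor contract — return an in-bounds vector — holds for any step size;
  `step_scale = 0` returns the incumbent unchanged.
* `quantile` type 7 (linear interpolation of order statistics) is used for
  bands; with very few members the band is narrower than the member range.
* Archive CSVs are written with 17 significant digits, which round-trips
  IEEE doubles exactly: re-reading a stored archive and re-ranking it
  reproduces the stored rank column bit for bit, and identical seeds yield
  byte-identical run directories.
* An all-zero trajectory yields all-zero features with a degeneracy flag
  rather than an error; constant parameter columns yield `NA` correlations
  rather than a silent 0.
* Capacity ties at equal rank keep the newest record; survivors of any
  pruning keep their original archive order.

## Problem sizes used in the test suite

The packaged studies are sized for a single CPU: ranking oracles run ~1000
random archives up to $n = 200$, $m \le 4$; benchmark recovery uses default
8-chain runs (~96k evaluations) on both analytic problems across three
seeds; the cell-free study uses 4 chains (~48k ODE evaluations) per seed
across three seeds, with the 2-of-3 pass rule reflecting the stochastic
nature of recovery from one noisy triplicate dataset. Deeper archives,
more chains, or longer quenches only improve front density and are a
matter of compute budget.

## Known limitations

* Ensembles are selected by rank, not probability; do not read the bands
  as posterior credible intervals. Reweighting the members against a
  formal (e.g. Gibbs) posterior is out of scope here.
* Ensemble *means* are sensitive to front geometry: on problems with
  antagonistic objectives the rank-filtered ensemble legitimately contains
  extreme trade-off members, and trajectory-space means can sit far from
  any individual good fit. Report medians or bands alongside means when the
  front is wide. Conversely, a very tight ensemble (deep quench on nearly
  separable objectives, as in the cell-free study) can under-cover a truth
  trajectory offset by data noise — band width reflects ensemble spread,
  not sampling error of the data.
* No adaptive cooling, reheating, surrogate models, or gradient
  refinement; chains are sequential by nature, and wall-clock time is
  dominated by objective evaluations (ODE solves for the biological
  problems).
* Hypervolume above three objectives falls back to Monte Carlo;
  non-dominated *sorting* into fronts (NSGA-style layering) and crowding
  measures are intentionally absent — rank here is a dominance count.
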