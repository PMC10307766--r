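# pabalance

Workload-balanced patient-to-doctor assignment for online (cloud) healthcare
triage, via an island-model (distributed) genetic algorithm.

## The problem

A triage step hands the assignment module, for each patient *i*, an
estimated diagnosis time *T̃ᵢ* (minutes) and a candidature list — the
doctors eligible to see that patient. Each patient must get exactly one
doctor from their list. With *Sᵢʲ = 1* when patient *i* is assigned to
doctor *j*, doctor *j*'s workload is

    T_j = Σᵢ T̃ᵢ · Sᵢʲ

and the objective is the **time factor**, the population standard deviation
of the workloads,

    TF = sqrt( Σⱼ (T_j − T̄)² / n_D ),    T̄ = Σⱼ T_j / n_D,

to be minimised (TF = 0 ⇔ perfectly balanced doctors). The package is for
health-systems / operations researchers who want a reproducible, seedable
implementation of this optimisation problem, its island-GA solver, the usual
baselines, and the statistics harness used to compare them.

## What is in the box

* `pa_instance()`, `generate_instance()`, `table1_suite()` — the problem
  container and a seeded synthetic benchmark generator (16 size classes,
  n_P ∈ {100..400} × n_D ∈ {10..40}, times uniform on [5, 20] minutes), plus
  a documented plain-text instance format (`read_instance()`,
  `write_instance()`, examples under `inst/extdata/`).
* `assign_patients()` — one front end over all algorithms, returning a
  classed fit with `print`, `summary`, `coef` (the assignment), `fitted`
  (per-doctor loads), `residuals` (load − mean load), `plot` (convergence or
  load profile) and `simulate` (re-runs under fresh seeds) methods.
* `run_dga()` — the island-model GA: integer encoding, uniform crossover,
  candidate-list mutation, family selection, ring-topology elite migration,
  fixed evaluation budget (default n_P × n_D), per-island RNG streams for
  exact reproducibility. Operator building blocks (`init_population()`,
  `uniform_crossover()`, `mutate_genes()`, `ring_migration()`,
  `evolve_generation()`) are exported.
* `run_random()`, `run_greedy()`, `run_de()` (discrete-adapted DE/best/1),
  `run_ga()` (panmictic GA) and `run_variant()` (no-crossover, no-mutation,
  no-distributed ablations), all sharing the evaluator and budget.
* `repeat_runs()`, `rank_sum_compare()` (two-sided Wilcoxon rank-sum, exact
  for pooled n ≤ 12), `build_table()` (mean/sd tables with best-in-row and
  dagger significance marks), `convergence_report()` (aligned mean
  best-so-far curves), `pa_experiment()` (full benchmark sweeps), and a thin
  CLI (`inst/scripts/pabalance-cli.R`) with `generate`, `run`, `experiment`
  and `compare` subcommands.

## A worked example

```r
library(pabalance)

inst <- generate_instance(100, 10, seed = 1)   # 100 patients, 10 doctors
fit  <- assign_patients(inst, "dga", seed = 3) # budget = 100 x 10 evaluations
fit
#> Patient assignment fit (method: dga)
#>   instance: 100 patients, 10 doctors
#>   best TF: 12.9309 min   evaluations used: 1000
#>   generations: 23

round(fitted(fit), 1)    # per-doctor total diagnosis time (minutes)
#>    D1    D2    D3    D4    D5    D6    D7    D8    D9   D10
#> 128.9 121.3 114.2 119.0 116.3 129.7 144.9 113.3 153.7 135.6
```

TF = 12.93 means the doctors' workloads spread about ±13 minutes (one
standard deviation) around their 127.7-minute mean — down from ~37 for a
typical random assignment at this size. For calibration on the same
instance: best-of-1000 random sampling reaches TF 14.44, and the
deterministic least-loaded greedy construction reaches TF 4.41 (greedy is a
very strong constructive heuristic for this objective; the GA family is the
interesting object here because it extends to constraints greedy cannot
see). Run-to-run spread of the optimiser:

```r
simulate(fit, nsim = 10, seed = 1)  # mean TF 11.62, sd 1.67
plot(fit)                           # best-so-far TF vs evaluations consumed
```

A small comparison table with significance marks:

```r
rr <- lapply(c("random", "dga"), function(m)
  repeat_runs(inst, m, n_runs = 25, base_seed = 7, instance_id = "T1",
              max_evals = 1000))
build_table(rr)
```

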