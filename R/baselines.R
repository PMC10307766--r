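#' Random-search baseline
#'
#' Draws `max_evals` independent uniform feasible assignments (each gene
#' uniform on its candidate set) and keeps the best.
#'
#' @param instance a [pa_instance()].
#' @param max_evals number of assignments to evaluate.
#' @param seed integer seed.
#' @return A [pa_fit] object.
#' @examples
#' run_random(generate_instance(30, 3, seed = 1), 100, seed = 2)$tf
#' @export
run_random <- function(instance, max_evals, seed = 1L) {
  stopifnot(inherits(instance, "pa_instance"))
  max_evals <- as.integer(max_evals)
  if (max_evals < 1L) .stopf("`max_evals` must be at least 1")
  old <- .rng_snapshot()
  on.exit(.rng_restore(old))
  set.seed(seed)
  cf <- .cand_flat(instance)
  res <- cpp_random_search(instance$est_time, instance$n_doctors,
                           cf$flat, cf$off, instance$all_doctors, max_evals)
  structure(
    list(method = "random", genes = res$best_genes, tf = res$best_tf,
         loads = cpp_loads(instance$est_time, res$best_genes, instance$n_doctors),
         trajectory = cbind(evals = res$imp_eval, tf = res$imp_tf),
         evals_used = res$evals, generations = NA_integer_,
         instance = instance, config = list(max_evals = max_evals), seed = seed),
    class = "pa_fit")
}

#' Greedy least-loaded baseline
#'
#' Processes patients in input order and assigns each to the candidate doctor
#' with the smallest current total load (ties broken by lowest doctor index).
#' Fully deterministic; counted as a single fitness evaluation.
#'
#' @param instance a [pa_instance()].
#' @return A [pa_fit] object.
#' @examples
#' run_greedy(pa_instance(c(4, 6, 10), 2))$loads
#' @export
run_greedy <- function(instance) {
  stopifnot(inherits(instance, "pa_instance"))
  nP <- instance$n_patients
  nD <- instance$n_doctors
  loads <- numeric(nD)
  genes <- integer(nP)
  for (i in seq_len(nP)) {
    cd <- .candidates_of(instance, i)
    j <- cd[which.min(loads[cd])]
    genes[i] <- j
    loads[j] <- loads[j] + instance$est_time[i]
  }
  tf <- cpp_tf(instance$est_time, genes, nD)
  structure(
    list(method = "greedy", genes = genes, tf = tf, loads = loads,
         trajectory = cbind(evals = 1L, tf = tf),
         evals_used = 1L, generations = NA_integer_,
         instance = instance, config = list(), seed = NA_integer_),
    class = "pa_fit")
}

#' Discrete-adapted DE/best/1 baseline
#'
#' Differential evolution over real vectors of length `n_patients`; a
#' coordinate is decoded to a doctor by clamping to
#' `[0, |candidates[i]|)` and flooring to an index into the patient's
#' candidate list, so every real vector decodes to a feasible assignment.
#' Mutants follow the DE/best/1 schema `v = x_best + F (x_r1 - x_r2)` with
#' distinct random `r1, r2`, binomial recombination at rate `cr` with one
#' guaranteed mutant coordinate, and greedy one-to-one replacement on the
#' decoded time factor (strictly-better, so ties keep the incumbent).
#'
#' @param instance a [pa_instance()].
#' @param max_evals fitness-evaluation budget (must cover the initial
#'   population).
#' @param np population size (>= 4).
#' @param f scale factor F.
#' @param cr recombination rate in `[0, 1]`.
#' @param seed integer seed.
#' @return A [pa_fit] object.
#' @examples
#' run_de(generate_instance(30, 3, seed = 1), 200, np = 10, seed = 2)$tf
#' @export
run_de <- function(instance, max_evals, np = 80L, f = 0.5, cr = 0.9, seed = 1L) {
  stopifnot(inherits(instance, "pa_instance"))
  np <- as.integer(np); max_evals <- as.integer(max_evals)
  if (np < 4L) .stopf("DE needs a population of at least 4")
  if (f <= 0) .stopf("`f` must be positive")
  if (cr < 0 || cr > 1) .stopf("`cr` must lie in [0, 1]")
  if (max_evals < np)
    .stopf("`max_evals` (%d) must cover the initial population (%d)", max_evals, np)
  nP <- instance$n_patients
  nD <- instance$n_doctors
  est <- instance$est_time
  if (instance$all_doctors) {
    len <- rep.int(nD, nP)
    flat <- NULL; off <- NULL
  } else {
    len <- lengths(instance$candidates)
    flat <- unlist(instance$candidates, use.names = FALSE)
    off <- c(0L, cumsum(len))[seq_len(nP)]
  }
  decode <- function(x) .de_decode(x, len, flat, off, instance$all_doctors)

  old <- .rng_snapshot()
  on.exit(.rng_restore(old))
  set.seed(seed)

  X <- matrix(runif(nP * np), nP, np) * len
  tf <- numeric(np)
  evals <- 0L
  best_tf <- Inf; best_genes <- NULL
  tr_e <- integer(0); tr_f <- numeric(0)
  for (m in seq_len(np)) {
    tf[m] <- cpp_tf(est, decode(X[, m]), nD)
    evals <- evals + 1L
    if (tf[m] < best_tf) {
      best_tf <- tf[m]; best_genes <- decode(X[, m])
      tr_e <- c(tr_e, evals); tr_f <- c(tr_f, tf[m])
    }
  }
  ib <- which.min(tf)
  i <- 0L
  while (evals < max_evals) {
    i <- if (i == np) 1L else i + 1L
    r <- sample.int(np, 2L)
    v <- X[, ib] + f * (X[, r[1L]] - X[, r[2L]])
    mask <- runif(nP) < cr
    mask[sample.int(nP, 1L)] <- TRUE
    trial <- X[, i]
    trial[mask] <- v[mask]
    gt <- decode(trial)
    tft <- cpp_tf(est, gt, nD)
    evals <- evals + 1L
    if (tft < tf[i]) {
      X[, i] <- trial
      tf[i] <- tft
      if (tft < tf[ib]) ib <- i
      if (tft < best_tf) {
        best_tf <- tft; best_genes <- gt
        tr_e <- c(tr_e, evals); tr_f <- c(tr_f, tft)
      }
    }
  }
  structure(
    list(method = "de", genes = best_genes, tf = best_tf,
         loads = cpp_loads(est, best_genes, nD),
         trajectory = cbind(evals = tr_e, tf = tr_f),
         evals_used = evals, generations = NA_integer_,
         instance = instance,
         config = list(max_evals = max_evals, np = np, f = f, cr = cr),
         seed = seed),
    class = "pa_fit")
}

# DE genotype-to-assignment decode: clamp each coordinate to
# [0, |candidates[i]|), floor, and index into the candidate list. Total:
# every real vector (including NaN-free infinities) decodes to a feasible
# assignment.
.de_decode <- function(x, len, flat, off, all_doctors) {
  idx <- as.integer(pmin(floor(pmax(x, 0)), len - 1L))
  if (all_doctors) idx + 1L else flat[off + idx + 1L]
}

#' Panmictic GA baseline
#'
#' The distributed GA with its distributed framework switched off: a single
#' population of size `sps * nsp` evolves with identical operators and no
#' migration.
#'
#' @inheritParams run_dga
#' @param ... passed to [dga_config()] (e.g. `max_evals`, `seed`).
#' @return A [pa_fit] object with method `"ga"`.
#' @examples
#' run_ga(generate_instance(30, 3, seed = 1), max_evals = 300, seed = 2)$tf
#' @export
run_ga <- function(instance, ...) {
  cfg <- dga_config(..., distributed = FALSE)
  run_dga(instance, cfg)
}

#' Ablation variants of the distributed GA
#'
#' `"no-crossover"` replaces each pair's child by a copy of one uniformly
#' chosen parent (still mutated and still evaluated, so the budget flow
#' matches the complete algorithm); `"no-mutation"` keeps crossover output
#' only; `"no-distributed"` evolves one panmictic population (identical to
#' [run_ga()]).
#'
#' @param instance a [pa_instance()].
#' @param which one of `"no-crossover"`, `"no-mutation"`, `"no-distributed"`.
#' @param ... passed to [dga_config()].
#' @return A [pa_fit] object; `method` is `"dga-<which>"`.
#' @examples
#' run_variant(generate_instance(30, 3, seed = 1), "no-mutation",
#'             max_evals = 300, seed = 2)$tf
#' @export
run_variant <- function(instance,
                        which = c("no-crossover", "no-mutation", "no-distributed"),
                        ...) {
  which <- match.arg(which)
  cfg <- switch(which,
    "no-crossover" = dga_config(..., crossover = FALSE),
    "no-mutation" = dga_config(..., mutation = FALSE),
    "no-distributed" = dga_config(..., distributed = FALSE))
  .run_engine(instance, cfg, method = paste0("dga-", which))
}

#' Solve a patient-assignment instance
#'
#' Common front end over all algorithms in the package. The default method
#' is the distributed genetic algorithm; the default evaluation budget is
#' `n_patients * n_doctors`, the benchmark convention shared by every
#' algorithm here so comparisons are budget-fair.
#'
#' @param instance a [pa_instance()].
#' @param method one of `"dga"`, `"ga"`, `"random"`, `"greedy"`, `"de"`,
#'   `"dga-no-crossover"`, `"dga-no-mutation"`, `"dga-no-distributed"`.
#' @param max_evals fitness-evaluation budget (ignored by `"greedy"`).
#' @param seed integer seed (ignored by `"greedy"`).
#' @param ... further arguments for the chosen algorithm ([dga_config()]
#'   fields for the GA family; `np`, `f`, `cr` for `"de"`).
#' @return An object of class `pa_fit`; see [run_dga()] for its fields.
#'   Methods: [print()], [summary()], [coef()] (the assignment), [fitted()]
#'   (per-doctor loads), [residuals()] (load minus mean load), [plot()]
#'   (convergence or load profile), [simulate()] (re-runs under fresh seeds).
#' @examples
#' inst <- generate_instance(50, 5, seed = 1)
#' fit <- assign_patients(inst, "dga", seed = 3)
#' fit
#' coef(fit)[1:10]
#' @export
assign_patients <- function(instance,
                            method = c("dga", "ga", "random", "greedy", "de",
                                       "dga-no-crossover", "dga-no-mutation",
                                       "dga-no-distributed"),
                            max_evals = instance$n_patients * instance$n_doctors,
                            seed = 1L, ...) {
  stopifnot(inherits(instance, "pa_instance"))
  method <- match.arg(method)
  switch(method,
    dga = run_dga(instance, dga_config(max_evals = max_evals, seed = seed, ...)),
    ga = run_ga(instance, max_evals = max_evals, seed = seed, ...),
    random = run_random(instance, max_evals = max_evals, seed = seed),
    greedy = run_greedy(instance),
    de = run_de(instance, max_evals = max_evals, seed = seed, ...),
    `dga-no-crossover` = run_variant(instance, "no-crossover",
                                     max_evals = max_evals, seed = seed, ...),
    `dga-no-mutation` = run_variant(instance, "no-mutation",
                                    max_evals = max_evals, seed = seed, ...),
    `dga-no-distributed` = run_variant(instance, "no-distributed",
                                       max_evals = max_evals, seed = seed, ...))
}
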