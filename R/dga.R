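#' Configuration of the distributed genetic algorithm
#'
#' Defaults follow the benchmark settings: sub-population size 20, 4
#' sub-populations, mutation rate 0.1, migration every 5 generations, and an
#' evaluation budget of `n_patients * n_doctors` (supplied per run). The
#' three switches turn individual components off for ablation studies;
#' with `distributed = FALSE` a single panmictic population of size
#' `sps * nsp` evolves with no migration (the plain GA baseline).
#'
#' @param max_evals fitness-evaluation budget (the termination criterion);
#'   must cover at least the initial population (`sps * nsp`).
#' @param sps sub-population size (>= 2).
#' @param nsp number of sub-populations (>= 1).
#' @param mr per-gene mutation rate in `[0, 1]`.
#' @param mi migration interval in generations (>= 1).
#' @param crossover,mutation,distributed component switches.
#' @param seed integer seed; all randomness of a run flows from it.
#' @return An object of class `dga_config`.
#' @examples
#' dga_config(max_evals = 1000)
#' @export
dga_config <- function(max_evals, sps = 20L, nsp = 4L, mr = 0.1, mi = 5L,
                       crossover = TRUE, mutation = TRUE, distributed = TRUE,
                       seed = 1L) {
  sps <- as.integer(sps); nsp <- as.integer(nsp); mi <- as.integer(mi)
  max_evals <- as.integer(max_evals); seed <- as.integer(seed)
  if (is.na(sps) || sps < 2L) .stopf("`sps` must be an integer >= 2")
  if (is.na(nsp) || nsp < 1L) .stopf("`nsp` must be an integer >= 1")
  if (is.na(mi) || mi < 1L) .stopf("`mi` must be an integer >= 1")
  if (!is.numeric(mr) || mr < 0 || mr > 1) .stopf("`mr` must lie in [0, 1]")
  if (is.na(max_evals) || max_evals < sps * nsp)
    .stopf("`max_evals` (%d) must cover the initial population (sps * nsp = %d)",
           max_evals, sps * nsp)
  structure(list(sps = sps, nsp = nsp, mr = mr, mi = mi, max_evals = max_evals,
                 crossover = isTRUE(crossover), mutation = isTRUE(mutation),
                 distributed = isTRUE(distributed), seed = seed),
            class = "dga_config")
}

#' @export
print.dga_config <- function(x, ...) {
  cat(sprintf(
    "dga_config: SPS=%d NSP=%d MR=%g MI=%d budget=%d seed=%d%s\n",
    x$sps, x$nsp, x$mr, x$mi, x$max_evals, x$seed,
    paste0(c(""[x$crossover], " no-crossover"[!x$crossover],
             " no-mutation"[!x$mutation], " no-distributed"[!x$distributed]),
           collapse = "")))
  invisible(x)
}

#' Run the distributed genetic algorithm
#'
#' Evolves `nsp` sub-populations of `sps` feasible assignments. Each
#' generation pairs the members of every sub-population at random; each pair
#' produces one child by uniform crossover and candidate-list mutation, which
#' replaces the worse parent iff strictly better (family selection). Every
#' `mi` generations the best member of each sub-population migrates to its
#' ring neighbour, overwriting a random non-best member of the receiver. The
#' run terminates when `max_evals` fitness evaluations (including the initial
#' population) have been consumed; a generation in progress keeps its partial
#' results.
#'
#' Determinism: each sub-population owns an RNG stream derived from
#' `config$seed`, sub-populations are stepped in index order, and migrations
#' are applied in receiver index order, so identical configurations give
#' identical results.
#'
#' @param instance a [pa_instance()].
#' @param config a [dga_config()].
#' @param keep_population also return the final sub-populations (for
#'   diagnostics).
#' @return A [pa_fit] object: list with `method`, `genes` (best assignment),
#'   `tf` (its time factor), `loads`, `trajectory` (two-column matrix of
#'   evaluation counts and best-so-far TF at each improvement), `evals_used`,
#'   `generations`, `instance`, `config`.
#' @examples
#' inst <- generate_instance(30, 3, seed = 1)
#' fit <- run_dga(inst, dga_config(max_evals = 300, seed = 7))
#' fit$tf
#' @seealso [assign_patients()] for the common front end.
#' @export
run_dga <- function(instance, config, keep_population = FALSE) {
  stopifnot(inherits(instance, "pa_instance"), inherits(config, "dga_config"))
  .run_engine(instance, config, keep_population = keep_population,
              method = if (config$distributed) "dga" else "ga")
}

.run_engine <- function(instance, config, keep_population = FALSE, method = "dga") {
  nP <- instance$n_patients
  nD <- instance$n_doctors
  est <- instance$est_time
  cf <- .cand_flat(instance)
  npop <- if (config$distributed) config$nsp else 1L
  psize <- if (config$distributed) config$sps else config$sps * config$nsp
  max_evals <- config$max_evals

  old <- .rng_snapshot()
  on.exit(.rng_restore(old))
  streams <- lapply(seq_len(npop), function(p)
    .rng_state(derive_seed(config$seed, "subpop", p)))

  evals <- 0L
  best_tf <- Inf
  best_genes <- NULL
  tr_e <- integer(256L); tr_f <- numeric(256L); tn <- 0L
  note <- function(e, f) {
    tn <<- tn + 1L
    if (tn > length(tr_e)) {
      tr_e <<- c(tr_e, integer(length(tr_e)))
      tr_f <<- c(tr_f, numeric(length(tr_f)))
    }
    tr_e[tn] <<- e; tr_f[tn] <<- f
  }

  pops <- vector("list", npop)
  tfs <- vector("list", npop)
  for (p in seq_len(npop)) {
    .rng_use(streams[[p]])
    G <- matrix(0L, nP, psize)
    if (instance$all_doctors) {
      G[] <- sample.int(nD, nP * psize, replace = TRUE)
    } else {
      for (i in seq_len(nP)) {
        cd <- instance$candidates[[i]]
        G[i, ] <- cd[sample.int(length(cd), psize, replace = TRUE)]
      }
    }
    streams[[p]] <- .rng_current()
    f <- numeric(psize)
    for (m in seq_len(psize)) {
      f[m] <- cpp_tf(est, G[, m], nD)
      evals <- evals + 1L
      if (f[m] < best_tf) {
        best_tf <- f[m]; best_genes <- G[, m]
        note(evals, f[m])
      }
    }
    pops[[p]] <- G
    tfs[[p]] <- f
  }

  g <- 0L
  while (evals < max_evals) {
    g <- g + 1L
    for (p in seq_len(npop)) {
      left <- max_evals - evals
      if (left <= 0L) break
      .rng_use(streams[[p]])
      perm <- sample.int(psize)
      res <- cpp_evolve_pairs(pops[[p]], tfs[[p]], perm, est, nD, config$mr,
                              config$crossover, config$mutation,
                              cf$flat, cf$off, instance$all_doctors,
                              left, best_tf)
      streams[[p]] <- .rng_current()
      pops[[p]] <- res$pop
      tfs[[p]] <- res$tf
      if (length(res$imp_eval)) {
        for (k in seq_along(res$imp_eval))
          note(evals + res$imp_eval[k], res$imp_tf[k])
        best_tf <- res$imp_tf[length(res$imp_tf)]
        best_genes <- res$best_genes
      }
      evals <- evals + res$evals
    }
    if (evals >= max_evals) break
    if (config$distributed && npop > 1L && g %% config$mi == 0L) {
      bests <- vapply(tfs, which.min, 0L)
      elite_g <- lapply(seq_len(npop), function(p) pops[[p]][, bests[p]])
      elite_f <- vapply(seq_len(npop), function(p) tfs[[p]][bests[p]], 0)
      for (q in seq_len(npop)) {
        s <- if (q == 1L) npop else q - 1L
        .rng_use(streams[[q]])
        pool <- setdiff(seq_len(psize), bests[q])
        victim <- pool[sample.int(length(pool), 1L)]
        streams[[q]] <- .rng_current()
        pops[[q]][, victim] <- elite_g[[s]]
        tfs[[q]][victim] <- elite_f[s]
      }
    }
  }

  out <- structure(
    list(method = method, genes = best_genes, tf = best_tf,
         loads = cpp_loads(est, best_genes, nD),
         trajectory = cbind(evals = tr_e[seq_len(tn)], tf = tr_f[seq_len(tn)]),
         evals_used = evals, generations = g,
         instance = instance, config = config, seed = config$seed),
    class = "pa_fit")
  if (keep_population)
    out$population <- lapply(seq_len(npop), function(p)
      structure(list(genes = pops[[p]], tf = tfs[[p]], generation = g),
                class = "pa_population"))
  out
}
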