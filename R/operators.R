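# Genetic operators. The exported functions are the reference, validated
# building blocks operating through R's global RNG (wrap with set.seed() for
# reproducibility). run_dga() drives the same semantics through the compiled
# kernel with explicit per-sub-population RNG streams.

#' Initialise a random population
#'
#' Each member's gene for patient `i` is drawn uniformly from that patient's
#' candidate set, so every member is feasible by construction; all members
#' are evaluated.
#'
#' @param instance a [pa_instance()].
#' @param size population size, at least 2.
#' @return An object of class `pa_population`: a list with `genes` (an
#'   `n_patients x size` integer matrix, members in columns), `tf` (numeric
#'   vector of member time factors) and `generation` (0).
#' @examples
#' set.seed(1)
#' pop <- init_population(generate_instance(20, 4, seed = 1), 10)
#' @export
init_population <- function(instance, size) {
  stopifnot(inherits(instance, "pa_instance"))
  size <- as.integer(size)
  if (size < 2L) .stopf("population size must be at least 2")
  nP <- instance$n_patients
  G <- matrix(0L, nP, size)
  if (instance$all_doctors) {
    G[] <- sample.int(instance$n_doctors, nP * size, replace = TRUE)
  } else {
    for (i in seq_len(nP)) {
      cd <- instance$candidates[[i]]
      G[i, ] <- cd[sample.int(length(cd), size, replace = TRUE)]
    }
  }
  tf <- vapply(seq_len(size), function(m)
    cpp_tf(instance$est_time, G[, m], instance$n_doctors), 0)
  structure(list(genes = G, tf = tf, generation = 0L), class = "pa_population")
}

#' @export
print.pa_population <- function(x, ...) {
  cat(sprintf("pa_population: %d members, %d genes, generation %d\n",
              ncol(x$genes), nrow(x$genes), x$generation))
  cat(sprintf("  TF: best %.4g, median %.4g, worst %.4g\n",
              min(x$tf), median(x$tf), max(x$tf)))
  invisible(x)
}

#' Uniform crossover of two assignments
#'
#' Each gene of the child is copied from either parent with probability 1/2,
#' independently per gene. Because both parents are feasible, the child is
#' feasible by construction.
#'
#' @param p1,p2 integer vectors of equal length (doctor indices).
#' @return The child assignment.
#' @examples
#' set.seed(1)
#' uniform_crossover(c(1, 1, 1, 1), c(2, 2, 2, 2))
#' @export
uniform_crossover <- function(p1, p2) {
  if (length(p1) != length(p2))
    .stopf("parents differ in length (%d vs %d)", length(p1), length(p2))
  mask <- runif(length(p1)) < 0.5
  child <- p1
  child[mask] <- p2[mask]
  child
}

#' Candidate-list mutation
#'
#' Independently with probability `mr`, each gene is resampled uniformly from
#' the patient's candidate set excluding its current value; genes whose
#' candidate set is a singleton are never changed. The result is always
#' feasible.
#'
#' @param genes a feasible assignment for `instance`.
#' @param instance a [pa_instance()].
#' @param mr mutation rate in `[0, 1]`.
#' @return The mutated assignment.
#' @examples
#' set.seed(1)
#' mutate_genes(c(1, 1, 1), generate_instance(3, 4, seed = 1), mr = 1)
#' @export
mutate_genes <- function(genes, instance, mr) {
  stopifnot(inherits(instance, "pa_instance"))
  if (mr < 0 || mr > 1) .stopf("`mr` must lie in [0, 1]")
  .assert_feasible(instance, genes)
  genes <- as.integer(genes)
  hit <- which(runif(length(genes)) < mr)
  if (!length(hit)) return(genes)
  nD <- instance$n_doctors
  if (instance$all_doctors) {
    if (nD > 1L) {
      cur <- genes[hit]
      r <- sample.int(nD - 1L, length(hit), replace = TRUE)
      r <- r + (r >= cur)
      genes[hit] <- r
    }
  } else {
    for (i in hit) {
      alt <- setdiff(instance$candidates[[i]], genes[i])
      if (length(alt)) genes[i] <- alt[sample.int(length(alt), 1L)]
    }
  }
  genes
}

# Family selection: given parent TFs and the child's TF, which parent (1 or
# 2) is replaced? 0 = child discarded. Strictly better than the worse parent
# wins; ties keep the incumbent; a parent tie treats the first as worse.
.family_replace <- function(f1, f2, fc) {
  worse <- if (f1 >= f2) 1L else 2L
  if (fc < max(f1, f2)) worse else 0L
}

#' Evolve a population by one generation
#'
#' Members are paired by a uniform random perfect matching (one member idles
#' when the size is odd). Each pair produces one child: uniform crossover
#' (when `crossover = TRUE`, otherwise a copy of a uniformly chosen parent),
#' then candidate-list mutation at rate `mr` (when `mutation = TRUE`). The
#' child is evaluated and replaces the worse parent iff its TF is strictly
#' lower (family selection), so the population's best TF never worsens.
#'
#' @param pop a `pa_population` from [init_population()].
#' @param instance the [pa_instance()] the population belongs to.
#' @param mr mutation rate.
#' @param crossover,mutation operator switches (ablation studies).
#' @param budget maximum number of child evaluations to spend this
#'   generation; the generation stops early (keeping partial results) once
#'   exhausted.
#' @return The updated `pa_population`, with `generation` incremented and an
#'   attribute `"evals"` holding the number of evaluations consumed.
#' @examples
#' inst <- generate_instance(20, 4, seed = 1)
#' set.seed(2)
#' pop <- init_population(inst, 10)
#' pop2 <- evolve_generation(pop, inst)
#' min(pop2$tf) <= min(pop$tf)
#' @export
evolve_generation <- function(pop, instance, mr = 0.1, crossover = TRUE,
                              mutation = TRUE, budget = Inf) {
  stopifnot(inherits(pop, "pa_population"), inherits(instance, "pa_instance"))
  psize <- ncol(pop$genes)
  cf <- .cand_flat(instance)
  perm <- sample.int(psize)
  res <- cpp_evolve_pairs(pop$genes, pop$tf, perm,
                          instance$est_time, instance$n_doctors, mr,
                          crossover, mutation, cf$flat, cf$off,
                          instance$all_doctors,
                          as.integer(min(budget, psize %/% 2L)), min(pop$tf))
  structure(list(genes = res$pop, tf = res$tf, generation = pop$generation + 1L),
            class = "pa_population", evals = res$evals)
}

#' Ring-topology elite migration
#'
#' Sub-population `p` sends a copy of its best member (lowest TF, ties broken
#' by lowest index) to sub-population `p + 1` (wrapping around). In each
#' receiver, a uniformly chosen member other than the receiver's own current
#' best is overwritten by the incoming copy; fitness travels with the migrant
#' so no evaluations are consumed. All bests are snapshotted before any
#' replacement, and replacements are applied in sub-population index order.
#' A single sub-population is returned unchanged.
#'
#' @param subpops a list of `pa_population` objects.
#' @return The list after migration (member counts unchanged).
#' @examples
#' inst <- generate_instance(10, 3, seed = 1)
#' set.seed(1)
#' pops <- list(init_population(inst, 6), init_population(inst, 6))
#' pops <- ring_migration(pops)
#' @export
ring_migration <- function(subpops) {
  if (!length(subpops) || !all(vapply(subpops, inherits, TRUE, "pa_population")))
    .stopf("`subpops` must be a list of pa_population objects")
  npop <- length(subpops)
  if (npop < 2L) return(subpops)
  bests <- vapply(subpops, function(p) which.min(p$tf), 0L)
  elite_g <- lapply(seq_len(npop), function(p) subpops[[p]]$genes[, bests[p]])
  elite_f <- vapply(seq_len(npop), function(p) subpops[[p]]$tf[bests[p]], 0)
  for (q in seq_len(npop)) {
    s <- if (q == 1L) npop else q - 1L
    pool <- setdiff(seq_len(ncol(subpops[[q]]$genes)), bests[q])
    victim <- pool[sample.int(length(pool), 1L)]
    subpops[[q]]$genes[, victim] <- elite_g[[s]]
    subpops[[q]]$tf[victim] <- elite_f[s]
  }
  subpops
}
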