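test_that("population initialisation is feasible, sized and seeded", {
  inst <- generate_instance(25, 4, seed = 1)
  set.seed(5)
  pop <- init_population(inst, 20)
  expect_equal(ncol(pop$genes), 20L)
  expect_equal(pop$generation, 0L)
  for (m in 1:20) {
    expect_true(is_feasible(inst, pop$genes[, m]))
    expect_equal(pop$tf[m], time_factor(inst, pop$genes[, m]))
  }
  set.seed(5)
  expect_identical(init_population(inst, 20)$genes, pop$genes)

  # singleton candidate sets force the unique feasible solution
  forced <- generate_instance(10, 5, candidate_mode = "fixed-k", k = 1, seed = 2)
  set.seed(1)
  fp <- init_population(forced, 6)
  expect_true(all(fp$genes == fp$genes[, 1]))

  expect_error(init_population(inst, 1), "at least 2")
})

test_that("uniform crossover mixes parents gene-wise at rate one half", {
  expect_identical(uniform_crossover(c(2L, 3L, 1L), c(2L, 3L, 1L)), c(2L, 3L, 1L))
  expect_error(uniform_crossover(1:3, 1:4), "length")

  p1 <- rep(1L, 50); p2 <- rep(2L, 50)
  set.seed(42)
  from_p1 <- 0; n_trials <- 10000
  for (t in seq_len(n_trials)) {
    child <- uniform_crossover(p1, p2)
    expect_true(all(child %in% c(1L, 2L)))
    from_p1 <- from_p1 + sum(child == 1L)
  }
  frac <- from_p1 / (n_trials * 50)
  expect_gte(frac, 0.47)
  expect_lte(frac, 0.53)
})

test_that("mutation resamples within candidate sets, excluding the current value", {
  inst <- generate_instance(40, 6, seed = 3)
  g <- random_feasible(inst, seed = 1)
  set.seed(2)
  expect_identical(mutate_genes(g, inst, mr = 0), g)

  # mr = 1 with 2-entry candidate sets flips every gene to its alternative
  two <- generate_instance(30, 5, candidate_mode = "fixed-k", k = 2, seed = 4)
  gt <- random_feasible(two, seed = 2)
  set.seed(3)
  flipped <- mutate_genes(gt, two, mr = 1)
  for (i in seq_along(gt)) {
    expect_equal(flipped[i], setdiff(two$candidates[[i]], gt[i]))
  }

  # all-doctors: mr = 1 changes every gene (nD > 1) and stays in range
  set.seed(4)
  m <- mutate_genes(g, inst, mr = 1)
  expect_true(all(m != g))
  expect_true(is_feasible(inst, m))

  # singleton sets are never altered
  forced <- generate_instance(10, 4, candidate_mode = "fixed-k", k = 1, seed = 5)
  gf <- random_feasible(forced, seed = 3)
  set.seed(5)
  expect_identical(mutate_genes(gf, forced, mr = 1), gf)

  expect_error(mutate_genes(g, inst, mr = 2), "0, 1")
})

test_that("family selection replaces the worse parent only on strict improvement", {
  fr <- pabalance:::.family_replace
  expect_equal(fr(6, 10, 8), 2L)   # worse parent (TF 10) replaced
  expect_equal(fr(10, 6, 8), 1L)
  expect_equal(fr(6, 10, 12), 0L)  # worse than both: discarded
  expect_equal(fr(6, 10, 10), 0L)  # tie with worse parent: incumbent kept
  expect_equal(fr(6, 10, 5), 2L)   # better than both: still one replacement
})

test_that("one generation never worsens the best member", {
  inst <- generate_instance(30, 4, seed = 6)
  for (s in 1:100) {
    set.seed(s)
    pop <- init_population(inst, 10)
    pop2 <- evolve_generation(pop, inst, mr = 0.1)
    expect_lte(min(pop2$tf), min(pop$tf))
    expect_equal(pop2$generation, 1L)
    expect_lte(attr(pop2, "evals"), 5L)
  }
})

test_that("degenerate generations behave as documented", {
  inst <- generate_instance(20, 3, seed = 7)
  set.seed(1)
  pop <- init_population(inst, 8)
  # both operators off: children are parent copies, so no new genotypes can
  # appear (a copy of the better parent may displace the worse one) and the
  # best TF cannot change
  off <- evolve_generation(pop, inst, crossover = FALSE, mutation = FALSE)
  expect_true(all(off$tf %in% pop$tf))
  for (m in seq_len(ncol(off$genes)))
    expect_true(any(apply(pop$genes, 2, identical, off$genes[, m])))
  expect_equal(min(off$tf), min(pop$tf))
  expect_equal(attr(off, "evals"), 4L)

  # two-member population: one pair, at most one evaluation
  set.seed(2)
  tiny <- init_population(inst, 2)
  g1 <- evolve_generation(tiny, inst)
  expect_lte(attr(g1, "evals"), 1L)

  # zero budget: nothing happens
  zero <- evolve_generation(pop, inst, budget = 0)
  expect_identical(zero$genes, pop$genes)
  expect_equal(attr(zero, "evals"), 0L)
})

test_that("ring migration copies each best to its neighbour and keeps sizes", {
  inst <- generate_instance(15, 3, seed = 8)
  set.seed(9)
  pops <- lapply(1:3, function(p) init_population(inst, 6))

  one <- ring_migration(pops[1])
  expect_identical(one, pops[1])

  two <- pops[1:2]
  b1 <- two[[1]]$genes[, which.min(two[[1]]$tf)]
  b2 <- two[[2]]$genes[, which.min(two[[2]]$tf)]
  after <- ring_migration(two)
  expect_true(any(apply(after[[2]]$genes, 2, identical, b1)))
  expect_true(any(apply(after[[1]]$genes, 2, identical, b2)))
  # original bests survive (the receiver's best is protected)
  expect_true(any(apply(after[[1]]$genes, 2, identical, b1)))
  expect_true(any(apply(after[[2]]$genes, 2, identical, b2)))
  expect_true(all(vapply(after, function(p) ncol(p$genes), 0L) == 6L))

  # fitness travels with the migrant
  after3 <- ring_migration(pops)
  for (p in 1:3)
    for (m in 1:6)
      expect_equal(after3[[p]]$tf[m], time_factor(inst, after3[[p]]$genes[, m]))
})
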