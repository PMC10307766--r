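test_that("repeated runs summarise deterministically", {
  inst <- generate_instance(15, 3, seed = 1)
  rr <- repeat_runs(inst, "random", n_runs = 5, base_seed = 3, max_evals = 60)
  expect_length(rr$tf, 5L)
  expect_equal(rr$mean, mean(rr$tf))
  expect_equal(rr$sd, sd(rr$tf))
  expect_identical(
    rr$tf,
    repeat_runs(inst, "random", n_runs = 5, base_seed = 3, max_evals = 60)$tf)
  expect_false(identical(
    rr$tf,
    repeat_runs(inst, "random", n_runs = 5, base_seed = 4, max_evals = 60)$tf))

  single <- repeat_runs(inst, "dga", n_runs = 1, base_seed = 1, max_evals = 120)
  expect_equal(single$sd, 0)
  expect_equal(single$mean, single$tf)

  one_doc <- repeat_runs(generate_instance(10, 1, seed = 2), "random",
                         n_runs = 3, base_seed = 1, max_evals = 10)
  expect_equal(one_doc$mean, 0)
  expect_equal(one_doc$sd, 0)
})

test_that("rank-sum comparison matches the exhaustive enumeration oracle", {
  res <- rank_sum_compare(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, rank_sum_exact_oracle(c(1, 2, 3), c(10, 11, 12)))
  expect_false(res$significant)
  expect_equal(res$direction, -1)

  set.seed(1)
  for (rep in 1:20) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    a <- round(runif(n1, 0, 100), 3); b <- round(runif(n2, 50, 150), 3)
    if (n1 + n2 <= 12)
      expect_equal(rank_sum_compare(a, b)$p_value, rank_sum_exact_oracle(a, b),
                   tolerance = 1e-12)
  }

  same <- rank_sum_compare(c(1, 2, 3), c(1, 2, 3))
  expect_false(same$significant)
  expect_equal(rank_sum_compare(rep(2, 5), rep(2, 4))$p_value, 1)
  expect_error(rank_sum_compare(1, c(1, 2)), "at least 2")
})

test_that("exact and approximate rank-sum p-values agree for moderate samples", {
  set.seed(2)
  for (rep in 1:100) {
    a <- runif(6); b <- runif(6)
    p_exact <- rank_sum_exact_oracle(a, b)
    p_norm <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    expect_lte(abs(p_exact - p_norm), 0.05)
  }
})

test_that("clearly separated samples are detected as significant", {
  set.seed(3)
  hits <- 0L
  for (rep in 1:200) {
    a <- rnorm(25, 0, 1)
    b <- rnorm(25, 5, 1) # separation of 5 pooled standard deviations
    cmp <- rank_sum_compare(a, b)
    if (cmp$significant && cmp$direction == -1) hits <- hits + 1L
  }
  expect_gte(hits, 198L)
})

test_that("summary tables flag the best algorithm and significance", {
  mk_runs <- function(id, method, tf) {
    structure(list(instance_id = id, method = method, n_runs = length(tf),
                   tf = tf, mean = mean(tf), sd = sd(tf),
                   seeds = seq_along(tf), evals_used = rep(1L, length(tf)),
                   trajectories = lapply(tf, function(f) cbind(evals = 1, tf = f))),
              class = "pa_runs")
  }
  # one dominant algorithm: bolded and marked in every row
  res <- list()
  for (id in c("A", "B")) {
    res <- c(res, list(mk_runs(id, "good", c(1, 1.1, 0.9, 1.2, 1.05)),
                       mk_runs(id, "bad", c(9, 9.1, 8.9, 9.2, 9.05))))
  }
  tab <- build_table(res)
  expect_equal(tab$summary$best, c("good", "good"))
  expect_true(all(tab$summary$significant))
  expect_match(tab$markdown[3], "\\*\\*.*\\*\\*†")

  # identical samples: best by tie-break but unmarked
  res2 <- list(mk_runs("A", "x", c(1, 2, 3)), mk_runs("A", "y", c(1, 2, 3)))
  tab2 <- build_table(res2)
  expect_false(any(tab2$summary$significant))

  # single algorithm: trivially best, no mark
  tab3 <- build_table(list(mk_runs("A", "only", c(1, 2, 3))))
  expect_equal(tab3$summary$best, "only")
  expect_false(tab3$summary$significant)

  # missing cell: explicit gap, no silent omission
  tab4 <- build_table(list(mk_runs("A", "x", 1:3), mk_runs("B", "x", 1:3),
                           mk_runs("A", "y", 4:6)))
  expect_true(is.na(tab4$summary$y_avg[2]))
  expect_match(tab4$markdown[4], "--")
})

test_that("convergence curves align by carrying the last observation forward", {
  mk_runs <- function(method, trajs) {
    structure(list(instance_id = "A", method = method, n_runs = length(trajs),
                   tf = vapply(trajs, function(tr)
                     if (nrow(tr)) tr[nrow(tr), 2] else NA_real_, 0),
                   mean = 0, sd = 0, seeds = seq_along(trajs),
                   evals_used = rep(1L, length(trajs)), trajectories = trajs),
              class = "pa_runs")
  }
  single <- mk_runs("m", list(cbind(evals = c(1, 5, 9), tf = c(10, 6, 2))))
  rep1 <- convergence_report(list(single))
  expect_equal(rep1$evals, c(1, 5, 9))
  expect_equal(rep1$m, c(10, 6, 2))

  # identical runs have zero spread
  twin <- mk_runs("m", rep(list(cbind(evals = c(2, 4), tf = c(8, 3))), 3))
  rep2 <- convergence_report(list(twin))
  expect_equal(rep2$m, c(8, 3))

  # mean of monotone step functions is monotone
  set.seed(4)
  for (rep in 1:100) {
    trajs <- lapply(1:3, function(i) {
      n <- sample(2:6, 1)
      cbind(evals = sort(sample.int(50, n)), tf = sort(runif(n, 0, 20), decreasing = TRUE))
    })
    curve <- convergence_report(list(mk_runs("m", trajs)))$m
    expect_true(all(diff(curve) <= 1e-12))
  }

  bad <- mk_runs("m", list(cbind(evals = numeric(0), tf = numeric(0))))
  expect_error(convergence_report(list(bad)), "empty trajectory")
})

test_that("a full experiment is reproducible and writes its reports", {
  suite <- table1_suite(1)[1, ]
  suite$n_patients <- 20L; suite$n_doctors <- 4L # desk-scale smoke test
  out <- withr::local_tempdir()
  ex <- pa_experiment(suite, methods = c("random", "greedy"), n_runs = 3,
                      base_seed = 5, out_dir = out)
  expect_s3_class(ex$table, "pa_table")
  expect_true(file.exists(file.path(out, "summary.tsv")))
  expect_true(file.exists(file.path(out, "summary.md")))
  runs <- read.delim(file.path(out, "runs.tsv"))
  expect_equal(nrow(runs), 4L) # 3 random + 1 greedy
  ex2 <- pa_experiment(suite, methods = c("random", "greedy"), n_runs = 3,
                       base_seed = 5)
  expect_identical(ex$table$summary, ex2$table$summary)
})
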