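test_that("generated instances respect the spec and are reproducible", {
  inst <- generate_instance(100, 10, c(5, 20), seed = 1)
  expect_equal(inst$n_patients, 100L)
  expect_equal(inst$n_doctors, 10L)
  expect_true(all(inst$est_time >= 5 & inst$est_time <= 20))
  expect_true(inst$all_doctors)

  expect_identical(generate_instance(50, 5, seed = 7)$est_time,
                   generate_instance(50, 5, seed = 7)$est_time)

  # bounds hold for every seed tested
  for (s in 1:20) {
    e <- generate_instance(40, 4, c(2, 9), seed = s)$est_time
    expect_gte(min(e), 2)
    expect_lte(max(e), 9)
  }

  ik <- generate_instance(30, 6, candidate_mode = "fixed-k", k = 3, seed = 2)
  expect_false(ik$all_doctors)
  expect_true(all(lengths(ik$candidates) == 3))
  # k = nD collapses to the all-doctors representation
  expect_true(generate_instance(10, 4, candidate_mode = "fixed-k", k = 4, seed = 3)$all_doctors)

  ii <- generate_instance(200, 5, integer_times = TRUE, seed = 4)
  expect_true(all(ii$est_time == round(ii$est_time)))

  expect_error(generate_instance(10, 5, c(20, 5)), "t_min")
  expect_error(generate_instance(10, 5, candidate_mode = "fixed-k", k = 9), "1..n_doctors")
  expect_error(generate_instance(0, 5), "positive")
})

test_that("empirical mean of generated times is near the interval midpoint", {
  hits <- 0L
  for (s in 1:100) {
    m <- mean(generate_instance(400, 10, c(5, 20), seed = 1000 + s)$est_time)
    if (abs(m - 12.5) <= 0.05 * 12.5) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("the benchmark suite covers the full size grid", {
  suite <- table1_suite(1)
  expect_equal(nrow(suite), 16L)
  expect_setequal(
    paste(suite$n_patients, suite$n_doctors),
    paste(rep(c(100, 200, 300, 400), each = 4), rep(c(10, 20, 30, 40), 4)))
  expect_equal(suite$n_patients[1], 100L)
  expect_equal(suite$n_doctors[1], 10L)
  expect_equal(suite$n_patients[16], 400L)
  expect_equal(suite$n_doctors[16], 40L)
  expect_true(all(suite$t_min == 5) && all(suite$t_max == 20))
  expect_identical(table1_suite(9), table1_suite(9))
  expect_false(identical(table1_suite(1)$seed, table1_suite(2)$seed))

  insts <- generate_suite(suite[c(1, 16), ])
  expect_named(insts, c("T1", "T16"))
  expect_equal(insts$T16$n_patients, 400L)
})

test_that("instance files round-trip bit-exactly", {
  for (s in 1:20) {
    inst <- if (s %% 2 == 0)
      generate_instance(sample(2:40, 1), sample(2:8, 1), seed = s)
    else
      generate_instance(sample(2:40, 1), sample(2:8, 1),
                        candidate_mode = "fixed-k", k = 2, seed = s)
    path <- withr::local_tempfile(fileext = ".pa")
    write_instance(inst, path)
    back <- read_instance(path)
    expect_identical(back$est_time, inst$est_time)
    expect_identical(back$n_doctors, inst$n_doctors)
    expect_identical(back$candidates, inst$candidates)
    expect_identical(back$all_doctors, inst$all_doctors)
  }
})

test_that("malformed instance files fail with located errors", {
  path <- withr::local_tempfile(fileext = ".pa")
  inst <- generate_instance(4, 3, candidate_mode = "fixed-k", k = 2, seed = 1)
  write_instance(inst, path)
  lines <- readLines(path)

  bad <- lines
  bad[7] <- "2: 1 9" # candidate doctor out of range for patient 2
  writeLines(bad, path)
  expect_error(read_instance(path), "patient 2.*doctor 9")

  bad <- lines
  bad[4] <- sub(" [^ ]+$", "", bad[4]) # drop one est_time entry
  writeLines(bad, path)
  expect_error(read_instance(path), "3 values for 4 patients")

  writeLines(sub("^pa-instance 1", "pa-instance 2", lines), path)
  expect_error(read_instance(path), "unsupported.*version")

  writeLines(c("something else", lines[-1]), path)
  expect_error(read_instance(path), "not a pa-instance")

  writeLines(lines[1:6], path) # truncated candidate list
  expect_error(read_instance(path), "candidates list")
})

test_that("shipped example instances parse", {
  small <- read_instance(system.file("extdata", "example_small.pa", package = "pabalance"))
  expect_equal(small$n_patients, 6L)
  expect_true(small$all_doctors)
  fk <- read_instance(system.file("extdata", "example_fixed_k.pa", package = "pabalance"))
  expect_equal(fk$n_doctors, 5L)
  expect_true(all(lengths(fk$candidates) == 3))
})
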