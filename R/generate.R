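#' Generate a synthetic benchmark instance
#'
#' Draws estimated diagnosis times independently and uniformly from
#' `t_range` (real-valued by default; `integer_times = TRUE` draws from the
#' integer grid instead) and builds candidate-doctor lists. The default
#' candidate mode makes every doctor available to every patient — the
#' least-parameterised assumption for benchmark suites that specify only a
#' time range; `"fixed-k"` draws a uniform random `k`-subset of doctors per
#' patient, emulating short candidature lists from a triage step.
#'
#' Identical arguments (including `seed`) always produce the identical
#' instance; the caller's RNG state is left untouched.
#'
#' @param n_patients,n_doctors positive integers.
#' @param t_range length-2 numeric, `0 < t_range[1] <= t_range[2]`, the range
#'   of estimated diagnosis times in minutes.
#' @param candidate_mode `"all"` or `"fixed-k"`.
#' @param k candidate-list size in `"fixed-k"` mode, `1 <= k <= n_doctors`.
#' @param integer_times draw times from `t_range[1]:t_range[2]` instead of
#'   the continuous interval.
#' @param seed integer seed; `NULL` uses (and advances) the current RNG.
#' @return A [pa_instance()] whose `spec` field records these arguments.
#' @examples
#' inst <- generate_instance(100, 10, seed = 1)
#' range(inst$est_time)
#' @export
generate_instance <- function(n_patients, n_doctors, t_range = c(5, 20),
                              candidate_mode = c("all", "fixed-k"), k = n_doctors,
                              integer_times = FALSE, seed = NULL) {
  candidate_mode <- match.arg(candidate_mode)
  n_patients <- as.integer(n_patients); n_doctors <- as.integer(n_doctors)
  if (n_patients < 1L || n_doctors < 1L)
    .stopf("`n_patients` and `n_doctors` must be positive")
  if (length(t_range) != 2L || !is.numeric(t_range) ||
      t_range[1] <= 0 || t_range[1] > t_range[2])
    .stopf("`t_range` must satisfy 0 < t_min <= t_max")
  k <- as.integer(k)
  if (candidate_mode == "fixed-k" && (k < 1L || k > n_doctors))
    .stopf("`k` must lie in 1..n_doctors")
  if (!is.null(seed)) {
    old <- .rng_snapshot()
    on.exit(.rng_restore(old))
    set.seed(seed)
  }
  est <- if (integer_times) {
    grid <- seq(ceiling(t_range[1]), floor(t_range[2]))
    grid[sample.int(length(grid), n_patients, replace = TRUE)]
  } else {
    runif(n_patients, t_range[1], t_range[2])
  }
  cands <- NULL
  if (candidate_mode == "fixed-k" && k < n_doctors)
    cands <- replicate(n_patients, sort(sample.int(n_doctors, k)), simplify = FALSE)
  pa_instance(est, n_doctors, cands,
              spec = list(n_patients = n_patients, n_doctors = n_doctors,
                          t_min = t_range[1], t_max = t_range[2],
                          candidate_mode = candidate_mode, k = k,
                          integer_times = integer_times,
                          seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
}

#' The 16-instance benchmark suite
#'
#' Specifications of the standard benchmark: every combination of
#' `n_patients` in {100, 200, 300, 400} and `n_doctors` in {10, 20, 30, 40},
#' with diagnosis times uniform on [5, 20] minutes and all doctors available
#' to all patients. Per-instance seeds are derived deterministically from
#' `base_seed`, so the whole suite is reproducible from one integer.
#'
#' @param base_seed integer; the suite's single source of randomness.
#' @return A data frame with columns `id` (`"T1".."T16"`), `n_patients`,
#'   `n_doctors`, `t_min`, `t_max`, `seed`.
#' @examples
#' table1_suite(1)[c(1, 16), ]
#' @seealso [generate_suite()]
#' @export
table1_suite <- function(base_seed = 1L) {
  grid <- expand.grid(n_doctors = c(10L, 20L, 30L, 40L),
                      n_patients = c(100L, 200L, 300L, 400L))
  data.frame(id = paste0("T", seq_len(16L)),
             n_patients = grid$n_patients, n_doctors = grid$n_doctors,
             t_min = 5, t_max = 20,
             seed = vapply(seq_len(16L), function(i)
               derive_seed(base_seed, "instance", i), 0L),
             stringsAsFactors = FALSE)
}

#' Materialise a suite of instances
#'
#' @param suite a data frame as returned by [table1_suite()].
#' @return A named list of [pa_instance()] objects.
#' @examples
#' insts <- generate_suite(table1_suite(1)[1:2, ])
#' @export
generate_suite <- function(suite) {
  out <- lapply(seq_len(nrow(suite)), function(i)
    generate_instance(suite$n_patients[i], suite$n_doctors[i],
                      c(suite$t_min[i], suite$t_max[i]), seed = suite$seed[i]))
  names(out) <- suite$id
  out
}
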