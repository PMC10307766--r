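#' Repeat independent optimiser runs on one instance
#'
#' Runs an algorithm `n_runs` times on a fixed instance, with run seeds
#' derived deterministically from `(base_seed, instance_id, method, run)`,
#' and summarises the final time factors. The instance is held fixed across
#' runs; only the optimiser's seed varies.
#'
#' @param instance a [pa_instance()].
#' @param method algorithm name as in [assign_patients()].
#' @param n_runs number of independent runs (>= 1).
#' @param base_seed base seed for the derived run seeds.
#' @param instance_id identifier mixed into the seed derivation and reported
#'   in summaries.
#' @param ... further arguments for [assign_patients()] (e.g. `max_evals`).
#' @return An object of class `pa_runs`: list with `instance_id`, `method`,
#'   `tf` (final TF per run), `mean`, `sd` (sample standard deviation; 0 when
#'   `n_runs = 1`), `seeds`, `evals_used`, and `trajectories` (list of
#'   two-column matrices).
#' @examples
#' inst <- generate_instance(30, 3, seed = 1)
#' rr <- repeat_runs(inst, "random", n_runs = 5, base_seed = 1, max_evals = 90)
#' rr$mean
#' @export
repeat_runs <- function(instance, method, n_runs = 25L, base_seed = 1L,
                        instance_id = "I1", ...) {
  stopifnot(inherits(instance, "pa_instance"))
  n_runs <- as.integer(n_runs)
  if (n_runs < 1L) .stopf("`n_runs` must be at least 1")
  seeds <- vapply(seq_len(n_runs), function(r)
    derive_seed(base_seed, instance_id, method, r), 0L)
  fits <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    fits[[r]] <- tryCatch(
      assign_patients(instance, method, seed = seeds[r], ...),
      error = function(e) .stopf("run %d of %s on %s (seed %d) failed: %s",
                                 r, method, instance_id, seeds[r], conditionMessage(e)))
  }
  tf <- vapply(fits, `[[`, 0, "tf")
  structure(list(instance_id = instance_id, method = method, n_runs = n_runs,
                 tf = tf, mean = mean(tf), sd = if (n_runs > 1L) sd(tf) else 0,
                 seeds = seeds,
                 evals_used = vapply(fits, `[[`, 0L, "evals_used"),
                 trajectories = lapply(fits, `[[`, "trajectory")),
            class = "pa_runs")
}

#' @export
print.pa_runs <- function(x, ...) {
  cat(sprintf("pa_runs: %s on %s, %d runs\n", x$method, x$instance_id, x$n_runs))
  cat(sprintf("  final TF: mean %.4g, sd %.4g, range [%.4g, %.4g]\n",
              x$mean, x$sd, min(x$tf), max(x$tf)))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Compares two samples of final TF values. For pooled sample sizes up to 12
#' the p-value is exact (enumeration of rank assignments); larger samples,
#' or samples with ties, use the normal approximation with tie correction.
#' A degenerate pooled sample (all values equal) yields p = 1.
#'
#' @param sample_a,sample_b numeric vectors of length >= 2.
#' @param alpha significance level.
#' @return A list with `p_value`, `significant` (`p_value < alpha`) and
#'   `direction`: -1 if `sample_a`'s median is lower (better), +1 if higher,
#'   0 if equal.
#' @examples
#' rank_sum_compare(c(1, 2, 3), c(10, 11, 12))
#' @export
rank_sum_compare <- function(sample_a, sample_b, alpha = 0.05) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    .stopf("both samples need at least 2 values")
  pooled <- c(sample_a, sample_b)
  if (all(pooled == pooled[1L])) {
    p <- 1
  } else {
    p <- suppressWarnings(
      wilcox.test(sample_a, sample_b,
                  exact = length(pooled) <= 12L, correct = TRUE)$p.value)
  }
  list(p_value = p, significant = p < alpha,
       direction = sign(median(sample_a) - median(sample_b)))
}

#' Benchmark summary table
#'
#' Collates [repeat_runs()] results into a per-instance table of mean and
#' sample standard deviation of final TF per algorithm. In each row the
#' algorithm with the lowest mean is flagged as best, and marked (dagger
#' style) when its sample is significantly better than every competitor's
#' under the two-sided rank-sum test at level `alpha`. Missing
#' instance-algorithm cells appear as `NA` (rendered as an explicit gap).
#'
#' @param results a list of `pa_runs` objects (any order; grouped by their
#'   `instance_id`).
#' @param alpha significance level for the dagger mark.
#' @return An object of class `pa_table`: list with `summary` (data frame
#'   with `<method>_avg` / `<method>_sd` columns plus `best` and
#'   `significant`), `markdown` (character vector of a rendered table) and
#'   `samples` (the per-cell TF samples).
#' @examples
#' inst <- generate_instance(30, 3, seed = 1)
#' rr <- lapply(c("random", "dga"), function(m)
#'   repeat_runs(inst, m, n_runs = 5, base_seed = 1, max_evals = 90))
#' build_table(rr)
#' @export
build_table <- function(results, alpha = 0.05) {
  if (!length(results) || !all(vapply(results, inherits, TRUE, "pa_runs")))
    .stopf("`results` must be a non-empty list of pa_runs objects")
  ids <- unique(vapply(results, `[[`, "", "instance_id"))
  methods <- unique(vapply(results, `[[`, "", "method"))
  samples <- lapply(ids, function(id) {
    row <- setNames(vector("list", length(methods)), methods)
    for (r in results)
      if (r$instance_id == id) row[[r$method]] <- r$tf
    row
  })
  names(samples) <- ids

  avg <- matrix(NA_real_, length(ids), length(methods), dimnames = list(ids, methods))
  sdv <- avg
  for (r in results) {
    avg[r$instance_id, r$method] <- r$mean
    sdv[r$instance_id, r$method] <- r$sd
  }
  best <- character(length(ids))
  signif_mark <- logical(length(ids))
  for (k in seq_along(ids)) {
    present <- methods[!is.na(avg[k, ])]
    if (!length(present)) { best[k] <- NA_character_; next }
    b <- present[which.min(avg[k, present])]
    best[k] <- b
    rivals <- setdiff(present, b)
    ok <- length(rivals) > 0L
    for (m in rivals) {
      # a single-run (e.g. deterministic) cell cannot support a rank-sum test
      if (length(samples[[k]][[b]]) < 2L || length(samples[[k]][[m]]) < 2L) {
        ok <- FALSE
        break
      }
      cmp <- rank_sum_compare(samples[[k]][[b]], samples[[k]][[m]], alpha)
      if (!(cmp$significant && cmp$direction < 0)) { ok <- FALSE; break }
    }
    signif_mark[k] <- ok
  }

  df <- data.frame(instance = ids, stringsAsFactors = FALSE)
  for (m in methods) {
    df[[paste0(m, "_avg")]] <- avg[, m]
    df[[paste0(m, "_sd")]] <- sdv[, m]
  }
  df$best <- best
  df$significant <- signif_mark

  fmt_cell <- function(a, s, is_best, mark) {
    if (is.na(a)) return("--")
    txt <- sprintf("%.2f (%.2f)", a, s)
    if (is_best) txt <- paste0("**", txt, "**", if (mark) "†" else "")
    txt
  }
  md <- c(paste0("| instance | ", paste(methods, collapse = " | "), " |"),
          paste0("|", paste(rep("---", length(methods) + 1L), collapse = "|"), "|"))
  for (k in seq_along(ids)) {
    cells <- vapply(methods, function(m)
      fmt_cell(avg[k, m], sdv[k, m], identical(best[k], m), signif_mark[k]), "")
    md <- c(md, paste0("| ", ids[k], " | ", paste(cells, collapse = " | "), " |"))
  }
  structure(list(summary = df, markdown = md, samples = samples, alpha = alpha),
            class = "pa_table")
}

#' @export
print.pa_table <- function(x, ...) {
  cat(paste(x$markdown, collapse = "\n"), "\n")
  cat(sprintf("(mean (sd) of final TF; bold = lowest mean, † = significantly better than all competitors, rank-sum alpha = %g)\n",
              x$alpha))
  invisible(x)
}

#' Aligned mean convergence curves
#'
#' Step-aligns best-so-far trajectories from repeated runs on the common
#' evaluation axis (last observation carried forward; a run's first recorded
#' value is extended backwards) and averages them per algorithm.
#'
#' @param results a list of `pa_runs` objects for a single instance.
#' @return An object of class `pa_convergence`: a data frame with column
#'   `evals` and one mean best-so-far TF column per method.
#' @examples
#' inst <- generate_instance(30, 3, seed = 1)
#' rr <- lapply(c("random", "dga"), function(m)
#'   repeat_runs(inst, m, n_runs = 3, base_seed = 1, max_evals = 90))
#' head(convergence_report(rr))
#' @export
convergence_report <- function(results) {
  if (!length(results) || !all(vapply(results, inherits, TRUE, "pa_runs")))
    .stopf("`results` must be a non-empty list of pa_runs objects")
  for (r in results)
    for (k in seq_along(r$trajectories))
      if (nrow(r$trajectories[[k]]) < 1L)
        .stopf("empty trajectory in run %d of %s on %s", k, r$method, r$instance_id)
  grid <- sort(unique(unlist(lapply(results, function(r)
    lapply(r$trajectories, function(tr) tr[, "evals"])))))
  locf <- function(tr) {
    idx <- findInterval(grid, tr[, "evals"])
    out <- tr[pmax(idx, 1L), "tf"]
    out
  }
  df <- data.frame(evals = grid)
  for (r in results) {
    curves <- vapply(r$trajectories, locf, numeric(length(grid)))
    df[[r$method]] <- rowMeans(as.matrix(curves))
  }
  class(df) <- c("pa_convergence", "data.frame")
  df
}

#' Plot mean convergence curves
#'
#' @param x a `pa_convergence` from [convergence_report()].
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.pa_convergence <- function(x, ...) {
  methods <- setdiff(names(x), "evals")
  matplot(x$evals, as.matrix(x[methods]), type = "s", lty = 1,
          col = seq_along(methods),
          xlab = "fitness evaluations", ylab = "mean best-so-far TF (min)", ...)
  legend("topright", legend = methods, col = seq_along(methods), lty = 1, bty = "n")
  invisible(x)
}

#' Run a full benchmark experiment
#'
#' Generates (or accepts) a set of instances, runs every algorithm `n_runs`
#' times on each with the budget `n_patients * n_doctors`, and collates the
#' summary table. The whole experiment is a pure function of
#' `(suite/instances, methods, n_runs, base_seed)`.
#'
#' @param suite instance specifications as from [table1_suite()]; ignored
#'   when `instances` is given.
#' @param instances optional named list of [pa_instance()] objects.
#' @param methods algorithms to run (names as in [assign_patients()]).
#' @param n_runs independent runs per instance-algorithm cell.
#' @param base_seed base seed for all run-seed derivation.
#' @param out_dir optional directory; when given, `summary.tsv`,
#'   `summary.md` and `runs.tsv` (per-run seeds, evaluations and final TF)
#'   are written there.
#' @param ... passed to [assign_patients()] (rarely needed).
#' @return A list with `table` (a `pa_table`), `results` (list of `pa_runs`)
#'   and `instances`.
#' @examples
#' ex <- pa_experiment(table1_suite(1)[1, ], methods = c("random", "greedy"),
#'                     n_runs = 3, base_seed = 1)
#' ex$table
#' @export
pa_experiment <- function(suite = table1_suite(base_seed), instances = NULL,
                          methods = c("random", "greedy", "de", "ga", "dga"),
                          n_runs = 25L, base_seed = 1L, out_dir = NULL, ...) {
  if (is.null(instances)) {
    instances <- generate_suite(suite)
  } else if (is.null(names(instances))) {
    names(instances) <- paste0("I", seq_along(instances))
  }
  results <- list()
  for (id in names(instances)) {
    inst <- instances[[id]]
    for (m in methods) {
      nr <- if (m == "greedy") 1L else n_runs
      results[[paste(id, m, sep = ".")]] <-
        repeat_runs(inst, m, n_runs = nr, base_seed = base_seed,
                    instance_id = id,
                    max_evals = inst$n_patients * inst$n_doctors, ...)
    }
  }
  tab <- build_table(results)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(tab$summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(tab$markdown, file.path(out_dir, "summary.md"))
    runs <- do.call(rbind, lapply(results, function(r)
      data.frame(instance = r$instance_id, method = r$method,
                 run = seq_len(r$n_runs), seed = r$seeds,
                 evals_used = r$evals_used, tf = r$tf)))
    utils::write.table(runs, file.path(out_dir, "runs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(table = tab, results = results, instances = instances)
}
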