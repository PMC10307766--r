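#' @rdname assign_patients
#' @name pa_fit
NULL

#' @export
print.pa_fit <- function(x, ...) {
  cat(sprintf("Patient assignment fit (method: %s)\n", x$method))
  cat(sprintf("  instance: %d patients, %d doctors\n",
              x$instance$n_patients, x$instance$n_doctors))
  cat(sprintf("  best TF: %.4f min   evaluations used: %d\n", x$tf, x$evals_used))
  if (!is.na(x$generations))
    cat(sprintf("  generations: %d\n", x$generations))
  invisible(x)
}

#' @export
summary.pa_fit <- function(object, ...) {
  loads <- object$loads
  structure(list(method = object$method, tf = object$tf,
                 n_patients = object$instance$n_patients,
                 n_doctors = object$instance$n_doctors,
                 loads = loads, mean_load = mean(loads),
                 spread = max(loads) - min(loads),
                 patients_per_doctor = tabulate(object$genes, object$instance$n_doctors),
                 evals_used = object$evals_used),
            class = "summary.pa_fit")
}

#' @export
print.summary.pa_fit <- function(x, ...) {
  cat(sprintf("Patient assignment summary (method: %s)\n", x$method))
  cat(sprintf("  %d patients over %d doctors\n", x$n_patients, x$n_doctors))
  cat(sprintf("  TF (pop. sd of loads): %.4f min\n", x$tf))
  cat(sprintf("  loads: mean %.2f, min %.2f, max %.2f, spread %.2f min\n",
              x$mean_load, min(x$loads), max(x$loads), x$spread))
  cat(sprintf("  patients per doctor: %s\n",
              paste(x$patients_per_doctor, collapse = " ")))
  cat(sprintf("  evaluations used: %d\n", x$evals_used))
  invisible(x)
}

#' @export
coef.pa_fit <- function(object, ...) {
  setNames(object$genes, paste0("P", seq_along(object$genes)))
}

#' @export
fitted.pa_fit <- function(object, ...) {
  setNames(object$loads, paste0("D", seq_along(object$loads)))
}

#' @export
residuals.pa_fit <- function(object, ...) {
  setNames(object$loads - mean(object$loads), paste0("D", seq_along(object$loads)))
}

#' Plot a patient-assignment fit
#'
#' `type = "convergence"` draws the best-so-far TF against fitness
#' evaluations consumed (a step function, one step per improvement);
#' `type = "loads"` draws the per-doctor load profile with the mean load.
#'
#' @param x a `pa_fit`.
#' @param type `"convergence"` or `"loads"`.
#' @param ... passed to the underlying plotting function.
#' @return `x`, invisibly.
#' @export
plot.pa_fit <- function(x, type = c("convergence", "loads"), ...) {
  type <- match.arg(type)
  if (type == "convergence") {
    tr <- x$trajectory
    plot(tr[, "evals"], tr[, "tf"], type = "s",
         xlab = "fitness evaluations", ylab = "best-so-far TF (min)",
         main = sprintf("Convergence (%s)", x$method), ...)
  } else {
    barplot(x$loads, names.arg = paste0("D", seq_along(x$loads)),
            xlab = "doctor", ylab = "total diagnosis time (min)",
            main = sprintf("Doctor loads (%s), TF = %.2f", x$method, x$tf), ...)
    abline(h = mean(x$loads), lty = 2)
  }
  invisible(x)
}

#' Re-run a fitted algorithm under fresh seeds
#'
#' Repeats the fit's algorithm and settings `nsim` times with seeds derived
#' from `seed`, returning the final time factors — the Monte-Carlo view of
#' the optimiser's run-to-run variability. The deterministic greedy method
#' returns its single value `nsim` times.
#'
#' @param object a `pa_fit`.
#' @param nsim number of repeated runs.
#' @param seed base seed for the derived run seeds; defaults to the fit's own.
#' @param ... ignored.
#' @return A data frame with columns `run`, `seed`, `tf`.
#' @export
simulate.pa_fit <- function(object, nsim = 25L, seed = NULL, ...) {
  if (is.null(seed)) seed <- if (is.na(object$seed)) 1L else object$seed
  seeds <- vapply(seq_len(nsim), function(r) derive_seed(seed, "sim", r), 0L)
  tf <- vapply(seq_len(nsim), function(r) .refit(object, seeds[r])$tf, 0)
  data.frame(run = seq_len(nsim), seed = seeds, tf = tf)
}

.refit <- function(object, seed) {
  inst <- object$instance
  if (inherits(object$config, "dga_config")) {
    cfg <- object$config
    cfg$seed <- seed
    .run_engine(inst, cfg, method = object$method)
  } else if (object$method == "random") {
    run_random(inst, object$config$max_evals, seed = seed)
  } else if (object$method == "de") {
    cfg <- object$config
    run_de(inst, cfg$max_evals, np = cfg$np, f = cfg$f, cr = cfg$cr, seed = seed)
  } else if (object$method == "greedy") {
    run_greedy(inst)
  } else {
    .stopf("cannot re-run method '%s'", object$method)
  }
}

#' Export a convergence trajectory
#'
#' Writes the best-so-far trajectory of a fit as a two-column tab-separated
#' file (`evals`, `tf`), one row per improvement.
#'
#' @param fit a `pa_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(fit, path) {
  stopifnot(inherits(fit, "pa_fit"))
  utils::write.table(as.data.frame(fit$trajectory), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @importFrom stats setNames simulate
NULL
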