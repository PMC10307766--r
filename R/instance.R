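#' Construct a patient-assignment problem instance
#'
#' A problem instance holds, for each patient, an estimated diagnosis time (in
#' minutes) and the set of doctors eligible to see that patient (the
#' candidature list). The optimisation task is to assign every patient to one
#' of their candidate doctors so that the time factor — the population
#' standard deviation of per-doctor total diagnosis time — is minimal.
#'
#' Doctor indices are 1-based (`1..n_doctors`). `candidates = NULL` means
#' every doctor is available to every patient, which is also stored compactly
#' (no per-patient lists are materialised).
#'
#' @param est_time numeric vector of positive estimated diagnosis times, one
#'   per patient (minutes).
#' @param n_doctors number of doctors, a positive integer.
#' @param candidates either `NULL` (all doctors available to all patients) or
#'   a list with one integer vector per patient, each a non-empty subset of
#'   `1:n_doctors`.
#' @param spec optional list recording how the instance was generated (kept
#'   for provenance; written to file by [write_instance()]).
#' @return An object of class `pa_instance` with fields `n_patients`,
#'   `n_doctors`, `est_time`, `candidates` (list or `NULL`), `all_doctors`.
#' @examples
#' inst <- pa_instance(c(4, 6, 10), n_doctors = 2)
#' time_factor(inst, c(1, 2, 2))
#' @seealso [generate_instance()], [assign_patients()]
#' @export
pa_instance <- function(est_time, n_doctors, candidates = NULL, spec = NULL) {
  if (!is.numeric(est_time) || length(est_time) < 1L)
    .stopf("`est_time` must be a non-empty numeric vector")
  if (any(!is.finite(est_time)) || any(est_time <= 0))
    .stopf("all estimated diagnosis times must be finite and > 0")
  n_doctors <- as.integer(n_doctors)
  if (length(n_doctors) != 1L || is.na(n_doctors) || n_doctors < 1L)
    .stopf("`n_doctors` must be a single positive integer")
  nP <- length(est_time)
  all_doctors <- is.null(candidates)
  if (!all_doctors) {
    if (!is.list(candidates) || length(candidates) != nP)
      .stopf("`candidates` must be a list with one entry per patient (%d), got %d",
             nP, length(candidates))
    candidates <- lapply(seq_len(nP), function(i) {
      cd <- candidates[[i]]
      if (length(cd) < 1L)
        .stopf("candidate set of patient %d is empty", i)
      cd <- sort(unique(as.integer(cd)))
      if (anyNA(cd) || cd[1L] < 1L || cd[length(cd)] > n_doctors)
        .stopf("candidate set of patient %d contains doctors outside 1..%d", i, n_doctors)
      cd
    })
    if (all(lengths(candidates) == n_doctors)) {
      candidates <- NULL
      all_doctors <- TRUE
    }
  }
  structure(
    list(n_patients = nP, n_doctors = n_doctors,
         est_time = as.numeric(est_time),
         candidates = candidates, all_doctors = all_doctors, spec = spec),
    class = "pa_instance")
}

#' @export
print.pa_instance <- function(x, ...) {
  cat("Patient-assignment instance\n")
  cat(sprintf("  patients: %d   doctors: %d\n", x$n_patients, x$n_doctors))
  cat(sprintf("  est. diagnosis time: [%.3g, %.3g] min (mean %.3g)\n",
              min(x$est_time), max(x$est_time), mean(x$est_time)))
  if (x$all_doctors) {
    cat("  candidates: all doctors available to every patient\n")
  } else {
    cat(sprintf("  candidates: per-patient lists, sizes %d..%d\n",
                min(lengths(x$candidates)), max(lengths(x$candidates))))
  }
  invisible(x)
}

# Flattened candidate lists for the C++ kernels: 0-based offsets into a flat
# 1-based doctor-index vector. Empty placeholders for all-doctors instances.
.cand_flat <- function(instance) {
  if (instance$all_doctors)
    return(list(flat = integer(0), off = integer(instance$n_patients + 1L)))
  len <- lengths(instance$candidates)
  list(flat = unlist(instance$candidates, use.names = FALSE),
       off = c(0L, cumsum(len)))
}

.candidates_of <- function(instance, i) {
  if (instance$all_doctors) seq_len(instance$n_doctors) else instance$candidates[[i]]
}

# First-violation report, NULL if feasible.
.check_solution <- function(instance, genes) {
  if (length(genes) != instance$n_patients)
    return(sprintf("solution has %d genes but the instance has %d patients",
                   length(genes), instance$n_patients))
  genes <- as.integer(genes)
  if (anyNA(genes))
    return(sprintf("gene %d is NA", which(is.na(genes))[1L]))
  bad <- which(genes < 1L | genes > instance$n_doctors)
  if (length(bad))
    return(sprintf("gene %d assigns doctor %d, outside 1..%d",
                   bad[1L], genes[bad[1L]], instance$n_doctors))
  if (!instance$all_doctors) {
    for (i in seq_along(genes)) {
      if (!any(instance$candidates[[i]] == genes[i]))
        return(sprintf("gene %d assigns doctor %d, not in that patient's candidate set {%s}",
                       i, genes[i], paste(instance$candidates[[i]], collapse = ", ")))
    }
  }
  NULL
}

#' Check feasibility of an assignment
#'
#' An assignment is feasible when it has one gene per patient and every gene
#' lies in that patient's candidate set.
#'
#' @param instance a [pa_instance()].
#' @param genes integer vector of assigned doctor indices, one per patient.
#' @return `TRUE`, or `FALSE` with a `"violation"` attribute describing the
#'   first violated constraint (offending gene or length mismatch).
#' @examples
#' inst <- pa_instance(c(4, 6, 10), 2)
#' is_feasible(inst, c(1, 2, 2))
#' attr(is_feasible(inst, c(1, 2, 3)), "violation")
#' @export
is_feasible <- function(instance, genes) {
  stopifnot(inherits(instance, "pa_instance"))
  v <- .check_solution(instance, genes)
  if (is.null(v)) TRUE else structure(FALSE, violation = v)
}

.assert_feasible <- function(instance, genes) {
  v <- .check_solution(instance, genes)
  if (!is.null(v)) .stopf("infeasible solution: %s", v)
  invisible(NULL)
}

#' Per-doctor total diagnosis time
#'
#' Sums the estimated diagnosis times of the patients assigned to each
#' doctor. Doctors with no patients have load 0 and still count towards the
#' mean and the time factor.
#'
#' @inheritParams is_feasible
#' @return Numeric vector of length `n_doctors` of total loads (minutes).
#' @examples
#' doctor_loads(pa_instance(c(4, 6, 10), 2), c(1, 2, 2))
#' @export
doctor_loads <- function(instance, genes) {
  stopifnot(inherits(instance, "pa_instance"))
  .assert_feasible(instance, genes)
  cpp_loads(instance$est_time, as.integer(genes), instance$n_doctors)
}

#' Mean doctor load
#'
#' @param loads numeric vector of per-doctor total loads.
#' @return The mean load (total time divided by the number of doctors).
#' @examples
#' mean_load(c(4, 16))
#' @export
mean_load <- function(loads) {
  if (length(loads) < 1L) .stopf("`loads` must be non-empty")
  mean(loads)
}

#' Time factor (TF) of an assignment
#'
#' The minimisation objective: the population standard deviation (divisor
#' `n_doctors`, not `n_doctors - 1`) of per-doctor total diagnosis time.
#' TF is 0 exactly when all doctors carry equal load.
#'
#' @inheritParams is_feasible
#' @return A single non-negative number (minutes).
#' @examples
#' time_factor(pa_instance(c(4, 6, 10), 2), c(1, 2, 2)) # loads 4, 16 -> TF 6
#' @export
time_factor <- function(instance, genes) {
  stopifnot(inherits(instance, "pa_instance"))
  .assert_feasible(instance, genes)
  cpp_tf(instance$est_time, as.integer(genes), instance$n_doctors)
}

#' Evaluate an assignment (loads, mean load and TF at once)
#'
#' @inheritParams is_feasible
#' @return A list with `loads`, `mean_load` and `tf`.
#' @examples
#' evaluate_assignment(pa_instance(c(4, 6, 10), 2), c(1, 2, 2))
#' @export
evaluate_assignment <- function(instance, genes) {
  loads <- doctor_loads(instance, genes)
  m <- mean(loads)
  list(loads = loads, mean_load = m, tf = sqrt(mean((loads - m)^2)))
}
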