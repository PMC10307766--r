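#' Read and write the plain-text instance format
#'
#' Instances are stored in a line-oriented plain-text format (version 1):
#' \preformatted{
#' pa-instance 1
#' n_patients 3
#' n_doctors 2
#' est_time 4 6 10
#' candidates all
#' }
#' `est_time` holds one full-precision (`\%.17g`) number per patient, so a
#' write/read round trip reproduces the instance bit-exactly. When candidate
#' lists are restricted, `candidates all` is replaced by `candidates list`
#' followed by one line per patient of the form `<patient>: <doctor> ...`
#' with 1-based doctor indices. Lines starting with `#` are comments; the
#' generating specification, when known, is recorded in them.
#'
#' @param instance a [pa_instance()].
#' @param path file path.
#' @return `write_instance()` returns `path` invisibly; `read_instance()`
#'   returns a [pa_instance()]. Malformed files raise an error naming the
#'   offending line or patient; an unknown format version is an explicit
#'   error.
#' @examples
#' f <- tempfile(fileext = ".pa")
#' write_instance(pa_instance(c(4, 6, 10), 2), f)
#' read_instance(f)
#' @export
write_instance <- function(instance, path) {
  stopifnot(inherits(instance, "pa_instance"))
  lines <- c("pa-instance 1",
             sprintf("n_patients %d", instance$n_patients),
             sprintf("n_doctors %d", instance$n_doctors),
             paste("est_time", paste(sprintf("%.17g", instance$est_time), collapse = " ")))
  if (instance$all_doctors) {
    lines <- c(lines, "candidates all")
  } else {
    lines <- c(lines, "candidates list",
               vapply(seq_len(instance$n_patients), function(i)
                 sprintf("%d: %s", i, paste(instance$candidates[[i]], collapse = " ")),
                 character(1)))
  }
  if (!is.null(instance$spec)) {
    sp <- instance$spec
    lines <- c(lines, paste("# spec", paste(names(sp), unlist(sp), sep = "=", collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_instance
#' @export
read_instance <- function(path) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- trimws(raw[keep])
  lineno <- which(keep)
  if (length(lines) < 1L) .stopf("'%s': empty instance file", path)

  expect <- function(idx, what) {
    if (idx > length(lines))
      .stopf("'%s': unexpected end of file, expected %s", path, what)
  }
  fields <- strsplit(lines, "\\s+")

  hd <- fields[[1L]]
  if (hd[1L] != "pa-instance")
    .stopf("'%s' line %d: not a pa-instance file (found '%s')", path, lineno[1L], lines[1L])
  if (length(hd) != 2L || hd[2L] != "1")
    .stopf("'%s': unsupported pa-instance format version '%s' (supported: 1)",
           path, paste(hd[-1L], collapse = " "))

  get_int <- function(idx, key) {
    expect(idx, key)
    f <- fields[[idx]]
    if (f[1L] != key || length(f) != 2L)
      .stopf("'%s' line %d: expected '%s <integer>', found '%s'",
             path, lineno[idx], key, lines[idx])
    v <- suppressWarnings(as.integer(f[2L]))
    if (is.na(v)) .stopf("'%s' line %d: '%s' is not an integer", path, lineno[idx], f[2L])
    v
  }
  nP <- get_int(2L, "n_patients")
  nD <- get_int(3L, "n_doctors")

  expect(4L, "est_time")
  f <- fields[[4L]]
  if (f[1L] != "est_time")
    .stopf("'%s' line %d: expected 'est_time ...', found '%s'", path, lineno[4L], lines[4L])
  est <- suppressWarnings(as.numeric(f[-1L]))
  if (length(est) != nP)
    .stopf("'%s' line %d: est_time lists %d values for %d patients",
           path, lineno[4L], length(est), nP)
  if (anyNA(est))
    .stopf("'%s' line %d: est_time entry %d ('%s') is not a number",
           path, lineno[4L], which(is.na(est))[1L], f[-1L][which(is.na(est))[1L]])

  expect(5L, "candidates")
  f <- fields[[5L]]
  if (f[1L] != "candidates" || length(f) != 2L || !f[2L] %in% c("all", "list"))
    .stopf("'%s' line %d: expected 'candidates all' or 'candidates list', found '%s'",
           path, lineno[5L], lines[5L])

  cands <- NULL
  if (f[2L] == "list") {
    if (length(lines) < 5L + nP)
      .stopf("'%s': candidates list has %d of %d patient lines",
             path, length(lines) - 5L, nP)
    cands <- vector("list", nP)
    for (i in seq_len(nP)) {
      idx <- 5L + i
      f <- fields[[idx]]
      tag <- suppressWarnings(as.integer(sub(":$", "", f[1L])))
      if (is.na(tag) || tag != i || !grepl(":$", f[1L]))
        .stopf("'%s' line %d: expected candidate line for patient %d, found '%s'",
               path, lineno[idx], i, lines[idx])
      cd <- suppressWarnings(as.integer(f[-1L]))
      if (length(cd) < 1L || anyNA(cd))
        .stopf("'%s' line %d: malformed candidate set for patient %d", path, lineno[idx], i)
      if (any(cd < 1L | cd > nD))
        .stopf("'%s' line %d: patient %d has candidate doctor %d outside 1..%d",
               path, lineno[idx], i, cd[which(cd < 1L | cd > nD)[1L]], nD)
      cands[[i]] <- cd
    }
  }
  pa_instance(est, nD, cands)
}
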