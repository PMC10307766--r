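# Independent oracle for the objective: explicit 0/1 status matrix S
# (S[i, j] = 1 iff patient i is assigned to doctor j), loads via matrix
# algebra, TF as the population standard deviation. Deliberately avoids the
# package's evaluation path.
tf_oracle <- function(instance, genes) {
  nP <- instance$n_patients
  nD <- instance$n_doctors
  S <- matrix(0, nP, nD)
  S[cbind(seq_len(nP), genes)] <- 1
  loads <- as.vector(crossprod(S, instance$est_time))
  m <- sum(loads) / nD
  sqrt(sum((loads - m)^2) / nD)
}

loads_oracle <- function(instance, genes) {
  S <- matrix(0, instance$n_patients, instance$n_doctors)
  S[cbind(seq_len(instance$n_patients), genes)] <- 1
  as.vector(crossprod(S, instance$est_time))
}

# All feasible assignments of an instance, one per row.
enum_solutions <- function(instance) {
  cands <- lapply(seq_len(instance$n_patients), function(i)
    if (instance$all_doctors) seq_len(instance$n_doctors) else instance$candidates[[i]])
  as.matrix(expand.grid(cands, KEEP.OUT.ATTRS = FALSE))
}

# Small random instance, optionally with restricted candidate lists.
rand_tiny_instance <- function(seed, max_np = 8, max_nd = 3) {
  set.seed(seed)
  nP <- sample(2:max_np, 1)
  nD <- sample(1:max_nd, 1)
  cands <- NULL
  if (nD > 1 && runif(1) < 0.5)
    cands <- replicate(nP, sort(sample.int(nD, sample(1:nD, 1))), simplify = FALSE)
  pa_instance(runif(nP, 1, 10), nD, cands)
}

# Exhaustive two-sided rank-sum p-value by enumeration of rank occupancies.
rank_sum_exact_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(n1 + n2, n1)
  w_all <- apply(combs, 2, function(ix) sum(r[ix]))
  mu <- n1 * (n1 + n2 + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

random_feasible <- function(instance, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(instance$n_patients), function(i) {
    cd <- if (instance$all_doctors) seq_len(instance$n_doctors) else instance$candidates[[i]]
    cd[sample.int(length(cd), 1)]
  }, 0L)
}
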