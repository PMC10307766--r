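#include <Rcpp.h>
using namespace Rcpp;

// Per-doctor workloads (Eq-1-style accumulation): loads[j] = sum of est[i]
// over patients assigned to doctor j. genes are 1-based doctor indices.
// [[Rcpp::export(rng = false)]]
NumericVector cpp_loads(NumericVector est, IntegerVector genes, int nD) {
  int nP = est.size();
  NumericVector loads(nD);
  for (int i = 0; i < nP; ++i) loads[genes[i] - 1] += est[i];
  return loads;
}

// Time factor: population standard deviation (divide by nD) of loads.
// [[Rcpp::export(rng = false)]]
double cpp_tf(NumericVector est, IntegerVector genes, int nD) {
  int nP = est.size();
  std::vector<double> loads(nD, 0.0);
  for (int i = 0; i < nP; ++i) loads[genes[i] - 1] += est[i];
  double m = 0.0;
  for (int j = 0; j < nD; ++j) m += loads[j];
  m /= nD;
  double s = 0.0;
  for (int j = 0; j < nD; ++j) { double d = loads[j] - m; s += d * d; }
  return std::sqrt(s / nD);
}

static inline double eval_tf(const std::vector<int> &genes, const NumericVector &est,
                             std::vector<double> &loads, int nD) {
  std::fill(loads.begin(), loads.end(), 0.0);
  int nP = (int) genes.size();
  for (int i = 0; i < nP; ++i) loads[genes[i] - 1] += est[i];
  double m = 0.0;
  for (int j = 0; j < nD; ++j) m += loads[j];
  m /= nD;
  double s = 0.0;
  for (int j = 0; j < nD; ++j) { double d = loads[j] - m; s += d * d; }
  return std::sqrt(s / nD);
}

// Resample a gene uniformly from its candidate set excluding the current
// value; no-op for singleton sets. Uses R's RNG so that results are
// reproducible from .Random.seed streams managed at the R level.
static inline int resample_gene(int cur, int i, bool all_doctors, int nD,
                                const IntegerVector &cand_flat,
                                const IntegerVector &cand_off) {
  if (all_doctors) {
    if (nD < 2) return cur;
    int r = 1 + (int) (unif_rand() * (nD - 1)); // 1..nD-1
    if (r >= cur) ++r;
    return r;
  }
  int lo = cand_off[i], hi = cand_off[i + 1]; // [lo, hi), 0-based into flat
  int L = hi - lo;
  if (L < 2) return cur;
  int k = (int) (unif_rand() * (L - 1)); // index among alternatives
  for (int t = lo; t < hi; ++t) {
    if (cand_flat[t] == cur) continue;
    if (k == 0) return cand_flat[t];
    --k;
  }
  return cur; // unreachable for feasible input
}

// One generation's worth of pair evolution for a single (sub-)population:
// random perfect matching is supplied as `perm` (1-based member indices);
// each pair yields one child via uniform crossover (or a parent copy when
// crossover is disabled), candidate-list mutation at rate mr (when enabled),
// then family selection: the child replaces the worse parent iff its TF is
// strictly lower. Stops early once `budget_left` evaluations are spent.
// [[Rcpp::export]]
List cpp_evolve_pairs(IntegerMatrix pop, NumericVector tf, IntegerVector perm,
                      NumericVector est, int nD, double mr,
                      bool crossover, bool mutation,
                      IntegerVector cand_flat, IntegerVector cand_off,
                      bool all_doctors, int budget_left, double best_tf) {
  int nP = pop.nrow();
  int psize = pop.ncol();
  IntegerMatrix P = clone(pop);
  NumericVector F = clone(tf);
  int npairs = psize / 2;
  int evals = 0;
  std::vector<int> child(nP);
  std::vector<double> loads(nD);
  std::vector<int> imp_eval;
  std::vector<double> imp_tf;
  IntegerVector best_genes(0);

  for (int k = 0; k < npairs; ++k) {
    if (evals >= budget_left) break;
    int i1 = perm[2 * k] - 1;
    int i2 = perm[2 * k + 1] - 1;
    double f1 = F[i1], f2 = F[i2];

    if (crossover) {
      for (int i = 0; i < nP; ++i)
        child[i] = (unif_rand() < 0.5) ? P(i, i1) : P(i, i2);
    } else {
      int src = (unif_rand() < 0.5) ? i1 : i2;
      for (int i = 0; i < nP; ++i) child[i] = P(i, src);
    }
    if (mutation && mr > 0.0) {
      for (int i = 0; i < nP; ++i)
        if (unif_rand() < mr)
          child[i] = resample_gene(child[i], i, all_doctors, nD, cand_flat, cand_off);
    }

    double tfc = eval_tf(child, est, loads, nD);
    ++evals;

    if (tfc < best_tf) {
      best_tf = tfc;
      imp_eval.push_back(evals);
      imp_tf.push_back(tfc);
      best_genes = IntegerVector(child.begin(), child.end());
    }

    // family selection: strictly better than the worse parent replaces it;
    // ties keep the incumbent; a parent-TF tie treats the first as worse.
    int worse = (f1 >= f2) ? i1 : i2;
    double wtf = (f1 >= f2) ? f1 : f2;
    if (tfc < wtf) {
      for (int i = 0; i < nP; ++i) P(i, worse) = child[i];
      F[worse] = tfc;
    }
  }

  return List::create(_["pop"] = P, _["tf"] = F, _["evals"] = evals,
                      _["imp_eval"] = IntegerVector(imp_eval.begin(), imp_eval.end()),
                      _["imp_tf"] = NumericVector(imp_tf.begin(), imp_tf.end()),
                      _["best_genes"] = best_genes);
}

// Pure random search: sample feasible assignments uniformly, keep the best.
// [[Rcpp::export]]
List cpp_random_search(NumericVector est, int nD,
                       IntegerVector cand_flat, IntegerVector cand_off,
                       bool all_doctors, int max_evals) {
  int nP = est.size();
  std::vector<int> genes(nP);
  std::vector<double> loads(nD);
  std::vector<int> imp_eval;
  std::vector<double> imp_tf;
  IntegerVector best_genes(0);
  double best = R_PosInf;
  for (int e = 1; e <= max_evals; ++e) {
    if (all_doctors) {
      for (int i = 0; i < nP; ++i) genes[i] = 1 + (int) (unif_rand() * nD);
    } else {
      for (int i = 0; i < nP; ++i) {
        int lo = cand_off[i], L = cand_off[i + 1] - lo;
        genes[i] = cand_flat[lo + (int) (unif_rand() * L)];
      }
    }
    double tfv = eval_tf(genes, est, loads, nD);
    if (tfv < best) {
      best = tfv;
      imp_eval.push_back(e);
      imp_tf.push_back(tfv);
      best_genes = IntegerVector(genes.begin(), genes.end());
    }
  }
  return List::create(_["imp_eval"] = IntegerVector(imp_eval.begin(), imp_eval.end()),
                      _["imp_tf"] = NumericVector(imp_tf.begin(), imp_tf.end()),
                      _["best_genes"] = best_genes, _["best_tf"] = best,
                      _["evals"] = max_evals);
}
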