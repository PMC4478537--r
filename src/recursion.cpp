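#include <Rcpp.h>
using namespace Rcpp;

// Synchronous forward recursion for the multilocus stabilizing-selection
// model.  One generation:
//   p_i' = p_i - (s g_i^2 / 2) p_i q_i (2*dc1/g_i + q_i - p_i) + mu (q_i - p_i)
// with dc1 = c1 - optimum evaluated once from the pre-update state (all
// loci are coupled only through c1).  Frequencies are clamped to [0,1];
// clamps and |increment| > 0.5 events are counted but never raised here.
//
// If tol > 0 the sweep stops once max_i |increment| < tol (equilibration);
// otherwise exactly max_gen generations are run.  Cumulants are recorded
// at generation offsets 0, record_every, 2*record_every, ... and at the
// final generation.

// long double accumulators match R's sum(), so cumulants recorded here
// are bit-identical to recomputation from a frequency snapshot in R
static inline void cumulants3(const std::vector<double>& p,
                              const NumericVector& g,
                              double& c1, double& c2, double& c3) {
  long double a1 = 0.0L, a2 = 0.0L, a3 = 0.0L;
  const int n = p.size();
  for (int i = 0; i < n; ++i) {
    const double pi = p[i], qi = 1.0 - pi, gi = g[i];
    a1 += (long double)(gi * (pi - qi));
    a2 += (long double)(2.0 * gi * gi * pi * qi);
    a3 += (long double)(2.0 * gi * gi * gi * (qi - pi) * pi * qi);
  }
  c1 = (double)a1; c2 = (double)a2; c3 = (double)a3;
}

// [[Rcpp::export(name = ".cpp_evolve")]]
List cpp_evolve(NumericVector p0, NumericVector gamma_, double s, double mu,
                double optimum, int max_gen, double tol, int record_every,
                bool record_freqs) {
  const int n = p0.size();
  if (gamma_.size() != n) stop("freqs and effects differ in length");
  std::vector<double> p(p0.begin(), p0.end());
  std::vector<double> rec_gen, rec_c1, rec_c2, rec_c3;
  std::vector<double> snaps;           // row-major, one row per record
  long n_clamped = 0, n_big = 0;
  double c1, c2, c3;

  auto record = [&](int gen) {
    cumulants3(p, gamma_, c1, c2, c3);
    rec_gen.push_back(gen); rec_c1.push_back(c1);
    rec_c2.push_back(c2);   rec_c3.push_back(c3);
    if (record_freqs) snaps.insert(snaps.end(), p.begin(), p.end());
  };

  record(0);
  int gen = 0;
  bool converged = (tol > 0.0 && max_gen == 0);
  while (gen < max_gen) {
    double c1_now = 0.0;
    for (int i = 0; i < n; ++i) c1_now += gamma_[i] * (2.0 * p[i] - 1.0);
    const double dc1 = c1_now - optimum;
    double max_step = 0.0;
    for (int i = 0; i < n; ++i) {
      const double pi = p[i], qi = 1.0 - pi, gi = gamma_[i];
      double incr = -(s * gi * gi / 2.0) * pi * qi * (2.0 * dc1 / gi + qi - pi)
                    + mu * (qi - pi);
      const double a = std::fabs(incr);
      if (a > max_step) max_step = a;
      if (a > 0.5) ++n_big;
      double np = pi + incr;
      if (np < 0.0) { np = 0.0; ++n_clamped; }
      else if (np > 1.0) { np = 1.0; ++n_clamped; }
      p[i] = np;
    }
    ++gen;
    if (gen % record_every == 0 && gen != max_gen) record(gen);
    if (tol > 0.0 && max_step < tol) { converged = true; break; }
  }
  if (gen > 0 && (rec_gen.back() != gen)) record(gen);

  const int nr = rec_gen.size();
  NumericMatrix records(nr, 4);
  for (int r = 0; r < nr; ++r) {
    records(r, 0) = rec_gen[r]; records(r, 1) = rec_c1[r];
    records(r, 2) = rec_c2[r];  records(r, 3) = rec_c3[r];
  }
  colnames(records) = CharacterVector::create("generation", "c1", "c2", "c3");

  List out = List::create(
    _["p"] = NumericVector(p.begin(), p.end()),
    _["generations"] = gen,
    _["converged"] = converged,
    _["records"] = records,
    _["n_clamped"] = (double) n_clamped,
    _["n_big_steps"] = (double) n_big);
  if (record_freqs) {
    NumericMatrix sm(nr, n);
    for (int r = 0; r < nr; ++r)
      for (int i = 0; i < n; ++i) sm(r, i) = snaps[(size_t) r * n + i];
    out["freq_snapshots"] = sm;
  }
  return out;
}
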