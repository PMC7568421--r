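#include <Rcpp.h>
using namespace Rcpp;

// Gillespie direct-method endpoint sampler.
//
// Runs one exact trajectory from x0 until time tmax and returns the state
// at tmax (the state holds between events, so the last pre-tmax state is
// the endpoint).  Uses R's RNG (unif_rand / exp_rand) so that results are
// reproducible under set.seed() from the R side.
//
// Reaction encoding (see .compileSystem in R/reaction-system.R):
//   rtype 0: association, a_j = rate * x[ri1] * x[ri2]
//            (rate already divided by V * N_Avogadro)
//   rtype 1: linear first order, a_j = rate * x[ri1]
//   rtype 2: conditional synthesis, a_j = rate * (x[ri1] >= 1)
// stoich is the dense (n_species x n_reactions) change matrix.

// [[Rcpp::export(name = ".ssaEndpoint")]]
IntegerVector ssa_endpoint(IntegerVector x0, double tmax,
                           IntegerVector rtype, NumericVector rate,
                           IntegerVector ri1, IntegerVector ri2,
                           IntegerMatrix stoich, double maxEvents) {
  const int ns = x0.size();
  const int nr = rate.size();
  std::vector<double> x(ns);
  for (int i = 0; i < ns; ++i) {
    if (x0[i] < 0) stop("invalid state: negative species count");
    x[i] = x0[i];
  }
  std::vector<double> a(nr);
  std::vector<int> rt(nr), i1(nr), i2(nr);
  std::vector<double> rr(nr);
  for (int j = 0; j < nr; ++j) {
    rt[j] = rtype[j]; i1[j] = ri1[j]; i2[j] = ri2[j]; rr[j] = rate[j];
  }
  // flatten stoichiometry, column-major per reaction
  std::vector<double> dz(static_cast<size_t>(ns) * nr);
  for (int j = 0; j < nr; ++j)
    for (int i = 0; i < ns; ++i)
      dz[static_cast<size_t>(j) * ns + i] = stoich(i, j);

  double t = 0.0;
  double events = 0.0;
  while (true) {
    double a0 = 0.0;
    for (int j = 0; j < nr; ++j) {
      double aj;
      switch (rt[j]) {
      case 0: aj = rr[j] * x[i1[j]] * x[i2[j]]; break;
      case 2: aj = (x[i1[j]] >= 1.0) ? rr[j] : 0.0; break;
      default: aj = rr[j] * x[i1[j]];
      }
      a[j] = aj;
      a0 += aj;
    }
    if (a0 <= 0.0) break;           // absorbed: state holds until tmax
    t += exp_rand() / a0;
    if (t > tmax) break;
    double thr = unif_rand() * a0;
    int j = 0;
    double cum = a[0];
    while (cum < thr && j < nr - 1) { ++j; cum += a[j]; }
    const double *d = &dz[static_cast<size_t>(j) * ns];
    for (int i = 0; i < ns; ++i) x[i] += d[i];
    if (++events > maxEvents)
      stop("event budget exceeded (maxEvents = %.0f)", maxEvents);
  }
  IntegerVector out(ns);
  for (int i = 0; i < ns; ++i) out[i] = static_cast<int>(x[i]);
  out.attr("names") = x0.attr("names");
  return out;
}
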