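#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation (direct method) with mass-action
// propensities.  Uses R's RNG so that set.seed() in R controls the draws.
//
// stoich: species x reactions net change matrix
// orders: species x reactions reactant multiplicity (0, 1 or 2)
// rates:  per-reaction rate constants
// State is sampled on a uniform grid (record_dt) to bound memory.

static inline double rec_t_grid(int i, double dt) { return i * dt; }

// [[Rcpp::export(name = ".gillespie_core")]]
List gillespie_core(IntegerMatrix stoich, IntegerMatrix orders,
                    NumericVector rates, NumericVector x0,
                    double t_end, double record_dt,
                    double max_events = 5e8) {
  int ns = stoich.nrow(), nr = stoich.ncol();
  std::vector<double> x(x0.begin(), x0.end());
  int nrec = (int)std::floor(t_end / record_dt) + 1;
  NumericMatrix rec(nrec, ns);
  NumericVector rec_t(nrec);

  // per-reaction reactant index lists for fast propensity updates
  std::vector< std::vector< std::pair<int,int> > > reac(nr);
  for (int j = 0; j < nr; ++j)
    for (int s = 0; s < ns; ++s)
      if (orders(s, j) > 0) reac[j].push_back(std::make_pair(s, orders(s, j)));

  std::vector<double> a(nr);
  double t = 0.0;
  int ri = 0;
  double events = 0.0;
  RNGScope scope;

  for (int s = 0; s < ns; ++s) rec(0, s) = x[s];
  rec_t[0] = 0.0;
  ri = 1;

  while (t < t_end) {
    double a0 = 0.0;
    for (int j = 0; j < nr; ++j) {
      double aj = rates[j];
      for (size_t q = 0; q < reac[j].size(); ++q) {
        int s = reac[j][q].first, o = reac[j][q].second;
        if (o == 1) aj *= x[s];
        else aj *= x[s] * (x[s] - 1.0) / 2.0;
      }
      if (aj < 0) aj = 0;
      a[j] = aj;
      a0 += aj;
    }
    double t_next;
    if (a0 <= 0.0) {
      t_next = t_end + record_dt;           // nothing can happen
    } else {
      t_next = t + R::rexp(1.0 / a0);
    }
    // fill the sampling grid up to the event (state is constant in between)
    while (ri < nrec && rec_t_grid(ri, record_dt) <= t_next &&
           rec_t_grid(ri, record_dt) <= t_end + 1e-12) {
      for (int s = 0; s < ns; ++s) rec(ri, s) = x[s];
      rec_t[ri] = rec_t_grid(ri, record_dt);
      ++ri;
    }
    if (a0 <= 0.0 || t_next > t_end) break;
    t = t_next;
    double u = unif_rand() * a0, cum = 0.0;
    int jsel = nr - 1;
    for (int j = 0; j < nr; ++j) {
      cum += a[j];
      if (u <= cum) { jsel = j; break; }
    }
    for (int s = 0; s < ns; ++s) x[s] += stoich(s, jsel);
    if (++events > max_events)
      stop("gillespie: event budget exceeded (%.0f events)", max_events);
  }
  while (ri < nrec) {                        // pad the tail of the grid
    for (int s = 0; s < ns; ++s) rec(ri, s) = x[s];
    rec_t[ri] = ri * record_dt;
    ++ri;
  }
  return List::create(_["times"] = rec_t, _["abundances"] = rec,
                      _["events"] = events);
}
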