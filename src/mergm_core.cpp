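// Core change statistics and Metropolis-Hastings sampler for MERGMs on a
// directed friendship network with fixed bipartite affiliations.
//
// Conventions shared with the R level (see R/effects.R):
//   * adjacency is 0/1 with an empty diagonal; arcs run sender -> receiver;
//   * affiliations are exogenous: dx[i] = number of groups of student i,
//     smat(i,j) = number of groups shared by i and j;
//   * each effect term carries an integer code, a smoothing constant lambda
//     (alternating terms only) and one resolved covariate column.
//
// The free tie space (structural zeros removed, senders = respondents) is
// supplied from R as a dyad list; the sampler never proposes outside it.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

enum TermCode {
  T_ARC = 0, T_RECIP = 1, T_AINS = 2, T_AOUTS = 3, T_ATAT = 4, T_A2PAT = 5,
  T_SENDER = 6, T_RECEIVER = 7, T_INTERACTION = 8, T_DIFFERENCE = 9,
  T_IN2STARAX = 10, T_OUT2STARAX = 11, T_TXAXARC = 12, T_L3XAX = 13
};

namespace {

struct NetState {
  int n;
  std::vector<int> adj;                   // n*n row-major, adj[i*n+j] = y_ij
  std::vector<int> din, dout;
  std::vector< std::vector<int> > outn;   // out-neighbour lists
  std::vector< std::vector<int> > inn;    // in-neighbour lists

  explicit NetState(const IntegerMatrix& a)
    : n(a.nrow()), adj(n * n, 0), din(n, 0), dout(n, 0), outn(n), inn(n) {
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (i != j && a(i, j) == 1) add_arc(i, j);
  }

  inline int y(int i, int j) const { return adj[i * n + j]; }

  void add_arc(int i, int j) {
    adj[i * n + j] = 1;
    ++dout[i]; ++din[j];
    outn[i].push_back(j);
    inn[j].push_back(i);
  }

  void remove_arc(int i, int j) {
    adj[i * n + j] = 0;
    --dout[i]; --din[j];
    for (size_t k = 0; k < outn[i].size(); ++k)
      if (outn[i][k] == j) { outn[i][k] = outn[i].back(); outn[i].pop_back(); break; }
    for (size_t k = 0; k < inn[j].size(); ++k)
      if (inn[j][k] == i) { inn[j][k] = inn[j].back(); inn[j].pop_back(); break; }
  }

  // directed two-paths a -> k -> b
  inline int tp(int a, int b) const {
    int cnt = 0;
    const std::vector<int>& oa = outn[a];
    for (size_t k = 0; k < oa.size(); ++k)
      if (adj[oa[k] * n + b] == 1) ++cnt;
    return cnt;
  }
};

// Change statistics for ADDING arc i -> j; y_ij must currently be 0.
void delta_add(const NetState& st, int i, int j,
               const IntegerVector& codes, const NumericVector& lambdas,
               const NumericMatrix& covs, const NumericVector& dx,
               const NumericMatrix& smat, double* out) {
  const int p = codes.size();
  for (int t = 0; t < p; ++t) {
    const double lam = lambdas[t];
    const double r = 1.0 - 1.0 / lam;
    double d = 0.0;
    switch (codes[t]) {
    case T_ARC: d = 1.0; break;
    case T_RECIP: d = st.y(j, i); break;
    case T_AINS: d = lam * (1.0 - std::pow(r, st.din[j])); break;
    case T_AOUTS: d = lam * (1.0 - std::pow(r, st.dout[i])); break;
    case T_ATAT: {
      // the arc's own closure contribution
      d = lam * (1.0 - std::pow(r, st.tp(i, j)));
      // new two-path a -> i -> j closing existing arcs (a, j)
      const std::vector<int>& ii = st.inn[i];
      for (size_t a = 0; a < ii.size(); ++a) {
        int av = ii[a];
        if (av != j && st.y(av, j) == 1) d += std::pow(r, st.tp(av, j));
      }
      // new two-path i -> j -> b closing existing arcs (i, b)
      const std::vector<int>& oj = st.outn[j];
      for (size_t b = 0; b < oj.size(); ++b) {
        int bv = oj[b];
        if (bv != i && st.y(i, bv) == 1) d += std::pow(r, st.tp(i, bv));
      }
      break;
    }
    case T_A2PAT: {
      // adding i -> j creates one extra two-path for ordered pairs (a, j)
      // with y_ai = 1 and for pairs (i, b) with y_jb = 1
      const std::vector<int>& ii = st.inn[i];
      for (size_t a = 0; a < ii.size(); ++a) {
        int av = ii[a];
        if (av != j) d += std::pow(r, st.tp(av, j));
      }
      const std::vector<int>& oj = st.outn[j];
      for (size_t b = 0; b < oj.size(); ++b) {
        int bv = oj[b];
        if (bv != i) d += std::pow(r, st.tp(i, bv));
      }
      break;
    }
    case T_SENDER: d = covs(i, t); break;
    case T_RECEIVER: d = covs(j, t); break;
    case T_INTERACTION: d = covs(i, t) * covs(j, t); break;
    case T_DIFFERENCE: d = std::fabs(covs(i, t) - covs(j, t)); break;
    case T_IN2STARAX: d = dx[j]; break;
    case T_OUT2STARAX: d = dx[i]; break;
    case T_TXAXARC: d = smat(i, j); break;
    case T_L3XAX: d = dx[i] * dx[j] - smat(i, j); break;
    default: stop("unknown term code");
    }
    out[t] = d;
  }
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_change_stats")]]
NumericVector cpp_change_stats(IntegerMatrix adj, int i, int j,
                               IntegerVector codes, NumericVector lambdas,
                               NumericMatrix covs, NumericVector dx,
                               NumericMatrix smat) {
  NetState st(adj);
  // always the "toggle on minus toggle off" difference
  bool present = st.y(i, j) == 1;
  if (present) st.remove_arc(i, j);
  NumericVector out(codes.size());
  delta_add(st, i, j, codes, lambdas, covs, dx, smat, REAL(out));
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_mh_run")]]
List cpp_mh_run(IntegerMatrix adj0, IntegerMatrix free_dyads,
                NumericVector theta, IntegerVector codes,
                NumericVector lambdas, NumericMatrix covs,
                NumericVector dx, NumericMatrix smat,
                int max_out, bool respect_cap,
                NumericVector z0, int burnin, int thin, int nsamp,
                bool retain, bool track_states) {
  NetState st(adj0);
  const int p = codes.size();
  const int nfree = free_dyads.nrow();
  if (theta.size() != p) stop("theta/spec length mismatch");
  if (nfree < 1) stop("empty free tie space");

  std::vector<double> z(z0.begin(), z0.end());
  std::vector<double> dvec(p);

  // state-visit tracking for exact-distribution checks (small spaces only)
  NumericVector visits;
  unsigned long mask = 0;
  if (track_states) {
    if (nfree > 25) stop("state tracking limited to 25 free dyads");
    visits = NumericVector(1 << nfree);
    for (int k = 0; k < nfree; ++k)
      if (st.y(free_dyads(k, 0), free_dyads(k, 1)) == 1)
        mask |= (1UL << k);
  }

  NumericMatrix stats(nsamp, p);
  List nets(retain ? nsamp : 0);
  long total_steps = (long)burnin + (long)thin * nsamp;
  long accepted = 0;
  int isamp = 0;
  long next_record = (nsamp > 0) ? burnin + thin : total_steps + 1;

  for (long step = 1; step <= total_steps; ++step) {
    int idx = (int)(unif_rand() * nfree);
    if (idx >= nfree) idx = nfree - 1;
    int i = free_dyads(idx, 0), j = free_dyads(idx, 1);
    bool present = st.y(i, j) == 1;

    bool blocked = (!present && respect_cap && st.dout[i] >= max_out);
    if (!blocked) {
      if (present) st.remove_arc(i, j);
      delta_add(st, i, j, codes, lambdas, covs, dx, smat, &dvec[0]);
      double lr = 0.0;
      for (int t = 0; t < p; ++t) lr += theta[t] * dvec[t];
      if (present) lr = -lr;
      bool accept = (lr >= 0.0) || (unif_rand() < std::exp(lr));
      if (accept) {
        ++accepted;
        if (!present) st.add_arc(i, j);   // removal already applied
        double sgn = present ? -1.0 : 1.0;
        for (int t = 0; t < p; ++t) z[t] += sgn * dvec[t];
        if (track_states) mask ^= (1UL << idx);
      } else if (present) {
        st.add_arc(i, j);                 // restore
      }
    }
    if (track_states) visits[mask] += 1.0;

    if (step == next_record) {
      for (int t = 0; t < p; ++t) stats(isamp, t) = z[t];
      if (retain) {
        int ne = 0;
        for (int a = 0; a < st.n; ++a) ne += st.dout[a];
        IntegerMatrix el(ne, 2);
        int row = 0;
        for (int a = 0; a < st.n; ++a)
          for (size_t k = 0; k < st.outn[a].size(); ++k) {
            el(row, 0) = a + 1; el(row, 1) = st.outn[a][k] + 1; ++row;
          }
        nets[isamp] = el;
      }
      ++isamp;
      next_record = (isamp < nsamp) ? next_record + thin : total_steps + 1;
    }
  }

  IntegerMatrix adj_out(st.n, st.n);
  for (int a = 0; a < st.n; ++a)
    for (int b = 0; b < st.n; ++b)
      adj_out(a, b) = st.adj[a * st.n + b];

  List res = List::create(
    _["stats"] = stats,
    _["adj"] = adj_out,
    _["z"] = NumericVector(z.begin(), z.end()),
    _["acceptance_rate"] = total_steps > 0 ? (double)accepted / total_steps : NA_REAL,
    _["steps"] = (double)total_steps);
  if (retain) res["networks"] = nets;
  if (track_states) res["visits"] = visits;
  return res;
}
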