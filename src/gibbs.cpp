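#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for microbial source tracking.
//
// Reads of the sink sample are assigned to sources; named sources have
// fixed taxon distributions phi_{s,t} = (m_{s,t} + alpha1) / (m_s. + alpha1*T),
// while the optional unknown source (last row when include_unknown) uses the
// sink reads currently assigned to it with pseudocount alpha2. The source
// mixing proportions carry a Dirichlet(beta) prior, giving the conditional
//   P(z_r = s) propto phi-term(s, t_r) * (n_s^{-r} + beta).
// Uses R's RNG: seed with set.seed() before calling.
//
// read_taxa: 0-based taxon index per sink read
// source_counts: named-sources x taxa count matrix
// returns: ndraws x S matrix of source-proportion draws (post burn-in)
// [[Rcpp::export]]
NumericMatrix gibbs_sourcetrack_cpp(IntegerVector read_taxa,
                                    NumericMatrix source_counts,
                                    bool include_unknown,
                                    double alpha1, double alpha2, double beta,
                                    int burnin, int ndraws, int thin) {
  const int n = read_taxa.size();
  const int S_named = source_counts.nrow();
  const int T = source_counts.ncol();
  const int S = S_named + (include_unknown ? 1 : 0);
  if (n == 0) stop("empty sink");

  // fixed per-taxon likelihoods for named sources
  NumericMatrix phi(S_named, T);
  for (int s = 0; s < S_named; s++) {
    double tot = 0.0;
    for (int t = 0; t < T; t++) tot += source_counts(s, t);
    for (int t = 0; t < T; t++)
      phi(s, t) = (source_counts(s, t) + alpha1) / (tot + alpha1 * T);
  }

  std::vector<int> z(n);
  std::vector<double> n_s(S, 0.0);
  std::vector<double> u(T, 0.0); // unknown-source taxon counts
  double n_u = 0.0;

  for (int r = 0; r < n; r++) {
    int s = (int)(unif_rand() * S);
    if (s >= S) s = S - 1;
    z[r] = s;
    n_s[s] += 1.0;
    if (include_unknown && s == S - 1) { u[read_taxa[r]] += 1.0; n_u += 1.0; }
  }

  NumericMatrix draws(ndraws, S);
  std::vector<double> prob(S);
  int sweeps = burnin + (ndraws - 1) * thin + 1;
  int drawn = 0;
  for (int it = 0; it < sweeps; it++) {
    for (int r = 0; r < n; r++) {
      int t = read_taxa[r];
      int old = z[r];
      n_s[old] -= 1.0;
      if (include_unknown && old == S - 1) { u[t] -= 1.0; n_u -= 1.0; }
      double tot = 0.0;
      for (int s = 0; s < S_named; s++) {
        prob[s] = phi(s, t) * (n_s[s] + beta);
        tot += prob[s];
      }
      if (include_unknown) {
        double pu = (u[t] + alpha2) / (n_u + alpha2 * T) * (n_s[S - 1] + beta);
        prob[S - 1] = pu;
        tot += pu;
      }
      double r01 = unif_rand() * tot;
      int snew = 0;
      double acc = prob[0];
      while (r01 > acc && snew < S - 1) { snew++; acc += prob[snew]; }
      z[r] = snew;
      n_s[snew] += 1.0;
      if (include_unknown && snew == S - 1) { u[t] += 1.0; n_u += 1.0; }
    }
    if (it >= burnin && (it - burnin) % thin == 0 && drawn < ndraws) {
      for (int s = 0; s < S; s++) draws(drawn, s) = n_s[s] / n;
      drawn++;
    }
  }
  return draws;
}
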