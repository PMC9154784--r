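#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for microbial source attribution.
//
// One sink community at a time. Each sink read carries a latent environment
// label among V known source environments plus one "unknown" environment.
// Following the original source-tracking Gibbs formulation, every
// environment's taxon distribution is estimated from its current read mass:
// the known environments start from their (rarefied, per-environment summed)
// training counts, the unknown from zero, and sink reads assigned to an
// environment count toward its distribution; beta is the per-taxon
// pseudocount smoothing every environment. The collapsed mixing factor gives
// each known environment prior mass depth*alpha1 and the unknown depth*alpha2.
//
//   P(z_i = v | ...) propto (c_xv + beta) / (c_v + beta*T) * (n_v + prior_v)
//
// with c_xv the environment's current taxon-x count (training + assigned sink
// reads, minus read i), c_v its total, and n_v the sink reads currently
// assigned to v.
//
// Returns a (restarts*draws) x (V+1) matrix of per-sweep mixing proportions.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix gibbs_sink(IntegerVector sink_counts,
                         NumericMatrix train,   // T x V training counts
                         double alpha1, double alpha2, double beta,
                         int n_burnin, int n_draws, int restarts) {
  const int T = train.nrow();
  const int V = train.ncol();
  if (sink_counts.size() != T) stop("sink/train taxon dimension mismatch");
  int depth = 0;
  for (int x = 0; x < T; ++x) depth += sink_counts[x];
  if (depth <= 0) stop("empty sink");

  // expand reads: taxon index per read
  std::vector<int> read_taxon(depth);
  for (int x = 0, i = 0; x < T; ++x)
    for (int c = 0; c < sink_counts[x]; ++c) read_taxon[i++] = x;

  std::vector<double> train_tot(V, 0.0);
  for (int v = 0; v < V; ++v)
    for (int x = 0; x < T; ++x) train_tot[v] += train(x, v);

  NumericMatrix out(restarts * n_draws, V + 1);
  std::vector<int> z(depth);                    // env per read
  std::vector<double> n_env(V + 1);             // sink reads per env
  std::vector<double> c_tax((V + 1) * T);       // env-major taxon counts
  std::vector<double> c_tot(V + 1);
  std::vector<double> prob(V + 1);

  const double betaT = beta * T;

  for (int rs = 0; rs < restarts; ++rs) {
    std::fill(n_env.begin(), n_env.end(), 0.0);
    std::fill(c_tot.begin(), c_tot.end(), 0.0);
    for (int v = 0; v < V; ++v) {
      for (int x = 0; x < T; ++x) c_tax[v * T + x] = train(x, v);
      c_tot[v] = train_tot[v];
    }
    for (int x = 0; x < T; ++x) c_tax[V * T + x] = 0.0;

    for (int i = 0; i < depth; ++i) {
      int v = (int)std::floor(unif_rand() * (V + 1));
      if (v > V) v = V;
      z[i] = v;
      n_env[v] += 1.0;
      c_tax[v * T + read_taxon[i]] += 1.0;
      c_tot[v] += 1.0;
    }

    for (int sweep = 0; sweep < n_burnin + n_draws; ++sweep) {
      for (int i = 0; i < depth; ++i) {
        const int x = read_taxon[i];
        const int old = z[i];
        n_env[old] -= 1.0;
        c_tax[old * T + x] -= 1.0;
        c_tot[old] -= 1.0;

        double tot = 0.0;
        for (int v = 0; v <= V; ++v) {
          const double prior = (v < V) ? depth * alpha1 : depth * alpha2;
          prob[v] = (c_tax[v * T + x] + beta) / (c_tot[v] + betaT) *
                    (n_env[v] + prior);
          tot += prob[v];
        }

        double u = unif_rand() * tot;
        int v_new = 0;
        double acc = prob[0];
        while (u > acc && v_new < V) acc += prob[++v_new];

        z[i] = v_new;
        n_env[v_new] += 1.0;
        c_tax[v_new * T + x] += 1.0;
        c_tot[v_new] += 1.0;
      }
      if (sweep >= n_burnin) {
        const int row = rs * n_draws + (sweep - n_burnin);
        for (int v = 0; v <= V; ++v) out(row, v) = n_env[v] / depth;
      }
    }
  }
  return out;
}
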