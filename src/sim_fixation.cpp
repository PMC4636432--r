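#include <Rcpp.h>
using namespace Rcpp;

// Moran chain on a graph, run to absorption, repeated n_reps times.
// rule_code: 0 = Bd (global fitness-proportional birth, uniform neighbour
// replacement), 1 = dB (uniform death, fitness-proportional in-neighbour
// competition). Wild-type fitness is 1, mutant fitness r. Uses R's RNG so
// results are reproducible under set.seed().

// [[Rcpp::export]]
int sim_fixation_cpp(List adj_out, List adj_in, int n, double r,
                     int rule_code, int n_reps) {
  std::vector< std::vector<int> > out_nb(n), in_nb(n);
  for (int i = 0; i < n; ++i) {
    out_nb[i] = as< std::vector<int> >(adj_out[i]);
    in_nb[i] = as< std::vector<int> >(adj_in[i]);
  }
  RNGScope scope;
  int n_fixed = 0;
  std::vector<int> mut(n);
  for (int rep = 0; rep < n_reps; ++rep) {
    std::fill(mut.begin(), mut.end(), 0);
    int start = (int)(unif_rand() * n);
    if (start >= n) start = n - 1;
    mut[start] = 1;
    int n_mut = 1;
    while (n_mut > 0 && n_mut < n) {
      if (rule_code == 0) {
        // birth lottery over nodes with out-neighbours
        double F = 0.0;
        for (int i = 0; i < n; ++i)
          if (!out_nb[i].empty()) F += mut[i] ? r : 1.0;
        double u = unif_rand() * F;
        int parent = -1;
        for (int i = 0; i < n; ++i) {
          if (out_nb[i].empty()) continue;
          u -= mut[i] ? r : 1.0;
          if (u <= 0.0) { parent = i; break; }
        }
        if (parent < 0) parent = n - 1;
        const std::vector<int>& nb = out_nb[parent];
        int child = nb[(int)(unif_rand() * nb.size()) % nb.size()];
        if (mut[child] != mut[parent]) {
          n_mut += mut[parent] ? 1 : -1;
          mut[child] = mut[parent];
        }
      } else {
        int dying = (int)(unif_rand() * n);
        if (dying >= n) dying = n - 1;
        const std::vector<int>& nb = in_nb[dying];
        double W = 0.0;
        for (size_t k = 0; k < nb.size(); ++k) W += mut[nb[k]] ? r : 1.0;
        double u = unif_rand() * W;
        int winner = nb[0];
        for (size_t k = 0; k < nb.size(); ++k) {
          u -= mut[nb[k]] ? r : 1.0;
          if (u <= 0.0) { winner = nb[k]; break; }
        }
        if (mut[dying] != mut[winner]) {
          n_mut += mut[winner] ? 1 : -1;
          mut[dying] = mut[winner];
        }
      }
    }
    if (n_mut == n) ++n_fixed;
  }
  return n_fixed;
}
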