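#include <Rcpp.h>
using namespace Rcpp;

// Forward Wright-Fisher evolution of phased haplotypes with recombination.
//
// hap: 2N x M binary matrix (rows 2i, 2i+1 are individual i's haplotypes),
// cm:  per-marker genetic position (centiMorgan), ascending within each
//      chromosome block, chr: integer chromosome id per marker.
// n_traj: diploid population size per generation (length = generations).
//
// Each generation: random mating (selfing allowed, as in the ideal
// Wright-Fisher population); each gamete is a recombinant mosaic of the
// parent's two haplotypes with a Poisson(L Morgans) number of crossovers per
// chromosome and a fair choice of starting haplotype. Uses R's RNG, so
// results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix wf_evolve(IntegerMatrix hap, NumericVector cm, IntegerVector chr,
                        IntegerVector n_traj) {
  const int M = hap.ncol();
  int n_cur = hap.nrow() / 2;

  // chromosome blocks
  std::vector<int> block_start, block_end; // inclusive marker ranges
  block_start.push_back(0);
  for (int j = 1; j < M; ++j) {
    if (chr[j] != chr[j - 1]) {
      block_end.push_back(j - 1);
      block_start.push_back(j);
    }
  }
  block_end.push_back(M - 1);
  const int n_blocks = block_start.size();

  IntegerMatrix cur = clone(hap);
  for (int g = 0; g < n_traj.size(); ++g) {
    const int n_next = n_traj[g];
    IntegerMatrix nxt(2 * n_next, M);
    for (int i = 0; i < n_next; ++i) {
      for (int par = 0; par < 2; ++par) {
        const int p = (int)(unif_rand() * n_cur); // parent individual
        const int row0 = 2 * p, row1 = 2 * p + 1;
        const int out = 2 * i + par;
        for (int b = 0; b < n_blocks; ++b) {
          const int s = block_start[b], e = block_end[b];
          const double len_m = (cm[e] - cm[s]) / 100.0; // Morgans
          const int n_x = (int)R::rpois(len_m);
          std::vector<double> bks(n_x);
          for (int k = 0; k < n_x; ++k)
            bks[k] = cm[s] + unif_rand() * (cm[e] - cm[s]);
          std::sort(bks.begin(), bks.end());
          int which_h = (unif_rand() < 0.5) ? 0 : 1;
          int bk = 0;
          for (int j = s; j <= e; ++j) {
            while (bk < n_x && bks[bk] < cm[j]) {
              which_h = 1 - which_h;
              ++bk;
            }
            nxt(out, j) = which_h ? cur(row1, j) : cur(row0, j);
          }
        }
      }
    }
    cur = nxt;
    n_cur = n_next;
  }
  return cur;
}
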