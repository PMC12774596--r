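#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Batch meiotic gamete simulation for a diploid parent.
//
// Crossover counts per chromosome are Poisson with mean length_kb * cm_per_kb / 100
// (no interference); breakpoint positions are uniform on the chromosome; the
// starting chromatid is chosen with probability 1/2 independently per chromosome.
// Uses R's RNG so results are reproducible under set.seed().
//
// h1, h2      integer origin vectors over all markers (0 = BY, 1 = CENPK)
// chrom_id    0-based chromosome index per marker; markers sorted by (chrom, pos)
// pos         marker positions in bp (1-based coordinates)
// chrom_len   chromosome lengths in bp
// [[Rcpp::export]]
IntegerMatrix meiosis_batch_cpp(int n, IntegerVector h1, IntegerVector h2,
                                IntegerVector chrom_id, NumericVector pos,
                                NumericVector chrom_len, double cm_per_kb) {
  const int m = h1.size();
  const int n_chrom = chrom_len.size();
  IntegerMatrix out(n, m);

  std::vector<int> first(n_chrom, -1), last(n_chrom, -1);
  for (int j = 0; j < m; ++j) {
    int c = chrom_id[j];
    if (c < 0 || c >= n_chrom) stop("chromosome index out of range");
    if (first[c] < 0) first[c] = j;
    last[c] = j;
  }

  std::vector<double> bp;
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < n_chrom; ++c) {
      if (first[c] < 0) continue;
      double mean_cx = chrom_len[c] / 1000.0 * cm_per_kb / 100.0;
      int ncx = mean_cx > 0 ? (int) R::rpois(mean_cx) : 0;
      int cur = (unif_rand() < 0.5) ? 0 : 1;
      if (ncx == 0) {
        for (int j = first[c]; j <= last[c]; ++j)
          out(i, j) = (cur == 0) ? h1[j] : h2[j];
      } else {
        bp.resize(ncx);
        for (int k = 0; k < ncx; ++k) bp[k] = unif_rand() * chrom_len[c];
        std::sort(bp.begin(), bp.end());
        int k = 0;
        for (int j = first[c]; j <= last[c]; ++j) {
          while (k < ncx && bp[k] < pos[j]) { cur = 1 - cur; ++k; }
          out(i, j) = (cur == 0) ? h1[j] : h2[j];
        }
      }
    }
  }
  return out;
}
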