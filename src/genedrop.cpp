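#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo gene dropping through a pedigree.  Founders receive unique
// allele labels; each offspring inherits one random allele from each parent.
// For a pair (i, j) the per-replicate statistic
//   x = [(p_i==p_j) + (p_i==m_j) + (m_i==p_j) + (m_i==m_j)] / 2
// has expectation A_ij; on the diagonal x = 1 + (p_i==m_i) has expectation
// 1 + F_i.  Returns the mean and its standard error per pair.  This is an
// independent estimator of the numerator relationship matrix used only as a
// test oracle for the tabular recursion.
// [[Rcpp::export(name = ".gene_drop_A")]]
List gene_drop_A(IntegerVector sire, IntegerVector dam, int nrep) {
  const int n = sire.size();
  std::vector<int> pat(n), mat(n);
  std::vector<double> sum(n * n, 0.0), sumsq(n * n, 0.0);

  for (int r = 0; r < nrep; ++r) {
    int next_allele = 0;
    for (int i = 0; i < n; ++i) {
      int s = sire[i], d = dam[i];
      if (s == NA_INTEGER)
        pat[i] = next_allele++;
      else {
        int k = s - 1;
        pat[i] = (unif_rand() < 0.5) ? pat[k] : mat[k];
      }
      if (d == NA_INTEGER)
        mat[i] = next_allele++;
      else {
        int k = d - 1;
        mat[i] = (unif_rand() < 0.5) ? pat[k] : mat[k];
      }
    }
    for (int i = 0; i < n; ++i) {
      const int pi = pat[i], mi = mat[i];
      {
        double x = 1.0 + (pi == mi ? 1.0 : 0.0);
        sum[i * n + i] += x;
        sumsq[i * n + i] += x * x;
      }
      for (int j = i + 1; j < n; ++j) {
        const int pj = pat[j], mj = mat[j];
        double x = 0.5 * ((pi == pj) + (pi == mj) + (mi == pj) + (mi == mj));
        sum[i * n + j] += x;
        sumsq[i * n + j] += x * x;
      }
    }
  }

  NumericMatrix Ahat(n, n), SE(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double m = sum[i * n + j] / nrep;
      double v = sumsq[i * n + j] / nrep - m * m;
      if (v < 0) v = 0;
      double se = std::sqrt(v / nrep);
      Ahat(i, j) = Ahat(j, i) = m;
      SE(i, j) = SE(j, i) = se;
    }
  }
  return List::create(_["A"] = Ahat, _["se"] = SE);
}
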