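#include <Rcpp.h>
using namespace Rcpp;

// Windowed IBS-run IBD between haplotypes.
//
// For a pair of haplotypes sharing the focal allele, the posterior IBD
// probability at the focal SNP is
//   prior / (prior + (1 - prior) * q_run)
// where q_run is the probability of observing the uninterrupted IBS run
// around the focal SNP by chance (product of per-SNP chance-IBS
// probabilities, i.e. the breed's expected homozygosity at each SNP in the
// run). Runs extend at most half_window SNPs to each side, never across a
// chromosome boundary; missing alleles neither extend nor break a run.
// Pairs differing at the focal SNP (or missing there) get probability 0.

static double pair_ibd(const IntegerMatrix &A, int i, int j, int l,
                       int half_window, const NumericVector &chance,
                       const IntegerVector &chrom, double prior) {
  int ai = A(i, l), aj = A(j, l);
  if (ai == NA_INTEGER || aj == NA_INTEGER || ai != aj) return 0.0;
  int m = A.ncol();
  double q = chance[l];
  int cc = chrom[l];
  for (int k = l - 1; k >= 0 && k >= l - half_window; --k) {
    if (chrom[k] != cc) break;
    int bi = A(i, k), bj = A(j, k);
    if (bi == NA_INTEGER || bj == NA_INTEGER) continue;
    if (bi != bj) break;
    q *= chance[k];
  }
  for (int k = l + 1; k < m && k <= l + half_window; ++k) {
    if (chrom[k] != cc) break;
    int bi = A(i, k), bj = A(j, k);
    if (bi == NA_INTEGER || bj == NA_INTEGER) continue;
    if (bi != bj) break;
    q *= chance[k];
  }
  return prior / (prior + (1.0 - prior) * q);
}

// [[Rcpp::export]]
NumericMatrix ibd_ibs_run(IntegerMatrix A, int focal0, int half_window,
                          NumericVector chance, IntegerVector chrom,
                          double prior) {
  int n = A.nrow();
  NumericMatrix U(n, n);
  for (int i = 0; i < n; ++i) {
    U(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double u = pair_ibd(A, i, j, focal0, half_window, chance, chrom, prior);
      U(i, j) = u;
      U(j, i) = u;
    }
  }
  return U;
}

// Mean of the per-locus IBD matrices over the given loci (0-based).
// [[Rcpp::export]]
NumericMatrix ibd_ibs_run_mean(IntegerMatrix A, IntegerVector loci0,
                               int half_window, NumericVector chance,
                               IntegerVector chrom, double prior) {
  int n = A.nrow();
  int nl = loci0.size();
  NumericMatrix U(n, n);
  for (int li = 0; li < nl; ++li) {
    int l = loci0[li];
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        U(i, j) += pair_ibd(A, i, j, l, half_window, chance, chrom, prior);
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    U(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      U(i, j) /= nl;
      U(j, i) = U(i, j);
    }
  }
  return U;
}
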