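#include <Rcpp.h>
using namespace Rcpp;

// Mutual information matrix of all unmasked column pairs of a paired
// alignment, plus the mean MI over random row re-pairings (the shuffle
// null).  Residues are integer codes 1..21 (21 = gap).
//
// With the count-based pseudocount
//   f~_ij = (c_ij + eta/441) / (M + eta),
//   f~_i  = (c_i  + eta/21 ) / (M + eta),
// the joint marginalizes exactly to the pseudocounted marginal
// (sum_B f~_ij = f~_i, since 21 * eta/441 = eta/21), so
//   MI_ij = H_i + H_j - H_ij
// with plug-in entropies of the pseudocounted tables.  Entropy terms are
// indexed by the integer cell count, so each (i, j, shuffle) evaluation
// costs O(M) additions via a count -> f~ log f~ lookup table.
//
// The permutation for each shuffle repetition is drawn from R's RNG
// (Fisher-Yates with unif_rand), so results are governed by set.seed().
//
// [[Rcpp::export]]
List mi_shuffle_core(const IntegerMatrix& A, const IntegerMatrix& B,
                     double eta, int n_shuffles,
                     const LogicalVector& mask_a,
                     const LogicalVector& mask_b) {
  const int M = A.nrow();
  const int na = A.ncol();
  const int nb = B.ncol();
  if (B.nrow() != M) stop("paired matrices must have equal row counts");
  if (M < 1) stop("no paired rows");
  if ((int) mask_a.size() != na || (int) mask_b.size() != nb)
    stop("mask length mismatch");

  // count-indexed  f~ log f~  lookup tables
  std::vector<double> jterm(M + 1), mterm(M + 1);
  for (int c = 0; c <= M; ++c) {
    double fj = (c + eta / 441.0) / (M + eta);
    double fm = (c + eta / 21.0) / (M + eta);
    jterm[c] = fj > 0 ? fj * std::log(fj) : 0.0;
    mterm[c] = fm > 0 ? fm * std::log(fm) : 0.0;
  }

  // marginal entropies per column (invariant under shuffling)
  std::vector<double> Ha(na), Hb(nb);
  {
    std::vector<int> cnt(21);
    for (int i = 0; i < na; ++i) {
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int r = 0; r < M; ++r) cnt[A(r, i) - 1]++;
      double h = 0.0;
      for (int s = 0; s < 21; ++s) h -= mterm[cnt[s]];
      Ha[i] = h;
    }
    for (int j = 0; j < nb; ++j) {
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int r = 0; r < M; ++r) cnt[B(r, j) - 1]++;
      double h = 0.0;
      for (int s = 0; s < 21; ++s) h -= mterm[cnt[s]];
      Hb[j] = h;
    }
  }

  const double zero_term = jterm[0];  // contribution of an empty cell
  std::vector<int> cnt(441, 0);
  std::vector<int> codes(M);

  // A's columns pre-shifted to (symbol - 1) * 21, contiguous per column
  std::vector<int> acode((size_t) M * na);
  for (int i = 0; i < na; ++i)
    for (int r = 0; r < M; ++r)
      acode[(size_t) i * M + r] = (A(r, i) - 1) * 21;

  // joint entropy of pre-shifted a-column `ac` and b-column `bc`
  auto joint_H = [&](const int* ac, const int* bc) {
    for (int r = 0; r < M; ++r) {
      int code = ac[r] + bc[r] - 1;
      codes[r] = code;
      cnt[code]++;
    }
    double sum = 0.0;
    int nnz = 0;
    for (int r = 0; r < M; ++r) {
      int c = cnt[codes[r]];
      if (c > 0) {           // first visit to this cell
        sum += jterm[c];
        nnz++;
        cnt[codes[r]] = 0;   // reset for the next call
      }
    }
    sum += (441 - nnz) * zero_term;
    return -sum;
  };

  NumericMatrix mi(na, nb), null_mean(na, nb);
  std::fill(mi.begin(), mi.end(), NA_REAL);
  std::fill(null_mean.begin(), null_mean.end(), NA_REAL);

  std::vector<int> bcol(M);
  for (int j = 0; j < nb; ++j) {
    if (mask_b[j]) continue;
    for (int r = 0; r < M; ++r) bcol[r] = B(r, j);
    for (int i = 0; i < na; ++i) {
      if (mask_a[i]) continue;
      double v = Ha[i] + Hb[j] - joint_H(&acode[(size_t) i * M],
                                         bcol.data());
      mi(i, j) = v > 0 ? v : 0.0;
      null_mean(i, j) = 0.0;
    }
  }

  std::vector<int> perm(M);
  for (int s = 0; s < n_shuffles; ++s) {
    for (int r = 0; r < M; ++r) perm[r] = r;
    // Fisher-Yates using R's RNG
    for (int r = M - 1; r > 0; --r) {
      int k = (int) (unif_rand() * (r + 1));
      if (k > r) k = r;
      std::swap(perm[r], perm[k]);
    }
    for (int j = 0; j < nb; ++j) {
      if (mask_b[j]) continue;
      for (int r = 0; r < M; ++r) bcol[r] = B(perm[r], j);
      for (int i = 0; i < na; ++i) {
        if (mask_a[i]) continue;
        double v = Ha[i] + Hb[j] - joint_H(&acode[(size_t) i * M],
                                           bcol.data());
        null_mean(i, j) += (v > 0 ? v : 0.0);
      }
    }
  }
  if (n_shuffles > 0) {
    for (int i = 0; i < na; ++i)
      for (int j = 0; j < nb; ++j)
        if (!mask_a[i] && !mask_b[j]) null_mean(i, j) /= n_shuffles;
  }

  return List::create(_["mi"] = mi, _["null_mean"] = null_mean);
}
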