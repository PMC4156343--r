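#include <Rcpp.h>
using namespace Rcpp;

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// IUPAC code for an unordered pair of distinct bases (indices into BASES)
static char iupac_pair(int a, int b) {
  int lo = std::min(a, b), hi = std::max(a, b);
  if (lo == 0 && hi == 2) return 'R';  // A/G
  if (lo == 1 && hi == 3) return 'Y';  // C/T
  if (lo == 1 && hi == 2) return 'S';  // C/G
  if (lo == 0 && hi == 3) return 'W';  // A/T
  if (lo == 2 && hi == 3) return 'K';  // G/T
  return 'M';                          // A/C
}

// Reference-anchored consensus caller.  Per position: depth (substitution
// evidence + deletion evidence) below min_cov, or no base evidence at all,
// gives 'N'; otherwise the majority base, or the IUPAC code of majority +
// best alternative when the alternative has >= alt_min_reads reads and
// >= alt_fraction of total depth (both inclusive).  Ties are broken by
// higher summed base quality, then alphabetically.
// [[Rcpp::export]]
List consensus_cpp(IntegerMatrix cf, IntegerMatrix cr, IntegerVector del,
                   NumericMatrix qsum, int min_cov, double alt_fraction,
                   int alt_min_reads) {
  const int L = cf.ncol();
  std::string cons(L, 'N');
  IntegerVector depth_out(L);

  for (int i = 0; i < L; ++i) {
    int n[4];
    int dsub = 0;
    for (int b = 0; b < 4; ++b) { n[b] = cf(b, i) + cr(b, i); dsub += n[b]; }
    const int depth = dsub + del[i];
    depth_out[i] = depth;
    if (depth < min_cov || dsub == 0) continue;  // stays 'N'

    int M = 0;
    for (int b = 1; b < 4; ++b) {
      if (n[b] > n[M] ||
          (n[b] == n[M] && qsum(b, i) > qsum(M, i)))
        M = b;
    }
    int A = -1;
    for (int b = 0; b < 4; ++b) {
      if (b == M || n[b] == 0) continue;
      if (A < 0 || n[b] > n[A] ||
          (n[b] == n[A] && (qsum(b, i) > qsum(A, i) ||
                            (qsum(b, i) == qsum(A, i) && b < A))))
        A = b;
    }
    if (A >= 0 && n[A] >= alt_min_reads &&
        (double) n[A] + 1e-9 >= alt_fraction * depth)
      cons[i] = iupac_pair(M, A);
    else
      cons[i] = BASES[M];
  }
  return List::create(_["seq"] = cons, _["depth"] = depth_out);
}

// Per-site top-two allele summary restricted to candidate variant sites
// (total depth >= min_cov and second allele count >= min_alt).
// Positions are 1-based.
// [[Rcpp::export]]
DataFrame variant_candidates_cpp(IntegerMatrix cf, IntegerMatrix cr,
                                 NumericMatrix qsum, IntegerVector del,
                                 int min_cov, int min_alt) {
  const int L = cf.ncol();
  std::vector<int> pos, depth, n1, n2, n2f, n2r, df, dr, nall;
  std::vector<double> q1, q2;
  std::vector<std::string> a1, a2;

  for (int i = 0; i < L; ++i) {
    int n[4], f[4];
    int dsub = 0, dfwd = 0;
    for (int b = 0; b < 4; ++b) {
      f[b] = cf(b, i);
      n[b] = f[b] + cr(b, i);
      dsub += n[b];
      dfwd += f[b];
    }
    const int dtot = dsub + del[i];
    if (dtot < min_cov) continue;
    int M = 0;
    for (int b = 1; b < 4; ++b)
      if (n[b] > n[M] || (n[b] == n[M] && qsum(b, i) > qsum(M, i))) M = b;
    int A = -1;
    for (int b = 0; b < 4; ++b) {
      if (b == M || n[b] == 0) continue;
      if (A < 0 || n[b] > n[A] ||
          (n[b] == n[A] && qsum(b, i) > qsum(A, i)))
        A = b;
    }
    if (A < 0 || n[A] < min_alt) continue;
    int nal = 0;
    for (int b = 0; b < 4; ++b) if (n[b] >= min_alt) ++nal;
    pos.push_back(i + 1);
    depth.push_back(dtot);
    a1.push_back(std::string(1, BASES[M]));
    a2.push_back(std::string(1, BASES[A]));
    n1.push_back(n[M]);
    n2.push_back(n[A]);
    n2f.push_back(cf(A, i));
    n2r.push_back(cr(A, i));
    df.push_back(dfwd + 0);  // forward substitution depth
    dr.push_back(dsub - dfwd);
    q1.push_back(n[M] > 0 ? qsum(M, i) / n[M] : NA_REAL);
    q2.push_back(n[A] > 0 ? qsum(A, i) / n[A] : NA_REAL);
    nall.push_back(nal);
  }
  return DataFrame::create(
      _["pos"] = pos, _["depth"] = depth, _["allele_a"] = a1,
      _["allele_b"] = a2, _["n1"] = n1, _["n2"] = n2, _["n2_fwd"] = n2f,
      _["n2_rev"] = n2r, _["depth_fwd"] = df, _["depth_rev"] = dr,
      _["qual_a"] = q1, _["qual_b"] = q2, _["n_alleles"] = nall,
      _["stringsAsFactors"] = false);
}
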