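#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// Paired-end read simulator.  Fragments are drawn uniformly from a randomly
// chosen haplotype; insert length ~ Normal(insert_mean, insert_sd) truncated
// to [read_len, haplotype length].  Mate 1 is the forward strand of the
// fragment's left end, mate 2 the reverse complement of its right end.
// Per-base error rate is linear from e_start (cycle 1) to e_end (last
// cycle); the quality string encodes the true error rate as PHRED+33.
// Uses R's RNG so results are reproducible via set.seed().
// [[Rcpp::export]]
List simulate_reads_cpp(std::string hapA, std::string hapB, int n_pairs,
                        int read_len, double insert_mean, double insert_sd,
                        double e_start, double e_end) {
  const char BASES[4] = {'A', 'C', 'G', 'T'};
  // per-cycle error rates and the shared quality string
  std::vector<double> err(read_len);
  std::string qual(read_len, '!');
  for (int j = 0; j < read_len; ++j) {
    double f = (read_len > 1) ? (double) j / (read_len - 1) : 0.0;
    double e = e_start + (e_end - e_start) * f;
    err[j] = e;
    int q = (int) std::lround(-10.0 * std::log10(std::max(e, 1e-6)));
    if (q > 41) q = 41;
    if (q < 2) q = 2;
    qual[j] = (char) (q + 33);
  }

  CharacterVector r1(n_pairs), r2(n_pairs);
  IntegerVector hap(n_pairs), start(n_pairs), insert(n_pairs);

  for (int i = 0; i < n_pairs; ++i) {
    const bool useA = unif_rand() < 0.5;
    const std::string& h = useA ? hapA : hapB;
    const int L = (int) h.size();
    int ins = (int) std::lround(R::rnorm(insert_mean, insert_sd));
    if (ins < read_len) ins = read_len;
    if (ins > L) ins = L;
    int s0 = (int) std::floor(unif_rand() * (L - ins + 1));
    if (s0 > L - ins) s0 = L - ins;

    std::string m1 = h.substr(s0, read_len);
    std::string m2 = revcomp_str(h.substr(s0 + ins - read_len, read_len));
    for (int j = 0; j < read_len; ++j) {
      if (unif_rand() < err[j]) {
        char c = m1[j];
        char nc;
        do { nc = BASES[(int) std::floor(unif_rand() * 4.0)]; } while (nc == c);
        m1[j] = nc;
      }
      if (unif_rand() < err[j]) {
        char c = m2[j];
        char nc;
        do { nc = BASES[(int) std::floor(unif_rand() * 4.0)]; } while (nc == c);
        m2[j] = nc;
      }
    }
    r1[i] = m1;
    r2[i] = m2;
    hap[i] = useA ? 1 : 2;
    start[i] = s0 + 1;
    insert[i] = ins;
  }

  return List::create(_["r1"] = r1, _["r2"] = r2, _["qual"] = qual,
                      _["hap"] = hap, _["start"] = start,
                      _["insert"] = insert);
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = revcomp_str(as<std::string>(x[i]));
  return out;
}
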