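#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Seed index: sorted (2-bit k-mer code << 32 | position) over the reference.
// ---------------------------------------------------------------------------

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

struct SeedIndex {
  std::vector<uint64_t> entries;  // (code << 32) | pos, sorted
  int k;
};

static void build_index(const std::string& ref, int k, SeedIndex& idx) {
  idx.k = k;
  idx.entries.clear();
  const int L = (int) ref.size();
  if (L < k) return;
  idx.entries.reserve(L);
  uint64_t code = 0;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int valid = 0;  // number of consecutive valid bases ending at i
  for (int i = 0; i < L; ++i) {
    int b = base_code(ref[i]);
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t) b) & mask;
    if (++valid >= k)
      idx.entries.push_back((code << 32) | (uint64_t) (i - k + 1));
  }
  std::sort(idx.entries.begin(), idx.entries.end());
}

// find reference positions of a k-mer code; returns [lo, hi) into entries
static inline void index_lookup(const SeedIndex& idx, uint64_t code,
                                size_t& lo, size_t& hi) {
  uint64_t key_lo = code << 32;
  uint64_t key_hi = (code + 1) << 32;
  lo = std::lower_bound(idx.entries.begin(), idx.entries.end(), key_lo) -
       idx.entries.begin();
  hi = std::lower_bound(idx.entries.begin(), idx.entries.end(), key_hi) -
       idx.entries.begin();
}

// ---------------------------------------------------------------------------
// Banded semi-global alignment.  The whole read (minus end overhang, which is
// soft-clipped) is aligned against the reference with free start/end on the
// reference side, restricted to diagonals within +/- band of the candidate
// diagonal d (d = ref position aligned to read position 0).  Unit costs:
// match 0, mismatch mm, read insertion ci, deletion cd.
// ---------------------------------------------------------------------------

struct AlnResult {
  bool ok = false;
  int cost = 0, refstart = 0, refend = 0;
  int matches = 0, cols = 0, qs = 0, qe = 0;
  std::string cigar;
};

static void cigar_push(std::string& cg, int n, char op) {
  if (n > 0) { cg += std::to_string(n); cg += op; }
}

static AlnResult banded_align(const char* ref, int L, const std::string& q,
                              int d, int b, int mm, int ci, int cd,
                              bool want_cigar) {
  AlnResult res;
  const int m = (int) q.size();
  const int qs = std::max(0, -d);
  const int qe = std::min(m, L - d);
  if (qe - qs <= 0) return res;
  const int n = qe - qs;
  const int dd = d + qs;         // ref position aligned to sub-read position 0
  const int W = 2 * b + 1;
  const int INF = 1 << 28;

  static std::vector<int> D;
  static std::vector<unsigned char> P;
  D.assign((size_t) (n + 1) * W, INF);
  P.assign((size_t) (n + 1) * W, 0);

  for (int c = 0; c < W; ++c) {
    int j = dd - b + c;
    if (j >= 0 && j <= L) D[c] = 0;  // free start on the reference
  }
  for (int i = 1; i <= n; ++i) {
    const char qc = q[qs + i - 1];
    const bool qv = base_code(qc) >= 0;
    const size_t base = (size_t) i * W;
    const int off = i + dd - b;  // j at c = 0
    for (int c = 0; c < W; ++c) {
      const int j = off + c;
      if (j < 0 || j > L) continue;
      int best = INF;
      unsigned char dir = 0;
      if (j >= 1) {
        int pc = D[base - W + c];
        if (pc < INF) {
          int v = pc + ((qv && ref[j - 1] == qc) ? 0 : mm);
          if (v < best) { best = v; dir = 1; }
        }
      }
      if (c + 1 < W) {  // insertion in read (consumes read only)
        int pc = D[base - W + c + 1];
        if (pc < INF && pc + ci < best) { best = pc + ci; dir = 2; }
      }
      if (c >= 1 && j >= 1) {  // deletion (consumes reference only)
        int pc = D[base + c - 1];
        if (pc < INF && pc + cd < best) { best = pc + cd; dir = 3; }
      }
      D[base + c] = best;
      P[base + c] = dir;
    }
  }

  const size_t basen = (size_t) n * W;
  int bestc = -1, best = INF;
  for (int c = 0; c < W; ++c) {
    int j = n + dd - b + c;
    if (j < 0 || j > L) continue;
    if (D[basen + c] < best) { best = D[basen + c]; bestc = c; }
  }
  if (bestc < 0) return res;

  // traceback; record per-column ops with match/mismatch distinguished
  int i = n, c = bestc, j = n + dd - b + bestc;
  std::string ops;  // reversed: 'M' match, 'X' mismatch, 'I', 'D'
  while (i > 0) {
    unsigned char dir = P[(size_t) i * W + c];
    if (dir == 1) {
      char qc = q[qs + i - 1];
      ops += (base_code(qc) >= 0 && ref[j - 1] == qc) ? 'M' : 'X';
      --i; --j;
    } else if (dir == 2) {
      ops += 'I'; --i; ++c;
    } else if (dir == 3) {
      ops += 'D'; --c; --j;
    } else {
      break;  // free start cell
    }
  }
  std::string fwd(ops.rbegin(), ops.rend());
  int refstart = j;

  // soft-clip alignment ends whose running match(+1)/mismatch,indel(-2)
  // score dips below -TRIM_DROP: tails of reads that run off into
  // sequence absent from the reference (or across an unmodelled indel)
  // align as dense mismatch stretches and would otherwise contaminate
  // the pileup with systematic false alleles
  const int TRIM_DROP = 5;
  auto trim_scan = [&](const std::string& v, bool from_left,
                       int& cut_cols) {
    int score = 0, minv = 0, mini = -1;
    const int nn = (int) v.size();
    for (int t = 0; t < nn; ++t) {
      char op = from_left ? v[t] : v[nn - 1 - t];
      score += (op == 'M') ? 1 : -2;
      if (score < minv) { minv = score; mini = t; }
    }
    cut_cols = (minv <= -TRIM_DROP) ? mini + 1 : 0;
  };
  int cutL = 0, cutR = 0;
  trim_scan(fwd, true, cutL);
  if (cutL < (int) fwd.size())
    trim_scan(fwd.substr(cutL), false, cutR);
  else
    cutL = (int) fwd.size();
  std::string body = fwd.substr(cutL, fwd.size() - cutL - cutR);
  // columns consumed by the clipped ends
  int readL = 0, refL = 0, readR = 0, refR = 0;
  for (int t = 0; t < cutL; ++t) {
    char op = fwd[t];
    if (op != 'D') ++readL;
    if (op != 'I') ++refL;
  }
  for (int t = 0; t < cutR; ++t) {
    char op = fwd[fwd.size() - 1 - t];
    if (op != 'D') ++readR;
    if (op != 'I') ++refR;
  }
  // drop clip-adjacent D/I columns left dangling after the trim
  while (!body.empty() && (body.front() == 'D' || body.front() == 'I')) {
    if (body.front() == 'D') ++refL; else ++readL;
    body.erase(body.begin());
  }
  while (!body.empty() && (body.back() == 'D' || body.back() == 'I')) {
    if (body.back() == 'D') ++refR; else ++readR;
    body.pop_back();
  }
  if (body.empty()) return res;

  int matches = 0;
  for (char op : body) if (op == 'M') ++matches;
  res.ok = true;
  res.cost = best;  // cost of the full (untrimmed) semi-global alignment
  res.refstart = refstart + refL;
  res.refend = (n + dd - b + bestc) - refR;
  res.matches = matches;
  res.cols = (int) body.size();
  res.qs = qs + readL;
  res.qe = qe - readR;
  if (want_cigar) {
    std::string cg;
    cigar_push(cg, res.qs, 'S');
    int run = 0; char cur = 0;
    for (char opx : body) {
      char op = (opx == 'X') ? 'M' : opx;
      if (op == cur) ++run;
      else { cigar_push(cg, run, cur ? cur : 'M'); cur = op; run = 1; }
    }
    cigar_push(cg, run, cur);
    cigar_push(cg, m - res.qe, 'S');
    res.cigar = cg;
  }
  return res;
}

static std::string revcomp_local(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'C': c = 'G'; break;
      case 'G': c = 'C'; break; case 'T': c = 'A'; break;
      default:  c = 'N';
    }
  }
  return r;
}

// candidate diagonals (with votes) for one oriented read sequence
static void seed_candidates(const SeedIndex& idx, const std::string& s,
                            int max_hits_per_seed,
                            std::vector<int>& diags) {
  const int k = idx.k;
  const int m = (int) s.size();
  if (m < k) return;
  std::vector<int> offs;
  const int stride = std::max(1, k / 2);
  for (int off = 0; off + k <= m; off += stride) offs.push_back(off);
  if (offs.empty() || offs.back() != m - k) offs.push_back(m - k);
  for (int off : offs) {
    uint64_t code = 0;
    bool okm = true;
    for (int t = 0; t < k; ++t) {
      int b = base_code(s[off + t]);
      if (b < 0) { okm = false; break; }
      code = (code << 2) | (uint64_t) b;
    }
    if (!okm) continue;
    size_t lo, hi;
    index_lookup(idx, code, lo, hi);
    if (hi - lo > (size_t) max_hits_per_seed) continue;
    for (size_t t = lo; t < hi; ++t) {
      int pos = (int) (idx.entries[t] & 0xffffffffULL);
      diags.push_back(pos - off);
    }
  }
}

struct Cluster { int diag; int votes; };

// cluster sorted diagonals that lie within `tol` of each other
static void cluster_diags(std::vector<int>& diags, int tol,
                          std::vector<Cluster>& out) {
  if (diags.empty()) return;
  std::sort(diags.begin(), diags.end());
  size_t i = 0;
  while (i < diags.size()) {
    size_t j = i + 1;
    while (j < diags.size() && diags[j] - diags[j - 1] <= tol) ++j;
    // representative: most frequent diagonal in cluster
    int best = diags[i], bestn = 1, cur = diags[i], curn = 0;
    for (size_t t = i; t < j; ++t) {
      if (diags[t] == cur) ++curn;
      else { cur = diags[t]; curn = 1; }
      if (curn > bestn) { bestn = curn; best = cur; }
    }
    out.push_back({best, (int) (j - i)});
    i = j;
  }
}

struct Accepted {
  int strand;  // 0 fwd, 1 rev
  AlnResult a;
};

// Map a batch of reads against a single reference sequence.
// Returns one row per read; pos is the 1-based reference start of the
// reported alignment.  Reads mapping equally well (same minimal cost) to
// more than one accepted locus are flagged nonspecific.
// [[Rcpp::export]]
List map_batch_cpp(std::string ref, CharacterVector reads, int seed_len,
                   double band_fraction, int mismatch_cost,
                   int insertion_cost, int deletion_cost,
                   double length_fraction, double similarity_fraction,
                   int max_hits_per_seed, int max_candidates) {
  const int L = (int) ref.size();
  if (L == 0) stop("empty reference");
  SeedIndex idx;
  build_index(ref, seed_len, idx);
  const char* rc = ref.c_str();

  const int nr = (int) reads.size();
  LogicalVector mapped(nr), nonspec(nr);
  IntegerVector pos(nr), cost(nr), matches(nr), cols(nr), nbest(nr);
  CharacterVector strand(nr), cigar(nr);
  NumericVector identity(nr), frac_aligned(nr);

  std::vector<int> diags;
  std::vector<Cluster> clusters;
  std::vector<Accepted> acc;

  for (int r = 0; r < nr; ++r) {
    const std::string fwd = as<std::string>(reads[r]);
    const int m = (int) fwd.size();
    const int b = std::max(6, (int) std::ceil(band_fraction * m));
    const std::string rev = revcomp_local(fwd);
    acc.clear();

    for (int st = 0; st < 2; ++st) {
      const std::string& s = st ? rev : fwd;
      diags.clear(); clusters.clear();
      seed_candidates(idx, s, max_hits_per_seed, diags);
      cluster_diags(diags, std::max(1, b / 2), clusters);
      std::sort(clusters.begin(), clusters.end(),
                [](const Cluster& x, const Cluster& y) {
                  return x.votes > y.votes;
                });
      int ncand = std::min((int) clusters.size(), max_candidates);
      for (int ci = 0; ci < ncand; ++ci) {
        AlnResult a = banded_align(rc, L, s, clusters[ci].diag, b,
                                   mismatch_cost, insertion_cost,
                                   deletion_cost, true);
        if (!a.ok || a.cols == 0) continue;
        double ident = (double) a.matches / a.cols;
        double frac = (double) (a.qe - a.qs) / m;
        if (frac + 1e-9 < length_fraction) continue;
        if (ident + 1e-9 < similarity_fraction) continue;
        // drop duplicates of an already accepted locus
        bool dup = false;
        for (auto& e : acc)
          if (e.strand == st && std::abs(e.a.refstart - a.refstart) <= b) {
            dup = true;
            if (a.cost < e.a.cost) e.a = a;  // keep the better one
            break;
          }
        if (!dup) acc.push_back({st, a});
      }
    }

    if (acc.empty()) { mapped[r] = false; continue; }
    int best = acc[0].a.cost;
    for (auto& e : acc) best = std::min(best, e.a.cost);
    int n_best = 0;
    const Accepted* rep = nullptr;
    for (auto& e : acc) {
      if (e.a.cost == best) {
        ++n_best;
        if (!rep || e.strand < rep->strand ||
            (e.strand == rep->strand && e.a.refstart < rep->a.refstart))
          rep = &e;
      }
    }
    mapped[r] = true;
    pos[r] = rep->a.refstart + 1;
    strand[r] = rep->strand ? "-" : "+";
    cigar[r] = rep->a.cigar;
    cost[r] = rep->a.cost;
    matches[r] = rep->a.matches;
    cols[r] = rep->a.cols;
    identity[r] = (double) rep->a.matches / rep->a.cols;
    frac_aligned[r] = (double) (rep->a.qe - rep->a.qs) / m;
    nbest[r] = n_best;
    nonspec[r] = n_best > 1;
  }

  return List::create(
      _["mapped"] = mapped, _["pos"] = pos, _["strand"] = strand,
      _["cigar"] = cigar, _["cost"] = cost, _["matches"] = matches,
      _["cols"] = cols, _["identity"] = identity,
      _["frac_aligned"] = frac_aligned, _["n_best"] = nbest,
      _["nonspecific"] = nonspec);
}

// All accepted local matches of library elements against a subject sequence
// (for repeat-library masking).  Returns 1-based [start, end] intervals.
// [[Rcpp::export]]
DataFrame match_library_cpp(std::string subject, CharacterVector queries,
                            int seed_len, double band_fraction,
                            int mismatch_cost, int insertion_cost,
                            int deletion_cost, int min_match,
                            double min_identity, int max_hits_per_seed) {
  const int L = (int) subject.size();
  SeedIndex idx;
  build_index(subject, seed_len, idx);
  const char* rc = subject.c_str();

  std::vector<int> qidx, start, end;
  std::vector<int> diags;
  std::vector<Cluster> clusters;

  for (int qi = 0; qi < (int) queries.size(); ++qi) {
    const std::string fwd = as<std::string>(queries[qi]);
    const int m = (int) fwd.size();
    const int b = std::max(6, (int) std::ceil(band_fraction * m));
    const std::string rev = revcomp_local(fwd);
    for (int st = 0; st < 2; ++st) {
      const std::string& s = st ? rev : fwd;
      diags.clear(); clusters.clear();
      seed_candidates(idx, s, max_hits_per_seed, diags);
      cluster_diags(diags, std::max(1, b / 2), clusters);
      for (auto& cl : clusters) {
        AlnResult a = banded_align(rc, L, s, cl.diag, b, mismatch_cost,
                                   insertion_cost, deletion_cost, false);
        if (!a.ok || a.cols == 0) continue;
        double ident = (double) a.matches / a.cols;
        if (a.refend - a.refstart < min_match) continue;
        if (ident + 1e-9 < min_identity) continue;
        qidx.push_back(qi + 1);
        start.push_back(a.refstart + 1);
        end.push_back(a.refend);
      }
    }
  }
  return DataFrame::create(_["query"] = qidx, _["start"] = start,
                           _["end"] = end);
}
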