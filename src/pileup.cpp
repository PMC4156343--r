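#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

static std::string revcomp_s(const std::string& s) {
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

struct IndelRec { int fwd = 0, rev = 0; double qsum = 0; int nq = 0; };

// Column-wise pileup over a single reference sequence.
// pos is 1-based; cigar uses M/I/D/S; seq and qual are in original read
// orientation and are reverse-complemented / reversed here for minus-strand
// alignments.  Insertions are anchored at the 1-based position of the
// preceding reference base (VCF-style); deletions at their first deleted
// base, with the deleted length as allele.
// [[Rcpp::export]]
List pileup_cpp(int ref_len, IntegerVector pos, CharacterVector cigar,
                CharacterVector seq, CharacterVector qual,
                LogicalVector minus, LogicalVector use) {
  IntegerMatrix cf(4, ref_len), cr(4, ref_len);
  IntegerVector del(ref_len), ins(ref_len);
  NumericMatrix qsum(4, ref_len);
  std::unordered_map<std::string, IndelRec> indels;

  const int n = (int) pos.size();
  for (int i = 0; i < n; ++i) {
    if (!use[i]) continue;
    std::string s = as<std::string>(seq[i]);
    std::string q = as<std::string>(qual[i]);
    const bool neg = minus[i];
    if (neg) {
      s = revcomp_s(s);
      std::reverse(q.begin(), q.end());
    }
    const std::string cg = as<std::string>(cigar[i]);
    int rp = pos[i] - 1;  // 0-based reference cursor
    size_t qp = 0;        // read cursor
    size_t ci = 0;
    while (ci < cg.size()) {
      int len = 0;
      while (ci < cg.size() && cg[ci] >= '0' && cg[ci] <= '9')
        len = len * 10 + (cg[ci++] - '0');
      if (ci >= cg.size()) stop("malformed CIGAR in record %d", i + 1);
      char op = cg[ci++];
      if (op == 'S' || op == 'H') {
        if (op == 'S') qp += len;
      } else if (op == 'M' || op == '=' || op == 'X') {
        if (rp + len > ref_len)
          stop("alignment beyond reference end at position %d", rp + len);
        for (int t = 0; t < len; ++t) {
          int b = base_idx(s[qp]);
          if (b >= 0) {
            if (neg) cr(b, rp)++; else cf(b, rp)++;
            qsum(b, rp) += (double) (q[qp] - 33);
          }
          ++rp; ++qp;
        }
      } else if (op == 'I') {
        int anchor = rp > 0 ? rp : 1;  // 1-based preceding base
        if (anchor > ref_len)
          stop("alignment beyond reference end at position %d", anchor);
        ins[anchor - 1]++;
        std::string key = "I\t" + std::to_string(anchor) + "\t" +
                          s.substr(qp, len);
        IndelRec& rec = indels[key];
        if (neg) rec.rev++; else rec.fwd++;
        for (int t = 0; t < len; ++t) {
          rec.qsum += (double) (q[qp + t] - 33);
          rec.nq++;
        }
        qp += len;
      } else if (op == 'D' || op == 'N') {
        if (rp + len > ref_len)
          stop("alignment beyond reference end at position %d", rp + len);
        for (int t = 0; t < len; ++t) del[rp + t]++;
        std::string key = "D\t" + std::to_string(rp + 1) + "\t" +
                          std::to_string(len);
        IndelRec& rec = indels[key];
        if (neg) rec.rev++; else rec.fwd++;
        if (qp > 0) { rec.qsum += (double) (q[qp - 1] - 33); rec.nq++; }
        rp += len;
      } else {
        stop("unsupported CIGAR op '%c' in record %d", op, i + 1);
      }
    }
  }

  // flatten the indel table
  const int ni = (int) indels.size();
  IntegerVector ipos(ni), ifwd(ni), irev(ni);
  CharacterVector itype(ni), iallele(ni);
  NumericVector iqual(ni);
  int t = 0;
  for (auto& kv : indels) {
    const std::string& key = kv.first;
    size_t p1 = key.find('\t'), p2 = key.find('\t', p1 + 1);
    itype[t] = key.substr(0, p1);
    int pv = 0;
    for (size_t c = p1 + 1; c < p2; ++c) pv = pv * 10 + (key[c] - '0');
    ipos[t] = pv;
    iallele[t] = key.substr(p2 + 1);
    ifwd[t] = kv.second.fwd;
    irev[t] = kv.second.rev;
    iqual[t] = kv.second.nq > 0 ? kv.second.qsum / kv.second.nq : NA_REAL;
    ++t;
  }

  return List::create(
      _["counts_fwd"] = cf, _["counts_rev"] = cr, _["del"] = del,
      _["ins"] = ins, _["qual_sum"] = qsum,
      _["indels"] = DataFrame::create(
          _["pos"] = ipos, _["type"] = itype, _["allele"] = iallele,
          _["fwd"] = ifwd, _["rev"] = irev, _["mean_qual"] = iqual,
          _["stringsAsFactors"] = false));
}

// Read base carried at each queried reference site by each alignment:
// "" if the site is not covered, "-" if deleted.
// [[Rcpp::export]]
CharacterMatrix read_bases_at_cpp(IntegerVector pos, CharacterVector cigar,
                                  CharacterVector seq, LogicalVector minus,
                                  IntegerVector sites) {
  const int n = (int) pos.size(), ns = (int) sites.size();
  CharacterMatrix out(n, ns);
  std::fill(out.begin(), out.end(), "");
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seq[i]);
    if (minus[i]) s = revcomp_s(s);
    const std::string cg = as<std::string>(cigar[i]);
    int rp = pos[i] - 1;
    size_t qp = 0, ci = 0;
    while (ci < cg.size()) {
      int len = 0;
      while (ci < cg.size() && cg[ci] >= '0' && cg[ci] <= '9')
        len = len * 10 + (cg[ci++] - '0');
      char op = cg[ci++];
      if (op == 'S') { qp += len; continue; }
      if (op == 'I') { qp += len; continue; }
      if (op == 'M' || op == '=' || op == 'X') {
        for (int t = 0; t < ns; ++t) {
          int st = sites[t] - 1;
          if (st >= rp && st < rp + len)
            out(i, t) = std::string(1, s[qp + (st - rp)]);
        }
        rp += len; qp += len;
      } else if (op == 'D' || op == 'N') {
        for (int t = 0; t < ns; ++t) {
          int st = sites[t] - 1;
          if (st >= rp && st < rp + len) out(i, t) = "-";
        }
        rp += len;
      }
    }
  }
  return out;
}

// reference bases consumed by each CIGAR ("" -> 0)
// [[Rcpp::export]]
IntegerVector ref_span_cpp(CharacterVector cigar) {
  const int n = (int) cigar.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const std::string cg = as<std::string>(cigar[i]);
    int span = 0, len = 0;
    for (char c : cg) {
      if (c >= '0' && c <= '9') { len = len * 10 + (c - '0'); continue; }
      if (c == 'M' || c == 'D' || c == 'N' || c == '=' || c == 'X')
        span += len;
      len = 0;
    }
    out[i] = span;
  }
  return out;
}
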