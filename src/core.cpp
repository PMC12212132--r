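#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// 2-bit nucleotide encoding; k <= 31 so a k-mer fits a uint64_t.
static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Enumerate canonical k-mers of seq into out (counts). Returns nothing.
static void count_canonical(const std::string& seq, int k,
                            std::unordered_map<uint64_t, uint32_t>& out) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  const int shift = 2 * (k - 1);
  for (size_t i = 0; i < seq.size(); ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++run >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      ++out[canon];
    }
  }
}

// [[Rcpp::export]]
List cpp_kmer_stats(CharacterVector read_seqs, CharacterVector asm_seqs,
                    int k, int min_mult) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  std::unordered_map<uint64_t, uint32_t> reads, asmk;
  for (R_xlen_t i = 0; i < read_seqs.size(); ++i)
    count_canonical(as<std::string>(read_seqs[i]), k, reads);
  for (R_xlen_t i = 0; i < asm_seqs.size(); ++i)
    count_canonical(as<std::string>(asm_seqs[i]), k, asmk);
  double read_total = (double)reads.size();
  double read_reliable = 0, shared_reliable = 0;
  for (auto& kv : reads) {
    if (kv.second >= (uint32_t)min_mult) {
      ++read_reliable;
      if (asmk.count(kv.first)) ++shared_reliable;
    }
  }
  double asm_total = (double)asmk.size(), asm_only = 0;
  for (auto& kv : asmk)
    if (!reads.count(kv.first)) ++asm_only;
  return List::create(
    _["read_kmers_total"] = read_total,
    _["read_kmers_reliable"] = read_reliable,
    _["asm_kmers_total"] = asm_total,
    _["asm_only_kmers"] = asm_only,
    _["shared_reliable"] = shared_reliable);
}

// Positions (0-based) of k-mers unique within each sequence and shared by
// both, as a 2-column matrix (pos1, pos2) sorted by pos1. Forward strand.
// [[Rcpp::export]]
IntegerMatrix cpp_unique_anchors(std::string s1, std::string s2, int k) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  auto scan = [k](const std::string& s,
                  std::unordered_map<uint64_t, int64_t>& m) {
    const uint64_t mask = (1ULL << (2 * k)) - 1;
    uint64_t fwd = 0; int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { run = 0; fwd = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        int64_t pos = (int64_t)(i + 1 - k);
        auto it = m.find(fwd);
        if (it == m.end()) m[fwd] = pos; else it->second = -1; // -1 = dup
      }
    }
  };
  std::unordered_map<uint64_t, int64_t> m1, m2;
  scan(s1, m1); scan(s2, m2);
  std::vector<std::pair<int, int>> pairs;
  for (auto& kv : m1) {
    if (kv.second < 0) continue;
    auto it = m2.find(kv.first);
    if (it != m2.end() && it->second >= 0)
      pairs.push_back({(int)kv.second, (int)it->second});
  }
  std::sort(pairs.begin(), pairs.end());
  IntegerMatrix out(pairs.size(), 2);
  for (size_t i = 0; i < pairs.size(); ++i) {
    out(i, 0) = pairs[i].first;
    out(i, 1) = pairs[i].second;
  }
  return out;
}

// Longest strictly increasing subsequence of y (input pre-sorted by the
// other coordinate). Returns 1-based indices of chain members.
// [[Rcpp::export]]
IntegerVector cpp_lis_chain(IntegerVector y) {
  int n = y.size();
  if (n == 0) return IntegerVector(0);
  std::vector<int> tails;       // index of smallest tail per length
  std::vector<int> parent(n, -1);
  for (int i = 0; i < n; ++i) {
    // strict increase: find first tail with y[tail] >= y[i]
    int lo = 0, hi = (int)tails.size();
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (y[tails[mid]] < y[i]) lo = mid + 1; else hi = mid;
    }
    if (lo > 0) parent[i] = tails[lo - 1];
    if (lo == (int)tails.size()) tails.push_back(i); else tails[lo] = i;
  }
  std::vector<int> chain;
  for (int i = tails.back(); i >= 0; i = parent[i]) chain.push_back(i + 1);
  std::reverse(chain.begin(), chain.end());
  return wrap(chain);
}

static inline int hamming_upto(const std::string& a, size_t ao,
                               const std::string& b, size_t bo,
                               size_t len, int maxmm) {
  int mm = 0;
  for (size_t i = 0; i < len; ++i) {
    if (a[ao + i] != b[bo + i] && ++mm > maxmm) return mm;
  }
  return mm;
}

struct SeedIndex {
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> idx;
  int k;
  void add(const std::string& s, int id, int stride) {
    if ((int)s.size() < k) return;
    int last = (int)s.size() - k;
    for (int off = 0; off <= last; off += stride) add_one(s, id, off);
    if (last % stride != 0) add_one(s, id, last);
  }
  void add_one(const std::string& s, int id, int off) {
    uint64_t code = 0;
    for (int j = 0; j < k; ++j) {
      int b = base2bits(s[off + j]);
      if (b < 0) return;
      code = (code << 2) | (uint64_t)b;
    }
    idx[code].push_back({id, off});
  }
};

// Greedy overlap-layout assembler for substitution-only long reads.
// Reads must be pre-ordered (length desc, id asc); seeds are exact k-mers
// sampled every `stride` bases, overlaps verified by Hamming distance at
// <= max_mismatch_frac. Returns contig sequences plus 1-based member read
// indices (into the given order).
// [[Rcpp::export]]
List cpp_greedy_assemble(CharacterVector reads, int min_overlap,
                         double max_mismatch_frac, int seed_k, int stride) {
  int n = reads.size();
  std::vector<std::string> rd(n);
  size_t maxlen = 0;
  for (int i = 0; i < n; ++i) {
    rd[i] = as<std::string>(reads[i]);
    maxlen = std::max(maxlen, rd[i].size());
  }
  SeedIndex S; S.k = seed_k;
  for (int i = 0; i < n; ++i) S.add(rd[i], i, stride);

  std::vector<bool> used(n, false);
  std::vector<std::string> contigs;
  std::vector<std::vector<int>> members;
  const uint64_t mask = (1ULL << (2 * seed_k)) - 1;

  for (int start = 0; start < n; ++start) {
    if (used[start]) continue;
    std::string contig = rd[start];
    std::vector<int> mem = {start};
    used[start] = true;

    // scan a window of the contig for seed hits; absorb contained reads,
    // collect best extension (largest overlap, tie -> smaller read id)
    auto scan = [&](long lo, long hi, bool right_side,
                    int& best_r, long& best_start, long& best_ov) {
      best_r = -1; best_start = 0; best_ov = -1;
      long clen = (long)contig.size();
      lo = std::max(0L, lo);
      hi = std::min(hi, clen - (long)seed_k);
      if (lo > hi) return;
      uint64_t code = 0; int run = 0;
      for (long p = lo; p <= hi + seed_k - 1 && p < clen; ++p) {
        int b = base2bits(contig[p]);
        if (b < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t)b) & mask;
        if (++run < seed_k) continue;
        long kpos = p - seed_k + 1;
        auto it = S.idx.find(code);
        if (it == S.idx.end()) continue;
        for (auto& ro : it->second) {
          int r = ro.first;
          if (used[r]) continue;
          long rs = kpos - (long)ro.second; // read start in contig coords
          long rlen = (long)rd[r].size();
          if (rs >= 0 && rs + rlen <= clen) {
            // contained: absorb
            int maxmm = (int)(max_mismatch_frac * rlen);
            if (hamming_upto(contig, rs, rd[r], 0, rlen, maxmm) <= maxmm) {
              used[r] = true; mem.push_back(r);
            }
          } else if (right_side && rs >= 0 && rs < clen) {
            long ov = clen - rs;
            if (ov < min_overlap) continue;
            if (ov < best_ov || (ov == best_ov && r >= best_r)) continue;
            int maxmm = (int)(max_mismatch_frac * ov);
            if (hamming_upto(contig, rs, rd[r], 0, ov, maxmm) <= maxmm) {
              best_ov = ov; best_r = r; best_start = rs;
            }
          } else if (!right_side && rs < 0 && rs + rlen <= clen) {
            long ov = rs + rlen;
            if (ov < min_overlap) continue;
            if (ov < best_ov || (ov == best_ov && r >= best_r)) continue;
            int maxmm = (int)(max_mismatch_frac * ov);
            if (hamming_upto(contig, 0, rd[r], -rs, ov, maxmm) <= maxmm) {
              best_ov = ov; best_r = r; best_start = rs;
            }
          }
        }
      }
    };

    bool grew = true;
    while (grew) {
      grew = false;
      long clen = (long)contig.size();
      int r; long rs, ov;
      scan(clen - 2L * (long)maxlen, clen, true, r, rs, ov);
      if (r >= 0) {
        contig += rd[r].substr(ov);
        used[r] = true; mem.push_back(r);
        grew = true;
        continue;
      }
      scan(0, 2L * (long)maxlen, false, r, rs, ov);
      if (r >= 0) {
        contig = rd[r].substr(0, (size_t)(-rs)) + contig;
        used[r] = true; mem.push_back(r);
        grew = true;
      }
    }
    contigs.push_back(contig);
    members.push_back(mem);
  }

  List memL(members.size());
  CharacterVector seqs(contigs.size());
  for (size_t i = 0; i < contigs.size(); ++i) {
    seqs[i] = contigs[i];
    std::vector<int> m = members[i];
    std::sort(m.begin(), m.end());
    IntegerVector mv(m.size());
    for (size_t j = 0; j < m.size(); ++j) mv[j] = m[j] + 1;
    memL[i] = mv;
  }
  return List::create(_["contigs"] = seqs, _["members"] = memL);
}

// Best ungapped hit of each query against a set of targets, by seed
// diagonal voting then Hamming over the clipped alignment. Returns a list
// of integer vectors (target, tstart0, qstart0, alen, mismatches); target
// is 0 when no seed hit. Forward strand only.
// [[Rcpp::export]]
IntegerMatrix cpp_map_ungapped(CharacterVector queries, CharacterVector targets,
                               int k, int stride) {
  int nt = targets.size();
  std::vector<std::string> tg(nt);
  SeedIndex S; S.k = k;
  for (int t = 0; t < nt; ++t) {
    tg[t] = as<std::string>(targets[t]);
    S.add(tg[t], t, 1);
  }
  int nq = queries.size();
  IntegerMatrix out(nq, 5);
  const size_t max_hits = 100; // skip hyper-repetitive seeds
  for (int q = 0; q < nq; ++q) {
    std::string qs = as<std::string>(queries[q]);
    std::map<std::pair<int, long>, int> votes;
    if ((int)qs.size() >= k) {
      int last = (int)qs.size() - k;
      std::vector<int> offs;
      for (int off = 0; off <= last; off += stride) offs.push_back(off);
      if (last % stride != 0) offs.push_back(last);
      for (int off : offs) {
        uint64_t code = 0; bool ok = true;
        for (int j = 0; j < k; ++j) {
          int b = base2bits(qs[off + j]);
          if (b < 0) { ok = false; break; }
          code = (code << 2) | (uint64_t)b;
        }
        if (!ok) continue;
        auto it = S.idx.find(code);
        if (it == S.idx.end() || it->second.size() > max_hits) continue;
        for (auto& ro : it->second)
          ++votes[{ro.first, (long)ro.second - off}];
      }
    }
    if (votes.empty()) { out(q, 0) = 0; continue; }
    std::pair<int, long> best; int bestv = -1;
    for (auto& kv : votes)
      if (kv.second > bestv) { bestv = kv.second; best = kv.first; }
    int t = best.first; long d = best.second;
    long qstart = std::max(0L, -d), tstart = std::max(0L, d);
    long alen = std::min((long)qs.size() - qstart, (long)tg[t].size() - tstart);
    int mm = hamming_upto(qs, qstart, tg[t], tstart, alen, (int)alen);
    out(q, 0) = t + 1;
    out(q, 1) = (int)tstart;
    out(q, 2) = (int)qstart;
    out(q, 3) = (int)alen;
    out(q, 4) = mm;
  }
  colnames(out) = CharacterVector::create("target", "tstart", "qstart",
                                          "alen", "mismatches");
  return out;
}
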