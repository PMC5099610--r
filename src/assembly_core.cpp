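// Read-level cores: substitution error injection, quality trimming,
// in-silico k-mer coverage normalization, greedy overlap-layout-consensus
// assembly with vote-based consensus, and gapless k-mer-seeded mapping.
// All randomness goes through R's RNG so set.seed() controls everything.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  }
  return -1;
}

static inline char bit2base(int b) { return "ACGT"[b]; }

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  }
  return 'N';
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp(c);
  return r;
}

// [[Rcpp::export(name = ".cpp_revcomp")]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}

// Uniform per-base substitutions at err_rate (uses R RNG).
// [[Rcpp::export(name = ".cpp_inject_substitutions")]]
CharacterVector cpp_inject_substitutions(CharacterVector seqs, double err_rate) {
  RNGScope scope;
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if (err_rate > 0) {
      for (size_t j = 0; j < s.size(); ++j) {
        if (unif_rand() < err_rate) {
          int b = base2bit(s[j]);
          if (b < 0) continue;
          int shift = 1 + (int)(unif_rand() * 3.0);
          if (shift > 3) shift = 3;
          s[j] = bit2base((b + shift) & 3);
        }
      }
    }
    out[i] = s;
  }
  return out;
}

// Trimmomatic-style LEADING/TRAILING/SLIDINGWINDOW/MINLEN on phred+33.
// Returns list(seq, qual, keep).
// [[Rcpp::export(name = ".cpp_trim_reads")]]
List cpp_trim_reads(CharacterVector seqs, CharacterVector quals,
                    int leading_q, int trailing_q,
                    int window, int window_q, int min_len) {
  R_xlen_t n = seqs.size();
  CharacterVector oseq(n), oqual(n);
  LogicalVector keep(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q = as<std::string>(quals[i]);
    int lo = 0, hi = (int)s.size();
    while (lo < hi && (q[lo] - 33) < leading_q) ++lo;
    while (hi > lo && (q[hi - 1] - 33) < trailing_q) --hi;
    // sliding window: cut at first window with mean quality < window_q,
    // then trim remaining low-quality tail bases (as Trimmomatic does).
    if (hi - lo >= window) {
      int sum = 0;
      for (int j = lo; j < lo + window; ++j) sum += q[j] - 33;
      int cut = -1;
      for (int j = lo;; ++j) {
        if (sum < window_q * window) { cut = j; break; }
        if (j + window >= hi) break;
        sum += (q[j + window] - 33) - (q[j] - 33);
      }
      if (cut >= 0) {
        hi = cut;
        while (hi > lo && (q[hi - 1] - 33) < window_q) --hi;
      }
    }
    int len = hi - lo;
    if (len >= min_len) {
      oseq[i] = s.substr(lo, len);
      oqual[i] = q.substr(lo, len);
      keep[i] = true;
    } else {
      oseq[i] = "";
      oqual[i] = "";
      keep[i] = false;
    }
  }
  return List::create(_["seq"] = oseq, _["qual"] = oqual, _["keep"] = keep);
}

static inline uint64_t canon(uint64_t fwd, uint64_t rev) {
  return fwd < rev ? fwd : rev;
}

// Streaming (diginorm-style) normalization: a read is kept if the median
// abundance of its canonical k-mers among *kept* reads so far is below
// target. Returns the logical keep vector; deterministic in input order.
// [[Rcpp::export(name = ".cpp_kmer_normalize_keep")]]
LogicalVector cpp_kmer_normalize_keep(CharacterVector seqs, int k, int target) {
  std::unordered_map<uint64_t, uint32_t> counts;
  counts.reserve(1 << 20);
  R_xlen_t n = seqs.size();
  LogicalVector keep(n);
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::vector<uint64_t> kms;
  std::vector<uint32_t> abund;
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int L = (int)s.size();
    kms.clear();
    if (L >= k) {
      uint64_t f = 0, r = 0;
      int valid = 0;
      for (int j = 0; j < L; ++j) {
        int b = base2bit(s[j]);
        if (b < 0) { valid = 0; f = 0; r = 0; continue; }
        f = ((f << 2) | (uint64_t)b) & mask;
        r = (r >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
        if (++valid >= k) kms.push_back(canon(f, r));
      }
    }
    if (kms.empty()) { keep[i] = true; continue; }
    abund.clear();
    for (uint64_t km : kms) {
      auto it = counts.find(km);
      abund.push_back(it == counts.end() ? 0u : it->second);
    }
    std::nth_element(abund.begin(), abund.begin() + abund.size() / 2, abund.end());
    uint32_t med = abund[abund.size() / 2];
    if (med < (uint32_t)target) {
      keep[i] = true;
      for (uint64_t km : kms) ++counts[km];
    } else {
      keep[i] = false;
    }
  }
  return keep;
}

// ---------------------------------------------------------------------------
// Greedy overlap-layout-consensus assembler.
//
// Reads (both orientations) are indexed by k-mers at a fixed stride. A
// contig is seeded from the first unused read and extended base-accurately
// to the right, then the structure is reverse-complemented and extended
// again. At each step candidate reads overlapping the contig end are found
// by seed lookup + offset voting and verified gaplessly against the current
// consensus; the candidate with the longest verified overlap that extends
// the contig wins (tie: lexicographically smaller read id). Reads fully
// contained in the contig are absorbed into the consensus votes. Extension
// stops at a branch point: when a second, well-supported extension base
// disagrees with the winning one (interspersed repeat boundary).
// ---------------------------------------------------------------------------

struct Contig {
  std::string cons;
  std::vector<std::array<uint16_t, 4>> votes;
};

static void contig_rc(Contig &C) {
  C.cons = revcomp(C.cons);
  std::reverse(C.votes.begin(), C.votes.end());
  for (auto &v : C.votes) {
    std::swap(v[0], v[3]);
    std::swap(v[1], v[2]);
  }
}

struct AsmIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<uint32_t>> idx; // (read<<10)|(pos<<1)|orient
};

// [[Rcpp::export(name = ".cpp_greedy_assemble")]]
List cpp_greedy_assemble(CharacterVector reads_in, CharacterVector ids_in,
                         int min_overlap, double min_identity,
                         int seed_k = 15, int seed_stride = 12) {
  int n = (int)reads_in.size();
  std::vector<std::string> fwd(n), rev(n), ids(n);
  int max_len = 0;
  for (int i = 0; i < n; ++i) {
    fwd[i] = as<std::string>(reads_in[i]);
    rev[i] = revcomp(fwd[i]);
    ids[i] = as<std::string>(ids_in[i]);
    max_len = std::max(max_len, (int)fwd[i].size());
  }
  if (max_len > 400) stop("greedy_assemble expects short reads (<= 400 bp)");
  const int k = seed_k;
  const uint64_t mask = (1ULL << (2 * k)) - 1;

  AsmIndex I;
  I.k = k;
  I.idx.reserve((size_t)n * 4);
  auto add_seed = [&](const std::string &s, int ri, int orient) {
    int L = (int)s.size();
    if (L < k) return;
    std::vector<int> positions;
    for (int p = 0; p + k <= L; p += seed_stride) positions.push_back(p);
    if (positions.empty() || positions.back() != L - k) positions.push_back(L - k);
    for (int p : positions) {
      uint64_t km = 0;
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        int b = base2bit(s[p + j]);
        if (b < 0) { ok = false; break; }
        km = (km << 2) | (uint64_t)b;
      }
      if (!ok) continue;
      I.idx[km & mask].push_back(((uint32_t)ri << 10) | ((uint32_t)p << 1) | orient);
    }
  };
  for (int i = 0; i < n; ++i) {
    add_seed(fwd[i], i, 0);
    add_seed(rev[i], i, 1);
  }

  std::vector<char> used(n, 0);

  // verify read (orient o) starting at contig offset off; region compared is
  // the intersection with current contig. Returns mismatches or -1 if over
  // budget. budget computed from compared length.
  auto mism_count = [&](const Contig &C, const std::string &r, long off,
                        long from, long to, long budget) -> long {
    long mm = 0;
    for (long p = from; p < to; ++p) {
      if (C.cons[p] != r[p - off]) {
        if (++mm > budget) return -1;
      }
    }
    return mm;
  };

  auto merge_read = [&](Contig &C, const std::string &r, long off) {
    long L = (long)r.size();
    long need = off + L;
    if ((long)C.cons.size() < need) {
      C.cons.resize(need, 'N');
      C.votes.resize(need, std::array<uint16_t, 4>{0, 0, 0, 0});
    }
    for (long p = off; p < need; ++p) {
      int b = base2bit(r[p - off]);
      if (b < 0) continue;
      if (C.votes[p][b] < 65535) C.votes[p][b]++;
      // recompute majority (lowest base index wins ties)
      int best = 0;
      for (int x = 1; x < 4; ++x)
        if (C.votes[p][x] > C.votes[p][best]) best = x;
      C.cons[p] = bit2base(best);
    }
  };

  struct Cand { int read; int orient; long off; long overlap; char ext; };

  // one rightward extension step; returns true if contig grew
  auto extend_right = [&](Contig &C) -> bool {
    long len = (long)C.cons.size();
    long lo = std::max(0L, len - (long)max_len - 10);
    // gather (read,orient,offset) vote counts from seeds in the end window
    std::unordered_map<uint64_t, int> ovotes;
    for (long p = lo; p + k <= len; ++p) {
      uint64_t km = 0;
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        int b = base2bit(C.cons[p + j]);
        if (b < 0) { ok = false; break; }
        km = (km << 2) | (uint64_t)b;
      }
      if (!ok) continue;
      auto it = I.idx.find(km & mask);
      if (it == I.idx.end()) continue;
      for (uint32_t e : it->second) {
        int ri = (int)(e >> 10);
        if (used[ri]) continue;
        int rp = (int)((e >> 1) & 0x1FF);
        int orient = (int)(e & 1);
        long off = p - rp;
        uint64_t key = (((uint64_t)ri << 2) | ((uint64_t)orient << 1)) << 32 ^
                       (uint64_t)(uint32_t)(off + (1L << 30));
        ovotes[key]++;
      }
    }
    // best offset per (read, orient)
    std::unordered_map<uint64_t, std::pair<long, int>> bestoff; // key ri*2+or
    for (auto &kv : ovotes) {
      uint64_t ro = kv.first >> 33; // ri*2 + orient
      long off = (long)(uint32_t)(kv.first & 0xFFFFFFFFULL) - (1L << 30);
      auto it = bestoff.find(ro);
      if (it == bestoff.end() || kv.second > it->second.second)
        bestoff[ro] = {off, kv.second};
    }
    std::vector<Cand> ext;
    std::vector<std::pair<int, long>> contained; // (read, off)
    for (auto &kv : bestoff) {
      int ri = (int)(kv.first >> 1);
      int orient = (int)(kv.first & 1);
      if (used[ri]) continue;
      long off = kv.second.first;
      const std::string &r = orient ? rev[ri] : fwd[ri];
      long L = (long)r.size();
      if (off < 0) continue; // handled by left phase
      long overlap = std::min(len - off, L);
      if (overlap < (long)min_overlap) continue;
      long budget = (long)((1.0 - min_identity) * (double)overlap);
      long mm = mism_count(C, r, off, off, off + overlap, budget);
      if (mm < 0) continue;
      if (off + L <= len) {
        contained.push_back({ri, off});
        merge_read(C, r, off);
        used[ri] = 1;
      } else {
        ext.push_back({ri, orient, off, overlap, r[len - off]});
      }
    }
    if (ext.empty()) return false;
    // branch check: tally extension bases (one vote per read)
    int support[5] = {0, 0, 0, 0, 0};
    for (auto &c : ext) {
      int b = base2bit(c.ext);
      support[b < 0 ? 4 : b]++;
    }
    int t1 = 0, t2 = 0;
    for (int x = 0; x < 4; ++x) {
      if (support[x] >= t1) { t2 = t1; t1 = support[x]; }
      else if (support[x] > t2) t2 = support[x];
    }
    if (t2 >= 2 && t2 * 10 >= 3 * (t1 + t2)) return false; // repeat branch
    // winner: longest overlap, tie -> smaller read id
    const Cand *best = nullptr;
    for (auto &c : ext) {
      if (!best || c.overlap > best->overlap ||
          (c.overlap == best->overlap && ids[c.read] < ids[best->read]))
        best = &c;
    }
    const std::string &r = best->orient ? rev[best->read] : fwd[best->read];
    merge_read(C, r, best->off);
    used[best->read] = 1;
    return true;
  };

  std::vector<std::string> contigs;
  std::vector<int> nreads;
  for (int s = 0; s < n; ++s) {
    if (used[s]) continue;
    Contig C;
    C.cons = fwd[s];
    C.votes.assign(C.cons.size(), std::array<uint16_t, 4>{0, 0, 0, 0});
    used[s] = 1;
    merge_read(C, fwd[s], 0); // votes for the seed read; merge_read resets majority
    int merged = 1;
    size_t before;
    while (true) { before = C.cons.size(); if (!extend_right(C)) break; ++merged; }
    contig_rc(C);
    while (true) { before = C.cons.size(); if (!extend_right(C)) break; ++merged; }
    contig_rc(C);
    (void)before;
    contigs.push_back(C.cons);
    nreads.push_back(merged);
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["sequence"] = wrap(contigs), _["n_reads"] = wrap(nreads));
}

// ---------------------------------------------------------------------------
// Gapless k-mer-seeded mapper. Refs are indexed at every position; queries
// are scanned at an adaptive stride in both orientations; (ref, diagonal)
// pairs are voted on and the top diagonals verified by ungapped comparison
// over the full query/ref intersection. Passing hits satisfy
// aligned_len >= min_len_frac * query_len and identity >= min_sim.
// If best_only, one best hit per query; otherwise best hit per (query, ref).
// Coordinates returned 0-based half-open on the reference; qstart/qend are
// on the reported strand of the query.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_map_seqs")]]
DataFrame cpp_map_seqs(CharacterVector refs_in, CharacterVector queries_in,
                       double min_len_frac, double min_sim,
                       bool best_only, int k = 15) {
  int nr = (int)refs_in.size();
  std::vector<std::string> refs(nr);
  std::unordered_map<uint64_t, std::vector<uint64_t>> ridx; // km -> (ref<<32|pos)
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  size_t total = 0;
  for (int i = 0; i < nr; ++i) { refs[i] = as<std::string>(refs_in[i]); total += refs[i].size(); }
  ridx.reserve(total);
  for (int i = 0; i < nr; ++i) {
    const std::string &s = refs[i];
    int L = (int)s.size();
    uint64_t km = 0;
    int valid = 0;
    for (int j = 0; j < L; ++j) {
      int b = base2bit(s[j]);
      if (b < 0) { valid = 0; km = 0; continue; }
      km = ((km << 2) | (uint64_t)b) & mask;
      if (++valid >= k)
        ridx[km].push_back(((uint64_t)i << 32) | (uint64_t)(j - k + 1));
    }
  }

  std::vector<int> o_query, o_ref, o_strand;
  std::vector<long> o_qstart, o_qend, o_rstart, o_rend, o_matches, o_aligned;

  int nq = (int)queries_in.size();
  for (int qi = 0; qi < nq; ++qi) {
    std::string q = as<std::string>(queries_in[qi]);
    long qlen = (long)q.size();
    if (qlen < k) continue;
    int stride = (int)std::max(1L, (qlen - k) / 400L);
    struct Hit { int ref; int strand; long rstart, rend, qstart, qend, matches, aligned; };
    std::vector<Hit> hits;
    for (int strand = 0; strand < 2; ++strand) {
      std::string qs = strand ? revcomp(q) : q;
      // diagonal voting
      std::unordered_map<uint64_t, int> votes; // (ref<<34) ^ (diag+2^31)
      for (long p = 0; p + k <= qlen; p += stride) {
        uint64_t km = 0;
        bool ok = true;
        for (int j = 0; j < k; ++j) {
          int b = base2bit(qs[p + j]);
          if (b < 0) { ok = false; break; }
          km = (km << 2) | (uint64_t)b;
        }
        if (!ok) continue;
        auto it = ridx.find(km & mask);
        if (it == ridx.end()) continue;
        if (it->second.size() > 64) continue; // high-copy repeat seed
        for (uint64_t e : it->second) {
          int ref = (int)(e >> 32);
          long rpos = (long)(e & 0xFFFFFFFFULL);
          long diag = rpos - p;
          uint64_t key = ((uint64_t)ref << 34) ^ (uint64_t)(uint32_t)(diag + (1L << 31));
          votes[key]++;
        }
      }
      // per ref keep top-3 voted diagonals
      std::unordered_map<int, std::vector<std::pair<int, long>>> perref;
      for (auto &kv : votes) {
        int ref = (int)(kv.first >> 34);
        long diag = (long)(uint32_t)(kv.first & 0x3FFFFFFFFULL) - (1L << 31);
        perref[ref].push_back({kv.second, diag});
      }
      for (auto &kv : perref) {
        auto &v = kv.second;
        std::sort(v.begin(), v.end(),
                  [](const std::pair<int, long> &a, const std::pair<int, long> &b) {
                    return a.first > b.first || (a.first == b.first && a.second < b.second);
                  });
        int ref = kv.first;
        long rlen = (long)refs[ref].size();
        Hit best{-1, 0, 0, 0, 0, 0, -1, 0};
        int ntry = std::min((size_t)3, v.size());
        for (int t = 0; t < ntry; ++t) {
          long diag = v[t].second;
          long qs0 = std::max(0L, -diag);
          long qe0 = std::min(qlen, rlen - diag);
          long aligned = qe0 - qs0;
          if (aligned < (long)(min_len_frac * (double)qlen)) continue;
          long matches = 0;
          const std::string &R = refs[ref];
          for (long p = qs0; p < qe0; ++p)
            if (qs[p] == R[diag + p]) ++matches;
          if ((double)matches < min_sim * (double)aligned) continue;
          if (matches > best.matches) {
            best = {ref, strand, diag + qs0, diag + qe0, qs0, qe0, matches, aligned};
          }
        }
        if (best.ref >= 0) hits.push_back(best);
      }
    }
    if (hits.empty()) continue;
    if (best_only) {
      auto it = std::max_element(hits.begin(), hits.end(),
                                 [](const Hit &a, const Hit &b) { return a.matches < b.matches; });
      hits = {*it};
    } else {
      // best per ref across strands
      std::unordered_map<int, Hit> byref;
      for (auto &h : hits) {
        auto it = byref.find(h.ref);
        if (it == byref.end() || h.matches > it->second.matches) byref[h.ref] = h;
      }
      hits.clear();
      for (auto &kv : byref) hits.push_back(kv.second);
      std::sort(hits.begin(), hits.end(),
                [](const Hit &a, const Hit &b) { return a.ref < b.ref; });
    }
    for (auto &h : hits) {
      o_query.push_back(qi + 1);
      o_ref.push_back(h.ref + 1);
      o_strand.push_back(h.strand ? -1 : 1);
      o_qstart.push_back(h.qstart);
      o_qend.push_back(h.qend);
      o_rstart.push_back(h.rstart);
      o_rend.push_back(h.rend);
      o_matches.push_back(h.matches);
      o_aligned.push_back(h.aligned);
    }
    if (qi % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector identity(o_query.size());
  for (size_t i = 0; i < o_query.size(); ++i)
    identity[i] = (double)o_matches[i] / (double)o_aligned[i];
  return DataFrame::create(
    _["query"] = wrap(o_query), _["ref"] = wrap(o_ref),
    _["strand"] = wrap(o_strand),
    _["qstart"] = wrap(o_qstart), _["qend"] = wrap(o_qend),
    _["rstart"] = wrap(o_rstart), _["rend"] = wrap(o_rend),
    _["matches"] = wrap(o_matches), _["aligned"] = wrap(o_aligned),
    _["identity"] = identity,
    _["stringsAsFactors"] = false);
}

// Column-majority consensus of equal-anchored strings (left-aligned),
// used for long-read gap fill; ties and uncovered columns give 'N'.
// Output length = median input length.
// [[Rcpp::export(name = ".cpp_column_majority")]]
String cpp_column_majority(CharacterVector strings) {
  int n = (int)strings.size();
  if (n == 0) return String("");
  std::vector<std::string> ss(n);
  std::vector<size_t> lens(n);
  for (int i = 0; i < n; ++i) { ss[i] = as<std::string>(strings[i]); lens[i] = ss[i].size(); }
  std::vector<size_t> sorted = lens;
  std::sort(sorted.begin(), sorted.end());
  size_t outlen = sorted[sorted.size() / 2];
  std::string out(outlen, 'N');
  for (size_t p = 0; p < outlen; ++p) {
    int cnt[4] = {0, 0, 0, 0};
    for (int i = 0; i < n; ++i) {
      if (p < lens[i]) {
        int b = base2bit(ss[i][p]);
        if (b >= 0) cnt[b]++;
      }
    }
    int best = -1, bestc = 0, tie = 0;
    for (int x = 0; x < 4; ++x) {
      if (cnt[x] > bestc) { bestc = cnt[x]; best = x; tie = 0; }
      else if (cnt[x] == bestc && cnt[x] > 0) tie = 1;
    }
    if (best >= 0 && (!tie || n == 1)) out[p] = bit2base(best);
    else if (best >= 0 && !tie) out[p] = bit2base(best);
  }
  return String(out);
}
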