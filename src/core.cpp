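// Core sequence machinery: 2-bit k-mer encoding, canonical rotation of
// circular sequences (Booth's least-rotation), exact read-vs-contig matching,
// a de Bruijn graph assembler for plasmid-scale circular contigs, and the
// inner loop of the Illumina-like read simulator (uses R's RNG so results
// are reproducible under set.seed()).

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <functional>
#include <map>
#include <set>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static inline char comp_char(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'N': return 'N';
  }
  return 0;
}

// reverse complement of a 2-bit encoded k-mer (A=0,C=1,G=2,T=3; ~x
// complements each 2-bit group, then the groups are reversed)
static inline uint64_t rc_kmer(uint64_t x, int k) {
  x = ~x;
  x = ((x >> 2) & 0x3333333333333333ULL) | ((x & 0x3333333333333333ULL) << 2);
  x = ((x >> 4) & 0x0F0F0F0F0F0F0F0FULL) | ((x & 0x0F0F0F0F0F0F0F0FULL) << 4);
  x = ((x >> 8) & 0x00FF00FF00FF00FFULL) | ((x & 0x00FF00FF00FF00FFULL) << 8);
  x = ((x >> 16) & 0x0000FFFF0000FFFFULL) | ((x & 0x0000FFFF0000FFFFULL) << 16);
  x = (x >> 32) | (x << 32);
  return x >> (64 - 2 * k);
}

static std::string decode_kmer(uint64_t x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BITS2BASE[x & 3];
    x >>= 2;
  }
  return s;
}

static std::string rc_string(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_char(c);
  return r;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (CharacterVector::is_na(x[i])) stop("NA sequence");
    std::string s = as<std::string>(x[i]);
    for (char c : s)
      if (!comp_char(c))
        stop("invalid character '%s' in DNA sequence (allowed: A,C,G,T,N)",
             std::string(1, c).c_str());
    out[i] = rc_string(s);
  }
  return out;
}

// Booth's O(n) least-rotation algorithm
static std::string least_rotation(const std::string& s) {
  const std::string t = s + s;
  const int n = (int)t.size();
  std::vector<int> f(n, -1);
  int kk = 0;
  for (int j = 1; j < n; ++j) {
    char sj = t[j];
    int i = f[j - kk - 1];
    while (i != -1 && sj != t[kk + i + 1]) {
      if (sj < t[kk + i + 1]) kk = j - i - 1;
      i = f[i];
    }
    if (sj != t[kk + i + 1]) {
      if (sj < t[kk]) kk = j;
      f[j - kk] = -1;
    } else {
      f[j - kk] = i + 1;
    }
  }
  return t.substr(kk, s.size());
}

static std::string canonical_rotation_str(const std::string& s) {
  std::string a = least_rotation(s);
  std::string b = least_rotation(rc_string(s));
  return a < b ? a : b;
}

// [[Rcpp::export(name = ".canonical_rotation_cpp")]]
CharacterVector canonical_rotation_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (CharacterVector::is_na(x[i])) stop("NA sequence");
    std::string s = as<std::string>(x[i]);
    if (s.empty()) stop("cannot canonicalize an empty sequence");
    for (char c : s) {
      if (c == 'N')
        stop("cannot canonicalize a sequence containing N");
      if (base2bits(c) < 0)
        stop("invalid character '%s' in DNA sequence (allowed: A,C,G,T)",
             std::string(1, c).c_str());
    }
    out[i] = canonical_rotation_str(s);
  }
  return out;
}

// Exact matching of reads against contigs. A read matches a contig if it (or
// its reverse complement) occurs as an exact substring; circular contigs are
// extended by len(read)-1 bases so origin-spanning matches count. Reads
// containing N never match. Implemented by hashing all substrings of the
// relevant lengths from both strands of each contig.
// [[Rcpp::export(name = ".match_reads_cpp")]]
LogicalVector match_reads_cpp(CharacterVector reads, CharacterVector contigs,
                              LogicalVector circular) {
  const R_xlen_t nr = reads.size(), nc = contigs.size();
  if (nc != circular.size()) stop("contigs and circular flags differ in length");
  std::vector<std::string> rd(nr);
  std::set<size_t> lens;
  size_t maxlen = 0;
  std::vector<bool> hasN(nr, false);
  for (R_xlen_t i = 0; i < nr; ++i) {
    rd[i] = as<std::string>(reads[i]);
    if (rd[i].empty()) stop("empty read");
    for (char c : rd[i]) {
      if (c == 'N') hasN[i] = true;
      else if (base2bits(c) < 0)
        stop("invalid character in read");
    }
    if (!hasN[i]) {
      lens.insert(rd[i].size());
      maxlen = std::max(maxlen, rd[i].size());
    }
  }
  LogicalVector out(nr, false);
  if (maxlen == 0) return out;
  for (R_xlen_t j = 0; j < nc; ++j) {
    std::string ctg = as<std::string>(contigs[j]);
    const size_t L = ctg.size();
    if (L == 0) continue;
    std::string fwd = ctg, rev = rc_string(ctg);
    if (circular[j]) {
      const size_t ext = std::min(maxlen > 0 ? maxlen - 1 : 0, L);
      fwd += ctg.substr(0, ext);
      rev += rev.substr(0, ext);
    }
    std::unordered_set<std::string> windows;
    for (size_t len : lens) {
      if (len > L) continue;  // read longer than (circular) contig: no match
      for (size_t p = 0; p + len <= fwd.size(); ++p)
        windows.insert(fwd.substr(p, len));
      for (size_t p = 0; p + len <= rev.size(); ++p)
        windows.insert(rev.substr(p, len));
    }
    for (R_xlen_t i = 0; i < nr; ++i)
      if (!out[i] && !hasN[i] && windows.count(rd[i])) out[i] = true;
  }
  return out;
}

// ----- k-mer counting -------------------------------------------------------

typedef std::unordered_map<uint64_t, double> KmerCounts;

static void count_into(KmerCounts& cnt, const std::string& s, int k) {
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t x = 0;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) {  // N (or other): reset the window
      valid = 0;
      x = 0;
      continue;
    }
    x = ((x << 2) | (uint64_t)b) & mask;
    if (++valid >= k) {
      uint64_t r = rc_kmer(x, k);
      cnt[x < r ? x : r] += 1.0;
    }
  }
}

// [[Rcpp::export(name = ".count_kmers_cpp")]]
List count_kmers_cpp(CharacterVector reads, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  KmerCounts cnt;
  for (R_xlen_t i = 0; i < reads.size(); ++i)
    count_into(cnt, as<std::string>(reads[i]), k);
  std::vector<uint64_t> keys;
  keys.reserve(cnt.size());
  for (auto& kv : cnt) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector km(keys.size());
  IntegerVector n(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    km[i] = decode_kmer(keys[i], k);
    n[i] = (int)cnt[keys[i]];
  }
  return List::create(_["kmer"] = km, _["count"] = n);
}

// ----- de Bruijn assembler --------------------------------------------------

struct DBG {
  int k, km1;
  uint64_t kmask, nmask;
  KmerCounts cnt;  // canonical k-mer -> count

  DBG(int k_) : k(k_), km1(k_ - 1) {
    kmask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    nmask = (1ULL << (2 * km1)) - 1;
  }
  uint64_t canon(uint64_t e) const {
    uint64_t r = rc_kmer(e, k);
    return e < r ? e : r;
  }
  bool has(uint64_t e) const { return cnt.count(canon(e)) > 0; }
  double depth(uint64_t e) const {
    auto it = cnt.find(canon(e));
    return it == cnt.end() ? 0.0 : it->second;
  }
  int outdeg(uint64_t v) const {
    int d = 0;
    for (uint64_t b = 0; b < 4; ++b)
      if (has(((v << 2) | b) & kmask)) ++d;
    return d;
  }
  int indeg(uint64_t v) const {
    int d = 0;
    for (uint64_t b = 0; b < 4; ++b)
      if (has((b << (2 * km1)) | v)) ++d;
    return d;
  }
  // unique out-edge of v (call only when outdeg == 1)
  uint64_t out_edge(uint64_t v) const {
    for (uint64_t b = 0; b < 4; ++b) {
      uint64_t e = ((v << 2) | b) & kmask;
      if (has(e)) return e;
    }
    return 0;  // unreachable
  }
  bool junction(uint64_t v) const { return indeg(v) != 1 || outdeg(v) != 1; }
};

struct Unitig {
  std::vector<uint64_t> edges;  // oriented k-mers, in path order
  uint64_t vstart, vend;        // (k-1)-mer endpoints
  bool cycle;
  double meandepth;
  size_t baselen() const { return edges.size() + (cycle ? 0 : 0); }
};

static double unitig_meandepth(const DBG& g, const Unitig& u) {
  double s = 0;
  for (uint64_t e : u.edges) s += g.depth(e);
  return s / (double)u.edges.size();
}

static std::string unitig_seq(const DBG& g, const Unitig& u) {
  std::string s;
  if (u.cycle) {
    s.reserve(u.edges.size());
    for (uint64_t e : u.edges) s.push_back(BITS2BASE[e & 3]);
  } else {
    s = decode_kmer(u.vstart, g.km1);
    for (uint64_t e : u.edges) s.push_back(BITS2BASE[e & 3]);
  }
  return s;
}

// Extract all maximal non-branching paths (and leftover perfect cycles).
// Every unitig is produced in both orientations; callers de-duplicate via
// canonical sequence where needed. Deterministic: edges visited in sorted
// 2-bit encoding order (= lexicographic order of k-mer strings).
static std::vector<Unitig> extract_unitigs(const DBG& g) {
  std::vector<uint64_t> oriented;
  oriented.reserve(2 * g.cnt.size());
  for (auto& kv : g.cnt) {
    oriented.push_back(kv.first);
    oriented.push_back(rc_kmer(kv.first, g.k));
  }
  std::sort(oriented.begin(), oriented.end());
  oriented.erase(std::unique(oriented.begin(), oriented.end()), oriented.end());

  std::unordered_set<uint64_t> visited;
  std::vector<Unitig> out;

  // paths starting at junctions
  for (uint64_t e : oriented) {
    if (visited.count(e)) continue;
    uint64_t p = e >> 2;
    if (!g.junction(p)) continue;
    Unitig u;
    u.cycle = false;
    u.vstart = p;
    uint64_t cur = e;
    visited.insert(cur);
    u.edges.push_back(cur);
    while (true) {
      uint64_t s = cur & g.nmask;
      if (g.junction(s)) break;
      uint64_t nxt = g.out_edge(s);
      if (visited.count(nxt)) break;  // guard against loops back into path
      visited.insert(nxt);
      u.edges.push_back(nxt);
      cur = nxt;
    }
    u.vend = cur & g.nmask;
    u.meandepth = unitig_meandepth(g, u);
    out.push_back(std::move(u));
  }
  // leftover perfect cycles (every node 1-in/1-out)
  for (uint64_t e : oriented) {
    if (visited.count(e)) continue;
    Unitig u;
    u.cycle = true;
    u.vstart = e >> 2;
    uint64_t cur = e;
    visited.insert(cur);
    u.edges.push_back(cur);
    while (true) {
      uint64_t s = cur & g.nmask;
      uint64_t nxt = g.out_edge(s);
      if (nxt == e) break;
      visited.insert(nxt);
      u.edges.push_back(nxt);
      cur = nxt;
    }
    u.vend = u.vstart;
    u.meandepth = unitig_meandepth(g, u);
    out.push_back(std::move(u));
  }
  return out;
}

static void erase_unitig(DBG& g, const Unitig& u,
                         std::unordered_set<uint64_t>& doomed) {
  for (uint64_t e : u.edges) doomed.insert(g.canon(e));
}

// canonical string key of a unitig (orientation-invariant)
static std::string unitig_key(const DBG& g, const Unitig& u) {
  std::string s = unitig_seq(g, u);
  if (u.cycle) return canonical_rotation_str(s);
  std::string r = rc_string(s);
  return s < r ? s : r;
}

// one tip-removal pass; returns true if anything was removed
static bool remove_tips(DBG& g, int tip_len_max) {
  std::vector<Unitig> us = extract_unitigs(g);
  std::unordered_set<uint64_t> doomed;
  for (const Unitig& u : us) {
    if (u.cycle) continue;
    size_t blen = u.edges.size() + (size_t)g.km1;  // length in bases
    if (blen > (size_t)tip_len_max) continue;
    if (g.indeg(u.vstart) == 0 || g.outdeg(u.vend) == 0)
      erase_unitig(g, u, doomed);
  }
  for (uint64_t c : doomed) g.cnt.erase(c);
  return !doomed.empty();
}

// one bubble-popping pass: among unitigs sharing both endpoints keep the one
// with the highest mean depth (ties: lexicographically smallest canonical
// sequence); returns true if anything was removed
static bool pop_bubbles(DBG& g) {
  std::vector<Unitig> us = extract_unitigs(g);
  std::map<std::pair<uint64_t, uint64_t>, std::vector<size_t> > groups;
  for (size_t i = 0; i < us.size(); ++i)
    if (!us[i].cycle)
      groups[std::make_pair(us[i].vstart, us[i].vend)].push_back(i);
  std::unordered_set<uint64_t> doomed;
  for (auto& kv : groups) {
    std::vector<size_t>& idx = kv.second;
    if (idx.size() < 2) continue;
    // de-duplicate by canonical sequence (a unitig can meet its own rc here)
    std::map<std::string, size_t> uniq;
    for (size_t i : idx) {
      std::string key = unitig_key(g, us[i]);
      if (!uniq.count(key)) uniq[key] = i;
    }
    if (uniq.size() < 2) continue;
    // winner: max depth, ties by smaller canonical sequence
    std::string best_key;
    double best_depth = -1.0;
    for (auto& u2 : uniq) {
      double d = us[u2.second].meandepth;
      if (d > best_depth || (d == best_depth && u2.first < best_key)) {
        best_depth = d;
        best_key = u2.first;
      }
    }
    for (auto& u2 : uniq)
      if (u2.first != best_key) erase_unitig(g, us[u2.second], doomed);
  }
  for (uint64_t c : doomed) g.cnt.erase(c);
  return !doomed.empty();
}

// erroneous-connection removal: drop a non-cycle unitig when its mean depth
// is below `ratio` times the deepest unitig sharing one of its endpoints.
// Recurrent sequencing errors (the same substitution drawn several times)
// can pass the k-mer count floor and form low-depth branches; when two such
// branches interlock within k bases neither is a simple bubble, so a local
// relative-depth rule is needed to restore the non-branching cycle.
static bool drop_weak_links(DBG& g, double ratio) {
  std::vector<Unitig> us = extract_unitigs(g);
  std::unordered_map<uint64_t, double> best;
  for (const Unitig& u : us) {
    if (u.cycle) continue;
    for (uint64_t v : {u.vstart, u.vend}) {
      auto it = best.find(v);
      if (it == best.end() || u.meandepth > it->second) best[v] = u.meandepth;
    }
  }
  std::unordered_set<uint64_t> doomed;
  for (const Unitig& u : us) {
    if (u.cycle) continue;
    double ref = std::max(best[u.vstart], best[u.vend]);
    if (u.meandepth < ratio * ref) erase_unitig(g, u, doomed);
  }
  for (uint64_t c : doomed) g.cnt.erase(c);
  return !doomed.empty();
}

// drop whole weakly-connected components whose median k-mer depth is below
// rel_depth_floor times the median depth of the dominant (highest total
// count) component
static void drop_shallow_components(DBG& g, double rel_depth_floor) {
  if (g.cnt.empty() || rel_depth_floor <= 0) return;
  std::vector<uint64_t> keys;
  keys.reserve(g.cnt.size());
  for (auto& kv : g.cnt) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  const size_t n = keys.size();
  std::vector<size_t> parent(n);
  for (size_t i = 0; i < n; ++i) parent[i] = i;
  std::function<size_t(size_t)> find = [&](size_t a) {
    while (parent[a] != a) {
      parent[a] = parent[parent[a]];
      a = parent[a];
    }
    return a;
  };
  auto unite = [&](size_t a, size_t b) {
    a = find(a);
    b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  // k-mers sharing a (strand-normalized) (k-1)-mer node are connected
  std::unordered_map<uint64_t, size_t> node_owner;
  for (size_t i = 0; i < n; ++i) {
    uint64_t f = keys[i];
    uint64_t nodes[2] = {f >> 2, f & g.nmask};
    for (uint64_t v : nodes) {
      uint64_t r = rc_kmer(v, g.km1);
      uint64_t nv = v < r ? v : r;
      auto it = node_owner.find(nv);
      if (it == node_owner.end())
        node_owner[nv] = i;
      else
        unite(i, it->second);
    }
  }
  std::map<size_t, std::vector<size_t> > comps;
  for (size_t i = 0; i < n; ++i) comps[find(i)].push_back(i);
  if (comps.size() < 2) return;

  struct CompStat {
    double total, median;
    size_t root;
  };
  std::vector<CompStat> stats;
  for (auto& kv : comps) {
    std::vector<double> depths;
    double total = 0;
    for (size_t i : kv.second) {
      double d = g.cnt[keys[i]];
      depths.push_back(d);
      total += d;
    }
    std::sort(depths.begin(), depths.end());
    size_t m = depths.size();
    double med = (m % 2) ? depths[m / 2] : 0.5 * (depths[m / 2 - 1] + depths[m / 2]);
    stats.push_back(CompStat{total, med, kv.first});
  }
  // dominant component: max total count (ties: larger median, smaller root)
  size_t dom = 0;
  for (size_t i = 1; i < stats.size(); ++i) {
    if (stats[i].total > stats[dom].total ||
        (stats[i].total == stats[dom].total &&
         (stats[i].median > stats[dom].median ||
          (stats[i].median == stats[dom].median && stats[i].root < stats[dom].root))))
      dom = i;
  }
  const double floor_depth = rel_depth_floor * stats[dom].median;
  for (size_t i = 0; i < stats.size(); ++i) {
    if (i == dom) continue;
    if (stats[i].median < floor_depth)
      for (size_t j : comps[stats[i].root]) g.cnt.erase(keys[j]);
  }
}

// [[Rcpp::export(name = ".assemble_cpp")]]
List assemble_cpp(CharacterVector reads, int k, int min_kmer_count,
                  int tip_len_max, double rel_depth_floor) {
  if (k < 3 || k > 31 || k % 2 == 0) stop("k must be odd and in [3, 31]");
  DBG g(k);
  for (R_xlen_t i = 0; i < reads.size(); ++i)
    count_into(g.cnt, as<std::string>(reads[i]), k);
  if (min_kmer_count > 1) {
    for (auto it = g.cnt.begin(); it != g.cnt.end();) {
      if (it->second < (double)min_kmer_count)
        it = g.cnt.erase(it);
      else
        ++it;
    }
  }
  // graph simplification: tips, erroneous connections, then bubbles
  const double kWeakLinkRatio = 0.05;
  for (int round = 0; round < 10; ++round) {
    bool a = remove_tips(g, tip_len_max);
    bool b = drop_weak_links(g, kWeakLinkRatio);
    bool c = pop_bubbles(g);
    if (!a && !b && !c) break;
  }
  drop_shallow_components(g, rel_depth_floor);

  std::vector<Unitig> us = extract_unitigs(g);
  struct Out {
    std::string seq;
    bool circular;
    double depth;
  };
  std::vector<Out> outs;
  std::set<std::string> seen;
  for (const Unitig& u : us) {
    std::string key = unitig_key(g, u);
    if (seen.count(key)) continue;
    seen.insert(key);
    outs.push_back(Out{key, u.cycle, u.meandepth});
  }
  std::sort(outs.begin(), outs.end(), [](const Out& a, const Out& b) {
    if (a.seq.size() != b.seq.size()) return a.seq.size() > b.seq.size();
    return a.seq < b.seq;
  });
  CharacterVector seq(outs.size());
  LogicalVector circ(outs.size());
  NumericVector dep(outs.size());
  for (size_t i = 0; i < outs.size(); ++i) {
    seq[i] = outs[i].seq;
    circ[i] = outs[i].circular;
    dep[i] = outs[i].depth;
  }
  return List::create(_["seq"] = seq, _["circular"] = circ,
                      _["mean_depth"] = dep);
}

// ----- read simulation inner loop ------------------------------------------

// Draw per-base Phred scores around a per-read class mean (sd qsd, clamped to
// [qmin, qmax]) and apply substitution errors with per-base probability
// max(base_error_rate, 10^(-q/10)). Uses R's RNG (deterministic under
// set.seed()).
// [[Rcpp::export(name = ".sim_block_cpp")]]
List sim_block_cpp(CharacterVector frags, NumericVector qmean, double qsd,
                   int qmin, int qmax, double base_error_rate) {
  const R_xlen_t n = frags.size();
  if (qmean.size() != n) stop("qmean length mismatch");
  CharacterVector reads(n), quals(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(frags[i]);
    std::string q(s.size(), '!');
    for (size_t j = 0; j < s.size(); ++j) {
      int qv = (int)std::lround(R::rnorm(qmean[i], qsd));
      if (qv < qmin) qv = qmin;
      if (qv > qmax) qv = qmax;
      q[j] = (char)(33 + qv);
      if (base_error_rate <= 0) continue;  // exact error-free limit
      double perr = std::max(base_error_rate, std::pow(10.0, -qv / 10.0));
      if (R::unif_rand() < perr) {
        int b = base2bits(s[j]);
        if (b >= 0) {
          int nb = (int)(R::unif_rand() * 3.0);
          if (nb > 2) nb = 2;
          // pick one of the three other bases
          nb = (nb >= b) ? nb + 1 : nb;
          s[j] = BITS2BASE[nb];
        }
      }
    }
    reads[i] = s;
    quals[i] = q;
  }
  return List::create(_["seq"] = reads, _["qual"] = quals);
}

// [[Rcpp::export(name = ".phred_means_cpp")]]
NumericVector phred_means_cpp(CharacterVector quals) {
  NumericVector out(quals.size());
  for (R_xlen_t i = 0; i < quals.size(); ++i) {
    std::string q = as<std::string>(quals[i]);
    if (q.empty()) stop("empty quality string");
    double s = 0;
    for (char c : q) s += (double)(c - 33);
    out[i] = s / (double)q.size();
  }
  return out;
}
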