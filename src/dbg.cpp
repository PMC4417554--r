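// De Bruijn (Euler-path style) assembler over canonical k-mers.
// k must be odd so no k-mer equals its own reverse complement.
// K-mers are 2-bit packed (A=0, C=1, G=2, T=3) in an unsigned 128-bit
// word, so numeric order equals lexicographic DNA order and k+1 <= 64.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

typedef unsigned __int128 u128;

struct Hash128 {
  size_t operator()(const u128& x) const {
    uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
    uint64_t h = lo * 0x9E3779B97F4A7C15ULL ^ (hi + 0x9E3779B97F4A7C15ULL);
    h ^= h >> 32;
    return (size_t)h;
  }
};

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static std::string decode(u128 x, int k) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = B[(int)(x & 3)];
    x >>= 2;
  }
  return s;
}

// oriented k-mer: forward word and its reverse complement, updated
// incrementally so no O(k) recomputation is ever needed
struct OKmer {
  u128 f, r;
  bool operator==(const OKmer& o) const { return f == o.f && r == o.r; }
};

static inline u128 canon_of(const OKmer& o) { return o.f <= o.r ? o.f : o.r; }

struct DBG {
  int k;
  u128 mask_k, mask_e;
  std::unordered_map<u128, int, Hash128> nodes;  // canonical k-mer -> count
  std::unordered_map<u128, int, Hash128> edges;  // canonical (k+1)-mer -> count

  void init(int k_) {
    k = k_;
    mask_k = (((u128)1) << (2 * k)) - 1;
    mask_e = (((u128)1) << (2 * (k + 1))) - 1;
  }
  int node_count(const OKmer& o) const {
    auto it = nodes.find(canon_of(o));
    return it == nodes.end() ? 0 : it->second;
  }
  bool has_node_canon(u128 c) const { return nodes.count(c) > 0; }

  // successor of oriented s by appending base b
  inline OKmer succ_km(const OKmer& s, int b) const {
    OKmer t;
    t.f = ((s.f << 2) | (u128)b) & mask_k;
    t.r = (s.r >> 2) | ((u128)(3 - b) << (2 * (k - 1)));
    return t;
  }
  inline OKmer pred_km(const OKmer& s, int b) const {
    OKmer t;
    t.f = ((u128)b << (2 * (k - 1))) | (s.f >> 2);
    t.r = ((s.r << 2) | (u128)(3 - b)) & mask_k;
    return t;
  }
  // edge (k+1)-mer for s -> succ(s, b)
  inline u128 succ_edge(const OKmer& s, int b) const {
    u128 ef = ((s.f << 2) | (u128)b) & mask_e;
    u128 er = ((u128)(3 - b) << (2 * k)) | s.r;
    return ef <= er ? ef : er;
  }
  inline u128 pred_edge(const OKmer& s, int b) const {
    u128 ef = ((u128)b << (2 * k)) | s.f;
    u128 er = ((s.r << 2) | (u128)(3 - b)) & mask_e;
    return ef <= er ? ef : er;
  }
  int n_succ(const OKmer& s, OKmer* out) const {
    int n = 0;
    for (int b = 0; b < 4; ++b) {
      if (edges.count(succ_edge(s, b))) {
        OKmer t = succ_km(s, b);
        if (has_node_canon(canon_of(t))) out[n++] = t;
      }
    }
    return n;
  }
  int n_pred(const OKmer& s, OKmer* out) const {
    int n = 0;
    for (int b = 0; b < 4; ++b) {
      if (edges.count(pred_edge(s, b))) {
        OKmer t = pred_km(s, b);
        if (has_node_canon(canon_of(t))) out[n++] = t;
      }
    }
    return n;
  }
  // removing the nodes is enough: traversal checks node existence after
  // every edge lookup, so edges to dead nodes are never followed
  void drop_nodes(const std::unordered_set<u128, Hash128>& kill) {
    for (const auto& km : kill) nodes.erase(km);
  }
  u128 canon_word(u128 f) const {
    u128 r = 0, x = f;
    for (int i = 0; i < k; ++i) { r = (r << 2) | (3 - (x & 3)); x >>= 2; }
    return f <= r ? f : r;
  }
  bool edge_alive(u128 e) const {
    return nodes.count(canon_word(e >> 2)) &&
           nodes.count(canon_word(e & mask_k));
  }
  // oriented k-mer for a canonical word (forward = the canonical word)
  OKmer orient(u128 c) const {
    OKmer o;
    o.f = c;
    u128 r = 0, x = c;
    for (int i = 0; i < k; ++i) { r = (r << 2) | (3 - (x & 3)); x >>= 2; }
    o.r = r;
    return o;
  }
  static OKmer flip(const OKmer& o) { OKmer t; t.f = o.r; t.r = o.f; return t; }
  std::vector<u128> sorted_nodes() const {
    std::vector<u128> keys;
    keys.reserve(nodes.size());
    for (const auto& kv : nodes) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end());
    return keys;
  }
};

static void build_graph(DBG& g, const std::vector<std::string>& reads,
                        int k) {
  g.init(k);
  for (const auto& rd : reads) {
    int n = rd.size();
    if (n < k) continue;
    OKmer cur;
    cur.f = 0; cur.r = 0;
    u128 ef = 0;  // rolling (k+1)-mer forward word
    int run = 0;  // valid bases in the current window
    for (int i = 0; i < n; ++i) {
      int b = base_code(rd[i]);
      if (b < 0) { run = 0; cur.f = 0; cur.r = 0; ef = 0; continue; }
      cur.f = ((cur.f << 2) | (u128)b) & g.mask_k;
      cur.r = (cur.r >> 2) | ((u128)(3 - b) << (2 * (k - 1)));
      ef = ((ef << 2) | (u128)b) & g.mask_e;
      ++run;
      if (run >= k) {
        g.nodes[canon_of(cur)]++;
        if (run >= k + 1) {
          // rc of the (k+1)-mer: complement of b0 prepended to prev rc;
          // compute from cur.r and the base that left the k-window
          u128 er = (cur.r << 2 | (u128)(3 - (int)((ef >> (2 * k)) & 3)));
          // er currently holds rc(kmer)·4 | comp(first base of edge)
          u128 ce = ef <= er ? ef : er;
          g.edges[ce]++;
        }
      }
    }
  }
}

static void apply_cutoff(DBG& g, int cutoff) {
  if (cutoff <= 1) return;
  std::unordered_set<u128, Hash128> kill;
  for (const auto& kv : g.nodes)
    if (kv.second < cutoff) kill.insert(kv.first);
  g.drop_nodes(kill);
}

static int auto_cutoff(const DBG& g) {
  if (g.nodes.empty()) return 1;
  double tot = 0;
  for (const auto& kv : g.nodes) tot += kv.second;
  return (tot / g.nodes.size() > 10.0) ? 2 : 1;
}

// Remove dead-end paths shorter than max_tip_len (bp) whose coverage is
// below the strongest competing branch at their junction. Runs to a
// fixed point, so a second call is a no-op.
static void clip_tips(DBG& g, int max_tip_len) {
  int max_nodes = std::max(1, max_tip_len - g.k + 1);
  OKmer nb[4], pb[4];
  for (int round = 0; round < 100; ++round) {
    std::unordered_set<u128, Hash128> kill;
    std::vector<u128> keys = g.sorted_nodes();
    for (u128 cn : keys) {
      if (kill.count(cn)) continue;
      OKmer fwd = g.orient(cn);
      for (int ori = 0; ori < 2; ++ori) {
        OKmer s = ori == 0 ? fwd : DBG::flip(fwd);
        if (g.n_succ(s, nb) != 0) continue;  // not a right dead end
        std::vector<OKmer> path;
        path.push_back(s);
        OKmer cur = s;
        bool is_tip = false;
        OKmer junction;
        while ((int)path.size() <= max_nodes) {
          if (g.n_pred(cur, pb) != 1) break;
          OKmer p = pb[0];
          if (g.n_succ(p, nb) > 1) { is_tip = true; junction = p; break; }
          if (g.n_pred(p, pb) > 1) break;
          path.push_back(p);
          cur = p;
        }
        if (!is_tip) continue;
        bool shared = false;
        double tip_cov = 0;
        for (const auto& nd : path) {
          if (kill.count(canon_of(nd))) shared = true;
          tip_cov += g.node_count(nd);
        }
        if (shared) continue;
        tip_cov /= path.size();
        double best_alt = 0;
        int ns = g.n_succ(junction, nb);
        u128 last = canon_of(path.back());
        for (int j = 0; j < ns; ++j) {
          if (canon_of(nb[j]) == last) continue;
          best_alt = std::max(best_alt, (double)g.node_count(nb[j]));
        }
        if (best_alt > tip_cov)
          for (const auto& nd : path) kill.insert(canon_of(nd));
      }
    }
    if (kill.empty()) break;
    g.drop_nodes(kill);
  }
}

struct Walk {
  std::vector<OKmer> interior;
  OKmer stop;
  bool ok = false;
};

static Walk walk_unipath(const DBG& g, const OKmer& t, int max_nodes) {
  Walk w;
  OKmer cur = t;
  OKmer nb[4], pb[4];
  std::unordered_set<u128, Hash128> seen;
  while ((int)w.interior.size() <= max_nodes) {
    if (g.n_pred(cur, pb) != 1) return w;
    u128 c = canon_of(cur);
    if (seen.count(c)) return w;
    seen.insert(c);
    int ns = g.n_succ(cur, nb);
    if (ns != 1) return w;
    w.interior.push_back(cur);
    OKmer nxt = nb[0];
    if (g.n_pred(nxt, pb) > 1) {
      w.stop = nxt;
      w.ok = true;
      return w;
    }
    cur = nxt;
  }
  return w;
}

// path sequence of oriented nodes (first node's word + trailing bases)
static std::string path_seq(const DBG& g, const std::vector<OKmer>& nodes) {
  std::string s = decode(nodes.front().f, g.k);
  static const char B[4] = {'A', 'C', 'G', 'T'};
  for (size_t i = 1; i < nodes.size(); ++i)
    s.push_back(B[(int)(nodes[i].f & 3)]);
  return s;
}

// Simplified tour-bus: two simple parallel paths between one divergence
// and one reconvergence node, length difference <= max_divergence; keep
// the higher-coverage arm, lexicographic tie-break. Fixed point.
static void pop_bubbles(DBG& g, int max_divergence) {
  int max_nodes = 2 * g.k + 2;
  OKmer nb[4];
  for (int round = 0; round < 100; ++round) {
    bool changed = false;
    std::vector<u128> keys = g.sorted_nodes();
    for (u128 cn : keys) {
      if (!g.nodes.count(cn)) continue;
      OKmer fwd = g.orient(cn);
      for (int ori = 0; ori < 2; ++ori) {
        OKmer s = ori == 0 ? fwd : DBG::flip(fwd);
        int ns = g.n_succ(s, nb);
        if (ns < 2) continue;
        // successor list is in base order = lexicographic order
        bool popped = false;
        for (int a = 0; a + 1 < ns && !popped; ++a) {
          for (int b2 = a + 1; b2 < ns && !popped; ++b2) {
            Walk wa = walk_unipath(g, nb[a], max_nodes);
            Walk wb = walk_unipath(g, nb[b2], max_nodes);
            if (!wa.ok || !wb.ok) continue;
            if (canon_of(wa.stop) != canon_of(wb.stop)) continue;
            int diff = (int)wa.interior.size() - (int)wb.interior.size();
            if (diff < 0) diff = -diff;
            if (diff > max_divergence) continue;
            std::unordered_set<u128, Hash128> seta;
            for (const auto& nd : wa.interior) seta.insert(canon_of(nd));
            bool overlap = false;
            for (const auto& nd : wb.interior)
              if (seta.count(canon_of(nd))) overlap = true;
            if (overlap) continue;
            double cova = 0, covb = 0;
            for (const auto& nd : wa.interior) cova += g.node_count(nd);
            for (const auto& nd : wb.interior) covb += g.node_count(nd);
            cova /= wa.interior.size();
            covb /= wb.interior.size();
            const std::vector<OKmer>* kill_arm;
            if (cova < covb) kill_arm = &wa.interior;
            else if (covb < cova) kill_arm = &wb.interior;
            else kill_arm = path_seq(g, wa.interior) <=
                            path_seq(g, wb.interior)
                            ? &wb.interior : &wa.interior;
            std::unordered_set<u128, Hash128> kill;
            for (const auto& nd : *kill_arm) kill.insert(canon_of(nd));
            g.drop_nodes(kill);
            changed = true;
            popped = true;
          }
        }
        if (popped) break;
      }
    }
    if (!changed) break;
  }
}

// Maximal non-branching paths, canonical orientation, ordered by length
// descending then lexicographic.
static void extract_unitigs(const DBG& g, int min_len,
                            std::vector<std::string>& seqs,
                            std::vector<double>& covs) {
  std::unordered_set<u128, Hash128> visited;
  std::vector<u128> keys = g.sorted_nodes();
  std::vector<std::pair<std::string, double>> out;
  OKmer nb[4], pb[4];
  for (u128 cn : keys) {
    if (visited.count(cn)) continue;
    OKmer start = g.orient(cn);
    std::vector<OKmer> chain;
    chain.push_back(start);
    std::unordered_set<u128, Hash128> inchain;
    inchain.insert(cn);
    OKmer cur = start;
    while (true) {
      if (g.n_succ(cur, nb) != 1) break;
      OKmer t = nb[0];
      if (g.n_pred(t, pb) != 1) break;
      u128 c = canon_of(t);
      if (inchain.count(c) || visited.count(c)) break;
      chain.push_back(t);
      inchain.insert(c);
      cur = t;
    }
    cur = start;
    while (true) {
      if (g.n_pred(cur, pb) != 1) break;
      OKmer p = pb[0];
      if (g.n_succ(p, nb) != 1) break;
      u128 c = canon_of(p);
      if (inchain.count(c) || visited.count(c)) break;
      chain.insert(chain.begin(), p);
      inchain.insert(c);
      cur = p;
    }
    double cov = 0;
    for (const auto& nd : chain) {
      visited.insert(canon_of(nd));
      cov += g.node_count(nd);
    }
    cov /= chain.size();
    std::string seq = path_seq(g, chain);
    {
      std::string rc(seq.rbegin(), seq.rend());
      for (auto& ch : rc)
        ch = ch == 'A' ? 'T' : ch == 'C' ? 'G' : ch == 'G' ? 'C' : 'A';
      if (rc < seq) seq = rc;
    }
    if ((int)seq.size() >= min_len) out.emplace_back(seq, cov);
  }
  std::sort(out.begin(), out.end(),
            [](const std::pair<std::string, double>& a,
               const std::pair<std::string, double>& b) {
              if (a.first.size() != b.first.size())
                return a.first.size() > b.first.size();
              return a.first < b.first;
            });
  for (auto& p : out) {
    seqs.push_back(p.first);
    covs.push_back(p.second);
  }
}

static std::vector<std::string> as_reads(const CharacterVector& reads) {
  std::vector<std::string> v;
  v.reserve(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i)
    v.push_back(as<std::string>(reads[i]));
  return v;
}

static void prepare_graph(DBG& g, const CharacterVector& reads, int k,
                          int cutoff, bool tips, bool bubbles,
                          int max_tip_len, int max_divergence) {
  if (k < 3 || k % 2 == 0)
    stop("k must be odd and >= 3");
  if (k > 63)
    stop("k must be <= 63");
  build_graph(g, as_reads(reads), k);
  int cut = cutoff;
  if (cut < 0) cut = auto_cutoff(g);
  apply_cutoff(g, cut);
  if (max_tip_len < 0) max_tip_len = 2 * k;
  if (tips) clip_tips(g, max_tip_len);
  if (bubbles) pop_bubbles(g, max_divergence);
  if (tips) clip_tips(g, max_tip_len);  // bubbles may expose new tips
}

// [[Rcpp::export]]
List cpp_graph_summary(CharacterVector reads, int k, int cutoff) {
  if (k < 3 || k % 2 == 0)
    stop("k must be odd and >= 3");
  if (k > 63)
    stop("k must be <= 63");
  DBG g;
  build_graph(g, as_reads(reads), k);
  int cut = cutoff;
  if (cut < 0) cut = auto_cutoff(g);
  apply_cutoff(g, cut);
  std::vector<u128> nk = g.sorted_nodes();
  std::vector<std::string> ns, es;
  std::vector<int> nc, ec;
  for (u128 x : nk) {
    ns.push_back(decode(x, k));
    nc.push_back(g.nodes[x]);
  }
  std::vector<u128> ek;
  for (const auto& kv : g.edges)
    if (g.edge_alive(kv.first)) ek.push_back(kv.first);
  std::sort(ek.begin(), ek.end());
  for (u128 x : ek) {
    es.push_back(decode(x, k + 1));
    ec.push_back(g.edges[x]);
  }
  return List::create(_["node"] = wrap(ns), _["node_count"] = wrap(nc),
                      _["edge"] = wrap(es), _["edge_count"] = wrap(ec));
}

// [[Rcpp::export]]
CharacterVector cpp_clean_kmers(CharacterVector reads, int k, int cutoff,
                                bool tips, bool bubbles, int max_tip_len,
                                int max_divergence) {
  DBG g;
  prepare_graph(g, reads, k, cutoff, tips, bubbles, max_tip_len,
                max_divergence);
  std::vector<u128> nk = g.sorted_nodes();
  std::vector<std::string> ns;
  for (u128 x : nk) ns.push_back(decode(x, k));
  return wrap(ns);
}

// [[Rcpp::export]]
List cpp_assemble(CharacterVector reads, int k, int cutoff, int min_len,
                  bool tips, bool bubbles, int max_tip_len,
                  int max_divergence) {
  DBG g;
  prepare_graph(g, reads, k, cutoff, tips, bubbles, max_tip_len,
                max_divergence);
  std::vector<std::string> seqs;
  std::vector<double> covs;
  extract_unitigs(g, min_len, seqs, covs);
  return List::create(_["sequence"] = wrap(seqs), _["coverage"] = wrap(covs));
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.rbegin(), s.rend());
    for (auto& c : r)
      c = c == 'A' ? 'T' : c == 'C' ? 'G' : c == 'G' ? 'C' :
          c == 'T' ? 'A' : 'N';
    out[i] = r;
  }
  return out;
}
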