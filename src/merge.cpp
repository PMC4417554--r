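// Stage-2 contig pooling: exact duplicate / containment removal and
// unambiguous exact suffix-prefix overlap merging (both orientations).

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline char comp_base2(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string rc2(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base2(c);
  return r;
}

// Returns indices (1-based) of contigs kept after removing exact duplicates
// and contigs contained (either orientation) in a longer kept contig.
// Input order defines the tie-break among equals: first wins.
// [[Rcpp::export]]
IntegerVector cpp_dedupe_contained(CharacterVector seqs) {
  int n = seqs.size();
  std::vector<std::string> v(n);
  for (int i = 0; i < n; ++i) v[i] = as<std::string>(seqs[i]);
  // process longest first; stable for equal lengths (lexicographic, then
  // original index) so the kept representative is deterministic
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (v[a].size() != v[b].size()) return v[a].size() > v[b].size();
    if (v[a] != v[b]) return v[a] < v[b];
    return a < b;
  });
  size_t w = 0;  // probe word length
  for (int i = 0; i < n; ++i) w = w == 0 ? v[i].size() : std::min(w, v[i].size());
  w = std::min<size_t>(w, 24);
  if (w == 0) return IntegerVector(0);
  // w-mer -> (kept slot, position)
  std::unordered_multimap<std::string, std::pair<int, int>> idx;
  std::vector<int> kept;  // original indices
  std::vector<char> keep(n, 0);
  for (int oi = 0; oi < n; ++oi) {
    int i = ord[oi];
    const std::string& s = v[i];
    bool contained = false;
    for (int pass = 0; pass < 2 && !contained; ++pass) {
      std::string probe = pass == 0 ? s : rc2(s);
      if (probe.size() < w) continue;
      auto range = idx.equal_range(probe.substr(0, w));
      for (auto it = range.first; it != range.second; ++it) {
        int slot = it->second.first;
        int pos = it->second.second;
        const std::string& host = v[kept[slot]];
        if (pos + probe.size() <= host.size() &&
            host.compare(pos, probe.size(), probe) == 0) {
          contained = true;
          break;
        }
      }
    }
    if (contained) continue;
    keep[i] = 1;
    int slot = kept.size();
    kept.push_back(i);
    for (size_t p = 0; p + w <= s.size(); ++p)
      idx.emplace(s.substr(p, w), std::make_pair(slot, (int)p));
  }
  std::vector<int> out;
  for (int i = 0; i < n; ++i)
    if (keep[i]) out.push_back(i + 1);
  return wrap(out);
}

// Merge contigs over exact suffix-prefix overlaps of length >= min_overlap,
// both orientations, joining only unambiguous junctions (each end pairs with
// at most one partner). Containment/duplicates must be removed first.
// [[Rcpp::export]]
CharacterVector cpp_merge_overlap(CharacterVector seqs, int min_overlap) {
  int n = seqs.size();
  if (min_overlap < 1) stop("min_overlap must be >= 1");
  // oriented contigs: 2*i = forward, 2*i+1 = reverse complement
  std::vector<std::string> o(2 * n);
  for (int i = 0; i < n; ++i) {
    o[2 * i] = as<std::string>(seqs[i]);
    o[2 * i + 1] = rc2(o[2 * i]);
  }
  size_t w = (size_t)min_overlap;
  // prefix index: first w chars of each oriented contig
  std::unordered_multimap<std::string, int> pref;
  for (int x = 0; x < 2 * n; ++x)
    if (o[x].size() >= w) pref.emplace(o[x].substr(0, w), x);
  // out-edges: for oriented x, partners y with suffix(x,l) == prefix(y,l),
  // l >= min_overlap maximal; exclude same underlying contig
  std::vector<std::vector<std::pair<int, int>>> outs(2 * n);  // (y, l)
  for (int x = 0; x < 2 * n; ++x) {
    const std::string& sx = o[x];
    if (sx.size() < w) continue;
    std::unordered_map<int, int> best;  // y -> longest exact overlap
    int lmax = (int)sx.size() - 1;
    // an overlap of length l aligns prefix(y, w) with sx[size-l .. size-l+w)
    for (int l = (int)w; l <= lmax; ++l) {
      auto range = pref.equal_range(sx.substr(sx.size() - l, w));
      for (auto it = range.first; it != range.second; ++it) {
        int y = it->second;
        if (y / 2 == x / 2) continue;
        const std::string& sy = o[y];
        if (l >= (int)sy.size()) continue;  // containment, handled upstream
        if (sx.compare(sx.size() - l, l, sy, 0, l) == 0) {
          auto b = best.find(y);
          if (b == best.end() || b->second < l) best[y] = l;
        }
      }
    }
    for (auto& kv : best) outs[x].emplace_back(kv.first, kv.second);
    std::sort(outs[x].begin(), outs[x].end());
  }
  // in-degree via symmetry: in-edges of y = {x : y in outs[x]}
  std::vector<int> indeg(2 * n, 0);
  std::vector<int> in_from(2 * n, -1);
  for (int x = 0; x < 2 * n; ++x)
    for (auto& e : outs[x]) {
      indeg[e.first]++;
      in_from[e.first] = x;
    }
  // unambiguous successor of x: unique out-edge to y with indeg[y] == 1
  auto succ_of = [&](int x) -> std::pair<int, int> {
    if (outs[x].size() != 1) return {-1, 0};
    int y = outs[x][0].first;
    if (indeg[y] != 1) return {-1, 0};
    return {y, outs[x][0].second};
  };
  auto has_unamb_pred = [&](int x) {
    if (indeg[x] != 1) return false;
    int p = in_from[x];
    return succ_of(p).first == x;
  };
  std::vector<char> used(n, 0);
  std::vector<std::string> result;
  // chains from canonical starts (no unambiguous predecessor)
  std::vector<int> starts;
  for (int x = 0; x < 2 * n; ++x)
    if (succ_of(x).first >= 0 && !has_unamb_pred(x)) starts.push_back(x);
  // deterministic order: by sequence
  std::sort(starts.begin(), starts.end(),
            [&](int a, int b) { return o[a] < o[b]; });
  for (int s : starts) {
    if (used[s / 2]) continue;
    std::string seq = o[s];
    used[s / 2] = 1;
    int cur = s;
    while (true) {
      auto nx = succ_of(cur);
      if (nx.first < 0) break;
      int y = nx.first;
      if (used[y / 2]) break;  // mirror chain or cycle
      seq += o[y].substr(nx.second);
      used[y / 2] = 1;
      cur = y;
    }
    result.push_back(seq);
  }
  // untouched contigs (isolated or ambiguous everywhere) pass through;
  // cycles are broken deterministically at the smallest index
  for (int i = 0; i < n; ++i) {
    if (used[i]) continue;
    int x = 2 * i;
    if (succ_of(x).first < 0 && succ_of(2 * i + 1).first < 0) {
      used[i] = 1;
      result.push_back(o[x]);
      continue;
    }
    // part of a cycle: walk from here
    std::string seq = o[x];
    used[i] = 1;
    int cur = x;
    while (true) {
      auto nx = succ_of(cur);
      if (nx.first < 0) break;
      int y = nx.first;
      if (used[y / 2]) break;
      seq += o[y].substr(nx.second);
      used[y / 2] = 1;
      cur = y;
    }
    result.push_back(seq);
  }
  // canonical orientation, deterministic order
  for (auto& s : result) {
    std::string r = rc2(s);
    if (r < s) s = r;
  }
  std::sort(result.begin(), result.end(), [](const std::string& a,
                                             const std::string& b) {
    if (a.size() != b.size()) return a.size() > b.size();
    return a < b;
  });
  return wrap(result);
}
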