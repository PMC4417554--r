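// Ungapped seed-and-extend local aligner (contigs vs references, both
// strands) and an exact-seed substitution-only read mapper.

#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline char comp_base3(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string rc3(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base3(c);
  return r;
}

struct Aln {
  int contig, ref;        // 0-based indices
  int c_start, c_end;     // 0-based half-open, forward contig frame
  int r_start, r_end;
  char strand;
  int matches, mismatches;
  double identity, bits;
};

// BLASTN-like ungapped scoring: match +1, mismatch -2;
// bits = (lambda*S - ln K)/ln 2 with ungapped lambda=1.33, K=0.621
static inline double bit_score(int matches, int mismatches) {
  double S = 1.0 * matches - 2.0 * mismatches;
  return (1.33 * S - std::log(0.621)) / std::log(2.0);
}

// [[Rcpp::export]]
DataFrame cpp_align(CharacterVector contigs, CharacterVector refs,
                    int seed_len, int xdrop, int min_aln_len) {
  int nc = contigs.size(), nr = refs.size();
  std::vector<std::string> C(nc), R(nr);
  for (int i = 0; i < nc; ++i) C[i] = as<std::string>(contigs[i]);
  for (int i = 0; i < nr; ++i) R[i] = as<std::string>(refs[i]);
  // seed index over references
  std::unordered_multimap<std::string, std::pair<int, int>> idx;
  for (int r = 0; r < nr; ++r)
    for (size_t p = 0; p + seed_len <= R[r].size(); ++p)
      idx.emplace(R[r].substr(p, seed_len), std::make_pair(r, (int)p));

  std::vector<Aln> alns;
  for (int ci = 0; ci < nc; ++ci) {
    for (int strand = 0; strand < 2; ++strand) {
      std::string q = strand == 0 ? C[ci] : rc3(C[ci]);
      int ql = q.size();
      if (ql < seed_len) continue;
      // per (ref, diagonal): contig positions already inside an alignment
      std::unordered_map<long long, std::vector<std::pair<int, int>>> covered;
      for (int qp = 0; qp + seed_len <= ql; ++qp) {
        auto range = idx.equal_range(q.substr(qp, seed_len));
        for (auto it = range.first; it != range.second; ++it) {
          int r = it->second.first, rp = it->second.second;
          long long key = (long long)r * 20000000LL + (rp - qp + 10000000);
          bool skip = false;
          auto cv = covered.find(key);
          if (cv != covered.end())
            for (auto& iv : cv->second)
              if (qp >= iv.first && qp < iv.second) { skip = true; break; }
          if (skip) continue;
          const std::string& ref = R[r];
          int rl = ref.size();
          // extend right from seed end
          int mat = seed_len, mis = 0;
          int best_right_q = qp + seed_len;
          {
            int sc = 0, best = 0, m = mat, mm = mis;
            int bq = qp + seed_len;
            int i = qp + seed_len, j = rp + seed_len;
            int bm = m, bmm = mm;
            while (i < ql && j < rl) {
              if (q[i] == ref[j]) { sc += 1; m++; } else { sc -= 2; mm++; }
              ++i; ++j;
              if (sc > best) { best = sc; bq = i; bm = m; bmm = mm; }
              if (best - sc > xdrop) break;
            }
            best_right_q = bq; mat = bm; mis = bmm;
          }
          int best_left_q = qp;
          {
            int sc = 0, best = 0, m = mat, mm = mis;
            int bq = qp;
            int i = qp - 1, j = rp - 1;
            int bm = m, bmm = mm;
            while (i >= 0 && j >= 0) {
              if (q[i] == ref[j]) { sc += 1; m++; } else { sc -= 2; mm++; }
              --i; --j;
              if (sc > best) { best = sc; bq = i + 1; bm = m; bmm = mm; }
              if (best - sc > xdrop) break;
            }
            best_left_q = bq; mat = bm; mis = bmm;
          }
          int len = best_right_q - best_left_q;
          int rs = rp - (qp - best_left_q);
          covered[key].emplace_back(best_left_q, best_right_q);
          if (len < min_aln_len) continue;
          Aln a;
          a.contig = ci; a.ref = r;
          a.strand = strand == 0 ? '+' : '-';
          if (strand == 0) { a.c_start = best_left_q; a.c_end = best_right_q; }
          else { a.c_start = ql - best_right_q; a.c_end = ql - best_left_q; }
          a.r_start = rs; a.r_end = rs + len;
          a.matches = mat; a.mismatches = mis;
          a.identity = 100.0 * mat / (mat + mis);
          a.bits = bit_score(mat, mis);
          alns.push_back(a);
        }
      }
    }
  }
  // drop exact duplicates (same contig/ref/strand/coords)
  std::sort(alns.begin(), alns.end(), [](const Aln& a, const Aln& b) {
    if (a.contig != b.contig) return a.contig < b.contig;
    if (a.ref != b.ref) return a.ref < b.ref;
    if (a.strand != b.strand) return a.strand < b.strand;
    if (a.c_start != b.c_start) return a.c_start < b.c_start;
    if (a.r_start != b.r_start) return a.r_start < b.r_start;
    if (a.c_end != b.c_end) return a.c_end > b.c_end;
    return a.bits > b.bits;
  });
  std::vector<Aln> uniq;
  for (auto& a : alns) {
    if (!uniq.empty()) {
      const Aln& u = uniq.back();
      if (u.contig == a.contig && u.ref == a.ref && u.strand == a.strand &&
          u.c_start == a.c_start && u.c_end == a.c_end &&
          u.r_start == a.r_start && u.r_end == a.r_end)
        continue;
    }
    uniq.push_back(a);
  }
  int n = uniq.size();
  IntegerVector oc(n), orf(n), cs(n), ce(n), rs(n), re(n), mt(n), mm(n);
  CharacterVector st(n);
  NumericVector id(n), bits(n);
  for (int i = 0; i < n; ++i) {
    const Aln& a = uniq[i];
    oc[i] = a.contig + 1; orf[i] = a.ref + 1;
    cs[i] = a.c_start; ce[i] = a.c_end;
    rs[i] = a.r_start; re[i] = a.r_end;
    st[i] = std::string(1, a.strand);
    mt[i] = a.matches; mm[i] = a.mismatches;
    id[i] = a.identity; bits[i] = a.bits;
  }
  return DataFrame::create(
      _["contig"] = oc, _["ref"] = orf, _["c_start"] = cs, _["c_end"] = ce,
      _["r_start"] = rs, _["r_end"] = re, _["strand"] = st,
      _["matches"] = mt, _["mismatches"] = mm, _["identity"] = id,
      _["bit_score"] = bits, _["stringsAsFactors"] = false);
}

// Map each read to at most one contig: exact seeds at both read ends, both
// strands, then full-length comparison allowing <= max_mismatch
// substitutions. Best = fewest mismatches; ties -> longer contig, then
// lexicographically smaller contig name.
// Returns 1-based contig index per read, 0 = unmapped.
// [[Rcpp::export]]
IntegerVector cpp_map_reads(CharacterVector reads, CharacterVector contigs,
                            CharacterVector contig_names, int seed_len,
                            int max_mismatch) {
  int nc = contigs.size();
  std::vector<std::string> C(nc), N(nc);
  for (int i = 0; i < nc; ++i) {
    C[i] = as<std::string>(contigs[i]);
    N[i] = as<std::string>(contig_names[i]);
  }
  std::unordered_multimap<std::string, std::pair<int, int>> idx;
  for (int ci = 0; ci < nc; ++ci)
    for (size_t p = 0; p + seed_len <= C[ci].size(); ++p)
      idx.emplace(C[ci].substr(p, seed_len), std::make_pair(ci, (int)p));

  int nr = reads.size();
  IntegerVector out(nr);
  for (int i = 0; i < nr; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int L = rd.size();
    if (L < seed_len) { out[i] = 0; continue; }
    int best_mm = max_mismatch + 1, best_ci = -1;
    for (int strand = 0; strand < 2; ++strand) {
      std::string q = strand == 0 ? rd : rc3(rd);
      int offs[2] = {0, L - seed_len};
      int noff = offs[0] == offs[1] ? 1 : 2;
      for (int oi = 0; oi < noff; ++oi) {
        int off = offs[oi];
        auto range = idx.equal_range(q.substr(off, seed_len));
        for (auto it = range.first; it != range.second; ++it) {
          int ci = it->second.first;
          int start = it->second.second - off;
          if (start < 0 || start + L > (int)C[ci].size()) continue;
          int mm = 0;
          const std::string& cs = C[ci];
          for (int p = 0; p < L && mm <= max_mismatch; ++p)
            if (q[p] != cs[start + p]) ++mm;
          if (mm > max_mismatch) continue;
          if (mm < best_mm) { best_mm = mm; best_ci = ci; }
          else if (mm == best_mm && best_ci >= 0 && ci != best_ci) {
            if (C[ci].size() > C[best_ci].size() ||
                (C[ci].size() == C[best_ci].size() && N[ci] < N[best_ci]))
              best_ci = ci;
          }
        }
      }
    }
    out[i] = best_ci < 0 ? 0 : best_ci + 1;
  }
  return out;
}

// Simulate read pairs with R's RNG (deterministic under set.seed).
// For each transcript t, n_pairs[t] fragments: insert ~ U{imin..imax},
// start ~ U{0..len-insert}; mate1 = 5' prefix of the fragment, mate2 =
// reverse complement of the 3' suffix; per-base substitution probability
// err_start + pos*err_inc at read position pos (0-based).
// [[Rcpp::export]]
List cpp_simulate_pairs(CharacterVector transcripts, IntegerVector n_pairs,
                        int read_len, int imin, int imax,
                        double err_start, double err_inc) {
  int nt = transcripts.size();
  std::vector<double> prate(read_len);
  for (int p = 0; p < read_len; ++p) prate[p] = err_start + p * err_inc;
  static const char B[4] = {'A', 'C', 'G', 'T'};
  std::vector<std::string> m1, m2, e1, e2;
  std::vector<int> tidx, fstart, fins;
  GetRNGstate();
  for (int t = 0; t < nt; ++t) {
    std::string seq = as<std::string>(transcripts[t]);
    int len = seq.size();
    for (int j = 0; j < n_pairs[t]; ++j) {
      int ins = imin + (int)std::floor(unif_rand() * (imax - imin + 1));
      if (ins > imax) ins = imax;
      if (ins > len) { continue; }  // caller validates; guard anyway
      int start = (int)std::floor(unif_rand() * (len - ins + 1));
      if (start > len - ins) start = len - ins;
      std::string frag = seq.substr(start, ins);
      std::string a = frag.substr(0, read_len);
      std::string b = rc3(frag.substr(ins - read_len, read_len));
      std::string ea, eb;
      for (int p = 0; p < read_len; ++p) {
        if (unif_rand() < prate[p]) {
          char cur = a[p];
          char nb = B[(int)std::floor(unif_rand() * 4)];
          while (nb == cur) nb = B[(int)std::floor(unif_rand() * 4)];
          a[p] = nb;
          if (!ea.empty()) ea += ",";
          ea += std::to_string(p);
        }
      }
      for (int p = 0; p < read_len; ++p) {
        if (unif_rand() < prate[p]) {
          char cur = b[p];
          char nb = B[(int)std::floor(unif_rand() * 4)];
          while (nb == cur) nb = B[(int)std::floor(unif_rand() * 4)];
          b[p] = nb;
          if (!eb.empty()) eb += ",";
          eb += std::to_string(p);
        }
      }
      m1.push_back(a); m2.push_back(b);
      e1.push_back(ea); e2.push_back(eb);
      tidx.push_back(t + 1); fstart.push_back(start); fins.push_back(ins);
    }
  }
  PutRNGstate();
  return List::create(
      _["transcript"] = wrap(tidx), _["frag_start"] = wrap(fstart),
      _["insert"] = wrap(fins), _["mate1"] = wrap(m1), _["mate2"] = wrap(m2),
      _["mate1_errors"] = wrap(e1), _["mate2_errors"] = wrap(e2));
}
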