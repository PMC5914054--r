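// Independent breadth-first-search oracle for the rearrangement distance.
//
// Deliberately written without reusing the solver in rearrange.cpp: states
// are canonicalised genome strings, moves are generated by fresh code, and
// the search is a plain level-by-level BFS over the full operation set
// (inversions, translocations, fusions, fissions). Intended for small
// genomes (<= ~6 blocks) where the reachable space is enumerable; used in
// tests to certify the production distance.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<int> VI;
typedef std::vector<VI> GG;

static VI flipped(const VI& c) {
  VI out(c.size());
  for (size_t k = 0; k < c.size(); ++k) out[k] = -c[c.size() - 1 - k];
  return out;
}

static std::string canon(const GG& g) {
  std::vector<VI> chroms;
  for (size_t i = 0; i < g.size(); ++i) {
    if (g[i].empty()) continue;
    VI f = flipped(g[i]);
    chroms.push_back(std::lexicographical_compare(f.begin(), f.end(),
                                                  g[i].begin(), g[i].end())
                         ? f : g[i]);
  }
  std::sort(chroms.begin(), chroms.end());
  std::string key;
  for (size_t i = 0; i < chroms.size(); ++i) {
    for (size_t k = 0; k < chroms[i].size(); ++k) {
      key += std::to_string(chroms[i][k]);
      key += ',';
    }
    key += ';';
  }
  return key;
}

static void moves(const GG& g, std::vector<GG>& out) {
  out.clear();
  size_t K = g.size();
  // inversions (any proper segment, including single elements)
  for (size_t c = 0; c < K; ++c) {
    size_t L = g[c].size();
    for (size_t i = 0; i < L; ++i) {
      for (size_t j = i; j < L; ++j) {
        if (i == 0 && j == L - 1) continue;
        GG h = g;
        VI seg(h[c].begin() + i, h[c].begin() + j + 1);
        VI fs = flipped(seg);
        for (size_t t = 0; t < fs.size(); ++t) h[c][i + t] = fs[t];
        out.push_back(h);
      }
    }
  }
  // fissions
  for (size_t c = 0; c < K; ++c) {
    size_t L = g[c].size();
    for (size_t i = 1; i < L; ++i) {
      GG h;
      for (size_t t = 0; t < K; ++t) if (t != c) h.push_back(g[t]);
      h.push_back(VI(g[c].begin(), g[c].begin() + i));
      h.push_back(VI(g[c].begin() + i, g[c].end()));
      out.push_back(h);
    }
  }
  // translocations / fusions: both tail-exchange orientations
  for (size_t c1 = 0; c1 < K; ++c1) {
    for (size_t c2 = 0; c2 < K; ++c2) {
      if (c2 <= c1) continue;
      size_t L1 = g[c1].size(), L2 = g[c2].size();
      for (size_t i = 0; i <= L1; ++i) {
        for (size_t j = 0; j <= L2; ++j) {
          for (int variant = 0; variant < 2; ++variant) {
            VI left2(g[c2].begin(), g[c2].begin() + j);
            VI right2(g[c2].begin() + j, g[c2].end());
            if (variant == 1) {  // flip the partner chromosome first
              VI f = flipped(g[c2]);
              left2.assign(f.begin(), f.begin() + (L2 - j));
              right2.assign(f.begin() + (L2 - j), f.end());
            }
            VI n1(g[c1].begin(), g[c1].begin() + i);
            n1.insert(n1.end(), right2.begin(), right2.end());
            VI n2(left2);
            n2.insert(n2.end(), g[c1].begin() + i, g[c1].end());
            GG h;
            for (size_t t = 0; t < K; ++t) if (t != c1 && t != c2) h.push_back(g[t]);
            if (!n1.empty()) h.push_back(n1);
            if (!n2.empty()) h.push_back(n2);
            if (canon(h) == canon(g)) continue;  // identity move
            out.push_back(h);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
int cpp_bfs_distance(List a, List b, int max_depth = 12,
                     double max_states = 2e6) {
  GG A, B;
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    IntegerVector v = a[i];
    if (v.size()) A.push_back(VI(v.begin(), v.end()));
  }
  for (R_xlen_t i = 0; i < b.size(); ++i) {
    IntegerVector v = b[i];
    if (v.size()) B.push_back(VI(v.begin(), v.end()));
  }
  std::string goal = canon(B);
  if (canon(A) == goal) return 0;
  std::unordered_set<std::string> seen;
  std::vector<GG> frontier;
  frontier.push_back(A);
  seen.insert(canon(A));
  std::vector<GG> nbrs;
  for (int depth = 1; depth <= max_depth; ++depth) {
    std::vector<GG> next;
    for (size_t s = 0; s < frontier.size(); ++s) {
      moves(frontier[s], nbrs);
      for (size_t m = 0; m < nbrs.size(); ++m) {
        std::string key = canon(nbrs[m]);
        if (key == goal) return depth;
        if (seen.insert(key).second) {
          next.push_back(nbrs[m]);
          if ((double)seen.size() > max_states)
            stop("BFS oracle exceeded its state budget");
        }
      }
    }
    if (next.empty()) break;  // space exhausted without reaching the goal
    frontier.swap(next);
  }
  stop("BFS oracle did not reach the target within max_depth");
  return -1;  // not reached
}
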