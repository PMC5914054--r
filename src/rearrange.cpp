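// Exact multichromosomal rearrangement distance over signed genomes.
//
// Genomes are lists of integer vectors (chromosomes of signed block ids,
// ids 1..n each appearing once in absolute value). The distance is the
// minimum number of {inversion, translocation, fusion, fission} operations,
// computed by iterative-deepening A* with the DCJ distance as an admissible,
// consistent lower bound (every operation above is a single DCJ, so each step
// reduces the DCJ distance by at most one). Chromosome flips and chromosome
// order are free (flip equivalence), which the adjacency/telomere encoding
// gives for free.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<int> Chrom;
typedef std::vector<Chrom> Genome;

static Genome genome_from_list(List g) {
  Genome out;
  for (R_xlen_t i = 0; i < g.size(); ++i) {
    IntegerVector v = g[i];
    if (v.size() == 0) continue;
    out.push_back(Chrom(v.begin(), v.end()));
  }
  return out;
}

// Extremities (0-based): gene v in 1..n has tail 2v-2 and head 2v-1.
// part[e] = extremity adjacent to e inside the genome, or -1 for a telomere.
static void partner_fill(const Genome& g, std::vector<int>& part) {
  std::fill(part.begin(), part.end(), -1);
  for (size_t c = 0; c < g.size(); ++c) {
    int prev = -1;
    for (size_t k = 0; k < g[c].size(); ++k) {
      int v = g[c][k];
      int first, second;
      if (v > 0) { first = 2 * v - 2; second = 2 * v - 1; }
      else       { first = -2 * v - 1; second = -2 * v - 2; }
      if (prev >= 0) { part[prev] = first; part[first] = prev; }
      prev = second;
    }
  }
}

// DCJ distance d = n - C - I/2 on the adjacency graph whose vertices are the
// adjacencies/telomeres of the two genomes and whose edges are extremities.
static int dcj_core(const std::vector<int>& pa, const std::vector<int>& pb,
                    int n, std::vector<char>& vis) {
  std::fill(vis.begin(), vis.end(), 0);
  int C = 0, I = 0;
  // paths starting at a telomere of genome A
  for (int e = 0; e < 2 * n; ++e) {
    if (vis[e] || pa[e] != -1) continue;
    int edges = 0, cur = e, side = 1;  // side 1: cross cur into its B-vertex
    for (;;) {
      vis[cur] = 1; ++edges;
      int q = side == 1 ? pb[cur] : pa[cur];
      if (q < 0) break;
      cur = q; side = 1 - side;
    }
    if (edges % 2 == 1) ++I;
  }
  // remaining paths start at a telomere of genome B
  for (int e = 0; e < 2 * n; ++e) {
    if (vis[e] || pb[e] != -1) continue;
    int edges = 0, cur = e, side = 0;
    for (;;) {
      vis[cur] = 1; ++edges;
      int q = side == 1 ? pb[cur] : pa[cur];
      if (q < 0) break;
      cur = q; side = 1 - side;
    }
    if (edges % 2 == 1) ++I;
  }
  // everything else lies on cycles
  for (int e = 0; e < 2 * n; ++e) {
    if (vis[e]) continue;
    int cur = e, side = 1;
    while (!vis[cur]) {
      vis[cur] = 1;
      int q = side == 1 ? pb[cur] : pa[cur];
      cur = q; side = 1 - side;
    }
    ++C;
  }
  return n - C - I / 2;
}

struct DcjScratch {
  std::vector<int> pa, pb;
  std::vector<char> vis;
  explicit DcjScratch(int n) : pa(2 * n, -1), pb(2 * n, -1), vis(2 * n, 0) {}
};

static int dcj_dist(const Genome& a, const Genome& b, int n, DcjScratch& s) {
  partner_fill(a, s.pa);
  partner_fill(b, s.pb);
  return dcj_core(s.pa, s.pb, n, s.vis);
}

static Chrom revneg(const Chrom& c, size_t from, size_t to) {  // [from, to)
  Chrom out;
  out.reserve(to - from);
  for (size_t k = to; k > from; --k) out.push_back(-c[k - 1]);
  return out;
}

static void append_range(Chrom& dst, const Chrom& src, size_t from, size_t to) {
  dst.insert(dst.end(), src.begin() + from, src.begin() + to);
}

// All genomes one operation away (inversions, fissions, translocations
// including fusions; empty chromosomes dropped; whole-chromosome inversions
// skipped as they are identities under flip equivalence).
static std::vector<Genome> hp_children(const Genome& g) {
  std::vector<Genome> out;
  int K = (int)g.size();
  for (int c = 0; c < K; ++c) {  // inversions
    int L = (int)g[c].size();
    for (int i = 0; i < L; ++i) {
      for (int j = i; j < L; ++j) {
        if (i == 0 && j == L - 1) continue;
        Genome h = g;
        std::reverse(h[c].begin() + i, h[c].begin() + j + 1);
        for (int t = i; t <= j; ++t) h[c][t] = -h[c][t];
        out.push_back(std::move(h));
      }
    }
  }
  for (int c = 0; c < K; ++c) {  // fissions
    int L = (int)g[c].size();
    for (int i = 1; i < L; ++i) {
      Genome h;
      for (int t = 0; t < K; ++t) if (t != c) h.push_back(g[t]);
      h.push_back(Chrom(g[c].begin(), g[c].begin() + i));
      h.push_back(Chrom(g[c].begin() + i, g[c].end()));
      out.push_back(std::move(h));
    }
  }
  for (int c1 = 0; c1 < K; ++c1) {  // translocations and fusions
    for (int c2 = c1 + 1; c2 < K; ++c2) {
      int L1 = (int)g[c1].size(), L2 = (int)g[c2].size();
      for (int i = 0; i <= L1; ++i) {
        for (int j = 0; j <= L2; ++j) {
          // type 1: (A,B),(C,D) -> (A,D),(C,B)
          if (!((i == L1 && j == L2) || (i == 0 && j == 0))) {
            Genome h;
            for (int t = 0; t < K; ++t) if (t != c1 && t != c2) h.push_back(g[t]);
            Chrom n1, n2;
            append_range(n1, g[c1], 0, i);  append_range(n1, g[c2], j, L2);
            append_range(n2, g[c2], 0, j);  append_range(n2, g[c1], i, L1);
            if (!n1.empty()) h.push_back(std::move(n1));
            if (!n2.empty()) h.push_back(std::move(n2));
            out.push_back(std::move(h));
          }
          // type 2: (A,B),(C,D) -> (A,-C^r),(-B^r,D)
          if (!((i == L1 && j == 0) || (i == 0 && j == L2))) {
            Genome h;
            for (int t = 0; t < K; ++t) if (t != c1 && t != c2) h.push_back(g[t]);
            Chrom n1, n2;
            append_range(n1, g[c1], 0, i);
            { Chrom r = revneg(g[c2], 0, j); n1.insert(n1.end(), r.begin(), r.end()); }
            { Chrom r = revneg(g[c1], i, L1); n2 = r; }
            append_range(n2, g[c2], j, L2);
            if (!n1.empty()) h.push_back(std::move(n1));
            if (!n2.empty()) h.push_back(std::move(n2));
            out.push_back(std::move(h));
          }
        }
      }
    }
  }
  return out;
}

// Inversion-only children (for unichromosomal reversal distance).
static std::vector<Genome> rev_children(const Genome& g) {
  std::vector<Genome> out;
  int K = (int)g.size();
  for (int c = 0; c < K; ++c) {
    int L = (int)g[c].size();
    for (int i = 0; i < L; ++i) {
      for (int j = i; j < L; ++j) {
        if (i == 0 && j == L - 1) continue;
        Genome h = g;
        std::reverse(h[c].begin() + i, h[c].begin() + j + 1);
        for (int t = i; t <= j; ++t) h[c][t] = -h[c][t];
        out.push_back(std::move(h));
      }
    }
  }
  return out;
}

struct Solver {
  Genome target;
  int n;
  bool inversions_only;
  DcjScratch scratch;
  long nodes, node_cap;
  Solver(const Genome& t, int n_, bool inv_only, long cap)
      : target(t), n(n_), inversions_only(inv_only), scratch(n_),
        nodes(0), node_cap(cap) {}
  int h(const Genome& g) { return dcj_dist(g, target, n, scratch); }
  bool dfs(const Genome& g, int hg, int cost, int limit) {
    if (hg == 0) return true;
    if (cost + hg > limit) return false;
    if (++nodes > node_cap) stop("rearrangement distance search exceeded its node budget");
    std::vector<Genome> kids = inversions_only ? rev_children(g) : hp_children(g);
    std::vector<std::pair<int, size_t> > ord;
    ord.reserve(kids.size());
    for (size_t k = 0; k < kids.size(); ++k) {
      int hk = h(kids[k]);
      if (cost + 1 + hk <= limit) ord.push_back(std::make_pair(hk, k));
    }
    std::stable_sort(ord.begin(), ord.end());
    for (size_t k = 0; k < ord.size(); ++k)
      if (dfs(kids[ord[k].second], ord[k].first, cost + 1, limit)) return true;
    return false;
  }
  int solve(const Genome& start) {
    int h0 = h(start);
    for (int limit = h0;; ++limit) {
      nodes = 0;
      if (dfs(start, h0, 0, limit)) return limit;
      if (limit > h0 + 2 * n + 2) stop("rearrangement distance did not converge");
    }
  }
};

// [[Rcpp::export]]
int cpp_dcj_distance(List a, List b, int n) {
  Genome A = genome_from_list(a), B = genome_from_list(b);
  DcjScratch s(n);
  return dcj_dist(A, B, n, s);
}

// [[Rcpp::export]]
int cpp_genome_distance(List a, List b, int n, bool inversions_only = false,
                        double node_cap = 5e6) {
  Genome A = genome_from_list(a), B = genome_from_list(b);
  Solver s(B, n, inversions_only, (long)node_cap);
  return s.solve(A);
}
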