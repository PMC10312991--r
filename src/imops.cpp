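// Pixel-graph primitives backing R/imops.R.
//
// Matrices are column-major (R layout); neighbors are 4- or 8-connected.

#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

static inline int idx(int r, int c, int nr) { return c * nr + r; }

// union-find with path halving
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  a = uf_find(parent, a);
  b = uf_find(parent, b);
  if (a < b) parent[b] = a; else if (b < a) parent[a] = b;
}

// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol(), n = nr * nc;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask[idx(r, c, nr)]) continue;
      int i = idx(r, c, nr);
      if (r > 0 && mask[idx(r - 1, c, nr)]) uf_union(parent, i, idx(r - 1, c, nr));
      if (c > 0 && mask[idx(r, c - 1, nr)]) uf_union(parent, i, idx(r, c - 1, nr));
      if (connectivity == 8) {
        if (r > 0 && c > 0 && mask[idx(r - 1, c - 1, nr)])
          uf_union(parent, i, idx(r - 1, c - 1, nr));
        if (r + 1 < nr && c > 0 && mask[idx(r + 1, c - 1, nr)])
          uf_union(parent, i, idx(r + 1, c - 1, nr));
      }
    }
  }
  // assign consecutive labels in order of root pixel index
  IntegerMatrix out(nr, nc);
  std::vector<int> lab(n, 0);
  int next = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int i = idx(r, c, nr);
      if (!mask[i]) continue;
      int root = uf_find(parent, i);
      if (lab[root] == 0) lab[root] = ++next;
      out[i] = lab[root];
    }
  return out;
}

// [[Rcpp::export(name = ".fill_holes_cpp")]]
LogicalMatrix fill_holes_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> outside(nr * nc, 0);
  std::queue<int> q;
  for (int r = 0; r < nr; ++r) {
    for (int c : {0, nc - 1}) {
      int i = idx(r, c, nr);
      if (!mask[i] && !outside[i]) { outside[i] = 1; q.push(i); }
    }
  }
  for (int c = 0; c < nc; ++c) {
    for (int r : {0, nr - 1}) {
      int i = idx(r, c, nr);
      if (!mask[i] && !outside[i]) { outside[i] = 1; q.push(i); }
    }
  }
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    int i = q.front(); q.pop();
    int r = i % nr, c = i / nr;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int j = idx(rr, cc, nr);
      if (!mask[j] && !outside[j]) { outside[j] = 1; q.push(j); }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int i = 0; i < nr * nc; ++i) out[i] = mask[i] || !outside[i];
  return out;
}

// [[Rcpp::export(name = ".distance_transform_cpp")]]
NumericMatrix distance_transform_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol(), n = nr * nc;
  NumericMatrix d(nr, nc);
  std::queue<int> q;
  for (int i = 0; i < n; ++i) {
    if (!mask[i]) { d[i] = 0; q.push(i); }
    else d[i] = R_PosInf;
  }
  // image border counts as background
  for (int r = 0; r < nr; ++r)
    for (int c : {0, nc - 1}) {
      int i = idx(r, c, nr);
      if (mask[i] && d[i] > 1) { d[i] = 1; q.push(i); }
    }
  for (int c = 0; c < nc; ++c)
    for (int r : {0, nr - 1}) {
      int i = idx(r, c, nr);
      if (mask[i] && d[i] > 1) { d[i] = 1; q.push(i); }
    }
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    int i = q.front(); q.pop();
    int r = i % nr, c = i / nr;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int j = idx(rr, cc, nr);
      if (d[j] > d[i] + 1) { d[j] = d[i] + 1; q.push(j); }
    }
  }
  return d;
}

struct GrowEntry {
  double pri;
  long order;
  int pixel;
  int label;
};

struct GrowCmp {
  bool operator()(const GrowEntry& a, const GrowEntry& b) const {
    if (a.pri != b.pri) return a.pri < b.pri;  // max-heap on priority
    return a.order > b.order;                  // FIFO among equals
  }
};

// [[Rcpp::export(name = ".seeded_grow_cpp")]]
IntegerMatrix seeded_grow_cpp(IntegerMatrix seeds, LogicalMatrix mask,
                              NumericMatrix priority) {
  int nr = seeds.nrow(), nc = seeds.ncol(), n = nr * nc;
  IntegerMatrix lab(nr, nc);
  std::priority_queue<GrowEntry, std::vector<GrowEntry>, GrowCmp> pq;
  long counter = 0;
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  for (int i = 0; i < n; ++i)
    lab[i] = (mask[i] && seeds[i] > 0) ? seeds[i] : 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int i = idx(r, c, nr);
      if (lab[i] == 0) continue;
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int j = idx(rr, cc, nr);
        if (mask[j] && lab[j] == 0)
          pq.push({priority[j], counter++, j, lab[i]});
      }
    }
  while (!pq.empty()) {
    GrowEntry e = pq.top(); pq.pop();
    if (lab[e.pixel] != 0) continue;
    lab[e.pixel] = e.label;
    int r = e.pixel % nr, c = e.pixel / nr;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int j = idx(rr, cc, nr);
      if (mask[j] && lab[j] == 0)
        pq.push({priority[j], counter++, j, e.label});
    }
  }
  return lab;
}
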