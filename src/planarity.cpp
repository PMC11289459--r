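// Left-right planarity test (Brandes' formulation of the de
// Fraysseix--Rosenstiehl criterion). Pass 1 orients the graph by DFS and
// computes lowpoints and nesting depths; pass 2 revisits vertices in nesting
// order maintaining a stack of conflict pairs of return-edge intervals.
// Conflict pairs carry serial ids so stack-bottom markers have identity
// semantics. 0 encodes "no edge" / "empty interval".

#include <Rcpp.h>
#include <vector>
#include <algorithm>

namespace {

struct LRState {
  int n, m;
  std::vector<std::vector<int>> nbr, eid;   // undirected adjacency
  std::vector<int> height, parentEdge;      // per vertex (height -1 = unset)
  std::vector<char> oriented;
  std::vector<int> esrc, edst, lowpt, lowpt2, nesting;
  std::vector<std::vector<int>> orderedAdj; // outgoing edges, nesting order
  // conflict-pair stack: intervals (Llow, Lhigh, Rlow, Rhigh) + serial id
  std::vector<int> Sll, Slh, Srl, Srh, Sid;
  int serial = 0;
  std::vector<int> ref, lowptEdge, stackBottom;

  bool conflicting(int lo, int hi, int b) const {
    (void)lo;
    return hi != 0 && lowpt[hi - 1] > lowpt[b - 1];
  }
  int topId() const { return Sid.empty() ? 0 : Sid.back(); }
  void push(int ll, int lh, int rl, int rh, int id) {
    Sll.push_back(ll); Slh.push_back(lh);
    Srl.push_back(rl); Srh.push_back(rh);
    Sid.push_back(id);
  }
  void pop() {
    Sll.pop_back(); Slh.pop_back(); Srl.pop_back(); Srh.pop_back();
    Sid.pop_back();
  }
  int lowestTop() const {
    int ll = Sll.back(), rl = Srl.back();
    if (ll == 0 && Slh.back() == 0) {
      if (rl == 0) return -1;               // fully empty pair
      return lowpt[rl - 1];
    }
    if (rl == 0 && Srh.back() == 0) return lowpt[ll - 1];
    return std::min(lowpt[ll - 1], lowpt[rl - 1]);
  }

  void dfs1(int v) {
    int e = parentEdge[v];
    int hv = height[v];
    const std::vector<int> &ws = nbr[v], &ids = eid[v];
    for (size_t k = 0; k < ws.size(); ++k) {
      int id = ids[k];
      if (oriented[id]) continue;
      int w = ws[k];
      oriented[id] = 1;
      esrc[id] = v; edst[id] = w;
      lowpt[id] = hv; lowpt2[id] = hv;
      if (height[w] < 0) {                  // tree edge
        parentEdge[w] = id + 1;
        height[w] = hv + 1;
        dfs1(w);
      } else {                              // back edge
        lowpt[id] = height[w];
      }
      nesting[id] = 2 * lowpt[id] + (lowpt2[id] < hv ? 1 : 0);
      if (e > 0) {
        int ep = e - 1;
        if (lowpt[id] < lowpt[ep]) {
          lowpt2[ep] = std::min(lowpt[ep], lowpt2[id]);
          lowpt[ep] = lowpt[id];
        } else if (lowpt[id] > lowpt[ep]) {
          lowpt2[ep] = std::min(lowpt2[ep], lowpt[id]);
        } else {
          lowpt2[ep] = std::min(lowpt2[ep], lowpt2[id]);
        }
      }
    }
  }

  bool addConstraints(int ei, int e) {
    int Pll = 0, Plh = 0, Prl = 0, Prh = 0;
    // merge return edges of ei into P's right interval
    for (;;) {
      int Qll = Sll.back(), Qlh = Slh.back(),
          Qrl = Srl.back(), Qrh = Srh.back();
      pop();
      if (!(Qll == 0 && Qlh == 0)) {
        std::swap(Qll, Qrl); std::swap(Qlh, Qrh);
      }
      if (!(Qll == 0 && Qlh == 0)) return false;    // not planar
      if (lowpt[Qrl - 1] > lowpt[e - 1]) {
        if (Prl == 0 && Prh == 0) Prh = Qrh;
        else ref[Prl - 1] = Qrh;
        Prl = Qrl;
      } else {                                      // align
        ref[Qrl - 1] = lowptEdge[e - 1];
      }
      if (topId() == stackBottom[ei - 1]) break;
    }
    // merge conflicting return edges of earlier siblings into the left side
    while (!Sid.empty() &&
           (conflicting(Sll.back(), Slh.back(), ei) ||
            conflicting(Srl.back(), Srh.back(), ei))) {
      int Qll = Sll.back(), Qlh = Slh.back(),
          Qrl = Srl.back(), Qrh = Srh.back();
      pop();
      if (conflicting(Qrl, Qrh, ei)) {
        std::swap(Qll, Qrl); std::swap(Qlh, Qrh);
      }
      if (conflicting(Qrl, Qrh, ei)) return false;  // not planar
      if (Prl != 0) ref[Prl - 1] = Qrh;
      if (Qrl != 0) Prl = Qrl;
      if (Pll == 0 && Plh == 0) Plh = Qlh;
      else ref[Pll - 1] = Qlh;
      Pll = Qll;
    }
    if (!(Pll == 0 && Plh == 0 && Prl == 0 && Prh == 0))
      push(Pll, Plh, Prl, Prh, ++serial);
    return true;
  }

  void removeBackEdges(int e) {
    int u = esrc[e - 1];
    // drop conflict pairs whose lowest return point is u
    while (!Sid.empty() && lowestTop() == height[u]) pop();
    if (!Sid.empty()) {                              // trim the next pair
      int Pll = Sll.back(), Plh = Slh.back(),
          Prl = Srl.back(), Prh = Srh.back();
      int pid = Sid.back();                          // keep identity
      pop();
      while (Plh != 0 && edst[Plh - 1] == u) Plh = ref[Plh - 1];
      if (Plh == 0 && Pll != 0) {                    // left just emptied
        ref[Pll - 1] = Prl;
        Pll = 0;
      }
      while (Prh != 0 && edst[Prh - 1] == u) Prh = ref[Prh - 1];
      if (Prh == 0 && Prl != 0) {                    // right just emptied
        ref[Prl - 1] = Pll;
        Prl = 0;
      }
      push(Pll, Plh, Prl, Prh, pid);
    }
    // the side of e follows the highest remaining return edge
    if (lowpt[e - 1] < height[u] && !Sid.empty()) {
      int hl = Slh.back(), hr = Srh.back();
      if (hl != 0 && (hr == 0 || lowpt[hl - 1] > lowpt[hr - 1]))
        ref[e - 1] = hl;
      else
        ref[e - 1] = hr;
    }
  }

  bool dfs2(int v) {
    int e = parentEdge[v];
    const std::vector<int> &oa = orderedAdj[v];
    for (size_t k = 0; k < oa.size(); ++k) {
      int ei = oa[k];                                // 1-based edge id
      stackBottom[ei - 1] = topId();
      int w = edst[ei - 1];
      if (ei == parentEdge[w]) {                     // tree edge
        if (!dfs2(w)) return false;
      } else {                                       // back edge
        lowptEdge[ei - 1] = ei;
        push(0, 0, ei, ei, ++serial);
      }
      if (lowpt[ei - 1] < height[v]) {               // has a return edge
        if (k == 0) {
          lowptEdge[e - 1] = lowptEdge[ei - 1];
        } else if (!addConstraints(ei, e)) {
          return false;
        }
      }
    }
    if (e > 0) removeBackEdges(e);
    return true;
  }
};

} // namespace

// [[Rcpp::export(name = ".lrPlanarityCpp")]]
bool lrPlanarityCpp(Rcpp::IntegerMatrix edges, int n) {
  LRState st;
  st.n = n;
  st.m = edges.nrow();
  st.nbr.assign(n, {});
  st.eid.assign(n, {});
  for (int k = 0; k < st.m; ++k) {
    int a = edges(k, 0) - 1, b = edges(k, 1) - 1;
    st.nbr[a].push_back(b); st.eid[a].push_back(k);
    st.nbr[b].push_back(a); st.eid[b].push_back(k);
  }
  st.height.assign(n, -1);
  st.parentEdge.assign(n, 0);
  st.oriented.assign(st.m, 0);
  st.esrc.assign(st.m, 0); st.edst.assign(st.m, 0);
  st.lowpt.assign(st.m, 0); st.lowpt2.assign(st.m, 0);
  st.nesting.assign(st.m, 0);

  std::vector<int> roots;
  for (int v = 0; v < n; ++v) {
    if (st.height[v] < 0 && !st.nbr[v].empty()) {
      st.height[v] = 0;
      roots.push_back(v);
      st.dfs1(v);
    }
  }

  std::vector<int> ord(st.m);
  for (int i = 0; i < st.m; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return st.nesting[a] < st.nesting[b];
  });
  st.orderedAdj.assign(n, {});
  for (int id : ord) st.orderedAdj[st.esrc[id]].push_back(id + 1);

  st.ref.assign(st.m, 0);
  st.lowptEdge.assign(st.m, 0);
  st.stackBottom.assign(st.m, 0);

  for (int v : roots)
    if (!st.dfs2(v)) return false;
  return true;
}
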