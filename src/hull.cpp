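// Incremental convex hull of a point set in strictly convex position
// (a Fibonacci lattice on the sphere): yields the 2V-4 face triangulation
// used as the initial vesicle connectivity.
#include "core.h"
using namespace Rcpp;
using namespace dtv;

namespace {

struct HFace {
  int a, b, c;
  bool alive = true;
};

double orient(const V3& p, const V3& a, const V3& b, const V3& c) {
  return dot(p - a, cross(b - a, c - a));
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_convex_hull(NumericMatrix P0) {
  const int n = P0.nrow();
  if (n < 4) stop("need at least 4 points");
  std::vector<V3> P(n);
  for (int i = 0; i < n; ++i) P[i] = {P0(i, 0), P0(i, 1), P0(i, 2)};

  // initial tetrahedron from points 0..3 (generic position assumed)
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  for (int i = 1; i < n && i1 < 0; ++i)
    if (norm(P[i] - P[i0]) > 1e-12) i1 = i;
  for (int i = 1; i < n && i2 < 0; ++i)
    if (i != i1 && norm(cross(P[i1] - P[i0], P[i] - P[i0])) > 1e-12) i2 = i;
  for (int i = 1; i < n && i3 < 0; ++i)
    if (i != i1 && i != i2 &&
        std::fabs(orient(P[i], P[i0], P[i1], P[i2])) > 1e-12)
      i3 = i;
  if (i1 < 0 || i2 < 0 || i3 < 0) stop("degenerate point set");
  if (orient(P[i3], P[i0], P[i1], P[i2]) > 0) std::swap(i1, i2);

  std::vector<HFace> F;
  F.push_back({i0, i1, i2});
  F.push_back({i0, i2, i3});
  F.push_back({i0, i3, i1});
  F.push_back({i1, i3, i2});

  std::vector<char> used(n, 0);
  used[i0] = used[i1] = used[i2] = used[i3] = 1;

  for (int pt = 0; pt < n; ++pt) {
    if (used[pt]) continue;
    used[pt] = 1;
    // faces visible from pt
    std::vector<int> visible;
    for (size_t f = 0; f < F.size(); ++f) {
      if (!F[f].alive) continue;
      if (orient(P[pt], P[F[f].a], P[F[f].b], P[F[f].c]) > 1e-12)
        visible.push_back(static_cast<int>(f));
    }
    if (visible.empty()) continue;  // inside current hull (should not happen)
    // horizon: directed edges of visible faces whose reverse is not visible
    std::unordered_map<uint64_t, int> dirEdges;  // (u<<32|v) -> count
    auto dkey = [](int u, int v) {
      return (static_cast<uint64_t>(u) << 32) | static_cast<uint32_t>(v);
    };
    for (int f : visible) {
      int vv[3] = {F[f].a, F[f].b, F[f].c};
      for (int k = 0; k < 3; ++k)
        dirEdges[dkey(vv[k], vv[(k + 1) % 3])] = 1;
    }
    std::vector<std::pair<int, int>> horizon;
    for (const auto& kv : dirEdges) {
      int u = static_cast<int>(kv.first >> 32);
      int v = static_cast<int>(kv.first & 0xFFFFFFFF);
      if (dirEdges.find(dkey(v, u)) == dirEdges.end())
        horizon.push_back({u, v});
    }
    for (int f : visible) F[f].alive = false;
    for (const auto& e : horizon) F.push_back({e.first, e.second, pt});
  }

  int nf = 0;
  for (const auto& f : F)
    if (f.alive) ++nf;
  IntegerMatrix out(nf, 3);
  int row = 0;
  for (const auto& f : F) {
    if (!f.alive) continue;
    out(row, 0) = f.a + 1;
    out(row, 1) = f.b + 1;
    out(row, 2) = f.c + 1;
    ++row;
  }
  return out;
}
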