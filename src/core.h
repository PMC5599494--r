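// Core data structures and discrete differential geometry for the
// dynamically triangulated vesicle model: closed orientable triangle mesh,
// per-face/edge/vertex geometry, the energy U = U_cc + U_eff + U_act and its
// exact per-vertex gradients, and the three local remeshing moves
// (edge flip, edge split, edge collapse).
#pragma once

#include <Rcpp.h>
#include <vector>
#include <array>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <cmath>
#include <string>

namespace dtv {

// ---------------------------------------------------------------- vectors

struct V3 { double x = 0.0, y = 0.0, z = 0.0; };

inline V3 operator+(V3 a, V3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline V3 operator-(V3 a, V3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline V3 operator*(double s, V3 a) { return {s * a.x, s * a.y, s * a.z}; }
inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline V3 cross(V3 a, V3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double norm(V3 a) { return std::sqrt(dot(a, a)); }

// ------------------------------------------------------------- parameters

// Mechanical constants in model units (l = sqrt(a_eq), k_B T = 1).
struct Params {
  double Kv, veq, Ka, aeq, Kc, Kr, lrep, kact, eta, kBT;
};

inline Params paramsFromList(const Rcpp::List& p) {
  Params q;
  q.Kv   = Rcpp::as<double>(p["K_v"]);
  q.veq  = Rcpp::as<double>(p["v_eq"]);
  q.Ka   = Rcpp::as<double>(p["K_a"]);
  q.aeq  = Rcpp::as<double>(p["a_eq"]);
  q.Kc   = Rcpp::as<double>(p["K_c"]);
  q.Kr   = Rcpp::as<double>(p["K_r"]);
  q.lrep = Rcpp::as<double>(p["l_rep"]);
  q.kact = Rcpp::as<double>(p["kappa_act"]);
  q.eta  = Rcpp::as<double>(p["eta"]);
  q.kBT  = Rcpp::as<double>(p["k_BT"]);
  return q;
}

// Quality gate for topological events: minimum face angle and valence bounds
// keep the triangulation non-degenerate; min_faces guards total collapse.
struct Gate {
  double min_angle;   // radians
  int min_valence;
  int max_valence;
  int min_faces;
};

inline Gate gateFromList(const Rcpp::List& g) {
  Gate q;
  q.min_angle   = Rcpp::as<double>(g["min_angle"]);
  q.min_valence = Rcpp::as<int>(g["min_valence"]);
  q.max_valence = Rcpp::as<int>(g["max_valence"]);
  q.min_faces   = Rcpp::as<int>(g["min_faces"]);
  return q;
}

// ------------------------------------------------------------------ mesh

// Vertices and faces carry tombstone flags so topological events never
// invalidate indices mid-run; compaction happens only on export.
struct Mesh {
  std::vector<V3> P;
  std::vector<std::array<int, 3>> F;  // 0-based, outward orientation
  std::vector<char> vAlive, fAlive;
  int nV = 0, nF = 0;                 // alive counts
};

inline Mesh meshFromR(const Rcpp::NumericMatrix& P0,
                      const Rcpp::IntegerMatrix& F0) {
  Mesh m;
  const int nv = P0.nrow(), nf = F0.nrow();
  m.P.resize(nv);
  for (int i = 0; i < nv; ++i) m.P[i] = {P0(i, 0), P0(i, 1), P0(i, 2)};
  m.F.resize(nf);
  for (int i = 0; i < nf; ++i)
    m.F[i] = {F0(i, 0) - 1, F0(i, 1) - 1, F0(i, 2) - 1};
  m.vAlive.assign(nv, 1);
  m.fAlive.assign(nf, 1);
  m.nV = nv;
  m.nF = nf;
  return m;
}

// Rotate so the smallest vertex index comes first; keeps face tuples in a
// canonical form so that rejected/undone events are bit-identical.
inline std::array<int, 3> normFace(int u, int v, int w) {
  if (u <= v && u <= w) return {u, v, w};
  if (v <= u && v <= w) return {v, w, u};
  return {w, u, v};
}

// ------------------------------------------------------------- adjacency

struct Edge {
  int a = -1, b = -1;  // a < b; a == -1 marks a dead slot
  int f1 = -1, f2 = -1;  // f1 traverses a->b, f2 traverses b->a (-1: boundary)
};

struct Adj {
  std::unordered_map<uint64_t, int> ix;  // ekey -> index into E
  std::vector<Edge> E;
  std::vector<std::vector<int>> vF;      // vertex -> alive incident faces
  int nE = 0;                            // alive edges
};

inline uint64_t ekey(int a, int b) {
  if (a > b) std::swap(a, b);
  return (static_cast<uint64_t>(a) << 32) | static_cast<uint32_t>(b);
}

inline bool hasDirected(const std::array<int, 3>& f, int u, int v) {
  return (f[0] == u && f[1] == v) || (f[1] == u && f[2] == v) ||
         (f[2] == u && f[0] == v);
}

inline int thirdVertex(const std::array<int, 3>& f, int u, int v) {
  for (int k = 0; k < 3; ++k)
    if (f[k] != u && f[k] != v) return f[k];
  return -1;
}

// Build edge table and vertex->face lists; validates 2-manifoldness and
// orientation consistency.  allowOpen permits boundary edges (geometry
// fixtures only); the simulator always runs closed.
inline void buildAdj(const Mesh& m, Adj& A, bool allowOpen) {
  A.ix.clear();
  A.E.clear();
  A.nE = 0;
  A.vF.assign(m.P.size(), {});
  A.ix.reserve(m.F.size() * 2);
  for (size_t f = 0; f < m.F.size(); ++f) {
    if (!m.fAlive[f]) continue;
    const auto& t = m.F[f];
    if (t[0] == t[1] || t[1] == t[2] || t[0] == t[2])
      Rcpp::stop("degenerate face (repeated vertex) at face %d", (int)f + 1);
    for (int k = 0; k < 3; ++k) {
      A.vF[t[k]].push_back(static_cast<int>(f));
      int u = t[k], v = t[(k + 1) % 3];
      uint64_t key = ekey(u, v);
      auto it = A.ix.find(key);
      int ei;
      if (it == A.ix.end()) {
        ei = static_cast<int>(A.E.size());
        A.E.push_back({std::min(u, v), std::max(u, v), -1, -1});
        A.ix.emplace(key, ei);
        ++A.nE;
      } else {
        ei = it->second;
      }
      Edge& e = A.E[ei];
      int& slot = (u < v) ? e.f1 : e.f2;
      if (slot != -1) {
        if (e.f1 != -1 && e.f2 != -1)
          Rcpp::stop("non-manifold edge %d-%d (more than 2 incident faces)",
                     std::min(u, v) + 1, std::max(u, v) + 1);
        Rcpp::stop("inconsistent orientation or duplicate face at edge %d-%d",
                   std::min(u, v) + 1, std::max(u, v) + 1);
      }
      slot = static_cast<int>(f);
    }
  }
  if (!allowOpen) {
    for (const Edge& e : A.E)
      if (e.a >= 0 && (e.f1 == -1 || e.f2 == -1))
        Rcpp::stop("open (boundary) edge %d-%d in a mesh declared closed",
                   e.a + 1, e.b + 1);
  }
}

inline void eraseFrom(std::vector<int>& v, int x) {
  for (size_t i = 0; i < v.size(); ++i)
    if (v[i] == x) { v[i] = v.back(); v.pop_back(); return; }
}

// ------------------------------------------------------------- geometry

inline V3 faceNormalRaw(const Mesh& m, int f) {
  const auto& t = m.F[f];
  return cross(m.P[t[1]] - m.P[t[0]], m.P[t[2]] - m.P[t[0]]);
}

inline double faceArea(const Mesh& m, int f) { return 0.5 * norm(faceNormalRaw(m, f)); }

inline V3 faceCentroid(const Mesh& m, int f) {
  const auto& t = m.F[f];
  return (1.0 / 3.0) * (m.P[t[0]] + m.P[t[1]] + m.P[t[2]]);
}

// Signed contribution of one face to the divergence-theorem volume.
inline double faceVolTerm(const Mesh& m, int f) {
  const auto& t = m.F[f];
  return dot(m.P[t[0]], cross(m.P[t[1]], m.P[t[2]])) / 6.0;
}

// Signed dihedral angle at an interior edge: positive where outward normals
// diverge (locally convex fold), in (-pi, pi).  Sign fixed by the triple
// product of the two unit normals with the edge direction as traversed by f1.
inline double dihedral(const Mesh& m, const Edge& e) {
  V3 n1 = faceNormalRaw(m, e.f1), n2 = faceNormalRaw(m, e.f2);
  double l1 = norm(n1), l2 = norm(n2);
  if (l1 <= 0.0 || l2 <= 0.0)
    Rcpp::stop("zero-area face incident to edge %d-%d", e.a + 1, e.b + 1);
  n1 = (1.0 / l1) * n1;
  n2 = (1.0 / l2) * n2;
  V3 ed = m.P[e.b] - m.P[e.a];
  double le = norm(ed);
  double s = dot(cross(n1, n2), (1.0 / le) * ed);
  double c = dot(n1, n2);
  return std::atan2(s, c);
}

struct Geom {
  std::vector<double> fa;   // face areas (0 for dead)
  std::vector<V3> fn;       // unit normals
  std::vector<V3> fc;       // centroids
  std::vector<double> el;   // edge lengths   (parallel to Adj.E)
  std::vector<double> eth;  // edge dihedrals
  std::vector<double> vM;   // total mean curvature per vertex
  std::vector<double> vA;   // vertex area per vertex
  std::vector<double> vDef; // angle deficit per vertex
  double area = 0.0, vol = 0.0;
  V3 center{0, 0, 0};       // area-weighted centroid of face centroids
};

inline void computeGeom(const Mesh& m, const Adj& A, Geom& G) {
  const size_t nf = m.F.size(), nv = m.P.size(), ne = A.E.size();
  G.fa.assign(nf, 0.0);
  G.fn.assign(nf, V3{});
  G.fc.assign(nf, V3{});
  G.el.assign(ne, 0.0);
  G.eth.assign(ne, 0.0);
  G.vM.assign(nv, 0.0);
  G.vA.assign(nv, 0.0);
  G.vDef.assign(nv, 0.0);
  G.area = 0.0;
  G.vol = 0.0;
  V3 cw{0, 0, 0};
  for (size_t f = 0; f < nf; ++f) {
    if (!m.fAlive[f]) continue;
    V3 n = faceNormalRaw(m, static_cast<int>(f));
    double a2 = norm(n);
    if (a2 <= 0.0) Rcpp::stop("zero-area face %d", (int)f + 1);
    G.fa[f] = 0.5 * a2;
    G.fn[f] = (1.0 / a2) * n;
    G.fc[f] = faceCentroid(m, static_cast<int>(f));
    G.area += G.fa[f];
    G.vol += faceVolTerm(m, static_cast<int>(f));
    cw = cw + G.fa[f] * G.fc[f];
    const auto& t = m.F[f];
    for (int k = 0; k < 3; ++k) {
      G.vA[t[k]] += G.fa[f] / 3.0;
      V3 u = m.P[t[(k + 1) % 3]] - m.P[t[k]];
      V3 v = m.P[t[(k + 2) % 3]] - m.P[t[k]];
      double cang = dot(u, v) / (norm(u) * norm(v));
      cang = std::max(-1.0, std::min(1.0, cang));
      G.vDef[t[k]] += std::acos(cang);
    }
  }
  if (G.area > 0.0) G.center = (1.0 / G.area) * cw;
  for (size_t v = 0; v < nv; ++v)
    if (m.vAlive[v]) G.vDef[v] = 2.0 * M_PI - G.vDef[v];
  for (size_t ei = 0; ei < ne; ++ei) {
    const Edge& e = A.E[ei];
    if (e.a < 0) continue;
    G.el[ei] = norm(m.P[e.b] - m.P[e.a]);
    if (e.f1 != -1 && e.f2 != -1) {
      G.eth[ei] = dihedral(m, e);
      double c = G.el[ei] * G.eth[ei] / 4.0;
      G.vM[e.a] += c;
      G.vM[e.b] += c;
    }
  }
}

// ---------------------------------------------------------------- energy

struct EnergyBK {
  double Ucc = 0, Uvol = 0, Uarea = 0, Ubend = 0, Uact = 0;
  double total() const { return Ucc + Uvol + Uarea + Ubend + Uact; }
};

inline double volEnergy(double v, const Params& p) {
  double x = v / p.veq - 1.0;
  return 0.5 * p.Kv * x * x;
}

// Active per-face weight kappa_act (1 + cos phi)/2 with phi the angle between
// +x and the vector from the vesicle center to the face centroid; phi is
// frozen while differentiating, so the weight multiplies d(area) only.
inline double actWeight(const V3& c, const V3& center, const Params& p) {
  V3 d = c - center;
  double dn = norm(d);
  if (dn <= 0.0) Rcpp::stop("face centroid coincides with the vesicle center");
  return 0.5 * p.kact * (1.0 + d.x / dn);
}

// Short-ranged vertex-pair repulsion via uniform spatial hashing with cell
// size l_rep; optionally accumulates -grad into force.
inline double repulsion(const Mesh& m, const Params& p, std::vector<V3>* force) {
  if (p.Kr <= 0.0 || p.lrep <= 0.0) return 0.0;
  const double h = p.lrep;
  std::unordered_map<uint64_t, std::vector<int>> cells;
  cells.reserve(m.nV * 2);
  auto key3 = [](long ix, long iy, long iz) {
    return (static_cast<uint64_t>(ix & 0x1FFFFF) << 42) |
           (static_cast<uint64_t>(iy & 0x1FFFFF) << 21) |
           static_cast<uint64_t>(iz & 0x1FFFFF);
  };
  for (size_t i = 0; i < m.P.size(); ++i) {
    if (!m.vAlive[i]) continue;
    long ix = static_cast<long>(std::floor(m.P[i].x / h));
    long iy = static_cast<long>(std::floor(m.P[i].y / h));
    long iz = static_cast<long>(std::floor(m.P[i].z / h));
    cells[key3(ix, iy, iz)].push_back(static_cast<int>(i));
  }
  double U = 0.0;
  for (size_t i = 0; i < m.P.size(); ++i) {
    if (!m.vAlive[i]) continue;
    long ix = static_cast<long>(std::floor(m.P[i].x / h));
    long iy = static_cast<long>(std::floor(m.P[i].y / h));
    long iz = static_cast<long>(std::floor(m.P[i].z / h));
    for (long dx = -1; dx <= 1; ++dx)
      for (long dy = -1; dy <= 1; ++dy)
        for (long dz = -1; dz <= 1; ++dz) {
          auto it = cells.find(key3(ix + dx, iy + dy, iz + dz));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            if (j <= static_cast<int>(i)) continue;
            V3 d = m.P[i] - m.P[j];
            double l = norm(d);
            if (l >= h || l <= 0.0) continue;
            double x = l / h - 1.0;
            U += 0.5 * p.Kr * x * x;
            if (force) {
              double dUdl = p.Kr * x / h;
              V3 g = (dUdl / l) * d;  // dU/dr_i
              (*force)[i] = (*force)[i] - g;
              (*force)[j] = (*force)[j] + g;
            }
          }
        }
  }
  return U;
}

inline EnergyBK computeEnergy(const Mesh& m, const Adj& A, const Geom& G,
                              const Params& p, bool useAct) {
  EnergyBK e;
  e.Uvol = volEnergy(G.vol, p);
  for (size_t f = 0; f < m.F.size(); ++f) {
    if (!m.fAlive[f]) continue;
    double x = G.fa[f] / p.aeq - 1.0;
    e.Uarea += 0.5 * p.Ka * x * x;
    if (useAct && p.kact > 0.0)
      e.Uact += actWeight(G.fc[f], G.center, p) * G.fa[f];
  }
  for (size_t v = 0; v < m.P.size(); ++v) {
    if (!m.vAlive[v]) continue;
    if (G.vA[v] <= 0.0) Rcpp::stop("vertex %d has zero vertex area", (int)v + 1);
    e.Ubend += 2.0 * p.Kc * G.vM[v] * G.vM[v] / G.vA[v];
  }
  e.Ucc = repulsion(m, p, nullptr);
  return e;
}

// ---------------------------------------------------------------- forces

// Gradient of the signed dihedral angle at a hinge: edge p->q (as traversed
// by face 1), r opposite in face 1 = (p,q,r), s opposite in face 2 = (q,p,s).
// Standard discrete-shell closed forms; gradients sum to zero.
inline void dihedralGrad(const V3& xp, const V3& xq, const V3& xr, const V3& xs,
                         V3& gp, V3& gq, V3& gr, V3& gs) {
  V3 e = xq - xp;
  double le = norm(e);
  V3 n1 = cross(xq - xp, xr - xp);
  V3 n2 = cross(xp - xq, xs - xq);
  double n1q = dot(n1, n1), n2q = dot(n2, n2);
  gr = (-le / n1q) * n1;
  gs = (-le / n2q) * n2;
  double c1p = dot(xr - xq, e) / (le * n1q);
  double c2p = dot(xs - xq, e) / (le * n2q);
  double c1q = dot(xr - xp, e) / (le * n1q);
  double c2q = dot(xs - xp, e) / (le * n2q);
  gp = (-1.0) * (c1p * n1 + c2p * n2);
  gq = c1q * n1 + c2q * n2;
}

// Exact -grad U for all terms; phi (active) is held constant per step.
inline void computeForces(const Mesh& m, const Adj& A, const Geom& G,
                          const Params& p, bool useAct, std::vector<V3>& force) {
  const size_t nv = m.P.size();
  force.assign(nv, V3{});

  // Volume term: dU/dv * dv/dr, with dv/dr accumulated per face corner.
  double dUdv = p.Kv * (G.vol / p.veq - 1.0) / p.veq;
  // Bending per-vertex coefficients.
  std::vector<double> mOverA(nv, 0.0), m2OverA2(nv, 0.0);
  for (size_t v = 0; v < nv; ++v) {
    if (!m.vAlive[v] || G.vA[v] <= 0.0) continue;
    mOverA[v] = G.vM[v] / G.vA[v];
    m2OverA2[v] = mOverA[v] * mOverA[v];
  }

  for (size_t f = 0; f < m.F.size(); ++f) {
    if (!m.fAlive[f]) continue;
    const auto& t = m.F[f];
    // face coefficient multiplying d(area)/dr: surface elasticity, active
    // tension, and the -M^2/A^2 part of the bending gradient
    double cf = p.Ka * (G.fa[f] / p.aeq - 1.0) / p.aeq
              - (2.0 * p.Kc / 3.0) * (m2OverA2[t[0]] + m2OverA2[t[1]] + m2OverA2[t[2]]);
    if (useAct && p.kact > 0.0) cf += actWeight(G.fc[f], G.center, p);
    for (int k = 0; k < 3; ++k) {
      int v0 = t[k], v1 = t[(k + 1) % 3], v2 = t[(k + 2) % 3];
      V3 dA = 0.5 * cross(G.fn[f], m.P[v2] - m.P[v1]);  // d(area)/dr_{v0}
      force[v0] = force[v0] - cf * dA;
      V3 dV = (1.0 / 6.0) * cross(m.P[v1], m.P[v2]);    // d(vol)/dr_{v0}
      force[v0] = force[v0] - dUdv * dV;
    }
  }

  // Bending edge part: U_b includes sum_e Kc (M_p/A_p + M_q/A_q) (l theta).
  for (size_t ei = 0; ei < A.E.size(); ++ei) {
    const Edge& e = A.E[ei];
    if (e.a < 0 || e.f1 == -1 || e.f2 == -1) continue;
    double be = p.Kc * (mOverA[e.a] + mOverA[e.b]);
    if (be == 0.0) continue;
    int r = thirdVertex(m.F[e.f1], e.a, e.b);
    int s = thirdVertex(m.F[e.f2], e.a, e.b);
    const V3 &xp = m.P[e.a], &xq = m.P[e.b];
    V3 gp, gq, gr, gs;
    dihedralGrad(xp, xq, m.P[r], m.P[s], gp, gq, gr, gs);
    double l = G.el[ei], th = G.eth[ei];
    V3 dlp = (1.0 / l) * (xp - xq);  // dl/dr_p
    force[e.a] = force[e.a] - be * (th * dlp + l * gp);
    force[e.b] = force[e.b] - be * ((-1.0) * (th * dlp) + l * gq);
    force[r] = force[r] - (be * l) * gr;
    force[s] = force[s] - (be * l) * gs;
  }

  repulsion(m, p, &force);
}

// --------------------------------------------------- topological operations

enum class Reason {
  ok, dead_edge, boundary_edge, opposite_connected, valence_low, valence_high,
  quality, link_condition, min_faces, reservoir_empty
};

inline const char* reasonStr(Reason r) {
  switch (r) {
    case Reason::ok: return "ok";
    case Reason::dead_edge: return "edge does not exist";
    case Reason::boundary_edge: return "edge is not interior (needs 2 faces)";
    case Reason::opposite_connected: return "opposite vertices already share an edge";
    case Reason::valence_low: return "vertex valence would drop below minimum";
    case Reason::valence_high: return "vertex valence would exceed maximum";
    case Reason::quality: return "resulting face quality below minimum angle";
    case Reason::link_condition: return "link condition violated (collapse not manifold)";
    case Reason::min_faces: return "face count would drop below minimum";
    case Reason::reservoir_empty: return "reservoir has too few molecules";
  }
  return "unknown";
}

inline double minAngle(const V3& a, const V3& b, const V3& c) {
  V3 u = b - a, v = c - a, w = c - b;
  double lu = norm(u), lv = norm(v), lw = norm(w);
  if (lu <= 0.0 || lv <= 0.0 || lw <= 0.0) return 0.0;
  auto ang = [](V3 p, V3 q, double lp, double lq) {
    double cg = dot(p, q) / (lp * lq);
    cg = std::max(-1.0, std::min(1.0, cg));
    return std::acos(cg);
  };
  double a1 = ang(u, v, lu, lv);
  double a2 = ang((-1.0) * u, w, lu, lw);
  double a3 = M_PI - a1 - a2;
  return std::min(a1, std::min(a2, a3));
}

inline std::vector<int> vertexNeighbors(const Mesh& m, const Adj& A, int v) {
  std::vector<int> nb;
  for (int f : A.vF[v]) {
    for (int k = 0; k < 3; ++k) {
      int u = m.F[f][k];
      if (u == v) continue;
      if (std::find(nb.begin(), nb.end(), u) == nb.end()) nb.push_back(u);
    }
  }
  return nb;
}

inline int edgeIndex(const Adj& A, int a, int b) {
  auto it = A.ix.find(ekey(a, b));
  return it == A.ix.end() ? -1 : it->second;
}

// ---- flip

inline Reason flipLegal(const Mesh& m, const Adj& A, int ei, const Gate& g) {
  if (ei < 0 || A.E[ei].a < 0) return Reason::dead_edge;
  const Edge& e = A.E[ei];
  if (e.f1 == -1 || e.f2 == -1) return Reason::boundary_edge;
  int r = thirdVertex(m.F[e.f1], e.a, e.b);
  int s = thirdVertex(m.F[e.f2], e.a, e.b);
  if (edgeIndex(A, r, s) >= 0) return Reason::opposite_connected;
  // valence floor applies to interior vertices (boundary vertices of open
  // test patches have one more edge than faces and may drop lower)
  for (int v : {e.a, e.b}) {
    if (static_cast<int>(A.vF[v].size()) - 1 < g.min_valence) {
      bool interior = vertexNeighbors(m, A, v).size() == A.vF[v].size();
      if (interior) return Reason::valence_low;
    }
  }
  if (static_cast<int>(A.vF[r].size()) + 1 > g.max_valence ||
      static_cast<int>(A.vF[s].size()) + 1 > g.max_valence)
    return Reason::valence_high;
  if (minAngle(m.P[e.a], m.P[s], m.P[r]) < g.min_angle ||
      minAngle(m.P[e.b], m.P[r], m.P[s]) < g.min_angle)
    return Reason::quality;
  return Reason::ok;
}

// Replace edge (a,b) by the opposite diagonal (r,s).  The edge slot is
// reused; face ids are unchanged.  Involution on connectivity.
inline void applyFlip(Mesh& m, Adj& A, int ei) {
  Edge& e = A.E[ei];
  const int a = e.a, b = e.b, f1 = e.f1, f2 = e.f2;
  int r = thirdVertex(m.F[f1], a, b);
  int s = thirdVertex(m.F[f2], a, b);
  m.F[f1] = normFace(a, s, r);
  m.F[f2] = normFace(b, r, s);
  // boundary edge (b,r): face f1 -> f2 ; (a,s): face f2 -> f1
  auto fixEdge = [&](int u, int v, int from, int to) {
    Edge& be = A.E[A.ix[ekey(u, v)]];
    if (be.f1 == from) be.f1 = to; else be.f2 = to;
  };
  fixEdge(b, r, f1, f2);
  fixEdge(a, s, f2, f1);
  A.ix.erase(ekey(a, b));
  int na = std::min(r, s), nb = std::max(r, s);
  int nf1 = hasDirected(m.F[f1], na, nb) ? f1 : f2;
  int nf2 = (nf1 == f1) ? f2 : f1;
  e = {na, nb, nf1, nf2};
  A.ix[ekey(na, nb)] = ei;
  eraseFrom(A.vF[a], f2);
  eraseFrom(A.vF[b], f1);
  A.vF[r].push_back(f2);
  A.vF[s].push_back(f1);
}

// ---- split

inline Reason splitLegal(const Mesh& m, const Adj& A, int ei, const Gate& g) {
  if (ei < 0 || A.E[ei].a < 0) return Reason::dead_edge;
  const Edge& e = A.E[ei];
  if (e.f1 == -1 || e.f2 == -1) return Reason::boundary_edge;
  int r = thirdVertex(m.F[e.f1], e.a, e.b);
  int s = thirdVertex(m.F[e.f2], e.a, e.b);
  if (static_cast<int>(A.vF[r].size()) + 1 > g.max_valence ||
      static_cast<int>(A.vF[s].size()) + 1 > g.max_valence)
    return Reason::valence_high;
  V3 mid = 0.5 * (m.P[e.a] + m.P[e.b]);
  if (minAngle(m.P[e.a], mid, m.P[r]) < g.min_angle ||
      minAngle(mid, m.P[e.b], m.P[r]) < g.min_angle ||
      minAngle(m.P[e.b], mid, m.P[s]) < g.min_angle ||
      minAngle(mid, m.P[e.a], m.P[s]) < g.min_angle)
    return Reason::quality;
  return Reason::ok;
}

// Insert the midpoint vertex on edge (a,b); each incident face is split
// toward its opposite vertex.  dV=+1, dF=+2, dE=+3; geometry pointwise
// unchanged at the instant of the split.  Returns the new vertex id.
inline int applySplit(Mesh& m, Adj& A, int ei) {
  Edge e = A.E[ei];
  const int a = e.a, b = e.b, f1 = e.f1, f2 = e.f2;
  int r = thirdVertex(m.F[f1], a, b);
  int s = thirdVertex(m.F[f2], a, b);
  int mm = static_cast<int>(m.P.size());
  m.P.push_back(0.5 * (m.P[a] + m.P[b]));
  m.vAlive.push_back(1);
  ++m.nV;
  A.vF.push_back({});
  int g1 = static_cast<int>(m.F.size());      // (m,b,r)
  int g2 = g1 + 1;                            // (m,a,s)
  m.F[f1] = normFace(a, mm, r);
  m.F[f2] = normFace(b, mm, s);
  m.F.push_back(normFace(mm, b, r));
  m.F.push_back(normFace(mm, a, s));
  m.fAlive.push_back(1);
  m.fAlive.push_back(1);
  m.nF += 2;
  auto fixEdge = [&](int u, int v, int from, int to) {
    Edge& be = A.E[A.ix[ekey(u, v)]];
    if (be.f1 == from) be.f1 = to; else be.f2 = to;
  };
  fixEdge(b, r, f1, g1);
  fixEdge(a, s, f2, g2);
  A.ix.erase(ekey(a, b));
  auto addEdge = [&](int u, int v, int fa, int fb) {
    int na = std::min(u, v), nb = std::max(u, v);
    int nf1 = hasDirected(m.F[fa], na, nb) ? fa : fb;
    int nf2 = (nf1 == fa) ? fb : fa;
    int slot = static_cast<int>(A.E.size());
    A.E.push_back({na, nb, nf1, nf2});
    A.ix[ekey(na, nb)] = slot;
    ++A.nE;
  };
  // reuse the old slot for (a,m)
  {
    int na = std::min(a, mm), nb = std::max(a, mm);
    int nf1 = hasDirected(m.F[f1], na, nb) ? f1 : g2;
    int nf2 = (nf1 == f1) ? g2 : f1;
    A.E[ei] = {na, nb, nf1, nf2};
    A.ix[ekey(na, nb)] = ei;
  }
  addEdge(mm, b, f2, g1);
  addEdge(mm, r, f1, g1);
  addEdge(mm, s, f2, g2);
  eraseFrom(A.vF[b], f1);
  A.vF[b].push_back(g1);
  eraseFrom(A.vF[a], f2);
  A.vF[a].push_back(g2);
  A.vF[r].push_back(g1);
  A.vF[s].push_back(g2);
  A.vF[mm] = {f1, f2, g1, g2};
  return mm;
}

// ---- collapse (merge)

inline Reason collapseLegal(const Mesh& m, const Adj& A, int ei, const Gate& g) {
  if (ei < 0 || A.E[ei].a < 0) return Reason::dead_edge;
  const Edge& e = A.E[ei];
  if (e.f1 == -1 || e.f2 == -1) return Reason::boundary_edge;
  int r = thirdVertex(m.F[e.f1], e.a, e.b);
  int s = thirdVertex(m.F[e.f2], e.a, e.b);
  // link condition: common neighbors of a and b must be exactly {r, s}
  std::vector<int> na = vertexNeighbors(m, A, e.a);
  std::vector<int> nb = vertexNeighbors(m, A, e.b);
  int common = 0;
  bool extra = false;
  for (int u : na)
    if (std::find(nb.begin(), nb.end(), u) != nb.end()) {
      ++common;
      if (u != r && u != s) extra = true;
    }
  if (common != 2 || extra) return Reason::link_condition;
  int valM = static_cast<int>(A.vF[e.a].size() + A.vF[e.b].size()) - 4;
  if (valM < g.min_valence) return Reason::valence_low;
  if (valM > g.max_valence) return Reason::valence_high;
  if (static_cast<int>(A.vF[r].size()) - 1 < g.min_valence ||
      static_cast<int>(A.vF[s].size()) - 1 < g.min_valence)
    return Reason::valence_low;
  if (m.nF - 2 < g.min_faces) return Reason::min_faces;
  // quality of every surviving face with a/b moved to the midpoint
  V3 mid = 0.5 * (m.P[e.a] + m.P[e.b]);
  for (int which = 0; which < 2; ++which) {
    int v = which == 0 ? e.a : e.b;
    for (int f : A.vF[v]) {
      if (f == e.f1 || f == e.f2) continue;
      V3 q[3];
      for (int k = 0; k < 3; ++k) {
        int u = m.F[f][k];
        q[k] = (u == e.a || u == e.b) ? mid : m.P[u];
      }
      if (minAngle(q[0], q[1], q[2]) < g.min_angle) return Reason::quality;
    }
  }
  return Reason::ok;
}

// Collapse edge (a,b) to its midpoint (kept as vertex a); the two incident
// faces are removed.  dV=-1, dF=-2, dE=-3.
inline void applyCollapse(Mesh& m, Adj& A, int ei) {
  Edge e = A.E[ei];
  const int a = e.a, b = e.b, f1 = e.f1, f2 = e.f2;
  int r = thirdVertex(m.F[f1], a, b);
  int s = thirdVertex(m.F[f2], a, b);
  m.P[a] = 0.5 * (m.P[a] + m.P[b]);
  // rewire edges at b
  std::vector<int> nbB = vertexNeighbors(m, A, b);
  // faces at b (excluding dying ones) get b -> a
  std::vector<int> facesB = A.vF[b];
  for (int f : facesB) {
    if (f == f1 || f == f2) continue;
    auto& t = m.F[f];
    for (int k = 0; k < 3; ++k)
      if (t[k] == b) t[k] = a;
    t = normFace(t[0], t[1], t[2]);
  }
  for (int x : nbB) {
    if (x == a) continue;
    int bei = edgeIndex(A, b, x);
    Edge be = A.E[bei];
    A.ix.erase(ekey(b, x));
    if (x == r || x == s) {
      int dying = (x == r) ? f1 : f2;
      int survivor = (be.f1 == dying) ? be.f2 : be.f1;
      int aei = edgeIndex(A, a, x);
      Edge& ae = A.E[aei];
      if (ae.f1 == dying) ae.f1 = survivor; else ae.f2 = survivor;
      A.E[bei].a = -1;  // dead slot
      --A.nE;
    } else {
      // edge becomes (a,x); faces unchanged ids, tuples already rewritten
      int na = std::min(a, x), nb2 = std::max(a, x);
      int nf1 = hasDirected(m.F[be.f1], na, nb2) ? be.f1 : be.f2;
      int nf2 = (nf1 == be.f1) ? be.f2 : be.f1;
      A.E[bei] = {na, nb2, nf1, nf2};
      A.ix[ekey(na, nb2)] = bei;
    }
  }
  A.ix.erase(ekey(a, b));
  A.E[ei].a = -1;
  --A.nE;
  // vertex->face lists
  eraseFrom(A.vF[a], f1);
  eraseFrom(A.vF[a], f2);
  eraseFrom(A.vF[r], f1);
  eraseFrom(A.vF[s], f2);
  for (int f : facesB)
    if (f != f1 && f != f2) A.vF[a].push_back(f);
  A.vF[b].clear();
  m.vAlive[b] = 0;
  --m.nV;
  m.fAlive[f1] = 0;
  m.fAlive[f2] = 0;
  m.nF -= 2;
}

// ------------------------------------------- local energies for flip trials

// Bending energy 2 Kc M^2/A of a single vertex, recomputed from scratch.
inline double bendAt(const Mesh& m, const Adj& A, int v, const Params& p) {
  double Av = 0.0, Mv = 0.0;
  for (int f : A.vF[v]) {
    Av += faceArea(m, f) / 3.0;
    const auto& t = m.F[f];
    for (int k = 0; k < 3; ++k) {
      if (t[k] != v) continue;
      for (int other : {t[(k + 1) % 3], t[(k + 2) % 3]}) {
        int ei = edgeIndex(A, v, other);
        const Edge& e = A.E[ei];
        if (e.f1 == -1 || e.f2 == -1) continue;
        double l = norm(m.P[e.b] - m.P[e.a]);
        // each interior edge is visited by its two incident faces: half each
        Mv += 0.5 * l * dihedral(m, e) / 4.0;
      }
    }
  }
  if (Av <= 0.0) Rcpp::stop("vertex %d has zero vertex area", v + 1);
  return 2.0 * p.Kc * Mv * Mv / Av;
}

// Stencil energy for a flip: bending at {a,b,r,s} + area/active of the two
// faces (volume handled by the caller through the running total).
inline double flipStencilEnergy(const Mesh& m, const Adj& A, int ei,
                                const Params& p, bool useAct, const V3& center) {
  const Edge& e = A.E[ei];
  int r = thirdVertex(m.F[e.f1], e.a, e.b);
  int s = thirdVertex(m.F[e.f2], e.a, e.b);
  double U = bendAt(m, A, e.a, p) + bendAt(m, A, e.b, p) +
             bendAt(m, A, r, p) + bendAt(m, A, s, p);
  for (int f : {e.f1, e.f2}) {
    double a = faceArea(m, f);
    double x = a / p.aeq - 1.0;
    U += 0.5 * p.Ka * x * x;
    if (useAct && p.kact > 0.0)
      U += actWeight(faceCentroid(m, f), center, p) * a;
  }
  return U;
}

}  // namespace dtv
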