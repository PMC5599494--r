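#include "core.h"
using namespace Rcpp;
using namespace dtv;

namespace {

// Compact tombstoned mesh back to dense R matrices (1-based).
List meshToR(const Mesh& m, int newVertex) {
  std::vector<int> vmap(m.P.size(), -1);
  int nv = 0;
  for (size_t i = 0; i < m.P.size(); ++i)
    if (m.vAlive[i]) vmap[i] = nv++;
  NumericMatrix P(nv, 3);
  for (size_t i = 0; i < m.P.size(); ++i) {
    if (!m.vAlive[i]) continue;
    P(vmap[i], 0) = m.P[i].x;
    P(vmap[i], 1) = m.P[i].y;
    P(vmap[i], 2) = m.P[i].z;
  }
  int nf = 0;
  for (size_t f = 0; f < m.F.size(); ++f)
    if (m.fAlive[f]) ++nf;
  IntegerMatrix F(nf, 3);
  int row = 0;
  for (size_t f = 0; f < m.F.size(); ++f) {
    if (!m.fAlive[f]) continue;
    for (int k = 0; k < 3; ++k) F(row, k) = vmap[m.F[f][k]] + 1;
    ++row;
  }
  return List::create(_["positions"] = P, _["faces"] = F,
                      _["new_vertex"] = newVertex >= 0 ? vmap[newVertex] + 1
                                                       : NA_INTEGER);
}

}  // namespace

// Apply one topological operation ("flip", "split", "merge") to edge (a,b).
// Returns ok = FALSE with a named reason when the move is illegal.
// [[Rcpp::export]]
List cpp_apply_op(NumericMatrix P, IntegerMatrix F, int a, int b,
                  std::string op, List gate, bool closed) {
  Mesh m = meshFromR(P, F);
  Gate g = gateFromList(gate);
  Adj A;
  buildAdj(m, A, !closed);
  int ei = edgeIndex(A, a - 1, b - 1);
  Reason rs;
  int newVertex = -1;
  if (op == "flip") {
    rs = flipLegal(m, A, ei, g);
    if (rs == Reason::ok) applyFlip(m, A, ei);
  } else if (op == "split") {
    rs = splitLegal(m, A, ei, g);
    if (rs == Reason::ok) newVertex = applySplit(m, A, ei);
  } else if (op == "merge") {
    rs = collapseLegal(m, A, ei, g);
    if (rs == Reason::ok) applyCollapse(m, A, ei);
  } else {
    stop("unknown operation '%s'", op.c_str());
  }
  if (rs != Reason::ok)
    return List::create(_["ok"] = false, _["reason"] = reasonStr(rs));
  List out = meshToR(m, newVertex);
  out["ok"] = true;
  out["reason"] = "ok";
  return out;
}

// Legality check only (no modification).
// [[Rcpp::export]]
List cpp_op_legal(NumericMatrix P, IntegerMatrix F, int a, int b,
                  std::string op, List gate, bool closed) {
  Mesh m = meshFromR(P, F);
  Gate g = gateFromList(gate);
  Adj A;
  buildAdj(m, A, !closed);
  int ei = edgeIndex(A, a - 1, b - 1);
  Reason rs = op == "flip"    ? flipLegal(m, A, ei, g)
              : op == "split" ? splitLegal(m, A, ei, g)
              : op == "merge" ? collapseLegal(m, A, ei, g)
                              : Reason::dead_edge;
  return List::create(_["ok"] = rs == Reason::ok, _["reason"] = reasonStr(rs));
}

// Energy gap Delta_i U of flipping edge (a,b), evaluated over the local
// stencil (bending at the four stencil vertices, area/active of the two
// faces, volume through the running total; repulsion is position-invariant).
// [[Rcpp::export]]
List cpp_flip_delta(NumericMatrix P, IntegerMatrix F, int a, int b, List par,
                    List gate, bool use_act, bool closed) {
  Mesh m = meshFromR(P, F);
  Params p = paramsFromList(par);
  Gate g = gateFromList(gate);
  if (!closed) p.Kv = 0.0;  // no enclosed volume on an open patch
  Adj A;
  buildAdj(m, A, !closed);
  Geom G;
  computeGeom(m, A, G);
  int ei = edgeIndex(A, a - 1, b - 1);
  Reason rs = flipLegal(m, A, ei, g);
  if (rs != Reason::ok)
    return List::create(_["ok"] = false, _["reason"] = reasonStr(rs),
                        _["delta"] = NA_REAL);
  const Edge& e = A.E[ei];
  double volBefore = faceVolTerm(m, e.f1) + faceVolTerm(m, e.f2);
  double before = flipStencilEnergy(m, A, ei, p, use_act, G.center);
  applyFlip(m, A, ei);
  double volAfter = faceVolTerm(m, e.f1) + faceVolTerm(m, e.f2);
  double after = flipStencilEnergy(m, A, ei, p, use_act, G.center);
  applyFlip(m, A, ei);  // restore (involution)
  double dU = (after - before) +
              volEnergy(G.vol + (volAfter - volBefore), p) - volEnergy(G.vol, p);
  return List::create(_["ok"] = true, _["reason"] = "ok", _["delta"] = dU);
}

// Smallest interior angle over all faces (degrees) - triangle-quality probe.
// [[Rcpp::export]]
double cpp_min_face_angle(NumericMatrix P, IntegerMatrix F) {
  Mesh m = meshFromR(P, F);
  double best = M_PI;
  for (size_t f = 0; f < m.F.size(); ++f) {
    const auto& t = m.F[f];
    best = std::min(best, minAngle(m.P[t[0]], m.P[t[1]], m.P[t[2]]));
  }
  return best * 180.0 / M_PI;
}
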