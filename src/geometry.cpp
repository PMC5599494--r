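#include "core.h"
using namespace Rcpp;
using namespace dtv;

// Validate a mesh (manifoldness, orientation) and return counts.
// [[Rcpp::export]]
List cpp_validate(NumericMatrix P, IntegerMatrix F, bool closed) {
  Mesh m = meshFromR(P, F);
  Adj A;
  buildAdj(m, A, !closed);
  int boundary = 0;
  for (const Edge& e : A.E)
    if (e.a >= 0 && (e.f1 == -1 || e.f2 == -1)) ++boundary;
  return List::create(_["n_edges"] = A.nE, _["n_boundary_edges"] = boundary);
}

// Full geometry cache: per-face, per-edge and per-vertex quantities.
// [[Rcpp::export]]
List cpp_geometry(NumericMatrix P, IntegerMatrix F, bool closed) {
  Mesh m = meshFromR(P, F);
  Adj A;
  buildAdj(m, A, !closed);
  Geom G;
  computeGeom(m, A, G);
  const int nf = m.F.size(), nv = m.P.size(), ne = A.E.size();
  NumericVector fa(nf);
  NumericMatrix fn(nf, 3), fc(nf, 3);
  for (int f = 0; f < nf; ++f) {
    fa[f] = G.fa[f];
    fn(f, 0) = G.fn[f].x; fn(f, 1) = G.fn[f].y; fn(f, 2) = G.fn[f].z;
    fc(f, 0) = G.fc[f].x; fc(f, 1) = G.fc[f].y; fc(f, 2) = G.fc[f].z;
  }
  IntegerMatrix ed(ne, 2);
  NumericVector el(ne), eth(ne);
  for (int e = 0; e < ne; ++e) {
    ed(e, 0) = A.E[e].a + 1;
    ed(e, 1) = A.E[e].b + 1;
    el[e] = G.el[e];
    eth[e] = (A.E[e].f1 != -1 && A.E[e].f2 != -1) ? G.eth[e] : NA_REAL;
  }
  NumericVector vM(nv), vA(nv), vDef(nv);
  for (int v = 0; v < nv; ++v) {
    vM[v] = G.vM[v]; vA[v] = G.vA[v]; vDef[v] = G.vDef[v];
  }
  return List::create(
      _["face_area"] = fa, _["face_normal"] = fn, _["face_centroid"] = fc,
      _["edges"] = ed, _["edge_length"] = el, _["edge_dihedral"] = eth,
      _["vertex_M"] = vM, _["vertex_A"] = vA, _["angle_deficit"] = vDef,
      _["total_area"] = G.area, _["volume"] = G.vol,
      _["center"] = NumericVector::create(G.center.x, G.center.y, G.center.z));
}

// Signed enclosed volume without orientation normalization.
// [[Rcpp::export]]
double cpp_signed_volume(NumericMatrix P, IntegerMatrix F) {
  Mesh m = meshFromR(P, F);
  double v = 0.0;
  for (int f = 0; f < (int)m.F.size(); ++f) v += faceVolTerm(m, f);
  return v;
}

// Energy breakdown U_cc, U_volume, U_area, U_bending, U_act.
// [[Rcpp::export]]
NumericVector cpp_energy(NumericMatrix P, IntegerMatrix F, List par,
                         bool use_act, bool closed) {
  Mesh m = meshFromR(P, F);
  Params p = paramsFromList(par);
  Adj A;
  buildAdj(m, A, !closed);
  Geom G;
  computeGeom(m, A, G);
  if (!closed) G.vol = NA_REAL;
  EnergyBK e;
  e.Uvol = closed ? volEnergy(G.vol, p) : 0.0;
  EnergyBK full = computeEnergy(m, A, G, p, use_act);
  full.Uvol = e.Uvol;
  return NumericVector::create(
      _["U_cc"] = full.Ucc, _["U_volume"] = full.Uvol, _["U_area"] = full.Uarea,
      _["U_bending"] = full.Ubend, _["U_act"] = full.Uact,
      _["U_total"] = full.total());
}

// Exact per-vertex forces -grad U (phi of the active term frozen).
// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix P, IntegerMatrix F, List par,
                         bool use_act, bool closed) {
  Mesh m = meshFromR(P, F);
  Params p = paramsFromList(par);
  Adj A;
  buildAdj(m, A, !closed);
  Geom G;
  computeGeom(m, A, G);
  if (!closed) p.Kv = 0.0;  // volume undefined for open patches
  std::vector<V3> frc;
  computeForces(m, A, G, p, use_act, frc);
  NumericMatrix out(m.P.size(), 3);
  for (size_t i = 0; i < frc.size(); ++i) {
    if (!R_finite(frc[i].x) || !R_finite(frc[i].y) || !R_finite(frc[i].z))
      stop("non-finite force at vertex %d", (int)i + 1);
    out(i, 0) = frc[i].x; out(i, 1) = frc[i].y; out(i, 2) = frc[i].z;
  }
  return out;
}

// Vertex-pair repulsion energy only (positions may come without faces).
// [[Rcpp::export]]
double cpp_repulsion(NumericMatrix P, double Kr, double lrep) {
  Mesh m;
  const int nv = P.nrow();
  m.P.resize(nv);
  for (int i = 0; i < nv; ++i) m.P[i] = {P(i, 0), P(i, 1), P(i, 2)};
  m.vAlive.assign(nv, 1);
  m.nV = nv;
  Params p{};
  p.Kr = Kr;
  p.lrep = lrep;
  return repulsion(m, p, nullptr);
}
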