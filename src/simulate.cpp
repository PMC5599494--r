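// Time integration of the overdamped Langevin equation with interleaved
// topological sweeps: per mechanical step, every edge is attempted for a
// flip with probability dt/tau_f (Metropolis on the local energy gap) and
// for a turnover move with probability dt/tau_t (split or merge with equal
// probability, accepted on the strain-dependent cost and the reservoir
// chemical potential).  All randomness comes from R's RNG so runs are
// reproducible from set.seed().
#include "core.h"
using namespace Rcpp;
using namespace dtv;

namespace {

struct Ctrl {
  double dt;
  int steps, sample_every;
  double tau_f, tau_t, eps_t, gamma_t, m_u;
  double M_eq, M_inst, M_tt;
  bool use_noise, use_act, greedy, turnover_on, mechanics;
  double stop_tol;     // relax: stop when |dU| per step < tol (0 = never)
  bool log_flip_attempts, log_events;
};

Ctrl ctrlFromList(const List& c) {
  Ctrl q;
  q.dt = as<double>(c["dt"]);
  q.steps = as<int>(c["steps"]);
  q.sample_every = as<int>(c["sample_every"]);
  q.tau_f = as<double>(c["tau_f"]);
  q.tau_t = as<double>(c["tau_t"]);
  q.eps_t = as<double>(c["eps_t"]);
  q.gamma_t = as<double>(c["gamma_t"]);
  q.m_u = as<double>(c["m_u"]);
  q.M_eq = as<double>(c["M_eq"]);
  q.M_inst = as<double>(c["M_inst"]);
  q.M_tt = as<double>(c["M_tt"]);
  q.use_noise = as<bool>(c["use_noise"]);
  q.use_act = as<bool>(c["use_act"]);
  q.greedy = as<bool>(c["greedy"]);
  q.turnover_on = as<bool>(c["turnover_on"]);
  q.mechanics = as<bool>(c["mechanics"]);
  q.stop_tol = as<double>(c["stop_tol"]);
  q.log_flip_attempts = as<bool>(c["log_flip_attempts"]);
  q.log_events = as<bool>(c["log_events"]);
  return q;
}

// mu_r = -dG_r/dM_t with the cubic reservoir free energy.
double chemPot(double Mt, double Meq, double Minst, double mu_mol, double kBT) {
  double x = Mt - Meq;
  return -(kBT / (4.0 * mu_mol * Minst * Minst)) * x * std::fabs(x);
}

struct EventLog {
  // acc: 1 accepted, 0 rejected by the Metropolis draw, -1 illegal move
  std::vector<double> t, kind, va, vb, d1, d2, acc, angle, strain;
  void push(double tt, int k, int a, int b, double e1, double e2, double ac,
            double ang, double st) {
    t.push_back(tt); kind.push_back(k); va.push_back(a + 1); vb.push_back(b + 1);
    d1.push_back(e1); d2.push_back(e2); acc.push_back(ac);
    angle.push_back(ang); strain.push_back(st);
  }
};

double polarAngle(const V3& site, const V3& center) {
  V3 d = site - center;
  double dn = norm(d);
  if (dn <= 0.0) return NA_REAL;
  double c = std::max(-1.0, std::min(1.0, d.x / dn));
  return std::acos(c);
}

void shuffled(std::vector<int>& idx) {
  for (int i = static_cast<int>(idx.size()) - 1; i > 0; --i) {
    int j = static_cast<int>(std::floor(unif_rand() * (i + 1)));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix P0, IntegerMatrix F0, List par, List ctrl,
                  List gate, List state) {
  Mesh m = meshFromR(P0, F0);
  Params p = paramsFromList(par);
  Ctrl c = ctrlFromList(ctrl);
  Gate g = gateFromList(gate);

  double t = as<double>(state["t"]);
  double Mt = as<double>(state["M_t"]);
  double nFlipAtt = as<double>(state["flip_att"]);
  double nFlipAcc = as<double>(state["flip_acc"]);
  double nTurnAtt = as<double>(state["turn_att"]);
  double nSplit = as<double>(state["splits"]);
  double nMerge = as<double>(state["merges"]);

  Adj A;
  buildAdj(m, A, false);
  Geom G;
  std::vector<V3> frc;
  EventLog ev;

  const int ncolObs = 21;
  int maxRows = c.steps / std::max(1, c.sample_every) + 2;
  NumericMatrix obs(maxRows, ncolObs);
  int nObs = 0;
  auto record = [&](double tt) {
    computeGeom(m, A, G);
    EnergyBK e = computeEnergy(m, A, G, p, c.use_act);
    double meanK = 0.0;
    int nv = 0;
    for (size_t v = 0; v < m.P.size(); ++v) {
      if (!m.vAlive[v]) continue;
      meanK += G.vDef[v] / G.vA[v];
      ++nv;
    }
    meanK /= std::max(1, nv);
    double sph = G.vol / ((4.0 * M_PI / 3.0) *
                          std::pow(G.area / (4.0 * M_PI), 1.5));
    double* row = &obs(nObs, 0);
    int k = 0;
    double vals[ncolObs] = {tt, (double)m.nF, Mt, G.area, G.vol, sph,
                            e.Ucc, e.Uvol, e.Uarea, e.Ubend, e.Uact, e.total(),
                            G.center.x, G.center.y, G.center.z, meanK,
                            nFlipAtt, nFlipAcc, nTurnAtt, nSplit, nMerge};
    for (k = 0; k < ncolObs; ++k) obs(nObs, k) = vals[k];
    (void)row;
    ++nObs;
  };

  double Uprev = NA_REAL;
  bool converged = false;
  int stepsRun = 0;
  double noiseSd = std::sqrt(2.0 * p.kBT * c.dt / p.eta);
  double pFlip = R_finite(c.tau_f) ? std::min(1.0, c.dt / c.tau_f) : 0.0;
  double pTurn = (c.turnover_on && R_finite(c.tau_t))
                     ? std::min(1.0, c.dt / c.tau_t) : 0.0;

  std::vector<int> snapshot;

  for (int step = 0; step < c.steps; ++step) {
    // ---- mechanics
    computeGeom(m, A, G);
    if (c.stop_tol > 0.0) {
      EnergyBK e = computeEnergy(m, A, G, p, c.use_act);
      double U = e.total();
      if (R_finite(Uprev) && std::fabs(U - Uprev) < c.stop_tol) {
        converged = true;
        break;
      }
      Uprev = U;
    }
    if (c.mechanics) {
      computeForces(m, A, G, p, c.use_act, frc);
      double mob = c.dt / p.eta;
      for (size_t i = 0; i < m.P.size(); ++i) {
        if (!m.vAlive[i]) continue;
        V3& r = m.P[i];
        r = r + mob * frc[i];
        if (c.use_noise) {
          r.x += noiseSd * norm_rand();
          r.y += noiseSd * norm_rand();
          r.z += noiseSd * norm_rand();
        }
        if (!R_finite(r.x) || !R_finite(r.y) || !R_finite(r.z))
          stop("simulation unstable: non-finite position at vertex %d, t = %g "
               "(reduce dt or check parameters)", (int)i + 1, t);
      }
    }
    t += c.dt;
    ++stepsRun;

    // refresh volume and center after the move (cheap pass)
    double runVol = 0.0, runArea = 0.0;
    V3 cw{0, 0, 0};
    for (size_t f = 0; f < m.F.size(); ++f) {
      if (!m.fAlive[f]) continue;
      runVol += faceVolTerm(m, static_cast<int>(f));
      double a = faceArea(m, static_cast<int>(f));
      runArea += a;
      cw = cw + a * faceCentroid(m, static_cast<int>(f));
    }
    V3 center = (1.0 / runArea) * cw;

    // ---- flip pass
    if (pFlip > 0.0) {
      snapshot.clear();
      for (size_t ei = 0; ei < A.E.size(); ++ei)
        if (A.E[ei].a >= 0) snapshot.push_back(static_cast<int>(ei));
      shuffled(snapshot);
      for (int ei : snapshot) {
        if (A.E[ei].a < 0) continue;
        if (unif_rand() >= pFlip) continue;
        nFlipAtt += 1.0;
        Reason rs = flipLegal(m, A, ei, g);
        int a0 = A.E[ei].a, b0 = A.E[ei].b;
        double aPair = 0.5 * (faceArea(m, A.E[ei].f1) + faceArea(m, A.E[ei].f2));
        double strain = aPair / p.aeq - 1.0;
        V3 mid = 0.5 * (m.P[a0] + m.P[b0]);
        if (rs != Reason::ok) {
          if (c.log_events && c.log_flip_attempts)
            ev.push(t, 1, a0, b0, NA_REAL, 0.0, -1.0,
                    polarAngle(mid, center), strain);
          continue;
        }
        double volBefore = faceVolTerm(m, A.E[ei].f1) + faceVolTerm(m, A.E[ei].f2);
        double before = flipStencilEnergy(m, A, ei, p, c.use_act, center);
        applyFlip(m, A, ei);
        double volAfter = faceVolTerm(m, A.E[ei].f1) + faceVolTerm(m, A.E[ei].f2);
        double after = flipStencilEnergy(m, A, ei, p, c.use_act, center);
        double dVol = volAfter - volBefore;
        double dU = (after - before) + volEnergy(runVol + dVol, p) -
                    volEnergy(runVol, p);
        bool accept;
        if (c.greedy) {
          accept = dU < 0.0;
        } else {
          accept = dU <= 0.0 || unif_rand() < std::exp(-dU / p.kBT);
        }
        if (accept) {
          runVol += dVol;
          nFlipAcc += 1.0;
        } else {
          applyFlip(m, A, ei);  // undo
        }
        if (c.log_events && (c.log_flip_attempts || accept))
          ev.push(t, 1, a0, b0, dU, 0.0, accept ? 1.0 : 0.0,
                  polarAngle(mid, center), strain);
      }
    }

    // ---- turnover pass
    if (pTurn > 0.0) {
      snapshot.clear();
      for (size_t ei = 0; ei < A.E.size(); ++ei)
        if (A.E[ei].a >= 0) snapshot.push_back(static_cast<int>(ei));
      shuffled(snapshot);
      for (int ei : snapshot) {
        if (A.E[ei].a < 0) continue;
        if (unif_rand() >= pTurn) continue;
        nTurnAtt += 1.0;
        bool split = unif_rand() < 0.5;
        const Edge& e = A.E[ei];
        int a0 = e.a, b0 = e.b;
        V3 mid = 0.5 * (m.P[a0] + m.P[b0]);
        double ang = polarAngle(mid, center);
        // <a_i>: mean area of the pre-event pair of faces
        double aPair = 0.5 * (faceArea(m, e.f1) + faceArea(m, e.f2));
        double strain = aPair / p.aeq - 1.0;
        double dE = c.eps_t * (1.0 + (split ? -1.0 : 1.0) * strain / c.gamma_t);
        double mu = chemPot(Mt, c.M_eq, c.M_inst, c.m_u, p.kBT);
        Reason rs;
        if (split) {
          rs = (c.M_tt - Mt < 2.0 * c.m_u) ? Reason::reservoir_empty
                                           : splitLegal(m, A, ei, g);
        } else {
          rs = collapseLegal(m, A, ei, g);
        }
        if (rs != Reason::ok) {
          if (c.log_events)
            ev.push(t, split ? 2 : 3, a0, b0, dE, mu, -1.0, ang, strain);
          continue;
        }
        // exponent: -(Delta_i E -+ 2 m_u mu_r)/kBT, minus for split
        double ex = -(dE + (split ? -2.0 : 2.0) * c.m_u * mu) / p.kBT;
        bool accept = ex >= 0.0 || unif_rand() < std::exp(ex);
        if (accept) {
          // track the volume change through the affected faces
          double volBefore = 0.0, volAfter = 0.0;
          if (split) {
            volBefore = faceVolTerm(m, e.f1) + faceVolTerm(m, e.f2);
            int f1 = e.f1, f2 = e.f2;
            applySplit(m, A, ei);
            int g1 = static_cast<int>(m.F.size()) - 2;
            volAfter = faceVolTerm(m, f1) + faceVolTerm(m, f2) +
                       faceVolTerm(m, g1) + faceVolTerm(m, g1 + 1);
            Mt += 2.0 * c.m_u;
            nSplit += 1.0;
          } else {
            for (int f : A.vF[a0]) volBefore += faceVolTerm(m, f);
            for (int f : A.vF[b0])
              if (f != e.f1 && f != e.f2) volBefore += faceVolTerm(m, f);
            applyCollapse(m, A, ei);
            for (int f : A.vF[a0]) volAfter += faceVolTerm(m, f);
            Mt -= 2.0 * c.m_u;
            nMerge += 1.0;
          }
          runVol += volAfter - volBefore;
        }
        if (c.log_events)
          ev.push(t, split ? 2 : 3, a0, b0, dE, mu, accept ? 1.0 : 0.0,
                  ang, strain);
      }
    }

    if (c.sample_every > 0 && ((step + 1) % c.sample_every == 0)) record(t);
  }

  if (c.sample_every > 0 && converged) record(t);

  // compact mesh for return
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
  IntegerMatrix F(m.nF, 3);
  int row = 0;
  for (size_t f = 0; f < m.F.size(); ++f) {
    if (!m.fAlive[f]) continue;
    for (int k = 0; k < 3; ++k) F(row, k) = vmap[m.F[f][k]] + 1;
    ++row;
  }

  NumericMatrix obsOut(nObs, ncolObs);
  for (int i = 0; i < nObs; ++i)
    for (int k = 0; k < ncolObs; ++k) obsOut(i, k) = obs(i, k);

  const int nevRows = static_cast<int>(ev.t.size());
  NumericMatrix evOut(nevRows, 9);
  for (int i = 0; i < nevRows; ++i) {
    evOut(i, 0) = ev.t[i];     evOut(i, 1) = ev.kind[i];
    evOut(i, 2) = ev.va[i];    evOut(i, 3) = ev.vb[i];
    evOut(i, 4) = ev.d1[i];    evOut(i, 5) = ev.d2[i];
    evOut(i, 6) = ev.acc[i];   evOut(i, 7) = ev.angle[i];
    evOut(i, 8) = ev.strain[i];
  }

  List stateOut = List::create(
      _["t"] = t, _["M_t"] = Mt, _["flip_att"] = nFlipAtt,
      _["flip_acc"] = nFlipAcc, _["turn_att"] = nTurnAtt,
      _["splits"] = nSplit, _["merges"] = nMerge);
  return List::create(_["positions"] = P, _["faces"] = F,
                      _["observables"] = obsOut, _["events"] = evOut,
                      _["state"] = stateOut, _["converged"] = converged,
                      _["steps_run"] = stepsRun);
}
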