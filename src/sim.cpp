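// Event-driven CTMC simulation of microtubule dynamic instability in a
// convex 2D cell, with angle-dependent collision resolution.  All geometry
// is in nm; lengths are integer tubulin dimers; time is non-dimensional
// (multiply by the dimensional factor R to get seconds).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Seg {
  double ox, oy;   // origin (nm)
  double dx, dy;   // unit direction
  int len;         // dimers
};

struct MT {
  std::vector<Seg> segs;
  int total = 0;
  int state = 0;          // 0 growing, 1 shrinking, 2 paused
  double tipx, tipy;
  double dirx, diry;      // current growth direction
  bool need_new_seg = true;
};

// outcome codes
enum { OUT_ZIP = 0, OUT_CROSS = 1, OUT_CAT = 2, OUT_STAB = 3 };
// rule-set codes (match R side)
enum { RULE_STAB_NOCROSS = 1, RULE_CROSS_STAB = 2, RULE_CROSS_BCAT = 3,
       RULE_ANGLE = 4 };

int resolve_outcome(double angle, bool boundary, int rule,
                    double p_cat, double theta_c, double u) {
  switch (rule) {
  case RULE_STAB_NOCROSS: return boundary ? OUT_STAB : OUT_CAT;
  case RULE_CROSS_STAB:   return boundary ? OUT_STAB : OUT_CROSS;
  case RULE_CROSS_BCAT:   return boundary ? OUT_CAT : OUT_CROSS;
  default:
    if (angle < theta_c) {                       // zipping regime
      double P = angle / theta_c * p_cat;
      return (u < P) ? OUT_CAT : OUT_ZIP;
    }
    if (boundary) return OUT_CAT;                // steep boundary hit
    return (u < p_cat) ? OUT_CAT : OUT_CROSS;    // steep MT-MT hit
  }
}

inline double axial_angle_deg(double ax, double ay, double bx, double by) {
  double dot = std::fabs(ax * bx + ay * by);
  if (dot > 1.0) dot = 1.0;
  return std::acos(dot) * 180.0 / M_PI;
}

} // namespace

// [[Rcpp::export(name = ".sim_run_cpp")]]
List sim_run_cpp(NumericMatrix boundary, NumericMatrix seeds, List par) {
  const double alpha   = as<double>(par["alpha"]);
  const double beta    = as<double>(par["beta"]);
  const double alpha_p = as<double>(par["alpha_prime"]);
  const double beta_p  = as<double>(par["beta_prime"]);
  const double p_cat   = as<double>(par["p_cat"]);
  const double theta_c = as<double>(par["theta_critical"]);
  const double dimer   = as<double>(par["dimer_len"]);
  const double t_end   = as<double>(par["t_end"]);
  const double sample_dt = as<double>(par["sample_dt"]);
  const int    rule    = as<int>(par["rule_code"]);
  const bool   frozen_pause = as<bool>(par["frozen_pause"]);

  const int nmt = seeds.nrow();
  const int nedge = boundary.nrow();
  const int nsamp = (int) std::lround(t_end / sample_dt);

  // boundary edges: vertex i -> i+1 (closed), unit tangents
  std::vector<double> ex0(nedge), ey0(nedge), evx(nedge), evy(nedge),
      elen(nedge), etx(nedge), ety(nedge);
  for (int i = 0; i < nedge; ++i) {
    int j = (i + 1) % nedge;
    ex0[i] = boundary(i, 0); ey0[i] = boundary(i, 1);
    evx[i] = boundary(j, 0) - ex0[i];
    evy[i] = boundary(j, 1) - ey0[i];
    elen[i] = std::sqrt(evx[i] * evx[i] + evy[i] * evy[i]);
    etx[i] = evx[i] / elen[i]; ety[i] = evy[i] / elen[i];
  }

  std::vector<MT> mts(nmt);
  // state bookkeeping: ids per state, with back-pointers
  std::vector<std::vector<int>> bucket(3);
  std::vector<int> pos(nmt);
  auto move_state = [&](int id, int to) {
    int from = mts[id].state;
    if (from == to) return;
    std::vector<int>& b = bucket[from];
    int p = pos[id];
    int last = b.back();
    b[p] = last; pos[last] = p; b.pop_back();
    mts[id].state = to;
    pos[id] = (int) bucket[to].size();
    bucket[to].push_back(id);
  };
  auto fresh_direction = [&](int id) {
    double th = unif_rand() * M_PI;  // uniform over inward half-plane
    double tx = seeds(id, 2), ty = seeds(id, 3);
    double nx = seeds(id, 4), ny = seeds(id, 5);
    mts[id].dirx = std::cos(th) * tx + std::sin(th) * nx;
    mts[id].diry = std::cos(th) * ty + std::sin(th) * ny;
    mts[id].need_new_seg = true;
  };
  for (int i = 0; i < nmt; ++i) {
    mts[i].tipx = seeds(i, 0);
    mts[i].tipy = seeds(i, 1);
    mts[i].state = 0;
    pos[i] = i;
    bucket[0].push_back(i);
    fresh_direction(i);
  }

  const double rate_g = alpha + beta_p;
  const double rate_s = beta + alpha_p;
  const double rate_p = frozen_pause ? 0.0 : beta_p;

  NumericMatrix hist(nsamp, 180);
  std::vector<double> ev_t, ev_angle;
  std::vector<int> ev_mt, ev_target, ev_outcome;

  double t = 0.0;
  int samp = 0;
  double next_sample = sample_dt;

  auto record_sample = [&]() {
    for (int i = 0; i < nmt; ++i)
      for (const Seg& s : mts[i].segs) {
        if (s.len == 0) continue;
        double a = std::atan2(s.dy, s.dx) * 180.0 / M_PI;
        a -= 180.0 * std::floor(a / 180.0);   // reduce to [0, 180)
        int b = (int) a;
        if (b > 179) b = 179;
        hist(samp, b) += s.len;
      }
    ++samp;
    next_sample += sample_dt;
  };

  while (samp < nsamp) {
    double total_rate = bucket[0].size() * rate_g +
                        bucket[1].size() * rate_s +
                        bucket[2].size() * rate_p;
    if (total_rate <= 0.0) { // everything frozen: fast-forward
      while (samp < nsamp) record_sample();
      break;
    }
    t += exp_rand() / total_rate;
    while (samp < nsamp && t >= next_sample) record_sample();
    if (samp >= nsamp) break;

    // pick category, then MT uniformly within it
    double v = unif_rand() * total_rate;
    int cat;
    double gsum = bucket[0].size() * rate_g;
    double ssum = gsum + bucket[1].size() * rate_s;
    if (v < gsum) cat = 0; else if (v < ssum) cat = 1; else cat = 2;
    int k = (int)(unif_rand() * bucket[cat].size());
    if (k >= (int) bucket[cat].size()) k = (int) bucket[cat].size() - 1;
    int id = bucket[cat][k];
    MT& m = mts[id];

    if (cat == 2) {            // paused: spontaneous catastrophe only
      move_state(id, 1);
      continue;
    }
    if (cat == 1) {            // shrinking: rescue or depolymerize
      if (unif_rand() * rate_s < alpha_p) {   // rescue
        if (m.total > 0) {
          const Seg& s = m.segs.back();
          m.dirx = s.dx; m.diry = s.dy;
          m.need_new_seg = false;
        } else fresh_direction(id);
        move_state(id, 0);
      } else {                                // lose one dimer
        if (m.total > 0) {
          Seg& s = m.segs.back();
          --s.len; --m.total;
          m.tipx -= s.dx * dimer;
          m.tipy -= s.dy * dimer;
          if (s.len == 0) m.segs.pop_back();
        }
        if (m.total == 0) {                   // fully depolymerized: wait
          // at the seed for a rescue event, then regrow at a fresh angle
          m.segs.clear();
          m.tipx = seeds(id, 0); m.tipy = seeds(id, 1);
        }
      }
      continue;
    }

    // growing: spontaneous catastrophe or polymerize one dimer
    if (unif_rand() * rate_g < beta_p) {
      move_state(id, 1);
      continue;
    }

    // candidate step; a single dimer advance can cross several targets
    // (e.g. a wall-hugging bundle and then the wall itself), so collect
    // every intersection and resolve them in order of distance
    double px = m.tipx, py = m.tipy;
    double rx = m.dirx * dimer, ry = m.diry * dimer;
    struct Hit { double t, ux, uy; bool boundary; };
    std::vector<Hit> hits;

    auto test_segment = [&](double bx, double by, double sx, double sy,
                            double ux, double uy, bool is_boundary) {
      // step p + t*r vs target b + w*s, s = full target vector, u unit tangent
      double denom = rx * sy - ry * sx;
      if (std::fabs(denom) < 1e-12) return;
      double qx = bx - px, qy = by - py;
      double tt = (qx * sy - qy * sx) / denom;
      double ww = (qx * ry - qy * rx) / denom;
      if (tt <= 1e-9 || tt > 1.0 + 1e-9 || ww < -1e-9 || ww > 1.0 + 1e-9)
        return;
      double ang = axial_angle_deg(m.dirx, m.diry, ux, uy);
      if (ang < 1e-6) return;                 // effectively parallel
      hits.push_back(Hit{tt, ux, uy, is_boundary});
    };

    for (int e = 0; e < nedge; ++e)
      test_segment(ex0[e], ey0[e], evx[e], evy[e], etx[e], ety[e], true);
    for (int j = 0; j < nmt; ++j) {
      if (j == id) continue;
      for (const Seg& s : mts[j].segs) {
        if (s.len == 0) continue;
        double L = s.len * dimer;
        // cheap bounding-box rejection around the one-dimer step
        double lox = std::min(s.ox, s.ox + s.dx * L);
        double hix = std::max(s.ox, s.ox + s.dx * L);
        if (hix < std::min(px, px + rx) - 1e-9 ||
            lox > std::max(px, px + rx) + 1e-9) continue;
        double loy = std::min(s.oy, s.oy + s.dy * L);
        double hiy = std::max(s.oy, s.oy + s.dy * L);
        if (hiy < std::min(py, py + ry) - 1e-9 ||
            loy > std::max(py, py + ry) + 1e-9) continue;
        test_segment(s.ox, s.oy, s.dx * L, s.dy * L, s.dx, s.dy, false);
      }
    }

    std::sort(hits.begin(), hits.end(),
              [](const Hit& a, const Hit& b) { return a.t < b.t; });
    int out = OUT_CROSS;  // no obstacle behaves like crossing everything
    for (const Hit& hh : hits) {
      double ang = axial_angle_deg(m.dirx, m.diry, hh.ux, hh.uy);
      out = resolve_outcome(ang, hh.boundary, rule, p_cat, theta_c,
                            unif_rand());
      ev_t.push_back(t); ev_mt.push_back(id + 1);
      ev_target.push_back(hh.boundary ? 0 : 1);
      ev_angle.push_back(ang); ev_outcome.push_back(out);
      if (out != OUT_CROSS) {
        if (out == OUT_ZIP) {
          // new direction: target tangent, signed to minimize the turning
          // angle; an exact 90-degree tie goes to the representative in
          // [0, 180)
          double dot = m.dirx * hh.ux + m.diry * hh.uy;
          double zx = hh.ux, zy = hh.uy;
          if (std::fabs(dot) < 1e-12) {
            if (zy < 0 || (zy == 0 && zx < 0)) { zx = -zx; zy = -zy; }
          } else if (dot < 0) { zx = -zx; zy = -zy; }
          m.dirx = zx; m.diry = zy;
          m.need_new_seg = true;
        } else if (out == OUT_CAT) {
          move_state(id, 1);
        } else {
          move_state(id, 2);
        }
        break;
      }
    }
    if (out == OUT_CROSS) {                   // free growth / crossed all
      if (m.need_new_seg || m.segs.empty()) {
        m.segs.push_back(Seg{m.tipx, m.tipy, m.dirx, m.diry, 0});
        m.need_new_seg = false;
      }
      ++m.segs.back().len; ++m.total;
      m.tipx += rx; m.tipy += ry;
      // containment backstop: a crossing landing within floating-point
      // epsilon of a step end can slip past the segment tests on the exact
      // 8.2-nm lattice that wall bundles live on; resolve it as the
      // boundary collision it geometrically is
      int viol = -1;
      double worst = -1e-9;
      for (int e2 = 0; e2 < nedge; ++e2) {
        double cr = (evx[e2] * (m.tipy - ey0[e2]) -
                     evy[e2] * (m.tipx - ex0[e2])) / elen[e2];
        if (cr < worst) { worst = cr; viol = e2; }
      }
      if (viol >= 0) {
        --m.segs.back().len; --m.total;
        m.tipx -= rx; m.tipy -= ry;
        if (m.segs.back().len == 0) { m.segs.pop_back(); m.need_new_seg = true; }
        double ang = axial_angle_deg(m.dirx, m.diry, etx[viol], ety[viol]);
        if (ang < 1e-6) ang = 1e-6;
        out = resolve_outcome(ang, true, rule, p_cat, theta_c, unif_rand());
        ev_t.push_back(t); ev_mt.push_back(id + 1);
        ev_target.push_back(0);
        ev_angle.push_back(ang); ev_outcome.push_back(out);
        if (out == OUT_ZIP) {
          double dot = m.dirx * etx[viol] + m.diry * ety[viol];
          double zx = etx[viol], zy = ety[viol];
          if (dot < 0) { zx = -zx; zy = -zy; }
          m.dirx = zx; m.diry = zy;
          m.need_new_seg = true;
        } else if (out == OUT_CAT) {
          move_state(id, 1);
        } else if (out == OUT_STAB) {
          move_state(id, 2);
        }
      }
    }
  }

  // final polylines
  int nseg = 0;
  for (const MT& m : mts) nseg += (int) m.segs.size();
  NumericMatrix fin(nseg, 6);
  int r = 0;
  for (int i = 0; i < nmt; ++i)
    for (const Seg& s : mts[i].segs) {
      fin(r, 0) = i + 1; fin(r, 1) = s.ox; fin(r, 2) = s.oy;
      fin(r, 3) = s.dx;  fin(r, 4) = s.dy; fin(r, 5) = s.len;
      ++r;
    }

  IntegerVector states(nmt), lengths(nmt);
  for (int i = 0; i < nmt; ++i) {
    states[i] = mts[i].state;
    lengths[i] = mts[i].total;
  }

  return List::create(
    _["hist"] = hist,
    _["event_t"] = wrap(ev_t),
    _["event_mt"] = wrap(ev_mt),
    _["event_target"] = wrap(ev_target),
    _["event_angle"] = wrap(ev_angle),
    _["event_outcome"] = wrap(ev_outcome),
    _["final_segments"] = fin,
    _["final_states"] = states,
    _["final_lengths"] = lengths,
    _["t_final"] = t);
}
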