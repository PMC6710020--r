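#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Effect codes shared with R/effects.R (must stay in sync with .net_codes /
// .beh_codes there).  Network effects act on tie toggles; behavior effects
// act on level shifts of one ordinal dimension.
enum NetEff {
  NET_OUT = 1, NET_RECIP = 2, NET_TRANS = 3, NET_INPOP = 4,
  NET_SAMEG = 5, NET_FSMSIM = 6,
  NET_ALC_ALT = 7, NET_ALC_EGO = 8, NET_ALC_SIM = 9,
  NET_CON_ALT = 10, NET_CON_EGO = 11, NET_CON_SIM = 12,
  NET_SEC_ALT = 13, NET_SEC_EGO = 14, NET_SEC_SIM = 15,
  NET_CONEGO_X_ALCSIM = 16
};

// behavior dims: 0 = alcohol (1..4), 1 = control (1..3), 2 = secrecy (1..3)
enum AlcEff { ALC_LIN = 1, ALC_QUAD = 2, ALC_TOTSIM = 3, ALC_CONxTOT = 4,
              ALC_SECxTOT = 5, ALC_GEND = 6, ALC_FSM = 7 };
enum ConEff { CON_LIN = 1, CON_QUAD = 2, CON_FROMALC = 3, CON_GEND = 4,
              CON_FSM = 5 };
enum SecEff { SEC_LIN = 1, SEC_QUAD = 2, SEC_AVGSIM = 3, SEC_AVGALCALT = 4,
              SEC_GEND = 5, SEC_FSM = 6 };

static const double BEH_RANGE[3] = {3.0, 2.0, 2.0};
static const int BEH_MIN[3] = {1, 1, 1};
static const int BEH_MAX[3] = {4, 3, 3};

inline double simval(double zi, double zj, double range) {
  return 1.0 - std::fabs(zi - zj) / range;
}

struct Spec {
  IntegerVector net_eff;   // network effect codes
  NumericVector net_theta;
  IntegerVector alc_eff; NumericVector alc_theta;
  IntegerVector con_eff; NumericVector con_theta;
  IntegerVector sec_eff; NumericVector sec_theta;
  NumericVector zbar;      // alc, con, sec
  NumericVector sbar;      // alc, con, sec, fsm
};

static Spec make_spec(List spec) {
  Spec sp;
  sp.net_eff = spec["net_eff"]; sp.net_theta = spec["net_theta"];
  sp.alc_eff = spec["alc_eff"]; sp.alc_theta = spec["alc_theta"];
  sp.con_eff = spec["con_eff"]; sp.con_theta = spec["con_theta"];
  sp.sec_eff = spec["sec_eff"]; sp.sec_theta = spec["sec_theta"];
  sp.zbar = spec["zbar"]; sp.sbar = spec["sbar"];
  return sp;
}

// objective-function gain for actor i toggling tie i -> a (sgn +1 add, -1 drop)
static double net_delta(const IntegerMatrix& adj, const IntegerMatrix& beh,
                        const IntegerVector& gender, const IntegerVector& fsm,
                        const IntegerVector& indeg, const Spec& sp,
                        int i, int a, int sgn) {
  const int n = adj.nrow();
  double df = 0.0;
  for (int k = 0; k < sp.net_eff.size(); ++k) {
    const double th = sp.net_theta[k];
    if (th == 0.0) continue;
    double d = 0.0;
    switch (sp.net_eff[k]) {
    case NET_OUT:   d = 1.0; break;
    case NET_RECIP: d = adj(a, i); break;
    case NET_TRANS: {
      // triangles closed by i->a, either with a as intermediate
      // (i->a, a->h, i->h) or as target (i->j, j->a, i->a); the toggled
      // tie itself never enters either sum
      double t = 0.0;
      for (int h = 0; h < n; ++h) {
        t += adj(a, h) * adj(i, h);
        t += adj(i, h) * adj(h, a);
      }
      d = t;
      break;
    }
    case NET_INPOP:
      d = (sgn > 0) ? std::sqrt((double)indeg[a] + 1.0)
                    : std::sqrt((double)indeg[a]);
      break;
    case NET_SAMEG:  d = (gender[i] == gender[a]) ? 1.0 : 0.0; break;
    case NET_FSMSIM: d = 1.0 - std::fabs((double)fsm[i] - fsm[a]) - sp.sbar[3]; break;
    case NET_ALC_ALT: d = beh(a, 0) - sp.zbar[0]; break;
    case NET_ALC_EGO: d = beh(i, 0) - sp.zbar[0]; break;
    case NET_ALC_SIM: d = simval(beh(i, 0), beh(a, 0), BEH_RANGE[0]) - sp.sbar[0]; break;
    case NET_CON_ALT: d = beh(a, 1) - sp.zbar[1]; break;
    case NET_CON_EGO: d = beh(i, 1) - sp.zbar[1]; break;
    case NET_CON_SIM: d = simval(beh(i, 1), beh(a, 1), BEH_RANGE[1]) - sp.sbar[1]; break;
    case NET_SEC_ALT: d = beh(a, 2) - sp.zbar[2]; break;
    case NET_SEC_EGO: d = beh(i, 2) - sp.zbar[2]; break;
    case NET_SEC_SIM: d = simval(beh(i, 2), beh(a, 2), BEH_RANGE[2]) - sp.sbar[2]; break;
    case NET_CONEGO_X_ALCSIM:
      d = (beh(i, 1) - sp.zbar[1]) *
          (simval(beh(i, 0), beh(a, 0), BEH_RANGE[0]) - sp.sbar[0]);
      break;
    default: stop("unknown network effect code");
    }
    df += th * sgn * d;
  }
  return df;
}

// raw statistic for one behavior effect, actor i at candidate level z
static double beh_stat(const IntegerMatrix& adj, const IntegerMatrix& beh,
                       const IntegerVector& gender, const IntegerVector& fsm,
                       const Spec& sp, int dim, int i, int z, int code) {
  const int n = adj.nrow();
  const double zc = z - sp.zbar[dim];
  if (dim == 0) {
    switch (code) {
    case ALC_LIN:  return zc;
    case ALC_QUAD: return zc * zc;
    case ALC_TOTSIM: case ALC_CONxTOT: case ALC_SECxTOT: {
      double tot = 0.0;
      for (int j = 0; j < n; ++j)
        if (adj(i, j))
          tot += simval((double)z, beh(j, 0), BEH_RANGE[0]) - sp.sbar[0];
      if (code == ALC_TOTSIM) return tot;
      if (code == ALC_CONxTOT) return (beh(i, 1) - sp.zbar[1]) * tot;
      return (beh(i, 2) - sp.zbar[2]) * tot;
    }
    case ALC_GEND: return zc * gender[i];
    case ALC_FSM:  return zc * fsm[i];
    }
  } else if (dim == 1) {
    switch (code) {
    case CON_LIN:  return zc;
    case CON_QUAD: return zc * zc;
    case CON_FROMALC: return zc * (beh(i, 0) - sp.zbar[0]);
    case CON_GEND: return zc * gender[i];
    case CON_FSM:  return zc * fsm[i];
    }
  } else {
    switch (code) {
    case SEC_LIN:  return zc;
    case SEC_QUAD: return zc * zc;
    case SEC_AVGSIM: {
      int outdeg = 0; double tot = 0.0;
      for (int j = 0; j < n; ++j)
        if (adj(i, j)) {
          ++outdeg;
          tot += simval((double)z, beh(j, 2), BEH_RANGE[2]) - sp.sbar[2];
        }
      return tot / std::max(1, outdeg);
    }
    case SEC_AVGALCALT: {
      int outdeg = 0; double tot = 0.0;
      for (int j = 0; j < n; ++j)
        if (adj(i, j)) { ++outdeg; tot += beh(j, 0) - sp.zbar[0]; }
      return zc * tot / std::max(1, outdeg);
    }
    case SEC_GEND: return zc * gender[i];
    case SEC_FSM:  return zc * fsm[i];
    }
  }
  stop("unknown behavior effect code");
  return 0.0;
}

// full objective value for actor i on behavior dim at candidate level z
static double beh_objective(const IntegerMatrix& adj, const IntegerMatrix& beh,
                            const IntegerVector& gender, const IntegerVector& fsm,
                            const Spec& sp, int dim, int i, int z) {
  const IntegerVector* codes;
  const NumericVector* theta;
  if (dim == 0)      { codes = &sp.alc_eff; theta = &sp.alc_theta; }
  else if (dim == 1) { codes = &sp.con_eff; theta = &sp.con_theta; }
  else               { codes = &sp.sec_eff; theta = &sp.sec_theta; }
  double f = 0.0;
  for (int k = 0; k < codes->size(); ++k) {
    const double th = (*theta)[k];
    if (th == 0.0) continue;
    f += th * beh_stat(adj, beh, gender, fsm, sp, dim, i, z, (*codes)[k]);
  }
  return f;
}

// multinomial draw from unnormalized log weights (log-sum-exp stabilized)
static int draw_multinomial(const std::vector<double>& logw) {
  double mx = logw[0];
  for (size_t k = 1; k < logw.size(); ++k) if (logw[k] > mx) mx = logw[k];
  double tot = 0.0;
  std::vector<double> w(logw.size());
  for (size_t k = 0; k < logw.size(); ++k) { w[k] = std::exp(logw[k] - mx); tot += w[k]; }
  double u = unif_rand() * tot, cum = 0.0;
  for (size_t k = 0; k < logw.size(); ++k) {
    cum += w[k];
    if (u <= cum) return (int)k;
  }
  return (int)logw.size() - 1;
}

// [[Rcpp::export]]
List sim_period_cpp(IntegerMatrix adj0, IntegerMatrix beh0,
                    IntegerVector gender, IntegerVector fsm,
                    List spec, NumericVector rates, double horizon,
                    int cap, bool keep_log) {
  IntegerMatrix adj = clone(adj0);
  IntegerMatrix beh = clone(beh0);
  Spec sp = make_spec(spec);
  const int n = adj.nrow();
  if (rates.size() != 4) stop("rates must have length 4");
  for (int d = 0; d < 4; ++d)
    if (rates[d] < 0 || !R_finite(rates[d])) stop("rates must be finite and nonnegative");

  IntegerVector indeg(n), outdeg(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j)) { outdeg[i]++; indeg[j]++; }

  const double rate_tot = rates[0] + rates[1] + rates[2] + rates[3];
  const double R_total = n * rate_tot;
  std::vector<int> log_actor, log_dim, log_move;
  std::vector<double> log_time;

  RNGScope scope;
  double clock = 0.0;
  int nsteps = 0;
  if (R_total > 0) {
    while (true) {
      clock += exp_rand() / R_total;
      if (clock >= horizon) break;
      int i = (int)(unif_rand() * n); if (i == n) i = n - 1;
      double u = unif_rand() * rate_tot;
      int dim = 0; double cum = rates[0];
      while (u > cum && dim < 3) { cum += rates[++dim]; }

      int move = 0;
      if (dim == 0) {
        // network microstep: no-change plus permissible single toggles
        std::vector<double> logw; std::vector<int> alter;
        logw.push_back(0.0); alter.push_back(-1);
        for (int a = 0; a < n; ++a) {
          if (a == i) continue;
          const bool present = adj(i, a) == 1;
          if (!present && outdeg[i] >= cap) continue;
          logw.push_back(net_delta(adj, beh, gender, fsm, indeg, sp, i, a,
                                   present ? -1 : +1));
          alter.push_back(a);
        }
        int pick = draw_multinomial(logw);
        int a = alter[pick];
        if (a >= 0) {
          if (adj(i, a)) { adj(i, a) = 0; outdeg[i]--; indeg[a]--; }
          else           { adj(i, a) = 1; outdeg[i]++; indeg[a]++; }
        }
        move = a + 1;   // 0 = no change, else 1-based alter
      } else {
        const int b = dim - 1;
        const int z = beh(i, b);
        std::vector<double> logw; std::vector<int> cand;
        for (int dz = -1; dz <= 1; ++dz) {
          const int znew = z + dz;
          if (znew < BEH_MIN[b] || znew > BEH_MAX[b]) continue;
          logw.push_back(beh_objective(adj, beh, gender, fsm, sp, b, i, znew));
          cand.push_back(znew);
        }
        int pick = draw_multinomial(logw);
        move = cand[pick] - z;
        beh(i, b) = cand[pick];
      }
      ++nsteps;
      if (keep_log) {
        log_actor.push_back(i + 1); log_dim.push_back(dim);
        log_move.push_back(move);   log_time.push_back(clock);
      }
    }
  }

  List out = List::create(_["adjacency"] = adj, _["behavior"] = beh,
                          _["n_steps"] = nsteps);
  if (keep_log)
    out["log"] = DataFrame::create(_["actor"] = wrap(log_actor),
                                   _["dimension"] = wrap(log_dim),
                                   _["move"] = wrap(log_move),
                                   _["time"] = wrap(log_time));
  return out;
}

// summed evaluation statistics (over actors) for one complete state,
// ordered: network effects, alcohol, control, secrecy effects
// [[Rcpp::export]]
NumericVector saom_stats_cpp(IntegerMatrix adj, IntegerMatrix beh,
                             IntegerVector gender, IntegerVector fsm,
                             List spec) {
  Spec sp = make_spec(spec);
  const int n = adj.nrow();
  const int pn = sp.net_eff.size(), pa = sp.alc_eff.size(),
            pc = sp.con_eff.size(), ps = sp.sec_eff.size();
  NumericVector out(pn + pa + pc + ps);

  IntegerVector indeg(n), outdeg(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j)) { outdeg[i]++; indeg[j]++; }

  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < pn; ++k) {
      double s = 0.0;
      switch (sp.net_eff[k]) {
      case NET_OUT: s = outdeg[i]; break;
      case NET_RECIP:
        for (int j = 0; j < n; ++j) s += adj(i, j) * adj(j, i);
        break;
      case NET_TRANS:
        for (int j = 0; j < n; ++j) {
          if (!adj(i, j)) continue;
          for (int h = 0; h < n; ++h) s += adj(j, h) * adj(i, h);
        }
        break;
      case NET_INPOP:
        for (int j = 0; j < n; ++j)
          if (adj(i, j)) s += std::sqrt((double)indeg[j]);
        break;
      case NET_SAMEG:
        for (int j = 0; j < n; ++j)
          if (adj(i, j) && gender[i] == gender[j]) s += 1.0;
        break;
      case NET_FSMSIM:
        for (int j = 0; j < n; ++j)
          if (adj(i, j)) s += 1.0 - std::fabs((double)fsm[i] - fsm[j]) - sp.sbar[3];
        break;
      case NET_ALC_ALT:
        for (int j = 0; j < n; ++j) if (adj(i, j)) s += beh(j, 0) - sp.zbar[0];
        break;
      case NET_ALC_EGO: s = (beh(i, 0) - sp.zbar[0]) * outdeg[i]; break;
      case NET_ALC_SIM:
        for (int j = 0; j < n; ++j)
          if (adj(i, j)) s += simval(beh(i, 0), beh(j, 0), BEH_RANGE[0]) - sp.sbar[0];
        break;
      case NET_CON_ALT:
        for (int j = 0; j < n; ++j) if (adj(i, j)) s += beh(j, 1) - sp.zbar[1];
        break;
      case NET_CON_EGO: s = (beh(i, 1) - sp.zbar[1]) * outdeg[i]; break;
      case NET_CON_SIM:
        for (int j = 0; j < n; ++j)
          if (adj(i, j)) s += simval(beh(i, 1), beh(j, 1), BEH_RANGE[1]) - sp.sbar[1];
        break;
      case NET_SEC_ALT:
        for (int j = 0; j < n; ++j) if (adj(i, j)) s += beh(j, 2) - sp.zbar[2];
        break;
      case NET_SEC_EGO: s = (beh(i, 2) - sp.zbar[2]) * outdeg[i]; break;
      case NET_SEC_SIM:
        for (int j = 0; j < n; ++j)
          if (adj(i, j)) s += simval(beh(i, 2), beh(j, 2), BEH_RANGE[2]) - sp.sbar[2];
        break;
      case NET_CONEGO_X_ALCSIM: {
        double t = 0.0;
        for (int j = 0; j < n; ++j)
          if (adj(i, j)) t += simval(beh(i, 0), beh(j, 0), BEH_RANGE[0]) - sp.sbar[0];
        s = (beh(i, 1) - sp.zbar[1]) * t;
        break;
      }
      default: stop("unknown network effect code");
      }
      out[k] += s;
    }

    for (int k = 0; k < pa; ++k)
      out[pn + k] += beh_stat(adj, beh, gender, fsm, sp, 0, i, beh(i, 0),
                              sp.alc_eff[k]);
    for (int k = 0; k < pc; ++k)
      out[pn + pa + k] += beh_stat(adj, beh, gender, fsm, sp, 1, i, beh(i, 1),
                                   sp.con_eff[k]);
    for (int k = 0; k < ps; ++k)
      out[pn + pa + pc + k] += beh_stat(adj, beh, gender, fsm, sp, 2, i,
                                        beh(i, 2), sp.sec_eff[k]);
  }
  return out;
}

// directed triad census by brute-force classification of all C(n,3) triples;
// `lookup` maps each 6-bit dyad pattern to a class index 0..15
// [[Rcpp::export]]
IntegerVector triad_census_cpp(IntegerMatrix adj, IntegerVector lookup) {
  const int n = adj.nrow();
  IntegerVector census(16);
  for (int i = 0; i < n - 2; ++i)
    for (int j = i + 1; j < n - 1; ++j)
      for (int k = j + 1; k < n; ++k) {
        int code = adj(i, j) | (adj(j, i) << 1) | (adj(i, k) << 2) |
                   (adj(k, i) << 3) | (adj(j, k) << 4) | (adj(k, j) << 5);
        census[lookup[code]]++;
      }
  return census;
}
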