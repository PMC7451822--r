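#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Parameter vector order everywhere:
// alpha, eps_actor, beta_exploit, r_shock, r_press, persev, gamma

// log(1 + exp(z)) without overflow
static inline double softplus(double z) {
  if (z > 0) return z + std::log1p(std::exp(-z));
  return std::log1p(std::exp(z));
}

struct Replay {
  double v[5];
  double m[2][5];
  int prev;      // 0 = OTHER, 1 = PRESS
  double nll;
  long nobs;
};

// One full forward pass through a frame sequence under fixed parameters,
// accumulating -log p(observed press bit) on chamber frames and (optionally)
// homecage frames, and applying TD updates throughout. Homecage frames force
// action OTHER. stim columns: danger, safety, shock, chamber, homecage.
static void replay_core(const int* d, const int* s, const int* sh,
                        const int* ch, const int* hm, const int* press,
                        int T, const double* par, bool include_home,
                        Replay& out) {
  const double alpha = par[0], eps = par[1], beta = par[2];
  const double rsh = par[3], rpr = par[4], pers = par[5], gam = par[6];
  double v0 = 0, v1 = 0, v2 = 0, v3 = 0, v4 = 0;
  double mo0 = 0, mo1 = 0, mo2 = 0, mo3 = 0, mo4 = 0;
  double mp0 = 0, mp1 = 0, mp2 = 0, mp3 = 0, mp4 = 0;
  int prev = 0;
  double nll = 0;
  long nobs = 0;

  for (int t = 0; t < T; t++) {
    const int x0 = d[t], x1 = s[t], x2 = sh[t], x3 = ch[t], x4 = hm[t];
    const bool home = (x4 == 1);
    int a;
    if (home) {
      a = 0;  // no lever in the homecage
      if (include_home) {
        double po = mo4 + (prev == 0 ? pers : 0.0);
        double pp = mp4 + (prev == 1 ? pers : 0.0);
        nll += softplus(beta * (pp - po));  // -log p(OTHER)
        nobs++;
      }
    } else {
      double po = mo0 * x0 + mo1 * x1 + mo2 * x2 + mo3 * x3 +
                  (prev == 0 ? pers : 0.0);
      double pp = mp0 * x0 + mp1 * x1 + mp2 * x2 + mp3 * x3 +
                  (prev == 1 ? pers : 0.0);
      double z = beta * (pp - po);
      a = press[t];
      nll += (a == 1) ? softplus(-z) : softplus(z);
      nobs++;
    }
    double r = rsh * x2 + rpr * a;
    double vnow = v0 * x0 + v1 * x1 + v2 * x2 + v3 * x3 + v4 * x4;
    double vnext = 0;
    if (t + 1 < T) {
      vnext = v0 * d[t + 1] + v1 * s[t + 1] + v2 * sh[t + 1] +
              v3 * ch[t + 1] + v4 * hm[t + 1];
    }
    double delta = r + gam * vnext - vnow;
    double ad = alpha * delta, ed = eps * delta;
    if (x0) { v0 += ad; if (a) mp0 += ed; else mo0 += ed; }
    if (x1) { v1 += ad; if (a) mp1 += ed; else mo1 += ed; }
    if (x2) { v2 += ad; if (a) mp2 += ed; else mo2 += ed; }
    if (x3) { v3 += ad; if (a) mp3 += ed; else mo3 += ed; }
    if (x4) { v4 += ad; if (a) mp4 += ed; else mo4 += ed; }
    prev = a;
  }
  out.v[0] = v0; out.v[1] = v1; out.v[2] = v2; out.v[3] = v3; out.v[4] = v4;
  out.m[0][0] = mo0; out.m[0][1] = mo1; out.m[0][2] = mo2;
  out.m[0][3] = mo3; out.m[0][4] = mo4;
  out.m[1][0] = mp0; out.m[1][1] = mp1; out.m[1][2] = mp2;
  out.m[1][3] = mp3; out.m[1][4] = mp4;
  out.prev = prev;
  out.nll = nll;
  out.nobs = nobs;
}

static void extract_cols(const IntegerMatrix& stim,
                         std::vector<int>& d, std::vector<int>& s,
                         std::vector<int>& sh, std::vector<int>& ch,
                         std::vector<int>& hm) {
  const int T = stim.nrow();
  d.resize(T); s.resize(T); sh.resize(T); ch.resize(T); hm.resize(T);
  for (int t = 0; t < T; t++) {
    d[t] = stim(t, 0); s[t] = stim(t, 1); sh[t] = stim(t, 2);
    ch[t] = stim(t, 3); hm[t] = stim(t, 4);
  }
}

// [[Rcpp::export]]
List nll_replay_cpp(IntegerMatrix stim, IntegerVector press,
                    NumericVector par, bool include_home) {
  const int T = stim.nrow();
  if (press.size() != T) stop("press length must match frame count");
  if (par.size() != 7) stop("expected 7 parameters");
  std::vector<int> d, s, sh, ch, hm;
  extract_cols(stim, d, s, sh, ch, hm);
  Replay out;
  replay_core(d.data(), s.data(), sh.data(), ch.data(), hm.data(),
              press.begin(), T, par.begin(), include_home, out);
  NumericVector v(out.v, out.v + 5);
  NumericMatrix m(2, 5);
  for (int a = 0; a < 2; a++)
    for (int i = 0; i < 5; i++) m(a, i) = out.m[a][i];
  return List::create(_["neg_lle"] = out.nll, _["v_weights"] = v,
                      _["m_weights"] = m, _["prev_action"] = out.prev,
                      _["n_obs"] = (double)out.nobs);
}

// Evaluate the replay negLLE at every row of a grid of parameter vectors.
// [[Rcpp::export]]
NumericVector grid_nll_cpp(IntegerMatrix stim, IntegerVector press,
                           NumericMatrix grid, bool include_home) {
  const int T = stim.nrow();
  if (press.size() != T) stop("press length must match frame count");
  if (grid.ncol() != 7) stop("grid must have 7 parameter columns");
  const int G = grid.nrow();
  std::vector<int> d, s, sh, ch, hm;
  extract_cols(stim, d, s, sh, ch, hm);
  NumericVector nll(G);
  double par[7];
  Replay out;
  for (int g = 0; g < G; g++) {
    for (int j = 0; j < 7; j++) par[j] = grid(g, j);
    replay_core(d.data(), s.data(), sh.data(), ch.data(), hm.data(),
                press.begin(), T, par, include_home, out);
    nll[g] = out.nll;
    if (g % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return nll;
}

// Generative simulation of the full experiment: the agent's sampled actions
// drive the task's phase transitions. Uses R's RNG (seeded from R) for the
// press/no-press draws; homecage steps force OTHER with no draw.
// cfg: n_sessions, trials_per_session, habituation_steps, danger_max_steps,
//      shock_max_steps, max_shocks, iti_steps, homecage_steps;
// shock_sched: shocks falling in each shock-period step (length
// shock_max_steps). init_v (5), init_m (2x5), init_prev allow pre-set agents.
// [[Rcpp::export]]
List simulate_frames_cpp(NumericVector par, IntegerVector cfg,
                         IntegerVector shock_sched, NumericVector init_v,
                         NumericMatrix init_m, int init_prev) {
  if (par.size() != 7) stop("expected 7 parameters");
  const int n_sessions = cfg[0], trials = cfg[1], hab = cfg[2];
  const int dmax = cfg[3], smax = cfg[4], max_shocks = cfg[5];
  const int iti = cfg[6], home = cfg[7];
  if (shock_sched.size() != smax) stop("shock schedule length mismatch");
  const double alpha = par[0], eps = par[1], beta = par[2];
  const double rsh = par[3], rpr = par[4], pers = par[5], gam = par[6];

  const int per_session = hab + home + trials * (dmax + smax + iti);
  const int cap = n_sessions * per_session;
  std::vector<int> vses(cap), vtri(cap), fd(cap), fs(cap), fsh(cap),
      fch(cap), fhm(cap), fpr(cap);

  double v[5] = {0, 0, 0, 0, 0};
  double m[2][5] = {{0, 0, 0, 0, 0}, {0, 0, 0, 0, 0}};
  for (int i = 0; i < 5; i++) {
    v[i] = init_v[i];
    m[0][i] = init_m(0, i);
    m[1][i] = init_m(1, i);
  }
  int prev = init_prev;
  int n = 0;

  // phase codes: 0 hab, 1 danger, 2 shock, 3 iti, 4 homecage
  int phase = 0, k = 0, trial = 1, shocks = 0, session = 1;

  auto stim_of_phase = [&](int ph, int* x) {
    x[0] = (ph == 1); x[1] = (ph == 3); x[2] = (ph == 2);
    x[3] = (ph != 4); x[4] = (ph == 4);
  };

  while (session <= n_sessions) {
    int x[5];
    stim_of_phase(phase, x);
    int a;
    if (phase == 4) {
      a = 0;
    } else {
      double po = m[0][0] * x[0] + m[0][1] * x[1] + m[0][2] * x[2] +
                  m[0][3] * x[3] + (prev == 0 ? pers : 0.0);
      double pp = m[1][0] * x[0] + m[1][1] * x[1] + m[1][2] * x[2] +
                  m[1][3] * x[3] + (prev == 1 ? pers : 0.0);
      double z = beta * (pp - po);
      double p_press = 1.0 / (1.0 + std::exp(-z));
      a = (unif_rand() < p_press) ? 1 : 0;
    }

    // record the emitted frame
    vses[n] = session;
    vtri[n] = (phase == 1 || phase == 2 || phase == 3) ? trial : 0;
    fd[n] = x[0]; fs[n] = x[1]; fsh[n] = x[2]; fch[n] = x[3]; fhm[n] = x[4];
    fpr[n] = a;

    // next phase (task transition driven by the action)
    int nphase = phase, nk = k + 1, ntrial = trial, nsession = session;
    int nshocks = shocks;
    switch (phase) {
      case 0:  // habituation
        if (nk >= hab) { nphase = 1; nk = 0; nshocks = 0; }
        break;
      case 1:  // danger
        if (a == 1) { nphase = 3; nk = 0; }            // avoidance
        else if (nk >= dmax) { nphase = 2; nk = 0; }   // shock begins
        break;
      case 2:  // shock
        nshocks = shocks + shock_sched[k];
        if (nshocks > max_shocks) nshocks = max_shocks;
        if (a == 1 || nk >= smax || nshocks >= max_shocks) {
          nphase = 3; nk = 0;                          // escape or cap
        }
        break;
      case 3:  // ITI
        if (nk >= iti) {
          if (trial < trials) { nphase = 1; nk = 0; ntrial = trial + 1; nshocks = 0; }
          else { nphase = 4; nk = 0; }
        }
        break;
      case 4:  // homecage
        if (nk >= home) {
          nsession = session + 1; nphase = 0; nk = 0; ntrial = 1; nshocks = 0;
        }
        break;
    }

    // TD update with the next frame's value (0 past the final frame)
    double r = rsh * x[2] + rpr * a;
    double vnow = v[0] * x[0] + v[1] * x[1] + v[2] * x[2] + v[3] * x[3] +
                  v[4] * x[4];
    double vnext = 0;
    if (nsession <= n_sessions) {
      int xn[5];
      stim_of_phase(nphase, xn);
      vnext = v[0] * xn[0] + v[1] * xn[1] + v[2] * xn[2] + v[3] * xn[3] +
              v[4] * xn[4];
    }
    double delta = r + gam * vnext - vnow;
    double ad = alpha * delta, ed = eps * delta;
    for (int i = 0; i < 5; i++) {
      if (x[i]) { v[i] += ad; m[a][i] += ed; }
    }
    prev = a;

    phase = nphase; k = nk; trial = ntrial; shocks = nshocks;
    session = nsession;
    n++;
  }

  IntegerVector timestep(n), ses(n), tri(n), cd(n), cs(n), csh(n), cch(n),
      chm(n), cpr(n);
  for (int t = 0; t < n; t++) {
    timestep[t] = t + 1; ses[t] = vses[t]; tri[t] = vtri[t];
    cd[t] = fd[t]; cs[t] = fs[t]; csh[t] = fsh[t]; cch[t] = fch[t];
    chm[t] = fhm[t]; cpr[t] = fpr[t];
  }
  NumericVector vout(v, v + 5);
  NumericMatrix mout(2, 5);
  for (int ac = 0; ac < 2; ac++)
    for (int i = 0; i < 5; i++) mout(ac, i) = m[ac][i];
  return List::create(
      _["timestep"] = timestep, _["session"] = ses, _["trial"] = tri,
      _["danger"] = cd, _["safety"] = cs, _["shock"] = csh,
      _["chamber"] = cch, _["homecage"] = chm, _["press"] = cpr,
      _["v_weights"] = vout, _["m_weights"] = mout, _["prev_action"] = prev);
}
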