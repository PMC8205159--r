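// Compiled agent core: the same learner as the R reference implementation
// (novelty counts, SMiLe world-model, surprise-modulated TD with traces,
// prioritized sweeping, hybrid softmax policy), specialised to the 11-state
// 4-action task. Used by trajectory replay (likelihood fitting, model
// variables) and cohort simulation, where the per-step cost matters.
// A parity test in the test suite holds this file and the R reference to
// identical outputs.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NS = 11;   // states incl. goal
static const int NG = 10;   // non-goal states
static const int NACT = 4;
static const int GOAL = 10; // 0-based goal index
static const double PS_TOL = 1e-9;
static const double PRED_CUTOFF = 1e-2;

struct Params {
  double epsilon, m, t_ps, beta_1, beta_2, beta_n1, beta_n2,
    lambda_r, lambda_n, mu_r, mu_n, rho_b, delta_rho, q_n0,
    omega_0, omega_11, omega_12, omega_scale, gamma_leak, q_oi,
    bn_theta, bn_n;
};

class Agent {
public:
  Params P;
  int policy;        // 0 RC, 1 MB, 2 MF, 3 Hyb
  int explo;         // 0 none, 1 novelty, 2 OI, 3 U, 4 BN
  bool smod;
  int bn_kind;       // 0 off, 1 threshold, 2 top-n
  bool count_goal;
  bool uses_mb, uses_mf, nov_channel, uses_wm;

  int counts[NS];
  long tobs;
  double pc[NG][NACT][NS];
  double pcsum[NG][NACT];   // cached successor sums of pc
  double qmbr[NG][NACT], qmbn[NG][NACT], qmfr[NG][NACT], qmfn[NG][NACT];
  double er[NG][NACT], en[NG][NACT];
  double prir[NG], prin[NG];

  void init(const NumericVector& par, const IntegerVector& flags) {
    P.epsilon = par[0]; P.m = par[1]; P.t_ps = par[2];
    P.beta_1 = par[3]; P.beta_2 = par[4]; P.beta_n1 = par[5]; P.beta_n2 = par[6];
    P.lambda_r = par[7]; P.lambda_n = par[8]; P.mu_r = par[9]; P.mu_n = par[10];
    P.rho_b = par[11]; P.delta_rho = par[12]; P.q_n0 = par[13];
    P.omega_0 = par[14]; P.omega_11 = par[15]; P.omega_12 = par[16];
    P.omega_scale = par[17]; P.gamma_leak = par[18]; P.q_oi = par[19];
    P.bn_theta = par[20]; P.bn_n = par[21];
    policy = flags[0]; explo = flags[1]; smod = flags[2] != 0;
    bn_kind = flags[3]; count_goal = flags[4] != 0;
    uses_mb = (policy == 1 || policy == 3);
    uses_mf = (policy == 2 || policy == 3);
    nov_channel = (explo == 1 || explo == 3 || explo == 4);
    uses_wm = uses_mb || smod || explo == 3;

    for (int s = 0; s < NS; s++) counts[s] = 0;
    tobs = 0;
    double oi = (explo == 2) ? P.q_oi : 0.0;
    double n0 = nov_channel ? P.q_n0 : 0.0;
    for (int s = 0; s < NG; s++) {
      prir[s] = prin[s] = R_PosInf;
      for (int a = 0; a < NACT; a++) {
        qmbr[s][a] = oi; qmbn[s][a] = 0.0;
        qmfr[s][a] = oi; qmfn[s][a] = n0;
        er[s][a] = en[s][a] = 0.0;
        pcsum[s][a] = 0.0;
        for (int sn = 0; sn < NS; sn++) pc[s][a][sn] = 0.0;
      }
    }
  }

  void begin_episode(int start) {
    for (int s = 0; s < NG; s++)
      for (int a = 0; a < NACT; a++) er[s][a] = en[s][a] = 0.0;
    counts[start]++; tobs++;
  }

  double novelty_of(int s) const {
    return -std::log((counts[s] + 1.0) / (tobs + (double)NS));
  }

  double trans_prob(int s, int a, int sn) const {
    return (pc[s][a][sn] + P.epsilon) / (pcsum[s][a] + NS * P.epsilon);
  }

  double nov_weight(int block, int episode) const {
    if (!nov_channel || episode != 1) return 0.0;
    return (block == 1) ? P.beta_n1 : P.beta_n2;
  }

  // Combined action values of the policy at state s.
  void combined(int s, int block, int episode, double* u) const {
    double bn = nov_weight(block, episode);
    if (policy == 1) {
      for (int a = 0; a < NACT; a++) u[a] = qmbr[s][a] + bn * qmbn[s][a];
    } else if (policy == 2) {
      for (int a = 0; a < NACT; a++) u[a] = qmfr[s][a] + bn * qmfn[s][a];
    } else {
      double om = P.omega_0;
      double om1b = (block == 1) ? P.omega_11 : P.omega_12;
      for (int a = 0; a < NACT; a++)
        u[a] = P.omega_scale * (om * qmbr[s][a] + (1.0 - om) * qmfr[s][a] +
                 bn * (om1b * qmbn[s][a] + (1.0 - om1b) * qmfn[s][a]));
    }
  }

  void probs(int s, int block, int episode, double* p) const {
    if (policy == 0) { for (int a = 0; a < NACT; a++) p[a] = 0.25; return; }
    double u[NACT];
    combined(s, block, episode, u);
    double beta = (block == 1) ? P.beta_1 : P.beta_2;
    double z[NACT], zmax = -1e300, zsum = 0.0;
    for (int a = 0; a < NACT; a++) { z[a] = beta * u[a]; if (z[a] > zmax) zmax = z[a]; }
    for (int a = 0; a < NACT; a++) { z[a] = std::exp(z[a] - zmax); zsum += z[a]; }
    for (int a = 0; a < NACT; a++) p[a] = z[a] / zsum;
  }

  // Best-minus-worst branch values at s (for the dominance analysis).
  void branch_spread(int s, int block, int episode, double* dq_mf, double* dq_mb) const {
    double bn = nov_weight(block, episode);
    double mf_lo = 1e300, mf_hi = -1e300, mb_lo = 1e300, mb_hi = -1e300;
    for (int a = 0; a < NACT; a++) {
      double bmf = qmfr[s][a] + bn * qmfn[s][a];
      double bmb = qmbr[s][a] + bn * qmbn[s][a];
      if (bmf < mf_lo) mf_lo = bmf;
      if (bmf > mf_hi) mf_hi = bmf;
      if (bmb < mb_lo) mb_lo = bmb;
      if (bmb > mb_hi) mb_hi = bmb;
    }
    *dq_mf = mf_hi - mf_lo; *dq_mb = mb_hi - mb_lo;
  }

  bool bn_flagged(int s) const {
    if (bn_kind == 1) return counts[s] > P.bn_theta;
    // top-n by count, ties broken toward lower state label; only visited
    // states can be flagged
    int n = (int)std::lround(P.bn_n);
    int rank = 0;
    if (counts[s] == 0) return false;
    for (int k = 0; k < NS; k++) {
      if (counts[k] > counts[s] || (counts[k] == counts[s] && k < s)) {
        if (counts[k] > 0) rank++;
      }
    }
    return rank < n;
  }

  double channel_sig(int s_next, double s_bf) const {
    switch (explo) {
      case 1: return novelty_of(s_next);
      case 3: return std::log(s_bf);
      case 4: return bn_flagged(s_next) ? -1.0 : 0.0;
      default: return 0.0;
    }
  }

  // Reward of arriving at s' from (s, a), for the model-based planner.
  double mb_reward(int channel, int s, int a, int sn) const {
    if (channel == 0) return (sn == GOAL) ? 1.0 : 0.0;
    switch (explo) {
      case 1: return novelty_of(sn);
      case 3: return std::log((1.0 / NS) / trans_prob(s, a, sn));
      case 4: return bn_flagged(sn) ? -1.0 : 0.0;
      default: return 0.0;
    }
  }

  // Prioritized sweeping for one channel (0 = reward, 1 = novelty).
  void ps_sweep(int channel, int s, int s_next) {
    double* pri = (channel == 0) ? prir : prin;
    double (*q)[NACT] = (channel == 0) ? qmbr : qmbn;
    double disc = (channel == 0) ? P.lambda_r : P.lambda_n;
    int t_ps = (int)std::lround(P.t_ps);
    pri[s] = R_PosInf;
    if (channel == 1 && s_next != GOAL) {
      pri[s_next] = R_PosInf;
      for (int u = 0; u < NG; u++)
        for (int a = 0; a < NACT; a++)
          if (pc[u][a][s_next] > PRED_CUTOFF) { pri[u] = R_PosInf; break; }
    }
    double v[NG];
    for (int k = 0; k < NG; k++) {
      v[k] = q[k][0];
      for (int a = 1; a < NACT; a++) if (q[k][a] > v[k]) v[k] = q[k][a];
    }
    // novelty values are fixed within one sweep; cache them
    bool use_nov = (channel == 1 && explo == 1);
    bool use_bn = (channel == 1 && explo == 4);
    double rcache[NS];
    if (channel == 0) {
      for (int sn = 0; sn < NS; sn++) rcache[sn] = (sn == GOAL) ? 1.0 : 0.0;
    } else if (use_nov) {
      for (int sn = 0; sn < NS; sn++) rcache[sn] = novelty_of(sn);
    } else if (use_bn) {
      for (int sn = 0; sn < NS; sn++) rcache[sn] = bn_flagged(sn) ? -1.0 : 0.0;
    }
    for (int it = 0; it < t_ps; it++) {
      int st = 0;
      for (int k = 1; k < NG; k++) if (pri[k] > pri[st]) st = k;
      if (pri[st] <= PS_TOL) break;
      double v_before = v[st];
      for (int a = 0; a < NACT; a++) {
        double denom = pcsum[st][a] + NS * P.epsilon;
        double acc = 0.0;
        bool state_reward = (channel == 0 || use_nov || use_bn);
        for (int sn = 0; sn < NS; sn++) {
          double pr = (pc[st][a][sn] + P.epsilon) / denom;
          double cont = (sn == GOAL) ? 0.0 : v[sn];
          double rew = state_reward ? rcache[sn] : mb_reward(channel, st, a, sn);
          acc += pr * (rew + disc * cont);
        }
        q[st][a] = acc;
      }
      pri[st] = 0.0;
      double vn = q[st][0];
      for (int a = 1; a < NACT; a++) if (q[st][a] > vn) vn = q[st][a];
      v[st] = vn;
      double dv = std::fabs(vn - v_before);
      if (dv > PS_TOL) {
        // the smoothed model links every state pair; weight the value
        // change by the strongest transition probability into the state
        for (int u = 0; u < NG; u++) {
          double p_in = 0.0;
          for (int a = 0; a < NACT; a++) {
            double cand = (pc[u][a][st] + P.epsilon) / (pcsum[u][a] + NS * P.epsilon);
            if (cand > p_in) p_in = cand;
          }
          if (dv * p_in > pri[u]) pri[u] = dv * p_in;
        }
      }
    }
  }

  // One learning step; fills vars = {surprise, novelty, npe, rpe, reward}.
  void step(int s, int a, int s_next, int reward, int block, int episode,
            double* vars) {
    double nov = novelty_of(s_next);
    double s_bf = 0.0;
    if (uses_wm) s_bf = (1.0 / NS) / trans_prob(s, a, s_next);
    double gamma = smod ? (P.m * s_bf) / (1.0 + P.m * s_bf) : 0.0;
    double n_sig = channel_sig(s_next, s_bf);
    if (uses_wm) {
      double g_wm = smod ? gamma : P.gamma_leak;
      for (int sn = 0; sn < NS; sn++) pc[s][a][sn] *= (1.0 - g_wm);
      pc[s][a][s_next] += 1.0;
      double rs = 0.0;
      for (int sn = 0; sn < NS; sn++) rs += pc[s][a][sn];
      pcsum[s][a] = rs;
    }
    if (s_next != GOAL || count_goal) { counts[s_next]++; tobs++; }
    double rpe = 0.0, npe = 0.0;
    if (uses_mf) {
      for (int k = 0; k < NG; k++)
        for (int b = 0; b < NACT; b++) er[k][b] *= P.lambda_r * P.mu_r;
      er[s][a] = 1.0;
      double rho = P.rho_b + (smod ? gamma * P.delta_rho : 0.0);
      double v_next = 0.0;
      if (s_next != GOAL) {
        v_next = qmfr[s_next][0];
        for (int b = 1; b < NACT; b++) if (qmfr[s_next][b] > v_next) v_next = qmfr[s_next][b];
      }
      rpe = reward + P.lambda_r * v_next - qmfr[s][a];
      for (int k = 0; k < NG; k++)
        for (int b = 0; b < NACT; b++) qmfr[k][b] += rho * er[k][b] * rpe;
      if (nov_channel) {
        for (int k = 0; k < NG; k++)
          for (int b = 0; b < NACT; b++) en[k][b] *= P.lambda_n * P.mu_n;
        en[s][a] = 1.0;
        double vn_next = 0.0;
        if (s_next != GOAL) {
          vn_next = qmfn[s_next][0];
          for (int b = 1; b < NACT; b++) if (qmfn[s_next][b] > vn_next) vn_next = qmfn[s_next][b];
        }
        npe = n_sig + P.lambda_n * vn_next - qmfn[s][a];
        for (int k = 0; k < NG; k++)
          for (int b = 0; b < NACT; b++) qmfn[k][b] += rho * en[k][b] * npe;
      }
    }
    if (uses_mb) {
      ps_sweep(0, s, s_next);
      if (nov_channel) ps_sweep(1, s, s_next);
    }
    vars[0] = s_bf; vars[1] = nov; vars[2] = npe; vars[3] = rpe;
    vars[4] = (double)reward;
  }
};

// Replay a recorded trajectory. `steps` columns (1-based labels):
// block, episode, state, action, next_state, reward.
// [[Rcpp::export]]
List cpp_replay(NumericVector par, IntegerVector flags, IntegerMatrix steps) {
  Agent ag;
  ag.init(par, flags);
  int n = steps.nrow();
  NumericMatrix probs(n, NACT);
  NumericMatrix vars(n, 7);
  double loglik = 0.0;
  int cur_block = -1, cur_ep = -1, prev_next = -1;
  for (int i = 0; i < n; i++) {
    int block = steps(i, 0), ep = steps(i, 1);
    int s = steps(i, 2) - 1, a = steps(i, 3) - 1, sn = steps(i, 4) - 1;
    int r = steps(i, 5);
    if (s < 0 || s >= NG || a < 0 || a >= NACT || sn < 0 || sn >= NS)
      stop("trajectory labels out of range at row %d", i + 1);
    if (block != cur_block || ep != cur_ep) {
      ag.begin_episode(s);
      cur_block = block; cur_ep = ep;
    } else if (prev_next != s) {
      stop("trajectory is inconsistent at row %d: state does not follow the previous transition", i + 1);
    }
    double p[NACT];
    ag.probs(s, block, ep, p);
    for (int b = 0; b < NACT; b++) probs(i, b) = p[b];
    loglik += std::log(p[a]);
    double dq_mf, dq_mb;
    ag.branch_spread(s, block, ep, &dq_mf, &dq_mb);
    double v[5];
    ag.step(s, a, sn, r, block, ep, v);
    for (int k = 0; k < 5; k++) vars(i, k) = v[k];
    vars(i, 5) = dq_mf; vars(i, 6) = dq_mb;
    prev_next = sn;
  }
  colnames(vars) = CharacterVector::create("surprise", "novelty", "npe",
                                           "rpe", "reward", "dq_mf", "dq_mb");
  return List::create(_["loglik"] = loglik, _["probs"] = probs,
                      _["vars"] = vars);
}

// Simulate one agent through 2 blocks x 5 episodes. dtrans1/dtrans2 are the
// displayed 10x4 successor tables (1-based) for blocks 1 and 2; `starts`
// are the 5 displayed episode start states. Uses R's RNG.
// [[Rcpp::export]]
IntegerMatrix cpp_simulate(NumericVector par, IntegerVector flags,
                           IntegerMatrix dtrans1, IntegerMatrix dtrans2,
                           IntegerVector starts, int step_cap) {
  Agent ag;
  ag.init(par, flags);
  std::vector<int> rows;
  rows.reserve(4096);
  for (int block = 1; block <= 2; block++) {
    const IntegerMatrix& dt = (block == 1) ? dtrans1 : dtrans2;
    for (int ep = 1; ep <= 5; ep++) {
      int s = starts[ep - 1] - 1;
      ag.begin_episode(s);
      int nstep = 0;
      while (s != GOAL && nstep < step_cap) {
        double p[NACT];
        ag.probs(s, block, ep, p);
        double u = unif_rand(), acc = 0.0;
        int a = NACT - 1;
        for (int b = 0; b < NACT; b++) { acc += p[b]; if (u <= acc) { a = b; break; } }
        int sn = dt(s, a) - 1;
        int r = (sn == GOAL) ? 1 : 0;
        double v[5];
        ag.step(s, a, sn, r, block, ep, v);
        nstep++;
        rows.push_back(block); rows.push_back(ep); rows.push_back(nstep);
        rows.push_back(s + 1); rows.push_back(a + 1); rows.push_back(sn + 1);
        rows.push_back(r);
        s = sn;
      }
    }
  }
  int n = rows.size() / 7;
  IntegerMatrix out(n, 7);
  for (int i = 0; i < n; i++)
    for (int j = 0; j < 7; j++) out(i, j) = rows[i * 7 + j];
  colnames(out) = CharacterVector::create("block", "episode", "step",
                                          "state", "action", "next_state",
                                          "reward");
  return out;
}

// Monte-Carlo first-passage times to the goal under the uniform policy.
// Returns per-start-state means and standard errors over `n_episodes`
// walks per start state.
// [[Rcpp::export]]
List cpp_hitting_mc(IntegerMatrix trans, int n_episodes) {
  NumericVector mean_(NG), se(NG);
  for (int s0 = 0; s0 < NG; s0++) {
    double sum = 0.0, sumsq = 0.0;
    for (int e = 0; e < n_episodes; e++) {
      int s = s0;
      long nstep = 0;
      while (s != GOAL) {
        int a = (int)(unif_rand() * NACT);
        if (a == NACT) a = NACT - 1;
        s = trans(s, a) - 1;
        nstep++;
      }
      sum += nstep; sumsq += (double)nstep * nstep;
    }
    double mu = sum / n_episodes;
    double var = (sumsq - n_episodes * mu * mu) / (n_episodes - 1.0);
    mean_[s0] = mu;
    se[s0] = std::sqrt(var / n_episodes);
  }
  return List::create(_["mean"] = mean_, _["se"] = se);
}
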