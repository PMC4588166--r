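#include <Rcpp.h>
using namespace Rcpp;

// State/action coding used throughout:
//   states  : s_A = 0, s_B = 1, s_C = 2
//   actions : a_A = 0, a_B = 1
//   transition model: a_A commonly leads to s_B, a_B commonly to s_C
// Per-trial parameter matrix `par` has columns
//   0 alpha1, 1 alpha2, 2 beta1, 3 beta2, 4 eps, 5 w
// lambda and sigma are session constants.

static inline double clip01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

// P(action 0) under softmax with lapse; stable for large |beta * dq|
static inline double p_first(double q0, double q1, double beta, double eps) {
  double d = beta * (q0 - q1);
  double p;
  if (d >= 0.0) {
    p = 1.0 / (1.0 + std::exp(-d));
  } else {
    double e = std::exp(d);
    p = e / (1.0 + e);
  }
  return eps + (1.0 - 2.0 * eps) * p;
}

static inline double maxq(const double q[3][2], int s) {
  return q[s][0] > q[s][1] ? q[s][0] : q[s][1];
}

static inline void reset_q(double q[3][2]) {
  for (int s = 0; s < 3; ++s) q[s][0] = q[s][1] = 0.0;
}

// [[Rcpp::export]]
List ll_session_cpp(IntegerVector day, IntegerVector choice1, IntegerVector state2,
                    IntegerVector choice2, IntegerVector reward,
                    IntegerVector scored,
                    NumericMatrix par, double lambda, double sigma,
                    double p_common, bool reset_each_day, bool trial_probs) {
  int n = day.size();
  double q[3][2];
  reset_q(q);
  double ll = 0.0;
  NumericMatrix probs;
  if (trial_probs) probs = NumericMatrix(n, 2);

  for (int i = 0; i < n; ++i) {
    if (i > 0 && day[i] != day[i - 1] && reset_each_day) reset_q(q);
    double a1r = par(i, 0), a2r = par(i, 1), b1 = par(i, 2), b2 = par(i, 3);
    double eps = par(i, 4), w = par(i, 5);
    double w_eff = clip01(w * std::exp(sigma * (day[i] - 2.0)));

    double qmb0 = p_common * maxq(q, 1) + (1.0 - p_common) * maxq(q, 2);
    double qmb1 = p_common * maxq(q, 2) + (1.0 - p_common) * maxq(q, 1);
    double qh0 = w_eff * qmb0 + (1.0 - w_eff) * q[0][0];
    double qh1 = w_eff * qmb1 + (1.0 - w_eff) * q[0][1];

    int a1 = choice1[i], s2 = state2[i], a2 = choice2[i], r = reward[i];
    double p1 = p_first(qh0, qh1, b1, eps);
    double pc1 = (a1 == 0) ? p1 : 1.0 - p1;
    if (scored[i]) ll += std::log(pc1);

    // stage-1 TD update once the second-stage state is observed (r1 = 0, gamma = 1)
    double d1 = maxq(q, s2) - q[0][a1];
    q[0][a1] += a1r * d1;

    double p2 = p_first(q[s2][0], q[s2][1], b2, eps);
    double pc2 = (a2 == 0) ? p2 : 1.0 - p2;
    if (scored[i]) ll += std::log(pc2);

    if (trial_probs) { probs(i, 0) = pc1; probs(i, 1) = pc2; }

    double d2 = (double)r - q[s2][a2];
    q[s2][a2] += a2r * d2;
    q[0][a1] += a1r * lambda * d2;  // eligibility-trace credit to the first-stage action
  }
  if (trial_probs) return List::create(_["loglik"] = ll, _["probs"] = probs);
  return List::create(_["loglik"] = ll);
}

// Constant-parameter fast path used inside optimizer loops.
// [[Rcpp::export]]
double ll_session_const_cpp(IntegerVector day, IntegerVector choice1,
                            IntegerVector state2, IntegerVector choice2,
                            IntegerVector reward, IntegerVector scored,
                            double alpha1, double alpha2, double beta1,
                            double beta2, double eps, double w,
                            double lambda, double sigma,
                            double p_common, bool reset_each_day) {
  int n = day.size();
  double q[3][2];
  reset_q(q);
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    if (i > 0 && day[i] != day[i - 1] && reset_each_day) reset_q(q);
    double w_eff = clip01(w * std::exp(sigma * (day[i] - 2.0)));
    double qmb0 = p_common * maxq(q, 1) + (1.0 - p_common) * maxq(q, 2);
    double qmb1 = p_common * maxq(q, 2) + (1.0 - p_common) * maxq(q, 1);
    double qh0 = w_eff * qmb0 + (1.0 - w_eff) * q[0][0];
    double qh1 = w_eff * qmb1 + (1.0 - w_eff) * q[0][1];
    int a1 = choice1[i], s2 = state2[i], a2 = choice2[i], r = reward[i];
    double p1 = p_first(qh0, qh1, beta1, eps);
    if (scored[i]) ll += std::log((a1 == 0) ? p1 : 1.0 - p1);
    double d1 = maxq(q, s2) - q[0][a1];
    q[0][a1] += alpha1 * d1;
    double p2 = p_first(q[s2][0], q[s2][1], beta2, eps);
    if (scored[i]) ll += std::log((a2 == 0) ? p2 : 1.0 - p2);
    double d2 = (double)r - q[s2][a2];
    q[s2][a2] += alpha2 * d2;
    q[0][a1] += alpha1 * lambda * d2;
  }
  return ll;
}

// Generative twin of ll_session_cpp: identical value updates, choices sampled.
// rp: n x 4 reward probabilities for (s_B,a_A),(s_B,a_B),(s_C,a_A),(s_C,a_B);
// u : n x 4 uniform draws for (choice1, transition, choice2, reward).
// [[Rcpp::export]]
List sim_session_cpp(IntegerVector day, NumericMatrix rp, NumericMatrix u,
                     NumericMatrix par, double lambda, double sigma,
                     double p_common, bool reset_each_day) {
  int n = day.size();
  double q[3][2];
  reset_q(q);
  IntegerVector choice1(n), common(n), state2(n), choice2(n), reward(n);

  for (int i = 0; i < n; ++i) {
    if (i > 0 && day[i] != day[i - 1] && reset_each_day) reset_q(q);
    double a1r = par(i, 0), a2r = par(i, 1), b1 = par(i, 2), b2 = par(i, 3);
    double eps = par(i, 4), w = par(i, 5);
    double w_eff = clip01(w * std::exp(sigma * (day[i] - 2.0)));

    double qmb0 = p_common * maxq(q, 1) + (1.0 - p_common) * maxq(q, 2);
    double qmb1 = p_common * maxq(q, 2) + (1.0 - p_common) * maxq(q, 1);
    double qh0 = w_eff * qmb0 + (1.0 - w_eff) * q[0][0];
    double qh1 = w_eff * qmb1 + (1.0 - w_eff) * q[0][1];

    int a1 = (u(i, 0) < p_first(qh0, qh1, b1, eps)) ? 0 : 1;
    bool com = u(i, 1) < p_common;
    int s2 = ((a1 == 0) == com) ? 1 : 2;

    double d1 = maxq(q, s2) - q[0][a1];
    q[0][a1] += a1r * d1;

    int a2 = (u(i, 2) < p_first(q[s2][0], q[s2][1], b2, eps)) ? 0 : 1;
    double pr = rp(i, (s2 == 1 ? 0 : 2) + a2);
    int r = (u(i, 3) < pr) ? 1 : 0;

    double d2 = (double)r - q[s2][a2];
    q[s2][a2] += a2r * d2;
    q[0][a1] += a1r * lambda * d2;

    choice1[i] = a1; common[i] = com ? 1 : 0; state2[i] = s2;
    choice2[i] = a2; reward[i] = r;
  }
  return List::create(_["choice1"] = choice1, _["common"] = common,
                      _["state2"] = state2, _["choice2"] = choice2,
                      _["reward"] = reward);
}
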