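#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Outcome likelihood pair (P(o | x=1), P(o | x=2)) for one trial.
static inline void lik_pair(int cue, int action, int outcome, double v,
                            double* l) {
  // action correct under x = 1 iff a == x for y = 1, a == 3 - x for y = 2
  bool conc1 = (cue == 1) ? (action == 1) : (action == 2);
  double p1 = conc1 ? v : 1.0 - v;       // P(o = 1 | x = 1)
  double p2 = conc1 ? 1.0 - v : v;       // P(o = 1 | x = 2)
  if (outcome == 1) { l[0] = p1;       l[1] = p2; }
  else              { l[0] = 1.0 - p1; l[1] = 1.0 - p2; }
}

// Extend a joint of length len by one state through the transition matrix.
static inline int extend(const double* joint, int len, double r, double* out) {
  for (int i = 0; i < len; ++i) {
    double stay = ((i & 1) == 0) ? 1.0 - r : r;   // P(new = 1 | last state)
    out[2 * i]     = joint[i] * stay;
    out[2 * i + 1] = joint[i] * (1.0 - stay);
  }
  return 2 * len;
}

// Windowed sequential inference: recursive fixed-window joint posterior with
// frozen boundary beliefs (evicted-state marginal) and re-application of the
// retained trials' likelihood factors. Matches the R reference implementation
// built from advance_window()/incorporate_outcome().
// [[Rcpp::export]]
List seq_inference_cpp(int order, double r, double v, double gamma,
                       IntegerVector cue, IntegerVector action,
                       IntegerVector outcome, bool keep_joints = false) {
  if (order < 1 || order > 5) stop("`order` must be in 1..5");
  const int T = cue.size();
  if (action.size() != T || outcome.size() != T)
    stop("cue, action and outcome must have equal length");

  double joint[64], buf[64];
  double fl[8][2];              // retained factors' likelihood pairs
  int nfac = 0;
  double b[2] = {0.5, 0.5};     // boundary belief
  int w = 0, len = 0;

  NumericVector pred_p1(T), post_p1(T), p_action1(T);
  NumericMatrix J = keep_joints ? NumericMatrix(T, 1 << order)
                                : NumericMatrix(0, 0);
  if (keep_joints) std::fill(J.begin(), J.end(), NA_REAL);

  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    int y = cue[t], a = action[t], o = outcome[t];
    if ((y != 1 && y != 2) || (a != 1 && a != 2) || (o != 1 && o != 2))
      stop("trial %d has a code outside {1, 2}", t + 1);

    // --- advance the window ---
    if (w == 0) {
      joint[0] = b[0] * (1.0 - r) + b[1] * r;
      joint[1] = b[0] * r + b[1] * (1.0 - r);
      len = 2;
    } else if (w < order) {
      len = extend(joint, len, r, buf);
      std::copy(buf, buf + len, joint);
    } else {
      // evict oldest state: its marginal becomes the new boundary
      int half = len / 2;
      double s0 = 0.0, s1 = 0.0;
      for (int i = 0; i < half; ++i) s0 += joint[i];
      for (int i = half; i < len; ++i) s1 += joint[i];
      b[0] = s0 / (s0 + s1); b[1] = s1 / (s0 + s1);
      for (int i = 1; i < nfac; ++i) { fl[i-1][0] = fl[i][0]; fl[i-1][1] = fl[i][1]; }
      --nfac;
      // rebuild over retained states against the boundary-propagated prior
      joint[0] = b[0] * (1.0 - r) + b[1] * r;
      joint[1] = b[0] * r + b[1] * (1.0 - r);
      len = 2;
      if (nfac > 0) {
        joint[0] *= fl[0][0]; joint[1] *= fl[0][1];
        for (int i = 1; i < nfac; ++i) {
          len = extend(joint, len, r, buf);
          for (int j = 0; j < len; ++j) joint[j] = buf[j] * fl[i][j & 1];
        }
        len = extend(joint, len, r, buf);
        std::copy(buf, buf + len, joint);
      }
    }
    double s = 0.0;
    for (int i = 0; i < len; ++i) s += joint[i];
    for (int i = 0; i < len; ++i) joint[i] /= s;
    if (w < order) ++w;

    // --- predictive marginal and action probability ---
    double m1 = 0.0;
    for (int i = 0; i < len; i += 2) m1 += joint[i];
    pred_p1[t] = m1;
    double p1 = 1.0 / (1.0 + std::exp(-gamma * (m1 - (1.0 - m1))));
    double pa1 = (y == 1) ? p1 : 1.0 - p1;
    p_action1[t] = pa1;
    ll += std::log(a == 1 ? pa1 : 1.0 - pa1);

    // --- incorporate the outcome ---
    double l[2];
    lik_pair(y, a, o, v, l);
    s = 0.0;
    for (int i = 0; i < len; ++i) { joint[i] *= l[i & 1]; s += joint[i]; }
    if (s <= 0.0) stop("outcome at trial %d has zero likelihood", t + 1);
    for (int i = 0; i < len; ++i) joint[i] /= s;
    fl[nfac][0] = l[0]; fl[nfac][1] = l[1]; ++nfac;

    double pm1 = 0.0;
    for (int i = 0; i < len; i += 2) pm1 += joint[i];
    post_p1[t] = pm1;
    if (keep_joints)
      for (int i = 0; i < len; ++i) J(t, i) = joint[i];
  }

  List out = List::create(_["log_likelihood"] = ll,
                          _["pred_p1"] = pred_p1,
                          _["post_p1"] = post_p1,
                          _["p_action1"] = p_action1);
  if (keep_joints) out["joints_matrix"] = J;
  return out;
}

// Delta-rule action-value likelihood (Q1/Q2/Q3) for fast fitting.
// variant: 1 = single update, 2 = quadruple update, 3 = quadruple asymmetric.
// [[Rcpp::export]]
List q_inference_cpp(int variant, double rate_gain, double rate_loss,
                     double gamma, IntegerVector cue, IntegerVector action,
                     IntegerVector outcome, bool keep_values = false) {
  if (variant < 1 || variant > 3) stop("`variant` must be 1, 2 or 3");
  const int T = cue.size();
  if (action.size() != T || outcome.size() != T)
    stop("cue, action and outcome must have equal length");

  double Q[2][2] = {{0.5, 0.5}, {0.5, 0.5}};   // [cue - 1][action - 1]
  NumericVector p_action1(T);
  NumericMatrix V = keep_values ? NumericMatrix(T, 4) : NumericMatrix(0, 0);
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    int y = cue[t], a = action[t], o = outcome[t];
    if ((y != 1 && y != 2) || (a != 1 && a != 2) || (o != 1 && o != 2))
      stop("trial %d has a code outside {1, 2}", t + 1);
    double p1 = 1.0 / (1.0 + std::exp(-gamma * (Q[y-1][0] - Q[y-1][1])));
    p_action1[t] = p1;
    double pch = (a == 1) ? p1 : 1.0 - p1;
    ll += std::log(pch);

    double R = (o == 1) ? 1.0 : 0.0;
    double rate = (variant == 3) ? (o == 1 ? rate_gain : rate_loss) : rate_gain;
    if (variant == 1) {
      Q[y-1][a-1] += rate * (R - Q[y-1][a-1]);
    } else {
      // chosen pair and its logical twin move toward R; the two mirrored
      // pairs move toward 1 - R, each with its own prediction error
      Q[y-1][a-1]   += rate * (R - Q[y-1][a-1]);
      Q[2-y][2-a]   += rate * (R - Q[2-y][2-a]);
      Q[y-1][2-a]   += rate * ((1.0 - R) - Q[y-1][2-a]);
      Q[2-y][a-1]   += rate * ((1.0 - R) - Q[2-y][a-1]);
    }
    if (keep_values) {
      V(t, 0) = Q[0][0]; V(t, 1) = Q[0][1]; V(t, 2) = Q[1][0]; V(t, 3) = Q[1][1];
    }
  }
  List out = List::create(_["log_likelihood"] = ll, _["p_action1"] = p_action1);
  if (keep_values) out["values_matrix"] = V;
  return out;
}
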