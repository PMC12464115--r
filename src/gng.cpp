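#include <Rcpp.h>
using namespace Rcpp;

// Parameter vector layout used throughout: c(alpha0, alpha1, tau, xi, b, pi).
// Models without a learning bias pass alpha0 == alpha1; inactive b/pi/xi are 0.
// Trial covariates are integer vectors: cond in 0..3 (cue index), vs = +1 for
// immediate-reward cues and -1 for delayed-reward cues.

namespace {

inline double p_go_trial(const double *Q, int c, double tau, double xi,
                         double b, double pi_, int vs) {
  double wg = Q[2 * c + 1] + b + pi_ * vs;
  double wn = Q[2 * c + 0];
  // softmax with max-subtraction for numerical stability at large tau
  double m = std::max(tau * wg, tau * wn);
  double eg = std::exp(tau * wg - m), en = std::exp(tau * wn - m);
  double p = eg / (eg + en);
  return p * (1.0 - xi) + xi / 2.0;
}

inline double alpha_eff(double a0, double a1, int action, int vs, int reward) {
  // Learning bias: faster learning for go followed by an obtained immediate
  // reward, and for nogo followed by an obtained delayed reward; everything
  // else (including all no-reward outcomes) uses the baseline rate.
  if (reward == 1 && ((action == 1 && vs > 0) || (action == 0 && vs < 0)))
    return a0;
  return a1;
}

inline double loglik_one(const double *par, const IntegerVector &cond,
                         const IntegerVector &vs, const IntegerVector &response,
                         const IntegerVector &outcome) {
  double a0 = par[0], a1 = par[1], tau = par[2], xi = par[3], b = par[4],
         pi_ = par[5];
  double Q[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  const int n = cond.size();
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    int c = cond[t];
    double pg = p_go_trial(Q, c, tau, xi, b, pi_, vs[t]);
    double p = response[t] == 1 ? pg : 1.0 - pg;
    if (p < 1e-12) p = 1e-12;  // only reachable when xi == 0
    ll += std::log(p);
    int a = response[t], r = outcome[t];
    double ae = alpha_eff(a0, a1, a, vs[t], r);
    Q[2 * c + a] += ae * (r - Q[2 * c + a]);
  }
  return ll;
}

}  // namespace

// [[Rcpp::export]]
double cpp_session_loglik(NumericVector par, IntegerVector cond,
                          IntegerVector vs, IntegerVector response,
                          IntegerVector outcome) {
  return loglik_one(REAL(par), cond, vs, response, outcome);
}

// Evaluate one session's log-likelihood for a whole population of parameter
// vectors (rows of `par`); this is the differential-evolution inner loop.
// [[Rcpp::export]]
NumericVector cpp_session_loglik_batch(NumericMatrix par, IntegerVector cond,
                                       IntegerVector vs,
                                       IntegerVector response,
                                       IntegerVector outcome) {
  const int np = par.nrow();
  NumericVector out(np);
  double p6[6];
  for (int i = 0; i < np; ++i) {
    for (int j = 0; j < 6; ++j) p6[j] = par(i, j);
    out[i] = loglik_one(p6, cond, vs, response, outcome);
  }
  return out;
}

// Per-trial go probabilities along an observed session (state evolved with
// the observed responses/outcomes, as in the likelihood).
// [[Rcpp::export]]
NumericVector cpp_session_pgo(NumericVector par, IntegerVector cond,
                              IntegerVector vs, IntegerVector response,
                              IntegerVector outcome) {
  double a0 = par[0], a1 = par[1], tau = par[2], xi = par[3], b = par[4],
         pi_ = par[5];
  double Q[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  const int n = cond.size();
  NumericVector pgo(n);
  for (int t = 0; t < n; ++t) {
    int c = cond[t];
    pgo[t] = p_go_trial(Q, c, tau, xi, b, pi_, vs[t]);
    int a = response[t], r = outcome[t];
    double ae = alpha_eff(a0, a1, a, vs[t], r);
    Q[2 * c + a] += ae * (r - Q[2 * c + a]);
  }
  return pgo;
}

// Simulate one agent on a schedule. Draws use R's RNG so results are
// reproducible under set.seed(). Returns response, correct, outcome, p_go.
// [[Rcpp::export]]
List cpp_simulate_agent(NumericVector par, IntegerVector cond, IntegerVector vs,
                        IntegerVector go_required,
                        IntegerVector feedback_valid) {
  double a0 = par[0], a1 = par[1], tau = par[2], xi = par[3], b = par[4],
         pi_ = par[5];
  double Q[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  const int n = cond.size();
  IntegerVector response(n), correct(n), outcome(n);
  NumericVector pgo(n);
  for (int t = 0; t < n; ++t) {
    int c = cond[t];
    double pg = p_go_trial(Q, c, tau, xi, b, pi_, vs[t]);
    pgo[t] = pg;
    int a = unif_rand() < pg ? 1 : 0;
    int corr = (a == go_required[t]) ? 1 : 0;
    int r = feedback_valid[t] == 1 ? corr : 1 - corr;
    response[t] = a;
    correct[t] = corr;
    outcome[t] = r;
    double ae = alpha_eff(a0, a1, a, vs[t], r);
    Q[2 * c + a] += ae * (r - Q[2 * c + a]);
  }
  return List::create(_["response"] = response, _["correct"] = correct,
                      _["outcome"] = outcome, _["p_go"] = pgo);
}

// Rejection-sample a condition sequence: uniform shuffles of the label
// multiset, rejecting any sequence with a same-label run longer than max_run.
// Exactly uniform over admissible sequences. Returns 1-based labels.
// [[Rcpp::export]]
IntegerVector cpp_generate_sequence(IntegerVector counts, int max_run,
                                    int max_attempts) {
  int total = 0;
  for (int i = 0; i < counts.size(); ++i) total += counts[i];
  std::vector<int> labels;
  labels.reserve(total);
  for (int i = 0; i < counts.size(); ++i)
    for (int j = 0; j < counts[i]; ++j) labels.push_back(i + 1);

  for (int attempt = 0; attempt < max_attempts; ++attempt) {
    // Fisher-Yates with R's RNG
    for (int i = total - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(labels[i], labels[j]);
    }
    int run = 1;
    bool ok = true;
    for (int i = 1; i < total; ++i) {
      run = (labels[i] == labels[i - 1]) ? run + 1 : 1;
      if (run > max_run) {
        ok = false;
        break;
      }
    }
    if (ok) return IntegerVector(labels.begin(), labels.end());
  }
  stop("no admissible sequence found within %d attempts", max_attempts);
}

// Sequential pseudorandomization for long sequences, where whole-shuffle
// rejection is infeasible: draw each label with probability proportional to
// its remaining count, excluding a label that would exceed max_run; restart
// on an endgame deadlock. Always terminates for balanced label sets.
// [[Rcpp::export]]
IntegerVector cpp_generate_sequence_seq(IntegerVector counts, int max_run,
                                        int max_restarts) {
  const int k = counts.size();
  int total = 0;
  for (int i = 0; i < k; ++i) total += counts[i];
  std::vector<int> out(total);
  for (int attempt = 0; attempt < max_restarts; ++attempt) {
    std::vector<int> left(counts.begin(), counts.end());
    int run = 0, last = -1;
    bool ok = true;
    for (int t = 0; t < total; ++t) {
      double w = 0.0;
      for (int j = 0; j < k; ++j)
        if (!(j == last && run >= max_run)) w += left[j];
      if (w <= 0) { ok = false; break; }
      double u = unif_rand() * w;
      int pick = -1;
      for (int j = 0; j < k; ++j) {
        if (j == last && run >= max_run) continue;
        u -= left[j];
        if (u <= 0) { pick = j; break; }
      }
      if (pick < 0) { ok = false; break; }
      out[t] = pick + 1;
      left[pick]--;
      run = (pick == last) ? run + 1 : 1;
      last = pick;
    }
    if (ok) return IntegerVector(out.begin(), out.end());
  }
  stop("no admissible sequence found within %d restarts", max_restarts);
}
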