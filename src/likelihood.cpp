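#include <Rcpp.h>
using namespace Rcpp;

// Negative log-likelihood of one subject's choice sequence under the hybrid
// model. Q-SARSA is the nested case omega = 0, rho = 0. Both stage choices of
// every non-omitted trial contribute a term; omitted trials contribute
// nothing, perform no update, and reset the perseveration reference.
//
// Coding: choice1, choice2, state2 are 0/1 (A/B, a/b, S1/S2); the common
// transition links choice k to state k. Arithmetic mirrors the R simulator
// exactly (same max-subtracted softmax), so the two agree to ~1e-16.

// [[Rcpp::export]]
List nll_choices_cpp(IntegerVector choice1, IntegerVector state2,
                     IntegerVector choice2, NumericVector outcome,
                     LogicalVector omitted,
                     double alpha, double beta, double rho, double omega,
                     double lam, double p_common, bool keep_probs = false) {
  int n = choice1.size();
  double q1[2] = {0.0, 0.0};
  double q2[2][2] = {{0.0, 0.0}, {0.0, 0.0}};
  int prev = -1;
  double nll = 0.0;
  int n_obs = 0;
  NumericVector p1_out, p2_out;
  if (keep_probs) { p1_out = NumericVector(n, NA_REAL); p2_out = NumericVector(n, NA_REAL); }

  for (int t = 0; t < n; ++t) {
    if (omitted[t]) { prev = -1; continue; }
    int c1 = choice1[t], s2 = state2[t], c2 = choice2[t];

    double best0 = q2[0][0] > q2[0][1] ? q2[0][0] : q2[0][1];
    double best1 = q2[1][0] > q2[1][1] ? q2[1][0] : q2[1][1];
    double qmb[2] = {p_common * best0 + (1.0 - p_common) * best1,
                     p_common * best1 + (1.0 - p_common) * best0};
    double z[2];
    for (int a = 0; a < 2; ++a) {
      double qnet = omega * qmb[a] + (1.0 - omega) * q1[a];
      z[a] = beta * qnet + ((a == prev) ? rho : 0.0);
    }
    double zmax = z[0] > z[1] ? z[0] : z[1];
    double e0 = std::exp(z[0] - zmax), e1 = std::exp(z[1] - zmax);
    double p1 = (c1 == 0 ? e0 : e1) / (e0 + e1);

    double w[2] = {beta * q2[s2][0], beta * q2[s2][1]};
    double wmax = w[0] > w[1] ? w[0] : w[1];
    double f0 = std::exp(w[0] - wmax), f1 = std::exp(w[1] - wmax);
    double p2 = (c2 == 0 ? f0 : f1) / (f0 + f1);

    nll -= std::log(p1) + std::log(p2);
    n_obs += 2;
    if (keep_probs) { p1_out[t] = p1; p2_out[t] = p2; }

    double d1 = q2[s2][c2] - q1[c1];
    q1[c1] += alpha * d1;
    double d2 = outcome[t] - q2[s2][c2];
    q2[s2][c2] += alpha * d2;
    q1[c1] += alpha * lam * d2;
    prev = c1;
  }
  if (!std::isfinite(nll)) stop("non-finite negative log-likelihood");
  List res = List::create(_["nll"] = nll, _["n_obs"] = n_obs);
  if (keep_probs) { res["p_choice1"] = p1_out; res["p_choice2"] = p2_out; }
  return res;
}
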