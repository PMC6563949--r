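#include <Rcpp.h>
using namespace Rcpp;

// Model codes must match .model_code() on the R side:
// 1 VSE, 2 VSE_LA, 3 EV, 4 PVL, 5 PVL_Delta, 6 VPP, 7 ORL.
// Parameter order matches model_spec()$params.

static inline double pow0(double x, double p) {
  return (x == 0.0) ? 0.0 : std::pow(x, p);
}

static inline double prospect(double gain, double loss, double nu, double lambda) {
  double x = gain - loss;
  if (x > 0.0) return std::pow(x, nu);
  if (x == 0.0) return 0.0;
  return -lambda * std::pow(-x, nu);
}

// Per-trial choice probabilities (softmax with max-subtraction) and
// summed log-likelihood for one session under one model.
// [[Rcpp::export(name = ".session_loglik_cpp")]]
List session_loglik_cpp(int model, IntegerVector choice, NumericVector gain,
                        NumericVector loss, NumericVector par) {
  const int T = choice.size();
  NumericMatrix probs(T, 4);
  NumericVector p_choice(T);
  double exploit[4] = {0, 0, 0, 0};
  double explore[4] = {1, 1, 1, 1};
  double pers[4] = {0, 0, 0, 0};
  double freq[4] = {0, 0, 0, 0};
  double ll = 0.0;

  for (int t = 0; t < T; ++t) {
    // combined deck values
    double v[4];
    for (int d = 0; d < 4; ++d) {
      switch (model) {
      case 1: case 2: v[d] = exploit[d] + explore[d]; break;
      case 6: v[d] = par[7] * exploit[d] + (1.0 - par[7]) * pers[d]; break;
      case 7: v[d] = exploit[d] + par[3] * freq[d] + par[4] * pers[d]; break;
      default: v[d] = exploit[d];
      }
    }
    // consistency
    double C;
    switch (model) {
    case 1: C = std::pow(3.0, par[4]) - 1.0; break;        // VSE
    case 2: C = std::pow(3.0, par[5]) - 1.0; break;        // VSE_LA
    case 3: C = std::pow((t + 1) / 10.0, par[2]); break;   // EV, 1-based t
    case 7: C = 1.0; break;                                // ORL
    default: C = std::pow(3.0, par[3]) - 1.0;              // PVL/PVL_Delta/VPP
    }
    double z[4], zmax = -INFINITY;
    for (int d = 0; d < 4; ++d) { z[d] = v[d] * C; if (z[d] > zmax) zmax = z[d]; }
    double denom = 0.0;
    for (int d = 0; d < 4; ++d) { z[d] = std::exp(z[d] - zmax); denom += z[d]; }
    for (int d = 0; d < 4; ++d) probs(t, d) = z[d] / denom;

    int c = choice[t] - 1;
    if (c < 0 || c > 3) stop("invalid deck at trial %d", t + 1);
    double pc = probs(t, c);
    if (!std::isfinite(pc)) stop("non-finite choice probability at trial %d", t + 1);
    p_choice[t] = pc;
    ll += std::log(pc < 1e-12 ? 1e-12 : pc);

    // state update from the observed outcome
    double g = gain[t], l = loss[t], x = g - l;
    switch (model) {
    case 1: { // VSE: theta delta alpha phi cons
      double u = pow0(g, par[0]) - pow0(l, par[0]);
      for (int d = 0; d < 4; ++d) exploit[d] *= par[1];
      exploit[c] += u;
      for (int d = 0; d < 4; ++d)
        if (d != c) explore[d] += par[2] * (par[3] - explore[d]);
      explore[c] = 0.0;
      break;
    }
    case 2: { // VSE_LA: nu lambda delta alpha phi cons
      double u = prospect(g, l, par[0], par[1]);
      for (int d = 0; d < 4; ++d) exploit[d] *= par[2];
      exploit[c] += u;
      for (int d = 0; d < 4; ++d)
        if (d != c) explore[d] += par[3] * (par[4] - explore[d]);
      explore[c] = 0.0;
      break;
    }
    case 3: { // EV: a w cons
      double u = (1.0 - par[1]) * g - par[1] * l;
      exploit[c] += par[0] * (u - exploit[c]);
      break;
    }
    case 4: { // PVL: delta nu lambda cons
      double u = prospect(g, l, par[1], par[2]);
      for (int d = 0; d < 4; ++d) exploit[d] *= par[0];
      exploit[c] += u;
      break;
    }
    case 5: { // PVL_Delta: a nu lambda cons
      double u = prospect(g, l, par[1], par[2]);
      exploit[c] += par[0] * (u - exploit[c]);
      break;
    }
    case 6: { // VPP: a nu lambda cons eps_gain eps_loss delta_pers w_ev
      double u = prospect(g, l, par[1], par[2]);
      exploit[c] += par[0] * (u - exploit[c]);
      for (int d = 0; d < 4; ++d) pers[d] *= par[6];
      pers[c] += (x >= 0.0) ? par[4] : par[5];
      break;
    }
    case 7: { // ORL: a_rew a_pun K w_f w_p
      double s = (x > 0.0) ? 1.0 : (x < 0.0 ? -1.0 : 0.0);
      double a_c = (x >= 0.0) ? par[0] : par[1];  // chosen-deck rate
      double a_u = (x >= 0.0) ? par[1] : par[0];  // fictive rate
      exploit[c] += a_c * (x - exploit[c]);
      freq[c] += a_c * (s - freq[c]);
      for (int d = 0; d < 4; ++d)
        if (d != c) freq[d] += a_u * (-s / 3.0 - freq[d]);
      pers[c] = 1.0;
      for (int d = 0; d < 4; ++d) pers[d] /= (1.0 + par[2]);
      break;
    }
    default: stop("unknown model code %d", model);
    }
  }
  return List::create(_["loglik"] = ll, _["probs"] = probs,
                      _["p_choice"] = p_choice);
}
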