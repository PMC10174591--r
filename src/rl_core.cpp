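#include <Rcpp.h>
using namespace Rcpp;

// Forward pass of a condition-keyed reinforcement-learning agent over one
// interleaved session. All parameter vectors are length 4 (one entry per
// condition), fully resolved by the R layer: shared parameters are simply
// replicated, absent components are passed as neutral values (eps = 0,
// phi = 0).
//
// update_rule: 0 = one-arm RW (unchosen value is the complement),
//              1 = two-arm RW (only the chosen option's value is updated),
//              2 = Pearce-Hall hybrid (associability-scaled update, one-arm
//                  complement rule).
//
// Value states are initialised at 0.5 (the indifference level). Missing
// trials contribute no likelihood term and no learning update, but the
// forgetting decay (phi) is still applied to every condition's state at the
// end of every global trial: time passes for all four contingencies while
// any one of them is on screen.

static const double P_FLOOR = 1e-12;

// [[Rcpp::export]]
List rl_forward_cpp(IntegerVector cond, IntegerVector choice,
                    IntegerVector outcome, LogicalVector missing,
                    int update_rule,
                    NumericVector alpha, NumericVector beta,
                    NumericVector eps, NumericVector phi,
                    NumericVector omega, NumericVector kappa,
                    NumericVector a0,
                    bool simulate,
                    IntegerVector high_option,
                    double p_high, double p_low) {
  int n = cond.size();
  std::vector<double> v1(4, 0.5), v0(4, 0.5), assoc(4);
  for (int c = 0; c < 4; ++c) assoc[c] = a0[c];

  NumericVector p1(n);
  NumericVector ll(n);        // NA for missing trials
  IntegerVector ch(n), out(n);
  double total = 0.0;

  for (int t = 0; t < n; ++t) {
    int c = cond[t];
    double V1, V0;
    if (update_rule == 1) { V1 = v1[c]; V0 = v0[c]; }
    else                  { V1 = v1[c]; V0 = 1.0 - v1[c]; }

    double sm = 1.0 / (1.0 + std::exp(-beta[c] * (V1 - V0)));
    double p = (1.0 - eps[c]) * sm + eps[c] / 2.0;
    p1[t] = p;

    bool miss = missing[t];
    int a, o;
    if (simulate) {
      miss = missing[t];
      if (miss) {
        a = NA_INTEGER;
        o = 0;                       // no response earns nothing
      } else {
        a = (unif_rand() < p) ? 1 : 0;
        double pr = (a == high_option[t]) ? p_high : p_low;
        o = (unif_rand() < pr) ? 1 : 0;
      }
      ch[t] = a; out[t] = o;
    } else {
      a = choice[t]; o = outcome[t];
    }

    if (miss) {
      ll[t] = NA_REAL;
    } else {
      double pc = (a == 1) ? p : (1.0 - p);
      if (pc < P_FLOOR) pc = P_FLOOR;
      double l = std::log(pc);
      ll[t] = l;
      total += l;

      // learning update for the cued condition only
      double Vc = (a == 1) ? V1 : V0;
      double Vc_new;
      if (update_rule == 2) {
        double delta = (double)o - Vc;
        Vc_new = Vc + kappa[c] * assoc[c] * delta;
        assoc[c] = (1.0 - omega[c]) * assoc[c] + omega[c] * std::fabs(delta);
      } else {
        Vc_new = Vc + alpha[c] * ((double)o - Vc);
      }
      if (update_rule == 1) {
        if (a == 1) v1[c] = Vc_new; else v0[c] = Vc_new;
      } else {
        v1[c] = (a == 1) ? Vc_new : 1.0 - Vc_new;
      }
    }

    // forgetting decays every condition's state toward 0.5
    for (int d = 0; d < 4; ++d) {
      if (phi[d] > 0.0) {
        v1[d] += phi[d] * (0.5 - v1[d]);
        if (update_rule == 1) v0[d] += phi[d] * (0.5 - v0[d]);
      }
    }
  }

  List res = List::create(_["p1"] = p1, _["ll"] = ll, _["total"] = total);
  if (simulate) { res["choice"] = ch; res["outcome"] = out; }
  return res;
}
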