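#include <Rcpp.h>
using namespace Rcpp;

// Euler first-passage sampler for the superimposed diffusion.
//
// Each trial starts at start[i] and evolves as
//   X(t + dt) = X(t) + mu[k] * dt + sigma * sqrt(dt) * Z,
// where mu[k] is the (trial-independent) total drift evaluated at
// t = (k + 1) * dt and Z is standard normal from R's RNG stream, so results
// are reproducible under set.seed(). Absorption at +boundary is a correct
// response, at -boundary an error; trials not absorbed within max_steps are
// flagged censored.
//
// [[Rcpp::export]]
List cpp_first_passage(NumericVector start, NumericVector mu,
                       double sigma, double dt, double boundary) {
  const int n = start.size();
  const int max_steps = mu.size();
  const double sd_step = sigma * std::sqrt(dt);

  NumericVector decision_time(n);
  IntegerVector correct(n);
  LogicalVector censored(n);

  for (int i = 0; i < n; ++i) {
    double x = start[i];
    bool done = false;
    for (int k = 0; k < max_steps; ++k) {
      x += mu[k] * dt + sd_step * norm_rand();
      if (x >= boundary || x <= -boundary) {
        decision_time[i] = (k + 1) * dt;
        correct[i] = (x >= boundary) ? 1 : 0;
        censored[i] = false;
        done = true;
        break;
      }
    }
    if (!done) {
      decision_time[i] = max_steps * dt;
      correct[i] = NA_INTEGER;
      censored[i] = true;
    }
  }
  return List::create(_["decision_time"] = decision_time,
                      _["correct"] = correct,
                      _["censored"] = censored);
}
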