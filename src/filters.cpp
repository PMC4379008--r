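#include <Rcpp.h>
using namespace Rcpp;

// First-order relaxation y' = (x - y)/tau, discretised exactly over each
// step: y <- y + (1 - exp(-dt/tau)) * (x - y). Asymmetric variant uses
// tau_on while the input exceeds the state (rising) and tau_off otherwise.

// [[Rcpp::export]]
NumericVector asym_filter_cpp(NumericVector x, double dt, double tau_on,
                              double tau_off, double init) {
  if (tau_on <= 0 || tau_off <= 0) stop("time constants must be positive");
  const int n = x.size();
  NumericVector y(n);
  const double a_on = 1.0 - std::exp(-dt / tau_on);
  const double a_off = 1.0 - std::exp(-dt / tau_off);
  double s = init;
  for (int i = 0; i < n; ++i) {
    s += (x[i] > s ? a_on : a_off) * (x[i] - s);
    y[i] = s;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector ema_cpp(NumericVector x, double dt, double tau, double init) {
  if (tau <= 0) stop("time constant must be positive");
  const int n = x.size();
  NumericVector y(n);
  const double a = 1.0 - std::exp(-dt / tau);
  double s = init;
  for (int i = 0; i < n; ++i) {
    s += a * (x[i] - s);
    y[i] = s;
  }
  return y;
}
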