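#include <Rcpp.h>
using namespace Rcpp;

// Exact-discretisation Ornstein-Uhlenbeck velocity process with Euler
// position accumulation.  Per velocity component:
//   v <- v * exp(-h/P) + sqrt((1 - exp(-2h/P)) * S^2/2) * N(0,1)
// which is the exact transition density of dv = -v/P dt + S/sqrt(P) dW
// (stationary per-component variance S^2/2), so the update is exact for any
// step h; only the position quadrature carries O(h) error.  Positions are
// recorded every `substeps` integration steps; velocities recorded are the
// instantaneous values at those same instants.
//
// RNG: R's generator via norm_rand(), cells in column order, two draws
// (x then y) per integration step, so results are reproducible under
// set.seed() and independent of vectorisation.
// [[Rcpp::export]]
List ou_integrate_cpp(NumericVector S, NumericVector P, int n_samples,
                      int substeps, double h, bool return_velocity) {
  const int n_cells = S.size();
  if (P.size() != n_cells) stop("S and P must have equal length");
  NumericMatrix x(n_samples + 1, n_cells), y(n_samples + 1, n_cells);
  NumericMatrix vx, vy;
  if (return_velocity) {
    vx = NumericMatrix(n_samples + 1, n_cells);
    vy = NumericMatrix(n_samples + 1, n_cells);
  }
  for (int c = 0; c < n_cells; ++c) {
    const double a  = std::exp(-h / P[c]);
    const double sv = S[c] / std::sqrt(2.0);           // per-component sd
    const double b  = sv * std::sqrt(1.0 - a * a);
    double vx_ = norm_rand() * sv;                     // stationary start
    double vy_ = norm_rand() * sv;
    double px = 0.0, py = 0.0;
    x(0, c) = 0.0; y(0, c) = 0.0;
    if (return_velocity) { vx(0, c) = vx_; vy(0, c) = vy_; }
    for (int s = 1; s <= n_samples; ++s) {
      for (int k = 0; k < substeps; ++k) {
        px += vx_ * h;
        py += vy_ * h;
        vx_ = vx_ * a + b * norm_rand();
        vy_ = vy_ * a + b * norm_rand();
      }
      x(s, c) = px; y(s, c) = py;
      if (return_velocity) { vx(s, c) = vx_; vy(s, c) = vy_; }
    }
  }
  if (return_velocity)
    return List::create(_["x"] = x, _["y"] = y, _["vx"] = vx, _["vy"] = vy);
  return List::create(_["x"] = x, _["y"] = y);
}
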