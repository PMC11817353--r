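#include <Rcpp.h>
using namespace Rcpp;

// SMO solver for a binary C-SVC given the kernel matrix.
// Working-set selection is the classic maximal-violating-pair rule on the
// gradient of the dual; convergence when the KKT gap drops below tol.
// Deterministic: no randomness, ties resolved by lowest index.
//
// K   : n x n kernel matrix of the training points
// y   : labels in {-1, +1}
// C   : box constraint
// tol : KKT stopping tolerance (on max violation gap)
// Returns alpha (length n) and rho (bias term; decision is
// sum_i alpha_i y_i K(x_i, x) - rho).
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, IntegerVector y, double C, double tol,
               int max_iter) {
  const int n = K.nrow();
  std::vector<double> alpha(n, 0.0);
  // gradient of dual objective: G_i = sum_j alpha_j y_i y_j K_ij - 1
  std::vector<double> G(n, -1.0);

  int iter = 0;
  while (iter < max_iter) {
    // select i in I_up maximizing -y_i G_i, j in I_low minimizing -y_j G_j
    int i = -1, j = -1;
    double gmax = -1e300, gmin = 1e300;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      bool low = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > gmax) { gmax = v; i = t; }
      if (low && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) break;

    // solve the two-variable subproblem analytically
    double Kii = K(i, i), Kjj = K(j, j), Kij = K(i, j);
    double eta = Kii + Kjj - 2.0 * Kij;
    if (eta <= 0) eta = 1e-12;
    double ai_old = alpha[i], aj_old = alpha[j];
    double delta = (-y[i] * G[i] + y[j] * G[j]) / eta;
    // move along the constraint y_i a_i + y_j a_j = const
    double ai = ai_old + y[i] * delta;
    double aj = aj_old - y[j] * delta;
    // clip to the box
    double sum_i = y[i] * ai_old + y[j] * aj_old;
    if (ai < 0) ai = 0;
    if (ai > C) ai = C;
    aj = y[j] * (sum_i - y[i] * ai);
    if (aj < 0) { aj = 0; ai = y[i] * (sum_i - y[j] * aj); }
    if (aj > C) { aj = C; ai = y[i] * (sum_i - y[j] * aj); }
    if (ai < 0) ai = 0; else if (ai > C) ai = C;

    double dai = ai - ai_old, daj = aj - aj_old;
    if (std::abs(dai) < 1e-15 && std::abs(daj) < 1e-15) break;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * dai * K(i, t) + y[j] * daj * K(j, t));
    alpha[i] = ai;
    alpha[j] = aj;
    ++iter;
  }

  // rho from free support vectors (average), else midpoint of bounds
  double rho;
  {
    double sum = 0; int nfree = 0;
    double ub = 1e300, lb = -1e300;
    for (int t = 0; t < n; ++t) {
      double yg = y[t] * G[t];
      bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      bool low = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
      if (alpha[t] > 0 && alpha[t] < C) { sum += yg; ++nfree; }
      else {
        if (up && yg < ub) ub = yg;
        if (low && yg > lb) lb = yg;
      }
    }
    if (nfree > 0) rho = sum / nfree;
    else rho = (ub + lb) / 2.0;
  }
  return List::create(_["alpha"] = alpha, _["rho"] = rho,
                      _["iterations"] = iter);
}
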