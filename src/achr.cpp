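// Artificial-centering hit-and-run chain over the flux polytope
//   { v : S v = 0, lb <= v <= ub }.
// Directions are differences of feasible points, so they stay in the null
// space of S up to floating-point drift; bound constraints delimit each
// chord exactly.  Uses R's RNG so set.seed() makes runs bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".achr_chain_cpp")]]
Rcpp::List achr_chain_cpp(const arma::mat& warmup,   // n_rxn x n_pts, feasible
                          const arma::vec& lb, const arma::vec& ub,
                          int n_samples, int thinning, int max_failures) {
  const int n = warmup.n_rows;
  const int npts = warmup.n_cols;
  const double DTOL = 1e-11;   // direction component considered zero
  if (npts < 1) Rcpp::stop("need at least one warmup point");

  Rcpp::RNGScope rng;

  vec center = mean(warmup, 1);
  double nseen = (double) npts;
  vec x = center;                       // start the chain at the center
  mat out(n_samples, n);
  int kept = 0, failures = 0;
  long step = 0;

  while (kept < n_samples) {
    // direction through the running center and a random warmup point
    int idx = (int) std::floor(R::unif_rand() * npts);
    if (idx >= npts) idx = npts - 1;
    vec u = warmup.col(idx) - center;
    double nrm = norm(u);
    if (nrm < 1e-12) { if (++failures > max_failures) break; continue; }
    u /= nrm;

    // feasible chord [amin, amax] from the box bounds
    double amin = -std::numeric_limits<double>::infinity();
    double amax =  std::numeric_limits<double>::infinity();
    for (int j = 0; j < n; ++j) {
      double uj = u[j];
      if (std::abs(uj) < DTOL) continue;
      double a1 = (lb[j] - x[j]) / uj;
      double a2 = (ub[j] - x[j]) / uj;
      if (uj > 0) { if (a1 > amin) amin = a1; if (a2 < amax) amax = a2; }
      else        { if (a2 > amin) amin = a2; if (a1 < amax) amax = a1; }
    }
    if (!std::isfinite(amin) || !std::isfinite(amax) || amax - amin < 1e-12) {
      // degenerate or numerically empty chord: retry with a new direction
      if (++failures > max_failures) break;
      continue;
    }
    double alpha = amin + (amax - amin) * R::unif_rand();
    x += alpha * u;
    // clip floating-point dust back into the box
    for (int j = 0; j < n; ++j) {
      if (x[j] < lb[j]) x[j] = lb[j];
      if (x[j] > ub[j]) x[j] = ub[j];
    }
    // incremental centering over every state visited
    nseen += 1.0;
    center += (x - center) / nseen;

    if (++step % thinning == 0) {
      out.row(kept) = x.t();
      ++kept;
    }
  }
  if (kept < n_samples)
    Rcpp::stop("ACHR chain stalled after %d degenerate directions (kept %d of %d)",
               max_failures, kept, n_samples);
  return Rcpp::List::create(
    Rcpp::Named("samples") = Rcpp::wrap(out),
    Rcpp::Named("failures") = failures,
    Rcpp::Named("steps") = (double) step);
}
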