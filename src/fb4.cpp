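#include <Rcpp.h>
using namespace Rcpp;

// Forward-backward for the 4-state grandparental-origin HMM of one child.
//
// Hidden state at marker j is the ordered pair (u, v): u = which of the
// sire's two haplotypes the paternal gamete carries, v likewise for the
// dam. States are indexed s = 2*(u-1) + v - 1 in {0,1,2,3}. The two
// gametes recombine independently, so the joint transition between
// adjacent markers is the Kronecker product of two 2-state chains with
// switch probability theta_j (Haldane recombination fraction for the gap).
// The prior at the first marker is uniform (1/4).
//
// emiss: 4 x M matrix of emission probabilities P(obs_j | state); columns
// for unobserved markers should be all ones. Columns must not be all zero
// (zero-likelihood conflicts are resolved by the caller).
// theta: length M-1 vector of recombination fractions.
//
// Returns posterior state probabilities (4 x M) and the log-likelihood.
// [[Rcpp::export(name = ".fb4")]]
List fb4(NumericMatrix emiss, NumericVector theta) {
  const int m = emiss.ncol();
  if (emiss.nrow() != 4) stop("emiss must have 4 rows");
  if (theta.size() != m - 1) stop("theta must have length ncol(emiss) - 1");

  NumericMatrix fwd(4, m), bwd(4, m), post(4, m);
  NumericVector scale(m);
  double loglik = 0.0;

  // forward, scaled to sum 1 per marker
  double s0 = 0.0;
  for (int s = 0; s < 4; ++s) { fwd(s, 0) = 0.25 * emiss(s, 0); s0 += fwd(s, 0); }
  if (s0 <= 0.0) stop("zero likelihood at marker 1");
  for (int s = 0; s < 4; ++s) fwd(s, 0) /= s0;
  scale[0] = s0;
  loglik = std::log(s0);

  for (int j = 1; j < m; ++j) {
    const double t = theta[j - 1], r = 1.0 - t;
    // per-gamete marginal transition applied as Tu (x) Tv
    const double a0 = fwd(0, j - 1), a1 = fwd(1, j - 1),
                 a2 = fwd(2, j - 1), a3 = fwd(3, j - 1);
    double p[4];
    p[0] = r * r * a0 + r * t * a1 + t * r * a2 + t * t * a3;
    p[1] = r * t * a0 + r * r * a1 + t * t * a2 + t * r * a3;
    p[2] = t * r * a0 + t * t * a1 + r * r * a2 + r * t * a3;
    p[3] = t * t * a0 + t * r * a1 + r * t * a2 + r * r * a3;
    double sj = 0.0;
    for (int s = 0; s < 4; ++s) { fwd(s, j) = p[s] * emiss(s, j); sj += fwd(s, j); }
    if (sj <= 0.0) stop("zero likelihood at marker %d", j + 1);
    for (int s = 0; s < 4; ++s) fwd(s, j) /= sj;
    scale[j] = sj;
    loglik += std::log(sj);
  }

  // backward, with the same scaling
  for (int s = 0; s < 4; ++s) bwd(s, m - 1) = 1.0;
  for (int j = m - 2; j >= 0; --j) {
    const double t = theta[j], r = 1.0 - t;
    double b[4];
    for (int s = 0; s < 4; ++s) b[s] = bwd(s, j + 1) * emiss(s, j + 1);
    bwd(0, j) = (r * r * b[0] + r * t * b[1] + t * r * b[2] + t * t * b[3]) / scale[j + 1];
    bwd(1, j) = (r * t * b[0] + r * r * b[1] + t * t * b[2] + t * r * b[3]) / scale[j + 1];
    bwd(2, j) = (t * r * b[0] + t * t * b[1] + r * r * b[2] + r * t * b[3]) / scale[j + 1];
    bwd(3, j) = (t * t * b[0] + t * r * b[1] + r * t * b[2] + r * r * b[3]) / scale[j + 1];
  }

  for (int j = 0; j < m; ++j) {
    double sj = 0.0;
    for (int s = 0; s < 4; ++s) { post(s, j) = fwd(s, j) * bwd(s, j); sj += post(s, j); }
    for (int s = 0; s < 4; ++s) post(s, j) /= sj;
  }
  return List::create(_["posterior"] = post, _["loglik"] = loglik);
}
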