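#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Pseudo-likelihood machinery for the pairwise maximum-entropy (Ising) model.
//
// The conditional distribution of spin i given the rest has mean
//   <s_i | s_{/i}> = tanh(beta * (h_i + sum_{j != i} J_ij s_j)),
// so the model-side 1-point moment is the time average of that tanh and the
// 2-point moment is the time average of s_j(t) * tanh(beta * f_i(t)),
// symmetrized over (i|j) and (j|i) so the coupling update stays symmetric.

static void pseudo_moments_impl(const arma::mat& S, const arma::vec& h,
                                const arma::mat& J, double beta,
                                arma::vec& m1, arma::mat& m2) {
  const double tmax = (double) S.n_cols;
  arma::mat F = J * S;           // N x T local fields (J has zero diagonal)
  F.each_col() += h;
  arma::mat TH = arma::tanh(beta * F);
  m1 = arma::mean(TH, 1);
  m2 = (TH * S.t() + S * TH.t()) / (2.0 * tmax);
  m2.diag().ones();              // convention: diagonal fixed at <s_i^2> = 1
}

// [[Rcpp::export]]
List pseudo_moments_cpp(const arma::mat& S, const arma::vec& h,
                        const arma::mat& J, double beta) {
  arma::vec m1;
  arma::mat m2;
  pseudo_moments_impl(S, h, J, beta, m1, m2);
  return List::create(_["m1"] = m1, _["m2"] = m2);
}

// Gradient-ascent pseudo-likelihood fit of (h, J) at beta = 1:
//   h_i  += eta * (<s_i>_emp    - <s_i>_model)
//   J_ij += eta * (<s_i s_j>_emp - <s_i s_j>_model)
// Convergence is declared on the maximum absolute moment mismatch.
// [[Rcpp::export]]
List fit_archetype_cpp(const arma::mat& S, double eta, int max_iter,
                       double tol, arma::vec h0, arma::mat J0) {
  const int N = S.n_rows;
  const double tmax = (double) S.n_cols;
  arma::vec me1 = arma::mean(S, 1);
  arma::mat ME2 = (S * S.t()) / tmax;
  ME2.diag().ones();

  arma::vec h = h0;
  arma::mat J = J0;
  arma::vec m1;
  arma::mat m2;
  double mismatch = NA_REAL, prev = R_PosInf;
  int grew = 0, iter = 0;
  bool converged = false;
  for (iter = 1; iter <= max_iter; ++iter) {
    pseudo_moments_impl(S, h, J, 1.0, m1, m2);
    arma::vec g1 = me1 - m1;
    arma::mat G2 = ME2 - m2;
    G2.diag().zeros();
    mismatch = std::max(arma::abs(g1).max(), arma::abs(G2).max());
    if (mismatch <= tol) { converged = true; break; }
    grew = (mismatch > prev) ? grew + 1 : 0;
    if (grew >= 100)
      stop("pseudo-likelihood ascent diverging; use a smaller learning rate");
    prev = mismatch;
    h += eta * g1;
    J += eta * G2;
  }
  return List::create(_["h"] = h, _["J"] = J,
                      _["iterations"] = std::min(iter, max_iter),
                      _["mismatch"] = mismatch, _["converged"] = converged);
}

// Single-parameter personalization: fit the inverse temperature beta of a
// frozen archetype (h, J) by the energy-matching fixed-point iteration
//   beta <- beta - eta * (<H>_emp - <H>_model),
// where <H>_model is assembled from the pseudo-moments at the current beta
// with pairs counted once. The step size is damped adaptively: it shrinks
// when the energy mismatch grows and relaxes back while it decreases, which
// keeps the plain gradient rule stable for any curvature of <H>(beta).
// allow_negative lifts the positivity constraint on beta: a model whose
// architecture is anti-matched to the data (e.g. under a parcel-label
// permutation) can have its energy-matching fixed point at beta <= 0, and
// the permutation null distribution must be allowed to reach it.
// [[Rcpp::export]]
List fit_beta_cpp(const arma::mat& S, const arma::vec& h, const arma::mat& J,
                  double eta, int max_iter, double tol, double beta0,
                  bool allow_negative = false) {
  const double tmax = (double) S.n_cols;
  const int N = S.n_rows;
  arma::mat F = J * S;
  F.each_col() += h;

  // empirical energy: E_t = -1/2 s'Js - h's = -1/2 dot(s, F) - 1/2 dot(h, s)
  double Hemp = 0.0;
  for (arma::uword t = 0; t < S.n_cols; ++t) {
    double sf = arma::dot(S.col(t), F.col(t));
    double hs = arma::dot(h, S.col(t));
    Hemp += -0.5 * sf - 0.5 * hs;
  }
  Hemp /= tmax;

  // coupling part of the local fields: F0 = J * S (J symmetric, zero diag).
  // The pair term of <H> collapses without per-iteration matrix products:
  //   sum_{ij} J_ij <s_j tanh(beta f_i)> = sum_t sum_i TH_it (J S)_it,
  // and symmetrizing over (i|j), (j|i) leaves it unchanged.
  arma::mat F0 = F;
  F0.each_col() -= h;

  double beta = beta0, g = NA_REAL, prev = R_PosInf, eta_t = eta;
  int iter = 0;
  bool converged = false;
  std::vector<double> traj;
  traj.reserve(64);
  for (iter = 1; iter <= max_iter; ++iter) {
    arma::mat TH = arma::tanh(beta * F);
    arma::vec m1 = arma::mean(TH, 1);
    double Hmod = -arma::dot(h, m1) - 0.5 * arma::accu(TH % F0) / tmax;
    g = Hemp - Hmod;
    if (std::fabs(g) <= tol) { converged = true; break; }
    if (std::fabs(g) > prev) eta_t *= 0.5; else eta_t = std::min(eta_t * 1.25, 1e6 * eta);
    prev = std::fabs(g);
    double step = eta_t * g;
    double bnew = beta - step;
    if (!allow_negative) {
      while (bnew <= 0.0 && std::fabs(step) > 1e-300) { step *= 0.5; bnew = beta - step; }
      if (bnew <= 0.0)
        stop("temperature fit drove beta to a non-positive value");
    }
    beta = bnew;
    traj.push_back(beta);
  }
  (void) N;
  return List::create(_["beta"] = beta,
                      _["iterations"] = std::min(iter, max_iter),
                      _["mismatch"] = std::fabs(g), _["converged"] = converged,
                      _["trajectory"] = NumericVector(traj.begin(), traj.end()),
                      _["empirical_energy"] = Hemp);
}
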