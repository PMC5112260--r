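#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Online GMLVQ training loop.
//
// X: n x m z-scored samples; y: class index (1-based) per sample;
// W0: L x m initial prototypes with classes wcls (1-based);
// Omega0: m x m with Lambda = Omega' Omega (unit trace);
// order: n x epochs matrix of 1-based presentation orders;
// update_omega: when false the metric stays fixed (prototype-only fit).
//
// Per sample the winning correct (w+) and incorrect (w-) prototypes are
// moved along the steepest-descent direction of mu = (d+ - d-)/(d+ + d-),
// Omega follows its gradient, and Lambda is trace-normalized after every
// step. Learning rates decay linearly to decay_to times their initial
// value over the epochs. Returns prototypes, Omega and the mean cost per
// epoch.
// [[Rcpp::export]]
List gmlvq_train_cpp(const arma::mat& X, const arma::ivec& y,
                     const arma::mat& W0, const arma::ivec& wcls,
                     const arma::mat& Omega0,
                     double lr_w, double lr_om, int epochs, double decay_to,
                     const arma::imat& order, bool update_omega) {
  const arma::uword n = X.n_rows;
  const arma::uword L = W0.n_rows;
  arma::mat W = W0;
  arma::mat Omega = Omega0;
  arma::mat Lambda = Omega.t() * Omega;
  arma::vec cost(epochs, arma::fill::zeros);

  for (int e = 0; e < epochs; ++e) {
    double f = (epochs > 1) ? (1.0 - (1.0 - decay_to) * e / (epochs - 1.0))
                            : 1.0;
    double aw = lr_w * f;
    double ao = lr_om * f;

    for (arma::uword t = 0; t < n; ++t) {
      arma::uword i = order(t, e) - 1;
      arma::rowvec x = X.row(i);
      int cls = y(i);

      // winning correct / incorrect prototypes
      double dp = arma::datum::inf, dm = arma::datum::inf;
      arma::uword qp = 0, qm = 0;
      for (arma::uword q = 0; q < L; ++q) {
        arma::rowvec diff = x - W.row(q);
        double d = arma::as_scalar(diff * Lambda * diff.t());
        if (wcls(q) == cls) {
          if (d < dp) { dp = d; qp = q; }
        } else {
          if (d < dm) { dm = d; qm = q; }
        }
      }
      double s = dp + dm;
      if (s <= 0.0) continue;  // both distances zero: flat cost, skip
      double gp = 2.0 * dm / (s * s);
      double gm = -2.0 * dp / (s * s);

      arma::rowvec ep = x - W.row(qp);
      arma::rowvec em = x - W.row(qm);

      // prototype updates (gradient of mu wrt w is -2 g Lambda (x - w))
      W.row(qp) += aw * 2.0 * gp * (ep * Lambda);
      W.row(qm) += aw * 2.0 * gm * (em * Lambda);

      if (update_omega) {
        arma::mat G = 2.0 * Omega *
          (gp * (ep.t() * ep) + gm * (em.t() * em));
        Omega -= ao * G;
        Lambda = Omega.t() * Omega;
        double tr = arma::trace(Lambda);
        if (tr > 0.0) {
          Omega /= std::sqrt(tr);
          Lambda /= tr;
        }
      }
    }

    // epoch cost: mean relative-distance cost over all samples
    double c = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      arma::rowvec x = X.row(i);
      double dp = arma::datum::inf, dm = arma::datum::inf;
      for (arma::uword q = 0; q < L; ++q) {
        arma::rowvec diff = x - W.row(q);
        double d = arma::as_scalar(diff * Lambda * diff.t());
        if (wcls(q) == y(i)) { if (d < dp) dp = d; }
        else { if (d < dm) dm = d; }
      }
      double s = dp + dm;
      c += (s > 0.0) ? (dp - dm) / s : 0.0;
    }
    cost(e) = c / n;
  }

  return List::create(Named("W") = W, Named("Omega") = Omega,
                      Named("cost") = cost);
}
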