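#include <Rcpp.h>
using namespace Rcpp;

// Cellwise variational expectations of the count log-density and their
// derivatives. U = E_q[log mu], t = Var_q[log mu]/2; the NB term uses the
// Jensen bound E_q[log(phi + mu)] <= log(phi + E_q[mu]) with E_q[mu] =
// exp(U + t). lgx1 = lgamma(x + 1), precomputed once per fit.

// [[Rcpp::export]]
List count_terms_nb_cpp(NumericMatrix x, NumericMatrix U, NumericMatrix t,
                        NumericVector phi, NumericMatrix lgx1, bool grad) {
  const int n = x.nrow(), p = x.ncol();
  NumericMatrix L(n, p), dU, dt, dphi;
  if (grad) {
    dU = NumericMatrix(n, p);
    dt = NumericMatrix(n, p);
    dphi = NumericMatrix(n, p);
  }
  // memo for lgamma(x + phi) / digamma(x + phi) at small integer counts,
  // reset per taxon (phi is taxon-specific); counts repeat heavily.
  const int CMAX = 256;
  std::vector<double> lgmemo(CMAX), dgmemo(CMAX);
  for (int j = 0; j < p; ++j) {
    const double ph = phi[j];
    const double lph = std::log(ph);
    const double lgph = R::lgammafn(ph);
    const double plp = ph * lph;
    const double dgph = grad ? R::digamma(ph) : 0.0;
    std::fill(lgmemo.begin(), lgmemo.end(), NA_REAL);
    std::fill(dgmemo.begin(), dgmemo.end(), NA_REAL);
    for (int i = 0; i < n; ++i) {
      const double xij = x(i, j);
      const double u = U(i, j);
      const double b = u + t(i, j);
      const double d = lph - b;
      // lse = log(phi + exp(b)) computed stably
      const double lse = d > 0 ? lph + std::log1p(std::exp(-d))
                               : b + std::log1p(std::exp(d));
      if (xij == 0.0) {  // gamma-function terms cancel at x = 0
        L(i, j) = plp - ph * lse;
        if (grad) {
          const double g = ph * std::exp(b - lse);
          dU(i, j) = -g;
          dt(i, j) = -g;
          dphi(i, j) = lph + 1.0 - lse - ph * std::exp(-lse);
        }
        continue;
      }
      const double xp = xij + ph;
      double lgxp, dgxp = 0.0;
      const int xi = (int)xij;
      if (xij == (double)xi && xi < CMAX) {
        if (ISNA(lgmemo[xi])) lgmemo[xi] = R::lgammafn(xp);
        lgxp = lgmemo[xi];
        if (grad) {
          if (ISNA(dgmemo[xi])) dgmemo[xi] = R::digamma(xp);
          dgxp = dgmemo[xi];
        }
      } else {
        lgxp = R::lgammafn(xp);
        if (grad) dgxp = R::digamma(xp);
      }
      L(i, j) = lgxp - lgph - lgx1(i, j) + plp + xij * u - xp * lse;
      if (grad) {
        const double g = xp * std::exp(b - lse);
        dU(i, j) = xij - g;
        dt(i, j) = -g;
        dphi(i, j) = dgxp - dgph + lph + 1.0 - lse - xp * std::exp(-lse);
      }
    }
  }
  if (grad) {
    return List::create(_["L"] = L, _["dU"] = dU, _["dt"] = dt,
                        _["dphi"] = dphi);
  }
  return List::create(_["L"] = L);
}

// [[Rcpp::export]]
List count_terms_pois_cpp(NumericMatrix x, NumericMatrix U, NumericMatrix t,
                          NumericMatrix lgx1, bool grad) {
  const int n = x.nrow(), p = x.ncol();
  NumericMatrix L(n, p), dU, dt;
  if (grad) {
    dU = NumericMatrix(n, p);
    dt = NumericMatrix(n, p);
  }
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) {
      const double xij = x(i, j);
      const double u = U(i, j);
      double b = u + t(i, j);
      if (b > 700.0) b = 700.0;
      const double E = std::exp(b);
      L(i, j) = xij * u - E - lgx1(i, j);
      if (grad) {
        dU(i, j) = xij - E;
        dt(i, j) = -E;
      }
    }
  }
  if (grad) return List::create(_["L"] = L, _["dU"] = dU, _["dt"] = dt);
  return List::create(_["L"] = L);
}
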