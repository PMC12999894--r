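// Spectral-domain ADMM solver for variational mode decomposition.
// The signal is mirror-extended to twice its length, transformed once,
// and the K modes are updated by Wiener-style narrowband filtering on
// the analytic (one-sided) spectrum; center frequencies follow the
// spectral centroid of each mode. All iteration work happens on the
// non-negative half of the spectrum (the negative half of every mode is
// zero throughout and is reinstated by Hermitian symmetry at the end).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::cx_vec ifftshift_cx(const arma::cx_vec& v) {
  const arma::uword n = v.n_elem, h = n / 2;
  arma::cx_vec out(n);
  out.head(h) = v.tail(h);
  out.tail(n - h) = v.head(n - h);
  return out;
}

// [[Rcpp::export(name = ".vmd_admm")]]
List vmd_admm(const arma::vec& x, int K, double alpha, double tau,
              double tol, int max_iter, const arma::vec& omega_init) {
  const int T = x.n_elem;
  const int half = T / 2;

  // mirror extension: [flip(first half), x, flip(second half)]
  arma::vec xm(2 * T);
  xm.head(half) = arma::flipud(x.head(half));
  xm.subvec(half, half + T - 1) = x;
  xm.tail(T - half) = arma::flipud(x.tail(T - half));

  const int Tm = xm.n_elem;           // even
  const int mid = Tm / 2;             // index of DC after fftshift
  const int hp = Tm - mid;            // non-negative frequency bins

  // non-negative frequency axis (cycles/sample)
  arma::vec freqs(hp);
  for (int i = 0; i < hp; ++i) freqs[i] = (double)i / Tm;

  arma::cx_vec xf = arma::fft(arma::cx_vec(xm, arma::zeros(Tm)));
  arma::cx_vec f_hat_plus = xf.head(hp);    // bins 0 .. Tm/2-1

  arma::cx_mat u_hat(hp, K, arma::fill::zeros);
  arma::vec omega = omega_init;       // normalized, in [0, 0.5]
  arma::cx_vec lambda_hat(hp, arma::fill::zeros);
  arma::cx_vec total = arma::sum(u_hat, 1);

  std::vector<double> resid_hist;
  bool converged = false;
  int n_iter = 0;

  const std::complex<double>* fh = f_hat_plus.memptr();
  for (int it = 0; it < max_iter; ++it) {
    double udiff = 0.0;
    for (int k = 0; k < K; ++k) {
      std::complex<double>* uk = u_hat.colptr(k);
      std::complex<double>* tot = total.memptr();
      const std::complex<double>* lam = lambda_hat.memptr();
      const double* fr = freqs.memptr();
      const double om = omega[k];
      double wsum = 0.0, psum = 0.0, num = 0.0, den = 0.0;
      for (int i = 0; i < hp; ++i) {
        const std::complex<double> old = uk[i];
        const std::complex<double> others = tot[i] - old;
        const double df = fr[i] - om;
        const std::complex<double> unew =
            (fh[i] - others + 0.5 * lam[i]) / (1.0 + 2.0 * alpha * df * df);
        uk[i] = unew;
        tot[i] = others + unew;
        const double p = std::norm(unew);
        psum += p;
        wsum += fr[i] * p;
        num += std::norm(unew - old);
        den += std::norm(old);
      }
      if (psum > 0.0) omega[k] = wsum / psum;
      if (num > 0.0) udiff += num / std::max(den, 1e-30);
    }
    if (tau > 0.0) lambda_hat += tau * (total - f_hat_plus);

    resid_hist.push_back(arma::accu(arma::square(arma::abs(
        f_hat_plus - total))));

    n_iter = it + 1;
    if (udiff < tol) { converged = true; break; }
  }

  // sort modes by ascending center frequency
  arma::uvec ord = arma::sort_index(omega);

  arma::mat modes(K, T);
  for (int k = 0; k < K; ++k) {
    const arma::cx_vec& uk = u_hat.col(ord[k]);
    // rebuild the fftshift-layout full spectrum: negative half by
    // Hermitian symmetry of the positive half
    arma::cx_vec full(Tm, arma::fill::zeros);
    full.subvec(mid, Tm - 1) = uk;
    for (int i = 1; i < mid; ++i) full[i] = std::conj(uk[mid - i]);
    full[0] = std::conj(full[Tm - 1]);
    arma::cx_vec ut = arma::ifft(ifftshift_cx(full));
    modes.row(k) = arma::real(ut.subvec(half, half + T - 1)).t();
  }

  arma::vec omega_sorted = omega(ord);
  arma::vec recon = arma::sum(modes, 0).t();

  return List::create(
      _["modes"] = modes,
      _["omega"] = omega_sorted,
      _["n_iter"] = n_iter,
      _["converged"] = converged,
      _["residual"] = x - recon,
      _["residual_energy"] = arma::vec(resid_hist));
}
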