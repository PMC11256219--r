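#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;

typedef std::complex<double> cplx;

// Specular reflectivity of a slab stack by the Abeles transfer-matrix
// recursion. Slabs are ordered fronting -> backing; the first and last
// entries are the semi-infinite media (their thicknesses are ignored).
// sigma[j] is the Gaussian width of the interface between slab j and
// slab j+1 (Nevot-Croce damping of the Fresnel coefficient); pass zeros
// for a microsliced (erf-discretised) profile.
//
// Media are non-absorbing, so each normal wavevector is either purely real
// (propagating) or purely imaginary (evanescent); the hot loop exploits
// this to avoid complex sqrt/exp.
//
// q     : momentum transfer [1/Angstrom], measured in the fronting medium
// d     : thicknesses [Angstrom]
// rho   : scattering length densities [1e-6 / Angstrom^2]
// sigma : interfacial widths [Angstrom], length >= n-1
// [[Rcpp::export]]
NumericVector abeles_cpp(NumericVector q, NumericVector d, NumericVector rho,
                         NumericVector sigma) {
  const int nq = q.size();
  const int n = d.size();
  if (rho.size() != n)
    stop("thickness and sld vectors must have equal length");
  if (sigma.size() < n - 1)
    stop("need a roughness for every interface");
  if (n < 2)
    stop("at least two slabs (fronting and backing) are required");

  NumericVector out(nq);
  const double four_pi = 4.0 * M_PI;

  // 4*pi*(rho_j - rho_0), precomputed once
  std::vector<double> drho(n);
  for (int j = 0; j < n; ++j) drho[j] = four_pi * (rho[j] - rho[0]) * 1e-6;

  std::vector<cplx> k(n);

  for (int iq = 0; iq < nq; ++iq) {
    const double k0 = 0.5 * q[iq];
    const double k0sq = k0 * k0;

    for (int j = 0; j < n; ++j) {
      const double arg = k0sq - drho[j];
      if (arg >= 0.0)
        k[j] = cplx(std::sqrt(arg), 0.0);
      else
        k[j] = cplx(0.0, std::sqrt(-arg));
    }

    cplx M00(1.0, 0.0), M01(0.0, 0.0), M10(0.0, 0.0), M11(1.0, 0.0);

    for (int j = 0; j < n - 1; ++j) {
      const cplx denom = k[j] + k[j + 1];
      cplx rj;
      if (denom.real() == 0.0 && denom.imag() == 0.0) {
        rj = cplx(0.0, 0.0);
      } else {
        rj = (k[j] - k[j + 1]) / denom;
        if (sigma[j] > 0.0)
          rj *= std::exp(-2.0 * k[j] * k[j + 1] * sigma[j] * sigma[j]);
      }

      // exp(+i k_j d_j) and exp(-i k_j d_j) without complex exp:
      // k_j is purely real (oscillatory) or purely imaginary (evanescent)
      cplx eb(1.0, 0.0), emb(1.0, 0.0);
      if (j > 0) {
        if (k[j].imag() == 0.0) {
          const double ph = k[j].real() * d[j];
          const double c = std::cos(ph), s = std::sin(ph);
          eb = cplx(c, s);
          emb = cplx(c, -s);
        } else {
          const double e = std::exp(-k[j].imag() * d[j]);
          eb = cplx(e, 0.0);
          emb = cplx(1.0 / e, 0.0);
        }
      }

      // layer characteristic matrix [[e^b, r e^b], [r e^-b, e^-b]]
      const cplx A00 = eb, A01 = rj * eb, A10 = rj * emb, A11 = emb;
      const cplx N00 = M00 * A00 + M01 * A10;
      const cplx N01 = M00 * A01 + M01 * A11;
      const cplx N10 = M10 * A00 + M11 * A10;
      const cplx N11 = M10 * A01 + M11 * A11;
      M00 = N00; M01 = N01; M10 = N10; M11 = N11;

      // renormalise to avoid overflow in evanescent regions of deep stacks
      if (std::fabs(M00.real()) + std::fabs(M00.imag()) > 1e100) {
        const double m = std::abs(M00);
        M00 /= m; M01 /= m; M10 /= m; M11 /= m;
      }
    }

    const cplx r = M10 / M00;
    out[iq] = std::norm(r);
  }
  return out;
}

// Deviation-bounded merging of consecutive thin slabs: greedily extends a
// run while every member SLD stays within `tol` of the running
// thickness-weighted mean, then emits one uniform slab with that mean.
// Exact on plateaus; error O(tol) on gentle gradients.
// [[Rcpp::export]]
List merge_slices_cpp(NumericVector d, NumericVector rho, double tol) {
  const int n = d.size();
  std::vector<double> md, mrho;
  md.reserve(n); mrho.reserve(n);
  int i = 0;
  while (i < n) {
    double td = d[i];
    double sum = rho[i] * d[i];
    double lo = rho[i], hi = rho[i];
    int j = i + 1;
    while (j < n) {
      const double nlo = std::min(lo, rho[j]);
      const double nhi = std::max(hi, rho[j]);
      if (nhi - nlo > 2.0 * tol) break;
      lo = nlo; hi = nhi;
      td += d[j];
      sum += rho[j] * d[j];
      ++j;
    }
    md.push_back(td);
    mrho.push_back(sum / td);
    i = j;
  }
  return List::create(Named("thickness") = wrap(md),
                      Named("sld") = wrap(mrho));
}
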