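// Extended phase graph (EPG) simulation of an inversion-prepared FISP
// acquisition with per-TR flip angle and repetition time.
//
// Configuration-state bookkeeping follows the usual (F+, F-, Z) triple
// with F-[k] storing conj(F(-k)). One unit of gradient dephasing is
// applied per TR (unbalanced FISP gradient, no RF spoiling); RF pulses
// have constant phase (rotation about a fixed transverse axis). The
// recorded sample is F+[0] at the echo time after each pulse.

#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;
typedef std::complex<double> cplx;

namespace {

struct EPGState {
  std::vector<cplx> Fp, Fm, Z;
  int kmax;
  explicit EPGState(int kmax_) : Fp(kmax_ + 1), Fm(kmax_ + 1), Z(kmax_ + 1),
                                 kmax(kmax_) {
    Z[0] = cplx(1.0, 0.0);
  }
  void relax(double dt, double T1, double T2) {
    const double e1 = std::exp(-dt / T1), e2 = std::exp(-dt / T2);
    for (int k = 0; k <= kmax; ++k) {
      Fp[k] *= e2;
      Fm[k] *= e2;
      Z[k] *= e1;
    }
    Z[0] += 1.0 - e1;  // recovery toward M0 = 1
  }
  void rf(double alpha) {  // rotation about a fixed axis, phase 0
    const double ca2 = std::cos(alpha / 2.0), sa2 = std::sin(alpha / 2.0);
    const double c2 = ca2 * ca2, s2 = sa2 * sa2;
    const double sa = std::sin(alpha), ca = std::cos(alpha);
    // mixing coefficients are real (c2, s2, ca) or purely imaginary
    // (-i sa, +i sa, -+ i sa / 2): expand into real arithmetic
    for (int k = 0; k <= kmax; ++k) {
      const double fpr = Fp[k].real(), fpi = Fp[k].imag();
      const double fmr = Fm[k].real(), fmi = Fm[k].imag();
      const double zr = Z[k].real(), zi = Z[k].imag();
      Fp[k] = cplx(c2 * fpr + s2 * fmr + sa * zi,
                   c2 * fpi + s2 * fmi - sa * zr);
      Fm[k] = cplx(s2 * fpr + c2 * fmr - sa * zi,
                   s2 * fpi + c2 * fmi + sa * zr);
      Z[k] = cplx(0.5 * sa * (fpi - fmi) + ca * zr,
                  0.5 * sa * (fmr - fpr) + ca * zi);
    }
  }
  void grad() {  // one unit of dephasing: F+ up, F- down
    for (int k = kmax; k >= 1; --k) Fp[k] = Fp[k - 1];
    for (int k = 0; k < kmax; ++k) Fm[k] = Fm[k + 1];
    Fm[kmax] = cplx(0.0, 0.0);
    Fp[0] = std::conj(Fm[0]);
  }
};

void fisp_signal(double T1, double T2, const NumericVector& fa_rad,
                 const NumericVector& tr_ms, double ti_ms, double te_ms,
                 double inv_eff, int kmax, std::vector<cplx>& out) {
  const int n = fa_rad.size();
  EPGState st(kmax);
  st.Z[0] *= -inv_eff;             // inversion preparation
  if (ti_ms > 0) st.relax(ti_ms, T1, T2);
  out.resize(n);
  for (int j = 0; j < n; ++j) {
    st.rf(fa_rad[j]);
    if (te_ms > 0) st.relax(te_ms, T1, T2);
    out[j] = st.Fp[0];
    st.relax(tr_ms[j] - te_ms, T1, T2);
    st.grad();
  }
}

}  // namespace

// [[Rcpp::export]]
ComplexVector epg_fisp_cpp(double T1, double T2, NumericVector fa_rad,
                           NumericVector tr_ms, double ti_ms, double te_ms,
                           double inv_eff, int kmax) {
  std::vector<cplx> sig;
  fisp_signal(T1, T2, fa_rad, tr_ms, ti_ms, te_ms, inv_eff, kmax, sig);
  ComplexVector out(sig.size());
  for (size_t j = 0; j < sig.size(); ++j) {
    out[j].r = sig[j].real();
    out[j].i = sig[j].imag();
  }
  return out;
}

// Batch version: one row per (T1, T2) pair; optionally unit-normalized.
// [[Rcpp::export]]
ComplexMatrix epg_fisp_batch_cpp(NumericVector T1, NumericVector T2,
                                 NumericVector fa_rad, NumericVector tr_ms,
                                 double ti_ms, double te_ms, double inv_eff,
                                 int kmax, bool normalize) {
  const int m = T1.size(), n = fa_rad.size();
  ComplexMatrix out(m, n);
  std::vector<cplx> sig;
  for (int a = 0; a < m; ++a) {
    fisp_signal(T1[a], T2[a], fa_rad, tr_ms, ti_ms, te_ms, inv_eff, kmax, sig);
    double nrm = 1.0;
    if (normalize) {
      double ss = 0.0;
      for (int j = 0; j < n; ++j) ss += std::norm(sig[j]);
      nrm = std::sqrt(ss);
      if (nrm == 0.0) nrm = 1.0;  // zero-norm atoms rejected by the caller
    }
    for (int j = 0; j < n; ++j) {
      out(a, j).r = sig[j].real() / nrm;
      out(a, j).i = sig[j].imag() / nrm;
    }
    if (a % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
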