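// FFT and inner-loop kernels. All transforms are the centered, unitary
// convention used package-wide: zero frequency at index floor(n/2)+1 (1-based),
// forward = fftshift(FFT(ifftshift(x)))/sqrt(N). FFTW plans use FFTW_ESTIMATE
// so the algorithm choice (and hence rounding) is reproducible across runs.
#include <Rcpp.h>
#include <fftw3.h>
#include <complex>
#include <cmath>
#include <map>
#include <vector>

using namespace Rcpp;
typedef std::complex<double> cplx;

namespace {

struct PlanSet {
  fftw_plan fwd = nullptr, bwd = nullptr;
  fftw_complex *a = nullptr, *b = nullptr;
  int n1 = 0, n2 = 0;
};

std::map<long long, PlanSet>& plan_cache() {
  static std::map<long long, PlanSet> cache;
  return cache;
}

PlanSet& get_plans(int n1, int n2) {
  long long key = (long long)n1 * 1000000LL + n2;
  auto& cache = plan_cache();
  auto it = cache.find(key);
  if (it != cache.end()) return it->second;
  PlanSet ps;
  ps.n1 = n1; ps.n2 = n2;
  ps.a = fftw_alloc_complex((size_t)n1 * n2);
  ps.b = fftw_alloc_complex((size_t)n1 * n2);
  // column-major (n1 rows) == row-major with dims (n2, n1)
  ps.fwd = fftw_plan_dft_2d(n2, n1, ps.a, ps.b, FFTW_FORWARD, FFTW_ESTIMATE);
  ps.bwd = fftw_plan_dft_2d(n2, n1, ps.a, ps.b, FFTW_BACKWARD, FFTW_ESTIMATE);
  cache[key] = ps;
  return cache[key];
}

// gather: out[j] = in[(j + s) % n] per dimension
void shift2(const cplx* in, cplx* out, int n1, int n2, int s1, int s2) {
  for (int j2 = 0; j2 < n2; j2++) {
    int i2 = (j2 + s2) % n2;
    const cplx* colin = in + (size_t)i2 * n1;
    cplx* colout = out + (size_t)j2 * n1;
    for (int j1 = 0; j1 < n1; j1++) colout[j1] = colin[(j1 + s1) % n1];
  }
}

inline int sh_i(int n) { return n / 2; }        // ifftshift
inline int sh_f(int n) { return (n + 1) / 2; }  // fftshift

// centered unitary transform of buffer x (length n1*n2) into y
void ft2_buf(const cplx* x, cplx* y, int n1, int n2, bool inverse,
             std::vector<cplx>& scratch) {
  PlanSet& ps = get_plans(n1, n2);
  size_t P = (size_t)n1 * n2;
  scratch.resize(P);
  shift2(x, scratch.data(), n1, n2, sh_i(n1), sh_i(n2));
  std::copy(scratch.begin(), scratch.end(), reinterpret_cast<cplx*>(ps.a));
  fftw_execute(inverse ? ps.bwd : ps.fwd);
  const cplx* out = reinterpret_cast<const cplx*>(ps.b);
  double sc = 1.0 / std::sqrt((double)P);
  for (size_t i = 0; i < P; i++) scratch[i] = out[i] * sc;
  shift2(scratch.data(), y, n1, n2, sh_f(n1), sh_f(n2));
}

} // namespace

// [[Rcpp::export]]
ComplexMatrix cpp_ft2(ComplexMatrix z, bool inverse) {
  int n1 = z.nrow(), n2 = z.ncol();
  ComplexMatrix out(n1, n2);
  std::vector<cplx> scratch;
  ft2_buf(reinterpret_cast<const cplx*>(z.begin()),
          reinterpret_cast<cplx*>(out.begin()), n1, n2, inverse, scratch);
  return out;
}

// Mixed-state alternating-projection retrieval.
// Et: (n1, n2, N) complex, initial SLM-plane fields (centered convention).
// masks: (n1, n2, M) complex unit-modulus; I: (n1, n2, M) measured intensities.
// One epoch = one cyclic pass over the masks in the order given by `order`
// (0-based). Residual per epoch: sum_m ||sum_n |psi|^2 - I_m||_1 / sum_m ||I_m||_1,
// evaluated pre-update. Stops when |res_prev - res| < tol * max(res, 1e-30).
// [[Rcpp::export]]
List cpp_retrieve(ComplexVector Et, ComplexVector masks, NumericVector I,
                  IntegerVector dims, int max_epochs, double tol,
                  IntegerVector order) {
  int n1 = dims[0], n2 = dims[1], N = dims[2], M = dims[3];
  size_t P = (size_t)n1 * n2;
  const double guard = 1e-30;

  // unshift everything once (pixelwise ops commute with the permutation)
  std::vector<cplx> E((size_t)P * N), K((size_t)P * M), psi((size_t)P * N);
  std::vector<double> Iv((size_t)P * M), T(P);
  {
    const cplx* src = reinterpret_cast<const cplx*>(Et.begin());
    for (int n = 0; n < N; n++)
      shift2(src + (size_t)n * P, E.data() + (size_t)n * P, n1, n2, sh_i(n1), sh_i(n2));
    const cplx* ms = reinterpret_cast<const cplx*>(masks.begin());
    std::vector<cplx> tmp(P);
    for (int m = 0; m < M; m++)
      shift2(ms + (size_t)m * P, K.data() + (size_t)m * P, n1, n2, sh_i(n1), sh_i(n2));
    for (int m = 0; m < M; m++) {
      // shift real data through complex helper
      for (size_t p = 0; p < P; p++) tmp[p] = cplx(I[(size_t)m * P + p], 0.0);
      std::vector<cplx> tmp2(P);
      shift2(tmp.data(), tmp2.data(), n1, n2, sh_i(n1), sh_i(n2));
      for (size_t p = 0; p < P; p++) Iv[(size_t)m * P + p] = tmp2[p].real();
    }
  }
  double denom = 0.0;
  for (size_t i = 0; i < Iv.size(); i++) denom += std::fabs(Iv[i]);
  if (denom <= 0) stop("measurement stack is identically zero");

  PlanSet& ps = get_plans(n1, n2);
  cplx* A = reinterpret_cast<cplx*>(ps.a);
  cplx* B = reinterpret_cast<cplx*>(ps.b);
  double usc = 1.0 / std::sqrt((double)P);

  std::vector<double> resid;
  int epochs_run = 0;
  std::string reason = "max_iters";
  double prev = -1.0;
  for (int ep = 0; ep < max_epochs; ep++) {
    double num = 0.0;
    for (int mi = 0; mi < M; mi++) {
      int m = order[mi];
      const cplx* Km = K.data() + (size_t)m * P;
      const double* Im = Iv.data() + (size_t)m * P;
      // psi_n = IFFT(E_n * K_m) (unitary)
      for (int n = 0; n < N; n++) {
        const cplx* En = E.data() + (size_t)n * P;
        for (size_t p = 0; p < P; p++) A[p] = En[p] * Km[p];
        fftw_execute(ps.bwd);
        cplx* pn = psi.data() + (size_t)n * P;
        for (size_t p = 0; p < P; p++) pn[p] = B[p] * usc;
      }
      for (size_t p = 0; p < P; p++) T[p] = 0.0;
      for (int n = 0; n < N; n++) {
        const cplx* pn = psi.data() + (size_t)n * P;
        for (size_t p = 0; p < P; p++) T[p] += std::norm(pn[p]);
      }
      for (size_t p = 0; p < P; p++) num += std::fabs(T[p] - Im[p]);
      // amplitude replacement; zero-denominator pixels untouched
      for (size_t p = 0; p < P; p++)
        T[p] = (T[p] > guard) ? std::sqrt(Im[p] / T[p]) : 1.0;
      for (int n = 0; n < N; n++) {
        cplx* pn = psi.data() + (size_t)n * P;
        cplx* En = E.data() + (size_t)n * P;
        for (size_t p = 0; p < P; p++) A[p] = pn[p] * T[p];
        fftw_execute(ps.fwd);
        for (size_t p = 0; p < P; p++) En[p] = B[p] * usc * std::conj(Km[p]);
      }
    }
    double res = num / denom;
    resid.push_back(res);
    epochs_run = ep + 1;
    if (res < 1e-12 ||
        (prev >= 0 && std::fabs(prev - res) < tol * std::max(res, 1e-30))) {
      reason = "tol";
      break;
    }
    prev = res;
    if (ep % 10 == 9) Rcpp::checkUserInterrupt();
  }

  ComplexVector out((size_t)P * N);
  out.attr("dim") = IntegerVector::create(n1, n2, N);
  cplx* dst = reinterpret_cast<cplx*>(out.begin());
  for (int n = 0; n < N; n++)
    shift2(E.data() + (size_t)n * P, dst + (size_t)n * P, n1, n2, sh_f(n1), sh_f(n2));
  return List::create(_["Etilde"] = out,
                      _["residuals"] = NumericVector(resid.begin(), resid.end()),
                      _["epochs"] = epochs_run,
                      _["reason"] = reason);
}

namespace {

// exclusion mask: true = allowed. Disk of radius `excl` around the center bin.
std::vector<char> allowed_mask(int n1, int n2, double excl) {
  std::vector<char> ok((size_t)n1 * n2, 1);
  int c1 = n1 / 2, c2 = n2 / 2;
  double r2 = excl * excl;
  for (int j = 0; j < n2; j++)
    for (int i = 0; i < n1; i++)
      if ((double)((i - c1) * (i - c1) + (j - c2) * (j - c2)) <= r2)
        ok[(size_t)j * n1 + i] = 0;
  return ok;
}

} // namespace

// Demixing metric M(U) = sum_{n != m} max_{r outside exclusion disk}
// |FT[conj(E'_n) E'_m](r)| for already-mixed fields (n1, n2, N).
// Returns peak values, centered peak indices (1-based) and the complex map
// value at each peak.
// [[Rcpp::export]]
List cpp_demix_metric(ComplexVector fields, IntegerVector dims, double excl) {
  int n1 = dims[0], n2 = dims[1], N = dims[2];
  size_t P = (size_t)n1 * n2;
  const cplx* F = reinterpret_cast<const cplx*>(fields.begin());
  std::vector<char> ok = allowed_mask(n1, n2, excl);
  std::vector<cplx> g(P), G(P), scratch;
  NumericMatrix peak(N, N);
  IntegerMatrix pi1(N, N), pi2(N, N);
  ComplexMatrix cval(N, N);
  double Msum = 0.0;
  for (int n = 0; n < N; n++) {
    for (int m = 0; m < N; m++) {
      if (n == m) continue;
      const cplx *fn = F + (size_t)n * P, *fm = F + (size_t)m * P;
      for (size_t p = 0; p < P; p++) g[p] = std::conj(fn[p]) * fm[p];
      ft2_buf(g.data(), G.data(), n1, n2, false, scratch);
      double best = -1.0; size_t bi = 0;
      for (size_t p = 0; p < P; p++) {
        if (!ok[p]) continue;
        double a = std::abs(G[p]);
        if (a > best) { best = a; bi = p; }
      }
      peak(n, m) = best;
      pi1(n, m) = (int)(bi % n1) + 1;
      pi2(n, m) = (int)(bi / n1) + 1;
      Rcomplex rc; rc.r = G[bi].real(); rc.i = G[bi].imag();
      cval(n, m) = rc;
      Msum += best;
    }
  }
  return List::create(_["M"] = Msum, _["peak"] = peak, _["i"] = pi1,
                      _["j"] = pi2, _["c"] = cval);
}

// Euclidean gradient of M(U) with the per-pair argmax pixel held fixed
// (subgradient of the max). E: original fields (n1,n2,N); U: N x N.
// dM = Re tr(G^H dU) for the returned G.
// [[Rcpp::export]]
List cpp_demix_grad(ComplexVector E, IntegerVector dims, ComplexMatrix Uin,
                    double excl) {
  int n1 = dims[0], n2 = dims[1], N = dims[2];
  size_t P = (size_t)n1 * n2;
  const cplx* E0 = reinterpret_cast<const cplx*>(E.begin());
  std::vector<cplx> U((size_t)N * N);
  for (int a = 0; a < N; a++)
    for (int b = 0; b < N; b++) {
      Rcomplex rc = Uin(a, b);
      U[(size_t)b * N + a] = cplx(rc.r, rc.i);
    }
  // mixed fields Fp_n = sum_b U[n,b] E_b
  std::vector<cplx> Fp((size_t)P * N, cplx(0, 0));
  for (int n = 0; n < N; n++) {
    cplx* out = Fp.data() + (size_t)n * P;
    for (int b = 0; b < N; b++) {
      cplx u = U[(size_t)b * N + n];
      if (u == cplx(0, 0)) continue;
      const cplx* Eb = E0 + (size_t)b * P;
      for (size_t p = 0; p < P; p++) out[p] += u * Eb[p];
    }
  }
  std::vector<char> ok = allowed_mask(n1, n2, excl);
  std::vector<cplx> g(P), G(P), d(P), scratch, delta(P);
  std::vector<cplx> Grad((size_t)N * N, cplx(0, 0)); // column-major N x N
  double Msum = 0.0;
  for (int n = 0; n < N; n++) {
    for (int m = 0; m < N; m++) {
      if (n == m) continue;
      const cplx *fn = Fp.data() + (size_t)n * P, *fm = Fp.data() + (size_t)m * P;
      for (size_t p = 0; p < P; p++) g[p] = std::conj(fn[p]) * fm[p];
      ft2_buf(g.data(), G.data(), n1, n2, false, scratch);
      double best = -1.0; size_t bi = 0;
      for (size_t p = 0; p < P; p++) {
        if (!ok[p]) continue;
        double a = std::abs(G[p]);
        if (a > best) { best = a; bi = p; }
      }
      cplx c = G[bi];
      double ac = std::abs(c);
      Msum += best;
      if (ac < 1e-300) continue;
      cplx w = c / ac; // phase of the peak value
      // d[p] = conj(ift2(delta at peak))[p]  =>  ft2(g)[peak] = sum_p d[p] g[p]
      std::fill(delta.begin(), delta.end(), cplx(0, 0));
      delta[bi] = cplx(1, 0);
      ft2_buf(delta.data(), d.data(), n1, n2, true, scratch);
      for (size_t p = 0; p < P; p++) d[p] = std::conj(d[p]);
      // alpha[a] = sum_p conj(E_a) * Fp_m * d ; beta[b] = sum_p conj(Fp_n) * d * E_b
      for (int a = 0; a < N; a++) {
        const cplx* Ea = E0 + (size_t)a * P;
        cplx alpha(0, 0), beta(0, 0);
        for (size_t p = 0; p < P; p++) {
          cplx dp = d[p];
          alpha += std::conj(Ea[p]) * fm[p] * dp;
          beta += std::conj(fn[p]) * dp * Ea[p];
        }
        Grad[(size_t)a * N + n] += std::conj(w) * alpha;
        Grad[(size_t)a * N + m] += w * std::conj(beta);
      }
    }
    Rcpp::checkUserInterrupt();
  }
  ComplexMatrix Gout(N, N);
  for (int a = 0; a < N; a++)
    for (int b = 0; b < N; b++) {
      cplx v = Grad[(size_t)b * N + a];
      Rcomplex rc; rc.r = v.real(); rc.i = v.imag();
      Gout(a, b) = rc;
    }
  return List::create(_["M"] = Msum, _["G"] = Gout);
}
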