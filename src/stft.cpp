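#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// In-place iterative radix-2 FFT of each column of `F` (rows = N, a
// power of two).  Twiddles and the bit-reversal permutation are
// precomputed once per call; the butterfly loops use raw pointers.
static void fft_radix2_columns(arma::cx_mat& F) {
  const arma::uword N = F.n_rows;
  arma::uword bits = 0;
  while ((1u << bits) < N) ++bits;
  std::vector<arma::uword> rev(N);
  for (arma::uword i = 0; i < N; ++i) {
    arma::uword r = 0, x = i;
    for (arma::uword b = 0; b < bits; ++b) { r = (r << 1) | (x & 1); x >>= 1; }
    rev[i] = r;
  }
  std::vector<std::complex<double> > tw(N / 2);
  for (arma::uword k = 0; k < N / 2; ++k) {
    const double ang = -2.0 * arma::datum::pi * k / N;
    tw[k] = std::complex<double>(std::cos(ang), std::sin(ang));
  }
  const arma::uword ncol = F.n_cols;
  for (arma::uword c = 0; c < ncol; ++c) {
    std::complex<double>* col = F.colptr(c);
    for (arma::uword i = 0; i < N; ++i) {
      if (rev[i] > i) std::swap(col[i], col[rev[i]]);
    }
    for (arma::uword len = 2; len <= N; len <<= 1) {
      const arma::uword half = len >> 1;
      const arma::uword step = N / len;
      for (arma::uword start = 0; start < N; start += len) {
        for (arma::uword k = 0; k < half; ++k) {
          const std::complex<double> t = col[start + k + half] * tw[k * step];
          col[start + k + half] = col[start + k] - t;
          col[start + k] += t;
        }
      }
    }
  }
}

// Short-time Fourier transform power for a complex baseband signal.
//
// Frames start at sample offsets 0, hop, 2*hop, ... and only full
// windows are used.  Returns |FFT|^2 as an n_frames x n_bins matrix.
// When `shift` is true the bins are reordered to run from -fs/2 to
// +fs/2 (fftshift); otherwise they run 0 .. fs*(N-1)/N.
// [[Rcpp::export]]
arma::mat stft_power_cpp(const arma::cx_vec& signal,
                         const arma::vec& window,
                         const int hop,
                         const bool shift) {
  const int n = signal.n_elem;
  const int N = window.n_elem;
  if (n < N) stop("signal shorter than the analysis window");
  if (hop < 1) stop("hop must be >= 1");
  const int n_frames = (n - N) / hop + 1;

  arma::cx_mat frames(N, n_frames);
  const std::complex<double>* sig = signal.memptr();
  const double* w = window.memptr();
  for (int f = 0; f < n_frames; ++f) {
    std::complex<double>* col = frames.colptr(f);
    const std::complex<double>* src = sig + (size_t)f * hop;
    for (int i = 0; i < N; ++i) col[i] = src[i] * w[i];
  }
  if ((N & (N - 1)) == 0) {
    fft_radix2_columns(frames);
  } else {
    frames = arma::fft(frames);
  }

  arma::mat power(n_frames, N);  // frames x bins, filled transposed
  const int half = N / 2;
  for (int f = 0; f < n_frames; ++f) {
    const std::complex<double>* col = frames.colptr(f);
    double* row = power.memptr() + f;  // column-major: stride n_frames
    for (int b = 0; b < N; ++b) {
      const int src = shift ? (b + half) % N : b;
      row[(size_t)b * n_frames] = std::norm(col[src]);
    }
  }
  return power;
}

// Per-frame envelope scan over a power matrix restricted to eligible
// bins (columns sorted by increasing velocity).  A bin is significant
// when its power is >= thr_lin * frame max.  Returns, per frame, the
// indices (1-based) of the highest and lowest significant bins and the
// power-weighted mean velocity over significant bins (rows of all-zero
// power get index 0 = gap).
// [[Rcpp::export]]
List envelope_scan_cpp(const arma::mat& P, const arma::vec& vels,
                       const double thr_lin) {
  const arma::uword n = P.n_rows, k = P.n_cols;
  if (vels.n_elem != k) stop("velocity axis does not match power matrix");
  IntegerVector iu(n), il(n);
  NumericVector vm(n);
  const double* pm = P.memptr();
  const double* vv = vels.memptr();
  for (arma::uword i = 0; i < n; ++i) {
    double pmax = 0;
    for (arma::uword j = 0; j < k; ++j) {
      pmax = std::max(pmax, pm[j * n + i]);
    }
    if (pmax <= 0) { iu[i] = 0; il[i] = 0; vm[i] = NA_REAL; continue; }
    const double thr = thr_lin * pmax;
    int lo = -1, hi = -1;
    double wsum = 0, vsum = 0;
    for (arma::uword j = 0; j < k; ++j) {
      const double p = pm[j * n + i];
      if (p >= thr) {
        if (lo < 0) lo = j;
        hi = j;
        wsum += p;
        vsum += p * vv[j];
      }
    }
    iu[i] = hi + 1;
    il[i] = lo + 1;
    vm[i] = vsum / wsum;
  }
  return List::create(_["iu"] = iu, _["il"] = il, _["v_m"] = vm);
}
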