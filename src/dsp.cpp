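#include <Rcpp.h>
using namespace Rcpp;

// Cascade of second-order sections, direct form II transposed.
// sos: rows of (b0, b1, b2, a1, a2) with a0 == 1.
// [[Rcpp::export]]
NumericVector cpp_sos_filter(NumericVector x, NumericMatrix sos) {
  int n = x.size(), ns = sos.nrow();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    double a1 = sos(s, 3), a2 = sos(s, 4);
    double z1 = 0.0, z2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double xi = y[i];
      double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}

// Normalized cross-correlation of analysis frames at per-frame integer lags.
// For frame i (1-based start, length n) the correlation is evaluated at the
// five lags lags[i]-2 .. lags[i]+2 after removing the frame mean, giving the
// ordinates used for local-maximum search plus parabolic peak refinement.
// [[Rcpp::export]]
NumericMatrix cpp_xcorr_frames(NumericVector x, IntegerVector starts, int n,
                               IntegerVector lags) {
  int m = starts.size();
  NumericMatrix out(5, m);
  std::vector<double> c(n);
  for (int i = 0; i < m; ++i) {
    int s = starts[i] - 1;
    double mu = 0.0;
    for (int t = 0; t < n; ++t) mu += x[s + t];
    mu /= n;
    double e0 = 0.0;
    for (int t = 0; t < n; ++t) { c[t] = x[s + t] - mu; e0 += c[t] * c[t]; }
    if (e0 <= 0) continue;
    for (int j = 0; j < 5; ++j) {
      int L = lags[i] - 2 + j;
      if (L < 1 || L >= n - 1) { out(j, i) = 0.0; continue; }
      double sxy = 0.0;
      int nn = n - L;
      for (int t = 0; t < nn; ++t) sxy += c[t] * c[t + L];
      // stationary-frame normalization: overlap energy ~ e0 * (n - L) / n
      double r = sxy / (e0 * nn / (double)n);
      out(j, i) = r;
    }
  }
  return out;
}

// band-limited (windowed-sinc) reconstruction of x at fractional position p
static double sinc_interp(const NumericVector &x, double p) {
  int n = x.size();
  int i0 = (int)std::lround(p);
  double frac = p - i0;
  if (std::fabs(frac) < 1e-9)
    return (i0 >= 0 && i0 < n) ? x[i0] : 0.0;
  double s = 0.0;
  for (int k = -16; k <= 16; ++k) {
    int i = i0 + k;
    if (i < 0 || i >= n) continue;
    double arg = k - frac;
    double u = M_PI * k / 16.5;
    double w = 0.42 + 0.5 * std::cos(u) + 0.08 * std::cos(2.0 * u);
    s += x[i] * w * std::sin(M_PI * arg) / (M_PI * arg);
  }
  return s;
}

// Pulse marking within one voiced run.  x: full waveform; run [s0, s1]
// (1-based, inclusive); period: per-sample period estimate in samples for the
// run (length s1 - s0 + 1).  Starting from the maximum of the first period,
// each next pulse is predicted one local period ahead and snapped to the
// waveform maximum within +/- period/3; positions are refined to sub-sample
// precision by parabolic interpolation.  The period between consecutive
// pulses is then re-estimated by waveform matching: the cross-correlation of
// one cycle's surroundings with the next is interpolated parabolically around
// the integer peak distance, which suppresses the timing noise that ringing
// interference puts on raw peak positions.  Rows of the result: fractional
// 1-based position, amplitude, refined period-to-next in samples (NA for the
// last pulse of the run).
// [[Rcpp::export]]
NumericMatrix cpp_mark_pulses(NumericVector x, int s0, int s1,
                              NumericVector period) {
  std::vector<double> pos, amp;
  std::vector<int> ipos;
  int a = s0 - 1, b = s1 - 1;  // 0-based bounds
  int rl = b - a + 1;
  int n = x.size();
  if (rl < 3) return NumericMatrix(3, 0);
  double T0 = period[0];
  int w_end = std::min(b, a + (int)std::ceil(T0) - 1);
  int t = a;
  for (int i = a; i <= w_end; ++i) if (x[i] > x[t]) t = i;
  while (true) {
    double p = (double)t, h = x[t];
    if (t > a && t < b) {
      double y0 = x[t - 1], y1 = x[t], y2 = x[t + 1];
      double den = y0 - 2.0 * y1 + y2;
      if (den < 0) {
        double d = 0.5 * (y0 - y2) / den;
        if (d > -0.5 && d < 0.5) {
          p = t + d;
          h = sinc_interp(x, p);       // band-limited peak amplitude
        }
      }
    }
    pos.push_back(p + 1.0);            // back to 1-based
    amp.push_back(std::fabs(h));
    ipos.push_back(t);
    double Tt = period[std::min(std::max(t - a, 0), rl - 1)];
    int pred = t + (int)std::lround(Tt);
    int hw = std::max(2, (int)std::lround(Tt / 3.0));
    int lo = std::max(pred - hw, t + 2), hi = std::min(pred + hw, b);
    if (pred > b || lo > hi) break;
    int nt = lo;
    for (int i = lo; i <= hi; ++i) if (x[i] > x[nt]) nt = i;
    t = nt;
  }
  size_t m = pos.size();
  NumericMatrix out(3, m);
  for (size_t i = 0; i < m; ++i) {
    out(0, i) = pos[i]; out(1, i) = amp[i]; out(2, i) = NA_REAL;
  }
  for (size_t i = 0; i + 1 < m; ++i) {
    int L0 = ipos[i + 1] - ipos[i];
    double Tt = period[std::min(std::max(ipos[i] - a, 0), rl - 1)];
    int hw = (int)std::lround(0.45 * Tt);
    // clamp the matching window and lags inside the waveform
    int lo = std::max(ipos[i] - hw, 0);
    int hi = std::min(ipos[i] + hw, n - 1);
    double c[3];
    bool ok = true;
    for (int j = 0; j < 3; ++j) {
      int L = L0 - 1 + j;
      double s = 0.0;
      if (hi + L > n - 1) { ok = false; break; }
      for (int k = lo; k <= hi; ++k) s += x[k] * x[k + L];
      c[j] = s;
    }
    double Tref = (double)L0;
    if (ok) {
      double den = c[0] - 2.0 * c[1] + c[2];
      if (den < 0) {
        double d = 0.5 * (c[0] - c[2]) / den;
        if (d > -1.0 && d < 1.0) Tref = L0 + d;
      }
    }
    out(2, i) = Tref;
  }
  return out;
}

// Pitch-period candidates from the decimated signal: per frame, the
// normalized autocorrelation (mean-removed, overlap-corrected) is evaluated
// over lags [lag_lo, lag_hi]; local maxima are refined by parabolic
// interpolation and compared under a log2-lag penalty so the fundamental
// beats its equally-correlated multiples.  Rows: fractional best lag, its
// interpolated correlation.
// [[Rcpp::export]]
NumericMatrix cpp_pitch_candidates(NumericVector x, IntegerVector starts,
                                   int n, int lag_lo, int lag_hi,
                                   double penalty) {
  int m = starts.size();
  int nl = lag_hi - lag_lo + 1;
  NumericMatrix out(2, m);
  std::vector<double> nac(nl), c(n);
  for (int i = 0; i < m; ++i) {
    int s = starts[i] - 1;
    double mu = 0.0, e0 = 0.0;
    for (int t = 0; t < n; ++t) mu += x[s + t];
    mu /= n;
    for (int t = 0; t < n; ++t) { c[t] = x[s + t] - mu; e0 += c[t] * c[t]; }
    if (e0 <= 0) { out(0, i) = lag_lo; out(1, i) = 0.0; continue; }
    for (int L = lag_lo; L <= lag_hi; ++L) {
      double sxy = 0.0;
      int nn = n - L;
      for (int t = 0; t < nn; ++t) sxy += c[t] * c[t + L];
      nac[L - lag_lo] = (sxy / e0) * ((double)n / nn);
    }
    double best_score = -1e30, best_lag = lag_lo, best_r = 0.0;
    for (int k = 1; k < nl - 1; ++k) {
      if (nac[k] < nac[k - 1] || nac[k] < nac[k + 1]) continue;
      double den = nac[k - 1] - 2.0 * nac[k] + nac[k + 1];
      double d = 0.0, ym = nac[k];
      if (den < -1e-12) {
        d = 0.5 * (nac[k - 1] - nac[k + 1]) / den;
        if (d < -0.5) d = -0.5; if (d > 0.5) d = 0.5;
        ym = nac[k] - 0.25 * (nac[k - 1] - nac[k + 1]) * d;
      }
      double score = ym - penalty * std::log2((double)(lag_lo + k) / lag_lo);
      if (score > best_score) {
        best_score = score; best_lag = lag_lo + k + d; best_r = ym;
      }
    }
    if (best_score <= -1e29) {       // no interior local max: plain argmax
      int kb = 0;
      for (int k = 1; k < nl; ++k) if (nac[k] > nac[kb]) kb = k;
      best_lag = lag_lo + kb; best_r = nac[kb];
    }
    out(0, i) = best_lag;
    out(1, i) = best_r;
  }
  return out;
}

// iterative radix-2 complex FFT (in place), n a power of two
static void fft_radix2(std::vector<double> &re, std::vector<double> &im) {
  int n = re.size();
  for (int i = 1, j = 0; i < n; ++i) {      // bit reversal
    int bit = n >> 1;
    for (; j & bit; bit >>= 1) j ^= bit;
    j ^= bit;
    if (i < j) { std::swap(re[i], re[j]); std::swap(im[i], im[j]); }
  }
  for (int len = 2; len <= n; len <<= 1) {
    double ang = -2.0 * M_PI / len;
    double wr0 = std::cos(ang), wi0 = std::sin(ang);
    for (int i = 0; i < n; i += len) {
      double wr = 1.0, wi = 0.0;
      for (int k = 0; k < len / 2; ++k) {
        int a = i + k, b = i + k + len / 2;
        double ur = re[a], ui = im[a];
        double vr = re[b] * wr - im[b] * wi;
        double vi = re[b] * wi + im[b] * wr;
        re[a] = ur + vr; im[a] = ui + vi;
        re[b] = ur - vr; im[b] = ui - vi;
        double nwr = wr * wr0 - wi * wi0;
        wi = wr * wi0 + wi * wr0; wr = nwr;
      }
    }
  }
}

// Power spectra of windowed frames: frame i starts at starts[i] (1-based),
// length n, multiplied by win, zero-padded to nfft (power of two).  Two real
// frames are packed into one complex transform.  Returns (nfft/2 + 1) x m.
// [[Rcpp::export]]
NumericMatrix cpp_power_frames(NumericVector x, IntegerVector starts, int n,
                               NumericVector win, int nfft) {
  int m = starts.size();
  int nb = nfft / 2 + 1;
  NumericMatrix out(nb, m);
  std::vector<double> re(nfft), im(nfft);
  for (int i = 0; i < m; i += 2) {
    std::fill(re.begin(), re.end(), 0.0);
    std::fill(im.begin(), im.end(), 0.0);
    int s1 = starts[i] - 1;
    for (int t = 0; t < n; ++t) re[t] = x[s1 + t] * win[t];
    bool pair = (i + 1) < m;
    if (pair) {
      int s2 = starts[i + 1] - 1;
      for (int t = 0; t < n; ++t) im[t] = x[s2 + t] * win[t];
    }
    fft_radix2(re, im);
    for (int k = 0; k < nb; ++k) {
      int kc = (nfft - k) % nfft;
      double ar = 0.5 * (re[k] + re[kc]);
      double ai = 0.5 * (im[k] - im[kc]);
      out(k, i) = ar * ar + ai * ai;
      if (pair) {
        double br = 0.5 * (im[k] + im[kc]);
        double bi = -0.5 * (re[k] - re[kc]);
        out(k, i + 1) = br * br + bi * bi;
      }
    }
  }
  return out;
}

// Per-frame root-mean-square over frames of length n starting at starts.
// [[Rcpp::export]]
NumericVector cpp_frame_rms(NumericVector x, IntegerVector starts, int n) {
  int m = starts.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    int s = starts[i] - 1;
    double ss = 0.0;
    for (int t = 0; t < n; ++t) ss += x[s + t] * x[s + t];
    out[i] = std::sqrt(ss / n);
  }
  return out;
}
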