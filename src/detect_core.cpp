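#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-pass 8-connected component labeling with union-find.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> parent(1, 0); // parent[0] unused
  auto find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 0;
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      if (!mask(r, c)) continue;
      // previously visited 8-neighbours (column-major scan):
      int best = 0;
      int nbr[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
      for (int k = 0; k < 4; ++k) {
        int rr = nbr[k][0], cc = nbr[k][1];
        if (rr < 0 || rr >= h || cc < 0) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
        }
      }
      if (best == 0) {
        best = ++next;
        parent.push_back(best);
      }
      lab(r, c) = best;
    }
  }
  // flatten and relabel consecutively
  std::vector<int> remap(next + 1, 0);
  int out = 0;
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = find(l);
      if (remap[root] == 0) remap[root] = ++out;
      lab(r, c) = remap[root];
    }
  return lab;
}

// One fused pass of the per-frame detection bookkeeping: frame statistics,
// instantaneous mask, count-matrix update, temporal mask, the summary
// sums feeding the adaptive updates (bright fraction, Jaccard terms, and
// the in-mask mean / out-of-mask std for the frame SNR), and the 8-bit
// output remapping on the gated support.
//
// To keep long batch runs allocation-free, the pass reads frame t
// (1-based) directly from the input stack and updates C, the temporal
// mask buffer, and the output stack IN PLACE; the caller owns these
// buffers and must not share them. Returns the scalar summaries.
// [[Rcpp::export]]
NumericVector cpp_frame_step(IntegerVector frames, int t, R_xlen_t fsz,
                             IntegerVector C, LogicalVector prev_tcm,
                             LogicalVector tcm, LogicalVector m_event,
                             double theta_g, int dthr, double denom,
                             IntegerVector out) {
  if (C.size() != fsz || prev_tcm.size() != fsz || tcm.size() != fsz ||
      m_event.size() != fsz)
    stop("state buffers do not match the frame size");
  if (frames.size() < (R_xlen_t)t * fsz || out.size() != frames.size())
    stop("frame index out of range");
  const int *fr = INTEGER(frames) + (R_xlen_t)(t - 1) * fsz;
  int *outp = INTEGER(out) + (R_xlen_t)(t - 1) * fsz;
  int *Cp = INTEGER(C);
  int *tcmp = LOGICAL(tcm), *prevp = LOGICAL(prev_tcm);
  int *mep = LOGICAL(m_event);
  long double s = 0.0L, s2 = 0.0L;
  int fmin = fr[0], fmax = fr[0];
  for (R_xlen_t i = 0; i < fsz; ++i) {
    int xi = fr[i];
    if (xi < fmin) fmin = xi;
    if (xi > fmax) fmax = xi;
    double x = xi;
    s += x; s2 += x * x;
  }
  double mu = (double)(s / fsz);
  double var = (double)(s2 / fsz) - mu * mu;
  double sigma = var > 0 ? std::sqrt(var) : 0.0;
  double thr = mu + theta_g * sigma;
  long long n_tcm = 0, n_inter = 0, n_union = 0;
  long double sum_in = 0.0L, sum_out = 0.0L, sumsq_out = 0.0L;
  const double scale = 255.0 / denom;
  for (R_xlen_t i = 0; i < fsz; ++i) {
    double x = fr[i];
    int c = (x > thr) ? Cp[i] + 1 : 0;
    Cp[i] = c;
    bool on = c >= dthr;
    tcmp[i] = on;
    if (on) { ++n_tcm; sum_in += x; }
    else { sum_out += x; sumsq_out += x * x; }
    bool p = prevp[i];
    if (on && p) ++n_inter;
    if (on || p) ++n_union;
    if (on && mep[i]) {
      double v = std::floor(x * scale + 0.5);
      outp[i] = (int)std::min(std::max(v, 0.0), 255.0);
    } else {
      outp[i] = 0;
    }
  }
  return NumericVector::create(
    _["mu"] = mu, _["sigma"] = sigma,
    _["fmin"] = fmin, _["fmax"] = fmax,
    _["n_tcm"] = (double)n_tcm,
    _["n_inter"] = (double)n_inter, _["n_union"] = (double)n_union,
    _["sum_in"] = (double)sum_in,
    _["sum_out"] = (double)sum_out, _["sumsq_out"] = (double)sumsq_out);
}

// Weighted EM for a 1-D Gaussian mixture over unique gray values v with
// multiplicities w. Convergence is declared when the increment of the
// mean (per-observation) log-likelihood falls below tol.
// [[Rcpp::export]]
List cpp_gmm_em(NumericVector v, NumericVector w, NumericVector pi0,
                NumericVector mu0, NumericVector sd0, double tol,
                int max_iter, double sd_floor) {
  int m = v.size(), K = mu0.size();
  std::vector<double> pi(pi0.begin(), pi0.end());
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sd(sd0.begin(), sd0.end());
  double n = 0.0;
  for (int i = 0; i < m; ++i) n += w[i];
  std::vector<double> resp(m * K);
  double loglik = R_NegInf, prev = R_NegInf;
  bool ok = true;
  int it = 0;
  const double log2pi = std::log(2.0 * M_PI);
  for (it = 1; it <= max_iter; ++it) {
    // E-step
    long double ll = 0.0L;
    for (int i = 0; i < m; ++i) {
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double z = (v[i] - mu[k]) / sd[k];
        double lp = std::log(pi[k]) - std::log(sd[k]) -
                    0.5 * (z * z + log2pi);
        resp[i * K + k] = lp;
        if (lp > mx) mx = lp;
      }
      double se = 0.0;
      for (int k = 0; k < K; ++k) se += std::exp(resp[i * K + k] - mx);
      double lse = mx + std::log(se);
      ll += (long double)(w[i] * lse);
      for (int k = 0; k < K; ++k)
        resp[i * K + k] = std::exp(resp[i * K + k] - lse);
    }
    loglik = (double)ll;
    if (it > 1 && (loglik - prev) / n < tol) break;
    prev = loglik;
    // M-step
    for (int k = 0; k < K; ++k) {
      long double nk = 0.0L, sk = 0.0L;
      for (int i = 0; i < m; ++i) {
        double r = w[i] * resp[i * K + k];
        nk += r; sk += r * v[i];
      }
      if (nk < 1e-10) { ok = false; break; }
      double mk = (double)(sk / nk);
      long double vk = 0.0L;
      for (int i = 0; i < m; ++i) {
        double d = v[i] - mk;
        vk += (long double)(w[i] * resp[i * K + k] * d * d);
      }
      pi[k] = (double)(nk / n);
      mu[k] = mk;
      sd[k] = std::max(std::sqrt((double)(vk / nk)), sd_floor);
    }
    if (!ok) break;
  }
  return List::create(
    _["pi"] = NumericVector(pi.begin(), pi.end()),
    _["mu"] = NumericVector(mu.begin(), mu.end()),
    _["sd"] = NumericVector(sd.begin(), sd.end()),
    _["loglik"] = loglik, _["iterations"] = std::min(it, max_iter),
    _["ok"] = ok);
}

// Fuse a 16-bit-quantized clean-signal stack with a background image on
// the 8-bit scale: out = round(255 * (sw * clean/65535 + bw * bg)).
// [[Rcpp::export]]
IntegerVector cpp_fuse(IntegerVector clean, NumericVector bg,
                       double signal_weight, double background_weight,
                       double clean_scale) {
  R_xlen_t n = clean.size(), fsz = bg.size();
  if (fsz == 0 || n % fsz != 0) stop("shape mismatch");
  IntegerVector out(n);
  const int *cp = INTEGER(clean);
  const double *bp = REAL(bg);
  int *op = INTEGER(out);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = 255.0 * (signal_weight * clean_scale * cp[i] +
                        background_weight * bp[i % fsz]);
    v = std::floor(v + 0.5);
    op[i] = (int)std::min(std::max(v, 0.0), 255.0);
  }
  return out;
}

// Combine per-frame Poisson and Gaussian draws into the clipped 8-bit
// noisy frame: round(max(pois/gain + gauss, 0)) clipped to [0, 255].
// [[Rcpp::export]]
IntegerVector cpp_noise_combine(IntegerVector pois, NumericVector gauss,
                                double gain) {
  R_xlen_t n = pois.size();
  bool has_gauss = gauss.size() == n;
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double y = pois[i] / gain;
    if (has_gauss) y += gauss[i];
    if (y < 0) y = 0;
    y = std::floor(y + 0.5);
    out[i] = (int)std::min(std::max(y, 0.0), 255.0);
  }
  return out;
}

static inline double elem_as_double(SEXP x, R_xlen_t i) {
  switch (TYPEOF(x)) {
  case REALSXP: return REAL(x)[i];
  case INTSXP:  return (double)INTEGER(x)[i];
  case LGLSXP:  return (double)LOGICAL(x)[i];
  default: stop("unsupported storage type");
  }
  return 0.0;
}

// Reference SNR building blocks: min-max normalize both stacks internally
// and return (sum truth^2, sum (truth - est)^2) without allocating copies.
// [[Rcpp::export]]
NumericVector cpp_ref_snr_sums(SEXP truth, SEXP est) {
  R_xlen_t n = Rf_xlength(truth);
  if (Rf_xlength(est) != n) stop("shape mismatch between truth and estimate");
  double tmin = R_PosInf, tmax = R_NegInf, emin = R_PosInf, emax = R_NegInf;
  for (R_xlen_t i = 0; i < n; ++i) {
    double t = elem_as_double(truth, i), e = elem_as_double(est, i);
    if (t < tmin) tmin = t; if (t > tmax) tmax = t;
    if (e < emin) emin = e; if (e > emax) emax = e;
  }
  double tr = tmax - tmin, er = emax - emin;
  long double st2 = 0.0L, sd2 = 0.0L;
  for (R_xlen_t i = 0; i < n; ++i) {
    double t = elem_as_double(truth, i), e = elem_as_double(est, i);
    t = tr > 0 ? (t - tmin) / tr : 0.0;
    e = er > 0 ? (e - emin) / er : 0.0;
    st2 += (long double)(t * t);
    double d = t - e;
    sd2 += (long double)(d * d);
  }
  return NumericVector::create((double)st2, (double)sd2);
}

// Per-frame building blocks of the reference SNR: both stacks are
// min-max normalized over the WHOLE stack (pass 1), then per-frame sums
// of truth^2 and (truth - est)^2 are accumulated (pass 2).
// Returns a 2 x n_frames matrix: row 0 = sum t^2, row 1 = sum (t-e)^2.
// [[Rcpp::export]]
NumericMatrix cpp_ref_snr_frame_sums(SEXP truth, SEXP est, int n_frames) {
  R_xlen_t n = Rf_xlength(truth);
  if (Rf_xlength(est) != n) stop("shape mismatch between truth and estimate");
  if (n_frames < 1 || n % n_frames != 0)
    stop("stack length is not a multiple of the frame count");
  R_xlen_t fsz = n / n_frames;
  double tmin = R_PosInf, tmax = R_NegInf, emin = R_PosInf, emax = R_NegInf;
  for (R_xlen_t i = 0; i < n; ++i) {
    double t = elem_as_double(truth, i), e = elem_as_double(est, i);
    if (t < tmin) tmin = t;
    if (t > tmax) tmax = t;
    if (e < emin) emin = e;
    if (e > emax) emax = e;
  }
  double tr = tmax - tmin, er = emax - emin;
  NumericMatrix out(2, n_frames);
  for (int f = 0; f < n_frames; ++f) {
    long double st2 = 0.0L, sd2 = 0.0L;
    R_xlen_t off = (R_xlen_t)f * fsz;
    for (R_xlen_t i = 0; i < fsz; ++i) {
      double t = elem_as_double(truth, off + i);
      double e = elem_as_double(est, off + i);
      t = tr > 0 ? (t - tmin) / tr : 0.0;
      e = er > 0 ? (e - emin) / er : 0.0;
      st2 += (long double)(t * t);
      double d = t - e;
      sd2 += (long double)(d * d);
    }
    out(0, f) = (double)st2;
    out(1, f) = (double)sd2;
  }
  return out;
}

// Overlap counts for Dice/Jaccard on large stacks: |A|, |B|, |A and B|.
// [[Rcpp::export]]
NumericVector cpp_overlap_counts(SEXP a, SEXP b) {
  R_xlen_t n = Rf_xlength(a);
  if (Rf_xlength(b) != n) stop("shape mismatch between masks");
  long long na = 0, nb = 0, ni = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    bool xa = elem_as_double(a, i) != 0.0;
    bool xb = elem_as_double(b, i) != 0.0;
    if (xa) ++na;
    if (xb) ++nb;
    if (xa && xb) ++ni;
  }
  return NumericVector::create((double)na, (double)nb, (double)ni);
}
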