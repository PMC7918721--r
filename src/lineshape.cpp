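#include <Rcpp.h>
using namespace Rcpp;

// CODATA 2018
static const double H_PLANCK = 6.62607015e-34;   // J s
static const double MU_B     = 9.2740100783e-24; // J/T

// h*nu/mu_B in mT * (g units); divide by g_eff to get a resonance field in mT
static inline double field_constant(double freq_Hz) {
  return H_PLANCK * freq_Hz / MU_B * 1e3;
}

struct Axial { double Apar, Aperp, gpar, gperp; };

// Motional (partial) averaging of the rhombic tensors to axial effective
// values; S = 1 recovers the rigid-limit axial values, S = 0 the isotropic
// average.  Polarity factors scale the whole tensor, preserving the trace
// relation (A_par + 2 A_perp)/3 = pA * a_iso.
static inline Axial partial_avg(double Axx, double Ayy, double Azz,
                                double gxx, double gyy, double gzz,
                                double S, double pA, double pg) {
  const double aiso = (Axx + Ayy + Azz) / 3.0;
  const double dA   = Azz - (Axx + Ayy) / 2.0;
  const double giso = (gxx + gyy + gzz) / 3.0;
  const double dg   = gzz - (gxx + gyy) / 2.0;
  Axial t;
  t.Apar  = pA * (aiso + 2.0 / 3.0 * S * dA);
  t.Aperp = pA * (aiso - S * dA / 3.0);
  t.gpar  = pg * (giso + 2.0 / 3.0 * S * dg);
  t.gperp = pg * (giso - S * dg / 3.0);
  return t;
}

static inline double eff_aniso(double par, double perp, double c2) {
  return std::sqrt(par * par * c2 + perp * perp * (1.0 - c2));
}

// Variance of the instantaneous resonance field over a wobble cone of
// half-angle theta0 about a director tilted by theta from B.  The probe axis
// is uniform over the cone's solid angle; cn_u/cn_w are Gauss-Legendre nodes
// and weights on cos(alpha) in [cos(theta0), 1] (weights sum to
// 1 - cos(theta0)); the azimuth is handled by an n_az-point midpoint rule.
// Rigid-limit (S = 1) tensors are used for the instantaneous field.
// [[Rcpp::export]]
double cpp_cone_variance(double costheta, int mI,
                         double Apar_r, double Aperp_r,
                         double gpar_r, double gperp_r,
                         double C1,
                         NumericVector cn_u, NumericVector cn_w, int n_az) {
  const int np = cn_u.size();
  double wsum = 0.0;
  for (int a = 0; a < np; ++a) wsum += cn_w[a];
  if (wsum < 1e-14) return 0.0;  // closed cone: no accessible motion

  std::vector<double> cphi(n_az);
  for (int j = 0; j < n_az; ++j)
    cphi[j] = std::cos(2.0 * M_PI * (j + 0.5) / n_az);

  const double st = std::sqrt(std::max(0.0, 1.0 - costheta * costheta));
  double e1 = 0.0, e2 = 0.0;
  for (int a = 0; a < np; ++a) {
    const double ca = cn_u[a];
    const double sa = std::sqrt(std::max(0.0, 1.0 - ca * ca));
    double s1 = 0.0, s2 = 0.0;
    for (int j = 0; j < n_az; ++j) {
      double cb = ca * costheta + sa * st * cphi[j];
      const double c2 = cb * cb;
      const double Aeff = eff_aniso(Apar_r, Aperp_r, c2);
      const double geff = eff_aniso(gpar_r, gperp_r, c2);
      const double B = C1 / geff - mI * Aeff;
      s1 += B;
      s2 += B * B;
    }
    e1 += cn_w[a] * s1 / n_az;
    e2 += cn_w[a] * s2 / n_az;
  }
  e1 /= wsum;
  e2 /= wsum;
  const double v = e2 - e1 * e1;
  return v > 0.0 ? v : 0.0;
}

// Raw (unnormalized) first-derivative lineshape of one domain component:
// powder average over director orientations (th_u = cos(theta) nodes on
// [0,1], th_w weights summing to 1) of the three 14N hyperfine lines, each a
// first-derivative Lorentzian centred at the motionally averaged resonance
// field with half-width W + kappa * tau_c * Var_cone(B_instantaneous).
// [[Rcpp::export]]
NumericVector cpp_component_deriv(NumericVector field,
                                  double Axx, double Ayy, double Azz,
                                  double gxx, double gyy, double gzz,
                                  double S, double tauc, double pA, double pg,
                                  double W, double freq_Hz, double kappa,
                                  NumericVector th_u, NumericVector th_w,
                                  NumericVector cn_u, NumericVector cn_w,
                                  int n_az) {
  const int nf = field.size();
  const int nt = th_u.size();
  NumericVector out(nf);

  const double C1 = field_constant(freq_Hz);
  const Axial avg = partial_avg(Axx, Ayy, Azz, gxx, gyy, gzz, S, pA, pg);
  const Axial rig = partial_avg(Axx, Ayy, Azz, gxx, gyy, gzz, 1.0, pA, pg);
  const double GAMMA_MIN = 1e-3;  // mT; keeps the line integrable on the grid

  // collect all line centres/widths, then accumulate in one pass
  std::vector<double> B0s(3 * nt), amps(3 * nt), G2s(3 * nt);
  int L = 0;
  for (int i = 0; i < nt; ++i) {
    const double ct = th_u[i];
    const double c2 = ct * ct;
    const double Aeff = eff_aniso(avg.Apar, avg.Aperp, c2);
    const double geff = eff_aniso(avg.gpar, avg.gperp, c2);
    const double wfac = th_w[i] / 3.0;
    for (int mI = -1; mI <= 1; ++mI) {
      const double var = cpp_cone_variance(ct, mI, rig.Apar, rig.Aperp,
                                           rig.gpar, rig.gperp, C1,
                                           cn_u, cn_w, n_az);
      double G = W + kappa * tauc * var;
      if (G < GAMMA_MIN) G = GAMMA_MIN;
      B0s[L] = C1 / geff - mI * Aeff;
      amps[L] = -2.0 / M_PI * G * wfac;
      G2s[L] = G * G;
      ++L;
    }
  }
  // Hot loop: L ~ 200 lines x nf ~ 1000 points, division-bound.  Single
  // precision is ample here (the shape is later detrended and rescaled by
  // its own integrals, and fit-relevant chi-square contrasts are percent
  // scale), and vectorizes 2x wider.
  // offsets are taken from the left edge of the sweep so the float
  // differences below keep ~1e-6 mT resolution despite the ~341 mT carrier
  const double* fp = REAL(field);
  double* op = REAL(out);
  std::vector<float> xs(nf), acc(nf, 0.0f);
  for (int p = 0; p < nf; ++p) xs[p] = (float)(fp[p] - fp[0]);
  for (int l = 0; l < L; ++l) {
    const float B0 = (float)(B0s[l] - fp[0]), amp = (float)amps[l],
                G2 = (float)G2s[l];
    for (int p = 0; p < nf; ++p) {
      const float x = xs[p] - B0;
      const float den = x * x + G2;
      acc[p] += amp * x / (den * den);
    }
  }
  for (int p = 0; p < nf; ++p) op[p] = (double)acc[p];
  return out;
}

// internal single-component evaluation used by the batch objective: raw
// lineshape followed by the same detrend/normalize steps as
// cpp_normalize_deriv; returns false for degenerate shapes
static bool component_norm(const double* fp, int nf,
                           double Axx, double Ayy, double Azz,
                           double gxx, double gyy, double gzz,
                           const double* g5,  // S, tau_c, pA, pg, W
                           double freq_Hz, double kappa,
                           const double* th_u, const double* th_w, int nt,
                           const double* cn_ref_x, const double* cn_ref_w,
                           int n_cn, int n_az, double* deriv) {
  const double S = g5[0], tauc = g5[1], pA = g5[2], pg = g5[3], W = g5[4];
  const double C1 = field_constant(freq_Hz);
  const Axial avg = partial_avg(Axx, Ayy, Azz, gxx, gyy, gzz, S, pA, pg);
  const Axial rig = partial_avg(Axx, Ayy, Azz, gxx, gyy, gzz, 1.0, pA, pg);
  const double GAMMA_MIN = 1e-3;

  // wobble-cone nodes: affine image of the reference [0,1] nodes
  const double ct0 = (-1.0 + std::sqrt(1.0 + 8.0 * S)) / 2.0;
  const double span_cn = 1.0 - ct0;
  std::vector<double> cn_x(n_cn), cn_w(n_cn);
  for (int a = 0; a < n_cn; ++a) {
    cn_x[a] = ct0 + span_cn * cn_ref_x[a];
    cn_w[a] = span_cn * cn_ref_w[a];
  }
  NumericVector cn_xv(cn_x.begin(), cn_x.end());
  NumericVector cn_wv(cn_w.begin(), cn_w.end());

  std::vector<double> B0s(3 * nt), amps(3 * nt), G2s(3 * nt);
  int L = 0;
  for (int i = 0; i < nt; ++i) {
    const double ct = th_u[i];
    const double c2 = ct * ct;
    const double Aeff = eff_aniso(avg.Apar, avg.Aperp, c2);
    const double geff = eff_aniso(avg.gpar, avg.gperp, c2);
    const double wfac = th_w[i] / 3.0;
    for (int mI = -1; mI <= 1; ++mI) {
      const double var = cpp_cone_variance(ct, mI, rig.Apar, rig.Aperp,
                                           rig.gpar, rig.gperp, C1,
                                           cn_xv, cn_wv, n_az);
      double G = W + kappa * tauc * var;
      if (G < GAMMA_MIN) G = GAMMA_MIN;
      B0s[L] = C1 / geff - mI * Aeff;
      amps[L] = -2.0 / M_PI * G * wfac;
      G2s[L] = G * G;
      ++L;
    }
  }
  std::vector<float> xs(nf), acc(nf, 0.0f);
  for (int p = 0; p < nf; ++p) xs[p] = (float)(fp[p] - fp[0]);
  for (int l = 0; l < L; ++l) {
    const float B0 = (float)(B0s[l] - fp[0]), amp = (float)amps[l],
                G2 = (float)G2s[l];
    for (int p = 0; p < nf; ++p) {
      const float x = xs[p] - B0;
      const float den = x * x + G2;
      acc[p] += amp * x / (den * den);
    }
  }
  // detrend + normalize (same arithmetic as cpp_normalize_deriv)
  const double span = fp[nf - 1] - fp[0];
  double tr = 0.0;
  for (int i = 1; i < nf; ++i)
    tr += 0.5 * ((double)acc[i] + (double)acc[i - 1]) * (fp[i] - fp[i - 1]);
  const double off = tr / span;
  for (int i = 0; i < nf; ++i) deriv[i] = (double)acc[i] - off;
  double cum = 0.0, I2 = 0.0;
  for (int i = 1; i < nf; ++i) {
    const double h = fp[i] - fp[i - 1];
    const double prev = cum;
    cum += 0.5 * (deriv[i] + deriv[i - 1]) * h;
    I2 += 0.5 * (cum + prev) * h;
  }
  if (!(I2 > 0.0)) return false;
  for (int i = 0; i < nf; ++i) deriv[i] /= I2;
  return true;
}

// Solve the K x K system M a = b by Gaussian elimination (K <= 5).
static bool solve_small(int K, double* M, double* b, double* a) {
  int idx[5];
  for (int i = 0; i < K; ++i) idx[i] = i;
  for (int c = 0; c < K; ++c) {
    int piv = c;
    for (int r = c + 1; r < K; ++r)
      if (std::fabs(M[idx[r] * K + c]) > std::fabs(M[idx[piv] * K + c]))
        piv = r;
    std::swap(idx[c], idx[piv]);
    const double m = M[idx[c] * K + c];
    if (std::fabs(m) < 1e-300) return false;
    for (int r = c + 1; r < K; ++r) {
      const double f = M[idx[r] * K + c] / m;
      for (int cc = c; cc < K; ++cc) M[idx[r] * K + cc] -= f * M[idx[c] * K + cc];
      b[idx[r]] -= f * b[idx[c]];
    }
  }
  for (int c = K - 1; c >= 0; --c) {
    double s = b[idx[c]];
    for (int cc = c + 1; cc < K; ++cc) s -= M[idx[c] * K + cc] * a[cc];
    a[c] = s / M[idx[c] * K + c];
  }
  return true;
}

// Non-negative least squares for K <= 5 by exhaustive support enumeration:
// the unrestricted solution on the optimal support is feasible and attains
// the NNLS optimum, so the feasible subset solution with minimal SSQ is it.
// Works on the normal equations: CtC (K x K), Cty (K), yty.
static double nnls_small(int K, const double* CtC, const double* Cty,
                         double yty, double* a_out) {
  double best = yty;  // empty support: a = 0
  for (int k = 0; k < K; ++k) a_out[k] = 0.0;
  const int nsub = (1 << K) - 1;
  for (int mask = 1; mask <= nsub; ++mask) {
    int cols[5], m = 0;
    for (int k = 0; k < K; ++k) if (mask & (1 << k)) cols[m++] = k;
    double M[25], b[5], a[5];
    for (int i = 0; i < m; ++i) {
      b[i] = Cty[cols[i]];
      for (int j = 0; j < m; ++j) M[i * m + j] = CtC[cols[i] * K + cols[j]];
    }
    if (!solve_small(m, M, b, a)) continue;
    bool feas = true;
    for (int i = 0; i < m; ++i) if (a[i] < 0.0) { feas = false; break; }
    if (!feas) continue;
    // ssq = yty - 2 a.Cty + a.CtC.a  (recompute CtC fresh, M was destroyed)
    double ssq = yty;
    for (int i = 0; i < m; ++i) {
      ssq -= 2.0 * a[i] * Cty[cols[i]];
      for (int j = 0; j < m; ++j)
        ssq += a[i] * a[j] * CtC[cols[i] * K + cols[j]];
    }
    if (ssq < best) {
      best = ssq;
      for (int k = 0; k < K; ++k) a_out[k] = 0.0;
      for (int i = 0; i < m; ++i) a_out[cols[i]] = a[i];
    }
  }
  return best;
}

// Batched HEO objective: for each genome (row of `genomes`, layout
// (S, tau_c, pA, pg, W) per component), simulate the K normalized
// components, profile the non-negative amplitudes by NNLS against the
// measured intensity, and return chi2 = SSQ / noise_sd^2 plus the
// proportions d = a / sum(a).  Degenerate genomes get `penalty`.
// [[Rcpp::export]]
List cpp_heo_objective(NumericMatrix genomes, int K,
                       NumericVector field, NumericVector y,
                       double Axx, double Ayy, double Azz,
                       double gxx, double gyy, double gzz,
                       double freq_Hz, double kappa,
                       NumericVector th_u, NumericVector th_w,
                       NumericVector cn_ref_x, NumericVector cn_ref_w,
                       int n_az, double noise_sd, double penalty) {
  const int P = genomes.nrow();
  const int nf = field.size();
  const double* fp = REAL(field);
  const double* yp = REAL(y);
  double yty = 0.0;
  for (int i = 0; i < nf; ++i) yty += yp[i] * yp[i];

  NumericVector chi2(P);
  NumericMatrix dmat(P, K);
  std::vector<double> C((size_t)nf * K);

  for (int r = 0; r < P; ++r) {
    bool ok = true;
    for (int k = 0; k < K && ok; ++k) {
      double g5[5];
      for (int j = 0; j < 5; ++j) g5[j] = genomes(r, k * 5 + j);
      ok = component_norm(fp, nf, Axx, Ayy, Azz, gxx, gyy, gzz, g5,
                          freq_Hz, kappa, REAL(th_u), REAL(th_w),
                          th_u.size(), REAL(cn_ref_x), REAL(cn_ref_w),
                          cn_ref_x.size(), n_az, &C[(size_t)nf * k]);
    }
    if (!ok) {
      chi2[r] = penalty;
      for (int k = 0; k < K; ++k) dmat(r, k) = 1.0 / K;
      continue;
    }
    double CtC[25], Cty[5], a[5];
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      const double* ci = &C[(size_t)nf * i];
      for (int p = 0; p < nf; ++p) s += ci[p] * yp[p];
      Cty[i] = s;
      for (int j = i; j < K; ++j) {
        double t = 0.0;
        const double* cj = &C[(size_t)nf * j];
        for (int p = 0; p < nf; ++p) t += ci[p] * cj[p];
        CtC[i * K + j] = t;
        CtC[j * K + i] = t;
      }
    }
    double ssq = nnls_small(K, CtC, Cty, yty, a);
    if (ssq < 1e-6 * yty) {
      // the normal-equations form cancels catastrophically for near-exact
      // fits; recompute the residual directly
      ssq = 0.0;
      for (int p = 0; p < nf; ++p) {
        double m = 0.0;
        for (int k = 0; k < K; ++k) m += a[k] * C[(size_t)nf * k + p];
        const double rres = yp[p] - m;
        ssq += rres * rres;
      }
    }
    chi2[r] = ssq / (noise_sd * noise_sd);
    double asum = 0.0;
    for (int k = 0; k < K; ++k) asum += a[k];
    for (int k = 0; k < K; ++k)
      dmat(r, k) = asum > 0.0 ? a[k] / asum : 1.0 / K;
  }
  return List::create(Named("chi2") = chi2, Named("d") = dmat);
}

// Plain weighted sum of first-derivative unit-area Lorentzians; generic
// accumulator used e.g. by Monte-Carlo orientation averages where centres,
// widths and weights come from elsewhere.
// [[Rcpp::export]]
NumericVector cpp_lorentzian_deriv_sum(NumericVector field,
                                       NumericVector B0, NumericVector G,
                                       NumericVector w) {
  const int nf = field.size();
  const int L = B0.size();
  NumericVector out(nf);
  const double* fp = REAL(field);
  double* op = REAL(out);
  for (int l = 0; l < L; ++l) {
    const double b = B0[l], g = G[l], amp = -2.0 / M_PI * G[l] * w[l];
    for (int p = 0; p < nf; ++p) {
      const double x = fp[p] - b;
      const double den = x * x + g * g;
      op[p] += amp * x / (den * den);
    }
  }
  return out;
}

// Detrend the raw analytic derivative so its trapezoid integral over the
// grid is exactly 0, reconstruct the absorption by cumulative trapezoid
// integration, and scale both so the absorption has unit trapezoid
// integral.  Mirrors the normalization contract of simulate_component().
// [[Rcpp::export]]
List cpp_normalize_deriv(NumericVector field, NumericVector raw) {
  const int n = field.size();
  const double span = field[n - 1] - field[0];
  double tr = 0.0;
  for (int i = 1; i < n; ++i)
    tr += 0.5 * (raw[i] + raw[i - 1]) * (field[i] - field[i - 1]);
  const double off = tr / span;
  NumericVector deriv(n), absorb(n);
  for (int i = 0; i < n; ++i) deriv[i] = raw[i] - off;
  double acc = 0.0, I2 = 0.0;
  absorb[0] = 0.0;
  for (int i = 1; i < n; ++i) {
    const double h = field[i] - field[i - 1];
    const double prev = acc;
    acc += 0.5 * (deriv[i] + deriv[i - 1]) * h;
    absorb[i] = acc;
    I2 += 0.5 * (acc + prev) * h;
  }
  if (!(I2 > 0.0))
    return List::create(Named("ok") = false);
  for (int i = 0; i < n; ++i) { deriv[i] /= I2; absorb[i] /= I2; }
  return List::create(Named("ok") = true,
                      Named("deriv") = deriv,
                      Named("absorption") = absorb);
}
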