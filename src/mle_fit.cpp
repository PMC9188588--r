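// Levenberg-Marquardt maximum-likelihood fitter for single-emitter ROIs.
//
// Likelihood: per-pixel-variance-aware Poisson model. The Gaussian
// (read + thermal) noise of variance v_k (photoelectron units) is folded
// into the Poisson likelihood by the variance-shift device: effective data
// d_k = e_k + v_k, effective model m_k = N*E_k(theta) + bg + v_k, and the
// objective is sum_k d_k*log(m_k) - m_k, maximized over
// theta = (x, y[, z], N, bg). E_k is the integrated (possibly astigmatic)
// Gaussian over unit pixels. Fisher scoring with LM damping; analytic
// gradients throughout.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

const double SQRT1_2 = 0.70710678118654752440;
const double INV_SQRT_2PI = 0.39894228040143267794;

inline double Phi(double u) { return 0.5 * std::erfc(-u * SQRT1_2); }
inline double phi(double u) { return INV_SQRT_2PI * std::exp(-0.5 * u * u); }

struct PsfPar {
  int model;            // 0 = gauss2d, 1 = astigmatic3d
  double s0x_px, s0y_px; // in-focus widths, pixels
  double gamma_nm, depth_nm, A, B;
};

// sigma (px) and d sigma / dz (px per nm) for one axis; sign = +1 for x
// (z - gamma), -1 for y (z + gamma).
inline void sigma_axis(const PsfPar& p, double z, double sign, double s0,
                       double& s, double& ds) {
  if (p.model == 0) { s = s0; ds = 0.0; return; }
  double u = (z - sign * p.gamma_nm) / p.depth_nm;
  double s2 = 1.0 + u * u + p.A * u * u * u + p.B * u * u * u * u;
  if (s2 < 1e-12) s2 = 1e-12;
  s = s0 * std::sqrt(s2);
  ds = s0 * s0 * (2.0 * u + 3.0 * p.A * u * u + 4.0 * p.B * u * u * u) /
       (2.0 * s * p.depth_nm);
}

// Integrated-Gaussian factors along one axis (n pixels) and derivatives
// with respect to center (px) and width (px).
inline void axis_terms(int n, double mu, double s, std::vector<double>& E,
                       std::vector<double>& dmu, std::vector<double>& dsg) {
  for (int j = 0; j < n; ++j) {
    double hi = (j + 1.0 - mu) / s, lo = (j - mu) / s;
    double phh = phi(hi), phl = phi(lo);
    E[j] = Phi(hi) - Phi(lo);
    dmu[j] = -(phh - phl) / s;
    dsg[j] = -(hi * phh - lo * phl) / s;
  }
}

struct Workspace {
  int nr, nc, np;
  std::vector<double> Ex, Ey, dEx, dEy, dSx, dSy;
  std::vector<double> mu;                 // model + v per pixel
  std::vector<std::vector<double>> J;     // np x npix derivatives
  Workspace(int nr_, int nc_, int np_)
      : nr(nr_), nc(nc_), np(np_), Ex(nc_), Ey(nr_), dEx(nc_), dEy(nr_),
        dSx(nc_), dSy(nr_), mu(nr_ * nc_),
        J(np_, std::vector<double>(nr_ * nc_)) {}
};

// Fill mu (including +v) and the Jacobian for parameter vector th.
void eval_model(const PsfPar& p, const double* v, const double* th,
                Workspace& w) {
  bool astig = p.model == 1;
  double x = th[0], y = th[1];
  double z = astig ? th[2] : 0.0;
  double N = th[astig ? 3 : 2], bg = th[astig ? 4 : 3];
  double sx, sy, dsx, dsy;
  sigma_axis(p, z, +1.0, p.s0x_px, sx, dsx);
  sigma_axis(p, z, -1.0, p.s0y_px, sy, dsy);
  axis_terms(w.nc, x, sx, w.Ex, w.dEx, w.dSx);
  axis_terms(w.nr, y, sy, w.Ey, w.dEy, w.dSy);

  int k = 0;
  for (int j = 0; j < w.nc; ++j) {
    for (int i = 0; i < w.nr; ++i, ++k) {
      double E = w.Ey[i] * w.Ex[j];
      w.mu[k] = N * E + bg + v[k];
      w.J[0][k] = N * w.Ey[i] * w.dEx[j];          // d/dx (px)
      w.J[1][k] = N * w.dEy[i] * w.Ex[j];          // d/dy (px)
      if (astig) {
        w.J[2][k] = N * (w.Ey[i] * w.dSx[j] * dsx + // d/dz (nm)
                         w.dSy[i] * w.Ex[j] * dsy);
        w.J[3][k] = E;
        w.J[4][k] = 1.0;
      } else {
        w.J[2][k] = E;
        w.J[3][k] = 1.0;
      }
    }
  }
}

inline double log_lik(const double* d, const Workspace& w) {
  double ll = 0.0;
  int npix = w.nr * w.nc;
  for (int k = 0; k < npix; ++k) {
    double m = w.mu[k] > 1e-6 ? w.mu[k] : 1e-6;
    ll += d[k] * std::log(m) - m;
  }
  return ll;
}

// Solve A x = b (np x np), Gaussian elimination with partial pivoting.
bool solve_sys(std::vector<double> A, std::vector<double> b, int n,
               std::vector<double>& x) {
  for (int c = 0; c < n; ++c) {
    int piv = c;
    for (int r = c + 1; r < n; ++r)
      if (std::fabs(A[r * n + c]) > std::fabs(A[piv * n + c])) piv = r;
    if (std::fabs(A[piv * n + c]) < 1e-300) return false;
    if (piv != c) {
      for (int cc = 0; cc < n; ++cc) std::swap(A[c * n + cc], A[piv * n + cc]);
      std::swap(b[c], b[piv]);
    }
    for (int r = c + 1; r < n; ++r) {
      double f = A[r * n + c] / A[c * n + c];
      for (int cc = c; cc < n; ++cc) A[r * n + cc] -= f * A[c * n + cc];
      b[r] -= f * b[c];
    }
  }
  x.assign(n, 0.0);
  for (int r = n - 1; r >= 0; --r) {
    double s = b[r];
    for (int cc = r + 1; cc < n; ++cc) s -= A[r * n + cc] * x[cc];
    x[r] = s / A[r * n + r];
  }
  return true;
}

inline void clamp_params(double* th, bool astig, int nr, int nc) {
  th[0] = std::min(std::max(th[0], 0.0), (double)nc);
  th[1] = std::min(std::max(th[1], 0.0), (double)nr);
  int iN = astig ? 3 : 2;
  if (astig) th[2] = std::min(std::max(th[2], -800.0), 800.0);
  th[iN] = std::max(th[iN], 1.0);
  th[iN + 1] = std::max(th[iN + 1], 0.0);
}

} // namespace

// [[Rcpp::export]]
NumericMatrix fit_mle_cpp(NumericMatrix d, NumericVector v, int nr, int nc,
                          int model, NumericVector psf_par,
                          NumericMatrix init, int max_iter = 50,
                          double tol_xy = 1e-4, double tol_z = 1e-2,
                          double tol_ph = 1e-2) {
  int npix = nr * nc, nrep = d.ncol();
  if (d.nrow() != npix || v.size() != npix)
    stop("data/variance dimensions do not match the ROI");
  PsfPar p;
  p.model = model;
  p.s0x_px = psf_par[0];
  p.s0y_px = psf_par[1];
  p.gamma_nm = psf_par[2];
  p.depth_nm = psf_par[3];
  p.A = psf_par[4];
  p.B = psf_par[5];
  bool astig = model == 1;
  int np = astig ? 5 : 4;
  if (init.ncol() != np || init.nrow() != nrep)
    stop("init must be nrep x n_params");

  Workspace w(nr, nc, np);
  NumericMatrix out(nrep, np + 3);
  std::vector<double> th(np), th_try(np), g(np), H(np * np), A(np * np),
      delta(np), tol(np);
  tol[0] = tol[1] = tol_xy;
  if (astig) tol[2] = tol_z;
  tol[np - 2] = tol_ph;
  tol[np - 1] = tol_ph;

  for (int r = 0; r < nrep; ++r) {
    const double* dr = &d(0, 0) + (size_t)r * npix;
    for (int i = 0; i < np; ++i) th[i] = init(r, i);
    clamp_params(th.data(), astig, nr, nc);
    eval_model(p, v.begin(), th.data(), w);
    double ll = log_lik(dr, w);
    double lambda = 1e-3;
    int iter = 0;
    bool converged = false;
    bool ws_current = true; // workspace evaluated at th?

    for (; iter < max_iter && !converged; ++iter) {
      // gradient and Fisher matrix at current theta (workspace may hold a
      // rejected trial point from the previous iteration)
      if (!ws_current) eval_model(p, v.begin(), th.data(), w);
      std::fill(g.begin(), g.end(), 0.0);
      std::fill(H.begin(), H.end(), 0.0);
      for (int k = 0; k < npix; ++k) {
        double m = w.mu[k] > 1e-6 ? w.mu[k] : 1e-6;
        double resid = dr[k] / m - 1.0;
        double invm = 1.0 / m;
        for (int a = 0; a < np; ++a) {
          double Ja = w.J[a][k];
          g[a] += resid * Ja;
          for (int b = a; b < np; ++b) H[a * np + b] += Ja * w.J[b][k] * invm;
        }
      }
      for (int a = 0; a < np; ++a)
        for (int b = 0; b < a; ++b) H[a * np + b] = H[b * np + a];

      bool stepped = false;
      for (int tries = 0; tries < 12 && !stepped; ++tries) {
        A = H;
        for (int a = 0; a < np; ++a)
          A[a * np + a] += lambda * std::max(H[a * np + a], 1e-12);
        if (!solve_sys(A, g, np, delta)) { lambda *= 10.0; continue; }
        for (int a = 0; a < np; ++a) th_try[a] = th[a] + delta[a];
        clamp_params(th_try.data(), astig, nr, nc);
        eval_model(p, v.begin(), th_try.data(), w);
        ws_current = false;
        double ll_try = log_lik(dr, w);
        if (ll_try >= ll) {
          bool small = true;
          for (int a = 0; a < np; ++a)
            if (std::fabs(th_try[a] - th[a]) > tol[a]) { small = false; break; }
          th = th_try;
          ll = ll_try;
          lambda = std::max(lambda * 0.3, 1e-9);
          stepped = true;
          ws_current = true; // workspace already at the accepted th
          converged = small;
        } else {
          lambda *= 10.0;
        }
      }
      if (!stepped) break; // damping exhausted; report flagged result
    }

    for (int a = 0; a < np; ++a) out(r, a) = th[a];
    out(r, np) = ll;
    out(r, np + 1) = iter;
    out(r, np + 2) = converged ? 1.0 : 0.0;
  }
  return out;
}
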