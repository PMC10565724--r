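#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Column-major 3D indexing with zero-flux closure at the faces: the ghost
// cell mirrors the edge cell (cell-centred reflection), so the 7-point
// Laplacian is in flux form and diffusion conserves mass exactly.
static inline int mir(int i, int n) {
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}
static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

static void get_dims(const NumericVector& f, int& nx, int& ny, int& nz) {
  IntegerVector d = f.attr("dim");
  if (d.size() != 3) stop("expected a 3D array");
  nx = d[0]; ny = d[1]; nz = d[2];
}

// Central differences in the interior, one-sided at the boundary faces.
static inline double dcomp(const double* f, int i, int j, int k,
                           int nx, int ny, int nz, int axis, double h) {
  int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  int c = (axis == 0) ? i : (axis == 1) ? j : k;
  int ip = std::min(c + 1, n - 1), im = std::max(c - 1, 0);
  if (ip == im) return 0.0;
  int vp, vm;
  if (axis == 0)      { vp = idx3(ip, j, k, nx, ny); vm = idx3(im, j, k, nx, ny); }
  else if (axis == 1) { vp = idx3(i, ip, k, nx, ny); vm = idx3(i, im, k, nx, ny); }
  else                { vp = idx3(i, j, ip, nx, ny); vm = idx3(i, j, im, nx, ny); }
  return (f[vp] - f[vm]) / ((ip - im) * h);
}

static inline double lap7(const double* f, int i, int j, int k,
                          int nx, int ny, int nz, double h2) {
  double c = f[idx3(i, j, k, nx, ny)];
  double s =
    f[idx3(mir(i - 1, nx), j, k, nx, ny)] + f[idx3(mir(i + 1, nx), j, k, nx, ny)] +
    f[idx3(i, mir(j - 1, ny), k, nx, ny)] + f[idx3(i, mir(j + 1, ny), k, nx, ny)] +
    f[idx3(i, j, mir(k - 1, nz), nx, ny)] + f[idx3(i, j, mir(k + 1, nz), nx, ny)];
  return (s - 6.0 * c) / h2;
}

// One-sided (upwind) difference of f at (i,j,k) along `axis` for transport
// velocity v: backward difference for v > 0, forward for v < 0.
static inline double dupw(const double* f, int i, int j, int k,
                          int nx, int ny, int nz, int axis, double h,
                          double v) {
  int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  int c = (axis == 0) ? i : (axis == 1) ? j : k;
  int o = (v > 0) ? std::max(c - 1, 0) : std::min(c + 1, n - 1);
  if (o == c) return 0.0;
  int vc = idx3(i, j, k, nx, ny), vo;
  if (axis == 0)      vo = idx3(o, j, k, nx, ny);
  else if (axis == 1) vo = idx3(i, o, k, nx, ny);
  else                vo = idx3(i, j, o, nx, ny);
  return (f[vc] - f[vo]) / ((c - o) * h);
}

// [[Rcpp::export]]
NumericVector cpp_gradient(NumericVector f, double h) {
  int nx, ny, nz; get_dims(f, nx, ny, nz);
  const double* p = f.begin();
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz * 3);
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  R_xlen_t N = static_cast<R_xlen_t>(nx) * ny * nz;
  double* o = out.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = idx3(i, j, k, nx, ny);
        o[v]         = dcomp(p, i, j, k, nx, ny, nz, 0, h);
        o[v + N]     = dcomp(p, i, j, k, nx, ny, nz, 1, h);
        o[v + 2 * N] = dcomp(p, i, j, k, nx, ny, nz, 2, h);
      }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_laplacian(NumericVector f, double h) {
  int nx, ny, nz; get_dims(f, nx, ny, nz);
  const double* p = f.begin();
  NumericVector out(no_init(f.size()));
  out.attr("dim") = f.attr("dim");
  double h2 = h * h;
  double* o = out.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        o[idx3(i, j, k, nx, ny)] = lap7(p, i, j, k, nx, ny, nz, h2);
  return out;
}

// Level-set mean curvature c = div(grad f / (|grad f| + eps)); 0 in the bulk.
// [[Rcpp::export]]
NumericVector cpp_curvature(NumericVector f, double h, double eps_norm,
                            double grad_min) {
  int nx, ny, nz; get_dims(f, nx, ny, nz);
  R_xlen_t N = static_cast<R_xlen_t>(nx) * ny * nz;
  const double* p = f.begin();
  std::vector<double> ux(N), uy(N), uz(N), gn(N);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = idx3(i, j, k, nx, ny);
        double gx = dcomp(p, i, j, k, nx, ny, nz, 0, h);
        double gy = dcomp(p, i, j, k, nx, ny, nz, 1, h);
        double gz = dcomp(p, i, j, k, nx, ny, nz, 2, h);
        double g = std::sqrt(gx * gx + gy * gy + gz * gz);
        gn[v] = g;
        ux[v] = gx / (g + eps_norm);
        uy[v] = gy / (g + eps_norm);
        uz[v] = gz / (g + eps_norm);
      }
  NumericVector out(f.size());
  out.attr("dim") = f.attr("dim");
  double* o = out.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = idx3(i, j, k, nx, ny);
        if (gn[v] < grad_min) { o[v] = 0.0; continue; }
        double c = dcomp(ux.data(), i, j, k, nx, ny, nz, 0, h) +
                   dcomp(uy.data(), i, j, k, nx, ny, nz, 1, h) +
                   dcomp(uz.data(), i, j, k, nx, ny, nz, 2, h);
        o[v] = c;
      }
  return out;
}

// Co-area surface estimator: sum |grad f| * h^3.
// [[Rcpp::export]]
double cpp_surface_area(NumericVector f, double h) {
  int nx, ny, nz; get_dims(f, nx, ny, nz);
  const double* p = f.begin();
  double s = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double gx = dcomp(p, i, j, k, nx, ny, nz, 0, h);
        double gy = dcomp(p, i, j, k, nx, ny, nz, 1, h);
        double gz = dcomp(p, i, j, k, nx, ny, nz, 2, h);
        s += std::sqrt(gx * gx + gy * gy + gz * gz);
      }
  return s * h * h * h;
}

// Zero-flux explicit diffusion (used for substrate interface relaxation).
// [[Rcpp::export]]
NumericVector cpp_diffuse(NumericVector f, double D, double dt, int nsteps,
                          double h) {
  int nx, ny, nz; get_dims(f, nx, ny, nz);
  R_xlen_t N = static_cast<R_xlen_t>(nx) * ny * nz;
  std::vector<double> a(f.begin(), f.end()), b(N);
  double h2 = h * h;
  for (int s = 0; s < nsteps; ++s) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t v = idx3(i, j, k, nx, ny);
          b[v] = a[v] + dt * D * lap7(a.data(), i, j, k, nx, ny, nz, h2);
        }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = f.attr("dim");
  return out;
}

// Chebyshev (box) dilation of a mask by r voxels, one axis pass at a time.
static void dilate_axis(std::vector<unsigned char>& m, int nx, int ny, int nz,
                        int axis, int r) {
  std::vector<unsigned char> out(m.size(), 0);
  int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!m[idx3(i, j, k, nx, ny)]) continue;
        int c = (axis == 0) ? i : (axis == 1) ? j : k;
        int lo = std::max(0, c - r), hi = std::min(n - 1, c + r);
        for (int t = lo; t <= hi; ++t) {
          if (axis == 0)      out[idx3(t, j, k, nx, ny)] = 1;
          else if (axis == 1) out[idx3(i, t, k, nx, ny)] = 1;
          else                out[idx3(i, j, t, nx, ny)] = 1;
        }
      }
  m.swap(out);
}

// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, int r) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t N = static_cast<R_xlen_t>(nx) * ny * nz;
  std::vector<unsigned char> m(N);
  for (R_xlen_t v = 0; v < N; ++v) m[v] = mask[v] ? 1 : 0;
  dilate_axis(m, nx, ny, nz, 0, r);
  dilate_axis(m, nx, ny, nz, 1, r);
  dilate_axis(m, nx, ny, nz, 2, r);
  LogicalVector out(N);
  for (R_xlen_t v = 0; v < N; ++v) out[v] = m[v] != 0;
  out.attr("dim") = mask.attr("dim");
  return out;
}

struct StepParams {
  double D_rho, D_p, alpha, lambda, tau1_inv, beta, gamma, sigma, mu,
         theta, epsilon, G, f0T, adh_scale;
};

// One fused explicit-Euler block for the coupled rho / p system, restricted
// to the active narrow band (rho >= 0.01 dilated by the 1-um buffer).
// [[Rcpp::export]]
List cpp_simulate_block(NumericVector rho0, NumericVector px0,
                        NumericVector py0, NumericVector pz0,
                        NumericVector phi2, NumericVector psi,
                        NumericVector kgx, NumericVector kgy,
                        NumericVector kgz, NumericVector wet,
                        double h, double dt, int nsub, int refresh_every,
                        List par, double V0, double A0,
                        double eps_norm, double grad_min,
                        bool full_domain, double band_tol) {
  int nx, ny, nz; get_dims(rho0, nx, ny, nz);
  R_xlen_t N = static_cast<R_xlen_t>(nx) * ny * nz;
  StepParams P;
  P.D_rho = par["D_rho"];   P.D_p = par["D_p"];     P.alpha = par["alpha"];
  P.lambda = par["lambda"]; P.tau1_inv = par["tau1_inv"];
  P.beta = par["beta"];     P.gamma = par["gamma"]; P.sigma = par["sigma"];
  P.mu = par["mu"];         P.theta = par["theta"]; P.epsilon = par["epsilon"];
  P.G = par["G"];           P.f0T = par["f0T"];
  P.adh_scale = par.containsElementNamed("adh_scale") ?
    (double)as<double>(par["adh_scale"]) : 1.0;
  double curv_mode = par.containsElementNamed("curv_signed") ?
    (double)as<double>(par["curv_signed"]) : 1.0;

  std::vector<double> rhoA(rho0.begin(), rho0.end()), rhoB(rhoA);
  std::vector<double> pxA(px0.begin(), px0.end()), pxB(pxA);
  std::vector<double> pyA(py0.begin(), py0.end()), pyB(pyA);
  std::vector<double> pzA(pz0.begin(), pz0.end()), pzB(pzA);
  const double* Phi2 = phi2.begin();
  const double* Psi  = psi.begin();
  const double* Kx = kgx.begin();
  const double* Ky = kgy.begin();
  const double* Kz = kgz.begin();
  const double* W  = wet.begin();

  std::vector<double> gx(N), gy(N), gz(N), gn(N), ux(N), uy(N), uz(N);
  std::vector<int> inner, ext;
  std::vector<int> ii(N), jj(N), kk(N); // coordinates per ext entry reuse
  int buf = std::max(1, (int)std::ceil(1.0 / h));

  double h2 = h * h, h3 = h * h * h;
  double A = NA_REAL, V = NA_REAL, zeta = 0.0;
  double max_drho = 0.0;
  bool ok = true;
  std::string err = "";

  std::vector<double>* rc = &rhoA; std::vector<double>* rn = &rhoB;
  std::vector<double>* pxc = &pxA; std::vector<double>* pxn = &pxB;
  std::vector<double>* pyc = &pyA; std::vector<double>* pyn = &pyB;
  std::vector<double>* pzc = &pzA; std::vector<double>* pzn = &pzB;

  for (int s = 0; s < nsub && ok; ++s) {
    if (s % refresh_every == 0) {
      // rebuild active band from the current rho
      std::vector<unsigned char> m(N, 0);
      for (R_xlen_t v = 0; v < N; ++v) m[v] = ((*rc)[v] >= band_tol) ? 1 : 0;
      if (full_domain) {
        for (R_xlen_t v = 0; v < N; ++v) m[v] = 1;
      } else {
        dilate_axis(m, nx, ny, nz, 0, buf);
        dilate_axis(m, nx, ny, nz, 1, buf);
        dilate_axis(m, nx, ny, nz, 2, buf);
      }
      std::vector<unsigned char> me(m);
      if (!full_domain) {
        dilate_axis(me, nx, ny, nz, 0, 1);
        dilate_axis(me, nx, ny, nz, 1, 1);
        dilate_axis(me, nx, ny, nz, 2, 1);
      }
      inner.clear(); ext.clear();
      for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            R_xlen_t v = idx3(i, j, k, nx, ny);
            if (me[v]) ext.push_back((int)v);
            if (m[v]) inner.push_back((int)v);
          }
      // keep the swap buffers in sync outside the (new) inner set
      *rn = *rc; *pxn = *pxc; *pyn = *pyc; *pzn = *pzc;
    }

    // pass 1: rho gradient + area/volume on the extended band
    const double* r = rc->data();
    double Asum = 0.0, Vsum = 0.0;
    for (size_t t = 0; t < ext.size(); ++t) {
      int v = ext[t];
      int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
      double a = dcomp(r, i, j, k, nx, ny, nz, 0, h);
      double b = dcomp(r, i, j, k, nx, ny, nz, 1, h);
      double c = dcomp(r, i, j, k, nx, ny, nz, 2, h);
      double g = std::sqrt(a * a + b * b + c * c);
      gx[v] = a; gy[v] = b; gz[v] = c; gn[v] = g;
      ux[v] = a / (g + eps_norm);
      uy[v] = b / (g + eps_norm);
      uz[v] = c / (g + eps_norm);
      Asum += g;
      Vsum += r[v];
    }
    A = Asum * h3;
    V = Vsum * h3;
    zeta = P.f0T * (A - A0) / A0;
    if (zeta < 0.0) zeta = 0.0;  // A0 is the minimum reference area
    double delta0 = 0.5 + P.mu * (V0 - V);

    const double* pxr = pxc->data();
    const double* pyr = pyc->data();
    const double* pzr = pzc->data();
    double* rw = rn->data();
    double* pxw = pxn->data();
    double* pyw = pyn->data();
    double* pzw = pzn->data();
    double md = 0.0;

    for (size_t t = 0; t < inner.size(); ++t) {
      int v = inner[t];
      int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
      double rv = r[v];
      double a = gx[v], b = gy[v], c = gz[v], g = gn[v];
      double pvx = pxr[v], pvy = pyr[v], pvz = pzr[v];
      double p2 = pvx * pvx + pvy * pvy + pvz * pvz;

      double lapr = lap7(r, i, j, k, nx, ny, nz, h2);
      double delta = delta0 - P.sigma * p2;
      double adv = P.alpha * (pvx * a + pvy * b + pvz * c);
      // adhesion: conformal transport toward the substrate (upwind, stable
      // under strong adhesion) plus the weaker graded wetting force — the
      // variational derivative of the contact energy
      // adh_scale * kappa * grad Phi . grad g(rho) — which makes the
      // spread footprint respond to the local adhesivity kappa
      double adh = -(
        Kx[v] * dupw(r, i, j, k, nx, ny, nz, 0, h, Kx[v]) +
        Ky[v] * dupw(r, i, j, k, nx, ny, nz, 1, h, Ky[v]) +
        Kz[v] * dupw(r, i, j, k, nx, ny, nz, 2, h, Kz[v])) +
        P.adh_scale * W[v] * 6.0 * rv * (1.0 - rv);
      // bistable boundary motion: threshold (1 - delta) keeps rho = 0 and 1
      // stable; delta > 1/2 advances the interface, delta < 1/2 retracts it
      double rr = P.D_rho * lapr - adv + adh - P.lambda * rv * Phi2[v] +
                  (1.0 - rv) * (rv - (1.0 - delta)) * rv;

      // membrane indicator and level-set curvature (only needed at membrane)
      double th = std::tanh(P.G * (rv - 0.5));
      double chi = 1.0 - th * th;
      double cur = 0.0;
      if (g >= grad_min) {
        cur = dcomp(ux.data(), i, j, k, nx, ny, nz, 0, h) +
              dcomp(uy.data(), i, j, k, nx, ny, nz, 1, h) +
              dcomp(uz.data(), i, j, k, nx, ny, nz, 2, h);
      }

      // theta-split actin source with rotation toward the substrate tangent
      double sx, sy, sz;
      double knx = Kx[v], kny = Ky[v], knz = Kz[v];
      double kn = std::sqrt(knx * knx + kny * kny + knz * knz);
      double tx = a, ty = b, tz = c;
      if (kn >= 1e-6) {
        knx /= kn; kny /= kn; knz /= kn;
        double dn = a * knx + b * kny + c * knz;
        tx = a - dn * knx; ty = b - dn * kny; tz = c - dn * knz;
        double tn = std::sqrt(tx * tx + ty * ty + tz * tz);
        if (tn < 1e-12) { tx = ty = tz = 0.0; }
        else { double sc = g / tn; tx *= sc; ty *= sc; tz *= sc; }
      }
      double e = (curv_mode > 0.5) ? (chi * zeta * cur)
                                     : (-chi * zeta * std::fabs(cur));
      if (e > 8.0) e = 8.0; else if (e < -8.0) e = -8.0;
      double wten = P.epsilon * chi * std::exp(e);
      double ps = Psi[v];
      sx = ps * ((1.0 - P.theta) * tx + P.theta * a) + wten * a;
      sy = ps * ((1.0 - P.theta) * ty + P.theta * b) + wten * b;
      sz = ps * ((1.0 - P.theta) * tz + P.theta * c) + wten * c;

      double lpx = lap7(pxr, i, j, k, nx, ny, nz, h2);
      double lpy = lap7(pyr, i, j, k, nx, ny, nz, h2);
      double lpz = lap7(pzr, i, j, k, nx, ny, nz, h2);
      double gp = a * pvx + b * pvy + c * pvz;
      double coef = P.tau1_inv + Phi2[v];
      double prx = P.D_p * lpx - coef * pvx - P.gamma * gp * pvx - P.beta * sx;
      double pry = P.D_p * lpy - coef * pvy - P.gamma * gp * pvy - P.beta * sy;
      double prz = P.D_p * lpz - coef * pvz - P.gamma * gp * pvz - P.beta * sz;

      double rnew = rv + dt * rr;
      rw[v] = rnew;
      pxw[v] = pvx + dt * prx;
      pyw[v] = pvy + dt * pry;
      pzw[v] = pvz + dt * prz;
      double d = std::fabs(rnew - rv);
      if (d > md) md = d;
      if (!std::isfinite(rnew) || std::fabs(rnew) > 2.0) {
        ok = false;
        err = "instability: |rho| > 2 or non-finite at voxel " +
              std::to_string(v + 1);
      }
    }
    max_drho = md;
    std::swap(rc, rn); std::swap(pxc, pxn);
    std::swap(pyc, pyn); std::swap(pzc, pzn);
  }

  NumericVector rOut(rc->begin(), rc->end());
  rOut.attr("dim") = rho0.attr("dim");
  NumericVector pxOut(pxc->begin(), pxc->end());
  pxOut.attr("dim") = rho0.attr("dim");
  NumericVector pyOut(pyc->begin(), pyc->end());
  pyOut.attr("dim") = rho0.attr("dim");
  NumericVector pzOut(pzc->begin(), pzc->end());
  pzOut.attr("dim") = rho0.attr("dim");
  return List::create(_["rho"] = rOut, _["px"] = pxOut, _["py"] = pyOut,
                      _["pz"] = pzOut, _["A"] = A, _["V"] = V,
                      _["zeta"] = zeta, _["max_drho"] = max_drho,
                      _["ok"] = ok, _["error"] = err,
                      _["n_active"] = (int)inner.size());
}

// 6-connected flood fill from seed voxels restricted to a mask; returns the
// reached set.
// [[Rcpp::export]]
LogicalVector cpp_flood6(LogicalVector mask, IntegerVector seeds) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  R_xlen_t N = static_cast<R_xlen_t>(nx) * ny * nz;
  std::vector<unsigned char> vis(N, 0);
  std::vector<int> stack;
  for (int s = 0; s < seeds.size(); ++s) {
    int v = seeds[s] - 1; // 1-based from R
    if (v >= 0 && v < N && mask[v] && !vis[v]) { vis[v] = 1; stack.push_back(v); }
  }
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    int i = v % nx, j = (v / nx) % ny, k = v / (nx * ny);
    const int off[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
    for (int q = 0; q < 6; ++q) {
      int ii = i + off[q][0], jj = j + off[q][1], kk = k + off[q][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      int w = idx3(ii, jj, kk, nx, ny);
      if (mask[w] && !vis[w]) { vis[w] = 1; stack.push_back(w); }
    }
  }
  LogicalVector out(N);
  for (R_xlen_t v = 0; v < N; ++v) out[v] = vis[v] != 0;
  out.attr("dim") = mask.attr("dim");
  return out;
}

// Volume fraction of a union of equal spheres in a box (per-axis periodic),
// by midpoint voxel sampling on a grid of spacing h.
// [[Rcpp::export]]
double cpp_sphere_union_fraction(NumericMatrix centers, double r,
                                 NumericVector box, double h,
                                 LogicalVector periodic) {
  int ns = centers.nrow();
  double bx = box[0], by = box[1], bz = box[2];
  bool px = periodic[0], py = periodic[1], pz = periodic[2];
  int nx = (int)std::round(bx / h), ny = (int)std::round(by / h),
      nz = (int)std::round(bz / h);
  double r2 = r * r;
  // cell list over spheres (cells no smaller than one radius)
  double cs = std::max(r, 1.0);
  int cxn = std::max(1, (int)std::floor(bx / cs));
  int cyn = std::max(1, (int)std::floor(by / cs));
  int czn = std::max(1, (int)std::floor(bz / cs));
  int reach = (int)std::ceil(r / (bx / cxn)) + 1;
  std::vector<std::vector<int> > cells(cxn * cyn * czn);
  for (int s = 0; s < ns; ++s) {
    int cx = std::min(cxn - 1, std::max(0, (int)(centers(s, 0) / bx * cxn)));
    int cy = std::min(cyn - 1, std::max(0, (int)(centers(s, 1) / by * cyn)));
    int cz = std::min(czn - 1, std::max(0, (int)(centers(s, 2) / bz * czn)));
    cells[cx + cxn * (cy + cyn * cz)].push_back(s);
  }
  int ry = (int)std::ceil(r / (by / cyn)) + 1;
  int rz = (int)std::ceil(r / (bz / czn)) + 1;
  long long inside = 0, total = (long long)nx * ny * nz;
  for (int k = 0; k < nz; ++k) {
    double z = (k + 0.5) * h;
    for (int j = 0; j < ny; ++j) {
      double y = (j + 0.5) * h;
      for (int i = 0; i < nx; ++i) {
        double x = (i + 0.5) * h;
        int cx = std::min(cxn - 1, (int)(x / bx * cxn));
        int cy = std::min(cyn - 1, (int)(y / by * cyn));
        int cz = std::min(czn - 1, (int)(z / bz * czn));
        bool in = false;
        for (int dz = -rz; dz <= rz && !in; ++dz)
          for (int dy = -ry; dy <= ry && !in; ++dy)
            for (int dx = -reach; dx <= reach && !in; ++dx) {
              int ax = cx + dx, ay = cy + dy, az = cz + dz;
              if (px) ax = (ax % cxn + cxn) % cxn;
              else if (ax < 0 || ax >= cxn) continue;
              if (py) ay = (ay % cyn + cyn) % cyn;
              else if (ay < 0 || ay >= cyn) continue;
              if (pz) az = (az % czn + czn) % czn;
              else if (az < 0 || az >= czn) continue;
              const std::vector<int>& cl = cells[ax + cxn * (ay + cyn * az)];
              for (size_t t = 0; t < cl.size(); ++t) {
                double ddx = x - centers(cl[t], 0);
                double ddy = y - centers(cl[t], 1);
                double ddz = z - centers(cl[t], 2);
                if (px) { if (ddx > bx / 2) ddx -= bx; if (ddx < -bx / 2) ddx += bx; }
                if (py) { if (ddy > by / 2) ddy -= by; if (ddy < -by / 2) ddy += by; }
                if (pz) { if (ddz > bz / 2) ddz -= bz; if (ddz < -bz / 2) ddz += bz; }
                if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) { in = true; break; }
              }
            }
        if (in) ++inside;
      }
    }
  }
  return (double)inside / (double)total;
}

// Steepest-descent settling of one sphere against a bed of placed spheres
// (periodic in x/y, floor at z = r), with a sticky-particle rolling budget.
// Mirrors the reference R implementation; kept in C++ for speed.
// [[Rcpp::export]]
NumericVector cpp_settle_sphere(NumericVector pos0, NumericMatrix centers,
                                double dmin, double r, double bx, double by,
                                double roll_budget) {
  double px = pos0[0], py = pos0[1], pz = pos0[2];
  int n = centers.nrow();
  double step = r / 2.0;
  bool contact = false;
  int rolls = 0;
  const double tol = 1e-9;

  for (;;) {
    double tx = px, ty = py, tz = pz - step;
    if (tz < r) tz = r;
    // project out of violations, worst first
    double ox = tx, oy = ty, oz = tz;
    for (int it = 0; it < 60; ++it) {
      int w = -1; double dw = 1e300;
      for (int s = 0; s < n; ++s) {
        double dx = std::fabs(centers(s, 0) - ox);
        if (dx > bx / 2) dx = bx - dx;
        double dy = std::fabs(centers(s, 1) - oy);
        if (dy > by / 2) dy = by - dy;
        double dz = centers(s, 2) - oz;
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (d < dmin - tol && d < dw) { dw = d; w = s; }
      }
      if (w < 0) break;
      double dx = ox - centers(w, 0);
      if (dx > bx / 2) dx -= bx; else if (dx < -bx / 2) dx += bx;
      double dy = oy - centers(w, 1);
      if (dy > by / 2) dy -= by; else if (dy < -by / 2) dy += by;
      double dz = oz - centers(w, 2);
      double nv = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (nv < 1e-9) { dx = 0; dy = 0; dz = 1; nv = 1; }
      ox = centers(w, 0) + dx / nv * dmin;
      oy = centers(w, 1) + dy / nv * dmin;
      oz = centers(w, 2) + dz / nv * dmin;
      ox -= bx * std::floor(ox / bx);
      oy -= by * std::floor(oy / by);
      if (oz < r) oz = r;
    }
    bool touched = (std::fabs(ox - tx) > 1e-12 || std::fabs(oy - ty) > 1e-12 ||
                    std::fabs(oz - tz) > 1e-12 || oz <= r + 1e-12);
    if (oz < pz - 1e-6) {
      px = ox; py = oy; pz = oz;
      if (contact) {
        if (++rolls >= roll_budget) break;
      }
      if (touched) contact = true;
    } else {
      if (touched) contact = true;
      step /= 2.0;
      if (step < 1e-3 * r) break;
    }
  }
  return NumericVector::create(px, py, pz);
}
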