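#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Backward-Euler / Newton solver for the normalized Fisher-Kolmogorov model
//   dn/dt = div(D grad n) + rho * n * (1 - n)
// on a masked voxel grid with zero-flux boundary conditions. The Laplacian is
// the 7-point finite-volume stencil restricted to the mask; fluxes across
// faces that leave the mask are omitted, which is the discrete analogue of
// the homogeneous Neumann condition. Each implicit step is solved by Newton
// iteration; the symmetric, diagonally dominant Newton systems are solved
// matrix-free with Jacobi-preconditioned conjugate gradients.

namespace {

struct Problem {
  int n;
  std::vector<int> nbr;   // n x 6, row-major, -1 where absent
  std::vector<int> deg;   // number of in-mask neighbours
  double inv_h2, D, rho, dt;

  // out = laplacian(u)
  void lap(const double* u, double* out) const {
    for (int i = 0; i < n; ++i) {
      const int* nb = &nbr[6 * i];
      double acc = -deg[i] * u[i];
      for (int k = 0; k < 6; ++k) {
        int j = nb[k];
        if (j >= 0) acc += u[j];
      }
      out[i] = acc * inv_h2;
    }
  }
  // y = J(u) x with J = I - dt*D*L - dt*rho*diag(1-2u)
  void jac(const double* x, const double* u, double* y, double* work) const {
    lap(x, work);
    for (int i = 0; i < n; ++i)
      y[i] = x[i] - dt * D * work[i] - dt * rho * (1.0 - 2.0 * u[i]) * x[i];
  }
  // F(u) = u - uold - dt*(D*L(u) + rho*u*(1-u)); returns ||F||
  double resid(const double* u, const double* uold, double* F,
               double* work) const {
    lap(u, work);
    double nrm2 = 0.0;
    for (int i = 0; i < n; ++i) {
      F[i] = u[i] - uold[i] -
        dt * (D * work[i] + rho * u[i] * (1.0 - u[i]));
      nrm2 += F[i] * F[i];
    }
    return std::sqrt(nrm2);
  }
};

struct Workspace {
  std::vector<double> F, work, dx, r, z, p, Ap, Mi;
  explicit Workspace(int n)
    : F(n), work(n), dx(n), r(n), z(n), p(n), Ap(n), Mi(n) {}
};

// Jacobi-preconditioned CG for J(u) dx = -F; returns success
bool pcg(const Problem& pb, const double* u, double tol, int maxit,
         Workspace& w) {
  const int n = pb.n;
  double bnrm = 0.0;
  for (int i = 0; i < n; ++i) {
    w.r[i] = -w.F[i];
    w.dx[i] = 0.0;
    bnrm += w.r[i] * w.r[i];
    double d = 1.0 + pb.dt * pb.D * pb.inv_h2 * pb.deg[i] -
      pb.dt * pb.rho * (1.0 - 2.0 * u[i]);
    w.Mi[i] = (std::abs(d) > 1e-300) ? 1.0 / d : 1.0;
  }
  bnrm = std::sqrt(bnrm);
  if (bnrm == 0.0) return true;
  const double target = tol * bnrm;
  double rz = 0.0;
  for (int i = 0; i < n; ++i) {
    w.z[i] = w.Mi[i] * w.r[i];
    rz += w.r[i] * w.z[i];
    w.p[i] = w.z[i];
  }
  for (int it = 0; it < maxit; ++it) {
    pb.jac(w.p.data(), u, w.Ap.data(), w.work.data());
    double pAp = 0.0;
    for (int i = 0; i < n; ++i) pAp += w.p[i] * w.Ap[i];
    if (pAp <= 0.0) return false;  // lost positive-definiteness
    const double alpha = rz / pAp;
    double rnrm2 = 0.0;
    for (int i = 0; i < n; ++i) {
      w.dx[i] += alpha * w.p[i];
      w.r[i] -= alpha * w.Ap[i];
      rnrm2 += w.r[i] * w.r[i];
    }
    if (std::sqrt(rnrm2) <= target) return true;
    double rz_new = 0.0;
    for (int i = 0; i < n; ++i) {
      w.z[i] = w.Mi[i] * w.r[i];
      rz_new += w.r[i] * w.z[i];
    }
    const double beta = rz_new / rz;
    rz = rz_new;
    for (int i = 0; i < n; ++i) w.p[i] = w.z[i] + beta * w.p[i];
  }
  return false;
}

// one backward-Euler step of size dt from uold into u (u starts at uold)
void be_step(std::vector<double>& u, const std::vector<double>& uold,
             const Problem& pb, Workspace& w,
             double newton_tol, int newton_max,
             double lin_tol, int lin_max, double clip_tol) {
  const int n = pb.n;
  double f0 = -1.0;
  bool done = false;
  // roundoff floor: ||F|| cannot drop below ~eps * sqrt(n) * scale(u)
  double unrm = 0.0;
  for (int i = 0; i < n; ++i) unrm += uold[i] * uold[i];
  const double atol = 1e-13 * std::sqrt((double)n) * (1.0 + std::sqrt(unrm));
  for (int it = 0; it <= newton_max; ++it) {
    double fn = pb.resid(u.data(), uold.data(), w.F.data(), w.work.data());
    if (it == 0) f0 = fn;
    if (fn <= std::max(newton_tol * f0, atol)) { done = true; break; }
    if (it == newton_max) break;
    if (!pcg(pb, u.data(), lin_tol, lin_max, w))
      stop("linear solver (CG) failed to converge in the implicit step");
    for (int i = 0; i < n; ++i) u[i] += w.dx[i];
  }
  if (!done)
    stop("Newton iteration did not converge within %d iterations "
         "(initial residual %g)", newton_max, f0);
  for (int i = 0; i < n; ++i) {
    if (u[i] < -clip_tol || u[i] > 1.0 + clip_tol)
      stop("density left [0,1] by more than the solver tolerance (value %g)",
           u[i]);
    if (u[i] < 0.0) u[i] = 0.0;
    if (u[i] > 1.0) u[i] = 1.0;
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix fk_simulate_cpp(NumericVector u0, IntegerMatrix nbr,
                              double spacing, double D, double rho,
                              double dt, double t0, NumericVector out_times,
                              double newton_tol, int newton_max,
                              double lin_tol, int lin_max,
                              double clip_tol) {
  const int n = u0.size(), m = out_times.size();
  if (nbr.nrow() != n) stop("neighbour table does not match state length");
  Problem pb;
  pb.n = n;
  pb.inv_h2 = 1.0 / (spacing * spacing);
  pb.D = D; pb.rho = rho; pb.dt = dt;
  pb.nbr.resize(6 * n);
  pb.deg.assign(n, 0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 6; ++k) {
      int j = nbr(i, k);
      pb.nbr[6 * i + k] = j;
      if (j >= 0) ++pb.deg[i];
    }
  Workspace w(n);
  std::vector<double> u(u0.begin(), u0.end()), uold(n);
  NumericMatrix out(n, m);
  double t = t0;
  long steps = 0;
  for (int j = 0; j < m; ++j) {
    const double T = out_times[j];
    if (T < t - 1e-9 * std::max(1.0, std::abs(t)))
      stop("output times must be sorted and >= the initial time");
    while (T - t > 1e-9) {
      double h = std::min(dt, T - t);
      uold = u;
      pb.dt = h;
      be_step(u, uold, pb, w, newton_tol, newton_max, lin_tol, lin_max,
              clip_tol);
      t += h;
      if (T - t < 1e-9) t = T;
      if (++steps % 256 == 0) Rcpp::checkUserInterrupt();
    }
    for (int i = 0; i < n; ++i) out(i, j) = u[i];
  }
  return out;
}
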