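#include <Rcpp.h>
using namespace Rcpp;

// Tridiagonal solve (Thomas algorithm) with constant coefficients.
// lower/diag/upper are the constant matrix bands; rhs is overwritten.
static void thomas_solve(int n, double lo, double di, double up,
                         std::vector<double> &cprime, std::vector<double> &rhs) {
  // forward sweep (cprime precomputed outside when reused)
  cprime[0] = up / di;
  rhs[0] = rhs[0] / di;
  for (int i = 1; i < n; ++i) {
    double m = di - lo * cprime[i - 1];
    cprime[i] = up / m;
    rhs[i] = (rhs[i] - lo * rhs[i - 1]) / m;
  }
  for (int i = n - 2; i >= 0; --i) rhs[i] -= cprime[i] * rhs[i + 1];
}

// Solve dF/dt = 0.5 F_zz + v F_z on z in (0, a), F(t,0)=0, F(t,a)=1,
// F(0,z)=0 for z<a (and 1 at z=a). Crank-Nicolson in t with two
// half-step backward-Euler startup steps (Rannacher smoothing) to damp
// oscillations from the discontinuous initial condition.
// Returns an (nt+1) x (nz+1) matrix: rows are times 0, dt, ..., nt*dt;
// columns are z = 0, h, ..., a.
// [[Rcpp::export]]
NumericMatrix cdf_pde_grid(double v, double a, int nz, double dt, int nt) {
  if (nz < 3 || nt < 1 || a <= 0 || dt <= 0)
    stop("invalid PDE grid specification");
  double h = a / nz;
  int n = nz - 1;  // interior nodes
  NumericMatrix F(nt + 1, nz + 1);
  std::vector<double> f(n, 0.0), rhs(n), cprime(n);

  // row 0: initial condition (interior zeros; boundary at z=a is 1)
  F(0, nz) = 1.0;

  // operator bands for step size tau:
  //   L f_j = (1/(2h^2))(f_{j+1}-2f_j+f_{j-1}) + (v/(2h))(f_{j+1}-f_{j-1})
  auto bands = [&](double tau, double theta, double &lo, double &di, double &up) {
    // (I - theta*tau*L) coefficients
    double p = theta * tau / (2.0 * h * h);
    double q = theta * tau * v / (2.0 * h);
    lo = -(p - q);
    di = 1.0 + 2.0 * p;
    up = -(p + q);
  };

  double lo_i, di_i, up_i;        // implicit side
  double lo_e, di_e, up_e;        // explicit side (CN only)

  // --- Rannacher startup: 2 backward-Euler steps of dt/2 ---
  bands(dt / 2.0, 1.0, lo_i, di_i, up_i);
  for (int s = 0; s < 2; ++s) {
    for (int j = 0; j < n; ++j) rhs[j] = f[j];
    rhs[n - 1] -= up_i * 1.0;  // boundary F(.,a)=1 moved to RHS
    thomas_solve(n, lo_i, di_i, up_i, cprime, rhs);
    f = rhs;
  }
  for (int j = 0; j < n; ++j) F(1, j + 1) = f[j];
  F(1, nz) = 1.0;

  // --- Crank-Nicolson for the remaining steps ---
  bands(dt, 0.5, lo_i, di_i, up_i);
  // explicit side: (I + 0.5*dt*L) has bands (-lo_i, 2-di_i, -up_i)
  lo_e = -lo_i; di_e = 2.0 - di_i; up_e = -up_i;
  for (int step = 2; step <= nt; ++step) {
    rhs[0] = di_e * f[0] + up_e * f[1];
    for (int j = 1; j < n - 1; ++j)
      rhs[j] = lo_e * f[j - 1] + di_e * f[j] + up_e * f[j + 1];
    rhs[n - 1] = lo_e * f[n - 2] + di_e * f[n - 1];
    rhs[n - 1] += (up_e - up_i) * 1.0;  // boundary contribution both sides
    thomas_solve(n, lo_i, di_i, up_i, cprime, rhs);
    f = rhs;
    for (int j = 0; j < n; ++j) {
      double x = f[j];
      if (x < 0.0) x = 0.0; else if (x > 1.0) x = 1.0;
      F(step, j + 1) = x;
    }
    F(step, nz) = 1.0;
  }

  // enforce monotonicity in t per z column (numerical safeguard; the
  // scheme is accurate to discretization error, this removes ~1e-12 ripples)
  for (int j = 1; j < nz; ++j) {
    double m = 0.0;
    for (int i = 0; i <= nt; ++i) {
      if (F(i, j) < m) F(i, j) = m; else m = F(i, j);
    }
  }
  return F;
}

// Euler-Maruyama first-passage simulation of the basic process.
// v and z are per-path vectors (absolute starting points); diffusion
// constant 1. Returns an n x 2 matrix: column 1 response (0 lower /
// 1 upper), column 2 decision time. Paths not absorbed by t_cap are
// assigned the nearer threshold at t_cap (mass below 10^-6 for sane caps).
// Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
NumericMatrix em_first_passage(NumericVector v, double a, NumericVector z,
                               double dt, double t_cap) {
  int n = v.size();
  if (z.size() != n) stop("v and z must have equal length");
  NumericMatrix out(n, 2);
  double sd = std::sqrt(dt);
  int max_steps = (int)std::ceil(t_cap / dt);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double x = z[i], drift = v[i] * dt;
    int step = 0;
    int resp = -1;
    while (step < max_steps) {
      x += drift + sd * norm_rand();
      ++step;
      if (x >= a) { resp = 1; break; }
      if (x <= 0.0) { resp = 0; break; }
    }
    if (resp < 0) resp = (x > a / 2.0) ? 1 : 0;
    out(i, 0) = resp;
    out(i, 1) = step * dt;
  }
  return out;
}
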