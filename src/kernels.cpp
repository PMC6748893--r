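#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Tridiagonal (Thomas) solve; a = sub, b = diag, c = sup, d = rhs (overwritten)
static void thomas(std::vector<double>& a, std::vector<double>& b,
                   std::vector<double>& c, std::vector<double>& d, int n) {
  for (int i = 1; i < n; ++i) {
    double w = a[i] / b[i - 1];
    b[i] -= w * c[i - 1];
    d[i] -= w * d[i - 1];
  }
  d[n - 1] /= b[n - 1];
  for (int i = n - 2; i >= 0; --i)
    d[i] = (d[i] - c[i] * d[i + 1]) / b[i];
}

static inline double harm(double a, double b) {
  double s = a + b;
  return s > 0 ? 2.0 * a * b / s : 0.0;
}

// One implicit-upwind ADI step (Lie splitting: x-part then y-part) of the
// conservative advection-diffusion equation on a uniform cell-centred grid.
// u: (nx+1) x ny face velocities, v: nx x (ny+1), D: nx x ny cell
// diffusivities. Boundary conditions: if closed == 0, Dirichlet c_in at the
// inlet (x = 0), zero-gradient outflow at x = L; if closed == 1, zero-flux
// x-boundaries. y-walls are always zero-flux. Implicit Euler in each sweep,
// unconditionally stable, non-negativity preserving (M-matrix).
// [[Rcpp::export]]
NumericMatrix cs_adi_step(NumericMatrix Cn, NumericMatrix u, NumericMatrix v,
                          NumericMatrix D, double dt, double dx, double dy,
                          double c_in, int closed) {
  int nx = Cn.nrow(), ny = Cn.ncol();
  NumericMatrix C = clone(Cn);
  std::vector<double> a(std::max(nx, ny)), b(std::max(nx, ny)),
      c(std::max(nx, ny)), d(std::max(nx, ny));

  // ---- x sweep ----
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double aw = 0, ap = 1, ae = 0, rhs = C(i, j);
      // west face (index i in u)
      double uf = u(i, j);
      double up = uf > 0 ? uf : 0, um = uf < 0 ? uf : 0;
      if (i == 0) {
        if (!closed) {
          double Df = D(0, j);
          ap += dt / dx * (-um + 2.0 * Df / dx);
          rhs += dt / dx * (up * c_in + 2.0 * Df * c_in / dx);
        } // closed: zero flux, nothing
      } else {
        double Df = harm(D(i - 1, j), D(i, j));
        aw -= dt / dx * (up + Df / dx);
        ap += dt / dx * (-um + Df / dx);
      }
      // east face (index i+1 in u)
      uf = u(i + 1, j);
      up = uf > 0 ? uf : 0; um = uf < 0 ? uf : 0;
      if (i == nx - 1) {
        if (!closed) ap += dt / dx * uf;  // outflow, zero-gradient
      } else {
        double Df = harm(D(i, j), D(i + 1, j));
        ap += dt / dx * (up + Df / dx);
        ae += dt / dx * (um - Df / dx);
      }
      a[i] = aw; b[i] = ap; c[i] = ae; d[i] = rhs;
    }
    thomas(a, b, c, d, nx);
    for (int i = 0; i < nx; ++i) C(i, j) = d[i];
  }

  // ---- y sweep ----
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      double as = 0, ap = 1, an = 0, rhs = C(i, j);
      if (j > 0) {
        double vf = v(i, j);
        double vp = vf > 0 ? vf : 0, vm = vf < 0 ? vf : 0;
        double Df = harm(D(i, j - 1), D(i, j));
        as -= dt / dy * (vp + Df / dy);
        ap += dt / dy * (-vm + Df / dy);
      }
      if (j < ny - 1) {
        double vf = v(i, j + 1);
        double vp = vf > 0 ? vf : 0, vm = vf < 0 ? vf : 0;
        double Df = harm(D(i, j), D(i, j + 1));
        ap += dt / dy * (vp + Df / dy);
        an += dt / dy * (vm - Df / dy);
      }
      a[j] = as; b[j] = ap; c[j] = an; d[j] = rhs;
    }
    thomas(a, b, c, d, ny);
    for (int j = 0; j < ny; ++j) C(i, j) = d[j];
  }
  return C;
}

// Evaluate per-species net rates (nM/s) for one cell's concentrations.
// rtype: 0 = first-order mass action (k1*[A]), 1 = second-order mass action
// (k1*[A][B]), 2 = Michaelis-Menten (k1*[A]*[B]/(k2+[B]), A = enzyme,
// B = substrate). gated reactions are multiplied by g.
static void cell_rates(const double* x, int nspec, int nr, const int* rtype,
                       const int* ia, const int* ib, const double* k1,
                       const double* k2, const double* stoich, // nr x nspec
                       const int* gated, double g, double* dC) {
  for (int s = 0; s < nspec; ++s) dC[s] = 0;
  for (int r = 0; r < nr; ++r) {
    double rate;
    if (rtype[r] == 0) rate = k1[r] * x[ia[r]];
    else if (rtype[r] == 1) rate = k1[r] * x[ia[r]] * x[ib[r]];
    else rate = k1[r] * x[ia[r]] * x[ib[r]] / (k2[r] + x[ib[r]]);
    if (gated[r]) rate *= g;
    if (rate == 0) continue;
    for (int s = 0; s < nspec; ++s) {
      double st = stoich[r + (size_t)nr * s];
      if (st != 0) dC[s] += st * rate;
    }
  }
}

// Advance the reaction network in every cell by dt using adaptive Heun (RK2)
// substeps. conc: ncell x nspec (nM), gate: per-cell multiplier for
// platelet-surface-gated reactions. Returns the updated matrix.
// [[Rcpp::export]]
NumericMatrix cs_react(NumericMatrix conc, IntegerVector rtype,
                       IntegerVector ia, IntegerVector ib, NumericVector k1,
                       NumericVector k2, NumericMatrix stoich,
                       IntegerVector gated, NumericVector gate, double dt,
                       double safety, int max_sub) {
  int ncell = conc.nrow(), nspec = conc.ncol(), nr = rtype.size();
  NumericMatrix out = clone(conc);
  std::vector<double> x(nspec), dC(nspec), x1(nspec), dC1(nspec);
  const double eps = 1e-3; // nM scale guard in relative-change control

  for (int cell = 0; cell < ncell; ++cell) {
    for (int s = 0; s < nspec; ++s) x[s] = out(cell, s);
    double g = gate[cell];
    double rem = dt;
    double h = dt;
    int sub = 0;
    while (rem > 1e-12 * dt && sub < max_sub) {
      cell_rates(x.data(), nspec, nr, rtype.begin(), ia.begin(), ib.begin(),
                 k1.begin(), k2.begin(), stoich.begin(), gated.begin(), g,
                 dC.data());
      double lam = 0;
      for (int s = 0; s < nspec; ++s) {
        double l = std::fabs(dC[s]) / (x[s] + eps);
        if (l > lam) lam = l;
      }
      if (lam * rem < 1e-10) break; // chemically inert cell
      if (h > rem) h = rem;
      // Heun trial with embedded Euler/Heun error estimate
      for (;;) {
        for (int s = 0; s < nspec; ++s) {
          x1[s] = x[s] + h * dC[s];
          if (x1[s] < 0) x1[s] = 0;
        }
        cell_rates(x1.data(), nspec, nr, rtype.begin(), ia.begin(),
                   ib.begin(), k1.begin(), k2.begin(), stoich.begin(),
                   gated.begin(), g, dC1.data());
        double err = 0;
        for (int s = 0; s < nspec; ++s) {
          double e = 0.5 * h * std::fabs(dC1[s] - dC[s]) / (x[s] + eps);
          if (e > err) err = e;
        }
        if (err <= safety || h <= 1e-9 * dt) {
          for (int s = 0; s < nspec; ++s) {
            x[s] += 0.5 * h * (dC[s] + dC1[s]);
            if (x[s] < 0) x[s] = 0;
          }
          rem -= h;
          double grow = err > 0 ? 0.9 * std::sqrt(safety / err) : 2.0;
          if (grow > 2.0) grow = 2.0;
          h *= grow;
          break;
        }
        h *= std::max(0.1, 0.9 * std::sqrt(safety / err));
        ++sub;
        if (sub >= max_sub) break;
      }
      ++sub;
    }
    for (int s = 0; s < nspec; ++s) out(cell, s) = x[s];
  }
  return out;
}
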