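// Hot numerical kernels of the immersed-boundary relaxation:
// Peskin-kernel spreading/interpolation and the projection substep on the
// MAC staggered grid. The 1D operator eigenbases are precomputed in R
// (ibm_workspace); each solve here is a pair of dense products.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// 4-point cosine kernel, argument in grid-cell units.
static inline double phi4(double r) {
  double a = std::fabs(r);
  return a < 2.0 ? 0.25 * (1.0 + std::cos(M_PI * r / 2.0)) : 0.0;
}

// Spread point forces F at positions X onto a component grid with node
// coordinates (x0 + i*h, y0 + j*h), i = 0..n1-1, j = 0..n2-1.
// [[Rcpp::export]]
arma::mat cpp_spread(const arma::mat& X, const arma::vec& F, double x0,
                     double y0, double h, int n1, int n2) {
  mat out(n1, n2, fill::zeros);
  double inv_h2 = 1.0 / (h * h);
  for (uword p = 0; p < X.n_rows; ++p) {
    double gx = (X(p, 0) - x0) / h, gy = (X(p, 1) - y0) / h;
    int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy);
    for (int a = -1; a <= 2; ++a) {
      int i = i0 + a;
      if (i < 0 || i >= n1) continue;
      double wx = phi4(gx - i);
      if (wx == 0.0) continue;
      for (int b = -1; b <= 2; ++b) {
        int j = j0 + b;
        if (j < 0 || j >= n2) continue;
        double wy = phi4(gy - j);
        if (wy != 0.0) out(i, j) += F(p) * wx * wy * inv_h2;
      }
    }
  }
  return out;
}

// Adjoint interpolation of a component field at positions X (same kernel).
// [[Rcpp::export]]
arma::vec cpp_interp(const arma::mat& fld, const arma::mat& X, double x0,
                     double y0, double h) {
  int n1 = fld.n_rows, n2 = fld.n_cols;
  vec out(X.n_rows, fill::zeros);
  for (uword p = 0; p < X.n_rows; ++p) {
    double gx = (X(p, 0) - x0) / h, gy = (X(p, 1) - y0) / h;
    int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy);
    double acc = 0.0;
    for (int a = -1; a <= 2; ++a) {
      int i = i0 + a;
      if (i < 0 || i >= n1) continue;
      double wx = phi4(gx - i);
      if (wx == 0.0) continue;
      for (int b = -1; b <= 2; ++b) {
        int j = j0 + b;
        if (j < 0 || j >= n2) continue;
        double wy = phi4(gy - j);
        if (wy != 0.0) acc += fld(i, j) * wx * wy;
      }
    }
    out(p) = acc;
  }
  return out;
}

// Clamped bilinear sample on a node grid (x0 + i*h, y0 + j*h).
static inline double bilin(const mat& f, double gx, double gy) {
  int n1 = f.n_rows, n2 = f.n_cols;
  int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy);
  if (i0 < 0) i0 = 0; if (i0 > n1 - 2) i0 = n1 - 2;
  if (j0 < 0) j0 = 0; if (j0 > n2 - 2) j0 = n2 - 2;
  double fx = gx - i0, fy = gy - j0;
  if (fx < 0) fx = 0; if (fx > 1) fx = 1;
  if (fy < 0) fy = 0; if (fy > 1) fy = 1;
  return f(i0, j0) * (1 - fx) * (1 - fy) + f(i0 + 1, j0) * fx * (1 - fy) +
         f(i0, j0 + 1) * (1 - fx) * fy + f(i0 + 1, j0 + 1) * fx * fy;
}

// One projection substep: semi-Lagrangian convection, implicit diffusion by
// tensor eigen-solves (Dirichlet box), source-modified Neumann Poisson
// correction. Returns u, v, Pi.
// [[Rcpp::export]]
Rcpp::List cpp_ibm_substep(const arma::mat& u, const arma::mat& v,
                           const arma::mat& fx, const arma::mat& fy,
                           const arma::mat& source,
                           const arma::mat& Qux, const arma::mat& Quy,
                           const arma::mat& du,
                           const arma::mat& Qvx, const arma::mat& Qvy,
                           const arma::mat& dv,
                           const arma::mat& Qpx, const arma::mat& Qpy,
                           const arma::mat& lam_p, int izero,
                           double h, double dt, double rho) {
  int nx = source.n_rows, ny = source.n_cols;
  mat u_adv = u, v_adv = v;

  double vmax = std::max(arma::abs(u).max(), arma::abs(v).max());
  if (vmax * dt > 1e-9 * h) {
    // u nodes: (i*h, (j+0.5)h) in grid units of each component grid
    // absolute coordinates a = (x - ox)/h, b = (y - oy)/h; the u-grid frame
    // is (a, b - 0.5), the v-grid frame (a - 0.5, b)
    for (int i = 0; i <= nx; ++i) {
      for (int j = 0; j < ny; ++j) {
        double a = i, b = j + 0.5;
        double vv = bilin(v, a - 0.5, b);
        double da = a - dt * u(i, j) / h, db = b - dt * vv / h;
        u_adv(i, j) = bilin(u, da, db - 0.5);
      }
    }
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j <= ny; ++j) {
        double a = i + 0.5, b = j;
        double uu = bilin(u, a, b - 0.5);
        double da = a - dt * uu / h, db = b - dt * v(i, j) / h;
        v_adv(i, j) = bilin(v, da - 0.5, db);
      }
    }
  }

  // predictor with implicit diffusion (interior unknowns; box faces no-slip)
  mat us(nx + 1, ny, fill::zeros), vs(nx, ny + 1, fill::zeros);
  {
    mat bu = u_adv.rows(1, nx - 1) + (dt / rho) * fx.rows(1, nx - 1);
    us.rows(1, nx - 1) = Qux * ((Qux.t() * bu * Quy) / du) * Quy.t();
    mat bv = v_adv.cols(1, ny - 1) + (dt / rho) * fy.cols(1, ny - 1);
    vs.cols(1, ny - 1) = Qvx * ((Qvx.t() * bv * Qvy) / dv) * Qvy.t();
  }

  // corrector: Lap(Pi) = (rho/dt) (div V* - s), homogeneous Neumann
  mat div = (us.rows(1, nx) - us.rows(0, nx - 1)) / h +
            (vs.cols(1, ny) - vs.cols(0, ny - 1)) / h;
  mat rhs = (rho / dt) * (div - source);
  rhs -= accu(rhs) / (nx * ny);
  mat Bh = (Qpx.t() * rhs * Qpy) / lam_p;
  Bh(izero - 1) = 0.0;  // constant mode (1-based index from R)
  mat Pi = Qpx * Bh * Qpy.t();

  mat un = us, vn = vs;
  un.rows(1, nx - 1) -= (dt / rho) * (Pi.rows(1, nx - 1) -
                                      Pi.rows(0, nx - 2)) / h;
  vn.cols(1, ny - 1) -= (dt / rho) * (Pi.cols(1, ny - 1) -
                                      Pi.cols(0, ny - 2)) / h;
  return Rcpp::List::create(Rcpp::Named("u") = un, Rcpp::Named("v") = vn,
                            Rcpp::Named("Pi") = Pi);
}

// TRUE when the closed polyline has no self-intersection (proper crossings
// of non-adjacent segments).
// [[Rcpp::export]]
bool cpp_curve_simple(const arma::mat& P) {
  int n = P.n_rows;
  auto cross = [](double ax, double ay, double bx, double by) {
    return ax * by - ay * bx;
  };
  for (int i = 0; i < n - 2; ++i) {
    int i2 = i + 1;
    double ax = P(i, 0), ay = P(i, 1), bx = P(i2, 0), by = P(i2, 1);
    int jmax = (i == 0) ? n - 1 : n;
    for (int j = i + 2; j < jmax; ++j) {
      int j2 = (j + 1) % n;
      double cx = P(j, 0), cy = P(j, 1), dx = P(j2, 0), dy = P(j2, 1);
      double d1 = cross(bx - ax, by - ay, cx - ax, cy - ay);
      double d2 = cross(bx - ax, by - ay, dx - ax, dy - ay);
      double d3 = cross(dx - cx, dy - cy, ax - cx, ay - cy);
      double d4 = cross(dx - cx, dy - cy, bx - cx, by - cy);
      if (d1 * d2 < 0 && d3 * d4 < 0) return false;
    }
  }
  return true;
}

// Summed pairwise repulsion velocities between same-layer cells; linear
// decay to zero at the cutoff, or the Lennard-Jones-like alternative.
// Coincident centres are reported back (1-based indices) for the caller to
// resolve with a random direction.
// [[Rcpp::export]]
Rcpp::List cpp_repulsion(const arma::vec& x, const arma::vec& y,
                         const arma::ivec& layer, double k_S, double cutoff,
                         double r_eq, bool lennard_jones) {
  int n = x.n_elem;
  mat out(n, 2, fill::zeros);
  std::vector<int> coincident;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (layer(i) != layer(j)) continue;
      double dx = x(i) - x(j), dy = y(i) - y(j);
      double d = std::sqrt(dx * dx + dy * dy);
      if (d >= cutoff) continue;
      if (d < 1e-12) {
        coincident.push_back(i + 1);
        coincident.push_back(j + 1);
        continue;
      }
      double mag = lennard_jones
        ? k_S * (std::pow(r_eq / d, 4) - std::pow(r_eq / d, 2))
        : k_S * (1.0 - d / cutoff);
      double ux = dx / d, uy = dy / d;
      out(i, 0) += mag * ux; out(i, 1) += mag * uy;
      out(j, 0) -= mag * ux; out(j, 1) -= mag * uy;
    }
  }
  return Rcpp::List::create(Rcpp::Named("v") = out,
                            Rcpp::Named("coincident") = coincident);
}
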