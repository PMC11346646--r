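// Matrix-free finite-volume operator and preconditioned conjugate-gradient
// solver for div(sigma grad V) = 0 on a structured voxel grid.
//
// Conventions shared with the R side:
//   uidx[p]  : 0 = excluded voxel (exterior air, hard Neumann),
//             -1 = fixed potential voxel (grounded cathode / Dirichlet),
//             >0 = 1-based unknown id; several voxels may share one id
//                  (equipotential metal terminal collapsed to one unknown).
//   gx[p]    : face conductance (S) between voxel p and its +x neighbour
//              (stored on the full grid; the last slice along x is unused).
//   gy, gz   : likewise for +y / +z neighbours.
// Faces with g = 0 carry no current (exterior faces: Neumann by omission).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  const int* u;
  const double* gx;
  const double* gy;
  const double* gz;
};

// Apply f(p, q, g) to every face with nonzero conductance; p < q.
template <typename F>
inline void for_each_face(const Grid& g, F f) {
  const int nx = g.nx, ny = g.ny, nz = g.nz;
  const long sx = 1, sy = nx, sz = (long)nx * ny;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      long base = (long)j * nx + (long)k * sz;
      for (int i = 0; i < nx; ++i) {
        long p = base + i;
        if (i + 1 < nx && g.gx[p] != 0.0) f(p, p + sx, g.gx[p]);
        if (j + 1 < ny && g.gy[p] != 0.0) f(p, p + sy, g.gy[p]);
        if (k + 1 < nz && g.gz[p] != 0.0) f(p, p + sz, g.gz[p]);
      }
    }
}

Grid make_grid(const IntegerVector& dims, const IntegerVector& uidx,
               const NumericVector& gx, const NumericVector& gy,
               const NumericVector& gz) {
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.u = INTEGER(uidx);
  g.gx = REAL(gx); g.gy = REAL(gy); g.gz = REAL(gz);
  return g;
}

void matvec(const Grid& g, const double* x, double* y, int n) {
  for (int t = 0; t < n; ++t) y[t] = 0.0;
  for_each_face(g, [&](long p, long q, double gc) {
    int up = g.u[p], uq = g.u[q];
    if (up > 0 && uq > 0) {
      if (up != uq) {
        double d = x[up - 1] - x[uq - 1];
        y[up - 1] += gc * d;
        y[uq - 1] -= gc * d;
      }
    } else if (up > 0 && uq == -1) {
      y[up - 1] += gc * x[up - 1];
    } else if (uq > 0 && up == -1) {
      y[uq - 1] += gc * x[uq - 1];
    }
  });
}

} // namespace

// [[Rcpp::export]]
NumericVector fv_matvec(IntegerVector dims, IntegerVector uidx,
                        NumericVector gx, NumericVector gy, NumericVector gz,
                        NumericVector x) {
  Grid g = make_grid(dims, uidx, gx, gy, gz);
  int n = x.size();
  NumericVector y(n);
  matvec(g, REAL(x), REAL(y), n);
  return y;
}

// [[Rcpp::export]]
NumericVector fv_diag(IntegerVector dims, IntegerVector uidx,
                      NumericVector gx, NumericVector gy, NumericVector gz,
                      int n) {
  Grid g = make_grid(dims, uidx, gx, gy, gz);
  NumericVector d(n);
  double* dp = REAL(d);
  for_each_face(g, [&](long p, long q, double gc) {
    int up = g.u[p], uq = g.u[q];
    if (up > 0 && uq > 0) {
      if (up != uq) { dp[up - 1] += gc; dp[uq - 1] += gc; }
    } else if (up > 0 && uq == -1) {
      dp[up - 1] += gc;
    } else if (uq > 0 && up == -1) {
      dp[uq - 1] += gc;
    }
  });
  return d;
}

// Right-hand-side contribution of fixed-potential voxels: b[u] += g * vfix.
// [[Rcpp::export]]
NumericVector fv_rhs_fixed(IntegerVector dims, IntegerVector uidx,
                           NumericVector gx, NumericVector gy, NumericVector gz,
                           NumericVector vfix, int n) {
  Grid g = make_grid(dims, uidx, gx, gy, gz);
  NumericVector b(n);
  double* bp = REAL(b);
  const double* vf = REAL(vfix);
  for_each_face(g, [&](long p, long q, double gc) {
    int up = g.u[p], uq = g.u[q];
    if (up > 0 && uq == -1) bp[up - 1] += gc * vf[q];
    else if (uq > 0 && up == -1) bp[uq - 1] += gc * vf[p];
  });
  return b;
}

// Flags unknowns reachable (through nonzero-conductance faces) from any
// fixed-potential voxel. Used to detect a floating anode terminal, which
// would make the grounded system singular.
// [[Rcpp::export]]
LogicalVector fv_reachable_from_fixed(IntegerVector dims, IntegerVector uidx,
                                      NumericVector gx, NumericVector gy,
                                      NumericVector gz, int n) {
  Grid g = make_grid(dims, uidx, gx, gy, gz);
  const long nvox = (long)g.nx * g.ny * g.nz;
  const long sx = 1, sy = g.nx, sz = (long)g.nx * g.ny;
  std::vector<char> vis(nvox, 0);
  std::vector<long> queue;
  queue.reserve(4096);
  // Seed: voxels with a conductive face to a fixed-potential voxel.
  for_each_face(g, [&](long p, long q, double) {
    int up = g.u[p], uq = g.u[q];
    if (up > 0 && uq == -1 && !vis[p]) { vis[p] = 1; queue.push_back(p); }
    else if (uq > 0 && up == -1 && !vis[q]) { vis[q] = 1; queue.push_back(q); }
  });
  // Voxel-level BFS across conductive faces between unknown voxels; voxels
  // sharing a collapsed terminal id count as reached once any member is.
  size_t head = 0;
  while (head < queue.size()) {
    long p = queue[head++];
    int i = (int)(p % g.nx);
    int j = (int)((p / g.nx) % g.ny);
    int k = (int)(p / sz);
    auto try_go = [&](long q, double gc) {
      if (gc != 0.0 && g.u[q] > 0 && !vis[q]) { vis[q] = 1; queue.push_back(q); }
    };
    if (i + 1 < g.nx) try_go(p + sx, g.gx[p]);
    if (i > 0)        try_go(p - sx, g.gx[p - sx]);
    if (j + 1 < g.ny) try_go(p + sy, g.gy[p]);
    if (j > 0)        try_go(p - sy, g.gy[p - sy]);
    if (k + 1 < g.nz) try_go(p + sz, g.gz[p]);
    if (k > 0)        try_go(p - sz, g.gz[p - sz]);
  }
  LogicalVector out(n);
  for (long p = 0; p < nvox; ++p)
    if (vis[p] && g.u[p] > 0) out[g.u[p] - 1] = true;
  return out;
}

// Jacobi-preconditioned conjugate gradient with a relative-residual
// (||r|| / ||b||) stopping rule.
// [[Rcpp::export]]
List fv_pcg(IntegerVector dims, IntegerVector uidx,
            NumericVector gx, NumericVector gy, NumericVector gz,
            NumericVector b, double tol, int max_iter,
            Nullable<NumericVector> x0 = R_NilValue) {
  Grid g = make_grid(dims, uidx, gx, gy, gz);
  const int n = b.size();
  NumericVector diag = fv_diag(dims, uidx, gx, gy, gz, n);
  const double* dp = REAL(diag);
  for (int t = 0; t < n; ++t)
    if (dp[t] <= 0.0)
      stop("singular system: unknown %d has no conductive faces", t + 1);

  std::vector<double> x(n, 0.0), r(n), z(n), p(n), q(n);
  if (x0.isNotNull()) {
    NumericVector xv(x0);
    if (xv.size() != n) stop("x0 has wrong length");
    std::copy(xv.begin(), xv.end(), x.begin());
  }
  const double* bp = REAL(b);
  double bnorm = 0.0;
  for (int t = 0; t < n; ++t) bnorm += bp[t] * bp[t];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) {
    return List::create(_["x"] = NumericVector(n), _["iterations"] = 0,
                        _["rel_residual"] = 0.0, _["converged"] = true,
                        _["resid_history"] = NumericVector::create(0.0));
  }

  matvec(g, x.data(), q.data(), n);
  double rnorm2 = 0.0, rho = 0.0;
  for (int t = 0; t < n; ++t) {
    r[t] = bp[t] - q[t];
    z[t] = r[t] / dp[t];
    p[t] = z[t];
    rho += r[t] * z[t];
    rnorm2 += r[t] * r[t];
  }
  std::vector<double> hist;
  hist.push_back(std::sqrt(rnorm2) / bnorm);
  int it = 0;
  bool converged = hist.back() <= tol;
  while (!converged && it < max_iter) {
    matvec(g, p.data(), q.data(), n);
    double pq = 0.0;
    for (int t = 0; t < n; ++t) pq += p[t] * q[t];
    if (!std::isfinite(pq) || pq <= 0.0) break; // breakdown: singular/indefinite
    double alpha = rho / pq;
    rnorm2 = 0.0;
    for (int t = 0; t < n; ++t) {
      x[t] += alpha * p[t];
      r[t] -= alpha * q[t];
      rnorm2 += r[t] * r[t];
    }
    ++it;
    hist.push_back(std::sqrt(rnorm2) / bnorm);
    if (hist.back() <= tol) { converged = true; break; }
    double rho_new = 0.0;
    for (int t = 0; t < n; ++t) {
      z[t] = r[t] / dp[t];
      rho_new += r[t] * z[t];
    }
    double beta = rho_new / rho;
    rho = rho_new;
    for (int t = 0; t < n; ++t) p[t] = z[t] + beta * p[t];
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["x"] = NumericVector(x.begin(), x.end()),
    _["iterations"] = it,
    _["rel_residual"] = hist.back(),
    _["converged"] = converged,
    _["resid_history"] = NumericVector(hist.begin(), hist.end()));
}
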