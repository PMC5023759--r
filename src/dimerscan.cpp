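#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Deterministic, roughly uniform points on the unit sphere (golden-section
// spiral). Used by the Shrake-Rupley quadrature.
static std::vector<double> sphere_points(int n) {
  std::vector<double> pts(3 * n);
  const double phi = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n; ++i) {
    double z = 1.0 - 2.0 * (i + 0.5) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = phi * i;
    pts[3 * i] = r * std::cos(th);
    pts[3 * i + 1] = r * std::sin(th);
    pts[3 * i + 2] = z;
  }
  return pts;
}

// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix xyz, NumericVector radii,
                       double probe, int n_points) {
  int n = xyz.nrow();
  NumericVector area(n);
  std::vector<double> pts = sphere_points(n_points);
  // expanded radii
  std::vector<double> R(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) {
    R[i] = radii[i] + probe;
    if (R[i] > rmax) rmax = R[i];
  }
  // neighbour lists via a coarse cell grid (cell = 2*rmax)
  double cell = 2.0 * rmax;
  double ox = R_PosInf, oy = R_PosInf, oz = R_PosInf;
  for (int i = 0; i < n; ++i) {
    ox = std::min(ox, xyz(i, 0)); oy = std::min(oy, xyz(i, 1));
    oz = std::min(oz, xyz(i, 2));
  }
  auto cix = [&](double v, double o) { return (int)std::floor((v - o) / cell); };
  int nx = 0, ny = 0, nz = 0;
  std::vector<int> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = cix(xyz(i, 0), ox); cy[i] = cix(xyz(i, 1), oy); cz[i] = cix(xyz(i, 2), oz);
    nx = std::max(nx, cx[i] + 1); ny = std::max(ny, cy[i] + 1); nz = std::max(nz, cz[i] + 1);
  }
  std::vector<std::vector<int> > grid((size_t)nx * ny * nz);
  for (int i = 0; i < n; ++i)
    grid[(size_t)cx[i] + (size_t)nx * (cy[i] + (size_t)ny * cz[i])].push_back(i);

  // flat copies for cache-friendly access
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) { X[i] = xyz(i, 0); Y[i] = xyz(i, 1); Z[i] = xyz(i, 2); }

  std::vector<double> nbx, nby, nbz, nbr2, nbd2;
  std::vector<int> ord;
  for (int i = 0; i < n; ++i) {
    nbx.clear(); nby.clear(); nbz.clear(); nbr2.clear(); nbd2.clear();
    double xi = X[i], yi = Y[i], zi = Z[i];
    for (int a = std::max(0, cx[i] - 1); a <= std::min(nx - 1, cx[i] + 1); ++a)
      for (int b = std::max(0, cy[i] - 1); b <= std::min(ny - 1, cy[i] + 1); ++b)
        for (int c = std::max(0, cz[i] - 1); c <= std::min(nz - 1, cz[i] + 1); ++c) {
          const std::vector<int>& cellv = grid[(size_t)a + (size_t)nx * (b + (size_t)ny * c)];
          for (size_t k = 0; k < cellv.size(); ++k) {
            int j = cellv[k];
            if (j == i) continue;
            double dx = X[j] - xi, dy = Y[j] - yi, dz = Z[j] - zi;
            double d2 = dx * dx + dy * dy + dz * dz;
            double cut = R[i] + R[j];
            if (d2 < cut * cut) {
              nbx.push_back(X[j]); nby.push_back(Y[j]); nbz.push_back(Z[j]);
              nbr2.push_back(R[j] * R[j]); nbd2.push_back(d2);
            }
          }
        }
    // nearest neighbours first: buried points terminate sooner
    size_t nn = nbx.size();
    ord.resize(nn);
    for (size_t k = 0; k < nn; ++k) ord[k] = (int)k;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return nbd2[a] < nbd2[b]; });
    std::vector<double> sx(nn), sy(nn), sz(nn), sr2(nn);
    for (size_t k = 0; k < nn; ++k) {
      sx[k] = nbx[ord[k]]; sy[k] = nby[ord[k]]; sz[k] = nbz[ord[k]];
      sr2[k] = nbr2[ord[k]];
    }
    int acc = 0;
    for (int p = 0; p < n_points; ++p) {
      double px = xi + R[i] * pts[3 * p];
      double py = yi + R[i] * pts[3 * p + 1];
      double pz = zi + R[i] * pts[3 * p + 2];
      bool buried = false;
      for (size_t k = 0; k < nn; ++k) {
        double dx = px - sx[k], dy = py - sy[k], dz = pz - sz[k];
        if (dx * dx + dy * dy + dz * dz < sr2[k]) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * R[i] * R[i] * acc / n_points;
  }
  return area;
}

// Per-atom SASA loss upon complexation, recomputing only atoms that have at
// least one cross-body neighbour; all other atoms keep their isolated-body
// reference area (exactly zero burial). baseA/baseB are the per-atom areas
// of the isolated bodies.
// [[Rcpp::export]]
List cpp_sasa_burial(NumericMatrix A, NumericMatrix B,
                     NumericVector ra, NumericVector rb,
                     double probe, int n_points,
                     NumericVector baseA, NumericVector baseB) {
  int na = A.nrow(), nb = B.nrow(), n = na + nb;
  std::vector<double> X(n), Y(n), Z(n), R(n);
  for (int i = 0; i < na; ++i) {
    X[i] = A(i, 0); Y[i] = A(i, 1); Z[i] = A(i, 2); R[i] = ra[i] + probe;
  }
  for (int i = 0; i < nb; ++i) {
    X[na + i] = B(i, 0); Y[na + i] = B(i, 1); Z[na + i] = B(i, 2);
    R[na + i] = rb[i] + probe;
  }
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, R[i]);
  double cell = 2.0 * rmax;
  double ox = X[0], oy = Y[0], oz = Z[0];
  for (int i = 0; i < n; ++i) {
    ox = std::min(ox, X[i]); oy = std::min(oy, Y[i]); oz = std::min(oz, Z[i]);
  }
  int nx = 0, ny = 0, nz = 0;
  std::vector<int> cxv(n), cyv(n), czv(n);
  for (int i = 0; i < n; ++i) {
    cxv[i] = (int)std::floor((X[i] - ox) / cell);
    cyv[i] = (int)std::floor((Y[i] - oy) / cell);
    czv[i] = (int)std::floor((Z[i] - oz) / cell);
    nx = std::max(nx, cxv[i] + 1); ny = std::max(ny, cyv[i] + 1);
    nz = std::max(nz, czv[i] + 1);
  }
  std::vector<std::vector<int> > grid((size_t)nx * ny * nz);
  for (int i = 0; i < n; ++i)
    grid[(size_t)cxv[i] + (size_t)nx * (cyv[i] + (size_t)ny * czv[i])].push_back(i);

  std::vector<double> pts = sphere_points(n_points);
  NumericVector burA(na), burB(nb);
  std::vector<double> sx, sy, sz, sr2, sd2;
  for (int i = 0; i < n; ++i) {
    // collect neighbours; note whether any is cross-body
    sx.clear(); sy.clear(); sz.clear(); sr2.clear(); sd2.clear();
    bool cross = false;
    for (int a = std::max(0, cxv[i] - 1); a <= std::min(nx - 1, cxv[i] + 1); ++a)
      for (int b = std::max(0, cyv[i] - 1); b <= std::min(ny - 1, cyv[i] + 1); ++b)
        for (int c = std::max(0, czv[i] - 1); c <= std::min(nz - 1, czv[i] + 1); ++c) {
          const std::vector<int>& cv =
            grid[(size_t)a + (size_t)nx * (b + (size_t)ny * c)];
          for (size_t k = 0; k < cv.size(); ++k) {
            int j = cv[k];
            if (j == i) continue;
            double dx = X[j] - X[i], dy = Y[j] - Y[i], dz = Z[j] - Z[i];
            double d2 = dx * dx + dy * dy + dz * dz;
            double cut = R[i] + R[j];
            if (d2 < cut * cut) {
              sx.push_back(X[j]); sy.push_back(Y[j]); sz.push_back(Z[j]);
              sr2.push_back(R[j] * R[j]); sd2.push_back(d2);
              if ((i < na) != (j < na)) cross = true;
            }
          }
        }
    if (!cross) continue;  // burial is exactly zero without cross neighbours
    size_t nn = sx.size();
    std::vector<int> ord(nn);
    for (size_t k = 0; k < nn; ++k) ord[k] = (int)k;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return sd2[a] < sd2[b]; });
    int acc = 0;
    for (int p = 0; p < n_points; ++p) {
      double px = X[i] + R[i] * pts[3 * p];
      double py = Y[i] + R[i] * pts[3 * p + 1];
      double pz = Z[i] + R[i] * pts[3 * p + 2];
      bool buried = false;
      for (size_t k = 0; k < nn; ++k) {
        int j = ord[k];
        double dx = px - sx[j], dy = py - sy[j], dz = pz - sz[j];
        if (dx * dx + dy * dy + dz * dz < sr2[j]) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    double area = 4.0 * M_PI * R[i] * R[i] * acc / n_points;
    if (i < na) burA[i] = baseA[i] - area;
    else burB[i - na] = baseB[i - na] - area;
  }
  return List::create(_["burial_a"] = burA, _["burial_b"] = burB);
}

// Dense cell grid over a fixed point set with per-cell contiguous copies of
// coordinates and force-field parameters (structure-of-arrays layout keeps
// the energy inner loop cache-friendly).
struct CellGrid {
  double cell, ox, oy, oz;
  int nx, ny, nz;
  std::vector<std::vector<double> > cx, cy, cz, cq, cr, ce;
  void build(const NumericMatrix& xyz, const NumericVector& q,
             const NumericVector& r, const NumericVector& e,
             double cellsize) {
    cell = cellsize;
    int n = xyz.nrow();
    ox = oy = oz = R_PosInf;
    double mx = R_NegInf, my = R_NegInf, mz = R_NegInf;
    for (int i = 0; i < n; ++i) {
      ox = std::min(ox, xyz(i, 0)); oy = std::min(oy, xyz(i, 1)); oz = std::min(oz, xyz(i, 2));
      mx = std::max(mx, xyz(i, 0)); my = std::max(my, xyz(i, 1)); mz = std::max(mz, xyz(i, 2));
    }
    nx = (int)std::floor((mx - ox) / cell) + 1;
    ny = (int)std::floor((my - oy) / cell) + 1;
    nz = (int)std::floor((mz - oz) / cell) + 1;
    size_t nc = (size_t)nx * ny * nz;
    cx.assign(nc, {}); cy.assign(nc, {}); cz.assign(nc, {});
    cq.assign(nc, {}); cr.assign(nc, {}); ce.assign(nc, {});
    for (int i = 0; i < n; ++i) {
      int a = (int)std::floor((xyz(i, 0) - ox) / cell);
      int b = (int)std::floor((xyz(i, 1) - oy) / cell);
      int c = (int)std::floor((xyz(i, 2) - oz) / cell);
      size_t idx = (size_t)a + (size_t)nx * (b + (size_t)ny * c);
      cx[idx].push_back(xyz(i, 0)); cy[idx].push_back(xyz(i, 1));
      cz[idx].push_back(xyz(i, 2)); cq[idx].push_back(q[i]);
      cr[idx].push_back(r[i]); ce[idx].push_back(e[i]);
    }
  }
};

// Cross (inter-body) pair energy: 6-12 Lennard-Jones (rmin/eps combining
// rules: arithmetic rmin, geometric eps) plus Coulomb with distance-dependent
// dielectric eps(r) = 4r. Pair LJ terms are clamped at `cap`; the Coulomb
// distance is floored at the pair contact distance so opposite charges
// cannot gain energy by interpenetrating; pairs closer than `clash_dist`
// raise the clash flag.
static void cross_energy_core(const double* Bx, const double* By,
                              const double* Bz, int nB,
                              const double* qb, const double* rb,
                              const double* eb,
                              const CellGrid& gridA, double cutoff,
                              double clash_dist, double cap, double coulomb_k,
                              double* energy, bool* clash, double* mind) {
  double E = 0.0, md2 = R_PosInf;
  bool cl = false;
  double cut2 = cutoff * cutoff;
  double cl2 = clash_dist * clash_dist;
  for (int i = 0; i < nB; ++i) {
    double x = Bx[i], y = By[i], z = Bz[i];
    int a0 = (int)std::floor((x - gridA.ox) / gridA.cell);
    int b0 = (int)std::floor((y - gridA.oy) / gridA.cell);
    int c0 = (int)std::floor((z - gridA.oz) / gridA.cell);
    if (a0 < -1 || a0 > gridA.nx || b0 < -1 || b0 > gridA.ny ||
        c0 < -1 || c0 > gridA.nz) continue;
    double qi = qb[i], ri = rb[i], ei = eb[i];
    for (int a = std::max(0, a0 - 1); a <= std::min(gridA.nx - 1, a0 + 1); ++a)
      for (int b = std::max(0, b0 - 1); b <= std::min(gridA.ny - 1, b0 + 1); ++b)
        for (int c = std::max(0, c0 - 1); c <= std::min(gridA.nz - 1, c0 + 1); ++c) {
          size_t idx = (size_t)a + (size_t)gridA.nx * (b + (size_t)gridA.ny * c);
          const double* ax = gridA.cx[idx].data();
          const double* ay = gridA.cy[idx].data();
          const double* az = gridA.cz[idx].data();
          const double* aq = gridA.cq[idx].data();
          const double* ar = gridA.cr[idx].data();
          const double* ae = gridA.ce[idx].data();
          size_t m = gridA.cx[idx].size();
          for (size_t k = 0; k < m; ++k) {
            double dx = x - ax[k], dy = y - ay[k], dz = z - az[k];
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 > cut2) continue;
            if (d2 < md2) md2 = d2;
            if (d2 < cl2) cl = true;
            double rmin = ar[k] + ri;
            double rmin2 = rmin * rmin;
            double s2 = rmin2 / std::max(d2, 1e-12);
            double s6 = s2 * s2 * s2;
            double lj = std::sqrt(ae[k] * ei) * (s6 * s6 - 2.0 * s6);
            if (lj > cap) lj = cap;
            double rc2 = std::max(d2, rmin2);
            E += lj + coulomb_k * aq[k] * qi / (4.0 * rc2);
          }
        }
  }
  *energy = E;
  *clash = cl;
  *mind = std::sqrt(md2);
}

// [[Rcpp::export]]
List cpp_cross_energy(NumericMatrix A, NumericMatrix B,
                      NumericVector qa, NumericVector qb,
                      NumericVector ra, NumericVector rb,
                      NumericVector ea, NumericVector eb,
                      double cutoff, double clash_dist, double cap,
                      double coulomb_k) {
  CellGrid g;
  g.build(A, qa, ra, ea, cutoff);
  int nB = B.nrow();
  std::vector<double> bx(nB), by(nB), bz(nB);
  for (int i = 0; i < nB; ++i) { bx[i] = B(i, 0); by[i] = B(i, 1); bz[i] = B(i, 2); }
  double E, md;
  bool cl;
  cross_energy_core(bx.data(), by.data(), bz.data(), nB, REAL(qb), REAL(rb),
                    REAL(eb), g, cutoff, clash_dist, cap, coulomb_k,
                    &E, &cl, &md);
  return List::create(_["energy"] = E, _["clash"] = cl, _["min_dist"] = md);
}

// [[Rcpp::export]]
double cpp_min_cross_dist(NumericMatrix A, NumericMatrix B) {
  double md2 = R_PosInf;
  for (int i = 0; i < B.nrow(); ++i) {
    double x = B(i, 0), y = B(i, 1), z = B(i, 2);
    for (int j = 0; j < A.nrow(); ++j) {
      double dx = x - A(j, 0), dy = y - A(j, 1), dz = z - A(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < md2) md2 = d2;
    }
  }
  return std::sqrt(md2);
}

// Slide body B along +x until its closest heavy-atom approach to A equals
// d_contact; returns the shift. Closed form: for every pair within d_contact
// in the yz-plane the contact shift is xA - xB + sqrt(dc^2 - dyz^2); the
// placement shift is the maximum over pairs (first touch coming from +inf).
// [[Rcpp::export]]
double cpp_contact_shift(NumericMatrix A, NumericMatrix B, double d_contact) {
  double dc2 = d_contact * d_contact;
  // yz cell grid over A with cell size d_contact
  int nA = A.nrow(), nB = B.nrow();
  double oy = R_PosInf, oz = R_PosInf, my = R_NegInf, mz = R_NegInf;
  for (int j = 0; j < nA; ++j) {
    oy = std::min(oy, A(j, 1)); oz = std::min(oz, A(j, 2));
    my = std::max(my, A(j, 1)); mz = std::max(mz, A(j, 2));
  }
  double cell = d_contact;
  int ny = (int)std::floor((my - oy) / cell) + 1;
  int nz = (int)std::floor((mz - oz) / cell) + 1;
  std::vector<std::vector<int> > grid((size_t)ny * nz);
  for (int j = 0; j < nA; ++j) {
    int b = (int)std::floor((A(j, 1) - oy) / cell);
    int c = (int)std::floor((A(j, 2) - oz) / cell);
    grid[(size_t)b + (size_t)ny * c].push_back(j);
  }
  double best = R_NegInf;
  for (int i = 0; i < nB; ++i) {
    double y = B(i, 1), z = B(i, 2);
    int b0 = (int)std::floor((y - oy) / cell);
    int c0 = (int)std::floor((z - oz) / cell);
    if (b0 < -1 || b0 > ny || c0 < -1 || c0 > nz) continue;
    for (int b = std::max(0, b0 - 1); b <= std::min(ny - 1, b0 + 1); ++b)
      for (int c = std::max(0, c0 - 1); c <= std::min(nz - 1, c0 + 1); ++c) {
        const std::vector<int>& cv = grid[(size_t)b + (size_t)ny * c];
        for (size_t k = 0; k < cv.size(); ++k) {
          int j = cv[k];
          double dy = y - A(j, 1), dz = z - A(j, 2);
          double dyz2 = dy * dy + dz * dz;
          if (dyz2 > dc2) continue;
          double s = A(j, 0) - B(i, 0) + std::sqrt(dc2 - dyz2);
          if (s > best) best = s;
        }
      }
  }
  if (!std::isfinite(best)) return NA_REAL;
  return best;
}

// Rigid-body Metropolis Monte Carlo over (theta about B's own z-axis, in-plane
// translation, bounded z-shift), minimizing the cross pair energy against a
// fixed body A. All random draws (Gaussian proposals, acceptance uniforms)
// come from R so that runs are reproducible under set.seed().
// state = (theta_deg, tx, ty, tz); B coordinates are
//   Rz(theta) (B0 - cB) + cB + t, with cB = centroid of B0.
// [[Rcpp::export]]
List cpp_mc_refine(NumericMatrix A, NumericMatrix B0,
                   NumericVector qa, NumericVector qb,
                   NumericVector ra, NumericVector rb,
                   NumericVector ea, NumericVector eb,
                   NumericVector start, NumericMatrix proposals,
                   NumericVector unifs, double temperature, double zmax,
                   double rot_max, double trans_max,
                   double cutoff, double clash_dist, double cap,
                   double coulomb_k) {
  int nB = B0.nrow();
  int nsteps = proposals.nrow();
  CellGrid g;
  g.build(A, qa, ra, ea, cutoff);
  double cBx = 0, cBy = 0, cBz = 0;
  std::vector<double> b0x(nB), b0y(nB), b0z(nB);
  for (int i = 0; i < nB; ++i) {
    b0x[i] = B0(i, 0); b0y[i] = B0(i, 1); b0z[i] = B0(i, 2);
    cBx += b0x[i]; cBy += b0y[i]; cBz += b0z[i];
  }
  cBx /= nB; cBy /= nB; cBz /= nB;

  std::vector<double> bx(nB), by(nB), bz(nB);
  auto place = [&](const double* st) {
    double th = st[0] * M_PI / 180.0, ct = std::cos(th), snt = std::sin(th);
    for (int i = 0; i < nB; ++i) {
      double x = b0x[i] - cBx, y = b0y[i] - cBy;
      bx[i] = ct * x - snt * y + cBx + st[1];
      by[i] = snt * x + ct * y + cBy + st[2];
      bz[i] = b0z[i] + st[3];
    }
  };
  double st[4] = { start[0], start[1], start[2], start[3] };
  double E, md; bool cl;
  place(st);
  cross_energy_core(bx.data(), by.data(), bz.data(), nB, REAL(qb), REAL(rb),
                    REAL(eb), g, cutoff, clash_dist, cap, coulomb_k,
                    &E, &cl, &md);
  double bst[4] = { st[0], st[1], st[2], st[3] };
  double bestE = E;
  for (int k = 0; k < nsteps; ++k) {
    double pr[4] = { st[0] + proposals(k, 0), st[1] + proposals(k, 1),
                     st[2] + proposals(k, 2), st[3] + proposals(k, 3) };
    if (std::fabs(pr[3]) > zmax) continue;  // keep membrane register
    // stay local to the parent interface ("refine only" role): bound the
    // rotation and in-plane drift relative to the enumerated pose
    if (std::fabs(pr[0]) > rot_max) continue;
    if (pr[1] * pr[1] + pr[2] * pr[2] > trans_max * trans_max) continue;
    place(pr);
    double Ep;
    cross_energy_core(bx.data(), by.data(), bz.data(), nB, REAL(qb), REAL(rb),
                      REAL(eb), g, cutoff, clash_dist, cap, coulomb_k,
                      &Ep, &cl, &md);
    if (Ep <= E || unifs[k] < std::exp(-(Ep - E) / temperature)) {
      E = Ep;
      st[0] = pr[0]; st[1] = pr[1]; st[2] = pr[2]; st[3] = pr[3];
      if (E < bestE) {
        bestE = E;
        bst[0] = st[0]; bst[1] = st[1]; bst[2] = st[2]; bst[3] = st[3];
      }
    }
  }
  return List::create(
    _["best_state"] = NumericVector::create(bst[0], bst[1], bst[2], bst[3]),
    _["best_energy"] = bestE,
    _["final_state"] = NumericVector::create(st[0], st[1], st[2], st[3]),
    _["final_energy"] = E);
}
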