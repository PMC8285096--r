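#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Grids are column-major (i fastest), 0-based linear index = i + nx*(j + ny*k).
// Label codes used throughout: 0 background, 1 lumen, 2 wall.

static inline int lin(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Successive over-relaxation for the discrete Laplace equation on the wall
// voxels of an anisotropically spaced grid (7-point stencil). Dirichlet
// boundaries are imposed at the voxel *faces* between wall and non-wall
// voxels via linear ghost values (u = 0 on the endocardial/lumen face,
// u = 1 on the epicardial/background face), so the discrete interface
// coincides with the label boundary rather than the outside voxel centres.
// Out-of-grid neighbours are zero-flux (mirror). After convergence the
// potential is extended into boundary-adjacent outside voxels by the same
// linear rule so that trilinear interpolation crosses the 0/1 levels at the
// faces; labels: 0 background, 1 lumen, 2 wall.
// [[Rcpp::export]]
List laplace_sor_cpp(IntegerVector labels, IntegerVector wall_idx,
                     IntegerVector dims, NumericVector spacing,
                     double omega, double tol, int max_iter) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nxy = nx * ny, ntot = nx * ny * nz;
  const double w[3] = {1.0 / (spacing[0] * spacing[0]),
                       1.0 / (spacing[1] * spacing[1]),
                       1.0 / (spacing[2] * spacing[2])};
  const int off[6] = {-1, +1, -nx, +nx, -nxy, +nxy};
  const int axis[6] = {0, 0, 1, 1, 2, 2};

  NumericVector u(ntot);
  for (int i = 0; i < ntot; ++i) u[i] = (labels[i] == 0) ? 1.0 : 0.0;
  const int n = wall_idx.size();
  for (int q = 0; q < n; ++q) u[wall_idx[q]] = 0.5;

  double maxres = R_PosInf;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    maxres = 0.0;
    for (int q = 0; q < n; ++q) {
      const int idx = wall_idx[q];
      const int i = idx % nx;
      const int j = (idx / nx) % ny;
      const int k = idx / nxy;
      const double uc = u[idx];
      double num = 0.0, diag = 0.0;
      for (int s = 0; s < 6; ++s) {
        const int a = axis[s];
        bool inside =
          (s == 0) ? (i > 0) : (s == 1) ? (i < nx - 1) :
          (s == 2) ? (j > 0) : (s == 3) ? (j < ny - 1) :
          (s == 4) ? (k > 0) : (k < nz - 1);
        if (!inside) { num += w[a] * uc; diag += w[a]; continue; } // mirror
        const int nb = idx + off[s];
        if (labels[nb] == 2) { num += w[a] * u[nb]; diag += w[a]; }
        else if (labels[nb] == 1) { diag += 2.0 * w[a]; }          // face u=0
        else { num += 2.0 * w[a]; diag += 2.0 * w[a]; }            // face u=1
      }
      const double unew = num / diag;
      const double r = unew - uc;
      const double ar = std::fabs(r);
      if (ar > maxres) maxres = ar;
      u[idx] = uc + omega * r;
    }
    if (maxres < tol) { ++it; break; }
  }

  // extend the potential linearly into two layers of outside voxels so
  // that trilinear interpolation and central differences remain accurate
  // across the interface: first layer is the ghost value 2*ub - u_wall
  // (ub = 0 lumen face, 1 background face) averaged over adjacent wall
  // voxels; second layer continues the line through (ghost, wall) pairs.
  std::vector<signed char> ext(ntot, 0);
  for (int idx = 0; idx < ntot; ++idx) {
    if (labels[idx] == 2) continue;
    const int i = idx % nx;
    const int j = (idx / nx) % ny;
    const int k = idx / nxy;
    double s = 0.0; int cnt = 0;
    for (int t = 0; t < 6; ++t) {
      bool inside =
        (t == 0) ? (i > 0) : (t == 1) ? (i < nx - 1) :
        (t == 2) ? (j > 0) : (t == 3) ? (j < ny - 1) :
        (t == 4) ? (k > 0) : (k < nz - 1);
      if (!inside) continue;
      const int nb = idx + off[t];
      if (labels[nb] == 2) { s += u[nb]; ++cnt; }
    }
    if (cnt > 0) {
      const double ub = (labels[idx] == 1) ? 0.0 : 1.0;
      u[idx] = 2.0 * ub - s / cnt;
      ext[idx] = 1;
    }
  }
  for (int idx = 0; idx < ntot; ++idx) {
    if (labels[idx] == 2 || ext[idx]) continue;
    const int i = idx % nx;
    const int j = (idx / nx) % ny;
    const int k = idx / nxy;
    double s = 0.0; int cnt = 0;
    for (int t = 0; t < 6; ++t) {
      const int step1[3] = {(t == 0) ? -1 : (t == 1) ? 1 : 0,
                            (t == 2) ? -1 : (t == 3) ? 1 : 0,
                            (t == 4) ? -1 : (t == 5) ? 1 : 0};
      const int i2 = i + 2 * step1[0], j2 = j + 2 * step1[1],
                k2 = k + 2 * step1[2];
      if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
        continue;
      const int nb = idx + off[t];
      const int nb2 = idx + 2 * off[t];
      if (ext[nb] == 1 && labels[nb2] == 2) {
        s += 2.0 * u[nb] - u[nb2];
        ++cnt;
      }
    }
    if (cnt > 0) { u[idx] = s / cnt; ext[idx] = 2; }
  }
  return List::create(_["u"] = u, _["iterations"] = it,
                      _["residual"] = maxres,
                      _["converged"] = (maxres < tol));
}

struct Grid {
  const double *v;
  int nx, ny, nz;
  double sample(double x, double y, double z) const {
    // trilinear interpolation at continuous voxel-index coordinates
    // (voxel centres at integers); coordinates clamped to the grid.
    if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
    if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
    if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
    int i0 = (int)std::floor(x); if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
    int j0 = (int)std::floor(y); if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
    int k0 = (int)std::floor(z); if (k0 > nz - 2) k0 = nz - 2; if (k0 < 0) k0 = 0;
    const double fx = x - i0, fy = y - j0, fz = z - k0;
    const int nxy = nx * ny;
    const int b = i0 + nx * (j0 + ny * k0);
    const double c00 = v[b]           * (1 - fx) + v[b + 1]           * fx;
    const double c10 = v[b + nx]      * (1 - fx) + v[b + nx + 1]      * fx;
    const double c01 = v[b + nxy]     * (1 - fx) + v[b + nxy + 1]     * fx;
    const double c11 = v[b + nxy + nx]* (1 - fx) + v[b + nxy + nx + 1]* fx;
    const double c0 = c00 * (1 - fy) + c10 * fy;
    const double c1 = c01 * (1 - fy) + c11 * fy;
    return c0 * (1 - fz) + c1 * fz;
  }
};

// Fixed-step Euler integration of the normalized potential gradient from a
// wall voxel centre, downhill to the endocardial (u = 0) and uphill to the
// epicardial (u = 1) level. With the face-boundary solver the 0/1 levels
// coincide with the wall interface, and the final partial step in each
// direction is obtained by linear interpolation of the remaining potential
// over the local gradient magnitude (sub-step accurate; exact on a slab).
//
// Flags: 0 ok, 1 flat gradient, 2 step cap reached, 3 left the grid.
// [[Rcpp::export]]
List trace_streamlines_cpp(NumericVector u, NumericVector gx, NumericVector gy,
                           NumericVector gz, IntegerVector dims,
                           NumericVector spacing, IntegerVector start_idx,
                           double step_mm, int max_steps, double grad_eps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  Grid U  {REAL(u),  nx, ny, nz};
  Grid GX {REAL(gx), nx, ny, nz};
  Grid GY {REAL(gy), nx, ny, nz};
  Grid GZ {REAL(gz), nx, ny, nz};

  const int n = start_idx.size();
  NumericVector length_mm(n), raw_mm(n), euclid_mm(n);
  IntegerVector flag(n), nsteps(n);

  for (int q = 0; q < n; ++q) {
    const int idx = start_idx[q];
    const int i = idx % nx;
    const int j = (idx / nx) % ny;
    const int k = idx / (nx * ny);
    double total = 0.0;
    int fl = 0, steps = 0;
    double endp[2][3];   // terminal positions of the two directions

    for (int dir = -1; dir <= 1; dir += 2) {   // -1 downhill (endo), +1 uphill (epi)
      double x = i, y = j, z = k;
      int s = 0;
      double rem_prev = (dir < 0) ? U.sample(x, y, z)
                                  : 1.0 - U.sample(x, y, z);
      if (rem_prev < 0) rem_prev = 0;
      for (; s < max_steps; ++s) {
        const double gxx = GX.sample(x, y, z);
        const double gyy = GY.sample(x, y, z);
        const double gzz = GZ.sample(x, y, z);
        const double gm = std::sqrt(gxx * gxx + gyy * gyy + gzz * gzz);
        if (gm < grad_eps) { fl = 1; break; }
        const double ux = dir * gxx / gm, uy = dir * gyy / gm, uz = dir * gzz / gm;
        x += ux * step_mm / dx;
        y += uy * step_mm / dy;
        z += uz * step_mm / dz;
        if (x < -1 || x > nx || y < -1 || y > ny || z < -1 || z > nz) { fl = 3; break; }
        total += step_mm;
        const double uv = U.sample(x, y, z);
        const double rem = (dir < 0) ? uv : (1.0 - uv);
        if (rem <= 0.0) {
          // crossed the Dirichlet level during this step: linear
          // back-interpolation of the potential along the segment,
          // moving the recorded endpoint back with it
          if (rem_prev - rem > 0) {
            const double f = (-rem) / (rem_prev - rem);
            total -= step_mm * f;
            x -= ux * f * step_mm / dx;
            y -= uy * f * step_mm / dy;
            z -= uz * f * step_mm / dz;
          }
          break;
        }
        rem_prev = rem;
      }
      if (s == max_steps) fl = 2;
      steps += s;
      const int e = (dir < 0) ? 0 : 1;
      endp[e][0] = x; endp[e][1] = y; endp[e][2] = z;
      if (fl != 0) break;
    }
    raw_mm[q] = total;
    double t = total;
    if (t < step_mm) t = step_mm;   // floor at one Euler step
    length_mm[q] = t;
    flag[q] = fl;
    nsteps[q] = steps;
    if (fl == 0) {
      const double ex = (endp[0][0] - endp[1][0]) * dx;
      const double ey = (endp[0][1] - endp[1][1]) * dy;
      const double ez = (endp[0][2] - endp[1][2]) * dz;
      euclid_mm[q] = std::sqrt(ex * ex + ey * ey + ez * ez);
    } else euclid_mm[q] = NA_REAL;
  }
  return List::create(_["length_mm"] = length_mm, _["raw_mm"] = raw_mm,
                      _["euclid_mm"] = euclid_mm,
                      _["flag"] = flag, _["steps"] = nsteps);
}

// Connected-component labelling (BFS) with 6- or 26-connectivity.
// Returns 0 outside the mask, 1..K component ids inside.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ntot = nx * ny * nz;
  IntegerVector lab(ntot, 0);
  std::vector<int> stack;
  stack.reserve(1024);
  int cur = 0;
  for (int seed = 0; seed < ntot; ++seed) {
    if (!mask[seed] || lab[seed] != 0) continue;
    ++cur;
    lab[seed] = cur;
    stack.push_back(seed);
    while (!stack.empty()) {
      const int idx = stack.back();
      stack.pop_back();
      const int i = idx % nx;
      const int j = (idx / nx) % ny;
      const int k = idx / (nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            if (connectivity == 6 && std::abs(di) + std::abs(dj) + std::abs(dk) != 1)
              continue;
            const int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            const int nb = lin(ii, jj, kk, nx, ny);
            if (mask[nb] && lab[nb] == 0) { lab[nb] = cur; stack.push_back(nb); }
          }
    }
  }
  return lab;
}

// One 6- or 26-neighbourhood binary dilation; out-of-grid treated as outside.
// [[Rcpp::export]]
LogicalVector binary_dilate_cpp(LogicalVector mask, IntegerVector dims,
                                int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ntot = nx * ny * nz;
  LogicalVector out(ntot);
  for (int idx = 0; idx < ntot; ++idx) {
    if (mask[idx]) { out[idx] = true; continue; }
    const int i = idx % nx;
    const int j = (idx / nx) % ny;
    const int k = idx / (nx * ny);
    bool hit = false;
    for (int dk = -1; dk <= 1 && !hit; ++dk)
      for (int dj = -1; dj <= 1 && !hit; ++dj)
        for (int di = -1; di <= 1 && !hit; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          if (connectivity == 6 && std::abs(di) + std::abs(dj) + std::abs(dk) != 1)
            continue;
          const int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          if (mask[lin(ii, jj, kk, nx, ny)]) hit = true;
        }
    out[idx] = hit;
  }
  return out;
}

// One binary erosion (dual of dilation); out-of-grid neighbours count as
// inside so that flat structures touching the grid edge are not eaten away.
// [[Rcpp::export]]
LogicalVector binary_erode_cpp(LogicalVector mask, IntegerVector dims,
                               int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ntot = nx * ny * nz;
  LogicalVector out(ntot);
  for (int idx = 0; idx < ntot; ++idx) {
    if (!mask[idx]) { out[idx] = false; continue; }
    const int i = idx % nx;
    const int j = (idx / nx) % ny;
    const int k = idx / (nx * ny);
    bool keep = true;
    for (int dk = -1; dk <= 1 && keep; ++dk)
      for (int dj = -1; dj <= 1 && keep; ++dj)
        for (int di = -1; di <= 1 && keep; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          if (connectivity == 6 && std::abs(di) + std::abs(dj) + std::abs(dk) != 1)
            continue;
          const int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          if (!mask[lin(ii, jj, kk, nx, ny)]) keep = false;
        }
    out[idx] = keep;
  }
  return out;
}
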