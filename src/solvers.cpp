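// Iterative kernels for the voxel physics solvers.
//
// em_cocg_solve: cell-centred finite-volume discretization of
//   div( sigma*(x) grad V ) = 0 with complex admittivity, Dirichlet
//   electrode cells and optional lumped surface impedance (thin dielectric
//   film) on electrode faces; solved by conjugate-orthogonal CG (COCG,
//   for complex symmetric systems) with Jacobi preconditioning.
//
// stokes_minres_solve: MAC staggered-grid Stokes system (momentum +
//   continuity) with no-slip solids, pressure openings, slip/symmetry
//   sides and prescribed-velocity patches; solved by preconditioned
//   MINRES on the symmetric indefinite saddle-point system.

#include <Rcpp.h>
#include <vector>
#include <complex>
#include <cmath>
#include <cstdint>

using namespace Rcpp;
typedef std::complex<double> cplx;
typedef std::vector<double> dvec;
typedef std::vector<cplx> cvec;
typedef std::int64_t i64;

// ---------------------------------------------------------------- EM solver

// roles: 0 = regular cell (unknown when |sigma| > 0), 1 = active electrode
// (V = V_amp), 2 = ground electrode (V = 0). sigma == 0 marks inactive
// cells (outside / perfect insulator): faces touching them carry no flux.
// [[Rcpp::export]]
List em_cocg_solve(IntegerVector dims, ComplexVector sigma_r,
                   IntegerVector role, double V_amp,
                   ComplexVector z_pet_r, double h,
                   double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const i64 N = (i64)nx * ny * nz;
  const i64 sx = 1, sy = nx, sz = (i64)nx * ny;
  cplx z_pet(z_pet_r[0].r, z_pet_r[0].i);

  std::vector<cplx> sig(N);
  for (i64 c = 0; c < N; ++c) sig[c] = cplx(sigma_r[c].r, sigma_r[c].i);

  // unknown numbering
  std::vector<i64> unk(N, -1);
  i64 nu = 0;
  for (i64 c = 0; c < N; ++c)
    if (role[c] == 0 && std::abs(sig[c]) > 0.0) unk[c] = nu++;
  if (nu == 0) stop("no active unknown cells");

  // face conductances g[d][c]: between cell c and c + stride(d)
  auto face_g = [&](i64 a, i64 b) -> cplx {
    cplx sa = sig[a], sb = sig[b];
    if (std::abs(sa) == 0.0 || std::abs(sb) == 0.0) return cplx(0.0, 0.0);
    cplx z = h / (2.0 * sa) + h / (2.0 * sb);
    bool elec_a = role[a] != 0, elec_b = role[b] != 0;
    if (elec_a != elec_b) z += z_pet;  // film at electrode-medium face
    return (h * h) / z;
  };
  std::vector<cvec> g(3);
  for (int d = 0; d < 3; ++d) g[d].assign(N, cplx(0, 0));
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        i64 c = i + sy * j + sz * k;
        if (i + 1 < nx) g[0][c] = face_g(c, c + sx);
        if (j + 1 < ny) g[1][c] = face_g(c, c + sy);
        if (k + 1 < nz) g[2][c] = face_g(c, c + sz);
      }

  // diagonal, rhs
  cvec diag(nu, cplx(0, 0)), b(nu, cplx(0, 0));
  auto dirichlet = [&](i64 c) -> cplx {
    return role[c] == 1 ? cplx(V_amp, 0.0) : cplx(0.0, 0.0);
  };
  const i64 strides[3] = {sx, sy, sz};
  const int nd[3] = {nx, ny, nz};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        i64 c = i + sy * j + sz * k;
        i64 u = unk[c];
        if (u < 0) continue;
        int idx[3] = {i, j, k};
        for (int d = 0; d < 3; ++d) {
          for (int s = -1; s <= 1; s += 2) {
            int q = idx[d] + s;
            if (q < 0 || q >= nd[d]) continue;
            i64 nb = c + s * strides[d];
            cplx gf = (s > 0) ? g[d][c] : g[d][nb];
            if (std::abs(gf) == 0.0) continue;
            diag[u] += gf;
            if (unk[nb] < 0 && role[nb] != 0) b[u] += gf * dirichlet(nb);
          }
        }
      }

  // COCG with Jacobi preconditioner; initial guess V_amp / 2
  cvec x(nu, cplx(V_amp / 2.0, 0.0)), r(nu), p(nu), q(nu), z(nu);
  auto matvec = [&](const cvec& v, cvec& out) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          i64 c = i + sy * j + sz * k;
          i64 u = unk[c];
          if (u < 0) continue;
          cplx acc = diag[u] * v[u];
          if (i > 0      && unk[c - sx] >= 0) acc -= g[0][c - sx] * v[unk[c - sx]];
          if (i + 1 < nx && unk[c + sx] >= 0) acc -= g[0][c]      * v[unk[c + sx]];
          if (j > 0      && unk[c - sy] >= 0) acc -= g[1][c - sy] * v[unk[c - sy]];
          if (j + 1 < ny && unk[c + sy] >= 0) acc -= g[1][c]      * v[unk[c + sy]];
          if (k > 0      && unk[c - sz] >= 0) acc -= g[2][c - sz] * v[unk[c - sz]];
          if (k + 1 < nz && unk[c + sz] >= 0) acc -= g[2][c]      * v[unk[c + sz]];
          out[u] = acc;
        }
  };
  auto cdot = [](const cvec& a, const cvec& b2) {  // unconjugated
    cplx s(0, 0);
    for (size_t i = 0; i < a.size(); ++i) s += a[i] * b2[i];
    return s;
  };
  auto nrm2 = [](const cvec& a) {
    double s = 0;
    for (size_t i = 0; i < a.size(); ++i) s += std::norm(a[i]);
    return std::sqrt(s);
  };

  matvec(x, q);
  for (i64 u = 0; u < nu; ++u) r[u] = b[u] - q[u];
  double bnorm = nrm2(b);
  if (bnorm == 0.0) bnorm = 1.0;
  for (i64 u = 0; u < nu; ++u) z[u] = r[u] / diag[u];
  cplx rho = cdot(r, z);
  p = z;
  double relres = nrm2(r) / bnorm;
  int it = 0;
  for (it = 0; it < maxit && relres > tol; ++it) {
    matvec(p, q);
    cplx pq = cdot(p, q);
    if (std::abs(pq) == 0.0) break;
    cplx alpha = rho / pq;
    for (i64 u = 0; u < nu; ++u) { x[u] += alpha * p[u]; r[u] -= alpha * q[u]; }
    relres = nrm2(r) / bnorm;
    if (relres <= tol) { ++it; break; }
    for (i64 u = 0; u < nu; ++u) z[u] = r[u] / diag[u];
    cplx rho2 = cdot(r, z);
    cplx beta = rho2 / rho;
    rho = rho2;
    for (i64 u = 0; u < nu; ++u) p[u] = z[u] + beta * p[u];
  }

  // assemble full potential and terminal currents
  ComplexVector V(N);
  std::vector<cplx> Vfull(N);
  for (i64 c = 0; c < N; ++c) {
    cplx v;
    if (unk[c] >= 0) v = x[unk[c]];
    else if (role[c] == 1) v = cplx(V_amp, 0);
    else if (role[c] == 2) v = cplx(0, 0);
    else v = cplx(NA_REAL, NA_REAL);
    Vfull[c] = v;
    V[c].r = v.real(); V[c].i = v.imag();
  }

  // flux-based field: E_d(cell) = average of the two face current
  // densities / cell admittivity. Interface-safe (the face current is
  // continuous across material and film interfaces); insulating faces
  // carry zero flux, so the wall-normal component tapers inside
  // wall-adjacent cells as the continuum field does.
  List Efield(3);
  for (int d = 0; d < 3; ++d) {
    ComplexVector Ed(N);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          i64 c = i + sy * j + sz * k;
          if (unk[c] < 0 && role[c] == 0) {  // excluded / outside
            Ed[c].r = NA_REAL; Ed[c].i = NA_REAL;
            continue;
          }
          if (role[c] != 0) {  // conductor interior: field ~ 0
            Ed[c].r = 0.0; Ed[c].i = 0.0;
            continue;
          }
          int idx[3] = {i, j, k};
          cplx Jsum(0, 0);
          int nopen = 0;
          if (idx[d] > 0) {
            i64 nb = c - strides[d];
            cplx gf = g[d][nb];
            if (std::abs(gf) > 0.0 && !std::isnan(Vfull[nb].real())) {
              Jsum += gf * (Vfull[nb] - Vfull[c]) / (h * h);
              ++nopen;
            }
          }
          if (idx[d] + 1 < nd[d]) {
            i64 nb = c + strides[d];
            cplx gf = g[d][c];
            if (std::abs(gf) > 0.0 && !std::isnan(Vfull[nb].real())) {
              Jsum += gf * (Vfull[c] - Vfull[nb]) / (h * h);
              ++nopen;
            }
          }
          // average over conducting faces only: a face blocked by an
          // insulating staircase wall must not zero the in-cell component
          cplx E = (nopen > 0) ? Jsum / ((double)nopen * sig[c]) : cplx(0, 0);
          Ed[c].r = E.real(); Ed[c].i = E.imag();
        }
    Ed.attr("dim") = dims;
    Efield[d] = Ed;
  }
  cplx I_act(0, 0), I_gnd(0, 0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        i64 c = i + sy * j + sz * k;
        if (role[c] == 0) continue;
        cplx Vd = dirichlet(c);
        int idx[3] = {i, j, k};
        for (int d = 0; d < 3; ++d)
          for (int s = -1; s <= 1; s += 2) {
            int qq = idx[d] + s;
            if (qq < 0 || qq >= nd[d]) continue;
            i64 nb = c + s * strides[d];
            if (unk[nb] < 0) continue;
            cplx gf = (s > 0) ? g[d][c] : g[d][nb];
            cplx If = gf * (Vd - x[unk[nb]]);
            if (role[c] == 1) I_act += If; else I_gnd += If;
          }
      }

  return List::create(
    _["V"] = V, _["E"] = Efield,
    _["iterations"] = it, _["relres"] = relres,
    _["n_unknowns"] = (double)nu,
    _["I_active"] = Rcomplex{I_act.real(), I_act.imag()},
    _["I_ground"] = Rcomplex{I_gnd.real(), I_gnd.imag()});
}

// BFS over 6-neighbour connectivity: mask of TRUE cells reachable from
// the first TRUE cell.
// [[Rcpp::export]]
LogicalVector flood_mask_cpp(IntegerVector dims, LogicalVector wet) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const i64 N = (i64)nx * ny * nz;
  LogicalVector vis(N);
  std::fill(vis.begin(), vis.end(), FALSE);
  i64 seed = -1;
  for (i64 c = 0; c < N; ++c) if (wet[c]) { seed = c; break; }
  if (seed < 0) return vis;
  std::vector<i64> stack;
  stack.push_back(seed);
  vis[seed] = TRUE;
  const i64 sy = nx, sz = (i64)nx * ny;
  while (!stack.empty()) {
    i64 c = stack.back();
    stack.pop_back();
    int i = c % nx, j = (c / sy) % ny, k = c / sz;
    auto push = [&](i64 n2) {
      if (!vis[n2] && wet[n2]) { vis[n2] = TRUE; stack.push_back(n2); }
    };
    if (i > 0) push(c - 1);
    if (i + 1 < nx) push(c + 1);
    if (j > 0) push(c - sy);
    if (j + 1 < ny) push(c + sy);
    if (k > 0) push(c - sz);
    if (k + 1 < nz) push(c + sz);
  }
  return vis;
}

// ------------------------------------------------------------ Stokes solver

namespace {

struct CSR {
  std::vector<i64> ptr;
  std::vector<i64> col;
  dvec val;
};

void csr_from_triplets(i64 nrow, std::vector<i64>& ri, std::vector<i64>& ci,
                       dvec& vv, CSR& M) {
  M.ptr.assign(nrow + 1, 0);
  for (size_t t = 0; t < ri.size(); ++t) M.ptr[ri[t] + 1]++;
  for (i64 r = 0; r < nrow; ++r) M.ptr[r + 1] += M.ptr[r];
  M.col.resize(ri.size());
  M.val.resize(ri.size());
  std::vector<i64> fill(M.ptr.begin(), M.ptr.end() - 1);
  for (size_t t = 0; t < ri.size(); ++t) {
    i64 at = fill[ri[t]]++;
    M.col[at] = ci[t];
    M.val[at] = vv[t];
  }
}

inline void csr_mv_add(const CSR& M, const double* x, double* y) {
  const i64 n = (i64)M.ptr.size() - 1;
  for (i64 r = 0; r < n; ++r) {
    double acc = 0;
    for (i64 t = M.ptr[r]; t < M.ptr[r + 1]; ++t) acc += M.val[t] * x[M.col[t]];
    y[r] += acc;
  }
}

}  // namespace

// cellclass: 0 = open (pressure opening), 1 = fluid, 2 = solid.
// side_type (xmin,xmax,ymin,ymax,zmin,zmax): 0 pressure, 1 wall, 2 slip,
// 3 velocity (signed normal value side_value). A patch rectangle on
// patch_side (0..5, -1 none) overrides that side with a prescribed signed
// normal velocity patch_value; rect = (lo1, hi1, lo2, hi2), 0-based
// inclusive, in the side's two tangential axes (lower axis first).
// [[Rcpp::export]]
List stokes_minres_solve(IntegerVector dims, IntegerVector cellclass,
                         IntegerVector side_type, NumericVector side_value,
                         int patch_side, IntegerVector patch_rect,
                         double patch_value, double mu, double h,
                         double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const i64 N = (i64)nx * ny * nz;
  const i64 sy = nx, sz = (i64)nx * ny;
  const int nd[3] = {nx, ny, nz};

  auto cls = [&](int i, int j, int k) -> int {  // 3 = out of box
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return 3;
    return cellclass[i + sy * (i64)j + sz * (i64)k];
  };
  // effective boundary condition at a box side, at tangential position
  auto side_bc = [&](int side, int t1, int t2, double& val) -> int {
    if (side == patch_side && t1 >= patch_rect[0] && t1 <= patch_rect[1] &&
        t2 >= patch_rect[2] && t2 <= patch_rect[3]) {
      val = patch_value;
      return 3;
    }
    val = side_value[side];
    return side_type[side];
  };

  // face grids: dir d faces have dims fd with nd[d] + 1 along d
  int fdim[3][3];
  i64 fstr[3][3], fN[3];
  for (int d = 0; d < 3; ++d) {
    for (int a = 0; a < 3; ++a) fdim[d][a] = nd[a] + (a == d ? 1 : 0);
    fstr[d][0] = 1;
    fstr[d][1] = fdim[d][0];
    fstr[d][2] = (i64)fdim[d][0] * fdim[d][1];
    fN[d] = fstr[d][2] * fdim[d][2];
  }
  auto fidx = [&](int d, int i, int j, int k) -> i64 {
    return i * fstr[d][0] + j * fstr[d][1] + k * fstr[d][2];
  };

  // classify faces: status >= 0 unknown id, -1 fixed (value in fval),
  // -2 irrelevant (no fluid side)
  std::vector<std::vector<i64>> fstat(3);
  std::vector<dvec> fval(3);
  i64 nu = 0;
  // tangential axes per side-normal axis, lower first
  const int tax[3][2] = {{1, 2}, {0, 2}, {0, 1}};
  for (int d = 0; d < 3; ++d) {
    fstat[d].assign(fN[d], -2);
    fval[d].assign(fN[d], 0.0);
    for (int k = 0; k < fdim[d][2]; ++k)
      for (int j = 0; j < fdim[d][1]; ++j)
        for (int i = 0; i < fdim[d][0]; ++i) {
          int cm[3] = {i, j, k}, cp[3] = {i, j, k};
          cm[d] -= 1;
          int a = cls(cm[0], cm[1], cm[2]);
          int b = cls(cp[0], cp[1], cp[2]);
          i64 f = fidx(d, i, j, k);
          if (a == 3 || b == 3) {  // box boundary face
            int inner = (a == 3) ? b : a;
            if (inner != 1) continue;  // stays -2
            int side = 2 * d + (a == 3 ? 0 : 1);
            int pos[3] = {i, j, k};
            int t1 = pos[tax[d][0]], t2 = pos[tax[d][1]];
            double v;
            int ty = side_bc(side, t1, t2, v);
            if (ty == 0) fstat[d][f] = nu++;            // pressure opening
            else if (ty == 3) { fstat[d][f] = -1; fval[d][f] = v; }
            else fstat[d][f] = -1;                      // wall / slip: 0
          } else if (a == 1 && b == 1) {
            fstat[d][f] = nu++;
          } else if ((a == 1 && b == 0) || (a == 0 && b == 1)) {
            fstat[d][f] = nu++;                         // interior opening
          } else if (a == 1 || b == 1) {
            fstat[d][f] = -1;                           // no-slip at solid
          }
        }
  }

  // pressure unknowns at fluid cells
  std::vector<i64> punk(N, -1);
  i64 np = 0;
  for (i64 c = 0; c < N; ++c)
    if (cellclass[c] == 1) punk[c] = np++;
  if (nu == 0 || np == 0) stop("no fluid unknowns");

  const double cmu = mu / (h * h);
  std::vector<i64> Ari, Aci, Gri, Gci;
  dvec Avv, Gvv;
  dvec rhs((size_t)(nu + np), 0.0);
  dvec adiag(nu, 0.0);

  // momentum rows
  for (int d = 0; d < 3; ++d) {
    for (int k = 0; k < fdim[d][2]; ++k)
      for (int j = 0; j < fdim[d][1]; ++j)
        for (int i = 0; i < fdim[d][0]; ++i) {
          i64 f = fidx(d, i, j, k);
          i64 row = fstat[d][f];
          if (row < 0) continue;
          int pos[3] = {i, j, k};
          double diag = 0.0;
          // longitudinal neighbours
          for (int s = -1; s <= 1; s += 2) {
            int cb[3] = {i, j, k};
            cb[d] += (s > 0 ? 0 : -1);          // in-between cell
            int cc = cls(cb[0], cb[1], cb[2]);
            if (cc != 1) continue;               // open/out: zero gradient
            int nf[3] = {i, j, k};
            nf[d] += s;
            if (nf[d] < 0 || nf[d] >= fdim[d][d]) continue;
            i64 fn = fidx(d, nf[0], nf[1], nf[2]);
            i64 st = fstat[d][fn];
            if (st >= 0) {
              Ari.push_back(row); Aci.push_back(st); Avv.push_back(-cmu);
              diag += cmu;
            } else if (st == -1) {
              diag += cmu;
              rhs[row] += cmu * fval[d][fn];
            }
            // st == -2 cannot happen next to an unknown along d
          }
          // transverse neighbours
          for (int a = 0; a < 3; ++a) {
            if (a == d) continue;
            for (int s = -1; s <= 1; s += 2) {
              int nf[3] = {i, j, k};
              nf[a] += s;
              if (nf[a] < 0 || nf[a] >= fdim[d][a]) {
                // beyond the box: bc of that side
                int side = 2 * a + (s < 0 ? 0 : 1);
                int t1 = pos[tax[a][0]], t2 = pos[tax[a][1]];
                // tangential index along the face's own normal may exceed
                // cell range; clamp for patch lookup only
                if (tax[a][0] == d) t1 = std::min(t1, nd[d] - 1);
                if (tax[a][1] == d) t2 = std::min(t2, nd[d] - 1);
                double v;
                int ty = side_bc(side, t1, t2, v);
                if (ty == 1 || ty == 3) diag += 2.0 * cmu;  // tangential 0
                continue;                                    // slip/pressure
              }
              i64 fn = fidx(d, nf[0], nf[1], nf[2]);
              i64 st = fstat[d][fn];
              if (st >= 0) {
                Ari.push_back(row); Aci.push_back(st); Avv.push_back(-cmu);
                diag += cmu;
              } else {
                int ca[3] = {nf[0], nf[1], nf[2]};
                int cb2[3] = {nf[0], nf[1], nf[2]};
                ca[d] -= 1;
                int c1 = cls(ca[0], ca[1], ca[2]);
                int c2 = cls(cb2[0], cb2[1], cb2[2]);
                if (c1 == 2 && c2 == 2) {
                  // whole neighbour row solid: no-slip plane halfway
                  diag += 2.0 * cmu;
                } else if (st == -1) {
                  diag += cmu;
                  rhs[row] += cmu * fval[d][fn];
                }
                // remaining -2 cases (open region): zero gradient
              }
            }
          }
          Ari.push_back(row); Aci.push_back(row); Avv.push_back(diag);
          adiag[row] = diag;
          // pressure gradient: (p_plus - p_minus) / h
          for (int s = -1; s <= 1; s += 2) {
            int cb[3] = {i, j, k};
            cb[d] += (s > 0 ? 0 : -1);
            if (cls(cb[0], cb[1], cb[2]) != 1) continue;  // open: p = 0
            i64 cidx = cb[0] + sy * (i64)cb[1] + sz * (i64)cb[2];
            Gri.push_back(row); Gci.push_back(punk[cidx]);
            Gvv.push_back(s / h);
          }
        }
  }

  // continuity rows: G^T u = rhs_p (from fixed faces)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        i64 c = i + sy * (i64)j + sz * (i64)k;
        i64 pc = punk[c];
        if (pc < 0) continue;
        for (int d = 0; d < 3; ++d)
          for (int s = 0; s <= 1; ++s) {
            int ff[3] = {i, j, k};
            ff[d] += s;
            i64 f = fidx(d, ff[0], ff[1], ff[2]);
            double sgn = (s == 1 ? 1.0 : -1.0) / h;  // div = sum sgn * u
            // matrix part comes from Gt (transpose of G built above);
            // (G^T u)_c = -div of the unknown faces, so fixed faces move
            // to the rhs with a + sign
            i64 st = fstat[d][f];
            if (st == -1) rhs[nu + pc] += sgn * fval[d][f];
          }
      }

  CSR A, G, Gt;
  csr_from_triplets(nu, Ari, Aci, Avv, A);
  {
    CSR tmp;
    csr_from_triplets(nu, Gri, Gci, Gvv, G);
    std::vector<i64> tri(Gci.begin(), Gci.end());
    std::vector<i64> tci(Gri.begin(), Gri.end());
    dvec tvv(Gvv);
    csr_from_triplets(np, tri, tci, tvv, Gt);
  }
  Ari.clear(); Aci.clear(); Avv.clear();
  Gri.clear(); Gci.clear(); Gvv.clear();

  // preconditioner: diag(A) for velocities; diagonal Schur estimate for p
  dvec pdiag(np, 0.0);
  for (i64 r = 0; r < np; ++r) {
    double acc = 0;
    for (i64 t = Gt.ptr[r]; t < Gt.ptr[r + 1]; ++t) {
      double gv = Gt.val[t];
      acc += gv * gv / adiag[Gt.col[t]];
    }
    pdiag[r] = (acc > 0) ? acc : 1.0;
  }
  const i64 ntot = nu + np;
  auto K_mv = [&](const dvec& v, dvec& out) {
    std::fill(out.begin(), out.end(), 0.0);
    csr_mv_add(A, v.data(), out.data());
    csr_mv_add(G, v.data() + nu, out.data());
    csr_mv_add(Gt, v.data(), out.data() + nu);
  };
  auto M_inv = [&](const dvec& v, dvec& out) {
    for (i64 r = 0; r < nu; ++r) out[r] = v[r] / adiag[r];
    for (i64 r = 0; r < np; ++r) out[nu + r] = v[nu + r] / pdiag[r];
  };
  auto dot = [&](const dvec& a, const dvec& b2) {
    double s = 0;
    for (i64 t = 0; t < (i64)a.size(); ++t) s += a[t] * b2[t];
    return s;
  };

  // preconditioned MINRES (Paige & Saunders)
  dvec x(ntot, 0.0), r1(rhs), r2(rhs), y(ntot), v(ntot), w(ntot, 0.0),
      w1(ntot, 0.0), w2(ntot, 0.0);
  M_inv(r1, y);
  double beta1 = dot(r1, y);
  if (beta1 < 0) stop("preconditioner is not positive definite");
  beta1 = std::sqrt(beta1);
  double qrnorm = beta1, phibar = beta1, oldb = 0.0, beta = beta1,
         dbar = 0.0, epsln = 0.0, cs = -1.0, sn = 0.0;
  int itn = 0;
  if (beta1 > 0) {
    for (itn = 1; itn <= maxit; ++itn) {
      double s = 1.0 / beta;
      for (i64 t = 0; t < ntot; ++t) v[t] = s * y[t];
      K_mv(v, y);
      if (itn >= 2) {
        double c0 = beta / oldb;
        for (i64 t = 0; t < ntot; ++t) y[t] -= c0 * r1[t];
      }
      double alfa = dot(v, y);
      double c1 = alfa / beta;
      for (i64 t = 0; t < ntot; ++t) y[t] -= c1 * r2[t];
      r1.swap(r2);
      r2 = y;
      M_inv(r2, y);
      oldb = beta;
      beta = dot(r2, y);
      if (beta < 0) stop("preconditioner is not positive definite");
      beta = std::sqrt(beta);
      double oldeps = epsln;
      double delta = cs * dbar + sn * alfa;
      double gbar = sn * dbar - cs * alfa;
      epsln = sn * beta;
      dbar = -cs * beta;
      double gamma = std::sqrt(gbar * gbar + beta * beta);
      gamma = std::max(gamma, 1e-300);
      cs = gbar / gamma;
      sn = beta / gamma;
      double phi = cs * phibar;
      phibar = sn * phibar;
      double denom = 1.0 / gamma;
      w1.swap(w2);
      w2.swap(w);
      for (i64 t = 0; t < ntot; ++t)
        w[t] = (v[t] - oldeps * w1[t] - delta * w2[t]) * denom;
      for (i64 t = 0; t < ntot; ++t) x[t] += phi * w[t];
      qrnorm = phibar;
      if (qrnorm <= tol * beta1) break;
    }
  }

  // pack face arrays (fixed faces carry their prescribed values)
  List ufield(3);
  for (int d = 0; d < 3; ++d) {
    NumericVector u(fN[d]);
    u.attr("dim") = IntegerVector::create(fdim[d][0], fdim[d][1], fdim[d][2]);
    for (i64 f = 0; f < fN[d]; ++f) {
      i64 st = fstat[d][f];
      u[f] = (st >= 0) ? x[st] : fval[d][f];
    }
    ufield[d] = u;
  }
  NumericVector p(N);
  for (i64 c = 0; c < N; ++c) p[c] = (punk[c] >= 0) ? x[nu + punk[c]] : NA_REAL;
  p.attr("dim") = dims;

  return List::create(_["u"] = ufield, _["p"] = p,
                      _["iterations"] = itn,
                      _["relres"] = qrnorm / (beta1 > 0 ? beta1 : 1.0),
                      _["n_unknowns"] = (double)ntot);
}
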