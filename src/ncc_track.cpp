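#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Normalized cross-correlation block matching, offset-major: for each search
// offset a summed-volume table (SAT) of the product a(x)*b(x+o) makes the
// cross term an O(1) box sum per center; block mean/variance terms come from
// global SATs of a, a^2, b, b^2. A second pass recomputes the correlations
// neighbouring each center's peak for parabolic subvoxel refinement.

struct Sat {
  std::vector<double> S;
  int nx1, ny1, nz1;
  void build(const double *v, int nx, int ny, int nz) {
    nx1 = nx + 1; ny1 = ny + 1; nz1 = nz + 1;
    S.assign((size_t)nx1 * ny1 * nz1, 0.0);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        double run = 0.0;
        const double *row = v + (size_t)z * nx * ny + (size_t)y * nx;
        double *Sc  = S.data() + (size_t)(z + 1) * nx1 * ny1 + (size_t)(y + 1) * nx1;
        double *Szy = S.data() + (size_t)(z + 1) * nx1 * ny1 + (size_t)y * nx1;
        double *Syz = S.data() + (size_t)z * nx1 * ny1 + (size_t)(y + 1) * nx1;
        double *Szz = S.data() + (size_t)z * nx1 * ny1 + (size_t)y * nx1;
        for (int x = 0; x < nx; ++x) {
          run += row[x];
          Sc[x + 1] = run + Szy[x + 1] + Syz[x + 1] - Szz[x + 1];
        }
      }
  }
  // inclusive 0-based box sum
  inline double box(int x0, int x1, int y0, int y1, int z0, int z1) const {
    const size_t p = (size_t)nx1 * ny1;
    const double *s = S.data();
    auto at = [&](int x, int y, int z) { return s[(size_t)z * p + (size_t)y * nx1 + x]; };
    return at(x1 + 1, y1 + 1, z1 + 1) - at(x0, y1 + 1, z1 + 1) -
           at(x1 + 1, y0, z1 + 1) - at(x1 + 1, y1 + 1, z0) +
           at(x0, y0, z1 + 1) + at(x0, y1 + 1, z0) + at(x1 + 1, y0, z0) -
           at(x0, y0, z0);
  }
};

// [[Rcpp::export(name = ".ncc_track_cpp")]]
List ncc_track_cpp(NumericVector a, NumericVector b, IntegerVector dim,
                   IntegerVector block_half, IntegerVector search,
                   IntegerVector centers0, bool subvoxel,
                   Nullable<NumericVector> support = R_NilValue) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int bhx = block_half[0], bhy = block_half[1], bhz = block_half[2];
  const int srx = search[0], sry = search[1], srz = search[2];
  const R_xlen_t nc = centers0.size();
  const double full_n = (double)(2 * bhx + 1) * (2 * bhy + 1) * (2 * bhz + 1);
  const double eps = 1e-12;
  const double *pa = REAL(a), *pb = REAL(b);

  // optional support mask (0/1): block statistics restricted to masked
  // voxels of the reference frame, so blocks straddling the segmentation
  // boundary are not contaminated by differently-moving exterior texture
  const bool masked = support.isNotNull();
  NumericVector msk;
  const double *pm = nullptr;
  if (masked) { msk = support.get(); pm = REAL(msk); }
  const double min_n = masked ? std::max(8.0, 0.25 * full_n)
                              : std::max(4.0, 0.5 * full_n);

  Sat SA, SAA, SB, SBB, SM;
  {
    std::vector<double> tmp((size_t)nx * ny * nz);
    if (masked) {
      for (size_t i = 0; i < tmp.size(); ++i) tmp[i] = pa[i] * pm[i];
      SA.build(tmp.data(), nx, ny, nz);
      for (size_t i = 0; i < tmp.size(); ++i) tmp[i] = pa[i] * pa[i] * pm[i];
      SAA.build(tmp.data(), nx, ny, nz);
      SM.build(pm, nx, ny, nz);
    } else {
      SA.build(pa, nx, ny, nz);
      for (size_t i = 0; i < tmp.size(); ++i) tmp[i] = pa[i] * pa[i];
      SAA.build(tmp.data(), nx, ny, nz);
      SB.build(pb, nx, ny, nz);
      for (size_t i = 0; i < tmp.size(); ++i) tmp[i] = pb[i] * pb[i];
      SBB.build(tmp.data(), nx, ny, nz);
    }
  }

  // per-center block boxes (clamped to the volume)
  std::vector<int> cx(nc), cy(nc), cz(nc), ax0(nc), ax1(nc), ay0(nc),
      ay1(nc), az0(nc), az1(nc);
  std::vector<char> usable(nc, 0);
  int rx0 = nx, rx1 = -1, ry0 = ny, ry1 = -1, rz0 = nz, rz1 = -1;
  for (R_xlen_t i = 0; i < nc; ++i) {
    const int lin = centers0[i];
    cx[i] = lin % nx; cy[i] = (lin / nx) % ny; cz[i] = lin / (nx * ny);
    ax0[i] = std::max(0, cx[i] - bhx); ax1[i] = std::min(nx - 1, cx[i] + bhx);
    ay0[i] = std::max(0, cy[i] - bhy); ay1[i] = std::min(ny - 1, cy[i] + bhy);
    az0[i] = std::max(0, cz[i] - bhz); az1[i] = std::min(nz - 1, cz[i] + bhz);
    const double avol = (double)(ax1[i] - ax0[i] + 1) * (ay1[i] - ay0[i] + 1) *
                        (az1[i] - az0[i] + 1);
    if (avol >= 0.5 * full_n) {
      usable[i] = 1;
      rx0 = std::min(rx0, ax0[i]); rx1 = std::max(rx1, ax1[i]);
      ry0 = std::min(ry0, ay0[i]); ry1 = std::max(ry1, ay1[i]);
      rz0 = std::min(rz0, az0[i]); rz1 = std::max(rz1, az1[i]);
    }
  }
  NumericVector dx(nc, NA_REAL), dy(nc, NA_REAL), dz(nc, NA_REAL),
      qual(nc, NA_REAL);
  if (rx1 < rx0)
    return List::create(_["dx"] = dx, _["dy"] = dy, _["dz"] = dz,
                        _["quality"] = qual);
  const int rnx = rx1 - rx0 + 1, rny = ry1 - ry0 + 1, rnz = rz1 - rz0 + 1;

  std::vector<double> prod((size_t)rnx * rny * rnz);
  std::vector<double> prod2, prod3;
  Sat SP, SP2, SP3;
  if (masked) {
    prod2.assign(prod.size(), 0.0);
    prod3.assign(prod.size(), 0.0);
  }
  auto build_prod = [&](int ox, int oy, int oz) {
    // cross products over the region, 0 where the b index is outside:
    // plain: prod = a(x) b(x+o); masked: additionally m-weighted b moments
    for (int z = 0; z < rnz; ++z) {
      const int gz = rz0 + z, bz_ = gz + oz;
      for (int y = 0; y < rny; ++y) {
        const int gy = ry0 + y, by_ = gy + oy;
        const size_t row = (size_t)z * rnx * rny + (size_t)y * rnx;
        double *dst = prod.data() + row;
        double *d2 = masked ? prod2.data() + row : nullptr;
        double *d3 = masked ? prod3.data() + row : nullptr;
        std::fill(dst, dst + rnx, 0.0);
        if (masked) {
          std::fill(d2, d2 + rnx, 0.0);
          std::fill(d3, d3 + rnx, 0.0);
        }
        if (bz_ < 0 || bz_ >= nz || by_ < 0 || by_ >= ny) continue;
        const double *ra = pa + (size_t)gz * nx * ny + (size_t)gy * nx;
        const double *rb = pb + (size_t)bz_ * nx * ny + (size_t)by_ * nx;
        const int xlo = std::max(0, -(rx0 + ox));
        const int xhi = std::min(rnx - 1, nx - 1 - ox - rx0);
        if (masked) {
          const double *rm = pm + (size_t)gz * nx * ny + (size_t)gy * nx;
          for (int x = xlo; x <= xhi; ++x) {
            const double m = rm[rx0 + x];
            if (m == 0.0) continue;
            const double bv = rb[rx0 + x + ox];
            dst[x] = ra[rx0 + x] * bv * m;
            d2[x] = bv * m;
            d3[x] = bv * bv * m;
          }
        } else {
          for (int x = xlo; x <= xhi; ++x)
            dst[x] = ra[rx0 + x] * rb[rx0 + x + ox];
        }
      }
    }
    SP.build(prod.data(), rnx, rny, rnz);
    if (masked) {
      SP2.build(prod2.data(), rnx, rny, rnz);
      SP3.build(prod3.data(), rnx, rny, rnz);
    }
  };

  // correlation of center i at offset o, given SP built for o; returns
  // false when the joint block support is insufficient
  auto corr_at = [&](R_xlen_t i, int ox, int oy, int oz, double &out) -> bool {
    const int jx0 = std::max(ax0[i], -ox), jx1 = std::min(ax1[i], nx - 1 - ox);
    const int jy0 = std::max(ay0[i], -oy), jy1 = std::min(ay1[i], ny - 1 - oy);
    const int jz0 = std::max(az0[i], -oz), jz1 = std::min(az1[i], nz - 1 - oz);
    if (jx1 < jx0 || jy1 < jy0 || jz1 < jz0) return false;
    double n, sb, sbb;
    if (masked) {
      n = SM.box(jx0, jx1, jy0, jy1, jz0, jz1);
      if (n < min_n) return false;
      sb = SP2.box(jx0 - rx0, jx1 - rx0, jy0 - ry0, jy1 - ry0, jz0 - rz0,
                   jz1 - rz0);
      sbb = SP3.box(jx0 - rx0, jx1 - rx0, jy0 - ry0, jy1 - ry0, jz0 - rz0,
                    jz1 - rz0);
    } else {
      n = (double)(jx1 - jx0 + 1) * (jy1 - jy0 + 1) * (jz1 - jz0 + 1);
      if (n < min_n) return false;
      sb = SB.box(jx0 + ox, jx1 + ox, jy0 + oy, jy1 + oy, jz0 + oz, jz1 + oz);
      sbb = SBB.box(jx0 + ox, jx1 + ox, jy0 + oy, jy1 + oy, jz0 + oz, jz1 + oz);
    }
    const double sa = SA.box(jx0, jx1, jy0, jy1, jz0, jz1);
    const double saa = SAA.box(jx0, jx1, jy0, jy1, jz0, jz1);
    const double sab = SP.box(jx0 - rx0, jx1 - rx0, jy0 - ry0, jy1 - ry0,
                              jz0 - rz0, jz1 - rz0);
    const double va = saa - sa * sa / n, vb = sbb - sb * sb / n;
    if (va <= eps || vb <= eps) { out = 0.0; return true; }
    double c = (sab - sa * sb / n) / std::sqrt(va * vb);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    out = c;
    return true;
  };

  std::vector<double> best(nc, -2.0);
  std::vector<int> bx(nc, 0), by(nc, 0), bz(nc, 0);
  std::vector<char> found(nc, 0);
  for (int oz = -srz; oz <= srz; ++oz)
    for (int oy = -sry; oy <= sry; ++oy)
      for (int ox = -srx; ox <= srx; ++ox) {
        build_prod(ox, oy, oz);
        const int om = ox * ox + oy * oy + oz * oz;
        for (R_xlen_t i = 0; i < nc; ++i) {
          if (!usable[i]) continue;
          double c;
          if (!corr_at(i, ox, oy, oz, c)) continue;
          const int bm = bx[i] * bx[i] + by[i] * by[i] + bz[i] * bz[i];
          if (!found[i] || c > best[i] + 1e-12 ||
              (c > best[i] - 1e-12 && om < bm)) {
            best[i] = c; bx[i] = ox; by[i] = oy; bz[i] = oz; found[i] = 1;
          }
        }
      }

  std::vector<double> sub(nc * 3, 0.0);
  if (subvoxel) {
    // gather the 6 peak-neighbour correlations per center, grouped by offset
    const long W = 2 * std::max(srx, std::max(sry, srz)) + 3;
    auto okey = [&](int ox, int oy, int oz) {
      return ((long)(oz + srz + 1) * W + (oy + sry + 1)) * W + (ox + srx + 1);
    };
    std::map<long, std::vector<std::pair<R_xlen_t, int>>> need;
    const int doff[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                            {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
    for (R_xlen_t i = 0; i < nc; ++i) {
      if (!found[i]) continue;
      for (int k = 0; k < 6; ++k) {
        const int ox = bx[i] + doff[k][0], oy = by[i] + doff[k][1],
                  oz = bz[i] + doff[k][2];
        if (ox < -srx || ox > srx || oy < -sry || oy > sry || oz < -srz ||
            oz > srz)
          continue;
        need[okey(ox, oy, oz)].push_back({i, k});
      }
    }
    std::vector<double> qn(nc * 6, NA_REAL);
    for (auto &kv : need) {
      long key = kv.first;
      const int ox = (int)(key % W) - srx - 1;
      const int oy = (int)((key / W) % W) - sry - 1;
      const int oz = (int)(key / (W * W)) - srz - 1;
      build_prod(ox, oy, oz);
      for (auto &pr : kv.second) {
        double c;
        if (corr_at(pr.first, ox, oy, oz, c)) qn[pr.first * 6 + pr.second] = c;
      }
    }
    for (R_xlen_t i = 0; i < nc; ++i) {
      if (!found[i]) continue;
      // a numerically perfect peak is an exact integer match; any 3-point
      // interpolation there only reflects autocorrelation asymmetry
      if (best[i] >= 1.0 - 1e-9) continue;
      for (int axis = 0; axis < 3; ++axis) {
        double qm = qn[i * 6 + 2 * axis], qp = qn[i * 6 + 2 * axis + 1];
        double q0 = best[i];
        if (ISNAN(qm) || ISNAN(qp)) continue;
        // three-point Gaussian peak fit (log-domain parabola) reduces the
        // integer-locking bias of the plain parabola on correlation peaks;
        // fall back to the parabola when a correlation is non-positive
        if (qm > 0 && qp > 0 && q0 > 0) {
          qm = std::log(qm); qp = std::log(qp); q0 = std::log(q0);
        }
        const double denom = qm - 2.0 * q0 + qp;
        if (denom >= -1e-12) continue;  // not a concave peak
        double d = 0.5 * (qm - qp) / denom;
        if (d > 0.5) d = 0.5;
        if (d < -0.5) d = -0.5;
        sub[i * 3 + axis] = d;
      }
    }
  }

  for (R_xlen_t i = 0; i < nc; ++i) {
    if (!found[i]) continue;
    dx[i] = bx[i] + sub[i * 3];
    dy[i] = by[i] + sub[i * 3 + 1];
    dz[i] = bz[i] + sub[i * 3 + 2];
    qual[i] = best[i];
  }
  return List::create(_["dx"] = dx, _["dy"] = dy, _["dz"] = dz,
                      _["quality"] = qual);
}

// Trilinear interpolation of a 3-component field at continuous voxel
// coordinates (0-based). NA corners fall back to the nearest defined voxel;
// points outside the grid return NA.
// [[Rcpp::export(name = ".trilinear3_cpp")]]
NumericMatrix trilinear3_cpp(NumericVector fx, NumericVector fy,
                             NumericVector fz, IntegerVector dim,
                             NumericMatrix pts) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t np = pts.nrow();
  NumericMatrix out(np, 3);
  const double *F[3] = {REAL(fx), REAL(fy), REAL(fz)};
  auto lin = [&](int x, int y, int z) {
    return (size_t)z * nx * ny + (size_t)y * nx + x;
  };
  for (R_xlen_t i = 0; i < np; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    if (ISNAN(px) || ISNAN(py) || ISNAN(pz) || px < 0 || py < 0 || pz < 0 ||
        px > nx - 1 || py > ny - 1 || pz > nz - 1) {
      out(i, 0) = out(i, 1) = out(i, 2) = NA_REAL;
      continue;
    }
    int x0 = (int)std::floor(px), y0 = (int)std::floor(py), z0 = (int)std::floor(pz);
    if (x0 >= nx - 1) x0 = nx - 2;
    if (y0 >= ny - 1) y0 = ny - 2;
    if (z0 >= nz - 1) z0 = nz - 2;
    const double tx = px - x0, ty = py - y0, tz = pz - z0;
    bool any_na = false;
    for (int c = 0; c < 3 && !any_na; ++c)
      for (int dz_ = 0; dz_ < 2 && !any_na; ++dz_)
        for (int dy_ = 0; dy_ < 2 && !any_na; ++dy_)
          for (int dx_ = 0; dx_ < 2; ++dx_)
            if (ISNAN(F[c][lin(x0 + dx_, y0 + dy_, z0 + dz_)])) {
              any_na = true;
              break;
            }
    if (!any_na) {
      for (int c = 0; c < 3; ++c) {
        double acc = 0.0;
        for (int dz_ = 0; dz_ < 2; ++dz_)
          for (int dy_ = 0; dy_ < 2; ++dy_)
            for (int dx_ = 0; dx_ < 2; ++dx_) {
              const double w = (dx_ ? tx : 1 - tx) * (dy_ ? ty : 1 - ty) *
                               (dz_ ? tz : 1 - tz);
              acc += w * F[c][lin(x0 + dx_, y0 + dy_, z0 + dz_)];
            }
        out(i, c) = acc;
      }
    } else {
      // nearest defined voxel within a small neighbourhood
      const int rx = (int)std::lround(px), ry = (int)std::lround(py),
                rz = (int)std::lround(pz);
      double bestd = 1e30;
      int bxx = -1, byy = -1, bzz = -1;
      for (int z = std::max(0, rz - 2); z <= std::min(nz - 1, rz + 2); ++z)
        for (int y = std::max(0, ry - 2); y <= std::min(ny - 1, ry + 2); ++y)
          for (int x = std::max(0, rx - 2); x <= std::min(nx - 1, rx + 2); ++x) {
            const size_t l = lin(x, y, z);
            if (ISNAN(F[0][l]) || ISNAN(F[1][l]) || ISNAN(F[2][l])) continue;
            const double dd = (x - px) * (x - px) + (y - py) * (y - py) +
                              (z - pz) * (z - pz);
            if (dd < bestd) { bestd = dd; bxx = x; byy = y; bzz = z; }
          }
      if (bxx >= 0) {
        const size_t l = lin(bxx, byy, bzz);
        out(i, 0) = F[0][l]; out(i, 1) = F[1][l]; out(i, 2) = F[2][l];
      } else {
        out(i, 0) = out(i, 1) = out(i, 2) = NA_REAL;
      }
    }
  }
  return out;
}
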