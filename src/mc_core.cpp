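// Canonical Metropolis Monte Carlo of the solvent primitive model cell:
// fixed central macroion, mobile charged/neutral hard spheres, Ewald
// electrostatics with conducting boundary conditions.  Energies in kT,
// lengths in nm, charges in e; the Coulomb prefactor is the Bjerrum length.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double mind(double d, double L) {
  if (d > 0.5 * L) d -= L; else if (d < -0.5 * L) d += L;
  return d;
}

struct KSpace {
  std::vector<int> nx, ny, nz;
  std::vector<double> A;       // 2*pi*lam/V * exp(-k^2/(4 a^2))/k^2 * mult
  std::vector<double> Sc, Ss;  // structure factor, cos and sin parts
  int nmax;
};

// build half-space k vectors with |n|^2 <= kmax2 (multiplicity 2)
static KSpace build_kspace(double L, double lam, double alpha, int kmax2) {
  KSpace K;
  K.nmax = (int)std::floor(std::sqrt((double)kmax2));
  double V = L * L * L;
  double twopiL = 2.0 * M_PI / L;
  for (int ix = -K.nmax; ix <= K.nmax; ++ix)
    for (int iy = -K.nmax; iy <= K.nmax; ++iy)
      for (int iz = -K.nmax; iz <= K.nmax; ++iz) {
        int n2 = ix * ix + iy * iy + iz * iz;
        if (n2 == 0 || n2 > kmax2) continue;
        // half space: keep the lexicographically positive representative
        if (!(iz > 0 || (iz == 0 && iy > 0) || (iz == 0 && iy == 0 && ix > 0)))
          continue;
        double k2 = twopiL * twopiL * n2;
        K.nx.push_back(ix); K.ny.push_back(iy); K.nz.push_back(iz);
        K.A.push_back(2.0 * (2.0 * M_PI * lam / V) *
                      std::exp(-k2 / (4.0 * alpha * alpha)) / k2);
      }
  K.Sc.assign(K.A.size(), 0.0);
  K.Ss.assign(K.A.size(), 0.0);
  return K;
}

// per-axis phase tables e^{i 2 pi n x / L}, n = 0..nmax
static void phase_tables(double coord, double L, int nmax,
                         std::vector<double>& c, std::vector<double>& s) {
  c.resize(nmax + 1); s.resize(nmax + 1);
  c[0] = 1.0; s[0] = 0.0;
  double a = 2.0 * M_PI * coord / L;
  double c1 = std::cos(a), s1 = std::sin(a);
  for (int n = 1; n <= nmax; ++n) {
    c[n] = c[n - 1] * c1 - s[n - 1] * s1;
    s[n] = s[n - 1] * c1 + c[n - 1] * s1;
  }
}

static inline void axis_phase(const std::vector<double>& c,
                              const std::vector<double>& s, int n,
                              double& cr, double& si) {
  if (n >= 0) { cr = c[n]; si = s[n]; }
  else        { cr = c[-n]; si = -s[-n]; }
}

static void sk_of_particle(const KSpace& K,
                           const std::vector<double>& cx, const std::vector<double>& sx,
                           const std::vector<double>& cy, const std::vector<double>& sy,
                           const std::vector<double>& cz, const std::vector<double>& sz,
                           std::vector<double>& ec, std::vector<double>& es) {
  size_t nk = K.A.size();
  ec.resize(nk); es.resize(nk);
  for (size_t m = 0; m < nk; ++m) {
    double cxr, sxi, cyr, syi, czr, szi;
    axis_phase(cx, sx, K.nx[m], cxr, sxi);
    axis_phase(cy, sy, K.ny[m], cyr, syi);
    axis_phase(cz, sz, K.nz[m], czr, szi);
    double cxy = cxr * cyr - sxi * syi;
    double sxy = sxi * cyr + cxr * syi;
    ec[m] = cxy * czr - sxy * szi;
    es[m] = sxy * czr + cxy * szi;
  }
}

static void fill_sk(KSpace& K, const NumericVector& x, const NumericVector& y,
                    const NumericVector& z, const NumericVector& q, double L) {
  std::fill(K.Sc.begin(), K.Sc.end(), 0.0);
  std::fill(K.Ss.begin(), K.Ss.end(), 0.0);
  std::vector<double> cx, sx, cy, sy, cz, sz, ec, es;
  for (int i = 0; i < x.size(); ++i) {
    if (q[i] == 0.0) continue;
    phase_tables(x[i], L, K.nmax, cx, sx);
    phase_tables(y[i], L, K.nmax, cy, sy);
    phase_tables(z[i], L, K.nmax, cz, sz);
    sk_of_particle(K, cx, sx, cy, sy, cz, sz, ec, es);
    for (size_t m = 0; m < K.A.size(); ++m) {
      K.Sc[m] += q[i] * ec[m];
      K.Ss[m] += q[i] * es[m];
    }
  }
}

static double recip_energy(const KSpace& K) {
  double u = 0.0;
  for (size_t m = 0; m < K.A.size(); ++m)
    u += K.A[m] * (K.Sc[m] * K.Sc[m] + K.Ss[m] * K.Ss[m]);
  return u;
}

// real-space energy of particle i against all others (minimum image,
// cutoff L/2); hard overlap returns +Inf
static double real_one(int i, const NumericVector& x, const NumericVector& y,
                       const NumericVector& z, const NumericVector& q,
                       const NumericVector& rad, double xi, double yi,
                       double zi, double L, double lam, double alpha) {
  double u = 0.0, rc = 0.5 * L;
  int n = x.size();
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double dx = mind(xi - x[j], L);
    double dy = mind(yi - y[j], L);
    double dz = mind(zi - z[j], L);
    double r2 = dx * dx + dy * dy + dz * dz;
    double cc = rad[i] + rad[j];
    if (r2 < cc * cc) return R_PosInf;
    if (q[i] == 0.0 || q[j] == 0.0) continue;
    if (r2 > rc * rc) continue;
    double r = std::sqrt(r2);
    u += lam * q[i] * q[j] * std::erfc(alpha * r) / r;
  }
  return u;
}

// hard-overlap test of a trial position against all other particles
static inline bool overlaps(int i, const double* x, const double* y,
                            const double* z, const double* rad, int n,
                            double xi, double yi, double zi, double L) {
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double dx = mind(xi - x[j], L);
    double dy = mind(yi - y[j], L);
    double dz = mind(zi - z[j], L);
    double cc = rad[i] + rad[j];
    if (dx * dx + dy * dy + dz * dz < cc * cc) return true;
  }
  return false;
}

// real-space Coulomb energy of charged particle i at (xi,yi,zi) against the
// charged subset (no overlap test)
static inline double real_coulomb(int i, const double* x, const double* y,
                                  const double* z, const double* q,
                                  const std::vector<int>& charged,
                                  double xi, double yi, double zi, double L,
                                  double lam, double alpha) {
  double u = 0.0, rc2 = 0.25 * L * L;
  for (size_t m = 0; m < charged.size(); ++m) {
    int j = charged[m];
    if (j == i) continue;
    double dx = mind(xi - x[j], L);
    double dy = mind(yi - y[j], L);
    double dz = mind(zi - z[j], L);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > rc2) continue;
    double r = std::sqrt(r2);
    u += lam * q[i] * q[j] * std::erfc(alpha * r) / r;
  }
  return u;
}

// [[Rcpp::export]]
List mc_total_energy(NumericVector x, NumericVector y, NumericVector z,
                     NumericVector q, NumericVector rad, double L,
                     double lam, double alpha, int kmax2, int nshell) {
  int n = x.size();
  double qs = 0.0;
  for (int i = 0; i < n; ++i) qs += q[i];
  if (std::abs(qs) > 1e-9) stop("cell is not electroneutral");
  double ur = 0.0;
  bool overlap = false;
  double rc = (nshell > 0) ? (nshell + 0.5) * L : 0.5 * L;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx0 = mind(x[i] - x[j], L);
      double dy0 = mind(y[i] - y[j], L);
      double dz0 = mind(z[i] - z[j], L);
      double r20 = dx0 * dx0 + dy0 * dy0 + dz0 * dz0;
      double cc = rad[i] + rad[j];
      if (r20 < cc * cc) overlap = true;
      if (q[i] == 0.0 || q[j] == 0.0) continue;
      for (int ax = -nshell; ax <= nshell; ++ax)
        for (int ay = -nshell; ay <= nshell; ++ay)
          for (int az = -nshell; az <= nshell; ++az) {
            double dx = dx0 + ax * L, dy = dy0 + ay * L, dz = dz0 + az * L;
            double r = std::sqrt(dx * dx + dy * dy + dz * dz);
            if (r > rc) continue;
            ur += lam * q[i] * q[j] * std::erfc(alpha * r) / r;
          }
    }
  // self-interaction with own periodic images (contributes for nshell >= 1)
  for (int i = 0; i < n; ++i) {
    if (q[i] == 0.0) continue;
    for (int ax = -nshell; ax <= nshell; ++ax)
      for (int ay = -nshell; ay <= nshell; ++ay)
        for (int az = -nshell; az <= nshell; ++az) {
          if (ax == 0 && ay == 0 && az == 0) continue;
          double r = L * std::sqrt((double)(ax * ax + ay * ay + az * az));
          if (r > rc) continue;
          ur += 0.5 * lam * q[i] * q[i] * std::erfc(alpha * r) / r;
        }
  }
  KSpace K = build_kspace(L, lam, alpha, kmax2);
  fill_sk(K, x, y, z, q, L);
  double uk = recip_energy(K);
  double us = 0.0;
  for (int i = 0; i < n; ++i) us -= lam * alpha / std::sqrt(M_PI) * q[i] * q[i];
  return List::create(_["real"] = ur, _["recip"] = uk, _["self"] = us,
                      _["total"] = ur + uk + us, _["overlap"] = overlap);
}

// [[Rcpp::export]]
List mc_run(NumericVector x, NumericVector y, NumericVector z,
            NumericVector q, NumericVector rad, IntegerVector spc,
            LogicalVector mobile, double L, double lam, double alpha,
            int kmax2, double disp, int sweeps, int sample_every,
            double bin_r0, double bin_w, int nbins, int nsp,
            double center) {
  int n = x.size();
  KSpace K = build_kspace(L, lam, alpha, kmax2);
  fill_sk(K, x, y, z, q, L);
  double uk = recip_energy(K);
  // running real-space energy
  double ur = 0.0;
  {
    bool any_overlap = false;
    for (int i = 0; i < n; ++i) {
      double ui = real_one(i, x, y, z, q, rad, x[i], y[i], z[i], L, lam, alpha);
      if (!R_finite(ui)) any_overlap = true; else ur += 0.5 * ui;
    }
    if (any_overlap) stop("initial configuration has hard overlaps");
  }
  long accepted = 0, attempted = 0;
  double* px = REAL(x); double* py = REAL(y); double* pz = REAL(z);
  double* pq = REAL(q); double* prad = REAL(rad);
  std::vector<int> charged_idx;
  std::vector<int> slot(n, -1);
  for (int i = 0; i < n; ++i)
    if (q[i] != 0.0) { slot[i] = (int)charged_idx.size(); charged_idx.push_back(i); }
  size_t nk = K.A.size();
  // cached e^{ik r_i} per charged particle (updated on acceptance)
  std::vector<double> pcC(charged_idx.size() * nk), pcS(charged_idx.size() * nk);
  {
    std::vector<double> cx, sx, cy, sy, cz, sz, ec, es;
    for (size_t m = 0; m < charged_idx.size(); ++m) {
      int i = charged_idx[m];
      phase_tables(x[i], L, K.nmax, cx, sx);
      phase_tables(y[i], L, K.nmax, cy, sy);
      phase_tables(z[i], L, K.nmax, cz, sz);
      sk_of_particle(K, cx, sx, cy, sy, cz, sz, ec, es);
      std::copy(ec.begin(), ec.end(), pcC.begin() + m * nk);
      std::copy(es.begin(), es.end(), pcS.begin() + m * nk);
    }
  }
  NumericMatrix counts(nbins, nsp);
  long nsamples = 0;
  std::vector<double> cx, sx, cy, sy, cz, sz, ecN, esN;
  RNGScope rngScope;
  for (int sw = 0; sw < sweeps; ++sw) {
    for (int i = 0; i < n; ++i) {
      if (!mobile[i]) continue;
      ++attempted;
      double xn = x[i] + disp * (unif_rand() - 0.5) * 2.0;
      double yn = y[i] + disp * (unif_rand() - 0.5) * 2.0;
      double zn = z[i] + disp * (unif_rand() - 0.5) * 2.0;
      // wrap into the box
      xn -= L * std::floor(xn / L);
      yn -= L * std::floor(yn / L);
      zn -= L * std::floor(zn / L);
      if (overlaps(i, px, py, pz, prad, n, xn, yn, zn, L))
        continue;                     // hard overlap: always reject
      bool charged = (q[i] != 0.0);
      double uold = 0.0, unew = 0.0, duk = 0.0;
      if (charged) {
        uold = real_coulomb(i, px, py, pz, pq, charged_idx,
                            x[i], y[i], z[i], L, lam, alpha);
        unew = real_coulomb(i, px, py, pz, pq, charged_idx,
                            xn, yn, zn, L, lam, alpha);
        phase_tables(xn, L, K.nmax, cx, sx);
        phase_tables(yn, L, K.nmax, cy, sy);
        phase_tables(zn, L, K.nmax, cz, sz);
        sk_of_particle(K, cx, sx, cy, sy, cz, sz, ecN, esN);
        const double* ecO = &pcC[slot[i] * nk];
        const double* esO = &pcS[slot[i] * nk];
        for (size_t m = 0; m < nk; ++m) {
          double dc = q[i] * (ecN[m] - ecO[m]);
          double ds = q[i] * (esN[m] - esO[m]);
          duk += K.A[m] * (dc * (2.0 * K.Sc[m] + dc) + ds * (2.0 * K.Ss[m] + ds));
        }
      }
      double du = (unew - uold) + duk;
      if (du <= 0.0 || unif_rand() < std::exp(-du)) {
        x[i] = xn; y[i] = yn; z[i] = zn;
        ur += unew - uold; uk += duk;
        if (charged) {
          double* ecO = &pcC[slot[i] * nk];
          double* esO = &pcS[slot[i] * nk];
          for (size_t m = 0; m < nk; ++m) {
            K.Sc[m] += q[i] * (ecN[m] - ecO[m]);
            K.Ss[m] += q[i] * (esN[m] - esO[m]);
            ecO[m] = ecN[m]; esO[m] = esN[m];
          }
        }
        ++accepted;
      }
    }
    if (sample_every > 0 && ((sw + 1) % sample_every == 0)) {
      ++nsamples;
      for (int i = 0; i < n; ++i) {
        if (spc[i] < 0) continue;
        double dx = mind(x[i] - center, L);
        double dy = mind(y[i] - center, L);
        double dz = mind(z[i] - center, L);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        int b = (int)std::floor((r - bin_r0) / bin_w);
        if (b >= 0 && b < nbins) counts(b, spc[i]) += 1.0;
      }
    }
  }
  double us = 0.0;
  for (int i = 0; i < n; ++i) us -= lam * alpha / std::sqrt(M_PI) * q[i] * q[i];
  // fresh full recompute for the bookkeeping invariant
  double ur_fresh = 0.0;
  for (int i = 0; i < n; ++i) {
    double ui = real_one(i, x, y, z, q, rad, x[i], y[i], z[i], L, lam, alpha);
    ur_fresh += 0.5 * ui;
  }
  KSpace K2 = build_kspace(L, lam, alpha, kmax2);
  fill_sk(K2, x, y, z, q, L);
  double uk_fresh = recip_energy(K2);
  return List::create(_["x"] = x, _["y"] = y, _["z"] = z,
                      _["accepted"] = (double)accepted,
                      _["attempted"] = (double)attempted,
                      _["counts"] = counts, _["nsamples"] = (double)nsamples,
                      _["U_running"] = ur + uk + us,
                      _["U_fresh"] = ur_fresh + uk_fresh + us);
}

// overlap-free sequential random insertion (positions for mobile particles);
// returns a matrix or throws after too many failures
// [[Rcpp::export]]
NumericMatrix mc_insert(NumericVector rad, double L, double Rmac,
                        int max_attempts) {
  int n = rad.size();
  NumericMatrix pos(n, 3);
  double c = 0.5 * L;
  RNGScope rngScope;
  for (int i = 0; i < n; ++i) {
    bool placed = false;
    for (int att = 0; att < max_attempts; ++att) {
      double xi = unif_rand() * L, yi = unif_rand() * L, zi = unif_rand() * L;
      double dx = mind(xi - c, L), dy = mind(yi - c, L), dz = mind(zi - c, L);
      double cc = Rmac + rad[i];
      if (dx * dx + dy * dy + dz * dz < cc * cc) continue;
      bool ok = true;
      for (int j = 0; j < i; ++j) {
        double ddx = mind(xi - pos(j, 0), L);
        double ddy = mind(yi - pos(j, 1), L);
        double ddz = mind(zi - pos(j, 2), L);
        double s = rad[i] + rad[j];
        if (ddx * ddx + ddy * ddy + ddz * ddz < s * s) { ok = false; break; }
      }
      if (ok) { pos(i, 0) = xi; pos(i, 1) = yi; pos(i, 2) = zi; placed = true; break; }
    }
    if (!placed) stop("random insertion failed for particle %d", i + 1);
  }
  return pos;
}
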