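// Phase-field cores for the two tissue models.
//
// Both models evolve smooth indicator fields by explicit relaxational
// dynamics of an interfacial energy
//
//   F = sum_i Int[ D/2 |grad phi_i|^2 + w phi_i^2(1-phi_i)^2 ]
//       + volume / overlap / boundary-contact terms (fc model)
//       + boundary wetting term (germline model),
//
// with h(phi) = phi^2 (3 - 2 phi) as the interface-localized volume
// measure, so that all non-gradient forces carry a factor
// h'(phi) = 6 phi (1 - phi) and vanish in the bulk phases.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double hfun(double p) { return p * p * (3.0 - 2.0 * p); }
static inline double hprime(double p) { return 6.0 * p * (1.0 - p); }
// W(p) = p^2 (1-p)^2, W'(p) = 2 p (1-p) (1-2p)
static inline double wprime(double p) {
  return 2.0 * p * (1.0 - p) * (1.0 - 2.0 * p);
}
static inline double wfun(double p) {
  double q = p * (1.0 - p);
  return q * q;
}

// 5-point Laplacian on the follicle-cell strip: the side walls are
// Dirichlet (ghost value 0, so walls carry normal interface cost and
// cells do not spuriously wet them), top and bottom are Neumann
static inline double lap_at(const std::vector<double>& f, int x, int y,
                            int nx, int ny) {
  const double c = f[x + nx * y];
  const double l = (x > 0) ? f[x - 1 + nx * y] : 0.0;
  const double r = (x < nx - 1) ? f[x + 1 + nx * y] : 0.0;
  const double d = (y > 0) ? f[x + nx * (y - 1)] : c;
  const double u = (y < ny - 1) ? f[x + nx * (y + 1)] : c;
  return l + r + d + u - 4.0 * c;
}

// ---------------------------------------------------------------------
// Multicellular follicle-cell model
// ---------------------------------------------------------------------

// [[Rcpp::export]]
List fc_evolve_cpp(NumericVector phi0, int nx, int ny, int ncell,
                   NumericMatrix aff, int sched_every, int n_affine,
                   double D, double well, double alpha_v, double beta,
                   double a_bg, NumericVector V0, double M, double dt,
                   int n_steps, int record_every) {
  const int nn = nx * ny;
  std::vector<std::vector<double>> phi(ncell, std::vector<double>(nn));
  for (int i = 0; i < ncell; ++i)
    for (int k = 0; k < nn; ++k) phi[i][k] = phi0[k + (R_xlen_t)nn * i];

  std::vector<double> hsum(nn), hi(nn);
  std::vector<std::vector<double>> hcell(ncell, std::vector<double>(nn));
  std::vector<double> vol(ncell), a_now(ncell);

  const int nrec = n_steps / record_every + 1;
  NumericMatrix rec_ca(nrec, ncell), rec_cn(nrec, ncell), rec_vol(nrec, ncell);
  NumericVector rec_en(nrec), rec_step(nrec);
  int irec = 0;

  auto record = [&](int step) {
    // contact lengths on affine / non-affine bottom segments, volumes,
    // energy
    double energy = 0.0;
    for (int i = 0; i < ncell; ++i) {
      double ca = 0.0, cn = 0.0, v = 0.0;
      for (int x = 0; x < nx; ++x) {
        double p = phi[i][x];           // bottom row y = 0
        if (x < n_affine) ca += p; else cn += p;
      }
      for (int k = 0; k < nn; ++k) v += hfun(phi[i][k]);
      rec_ca(irec, i) = ca; rec_cn(irec, i) = cn; rec_vol(irec, i) = v;
      // interfacial + well energy
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          double c = phi[i][x + nx * y];
          if (x < nx - 1) {
            double dxv = phi[i][x + 1 + nx * y] - c;
            energy += 0.5 * D * dxv * dxv;
          }
          if (y < ny - 1) {
            double dyv = phi[i][x + nx * (y + 1)] - c;
            energy += 0.5 * D * dyv * dyv;
          }
          if (x == 0 || x == nx - 1) energy += 0.5 * D * c * c;
          energy += well * wfun(c);
        }
      double dv = 1.0 - v / V0[i];
      energy += 0.5 * alpha_v * V0[i] * dv * dv;
      // boundary contact reward (negative energy)
      for (int x = 0; x < nx; ++x) {
        double rewards = a_bg + ((x < n_affine) ? a_now[i] : 0.0);
        energy -= rewards * hfun(phi[i][x]);
      }
    }
    // pairwise overlap
    for (int k = 0; k < nn; ++k) {
      double s = 0.0, s2 = 0.0;
      for (int i = 0; i < ncell; ++i) {
        double h = hcell[i][k];
        s += h; s2 += h * h;
      }
      energy += 0.5 * beta * (s * s - s2);
    }
    rec_en(irec) = energy; rec_step(irec) = step;
    ++irec;
  };

  for (int step = 0; step <= n_steps; ++step) {
    // schedule update
    if (step % sched_every == 0 || step == 0) {
      int su = step / sched_every;
      if (su > aff.nrow() - 1) su = aff.nrow() - 1;
      for (int i = 0; i < ncell; ++i) a_now[i] = aff(su, i);
    }
    // precompute h fields, their sum, volumes
    for (int k = 0; k < nn; ++k) hsum[k] = 0.0;
    for (int i = 0; i < ncell; ++i) {
      double v = 0.0;
      for (int k = 0; k < nn; ++k) {
        double h = hfun(phi[i][k]);
        hcell[i][k] = h; hsum[k] += h; v += h;
      }
      vol[i] = v;
    }
    if (step % record_every == 0) record(step);
    if (step == n_steps) break;

    for (int i = 0; i < ncell; ++i) {
      const double volforce = alpha_v * (1.0 - vol[i] / V0[i]);
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          const int k = x + nx * y;
          const double p = phi[i][k];
          double force = D * lap_at(phi[i], x, y, nx, ny)
                       - well * wprime(p);
          double tilt = volforce - beta * (hsum[k] - hcell[i][k]);
          if (y == 0) tilt += a_bg + ((x < n_affine) ? a_now[i] : 0.0);
          force += hprime(p) * tilt;
          double np = p + dt * M * force;
          if (np < -0.1) np = -0.1;
          if (np > 1.1) np = 1.1;
          phi[i][k] = np;
        }
      }
    }
  }

  NumericVector phiR((R_xlen_t)nn * ncell);
  for (int i = 0; i < ncell; ++i)
    for (int k = 0; k < nn; ++k) phiR[k + (R_xlen_t)nn * i] = phi[i][k];
  phiR.attr("dim") = IntegerVector::create(nx, ny, ncell);
  return List::create(_["phi"] = phiR, _["contact_affine"] = rec_ca,
                      _["contact_nonaffine"] = rec_cn,
                      _["volumes"] = rec_vol, _["energy"] = rec_en,
                      _["step"] = rec_step);
}

// standalone energy of a follicle-cell state (same functional as above)
// [[Rcpp::export]]
List fc_energy_cpp(NumericVector phiR, int nx, int ny, int ncell,
                   NumericVector a_now, int n_affine, double D, double well,
                   double alpha_v, double beta, double a_bg,
                   NumericVector V0) {
  const int nn = nx * ny;
  double e_int = 0.0, e_vol = 0.0, e_ov = 0.0, e_con = 0.0;
  std::vector<double> hsum(nn, 0.0), hsq(nn, 0.0);
  for (int i = 0; i < ncell; ++i) {
    const double* phi = &phiR[(R_xlen_t)nn * i];
    double v = 0.0;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double c = phi[x + nx * y];
        if (x < nx - 1) {
          double dx = phi[x + 1 + nx * y] - c; e_int += 0.5 * D * dx * dx;
        }
        if (y < ny - 1) {
          double dy = phi[x + nx * (y + 1)] - c; e_int += 0.5 * D * dy * dy;
        }
        if (x == 0 || x == nx - 1) e_int += 0.5 * D * c * c;
        e_int += well * wfun(c);
        double h = hfun(c);
        v += h; hsum[x + nx * y] += h; hsq[x + nx * y] += h * h;
      }
    double dv = 1.0 - v / V0[i];
    e_vol += 0.5 * alpha_v * V0[i] * dv * dv;
    for (int x = 0; x < nx; ++x)
      e_con -= (a_bg + ((x < n_affine) ? a_now[i] : 0.0)) * hfun(phi[x]);
  }
  for (int k = 0; k < nn; ++k)
    e_ov += 0.5 * beta * (hsum[k] * hsum[k] - hsq[k]);
  return List::create(_["interfacial"] = e_int, _["volume"] = e_vol,
                      _["overlap"] = e_ov, _["contact"] = e_con,
                      _["total"] = e_int + e_vol + e_ov + e_con);
}

// ---------------------------------------------------------------------
// Two-phase germline model (oocyte vs nurse compartment)
// ---------------------------------------------------------------------

// [[Rcpp::export]]
List germline_evolve_cpp(NumericVector psi0, int nx, int ny,
                         IntegerVector mask, IntegerVector bnd_idx,
                         NumericMatrix gmat, int sched_every,
                         double D, double well, double cwet,
                         double M, double dt, int n_steps,
                         int record_every, int snapshot_every,
                         double growth_cap_step) {
  const int nn = nx * ny;
  std::vector<double> psi(nn), G(nn, 0.0), gnode(nn, 0.0);
  std::vector<int> inside;
  inside.reserve(nn);
  for (int k = 0; k < nn; ++k) {
    psi[k] = psi0[k];
    if (mask[k]) inside.push_back(k);
  }
  const int nb = bnd_idx.size();
  std::vector<char> is_bnd(nn, 0);
  for (int b = 0; b < nb; ++b) is_bnd[bnd_idx[b]] = 1;

  const int nrec = n_steps / record_every + 1;
  NumericVector rec_en(nrec), rec_area(nrec), rec_bfrac(nrec), rec_step(nrec);
  const int nsnap = n_steps / snapshot_every + 1;
  NumericVector snaps((R_xlen_t)nn * nsnap);
  NumericVector snap_step(nsnap);
  int irec = 0, isnap = 0;

  double mask_area = (double)inside.size();

  auto energy_now = [&]() {
    double e = 0.0;
    for (int idx : inside) {
      int x = idx % nx, y = idx / nx;
      double c = psi[idx];
      if (x < nx - 1 && mask[idx + 1]) {
        double dxv = psi[idx + 1] - c; e += 0.5 * D * dxv * dxv;
      }
      if (y < ny - 1 && mask[idx + nx]) {
        double dyv = psi[idx + nx] - c; e += 0.5 * D * dyv * dyv;
      }
      e += well * wfun(c);
    }
    for (int b = 0; b < nb; ++b)
      e += cwet * gnode[bnd_idx[b]] * hfun(psi[bnd_idx[b]]);
    return e;
  };

  for (int step = 0; step <= n_steps; ++step) {
    if (step % sched_every == 0 || step == 0) {
      int su = step / sched_every;
      if (su > gmat.nrow() - 1) su = gmat.nrow() - 1;
      for (int b = 0; b < nb; ++b) gnode[bnd_idx[b]] = gmat(su, b);
    }
    if (step % record_every == 0) {
      double area = 0.0, bocc = 0.0;
      for (int idx : inside) area += hfun(psi[idx]);
      for (int b = 0; b < nb; ++b) bocc += hfun(psi[bnd_idx[b]]);
      rec_en(irec) = energy_now();
      rec_area(irec) = area / mask_area;
      rec_bfrac(irec) = bocc / (double)nb;
      rec_step(irec) = step;
      ++irec;
    }
    if (step % snapshot_every == 0) {
      for (int k = 0; k < nn; ++k) snaps[k + (R_xlen_t)nn * isnap] = psi[k];
      snap_step(isnap) = step;
      ++isnap;
    }
    if (step == n_steps) break;

    // bulk force and projection coefficients
    double num_bulk = 0.0, num_full = 0.0, den = 1e-12, area_now = 0.0;
    for (int idx : inside) {
      int x = idx % nx, y = idx / nx;
      double c = psi[idx];
      double lap = 0.0;
      if (x > 0 && mask[idx - 1]) lap += psi[idx - 1] - c;
      if (x < nx - 1 && mask[idx + 1]) lap += psi[idx + 1] - c;
      if (y > 0 && mask[idx - nx]) lap += psi[idx - nx] - c;
      if (y < ny - 1 && mask[idx + nx]) lap += psi[idx + nx] - c;
      double gb = D * lap - well * wprime(c);
      double hp = hprime(c);
      double gtot = gb;
      if (is_bnd[idx]) gtot -= cwet * gnode[idx] * hp;
      G[idx] = gtot;
      num_bulk += gb * hp; num_full += gtot * hp; den += hp * hp;
      area_now += hfun(c);
    }
    // Volume stabilization.  The h'-component of the bulk force
    // (curvature-driven shrinkage of the minority phase) is projected
    // out, standing in for active germline growth, so the oocyte's
    // relative volume responds only to the boundary wetting term; and
    // the response is one-sided (the oocyte's share never falls below
    // its starting value).  When the wetting term drives growth the
    // projection does work against the curvature forces, so the energy
    // is non-increasing only while the volume constraint is passive.
    double lam_bulk = num_bulk / den, lam_full = num_full / den;
    double lambda = (lam_full < lam_bulk) ? lam_full : lam_bulk;
    // cap the relative growth rate of the oocyte share: its volume
    // fraction cannot rise faster than a physiological rate
    if (growth_cap_step > 0) {
      double dA = M * dt * (num_full - lambda * den);
      double dA_cap = growth_cap_step * area_now;
      if (dA > dA_cap) lambda += (dA - dA_cap) / (M * dt * den);
    }
    for (int idx : inside) {
      double c = psi[idx];
      double force = G[idx] - lambda * hprime(c);
      double np = c + dt * M * force;
      if (np < -0.1) np = -0.1;
      if (np > 1.1) np = 1.1;
      psi[idx] = np;
    }
  }

  snaps.attr("dim") = IntegerVector::create(nx, ny, nsnap);
  return List::create(_["psi"] = snaps, _["snap_step"] = snap_step,
                      _["energy"] = rec_en, _["area_fraction"] = rec_area,
                      _["boundary_fraction"] = rec_bfrac,
                      _["step"] = rec_step);
}
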