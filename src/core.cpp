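// Compiled simulation core: hysteretic (Walton-Braun) sphere contacts,
// viscoelastic springs/tethers/bonds, 4th-order Gear predictor-corrector,
// periodic x/y box with a bottom wall, and the per-step adhesion state
// machine (talin-like reinforcement, contraction-distance detachment).
//
// All quantities are dimensionless: lengths in mean microparticle diameters,
// forces in buoyant weights of a mean-diameter baseline particle, g = 1.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gear 5-value corrector coefficients for second-order equations with
// velocity-dependent forces (damping, hysteretic branch selection).
static const double GA0 = 19.0 / 90.0;
static const double GA1 = 3.0 / 4.0;
static const double GA3 = 1.0 / 2.0;
static const double GA4 = 1.0 / 12.0;

// viscous coefficients are capped at the explicit-integration stability
// limit per pair (reduced mass / dt); nominal values far below the cap are
// untouched, the stiff binding-spring damping is clipped to a still strongly
// damped, stable value
static const double DAMP_CAP = 0.15;

static inline double minimg(double dx, double L, double invL) {
  return dx - L * std::round(dx * invL);
}

struct PairList {
  std::vector<int> pi, pj;
  void clear() { pi.clear(); pj.clear(); }
  size_t size() const { return pi.size(); }
};

// Uniform cell grid over the periodic box cross-section; z binned from the
// instantaneous span. Only contact-enabled bodies are inserted; only pairs
// with at least one mobile member are kept.
static void build_pairs(const std::vector<double>& r0,
                        const std::vector<double>& rad,
                        const std::vector<int>& mobile,
                        const std::vector<int>& incontact,
                        int n, double Lx, double Ly, double cell,
                        double skin, PairList& pl) {
  pl.clear();
  int nx = std::max(1, (int)std::floor(Lx / cell));
  int ny = std::max(1, (int)std::floor(Ly / cell));
  double zmin = 1e300, zmax = -1e300;
  for (int i = 0; i < n; ++i) {
    if (!incontact[i]) continue;
    zmin = std::min(zmin, r0[3 * i + 2]);
    zmax = std::max(zmax, r0[3 * i + 2]);
  }
  if (zmin > zmax) return;
  int nz = std::max(1, (int)std::floor((zmax - zmin) / cell) + 1);
  double cx = Lx / nx, cy = Ly / ny, cz = (zmax - zmin) / nz + 1e-12;
  std::vector<int> head((size_t)nx * ny * nz, -1), nxt(n, -1);
  std::vector<int> cix(n), ciy(n), ciz(n);
  double invLx = 1.0 / Lx, invLy = 1.0 / Ly;
  for (int i = 0; i < n; ++i) {
    if (!incontact[i]) continue;
    double x = r0[3 * i] - Lx * std::floor(r0[3 * i] * invLx);
    double y = r0[3 * i + 1] - Ly * std::floor(r0[3 * i + 1] * invLy);
    int ix = std::min(nx - 1, (int)(x / cx));
    int iy = std::min(ny - 1, (int)(y / cy));
    int iz = std::min(nz - 1, std::max(0, (int)((r0[3 * i + 2] - zmin) / cz)));
    cix[i] = ix; ciy[i] = iy; ciz[i] = iz;
    int c = (iz * ny + iy) * nx + ix;
    nxt[i] = head[c]; head[c] = i;
  }
  for (int i = 0; i < n; ++i) {
    if (!incontact[i] || !mobile[i]) continue;
    for (int dz = -1; dz <= 1; ++dz) {
      int iz = ciz[i] + dz;
      if (iz < 0 || iz >= nz) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int iy = (ciy[i] + dy + ny) % ny;
        for (int dx = -1; dx <= 1; ++dx) {
          int ix = (cix[i] + dx + nx) % nx;
          for (int j = head[(iz * ny + iy) * nx + ix]; j >= 0; j = nxt[j]) {
            if (j == i) continue;
            // each mobile-mobile pair once; mobile-static kept from the
            // mobile side only
            if (mobile[j] && j < i) continue;
            double ddx = minimg(r0[3 * j] - r0[3 * i], Lx, invLx);
            double ddy = minimg(r0[3 * j + 1] - r0[3 * i + 1], Ly, invLy);
            double ddz = r0[3 * j + 2] - r0[3 * i + 2];
            double cut = rad[i] + rad[j] + skin;
            if (ddx * ddx + ddy * ddy + ddz * ddz < cut * cut) {
              pl.pi.push_back(i); pl.pj.push_back(j);
            }
          }
        }
      }
    }
  }
}

// phase codes: 0 = settle (kinetic-energy criterion over particles),
//              2 = relax (net-force criterion over watched elements),
//              3 = fixed-step run (optional natural-length shrink +
//                  adhesion checks every step)
// [[Rcpp::export]]
List cpp_run_phase(List scene, List par) {
  NumericMatrix pos0 = scene["pos"], vel0 = scene["vel"], hd0 = scene["hd"];
  NumericVector diamR = scene["diam"], massR = scene["mass"], weightR = scene["weight"];
  IntegerVector mobileR = scene["mobile"], incontactR = scene["incontact"],
    kindR = scene["kind"], terminalR = scene["terminal"];
  NumericVector boxR = scene["box"];
  double floorz = as<double>(scene["floor"]);
  NumericMatrix springs = clone(as<NumericMatrix>(scene["springs"]));
  NumericMatrix tethers = scene["tethers"];
  int center = as<int>(scene["center"]) - 1;  // -1 when absent
  NumericMatrix bonds = clone(as<NumericMatrix>(scene["bonds"]));

  const int n = pos0.nrow();
  const int S = springs.nrow(), T = tethers.nrow(), B = bonds.nrow();
  const double dt = as<double>(par["dt"]);
  const double yu = as<double>(par["yu"]), yl = as<double>(par["yl"]);
  const double g = as<double>(par["g"]);
  const double skin = as<double>(par["skin"]);
  const int phase = as<int>(par["phase"]);
  const long max_steps = (long)as<double>(par["max_steps"]);
  const int check_every = as<int>(par["check_every"]);
  const double ke_threshold = as<double>(par["ke_threshold"]);
  const double ke_cap = as<double>(par["ke_cap"]);
  const long arm_steps = (long)as<double>(par["arm_steps"]);
  IntegerVector watchR = par["watch"];          // 1-based element indices
  NumericVector watch_tol = par["watch_tol"];   // per-watched-body tolerance
  NumericVector shrinkR = par["shrink"];        // per-spring dL0/dt, length S or 0
  const double detach_dist = as<double>(par["detach_dist"]);
  const double f_threshold = as<double>(par["f_threshold"]);
  const bool adhesion = as<bool>(par["adhesion"]);
  const double drag = as<double>(par["drag"]);
  const double v_still = as<double>(par["v_still"]);
  const bool bind_enabled = as<bool>(par["bind"]);
  const double bond_rate = as<double>(par["bond_rate"]);

  const double Lx = boxR[0], Ly = boxR[1];
  const double invLx = 1.0 / Lx, invLy = 1.0 / Ly;

  std::vector<double> r0(3 * n), r1(3 * n), r2(3 * n), r3(3 * n), r4(3 * n);
  std::vector<double> F(3 * n, 0.0), Fb(3 * n, 0.0), rad(n), mass(n),
    weight(n), diam(n);
  std::vector<int> mobile(n), incontact(n), kind(n), terminal(n);
  const double dt2 = dt * dt / 2.0, dt3 = dt * dt * dt / 6.0,
    dt4 = dt * dt * dt * dt / 24.0;
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < 3; ++d) {
      r0[3 * i + d] = pos0(i, d);
      r1[3 * i + d] = vel0(i, d) * dt;
      r2[3 * i + d] = hd0(i, d) * dt2;
      r3[3 * i + d] = hd0(i, 3 + d) * dt3;
      r4[3 * i + d] = hd0(i, 6 + d) * dt4;
    }
    rad[i] = diamR[i] / 2.0; diam[i] = diamR[i];
    mass[i] = massR[i]; weight[i] = weightR[i];
    mobile[i] = mobileR[i]; incontact[i] = incontactR[i];
    kind[i] = kindR[i]; terminal[i] = terminalR[i];
  }
  int n_particles = 0;
  for (int i = 0; i < n; ++i) if (kind[i] == 0) ++n_particles;

  const int W = watchR.size();
  std::vector<int> watch(W);
  for (int w = 0; w < W; ++w) watch[w] = watchR[w] - 1;

  bool do_shrink = false;
  for (int s = 0; s < (int)shrinkR.size(); ++s)
    if (shrinkR[s] > 0) { do_shrink = true; break; }

  double maxdiam = 0.0;
  for (int i = 0; i < n; ++i) if (incontact[i]) maxdiam = std::max(maxdiam, diam[i]);
  const double gridcell = std::max(maxdiam + skin, 1e-6);

  PairList pl;
  build_pairs(r0, rad, mobile, incontact, n, Lx, Ly, gridcell, skin, pl);
  double disp_acc = 0.0;
  std::vector<int> mob_idx;
  mob_idx.reserve(n);
  bool mob_dirty = true;

  std::vector<double> belast(B, 0.0), belast_f(B, 0.0);
  std::vector<int> has_bond(n, 0);
  for (int b = 0; b < B; ++b)
    if (bonds(b, 5) == 0.0 || bonds(b, 5) == 1.0)
      has_bond[(int)bonds(b, 0) - 1] = 1;
  std::vector<double> best_ov(n);
  std::vector<int> best_pj(n);
  std::vector<long> ev_step; std::vector<int> ev_bond, ev_type;
  std::vector<double> ev_force;

  bool converged = false, armed = false;
  long steps_done = 0;
  double ke_avg = NA_REAL, maxF_watch = NA_REAL;
  // time-averaged net force per watched body: the hysteretic contact law
  // makes instantaneous forces flip between branches at rest, so the
  // relaxation criterion uses the mean over the check interval (the momentum
  // drift rate), which vanishes in a quasi-static state
  std::vector<double> Facc(3 * W, 0.0);
  long acc_steps = 0;

  auto freeze = [&](int i) {
    mobile[i] = 0;
    mob_dirty = true;
    for (int d = 0; d < 3; ++d) {
      r1[3 * i + d] = 0; r2[3 * i + d] = 0; r3[3 * i + d] = 0; r4[3 * i + d] = 0;
    }
  };

  for (long step = 1; step <= max_steps; ++step) {
    steps_done = step;
    if (mob_dirty) {
      mob_idx.clear();
      for (int i = 0; i < n; ++i) if (mobile[i]) mob_idx.push_back(i);
      mob_dirty = false;
    }
    if (do_shrink) {
      for (int s = 0; s < S; ++s) {
        double L0 = springs(s, 2) - shrinkR[s] * dt;
        springs(s, 2) = (L0 > 0.0) ? L0 : 0.0;
      }
    }
    // predictor
    double vmax = 0.0;
    for (size_t mi = 0; mi < mob_idx.size(); ++mi) {
      int i = mob_idx[mi];
      {for (int d = 0; d < 3; ++d) {
        int k = 3 * i + d;
        r0[k] += r1[k] + r2[k] + r3[k] + r4[k];
        r1[k] += 2.0 * r2[k] + 3.0 * r3[k] + 4.0 * r4[k];
        r2[k] += 3.0 * r3[k] + 6.0 * r4[k];
        r3[k] += 4.0 * r4[k];
      }
      }
      // periodic wrap (x, y)
      r0[3 * i] -= Lx * std::floor(r0[3 * i] * invLx);
      r0[3 * i + 1] -= Ly * std::floor(r0[3 * i + 1] * invLy);
    }
    if (2.0 * disp_acc > skin) {
      build_pairs(r0, rad, mobile, incontact, n, Lx, Ly, gridcell, skin, pl);
      disp_acc = 0.0;
    }

    // forces (accumulated only on mobile bodies / bond endpoints)
    for (size_t mi = 0; mi < mob_idx.size(); ++mi) {
      int i = mob_idx[mi];
      F[3 * i] = 0.0; F[3 * i + 1] = 0.0; F[3 * i + 2] = -weight[i] * g;
      Fb[3 * i] = 0.0; Fb[3 * i + 1] = 0.0; Fb[3 * i + 2] = 0.0;
    }
    for (int b = 0; b < B; ++b) {
      if (bonds(b, 5) != 0.0 && bonds(b, 5) != 1.0) continue;
      for (int z = 0; z < 2; ++z) {
        int i = (int)bonds(b, z) - 1;
        if (!mobile[i]) {
          F[3 * i] = 0.0; F[3 * i + 1] = 0.0; F[3 * i + 2] = 0.0;
          Fb[3 * i] = 0.0; Fb[3 * i + 1] = 0.0; Fb[3 * i + 2] = 0.0;
        }
      }
    }
    if (drag > 0.0) {
      // equilibrium-seeking viscous drag (relaxation phases only): does not
      // alter the quasi-static endpoint, only how fast it is reached
      for (size_t mi = 0; mi < mob_idx.size(); ++mi) {
        int i = mob_idx[mi];
        double cd = drag * mass[i];
        F[3 * i] -= cd * r1[3 * i] / dt;
        F[3 * i + 1] -= cd * r1[3 * i + 1] / dt;
        F[3 * i + 2] -= cd * r1[3 * i + 2] / dt;
      }
    }
    // bottom wall, same hysteretic law, stiffness scaled by own diameter
    for (int i = 0; i < n; ++i) {
      if (!mobile[i] || !incontact[i]) continue;
      double delta = floorz + rad[i] - r0[3 * i + 2];
      if (delta > 0.0) {
        double Y = ((r1[3 * i + 2] < 0.0) ? yu : yl) * diam[i];
        F[3 * i + 2] += Y * delta;
      }
    }
    // sphere-sphere contacts
    if (bind_enabled)
      for (int i = 0; i < n; ++i) { best_ov[i] = 0.0; best_pj[i] = -1; }
    const size_t NP = pl.size();
    for (size_t p = 0; p < NP; ++p) {
      int i = pl.pi[p], j = pl.pj[p];
      if (!mobile[i] && !mobile[j]) continue;
      double dx = minimg(r0[3 * j] - r0[3 * i], Lx, invLx);
      double dy = minimg(r0[3 * j + 1] - r0[3 * i + 1], Ly, invLy);
      double dz = r0[3 * j + 2] - r0[3 * i + 2];
      double rsum = rad[i] + rad[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= rsum * rsum) continue;
      if (bind_enabled) {
        double ov = rsum - std::sqrt(d2);
        // integrin binding is instantaneous: an unbonded, non-terminal
        // element engages the deepest-overlap microparticle it touches
        if (kind[i] == 1 && kind[j] == 0 && !has_bond[i] && !terminal[i] &&
            ov > best_ov[i]) { best_ov[i] = ov; best_pj[i] = j; }
        if (kind[j] == 1 && kind[i] == 0 && !has_bond[j] && !terminal[j] &&
            ov > best_ov[j]) { best_ov[j] = ov; best_pj[j] = i; }
      }
      if (d2 < 1e-24)
        stop("degenerate geometry: coincident centers (bodies %d, %d) at step %ld",
             i + 1, j + 1, step);
      double r = std::sqrt(d2);
      double delta = rsum - r;
      double rv = (r1[3 * j] - r1[3 * i]) * dx + (r1[3 * j + 1] - r1[3 * i + 1]) * dy
        + (r1[3 * j + 2] - r1[3 * i + 2]) * dz;  // sign of d|r|/dt
      double Y = ((rv < 0.0) ? yu : yl) * 0.5 * (diam[i] + diam[j]);
      double f = Y * delta / r;
      if (mobile[i]) { F[3 * i] -= f * dx; F[3 * i + 1] -= f * dy; F[3 * i + 2] -= f * dz; }
      if (mobile[j]) { F[3 * j] += f * dx; F[3 * j + 1] += f * dy; F[3 * j + 2] += f * dz; }
    }
    // structural springs (viscous term integrated semi-implicitly)
    for (int s = 0; s < S; ++s) {
      int i = (int)springs(s, 0) - 1, j = (int)springs(s, 1) - 1;
      if (!mobile[i] && !mobile[j]) continue;
      double dx = minimg(r0[3 * j] - r0[3 * i], Lx, invLx);
      double dy = minimg(r0[3 * j + 1] - r0[3 * i + 1], Ly, invLy);
      double dz = r0[3 * j + 2] - r0[3 * i + 2];
      double L = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (L < 1e-12)
        stop("degenerate geometry: coincident spring endpoints (spring %d) at step %ld",
             s + 1, step);
      double nx = dx / L, ny = dy / L, nz = dz / L;
      double ext = L - springs(s, 2);
      double vrel = ((r1[3 * j] - r1[3 * i]) * nx + (r1[3 * j + 1] - r1[3 * i + 1]) * ny
                     + (r1[3 * j + 2] - r1[3 * i + 2]) * nz) / dt;
      double mu = (mobile[i] && mobile[j])
        ? mass[i] * mass[j] / (mass[i] + mass[j])
        : (mobile[i] ? mass[i] : mass[j]);
      double c = springs(s, 4);
      double ceff = std::min(c, DAMP_CAP * mu / dt);
      double fmag = springs(s, 3) * ext + ceff * vrel;
      if (mobile[i]) { F[3 * i] += fmag * nx; F[3 * i + 1] += fmag * ny; F[3 * i + 2] += fmag * nz; }
      if (mobile[j]) { F[3 * j] -= fmag * nx; F[3 * j + 1] -= fmag * ny; F[3 * j + 2] -= fmag * nz; }
    }
    // fictitious tethers for inactive elements (anchor follows the center)
    for (int t = 0; t < T; ++t) {
      int i = (int)tethers(t, 0) - 1;
      if (!mobile[i] || center < 0) continue;
      double ax = r0[3 * center] + tethers(t, 1);
      double ay = r0[3 * center + 1] + tethers(t, 2);
      double az = r0[3 * center + 2] + tethers(t, 3);
      double dx = minimg(ax - r0[3 * i], Lx, invLx);
      double dy = minimg(ay - r0[3 * i + 1], Ly, invLy);
      double dz = az - r0[3 * i + 2];
      double c = tethers(t, 5);
      double ceff = std::min(c, DAMP_CAP * mass[i] / dt);
      double k = tethers(t, 4);
      F[3 * i] += k * dx + ceff * (r1[3 * center] - r1[3 * i]) / dt;
      F[3 * i + 1] += k * dy + ceff * (r1[3 * center + 1] - r1[3 * i + 1]) / dt;
      F[3 * i + 2] += k * dz + ceff * (r1[3 * center + 2] - r1[3 * i + 2]) / dt;
    }
    // corrector
    for (size_t mi = 0; mi < mob_idx.size(); ++mi) {
      int i = mob_idx[mi];
      double vm = 0.0;
      for (int d = 0; d < 3; ++d) {
        int k = 3 * i + d;
        double r2new = F[k] / mass[i] * dt2;
        double corr = r2new - r2[k];
        r0[k] += GA0 * corr;
        r1[k] += GA1 * corr;
        r2[k] = r2new;
        r3[k] += GA3 * corr;
        r4[k] += GA4 * corr;
        vm = std::max(vm, std::fabs(r1[k]));
      }
      vmax = std::max(vmax, vm);
    }
    disp_acc += vmax * 1.7320508;

    // Engaged/reinforced bonds are enforced as rigid constraints (SHAKE
    // position + RATTLE velocity projections), the stiff limit of the
    // published binding spring (saturation stretch 2.5e-5 L_i, far below
    // position resolution at this time step). The constraint dimensionality
    // follows the rotational freedom of the anchor: a MOBILE particle may
    // roll under the adhesion patch, so its bond fixes only the
    // center-to-center distance (tangential slip free); an IMMOBILE (fused /
    // frozen) particle cannot roll, so its bond locks the full relative
    // position vector recorded at binding. The per-step projection impulse
    // is the transmitted bond force, used for the net-force readout and the
    // reinforcement threshold.
    if (B > 0) {
      bool anylive = false;
      for (int b = 0; b < B; ++b)
        if ((bonds(b, 5) == 0.0 || bonds(b, 5) == 1.0) &&
            (mobile[(int)bonds(b, 0) - 1] || mobile[(int)bonds(b, 1) - 1]))
          anylive = true;
      if (anylive) {
        for (int iter = 0; iter < 50; ++iter) {
          bool done = true;
          for (int b = 0; b < B; ++b) {
            if (bonds(b, 5) != 0.0 && bonds(b, 5) != 1.0) continue;
            int i = (int)bonds(b, 0) - 1, j = (int)bonds(b, 1) - 1;
            double wi = mobile[i] ? 1.0 / mass[i] : 0.0;
            double wj = mobile[j] ? 1.0 / mass[j] : 0.0;
            double wsum = wi + wj;
            if (wsum <= 0.0) continue;
            double dx = minimg(r0[3 * j] - r0[3 * i], Lx, invLx);
            double dy = minimg(r0[3 * j + 1] - r0[3 * i + 1], Ly, invLy);
            double dz = r0[3 * j + 2] - r0[3 * i + 2];
            double ex, ey, ez;
            if (!mobile[j]) {
              // full relative-position lock to the fused anchor
              ex = dx - bonds(b, 2); ey = dy - bonds(b, 3); ez = dz - bonds(b, 4);
            } else {
              double rest = std::sqrt(bonds(b, 2) * bonds(b, 2) +
                                      bonds(b, 3) * bonds(b, 3) +
                                      bonds(b, 4) * bonds(b, 4));
              double L = std::sqrt(dx * dx + dy * dy + dz * dz);
              if (L < 1e-12)
                stop("degenerate geometry: coincident bond endpoints (bond %d) at step %ld",
                     b + 1, step);
              double u = (L - rest) / L;
              ex = dx * u; ey = dy * u; ez = dz * u;
            }
            if (std::fabs(ex) < 1e-11 && std::fabs(ey) < 1e-11 &&
                std::fabs(ez) < 1e-11) continue;
            done = false;
            double fj = wj / wsum, fi = wi / wsum;
            r0[3 * j] -= ex * fj; r0[3 * j + 1] -= ey * fj; r0[3 * j + 2] -= ez * fj;
            r0[3 * i] += ex * fi; r0[3 * i + 1] += ey * fi; r0[3 * i + 2] += ez * fi;
          }
          if (done) break;
        }
        // velocity projection and transmitted-force readout
        for (int b = 0; b < B; ++b) {
          if (bonds(b, 5) != 0.0 && bonds(b, 5) != 1.0) continue;
          int i = (int)bonds(b, 0) - 1, j = (int)bonds(b, 1) - 1;
          double wi = mobile[i] ? 1.0 / mass[i] : 0.0;
          double wj = mobile[j] ? 1.0 / mass[j] : 0.0;
          double wsum = wi + wj;
          if (wsum <= 0.0) { belast[b] = NA_REAL; continue; }
          double svx, svy, svz;
          if (!mobile[j]) {
            svx = (r1[3 * j] - r1[3 * i]) / wsum;
            svy = (r1[3 * j + 1] - r1[3 * i + 1]) / wsum;
            svz = (r1[3 * j + 2] - r1[3 * i + 2]) / wsum;
          } else {
            double dx = minimg(r0[3 * j] - r0[3 * i], Lx, invLx);
            double dy = minimg(r0[3 * j + 1] - r0[3 * i + 1], Ly, invLy);
            double dz = r0[3 * j + 2] - r0[3 * i + 2];
            double L = std::sqrt(dx * dx + dy * dy + dz * dz);
            if (L < 1e-12) { belast[b] = NA_REAL; continue; }
            double nx = dx / L, ny = dy / L, nz = dz / L;
            double vrel = (r1[3 * j] - r1[3 * i]) * nx +
              (r1[3 * j + 1] - r1[3 * i + 1]) * ny +
              (r1[3 * j + 2] - r1[3 * i + 2]) * nz;
            double sv = vrel / wsum;
            svx = sv * nx; svy = sv * ny; svz = sv * nz;
          }
          r1[3 * j] -= svx * wj; r1[3 * j + 1] -= svy * wj; r1[3 * j + 2] -= svz * wj;
          r1[3 * i] += svx * wi; r1[3 * i + 1] += svy * wi; r1[3 * i + 2] += svz * wi;
          // transmitted force = RATTLE impulse per step over dt, low-pass
          // filtered at the binding spring's own relaxation rate k_b/c_b so
          // the reinforcement readout tracks load like the physical elastic
          // force and ignores single-step collision impulses
          double lx = svx / (dt * dt), ly = svy / (dt * dt), lz = svz / (dt * dt);
          double lam = std::sqrt(lx * lx + ly * ly + lz * lz);
          belast[b] = lam;
          double alpha = 1.0 - std::exp(-bond_rate * dt);
          belast_f[b] += alpha * (lam - belast_f[b]);
          Fb[3 * i] += lx; Fb[3 * i + 1] += ly; Fb[3 * i + 2] += lz;
          Fb[3 * j] -= lx; Fb[3 * j + 1] -= ly; Fb[3 * j + 2] -= lz;
        }
      }
    }
    for (int w = 0; w < W; ++w) {
      int i = watch[w];
      Facc[3 * w] += F[3 * i] + Fb[3 * i];
      Facc[3 * w + 1] += F[3 * i + 1] + Fb[3 * i + 1];
      Facc[3 * w + 2] += F[3 * i + 2] + Fb[3 * i + 2];
    }
    ++acc_steps;

    // instantaneous integrin binding on contact (one bond per element)
    if (bind_enabled) {
      for (int e = 0; e < n; ++e) {
        if (best_pj[e] < 0) continue;
        int jp = best_pj[e];
        int row = -1;
        for (int b = 0; b < B; ++b)
          if (bonds(b, 5) < 0.0) { row = b; break; }
        if (row < 0) continue;  // no spare capacity; bound at next R-level pass
        double dx = minimg(r0[3 * jp] - r0[3 * e], Lx, invLx);
        double dy = minimg(r0[3 * jp + 1] - r0[3 * e + 1], Ly, invLy);
        double dz = r0[3 * jp + 2] - r0[3 * e + 2];
        double bd = 0.0;
        if (center >= 0 && e != center) {
          double cx = minimg(r0[3 * e] - r0[3 * center], Lx, invLx);
          double cy = minimg(r0[3 * e + 1] - r0[3 * center + 1], Ly, invLy);
          double cz = r0[3 * e + 2] - r0[3 * center + 2];
          bd = std::sqrt(cx * cx + cy * cy + cz * cz);
        }
        bonds(row, 0) = e + 1; bonds(row, 1) = jp + 1; bonds(row, 2) = dx;
        bonds(row, 3) = dy; bonds(row, 4) = dz;
        bonds(row, 5) = 0.0; bonds(row, 6) = bd;
        belast_f[row] = 0.0;
        has_bond[e] = 1;
        ev_step.push_back(step); ev_bond.push_back(row + 1);
        ev_type.push_back(0); ev_force.push_back(0.0);
      }
    }

    // adhesion state machine (during contraction runs)
    if (adhesion) {
      for (int b = 0; b < B; ++b) {
        if (bonds(b, 5) != 0.0) continue;  // engaged bonds only
        int ie = (int)bonds(b, 0) - 1, ip = (int)bonds(b, 1) - 1;
        if (R_finite(belast_f[b]) && belast_f[b] >= f_threshold) {
          bonds(b, 5) = 1.0;  // reinforced: freeze both bodies
          freeze(ie); freeze(ip);
          ev_step.push_back(step); ev_bond.push_back(b + 1);
          ev_type.push_back(1); ev_force.push_back(belast_f[b]);
          continue;
        }
        double bd = bonds(b, 6);
        // detachment when the element has moved more than the threshold
        // distance (4 percent of the initial cell diameter) toward the
        // center since the bindings were last recalculated
        double thr = bd - detach_dist;
        if (thr > 0.0 && center >= 0 && ie != center) {
          double dx = minimg(r0[3 * center] - r0[3 * ie], Lx, invLx);
          double dy = minimg(r0[3 * center + 1] - r0[3 * ie + 1], Ly, invLy);
          double dz = r0[3 * center + 2] - r0[3 * ie + 2];
          if (dx * dx + dy * dy + dz * dz < thr * thr) {
            bonds(b, 5) = 2.0;  // broken
            terminal[ie] = 1;
            has_bond[ie] = 0;
            ev_step.push_back(step); ev_bond.push_back(b + 1);
            ev_type.push_back(2); ev_force.push_back(belast[b]);
          }
        }
      }
    }

    // termination checks
    if (step % check_every == 0 || step == max_steps) {
      for (int i = 0; i < n; ++i)
        if (mobile[i] && !R_finite(r0[3 * i + 2]))
          stop("non-finite state at step %ld (body %d); reduce dt or check forces",
               step, i + 1);
      if (phase == 0) {
        double ke = 0.0, ke_max = 0.0;
        for (int i = 0; i < n; ++i) {
          if (kind[i] != 0) continue;
          double v2 = r1[3 * i] * r1[3 * i] + r1[3 * i + 1] * r1[3 * i + 1]
            + r1[3 * i + 2] * r1[3 * i + 2];
          double kei = 0.5 * mass[i] * v2 / (dt * dt);
          ke += kei;
          ke_max = std::max(ke_max, kei);
        }
        ke_avg = (n_particles > 0) ? ke / n_particles : 0.0;
        if (ke_avg >= ke_threshold) armed = true;
        // a single particle still in ballistic flight can hide under the
        // average; require stragglers to have stopped too
        if (ke_avg < ke_threshold && ke_max < ke_cap &&
            (armed || step >= arm_steps)) {
          converged = true; break;
        }
      } else if (phase == 2) {
        double mx = 0.0, vx = 0.0;
        bool any_mobile = false;
        bool ok = true;
        for (int w = 0; w < W; ++w) {
          int i = watch[w];
          if (!mobile[i]) continue;
          any_mobile = true;
          double fx = Facc[3 * w] / acc_steps, fy = Facc[3 * w + 1] / acc_steps,
            fz = Facc[3 * w + 2] / acc_steps;
          double fm = std::sqrt(fx * fx + fy * fy + fz * fz);
          mx = std::max(mx, fm);
          if (fm >= watch_tol[w]) ok = false;
          double v2 = (r1[3 * i] * r1[3 * i] + r1[3 * i + 1] * r1[3 * i + 1]
                       + r1[3 * i + 2] * r1[3 * i + 2]) / (dt * dt);
          vx = std::max(vx, std::sqrt(v2));
        }
        maxF_watch = mx;
        std::fill(Facc.begin(), Facc.end(), 0.0);
        acc_steps = 0;
        // converged when the mean net force vanishes or when every watched
        // element is still (the hysteretic contact branches make the
        // instantaneous force readout noisy at rest)
        if (ok || vx < v_still || !any_mobile) { converged = true; break; }
      } else if (W > 0) {
        bool any_mobile = false;
        for (int w = 0; w < W; ++w) if (mobile[watch[w]]) { any_mobile = true; break; }
        if (!any_mobile) { converged = true; break; }
      }
    }
  }
  if (phase == 3) converged = true;

  NumericMatrix pos_out(n, 3), vel_out(n, 3), hd_out(n, 9);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < 3; ++d) {
      pos_out(i, d) = r0[3 * i + d];
      vel_out(i, d) = r1[3 * i + d] / dt;
      hd_out(i, d) = r2[3 * i + d] / dt2;
      hd_out(i, 3 + d) = r3[3 * i + d] / dt3;
      hd_out(i, 6 + d) = r4[3 * i + d] / dt4;
    }
  }
  IntegerVector mobile_out(n), terminal_out(n);
  for (int i = 0; i < n; ++i) { mobile_out[i] = mobile[i]; terminal_out[i] = terminal[i]; }
  int NE = ev_step.size();
  NumericMatrix events(NE, 4);
  for (int e = 0; e < NE; ++e) {
    events(e, 0) = (double)ev_step[e]; events(e, 1) = ev_bond[e];
    events(e, 2) = ev_type[e]; events(e, 3) = ev_force[e];
  }
  return List::create(
    _["pos"] = pos_out, _["vel"] = vel_out, _["hd"] = hd_out,
    _["mobile"] = mobile_out, _["terminal"] = terminal_out,
    _["springs"] = springs, _["bonds"] = bonds, _["events"] = events,
    _["bond_force"] = NumericVector(belast_f.begin(), belast_f.end()),
    _["steps"] = (double)steps_done, _["converged"] = converged,
    _["ke_avg"] = ke_avg, _["max_watch_force"] = maxF_watch);
}
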