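// Core numerics: coarse-grained landscape evaluation, spherical /
// coordination-number collective variables, well-tempered bias, and the
// overdamped Langevin propagator.  Everything here is mirrored by thin R
// wrappers; R's RNG is used throughout so set.seed() gives bitwise
// reproducibility.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double KB = 0.0083145; // kJ/mol/K

struct Landscape {
  NumericMatrix wells;    // cx cy cz depth width
  NumericMatrix barriers; // cx cy cz height width
  double wall_limit, wall_k;
  double refx, refy, refz;
  bool has_pore;
  double pore_R, pore_k, pore_zmin, pore_zmax, pore_tau;
};

static Landscape as_landscape(List ls) {
  Landscape L;
  L.wells = as<NumericMatrix>(ls["wells"]);
  L.barriers = as<NumericMatrix>(ls["barriers"]);
  L.wall_limit = as<double>(ls["wall_limit"]);
  L.wall_k = as<double>(ls["wall_k"]);
  NumericVector rc = as<NumericVector>(ls["ref_com"]);
  L.refx = rc[0]; L.refy = rc[1]; L.refz = rc[2];
  L.has_pore = false;
  if (ls.containsElementNamed("pore") && !Rf_isNull(ls["pore"])) {
    List p = ls["pore"];
    L.has_pore = true;
    L.pore_R = as<double>(p["radius"]);
    L.pore_k = as<double>(p["k"]);
    L.pore_zmin = as<double>(p["z_min"]);
    L.pore_zmax = as<double>(p["z_max"]);
    L.pore_tau = as<double>(p["taper"]);
  }
  return L;
}

// energy and gradient of the smooth landscape at (x,y,z)
static double potential(const Landscape& L, double x, double y, double z,
                        double* g) {
  double U = 0.0;
  g[0] = g[1] = g[2] = 0.0;
  const int nw = L.wells.nrow();
  for (int i = 0; i < nw; ++i) {
    const double dx = x - L.wells(i, 0), dy = y - L.wells(i, 1),
                 dz = z - L.wells(i, 2);
    const double w = L.wells(i, 4), d = L.wells(i, 3);
    const double e = -d * std::exp(-(dx * dx + dy * dy + dz * dz) / (2 * w * w));
    U += e;
    const double f = -e / (w * w); // dU/ddx = f*dx
    g[0] += f * dx; g[1] += f * dy; g[2] += f * dz;
  }
  const int nb = L.barriers.nrow();
  for (int i = 0; i < nb; ++i) {
    const double dx = x - L.barriers(i, 0), dy = y - L.barriers(i, 1),
                 dz = z - L.barriers(i, 2);
    const double w = L.barriers(i, 4), h = L.barriers(i, 3);
    const double e = h * std::exp(-(dx * dx + dy * dy + dz * dz) / (2 * w * w));
    U += e;
    const double f = -e / (w * w);
    g[0] += f * dx; g[1] += f * dy; g[2] += f * dz;
  }
  // one-sided quadratic wall on rho about the reference COM
  const double vx = x - L.refx, vy = y - L.refy, vz = z - L.refz;
  const double rho = std::sqrt(vx * vx + vy * vy + vz * vz);
  if (rho > L.wall_limit && rho > 1e-12) {
    const double ex = rho - L.wall_limit;
    U += 0.5 * L.wall_k * ex * ex;
    const double f = L.wall_k * ex / rho;
    g[0] += f * vx; g[1] += f * vy; g[2] += f * vz;
  }
  // cylindrical pore wall, smoothly windowed in z
  if (L.has_pore) {
    const double rxy = std::sqrt(x * x + y * y);
    if (rxy > L.pore_R) {
      const double s1 = 1.0 / (1.0 + std::exp(-(z - L.pore_zmin) / L.pore_tau));
      const double s2 = 1.0 / (1.0 + std::exp((z - L.pore_zmax) / L.pore_tau));
      const double S = s1 * s2;
      const double ex = rxy - L.pore_R;
      U += 0.5 * L.pore_k * ex * ex * S;
      if (rxy > 1e-12) {
        const double fr = L.pore_k * ex * S / rxy;
        g[0] += fr * x; g[1] += fr * y;
      }
      const double dS = (s1 * (1 - s1) * s2 - s1 * s2 * (1 - s2)) / L.pore_tau;
      g[2] += 0.5 * L.pore_k * ex * ex * dS;
    }
  }
  return U;
}

// [[Rcpp::export]]
List cpp_potential(NumericMatrix pts, List landscape) {
  Landscape L = as_landscape(landscape);
  const int n = pts.nrow();
  NumericVector U(n);
  NumericMatrix G(n, 3);
  double g[3];
  for (int i = 0; i < n; ++i) {
    U[i] = potential(L, pts(i, 0), pts(i, 1), pts(i, 2), g);
    G(i, 0) = g[0]; G(i, 1) = g[1]; G(i, 2) = g[2];
  }
  return List::create(_["energy"] = U, _["gradient"] = G);
}

// rational switching function s(r) and ds/dr
static double switch_fun(double r, double r0, int n, int m, double* dsdr) {
  const double x = r / r0;
  double s, dsdx;
  if (m == 2 * n) {
    const double xn = std::pow(x, n);
    s = 1.0 / (1.0 + xn);
    dsdx = -n * std::pow(x, n - 1) / ((1.0 + xn) * (1.0 + xn));
  } else {
    if (std::abs(x - 1.0) < 1e-10) {
      // l'Hopital limit of (1-x^n)/(1-x^m) at x=1
      s = (double)n / (double)m;
      dsdx = 0.5 * n * (m - n) / (double)m; // from series expansion
      dsdx = -dsdx; // decreasing
    } else {
      const double xn = std::pow(x, n), xm = std::pow(x, m);
      s = (1.0 - xn) / (1.0 - xm);
      dsdx = (-n * std::pow(x, n - 1) * (1.0 - xm) +
              m * std::pow(x, m - 1) * (1.0 - xn)) /
             ((1.0 - xm) * (1.0 - xm));
    }
  }
  if (dsdr) *dsdr = dsdx / r0;
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_cn_values(NumericMatrix pts, NumericMatrix group, double r0,
                            int n, int m) {
  const int np = pts.nrow(), ng = group.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double cn = 0.0;
    for (int j = 0; j < ng; ++j) {
      const double dx = pts(i, 0) - group(j, 0), dy = pts(i, 1) - group(j, 1),
                   dz = pts(i, 2) - group(j, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      cn += switch_fun(r, r0, n, m, nullptr);
    }
    out[i] = cn;
  }
  return out;
}

// spherical CVs about ref; grads[9] = d(rho,theta,phi)/d(x,y,z) row-major
static void spherical(double x, double y, double z, double rx, double ry,
                      double rz, double* cv, double* grads) {
  const double vx = x - rx, vy = y - ry, vz = z - rz;
  const double rho = std::sqrt(vx * vx + vy * vy + vz * vz);
  double ct = vz / rho;
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  const double th = std::acos(ct);
  const double st = std::sin(th);
  double phi;
  cv[0] = rho; cv[1] = th;
  if (st < 1e-9) {
    phi = 0.0;
    cv[2] = phi;
    if (grads) {
      grads[0] = vx / rho; grads[1] = vy / rho; grads[2] = vz / rho;
      // theta gradient evaluated on the phi = 0 meridian for continuity
      grads[3] = ct / rho; grads[4] = 0.0; grads[5] = -st / rho;
      grads[6] = 0.0; grads[7] = 0.0; grads[8] = 0.0;
    }
    return;
  }
  phi = std::atan2(vy, vx);
  cv[2] = phi;
  if (grads) {
    const double cp = std::cos(phi), sp = std::sin(phi);
    grads[0] = vx / rho; grads[1] = vy / rho; grads[2] = vz / rho;
    grads[3] = ct * cp / rho; grads[4] = ct * sp / rho; grads[5] = -st / rho;
    grads[6] = -sp / (rho * st); grads[7] = cp / (rho * st); grads[8] = 0.0;
  }
}

// [[Rcpp::export]]
List cpp_spherical(NumericMatrix pts, NumericVector ref) {
  const int n = pts.nrow();
  NumericMatrix cvs(n, 3);
  double cv[3];
  for (int i = 0; i < n; ++i) {
    spherical(pts(i, 0), pts(i, 1), pts(i, 2), ref[0], ref[1], ref[2], cv,
              nullptr);
    cvs(i, 0) = cv[0]; cvs(i, 1) = cv[1]; cvs(i, 2) = cv[2];
  }
  return List::create(_["cv"] = cvs);
}

static inline double wrap_pi(double d) {
  while (d > M_PI) d -= 2.0 * M_PI;
  while (d <= -M_PI) d += 2.0 * M_PI;
  return d;
}

// hills: columns time, c_rho, c_th, c_phi, s_rho, s_th, s_phi, height.
// A non-positive width marks an inactive dimension.
static double bias_eval(const NumericMatrix& hills, int nh, const double* cv,
                        double* dVds) {
  double V = 0.0;
  if (dVds) { dVds[0] = dVds[1] = dVds[2] = 0.0; }
  for (int i = 0; i < nh; ++i) {
    double e = 0.0, d[3] = {0, 0, 0};
    bool skip = false;
    for (int k = 0; k < 3; ++k) {
      const double s = hills(i, 4 + k);
      if (s <= 0) { d[k] = 0; continue; }
      double dd = cv[k] - hills(i, 1 + k);
      if (k == 2) dd = wrap_pi(dd);
      d[k] = dd;
      e += dd * dd / (2.0 * s * s);
      if (e > 30.0) { skip = true; break; }
    }
    if (skip) continue;
    const double g = hills(i, 7) * std::exp(-e);
    V += g;
    if (dVds) {
      for (int k = 0; k < 3; ++k) {
        const double s = hills(i, 4 + k);
        if (s > 0) dVds[k] += -g * d[k] / (s * s);
      }
    }
  }
  return V;
}

// [[Rcpp::export]]
NumericVector cpp_bias_values(NumericMatrix hills, NumericMatrix cvpts) {
  const int n = cvpts.nrow();
  NumericVector out(n);
  double cv[3];
  for (int i = 0; i < n; ++i) {
    cv[0] = cvpts(i, 0); cv[1] = cvpts(i, 1); cv[2] = cvpts(i, 2);
    out[i] = bias_eval(hills, hills.nrow(), cv, nullptr);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_run_sim(NumericVector ion0, List landscape, NumericMatrix cn_group,
                 double cn_r0, int cn_n, int cn_m, List sim,
                 Nullable<List> mtd_, Nullable<List> steered_) {
  Landscape L = as_landscape(landscape);
  const double dt = as<double>(sim["dt"]);
  const double Temp = as<double>(sim["temperature"]);
  const double mob = as<double>(sim["mobility"]);
  const long n_steps = (long)as<double>(sim["n_steps"]);
  const int stride = as<int>(sim["record_stride"]);
  NumericMatrix box = as<NumericMatrix>(sim["box"]); // 2 x 3 (lo; hi)
  // noise variance 2 D dt with D = mobility * kT; vanishes at T = 0
  const double noise = std::sqrt(2.0 * mob * KB * Temp * dt);

  bool do_mtd = mtd_.isNotNull();
  double w0 = 0, gamma = 0, sig[3] = {0, 0, 0};
  long interval = 0;
  int max_hills = 0;
  if (do_mtd) {
    List mtd(mtd_);
    w0 = as<double>(mtd["w0"]);
    gamma = as<double>(mtd["bias_factor"]);
    NumericVector s = as<NumericVector>(mtd["sigma"]);
    sig[0] = s[0]; sig[1] = s[1]; sig[2] = s[2];
    interval = (long)as<double>(mtd["interval_steps"]);
    if (interval < 1) stop("deposition interval must be at least one step");
    max_hills = (int)(n_steps / interval) + 2;
  }
  NumericMatrix hills(do_mtd ? max_hills : 0, 8);
  int nh = 0;

  bool do_steer = steered_.isNotNull();
  double st_k = 0;
  NumericVector st_t, st_target;
  if (do_steer) {
    List st(steered_);
    st_k = as<double>(st["k"]);
    st_t = as<NumericVector>(st["times"]);
    st_target = as<NumericVector>(st["targets"]);
    if (st_t[st_t.size() - 1] < n_steps * dt - 1e-9)
      stop("steering schedule is shorter than the simulation");
  }

  const long n_rec_max = n_steps / stride + 2;
  NumericVector times(n_rec_max);
  NumericMatrix pos(n_rec_max, 3), cvs(n_rec_max, 4);
  NumericVector biasrec(n_rec_max);
  long nrec = 0;

  double x[3] = {ion0[0], ion0[1], ion0[2]};
  bool escaped = false;
  long escape_step = -1;

  double cv[3], sgrad[9], g[3], dVds[3];
  for (long step = 0;; ++step) {
    spherical(x[0], x[1], x[2], L.refx, L.refy, L.refz, cv, sgrad);
    double V = 0.0;
    if (do_mtd || nh > 0) V = bias_eval(hills, nh, cv, dVds);

    if (step % stride == 0 || step == n_steps) {
      times[nrec] = step * dt;
      pos(nrec, 0) = x[0]; pos(nrec, 1) = x[1]; pos(nrec, 2) = x[2];
      cvs(nrec, 0) = cv[0]; cvs(nrec, 1) = cv[1]; cvs(nrec, 2) = cv[2];
      double one[3] = {x[0], x[1], x[2]};
      NumericMatrix pm(1, 3, &one[0]);
      cvs(nrec, 3) = cpp_cn_values(pm, cn_group, cn_r0, cn_n, cn_m)[0];
      biasrec[nrec] = V;
      ++nrec;
    }
    if (step >= n_steps) break;

    // well-tempered deposition happens before the move, using V(s) now
    if (do_mtd && step > 0 && step % interval == 0) {
      const double h = w0 * std::exp(-V / ((gamma - 1.0) * KB * Temp));
      hills(nh, 0) = step * dt;
      hills(nh, 1) = cv[0]; hills(nh, 2) = cv[1]; hills(nh, 3) = cv[2];
      hills(nh, 4) = sig[0]; hills(nh, 5) = sig[1]; hills(nh, 6) = sig[2];
      hills(nh, 7) = h;
      ++nh;
      V = bias_eval(hills, nh, cv, dVds);
    }

    potential(L, x[0], x[1], x[2], g);
    double F[3] = {-g[0], -g[1], -g[2]};
    if (nh > 0) {
      for (int k = 0; k < 3; ++k)
        for (int d2 = 0; d2 < 3; ++d2)
          F[d2] -= dVds[k] * sgrad[3 * k + d2];
    }
    if (do_steer && st_k > 0) {
      // moving harmonic restraint on rho
      const double t = step * dt;
      int j = 0;
      const int ns = st_t.size();
      while (j < ns - 1 && st_t[j + 1] < t) ++j;
      double target;
      if (j >= ns - 1) target = st_target[ns - 1];
      else {
        const double f = (t - st_t[j]) / (st_t[j + 1] - st_t[j]);
        target = st_target[j] + f * (st_target[j + 1] - st_target[j]);
      }
      const double fmag = -st_k * (cv[0] - target);
      for (int d2 = 0; d2 < 3; ++d2) F[d2] += fmag * sgrad[d2];
    }
    for (int d2 = 0; d2 < 3; ++d2) {
      if (!std::isfinite(F[d2]))
        stop("non-finite force at step " + std::to_string(step));
      x[d2] += mob * F[d2] * dt + noise * norm_rand();
    }
    if (x[0] < box(0, 0) || x[0] > box(1, 0) || x[1] < box(0, 1) ||
        x[1] > box(1, 1) || x[2] < box(0, 2) || x[2] > box(1, 2)) {
      escaped = true;
      escape_step = step + 1;
      spherical(x[0], x[1], x[2], L.refx, L.refy, L.refz, cv, sgrad);
      V = (nh > 0) ? bias_eval(hills, nh, cv, nullptr) : 0.0;
      times[nrec] = (step + 1) * dt;
      pos(nrec, 0) = x[0]; pos(nrec, 1) = x[1]; pos(nrec, 2) = x[2];
      cvs(nrec, 0) = cv[0]; cvs(nrec, 1) = cv[1]; cvs(nrec, 2) = cv[2];
      double one[3] = {x[0], x[1], x[2]};
      NumericMatrix pm(1, 3, &one[0]);
      cvs(nrec, 3) = cpp_cn_values(pm, cn_group, cn_r0, cn_n, cn_m)[0];
      biasrec[nrec] = V;
      ++nrec;
      break;
    }
  }

  NumericVector t_out(nrec), b_out(nrec);
  NumericMatrix p_out(nrec, 3), c_out(nrec, 4);
  for (long i = 0; i < nrec; ++i) {
    t_out[i] = times[i]; b_out[i] = biasrec[i];
    for (int k = 0; k < 3; ++k) p_out(i, k) = pos(i, k);
    for (int k = 0; k < 4; ++k) c_out(i, k) = cvs(i, k);
  }
  NumericMatrix h_out(nh, 8);
  for (int i = 0; i < nh; ++i)
    for (int k = 0; k < 8; ++k) h_out(i, k) = hills(i, k);
  return List::create(_["times"] = t_out, _["pos"] = p_out, _["cv"] = c_out,
                      _["bias"] = b_out, _["hills"] = h_out,
                      _["escaped"] = escaped, _["escape_step"] = escape_step);
}
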