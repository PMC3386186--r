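// Numerical kernels for the spherical-flow template model.
// All heavy per-frame loops live here; the R level owns orchestration,
// parameterization and read-outs.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double EPS = 1e-12;

// Ray casting against the plan-view arena description: wall segments are
// vertical quads spanning y in [0, wall_h]; the ground is y = 0 restricted
// to the footprint. foot_type: 0 = circle (fa = radius), 1 = rect
// (fa, fb = half widths). Labels: 0 ground, 1 wall, 2 none.
// [[Rcpp::export]]
List cpp_raycast(NumericVector eye, NumericMatrix dirs, NumericMatrix segs,
                 double wall_h, int foot_type, double fa, double fb,
                 double max_dist, double min_dist) {
  const int n = dirs.nrow();
  const int m = segs.nrow();
  NumericVector D(n, NA_REAL);
  IntegerVector label(n, 2);
  NumericMatrix pt(n, 3);
  const double ex = eye[0], ey = eye[1], ez = eye[2];

  for (int i = 0; i < n; ++i) {
    const double ux = dirs(i, 0), uy = dirs(i, 1), uz = dirs(i, 2);
    double t_wall = R_PosInf;
    for (int k = 0; k < m; ++k) {
      const double x1 = segs(k, 0), z1 = segs(k, 1);
      const double x2 = segs(k, 2), z2 = segs(k, 3);
      const double gx = x2 - x1, gz = z2 - z1;
      const double den = ux * (-gz) + uz * gx;
      if (std::fabs(den) < EPS) continue;
      const double t = ((x1 - ex) * (-gz) + (z1 - ez) * gx) / den;
      if (t <= 1e-9 || t >= t_wall) continue;
      const double u = (ux * (z1 - ez) - uz * (x1 - ex)) / den;
      if (u < -1e-9 || u > 1.0 + 1e-9) continue;
      const double yh = ey + t * uy;
      if (yh < -1e-9 || yh > wall_h + 1e-9) continue;
      t_wall = t;
    }
    double t_ground = R_PosInf;
    if (uy < -EPS) {
      const double t = -ey / uy;
      const double px = ex + t * ux, pz = ez + t * uz;
      bool inside = (foot_type == 0)
        ? (px * px + pz * pz <= fa * fa + 1e-6)
        : (std::fabs(px) <= fa + 1e-6 && std::fabs(pz) <= fb + 1e-6);
      if (inside) t_ground = t;
    }
    double t = R_PosInf; int lab = 2;
    if (t_wall < t_ground) { t = t_wall; lab = 1; }
    else if (t_ground < R_PosInf) { t = t_ground; lab = 0; }
    if (lab != 2 && t <= max_dist) {
      if (t < min_dist) t = min_dist;
      D[i] = t; label[i] = lab;
      pt(i, 0) = ex + t * ux; pt(i, 1) = ey + t * uy; pt(i, 2) = ez + t * uz;
    } else {
      pt(i, 0) = NA_REAL; pt(i, 1) = NA_REAL; pt(i, 2) = NA_REAL;
    }
  }
  return List::create(_["distance"] = D, _["label"] = label, _["point"] = pt);
}

// Reference Moeller-Trumbore ray casting against a labeled triangle soup.
// tri: n x 9 (three (x,y,z) corners per row); label_tri: 0 ground, 1 wall.
// [[Rcpp::export]]
List cpp_raycast_mesh(NumericVector eye, NumericMatrix dirs, NumericMatrix tri,
                      IntegerVector label_tri, double max_dist,
                      double min_dist) {
  const int n = dirs.nrow(), m = tri.nrow();
  NumericVector D(n, NA_REAL);
  IntegerVector label(n, 2);
  NumericMatrix pt(n, 3);
  for (int i = 0; i < n; ++i) {
    const double ux = dirs(i, 0), uy = dirs(i, 1), uz = dirs(i, 2);
    double best = R_PosInf; int lab = 2;
    for (int k = 0; k < m; ++k) {
      const double ax = tri(k, 0), ay = tri(k, 1), az = tri(k, 2);
      const double e1x = tri(k, 3) - ax, e1y = tri(k, 4) - ay, e1z = tri(k, 5) - az;
      const double e2x = tri(k, 6) - ax, e2y = tri(k, 7) - ay, e2z = tri(k, 8) - az;
      const double px = uy * e2z - uz * e2y;
      const double py = uz * e2x - ux * e2z;
      const double pz = ux * e2y - uy * e2x;
      const double det = e1x * px + e1y * py + e1z * pz;
      if (std::fabs(det) < EPS) continue;
      const double inv = 1.0 / det;
      const double tx = eye[0] - ax, ty = eye[1] - ay, tz = eye[2] - az;
      const double u = (tx * px + ty * py + tz * pz) * inv;
      if (u < -1e-9 || u > 1.0 + 1e-9) continue;
      const double qx = ty * e1z - tz * e1y;
      const double qy = tz * e1x - tx * e1z;
      const double qz = tx * e1y - ty * e1x;
      const double v = (ux * qx + uy * qy + uz * qz) * inv;
      if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
      const double t = (e2x * qx + e2y * qy + e2z * qz) * inv;
      if (t > 1e-9 && t < best) { best = t; lab = label_tri[k]; }
    }
    if (lab != 2 && best <= max_dist) {
      double t = best < min_dist ? min_dist : best;
      D[i] = t; label[i] = lab;
      pt(i, 0) = eye[0] + t * ux; pt(i, 1) = eye[1] + t * uy; pt(i, 2) = eye[2] + t * uz;
    } else {
      pt(i, 0) = NA_REAL; pt(i, 1) = NA_REAL; pt(i, 2) = NA_REAL;
    }
  }
  return List::create(_["distance"] = D, _["label"] = label, _["point"] = pt);
}

// Rotational-velocity matcher: Gaussian of the Euclidean distance between
// input flow and ground templates built at the estimated linear velocity.
// a[i] = azimuth-flow residual at omega = 0, b[i] = elevation-flow residual
// (omega-independent); template azimuth flow subtracts omega.
// [[Rcpp::export]]
NumericVector cpp_match_rotation(NumericVector a, NumericVector b,
                                 NumericVector omega, double sigma) {
  const int n = a.size(), K = omega.size();
  NumericVector M(K);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  // subtract the global minimum squared residual before exponentiating:
  // a single constant shift rescales the whole curve and keeps the argmax
  // and the read-out weights intact while avoiding underflow to zero
  double minE = R_PosInf;
  for (int k = 0; k < K; ++k) {
    const double w = omega[k];
    for (int i = 0; i < n; ++i) {
      const double da = a[i] + w;
      const double E = da * da + b[i] * b[i];
      if (E < minE) minE = E;
    }
  }
  if (!R_FINITE(minE)) minE = 0.0;
  for (int k = 0; k < K; ++k) {
    const double w = omega[k];
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      const double da = a[i] + w;
      acc += std::exp(-(da * da + b[i] * b[i] - minE) * inv2s2);
    }
    M[k] = acc;
  }
  return M;
}

static inline double wrap_pi(double x) {
  while (x > M_PI) x -= 2.0 * M_PI;
  while (x < -M_PI) x += 2.0 * M_PI;
  return x;
}

// Exact wall speed-direction matcher (Perrone-style log-speed x direction
// tuning). For each (alpha, dist) template the wall-plane depth at a node
// with plan-view azimuth w (theta + phi, world) and elevation cosine cosphi
// is D = d / (cosphi * cos(alpha - w)); templates with the plane behind the
// node direction contribute nothing.
// K1/K2 carry the translational flow factors at v_est (deg/sec * cm):
// template flow = (K1 / D - omega_est, K2 / D).
// [[Rcpp::export]]
NumericMatrix cpp_match_wall2d(NumericVector logr_in, NumericVector dir_in,
                               NumericVector K1, NumericVector K2,
                               double omega_est,
                               NumericVector cosphi, NumericVector wazi,
                               NumericVector alpha, NumericVector dist,
                               double sigma_log, double sigma_dir_rad,
                               double dir_offset) {
  const int n = logr_in.size(), A = alpha.size(), J = dist.size();
  NumericMatrix M(A, J);
  const double inv2sl = 1.0 / (2.0 * sigma_log * sigma_log);
  const double inv2sd = 1.0 / (2.0 * sigma_dir_rad * sigma_dir_rad);
  std::vector<double> invd(J);
  for (int j = 0; j < J; ++j) invd[j] = 1.0 / dist[j];
  for (int ia = 0; ia < A; ++ia) {
    const double ar = alpha[ia] * M_PI / 180.0;
    for (int i = 0; i < n; ++i) {
      const double c = cosphi[i] * std::cos(ar - wazi[i]);
      if (c <= 1e-9) continue;
      for (int j = 0; j < J; ++j) {
        const double P = c * invd[j];
        const double t1 = K1[i] * P - omega_est;
        const double t2 = K2[i] * P;
        double r2 = t1 * t1 + t2 * t2;
        if (r2 < 1e-12) r2 = 1e-12;
        const double dl = 0.5 * std::log(r2) - logr_in[i];
        const double dd = wrap_pi(std::atan2(t2, t1) - dir_in[i]);
        M(ia, j) += std::exp(-dl * dl * inv2sl) *
                    (std::exp(-dd * dd * inv2sd) - dir_offset);
      }
    }
  }
  return M;
}

// Raw-speed variant of the wall matcher (ablation of the log-speed
// tuning): Gaussian of the plain speed difference in deg/sec.
// [[Rcpp::export]]
NumericMatrix cpp_match_wall2d_plain(NumericVector r_in, NumericVector dir_in,
                                     NumericVector K1, NumericVector K2,
                                     double omega_est,
                                     NumericVector cosphi, NumericVector wazi,
                                     NumericVector alpha, NumericVector dist,
                                     double sigma_speed, double sigma_dir_rad,
                                     double dir_offset) {
  const int n = r_in.size(), A = alpha.size(), J = dist.size();
  NumericMatrix M(A, J);
  const double inv2ss = 1.0 / (2.0 * sigma_speed * sigma_speed);
  const double inv2sd = 1.0 / (2.0 * sigma_dir_rad * sigma_dir_rad);
  for (int ia = 0; ia < A; ++ia) {
    const double ar = alpha[ia] * M_PI / 180.0;
    for (int i = 0; i < n; ++i) {
      const double c = cosphi[i] * std::cos(ar - wazi[i]);
      if (c <= 1e-9) continue;
      for (int j = 0; j < J; ++j) {
        const double P = c / dist[j];
        const double t1 = K1[i] * P - omega_est;
        const double t2 = K2[i] * P;
        const double r = std::sqrt(t1 * t1 + t2 * t2);
        const double ds = r - r_in[i];
        const double dd = wrap_pi(std::atan2(t2, t1) - dir_in[i]);
        M(ia, j) += std::exp(-ds * ds * inv2ss) *
                    (std::exp(-dd * dd * inv2sd) - dir_offset);
      }
    }
  }
  return M;
}

// Fast accumulation variant of cpp_match_wall2d for trajectory sweeps.
// Exploits that the template depends on (alpha, dist) only through
// P = cos(alpha - w) * cosphi / dist, and that the distance grid is
// log-uniform: per node the tuning is evaluated once on a dense log-P grid
// and then window-added into the (alpha, dist) map with an integer shift
// (nearest-neighbour in log-P at `oversample` times the distance-grid
// resolution).
// [[Rcpp::export]]
NumericMatrix cpp_match_wall2d_binned(NumericVector logr_in, NumericVector dir_in,
                                      NumericVector K1, NumericVector K2,
                                      double omega_est,
                                      NumericVector cosphi, NumericVector wazi,
                                      NumericVector alpha, NumericVector dist,
                                      double sigma_log, double sigma_dir_rad,
                                      double dir_offset, int oversample) {
  const int n = logr_in.size(), A = alpha.size(), J = dist.size();
  NumericMatrix M(A, J);
  if (n == 0 || J < 2) return M;
  const double inv2sl = 1.0 / (2.0 * sigma_log * sigma_log);
  const double inv2sd = 1.0 / (2.0 * sigma_dir_rad * sigma_dir_rad);
  const double ld0 = std::log(dist[0]);
  const double Dstep = (std::log(dist[J - 1]) - ld0) / (J - 1);
  const double delta = Dstep / oversample;
  // log-P grid: from a plateau floor (flow ~ pure rotation) up to the
  // largest attainable P = 1 / dist[0].
  const double lp_min = std::log(2.5e-4);
  const double lp_max = -ld0;
  const int Mp = (int)std::floor((lp_max - lp_min) / delta) + 2;
  std::vector<double> f(Mp);
  std::vector<double> ar(A), ca(A), sa(A);
  for (int ia = 0; ia < A; ++ia) {
    ar[ia] = alpha[ia] * M_PI / 180.0;
    ca[ia] = std::cos(ar[ia]); sa[ia] = std::sin(ar[ia]);
  }
  for (int i = 0; i < n; ++i) {
    const double k1 = K1[i], k2 = K2[i];
    const double lr = logr_in[i], di = dir_in[i];
    // plateau value at P -> 0 (template = pure rotation)
    double f0;
    {
      const double t1 = -omega_est;
      double r2 = t1 * t1; if (r2 < 1e-12) r2 = 1e-12;
      const double dl = 0.5 * std::log(r2) - lr;
      const double dd = wrap_pi(std::atan2(0.0, t1) - di);
      f0 = std::exp(-dl * dl * inv2sl) *
           (std::exp(-dd * dd * inv2sd) - dir_offset);
    }
    for (int m = 0; m < Mp; ++m) {
      const double P = std::exp(lp_min + m * delta);
      const double t1 = k1 * P - omega_est;
      const double t2 = k2 * P;
      double r2 = t1 * t1 + t2 * t2; if (r2 < 1e-12) r2 = 1e-12;
      const double dl = 0.5 * std::log(r2) - lr;
      const double dd = wrap_pi(std::atan2(t2, t1) - di);
      f[m] = std::exp(-dl * dl * inv2sl) *
             (std::exp(-dd * dd * inv2sd) - dir_offset);
    }
    const double cw = std::cos(wazi[i]) * cosphi[i];
    const double sw = std::sin(wazi[i]) * cosphi[i];
    for (int ia = 0; ia < A; ++ia) {
      const double c = ca[ia] * cw + sa[ia] * sw;  // cosphi * cos(alpha - w)
      if (c <= 1e-9) continue;
      const double lc = std::log(c);
      const int base = (int)std::lround((lc - ld0 - lp_min) / delta);
      for (int j = 0; j < J; ++j) {
        int m = base - j * oversample;
        if (m >= Mp) m = Mp - 1;
        M(ia, j) += (m < 0) ? f0 : f[m];
      }
    }
  }
  return M;
}

// Per-node best wall-template match of the rotation-invariant elevation
// constraint. For each node and each alpha the log-spaced distance grid is
// searched in closed form (round in log space); returns the minimum
// residual (deg/sec) over all (alpha, dist).
// phird: elevation flow of the input (deg/sec); Aw[i] = vbar_deg * s2 factor
// such that template elevation flow = Aw * cos(alpha - w) * cosphi / dist.
// [[Rcpp::export]]
NumericVector cpp_wall_seg_residual(NumericVector phird, NumericVector Aw,
                                    NumericVector cosphi, NumericVector wazi,
                                    NumericVector alpha, NumericVector dist) {
  const int n = phird.size(), A = alpha.size(), J = dist.size();
  const double ld0 = std::log(dist[0]);
  const double Dstep = (std::log(dist[J - 1]) - ld0) / (J - 1);
  NumericVector res(n);
  std::vector<double> ar(A);
  for (int ia = 0; ia < A; ++ia) ar[ia] = alpha[ia] * M_PI / 180.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double y = phird[i], Awi = Aw[i];
    for (int ia = 0; ia < A; ++ia) {
      const double c = cosphi[i] * std::cos(ar[ia] - wazi[i]);
      if (c <= 1e-9) continue;
      const double num = Awi * c; // template = num / d
      double r;
      if (y * num > 0.0) {
        double dstar = num / y;
        int j = (int)std::lround((std::log(dstar) - ld0) / Dstep);
        if (j < 0) j = 0; if (j >= J) j = J - 1;
        r = std::fabs(y - num / dist[j]);
        // neighbours guard against rounding across the log grid
        if (j > 0) { double r2 = std::fabs(y - num / dist[j - 1]); if (r2 < r) r = r2; }
        if (j < J - 1) { double r2 = std::fabs(y - num / dist[j + 1]); if (r2 < r) r = r2; }
      } else {
        r = std::fabs(y - num / dist[J - 1]);
      }
      if (r < best) best = r;
    }
    res[i] = best;
  }
  return res;
}
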