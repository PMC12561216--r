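// Dynamic-relaxation solver for nonlinear membrane (constant-strain
// triangle) structures with node-to-triangle penalty contact between
// leaflets. Total-Lagrangian kinematics, plane-stress isotropic response
// with a secant modulus taken from a tabulated strain->stress curve.
// Units: mm, N, MPa.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <map>
#include <utility>
using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double a, double b, double c) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(x * x + y * y + z * z); }
};

// secant modulus sigma(eps)/eps from a piecewise-linear curve through the
// origin; beyond the last tabulated point the final slope is extrapolated
static double secant_modulus(double eps, const std::vector<double>& cs,
                             const std::vector<double>& ct) {
  const double eps0 = 1e-8;
  if (eps < eps0) eps = eps0;
  size_t n = cs.size();
  double sig;
  if (eps <= cs[0]) {
    sig = ct[0] / cs[0] * eps;
  } else if (eps >= cs[n - 1]) {
    double slope = (n >= 2) ? (ct[n - 1] - ct[n - 2]) / (cs[n - 1] - cs[n - 2])
                            : ct[n - 1] / cs[n - 1];
    sig = ct[n - 1] + slope * (eps - cs[n - 1]);
  } else {
    size_t i = 1;
    while (cs[i] < eps) ++i;
    double f = (eps - cs[i - 1]) / (cs[i] - cs[i - 1]);
    sig = ct[i - 1] + f * (ct[i] - ct[i - 1]);
  }
  return sig / eps;
}

// closest point on triangle (a,b,c) to p (Ericson, Real-Time Collision
// Detection)
static Vec3 closest_point_triangle(const Vec3& p, const Vec3& a,
                                   const Vec3& b, const Vec3& c) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = ab.dot(ap), d2 = ac.dot(ap);
  if (d1 <= 0 && d2 <= 0) return a;
  Vec3 bp = p - b;
  double d3 = ab.dot(bp), d4 = ac.dot(bp);
  if (d3 >= 0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    return a + ab * v;
  }
  Vec3 cp = p - c;
  double d5 = ab.dot(cp), d6 = ac.dot(cp);
  if (d6 >= 0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    return a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + ab * v + ac * w;
}

struct ContactPair {
  int node;
  int tri;
  double side;  // +1/-1: which side of the triangle the node was on
};

// hinge between two triangles sharing edge (p,q); r and s are the apexes
struct Hinge {
  int p, q, r, s;
  double theta0;  // rest dihedral deviation
};

static double hinge_angle(const Vec3& xp, const Vec3& xq, const Vec3& xr,
                          const Vec3& xs, Vec3& N1, Vec3& N2, Vec3& E) {
  E = xq - xp;
  N1 = (xp - xr).cross(xq - xr);
  N2 = (xq - xs).cross(xp - xs);
  double n1l = N1.norm(), n2l = N2.norm(), el = E.norm();
  if (n1l < 1e-14 || n2l < 1e-14 || el < 1e-14) return 0.0;
  Vec3 n1h = N1 * (1.0 / n1l), n2h = N2 * (1.0 / n2l);
  double s = n1h.cross(n2h).dot(E * (1.0 / el));
  double c = n1h.dot(n2h);
  return std::atan2(s, c);
}

// [[Rcpp::export(name = ".dr_relax")]]
List dr_relax(NumericMatrix X_in, NumericMatrix V0,
              IntegerMatrix Tr, IntegerVector tri_leaflet,
              IntegerVector leaflet_id,
              IntegerVector fixed_idx, NumericMatrix fixed_pos,
              double pressure, double thickness, double nu,
              NumericVector curve_strain, NumericVector curve_stress,
              bool contact_on, double contact_gap, double contact_penalty,
              int rebuild_every, double search_margin,
              int max_iter, double tol_rel, int check_every,
              double mass_factor, double compression_retention,
              double bending_stiffness, int pressure_mode,
              double viscous_eta) {
  // pressure_mode: 0 follower, 1 axial (projected), 2 shielded follower
  // (contacted triangles are sealed coaptation interface: no fluid load)
  const int n = X_in.nrow();
  const int m = Tr.nrow();
  std::vector<double> cs(curve_strain.begin(), curve_strain.end());
  std::vector<double> ct(curve_stress.begin(), curve_stress.end());

  std::vector<Vec3> X(n), F(n), Vel(n, Vec3());
  for (int i = 0; i < n; ++i) X[i] = Vec3(X_in(i, 0), X_in(i, 1), X_in(i, 2));

  std::vector<bool> is_fixed(n, false);
  for (int k = 0; k < fixed_idx.size(); ++k) {
    int i = fixed_idx[k];
    is_fixed[i] = true;
    X[i] = Vec3(fixed_pos(k, 0), fixed_pos(k, 1), fixed_pos(k, 2));
  }

  // element rest-state precomputation
  std::vector<double> i00(m), i01(m), i11(m), area(m), hmin(m);
  std::vector<int> t0(m), t1v(m), t2v(m);
  for (int e = 0; e < m; ++e) {
    t0[e] = Tr(e, 0) - 1; t1v[e] = Tr(e, 1) - 1; t2v[e] = Tr(e, 2) - 1;
    Vec3 p0(V0(t0[e], 0), V0(t0[e], 1), V0(t0[e], 2));
    Vec3 p1(V0(t1v[e], 0), V0(t1v[e], 1), V0(t1v[e], 2));
    Vec3 p2(V0(t2v[e], 0), V0(t2v[e], 1), V0(t2v[e], 2));
    Vec3 e1 = p1 - p0, e2 = p2 - p0;
    Vec3 nn = e1.cross(e2);
    double A = 0.5 * nn.norm();
    area[e] = A;
    double l1 = e1.norm(), l2 = e2.norm(), l3 = (p2 - p1).norm();
    hmin[e] = std::min(l1, std::min(l2, l3));
    Vec3 u = e1 * (1.0 / l1);
    Vec3 w = nn * (1.0 / nn.norm());
    Vec3 vv = w.cross(u);
    double Dm00 = e1.dot(u), Dm01 = e2.dot(u), Dm11 = e2.dot(vv);
    double det = Dm00 * Dm11;
    if (std::fabs(det) < 1e-14)
      stop("degenerate element %d in reference configuration", e + 1);
    i00[e] = Dm11 / det;
    i01[e] = -Dm01 / det;
    i11[e] = Dm00 / det;
  }

  // triangle adjacency across shared edges (same leaflet), for the
  // wetted-surface flood fill
  std::vector< std::vector<int> > tri_adj(m);
  {
    std::map<std::pair<int, int>, int> first_tri;
    for (int e = 0; e < m; ++e) {
      int vv[3] = { t0[e], t1v[e], t2v[e] };
      for (int k = 0; k < 3; ++k) {
        int a = vv[k], b = vv[(k + 1) % 3];
        std::pair<int, int> key(std::min(a, b), std::max(a, b));
        std::map<std::pair<int, int>, int>::iterator it = first_tri.find(key);
        if (it == first_tri.end()) first_tri[key] = e;
        else { tri_adj[e].push_back(it->second); tri_adj[it->second].push_back(e); }
      }
    }
  }

  // hinge (bending) topology from shared interior edges, rest angles from
  // the reference surface
  std::vector<Hinge> hinges;
  if (bending_stiffness > 0) {
    std::map<std::pair<int, int>, std::pair<int, int> > edge_map;  // edge -> (tri, apex)
    for (int e = 0; e < m; ++e) {
      int vv[3] = { t0[e], t1v[e], t2v[e] };
      for (int k = 0; k < 3; ++k) {
        int a = vv[k], b = vv[(k + 1) % 3], c = vv[(k + 2) % 3];
        std::pair<int, int> key(std::min(a, b), std::max(a, b));
        std::map<std::pair<int, int>, std::pair<int, int> >::iterator it =
          edge_map.find(key);
        if (it == edge_map.end()) {
          edge_map[key] = std::make_pair(e, c);
        } else {
          Hinge h;
          h.p = key.first; h.q = key.second;
          h.r = it->second.second; h.s = c;
          Vec3 vp(V0(h.p, 0), V0(h.p, 1), V0(h.p, 2));
          Vec3 vq(V0(h.q, 0), V0(h.q, 1), V0(h.q, 2));
          Vec3 vr(V0(h.r, 0), V0(h.r, 1), V0(h.r, 2));
          Vec3 vs(V0(h.s, 0), V0(h.s, 1), V0(h.s, 2));
          Vec3 N1, N2, E;
          h.theta0 = hinge_angle(vp, vq, vr, vs, N1, N2, E);
          hinges.push_back(h);
        }
      }
    }
  }

  // fictitious nodal masses from a stiffness bound (max tangent modulus)
  double Emax = 0;
  {
    size_t nc = cs.size();
    Emax = ct[0] / cs[0];
    for (size_t i = 1; i < nc; ++i)
      Emax = std::max(Emax, (ct[i] - ct[i - 1]) / (cs[i] - cs[i - 1]));
  }
  std::vector<double> mass_base(n, 0.0);
  for (int e = 0; e < m; ++e) {
    double k = Emax / (1 - nu * nu) * thickness * area[e] / (hmin[e] * hmin[e]);
    mass_base[t0[e]] += k; mass_base[t1v[e]] += k; mass_base[t2v[e]] += k;
  }
  // bending stiffness contribution to masses: k ~ kb * |E| / h_min^3 with
  // h_min the smaller rest altitude of the two apexes (slivers at the
  // commissure fans dominate the bending eigenvalues)
  for (size_t hh = 0; hh < hinges.size(); ++hh) {
    const Hinge& h = hinges[hh];
    Vec3 vp(V0(h.p, 0), V0(h.p, 1), V0(h.p, 2));
    Vec3 vq(V0(h.q, 0), V0(h.q, 1), V0(h.q, 2));
    Vec3 vr(V0(h.r, 0), V0(h.r, 1), V0(h.r, 2));
    Vec3 vs(V0(h.s, 0), V0(h.s, 1), V0(h.s, 2));
    Vec3 N1, N2, E;
    hinge_angle(vp, vq, vr, vs, N1, N2, E);
    double el = E.norm();
    if (el < 1e-12) continue;
    double h1 = N1.norm() / el, h2 = N2.norm() / el;
    double hm = std::max(std::min(h1, h2), 1e-3 * el);
    double k = bending_stiffness * el / (hm * hm * hm) * 4.0;
    mass_base[h.p] += k; mass_base[h.q] += k;
    mass_base[h.r] += k; mass_base[h.s] += k;
  }
  std::vector<double> mass(n);
  for (int i = 0; i < n; ++i) mass[i] = mass_factor * mass_base[i];

  // per-step displacement cap (fraction of the smallest adjacent rest edge):
  // bounds transient overshoot where the geometric stiffness exceeds the
  // small-strain mass estimate
  std::vector<double> vcap(n, R_PosInf);
  for (int e = 0; e < m; ++e) {
    double c = 0.1 * hmin[e];
    if (c < vcap[t0[e]]) vcap[t0[e]] = c;
    if (c < vcap[t1v[e]]) vcap[t1v[e]] = c;
    if (c < vcap[t2v[e]]) vcap[t2v[e]] = c;
  }

  std::vector<ContactPair> pairs;
  std::vector<Vec3> centroid(m);
  std::vector<bool> tri_shielded(m, false);
  std::vector<bool> tri_seed(m, false);
  for (int e = 0; e < m; ++e)
    if (is_fixed[t0[e]] || is_fixed[t1v[e]] || is_fixed[t2v[e]])
      tri_seed[e] = true;

  double ke_prev = 0, ke_peak = 0, ke_last = 0;
  bool converged = false;
  int iter = 0;
  std::vector<double> res_hist;
  double res_ratio = NA_REAL;

  for (iter = 0; iter < max_iter; ++iter) {
    // ---- forces
    double pr_norm2 = 0;
    for (int i = 0; i < n; ++i) F[i] = Vec3();

    for (int e = 0; e < m; ++e) {
      const Vec3 &x0 = X[t0[e]], &x1 = X[t1v[e]], &x2 = X[t2v[e]];
      Vec3 d1 = x1 - x0, d2 = x2 - x0;
      // F = [d1 d2] * invDm  (3x2)
      Vec3 Fc0 = d1 * i00[e];
      Vec3 Fc1 = d1 * i01[e] + d2 * i11[e];
      double C00 = Fc0.dot(Fc0), C01 = Fc0.dot(Fc1), C11 = Fc1.dot(Fc1);
      double E00 = 0.5 * (C00 - 1.0), E11 = 0.5 * (C11 - 1.0), E01 = 0.5 * C01;
      double disc = std::sqrt((C00 - C11) * (C00 - C11) + 4 * C01 * C01);
      double lam = 0.5 * (C00 + C11 + disc);
      double eps_eq = std::sqrt(std::max(lam, 1e-12)) - 1.0;
      double Es = secant_modulus(std::fabs(eps_eq), cs, ct);
      double coef = Es / (1 - nu * nu);
      double S00 = coef * (E00 + nu * E11);
      double S11 = coef * (E11 + nu * E00);
      double S01 = coef * (1 - nu) * E01;
      // tension-field (wrinkling) correction: a membrane cannot carry
      // compression; compressive principal stresses are scaled down to a
      // small retained fraction, which stabilizes the crimped state
      {
        double tr = 0.5 * (S00 + S11);
        double dd = std::sqrt(0.25 * (S00 - S11) * (S00 - S11) + S01 * S01);
        double s1 = tr + dd, s2 = tr - dd;
        if (s2 < 0 || s1 < 0) {
          double c, s;
          if (dd < 1e-30) { c = 1; s = 0; }
          else {
            double theta = 0.5 * std::atan2(2 * S01, S00 - S11);
            c = std::cos(theta); s = std::sin(theta);
          }
          if (s1 < 0) s1 *= compression_retention;
          if (s2 < 0) s2 *= compression_retention;
          S00 = s1 * c * c + s2 * s * s;
          S11 = s1 * s * s + s2 * c * c;
          S01 = (s1 - s2) * c * s;
        }
      }
      Vec3 P0 = Fc0 * S00 + Fc1 * S01;
      Vec3 P1 = Fc0 * S01 + Fc1 * S11;
      double At = area[e] * thickness;
      Vec3 f1 = (P0 * i00[e] + P1 * i01[e]) * (-At);
      Vec3 f2 = (P1 * i11[e]) * (-At);
      F[t1v[e]] = F[t1v[e]] + f1;
      F[t2v[e]] = F[t2v[e]] + f2;
      F[t0[e]] = F[t0[e]] - f1 - f2;

      if (pressure != 0 && !(pressure_mode == 2 && tri_shielded[e])) {
        Vec3 cr = d1.cross(d2);           // 2 * A * n_hat
        Vec3 fp = (pressure_mode == 1)
          ? Vec3(0, 0, -pressure * cr.z / 6.0)  // projected axial traction
          : cr * (-pressure / 6.0);             // follower face load
        F[t0[e]] = F[t0[e]] + fp;
        F[t1v[e]] = F[t1v[e]] + fp;
        F[t2v[e]] = F[t2v[e]] + fp;
        pr_norm2 += 3.0 * fp.dot(fp);
      }
      centroid[e] = (x0 + x1 + x2) * (1.0 / 3.0);
    }

    // ---- bending (hinge) forces, restoring the rest dihedral angle
    for (size_t hh = 0; hh < hinges.size(); ++hh) {
      const Hinge& h = hinges[hh];
      Vec3 N1, N2, E;
      double th = hinge_angle(X[h.p], X[h.q], X[h.r], X[h.s], N1, N2, E);
      double n1l2 = N1.dot(N1), n2l2 = N2.dot(N2);
      double el = E.norm();
      if (n1l2 < 1e-20 || n2l2 < 1e-20 || el < 1e-12) continue;
      Vec3 Eh = E * (1.0 / el);
      double dth = th - h.theta0;
      if (dth > M_PI) dth -= 2 * M_PI;
      if (dth < -M_PI) dth += 2 * M_PI;
      double mag = bending_stiffness * el * el /
        (std::sqrt(n1l2) + std::sqrt(n2l2)) * std::sin(0.5 * dth);
      Vec3 ur = N1 * (el / n1l2);
      Vec3 us = N2 * (el / n2l2);
      Vec3 up = N1 * ((X[h.r] - X[h.q]).dot(Eh) / n1l2) +
                N2 * ((X[h.s] - X[h.q]).dot(Eh) / n2l2);
      Vec3 uq = N1 * ((X[h.p] - X[h.r]).dot(Eh) / n1l2) +
                N2 * ((X[h.p] - X[h.s]).dot(Eh) / n2l2);
      F[h.p] = F[h.p] + up * mag;
      F[h.q] = F[h.q] + uq * mag;
      F[h.r] = F[h.r] + ur * mag;
      F[h.s] = F[h.s] + us * mag;
    }

    // ---- contact
    if (contact_on) {
      if (iter % rebuild_every == 0) {
        pairs.clear();
        double sr = contact_gap + search_margin;
        double sr2 = sr * sr;
        for (int i = 0; i < n; ++i) {
          if (is_fixed[i]) continue;
          int li = leaflet_id[i];
          const Vec3& p = X[i];
          for (int e = 0; e < m; ++e) {
            if (tri_leaflet[e] == li) continue;
            Vec3 d = p - centroid[e];
            if (d.dot(d) > sr2) continue;
            Vec3 cp = closest_point_triangle(p, X[t0[e]], X[t1v[e]], X[t2v[e]]);
            Vec3 dd = p - cp;
            double dist = dd.norm();
            if (dist > sr) continue;
            Vec3 e1 = X[t1v[e]] - X[t0[e]], e2 = X[t2v[e]] - X[t0[e]];
            Vec3 nn = e1.cross(e2);
            double nl = nn.norm();
            if (nl < 1e-14) continue;
            Vec3 nh = nn * (1.0 / nl);
            double sd = dd.dot(nh);
            if (std::fabs(sd) < 1e-10) continue;  // exactly on surface: skip
            ContactPair cpair;
            cpair.node = i; cpair.tri = e; cpair.side = (sd > 0) ? 1.0 : -1.0;
            pairs.push_back(cpair);
          }
        }
        // per-node contact stiffness enters the fictitious masses: a node
        // engaged in several pairs sees the penalty stiffness once per pair
        std::vector<int> cnt(n, 0);
        for (size_t k = 0; k < pairs.size(); ++k) {
          ++cnt[pairs[k].node];
          ++cnt[t0[pairs[k].tri]]; ++cnt[t1v[pairs[k].tri]];
          ++cnt[t2v[pairs[k].tri]];
        }
        for (int i = 0; i < n; ++i)
          mass[i] = mass_factor * (mass_base[i] + contact_penalty * cnt[i]);
        if (pressure_mode == 2) {
          // wetted-surface flood fill: the arterial fluid reaches from the
          // attachment rim across the leaflet; triangles engaged in
          // coaptation contact are sealed barriers, and triangles beyond
          // them (the funnel below the seal) carry no static fluid load
          std::vector<bool> node_c(n, false);
          for (size_t k = 0; k < pairs.size(); ++k)
            node_c[pairs[k].node] = true;
          std::vector<bool> barrier(m, false);
          for (size_t k = 0; k < pairs.size(); ++k)
            barrier[pairs[k].tri] = true;
          for (int e = 0; e < m; ++e)
            if (node_c[t0[e]] && node_c[t1v[e]] && node_c[t2v[e]])
              barrier[e] = true;
          std::vector<bool> reached(m, false);
          std::vector<int> stack;
          for (int e = 0; e < m; ++e)
            if (tri_seed[e]) { reached[e] = true; stack.push_back(e); }
          while (!stack.empty()) {
            int e = stack.back(); stack.pop_back();
            if (barrier[e]) continue;   // wetted but does not transmit past
            for (size_t a = 0; a < tri_adj[e].size(); ++a) {
              int f = tri_adj[e][a];
              if (!reached[f]) { reached[f] = true; stack.push_back(f); }
            }
          }
          for (int e = 0; e < m; ++e) tri_shielded[e] = !reached[e];
        }
      }
      for (size_t k = 0; k < pairs.size(); ++k) {
        int i = pairs[k].node, e = pairs[k].tri;
        double s = pairs[k].side;
        const Vec3 &a = X[t0[e]], &b = X[t1v[e]], &c = X[t2v[e]];
        Vec3 e1 = b - a, e2 = c - a;
        Vec3 nn = e1.cross(e2);
        double nl = nn.norm();
        if (nl < 1e-14) continue;
        Vec3 nh = nn * (1.0 / nl);
        Vec3 cp = closest_point_triangle(X[i], a, b, c);
        Vec3 dd = X[i] - cp;
        double dist = dd.norm();
        double sd = s * dd.dot(nh);  // positive when on original side
        double pen;
        if (sd >= 0) {
          pen = contact_gap - dist;   // approaching from original side
        } else {
          if (dist > 2 * contact_gap) continue;  // escaped elsewhere; stale pair
          pen = contact_gap + dist;   // crossed through the surface
        }
        if (pen <= 0) continue;
        Vec3 fdir = nh * s;
        Vec3 fc = fdir * (contact_penalty * pen);
        F[i] = F[i] + fc;
        // reaction spread evenly over the triangle nodes
        Vec3 fr = fc * (-1.0 / 3.0);
        F[t0[e]] = F[t0[e]] + fr;
        F[t1v[e]] = F[t1v[e]] + fr;
        F[t2v[e]] = F[t2v[e]] + fr;
      }
    }

    // ---- convergence bookkeeping
    if (iter % check_every == 0) {
      double rf2 = 0, rr2 = 0;
      int nf = 0, nr = 0;
      for (int i = 0; i < n; ++i) {
        double f2 = F[i].dot(F[i]);
        if (is_fixed[i]) { rr2 += f2; ++nr; } else { rf2 += f2; ++nf; }
      }
      double rms_free = std::sqrt(rf2 / std::max(nf, 1));
      double rms_reac = std::sqrt(rr2 / std::max(nr, 1));
      double rms_pr = std::sqrt(pr_norm2 / std::max(n, 1));
      // floor: characteristic elastic force scale, so zero-load states
      // converge on roundoff-level residuals
      double hbar = 0;
      for (int e = 0; e < m; ++e) hbar += hmin[e];
      hbar /= m;
      double load = std::max(rms_reac, rms_pr);
      double floor_f = 1e-6 * Emax * thickness * hbar;
      if (load < floor_f) load = floor_f;
      res_ratio = rms_free / load;
      res_hist.push_back(res_ratio);
      if (res_ratio < tol_rel && iter > 0) { converged = true; break; }
    }

    // ---- kinetic-damping step
    double ke = 0;
    double vkeep = 1.0 - viscous_eta;
    for (int i = 0; i < n; ++i) {
      if (is_fixed[i]) continue;
      Vel[i] = (Vel[i] + F[i] * (1.0 / mass[i])) * vkeep;
      double vn = Vel[i].norm();
      if (vn > vcap[i]) Vel[i] = Vel[i] * (vcap[i] / vn);
      ke += mass[i] * Vel[i].dot(Vel[i]);
    }
    ke *= 0.5;
    if (!std::isfinite(ke))
      stop("dynamic relaxation diverged (non-finite kinetic energy) at iteration %d",
           iter);
    if (ke < ke_prev) {
      for (int i = 0; i < n; ++i) Vel[i] = Vec3();
      ke_prev = 0;
    } else {
      ke_prev = ke;
      for (int i = 0; i < n; ++i)
        if (!is_fixed[i]) X[i] = X[i] + Vel[i];
    }
    if (ke > ke_peak) ke_peak = ke;
    ke_last = ke;
  }

  NumericMatrix Xout(n, 3);
  for (int i = 0; i < n; ++i) {
    Xout(i, 0) = X[i].x; Xout(i, 1) = X[i].y; Xout(i, 2) = X[i].z;
  }
  return List::create(_["X"] = Xout, _["converged"] = converged,
                      _["iterations"] = iter,
                      _["residual_ratio"] = res_ratio,
                      _["residual_history"] = wrap(res_hist),
                      _["ke_peak"] = ke_peak, _["ke_last"] = ke_last,
                      _["n_contact_pairs"] = (int)pairs.size());
}

// minimum distance from any vertex of one leaflet to any triangle of a
// different leaflet (post-hoc contact/penetration audit)
// [[Rcpp::export(name = ".min_cross_leaflet_distance")]]
double min_cross_leaflet_distance(NumericMatrix X, IntegerMatrix Tr,
                                  IntegerVector tri_leaflet,
                                  IntegerVector leaflet_id,
                                  LogicalVector consider) {
  int n = X.nrow(), m = Tr.nrow();
  std::vector<Vec3> P(n);
  for (int i = 0; i < n; ++i) P[i] = Vec3(X(i, 0), X(i, 1), X(i, 2));
  double best = R_PosInf;
  for (int i = 0; i < n; ++i) {
    if (!consider[i]) continue;
    for (int e = 0; e < m; ++e) {
      if (tri_leaflet[e] == leaflet_id[i]) continue;
      Vec3 cp = closest_point_triangle(P[i], P[Tr(e, 0) - 1],
                                       P[Tr(e, 1) - 1], P[Tr(e, 2) - 1]);
      double d = (P[i] - cp).norm();
      if (d < best) best = d;
    }
  }
  return best;
}
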