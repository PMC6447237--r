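// Core numerics: all-atom structure-based potential (energies + analytic
// forces), residue-level Debye scattering with coordinate gradients, the
// chi-square scattering bias, and a BAOAB Langevin integrator in reduced
// units. Higher-level logic (topology construction, configuration, I/O)
// lives in R; these routines only evaluate and integrate.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double wrap_pi(double d) {
  while (d > M_PI) d -= 2.0 * M_PI;
  while (d <= -M_PI) d += 2.0 * M_PI;
  return d;
}

// ---------------------------------------------------------------------------
// Topology container (parsed once per evaluation context)

struct Topology {
  int n;
  std::vector<int> b_i, b_j; std::vector<double> b_r0, b_k;
  std::vector<int> a_i, a_j, a_k; std::vector<double> a_t0, a_k2;
  std::vector<int> im_i, im_j, im_k, im_l; std::vector<double> im_x0, im_kc;
  std::vector<int> p_i, p_j, p_k, p_l; std::vector<double> p_f0, p_kc;
  std::vector<int> c_i, c_j; std::vector<double> c_s0, c_k;
  double knc, sigma_nn;
  std::vector<std::vector<int>> excl; // for i, sorted list of excluded j > i
};

static void fill_pairs(const NumericMatrix& m, std::vector<int>& vi,
                       std::vector<int>& vj, std::vector<double>& p1,
                       std::vector<double>& p2) {
  int nr = m.nrow();
  vi.resize(nr); vj.resize(nr); p1.resize(nr); p2.resize(nr);
  for (int r = 0; r < nr; ++r) {
    vi[r] = (int)m(r, 0) - 1; vj[r] = (int)m(r, 1) - 1;
    p1[r] = m(r, 2); p2[r] = m(r, 3);
  }
}

static Topology parse_topology(const List& top) {
  Topology t;
  t.n = as<int>(top["n_atoms"]);
  NumericMatrix bonds = top["bonds"], angles = top["angles"],
                imps = top["impropers"], props = top["propers"],
                contacts = top["contacts"], excl = top["exclusions"];
  fill_pairs(bonds, t.b_i, t.b_j, t.b_r0, t.b_k);
  fill_pairs(contacts, t.c_i, t.c_j, t.c_s0, t.c_k);
  int na = angles.nrow();
  t.a_i.resize(na); t.a_j.resize(na); t.a_k.resize(na);
  t.a_t0.resize(na); t.a_k2.resize(na);
  for (int r = 0; r < na; ++r) {
    t.a_i[r] = (int)angles(r, 0) - 1; t.a_j[r] = (int)angles(r, 1) - 1;
    t.a_k[r] = (int)angles(r, 2) - 1;
    t.a_t0[r] = angles(r, 3); t.a_k2[r] = angles(r, 4);
  }
  auto fill_dih = [](const NumericMatrix& m, std::vector<int>& i,
                     std::vector<int>& j, std::vector<int>& k,
                     std::vector<int>& l, std::vector<double>& x0,
                     std::vector<double>& kk) {
    int nr = m.nrow();
    i.resize(nr); j.resize(nr); k.resize(nr); l.resize(nr);
    x0.resize(nr); kk.resize(nr);
    for (int r = 0; r < nr; ++r) {
      i[r] = (int)m(r, 0) - 1; j[r] = (int)m(r, 1) - 1;
      k[r] = (int)m(r, 2) - 1; l[r] = (int)m(r, 3) - 1;
      x0[r] = m(r, 4); kk[r] = m(r, 5);
    }
  };
  fill_dih(imps, t.im_i, t.im_j, t.im_k, t.im_l, t.im_x0, t.im_kc);
  fill_dih(props, t.p_i, t.p_j, t.p_k, t.p_l, t.p_f0, t.p_kc);
  t.knc = as<double>(top["k_nc"]);
  t.sigma_nn = as<double>(top["sigma_nn"]);
  t.excl.assign(t.n, std::vector<int>());
  for (int r = 0; r < excl.nrow(); ++r) {
    int i = (int)excl(r, 0) - 1, j = (int)excl(r, 1) - 1;
    if (i > j) std::swap(i, j);
    t.excl[i].push_back(j);
  }
  for (int i = 0; i < t.n; ++i) {
    std::sort(t.excl[i].begin(), t.excl[i].end());
    t.excl[i].erase(std::unique(t.excl[i].begin(), t.excl[i].end()),
                    t.excl[i].end());
  }
  return t;
}

// dihedral angle and d(phi)/d(r) for the four atoms; returns false when the
// geometry is degenerate (collinear bonds) and forces are skipped
static bool dihedral_geom(const double* xi, const double* xj,
                          const double* xk, const double* xl,
                          double& phi, double dphi[4][3]) {
  double b1[3], b2[3], b3[3], n1[3], n2[3];
  for (int d = 0; d < 3; ++d) {
    b1[d] = xj[d] - xi[d]; b2[d] = xk[d] - xj[d]; b3[d] = xl[d] - xk[d];
  }
  cross3(b1, b2, n1); cross3(b2, b3, n2);
  double n1sq = dot3(n1, n1), n2sq = dot3(n2, n2);
  double b2n = std::sqrt(dot3(b2, b2));
  if (n1sq < 1e-18 || n2sq < 1e-18 || b2n < 1e-12) return false;
  double m1[3], b2h[3] = {b2[0] / b2n, b2[1] / b2n, b2[2] / b2n};
  cross3(n1, b2h, m1);
  phi = std::atan2(dot3(m1, n2), dot3(n1, n2));
  double A = dot3(b1, b2) / (b2n * b2n), B = dot3(b3, b2) / (b2n * b2n);
  double dri[3], drl[3];
  for (int d = 0; d < 3; ++d) {
    dri[d] = b2n / n1sq * n1[d];
    drl[d] = -b2n / n2sq * n2[d];
  }
  for (int d = 0; d < 3; ++d) {
    dphi[0][d] = dri[d];
    dphi[3][d] = drl[d];
    dphi[1][d] = -(1.0 + A) * dri[d] + B * drl[d];
    dphi[2][d] = A * dri[d] - (1.0 + B) * drl[d];
  }
  return true;
}

// energies indices in the breakdown vector
enum { E_BOND = 0, E_ANGLE, E_IMP, E_PROP, E_CONT, E_NONNAT, E_NTERMS };

// Evaluate V_SB and -grad(V_SB); x and f are n x 3 (column-major R matrices)
static void sbm_eval(const Topology& t, const double* x, double* f,
                     double* e) {
  int n = t.n;
  std::fill(f, f + 3 * n, 0.0);
  std::fill(e, e + E_NTERMS, 0.0);
  auto X = [&](int i, int d) { return x[i + d * n]; };
  auto addF = [&](int i, int d, double v) { f[i + d * n] += v; };

  // bonds: Kb (r - r0)^2
  for (size_t r = 0; r < t.b_i.size(); ++r) {
    int i = t.b_i[r], j = t.b_j[r];
    double dvec[3], rr = 0;
    for (int d = 0; d < 3; ++d) { dvec[d] = X(i, d) - X(j, d); rr += dvec[d] * dvec[d]; }
    rr = std::sqrt(rr);
    double dr = rr - t.b_r0[r];
    e[E_BOND] += t.b_k[r] * dr * dr;
    double coef = -2.0 * t.b_k[r] * dr / rr;
    for (int d = 0; d < 3; ++d) {
      addF(i, d, coef * dvec[d]); addF(j, d, -coef * dvec[d]);
    }
  }

  // angles: Ka (theta - theta0)^2
  for (size_t r = 0; r < t.a_i.size(); ++r) {
    int i = t.a_i[r], j = t.a_j[r], k = t.a_k[r];
    double u[3], v[3], un = 0, vn = 0;
    for (int d = 0; d < 3; ++d) {
      u[d] = X(i, d) - X(j, d); v[d] = X(k, d) - X(j, d);
      un += u[d] * u[d]; vn += v[d] * v[d];
    }
    un = std::sqrt(un); vn = std::sqrt(vn);
    double c = dot3(u, v) / (un * vn);
    c = std::max(-1.0, std::min(1.0, c));
    double theta = std::acos(c), s = std::sqrt(1.0 - c * c);
    double dt = theta - t.a_t0[r];
    e[E_ANGLE] += t.a_k2[r] * dt * dt;
    if (s < 1e-8) continue;  // collinear: zero-measure, force direction undefined
    double dVdt = 2.0 * t.a_k2[r] * dt;
    for (int d = 0; d < 3; ++d) {
      double fi = -dVdt * (c * u[d] / un - v[d] / vn) / (un * s);
      double fk = -dVdt * (c * v[d] / vn - u[d] / un) / (vn * s);
      addF(i, d, fi); addF(k, d, fk); addF(j, d, -fi - fk);
    }
  }

  // improper dihedrals: Ki (chi - chi0)^2 with periodic wrap
  for (size_t r = 0; r < t.im_i.size(); ++r) {
    int ii = t.im_i[r], jj = t.im_j[r], kk = t.im_k[r], ll = t.im_l[r];
    double xi[3], xj[3], xk[3], xl[3];
    for (int d = 0; d < 3; ++d) {
      xi[d] = X(ii, d); xj[d] = X(jj, d); xk[d] = X(kk, d); xl[d] = X(ll, d);
    }
    double phi, dphi[4][3];
    if (!dihedral_geom(xi, xj, xk, xl, phi, dphi)) continue;
    double dd = wrap_pi(phi - t.im_x0[r]);
    e[E_IMP] += t.im_kc[r] * dd * dd;
    double dVdphi = 2.0 * t.im_kc[r] * dd;
    int idx[4] = {ii, jj, kk, ll};
    for (int a = 0; a < 4; ++a)
      for (int d = 0; d < 3; ++d) addF(idx[a], d, -dVdphi * dphi[a][d]);
  }

  // proper dihedrals: Kd [(1 - cos d) + 1/2 (1 - cos 3d)]
  for (size_t r = 0; r < t.p_i.size(); ++r) {
    int ii = t.p_i[r], jj = t.p_j[r], kk = t.p_k[r], ll = t.p_l[r];
    double xi[3], xj[3], xk[3], xl[3];
    for (int d = 0; d < 3; ++d) {
      xi[d] = X(ii, d); xj[d] = X(jj, d); xk[d] = X(kk, d); xl[d] = X(ll, d);
    }
    double phi, dphi[4][3];
    if (!dihedral_geom(xi, xj, xk, xl, phi, dphi)) continue;
    double dd = phi - t.p_f0[r];
    e[E_PROP] += t.p_kc[r] * ((1.0 - std::cos(dd)) +
                             0.5 * (1.0 - std::cos(3.0 * dd)));
    double dVdphi = t.p_kc[r] * (std::sin(dd) + 1.5 * std::sin(3.0 * dd));
    int idx[4] = {ii, jj, kk, ll};
    for (int a = 0; a < 4; ++a)
      for (int d = 0; d < 3; ++d) addF(idx[a], d, -dVdphi * dphi[a][d]);
  }

  // native contacts: Kc [(s0/r)^12 - 2 (s0/r)^6]
  for (size_t r = 0; r < t.c_i.size(); ++r) {
    int i = t.c_i[r], j = t.c_j[r];
    double dvec[3], r2 = 0;
    for (int d = 0; d < 3; ++d) { dvec[d] = X(i, d) - X(j, d); r2 += dvec[d] * dvec[d]; }
    double rr = std::sqrt(r2);
    double s6 = std::pow(t.c_s0[r] / rr, 6), s12 = s6 * s6;
    e[E_CONT] += t.c_k[r] * (s12 - 2.0 * s6);
    double dVdr = 12.0 * t.c_k[r] * (s6 - s12) / rr;
    double coef = -dVdr / rr;
    for (int d = 0; d < 3; ++d) {
      addF(i, d, coef * dvec[d]); addF(j, d, -coef * dvec[d]);
    }
  }

  // non-native repulsion: Knc (sigma~/r)^12 over all non-excluded pairs
  if (t.knc > 0) {
    double s12ref = std::pow(t.sigma_nn, 12);
    for (int i = 0; i < n; ++i) {
      const std::vector<int>& ex = t.excl[i];
      size_t ep = 0;
      for (int j = i + 1; j < n; ++j) {
        while (ep < ex.size() && ex[ep] < j) ++ep;
        if (ep < ex.size() && ex[ep] == j) continue;
        double dvec[3], r2 = 0;
        for (int d = 0; d < 3; ++d) {
          dvec[d] = X(i, d) - X(j, d); r2 += dvec[d] * dvec[d];
        }
        if (r2 < 1e-20) stop("overlapping atoms in repulsive pair (%d, %d)",
                             i + 1, j + 1);
        double s12 = s12ref / (r2 * r2 * r2 * r2 * r2 * r2);
        e[E_NONNAT] += t.knc * s12;
        double coef = 12.0 * t.knc * s12 / r2;  // = -dV/dr / r
        for (int d = 0; d < 3; ++d) {
          addF(i, d, coef * dvec[d]); addF(j, d, -coef * dvec[d]);
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".sbm_eval_cpp")]]
List sbm_eval_cpp(NumericMatrix x, List top) {
  Topology t = parse_topology(top);
  if (x.nrow() != t.n) stop("coordinate/topology size mismatch");
  NumericMatrix f(t.n, 3);
  std::vector<double> e(E_NTERMS);
  sbm_eval(t, REAL(x), REAL(f), e.data());
  double total = 0; for (int i = 0; i < E_NTERMS; ++i) total += e[i];
  return List::create(
    _["bond"] = e[E_BOND], _["angle"] = e[E_ANGLE], _["improper"] = e[E_IMP],
    _["proper"] = e[E_PROP], _["contact"] = e[E_CONT],
    _["nonnative"] = e[E_NONNAT], _["total"] = total, _["forces"] = f);
}

// ---------------------------------------------------------------------------
// Native contact search: heavy-atom pairs within cutoff whose residues are
// separated by more than 3 positions (always eligible across chains)

// [[Rcpp::export(name = ".find_contacts_cpp")]]
NumericMatrix find_contacts_cpp(NumericMatrix x, IntegerVector resindex,
                                IntegerVector chainindex, double cutoff) {
  int n = x.nrow();
  double c2 = cutoff * cutoff;
  std::vector<double> out;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      bool eligible = (chainindex[i] != chainindex[j]) ||
                      (std::abs(resindex[j] - resindex[i]) > 3);
      if (!eligible) continue;
      double dx = x(i, 0) - x(j, 0), dy = x(i, 1) - x(j, 1),
             dz = x(i, 2) - x(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 <= c2) {
        out.push_back(i + 1); out.push_back(j + 1);
        out.push_back(std::sqrt(r2));
      }
    }
  }
  int nc = out.size() / 3;
  NumericMatrix res(nc, 3);
  for (int r = 0; r < nc; ++r) {
    res(r, 0) = out[3 * r]; res(r, 1) = out[3 * r + 1]; res(r, 2) = out[3 * r + 2];
  }
  return res;
}

// ---------------------------------------------------------------------------
// Debye scattering

static inline double sinc(double u) {
  if (std::fabs(u) < 1e-6) return 1.0 - u * u / 6.0;
  return std::sin(u) / u;
}
// d/dr [sinc(q r)] = [q r cos(q r) - sin(q r)] / (q r^2); -> 0 as r -> 0
static inline double dsinc_dr(double q, double r) {
  double u = q * r;
  if (std::fabs(u) < 1e-6) return -q * u / 3.0;
  return (u * std::cos(u) - std::sin(u)) / (q * r * r);
}

// I(q) = sum_ij f_i f_j sinc(q r_ij); F is m x nq (site x q)
// [[Rcpp::export(name = ".debye_intensity_cpp")]]
NumericVector debye_intensity_cpp(NumericMatrix sites, NumericMatrix F,
                                  NumericVector q) {
  int m = sites.nrow(), nq = q.size();
  if (F.nrow() != m || F.ncol() != nq) stop("form-factor table shape mismatch");
  NumericVector I(nq);
  for (int iq = 0; iq < nq; ++iq) {
    double s = 0;
    for (int i = 0; i < m; ++i) s += F(i, iq) * F(i, iq);
    I[iq] = s;
  }
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j) {
      double dx = sites(i, 0) - sites(j, 0), dy = sites(i, 1) - sites(j, 1),
             dz = sites(i, 2) - sites(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      for (int iq = 0; iq < nq; ++iq) {
        I[iq] += 2.0 * F(i, iq) * F(j, iq) * sinc(q[iq] * r);
      }
    }
  }
  return I;
}

// gradient of I(q) wrt site positions: array dim (nq, m, 3)
// [[Rcpp::export(name = ".debye_gradient_cpp")]]
NumericVector debye_gradient_cpp(NumericMatrix sites, NumericMatrix F,
                                 NumericVector q) {
  int m = sites.nrow(), nq = q.size();
  if (F.nrow() != m || F.ncol() != nq) stop("form-factor table shape mismatch");
  NumericVector g(nq * m * 3);
  g.attr("dim") = IntegerVector::create(nq, m, 3);
  auto G = [&](int iq, int i, int d) -> double& { return g[iq + nq * (i + m * d)]; };
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j) {
      double dvec[3] = {sites(i, 0) - sites(j, 0), sites(i, 1) - sites(j, 1),
                        sites(i, 2) - sites(j, 2)};
      double r = std::sqrt(dot3(dvec, dvec));
      if (r < 1e-12) continue;  // coincident sites: gradient contribution 0
      for (int iq = 0; iq < nq; ++iq) {
        double coef = 2.0 * F(i, iq) * F(j, iq) * dsinc_dr(q[iq], r) / r;
        for (int d = 0; d < 3; ++d) {
          G(iq, i, d) += coef * dvec[d];
          G(iq, j, d) -= coef * dvec[d];
        }
      }
    }
  }
  return g;
}

// ---------------------------------------------------------------------------
// chi-square bias

struct Bias {
  int m, nq;
  std::vector<int> site_of_atom;      // 0-based site per atom
  std::vector<double> weight;         // per-atom weight within its site
  NumericMatrix F;                    // m x nq
  std::vector<double> q, Iref, dIexp, sigma;
  double kchi, alpha;
};

static Bias parse_bias(const List& b, int n_atoms) {
  Bias bi;
  IntegerVector soa = b["site_of_atom"];
  NumericVector w = b["weight"];
  if (soa.size() != n_atoms) stop("bias site map does not match atom count");
  bi.site_of_atom.assign(soa.begin(), soa.end());
  for (int& s : bi.site_of_atom) s -= 1;
  bi.weight.assign(w.begin(), w.end());
  bi.F = as<NumericMatrix>(b["F"]);
  NumericVector q = b["q"], Iref = b["I_ref"], dI = b["dI_exp"], sg = b["sigma"];
  bi.q.assign(q.begin(), q.end());
  bi.Iref.assign(Iref.begin(), Iref.end());
  bi.dIexp.assign(dI.begin(), dI.end());
  bi.sigma.assign(sg.begin(), sg.end());
  bi.m = bi.F.nrow(); bi.nq = q.size();
  bi.kchi = as<double>(b["k_chi"]);
  bi.alpha = as<double>(b["alpha"]);
  return bi;
}

// V_XS = (k_chi / 2) chi^2, atom forces via residue-site chain rule.
// Returns chi^2; adds forces into f (n x 3 column-major) when f != nullptr.
static double bias_eval(const Bias& b, const double* x, int n, double* f,
                        double& vxs) {
  // site positions
  std::vector<double> sx(b.m, 0.0), sy(b.m, 0.0), sz(b.m, 0.0);
  for (int a = 0; a < n; ++a) {
    int s = b.site_of_atom[a];
    sx[s] += b.weight[a] * x[a];
    sy[s] += b.weight[a] * x[a + n];
    sz[s] += b.weight[a] * x[a + 2 * n];
  }
  int nq = b.nq, m = b.m;
  std::vector<double> I(nq);
  for (int iq = 0; iq < nq; ++iq) {
    double s = 0;
    for (int i = 0; i < m; ++i) s += b.F(i, iq) * b.F(i, iq);
    I[iq] = s;
  }
  // pair distances reused for intensity and gradient
  std::vector<double> rij(m * (m - 1) / 2);
  {
    int p = 0;
    for (int i = 0; i < m; ++i)
      for (int j = i + 1; j < m; ++j, ++p) {
        double dx = sx[i] - sx[j], dy = sy[i] - sy[j], dz = sz[i] - sz[j];
        rij[p] = std::sqrt(dx * dx + dy * dy + dz * dz);
      }
  }
  {
    int p = 0;
    for (int i = 0; i < m; ++i)
      for (int j = i + 1; j < m; ++j, ++p)
        for (int iq = 0; iq < nq; ++iq)
          I[iq] += 2.0 * b.F(i, iq) * b.F(j, iq) * sinc(b.q[iq] * rij[p]);
  }
  double chi2 = 0;
  std::vector<double> resid(nq), cq(nq);
  for (int iq = 0; iq < nq; ++iq) {
    resid[iq] = (b.dIexp[iq] - b.alpha * (I[iq] - b.Iref[iq])) / b.sigma[iq];
    chi2 += resid[iq] * resid[iq];
    // dV/dI(q) = k_chi * resid * (-alpha / sigma_q)
    cq[iq] = -b.kchi * b.alpha * resid[iq] / b.sigma[iq];
  }
  vxs = 0.5 * b.kchi * chi2;
  if (f != nullptr && b.kchi != 0.0) {
    std::vector<double> gx(m, 0.0), gy(m, 0.0), gz(m, 0.0); // dV/dsite
    int p = 0;
    for (int i = 0; i < m; ++i) {
      for (int j = i + 1; j < m; ++j, ++p) {
        double r = rij[p];
        if (r < 1e-12) continue;
        double coef = 0;
        for (int iq = 0; iq < nq; ++iq)
          coef += cq[iq] * 2.0 * b.F(i, iq) * b.F(j, iq) * dsinc_dr(b.q[iq], r);
        coef /= r;
        double dx = sx[i] - sx[j], dy = sy[i] - sy[j], dz = sz[i] - sz[j];
        gx[i] += coef * dx; gy[i] += coef * dy; gz[i] += coef * dz;
        gx[j] -= coef * dx; gy[j] -= coef * dy; gz[j] -= coef * dz;
      }
    }
    for (int a = 0; a < n; ++a) {
      int s = b.site_of_atom[a];
      f[a]         -= b.weight[a] * gx[s];
      f[a + n]     -= b.weight[a] * gy[s];
      f[a + 2 * n] -= b.weight[a] * gz[s];
    }
  }
  return chi2;
}

// [[Rcpp::export(name = ".bias_eval_cpp")]]
List bias_eval_cpp(NumericMatrix x, List bias) {
  int n = x.nrow();
  Bias b = parse_bias(bias, n);
  NumericMatrix f(n, 3);
  double vxs = 0;
  double chi2 = bias_eval(b, REAL(x), n, REAL(f), vxs);
  return List::create(_["V_XS"] = vxs, _["chi2"] = chi2, _["forces"] = f);
}

// ---------------------------------------------------------------------------
// BAOAB Langevin integrator (unit masses, reduced units). With friction = 0
// this reduces exactly to velocity Verlet (no RNG draws), giving NVE.

// [[Rcpp::export(name = ".run_langevin_cpp")]]
List run_langevin_cpp(NumericMatrix x0, NumericMatrix v0, List top,
                      double dt, double friction, double kT,
                      int n_steps, int out_stride, Nullable<List> bias_,
                      int bias_stride) {
  Topology t = parse_topology(top);
  int n = t.n;
  if (x0.nrow() != n || v0.nrow() != n) stop("state/topology size mismatch");
  bool has_bias = bias_.isNotNull();
  Bias b;
  if (has_bias) b = parse_bias(List(bias_), n);

  std::vector<double> x(REAL(x0), REAL(x0) + 3 * n);
  std::vector<double> v(REAL(v0), REAL(v0) + 3 * n);
  std::vector<double> f(3 * n), fb(3 * n, 0.0), e(E_NTERMS);

  double c1 = (friction > 0) ? std::exp(-friction * dt) : 1.0;
  double c2 = (friction > 0) ? std::sqrt((1.0 - c1 * c1) * kT) : 0.0;

  int n_frames = n_steps / out_stride + 1;
  NumericVector frames(n_frames * n * 3);
  frames.attr("dim") = IntegerVector::create(n_frames, n, 3);
  int n_ecol = 12;
  NumericMatrix energies(n_frames, n_ecol);
  NumericVector times(n_frames);

  double vxs = 0, chi2 = 0;
  sbm_eval(t, x.data(), f.data(), e.data());
  if (has_bias) {
    std::fill(fb.begin(), fb.end(), 0.0);
    chi2 = bias_eval(b, x.data(), n, fb.data(), vxs);
  }

  int frame = 0, last_ok_step = 0;
  bool blown = false;
  auto record = [&](int step) {
    for (int a = 0; a < n; ++a)
      for (int d = 0; d < 3; ++d)
        frames[frame + n_frames * (a + n * d)] = x[a + d * n];
    double ke = 0;
    for (int i = 0; i < 3 * n; ++i) ke += 0.5 * v[i] * v[i];
    double vsb = 0; for (int i = 0; i < E_NTERMS; ++i) vsb += e[i];
    times[frame] = step * dt;
    energies(frame, 0) = e[E_BOND]; energies(frame, 1) = e[E_ANGLE];
    energies(frame, 2) = e[E_IMP]; energies(frame, 3) = e[E_PROP];
    energies(frame, 4) = e[E_CONT]; energies(frame, 5) = e[E_NONNAT];
    energies(frame, 6) = vsb; energies(frame, 7) = vxs;
    energies(frame, 8) = chi2; energies(frame, 9) = ke;
    energies(frame, 10) = (n > 0) ? 2.0 * ke / (3.0 * n) : 0.0; // kB*T_inst
    energies(frame, 11) = vsb + vxs + ke;
    ++frame;
  };
  record(0);

  for (int step = 1; step <= n_steps; ++step) {
    // B
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * (f[i] + fb[i]);
    // A
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // O
    if (friction > 0) {
      for (int i = 0; i < 3 * n; ++i)
        v[i] = c1 * v[i] + c2 * ::norm_rand();
    }
    // A
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    // force refresh + B
    // a coordinate beyond ~10 micrometres means the integration has failed
    // (the observed blow-up mode under an excessive bias weight)
    bool finite = true;
    for (int i = 0; i < 3 * n && finite; ++i)
      if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e4) finite = false;
    if (finite) {
      sbm_eval(t, x.data(), f.data(), e.data());
      for (int i = 0; i < 3 * n && finite; ++i)
        if (!std::isfinite(f[i])) finite = false;
    }
    if (finite && has_bias && (step % bias_stride == 0)) {
      std::fill(fb.begin(), fb.end(), 0.0);
      chi2 = bias_eval(b, x.data(), n, fb.data(), vxs);
      for (int i = 0; i < 3 * n && finite; ++i)
        if (!std::isfinite(fb[i])) finite = false;
    }
    if (!finite) { blown = true; last_ok_step = step - 1; break; }
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * (f[i] + fb[i]);

    if (step % out_stride == 0) record(step);
    last_ok_step = step;
    if (step % 8192 == 0) Rcpp::checkUserInterrupt();
  }

  if (blown) {
    // truncate to recorded frames
    frames = frames[Range(0, n_frames * n * 3 - 1)]; // dims kept; frame count below
  }
  NumericMatrix xf(n, 3), vf(n, 3);
  for (int a = 0; a < n; ++a)
    for (int d = 0; d < 3; ++d) { xf(a, d) = x[a + d * n]; vf(a, d) = v[a + d * n]; }

  return List::create(
    _["frames"] = frames, _["times"] = times, _["energies"] = energies,
    _["n_frames_recorded"] = frame, _["status"] = blown ? "blowup" : "ok",
    _["last_stable_step"] = last_ok_step, _["x_final"] = xf, _["v_final"] = vf);
}
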