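// Coarse-grained clamp dynamics: one bead per clamp domain, harmonic bonded
// terms, moving harmonic restraints on COM-distance / torsion collective
// variables, BAOAB Langevin integration.
//
// Units: Angstrom, ps, amu, kcal/mol.  1 kcal/mol = 418.4 amu A^2 ps^-2.
// Angles handled internally in radians; restraint schedules in ps.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double EKCAL = 418.4;
static const double KB = 0.0019872041;  // kcal mol^-1 K^-1

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(dot(*this)); }
};

static inline double wrap_pi(double a) {
  while (a > M_PI) a -= 2.0 * M_PI;
  while (a <= -M_PI) a += 2.0 * M_PI;
  return a;
}

// dihedral angle and gradients; returns phi (IUPAC sign, cis = 0)
static double dihedral_grad(const Vec3& p1, const Vec3& p2, const Vec3& p3,
                            const Vec3& p4, Vec3 g[4]) {
  Vec3 b1 = p2 - p1, b2 = p3 - p2, b3 = p4 - p3;
  Vec3 n1 = b1.cross(b2), n2 = b2.cross(b3);
  double lb2 = b2.norm();
  double n1sq = n1.dot(n1), n2sq = n2.dot(n2);
  // regularise near-collinear geometry (cap the 1/sin^2 factor); CG rings
  // never approach collinearity in normal operation
  double cap1 = 1e-10 * b1.dot(b1) * b2.dot(b2);
  double cap2 = 1e-10 * b2.dot(b2) * b3.dot(b3);
  if (n1sq < cap1) n1sq = cap1;
  if (n2sq < cap2) n2sq = cap2;
  Vec3 b2u = b2 * (1.0 / lb2);
  double phi = std::atan2(n1.cross(n2).dot(b2u), n1.dot(n2));
  Vec3 dp1 = n1 * (-lb2 / n1sq);
  Vec3 dp4 = n2 * (lb2 / n2sq);
  double c12 = b1.dot(b2) / b2.dot(b2);
  double c32 = b3.dot(b2) / b2.dot(b2);
  g[0] = dp1;
  g[1] = dp1 * (-c12 - 1.0) + dp4 * c32;
  g[2] = dp4 * (-c32 - 1.0) + dp1 * c12;
  g[3] = dp4;
  return phi;
}

// angle at vertex j and gradients
static double angle_grad(const Vec3& pi, const Vec3& pj, const Vec3& pk,
                         Vec3 g[3]) {
  Vec3 u = pi - pj, v = pk - pj;
  double lu = u.norm(), lv = v.norm();
  Vec3 uh = u * (1.0 / lu), vh = v * (1.0 / lv);
  double ct = uh.dot(vh);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  double th = std::acos(ct);
  double st = std::sqrt(1.0 - ct * ct);
  if (st < 1e-8) st = 1e-8;
  g[0] = (uh * ct - vh) * (1.0 / (lu * st));
  g[2] = (vh * ct - uh) * (1.0 / (lv * st));
  g[1] = (g[0] + g[2]) * (-1.0);
  return th;
}

struct System {
  int n;
  std::vector<double> mass;
  // bonds
  std::vector<int> bi, bj; std::vector<double> bk, br0;
  // angles (theta0 in rad)
  std::vector<int> ai, aj, ak_; std::vector<double> akf, ath0;
  // torsions (phi0 in rad)
  std::vector<int> t1, t2, t3, t4; std::vector<double> tkf, tphi0;
  // restraints: kind 0 = distance(i,j), 1 = torsion(i,j,k,l)
  std::vector<int> rkind;
  std::vector<std::array<int, 4> > ridx;
  std::vector<double> rk, rt0, rrate, rdur, roff;  // k, target0, rate/ps, move duration ps, active-until ps
};

static System unpack(List sys) {
  System S;
  NumericVector mass = sys["mass"];
  S.n = mass.size();
  S.mass.assign(mass.begin(), mass.end());
  IntegerMatrix B = sys["bonds_idx"]; NumericMatrix Bp = sys["bonds_par"];
  for (int i = 0; i < B.nrow(); ++i) {
    S.bi.push_back(B(i, 0) - 1); S.bj.push_back(B(i, 1) - 1);
    S.bk.push_back(Bp(i, 0)); S.br0.push_back(Bp(i, 1));
  }
  IntegerMatrix A = sys["angles_idx"]; NumericMatrix Ap = sys["angles_par"];
  for (int i = 0; i < A.nrow(); ++i) {
    S.ai.push_back(A(i, 0) - 1); S.aj.push_back(A(i, 1) - 1);
    S.ak_.push_back(A(i, 2) - 1);
    S.akf.push_back(Ap(i, 0)); S.ath0.push_back(Ap(i, 1));
  }
  IntegerMatrix T = sys["torsions_idx"]; NumericMatrix Tp = sys["torsions_par"];
  for (int i = 0; i < T.nrow(); ++i) {
    S.t1.push_back(T(i, 0) - 1); S.t2.push_back(T(i, 1) - 1);
    S.t3.push_back(T(i, 2) - 1); S.t4.push_back(T(i, 3) - 1);
    S.tkf.push_back(Tp(i, 0)); S.tphi0.push_back(Tp(i, 1));
  }
  if (sys.containsElementNamed("restraints")) {
    List R = sys["restraints"];
    for (int i = 0; i < R.size(); ++i) {
      List r = R[i];
      S.rkind.push_back(as<int>(r["kind"]));
      IntegerVector idx = r["idx"];
      std::array<int, 4> a = {0, 0, 0, 0};
      for (int k = 0; k < idx.size(); ++k) a[k] = idx[k] - 1;
      S.ridx.push_back(a);
      S.rk.push_back(as<double>(r["k"]));
      S.rt0.push_back(as<double>(r["target0"]));
      S.rrate.push_back(as<double>(r["rate"]));
      S.rdur.push_back(as<double>(r["duration"]));
      S.roff.push_back(as<double>(r["active_until"]));
    }
  }
  return S;
}

static double restraint_target(const System& S, int r, double t) {
  double tm = t;
  if (tm < 0) tm = 0;
  if (tm > S.rdur[r]) tm = S.rdur[r];
  return S.rt0[r] + S.rrate[r] * tm;
}

// total potential energy and forces (-grad U); optionally per-restraint
// colvar value/target/energy
static double eval_forces(const System& S, const std::vector<Vec3>& x,
                          double t, std::vector<Vec3>& F,
                          std::vector<double>* cv_val = nullptr,
                          std::vector<double>* cv_tgt = nullptr,
                          std::vector<double>* cv_en = nullptr) {
  double U = 0.0;
  for (int i = 0; i < S.n; ++i) F[i] = Vec3();
  for (size_t b = 0; b < S.bi.size(); ++b) {
    Vec3 d = x[S.bj[b]] - x[S.bi[b]];
    double r = d.norm();
    double dr = r - S.br0[b];
    U += 0.5 * S.bk[b] * dr * dr;
    Vec3 f = d * (S.bk[b] * dr / r);
    F[S.bi[b]] = F[S.bi[b]] + f;
    F[S.bj[b]] = F[S.bj[b]] - f;
  }
  Vec3 g3[3];
  for (size_t a = 0; a < S.ai.size(); ++a) {
    double th = angle_grad(x[S.ai[a]], x[S.aj[a]], x[S.ak_[a]], g3);
    double dth = th - S.ath0[a];
    U += 0.5 * S.akf[a] * dth * dth;
    double c = -S.akf[a] * dth;
    F[S.ai[a]] = F[S.ai[a]] + g3[0] * c;
    F[S.aj[a]] = F[S.aj[a]] + g3[1] * c;
    F[S.ak_[a]] = F[S.ak_[a]] + g3[2] * c;
  }
  Vec3 g4[4];
  for (size_t tt = 0; tt < S.t1.size(); ++tt) {
    double phi = dihedral_grad(x[S.t1[tt]], x[S.t2[tt]], x[S.t3[tt]],
                               x[S.t4[tt]], g4);
    double dphi = wrap_pi(phi - S.tphi0[tt]);
    U += 0.5 * S.tkf[tt] * dphi * dphi;
    double c = -S.tkf[tt] * dphi;
    F[S.t1[tt]] = F[S.t1[tt]] + g4[0] * c;
    F[S.t2[tt]] = F[S.t2[tt]] + g4[1] * c;
    F[S.t3[tt]] = F[S.t3[tt]] + g4[2] * c;
    F[S.t4[tt]] = F[S.t4[tt]] + g4[3] * c;
  }
  for (size_t r = 0; r < S.rkind.size(); ++r) {
    bool active = (t < S.roff[r]);
    double val, en = 0.0, tgt = restraint_target(S, r, t);
    if (S.rkind[r] == 0) {
      Vec3 d = x[S.ridx[r][1]] - x[S.ridx[r][0]];
      val = d.norm();
      if (active) {
        double dr = val - tgt;
        en = 0.5 * S.rk[r] * dr * dr;
        Vec3 f = d * (S.rk[r] * dr / val);
        F[S.ridx[r][0]] = F[S.ridx[r][0]] + f;
        F[S.ridx[r][1]] = F[S.ridx[r][1]] - f;
      }
    } else {
      double phi = dihedral_grad(x[S.ridx[r][0]], x[S.ridx[r][1]],
                                 x[S.ridx[r][2]], x[S.ridx[r][3]], g4);
      val = phi;
      if (active) {
        double dphi = wrap_pi(phi - tgt);
        en = 0.5 * S.rk[r] * dphi * dphi;
        double c = -S.rk[r] * dphi;
        for (int k = 0; k < 4; ++k)
          F[S.ridx[r][k]] = F[S.ridx[r][k]] + g4[k] * c;
      }
    }
    if (active) U += en;
    if (cv_val) { (*cv_val)[r] = val; (*cv_tgt)[r] = tgt; (*cv_en)[r] = en; }
  }
  return U;
}

// [[Rcpp::export(name = ".cg_eval_cpp")]]
List cg_eval_cpp(List sys, NumericMatrix x, double t) {
  System S = unpack(sys);
  std::vector<Vec3> X(S.n), F(S.n);
  for (int i = 0; i < S.n; ++i) X[i] = Vec3(x(i, 0), x(i, 1), x(i, 2));
  int nr = S.rkind.size();
  std::vector<double> cv(nr), ct(nr), ce(nr);
  double U = eval_forces(S, X, t, F, &cv, &ct, &ce);
  NumericMatrix Fout(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    Fout(i, 0) = F[i].x; Fout(i, 1) = F[i].y; Fout(i, 2) = F[i].z;
  }
  return List::create(_["energy"] = U, _["forces"] = Fout,
                      _["cv_value"] = NumericVector(cv.begin(), cv.end()),
                      _["cv_target"] = NumericVector(ct.begin(), ct.end()),
                      _["cv_energy"] = NumericVector(ce.begin(), ce.end()));
}

// [[Rcpp::export(name = ".cg_run_cpp")]]
List cg_run_cpp(List sys, NumericMatrix x0, NumericMatrix v0,
                double temperature, double damping, double dt,
                int n_steps, int save_every, double t0) {
  System S = unpack(sys);
  int n = S.n;
  std::vector<Vec3> x(n), v(n), F(n);
  for (int i = 0; i < n; ++i) {
    x[i] = Vec3(x0(i, 0), x0(i, 1), x0(i, 2));
    v[i] = Vec3(v0(i, 0), v0(i, 1), v0(i, 2));
  }
  double c1 = std::exp(-damping * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);
  std::vector<double> sig(n), facc(n);
  for (int i = 0; i < n; ++i) {
    sig[i] = std::sqrt(KB * temperature * EKCAL / S.mass[i]);
    facc[i] = EKCAL / S.mass[i];
  }
  int n_save = n_steps / save_every;
  int nr = S.rkind.size();
  NumericMatrix frames(n_save, 3 * n);
  NumericVector times(n_save), e_tot(n_save), e_pot(n_save);
  NumericMatrix cv_val(n_save, nr), cv_tgt(n_save, nr), cv_en(n_save, nr);
  std::vector<double> cv(nr), ct(nr), ce(nr);

  RNGScope rng;
  double U = eval_forces(S, x, t0, F, &cv, &ct, &ce);
  int isave = 0;
  for (int s = 0; s < n_steps; ++s) {
    double t_end = t0 + (s + 1) * dt;
    for (int i = 0; i < n; ++i) {
      v[i] = v[i] + F[i] * (0.5 * dt * facc[i]);
      x[i] = x[i] + v[i] * (0.5 * dt);
    }
    if (temperature > 0.0 && damping > 0.0) {
      for (int i = 0; i < n; ++i) {
        v[i].x = c1 * v[i].x + c2 * sig[i] * norm_rand();
        v[i].y = c1 * v[i].y + c2 * sig[i] * norm_rand();
        v[i].z = c1 * v[i].z + c2 * sig[i] * norm_rand();
      }
    } else if (damping > 0.0) {
      for (int i = 0; i < n; ++i) v[i] = v[i] * c1;
    }
    for (int i = 0; i < n; ++i) x[i] = x[i] + v[i] * (0.5 * dt);
    U = eval_forces(S, x, t_end, F, &cv, &ct, &ce);
    for (int i = 0; i < n; ++i) v[i] = v[i] + F[i] * (0.5 * dt * facc[i]);

    if ((s + 1) % save_every == 0) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i) ke += 0.5 * S.mass[i] * v[i].dot(v[i]);
      ke /= EKCAL;
      for (int i = 0; i < n; ++i) {
        frames(isave, 3 * i) = x[i].x;
        frames(isave, 3 * i + 1) = x[i].y;
        frames(isave, 3 * i + 2) = x[i].z;
      }
      times[isave] = t_end;
      e_pot[isave] = U;
      e_tot[isave] = U + ke;
      for (int r = 0; r < nr; ++r) {
        cv_val(isave, r) = cv[r]; cv_tgt(isave, r) = ct[r];
        cv_en(isave, r) = ce[r];
      }
      ++isave;
    }
    if (s % 100000 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix xf(n, 3), vf(n, 3);
  for (int i = 0; i < n; ++i) {
    xf(i, 0) = x[i].x; xf(i, 1) = x[i].y; xf(i, 2) = x[i].z;
    vf(i, 0) = v[i].x; vf(i, 1) = v[i].y; vf(i, 2) = v[i].z;
  }
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["e_pot"] = e_pot, _["e_tot"] = e_tot,
                      _["cv_value"] = cv_val, _["cv_target"] = cv_tgt,
                      _["cv_energy"] = cv_en,
                      _["x_final"] = xf, _["v_final"] = vf);
}
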