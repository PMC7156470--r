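// Fixed-step RK4 integration of ions under screened Coulomb + short-range
// collision forces, with a Verlet neighbour list over periodic replicas.
// The replication sum is truncated where exp(-kappa r) drops below the image
// cutoff tolerance (hard-capped at rcut_max); at least the nearest images are
// always present.  Charges are piecewise-constant staircases, kappa is
// linearly interpolated.  Atoms flagged non-mobile never move.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

namespace {

const double KE_CONST = 14.3996;        // eV*Angstrom
const double ACC_CONV = 1.0 / 103.6427; // (eV/A)/u -> A/fs^2
const double U_TO_EV  = 103.6427;       // u (A/fs)^2 -> eV

struct Neighbour {
  int j;
  double sx, sy, sz;  // image shift of atom j
};

// exp(-x) for x in [0, XMAX], tabulated with linear interpolation
// (relative error ~1e-7; screened terms beyond XMAX are below any image
// tolerance the integrator uses)
const double EXP_XMAX = 16.0;
const int EXP_N = 1 << 15;
struct ExpTable {
  double tab[EXP_N + 2];
  double inv_dx;
  ExpTable() {
    inv_dx = (EXP_N) / EXP_XMAX;
    for (int i = 0; i <= EXP_N + 1; ++i)
      tab[i] = std::exp(-i * EXP_XMAX / EXP_N);
  }
  inline double operator()(double x) const {
    if (x <= 0.0) return 1.0;
    if (x >= EXP_XMAX) return 0.0;
    double u = x * inv_dx;
    int k = (int)u;
    double f = u - k;
    return tab[k] * (1.0 - f) + tab[k + 1] * f;
  }
};
const ExpTable fast_expneg;

struct Engine {
  int n;
  std::vector<double> x, v, mass;        // 3n
  std::vector<char> mobile;
  std::vector<int> mids;                 // indices of mobile atoms
  std::vector<int> eidx;
  NumericMatrix re;                      // contact radii per element pair
  double D, a_hard;
  bool collision;
  NumericMatrix qmat;                    // n x nq charge staircases
  NumericVector qtimes;
  NumericVector kap, kaptimes;
  double L;
  bool periodic;
  double tol_img, rcut_max, skin;
  std::vector<std::vector<Neighbour> > nl;   // geometric lists
  std::vector<std::vector<Neighbour> > nlq;  // charged-neighbour sublists
  std::vector<double> x_build;           // positions at last build
  double rcut_build;
  std::vector<double> q;                 // current charges
  int qcol = -1;                         // current charge-staircase column

  double rcut_of(double kappa) const {
    double rc = rcut_max;
    // floor just above the collision contact radii: the screened interaction
    // at the floor is below the image tolerance whenever the floor binds
    if (kappa > 1e-9) rc = std::min(rc, std::max(3.5, -std::log(tol_img) / kappa));
    return rc;
  }

  double kappa_at(double t) const {
    int nk = kap.size();
    if (nk == 1 || t <= kaptimes[0]) return kap[0];
    if (t >= kaptimes[nk - 1]) return kap[nk - 1];
    int k = 0;
    while (k + 1 < nk && kaptimes[k + 1] < t) ++k;
    double w = (t - kaptimes[k]) / (kaptimes[k + 1] - kaptimes[k]);
    return kap[k] * (1 - w) + kap[k + 1] * w;
  }

  void charges_at(double t) {
    int nq = qtimes.size();
    int k = nq - 1;
    if (nq > 1) {
      k = 0;
      while (k + 1 < nq && qtimes[k + 1] <= t) ++k;
    }
    if (k != qcol) {
      qcol = k;
      for (int i = 0; i < n; ++i) q[i] = qmat(i, k);
      refilter();
    }
  }

  // keep, per mobile atom, only the neighbours that currently carry charge
  void refilter() {
    if (nl.empty()) return;
    if (nlq.size() != nl.size()) nlq.resize(nl.size());
    for (size_t mi = 0; mi < nl.size(); ++mi) {
      nlq[mi].clear();
      const std::vector<Neighbour>& full = nl[mi];
      for (size_t kk = 0; kk < full.size(); ++kk)
        if (q[full[kk].j] > 0.0) nlq[mi].push_back(full[kk]);
    }
  }

  void wrap_mobile() {
    if (!periodic) return;
    for (size_t mi = 0; mi < mids.size(); ++mi) {
      int i = mids[mi];
      for (int d = 0; d < 3; ++d) {
        double c = x[3 * i + d];
        c -= L * std::floor(c / L);
        x[3 * i + d] = c;
      }
    }
  }

  void build_neighbours(double kappa) {
    wrap_mobile();
    rcut_build = rcut_of(kappa);
    double reach = rcut_build + skin;
    double reach2 = reach * reach;
    nl.assign(mids.size(), std::vector<Neighbour>());
    std::vector<std::array<double, 3> > shifts;
    if (periodic) {
      int nmax = (int)std::ceil(reach / L);
      if (nmax < 1) nmax = 1;
      for (int ax = -nmax; ax <= nmax; ++ax)
        for (int ay = -nmax; ay <= nmax; ++ay)
          for (int az = -nmax; az <= nmax; ++az)
            shifts.push_back({ax * L, ay * L, az * L});
    } else {
      shifts.push_back({0.0, 0.0, 0.0});
    }
    for (size_t mi = 0; mi < mids.size(); ++mi) {
      int i = mids[mi];
      double xi = x[3 * i], yi = x[3 * i + 1], zi = x[3 * i + 2];
      std::vector<Neighbour>& lst = nl[mi];
      for (size_t s = 0; s < shifts.size(); ++s) {
        double sx = shifts[s][0], sy = shifts[s][1], sz = shifts[s][2];
        bool central = (sx == 0.0 && sy == 0.0 && sz == 0.0);
        for (int j = 0; j < n; ++j) {
          if (central && j == i) continue;
          if (!periodic) { lst.push_back({j, 0.0, 0.0, 0.0}); continue; }
          double dx = xi - (x[3 * j] + sx);
          double dy = yi - (x[3 * j + 1] + sy);
          double dz = zi - (x[3 * j + 2] + sz);
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 < reach2) lst.push_back({j, sx, sy, sz});
        }
      }
    }
    x_build.assign(x.begin(), x.end());
    refilter();
  }

  // rebuild when the current cutoff plus accumulated drift outgrows the list
  // reach (with the skin as hysteresis), or when the screening has tightened
  // enough that much smaller lists suffice
  bool need_rebuild(double kappa) const {
    if (!periodic && !nl.empty()) return false;
    if (nl.empty()) return true;
    double rc = rcut_of(kappa);
    if (rc < 0.6 * rcut_build) return true;               // shrink the lists
    double maxd2 = 0.0;
    for (size_t mi = 0; mi < mids.size(); ++mi) {
      int i = mids[mi];
      double dx = x[3 * i] - x_build[3 * i];
      double dy = x[3 * i + 1] - x_build[3 * i + 1];
      double dz = x[3 * i + 2] - x_build[3 * i + 2];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > maxd2) maxd2 = d2;
    }
    return rc + 2.0 * std::sqrt(maxd2) > rcut_build + skin;
  }

  // forces (eV/A) on mobile atoms only, positions given in `pos`
  void forces(const std::vector<double>& pos, double kappa,
              std::vector<double>& F) const {
    std::fill(F.begin(), F.end(), 0.0);
    double rc2 = rcut_build * rcut_build;
    for (size_t mi = 0; mi < mids.size(); ++mi) {
      int i = mids[mi];
      double qi = q[i];
      if (qi <= 0.0) continue;           // neutral atoms feel no force
      double xi = pos[3 * i], yi = pos[3 * i + 1], zi = pos[3 * i + 2];
      double fx = 0, fy = 0, fz = 0;
      const std::vector<Neighbour>& lst = nlq[mi];
      int ei = eidx[i];
      for (size_t kk = 0; kk < lst.size(); ++kk) {
        const Neighbour& nb = lst[kk];
        int j = nb.j;
        double qq = qi * q[j];
        if (qq <= 0.0) continue;
        double dx = xi - (pos[3 * j] + nb.sx);
        double dy = yi - (pos[3 * j + 1] + nb.sy);
        double dz = zi - (pos[3 * j + 2] + nb.sz);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (periodic && r2 > rc2) continue;
        double r = std::sqrt(r2);
        if (r < 1e-9)
          stop("overlapping atoms %d and %d during integration", i + 1, j + 1);
        double fmag = KE_CONST * qq * fast_expneg(kappa * r) * (1.0 + kappa * r) / r2;
        if (collision) {
          double rei = re(ei, eidx[j]);
          if (r < rei) {
            double e1 = std::exp(-a_hard * (r - rei));
            fmag -= 2.0 * D * (1.0 - e1) * a_hard * e1;
          }
        }
        double inv = fmag / r;
        fx += dx * inv; fy += dy * inv; fz += dz * inv;
      }
      F[3 * i] = fx; F[3 * i + 1] = fy; F[3 * i + 2] = fz;
    }
  }

  // energy ledger over pairs involving at least one mobile atom
  // (mobile-mobile pairs appear in two lists and are halved)
  double potential(double kappa) const {
    double V = 0.0;
    double rc2 = rcut_build * rcut_build;
    for (size_t mi = 0; mi < mids.size(); ++mi) {
      int i = mids[mi];
      double qi = q[i];
      if (qi <= 0.0) continue;
      double xi = x[3 * i], yi = x[3 * i + 1], zi = x[3 * i + 2];
      const std::vector<Neighbour>& lst = nlq[mi];
      int ei = eidx[i];
      for (size_t kk = 0; kk < lst.size(); ++kk) {
        const Neighbour& nb = lst[kk];
        int j = nb.j;
        double qq = qi * q[j];
        if (qq <= 0.0) continue;
        double dx = xi - (x[3 * j] + nb.sx);
        double dy = yi - (x[3 * j + 1] + nb.sy);
        double dz = zi - (x[3 * j + 2] + nb.sz);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (periodic && r2 > rc2) continue;
        double r = std::sqrt(r2);
        double v = KE_CONST * qq * fast_expneg(kappa * r) / r;
        if (collision) {
          double rei = re(ei, eidx[j]);
          if (r < rei) {
            double e1 = std::exp(-a_hard * (r - rei));
            v += D * (1.0 - e1) * (1.0 - e1);
          }
        }
        V += mobile[j] ? 0.5 * v : v;
      }
    }
    return V;
  }

  double kinetic() const {
    double K = 0.0;
    for (size_t mi = 0; mi < mids.size(); ++mi) {
      int i = mids[mi];
      double v2 = v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                  v[3 * i + 2] * v[3 * i + 2];
      K += 0.5 * mass[i] * v2 * U_TO_EV;
    }
    return K;
  }

  double ss_dist(int i1, int i2) const {
    double d[3];
    for (int k = 0; k < 3; ++k) {
      d[k] = x[3 * i1 + k] - x[3 * i2 + k];
      if (periodic) d[k] -= L * std::round(d[k] / L);
    }
    return std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  }
};

} // namespace

// [[Rcpp::export]]
List integrate_ions_cpp(NumericMatrix pos0, NumericVector mass,
                        LogicalVector mobile, IntegerVector eidx,
                        NumericMatrix re_mat, double D, double a_hard,
                        bool collision,
                        NumericMatrix qmat, NumericVector qtimes,
                        NumericVector kappa, NumericVector kappa_times,
                        double L, int i1, int i2,
                        double dt, double t_end, double out_stride,
                        double tol_img, double rcut_max, double skin,
                        double max_step_disp, bool store_positions) {
  int n = pos0.nrow();
  Engine E;
  E.n = n;
  E.x.resize(3 * n); E.v.assign(3 * n, 0.0);
  E.mass.assign(mass.begin(), mass.end());
  E.mobile.resize(n);
  E.eidx.assign(eidx.begin(), eidx.end());
  E.re = re_mat; E.D = D; E.a_hard = a_hard; E.collision = collision;
  E.qmat = qmat; E.qtimes = qtimes;
  E.kap = kappa; E.kaptimes = kappa_times;
  E.L = L; E.periodic = (L > 0);
  E.tol_img = tol_img; E.rcut_max = rcut_max; E.skin = skin;
  E.q.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    E.x[3 * i] = pos0(i, 0); E.x[3 * i + 1] = pos0(i, 1); E.x[3 * i + 2] = pos0(i, 2);
    E.mobile[i] = mobile[i];
    if (mobile[i]) E.mids.push_back(i);
  }
  int nm = E.mids.size();

  int nstep = (int)std::ceil(t_end / dt - 1e-9);
  if (nstep < 1) nstep = 1;
  double h = t_end / nstep;
  int out_every = (int)std::max(1.0, std::round(out_stride / h));
  int nout_max = nstep / out_every + 2;

  std::vector<double> times_out, ss_out, kin_out, pot_out;
  times_out.reserve(nout_max);
  NumericVector poses;
  std::vector<double> pos_frames;
  if (store_positions) pos_frames.reserve((size_t)nout_max * 3 * n);

  std::vector<double> F(3 * n), xs(3 * n);
  std::vector<double> k1x(3 * nm), k1v(3 * nm), k2x(3 * nm), k2v(3 * nm),
      k3x(3 * nm), k3v(3 * nm), k4x(3 * nm), k4v(3 * nm);

  E.charges_at(0.0);
  double kap0 = E.kappa_at(0.0);
  E.build_neighbours(kap0);

  int nframes = 0;
  // record initial frame
  times_out.push_back(0.0);
  ss_out.push_back(E.ss_dist(i1, i2));
  kin_out.push_back(E.kinetic());
  pot_out.push_back(E.potential(kap0));
  if (store_positions) {
    for (int i = 0; i < 3 * n; ++i) pos_frames.push_back(E.x[i]);
  }
  ++nframes;

  for (int step = 0; step < nstep; ++step) {
    double t = step * h;
    double kmid = E.kappa_at(t + h / 2), kend = E.kappa_at(t + h);
    double know = E.kappa_at(t);
    if (E.need_rebuild(know)) E.build_neighbours(know);
    E.charges_at(t);

    // stage 1
    E.forces(E.x, know, F);
    for (int m = 0; m < nm; ++m) {
      int i = E.mids[m];
      for (int d = 0; d < 3; ++d) {
        k1x[3 * m + d] = E.v[3 * i + d];
        k1v[3 * m + d] = F[3 * i + d] * ACC_CONV / E.mass[i];
      }
    }
    // stage 2
    xs = E.x;
    for (int m = 0; m < nm; ++m) {
      int i = E.mids[m];
      for (int d = 0; d < 3; ++d) xs[3 * i + d] += 0.5 * h * k1x[3 * m + d];
    }
    E.charges_at(t + h / 2);
    E.forces(xs, kmid, F);
    for (int m = 0; m < nm; ++m) {
      int i = E.mids[m];
      for (int d = 0; d < 3; ++d) {
        k2x[3 * m + d] = E.v[3 * i + d] + 0.5 * h * k1v[3 * m + d];
        k2v[3 * m + d] = F[3 * i + d] * ACC_CONV / E.mass[i];
      }
    }
    // stage 3
    xs = E.x;
    for (int m = 0; m < nm; ++m) {
      int i = E.mids[m];
      for (int d = 0; d < 3; ++d) xs[3 * i + d] += 0.5 * h * k2x[3 * m + d];
    }
    E.forces(xs, kmid, F);
    for (int m = 0; m < nm; ++m) {
      int i = E.mids[m];
      for (int d = 0; d < 3; ++d) {
        k3x[3 * m + d] = E.v[3 * i + d] + 0.5 * h * k2v[3 * m + d];
        k3v[3 * m + d] = F[3 * i + d] * ACC_CONV / E.mass[i];
      }
    }
    // stage 4
    xs = E.x;
    for (int m = 0; m < nm; ++m) {
      int i = E.mids[m];
      for (int d = 0; d < 3; ++d) xs[3 * i + d] += h * k3x[3 * m + d];
    }
    E.charges_at(t + h);
    E.forces(xs, kend, F);
    for (int m = 0; m < nm; ++m) {
      int i = E.mids[m];
      for (int d = 0; d < 3; ++d) {
        k4x[3 * m + d] = E.v[3 * i + d] + h * k3v[3 * m + d];
        k4v[3 * m + d] = F[3 * i + d] * ACC_CONV / E.mass[i];
      }
    }
    // combine
    double max_d2 = 0.0;
    for (int m = 0; m < nm; ++m) {
      int i = E.mids[m];
      double d2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        double dx = h / 6.0 * (k1x[3 * m + d] + 2 * k2x[3 * m + d] +
                               2 * k3x[3 * m + d] + k4x[3 * m + d]);
        E.x[3 * i + d] += dx;
        d2 += dx * dx;
        E.v[3 * i + d] += h / 6.0 * (k1v[3 * m + d] + 2 * k2v[3 * m + d] +
                                     2 * k3v[3 * m + d] + k4v[3 * m + d]);
      }
      if (d2 > max_d2) max_d2 = d2;
    }
    if (max_d2 > max_step_disp * max_step_disp)
      stop("integration unstable: per-step displacement %.3g A exceeds %.3g A at t = %.3f fs; use a smaller dt",
           std::sqrt(max_d2), max_step_disp, t + h);

    if ((step + 1) % out_every == 0 || step + 1 == nstep) {
      double tn = (step + 1) * h;
      E.charges_at(tn);
      double kn = E.kappa_at(tn);
      if (E.need_rebuild(kn)) E.build_neighbours(kn);
      times_out.push_back(tn);
      ss_out.push_back(E.ss_dist(i1, i2));
      kin_out.push_back(E.kinetic());
      pot_out.push_back(E.potential(kn));
      if (store_positions)
        for (int i = 0; i < 3 * n; ++i) pos_frames.push_back(E.x[i]);
      ++nframes;
    }
    if (step % 256 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pf(n, 3), vf(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      pf(i, d) = E.x[3 * i + d];
      vf(i, d) = E.v[3 * i + d];
    }
  List out = List::create(
      _["times"] = NumericVector(times_out.begin(), times_out.end()),
      _["ss"] = NumericVector(ss_out.begin(), ss_out.end()),
      _["kinetic"] = NumericVector(kin_out.begin(), kin_out.end()),
      _["potential"] = NumericVector(pot_out.begin(), pot_out.end()),
      _["pos_final"] = pf, _["vel_final"] = vf,
      _["positions"] = R_NilValue);
  if (store_positions) {
    NumericVector arr(pos_frames.size());
    // reorder frame-major (frame, atom, coord) -> R array dim (nframes, n, 3)
    for (int f = 0; f < nframes; ++f)
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          arr[f + nframes * (i + (size_t)n * d)] =
              pos_frames[(size_t)f * 3 * n + 3 * i + d];
    arr.attr("dim") = IntegerVector::create(nframes, n, 3);
    out["positions"] = arr;
  }
  return out;
}
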