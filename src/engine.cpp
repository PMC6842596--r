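// Structure-based (Go-type) Hamiltonian evaluation and Langevin dynamics.
//
// Reduced units: energy in units of the contact well depth, length in
// Angstrom, all masses 1 by default, k_B = 1.  Functional forms:
//   bonds      V = k (r - r0)^2
//   angles     V = k (th - th0)^2
//   dihedrals  V = k [ (1 - cos(phi - phi0)) + 0.5 (1 - cos 3(phi - phi0)) ]
//   contacts   V = eps [ (s/r)^12 - 2 (s/r)^6 ]          (minimum -eps at r = s)
//   excl. vol. V = eps_ex [ (rx/r)^12 - 2 (rx/r)^6 + 1 ]  for r < rx, else 0
//   pulling    V = -f * x_ee          (constant force on the end-to-end distance)
//   wall       V = k_w (x_ee - x_w)^2 for x_ee > x_w, else 0
// The excluded-volume term is purely repulsive and C1-continuous at rx, so
// the native configuration (where all non-excluded non-contact pairs lie
// beyond rx) is an exact stationary point.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Breakdown {
  double bond = 0, angle = 0, dihedral = 0, contact = 0, excluded = 0,
         pulling = 0, wall = 0;
  double total() const {
    return bond + angle + dihedral + contact + excluded + pulling + wall;
  }
};

class Engine {
public:
  int n;
  std::vector<double> mass;
  // bonded terms
  std::vector<int> b_i, b_j;
  std::vector<double> b_r0, b_k;
  std::vector<int> a_i, a_j, a_k;
  std::vector<double> a_th0, a_kk;
  std::vector<int> d_i, d_j, d_k, d_l;
  std::vector<double> d_phi0, d_kk, d_c0, d_s0;
  std::vector<int> c_i, c_j;
  std::vector<double> c_sig, c_eps;
  // excluded volume
  double r_ex = 2.5, eps_ex = 1.0;
  std::vector<uint8_t> excl; // n*n exclusion map (bonded<=3 bonds or contact)
  std::vector<int> nl_i, nl_j; // neighbour list for the repulsive term
  // pulling
  int pull_a = -1, pull_b = -1;
  double f_pull = 0, wall_x = -1, wall_k = 0;

  bool excluded_pair(int i, int j) const { return excl[(size_t)i * n + j] != 0; }

  void build_neighbour_list(const std::vector<double>& x, double skin) {
    nl_i.clear();
    nl_j.clear();
    const double cut2 = (r_ex + skin) * (r_ex + skin);
    for (int i = 0; i < n; ++i) {
      const double xi = x[3 * i], yi = x[3 * i + 1], zi = x[3 * i + 2];
      for (int j = i + 1; j < n; ++j) {
        if (excluded_pair(i, j)) continue;
        const double dx = xi - x[3 * j], dy = yi - x[3 * j + 1],
                     dz = zi - x[3 * j + 2];
        if (dx * dx + dy * dy + dz * dz < cut2) {
          nl_i.push_back(i);
          nl_j.push_back(j);
        }
      }
    }
  }

  double end_to_end(const std::vector<double>& x) const {
    const double dx = x[3 * pull_a] - x[3 * pull_b],
                 dy = x[3 * pull_a + 1] - x[3 * pull_b + 1],
                 dz = x[3 * pull_a + 2] - x[3 * pull_b + 2];
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  }

  Breakdown forces(const std::vector<double>& x, std::vector<double>& f) const {
    Breakdown e;
    std::fill(f.begin(), f.end(), 0.0);

    // bonds
    for (size_t t = 0; t < b_i.size(); ++t) {
      const int i = b_i[t], j = b_j[t];
      double d[3], r2 = 0;
      for (int c = 0; c < 3; ++c) {
        d[c] = x[3 * i + c] - x[3 * j + c];
        r2 += d[c] * d[c];
      }
      const double r = std::sqrt(r2), dr = r - b_r0[t];
      e.bond += b_k[t] * dr * dr;
      const double fac = -2.0 * b_k[t] * dr / r;
      for (int c = 0; c < 3; ++c) {
        f[3 * i + c] += fac * d[c];
        f[3 * j + c] -= fac * d[c];
      }
    }

    // angles
    for (size_t t = 0; t < a_i.size(); ++t) {
      const int i = a_i[t], j = a_j[t], k = a_k[t];
      double rij[3], rkj[3], nij2 = 0, nkj2 = 0, dot = 0;
      for (int c = 0; c < 3; ++c) {
        rij[c] = x[3 * i + c] - x[3 * j + c];
        rkj[c] = x[3 * k + c] - x[3 * j + c];
        nij2 += rij[c] * rij[c];
        nkj2 += rkj[c] * rkj[c];
        dot += rij[c] * rkj[c];
      }
      const double nij = std::sqrt(nij2), nkj = std::sqrt(nkj2);
      double cs = dot / (nij * nkj);
      cs = std::max(-1.0, std::min(1.0, cs));
      const double th = std::acos(cs), dth = th - a_th0[t];
      e.angle += a_kk[t] * dth * dth;
      const double sn = std::sqrt(std::max(1e-12, 1.0 - cs * cs));
      const double coef = 2.0 * a_kk[t] * dth / sn; // -dV/dcos * dcos...
      for (int c = 0; c < 3; ++c) {
        const double di = (rkj[c] / (nij * nkj) - cs * rij[c] / nij2);
        const double dk = (rij[c] / (nij * nkj) - cs * rkj[c] / nkj2);
        f[3 * i + c] += coef * di;
        f[3 * k + c] += coef * dk;
        f[3 * j + c] -= coef * (di + dk);
      }
    }

    // dihedrals
    for (size_t t = 0; t < d_i.size(); ++t) {
      const int i = d_i[t], j = d_j[t], k = d_k[t], l = d_l[t];
      double b1[3], b2[3], b3[3];
      for (int c = 0; c < 3; ++c) {
        b1[c] = x[3 * j + c] - x[3 * i + c];
        b2[c] = x[3 * k + c] - x[3 * j + c];
        b3[c] = x[3 * l + c] - x[3 * k + c];
      }
      double n1[3], n2[3];
      n1[0] = b1[1] * b2[2] - b1[2] * b2[1];
      n1[1] = b1[2] * b2[0] - b1[0] * b2[2];
      n1[2] = b1[0] * b2[1] - b1[1] * b2[0];
      n2[0] = b2[1] * b3[2] - b2[2] * b3[1];
      n2[1] = b2[2] * b3[0] - b2[0] * b3[2];
      n2[2] = b2[0] * b3[1] - b2[1] * b3[0];
      const double n1s = n1[0] * n1[0] + n1[1] * n1[1] + n1[2] * n1[2];
      const double n2s = n2[0] * n2[0] + n2[1] * n2[1] + n2[2] * n2[2];
      const double b2n = std::sqrt(b2[0] * b2[0] + b2[1] * b2[1] + b2[2] * b2[2]);
      double m1[3];
      m1[0] = n1[1] * n2[2] - n1[2] * n2[1];
      m1[1] = n1[2] * n2[0] - n1[0] * n2[2];
      m1[2] = n1[0] * n2[1] - n1[1] * n2[0];
      // cos/sin of (phi - phi0) by angle addition: no transcendentals
      const double inv = 1.0 / std::sqrt(n1s * n2s);
      const double cp = (n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2]) * inv;
      const double sp =
          (m1[0] * b2[0] + m1[1] * b2[1] + m1[2] * b2[2]) / b2n * inv;
      const double cd = cp * d_c0[t] + sp * d_s0[t];
      const double sd = sp * d_c0[t] - cp * d_s0[t];
      const double c3 = 4 * cd * cd * cd - 3 * cd;  // cos 3(phi-phi0)
      const double s3 = 3 * sd - 4 * sd * sd * sd;  // sin 3(phi-phi0)
      e.dihedral += d_kk[t] * ((1 - cd) + 0.5 * (1 - c3));
      const double dV = d_kk[t] * (sd + 1.5 * s3); // dV/dphi
      double fi[3], fl[3];
      for (int c = 0; c < 3; ++c) {
        fi[c] = dV * b2n / n1s * n1[c];
        fl[c] = -dV * b2n / n2s * n2[c];
      }
      const double tb = (b1[0] * b2[0] + b1[1] * b2[1] + b1[2] * b2[2]) / (b2n * b2n);
      const double sb = (b3[0] * b2[0] + b3[1] * b2[1] + b3[2] * b2[2]) / (b2n * b2n);
      for (int c = 0; c < 3; ++c) {
        const double fj = -(1.0 + tb) * fi[c] + sb * fl[c];
        const double fk = tb * fi[c] - (1.0 + sb) * fl[c];
        f[3 * i + c] += fi[c];
        f[3 * j + c] += fj;
        f[3 * k + c] += fk;
        f[3 * l + c] += fl[c];
      }
    }

    // native contacts (12-6 with minimum at sigma)
    for (size_t t = 0; t < c_i.size(); ++t) {
      const int i = c_i[t], j = c_j[t];
      double d[3], r2 = 0;
      for (int c = 0; c < 3; ++c) {
        d[c] = x[3 * i + c] - x[3 * j + c];
        r2 += d[c] * d[c];
      }
      const double s2 = c_sig[t] * c_sig[t] / r2;
      const double s6 = s2 * s2 * s2, s12 = s6 * s6;
      e.contact += c_eps[t] * (s12 - 2.0 * s6);
      const double fac = 12.0 * c_eps[t] * (s12 - s6) / r2; // -dV/dr / r
      for (int c = 0; c < 3; ++c) {
        f[3 * i + c] += fac * d[c];
        f[3 * j + c] -= fac * d[c];
      }
    }

    // excluded volume (repulsive, zero beyond r_ex)
    const double rx2 = r_ex * r_ex;
    for (size_t t = 0; t < nl_i.size(); ++t) {
      const int i = nl_i[t], j = nl_j[t];
      double d[3], r2 = 0;
      for (int c = 0; c < 3; ++c) {
        d[c] = x[3 * i + c] - x[3 * j + c];
        r2 += d[c] * d[c];
      }
      if (r2 >= rx2) continue;
      const double s2 = rx2 / r2;
      const double s6 = s2 * s2 * s2, s12 = s6 * s6;
      e.excluded += eps_ex * (s12 - 2.0 * s6 + 1.0);
      const double fac = 12.0 * eps_ex * (s12 - s6) / r2;
      for (int c = 0; c < 3; ++c) {
        f[3 * i + c] += fac * d[c];
        f[3 * j + c] -= fac * d[c];
      }
    }

    // constant pulling force and confining wall on the end-to-end distance
    if (pull_a >= 0 && (f_pull != 0.0 || wall_k > 0)) {
      double d[3], r2 = 0;
      for (int c = 0; c < 3; ++c) {
        d[c] = x[3 * pull_a + c] - x[3 * pull_b + c];
        r2 += d[c] * d[c];
      }
      const double r = std::sqrt(r2);
      e.pulling = -f_pull * r;
      double fr = f_pull; // -dV/dr
      if (wall_k > 0 && wall_x > 0 && r > wall_x) {
        const double dr = r - wall_x;
        e.wall = wall_k * dr * dr;
        fr -= 2.0 * wall_k * dr;
      }
      for (int c = 0; c < 3; ++c) {
        f[3 * pull_a + c] += fr * d[c] / r;
        f[3 * pull_b + c] -= fr * d[c] / r;
      }
    }
    return e;
  }
};

Engine parse_topology(const List& topo, double f_pull, double wall_x,
                      double wall_k) {
  Engine E;
  E.n = as<int>(topo["n_atoms"]);
  E.mass = as<std::vector<double>>(topo["masses"]);
  auto getmat = [&](const char* nm) { return as<IntegerMatrix>(topo[nm]); };
  IntegerMatrix B = getmat("bond_atoms");
  NumericMatrix Bp = as<NumericMatrix>(topo["bond_params"]);
  for (int t = 0; t < B.nrow(); ++t) {
    E.b_i.push_back(B(t, 0) - 1);
    E.b_j.push_back(B(t, 1) - 1);
    E.b_r0.push_back(Bp(t, 0));
    E.b_k.push_back(Bp(t, 1));
  }
  IntegerMatrix A = getmat("angle_atoms");
  NumericMatrix Ap = as<NumericMatrix>(topo["angle_params"]);
  for (int t = 0; t < A.nrow(); ++t) {
    E.a_i.push_back(A(t, 0) - 1);
    E.a_j.push_back(A(t, 1) - 1);
    E.a_k.push_back(A(t, 2) - 1);
    E.a_th0.push_back(Ap(t, 0));
    E.a_kk.push_back(Ap(t, 1));
  }
  IntegerMatrix D = getmat("dihedral_atoms");
  NumericMatrix Dp = as<NumericMatrix>(topo["dihedral_params"]);
  for (int t = 0; t < D.nrow(); ++t) {
    E.d_i.push_back(D(t, 0) - 1);
    E.d_j.push_back(D(t, 1) - 1);
    E.d_k.push_back(D(t, 2) - 1);
    E.d_l.push_back(D(t, 3) - 1);
    E.d_phi0.push_back(Dp(t, 0));
    E.d_kk.push_back(Dp(t, 1));
    E.d_c0.push_back(std::cos(Dp(t, 0)));
    E.d_s0.push_back(std::sin(Dp(t, 0)));
  }
  IntegerMatrix C = getmat("contact_atoms");
  NumericMatrix Cp = as<NumericMatrix>(topo["contact_params"]);
  for (int t = 0; t < C.nrow(); ++t) {
    E.c_i.push_back(C(t, 0) - 1);
    E.c_j.push_back(C(t, 1) - 1);
    E.c_sig.push_back(Cp(t, 0));
    E.c_eps.push_back(Cp(t, 1));
  }
  E.r_ex = as<double>(topo["r_ex"]);
  E.eps_ex = as<double>(topo["eps_ex"]);
  E.excl.assign((size_t)E.n * E.n, 0);
  IntegerMatrix X = getmat("excluded_pairs");
  for (int t = 0; t < X.nrow(); ++t) {
    const int i = X(t, 0) - 1, j = X(t, 1) - 1;
    E.excl[(size_t)i * E.n + j] = 1;
    E.excl[(size_t)j * E.n + i] = 1;
  }
  IntegerVector pp = topo["pull_pair"];
  E.pull_a = pp[0] - 1;
  E.pull_b = pp[1] - 1;
  E.f_pull = f_pull;
  E.wall_x = wall_x;
  E.wall_k = wall_k;
  return E;
}

List breakdown_list(const Breakdown& e) {
  return List::create(
      _["bond"] = e.bond, _["angle"] = e.angle, _["dihedral"] = e.dihedral,
      _["contact"] = e.contact, _["excluded"] = e.excluded,
      _["pulling"] = e.pulling, _["wall"] = e.wall, _["total"] = e.total());
}

// Deterministic, platform-independent normal deviates (Box-Muller on a
// 64-bit Mersenne Twister); the spare deviate is cached.
struct Gauss {
  std::mt19937_64 rng;
  bool have = false;
  double spare = 0;
  explicit Gauss(uint64_t seed) : rng(seed) {}
  double unif() {
    return (rng() >> 11) * (1.0 / 9007199254740992.0); // [0,1)
  }
  double operator()() {
    if (have) {
      have = false;
      return spare;
    }
    double u1 = unif(), u2 = unif();
    while (u1 <= 1e-300) u1 = unif();
    const double r = std::sqrt(-2.0 * std::log(u1)), a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    have = true;
    return r * std::cos(a);
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_energy_forces(List topo, NumericMatrix xyz, double f_pull,
                       double wall_x, double wall_k) {
  Engine E = parse_topology(topo, f_pull, wall_x, wall_k);
  std::vector<double> x(3 * E.n), f(3 * E.n);
  for (int i = 0; i < E.n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = xyz(i, c);
  E.build_neighbour_list(x, 0.0);
  Breakdown e = E.forces(x, f);
  NumericMatrix fm(E.n, 3);
  for (int i = 0; i < E.n; ++i)
    for (int c = 0; c < 3; ++c) fm(i, c) = f[3 * i + c];
  return List::create(_["energy"] = breakdown_list(e), _["forces"] = fm);
}

// [[Rcpp::export]]
List cpp_run(List topo, NumericMatrix xyz0, Nullable<NumericMatrix> v0_,
             double dt, double gamma, double temp, double n_steps_d,
             int save_stride, int frame_stride, double seed, double f_pull,
             double wall_x, double wall_k, bool channels,
             List channel_spec) {
  Engine E = parse_topology(topo, f_pull, wall_x, wall_k);
  const long long n_steps = (long long)n_steps_d;
  const int n = E.n;
  std::vector<double> x(3 * n), v(3 * n, 0.0), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3 * i + c] = xyz0(i, c);

  Gauss g((uint64_t)seed);
  if (v0_.isNotNull()) {
    NumericMatrix v0(v0_);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) v[3 * i + c] = v0(i, c);
  } else if (temp > 0) {
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c)
        v[3 * i + c] = std::sqrt(temp / E.mass[i]) * g();
  }

  // channel bookkeeping
  IntegerMatrix wc;
  std::vector<int> grp_ptr, grp_idx;
  int npair = 0;
  if (channels) {
    wc = as<IntegerMatrix>(channel_spec["wc_pairs"]);
    npair = wc.nrow();
    grp_ptr = as<std::vector<int>>(channel_spec["group_ptr"]);
    grp_idx = as<std::vector<int>>(channel_spec["group_idx"]);
  }
  auto centroid = [&](int gi, double* out) {
    out[0] = out[1] = out[2] = 0;
    const int a = grp_ptr[gi], b = grp_ptr[gi + 1];
    for (int t = a; t < b; ++t) {
      const int at = grp_idx[t] - 1;
      for (int c = 0; c < 3; ++c) out[c] += x[3 * at + c];
    }
    for (int c = 0; c < 3; ++c) out[c] /= (b - a);
  };

  const long long n_save = n_steps / save_stride;
  NumericVector xs(n_save), ep(n_save), ek(n_save);
  const int nchan = channels ? npair + 2 * (npair - 1) : 0;
  NumericMatrix chan(channels ? n_save : 0, nchan);
  const long long n_frames = frame_stride > 0 ? n_steps / frame_stride : 0;
  NumericVector frames(n_frames * 3 * n);

  const double c1 = gamma > 0 ? std::exp(-gamma * dt) : 1.0;
  const double c2 = gamma > 0 ? std::sqrt(1.0 - c1 * c1) : 0.0;
  const double skin = 1.0;
  const int nl_every = 20;

  E.build_neighbour_list(x, skin);
  Breakdown e = E.forces(x, f);
  long long isave = 0, iframe = 0;

  for (long long step = 1; step <= n_steps; ++step) {
    // BAOAB splitting (reduces to velocity Verlet when gamma = 0)
    for (int i = 0; i < n; ++i) {
      const double h = 0.5 * dt / E.mass[i];
      for (int c = 0; c < 3; ++c) v[3 * i + c] += h * f[3 * i + c];
    }
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    if (gamma > 0 && temp >= 0) {
      for (int i = 0; i < n; ++i) {
        const double s = std::sqrt(temp / E.mass[i]);
        for (int c = 0; c < 3; ++c)
          v[3 * i + c] = c1 * v[3 * i + c] + c2 * s * g();
      }
    }
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    if (step % nl_every == 0) E.build_neighbour_list(x, skin);
    e = E.forces(x, f);
    for (int i = 0; i < n; ++i) {
      const double h = 0.5 * dt / E.mass[i];
      for (int c = 0; c < 3; ++c) v[3 * i + c] += h * f[3 * i + c];
    }

    if (step % save_stride == 0) {
      double ke = 0;
      for (int i = 0; i < n; ++i) {
        double s = 0;
        for (int c = 0; c < 3; ++c) s += v[3 * i + c] * v[3 * i + c];
        ke += 0.5 * E.mass[i] * s;
      }
      const double pot = e.total();
      if (!std::isfinite(pot) || pot > 1e10) {
        stop("numerical blow-up at step %lld (potential energy %g)",
             step, pot);
      }
      xs[isave] = E.end_to_end(x);
      ep[isave] = pot;
      ek[isave] = ke;
      if (channels) {
        for (int p = 0; p < npair; ++p) {
          const int ia = wc(p, 0) - 1, ib = wc(p, 1) - 1;
          double r2 = 0;
          for (int c = 0; c < 3; ++c) {
            const double d = x[3 * ia + c] - x[3 * ib + c];
            r2 += d * d;
          }
          chan(isave, p) = std::sqrt(r2);
        }
        double ca[3], cb[3];
        for (int k = 0; k < npair - 1; ++k) {
          centroid(k, ca);
          centroid(k + 1, cb);
          double r2 = 0;
          for (int c = 0; c < 3; ++c) r2 += (ca[c] - cb[c]) * (ca[c] - cb[c]);
          chan(isave, npair + k) = std::sqrt(r2);
          centroid(npair + (npair - k) - 1, ca); // chain B residue npair-k
          centroid(npair + (npair - k) - 2, cb); // chain B residue npair-k-1
          r2 = 0;
          for (int c = 0; c < 3; ++c) r2 += (ca[c] - cb[c]) * (ca[c] - cb[c]);
          chan(isave, 2 * npair - 1 + k) = std::sqrt(r2);
        }
      }
      ++isave;
    }
    if (frame_stride > 0 && step % frame_stride == 0) {
      for (int i = 0; i < 3 * n; ++i) frames[iframe * 3 * n + i] = x[i];
      ++iframe;
    }
  }

  NumericMatrix xyz_final(n, 3), v_final(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      xyz_final(i, c) = x[3 * i + c];
      v_final(i, c) = v[3 * i + c];
    }
  return List::create(
      _["x_series"] = xs, _["epot"] = ep, _["ekin"] = ek,
      _["channels"] = chan, _["frames"] = frames,
      _["xyz_final"] = xyz_final, _["v_final"] = v_final);
}
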