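// Core numerical routines: contact search, Shrake-Rupley SASA, Kabsch
// RMSD, and the Metropolis Monte Carlo engine (native-state sampling and
// constant-force pulling) over a native-contact (Go-type) potential with
// a backbone-RMSD restraint.
//
// Conventions: energies kcal/mol, distances Angstrom. Randomness comes
// from R's RNG (RNGScope via Rcpp attributes), so runs are reproducible
// with set.seed() on the R side.

#include <RcppArmadillo.h>
#include <unordered_set>
#include <map>
#include <vector>
#include <algorithm>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double sqr(double x) { return x * x; }

// Minimum-image squared distance between rows a and b of X.
static inline double dist2_mi(const arma::mat& X, int a, int b,
                              double box, bool periodic) {
  double s = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = X(a, k) - X(b, k);
    if (periodic) d -= box * std::round(d / box);
    s += d * d;
  }
  return s;
}

static inline double dist2_plain(const arma::mat& X, int a, int b) {
  double s = 0.0;
  for (int k = 0; k < 3; ++k) s += sqr(X(a, k) - X(b, k));
  return s;
}

// ---------------------------------------------------------------------
// Residue-level inter-monomer contacts via a cell list.
// Returns one row per residue pair with min heavy-atom distance <= cutoff.
// [[Rcpp::export]]
DataFrame cpp_contact_pairs(const arma::mat& xyz_a, const IntegerVector& res_a,
                            const arma::mat& xyz_b, const IntegerVector& res_b,
                            double cutoff) {
  const int na = xyz_a.n_rows, nb = xyz_b.n_rows;
  const double c2 = cutoff * cutoff;
  // bounding box over B atoms, cell size = cutoff
  arma::rowvec lo = arma::min(xyz_b, 0), hi = arma::max(xyz_b, 0);
  int nx = std::max(1, (int)std::floor((hi(0) - lo(0)) / cutoff) + 1);
  int ny = std::max(1, (int)std::floor((hi(1) - lo(1)) / cutoff) + 1);
  int nz = std::max(1, (int)std::floor((hi(2) - lo(2)) / cutoff) + 1);
  std::vector<std::vector<int>> cells((size_t)nx * ny * nz);
  auto cell_of = [&](double x, double y, double z, int& cx, int& cy, int& cz) {
    cx = std::min(nx - 1, std::max(0, (int)std::floor((x - lo(0)) / cutoff)));
    cy = std::min(ny - 1, std::max(0, (int)std::floor((y - lo(1)) / cutoff)));
    cz = std::min(nz - 1, std::max(0, (int)std::floor((z - lo(2)) / cutoff)));
  };
  for (int j = 0; j < nb; ++j) {
    int cx, cy, cz;
    cell_of(xyz_b(j, 0), xyz_b(j, 1), xyz_b(j, 2), cx, cy, cz);
    cells[(size_t)(cx * ny + cy) * nz + cz].push_back(j);
  }
  std::map<std::pair<int, int>, double> best;
  for (int i = 0; i < na; ++i) {
    int cx, cy, cz;
    cell_of(xyz_a(i, 0), xyz_a(i, 1), xyz_a(i, 2), cx, cy, cz);
    for (int dx = -1; dx <= 1; ++dx) {
      int ux = cx + dx; if (ux < 0 || ux >= nx) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int uy = cy + dy; if (uy < 0 || uy >= ny) continue;
        for (int dz = -1; dz <= 1; ++dz) {
          int uz = cz + dz; if (uz < 0 || uz >= nz) continue;
          for (int j : cells[(size_t)(ux * ny + uy) * nz + uz]) {
            double d2 = sqr(xyz_a(i, 0) - xyz_b(j, 0)) +
                        sqr(xyz_a(i, 1) - xyz_b(j, 1)) +
                        sqr(xyz_a(i, 2) - xyz_b(j, 2));
            if (d2 <= c2) {
              auto key = std::make_pair(res_a[i], res_b[j]);
              auto it = best.find(key);
              if (it == best.end() || d2 < it->second) best[key] = d2;
            }
          }
        }
      }
    }
  }
  int n = best.size();
  IntegerVector ra(n), rb(n);
  NumericVector md(n);
  int k = 0;
  for (auto& kv : best) {
    ra[k] = kv.first.first;
    rb[k] = kv.first.second;
    md[k] = std::sqrt(kv.second);
    ++k;
  }
  return DataFrame::create(_["res_a"] = ra, _["res_b"] = rb,
                           _["min_dist"] = md);
}

// All atom pairs (i < j) within cutoff; plain O(n^2), used for building
// native-contact lists on reference structures.
// [[Rcpp::export]]
DataFrame cpp_pairs_within(const arma::mat& xyz, double cutoff) {
  const int n = xyz.n_rows;
  const double c2 = cutoff * cutoff;
  std::vector<int> vi, vj;
  std::vector<double> vd;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d2 = dist2_plain(xyz, i, j);
      if (d2 <= c2) {
        vi.push_back(i + 1);
        vj.push_back(j + 1);
        vd.push_back(std::sqrt(d2));
      }
    }
  return DataFrame::create(_["i"] = vi, _["j"] = vj, _["dist"] = vd);
}

// ---------------------------------------------------------------------
// Shrake-Rupley SASA: golden-spiral quadrature points on each atom's
// solvent-expanded sphere, occlusion tested against neighbours.
// [[Rcpp::export]]
NumericVector cpp_sasa(const arma::mat& xyz, const NumericVector& radii,
                       double probe, int n_points) {
  const int n = xyz.n_rows;
  // golden-spiral points on unit sphere
  arma::mat pts(n_points, 3);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * k;
    pts(k, 0) = r * std::cos(th);
    pts(k, 1) = r * std::sin(th);
    pts(k, 2) = z;
  }
  NumericVector area(n);
  std::vector<double> er(n);
  for (int i = 0; i < n; ++i) er[i] = radii[i] + probe;
  for (int i = 0; i < n; ++i) {
    // neighbours that can occlude i
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (dist2_plain(xyz, i, j) < sqr(er[i] + er[j])) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double px = xyz(i, 0) + er[i] * pts(k, 0);
      double py = xyz(i, 1) + er[i] * pts(k, 1);
      double pz = xyz(i, 2) + er[i] * pts(k, 2);
      bool buried = false;
      for (int j : nb) {
        double d2 = sqr(px - xyz(j, 0)) + sqr(py - xyz(j, 1)) +
                    sqr(pz - xyz(j, 2));
        if (d2 < sqr(er[j])) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * er[i] * er[i] * acc / n_points;
  }
  return area;
}

// ---------------------------------------------------------------------
// Kabsch minimum RMSD after optimal rigid superposition.
static double kabsch_rmsd_cpp(const arma::mat& A, const arma::mat& B) {
  arma::rowvec ca = arma::mean(A, 0), cb = arma::mean(B, 0);
  arma::mat Ac = A.each_row() - ca;
  arma::mat Bc = B.each_row() - cb;
  arma::mat H = Ac.t() * Bc;
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(V * U.t()) < 0 ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = d;
  arma::mat R = V * D * U.t();
  arma::mat diff = Bc - Ac * R.t();
  return std::sqrt(arma::accu(diff % diff) / A.n_rows);
}

// [[Rcpp::export]]
double cpp_kabsch_rmsd(const arma::mat& A, const arma::mat& B) {
  return kabsch_rmsd_cpp(A, B);
}

// ---------------------------------------------------------------------
// MC engine.

struct Model {
  arma::mat ref;                 // reference coords (n x 3)
  arma::imat contacts;           // native contacts: site_i, site_j (0-based)
  arma::vec r0, eps;             // per-contact reference distance, depth
  std::vector<std::vector<int>> cpartner;   // contact ids per site
  std::vector<char> cmat;        // flat n x n native-pair lookup
  int n_sites;
  std::vector<int> mono;         // 0/1 per site
  std::vector<int> bbA, bbB;     // backbone site ids per monomer
  double sigma, eps_rep, ev_cut2;
  double k_rmsd;
  double f_kcal;                 // signed pulling prefactor, kcal/mol/A
  int anchor1, anchor2;
  double box;
  bool periodic;
  bool is_native(int a, int b) const { return cmat[(size_t)a * n_sites + b]; }
};

// Largest eigenvalue of a symmetric 4x4 via Jacobi rotations.
static double max_eig4(double K[4][4]) {
  double scale = 0.0;
  for (int p = 0; p < 4; ++p)
    for (int q = 0; q < 4; ++q) scale += K[p][q] * K[p][q];
  const double tol = 1e-28 * std::max(1.0, scale);
  for (int sweep = 0; sweep < 60; ++sweep) {
    double off = 0.0;
    for (int p = 0; p < 3; ++p)
      for (int q = p + 1; q < 4; ++q) off += K[p][q] * K[p][q];
    if (off < tol) break;
    for (int p = 0; p < 3; ++p)
      for (int q = p + 1; q < 4; ++q) {
        if (std::fabs(K[p][q]) < 1e-18) continue;
        double theta = (K[q][q] - K[p][p]) / (2.0 * K[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < 4; ++k) {
          double kp = K[k][p], kq = K[k][q];
          K[k][p] = c * kp - s * kq;
          K[k][q] = s * kp + c * kq;
        }
        for (int k = 0; k < 4; ++k) {
          double pk = K[p][k], qk = K[q][k];
          K[p][k] = c * pk - s * qk;
          K[q][k] = s * pk + c * qk;
        }
      }
  }
  double m = K[0][0];
  for (int k = 1; k < 4; ++k) m = std::max(m, K[k][k]);
  return m;
}

// Minimum RMSD over proper rotations (quaternion method), matched sets
// given as site index lists into ref (A) and current coords (B).
static double qcp_rmsd(const arma::mat& A, const arma::mat& B,
                       const std::vector<int>& idx) {
  const int n = idx.size();
  double ca[3] = {0, 0, 0}, cb[3] = {0, 0, 0};
  for (int k = 0; k < n; ++k) {
    for (int d = 0; d < 3; ++d) {
      ca[d] += A(idx[k], d);
      cb[d] += B(idx[k], d);
    }
  }
  for (int d = 0; d < 3; ++d) { ca[d] /= n; cb[d] /= n; }
  double S[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  double GA = 0, GB = 0;
  for (int k = 0; k < n; ++k) {
    double a[3], b[3];
    for (int d = 0; d < 3; ++d) {
      a[d] = A(idx[k], d) - ca[d];
      b[d] = B(idx[k], d) - cb[d];
      GA += a[d] * a[d];
      GB += b[d] * b[d];
    }
    for (int p = 0; p < 3; ++p)
      for (int q = 0; q < 3; ++q) S[p][q] += a[p] * b[q];
  }
  double K[4][4] = {
    {S[0][0] + S[1][1] + S[2][2], S[1][2] - S[2][1],
     S[2][0] - S[0][2], S[0][1] - S[1][0]},
    {S[1][2] - S[2][1], S[0][0] - S[1][1] - S[2][2],
     S[0][1] + S[1][0], S[2][0] + S[0][2]},
    {S[2][0] - S[0][2], S[0][1] + S[1][0],
     -S[0][0] + S[1][1] - S[2][2], S[1][2] + S[2][1]},
    {S[0][1] - S[1][0], S[2][0] + S[0][2],
     S[1][2] + S[2][1], -S[0][0] - S[1][1] + S[2][2]}};
  double lmax = max_eig4(K);
  double msd = (GA + GB - 2.0 * lmax) / n;
  return std::sqrt(std::max(0.0, msd));
}

static inline double go_well(double r2, double r0, double eps) {
  // 12-10 native well, minimum -eps at r = r0
  double q2 = r0 * r0 / r2;
  double q10 = q2 * q2 * q2 * q2 * q2;
  double q12 = q10 * q2;
  return eps * (5.0 * q12 - 6.0 * q10);
}

static inline double pair_energy(const Model& m, const arma::mat& X,
                                 int a, int b, bool native, int cid) {
  bool cross = m.mono[a] != m.mono[b];
  double d2 = cross ? dist2_mi(X, a, b, m.box, m.periodic)
                    : dist2_plain(X, a, b);
  if (native) return go_well(d2, m.r0[cid], m.eps[cid]);
  if (d2 >= m.ev_cut2) return 0.0;
  double q2 = m.sigma * m.sigma / d2;
  double q6 = q2 * q2 * q2;
  return m.eps_rep * q6 * q6;
}

static double rmsd_monomer(const Model& m, const arma::mat& X, int mono) {
  const std::vector<int>& bb = (mono == 0) ? m.bbA : m.bbB;
  return qcp_rmsd(m.ref, X, bb);
}

static double anchor_dist(const Model& m, const arma::mat& X) {
  return std::sqrt(dist2_mi(X, m.anchor1, m.anchor2, m.box, m.periodic));
}

// Full energy decomposition: contact, excluded-volume, restraint, pull.
static arma::vec full_energy(const Model& m, const arma::mat& X,
                             double& rmsdA, double& rmsdB) {
  const int n = X.n_rows;
  double e_con = 0.0, e_ev = 0.0;
  for (arma::uword c = 0; c < m.contacts.n_rows; ++c)
    e_con += pair_energy(m, X, m.contacts(c, 0), m.contacts(c, 1), true, c);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (m.is_native(i, j)) continue;
      e_ev += pair_energy(m, X, i, j, false, -1);
    }
  rmsdA = rmsd_monomer(m, X, 0);
  rmsdB = rmsd_monomer(m, X, 1);
  double e_rmsd = m.k_rmsd * (rmsdA + rmsdB);
  double e_pull = m.f_kcal * anchor_dist(m, X);
  arma::vec out(4);
  out(0) = e_con; out(1) = e_ev; out(2) = e_rmsd; out(3) = e_pull;
  return out;
}

// Energy of all pair terms involving one site.
static double site_energy(const Model& m, const arma::mat& X, int s) {
  double e = 0.0;
  for (int cid : m.cpartner[s])
    e += pair_energy(m, X, m.contacts(cid, 0), m.contacts(cid, 1), true, cid);
  const int n = X.n_rows;
  for (int j = 0; j < n; ++j) {
    if (j == s || m.is_native(s, j)) continue;
    e += pair_energy(m, X, s, j, false, -1);
  }
  return e;
}

// Inter-monomer pair energy (contacts + ev across the interface).
static double cross_energy(const Model& m, const arma::mat& X) {
  double e = 0.0;
  for (arma::uword c = 0; c < m.contacts.n_rows; ++c) {
    int a = m.contacts(c, 0), b = m.contacts(c, 1);
    if (m.mono[a] != m.mono[b]) e += pair_energy(m, X, a, b, true, c);
  }
  const int n = X.n_rows;
  for (int i = 0; i < n; ++i) {
    if (m.mono[i] != 0) continue;
    for (int j = 0; j < n; ++j) {
      if (m.mono[j] != 1 || m.is_native(i, j)) continue;
      e += pair_energy(m, X, i, j, false, -1);
    }
  }
  return e;
}

static Model build_model(const List& model) {
  Model m;
  m.ref = as<arma::mat>(model["ref_coords"]);
  arma::imat con = as<arma::imat>(model["contact_sites"]); // 1-based
  m.contacts = con - 1;
  m.r0 = as<arma::vec>(model["contact_r0"]);
  m.eps = as<arma::vec>(model["contact_eps"]);
  IntegerVector mono = model["site_monomer"];   // 0/1
  LogicalVector bb = model["site_backbone"];
  const int n = m.ref.n_rows;
  m.mono.assign(mono.begin(), mono.end());
  m.n_sites = n;
  m.cpartner.resize(n);
  m.cmat.assign((size_t)n * n, 0);
  for (arma::uword c = 0; c < m.contacts.n_rows; ++c) {
    int a = m.contacts(c, 0), b = m.contacts(c, 1);
    m.cpartner[a].push_back(c);
    m.cpartner[b].push_back(c);
    m.cmat[(size_t)a * n + b] = 1;
    m.cmat[(size_t)b * n + a] = 1;
  }
  for (int i = 0; i < n; ++i) {
    if (bb[i]) {
      if (m.mono[i] == 0) m.bbA.push_back(i); else m.bbB.push_back(i);
    }
  }
  m.sigma = as<double>(model["ev_sigma"]);
  m.eps_rep = as<double>(model["ev_strength"]);
  m.ev_cut2 = sqr(2.5 * m.sigma);
  m.k_rmsd = as<double>(model["k_rmsd"]);
  m.f_kcal = as<double>(model["pull_prefactor"]);
  IntegerVector anch = model["anchor_sites"]; // 1-based
  m.anchor1 = anch[0] - 1;
  m.anchor2 = anch[1] - 1;
  m.box = as<double>(model["box_side"]);
  m.periodic = as<bool>(model["periodic"]);
  return m;
}

// [[Rcpp::export]]
List cpp_full_energy(const List& model, const arma::mat& coords) {
  Model m = build_model(model);
  double ra, rb;
  arma::vec e = full_energy(m, coords, ra, rb);
  return List::create(_["contact"] = e(0), _["excluded_volume"] = e(1),
                      _["restraint"] = e(2), _["pulling"] = e(3),
                      _["total"] = arma::accu(e),
                      _["rmsd_a"] = ra, _["rmsd_b"] = rb,
                      _["d_ca"] = anchor_dist(m, coords));
}

// Random unit vector (Marsaglia) using R's RNG.
static void rand_axis(double& x, double& y, double& z) {
  double s = 2.0;
  double a = 0, b = 0;
  while (s >= 1.0 || s == 0.0) {
    a = 2.0 * unif_rand() - 1.0;
    b = 2.0 * unif_rand() - 1.0;
    s = a * a + b * b;
  }
  double t = 2.0 * std::sqrt(1.0 - s);
  x = a * t;
  y = b * t;
  z = 1.0 - 2.0 * s;
}

// [[Rcpp::export]]
List cpp_run_mc(const List& model, const arma::mat& start,
                double kT, int n_cycles,
                const IntegerVector& snapshot_cycles,
                int dca_stride, double d_threshold, int stop_margin,
                double amp_site, double amp_trans, double amp_rot,
                int check_stride) {
  Model m = build_model(model);
  arma::mat X = start;
  const int n = X.n_rows;
  double rmsdA, rmsdB;
  double e_total = arma::accu(full_energy(m, X, rmsdA, rmsdB));

  std::vector<int> monoSites[2];
  for (int i = 0; i < n; ++i) monoSites[m.mono[i]].push_back(i);

  // snapshot bookkeeping
  std::unordered_set<int> snap_at(snapshot_cycles.begin(),
                                  snapshot_cycles.end());
  List snapshots(snapshot_cycles.size());
  IntegerVector snap_cycle(snapshot_cycles.size());
  int snap_k = 0;

  std::vector<int> dca_cycles;
  std::vector<double> dca_vals, dca_etot;
  std::vector<double> drift;            // |incremental - full| checkpoints
  long acc_site = 0, try_site = 0, acc_rigid = 0, try_rigid = 0;
  int t_dis = -1;
  int stop_at = n_cycles;

  arma::rowvec backup(3);
  arma::mat mono_backup;

  for (int cycle = 1; cycle <= stop_at; ++cycle) {
    // one attempted move per degree of freedom: every site once, plus
    // 4 rigid-body slots (translation + rotation per monomer).
    for (int s = 0; s < n; ++s) {
      ++try_site;
      double e_old = site_energy(m, X, s);
      bool is_bb = (m.mono[s] == 0)
        ? std::binary_search(m.bbA.begin(), m.bbA.end(), s)
        : std::binary_search(m.bbB.begin(), m.bbB.end(), s);
      bool is_anchor = (s == m.anchor1 || s == m.anchor2);
      double r_old = is_bb ? ((m.mono[s] == 0) ? rmsdA : rmsdB) : 0.0;
      double pull_old = is_anchor ? m.f_kcal * anchor_dist(m, X) : 0.0;
      backup = X.row(s);
      X(s, 0) += amp_site * (2.0 * unif_rand() - 1.0);
      X(s, 1) += amp_site * (2.0 * unif_rand() - 1.0);
      X(s, 2) += amp_site * (2.0 * unif_rand() - 1.0);
      double e_new = site_energy(m, X, s);
      double r_new = is_bb ? rmsd_monomer(m, X, m.mono[s]) : 0.0;
      double pull_new = is_anchor ? m.f_kcal * anchor_dist(m, X) : 0.0;
      double dE = (e_new - e_old) + m.k_rmsd * (r_new - r_old) +
                  (pull_new - pull_old);
      if (std::isfinite(dE) && (dE <= 0.0 || unif_rand() < std::exp(-dE / kT))) {
        ++acc_site;
        e_total += dE;
        if (is_bb) { if (m.mono[s] == 0) rmsdA = r_new; else rmsdB = r_new; }
      } else {
        X.row(s) = backup;
      }
    }
    for (int slot = 0; slot < 4; ++slot) {
      ++try_rigid;
      int mono = slot % 2;
      const std::vector<int>& sites = monoSites[mono];
      double e_old = cross_energy(m, X) + m.f_kcal * anchor_dist(m, X);
      mono_backup.set_size(sites.size(), 3);
      for (size_t k = 0; k < sites.size(); ++k)
        mono_backup.row(k) = X.row(sites[k]);
      if (slot < 2) {
        double dx = amp_trans * (2.0 * unif_rand() - 1.0);
        double dy = amp_trans * (2.0 * unif_rand() - 1.0);
        double dz = amp_trans * (2.0 * unif_rand() - 1.0);
        for (int sid : sites) {
          X(sid, 0) += dx; X(sid, 1) += dy; X(sid, 2) += dz;
        }
      } else {
        double ax, ay, az;
        rand_axis(ax, ay, az);
        double ang = amp_rot * (2.0 * unif_rand() - 1.0);
        double ca = std::cos(ang), sa = std::sin(ang);
        double cx = 0, cy = 0, cz = 0;
        for (int sid : sites) { cx += X(sid, 0); cy += X(sid, 1); cz += X(sid, 2); }
        cx /= sites.size(); cy /= sites.size(); cz /= sites.size();
        for (int sid : sites) {
          double vx = X(sid, 0) - cx, vy = X(sid, 1) - cy, vz = X(sid, 2) - cz;
          double dot = ax * vx + ay * vy + az * vz;
          double rx = vx * ca + (ay * vz - az * vy) * sa + ax * dot * (1 - ca);
          double ry = vy * ca + (az * vx - ax * vz) * sa + ay * dot * (1 - ca);
          double rz = vz * ca + (ax * vy - ay * vx) * sa + az * dot * (1 - ca);
          X(sid, 0) = cx + rx; X(sid, 1) = cy + ry; X(sid, 2) = cz + rz;
        }
      }
      double e_new = cross_energy(m, X) + m.f_kcal * anchor_dist(m, X);
      double dE = e_new - e_old;
      if (std::isfinite(dE) && (dE <= 0.0 || unif_rand() < std::exp(-dE / kT))) {
        ++acc_rigid;
        e_total += dE;
      } else {
        for (size_t k = 0; k < sites.size(); ++k)
          X.row(sites[k]) = mono_backup.row(k);
      }
    }

    // periodic exact refresh (doubles as the incremental-vs-full check)
    if (check_stride > 0 && cycle % check_stride == 0) {
      double ra2, rb2;
      arma::vec fe = full_energy(m, X, ra2, rb2);
      drift.push_back(std::abs(arma::accu(fe) - e_total));
      e_total = arma::accu(fe);
      rmsdA = ra2;
      rmsdB = rb2;
    }

    if (dca_stride > 0 && cycle % dca_stride == 0) {
      double d = anchor_dist(m, X);
      dca_cycles.push_back(cycle);
      dca_vals.push_back(d);
      dca_etot.push_back(e_total);
      if (t_dis < 0 && d > d_threshold) {
        t_dis = cycle;
        if (stop_margin >= 0)
          stop_at = std::min(n_cycles, cycle + stop_margin);
      }
    }
    if (snap_at.count(cycle)) {
      snapshots[snap_k] = wrap(X);
      snap_cycle[snap_k] = cycle;
      ++snap_k;
    }
    if (cycle % 2048 == 0) Rcpp::checkUserInterrupt();
  }

  double ra3, rb3;
  arma::vec fe = full_energy(m, X, ra3, rb3);
  if (snap_k < snapshots.size()) {
    snapshots = snapshots[Range(0, std::max(0, snap_k - 1))];
    snap_cycle = snap_cycle[Range(0, std::max(0, snap_k - 1))];
    if (snap_k == 0) { snapshots = List(0); snap_cycle = IntegerVector(0); }
  }
  return List::create(
    _["final_coords"] = X,
    _["energy"] = List::create(_["contact"] = fe(0),
                               _["excluded_volume"] = fe(1),
                               _["restraint"] = fe(2), _["pulling"] = fe(3),
                               _["total"] = arma::accu(fe)),
    _["snapshots"] = snapshots,
    _["snapshot_cycle"] = snap_cycle,
    _["dca"] = DataFrame::create(_["cycle"] = wrap(dca_cycles),
                                 _["d_ca"] = wrap(dca_vals),
                                 _["energy"] = wrap(dca_etot)),
    _["t_dis"] = t_dis,
    _["rmsd_a"] = ra3, _["rmsd_b"] = rb3,
    _["acceptance"] = NumericVector::create(
        _["site"] = try_site ? (double)acc_site / try_site : NA_REAL,
        _["rigid"] = try_rigid ? (double)acc_rigid / try_rigid : NA_REAL),
    _["energy_drift"] = wrap(drift));
}
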