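// Core simulation kernels: neighbor lists (cell binning), bead-spring
// physics (random walk, linear spring, torsion spring, soft collisions,
// drag), semi-implicit Euler integration with reflective walls, and the
// per-timestep stochastic chemistry (mechanisms A-F).
//
// All randomness goes through R's RNG (unif_rand / norm_rand) so that
// set.seed() at the R level makes runs bit-reproducible.

#include <Rcpp.h>
#include <array>
#include <cmath>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Species constants (Table-driven; order: alpha, beta, gamma).
// rc: collision radius, ri: interaction radius, m: mass, D: drag [1/s],
// maxb: bond capacity.
static const double RC[3]   = {0.25, 0.5, 1.0};
static const double RI[3]   = {1.0, 2.0, 3.0};
static const double MASS[3] = {1.0, 2.0, 4.0};
static const double DRAG[3] = {1.0, 2.0, 4.0};
static const int    MAXB[3] = {0, 2, 4};

static const double DEG_TO_RAD = M_PI / 180.0;

struct Schema {
  std::vector<double> pA1, pA2, pB, pD2b, pD2g, pE, pF;
  double pC, pD1, KL, KT, c, w, Kcoll;
  double target_deg[5]; // indexed by bound-neighbor count, entries 2..4 used
  bool overdamped_rw;   // random walk as overdamped drift vs plain force
};

static Schema parse_schema(const List& s) {
  Schema sc;
  sc.pA1  = as<std::vector<double>>(s["pA1"]);
  sc.pA2  = as<std::vector<double>>(s["pA2"]);
  sc.pB   = as<std::vector<double>>(s["pB"]);
  sc.pD2b = as<std::vector<double>>(s["pD2_beta"]);
  sc.pD2g = as<std::vector<double>>(s["pD2_gamma"]);
  sc.pE   = as<std::vector<double>>(s["pE"]);
  sc.pF   = as<std::vector<double>>(s["pF"]);
  sc.pC   = as<double>(s["pC"]);
  sc.pD1  = as<double>(s["pD1"]);
  sc.KL   = as<double>(s["K_L"]);
  sc.KT   = as<double>(s["K_T"]);
  sc.c    = as<double>(s["c"]);
  sc.w    = as<double>(s["w"]);
  sc.Kcoll = as<double>(s["K_coll"]);
  sc.overdamped_rw = true;
  if (s.containsElementNamed("rw_coupling")) {
    std::string mode = as<std::string>(s["rw_coupling"]);
    if (mode == "force") sc.overdamped_rw = false;
    else if (mode != "drift") stop("rw_coupling must be 'drift' or 'force'");
  }
  std::vector<double> ta = as<std::vector<double>>(s["target_angles"]);
  sc.target_deg[0] = sc.target_deg[1] = 0.0;
  for (int k = 0; k < 3 && k < (int)ta.size(); ++k) sc.target_deg[k + 2] = ta[k];
  if (sc.pA1.size() != 5 || sc.pB.size() != 5 || sc.pF.size() != 5 ||
      sc.pD2g.size() != 5 || sc.pD2b.size() != 3 || sc.pE.size() != 3 ||
      sc.pA2.size() != 5)
    stop("schema probability tables have wrong lengths");
  return sc;
}

struct World {
  std::vector<int> id, species, color; // species 0=alpha,1=beta,2=gamma
  std::vector<double> px, py, pz, vx, vy, vz, rx, ry, rz;
  std::vector<int> nb;                  // bond count
  std::vector<std::array<int, 4>> bnd;  // bond partner indices
  std::vector<std::vector<int>> unb;    // unbound neighbor indices
  std::vector<std::pair<int, int>> overlaps; // colliding pairs, from last build
  std::vector<char> alive;
  double side, dt;
  int step, next_id;
  int n() const { return (int)id.size(); }
};

static World world_from(const List& st) {
  World w;
  IntegerVector id = st["id"], sp = st["species"], col = st["color"];
  NumericMatrix pos = st["pos"], vel = st["vel"], rwf = st["rwf"];
  List bonds = st["bonds"];
  int n = id.size();
  w.id.assign(id.begin(), id.end());
  w.species.resize(n);
  for (int i = 0; i < n; ++i) {
    int s = sp[i];
    if (s < 1 || s > 3) stop("species codes must be 1 (alpha), 2 (beta) or 3 (gamma)");
    w.species[i] = s - 1;
  }
  w.color.assign(col.begin(), col.end());
  w.px.resize(n); w.py.resize(n); w.pz.resize(n);
  w.vx.resize(n); w.vy.resize(n); w.vz.resize(n);
  w.rx.resize(n); w.ry.resize(n); w.rz.resize(n);
  for (int i = 0; i < n; ++i) {
    w.px[i] = pos(i, 0); w.py[i] = pos(i, 1); w.pz[i] = pos(i, 2);
    w.vx[i] = vel(i, 0); w.vy[i] = vel(i, 1); w.vz[i] = vel(i, 2);
    w.rx[i] = rwf(i, 0); w.ry[i] = rwf(i, 1); w.rz[i] = rwf(i, 2);
  }
  std::unordered_map<int, int> idx;
  idx.reserve(2 * n);
  for (int i = 0; i < n; ++i) idx[w.id[i]] = i;
  w.nb.assign(n, 0);
  w.bnd.assign(n, {{-1, -1, -1, -1}});
  for (int i = 0; i < n; ++i) {
    IntegerVector bi = bonds[i];
    if (bi.size() > MAXB[w.species[i]]) stop("bond capacity exceeded in input state");
    for (int k = 0; k < bi.size(); ++k) {
      auto it = idx.find(bi[k]);
      if (it == idx.end()) stop("bond references unknown particle id");
      w.bnd[i][w.nb[i]++] = it->second;
    }
  }
  // symmetry check
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < w.nb[i]; ++k) {
      int j = w.bnd[i][k];
      bool found = false;
      for (int l = 0; l < w.nb[j]; ++l) if (w.bnd[j][l] == i) found = true;
      if (!found) stop("asymmetric bond detected in input state");
    }
  w.unb.assign(n, {});
  if (st.containsElementNamed("unbound") && !Rf_isNull(st["unbound"])) {
    List ul = st["unbound"];
    if (ul.size() == n)
      for (int i = 0; i < n; ++i) {
        IntegerVector ui = ul[i];
        for (int k = 0; k < ui.size(); ++k) {
          auto it = idx.find(ui[k]);
          if (it != idx.end()) w.unb[i].push_back(it->second);
        }
      }
  }
  w.alive.assign(n, 1);
  w.side = as<double>(st["side"]);
  w.dt = as<double>(st["dt"]);
  w.step = as<int>(st["step"]);
  w.next_id = as<int>(st["next_id"]);
  return w;
}

static List world_to(const World& w) {
  int n = w.n();
  IntegerVector id(n), sp(n), col(n);
  NumericMatrix pos(n, 3), vel(n, 3), rwf(n, 3);
  List bonds(n), unbound(n);
  for (int i = 0; i < n; ++i) {
    id[i] = w.id[i]; sp[i] = w.species[i] + 1; col[i] = w.color[i];
    pos(i, 0) = w.px[i]; pos(i, 1) = w.py[i]; pos(i, 2) = w.pz[i];
    vel(i, 0) = w.vx[i]; vel(i, 1) = w.vy[i]; vel(i, 2) = w.vz[i];
    rwf(i, 0) = w.rx[i]; rwf(i, 1) = w.ry[i]; rwf(i, 2) = w.rz[i];
    IntegerVector bi(w.nb[i]);
    for (int k = 0; k < w.nb[i]; ++k) bi[k] = w.id[w.bnd[i][k]];
    bonds[i] = bi;
    IntegerVector ui(w.unb[i].size());
    for (size_t k = 0; k < w.unb[i].size(); ++k) ui[k] = w.id[w.unb[i][k]];
    unbound[i] = ui;
  }
  return List::create(
      _["id"] = id, _["species"] = sp, _["color"] = col, _["pos"] = pos,
      _["vel"] = vel, _["rwf"] = rwf, _["bonds"] = bonds,
      _["unbound"] = unbound, _["side"] = w.side, _["dt"] = w.dt,
      _["step"] = w.step, _["next_id"] = w.next_id);
}

static inline double dist3(const World& w, int i, int j) {
  double dx = w.px[i] - w.px[j], dy = w.py[i] - w.py[j], dz = w.pz[i] - w.pz[j];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

static inline bool bonded(const World& w, int i, int j) {
  for (int k = 0; k < w.nb[i]; ++k) if (w.bnd[i][k] == j) return true;
  return false;
}

static void add_bond(World& w, int i, int j) {
  if (w.nb[i] >= MAXB[w.species[i]] || w.nb[j] >= MAXB[w.species[j]])
    stop("internal error: bond capacity exceeded");
  w.bnd[i][w.nb[i]++] = j;
  w.bnd[j][w.nb[j]++] = i;
}

static void remove_bond(World& w, int i, int j) {
  for (int k = 0; k < w.nb[i]; ++k)
    if (w.bnd[i][k] == j) { w.bnd[i][k] = w.bnd[i][--w.nb[i]]; w.bnd[i][w.nb[i]] = -1; break; }
  for (int k = 0; k < w.nb[j]; ++k)
    if (w.bnd[j][k] == i) { w.bnd[j][k] = w.bnd[j][--w.nb[j]]; w.bnd[j][w.nb[j]] = -1; break; }
}

// Sever every bond; used before killing a particle.
static void sever_all(World& w, int i) {
  while (w.nb[i] > 0) remove_bond(w, i, w.bnd[i][0]);
}

static void kill(World& w, int i) {
  sever_all(w, i);
  w.alive[i] = 0;
}

static inline double fold(double x, double side) {
  // reflect into [0, side]
  while (x < 0.0 || x > side) {
    if (x < 0.0) x = -x;
    if (x > side) x = 2.0 * side - x;
  }
  return x;
}

static int new_particle(World& w, int species, int color, double x, double y,
                        double z, double vx, double vy, double vz) {
  w.id.push_back(w.next_id++);
  w.species.push_back(species);
  w.color.push_back(color);
  w.px.push_back(fold(x, w.side)); w.py.push_back(fold(y, w.side)); w.pz.push_back(fold(z, w.side));
  w.vx.push_back(vx); w.vy.push_back(vy); w.vz.push_back(vz);
  w.rx.push_back(0.0); w.ry.push_back(0.0); w.rz.push_back(0.0);
  w.nb.push_back(0);
  w.bnd.push_back({{-1, -1, -1, -1}});
  w.unb.push_back({});
  w.alive.push_back(1);
  return w.n() - 1;
}

// Drop dead particles, remapping bond and unbound indices.
static void compact(World& w) {
  int n = w.n(), m = 0;
  std::vector<int> map(n, -1);
  for (int i = 0; i < n; ++i) if (w.alive[i]) map[i] = m++;
  if (m == n) return;
  World v;
  v.id.reserve(m);
  for (int i = 0; i < n; ++i) {
    if (!w.alive[i]) continue;
    v.id.push_back(w.id[i]); v.species.push_back(w.species[i]); v.color.push_back(w.color[i]);
    v.px.push_back(w.px[i]); v.py.push_back(w.py[i]); v.pz.push_back(w.pz[i]);
    v.vx.push_back(w.vx[i]); v.vy.push_back(w.vy[i]); v.vz.push_back(w.vz[i]);
    v.rx.push_back(w.rx[i]); v.ry.push_back(w.ry[i]); v.rz.push_back(w.rz[i]);
    std::array<int, 4> b = {{-1, -1, -1, -1}};
    int c = 0;
    for (int k = 0; k < w.nb[i]; ++k) b[c++] = map[w.bnd[i][k]];
    v.nb.push_back(c); v.bnd.push_back(b);
    std::vector<int> u;
    u.reserve(w.unb[i].size());
    for (int j : w.unb[i]) if (map[j] >= 0) u.push_back(map[j]);
    v.unb.push_back(std::move(u));
    v.alive.push_back(1);
  }
  v.side = w.side; v.dt = w.dt; v.step = w.step; v.next_id = w.next_id;
  w = std::move(v);
}

// ---------------------------------------------------------------------------
// Neighbor lists: sever over-stretched bonds, then rebuild unbound lists
// with a cell list (cell edge >= max interaction-radius sum of 6). Each
// candidate pair is enumerated once via a half stencil over cells; squared
// distances avoid sqrt in the hot loop. Overlapping (colliding) pairs are
// recorded as a by-product for the collision force.
// ---------------------------------------------------------------------------
static void build_neighbors(World& w) {
  int n = w.n();
  static double RISUM2[3][3], RCSUM2[3][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) {
      RISUM2[a][b] = (RI[a] + RI[b]) * (RI[a] + RI[b]);
      RCSUM2[a][b] = (RC[a] + RC[b]) * (RC[a] + RC[b]);
    }
  // sever bonds whose endpoints left each other's interaction volume
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < w.nb[i];) {
      int j = w.bnd[i][k];
      if (j > i && dist3(w, i, j) > RI[w.species[i]] + RI[w.species[j]])
        remove_bond(w, i, j); // does not advance k; slot refilled
      else ++k;
    }
  for (int i = 0; i < n; ++i) w.unb[i].clear();
  w.overlaps.clear();
  if (n == 0) return;
  const double cutoff = 6.0;
  int nc = std::max(1, (int)std::floor(w.side / cutoff));
  double cell = w.side / nc;
  std::vector<int> head(nc * nc * nc, -1), nxt(n), cx(n), cy(n), cz(n);
  auto cidx = [&](double x) {
    int c = (int)std::floor(x / cell);
    if (c < 0) c = 0;
    if (c >= nc) c = nc - 1;
    return c;
  };
  for (int i = 0; i < n; ++i) {
    cx[i] = cidx(w.px[i]); cy[i] = cidx(w.py[i]); cz[i] = cidx(w.pz[i]);
    int c = (cx[i] * nc + cy[i]) * nc + cz[i];
    nxt[i] = head[c];
    head[c] = i;
  }
  auto test_pair = [&](int i, int j) {
    double dx = w.px[i] - w.px[j], dy = w.py[i] - w.py[j], dz = w.pz[i] - w.pz[j];
    double d2 = dx * dx + dy * dy + dz * dz;
    int si = w.species[i], sj = w.species[j];
    if (d2 > RISUM2[si][sj]) return;
    if (d2 < RCSUM2[si][sj]) w.overlaps.emplace_back(i, j);
    if (bonded(w, i, j)) return;
    w.unb[i].push_back(j);
    w.unb[j].push_back(i);
  };
  // half stencil: self cell plus 13 of the 26 neighbors
  static const int HALF[13][3] = {
      {1, 0, 0}, {-1, 1, 0}, {0, 1, 0}, {1, 1, 0},
      {-1, -1, 1}, {0, -1, 1}, {1, -1, 1}, {-1, 0, 1}, {0, 0, 1},
      {1, 0, 1}, {-1, 1, 1}, {0, 1, 1}, {1, 1, 1}};
  for (int a = 0; a < nc; ++a)
    for (int b = 0; b < nc; ++b)
      for (int c = 0; c < nc; ++c) {
        int here = (a * nc + b) * nc + c;
        for (int i = head[here]; i >= 0; i = nxt[i]) {
          for (int j = nxt[i]; j >= 0; j = nxt[j]) test_pair(i, j);
        }
        for (const auto& off : HALF) {
          int aa = a + off[0], bb = b + off[1], cc = c + off[2];
          if (aa < 0 || aa >= nc || bb < 0 || bb >= nc || cc < 0 || cc >= nc)
            continue;
          int there = (aa * nc + bb) * nc + cc;
          for (int i = head[here]; i >= 0; i = nxt[i])
            for (int j = head[there]; j >= 0; j = nxt[j]) test_pair(i, j);
        }
      }
  // deterministic ordering regardless of cell traversal
  for (int i = 0; i < n; ++i) std::sort(w.unb[i].begin(), w.unb[i].end());
}

// ---------------------------------------------------------------------------
// Forces
// ---------------------------------------------------------------------------
struct Forces {
  std::vector<double> x, y, z;
  Forces(int n) : x(n, 0.0), y(n, 0.0), z(n, 0.0) {}
};

static void add_spring(const World& w, double KL, Forces& f) {
  for (int i = 0; i < w.n(); ++i)
    for (int k = 0; k < w.nb[i]; ++k) {
      int j = w.bnd[i][k];
      if (j < i) continue;
      double sx = w.px[j] - w.px[i], sy = w.py[j] - w.py[i], sz = w.pz[j] - w.pz[i];
      double d = std::sqrt(sx * sx + sy * sy + sz * sz);
      if (d < 1e-12) continue;
      double rest = RC[w.species[i]] + RC[w.species[j]];
      double mag = KL * (d - rest) / d; // force on i along s_ij
      f.x[i] += mag * sx; f.y[i] += mag * sy; f.z[i] += mag * sz;
      f.x[j] -= mag * sx; f.y[j] -= mag * sy; f.z[j] -= mag * sz;
    }
}

// Torsion spring: for each center B with >= 2 bonds and each unordered pair
// (A, C) of its bound neighbors, torque tau = KT * (angle(ABC) - target) with
// the angle error in degrees; |F_A| = tau / |BA|, perpendicular to BA in the
// ABC plane, driving the angle toward the target; recoil on B closes the sum.
static void add_torsion(const World& w, double KT, const double* target_deg,
                        Forces& f) {
  for (int b = 0; b < w.n(); ++b) {
    int m = w.nb[b];
    if (m < 2) continue;
    double tgt = target_deg[m] * DEG_TO_RAD;
    for (int p = 0; p < m; ++p)
      for (int q = p + 1; q < m; ++q) {
        int A = w.bnd[b][p], C = w.bnd[b][q];
        double ux = w.px[A] - w.px[b], uy = w.py[A] - w.py[b], uz = w.pz[A] - w.pz[b];
        double vx_ = w.px[C] - w.px[b], vy_ = w.py[C] - w.py[b], vz_ = w.pz[C] - w.pz[b];
        double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
        double nv = std::sqrt(vx_ * vx_ + vy_ * vy_ + vz_ * vz_);
        if (nu < 1e-12 || nv < 1e-12) continue;
        double uhx = ux / nu, uhy = uy / nu, uhz = uz / nu;
        double vhx = vx_ / nv, vhy = vy_ / nv, vhz = vz_ / nv;
        double ct = uhx * vhx + uhy * vhy + uhz * vhz;
        ct = std::max(-1.0, std::min(1.0, ct));
        double theta = std::acos(ct);
        double tau = KT * (theta - tgt) / DEG_TO_RAD; // angle error in degrees
        if (tau == 0.0) continue;
        // unit vector perp to u, in plane, pointing toward C
        double pax = vhx - ct * uhx, pay = vhy - ct * uhy, paz = vhz - ct * uhz;
        double npa = std::sqrt(pax * pax + pay * pay + paz * paz);
        double pcx = uhx - ct * vhx, pcy = uhy - ct * vhy, pcz = uhz - ct * vhz;
        double npc = std::sqrt(pcx * pcx + pcy * pcy + pcz * pcz);
        if (npa < 1e-9 || npc < 1e-9) continue; // collinear: undefined plane
        double fa = tau / nu, fc = tau / nv;
        double fax = fa * pax / npa, fay = fa * pay / npa, faz = fa * paz / npa;
        double fcx = fc * pcx / npc, fcy = fc * pcy / npc, fcz = fc * pcz / npc;
        f.x[A] += fax; f.y[A] += fay; f.z[A] += faz;
        f.x[C] += fcx; f.y[C] += fcy; f.z[C] += fcz;
        f.x[b] -= fax + fcx; f.y[b] -= fay + fcy; f.z[b] -= faz + fcz;
      }
  }
}

// Soft-sphere repulsion for the overlapping pairs recorded by the last
// neighbor sweep (overlap implies interaction range, since collision radii
// are smaller than interaction radii).
static void add_collision(const World& w, double Kcoll, Forces& f) {
  for (const auto& pr : w.overlaps) {
    int i = pr.first, j = pr.second;
    double sx = w.px[i] - w.px[j], sy = w.py[i] - w.py[j], sz = w.pz[i] - w.pz[j];
    double d = std::sqrt(sx * sx + sy * sy + sz * sz);
    double rsum = RC[w.species[i]] + RC[w.species[j]];
    if (d >= rsum || d < 1e-12) continue;
    double mag = Kcoll * (rsum - d) / d;
    f.x[i] += mag * sx; f.y[i] += mag * sy; f.z[i] += mag * sz;
    f.x[j] -= mag * sx; f.y[j] -= mag * sy; f.z[j] -= mag * sz;
  }
}

// AR(1) random-walk force update: F <- c*F + (1-c)*g, g ~ N(0, w I3)
static void rw_update(World& w, double c, double wvar) {
  double sd = std::sqrt(wvar);
  for (int i = 0; i < w.n(); ++i) {
    w.rx[i] = c * w.rx[i] + (1.0 - c) * norm_rand() * sd;
    w.ry[i] = c * w.ry[i] + (1.0 - c) * norm_rand() * sd;
    w.rz[i] = c * w.rz[i] + (1.0 - c) * norm_rand() * sd;
  }
}

// Semi-implicit Euler with linear drag and reflective walls. When
// `overdamped_rw` is set, the random-walk force memory contributes an
// overdamped drift F_R/(m D) (drag balances agitation within a timestep)
// on top of the dynamical velocity, instead of entering the force sum.
static void integrate(World& w, const Forces& f, bool overdamped_rw = false) {
  double dt = w.dt, side = w.side;
  for (int i = 0; i < w.n(); ++i) {
    double m = MASS[w.species[i]], D = DRAG[w.species[i]];
    w.vx[i] += dt * (f.x[i] / m - D * w.vx[i]);
    w.vy[i] += dt * (f.y[i] / m - D * w.vy[i]);
    w.vz[i] += dt * (f.z[i] / m - D * w.vz[i]);
    double gx = 0.0, gy = 0.0, gz = 0.0;
    if (overdamped_rw) {
      double mob = 1.0 / (m * D);
      gx = mob * w.rx[i]; gy = mob * w.ry[i]; gz = mob * w.rz[i];
    }
    double x = w.px[i] + dt * (w.vx[i] + gx);
    double y = w.py[i] + dt * (w.vy[i] + gy);
    double z = w.pz[i] + dt * (w.vz[i] + gz);
    if (x < 0.0 || x > side) { w.vx[i] = -w.vx[i]; x = fold(x, side); }
    if (y < 0.0 || y > side) { w.vy[i] = -w.vy[i]; y = fold(y, side); }
    if (z < 0.0 || z > side) { w.vz[i] = -w.vz[i]; z = fold(z, side); }
    if (!std::isfinite(x) || !std::isfinite(y) || !std::isfinite(z))
      stop("integration produced non-finite positions at step %d", w.step);
    w.px[i] = x; w.py[i] = y; w.pz[i] = z;
  }
}

// ---------------------------------------------------------------------------
// Chemistry
// ---------------------------------------------------------------------------
struct EventLog {
  std::vector<int> step, initiator;
  std::vector<std::string> mech, consumed, created, formed, severed;
  bool active = false;
  void push(int st, const char* m, int init, const std::string& cons,
            const std::string& crea, const std::string& form,
            const std::string& sev) {
    if (!active) return;
    step.push_back(st); mech.push_back(m); initiator.push_back(init);
    consumed.push_back(cons); created.push_back(crea);
    formed.push_back(form); severed.push_back(sev);
  }
};

static std::string join_ids(const World& w, const std::vector<int>& idxs) {
  std::string s;
  for (size_t k = 0; k < idxs.size(); ++k) {
    if (k) s += ",";
    s += std::to_string(w.id[idxs[k]]);
  }
  return s;
}

static void rand_unit(double& x, double& y, double& z) {
  double n = 0.0;
  do {
    x = norm_rand(); y = norm_rand(); z = norm_rand();
    n = std::sqrt(x * x + y * y + z * z);
  } while (n < 1e-12);
  x /= n; y /= n; z /= n;
}

// One full chemistry pass over the particles present at the start of the
// timestep, in a fresh uniform random visiting order. Returns number of
// events. The world still contains dead (tombstoned) particles afterwards;
// callers must compact().
static int chemistry(World& w, const Schema& sc, EventLog& ev) {
  int n0 = w.n();
  int nevents = 0;
  std::vector<int> order(n0);
  for (int i = 0; i < n0; ++i) order[i] = i;
  for (int i = n0 - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(order[i], order[j]);
  }
  for (int oi = 0; oi < n0; ++oi) {
    int p = order[oi];
    if (!w.alive[p]) continue;
    int sp = w.species[p];
    if (sp == 2) { // gamma: A, B, F
      // --- A: beta synthesis from 2 alpha ---
      {
        std::vector<int> alphas;
        for (int q : w.unb[p])
          if (w.alive[q] && w.species[q] == 0) alphas.push_back(q);
        if (alphas.size() >= 2 && unif_rand() < sc.pA1[w.nb[p]]) {
          // two nearest alphas: nearer transformed to beta, farther destroyed
          int a1 = -1, a2 = -1;
          double d1 = 1e300, d2 = 1e300;
          for (int q : alphas) {
            double d = dist3(w, p, q);
            if (d < d1) { a2 = a1; d2 = d1; a1 = q; d1 = d; }
            else if (d < d2) { a2 = q; d2 = d; }
          }
          int b = new_particle(w, 1, w.color[p], w.px[a1], w.py[a1], w.pz[a1],
                               w.vx[a1], w.vy[a1], w.vz[a1]);
          std::string formed;
          bool incorporate = unif_rand() < sc.pA2[w.nb[p]] && w.nb[p] < MAXB[2];
          if (incorporate) {
            double ux = w.px[a1] - w.px[p], uy = w.py[a1] - w.py[p], uz = w.pz[a1] - w.pz[p];
            double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
            if (nu < 1e-12) { rand_unit(ux, uy, uz); nu = 1.0; }
            double rest = RC[2] + RC[1];
            w.px[b] = fold(w.px[p] + rest * ux / nu, w.side);
            w.py[b] = fold(w.py[p] + rest * uy / nu, w.side);
            w.pz[b] = fold(w.pz[p] + rest * uz / nu, w.side);
            add_bond(w, p, b);
            formed = std::to_string(w.id[p]) + "-" + std::to_string(w.id[b]);
          }
          kill(w, a1);
          kill(w, a2);
          ev.push(w.step, "A", w.id[p], join_ids(w, {a1, a2}),
                  std::to_string(w.id[b]), formed, "");
          ++nevents;
          continue;
        }
      }
      // --- B: gamma splitting, consuming 2 bound betas ---
      {
        std::vector<int> bb;
        for (int k = 0; k < w.nb[p]; ++k)
          if (w.species[w.bnd[p][k]] == 1) bb.push_back(w.bnd[p][k]);
        if (bb.size() >= 2 && unif_rand() < sc.pB[w.nb[p]]) {
          // consume the two bound betas nearest to the parent
          std::sort(bb.begin(), bb.end(), [&](int a, int c) {
            double da = dist3(w, p, a), dc = dist3(w, p, c);
            return da < dc || (da == dc && w.id[a] < w.id[c]);
          });
          int b1 = bb[0], b2 = bb[1];
          std::vector<int> survivors;
          for (int k = 0; k < w.nb[p]; ++k) {
            int q = w.bnd[p][k];
            if (q != b1 && q != b2) survivors.push_back(q);
          }
          int pcol = w.color[p];
          double x = w.px[p], y = w.py[p], z = w.pz[p];
          double vx_ = w.vx[p], vy_ = w.vy[p], vz_ = w.vz[p];
          kill(w, b1); kill(w, b2); kill(w, p);
          double ux, uy, uz;
          rand_unit(ux, uy, uz);
          double off = RC[2] / 2.0;
          int d1 = new_particle(w, 2, pcol, x + off * ux, y + off * uy, z + off * uz, vx_, vy_, vz_);
          int d2 = new_particle(w, 2, pcol, x - off * ux, y - off * uy, z - off * uz, vx_, vy_, vz_);
          add_bond(w, d1, d2);
          std::string formed = std::to_string(w.id[d1]) + "-" + std::to_string(w.id[d2]);
          for (int s : survivors) {
            int to = (dist3(w, s, d1) <= dist3(w, s, d2)) ? d1 : d2;
            if (w.nb[to] >= MAXB[2]) to = (to == d1) ? d2 : d1;
            if (w.nb[to] < MAXB[2] && w.nb[s] < MAXB[w.species[s]]) {
              add_bond(w, s, to);
              formed += ";" + std::to_string(w.id[s]) + "-" + std::to_string(w.id[to]);
            }
          }
          ev.push(w.step, "B", w.id[p], join_ids(w, {b1, b2, p}),
                  join_ids(w, {d1, d2}), formed, "");
          ++nevents;
          continue;
        }
      }
      // --- F: gamma decay to 4 alphas ---
      if (unif_rand() < sc.pF[w.nb[p]]) {
        std::string sev;
        for (int k = 0; k < w.nb[p]; ++k) {
          if (k) sev += ";";
          sev += std::to_string(w.id[p]) + "-" + std::to_string(w.id[w.bnd[p][k]]);
        }
        std::vector<int> made;
        for (int k = 0; k < 4; ++k) {
          double ux, uy, uz;
          rand_unit(ux, uy, uz);
          made.push_back(new_particle(w, 0, 0, w.px[p] + 0.1 * ux,
                                      w.py[p] + 0.1 * uy, w.pz[p] + 0.1 * uz,
                                      w.vx[p], w.vy[p], w.vz[p]));
        }
        int pid = w.id[p];
        kill(w, p);
        ev.push(w.step, "F", pid, std::to_string(pid), join_ids(w, made), "", sev);
        ++nevents;
        continue;
      }
    } else if (sp == 1) { // beta: C or D, then E
      bool initiated = false;
      if (w.nb[p] == 1 && sc.pC > 0.0) {
        // --- C: partially bonded beta addition ---
        std::vector<int> cand;
        for (int q : w.unb[p])
          if (w.alive[q] && w.species[q] > 0 && w.nb[q] < MAXB[w.species[q]])
            cand.push_back(q);
        if (!cand.empty() && unif_rand() < sc.pC) {
          int pick = (int)std::floor(unif_rand() * cand.size());
          if (pick >= (int)cand.size()) pick = cand.size() - 1;
          int q = cand[pick];
          add_bond(w, p, q);
          ev.push(w.step, "C", w.id[p], "", "",
                  std::to_string(w.id[p]) + "-" + std::to_string(w.id[q]), "");
          ++nevents;
          initiated = true;
        }
      } else if (w.nb[p] == 0 && sc.pD1 > 0.0) {
        // --- D: free beta bonding (addition or insertion) ---
        std::vector<int> cand;
        for (int q : w.unb[p])
          if (w.alive[q] && w.species[q] > 0) cand.push_back(q);
        if (!cand.empty() && unif_rand() < sc.pD1) {
          initiated = true; // counts as the particle's one initiation
          int pick = (int)std::floor(unif_rand() * cand.size());
          if (pick >= (int)cand.size()) pick = cand.size() - 1;
          int ra = cand[pick];
          double p2 = (w.species[ra] == 1) ? sc.pD2b[w.nb[ra]] : sc.pD2g[w.nb[ra]];
          bool addition = unif_rand() < p2;
          if (!addition && w.nb[ra] == 0) addition = true; // no bond to insert into
          if (addition) {
            if (w.nb[ra] < MAXB[w.species[ra]]) {
              add_bond(w, p, ra);
              ev.push(w.step, "D", w.id[p], "", "",
                      std::to_string(w.id[p]) + "-" + std::to_string(w.id[ra]), "");
              ++nevents;
            }
          } else {
            // insert between ra and its bound neighbor nearest to p
            int X = -1;
            double best = 1e300;
            for (int k = 0; k < w.nb[ra]; ++k) {
              int q = w.bnd[ra][k];
              double d = dist3(w, p, q);
              if (d < best || (d == best && X >= 0 && w.id[q] < w.id[X])) { best = d; X = q; }
            }
            remove_bond(w, ra, X);
            add_bond(w, ra, p);
            add_bond(w, p, X);
            ev.push(w.step, "D", w.id[p], "", "",
                    std::to_string(w.id[p]) + "-" + std::to_string(w.id[ra]) + ";" +
                        std::to_string(w.id[p]) + "-" + std::to_string(w.id[X]),
                    std::to_string(w.id[ra]) + "-" + std::to_string(w.id[X]));
            ++nevents;
          }
        }
      }
      if (initiated) continue;
      // --- E: beta decay to 2 alphas ---
      if (unif_rand() < sc.pE[w.nb[p]]) {
        std::string sev;
        for (int k = 0; k < w.nb[p]; ++k) {
          if (k) sev += ";";
          sev += std::to_string(w.id[p]) + "-" + std::to_string(w.id[w.bnd[p][k]]);
        }
        std::vector<int> made;
        for (int k = 0; k < 2; ++k) {
          double ux, uy, uz;
          rand_unit(ux, uy, uz);
          made.push_back(new_particle(w, 0, 0, w.px[p] + 0.1 * ux,
                                      w.py[p] + 0.1 * uy, w.pz[p] + 0.1 * uz,
                                      w.vx[p], w.vy[p], w.vz[p]));
        }
        int pid = w.id[p];
        kill(w, p);
        ev.push(w.step, "E", pid, std::to_string(pid), join_ids(w, made), "", sev);
        ++nevents;
        continue;
      }
    }
  }
  return nevents;
}

static DataFrame events_to_df(const EventLog& ev) {
  return DataFrame::create(
      _["step"] = ev.step, _["mechanism"] = ev.mech,
      _["initiator"] = ev.initiator, _["consumed"] = ev.consumed,
      _["created"] = ev.created, _["bonds_formed"] = ev.formed,
      _["bonds_severed"] = ev.severed, _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Exposed kernels
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_build_neighbors(List state) {
  World w = world_from(state);
  build_neighbors(w);
  return world_to(w);
}

// [[Rcpp::export]]
NumericMatrix cpp_spring_forces(List state, double KL) {
  World w = world_from(state);
  Forces f(w.n());
  add_spring(w, KL, f);
  NumericMatrix out(w.n(), 3);
  for (int i = 0; i < w.n(); ++i) { out(i, 0) = f.x[i]; out(i, 1) = f.y[i]; out(i, 2) = f.z[i]; }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_torsion_forces(List state, double KT, NumericVector target_angles) {
  World w = world_from(state);
  double ta[5] = {0, 0, 0, 0, 0};
  for (int k = 0; k < 3 && k < target_angles.size(); ++k) ta[k + 2] = target_angles[k];
  Forces f(w.n());
  add_torsion(w, KT, ta, f);
  NumericMatrix out(w.n(), 3);
  for (int i = 0; i < w.n(); ++i) { out(i, 0) = f.x[i]; out(i, 1) = f.y[i]; out(i, 2) = f.z[i]; }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_collision_forces(List state, double Kcoll) {
  World w = world_from(state);
  build_neighbors(w); // candidate pairs come from the neighbor sweep
  Forces f(w.n());
  add_collision(w, Kcoll, f);
  NumericMatrix out(w.n(), 3);
  for (int i = 0; i < w.n(); ++i) { out(i, 0) = f.x[i]; out(i, 1) = f.y[i]; out(i, 2) = f.z[i]; }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_rw_step(NumericMatrix f_prev, double c, double wvar) {
  int n = f_prev.nrow();
  NumericMatrix out(n, 3);
  double sd = std::sqrt(wvar);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k)
      out(i, k) = c * f_prev(i, k) + (1.0 - c) * norm_rand() * sd;
  return out;
}

// [[Rcpp::export]]
List cpp_integrate(List state, NumericMatrix forces, bool overdamped_rw = false) {
  World w = world_from(state);
  if (forces.nrow() != w.n()) stop("force matrix does not match particle count");
  Forces f(w.n());
  for (int i = 0; i < w.n(); ++i) { f.x[i] = forces(i, 0); f.y[i] = forces(i, 1); f.z[i] = forces(i, 2); }
  integrate(w, f, overdamped_rw);
  w.step += 1;
  return world_to(w);
}

// [[Rcpp::export]]
List cpp_chemistry(List state, List schema, bool record_events) {
  World w = world_from(state);
  Schema sc = parse_schema(schema);
  EventLog ev; ev.active = record_events;
  chemistry(w, sc, ev);
  compact(w);
  return List::create(_["state"] = world_to(w), _["events"] = events_to_df(ev));
}

static List frame_snapshot(const World& w, double t) {
  int n = w.n();
  IntegerVector id(n), sp(n), col(n);
  NumericMatrix pos(n, 3);
  List bonds(n);
  for (int i = 0; i < n; ++i) {
    id[i] = w.id[i]; sp[i] = w.species[i] + 1; col[i] = w.color[i];
    pos(i, 0) = w.px[i]; pos(i, 1) = w.py[i]; pos(i, 2) = w.pz[i];
    IntegerVector bi(w.nb[i]);
    for (int k = 0; k < w.nb[i]; ++k) bi[k] = w.id[w.bnd[i][k]];
    bonds[i] = bi;
  }
  return List::create(_["t"] = t, _["id"] = id, _["species"] = sp,
                      _["color"] = col, _["pos"] = pos, _["bonds"] = bonds);
}

// Full simulation loop. Per timestep: refresh neighbor lists, chemistry,
// refresh again, forces, integrate. Frames sampled every `sample_every`
// steps (frame 0 = the initial state).
// [[Rcpp::export]]
List cpp_run(List state, List schema, int n_steps, int sample_every,
             bool record_frames, bool record_events, bool do_chemistry) {
  World w = world_from(state);
  Schema sc = parse_schema(schema);
  EventLog ev; ev.active = record_events;
  List frames;
  std::vector<List> frame_buf;
  build_neighbors(w);
  if (record_frames) frame_buf.push_back(frame_snapshot(w, w.step * w.dt));
  for (int s = 0; s < n_steps; ++s) {
    if (do_chemistry && chemistry(w, sc, ev) > 0) {
      // the particle set or bond graph changed: refresh lists and
      // collision pairs before computing forces (positions are unchanged)
      compact(w);
      build_neighbors(w);
    }
    Forces f(w.n());
    rw_update(w, sc.c, sc.w);
    if (!sc.overdamped_rw)
      for (int i = 0; i < w.n(); ++i) { f.x[i] += w.rx[i]; f.y[i] += w.ry[i]; f.z[i] += w.rz[i]; }
    add_spring(w, sc.KL, f);
    add_torsion(w, sc.KT, sc.target_deg, f);
    add_collision(w, sc.Kcoll, f);
    integrate(w, f, sc.overdamped_rw);
    w.step += 1;
    build_neighbors(w); // lists the next chemistry pass will consult
    if (record_frames && (s + 1) % sample_every == 0)
      frame_buf.push_back(frame_snapshot(w, w.step * w.dt));
    if ((s & 63) == 0) Rcpp::checkUserInterrupt();
  }
  frames = List(frame_buf.size());
  for (size_t k = 0; k < frame_buf.size(); ++k) frames[k] = frame_buf[k];
  return List::create(_["state"] = world_to(w), _["frames"] = frames,
                      _["events"] = events_to_df(ev));
}
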