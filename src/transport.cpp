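// Simplified voxel Monte Carlo transport kernel for megavoltage photons and
// electrons in a layered slab phantom.
//
// Photons: Woodcock (delta) tracking against a per-energy majorant;
// interactions are photoelectric absorption, Klein-Nishina Compton scattering
// (exact kinematics), and pair production (energy split uniformly between the
// pair, annihilation photons emitted at positron end of track).
//
// Electrons/positrons: condensed-history CSDA steps with Gaussian multiple
// scattering (Highland) plus a screened-Rutherford hard-scatter tail for
// large single deflections; radiative losses are treated as continuous and
// are not deposited locally (bremsstrahlung photons are not generated).
//
// All cross-section data arrive pre-tabulated on a log-uniform energy grid;
// the kernel only interpolates. RNG is a counter-based PCG32 seeded per
// history, so runs are reproducible for a fixed seed and independent of
// history order.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

const double MEC2 = 0.51099895;       // MeV
const double PAIR_THRESH = 1.0219979; // MeV

// ---------------------------------------------------------------- RNG (PCG32)
struct Pcg32 {
  uint64_t state, inc;
  void seed(uint64_t initstate, uint64_t initseq) {
    state = 0u; inc = (initseq << 1u) | 1u;
    next(); state += initstate; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-(int)rot) & 31));
  }
  // uniform in (0,1]
  double u() { return (next() + 1.0) * 2.3283064365386963e-10; }
  double normal() {
    double a = u(), b = u();
    return std::sqrt(-2.0 * std::log(a)) * std::cos(6.283185307179586 * b);
  }
};

uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// --------------------------------------------------------- tabulated physics
struct MatTables {
  // per energy grid point, per-cm units
  std::vector<double> mu_pe, mu_inc, mu_pair, mu_tot;
  std::vector<double> s_col, s_tot;   // MeV/cm
  std::vector<double> spr;            // (S/rho)_water / (S/rho)_medium
  std::vector<double> range_cm;       // CSDA range, cm
  double density, invX0_cm, hsA;      // hsA: hard-scatter prefactor, 1/cm
};

struct Grid {
  std::vector<double> loge;
  double lg0, dlg;
  int n;
  void init(const NumericVector& e) {
    n = e.size();
    loge.resize(n);
    for (int i = 0; i < n; i++) loge[i] = std::log(e[i]);
    lg0 = loge[0];
    dlg = (loge[n - 1] - loge[0]) / (n - 1);
  }
  // fractional index, clamped
  inline double fidx(double E) const {
    double t = (std::log(E) - lg0) / dlg;
    if (t < 0) t = 0;
    if (t > n - 1.000001) t = n - 1.000001;
    return t;
  }
};

inline double interp(const std::vector<double>& y, double t) {
  int i = (int)t;
  double f = t - i;
  return y[i] * (1 - f) + y[i + 1] * f;
}

// ----------------------------------------------------------------- geometry
struct Geometry {
  std::vector<double> zb;       // zone boundaries, cm, ascending, zb[0]=0
  std::vector<int> zone_mat;    // n_zone*4, material id per (zone, quadrant)
  int n_zone;
  double hw, zbot;              // lateral halfwidth, slab bottom (cm)
  double tz0, tz1;              // tattoo sublayer depth range (cm)

  inline int zone_of(double z) const {
    // half-open [top, bottom); z guaranteed in [0, zbot)
    int lo = 0, hi = n_zone - 1;
    while (lo < hi) {
      int mid = (lo + hi + 1) / 2;
      if (z >= zb[mid]) lo = mid; else hi = mid - 1;
    }
    return lo;
  }
  inline int quadrant(double x, double y) const {
    return (y >= 0) ? (x < 0 ? 0 : 1) : (x < 0 ? 2 : 3);
  }
  inline int mat_at(double x, double y, double z) const {
    return zone_mat[zone_of(z) * 4 + quadrant(x, y)];
  }
};

// ----------------------------------------------------------------- scoring
struct Scoring {
  double x0, dx, y0, dy, dz;
  int nx, ny, nz, nbatch;
  std::vector<double> edep_w, edep_m;   // (nx*ny*nz) * nbatch
  void init(double x0_, double dx_, int nx_, double y0_, double dy_, int ny_,
            double dz_, int nz_, int nb) {
    x0 = x0_; dx = dx_; nx = nx_; y0 = y0_; dy = dy_; ny = ny_;
    dz = dz_; nz = nz_; nbatch = nb;
    edep_w.assign((size_t)nx * ny * nz * nb, 0.0);
    edep_m.assign((size_t)nx * ny * nz * nb, 0.0);
  }
  inline void add(double x, double y, double z, double dep_m, double dep_w, int b) {
    if (z < 0 || z >= nz * dz) return;
    int ix = (int)std::floor((x - x0) / dx);
    if (ix < 0 || ix >= nx) return;
    int iy = (int)std::floor((y - y0) / dy);
    if (iy < 0 || iy >= ny) return;
    int iz = (int)(z / dz);
    size_t v = ((size_t)iz * ny + iy) * nx + ix;
    edep_m[v * nbatch + b] += dep_m;
    edep_w[v * nbatch + b] += dep_w;
  }
};

// ------------------------------------------------------------ direction math
struct Vec { double x, y, z; };

inline void rotate_dir(Vec& d, double cost, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double cphi = std::cos(phi), sphi = std::sin(phi);
  // orthonormal basis perpendicular to d
  double ax, ay, az;
  if (std::fabs(d.z) < 0.99) { ax = -d.y; ay = d.x; az = 0.0; }
  else { ax = 1.0; ay = 0.0; az = 0.0; }
  double n = std::sqrt(ax * ax + ay * ay + az * az);
  ax /= n; ay /= n; az /= n;
  double bx = d.y * az - d.z * ay;
  double by = d.z * ax - d.x * az;
  double bz = d.x * ay - d.y * ax;
  double nx = cost * d.x + sint * (cphi * ax + sphi * bx);
  double ny = cost * d.y + sint * (cphi * ay + sphi * by);
  double nz = cost * d.z + sint * (cphi * az + sphi * bz);
  n = std::sqrt(nx * nx + ny * ny + nz * nz);
  d.x = nx / n; d.y = ny / n; d.z = nz / n;
}

// Highland multiple-scattering deflection plus screened-Rutherford hard tail.
// Returns via rotation of d. s in cm, step already taken in material m.
inline void msc_deflect(Vec& d, double E, double s, const MatTables& m, Pcg32& rng) {
  double pc = std::sqrt(E * (E + 2.0 * MEC2));
  double beta = pc / (E + MEC2);
  double pbc = pc * beta;
  double sx0 = s * m.invX0_cm;
  if (sx0 > 0) {
    double br = 1.0 + 0.038 * std::log(sx0);
    if (br < 0.5) br = 0.5;
    // Highland: theta0 [rad] = (13.6 MeV / (p beta c [MeV])) sqrt(s/X0) (1 + 0.038 ln(s/X0))
    double th0 = 13.6 / pbc * std::sqrt(sx0) * br;
    double gx = rng.normal() * th0;
    double gy = rng.normal() * th0;
    double th = std::sqrt(gx * gx + gy * gy);
    if (th > 3.14159265) th = 3.14159265;
    rotate_dir(d, std::cos(th), 6.283185307179586 * rng.u());
  }
  // hard single-scatter tail beyond theta_c = 0.4 rad
  const double one_m_costc = 1.0 - std::cos(0.4);
  double rate = m.hsA * (MEC2 / pbc) * (MEC2 / pbc) *
                (2.0 / one_m_costc - 1.0);
  double p = 1.0 - std::exp(-rate * s);
  if (rng.u() < p) {
    double omc = one_m_costc / rng.u();
    if (omc > 2.0) omc = 2.0;
    rotate_dir(d, 1.0 - omc, 6.283185307179586 * rng.u());
  }
}

// Klein-Nishina sampling of the scattered-photon energy fraction eps = E'/E.
inline double sample_kn_eps(double E, Pcg32& rng, double& cost) {
  double k = E / MEC2;
  double eps0 = 1.0 / (1.0 + 2.0 * k);
  double a1 = -std::log(eps0);
  double a2 = 0.5 * (1.0 - eps0 * eps0);
  double eps, t, g;
  do {
    if (rng.u() * (a1 + a2) < a1) eps = std::exp(-a1 * rng.u());
    else eps = std::sqrt(eps0 * eps0 + (1.0 - eps0 * eps0) * rng.u());
    t = (1.0 - eps) / (k * eps);
    double sint2 = t * (2.0 - t);
    g = 1.0 - eps * sint2 / (1.0 + eps * eps);
  } while (rng.u() > g);
  cost = 1.0 - t;
  return eps;
}

struct Part { int type; double E; Vec pos, dir; }; // 0 photon, 1 e-, 2 e+

struct Engine {
  Grid grid;
  std::vector<MatTables> mats;
  Geometry geo;
  Scoring score;
  double g_cut, e_cut, e_cut_tattoo;
  double step_skin, step_water, skin_fine_zmax, z_score_max;
  std::vector<double> maj; // majorant mu_tot over materials, per grid point
  double e_emitted = 0, e_dep = 0, e_escape = 0, e_rad = 0;

  inline double ecut_at(double z) const {
    return (z >= geo.tz0 && z < geo.tz1) ? e_cut_tattoo : e_cut;
  }
  inline double mu_majorant(double t) const { return interp(maj, t); }

  void deposit_local(const Vec& p, double dep, int mat, double E, int b) {
    e_dep += dep;
    double t = grid.fidx(std::max(E, 0.011));
    score.add(p.x, p.y, p.z, dep, dep * interp(mats[mat].spr, t), b);
  }

  bool outside(const Vec& p) const {
    return p.z < 0 || p.z >= geo.zbot ||
           std::fabs(p.x) > geo.hw || std::fabs(p.y) > geo.hw;
  }

  void transport_photon(Part ph, std::vector<Part>& stack, Pcg32& rng, int b) {
    while (true) {
      if (ph.E <= g_cut) {
        if (!outside(ph.pos))
          deposit_local(ph.pos, ph.E, geo.mat_at(ph.pos.x, ph.pos.y, ph.pos.z),
                        ph.E, b);
        else e_escape += ph.E;
        return;
      }
      double t = grid.fidx(ph.E);
      double mumax = mu_majorant(t);
      double s = -std::log(rng.u()) / mumax;
      ph.pos.x += s * ph.dir.x; ph.pos.y += s * ph.dir.y; ph.pos.z += s * ph.dir.z;
      if (outside(ph.pos)) { e_escape += ph.E; return; }
      int mat = geo.mat_at(ph.pos.x, ph.pos.y, ph.pos.z);
      const MatTables& m = mats[mat];
      double mu_pe = interp(m.mu_pe, t), mu_in = interp(m.mu_inc, t),
             mu_pp = interp(m.mu_pair, t);
      double mu = mu_pe + mu_in + mu_pp;
      if (rng.u() * mumax > mu) continue; // virtual collision
      double xi = rng.u() * mu;
      if (xi < mu_pe) {
        // photoelectric: full energy to a local electron
        stack.push_back({1, ph.E, ph.pos, ph.dir});
        return;
      } else if (xi < mu_pe + mu_in) {
        double cost;
        double eps = sample_kn_eps(ph.E, rng, cost);
        double Eout = eps * ph.E, T = ph.E - Eout;
        double phi = 6.283185307179586 * rng.u();
        // electron direction from momentum conservation
        double pe = std::sqrt(ph.E * ph.E + Eout * Eout - 2.0 * ph.E * Eout * cost);
        double coste = (pe > 0) ? (ph.E - Eout * cost) / pe : 1.0;
        if (coste > 1) coste = 1; if (coste < -1) coste = -1;
        Part el = {1, T, ph.pos, ph.dir};
        rotate_dir(el.dir, coste, phi + 3.14159265358979);
        if (T > 0) stack.push_back(el);
        rotate_dir(ph.dir, cost, phi);
        ph.E = Eout;
      } else {
        double Ek = ph.E - PAIR_THRESH;
        double f = rng.u();
        stack.push_back({1, Ek * f, ph.pos, ph.dir});
        stack.push_back({2, Ek * (1.0 - f), ph.pos, ph.dir});
        return;
      }
    }
  }

  void annihilate(const Vec& p, std::vector<Part>& stack, Pcg32& rng) {
    e_emitted += 2.0 * MEC2;
    Vec d = {0, 0, 1};
    double cost = 2.0 * rng.u() - 1.0;
    rotate_dir(d, cost, 6.283185307179586 * rng.u());
    stack.push_back({0, MEC2, p, d});
    Vec dneg = {-d.x, -d.y, -d.z};
    stack.push_back({0, MEC2, p, dneg});
  }

  void transport_electron(Part el, std::vector<Part>& stack, Pcg32& rng, int b) {
    while (true) {
      double cut = ecut_at(el.pos.z);
      if (el.E <= cut) {
        if (!outside(el.pos))
          deposit_local(el.pos, el.E, geo.mat_at(el.pos.x, el.pos.y, el.pos.z),
                        std::max(el.E, 0.011), b);
        else e_escape += el.E;
        if (el.type == 2) annihilate(el.pos, stack, rng);
        return;
      }
      if (outside(el.pos)) { e_escape += el.E; return; }
      int mat = geo.mat_at(el.pos.x, el.pos.y, el.pos.z);
      const MatTables& m = mats[mat];
      double t = grid.fidx(el.E);
      // deep-region kill: cannot return to the scoring slab
      if (el.pos.z > skin_fine_zmax &&
          el.pos.z - z_score_max > interp(m.range_cm, t)) {
        e_dep += el.E;
        if (el.type == 2) annihilate(el.pos, stack, rng);
        return;
      }
      double stot = interp(m.s_tot, t);
      double smax = (el.pos.z < skin_fine_zmax) ? step_skin : step_water;
      double s = std::min(smax, 0.05 * el.E / stot);
      // split the step at material interfaces (z-zone boundaries; quadrant
      // planes inside the tattoo sublayer), overshooting by 0.1 um so the
      // next step starts in the new material
      {
        int zone = geo.zone_of(el.pos.z);
        double dbound = 1e30;
        if (el.dir.z > 1e-12)
          dbound = (geo.zb[zone + 1] - el.pos.z) / el.dir.z;
        else if (el.dir.z < -1e-12)
          dbound = (geo.zb[zone] - el.pos.z) / el.dir.z;
        if (el.pos.z >= geo.tz0 && el.pos.z < geo.tz1) {
          if (el.dir.x > 1e-12 && el.pos.x < 0)
            dbound = std::min(dbound, -el.pos.x / el.dir.x);
          else if (el.dir.x < -1e-12 && el.pos.x > 0)
            dbound = std::min(dbound, -el.pos.x / el.dir.x);
          if (el.dir.y > 1e-12 && el.pos.y < 0)
            dbound = std::min(dbound, -el.pos.y / el.dir.y);
          else if (el.dir.y < -1e-12 && el.pos.y > 0)
            dbound = std::min(dbound, -el.pos.y / el.dir.y);
        }
        if (dbound + 1e-5 < s) s = dbound + 1e-5;
      }
      // keep hard-scatter probability per step small
      double pc = std::sqrt(el.E * (el.E + 2.0 * MEC2));
      double pbc = pc * pc / (el.E + MEC2);
      double hs_rate = m.hsA * (MEC2 / pbc) * (MEC2 / pbc) *
                       (2.0 / (1.0 - std::cos(0.4)) - 1.0);
      if (hs_rate * s > 0.2) s = 0.2 / hs_rate;
      double dEtot = s * stot;
      Vec mid = {el.pos.x + 0.5 * s * el.dir.x,
                 el.pos.y + 0.5 * s * el.dir.y,
                 el.pos.z + 0.5 * s * el.dir.z};
      if (dEtot >= el.E - cut) {
        // terminal sub-step: deposit remaining kinetic energy at midpoint
        double dep = el.E;
        e_dep += dep;
        score.add(mid.x, mid.y, mid.z, dep,
                  dep * interp(m.spr, t), b);
        el.pos = mid; el.E = 0;
        if (el.type == 2) annihilate(el.pos, stack, rng);
        return;
      }
      double dcol = s * interp(m.s_col, t);
      e_dep += dcol;
      e_rad += dEtot - dcol;
      score.add(mid.x, mid.y, mid.z, dcol, dcol * interp(m.spr, t), b);
      el.pos.x += s * el.dir.x; el.pos.y += s * el.dir.y; el.pos.z += s * el.dir.z;
      el.E -= dEtot;
      msc_deflect(el.dir, el.E, s, m, rng);
    }
  }
};

Engine* build_engine(const List& eng) {
  Engine* E = new Engine();
  NumericVector egrid = eng["egrid"];
  E->grid.init(egrid);
  int ne = egrid.size();

  List matlist = eng["materials"];
  int nm = matlist.size();
  E->mats.resize(nm);
  for (int i = 0; i < nm; i++) {
    List ml = matlist[i];
    MatTables& m = E->mats[i];
    NumericVector pe = ml["mu_pe"], inc = ml["mu_inc"], pp = ml["mu_pair"],
                  sc = ml["s_col"], st = ml["s_tot"], sp = ml["spr"],
                  rg = ml["range_cm"];
    m.mu_pe.assign(pe.begin(), pe.end());
    m.mu_inc.assign(inc.begin(), inc.end());
    m.mu_pair.assign(pp.begin(), pp.end());
    m.s_col.assign(sc.begin(), sc.end());
    m.s_tot.assign(st.begin(), st.end());
    m.spr.assign(sp.begin(), sp.end());
    m.range_cm.assign(rg.begin(), rg.end());
    m.mu_tot.resize(ne);
    for (int j = 0; j < ne; j++)
      m.mu_tot[j] = m.mu_pe[j] + m.mu_inc[j] + m.mu_pair[j];
    m.density = as<double>(ml["density"]);
    m.invX0_cm = as<double>(ml["invX0_cm"]);
    m.hsA = as<double>(ml["hsA"]);
  }
  E->maj.resize(ne);
  for (int j = 0; j < ne; j++) {
    double mx = 0;
    for (int i = 0; i < nm; i++) mx = std::max(mx, E->mats[i].mu_tot[j]);
    E->maj[j] = mx;
  }

  List g = eng["geometry"];
  NumericVector zb = g["zb"];
  IntegerVector zm = g["zone_mat"];
  E->geo.zb.assign(zb.begin(), zb.end());
  E->geo.n_zone = zb.size() - 1;
  E->geo.zone_mat.assign(zm.begin(), zm.end());
  E->geo.hw = as<double>(g["hw"]);
  E->geo.zbot = as<double>(g["zbot"]);
  E->geo.tz0 = as<double>(g["tz0"]);
  E->geo.tz1 = as<double>(g["tz1"]);

  List sc = eng["scoring"];
  E->score.init(as<double>(sc["x0"]), as<double>(sc["dx"]), as<int>(sc["nx"]),
                as<double>(sc["y0"]), as<double>(sc["dy"]), as<int>(sc["ny"]),
                as<double>(sc["dz"]), as<int>(sc["nz"]), as<int>(sc["nbatch"]));

  List cuts = eng["cuts"];
  E->g_cut = as<double>(cuts["g_cut"]);
  E->e_cut = as<double>(cuts["e_cut"]);
  E->e_cut_tattoo = as<double>(cuts["e_cut_tattoo"]);

  List run = eng["run"];
  E->step_skin = as<double>(run["step_skin"]);
  E->step_water = as<double>(run["step_water"]);
  E->skin_fine_zmax = as<double>(run["skin_fine_zmax"]);
  E->z_score_max = E->score.nz * E->score.dz;
  return E;
}

} // namespace

// [[Rcpp::export]]
List cpp_run_engine(List eng) {
  Engine* E = build_engine(eng);
  List beam = eng["beam"];
  int ptype = as<int>(beam["ptype"]);
  double E0 = as<double>(beam["E0"]);
  double sigE = as<double>(beam["sigE"]);
  double hf = as<double>(beam["half_field"]);
  int src = as<int>(beam["source"]);
  double ssd = as<double>(beam["ssd"]);
  List run = eng["run"];
  double n_hist_d = as<double>(run["n_histories"]);
  long long n_hist = (long long)n_hist_d;
  uint64_t seed = (uint64_t)as<double>(run["seed"]);
  int nb = E->score.nbatch;

  std::vector<Part> stack;
  stack.reserve(64);
  Pcg32 rng;

  for (long long h = 0; h < n_hist; h++) {
    rng.seed(splitmix64(seed ^ (uint64_t)h * 0x9E3779B97F4A7C15ULL),
             splitmix64(seed + 0x632BE59BD9B4E019ULL + (uint64_t)h));
    int b = (int)((h * (long long)nb) / n_hist);

    double Ep = E0 * (1.0 + sigE * rng.normal());
    if (Ep < 0.02) Ep = 0.02;
    if (Ep > 24.9) Ep = 24.9;
    Part p;
    p.type = ptype;
    p.E = Ep;
    p.pos = {(2.0 * rng.u() - 1.0) * hf, (2.0 * rng.u() - 1.0) * hf, 0.0};
    if (src == 1) {
      double n = std::sqrt(p.pos.x * p.pos.x + p.pos.y * p.pos.y + ssd * ssd);
      p.dir = {p.pos.x / n, p.pos.y / n, ssd / n};
    } else {
      p.dir = {0, 0, 1};
    }
    E->e_emitted += Ep;

    stack.clear();
    stack.push_back(p);
    while (!stack.empty()) {
      Part q = stack.back();
      stack.pop_back();
      if (q.type == 0) E->transport_photon(q, stack, rng, b);
      else E->transport_electron(q, stack, rng, b);
    }
    if (h % 65536 == 0) Rcpp::checkUserInterrupt();
  }

  size_t nvox = (size_t)E->score.nx * E->score.ny * E->score.nz;
  NumericMatrix ew(nvox, nb), em(nvox, nb);
  for (size_t v = 0; v < nvox; v++)
    for (int bb = 0; bb < nb; bb++) {
      ew(v, bb) = E->score.edep_w[v * nb + bb];
      em(v, bb) = E->score.edep_m[v * nb + bb];
    }
  List out = List::create(
    _["edep_water"] = ew, _["edep_medium"] = em,
    _["e_emitted"] = E->e_emitted, _["e_deposited"] = E->e_dep,
    _["e_escaped"] = E->e_escape, _["e_radiated"] = E->e_rad,
    _["dim"] = IntegerVector::create(E->score.nx, E->score.ny, E->score.nz));
  delete E;
  return out;
}

// Draw Compton samples at a fixed photon energy. Returns a matrix with
// columns: eps (E'/E), cos_theta_photon, T_electron (MeV), cos_theta_electron.
// [[Rcpp::export]]
NumericMatrix cpp_sample_compton(double energy, int n, double seed) {
  NumericMatrix out(n, 4);
  Pcg32 rng;
  for (int i = 0; i < n; i++) {
    rng.seed(splitmix64((uint64_t)seed ^ (uint64_t)i * 0x9E3779B97F4A7C15ULL),
             splitmix64((uint64_t)seed + 0x632BE59BD9B4E019ULL + (uint64_t)i));
    double cost;
    double eps = sample_kn_eps(energy, rng, cost);
    double Eout = eps * energy;
    double pe = std::sqrt(energy * energy + Eout * Eout - 2.0 * energy * Eout * cost);
    double coste = (pe > 0) ? (energy - Eout * cost) / pe : 1.0;
    out(i, 0) = eps; out(i, 1) = cost;
    out(i, 2) = energy - Eout; out(i, 3) = coste;
  }
  return out;
}

// One condensed-history electron step in an infinite medium: CSDA energy
// loss over path s (cm) plus the same angular sampling used by the engine.
// Returns new energy, collision deposit, and the deflected direction.
// [[Rcpp::export]]
List cpp_condensed_step(double energy, NumericVector dir, double s,
                        double s_col, double s_tot, double invX0_cm,
                        double hsA, double e_cut, double seed, int substream) {
  Pcg32 rng;
  rng.seed(splitmix64((uint64_t)seed ^ (uint64_t)substream * 0x9E3779B97F4A7C15ULL),
           splitmix64((uint64_t)seed + 0x632BE59BD9B4E019ULL + (uint64_t)substream));
  Vec d = {dir[0], dir[1], dir[2]};
  if (s <= 0)
    return List::create(_["energy"] = energy, _["deposit"] = 0.0,
                        _["dir"] = dir, _["path"] = 0.0);
  double dEtot = s * s_tot;
  double Enew, dcol;
  if (dEtot >= energy - e_cut) {
    Enew = 0.0;
    dcol = energy;
    s = (energy - e_cut) / s_tot;
  } else {
    Enew = energy - dEtot;
    dcol = s * s_col;
  }
  MatTables m;
  m.invX0_cm = invX0_cm; m.hsA = hsA;
  if (Enew > 0) msc_deflect(d, Enew, s, m, rng);
  return List::create(_["energy"] = Enew, _["deposit"] = dcol,
                      _["dir"] = NumericVector::create(d.x, d.y, d.z),
                      _["path"] = s);
}

// Exponential free-path depths used by the photon flight sampler.
// [[Rcpp::export]]
NumericVector cpp_sample_free_depth(double mu, int n, double seed) {
  NumericVector out(n);
  Pcg32 rng;
  for (int i = 0; i < n; i++) {
    rng.seed(splitmix64((uint64_t)seed ^ (uint64_t)i * 0x9E3779B97F4A7C15ULL),
             splitmix64((uint64_t)seed + 0x632BE59BD9B4E019ULL + (uint64_t)i));
    out[i] = -std::log(rng.u()) / mu;
  }
  return out;
}
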