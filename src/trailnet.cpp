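// Compiled cores: continuous-space arena simulator (correlated random walk +
// obstacle avoidance + trail following over a pheromone raster) and the
// discrete stochastic network-choice model.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <cstdint>

using namespace Rcpp;

static const double TWO_PI = 6.283185307179586;

// ---------------------------------------------------------------------------
// Signed-distance grid over the corridor union.
// sd(cell) = (half corridor width) - distance to nearest centerline, maxed
// with the hexagon interior distance; positive inside the walkable domain.
// ---------------------------------------------------------------------------

struct Domain {
  int nx, ny;
  double x0, y0, csx, csy;       // cell size
  std::vector<float> sd;         // ny*nx, column-major [i + ny*j]
  std::vector<int>  seg;         // segment assignment per cell (0 = none), same layout

  inline double sd_at(double x, double y) const {
    double gx = (x - x0) / csx - 0.5, gy = (y - y0) / csy - 0.5;
    int j = (int)std::floor(gx), i = (int)std::floor(gy);
    if (i < 0 || j < 0 || i >= ny - 1 || j >= nx - 1) return -100.0;
    double fx = gx - j, fy = gy - i;
    double a = sd[i + ny * j], b = sd[i + ny * (j + 1)];
    double c = sd[i + 1 + ny * j], d = sd[i + 1 + ny * (j + 1)];
    return (a * (1 - fx) + b * fx) * (1 - fy) + (c * (1 - fx) + d * fx) * fy;
  }
  inline int seg_at(double x, double y) const {
    int j = (int)std::floor((x - x0) / csx), i = (int)std::floor((y - y0) / csy);
    if (i < 0 || j < 0 || i >= ny || j >= nx) return 0;
    return seg[i + ny * j];
  }
};

static Domain build_domain(const List& polys, const NumericMatrix& hex_centers,
                           double hex_diameter, double half_width,
                           int nx, int ny, NumericVector extent,
                           const IntegerMatrix& assignment) {
  Domain D;
  D.nx = nx; D.ny = ny;
  D.x0 = extent[0]; D.y0 = extent[2];
  D.csx = (extent[1] - extent[0]) / nx;
  D.csy = (extent[3] - extent[2]) / ny;
  D.sd.assign((size_t)nx * ny, -100.0f);
  D.seg.assign((size_t)nx * ny, 0);
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i)
      D.seg[i + (size_t)ny * j] = assignment(i, j);
  double margin = 8.0;   // update cells within this band of each centerline
  for (int p = 0; p < polys.size(); ++p) {
    NumericMatrix P(polys[p]);
    for (int k = 0; k + 1 < P.nrow(); ++k) {
      double ax = P(k, 0), ay = P(k, 1), bx = P(k + 1, 0), by = P(k + 1, 1);
      double lox = std::min(ax, bx) - half_width - margin;
      double hix = std::max(ax, bx) + half_width + margin;
      double loy = std::min(ay, by) - half_width - margin;
      double hiy = std::max(ay, by) + half_width + margin;
      int j0 = std::max(0, (int)((lox - D.x0) / D.csx));
      int j1 = std::min(nx - 1, (int)((hix - D.x0) / D.csx) + 1);
      int i0 = std::max(0, (int)((loy - D.y0) / D.csy));
      int i1 = std::min(ny - 1, (int)((hiy - D.y0) / D.csy) + 1);
      double abx = bx - ax, aby = by - ay;
      double len2 = abx * abx + aby * aby;
      for (int j = j0; j <= j1; ++j) {
        double cx = D.x0 + (j + 0.5) * D.csx;
        for (int i = i0; i <= i1; ++i) {
          double cy = D.y0 + (i + 0.5) * D.csy;
          double t = len2 > 1e-12 ? ((cx - ax) * abx + (cy - ay) * aby) / len2 : 0.0;
          t = std::min(1.0, std::max(0.0, t));
          double dx = ax + t * abx - cx, dy = ay + t * aby - cy;
          float cand = (float)(half_width - std::sqrt(dx * dx + dy * dy));
          size_t idx = i + (size_t)ny * j;
          if (cand > D.sd[idx]) D.sd[idx] = cand;
        }
      }
    }
  }
  // hexagonal areas: signed distance = min over the 6 half-planes
  double rad = hex_diameter / 2.0, apo = rad * std::cos(M_PI / 6.0);
  for (int h = 0; h < hex_centers.nrow(); ++h) {
    double hx = hex_centers(h, 0), hy = hex_centers(h, 1);
    int j0 = std::max(0, (int)((hx - rad - 2 - D.x0) / D.csx));
    int j1 = std::min(nx - 1, (int)((hx + rad + 2 - D.x0) / D.csx) + 1);
    int i0 = std::max(0, (int)((hy - rad - 2 - D.y0) / D.csy));
    int i1 = std::min(ny - 1, (int)((hy + rad + 2 - D.y0) / D.csy) + 1);
    for (int j = j0; j <= j1; ++j) {
      double cx = D.x0 + (j + 0.5) * D.csx - hx;
      for (int i = i0; i <= i1; ++i) {
        double cy = D.y0 + (i + 0.5) * D.csy - hy;
        double m = 1e9;
        for (int k = 0; k < 6; ++k) {
          double th = M_PI / 6.0 + k * M_PI / 3.0;
          m = std::min(m, apo - (cx * std::cos(th) + cy * std::sin(th)));
        }
        size_t idx = i + (size_t)ny * j;
        if ((float)m > D.sd[idx]) D.sd[idx] = (float)m;
      }
    }
  }
  return D;
}

static inline bool in_hex(double x, double y, double hx, double hy, double diameter) {
  double rad = diameter / 2.0, apo = rad * std::cos(M_PI / 6.0);
  double cx = x - hx, cy = y - hy;
  for (int k = 0; k < 6; ++k) {
    double th = M_PI / 6.0 + k * M_PI / 3.0;
    if (cx * std::cos(th) + cy * std::sin(th) > apo) return false;
  }
  return true;
}

// ---------------------------------------------------------------------------
// Arena simulation
// ---------------------------------------------------------------------------

struct Agent {
  double x, y, heading;
  double expl;              // exploratory direction (rad)
  double next_redir;        // s
  double last_disc_x, last_disc_y;
  bool   has_disc;
  bool   marker;
  int    stage;             // 0 outbound, 1 returning
  double anchor_x, anchor_y;   // slow-progress watchdog anchor
};

struct ArenaParams {
  double speed, tick, turn_half, redir_mean;
  double w_explore, w_avoid, w_follow;
  double sensor_range, sigmoid_mid, sigmoid_slope, robot_radius;
  double photo_offset, photo_radius;
  double disc_diameter, disc_intensity, cap, tau, evap_period, deposit_period;
};

static ArenaParams read_params(const List& par) {
  ArenaParams p;
  p.speed = as<double>(par["speed"]);            // cm/s
  p.tick = as<double>(par["tick"]);
  p.turn_half = as<double>(par["turn_half_deg"]) * M_PI / 180.0;
  p.redir_mean = as<double>(par["redirection_mean_s"]);
  p.w_explore = as<double>(par["w_explore"]);
  p.w_avoid = as<double>(par["w_avoid"]);
  p.w_follow = as<double>(par["w_follow"]);
  p.sensor_range = as<double>(par["sensor_range"]);
  p.sigmoid_mid = as<double>(par["sigmoid_mid"]);
  p.sigmoid_slope = as<double>(par["sigmoid_slope"]);
  p.robot_radius = as<double>(par["robot_radius"]);
  p.photo_offset = as<double>(par["photo_offset"]);
  p.photo_radius = as<double>(par["photo_radius"]);
  p.disc_diameter = as<double>(par["disc_diameter"]);
  p.disc_intensity = as<double>(par["disc_intensity"]);
  p.cap = as<double>(par["cap"]);
  p.tau = as<double>(par["tau"]);
  p.evap_period = as<double>(par["evap_period"]);
  p.deposit_period = as<double>(par["deposit_period"]);
  return p;
}

// wall distance along a ray, by marching the signed-distance grid
static inline double ray_wall_distance(const Domain& D, double x, double y,
                                       double dx, double dy, double maxd) {
  const double step = 0.25;
  for (double d = step; d <= maxd; d += step) {
    if (D.sd_at(x + d * dx, y + d * dy) <= 0.0) return d;
  }
  return maxd + 1.0;
}

// mean field intensity (scaled by cap) in a small disc around (x, y)
static inline double field_sample(const std::vector<double>& F, const Domain& D,
                                  double x, double y, double radius, double cap) {
  int n = 0; double s = 0.0;
  int r = std::max(1, (int)(radius / D.csx));
  int jc = (int)((x - D.x0) / D.csx), ic = (int)((y - D.y0) / D.csy);
  for (int j = jc - r; j <= jc + r; ++j) {
    if (j < 0 || j >= D.nx) continue;
    for (int i = ic - r; i <= ic + r; ++i) {
      if (i < 0 || i >= D.ny) continue;
      double px = D.x0 + (j + 0.5) * D.csx - x, py = D.y0 + (i + 0.5) * D.csy - y;
      if (px * px + py * py <= radius * radius) { s += F[i + (size_t)D.ny * j]; ++n; }
    }
  }
  return n ? s / (n * cap) : 0.0;
}

// deposit a disc, updating per-segment totals; returns deposited mass
static double field_deposit(std::vector<double>& F, std::vector<double>& segtot,
                            const Domain& D, double x, double y,
                            double radius, double intensity, double cap) {
  double mass = 0.0;
  int jc = (int)((x - D.x0) / D.csx), ic = (int)((y - D.y0) / D.csy);
  int rx = (int)(radius / D.csx) + 1, ry = (int)(radius / D.csy) + 1;
  for (int j = jc - rx; j <= jc + rx; ++j) {
    if (j < 0 || j >= D.nx) continue;
    for (int i = ic - ry; i <= ic + ry; ++i) {
      if (i < 0 || i >= D.ny) continue;
      double px = D.x0 + (j + 0.5) * D.csx - x, py = D.y0 + (i + 0.5) * D.csy - y;
      if (px * px + py * py <= radius * radius) {
        size_t idx = i + (size_t)D.ny * j;
        double before = F[idx];
        double after = std::min(before + intensity, cap);
        F[idx] = after;
        mass += after - before;
        int s = D.seg[idx];
        if (s > 0) segtot[s - 1] += after - before;
      }
    }
  }
  return mass;
}

// [[Rcpp::export(name = ".arena_run_cpp")]]
List arena_run_cpp(List polys, NumericMatrix hex_centers, double hex_diameter,
                   double half_width, NumericVector extent,
                   IntegerMatrix assignment, int nseg,
                   List par, int n_agents, double duration,
                   double record_dt, uint32_t seed, bool enable_field,
                   bool return_field) {
  ArenaParams P = read_params(par);
  int nx = assignment.ncol(), ny = assignment.nrow();
  Domain D = build_domain(polys, hex_centers, hex_diameter, half_width,
                          nx, ny, extent, assignment);
  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> U01(0.0, 1.0);

  double sx = hex_centers(0, 0), sy = hex_centers(0, 1);
  double tx = hex_centers.nrow() > 1 ? hex_centers(1, 0) : 1e9;
  double ty = hex_centers.nrow() > 1 ? hex_centers(1, 1) : 1e9;

  std::vector<Agent> ag(n_agents);
  for (int a = 0; a < n_agents; ++a) {
    // start inside the start hexagon
    for (;;) {
      double rx = (U01(rng) * 2 - 1) * hex_diameter / 2;
      double ry = (U01(rng) * 2 - 1) * hex_diameter / 2;
      if (in_hex(sx + rx, sy + ry, sx, sy, hex_diameter * 0.85)) {
        ag[a].x = sx + rx; ag[a].y = sy + ry; break;
      }
    }
    ag[a].heading = U01(rng) * TWO_PI;
    ag[a].expl = ag[a].heading;
    ag[a].next_redir = -P.redir_mean * std::log(1.0 - U01(rng));
    ag[a].has_disc = false;
    ag[a].marker = false;
    ag[a].stage = 0;
    ag[a].anchor_x = ag[a].x; ag[a].anchor_y = ag[a].y;
  }

  std::vector<double> F((size_t)nx * ny, 0.0), segtot(nseg, 0.0);
  int nticks = (int)std::llround(duration / P.tick);
  int evap_every = std::max(1, (int)std::llround(P.evap_period / P.tick));
  int depo_every = std::max(1, (int)std::llround(P.deposit_period / P.tick));
  int rec_every = record_dt > 0 ? std::max(1, (int)std::llround(record_dt / P.tick)) : 0;
  int sec_every = std::max(1, (int)std::llround(1.0 / P.tick));
  double evap_f = std::exp(-P.evap_period / P.tau);

  int n_seconds = (int)std::floor(duration) + 1;
  NumericMatrix usage(nseg, n_seconds);
  std::vector<double> rec_t, rec_x, rec_y, rec_h;
  std::vector<int> rec_a, rec_m;
  int trips = 0;

  const double sens_off[4] = {M_PI / 4, -M_PI / 4, 0.0, M_PI};
  int sec_idx = 0;
  for (int s2 = 0; s2 < nseg; ++s2) usage(s2, 0) = 0.0;
  sec_idx = 1;

  for (int tk = 1; tk <= nticks; ++tk) {
    double t = tk * P.tick;
    for (int a = 0; a < n_agents; ++a) {
      Agent& A = ag[a];
      // exploratory redirection
      if (t >= A.next_redir) {
        A.expl += (U01(rng) * 2 - 1) * P.turn_half;
        A.next_redir = t - P.redir_mean * std::log(1.0 - U01(rng));
      }
      double ex = std::cos(A.expl), ey = std::sin(A.expl);
      // avoidance: 4 proximity sensors (walls and other robots)
      double avx = 0.0, avy = 0.0;
      for (int s = 0; s < 4; ++s) {
        double th = A.heading + sens_off[s];
        double dx = std::cos(th), dy = std::sin(th);
        double d = ray_wall_distance(D, A.x, A.y, dx, dy, P.sensor_range);
        for (int b = 0; b < n_agents; ++b) {
          if (b == a) continue;
          double ox = ag[b].x - A.x, oy = ag[b].y - A.y;
          double dist = std::sqrt(ox * ox + oy * oy);
          if (dist > P.sensor_range + 2 * P.robot_radius || dist < 1e-9) continue;
          double cosang = (ox * dx + oy * dy) / dist;
          if (cosang > 0.7071) {
            double dd = std::max(0.0, dist - 2 * P.robot_radius);
            if (dd < d) d = dd;
          }
        }
        if (d <= P.sensor_range) {
          double reading = 1.0 / (1.0 + std::exp((d - P.sigmoid_mid) / P.sigmoid_slope));
          avx -= reading * dx; avy -= reading * dy;
        }
      }
      // trail following: two photoreceptors
      double tvx = 0.0, tvy = 0.0;
      if (enable_field && P.w_follow > 0) {
        double lx = A.x + P.photo_offset * std::cos(A.heading + M_PI / 2);
        double ly = A.y + P.photo_offset * std::sin(A.heading + M_PI / 2);
        double rx = A.x + P.photo_offset * std::cos(A.heading - M_PI / 2);
        double ry = A.y + P.photo_offset * std::sin(A.heading - M_PI / 2);
        double il = field_sample(F, D, lx, ly, P.photo_radius, P.cap);
        double ir = field_sample(F, D, rx, ry, P.photo_radius, P.cap);
        tvx = il * std::cos(A.heading + M_PI / 2) + ir * std::cos(A.heading - M_PI / 2);
        tvy = il * std::sin(A.heading + M_PI / 2) + ir * std::sin(A.heading - M_PI / 2);
      }
      double vx = P.w_explore * ex + P.w_avoid * avx + P.w_follow * tvx;
      double vy = P.w_explore * ey + P.w_avoid * avy + P.w_follow * tvy;
      double nrm = std::sqrt(vx * vx + vy * vy);
      if (nrm > 1e-9) A.heading = std::atan2(vy, vx);
      // advance with hard no-penetration projection
      double ox = A.x, oy = A.y;
      double nxp = A.x + P.speed * P.tick * std::cos(A.heading);
      double nyp = A.y + P.speed * P.tick * std::sin(A.heading);
      if (D.sd_at(nxp, nyp) > 0.0) {
        A.x = nxp; A.y = nyp;
      } else {
        // slide: project along grid gradient of the signed distance
        double h = 0.35;
        for (int it = 0; it < 8; ++it) {
          double sd = D.sd_at(nxp, nyp);
          if (sd > 0.05) break;
          double gx = (D.sd_at(nxp + h, nyp) - D.sd_at(nxp - h, nyp)) / (2 * h);
          double gy = (D.sd_at(nxp, nyp + h) - D.sd_at(nxp, nyp - h)) / (2 * h);
          double gn = std::sqrt(gx * gx + gy * gy);
          if (gn < 1e-6) { nxp = A.x; nyp = A.y; break; }
          nxp += (0.1 - sd) * gx / gn;
          nyp += (0.1 - sd) * gy / gn;
        }
        if (D.sd_at(nxp, nyp) > 0.0) { A.x = nxp; A.y = nyp; }
      }
      // pinned against a wall (wedge or head-on): actively turn away, like a
      // robot that cannot pass an obstacle - re-aim the exploratory
      // direction inward along the signed-distance gradient, with noise
      (void)ox; (void)oy;
      // areas: marker discipline and trip accounting
      bool inS = in_hex(A.x, A.y, sx, sy, hex_diameter);
      bool inT = in_hex(A.x, A.y, tx, ty, hex_diameter);
      A.marker = !(inS || inT);
      if (inT && A.stage == 0) A.stage = 1;
      if (inS && A.stage == 1) { A.stage = 0; ++trips; }
      // deposition at ~5 Hz with the non-overlap rule
      if (enable_field && A.marker && tk % depo_every == 0) {
        bool ok = !A.has_disc;
        if (!ok) {
          double ddx = A.x - A.last_disc_x, ddy = A.y - A.last_disc_y;
          ok = ddx * ddx + ddy * ddy >= P.disc_diameter * P.disc_diameter;
        }
        if (ok) {
          field_deposit(F, segtot, D, A.x, A.y, P.disc_diameter / 2,
                        P.disc_intensity, P.cap);
          A.last_disc_x = A.x; A.last_disc_y = A.y; A.has_disc = true;
        }
      }
    }
    // evaporation on its schedule (multiplicative: segment totals follow)
    if (enable_field && tk % evap_every == 0) {
      for (auto& v : F) v *= evap_f;
      for (auto& v : segtot) v *= evap_f;
    }
    // per-second usage snapshot
    if (tk % sec_every == 0 && sec_idx < n_seconds) {
      for (int s2 = 0; s2 < nseg; ++s2) usage(s2, sec_idx) = segtot[s2];
      ++sec_idx;
    }
    if (rec_every > 0 && tk % rec_every == 0) {
      for (int a = 0; a < n_agents; ++a) {
        rec_t.push_back(t); rec_a.push_back(a + 1);
        rec_x.push_back(ag[a].x); rec_y.push_back(ag[a].y);
        rec_h.push_back(ag[a].heading); rec_m.push_back(ag[a].marker ? 1 : 0);
      }
    }
  }

  List out = List::create(
    _["usage"] = usage,
    _["trips"] = trips,
    _["trajectory"] = DataFrame::create(
      _["t"] = rec_t, _["agent"] = rec_a, _["x"] = rec_x, _["y"] = rec_y,
      _["heading"] = rec_h, _["marker"] = rec_m));
  if (return_field) {
    NumericMatrix FM(ny, nx);
    for (int j = 0; j < nx; ++j)
      for (int i = 0; i < ny; ++i) FM(i, j) = F[i + (size_t)ny * j];
    out["field"] = FM;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Single-agent bifurcation choice assay in a Y-corridor
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".arena_assay_cpp")]]
List arena_assay_cpp(List polys, double half_width, NumericVector extent,
                     NumericVector junction, List branch_ends,
                     List par, int n_trials, double max_trial_s, uint32_t seed,
                     double choice_dist, double heading_spread) {
  ArenaParams P = read_params(par);
  // domain grid for the Y-corridor (coarser than the arena raster is fine)
  double cs = 0.25;
  int nx = (int)((extent[1] - extent[0]) / cs), ny = (int)((extent[3] - extent[2]) / cs);
  IntegerMatrix assignment(ny, nx);
  NumericMatrix hexes(0, 2);
  Domain D = build_domain(polys, hexes, 1.0, half_width, nx, ny, extent, assignment);
  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> U01(0.0, 1.0);

  NumericMatrix be(2, 2);
  NumericMatrix b1(as<NumericMatrix>(branch_ends[0]));
  // branch end points (beyond which the choice is recorded)
  double e1x = b1(0, 0), e1y = b1(0, 1);
  NumericMatrix b2(as<NumericMatrix>(branch_ends[1]));
  double e2x = b2(0, 0), e2y = b2(0, 1);
  double jx = junction[0], jy = junction[1];

  int choose1 = 0, choose2 = 0, timeouts = 0;
  const double sens_off[4] = {M_PI / 4, -M_PI / 4, 0.0, M_PI};
  int nticks = (int)(max_trial_s / P.tick);

  for (int tr = 0; tr < n_trials; ++tr) {
    NumericMatrix entry(as<NumericMatrix>(polys[0]));
    Agent A;
    A.x = entry(0, 0); A.y = entry(0, 1);
    double hd = std::atan2(entry(1, 1) - entry(0, 1), entry(1, 0) - entry(0, 0));
    hd += (U01(rng) * 2 - 1) * heading_spread;
    A.heading = hd; A.expl = hd;
    A.next_redir = -P.redir_mean * std::log(1.0 - U01(rng));
    A.anchor_x = A.x; A.anchor_y = A.y;
    int result = 0;
    for (int tk = 1; tk <= nticks && result == 0; ++tk) {
      double t = tk * P.tick;
      if (t >= A.next_redir) {
        A.expl += (U01(rng) * 2 - 1) * P.turn_half;
        A.next_redir = t - P.redir_mean * std::log(1.0 - U01(rng));
      }
      double avx = 0.0, avy = 0.0;
      for (int s = 0; s < 4; ++s) {
        double th = A.heading + sens_off[s];
        double dx = std::cos(th), dy = std::sin(th);
        double d = ray_wall_distance(D, A.x, A.y, dx, dy, P.sensor_range);
        if (d <= P.sensor_range) {
          double reading = 1.0 / (1.0 + std::exp((d - P.sigmoid_mid) / P.sigmoid_slope));
          avx -= reading * dx; avy -= reading * dy;
        }
      }
      double vx = P.w_explore * std::cos(A.expl) + P.w_avoid * avx;
      double vy = P.w_explore * std::sin(A.expl) + P.w_avoid * avy;
      if (vx * vx + vy * vy > 1e-18) A.heading = std::atan2(vy, vx);
      double nxp = A.x + P.speed * P.tick * std::cos(A.heading);
      double nyp = A.y + P.speed * P.tick * std::sin(A.heading);
      if (D.sd_at(nxp, nyp) > 0.0) { A.x = nxp; A.y = nyp; }
      else {
        double h = 0.35;
        for (int it = 0; it < 8; ++it) {
          double sd = D.sd_at(nxp, nyp);
          if (sd > 0.05) break;
          double gx = (D.sd_at(nxp + h, nyp) - D.sd_at(nxp - h, nyp)) / (2 * h);
          double gy = (D.sd_at(nxp, nyp + h) - D.sd_at(nxp, nyp - h)) / (2 * h);
          double gn = std::sqrt(gx * gx + gy * gy);
          if (gn < 1e-6) { nxp = A.x; nyp = A.y; break; }
          nxp += (0.1 - sd) * gx / gn; nyp += (0.1 - sd) * gy / gn;
        }
        if (D.sd_at(nxp, nyp) > 0.0) { A.x = nxp; A.y = nyp; }
      }
      // a choice is recorded once the agent is `choice_dist` past the
      // junction and closer to one branch's centerline than to the others
      double dj = std::hypot(A.x - jx, A.y - jy);
      if (dj > choice_dist) {
        double best = 1e18; int which = 0;
        for (int p = 0; p < polys.size(); ++p) {
          NumericMatrix P(polys[p]);
          for (int k2 = 0; k2 + 1 < P.nrow(); ++k2) {
            double ax = P(k2,0), ay = P(k2,1), bx = P(k2+1,0), by = P(k2+1,1);
            double abx = bx-ax, aby = by-ay, l2 = abx*abx+aby*aby;
            double tt = l2 > 1e-12 ? ((A.x-ax)*abx + (A.y-ay)*aby)/l2 : 0.0;
            tt = std::min(1.0, std::max(0.0, tt));
            double ddx = ax+tt*abx-A.x, ddy = ay+tt*aby-A.y;
            double dd = ddx*ddx+ddy*ddy;
            if (dd < best) { best = dd; which = p; }
          }
        }
        if (which == 1) result = 1;
        else if (which == 2) result = 2;
      }
      double d1 = std::hypot(A.x - e1x, A.y - e1y);
      double d2 = std::hypot(A.x - e2x, A.y - e2y);
      if (result == 0) {
        if (d1 < 6.0) result = 1;
        else if (d2 < 6.0) result = 2;
      }
    }
    if (result == 1) ++choose1;
    else if (result == 2) ++choose2;
    else ++timeouts;
  }
  return List::create(_["choose_first"] = choose1, _["choose_second"] = choose2,
                      _["timeouts"] = timeouts);
}

// ---------------------------------------------------------------------------
// Discrete network model
// ---------------------------------------------------------------------------

struct NetSpec {
  int nseg;
  std::vector<int> transit;              // s per segment
  // per (node, incoming corridor or -1 for area exit): two options
  // encoded via flat tables below
  std::vector<int> ends_a, ends_b;       // node indices per segment
};

// choose between two segments given pheromone, with optional asymmetric bias
static inline int choose2(double C1, double C2, double k, double nexp,
                          double alpha, int direct_idx, // 0 none, 1 or 2
                          std::mt19937_64& rng,
                          std::uniform_real_distribution<double>& U01) {
  double a = std::pow(k + C1, nexp), b = std::pow(k + C2, nexp);
  double p1 = a / (a + b);
  if (direct_idx == 1) p1 = std::min(1.0, std::max(0.0, p1 + 4 * alpha * p1 * (1 - p1)));
  else if (direct_idx == 2) {
    double p2 = 1 - p1;
    p2 = std::min(1.0, std::max(0.0, p2 + 4 * alpha * p2 * (1 - p2)));
    p1 = 1 - p2;
  }
  return (U01(rng) < p1) ? 1 : 2;
}

// [[Rcpp::export(name = ".network_sim_cpp")]]
List network_sim_cpp(int n_nodes, IntegerVector seg_from, IntegerVector seg_to,
                     IntegerVector transit_s,
                     IntegerMatrix options,   // rows: (node, incoming_seg[-1 area], opt1, opt2, direct_idx)
                     int start_node, int target_node,
                     double k, double nexp, double alpha,
                     double Q, double tau, double p_leave, double C_cap,
                     int n_agents, int duration_s,
                     int n_runs, uint32_t seed, bool trace_run,
                     NumericVector C_init, bool freeze_field) {
  int nseg = seg_from.size();
  // decision lookup: key = (node * (nseg + 1)) + (incoming + 1)
  std::vector<int> opt1((size_t)n_nodes * (nseg + 1), -1),
                   opt2((size_t)n_nodes * (nseg + 1), -1),
                   dir_((size_t)n_nodes * (nseg + 1), 0);
  for (int r = 0; r < options.nrow(); ++r) {
    size_t key = (size_t)options(r, 0) * (nseg + 1) + (options(r, 1) + 1);
    opt1[key] = options(r, 2); opt2[key] = options(r, 3); dir_[key] = options(r, 4);
  }
  double decay = std::exp(-1.0 / tau);
  IntegerVector trips_out(n_runs);
  std::vector<int> first_choice_counts(nseg, 0);
  // optional trace of the first run
  std::vector<int> ev_t, ev_agent, ev_seg, ev_node;

  for (int run = 0; run < n_runs; ++run) {
    std::mt19937_64 rng(seed + (uint64_t)run * 9973u);
    std::uniform_real_distribution<double> U01(0.0, 1.0);
    std::vector<double> C(nseg, 0.0);
    for (int s = 0; s < nseg && s < C_init.size(); ++s) C[s] = C_init[s];
    // agent state: loc >= 0 -> on segment, heading to node `to`; -1 in start, -2 in target
    std::vector<int> loc(n_agents, -1), to(n_agents, -1), rem(n_agents, 0),
                     stage(n_agents, 0), came(n_agents, -1);
    int trips = 0;
    for (int t = 1; t <= duration_s; ++t) {
      if (!freeze_field) for (auto& c : C) c *= decay;
      for (int a = 0; a < n_agents; ++a) {
        if (loc[a] == -1 || loc[a] == -2) {      // inside an area
          if (U01(rng) < p_leave) {
            int node = (loc[a] == -1) ? start_node : target_node;
            size_t key = (size_t)node * (nseg + 1) + 0;   // incoming = -1
            int o1 = opt1[key], o2 = opt2[key];
            int chosen;
            // inside the areas agents random-walk with no pheromone, so the
            // exit corridor is drawn uniformly
            if (o2 < 0) chosen = o1;
            else chosen = (U01(rng) < 0.5) ? o1 : o2;
            if (loc[a] == -1 && t > 0) first_choice_counts[chosen]++;
            loc[a] = chosen;
            to[a] = (seg_from[chosen] == node) ? seg_to[chosen] : seg_from[chosen];
            came[a] = node;
            rem[a] = transit_s[chosen];
            if (!freeze_field) C[chosen] = std::min(C[chosen] + Q * transit_s[chosen], C_cap);
            if (trace_run && run == 0) {
              ev_t.push_back(t); ev_agent.push_back(a + 1);
              ev_seg.push_back(chosen + 1); ev_node.push_back(node + 1);
            }
          }
        } else {                                  // traversing a segment
          if (--rem[a] <= 0) {
            int node = to[a];
            if (node == target_node) {
              if (stage[a] == 0) stage[a] = 1;
              loc[a] = -2; continue;
            }
            if (node == start_node) {
              if (stage[a] == 1) { stage[a] = 0; ++trips; }
              loc[a] = -1; continue;
            }
            size_t key = (size_t)node * (nseg + 1) + (loc[a] + 1);
            int o1 = opt1[key], o2 = opt2[key];
            int chosen;
            if (o1 < 0) { loc[a] = -1; continue; }  // should not happen
            if (o2 < 0) chosen = o1;
            else {
              int c12 = choose2(C[o1], C[o2], k, nexp, alpha, dir_[key], rng, U01);
              chosen = (c12 == 1) ? o1 : o2;
            }
            loc[a] = chosen;
            to[a] = (seg_from[chosen] == node) ? seg_to[chosen] : seg_from[chosen];
            came[a] = node;
            rem[a] = transit_s[chosen];
            if (!freeze_field) C[chosen] = std::min(C[chosen] + Q * transit_s[chosen], C_cap);
            if (trace_run && run == 0) {
              ev_t.push_back(t); ev_agent.push_back(a + 1);
              ev_seg.push_back(chosen + 1); ev_node.push_back(node + 1);
            }
          }
        }
      }
    }
    trips_out[run] = trips;
  }
  List out = List::create(_["trips"] = trips_out,
                          _["first_choice"] = IntegerVector(first_choice_counts.begin(),
                                                            first_choice_counts.end()));
  if (trace_run) {
    out["trace"] = DataFrame::create(_["t"] = ev_t, _["agent"] = ev_agent,
                                     _["segment"] = ev_seg, _["from_node"] = ev_node);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Raster segment assignment (fast path for segment_masks)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".segment_assign_cpp")]]
IntegerMatrix segment_assign_cpp(List polys, NumericMatrix hex_centers,
                                 double hex_diameter, double half_width,
                                 int nx, int ny, NumericVector extent) {
  double x0 = extent[0], y0 = extent[2];
  double csx = (extent[1] - extent[0]) / nx, csy = (extent[3] - extent[2]) / ny;
  std::vector<float> bestd((size_t)nx * ny, 1e9f);
  std::vector<int> bestid((size_t)nx * ny, 0);
  for (int p = 0; p < polys.size(); ++p) {
    NumericMatrix P(polys[p]);
    for (int k = 0; k + 1 < P.nrow(); ++k) {
      double ax = P(k, 0), ay = P(k, 1), bx = P(k + 1, 0), by = P(k + 1, 1);
      int j0 = std::max(0, (int)((std::min(ax, bx) - half_width - 1 - x0) / csx));
      int j1 = std::min(nx - 1, (int)((std::max(ax, bx) + half_width + 1 - x0) / csx) + 1);
      int i0 = std::max(0, (int)((std::min(ay, by) - half_width - 1 - y0) / csy));
      int i1 = std::min(ny - 1, (int)((std::max(ay, by) + half_width + 1 - y0) / csy) + 1);
      double abx = bx - ax, aby = by - ay, len2 = abx * abx + aby * aby;
      for (int j = j0; j <= j1; ++j) {
        double cx = x0 + (j + 0.5) * csx;
        for (int i = i0; i <= i1; ++i) {
          double cy = y0 + (i + 0.5) * csy;
          double t = len2 > 1e-12 ? ((cx - ax) * abx + (cy - ay) * aby) / len2 : 0.0;
          t = std::min(1.0, std::max(0.0, t));
          double dx = ax + t * abx - cx, dy = ay + t * aby - cy;
          float d = (float)std::sqrt(dx * dx + dy * dy);
          size_t idx = i + (size_t)ny * j;
          if (d < bestd[idx]) { bestd[idx] = d; bestid[idx] = p + 1; }
        }
      }
    }
  }
  IntegerMatrix out(ny, nx);
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i) {
      size_t idx = i + (size_t)ny * j;
      out(i, j) = bestd[idx] <= half_width ? bestid[idx] : 0;
    }
  // clear cells inside the area hexagons
  double rad = hex_diameter / 2.0;
  for (int h = 0; h < hex_centers.nrow(); ++h) {
    double hx = hex_centers(h, 0), hy = hex_centers(h, 1);
    int j0 = std::max(0, (int)((hx - rad - x0) / csx));
    int j1 = std::min(nx - 1, (int)((hx + rad - x0) / csx) + 1);
    int i0 = std::max(0, (int)((hy - rad - y0) / csy));
    int i1 = std::min(ny - 1, (int)((hy + rad - y0) / csy) + 1);
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i)
        if (in_hex(x0 + (j + 0.5) * csx, y0 + (i + 0.5) * csy, hx, hy, hex_diameter))
          out(i, j) = 0;
  }
  return out;
}
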