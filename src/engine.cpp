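// Overdamped Langevin dynamics with excluded volume, harmonic bonds and
// angles, reflective boundaries, optional centering drag, rigid-body
// template groups, and distance-triggered rule firing.
//
// One compiled core serves step_dynamics(), fire_reactions() and
// run_protocol(); randomness comes from R's RNG so a seed set in R makes
// whole trajectories reproducible.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <array>
#include <cmath>
using namespace Rcpp;

struct BiRule {
  int tA, sA, tB, sB;     // type / site-name codes (0-based)
  double p;               // per-encounter binding probability
  bool on;
  int id;
  std::vector<std::array<int,2>> ctxA, ctxB;  // (site name, required mod)
  std::vector<std::array<int,2>> setA, setB;  // (site name, new mod)
};

struct UniRule {
  int kind;               // 0 unbind, 1 modify (one molecule), 2 bound-pair modify
  int tA, sA, tB, sB;     // sA/sB: bonded site pair for kinds 0 and 2
  double k;               // first-order rate constant
  bool on;
  int id;
  std::vector<std::array<int,2>> ctxA, ctxB, setA, setB;
};

struct CellList {
  double lo[3], cell[3];
  int nc[3];
  std::vector<int> head, nxt;
  std::vector<std::vector<int>> half_neigh;  // neighbor cells with c1 >= c0
  void init(const double* blo, const double* bhi, double cutoff) {
    for (int k = 0; k < 3; ++k) {
      lo[k] = blo[k];
      double L = bhi[k] - blo[k];
      nc[k] = std::max(1, std::min(128, (int)std::floor(L / cutoff)));
      cell[k] = L / nc[k];
    }
    int ncell = nc[0] * nc[1] * nc[2];
    half_neigh.assign(ncell, {});
    for (int ci = 0; ci < nc[0]; ++ci)
    for (int cj = 0; cj < nc[1]; ++cj)
    for (int ck = 0; ck < nc[2]; ++ck) {
      int c0 = (ci * nc[1] + cj) * nc[2] + ck;
      for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj)
      for (int dk = -1; dk <= 1; ++dk) {
        int ni = ci + di, nj = cj + dj, nk2 = ck + dk;
        if (ni < 0 || nj < 0 || nk2 < 0 || ni >= nc[0] || nj >= nc[1] ||
            nk2 >= nc[2]) continue;
        int c1 = (ni * nc[1] + nj) * nc[2] + nk2;
        if (c1 >= c0) half_neigh[c0].push_back(c1);
      }
    }
  }
  void fill(const std::vector<double>& x, int n) {
    head.assign(nc[0] * nc[1] * nc[2], -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int c = index_of(&x[3 * i]);
      nxt[i] = head[c];
      head[c] = i;
    }
  }
  int clampc(int v, int k) const {
    return std::min(nc[k] - 1, std::max(0, v));
  }
  int index_of(const double* p) const {
    int ix = clampc((int)((p[0] - lo[0]) / cell[0]), 0);
    int iy = clampc((int)((p[1] - lo[1]) / cell[1]), 1);
    int iz = clampc((int)((p[2] - lo[2]) / cell[2]), 2);
    return (ix * nc[1] + iy) * nc[2] + iz;
  }
};

static inline double d2(const std::vector<double>& x, int i, int j) {
  double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1], dz = x[3*i+2] - x[3*j+2];
  return dx*dx + dy*dy + dz*dz;
}

static std::vector<std::array<int,2>> as_pairs(SEXP m) {
  std::vector<std::array<int,2>> out;
  if (Rf_isNull(m)) return out;
  IntegerMatrix im(m);
  for (int i = 0; i < im.nrow(); ++i)
    out.push_back({im(i, 0), im(i, 1)});
  return out;
}

// does particle p own a site named `name` with modification `mod`?
static bool has_ctx(int p, const std::vector<std::array<int,2>>& ctx,
                    const std::vector<int>& ps_start,
                    const std::vector<int>& ps_list,
                    const std::vector<int>& sname,
                    const std::vector<int>& smod) {
  for (auto& c : ctx) {
    bool found = false;
    for (int k = ps_start[p]; k < ps_start[p + 1]; ++k) {
      int s = ps_list[k];
      if (sname[s] == c[0] && smod[s] == c[1]) { found = true; break; }
    }
    if (!found) return false;
  }
  return true;
}

static void apply_set(int p, const std::vector<std::array<int,2>>& set,
                      const std::vector<int>& ps_start,
                      const std::vector<int>& ps_list,
                      const std::vector<int>& sname,
                      std::vector<int>& smod) {
  for (auto& m : set)
    for (int k = ps_start[p]; k < ps_start[p + 1]; ++k) {
      int s = ps_list[k];
      if (sname[s] == m[0]) { smod[s] = m[1]; break; }
    }
}

// rotation matrix from an axis-angle vector (Rodrigues)
static void rot_from_omega(const double* w, double R[9]) {
  double th = std::sqrt(w[0]*w[0] + w[1]*w[1] + w[2]*w[2]);
  if (th < 1e-12) {
    R[0]=1;R[1]=0;R[2]=0;R[3]=0;R[4]=1;R[5]=0;R[6]=0;R[7]=0;R[8]=1;
    return;
  }
  double kx = w[0]/th, ky = w[1]/th, kz = w[2]/th;
  double c = std::cos(th), s = std::sin(th), v = 1 - c;
  R[0]=c+kx*kx*v;   R[1]=kx*ky*v-kz*s; R[2]=kx*kz*v+ky*s;
  R[3]=ky*kx*v+kz*s;R[4]=c+ky*ky*v;   R[5]=ky*kz*v-kx*s;
  R[6]=kz*kx*v-ky*s;R[7]=kz*ky*v+kx*s;R[8]=c+kz*kz*v;
}

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(NumericMatrix pos_in, IntegerVector type, NumericVector radius,
                IntegerVector group, LogicalVector grp_rigid,
                LogicalVector grp_fixed, LogicalVector grp_rotfree,
                List grp_rot_in,
                IntegerVector sparticle, IntegerVector sname,
                IntegerVector smod_in, IntegerVector sbond_in,
                NumericVector slen, NumericVector sphi, NumericVector stheta,
                IntegerMatrix struct_bonds, NumericVector struct_rest,
                IntegerMatrix angle_triples, NumericVector angle_theta0,
                List bi_rules, List uni_rules,
                NumericMatrix box, List params,
                int nsteps, int dump_every, bool do_move, bool do_react,
                int step0) {
  RNGScope rngScope;
  const int n = pos_in.nrow();
  const int ns = sparticle.size();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3*i+k] = pos_in(i, k);
  std::vector<int> smod(smod_in.begin(), smod_in.end());
  std::vector<int> sbond(ns);      // 0-based partner site, -1 free
  for (int s = 0; s < ns; ++s) sbond[s] = sbond_in[s] - 1;
  std::vector<int> sp(ns);
  for (int s = 0; s < ns; ++s) sp[s] = sparticle[s] - 1;

  // per-particle site index ranges (sites are sorted by particle in R)
  std::vector<int> ps_start(n + 1, 0), ps_list(ns);
  {
    std::vector<int> cnt(n, 0);
    for (int s = 0; s < ns; ++s) cnt[sp[s]]++;
    for (int i = 0; i < n; ++i) ps_start[i + 1] = ps_start[i] + cnt[i];
    std::vector<int> fill(ps_start.begin(), ps_start.end() - 1);
    for (int s = 0; s < ns; ++s) ps_list[fill[sp[s]]++] = s;
  }
  std::vector<int> snv(sname.begin(), sname.end());
  std::vector<double> max_reach(n, 0.0);
  for (int s = 0; s < ns; ++s)
    max_reach[sp[s]] = std::max(max_reach[sp[s]], slen[s]);

  // groups
  const int ng = grp_rigid.size();
  std::vector<std::vector<int>> members(ng);
  for (int i = 0; i < n; ++i)
    if (group[i] > 0) members[group[i] - 1].push_back(i);
  std::vector<std::array<double,9>> grot(ng);
  for (int g = 0; g < ng; ++g) {
    NumericMatrix m = grp_rot_in[g];
    for (int k = 0; k < 9; ++k) grot[g][k] = m[k];
  }

  // rules
  std::vector<BiRule> bi;
  for (int r = 0; r < bi_rules.size(); ++r) {
    List L = bi_rules[r];
    BiRule b;
    b.tA = L["tA"]; b.sA = L["sA"]; b.tB = L["tB"]; b.sB = L["sB"];
    b.p = L["p"]; b.on = L["on"]; b.id = L["id"];
    b.ctxA = as_pairs(L["ctxA"]); b.ctxB = as_pairs(L["ctxB"]);
    b.setA = as_pairs(L["setA"]); b.setB = as_pairs(L["setB"]);
    bi.push_back(b);
  }
  std::vector<UniRule> uni;
  for (int r = 0; r < uni_rules.size(); ++r) {
    List L = uni_rules[r];
    UniRule u;
    u.kind = L["kind"];
    u.tA = L["tA"]; u.sA = L["sA"]; u.tB = L["tB"]; u.sB = L["sB"];
    u.k = L["k"]; u.on = L["on"]; u.id = L["id"];
    u.ctxA = as_pairs(L["ctxA"]); u.ctxB = as_pairs(L["ctxB"]);
    u.setA = as_pairs(L["setA"]); u.setB = as_pairs(L["setB"]);
    uni.push_back(u);
  }
  bool any_bi = false;
  for (auto& b : bi) if (b.on) any_bi = true;
  // lookup by (typeA, siteA, typeB, siteB)
  int nT = 0, nS = 0;
  for (int i = 0; i < n; ++i) nT = std::max(nT, type[i] + 1);
  for (auto& b : bi) nT = std::max(nT, std::max(b.tA, b.tB) + 1);
  for (int s = 0; s < ns; ++s) nS = std::max(nS, sname[s] + 1);
  for (auto& b : bi) nS = std::max(nS, std::max(b.sA, b.sB) + 1);
  auto rkey = [&](int tA, int sA, int tB, int sB) {
    return ((long long)(tA * nS + sA) * nT + tB) * nS + sB;
  };
  std::map<long long, std::vector<int>> rmap;
  for (size_t r = 0; r < bi.size(); ++r)
    rmap[rkey(bi[r].tA, bi[r].sA, bi[r].tB, bi[r].sB)].push_back((int)r);

  // parameters
  const double kT = params["kT"], gamma = params["gamma"], dt = params["dt"];
  const double eps = params["epsilon"], k_bond = params["k_bond"];
  const double k_angle = params["k_angle"], rot_diff = params["rot_diff"];
  const double slack = params["bind_slack"], fcap = params["fcap"];
  const double cone_cos = std::cos((double)params["cone_deg"] * M_PI / 180.0);
  const int react_every = params["react_every"];
  const bool pair_on = as<std::string>(params["pair"]) == "lj";
  bool drag_on = false;
  double drag_c[3] = {0, 0, 0}, drag_R = 0, drag_k = 0;
  if (params.containsElementNamed("drag") && !Rf_isNull(params["drag"])) {
    List dg = params["drag"];
    NumericVector c = dg["center"];
    for (int k = 0; k < 3; ++k) drag_c[k] = c[k];
    drag_R = dg["radius"]; drag_k = dg["k"];
    drag_on = true;
  }
  double blo[3], bhi[3];
  for (int k = 0; k < 3; ++k) { blo[k] = box(0, k); bhi[k] = box(1, k); }
  double minext = bhi[0] - blo[0];
  for (int k = 1; k < 3; ++k) minext = std::min(minext, bhi[k] - blo[k]);
  const double noise_sd = std::sqrt(2.0 * kT * dt / gamma);

  // cutoffs
  double rmax = 0, lmax = 0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radius[i]);
  for (int i = 0; i < n; ++i) lmax = std::max(lmax, max_reach[i]);
  double cut_pair = pair_on ? std::pow(2.0, 1.0 / 6.0) * 2.0 * rmax : 0.0;
  double cut_react = any_bi ? 2.0 * lmax * (1.0 + slack) : 0.0;
  double cutoff = std::max(cut_pair, cut_react);
  const bool cells_needed =
    ((do_move && pair_on) || (do_react && any_bi)) && cutoff > 0;
  CellList cl;
  if (cells_needed) cl.init(blo, bhi, cutoff);

  std::vector<double> f(3 * n);
  // event log
  std::vector<int> ev_step, ev_rule, ev_sa, ev_sb, ev_formed;
  // snapshots
  List snaps;
  struct Cand { int si, sj, rule; };
  std::vector<Cand> cands;
  std::vector<std::array<int,2>> bonded_pairs;

  auto site_dir_ok = [&](int s, int i, const double* dvec, double r) {
    // angular veto: only for sites with declared angles on particles whose
    // orientation is tracked (template members); others are isotropic
    if (std::isnan(sphi[s])) return true;
    int g = group[i] - 1;
    if (g < 0) return true;
    double ph = sphi[s], th = stheta[s];
    double u[3] = {std::sin(ph) * std::cos(th), std::sin(ph) * std::sin(th),
                   std::cos(ph)};
    const double* R = grot[g].data();
    double w[3] = {R[0]*u[0]+R[1]*u[1]+R[2]*u[2],
                   R[3]*u[0]+R[4]*u[1]+R[5]*u[2],
                   R[6]*u[0]+R[7]*u[1]+R[8]*u[2]};
    double dp = (w[0]*dvec[0] + w[1]*dvec[1] + w[2]*dvec[2]) / r;
    return dp >= cone_cos;
  };

  for (int step = 1; step <= nsteps; ++step) {
    int cur_step = step0 + step;
    bool need_cells = cells_needed && do_move && pair_on;
    if (need_cells) cl.fill(x, n);

    if (do_move) {
      std::fill(f.begin(), f.end(), 0.0);
      // pair repulsion (LJ cut at its minimum => purely repulsive)
      if (pair_on) {
        for (int c0 = 0; c0 < (int)cl.head.size(); ++c0) {
          if (cl.head[c0] < 0) continue;
          for (int c1 : cl.half_neigh[c0]) {
            if (cl.head[c1] < 0) continue;
            for (int i = cl.head[c0]; i >= 0; i = cl.nxt[i])
            for (int j = (c0 == c1 ? cl.nxt[i] : cl.head[c1]); j >= 0;
                 j = cl.nxt[j]) {
              if (group[i] > 0 && group[i] == group[j] &&
                  grp_rigid[group[i] - 1]) continue;
              double sig = radius[i] + radius[j];
              double cut2 = std::pow(2.0, 1.0 / 3.0) * sig * sig;
              double r2 = d2(x, i, j);
              if (r2 >= cut2 || r2 < 1e-12) continue;
              double s2 = sig * sig / r2;
              double s6 = s2 * s2 * s2;
              double fmag = 24.0 * eps * (2.0 * s6 * s6 - s6) / r2;
              double fm = fmag * std::sqrt(r2);    // |F|
              if (fm > fcap) fmag = fcap / std::sqrt(r2);
              for (int k = 0; k < 3; ++k) {
                double dxk = x[3*i+k] - x[3*j+k];
                f[3*i+k] += fmag * dxk;
                f[3*j+k] -= fmag * dxk;
              }
            }
          }
        }
      }
      // harmonic springs: site bonds + structural template bonds
      auto spring = [&](int i, int j, double rest) {
        double r = std::sqrt(d2(x, i, j));
        if (r < 1e-9) return;
        double fmag = -k_bond * (r - rest) / r;
        double fm = std::fabs(fmag) * r;
        if (fm > fcap) fmag = (fmag > 0 ? 1 : -1) * fcap / r;
        for (int k = 0; k < 3; ++k) {
          double dxk = x[3*i+k] - x[3*j+k];
          f[3*i+k] += fmag * dxk;
          f[3*j+k] -= fmag * dxk;
        }
      };
      if (k_bond > 0) {
        for (int s = 0; s < ns; ++s) {
          int t = sbond[s];
          if (t > s) spring(sp[s], sp[t], slen[s] + slen[t]);
        }
        for (int b = 0; b < struct_bonds.nrow(); ++b)
          spring(struct_bonds(b, 0) - 1, struct_bonds(b, 1) - 1,
                 struct_rest[b]);
      }
      // harmonic angles
      if (k_angle > 0) {
        for (int a = 0; a < angle_triples.nrow(); ++a) {
          int i = angle_triples(a, 0) - 1, m = angle_triples(a, 1) - 1,
              j = angle_triples(a, 2) - 1;
          double v1[3], v2[3], r1 = 0, r2v = 0, dot = 0;
          for (int k = 0; k < 3; ++k) {
            v1[k] = x[3*i+k] - x[3*m+k];
            v2[k] = x[3*j+k] - x[3*m+k];
            r1 += v1[k]*v1[k]; r2v += v2[k]*v2[k]; dot += v1[k]*v2[k];
          }
          r1 = std::sqrt(r1); r2v = std::sqrt(r2v);
          if (r1 < 1e-9 || r2v < 1e-9) continue;
          double c = std::min(1.0, std::max(-1.0, dot / (r1 * r2v)));
          double th = std::acos(c);
          double s = std::sqrt(std::max(1e-12, 1.0 - c * c));
          double coef = -k_angle * (th - angle_theta0[a]) / s;
          for (int k = 0; k < 3; ++k) {
            double gi = coef * (v2[k] / (r1 * r2v) - c * v1[k] / (r1 * r1));
            double gj = coef * (v1[k] / (r1 * r2v) - c * v2[k] / (r2v * r2v));
            f[3*i+k] += gi;
            f[3*j+k] += gj;
            f[3*m+k] -= gi + gj;
          }
        }
      }
      // centering drag-fix
      if (drag_on) {
        for (int i = 0; i < n; ++i) {
          double dv[3], r = 0;
          for (int k = 0; k < 3; ++k) {
            dv[k] = x[3*i+k] - drag_c[k];
            r += dv[k] * dv[k];
          }
          r = std::sqrt(r);
          if (r > drag_R)
            for (int k = 0; k < 3; ++k)
              f[3*i+k] -= drag_k * (r - drag_R) * dv[k] / r;
        }
      }
      // integrate free particles and non-rigid template members
      double mob = dt / gamma;
      for (int i = 0; i < n; ++i) {
        int g = group[i] - 1;
        if (g >= 0 && grp_rigid[g]) continue;    // handled as a body
        double mx = 0;
        for (int k = 0; k < 3; ++k) {
          double dxk = f[3*i+k] * mob + (kT > 0 ? noise_sd * norm_rand() : 0);
          mx = std::max(mx, std::fabs(dxk));
          x[3*i+k] += dxk;
        }
        if (mx > 0.5 * minext)
          stop("step size instability: displacement %.1f exceeds half the "
               "smallest box extent at step %d", mx, cur_step);
      }
      // rigid bodies: translate by net force, rotate diffusively
      for (int g = 0; g < ng; ++g) {
        if (!grp_rigid[g] || members[g].empty()) continue;
        int m = members[g].size();
        double c[3] = {0, 0, 0};
        for (int i : members[g])
          for (int k = 0; k < 3; ++k) c[k] += x[3*i+k];
        for (int k = 0; k < 3; ++k) c[k] /= m;
        if (!grp_fixed[g]) {
          double fn[3] = {0, 0, 0};
          for (int i : members[g])
            for (int k = 0; k < 3; ++k) fn[k] += f[3*i+k];
          for (int k = 0; k < 3; ++k) {
            double dxk = fn[k] * dt / (gamma * m) +
              (kT > 0 ? noise_sd / std::sqrt((double)m) * norm_rand() : 0);
            if (std::fabs(dxk) > 0.5 * minext)
              stop("step size instability in rigid group at step %d", cur_step);
            for (int i : members[g]) x[3*i+k] += dxk;
            c[k] += dxk;
          }
        }
        if (grp_rotfree[g] && kT > 0 && rot_diff > 0) {
          double sd = std::sqrt(2.0 * rot_diff * dt);
          double w[3] = {sd * norm_rand(), sd * norm_rand(), sd * norm_rand()};
          double R[9];
          rot_from_omega(w, R);
          for (int i : members[g]) {
            double v[3];
            for (int k = 0; k < 3; ++k) v[k] = x[3*i+k] - c[k];
            for (int k = 0; k < 3; ++k)
              x[3*i+k] = c[k] + R[3*k]*v[0] + R[3*k+1]*v[1] + R[3*k+2]*v[2];
          }
          double Rn[9];
          for (int a = 0; a < 3; ++a)
            for (int b = 0; b < 3; ++b)
              Rn[3*a+b] = R[3*a]*grot[g][b] + R[3*a+1]*grot[g][3+b] +
                          R[3*a+2]*grot[g][6+b];
          for (int k = 0; k < 9; ++k) grot[g][k] = Rn[k];
        }
      }
      // reflective boundaries
      for (int i = 0; i < n; ++i) {
        int g = group[i] - 1;
        if (g >= 0 && (grp_fixed[g] || grp_rigid[g])) continue;
        for (int k = 0; k < 3; ++k) {
          if (x[3*i+k] < blo[k]) x[3*i+k] = 2 * blo[k] - x[3*i+k];
          if (x[3*i+k] > bhi[k]) x[3*i+k] = 2 * bhi[k] - x[3*i+k];
          if (x[3*i+k] < blo[k]) x[3*i+k] = blo[k];   // pathological overshoot
        }
      }
      // mobile rigid groups reflect by centroid shift
      for (int g = 0; g < ng; ++g) {
        if (!grp_rigid[g] || grp_fixed[g] || members[g].empty()) continue;
        int m = members[g].size();
        double c[3] = {0, 0, 0};
        for (int i : members[g])
          for (int k = 0; k < 3; ++k) c[k] += x[3*i+k] / m;
        for (int k = 0; k < 3; ++k) {
          double shift = 0;
          if (c[k] < blo[k]) shift = 2 * (blo[k] - c[k]);
          if (c[k] > bhi[k]) shift = 2 * (bhi[k] - c[k]);
          if (shift != 0)
            for (int i : members[g]) x[3*i+k] += shift;
        }
      }
    }

    // reactions
    if (do_react && (step % react_every == 0)) {
      if (any_bi && cells_needed) {
        if (!need_cells) cl.fill(x, n);
        cands.clear();
        for (int c0 = 0; c0 < (int)cl.head.size(); ++c0) {
          if (cl.head[c0] < 0) continue;
          for (int c1 : cl.half_neigh[c0]) {
            if (cl.head[c1] < 0) continue;
            for (int i = cl.head[c0]; i >= 0; i = cl.nxt[i])
            for (int j = (c0 == c1 ? cl.nxt[i] : cl.head[c1]); j >= 0;
                 j = cl.nxt[j]) {
              if (group[i] > 0 && group[i] == group[j]) continue; // same template
              double reach = (max_reach[i] + max_reach[j]) * (1.0 + slack);
              double r2 = d2(x, i, j);
              if (r2 > reach * reach || max_reach[i] <= 0 ||
                  max_reach[j] <= 0) continue;
              double r = std::sqrt(r2);
              double dvec[3] = {x[3*j] - x[3*i], x[3*j+1] - x[3*i+1],
                                x[3*j+2] - x[3*i+2]};
              double dneg[3] = {-dvec[0], -dvec[1], -dvec[2]};
              for (int ki = ps_start[i]; ki < ps_start[i + 1]; ++ki) {
                int si = ps_list[ki];
                if (sbond[si] >= 0) continue;
                for (int kj = ps_start[j]; kj < ps_start[j + 1]; ++kj) {
                  int sj = ps_list[kj];
                  if (sbond[sj] >= 0) continue;
                  double rr = (slen[si] + slen[sj]) * (1.0 + slack);
                  if (r2 > rr * rr) continue;
                  bool sym_seen = false;
                  auto push_rules = [&](int ti, int sni, int tj2, int snj,
                                        int a, int b, const double* da,
                                        const double* db, int sa, int sb2) {
                    auto it = rmap.find(rkey(ti, sni, tj2, snj));
                    if (it == rmap.end()) return;
                    for (int r_idx : it->second) {
                      BiRule& br = bi[r_idx];
                      if (!br.on) continue;
                      bool sym = (br.tA == br.tB && br.sA == br.sB);
                      if (sym && sym_seen) continue;
                      if (!has_ctx(a, br.ctxA, ps_start, ps_list, snv,
                                   smod)) continue;
                      if (!has_ctx(b, br.ctxB, ps_start, ps_list, snv,
                                   smod)) continue;
                      if (!site_dir_ok(sa, a, da, r) ||
                          !site_dir_ok(sb2, b, db, r)) continue;
                      cands.push_back({sa, sb2, r_idx});
                      if (sym) sym_seen = true;
                    }
                  };
                  push_rules(type[i], sname[si], type[j], sname[sj],
                             i, j, dvec, dneg, si, sj);
                  push_rules(type[j], sname[sj], type[i], sname[si],
                             j, i, dneg, dvec, sj, si);
                }
              }
            }
          }
        }
        // shuffle candidate pairs to avoid positional bias
        for (int i = (int)cands.size() - 1; i > 0; --i) {
          int j = (int)std::floor(unif_rand() * (i + 1));
          if (j > i) j = i;
          std::swap(cands[i], cands[j]);
        }
        for (auto& cd : cands) {
          if (sbond[cd.si] >= 0 || sbond[cd.sj] >= 0) continue;
          BiRule& br = bi[cd.rule];
          int pa = sp[cd.si], pb = sp[cd.sj];
          if (!has_ctx(pa, br.ctxA, ps_start, ps_list, snv, smod)) continue;
          if (!has_ctx(pb, br.ctxB, ps_start, ps_list, snv, smod)) continue;
          if (br.p < 1.0 && unif_rand() >= br.p) continue;
          sbond[cd.si] = cd.sj;
          sbond[cd.sj] = cd.si;
          apply_set(pa, br.setA, ps_start, ps_list, snv, smod);
          apply_set(pb, br.setB, ps_start, ps_list, snv, smod);
          ev_step.push_back(cur_step);
          ev_rule.push_back(br.id);
          ev_sa.push_back(cd.si + 1);
          ev_sb.push_back(cd.sj + 1);
          ev_formed.push_back(1);
        }
      }
      if (!uni.empty()) {
        bonded_pairs.clear();
        for (int s = 0; s < ns; ++s)
          if (sbond[s] > s) bonded_pairs.push_back({s, sbond[s]});
        for (auto& u : uni) {
          if (!u.on) continue;
          double pfire = 1.0 - std::exp(-u.k * dt * react_every);
          if (u.kind == 1) {
            for (int i = 0; i < n; ++i) {
              if (type[i] != u.tA) continue;
              if (!has_ctx(i, u.ctxA, ps_start, ps_list, snv, smod)) continue;
              if (unif_rand() < pfire)
                apply_set(i, u.setA, ps_start, ps_list, snv, smod);
            }
          } else {
            for (auto& bp : bonded_pairs) {
              int s1 = bp[0], s2 = bp[1];
              if (sbond[s1] != s2) continue;   // broken earlier this sweep
              int p1 = sp[s1], p2 = sp[s2];
              int a = -1, b = -1, sa = -1, sb2 = -1;
              if (type[p1] == u.tA && snv[s1] == u.sA &&
                  type[p2] == u.tB && snv[s2] == u.sB &&
                  has_ctx(p1, u.ctxA, ps_start, ps_list, snv, smod) &&
                  has_ctx(p2, u.ctxB, ps_start, ps_list, snv, smod)) {
                a = p1; b = p2; sa = s1; sb2 = s2;
              } else if (type[p2] == u.tA && snv[s2] == u.sA &&
                         type[p1] == u.tB && snv[s1] == u.sB &&
                         has_ctx(p2, u.ctxA, ps_start, ps_list, snv, smod) &&
                         has_ctx(p1, u.ctxB, ps_start, ps_list, snv, smod)) {
                a = p2; b = p1; sa = s2; sb2 = s1;
              }
              if (a < 0) continue;
              if (unif_rand() >= pfire) continue;
              if (u.kind == 0) {
                sbond[sa] = -1;
                sbond[sb2] = -1;
                ev_step.push_back(cur_step);
                ev_rule.push_back(u.id);
                ev_sa.push_back(sa + 1);
                ev_sb.push_back(sb2 + 1);
                ev_formed.push_back(0);
              }
              apply_set(a, u.setA, ps_start, ps_list, snv, smod);
              apply_set(b, u.setB, ps_start, ps_list, snv, smod);
            }
          }
        }
      }
    }

    if (dump_every > 0 && (cur_step % dump_every == 0)) {
      NumericMatrix ps(n, 3);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) ps(i, k) = x[3*i+k];
      IntegerVector bnd(ns);
      for (int s = 0; s < ns; ++s) bnd[s] = sbond[s] + 1;
      snaps.push_back(List::create(_["step"] = cur_step, _["pos"] = ps,
                                   _["bond"] = bnd));
    }
    if (step % 1024 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pos_out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) pos_out(i, k) = x[3*i+k];
  IntegerVector sbond_out(ns), smod_out(ns);
  for (int s = 0; s < ns; ++s) {
    sbond_out[s] = sbond[s] + 1;
    smod_out[s] = smod[s];
  }
  List grot_out(ng);
  for (int g = 0; g < ng; ++g) {
    NumericMatrix m(3, 3);
    for (int k = 0; k < 9; ++k) m[k] = grot[g][k];
    grot_out[g] = m;
  }
  return List::create(
    _["pos"] = pos_out, _["sbond"] = sbond_out, _["smod"] = smod_out,
    _["grot"] = grot_out,
    _["events"] = List::create(
      _["step"] = wrap(ev_step), _["rule"] = wrap(ev_rule),
      _["site_a"] = wrap(ev_sa), _["site_b"] = wrap(ev_sb),
      _["formed"] = wrap(ev_formed)),
    _["snapshots"] = snaps);
}
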