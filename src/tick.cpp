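// Production tick engine.
//
// Implements one 1-minute tick of the vesicle/nutrient model with the same
// sub-step order and, crucially, the same RNG draw protocol as the R
// implementations (vectorised ops and the naive reference tick), using R's
// own generator: under a common seed all three engines produce identical
// trajectories. sample.int() is replicated via R_unif_index with the same
// partial-Fisher-Yates loop R uses internally.

#include <Rcpp.h>
#include <Rmath.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const int PP = 1, AP = 2, LY = 3, AL = 4;

struct Pool {
  std::vector<int> id, kind;
  std::vector<double> x, y, size, birth, mat_time, lifetime, cargo, formed,
      ingested, released;
  size_t n() const { return id.size(); }
  void erase_where(const std::vector<char> &drop) {
    size_t w = 0;
    for (size_t i = 0; i < id.size(); i++) {
      if (drop[i]) continue;
      id[w] = id[i]; kind[w] = kind[i]; x[w] = x[i]; y[w] = y[i];
      size[w] = size[i]; birth[w] = birth[i]; mat_time[w] = mat_time[i];
      lifetime[w] = lifetime[i]; cargo[w] = cargo[i]; formed[w] = formed[i];
      ingested[w] = ingested[i]; released[w] = released[i];
      w++;
    }
    id.resize(w); kind.resize(w); x.resize(w); y.resize(w); size.resize(w);
    birth.resize(w); mat_time.resize(w); lifetime.resize(w);
    cargo.resize(w); formed.resize(w); ingested.resize(w);
    released.resize(w);
  }
  void push(int id_, int kind_, double x_, double y_, double size_,
            double birth_, double mat_, double life_, double cargo_,
            double formed_, double ing_, double rel_) {
    id.push_back(id_); kind.push_back(kind_); x.push_back(x_);
    y.push_back(y_); size.push_back(size_); birth.push_back(birth_);
    mat_time.push_back(mat_); lifetime.push_back(life_);
    cargo.push_back(cargo_); formed.push_back(formed_);
    ingested.push_back(ing_); released.push_back(rel_);
  }
};

// sampled duration: exponential with stated mean, or the mean in fixed mode
double sample_duration(double mean, bool fixed) {
  if (fixed) return mean;
  if (mean <= 0) return 0.0;
  // matches rexp(1, rate = 1/mean): R computes scale = 1/rate at R level
  double scale = 1.0 / (1.0 / mean);
  return scale * exp_rand();
}

// replicate R's sample.int(m) (Rejection sampling kind): 0-based result
void sample_perm(int m, std::vector<int> &ord) {
  ord.resize(m);
  std::vector<int> x(m);
  for (int i = 0; i < m; i++) x[i] = i;
  int n = m;
  for (int i = 0; i < m; i++) {
    int j = (int) R_unif_index((double) n);
    ord[i] = x[j];
    x[j] = x[--n];
  }
}

// first segment-circle crossing, mirroring the R clamp arithmetic
void clamp_point(double fx, double fy, double tx, double ty, double radius,
                 bool outward, double &ox, double &oy) {
  double dx = tx - fx, dy = ty - fy;
  double a = dx * dx + dy * dy;
  double b = 2.0 * (fx * dx + fy * dy);
  double cc = fx * fx + fy * fy - radius * radius;
  double disc = b * b - 4.0 * a * cc;
  if (disc < 0) disc = 0;
  double t = outward ? (-b + std::sqrt(disc)) / (2.0 * a)
                     : (-b - std::sqrt(disc)) / (2.0 * a);
  if (!std::isfinite(t)) t = 0;
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  double px = fx + t * dx, py = fy + t * dy;
  double r = std::sqrt(px * px + py * py);
  double s = r > 0 ? radius / r : 1.0;
  ox = px * s; oy = py * s;
}

struct Geom {
  int n;
  double r_cell, r_nuc, patch_size;
  const int *cytosol, *border;     // logical matrices
  const double *neigh, *centers;
  int patch_of(double x, double y) const {
    int i = (int) std::floor((x + r_cell) / patch_size);
    int j = (int) std::floor((y + r_cell) / patch_size);
    if (i < 0) i = 0; if (i > n - 1) i = n - 1;
    if (j < 0) j = 0; if (j > n - 1) j = n - 1;
    return i + j * n;
  }
  // cytosol patch receiving an agent's nutrient flux: own patch, else the
  // nearest cytosolic patch of the 3x3 neighbourhood (fixed scan order),
  // mirroring the R helper
  int flux_patch_of(double x, double y) const {
    int c = patch_of(x, y);
    if (cytosol[c]) return c;
    int i = c % n, j = c / n;
    int best = -1;
    double bestd = R_PosInf;
    for (int di = -1; di <= 1; di++) {
      for (int dj = -1; dj <= 1; dj++) {
        int ii = i + di, jj = j + dj;
        if (ii < 0 || ii >= n || jj < 0 || jj >= n) continue;
        int cc = ii + jj * n;
        if (!cytosol[cc]) continue;
        double ddx = x - centers[ii], ddy = y - centers[jj];
        double d2 = ddx * ddx + ddy * ddy;
        if (d2 < bestd) { bestd = d2; best = cc; }
      }
    }
    if (best >= 0) return best;
    for (int cc = 0; cc < n * n; cc++) {
      if (!cytosol[cc]) continue;
      double ddx = x - centers[cc % n], ddy = y - centers[cc / n];
      double d2 = ddx * ddx + ddy * ddy;
      if (d2 < bestd) { bestd = d2; best = cc; }
    }
    return best;
  }
  // radial projection into the cytosolic annulus
  void project_annulus(double &x, double &y) const {
    double r = std::sqrt(x * x + y * y);
    if (r < r_nuc) {
      if (r > 0) { x *= r_nuc / r; y *= r_nuc / r; }
      else { x = r_nuc; y = 0; }
    } else if (r > r_cell) {
      x *= r_cell / r; y *= r_cell / r;
    }
  }
};

// per-grid cache for the diffusion loop: cytosol cells and their
// in-lattice neighbour indices (-1 when off-lattice), in the fixed
// (di, dj) source order
struct DiffCache {
  std::vector<int> cells;
  std::vector<int> nbr;   // 8 entries per cell
  void build(const Geom &G) {
    int N = G.n;
    for (int j = 0; j < N; j++) {
      for (int i = 0; i < N; i++) {
        int c = i + j * N;
        if (!G.cytosol[c]) continue;
        cells.push_back(c);
        for (int di = -1; di <= 1; di++) {
          for (int dj = -1; dj <= 1; dj++) {
            if (di == 0 && dj == 0) continue;
            int si = i + di, sj = j + dj;
            nbr.push_back((si < 0 || si >= N || sj < 0 || sj >= N)
                          ? -1 : si + sj * N);
          }
        }
      }
    }
  }
};

double fusion_prob(int k1, int k2, double p_aply, double p_nonal,
                   double p_alal) {
  int lo = k1 < k2 ? k1 : k2, hi = k1 < k2 ? k2 : k1;
  if (lo == AP && hi == LY) return p_aply;
  if (hi == AL && (lo == AP || lo == LY)) return p_nonal;
  if (lo == AL && hi == AL) return p_alal;
  return 0.0;
}

} // namespace

// Shared per-tick core. par/rate layouts as documented below; fr/bo are
// the live field arrays (null in the core variant).
namespace {

void do_tick(Pool &P, const Geom &G, const DiffCache &D,
             const double *par, const double *rate,
             bool integrative, bool fixed_dur, bool decay_free,
             double tnow, int &next_id, double *fr, double *bo) {
  const double growth[5] = {0.0, par[0], par[1], par[2], par[3]};
  const double pp_init = par[4];
  const double ly_init = par[5];
  const double pp_mat_mean = par[6];
  const double ly_life_mean = par[7];
  const double sp = par[8];
  const double contact = par[9];

  const double r_ppc = rate[0];
  const double r_lyc = rate[1];
  const double r_aldeg = integrative ? rate[2] : 0.0;
  const double al_mean = rate[3];
  const double p_ap_in = rate[4];
  const double p_ly_in = rate[5];
  const double p_aply = rate[6];
  const double p_nonal = rate[7];
  const double p_alal = rate[8];
  const double p_reform = rate[9];

  const double ann2 = G.r_cell * G.r_cell - G.r_nuc * G.r_nuc;
  const double rn2 = G.r_nuc * G.r_nuc;

  // (1) creation: PP then LY, one spawn at a time (position u,v then the
  // kind's duration draw), matching spawn_agent()
  for (int pass = 0; pass < 2; pass++) {
    int kind = pass == 0 ? PP : LY;
    double lambda = pass == 0 ? r_ppc : r_lyc;
    int n_new = (int) ::Rf_rpois(lambda);
    for (int k = 0; k < n_new; k++) {
      double u = unif_rand(), v = unif_rand();
      double r = std::sqrt(u * ann2 + rn2);
      double th = 2.0 * M_PI * v;
      double px = r * std::cos(th), py = r * std::sin(th);
      if (kind == PP) {
        double mt = sample_duration(pp_mat_mean, fixed_dur);
        P.push(next_id++, PP, px, py, pp_init, tnow, mt, NA_REAL, 0,
               NA_REAL, 0, 0);
      } else {
        double lf = sample_duration(ly_life_mean, fixed_dur);
        P.push(next_id++, LY, px, py, ly_init, tnow, NA_REAL, lf, 0,
               NA_REAL, 0, 0);
      }
    }
  }

  size_t n = P.n();

  // (2) growth
  for (size_t i = 0; i < n; i++) P.size[i] += growth[P.kind[i]];

  // (3) maturation PP -> AP
  for (size_t i = 0; i < n; i++) {
    if (P.kind[i] == PP && (tnow - P.birth[i]) >= P.mat_time[i]) {
      P.kind[i] = AP;
      P.mat_time[i] = NA_REAL;
      P.cargo[i] = 0;
    }
  }

  // (4) movement: one uniform per agent in pool order
  for (size_t i = 0; i < n; i++) {
    double u = unif_rand();
    double fx = P.x[i], fy = P.y[i], tx, ty;
    if (P.kind[i] == PP || P.kind[i] == AL) {
      double th = 2.0 * M_PI * u;
      tx = fx + sp * std::cos(th);
      ty = fy + sp * std::sin(th);
    } else {
      double p_in = P.kind[i] == AP ? p_ap_in : p_ly_in;
      double r = std::sqrt(fx * fx + fy * fy);
      if (r == 0) r = 1;
      double sgn = u < p_in ? -1.0 : 1.0;
      tx = fx + sgn * sp * fx / r;
      ty = fy + sgn * sp * fy / r;
    }
    double r2 = tx * tx + ty * ty;
    if (r2 > G.r_cell * G.r_cell)
      clamp_point(fx, fy, tx, ty, G.r_cell, true, tx, ty);
    else if (G.r_nuc > 0 && r2 < rn2)
      clamp_point(fx, fy, tx, ty, G.r_nuc, false, tx, ty);
    P.x[i] = tx; P.y[i] = ty;
  }

  // (5) fusion: canonical (i < j) candidate list, randomised visit order
  std::vector<int> pi1, pi2;
  for (size_t i = 0; i + 1 < n; i++) {
    if (P.kind[i] == PP) continue;
    for (size_t j = i + 1; j < n; j++) {
      if (P.kind[j] == PP) continue;
      double dx = P.x[i] - P.x[j], dy = P.y[i] - P.y[j];
      double dd = std::sqrt(dx * dx + dy * dy);
      if (dd <= contact) { pi1.push_back((int) i); pi2.push_back((int) j); }
    }
  }
  if (!pi1.empty()) {
    std::vector<int> ord;
    sample_perm((int) pi1.size(), ord);
    std::vector<char> used(n, 0), drop(n, 0);
    for (size_t kk = 0; kk < ord.size(); kk++) {
      int i = pi1[ord[kk]], j = pi2[ord[kk]];
      if (used[i] || used[j]) continue;
      double pr = fusion_prob(P.kind[i], P.kind[j], p_aply, p_nonal, p_alal);
      if (pr <= 0) continue;
      double u = unif_rand();
      if (u >= pr) continue;
      used[i] = used[j] = 1;
      int ki = P.kind[i], kj = P.kind[j], surv, gone;
      if (ki != AL && kj != AL) {
        surv = i; gone = j;
        P.kind[surv] = AL;
        double mx = (P.x[i] + P.x[j]) / 2.0, my = (P.y[i] + P.y[j]) / 2.0;
        G.project_annulus(mx, my);
        P.x[surv] = mx;
        P.y[surv] = my;
        P.formed[surv] = tnow;
        P.birth[surv] = tnow;
        P.mat_time[surv] = NA_REAL;
        P.lifetime[surv] = integrative ? NA_REAL
                                       : sample_duration(al_mean, fixed_dur);
      } else if (ki == AL && kj == AL) {
        surv = (P.formed[j] < P.formed[i]) ? j : i;
        gone = (surv == i) ? j : i;
      } else {
        surv = (ki == AL) ? i : j;
        gone = (surv == i) ? j : i;
      }
      P.size[surv] = P.size[i] + P.size[j];
      P.cargo[surv] = P.cargo[i] + P.cargo[j];
      P.ingested[surv] = P.ingested[i] + P.ingested[j];
      P.released[surv] = P.released[i] + P.released[j];
      drop[gone] = 1;
    }
    bool any = false;
    for (size_t i = 0; i < n; i++) if (drop[i]) { any = true; break; }
    if (any) P.erase_where(drop);
    n = P.n();
  }

  // (6) degradation: LY/AL deaths, cargo release, lysosomal reformation
  std::vector<char> die(n, 0);
  for (size_t i = 0; i < n; i++) {
    if (P.kind[i] == LY) die[i] = (tnow - P.birth[i]) > P.lifetime[i];
    else if (P.kind[i] == AL && !integrative)
      die[i] = (tnow - P.formed[i]) > P.lifetime[i];
  }
  if (integrative) {
    for (size_t i = 0; i < n; i++)
      if (P.kind[i] == AL) die[i] = unif_rand() < r_aldeg;
  }
  std::vector<int> rel_idx;
  std::vector<double> rel_amt;
  Pool reformed;
  for (size_t i = 0; i < n; i++) {
    if (!die[i] || P.kind[i] != AL) continue;
    if (P.cargo[i] > 0) {
      rel_idx.push_back(G.flux_patch_of(P.x[i], P.y[i]));
      rel_amt.push_back(P.cargo[i]);
      P.released[i] += P.cargo[i];
      P.cargo[i] = 0;
    }
    if (unif_rand() < p_reform) {
      double lf = sample_duration(ly_life_mean, fixed_dur);
      reformed.push(next_id++, LY, P.x[i], P.y[i], ly_init, tnow, NA_REAL,
                    lf, 0, NA_REAL, 0, 0);
    }
  }
  {
    bool any = false;
    for (size_t i = 0; i < n; i++) if (die[i]) { any = true; break; }
    if (any) P.erase_where(die);
  }
  for (size_t i = 0; i < reformed.n(); i++)
    P.push(reformed.id[i], reformed.kind[i], reformed.x[i], reformed.y[i],
           reformed.size[i], reformed.birth[i], reformed.mat_time[i],
           reformed.lifetime[i], reformed.cargo[i], reformed.formed[i],
           reformed.ingested[i], reformed.released[i]);
  n = P.n();

  if (integrative) {
    int ncell = G.n * G.n;

    // cargo released by ALs that died this tick
    for (size_t k = 0; k < rel_idx.size(); k++) fr[rel_idx[k]] += rel_amt[k];

    const double influx = par[10];
    const double decay = par[11];
    const double convr = par[12];
    const double r_ly = par[13];
    const double r_ap = par[14];
    const double r_al = par[15];

    for (size_t k = 0; k < D.cells.size(); k++) {
      int c = D.cells[k];
      if (influx > 0 && G.border[c]) fr[c] += influx;
      if (decay_free) { fr[c] -= decay; if (fr[c] < 0) fr[c] = 0; }
      else { bo[c] -= decay; if (bo[c] < 0) bo[c] = 0; }
      double conv = convr < fr[c] ? convr : fr[c];
      fr[c] -= conv; bo[c] += conv;
    }
    for (size_t i = 0; i < n; i++) {
      if (P.kind[i] != LY) continue;
      int c = G.flux_patch_of(P.x[i], P.y[i]);
      double amt = r_ly < bo[c] ? r_ly : bo[c];
      bo[c] -= amt; fr[c] += amt;
    }
    for (size_t i = 0; i < n; i++) {
      if (P.kind[i] != AP) continue;
      int c = G.flux_patch_of(P.x[i], P.y[i]);
      double amt = r_ap < bo[c] ? r_ap : bo[c];
      bo[c] -= amt;
      P.cargo[i] += amt;
      P.ingested[i] += amt;
    }
    for (size_t i = 0; i < n; i++) {
      if (P.kind[i] != AL) continue;
      int c = G.flux_patch_of(P.x[i], P.y[i]);
      double amt = r_al < P.cargo[i] ? r_al : P.cargo[i];
      P.cargo[i] -= amt;
      P.released[i] += amt;
      fr[c] += amt;
    }

    // diffusion: share f/8 per neighbour, off-cytosol shares retained
    const double fdiff[2] = {par[16], par[17]};
    std::vector<double> tmp(ncell);
    for (int pool_i = 0; pool_i < 2; pool_i++) {
      double f = fdiff[pool_i];
      if (f <= 0) continue;
      double *A = pool_i == 0 ? fr : bo;
      int N = G.n;
      (void) N;
      for (int c = 0; c < ncell; c++) tmp[c] = A[c];
      // only cytosol patches hold nutrients; the source order of the
      // inflow sum mirrors the R padded-matrix formulation
      for (size_t k = 0; k < D.cells.size(); k++) {
        int c = D.cells[k];
        const int *nb = &D.nbr[8 * k];
        double inflow = 0;
        for (int q = 0; q < 8; q++)
          if (nb[q] >= 0) inflow += (f / 8.0) * tmp[nb[q]];
        A[c] = tmp[c] - (f / 8.0) * tmp[c] * G.neigh[c] + inflow;
      }
    }
  }

}

Geom geom_from(List grid, LogicalMatrix &cytm, LogicalMatrix &borm,
               NumericMatrix &neim, NumericVector &cenv) {
  Geom G;
  G.n = as<int>(grid["n"]);
  G.r_cell = as<double>(grid["r_cell"]);
  G.r_nuc = as<double>(grid["r_nuc"]);
  G.patch_size = as<double>(grid["patch_size"]);
  cytm = as<LogicalMatrix>(grid["cytosol"]);
  borm = as<LogicalMatrix>(grid["border"]);
  neim = as<NumericMatrix>(grid["neigh_count"]);
  cenv = as<NumericVector>(grid["centers"]);
  G.cytosol = LOGICAL(cytm); G.border = LOGICAL(borm);
  G.neigh = REAL(neim); G.centers = REAL(cenv);
  return G;
}

Pool pool_from(List pool_in) {
  Pool P;
  IntegerVector id = pool_in["id"], kind = pool_in["kind"];
  NumericVector x = pool_in["x"], y = pool_in["y"], sz = pool_in["size"],
      bi = pool_in["birth"], mt = pool_in["mat_time"],
      lt = pool_in["lifetime"], cg = pool_in["cargo"],
      fo = pool_in["formed"], ing = pool_in["ingested"],
      rel = pool_in["released"];
  P.id.assign(id.begin(), id.end());
  P.kind.assign(kind.begin(), kind.end());
  P.x.assign(x.begin(), x.end()); P.y.assign(y.begin(), y.end());
  P.size.assign(sz.begin(), sz.end());
  P.birth.assign(bi.begin(), bi.end());
  P.mat_time.assign(mt.begin(), mt.end());
  P.lifetime.assign(lt.begin(), lt.end());
  P.cargo.assign(cg.begin(), cg.end());
  P.formed.assign(fo.begin(), fo.end());
  P.ingested.assign(ing.begin(), ing.end());
  P.released.assign(rel.begin(), rel.end());
  return P;
}

List pool_to_r(const Pool &P) {
  List pool_out = List::create(
      Named("id") = IntegerVector(P.id.begin(), P.id.end()),
      Named("kind") = IntegerVector(P.kind.begin(), P.kind.end()),
      Named("x") = NumericVector(P.x.begin(), P.x.end()),
      Named("y") = NumericVector(P.y.begin(), P.y.end()),
      Named("size") = NumericVector(P.size.begin(), P.size.end()),
      Named("birth") = NumericVector(P.birth.begin(), P.birth.end()),
      Named("mat_time") = NumericVector(P.mat_time.begin(), P.mat_time.end()),
      Named("lifetime") = NumericVector(P.lifetime.begin(), P.lifetime.end()),
      Named("cargo") = NumericVector(P.cargo.begin(), P.cargo.end()),
      Named("formed") = NumericVector(P.formed.begin(), P.formed.end()),
      Named("ingested") = NumericVector(P.ingested.begin(), P.ingested.end()),
      Named("released") = NumericVector(P.released.begin(), P.released.end()));
  pool_out.attr("class") = "agent_pool";
  return pool_out;
}

} // namespace

// Packed argument layout (built by the R wrappers; positions fixed):
// par: pp_growth, ap_growth, ly_growth, al_growth, pp_initial_size,
//      ly_initial_size, pp_maturation_mean, ly_lifetime_mean,
//      movement_speed, contact_radius, influx_eff (border_influx *
//      uptake_scale), free_decay, conv_eff (conversion_rate *
//      metabolism_scale), ly_recycling, ap_uptake, al_release,
//      free_diffusion, bound_diffusion
// rate: pp_creation, ly_creation, al_degradation, al_lifetime_mean,
//      ap_toward_nucleus, ly_toward_nucleus, ap_ly_fusion,
//      fusion_nonAL_AL, fusion_AL_AL, reformation
// flags: integrative, fixed_durations, decay_on_free
// [[Rcpp::export(name = ".tick_cpp")]]
List tick_cpp(List pool_in, NumericVector par, NumericVector rate,
              List grid,
              Nullable<NumericMatrix> free_in,
              Nullable<NumericMatrix> bound_in,
              double tnow, int next_id, LogicalVector flags) {
  const bool integrative = flags[0];
  Pool P = pool_from(pool_in);
  LogicalMatrix cytm, borm; NumericMatrix neim; NumericVector cenv;
  Geom G = geom_from(grid, cytm, borm, neim, cenv);

  NumericMatrix free_out, bound_out;
  double *fr = 0, *bo = 0;
  if (integrative) {
    NumericMatrix fin(free_in.get()), bin(bound_in.get());
    free_out = clone(fin);
    bound_out = clone(bin);
    fr = REAL(free_out); bo = REAL(bound_out);
  }
  DiffCache D;
  if (integrative) D.build(G);
  RNGScope scope;
  do_tick(P, G, D, REAL(par), REAL(rate), integrative, flags[1], flags[2],
          tnow, next_id, fr, bo);

  if (integrative)
    return List::create(Named("pool") = pool_to_r(P),
                        Named("free") = free_out,
                        Named("bound") = bound_out,
                        Named("next_id") = next_id);
  return List::create(Named("pool") = pool_to_r(P),
                      Named("next_id") = next_id);
}

// Whole-run loop: recomputes the nutrient-coupled effective rates each
// tick and records the census, exactly as the R tick loop does.
// nmod: pp_base, pp_lin, pp_exp, ly_base, ly_lin, ly_exp, al_base,
//       al_lin, al_exp, baf_factor_eff, ly_toward_base, ly_slope,
//       ap_toward_eff, al_lifetime_eff, agent_cap, free_baseline,
//       reformation, ap_ly_fusion, fusion_nonAL_AL, fusion_AL_AL
// [[Rcpp::export(name = ".run_cpp")]]
List run_cpp(List pool_in, NumericVector par, NumericVector nmod,
             List grid,
             Nullable<NumericMatrix> free_in,
             Nullable<NumericMatrix> bound_in,
             int duration, int next_id, LogicalVector flags,
             double delta0) {
  const bool integrative = flags[0];
  Pool P = pool_from(pool_in);
  LogicalMatrix cytm, borm; NumericMatrix neim; NumericVector cenv;
  Geom G = geom_from(grid, cytm, borm, neim, cenv);
  IntegerVector cyt1 = grid["cyto_idx"];
  const int ncyt = cyt1.size();
  std::vector<int> cyt0(ncyt);
  for (int k = 0; k < ncyt; k++) cyt0[k] = cyt1[k] - 1;

  NumericMatrix free_out, bound_out;
  double *fr = 0, *bo = 0;
  if (integrative) {
    NumericMatrix fin(free_in.get()), bin(bound_in.get());
    free_out = clone(fin);
    bound_out = clone(bin);
    fr = REAL(free_out); bo = REAL(bound_out);
  }
  const int ncell = G.n * G.n;

  const double pp_base = nmod[0], pp_lin = nmod[1], pp_exp = nmod[2];
  const double ly_base = nmod[3], ly_lin = nmod[4], ly_exp = nmod[5];
  const double al_base = nmod[6], al_lin = nmod[7], al_exp = nmod[8];
  const double baf_f = nmod[9];
  const double lyt_base = nmod[10], ly_slope = nmod[11];
  const double ap_tow = nmod[12], al_life = nmod[13];
  const double cap = nmod[14], baseline = nmod[15];
  const double p_reform = nmod[16], p_aply = nmod[17];
  const double p_nonal = nmod[18], p_alal = nmod[19];

  DiffCache D;
  if (integrative) D.build(G);
  NumericMatrix rec(duration + 1, 12);
  double delta = delta0;
  int aborted = 0;
  int nrow_used = 0;

  RNGScope scope;
  for (int t = 0; t <= duration; t++) {
    if (t > 0) {
      double rate[10];
      rate[0] = pp_base * (pp_lin * std::pow(delta, pp_exp) + 1.0);
      rate[1] = ly_base * (ly_lin * std::pow(delta, ly_exp) + 1.0);
      double ad = al_base * (al_lin * std::pow(delta, al_exp) + 1.0) * baf_f;
      rate[2] = ad < 1.0 ? ad : 1.0;
      rate[3] = al_life;
      rate[4] = ap_tow;
      double lt = lyt_base + ly_slope * delta;
      rate[5] = lt < 1.0 ? lt : 1.0;
      rate[6] = p_aply;
      rate[7] = p_nonal;
      rate[8] = p_alal;
      rate[9] = p_reform;
      do_tick(P, G, D, REAL(par), rate, integrative, flags[1], flags[2],
              (double) t, next_id, fr, bo);
      if (integrative) {
        double s = 0;
        for (int k = 0; k < ncyt; k++) s += fr[cyt0[k]];
        double m = s / (double) ncyt;
        delta = baseline - m;
        if (delta < 0) delta = 0;
      }
    }
    // census row: tick, counts, mean sizes, nutrient means, delta
    int cnt[5] = {0, 0, 0, 0, 0};
    double ssz[5] = {0, 0, 0, 0, 0};
    for (size_t i = 0; i < P.n(); i++) {
      cnt[P.kind[i]]++;
      ssz[P.kind[i]] += P.size[i];
    }
    rec(nrow_used, 0) = t;
    for (int k = 1; k <= 4; k++) {
      rec(nrow_used, k) = cnt[k];
      rec(nrow_used, 4 + k) = cnt[k] > 0 ? ssz[k] / cnt[k] : 0.0;
    }
    if (integrative) {
      double sf = 0, sb = 0;
      for (int c = 0; c < ncell; c++) { sf += fr[c]; sb += bo[c]; }
      rec(nrow_used, 9) = sf / (double) ncyt;
      rec(nrow_used, 10) = sb / (double) ncyt;
    } else {
      rec(nrow_used, 9) = NA_REAL;
      rec(nrow_used, 10) = NA_REAL;
    }
    rec(nrow_used, 11) = delta;
    nrow_used++;
    if (t > 0) {
      if ((double) P.n() > cap) { aborted = 1; break; }
      if (integrative) {
        double sf = 0;
        for (int c = 0; c < ncell; c++) sf += fr[c];
        if (sf <= 0) { aborted = 2; break; }
      }
    }
  }

  List out = List::create(
      Named("record") = rec, Named("nrow") = nrow_used,
      Named("pool") = pool_to_r(P), Named("next_id") = next_id,
      Named("aborted") = aborted, Named("delta") = delta);
  if (integrative) {
    out["free"] = free_out;
    out["bound"] = bound_out;
  }
  return out;
}
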