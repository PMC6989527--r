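// Metropolis Monte-Carlo engine for the coarse-grained binding models:
// canonical sampling and multicanonical (flat-histogram) sampling on a
// tabulated log density of states.
// Uses R's RNG so runs are bit-reproducible under set.seed().
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double KB = 0.0019872; // kcal/mol/K

struct Pack {
  bool harmonic;
  double hk;
  int hdims;
  int nrec, nlig, ntot;
  NumericMatrix rec_ref;     // nrec x 3 reference positions (tether targets)
  std::vector<int> mobile;   // 0-based indices of movable beads (loops + ligand)
  std::vector<int> loops;    // 0-based receptor loop bead indices
  double tether_k;
  double bond_r0, k_bond, theta0, k_angle;
  IntegerMatrix con;         // m x 2 global 0-based (receptor idx, ligand global idx)
  NumericVector con_eps, con_sigma;
  IntegerMatrix rep_pairs;   // p x 2 global 0-based
  double d_ex, eps_rep;      // excluded-volume diameter and prefactor
  bool cyl_on;
  double cox, coy, coz;      // cylinder origin
  double ax, ay, az, vx, vy, vz, zx, zy, zz; // axis + transverse basis
  double lam_min, lam_max, radius, k_perp, k_par, half;
  bool bias_on;
  double bias_k, bias_c;
};

static Pack unpack(const List& p) {
  Pack s;
  s.harmonic = as<bool>(p["harmonic"]);
  if (s.harmonic) {
    s.hk = as<double>(p["hk"]);
    s.hdims = as<int>(p["hdims"]);
    s.nrec = 0; s.nlig = 1; s.ntot = 1;
    s.mobile.push_back(0);
    s.tether_k = 0; s.k_bond = 0; s.k_angle = 0; s.bond_r0 = 0; s.theta0 = 0;
    s.d_ex = 0; s.eps_rep = 0;
  } else {
    s.hk = 0; s.hdims = 0;
    s.rec_ref = as<NumericMatrix>(p["rec_ref"]);
    s.nrec = s.rec_ref.nrow();
    s.nlig = as<int>(p["nlig"]);
    s.ntot = s.nrec + s.nlig;
    IntegerVector lp = p["loops"]; // 0-based
    for (int i = 0; i < lp.size(); i++) s.loops.push_back(lp[i]);
    for (size_t i = 0; i < s.loops.size(); i++) s.mobile.push_back(s.loops[i]);
    for (int i = 0; i < s.nlig; i++) s.mobile.push_back(s.nrec + i);
    s.tether_k = as<double>(p["tether_k"]);
    s.bond_r0 = as<double>(p["bond_r0"]);
    s.k_bond = as<double>(p["k_bond"]);
    s.theta0 = as<double>(p["theta0"]);
    s.k_angle = as<double>(p["k_angle"]);
    s.con = as<IntegerMatrix>(p["con"]);
    s.con_eps = as<NumericVector>(p["con_eps"]);
    s.con_sigma = as<NumericVector>(p["con_sigma"]);
    s.rep_pairs = as<IntegerMatrix>(p["rep_pairs"]);
    s.d_ex = as<double>(p["d_ex"]);
    s.eps_rep = as<double>(p["eps_rep"]);
  }
  s.cyl_on = as<bool>(p["cyl_on"]);
  {
    NumericVector o = p["cyl_origin"], a = p["cyl_axis"], v = p["cyl_v"], z = p["cyl_z"];
    s.cox = o[0]; s.coy = o[1]; s.coz = o[2];
    s.ax = a[0]; s.ay = a[1]; s.az = a[2];
    s.vx = v[0]; s.vy = v[1]; s.vz = v[2];
    s.zx = z[0]; s.zy = z[1]; s.zz = z[2];
    s.lam_min = as<double>(p["lam_min"]);
    s.lam_max = as<double>(p["lam_max"]);
    s.radius = as<double>(p["radius"]);
    s.k_perp = as<double>(p["k_perp"]);
    s.k_par = as<double>(p["k_par"]);
    s.half = as<double>(p["half"]);
  }
  s.bias_on = as<bool>(p["bias_on"]);
  s.bias_k = s.bias_on ? as<double>(p["bias_k"]) : 0.0;
  s.bias_c = s.bias_on ? as<double>(p["bias_c"]) : 0.0;
  return s;
}

static inline double dist3(const NumericMatrix& x, int i, int j) {
  double dx = x(i,0) - x(j,0), dy = x(i,1) - x(j,1), dz = x(i,2) - x(j,2);
  return std::sqrt(dx*dx + dy*dy + dz*dz);
}

// system potential: bonds + angles + Go contacts + excluded volume
static double e_system(const Pack& s, const NumericMatrix& x) {
  if (s.harmonic) {
    double e = 0;
    for (int d = 0; d < s.hdims; d++) e += x(0,d) * x(0,d);
    return 0.5 * s.hk * e;
  }
  double e = 0;
  int off = s.nrec;
  for (int i = 0; i + 1 < s.nlig; i++) {
    double d = dist3(x, off + i, off + i + 1);
    double dd = d - s.bond_r0;
    e += s.k_bond * dd * dd;
  }
  for (int i = 1; i + 1 < s.nlig; i++) {
    double ax = x(off+i-1,0) - x(off+i,0), ay = x(off+i-1,1) - x(off+i,1), az = x(off+i-1,2) - x(off+i,2);
    double bx = x(off+i+1,0) - x(off+i,0), by = x(off+i+1,1) - x(off+i,1), bz = x(off+i+1,2) - x(off+i,2);
    double na = std::sqrt(ax*ax + ay*ay + az*az), nb = std::sqrt(bx*bx + by*by + bz*bz);
    double c = (ax*bx + ay*by + az*bz) / (na * nb);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double dth = std::acos(c) - s.theta0;
    e += s.k_angle * dth * dth;
  }
  for (int m = 0; m < s.con.nrow(); m++) {
    double r = dist3(x, s.con(m,0), s.con(m,1));
    double q = s.con_sigma[m] / r;
    double q2 = q*q, q10 = q2*q2*q2*q2*q2, q12 = q10*q2;
    e += s.con_eps[m] * (5.0 * q12 - 6.0 * q10);
  }
  for (int m = 0; m < s.rep_pairs.nrow(); m++) {
    double r = dist3(x, s.rep_pairs(m,0), s.rep_pairs(m,1));
    if (r < s.d_ex) {
      double q = s.d_ex / r;
      double q2 = q*q, q12 = q2*q2*q2*q2*q2*q2;
      e += s.eps_rep * (q12 - 1.0);
    }
  }
  return e;
}

static double e_tether(const Pack& s, const NumericMatrix& x) {
  if (s.harmonic || s.tether_k <= 0) return 0;
  double e = 0;
  for (size_t i = 0; i < s.loops.size(); i++) {
    int b = s.loops[i];
    double dx = x(b,0) - s.rec_ref(b,0), dy = x(b,1) - s.rec_ref(b,1), dz = x(b,2) - s.rec_ref(b,2);
    e += s.tether_k * (dx*dx + dy*dy + dz*dz);
  }
  return e;
}

static void lig_com(const Pack& s, const NumericMatrix& x, double* c) {
  c[0] = c[1] = c[2] = 0;
  int off = s.nrec;
  for (int i = 0; i < s.nlig; i++) {
    c[0] += x(off+i,0); c[1] += x(off+i,1); c[2] += x(off+i,2);
  }
  c[0] /= s.nlig; c[1] /= s.nlig; c[2] /= s.nlig;
}

static void lvz(const Pack& s, const double* c, double* out) {
  double dx = c[0]-s.cox, dy = c[1]-s.coy, dz = c[2]-s.coz;
  out[0] = dx*s.ax + dy*s.ay + dz*s.az;
  out[1] = dx*s.vx + dy*s.vy + dz*s.vz;
  out[2] = dx*s.zx + dy*s.zy + dz*s.zz;
}

static double e_cyl(const Pack& s, const double* lvzc) {
  if (!s.cyl_on) return 0;
  double e = 0;
  double r = std::sqrt(lvzc[1]*lvzc[1] + lvzc[2]*lvzc[2]);
  if (r > s.radius) { double d = r - s.radius; e += s.k_perp * d * d; }
  if (lvzc[0] > s.lam_max) { double d = lvzc[0] - s.lam_max; e += s.k_par * d * d; }
  if (lvzc[0] < s.lam_min) { double d = s.lam_min - lvzc[0]; e += s.k_par * d * d; }
  return s.half * e;
}

static double e_bias(const Pack& s, double lam) {
  if (!s.bias_on) return 0;
  double d = lam - s.bias_c;
  return s.bias_k * d * d;
}

// [[Rcpp::export]]
double cpp_system_energy(List pack, NumericMatrix coords) {
  Pack s = unpack(pack);
  return e_system(s, coords);
}

// [[Rcpp::export]]
double cpp_full_energy(List pack, NumericMatrix coords) {
  Pack s = unpack(pack);
  double com[3], c3[3];
  if (s.harmonic) {
    com[0] = coords(0,0);
    com[1] = s.hdims > 1 ? coords(0,1) : 0.0;
    com[2] = s.hdims > 2 ? coords(0,2) : 0.0;
  } else lig_com(s, coords, com);
  lvz(s, com, c3);
  return e_system(s, coords) + e_tether(s, coords) + e_cyl(s, c3);
}

// piecewise-linear interpolation of ln n(E) with canonical-slope extrapolation
static double lndos_at(const NumericVector& grid, const NumericVector& lnd,
                       double bl, double bh, double E) {
  int n = grid.size();
  if (E <= grid[0]) return lnd[0] + bl * (E - grid[0]);
  if (E >= grid[n-1]) return lnd[n-1] + bh * (E - grid[n-1]);
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) { int mid = (lo + hi) / 2; if (grid[mid] <= E) lo = mid; else hi = mid; }
  double f = (E - grid[lo]) / (grid[hi] - grid[lo]);
  return lnd[lo] + f * (lnd[hi] - lnd[lo]);
}

// [[Rcpp::export]]
NumericVector cpp_lndos_interp(NumericVector grid, NumericVector lnd,
                               double slope_lo, double slope_hi, NumericVector E) {
  NumericVector out(E.size());
  for (int i = 0; i < E.size(); i++) out[i] = lndos_at(grid, lnd, slope_lo, slope_hi, E[i]);
  return out;
}

struct MoveState {
  NumericMatrix x;
  double e_sys, e_teth, lam, v, zeta, e_restr; // e_restr = cyl only
};

static void recompute(const Pack& s, MoveState& st) {
  double com[3], c3[3];
  st.e_sys = e_system(s, st.x);
  st.e_teth = e_tether(s, st.x);
  if (s.harmonic) {
    com[0] = st.x(0,0);
    com[1] = s.hdims > 1 ? st.x(0,1) : 0.0;
    com[2] = s.hdims > 2 ? st.x(0,2) : 0.0;
  } else lig_com(s, st.x, com);
  lvz(s, com, c3);
  st.lam = c3[0]; st.v = c3[1]; st.zeta = c3[2];
  st.e_restr = e_cyl(s, c3);
}

// propose a move into xnew (copy of x already); kind: 0 bead, 1 trans, 2 rot
static void propose(const Pack& s, const NumericMatrix& x, NumericMatrix& xnew,
                    double bead_step, double trans_step, double rot_step,
                    double p_trans, double p_rot) {
  int n = s.ntot;
  for (int i = 0; i < n; i++) for (int d = 0; d < 3; d++) xnew(i,d) = x(i,d);
  if (s.harmonic) {
    for (int d = 0; d < s.hdims; d++) xnew(0,d) += (unif_rand() * 2.0 - 1.0) * bead_step;
    return;
  }
  double u = unif_rand();
  if (u < p_trans && s.nlig > 0) {
    double tx = (unif_rand()*2-1)*trans_step, ty = (unif_rand()*2-1)*trans_step, tz = (unif_rand()*2-1)*trans_step;
    for (int i = 0; i < s.nlig; i++) {
      xnew(s.nrec+i,0) += tx; xnew(s.nrec+i,1) += ty; xnew(s.nrec+i,2) += tz;
    }
  } else if (u < p_trans + p_rot && s.nlig > 1) {
    // rigid rotation about ligand COM, Rodrigues formula
    double com[3]; lig_com(s, x, com);
    double ux = norm_rand(), uy = norm_rand(), uz = norm_rand();
    double nu = std::sqrt(ux*ux + uy*uy + uz*uz);
    if (nu < 1e-12) { ux = 1; uy = 0; uz = 0; nu = 1; }
    ux /= nu; uy /= nu; uz /= nu;
    double th = (unif_rand()*2-1) * rot_step;
    double ct = std::cos(th), st = std::sin(th);
    for (int i = 0; i < s.nlig; i++) {
      double px = x(s.nrec+i,0)-com[0], py = x(s.nrec+i,1)-com[1], pz = x(s.nrec+i,2)-com[2];
      double dot = ux*px + uy*py + uz*pz;
      double cx = uy*pz - uz*py, cy = uz*px - ux*pz, cz = ux*py - uy*px;
      xnew(s.nrec+i,0) = com[0] + px*ct + cx*st + ux*dot*(1-ct);
      xnew(s.nrec+i,1) = com[1] + py*ct + cy*st + uy*dot*(1-ct);
      xnew(s.nrec+i,2) = com[2] + pz*ct + cz*st + uz*dot*(1-ct);
    }
  } else {
    int b = s.mobile[(int)std::floor(unif_rand() * s.mobile.size())];
    for (int d = 0; d < 3; d++) xnew(b,d) += (unif_rand()*2-1) * bead_step;
  }
}

// [[Rcpp::export]]
List cpp_run_mc(List pack, NumericMatrix coords0, double T, bool muca,
                NumericVector grid, NumericVector lnd, double slope_lo, double slope_hi,
                int n_steps, int thin,
                double bead_step, double trans_step, double rot_step,
                double p_trans, double p_rot, bool store_coords) {
  Pack s = unpack(pack);
  MoveState cur, prop;
  cur.x = clone(coords0);
  prop.x = NumericMatrix(s.ntot, 3);
  recompute(s, cur);
  double e_cur = cur.e_sys + cur.e_teth + cur.e_restr;             // recorded energy
  if (!R_finite(e_cur)) stop("non-finite starting energy");
  double beta = 1.0 / (KB * T);
  int n_frames = n_steps / thin;
  NumericVector fe(n_frames), flam(n_frames), fv(n_frames), fz(n_frames);
  IntegerVector fstep(n_frames);
  NumericVector fcoords(store_coords ? (R_xlen_t)n_frames * s.ntot * 3 : 0);
  long accepted = 0;
  int fi = 0;
  for (int step = 1; step <= n_steps; step++) {
    propose(s, cur.x, prop.x, bead_step, trans_step, rot_step, p_trans, p_rot);
    recompute(s, prop);
    double e_new = prop.e_sys + prop.e_teth + prop.e_restr;
    double lnacc;
    if (muca) {
      lnacc = lndos_at(grid, lnd, slope_lo, slope_hi, e_cur)
            - lndos_at(grid, lnd, slope_lo, slope_hi, e_new);
    } else {
      double de = (e_new + e_bias(s, prop.lam)) - (e_cur + e_bias(s, cur.lam));
      lnacc = -beta * de;
    }
    if (lnacc >= 0 || unif_rand() < std::exp(lnacc)) {
      std::swap(cur.x, prop.x);
      cur.e_sys = prop.e_sys; cur.e_teth = prop.e_teth; cur.e_restr = prop.e_restr;
      cur.lam = prop.lam; cur.v = prop.v; cur.zeta = prop.zeta;
      e_cur = e_new;
      accepted++;
    }
    if (step % thin == 0 && fi < n_frames) {
      fe[fi] = e_cur; flam[fi] = cur.lam; fv[fi] = cur.v; fz[fi] = cur.zeta;
      fstep[fi] = step;
      if (store_coords) {
        double* base = REAL(fcoords) + (R_xlen_t)fi * s.ntot * 3;
        for (int i = 0; i < s.ntot; i++)
          for (int d = 0; d < 3; d++) base[i + d * s.ntot] = cur.x(i,d);
      }
      fi++;
    }
  }
  if (store_coords)
    fcoords.attr("dim") = IntegerVector::create(s.ntot, 3, n_frames);
  return List::create(_["coords"] = store_coords ? (SEXP)fcoords : R_NilValue,
                      _["energy"] = fe,
                      _["lam"] = flam, _["v"] = fv, _["zeta"] = fz,
                      _["step"] = fstep,
                      _["acceptance"] = (double)accepted / n_steps,
                      _["final_coords"] = cur.x);
}
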