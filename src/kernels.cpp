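// Core time-stepping kernels: MAC-staggered projection solver for the
// incompressible momentum equation with penalized solid regions (exterior
// wall, mobile intimal flap) and the Brinkman-type thrombus momentum sink,
// plus the four-species thrombosis transport step and per-cycle ledger
// accumulation.
//
// Grid convention (0-based): cells (i, j), i = 0..nx-1, j = 0..ny-1.
//   u: (nx+1) x ny   at vertical faces   (u(i,j) between cells i-1 and i)
//   v:  nx x (ny+1)  at horizontal faces (v(i,j) between cells j-1 and j)
//   p, species, mu, gamma: nx x ny at cell centers
// dx uniform; dy(j) variable per row.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// van Leer (harmonic) limited slope
static inline double minmod(double a, double b) {
  if (a * b <= 0.0) return 0.0;
  return 2.0 * a * b / (a + b);
}

// MUSCL face value between nodes k (c0) and k+1 (cp1); vel is the advecting
// velocity at the face. Passing cm1 == c0 (or cp2 == cp1) degrades to
// first-order upwind, which is how boundary-adjacent faces are handled.
static inline double muscl_face(double cm1, double c0, double cp1, double cp2,
                                double vel) {
  if (vel >= 0.0) return c0 + 0.5 * minmod(c0 - cm1, cp1 - c0);
  return cp1 - 0.5 * minmod(cp1 - c0, cp2 - cp1);
}

struct Grid {
  int nx, ny;
  double dx;
  std::vector<double> dy, dyc; // dy: ny; dyc(j) = yc(j+1)-yc(j): ny-1
};

struct Quemada {
  bool use_const;
  double mu_const, mu_p, H, k0, kinf, gamma_c, gamma_min;
  double visc(double g) const {
    if (use_const) return mu_const;
    double gg = g < gamma_min ? gamma_min : g;
    double s = std::sqrt(gg / gamma_c);
    double k = (k0 + kinf * s) / (1.0 + s);
    double d = 1.0 - 0.5 * k * H;
    return mu_p / (d * d);
  }
};

#define U(i, j) u[(i) + (j) * (nx + 1)]
#define V(i, j) v[(i) + (j) * nx]
#define P(i, j) p[(i) + (j) * nx]
#define CC(a, i, j) a[(i) + (j) * nx]

// ---------------------------------------------------------------------------
// Jacobi-preconditioned conjugate gradient for the pressure Poisson system.
// Operator: for each cell, sum_faces g_f (p - p_nb) [+ g_dir (p - p_bc)],
// with g coefficients precomputed. Matrix-free, warm-started.
struct Poisson {
  int nx, ny, n;
  std::vector<double> gW, gE, gS, gN, gD, diag; // gD: Dirichlet face coef
  std::vector<double> r, z, pk, Ap;
  void apply(const double* x, double* y) const {
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = i + j * nx;
        double s = diag[c] * x[c];
        if (i > 0) s -= gW[c] * x[c - 1];
        if (i < nx - 1) s -= gE[c] * x[c + 1];
        if (j > 0) s -= gS[c] * x[c - nx];
        if (j < ny - 1) s -= gN[c] * x[c + nx];
        y[c] = s;
      }
  }
  // solves A x = b in place; returns iterations used
  int solve(std::vector<double>& x, const std::vector<double>& b,
            double rtol, int maxit) {
    r.assign(n, 0.0); z.assign(n, 0.0); pk.assign(n, 0.0); Ap.assign(n, 0.0);
    apply(x.data(), Ap.data());
    double bnorm = 0.0;
    for (int c = 0; c < n; ++c) { r[c] = b[c] - Ap[c]; bnorm += b[c] * b[c]; }
    bnorm = std::sqrt(bnorm);
    double tol = rtol * (bnorm > 1e-300 ? bnorm : 1.0);
    double rz = 0.0;
    for (int c = 0; c < n; ++c) { z[c] = r[c] / diag[c]; pk[c] = z[c]; rz += r[c] * z[c]; }
    int it = 0;
    for (; it < maxit; ++it) {
      double rn = 0.0;
      for (int c = 0; c < n; ++c) rn += r[c] * r[c];
      if (std::sqrt(rn) <= tol) break;
      apply(pk.data(), Ap.data());
      double pAp = 0.0;
      for (int c = 0; c < n; ++c) pAp += pk[c] * Ap[c];
      if (pAp <= 0.0) break;
      double alpha = rz / pAp;
      for (int c = 0; c < n; ++c) { x[c] += alpha * pk[c]; r[c] -= alpha * Ap[c]; }
      double rz_new = 0.0;
      for (int c = 0; c < n; ++c) { z[c] = r[c] / diag[c]; rz_new += r[c] * z[c]; }
      double beta = rz_new / rz; rz = rz_new;
      for (int c = 0; c < n; ++c) pk[c] = z[c] + beta * pk[c];
    }
    return it;
  }
};

// Thomas algorithm, solves tridiagonal in place (a sub, b diag, c super)
static void thomas(std::vector<double>& a, std::vector<double>& b,
                   std::vector<double>& c, std::vector<double>& d, int n) {
  for (int k = 1; k < n; ++k) {
    double m = a[k] / b[k - 1];
    b[k] -= m * c[k - 1];
    d[k] -= m * d[k - 1];
  }
  d[n - 1] /= b[n - 1];
  for (int k = n - 2; k >= 0; --k) d[k] = (d[k] - c[k] * d[k + 1]) / b[k];
}

// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_advance(List st, List gr, List par, int nsteps) {
  // --- unpack grid ---------------------------------------------------------
  const int nx = as<int>(gr["nx"]), ny = as<int>(gr["ny"]);
  const double dx = as<double>(gr["dx"]);
  NumericVector dyR = gr["dy"];
  Grid G; G.nx = nx; G.ny = ny; G.dx = dx;
  G.dy.assign(dyR.begin(), dyR.end());
  G.dyc.resize(ny - 1);
  for (int j = 0; j < ny - 1; ++j) G.dyc[j] = 0.5 * (G.dy[j] + G.dy[j + 1]);
  IntegerVector ctypeR = gr["cell_type"]; // 0 exterior, 1 fluid, 2 flap
  // facets for WSS / species BCs
  IntegerVector fi = gr["facet_i"], fj = gr["facet_j"], fside = gr["facet_side"];
  NumericVector flen = gr["facet_len"];
  LogicalVector fwall = gr["facet_is_wall"]; // species BCs act on walls only
  const int nfac = fi.size();
  // inlet fluid rows (west velocity BC), outlet rows (east pressure BC)
  IntegerVector inlet_rows = gr["inlet_rows"], outlet_rows = gr["outlet_rows"];
  std::vector<bool> is_inlet_row(ny, false), is_outlet_row(ny, false);
  for (int k = 0; k < inlet_rows.size(); ++k) is_inlet_row[inlet_rows[k]] = true;
  for (int k = 0; k < outlet_rows.size(); ++k) is_outlet_row[outlet_rows[k]] = true;

  // flap geometry (may be empty for channels)
  IntegerVector flap_cols = gr["flap_cols"];     // 0-based columns with flap material
  NumericVector flap_y0v = gr["flap_y0"];        // scalar: rest lower face
  NumericVector flap_y1v = gr["flap_y1"];
  IntegerVector flap_row_lo = gr["flap_row_lo"], flap_row_hi = gr["flap_row_hi"];
  NumericVector yfR = gr["y_faces"];
  std::vector<double> yf(yfR.begin(), yfR.end());

  // --- unpack parameters ---------------------------------------------------
  const double rho = as<double>(par["rho"]);
  const double dt = as<double>(par["dt"]);
  const double kM = as<double>(par["k_M"]);
  const double BPt_sink = as<double>(par["BP_t_sink"]);
  const double k_pen = as<double>(par["k_pen"]);
  const bool advance_flow = as<bool>(par["advance_flow"]);
  const bool species_on = as<bool>(par["species_on"]);
  const bool flap_on = as<bool>(par["flap_on"]);
  const int west_bc = as<int>(par["west_bc"]);   // 0 velocity, 1 pressure
  const int east_bc = as<int>(par["east_bc"]);   // 1 pressure, 2 windkessel
  NumericVector inletU = par["inlet_u"];         // per-step inlet speed
  NumericVector westP = par["west_p"], eastP = par["east_p"]; // per-step
  NumericVector fxv = par["fx"];                 // per-step body force, N/m^3
  const double cg_rtol = as<double>(par["cg_rtol"]);
  const int cg_maxit = as<int>(par["cg_maxit"]);

  Quemada Q;
  Q.use_const = as<bool>(par["mu_is_const"]);
  Q.mu_const = as<double>(par["mu_const"]);
  Q.mu_p = as<double>(par["mu_p"]); Q.H = as<double>(par["hct"]);
  Q.k0 = as<double>(par["qk0"]); Q.kinf = as<double>(par["qkinf"]);
  Q.gamma_c = as<double>(par["qgc"]); Q.gamma_min = as<double>(par["qgmin"]);

  // thrombosis constants
  const double D_RP = as<double>(par["D_RP"]), D_AP = as<double>(par["D_AP"]);
  const double D_C = as<double>(par["D_C_base"]);
  const double k_RP = as<double>(par["k_RP"]), k_AP = as<double>(par["k_AP"]);
  const double k_C1 = as<double>(par["k_C1"]), k_C2 = as<double>(par["k_C2"]);
  const double k_BP = as<double>(par["k_BP"]);
  const double gt = as<double>(par["gamma_t"]);
  const double APt = as<double>(par["AP_t"]), Ct = as<double>(par["C_t"]);
  const double BPt = as<double>(par["BP_t"]);
  const double tawss_thr = as<double>(par["TAWSS_threshold"]);
  const double c_wall_src = as<double>(par["c_wall_flux_density"]); // nmol/L m/s
  const double wall_conc = as<double>(par["wall_relative_concentration"]);
  const bool literal_switch = as<bool>(par["literal_shear_switch"]);
  const bool species_adv = as<bool>(par["species_advection"]);
  const bool wall_flux_on = as<bool>(par["wall_flux_on"]);
  const bool reactions_on = as<bool>(par["reactions_on"]);

  // windkessel
  const double wkC = as<double>(par["wk_C"]), wkRp = as<double>(par["wk_Rp"]);
  const double wkRc = as<double>(par["wk_Rc"]);

  // flap reduced-order model
  NumericMatrix Minv = par["flap_Minv"];   // n_st x n_st (may be 0 x 0)
  const double flap_relax = as<double>(par["flap_relax"]);
  const double flap_cap = as<double>(par["flap_cap"]);
  LogicalVector flap_tear = par["flap_tear"];  // per station: inside a tear?

  // --- unpack state (cloned: caller keeps its copy) ------------------------
  NumericVector u = clone(as<NumericVector>(st["u"]));
  NumericVector v = clone(as<NumericVector>(st["v"]));
  NumericVector p = clone(as<NumericVector>(st["p"]));
  NumericVector RP = clone(as<NumericVector>(st["RP"]));
  NumericVector AP = clone(as<NumericVector>(st["AP"]));
  NumericVector Cc = clone(as<NumericVector>(st["C"]));
  NumericVector BP = clone(as<NumericVector>(st["BP"]));
  NumericVector flap_w = clone(as<NumericVector>(st["flap_w"]));
  NumericVector tawss_prev = clone(as<NumericVector>(st["tawss_prev"]));
  double pwk = as<double>(st["pwk"]);
  double tcur = as<double>(st["t"]);
  // last boundary pressures already imprinted on the p field (incremental
  // projection applies only the change at the Dirichlet boundaries)
  double p_west_applied = as<double>(st["p_west_applied"]);
  double p_east_applied = as<double>(st["p_east_applied"]);
  // ledger accumulators
  NumericVector acc_wss = clone(as<NumericVector>(st["acc_wss"]));
  NumericVector acc_gamma = clone(as<NumericVector>(st["acc_gamma"]));
  NumericVector acc_AP = clone(as<NumericVector>(st["acc_AP"]));
  NumericVector acc_mu = clone(as<NumericVector>(st["acc_mu"]));
  double acc_t = as<double>(st["acc_t"]);

  const int ncell = nx * ny;
  std::vector<double> mu(ncell), gam(ncell), sfrac(ncell), svel(ncell, 0.0);
  std::vector<double> wss(nfac, 0.0);
  std::vector<double> ustar(u.begin(), u.end()), vstar(v.begin(), v.end());

  // static solid fraction from cell_type (flap columns updated per step)
  std::vector<int> ctype(ctypeR.begin(), ctypeR.end());
  const double flap_y0 = flap_y0v.size() ? flap_y0v[0] : 0.0;
  const double flap_y1 = flap_y1v.size() ? flap_y1v[0] : 0.0;
  const int frow_lo = flap_row_lo.size() ? flap_row_lo[0] : 0;
  const int frow_hi = flap_row_hi.size() ? flap_row_hi[0] : -1;
  const int nst = flap_cols.size();
  std::vector<double> flap_load(nst, 0.0), flap_wn(nst, 0.0), flap_wdot(nst, 0.0);

  // set solid fraction for a given flap displacement
  auto set_solid = [&](void) {
    for (int c = 0; c < ncell; ++c) {
      sfrac[c] = (ctype[c] == 0) ? 1.0 : 0.0;
      svel[c] = 0.0;
    }
    for (int k = 0; k < nst; ++k) {
      int i = flap_cols[k];
      if (flap_tear[k]) continue;                  // no material across tears
      double lo = flap_y0 + flap_w[k], hi = flap_y1 + flap_w[k];
      int jlo = std::max(0, frow_lo - 8), jhi = std::min(ny - 1, frow_hi + 8);
      for (int j = jlo; j <= jhi; ++j) {
        double o = std::min(hi, yf[j + 1]) - std::max(lo, yf[j]);
        if (o > 0.0) {
          double f = o / G.dy[j];
          if (f > sfrac[i + j * nx]) {
            sfrac[i + j * nx] = f;
            svel[i + j * nx] = flap_wdot[k];
          }
        }
      }
    }
  };

  auto update_gamma_mu = [&](void) {
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double ux = (U(i + 1, j) - U(i, j)) / dx;
        double vy = (V(i, j + 1) - V(i, j)) / G.dy[j];
        double ub0 = 0.5 * (U(i, j) + U(i + 1, j));
        // d(ubar)/dy with no-slip ghosts at domain walls
        double uy;
        if (j == 0) {
          double ubN = 0.5 * (U(i, 1) + U(i + 1, 1));
          uy = (ubN - (-ub0)) / (G.dyc[0] + G.dy[0]);
        } else if (j == ny - 1) {
          double ubS = 0.5 * (U(i, j - 1) + U(i + 1, j - 1));
          uy = ((-ub0) - ubS) / (G.dyc[j - 1] + G.dy[j]);
        } else {
          double ubN = 0.5 * (U(i, j + 1) + U(i + 1, j + 1));
          double ubS = 0.5 * (U(i, j - 1) + U(i + 1, j - 1));
          uy = (ubN - ubS) / (G.dyc[j - 1] + G.dyc[j]);
        }
        double vb0 = 0.5 * (V(i, j) + V(i, j + 1));
        double vx;
        if (i == 0) vx = (0.5 * (V(1, j) + V(1, j + 1)) - vb0) / dx;
        else if (i == nx - 1) vx = (vb0 - 0.5 * (V(i - 1, j) + V(i - 1, j + 1))) / dx;
        else vx = (0.5 * (V(i + 1, j) + V(i + 1, j + 1)) -
                   0.5 * (V(i - 1, j) + V(i - 1, j + 1))) / (2.0 * dx);
        double g = std::sqrt(2.0 * (ux * ux + vy * vy) + (uy + vx) * (uy + vx));
        gam[i + j * nx] = g;
        mu[i + j * nx] = Q.visc(g);
      }
  };

  auto phi_bp_sink = [&](double bp) {
    return bp * bp / (bp * bp + BPt_sink * BPt_sink);
  };
  auto phi_gam = [&](double g) {
    return literal_switch ? gt * gt / (g + gt * gt) : gt * gt / (g * g + gt * gt);
  };

  // --- Poisson operator (constant during the call) -------------------------
  Poisson PS; PS.nx = nx; PS.ny = ny; PS.n = ncell;
  PS.gW.assign(ncell, 0.0); PS.gE.assign(ncell, 0.0);
  PS.gS.assign(ncell, 0.0); PS.gN.assign(ncell, 0.0);
  PS.gD.assign(ncell, 0.0); PS.diag.assign(ncell, 0.0);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int c = i + j * nx;
      double aW = 0, aE = 0, aS = 0, aN = 0, aD = 0;
      if (i > 0) aW = G.dy[j] / dx;
      else if (west_bc == 1) aD += G.dy[j] / (dx / 2.0);      // Dirichlet p west
      if (i < nx - 1) aE = G.dy[j] / dx;
      else if (is_outlet_row[j]) aD += G.dy[j] / (dx / 2.0);  // Dirichlet p east
      if (j > 0) aS = dx / G.dyc[j - 1];
      if (j < ny - 1) aN = dx / G.dyc[j];
      PS.gW[c] = aW; PS.gE[c] = aE; PS.gS[c] = aS; PS.gN[c] = aN; PS.gD[c] = aD;
      PS.diag[c] = aW + aE + aS + aN + aD;
      if (PS.diag[c] <= 0.0) PS.diag[c] = 1.0; // isolated cell safeguard
    }
  std::vector<double> pvec(ncell, 0.0), brhs(ncell, 0.0); // phi increment

  // --- diagnostics ---------------------------------------------------------
  NumericVector d_Qin(nsteps), d_Qout(nsteps), d_Pout(nsteps), d_KE(nsteps),
      d_umax(nsteps), d_cg(nsteps), d_flapmax(nsteps), d_div(nsteps);
  bool blew_up = false;

  set_solid();
  update_gamma_mu();

  // =========================================================================
  for (int step = 0; step < nsteps; ++step) {
    const double Uin = inletU[step];
    const double fx = fxv[step];
    double p_east = eastP[step], p_west = westP[step];

    // -- windkessel outlet pressure from current outflow --------------------
    double Qout = 0.0;
    for (int j = 0; j < ny; ++j)
      if (is_outlet_row[j]) Qout += U(nx, j) * G.dy[j];
    if (east_bc == 2) {
      pwk = (pwk + dt * Qout / wkC) / (1.0 + dt / (wkRp * wkC));
      p_east = pwk + Qout * wkRc;
    }

    // -- flap: quasi-static beam update from transmural load ----------------
    if (flap_on && nst > 0) {
      for (int k = 0; k < nst; ++k) {
        int i = flap_cols[k];
        double pTL = P(i, frow_lo - 1);       // cell just below the flap band
        double pFL = P(i, frow_hi + 1);       // cell just above
        flap_load[k] = flap_tear[k] ? 0.0 : (pTL - pFL);
      }
      for (int k = 0; k < nst; ++k) {
        double w = 0.0;
        for (int m = 0; m < nst; ++m) w += Minv(k, m) * flap_load[m];
        flap_wn[k] = w;
      }
      for (int k = 0; k < nst; ++k) {
        double wn = flap_w[k] + flap_relax * (flap_wn[k] - flap_w[k]);
        if (wn > flap_cap) wn = flap_cap;
        if (wn < -flap_cap) wn = -flap_cap;
        if (flap_tear[k]) wn = 0.0;
        flap_wdot[k] = (wn - flap_w[k]) / dt;
        flap_w[k] = wn;
      }
      set_solid();
    }

    if (advance_flow) {
      // -- predictor: explicit advection + x-diffusion + body force ---------
      // u faces
      for (int j = 0; j < ny; ++j) {
        for (int i = 1; i < nx; ++i) {
          double adv = 0.0;
          { // x-fluxes through cell centers i and i-1
            double ue = 0.5 * (U(i, j) + U(i + 1, j));
            double uw = 0.5 * (U(i - 1, j) + U(i, j));
            double um2 = (i >= 2) ? U(i - 2, j) : U(i - 1, j);
            double up2 = (i <= nx - 2) ? U(i + 2, j) : U(i + 1, j);
            double fe = ue * muscl_face(U(i - 1, j), U(i, j), U(i + 1, j), up2, ue);
            double fw = uw * muscl_face(um2, U(i - 1, j), U(i, j), U(i + 1, j), uw);
            adv += (fe - fw) / dx;
          }
          { // y-fluxes through horizontal CV faces
            double vn = 0.5 * (V(i - 1, j + 1) + V(i, j + 1));
            double vs = 0.5 * (V(i - 1, j) + V(i, j));
            double ujm1 = (j >= 1) ? U(i, j - 1) : -U(i, j); // no-slip ghost
            double ujp1 = (j <= ny - 2) ? U(i, j + 1) : -U(i, j);
            double ujm2 = (j >= 2) ? U(i, j - 2) : ujm1;
            double ujp2 = (j <= ny - 3) ? U(i, j + 2) : ujp1;
            double fn = vn * muscl_face(ujm1, U(i, j), ujp1, ujp2, vn);
            double fs = vs * muscl_face(ujm2, ujm1, U(i, j), ujp1, vs);
            adv += (fn - fs) / G.dy[j];
          }
          double diffx = (CC(mu, i, j) * (U(i + 1, j) - U(i, j)) -
                          CC(mu, i - 1, j) * (U(i, j) - U(i - 1, j))) / (dx * dx);
          double gradp = (P(i, j) - P(i - 1, j)) / dx;   // old pressure
          ustar[i + j * (nx + 1)] =
              U(i, j) + dt * (-adv + (diffx - gradp + fx) / rho);
        }
      }
      // v faces
      for (int j = 1; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          double adv = 0.0;
          { // x-fluxes
            double ue = 0.5 * (U(i + 1, j - 1) + U(i + 1, j));
            double uw = 0.5 * (U(i, j - 1) + U(i, j));
            double vim1 = (i >= 1) ? V(i - 1, j) : V(i, j);
            double vip1 = (i <= nx - 2) ? V(i + 1, j) : V(i, j);
            double vim2 = (i >= 2) ? V(i - 2, j) : vim1;
            double vip2 = (i <= nx - 3) ? V(i + 2, j) : vip1;
            double fe = ue * muscl_face(vim1, V(i, j), vip1, vip2, ue);
            double fw = uw * muscl_face(vim2, vim1, V(i, j), vip1, uw);
            adv += (fe - fw) / dx;
          }
          { // y-fluxes through cell centers j and j-1
            double vn = 0.5 * (V(i, j) + V(i, j + 1));
            double vs = 0.5 * (V(i, j - 1) + V(i, j));
            double vjm2 = (j >= 2) ? V(i, j - 2) : V(i, j - 1);
            double vjp2 = (j <= ny - 2) ? V(i, j + 2) : V(i, j + 1);
            double fn = vn * muscl_face(V(i, j - 1), V(i, j), V(i, j + 1), vjp2, vn);
            double fs = vs * muscl_face(vjm2, V(i, j - 1), V(i, j), V(i, j + 1), vs);
            adv += (fn - fs) / G.dyc[j - 1];
          }
          // explicit x-diffusion: flux between v(i,j) and v(i+1,j) uses the
          // corner-averaged viscosity
          double mue, muw;
          if (i < nx - 1)
            mue = 0.25 * (CC(mu, i, j - 1) + CC(mu, i + 1, j - 1) +
                          CC(mu, i, j) + CC(mu, i + 1, j));
          else mue = 0.5 * (CC(mu, i, j - 1) + CC(mu, i, j));
          if (i > 0)
            muw = 0.25 * (CC(mu, i - 1, j - 1) + CC(mu, i, j - 1) +
                          CC(mu, i - 1, j) + CC(mu, i, j));
          else muw = 0.5 * (CC(mu, i, j - 1) + CC(mu, i, j));
          double vE = (i < nx - 1) ? V(i + 1, j) : V(i, j); // free-slip ends
          double vW = (i > 0) ? V(i - 1, j) : V(i, j);
          double diffx = (mue * (vE - V(i, j)) - muw * (V(i, j) - vW)) / (dx * dx);
          double gradp = (P(i, j) - P(i, j - 1)) / G.dyc[j - 1];
          vstar[i + j * nx] = V(i, j) + dt * (-adv + (diffx - gradp) / rho);
        }
      }

      // -- implicit y-diffusion + momentum sinks (per column tridiagonal) ---
      {
        std::vector<double> ta(ny), tb(ny), tc(ny), td(ny);
        // u component, interior faces i = 1..nx-1. Domain-wall viscous
        // fluxes use the quadratic-consistent one-sided gradient
        // (9 u0 - u1)/(3 dy), which makes the discrete Poiseuille solution
        // (and its wall shear stress) exact.
        for (int i = 1; i < nx; ++i) {
          for (int j = 0; j < ny; ++j) {
            double gn, gs;        // viscous couplings / dy (diagonal part)
            double xn = 0.0, xs = 0.0; // extra off-diagonal wall terms
            if (j < ny - 1) {
              double mun = 0.25 * (CC(mu, i - 1, j) + CC(mu, i, j) +
                                   CC(mu, i - 1, j + 1) + CC(mu, i, j + 1));
              gn = mun / G.dyc[j];
            } else {
              double munw = 0.5 * (CC(mu, i - 1, j) + CC(mu, i, j));
              gn = 3.0 * munw / G.dy[j];       // wall at the top
              xs = munw / (3.0 * G.dy[j]);     // couples to u(j-1)
            }
            if (j > 0) {
              double mus = 0.25 * (CC(mu, i - 1, j) + CC(mu, i, j) +
                                   CC(mu, i - 1, j - 1) + CC(mu, i, j - 1));
              gs = mus / G.dyc[j - 1];
            } else {
              double musw = 0.5 * (CC(mu, i - 1, j) + CC(mu, i, j));
              gs = 3.0 * musw / G.dy[j];       // wall at the bottom
              xn = musw / (3.0 * G.dy[j]);     // couples to u(j+1)
            }
            double sf = 0.5 * (CC(sfrac, i - 1, j) + CC(sfrac, i, j));
            double bp = 0.5 * (CC(BP, i - 1, j) + CC(BP, i, j));
            double K = k_pen * sf + kM * phi_bp_sink(bp);
            tb[j] = 1.0 + dt / rho * ((gn + gs) / G.dy[j] + K);
            tc[j] = (j < ny - 1) ? -dt / rho * (gn + xn) / G.dy[j] : 0.0;
            ta[j] = (j > 0) ? -dt / rho * (gs + xs) / G.dy[j] : 0.0;
            td[j] = ustar[i + j * (nx + 1)]; // solid x-velocity is 0
          }
          thomas(ta, tb, tc, td, ny);
          for (int j = 0; j < ny; ++j) ustar[i + j * (nx + 1)] = td[j];
        }
        // v component, interior faces j = 1..ny-1 per column i
        for (int i = 0; i < nx; ++i) {
          int n = ny - 1;
          for (int j = 1; j < ny; ++j) {
            double gn = CC(mu, i, j) / G.dy[j];
            double gs = CC(mu, i, j - 1) / G.dy[j - 1];
            double hh = G.dyc[j - 1];
            double sf = 0.5 * (CC(sfrac, i, j - 1) + CC(sfrac, i, j));
            double bp = 0.5 * (CC(BP, i, j - 1) + CC(BP, i, j));
            double vs_loc = 0.0;
            if (sf > 0.0)
              vs_loc = (CC(sfrac, i, j - 1) * CC(svel, i, j - 1) +
                        CC(sfrac, i, j) * CC(svel, i, j)) /
                       (CC(sfrac, i, j - 1) + CC(sfrac, i, j) + 1e-300);
            double K = k_pen * sf + kM * phi_bp_sink(bp);
            tb[j - 1] = 1.0 + dt / rho * ((gn + gs) / hh + K);
            tc[j - 1] = (j < ny - 1) ? -dt / rho * gn / hh : 0.0;
            ta[j - 1] = (j > 1) ? -dt / rho * gs / hh : 0.0;
            td[j - 1] = vstar[i + j * nx] + dt / rho * k_pen * sf * vs_loc;
          }
          thomas(ta, tb, tc, td, n);
          for (int j = 1; j < ny; ++j) vstar[i + j * nx] = td[j - 1];
        }
      }

      // -- boundary faces of the predictor -----------------------------------
      for (int j = 0; j < ny; ++j) {
        if (west_bc == 0)
          ustar[0 + j * (nx + 1)] = is_inlet_row[j] ? Uin : 0.0;
        else
          ustar[0 + j * (nx + 1)] = ustar[1 + j * (nx + 1)];
        if (is_outlet_row[j])
          ustar[nx + j * (nx + 1)] = ustar[nx - 1 + j * (nx + 1)];
        else
          ustar[nx + j * (nx + 1)] = 0.0;
      }
      for (int i = 0; i < nx; ++i) { vstar[i] = 0.0; vstar[i + ny * nx] = 0.0; }

      // -- pressure Poisson for the increment phi = p^{n+1} - p^n ------------
      // At Dirichlet boundaries phi_bc is the *change* in imposed pressure;
      // the predictor's boundary faces also carry the old gradient there.
      double phi_w = p_west - p_west_applied;
      double phi_e = p_east - p_east_applied;
      for (int j = 0; j < ny; ++j) {
        if (west_bc == 1)
          ustar[0 + j * (nx + 1)] -=
              dt / rho * (P(0, j) - p_west_applied) / (dx / 2.0) -
              dt / rho * (P(1, j) - P(0, j)) / dx; // replace copied gradient
        if (is_outlet_row[j])
          ustar[nx + j * (nx + 1)] -=
              dt / rho * (p_east_applied - P(nx - 1, j)) / (dx / 2.0) -
              dt / rho * (P(nx - 1, j) - P(nx - 2, j)) / dx;
      }
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int c = i + j * nx;
          double div = (ustar[(i + 1) + j * (nx + 1)] - ustar[i + j * (nx + 1)]) / dx +
                       (vstar[i + (j + 1) * nx] - vstar[i + j * nx]) / G.dy[j];
          double b = -rho / dt * div * (dx * G.dy[j]);
          if (i == 0 && west_bc == 1) b += G.dy[j] / (dx / 2.0) * phi_w;
          if (i == nx - 1 && is_outlet_row[j]) b += G.dy[j] / (dx / 2.0) * phi_e;
          brhs[c] = b;
        }
      int it = PS.solve(pvec, brhs, cg_rtol, cg_maxit);
      d_cg[step] = it;

      // -- corrector ----------------------------------------------------------
      for (int j = 0; j < ny; ++j) {
        for (int i = 1; i < nx; ++i)
          U(i, j) = ustar[i + j * (nx + 1)] -
                    dt / rho * (pvec[i + j * nx] - pvec[i - 1 + j * nx]) / dx;
        // west face
        if (west_bc == 0) U(0, j) = ustar[0 + j * (nx + 1)];
        else U(0, j) = ustar[0 + j * (nx + 1)] -
                       dt / rho * (pvec[0 + j * nx] - phi_w) / (dx / 2.0);
        // east face
        if (is_outlet_row[j])
          U(nx, j) = ustar[nx + j * (nx + 1)] -
                     dt / rho * (phi_e - pvec[nx - 1 + j * nx]) / (dx / 2.0);
        else U(nx, j) = 0.0;
      }
      for (int i = 0; i < nx; ++i) {
        for (int j = 1; j < ny; ++j)
          V(i, j) = vstar[i + j * nx] -
                    dt / rho * (pvec[i + j * nx] - pvec[i + (j - 1) * nx]) / G.dyc[j - 1];
        V(i, 0) = 0.0; V(i, ny) = 0.0;
      }
      for (int c = 0; c < ncell; ++c) p[c] += pvec[c];
      p_west_applied = p_west;
      p_east_applied = p_east;

      update_gamma_mu();
    } // advance_flow

    // -- wall shear stress on boundary facets --------------------------------
    for (int f = 0; f < nfac; ++f) {
      int i = fi[f], j = fj[f], s = fside[f];
      double slope = 0.0, muw = CC(mu, i, j);
      if (s == 2 || s == 3) { // S/N horizontal facet: tangential u
        int j2 = (s == 2) ? j + 1 : j - 1;
        double d1 = 0.5 * G.dy[j];
        double u1 = 0.5 * (U(i, j) + U(i + 1, j));
        if (j2 >= 0 && j2 < ny) {
          double d2 = d1 + ((s == 2) ? G.dyc[j] : G.dyc[j2]);
          double u2 = 0.5 * (U(i, j2) + U(i + 1, j2));
          slope = (u1 * d2 * d2 - u2 * d1 * d1) / (d1 * d2 * (d2 - d1));
        } else slope = u1 / d1;
      } else {               // W/E vertical facet: tangential v
        int i2 = (s == 0) ? i + 1 : i - 1;
        double d1 = 0.5 * dx;
        double v1 = 0.5 * (V(i, j) + V(i, j + 1));
        if (i2 >= 0 && i2 < nx) {
          double d2 = 1.5 * dx;
          double v2 = 0.5 * (V(i2, j) + V(i2, j + 1));
          slope = (v1 * d2 * d2 - v2 * d1 * d1) / (d1 * d2 * (d2 - d1));
        } else slope = v1 / d1;
      }
      wss[f] = muw * std::fabs(slope);
    }

    // -- species transport ---------------------------------------------------
    if (species_on) {
      std::vector<double> RPn(ncell), APn(ncell), Cn(ncell);
      std::vector<double> rate1(ncell), rate2(ncell), ctmp(ncell);
      // advection-diffusion rate for a platelet species (conservative
      // limited MUSCL fluxes, Dirichlet wall exchange)
      auto ad_rate = [&](const double* c0, std::vector<double>& rout,
                         double D, double c_in, double c_wall) {
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nx; ++i) {
            int cix = i + j * nx;
            double val = c0[cix];
            double rate = 0.0;
            if (species_adv) {
              // x-faces
              double fe, fw;
              {
                double ue = U(i + 1, j);
                if (i == nx - 1) fe = ue * val;                    // outflow
                else {
                  double cm1 = (i >= 1) ? c0[cix - 1] : val;
                  double cp1 = c0[cix + 1];
                  double cp2 = (i <= nx - 3) ? c0[cix + 2] : cp1;
                  fe = ue * muscl_face(cm1, val, cp1, cp2, ue);
                }
                double uw = U(i, j);
                if (i == 0) fw = uw * ((uw >= 0) ? c_in : val);     // inflow
                else {
                  double cm1 = c0[cix - 1];
                  double cm2 = (i >= 2) ? c0[cix - 2] : cm1;
                  double cp2 = (i <= nx - 2) ? c0[cix + 1] : val;
                  fw = uw * muscl_face(cm2, cm1, val, cp2, uw);
                }
              }
              rate -= (fe - fw) / dx;
              // y-faces
              double fn, fs;
              {
                double vn = V(i, j + 1);
                if (j == ny - 1) fn = 0.0;
                else {
                  double cm1 = (j >= 1) ? c0[cix - nx] : val;
                  double cp1 = c0[cix + nx];
                  double cp2 = (j <= ny - 3) ? c0[cix + 2 * nx] : cp1;
                  fn = vn * muscl_face(cm1, val, cp1, cp2, vn);
                }
                double vs = V(i, j);
                if (j == 0) fs = 0.0;
                else {
                  double cm1 = c0[cix - nx];
                  double cm2 = (j >= 2) ? c0[cix - 2 * nx] : cm1;
                  double cp2 = (j <= ny - 2) ? c0[cix + nx] : val;
                  fs = vs * muscl_face(cm2, cm1, val, cp2, vs);
                }
              }
              rate -= (fn - fs) / G.dy[j];
            }
            if (D > 0.0) {
              double fE = (i < nx - 1) ? D * (c0[cix + 1] - val) / dx : 0.0;
              double fW = (i > 0) ? D * (val - c0[cix - 1]) / dx : 0.0;
              double fN = (j < ny - 1) ? D * (c0[cix + nx] - val) / G.dyc[j] : 0.0;
              double fS = (j > 0) ? D * (val - c0[cix - nx]) / G.dyc[j - 1] : 0.0;
              rate += (fE - fW) / dx + (fN - fS) / G.dy[j];
            }
            rout[cix] = rate;
          }
        // Dirichlet wall value via facet diffusive exchange (D is tiny for
        // platelets; this is the literal wall condition)
        if (D > 0.0 && c_wall >= 0.0)
          for (int f = 0; f < nfac; ++f) {
            if (!fwall[f]) continue;
            int i = fi[f], j = fj[f], s = fside[f];
            int cix = i + j * nx;
            double d = (s == 2 || s == 3) ? 0.5 * G.dy[j] : 0.5 * dx;
            double area = dx * G.dy[j];
            rout[cix] += D * (c_wall - c0[cix]) / d * flen[f] / area;
          }
      };
      // Heun (RK2) transport update: second order in time
      auto transport = [&](NumericVector& c0, std::vector<double>& cn,
                           double D, double c_in, double c_wall) {
        ad_rate(&c0[0], rate1, D, c_in, c_wall);
        for (int c = 0; c < ncell; ++c) ctmp[c] = c0[c] + dt * rate1[c];
        ad_rate(ctmp.data(), rate2, D, c_in, c_wall);
        for (int c = 0; c < ncell; ++c)
          cn[c] = c0[c] + 0.5 * dt * (rate1[c] + rate2[c]);
      };
      transport(RP, RPn, D_RP, 1.0, wall_conc);
      transport(AP, APn, D_AP, 1.0, wall_conc);
      // coagulant: diffusion only, D_C_base * phi_gamma (local, instantaneous)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int cix = i + j * nx;
          double val = Cc[cix];
          double Dh = D_C * phi_gam(gam[cix]);
          auto Dface = [&](int c2) {
            return 0.5 * (Dh + D_C * phi_gam(gam[c2]));
          };
          double rate = 0.0;
          if (i < nx - 1) rate += Dface(cix + 1) * (Cc[cix + 1] - val) / (dx * dx);
          if (i > 0) rate -= Dface(cix - 1) * (val - Cc[cix - 1]) / (dx * dx);
          if (j < ny - 1) rate += Dface(cix + nx) * (Cc[cix + nx] - val) / (G.dyc[j] * G.dy[j]);
          if (j > 0) rate -= Dface(cix - nx) * (val - Cc[cix - nx]) / (G.dyc[j - 1] * G.dy[j]);
          Cn[cix] = val + dt * rate;
        }
      // gated coagulant wall flux (previous-cycle TAWSS, local BP)
      if (wall_flux_on)
        for (int f = 0; f < nfac; ++f) {
          if (!fwall[f]) continue;
          int i = fi[f], j = fj[f];
          int cix = i + j * nx;
          if (tawss_prev[f] < tawss_thr && BP[cix] < BPt) {
            double area = dx * G.dy[j];
            Cn[cix] += dt * c_wall_src * flen[f] / area;
          }
        }
      // reactions (positivity-preserving splitting)
      if (reactions_on) {
        for (int c = 0; c < ncell; ++c) {
          double rp = RPn[c] > 0.0 ? RPn[c] : 0.0;
          double ap = APn[c] > 0.0 ? APn[c] : 0.0;
          double cc = Cn[c] > 0.0 ? Cn[c] : 0.0;
          double bp = BP[c];
          double pg = phi_gam(gam[c]);
          double rp_new = rp / (1.0 - dt * k_RP * ap);   // k_RP < 0
          double ap_new = ap + dt * k_AP * ap * rp;
          double prodC = k_C1 * (bp * bp / (bp * bp + BPt * BPt)) * ap;
          double lamC = -k_C2 * ap * (1.0 - pg) * cc / (cc * cc + Ct * Ct);
          double c_new = (cc + dt * prodC) / (1.0 + dt * lamC);
          double phiBP = (ap * ap / (ap * ap + APt * APt)) *
                         (cc * cc / (cc * cc + Ct * Ct));
          double bp_new = bp + dt * k_BP * phiBP * pg * ap;
          RP[c] = rp_new; AP[c] = ap_new; Cc[c] = c_new; BP[c] = bp_new;
        }
      } else {
        for (int c = 0; c < ncell; ++c) {
          RP[c] = RPn[c] > 0.0 ? RPn[c] : 0.0;
          AP[c] = APn[c] > 0.0 ? APn[c] : 0.0;
          Cc[c] = Cn[c] > 0.0 ? Cn[c] : 0.0;
        }
      }
    }

    // -- ledger accumulation and diagnostics ---------------------------------
    for (int f = 0; f < nfac; ++f) acc_wss[f] += wss[f] * dt;
    double KE = 0.0, umax = 0.0;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int c = i + j * nx;
        acc_gamma[c] += gam[c] * dt;
        acc_AP[c] += AP[c] * dt;
        acc_mu[c] += mu[c] * dt;
        double ub = 0.5 * (U(i, j) + U(i + 1, j));
        double vb = 0.5 * (V(i, j) + V(i, j + 1));
        double sp = std::sqrt(ub * ub + vb * vb);
        if (ctype[c] == 1) {
          KE += 0.5 * rho * (ub * ub + vb * vb) * dx * G.dy[j];
          if (sp > umax) umax = sp;
        }
      }
    acc_t += dt;
    double Qin = 0.0;
    for (int j = 0; j < ny; ++j) Qin += U(0, j) * G.dy[j];
    double Qout2 = 0.0;
    for (int j = 0; j < ny; ++j)
      if (is_outlet_row[j]) Qout2 += U(nx, j) * G.dy[j];
    double divmax = 0.0;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double div = (U(i + 1, j) - U(i, j)) / dx +
                     (V(i, j + 1) - V(i, j)) / G.dy[j];
        double a = std::fabs(div);
        if (a > divmax) divmax = a;
      }
    double fmax = 0.0;
    for (int k = 0; k < nst; ++k)
      if (std::fabs(flap_w[k]) > fmax) fmax = std::fabs(flap_w[k]);
    d_Qin[step] = Qin; d_Qout[step] = Qout2; d_Pout[step] = p_east;
    d_KE[step] = KE; d_umax[step] = umax; d_flapmax[step] = fmax;
    d_div[step] = divmax;
    tcur += dt;
    if (!std::isfinite(KE) || umax * dt / dx > 2.0) { blew_up = true; break; }
  }

  NumericVector wss_out(nfac);
  for (int f = 0; f < nfac; ++f) wss_out[f] = wss[f];
  NumericVector mu_out(ncell), gam_out(ncell), sf_out(ncell);
  for (int c = 0; c < ncell; ++c) {
    mu_out[c] = mu[c]; gam_out[c] = gam[c]; sf_out[c] = sfrac[c];
  }
  mu_out.attr("dim") = IntegerVector::create(nx, ny);
  gam_out.attr("dim") = IntegerVector::create(nx, ny);
  sf_out.attr("dim") = IntegerVector::create(nx, ny);
  NumericVector wdot_out(nst);
  for (int k = 0; k < nst; ++k) wdot_out[k] = flap_wdot[k];

  return List::create(
      _["u"] = u, _["v"] = v, _["p"] = p,
      _["RP"] = RP, _["AP"] = AP, _["C"] = Cc, _["BP"] = BP,
      _["flap_w"] = flap_w, _["flap_wdot"] = wdot_out,
      _["pwk"] = pwk, _["t"] = tcur,
      _["p_west_applied"] = p_west_applied,
      _["p_east_applied"] = p_east_applied,
      _["mu"] = mu_out, _["gamma"] = gam_out, _["solid_frac"] = sf_out,
      _["wss"] = wss_out, _["tawss_prev"] = tawss_prev,
      _["acc_wss"] = acc_wss, _["acc_gamma"] = acc_gamma,
      _["acc_AP"] = acc_AP, _["acc_mu"] = acc_mu, _["acc_t"] = acc_t,
      _["diag"] = DataFrame::create(
          _["Qin"] = d_Qin, _["Qout"] = d_Qout, _["Pout"] = d_Pout,
          _["KE"] = d_KE, _["umax"] = d_umax, _["cg_iters"] = d_cg,
          _["flap_max"] = d_flapmax, _["div_max"] = d_div),
      _["blew_up"] = blew_up);
}
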