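// Core numerical kernels: NeRF backbone construction from (phi, psi),
// backbone torsion extraction, Kabsch best-fit CA RMSD, and the
// overdamped-Langevin targeted-MD integrator in dihedral space.
//
// Geometry is idealised: fixed bond lengths/angles, omega fixed at 180
// degrees (trans), so the only degrees of freedom are the backbone
// dihedrals.  All angles cross the R/C++ boundary in degrees; internal
// dynamics run in radians.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Ideal backbone geometry (Engh-Huber-like values), Angstrom / degrees.
static const double B_N_CA = 1.458;
static const double B_CA_C = 1.525;
static const double B_C_N = 1.329;
static const double B_C_O = 1.231;
// N-CA-C set at the lower end of the observed range so the canonical
// alpha-helix at (-57, -47) carries proper i,i+4 hydrogen-bond geometry
// (O...N ~2.96 A, N-H...O within 20 degrees of linear)
static const double A_N_CA_C = 110.0;
static const double A_CA_C_N = 116.2;
static const double A_C_N_CA = 121.7;
static const double A_CA_C_O = 120.8;
static const double DEG = M_PI / 180.0;

// Place atom D given chain A-B-C, bond length |C-D|, bond angle B-C-D and
// torsion A-B-C-D (standard natural extension reference frame step).
static inline arma::rowvec3 nerf_place(const arma::rowvec3 &A,
                                       const arma::rowvec3 &B,
                                       const arma::rowvec3 &C,
                                       double bond, double angle_deg,
                                       double torsion_rad) {
  double ang = angle_deg * DEG;
  arma::rowvec3 bc = C - B;
  bc /= arma::norm(bc);
  arma::rowvec3 ab = B - A;
  arma::rowvec3 n = arma::cross(ab, bc);
  n /= arma::norm(n);
  arma::rowvec3 m = arma::cross(n, bc);
  // local displacement in the (bc, m, n) frame
  double d_bc = -bond * std::cos(ang);
  double d_m = bond * std::sin(ang) * std::cos(torsion_rad);
  double d_n = -bond * std::sin(ang) * std::sin(torsion_rad);
  return C + d_bc * bc + d_m * m + d_n * n;
}

// Build N/CA/C coordinates for an n-residue chain.  phi[0] is unused
// (undefined for the first residue); psi[i] for i < n-1 sets the chain
// path, psi[n-1] is unused here (it only orients the terminal O).
static void build_ncac(const arma::vec &phi, const arma::vec &psi,
                       arma::mat &N, arma::mat &CA, arma::mat &C) {
  int n = phi.n_elem;
  // seed residue: N at origin, CA on x, C in the xy-plane
  N.row(0) = arma::rowvec3({0.0, 0.0, 0.0});
  CA.row(0) = arma::rowvec3({B_N_CA, 0.0, 0.0});
  double a = A_N_CA_C * DEG;
  C.row(0) = CA.row(0) +
             arma::rowvec3({-B_CA_C * std::cos(a), B_CA_C * std::sin(a), 0.0});
  for (int i = 1; i < n; i++) {
    // N_i from psi_{i-1}; CA_i from omega = 180; C_i from phi_i
    N.row(i) = nerf_place(N.row(i - 1), CA.row(i - 1), C.row(i - 1), B_C_N,
                          A_CA_C_N, psi(i - 1));
    CA.row(i) = nerf_place(CA.row(i - 1), C.row(i - 1), N.row(i), B_N_CA,
                           A_C_N_CA, M_PI);
    C.row(i) = nerf_place(C.row(i - 1), N.row(i), CA.row(i), B_CA_C, A_N_CA_C,
                          phi(i));
  }
}

// Carbonyl O of residue i lies in the peptide plane, anti to N_{i+1}:
// torsion N_i-CA_i-C_i-O_i = psi_i - 180.
static void place_oxygens(const arma::vec &psi, const arma::mat &N,
                          const arma::mat &CA, const arma::mat &C,
                          arma::mat &O) {
  int n = N.n_rows;
  for (int i = 0; i < n; i++) {
    double ps = psi(i);
    if (!std::isfinite(ps)) ps = M_PI; // terminal residue: arbitrary trans
    O.row(i) =
        nerf_place(N.row(i), CA.row(i), C.row(i), B_C_O, A_CA_C_O, ps - M_PI);
  }
}

static inline double torsion4(const arma::rowvec3 &a, const arma::rowvec3 &b,
                              const arma::rowvec3 &c, const arma::rowvec3 &d) {
  arma::rowvec3 b1 = b - a, b2 = c - b, b3 = d - c;
  arma::rowvec3 n1 = arma::cross(b1, b2);
  arma::rowvec3 n2 = arma::cross(b2, b3);
  arma::rowvec3 m = arma::cross(n1, b2 / arma::norm(b2));
  double x = arma::dot(n1, n2);
  double y = arma::dot(m, n2);
  return std::atan2(y, x);
}

// Best-fit (proper-rotation Kabsch) RMSD between two point sets.
static double kabsch_rmsd_internal(const arma::mat &A, const arma::mat &B) {
  int n = A.n_rows;
  arma::rowvec ca = arma::mean(A, 0);
  arma::rowvec cb = arma::mean(B, 0);
  arma::mat A0 = A.each_row() - ca;
  arma::mat B0 = B.each_row() - cb;
  arma::mat H = A0.t() * B0;
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H, "std"))
    stop("SVD failed in Kabsch superposition");
  double d = arma::det(V * U.t());
  arma::vec sgn = {1.0, 1.0, (d < 0.0) ? -1.0 : 1.0};
  // rmsd^2 = (|A0|^2 + |B0|^2 - 2 * sum(sgn * s)) / n
  double e0 = arma::accu(A0 % A0) + arma::accu(B0 % B0);
  double tr = arma::dot(sgn, s);
  double msd = (e0 - 2.0 * tr) / n;
  if (msd < 0) msd = 0;
  return std::sqrt(msd);
}

// [[Rcpp::export]]
List cpp_build_backbone(NumericVector phi_deg, NumericVector psi_deg) {
  int n = phi_deg.size();
  if (psi_deg.size() != n) stop("phi and psi must have equal length");
  arma::vec phi(n), psi(n);
  for (int i = 0; i < n; i++) {
    phi(i) = R_finite(phi_deg[i]) ? phi_deg[i] * DEG : -0.4 * M_PI;
    psi(i) = R_finite(psi_deg[i]) ? psi_deg[i] * DEG : NA_REAL;
  }
  // chain path needs finite psi for residues 1..n-1
  for (int i = 0; i < n - 1; i++)
    if (!std::isfinite(psi(i))) stop("psi must be finite for residues 1..n-1");
  arma::mat N(n, 3), CA(n, 3), C(n, 3), O(n, 3);
  build_ncac(phi, psi, N, CA, C);
  place_oxygens(psi, N, CA, C, O);
  return List::create(Named("N") = wrap(N), Named("CA") = wrap(CA),
                      Named("C") = wrap(C), Named("O") = wrap(O));
}

// [[Rcpp::export]]
List cpp_extract_dihedrals(NumericMatrix Nm, NumericMatrix CAm,
                           NumericMatrix Cm) {
  int n = Nm.nrow();
  arma::mat N = as<arma::mat>(Nm), CA = as<arma::mat>(CAm),
            C = as<arma::mat>(Cm);
  NumericVector phi(n, NA_REAL), psi(n, NA_REAL);
  for (int i = 0; i < n; i++) {
    if (i > 0)
      phi[i] = torsion4(C.row(i - 1), N.row(i), CA.row(i), C.row(i)) / DEG;
    if (i < n - 1)
      psi[i] = torsion4(N.row(i), CA.row(i), C.row(i), N.row(i + 1)) / DEG;
  }
  return List::create(Named("phi") = phi, Named("psi") = psi);
}

// [[Rcpp::export]]
double cpp_kabsch_rmsd(NumericMatrix Am, NumericMatrix Bm) {
  if (Am.nrow() != Bm.nrow()) stop("point counts differ");
  arma::mat A = as<arma::mat>(Am), B = as<arma::mat>(Bm);
  return kabsch_rmsd_internal(A, B);
}

static inline double wrap_pi(double x) {
  while (x > M_PI) x -= 2.0 * M_PI;
  while (x <= -M_PI) x += 2.0 * M_PI;
  return x;
}

// Overdamped Langevin dynamics in (phi, psi) space under
//   U = sum_i k_i [1 - max(cos(theta_i - thetaA_i), cos(theta_i - thetaB_i))]
//       + (N_CA * K / 2) * (R - rho(t))^2
// summed over both dihedrals of every residue: each torsion sits in a
// double-minimum potential anchored at the start-state (A) and
// target-state (B) dihedrals (nearest-well cosine form; the ridge between
// the minima is the local opening barrier, and the per-residue stiffness
// k_i sets its height).  rho(t) = rho0 * (1 - t/steps); R is the best-fit
// CA RMSD to the target.  The restraint gradient dR/dtheta is taken by
// central finite differences (fd_deg) through full backbone rebuilding.
// Uses R's RNG.
// [[Rcpp::export]]
List cpp_tmd_run(NumericVector phi0_deg, NumericVector psi0_deg,
                 NumericVector phiT_deg, NumericVector psiT_deg,
                 NumericMatrix target_ca, double K, double rho0, int steps,
                 double kT, double dt, NumericVector kdih, double fd_deg,
                 double max_dr, int save_every) {
  int n = phi0_deg.size();
  if (psi0_deg.size() != n) stop("phi and psi must have equal length");
  if (target_ca.nrow() != n) stop("target CA count differs from chain length");
  if (kdih.size() != n) stop("kdih must cover every residue");
  arma::mat T = as<arma::mat>(target_ca);

  if (phiT_deg.size() != n || psiT_deg.size() != n)
    stop("target dihedrals must cover every residue");
  arma::vec phi(n), psi(n), phiA(n), psiA(n), phiB(n), psiB(n);
  for (int i = 0; i < n; i++) {
    phi(i) = R_finite(phi0_deg[i]) ? phi0_deg[i] * DEG : -0.4 * M_PI;
    psi(i) = R_finite(psi0_deg[i]) ? psi0_deg[i] * DEG : -0.4 * M_PI;
    phiA(i) = phi(i);
    psiA(i) = psi(i);
    phiB(i) = R_finite(phiT_deg[i]) ? phiT_deg[i] * DEG : phiA(i);
    psiB(i) = R_finite(psiT_deg[i]) ? psiT_deg[i] * DEG : psiA(i);
  }
  arma::mat N(n, 3), CA(n, 3), C(n, 3);
  double del = fd_deg * DEG;

  int nsave = steps / save_every + 1;
  NumericMatrix phi_out(nsave, n), psi_out(nsave, n);
  NumericVector rmsd_out(nsave), rho_out(nsave), time_out(nsave), s_out(nsave);
  int isave = 0;

  RNGScope scope;
  double noise = std::sqrt(2.0 * kT * dt);
  double lastS = 0.0;

  for (int t = 0; t <= steps; t++) {
    double rho = rho0 * (1.0 - (double)t / steps);
    build_ncac(phi, psi, N, CA, C);
    double R = kabsch_rmsd_internal(CA, T);
    if (!std::isfinite(R))
      stop("non-finite RMSD at step %d", t);

    if (t % save_every == 0 || t == steps) {
      if (isave < nsave) {
        for (int i = 0; i < n; i++) {
          phi_out(isave, i) = wrap_pi(phi(i)) / DEG;
          psi_out(isave, i) = wrap_pi(psi(i)) / DEG;
        }
        rmsd_out[isave] = R;
        rho_out[isave] = rho;
        time_out[isave] = t;
        s_out[isave] = lastS;
        isave++;
      }
    }
    if (t == steps) break;

    // dihedral well gradients (nearest anchor wins)
    arma::vec gphi(n, arma::fill::zeros), gpsi(n, arma::fill::zeros);
    for (int i = 0; i < n; i++) {
      double da = phi(i) - phiA(i), db = phi(i) - phiB(i);
      gphi(i) = kdih(i) * std::sin(std::cos(da) >= std::cos(db) ? da : db);
      da = psi(i) - psiA(i); db = psi(i) - psiB(i);
      gpsi(i) = kdih(i) * std::sin(std::cos(da) >= std::cos(db) ? da : db);
    }

    // restraint gradient dR/dtheta by central finite differences; phi_1
    // and psi_n do not change internal CA geometry and carry no force
    arma::vec rphi(n, arma::fill::zeros), rpsi(n, arma::fill::zeros);
    double S = 0.0; // |grad R|^2
    if (K > 0.0) {
      arma::vec ph = phi, ps = psi;
      for (int i = 1; i < n; i++) {
        ph(i) = phi(i) + del;
        build_ncac(ph, psi, N, CA, C);
        double Rp = kabsch_rmsd_internal(CA, T);
        ph(i) = phi(i) - del;
        build_ncac(ph, psi, N, CA, C);
        double Rm = kabsch_rmsd_internal(CA, T);
        ph(i) = phi(i);
        rphi(i) = (Rp - Rm) / (2.0 * del);
      }
      for (int i = 0; i < n - 1; i++) {
        ps(i) = psi(i) + del;
        build_ncac(phi, ps, N, CA, C);
        double Rp = kabsch_rmsd_internal(CA, T);
        ps(i) = psi(i) - del;
        build_ncac(phi, ps, N, CA, C);
        double Rm = kabsch_rmsd_internal(CA, T);
        ps(i) = psi(i);
        rpsi(i) = (Rp - Rm) / (2.0 * del);
      }
      S = arma::dot(rphi, rphi) + arma::dot(rpsi, rpsi);
      lastS = S;
    }

    // Restraint displacement -alpha (R - rho) dR/dtheta.  The bare
    // overdamped factor alpha = dt N K is capped twice: at half the
    // Newton step 1/|grad R|^2 (the restraint stiffness N K |grad R|^2
    // is huge for large K and an uncapped explicit update is violently
    // unstable), and by a trust region limiting the displacement of any
    // single dihedral to max_dr radians (the linearisation of R breaks
    // down for large angular moves).  Below the caps the K-dependence
    // of the tracking lag is preserved.
    double alpha = 0.0;
    if (K > 0.0 && S > 0.0) {
      alpha = dt * n * K;
      if (alpha > 0.5 / S) alpha = 0.5 / S;
      double lag = std::abs(R - rho);
      double gmax = std::max(arma::abs(rphi).max(), arma::abs(rpsi).max());
      if (lag * gmax > 0 && alpha * lag * gmax > max_dr)
        alpha = max_dr / (lag * gmax);
      alpha *= (R - rho);
    }

    for (int i = 0; i < n; i++) {
      double dphi = -dt * gphi(i) - alpha * rphi(i) + noise * norm_rand();
      double dpsi = -dt * gpsi(i) - alpha * rpsi(i) + noise * norm_rand();
      if (!std::isfinite(dphi) || !std::isfinite(dpsi))
        stop("non-finite displacement at step %d, residue %d", t, i + 1);
      phi(i) = wrap_pi(phi(i) + dphi);
      psi(i) = wrap_pi(psi(i) + dpsi);
    }
  }

  return List::create(Named("phi") = phi_out, Named("psi") = psi_out,
                      Named("rmsd") = rmsd_out, Named("rho") = rho_out,
                      Named("step") = time_out, Named("gradsq") = s_out);
}
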