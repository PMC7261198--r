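// Coarse-grained helix-coil Monte Carlo engine.
//
// Units: nm, kJ/mol, K. kB = 0.0083145 kJ/mol/K.
// Chain geometry is a Calpha trace built from internal coordinates
// (bond 0.38 nm; helical runs of >= 4 residues use the virtual bond
// angle/dihedral of an ideal alpha helix, everything else uses per-residue
// coil angles). Charged residues carry one pseudo-atom 0.25 nm off the
// backbone.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double KB = 0.0083145;
static const double BOND = 0.38;
static const double RISE = 0.15;
static const double TWIST_DEG = 100.0;
static const double CHARGE_OFFSET = 0.25;
static const double HARDCORE_R = 0.01;
static const double HARDCORE_E = 1e10;
static const double PI_ = 3.141592653589793238462643383280;

// ---------------------------------------------------------------------------
// geometry helpers

static arma::mat helix_template(int n) {
  double phi = TWIST_DEG * PI_ / 180.0;
  double radius = std::sqrt(BOND * BOND - RISE * RISE) / (2.0 * std::sin(phi / 2.0));
  arma::mat T(n, 3);
  for (int i = 0; i < n; i++) {
    T(i, 0) = radius * std::cos(i * phi);
    T(i, 1) = radius * std::sin(i * phi);
    T(i, 2) = i * RISE;
  }
  return T;
}

static double vangle(const arma::rowvec& a, const arma::rowvec& b,
                     const arma::rowvec& c) {
  arma::rowvec u = a - b, v = c - b;
  double cs = arma::dot(u, v) / (arma::norm(u) * arma::norm(v));
  cs = std::max(-1.0, std::min(1.0, cs));
  return std::acos(cs);
}

static double vdihedral(const arma::rowvec& a, const arma::rowvec& b,
                        const arma::rowvec& c, const arma::rowvec& d) {
  arma::rowvec b1 = b - a, b2 = c - b, b3 = d - c;
  arma::rowvec n1 = arma::cross(b1, b2), n2 = arma::cross(b2, b3);
  arma::rowvec m1 = arma::cross(n1, b2 / arma::norm(b2));
  double x = arma::dot(n1, n2), y = arma::dot(m1, n2);
  return std::atan2(y, x);
}

// place point D given A,B,C and internal coordinates (NeRF)
static arma::rowvec nerf(const arma::rowvec& A, const arma::rowvec& B,
                         const arma::rowvec& C, double bond, double theta,
                         double tau) {
  arma::rowvec bc = C - B;
  bc /= arma::norm(bc);
  arma::rowvec ab = B - A;
  arma::rowvec n = arma::cross(ab, bc);
  double nn = arma::norm(n);
  if (nn < 1e-12) { // colinear history: pick any perpendicular
    arma::rowvec ref = {1.0, 0.0, 0.0};
    n = arma::cross(bc, ref);
    if (arma::norm(n) < 1e-12) {
      ref = {0.0, 1.0, 0.0};
      n = arma::cross(bc, ref);
    }
    nn = arma::norm(n);
  }
  n /= nn;
  arma::rowvec m = arma::cross(n, bc);
  double ang = PI_ - theta;
  arma::rowvec d2 = {bond * std::cos(ang), bond * std::cos(tau) * std::sin(ang),
                     -bond * std::sin(tau) * std::sin(ang)};
  return C + d2(0) * bc + d2(1) * m + d2(2) * n;
}

struct HelixInternal {
  double theta;
  double tau;
};

static HelixInternal helix_internal() {
  arma::mat T = helix_template(4);
  HelixInternal h;
  h.theta = vangle(T.row(0), T.row(1), T.row(2));
  h.tau = vdihedral(T.row(0), T.row(1), T.row(2), T.row(3));
  return h;
}

// residues belonging to a maximal h-run of length >= 4
static void helical_built(const std::vector<int>& states, std::vector<int>& run_id,
                          std::vector<bool>& built) {
  int n = states.size();
  run_id.assign(n, -1);
  built.assign(n, false);
  int i = 0, rid = 0;
  while (i < n) {
    if (states[i] == 1) {
      int j = i;
      while (j < n && states[j] == 1) j++;
      for (int k = i; k < j; k++) run_id[k] = rid;
      if (j - i >= 4)
        for (int k = i; k < j; k++) built[k] = true;
      rid++;
      i = j;
    } else {
      i++;
    }
  }
}

static arma::mat build_chain(const std::vector<int>& states,
                             const arma::vec& coil_theta,
                             const arma::vec& coil_tau) {
  int n = states.size();
  static HelixInternal H = helix_internal();
  std::vector<int> run_id;
  std::vector<bool> built;
  helical_built(states, run_id, built);
  arma::mat ca(n, 3, arma::fill::zeros);
  if (n == 0) return ca;
  ca(0, 0) = 0.0;
  if (n > 1) ca(1, 0) = BOND;
  if (n > 2) {
    bool hx = built[0] && built[1] && built[2] && run_id[0] == run_id[2];
    double th = hx ? H.theta : coil_theta(2);
    ca(2, 0) = BOND - BOND * std::cos(th);
    ca(2, 1) = BOND * std::sin(th);
  }
  for (int i = 3; i < n; i++) {
    bool same3 = built[i] && built[i - 1] && built[i - 2] &&
                 run_id[i] == run_id[i - 2];
    bool same4 = same3 && built[i - 3] && run_id[i] == run_id[i - 3];
    double th = same3 ? H.theta : coil_theta(i);
    double ta = same4 ? H.tau : coil_tau(i);
    ca.row(i) = nerf(ca.row(i - 3), ca.row(i - 2), ca.row(i - 1), BOND, th, ta);
  }
  return ca;
}

static arma::mat charge_site_coords(const arma::mat& ca,
                                    const std::vector<int>& charged_idx) {
  int m = charged_idx.size();
  int n = ca.n_rows;
  arma::mat s(m, 3);
  for (int k = 0; k < m; k++) {
    int i = charged_idx[k];
    arma::rowvec d;
    if (n == 1) {
      d = {0.0, 0.0, 1.0};
    } else if (i == 0) {
      d = ca.row(0) - ca.row(1);
    } else if (i == n - 1) {
      d = ca.row(n - 1) - ca.row(n - 2);
    } else {
      d = ca.row(i) - 0.5 * (ca.row(i - 1) + ca.row(i + 1));
    }
    double nd = arma::norm(d);
    if (nd < 1e-8) { // straight chain: any perpendicular to the local axis
      arma::rowvec ax = ca.row(std::min(i + 1, n - 1)) - ca.row(std::max(i - 1, 0));
      arma::rowvec ref = {1.0, 0.0, 0.0};
      d = arma::cross(ax, ref);
      if (arma::norm(d) < 1e-8) {
        ref = {0.0, 1.0, 0.0};
        d = arma::cross(ax, ref);
      }
      nd = arma::norm(d);
    }
    s.row(k) = ca.row(i) + CHARGE_OFFSET * d / nd;
  }
  return s;
}

// ---------------------------------------------------------------------------
// collective variables

static double kabsch_rmsd(const arma::mat& A, const arma::mat& B) {
  arma::mat Ac = A.each_row() - arma::mean(A, 0);
  arma::mat Bc = B.each_row() - arma::mean(B, 0);
  arma::mat C = Ac.t() * Bc;
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, C);
  double d = arma::det(V * U.t());
  double tr = s(0) + s(1) + (d < 0 ? -s(2) : s(2));
  double e = (arma::accu(Ac % Ac) + arma::accu(Bc % Bc) - 2.0 * tr) / A.n_rows;
  return std::sqrt(std::max(0.0, e));
}

static double rational_switch_cpp(double x, double n, double m) {
  if (std::fabs(x - 1.0) < 1e-9) return n / m;
  return (1.0 - std::pow(x, n)) / (1.0 - std::pow(x, m));
}

static double cv_salpha(const arma::mat& ca, const arma::mat& tmpl6, double r0,
                        double n, double m) {
  int L = ca.n_rows;
  if (L < 6) return 0.0;
  double tot = 0.0;
  for (int i = 0; i + 5 < L; i++) {
    double r = kabsch_rmsd(ca.rows(i, i + 5), tmpl6);
    tot += rational_switch_cpp(r / r0, n, m);
  }
  return tot;
}

static double cv_srg(const arma::mat& ca) {
  arma::rowvec com = arma::mean(ca, 0);
  double s = 0.0;
  for (arma::uword i = 0; i < ca.n_rows; i++) {
    arma::rowvec d = ca.row(i) - com;
    s += arma::dot(d, d);
  }
  return std::sqrt(s / ca.n_rows);
}

// ---------------------------------------------------------------------------
// model state and energy

struct DnaRod {
  arma::mat sites;       // phosphate coordinates
  std::vector<bool> central;
  double site_charge;    // usually -1
  arma::rowvec center;   // central-bp reference point
  bool present = false;
};

struct Model {
  int L;
  arma::vec log_w;       // per-residue propagation weight (log)
  double log_v;          // nucleation weight (log)
  arma::vec charge;      // per-residue charge after neutralization handling
  std::vector<int> charged_idx;
  double debye;
  double pref;           // kJ/mol nm, screened-Coulomb prefactor
  double dna_strength;   // scales the rod interaction
  double t_ref;          // temperature defining the helix-coil energy scale
  DnaRod rod;
  arma::mat tmpl6;
  double sa_r0 = 0.08, sa_n = 8.0, sa_m = 12.0;
  double sc_r0 = 0.20, sc_n = 8.0, sc_m = 10.0;
};

struct Conf {
  std::vector<int> states;
  arma::vec coil_theta, coil_tau;
  arma::rowvec shift;    // rigid-body offset of the whole peptide
  arma::mat ca;          // includes shift
  arma::mat sites;       // charge pseudo-atoms, includes shift
};

static void rebuild(Conf& c, const Model& M) {
  c.ca = build_chain(c.states, c.coil_theta, c.coil_tau);
  c.ca.each_row() += c.shift;
  c.sites = charge_site_coords(c.ca, M.charged_idx);
}

struct EnergyTerms {
  double hc = 0, elec = 0, dna = 0;
  double total() const { return hc + elec + dna; }
};

static EnergyTerms energy_terms(const Conf& c, const Model& M) {
  EnergyTerms E;
  int n_runs = 0;
  double sum_logw = 0.0;
  for (int i = 0; i < M.L; i++) {
    if (c.states[i] == 1) {
      sum_logw += M.log_w(i);
      if (i == 0 || c.states[i - 1] == 0) n_runs++;
    }
  }
  E.hc = -KB * M.t_ref * (sum_logw + n_runs * M.log_v);
  int m = M.charged_idx.size();
  for (int a = 0; a < m; a++) {
    double qa = M.charge(M.charged_idx[a]);
    for (int b = a + 1; b < m; b++) {
      double r = arma::norm(c.sites.row(a) - c.sites.row(b));
      if (r < HARDCORE_R) {
        E.elec = HARDCORE_E;
        return E;
      }
      E.elec += M.pref * qa * M.charge(M.charged_idx[b]) *
                std::exp(-r / M.debye) / r;
    }
  }
  if (M.rod.present) {
    for (int a = 0; a < m; a++) {
      double qa = M.charge(M.charged_idx[a]);
      for (arma::uword j = 0; j < M.rod.sites.n_rows; j++) {
        double r = arma::norm(c.sites.row(a) - M.rod.sites.row(j));
        if (r < HARDCORE_R) {
          E.dna = HARDCORE_E;
          return E;
        }
        E.dna += M.pref * M.dna_strength * qa * M.rod.site_charge *
                 std::exp(-r / M.debye) / r;
      }
    }
  }
  return E;
}

// ---------------------------------------------------------------------------
// collective-variable dispatch
// ids: 1 s_alpha, 2 s_rg, 3 s_cont, 4 rdist, 5 energy, 6 n_h

static double eval_cv(int id, const Conf& c, const Model& M, double U) {
  switch (id) {
  case 1:
    return cv_salpha(c.ca, M.tmpl6, M.sa_r0, M.sa_n, M.sa_m);
  case 2:
    return cv_srg(c.ca);
  case 3: {
    if (!M.rod.present) return 0.0;
    double tot = 0.0;
    for (arma::uword a = 0; a < c.sites.n_rows; a++) {
      if (M.charge(M.charged_idx[a]) <= 0) continue;
      for (arma::uword j = 0; j < M.rod.sites.n_rows; j++) {
        if (!M.rod.central[j]) continue;
        double r = arma::norm(c.sites.row(a) - M.rod.sites.row(j));
        tot += rational_switch_cpp(r / M.sc_r0, M.sc_n, M.sc_m);
      }
    }
    return tot;
  }
  case 4: {
    if (!M.rod.present) return 0.0;
    arma::rowvec cen = arma::mean(c.ca, 0);
    double dx = cen(0) - M.rod.center(0), dy = cen(1) - M.rod.center(1);
    return std::sqrt(dx * dx + dy * dy);
  }
  case 5:
    return U;
  case 6: {
    int k = 0;
    for (int i = 0; i < M.L; i++) k += c.states[i];
    return (double)k;
  }
  }
  return 0.0;
}

// ---------------------------------------------------------------------------
// metadynamics bias

struct Bias {
  bool active = false;
  bool frozen = false;
  int dim = 0;
  int cv1 = 0, cv2 = 0;
  double sigma1 = 0.1, sigma2 = 0.1;
  double W = 1.0;
  double gamma = std::numeric_limits<double>::infinity();
  int stride = 500;
  std::vector<double> t, c1, c2, h;

  double value(double s1, double s2) const {
    double v = 0.0;
    for (size_t k = 0; k < t.size(); k++) {
      double z = (s1 - c1[k]) * (s1 - c1[k]) / (2.0 * sigma1 * sigma1);
      if (dim == 2) z += (s2 - c2[k]) * (s2 - c2[k]) / (2.0 * sigma2 * sigma2);
      v += h[k] * std::exp(-z);
    }
    return v;
  }

  void deposit(double time, double s1, double s2, double temperature) {
    double height = W;
    if (std::isfinite(gamma)) {
      double dT = (gamma - 1.0) * temperature;
      height = W * std::exp(-value(s1, s2) / (KB * dT));
    }
    t.push_back(time);
    c1.push_back(s1);
    c2.push_back(dim == 2 ? s2 : 0.0);
    h.push_back(height);
  }
};

static Bias bias_from_list(Nullable<List> spec_) {
  Bias b;
  if (spec_.isNull()) return b;
  List spec(spec_);
  b.active = true;
  IntegerVector cvs = spec["cv_ids"];
  b.dim = cvs.size();
  b.cv1 = cvs[0];
  b.cv2 = b.dim > 1 ? cvs[1] : 0;
  NumericVector sig = spec["sigma"];
  b.sigma1 = sig[0];
  b.sigma2 = b.dim > 1 ? sig[1] : sig[0];
  b.W = as<double>(spec["height"]);
  b.gamma = as<double>(spec["gamma"]);
  b.stride = as<int>(spec["stride"]);
  b.frozen = as<bool>(spec["frozen"]);
  if (spec.containsElementNamed("kernels")) {
    NumericMatrix k = spec["kernels"];
    for (int i = 0; i < k.nrow(); i++) {
      b.t.push_back(k(i, 0));
      b.c1.push_back(k(i, 1));
      b.c2.push_back(k(i, 2));
      b.h.push_back(k(i, 3));
    }
  }
  return b;
}

static NumericMatrix bias_kernels(const Bias& b) {
  NumericMatrix k(b.t.size(), 4);
  for (size_t i = 0; i < b.t.size(); i++) {
    k(i, 0) = b.t[i];
    k(i, 1) = b.c1[i];
    k(i, 2) = b.c2[i];
    k(i, 3) = b.h[i];
  }
  colnames(k) = CharacterVector::create("time", "center1", "center2", "height");
  return k;
}

// ---------------------------------------------------------------------------
// exported geometry / CV helpers

// [[Rcpp::export(name = ".cpp_helix_template")]]
arma::mat cpp_helix_template(int n) { return helix_template(n); }

// [[Rcpp::export(name = ".cpp_build_chain")]]
arma::mat cpp_build_chain(IntegerVector states, NumericVector coil_theta,
                          NumericVector coil_tau) {
  std::vector<int> st = as<std::vector<int>>(states);
  return build_chain(st, as<arma::vec>(coil_theta), as<arma::vec>(coil_tau));
}

// [[Rcpp::export(name = ".cpp_charge_sites")]]
arma::mat cpp_charge_sites(arma::mat ca, IntegerVector charged_idx0) {
  std::vector<int> idx = as<std::vector<int>>(charged_idx0);
  return charge_site_coords(ca, idx);
}

// [[Rcpp::export(name = ".cpp_kabsch_rmsd")]]
double cpp_kabsch_rmsd(arma::mat A, arma::mat B) { return kabsch_rmsd(A, B); }

// [[Rcpp::export(name = ".cpp_salpha")]]
double cpp_salpha(arma::mat ca, arma::mat tmpl6, double r0, double n, double m) {
  return cv_salpha(ca, tmpl6, r0, n, m);
}

// ---------------------------------------------------------------------------
// model assembly from R lists

static Model model_from_list(List mspec, Nullable<List> rod_) {
  Model M;
  M.log_w = arma::log(as<arma::vec>(mspec["w"]));
  M.L = M.log_w.n_elem;
  M.log_v = std::log(as<double>(mspec["v"]));
  M.charge = as<arma::vec>(mspec["charge"]);
  for (int i = 0; i < M.L; i++) {
    if (M.charge(i) != 0.0) M.charged_idx.push_back(i);
  }
  M.debye = as<double>(mspec["debye"]);
  M.pref = as<double>(mspec["prefactor"]);
  M.dna_strength = as<double>(mspec["dna_strength"]);
  M.t_ref = as<double>(mspec["t_ref"]);
  M.tmpl6 = helix_template(6);
  if (rod_.isNotNull()) {
    List rod(rod_);
    M.rod.present = true;
    M.rod.sites = as<arma::mat>(rod["sites"]);
    LogicalVector cen = rod["central"];
    M.rod.central.assign(cen.begin(), cen.end());
    M.rod.site_charge = as<double>(rod["site_charge"]);
    M.rod.center = as<arma::rowvec>(rod["center"]);
  }
  return M;
}

// [[Rcpp::export(name = ".cpp_energy")]]
List cpp_energy(List mspec, Nullable<List> rod, IntegerVector states,
                NumericVector coil_theta, NumericVector coil_tau,
                NumericVector shift) {
  Model M = model_from_list(mspec, rod);
  Conf c;
  c.states = as<std::vector<int>>(states);
  c.coil_theta = as<arma::vec>(coil_theta);
  c.coil_tau = as<arma::vec>(coil_tau);
  c.shift = as<arma::rowvec>(shift);
  rebuild(c, M);
  EnergyTerms E = energy_terms(c, M);
  return List::create(
      _["hc"] = E.hc, _["elec"] = E.elec, _["dna"] = E.dna,
      _["total"] = E.total(), _["ca"] = c.ca, _["sites"] = c.sites);
}

// ---------------------------------------------------------------------------
// main Monte Carlo driver

// [[Rcpp::export(name = ".cpp_cg_run")]]
List cpp_cg_run(List mspec, Nullable<List> rod, IntegerVector states0,
                NumericVector coil_theta0, NumericVector coil_tau0,
                NumericVector shift0, double temperature, int n_sweeps,
                int record_stride, NumericVector move_prob,
                Nullable<List> biasA_, Nullable<List> biasB_,
                Nullable<List> umbrella_, bool record_states,
                double time_offset) {
  RNGScope scope;
  Model M = model_from_list(mspec, rod);
  Conf c;
  c.states = as<std::vector<int>>(states0);
  c.coil_theta = as<arma::vec>(coil_theta0);
  c.coil_tau = as<arma::vec>(coil_tau0);
  c.shift = as<arma::rowvec>(shift0);
  rebuild(c, M);

  Bias bA = bias_from_list(biasA_); // e.g. frozen WTE bias
  Bias bB = bias_from_list(biasB_); // e.g. production CV bias
  bool umb = false;
  int umb_cv = 0;
  double umb_center = 0, umb_k = 0;
  if (umbrella_.isNotNull()) {
    List u(umbrella_);
    umb = true;
    umb_cv = as<int>(u["cv_id"]);
    umb_center = as<double>(u["center"]);
    umb_k = as<double>(u["k"]);
  }

  double beta = 1.0 / (KB * temperature);
  EnergyTerms E = energy_terms(c, M);
  double U = E.total();

  auto cvs_of = [&](const Conf& cc, double Uc, double* sA1, double* sA2,
                    double* sB1, double* sB2, double* su) {
    if (bA.active) {
      *sA1 = eval_cv(bA.cv1, cc, M, Uc);
      *sA2 = bA.dim == 2 ? eval_cv(bA.cv2, cc, M, Uc) : 0.0;
    }
    if (bB.active) {
      *sB1 = eval_cv(bB.cv1, cc, M, Uc);
      *sB2 = bB.dim == 2 ? eval_cv(bB.cv2, cc, M, Uc) : 0.0;
    }
    if (umb) *su = eval_cv(umb_cv, cc, M, Uc);
  };

  double sA1 = 0, sA2 = 0, sB1 = 0, sB2 = 0, su = 0;
  cvs_of(c, U, &sA1, &sA2, &sB1, &sB2, &su);
  double H = U + (bA.active ? bA.value(sA1, sA2) : 0.0) +
             (bB.active ? bB.value(sB1, sB2) : 0.0) +
             (umb ? 0.5 * umb_k * (su - umb_center) * (su - umb_center) : 0.0);

  int n_rec = n_sweeps / record_stride;
  int ncol = 12;
  NumericMatrix frames(n_rec, ncol);
  colnames(frames) = CharacterVector::create(
      "sweep", "e_total", "e_hc", "e_elec", "e_dna", "s_alpha", "s_rg",
      "s_cont", "rdist", "n_h", "bias", "bias_wte");
  NumericVector state_codes(record_states ? n_rec : 0);

  long accepted = 0, attempted = 0;
  double p_flip = move_prob[0], p_dih = move_prob[1];

  for (int sweep = 1; sweep <= n_sweeps; sweep++) {
    for (int mv = 0; mv < M.L; mv++) {
      attempted++;
      Conf cand = c;
      double r = R::unif_rand();
      if (r < p_flip) {
        int i = (int)std::floor(R::unif_rand() * M.L);
        cand.states[i] = 1 - cand.states[i];
        rebuild(cand, M);
      } else if (r < p_flip + p_dih) {
        int i = (int)std::floor(R::unif_rand() * M.L);
        double th = cand.coil_theta(i) + R::norm_rand() * (10.0 * PI_ / 180.0);
        double ta = cand.coil_tau(i) + R::norm_rand() * (30.0 * PI_ / 180.0);
        if (th < 75.0 * PI_ / 180.0 || th > 145.0 * PI_ / 180.0) continue;
        // wrap to (-pi, pi] without fmod (keeps glibc symbol deps minimal)
        ta = ta - 2.0 * PI_ * std::floor((ta + PI_) / (2.0 * PI_));
        cand.coil_theta(i) = th;
        cand.coil_tau(i) = ta;
        rebuild(cand, M);
      } else {
        arma::rowvec dx = {R::norm_rand(), R::norm_rand(), R::norm_rand()};
        cand.shift = c.shift + 0.05 * dx;
        cand.ca = c.ca;
        cand.ca.each_row() += (cand.shift - c.shift);
        cand.sites = c.sites;
        cand.sites.each_row() += (cand.shift - c.shift);
      }
      EnergyTerms Ec = energy_terms(cand, M);
      double Uc = Ec.total();
      double cA1 = 0, cA2 = 0, cB1 = 0, cB2 = 0, cu = 0;
      cvs_of(cand, Uc, &cA1, &cA2, &cB1, &cB2, &cu);
      double Hc = Uc + (bA.active ? bA.value(cA1, cA2) : 0.0) +
                  (bB.active ? bB.value(cB1, cB2) : 0.0) +
                  (umb ? 0.5 * umb_k * (cu - umb_center) * (cu - umb_center)
                       : 0.0);
      if (Hc <= H || R::unif_rand() < std::exp(-beta * (Hc - H))) {
        c = cand;
        E = Ec;
        U = Uc;
        sA1 = cA1; sA2 = cA2; sB1 = cB1; sB2 = cB2; su = cu;
        H = Hc;
        accepted++;
      }
    }
    double tnow = time_offset + sweep;
    if (bA.active && !bA.frozen && sweep % bA.stride == 0) {
      bA.deposit(tnow, sA1, sA2, temperature);
      H = U + bA.value(sA1, sA2) + (bB.active ? bB.value(sB1, sB2) : 0.0) +
          (umb ? 0.5 * umb_k * (su - umb_center) * (su - umb_center) : 0.0);
    }
    if (bB.active && !bB.frozen && sweep % bB.stride == 0) {
      bB.deposit(tnow, sB1, sB2, temperature);
      H = U + (bA.active ? bA.value(sA1, sA2) : 0.0) + bB.value(sB1, sB2) +
          (umb ? 0.5 * umb_k * (su - umb_center) * (su - umb_center) : 0.0);
    }
    if (sweep % record_stride == 0) {
      int row = sweep / record_stride - 1;
      frames(row, 0) = tnow;
      frames(row, 1) = U;
      frames(row, 2) = E.hc;
      frames(row, 3) = E.elec;
      frames(row, 4) = E.dna;
      frames(row, 5) = eval_cv(1, c, M, U);
      frames(row, 6) = eval_cv(2, c, M, U);
      frames(row, 7) = M.rod.present ? eval_cv(3, c, M, U) : NA_REAL;
      frames(row, 8) = M.rod.present ? eval_cv(4, c, M, U) : NA_REAL;
      frames(row, 9) = eval_cv(6, c, M, U);
      frames(row, 10) = bB.active ? bB.value(sB1, sB2) : 0.0;
      frames(row, 11) = bA.active ? bA.value(sA1, sA2) : 0.0;
      if (record_states) {
        double code = 0;
        for (int i = 0; i < M.L && i < 52; i++) {
          if (c.states[i] == 1) code += std::pow(2.0, i);
        }
        state_codes[row] = code;
      }
    }
  }

  return List::create(
      _["frames"] = frames, _["state_codes"] = state_codes,
      _["states"] = wrap(c.states),
      _["coil_theta"] = wrap(c.coil_theta),
      _["coil_tau"] = wrap(c.coil_tau), _["shift"] = wrap(c.shift),
      _["energy"] = U, _["acceptance"] = (double)accepted / attempted,
      _["kernelsA"] = bias_kernels(bA), _["kernelsB"] = bias_kernels(bB));
}

// ---------------------------------------------------------------------------
// toy one-dimensional systems (analytic potentials)
// potential ids: 1 double well U = a*(x^2-1)^2, 2 harmonic U = 0.5*k*x^2
// cv ids: 1 x, 5 energy

static double toy_U(int pot, const arma::vec& p, double x) {
  if (pot == 1) {
    double z = x * x - 1.0;
    return p(0) * z * z;
  }
  return 0.5 * p(0) * x * x;
}

// [[Rcpp::export(name = ".cpp_toy_run")]]
List cpp_toy_run(int potential, NumericVector pot_params, double x0,
                 double step_sd, double temperature, int n_steps,
                 int record_stride, Nullable<List> biasA_,
                 Nullable<List> biasB_, Nullable<List> umbrella_,
                 double time_offset) {
  RNGScope scope;
  arma::vec pp = as<arma::vec>(pot_params);
  Bias bA = bias_from_list(biasA_);
  Bias bB = bias_from_list(biasB_);
  bool umb = false;
  double umb_center = 0, umb_k = 0;
  if (umbrella_.isNotNull()) {
    List u(umbrella_);
    umb = true;
    umb_center = as<double>(u["center"]);
    umb_k = as<double>(u["k"]);
  }
  double beta = 1.0 / (KB * temperature);
  double x = x0;
  double U = toy_U(potential, pp, x);

  auto cv_val = [&](int id, double xx, double Uu) {
    return id == 5 ? Uu : xx;
  };
  auto ham = [&](double xx, double Uu) {
    double h = Uu;
    if (bA.active)
      h += bA.value(cv_val(bA.cv1, xx, Uu),
                    bA.dim == 2 ? cv_val(bA.cv2, xx, Uu) : 0.0);
    if (bB.active)
      h += bB.value(cv_val(bB.cv1, xx, Uu),
                    bB.dim == 2 ? cv_val(bB.cv2, xx, Uu) : 0.0);
    if (umb) h += 0.5 * umb_k * (xx - umb_center) * (xx - umb_center);
    return h;
  };

  double H = ham(x, U);
  int n_rec = n_steps / record_stride;
  NumericMatrix frames(n_rec, 5);
  colnames(frames) =
      CharacterVector::create("sweep", "x", "e_total", "bias", "bias_wte");
  long accepted = 0;
  for (int step = 1; step <= n_steps; step++) {
    double xc = x + R::norm_rand() * step_sd;
    double Uc = toy_U(potential, pp, xc);
    double Hc = ham(xc, Uc);
    if (Hc <= H || R::unif_rand() < std::exp(-beta * (Hc - H))) {
      x = xc;
      U = Uc;
      H = Hc;
      accepted++;
    }
    double tnow = time_offset + step;
    if (bA.active && !bA.frozen && step % bA.stride == 0) {
      double s1 = cv_val(bA.cv1, x, U);
      double s2 = bA.dim == 2 ? cv_val(bA.cv2, x, U) : 0.0;
      bA.deposit(tnow, s1, s2, temperature);
      H = ham(x, U);
    }
    if (bB.active && !bB.frozen && step % bB.stride == 0) {
      double s1 = cv_val(bB.cv1, x, U);
      double s2 = bB.dim == 2 ? cv_val(bB.cv2, x, U) : 0.0;
      bB.deposit(tnow, s1, s2, temperature);
      H = ham(x, U);
    }
    if (step % record_stride == 0) {
      int row = step / record_stride - 1;
      frames(row, 0) = tnow;
      frames(row, 1) = x;
      frames(row, 2) = U;
      frames(row, 3) =
          bB.active ? bB.value(cv_val(bB.cv1, x, U),
                               bB.dim == 2 ? cv_val(bB.cv2, x, U) : 0.0)
                    : 0.0;
      frames(row, 4) =
          bA.active ? bA.value(cv_val(bA.cv1, x, U),
                               bA.dim == 2 ? cv_val(bA.cv2, x, U) : 0.0)
                    : 0.0;
    }
  }
  return List::create(_["frames"] = frames, _["x"] = x, _["energy"] = U,
                      _["acceptance"] = (double)accepted / n_steps,
                      _["kernelsA"] = bias_kernels(bA),
                      _["kernelsB"] = bias_kernels(bB));
}

// evaluate a bias (kernel matrix) on a grid of CV points
// [[Rcpp::export(name = ".cpp_bias_grid")]]
NumericVector cpp_bias_grid(NumericMatrix kernels, NumericMatrix pts,
                            NumericVector sigma, double t_max) {
  int np = pts.nrow();
  int dim = pts.ncol();
  NumericVector out(np);
  for (int i = 0; i < np; i++) {
    double v = 0.0;
    for (int k = 0; k < kernels.nrow(); k++) {
      if (kernels(k, 0) > t_max) break;
      double z = (pts(i, 0) - kernels(k, 1)) * (pts(i, 0) - kernels(k, 1)) /
                 (2.0 * sigma[0] * sigma[0]);
      if (dim == 2)
        z += (pts(i, 1) - kernels(k, 2)) * (pts(i, 1) - kernels(k, 2)) /
             (2.0 * sigma[1] * sigma[1]);
      v += kernels(k, 3) * std::exp(-z);
    }
    out[i] = v;
  }
  return out;
}
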