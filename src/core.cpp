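// Compiled core: analytic host potentials, bonded guest terms, collective
// variables with analytic gradients, BAOAB Langevin integrator and the
// extended-system ABF engine.  Units: A, ps, amu, kcal/mol; angles are
// reported in degrees (gradients in degrees/A) to match the conventional
// angular force-constant units kcal/(mol degree^2).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double KB   = 0.0019872041;      // kcal/(mol K)
static const double FKE  = 1.0 / 418.4;       // kcal/mol per amu (A/ps)^2
static const double D2R  = M_PI / 180.0;

// ---------------------------------------------------------------------------
// Host potentials
// ---------------------------------------------------------------------------

struct Host {
  int type; // 0 none, 1 wells, 2 axis_double_well, 3 harmonic, 4 square_well
  arma::mat centers;              // wells: one row per well
  arma::vec depths, sigmas;
  arma::vec axis, center;         // axis_double_well / harmonic / square_well
  double height, halfwidth, kperp, kh, radius, swdepth;
};

static Host parse_host(const List& h) {
  Host out;
  std::string ty = as<std::string>(h["type"]);
  if (ty == "none") { out.type = 0; return out; }
  if (ty == "wells") {
    out.type = 1;
    out.centers = as<arma::mat>(h["centers"]);
    out.depths  = as<arma::vec>(h["depths"]);
    out.sigmas  = as<arma::vec>(h["sigmas"]);
    return out;
  }
  if (ty == "axis_double_well") {
    out.type = 2;
    out.axis = arma::normalise(as<arma::vec>(h["axis"]));
    out.center = as<arma::vec>(h["center"]);
    out.height = as<double>(h["height"]);
    out.halfwidth = as<double>(h["halfwidth"]);
    out.kperp = as<double>(h["k_perp"]);
    return out;
  }
  if (ty == "harmonic") {
    out.type = 3;
    out.center = as<arma::vec>(h["center"]);
    out.kh = as<double>(h["k"]);
    return out;
  }
  if (ty == "square_well") {
    out.type = 4;
    out.center = as<arma::vec>(h["center"]);
    out.radius = as<double>(h["radius"]);
    out.swdepth = as<double>(h["depth"]);
    return out;
  }
  stop("unknown host potential type '" + ty + "'");
}

// energy of one bead in the host field; adds -dU/dx into f
static double host_bead(const Host& h, const arma::rowvec& x, arma::rowvec& f) {
  double u = 0.0;
  switch (h.type) {
  case 0: break;
  case 1:
    for (arma::uword w = 0; w < h.depths.n_elem; ++w) {
      arma::rowvec d = x - h.centers.row(w);
      double s2 = h.sigmas(w) * h.sigmas(w);
      double e  = std::exp(-arma::dot(d, d) / (2.0 * s2));
      u += -h.depths(w) * e;
      f += -h.depths(w) * e * d / s2;   // -dU/dx
    }
    break;
  case 2: {
    arma::rowvec d = x - h.center.t();
    double s = arma::dot(d, h.axis.t());
    arma::rowvec perp = d - s * h.axis.t();
    double w4 = std::pow(h.halfwidth, 4);
    u += h.height * std::pow(s * s - h.halfwidth * h.halfwidth, 2) / w4
       + 0.5 * h.kperp * arma::dot(perp, perp);
    double duds = h.height * 4.0 * s * (s * s - h.halfwidth * h.halfwidth) / w4;
    f += -duds * h.axis.t() - h.kperp * perp;
    break;
  }
  case 3: {
    arma::rowvec d = x - h.center.t();
    u += 0.5 * h.kh * arma::dot(d, d);
    f += -h.kh * d;
    break;
  }
  case 4: {
    arma::rowvec d = x - h.center.t();
    if (std::sqrt(arma::dot(d, d)) < h.radius) u += -h.swdepth;
    // discontinuous: no force; intended for quadrature oracles, not dynamics
    break;
  }
  }
  return u;
}

// ---------------------------------------------------------------------------
// Bonded terms
// ---------------------------------------------------------------------------

// dihedral angle (radians) of 4 points with gradients (per point, 1/A)
static double dihedral_raw(const arma::rowvec& p1, const arma::rowvec& p2,
                           const arma::rowvec& p3, const arma::rowvec& p4,
                           arma::rowvec g[4], bool& ok) {
  arma::rowvec b1 = p2 - p1, b2 = p3 - p2, b3 = p4 - p3;
  arma::rowvec n1 = arma::cross(b1, b2), n2 = arma::cross(b2, b3);
  double nn1 = arma::dot(n1, n1), nn2 = arma::dot(n2, n2);
  double nb2 = std::sqrt(arma::dot(b2, b2));
  if (nn1 < 1e-18 || nn2 < 1e-18 || nb2 < 1e-12) {
    ok = false;
    for (int i = 0; i < 4; ++i) g[i].zeros(3);
    return 0.0;
  }
  ok = true;
  double y = arma::dot(arma::cross(n1, n2), b2) / nb2;
  double x = arma::dot(n1, n2);
  double phi = std::atan2(y, x);
  g[0] = -nb2 / nn1 * n1;
  g[3] =  nb2 / nn2 * n2;
  double c12 = arma::dot(b1, b2) / (nb2 * nb2);
  double c32 = arma::dot(b3, b2) / (nb2 * nb2);
  g[1] = -(1.0 + c12) * g[0] + c32 * g[3];
  g[2] = -(1.0 + c32) * g[3] + c12 * g[0];
  return phi;
}

struct SystemC {
  int n;
  arma::vec mass;
  arma::mat bonds;      // i j k r0   (0-based already)
  arma::mat dihedrals;  // i j k l kd mult phi0_deg
  Host host;
};

static SystemC parse_system(const List& sys) {
  SystemC s;
  s.mass = as<arma::vec>(sys["masses"]);
  s.n = s.mass.n_elem;
  s.bonds = sys.containsElementNamed("bonds") && !Rf_isNull(sys["bonds"]) ?
    as<arma::mat>(sys["bonds"]) : arma::mat(0, 4);
  s.dihedrals = sys.containsElementNamed("dihedrals") && !Rf_isNull(sys["dihedrals"]) ?
    as<arma::mat>(sys["dihedrals"]) : arma::mat(0, 7);
  s.host = parse_host(as<List>(sys["host"]));
  return s;
}

// total potential energy; if f != NULL accumulate forces
static double system_energy(const SystemC& s, const arma::mat& X, arma::mat* f) {
  if (!X.is_finite()) stop("non-finite positions in energy evaluation");
  double u = 0.0;
  arma::rowvec fb(3);
  for (int i = 0; i < s.n; ++i) {
    fb.zeros();
    u += host_bead(s.host, X.row(i), fb);
    if (f) f->row(i) += fb;
  }
  for (arma::uword b = 0; b < s.bonds.n_rows; ++b) {
    int i = (int)s.bonds(b, 0), j = (int)s.bonds(b, 1);
    double k = s.bonds(b, 2), r0 = s.bonds(b, 3);
    arma::rowvec d = X.row(i) - X.row(j);
    double r = std::sqrt(arma::dot(d, d));
    u += 0.5 * k * (r - r0) * (r - r0);
    if (f && r > 1e-12) {
      arma::rowvec fr = -k * (r - r0) * d / r;
      f->row(i) += fr;
      f->row(j) -= fr;
    }
  }
  for (arma::uword d = 0; d < s.dihedrals.n_rows; ++d) {
    int i = (int)s.dihedrals(d, 0), j = (int)s.dihedrals(d, 1),
        k = (int)s.dihedrals(d, 2), l = (int)s.dihedrals(d, 3);
    double kd = s.dihedrals(d, 4), mult = s.dihedrals(d, 5),
           phi0 = s.dihedrals(d, 6) * D2R;
    arma::rowvec g[4]; bool ok;
    double phi = dihedral_raw(X.row(i), X.row(j), X.row(k), X.row(l), g, ok);
    if (!ok) continue;
    u += kd * (1.0 + std::cos(mult * phi - phi0));
    double dud = -kd * mult * std::sin(mult * phi - phi0);
    if (f) {
      f->row(i) -= dud * g[0]; f->row(j) -= dud * g[1];
      f->row(k) -= dud * g[2]; f->row(l) -= dud * g[3];
    }
  }
  return u;
}

// ---------------------------------------------------------------------------
// Collective variables
// ---------------------------------------------------------------------------

struct CVSpec {
  std::string kind;
  arma::uvec atoms;     // 0-based
  arma::vec  amass;     // masses of those atoms
  arma::vec  origin;    // host frame origin
  arma::mat  A;         // 3x3, rows = host axes (v_host = A (x - origin))
  arma::mat  ref;       // centered reference coords (k x 3)
  arma::vec  axis;      // axis_projection direction, host frame
  int rmsd_mode;        // 0 fitted, 1 dmatrix
};

static CVSpec parse_cv(const List& cv, const arma::vec& mass) {
  CVSpec c;
  c.kind = as<std::string>(cv["kind"]);
  if (cv.containsElementNamed("atoms") && !Rf_isNull(cv["atoms"])) {
    arma::uvec a1 = as<arma::uvec>(cv["atoms"]);
    c.atoms = a1 - 1;
  } else {
    c.atoms = arma::regspace<arma::uvec>(0, mass.n_elem - 1);
  }
  c.amass = mass.elem(c.atoms);
  c.origin = cv.containsElementNamed("origin") && !Rf_isNull(cv["origin"]) ?
    as<arma::vec>(cv["origin"]) : arma::vec(3, arma::fill::zeros);
  c.A = cv.containsElementNamed("frame") && !Rf_isNull(cv["frame"]) ?
    as<arma::mat>(cv["frame"]) : arma::mat(3, 3, arma::fill::eye);
  if (cv.containsElementNamed("ref") && !Rf_isNull(cv["ref"])) {
    arma::mat r = as<arma::mat>(cv["ref"]);
    c.ref = r.each_row() - arma::mean(r, 0);
  }
  c.axis = cv.containsElementNamed("axis") && !Rf_isNull(cv["axis"]) ?
    arma::normalise(as<arma::vec>(cv["axis"])) : arma::vec({1, 0, 0});
  c.rmsd_mode = 0;
  if (cv.containsElementNamed("mode") && !Rf_isNull(cv["mode"]))
    c.rmsd_mode = as<std::string>(cv["mode"]) == "dmatrix" ? 1 : 0;
  return c;
}

// quaternion -> rotation matrix (maps reference onto moving frame)
static arma::mat33 quat_to_rot(const arma::vec4& q) {
  double q0 = q(0), q1 = q(1), q2 = q(2), q3 = q(3);
  arma::mat33 R;
  R(0,0) = q0*q0+q1*q1-q2*q2-q3*q3; R(0,1) = 2*(q1*q2-q0*q3); R(0,2) = 2*(q1*q3+q0*q2);
  R(1,0) = 2*(q1*q2+q0*q3); R(1,1) = q0*q0-q1*q1+q2*q2-q3*q3; R(1,2) = 2*(q2*q3-q0*q1);
  R(2,0) = 2*(q1*q3-q0*q2); R(2,1) = 2*(q2*q3+q0*q1); R(2,2) = q0*q0-q1*q1-q2*q2+q3*q3;
  return R;
}

// Horn key matrix from the 3x3 correlation S = Z^T Y
static arma::mat44 horn_matrix(const arma::mat33& S) {
  arma::mat44 N;
  N(0,0) =  S(0,0)+S(1,1)+S(2,2);
  N(0,1) = N(1,0) = S(1,2)-S(2,1);
  N(0,2) = N(2,0) = S(2,0)-S(0,2);
  N(0,3) = N(3,0) = S(0,1)-S(1,0);
  N(1,1) =  S(0,0)-S(1,1)-S(2,2);
  N(1,2) = N(2,1) = S(0,1)+S(1,0);
  N(1,3) = N(3,1) = S(2,0)+S(0,2);
  N(2,2) = -S(0,0)+S(1,1)-S(2,2);
  N(2,3) = N(3,2) = S(1,2)+S(2,1);
  N(3,3) = -S(0,0)-S(1,1)+S(2,2);
  return N;
}

// best-fit rotation of centered ref Z onto centered moving Y plus the
// eigen-system needed for gradients
struct FitResult {
  arma::mat33 R;        // y ~ R z
  arma::vec4 q, eval;
  arma::mat44 evec;     // columns
  bool degenerate;
};

// cyclic Jacobi eigensolver for symmetric 4x4 matrices (ascending order);
// much cheaper than a LAPACK call at this size and called every MD step
static void jacobi4(arma::mat44 A, arma::vec4& eval, arma::mat44& evec) {
  evec.eye();
  double nrm2 = arma::accu(A % A) + 1e-300;
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = 0.0;
    for (int p = 0; p < 3; ++p)
      for (int q = p + 1; q < 4; ++q) off += A(p, q) * A(p, q);
    if (off < 1e-28 * nrm2) break;
    for (int p = 0; p < 3; ++p) for (int q = p + 1; q < 4; ++q) {
      if (std::abs(A(p, q)) < 1e-300) continue;
      double theta = (A(q, q) - A(p, p)) / (2.0 * A(p, q));
      double t = (theta >= 0 ? 1.0 : -1.0) /
        (std::abs(theta) + std::sqrt(theta * theta + 1.0));
      double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
      for (int k = 0; k < 4; ++k) {
        double akp = A(k, p), akq = A(k, q);
        A(k, p) = c * akp - s * akq;
        A(k, q) = s * akp + c * akq;
      }
      for (int k = 0; k < 4; ++k) {
        double apk = A(p, k), aqk = A(q, k);
        A(p, k) = c * apk - s * aqk;
        A(q, k) = s * apk + c * aqk;
      }
      for (int k = 0; k < 4; ++k) {
        double vkp = evec(k, p), vkq = evec(k, q);
        evec(k, p) = c * vkp - s * vkq;
        evec(k, q) = s * vkp + c * vkq;
      }
    }
  }
  int ord[4] = {0, 1, 2, 3};
  for (int a = 0; a < 3; ++a)              // insertion sort by eigenvalue
    for (int b = a + 1; b < 4; ++b)
      if (A(ord[b], ord[b]) < A(ord[a], ord[a])) std::swap(ord[a], ord[b]);
  arma::mat44 ev = evec;
  for (int k = 0; k < 4; ++k) {
    eval(k) = A(ord[k], ord[k]);
    evec.col(k) = ev.col(ord[k]);
  }
}

static FitResult best_fit(const arma::mat& Y, const arma::mat& Z) {
  FitResult fr;
  arma::mat33 S(arma::fill::zeros);
  for (arma::uword i = 0; i < Y.n_rows; ++i)
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) S(a, b) += Z(i, a) * Y(i, b);
  arma::mat44 N = horn_matrix(S);
  jacobi4(N, fr.eval, fr.evec);         // ascending
  fr.q = fr.evec.col(3);
  if (fr.q(0) < 0) { fr.q = -fr.q; fr.evec.col(3) = fr.q; }
  fr.R = quat_to_rot(fr.q);
  double scale = std::max(1.0, std::abs(fr.eval(3)));
  fr.degenerate = (fr.eval(3) - fr.eval(2)) < 1e-8 * scale;
  return fr;
}

// dR/dq as four 3x3 matrices
static void rot_jacobian(const arma::vec4& q, arma::mat33 dR[4]) {
  double q0 = q(0), q1 = q(1), q2 = q(2), q3 = q(3);
  const double v0[9] = { 2*q0, -2*q3,  2*q2,  2*q3,  2*q0, -2*q1, -2*q2,  2*q1,  2*q0};
  const double v1[9] = { 2*q1,  2*q2,  2*q3,  2*q2, -2*q1, -2*q0,  2*q3,  2*q0, -2*q1};
  const double v2[9] = {-2*q2,  2*q1,  2*q0,  2*q1,  2*q2,  2*q3, -2*q0,  2*q3, -2*q2};
  const double v3[9] = {-2*q3, -2*q0,  2*q1,  2*q0, -2*q3,  2*q2,  2*q1,  2*q2,  2*q3};
  const double* v[4] = {v0, v1, v2, v3};
  for (int m = 0; m < 4; ++m)
    for (int r = 0; r < 3; ++r)
      for (int cidx = 0; cidx < 3; ++cidx) dR[m](r, cidx) = v[m][3 * r + cidx];
}

struct CVOut { double value; arma::mat grad; bool flag; };

static CVOut euler_from_fit(const CVSpec& c, const FitResult& fr, int n);

// full CV evaluation with gradient over all n atoms (zero rows outside subset)
static CVOut cv_eval(const CVSpec& c, const arma::mat& X) {
  CVOut out; out.flag = false;
  int n = X.n_rows;
  out.grad.zeros(n, 3);
  const arma::uvec& idx = c.atoms;
  int k = idx.n_elem;
  double M = arma::accu(c.amass);

  if (c.kind == "separation" || c.kind == "theta" || c.kind == "phi" ||
      c.kind == "axis_projection") {
    arma::rowvec com(3, arma::fill::zeros);
    for (int i = 0; i < k; ++i) com += c.amass(i) / M * X.row(idx(i));
    arma::vec v = com.t() - c.origin;
    if (c.kind == "separation") {
      double r = arma::norm(v);
      out.value = r;
      if (r < 1e-10) { out.flag = true; return out; }
      arma::rowvec u = (v / r).t();
      for (int i = 0; i < k; ++i) out.grad.row(idx(i)) = c.amass(i) / M * u;
      return out;
    }
    if (c.kind == "axis_projection") {
      arma::vec uw = c.A.t() * c.axis;   // host-frame axis in world coords
      out.value = arma::dot(v, uw);
      for (int i = 0; i < k; ++i) out.grad.row(idx(i)) = c.amass(i) / M * uw.t();
      return out;
    }
    arma::vec vh = c.A * v;
    double rho2 = vh(0) * vh(0) + vh(1) * vh(1), rho = std::sqrt(rho2);
    double r2 = rho2 + vh(2) * vh(2);
    arma::vec dAdv(3, arma::fill::zeros);
    if (c.kind == "theta") {
      out.value = std::atan2(rho, vh(2)) / D2R;
      if (rho < 1e-10 || r2 < 1e-18) { out.flag = true; return out; }
      dAdv(0) = vh(2) * vh(0) / (rho * r2);
      dAdv(1) = vh(2) * vh(1) / (rho * r2);
      dAdv(2) = -rho / r2;
    } else { // phi
      if (rho < 1e-10) { out.flag = true; out.value = 0.0; return out; }
      out.value = std::atan2(vh(1), vh(0)) / D2R;
      dAdv(0) = -vh(1) / rho2;
      dAdv(1) =  vh(0) / rho2;
    }
    arma::rowvec g = (c.A.t() * dAdv).t() / D2R;
    for (int i = 0; i < k; ++i) out.grad.row(idx(i)) = c.amass(i) / M * g;
    return out;
  }

  if (c.kind == "bond") {
    arma::rowvec d = X.row(idx(0)) - X.row(idx(1));
    double r = std::sqrt(arma::dot(d, d));
    out.value = r;
    if (r < 1e-10) { out.flag = true; return out; }
    out.grad.row(idx(0)) =  d / r;
    out.grad.row(idx(1)) = -d / r;
    return out;
  }

  if (c.kind == "dihedral") {
    arma::rowvec g[4]; bool ok;
    double phi = dihedral_raw(X.row(idx(0)), X.row(idx(1)),
                              X.row(idx(2)), X.row(idx(3)), g, ok);
    out.flag = !ok;
    double deg = phi / D2R;
    if (deg <= -180.0) deg += 360.0;
    out.value = deg;
    for (int i = 0; i < 4; ++i) out.grad.row(idx(i)) = g[i] / D2R;
    return out;
  }

  if (c.kind == "rmsd") {
    arma::mat Y(k, 3);
    for (int i = 0; i < k; ++i) Y.row(i) = X.row(idx(i));
    if (c.rmsd_mode == 1) { // distance-matrix RMSD
      if (k < 2) stop("distance-matrix RMSD needs at least 2 atoms");
      double np = k * (k - 1) / 2.0, ss = 0.0;
      arma::mat g(k, 3, arma::fill::zeros);
      for (int i = 0; i < k; ++i) for (int j = i + 1; j < k; ++j) {
        arma::rowvec dv = Y.row(i) - Y.row(j);
        double dij = std::sqrt(arma::dot(dv, dv));
        double eij = arma::norm(c.ref.row(i) - c.ref.row(j));
        ss += (dij - eij) * (dij - eij);
        if (dij > 1e-12) {
          arma::rowvec t = (dij - eij) * dv / dij;
          g.row(i) += t; g.row(j) -= t;
        }
      }
      double D = std::sqrt(ss / np);
      out.value = D;
      if (D < 1e-12) { out.flag = true; return out; }
      for (int i = 0; i < k; ++i) out.grad.row(idx(i)) = g.row(i) / (np * D);
      return out;
    }
    arma::mat Yc = Y.each_row() - arma::mean(Y, 0);
    FitResult fr = best_fit(Yc, c.ref);
    arma::mat Dm = Yc - c.ref * fr.R.t();
    double rmsd = std::sqrt(arma::accu(Dm % Dm) / k);
    out.value = rmsd;
    if (rmsd < 1e-12) { out.flag = true; return out; }
    for (int i = 0; i < k; ++i) out.grad.row(idx(i)) = Dm.row(i) / (k * rmsd);
    return out;
  }

  if (c.kind == "Theta" || c.kind == "Phi" || c.kind == "Psi") {
    arma::mat Y(k, 3);
    for (int i = 0; i < k; ++i) Y.row(i) = X.row(idx(i));
    arma::mat Yc = Y.each_row() - arma::mean(Y, 0);
    FitResult fr = best_fit(Yc, c.ref);
    return euler_from_fit(c, fr, n);
  }

  stop("unknown collective variable kind '" + c.kind + "'");
}

// Euler angles + gradients given a precomputed best-fit (shared across the
// three angle restraints acting on the same selection)
static CVOut euler_from_fit(const CVSpec& c, const FitResult& fr, int n) {
  CVOut out; out.flag = false;
  out.grad.zeros(n, 3);
  const arma::uvec& idx = c.atoms;
  int k = idx.n_elem;
  {
    if (fr.degenerate) { out.flag = true; }
    arma::mat33 Am(c.A);
    arma::mat33 Rh = Am * fr.R;   // reference -> host-frame rotation
    double st2 = Rh(0,2)*Rh(0,2) + Rh(1,2)*Rh(1,2); // sin^2(Theta)
    bool lock = st2 < 1e-14;
    double Theta = std::atan2(std::sqrt(st2), Rh(2,2));
    double Phi, Psi;
    if (lock) {
      Phi = 0.0;
      Psi = std::atan2(-Rh(0,1), Rh(0,0));   // Theta ~ 0 convention
      if (Rh(2,2) < 0) Psi = std::atan2(Rh(0,1), -Rh(0,0));
    } else {
      Phi = std::atan2(Rh(1,2), Rh(0,2));
      Psi = std::atan2(Rh(2,1), -Rh(2,0));
    }
    double val;
    if (c.kind == "Theta") val = Theta;
    else if (c.kind == "Phi") val = Phi;
    else val = Psi;
    out.value = val / D2R;
    if (out.value <= -180.0) out.value += 360.0;
    if (lock && c.kind != "Theta") { out.flag = true; if (c.kind=="Phi") out.value = 0.0; }
    if (fr.degenerate || lock) return out;   // gradients undefined/degenerate

    // d(angle)/dRh as a 3x3 selection
    arma::mat33 dAdR(arma::fill::zeros);
    if (c.kind == "Theta") {
      double st = std::sqrt(st2), den = st2 + Rh(2,2)*Rh(2,2);
      dAdR(0,2) = Rh(2,2) * Rh(0,2) / (st * den);
      dAdR(1,2) = Rh(2,2) * Rh(1,2) / (st * den);
      dAdR(2,2) = -st / den;
    } else if (c.kind == "Phi") {
      dAdR(0,2) = -Rh(1,2) / st2;
      dAdR(1,2) =  Rh(0,2) / st2;
    } else {
      double den = Rh(2,0)*Rh(2,0) + Rh(2,1)*Rh(2,1);
      dAdR(2,0) =  Rh(2,1) / den;
      dAdR(2,1) = -Rh(2,0) / den;
    }
    // chain through Rh = A R :  dval/dR = A^T dAdR
    arma::mat33 dAdRw = Am.t() * dAdR;
    arma::mat33 dRq[4];
    rot_jacobian(fr.q, dRq);
    arma::vec4 dval_dq;
    for (int m = 0; m < 4; ++m) dval_dq(m) = arma::accu(dAdRw % dRq[m]);
    // eigenvector perturbation: dq = sum_m v_m v_m^T/(l3-l_m) dN q,
    // contracted with dval/dq into w
    arma::vec4 w(arma::fill::zeros);
    for (int m = 0; m < 3; ++m)
      w += fr.evec.col(m) *
        (arma::dot(fr.evec.col(m), dval_dq) / (fr.eval(3) - fr.eval(m)));
    // dval/dS_ab = w^T horn(E_ab) q, expanded analytically: grad_j = z_j^T C
    const double w0 = w(0), w1 = w(1), w2 = w(2), w3 = w(3);
    const double q0 = fr.q(0), q1 = fr.q(1), q2 = fr.q(2), q3 = fr.q(3);
    arma::mat33 Cm;
    Cm(0,0) =  w0*q0 + w1*q1 - w2*q2 - w3*q3;
    Cm(1,1) =  w0*q0 - w1*q1 + w2*q2 - w3*q3;
    Cm(2,2) =  w0*q0 - w1*q1 - w2*q2 + w3*q3;
    Cm(1,2) =  (w0*q1 + w1*q0) + (w2*q3 + w3*q2);
    Cm(2,1) = -(w0*q1 + w1*q0) + (w2*q3 + w3*q2);
    Cm(2,0) =  (w0*q2 + w2*q0) + (w1*q3 + w3*q1);
    Cm(0,2) = -(w0*q2 + w2*q0) + (w1*q3 + w3*q1);
    Cm(0,1) =  (w0*q3 + w3*q0) + (w1*q2 + w2*q1);
    Cm(1,0) = -(w0*q3 + w3*q0) + (w1*q2 + w2*q1);
    for (int j = 0; j < k; ++j)
      for (int beta = 0; beta < 3; ++beta)
        out.grad(idx(j), beta) =
          (c.ref(j, 0) * Cm(0, beta) + c.ref(j, 1) * Cm(1, beta) +
           c.ref(j, 2) * Cm(2, beta)) / D2R;
    return out;
  }
}

// [[Rcpp::export(name = ".cpp_cv_eval")]]
List cpp_cv_eval(List cv, arma::mat X, arma::vec masses) {
  CVSpec c = parse_cv(cv, masses);
  CVOut o = cv_eval(c, X);
  return List::create(_["value"] = o.value, _["grad"] = o.grad,
                      _["degenerate"] = o.flag);
}

// batch evaluation over many configurations (cube slices) for quadrature /
// Monte-Carlo oracles: returns an (n_config x n_cv) matrix of CV values
// [[Rcpp::export(name = ".cpp_cv_batch")]]
arma::mat cpp_cv_batch(List cvs, arma::cube X, arma::vec masses) {
  std::vector<CVSpec> cs;
  for (int i = 0; i < cvs.size(); ++i)
    cs.push_back(parse_cv(as<List>(cvs[i]), masses));
  arma::mat out(X.n_slices, cs.size());
  for (arma::uword s = 0; s < X.n_slices; ++s)
    for (size_t c = 0; c < cs.size(); ++c)
      out(s, c) = cv_eval(cs[c], X.slice(s)).value;
  return out;
}

// batch potential energies
// [[Rcpp::export(name = ".cpp_energy_batch")]]
arma::vec cpp_energy_batch(List sys, arma::cube X) {
  SystemC s = parse_system(sys);
  arma::vec out(X.n_slices);
  for (arma::uword i = 0; i < X.n_slices; ++i)
    out(i) = system_energy(s, X.slice(i), nullptr);
  return out;
}

// [[Rcpp::export(name = ".cpp_best_fit_rotation")]]
List cpp_best_fit(arma::mat moving, arma::mat ref) {
  arma::mat Yc = moving.each_row() - arma::mean(moving, 0);
  arma::mat Zc = ref.each_row() - arma::mean(ref, 0);
  FitResult fr = best_fit(Yc, Zc);
  return List::create(_["R"] = arma::mat(fr.R), _["q"] = arma::vec(fr.q),
                      _["degenerate"] = fr.degenerate);
}

// [[Rcpp::export(name = ".cpp_potential_energy")]]
double cpp_potential_energy(List sys, arma::mat X) {
  SystemC s = parse_system(sys);
  if ((int)X.n_rows != s.n) stop("positions have %d rows; system has %d beads",
                                 X.n_rows, s.n);
  return system_energy(s, X, nullptr);
}

// [[Rcpp::export(name = ".cpp_forces")]]
List cpp_forces(List sys, arma::mat X) {
  SystemC s = parse_system(sys);
  if ((int)X.n_rows != s.n) stop("positions have %d rows; system has %d beads",
                                 X.n_rows, s.n);
  arma::mat f(s.n, 3, arma::fill::zeros);
  double u = system_energy(s, X, &f);
  return List::create(_["energy"] = u, _["forces"] = f);
}

// ---------------------------------------------------------------------------
// Restraints
// ---------------------------------------------------------------------------

struct RestraintC {
  CVSpec cv;
  double center, k;
  int type;             // 0 harmonic, 1 upper wall, 2 lower wall
  bool moving;
  double c_from, c_to;
};

static std::vector<RestraintC> parse_restraints(const List& rl,
                                                const arma::vec& mass) {
  std::vector<RestraintC> out;
  for (int i = 0; i < rl.size(); ++i) {
    List r = as<List>(rl[i]);
    RestraintC rc;
    rc.cv = parse_cv(as<List>(r["cv"]), mass);
    rc.k = as<double>(r["k"]);
    rc.center = as<double>(r["center"]);
    std::string ty = r.containsElementNamed("type") ?
      as<std::string>(r["type"]) : "harmonic";
    rc.type = ty == "upper_wall" ? 1 : (ty == "lower_wall" ? 2 : 0);
    rc.moving = r.containsElementNamed("center_to") && !Rf_isNull(r["center_to"]);
    if (rc.moving) { rc.c_from = rc.center; rc.c_to = as<double>(r["center_to"]); }
    out.push_back(rc);
  }
  return out;
}

static bool is_euler_kind(const std::string& k) {
  return k == "Theta" || k == "Phi" || k == "Psi";
}

// periodic CVs take the minimum-image difference in restraint energies
static bool is_periodic_kind(const std::string& k) {
  return k == "phi" || k == "Phi" || k == "Psi" || k == "dihedral";
}

static double restraint_diff(const RestraintC& r, double value, double c0) {
  double d = value - c0;
  if (is_periodic_kind(r.cv.kind)) d -= 360.0 * std::round(d / 360.0);
  return d;
}

static double restraint_forces(const std::vector<RestraintC>& rs,
                               const arma::mat& X, arma::mat& F, double frac) {
  double u = 0.0;
  // the three Euler-angle restraints of one protocol stage act on the same
  // selection and reference: compute the optimal superposition once
  FitResult fit;
  const CVSpec* fit_cv = nullptr;
  for (const RestraintC& r : rs) {
    CVOut o;
    if (is_euler_kind(r.cv.kind)) {
      bool reuse = fit_cv != nullptr &&
        fit_cv->atoms.n_elem == r.cv.atoms.n_elem &&
        arma::all(fit_cv->atoms == r.cv.atoms) &&
        arma::approx_equal(fit_cv->ref, r.cv.ref, "absdiff", 0.0);
      if (!reuse) {
        int k = r.cv.atoms.n_elem;
        arma::mat Y(k, 3);
        for (int i = 0; i < k; ++i) Y.row(i) = X.row(r.cv.atoms(i));
        arma::mat Yc = Y.each_row() - arma::mean(Y, 0);
        fit = best_fit(Yc, r.cv.ref);
        fit_cv = &r.cv;
      }
      o = euler_from_fit(r.cv, fit, X.n_rows);
    } else {
      o = cv_eval(r.cv, X);
    }
    double c0 = r.moving ? r.c_from + (r.c_to - r.c_from) * frac : r.center;
    double d = restraint_diff(r, o.value, c0);
    if (r.type == 1 && d < 0) continue;
    if (r.type == 2 && d > 0) continue;
    u += 0.5 * r.k * d * d;
    F += (-r.k * d) * o.grad;
  }
  return u;
}

// ---------------------------------------------------------------------------
// Langevin dynamics (BAOAB)
// ---------------------------------------------------------------------------

struct Thermostat {
  double c1, c2;
  arma::vec sigv;       // per-bead velocity scale
};

static Thermostat make_thermostat(const arma::vec& mass, double T,
                                  double gamma, double dt) {
  Thermostat th;
  th.c1 = std::exp(-gamma * dt);
  th.c2 = std::sqrt(std::max(0.0, 1.0 - th.c1 * th.c1));
  th.sigv = arma::sqrt(KB * T / (mass * FKE));
  return th;
}

static void sample_velocities(arma::mat& V, const Thermostat& th) {
  for (arma::uword i = 0; i < V.n_rows; ++i)
    for (int b = 0; b < 3; ++b) V(i, b) = th.sigv(i) * norm_rand();
}

// [[Rcpp::export(name = ".cpp_run_md")]]
List cpp_run_md(List sys, arma::mat x0, Nullable<NumericMatrix> v0,
                List restraints, List cvs, int n_steps, double dt,
                double gamma, double temperature, int stride) {
  SystemC s = parse_system(sys);
  if ((int)x0.n_rows != s.n) stop("x0 shape mismatch");
  std::vector<RestraintC> rs = parse_restraints(restraints, s.mass);
  std::vector<CVSpec> obs;
  for (int i = 0; i < cvs.size(); ++i)
    obs.push_back(parse_cv(as<List>(cvs[i]), s.mass));

  Thermostat th = make_thermostat(s.mass, temperature, gamma, dt);
  arma::mat X = x0, V(s.n, 3);
  if (v0.isNotNull()) V = as<arma::mat>(v0.get()); else sample_velocities(V, th);

  arma::vec minv = 1.0 / (s.mass * FKE);
  arma::mat F(s.n, 3, arma::fill::zeros);
  double pe = system_energy(s, X, &F) + restraint_forces(rs, X, F, 0.0);

  int nrec = n_steps / std::max(stride, 1) + 1;
  arma::mat cvrec(nrec, obs.size());
  arma::vec perec(nrec), kerec(nrec), steprec(nrec);
  int irec = 0;
  auto record = [&](int step) {
    for (size_t c = 0; c < obs.size(); ++c)
      cvrec(irec, c) = cv_eval(obs[c], X).value;
    double ke = 0.0;
    for (int i = 0; i < s.n; ++i)
      ke += 0.5 * s.mass(i) * FKE * arma::dot(V.row(i), V.row(i));
    perec(irec) = pe; kerec(irec) = ke; steprec(irec) = step;
    ++irec;
  };
  record(0);

  for (int step = 1; step <= n_steps; ++step) {
    V += 0.5 * dt * (F.each_col() % minv);
    X += 0.5 * dt * V;
    if (th.c2 > 0) {
      for (int i = 0; i < s.n; ++i)
        for (int b = 0; b < 3; ++b)
          V(i, b) = th.c1 * V(i, b) + th.c2 * th.sigv(i) * norm_rand();
    } else {
      V *= th.c1;
    }
    X += 0.5 * dt * V;
    F.zeros();
    double frac = n_steps > 0 ? (double)step / n_steps : 0.0;
    pe = system_energy(s, X, &F) + restraint_forces(rs, X, F, frac);
    V += 0.5 * dt * (F.each_col() % minv);
    if (!X.is_finite())
      stop("NaN/Inf positions at step %d", step);
    if (stride > 0 && step % stride == 0) record(step);
  }
  return List::create(
    _["step"] = steprec.head(irec), _["cv"] = cvrec.head_rows(irec),
    _["potential"] = perec.head(irec), _["kinetic"] = kerec.head(irec),
    _["x_final"] = X, _["v_final"] = V, _["dt"] = dt);
}

// ---------------------------------------------------------------------------
// eABF engine
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_run_eabf")]]
List cpp_run_eabf(List sys, arma::mat x0, List cv, List restraints,
                  double lo, double hi, int nbins, double n_full,
                  double kc, double lambda_mass, double ext_gamma,
                  int n_steps, double dt, double gamma, double temperature,
                  int stride, int n_blocks, bool periodic) {
  double period = hi - lo;
  SystemC s = parse_system(sys);
  if ((int)x0.n_rows != s.n) stop("x0 shape mismatch");
  CVSpec c = parse_cv(cv, s.mass);
  std::vector<RestraintC> rs = parse_restraints(restraints, s.mass);
  double bw = (hi - lo) / nbins;
  if (nbins < 2) stop("eABF grid needs at least 2 bins");
  if (n_blocks < 1) n_blocks = 1;

  Thermostat th = make_thermostat(s.mass, temperature, gamma, dt);
  double c1l = std::exp(-ext_gamma * dt);
  double c2l = std::sqrt(std::max(0.0, 1.0 - c1l * c1l));
  double sigl = std::sqrt(KB * temperature / (lambda_mass * FKE));
  double minvl = 1.0 / (lambda_mass * FKE);

  arma::mat X = x0, V(s.n, 3);
  sample_velocities(V, th);
  arma::vec minv = 1.0 / (s.mass * FKE);

  auto wrapd = [&](double d) {        // coupling difference, periodic-aware
    if (periodic) d -= period * std::round(d / period);
    return d;
  };
  auto confine = [&](double& l, double& vl) {
    if (periodic) {
      while (l < lo) l += period;
      while (l >= hi) l -= period;
    } else {
      if (l < lo) { l = 2 * lo - l; vl = -vl; }
      if (l > hi) { l = 2 * hi - l; vl = -vl; }
    }
  };
  CVOut o = cv_eval(c, X);
  double lam = o.value;
  if (periodic) {
    lam -= period * std::floor((lam - lo) / period);
    lam = std::min(hi - 1e-9, std::max(lo, lam));
  } else {
    lam = std::min(hi - 0.5 * bw, std::max(lo + 0.5 * bw, lam));
  }
  double vlam = sigl * norm_rand();

  arma::vec cnt(nbins, arma::fill::zeros), fsum(nbins, arma::fill::zeros);
  arma::vec zcnt(nbins, arma::fill::zeros), zsum(nbins, arma::fill::zeros);
  arma::mat bcnt(n_blocks, nbins, arma::fill::zeros),
            bfsum(n_blocks, nbins, arma::fill::zeros),
            bzcnt(n_blocks, nbins, arma::fill::zeros),
            bzsum(n_blocks, nbins, arma::fill::zeros);

  arma::mat F(s.n, 3, arma::fill::zeros);
  system_energy(s, X, &F);
  restraint_forces(rs, X, F, 0.0);
  F += (-kc * wrapd(o.value - lam)) * o.grad;
  double flam = kc * wrapd(o.value - lam);

  int nrec = stride > 0 ? n_steps / stride : 0;
  arma::vec xirec(std::max(nrec, 1)), lamrec(std::max(nrec, 1));
  int irec = 0;

  for (int step = 1; step <= n_steps; ++step) {
    // B
    V += 0.5 * dt * (F.each_col() % minv);
    vlam += 0.5 * dt * flam * minvl;
    // A
    X += 0.5 * dt * V;
    lam += 0.5 * dt * vlam;
    confine(lam, vlam);
    // O
    if (th.c2 > 0) {
      for (int i = 0; i < s.n; ++i)
        for (int b = 0; b < 3; ++b)
          V(i, b) = th.c1 * V(i, b) + th.c2 * th.sigv(i) * norm_rand();
      vlam = c1l * vlam + c2l * sigl * norm_rand();
    } else { V *= th.c1; vlam *= c1l; }
    // A
    X += 0.5 * dt * V;
    lam += 0.5 * dt * vlam;
    confine(lam, vlam);
    // force update + accumulation + B
    F.zeros();
    system_energy(s, X, &F);
    restraint_forces(rs, X, F, 0.0);
    o = cv_eval(c, X);
    double dlx = wrapd(o.value - lam);
    F += (-kc * dlx) * o.grad;
    double finst = kc * dlx;

    int b = (int)((lam - lo) / bw);
    if (b < 0) b = 0;
    if (b >= nbins) b = nbins - 1;
    int blk = std::min(n_blocks - 1, (int)((step - 1.0) * n_blocks / n_steps));
    cnt(b) += 1.0; fsum(b) += finst;
    bcnt(blk, b) += 1.0; bfsum(blk, b) += finst;
    double zx = o.value;
    if (periodic) zx -= period * std::floor((zx - lo) / period);
    int zb = (int)((zx - lo) / bw);
    if (zb >= 0 && zb < nbins) {
      // store lambda relative to the bin centre (periodic-safe)
      double dl = wrapd(lam - (lo + (zb + 0.5) * bw));
      zcnt(zb) += 1.0; zsum(zb) += dl;
      bzcnt(blk, zb) += 1.0; bzsum(blk, zb) += dl;
    }
    double ramp = std::min(1.0, cnt(b) / n_full);
    flam = finst - ramp * (fsum(b) / cnt(b));

    vlam += 0.5 * dt * flam * minvl;
    V += 0.5 * dt * (F.each_col() % minv);
    if (!X.is_finite() || !std::isfinite(lam))
      stop("NaN/Inf encountered in eABF at step %d", step);
    if (stride > 0 && step % stride == 0 && irec < nrec) {
      xirec(irec) = o.value; lamrec(irec) = lam; ++irec;
    }
  }

  return List::create(
    _["centers"] = lo + bw * (arma::regspace(0, nbins - 1) + 0.5),
    _["count"] = cnt, _["force_sum"] = fsum,
    _["z_count"] = zcnt, _["z_lambda_sum"] = zsum,
    _["block_count"] = bcnt, _["block_force_sum"] = bfsum,
    _["block_z_count"] = bzcnt, _["block_z_lambda_sum"] = bzsum,
    _["xi_series"] = xirec.head(irec), _["lambda_series"] = lamrec.head(irec),
    _["x_final"] = X, _["lambda_final"] = lam,
    _["lo"] = lo, _["hi"] = hi, _["bin_width"] = bw);
}
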